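# Synthetic-data generators emulating a two-group (NC vs VT), three-generation
# (F1/F2/F3) embryo cryopreservation-transfer study: phenotype tables,
# negative-binomial RNA-seq count matrices and log-normal targeted-metabolite
# intensity tables. Every generated object carries a ground-truth sidecar
# (attribute "truth") consumed only by tests, never by pipeline stages.

#' Configuration for the phenotype-table generator
#'
#' Defaults reproduce the scale of the study design: ~30 adult males per group
#' per generation, growth/weight traits with group shifts at the published
#' scale (adult body weight deficit of 437.4 g in F1, 249.5 g in F2 and
#' 247.9 g in F3 for the vitrified-transferred group), and within-group SDs
#' back-computed from the printed standard errors of the group contrasts
#' (SD = SE / sqrt(1/n1 + 1/n2) with n1 = 35, n2 = 30).
#'
#' @param n_per_group_per_generation animals per group within each generation.
#' @param trait_means named numeric vector, trait -> mean (trait units).
#' @param trait_sds named numeric vector, trait -> within-group SD (> 0).
#' @param group_deltas named list, trait -> named numeric vector over
#'   generations, giving the NC-minus-VT shift in trait units. VT animals are
#'   simulated at `mean - delta`; missing entries mean no shift.
#' @param covariate_slope slope (trait units per gram of adult body weight)
#'   applied to the traits listed in `covariate_traits`.
#' @param covariate_traits character vector of traits receiving the body
#'   weight covariate effect (typically organ weights).
#' @param bodyweight_mean,bodyweight_sd distribution of the adult body-weight
#'   covariate (grams), drawn independently per animal.
#' @param generations generations to simulate.
#' @param seed integer seed; each (generation, group) block uses an
#'   independent sub-stream via [sub_seed()], so adding a generation leaves
#'   earlier draws untouched.
#' @return an object of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(n_per_group_per_generation = 30L,
                             trait_means = c(weaning_weight = 700,
                                             prepubertal_weight = 1750,
                                             adult_weight = 4500,
                                             awg = 30),
                             trait_sds = c(weaning_weight = 152,
                                           prepubertal_weight = 311,
                                           adult_weight = 616.7,
                                           awg = 5.39),
                             group_deltas = list(
                               weaning_weight = c(F1 = 62.2),
                               prepubertal_weight = c(F1 = 370.1, F2 = 139.3, F3 = 287.9),
                               adult_weight = c(F1 = 437.4, F2 = 249.5, F3 = 247.9),
                               awg = c(F1 = 8.6, F2 = 4.7, F3 = 6.6)),
                             covariate_slope = 0,
                             covariate_traits = character(0),
                             bodyweight_mean = 4500,
                             bodyweight_sd = 616.7,
                             generations = .GENERATIONS,
                             seed = 1L) {
  check_scalar_number(n_per_group_per_generation, "n_per_group_per_generation",
                      positive = TRUE, integer = TRUE)
  if (!length(trait_means) || is.null(names(trait_means)))
    config_error("trait_means must be a named numeric vector")
  if (!setequal(names(trait_means), names(trait_sds)))
    config_error("trait_means and trait_sds must name the same traits")
  if (any(!is.finite(trait_sds)) || any(trait_sds <= 0))
    config_error("all trait_sds must be finite and > 0")
  check_in(generations, .GENERATIONS, "generations")
  check_in(names(group_deltas), names(trait_means), "group_deltas traits")
  for (tr in names(group_deltas))
    check_in(names(group_deltas[[tr]]), .GENERATIONS,
             paste0("group_deltas[[", tr, "]] generations"))
  check_in(covariate_traits, names(trait_means), "covariate_traits")
  check_scalar_number(covariate_slope, "covariate_slope")
  check_scalar_number(bodyweight_sd, "bodyweight_sd", positive = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n = as.integer(n_per_group_per_generation),
                 trait_means = trait_means, trait_sds = trait_sds,
                 group_deltas = group_deltas,
                 covariate_slope = covariate_slope,
                 covariate_traits = covariate_traits,
                 bodyweight_mean = bodyweight_mean,
                 bodyweight_sd = bodyweight_sd,
                 generations = as.character(generations),
                 seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Generate a long-format phenotype trait table
#'
#' For each generation and group, simulates `n` animals with
#' `value = mean - delta * [group == VT] + slope * (bodyweight - mean bw) + N(0, sd)`.
#' Deterministic given the config seed.
#'
#' @param config a [pheno_sim_config()].
#' @return a `data.frame` with columns `animal_id`, `group`, `generation`,
#'   `trait`, `value`, `covariate`, plus a `truth` attribute (data.frame of
#'   trait, generation, true_delta) for test use only.
#' @export
gen_phenotype_table <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  traits <- names(config$trait_means)
  out <- vector("list", 0L)
  for (gen in config$generations) {
    for (grp in .GROUPS) {
      set.seed(sub_seed(config$seed, "phenotype", gen, grp))
      n <- config$n
      ids <- sprintf("%s_%s_%03d", gen, grp, seq_len(n))
      bw <- stats::rnorm(n, config$bodyweight_mean, config$bodyweight_sd)
      for (tr in traits) {
        delta <- 0
        d <- config$group_deltas[[tr]]
        if (!is.null(d) && gen %in% names(d)) delta <- unname(d[[gen]])
        mu <- config$trait_means[[tr]] - delta * (grp == "VT")
        val <- mu + stats::rnorm(n, 0, config$trait_sds[[tr]])
        if (tr %in% config$covariate_traits)
          val <- val + config$covariate_slope * (bw - config$bodyweight_mean)
        out[[length(out) + 1L]] <- data.frame(
          animal_id = ids, group = grp, generation = gen, trait = tr,
          value = val, covariate = bw, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  truth <- do.call(rbind, lapply(names(config$group_deltas), function(tr) {
    d <- config$group_deltas[[tr]]
    data.frame(trait = tr, generation = names(d), true_delta = unname(d),
               stringsAsFactors = FALSE)
  }))
  attr(tab, "truth") <- truth
  tab
}

#' Configuration for the RNA-seq count-matrix generator
#'
#' The defaults are a desk-scale stand-in for the study's liver RNA-seq
#' (13k-14k expressed genes, ~65M reads, 3-5 animals per group): 2,000 genes,
#' 4 samples per group, library sizes around 1M and a 5% differentially
#' expressed fraction (642 of ~13,300 expressed genes is ~4.8%). Only the
#' relative statistical structure matters downstream.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (NC and VT).
#' @param de_fraction expected fraction of genes that are truly differentially
#'   expressed, in \[0, 1\].
#' @param log2fc_magnitude absolute log2 fold change of DE genes.
#' @param de_up_fraction fraction of DE genes upregulated in VT (default 0.5).
#' @param nb_dispersion negative-binomial dispersion (var = mu + phi mu^2).
#' @param library_size_range length-2 integer range of per-sample library sizes.
#' @param gene_length_bp fixed gene length for the FPKM view.
#' @param seed integer seed.
#' @return an object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 2000L, n_per_group = 4L,
                            de_fraction = 0.05, log2fc_magnitude = 2,
                            de_up_fraction = 0.5, nb_dispersion = 0.1,
                            library_size_range = c(8e5, 1.2e6),
                            gene_length_bp = 1000, seed = 1L) {
  check_scalar_number(n_genes, "n_genes", positive = TRUE, integer = TRUE)
  check_scalar_number(n_per_group, "n_per_group", positive = TRUE, integer = TRUE)
  check_scalar_number(de_fraction, "de_fraction")
  if (de_fraction < 0 || de_fraction > 1)
    config_error("de_fraction must lie in [0, 1]")
  check_scalar_number(log2fc_magnitude, "log2fc_magnitude", positive = TRUE)
  check_scalar_number(nb_dispersion, "nb_dispersion", positive = TRUE)
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    config_error("library_size_range must be an increasing pair of positive sizes")
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 de_fraction = de_fraction,
                 log2fc_magnitude = log2fc_magnitude,
                 de_up_fraction = de_up_fraction,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 gene_length_bp = gene_length_bp,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Construct an expression-matrix container
#'
#' Bundles counts, an FPKM view (`counts * 1e9 / (libsize * length)`), and the
#' sample-to-group map; the canonical input of [call_dets()].
#'
#' @param counts gene x sample matrix of non-negative integers with row and
#'   column names.
#' @param group_of named character vector sample -> "NC"/"VT".
#' @param gene_length_bp per-gene length in bp (scalar or named vector).
#' @param fpkm optional precomputed FPKM matrix (same dimnames as counts).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, group_of, gene_length_bp = 1000,
                              fpkm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    config_error("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(!is.finite(counts)))
    config_error("counts must be finite and non-negative")
  if (!all(colnames(counts) %in% names(group_of)))
    config_error("every sample needs a group label: missing ",
                 paste(setdiff(colnames(counts), names(group_of)), collapse = ", "))
  group_of <- group_of[colnames(counts)]
  check_in(group_of, .GROUPS, "group_of")
  len <- if (length(gene_length_bp) == 1L)
    stats::setNames(rep(gene_length_bp, nrow(counts)), rownames(counts))
  else gene_length_bp[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    config_error("gene lengths must be positive for all genes")
  if (is.null(fpkm)) {
    libsize <- colSums(counts)
    fpkm <- sweep(counts, 2, libsize, "/") * 1e9 / len
  }
  if (any(!is.finite(fpkm)))
    config_error("FPKM view contains non-finite values")
  structure(list(counts = counts, fpkm = fpkm,
                 group_of = group_of, gene_length_bp = len,
                 gene_ids = rownames(counts), sample_ids = colnames(counts)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples (",
      sum(x$group_of == "NC"), "NC /", sum(x$group_of == "VT"), "VT )\n")
  invisible(x)
}

#' Generate a negative-binomial expression matrix with known DE structure
#'
#' Baseline relative abundances are drawn log-normal and renormalised; DE
#' genes get a symmetric half-shift in each group (`2^(+lfc/2)` in the
#' upregulated group, `2^(-lfc/2)` in the other) so the total fold change is
#' `2^lfc`. Counts are `rnbinom(mu = libsize * abundance, size = 1/dispersion)`.
#'
#' @param config an [expr_sim_config()].
#' @return an `expression_matrix` with a `truth` attribute
#'   (gene_id, is_de, true_log2fc with VT-over-NC sign).
#' @export
gen_expression_matrix <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(sub_seed(config$seed, "expression"))
  G <- config$n_genes; n <- config$n_per_group
  genes <- sprintf("gene_%05d", seq_len(G))
  samples <- c(sprintf("NC_%d", seq_len(n)), sprintf("VT_%d", seq_len(n)))
  group <- stats::setNames(rep(.GROUPS, each = n), samples)

  rel <- exp(stats::rnorm(G, meanlog_abundance(), 1.2))
  rel <- rel / sum(rel)
  is_de <- stats::runif(G) < config$de_fraction
  sign_up <- ifelse(stats::runif(G) < config$de_up_fraction, 1, -1)  # sign in VT
  lfc <- ifelse(is_de, sign_up * config$log2fc_magnitude, 0)

  libsize <- round(stats::runif(2 * n, config$library_size_range[1],
                                config$library_size_range[2]))
  mu_nc <- rel * 2^(-lfc / 2)
  mu_vt <- rel * 2^(+lfc / 2)
  mu <- cbind(matrix(mu_nc, G, n), matrix(mu_vt, G, n))
  mu <- sweep(mu, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(G * 2 * n, mu = mu, size = 1 / config$nb_dispersion),
                   G, 2 * n, dimnames = list(genes, samples))
  em <- expression_matrix(counts, group, gene_length_bp = config$gene_length_bp)
  attr(em, "truth") <- data.frame(gene_id = genes, is_de = is_de,
                                  true_log2fc = lfc, stringsAsFactors = FALSE)
  em
}

# log-scale centre for baseline abundances; arbitrary (normalised away)
meanlog_abundance <- function() 0

#' Configuration for the targeted-metabolite table generator
#'
#' Defaults emulate the study's targeted LC-MS design: two fractions
#' (semi-polar, non-polar), 3 biological replicates per group (each a pool of
#' 4 animals), one internal standard per fraction (formononetin; DL-alpha-
#' tocopherol acetate), and fraction-level mean log2 fold changes at the
#' published F1 scale (+0.22 semi-polar, -0.36 non-polar, VT over NC sign
#' convention). `noise_cv` is the technical CV of normalised peak areas; 0.03
#' reflects pooled biological replicates under internal-standard
#' normalisation.
#'
#' @param n_metabolites_per_fraction named integer vector fraction -> count
#'   (excludes the internal standards, which are added on top).
#' @param n_replicates biological replicates per group.
#' @param dam_fraction fraction of metabolites that are truly differentially
#'   accumulated, in \[0, 1\].
#' @param fraction_log2fc_mean named numeric, fraction -> mean log2 fold
#'   change (VT over NC) of its true DAMs.
#' @param noise_cv multiplicative coefficient of variation per measured cell.
#' @param internal_standard_names length-2 character vector, standards for
#'   the semi-polar and non-polar fraction respectively.
#' @param generation generation label attached to the samples.
#' @param seed integer seed.
#' @return an object of class `metab_sim_config`.
#' @export
metab_sim_config <- function(n_metabolites_per_fraction = c("semi-polar" = 150L,
                                                            "non-polar" = 100L),
                             n_replicates = 3L, dam_fraction = 0.3,
                             fraction_log2fc_mean = c("semi-polar" = 0.22,
                                                      "non-polar" = -0.36),
                             noise_cv = 0.03,
                             internal_standard_names = c("formononetin",
                                                         "DL-alpha-tocopherol acetate"),
                             generation = "F1", seed = 1L) {
  check_in(names(n_metabolites_per_fraction), .FRACTIONS,
           "n_metabolites_per_fraction fractions")
  check_in(names(fraction_log2fc_mean), .FRACTIONS, "fraction_log2fc_mean fractions")
  if (any(n_metabolites_per_fraction < 1))
    config_error("need at least one metabolite per fraction")
  check_scalar_number(n_replicates, "n_replicates", positive = TRUE, integer = TRUE)
  check_scalar_number(dam_fraction, "dam_fraction")
  if (dam_fraction < 0 || dam_fraction > 1)
    config_error("dam_fraction must lie in [0, 1]")
  check_scalar_number(noise_cv, "noise_cv", positive = TRUE)
  if (length(internal_standard_names) != 2L)
    config_error("internal_standard_names must give one standard per fraction")
  check_in(generation, .GENERATIONS, "generation")
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_per_fraction = n_metabolites_per_fraction,
                 n_replicates = as.integer(n_replicates),
                 dam_fraction = dam_fraction,
                 fraction_log2fc_mean = fraction_log2fc_mean,
                 noise_cv = noise_cv,
                 internal_standard_names = internal_standard_names,
                 generation = generation, seed = as.integer(seed)),
            class = "metab_sim_config")
}

#' Construct a metabolite-table container
#'
#' @param intensities metabolite x sample matrix of positive reals with
#'   dimnames.
#' @param fraction_of named character vector metabolite -> fraction.
#' @param group_of named character vector sample -> "NC"/"VT".
#' @param generation_of named character vector sample -> generation.
#' @param internal_standards character vector of metabolite ids acting as
#'   internal standards (at most one per fraction).
#' @return an object of class `metabolite_table`.
#' @export
metabolite_table <- function(intensities, fraction_of, group_of, generation_of,
                             internal_standards = character(0)) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    config_error("intensities must have metabolite rownames and sample colnames")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    config_error("intensities must be finite and > 0")
  mets <- rownames(intensities); samples <- colnames(intensities)
  if (!all(mets %in% names(fraction_of)))
    config_error("every metabolite needs a fraction label")
  fraction_of <- fraction_of[mets]
  check_in(fraction_of, .FRACTIONS, "fraction_of")
  if (!all(samples %in% names(group_of)) || !all(samples %in% names(generation_of)))
    config_error("every sample needs group and generation labels")
  group_of <- group_of[samples]; generation_of <- generation_of[samples]
  check_in(group_of, .GROUPS, "group_of")
  check_in(generation_of, .GENERATIONS, "generation_of")
  if (!all(internal_standards %in% mets))
    config_error("internal_standards must be rows of the intensity matrix")
  structure(list(intensities = intensities, fraction_of = fraction_of,
                 group_of = group_of, generation_of = generation_of,
                 internal_standards = internal_standards,
                 metabolite_ids = mets, sample_ids = samples),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("metabolite_table:", length(x$metabolite_ids), "metabolites x",
      length(x$sample_ids), "samples;",
      length(x$internal_standards), "internal standard(s)\n")
  invisible(x)
}

#' Generate a log-normal targeted-metabolite intensity table
#'
#' Baseline intensities are log-normal per metabolite; true DAMs are shifted
#' by the fraction's configured mean log2 fold change in the VT group; every
#' measured cell (internal standards included) gets multiplicative log-normal
#' noise at `noise_cv`.
#'
#' @param config a [metab_sim_config()].
#' @return a `metabolite_table` including the internal-standard rows, with a
#'   `truth` attribute (metabolite_id, fraction, is_dam, true_log2fc).
#' @export
gen_metabolite_table <- function(config) {
  stopifnot(inherits(config, "metab_sim_config"))
  nrep <- config$n_replicates
  samples <- c(sprintf("NC_R%d", seq_len(nrep)), sprintf("VT_R%d", seq_len(nrep)))
  group <- stats::setNames(rep(.GROUPS, each = nrep), samples)
  gen_of <- stats::setNames(rep(config$generation, 2 * nrep), samples)
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  rows <- list(); fraction_of <- character(0); truth <- list()
  standards <- character(0)
  for (i in seq_along(.FRACTIONS)) {
    frac <- .FRACTIONS[i]
    if (!frac %in% names(config$n_per_fraction)) next
    set.seed(sub_seed(config$seed, "metabolome", config$generation, frac))
    m <- config$n_per_fraction[[frac]]
    ids <- sprintf("%s_met_%04d", gsub("-", "", frac), seq_len(m))
    base <- exp(stats::rnorm(m, log(1e6), 1))
    is_dam <- stats::runif(m) < config$dam_fraction
    lfc_frac <- if (frac %in% names(config$fraction_log2fc_mean))
      config$fraction_log2fc_mean[[frac]] else 0
    lfc <- ifelse(is_dam, lfc_frac, 0)
    mu <- outer(base, rep(1, 2 * nrep))
    mu[, group == "VT"] <- mu[, group == "VT"] * 2^lfc
    noise <- matrix(exp(stats::rnorm(m * 2 * nrep, -sdlog^2 / 2, sdlog)), m)
    x <- mu * noise
    rownames(x) <- ids; colnames(x) <- samples
    # internal standard: constant nominal amount up to the same noise
    std_id <- config$internal_standard_names[i]
    std <- exp(stats::rnorm(2 * nrep, -sdlog^2 / 2, sdlog)) * 1e5
    x <- rbind(x, matrix(std, 1, dimnames = list(std_id, samples)))
    rows[[frac]] <- x
    fraction_of <- c(fraction_of,
                     stats::setNames(rep(frac, m + 1L), c(ids, std_id)))
    standards <- c(standards, std_id)
    truth[[frac]] <- data.frame(metabolite_id = ids, fraction = frac,
                                is_dam = is_dam, true_log2fc = lfc,
                                stringsAsFactors = FALSE)
  }
  tab <- metabolite_table(do.call(rbind, rows), fraction_of, group, gen_of,
                          internal_standards = standards)
  attr(tab, "truth") <- do.call(rbind, unname(truth))
  tab
}
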