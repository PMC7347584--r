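# Umbrella pipeline: run the synthetic generators and/or the analysis stages
# in dependency order, write per-stage TSVs and a machine-readable JSON
# summary. Fully reproducible from (inputs, config, seed).

#' Pipeline run configuration
#'
#' Unknown keys are rejected; the effective configuration is echoed into the
#' run summary. When `simulate = TRUE` the synthetic generators provide every
#' stage input (sub-seeded per stage and generation from `seed`); otherwise
#' the file paths for the requested stages must be supplied.
#'
#' @param stages stages to run, subset of
#'   `c("simulate", "traits", "dets", "dams", "venn")`.
#' @param out_dir output directory (created if needed).
#' @param seed global seed; per-stage sub-seeds derive from it.
#' @param simulate generate synthetic inputs instead of reading files.
#' @param n_iter,burn_in,thin Gibbs settings (see [gibbs_config()]).
#' @param use_covariate covariate adjustment for the trait stage.
#' @param fdr_threshold DET FDR cutoff.
#' @param dam_alpha DAM p-value cutoff.
#' @param fold_change_scale `"log2"` or `"ratio"` for the fraction summary.
#' @param kinematics_dialect `"as-printed"` or `"conventional"` (derive stage).
#' @param pheno_config,expr_config,metab_config generator configs used when
#'   simulating (seeds are re-derived from `seed`).
#' @param traits_file,counts_file,groups_file,lengths_file file inputs for the
#'   trait/DET stages when not simulating.
#' @param intensities_file,meta_file,fractions_file,internal_standards
#'   metabolite-stage inputs when not simulating.
#' @param det_files named list (F1/F2/F3) of DET tables for a file-based venn
#'   stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "traits", "dets", "dams", "venn"),
                       out_dir = tempfile("cryofx_run_"), seed = 1L,
                       simulate = "simulate" %in% stages,
                       n_iter = 60000L, burn_in = 10000L, thin = 10L,
                       use_covariate = FALSE,
                       fdr_threshold = 0.05, dam_alpha = 0.05,
                       fold_change_scale = "log2",
                       kinematics_dialect = "as-printed",
                       pheno_config = NULL, expr_config = NULL,
                       metab_config = NULL,
                       traits_file = NULL, counts_file = NULL,
                       groups_file = NULL, lengths_file = NULL,
                       intensities_file = NULL, meta_file = NULL,
                       fractions_file = NULL,
                       internal_standards = character(0),
                       det_files = NULL) {
  check_in(stages, c("simulate", "traits", "dets", "dams", "venn"), "stages")
  check_scalar_number(seed, "seed", integer = TRUE)
  check_in(fold_change_scale, c("log2", "ratio"), "fold_change_scale")
  check_in(kinematics_dialect, c("as-printed", "conventional"),
           "kinematics_dialect")
  cfg <- structure(as.list(environment()), class = "run_config")
  # fail before any computation if a requested stage lacks its input
  if (!cfg$simulate) {
    need <- function(stage, files) {
      miss <- names(files)[vapply(files, is.null, TRUE)]
      if (stage %in% stages && length(miss))
        config_error("stage '", stage, "' requested without input(s): ",
                     paste(miss, collapse = ", "))
    }
    need("traits", list(traits_file = traits_file))
    need("dets", list(counts_file = counts_file, groups_file = groups_file))
    need("dams", list(intensities_file = intensities_file,
                      meta_file = meta_file, fractions_file = fractions_file))
    need("venn", list(det_files = det_files))
  }
  cfg
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order (simulate -> traits /
#' dets / dams -> venn), writes one TSV per stage output under
#' `config$out_dir`, and returns (and writes as `summary.json`) a summary of
#' relevance decisions, DET/DAM counts and Venn region sizes. Identical
#' (inputs, config, seed) give identical outputs.
#'
#' @param config a [run_config()].
#' @return the summary, invisibly (a named list, also at
#'   `<out_dir>/summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  summary <- list(config = list(
    stages = stages, seed = config$seed, simulate = config$simulate,
    n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
    fdr_threshold = config$fdr_threshold, dam_alpha = config$dam_alpha,
    fold_change_scale = config$fold_change_scale,
    kinematics_dialect = config$kinematics_dialect))
  path <- function(...) file.path(config$out_dir, paste0(...))

  pheno <- NULL; exprs <- list(); metabs <- list()
  if (config$simulate) {
    pcfg <- config$pheno_config %||% pheno_sim_config()
    pcfg$seed <- sub_seed(config$seed, "stage", "phenotype")
    pheno <- gen_phenotype_table(pcfg)
    write_table(pheno, path("phenotypes.tsv"))
    for (gen in .GENERATIONS) {
      ecfg <- config$expr_config %||% expr_sim_config()
      ecfg$seed <- sub_seed(config$seed, "stage", "expression", gen)
      exprs[[gen]] <- gen_expression_matrix(ecfg)
      write_expression_bundle(exprs[[gen]], path("expression_", gen))
      mcfg <- config$metab_config %||% metab_sim_config()
      mcfg$seed <- sub_seed(config$seed, "stage", "metabolome", gen)
      mcfg$generation <- gen
      metabs[[gen]] <- gen_metabolite_table(mcfg)
      write_metabolite_bundle(metabs[[gen]], path("metabolome_", gen))
    }
  }

  if ("traits" %in% stages) {
    if (is.null(pheno)) pheno <- read_trait_table(config$traits_file)
    gc <- gibbs_config(n_iter = config$n_iter, burn_in = config$burn_in,
                       thin = config$thin,
                       seed = sub_seed(config$seed, "stage", "traits"))
    trait_report <- compare_traits(pheno, use_covariate = config$use_covariate,
                                   config = gc)
    write_table(trait_report, path("trait_report.tsv"))
    trait_report$effect_class <- classify_effect(trait_report$generation)
    summary$relevance <- trait_report
  }

  det_sets <- NULL
  if ("dets" %in% stages) {
    if (config$simulate) {
      det_sets <- lapply(exprs, function(em) call_dets(em, config$fdr_threshold))
      for (gen in names(det_sets))
        write_table(det_sets[[gen]], path("dets_", gen, ".tsv"))
      summary$det_counts <- vapply(det_sets, nrow, 1L)
    } else {
      em <- read_expression_matrix(config$counts_file, config$groups_file,
                                   config$lengths_file)
      dets <- call_dets(em, config$fdr_threshold)
      write_table(dets, path("dets.tsv"))
      summary$det_counts <- nrow(dets)
    }
  }

  if ("dams" %in% stages) {
    dam_sets <- list()
    if (config$simulate) {
      for (gen in .GENERATIONS) {
        norm <- normalize_internal_standard(metabs[[gen]])
        dam_sets[[gen]] <- call_dams(norm, generation = gen,
                                     alpha = config$dam_alpha)
        write_table(dam_sets[[gen]], path("dams_", gen, ".tsv"))
      }
    } else {
      mt <- read_metabolite_table(config$intensities_file, config$meta_file,
                                  config$fractions_file,
                                  config$internal_standards)
      norm <- if (length(mt$internal_standards))
        normalize_internal_standard(mt) else mt
      for (gen in intersect(.GENERATIONS, unique(norm$generation_of))) {
        dam_sets[[gen]] <- call_dams(norm, generation = gen,
                                     alpha = config$dam_alpha)
        write_table(dam_sets[[gen]], path("dams_", gen, ".tsv"))
      }
    }
    summary$dam_counts <- vapply(dam_sets, function(d) sum(d$is_dam), 1L)
    summary$fraction_fold_change <- lapply(dam_sets, function(d)
      as.list(fraction_fold_change_summary(d, scale = config$fold_change_scale)))
  }

  if ("venn" %in% stages) {
    if (is.null(det_sets) && !is.null(config$det_files)) {
      det_sets <- lapply(config$det_files, function(f)
        read_table(f, columns = c(gene_id = "character",
                                  direction = "character")))
    }
    if (is.null(det_sets))
      config_error("venn stage needs DET sets (run 'dets' or give det_files)")
    vp <- venn_partition(det_sets[["F1"]]$gene_id, det_sets[["F2"]]$gene_id,
                         det_sets[["F3"]]$gene_id)
    region_tab <- do.call(rbind, lapply(names(vp$region_sets), function(r)
      if (length(vp$region_sets[[r]]))
        data.frame(region = r, id = vp$region_sets[[r]]) else NULL))
    write_table(region_tab %||% data.frame(region = character(0), id = character(0)),
                path("venn_regions.tsv"))
    conc <- direction_concordance(lapply(det_sets, function(d)
      d[, c("gene_id", "direction")]))
    write_table(conc, path("concordance.tsv"))
    summary$venn <- as.list(vp$counts)
    summary$inherited <- list(F2 = length(vp$inherited_F2),
                              F3 = length(vp$inherited_F3))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
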