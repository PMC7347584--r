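# Targeted-metabolomics stage: internal-standard normalisation, one-way
# ANOVA + Tukey HSD calling of differentially accumulated metabolites (raw
# p < 0.05, as in the source protocol), and per-fraction average fold-change
# summaries on the log2 scale.

#' Normalise metabolite intensities on the internal standards
#'
#' Each metabolite's intensity in a sample is divided by the intensity of its
#' fraction's internal standard in that sample (formononetin for the
#' semi-polar fraction, DL-alpha-tocopherol acetate for the non-polar one in
#' the source protocol); the standard rows are removed from the output.
#'
#' @param table a [metabolite_table()] whose `internal_standards` contain one
#'   standard per fraction present.
#' @return the normalised `metabolite_table` (no internal-standard rows).
#' @export
normalize_internal_standard <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  if (!length(table$internal_standards))
    config_error("table has no internal standards to normalise on")
  std_frac <- table$fraction_of[table$internal_standards]
  if (anyDuplicated(std_frac))
    config_error("more than one internal standard for fraction ",
                 std_frac[duplicated(std_frac)][1])
  fracs <- unique(table$fraction_of)
  missing <- setdiff(fracs, std_frac)
  if (length(missing))
    config_error("no internal standard for fraction(s): ",
                 paste(missing, collapse = ", "))
  std_of <- stats::setNames(names(std_frac), std_frac)  # fraction -> std id
  x <- table$intensities
  for (s in table$sample_ids) {
    sv <- x[table$internal_standards, s]
    if (any(!is.finite(sv)) || any(sv <= 0))
      stop("internal standard missing or non-positive in sample ", s)
  }
  keep <- setdiff(table$metabolite_ids, table$internal_standards)
  out <- x[keep, , drop = FALSE] /
    x[std_of[table$fraction_of[keep]], , drop = FALSE]
  res <- metabolite_table(out, table$fraction_of[keep], table$group_of,
                          table$generation_of, internal_standards = character(0))
  tr <- attr(table, "truth")
  if (!is.null(tr)) attr(res, "truth") <- tr[tr$metabolite_id %in% keep, , drop = FALSE]
  res
}

#' One-way ANOVA (classical decomposition)
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `F` and `p` (upper tail of F(k-1, N-k)); when both the
#'   between- and within-group sums of squares are zero, `p = 1` with
#'   attribute `degenerate = TRUE`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) stop("values must be finite")
  k <- length(groups); N <- length(y)
  if (N - k <= 0L) stop("no within-group degrees of freedom")
  gm <- mean(y)
  means <- vapply(groups, mean, 1)
  ns <- vapply(groups, length, 1L)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  if (ssw == 0 && ssb == 0)
    return(structure(list(F = 0, p = 1), degenerate = TRUE))
  if (ssw == 0) return(list(F = Inf, p = 0))
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat, p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

#' Tukey HSD pairwise p-values
#'
#' Studentized-range p per group pair from the pooled within-group variance
#' (Tukey-Kramer standard error for unequal sizes). At k = 2 this reduces to
#' the two-sided pooled t-test (q = t * sqrt(2)).
#'
#' @param groups list of numeric vectors (named or numbered).
#' @return named numeric vector of p-values, names `"<i>-<j>"`.
#' @export
tukey_hsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 values")
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  ns <- vapply(groups, length, 1L); N <- sum(ns)
  means <- vapply(groups, mean, 1)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df <- N - k
  s2 <- ssw / df
  out <- numeric(0)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    se <- sqrt(s2 / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se > 0) abs(means[i] - means[j]) / se
    else if (means[i] == means[j]) 0 else Inf
    p <- if (is.infinite(q)) 0
    else stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    out[paste0(labels[i], "-", labels[j])] <- p
  }
  out
}

#' Call differentially accumulated metabolites within a generation
#'
#' Per metabolite: one-way ANOVA across groups (NC vs VT within the requested
#' generation by default, or all group-by-generation cells with
#' `scope = "all-cells"`) plus Tukey pairwise comparisons; a metabolite is a
#' DAM when its raw ANOVA p is below `alpha` (no multiplicity correction, per
#' the source protocol; set `adjust = TRUE` for BH). Technical replicates, if
#' declared, are averaged into their biological replicate before testing.
#'
#' @param table a normalised [metabolite_table()] (no internal-standard rows;
#'   see [normalize_internal_standard()]).
#' @param generation generation whose NC/VT contrast is reported.
#' @param alpha DAM threshold on the (possibly adjusted) p-value.
#' @param adjust apply Benjamini-Hochberg before thresholding (default FALSE).
#' @param scope `"per-generation"` (2-group ANOVA within `generation`) or
#'   `"all-cells"` (6 group-by-generation cells, Tukey across all pairs, the
#'   reported p is still the ANOVA p).
#' @param tech_rep_of optional named map sample -> biological replicate id.
#' @return data.frame: `metabolite_id`, `fraction`, `log2fc` (VT over NC in
#'   `generation`), `p_value`, `tukey_p` (the NC-vs-VT pair), `is_dam`; the
#'   full Tukey maps are in attribute `"tukey_pairs"`.
#' @export
call_dams <- function(table, generation = "F1", alpha = 0.05, adjust = FALSE,
                      scope = c("per-generation", "all-cells"),
                      tech_rep_of = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  scope <- match.arg(scope)
  if (length(table$internal_standards))
    config_error("normalise the table first (internal standards still present)")
  check_in(generation, .GENERATIONS, "generation")
  x <- table$intensities
  grp <- table$group_of; gen <- table$generation_of
  if (!is.null(tech_rep_of)) {
    rep_id <- tech_rep_of[table$sample_ids]
    agg <- t(apply(x, 1, function(r) tapply(r, rep_id, mean)))
    first <- !duplicated(rep_id)
    keep_names <- unique(rep_id)
    x <- agg[, keep_names, drop = FALSE]
    grp <- stats::setNames(grp[first], rep_id[first])[keep_names]
    gen <- stats::setNames(gen[first], rep_id[first])[keep_names]
  }
  in_gen <- gen == generation
  if (!any(grp[in_gen] == "NC") || !any(grp[in_gen] == "VT"))
    design_error("both groups must be present in generation ", generation)

  if (scope == "per-generation") {
    split_cols <- lapply(c(NC = "NC", VT = "VT"),
                         function(g) which(in_gen & grp == g))
  } else {
    cells <- interaction(grp, gen, sep = ".", drop = TRUE)
    split_cols <- split(seq_along(grp), cells)
  }
  pair_name <- paste0("NC", if (scope == "all-cells") paste0(".", generation),
                      "-", "VT", if (scope == "all-cells") paste0(".", generation))

  nc_cols <- which(in_gen & grp == "NC"); vt_cols <- which(in_gen & grp == "VT")
  res <- lapply(table$metabolite_ids, function(m) {
    groups <- lapply(split_cols, function(cols) x[m, cols])
    a <- anova_oneway(groups)
    tk <- tukey_hsd(groups)
    lfc <- log2(mean(x[m, vt_cols]) / mean(x[m, nc_cols]))
    list(row = data.frame(metabolite_id = m, fraction = table$fraction_of[[m]],
                          log2fc = lfc, p_value = a$p,
                          tukey_p = unname(tk[pair_name]),
                          stringsAsFactors = FALSE),
         tukey = tk)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  pv <- if (adjust) benjamini_hochberg(out$p_value) else out$p_value
  out$is_dam <- pv < alpha
  attr(out, "tukey_pairs") <- stats::setNames(lapply(res, `[[`, "tukey"),
                                              out$metabolite_id)
  out
}

#' Per-fraction average fold change of called DAMs
#'
#' @param dams data.frame from [call_dams()] (or any frame with `fraction`,
#'   `log2fc`, `is_dam`).
#' @param scale `"log2"` (default; mean log2 fold change, so up-accumulation
#'   is positive and down-accumulation negative) or `"ratio"` (mean of the
#'   raw VT/NC ratios).
#' @return named numeric vector fraction -> average fold change; fractions
#'   with no DAMs are absent.
#' @export
fraction_fold_change_summary <- function(dams, scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  d <- dams[dams$is_dam, , drop = FALSE]
  if (!nrow(d)) return(stats::setNames(numeric(0), character(0)))
  v <- if (scale == "log2") d$log2fc else 2^d$log2fc
  s <- tapply(v, d$fraction, mean)
  stats::setNames(as.numeric(s), names(s))
}
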