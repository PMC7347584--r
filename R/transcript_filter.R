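# Differential-transcript calling on count/FPKM matrices: a self-contained
# negative-binomial quasi-likelihood two-group test (library-size offsets,
# moment dispersion moderated toward the common value), Benjamini-Hochberg
# FDR control at 0.05, and the study's coefficient-of-variation post-filter.

#' Benjamini-Hochberg adjusted p-values
#'
#' Classic step-up adjustment: `adj_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1, returned in the input order.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (same length/order).
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (!m) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, cummin(rev(p_values[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}

# ---- internal NB machinery (vectorised across genes) ----------------------

# Fisher-scoring fit of log-mean eta per gene over sample subset `cols`:
# mu_ij = exp(eta_i) * libsize_j, NB dispersion phi_i. Returns list(mu, eta).
nb_fit_mean <- function(counts, libsize, phi, cols) {
  y <- counts[, cols, drop = FALSE]
  N <- libsize[cols]
  tot <- rowSums(y)
  eta <- log((tot + 0.5) / sum(N))
  for (it in 1:30) {
    mu <- exp(eta) %o% N
    w <- 1 + phi * mu
    score <- rowSums((y - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-10)
    step <- pmax(pmin(step, 5), -5)
    eta <- eta + step
    if (max(abs(step)) < 1e-10) break
  }
  list(mu = exp(eta) %o% N, eta = eta)
}

# NB deviance per gene given fitted means and dispersion phi (vector)
nb_deviance <- function(y, mu, phi) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  phi <- pmax(phi, 1e-12)
  t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  2 * rowSums(t1 - t2)
}

#' Minimal two-group differential-expression test
#'
#' Per gene: library-size-offset negative-binomial means are fitted under the
#' null (one mean) and the alternative (one mean per group); the gene-wise
#' dispersion is estimated by pseudo-Pearson moments and moderated toward the
#' common (median) dispersion with prior weight `prior_df`; significance is a
#' quasi-likelihood F test (deviance drop over the alternative's scaled
#' deviance, F(1, n - 2)). Fold changes are reported on the FPKM view with a
#' small pseudocount (an eighth of the typical per-sample minimum positive
#' FPKM), VT over NC.
#'
#' @param matrix an [expression_matrix()].
#' @param prior_df prior degrees of freedom for dispersion moderation.
#' @return data.frame (one row per gene): `gene_id`, `log2fc`, `p_value`,
#'   `fdr`, `direction` ("up"/"down" in VT relative to NC).
#' @export
de_test <- function(matrix, prior_df = 20) {
  stopifnot(inherits(matrix, "expression_matrix"))
  grp <- matrix$group_of
  if (sum(grp == "NC") < 3L || sum(grp == "VT") < 3L)
    design_error("de_test needs >= 3 samples per group (NC: ",
                 sum(grp == "NC"), ", VT: ", sum(grp == "VT"), ")")
  y <- matrix$counts
  libsize <- colSums(y)
  n <- ncol(y)
  df_res <- n - 2L

  # initial group means (Poisson ratio estimator) for moment dispersion
  mu0 <- y * 0
  for (g in .GROUPS) {
    cols <- grp == g
    q <- (rowSums(y[, cols, drop = FALSE]) + 0.25) / sum(libsize[cols])
    mu0[, cols] <- q %o% libsize[cols]
  }
  disp_mom <- rowSums(((y - mu0)^2 - mu0) / pmax(mu0, 1e-8)^2) / df_res
  disp_mom <- pmax(disp_mom, 0)
  expressed <- rowSums(y) > 0
  common <- if (any(expressed)) stats::median(disp_mom[expressed]) else 0.1
  common <- max(common, 1e-4)
  phi <- pmax((prior_df * common + df_res * disp_mom) / (prior_df + df_res), 1e-6)

  fit0 <- nb_fit_mean(y, libsize, phi, seq_len(n))
  dev0 <- nb_deviance(y, fit0$mu, phi)
  mu1 <- y * 0
  for (g in .GROUPS) {
    cols <- which(grp == g)
    mu1[, cols] <- nb_fit_mean(y, libsize, phi, cols)$mu
  }
  dev1 <- nb_deviance(y, mu1, phi)

  s2 <- pmax(dev1 / df_res, 1e-8)
  Fstat <- pmax(dev0 - dev1, 0) / s2
  p <- stats::pf(Fstat, 1, df_res, lower.tail = FALSE)
  p[!expressed] <- 1

  # fold change on the FPKM view, VT over NC, with a small pseudocount
  fpkm <- matrix$fpkm
  pos_min <- apply(fpkm, 2, function(col) {
    v <- col[col > 0]; if (length(v)) min(v) else NA_real_
  })
  pseudo <- 0.125 * stats::median(pos_min, na.rm = TRUE)
  if (!is.finite(pseudo) || pseudo <= 0) pseudo <- 0.125
  m_nc <- rowMeans(fpkm[, grp == "NC", drop = FALSE])
  m_vt <- rowMeans(fpkm[, grp == "VT", drop = FALSE])
  log2fc <- log2((m_vt + pseudo) / (m_nc + pseudo))

  data.frame(gene_id = matrix$gene_ids, log2fc = log2fc, p_value = p,
             fdr = benjamini_hochberg(p),
             direction = ifelse(log2fc >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variability post-filter for differential-transcript candidates
#'
#' On the FPKM view across all samples of the comparison: when a candidate
#' gene shows a coefficient of variation above 50% AND an absolute
#' mean-median gap above 1 (FPKM units), it is kept only if at least half
#' (ceiling for odd sizes) of the samples of the more expressed group have
#' FPKM at least twice the mean FPKM of the other group; otherwise it is kept
#' unconditionally. Genes with zero mean FPKM in both groups are dropped and
#' flagged.
#'
#' @param matrix an [expression_matrix()].
#' @param candidates data.frame of DE candidates (rows of a [de_test()]
#'   result); its `gene_id` values must exist in `matrix`.
#' @param cv_threshold CV trigger in percent (default 50).
#' @param gap_threshold mean-median trigger in FPKM units (default 1).
#' @return list with `kept` (the surviving candidate rows) and `trace`
#'   (per-candidate: cv_percent, mean_median_gap, triggered, kept,
#'   n_qualifying_samples, required, zero_expression).
#' @export
variability_postfilter <- function(matrix, candidates,
                                   cv_threshold = 50, gap_threshold = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!all(candidates$gene_id %in% matrix$gene_ids))
    config_error("candidate gene(s) not in matrix: ",
                 paste(setdiff(candidates$gene_id, matrix$gene_ids), collapse = ", "))
  grp <- matrix$group_of
  trace <- lapply(candidates$gene_id, function(gid) {
    v <- matrix$fpkm[gid, ]
    m_nc <- mean(v[grp == "NC"]); m_vt <- mean(v[grp == "VT"])
    if (m_nc == 0 && m_vt == 0)
      return(data.frame(gene_id = gid, cv_percent = NA_real_,
                        mean_median_gap = NA_real_, triggered = FALSE,
                        kept = FALSE, n_qualifying_samples = NA_integer_,
                        required = NA_integer_, zero_expression = TRUE))
    mu <- mean(v)
    cv <- 100 * stats::sd(v) / mu
    gap <- abs(mu - stats::median(v))
    triggered <- (cv > cv_threshold) && (gap > gap_threshold)
    nq <- NA_integer_; req <- NA_integer_; kept <- TRUE
    if (triggered && m_nc != m_vt) {   # ties broken toward keeping
      hi <- if (m_vt > m_nc) "VT" else "NC"
      other_mean <- if (hi == "VT") m_nc else m_vt
      hv <- v[grp == hi]
      req <- as.integer(ceiling(length(hv) / 2))
      nq <- as.integer(sum(hv >= 2 * other_mean))
      kept <- nq >= req
    }
    data.frame(gene_id = gid, cv_percent = cv, mean_median_gap = gap,
               triggered = triggered, kept = kept,
               n_qualifying_samples = nq, required = req,
               zero_expression = FALSE)
  })
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  list(kept = candidates[trace$kept, , drop = FALSE], trace = trace)
}

#' Call differentially expressed transcripts
#'
#' Full stage: [de_test()], keep genes at BH-FDR <= `fdr_threshold`, then
#' apply the [variability_postfilter()]. Deterministic given the matrix.
#'
#' @param matrix an [expression_matrix()].
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param apply_postfilter apply the CV post-filter (default TRUE).
#' @return data.frame of kept DETs (columns of [de_test()]), with the filter
#'   trace in attribute `"filter_trace"`.
#' @export
call_dets <- function(matrix, fdr_threshold = 0.05, apply_postfilter = TRUE) {
  res <- de_test(matrix)
  cand <- res[res$fdr <= fdr_threshold, , drop = FALSE]
  if (!apply_postfilter || !nrow(cand)) {
    attr(cand, "filter_trace") <- NULL
    rownames(cand) <- NULL
    return(cand)
  }
  filt <- variability_postfilter(matrix, cand)
  out <- filt$kept
  rownames(out) <- NULL
  attr(out, "filter_trace") <- filt$trace
  out
}
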