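# Bayesian two-group trait comparison via Gibbs sampling with bounded flat
# priors, posterior summaries of the NC-minus-VT contrast (D, P0, HPD95%,
# batch-means Monte Carlo SE, Geweke Z) and the biological-relevance decision
# rule |D| > R with P0 > 0.8, where R is one third of the trait SD.

#' Gibbs sampler settings
#'
#' Defaults follow the study protocol: 60,000 iterations, 10,000 burn-in,
#' thinning 1-in-10, i.e. 5,000 saved draws per chain.
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (< n_iter).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param prior_bounds list with elements `location` (length-2, bounds for all
#'   location parameters, trait units) and `sigma2` (length-2, bounds for the
#'   residual variance). Defaults are effectively non-informative.
#' @param seed integer seed for the chain.
#' @return an object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 60000L, burn_in = 10000L, thin = 10L,
                         prior_bounds = list(location = c(-1e6, 1e6),
                                             sigma2 = c(1e-12, 1e12)),
                         seed = 1L) {
  check_scalar_number(n_iter, "n_iter", positive = TRUE, integer = TRUE)
  check_scalar_number(burn_in, "burn_in", integer = TRUE)
  check_scalar_number(thin, "thin", positive = TRUE, integer = TRUE)
  if (burn_in < 0 || burn_in >= n_iter) config_error("need 0 <= burn_in < n_iter")
  if (!all(c("location", "sigma2") %in% names(prior_bounds)))
    config_error("prior_bounds needs 'location' and 'sigma2' entries")
  for (nm in c("location", "sigma2")) {
    b <- prior_bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      config_error("prior_bounds$", nm, " must be an increasing (low, high) pair")
  }
  if (prior_bounds$sigma2[1] <= 0)
    config_error("prior_bounds$sigma2 must be positive")
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior_bounds = prior_bounds,
                 seed = as.integer(seed)),
            class = "gibbs_config")
}

# one draw from Normal(mean, sd) truncated to [lo, hi]; rejection first
# (counting escapes for diagnostics), inverse-CDF fallback
rtnorm1 <- function(mean, sd, lo, hi, env) {
  for (i in 1:50) {
    x <- stats::rnorm(1, mean, sd)
    env$proposals <- env$proposals + 1L
    if (x >= lo && x <= hi) return(x)
    env$escapes <- env$escapes + 1L
  }
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  if (phi <= plo) return(if (mean < lo) lo else hi)
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

# sigma^2 ~ scaled-inverse-chi-square full conditional within bounds:
# sigma^2 = SSE / X with X ~ chisq(n), restricted to the bounds. The df = n
# draw corresponds to the scale-uniform (Jeffreys) parameterisation of the
# flat prior, under which the marginal posterior of a location contrast is
# exactly location-scale t with n - p df (the closed-form oracle used in the
# tests); a flat prior on sigma^2 itself would widen that marginal to
# t(n - p - 2) with an inflated scale.
rsigma2 <- function(sse, n, lo, hi) {
  df <- n
  x <- stats::rchisq(1, df)
  s2 <- sse / x
  if (s2 >= lo && s2 <= hi) return(s2)
  plo <- stats::pchisq(sse / hi, df); phi <- stats::pchisq(sse / lo, df)
  if (phi <= plo) return(if (s2 < lo) lo else hi)
  sse / stats::qchisq(stats::runif(1, plo, phi), df)
}

#' Fit the two-group trait model by Gibbs sampling
#'
#' Linear model `value = mu_group (+ beta * (covariate - mean covariate)) + e`,
#' `e ~ N(0, sigma2)`, with bounded flat priors on all unknowns. Location
#' parameters are drawn from their normal full conditionals truncated to the
#' prior bounds; `sigma2` from its scaled-inverse-chi-square full conditional
#' (rejecting draws outside the bounds). The saved chain records the
#' NC-minus-VT contrast `D = mu_NC - mu_VT` at every kept iteration.
#'
#' @param table long-format trait table (columns `animal_id`, `group`,
#'   `generation`, `trait`, `value`, optionally `covariate`), e.g. from
#'   [gen_phenotype_table()] or [read_trait_table()].
#' @param trait trait name to model.
#' @param generation generation ("F1"/"F2"/"F3") whose animals are compared.
#' @param use_covariate adjust for the centred adult body-weight covariate
#'   (the study corrects organ weights this way).
#' @param config a [gibbs_config()].
#' @return an object of class `posterior_chain` with elements `samples_D`,
#'   `samples_sigma2`, `samples_beta` (NULL without covariate), `config_used`,
#'   and bookkeeping fields.
#' @export
fit_two_group_model <- function(table, trait, generation,
                                use_covariate = FALSE,
                                config = gibbs_config()) {
  stopifnot(inherits(config, "gibbs_config"))
  need <- c("group", "generation", "trait", "value")
  if (!all(need %in% names(table)))
    config_error("trait table must have columns ", paste(need, collapse = ", "))
  rows <- table$trait == trait & table$generation == generation
  dat <- table[rows, , drop = FALSE]
  if (!nrow(dat)) design_error("no observations for trait '", trait,
                               "' in generation ", generation)
  check_in(dat$group, .GROUPS, "group")
  y <- dat$value
  if (any(!is.finite(y))) config_error("trait values must be finite")
  g <- dat$group
  n_nc <- sum(g == "NC"); n_vt <- sum(g == "VT")
  if (n_nc == 0L || n_vt == 0L)
    design_error("both groups must be present (NC: ", n_nc, ", VT: ", n_vt, ")")
  if (n_nc < 2L || n_vt < 2L)
    design_error("need >= 2 observations per group")
  n <- length(y)
  p <- 2L + as.integer(use_covariate)
  if (n - p <= 0L) stop("zero residual degrees of freedom")

  if (use_covariate) {
    if (!"covariate" %in% names(dat) || any(!is.finite(dat$covariate)))
      config_error("use_covariate = TRUE requires a finite covariate for every row")
    x <- dat$covariate - mean(dat$covariate)
  } else x <- numeric(n)

  # sufficient statistics (scalar work per iteration)
  inc <- g == "NC"
  Sy  <- c(NC = sum(y[inc]),  VT = sum(y[!inc]))
  Syy <- sum(y^2)
  Sx  <- c(NC = sum(x[inc]),  VT = sum(x[!inc]))
  Sxy <- sum(x * y)
  Sxx <- sum(x^2)
  ng  <- c(NC = n_nc, VT = n_vt)
  if (use_covariate && Sxx <= 0) stop("covariate has zero variance")

  lb <- config$prior_bounds$location
  sb <- config$prior_bounds$sigma2
  n_saved <- (config$n_iter - config$burn_in) %/% config$thin
  samples_D <- numeric(n_saved)
  samples_s2 <- numeric(n_saved)
  samples_b <- if (use_covariate) numeric(n_saved) else NULL

  set.seed(config$seed)
  # initialise at least-squares values
  mu <- Sy / ng
  beta <- if (use_covariate) (Sxy - mu["NC"] * Sx["NC"] - mu["VT"] * Sx["VT"]) / Sxx else 0
  s2 <- max(sb[1], min(sb[2], stats::var(y)))
  diag_env <- new.env(parent = emptyenv())
  diag_env$proposals <- 0L; diag_env$escapes <- 0L

  k <- 0L
  for (t in seq_len(config$n_iter)) {
    for (grp in c("NC", "VT")) {
      m <- (Sy[[grp]] - beta * Sx[[grp]]) / ng[[grp]]
      mu[[grp]] <- rtnorm1(m, sqrt(s2 / ng[[grp]]), lb[1], lb[2], diag_env)
    }
    if (use_covariate) {
      num <- Sxy - mu[["NC"]] * Sx[["NC"]] - mu[["VT"]] * Sx[["VT"]]
      beta <- rtnorm1(num / Sxx, sqrt(s2 / Sxx), lb[1], lb[2], diag_env)
    }
    sse <- Syy - 2 * (mu[["NC"]] * Sy[["NC"]] + mu[["VT"]] * Sy[["VT"]]) +
      ng[["NC"]] * mu[["NC"]]^2 + ng[["VT"]] * mu[["VT"]]^2
    if (use_covariate) {
      num <- Sxy - mu[["NC"]] * Sx[["NC"]] - mu[["VT"]] * Sx[["VT"]]
      sse <- sse - 2 * beta * num + beta^2 * Sxx
    }
    sse <- max(sse, 0)
    s2 <- rsigma2(sse, n, sb[1], sb[2])

    if (t > config$burn_in && (t - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      samples_D[k] <- mu[["NC"]] - mu[["VT"]]
      samples_s2[k] <- s2
      if (use_covariate) samples_b[k] <- beta
    }
  }
  if (diag_env$proposals > 0L &&
      diag_env$escapes / diag_env$proposals > 0.5)
    warning("more than 50% of location proposals escaped the prior bounds; ",
            "bounds may be too tight for this trait scale")

  structure(list(samples_D = samples_D, samples_sigma2 = samples_s2,
                 samples_beta = samples_b, config_used = config,
                 trait = trait, generation = generation,
                 n_obs = c(NC = n_nc, VT = n_vt),
                 escape_rate = if (diag_env$proposals)
                   diag_env$escapes / diag_env$proposals else 0),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior_chain:", length(x$samples_D), "saved draws for trait '",
      x$trait, "' (", x$generation, "), D mean ",
      signif(mean(x$samples_D), 4), "\n", sep = "")
  invisible(x)
}

#' Shortest (highest posterior density) interval from MCMC samples
#'
#' Among all contiguous windows of `ceiling(prob * n)` sorted samples, returns
#' the narrowest; the first such window on ties.
#'
#' @param samples numeric vector of posterior draws.
#' @param prob interval probability in (0, 1).
#' @return numeric `c(low, high)`.
#' @export
#' @examples
#' hpd_interval(1:100, 0.95)   # c(1, 95)
hpd_interval <- function(samples, prob = 0.95) {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("samples must be finite numerics")
  if (prob <= 0 || prob >= 1) stop("prob must lie in (0, 1)")
  n <- length(samples)
  k <- ceiling(prob * n)
  if (n < k + 1L) stop("too few samples for a ", prob, " HPD interval")
  s <- sort(samples)
  lo_idx <- seq_len(n - k + 1L)
  widths <- s[lo_idx + k - 1L] - s[lo_idx]
  i <- which.min(widths)  # first narrowest on ties
  c(low = s[i], high = s[i + k - 1L])
}

#' Monte Carlo standard error of a chain mean by batch means
#'
#' Splits the chain into `n_batches` consecutive batches and returns
#' `sd(batch means) / sqrt(n_batches)` (a time-series SE valid under chain
#' autocorrelation).
#'
#' @param samples numeric chain.
#' @param n_batches number of batches (>= 10, each of size >= 10).
#' @return the Monte Carlo SE of `mean(samples)`.
#' @export
mc_se_batch_means <- function(samples, n_batches = 50L) {
  n <- length(samples)
  if (n_batches < 10L) stop("need at least 10 batches")
  m <- n %/% n_batches
  if (m < 10L) stop("too few samples: need >= ", 10L * n_batches,
                    " for batches of size >= 10")
  use <- samples[seq_len(m * n_batches)]
  bm <- colMeans(matrix(use, nrow = m))
  stats::sd(bm) / sqrt(n_batches)
}

# batch-means estimate of the spectral density at frequency zero (the
# long-run variance), used by the Geweke diagnostic
spectral0_batch <- function(w) {
  nw <- length(w)
  m <- max(1L, floor(sqrt(nw)))
  nb <- nw %/% m
  if (nb < 2L) return(stats::var(w))
  bm <- colMeans(matrix(w[seq_len(nb * m)], nrow = m))
  m * stats::var(bm)
}

#' Geweke convergence Z score
#'
#' Compares the mean of the first `frac_a` of the chain with the mean of the
#' last `frac_b`, standardised by batch-means estimates of the spectral
#' density at zero: `Z = (mA - mB) / sqrt(sA/nA + sB/nB)`. Approximately
#' standard normal for a stationary chain.
#'
#' @param samples numeric chain.
#' @param frac_a leading window fraction (default 0.1).
#' @param frac_b trailing window fraction (default 0.5).
#' @return the Z score; `NA` with attribute `undefined = TRUE` when both
#'   windows are constant.
#' @export
geweke_z <- function(samples, frac_a = 0.1, frac_b = 0.5) {
  n <- length(samples)
  if (frac_a <= 0 || frac_b <= 0 || frac_a + frac_b > 1)
    stop("need frac_a > 0, frac_b > 0, frac_a + frac_b <= 1")
  na <- floor(frac_a * n); nb <- floor(frac_b * n)
  if (na < 10L || nb < 10L) stop("each Geweke window needs >= 10 samples")
  a <- samples[seq_len(na)]
  b <- samples[seq.int(n - nb + 1L, n)]
  sa <- spectral0_batch(a); sb <- spectral0_batch(b)
  denom <- sa / na + sb / nb
  if (!is.finite(denom) || denom <= 0)
    return(structure(NA_real_, undefined = TRUE))
  (mean(a) - mean(b)) / sqrt(denom)
}

#' Summarise a posterior chain of the NC-minus-VT contrast
#'
#' @param chain a `posterior_chain` (or a bare numeric vector of contrast
#'   draws).
#' @param prob HPD probability (default 0.95).
#' @return an object of class `posterior_summary` with `D_mean`, `P0` (the
#'   posterior probability that the contrast has the sign of its mean; draws
#'   exactly 0 are excluded; a zero mean is reported on the positive side),
#'   `hpd_low`, `hpd_high`, `mcse`, `geweke_z`, `n_saved`.
#' @export
summarize_posterior <- function(chain, prob = 0.95) {
  d <- if (inherits(chain, "posterior_chain")) chain$samples_D else as.numeric(chain)
  if (!length(d)) stop("empty chain")
  D_mean <- mean(d)
  nz <- d[d != 0]
  P0 <- if (!length(nz)) 1
  else if (D_mean >= 0) mean(nz > 0) else mean(nz < 0)
  hpd <- hpd_interval(d, prob)
  constant <- stats::sd(d) == 0
  mcse <- if (constant) 0
  else tryCatch(mc_se_batch_means(d), error = function(e) stats::sd(d) / sqrt(length(d)))
  gz <- if (constant || length(d) < 100L) structure(NA_real_, undefined = TRUE)
  else geweke_z(d)
  structure(list(D_mean = D_mean, P0 = P0,
                 hpd_low = unname(hpd[1]), hpd_high = unname(hpd[2]),
                 mcse = mcse, geweke_z = gz, n_saved = length(d),
                 trait = if (inherits(chain, "posterior_chain")) chain$trait else NA,
                 generation = if (inherits(chain, "posterior_chain")) chain$generation else NA),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("D_NC-VT = %.4g  P0 = %.3f  HPD95%% = [%.4g, %.4g]  MCse = %.3g  Geweke Z = %.3g\n",
              x$D_mean, x$P0, x$hpd_low, x$hpd_high, x$mcse,
              as.numeric(x$geweke_z)))
  invisible(x)
}

#' Relevance threshold: one third of the trait SD
#'
#' @param values pooled trait values (both groups) of the comparison.
#' @return `R = sd(values) / 3` (sample SD, denominator n - 1).
#' @export
relevant_value <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for the trait SD")
  s <- stats::sd(values)
  if (s == 0) warning("all trait values identical; R = 0")
  s / 3
}

#' Apply the biological-relevance decision rule
#'
#' A difference is declared relevant when the absolute posterior mean of the
#' contrast strictly exceeds the relevance threshold R (one third of the
#' trait SD) and the posterior probability P0 strictly exceeds 0.8.
#'
#' @param summary a `posterior_summary`.
#' @param R relevance threshold (trait units, >= 0), from [relevant_value()].
#' @return an object of class `relevance_decision`: `R`, `relevant`, and a
#'   `criterion_trace` with the two sub-criteria.
#' @export
decide_relevance <- function(summary, R) {
  stopifnot(inherits(summary, "posterior_summary"))
  check_scalar_number(R, "R")
  if (R < 0) config_error("R must be >= 0")
  abs_D <- abs(summary$D_mean)
  structure(list(R = R,
                 relevant = (abs_D > R) && (summary$P0 > 0.8),
                 criterion_trace = list(abs_D = abs_D, P0 = summary$P0)),
            class = "relevance_decision")
}

#' Fit, summarise and decide for a set of trait/generation comparisons
#'
#' Convenience wrapper producing one report row per (trait, generation), the
#' shape of the study's supplementary trait tables.
#'
#' @param table long-format trait table.
#' @param traits traits to compare (default: all in the table).
#' @param generations generations to compare (default: all present).
#' @param use_covariate covariate adjustment passed to [fit_two_group_model()].
#' @param config a [gibbs_config()]; each comparison gets a deterministic
#'   sub-seed derived from `config$seed` and the comparison labels.
#' @return data.frame with columns trait, generation, D_mean, P0, hpd_low,
#'   hpd_high, mcse, geweke_z, R, relevant.
#' @export
compare_traits <- function(table, traits = unique(table$trait),
                           generations = intersect(.GENERATIONS, table$generation),
                           use_covariate = FALSE, config = gibbs_config()) {
  rows <- list()
  for (tr in traits) for (gen in generations) {
    cfg <- config
    cfg$seed <- sub_seed(config$seed, "fit", tr, gen)
    chain <- fit_two_group_model(table, tr, gen, use_covariate, cfg)
    s <- summarize_posterior(chain)
    vals <- table$value[table$trait == tr & table$generation == gen]
    dec <- decide_relevance(s, relevant_value(vals))
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, generation = gen, D_mean = s$D_mean, P0 = s$P0,
      hpd_low = s$hpd_low, hpd_high = s$hpd_high, mcse = s$mcse,
      geweke_z = as.numeric(s$geweke_z), R = dec$R, relevant = dec$relevant,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
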