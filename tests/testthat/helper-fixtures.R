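# shared fixture builders and independent oracles

# two-group normal trait table, NC mean = delta, VT mean = 0
make_trait_table <- function(n_per_group, delta = 0, sd = 1, seed = 1,
                             trait = "x", generation = "F1",
                             covariate = NULL) {
  set.seed(seed)
  df <- data.frame(
    animal_id = sprintf("a%04d", seq_len(2 * n_per_group)),
    group = rep(c("NC", "VT"), each = n_per_group),
    generation = generation, trait = trait,
    value = c(rnorm(n_per_group, delta, sd), rnorm(n_per_group, 0, sd)),
    stringsAsFactors = FALSE)
  if (!is.null(covariate)) df$covariate <- covariate
  df
}

# closed-form flat-prior posterior of the NC-VT contrast for the
# no-covariate model: location-scale t with n - 2 df
analytic_contrast_posterior <- function(tab) {
  y1 <- tab$value[tab$group == "NC"]; y2 <- tab$value[tab$group == "VT"]
  n1 <- length(y1); n2 <- length(y2); df <- n1 + n2 - 2
  s2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / df
  list(center = mean(y1) - mean(y2),
       scale = sqrt(s2 * (1 / n1 + 1 / n2)), df = df)
}

# brute-force BH oracle: adj_i = min over j with p_j >= p_i (by rank) of
# p_(j) * m / j, computed directly from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    r[i] <- min(1, min(p[o][rank_i:m] * m / (rank_i:m)))
  }
  r
}

# expression matrix with hand-set FPKM values for one gene (postfilter
# fixtures); counts are irrelevant to the filter and set arbitrarily
make_fpkm_fixture <- function(nc_fpkm, vt_fpkm) {
  n1 <- length(nc_fpkm); n2 <- length(vt_fpkm)
  samples <- c(paste0("NC_", seq_len(n1)), paste0("VT_", seq_len(n2)))
  counts <- matrix(10, 1, n1 + n2, dimnames = list("g1", samples))
  fpkm <- matrix(c(nc_fpkm, vt_fpkm), 1, dimnames = list("g1", samples))
  expression_matrix(counts,
                    setNames(rep(c("NC", "VT"), c(n1, n2)), samples),
                    fpkm = fpkm)
}

# minimal valid metabolite table built by hand
make_metab_fixture <- function(intensities, standards = character(0),
                               fraction = "semi-polar") {
  samples <- colnames(intensities)
  grp <- setNames(ifelse(grepl("^NC", samples), "NC", "VT"), samples)
  metabolite_table(intensities,
                   fraction_of = setNames(rep(fraction, nrow(intensities)),
                                          rownames(intensities)),
                   group_of = grp,
                   generation_of = setNames(rep("F1", length(samples)), samples),
                   internal_standards = standards)
}
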