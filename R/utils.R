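#' @keywords internal
"_PACKAGE"

# Valid factor levels used across the pipeline
.GROUPS <- c("NC", "VT")
.GENERATIONS <- c("F1", "F2", "F3")
.FRACTIONS <- c("semi-polar", "non-polar")

#' Derive a deterministic sub-seed from a base seed and a label
#'
#' Generators derive one independent sub-stream per (stage, generation, group)
#' so that, e.g., adding a generation to a simulated design does not perturb
#' the draws of earlier generations. The derivation is a small polynomial
#' string hash folded into the base seed modulo 2^31 - 1, so results are
#' identical across platforms and R versions.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
#' @examples
#' sub_seed(42, "phenotype", "F1", "NC")
sub_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double integer range
  h <- as.double(seed %% m)
  for (code in utf8ToInt(label)) {
    # h <- (h * 31 + code) mod m, split to stay below 2^53
    h <- ((h %% 65536) * 31 + (h %/% 65536) * 31 * 65536 %% m + code) %% m
  }
  as.integer(h)
}

# stop() with a consistent config-error class so callers/tests can match it
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cryofx_config_error", "error")))
}

design_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cryofx_design_error", "error")))
}

check_scalar_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(name, " must be a single finite number")
  if (positive && x <= 0) config_error(name, " must be > 0")
  if (integer && x != round(x)) config_error(name, " must be an integer")
  invisible(x)
}

check_in <- function(x, allowed, name) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad))
    config_error(name, " contains invalid value(s): ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(x)
}

# round-half-up at `digits` decimals (table reproduction; R's round() is
# round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
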