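# Deterministic per-animal derived quantities: average weight gain, sperm
# kinematic coefficients and totals, and mean litter sizes. All vectorised
# and pure.

#' Average weight gain over the exponential growth period
#'
#' `AWG = (week-9 weight - week-4 weight) / 35 days`, grams per day. A
#' negative AWG (weight loss) is allowed but flagged with a warning.
#'
#' @param w4 week-4 (weaning) weight, grams.
#' @param w9 week-9 (prepubertal) weight, grams.
#' @return grams/day.
#' @export
#' @examples
#' awg(700, 1750)  # 30 g/day
awg <- function(w4, w9) {
  if (any(w4 < 0 | w9 < 0, na.rm = TRUE)) stop("weights must be >= 0")
  out <- (w9 - w4) / 35
  if (any(out < 0, na.rm = TRUE)) warning("negative AWG (weight loss) present")
  out
}

#' Derived sperm quantities from ejaculate measurements
#'
#' Total sperm per ejaculate `TSE = VOL * CON`; linearity
#' `LIN = 100 * VSL / VCL`; wobble as printed in the source table
#' `WOB = 100 * VSL / VAP`. The source gives no straightness formula and its
#' printed WOB collides with the conventional CASA wobble (VAP/VCL); the
#' `dialect` switch selects between fidelity to the printed definitions
#' (default: STR = 100*VSL/VAP, identical to the printed WOB) and the CASA
#' convention (STR = 100*VSL/VAP, WOB = 100*VAP/VCL).
#'
#' @param vol ejaculate volume, mL.
#' @param con sperm concentration, 10^6 spermatozoa / mL.
#' @param vcl curvilinear velocity, um/s (> 0).
#' @param vsl straight-line velocity, um/s.
#' @param vap average path velocity, um/s (> 0).
#' @param dialect `"as-printed"` or `"conventional"` (see above).
#' @return data.frame with columns `tse` (10^6 spz), `lin`, `str`, `wob`
#'   (percent).
#' @export
#' @examples
#' sperm_derived(0.5, 200, vcl = 100, vsl = 40, vap = 60)
sperm_derived <- function(vol, con, vcl, vsl, vap,
                          dialect = c("as-printed", "conventional")) {
  dialect <- match.arg(dialect)
  n <- max(length(vol), length(con), length(vcl), length(vsl), length(vap))
  bad <- vcl <= 0 | vap <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("zero or negative VCL/VAP: kinematic coefficients undefined (NA)")
  }
  lin <- ifelse(vcl > 0, 100 * vsl / vcl, NA_real_)
  vslvap <- ifelse(vap > 0, 100 * vsl / vap, NA_real_)
  wob <- if (dialect == "as-printed") vslvap
  else ifelse(vcl > 0, 100 * vap / vcl, NA_real_)
  data.frame(tse = vol * con, lin = lin, str = vslvap, wob = wob)
}

#' Mean litter size from live-birth and parity counts
#'
#' @param live_births total live births (non-negative integer).
#' @param parities number of parities (> 0).
#' @param digits decimals for table reproduction (half-up rounding; the
#'   source table prints one decimal). `NULL` for the exact ratio.
#' @return live_births / parities, rounded half-up to `digits`.
#' @export
#' @examples
#' mean_litter_size(77, 14)  # 5.5
#' mean_litter_size(69, 13)  # 5.3
mean_litter_size <- function(live_births, parities, digits = 1) {
  if (any(parities <= 0)) stop("parities must be > 0")
  if (any(live_births < 0)) stop("live_births must be >= 0")
  r <- live_births / parities
  if (is.null(digits)) r else round_half_up(r, digits)
}
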