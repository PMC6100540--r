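#' Enzyme activity from an absorbance trace
#'
#' Ellman-style activities are slopes of absorbance versus time. The slope
#' is an ordinary least-squares fit over a configurable linear window
#' (default: the whole trace); no automatic curvature detection is
#' attempted, so the result is deterministic in the input.
#'
#' @param times Time points in minutes, strictly increasing, length >= 3.
#' @param absorbance Absorbance readings (AU), same length.
#' @param window Optional `c(t_min, t_max)` restricting the fit window.
#' @return Slope in AU/min. A negative slope is allowed but warned about.
#' @export
activity_from_trace <- function(times, absorbance, window = NULL) {
  stopifnot(length(times) == length(absorbance))
  if (length(times) < 3L)
    stop("activity_from_trace: need at least 3 points")
  if (any(diff(times) <= 0))
    stop("activity_from_trace: times must be strictly increasing")
  if (!is.null(window)) {
    keep <- times >= window[1L] & times <= window[2L]
    if (sum(keep) < 3L)
      stop("activity_from_trace: fewer than 3 points in window")
    times <- times[keep]; absorbance <- absorbance[keep]
  }
  slope <- unname(stats::coef(stats::lm(absorbance ~ times))[2L])
  if (slope < 0) warning("negative activity slope: ", format(slope))
  slope
}

#' Percent reactivation from intact, inhibited, and reactivated activities
#'
#' Evaluates `%R = [1 - (a0 - ar) / (a0 - ai)] * 100`, where `a0` is the
#' intact-enzyme activity, `ai` the inhibited activity, and
#' `ar = ar_raw - oximolysis` the reactivated activity corrected for
#' non-enzymatic substrate hydrolysis by the oxime itself. The value is not
#' clamped: results below 0 or above 100 pass through carrying an
#' `out_of_range` attribute so that recovery statistics stay unbiased.
#'
#' @param a0 Intact-enzyme activity (> `ai`).
#' @param ai Inhibited-enzyme activity.
#' @param ar_raw Measured activity after reactivation, before oximolysis
#'   correction.
#' @param oximolysis Oximolysis-control activity subtracted from `ar_raw`
#'   (default 0).
#' @return Percent reactivation.
#' @export
#' @examples
#' percent_reactivation(1.0, 0.05, 1.0)  # 100
percent_reactivation <- function(a0, ai, ar_raw, oximolysis = 0) {
  stopifnot(is.finite(a0), is.finite(ai), is.finite(ar_raw),
            is.finite(oximolysis))
  if (a0 <= ai)
    stop("no inhibition window: a0 must exceed ai")
  ar <- ar_raw - oximolysis
  pct <- (1 - (a0 - ar) / (a0 - ai)) * 100
  if (pct < 0 || pct > 100) attr(pct, "out_of_range") <- TRUE
  pct
}

#' Replicate statistics for percent reactivation
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) over
#' replicate percent-reactivation values, in the shape of a published
#' reactivation table row (reactivator x enzyme x concentration).
#'
#' @param pct_R Numeric vector of per-replicate percent reactivation.
#' @param oxime,enzyme Labels carried to the result.
#' @param concentration Reactivator concentration in mol/L.
#' @return A one-row data.frame (`reactivation_result`): `oxime`, `enzyme`,
#'   `concentration`, `pct_R_mean`, `pct_R_sd`, `n_replicates`. With a
#'   single replicate the SD is 0 and `single_replicate` is flagged.
#' @export
summarize_reactivation <- function(pct_R, oxime = "", enzyme = "",
                                   concentration = NA_real_) {
  pct_R <- as.numeric(pct_R)
  stopifnot(length(pct_R) >= 1L, all(is.finite(pct_R)))
  n <- length(pct_R)
  out <- data.frame(oxime = oxime, enzyme = enzyme,
                    concentration = concentration,
                    pct_R_mean = mean(pct_R),
                    pct_R_sd = if (n > 1L) stats::sd(pct_R) else 0,
                    n_replicates = n, stringsAsFactors = FALSE)
  if (n == 1L) attr(out, "single_replicate") <- TRUE
  class(out) <- c("reactivation_result", class(out))
  out
}

#' Pseudo-first-order inhibition kinetics
#'
#' Fits `ln(a(t) / a(0))` versus time by least squares on a residual
#' activity time-course of the enzyme + organophosphate reaction, returning
#' the observed rate constant, the half-life `ln(2) / k_obs`, and the R^2
#' of the log-linear fit.
#'
#' @param times Time points in minutes, length >= 3.
#' @param residual_activities Activities at those times, all > 0.
#' @return A list of class `inhibition_kinetics`: `k_obs` (1/min),
#'   `half_life` (min), `r_squared`.
#' @export
fit_half_life <- function(times, residual_activities) {
  stopifnot(length(times) == length(residual_activities))
  if (length(times) < 3L) stop("fit_half_life: need at least 3 points")
  if (any(residual_activities <= 0))
    stop("fit_half_life: activities must be positive")
  y <- log(residual_activities / residual_activities[1L])
  fit <- stats::lm(y ~ times)
  k <- -unname(stats::coef(fit)[2L])
  if (k <= 0) stop("no decay: fitted rate constant is not positive")
  # summary.lm warns on exactly exponential (residual-free) input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(k_obs = k, half_life = log(2) / k, r_squared = r2),
            class = "inhibition_kinetics")
}

#' Inhibition time as a multiple of the half-life
#'
#' The incubation time ensuring near-complete inhibition is taken as a
#' multiple of the fitted half-life; 7 half-lives leave a residual active
#' fraction of 2^-7 (under 1%), which for a half-life of 120/7 minutes
#' gives the conventional 2-hour incubation.
#'
#' @param kinetics An `inhibition_kinetics` object (or a list with a
#'   `half_life` element in minutes).
#' @param n_halflives Number of half-lives (default 7).
#' @return A list: `minutes` and `residual_fraction = 2^-n_halflives`.
#' @export
inhibition_time <- function(kinetics, n_halflives = 7) {
  hl <- kinetics$half_life
  stopifnot(is.finite(hl), hl > 0, n_halflives >= 0)
  list(minutes = n_halflives * hl, residual_fraction = 2^(-n_halflives))
}

#' Percent reactivation from an activity table
#'
#' Convenience wrapper: takes a long-format activity table for one scenario
#' (columns `condition` in intact / inhibited / reactivated /
#' oximolysis_control and `replicate`, `activity`), pairs conditions within
#' each replicate, applies [percent_reactivation()] per replicate, and
#' summarizes. Intact and inhibited activities are averaged over replicates
#' when the reactivated condition has replicates they lack. An absent
#' oximolysis control means no correction.
#'
#' @param activities Data.frame with columns `condition`, `replicate`,
#'   `activity`.
#' @param oxime,enzyme,concentration Labels for the result row.
#' @return A `reactivation_result` (see [summarize_reactivation()]).
#' @export
reactivation_from_activities <- function(activities, oxime = "",
                                         enzyme = "",
                                         concentration = NA_real_) {
  need <- c("condition", "replicate", "activity")
  if (!all(need %in% names(activities)))
    stop("activity table lacks columns: ",
         paste(setdiff(need, names(activities)), collapse = ", "))
  get <- function(cond) activities[activities$condition == cond, ,
                                   drop = FALSE]
  reac <- get("reactivated")
  if (nrow(reac) == 0L) stop("no 'reactivated' rows in activity table")
  intact <- get("intact"); inhib <- get("inhibited")
  if (nrow(intact) == 0L || nrow(inhib) == 0L)
    stop("activity table needs 'intact' and 'inhibited' conditions")
  oxi <- get("oximolysis_control")
  pick <- function(tab, rep_id) {
    i <- which(tab$replicate == rep_id)
    if (length(i) == 1L) tab$activity[i] else mean(tab$activity)
  }
  pct <- vapply(reac$replicate, function(r) {
    percent_reactivation(pick(intact, r), pick(inhib, r),
                         pick(reac, r),
                         if (nrow(oxi)) pick(oxi, r) else 0)
  }, 0)
  summarize_reactivation(pct, oxime = oxime, enzyme = enzyme,
                         concentration = concentration)
}
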