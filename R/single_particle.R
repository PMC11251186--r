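# Conversion of raw single-particle observations (CDMS ion events, MP
# contrasts) into calibrated mass events.

#' CDMS charge calibration
#'
#' @param factor_k Charges per unit normalized single-ion intensity
#'   (default 14.713, the standard-protein calibration factor).
#' @param round_to_integer Round charges half-up to the nearest integer
#'   (>= 1)? Physical charges are integral; rounding sharpens the mass
#'   histogram. Default TRUE.
#' @param proton_mass Proton mass in Da.
#' @return A list of class `charge_calibration`.
#' @export
charge_calibration <- function(factor_k = 14.713, round_to_integer = TRUE,
                               proton_mass = 1.007276) {
  stopifnot(factor_k > 0, proton_mass > 0)
  structure(list(factor_k = factor_k, round_to_integer = round_to_integer,
                 proton_mass = proton_mass),
            class = "charge_calibration")
}

#' Convert normalized single-ion intensity to charge
#'
#' Raw charge = factor_k * intensity; optionally rounded half-up to the
#' nearest integer, floored at 1.
#'
#' @param intensity_norm Positive normalized intensity (vectorized).
#' @param cal A [charge_calibration()].
#' @return Charge(s), numeric (integral when rounding is on).
#' @examples
#' intensity_to_charge(1.0, charge_calibration(round_to_integer = FALSE))
#' @export
intensity_to_charge <- function(intensity_norm, cal = charge_calibration()) {
  stopifnot(inherits(cal, "charge_calibration"))
  if (any(!is.finite(intensity_norm)) || any(intensity_norm <= 0))
    stop("intensity_norm must be positive")
  z <- cal$factor_k * intensity_norm
  if (cal$round_to_integer) z <- pmax(1, floor(z + 0.5))
  z
}

#' Convert CDMS ion events to mass events
#'
#' mass (Da) = z * (m/z - proton mass), with z from
#' [intensity_to_charge()]; reported in kDa.
#'
#' @param events data.frame with columns `mz` and `intensity_norm` (extra
#'   columns are carried through).
#' @param cal A [charge_calibration()].
#' @return data.frame of mass events: `mass` (kDa), `charge`, `source`
#'   (`"cdms"`), plus any input ground-truth columns.
#' @export
cdms_event_to_mass <- function(events, cal = charge_calibration()) {
  stopifnot(is.data.frame(events),
            all(c("mz", "intensity_norm") %in% names(events)))
  if (any(events$mz <= 0)) stop("m/z must be positive")
  z <- intensity_to_charge(events$intensity_norm, cal)
  mass_kda <- z * (events$mz - cal$proton_mass) / 1000
  if (any(mass_kda <= 0)) stop("event(s) yield non-positive mass")
  out <- data.frame(mass = mass_kda, charge = z, source = "cdms")
  extra <- setdiff(names(events), c("mz", "intensity_norm"))
  if (length(extra)) out <- cbind(out, events[, extra, drop = FALSE])
  out
}

#' Fit a mass photometry contrast calibration
#'
#' Least-squares line contrast = slope * mass + intercept, fitted to the
#' per-calibrant median contrast (median first, for robustness to outlier
#' landing events).
#'
#' @param calibrant_events data.frame with columns `calibrant_mass` (kDa)
#'   and `contrast`.
#' @param calibrant_masses Optional subset of calibrant masses to use.
#' @return Object of class `mp_calibration`: `slope`, `intercept`, `r2`,
#'   `calibrant_masses`, `median_contrasts`.
#' @export
fit_mp_calibration <- function(calibrant_events, calibrant_masses = NULL) {
  stopifnot(is.data.frame(calibrant_events),
            all(c("calibrant_mass", "contrast") %in% names(calibrant_events)))
  if (!is.null(calibrant_masses))
    calibrant_events <- calibrant_events[
      calibrant_events$calibrant_mass %in% calibrant_masses, , drop = FALSE]
  masses <- sort(unique(calibrant_events$calibrant_mass))
  if (length(masses) < 2)
    stop("need at least 2 distinct calibrant masses")
  med <- vapply(masses, function(m)
    stats::median(calibrant_events$contrast[
      calibrant_events$calibrant_mass == m]), numeric(1))
  if (stats::var(med) == 0) stop("zero contrast variance across calibrants")
  fit <- stats::lm(med ~ masses)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, calibrant_masses = masses,
                 median_contrasts = med),
            class = "mp_calibration")
}

#' @export
print.mp_calibration <- function(x, ...) {
  cat(sprintf("<MP calibration> slope=%.4g contrast/kDa, intercept=%.4g, r2=%.5f\n",
              x$slope, x$intercept, x$r2))
  cat("  calibrants (kDa):", paste(x$calibrant_masses, collapse = ", "), "\n")
  invisible(x)
}

#' Convert MP contrasts to mass events
#'
#' mass = (contrast - intercept) / slope; events yielding non-positive
#' mass are dropped with a message reporting the count.
#'
#' @param events data.frame with a `contrast` column (extra columns carried
#'   through), or a numeric contrast vector.
#' @param cal An [fit_mp_calibration()] result or any list with `slope`
#'   and `intercept`.
#' @return data.frame of mass events: `mass` (kDa), `source` (`"mp"`).
#' @export
mp_contrast_to_mass <- function(events, cal) {
  stopifnot(!is.null(cal$slope), !is.null(cal$intercept), cal$slope != 0)
  if (is.numeric(events)) events <- data.frame(contrast = events)
  stopifnot("contrast" %in% names(events))
  mass <- (events$contrast - cal$intercept) / cal$slope
  keep <- mass > 0
  if (any(!keep))
    message(sum(!keep), " event(s) dropped (non-positive mass)")
  out <- data.frame(mass = mass[keep], source = "mp")
  extra <- setdiff(names(events), "contrast")
  if (length(extra)) out <- cbind(out, events[keep, extra, drop = FALSE])
  out
}
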