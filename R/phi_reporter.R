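#' Fit a fluorescence-pH calibration curve
#'
#' Fits the monotone calibration used to infer intracellular pH from a
#' pH-dependent fluorescent reporter. Standards are cells whose interior has
#' been equilibrated with the buffer (benzoate collapse), so the known
#' buffer pH is the intracellular pH. The default model is linear in pH,
#' fitted by least squares on all replicate readings; the fitted span is the
#' range of the standard pH values and its lower edge becomes the censoring
#' floor for [estimate_ph()].
#'
#' @param standards A data.frame with columns `pH` and `fluorescence`
#'   (arbitrary units, > 0); replicate rows per pH are allowed.
#' @return An object of class `calibration_curve` with fields `intercept`,
#'   `slope`, `span`, `censor_lo`, `sigma` (residual sd) and `r_squared`.
#' @details At least 3 distinct pH levels spanning >= 1 pH unit are
#'   required, and the per-level mean fluorescence must increase strictly
#'   with pH (the reporter brightens with pH); a reversed or non-monotone
#'   trend is a fit-quality error.
#' @examples
#' std <- data.frame(pH = c(5.5, 6.5, 7.5), fluorescence = c(50, 150, 250))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("pH", "fluorescence") %in% names(standards))) {
    stop("`standards` must be a data.frame with columns pH and fluorescence",
         call. = FALSE)
  }
  check_ph(standards$pH)
  if (any(!is.finite(standards$fluorescence)) ||
      any(standards$fluorescence <= 0)) {
    stop("standard fluorescence readings must be finite and > 0", call. = FALSE)
  }
  levels_pH <- sort(unique(standards$pH))
  if (length(levels_pH) < 3L) {
    stop("calibration needs >= 3 standards at distinct pH", call. = FALSE)
  }
  if (diff(range(levels_pH)) < 1) {
    stop("calibration standards must span >= 1 pH unit", call. = FALSE)
  }
  means <- vapply(levels_pH, function(p) {
    mean(standards$fluorescence[standards$pH == p])
  }, numeric(1))
  if (any(diff(means) <= 0)) {
    stop("standard mean fluorescence must increase strictly with pH; ",
         "the calibration trend is reversed or non-monotone", call. = FALSE)
  }
  fit <- stats::lm(fluorescence ~ pH, data = standards)
  r <- stats::residuals(fit)
  ss_tot <- sum((standards$fluorescence - mean(standards$fluorescence))^2)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 span = range(levels_pH),
                 censor_lo = min(levels_pH),
                 sigma = sqrt(sum(r^2) / stats::df.residual(fit)),
                 r_squared = if (ss_tot > 0) 1 - sum(r^2) / ss_tot else 1),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> F = %.3f + %.3f * pH over [%.2f, %.2f] (censor floor %.2f, R^2 %.4f)\n",
              x$intercept, x$slope, x$span[1], x$span[2], x$censor_lo,
              x$r_squared))
  invisible(x)
}

#' Predicted fluorescence at a given pH
#'
#' @param curve A [fit_calibration()] result.
#' @param pH pH values (vectorised).
#' @return Expected fluorescence in the curve's arbitrary units.
#' @export
predict_fluorescence <- function(curve, pH) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_ph(pH)
  curve$intercept + curve$slope * pH
}

#' Estimate intracellular pH from reporter fluorescence
#'
#' Inverts the calibration curve. Readings mapping below the calibrated
#' span's lower edge are censored: the estimate is reported *at* the floor
#' with `censored = TRUE`, meaning the true pH may be lower (the floor is an
#' upper bound). No upper censoring is applied. When >= 3 replicate
#' readings are given, a t-based 95% interval from the replicate spread of
#' per-replicate inversions is attached.
#'
#' @param fluorescence Numeric vector of replicate readings for one sample.
#' @param curve A [fit_calibration()] result.
#' @return An object of class `ph_estimate`: fields `value`, `censored`,
#'   `interval` (NA for < 3 replicates), `n_replicates`.
#' @examples
#' std <- data.frame(pH = c(5.5, 6.5, 7.5), fluorescence = c(50, 150, 250))
#' cal <- fit_calibration(std)
#' estimate_ph(260, cal) # pH 7.6
#' @export
estimate_ph <- function(fluorescence, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(fluorescence) || length(fluorescence) < 1L ||
      any(!is.finite(fluorescence))) {
    stop("`fluorescence` must be a finite numeric vector", call. = FALSE)
  }
  invert <- function(f) (f - curve$intercept) / curve$slope
  ph_reps <- invert(fluorescence)
  value <- invert(mean(fluorescence))
  censored <- value < curve$censor_lo
  if (censored) value <- curve$censor_lo
  interval <- c(NA_real_, NA_real_)
  n <- length(fluorescence)
  if (n >= 3L && !censored && stats::sd(ph_reps) > 0) {
    half <- stats::qt(0.975, df = n - 1L) * stats::sd(ph_reps) / sqrt(n)
    interval <- value + c(-half, half)
  }
  structure(list(value = value, censored = censored, interval = interval,
                 n_replicates = n),
            class = "ph_estimate")
}

#' @export
print.ph_estimate <- function(x, ...) {
  cat(sprintf("<ph_estimate> %s%.3f (%d replicate%s%s)\n",
              if (x$censored) "<= " else "", x$value, x$n_replicates,
              if (x$n_replicates > 1) "s" else "",
              if (x$censored) ", censored at the detection floor" else ""))
  invisible(x)
}

#' Estimate intracellular pH for a table of samples
#'
#' @param samples A data.frame with columns `sample_id` and `fluorescence`
#'   (one row per replicate reading).
#' @param curve A [fit_calibration()] result.
#' @return A data.frame with one row per sample: `sample_id`, `pH`,
#'   `censored`, `ci_lo`, `ci_hi`, `n_replicates`.
#' @export
estimate_ph_samples <- function(samples, curve) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "fluorescence") %in% names(samples))) {
    stop("`samples` must have columns sample_id and fluorescence", call. = FALSE)
  }
  ids <- unique(samples$sample_id)
  rows <- lapply(ids, function(id) {
    est <- estimate_ph(samples$fluorescence[samples$sample_id == id], curve)
    data.frame(sample_id = id, pH = est$value, censored = est$censored,
               ci_lo = est$interval[1], ci_hi = est$interval[2],
               n_replicates = est$n_replicates, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
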