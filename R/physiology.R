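#' OD time series for growth-rate estimation
#'
#' @param time Time points in hours.
#' @param od Optical density (OD550) readings, > 0.
#' @param window Length-2 bounds of the exponential phase (default: all
#'   points).
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(time, od, window = range(time)) {
  if (length(time) != length(od)) stop("time and od lengths differ", call. = FALSE)
  if (any(!is.finite(od)) || any(od <= 0)) {
    stop("OD readings must be finite and > 0", call. = FALSE)
  }
  window <- sort(window)
  if (sum(time >= window[1] & time <= window[2]) < 3L) {
    stop("exponential window must contain >= 3 points", call. = FALSE)
  }
  structure(list(time = time, od = od, window = window),
            class = "growth_series")
}

#' Specific growth rate from an OD time series
#'
#' The specific growth rate mu (h^-1) is the least-squares slope of ln(OD)
#' versus time over the exponential window.
#'
#' @param series A [growth_series()].
#' @return mu in h^-1.
#' @examples
#' t <- seq(0, 5, by = 1)
#' fit_growth_rate(growth_series(t, 0.05 * exp(0.6 * t))) # 0.6
#' @export
fit_growth_rate <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  keep <- series$time >= series$window[1] & series$time <= series$window[2]
  fit <- stats::lm(log(series$od[keep]) ~ series$time[keep])
  unname(stats::coef(fit)[2])
}

#' Percent growth inhibition
#'
#' @param mu_control Specific growth rate of the untreated culture (> 0),
#'   h^-1.
#' @param mu_treated Specific growth rate of the treated culture, h^-1.
#' @return 100 (1 - mu_treated / mu_control), in percent.
#' @examples
#' percent_inhibition(0.5, 0.385) # 23
#' @export
percent_inhibition <- function(mu_control, mu_treated) {
  if (!is.numeric(mu_control) || any(mu_control <= 0)) {
    stop("`mu_control` must be > 0", call. = FALSE)
  }
  100 * (1 - mu_treated / mu_control)
}

lipid_species <- c("C12:0", "C14:0", "C16:0", "C16:1",
                   "C17cyc", "C18:0", "C18:1", "C19cyc")
lipid_saturated <- c("C12:0", "C14:0", "C16:0", "C18:0")
lipid_unsaturated <- c("C16:1", "C18:1", "C17cyc", "C19cyc")
lipid_cyclopropane <- c("C17cyc", "C19cyc")

#' Membrane lipid mol% profile
#'
#' @param molpct Named numeric vector of mol% over (a subset of) the
#'   species C12:0, C14:0, C16:0, C16:1, C17cyc, C18:0, C18:1, C19cyc.
#'   Entries must be >= 0 and sum to 100 +/- 0.5; missing species count as
#'   zero.
#' @return An object of class `lipid_profile` (full named vector).
#' @export
lipid_profile <- function(molpct) {
  if (is.null(names(molpct)) || !all(names(molpct) %in% lipid_species)) {
    stop("mol% entries must be named by lipid species (",
         paste(lipid_species, collapse = ", "), ")", call. = FALSE)
  }
  if (any(!is.finite(molpct)) || any(molpct < 0)) {
    stop("mol% entries must be finite and >= 0", call. = FALSE)
  }
  full <- stats::setNames(numeric(length(lipid_species)), lipid_species)
  full[names(molpct)] <- molpct
  if (abs(sum(full) - 100) > 0.5) {
    stop(sprintf("mol%% must sum to 100 +/- 0.5 (got %.2f)", sum(full)),
         call. = FALSE)
  }
  structure(full, class = "lipid_profile")
}

#' Membrane composition metrics
#'
#' Computes, from a mol% lipid profile:
#' * the saturated:unsaturated ratio, S:U = (C12:0 + C14:0 + C16:0 + C18:0)
#'   / (C16:1 + C18:1 + C17cyc + C19cyc), with cyclopropane species counted
#'   in the unsaturated pool they derive from;
#' * the average lipid length, sum(mol% x chain length) / 100;
#' * total cyclopropane content, C17cyc + C19cyc mol%.
#'
#' @param profile A [lipid_profile()] (or named mol% vector).
#' @param length_convention `"actual"` counts the cyclopropane carbon
#'   (C17cyc = 17, C19cyc = 19); `"precursor"` groups them with their
#'   16- and 18-carbon families (16, 18).
#' @return A list: `su_ratio`, `avg_length`, `cyclopropane_molpct`.
#' @examples
#' pr <- lipid_profile(c("C16:0" = 30, "C16:1" = 40, "C17cyc" = 10,
#'                       "C18:1" = 20))
#' lipid_metrics(pr) # S:U 0.4286, length 16.5, cyclopropane 10
#' @export
lipid_metrics <- function(profile, length_convention = c("actual", "precursor")) {
  if (!inherits(profile, "lipid_profile")) profile <- lipid_profile(profile)
  length_convention <- match.arg(length_convention)
  x <- unclass(profile)
  unsat <- sum(x[lipid_unsaturated])
  if (unsat == 0) stop("undefined S:U ratio: unsaturated pool is zero",
                       call. = FALSE)
  lengths <- c("C12:0" = 12, "C14:0" = 14, "C16:0" = 16, "C16:1" = 16,
               "C17cyc" = 17, "C18:0" = 18, "C18:1" = 18, "C19cyc" = 19)
  if (length_convention == "precursor") {
    lengths["C17cyc"] <- 16
    lengths["C19cyc"] <- 18
  }
  list(su_ratio = sum(x[lipid_saturated]) / unsat,
       avg_length = sum(x * lengths[names(x)]) / sum(x),
       cyclopropane_molpct = sum(x[lipid_cyclopropane]))
}

#' GABA proton-sink accounting
#'
#' Glutamate decarboxylation consumes one intracellular proton per GABA
#' produced, so total GABA (intracellular + extracellular) is a lower
#' bound on protons sunk by the glutamate-dependent acid resistance
#' system - a lower bound because GABA can be further converted to
#' succinate and escape the count.
#'
#' @param intracellular,extracellular Non-negative GABA concentrations in a
#'   common unit.
#' @return A list: `total` and `protons_sunk` (equal; the latter is a
#'   lower bound).
#' @export
gaba_balance <- function(intracellular, extracellular) {
  if (any(!is.finite(c(intracellular, extracellular))) ||
      any(c(intracellular, extracellular) < 0)) {
    stop("GABA concentrations must be finite and >= 0", call. = FALSE)
  }
  total <- intracellular + extracellular
  list(total = total, protons_sunk = total)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param m_tests Number of tests (>= 1). For a survey over the 20
#'   proteinogenic amino acids at alpha = 0.05 the cutoff is 0.0025.
#' @return alpha / m_tests.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m_tests) || m_tests < 1) {
    stop("`m_tests` must be >= 1", call. = FALSE)
  }
  alpha / m_tests
}
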