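#' Acid-challenge scenario
#'
#' A named physiological state of the cell used by the shock/adaptation
#' solver: intracellular and extracellular pH, membrane potential, the acid
#' applied, and the PMF target the cell regulates towards. When `delta_psi`
#' is omitted for a `normal` scenario, it is closed over the PMF anchor:
#' given pH_i, pH_e and the target mean PMF, Delta-psi is solved as
#' target - ph_gradient_force (for the textbook state pH 7.6 in / 7.0 out
#' and -160 mV this gives about -123.1 mV).
#'
#' @param label One of `"normal"`, `"shock"`, `"adapted"`.
#' @param acid An [acid_species()] for carboxylic acids, or the string
#'   `"inorganic"` for strong mineral acids such as HCl.
#' @param dose_mM Acid dose in mM (>= 0).
#' @param pH_i,pH_e Intracellular and extracellular pH.
#' @param delta_psi Membrane potential in mV (inside minus outside); if
#'   `NULL` and `label = "normal"`, solved from the PMF anchor.
#' @param thermo A [thermo_context()].
#' @param target_pmf_mean Target PMF in mV (default -160, the physiological
#'   average).
#' @param target_pmf_range Admissible PMF interval in mV (default
#'   c(-180, -140), the physiological range for E. coli).
#' @return An object of class `scenario`.
#' @examples
#' normal_scenario()
#' @export
scenario <- function(label = c("normal", "shock", "adapted"),
                     acid = "inorganic", dose_mM = 0,
                     pH_i, pH_e, delta_psi = NULL,
                     thermo = thermo_context(),
                     target_pmf_mean = -160,
                     target_pmf_range = c(-180, -140)) {
  label <- match.arg(label)
  check_ph(pH_i, "pH_i"); check_ph(pH_e, "pH_e")
  thermo <- as_thermo(thermo)
  target_pmf_range <- sort(target_pmf_range)
  if (length(target_pmf_range) != 2L ||
      target_pmf_mean < target_pmf_range[1] ||
      target_pmf_mean > target_pmf_range[2]) {
    stop("`target_pmf_range` must be an interval containing `target_pmf_mean`",
         call. = FALSE)
  }
  if (dose_mM < 0) stop("`dose_mM` must be >= 0", call. = FALSE)
  if (is.null(delta_psi)) {
    if (label != "normal") {
      stop("`delta_psi` may only be solved implicitly for a normal scenario",
           call. = FALSE)
    }
    delta_psi <- target_pmf_mean - ph_gradient_force(pH_i, pH_e, thermo)
  }
  structure(list(label = label, acid = acid, dose_mM = dose_mM,
                 pH_i = pH_i, pH_e = pH_e, delta_psi = delta_psi,
                 thermo = thermo, target_pmf_mean = target_pmf_mean,
                 target_pmf_range = target_pmf_range),
            class = "scenario")
}

#' @rdname scenario
#' @export
normal_scenario <- function(pH_i = 7.6, pH_e = 7.0,
                            thermo = thermo_context(),
                            target_pmf_mean = -160,
                            target_pmf_range = c(-180, -140)) {
  scenario("normal", pH_i = pH_i, pH_e = pH_e, thermo = thermo,
           target_pmf_mean = target_pmf_mean,
           target_pmf_range = target_pmf_range)
}

scenario_result <- function(label, scenario, pH_i, pH_e, delta_psi,
                            delta_psi_required = NA_real_,
                            ion_fold_change = NA_real_) {
  ph_force <- ph_gradient_force(pH_i, pH_e, scenario$thermo)
  pmf <- delta_psi + ph_force
  structure(list(label = label, pH_i = pH_i, pH_e = pH_e,
                 delta_psi = delta_psi, psi_force = delta_psi,
                 ph_force = ph_force, pmf = pmf,
                 inverted = pmf > 0,
                 delta_psi_required = delta_psi_required,
                 ion_fold_change = ion_fold_change,
                 scenario = scenario),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: %s> pH_i %.2f / pH_e %.2f | dpsi %.1f mV | pH force %.1f mV | PMF %.1f mV%s\n",
              x$label, x$pH_i, x$pH_e, x$delta_psi, x$ph_force, x$pmf,
              if (isTRUE(x$inverted)) " [INVERTED]" else ""))
  if (is.finite(x$ion_fold_change)) {
    cat(sprintf("  adaptation: required dpsi %.1f mV, carrier-ion fold change %.3g\n",
                x$delta_psi_required, x$ion_fold_change))
  }
  invisible(x)
}

is_carboxylic <- function(acid) {
  inherits(acid, "acid_species") && isTRUE(acid$permeant_protonated)
}

#' Instantaneous acid shock
#'
#' Computes the PMF immediately after an extreme acid challenge, before any
#' cellular response. The two acid classes behave differently:
#'
#' * **Inorganic** (e.g. HCl): the acid adds equal amounts of protons and
#'   anions outside, so the membrane potential is unchanged; only the pH
#'   terms move. If the medium is not re-adjusted, the post-shock
#'   extracellular pH must be supplied via `pH_e` (it is never guessed).
#' * **Carboxylic** (e.g. C8): the neutral protonated acid crosses the
#'   membrane and deprotonates inside, irreversibly loading the cytoplasm
#'   with protons. The uncompensated positive charge shifts the membrane
#'   potential by +Z (pH_i_normal - pH_i_shock), the Nernst equivalent of
#'   the proton-pool fold increase. With a collapsed pH gradient this can
#'   invert the PMF to positive values.
#'
#' @param normal A `"normal"` [scenario()] (the pre-challenge state).
#' @param acid An [acid_species()] or `"inorganic"`.
#' @param dose_mM Acid dose in mM; a zero dose is a no-op.
#' @param measured_pH_i Post-shock intracellular pH (from reporter data or a
#'   preset).
#' @param pH_e Post-shock extracellular pH. Defaults to the normal-state
#'   value (medium re-adjusted); pass the acidified value for unadjusted
#'   media.
#' @return A `scenario_result` with the shock-phase PMF and an `inverted`
#'   flag set when PMF > 0.
#' @examples
#' ns <- normal_scenario()
#' apply_shock(ns, octanoic_acid(), 20, measured_pH_i = 5.5)
#' @export
apply_shock <- function(normal, acid, dose_mM, measured_pH_i,
                        pH_e = NULL) {
  stopifnot(inherits(normal, "scenario"))
  if (normal$label != "normal") {
    stop("`normal` must be a scenario with label 'normal'", call. = FALSE)
  }
  if (dose_mM < 0) stop("`dose_mM` must be >= 0", call. = FALSE)
  if (dose_mM == 0) {
    return(scenario_result("normal", normal, normal$pH_i, normal$pH_e,
                           normal$delta_psi))
  }
  check_ph(measured_pH_i, "measured_pH_i")
  pH_e <- if (is.null(pH_e)) normal$pH_e else check_ph(pH_e, "pH_e")

  shocked <- scenario("shock", acid = acid, dose_mM = dose_mM,
                      pH_i = measured_pH_i, pH_e = pH_e,
                      delta_psi = normal$delta_psi, thermo = normal$thermo,
                      target_pmf_mean = normal$target_pmf_mean,
                      target_pmf_range = normal$target_pmf_range)

  if (is_carboxylic(acid)) {
    if (measured_pH_i >= normal$pH_i) {
      warning("carboxylic shock with pH_i >= normal pH_i: no proton load",
              call. = FALSE)
    }
    dpsi <- normal$delta_psi +
      zeta_factor(normal$thermo) * (normal$pH_i - measured_pH_i)
  } else {
    dpsi <- normal$delta_psi # equal anions and protons: potential unchanged
  }
  scenario_result("shock", shocked, measured_pH_i, pH_e, dpsi)
}

#' Solve the adapted state that restores the PMF target
#'
#' After the instantaneous shock, the cell adjusts its membrane potential by
#' net ion transport until the PMF returns to the target mean: cation
#' accumulation (or anion release) for inorganic acids, anion accumulation
#' for carboxylic acids whose inverted pH gradient demands a strongly
#' negative Delta-psi. The required potential has the closed form
#' Delta-psi = target - ph_force; a bisection solver over the same PMF
#' function is available as a numerical cross-check.
#'
#' The carrier-ion cost is summarised as
#' `ion_fold_change = exp(|Delta-Delta-psi| F / (R T))` for a single
#' monovalent ion, the Nernst fold-change of that ion's pool between the
#' pre-adaptation and adapted states.
#'
#' @param shock A `scenario_result` from [apply_shock()].
#' @param scenario Optional [scenario()] carrying the target; defaults to
#'   the one embedded in `shock`.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @param tol Convergence tolerance on the PMF, mV.
#' @param max_iter Bisection iteration cap.
#' @return A `scenario_result` with `delta_psi_required` and
#'   `ion_fold_change` populated; its PMF is within `tol` of the target.
#' @examples
#' ns <- normal_scenario()
#' sh <- apply_shock(ns, octanoic_acid(), 20, measured_pH_i = 5.5)
#' solve_adaptation(sh)
#' @export
solve_adaptation <- function(shock, scenario = shock$scenario,
                             method = c("closed_form", "bisection"),
                             tol = 0.1, max_iter = 200) {
  stopifnot(inherits(shock, "scenario_result"), inherits(scenario, "scenario"))
  method <- match.arg(method)
  target <- scenario$target_pmf_mean
  rng <- scenario$target_pmf_range
  if (target < rng[1] || target > rng[2]) {
    stop("target PMF must lie inside the target range", call. = FALSE)
  }
  ph_force <- ph_gradient_force(shock$pH_i, shock$pH_e, scenario$thermo)

  if (method == "closed_form") {
    dpsi <- target - ph_force
  } else {
    f <- function(d) pmf_total(d, shock$pH_i, shock$pH_e, scenario$thermo) - target
    lo <- -2000; hi <- 2000
    if (f(lo) * f(hi) > 0) stop("adaptation solver failed to bracket the target",
                                call. = FALSE)
    iter <- 0L
    while (hi - lo > tol / 10 && iter < max_iter) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      iter <- iter + 1L
    }
    dpsi <- (lo + hi) / 2
  }
  if (!is.finite(dpsi)) {
    stop("adaptation solver produced a non-finite membrane potential",
         call. = FALSE)
  }
  th <- scenario$thermo
  ddpsi <- dpsi - shock$delta_psi
  fold <- exp(abs(ddpsi) / 1000 * th$F / (th$R * th$T))
  if (!is.finite(fold)) {
    stop("adaptation solver failed: required ion fold change is non-finite",
         call. = FALSE)
  }
  res <- scenario_result("adapted", scenario, shock$pH_i, shock$pH_e, dpsi,
                         delta_psi_required = dpsi, ion_fold_change = fold)
  if (abs(res$pmf - target) > tol) {
    stop(sprintf("adaptation solver failed: |PMF - target| = %.3g mV > %.3g mV",
                 abs(res$pmf - target), tol), call. = FALSE)
  }
  res
}

#' Run the normal / shock / adapted phases of an acid-challenge scenario
#'
#' Convenience driver producing the full three-phase trajectory as a tidy
#' table, one row per phase.
#'
#' @param acid An [acid_species()] or `"inorganic"`.
#' @param dose_mM Acid dose in mM.
#' @param measured_pH_i Post-shock intracellular pH.
#' @param pH_e_shock Post-shock extracellular pH (default: normal pH_e).
#' @param normal The pre-challenge [normal_scenario()].
#' @return A data.frame with columns `label`, `pH_i`, `pH_e`,
#'   `delta_psi_mV`, `ph_force_mV`, `pmf_mV`, `inverted`,
#'   `ion_fold_change`.
#' @export
run_pmf_scenario <- function(acid, dose_mM, measured_pH_i,
                             pH_e_shock = NULL,
                             normal = normal_scenario()) {
  nr <- apply_shock(normal, acid, 0, measured_pH_i = normal$pH_i)
  sh <- apply_shock(normal, acid, dose_mM, measured_pH_i, pH_e = pH_e_shock)
  ad <- solve_adaptation(sh)
  rows <- lapply(list(nr, sh, ad), function(r) {
    data.frame(label = r$label, pH_i = r$pH_i, pH_e = r$pH_e,
               delta_psi_mV = r$delta_psi, ph_force_mV = r$ph_force,
               pmf_mV = r$pmf, inverted = r$inverted,
               ion_fold_change = r$ion_fold_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an acid-challenge scenario from a YAML file
#'
#' Expected keys: `acid` (name; `"inorganic"` for mineral acids), `pKa`
#' (required for carboxylic acids), `dose_mM`, `pH_i` (post-shock
#' intracellular pH), `pH_e` (post-shock extracellular pH; optional),
#' `temperature_K`, `target_pmf_mV`, `target_range_mV` (length-2),
#' and optional `pH_i_normal` / `pH_e_normal` (defaults 7.6 / 7.0).
#'
#' @param path Path to the YAML scenario file.
#' @return A list with elements `normal` (a [scenario()]), `acid`,
#'   `dose_mM`, `measured_pH_i` and `pH_e_shock`, ready for
#'   [run_pmf_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("acid", "dose_mM", "pH_i")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("scenario file is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  acid <- if (identical(cfg$acid, "inorganic")) "inorganic" else {
    if (is.null(cfg$pKa)) stop("carboxylic scenario requires `pKa`", call. = FALSE)
    acid_species(cfg$acid, cfg$pKa)
  }
  th <- thermo_context(cfg$temperature_K %||% 310.15)
  normal <- normal_scenario(pH_i = cfg$pH_i_normal %||% 7.6,
                            pH_e = cfg$pH_e_normal %||% 7.0,
                            thermo = th,
                            target_pmf_mean = cfg$target_pmf_mV %||% -160,
                            target_pmf_range = unlist(cfg$target_range_mV %||%
                                                        c(-180, -140)))
  list(normal = normal, acid = acid, dose_mM = cfg$dose_mM,
       measured_pH_i = cfg$pH_i, pH_e_shock = cfg$pH_e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
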