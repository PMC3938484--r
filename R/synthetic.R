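# ---------------------------------------------------------------------------
# Preset registry: every constant a generator embeds, in one place.
# Values marked [measured] are physiological values reported for the modelled
# study conditions (E. coli MG1655, MOPS minimal medium, pH 7.0, 37 C unless
# noted); the rest are generator choices documented in the methods vignette.
# ---------------------------------------------------------------------------
.presets <- list(
  growth = list(
    # mu_control: typical MG1655 exponential rate in MOPS minimal glucose.
    # inhibition 0.23: 10 mM C8 at pH 7.0 inhibits growth by 23% [measured].
    c8_10mM = list(mu_control = 0.60, inhibition = 0.23, od0 = 0.05,
                   t_max = 5, n_points = 11, noise_cv = 0.02),
    control = list(mu_control = 0.60, inhibition = 0.00, od0 = 0.05,
                   t_max = 5, n_points = 11, noise_cv = 0.02)
  ),
  fluorescence = list(
    # Reporter curve: linear in pH, F = 20 + 100 (pH - 5), arbitrary units.
    # true_pH values [measured]: 5.32 after 20 mM HCl with unadjusted media;
    # at/below the 5.5 reporter floor after 3 h C8 (value here is nominal,
    # chosen below the floor); > 6.5 during carboxylic acid production;
    # 7.6 resting intracellular pH.
    hcl_20mM_unadjusted = list(true_pH = 5.32,
                               standard_pH = seq(5.0, 8.0, by = 0.5),
                               n_std_rep = 3, n_sample_rep = 4,
                               noise_cv = 0.02),
    c8_longterm = list(true_pH = 5.2,
                       standard_pH = seq(5.5, 8.0, by = 0.5),
                       n_std_rep = 3, n_sample_rep = 4, noise_cv = 0.02),
    production = list(true_pH = 6.8,
                      standard_pH = seq(5.5, 8.0, by = 0.5),
                      n_std_rep = 3, n_sample_rep = 4, noise_cv = 0.02),
    control = list(true_pH = 7.6,
                   standard_pH = seq(5.5, 8.0, by = 0.5),
                   n_std_rep = 3, n_sample_rep = 4, noise_cv = 0.02)
  ),
  fluor_curve = list(intercept = -480, slope = 100), # F = 20 at pH 5.0
  lipids = list(
    # Base mol% profiles at zero dose. Cyclopropane content anchors
    # [measured]: > 32 mol% for cfa overexpression, < 11 mol% wildtype,
    # zero for the cfa deletion.
    WT    = c("C12:0" = 2, "C14:0" = 3, "C16:0" = 31, "C16:1" = 28,
              "C17cyc" = 6, "C18:0" = 2, "C18:1" = 25, "C19cyc" = 3),
    dcfa  = c("C12:0" = 2, "C14:0" = 3, "C16:0" = 29, "C16:1" = 36,
              "C17cyc" = 0, "C18:0" = 2, "C18:1" = 28, "C19cyc" = 0),
    `cfa++` = c("C12:0" = 1, "C14:0" = 2, "C16:0" = 27, "C16:1" = 8,
                "C17cyc" = 23, "C18:0" = 2, "C18:1" = 24, "C19cyc" = 13),
    # mol% moved per mM C8: WT/dcfa shift saturated C16:0 into unsaturated
    # C18:1 (S:U falls, average length rises with dose); cfa++ shifts the
    # other way (its S:U rises relative to wildtype under C8).
    dose_shift = 0.35, dose_shift_cfapp = 0.15,
    dirichlet_conc = 100
  ),
  gaba = list(
    # Concentration means (uM). Orderings: control pools roughly equal
    # in/out; glutamate raises export at unchanged total; C8 lowers every
    # pool with or without glutamate.
    control       = c(intracellular = 5.0, extracellular = 5.0),
    glutamate     = c(intracellular = 3.0, extracellular = 7.0),
    c8            = c(intracellular = 2.0, extracellular = 2.5),
    c8_glutamate  = c(intracellular = 2.2, extracellular = 3.3),
    noise_cv = 0.05
  ),
  de = list(
    # Spiked two-condition study: 4-fold (|log2 FC| = 2) signal genes on a
    # null background, log2 noise sd 0.25, 4 replicates per condition.
    default = list(n_genes = 500, n_de = 10, lfc = 2, sd = 0.25, n_rep = 4,
                   baseline_mean = 8, baseline_sd = 1.5)
  )
)

#' Synthetic-data preset registry
#'
#' @return The nested list of named presets used by the `gen_*` generators,
#'   with the parameter values each embeds.
#' @export
preset_registry <- function() .presets

get_preset <- function(group, name) {
  p <- .presets[[group]][[name]]
  if (is.null(p)) {
    stop(sprintf("unknown %s preset '%s' (available: %s)", group, name,
                 paste(names(.presets[[group]]), collapse = ", ")),
         call. = FALSE)
  }
  p
}

mult_noise <- function(x, cv) x * exp(stats::rnorm(length(x), 0, cv))

#' Generate paired control/treated growth curves
#'
#' Exponential OD550 series for a control and a treated culture whose true
#' specific growth rates embed the preset's inhibition fraction, with
#' multiplicative lognormal noise. The true rates are recorded in `truth`.
#'
#' @param preset Preset name: `"c8_10mM"` (23% inhibition at 10 mM C8) or
#'   `"control"` (no inhibition).
#' @param seed Integer seed.
#' @return A list: `control` and `treated` ([growth_series()]), `truth`
#'   (`mu_control`, `mu_treated`, `inhibition_pct`).
#' @examples
#' g <- gen_growth_curves("c8_10mM", seed = 17)
#' percent_inhibition(fit_growth_rate(g$control), fit_growth_rate(g$treated))
#' @export
gen_growth_curves <- function(preset = "c8_10mM", seed = 1) {
  p <- get_preset("growth", preset)
  set.seed(seed)
  mu_c <- p$mu_control
  mu_t <- mu_c * (1 - p$inhibition)
  t <- seq(0, p$t_max, length.out = p$n_points)
  make <- function(mu) {
    od <- p$od0 * exp(mu * t)
    if (p$noise_cv > 0) od <- mult_noise(od, p$noise_cv)
    growth_series(t, od)
  }
  list(control = make(mu_c), treated = make(mu_t),
       truth = list(mu_control = mu_c, mu_treated = mu_t,
                    inhibition_pct = 100 * p$inhibition))
}

#' Generate reporter calibration standards and sample readings
#'
#' Benzoate-collapse-style standards over the preset's pH grid plus
#' replicate fluorescence readings of a sample with known true pH, all from
#' the same monotone linear pH-fluorescence curve with multiplicative
#' noise. The `hcl_20mM_unadjusted` preset carries standards down to pH
#' 5.0 so its acidified sample lies inside the calibrated span; the other
#' presets use the usual 5.5-8.0 span whose lower edge is the reporter's
#' detection floor.
#'
#' @param preset One of `"hcl_20mM_unadjusted"`, `"c8_longterm"`,
#'   `"production"`, `"control"`.
#' @param seed Integer seed.
#' @return A list: `standards` (data.frame pH, fluorescence, replicate),
#'   `samples` (data.frame sample_id, fluorescence, replicate), `truth`
#'   (`true_pH`, curve parameters).
#' @export
gen_fluorescence <- function(preset = "hcl_20mM_unadjusted", seed = 1) {
  p <- get_preset("fluorescence", preset)
  curve <- .presets$fluor_curve
  set.seed(seed)
  f_of <- function(pH) curve$intercept + curve$slope * pH
  std <- expand.grid(replicate = seq_len(p$n_std_rep), pH = p$standard_pH)
  std$fluorescence <- mult_noise(f_of(std$pH), p$noise_cv)
  std <- std[, c("pH", "fluorescence", "replicate")]
  smp <- data.frame(sample_id = preset,
                    fluorescence = mult_noise(rep(f_of(p$true_pH),
                                                  p$n_sample_rep),
                                              p$noise_cv),
                    replicate = seq_len(p$n_sample_rep))
  list(standards = std, samples = smp,
       truth = list(true_pH = p$true_pH, intercept = curve$intercept,
                    slope = curve$slope))
}

#' Generate a membrane lipid mol% profile
#'
#' Strain-specific base compositions with a deterministic dose response
#' (for the wildtype, increasing C8 dose moves saturated C16:0 into
#' unsaturated C18:1, so the S:U ratio falls and the average lipid length
#' rises; the cfa-overexpression strain shifts the other way) and Dirichlet
#' measurement noise. The cfa-deletion strain has exactly zero cyclopropane
#' species at any dose.
#'
#' @param strain `"WT"`, `"dcfa"` (cfa deletion) or `"cfa++"`
#'   (overexpression).
#' @param dose_mM C8 dose in mM (>= 0).
#' @param seed Integer seed.
#' @return A [lipid_profile()] with attribute `truth` (the noise-free base
#'   composition after the dose shift).
#' @export
gen_lipid_profiles <- function(strain = c("WT", "dcfa", "cfa++"),
                               dose_mM = 0, seed = 1) {
  strain <- match.arg(strain)
  if (dose_mM < 0) stop("`dose_mM` must be >= 0", call. = FALSE)
  L <- .presets$lipids
  base <- L[[strain]]
  if (strain == "cfa++") {
    shift <- min(L$dose_shift_cfapp * dose_mM, base[["C18:1"]] - 5)
    base[["C18:1"]] <- base[["C18:1"]] - shift
    base[["C16:0"]] <- base[["C16:0"]] + shift
  } else {
    shift <- min(L$dose_shift * dose_mM, base[["C16:0"]] - 5)
    base[["C16:0"]] <- base[["C16:0"]] - shift
    base[["C18:1"]] <- base[["C18:1"]] + shift
  }
  set.seed(seed)
  pos <- base > 0
  draw <- numeric(length(base))
  draw[pos] <- stats::rgamma(sum(pos), shape = base[pos] * L$dirichlet_conc)
  molpct <- stats::setNames(100 * draw / sum(draw), names(base))
  out <- lipid_profile(molpct)
  attr(out, "truth") <- base
  out
}

#' Generate a GABA measurement
#'
#' Intra- and extracellular GABA concentrations drawn around
#' condition-specific means with multiplicative noise. The condition means
#' encode the qualitative behaviour of the glutamate-dependent acid
#' resistance system: balanced pools in the control, glutamate
#' supplementation shifting GABA outward at unchanged total, and C8
#' challenge depressing every pool.
#'
#' @param condition One of `"control"`, `"glutamate"`, `"c8"`,
#'   `"c8_glutamate"`.
#' @param seed Integer seed.
#' @return A list: `intracellular`, `extracellular`, `condition`, `truth`
#'   (the noise-free means).
#' @export
gen_gaba <- function(condition = c("control", "glutamate", "c8",
                                   "c8_glutamate"), seed = 1) {
  condition <- match.arg(condition)
  m <- get_preset("gaba", condition)
  set.seed(seed)
  vals <- mult_noise(m, .presets$gaba$noise_cv)
  list(intracellular = unname(vals["intracellular"]),
       extracellular = unname(vals["extracellular"]),
       condition = condition, truth = as.list(m))
}

#' Generate an identifiable random regulatory topology
#'
#' Each TF receives one private target gene (which guarantees the NCA
#' identifiability criteria) plus random additional targets; edge signs are
#' drawn at random.
#'
#' @param n_tf Number of transcription factors.
#' @param n_genes Number of genes (>= 2 * n_tf).
#' @param extra_frac Probability of each non-private TF-gene edge.
#' @param seed Integer seed.
#' @return A [regulatory_topology()].
#' @export
gen_topology <- function(n_tf = 5, n_genes = 30, extra_frac = 0.15, seed = 1) {
  if (n_genes < 2 * n_tf) stop("need n_genes >= 2 * n_tf", call. = FALSE)
  set.seed(seed)
  tfs <- paste0("TF", seq_len(n_tf))
  genes <- paste0("g", seq_len(n_genes))
  edges <- data.frame(TF = tfs, gene = genes[seq_len(n_tf)],
                      stringsAsFactors = FALSE) # private targets
  for (l in seq_len(n_tf)) {
    extra <- genes[-seq_len(n_tf)][stats::runif(n_genes - n_tf) < extra_frac]
    if (length(extra)) {
      edges <- rbind(edges, data.frame(TF = tfs[l], gene = extra,
                                       stringsAsFactors = FALSE))
    }
  }
  # make sure every gene is regulated by someone
  orphan <- setdiff(genes, edges$gene)
  if (length(orphan)) {
    edges <- rbind(edges, data.frame(TF = sample(tfs, length(orphan),
                                                 replace = TRUE),
                                     gene = orphan, stringsAsFactors = FALSE))
  }
  edges$sign <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  regulatory_topology(edges, tfs = tfs, genes = genes)
}

#' Generate expression data from the NCA model
#'
#' Draws a connectivity matrix A on the topology's support (magnitudes
#' uniform on \[0.5, 2\], signs following annotated edge signs where
#' present) and emits E = A P + Gaussian noise, with `n_replicates`
#' noisy replicate columns per condition of `true_P`.
#'
#' @param topology A [regulatory_topology()].
#' @param true_P TFs x conditions matrix of true activities (rownames must
#'   match the topology TFs; colnames name the conditions).
#' @param noise_sd Gaussian noise sd in log2 units (>= 0).
#' @param n_replicates Replicate columns per condition.
#' @param seed Integer seed.
#' @return A list: `matrix` (genes x samples), `samples` (sample sheet with
#'   `sample_id`, `condition`), `truth` (`A`, `P`, `identifiable`).
#' @export
gen_expression <- function(topology, true_P, noise_sd = 0.05,
                           n_replicates = 1, seed = 1) {
  stopifnot(inherits(topology, "regulatory_topology"), is.matrix(true_P))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(rownames(true_P)) &&
      !identical(rownames(true_P), topology$tfs)) {
    true_P <- true_P[topology$tfs, , drop = FALSE]
  }
  ident <- check_identifiability(topology, ncol(true_P) * n_replicates)
  if (!ident$pass) {
    warning("topology fails NCA identifiability; recovery is not guaranteed",
            call. = FALSE)
  }
  set.seed(seed)
  S <- topology$support
  A <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  sgn <- topology$signs[S]
  sgn[sgn == 0] <- sample(c(-1, 1), sum(sgn == 0), replace = TRUE)
  A[S] <- sgn * stats::runif(sum(S), 0.5, 2)
  conds <- colnames(true_P) %||% paste0("cond", seq_len(ncol(true_P)))
  cols <- list()
  sample_id <- condition <- character(0)
  for (c in seq_along(conds)) {
    for (r in seq_len(n_replicates)) {
      e <- A %*% true_P[, c]
      if (noise_sd > 0) e <- e + stats::rnorm(length(e), 0, noise_sd)
      cols[[length(cols) + 1L]] <- e
      sample_id <- c(sample_id, paste0(conds[c], "_r", r))
      condition <- c(condition, conds[c])
    }
  }
  M <- do.call(cbind, cols)
  dimnames(M) <- list(rownames(S), sample_id)
  list(matrix = M,
       samples = data.frame(sample_id = sample_id, condition = condition,
                            stringsAsFactors = FALSE),
       truth = list(A = A, P = true_P, identifiable = ident$pass))
}

#' Generate a spiked two-condition differential-expression study
#'
#' A null log2-expression background with `n_de` genes shifted by `lfc` in
#' the treated condition, the ground-truth benchmark for the permutation
#' test / FDR pipeline.
#'
#' @param n_genes Total genes (signal + null).
#' @param n_de Number of true differentially expressed genes.
#' @param lfc True log2 fold change of the spiked genes.
#' @param sd Log2 noise standard deviation.
#' @param n_rep Replicates per condition.
#' @param seed Integer seed.
#' @return An [expression_study()] with attribute `truth` listing the
#'   spiked gene ids.
#' @export
gen_de_study <- function(n_genes = 500, n_de = 10, lfc = 2, sd = 0.25,
                         n_rep = 4, seed = 1) {
  p <- .presets$de$default
  set.seed(seed)
  base <- stats::rnorm(n_genes, p$baseline_mean, p$baseline_sd)
  M <- matrix(stats::rnorm(n_genes * 2 * n_rep, 0, sd), n_genes) + base
  de_idx <- seq_len(n_de)
  M[de_idx, n_rep + seq_len(n_rep)] <-
    M[de_idx, n_rep + seq_len(n_rep)] + lfc
  genes <- sprintf("gene%04d", seq_len(n_genes))
  rownames(M) <- genes
  sample_id <- c(paste0("ctrl_r", seq_len(n_rep)),
                 paste0("trt_r", seq_len(n_rep)))
  colnames(M) <- sample_id
  st <- expression_study(M, data.frame(
    sample_id = sample_id,
    condition = rep(c("control", "treated"), each = n_rep),
    stringsAsFactors = FALSE))
  attr(st, "truth") <- list(de_genes = genes[de_idx], lfc = lfc)
  st
}
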