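# small fixtures shared across test files; everything is built in code

# exact linear calibration standards: F = 100 * (pH - 5.0)
exact_standards <- function(pH = c(5.5, 6.5, 7.5)) {
  data.frame(pH = pH, fluorescence = 100 * (pH - 5.0))
}

# a 6-gene / 2-TF / 4-condition identifiable toy system with known factors
toy_nca_system <- function() {
  edges <- data.frame(
    TF = c("TF1", "TF1", "TF1", "TF2", "TF2", "TF2"),
    gene = c("g1", "g2", "g3", "g4", "g5", "g3"),
    sign = c(1, 1, -1, 1, -1, 1))
  topo <- regulatory_topology(edges)
  A0 <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), c("TF1", "TF2")))
  A0["g1", "TF1"] <- 1.0
  A0["g2", "TF1"] <- 0.6
  A0["g3", "TF1"] <- -0.8
  A0["g4", "TF2"] <- 1.2
  A0["g5", "TF2"] <- -0.5
  A0["g3", "TF2"] <- 0.7
  # g6 is unregulated in this toy; drop it from the topology gene set
  A0 <- A0[topo$genes, , drop = FALSE]
  P0 <- matrix(c(1, -0.5, 0.25, 2,
                 -1, 1.5, 0.5, -0.25), 2, 4, byrow = TRUE,
               dimnames = list(c("TF1", "TF2"), paste0("c", 1:4)))
  list(topology = topo, A = A0, P = P0, E = A0 %*% P0)
}

# independent brute-force enumeration of the two-sample permutation test
# for one gene (oracle for permutation_t_test, per-gene null)
brute_force_perm_p <- function(x_control, x_treated) {
  vals <- c(x_control, x_treated)
  n <- length(vals)
  n_t <- length(x_treated)
  tstat <- function(idx_t) {
    a <- vals[idx_t]; b <- vals[-idx_t]
    sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2))
    d <- sp * sqrt(1 / length(a) + 1 / length(b))
    if (d == 0) return(0)
    (mean(a) - mean(b)) / d
  }
  obs <- abs(tstat(seq.int(n - n_t + 1, n)))
  splits <- utils::combn(n, n_t, simplify = FALSE)
  mean(vapply(splits, function(s) abs(tstat(s)) >= obs - 1e-10, logical(1)))
}
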