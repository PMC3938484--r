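#' Signed TF-gene regulatory topology
#'
#' The fixed sparsity pattern for network component analysis: which
#' transcription factor (TF) may regulate which gene, optionally with the
#' regulatory sign (+1 activation, -1 repression, 0 unknown). The pattern is
#' the support of the connectivity matrix A in the model E = A P.
#'
#' @param edges Data.frame with columns `TF`, `gene` and optionally `sign`
#'   (values in -1, 0, +1, or "+", "-", "0"). Duplicate TF-gene pairs are an
#'   error.
#' @param tfs,genes Optional explicit label sets (superset of those in
#'   `edges`); TFs with no targets are tolerated here and flagged by
#'   [check_identifiability()].
#' @return An object of class `regulatory_topology` with the edge list and
#'   logical support matrix `support` (genes x TFs) plus numeric `signs`.
#' @export
regulatory_topology <- function(edges, tfs = NULL, genes = NULL) {
  if (!is.data.frame(edges) || !all(c("TF", "gene") %in% names(edges))) {
    stop("`edges` must be a data.frame with columns TF and gene", call. = FALSE)
  }
  key <- paste(edges$TF, edges$gene, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate TF-gene edges", call. = FALSE)
  sgn <- if ("sign" %in% names(edges)) {
    s <- edges$sign
    if (is.character(s)) s <- c("+" = 1, "-" = -1, "0" = 0)[s]
    s <- as.numeric(s)
    if (anyNA(s) || !all(s %in% c(-1, 0, 1))) {
      stop("edge signs must be -1/0/+1 (or '-'/'0'/'+')", call. = FALSE)
    }
    s
  } else rep(0, nrow(edges))
  tfs <- union(as.character(tfs), unique(as.character(edges$TF)))
  genes <- union(as.character(genes), unique(as.character(edges$gene)))
  S <- matrix(FALSE, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  Sg <- matrix(0, length(genes), length(tfs), dimnames = dimnames(S))
  S[cbind(match(edges$gene, genes), match(edges$TF, tfs))] <- TRUE
  Sg[cbind(match(edges$gene, genes), match(edges$TF, tfs))] <- sgn
  structure(list(edges = edges, tfs = tfs, genes = genes,
                 support = S, signs = Sg),
            class = "regulatory_topology")
}

#' @export
print.regulatory_topology <- function(x, ...) {
  cat(sprintf("<regulatory_topology> %d TFs, %d genes, %d edges\n",
              length(x$tfs), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Read a RegulonDB-style network TSV
#'
#' @param path TSV with columns `TF`, `gene` and optional `sign`.
#' @return A [regulatory_topology()].
#' @export
read_topology <- function(path) {
  regulatory_topology(utils::read.delim(path, stringsAsFactors = FALSE))
}

# evaluate with a generic (random) realisation on the support without
# disturbing the caller's RNG stream
with_local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Check NCA identifiability of a topology
#'
#' Verifies the standard identifiability criteria for the factorisation
#' E = A P over a fixed support: (1) the connectivity matrix has full
#' column rank for generic values on the support; (2) removing any TF
#' together with all genes it regulates leaves a sub-pattern of full column
#' rank (each TF's influence is distinguishable); (3) at least as many
#' conditions as TFs. Structural defects - TFs with no targets, TFs with
#' identical target sets - are reported by name.
#'
#' @param topology A [regulatory_topology()].
#' @param n_conditions Number of expression conditions available.
#' @return A list (class `nca_identifiability`): `pass` (logical),
#'   `offending_tfs`, and per-criterion logical fields `full_rank`,
#'   `reduced_rank`, `enough_conditions`, plus `messages`.
#' @export
check_identifiability <- function(topology, n_conditions) {
  stopifnot(inherits(topology, "regulatory_topology"))
  S <- topology$support
  L <- ncol(S)
  msgs <- character()
  offending <- character()

  no_targets <- colSums(S) == 0
  if (any(no_targets)) {
    offending <- c(offending, colnames(S)[no_targets])
    msgs <- c(msgs, paste0("TF(s) with no targets: ",
                           paste(colnames(S)[no_targets], collapse = ", ")))
  }
  sig <- apply(S, 2L, function(col) paste(which(col), collapse = ","))
  dup <- duplicated(sig) | duplicated(sig, fromLast = TRUE)
  dup <- dup & !no_targets
  if (any(dup)) {
    offending <- c(offending, colnames(S)[dup])
    msgs <- c(msgs, paste0("TF(s) with identical target sets: ",
                           paste(colnames(S)[dup], collapse = ", ")))
  }

  Ag <- with_local_rng(97, {
    A <- matrix(0, nrow(S), L)
    A[S] <- stats::runif(sum(S), 0.5, 1.5) * sample(c(-1, 1), sum(S), TRUE)
    A
  })
  full_rank <- qr(Ag)$rank == L

  reduced_rank <- TRUE
  if (L > 1L) {
    for (l in seq_len(L)) {
      rows <- !S[, l]
      sub <- Ag[rows, -l, drop = FALSE]
      if (qr(sub)$rank < L - 1L) {
        reduced_rank <- FALSE
        offending <- c(offending, colnames(S)[l])
        msgs <- c(msgs, paste0("reduced sub-pattern rank-deficient after removing TF ",
                               colnames(S)[l]))
      }
    }
  }
  enough_conditions <- n_conditions >= L
  if (!enough_conditions) {
    msgs <- c(msgs, sprintf("need >= %d conditions for %d TFs, got %d",
                            L, L, n_conditions))
  }
  pass <- full_rank && reduced_rank && enough_conditions &&
    !any(no_targets) && !any(dup)
  structure(list(pass = pass, offending_tfs = unique(offending),
                 full_rank = full_rank, reduced_rank = reduced_rank,
                 enough_conditions = enough_conditions, messages = msgs),
            class = "nca_identifiability")
}

#' @export
print.nca_identifiability <- function(x, ...) {
  cat(sprintf("<nca_identifiability> %s\n", if (x$pass) "PASS" else "FAIL"))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

# least-squares solve with ridge fallback for singular subproblems
ls_solve <- function(X, y, ridge = 1e-10) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("singular NCA subproblem; using ridge-regularised solve",
            call. = FALSE)
    XtX <- crossprod(X) + diag(ridge, ncol(X))
    return(solve(XtX, crossprod(X, y)))
  }
  qr.coef(qrx, y)
}

#' Gauge-fix an NCA factorisation
#'
#' The factorisation E = A P is invariant under A -> A D, P -> D^-1 P for
#' any invertible diagonal D. This fixes the gauge: each TF column of A is
#' scaled by its largest-magnitude entry so that entry becomes +1; when the
#' topology carries edge signs, the column's sign is instead anchored so
#' that the majority of its entries agree with the annotated signs. P rows
#' are rescaled inversely, so A P is unchanged.
#'
#' @param A Connectivity matrix (genes x TFs).
#' @param P Activity matrix (TFs x conditions).
#' @param topology Optional [regulatory_topology()] supplying edge signs.
#' @return `list(A, P)` in the canonical gauge.
#' @export
nca_gauge <- function(A, P, topology = NULL) {
  for (l in seq_len(ncol(A))) {
    a <- A[, l]
    amax <- max(abs(a))
    if (amax == 0) next
    d <- a[which.max(abs(a))] # signed: makes the largest entry +1
    if (!is.null(topology) && !is.null(rownames(A))) {
      sg <- topology$signs[rownames(A), l]
      signed <- sg != 0
      if (any(signed)) {
        agree <- sum(sign(a[signed] / d) == sg[signed])
        # anchor the column sign to the annotated majority (ties keep the
        # max-entry-positive convention)
        if (agree < sum(signed) / 2) d <- -d
      }
    }
    A[, l] <- a / d
    P[l, ] <- P[l, ] * d
  }
  list(A = A, P = P)
}

#' Network component analysis by alternating least squares
#'
#' Estimates the constrained factorisation E ~ A P, where E is the genes x
#' conditions expression (log-ratio) matrix, A is a connectivity matrix
#' supported only on the regulatory topology, and P holds the relative
#' transcription-factor activities. Starting from a seeded standard-normal
#' P, the solver alternates exact least-squares updates - each gene's row
#' of A restricted to its permitted TFs, then P given A - until the
#' relative Frobenius residual stops decreasing by more than `tol` or the
#' residual is numerically zero. Each update solves its subproblem exactly,
#' so the residual trace is non-increasing. The result is reported in the
#' canonical gauge of [nca_gauge()].
#'
#' Genes present in E but absent from the topology are excluded from the
#' factorisation (recorded in `excluded_genes`).
#'
#' @param E Numeric matrix, genes x conditions, rownames = gene ids
#'   covering all topology genes.
#' @param topology A [regulatory_topology()].
#' @param tol Relative residual-decrease tolerance (default 1e-8).
#' @param max_iter Maximum ALS sweeps (default 500).
#' @param seed Seed for the random initialisation of P.
#' @param ridge Ridge constant for singular subproblems.
#' @return An object of class `nca_fit`: `A` (genes x TFs, zero off
#'   support), `P` (TFs x conditions), `residuals` (relative Frobenius
#'   trace, one entry per sweep), `converged`, `iterations`,
#'   `excluded_genes`.
#' @export
nca_decompose <- function(E, topology, tol = 1e-8, max_iter = 500,
                          seed = NULL, ridge = 1e-10) {
  stopifnot(is.matrix(E), inherits(topology, "regulatory_topology"))
  if (is.null(rownames(E))) stop("`E` must have gene rownames", call. = FALSE)
  missing_genes <- setdiff(topology$genes, rownames(E))
  if (length(missing_genes)) {
    stop("E lacks topology genes: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  excluded <- setdiff(rownames(E), topology$genes)
  Ef <- E[topology$genes, , drop = FALSE]
  S <- topology$support
  L <- ncol(S)
  C <- ncol(Ef)

  if (!is.null(seed)) set.seed(seed)
  P <- matrix(stats::rnorm(L * C), L, C,
              dimnames = list(colnames(S), colnames(Ef)))
  A <- matrix(0, nrow(Ef), L, dimnames = list(rownames(Ef), colnames(S)))

  normE <- sqrt(sum(Ef^2))
  rel_res <- function(A, P) {
    r <- sqrt(sum((Ef - A %*% P)^2))
    if (normE > 0) r / normE else r
  }

  residuals <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # A-step: per gene, least squares on the permitted TFs
    for (i in seq_len(nrow(Ef))) {
      supp <- which(S[i, ])
      if (!length(supp)) next
      X <- t(P[supp, , drop = FALSE])
      A[i, ] <- 0
      A[i, supp] <- ls_solve(X, Ef[i, ], ridge)
    }
    # P-step: least squares over all genes
    P <- ls_solve(A, Ef, ridge)
    if (is.null(dim(P))) P <- matrix(P, L, C)
    dimnames(P) <- list(colnames(S), colnames(Ef))

    cur <- rel_res(A, P)
    residuals <- c(residuals, cur)
    if (cur < 1e-12 || (is.finite(prev) && (prev - cur) < tol * max(prev, 1e-300))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }

  g <- nca_gauge(A, P, topology)
  structure(list(A = g$A, P = g$P, residuals = residuals,
                 converged = converged, iterations = iter,
                 excluded_genes = excluded, topology = topology),
            class = "nca_fit")
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("<nca_fit> %d TFs x %d conditions; %d sweeps, final relative residual %.3g%s\n",
              nrow(x$P), ncol(x$P), x$iterations,
              if (length(x$residuals)) utils::tail(x$residuals, 1) else NA,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Differential transcription-factor activity
#'
#' Per-TF change in activity between conditions, Delta-TFA =
#' mean(treated) - mean(control) over replicate columns of P, with an
#' empirical p-value from a null-centred bootstrap over replicate columns:
#' replicates are resampled with replacement within each group, and p is
#' the add-one fraction of |Delta* - Delta-hat| at least |Delta-hat|.
#'
#' @param P Activity matrix, TFs x conditions (e.g. from [nca_decompose()]).
#' @param condition_labels Character vector, one per column of P, values
#'   `"control"` / `"treated"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A data.frame: `tf`, `delta`, `direction` (`"+"`/`"-"`), `p`,
#'   `significant` (p < 0.05). With fewer than 2 replicates per group, `p`
#'   is `NA` and only the magnitude is reported.
#' @export
delta_tfa <- function(P, condition_labels, n_boot = 1000, seed = NULL) {
  stopifnot(is.matrix(P), length(condition_labels) == ncol(P))
  cl <- as.character(condition_labels)
  if (!all(cl %in% c("control", "treated"))) {
    stop("condition labels must be 'control' or 'treated'", call. = FALSE)
  }
  ic <- which(cl == "control"); it <- which(cl == "treated")
  delta <- rowMeans(P[, it, drop = FALSE]) - rowMeans(P[, ic, drop = FALSE])
  p <- rep(NA_real_, nrow(P))
  if (length(ic) >= 2L && length(it) >= 2L) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- integer(nrow(P))
    for (b in seq_len(n_boot)) {
      bc <- sample(ic, length(ic), replace = TRUE)
      bt <- sample(it, length(it), replace = TRUE)
      db <- rowMeans(P[, bt, drop = FALSE]) - rowMeans(P[, bc, drop = FALSE])
      exceed <- exceed + (abs(db - delta) >= abs(delta))
    }
    p <- (exceed + 1) / (n_boot + 1)
  }
  data.frame(tf = rownames(P) %||% paste0("TF", seq_len(nrow(P))),
             delta = unname(delta),
             direction = ifelse(delta >= 0, "+", "-"),
             p = p,
             significant = !is.na(p) & p < 0.05,
             row.names = NULL, stringsAsFactors = FALSE)
}
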