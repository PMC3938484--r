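#' Two-condition expression study
#'
#' Container for a genes x samples matrix of log2 intensities with a sample
#' sheet assigning each column to `control` or `treated`.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param samples Data.frame with columns `sample_id` and `condition`
#'   (`"control"` / `"treated"`), one row per matrix column.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, samples) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("expression matrix must be complete and finite", call. = FALSE)
  }
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "condition") %in% names(samples))) {
    stop("`samples` must have columns sample_id and condition", call. = FALSE)
  }
  if (nrow(samples) != ncol(matrix)) {
    stop("sample sheet must have one row per matrix column", call. = FALSE)
  }
  if (!is.null(colnames(matrix)) &&
      !identical(as.character(samples$sample_id), colnames(matrix))) {
    samples <- samples[match(colnames(matrix), samples$sample_id), ]
    if (anyNA(samples$sample_id)) {
      stop("sample sheet ids do not match matrix column names", call. = FALSE)
    }
  }
  cond <- as.character(samples$condition)
  if (!all(cond %in% c("control", "treated"))) {
    stop("conditions must be 'control' or 'treated'", call. = FALSE)
  }
  if (any(table(factor(cond, c("control", "treated"))) < 2L)) {
    stop("each condition needs >= 2 samples", call. = FALSE)
  }
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- paste0("gene", seq_len(nrow(matrix)))
  }
  structure(list(matrix = matrix, samples = samples), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%d control, %d treated)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$samples$condition == "control"),
              sum(x$samples$condition == "treated")))
  invisible(x)
}

#' Median-centre each sample in log2 space
#'
#' Lightweight normalisation for synthetic or pre-summarised inputs: the
#' per-sample median is subtracted so samples share a common centre.
#'
#' @param study An [expression_study()].
#' @return The study with a median-centred matrix.
#' @export
median_center <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  med <- apply(study$matrix, 2L, stats::median)
  study$matrix <- sweep(study$matrix, 2L, med, "-")
  study
}

# Equal-variance two-sample t statistics, one per row of M.
# idx_t: treated column indices. Degenerate rows (zero pooled within-group
# variance) get t = 0.
row_tstats <- function(M, idx_t) {
  n <- ncol(M)
  n1 <- length(idx_t)
  n2 <- n - n1
  Mt <- M[, idx_t, drop = FALSE]
  Mc <- M[, -idx_t, drop = FALSE]
  m1 <- rowMeans(Mt)
  m2 <- rowMeans(Mc)
  ss1 <- rowSums((Mt - m1)^2)
  ss2 <- rowSums((Mc - m2)^2)
  sp <- sqrt((ss1 + ss2) / (n1 + n2 - 2))
  denom <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / denom
  t[denom == 0] <- 0
  t
}

#' Gene-wise permutation t-tests
#'
#' Two-sample equal-variance t statistics per gene with a permutation null
#' built by relabelling samples. When the number of distinct label
#' assignments `choose(n, n_treated)` does not exceed `n_perm`, the null is
#' enumerated exhaustively; otherwise `n_perm` random relabellings are
#' drawn (seeded).
#'
#' The null can be *pooled* across genes (default) - all permuted |t|
#' values from all genes form one reference distribution, the reading of
#' "pooled data" that makes small-replicate q-values attainable - or kept
#' *per gene*. Exhaustive p-values are b / B with the identity labelling
#' included in the null; sampled p-values use the add-one estimator
#' (b + 1) / (B + 1) so p is never zero.
#'
#' Genes with zero within-group variance in both groups are degenerate:
#' they get p = 1 and `degenerate = TRUE`.
#'
#' @param study An [expression_study()].
#' @param n_perm Maximum number of permutations (default 10000).
#' @param seed Integer seed for random relabellings (ignored in exhaustive
#'   mode).
#' @param null `"pooled"` or `"per_gene"`.
#' @return A data.frame with columns `gene`, `t`, `p`, `degenerate`;
#'   attributes `exhaustive` (logical) and `B` (permutations used).
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 11, 12, 13))
#' colnames(m) <- paste0("s", 1:6)
#' st <- expression_study(m, data.frame(sample_id = paste0("s", 1:6),
#'   condition = rep(c("control", "treated"), each = 3)))
#' permutation_t_test(st)$p # 2/20 = 0.1
#' @export
permutation_t_test <- function(study, n_perm = 10000, seed = NULL,
                               null = c("pooled", "per_gene")) {
  stopifnot(inherits(study, "expression_study"))
  null <- match.arg(null)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  M <- study$matrix
  cond <- as.character(study$samples$condition)
  n <- ncol(M)
  idx_t_obs <- which(cond == "treated")
  n1 <- length(idx_t_obs)

  t_obs <- row_tstats(M, idx_t_obs)
  degenerate <- {
    # zero pooled within-group variance under the observed labelling
    Mt <- M[, idx_t_obs, drop = FALSE]
    Mc <- M[, -idx_t_obs, drop = FALSE]
    rowSums((Mt - rowMeans(Mt))^2) + rowSums((Mc - rowMeans(Mc))^2) == 0
  }

  n_splits <- choose(n, n1)
  exhaustive <- n_splits <= n_perm
  if (exhaustive) {
    splits <- utils::combn(n, n1, simplify = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    splits <- replicate(n_perm, sample.int(n, n1), simplify = FALSE)
  }
  B <- length(splits)
  Tnull <- vapply(splits, function(idx) abs(row_tstats(M, idx)),
                  numeric(nrow(M)))
  if (nrow(M) == 1L) Tnull <- matrix(Tnull, nrow = 1L)

  a_obs <- abs(t_obs)
  eps <- 1e-8 * (1 + a_obs)
  if (null == "per_gene") {
    b <- rowSums(Tnull >= a_obs - eps)
    p <- if (exhaustive) b / B else (b + 1) / (B + 1)
  } else {
    pool <- sort(as.numeric(Tnull))
    N <- length(pool)
    # count pooled null values >= |t_obs| per gene
    b <- N - findInterval(a_obs - eps, pool)
    p <- if (exhaustive) b / N else (b + 1) / (N + 1)
  }
  p[degenerate] <- 1
  p <- pmin(p, 1)
  out <- data.frame(gene = rownames(M), t = t_obs, p = p,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "exhaustive") <- exhaustive
  attr(out, "B") <- B
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted values with enforced monotonicity, standing in for
#' the unnamed q-value procedure of the original analysis.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\], in the input order.
#' @export
fdr_qvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must be numeric within [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Signed linear expression ratio from a log2 fold change
#'
#' Converts log2(treated/control) to the signed ratio convention used for
#' reporting: +2^FC for increased abundance, -2^|FC| for decreased.
#'
#' @param lfc Log2 fold changes.
#' @return Signed ratios; `|ratio| >= 1` always, sign matches `lfc`.
#' @export
signed_ratio <- function(lfc) {
  ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))
}

#' @rdname signed_ratio
#' @param ratio Signed linear ratios (|ratio| >= 1).
#' @export
ratio_to_lfc <- function(ratio) {
  if (any(abs(ratio) < 1)) stop("signed ratios must satisfy |ratio| >= 1",
                                call. = FALSE)
  sign(ratio) * log2(abs(ratio))
}

#' Differential expression on a two-condition study
#'
#' Median-centres the matrix, runs [permutation_t_test()], attaches BH
#' q-values, log2 fold changes (treated minus control means) and signed
#' linear ratios, and flags significance at `q < q_cut` and
#' `|log2 FC| >= fc_cut`.
#'
#' @inheritParams permutation_t_test
#' @param q_cut q-value threshold (strict), default 0.05.
#' @param fc_cut absolute log2 fold-change threshold (inclusive), default 1.
#' @param center Median-centre samples first (default TRUE).
#' @return A data.frame: `gene`, `lfc`, `ratio`, `t`, `p`, `q`,
#'   `degenerate`, `significant`.
#' @export
differential_expression <- function(study, n_perm = 10000, seed = NULL,
                                    null = c("pooled", "per_gene"),
                                    q_cut = 0.05, fc_cut = 1.0,
                                    center = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (center) study <- median_center(study)
  res <- permutation_t_test(study, n_perm = n_perm, seed = seed,
                            null = match.arg(null))
  cond <- as.character(study$samples$condition)
  lfc <- rowMeans(study$matrix[, cond == "treated", drop = FALSE]) -
    rowMeans(study$matrix[, cond == "control", drop = FALSE])
  res$lfc <- unname(lfc)
  res$ratio <- signed_ratio(res$lfc)
  res$q <- fdr_qvalues(res$p)
  res$significant <- res$q < q_cut & abs(res$lfc) >= fc_cut
  res[, c("gene", "lfc", "ratio", "t", "p", "q", "degenerate", "significant")]
}

#' Filter differential-expression results to significant calls
#'
#' Retains genes with `q < q_cut` (strict) and `|log2 FC| >= fc_cut`
#' (inclusive, so a gene at exactly 2-fold is kept), sorted by the
#' magnitude of the signed ratio.
#'
#' @param results A [differential_expression()] table (needs columns `q`
#'   and `lfc`).
#' @param q_cut,fc_cut Thresholds as in [differential_expression()].
#' @return The filtered, sorted subset of `results`.
#' @export
call_significant <- function(results, q_cut = 0.05, fc_cut = 1.0) {
  stopifnot(is.data.frame(results), all(c("q", "lfc") %in% names(results)))
  keep <- results$q < q_cut & abs(results$lfc) >= fc_cut
  out <- results[keep, , drop = FALSE]
  out[order(-abs(out$lfc)), , drop = FALSE]
}

#' Load the packaged C8 differential-expression table
#'
#' The curated table of genes significantly perturbed by octanoic acid
#' challenge (q < 0.05, >= 2-fold), shipped as a plain-text fixture. Signed
#' ratios are positive for increased and negative for decreased abundance;
#' the table is sorted by ratio magnitude.
#'
#' @param path Path to a table in the same TSV dialect; defaults to the
#'   packaged fixture.
#' @return A data.frame with columns `probe`, `gene`, `p_value`, `q_value`,
#'   `ratio`, `annotation`.
#' @export
load_de_table <- function(path = system.file("extdata", "c8_de_table.tsv",
                                             package = "acidstress")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("differential-expression table not found", call. = FALSE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Extreme signed expression ratios of a DE table
#'
#' @param de_table A data.frame with columns `gene` and `ratio` (e.g. from
#'   [load_de_table()] or [differential_expression()]).
#' @return A list with elements `max` and `min`, each `list(gene, ratio)`:
#'   the largest positive and most negative signed ratios.
#' @examples
#' \donttest{
#' table_extremes(load_de_table())
#' }
#' @export
table_extremes <- function(de_table) {
  stopifnot(is.data.frame(de_table))
  if (!all(c("gene", "ratio") %in% names(de_table))) {
    stop("`de_table` must have columns gene and ratio", call. = FALSE)
  }
  if (nrow(de_table) == 0L) stop("empty table", call. = FALSE)
  i_max <- which.max(de_table$ratio)
  i_min <- which.min(de_table$ratio)
  list(max = list(gene = de_table$gene[i_max], ratio = de_table$ratio[i_max]),
       min = list(gene = de_table$gene[i_min], ratio = de_table$ratio[i_min]))
}

#' Read an expression matrix and sample sheet from TSV files
#'
#' @param matrix_path TSV whose first column is `gene_id`, remaining
#'   columns one per sample.
#' @param samples_path TSV with columns `sample_id` and `condition`.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, samples_path) {
  tab <- utils::read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  expression_study(m, samples)
}
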