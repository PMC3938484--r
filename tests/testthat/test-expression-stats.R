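make_study <- function(rows, n_ctrl = 3, n_trt = 3) {
  m <- do.call(rbind, rows)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_study(m, data.frame(
    sample_id = colnames(m),
    condition = rep(c("control", "treated"), c(n_ctrl, n_trt))))
}

test_that("well-separated 3v3 gene has exhaustive p = 2/20", {
  st <- make_study(list(c(1, 2, 3, 11, 12, 13)))
  res <- permutation_t_test(st)
  expect_true(attr(res, "exhaustive"))
  expect_identical(attr(res, "B"), 20L)
  expect_equal(res$p, 0.1)
})

test_that("identical groups give p = 1 and degenerate genes are flagged", {
  st <- make_study(list(c(1, 2, 3, 1, 2, 3)))
  expect_equal(permutation_t_test(st)$p, 1)
  flat <- make_study(list(c(5, 5, 5, 5, 5, 5)))
  res <- permutation_t_test(flat)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
})

test_that("relabelling which group is control leaves p unchanged", {
  vals <- c(0.3, 1.1, 0.7, 2.4, 3.0, 2.2)
  st1 <- make_study(list(vals))
  m2 <- rbind(g1 = c(vals[4:6], vals[1:3]))
  colnames(m2) <- paste0("s", 1:6)
  st2 <- expression_study(m2, data.frame(
    sample_id = colnames(m2),
    condition = rep(c("control", "treated"), each = 3)))
  expect_equal(permutation_t_test(st1)$p, permutation_t_test(st2)$p)
})

test_that("per-gene exhaustive p equals independent brute-force enumeration", {
  set.seed(31)
  for (n in c(3, 4)) {
    rows <- replicate(8, rnorm(2 * n, mean = rep(c(0, runif(1, 0, 2)), each = n)),
                      simplify = FALSE)
    st <- make_study(rows, n_ctrl = n, n_trt = n)
    res <- permutation_t_test(st, null = "per_gene")
    expect_true(attr(res, "exhaustive"))
    oracle <- vapply(rows, function(v) {
      brute_force_perm_p(v[seq_len(n)], v[n + seq_len(n)])
    }, numeric(1))
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }
})

test_that("sampled-permutation p approximates the exhaustive value", {
  set.seed(55)
  st <- make_study(replicate(5, rnorm(12, rep(c(0, 1), each = 6)),
                             simplify = FALSE),
                   n_ctrl = 6, n_trt = 6) # 924 splits > n_perm
  res_s <- permutation_t_test(st, n_perm = 500, seed = 9, null = "per_gene")
  expect_false(attr(res_s, "exhaustive"))
  expect_true(all(res_s$p >= 1 / 501)) # add-one estimator floor
  res_e <- permutation_t_test(st, n_perm = 1000, null = "per_gene")
  expect_true(attr(res_e, "exhaustive"))
  expect_lt(max(abs(res_s$p - res_e$p)), 0.1)
})

test_that("null simulations keep per-gene type-I error at the discrete achievable level", {
  set.seed(77)
  st <- make_study(replicate(1000, rnorm(6), simplify = FALSE))
  res <- permutation_t_test(st, null = "per_gene")
  frac <- mean(res$p <= 0.1)
  # achievable level is exactly 0.1 for the 20-split null; 3 binomial sds
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("BH q-values match the hand-worked example and are order-invariant", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_qvalues(rep(1, 5)), rep(1, 5))
  set.seed(12)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(fdr_qvalues(p)[perm], fdr_qvalues(p[perm]))
  # step-up dominance: monotone in sorted p, never below p, capped at 1
  q <- fdr_qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  expect_error(fdr_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signed ratio and log2 fold change are mutually recoverable", {
  lfc <- c(-4.7, -1, -0.2, 0, 0.5, 1, 3.3)
  expect_equal(ratio_to_lfc(signed_ratio(lfc)), lfc, tolerance = 1e-12)
  expect_equal(signed_ratio(1), 2)
  expect_equal(signed_ratio(-1), -2)
})

test_that("significance filter applies strict q and inclusive fold-change cuts", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    q = c(0.04, 0.04, 0.05, 0.01),
                    lfc = c(0.5, 1.0, 2.0, -1.5))
  out <- call_significant(res)
  expect_false("a" %in% out$gene) # fails fc_cut
  expect_true("b" %in% out$gene)  # |lfc| = 1 exactly is included
  expect_false("c" %in% out$gene) # q = 0.05 is not < 0.05
  expect_true("d" %in% out$gene)
})

test_that("spiked 4-fold genes are recovered from a null background", {
  st <- gen_de_study(n_genes = 510, n_de = 10, lfc = 2, sd = 0.25,
                     n_rep = 4, seed = 41)
  truth <- attr(st, "truth")$de_genes
  de <- differential_expression(st, seed = 41)
  sig <- call_significant(de)
  expect_equal(sort(intersect(sig$gene, truth)), sort(truth)) # all 10 found
  expect_lte(sum(!sig$gene %in% truth), 1)                    # <= 1 false call
})

test_that("packaged DE table has the expected extremes and structure", {
  tab <- load_de_table()
  expect_true(all(c("probe", "gene", "ratio", "annotation") %in% names(tab)))
  expect_gt(nrow(tab), 70)
  ex <- table_extremes(tab)
  expect_equal(ex$max$gene, "gadB")
  expect_equal(ex$max$ratio, 25.3)
  expect_equal(ex$min$gene, "nmpC")
  expect_equal(ex$min$ratio, -16.3)
  one <- tab[1, ]
  ex1 <- table_extremes(one)
  expect_equal(ex1$max$gene, ex1$min$gene)
  expect_error(table_extremes(tab[0, ]), "empty")
})

test_that("expression matrices round-trip through the TSV reader", {
  st <- gen_de_study(n_genes = 20, n_de = 2, seed = 3)
  mdir <- withr::local_tempdir()
  mtab <- data.frame(gene_id = rownames(st$matrix), st$matrix,
                     check.names = FALSE)
  write.table(mtab, file.path(mdir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(st$samples, file.path(mdir, "s.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  st2 <- read_expression_study(file.path(mdir, "m.tsv"),
                               file.path(mdir, "s.tsv"))
  expect_equal(st2$matrix, st$matrix, tolerance = 1e-12)
  expect_equal(st2$samples$condition, st$samples$condition)
})
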