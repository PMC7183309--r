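# log2-CPM, the Welch DE substitute, gene sets, matrices, clustering,
# trajectories and ddCt.

test_that("log2_cpm follows its stated formula", {
  m <- matrix(c(0, 999999), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lcpm <- log2_cpm(m)
  expect_equal(lcpm["g1", "s1"], -1.0)
  m2 <- matrix(c(1023, 999999 - 1023), 2, 1,
               dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(log2_cpm(m2)["g1", "s1"], log2(1023.5), tolerance = 1e-9)
  # scale invariance for counts >> prior
  big <- matrix(rpois(200, 500) + 50, 50, 4)
  expect_true(all(abs(log2_cpm(2 * big) - log2_cpm(big)) < 1e-3))
  expect_error(log2_cpm(matrix(-1)), "non-negative")
})

test_that("simple_de is calibrated under the null and detects planted FC", {
  st <- generate_expression_study(400, c("kd", "ctrl"), 3,
                                  expression_truth(dispersion = 0.05),
                                  seed = 3)
  a <- st$samples$sample[st$samples$group == "kd"]
  b <- st$samples$sample[st$samples$group == "ctrl"]
  expect_error(simple_de(st$counts, a, c(a[1], b[-1])), "overlap")
  de <- simple_de(st$counts, a, b)
  # BH adjustment equals the step-up oracle exactly
  expect_equal(de$padj, bh_stepup(de$p))
  expect_true(all(de$padj >= de$p - 1e-15))
  expect_true(all(diff(de$padj[order(de$p)]) >= -1e-15))
  # planted log2FC = 2 on 40 genes is detected
  lfc <- stats::setNames(rep(2, 40), sprintf("G%04d", 1:40))
  st2 <- generate_expression_study(
    400, c("kd", "ctrl"), 3,
    expression_truth(de_genes = list(kd = lfc), dispersion = 0.05,
                     baseline_mu = 100), seed = 4)
  de2 <- simple_de(st2$counts, a, b)
  power <- mean(de2$p[match(names(lfc), de2$gene)] < 0.05)
  expect_gte(power, 0.8)
  expect_equal(mean(de2$log2fc[match(names(lfc), de2$gene)]), 2,
               tolerance = 0.2)
})

test_that("all-zero genes are excluded and reported", {
  cts <- matrix(rpois(40, 50), 10, 4,
                dimnames = list(sprintf("g%02d", 1:10),
                                c("a1", "a2", "b1", "b2")))
  cts[3, ] <- 0
  expect_message(de <- simple_de(cts, c("a1", "a2"), c("b1", "b2")),
                 "all-zero")
  expect_false("g03" %in% de$gene)
  expect_identical(attr(de, "excluded_genes"), "g03")
})

test_that("DE gene sets apply a strict padj cutoff", {
  tab <- data.frame(gene = c("u", "d", "n", "edge"),
                    log2fc = c(1, -1, -1, 2),
                    p = c(0.001, 0.002, 0.1, 0.02),
                    padj = c(0.01, 0.02, 0.2, 0.05))
  sets <- de_gene_sets(tab, alpha = 0.05)
  expect_identical(sets$up, "u")
  expect_identical(sets$down, "d")
  expect_setequal(sets$universe, tab$gene)
  expect_false("edge" %in% c(sets$up, sets$down))  # exactly 0.05: excluded
  expect_length(intersect(sets$up, sets$down), 0)
  expect_error(de_gene_sets(tab, alpha = 1), "alpha")
})

test_that("de_summary mirrors the headline arithmetic", {
  tab <- data.frame(gene = sprintf("g%03d", 1:110),
                    log2fc = c(rep(0.5, 94), rep(-0.5, 6), rep(0.1, 10)),
                    p = c(rep(0.001, 100), rep(0.9, 10)),
                    padj = c(rep(0.01, 100), rep(0.95, 10)))
  s <- de_summary(tab, 0.05)
  expect_equal(s$n_deregulated, 100)
  expect_equal(s$fraction_up, 0.94)
  expect_equal(s$mean_abs_log2fc_of_significant, 0.5)
  s2 <- de_summary(data.frame(gene = "g", log2fc = 0.5, p = 0.9,
                              padj = 0.9), 0.05)
  expect_equal(s2$n_deregulated, 0)
  expect_true(is.na(s2$fraction_up))
  expect_true(is.na(s2$mean_abs_log2fc_of_significant))
  s3 <- de_summary(data.frame(gene = c("a", "b", "c"),
                              log2fc = c(0.5, -0.5, 0.2),
                              p = c(0.001, 0.001, 0.001),
                              padj = c(0.01, 0.01, 0.01)), 0.05)
  expect_equal(s3$mean_abs_log2fc_of_significant, 0.4)
})

test_that("log2fc_matrix applies the configured missing-gene policy", {
  t1 <- data.frame(gene = c("a", "b"), log2fc = c(0.3, 1), p = 0.01,
                   padj = 0.02)
  t2 <- data.frame(gene = "a", log2fc = -0.2, p = 0.01, padj = 0.02)
  expect_warning(
    m <- log2fc_matrix(list(c1 = t1, c2 = t2), c("a", "b")),
    "filled with 0")
  expect_equal(m["a", ], c(c1 = 0.3, c2 = -0.2))
  expect_equal(unname(m["b", "c2"]), 0)
  expect_warning(
    m2 <- log2fc_matrix(list(c1 = t1, c2 = t2), c("a", "b"),
                        missing = "drop-gene"), "dropped")
  expect_identical(rownames(m2), "a")
})

test_that("row_zscore normalizes rows and excludes constant ones", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 0, 5))
  expect_warning(z <- row_zscore(m), "constant row")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_false("b" %in% rownames(z))
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
})

test_that("transcriptome correlation matches the brute-force oracle", {
  m <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(NULL, sprintf("K%02d", 1:10)))
  r <- transcriptome_correlation(m)
  for (i in c(1, 5)) for (j in c(2, 10))
    expect_equal(r[i, j], pearson_brute(m[, i], m[, j]), tolerance = 1e-12)
  two <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(transcriptome_correlation(two)["a", "b"], 1)
  expect_equal(transcriptome_correlation(cbind(a = c(1, 2, 3),
                                               b = -c(1, 2, 3)))["a", "b"],
               -1)
  expect_error(transcriptome_correlation(cbind(a = c(1, 2, 3),
                                               b = c(1, 1, 1))),
               "zero-variance.*b")
})

test_that("hierarchical clustering recovers separated blobs", {
  recovered <- vapply(1:20, function(s) {
    set.seed(s)
    m <- rbind(matrix(rnorm(10 * 4), 10, 4),
               matrix(rnorm(10 * 4, mean = 10), 10, 4))
    rownames(m) <- sprintf("g%02d", 1:20)
    cl <- hierarchical_clusters(m, k = 2)
    length(unique(cl[1:10])) == 1 && length(unique(cl[11:20])) == 1 &&
      cl[1] != cl[11]
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  expect_setequal(unname(hierarchical_clusters(m, k = 4)), 1:4)
  expect_error(hierarchical_clusters(m, k = 5), "exceeds")
  # permutation invariance up to relabeling
  set.seed(1)
  mm <- rbind(matrix(rnorm(8 * 3), 8, 3),
              matrix(rnorm(8 * 3, mean = 6), 8, 3))
  rownames(mm) <- sprintf("g%02d", 1:16)
  cl1 <- hierarchical_clusters(mm, k = 2)
  perm <- sample(nrow(mm))
  cl2 <- hierarchical_clusters(mm[perm, ], k = 2)
  expect_equal(unname(cl2[rownames(mm)] == cl2[rownames(mm)[1]]),
               unname(cl1 == cl1[1]))
})

test_that("cluster labels are ordered by decreasing size", {
  m <- rbind(matrix(rnorm(3 * 2, 0, 0.1), 3, 2),
             matrix(rnorm(7 * 2, 20, 0.1), 7, 2))
  rownames(m) <- sprintf("g%02d", 1:10)
  cl <- hierarchical_clusters(m, k = 2)
  expect_equal(unname(table(cl)[["1"]]), 7)
  expect_equal(unname(table(cl)[["2"]]), 3)
})

test_that("trajectory summaries max-normalize and bound their CIs", {
  one <- matrix(c(4, 2, 1), 1, 3,
                dimnames = list("g1", c("t0", "t1", "t2")))
  ts <- trajectory_summary(one, n_boot = 100, seed = 1)
  expect_equal(ts$median, c(1.0, 0.5, 0.25))
  expect_equal(ts$ci_low, ts$median)
  expect_equal(ts$ci_high, ts$median)
  same <- matrix(rep(c(8, 4, 2), each = 5), 5, 3,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  ts2 <- trajectory_summary(same, n_boot = 100, seed = 1)
  expect_equal(ts2$ci_high - ts2$ci_low, rep(0, 3))
  expect_true(all(ts2$median > 0 & ts2$median <= 1))
  expect_true(all(ts2$ci_low <= ts2$median & ts2$median <= ts2$ci_high))
  expect_error(trajectory_summary(matrix(c(-1, 2, 3), 1, 3)),
               "must be > 0")
  # every gene attains 1 at its argmax
  set.seed(2)
  m <- matrix(rlnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10),
                                                 NULL))
  norm <- m / apply(m, 1, max)
  expect_equal(unname(apply(norm, 1, max)), rep(1, 10))
})

test_that("ddct implements 2^-ddCt", {
  expect_equal(ddct(20, 15, 22, 15), 4.0)
  expect_equal(ddct(18, 14, 18, 14), 1.0)
  expect_equal(ddct(22, 15, 20, 15), 0.25)
})
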