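# Plate Z-scoring, replicate aggregation, hit ranking and phenotype
# correlation.

screen_row <- function(kd, plate, rep, feature, value) {
  data.frame(knockdown = kd, plate = plate, replicate = rep,
             feature = feature, value = value)
}

test_that("per-plate Z-scores have mean 0, sample SD 1 and known values", {
  tab <- screen_row(c("A", "B", "C"), "P1", 1, "f", c(1, 2, 3))
  z <- zscore_by_plate(tab)
  expect_equal(z$value, c(-1, 0, 1))
  scr <- generate_screen(12, 5, 4, 2,
                         screen_truth(plate_shift = 2), seed = 3)
  z <- zscore_by_plate(scr$table)
  for (gl in split(z$value, paste(z$plate, z$feature))) {
    expect_lt(abs(mean(gl)), 1e-9)
    expect_lt(abs(sd(gl) - 1), 1e-9)
  }
})

test_that("Z-scoring is idempotent and removes plate offsets", {
  scr <- generate_screen(10, 6, 4, 2, screen_truth(plate_shift = 5),
                         seed = 5)
  z1 <- zscore_by_plate(scr$table)
  z2 <- zscore_by_plate(z1)
  expect_equal(z1$value, z2$value, tolerance = 1e-9)
  # identical data on two plates with +/-10 offsets normalizes identically
  base <- expand.grid(knockdown = sprintf("K%02d", 1:6),
                      feature = c("f1", "f2"), stringsAsFactors = FALSE)
  base$value <- rnorm(nrow(base))
  p1 <- cbind(base, plate = "P1", replicate = 1)
  p2 <- cbind(base, plate = "P2", replicate = 2)
  p1$value <- p1$value + 10
  p2$value <- p2$value - 10
  z <- zscore_by_plate(rbind(p1, p2))
  z1 <- z[z$plate == "P1", ]
  z2 <- z[z$plate == "P2", ]
  expect_equal(z1$value[order(z1$knockdown, z1$feature)],
               z2$value[order(z2$knockdown, z2$feature)],
               tolerance = 1e-9)
})

test_that("degenerate plate groups are flagged, not NaN'd", {
  tab <- screen_row(c("A", "B"), "P1", 1:2, "f", c(2, 2))
  expect_error(zscore_by_plate(tab), "zero-variance.*P1 / f")
  dup <- screen_row(c("A", "A"), "P1", 1, "f", c(1, 2))
  expect_error(zscore_by_plate(dup), "duplicate")
})

test_that("replicate aggregation averages, reports and excludes", {
  tab <- rbind(screen_row("A", "P1", 1, "f", -1),
               screen_row("A", "P2", 2, "f", 1),
               screen_row("B", "P1", 1, "f", 0.5),
               screen_row("B", "P2", 2, "f", 0.5),
               screen_row("B", "P1", 3, "f", 0.5),
               screen_row("B", "P2", 4, "f", 0.5))
  prof <- aggregate_replicates(tab)
  expect_equal(unname(prof$z["A", "f"]), 0)
  expect_equal(unname(prof$z["B", "f"]), 0.5)
  expect_equal(unname(prof$n_replicates_used["B"]), 4L)
  # 3 of 4 replicates present: retained with n = 3
  tab3 <- tab[-1, ]
  tab3$knockdown[1] <- "A"
  prof3 <- aggregate_replicates(rbind(screen_row("A", "P1", 1, "f", 0),
                                      screen_row("A", "P2", 2, "f", 1),
                                      screen_row("A", "P1", 3, "f", 2),
                                      tab[3:6, ]))
  expect_equal(unname(prof3$n_replicates_used["A"]), 3L)
  # below min_replicates: excluded and reported
  expect_message(
    prof1 <- aggregate_replicates(rbind(screen_row("C", "P1", 1, "f", 1),
                                        tab[3:6, ])),
    "excluding")
  expect_false("C" %in% rownames(prof1$z))
  expect_true("C" %in% prof1$excluded)
  expect_error(aggregate_replicates(tab[0, ]), "empty")
})

test_that("hit ranking is ascending with lexicographic ties", {
  z <- matrix(c(-2, 0, 1, 0), 4, 1,
              dimnames = list(c("B", "A", "C", "Aa"), "colonies"))
  ranked <- rank_hits(z, "colonies")
  expect_equal(ranked$knockdown, c("B", "A", "Aa", "C"))
  expect_equal(ranked$score, c(-2, 0, 0, 1))
  expect_error(rank_hits(z, "nope"), "unknown feature")
})

test_that("strong-negative module members rank in the bottom decile", {
  # -2 SD colony effect for 3 planted members, 4 replicates, 2 offset
  # plates; members should land in the bottom decile of 30 knockdowns
  members <- c("KD001", "KD002", "KD003")
  kds <- sprintf("KD%03d", 1:30)
  in_decile <- vapply(1:50, function(s) {
    set.seed(s)
    tab <- do.call(rbind, lapply(1:4, function(r) {
      plate <- c("P1", "P2")[(r - 1) %% 2 + 1]
      offset <- c(P1 = 3, P2 = -3)[plate]
      data.frame(knockdown = kds, plate = plate, replicate = r,
                 feature = "colonies",
                 value = ifelse(kds %in% members, -2, 0) +
                   rnorm(30) + offset)
    }))
    prof <- aggregate_replicates(zscore_by_plate(tab), min_replicates = 2)
    ranked <- rank_hits(prof, "colonies")
    mean(match(members, ranked$knockdown) <= 3)
  }, numeric(1))
  expect_gte(mean(in_decile), 0.9)
})

test_that("phenotype correlation matches a brute-force Pearson oracle", {
  z <- matrix(rnorm(20 * 27), 20, 27,
              dimnames = list(sprintf("K%02d", 1:20),
                              sprintf("F%02d", 1:27)))
  r <- phenotype_correlation(z)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 20))
  for (i in c(1, 7, 20)) {
    for (j in c(2, 13)) {
      expect_equal(r[i, j], pearson_brute(z[i, ], z[j, ]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(
    phenotype_correlation(rbind(x = c(1, 2, 3), y = c(2, 4, 6)))["x", "y"],
    1)
  expect_equal(
    phenotype_correlation(rbind(x = c(1, 2, 3), y = c(3, 2, 1)))["x", "y"],
    -1)
  expect_error(
    phenotype_correlation(rbind(x = c(1, 2, 3), y = c(1, 1, 1))),
    "zero-variance.*y")
  expect_error(phenotype_correlation(z[, 1:2]), ">= 3 features")
})

test_that("profile correlations are invariant to per-feature affine maps", {
  scr <- generate_screen(8, 6, 4, 2, screen_truth(), seed = 9)
  r0 <- phenotype_correlation(
    aggregate_replicates(zscore_by_plate(scr$table)))
  tab <- scr$table
  key <- paste(tab$plate, tab$feature)
  scale <- stats::setNames(runif(length(unique(key)), 0.5, 4),
                           unique(key))
  shift <- stats::setNames(rnorm(length(unique(key)), 0, 10), unique(key))
  tab$value <- tab$value * scale[key] + shift[key]
  r1 <- phenotype_correlation(aggregate_replicates(zscore_by_plate(tab)))
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("linear_fit recovers exact and null relationships", {
  f <- linear_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  f0 <- linear_fit(c(0, 1, 2), c(1, 1, 1))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(f0$intercept, 1)
  expect_equal(f0$r_squared, 0, tolerance = 1e-12)
  set.seed(42)
  fr <- linear_fit(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(fr$slope), 0.05)
  expect_lt(fr$r_squared, 0.01)
  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
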