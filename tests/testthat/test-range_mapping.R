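test_that("collinearity_filter applies the greedy |rho| rule in priority order", {
  cm <- function(names, ...) {
    m <- diag(length(names)); dimnames(m) <- list(names, names)
    for (p in list(...)) { m[p[[1]], p[[2]]] <- p[[3]]; m[p[[2]], p[[1]]] <- p[[3]] }
    m
  }
  # one highly correlated pair: the lower-priority member is dropped
  expect_identical(collinearity_filter(cm(c("A", "B"), list("A", "B", 0.8))),
                   "A")
  # no conflicts: everything kept
  m3 <- cm(c("A", "B", "C"), list("A", "B", 0.3), list("A", "C", 0.5),
           list("B", "C", 0.6))
  expect_identical(collinearity_filter(m3), c("A", "B", "C"))
  # hand-traced chain under a reordered priority
  m4 <- cm(c("A", "B", "C"), list("A", "B", 0.75), list("B", "C", 0.72),
           list("A", "C", 0.3))
  expect_identical(collinearity_filter(m4, priority = c("A", "C", "B")),
                   c("A", "C"))
  # negative correlations count by absolute value
  expect_identical(collinearity_filter(cm(c("A", "B"), list("A", "B", -0.9))),
                   "A")
  bad <- cm(c("A", "B"), list("A", "B", 0.2)); bad[1, 2] <- 0.5
  expect_error(collinearity_filter(bad), "symmetric")
})

test_that("threshold_10pct uses the linear-interpolation percentile and keeps >= 90% of presences", {
  g <- make_grid(2, 5)
  vals <- matrix(seq(0.1, 1.0, by = 0.1), 2, 5)  # cells hold 0.1 .. 1.0
  lay <- species_layer("s", g, vals)
  occ <- occurrence_set("s", rows = rep(1:2, 5), cols = rep(1:5, each = 2),
                        grid = g)
  res <- threshold_10pct(lay, occ, percentile = 10)
  # frozen oracle value: type-4 10th percentile of {0.1,...,1.0} is h = np = 1
  # -> the first order statistic, 0.1; no presence falls strictly below
  expect_equal(res$threshold, 0.1)
  expect_identical(unname(res$binary$values), unname(vals >= 0.1))
  expect_equal(sum(vals[cbind(occ$row, occ$col)] < res$threshold), 0)
  # an 11-point sample (max repeated) exercises true interpolation:
  # h = n*p = 1.1 -> x_(1) + 0.1 * (x_(2) - x_(1)) = 0.11
  occ1 <- occurrence_set("s", rows = c(rep(1:2, 5), 2),
                         cols = c(rep(1:5, each = 2), 5), grid = g)
  expect_equal(threshold_10pct(lay, occ1, 10)$threshold, 0.11)

  # constant training sample: threshold = the constant, all presences kept
  layc <- species_layer("c", g, matrix(0.5, 2, 5))
  resc <- threshold_10pct(layc, occ)
  expect_equal(resc$threshold, 0.5)
  expect_true(all(resc$binary$values))

  # percentile 0: minimum-training-presence threshold keeps every presence
  res0 <- threshold_10pct(lay, occ, percentile = 0)
  expect_equal(res0$threshold, min(vals))
  expect_true(all(res0$binary$values[cbind(occ$row, occ$col)]))

  expect_error(threshold_10pct(lay, occ[0, ]), "empty")
})

test_that("lowering the percentile never shrinks the binary range", {
  for (s in 1:5) {
    g <- make_grid(10, 10)
    spec <- gen_species_pool(g, 1, seed = s)[[1]]
    lay <- gen_suitability(g, spec, noise_sd = 0.05, seed = s)
    occ <- sample_presences(lay, 30, seed = s)
    prev <- Inf
    for (p in c(20, 10, 5, 0)) {
      n <- sum(threshold_10pct(lay, occ, p)$binary$values, na.rm = TRUE)
      expect_gte(n, ifelse(is.finite(prev), prev, n))
      prev <- n
    }
  }
})

test_that("range_size multiplies presence cells by cell area", {
  m <- matrix(FALSE, 10, 10); m[1:33] <- TRUE
  expect_equal(range_size(bin_layer(m)), 33)  # 33 one-km2 cells
  expect_equal(range_size(bin_layer(matrix(FALSE, 4, 4),
                                    make_grid(4, 4))), 0)
  g25 <- make_grid(10, 10, cell_area = 2.5)
  m50 <- matrix(FALSE, 10, 10); m50[1:50] <- TRUE
  expect_equal(range_size(species_layer("s", g25, m50)), 125)
})

test_that("breadth_class is total with inclusive-intermediate boundaries", {
  expect_identical(breadth_class(c(800, 30000, 1000, 25000, 5000, 0)),
                   c("restricted", "wide", "intermediate", "intermediate",
                     "intermediate", "restricted"))
  expect_error(breadth_class(-1), "nonnegative")
})

test_that("block_folds partitions records into balanced, block-coherent folds", {
  g <- make_grid(25, 25)
  # records everywhere: 25 blocks of 5x5, k = 5 -> 5 blocks per fold
  occ <- occurrence_set("s", rows = rep(1:25, 25), cols = rep(1:25, each = 25),
                        grid = g)
  f <- block_folds(occ, g, block_size = 5, k = 5, seed = 1)
  expect_setequal(unique(f$fold), 1:5)
  blk <- paste((f$row - 1) %/% 5, (f$col - 1) %/% 5)
  # block coherence: one fold per block
  expect_true(all(tapply(f$fold, blk, function(x) length(unique(x))) == 1))
  # balanced by block count
  expect_true(all(table(tapply(f$fold, blk, unique)) == 5))
  # partition: every record has exactly one fold
  expect_false(anyNA(f$fold))

  # two records in one block share the fold
  occ2 <- occurrence_set("s", rows = c(1, 2, 20), cols = c(1, 2, 20), grid = g)
  f2 <- block_folds(occ2, g, block_size = 5, k = 2, seed = 3)
  expect_equal(f2$fold[1], f2$fold[2])

  expect_error(block_folds(occ2, g, block_size = 25, k = 5, seed = 1),
               "non-empty blocks")
})

test_that("auc_presence_background is the tie-aware pair-counting statistic", {
  expect_equal(auc_presence_background(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc_presence_background(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # frozen oracle: exhaustive count over the 4 pairs -> 3 wins / 4
  expect_equal(auc_presence_background(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(auc_presence_background(numeric(0), 1), "non-empty")
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(42, {
    for (i in 1:10) {
      sp <- stats::runif(20); sb <- stats::runif(30)
      a0 <- auc_presence_background(sp, sb)
      expect_equal(auc_presence_background(exp(sp), exp(sb)), a0)
      expect_equal(auc_presence_background(sp^3 + 2 * sp, sb^3 + 2 * sb), a0)
    }
  })
})

test_that("tss is sensitivity + specificity - 1", {
  expect_equal(tss(rep(TRUE, 5), rep(FALSE, 7)), 1)
  expect_equal(tss(rep(TRUE, 5), rep(TRUE, 7)), 0)  # everything predicted present
  # constructed 2x2 table: sensitivity 0.8, specificity 0.7
  expect_equal(tss(rep(c(TRUE, FALSE), c(8, 2)), rep(c(FALSE, TRUE), c(7, 3))),
               0.5)
  expect_error(tss(logical(0), TRUE), "non-empty")
})

test_that("noiseless suitability separates presences from uniform background (AUC > 0.5)", {
  g <- make_grid(30, 30)
  spec <- virtual_species_spec("v", c(15, 15), spread = 4)
  lay <- gen_suitability(g, spec, noise_sd = 0)
  occ <- sample_presences(lay, 40, seed = 5)
  ev <- evaluate_layer(lay, occ, threshold_10pct(lay, occ)$threshold)
  expect_gt(ev$auc, 0.5)
  expect_true(ev$tss >= -1 && ev$tss <= 1)
})
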