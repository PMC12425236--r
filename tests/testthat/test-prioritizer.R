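test_that("benefit is a normalized increasing power function", {
  expect_equal(benefit(1, 0.25), 1)
  expect_equal(benefit(0, 0.25), 0)
  expect_equal(benefit(0.25, 1), 0.25)
  q <- seq(0, 1, 0.1)
  expect_true(all(diff(benefit(q, 0.25)) > 0))
  # concave for z < 1: chord below the curve
  expect_gt(benefit(0.5, 0.25), (benefit(0, 0.25) + benefit(1, 0.25)) / 2)
  expect_error(benefit(1.2, 0.25), "\\[0, 1\\]")
  expect_error(benefit(0.5, 0), "positive")
})

test_that("marginal_value reproduces the hand-evaluated delta examples", {
  # single species on all 4 cells of a 2x2 landscape, w=1, c=1, beta=0, z=1
  g <- make_grid(2, 2)
  lay <- bin_layer(matrix(TRUE, 2, 2), g)
  st <- representation_state(list(lay))
  cfg <- scp_config(beta = 0, z = 1)
  expect_equal(marginal_value(st, c(1, 1), weights = 1, config = cfg),
               0.25, tolerance = 1e-12)
  # a cell occupied by no species contributes nothing
  g3 <- make_grid(2, 2)
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  st2 <- representation_state(list(bin_layer(m, g3)))
  expect_equal(marginal_value(st2, c(2, 2), weights = 1, config = cfg), 0)
  # cost 10 divides the species term
  cost10 <- cost_layer(g, matrix(10, 2, 2))
  expect_equal(marginal_value(st, c(1, 1), weights = 1, cost = cost10,
                              config = cfg), 0.025, tolerance = 1e-12)
  expect_error(marginal_value(st2, c(2, 2), weights = c(1, 1), config = cfg),
               "align")
})

test_that("boundary_delta matches hand-counted geometry", {
  # full 3x3 block: BL 12, A 9; removing a corner -> 12/8 - 12/9 = 1/6
  st <- representation_state(list(bin_layer(matrix(TRUE, 3, 3))))
  expect_equal(boundary_delta(st, c(1, 1)), 1 / 6, tolerance = 1e-12)
  # 1x2 block: 4/1 - 6/2 = 1
  st2 <- representation_state(list(bin_layer(matrix(TRUE, 1, 2))))
  expect_equal(boundary_delta(st2, c(1, 1)), 1, tolerance = 1e-12)
  # removing an isolated single-cell patch: BL drops by 4, A by 1
  m <- matrix(FALSE, 5, 5); m[1:3, 1:3] <- TRUE; m[5, 5] <- TRUE
  st3 <- representation_state(list(bin_layer(m)),
                              remaining = m)
  expect_equal(st3$boundary_length, 16)
  expect_equal(boundary_delta(st3, c(5, 5)), 12 / 9 - 16 / 10,
               tolerance = 1e-12)
  expect_error(boundary_delta(st2, c(1, 1), scp_config()), NA)
  st1 <- representation_state(list(bin_layer(matrix(TRUE, 1, 1))))
  expect_error(boundary_delta(st1, c(1, 1)), "degenerate")
})

test_that("edge_candidates returns perimeter cells, never protected ones", {
  g <- make_grid(5, 5)
  lay <- bin_layer(matrix(TRUE, 5, 5), g)
  st <- representation_state(list(lay))
  cfg <- scp_config()
  cand <- edge_candidates(st, config = cfg)
  full <- matrix(TRUE, 5, 5)
  perim <- which(row(full) %in% c(1, 5) | col(full) %in% c(1, 5))
  expect_setequal(cand, perim)

  # 3x3 remaining block inside a 5x5 grid: 8 border cells, centre excluded
  rem <- matrix(FALSE, 5, 5); rem[2:4, 2:4] <- TRUE
  st2 <- representation_state(list(lay), remaining = rem)
  cand2 <- edge_candidates(st2, config = cfg)
  expect_length(cand2, 8)
  expect_false(13 %in% cand2)  # centre cell (3,3) is interior
  expect_setequal(cand2, setdiff(which(rem), 13))

  # all remaining cells protected -> empty candidate set (termination)
  pa <- pa_mask(g, matrix(TRUE, 5, 5))
  expect_length(edge_candidates(st, pa, cfg), 0)

  # interior-only fallback: unprotected island enclosed by PA
  pam <- matrix(TRUE, 5, 5); pam[3, 3] <- FALSE
  st3 <- representation_state(list(lay))
  expect_identical(edge_candidates(st3, pa_mask(g, pam), cfg), 13L)
})

test_that("run_prioritization removes worthless cells first and normalizes ranks", {
  # 2x2, one occupied cell: occupied cell is removed last, rank 1
  g <- make_grid(2, 2)
  m <- matrix(FALSE, 2, 2); m[2, 1] <- TRUE
  res <- run_prioritization(list(bin_layer(m, g)),
                            config = scp_config(beta = 0, warp = 1,
                                                edge_only = FALSE, seed = 3))
  expect_equal(res$rank_map$rank[2, 1], 1)
  expect_setequal(res$rank_map$rank, (1:4) / 4)

  # rank multiset {k/N} and species-zero-occurrence error
  inst <- random_instance(7)
  res2 <- run_prioritization(inst$layers, cost = inst$cost,
                             config = scp_config(warp = 5, seed = 1))
  N <- n_valid_cells(inst$grid)
  expect_equal(sort(res2$rank_map$rank[!is.na(res2$rank_map$rank)]),
               (1:N) / N)
  empty_sp <- bin_layer(matrix(FALSE, 8, 8), inst$grid, id = "ghost")
  expect_error(run_prioritization(c(inst$layers, list(empty_sp))),
               "ghost")
})

test_that("PA cells always out-rank unprotected cells", {
  inst <- random_instance(11, nr = 10, nc = 10)
  pa <- gen_pa_mask(inst$grid, 0.05, 1, seed = 2)
  res <- run_prioritization(inst$layers, cost = inst$cost, pa = pa,
                            config = scp_config(warp = 3, seed = 4))
  expect_gt(min(res$rank_map$rank[pa$mask]),
            max(res$rank_map$rank[!pa$mask & inst$grid$valid_mask]))
})

test_that("incremental ranking equals the exhaustive greedy oracle (warp=1, no BLP)", {
  for (s in 1:6) {
    inst <- random_instance(s, nr = 6, nc = 6, n_species = 3)
    cfg <- scp_config(beta = 0, warp = 1, edge_only = FALSE, seed = s)
    expect_identical(
      run_prioritization(inst$layers, cost = inst$cost, config = cfg)$removal_order,
      greedy_oracle(inst$layers, cost = inst$cost, config = cfg))
  }
  expect_error(greedy_oracle(list(), config = scp_config()), "requires")
})

test_that("unoccupied cells fall before occupied ones; weight 5 ranks above weight 1", {
  g <- make_grid(6, 6)
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  cfg <- scp_config(beta = 0, warp = 1, edge_only = FALSE, z = 1, seed = 2)
  ord <- greedy_oracle(list(bin_layer(m, g)), config = cfg)
  occupied <- which(m)
  expect_true(all(match(setdiff(ord, occupied), ord) <
                  min(match(occupied, ord))))

  # disjoint equal ranges with weights 5 vs 1: the heavy range survives longer
  m1 <- matrix(FALSE, 6, 6); m1[1:2, 1:2] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[5:6, 5:6] <- TRUE
  res <- run_prioritization(list(bin_layer(m1, g, "heavy"),
                                 bin_layer(m2, g, "light")),
                            weights = c(5, 1),
                            config = scp_config(beta = 0, warp = 1,
                                                edge_only = FALSE, seed = 9))
  expect_gt(mean(res$rank_map$rank[m1]), mean(res$rank_map$rank[m2]))
})

test_that("q stays a from-scratch recount at every iteration and curves decline", {
  inst <- random_instance(21, nr = 12, nc = 12, n_species = 4)
  pa <- gen_pa_mask(inst$grid, 0.05, 1, seed = 1)
  res <- run_prioritization(inst$layers, cost = inst$cost, pa = pa,
                            config = scp_config(warp = 10, seed = 5))
  # replay the removal order at iteration boundaries and recount q
  remaining <- inst$grid$valid_mask
  taken <- 0L
  for (i in seq_len(nrow(res$log))) {
    nrem <- res$log$n_removed[i]
    remaining[res$removal_order[taken + seq_len(nrem)]] <- FALSE
    taken <- taken + nrem
    expect_equal(res$curves$representation[, i + 1],
                 recount_q(inst$layers, remaining), tolerance = 1e-12)
  }
  expect_true(all(res$curves$representation[, 1] == 1))
  expect_true(all(apply(res$curves$representation, 1,
                        function(x) all(diff(x) <= 1e-12))))
  expect_true(all(diff(res$curves$retained_fractions) < 0))
})

test_that("a cell's rank is non-increasing in its own cost (warp=1, one species)", {
  g <- make_grid(5, 5)
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  target <- c(3, 3)
  rank_at <- function(cval) {
    cv <- matrix(1, 5, 5); cv[target[1], target[2]] <- cval
    res <- run_prioritization(list(bin_layer(m, g)),
                              cost = cost_layer(g, cv),
                              config = scp_config(beta = 0, warp = 1,
                                                  edge_only = FALSE, seed = 8))
    res$rank_map$rank[target[1], target[2]]
  }
  ranks <- vapply(c(1, 2, 5, 10, 100), rank_at, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("beta = 1 yields top-30% selections at least as compact as beta = 0 on average", {
  ratio <- function(mask) boundary_length(mask) / sum(mask)
  ratios <- vapply(1:6, function(s) {
    inst <- random_instance(s + 100, nr = 20, nc = 20, n_species = 3)
    out <- vapply(c(0, 1), function(b) {
      res <- run_prioritization(inst$layers, cost = inst$cost,
                                config = scp_config(beta = b, warp = 10,
                                                    seed = s))
      sc <- select_top_fraction(res$rank_map, 0.30)
      ratio(sc$mask)
    }, numeric(1))
    out
  }, numeric(2))
  expect_lte(mean(ratios[2, ]), mean(ratios[1, ]))
})

test_that("a PA mask covering everything warns and ranks from the protected phase", {
  g <- make_grid(3, 3)
  lay <- bin_layer(matrix(TRUE, 3, 3), g)
  expect_warning(res <- run_prioritization(list(lay),
                                           pa = pa_mask(g, matrix(TRUE, 3, 3)),
                                           config = scp_config(seed = 1)),
                 "whole landscape")
  expect_setequal(res$rank_map$rank, (1:9) / 9)
  expect_true(all(res$log$phase == "pa"))
})
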