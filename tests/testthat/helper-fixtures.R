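# Fixtures are built in code: small grids, hand-placed binary ranges, and a
# 4-connected patch counter used to verify PA connectivity independently of
# the generator.

make_grid <- function(nr, nc, cell_area = 1, valid = NULL)
  scp_grid(nr, nc, cell_area, valid)

# binary species layer from a logical matrix
bin_layer <- function(m, grid = scp_grid(nrow(m), ncol(m)), id = "sp",
                      iucn = "LC")
  species_layer(id, grid, m, iucn_category = iucn)

# logical matrix with TRUE at the given (row, col) pairs
mask_at <- function(nr, nc, cells) {
  m <- matrix(FALSE, nr, nc)
  if (length(cells)) m[do.call(rbind, cells)] <- TRUE
  m
}

# number of 4-connected patches of TRUE cells (independent flood fill)
count_patches <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (start in which(mask)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L; c <- (cell - 1L) %/% nr + 1L
      for (nb in c(if (r > 1) cell - 1L, if (r < nr) cell + 1L,
                   if (c > 1) cell - nr, if (c < nc) cell + nr))
        if (mask[nb] && !seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  n
}

# random small prioritization instance: binarized virtual species on a
# patchy landcover with the 10/1 cost layer
random_instance <- function(seed, nr = 8, nc = 8, n_species = 3) {
  g <- scp_grid(nr, nc)
  lc <- gen_landcover(g, 4, 0.5, seed = seed)
  specs <- gen_species_pool(g, n_species, spread_range = c(1, 3),
                            seed = seed + 1000)
  bins <- lapply(seq_along(specs), function(i) {
    lay <- gen_suitability(g, specs[[i]], lc, noise_sd = 0.05,
                           seed = seed + i)
    threshold_10pct(lay, sample_presences(lay, 25, seed = seed + 50 + i))$binary
  })
  list(grid = g, landcover = lc, cost = gen_cost(lc), layers = bins)
}

# from-scratch recount of per-species representation over a remaining mask
recount_q <- function(layers, remaining)
  vapply(layers, function(l) {
    occ <- l$values & l$grid$valid_mask
    occ[is.na(occ)] <- FALSE
    sum(occ & remaining) / sum(occ)
  }, numeric(1))
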