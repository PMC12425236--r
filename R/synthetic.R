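# Virtual-landscape generators. These emulate the statistical structure the
# downstream analysis assumes — a categorical land cover driving a two-valued
# cost layer, Gaussian-kernel species suitability with land-class affinity,
# presence-only sampling proportional to suitability, and compact protected
# areas grown by seeded region-growing — so every stage is testable without
# any download. All randomness flows from one explicit integer seed per call;
# the caller's global RNG state is left untouched.

#' Map an IUCN Red List category to a conservation weight
#'
#' Least-concern species weigh 1, near-threatened 2, vulnerable 3,
#' endangered 4 and critically endangered 5.
#'
#' @param category Character vector with elements in
#'   `c("LC", "NT", "VU", "EN", "CR")`.
#' @return Integer vector of weights in 1..5. Unknown categories are an
#'   error, never a silent default.
#' @examples
#' weight_from_iucn(c("LC", "VU", "CR"))  # 1 3 5
#' @export
weight_from_iucn <- function(category) {
  w <- c(LC = 1L, NT = 2L, VU = 3L, EN = 4L, CR = 5L)
  bad <- !(category %in% names(w))
  if (any(bad))
    stop("unknown IUCN category: ", paste(unique(category[bad]), collapse = ", "),
         call. = FALSE)
  unname(w[category])
}

#' Specification of a virtual species
#'
#' @param species_id Character scalar.
#' @param center Length-2 integer vector `c(row, col)`, kernel centre.
#' @param spread Positive real, Gaussian kernel standard deviation in cells;
#'   the single knob controlling realized range size.
#' @param max_suitability Peak suitability in (0, 1].
#' @param iucn_category IUCN category, see [weight_from_iucn()].
#' @param n_presences Positive integer, number of presence records to sample.
#' @return Object of class `scp_species_spec`.
#' @export
virtual_species_spec <- function(species_id, center, spread,
                                 max_suitability = 1, iucn_category = "LC",
                                 n_presences = 50) {
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0)
    stop("spread must be a positive real (cells)", call. = FALSE)
  if (max_suitability <= 0 || max_suitability > 1)
    stop("max_suitability must lie in (0, 1]", call. = FALSE)
  if (n_presences < 1 || n_presences != round(n_presences))
    stop("n_presences must be a positive integer", call. = FALSE)
  weight_from_iucn(iucn_category)  # validates the category
  structure(list(species_id = as.character(species_id),
                 center = as.integer(center), spread = as.numeric(spread),
                 max_suitability = as.numeric(max_suitability),
                 iucn_category = iucn_category,
                 n_presences = as.integer(n_presences)),
            class = "scp_species_spec")
}

# Land-cover class labels; the first pool is natural, the second
# human-associated, recycled with suffixes if n_types is large.
.natural_labels <- c("evergreen_forest", "deciduous_forest", "grassland_scrub",
                     "flooded_vegetation", "mangrove", "karst_forest")
.human_labels <- c("cropland", "urban", "plantation", "bare_sparse",
                   "aquaculture", "mosaic_agriculture")

make_labels <- function(pool, n) {
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, paste0(pool[1], "_", seq_len(n - length(pool))))[seq_len(n)]
}

#' Generate a patchy categorical land cover
#'
#' Valid cells are assigned the class of their nearest seed point (a Voronoi
#' mosaic), with seed classes drawn so that the expected fraction of cells in
#' natural classes equals `natural_fraction`. Codes `0..k_nat-1` are natural,
#' the rest human-associated.
#'
#' @param grid An [scp_grid].
#' @param n_types Integer >= 2, number of land-cover classes.
#' @param natural_fraction Target fraction of cells in natural classes,
#'   in \[0, 1\].
#' @param patchiness Positive real: approximate patch diameter in cells (the
#'   number of Voronoi seeds is about `n_valid / patchiness^2`).
#' @param seed Integer seed; identical seed + parameters give identical maps.
#' @return Object of class `scp_landcover`: the grid, an integer code matrix
#'   (NA outside the valid mask) and a `class_map` data.frame with columns
#'   `code, label, is_natural`.
#' @export
gen_landcover <- function(grid, n_types, natural_fraction, patchiness = 5,
                          seed = 1) {
  stopifnot(is_scp_grid(grid))
  if (n_types < 2 || n_types != round(n_types))
    stop("n_types must be an integer >= 2", call. = FALSE)
  if (!is.finite(natural_fraction) || natural_fraction < 0 || natural_fraction > 1)
    stop("natural_fraction must lie in [0, 1]", call. = FALSE)
  if (patchiness <= 0) stop("patchiness must be positive", call. = FALSE)
  n_types <- as.integer(n_types)

  k_nat <- if (natural_fraction == 0) 0L
  else if (natural_fraction == 1) n_types
  else max(1L, min(n_types - 1L, as.integer(round(natural_fraction * n_types))))
  is_nat <- seq_len(n_types) <= k_nat
  p_class <- numeric(n_types)
  if (k_nat > 0) p_class[is_nat] <- natural_fraction / k_nat
  if (k_nat < n_types) p_class[!is_nat] <- (1 - natural_fraction) / (n_types - k_nat)

  valid_idx <- which(grid$valid_mask)
  n_val <- length(valid_idx)
  n_seeds <- max(n_types, min(n_val, as.integer(round(n_val / patchiness^2))))

  codes <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  withr::with_seed(as.integer(seed), {
    seed_idx <- sample(valid_idx, n_seeds)
    seed_class <- sample.int(n_types, n_seeds, replace = TRUE, prob = p_class) - 1L
    sr <- (seed_idx - 1L) %% grid$n_rows + 1L
    sc <- (seed_idx - 1L) %/% grid$n_rows + 1L
    vr <- (valid_idx - 1L) %% grid$n_rows + 1L
    vc <- (valid_idx - 1L) %/% grid$n_rows + 1L
    # chunked nearest-seed assignment to bound memory on large grids
    chunk <- max(1L, as.integer(2e6 / n_seeds))
    for (start in seq(1L, n_val, by = chunk)) {
      ii <- start:min(start + chunk - 1L, n_val)
      d2 <- outer(vr[ii], sr, "-")^2 + outer(vc[ii], sc, "-")^2
      codes[valid_idx[ii]] <- seed_class[max.col(-d2, ties.method = "first")]
    }
  })

  labels <- character(n_types)
  if (k_nat > 0) labels[is_nat] <- make_labels(.natural_labels, k_nat)
  if (k_nat < n_types) labels[!is_nat] <- make_labels(.human_labels, n_types - k_nat)
  class_map <- data.frame(code = 0:(n_types - 1L), label = labels,
                          is_natural = is_nat, stringsAsFactors = FALSE)
  structure(list(grid = grid, codes = codes, class_map = class_map),
            class = "scp_landcover")
}

#' Generate a continuous suitability surface for a virtual species
#'
#' Suitability is an isotropic Gaussian kernel in cell distance from the
#' species centre, scaled by `max_suitability`, multiplied by a per-class
#' habitat affinity, and jittered by truncated Gaussian noise that is
#' modulated by the noiseless signal (`s * max(1 + e, 0)`, `e ~ N(0,
#' noise_sd)`); the result is truncated to \[0, 1\]. Signal-modulated noise
#' keeps zero-suitability cells exactly zero, so the realized range size
#' stays controlled by `spread` alone and a zero-affinity land class is a
#' hard mask even under noise.
#'
#' @param grid An [scp_grid].
#' @param spec A [virtual_species_spec()].
#' @param landcover An [gen_landcover()] result on the same grid.
#' @param affinity Named numeric vector in \[0, 1\]: one entry per land-cover
#'   code (names are the codes as character). Default: affinity 1 everywhere.
#' @param noise_sd Nonnegative standard deviation of the additive noise.
#' @param seed Integer seed for the noise; ignored when `noise_sd = 0`.
#' @return Continuous-mode [species_layer()].
#' @export
gen_suitability <- function(grid, spec, landcover = NULL, affinity = NULL,
                            noise_sd = 0, seed = 1) {
  stopifnot(is_scp_grid(grid), inherits(spec, "scp_species_spec"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  r <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
  cc <- matrix(seq_len(grid$n_cols), grid$n_rows, grid$n_cols, byrow = TRUE)
  d2 <- (r - spec$center[1])^2 + (cc - spec$center[2])^2
  s <- spec$max_suitability * exp(-d2 / (2 * spec$spread^2))
  if (!is.null(landcover)) {
    check_same_grid(grid, landcover$grid, "landcover")
    codes_present <- unique(landcover$codes[grid$valid_mask])
    if (is.null(affinity))
      affinity <- stats::setNames(rep(1, length(codes_present)),
                                  as.character(codes_present))
    missing_codes <- setdiff(as.character(codes_present), names(affinity))
    if (length(missing_codes))
      stop("affinity undefined for land-cover code(s): ",
           paste(missing_codes, collapse = ", "), call. = FALSE)
    aff <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    aff[grid$valid_mask] <-
      affinity[as.character(landcover$codes[grid$valid_mask])]
    s <- s * aff
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              matrix(stats::rnorm(length(s), 0, noise_sd),
                                     grid$n_rows, grid$n_cols))
    s <- s * pmax(1 + noise, 0)
  }
  s <- pmin(pmax(s, 0), 1)
  species_layer(spec$species_id, grid, s, iucn_category = spec$iucn_category)
}

#' Sample presence-only records proportional to suitability
#'
#' Cells are drawn with replacement with probability proportional to
#' suitability, mirroring presence-only occurrence data where habitat
#' hotspots are resampled.
#'
#' @param layer Continuous-mode [species_layer()].
#' @param n Number of presences (>= 1).
#' @param seed Integer seed.
#' @return An [occurrence_set()] of `n` records, all on cells with
#'   suitability > 0.
#' @export
sample_presences <- function(layer, n, seed = 1) {
  stopifnot(inherits(layer, "scp_species_layer"), layer$mode == "continuous")
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  w <- layer$values
  w[is.na(w)] <- 0
  if (all(w == 0))
    stop("empty-support: all suitability values are zero for species ",
         layer$species_id, call. = FALSE)
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(length(w), n, replace = TRUE, prob = as.vector(w)))
  occurrence_set(layer$species_id,
                 rows = (idx - 1L) %% layer$grid$n_rows + 1L,
                 cols = (idx - 1L) %/% layer$grid$n_rows + 1L,
                 grid = layer$grid)
}

#' Build the acquisition-cost layer from land cover
#'
#' Natural land-cover classes (e.g. evergreen forest) cost `natural_cost`,
#' human-associated classes (e.g. urban, cropland) cost `human_cost`. The
#' defaults, 10 and 1, encode that converting natural habitat into reserves
#' is an order of magnitude more expensive than already-transformed land.
#'
#' @param landcover An [gen_landcover()] result.
#' @param natural_cost,human_cost Strictly positive costs.
#' @return An [cost_layer()].
#' @export
gen_cost <- function(landcover, natural_cost = 10, human_cost = 1) {
  stopifnot(inherits(landcover, "scp_landcover"))
  if (natural_cost <= 0 || human_cost <= 0)
    stop("costs must be strictly positive", call. = FALSE)
  nat <- stats::setNames(landcover$class_map$is_natural,
                         as.character(landcover$class_map$code))
  v <- matrix(NA_real_, landcover$grid$n_rows, landcover$grid$n_cols)
  vm <- landcover$grid$valid_mask
  v[vm] <- ifelse(nat[as.character(landcover$codes[vm])], natural_cost, human_cost)
  cost_layer(landcover$grid, v)
}

#' Generate a protected-area mask of compact patches
#'
#' Grows `n_patches` 4-connected patches by seeded region-growing until the
#' requested fraction of valid cells is protected. Compact patches emulate
#' real reserves and exercise the prioritizer's edge-removal logic.
#'
#' @param grid An [scp_grid].
#' @param fraction Fraction of valid cells to protect, in \[0, 1\].
#' @param n_patches Number of patches to seed (patches may merge while
#'   growing, so this is an upper bound).
#' @param seed Integer seed.
#' @return An [pa_mask()] with exactly `round(fraction * n_valid)` protected
#'   cells. If the target count is below `n_patches` the patch count is
#'   reduced with a warning.
#' @export
gen_pa_mask <- function(grid, fraction, n_patches = 1, seed = 1) {
  stopifnot(is_scp_grid(grid))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  n_val <- n_valid_cells(grid)
  target <- as.integer(floor(fraction * n_val + 0.5))
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (target == 0L) return(pa_mask(grid, mask))
  if (target < n_patches) {
    warning("PA target of ", target, " cells is below n_patches = ", n_patches,
            "; reducing patch count", call. = FALSE)
    n_patches <- target
  }
  nr <- grid$n_rows; nc <- grid$n_cols
  withr::with_seed(as.integer(seed), {
    seeds <- sample(which(grid$valid_mask), n_patches)
    mask[seeds] <- TRUE
    n_pa <- n_patches
    # per-patch frontier of valid, unprotected 4-neighbours
    frontier <- lapply(seeds, function(i) neighbors4(i, nr, nc))
    frontier <- lapply(frontier, function(f) f[grid$valid_mask[f] & !mask[f]])
    turn <- 0L
    while (n_pa < target) {
      live <- which(vapply(frontier, length, 1L) > 0L)
      if (!length(live)) {  # disconnected valid area: seed a new patch
        free <- which(grid$valid_mask & !mask)
        s <- if (length(free) == 1L) free else sample(free, 1L)
        mask[s] <- TRUE; n_pa <- n_pa + 1L
        frontier[[length(frontier) + 1L]] <- {
          f <- neighbors4(s, nr, nc); f[grid$valid_mask[f] & !mask[f]]
        }
        next
      }
      turn <- turn + 1L
      p <- live[(turn - 1L) %% length(live) + 1L]
      f <- frontier[[p]]
      pick <- if (length(f) == 1L) f else sample(f, 1L)
      if (!mask[pick]) {
        mask[pick] <- TRUE; n_pa <- n_pa + 1L
        nb <- neighbors4(pick, nr, nc)
        frontier[[p]] <- unique(c(f[f != pick], nb[grid$valid_mask[nb] & !mask[nb]]))
      } else {
        frontier[[p]] <- f[f != pick]
      }
      frontier[[p]] <- frontier[[p]][!mask[frontier[[p]]]]
    }
  })
  pa_mask(grid, mask)
}

# 4-neighbours of a linear index, staying inside the lattice
neighbors4 <- function(i, nr, nc) {
  r <- (i - 1L) %% nr + 1L
  c <- (i - 1L) %/% nr + 1L
  out <- integer(0)
  if (r > 1L) out <- c(out, i - 1L)
  if (r < nr) out <- c(out, i + 1L)
  if (c > 1L) out <- c(out, i - nr)
  if (c < nc) out <- c(out, i + nr)
  out
}

#' Generate a pool of virtual species spanning restricted to wide ranges
#'
#' Spreads are log-uniform between `spread_range[1]` and `spread_range[2]`
#' cells so realized range sizes span orders of magnitude, as in real
#' regional faunas; IUCN categories are drawn LC-heavy (60/15/10/10/5 % for
#' LC/NT/VU/EN/CR), matching the typical skew of assessed faunas.
#'
#' @param grid An [scp_grid].
#' @param n_species Number of species.
#' @param spread_range Length-2 positive reals, kernel sd bounds in cells.
#' @param n_presences_range Integer bounds for records per species; the lower
#'   default of 21 mirrors the common modelling floor of >20 records.
#' @param seed Integer seed.
#' @return List of [virtual_species_spec()] objects.
#' @export
gen_species_pool <- function(grid, n_species, spread_range = c(1.5, 40),
                             n_presences_range = c(21, 200), seed = 1) {
  stopifnot(is_scp_grid(grid), n_species >= 1)
  withr::with_seed(as.integer(seed), {
    valid_idx <- which(grid$valid_mask)
    centers <- sample(valid_idx, n_species, replace = n_species > length(valid_idx))
    spreads <- exp(stats::runif(n_species, log(spread_range[1]), log(spread_range[2])))
    cats <- sample(c("LC", "NT", "VU", "EN", "CR"), n_species, replace = TRUE,
                   prob = c(0.60, 0.15, 0.10, 0.10, 0.05))
    npres <- sample(seq(n_presences_range[1], n_presences_range[2]), n_species,
                    replace = TRUE)
    lapply(seq_len(n_species), function(i)
      virtual_species_spec(sprintf("sp%03d", i),
                           center = c((centers[i] - 1L) %% grid$n_rows + 1L,
                                      (centers[i] - 1L) %/% grid$n_rows + 1L),
                           spread = spreads[i],
                           max_suitability = 1,
                           iucn_category = cats[i],
                           n_presences = npres[i]))
  })
}
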