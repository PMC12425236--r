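# Shared lattice and layer containers. Every analysis layer (land cover,
# suitability, binary range, cost, PA mask, rank map) lives on one scp_grid;
# alignment is checked by dimension + cell_area, never silently recycled.

#' Create an analysis grid
#'
#' The grid is the shared 2-D lattice on which all layers live: a number of
#' rows and columns, a per-cell area in km2, and a validity mask separating
#' analysable cells from NoData (sea, outside the study region, ...).
#'
#' @param n_rows,n_cols Positive integers, lattice dimensions.
#' @param cell_area Positive real, area of one cell in km2. Default 1 (the
#'   1-by-1 km convention common in national-scale prioritizations).
#' @param valid_mask Logical matrix `n_rows x n_cols`; `TRUE` marks analysable
#'   cells. Default: all cells valid. Must contain at least one `TRUE`.
#' @return An object of class `scp_grid`.
#' @examples
#' g <- scp_grid(20, 20)
#' n_valid_cells(g)
#' @export
scp_grid <- function(n_rows, n_cols, cell_area = 1, valid_mask = NULL) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  if (length(cell_area) != 1L || !is.finite(cell_area) || cell_area <= 0)
    stop("cell_area must be a positive real (km2)", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, n_rows, n_cols)
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), c(n_rows, n_cols)))
    stop("valid_mask must be a logical n_rows x n_cols matrix", call. = FALSE)
  valid_mask[is.na(valid_mask)] <- FALSE
  if (!any(valid_mask))
    stop("valid_mask must contain at least one analysable cell", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_area = as.numeric(cell_area), valid_mask = valid_mask),
            class = "scp_grid")
}

#' @export
print.scp_grid <- function(x, ...) {
  cat(sprintf("scp_grid: %d x %d cells (%d valid), cell area %g km2\n",
              x$n_rows, x$n_cols, sum(x$valid_mask), x$cell_area))
  invisible(x)
}

#' Number of valid (analysable) cells of a grid
#' @param grid An [scp_grid].
#' @return Integer count of valid cells.
#' @export
n_valid_cells <- function(grid) {
  stopifnot(inherits(grid, "scp_grid"))
  sum(grid$valid_mask)
}

is_scp_grid <- function(x) inherits(x, "scp_grid")

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_area, b$cell_area)) &&
    identical(a$valid_mask, b$valid_mask)
}

check_same_grid <- function(a, b, what = "layer") {
  if (!same_grid(a, b))
    stop("alignment error: ", what, " is not on the shared grid", call. = FALSE)
  invisible(TRUE)
}

# Sum of TRUE/positive 4- or 8-neighbours for every cell; cells outside the
# lattice count 0 (the lattice border is always exposed).
neighbor_sum <- function(m, neighborhood = 4) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  m[is.na(m)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc)
  if (nr > 1) {
    s[-1, ] <- s[-1, ] + m[-nr, ]
    s[-nr, ] <- s[-nr, ] + m[-1, ]
  }
  if (nc > 1) {
    s[, -1] <- s[, -1] + m[, -nc]
    s[, -nc] <- s[, -nc] + m[, -1]
  }
  if (neighborhood == 8 && nr > 1 && nc > 1) {
    s[-1, -1] <- s[-1, -1] + m[-nr, -nc]
    s[-1, -nc] <- s[-1, -nc] + m[-nr, -1]
    s[-nr, -1] <- s[-nr, -1] + m[-1, -nc]
    s[-nr, -nc] <- s[-nr, -nc] + m[-1, -1]
  } else if (neighborhood != 4 && neighborhood != 8) {
    stop("neighborhood must be 4 or 8", call. = FALSE)
  }
  s
}

#' Total boundary length of the remaining cell patches
#'
#' Counts exposed cell sides under the 4-neighbourhood: a side is exposed when
#' its neighbour is removed, NoData, or outside the lattice. Boundary length
#' is always side-counting regardless of the candidate neighbourhood used for
#' edge detection. Units: cell sides.
#'
#' @param remaining Logical matrix; `TRUE` = cell still in the landscape.
#' @return Nonnegative number of exposed sides.
#' @examples
#' boundary_length(matrix(TRUE, 3, 3))  # 12
#' @export
boundary_length <- function(remaining) {
  if (!any(remaining, na.rm = TRUE)) return(0)
  remaining[is.na(remaining)] <- FALSE
  nb <- neighbor_sum(remaining, 4)
  sum(4 - nb[remaining])
}

#' Construct a species layer
#'
#' A species layer holds one species' occurrence on the grid: either a
#' continuous habitat-suitability surface in \[0, 1\] or a binary range, plus
#' metadata (IUCN category, conservation weight, and — for binary layers —
#' range size in km2 and a distribution-breadth class).
#'
#' @param species_id Character scalar identifier.
#' @param grid An [scp_grid].
#' @param values Numeric (continuous mode, in \[0, 1\]) or logical (binary
#'   mode) matrix matching the grid; cells outside the valid mask are set NA.
#' @param iucn_category One of `"LC", "NT", "VU", "EN", "CR"`; determines the
#'   conservation weight via [weight_from_iucn()].
#' @return An object of class `scp_species_layer` with a `mode` field
#'   (`"continuous"` or `"binary"`) and a `meta` list (`iucn_category`,
#'   `weight`, and in binary mode `range_size_km2` and `breadth`).
#' @export
species_layer <- function(species_id, grid, values, iucn_category = "LC") {
  stopifnot(is_scp_grid(grid))
  if (!is.matrix(values) || !identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values must be a matrix matching the grid dimensions", call. = FALSE)
  mode <- if (is.logical(values)) "binary" else "continuous"
  if (mode == "continuous") {
    rng <- range(values[grid$valid_mask], na.rm = TRUE)
    if (any(is.finite(rng)) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      stop("continuous suitability must lie in [0, 1]", call. = FALSE)
  }
  values[!grid$valid_mask] <- NA
  meta <- list(iucn_category = iucn_category,
               weight = weight_from_iucn(iucn_category))
  if (mode == "binary") {
    meta$range_size_km2 <- sum(values & grid$valid_mask, na.rm = TRUE) * grid$cell_area
    meta$breadth <- breadth_class(meta$range_size_km2)
  }
  structure(list(species_id = as.character(species_id), grid = grid,
                 values = values, mode = mode, meta = meta),
            class = "scp_species_layer")
}

#' @export
print.scp_species_layer <- function(x, ...) {
  extra <- if (x$mode == "binary")
    sprintf(", range %.0f km2 (%s)", x$meta$range_size_km2, x$meta$breadth) else ""
  cat(sprintf("scp_species_layer '%s': %s, IUCN %s (weight %d)%s\n",
              x$species_id, x$mode, x$meta$iucn_category, x$meta$weight, extra))
  invisible(x)
}

#' Construct a cost layer
#'
#' Per-cell acquisition cost `c_i > 0` used to divide each cell's marginal
#' conservation value.
#'
#' @param grid An [scp_grid].
#' @param values Positive numeric matrix matching the grid.
#' @return Object of class `scp_cost_layer`.
#' @export
cost_layer <- function(grid, values) {
  stopifnot(is_scp_grid(grid))
  if (!is.matrix(values) || !identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("cost values must be a matrix matching the grid", call. = FALSE)
  if (any(values[grid$valid_mask] <= 0, na.rm = TRUE))
    stop("cost must be strictly positive on valid cells", call. = FALSE)
  values[!grid$valid_mask] <- NA
  structure(list(grid = grid, values = values), class = "scp_cost_layer")
}

#' Construct a protected-area mask
#'
#' Cells under existing protection, forced into the top of the priority
#' ranking by the prioritizer.
#'
#' @param grid An [scp_grid].
#' @param mask Logical matrix matching the grid; PA cells outside the valid
#'   mask are dropped.
#' @return Object of class `scp_pa_mask`.
#' @export
pa_mask <- function(grid, mask) {
  stopifnot(is_scp_grid(grid))
  if (!is.logical(mask) || !identical(dim(mask), c(grid$n_rows, grid$n_cols)))
    stop("mask must be a logical matrix matching the grid", call. = FALSE)
  mask[is.na(mask)] <- FALSE
  mask <- mask & grid$valid_mask
  structure(list(grid = grid, mask = mask), class = "scp_pa_mask")
}

#' Construct an occurrence set
#'
#' Presence records as grid cell coordinates (1-based row/col, as usual in R;
#' on-disk CSVs use 0-based indices, see [write_occurrences()]).
#'
#' @param species_id Character scalar.
#' @param rows,cols Integer vectors of equal length.
#' @param grid Optional [scp_grid]; when supplied, coordinates are checked to
#'   lie inside it.
#' @param fold Optional integer vector of cross-validation folds.
#' @return A data.frame of class `scp_occurrences` with columns
#'   `species_id, row, col` and optionally `fold`.
#' @export
occurrence_set <- function(species_id, rows, cols, grid = NULL, fold = NULL) {
  if (length(rows) != length(cols))
    stop("rows and cols must have equal length", call. = FALSE)
  if (!is.null(grid)) {
    stopifnot(is_scp_grid(grid))
    if (any(rows < 1 | rows > grid$n_rows | cols < 1 | cols > grid$n_cols))
      stop("occurrence coordinates fall outside the grid", call. = FALSE)
  }
  out <- data.frame(species_id = as.character(species_id),
                    row = as.integer(rows), col = as.integer(cols),
                    stringsAsFactors = FALSE)
  if (!is.null(fold)) out$fold <- as.integer(fold)
  class(out) <- c("scp_occurrences", "data.frame")
  out
}

# Seeded tie-break permutation: maps each linear cell index to a distinct
# priority, fixed at prioritizer startup so equal-delta cells are ordered
# reproducibly but without spatial bias.
tiebreak_perm <- function(grid, seed) {
  n <- grid$n_rows * grid$n_cols
  withr::with_seed(as.integer(seed), sample.int(n))
}
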