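# From continuous suitability to binary ranges and quality metrics:
# collinearity pruning of predictors, the 10th-percentile training-presence
# threshold, range size and distribution-breadth classing, spatial-block CV
# folds, and threshold-free (AUC) / thresholded (TSS) evaluation against
# background cells.

#' Greedy collinearity filter on a Spearman correlation matrix
#'
#' Variables are visited in priority order (most ecologically relevant
#' first); a variable is retained iff its absolute correlation with every
#' already-retained variable is below the threshold. With the default
#' threshold 0.7 this removes one member of every highly correlated pair
#' (|rho| >= 0.7).
#'
#' @param correlations Symmetric numeric matrix of Spearman rho with unit
#'   diagonal; dimnames give variable names unless `names` is supplied.
#' @param names Character vector of variable names (default: column names).
#' @param priority Permutation of `names`, most important first (default:
#'   `names` in order).
#' @param threshold Absolute-correlation cutoff; pairs at or above it
#'   conflict. Default 0.7.
#' @return Character vector of retained names, in priority order.
#' @examples
#' m <- matrix(c(1, .8, .8, 1), 2, 2, dimnames = list(c("A","B"), c("A","B")))
#' collinearity_filter(m)  # "A"
#' @export
collinearity_filter <- function(correlations, names = NULL, priority = NULL,
                                threshold = 0.7) {
  if (!is.matrix(correlations) || nrow(correlations) != ncol(correlations))
    stop("correlations must be a square matrix", call. = FALSE)
  if (max(abs(correlations - t(correlations))) > 1e-8)
    stop("correlations must be symmetric", call. = FALSE)
  if (any(abs(diag(correlations) - 1) > 1e-8))
    stop("correlations must have a unit diagonal", call. = FALSE)
  if (is.null(names)) names <- colnames(correlations)
  if (is.null(names)) stop("variable names are required", call. = FALSE)
  dimnames(correlations) <- list(names, names)
  if (is.null(priority)) priority <- names
  if (!setequal(priority, names) || length(priority) != length(names))
    stop("priority must be a permutation of names", call. = FALSE)
  kept <- character(0)
  for (v in priority) {
    if (!length(kept) || all(abs(correlations[v, kept]) < threshold))
      kept <- c(kept, v)
  }
  kept
}

#' Binarize a suitability surface at a training-presence percentile
#'
#' The threshold is the given percentile (default 10th) of the suitability
#' values at the training presences, computed by linear interpolation of the
#' empirical CDF between order statistics (R's `quantile` type 4 — the one
#' linear-interpolation convention that can never strand more than
#' `percentile` percent of presences); the binary range keeps all
#' cells with suitability at or above the threshold. By construction at most
#' `percentile` percent of training presences fall strictly below the
#' threshold. `percentile = 0` gives the minimum-training-presence
#' threshold, which keeps every presence inside the range.
#'
#' @param layer Continuous-mode [species_layer()].
#' @param training Non-empty [occurrence_set()] of training presences.
#' @param percentile Percentile in \[0, 100\]; default 10.
#' @return List with `threshold` (numeric scalar) and `binary` (binary-mode
#'   [species_layer()] carrying `range_size_km2` and `breadth` metadata).
#' @export
threshold_10pct <- function(layer, training, percentile = 10) {
  stopifnot(inherits(layer, "scp_species_layer"), layer$mode == "continuous")
  if (!nrow(training)) stop("training set is empty", call. = FALSE)
  if (any(training$row < 1 | training$row > layer$grid$n_rows |
          training$col < 1 | training$col > layer$grid$n_cols))
    stop("training cells fall outside the grid", call. = FALSE)
  vals <- layer$values[cbind(training$row, training$col)]
  if (anyNA(vals))
    stop("training cells fall on NoData cells", call. = FALSE)
  threshold <- as.numeric(stats::quantile(vals, percentile / 100, type = 4,
                                          names = FALSE))
  bin <- layer$values >= threshold
  binary <- species_layer(layer$species_id, layer$grid, bin,
                          iucn_category = layer$meta$iucn_category)
  binary$meta$threshold <- threshold
  binary$meta$percentile_method <- "linear_interpolation_type4"
  list(threshold = threshold, binary = binary)
}

#' Range size of a binary species layer
#'
#' @param binary Binary-mode [species_layer()].
#' @param grid Grid to evaluate on (default: the layer's own grid).
#' @return Count of presence cells times cell area, in km2.
#' @export
range_size <- function(binary, grid = binary$grid) {
  stopifnot(inherits(binary, "scp_species_layer"))
  if (binary$mode != "binary")
    stop("range_size requires a binary layer", call. = FALSE)
  check_same_grid(binary$grid, grid, "binary range")
  sum(binary$values & grid$valid_mask, na.rm = TRUE) * grid$cell_area
}

#' Classify distribution breadth from range size
#'
#' Ranges under 1,000 km2 are restricted, over 25,000 km2 wide, in between
#' (boundaries included) intermediate.
#'
#' @param area_km2 Nonnegative numeric vector of range sizes.
#' @return Character vector in `c("restricted", "intermediate", "wide")`.
#' @export
breadth_class <- function(area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 < 0))
    stop("area_km2 must be nonnegative", call. = FALSE)
  ifelse(area_km2 < 1000, "restricted",
         ifelse(area_km2 > 25000, "wide", "intermediate"))
}

#' Assign spatial-block cross-validation folds to occurrence records
#'
#' The grid is tiled into `block_size` x `block_size` square blocks; blocks
#' are shuffled and dealt to `k` folds balanced by block count, and every
#' record inherits the fold of its block, so records in one block always
#' share a fold (the point of spatial blocking: test folds are spatially
#' separated from training folds).
#'
#' @param occ An [occurrence_set()].
#' @param grid An [scp_grid].
#' @param block_size Block side length in cells (>= 1).
#' @param k Number of folds (>= 2), default 5.
#' @param seed Integer seed for the block shuffle.
#' @return The occurrence set with a `fold` column in 1..k.
#' @export
block_folds <- function(occ, grid, block_size, k = 5, seed = 1) {
  stopifnot(is_scp_grid(grid))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (block_size < 1 || block_size != round(block_size))
    stop("block_size must be a positive integer", call. = FALSE)
  if (any(occ$row < 1 | occ$row > grid$n_rows |
          occ$col < 1 | occ$col > grid$n_cols))
    stop("occurrence records fall outside the grid", call. = FALSE)
  nbr <- ceiling(grid$n_rows / block_size)
  nbc <- ceiling(grid$n_cols / block_size)
  block_of <- function(r, c)
    ((r - 1L) %/% block_size) * nbc + (c - 1L) %/% block_size + 1L
  rec_block <- block_of(occ$row, occ$col)
  if (length(unique(rec_block)) < k)
    stop("fewer non-empty blocks (", length(unique(rec_block)),
         ") than folds (", k, ")", call. = FALSE)
  n_blocks <- nbr * nbc
  fold_of_block <- withr::with_seed(as.integer(seed), {
    f <- integer(n_blocks)
    f[sample.int(n_blocks)] <- rep(seq_len(k), length.out = n_blocks)
    f
  })
  occ$fold <- fold_of_block[rec_block]
  occ
}

#' Rank-based AUC for presence-background evaluation
#'
#' The probability that a randomly chosen presence scores higher than a
#' randomly chosen background point, with ties counted half — the
#' Mann-Whitney statistic. Invariant under any strictly increasing
#' transformation of the scores.
#'
#' @param scores_presence,scores_background Non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_presence_background <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n0 <- length(scores_background)
  if (!n1 || !n0) stop("score vectors must be non-empty", call. = FALSE)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic of a binary prediction
#'
#' Sensitivity (fraction of presences predicted present) plus specificity
#' (fraction of background predicted absent) minus one; 1 is perfect skill,
#' 0 no skill.
#'
#' @param binary_pred_at_presences,binary_pred_at_background Non-empty
#'   logical vectors of predictions at presence / background points.
#' @return TSS in \[-1, 1\].
#' @export
tss <- function(binary_pred_at_presences, binary_pred_at_background) {
  if (!length(binary_pred_at_presences) || !length(binary_pred_at_background))
    stop("prediction vectors must be non-empty", call. = FALSE)
  mean(binary_pred_at_presences) + mean(!binary_pred_at_background) - 1
}

#' Evaluate one species' suitability surface against background cells
#'
#' Convenience wrapper producing the per-species evaluation row: AUC of the
#' continuous scores and TSS of the thresholded prediction, using all valid
#' cells (or a supplied set) as background.
#'
#' @param layer Continuous-mode [species_layer()].
#' @param presences [occurrence_set()] of evaluation presences.
#' @param threshold Binarization threshold (e.g. from [threshold_10pct()]).
#' @param background Optional two-column matrix/data.frame of background
#'   `row, col`; default all valid cells.
#' @return List with `auc`, `tss`, `threshold`.
#' @export
evaluate_layer <- function(layer, presences, threshold, background = NULL) {
  stopifnot(inherits(layer, "scp_species_layer"), layer$mode == "continuous")
  sp <- layer$values[cbind(presences$row, presences$col)]
  sb <- if (is.null(background)) layer$values[layer$grid$valid_mask]
  else layer$values[cbind(background$row, background$col)]
  sb <- sb[!is.na(sb)]
  list(auc = auc_presence_background(sp, sb),
       tss = tss(sp >= threshold, sb >= threshold),
       threshold = threshold)
}
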