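# Plain-text raster and table I/O. The raster dialect is the ESRI ASCII
# grid (.asc): a 6-line header (ncols, nrows, xllcorner, yllcorner,
# cellsize, NODATA_value) followed by rows of values, top row first. Values
# are written with 17 significant digits so write -> read round-trips
# doubles bit-exactly. GeoTIFF is not supported in this build (no raster
# library in the dependency set); .tif paths raise a format error.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values Numeric or logical matrix; NA becomes the NoData value.
#' @param path Output file path (conventionally `.asc`).
#' @param cellsize Cell size written to the header (default 1).
#' @param xllcorner,yllcorner Lower-left corner coordinates (default 0).
#' @param nodata NoData sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, path, cellsize = 1, xllcorner = 0,
                      yllcorner = 0, nodata = -9999) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  v <- matrix(as.numeric(values), nrow(values), ncol(values))
  v[is.na(v)] <- nodata
  header <- c(sprintf("ncols %d", ncol(v)),
              sprintf("nrows %d", nrow(v)),
              sprintf("xllcorner %.10g", xllcorner),
              sprintf("yllcorner %.10g", yllcorner),
              sprintf("cellsize %.10g", cellsize),
              sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `values` (numeric matrix, NoData as NA), `cellsize`,
#'   `xllcorner`, `yllcorner`, `nodata`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2 &&
        tolower(parts[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("format error: not an ESRI ASCII grid: ", path, call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("format error: expected ", hdr$ncols * hdr$nrows, " values, found ",
         length(vals), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m, cellsize = hdr$cellsize %||% 1,
       xllcorner = hdr$xllcorner %||% 0, yllcorner = hdr$yllcorner %||% 0,
       nodata = nodata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a raster file into a matrix, optionally checked against a grid
#'
#' Dispatches on extension; only the plain-text ESRI ASCII grid dialect is
#' supported in this build. When `grid` is supplied, the raster must match
#' its dimensions (alignment error otherwise).
#'
#' @param path File path (`.asc`).
#' @param grid Optional [scp_grid] to validate shape against.
#' @return As [read_asc()].
#' @export
read_raster <- function(path, grid = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    stop("format error: GeoTIFF is not supported in this build; ",
         "use ESRI ASCII grid (.asc)", call. = FALSE)
  if (ext != "asc")
    stop("format error: unknown raster format '", ext, "'", call. = FALSE)
  r <- read_asc(path)
  if (!is.null(grid) &&
      !identical(dim(r$values), c(grid$n_rows, grid$n_cols)))
    stop("alignment error: raster ", path, " is ", nrow(r$values), "x",
         ncol(r$values), " but the session grid is ", grid$n_rows, "x",
         grid$n_cols, call. = FALSE)
  r
}

#' Write a species metadata table
#'
#' Columns: `species_id, iucn_category, weight, n_presences`.
#'
#' @param specs List of [virtual_species_spec()]s, or a data.frame with the
#'   columns above.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(specs, path) {
  df <- if (is.data.frame(specs)) specs
  else do.call(rbind, lapply(specs, function(s)
    data.frame(species_id = s$species_id, iucn_category = s$iucn_category,
               weight = weight_from_iucn(s$iucn_category),
               n_presences = s$n_presences, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species metadata table
#' @param path CSV path with header `species_id,iucn_category,weight,n_presences`.
#' @return data.frame.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "iucn_category")
  if (!all(need %in% names(df)))
    stop("species CSV must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Write occurrence records as CSV (0-based grid indices)
#'
#' On-disk occurrence CSVs use 0-based, row-major `row,col` indices with the
#' origin at the top-left cell; in-memory occurrence sets use R's 1-based
#' indices. The two writers/readers convert between the conventions.
#'
#' @param occ An [occurrence_set()] (1-based).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(species_id = occ$species_id, row = occ$row - 1L,
                   col = occ$col - 1L)
  if (!is.null(occ$fold)) df$fold <- occ$fold
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read occurrence records from CSV (0-based grid indices)
#' @param path CSV path with header `species_id,row,col`.
#' @param grid Optional [scp_grid] for bounds checking.
#' @return An [occurrence_set()] (1-based).
#' @export
read_occurrences <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrence_set(df$species_id, df$row + 1L, df$col + 1L, grid = grid,
                 fold = df$fold)
}

#' Write a gap report to CSV
#'
#' Emits the per-species table and, beside it, a one-row `*_summary.csv`.
#'
#' @param report An [gap_report()].
#' @param path Output CSV path for the per-species rows.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(report, path) {
  stopifnot(inherits(report, "scp_gap_report"))
  utils::write.csv(report$rows, path, row.names = FALSE, quote = FALSE)
  s <- report$summary
  utils::write.csv(data.frame(mean_coverage_pct = s$mean_coverage_pct,
                              n_well = s$n_well, n_poor = s$n_poor,
                              n_species = s$n_species),
                   sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write performance curves to CSV
#'
#' One `retained_fraction` column plus one representation column per
#' species.
#'
#' @param curves `scp_curves` from [run_prioritization()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "scp_curves"))
  df <- data.frame(retained_fraction = curves$retained_fractions)
  rep_t <- t(curves$representation)
  colnames(rep_t) <- curves$species_ids
  utils::write.csv(cbind(df, rep_t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Plain `key = value` config file parser (comments with #, blank lines ok);
# values are parsed as numeric vectors when possible, else kept as strings.
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(strsplit(trimws(kv[2]), ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num
    else if (all(val %in% c("true", "false", "TRUE", "FALSE")))
      as.logical(toupper(val)) else val
  }
  out
}
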