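#' A single Raman spectrum
#'
#' @param sample_id Sample identifier.
#' @param wavenumbers Strictly increasing Raman shifts (cm^-1).
#' @param intensities Intensities (CCD counts, arbitrary units), same length.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(sample_id, wavenumbers, intensities) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (length(wavenumbers) != length(intensities)) {
    stop("'wavenumbers' and 'intensities' must have equal length")
  }
  if (any(diff(wavenumbers) <= 0)) stop("'wavenumbers' must be strictly increasing")
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  structure(list(sample_id = sample_id,
                 wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities)),
            class = "spectrum")
}

#' A cohort of spectra on a shared wavenumber grid
#'
#' The n x k spectral matrix: one row per sample, one column per grid
#' wavenumber. Columns are the "spectral vectors" the correlation analysis
#' works on. Provenance (e.g. background-filter parameters) travels with the
#' object.
#'
#' @param sample_ids Character vector of n sample identifiers.
#' @param grid Shared wavenumber grid (k entries, strictly increasing).
#' @param matrix n x k numeric intensity matrix.
#' @param provenance Optional list of processing metadata.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(sample_ids, grid, matrix, provenance = list()) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(sample_ids)) {
    stop("number of rows must match 'sample_ids'")
  }
  if (ncol(matrix) != length(grid)) stop("number of columns must match 'grid'")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing")
  }
  rownames(matrix) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids),
                 grid = as.numeric(grid), matrix = matrix,
                 provenance = provenance),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d wavenumbers [%.1f, %.1f] cm^-1\n",
              nrow(x$matrix), ncol(x$matrix),
              if (length(x$grid)) min(x$grid) else NA,
              if (length(x$grid)) max(x$grid) else NA))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-sample laboratory marker values
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param values data.frame of marker columns aligned to `sample_ids`;
#'   `NA` marks a missing laboratory value.
#' @param units Optional named character vector of per-marker units.
#' @return An object of class `marker_table`.
#' @export
marker_table <- function(sample_ids, values, units = NULL) {
  values <- as.data.frame(values)
  if (nrow(values) != length(sample_ids)) {
    stop("'values' must have one row per sample")
  }
  structure(list(sample_ids = as.character(sample_ids),
                 values = values, units = units),
            class = "marker_table")
}

#' Read a two-column spectrum text file
#'
#' Expects whitespace- or comma-separated `wavenumber intensity` rows;
#' lines starting with `#` are comments. Rows are sorted by wavenumber and
#' duplicated wavenumbers are averaged.
#'
#' @param path File path.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  wn <- numeric(0)
  it <- numeric(0)
  for (ln in which(keep)) {
    fields <- strsplit(trimws(lines[ln]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || any(is.na(vals))) {
      stop("malformed spectrum line ", ln, " in ", path, ": '", lines[ln], "'")
    }
    wn <- c(wn, vals[1])
    it <- c(it, vals[2])
  }
  if (length(wn) < 2L) stop("spectrum file ", path, " has fewer than 2 data rows")
  o <- order(wn)
  wn <- wn[o]
  it <- it[o]
  if (anyDuplicated(wn)) {
    it <- as.numeric(tapply(it, wn, mean))
    wn <- sort(unique(wn))
  }
  spectrum(sample_id, wn, it)
}

#' Write a spectrum as a two-column text file
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @param digits Significant digits to write (default preserves doubles).
#' @export
write_spectrum <- function(spec, path, digits = 17) {
  stopifnot(inherits(spec, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id: %s", spec$sample_id), con)
  writeLines(sprintf(paste0("%.", digits, "g %.", digits, "g"),
                     spec$wavenumbers, spec$intensities), con)
  invisible(path)
}

#' Write every spectrum of a dataset to a directory
#'
#' @param dataset A [spectral_dataset()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$sample_ids)) {
    write_spectrum(spectrum(dataset$sample_ids[i], dataset$grid,
                            dataset$matrix[i, ]),
                   file.path(dir, paste0(dataset$sample_ids[i], ".txt")))
  }
  invisible(dir)
}

#' Interpolate spectra onto a common grid
#'
#' Linear interpolation of every spectrum onto `grid`; each spectrum's
#' wavenumber range must cover the grid span. Row order follows the input.
#'
#' @param spectra List of [spectrum()] objects.
#' @param grid Target wavenumber grid.
#' @return A [spectral_dataset()].
#' @export
assemble_dataset <- function(spectra, grid) {
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  mat <- matrix(0, length(spectra), length(grid))
  ids <- character(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    stopifnot(inherits(sp, "spectrum"))
    if (min(sp$wavenumbers) > min(grid) || max(sp$wavenumbers) < max(grid)) {
      stop("spectrum '", sp$sample_id, "' does not cover the grid span [",
           min(grid), ", ", max(grid), "] cm^-1")
    }
    mat[i, ] <- stats::approx(sp$wavenumbers, sp$intensities, xout = grid)$y
    ids[i] <- sp$sample_id
  }
  spectral_dataset(ids, grid, mat)
}

#' Read a marker CSV
#'
#' Comma-separated with a header row; first column is `sample_id`, remaining
#' columns are marker values. Empty cells are missing values; decimal commas
#' (as printed in many clinical tables) are normalized to points.
#'
#' @param path File path.
#' @return A [marker_table()].
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("marker CSV needs a sample_id column and >= 1 marker")
  ids <- raw[[1]]
  values <- raw[-1]
  for (nm in names(values)) {
    v <- trimws(values[[nm]])
    v[v == ""] <- NA
    # decimal-comma cells like "48,8"; true thousands separators are not
    # expected in laboratory exports
    v <- gsub(",", ".", v, fixed = TRUE)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", values[[nm]][bad[1]], "' for marker '", nm,
           "' (row ", bad[1], ")")
    }
    values[[nm]] <- num
  }
  marker_table(ids, values)
}

#' Write a marker table as CSV
#'
#' @param table A [marker_table()].
#' @param path Output path.
#' @export
write_marker_table <- function(table, path) {
  stopifnot(inherits(table, "marker_table"))
  df <- cbind(data.frame(sample_id = table$sample_ids), table$values)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pair spectra with one marker's laboratory values
#'
#' Restricts the spectral matrix and the marker vector to the samples for
#' which both exist; `n_spectra` is the number of usable pairs (the per-
#' marker n of the analysis).
#'
#' @param dataset A [spectral_dataset()].
#' @param table A [marker_table()] on the same sample ids.
#' @param marker Marker column name.
#' @return An object of class `paired_data` with fields `marker`,
#'   `sample_ids`, `spectra` (submatrix), `values`, `grid`, `n_spectra`.
#' @export
pair <- function(dataset, table, marker) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(table, "marker_table"))
  if (!marker %in% names(table$values)) {
    stop("marker '", marker, "' not present in the marker table")
  }
  idx <- match(dataset$sample_ids, table$sample_ids)
  vals <- table$values[[marker]][idx]
  usable <- which(!is.na(idx) & !is.na(vals))
  if (length(usable) < 3L) {
    stop("fewer than 3 usable spectrum/value pairs for marker '", marker,
         "'; correlation is undefined")
  }
  structure(list(marker = marker,
                 sample_ids = dataset$sample_ids[usable],
                 spectra = dataset$matrix[usable, , drop = FALSE],
                 values = vals[usable],
                 grid = dataset$grid,
                 n_spectra = length(usable),
                 provenance = dataset$provenance),
            class = "paired_data")
}
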