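#' Spectra collection with design metadata
#'
#' A `spectra_set` bundles an aligned spectral matrix (rows = spectra,
#' columns = wavenumbers on a shared, strictly descending grid in cm^-1)
#' with a per-spectrum metadata table and, optionally, per-sample reference
#' chemistry (total lipids and phosphorus in \% of dry weight, total
#' carotenoids in ug/g dry weight).
#'
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly monotone.
#'   Stored descending (instrument convention); ascending input is flipped
#'   together with the matrix columns.
#' @param intensities Numeric matrix, one row per spectrum, `length(grid)`
#'   columns. All values must be finite.
#' @param meta Data frame with one row per spectrum. Must contain a
#'   `sample_id` column; the cultivation-design columns (`strain`,
#'   `pi_level`, `ca_level`, `bio_rep`, `tech_rep`, `laser_power_mw`,
#'   `block`) are used by downstream analyses when present.
#' @param chemistry Optional data frame of reference values keyed by
#'   `sample_id` with columns `lipid_pct_dw`, `phosphorus_pct_dw`,
#'   `carotenoid_ug_per_g` (non-negative).
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, intensities, meta, chemistry = NULL) {
  grid <- as.numeric(grid)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(meta$sample_id))
    stop("meta must contain a 'sample_id' column")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  x <- structure(
    list(grid = grid, intensities = intensities, meta = meta,
         chemistry = chemistry),
    class = "spectra_set")
  validate_spectra_set(x)
}

#' @keywords internal
validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  d <- diff(x$grid)
  if (length(x$grid) > 1 && !(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (length(x$grid) > 1 && all(d > 0)) {   # normalize to descending
    x$grid <- rev(x$grid)
    x$intensities <- x$intensities[, rev(seq_len(ncol(x$intensities))),
                                   drop = FALSE]
  }
  if (ncol(x$intensities) != length(x$grid))
    stop(sprintf("matrix has %d columns but grid has %d wavenumbers",
                 ncol(x$intensities), length(x$grid)))
  if (nrow(x$intensities) != nrow(x$meta))
    stop(sprintf("matrix has %d rows but meta has %d rows",
                 nrow(x$intensities), nrow(x$meta)))
  if (anyDuplicated(x$grid))
    stop(sprintf("duplicate wavenumber in grid: %g",
                 x$grid[anyDuplicated(x$grid)]))
  bad <- which(!is.finite(x$intensities), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite intensity at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  if (!is.null(x$chemistry)) {
    num <- intersect(c("lipid_pct_dw", "phosphorus_pct_dw",
                       "carotenoid_ug_per_g"), names(x$chemistry))
    for (cc in num)
      if (any(x$chemistry[[cc]] < 0, na.rm = TRUE))
        stop(sprintf("chemistry column '%s' has negative values", cc))
  }
  x
}

#' Number of spectra in a set
#' @param x A `spectra_set`.
#' @return Integer row count.
#' @export
n_spectra <- function(x) nrow(x$intensities)

#' Subset the spectra (rows) of a set
#'
#' @param x A `spectra_set`.
#' @param i Row index (logical or integer).
#' @return A `spectra_set` with matching metadata; chemistry is restricted
#'   to the sample ids that remain.
#' @export
subset_spectra <- function(x, i) {
  out <- x
  out$intensities <- x$intensities[i, , drop = FALSE]
  out$meta <- x$meta[i, , drop = FALSE]
  rownames(out$meta) <- NULL
  if (!is.null(x$chemistry))
    out$chemistry <- x$chemistry[
      x$chemistry$sample_id %in% unique(out$meta$sample_id), , drop = FALSE]
  out
}

#' Restrict a set to a common wavenumber window or column index
#' @keywords internal
subset_columns <- function(x, j) {
  out <- x
  out$grid <- x$grid[j]
  out$intensities <- x$intensities[, j, drop = FALSE]
  out
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavenumbers (%.1f to %.1f cm^-1)\n",
              nrow(x$intensities), length(x$grid),
              max(x$grid), min(x$grid)))
  if (!is.null(x$meta$block))
    cat("  block:", paste(unique(x$meta$block), collapse = ", "), "\n")
  if (!is.null(x$meta$strain))
    cat("  strains:", paste(sort(unique(x$meta$strain)), collapse = ", "), "\n")
  if (!is.null(x$chemistry))
    cat(sprintf("  chemistry: %d samples x %d columns\n",
                nrow(x$chemistry), ncol(x$chemistry) - 1L))
  invisible(x)
}

#' @export
plot.spectra_set <- function(x, rows = seq_len(min(6, n_spectra(x))),
                             col = NULL, ...) {
  if (is.null(col)) col <- seq_along(rows)
  graphics::matplot(x$grid, t(x$intensities[rows, , drop = FALSE]),
                    type = "l", lty = 1, col = col,
                    xlim = rev(range(x$grid)),
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Intensity (a.u.)", ...)
  invisible(x)
}

#' Chemistry values aligned to the rows of a set
#'
#' Looks up a reference-chemistry column for every spectrum row via
#' `sample_id`.
#'
#' @param x A `spectra_set` with a chemistry table.
#' @param analyte Column name in the chemistry table.
#' @return Numeric vector, one value per spectrum row.
#' @export
chemistry_for_rows <- function(x, analyte) {
  if (is.null(x$chemistry)) stop("spectra_set has no chemistry table")
  if (!analyte %in% names(x$chemistry))
    stop(sprintf("analyte '%s' not in chemistry table", analyte))
  idx <- match(x$meta$sample_id, x$chemistry$sample_id)
  if (anyNA(idx))
    stop("some sample_ids have no chemistry entry: ",
         paste(utils::head(x$meta$sample_id[is.na(idx)]), collapse = ", "))
  x$chemistry[[analyte]][idx]
}
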