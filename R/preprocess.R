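#' Savitzky-Golay smoothing and derivatives
#'
#' Per-spectrum local polynomial filtering. Derivatives are taken with
#' respect to wavenumber, so a derivative of order `m` is returned in
#' units of intensity per (cm^-1)^m; the internally descending grid is
#' differentiated on its ascending copy and restored, giving the usual
#' spectroscopic sign convention. Edge points are handled by the one-sided
#' polynomial fits of the filter's startup/closing rows (no padding).
#'
#' @param set A [spectra_set()].
#' @param polynomial Polynomial order (default 2).
#' @param window Odd window length, `window > polynomial` (default 15).
#' @param derivative_order Derivative order, `<= polynomial` (default 0).
#' @return The filtered [spectra_set()].
#' @export
savgol <- function(set, polynomial = 2, window = 15, derivative_order = 0) {
  stopifnot(inherits(set, "spectra_set"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polynomial) stop("window must exceed the polynomial order")
  if (derivative_order > polynomial)
    stop("derivative_order must not exceed the polynomial order")
  if (window > length(set$grid))
    stop("window larger than the wavenumber grid")
  h <- abs(stats::median(diff(set$grid)))
  asc <- rev(seq_along(set$grid))   # ascending-wavenumber view
  out <- set
  filt <- signal::sgolay(p = polynomial, n = window, m = derivative_order,
                         ts = h)
  out$intensities <- t(apply(set$intensities, 1, function(y) {
    rev(signal::sgolayfilt(y[asc], filt))
  }))
  dimnames(out$intensities) <- NULL
  out
}

#' Rubber-band (lower convex hull) baseline correction
#'
#' Estimates each spectrum's baseline as the lower convex hull of its
#' (wavenumber, intensity) points and subtracts the piecewise-linear
#' chain. The corrected spectrum is exactly zero at the hull vertices
#' (including both endpoints) and non-negative wherever the spectrum lies
#' above its hull.
#'
#' @param set A [spectra_set()] with positively oriented peaks.
#' @return Baseline-corrected [spectra_set()].
#' @export
rubberband_baseline <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (length(set$grid) < 3)
    stop("rubber-band correction needs at least 3 grid points")
  asc <- rev(seq_along(set$grid))
  x <- set$grid[asc]
  out <- set
  out$intensities <- t(apply(set$intensities, 1, function(yrow) {
    y <- yrow[asc]
    v <- lower_hull(x, y)
    base <- stats::approx(x[v], y[v], xout = x, method = "linear")$y
    corr <- y - base
    corr[v] <- 0   # exact zeros at hull vertices
    rev(corr)
  }))
  dimnames(out$intensities) <- NULL
  out
}

# Andrew's monotone chain, lower hull only; x strictly increasing.
# Returns vertex indices (includes both endpoints).
lower_hull <- function(x, y) {
  n <- length(x)
  v <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L &&
           (x[v[k]] - x[v[k - 1L]]) * (y[i] - y[v[k - 1L]]) -
           (y[v[k]] - y[v[k - 1L]]) * (x[i] - x[v[k - 1L]]) <= 0)
      k <- k - 1L
    k <- k + 1L
    v[k] <- i
  }
  v[seq_len(k)]
}

#' Truncate spectra to a union of wavenumber regions
#'
#' @param set A [spectra_set()].
#' @param regions List of `c(lo, hi)` closed intervals in cm^-1 (order
#'   within a pair is irrelevant); regions must not overlap.
#' @return [spectra_set()] restricted to the union of the regions,
#'   descending column order preserved.
#' @export
truncate_regions <- function(set, regions) {
  stopifnot(inherits(set, "spectra_set"))
  if (!is.list(regions)) regions <- list(regions)
  iv <- lapply(regions, function(r) sort(as.numeric(r)))
  if (length(iv) > 1) {
    o <- order(vapply(iv, `[`, 0, 1))
    s <- iv[o]
    for (k in seq_len(length(s) - 1))
      if (s[[k]][2] > s[[k + 1]][1]) stop("regions overlap")
  }
  keep <- Reduce(`|`, lapply(iv, function(r)
    set$grid >= r[1] & set$grid <= r[2]))
  if (!any(keep)) stop("truncation removed every wavenumber")
  subset_columns(set, which(keep))
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Least-squares fits every spectrum `s` to the model
#' `s = a * m + sum_{k=0}^{d} c_k u^k`, where `m` is the reference
#' spectrum and `u` is the wavenumber axis rescaled to `[-1, 1]`, then
#' returns the corrected spectrum `(s - sum_k c_k u^k) / a`. This removes
#' multiplicative scatter (the gain `a`) and polynomial baseline
#' contributions in one step; the plain MSC is the `poly_degree = 1`
#' model without the quadratic/cubic terms.
#'
#' @param set A [spectra_set()].
#' @param reference `"mean"` (the mean spectrum of `set`) or a numeric
#'   vector on the same grid. For calibration/validation workflows pass
#'   the training-partition mean explicitly to avoid leakage.
#' @param poly_degree Degree of the polynomial baseline model (1-3;
#'   default 3, i.e. constant + linear + quadratic + cubic).
#' @return Corrected [spectra_set()]; fitted coefficients are attached as
#'   attribute `"emsc_coefficients"` (columns `a`, `c0`, ..., `cd`) and
#'   the reference as `"emsc_reference"`.
#' @export
emsc <- function(set, reference = "mean", poly_degree = 3) {
  stopifnot(inherits(set, "spectra_set"))
  if (!poly_degree %in% 1:3) stop("poly_degree must be 1, 2 or 3")
  m <- if (identical(reference, "mean")) colMeans(set$intensities)
       else as.numeric(reference)
  if (length(m) != length(set$grid))
    stop("reference must be on the same wavenumber grid")
  u <- 2 * (set$grid - min(set$grid)) / diff(range(set$grid)) - 1
  P <- stats::poly(u, degree = poly_degree, raw = TRUE)
  D <- cbind(m = m, c0 = 1, P)                      # p x (d + 2)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("singular EMSC design: the reference is collinear with the ",
         "polynomial baseline; use a different reference spectrum")
  coefs <- t(qr.coef(qrD, t(set$intensities)))      # n x (d + 2)
  a <- coefs[, 1]
  if (any(abs(a) < 1e-12))
    stop("EMSC gain is zero for at least one spectrum")
  baseline <- coefs[, -1, drop = FALSE] %*% t(D[, -1, drop = FALSE])
  out <- set
  out$intensities <- (set$intensities - baseline) / a
  colnames(coefs) <- c("a", paste0("c", 0:poly_degree))
  attr(out, "emsc_coefficients") <- coefs
  attr(out, "emsc_reference") <- m
  out
}

#' Preprocessing recipes
#'
#' The four standard recipes, as ordered step lists:
#' \describe{
#'   \item{raman_nonderiv}{SG(2, 15, 0) -> rubber band -> truncate to
#'     3200-2400 and 1900-500 cm^-1 -> EMSC(degree 3)}
#'   \item{raman_deriv}{SG(2, 15, 2) -> EMSC(degree 3) -> truncate to
#'     1800-900 cm^-1}
#'   \item{ftir_nonderiv}{EMSC(degree 3)}
#'   \item{ftir_deriv}{SG(2, 15, 2) -> EMSC(degree 2) -> truncate to
#'     1800-900 cm^-1}
#' }
#'
#' @param name Recipe name.
#' @return A list of class `preprocess_recipe` with `name` and `steps`
#'   (each step a list with `fn` and parameters).
#' @export
preprocess_recipe <- function(name = c("raman_nonderiv", "raman_deriv",
                                       "ftir_nonderiv", "ftir_deriv")) {
  name <- match.arg(name)
  sg0 <- list(fn = "savgol", polynomial = 2, window = 15,
              derivative_order = 0)
  sg2 <- list(fn = "savgol", polynomial = 2, window = 15,
              derivative_order = 2)
  steps <- switch(name,
    raman_nonderiv = list(
      sg0,
      list(fn = "rubberband_baseline"),
      list(fn = "truncate_regions",
           regions = list(c(2400, 3200), c(500, 1900))),
      list(fn = "emsc", poly_degree = 3)),
    raman_deriv = list(
      sg2,
      list(fn = "emsc", poly_degree = 3),
      list(fn = "truncate_regions", regions = list(c(900, 1800)))),
    ftir_nonderiv = list(
      list(fn = "emsc", poly_degree = 3)),
    ftir_deriv = list(
      sg2,
      list(fn = "emsc", poly_degree = 2),
      list(fn = "truncate_regions", regions = list(c(900, 1800)))))
  structure(list(name = name, steps = steps), class = "preprocess_recipe")
}

#' Apply a preprocessing recipe
#'
#' Applies the recipe's steps strictly in order. An explicit EMSC
#' reference (e.g. the training-partition mean, possibly itself run
#' through the preceding steps) can be supplied to override the default
#' set mean; it must live on the grid the set has when the EMSC step is
#' reached.
#'
#' @param set A [spectra_set()].
#' @param recipe A [preprocess_recipe()] or a recipe name.
#' @param emsc_reference Optional numeric reference for the EMSC step(s).
#' @return The preprocessed [spectra_set()].
#' @export
apply_recipe <- function(set, recipe, emsc_reference = NULL) {
  if (is.character(recipe)) recipe <- preprocess_recipe(recipe)
  stopifnot(inherits(recipe, "preprocess_recipe"))
  for (st in recipe$steps) {
    set <- switch(st$fn,
      savgol = savgol(set, st$polynomial, st$window, st$derivative_order),
      rubberband_baseline = rubberband_baseline(set),
      truncate_regions = truncate_regions(set, st$regions),
      emsc = emsc(set,
                  reference = if (is.null(emsc_reference)) "mean"
                              else emsc_reference,
                  poly_degree = st$poly_degree),
      stop("unknown preprocessing step: ", st$fn))
  }
  set
}

#' Average technical replicates into biological samples
#'
#' Averages the spectra of each biological sample's technical replicates
#' (grouped by `sample_id`), producing one row per biological sample and
#' restoring sample-to-sample correspondence between data blocks. Rows
#' are ordered by first appearance of each sample.
#'
#' @param set A [spectra_set()] whose metadata carries `sample_id`.
#' @return A [spectra_set()] with one row per biological sample and
#'   `tech_rep` dropped from the metadata.
#' @export
average_technical_replicates <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$meta$sample_id)
  keepcols <- setdiff(names(set$meta), "tech_rep")
  mat <- matrix(0, length(ids), length(set$grid))
  meta <- NULL
  for (k in seq_along(ids)) {
    rows <- which(set$meta$sample_id == ids[k])
    grp <- unique(set$meta[rows, keepcols, drop = FALSE])
    if (nrow(grp) != 1)
      stop("inconsistent metadata within replicates of sample ", ids[k])
    mat[k, ] <- colMeans(set$intensities[rows, , drop = FALSE])
    meta <- rbind(meta, grp)
  }
  rownames(meta) <- NULL
  spectra_set(set$grid, mat, meta, set$chemistry)
}
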