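# Shared fixtures. The default synthetic dataset and its preprocessed
# blocks are expensive enough to build once per session and reuse.

.fixture_env <- new.env(parent = emptyenv())

default_dataset <- function(seed = 2026) {
  key <- paste0("data_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- synth_dataset(design_effects(), seed = seed)
  .fixture_env[[key]]
}

preprocessed_raman_nonderiv <- function(seed = 2026) {
  key <- paste0("ppraman_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <-
      apply_recipe(default_dataset(seed)$raman, "raman_nonderiv")
  .fixture_env[[key]]
}

# small ad-hoc spectra_set on a short descending grid
tiny_set <- function(mat, grid = NULL, meta = NULL) {
  mat <- rbind(mat)
  if (is.null(grid)) grid <- seq(100 + 2 * ncol(mat), 102, by = -2)
  if (is.null(meta))
    meta <- data.frame(sample_id = sprintf("S%02d", seq_len(nrow(mat))))
  spectra_set(grid, mat, meta)
}

unit_lorentz <- function(x, center, fwhm) {
  (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
}

# Brute-force lower-convex-hull baseline oracle, independent of the
# implementation: a chord through points (i, j) supports the hull iff the
# full line through them lies on-or-below every data point; the baseline
# is the pointwise maximum over all supporting lines.
hull_oracle_baseline <- function(x, y, eps = 1e-9) {
  n <- length(x)
  support <- list()
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    s <- (y[js] - y[i]) / (x[js] - x[i])
    # lines[l, k]: value at x_l of the line through (i, js[k])
    lines <- y[i] + outer(x - x[i], s)
    ok <- colSums(lines > y + eps) == 0
    for (k in which(ok)) support[[length(support) + 1]] <- c(i, js[k])
  }
  base <- rep(-Inf, n)
  for (pr in support) {
    i <- pr[1]; j <- pr[2]
    s <- (y[j] - y[i]) / (x[j] - x[i])
    base <- pmax(base, y[i] + s * (x - x[i]))
  }
  base
}
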