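#' Principal component analysis of a spectral block
#'
#' PCA of the mean-centered spectral matrix via singular value
#' decomposition, with a deterministic sign convention: each loading's
#' largest-magnitude element is positive. Explained variances are
#' percentages of the total (centered) variance.
#'
#' @param set A [spectra_set()] (or plain matrix).
#' @param n_components Number of components to retain,
#'   `<= min(samples - 1, wavenumbers)`.
#' @return Object of class `spec_pca`: `mean`, `loadings` (components x
#'   wavenumbers), `scores` (samples x components), `explained_pct`,
#'   `grid`, `meta`.
#' @export
fit_pca <- function(set, n_components = 5) {
  X <- if (inherits(set, "spectra_set")) set$intensities else as.matrix(set)
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop(sprintf("n_components must be <= min(samples - 1, wavenumbers) = %d",
                 min(n - 1, p)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  load <- t(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)],
                          n_components, n_components)
  # sign convention: largest |loading| element positive
  for (a in seq_len(n_components)) {
    i <- which.max(abs(load[a, ]))
    if (load[a, i] < 0) {
      load[a, ] <- -load[a, ]
      scores[, a] <- -scores[, a]
    }
  }
  total <- sum(Xc^2)
  ev <- 100 * sv$d^2 / total
  structure(list(
    mean = ctr, loadings = load, scores = scores,
    explained_pct = ev[seq_len(n_components)],
    singular_values = sv$d,
    grid = if (inherits(set, "spectra_set")) set$grid else NULL,
    meta = if (inherits(set, "spectra_set")) set$meta else NULL),
    class = "spec_pca")
}

#' @export
print.spec_pca <- function(x, ...) {
  cat(sprintf("<spec_pca> %d components, %d samples x %d variables\n",
              ncol(x$scores), nrow(x$scores), ncol(x$loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.spec_pca <- function(x, components = c(1, 2), col = 1, ...) {
  graphics::plot(x$scores[, components[1]], x$scores[, components[2]],
                 col = col,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                x$explained_pct[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                x$explained_pct[components[2]]), ...)
  invisible(x)
}

#' Consensus (multiblock) PCA of row-aligned spectral blocks
#'
#' Each block is mean-centered and scaled to unit total sum of squares,
#' the scaled blocks are concatenated column-wise, and a PCA of the
#' super-matrix yields the global scores and loadings. Per block, the
#' global loading segment (renormalized to unit length) gives the block
#' loading, the scaled block times the block loading gives the block
#' scores, and the squared norm of the (unnormalized) loading segment
#' gives the block's contribution to that component.
#'
#' @param blocks Named list of [spectra_set()]s (typically after
#'   [average_technical_replicates()]) with identical sample ordering.
#' @param n_components Number of global components.
#' @return Object of class `spec_cpca`: `global_scores`,
#'   `explained_pct`, `block_loadings`, `block_scores`,
#'   `block_contrib_pct` (components x blocks), `block_weights`, `meta`.
#' @export
fit_cpca <- function(blocks, n_components = 5) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  ids <- lapply(blocks, function(b) b$meta$sample_id)
  for (k in seq_along(ids)[-1]) {
    mism <- which(ids[[k]] != ids[[1]])
    if (length(mism))
      stop(sprintf("blocks are row-misaligned: sample '%s' vs '%s' at row %d",
                   ids[[1]][mism[1]], ids[[k]][mism[1]], mism[1]))
  }
  centered <- lapply(blocks, function(b)
    sweep(b$intensities, 2, colMeans(b$intensities)))
  w <- vapply(centered, function(Xc) 1 / sqrt(sum(Xc^2)), 0)
  scaled <- Map(function(Xc, wk) Xc * wk, centered, w)
  super <- do.call(cbind, scaled)
  pca <- fit_pca(super, n_components)

  pcols <- vapply(scaled, ncol, 0L)
  offs <- cumsum(c(0, pcols))
  block_loadings <- list(); block_scores <- list()
  contrib <- matrix(0, n_components, length(blocks),
                    dimnames = list(paste0("PC", seq_len(n_components)),
                                    names(blocks)))
  for (k in seq_along(blocks)) {
    seg <- pca$loadings[, (offs[k] + 1):offs[k + 1], drop = FALSE]
    nrm <- sqrt(rowSums(seg^2))
    contrib[, k] <- nrm^2
    block_loadings[[names(blocks)[k]]] <- seg / nrm
    block_scores[[names(blocks)[k]]] <-
      scaled[[k]] %*% t(seg / nrm)
  }
  contrib <- 100 * contrib / rowSums(contrib)
  structure(list(
    global_scores = pca$scores, explained_pct = pca$explained_pct,
    global_loadings = pca$loadings,
    block_loadings = block_loadings, block_scores = block_scores,
    block_contrib_pct = contrib, block_weights = w,
    block_columns = pcols,
    meta = blocks[[1]]$meta),
    class = "spec_cpca")
}

#' @export
print.spec_cpca <- function(x, ...) {
  cat(sprintf("<spec_cpca> %d global components over %d blocks (%s)\n",
              length(x$explained_pct), length(x$block_loadings),
              paste(names(x$block_loadings), collapse = ", ")))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  cat("  block contributions (%, PC1):",
      paste(sprintf("%s %.1f", colnames(x$block_contrib_pct),
                    x$block_contrib_pct[1, ]), collapse = ", "), "\n")
  invisible(x)
}
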