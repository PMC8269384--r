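#' Technical-replicate reproducibility by Pearson correlation
#'
#' For each biological sample, computes all pairwise Pearson correlation
#' coefficients (PCC) between its technical-replicate spectra across the
#' wavenumber axis. The variability score is `1 - mean(PCC)`: near zero
#' for reproducible measurements, larger for noisy ones (2 at perfect
#' anticorrelation). Intended for preprocessed non-derivative data.
#'
#' Replicates with zero intensity variance have undefined PCC; the pairs
#' involving them are excluded from the mean with a warning and counted
#' in `n_undefined`.
#'
#' @param set A [spectra_set()] with at least 2 technical replicates per
#'   biological sample.
#' @return Data frame with one row per biological sample (`sample_id`,
#'   design columns when present, `n_pairs`, `n_undefined`, `mean_pcc`,
#'   `variability`), sorted by decreasing variability.
#' @export
replicate_pcc <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$meta$sample_id)
  keep <- intersect(c("strain", "pi_level", "ca_level", "bio_rep",
                      "heating", "laser_power_mw"), names(set$meta))
  res <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- which(set$meta$sample_id == ids[k])
    if (length(rows) < 2)
      stop("sample ", ids[k], " has fewer than 2 technical replicates")
    X <- set$intensities[rows, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    pcc <- c(); undef <- 0L
    for (i in seq_len(length(rows) - 1)) {
      for (j in (i + 1):length(rows)) {
        if (sds[i] == 0 || sds[j] == 0) {
          undef <- undef + 1L
        } else {
          pcc <- c(pcc, stats::cor(X[i, ], X[j, ]))
        }
      }
    }
    if (undef > 0)
      warning("sample ", ids[k], ": ", undef,
              " replicate pair(s) with zero variance excluded from PCC")
    row <- data.frame(sample_id = ids[k], stringsAsFactors = FALSE)
    for (cc in keep) row[[cc]] <- set$meta[[cc]][rows[1]]
    row$n_pairs <- length(pcc)
    row$n_undefined <- undef
    row$mean_pcc <- if (length(pcc)) mean(pcc) else NA_real_
    row$variability <- 1 - row$mean_pcc
    res[[k]] <- row
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$variability), ]
  rownames(out) <- NULL
  out
}
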