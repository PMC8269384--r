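#' ANOVA-model decomposition of a single-strain spectral matrix
#'
#' Represents the (grand-mean-centered) data matrix of one strain's
#' replicate-averaged spectra as a sum of design-factor effect matrices
#' plus residual: calcium availability (2 levels), phosphate
#' concentration (3 levels), their interaction (6 cells), and biological
#' replicate (2 levels). Each main-effect matrix replaces rows by the
#' level means of the centered data; the interaction matrix is the
#' Ca-Pi cell mean minus both main effects; the residual is the
#' remainder. Factor importance is the squared Frobenius norm (sum of
#' squares) of its effect matrix; for the balanced 3 x 2 x 2 design the
#' effect matrices are mutually orthogonal and the sums of squares are
#' additive. This is the decomposition underlying ANOVA-PCA and ASCA.
#'
#' @param set A [spectra_set()] of one strain, technical replicates
#'   averaged: 12 rows (3 Pi x 2 Ca x 2 bioreplicates).
#' @param check_balance Error on unbalanced designs (default TRUE):
#'   additivity of the decomposition silently fails otherwise.
#' @return Object of class `variation_decomp` with `effects` (named list
#'   of effect matrices incl. `residual`), `ss` (named sums of squares),
#'   `grand_mean`, `strain`, `meta`.
#' @export
decompose_by_design <- function(set, check_balance = TRUE) {
  stopifnot(inherits(set, "spectra_set"))
  meta <- set$meta
  need <- c("pi_level", "ca_level", "bio_rep")
  if (!all(need %in% names(meta)))
    stop("metadata must contain pi_level, ca_level and bio_rep")
  if (!is.null(meta$strain) && length(unique(meta$strain)) != 1)
    stop("decompose_by_design expects a single strain; got: ",
         paste(unique(meta$strain), collapse = ", "))
  cell <- interaction(meta$pi_level, meta$ca_level, meta$bio_rep,
                      drop = TRUE)
  if (check_balance) {
    tab <- table(meta$pi_level, meta$ca_level, meta$bio_rep)
    if (length(tab) != 12 || length(unique(as.vector(tab))) != 1 ||
        any(tab == 0))
      stop("unbalanced design: need equal counts in all ",
           "3 Pi x 2 Ca x 2 bio_rep cells")
  }
  X <- set$intensities
  grand <- colMeans(X)
  Xc <- sweep(X, 2, grand)

  level_means <- function(f) {
    f <- as.factor(f)
    M <- rowsum(Xc, f) / as.vector(table(f))
    M[as.character(f), , drop = FALSE]
  }
  eff_ca <- level_means(meta$ca_level)
  eff_pi <- level_means(meta$pi_level)
  cellmean <- level_means(interaction(meta$pi_level, meta$ca_level))
  eff_int <- cellmean - eff_ca - eff_pi
  eff_bio <- level_means(meta$bio_rep)
  resid <- Xc - eff_ca - eff_pi - eff_int - eff_bio

  effects <- list(ca = eff_ca, pi = eff_pi, ca_pi = eff_int,
                  bio_rep = eff_bio, residual = resid)
  ss <- vapply(effects, function(M) sum(M^2), 0)
  ss <- c(ss, total = sum(Xc^2))
  structure(list(effects = effects, ss = ss, grand_mean = grand,
                 strain = if (!is.null(meta$strain)) meta$strain[1] else NA,
                 meta = meta),
            class = "variation_decomp")
}

#' Factor contribution percentages of a decomposition
#'
#' Normalizes each design factor's sum of squares by the total over the
#' four design factors (Ca, Pi, Ca-Pi interaction, bioreplicate), so the
#' four contributions sum to 100\%. The residual is reported separately
#' as its share of the total centered sum of squares.
#'
#' @param decomp A [decompose_by_design()] result.
#' @return Data frame with columns `ca`, `pi`, `ca_pi`, `bio_rep`
#'   (summing to 100) and `residual_pct_of_total`.
#' @export
variation_contributions <- function(decomp) {
  stopifnot(inherits(decomp, "variation_decomp"))
  f <- decomp$ss[c("ca", "pi", "ca_pi", "bio_rep")]
  if (sum(f) == 0)
    stop("all design-factor sums of squares are zero; ",
         "contributions are undefined")
  out <- as.data.frame(as.list(100 * f / sum(f)))
  out$residual_pct_of_total <-
    100 * decomp$ss["residual"] / decomp$ss["total"]
  rownames(out) <- NULL
  out
}

#' @export
print.variation_decomp <- function(x, ...) {
  cat(sprintf("<variation_decomp> strain %s, %d spectra x %d wavenumbers\n",
              x$strain, nrow(x$effects$residual),
              ncol(x$effects$residual)))
  vc <- variation_contributions(x)
  cat(sprintf("  Ca %.1f%%, Pi %.1f%%, Ca-Pi %.1f%%, bio_rep %.1f%% ",
              vc$ca, vc$pi, vc$ca_pi, vc$bio_rep))
  cat(sprintf("(residual %.1f%% of total)\n", vc$residual_pct_of_total))
  invisible(x)
}

#' Per-strain, per-block design-factor contributions
#'
#' Runs [decompose_by_design()] for every strain in each preprocessed,
#' replicate-averaged block and assembles the factor-contribution table
#' (four normalized design-factor shares plus the residual share of
#' total).
#'
#' @param ... Named [spectra_set()]s, e.g. `raman = ..., ftir = ...`,
#'   each replicate-averaged.
#' @return Data frame with columns `strain`, `block`, `ca`, `pi`,
#'   `ca_pi`, `bio_rep`, `residual_pct_of_total`.
#' @export
decompose_all_strains <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && is.list(blocks[[1]]) &&
      !inherits(blocks[[1]], "spectra_set"))
    blocks <- blocks[[1]]
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("blocks must be named, e.g. raman = ..., ftir = ...")
  rows <- list()
  for (b in names(blocks)) {
    set <- blocks[[b]]
    strains <- unique(set$meta$strain)
    for (s in strains) {
      sub <- subset_spectra(set, set$meta$strain == s)
      vc <- variation_contributions(decompose_by_design(sub))
      rows[[length(rows) + 1]] <-
        cbind(data.frame(strain = s, block = b,
                         stringsAsFactors = FALSE), vc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
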