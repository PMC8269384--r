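#' Default wavenumber grids of the two instrument blocks
#'
#' Descending grids at the instruments' digital spacing of 1.928 cm^-1:
#' 3785-50 cm^-1 for FT-Raman, 4000-400 cm^-1 for FTIR.
#'
#' @param block `"raman"` or `"ftir"`.
#' @param step Digital spacing (cm^-1).
#' @return Descending numeric wavenumber vector.
#' @export
default_grid <- function(block, step = 1.928) {
  block <- match.arg(block, c("raman", "ftir"))
  rng <- if (block == "raman") c(3785, 50) else c(4000, 400)
  seq(rng[1], rng[2], by = -step)
}

# independent substream seeds so each randomness source can be zeroed in
# tests without displacing the others
substream_seed <- function(seed, k) (seed * 7L + k * 1000003L) %% 2147483629L

#' Generate the full synthetic two-block spectral dataset
#'
#' Simulates the factorial cultivation experiment: for every biological
#' sample, component concentrations are the design-cell means
#' ([expected_concentrations()]) times log-normal bioreplicate jitter;
#' each of the three technical-replicate spectra per block is then
#'
#' `gain * sum_c response_c * conc_c * pure_c  + polynomial drift
#'  + heating baseline (flagged samples, Raman only) + white noise`
#'
#' with the pure-component profiles built from [make_band_catalog()].
#' Both blocks share the same concentration draws, so the FT-Raman and
#' FTIR matrices describe the same biological material. The chemistry
#' table carries the true per-sample values of total lipids (\% DW),
#' total phosphorus (\% DW) and total carotenoids (ug/g DW).
#'
#' @param effects A [design_effects()] object.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param strains Subset of strains to simulate (default all six).
#' @param blocks Which blocks to generate.
#' @param tech_reps Technical replicates per sample (default 3).
#' @param step Digital grid spacing (cm^-1).
#' @return A list with elements `raman` and/or `ftir` (each a
#'   [spectra_set()] of `12 * nstrains * tech_reps` spectra carrying the
#'   chemistry table) and `chemistry` (the 72-row ground-truth table for
#'   the full design). Pure profiles and responses are attached as
#'   attribute `"generator"` for consistency checks.
#' @export
synth_dataset <- function(effects = design_effects(), seed = 1,
                          strains = c("Ar", "Mc1", "Mc2", "Mr", "Rs", "Uv"),
                          blocks = c("raman", "ftir"),
                          tech_reps = 3, step = 1.928) {
  stopifnot(inherits(effects, "design_effects"))
  blocks <- match.arg(blocks, c("raman", "ftir"), several.ok = TRUE)
  design <- design_table(strains)
  n_bio <- nrow(design)
  cellmeans <- expected_concentrations(effects, design)
  comps <- colnames(cellmeans)

  # --- substream 1: bioreplicate concentration jitter -------------------
  set.seed(substream_seed(seed, 1L))
  conc <- cellmeans
  for (cc in comps) {
    sdlog <- effects$jitter[[cc]] %||% 0
    if (cc == "carotenoid") {
      mult <- cellmeans[, "carotenoid"] /
        effects$carot_base[design$strain]
      sdlog <- effects$jitter$carotenoid +
        effects$jitter$carotenoid_stress_slope * log(pmax(mult, 1))
    }
    conc[, cc] <- cellmeans[, cc] * exp(stats::rnorm(n_bio, 0, sdlog))
  }

  chemistry <- data.frame(
    sample_id = design$sample_id,
    strain = design$strain, pi_level = design$pi_level,
    ca_level = design$ca_level, bio_rep = design$bio_rep,
    lipid_pct_dw = unname(conc[, "lipid"]),
    phosphorus_pct_dw = unname(conc[, "polyphosphate"]),
    carotenoid_ug_per_g = unname(conc[, "carotenoid"]),
    stringsAsFactors = FALSE)

  n_spec <- n_bio * tech_reps
  rep_of <- rep(seq_len(n_bio), each = tech_reps)

  # --- substreams 2-5: gain, drift, heating, noise ----------------------
  set.seed(substream_seed(seed, 2L))
  gains <- matrix(exp(stats::rnorm(n_spec * length(blocks), 0,
                                   effects$gain_sdlog)),
                  n_spec, length(blocks), dimnames = list(NULL, blocks))
  set.seed(substream_seed(seed, 3L))
  drift_coef <- array(stats::rnorm(n_spec * 4 * length(blocks), 0,
                                   effects$drift_sd),
                      dim = c(n_spec, 4, length(blocks)),
                      dimnames = list(NULL, NULL, blocks))
  set.seed(substream_seed(seed, 4L))
  heat_jit <- matrix(exp(stats::rnorm(n_spec, 0, 0.3)), n_spec, 1)
  noise_seed <- substream_seed(seed, 5L)

  generator <- list(profiles = list(), responses = effects$response,
                    concentrations = conc)
  out <- list()
  for (b in blocks) {
    grid <- default_grid(b, step)
    p <- length(grid)
    catalog <- make_band_catalog(b)
    pure <- component_profile_matrix(catalog, grid)  # comps x p
    resp <- effects$response[[b]][rownames(pure)]
    signal_bio <- conc[, rownames(pure), drop = FALSE] %*% (pure * resp)

    u <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
    drift_basis <- cbind(1, u, u^2, u^3)        # p x 4
    heat_prof <- if (b == "raman")
      exp(-(grid - effects$heating_center)^2 /
            (2 * effects$heating_sigma^2)) else numeric(p)

    set.seed(noise_seed + match(b, c("raman", "ftir")))
    mat <- matrix(0, n_spec, p)
    # heating raises the noise floor of the Raman measurement only
    noise_mult <- if (b == "raman")
      ifelse(design$heating[rep_of], effects$heating_noise_factor, 1)
    else rep(1, n_spec)
    heat_amp <- ifelse(design$heating[rep_of],
                       effects$heating_amplitude *
                         ifelse(design$laser_power_mw[rep_of] == 200,
                                effects$heating_power_factor, 1), 0)
    for (i in seq_len(n_spec)) {
      s <- gains[i, b] * signal_bio[rep_of[i], ] +
        drop(drift_basis %*% drift_coef[i, , b])
      if (b == "raman" && heat_amp[i] > 0)
        s <- s + heat_amp[i] * heat_jit[i, 1] * heat_prof
      s <- s + stats::rnorm(p, 0, effects$noise_sd * noise_mult[i])
      mat[i, ] <- s
    }

    meta <- design[rep_of, c("sample_id", "strain", "pi_level", "ca_level",
                             "bio_rep", "heating", "laser_power_mw")]
    meta$tech_rep <- rep(seq_len(tech_reps), times = n_bio)
    meta$block <- b
    rownames(meta) <- NULL
    out[[b]] <- spectra_set(grid, mat, meta, chemistry)
    generator$profiles[[b]] <- pure
  }
  out$chemistry <- chemistry
  attr(out, "generator") <- generator
  out
}
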