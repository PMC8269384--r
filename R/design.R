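#' Default cultivation-design effects for the synthetic generator
#'
#' Encodes how the factorial cultivation design (6 Mucoromycota strains x
#' 3 phosphate levels x 2 calcium conditions x 2 biological replicates)
#' drives the concentrations of the six spectral components, plus the
#' instrument noise model. Defaults are anchored to the published
#' composition ranges of these strains: per-strain total-lipid and
#' total-phosphorus ranges (\% of dry weight), a roughly tenfold
#' stress-induced carotenoid increase in *Mucor circinelloides* FRR 5020
#' (Mc2) under low phosphate without calcium, calcium-dependent chitin
#' synthesis, and calcium-dependent polyphosphate storage.
#'
#' Laser-heating artifacts are restricted to the ten samples measured at
#' reduced laser power: *Rhizopus stolonifer* (Rs) under moderate and high
#' phosphate (both calcium conditions, both bioreplicates) and
#' *Amylomyces rouxii* (Ar) under high phosphate with calcium.
#'
#' @param noise_sd White-noise standard deviation (a.u.).
#' @param gain_sdlog Log-sd of the per-spectrum multiplicative scatter gain.
#' @param drift_sd Scale of random polynomial (degree 3) baseline drift
#'   coefficients (a.u.).
#' @param heating_amplitude Peak amplitude (a.u.) of the heating emission
#'   baseline at 500 mW; scaled by `heating_power_factor` at 200 mW.
#' @param heating_power_factor Multiplier applied to the heating amplitude
#'   for samples measured at reduced (200 mW) laser power.
#' @param heating_noise_factor Multiplier on `noise_sd` for heating-flagged
#'   samples (thermal emission raises the noise floor).
#' @param heating_center,heating_sigma Center (cm^-1, below the recorded
#'   range) and width of the Gaussian emission profile.
#' @param jitter Named list of per-bioreplicate log-sd values for component
#'   concentrations. For carotenoids the log-sd grows with the strength of
#'   stress induction, `carotenoid + carotenoid_stress_slope * log(mult)`
#'   where `mult` is the design-cell induction multiplier: strongly induced
#'   pigment production is proportionally the most variable between
#'   independent cultivations.
#' @return A list of class `design_effects`.
#' @export
design_effects <- function(noise_sd = 0.004,
                           gain_sdlog = 0.12,
                           drift_sd = 0.02,
                           heating_amplitude = 2.0,
                           heating_power_factor = 0.4,
                           heating_noise_factor = 3,
                           heating_center = -300,
                           heating_sigma = 700,
                           jitter = list(lipid = 0.05,
                                         polyphosphate = 0.08,
                                         carotenoid = 0.3,
                                         carotenoid_stress_slope = 0.215,
                                         chitin = 0.10,
                                         chitosan_glucan = 0.08,
                                         protein = 0.06)) {
  if (noise_sd < 0 || gain_sdlog < 0 || drift_sd < 0)
    stop("noise scales must be non-negative")

  strains <- c("Ar", "Mc1", "Mc2", "Mr", "Rs", "Uv")

  # printed per-strain composition ranges (% of dry weight)
  lipid_range <- rbind(Ar = c(27, 49), Mc1 = c(20, 49), Mc2 = c(34, 52),
                       Mr = c(19, 41), Rs = c(22, 28), Uv = c(49, 83))
  phos_range <- rbind(Ar = c(2.65, 6.24), Mc1 = c(1.40, 4.91),
                      Mc2 = c(1.86, 4.50), Mr = c(2.28, 5.20),
                      Rs = c(2.70, 4.13), Uv = c(0.64, 1.37))

  # carotenoid production (ug/g DW) at the reference condition, and the
  # stress response magnitude (low phosphate / calcium starvation)
  carot_base <- c(Ar = 190, Mc1 = 60, Mc2 = 140, Mr = 20, Rs = 50, Uv = 5)
  carot_stress <- c(Ar = 2, Mc1 = 3, Mc2 = 9.4, Mr = 0, Rs = 0, Uv = 0)
  # stress weight by (pi, ca): the induction is concentrated in the
  # low-phosphate, calcium-free cell, with near-baseline production in
  # the other conditions
  stress_w <- matrix(c(1, 0.10,
                       0.12, 0,
                       0.08, 0), nrow = 3, byrow = TRUE,
                     dimnames = list(c("0.5", "1", "4"), c("0", "1")))

  # cell-wall chitin: acid-stress overproduction at low phosphate;
  # suppressed without calcium (chitin synthase is calcium dependent)
  chitin_base <- c(Ar = 22, Mc1 = 25, Mc2 = 18, Mr = 20, Rs = 20, Uv = 10)
  chitin_pi <- c("0.5" = 1.45, "1" = 1, "4" = 0.9)
  chitin_ca0 <- c("0.5" = 0.60, "1" = 0.70, "4" = 0.70)

  # polyphosphate storage scales with phosphate supply and needs calcium
  phos_ca0 <- c("0.5" = 0.85, "1" = 0.72, "4" = 0.62)

  other_base <- c(chitosan_glucan = 20, protein = 15)

  # spectral response per concentration unit, by block; carotenoids are
  # resonance-enhanced in Raman and absent in FTIR
  response <- list(
    raman = c(lipid = 1 / 50, chitin = 1 / 50, chitosan_glucan = 1 / 50,
              protein = 1 / 50, polyphosphate = 0.02, carotenoid = 7e-4),
    ftir = c(lipid = 1 / 50, chitin = 1 / 50, chitosan_glucan = 1 / 50,
             protein = 1 / 50, polyphosphate = 0.15, carotenoid = 0))

  structure(list(
    strains = strains,
    lipid_range = lipid_range, phos_range = phos_range,
    carot_base = carot_base, carot_stress = carot_stress,
    stress_w = stress_w,
    chitin_base = chitin_base, chitin_pi = chitin_pi,
    chitin_ca0 = chitin_ca0, phos_ca0 = phos_ca0,
    other_base = other_base, response = response,
    jitter = jitter, noise_sd = noise_sd, gain_sdlog = gain_sdlog,
    drift_sd = drift_sd,
    heating_amplitude = heating_amplitude,
    heating_power_factor = heating_power_factor,
    heating_noise_factor = heating_noise_factor,
    heating_center = heating_center, heating_sigma = heating_sigma),
    class = "design_effects")
}

#' The factorial design table of biological samples
#'
#' @param strains Subset of strain labels (default all six).
#' @return Data frame with one row per biological sample (`sample_id`,
#'   `strain`, `pi_level`, `ca_level`, `bio_rep`, `laser_power_mw`,
#'   `heating`), 72 rows for the full design.
#' @export
design_table <- function(strains = c("Ar", "Mc1", "Mc2", "Mr", "Rs", "Uv")) {
  d <- expand.grid(bio_rep = 1:2, ca_level = c(0, 1),
                   pi_level = c(0.5, 1, 4), strain = strains,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("strain", "pi_level", "ca_level", "bio_rep")]
  d$heating <- (d$strain == "Rs" & d$pi_level %in% c(1, 4)) |
    (d$strain == "Ar" & d$pi_level == 4 & d$ca_level == 1)
  d$laser_power_mw <- ifelse(d$heating, 200, 500)
  d$sample_id <- sprintf("%s_Pi%s_Ca%d_B%d", d$strain,
                         as.character(d$pi_level), d$ca_level, d$bio_rep)
  rownames(d) <- NULL
  d[, c("sample_id", "strain", "pi_level", "ca_level", "bio_rep",
        "heating", "laser_power_mw")]
}

#' Deterministic (jitter-free) expected concentrations per design cell
#'
#' Returns the design-cell mean concentration of each component before
#' bioreplicate jitter is applied — the systematic part of the generative
#' model. Used both by the generator and to state the design's qualitative
#' effects (e.g. the Mc2 carotenoid stress response).
#'
#' @param effects A [design_effects()] object.
#' @param design A [design_table()] (or subset).
#' @return Matrix (samples x components) of expected concentrations, on
#'   chemistry units for lipid (\% DW), polyphosphate (\% DW as total
#'   phosphorus) and carotenoid (ug/g DW).
#' @export
expected_concentrations <- function(effects, design = design_table()) {
  n <- nrow(design)
  comps <- c("lipid", "chitin", "chitosan_glucan", "protein",
             "polyphosphate", "carotenoid")
  out <- matrix(0, n, length(comps), dimnames = list(design$sample_id, comps))
  pi_chr <- as.character(design$pi_level)
  ca_chr <- as.character(design$ca_level)
  for (i in seq_len(n)) {
    s <- design$strain[i]
    lr <- effects$lipid_range[s, ]
    lbase <- sqrt(lr[1] * lr[2])
    lmult <- switch(pi_chr[i],
                    "0.5" = (lr[2] / lbase)^0.9,
                    "1" = 1,
                    "4" = (lr[1] / lbase)^0.9)
    out[i, "lipid"] <- lbase * lmult

    pr <- effects$phos_range[s, ]
    pbase <- sqrt(pr[1] * pr[2])
    pmult <- switch(pi_chr[i],
                    "0.5" = (pr[1] / pbase)^0.9,
                    "1" = 1,
                    "4" = (pr[2] / pbase)^0.9)
    camult <- if (design$ca_level[i] == 0) effects$phos_ca0[pi_chr[i]] else 1
    out[i, "polyphosphate"] <- pbase * pmult * camult

    w <- effects$stress_w[pi_chr[i], ca_chr[i]]
    out[i, "carotenoid"] <- effects$carot_base[s] *
      (1 + effects$carot_stress[s] * w)

    cmult <- effects$chitin_pi[pi_chr[i]]
    if (s == "Uv") cmult <- 1   # no significant chitin response
    ccamult <- if (design$ca_level[i] == 0) effects$chitin_ca0[pi_chr[i]] else 1
    out[i, "chitin"] <- effects$chitin_base[s] * cmult * ccamult

    out[i, "chitosan_glucan"] <- effects$other_base["chitosan_glucan"] *
      (if (pi_chr[i] == "0.5") 1.1 else 1)
    out[i, "protein"] <- effects$other_base["protein"]
  }
  stopifnot(all(out >= 0))
  out
}
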