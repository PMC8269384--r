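test_that("band catalogs carry the expected marker bands per block", {
  ram <- make_band_catalog("raman")
  car <- ram[ram$component == "carotenoid", ]
  expect_setequal(car$center, c(1525, 1155, 1005))
  pp <- ram[ram$component == "polyphosphate", ]
  expect_setequal(pp$center, c(1165, 685))
  # lipid C-H stretch region holds the tallest lipid band
  lip <- ram[ram$component == "lipid", ]
  expect_gte(lip$center[which.max(lip$height)], 2800)

  ftir <- make_band_catalog("ftir")
  expect_equal(sum(ftir$component == "carotenoid"), 0L)
  expect_setequal(ftir$center[ftir$component == "polyphosphate"],
                  c(1263, 885))
  expect_error(make_band_catalog("nir"))
})

test_that("component profiles are non-negative, linear, peak where expected", {
  grid <- default_grid("raman")
  cat <- make_band_catalog("raman")
  prof <- synth_component_spectrum(cat, "carotenoid", grid)
  expect_gte(min(prof$pure_spectrum), 0)
  expect_equal(grid[which.max(prof$pure_spectrum)],
               grid[which.min(abs(grid - 1525))])

  cat2 <- cat
  cat2$height <- 2 * cat2$height
  prof2 <- synth_component_spectrum(cat2, "carotenoid", grid)
  expect_equal(prof2$pure_spectrum, 2 * prof$pure_spectrum)

  expect_error(synth_component_spectrum(cat, "melanin", grid), "no bands")
})

test_that("the generator is deterministic and respects the design size", {
  d1 <- synth_dataset(design_effects(), seed = 99, strains = c("Ar", "Uv"),
                      blocks = "raman")
  d2 <- synth_dataset(design_effects(), seed = 99, strains = c("Ar", "Uv"),
                      blocks = "raman")
  expect_identical(d1$raman$intensities, d2$raman$intensities)
  expect_identical(d1$chemistry, d2$chemistry)

  d <- default_dataset()
  expect_equal(n_spectra(d$raman), 216L)
  expect_equal(n_spectra(d$ftir), 216L)
  expect_equal(nrow(d$chemistry), 72L)
  # the raman block is unchanged by also generating ftir
  dr <- synth_dataset(design_effects(), seed = 2026, blocks = "raman")
  expect_identical(dr$raman$intensities, d$raman$intensities)
})

test_that("zero-noise single-component spectra are proportional to the profile", {
  eff <- design_effects(noise_sd = 0, gain_sdlog = 0, drift_sd = 0,
                        heating_amplitude = 0)
  # suppress all but lipids by zeroing the other responses
  eff$response$raman[c("chitin", "chitosan_glucan", "protein",
                       "polyphosphate", "carotenoid")] <- 0
  d <- synth_dataset(eff, seed = 3, strains = "Uv", blocks = "raman")
  pure <- attr(d, "generator")$profiles$raman["lipid", ]
  for (i in seq_len(n_spectra(d$raman))) {
    y <- d$raman$intensities[i, ]
    a <- sum(y * pure) / sum(pure^2)
    expect_lt(max(abs(y - a * pure)), 1e-10)
  }
})

test_that("noiseless spectra regress back to the true concentrations", {
  eff <- design_effects(noise_sd = 0, gain_sdlog = 0, drift_sd = 0,
                        heating_amplitude = 0)
  d <- synth_dataset(eff, seed = 17, blocks = c("raman", "ftir"))
  gen <- attr(d, "generator")
  for (b in c("raman", "ftir")) {
    pure <- gen$profiles[[b]]
    resp <- gen$responses[[b]][rownames(pure)]
    keep <- resp > 0
    X <- t(pure[keep, , drop = FALSE] * resp[keep])
    rec <- t(qr.coef(qr(X), t(d[[b]]$intensities)))
    true <- gen$concentrations[d[[b]]$meta$sample_id, rownames(pure)[keep]]
    expect_lt(max(abs(rec - true)), 1e-8)
  }
})

test_that("design effects reproduce the published composition patterns", {
  d <- default_dataset()
  chem <- d$chemistry
  # Umbelopsis vinacea is by far the most oleaginous strain
  mlip <- tapply(chem$lipid_pct_dw, chem$strain, mean)
  expect_equal(names(which.max(mlip)), "Uv")
  expect_true(all(mlip["Uv"] > mlip[names(mlip) != "Uv"]))
  # and accumulates the least phosphorus
  mphos <- tapply(chem$phosphorus_pct_dw, chem$strain, mean)
  expect_equal(names(which.min(mphos)), "Uv")

  # deterministic cell means: Mc2 carotenoid stress response is ~tenfold
  cm <- expected_concentrations(design_effects())
  dt <- design_table()
  hi <- cm[dt$strain == "Mc2" & dt$pi_level == 0.5 & dt$ca_level == 0,
           "carotenoid"][1]
  ref <- cm[dt$strain == "Mc2" & dt$pi_level == 1 & dt$ca_level == 1,
            "carotenoid"][1]
  expect_gte(hi / ref, 8)

  # chitin is suppressed without calcium at every phosphate level
  for (p in c(0.5, 1, 4)) {
    ca0 <- cm[dt$strain == "Mc1" & dt$pi_level == p & dt$ca_level == 0,
              "chitin"][1]
    ca1 <- cm[dt$strain == "Mc1" & dt$pi_level == p & dt$ca_level == 1,
              "chitin"][1]
    expect_lt(ca0, ca1)
  }

  # polyphosphate storage drops without calcium
  p0 <- tapply(chem$phosphorus_pct_dw[chem$ca_level == 0],
               chem$strain[chem$ca_level == 0], mean)
  p1 <- tapply(chem$phosphorus_pct_dw[chem$ca_level == 1],
               chem$strain[chem$ca_level == 1], mean)
  expect_true(all(p0 < p1))
})

test_that("heating-flagged cells have excess low-frequency baseline energy", {
  d <- default_dataset()
  raw <- d$raman
  # spatial-frequency power below 1/200 cycles per cm^-1, via FFT
  h <- abs(median(diff(raw$grid)))
  n <- length(raw$grid)
  freq <- (seq_len(n) - 1) / (n * h)          # cycles per cm^-1
  low <- freq > 0 & freq < 1 / 200
  lowpower <- apply(raw$intensities, 1, function(y) {
    sp <- Mod(stats::fft(y - mean(y)))^2 / n
    sum(sp[low])
  })
  flagged <- raw$meta$heating
  expect_equal(sum(flagged) / 3, 10)   # ten flagged biological samples
  # compare within strain: composition differences between strains also
  # carry low-frequency power, so the clean control is the same strain's
  # unflagged cultivation cells
  for (s in c("Rs", "Ar")) {
    in_strain <- raw$meta$strain == s
    pw <- tapply(lowpower[in_strain], raw$meta$sample_id[in_strain], mean)
    fl <- tapply(flagged[in_strain], raw$meta$sample_id[in_strain], any)
    expect_gt(min(pw[fl]), max(pw[!fl]))
  }
})

test_that("generator rejects invalid noise scales", {
  expect_error(design_effects(noise_sd = -1), "non-negative")
})
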