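test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  g <- seq(300, 100, by = -1.928)
  quad <- 0.01 * g^2 - 2 * g + 5
  s <- tiny_set(rbind(quad), grid = g)

  sm <- savgol(s, 2, 15, 0)
  expect_lt(max(abs(sm$intensities - quad)), 1e-8)

  d2 <- savgol(tiny_set(rbind(3 * g^2), grid = g), 2, 15, 2)
  expect_lt(max(abs(d2$intensities - 6)), 1e-8)   # everywhere, incl. edges

  expect_error(savgol(s, 2, 14, 0), "odd")
  expect_error(savgol(s, 2, 15, 3), "derivative_order")
  expect_error(savgol(tiny_set(rbind(1:5), grid = c(10, 8, 6, 4, 2)),
                      2, 15, 0), "grid")
})

test_that("Savitzky-Golay equals a brute-force moving least-squares fit", {
  set.seed(42)
  g <- seq(260, 140, by = -1.928)
  y <- runif(length(g))
  sm <- savgol(tiny_set(rbind(y), grid = g), 2, 15, 0)
  # independent oracle: quadratic fit over each centered window,
  # evaluated at the window midpoint (interior points)
  half <- 7
  for (i in seq(half + 1, length(g) - half, by = 9)) {
    idx <- (i - half):(i + half)
    cf <- coef(lm(yy ~ xx + I(xx^2),
                  data.frame(yy = y[idx], xx = g[idx])))
    expect_equal(unname(cf[1] + cf[2] * g[i] + cf[3] * g[i]^2),
                 sm$intensities[1, i], tolerance = 1e-8)
  }
})

test_that("rubber-band correction removes the lower convex hull", {
  g <- seq(200, 100, by = -2)
  # straight line is its own hull
  line <- tiny_set(rbind(0.3 * g + 7), grid = g)
  expect_lt(max(abs(rubberband_baseline(line)$intensities)), 1e-12)

  # convex bowl equals its hull
  bowl <- tiny_set(rbind(0.01 * (g - 150)^2), grid = g)
  expect_lt(max(abs(rubberband_baseline(bowl)$intensities)), 1e-12)

  # Lorentzian on a slope: correction = peak minus its endpoint chord
  peak <- unit_lorentz(g, 150, 12)
  slope <- 0.05 * g + 1
  corr <- rubberband_baseline(tiny_set(rbind(peak + slope), grid = g))
  expect_equal(corr$intensities[1, 1], 0)
  expect_equal(corr$intensities[1, length(g)], 0)
  # the peak is narrow: hull endpoints give a chord through the two ends
  x1 <- g[length(g)]; x2 <- g[1]
  chord <- peak[length(g)] + (peak[1] - peak[length(g)]) *
    (g - x1) / (x2 - x1)
  expect_lt(max(abs(corr$intensities[1, ] - (peak - chord))), 1e-10)

  expect_error(rubberband_baseline(tiny_set(rbind(1:2), grid = c(4, 2))),
               "3 grid points")
})

test_that("rubber-band baseline agrees with an exhaustive chord oracle", {
  set.seed(7)
  for (rep in 1:8) {
    n <- 120
    x <- sort(runif(n, 0, 100))
    y <- cumsum(rnorm(n))
    s <- spectra_set(rev(x), rbind(rev(y)), data.frame(sample_id = "r"))
    corr <- rev(rubberband_baseline(s)$intensities[1, ])
    base_oracle <- hull_oracle_baseline(x, y)
    expect_lt(max(abs((y - corr) - base_oracle)), 1e-8)
    expect_gte(min(corr), -1e-10)
    expect_equal(corr[1], 0)
    expect_equal(corr[n], 0)
  }
  # idempotence
  set.seed(8)
  x <- seq(100, 2, by = -2)
  y <- rbind(runif(50) + 0.1 * x)
  s <- spectra_set(x, y, data.frame(sample_id = "i"))
  once <- rubberband_baseline(s)
  twice <- rubberband_baseline(once)
  expect_lt(max(abs(once$intensities - twice$intensities)), 1e-10)
})

test_that("truncation keeps exactly the requested closed regions", {
  d <- default_dataset()
  tr <- truncate_regions(d$raman, list(c(2400, 3200), c(500, 1900)))
  expect_false(any(tr$grid > 1900 & tr$grid < 2400))
  expect_true(all((tr$grid >= 2400 & tr$grid <= 3200) |
                    (tr$grid >= 500 & tr$grid <= 1900)))
  expect_true(all(diff(tr$grid) < 0))

  tr2 <- truncate_regions(d$raman, list(c(900, 1800)))
  expect_lte(max(tr2$grid), 1800)
  expect_gte(min(tr2$grid), 900)

  full <- truncate_regions(d$raman, list(range(d$raman$grid)))
  expect_identical(full$intensities, d$raman$intensities)

  expect_error(truncate_regions(d$raman, list(c(1, 2))), "every wavenumber")
  expect_error(truncate_regions(d$raman, list(c(500, 1900), c(1800, 2400))),
               "overlap")
})

test_that("EMSC recovers the reference from scatter/baseline models", {
  g <- seq(1900, 500, by = -1.928)
  u <- 2 * (g - min(g)) / diff(range(g)) - 1
  m <- unit_lorentz(g, 1445, 16) + 0.6 * unit_lorentz(g, 1080, 20)

  for (a in c(0.5, 2)) {
    s <- a * m + 0.5 + 0.2 * u + 0.1 * u^2 + 0.05 * u^3
    st <- spectra_set(g, rbind(s, m), data.frame(sample_id = c("x", "ref")))
    out <- emsc(st, reference = m, poly_degree = 3)
    expect_lt(max(abs(out$intensities[1, ] - m)), 1e-10)
    cf <- attr(out, "emsc_coefficients")
    expect_equal(unname(cf[1, "a"]), a, tolerance = 1e-8)
  }

  # identity: s = m gives a = 1, all polynomial terms 0
  st <- spectra_set(g, rbind(m), data.frame(sample_id = "m"))
  out <- emsc(st, reference = m, poly_degree = 3)
  cf <- attr(out, "emsc_coefficients")
  expect_equal(unname(cf[1, "a"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(cf[1, -1])), 1e-10)
  expect_lt(max(abs(out$intensities[1, ] - m)), 1e-10)

  # random spectrum vs an independent normal-equations solve
  set.seed(3)
  s <- runif(length(g))
  st <- spectra_set(g, rbind(s), data.frame(sample_id = "r"))
  out <- emsc(st, reference = m, poly_degree = 3)
  D <- cbind(m, 1, u, u^2, u^3)
  beta <- solve(t(D) %*% D, t(D) %*% s)
  corr_oracle <- (s - D[, -1] %*% beta[-1]) / beta[1]
  expect_lt(max(abs(out$intensities[1, ] - drop(corr_oracle))), 1e-8)

  # multiplicative-rescaling invariance
  out2 <- emsc(spectra_set(g, rbind(37 * s), data.frame(sample_id = "r")),
               reference = m, poly_degree = 3)
  expect_lt(max(abs(out2$intensities - out$intensities)), 1e-10)

  # collinear reference errors
  st2 <- spectra_set(g, rbind(s), data.frame(sample_id = "r"))
  expect_error(emsc(st2, reference = 2 + 3 * u, poly_degree = 3),
               "singular")
})

test_that("recipes compose the documented steps on the expected grids", {
  d <- default_dataset()
  pr <- preprocessed_raman_nonderiv()
  expect_true(all((pr$grid >= 2400 & pr$grid <= 3200) |
                    (pr$grid >= 500 & pr$grid <= 1900)))

  fd <- apply_recipe(subset_spectra(d$ftir, d$ftir$meta$strain == "Uv"),
                     "ftir_deriv")
  expect_lte(max(fd$grid), 1800)
  expect_gte(min(fd$grid), 900)

  rd <- apply_recipe(subset_spectra(d$raman, d$raman$meta$strain == "Uv"),
                     "raman_deriv")
  expect_lte(max(rd$grid), 1800)

  # an empty recipe is the identity
  id <- structure(list(name = "identity", steps = list()),
                  class = "preprocess_recipe")
  expect_identical(apply_recipe(d$ftir, id), d$ftir)
})

test_that("preprocessing output is locked by a regression fixture", {
  # frozen values computed at a pinned seed guard the step order
  d <- synth_dataset(design_effects(), seed = 314, strains = "Mc1",
                     blocks = "raman")
  pp <- apply_recipe(d$raman, "raman_nonderiv")
  fingerprint <- c(mean(pp$intensities), sd(pp$intensities),
                   pp$intensities[1, 100], pp$intensities[36, 500])
  expect_equal(fingerprint,
               c(0.09718738392534469, 0.1570918677066515,
                 0.3522240872243674, 0.1135261443616405),
               tolerance = 1e-10)
})

test_that("technical replicates average to one row per biological sample", {
  g <- seq(20, 10, by = -2)
  mat <- rbind(c(0, 0, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 1),
               c(2, 2, 2, 2, 2, 2))
  meta <- data.frame(sample_id = "s1", strain = "Ar", tech_rep = 1:3)
  avg <- average_technical_replicates(spectra_set(g, mat, meta))
  expect_equal(n_spectra(avg), 1L)
  expect_equal(unname(avg$intensities[1, ]), rep(1, 6))
  expect_false("tech_rep" %in% names(avg$meta))

  # identical replicates: mean equals any one of them
  mat2 <- mat[c(2, 2, 2), ]
  avg2 <- average_technical_replicates(spectra_set(g, mat2, meta))
  expect_equal(unname(avg2$intensities[1, ]), rep(1, 6))

  d <- default_dataset()
  a <- average_technical_replicates(d$raman)
  expect_equal(n_spectra(a), 72L)

  bad <- spectra_set(g, mat, data.frame(sample_id = "s1",
                                        strain = c("Ar", "Ar", "Uv"),
                                        tech_rep = 1:3))
  expect_error(average_technical_replicates(bad), "inconsistent")
})
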