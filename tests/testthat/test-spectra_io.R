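test_that("wide CSV reading validates shape and values", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "s.csv")
  df <- data.frame(sample_id = c("a", "b", "c"),
                   matrix(runif(15), 3, 5))
  names(df)[2:6] <- c(110, 108, 106, 104, 102)
  write.csv(df, path, row.names = FALSE)
  set <- read_spectra_matrix(path)
  expect_identical(dim(set$intensities), c(3L, 5L))
  expect_equal(set$grid, c(110, 108, 106, 104, 102))

  df$`106`[2] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_error(read_spectra_matrix(path), "row 2")

  df$`106`[2] <- "oops"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_spectra_matrix(path), "non-numeric")

  df2 <- data.frame(sample_id = c("a", "b"), matrix(1, 2, 3))
  names(df2)[2:4] <- c(110, 108, 108)   # duplicated wavenumber column
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_spectra_matrix(path), "duplicate")
})

test_that("write -> read round-trips intensities, metadata and chemistry", {
  tmp <- withr::local_tempdir()
  d <- synth_dataset(design_effects(), seed = 5, strains = "Mc2",
                     blocks = "raman")
  path <- file.path(tmp, "raman.csv")
  write_spectra_matrix(d$raman, path)
  back <- read_spectra_matrix(path)
  expect_identical(back$grid, d$raman$grid)
  expect_lt(max(abs(back$intensities - d$raman$intensities)), 1e-12)
  expect_equal(back$meta$sample_id, d$raman$meta$sample_id)
  expect_equal(back$meta$strain, d$raman$meta$strain)
  expect_equal(back$meta$tech_rep, d$raman$meta$tech_rep)
  expect_equal(back$chemistry$lipid_pct_dw, d$raman$chemistry$lipid_pct_dw)
})

test_that("writing an empty set yields a header-only file", {
  tmp <- withr::local_tempdir()
  empty <- spectra_set(c(10, 8, 6), matrix(0, 0, 3),
                       data.frame(sample_id = character(0)))
  path <- file.path(tmp, "empty.csv")
  write_spectra_matrix(empty, path)
  expect_length(readLines(path), 1L)
  back <- read_spectra_matrix(path)
  expect_equal(n_spectra(back), 0L)
})

test_that("a full synthetic block writes 216 spectrum rows", {
  tmp <- withr::local_tempdir()
  d <- default_dataset()
  path <- file.path(tmp, "full.csv")
  write_spectra_matrix(d$raman, path)
  expect_length(readLines(path), 217L)   # header + 216
})

test_that("spectra_set enforces its invariants", {
  expect_error(spectra_set(c(3, 2, 1), matrix(1, 1, 2),
                           data.frame(sample_id = "a")), "columns")
  expect_error(spectra_set(c(3, 1, 2), matrix(1, 1, 3),
                           data.frame(sample_id = "a")), "monotone")
  expect_error(spectra_set(c(3, 2, 1), matrix(c(1, NA, 1), 1, 3),
                           data.frame(sample_id = "a")), "non-finite")
  # ascending input is normalized to descending with columns flipped
  s <- spectra_set(c(1, 2, 3), matrix(c(10, 20, 30), 1, 3),
                   data.frame(sample_id = "a"))
  expect_equal(s$grid, c(3, 2, 1))
  expect_equal(drop(s$intensities), c(30, 20, 10))
})

test_that("alignment interpolates onto the grid intersection", {
  # identical grids: stacked passthrough
  g <- seq(200, 100, by = -1.928)
  s1 <- list(wavenumbers = g, intensities = sin(g / 10),
             meta = list(sample_id = "a"))
  s2 <- list(wavenumbers = g, intensities = cos(g / 10),
             meta = list(sample_id = "b"))
  al <- align_to_common_grid(list(s1, s2))
  expect_equal(al$grid, g)
  expect_equal(al$intensities[1, ], unname(sin(g / 10)))

  # linear signals are interpolated exactly from a 2x finer grid
  gf <- seq(200, 100, by = -0.964)
  ramp <- list(wavenumbers = gf, intensities = 3 * gf + 2,
               meta = list(sample_id = "r"))
  al2 <- align_to_common_grid(list(ramp, s1))
  expect_equal(al2$intensities[1, ], 3 * al2$grid + 2, tolerance = 1e-12)

  # half-step offset grids vs an independent piecewise-linear oracle
  set.seed(1)
  ga <- seq(150, 120, by = -1.928)
  gb <- ga - 0.964
  ya <- runif(length(ga)); yb <- runif(length(gb))
  al3 <- align_to_common_grid(list(
    list(wavenumbers = ga, intensities = ya, meta = list(sample_id = "a")),
    list(wavenumbers = gb, intensities = yb, meta = list(sample_id = "b"))))
  oracle <- function(xs, ys, x) {   # brute-force piecewise-linear
    o <- order(xs); xs <- xs[o]; ys <- ys[o]
    vapply(x, function(xi) {
      i <- max(which(xs <= xi))
      if (xs[i] == xi) return(ys[i])
      ys[i] + (ys[i + 1] - ys[i]) * (xi - xs[i]) / (xs[i + 1] - xs[i])
    }, 0)
  }
  expect_lt(max(abs(al3$intensities[2, ] -
                      oracle(gb, yb, al3$grid))), 1e-10)
  # no extrapolation: every target point is inside both ranges
  expect_true(all(al3$grid <= min(max(ga), max(gb)) &
                    al3$grid >= max(min(ga), min(gb))))

  # aligning an already-aligned set changes nothing (idempotence)
  spectra <- lapply(seq_len(n_spectra(al)), function(i)
    list(wavenumbers = al$grid, intensities = al$intensities[i, ],
         meta = al$meta[i, , drop = FALSE]))
  al4 <- align_to_common_grid(spectra)
  expect_equal(al4$grid, al$grid)
  expect_equal(al4$intensities, al$intensities)

  expect_error(align_to_common_grid(list(
    list(wavenumbers = 1:10, intensities = 1:10),
    list(wavenumbers = 20:30, intensities = 20:30))), "overlap")
})

test_that("JCAMP-DX spectra are parsed and aligned", {
  tmp <- withr::local_tempdir()
  writeLines(c("##TITLE=sampleA", "##JCAMP-DX=4.24", "##XFACTOR=1",
               "##YFACTOR=0.5", "##XYDATA=(X++(Y..Y))",
               "100 2 4 6 8", "108 10 12 14 16", "##END="),
             file.path(tmp, "a.jdx"))
  sp <- read_jcamp(file.path(tmp, "a.jdx"))
  expect_equal(sp$wavenumbers, seq(100, 114, by = 2))
  expect_equal(sp$intensities, seq(1, 8))
  expect_equal(sp$meta$sample_id, "sampleA")

  writeLines(c("##TITLE=sampleB", "##XYPOINTS=(XY..XY)",
               "100, 1.5; 102, 2.5", "104, 3.5", "##END="),
             file.path(tmp, "b.jdx"))
  sp2 <- read_jcamp(file.path(tmp, "b.jdx"))
  expect_equal(sp2$wavenumbers, c(100, 102, 104))
  expect_equal(sp2$intensities, c(1.5, 2.5, 3.5))

  set <- read_spectra_matrix(tmp, format = "jcamp")
  expect_equal(n_spectra(set), 2L)
  expect_true(all(diff(set$grid) < 0))
})
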