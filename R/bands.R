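#' Catalog of characteristic Raman / infrared bands of fungal biomass
#'
#' Returns the band assignments for the main chemical constituents of
#' Mucoromycota biomass — acylglycerol lipids, cell-wall glucosamines
#' (chitin) and chitosan/glucan/glucuronan carbohydrates, proteins,
#' polyphosphates, and carotenoid pigments — for one spectral block.
#' Carotenoids appear only in the Raman catalog: at the concentrations
#' present in fungal biomass they are detectable only through the
#' resonance Raman effect and have no usable infrared bands.
#'
#' Relative heights order the bands within each component so that, for the
#' Raman block, the lipid C-H stretching region and the resonance-enhanced
#' carotenoid bands are the strongest signals of their components.
#'
#' @param block `"raman"` or `"ftir"`.
#' @return A data frame of class `band_catalog` with columns `component`,
#'   `block`, `center`, `height`, `fwhm`, `assignment`.
#' @export
make_band_catalog <- function(block) {
  block <- match.arg(block, c("raman", "ftir"))
  B <- function(component, center, height, fwhm, assignment)
    data.frame(component = component, block = block, center = center,
               height = height, fwhm = fwhm, assignment = assignment,
               stringsAsFactors = FALSE)

  if (block == "raman") {
    cat <- rbind(
      # acylglycerol lipids (triglycerides)
      B("lipid", 3008, 0.50, 16, "=C-H str."),
      B("lipid", 2933, 0.80, 16, "-C-H str. (CH3)"),
      B("lipid", 2895, 0.90, 16, "-C-H str. (CH3)"),
      B("lipid", 2855, 1.00, 16, "-C-H str. (CH2)"),
      B("lipid", 1750, 0.50, 16, "C=O str."),
      B("lipid", 1660, 0.55, 16, "C=C str."),
      B("lipid", 1445, 0.80, 16, "CH2 and CH3 def."),
      B("lipid", 1305, 0.50, 16, "CH2 def."),
      B("lipid", 1070, 0.30, 16, "C-C str., C-O str."),
      # chitin (glucosamine cell-wall fraction)
      B("chitin", 2933, 0.70, 16, "-C-H str. (CH3)"),
      B("chitin", 2895, 0.60, 16, "-C-H str. (CH3)"),
      B("chitin", 1650, 0.80, 16, "-C=O str. (Amide I, chitin)"),
      B("chitin", 1445, 0.90, 16, "CH2 and CH3 def."),
      B("chitin", 1377, 0.50, 16, "CH2, CH, COH def."),
      B("chitin", 1327, 0.50, 16, "CH2, CH, COH def."),
      B("chitin", 1155, 0.45, 16, "C-O-C str."),
      B("chitin", 1109, 0.40, 16, "C-N str. & C-C str."),
      # chitosan / glucan / glucuronan carbohydrates
      B("chitosan_glucan", 2855, 0.50, 16, "-C-H str. (CH2, glucan)"),
      B("chitosan_glucan", 1755, 0.20, 16, "-C=O str. (glucuronan)"),
      B("chitosan_glucan", 1595, 0.30, 16, "NH2 def. (chitosan)"),
      B("chitosan_glucan", 1256, 0.30, 16, "C-C, C-O, CH, CH2"),
      B("chitosan_glucan", 1085, 0.40, 16, "C-N str. & C-C str."),
      B("chitosan_glucan",  900, 0.30, 16, "C-C str., C-O-C str. & def."),
      B("chitosan_glucan",  715, 0.20, 16, "O-C-O str. & CH def."),
      # proteins
      B("protein", 1660, 0.60, 16, "-C=O str. (Amide I)"),
      B("protein", 1605, 0.30, 16, "C=C str. (phenyl ring)"),
      B("protein", 1445, 0.40, 16, "CH2 and CH3 def."),
      B("protein", 1280, 0.40, 16, "C-N-H def. (Amide III)"),
      B("protein", 1005, 0.50, 16, "phenyl ring def."),
      # polyphosphates
      B("polyphosphate", 1165, 1.00, 16, "P=O str. (PO2-)"),
      B("polyphosphate",  685, 0.60, 16, "P-O-P str."),
      # carotenoids (resonance enhanced, narrower)
      B("carotenoid", 1525, 1.00, 10, "C=C str. (polyene chain)"),
      B("carotenoid", 1155, 0.85, 10, "C-C str. & CH def."),
      B("carotenoid", 1005, 0.50, 10, "C-CH3 def.")
    )
  } else {
    cat <- rbind(
      B("lipid", 3010, 0.30, 16, "=C-H str."),
      B("lipid", 2921, 1.00, 16, "-C-H str. (CH3)"),
      B("lipid", 2852, 0.80, 16, "-C-H str. (CH2)"),
      B("lipid", 1743, 0.90, 16, "-C=O str."),
      B("lipid", 1463, 0.40, 16, "-CH2 def."),
      B("lipid", 1160, 0.40, 16, "C-O-C str."),
      B("lipid",  723, 0.20, 16, "-CH2 def."),
      B("chitin", 3250, 0.40, 40, "N-H str., N-H2 str."),
      B("chitin", 2879, 0.40, 16, "-C-H str. (CH3)"),
      B("chitin", 1650, 0.90, 16, "-C=O str. (Amide I, chitin)"),
      B("chitin", 1554, 0.70, 16, "C-N str. & NH def. (Amide II, chitin)"),
      B("chitin", 1375, 0.40, 16, "-CH3 def."),
      B("chitin", 1305, 0.40, 16, "C-N-H def. (Amide III, chitin)"),
      B("chitin", 1100, 1.00, 30, "C-O-C str., COH def., COC def."),
      B("chitosan_glucan", 3300, 0.50, 40, "O-H str."),
      B("chitosan_glucan", 1730, 0.30, 16, "-C=O str. (glucuronans)"),
      B("chitosan_glucan", 1575, 0.30, 16, "NH2 def. (chitosan)"),
      B("chitosan_glucan", 1100, 0.90, 30, "C-O-C str., COH def."),
      B("chitosan_glucan",  950, 0.30, 16, "-CH3 def."),
      B("protein", 1655, 1.00, 16, "-C=O str. (Amide I)"),
      B("protein", 1545, 0.70, 16, "C-N-H def. (Amide II)"),
      B("protein", 1280, 0.30, 16, "C-N-H def. (Amide III)"),
      B("polyphosphate", 1263, 1.00, 16, "P=O str. (PO2-)"),
      B("polyphosphate",  885, 0.70, 16, "P-O-P str.")
      # carotenoids: not detectable by FTIR at biomass concentrations
    )
  }
  rng <- if (block == "raman") c(50, 3785) else c(400, 4000)
  stopifnot(all(cat$center >= rng[1] & cat$center <= rng[2]),
            all(cat$height > 0))
  class(cat) <- c("band_catalog", "data.frame")
  cat
}

#' Unit-peak Lorentzian line profile
#' @keywords internal
lorentzian <- function(x, center, fwhm) {
  hw <- fwhm / 2
  hw^2 / ((x - center)^2 + hw^2)
}

#' Pure-component spectrum from a band catalog
#'
#' Realizes a component as a sum of unit-peak Lorentzian bands with the
#' catalog's relative heights: the spectrum of the component at unit
#' concentration on the given grid.
#'
#' @param catalog A [make_band_catalog()] result.
#' @param component Component label present in the catalog.
#' @param grid Wavenumber vector (cm^-1).
#' @return A list of class `component_profile` with `component`, `grid`,
#'   `pure_spectrum` (non-negative).
#' @export
synth_component_spectrum <- function(catalog, component, grid) {
  rows <- catalog[catalog$component == component, , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("component '%s' has no bands in this catalog", component))
  y <- numeric(length(grid))
  for (i in seq_len(nrow(rows)))
    y <- y + rows$height[i] * lorentzian(grid, rows$center[i], rows$fwhm[i])
  structure(list(component = component, grid = grid, pure_spectrum = y),
            class = "component_profile")
}

#' Matrix of pure-component spectra on a grid
#'
#' @param catalog A [make_band_catalog()] result.
#' @param grid Wavenumber vector.
#' @return Matrix (components x wavenumbers) with component row names.
#' @export
component_profile_matrix <- function(catalog, grid) {
  comps <- unique(catalog$component)
  out <- t(vapply(comps, function(cc)
    synth_component_spectrum(catalog, cc, grid)$pure_spectrum,
    numeric(length(grid))))
  rownames(out) <- comps
  out
}
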