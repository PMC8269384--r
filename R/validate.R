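#' Bioreplicate-held-out PLSR calibration and validation
#'
#' Builds a PLSR calibration on one biological replicate set and
#' validates it on the other, the standard guard against over-optimistic
#' error estimates when technical replicates are present. Preprocessing
#' is applied inside the split: the EMSC reference is the mean of the
#' training partition only (computed after the recipe's pre-EMSC steps),
#' so no information from the validation bioreplicate leaks into the
#' model. Models are fitted on replicate-level spectra with
#' leave-one-biological-sample-out cross-validation for component
#' selection; predictions are reported per biological sample as
#' technical-replicate means.
#'
#' @param set A raw [spectra_set()] with a chemistry table.
#' @param analyte Chemistry column to calibrate (`"lipid_pct_dw"`,
#'   `"phosphorus_pct_dw"` or `"carotenoid_ug_per_g"`).
#' @param recipe Preprocessing recipe name or object.
#' @param strains Optional strain subset (e.g. the *Mucor* strains).
#' @param train_bio_rep Which biological replicate trains the model.
#' @param max_components Maximum number of PLS components.
#' @param aopt_rule Component-selection rule (see [select_aopt()]).
#' @param tau Relative tolerance for the `"relative"` rule.
#' @return Object of class `biorep_validation`: the fitted `model`,
#'   `aopt`, `r2_cal`, `rmse_cal`, `r2_val`, `rmse_val`, per-sample
#'   `predictions` (data frame with truth and prediction on both
#'   partitions), and the settings used.
#' @export
validate_bioreplicate <- function(set, analyte,
                                  recipe = "raman_nonderiv",
                                  strains = NULL, train_bio_rep = 1,
                                  max_components = 10,
                                  aopt_rule = "relative", tau = 0.05) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(set$chemistry)) stop("spectra_set has no chemistry table")
  if (!is.null(strains))
    set <- subset_spectra(set, set$meta$strain %in% strains)
  if (is.character(recipe)) recipe <- preprocess_recipe(recipe)

  is_train <- set$meta$bio_rep == train_bio_rep
  if (!any(is_train) || all(is_train))
    stop("train/test split by bio_rep is degenerate")
  train <- subset_spectra(set, is_train)
  test <- subset_spectra(set, !is_train)
  if (length(intersect(train$meta$sample_id, test$meta$sample_id)))
    stop("leakage: sample ids overlap between partitions")

  # run the training partition through the recipe with its own mean as
  # EMSC reference, then re-apply to the test partition with the same
  # (training-derived) reference
  pre <- recipe_with_train_reference(train, test, recipe)

  y_train <- chemistry_for_rows(pre$train, analyte)
  y_test <- chemistry_for_rows(pre$test, analyte)

  model <- fit_plsr(pre$train, y_train, max_components)
  aopt <- select_aopt(model, rule = aopt_rule, tau = tau)
  model$aopt <- aopt

  per_sample <- function(pset, yvec, pred) {
    agg <- stats::aggregate(cbind(truth = yvec, pred = pred),
                            by = list(sample_id = pset$meta$sample_id),
                            FUN = mean)
    agg
  }
  pr_tr <- per_sample(pre$train, y_train,
                      predict(model, pre$train, ncomp = aopt))
  pr_te <- per_sample(pre$test, y_test,
                      predict(model, pre$test, ncomp = aopt))
  pr_tr$partition <- "calibration"; pr_te$partition <- "validation"
  preds <- rbind(pr_tr, pr_te)

  metr <- function(d) {
    rmse <- sqrt(mean((d$truth - d$pred)^2))
    r2 <- 1 - sum((d$truth - d$pred)^2) / sum((d$truth - mean(d$truth))^2)
    c(r2 = r2, rmse = rmse)
  }
  mc <- metr(pr_tr); mv <- metr(pr_te)
  structure(list(
    model = model, aopt = aopt,
    r2_cal = unname(mc["r2"]), rmse_cal = unname(mc["rmse"]),
    r2_val = unname(mv["r2"]), rmse_val = unname(mv["rmse"]),
    predictions = preds,
    analyte = analyte, recipe = recipe$name,
    strains = strains %||% "all", train_bio_rep = train_bio_rep,
    aopt_rule = aopt_rule, tau = tau,
    response_range = range(c(y_train, y_test))),
    class = "biorep_validation")
}

# Apply a recipe to train and test so that any EMSC step uses the
# training partition's mean spectrum (taken at that point of the chain).
recipe_with_train_reference <- function(train, test, recipe) {
  for (st in recipe$steps) {
    if (st$fn == "emsc") {
      ref <- colMeans(train$intensities)
      train <- emsc(train, ref, st$poly_degree)
      test <- emsc(test, ref, st$poly_degree)
    } else {
      one <- function(s) switch(st$fn,
        savgol = savgol(s, st$polynomial, st$window, st$derivative_order),
        rubberband_baseline = rubberband_baseline(s),
        truncate_regions = truncate_regions(s, st$regions),
        stop("unknown preprocessing step: ", st$fn))
      train <- one(train); test <- one(test)
    }
  }
  list(train = train, test = test)
}

#' @export
print.biorep_validation <- function(x, ...) {
  cat(sprintf("<biorep_validation> %s, recipe %s, strains: %s\n",
              x$analyte, x$recipe, paste(x$strains, collapse = ", ")))
  cat(sprintf("  AOpt = %d (%s rule)\n", x$aopt, x$aopt_rule))
  cat(sprintf("  calibration: R2 = %.3f, RMSE = %.4g\n",
              x$r2_cal, x$rmse_cal))
  cat(sprintf("  validation:  R2 = %.3f, RMSE = %.4g\n",
              x$r2_val, x$rmse_val))
  invisible(x)
}

#' Raman band-intensity ratios
#'
#' Reads intensities at the two wavenumbers (nearest grid point, lookup
#' error at most half the grid spacing) and returns their ratio per
#' spectrum. The three classical screening pairs are available as
#' presets: `"lipids"` (1747 / 1445, lipid carbonyl over total-biomass
#' CH deformation), `"polyphosphates"` (1163 / 1155, P=O over chitin),
#' and `"carotenoids"` (1523 / 1445). Intended for non-derivative
#' preprocessed Raman data.
#'
#' @param set A [spectra_set()].
#' @param numerator,denominator Wavenumbers in cm^-1 (ignored when
#'   `preset` is given).
#' @param preset Optional preset name.
#' @return Data frame with `sample_id` (and design columns when present),
#'   the wavenumbers actually used, both intensities and `ratio`.
#' @export
band_ratio <- function(set, numerator = NULL, denominator = NULL,
                       preset = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (!is.null(preset)) {
    pair <- band_ratio_presets()[[match.arg(preset,
                                            names(band_ratio_presets()))]]
    numerator <- pair[1]; denominator <- pair[2]
  }
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  half <- abs(stats::median(diff(set$grid))) / 2
  pick <- function(wn) {
    i <- which.min(abs(set$grid - wn))
    if (abs(set$grid[i] - wn) > half + 1e-9)
      stop(sprintf("wavenumber %g cm^-1 is outside the grid", wn))
    i
  }
  i_num <- pick(numerator); i_den <- pick(denominator)
  den <- set$intensities[, i_den]
  if (any(abs(den) < .Machine$double.eps * 100))
    stop("denominator intensity is zero for at least one spectrum")
  keep <- intersect(c("strain", "pi_level", "ca_level", "bio_rep",
                      "tech_rep"), names(set$meta))
  out <- data.frame(sample_id = set$meta$sample_id,
                    stringsAsFactors = FALSE)
  for (cc in keep) out[[cc]] <- set$meta[[cc]]
  out$numerator_cm1 <- set$grid[i_num]
  out$denominator_cm1 <- set$grid[i_den]
  out$numerator_intensity <- set$intensities[, i_num]
  out$denominator_intensity <- den
  out$ratio <- out$numerator_intensity / den
  out
}

#' @rdname band_ratio
#' @export
band_ratio_presets <- function() {
  list(lipids = c(1747, 1445),
       polyphosphates = c(1163, 1155),
       carotenoids = c(1523, 1445))
}
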