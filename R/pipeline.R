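#' Default pipeline configuration
#'
#' @param output_dir Directory for all output artifacts.
#' @param seed Integer seed governing the whole run (synthetic data and
#'   any other randomness); recorded in every output.
#' @param blocks Blocks to analyze.
#' @param strains Strains to simulate (synthetic input).
#' @param input Optional list of paths (`raman`, `ftir`) to wide spectral
#'   CSVs written by [write_spectra_matrix()]; when given, data is read
#'   instead of simulated.
#' @param effects Arguments passed to [design_effects()] for synthetic
#'   generation.
#' @param pca_components Components for PCA/CPCA.
#' @param plsr List of PLSR model specs, each a list with `analyte`,
#'   `recipe`, optional `strains`; `NULL` uses the standard set (lipids
#'   and phosphorus on all strains and on the *Mucor* subset, carotenoids
#'   on the two *Mucor circinelloides* strains, all on non-derivative
#'   FT-Raman).
#' @param max_components,train_bio_rep,aopt_rule,tau PLSR settings.
#' @param anova_recipe `"deriv"` (default) or `"nonderiv"` preprocessing
#'   for the variance decomposition.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1,
                       blocks = c("raman", "ftir"),
                       strains = c("Ar", "Mc1", "Mc2", "Mr", "Rs", "Uv"),
                       input = NULL, effects = list(),
                       pca_components = 5, plsr = NULL,
                       max_components = 10, train_bio_rep = 1,
                       aopt_rule = "relative", tau = 0.05,
                       anova_recipe = "deriv") {
  if (is.null(plsr)) {
    mucor <- intersect(c("Mc1", "Mc2", "Mr"), strains)
    mc <- intersect(c("Mc1", "Mc2"), strains)
    plsr <- list(
      list(analyte = "lipid_pct_dw", recipe = "raman_nonderiv"),
      list(analyte = "phosphorus_pct_dw", recipe = "raman_nonderiv"))
    if (length(mucor) > 1) {
      plsr <- c(plsr, list(
        list(analyte = "lipid_pct_dw", recipe = "raman_nonderiv",
             strains = mucor),
        list(analyte = "phosphorus_pct_dw", recipe = "raman_nonderiv",
             strains = mucor)))
    }
    if (length(mc) > 1)
      plsr <- c(plsr, list(
        list(analyte = "carotenoid_ug_per_g", recipe = "raman_nonderiv",
             strains = mc)))
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 blocks = blocks, strains = strains, input = input,
                 effects = effects, pca_components = pca_components,
                 plsr = plsr, max_components = max_components,
                 train_bio_rep = train_bio_rep, aopt_rule = aopt_rule,
                 tau = tau, anova_recipe = anova_recipe),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the arguments of [run_config()].
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$plsr) && is.data.frame(cfg$plsr))
    cfg$plsr <- lapply(seq_len(nrow(cfg$plsr)), function(i) {
      r <- as.list(cfg$plsr[i, ])
      r[!vapply(r, function(v) all(is.na(v)), TRUE)]
    })
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the two-block spectral dataset, then runs the
#' complete workflow: preprocessing (non-derivative and derivative
#' recipes per block), technical-replicate QC, PCA of the non-derivative
#' FT-Raman block, consensus PCA of the derivative blocks, PLSR
#' calibration with bioreplicate-held-out validation, band-intensity
#' ratios, and the per-strain ANOVA variance decomposition. All tables
#' are written as CSV under `config$output_dir` together with a
#' machine-readable `summary.json` (seed, parameters, headline numbers).
#' Stages whose inputs are absent (e.g. CPCA with a single block) are
#' skipped with a logged notice.
#'
#' @param config A [run_config()] (or path to a JSON config).
#' @param verbose Print stage progress.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  summary <- list(package_version =
                    as.character(utils::packageVersion("mycospec")),
                  seed = config$seed,
                  parameters = config[c("blocks", "strains",
                                        "pca_components", "max_components",
                                        "train_bio_rep", "aopt_rule",
                                        "tau", "anova_recipe")],
                  skipped = list())

  # --- stage: data ------------------------------------------------------
  stage <- "data"
  data <- tryCatch({
    if (is.null(config$input)) {
      say("stage data: simulating %d-strain design (seed %d)",
          length(config$strains), config$seed)
      eff <- do.call(design_effects, config$effects)
      synth_dataset(eff, seed = config$seed, strains = config$strains,
                    blocks = config$blocks)
    } else {
      say("stage data: reading input spectra")
      d <- list()
      for (b in config$blocks)
        if (!is.null(config$input[[b]]))
          d[[b]] <- read_spectra_matrix(config$input[[b]])
      d$chemistry <- d[[config$blocks[1]]]$chemistry
      d
    }
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e)))
  blocks <- intersect(config$blocks, c("raman", "ftir"))
  blocks <- blocks[vapply(blocks, function(b) !is.null(data[[b]]), TRUE)]
  summary$n_spectra <- lapply(data[blocks], n_spectra)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }

  # --- stage: preprocess ------------------------------------------------
  pp <- list()
  run_stage("preprocess", {
    for (b in blocks) {
      say("stage preprocess: block %s", b)
      pp[[b]] <- list(
        nonderiv = apply_recipe(data[[b]],
                                paste0(b, "_nonderiv")),
        deriv = apply_recipe(data[[b]], paste0(b, "_deriv")))
      write_spectra_matrix(pp[[b]]$nonderiv,
                           file.path(config$output_dir,
                                     paste0("pp_", b, "_nonderiv.csv")))
      write_spectra_matrix(pp[[b]]$deriv,
                           file.path(config$output_dir,
                                     paste0("pp_", b, "_deriv.csv")))
    }
  })

  # --- stage: qc --------------------------------------------------------
  if ("raman" %in% blocks && any(duplicated(data$raman$meta$sample_id))) {
    run_stage("qc", {
      say("stage qc: replicate PCC variability")
      qc <- withCallingHandlers(
        replicate_pcc(pp$raman$nonderiv),
        warning = function(w) {
          say("qc warning: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      utils::write.csv(qc, file.path(config$output_dir, "variability.csv"),
                       row.names = FALSE)
      summary$qc <- list(max_variability = max(qc$variability),
                         worst_sample = qc$sample_id[1],
                         median_variability = stats::median(qc$variability))
    })
  } else {
    summary$skipped$qc <- "no raman block with technical replicates"
    say("stage qc skipped: %s", summary$skipped$qc)
  }

  avg <- lapply(pp, lapply, average_technical_replicates)

  # --- stage: pca -------------------------------------------------------
  if ("raman" %in% blocks) {
    run_stage("pca", {
      say("stage pca: FT-Raman nonderivative block")
      pca <- fit_pca(avg$raman$nonderiv, config$pca_components)
      utils::write.csv(
        data.frame(sample_id = avg$raman$nonderiv$meta$sample_id,
                   pca$scores),
        file.path(config$output_dir, "pca_scores.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(wavenumber = pca$grid, t(pca$loadings)),
        file.path(config$output_dir, "pca_loadings.csv"),
        row.names = FALSE)
      summary$pca <- list(explained_pct = pca$explained_pct)
    })
  }

  # --- stage: cpca ------------------------------------------------------
  if (length(blocks) >= 2) {
    run_stage("cpca", {
      say("stage cpca: consensus PCA of derivative blocks")
      cp <- fit_cpca(list(raman = avg$raman$deriv, ftir = avg$ftir$deriv),
                     config$pca_components)
      utils::write.csv(
        data.frame(sample_id = cp$meta$sample_id, cp$global_scores),
        file.path(config$output_dir, "cpca_global_scores.csv"),
        row.names = FALSE)
      summary$cpca <- list(explained_pct = cp$explained_pct,
                           block_contrib_pct = as.data.frame(
                             cp$block_contrib_pct))
    })
  } else {
    summary$skipped$cpca <- "needs both raman and ftir blocks"
    say("stage cpca skipped: %s", summary$skipped$cpca)
  }

  # --- stage: plsr ------------------------------------------------------
  if (!is.null(data$chemistry)) {
    run_stage("plsr", {
      reports <- list()
      for (spec in config$plsr) {
        b <- if (grepl("^ftir", spec$recipe)) "ftir" else "raman"
        if (!b %in% blocks) next
        say("stage plsr: %s (%s, strains %s)", spec$analyte, spec$recipe,
            paste(spec$strains %||% "all", collapse = ","))
        rep <- validate_bioreplicate(
          data[[b]], spec$analyte, recipe = spec$recipe,
          strains = spec$strains,
          train_bio_rep = config$train_bio_rep,
          max_components = config$max_components,
          aopt_rule = config$aopt_rule, tau = config$tau)
        key <- paste0(spec$analyte, "_",
                      paste(spec$strains %||% "all", collapse = ""))
        reports[[key]] <- list(
          analyte = spec$analyte, recipe = spec$recipe,
          strains = spec$strains %||% "all",
          aopt = rep$aopt, r2_cal = rep$r2_cal, rmse_cal = rep$rmse_cal,
          r2_val = rep$r2_val, rmse_val = rep$rmse_val)
      }
      summary$plsr <- reports
      jsonlite::write_json(reports,
                           file.path(config$output_dir, "plsr_reports.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  } else {
    summary$skipped$plsr <- "no chemistry table"
    say("stage plsr skipped: %s", summary$skipped$plsr)
  }

  # --- stage: ratios ----------------------------------------------------
  if ("raman" %in% blocks) {
    run_stage("ratio", {
      say("stage ratio: band-intensity ratios (3 presets)")
      tabs <- lapply(names(band_ratio_presets()), function(p) {
        t <- band_ratio(pp$raman$nonderiv, preset = p)
        t$preset <- p
        t
      })
      ratios <- do.call(rbind, tabs)
      utils::write.csv(ratios,
                       file.path(config$output_dir, "band_ratios.csv"),
                       row.names = FALSE)
      summary$ratios <- lapply(split(ratios, ratios$preset), function(d)
        list(mean = mean(d$ratio), max = max(d$ratio)))
    })
  }

  # --- stage: anova -----------------------------------------------------
  run_stage("anova", {
    rec <- if (config$anova_recipe == "deriv") "deriv" else "nonderiv"
    say("stage anova: per-strain decomposition (%s recipe)", rec)
    sets <- lapply(avg[blocks], function(x) {
      s <- x[[rec]]
      truncate_regions(s, list(c(900, 1800)))
    })
    contrib <- decompose_all_strains(sets)
    contrib$recipe <- rec
    utils::write.csv(contrib,
                     file.path(config$output_dir, "anova_contributions.csv"),
                     row.names = FALSE)
    summary$anova <- list(recipe = rec, n_rows = nrow(contrib),
                          mean_pi_share = mean(contrib$pi))
    if (!"ftir" %in% blocks) {
      summary$skipped$anova_ftir <- "ftir block absent"
      say("stage anova: ftir part skipped (block absent)")
    }
  })

  summary$log <- log_lines
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %s", config$output_dir)
  invisible(summary)
}
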