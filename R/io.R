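#' Read a wide spectral matrix with sidecar metadata
#'
#' The canonical on-disk layout is a wide CSV (one row per spectrum, first
#' column `sample_id` plus a `tech_rep` column when present, remaining
#' column names the wavenumbers in cm^-1), a metadata CSV keyed by
#' `sample_id`, and an optional chemistry CSV. A directory of JCAMP-DX
#' files is also accepted (`format = "jcamp"`), in which case spectra are
#' aligned onto their common grid with [align_to_common_grid()].
#'
#' @param path Path to the wide CSV (or a directory of `.jdx`/`.dx` files).
#' @param meta_path Path to the metadata CSV; defaults to
#'   `<path minus extension>_meta.csv` if that file exists.
#' @param chemistry_path Optional chemistry CSV; same default convention
#'   with suffix `_chemistry.csv`.
#' @param format `"wide"` (default) or `"jcamp"`.
#' @return A [spectra_set()].
#' @export
read_spectra_matrix <- function(path, meta_path = NULL,
                                chemistry_path = NULL, format = "wide") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("wide", "jcamp"))
  if (format == "jcamp") return(read_jcamp_collection(path))

  stem <- sub("\\.[^.]+$", "", path)
  if (is.null(meta_path)) {
    cand <- paste0(stem, "_meta.csv")
    if (file.exists(cand)) meta_path <- cand
  }
  if (is.null(chemistry_path)) {
    cand <- paste0(stem, "_chemistry.csv")
    if (file.exists(cand)) chemistry_path <- cand
  }

  wide <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  idcols <- intersect(c("sample_id", "tech_rep"), names(wide))
  speccols <- names(wide)[!names(wide) %in% idcols]
  grid <- suppressWarnings(as.numeric(speccols))
  if (anyNA(grid))
    stop("non-numeric wavenumber column name: ",
         speccols[which(is.na(grid))[1]])
  if (anyDuplicated(grid))
    stop("duplicate wavenumber column: ", grid[anyDuplicated(grid)])
  if (nrow(wide) > 0) {
    isnum <- vapply(wide[, speccols, drop = FALSE], is.numeric, TRUE)
    if (!all(isnum))
      stop("non-numeric cell(s) in column ", speccols[which(!isnum)[1]])
  }
  mat <- as.matrix(wide[, speccols, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite intensity at row %d (column %s)",
                 bad[1, 1], speccols[bad[1, 2]]))

  meta <- data.frame(sample_id = as.character(wide$sample_id),
                     stringsAsFactors = FALSE)
  if ("tech_rep" %in% names(wide)) meta$tech_rep <- wide$tech_rep
  if (!is.null(meta_path)) {
    mtab <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(mtab))
      stop("metadata table must have a sample_id column")
    idx <- match(meta$sample_id, mtab$sample_id)
    if (anyNA(idx))
      stop("sample_id without metadata: ",
           meta$sample_id[which(is.na(idx))[1]])
    extra <- setdiff(names(mtab), names(meta))
    meta <- cbind(meta, mtab[idx, extra, drop = FALSE])
    rownames(meta) <- NULL
  }
  chem <- NULL
  if (!is.null(chemistry_path))
    chem <- utils::read.csv(chemistry_path, stringsAsFactors = FALSE)

  ord <- order(grid, decreasing = TRUE)
  spectra_set(grid[ord], mat[, ord, drop = FALSE], meta, chem)
}

#' Write a spectra set as a wide matrix plus sidecar tables
#'
#' Inverse of [read_spectra_matrix()]: writes `<path>` (wide CSV),
#' `<stem>_meta.csv`, and `<stem>_chemistry.csv` when chemistry is present.
#' Intensities are written at full double precision so a read back is
#' lossless to ~1e-15 relative.
#'
#' @param set A [spectra_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_matrix <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  stem <- sub("\\.[^.]+$", "", path)

  wide <- data.frame(sample_id = if (nrow(set$meta)) set$meta$sample_id
                     else character(0),
                     stringsAsFactors = FALSE)
  if ("tech_rep" %in% names(set$meta)) wide$tech_rep <- set$meta$tech_rep
  mat <- set$intensities
  colnames(mat) <- format(set$grid, digits = 17, trim = TRUE,
                          scientific = FALSE)
  wide <- cbind(wide, as.data.frame(mat, check.names = FALSE))
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(wide, path, row.names = FALSE)

  meta_cols <- setdiff(names(set$meta), "tech_rep")
  meta_out <- unique(set$meta[, meta_cols, drop = FALSE])
  utils::write.csv(meta_out, paste0(stem, "_meta.csv"), row.names = FALSE)
  if (!is.null(set$chemistry))
    utils::write.csv(set$chemistry, paste0(stem, "_chemistry.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Align individual spectra onto a common wavenumber grid
#'
#' Spectra measured on different grids are linearly interpolated onto the
#' intersection of their wavenumber ranges, sampled at a fixed digital
#' spacing (default 1.928 cm^-1, the instrument spacing). No extrapolation
#' is ever performed.
#'
#' @param spectra A list of spectra, each a list with elements
#'   `wavenumbers`, `intensities` and (optionally) `meta` (a one-row data
#'   frame or named list).
#' @param step Digital spacing of the target grid in cm^-1.
#' @return A [spectra_set()] on the shared descending grid.
#' @export
align_to_common_grid <- function(spectra, step = 1.928) {
  stopifnot(length(spectra) >= 1, step > 0)
  los <- vapply(spectra, function(s) min(s$wavenumbers), 0)
  his <- vapply(spectra, function(s) max(s$wavenumbers), 0)
  lo <- max(los); hi <- min(his)
  if (hi <= lo)
    stop(sprintf("spectra do not overlap (intersection [%g, %g])", lo, hi))
  grid <- seq(hi, lo, by = -step)

  mat <- t(vapply(spectra, function(s) {
    o <- order(s$wavenumbers)
    stats::approx(s$wavenumbers[o], s$intensities[o], xout = grid,
                  method = "linear", rule = 1)$y
  }, numeric(length(grid))))

  metas <- lapply(seq_along(spectra), function(i) {
    m <- spectra[[i]]$meta
    if (is.null(m)) m <- list(sample_id = sprintf("S%03d", i))
    as.data.frame(m, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, lapply(metas, function(m) {
    allcols <- unique(unlist(lapply(metas, names)))
    for (cc in setdiff(allcols, names(m))) m[[cc]] <- NA
    m[, allcols, drop = FALSE]
  }))
  rownames(meta) <- NULL
  spectra_set(grid, mat, meta)
}

# --- minimal JCAMP-DX reader (AFFN; (X++(Y..Y)) and XYPOINTS) ------------

#' Read one JCAMP-DX spectrum
#'
#' Supports AFFN-encoded `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)`
#' records, honouring `XFACTOR`/`YFACTOR`. Compressed (SQZ/DIF/DUP) forms
#' are not supported.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return A list with `wavenumbers`, `intensities`, `meta`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getfield <- function(key) {
    i <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    sub(paste0("^##", key, "="), "", lines[i[1]], ignore.case = TRUE)
  }
  xf <- as.numeric(getfield("XFACTOR") %||% "1")
  yf <- as.numeric(getfield("YFACTOR") %||% "1")
  title <- trimws(getfield("TITLE") %||% basename(path))

  ix <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  ip <- grep("^##XYPOINTS=", lines, ignore.case = TRUE)
  end <- grep("^##END", lines, ignore.case = TRUE)
  parse_nums <- function(txt)
    as.numeric(strsplit(trimws(txt), "[,;[:space:]]+")[[1]])

  if (length(ix)) {
    stopval <- if (length(end)) min(end[end > ix[1]]) - 1 else length(lines)
    block <- lines[(ix[1] + 1):stopval]
    block <- block[!grepl("^##", block) & nzchar(trimws(block))]
    if (any(grepl("[A-DF-Za-df-z%@]", sub("[eE][+-]?[0-9]+", "", block))))
      stop("compressed JCAMP-DX (SQZ/DIF) is not supported: ", path)
    wn <- c(); y <- c()
    for (ln in block) {
      v <- parse_nums(ln)
      if (length(v) < 2) next
      x0 <- v[1] * xf
      yi <- v[-1] * yf
      # per-line abscissa: x0 plus implied increments reconstructed later
      wn <- c(wn, x0)
      y <- c(y, list(yi))
    }
    ylen <- lengths(y)
    # reconstruct each line's x values from consecutive line starts
    xs <- vector("list", length(wn))
    for (k in seq_along(wn)) {
      if (k < length(wn) && ylen[k] > 1) {
        dx <- (wn[k + 1] - wn[k]) / ylen[k]
      } else if (k > 1) {
        dx <- (wn[k] - wn[k - 1]) / ylen[k - 1]
      } else dx <- 0
      xs[[k]] <- wn[k] + dx * (seq_len(ylen[k]) - 1)
    }
    wavenumbers <- unlist(xs); intens <- unlist(y)
  } else if (length(ip)) {
    stopval <- if (length(end)) min(end[end > ip[1]]) - 1 else length(lines)
    block <- lines[(ip[1] + 1):stopval]
    block <- block[!grepl("^##", block) & nzchar(trimws(block))]
    v <- unlist(lapply(block, parse_nums))
    wavenumbers <- v[seq(1, length(v), by = 2)] * xf
    intens <- v[seq(2, length(v), by = 2)] * yf
  } else stop("no XYDATA/XYPOINTS record in ", path)

  if (anyNA(wavenumbers) || anyNA(intens))
    stop("non-numeric JCAMP data in ", path)
  list(wavenumbers = wavenumbers, intensities = intens,
       meta = list(sample_id = title))
}

#' @keywords internal
read_jcamp_collection <- function(dir) {
  files <- list.files(dir, pattern = "\\.(jdx|dx|JDX|DX)$",
                      full.names = TRUE)
  if (!length(files)) stop("no JCAMP-DX files in ", dir)
  align_to_common_grid(lapply(files, read_jcamp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
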