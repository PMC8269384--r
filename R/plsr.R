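#' Partial least squares regression (single response)
#'
#' PLS1 fitted by the classical NIPALS weight/score/deflation scheme on
#' mean-centered data. Regression coefficient vectors are stored for every
#' number of components `A <= max_components`, together with calibration
#' RMSE and, when fold groups are given, cross-validated RMSE per `A`
#' (leave-one-group-out; the intended grouping is by biological sample so
#' that all technical replicates leave together).
#'
#' @param X A [spectra_set()] or numeric matrix of predictors.
#' @param y Numeric response vector, one value per row of `X`.
#' @param max_components Maximum number of latent components.
#' @param cv_groups Optional vector (length `nrow(X)`) defining
#'   cross-validation folds; `NULL` skips CV. For a `spectra_set` the
#'   default is its `sample_id` column.
#' @return Object of class `spec_plsr` with centering vectors, `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, per-A `coefficients` (p x A
#'   matrix) and `intercepts`, `rmse_cal`, `rmsecv`, `rmsecv_se`,
#'   `r2_cal`, and `aopt` (selected by [select_aopt()] with the default
#'   relative rule when CV was run, otherwise the RMSE-optimal A).
#' @export
fit_plsr <- function(X, y, max_components = 10, cv_groups = NULL) {
  set <- NULL
  if (inherits(X, "spectra_set")) {
    set <- X
    if (is.null(cv_groups)) cv_groups <- set$meta$sample_id
    X <- set$intensities
  }
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("response has zero variance")
  max_components <- min(max_components, nrow(X) - 1, ncol(X))

  core <- plsr_core(X, y, max_components)
  yhat <- predict_core(core, X)                    # n x A
  resid <- y - yhat
  rmse_cal <- sqrt(colMeans(resid^2))
  r2_cal <- 1 - colSums(resid^2) / sum((y - mean(y))^2)

  rmsecv <- rmsecv_se <- NULL
  if (!is.null(cv_groups)) {
    folds <- split(seq_along(y), cv_groups)
    press <- matrix(NA_real_, length(folds), max_components)
    nout <- lengths(folds)
    for (f in seq_along(folds)) {
      out <- folds[[f]]
      corf <- plsr_core(X[-out, , drop = FALSE], y[-out], max_components)
      pf <- predict_core(corf, X[out, , drop = FALSE])
      press[f, ] <- colSums((y[out] - pf)^2)
    }
    rmsecv <- sqrt(colSums(press) / length(y))
    # fold-level RMSE spread for the one-standard-error rule
    fold_rmse <- sqrt(press / nout)
    rmsecv_se <- apply(fold_rmse, 2, stats::sd) / sqrt(length(folds))
  }

  obj <- structure(list(
    x_center = core$x_center, y_center = core$y_center,
    weights = core$W, x_loadings = core$P, y_loadings = core$q,
    scores = core$T,
    coefficients = core$B, intercepts = core$b0,
    rmse_cal = rmse_cal, r2_cal = r2_cal,
    y = y, fitted_cal = yhat,
    rmsecv = rmsecv, rmsecv_se = rmsecv_se,
    max_components = max_components,
    grid = if (!is.null(set)) set$grid else NULL),
    class = "spec_plsr")
  obj$aopt <- if (is.null(rmsecv)) which.min(rmse_cal)
              else select_aopt(obj)
  obj
}

# NIPALS PLS1 on centered data; returns centers, W/P/q/T and per-A
# coefficient matrix B (p x A) with intercepts b0.
plsr_core <- function(X, y, A) {
  x_center <- colMeans(X); y_center <- mean(y)
  Xd <- sweep(X, 2, x_center); yd <- y - y_center
  p <- ncol(X)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  T <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { A <- a - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pa)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; T[, a] <- t
  }
  if (A < 1) stop("no usable PLS component (X'y vanished)")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]; T <- T[, seq_len(A), drop = FALSE]
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- W[, 1:a, drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa),
                           q[1:a])
  }
  b0 <- y_center - drop(crossprod(x_center, B))
  list(x_center = x_center, y_center = y_center, W = W, P = P, q = q,
       T = T, B = B, b0 = b0, A = A)
}

predict_core <- function(core, Xnew) {
  sweep(Xnew %*% core$B, 2, core$b0, `+`)
}

#' Predict from a fitted PLSR model
#'
#' @param object A `spec_plsr` model.
#' @param newdata A [spectra_set()] or matrix on the same grid.
#' @param ncomp Number of components (default the model's `aopt`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.spec_plsr <- function(object, newdata, ncomp = object$aopt, ...) {
  X <- if (inherits(newdata, "spectra_set")) newdata$intensities
       else as.matrix(newdata)
  stopifnot(ncomp >= 1, ncomp <= ncol(object$coefficients))
  drop(X %*% object$coefficients[, ncomp]) + object$intercepts[ncomp]
}

#' @export
print.spec_plsr <- function(x, ...) {
  cat(sprintf("<spec_plsr> max %d components, AOpt = %d\n",
              x$max_components, x$aopt))
  cat(sprintf("  calibration RMSE at AOpt: %.4g (R2 = %.3f)\n",
              x$rmse_cal[x$aopt], x$r2_cal[x$aopt]))
  if (!is.null(x$rmsecv))
    cat(sprintf("  RMSECV at AOpt: %.4g\n", x$rmsecv[x$aopt]))
  invisible(x)
}

#' @export
residuals.spec_plsr <- function(object, ncomp = object$aopt, ...) {
  object$y - object$fitted_cal[, ncomp]
}

#' Select the optimal number of PLSR components
#'
#' The parsimony rule: the smallest number of components whose
#' cross-validated RMSE is only insignificantly higher than the global
#' minimum. Under `rule = "relative"` (default) "insignificant" means
#' within a fraction `tau` of the minimum RMSECV; `rule = "one_se"` uses
#' the one-standard-error rule (smallest A with
#' `RMSECV <= min + SE[argmin]`).
#'
#' @param model A `spec_plsr` with cross-validation results, or a numeric
#'   RMSECV vector.
#' @param rule `"relative"` or `"one_se"`.
#' @param tau Relative tolerance for `rule = "relative"` (default 0.05).
#' @param se RMSECV standard errors (needed for `"one_se"` when `model`
#'   is a plain vector).
#' @return Integer: the selected number of components.
#' @export
select_aopt <- function(model, rule = c("relative", "one_se"), tau = 0.05,
                        se = NULL) {
  rule <- match.arg(rule)
  if (inherits(model, "spec_plsr")) {
    rmsecv <- model$rmsecv; se <- model$rmsecv_se
  } else rmsecv <- as.numeric(model)
  if (is.null(rmsecv)) stop("no cross-validation results present")
  amin <- which.min(rmsecv)
  thresh <- if (rule == "relative") (1 + tau) * rmsecv[amin]
            else {
              if (is.null(se)) stop("one_se rule needs RMSECV standard errors")
              rmsecv[amin] + se[amin]
            }
  as.integer(which(rmsecv <= thresh)[1])
}
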