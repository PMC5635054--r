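#' Assemble the first-level design matrix
#'
#' Columns `[alpha, artifact, constant]`; alpha and artifact are
#' mean-centered. A degenerate (all-zero) artifact regressor is dropped
#' with a warning; collinear predictors raise an error naming the columns.
#'
#' @param alpha the alpha-power [fmri_regressor()].
#' @param artifact the artifact nuisance [fmri_regressor()] (optional).
#' @return object of class `design_matrix` with fields `X` (volumes x
#'   predictors), `volume_onsets`, `rank`.
#' @export
build_design <- function(alpha, artifact = NULL) {
  stopifnot(inherits(alpha, "fmri_regressor"))
  a <- alpha$values - mean(alpha$values)
  if (stats::sd(a) < 1e-12)
    stop("alpha regressor is constant", call. = FALSE)
  cols <- list(alpha = a)
  if (!is.null(artifact)) {
    stopifnot(inherits(artifact, "fmri_regressor"))
    if (length(artifact$values) != length(a))
      stop("alpha and artifact regressors differ in length", call. = FALSE)
    b <- artifact$values - mean(artifact$values)
    if (stats::sd(b) < 1e-12) {
      warning("artifact regressor is constant; column dropped", call. = FALSE)
    } else cols$artifact <- b
  }
  cols$constant <- rep(1, length(a))
  X <- do.call(cbind, cols)
  r <- qr(X)$rank
  if (r < ncol(X)) {
    cc <- stats::cor(X[, setdiff(colnames(X), "constant"), drop = FALSE])
    bad <- which(abs(cc) > 1 - 1e-10 & row(cc) < col(cc), arr.ind = TRUE)
    nm <- if (nrow(bad)) paste(rownames(cc)[bad[1, 1]], colnames(cc)[bad[1, 2]],
                               sep = " ~ ") else "unknown"
    stop("design matrix is rank deficient (collinear columns: ", nm, ")",
         call. = FALSE)
  }
  structure(list(X = X, volume_onsets = alpha$volume_onsets, rank = r),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d predictors [%s], rank %d\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              x$rank))
  invisible(x)
}

#' Voxel-wise ordinary least squares GLM
#'
#' Fits `y = X beta + e` independently at every in-mask voxel.
#'
#' @param bold a [bold_series()] with as many volumes as design rows.
#' @param design a [build_design()] result.
#' @param mask optional logical 3D array; default all voxels.
#' @param df_drop additional degrees of freedom already spent outside the
#'   design (e.g. temporal drift dimensions removed by [highpass_time()]);
#'   subtracted from the residual df.
#' @return object of class `glm_fit`: `beta` (predictors x voxels),
#'   `sigma2`, `df`, `xtx_inv`, `mask`, `grid_shape`, `voxel_size`.
#' @export
fit_glm <- function(bold, design, mask = NULL, df_drop = 0) {
  stopifnot(inherits(bold, "bold_series"), inherits(design, "design_matrix"))
  d <- dim(bold$data)
  if (d[4] != nrow(design$X))
    stop("number of volumes does not match design rows", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!all(dim(mask) == d[1:3]))
    stop("mask does not match the voxel grid", call. = FALSE)
  df <- d[4] - design$rank - df_drop
  if (df <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  Y <- t(matrix(bold$data, prod(d[1:3]), d[4]))[, as.logical(mask), drop = FALSE]
  X <- design$X
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  # voxels fitted exactly (e.g. constant time courses) leave only rounding
  # noise in the residual: treat as zero variance, not as a tiny sigma2
  sigma2[sigma2 <= 1e-20 * pmax(colMeans(Y^2), .Machine$double.xmin)] <- 0
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, df = df, xtx_inv = xtx_inv,
                 design = design, mask = as.logical(mask),
                 grid_shape = d[1:3], voxel_size = bold$voxel_size),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d voxels, predictors [%s], df = %d\n",
              ncol(x$beta), paste(rownames(x$beta), collapse = ", "), x$df))
  invisible(x)
}

#' Extract a coefficient map from a fitted GLM
#'
#' @param fit a [fit_glm()] result.
#' @param predictor predictor name (e.g. `"alpha"`).
#' @return 3D array, `NA` outside the mask.
#' @export
beta_map <- function(fit, predictor = "alpha") {
  stopifnot(predictor %in% rownames(fit$beta))
  out <- array(NA_real_, fit$grid_shape)
  out[fit$mask] <- fit$beta[predictor, ]
  out
}

#' Statistical parametric map
#'
#' @param values 3D array of t statistics (`NA`/`NaN` outside the mask or
#'   at zero-variance voxels).
#' @param df residual degrees of freedom.
#' @param contrast contrast label.
#' @param band band name (optional).
#' @param voxel_size voxel edge, mm (optional, for mm peak coordinates).
#' @return object of class `stat_map`.
#' @export
stat_map <- function(values, df, contrast, band = NA_character_,
                     voxel_size = NA_real_) {
  stopifnot(length(dim(values)) == 3, df > 0)
  structure(list(values = values, df = df, contrast = contrast, band = band,
                 voxel_size = voxel_size),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> '%s'%s, df = %g, %d finite voxels\n", x$contrast,
              if (!is.na(x$band)) paste0(" [", x$band, "]") else "",
              x$df, sum(is.finite(x$values))))
  invisible(x)
}

#' @export
plot.stat_map <- function(x, z = ceiling(dim(x$values)[3] / 2), ...) {
  graphics::image(x$values[, , z], main = sprintf("%s (z = %d)", x$contrast, z),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' t contrast of a fitted GLM
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)`. Zero-variance voxels give
#' `NaN`; their count is recorded as attribute `n_zero_variance`.
#'
#' @param fit a [fit_glm()] result.
#' @param contrast numeric contrast vector, one weight per predictor.
#' @param label contrast label (default built from the weights).
#' @param band band name carried into the map.
#' @return a [stat_map()].
#' @export
t_contrast <- function(fit, contrast, label = NULL, band = NA_character_) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$beta)
  if (length(contrast) != p)
    stop("contrast length must equal the number of predictors", call. = FALSE)
  if (all(contrast == 0)) stop("contrast is all zeros", call. = FALSE)
  num <- as.numeric(contrast %*% fit$beta)
  quad <- as.numeric(t(contrast) %*% fit$xtx_inv %*% contrast)
  tvals <- ifelse(fit$sigma2 > 0, num / sqrt(fit$sigma2 * quad), NaN)
  out <- array(NA_real_, fit$grid_shape)
  out[fit$mask] <- tvals
  if (is.null(label))
    label <- paste0(rownames(fit$beta)[contrast != 0], collapse = "+")
  sm <- stat_map(out, fit$df, label, band, fit$voxel_size)
  attr(sm, "n_zero_variance") <- sum(fit$sigma2 == 0)
  sm
}

#' Tidy a fitted voxel-wise GLM
#'
#' @param x a `glm_fit`.
#' @param ... unused.
#' @return tibble with one row per predictor: mean, sd and range of the
#'   coefficient over in-mask voxels.
#' @export
tidy.glm_fit <- function(x, ...) {
  tibble::tibble(
    term = rownames(x$beta),
    estimate_mean = rowMeans(x$beta),
    estimate_sd = apply(x$beta, 1, stats::sd),
    estimate_min = apply(x$beta, 1, min),
    estimate_max = apply(x$beta, 1, max)
  )
}

#' Glance at a fitted voxel-wise GLM
#' @param x a `glm_fit`.
#' @param ... unused.
#' @return one-row tibble: voxel count, df, median residual variance.
#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(n_voxels = ncol(x$beta), df = x$df,
                 sigma2_median = stats::median(x$sigma2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a statistical map
#' @param x a `stat_map`.
#' @param ... unused.
#' @return tibble with voxel indices and t values for finite voxels.
#' @export
tidy.stat_map <- function(x, ...) {
  idx <- which(is.finite(x$values), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                 t = x$values[idx])
}
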