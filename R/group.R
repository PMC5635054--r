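#' Gray-matter inclusion mask
#'
#' @param prob_map 3D array of tissue probabilities in `[0, 1]`.
#' @param thresh inclusion threshold: a voxel is in the mask iff its
#'   probability is >= `thresh` (default 0.3).
#' @return logical 3D array.
#' @export
make_gm_mask <- function(prob_map, thresh = 0.3) {
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  m <- !is.na(prob_map) & prob_map >= thresh
  if (!any(m)) stop("gray-matter mask is empty", call. = FALSE)
  m
}

# stack a list of 3D maps into subjects x voxels over jointly finite voxels
stack_maps <- function(maps) {
  v <- vapply(maps, function(m) as.numeric(m), numeric(length(maps[[1]])))
  Y <- t(v)
  ok <- colSums(!is.finite(Y)) == 0
  list(Y = Y, ok = ok, grid = dim(maps[[1]]))
}

# voxelwise regression returning the t map for one coefficient
voxelwise_t <- function(Y, X, coef_index, df) {
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se2 <- sigma2 * xtx_inv[coef_index, coef_index]
  num <- beta[coef_index, ]
  t <- ifelse(se2 > 0, num / sqrt(se2),
              ifelse(abs(num) > 0, sign(num) * Inf, 0))
  list(t = t, zero_var = se2 == 0 & abs(num) > 0)
}

center_covars <- function(covars, n) {
  if (is.null(covars)) return(NULL)
  C <- as.matrix(covars)
  stopifnot(nrow(C) == n, all(is.finite(C)))
  sweep(C, 2, colMeans(C))
}

#' Second-level one-sample t-test map
#'
#' Per voxel, the intercept t from regressing subject values on a constant
#' and (mean-centered) covariates. Zero-variance voxels with a nonzero
#' mean are reported as a signed infinity sentinel and flagged via
#' attribute `n_zero_variance`.
#'
#' @param maps list (>= 3) of per-subject 3D coefficient maps.
#' @param covars optional per-subject covariate data frame / matrix.
#' @param contrast label for the resulting map.
#' @param band band name.
#' @param voxel_size voxel edge, mm.
#' @return a [stat_map()] with `df = n - 1 - n_covars`.
#' @export
one_sample_t <- function(maps, covars = NULL, contrast = "one-sample",
                         band = NA_character_, voxel_size = NA_real_) {
  n <- length(maps)
  if (n < 3) stop("need at least 3 maps", call. = FALSE)
  st <- stack_maps(maps)
  C <- center_covars(covars, n)
  X <- cbind(intercept = rep(1, n), C)
  df <- n - ncol(X)
  if (df <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  fit <- voxelwise_t(st$Y[, st$ok, drop = FALSE], X, 1L, df)
  out <- array(NA_real_, st$grid)
  out[st$ok] <- fit$t
  sm <- stat_map(out, df, contrast, band, voxel_size)
  attr(sm, "n_zero_variance") <- sum(fit$zero_var)
  sm
}

#' Second-level two-sample t-test map
#'
#' Per voxel, the group-difference t (group A minus group B) from
#' regressing subject values on a group indicator, a constant and
#' (mean-centered across all subjects) covariates, with pooled residual
#' variance.
#'
#' @param maps_a,maps_b lists of per-subject 3D maps (>= 2 each); the
#'   resulting t is positive where group A exceeds group B (pass HC as
#'   `maps_a` for an HC > AD contrast).
#' @param covars optional covariates, subjects of A then B row-wise.
#' @param contrast,band,voxel_size metadata carried into the map.
#' @return a [stat_map()] with `df = n - 2 - n_covars`.
#' @export
two_sample_t <- function(maps_a, maps_b, covars = NULL,
                         contrast = "A>B", band = NA_character_,
                         voxel_size = NA_real_) {
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 maps", call. = FALSE)
  st <- stack_maps(c(maps_a, maps_b))
  n <- na + nb
  C <- center_covars(covars, n)
  g <- c(rep(0.5, na), rep(-0.5, nb))        # coefficient = mean A - mean B
  X <- cbind(group = g, intercept = rep(1, n), C)
  df <- n - ncol(X)
  if (df <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  fit <- voxelwise_t(st$Y[, st$ok, drop = FALSE], X, 1L, df)
  out <- array(NA_real_, st$grid)
  out[st$ok] <- fit$t
  sm <- stat_map(out, df, contrast, band, voxel_size)
  attr(sm, "n_zero_variance") <- sum(fit$zero_var)
  sm
}

neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d1 <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d1 == 1, "18" = d1 >= 1 & d1 <= 2, "26" = d1 >= 1)
  as.matrix(g[keep, ])
}

#' Label connected components of a 3D binary mask
#'
#' Builds the adjacency graph of active voxels at the requested
#' connectivity and labels its connected components (via igraph).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (+ corners).
#' @return integer 3D array of component labels (0 = background), labels
#'   ordered by decreasing component size.
#' @export
label_components <- function(mask, connectivity = 18) {
  off <- neighbor_offsets(connectivity)
  d <- dim(mask)
  act <- which(mask)
  lab <- array(0L, d)
  if (!length(act)) return(lab)
  pos <- arrayInd(act, d)
  id <- integer(prod(d))
  id[act] <- seq_along(act)
  # half of the offsets suffice for an undirected edge list
  half <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(half))) {
    np <- sweep(pos, 2, half[r, ], `+`)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nl <- np[ok, 1] + (np[ok, 2] - 1) * d[1] + (np[ok, 3] - 1) * d[1] * d[2]
    src <- which(ok)[id[nl] > 0]
    if (!length(src)) next
    nl <- nl[id[nl] > 0]
    edges <- rbind(edges, cbind(src, id[nl]))
  }
  g <- igraph::make_empty_graph(n = length(act), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # relabel by decreasing size, ties by smallest member index
  sizes <- comp$csize
  ord <- order(-sizes, vapply(seq_along(sizes), function(cc)
    min(act[comp$membership == cc]), numeric(1)))
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(sizes)
  lab[act] <- relab[comp$membership]
  lab
}

#' Cluster-extent thresholding of a statistical map
#'
#' Thresholds at the one-sided p-quantile of Student's t with the map's
#' df, labels suprathreshold connected components, and keeps those of at
#' least `k` voxels.
#'
#' @param map a [stat_map()] (threshold is applied to positive t; negate
#'   the map or use the negative contrast for the other direction).
#' @param p one-sided uncorrected p threshold (default 0.01).
#' @param k minimum cluster size in voxels (default 50).
#' @param connectivity 6, 18 or 26 (default 18).
#' @param mask optional logical 3D inclusion mask applied before labeling.
#' @param sign label recorded per cluster (`"positive"`/`"negative"`).
#' @return tibble with one row per retained cluster: `cluster_id`, `size`,
#'   `peak_t`, `i/j/k` voxel peak, `x/y/z_mm`, `sign`, `band`; sorted by
#'   size then peak t (descending). The full suprathreshold label array is
#'   attached as attribute `labels`.
#' @export
threshold_clusters <- function(map, p = 0.01, k = 50, connectivity = 18,
                               mask = NULL, sign = "positive") {
  stopifnot(inherits(map, "stat_map"))
  t_thr <- stats::qt(1 - p, df = map$df)
  vals <- map$values
  supra <- is.finite(vals) & vals > t_thr
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(vals)))
    supra <- supra & mask
  }
  lab <- label_components(supra, connectivity)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  rows <- lapply(ids, function(cc) {
    vox <- which(lab == cc)
    size <- length(vox)
    if (size < k) return(NULL)
    pk <- vox[which.max(vals[vox])]
    pc <- arrayInd(pk, dim(vals))
    tibble::tibble(cluster_id = cc, size = size, peak_t = vals[pk],
                   i = pc[1], j = pc[2], k = pc[3],
                   x_mm = (pc[1] - 1) * map$voxel_size,
                   y_mm = (pc[2] - 1) * map$voxel_size,
                   z_mm = (pc[3] - 1) * map$voxel_size,
                   sign = sign, band = map$band)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- tibble::tibble(cluster_id = integer(), size = integer(),
                          peak_t = numeric(), i = integer(), j = integer(),
                          k = integer(), x_mm = numeric(), y_mm = numeric(),
                          z_mm = numeric(), sign = character(),
                          band = character())
  ord <- order(-out$size, -out$peak_t, out$i, out$j, out$k)
  out <- out[ord, ]
  keep_lab <- array(0L, dim(vals))
  for (cc in out$cluster_id) keep_lab[lab == cc] <- cc
  attr(out, "labels") <- keep_lab
  attr(out, "t_threshold") <- t_thr
  out
}

#' Overlap of thresholded clusters with an atlas mask
#'
#' Quantitative stand-in for visual atlas comparison: per cluster, the
#' fraction of its voxels inside the atlas and the Dice coefficient.
#'
#' @param clusters a [threshold_clusters()] table (with its `labels`
#'   attribute).
#' @param atlas_mask logical 3D array on the same grid.
#' @return tibble: `cluster_id`, `size`, `overlap_frac`, `dice`.
#' @export
atlas_overlap <- function(clusters, atlas_mask) {
  lab <- attr(clusters, "labels")
  if (is.null(lab)) stop("clusters table lacks its label array", call. = FALSE)
  if (!all(dim(lab) == dim(atlas_mask)))
    stop("atlas grid does not match the cluster grid", call. = FALSE)
  n_atlas <- sum(atlas_mask)
  rows <- lapply(seq_len(nrow(clusters)), function(r) {
    cc <- clusters$cluster_id[r]
    vox <- lab == cc
    inter <- sum(vox & atlas_mask)
    tibble::tibble(cluster_id = cc, size = clusters$size[r],
                   overlap_frac = inter / sum(vox),
                   dice = 2 * inter / (sum(vox) + n_atlas))
  })
  if (!length(rows))
    return(tibble::tibble(cluster_id = integer(), size = integer(),
                          overlap_frac = numeric(), dice = numeric()))
  do.call(rbind, rows)
}

#' Count subjects with suprathreshold first-level voxels inside ROIs
#'
#' A subject counts as a hit for an ROI if any voxel of their first-level
#' map exceeds the one-sided p threshold inside the ROI mask.
#'
#' @param subject_maps tibble with columns `subject_id`, `group`, `band`,
#'   `map` (list column of [stat_map()]s).
#' @param roi_masks named list of logical 3D ROI masks (e.g. DMN and
#'   thalamus).
#' @param p one-sided uncorrected p threshold (default 0.01).
#' @return tibble: `group` x `band` x `roi` with column `n_subjects`.
#' @export
count_first_level_hits <- function(subject_maps, roi_masks, p = 0.01) {
  stopifnot(all(c("subject_id", "group", "band", "map") %in%
                  names(subject_maps)))
  for (nm in names(roi_masks))
    if (!any(roi_masks[[nm]])) stop("ROI mask '", nm, "' is empty",
                                    call. = FALSE)
  grid <- expand.grid(group = unique(subject_maps$group),
                      band = unique(subject_maps$band),
                      roi = names(roi_masks), stringsAsFactors = FALSE)
  counts <- vapply(seq_len(nrow(grid)), function(r) {
    sel <- subject_maps$group == grid$group[r] &
      subject_maps$band == grid$band[r]
    maps <- subject_maps$map[sel]
    roi <- roi_masks[[grid$roi[r]]]
    sum(vapply(maps, function(m) {
      thr <- stats::qt(1 - p, df = m$df)
      any(m$values[roi] > thr, na.rm = TRUE)
    }, logical(1)))
  }, numeric(1))
  tibble::tibble(group = grid$group, band = grid$band, roi = grid$roi,
                 n_subjects = as.integer(counts))
}

#' Two-sided pooled-variance two-sample t-test
#'
#' Sample-based and summary-statistic variants of the classical
#' independent-samples t-test with pooled variance,
#' `df = n_a + n_b - 2`.
#'
#' @param values_a,values_b numeric samples (>= 2 each).
#' @param two_sided two-sided p (default) or one-sided (greater, A > B).
#' @return one-row tibble: `t`, `df`, `p`.
#' @export
compare_scalars <- function(values_a, values_b, two_sided = TRUE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  compare_scalars_summary(mean(values_a), stats::sd(values_a),
                          length(values_a),
                          mean(values_b), stats::sd(values_b),
                          length(values_b), two_sided)
}

#' @rdname compare_scalars
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b printed group moments.
#' @export
compare_scalars_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                    two_sided = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  diff <- mean_a - mean_b
  if (se == 0) {
    if (diff == 0) return(tibble::tibble(t = 0, df = df, p = 1))
    return(tibble::tibble(t = sign(diff) * Inf, df = df, p = 0))
  }
  t <- diff / se
  p <- if (two_sided) 2 * stats::pt(-abs(t), df) else stats::pt(-t, df)
  tibble::tibble(t = t, df = df, p = p)
}
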