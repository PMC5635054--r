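rand_maps <- function(n, gs = c(4, 4, 4), seed = 1, shift = 0)
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    array(rnorm(prod(gs)) + shift, gs)))

test_that("gray-matter mask thresholds inclusively at 0.3", {
  p <- array(0.5, c(3, 3, 3))
  p[1, 1, 1] <- 0.31; p[2, 1, 1] <- 0.29; p[3, 1, 1] <- 0.30
  m <- make_gm_mask(p, 0.3)
  expect_true(m[1, 1, 1]); expect_false(m[2, 1, 1]); expect_true(m[3, 1, 1])
  expect_true(all(make_gm_mask(array(1, c(2, 2, 2)))))
  expect_true(all(make_gm_mask(array(0.01, c(2, 2, 2)), 0)))
  expect_error(make_gm_mask(array(0.1, c(2, 2, 2)), 0.3), "empty")
  expect_error(make_gm_mask(array(1.5, c(2, 2, 2))), "probabilities")
})

test_that("one-sample t map: symmetry, sentinels, covariate oracle", {
  gs <- c(2, 2, 2)
  # values symmetric about zero at every voxel -> t = 0
  m1 <- array(1, gs); m2 <- array(-1, gs)
  sm <- one_sample_t(list(m1, m2, m1, m2))
  expect_equal(max(abs(sm$values)), 0)
  expect_equal(sm$df, 3)

  # all equal nonzero constant -> +Inf sentinel, flagged
  mc <- array(2, gs)
  smc <- one_sample_t(list(mc, mc, mc))
  expect_true(all(smc$values == Inf))
  expect_gt(attr(smc, "n_zero_variance"), 0)

  # random fixture with one covariate matches the regression oracle
  maps <- rand_maps(8, gs, seed = 11)
  cov1 <- withr::with_seed(12, data.frame(age = rnorm(8, 70, 5)))
  sm2 <- one_sample_t(maps, covars = cov1)
  expect_equal(sm2$df, 8 - 2)
  y <- vapply(maps, function(m) m[1, 2, 1], numeric(1))
  Xo <- cbind(1, cov1$age - mean(cov1$age))
  o <- oracle_ols(Xo, y, df = 6)
  expect_equal(sm2$values[1, 2, 1], o$t[1], tolerance = 1e-8)

  expect_error(one_sample_t(rand_maps(2)), "at least 3")
})

test_that("two-sample t map: null, textbook oracle, antisymmetry, covariates", {
  gs <- c(3, 3, 2)
  a <- rand_maps(5, gs, seed = 1)
  # identical groups -> exactly zero
  sm0 <- two_sample_t(a, a)
  expect_equal(max(abs(sm0$values)), 0)
  expect_equal(sm0$df, 8)

  b <- rand_maps(6, gs, seed = 2, shift = 0.5)
  sm <- two_sample_t(a, b)
  # classical pooled two-sample t at every voxel
  for (v in c(1, 7, 18)) {
    idx <- arrayInd(v, gs)
    ya <- vapply(a, function(m) m[idx], numeric(1))
    yb <- vapply(b, function(m) m[idx], numeric(1))
    tt <- compare_scalars(ya, yb)
    expect_equal(sm$values[idx], tt$t, tolerance = 1e-8)
  }
  # swapping the groups negates the map
  sm_rev <- two_sample_t(b, a)
  expect_equal(sm_rev$values, -sm$values, tolerance = 1e-10)

  # covariates orthogonal to the group indicator leave the map unchanged
  g <- c(rep(0.5, 5), rep(-0.5, 6))
  cv <- data.frame(x = rep(c(-1, 1), length.out = 11))
  cv$x <- unname(resid(lm(cv$x ~ g)))   # orthogonal to intercept and group
  sm_cv <- two_sample_t(a, b, covars = cv)
  for (v in c(3, 12)) {
    idx <- arrayInd(v, gs)
    y <- c(vapply(a, function(m) m[idx], numeric(1)),
           vapply(b, function(m) m[idx], numeric(1)))
    o <- oracle_ols(cbind(g, 1, cv$x), y, df = 11 - 3)
    # adjusted t matches the oracle with the covariate included
    expect_equal(sm_cv$values[idx], o$t[1], tolerance = 1e-8)
    # and the group-difference estimate is untouched by an orthogonal
    # covariate (only the residual df changes)
    o0 <- oracle_ols(cbind(g, 1), y, df = 11 - 2)
    expect_equal(o$beta[1], o0$beta[1], tolerance = 1e-8)
  }
})

test_that("cluster thresholding enforces extent, emptiness, connectivity", {
  gs <- c(12, 12, 12)
  df <- 20
  t_hi <- stats::qt(1 - 0.005, df)   # safely above the p = 0.01 cut
  base <- array(0, gs)

  # 49 suprathreshold voxels -> discarded at k = 50, kept at k = 49
  m49 <- base; m49[1:7, 1:7, 1] <- t_hi              # 49-voxel slab
  sm49 <- stat_map(m49, df, "c", voxel_size = 3.5)
  expect_equal(nrow(threshold_clusters(sm49, 0.01, k = 49)), 1)
  expect_equal(nrow(threshold_clusters(sm49, 0.01, k = 50)), 0)
  m50 <- base; m50[1:10, 1:5, 1] <- t_hi             # exactly 50
  sm50 <- stat_map(m50, df, "c", voxel_size = 3.5)
  tab <- threshold_clusters(sm50, 0.01, k = 50)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 50)

  # no suprathreshold voxels -> empty table
  expect_equal(nrow(threshold_clusters(stat_map(base, df, "c"), 0.01, 1)), 0)

  # two voxels sharing only an edge: one cluster at 18, two at 6
  m2 <- base; m2[3, 3, 3] <- t_hi; m2[4, 4, 3] <- t_hi
  sm2 <- stat_map(m2, df, "c")
  expect_equal(nrow(threshold_clusters(sm2, 0.01, k = 1, connectivity = 18)), 1)
  expect_equal(nrow(threshold_clusters(sm2, 0.01, k = 1, connectivity = 6)), 2)
  expect_error(threshold_clusters(sm2, 0.01, 1, connectivity = 10),
               "connectivity")

  # peak and ordering metadata
  m3 <- base
  m3[1:5, 1:5, 1:2] <- t_hi; m3[3, 3, 1] <- t_hi + 2      # 50-voxel cluster
  m3[8:12, 8:12, 5:8] <- t_hi + 1                         # 100-voxel cluster
  tab3 <- threshold_clusters(stat_map(m3, df, "c", voxel_size = 3.5), 0.01, 50)
  expect_equal(tab3$size, c(100, 50))
  expect_equal(tab3$i[2], 3)
  expect_equal(tab3$x_mm[2], (3 - 1) * 3.5)
})

test_that("atlas overlap: containment, disjointness, half overlap", {
  gs <- c(10, 10, 10)
  df <- 15
  m <- array(0, gs); m[2:5, 2:5, 2:5] <- 10          # 64-voxel cluster
  cl <- threshold_clusters(stat_map(m, df, "c", voxel_size = 3.5), 0.01, 10)
  inside <- array(FALSE, gs); inside[1:6, 1:6, 1:6] <- TRUE
  expect_equal(atlas_overlap(cl, inside)$overlap_frac, 1)
  disjoint <- array(FALSE, gs); disjoint[8:10, 8:10, 8:10] <- TRUE
  expect_equal(atlas_overlap(cl, disjoint)$overlap_frac, 0)
  half <- array(FALSE, gs); half[2:5, 2:5, 2:3] <- TRUE   # half the cluster
  ov <- atlas_overlap(cl, half)
  expect_equal(ov$overlap_frac, 0.5)
  expect_equal(ov$dice, 2 * 32 / (64 + 32))
  expect_error(atlas_overlap(cl, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("first-level hit counting over groups, bands and ROIs", {
  gs <- c(6, 6, 6)
  df <- 100
  roi <- list(DMN = array(FALSE, gs), thalamus = array(FALSE, gs))
  roi$DMN[1:3, 1:3, 1:3] <- TRUE
  roi$thalamus[5:6, 5:6, 5:6] <- TRUE
  hot <- function(in_roi) {
    m <- array(0, gs)
    if (in_roi) m[2, 2, 2] <- 10
    stat_map(m, df, "alpha+")
  }
  tbl <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:10),
    group = rep(c("AD", "HC"), each = 5),
    band = "total_alpha",
    map = c(lapply(rep(FALSE, 5), hot), lapply(c(TRUE, TRUE, TRUE, FALSE,
                                                 FALSE), hot)))
  out <- count_first_level_hits(tbl, roi)
  expect_equal(nrow(out), 2 * 1 * 2)
  expect_equal(out$n_subjects[out$group == "HC" & out$roi == "DMN"], 3L)
  expect_equal(sum(out$n_subjects[out$group == "AD"]), 0L)
  expect_equal(sum(out$n_subjects[out$roi == "thalamus"]), 0L)

  # full demonstration geometry: 2 groups x 3 bands x 2 ROIs
  tbl3 <- do.call(rbind, lapply(names(alpha_bands()), function(b) {
    t2 <- tbl; t2$band <- b; t2
  }))
  expect_equal(nrow(count_first_level_hits(tbl3, roi)), 12)
  expect_error(count_first_level_hits(tbl, list(DMN = array(FALSE, gs))),
               "empty")
})

test_that("scalar group comparison matches the textbook pooled t", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  r <- compare_scalars(a, b)
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_equal(r$df, 6)

  set.seed(20)
  x <- rnorm(14); y <- rnorm(14, 0.5)
  r2 <- compare_scalars(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r2$df, unname(tt$parameter))

  # summary-statistic variant agrees with the sample variant
  r3 <- compare_scalars_summary(mean(x), sd(x), 14, mean(y), sd(y), 14)
  expect_equal(r3$t, r2$t, tolerance = 1e-12)

  # degenerate cases
  expect_equal(compare_scalars(c(2, 2), c(2, 2))$p, 1)
  expect_equal(compare_scalars(c(3, 3), c(2, 2))$t, Inf)
})
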