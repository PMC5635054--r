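stage <- function(name, subject_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s | %s] %s", subject_id, name, conditionMessage(e)),
         call. = FALSE))
}

#' Subject-level EEG-fMRI analysis
#'
#' Runs the full first-level chain for one subject: EEG cleaning
#' (decimation, gradient and pulse average-artifact subtraction, band
#' filters, optional ICA proxy), occipital pooling, complex-demodulation
#' band power in 1-s segments, HRF-convolved alpha and artifact
#' regressors, BOLD preprocessing (volume dropping, smoothing,
#' discrete-cosine high-pass), and a voxel-wise GLM with positive and
#' negative alpha t-contrasts per band.
#'
#' @param eeg an [eeg_recording()] with scanner markers and an ECG channel.
#' @param bold the subject's [bold_series()].
#' @param bands list of [band()]s (default the three alpha bands).
#' @param subject_id identifier used in error messages and reports.
#' @param target_fs EEG working sampling rate after decimation, Hz.
#' @param n_avg sliding-window width (epochs) for artifact templates.
#' @param drop_k initial volumes removed.
#' @param fwhm_mm spatial smoothing kernel, mm.
#' @param hp_cutoff_s temporal high-pass cutoff period, s.
#' @param do_bcg,do_ica stage toggles for pulse-artifact subtraction and
#'   the ICA proxy.
#' @param mask optional logical 3D analysis mask for the GLM.
#' @param seed seed for the ICA initialization.
#' @return list with `maps` (tibble: band, sign, list-column `map`),
#'   `alpha_beta` (named list of 3D coefficient arrays per band),
#'   `relative_power` (tibble band/value), `artifact_mask`, `report`.
#' @export
run_first_level <- function(eeg, bold, bands = alpha_bands(),
                            subject_id = "subject", target_fs = 250,
                            n_avg = 21, drop_k = 6, fwhm_mm = 8,
                            hp_cutoff_s = 128, do_bcg = TRUE,
                            do_ica = FALSE, mask = NULL, seed = 1L) {
  rec <- eeg
  if (rec$fs > target_fs)
    rec <- stage("decimate", subject_id, decimate_eeg(rec, target_fs))
  onsets <- stage("epoch_onsets", subject_id,
                  epoch_onsets_from_markers(rec, "Scanner"))
  tr <- bold$tr
  rec <- stage("aas_subtract", subject_id,
               aas_subtract(rec, onsets, epoch_len = tr, n_avg = n_avg))
  if (do_bcg) {
    rec <- stage("bcg_subtract", subject_id, {
      ecg <- get_channel(rec, "ECG")
      peaks <- detect_r_peaks(ecg, rec$fs)
      bcg_subtract(rec, peaks, n_avg = n_avg)
    })
  }
  rec <- stage("filter", subject_id, filter_eeg(rec))
  if (do_ica)
    rec <- stage("ica_autoclean", subject_id, ica_autoclean(rec, seed = seed))
  rec <- stage("rereference", subject_id, rereference_common_average(rec))
  pooled <- stage("pool_occipital", subject_id, pool_occipital(rec))
  amask <- stage("mark_artifacts", subject_id,
                 mark_artifacts(as.numeric(pooled), rec$fs))

  bold_p <- stage("fmri_prep", subject_id, {
    b <- drop_initial_volumes(bold, drop_k)
    b <- gaussian_smooth(b, fwhm_mm)
    highpass_time(b, hp_cutoff_s)
  })
  n_drift <- attr(bold_p, "n_drift")
  all_onsets <- bold$volume_onsets
  hrf <- canonical_hrf()
  art_reg <- build_artifact_regressor(amask, all_onsets, tr, drop_k)

  maps <- list(); betas <- list(); relpow <- list()
  for (b in bands) {
    dp <- stage(paste0("demodulate_", b$name), subject_id,
                complex_demodulate(as.numeric(pooled), rec$fs, b))
    ps <- segment_power(dp, mask = amask)
    alpha_reg <- stage(paste0("regressor_", b$name), subject_id,
                       build_alpha_regressor(ps, hrf, all_onsets, drop_k))
    alpha_f <- highpass_time(alpha_reg, hp_cutoff_s, tr)
    # a session without flagged artifacts has no nuisance column to model
    art_f <- if (stats::sd(art_reg$values) > 0)
      highpass_time(art_reg, hp_cutoff_s, tr) else NULL
    X <- stage(paste0("design_", b$name), subject_id,
               build_design(alpha_f, art_f))
    fit <- stage(paste0("glm_", b$name), subject_id,
                 fit_glm(bold_p, X, mask = mask, df_drop = n_drift))
    cvec <- c(1, rep(0, ncol(X$X) - 1))
    pos <- t_contrast(fit, cvec, label = "alpha+", band = b$name)
    neg <- t_contrast(fit, -cvec, label = "alpha-", band = b$name)
    maps[[b$name]] <- list(pos = pos, neg = neg)
    betas[[b$name]] <- beta_map(fit, "alpha")
    relpow[[b$name]] <- fft_relative_power(as.numeric(pooled), rec$fs, b)
  }
  map_tbl <- do.call(rbind, lapply(names(maps), function(nm) {
    tibble::tibble(band = nm, sign = c("positive", "negative"),
                   map = list(maps[[nm]]$pos, maps[[nm]]$neg))
  }))
  list(
    subject_id = subject_id,
    maps = map_tbl,
    alpha_beta = betas,
    relative_power = tibble::tibble(band = names(relpow),
                                    value = unlist(relpow)),
    artifact_mask = amask,
    report = list(history = rec$history, n_drift = n_drift,
                  n_volumes_retained = dim(bold_p$data)[4])
  )
}

#' Group-level inference over first-level results
#'
#' For each band: one-sample t maps per group and the HC > AD two-sample
#' map, for positive and negative associations, each with demographic
#' covariates (age, gender, education) and optionally also normalized
#' hippocampal volume; cluster-extent thresholding inside the gray-matter
#' mask; ROI hit counts per subject; and scalar group comparisons of
#' relative alpha power and hippocampal volume.
#'
#' @param first_levels list of [run_first_level()] results, one per
#'   subject, in the order of `covariates`.
#' @param covariates tibble with `subject_id`, `group` (`AD`/`HC`),
#'   `age`, `gender`, `education`, `hippo_norm`.
#' @param gm_mask logical 3D gray-matter inclusion mask.
#' @param roi_masks optional named list of ROI masks for hit counting.
#' @param p,k,connectivity cluster thresholding parameters.
#' @param voxel_size voxel edge, mm (for cluster coordinates).
#' @param use_demographics include age/gender/education as second-level
#'   covariates.
#' @return list with `stat_maps` (tibble: band, analysis, sign,
#'   hippo_covariate, map, clusters), `hit_counts`, `scalar_tests`.
#' @export
run_group <- function(first_levels, covariates, gm_mask, roi_masks = NULL,
                      p = 0.01, k = 50, connectivity = 18, voxel_size = 3.5,
                      use_demographics = TRUE) {
  stopifnot(length(first_levels) == nrow(covariates))
  grp <- covariates$group
  if (sum(grp == "AD") < 2 || sum(grp == "HC") < 2)
    stop("need at least 2 completed subjects per group", call. = FALSE)
  bands <- names(first_levels[[1]]$alpha_beta)
  demog <- if (use_demographics)
    covariates[, c("age", "gender", "education")] else NULL

  rows <- list()
  for (b in bands) {
    maps <- lapply(first_levels, function(fl) fl$alpha_beta[[b]])
    for (hippo in c(FALSE, TRUE)) {
      cv <- demog
      if (hippo) {
        cv <- if (is.null(cv)) covariates[, "hippo_norm", drop = FALSE]
        else cbind(cv, covariates[, "hippo_norm", drop = FALSE])
      }
      for (g in c("AD", "HC")) {
        sel <- grp == g
        sm <- one_sample_t(maps[sel],
                           covars = if (is.null(cv)) NULL else cv[sel, ],
                           contrast = paste0("one-sample ", g), band = b,
                           voxel_size = voxel_size)
        for (sgn in c("positive", "negative")) {
          m <- sm
          if (sgn == "negative") m$values <- -m$values
          cl <- threshold_clusters(m, p, k, connectivity, gm_mask, sgn)
          rows[[length(rows) + 1]] <- tibble::tibble(
            band = b, analysis = paste0("one_sample_", g), sign = sgn,
            hippo_covariate = hippo, map = list(m), clusters = list(cl))
        }
      }
      hc <- maps[grp == "HC"]; ad <- maps[grp == "AD"]
      cv_ord <- if (is.null(cv)) NULL else rbind(cv[grp == "HC", ],
                                                 cv[grp == "AD", ])
      sm <- two_sample_t(hc, ad, covars = cv_ord, contrast = "HC>AD",
                         band = b, voxel_size = voxel_size)
      for (sgn in c("positive", "negative")) {
        m <- sm
        if (sgn == "negative") m$values <- -m$values
        cl <- threshold_clusters(m, p, k, connectivity, gm_mask, sgn)
        rows[[length(rows) + 1]] <- tibble::tibble(
          band = b, analysis = "two_sample_HC_gt_AD", sign = sgn,
          hippo_covariate = hippo, map = list(m), clusters = list(cl))
      }
    }
  }
  stat_maps <- do.call(rbind, rows)

  hit_counts <- NULL
  if (!is.null(roi_masks)) {
    sm_tbl <- do.call(rbind, lapply(seq_along(first_levels), function(i) {
      fl <- first_levels[[i]]
      pos <- fl$maps[fl$maps$sign == "positive", ]
      tibble::tibble(subject_id = covariates$subject_id[i],
                     group = grp[i], band = pos$band, map = pos$map)
    }))
    hit_counts <- count_first_level_hits(sm_tbl, roi_masks, p)
  }

  relp <- do.call(rbind, lapply(seq_along(first_levels), function(i) {
    rp <- first_levels[[i]]$relative_power
    rp$group <- grp[i]
    rp
  }))
  scalar_tests <- do.call(rbind, lapply(bands, function(b) {
    sub <- relp[relp$band == b, ]
    res <- compare_scalars(sub$value[sub$group == "AD"],
                           sub$value[sub$group == "HC"])
    res$quantity <- paste0("relative_power_", b)
    res
  }))
  hip <- compare_scalars(covariates$hippo_norm[grp == "AD"],
                         covariates$hippo_norm[grp == "HC"])
  hip$quantity <- "hippo_norm"
  scalar_tests <- rbind(scalar_tests, hip)

  list(stat_maps = stat_maps, hit_counts = hit_counts,
       scalar_tests = scalar_tests)
}

#' Run the bundled end-to-end demonstration
#'
#' Simulates the demonstration cohort (HC with positive coupling in
#' region A and negative coupling in region B, AD with no coupling),
#' processes every subject one at a time (bounded memory), and runs the
#' group analysis. Deterministic for fixed `(spec, seed)`.
#'
#' @param spec a [demo_cohort_spec()].
#' @param seed master seed.
#' @param do_bcg,do_ica stage toggles forwarded to [run_first_level()].
#' @param verbose print per-subject progress.
#' @return list: `group` ([run_group()] output), `first_levels`,
#'   `cohort` (covariates + config), `spec`.
#' @export
run_demo <- function(spec = demo_cohort_spec(), seed = 1L, do_bcg = TRUE,
                     do_ica = FALSE, verbose = FALSE) {
  cohort <- simulate_cohort(spec$config, spec$groups, seed = seed,
                            materialize = FALSE)
  gm_mask <- make_gm_mask(spec$gm_template, 0.3)
  firsts <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- simulate_subject(cohort, i)
    if (verbose) message("first level: ", s$subject_id)
    firsts[[i]] <- run_first_level(
      s$eeg, s$bold, subject_id = s$subject_id,
      do_bcg = do_bcg, do_ica = do_ica, seed = s$seed)
  }
  grp <- run_group(firsts, cohort$covariates, gm_mask,
                   roi_masks = spec$roi_masks,
                   voxel_size = spec$config$voxel_size)
  list(group = grp, first_levels = firsts, cohort = cohort, spec = spec)
}

#' Export group results to disk
#'
#' Writes thresholded t maps as NIfTI, cluster tables / hit counts as TSV
#' and scalar tests as JSON into `dir`.
#'
#' @param group a [run_group()] result.
#' @param dir output directory (created if needed).
#' @param voxel_size voxel edge for the NIfTI headers, mm.
#' @return tibble manifest of written files, invisibly.
#' @export
export_group_results <- function(group, dir, voxel_size = 3.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (r in seq_len(nrow(group$stat_maps))) {
    row <- group$stat_maps[r, ]
    stem <- sprintf("%s_%s_%s%s", row$band, row$analysis, row$sign,
                    if (row$hippo_covariate) "_hippo" else "")
    f <- file.path(dir, paste0(stem, "_tmap.nii.gz"))
    write_map_nifti(row$map[[1]]$values, voxel_size, f)
    written <- c(written, f)
    cl <- row$clusters[[1]]
    f2 <- file.path(dir, paste0(stem, "_clusters.tsv"))
    utils::write.table(as.data.frame(cl), f2, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, f2)
  }
  if (!is.null(group$hit_counts)) {
    f <- file.path(dir, "first_level_hit_counts.tsv")
    utils::write.table(as.data.frame(group$hit_counts), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  f <- file.path(dir, "scalar_tests.json")
  jsonlite::write_json(group$scalar_tests, f, digits = NA, auto_unbox = TRUE)
  written <- c(written, f)
  manifest <- tibble::tibble(
    file = written,
    md5 = vapply(written, function(x) unname(tools::md5sum(x)), ""))
  utils::write.table(as.data.frame(manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
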