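## Two-timepoint synthetic cohort with planted effect structure:
##   - AgeAccelGrim (GrimAge residualized on age) predicts WMH volume and
##     the free-water elevation in the peri-lesional bundle (the
##     lesionometry ROI's catchment), cross-sectionally and longitudinally;
##   - whole-phantom mean fractions drift identically across subjects, so
##     no whole-brain x AgeAccelGrim interaction exists by construction
##     (the generator balances the background to cancel the leak from the
##     subject-specific lesion/penumbra into the whole-mask mean);
##   - follow-up retention is a simple random sample, independent of all
##     covariates, so the data are missing completely at random.

#' Effect structure of the synthetic cohort
#'
#' Defaults state the simulated world once: ages uniform on 58-81 years,
#' GrimAge linear in age and sex with 3.5-year residual scatter, phantom
#' lesions of a few tens of mm^3 (always spanning multiple voxels at the
#' 1.7 mm grid) whose volume rises 2 mm^3 per
#' AgeAccelGrim year, a peri-lesional free-water elevation of 0.12 signal
#' fraction rising 0.012 per AgeAccelGrim year at baseline and an
#' additional 0.04 + 0.012/yr over the follow-up interval, a global
#' free-water drift of 0.01 identical for all subjects, and 41/98 retained
#' at follow-up.
#'
#' @param ... overrides of the default fields (see source for the full
#'   list).
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(...) {
  eff <- list(
    age_range = c(58, 81), p_male = 0.3, followup_years = 2,
    grim_intercept = 20, grim_beta_age = 0.6, grim_beta_sex = 4,
    grim_sd = 3.5,
    tbv_mean = 1250000, tbv_beta_age = -3000, tbv_beta_sex = 120000,
    tbv_sd = 60000, tbv_decline_mean = 8000, tbv_decline_sd = 3000,
    wmh_gamma0 = 45, wmh_gamma1 = 2, wmh_sd = 8, wmh_min = 25,
    wmh_growth_mean = 8, wmh_growth_slope_aag = 0, wmh_growth_sd = 3,
    pen_base = 0.12, pen_slope_aag = 0.012, pen_sd = 0.02,
    pen_growth_mean = 0.04, pen_growth_slope_aag = 0.012,
    pen_growth_sd = 0.012,
    drift_eci = 0.01, retention_frac = 41 / 98, snr = 30,
    grid_n = 10, voxel_size = 1.7, bundle_radius = 2.6, penumbra_mm = 4,
    mask_margin_mm = 4.0, csf_corner_mm = 3.5,
    lesion_fractions = c(0.55, 0.30, 0.15))
  over <- list(...)
  unknown <- setdiff(names(over), names(eff))
  if (length(unknown))
    stop_invalid("unknown effect field(s): ", paste(unknown, collapse = ", "))
  eff <- modifyList(eff, over)
  for (f in grep("_sd$", names(eff), value = TRUE))
    if (eff[[f]] < 0) stop_invalid("negative variance: ", f, " < 0")
  structure(eff, class = "cohort_effects")
}

lesion_radius_from_volume <- function(v) (3 * v / (4 * pi))^(1 / 3)

#' Generate a synthetic two-timepoint cohort with per-subject phantoms
#'
#' @param n_subjects number of baseline subjects (>= 10).
#' @param effects [cohort_effects()].
#' @param seed integer; all randomness (including each subject's phantom
#'   noise seed) derives from it.
#' @return list with `cohort` (data.frame, one row per subject x timepoint:
#'   subject_id, timepoint, age_years, sex, sex01, grimage_years,
#'   age_accel_grim, total_brain_volume, wmh_volume (generative, mm^3),
#'   retained_at_followup) and `phantoms` (named list per subject:
#'   `baseline` and, when retained, `followup` [phantom_spec()]s).
#' @export
generate_cohort <- function(n_subjects = 98, effects = cohort_effects(),
                            seed = 1L) {
  if (n_subjects < 10) stop_invalid("n_subjects must be >= 10")
  e <- effects
  with_seed(derive_seed(seed, "cohort"), {
    age <- runif(n_subjects, e$age_range[1], e$age_range[2])
    sex01 <- rbinom(n_subjects, 1, e$p_male)
    grim <- e$grim_intercept + e$grim_beta_age * age +
      e$grim_beta_sex * sex01 + rnorm(n_subjects, 0, e$grim_sd)
    aag <- age_accel(grim, age)
    tbv <- e$tbv_mean + e$tbv_beta_age * (age - mean(e$age_range)) +
      e$tbv_beta_sex * sex01 + rnorm(n_subjects, 0, e$tbv_sd)
    tbv_fu <- tbv - (e$tbv_decline_mean + rnorm(n_subjects, 0,
                                                e$tbv_decline_sd))
    wmh_b <- pmax(e$wmh_min,
                  e$wmh_gamma0 + e$wmh_gamma1 * aag +
                    rnorm(n_subjects, 0, e$wmh_sd))
    wmh_f <- wmh_b + pmax(0, e$wmh_growth_mean +
                            e$wmh_growth_slope_aag * aag +
                            rnorm(n_subjects, 0, e$wmh_growth_sd))
    pen_b <- pmin(pmax(e$pen_base + e$pen_slope_aag * aag +
                         rnorm(n_subjects, 0, e$pen_sd), 0.01), 0.45)
    pen_f <- pmin(pmax(pen_b + e$pen_growth_mean +
                         e$pen_growth_slope_aag * aag +
                         rnorm(n_subjects, 0, e$pen_growth_sd), 0.01), 0.5)
    n_keep <- round(e$retention_frac * n_subjects)
    retained <- rep(FALSE, n_subjects)
    retained[sample.int(n_subjects, n_keep)] <- TRUE

    ids <- sprintf("sub-%03d", seq_len(n_subjects))
    phantoms <- vector("list", n_subjects)
    names(phantoms) <- ids
    for (i in seq_len(n_subjects)) {
      pb <- cohort_phantom(e, wmh_b[i], pen_b[i], drift = 0,
                           seed = derive_seed(seed, "phantom", ids[i],
                                              "baseline"))
      pf <- NULL
      if (retained[i]) {
        pf <- cohort_phantom(e, wmh_f[i], pen_f[i], drift = e$drift_eci,
                             seed = derive_seed(seed, "phantom", ids[i],
                                                "followup"))
        pf <- balance_whole_mask_drift(pb, pf, e$drift_eci)
      }
      phantoms[[i]] <- list(baseline = pb, followup = pf)
    }

    base <- data.frame(subject_id = ids, timepoint = "baseline",
                       age_years = age, sex = ifelse(sex01 == 1, "M", "F"),
                       sex01 = sex01, grimage_years = grim,
                       age_accel_grim = aag, total_brain_volume = tbv,
                       wmh_volume = wmh_b, retained_at_followup = retained)
    fu <- base[retained, ]
    fu$timepoint <- "followup"
    fu$age_years <- fu$age_years + e$followup_years
    fu$total_brain_volume <- tbv_fu[retained]
    fu$wmh_volume <- wmh_f[retained]
    cohort <- rbind(base, fu)
    rownames(cohort) <- NULL
    list(cohort = cohort, phantoms = phantoms)
  })
}

## one smoke-scale straight-bundle phantom for a subject x timepoint
cohort_phantom <- function(e, wmh_volume, pen_delta, drift, seed) {
  n <- e$grid_n; vs <- e$voxel_size
  cxy <- (floor(n / 2) + 0.5) * vs # a voxel centre, so tiny lesions rasterize
  ctr <- c(cxy, cxy, cxy)
  bundle_frac <- c(drift, 0, 1 - drift)
  bg <- c(0.1 + drift, 0.9 - drift, 0)
  phantom_spec(
    grid_shape = c(n, n, n), voxel_size = vs,
    bundles = list(bundle_spec(rbind(c(cxy, cxy, 0), c(cxy, cxy, n * vs)),
                               radius_mm = e$bundle_radius,
                               fractions = bundle_frac)),
    background = bg, csf_corner_mm = e$csf_corner_mm,
    lesions = list(lesion_spec(ctr,
                               radius_mm =
                                 lesion_radius_from_volume(wmh_volume),
                               fractions = e$lesion_fractions,
                               penumbra_mm = e$penumbra_mm,
                               penumbra_delta_eci = pen_delta)),
    snr = e$snr, mask_margin_mm = e$mask_margin_mm, seed = seed)
}

## adjust the follow-up background so every subject's whole-mask mean
## f_ECI change equals `drift` exactly (no whole-brain x AAG interaction)
balance_whole_mask_drift <- function(spec_b, spec_f, drift) {
  rb <- rasterize_phantom(spec_b)
  rf <- rasterize_phantom(spec_f)
  mean_b <- mean(rb$frac[rb$mask, 1])
  mean_f <- mean(rf$frac[rf$mask, 1])
  excess <- (mean_f - mean_b) - drift
  bg_vox <- rf$mask & !rf$in_bundle & !rf$wmh & !rf$csf
  n_bg <- sum(bg_vox)
  if (n_bg == 0) return(spec_f)
  adj <- excess * sum(rf$mask) / n_bg
  bg <- spec_f$background
  adj <- min(max(adj, -bg[1] + 1e-6), bg[2] - 1e-6)
  spec_f$background <- c(bg[1] - adj, bg[2] + adj, bg[3])
  spec_f
}
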