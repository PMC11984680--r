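## Orchestration: one reproducible run from configuration to TSV/NIfTI/TCK
## outputs plus a manifest of checksums and seeds. Two modes:
##   subject - one phantom (or real DWI paths) through response estimation,
##             SS3T-CSD, tractography, SIFT and lesionometry;
##   cohort  - a full synthetic cohort (default 98 baseline / 41 follow-up)
##             through per-subject smoke-scale pipelines and the planted-
##             effect statistical models.

#' Pipeline configuration
#'
#' @param mode `"subject"` or `"cohort"`.
#' @param out_dir output directory.
#' @param seed global seed; all per-stage and per-subject seeds derive from
#'   it via [derive_seed()].
#' @param phantom `phantom_spec` for subject mode (default
#'   [default_phantom_spec()]); ignored in cohort mode.
#' @param dwi_paths optional named list (dwi, bvals, bvecs, mask, wmh) of
#'   real-data paths for subject mode; overrides `phantom`.
#' @param tracking [tracking_params()].
#' @param keep_ratio SIFT retention ratio (default 1/5, the published
#'   10M -> 2M pruning).
#' @param min_tracts lesionometry threshold (default 10).
#' @param lmax FOD harmonic order.
#' @param n_subjects,effects cohort-mode size and [cohort_effects()].
#' @param models cohort-mode model set, subset of
#'   `c("baseline", "longitudinal", "missingness")`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("subject", "cohort"), out_dir, seed = 1L,
                            phantom = default_phantom_spec(),
                            dwi_paths = NULL,
                            tracking = tracking_params(),
                            keep_ratio = 0.2, min_tracts = 10, lmax = 8,
                            n_subjects = 98, effects = cohort_effects(),
                            models = c("baseline", "longitudinal",
                                       "missingness")) {
  mode <- match.arg(mode)
  if (missing(out_dir)) stop_invalid("out_dir is required")
  if (mode == "subject" && is.null(dwi_paths) &&
      !inherits(phantom, "phantom_spec"))
    stop_invalid("subject mode needs a phantom_spec or dwi_paths")
  if (!is.null(dwi_paths)) {
    need <- c("dwi", "bvals", "bvecs", "wmh")
    miss <- setdiff(need, names(dwi_paths))
    if (length(miss))
      stop_invalid("dwi_paths missing required entries: ",
                   paste(miss, collapse = ", "))
  }
  if (keep_ratio <= 0 || keep_ratio > 1)
    stop_invalid("keep_ratio must be in (0, 1]")
  bad <- setdiff(models, c("baseline", "longitudinal", "missingness"))
  if (length(bad)) stop_invalid("unknown model(s): ", paste(bad, collapse = ", "))
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, dwi_paths = dwi_paths,
                 tracking = tracking, keep_ratio = keep_ratio,
                 min_tracts = min_tracts, lmax = lmax,
                 n_subjects = n_subjects, effects = effects,
                 models = models),
            class = "pipeline_config")
}

## write through a .partial marker so an aborted run is detectable
commit_file <- function(writer, path) {
  partial <- paste0(path, ".partial")
  writer(partial)
  file.rename(partial, path)
  path
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run one subject (phantom or real DWI) through the imaging pipeline
#'
#' Response estimation, SS3T-CSD, tractography, SIFT pruning, lesionometry
#' ROI and statistics. This is the unit the cohort pipeline repeats.
#'
#' @param dwi `dwi_dataset`.
#' @param wmh [lesion_mask()].
#' @param tissue_masks list wm/gm/csf for response estimation.
#' @param tracking [tracking_params()].
#' @param keep_ratio SIFT retention ratio.
#' @param min_tracts lesionometry threshold.
#' @param lmax FOD order.
#' @param seed stage seed.
#' @return list: `responses`, `fod`, `fractions`, `tractogram` (post-SIFT),
#'   `roi`, and `metrics` (one-row data.frame).
#' @export
run_subject <- function(dwi, wmh, tissue_masks, tracking = tracking_params(),
                        keep_ratio = 0.2, min_tracts = 10, lmax = 8,
                        seed = 1L) {
  responses <- estimate_responses(dwi, tissue_masks, lmax = lmax)
  fit <- fit_ss3t_field(dwi, responses, options = ss3t_options(lmax = lmax))
  tract <- generate_tractogram(fit$fod, dwi$brain_mask, tracking,
                               seed = derive_seed(seed, "track"))
  keep <- max(1L, round(length(tract$streamlines) * keep_ratio))
  pruned <- sift_filter(tract, fit$fod, keep)
  subset <- select_lesioned_streamlines(pruned, wmh)
  roi <- build_lesionometry_roi(subset, wmh, min_tracts)
  roi <- if (roi$empty) roi else roi_statistics(roi, fit$fractions)
  fmask <- matrix(fit$fractions$f, ncol = 3)[which(dwi$brain_mask), ,
                                             drop = FALSE]
  whole <- colMeans(fmask, na.rm = TRUE)
  metrics <- data.frame(
    wmh_volume_measured = wmh$volume_mm3,
    roi_volume = roi$volume_mm3, roi_empty = roi$empty,
    lesion_load = roi$lesion_load,
    roi_f_eci = roi$mean_f_ECI, roi_f_ici = roi$mean_f_ICI,
    roi_f_ica = roi$mean_f_ICA,
    whole_f_eci = whole[1], whole_f_ici = whole[2], whole_f_ica = whole[3],
    n_streamlines = length(pruned$streamlines),
    n_lesioned = length(subset$streamlines))
  list(responses = responses, fod = fit$fod, fractions = fit$fractions,
       tractogram = pruned, roi = roi, metrics = metrics)
}

## smoke-scale tracking defaults for the cohort's 10-voxel phantoms
cohort_tracking_params <- function() {
  tracking_params(target_count = 800, max_length = 60)
}

#' Run the synthetic cohort through per-subject pipelines
#'
#' @param sim output of [generate_cohort()].
#' @param tracking tracking parameters (smoke-scale defaults).
#' @param keep_ratio,min_tracts,lmax see [run_subject()]; cohort default
#'   lmax 6 keeps desk-scale runtimes.
#' @param seed global seed for per-subject stage seeds.
#' @param progress emit a log line every that many subjects (0 = quiet).
#' @return the cohort data.frame augmented with per-row imaging metrics.
#' @export
run_cohort_pipeline <- function(sim, tracking = cohort_tracking_params(),
                                keep_ratio = 0.2, min_tracts = 10, lmax = 4,
                                seed = 1L, progress = 0) {
  cohort <- sim$cohort
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    tp <- cohort$timepoint[i]
    spec <- sim$phantoms[[id]][[tp]]
    ph <- build_phantom(spec)
    wmh <- lesion_mask(ph$truth$wmh_mask, ph$truth$affine)
    res <- run_subject(ph$dwi, wmh, ph$truth$tissue_masks, tracking,
                       keep_ratio, min_tracts, lmax,
                       seed = derive_seed(seed, "subject", id, tp))
    rows[[i]] <- res$metrics
    if (progress > 0 && i %% progress == 0)
      log_stage("cohort", sprintf("%d/%d subjects-timepoints done", i,
                                  nrow(cohort)))
  }
  cbind(cohort, do.call(rbind, rows))
}

#' Fit the planted-effect models on a processed cohort table
#'
#' Baseline: `wmh_volume_measured ~ AAG + age + sex + TBV`, ROI free-water
#' `roi_f_eci ~ AAG + age + sex + ROI volume`; longitudinal change-score
#' models for ROI free water (controls sex, baseline age, ROI volume) and
#' whole-phantom free water (controls sex, baseline age, TBV);
#' missingness t-tests of baseline variables by retention.
#'
#' @param df output of [run_cohort_pipeline()].
#' @param models subset of `c("baseline", "longitudinal", "missingness")`.
#' @return named list of `glm_result` / `longitudinal_result` /
#'   missingness data.frames.
#' @export
cohort_models <- function(df, models = c("baseline", "longitudinal",
                                         "missingness")) {
  base <- df[df$timepoint == "baseline", ]
  fu <- df[df$timepoint == "followup", ]
  fu <- fu[match(base$subject_id, fu$subject_id), ] # align; NAs if absent
  out <- list()
  if ("baseline" %in% models) {
    out$wmh_volume <- fit_glm(
      base$wmh_volume_measured,
      list(age_accel_grim = base$age_accel_grim, age = base$age_years,
           sex = base$sex01, total_brain_volume = base$total_brain_volume),
      "age_accel_grim")
    ok <- !base$roi_empty
    out$roi_f_eci <- fit_glm(
      base$roi_f_eci[ok],
      list(age_accel_grim = base$age_accel_grim[ok],
           age = base$age_years[ok], sex = base$sex01[ok],
           roi_volume = base$roi_volume[ok]),
      "age_accel_grim")
  }
  if ("longitudinal" %in% models) {
    ctrl <- list(age_accel_grim = base$age_accel_grim, sex = base$sex01,
                 age_baseline = base$age_years)
    out$roi_f_eci_change <- longitudinal_model(
      base$roi_f_eci, fu$roi_f_eci,
      c(ctrl, list(roi_volume = base$roi_volume)), "age_accel_grim")
    out$whole_f_eci_change <- longitudinal_model(
      base$whole_f_eci, fu$whole_f_eci,
      c(ctrl, list(total_brain_volume = base$total_brain_volume)),
      "age_accel_grim")
    out$roi_f_eci_timepoint <- longitudinal_model(
      base$roi_f_eci, fu$roi_f_eci,
      list(sex = base$sex01, age_baseline = base$age_years,
           roi_volume = base$roi_volume), NULL)
  }
  if ("missingness" %in% models) out$missingness <- missingness_tests(df)
  out
}

#' Run the full pipeline from a configuration
#'
#' Executes phantom (or ingest) -> CSD -> tracking -> lesionometry
#' (-> cohort statistics), writing each stage's outputs before the next
#' begins and returning a manifest of checksums, seeds and timestamps.
#'
#' @param config [pipeline_config()].
#' @return list of class `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  if (config$mode == "subject") {
    log_stage("ingest", "preparing subject inputs")
    if (is.null(config$dwi_paths)) {
      ph <- build_phantom(config$phantom)
      dwi <- ph$dwi
      wmh <- lesion_mask(ph$truth$wmh_mask, ph$truth$affine)
      tm <- ph$truth$tissue_masks
      add(commit_file(function(p) write_nifti(ph$truth$wmh_mask + 0L, p,
                                              ph$truth$affine, "uint8"),
                      file.path(config$out_dir, "wmh_mask.nii")))
      for (p in write_dwi(dwi, file.path(config$out_dir, "subject"))) add(p)
    } else {
      dwi <- read_dwi(config$dwi_paths$dwi, config$dwi_paths$bvals,
                      config$dwi_paths$bvecs, config$dwi_paths$mask)
      wnii <- read_nifti(config$dwi_paths$wmh)
      check_affine_match(dwi$affine, wnii$affine, "DWI/WMH mask")
      wmh <- lesion_mask(wnii$data != 0, wnii$affine)
      tm <- estimate_tissue_masks(dwi)
    }
    log_stage("csd+tracking+lesionometry", "running subject pipeline")
    res <- run_subject(dwi, wmh, tm, config$tracking, config$keep_ratio,
                       config$min_tracts, config$lmax,
                       seed = derive_seed(config$seed, "subject"))
    add(commit_file(function(p) write_fod(res$fod, p),
                    file.path(config$out_dir, "fod.nii")))
    for (p in write_fractions(res$fractions,
                              file.path(config$out_dir, "subject"))) add(p)
    add(commit_file(function(p) write_tck(res$tractogram, p),
                    file.path(config$out_dir, "tracks.tck")))
    add(commit_file(function(p) write_nifti(res$roi$mask + 0L, p,
                                            res$roi$affine, "uint8"),
                    file.path(config$out_dir, "lesionometry_roi.nii")))
    add(commit_file(function(p) write_tsv(res$metrics, p),
                    file.path(config$out_dir, "subject_metrics.tsv")))
  } else {
    log_stage("cohort", "generating ", config$n_subjects, " subjects")
    sim <- generate_cohort(config$n_subjects, config$effects, config$seed)
    df <- run_cohort_pipeline(sim, cohort_tracking_params(),
                              config$keep_ratio, config$min_tracts,
                              lmax = min(config$lmax, 4),
                              seed = config$seed, progress = 25)
    add(commit_file(function(p) write_tsv(df, p),
                    file.path(config$out_dir, "cohort_metrics.tsv")))
    log_stage("stats", "fitting models: ",
              paste(config$models, collapse = ", "))
    mods <- cohort_models(df, config$models)
    add(commit_file(function(p) write_tsv(models_to_table(mods), p),
                    file.path(config$out_dir, "model_results.tsv")))
  }

  cfg_json <- jsonlite::toJSON(config_fingerprint(config), auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(tmp)),
    files = vapply(files, function(f) unname(tools::md5sum(f)), ""),
    version = as.character(utils::packageVersion("lesionometry")),
    seed = config$seed,
    started = format(t0), finished = format(Sys.time())),
    class = "run_manifest")
  unlink(tmp)
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  manifest
}

## deterministic fingerprint of a config: strip classes recursively so the
## structure serializes to plain JSON
config_fingerprint <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL  # the hash identifies the scientific run, not paths
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE)
    else if (is.numeric(x)) signif(unclass(x), 12)
    else unclass(x)
  }
  strip(config)
}

## flatten model results into a tidy table
models_to_table <- function(mods) {
  rows <- lapply(names(mods), function(nm) {
    m <- mods[[nm]]
    if (inherits(m, "glm_result")) {
      t <- glm_term(m)
      data.frame(model = nm, term = t$term, estimate = t$estimate,
                 statistic = t$t, df1 = 1, df2 = m$df_residual, p = t$p,
                 kind = "t")
    } else if (inherits(m, "longitudinal_result")) {
      data.frame(model = nm, term = m$term, estimate = m$estimate,
                 statistic = m$F_statistic, df1 = m$df_numerator,
                 df2 = m$df_denominator, p = m$p_value, kind = "F")
    } else {
      data.frame(model = nm, term = m$variable, estimate = NA,
                 statistic = m$t_statistic, df1 = 1, df2 = m$df, p = m$p,
                 kind = "t")
    }
  })
  do.call(rbind, rows)
}

## crude tissue masks from the raw signal when no ground truth exists:
## CSF = strong isotropic decay at the outer shell; WM = most anisotropic
## voxels; GM = the rest (adequate for response estimation on real data)
estimate_tissue_masks <- function(dwi, frac_wm = 0.05, frac_csf = 0.05) {
  dims <- dim(dwi$data)[1:3]
  sig <- matrix(dwi$data, prod(dims), dim(dwi$data)[4])
  rows <- ss_rows(dwi$gtab)
  b0 <- rowMeans(sig[, rows$b0, drop = FALSE])
  sh <- sig[, rows$shell, drop = FALSE]
  msk <- as.vector(dwi$brain_mask) & b0 > 0.1 * max(b0)
  mean_att <- rowMeans(sh) / pmax(b0, 1e-9)
  aniso <- apply(sh, 1, sd) / pmax(b0, 1e-9)
  wm <- msk & aniso >= stats::quantile(aniso[msk], 1 - frac_wm)
  csf <- msk & mean_att <= stats::quantile(mean_att[msk], frac_csf) * 1.0 &
    !wm
  gm <- msk & !wm & !csf
  list(wm = array(wm, dims), gm = array(gm, dims), csf = array(csf, dims))
}
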