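# Pipeline composition: per-study analysis from raw series to the
# normalized metrics record, file round-tripping (NIfTI-1 stacks + JSON
# sidecar + CSV tables), and the cohort runner feeding the threshold
# sweeps.

#' Run the full per-study analysis
#'
#' Flip-angle corrects all three series, estimates one noise sigma for the
#' study from the pre-bolus frames of the corrected pyruvate series (shared
#' by all metabolites), forms the summed-pyruvate image, sorts and fits the
#' endocardial intensity profile, computes the adaptive-threshold delivery
#' term Pyr(alpha%) over `alpha_grid` and the percentile term Pyr(T%) over
#' `T_grid`, and the metabolic outcome (lactate+bicarbonate SNR AUC in the
#' mid-myocardium).
#'
#' @param study list with `pyruvate`, `lactate`, `bicarbonate`
#'   (`dynamic_series`, uncorrected) and `masks` (`mask_set`), e.g. a
#'   `phantom_study`.
#' @param alpha_grid integer threshold percentages (default `1:63`).
#' @param T_grid percentile grid (default `seq(10, 100, by = 10)`).
#' @param noise_frames number of leading pyruvate frames treated as
#'   noise-only baseline (default 6).
#' @return A `study_metrics` object.
#' @export
compute_study_metrics <- function(study, alpha_grid = 1:63,
                                  T_grid = seq(10, 100, by = 10),
                                  noise_frames = 6L) {
  pyr <- flip_angle_correct(study$pyruvate)
  lac <- flip_angle_correct(study$lactate)
  bic <- flip_angle_correct(study$bicarbonate)
  noise <- estimate_noise(pyr, seq_len(noise_frames))
  sp <- sum_pyruvate(pyr)
  endo <- study$masks$endo
  prof <- sort_roi(sp, endo)
  fit <- fit_exponential(prof)

  # hot path: the per-frame mean-SNR AUC over each retained set, computed
  # on one F x V matrix; identical to snr_curve() on the retained mask
  mat <- frames_matrix(pyr)
  idx <- which(as.vector(endo))
  ord_idx <- idx[order(-sp[idx])]
  sp_vec <- as.vector(sp)
  auc_over <- function(cols) {
    v <- rowMeans(mat[, cols, drop = FALSE]) / noise$sigma
    trapz_unit(v)
  }

  pyr_alpha <- numeric(length(alpha_grid))
  n_ret_a <- integer(length(alpha_grid))
  for (k in seq_along(alpha_grid)) {
    thr <- alpha_grid[k] / 100 * prof$i_max + prof$i_min
    keep <- ord_idx[sp_vec[ord_idx] >= thr]
    if (length(keep) == 0L) keep <- ord_idx[1L]
    pyr_alpha[k] <- auc_over(keep)
    n_ret_a[k] <- length(keep)
  }
  names(pyr_alpha) <- names(n_ret_a) <- alpha_grid

  pyr_T <- numeric(length(T_grid))
  n_ret_T <- integer(length(T_grid))
  for (k in seq_along(T_grid)) {
    kk <- max(1L, as.integer(ceiling(T_grid[k] / 100 * prof$n)))
    pyr_T[k] <- auc_over(ord_idx[seq_len(kk)])
    n_ret_T[k] <- kk
  }
  names(pyr_T) <- names(n_ret_T) <- T_grid

  lac_bic <- metabolic_outcome(lac, bic, study$masks$mid_myo, noise)
  m <- study_metrics(fit, pyr_alpha, pyr_T, n_ret_a, n_ret_T, lac_bic)
  m$sigma <- noise$sigma
  m$alpha_max <- alpha_max(prof$i_max, max(prof$i_min, 0))
  m
}

#' Write a study to disk (NIfTI-1 stacks + JSON sidecar)
#'
#' One `.nii` file per metabolite plus `sidecar.json` holding flip angles,
#' frame intervals, run-length-encoded masks, and (for phantoms) the truth
#' parameters, which round-trip through serialization.
#'
#' @param study a `phantom_study` or compatible list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (met in c("pyruvate", "lactate", "bicarbonate"))
    write_nifti(study[[met]]$frames, file.path(dir, paste0(met, ".nii")),
                datatype = "float64")
  meta <- list(
    series = lapply(c("pyruvate", "lactate", "bicarbonate"), function(met) {
      s <- study[[met]]
      list(metabolite = met, flip_angle = s$flip_angle,
           frame_interval = s$frame_interval, corrected = s$corrected)
    }),
    grid_size = study$masks$grid_size,
    masks = lapply(study$masks[c("epic", "endo", "myo", "mid_myo")],
                   mask_to_rle))
  if (!is.null(study$truth)) {
    tr <- study$truth
    tr$spec <- unclass(tr$spec)
    meta$truth <- tr
  }
  jsonlite::write_json(meta, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir study directory.
#' @return List with the three `dynamic_series`, the `mask_set`, and
#'   `truth` when present.
#' @export
read_study <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                            simplifyVector = TRUE)
  series <- list()
  for (i in seq_len(nrow(sc$series))) {
    met <- sc$series$metabolite[i]
    fr <- read_nifti(file.path(dir, paste0(met, ".nii")))
    series[[met]] <- dynamic_series(fr, flip_angle = sc$series$flip_angle[i],
                                    metabolite = met,
                                    frame_interval = sc$series$frame_interval[i],
                                    corrected = sc$series$corrected[i])
  }
  masks <- lapply(sc$masks, rle_to_mask)
  masks$grid_size <- as.integer(sc$grid_size)
  class(masks) <- "mask_set"
  out <- list(pyruvate = series$pyruvate, lactate = series$lactate,
              bicarbonate = series$bicarbonate, masks = masks)
  if (!is.null(sc$truth)) out$truth <- sc$truth
  out
}

#' Run one study from disk and emit its metrics tables
#'
#' @param dir study directory (from [write_study()]).
#' @param study_id identifier used in the output rows (default: basename).
#' @param alpha_grid,T_grid,noise_frames passed to
#'   [compute_study_metrics()].
#' @param out_dir if non-NULL, writes `<study_id>_summary.csv` and
#'   `<study_id>_long.csv` there.
#' @param save_intermediates if TRUE (and `out_dir` set), also writes the
#'   summed-pyruvate image and the full-ROI SNR curve as CSV.
#' @return List with `summary` (one-row data.frame) and `long`
#'   (long-format data.frame: study_id, model, grid, n_retained, pyr,
#'   metric), plus the `study_metrics` object as `$metrics`.
#' @export
run_study <- function(dir, study_id = basename(dir), alpha_grid = 1:63,
                      T_grid = seq(10, 100, by = 10), noise_frames = 6L,
                      out_dir = NULL, save_intermediates = FALSE) {
  study <- read_study(dir)
  m <- compute_study_metrics(study, alpha_grid, T_grid, noise_frames)
  summary_df <- data.frame(study_id = study_id, b_value = m$b_value,
                           i_max = m$i_max, i_min = m$i_min, n = m$n,
                           r2 = m$r2, sigma = m$sigma,
                           alpha_max = m$alpha_max, lac_bic = m$lac_bic)
  long <- rbind(
    data.frame(study_id = study_id, model = "numfit",
               grid = as.numeric(names(m$pyr_alpha)),
               n_retained = as.integer(m$n_retained_alpha),
               pyr = as.numeric(m$pyr_alpha),
               metric = as.numeric(m$metric_numfit)),
    data.frame(study_id = study_id, model = "peak",
               grid = as.numeric(names(m$pyr_alpha)),
               n_retained = as.integer(m$n_retained_alpha),
               pyr = as.numeric(m$pyr_alpha),
               metric = as.numeric(m$metric_peak)),
    data.frame(study_id = study_id, model = "percentile",
               grid = as.numeric(names(m$pyr_T)),
               n_retained = as.integer(m$n_retained_T),
               pyr = as.numeric(m$pyr_T),
               metric = as.numeric(m$metric_percentile)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_df,
                     file.path(out_dir, paste0(study_id, "_summary.csv")),
                     row.names = FALSE)
    utils::write.csv(long, file.path(out_dir, paste0(study_id, "_long.csv")),
                     row.names = FALSE)
    if (save_intermediates) {
      pyr <- flip_angle_correct(study$pyruvate)
      noise <- estimate_noise(pyr, seq_len(noise_frames))
      utils::write.csv(as.data.frame(sum_pyruvate(pyr)),
                       file.path(out_dir, paste0(study_id, "_sumpyr.csv")),
                       row.names = FALSE)
      cv <- snr_curve(pyr, study$masks$endo, noise)
      utils::write.csv(data.frame(frame = seq_along(cv$values),
                                  snr = cv$values),
                       file.path(out_dir, paste0(study_id, "_snr_curve.csv")),
                       row.names = FALSE)
    }
  }
  list(summary = summary_df, long = long, metrics = m)
}

#' Run a cohort of studies and sweep all three models
#'
#' Processes every study directory (continuing past individual failures),
#' derives the usable threshold grid from the cohort's per-study
#' `alpha_max` values, sweeps the numerical-fitting, peak-intensity and
#' percentile metrics against the metabolic outcome, and writes the
#' combined tables plus a JSON summary.
#'
#' @param dirs character vector of study directories (>= 4).
#' @param out_dir output directory for `cohort_summary.csv`,
#'   `cohort_long.csv`, `sweep_<model>.csv` and `cohort_sweeps.json`
#'   (optional).
#' @param alpha_grid requested threshold grid before the cohort upper
#'   limit is applied (default `1:63`).
#' @param T_grid percentile grid.
#' @param noise_frames baseline frames for noise estimation.
#' @param delta sweep window tolerance (default 0.005).
#' @param outcome optional per-study outcome vector overriding the
#'   image-derived lactate+bicarbonate (e.g. a phantom cohort's planted
#'   outcome); named by study_id or in `dirs` order.
#' @return List with `summary`, `long`, `sweeps` (per model), `failed`
#'   (character vector of failed dirs), `alpha_upper`.
#' @export
run_cohort <- function(dirs, out_dir = NULL, alpha_grid = 1:63,
                       T_grid = seq(10, 100, by = 10), noise_frames = 6L,
                       delta = 0.005, outcome = NULL) {
  if (length(dirs) < 4L) stopf("a cohort needs at least 4 studies; got %d",
                               length(dirs))
  res <- list(); failed <- character(0)
  for (d in dirs) {
    r <- tryCatch(run_study(d, alpha_grid = alpha_grid, T_grid = T_grid,
                            noise_frames = noise_frames),
                  error = function(e) {
                    message(sprintf("study %s failed: %s", d, conditionMessage(e)))
                    NULL
                  })
    if (is.null(r)) failed <- c(failed, d) else res[[basename(d)]] <- r
  }
  if (length(res) < 4L)
    stopf("fewer than 4 usable studies (%d of %d); aborting cohort",
          length(res), length(dirs))

  summary_df <- do.call(rbind, lapply(res, `[[`, "summary"))
  rownames(summary_df) <- NULL
  long <- do.call(rbind, lapply(res, `[[`, "long"))
  rownames(long) <- NULL

  upper <- alpha_grid_upper(summary_df$alpha_max)
  grid_a <- alpha_grid[alpha_grid <= upper]
  message(sprintf("cohort alpha grid upper limit: %d", upper))

  y <- if (is.null(outcome)) summary_df$lac_bic
       else if (!is.null(names(outcome))) outcome[summary_df$study_id]
       else outcome[match(summary_df$study_id, basename(dirs))]

  take <- function(field) do.call(rbind, lapply(res, function(r)
    r$metrics[[field]]))
  sweeps <- list(
    numfit = sweep_metric(take("metric_numfit")[, as.character(grid_a),
                                                drop = FALSE],
                          y, grid = grid_a, delta = delta),
    peak = sweep_metric(take("metric_peak")[, as.character(grid_a),
                                            drop = FALSE],
                        y, grid = grid_a, delta = delta),
    percentile = sweep_metric(take("metric_percentile"), y, grid = T_grid,
                              delta = delta))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(long, file.path(out_dir, "cohort_long.csv"),
                     row.names = FALSE)
    for (nm in names(sweeps)) {
      sw <- sweeps[[nm]]
      utils::write.csv(data.frame(grid = sw$grid, corr = sw$corr,
                                  regime = sw$regime_labels,
                                  n_used = sw$n_used),
                       file.path(out_dir, paste0("sweep_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(alpha_upper = upper, failed = failed,
           sweeps = lapply(sweeps, function(s)
             list(argmin = s$argmin_alpha, min_corr = min(s$corr),
                  window = s$optimal_window))),
      file.path(out_dir, "cohort_sweeps.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(summary = summary_df, long = long, sweeps = sweeps, failed = failed,
       alpha_upper = upper)
}

#' Write a phantom cohort to disk
#'
#' One subdirectory per study plus `truth.csv` with the planted parameters
#' and the planted outcome table.
#'
#' @param cohort a `phantom_cohort` built with `keep_studies = TRUE`.
#' @param dir output directory.
#' @return Character vector of study directories, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$studies))
    stopf("cohort was built with keep_studies = FALSE; nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- file.path(dir, sprintf("study_%03d", seq_along(cohort$studies)))
  for (i in seq_along(cohort$studies)) write_study(cohort$studies[[i]], dirs[i])
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dirs)
}
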