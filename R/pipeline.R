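# Study-level orchestration: imaging cohorts and the end-to-end pipeline.

#' Simulate an imaging cohort and extract connectivity records
#'
#' For each participant: pre- and post-intervention resting runs are
#' simulated on a shared phantom with a participant-specific mPFC-PCC
#' coupling that drops from pre to post by `true_drop_z` (on the Fisher-z
#' scale of the latent coupling), runs are cleaned ([clean_run()]), and
#' mPFC-PCC connectivity is computed per run ([roi_connectivity()]). The
#' result is the tidy records table the group models consume. Measured
#' effects are attenuated relative to the latent drop by voxel noise and
#' bandpass filtering; the direction and significance are the properties of
#' interest at desk scale.
#'
#' @param n_participants cohort size.
#' @param true_drop_z latent pre-to-post Fisher-z connectivity decrease.
#' @param baseline_z latent pre Fisher-z mPFC-PCC coupling (default
#'   atanh(0.5)).
#' @param sd_id between-participant SD of the latent coupling (z scale).
#' @param phantom optional shared phantom; default: a compact cohort
#'   phantom on a 14^3 grid.
#' @param n_volumes rest-run length (default 150 to keep cohorts fast;
#'   protocol rest runs are 250).
#' @param runs_per_phase rest runs per phase (default 2: 4 records each).
#' @param cleaning a [cleaning_params()].
#' @param seed integer master seed.
#' @return tibble of connectivity records (`id`, `run`, `time`, `dose`,
#'   `fisher_z`, `mean_fd`, `age`).
#' @export
simulate_study <- function(n_participants = 20L, true_drop_z = 0.18,
                           baseline_z = atanh(0.5), sd_id = 0.15,
                           phantom = NULL, n_volumes = 150L,
                           runs_per_phase = 2L,
                           cleaning = cleaning_params(), seed = 1L) {
  if (is.null(phantom)) phantom <- cohort_phantom(seed = derive_seed(seed, "phantom"))
  acq <- acquisition_params(n_volumes = n_volumes)
  arm <- rep(c(0L, 1L), length.out = n_participants)
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pseed <- derive_seed(seed, paste0("participant", i))
    z_pre <- with_seed(pseed, baseline_z + stats::rnorm(1, 0, sd_id))
    z_post <- z_pre - true_drop_z
    age <- with_seed(derive_seed(pseed, "age"), stats::runif(1, 13, 18))
    rec <- list()
    for (phase in c(0L, 1L)) {
      r_lat <- tanh(if (phase == 0) z_pre else z_post)
      r_lat <- min(max(r_lat, 0), 0.99)
      for (j in seq_len(runs_per_phase)) {
        sig <- signal_spec(
          mpfc_pcc_corr = r_lat,
          seed = derive_seed(pseed, paste0("run", phase, "_", j))
        )
        run <- simulate_run(phantom, acq, sig)
        cl <- clean_run(run, phantom$masks$WM, phantom$masks$CSF,
                        phantom$masks$whole_brain, cleaning)
        cc <- roi_connectivity(cl, phantom$masks$mPFC, phantom$masks$PCC)
        rec[[length(rec) + 1]] <- tibble::tibble(
          id = sprintf("p%03d", i), run = phase * runs_per_phase + j,
          time = phase, dose = arm[i], fisher_z = cc$fisher_z,
          mean_fd = cl$mean_fd, age = age
        )
      }
    }
    rows[[i]] <- dplyr::bind_rows(rec)
  }
  dplyr::bind_rows(rows)
}

#' Compact phantom for cohort-scale simulation
#'
#' A 14^3-grid phantom with region sizes scaled down for speed while
#' keeping the mPFC and PCC ROIs at the 200-voxel floor.
#'
#' @param seed integer RNG seed.
#' @return an `npda_phantom`.
#' @export
cohort_phantom <- function(seed = 1L) {
  spec <- phantom_spec(
    grid_shape = c(14L, 14L, 14L),
    region_sizes = c(
      DMN_mPFC = 200L, DMN_PCC = 200L, DMN_other = 150L,
      FPN = 300L, WM = 150L, CSF = 100L
    )
  )
  make_phantom(spec, seed = seed)
}

#' Run the full pipeline and write an artifacts directory
#'
#' Executes simulate -> localize -> session -> connectivity -> analyze for
#' one simulated participant session plus a cohort-level analysis, writing
#' session logs, masks, connectivity records and model reports with full
#' provenance (config and seeds echoed to JSON).
#'
#' @param out_dir output directory.
#' @param dose `"min15"` or `"min30"`.
#' @param n_participants cohort size for the group analysis stage.
#' @param true_drop_z latent pre-to-post connectivity drop for the cohort.
#' @param seed integer master seed.
#' @param session_phantom phantom for the single showcased session
#'   (default: the full-size default phantom).
#' @return list with `session`, `records`, `fit` (primary model),
#'   `dose_fit`, and `paths`; artifacts under `out_dir`.
#' @export
run_pipeline <- function(out_dir, dose = "min15", n_participants = 12L,
                         true_drop_z = 0.18, seed = 1L,
                         session_phantom = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(session_phantom)) {
    session_phantom <- make_phantom(phantom_spec(), seed = derive_seed(seed, "phantom"))
  }
  session <- run_session(session_phantom, dose = dose,
                         seed = derive_seed(seed, "session"))
  sess_dir <- file.path(out_dir, "session")
  write_session_log(session, sess_dir)
  write_mask(session$masks$dmn, file.path(sess_dir, "dmn_mask.nii"),
             voxel_size_mm = session_phantom$voxel_size_mm)
  write_mask(session$masks$fpn, file.path(sess_dir, "fpn_mask.nii"),
             voxel_size_mm = session_phantom$voxel_size_mm)

  records <- simulate_study(n_participants = n_participants,
                            true_drop_z = true_drop_z,
                            seed = derive_seed(seed, "cohort"))
  rec_path <- file.path(out_dir, "connectivity_records.csv")
  utils::write.csv(records, rec_path, row.names = FALSE)

  fit <- fit_primary_model(records)
  dose_fit <- tryCatch(fit_dose_model(records), npda_model_error = function(e) NULL)
  report <- list(
    config = list(dose = dose, n_participants = n_participants,
                  true_drop_z = true_drop_z, seed = seed),
    primary = as.list(glance(fit)),
    primary_terms = as.list(tidy(fit)),
    dose = if (!is.null(dose_fit)) as.list(glance(dose_fit)) else NULL
  )
  rep_path <- file.path(out_dir, "analysis_report.json")
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA)

  list(
    session = session, records = records, fit = fit, dose_fit = dose_fit,
    paths = list(session = sess_dir, records = rec_path, report = rep_path)
  )
}
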