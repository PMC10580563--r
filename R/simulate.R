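#' Acquisition parameters for a simulated BOLD run
#'
#' @param tr_ms repetition time in milliseconds (default 1200, the protocol's
#'   multiband EPI sampling rate).
#' @param n_volumes number of volumes in the run (150 for feedback-type runs,
#'   250 for 5-min resting runs).
#' @param baseline_volumes volumes in the pre-feedback baseline window
#'   (default 25, i.e. 30 s at TR 1200 ms).
#' @return an `npda_acq` object.
#' @export
acquisition_params <- function(tr_ms = 1200, n_volumes = 150L,
                               baseline_volumes = 25L) {
  stopifnot(tr_ms > 0, n_volumes >= 1, baseline_volumes >= 0)
  if (baseline_volumes >= n_volumes) {
    stop_npda("baseline_volumes must be < n_volumes", "npda_spec_error")
  }
  structure(
    list(
      tr_ms = tr_ms,
      n_volumes = as.integer(n_volumes),
      baseline_volumes = as.integer(baseline_volumes)
    ),
    class = "npda_acq"
  )
}

#' Signal model for a simulated run
#'
#' Each labeled region follows a latent AR(1) Gaussian timecourse (unit
#' marginal variance). The DMN latent and FPN latent are cross-correlated at
#' `network_corr`; the mPFC and PCC latents each load on the shared DMN
#' latent so that their mutual correlation is `mpfc_pcc_corr`. WM, CSF and
#' unlabeled brain carry independent latents scaled by `tissue_amplitude`.
#' Voxel series add linear drift, a motion-coupled nuisance term proportional
#' to relative displacement, and white Gaussian noise.
#'
#' Defaults state the simulated world once: unit network amplitude against
#' unit noise (SNR 1), a moderate DMN-FPN anticorrelation (-0.35) and
#' mPFC-PCC coupling (0.5) typical of resting-state data, weak temporal
#' autocorrelation (AR(1) 0.3 at TR 1.2 s), and a small scanner drift.
#'
#' @param dmn_amplitude,fpn_amplitude latent amplitudes in noise-SD units.
#' @param network_corr target DMN-FPN latent correlation, in `[-1, 1]`.
#' @param mpfc_pcc_corr target mPFC-PCC latent correlation, in `[0, 1]`.
#' @param drift_slope linear drift per volume (signal units).
#' @param noise_sd white-noise SD.
#' @param ar1_coef AR(1) coefficient of the latents, in `[0, 1)`.
#' @param tissue_amplitude amplitude of WM/CSF/unlabeled-brain latents.
#' @param motion_coupling amplitude of the additive motion nuisance
#'   (signal units per mm of relative displacement).
#' @param outlier_volumes integer volume indices that receive a motion spike.
#' @param spike_mm translation magnitude of a motion spike.
#' @param feedback_effect constant shift (in noise-SD units) added to FPN
#'   voxels and subtracted from DMN voxels after the baseline window;
#'   emulates successful regulation during feedback runs (0 = rest).
#' @param brain_intensity constant baseline intensity added to brain voxels,
#'   giving images the bright-brain/dark-background structure that
#'   intensity-threshold brain extraction relies on.
#' @param seed integer RNG seed.
#' @return an `npda_signal` object.
#' @export
signal_spec <- function(dmn_amplitude = 1, fpn_amplitude = 1,
                        network_corr = -0.35, mpfc_pcc_corr = 0.5,
                        drift_slope = 0.01, noise_sd = 1,
                        ar1_coef = 0.3, tissue_amplitude = 0.5,
                        motion_coupling = 0.5,
                        outlier_volumes = integer(0), spike_mm = 2,
                        feedback_effect = 0, brain_intensity = 100,
                        seed = 1L) {
  stopifnot(
    abs(network_corr) <= 1, mpfc_pcc_corr >= 0, mpfc_pcc_corr <= 1,
    noise_sd >= 0, ar1_coef >= 0, ar1_coef < 1
  )
  # latent correlation structure must be a valid covariance: the shared-DMN
  # construction below is PSD for any mpfc_pcc_corr in [0,1] and
  # |network_corr| <= 1, so only bounds need checking.
  structure(
    list(
      dmn_amplitude = dmn_amplitude, fpn_amplitude = fpn_amplitude,
      network_corr = network_corr, mpfc_pcc_corr = mpfc_pcc_corr,
      drift_slope = drift_slope, noise_sd = noise_sd,
      ar1_coef = ar1_coef, tissue_amplitude = tissue_amplitude,
      motion_coupling = motion_coupling,
      outlier_volumes = as.integer(outlier_volumes), spike_mm = spike_mm,
      feedback_effect = feedback_effect, brain_intensity = brain_intensity,
      seed = as.integer(seed)
    ),
    class = "npda_signal"
  )
}

# AR(1) series with unit marginal variance from standard-normal innovations.
ar1_filter <- function(innov, phi) {
  n <- length(innov)
  x <- numeric(n)
  x[1] <- innov[1]
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * innov[t]
  x
}

#' Simulate a head-motion trace
#'
#' A slow random walk over 6 rigid-body parameters (3 translations in mm,
#' 3 rotations in radians) with optional spike displacements at given
#' volumes. Relative displacement (difference from the previous volume; zero
#' for volume 1) and a Jenkinson-style framewise displacement scalar
#' (translation displacement plus rotation displacement on a 50 mm sphere)
#' are derived per volume.
#'
#' @param n_volumes run length.
#' @param step_trans_mm,step_rot_rad random-walk innovation SDs.
#' @param outlier_volumes volumes receiving a translation spike.
#' @param spike_mm spike magnitude in mm.
#' @param seed integer RNG seed.
#' @return tibble with columns `volume`, `trans_x..rot_z`, the six relative
#'   displacements `d_*`, and `fd`.
#' @export
simulate_motion <- function(n_volumes, step_trans_mm = 0.02,
                            step_rot_rad = 4e-4,
                            outlier_volumes = integer(0), spike_mm = 2,
                            seed = 1L) {
  with_seed(seed, {
    steps <- cbind(
      matrix(stats::rnorm(n_volumes * 3, 0, step_trans_mm), n_volumes, 3),
      matrix(stats::rnorm(n_volumes * 3, 0, step_rot_rad), n_volumes, 3)
    )
    steps[1, ] <- 0
    ov <- outlier_volumes[outlier_volumes >= 2 & outlier_volumes <= n_volumes]
    if (length(ov)) {
      ax <- sample.int(3, length(ov), replace = TRUE)
      sgn <- sample(c(-1, 1), length(ov), replace = TRUE)
      for (i in seq_along(ov)) {
        steps[ov[i], ax[i]] <- steps[ov[i], ax[i]] + sgn[i] * spike_mm
      }
    }
    pos <- apply(steps, 2, cumsum)
    if (n_volumes == 1) pos <- matrix(pos, nrow = 1)
    colnames(pos) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    rel <- rbind(rep(0, 6), diff(pos))
    colnames(rel) <- paste0("d_", colnames(pos))
    fd <- rowSums(abs(rel[, 1:3, drop = FALSE])) +
      50 * rowSums(abs(rel[, 4:6, drop = FALSE]))
    tibble::as_tibble(cbind(volume = seq_len(n_volumes), pos, rel, fd = fd))
  })
}

#' Simulate a 4D BOLD run on a phantom
#'
#' @param phantom an [make_phantom()] result.
#' @param acq an [acquisition_params()].
#' @param sig a [signal_spec()].
#' @return an `npda_run`: 4D `data` array (x, y, z, t), `params`, a `motion`
#'   tibble (see [simulate_motion()]), and `ground_truth` latent timecourses.
#' @export
simulate_run <- function(phantom, acq = acquisition_params(),
                         sig = signal_spec()) {
  stopifnot(inherits(phantom, "npda_phantom"), inherits(acq, "npda_acq"),
            inherits(sig, "npda_signal"))
  dim3 <- phantom$grid_shape
  nt <- acq$n_volumes
  nv <- prod(dim3)

  motion <- simulate_motion(
    nt,
    outlier_volumes = sig$outlier_volumes, spike_mm = sig$spike_mm,
    seed = derive_seed(sig$seed, "motion")
  )

  run <- with_seed(sig$seed, {
    phi <- sig$ar1_coef
    # correlated innovations: DMN factor d, FPN factor f at network_corr;
    # hub-specific parts for mPFC/PCC at loading sqrt(mpfc_pcc_corr) on d.
    z <- matrix(stats::rnorm(nt * 6), nt, 6)
    d_in <- z[, 1]
    f_in <- sig$network_corr * z[, 1] + sqrt(1 - sig$network_corr^2) * z[, 2]
    a <- sqrt(sig$mpfc_pcc_corr)
    b <- sqrt(1 - sig$mpfc_pcc_corr)
    lat <- list(
      DMN_other = ar1_filter(d_in, phi),
      FPN = ar1_filter(f_in, phi)
    )
    lat$DMN_mPFC <- a * lat$DMN_other + b * ar1_filter(z[, 3], phi)
    lat$DMN_PCC <- a * lat$DMN_other + b * ar1_filter(z[, 4], phi)
    lat$WM <- ar1_filter(z[, 5], phi)
    lat$CSF <- ar1_filter(z[, 6], phi)
    # one independent latent per other-brain parcel: a realistic mosaic of
    # unrelated sources rather than one monolithic background signal
    parcels <- phantom$parcels %||% list(phantom$regions$other_brain)
    parcel_lat <- lapply(seq_along(parcels),
                         function(i) ar1_filter(stats::rnorm(nt), phi))

    amp <- c(
      DMN_mPFC = sig$dmn_amplitude, DMN_PCC = sig$dmn_amplitude,
      DMN_other = sig$dmn_amplitude, FPN = sig$fpn_amplitude,
      WM = sig$tissue_amplitude, CSF = sig$tissue_amplitude,
      other_brain = sig$tissue_amplitude
    )

    # regulation step during feedback: FPN up, DMN down, after baseline
    shift <- numeric(nt)
    if (sig$feedback_effect != 0 && acq$baseline_volumes < nt) {
      shift[(acq$baseline_volumes + 1):nt] <- sig$feedback_effect * sig$noise_sd
    }

    dat <- matrix(0, nt, nv)  # time x voxel, reshaped at the end
    for (rn in setdiff(names(phantom$regions), "other_brain")) {
      idx <- phantom$regions[[rn]]
      if (!length(idx)) next
      tc <- amp[[rn]] * lat[[rn]]
      if (rn %in% c("DMN_mPFC", "DMN_PCC", "DMN_other")) tc <- tc - shift
      if (rn == "FPN") tc <- tc + shift
      dat[, idx] <- dat[, idx] + tc
    }
    for (i in seq_along(parcels)) {
      idx <- parcels[[i]]
      if (!length(idx)) next
      dat[, idx] <- dat[, idx] + amp[["other_brain"]] * parcel_lat[[i]]
    }
    dat <- dat + sig$drift_slope * seq_len(nt)
    if (sig$brain_intensity != 0) {
      brain_idx0 <- which(phantom$masks$whole_brain$voxels)
      dat[, brain_idx0] <- dat[, brain_idx0] + sig$brain_intensity
    }

    if (sig$motion_coupling != 0) {
      rel <- as.matrix(motion[, paste0("d_", c("trans_x", "trans_y", "trans_z",
                                               "rot_x", "rot_y", "rot_z"))])
      brain_idx <- which(phantom$masks$whole_brain$voxels)
      coup <- matrix(stats::rnorm(length(brain_idx) * 6, 0, sig$motion_coupling),
                     6, length(brain_idx))
      dat[, brain_idx] <- dat[, brain_idx] + rel %*% coup
    }

    if (sig$noise_sd > 0) {
      dat <- dat + matrix(stats::rnorm(nt * nv, 0, sig$noise_sd), nt, nv)
    }

    gt <- tibble::as_tibble(lat)
    gt$volume <- seq_len(nt)
    list(dat = dat, gt = gt[, c("volume", names(lat))])
  })

  structure(
    list(
      data = array(t(run$dat), dim = c(dim3, nt)),
      params = acq,
      motion = motion,
      ground_truth = run$gt,
      voxel_size_mm = phantom$voxel_size_mm,
      grid_shape = dim3
    ),
    class = "npda_run"
  )
}

#' @export
print.npda_run <- function(x, ...) {
  cat(sprintf(
    "<npda_run> %s grid x %d volumes (TR %g ms)\n",
    paste(x$grid_shape, collapse = "x"), x$params$n_volumes, x$params$tr_ms
  ))
  invisible(x)
}

# time x voxel matrix view of a run
run_matrix <- function(run) {
  nv <- prod(run$grid_shape)
  nt <- run$params$n_volumes
  t(matrix(run$data, nv, nt))
}

# rebuild a run from a time x voxel matrix, preserving metadata
run_from_matrix <- function(run, mat, n_volumes = nrow(mat)) {
  run$data <- array(t(mat), dim = c(run$grid_shape, n_volumes))
  run$params$n_volumes <- as.integer(n_volumes)
  run
}

#' Stream a run volume-by-volume, emulating real-time acquisition
#'
#' @param run an `npda_run`.
#' @return list of items, each `list(volume = t, data = 3D array,
#'   motion = named 6-vector)`, strictly in time order. Replayable: the list
#'   can be consumed any number of times and is identical each time.
#' @export
stream_volumes <- function(run) {
  stopifnot(inherits(run, "npda_run"))
  mcols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  lapply(seq_len(run$params$n_volumes), function(t) {
    m <- as.numeric(run$motion[t, mcols])
    names(m) <- mcols
    list(
      volume = t,
      data = run$data[, , , t, drop = TRUE],
      motion = m
    )
  })
}

#' Framewise displacement of a motion trace
#'
#' Jenkinson-style scalar: sum of absolute relative translations (mm) plus
#' 50 mm times the sum of absolute relative rotations (radians).
#'
#' @param motion a motion tibble as produced by [simulate_motion()], or any
#'   data frame with `trans_*`/`rot_*` columns.
#' @return numeric vector of per-volume FD (first volume 0).
#' @export
framewise_displacement <- function(motion) {
  pos <- as.matrix(motion[, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z")])
  rel <- rbind(rep(0, 6), diff(pos))
  rowSums(abs(rel[, 1:3, drop = FALSE])) +
    50 * rowSums(abs(rel[, 4:6, drop = FALSE]))
}
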