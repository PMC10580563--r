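# Post-hoc resting-state cleaning and mPFC-PCC connectivity.

#' Cleaning parameters for post-hoc connectivity preprocessing
#'
#' @param acompcor_components principal components per tissue (WM, CSF)
#'   entered as nuisance regressors (default 5).
#' @param gsr include global signal regression (mean gray-matter series)?
#' @param bandpass_low,bandpass_high bandpass edges in Hz (defaults 0.008
#'   and 0.09).
#' @param fd_censor_threshold_mm framewise-displacement censoring threshold
#'   in mm (default 0.3; the protocol defers the exact value to standards
#'   at analysis time, so this is configurable and echoed in outputs).
#' @param butter_order Butterworth filter order (default 4).
#' @return an `npda_cleaning` object. The motion set (6 parameters + first
#'   derivatives = 12) and the linear drift term are always included.
#' @export
cleaning_params <- function(acompcor_components = 5L, gsr = FALSE,
                            bandpass_low = 0.008, bandpass_high = 0.09,
                            fd_censor_threshold_mm = 0.3,
                            butter_order = 4L) {
  stopifnot(bandpass_low > 0, bandpass_low < bandpass_high,
            fd_censor_threshold_mm > 0, acompcor_components >= 1)
  structure(
    list(
      motion_regressors = 12L,
      acompcor_components = as.integer(acompcor_components),
      linear_drift = TRUE,
      gsr = gsr,
      bandpass_low = bandpass_low, bandpass_high = bandpass_high,
      fd_censor_threshold_mm = fd_censor_threshold_mm,
      butter_order = as.integer(butter_order)
    ),
    class = "npda_cleaning"
  )
}

# Zero-phase Butterworth bandpass applied in the frequency domain: the
# squared-magnitude response of an order-n analog Butterworth band filter
# (the gain filtfilt would realize) multiplies the FFT, giving zero phase
# and no edge transients.
butter_bandpass_fft <- function(mat, tr_s, low, high, order = 4) {
  nt <- nrow(mat)
  f <- (seq_len(nt) - 1) / (nt * tr_s)
  f <- pmin(f, 1 / tr_s - f)
  hp <- ifelse(f == 0, 0, 1 / (1 + (low / pmax(f, 1e-12))^(2 * order)))
  lp <- 1 / (1 + (f / high)^(2 * order))
  gain <- hp * lp
  ft <- stats::mvfft(mat)
  ft <- ft * gain
  Re(stats::mvfft(ft, inverse = TRUE)) / nt
}

# top-k principal component scores of a time x voxel matrix
tissue_pcs <- function(mat, k) {
  mat <- sweep(mat, 2, colMeans(mat), `-`)
  sv <- svd(mat, nu = min(k, ncol(mat), nrow(mat) - 1), nv = 0)
  u <- sv$u
  keep <- seq_len(min(k, ncol(u)))
  scale(u[, keep, drop = FALSE])
}

#' Clean a resting run for connectivity analysis
#'
#' Builds the anticipated nuisance design -- 12 motion regressors (6 rigid
#' parameters and their first differences), the top-`acompcor_components`
#' principal components of the white-matter and CSF voxel series (aCompCor),
#' a linear drift term, and optionally the mean gray-matter signal (GSR) --
#' regresses it out of every voxel, bandpasses the residuals (0.008-0.09 Hz
#' zero-phase Butterworth by default), and flags volumes whose framewise
#' displacement exceeds the censoring threshold. Censored volumes are
#' retained in the array but excluded downstream (filter-then-censor).
#'
#' @param run an `npda_run` with a motion table.
#' @param wm,csf tissue `npda_mask`s.
#' @param brain whole-brain `npda_mask` (gray matter = brain minus WM/CSF).
#' @param p a [cleaning_params()].
#' @return the cleaned `npda_run`, with logical `censor` (TRUE = censored)
#'   and `mean_fd` attached.
#' @export
clean_run <- function(run, wm, csf, brain, p = cleaning_params()) {
  stopifnot(inherits(run, "npda_run"))
  nt <- run$params$n_volumes
  m <- run_matrix(run)

  pos <- as.matrix(run$motion[, c("trans_x", "trans_y", "trans_z",
                                  "rot_x", "rot_y", "rot_z")])
  dpos <- rbind(rep(0, 6), diff(pos))
  fd <- framewise_displacement(run$motion)

  wm_idx <- which(wm$voxels)
  csf_idx <- which(csf$voxels)
  if (!length(wm_idx) || !length(csf_idx)) {
    stop_npda("WM and CSF masks must be nonempty", "npda_cleaning_error")
  }
  X <- cbind(
    1,
    scale(pos, scale = FALSE), dpos,
    tissue_pcs(m[, wm_idx, drop = FALSE], p$acompcor_components),
    tissue_pcs(m[, csf_idx, drop = FALSE], p$acompcor_components),
    seq_len(nt) / nt - 0.5
  )
  if (p$gsr) {
    gm_idx <- which(brain$voxels & !wm$voxels & !csf$voxels)
    X <- cbind(X, scale(rowMeans(m[, gm_idx, drop = FALSE])))
  }
  if (nt <= ncol(X)) {
    stop_npda("fewer timepoints than nuisance regressors", "npda_cleaning_error")
  }
  qr_X <- qr(X)
  resid <- m - X %*% qr.coef(qr_X, m)
  resid[is.na(resid)] <- 0

  resid <- butter_bandpass_fft(resid, run$params$tr_ms / 1000,
                               p$bandpass_low, p$bandpass_high,
                               p$butter_order)
  out <- run_from_matrix(run, resid)
  out$censor <- fd > p$fd_censor_threshold_mm
  out$mean_fd <- mean(fd)
  out$cleaning <- p
  out
}

#' ROI-to-ROI functional connectivity
#'
#' Product-moment correlation between the average timecourses of two ROIs
#' over uncensored volumes, with the Fisher r-to-z transform. A personalized
#' ROI containing fewer than `min_voxels` voxels is replaced by its template
#' counterpart and the substitution flagged.
#'
#' @param run a cleaned `npda_run` (with `censor` attached; absent means no
#'   censoring).
#' @param roi_a,roi_b `npda_mask` ROIs.
#' @param template_a,template_b template fallbacks for undersized
#'   personalized ROIs (optional).
#' @param min_voxels ROI size floor (default 200).
#' @return tibble with `r`, `fisher_z`, `n_volumes_used`,
#'   `roi_a_substituted`, `roi_b_substituted`.
#' @export
roi_connectivity <- function(run, roi_a, roi_b,
                             template_a = NULL, template_b = NULL,
                             min_voxels = 200L) {
  stopifnot(inherits(run, "npda_run"))
  sub_a <- FALSE
  sub_b <- FALSE
  if (roi_a$n_voxels < min_voxels && !is.null(template_a)) {
    roi_a <- template_a
    sub_a <- TRUE
  }
  if (roi_b$n_voxels < min_voxels && !is.null(template_b)) {
    roi_b <- template_b
    sub_b <- TRUE
  }
  keep <- !(run$censor %||% rep(FALSE, run$params$n_volumes))
  if (sum(keep) < 10) {
    stop_npda("fewer than 10 uncensored volumes", "npda_connectivity_error")
  }
  m <- run_matrix(run)[keep, , drop = FALSE]
  a <- rowMeans(m[, which(roi_a$voxels), drop = FALSE])
  b <- rowMeans(m[, which(roi_b$voxels), drop = FALSE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_npda("constant ROI timecourse; correlation undefined",
              "npda_connectivity_error")
  }
  r <- stats::cor(a, b)
  tibble::tibble(
    r = r,
    fisher_z = fisher_z(r),
    n_volumes_used = sum(keep),
    roi_a_substituted = sub_a,
    roi_b_substituted = sub_b
  )
}

#' Fisher r-to-z transform
#'
#' `atanh` with the correlation clipped to +/-(1 - 1e-7) so the transform is
#' always finite.
#'
#' @param r correlation coefficient(s).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Benjamini-Hochberg adjustment within test families
#'
#' Applies the BH step-up procedure separately within each family (the
#' analysis plan groups its secondary tests into a 4-test depression family
#' and a 3-test rumination family) and reports which hypotheses are
#' rejected at the target false-discovery rate.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param families factor/vector assigning each p-value to a family
#'   (default: one family).
#' @param alpha FDR level (default 0.05).
#' @return tibble with `p`, `family`, `p_adjusted`, `rejected`.
#' @export
bh_adjust <- function(p_values, families = rep(1L, length(p_values)),
                      alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop_npda("p-values must lie in [0, 1]", "npda_contract_error")
  }
  stopifnot(length(families) == length(p_values))
  fam <- as.character(families)
  adj <- numeric(length(p_values))
  for (f in unique(fam)) {
    i <- fam == f
    adj[i] <- stats::p.adjust(p_values[i], method = "BH")
  }
  tibble::tibble(
    p = p_values, family = fam, p_adjusted = adj, rejected = adj <= alpha
  )
}

#' Item-level imputation for self-report scales
#'
#' Person-mean imputation for respondents missing fewer than 10% of a
#' scale's items; respondents at or above that threshold get a missing
#' scale score. Sum scores are returned.
#'
#' @param items data frame / matrix of item responses (rows = respondents),
#'   `NA` = missing.
#' @param max_missing_prop threshold proportion (default 0.10, exclusive).
#' @return numeric vector of scale sum scores (NA where unscorable).
#' @export
item_impute <- function(items, max_missing_prop = 0.10) {
  items <- as.matrix(items)
  apply(items, 1, function(row) {
    miss <- mean(is.na(row))
    if (miss >= max_missing_prop) return(NA_real_)
    if (miss > 0) row[is.na(row)] <- mean(row, na.rm = TRUE)
    sum(row)
  })
}
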