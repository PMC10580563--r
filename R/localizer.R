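#' Preprocessing parameters for the network localizer
#'
#' @param smoothing_fwhm_mm Gaussian smoothing kernel FWHM in mm (default 5).
#' @param highpass_hz temporal high-pass cutoff in Hz (default 0.01).
#' @param brain_threshold brain-extraction threshold as a fraction of the
#'   robust (2nd-98th percentile) intensity range of the mean image.
#' @return an `npda_preproc` object.
#' @export
preproc_params <- function(smoothing_fwhm_mm = 5, highpass_hz = 0.01,
                           brain_threshold = 0.5) {
  stopifnot(smoothing_fwhm_mm >= 0, highpass_hz > 0,
            brain_threshold > 0, brain_threshold < 1)
  structure(
    list(
      smoothing_fwhm_mm = smoothing_fwhm_mm,
      highpass_hz = highpass_hz,
      brain_threshold = brain_threshold
    ),
    class = "npda_preproc"
  )
}

# Column-normalized 1D Gaussian convolution matrix: an impulse keeps its
# total mass even at grid edges where the kernel is truncated.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
  K <- exp(-d^2 / (2 * sigma_vox^2))
  sweep(K, 2, colSums(K), `/`)
}

# Separable 3D Gaussian smoothing applied to every volume of a 4D array.
smooth_4d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  K1 <- gauss_conv_matrix(d[1], sigma_vox)
  K2 <- gauss_conv_matrix(d[2], sigma_vox)
  K3 <- gauss_conv_matrix(d[3], sigma_vox)
  # axis 1
  m <- matrix(arr, d[1], prod(d[-1]))
  arr <- array(K1 %*% m, dim = d)
  # axis 2
  p <- aperm(arr, c(2, 1, 3, 4))
  m <- matrix(p, d[2], prod(d[-2]))
  p <- array(K2 %*% m, dim = d[c(2, 1, 3, 4)])
  arr <- aperm(p, c(2, 1, 3, 4))
  # axis 3
  p <- aperm(arr, c(3, 1, 2, 4))
  m <- matrix(p, d[3], prod(d[c(1, 2, 4)]))
  p <- array(K3 %*% m, dim = d[c(3, 1, 2, 4)])
  aperm(p, c(2, 3, 1, 4))
}

# Discrete high-pass: zero all FFT bins strictly below the cutoff frequency,
# including DC, symmetrically in positive and negative frequencies.
highpass_fft <- function(mat, tr_s, cutoff_hz) {
  nt <- nrow(mat)
  freqs <- (seq_len(nt) - 1) / (nt * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= cutoff_hz
  ft <- stats::mvfft(mat)
  ft[!keep, ] <- 0
  Re(stats::mvfft(ft, inverse = TRUE)) / nt
}

#' Preprocess a localizer run
#'
#' Desk-scale analog of the protocol's speed-first localizer preprocessing:
#' realignment is the identity (motion is tabulated, not re-estimated), brain
#' extraction is an intensity threshold on the mean image, then Gaussian
#' spatial smoothing (FWHM in mm converted to voxel sigma) and a temporal
#' high-pass (0.01 Hz default) are applied to brain voxels.
#'
#' @param run an `npda_run`.
#' @param p a [preproc_params()].
#' @return the preprocessed `npda_run`; the derived brain mask is attached as
#'   `run$brain_mask` (an `npda_mask`).
#' @export
preprocess_localizer <- function(run, p = preproc_params()) {
  stopifnot(inherits(run, "npda_run"))
  if (run$params$n_volumes < 3) {
    stop_npda("run must have at least 3 volumes", "npda_length_error")
  }
  mean_img <- apply(run$data, c(1, 2, 3), mean)
  qs <- stats::quantile(mean_img, c(0.02, 0.98), names = FALSE)
  thr <- qs[1] + p$brain_threshold * (qs[2] - qs[1])
  brain <- mean_img > thr
  if (!any(brain)) stop_npda("brain extraction found no voxels", "npda_preproc_error")

  arr <- run$data
  # zero out non-brain voxels across all volumes
  nb <- which(!brain)
  if (length(nb)) {
    nv <- prod(run$grid_shape)
    m <- matrix(arr, nv, run$params$n_volumes)
    m[nb, ] <- 0
    arr <- array(m, dim = dim(arr))
  }

  sigma_vox <- (p$smoothing_fwhm_mm / (2 * sqrt(2 * log(2)))) / run$voxel_size_mm
  arr <- smooth_4d(arr, sigma_vox)

  nv <- prod(run$grid_shape)
  m <- t(matrix(arr, nv, run$params$n_volumes))
  bidx <- which(brain)
  m[, bidx] <- highpass_fft(m[, bidx, drop = FALSE], run$params$tr_ms / 1000,
                            p$highpass_hz)
  out <- run_from_matrix(run, m)
  out$brain_mask <- network_mask("whole_brain", brain, provenance = "personalized")
  out
}

# Integer-voxel translation registration by center-of-mass alignment of the
# positive part of the reference and moving mean images.
estimate_translation <- function(ref_vol, mov_vol) {
  com <- function(v) {
    v <- pmax(v, 0)
    s <- sum(v)
    if (s == 0) return(c(0, 0, 0))
    d <- dim(v)
    idx <- arrayInd(seq_along(v), .dim = d)
    colSums(idx * as.numeric(v)) / s
  }
  round(com(ref_vol) - com(mov_vol))
}

shift_array <- function(arr4d, shift) {
  if (all(shift == 0)) return(arr4d)
  d <- dim(arr4d)
  out <- array(0, dim = d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - shift[a]
    i[i >= 1 & i <= d[a]]
  })
  dst <- lapply(1:3, function(a) src[[a]] + shift[a])
  out[dst[[1]], dst[[2]], dst[[3]], ] <- arr4d[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  out
}

#' Concatenate one or two resting runs for ICA
#'
#' Implements the protocol's concatenation rules: the second run is used only
#' if it has at least `min_volumes` volumes (2.5 min at TR 1200 ms);
#' if the runs differ in length, volumes are removed from the end of the
#' longer run; the second run is registered to the median volume of the first
#' (translation-only in the shared synthetic frame); each run's voxelwise
#' mean is removed before temporal concatenation.
#'
#' @param run1 first (required) preprocessed resting run.
#' @param run2 optional second preprocessed resting run.
#' @param min_volumes minimum usable run length (default 125).
#' @return an `npda_run` holding the concatenated series. Errors with class
#'   `npda_localizer_unusable` if `run1` itself is shorter than
#'   `min_volumes`, which signals the template-fallback path.
#' @export
concatenate_runs <- function(run1, run2 = NULL, min_volumes = 125L) {
  stopifnot(inherits(run1, "npda_run"))
  if (run1$params$n_volumes < min_volumes) {
    stop_npda(
      sprintf("first resting run has %d < %d volumes; localizer unusable",
              run1$params$n_volumes, min_volumes),
      "npda_localizer_unusable"
    )
  }
  demean <- function(m) sweep(m, 2, colMeans(m), `-`)
  m1 <- run_matrix(run1)
  if (is.null(run2) || run2$params$n_volumes < min_volumes) {
    return(run_from_matrix(run1, demean(m1)))
  }
  n <- min(run1$params$n_volumes, run2$params$n_volumes)
  median_vol <- run1$data[, , , ceiling(run1$params$n_volumes / 2), drop = TRUE]
  mov_mean <- apply(run2$data, c(1, 2, 3), mean)
  shift <- estimate_translation(median_vol, mov_mean)
  reg2 <- shift_array(run2$data, shift)
  m2 <- t(matrix(reg2, prod(run2$grid_shape), run2$params$n_volumes))
  m <- rbind(demean(m1[seq_len(n), , drop = FALSE]),
             demean(m2[seq_len(n), , drop = FALSE]))
  out <- run_from_matrix(run1, m)
  out$motion <- NULL  # motion traces are per-run; not meaningful concatenated
  out
}
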