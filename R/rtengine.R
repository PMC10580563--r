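# Real-time per-voxel incremental GLM engine.
#
# Each voxel in the (eroded) DMN and FPN masks carries a least-squares fit
# of its signal on nuisance regressors only: an intercept, the six relative
# head displacements, and a linear drift term. The fit is updated by
# Gentleman's square-root-free Givens algorithm (AS 75): one shared
# unit-upper-triangular factor and row-scale vector for the common design,
# plus per-voxel rotated right-hand sides, so a volume's update costs
# O(p^2 + p * n_voxels). Residuals from volumes after the 25-volume baseline
# window are z-scored against the frozen baseline residual distribution and
# combined into network activations by inverse-baseline-variance
# ("efficiency") weighting.

N_REGRESSORS <- 8L  # intercept + 6 relative displacements + drift

# 6-connectivity erosion of a logical 3D array.
erode_mask <- function(voxels) {
  d <- dim(voxels)
  padded <- array(FALSE, dim = d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- voxels
  core <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  core &
    padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
}

#' Initialize the real-time GLM engine
#'
#' The DMN and FPN masks are intersected with the whole-brain mask eroded by
#' one voxel (6-connectivity), excluding voxels near or off the brain edge.
#'
#' @param dmn,fpn network `npda_mask`s.
#' @param whole_brain whole-brain `npda_mask` on the same grid.
#' @param baseline_volumes baseline window length (default 25 volumes, 30 s
#'   at TR 1200 ms).
#' @param n_volumes planned run length, used to scale the drift regressor.
#' @param outlier_sd activation magnitude beyond which a volume is flagged
#'   an outlier (default 2 SD).
#' @return an `npda_engine` state object.
#' @export
init_engine <- function(dmn, fpn, whole_brain, baseline_volumes = 25L,
                        n_volumes = 150L, outlier_sd = 2) {
  stopifnot(inherits(dmn, "npda_mask"), inherits(fpn, "npda_mask"),
            inherits(whole_brain, "npda_mask"))
  d <- dim(whole_brain$voxels)
  if (!identical(dim(dmn$voxels), d) || !identical(dim(fpn$voxels), d)) {
    stop_npda("masks must share one grid", "npda_config_error")
  }
  eroded <- erode_mask(whole_brain$voxels)
  dmn_idx <- which(dmn$voxels & eroded)
  fpn_idx <- which(fpn$voxels & eroded)
  if (!length(dmn_idx) || !length(fpn_idx)) {
    stop_npda("a network mask is empty after erosion intersection",
              "npda_config_error")
  }
  vox_idx <- sort(unique(c(dmn_idx, fpn_idx)))
  p <- N_REGRESSORS
  nv <- length(vox_idx)
  structure(
    list(
      grid_shape = d,
      vox_idx = vox_idx,
      dmn_cols = match(dmn_idx, vox_idx),
      fpn_cols = match(fpn_idx, vox_idx),
      baseline_volumes = as.integer(baseline_volumes),
      n_volumes = as.integer(n_volumes),
      outlier_sd = outlier_sd,
      # Gentleman state: D (row scales), Rbar (unit upper triangular),
      # theta (p x nv rotated responses)
      D = numeric(p),
      Rbar = diag(p),
      theta = matrix(0, p, nv),
      volumes_seen = 0L,
      prev_motion = NULL,
      # baseline window storage (design rows and responses through t = 25)
      base_X = matrix(0, baseline_volumes, p),
      base_Y = matrix(0, baseline_volumes, nv),
      frozen = FALSE,
      mu = NULL, sigma = NULL,
      w_dmn = NULL, w_fpn = NULL,
      dropped_voxels = integer(0)
    ),
    class = "npda_engine"
  )
}

# Gentleman / AS 75 INCLUD step for one observation row shared across
# voxels: updates D, Rbar in place-ish and the p x nv theta matrix; returns
# the residual weight w and transformed responses for the SSE update.
gentleman_include <- function(D, Rbar, theta, x, y) {
  p <- length(D)
  w <- 1
  for (i in seq_len(p)) {
    if (w == 0) break          # row fully absorbed; nothing left to rotate
    if (x[i] == 0) next
    di <- D[i]
    dpi <- di + w * x[i]^2
    if (dpi == 0) next
    cbar <- di / dpi
    sbar <- w * x[i] / dpi
    w <- cbar * w
    D[i] <- dpi
    xi <- x[i]
    if (i < p) {
      k <- (i + 1):p
      xk <- x[k]
      x[k] <- xk - xi * Rbar[i, k]
      Rbar[i, k] <- cbar * Rbar[i, k] + sbar * xk
    }
    yk <- y
    y <- yk - xi * theta[i, ]
    theta[i, ] <- cbar * theta[i, ] + sbar * yk
  }
  list(D = D, Rbar = Rbar, theta = theta, w = w, resid_y = y)
}

# Solve the triangular system for coefficients; columns with (near-)zero
# row scale are dependent and get zero coefficients for this solve.
gentleman_coef <- function(D, Rbar, theta, tol = 1e-10) {
  p <- length(D)
  scale_ref <- max(D, 0)
  active <- D > tol * max(scale_ref, 1)
  beta <- matrix(0, p, ncol(theta))
  for (i in rev(seq_len(p))) {
    if (!active[i]) next
    acc <- theta[i, ]
    if (i < p) {
      k <- (i + 1):p
      acc <- acc - drop(Rbar[i, k, drop = FALSE] %*% beta[k, , drop = FALSE])
    }
    beta[i, ] <- acc
  }
  beta
}

# Design row for volume t: intercept, relative displacement 6-vector,
# centered/scaled drift.
design_row <- function(t, motion, prev_motion, n_volumes) {
  rel <- if (t == 1 || is.null(prev_motion)) rep(0, 6) else motion - prev_motion
  drift <- (t - (n_volumes + 1) / 2) / n_volumes
  c(1, rel, drift)
}

#' Ingest one streamed volume into the engine
#'
#' Updates every masked voxel's incremental least-squares fit with the new
#' volume, computes the current residual (measured signal minus the
#' nuisance-model reconstruction at time `t`, with coefficients fit on all
#' volumes through `t`), and, once past the baseline window, emits an
#' activation sample: per-network inverse-variance-weighted mean of the
#' voxel residual z-scores against the frozen baseline residual mean/SD.
#'
#' At `t = baseline_volumes` the baseline statistics are frozen: residuals
#' of volumes 1..baseline from the baseline-final fit define each voxel's
#' residual mean and sample SD, and the efficiency weights (proportional to
#' inverse baseline variance, normalized to sum 1 within each network).
#' Zero-variance voxels are dropped from weighting and recorded.
#'
#' @param state an `npda_engine`.
#' @param item a streamed item from [stream_volumes()], or a list with
#'   `volume`, `data` (3D array), `motion` (6-vector).
#' @return list with `state` (updated) and `sample`: `NULL` during the
#'   baseline phase, otherwise a one-row tibble with `volume`, `z_dmn`,
#'   `z_fpn`, `pda`, `outlier`.
#' @export
ingest <- function(state, item) {
  stopifnot(inherits(state, "npda_engine"))
  t <- item$volume
  if (t != state$volumes_seen + 1L) {
    stop_npda(sprintf("out-of-order volume: expected %d, got %d",
                      state$volumes_seen + 1L, t), "npda_sequence_error")
  }
  y <- as.numeric(item$data)[state$vox_idx]
  bad_volume <- any(!is.finite(y))
  if (bad_volume) y[!is.finite(y)] <- 0

  x <- design_row(t, as.numeric(item$motion), state$prev_motion, state$n_volumes)
  upd <- gentleman_include(state$D, state$Rbar, state$theta, x, y)
  state$D <- upd$D
  state$Rbar <- upd$Rbar
  state$theta <- upd$theta
  state$volumes_seen <- t
  state$prev_motion <- as.numeric(item$motion)

  if (t <= state$baseline_volumes) {
    state$base_X[t, ] <- x
    state$base_Y[t, ] <- y
    if (t == state$baseline_volumes) state <- freeze_baseline(state)
    return(list(state = state, sample = NULL))
  }

  # residual at t from coefficients fit on volumes 1..t
  beta <- gentleman_coef(state$D, state$Rbar, state$theta)
  resid <- if (t < N_REGRESSORS) rep(0, length(y)) else y - drop(x %*% beta)

  z_vox <- (resid - state$mu) / state$sigma
  z_vox[state$sigma <= 0] <- 0
  z_dmn <- network_activation(z_vox[state$dmn_cols], state$w_dmn)
  z_fpn <- network_activation(z_vox[state$fpn_cols], state$w_fpn)
  outlier <- bad_volume || abs(z_dmn) > state$outlier_sd ||
    abs(z_fpn) > state$outlier_sd
  sample <- tibble::tibble(
    volume = t, z_dmn = z_dmn, z_fpn = z_fpn,
    pda = z_fpn - z_dmn, outlier = outlier
  )
  list(state = state, sample = sample)
}

freeze_baseline <- function(state) {
  beta <- gentleman_coef(state$D, state$Rbar, state$theta)
  fitted <- state$base_X %*% beta
  res <- state$base_Y - fitted
  mu <- colMeans(res)
  n <- nrow(res)
  sigma <- sqrt(colSums(sweep(res, 2, mu, `-`)^2) / (n - 1))
  state$mu <- mu
  state$sigma <- sigma
  zero_var <- which(sigma <= .Machine$double.eps^0.5)
  state$dropped_voxels <- zero_var

  inv_var <- 1 / sigma^2
  inv_var[zero_var] <- 0
  mk_w <- function(cols) {
    w <- inv_var[cols]
    s <- sum(w)
    # all voxels noiseless in baseline: degenerate but well-defined --
    # every voxel is excluded from weighting and the activation is 0
    if (s <= 0) return(rep(0, length(w)))
    w / s
  }
  state$w_dmn <- mk_w(state$dmn_cols)
  state$w_fpn <- mk_w(state$fpn_cols)
  state$frozen <- TRUE
  state
}

#' Efficiency-weighted network activation
#'
#' Weighted mean of voxel z-scores with weights proportional to inverse
#' baseline residual variance, normalized to sum 1.
#'
#' @param z voxel z-scores.
#' @param w normalized weights (same length as `z`).
#' @return scalar activation in baseline-SD units.
#' @export
network_activation <- function(z, w) {
  if (!length(z) || !length(w)) {
    stop_npda("no weighted voxels", "npda_activation_error")
  }
  stopifnot(length(z) == length(w))
  sum(w * z)
}

#' Run the engine over a whole run
#'
#' Convenience wrapper: streams a run through [ingest()] and collects the
#' per-volume activation samples.
#'
#' @param engine an initialized `npda_engine`.
#' @param run an `npda_run`.
#' @return list with `state` (final engine) and `samples` (tibble of
#'   post-baseline activation samples: volume, z_dmn, z_fpn, pda, outlier).
#' @export
run_engine <- function(engine, run) {
  items <- stream_volumes(run)
  samples <- vector("list", length(items))
  for (it in items) {
    out <- ingest(engine, it)
    engine <- out$state
    samples[[it$volume]] <- out$sample
  }
  list(state = engine, samples = dplyr::bind_rows(samples))
}
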