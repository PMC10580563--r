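# Spatial ICA for personalized network localization.
#
# No FastICA implementation ships with this R stack, so the standard
# fixed-point algorithm (symmetric orthogonalization, cube/kurtosis
# contrast -- well-suited to sparse spatial sources) is implemented here,
# operating on PCA-whitened spatial sources: time points are variables,
# voxels are observations, and each independent component is a spatial
# map with an associated mixing timecourse.

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

fastica_core <- function(V, seed, max_iter = 1000, tol = 1e-4, damp = 0) {
  k <- nrow(V)
  nv <- ncol(V)
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    S <- W %*% V
    G <- S^3
    gprime <- rowMeans(3 * S^2)
    W_new <- (G %*% t(V)) / nv - diag(gprime, k) %*% W
    # damping breaks period-2 oscillations that arise when latent sources
    # are mutually correlated (as anticorrelated networks are)
    if (damp > 0) W_new <- (1 - damp) * W_new + damp * W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) return(list(W = W, converged = TRUE, iterations = it))
  }
  list(W = W, converged = FALSE, iterations = max_iter)
}

#' Extract spatial independent components from a preprocessed run
#'
#' PCA reduces the temporal dimension to `n_components`, whitening the
#' spatial sources, and fixed-point ICA rotates them to maximal
#' non-Gaussianity. Component maps are variance-normalized over the analysis
#' support (nonzero-variance voxels); full-grid maps carry zeros elsewhere.
#' The decomposition is deterministic given `seed`; if the fixed-point
#' iteration fails to converge it is retried with derived sub-seeds a
#' bounded number of times.
#'
#' @param run preprocessed (and possibly concatenated) `npda_run`.
#' @param n_components number of components (default 35).
#' @param seed integer RNG seed for the unmixing initialization.
#' @param max_retries convergence retries before erroring.
#' @return an `npda_components` object: `maps` (list of 3D arrays),
#'   `mixing` (time x component matrix), `n_components`, `support`
#'   (linear voxel indices analyzed), `converged`, `iterations`.
#' @export
extract_components <- function(run, n_components = 35L, seed = 1L,
                               max_retries = 5L) {
  stopifnot(inherits(run, "npda_run"))
  nt <- run$params$n_volumes
  if (nt <= n_components) {
    stop_npda("run must have more volumes than components", "npda_ica_error")
  }
  m <- run_matrix(run)                      # time x voxel
  v <- matrixStats_colVars(m)
  support <- which(v > 1e-12)
  X <- m[, support, drop = FALSE]
  X <- X - rowMeans(X)                      # center each time variable

  # temporal PCA: eigendecomposition of the small (nt x nt) Gram matrix
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  k <- n_components
  lam <- e$values[seq_len(k)]
  if (any(lam <= 1e-12)) {
    stop_npda("data rank below requested component count", "npda_ica_error")
  }
  E <- e$vectors[, seq_len(k), drop = FALSE]
  V <- diag(1 / sqrt(lam), k) %*% t(E) %*% X   # k x voxels, whitened

  res <- NULL
  damps <- c(0, 0.3, 0.3, 0.5, 0.5, 0.7, rep(0.7, max(0, max_retries - 5)))
  for (r in 0:max_retries) {
    s <- if (r == 0) seed else derive_seed(seed, paste0("ica_retry", r))
    res <- fastica_core(V, s, damp = damps[r + 1])
    if (res$converged) break
  }
  if (!res$converged) {
    stop_npda("fixed-point ICA failed to converge after retries", "npda_ica_error")
  }

  S <- res$W %*% V                          # k x voxels, unit variance rows
  S <- S / sqrt(rowMeans(S^2))
  # mixing timecourses: X ~ A S  =>  A = X S^T (S S^T)^{-1}
  A <- X %*% t(S) %*% solve(tcrossprod(S))

  nvox <- prod(run$grid_shape)
  maps <- lapply(seq_len(k), function(i) {
    full <- numeric(nvox)
    full[support] <- S[i, ]
    array(full, dim = run$grid_shape)
  })
  structure(
    list(
      maps = maps, mixing = A, n_components = k, support = support,
      grid_shape = run$grid_shape,
      converged = res$converged, iterations = res$iterations, seed = seed
    ),
    class = "npda_components"
  )
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' @export
print.npda_components <- function(x, ...) {
  cat(sprintf("<npda_components> %d spatial maps on %s grid (%s, %d iterations)\n",
              x$n_components, paste(x$grid_shape, collapse = "x"),
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Spatial correlations between component maps and a template mask
#'
#' @param components an `npda_components`.
#' @param template an `npda_mask` on the same grid.
#' @return numeric vector of signed Pearson correlations, one per component,
#'   computed over the ICA analysis support.
#' @export
template_correlations <- function(components, template) {
  stopifnot(inherits(components, "npda_components"), inherits(template, "npda_mask"))
  if (!identical(dim(template$voxels), as.integer(components$grid_shape))) {
    stop_npda("template grid does not match component grid", "npda_grid_error")
  }
  tv <- as.numeric(template$voxels[components$support])
  vapply(components$maps, function(mp) {
    x <- mp[components$support]
    if (stats::sd(x) == 0 || stats::sd(tv) == 0) return(0)
    stats::cor(x, tv)
  }, numeric(1))
}

#' Select the component best matching a network template
#'
#' Picks the component whose spatial map has the highest absolute Pearson
#' correlation with the binary template. A negative winning correlation means
#' the map is sign-flipped relative to the network; downstream thresholding
#' uses the sign-corrected map.
#'
#' @param components an `npda_components`.
#' @param template an `npda_mask`.
#' @return list with `component` (index), `corr` (signed), and `sign`.
#' @export
select_network_component <- function(components, template) {
  rho <- template_correlations(components, template)
  if (all(abs(rho) < 1e-12)) {
    stop_npda("all component-template correlations are zero", "npda_selection_error")
  }
  i <- which.max(abs(rho))
  list(component = i, corr = rho[i], sign = if (rho[i] < 0) -1 else 1)
}

#' Personalize a network mask from a selected component
#'
#' Restricts the sign-corrected component map to the template support, keeps
#' the `n_vox` voxels with the largest positive weights (ties broken by
#' ascending linear voxel index), and binarizes. If fewer than `n_vox`
#' positive-weight voxels exist in the support, all of them are kept and a
#' warning is issued.
#'
#' @param component_map 3D array (sign-corrected component weights).
#' @param template an `npda_mask` delimiting the admissible voxels.
#' @param n_vox target mask size (default 2000).
#' @param source_component,selection_corr provenance bookkeeping.
#' @return a personalized `npda_mask`.
#' @export
personalize_mask <- function(component_map, template, n_vox = 2000L,
                             source_component = NULL, selection_corr = NULL) {
  stopifnot(is.array(component_map), inherits(template, "npda_mask"))
  support <- which(template$voxels)
  if (!length(support)) stop_npda("template support is empty", "npda_mask_error")
  w <- component_map[support]
  pos <- support[w > 0]
  wpos <- w[w > 0]
  if (length(pos) < n_vox) {
    warning(sprintf(
      "only %d positive-weight voxels in template support (requested %d); keeping all",
      length(pos), n_vox
    ))
    keep <- pos
  } else {
    ord <- order(-wpos, pos)           # weight desc, then voxel index asc
    keep <- pos[ord[seq_len(n_vox)]]
  }
  arr <- array(FALSE, dim = dim(template$voxels))
  arr[keep] <- TRUE
  network_mask(template$network, arr, provenance = "personalized",
               source_component = source_component,
               selection_corr = selection_corr)
}

#' Template fallback masks
#'
#' Used when personalized mask generation is not possible (insufficient
#' resting-state data): the template DMN and FPN masks are passed through
#' with provenance `template_fallback`.
#'
#' @param templates named list with `DMN` and `FPN` `npda_mask` entries.
#' @return list with `dmn` and `fpn` masks.
#' @export
fallback_template_masks <- function(templates) {
  stopifnot(all(c("DMN", "FPN") %in% names(templates)))
  mk <- function(m) {
    network_mask(m$network, m$voxels, provenance = "template_fallback")
  }
  list(dmn = mk(templates$DMN), fpn = mk(templates$FPN))
}

#' Personalized DMN/FPN mask generation pipeline
#'
#' End-to-end localizer: preprocess one or two resting runs, concatenate
#' them under the minimum-length rules, extract spatial components, select
#' the components best matching the DMN and FPN templates, and threshold to
#' personalized binary masks. If the resting data are unusable (first run
#' shorter than `min_volumes`), the template masks are returned with
#' provenance `template_fallback`.
#'
#' If one component wins both networks, it is assigned to the network with
#' the larger absolute correlation and the runner-up component serves the
#' other network; the event is recorded in the report.
#'
#' @param run1,run2 resting `npda_run`s (`run2` optional).
#' @param templates named list of template masks (needs `DMN`, `FPN`).
#' @param n_components ICA model order (default 35).
#' @param n_vox personalized mask size (default 2000).
#' @param preproc a [preproc_params()].
#' @param min_volumes minimum usable run length (default 125).
#' @param seed integer RNG seed.
#' @return list with `dmn`, `fpn` (masks), `components` (or NULL on
#'   fallback), and `report` (a tibble with one row per network: component,
#'   correlation, provenance, events).
#' @export
localize_networks <- function(run1, run2 = NULL, templates,
                              n_components = 35L, n_vox = 2000L,
                              preproc = preproc_params(),
                              min_volumes = 125L, seed = 1L) {
  concat <- tryCatch(
    {
      p1 <- preprocess_localizer(run1, preproc)
      p2 <- if (!is.null(run2)) preprocess_localizer(run2, preproc) else NULL
      concatenate_runs(p1, p2, min_volumes = min_volumes)
    },
    npda_localizer_unusable = function(e) NULL
  )
  if (is.null(concat)) {
    fb <- fallback_template_masks(templates)
    report <- tibble::tibble(
      network = c("DMN", "FPN"), component = NA_integer_,
      selection_corr = NA_real_, provenance = "template_fallback",
      event = "insufficient resting data; template fallback"
    )
    return(list(dmn = fb$dmn, fpn = fb$fpn, components = NULL, report = report))
  }

  comps <- extract_components(concat, n_components = n_components, seed = seed)
  sel_dmn <- select_network_component(comps, templates$DMN)
  sel_fpn <- select_network_component(comps, templates$FPN)
  event <- c(DMN = "", FPN = "")
  if (sel_dmn$component == sel_fpn$component) {
    rho_d <- template_correlations(comps, templates$DMN)
    rho_f <- template_correlations(comps, templates$FPN)
    if (abs(sel_dmn$corr) >= abs(sel_fpn$corr)) {
      rho_f[sel_dmn$component] <- 0
      j <- which.max(abs(rho_f))
      sel_fpn <- list(component = j, corr = rho_f[j],
                      sign = if (rho_f[j] < 0) -1 else 1)
      event["FPN"] <- "shared winner reassigned to runner-up"
    } else {
      rho_d[sel_fpn$component] <- 0
      j <- which.max(abs(rho_d))
      sel_dmn <- list(component = j, corr = rho_d[j],
                      sign = if (rho_d[j] < 0) -1 else 1)
      event["DMN"] <- "shared winner reassigned to runner-up"
    }
  }

  mk <- function(sel, template) {
    personalize_mask(
      sel$sign * comps$maps[[sel$component]], template, n_vox = n_vox,
      source_component = sel$component, selection_corr = sel$corr
    )
  }
  dmn <- mk(sel_dmn, templates$DMN)
  fpn <- mk(sel_fpn, templates$FPN)
  report <- tibble::tibble(
    network = c("DMN", "FPN"),
    component = c(sel_dmn$component, sel_fpn$component),
    selection_corr = c(sel_dmn$corr, sel_fpn$corr),
    provenance = "personalized",
    event = unname(event)
  )
  list(dmn = dmn, fpn = fpn, components = comps, report = report)
}
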