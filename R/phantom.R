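#' Specify a synthetic brain phantom
#'
#' A phantom is a 3D voxel grid partitioned into labeled, pairwise-disjoint
#' regions: the two default-mode hubs (mPFC, PCC), the remaining DMN, the
#' frontoparietal network (FPN), white matter (WM), cerebrospinal fluid (CSF),
#' and unlabeled brain. Region sizes default to values that make downstream
#' top-2000-voxel mask thresholding nontrivial (DMN and FPN each > 2000
#' voxels) and keep both hub ROIs comfortably above the 200-voxel floor used
#' by the connectivity stage.
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param region_sizes named integer vector of voxel counts for
#'   `DMN_mPFC`, `DMN_PCC`, `DMN_other`, `FPN`, `WM`, `CSF`. Brain voxels not
#'   claimed by any of these become `other_brain`.
#' @param n_noise_parcels number of independent-signal parcels the
#'   `other_brain` tissue is subdivided into (default 28). Real resting
#'   brains contain dozens of coherent sources; giving the phantom
#'   comparable source richness keeps a 35-component decomposition from
#'   over-factoring the planted networks.
#' @return an object of class `npda_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L),
                         voxel_size_mm = 2,
                         region_sizes = c(
                           DMN_mPFC = 300L, DMN_PCC = 300L,
                           DMN_other = 2000L, FPN = 2600L,
                           WM = 800L, CSF = 400L
                         ),
                         n_noise_parcels = 28L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4), voxel_size_mm > 0)
  need <- c("DMN_mPFC", "DMN_PCC", "DMN_other", "FPN", "WM", "CSF")
  if (!all(need %in% names(region_sizes))) {
    stop_npda(paste("region_sizes must name:", paste(need, collapse = ", ")),
              "npda_spec_error")
  }
  region_sizes <- as.integer(region_sizes[need])
  names(region_sizes) <- need
  if (any(region_sizes < 1)) stop_npda("region sizes must be positive", "npda_spec_error")
  if (region_sizes["DMN_mPFC"] < 200L || region_sizes["DMN_PCC"] < 200L) {
    stop_npda("mPFC and PCC regions must each have >= 200 voxels", "npda_spec_error")
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape),
      voxel_size_mm = voxel_size_mm,
      region_sizes = region_sizes,
      n_noise_parcels = as.integer(n_noise_parcels)
    ),
    class = "npda_phantom_spec"
  )
}

#' Construct a binary network mask
#'
#' @param network mask label, e.g. `"DMN"`, `"FPN"`, `"mPFC"`, `"PCC"`,
#'   `"WM"`, `"CSF"`, `"whole_brain"`.
#' @param voxels logical 3D array marking member voxels.
#' @param provenance `"template"`, `"personalized"`, or `"template_fallback"`.
#' @param source_component ICA component index the mask was derived from, if any.
#' @param selection_corr spatial correlation that selected that component, if any.
#' @return an object of class `npda_mask`.
#' @export
network_mask <- function(network, voxels, provenance = "template",
                         source_component = NULL, selection_corr = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, is.logical(voxels))
  structure(
    list(
      network = network,
      voxels = voxels,
      n_voxels = sum(voxels),
      provenance = provenance,
      source_component = source_component,
      selection_corr = selection_corr
    ),
    class = "npda_mask"
  )
}

#' @export
print.npda_mask <- function(x, ...) {
  cat(sprintf(
    "<npda_mask> %s: %d voxels (%s)\n", x$network, x$n_voxels, x$provenance
  ))
  invisible(x)
}

# Brain support: the grid with a one-voxel margin stripped on every face,
# so erosion and edge handling are observable at toy scale.
brain_support <- function(grid_shape) {
  arr <- array(FALSE, dim = grid_shape)
  arr[2:(grid_shape[1] - 1), 2:(grid_shape[2] - 1), 2:(grid_shape[3] - 1)] <- TRUE
  arr
}

# Grow a quasi-compact region of `size` voxels over `available` (logical 3D)
# by breadth-first expansion from a random seed voxel.
grow_region <- function(available, size, dim3) {
  open <- which(available)
  if (length(open) < size) {
    stop_npda("requested region sizes exceed grid capacity", "npda_sizing_error")
  }
  start <- open[sample.int(length(open), 1L)]
  ncap <- prod(dim3)
  claimed <- integer(size)
  n_claimed <- 0L
  in_queue <- logical(ncap)
  queue <- integer(ncap)
  q_head <- 1L
  q_tail <- 1L
  queue[1L] <- start
  in_queue[start] <- TRUE
  avail <- available
  nx <- dim3[1]
  nxy <- dim3[1] * dim3[2]
  # precomputed 6-neighbour offsets in linear-index space; axis wraparound
  # is prevented by coordinate checks below
  while (n_claimed < size) {
    if (q_head > q_tail) {
      # region became landlocked; jump to a random free voxel
      rest <- which(avail)
      if (length(rest) == 0L) {
        stop_npda("requested region sizes exceed grid capacity", "npda_sizing_error")
      }
      q_tail <- q_tail + 1L
      queue[q_tail] <- rest[sample.int(length(rest), 1L)]
      in_queue[queue[q_tail]] <- TRUE
    }
    v <- queue[q_head]
    q_head <- q_head + 1L
    if (!avail[v]) next
    n_claimed <- n_claimed + 1L
    claimed[n_claimed] <- v
    avail[v] <- FALSE
    v0 <- v - 1L
    i <- v0 %% nx
    j <- (v0 %/% nx) %% dim3[2]
    k <- v0 %/% nxy
    nidx <- c(
      if (i > 0L) v - 1L,
      if (i < nx - 1L) v + 1L,
      if (j > 0L) v - nx,
      if (j < dim3[2] - 1L) v + nx,
      if (k > 0L) v - nxy,
      if (k < dim3[3] - 1L) v + nxy
    )
    nidx <- nidx[avail[nidx] & !in_queue[nidx]]
    nn <- length(nidx)
    if (nn) {
      in_queue[nidx] <- TRUE
      if (nn > 1L) nidx <- nidx[sample.int(nn)]
      queue[(q_tail + 1L):(q_tail + nn)] <- nidx
      q_tail <- q_tail + nn
    }
  }
  list(voxels = claimed, available = avail)
}

#' Realize a phantom: place regions and build template masks
#'
#' Regions are grown as quasi-compact blobs inside the brain support, in a
#' fixed order, by seeded breadth-first expansion; the same `(spec, seed)`
#' pair always yields the same phantom. Template masks for DMN
#' (mPFC + PCC + other DMN), FPN, mPFC, PCC, WM, CSF, and whole brain are
#' attached.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return an `npda_phantom`: the spec plus `regions` (named list of linear
#'   voxel indices) and `masks` (named list of [network_mask()] objects).
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "npda_phantom_spec"))
  dim3 <- spec$grid_shape
  brain <- brain_support(dim3)
  if (sum(brain) < sum(spec$region_sizes)) {
    stop_npda("requested region sizes exceed grid capacity", "npda_sizing_error")
  }
  placed <- with_seed(seed, {
    avail <- brain
    out <- list()
    for (rn in names(spec$region_sizes)) {
      g <- grow_region(avail, spec$region_sizes[[rn]], dim3)
      out[[rn]] <- sort(g$voxels)
      avail <- g$available
    }
    out$other_brain <- which(avail)
    # subdivide other_brain into independent-signal parcels
    np <- max(1L, spec$n_noise_parcels %||% 1L)
    parcels <- list()
    n_other <- length(out$other_brain)
    if (n_other > 0 && np > 1) {
      base_size <- n_other %/% np
      for (i in seq_len(np - 1)) {
        if (sum(avail) < base_size) break
        g <- grow_region(avail, base_size, dim3)
        parcels[[i]] <- sort(g$voxels)
        avail <- g$available
      }
      parcels[[length(parcels) + 1]] <- which(avail)
    } else {
      parcels[[1]] <- out$other_brain
    }
    list(regions = out, parcels = parcels)
  })
  regions <- placed$regions

  as_mask <- function(name, idx) {
    arr <- array(FALSE, dim = dim3)
    arr[idx] <- TRUE
    network_mask(name, arr, provenance = "template")
  }
  dmn_idx <- sort(c(regions$DMN_mPFC, regions$DMN_PCC, regions$DMN_other))
  masks <- list(
    DMN = as_mask("DMN", dmn_idx),
    FPN = as_mask("FPN", regions$FPN),
    mPFC = as_mask("mPFC", regions$DMN_mPFC),
    PCC = as_mask("PCC", regions$DMN_PCC),
    WM = as_mask("WM", regions$WM),
    CSF = as_mask("CSF", regions$CSF),
    whole_brain = network_mask("whole_brain", brain, provenance = "template")
  )
  structure(
    c(spec, list(regions = regions, parcels = placed$parcels,
                 masks = masks, seed = as.integer(seed))),
    class = c("npda_phantom", "npda_phantom_spec")
  )
}

#' @export
print.npda_phantom <- function(x, ...) {
  cat("<npda_phantom>", paste(x$grid_shape, collapse = "x"),
      "grid,", x$voxel_size_mm, "mm voxels\n")
  sizes <- vapply(x$regions, length, integer(1))
  cat("  regions:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}
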