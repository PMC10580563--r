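# Shared fixtures, computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Full-size phantom (24^3, default region sizes)
default_phantom <- function() fixture("phantom", make_phantom(phantom_spec(), seed = 2))

# Two localizer resting runs with planted networks on the default phantom
localizer_runs <- function() {
  fixture("loc_runs", {
    ph <- default_phantom()
    list(
      r1 = simulate_run(ph, acquisition_params(n_volumes = 250),
                        signal_spec(seed = 3)),
      r2 = simulate_run(ph, acquisition_params(n_volumes = 240),
                        signal_spec(seed = 4))
    )
  })
}

# Personalized-mask pipeline output on the default phantom (also used by
# the acceptance suite)
localizer_result <- function() {
  fixture("loc_result", {
    ph <- default_phantom()
    runs <- localizer_runs()
    localize_networks(runs$r1, runs$r2, ph$masks, seed = 7)
  })
}

# Tiny 6^3 mask trio for engine unit tests: whole-brain TRUE everywhere,
# DMN and FPN interior slabs (untouched by one-voxel erosion)
tiny_masks <- function() {
  d3 <- c(6L, 6L, 6L)
  dmn <- array(FALSE, d3)
  fpn <- array(FALSE, d3)
  dmn[2:3, 2:5, 2:5] <- TRUE
  fpn[4:5, 2:5, 2:5] <- TRUE
  list(
    dmn = network_mask("DMN", dmn),
    fpn = network_mask("FPN", fpn),
    wb = network_mask("whole_brain", array(TRUE, d3)),
    dim = d3
  )
}

# Random-walk motion trace as a plain matrix (volumes x 6)
random_motion <- function(nt, seed = 1, step = 0.05) {
  set.seed(seed)
  matrix(cumsum(stats::rnorm(nt * 6, 0, step)), nt, 6)
}

# Stream a raw (time x voxel) matrix through the engine, returning the
# final state and all samples
ingest_matrix <- function(engine, Y, motion, d3) {
  samples <- list()
  for (t in seq_len(nrow(Y))) {
    out <- ingest(engine, list(volume = t, data = array(Y[t, ], d3),
                               motion = motion[t, ]))
    engine <- out$state
    if (!is.null(out$sample)) samples[[length(samples) + 1]] <- out$sample
  }
  list(state = engine, samples = dplyr::bind_rows(samples))
}
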