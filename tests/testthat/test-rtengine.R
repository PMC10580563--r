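# Incremental per-voxel GLM engine.

test_that("whole-brain erosion removes edge voxels and spares the interior", {
  tm <- tiny_masks()
  eng <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = 60L)
  # 6^3 all-TRUE brain erodes to the 4^3 interior; both slabs lie inside it
  expect_equal(length(eng$vox_idx), 64L)
  expect_equal(length(eng$dmn_cols), 32L)

  edge <- array(FALSE, tm$dim)
  edge[1, , ] <- TRUE                       # mask entirely on the brain edge
  edge_mask <- network_mask("DMN", edge)
  expect_error(init_engine(edge_mask, tm$fpn, tm$wb, n_volumes = 60L),
               class = "npda_config_error")

  expect_equal(eng$baseline_volumes, 25L)
})

test_that("incremental residuals equal batch OLS at every timepoint", {
  tm <- tiny_masks()
  nt <- 60L
  motion <- random_motion(nt, seed = 1)
  set.seed(2)
  Y <- matrix(rnorm(nt * prod(tm$dim)), nt)
  eng <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  X <- matrix(0, 0, 8)
  maxerr <- 0
  for (t in seq_len(nt)) {
    out <- ingest(eng, list(volume = t, data = array(Y[t, ], tm$dim),
                            motion = motion[t, ]))
    eng <- out$state
    x <- neuropda:::design_row(t, motion[t, ],
                               if (t > 1) motion[t - 1, ] else NULL, nt)
    X <- rbind(X, x)
    if (t >= 8) {
      batch <- lm.fit(X, Y[seq_len(t), eng$vox_idx])$residuals
      beta <- neuropda:::gentleman_coef(eng$D, eng$Rbar, eng$theta)
      r_inc <- Y[t, eng$vox_idx] - drop(x %*% beta)
      maxerr <- max(maxerr, max(abs(r_inc - batch[t, ])))
    }
  }
  expect_lt(maxerr, 1e-8)
})

test_that("signal spanned by the nuisance design yields zero activation", {
  tm <- tiny_masks()
  nt <- 60L
  motion <- random_motion(nt, seed = 3)
  drift <- ((seq_len(nt)) - (nt + 1) / 2) / nt
  rel <- rbind(rep(0, 6), diff(motion))
  set.seed(4)
  sig <- 5 + 2 * drift + drop(rel %*% runif(6, -1, 1))
  eng <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  res <- ingest_matrix(eng, matrix(sig, nt, prod(tm$dim)), motion, tm$dim)
  expect_lt(max(abs(res$samples$z_dmn)), 1e-6)
  expect_lt(max(abs(res$samples$z_fpn)), 1e-6)
})

test_that("a step injection in FPN voxels appears as the expected z and positive PDA", {
  tm <- tiny_masks()
  nt <- 50L
  motion <- matrix(0, nt, 6)
  set.seed(5)
  noise_sd <- 0.3
  Y <- matrix(rnorm(nt * prod(tm$dim), 0, noise_sd), nt)

  eng0 <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  base <- ingest_matrix(eng0, Y, motion, tm$dim)

  # +3 baseline-SD step on all FPN voxels at t = 40
  fpn_idx <- base$state$vox_idx[base$state$fpn_cols]
  Y2 <- Y
  Y2[40, fpn_idx] <- Y2[40, fpn_idx] + 3 * base$state$sigma[base$state$fpn_cols]
  eng <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt, outlier_sd = 10)
  res <- ingest_matrix(eng, Y2, motion, tm$dim)
  s40 <- res$samples[res$samples$volume == 40, ]
  expect_equal(s40$z_fpn, 3, tolerance = 0.35)   # noise floor + refit shrinkage
  expect_gt(s40$pda, 1.5)
})

test_that("efficiency weighting is inverse-variance weighting, normalized", {
  # two voxels, baseline variances 1 and 4 -> weights 0.8 / 0.2
  w <- c(1 / 1, 1 / 4)
  w <- w / sum(w)
  expect_equal(w, c(0.8, 0.2))
  expect_equal(network_activation(c(1, 1), w), 1)
  expect_equal(network_activation(c(0, 0), w), 0)
  # uniform variances -> unweighted mean
  wu <- rep(1 / 4, 4)
  z <- c(0.5, 1, -2, 3)
  expect_equal(network_activation(z, wu), mean(z))
  expect_error(network_activation(numeric(0), numeric(0)),
               class = "npda_activation_error")

  # engine reproduces the hand computation through its baseline freeze
  tm <- tiny_masks()
  nt <- 30L
  motion <- matrix(0, nt, 6)
  set.seed(6)
  Y <- matrix(rnorm(nt * prod(tm$dim)), nt)
  eng <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  res <- ingest_matrix(eng, Y, motion, tm$dim)
  st <- res$state
  expect_equal(sum(st$w_dmn), 1, tolerance = 1e-12)
  expect_equal(sum(st$w_fpn), 1, tolerance = 1e-12)
  manual <- (1 / st$sigma[st$dmn_cols]^2) / sum(1 / st$sigma[st$dmn_cols]^2)
  expect_equal(st$w_dmn, manual, tolerance = 1e-12)
})

test_that("activation is invariant to a constant intensity offset", {
  tm <- tiny_masks()
  nt <- 40L
  motion <- random_motion(nt, seed = 7)
  set.seed(8)
  Y <- matrix(rnorm(nt * prod(tm$dim)), nt)
  eng1 <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  r1 <- ingest_matrix(eng1, Y, motion, tm$dim)
  eng2 <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  r2 <- ingest_matrix(eng2, Y + 500, motion, tm$dim)
  expect_equal(r1$samples$z_dmn, r2$samples$z_dmn, tolerance = 1e-7)
  expect_equal(r1$samples$z_fpn, r2$samples$z_fpn, tolerance = 1e-7)
})

test_that("out-of-order volumes are rejected and outliers flagged", {
  tm <- tiny_masks()
  eng <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = 30L)
  item1 <- list(volume = 1L, data = array(rnorm(prod(tm$dim)), tm$dim),
                motion = rep(0, 6))
  eng <- ingest(eng, item1)$state
  bad <- list(volume = 5L, data = item1$data, motion = rep(0, 6))
  expect_error(ingest(eng, bad), class = "npda_sequence_error")

  # |z| > 2 flags the sample as an outlier
  nt <- 40L
  set.seed(9)
  Y <- matrix(rnorm(nt * prod(tm$dim)), nt)
  Y[30, ] <- Y[30, ] + 10
  eng2 <- init_engine(tm$dmn, tm$fpn, tm$wb, n_volumes = nt)
  res <- ingest_matrix(eng2, Y, matrix(0, nt, 6), tm$dim)
  expect_true(res$samples$outlier[res$samples$volume == 30])
})

test_that("per-volume ingest on the full-size grid beats the TR budget", {
  ph <- default_phantom()
  res <- localizer_result()
  eng <- init_engine(res$dmn, res$fpn, ph$masks$whole_brain, n_volumes = 150L)
  run <- simulate_run(ph, acquisition_params(n_volumes = 30),
                      signal_spec(seed = 17))
  items <- stream_volumes(run)
  for (t in 1:29) eng <- ingest(eng, items[[t]])$state
  elapsed <- system.time(ingest(eng, items[[30]]))[3]
  expect_lt(elapsed, 1.2)   # well under TR = 1.2 s
})
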