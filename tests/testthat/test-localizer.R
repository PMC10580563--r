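# Personalized network localization: preprocessing, concatenation, spatial
# ICA, component selection and mask thresholding.

test_that("high-pass removes slow components much more than passband ones", {
  ph <- cohort_phantom(seed = 1)
  nt <- 1250L   # both probe frequencies fall exactly on FFT bins
  tr <- 1.2
  t_s <- (seq_len(nt) - 1) * tr
  slow <- sin(2 * pi * 0.002 * t_s)
  fast <- sin(2 * pi * 0.05 * t_s)
  sig <- signal_spec(dmn_amplitude = 0, fpn_amplitude = 0, tissue_amplitude = 0,
                     drift_slope = 0, noise_sd = 0, motion_coupling = 0,
                     brain_intensity = 100, seed = 1)
  run <- simulate_run(ph, acquisition_params(n_volumes = nt), sig)
  v_slow <- ph$regions$DMN_mPFC[1]
  v_fast <- ph$regions$DMN_PCC[1]
  m <- t(matrix(run$data, prod(ph$grid_shape), nt))
  m[, v_slow] <- m[, v_slow] + slow
  m[, v_fast] <- m[, v_fast] + fast
  run$data <- array(t(m), dim = c(ph$grid_shape, nt))

  pp <- preprocess_localizer(run, preproc_params(smoothing_fwhm_mm = 0))
  mp <- t(matrix(pp$data, prod(ph$grid_shape), nt))
  att_slow <- sd(mp[, v_slow]) / sd(slow)
  att_fast <- sd(mp[, v_fast]) / sd(fast)
  expect_lt(att_slow * 10, att_fast)     # >= 10x stronger attenuation below cutoff
  # every brain voxel is (close to) mean-zero after DC removal
  bidx <- which(pp$brain_mask$voxels)
  expect_lt(max(abs(colMeans(mp[, bidx]))), 1e-8)
})

test_that("spatial smoothing conserves total mass and spreads an impulse", {
  arr <- array(0, c(9, 9, 9, 1))
  arr[5, 5, 5, 1] <- 10
  sm <- neuropda:::smooth_4d(arr, sigma_vox = 5 / 2.355 / 2)
  expect_equal(sum(sm), 10, tolerance = 1e-10)
  expect_lt(max(sm), 10)
  expect_gt(sm[4, 5, 5, 1], 0)
})

test_that("run concatenation follows the trim and minimum-length rules", {
  runs <- localizer_runs()
  p1 <- preprocess_localizer(runs$r1)
  p2 <- preprocess_localizer(runs$r2)

  cc <- concatenate_runs(p1, p2)
  expect_equal(cc$params$n_volumes, 480L)   # 250 + 240 -> 240 + 240

  short <- p2
  m2 <- neuropda:::run_matrix(p2)
  short <- neuropda:::run_from_matrix(short, m2[1:120, , drop = FALSE])
  cc1 <- concatenate_runs(p1, short)
  expect_equal(cc1$params$n_volumes, 250L)  # 120 < 125: second run dropped

  solo <- concatenate_runs(p1, NULL)
  m1 <- neuropda:::run_matrix(p1)
  expect_equal(neuropda:::run_matrix(solo),
               sweep(m1, 2, colMeans(m1), `-`), tolerance = 1e-10)

  short1 <- neuropda:::run_from_matrix(p1, m1[1:100, , drop = FALSE])
  expect_error(concatenate_runs(short1, p2), class = "npda_localizer_unusable")
})

test_that("spatial ICA extracts the requested number of deterministic components", {
  runs <- localizer_runs()
  cc <- concatenate_runs(preprocess_localizer(runs$r1))
  comps <- extract_components(cc, n_components = 35L, seed = 7)
  expect_equal(comps$n_components, 35L)
  expect_length(comps$maps, 35)
  expect_equal(dim(comps$mixing), c(250L, 35L))

  comps2 <- extract_components(cc, n_components = 35L, seed = 7)
  expect_identical(comps$maps, comps2$maps)

  expect_error(extract_components(cc, n_components = 300L, seed = 1),
               class = "npda_ica_error")
})

test_that("a planted network is recovered as a single component at low model order", {
  ph <- cohort_phantom(seed = 1)
  sig <- signal_spec(dmn_amplitude = 0, fpn_amplitude = 2, tissue_amplitude = 0,
                     network_corr = 0, motion_coupling = 0, seed = 31)
  run <- simulate_run(ph, acquisition_params(n_volumes = 200), sig)
  pp <- preprocess_localizer(run)
  comps <- extract_components(concatenate_runs(pp, min_volumes = 100L),
                              n_components = 5L, seed = 9)
  rho <- template_correlations(comps, ph$masks$FPN)
  expect_gte(max(abs(rho)), 0.8)
})

test_that("component selection maximizes |spatial correlation| and handles sign", {
  ph <- default_phantom()
  template <- ph$masks$DMN
  # hand-built component set: noise maps plus the template itself / negated
  set.seed(11)
  mk_map <- function(v) array(v, dim = ph$grid_shape)
  support <- which(neuropda:::brain_support(ph$grid_shape))
  noise_map <- function() {
    full <- numeric(prod(ph$grid_shape))
    full[support] <- rnorm(length(support))
    mk_map(full)
  }
  tmpl_map <- mk_map(as.numeric(template$voxels))
  comps <- structure(
    list(maps = list(noise_map(), tmpl_map, noise_map()),
         mixing = NULL, n_components = 3L, support = support,
         grid_shape = ph$grid_shape, converged = TRUE, iterations = 1L, seed = 1L),
    class = "npda_components"
  )
  sel <- select_network_component(comps, template)
  expect_equal(sel$component, 2L)
  expect_equal(sel$corr, 1.0, tolerance = 1e-12)
  expect_equal(sel$sign, 1)

  comps$maps[[2]] <- mk_map(-as.numeric(template$voxels))
  sel2 <- select_network_component(comps, template)
  expect_equal(sel2$component, 2L)
  expect_equal(abs(sel2$corr), 1.0, tolerance = 1e-12)
  expect_equal(sel2$sign, -1)

  # brute-force oracle over a noisy component set with one planted map
  planted <- noise_map()
  planted[which(template$voxels)] <- planted[which(template$voxels)] + 2
  comps$maps <- list(noise_map(), noise_map(), planted, noise_map())
  comps$n_components <- 4L
  oracle <- which.max(vapply(comps$maps, function(mp) {
    abs(cor(mp[support], as.numeric(template$voxels[support])))
  }, numeric(1)))
  expect_equal(select_network_component(comps, template)$component, oracle)
})

test_that("mask personalization keeps the top positive weights inside the template", {
  ph <- default_phantom()
  template <- ph$masks$DMN              # 2600 support voxels
  set.seed(21)
  # a generic sign-corrected component: positive over the network with
  # voxelwise variation (as a selected, sign-flipped ICA map would be)
  comp <- array(abs(rnorm(prod(ph$grid_shape))) + 0.01, dim = ph$grid_shape)

  mask <- personalize_mask(comp, template, n_vox = 2000L)
  expect_equal(mask$n_voxels, 2000L)
  expect_true(all(template$voxels[mask$voxels]))
  expect_equal(mask$provenance, "personalized")
  # kept voxels are exactly the 2000 largest positive weights (sort oracle)
  support <- which(template$voxels)
  w <- comp[support]
  oracle <- sort(support[w > 0][order(-w[w > 0])][1:2000])
  expect_equal(sort(which(mask$voxels)), oracle)

  # capacity: small support keeps everything positive, with a warning
  small <- ph$masks$mPFC                # 300 support voxels
  expect_warning(msk2 <- personalize_mask(comp, small, n_vox = 2000L),
                 "positive-weight")
  expect_lte(msk2$n_voxels, 300L)

  # ties at the threshold break by ascending voxel index, deterministically
  tied <- array(0, dim = ph$grid_shape)
  tied[support] <- 1
  msk3 <- personalize_mask(tied, template, n_vox = 2000L)
  expect_equal(which(msk3$voxels), support[1:2000])
})

test_that("template fallback is returned when resting data are unusable", {
  ph <- default_phantom()
  sig <- signal_spec(seed = 13)
  short <- simulate_run(ph, acquisition_params(n_volumes = 100), sig)
  res <- localize_networks(short, NULL, ph$masks, seed = 3)
  expect_equal(res$dmn$provenance, "template_fallback")
  expect_identical(res$dmn$voxels, ph$masks$DMN$voxels)
  expect_identical(res$fpn$voxels, ph$masks$FPN$voxels)
  expect_true(all(res$report$provenance == "template_fallback"))
})

test_that("the full localizer recovers planted networks within the time budget", {
  ph <- default_phantom()
  elapsed <- system.time(res <- localizer_result())[3]
  # fixture may be cached; re-run once for timing if so
  if (elapsed < 0.1) {
    runs <- localizer_runs()
    elapsed <- system.time(
      localize_networks(runs$r1, runs$r2, ph$masks, seed = 7)
    )[3]
  }
  expect_lt(elapsed, 60)

  res <- localizer_result()
  jaccard <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jaccard(res$dmn$voxels, ph$masks$DMN$voxels), 0.5)
  expect_gte(jaccard(res$fpn$voxels, ph$masks$FPN$voxels), 0.5)
  expect_false(res$report$component[1] == res$report$component[2])
  expect_true(all(!res$dmn$voxels | ph$masks$DMN$voxels))  # subset of template
})
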