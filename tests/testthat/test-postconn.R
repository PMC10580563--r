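# Post-hoc cleaning, connectivity, BH adjustment, imputation, MNAR grid.

test_that("cleaning a quiet run censors nothing and centers the series", {
  ph <- cohort_phantom(seed = 1)
  sig <- signal_spec(dmn_amplitude = 0, fpn_amplitude = 0, tissue_amplitude = 0,
                     drift_slope = 0, noise_sd = 0.01, motion_coupling = 0,
                     seed = 2)
  run <- simulate_run(ph, acquisition_params(n_volumes = 120), sig)
  cl <- clean_run(run, ph$masks$WM, ph$masks$CSF, ph$masks$whole_brain)
  expect_equal(sum(cl$censor), 0)
  m <- neuropda:::run_matrix(cl)
  expect_lt(max(abs(colMeans(m))), 1e-8)
  expect_gte(cl$mean_fd, 0)
})

test_that("a confound living in the WM principal subspace is projected out", {
  ph <- cohort_phantom(seed = 1)
  nt <- 150L
  sig <- signal_spec(seed = 5)
  run <- simulate_run(ph, acquisition_params(n_volumes = nt), sig)
  # plant a strong shared confound in all WM voxels and a gray-matter ROI
  set.seed(6)
  conf <- as.numeric(arima.sim(list(ar = 0.4), nt))
  m <- neuropda:::run_matrix(run)
  m[, ph$regions$WM] <- m[, ph$regions$WM] + 5 * conf
  m[, ph$regions$DMN_mPFC] <- m[, ph$regions$DMN_mPFC] + 2 * conf
  run$data <- array(t(m), dim = c(ph$grid_shape, nt))

  cl <- clean_run(run, ph$masks$WM, ph$masks$CSF, ph$masks$whole_brain)
  mc <- neuropda:::run_matrix(cl)
  roi_tc <- rowMeans(mc[, ph$regions$DMN_mPFC])
  # compare against the same run cleaned without aCompCor's WM confound:
  # residual correlation with the planted confound must be negligible
  conf_band <- neuropda:::butter_bandpass_fft(matrix(conf), 1.2, 0.008, 0.09)
  expect_lt(abs(cor(roi_tc, conf_band)), 0.15)
  raw_cor <- abs(cor(rowMeans(m[, ph$regions$DMN_mPFC]), conf))
  expect_gt(raw_cor, 0.8)   # the confound dominated before cleaning
})

test_that("global signal regression removes a planted global component only when enabled", {
  ph <- cohort_phantom(seed = 1)
  nt <- 150L
  run <- simulate_run(ph, acquisition_params(n_volumes = nt), signal_spec(seed = 7))
  set.seed(8)
  glob <- as.numeric(arima.sim(list(ar = 0.3), nt))
  m <- neuropda:::run_matrix(run)
  gm <- which(ph$masks$whole_brain$voxels & !ph$masks$WM$voxels & !ph$masks$CSF$voxels)
  m[, gm] <- m[, gm] + 3 * glob
  run$data <- array(t(m), dim = c(ph$grid_shape, nt))

  glob_band <- neuropda:::butter_bandpass_fft(matrix(glob), 1.2, 0.008, 0.09)
  roi_cor <- function(cl) {
    abs(cor(rowMeans(neuropda:::run_matrix(cl)[, ph$regions$DMN_PCC]), glob_band))
  }
  cl_nogsr <- clean_run(run, ph$masks$WM, ph$masks$CSF, ph$masks$whole_brain,
                        cleaning_params(gsr = FALSE))
  cl_gsr <- clean_run(run, ph$masks$WM, ph$masks$CSF, ph$masks$whole_brain,
                      cleaning_params(gsr = TRUE))
  expect_gt(roi_cor(cl_nogsr), 0.5)
  expect_lt(roi_cor(cl_gsr), 0.2)
})

test_that("high-motion volumes are censored and excluded from correlation", {
  ph <- cohort_phantom(seed = 1)
  sig <- signal_spec(outlier_volumes = c(40L, 41L), spike_mm = 2, seed = 9)
  run <- simulate_run(ph, acquisition_params(n_volumes = 120), sig)
  cl <- clean_run(run, ph$masks$WM, ph$masks$CSF, ph$masks$whole_brain)
  expect_true(cl$censor[40] || cl$censor[41])
  cc <- roi_connectivity(cl, ph$masks$mPFC, ph$masks$PCC)
  expect_equal(cc$n_volumes_used, 120L - sum(cl$censor))
})

test_that("ROI connectivity handles perfect, null, and undersized-ROI cases", {
  ph <- cohort_phantom(seed = 1)
  nt <- 250L
  run <- simulate_run(ph, acquisition_params(n_volumes = nt),
                      signal_spec(seed = 10, noise_sd = 1, mpfc_pcc_corr = 0.5))
  cl <- clean_run(run, ph$masks$WM, ph$masks$CSF, ph$masks$whole_brain)

  # identical ROI against itself: r = 1, finite fisher z
  cc_self <- roi_connectivity(cl, ph$masks$mPFC, ph$masks$mPFC)
  expect_equal(cc_self$r, 1)
  expect_true(is.finite(cc_self$fisher_z))

  # undersized personalized ROI falls back to its template, flagged
  small_arr <- ph$masks$mPFC$voxels
  small_arr[which(small_arr)[51:200]] <- FALSE   # 50 voxels < 200
  small <- network_mask("mPFC", small_arr, provenance = "personalized")
  cc_sub <- roi_connectivity(cl, small, ph$masks$PCC,
                             template_a = ph$masks$mPFC)
  expect_true(cc_sub$roi_a_substituted)
  cc_full <- roi_connectivity(cl, ph$masks$mPFC, ph$masks$PCC)
  expect_equal(cc_sub$r, cc_full$r)

  # independent white-noise ROIs at n = 250: |r| stays small
  set.seed(11)
  noise_run <- run
  m <- matrix(rnorm(nt * prod(ph$grid_shape)), nt)
  noise_run$data <- array(t(m), dim = c(ph$grid_shape, nt))
  noise_run$censor <- rep(FALSE, nt)
  cc_null <- roi_connectivity(noise_run, ph$masks$mPFC, ph$masks$PCC)
  expect_lt(abs(cc_null$r), 0.2)
})

test_that("fisher transform is monotone, zero-centered and clipped finite", {
  expect_equal(fisher_z(0), 0)
  expect_true(all(diff(fisher_z(seq(-0.9, 0.9, 0.1))) > 0))
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
})

test_that("BH adjustment matches a brute-force step-up oracle within families", {
  bh_oracle <- function(p, alpha) {
    # largest k with p_(k) <= k/m * alpha; reject the k smallest
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    k <- max(c(0L, which(ps <= seq_len(m) / m * alpha)))
    rej <- rep(FALSE, m)
    if (k > 0) rej[ord[seq_len(k)]] <- TRUE
    rej
  }
  p_dep <- c(0.001, 0.02, 0.03, 0.9)      # 4-test depression family
  p_rum <- c(0.04, 0.012, 0.2)            # 3-test rumination family
  res <- bh_adjust(c(p_dep, p_rum),
                   families = rep(c("depression", "rumination"), c(4, 3)))
  expect_equal(res$rejected[1:4], bh_oracle(p_dep, 0.05))
  expect_equal(res$rejected[5:7], bh_oracle(p_rum, 0.05))

  expect_false(any(bh_adjust(rep(1, 4))$rejected))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "npda_contract_error")

  # randomized cross-check against the oracle
  set.seed(13)
  for (i in 1:25) {
    p <- runif(7)
    fam <- sample(rep(c("a", "b"), c(4, 3)))
    got <- bh_adjust(p, fam)$rejected
    want <- logical(7)
    for (f in c("a", "b")) want[fam == f] <- bh_oracle(p[fam == f], 0.05)
    expect_equal(got, want)
  }
})

test_that("BH controls the realized FDR within each family under the null", {
  set.seed(14)
  # all hypotheses null: the per-family FDR is the probability of any
  # rejection in that family, which BH holds at alpha
  fdp <- replicate(1000, {
    res <- bh_adjust(runif(7), rep(c("a", "b"), c(4, 3)))
    c(any(res$rejected[1:4]), any(res$rejected[5:7]))
  })
  expect_lte(mean(fdp[1, ]), 0.065)   # 0.05 nominal + 3 MC SEs
  expect_lte(mean(fdp[2, ]), 0.065)
})

test_that("item-level imputation respects the 10% missingness rule", {
  items13 <- rbind(
    rep(2, 13),
    c(NA, rep(2, 12)),     # 1/13 = 7.7% missing -> impute
    c(NA, NA, rep(2, 11)), # 2/13 = 15.4% -> missing score
    rep(NA, 13)
  )
  scores <- item_impute(items13)
  expect_equal(scores[1], 26)
  expect_equal(scores[2], 26)   # person-mean imputation of a constant row
  expect_true(is.na(scores[3]))
  expect_true(is.na(scores[4]))
})

test_that("MNAR sensitivity reduces to the complete-data fit and mean imputation", {
  rec <- simulate_connectivity_records(n_participants = 30, seed = 15)
  tab0 <- mnar_sensitivity(rec)
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$n_imputed, 0L)
  expect_equal(tab0$estimate, glance(fit_primary_model(rec))$estimate)

  rec_m <- simulate_connectivity_records(n_participants = 30, missing_prop = 0.1,
                                         seed = 15)
  tab <- mnar_sensitivity(rec_m, shifts = c(-2, 0, 2))
  expect_equal(nrow(tab), 3)
  # shift 0 equals direct mean imputation
  rec_mi <- rec_m
  rec_mi$fisher_z[is.na(rec_mi$fisher_z)] <-
    mean(rec_m$fisher_z, na.rm = TRUE)
  direct <- glance(fit_primary_model(rec_mi))$estimate
  expect_equal(tab$estimate[tab$shift == 0], direct, tolerance = 1e-10)

  # missingness concentrated post-intervention: estimates move monotonically
  rec_c <- simulate_connectivity_records(n_participants = 30, seed = 16)
  post_idx <- which(rec_c$time == 1)[1:12]
  rec_c$fisher_z[post_idx] <- NA
  tab_c <- mnar_sensitivity(rec_c, shifts = seq(-2, 2, 1))
  expect_true(all(diff(tab_c$estimate) > 0))  # larger replacements weaken the drop
})
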