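# Repeated-measures ANOVA power via the noncentral F distribution,
# following the G*Power convention for within-subject factors:
# lambda = f^2 * N * m / (1 - rho) * epsilon.

#' Specify a repeated-measures power analysis
#'
#' @param effect_size_f Cohen's f.
#' @param alpha type-I error rate.
#' @param target_power desired power (for [required_n()]).
#' @param n_groups number of between-subject groups (1 for a pure
#'   within-subject design).
#' @param n_measurements number of repeated measurements m.
#' @param rho correlation between repeated measures.
#' @param nonsphericity_epsilon Greenhouse-Geisser epsilon (1 = sphericity).
#' @param design `"within"` (main effect of the repeated factor) or
#'   `"within_between_interaction"` (group x time interaction).
#' @return an `npda_power_spec`.
#' @export
power_spec <- function(effect_size_f = 0.19, alpha = 0.05,
                       target_power = 0.80, n_groups = 1L,
                       n_measurements = 2L, rho = 0.3,
                       nonsphericity_epsilon = 1,
                       design = c("within", "within_between_interaction")) {
  design <- match.arg(design)
  stopifnot(
    effect_size_f > 0, alpha > 0, alpha < 1,
    target_power > 0, target_power < 1,
    n_groups >= 1, n_measurements >= 2,
    rho >= 0, rho < 1,
    nonsphericity_epsilon > 0, nonsphericity_epsilon <= 1
  )
  if (design == "within_between_interaction" && n_groups < 2) {
    stop_npda("interaction design needs at least 2 groups", "npda_contract_error")
  }
  structure(
    list(
      effect_size_f = effect_size_f, alpha = alpha,
      target_power = target_power, n_groups = as.integer(n_groups),
      n_measurements = as.integer(n_measurements), rho = rho,
      nonsphericity_epsilon = nonsphericity_epsilon, design = design
    ),
    class = "npda_power_spec"
  )
}

#' Power of a repeated-measures design at a given total N
#'
#' Noncentrality `lambda = f^2 * N * m / (1 - rho) * epsilon`; numerator df
#' `(m - 1) * epsilon`, multiplied by `(groups - 1)` for the interaction
#' design; denominator df `(N - groups) * (m - 1) * epsilon`. Power is the
#' upper tail of the noncentral F beyond the central critical value.
#'
#' @param n_total total sample size across groups.
#' @param spec a [power_spec()].
#' @return tibble with `n_total`, `lambda`, `df1`, `df2`, `f_crit`, `power`.
#' @export
rm_power <- function(n_total, spec = power_spec()) {
  stopifnot(inherits(spec, "npda_power_spec"))
  if (n_total < spec$n_groups + 1) {
    stop_npda("n_total must exceed the number of groups", "npda_contract_error")
  }
  f2 <- spec$effect_size_f^2
  m <- spec$n_measurements
  eps <- spec$nonsphericity_epsilon
  lambda <- f2 * n_total * m / (1 - spec$rho) * eps
  df1 <- (m - 1) * eps
  if (spec$design == "within_between_interaction") df1 <- df1 * (spec$n_groups - 1)
  df2 <- (n_total - spec$n_groups) * (m - 1) * eps
  f_crit <- stats::qf(1 - spec$alpha, df1, df2)
  pw <- stats::pf(f_crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  tibble::tibble(
    n_total = n_total, lambda = lambda, df1 = df1, df2 = df2,
    f_crit = f_crit, power = pw
  )
}

#' Smallest total N achieving the target power
#'
#' Doubling search for an upper bracket followed by bisection over
#' integers; the returned N satisfies `rm_power(N) >= target` and
#' `rm_power(N - 1) < target`. Per-group size is derived for grouped
#' designs (rounded up to a multiple of the group count).
#'
#' @param spec a [power_spec()].
#' @return tibble: the [rm_power()] row at the solution plus `n_per_group`
#'   and `target_power`.
#' @export
required_n <- function(spec = power_spec()) {
  stopifnot(inherits(spec, "npda_power_spec"))
  if (spec$target_power >= 1) {
    stop_npda("target power must be < 1", "npda_contract_error")
  }
  pw <- function(n) rm_power(n, spec)$power
  lo <- spec$n_groups + 1
  hi <- lo
  while (pw(hi) < spec$target_power) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e7) stop_npda("required N exceeds search bound", "npda_contract_error")
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pw(mid) >= spec$target_power) hi <- mid else lo <- mid
  }
  n <- if (pw(lo) >= spec$target_power) lo else hi
  if (spec$n_groups > 1 && n %% spec$n_groups != 0) {
    n_bal <- n + (spec$n_groups - n %% spec$n_groups)
  } else {
    n_bal <- n
  }
  out <- rm_power(n, spec)
  out$n_per_group <- n_bal / spec$n_groups
  out$target_power <- spec$target_power
  out
}

#' Monte-Carlo cross-check of analytic repeated-measures power
#'
#' Simulates compound-symmetric repeated measures at the design's effect
#' size and tests the within factor with a repeated-measures ANOVA F test,
#' returning the rejection rate. Used as an independent oracle for
#' [rm_power()].
#'
#' @param n_total sample size; @param spec a [power_spec()];
#' @param n_reps simulation replicates; @param seed RNG seed.
#' @return empirical power (scalar).
#' @export
rm_power_mc <- function(n_total, spec = power_spec(), n_reps = 2000,
                        seed = 1L) {
  stopifnot(spec$design == "within", spec$nonsphericity_epsilon == 1)
  m <- spec$n_measurements
  rho <- spec$rho
  # Cohen's f = SD of occasion means / total within-cell SD (= 1 here);
  # occasion means are an rms-1 contrast scaled by f
  mu <- if (m == 2) c(-1, 1) * spec$effect_size_f else {
    v <- seq_len(m) - (m + 1) / 2
    v / sqrt(mean(v^2)) * spec$effect_size_f
  }
  Sigma <- matrix(rho, m, m)
  diag(Sigma) <- 1
  L <- chol(Sigma)
  with_seed(seed, {
    rej <- logical(n_reps)
    fc <- stats::qf(1 - spec$alpha, m - 1, (n_total - 1) * (m - 1))
    for (r in seq_len(n_reps)) {
      y <- matrix(stats::rnorm(n_total * m), n_total, m) %*% L
      y <- sweep(y, 2, mu, `+`)
      subj <- rowMeans(y)
      occ <- colMeans(y)
      grand <- mean(y)
      ss_occ <- n_total * sum((occ - grand)^2)
      res <- y - outer(subj, rep(1, m)) - outer(rep(1, n_total), occ) + grand
      ss_err <- sum(res^2)
      Fstat <- (ss_occ / (m - 1)) / (ss_err / ((n_total - 1) * (m - 1)))
      rej[r] <- Fstat > fc
    }
    mean(rej)
  })
}
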