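# Closed-loop PDA feedback controller.
#
# The per-volume PDA value (FPN minus DMN activation, in baseline-SD units)
# sets the velocity of a ball on a 1-D vertical track between two target
# circles. Hits shrink the hit circle's radius by 10% within a run;
# between runs the gain is recalibrated by the previous run's hit count
# (x1.25 below 3 hits, x0.75 above 5, unchanged in the 3-5 band). Outlier
# volumes (|z| > 2 SD on either network) pause the ball.

#' Initialize feedback controller state
#'
#' Geometry convention: `ball_y = 0` is the screen center, +1 and -1 are the
#' initial centers of the top and bottom circles. Radii start at 1.0. Two
#' interpretations of the within-run radius shrink are available:
#' `radius_mode = "boundary"` (default) makes the shrink consequential --
#' the hit threshold moves to `2 - radius`, so each hit pushes the target
#' center farther away and the ball may travel beyond 1; `"cosmetic"` keeps
#' the hit threshold fixed at 1 and treats the radius as display-only.
#'
#' @param gain screen units per volume per PDA unit (default 0.05: a
#'   sustained |PDA| of 1 reaches a circle in 20 volumes).
#' @param radius_top,radius_bottom initial circle radii (fractions, 1.0 =
#'   hit boundary at the initial circle center).
#' @param radius_mode `"boundary"` or `"cosmetic"` (see above).
#' @param shrink multiplicative radius shrink per hit (default 0.9).
#' @return an `npda_feedback` state object.
#' @export
feedback_state <- function(gain = 0.05, radius_top = 1, radius_bottom = 1,
                           radius_mode = c("boundary", "cosmetic"),
                           shrink = 0.9) {
  radius_mode <- match.arg(radius_mode)
  stopifnot(gain > 0, radius_top > 0, radius_top <= 1,
            radius_bottom > 0, radius_bottom <= 1, shrink > 0, shrink < 1)
  structure(
    list(
      ball_y = 0, radius_top = radius_top, radius_bottom = radius_bottom,
      gain = gain, hits_this_run = 0L, paused = FALSE,
      radius_mode = radius_mode, shrink = shrink, flash = FALSE
    ),
    class = "npda_feedback"
  )
}

hit_threshold <- function(state, side) {
  r <- if (side == "top") state$radius_top else state$radius_bottom
  if (state$radius_mode == "boundary") 2 - r else 1
}

#' Advance the controller by one feedback volume
#'
#' Outlier samples pause the ball (position unchanged). Otherwise the ball
#' moves by `gain * pda`, clipped at the current hit thresholds. Reaching the
#' top (bottom) threshold is a hit: the hit circle's radius shrinks by 10%,
#' the circle flashes for one volume, and the ball resets to center. A flash
#' volume consumes the step without movement.
#'
#' @param state an `npda_feedback`.
#' @param sample one activation sample (list/row with `pda` and `outlier`).
#' @return list with `state` and `events` (character vector, possibly empty,
#'   from `"hit_top"`, `"hit_bottom"`, `"paused"`, `"flash"`).
#' @export
feedback_step <- function(state, sample) {
  stopifnot(inherits(state, "npda_feedback"))
  events <- character(0)
  if (isTRUE(state$flash)) {
    state$flash <- FALSE
    return(list(state = state, events = "flash"))
  }
  if (isTRUE(sample$outlier)) {
    state$paused <- TRUE
    return(list(state = state, events = "paused"))
  }
  state$paused <- FALSE
  thr_top <- hit_threshold(state, "top")
  thr_bot <- hit_threshold(state, "bottom")
  y <- state$ball_y + state$gain * sample$pda
  y <- min(max(y, -thr_bot), thr_top)
  if (y >= thr_top) {
    state$radius_top <- state$radius_top * state$shrink
    state$ball_y <- 0
    state$hits_this_run <- state$hits_this_run + 1L
    state$flash <- TRUE
    events <- "hit_top"
  } else if (y <= -thr_bot) {
    state$radius_bottom <- state$radius_bottom * state$shrink
    state$ball_y <- 0
    state$hits_this_run <- state$hits_this_run + 1L
    state$flash <- TRUE
    events <- "hit_bottom"
  } else {
    state$ball_y <- y
  }
  list(state = state, events = events)
}

#' Between-run gain recalibration
#'
#' @param gain current gain (> 0).
#' @param hits_previous_run hit count of the completed run.
#' @return new gain: x1.25 if fewer than 3 hits, x0.75 if more than 5,
#'   unchanged for 3-5 hits.
#' @export
recalibrate_between_runs <- function(gain, hits_previous_run) {
  stopifnot(gain > 0)
  if (hits_previous_run < 0) {
    stop_npda("hit count cannot be negative", "npda_contract_error")
  }
  if (hits_previous_run < 3) gain * 1.25
  else if (hits_previous_run > 5) gain * 0.75
  else gain
}

#' Build the run schedule for a dose condition
#'
#' @param dose `"min15"` or `"min30"`.
#' @param rest_volumes,feedback_volumes run lengths (defaults 250 and 150).
#' @return tibble with columns `run`, `kind` (`rest`, `no_neurofeedback`,
#'   `neurofeedback`), `n_volumes`, `phase` (`pre`, `nf`, `post`).
#' @export
build_schedule <- function(dose = c("min15", "min30"),
                           rest_volumes = 250L, feedback_volumes = 150L) {
  dose <- match.arg(dose)
  kinds <- if (dose == "min15") {
    c("rest", "rest", "no_neurofeedback", rep("neurofeedback", 5),
      "no_neurofeedback", "rest", "rest")
  } else {
    c("rest", "rest", "no_neurofeedback", rep("neurofeedback", 5),
      "no_neurofeedback", rep("neurofeedback", 5), "no_neurofeedback",
      "rest", "rest")
  }
  n <- ifelse(kinds == "rest", rest_volumes, feedback_volumes)
  pre <- cumsum(kinds == "rest") <= 2 & kinds == "rest"
  phase <- ifelse(pre, "pre", ifelse(kinds == "rest", "post", "nf"))
  tibble::tibble(
    run = seq_along(kinds), kind = kinds,
    n_volumes = as.integer(n), phase = phase
  )
}

#' Simulate one feedback-type run through engine and controller
#'
#' @param run an `npda_run` (feedback or no-neurofeedback).
#' @param dmn,fpn,whole_brain masks for the engine.
#' @param fb an `npda_feedback` controller state (carried across runs).
#' @param active if `FALSE` (no-neurofeedback run) the engine still runs and
#'   logs, but the controller is inert: the ball stays at center.
#' @param reset_radii reset circle radii to their initial values at run
#'   start (default TRUE; per-run difficulty adaptation).
#' @param baseline_volumes,outlier_sd engine settings.
#' @return list with `log` (per-volume tibble: volume, pda, z_dmn, z_fpn,
#'   ball_y, paused, hit, flash), `hits`, `fb` (controller state after the
#'   run), `engine` (final engine state).
#' @export
simulate_feedback_run <- function(run, dmn, fpn, whole_brain, fb,
                                  active = TRUE, reset_radii = TRUE,
                                  baseline_volumes = 25L, outlier_sd = 2) {
  if (reset_radii) {
    fb$radius_top <- 1
    fb$radius_bottom <- 1
  }
  fb$hits_this_run <- 0L
  fb$ball_y <- 0
  fb$flash <- FALSE
  engine <- init_engine(dmn, fpn, whole_brain,
                        baseline_volumes = baseline_volumes,
                        n_volumes = run$params$n_volumes,
                        outlier_sd = outlier_sd)
  items <- stream_volumes(run)
  rows <- vector("list", length(items))
  for (it in items) {
    out <- ingest(engine, it)
    engine <- out$state
    if (is.null(out$sample)) next
    s <- out$sample
    if (active) {
      st <- feedback_step(fb, s)
      fb <- st$state
      hit <- any(st$events %in% c("hit_top", "hit_bottom"))
      flash <- "flash" %in% st$events
    } else {
      hit <- FALSE
      flash <- FALSE
      fb$paused <- FALSE
    }
    rows[[it$volume]] <- tibble::tibble(
      volume = s$volume, pda = s$pda, z_dmn = s$z_dmn, z_fpn = s$z_fpn,
      ball_y = fb$ball_y, paused = fb$paused, hit = hit, flash = flash
    )
  }
  list(log = dplyr::bind_rows(rows), hits = fb$hits_this_run, fb = fb,
       engine = engine)
}

#' Simulate a full neurofeedback session
#'
#' Orchestrates the whole MRI visit computationally: two localizer resting
#' runs feed the personalized-mask pipeline (template fallback if they are
#' unusable), then the dose schedule is executed run by run -- pre rest
#' runs, no-neurofeedback and neurofeedback runs through the incremental
#' engine and controller with between-run gain recalibration, post rest
#' runs. Rest runs are retained for connectivity analysis.
#'
#' @param phantom a realized phantom.
#' @param dose `"min15"` or `"min30"`.
#' @param sig a [signal_spec()] describing the resting-state world;
#'   neurofeedback runs inherit it with `feedback_effect` applied.
#' @param feedback_effect mean regulation effect during neurofeedback runs
#'   (noise-SD units; drives positive PDA).
#' @param gain initial controller gain.
#' @param localizer_volumes length of each localizer resting run.
#' @param seed integer master seed; all per-run seeds derive from it.
#' @param n_components,n_vox localizer settings.
#' @return an `npda_session` list: `dose`, `schedule`, `masks`, `localizer`
#'   report, per-run `logs`, `runs` (tibble of per-run hit counts and
#'   gains), `rest_runs` (list of retained rest `npda_run`s with phase
#'   labels), `gain_trajectory`.
#' @export
run_session <- function(phantom, dose = c("min15", "min30"),
                        sig = signal_spec(), feedback_effect = 0.5,
                        gain = 0.05, localizer_volumes = 250L,
                        seed = 1L, n_components = 35L, n_vox = 2000L) {
  dose <- match.arg(dose)
  mk_sig <- function(stream, fx = 0) {
    s <- sig
    s$seed <- derive_seed(seed, stream)
    s$feedback_effect <- fx
    s
  }
  acq_loc <- acquisition_params(n_volumes = localizer_volumes)
  loc1 <- simulate_run(phantom, acq_loc, mk_sig("loc1"))
  loc2 <- simulate_run(phantom, acq_loc, mk_sig("loc2"))
  loc <- localize_networks(
    loc1, loc2,
    templates = phantom$masks,
    n_components = n_components, n_vox = n_vox,
    seed = derive_seed(seed, "ica")
  )

  schedule <- build_schedule(dose)
  fb <- feedback_state(gain = gain)
  logs <- list()
  rest_runs <- list()
  run_rows <- list()
  gains <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    kind <- schedule$kind[i]
    acq <- acquisition_params(n_volumes = schedule$n_volumes[i])
    if (kind == "rest") {
      r <- simulate_run(phantom, acq, mk_sig(paste0("rest", i)))
      rest_runs[[length(rest_runs) + 1]] <- list(
        run = r, phase = schedule$phase[i], index = i
      )
      run_rows[[i]] <- tibble::tibble(
        run = i, kind = kind, hits = NA_integer_, gain = NA_real_
      )
      next
    }
    active <- kind == "neurofeedback"
    fx <- if (active) feedback_effect else 0
    r <- simulate_run(phantom, acq, mk_sig(paste0("fb", i), fx))
    res <- simulate_feedback_run(
      r, loc$dmn, loc$fpn, phantom$masks$whole_brain, fb, active = active
    )
    logs[[as.character(i)]] <- res$log
    fb <- res$fb
    run_rows[[i]] <- tibble::tibble(
      run = i, kind = kind, hits = as.integer(res$hits), gain = fb$gain
    )
    if (active) {
      gains <- c(gains, fb$gain)
      fb$gain <- recalibrate_between_runs(fb$gain, res$hits)
    }
  }
  structure(
    list(
      dose = dose, schedule = schedule,
      masks = list(dmn = loc$dmn, fpn = loc$fpn),
      localizer = loc$report,
      logs = logs,
      runs = dplyr::bind_rows(run_rows),
      rest_runs = rest_runs,
      gain_trajectory = gains,
      seed = as.integer(seed)
    ),
    class = "npda_session"
  )
}

#' @export
print.npda_session <- function(x, ...) {
  nf <- sum(x$schedule$kind == "neurofeedback")
  cat(sprintf("<npda_session> dose %s: %d runs (%d neurofeedback)\n",
              x$dose, nrow(x$schedule), nf))
  hits <- x$runs$hits[x$runs$kind == "neurofeedback"]
  cat("  hits per NF run:", paste(hits, collapse = " "), "\n")
  invisible(x)
}

#' Write a session log directory
#'
#' Per-run TSVs (volume, pda, z_dmn, z_fpn, ball_y, paused, hit, flash) and
#' a session-level JSON with dose, run order, gains and hit counts.
#'
#' @param session an `npda_session`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_session_log <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(session$logs)) {
    utils::write.table(
      session$logs[[nm]], file.path(dir, sprintf("run%s.tsv", nm)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  meta <- list(
    dose = session$dose,
    schedule = as.list(session$schedule),
    runs = as.list(session$runs),
    gain_trajectory = session$gain_trajectory,
    localizer = as.list(session$localizer),
    seed = session$seed
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
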