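# Arrhythmia induction protocols (burst pacing at the LAA/roof analogues,
# four-spiral initial condition), episode tracking and binary endpoints.

#' Burst-pacing stimulus schedule
#'
#' S1 train of 5 stimuli at CL 700 ms at the coronary-sinus analogue, a 400 ms
#' delay measured from the last S1, then 5 ectopic stimuli at CL 160 ms.
#'
#' @param s1_cl S1 cycle length, ms
#' @param n_s1 number of S1 stimuli
#' @param delay pause after the last S1, ms
#' @param burst_cl ectopic burst cycle length, ms
#' @param n_burst number of burst stimuli
#' @return data.frame with columns `onset` (ms) and `phase` ("S1"/"burst")
#' @export
burst_schedule <- function(s1_cl = 700, n_s1 = 5, delay = 400,
                           burst_cl = 160, n_burst = 5) {
  s1 <- (seq_len(n_s1) - 1) * s1_cl
  burst <- max(s1) + delay + (seq_len(n_burst) - 1) * burst_cl
  data.frame(onset = c(s1, burst),
             phase = rep(c("S1", "burst"), c(n_s1, n_burst)))
}

#' Burst-pacing arrhythmia induction on a substrate
#'
#' Initialises every node from the 0D limit cycle at CL 700 ms, applies the S1
#' train at the CS-analogue box, the ectopic burst at the requested site, and
#' tracks the tissue for `track_ms` beyond the final stimulus.
#'
#' @param substrate a [build_substrate()] object with named stimulus boxes
#' @param site "LAA" or "roof"
#' @param electrolytes [electrolyte_set()]
#' @param n_prepace_beats 0D pre-pacing beats at CL 700 ms
#' @param track_ms tracking window after the final stimulus (default 5000)
#' @param dt,out_dt solver steps, ms
#' @param reference,mask optional electrolyte override
#' @return list with the `tissue_result`, the schedule, `final_stim_time` and
#'   `site`
#' @export
burst_induction <- function(substrate, site = c("LAA", "roof"), electrolytes,
                            n_prepace_beats = 30, track_ms = 5000,
                            dt = 0.05, out_dt = 10,
                            reference = electrolytes, mask = override_mask()) {
  site <- match.arg(site)
  sched <- burst_schedule()
  pp <- prepace(crn_parameters(), electrolytes,
                pacing_spec(cl = 700, n_beats = n_prepace_beats),
                reference = reference, mask = mask)
  stim_dur <- 2
  nodes <- ifelse(sched$phase == "S1", "CS", site)
  stimuli <- lapply(seq_len(nrow(sched)), function(i)
    stimulus_event(substrate$boxes[[nodes[i]]], onset = sched$onset[i],
                   duration = stim_dur, amplitude = 2 * .DEFAULT_STIM_AMP))
  final_stim <- max(sched$onset) + stim_dur
  res <- solve_monodomain(substrate$geometry, substrate$params, electrolytes,
                          stimuli, t_end = final_stim + track_ms,
                          dt = dt, out_dt = out_dt,
                          initial_states = pp$state,
                          reference = reference, mask = mask)
  list(result = res, schedule = sched, final_stim_time = final_stim,
       site = site)
}

#' Four-spiral initial condition
#'
#' Builds the "induction initial condition": a 2 x 2 arrangement of
#' Archimedean spiral phase fields with alternating chirality, phases mapped
#' to states sampled along the CL-300 limit cycle. Deterministic given the
#' substrate and configuration.
#'
#' @param substrate a substrate whose sheet spans at least 4 cm across
#' @param electrolytes [electrolyte_set()]
#' @param n_prepace_beats 0D pre-pacing beats at CL 300 ms
#' @param wavelength spiral arm winding length, cm. The default (10 cm, of
#'   the order of the tissue's natural wavelength CV x CL) makes each
#'   quadrant a gently wound pinwheel whose rotation period self-selects;
#'   much shorter windings leave no excitable gap and the pattern collapses.
#' @param n_samples limit-cycle samples used for the phase-to-state map
#' @param reference,mask optional electrolyte override
#' @return list with `states` (node x 21 matrix), `phase` (radians in
#'   \[0, 2pi)) and `chirality` of the four cores
#' @export
spiral_initial_condition <- function(substrate, electrolytes,
                                     n_prepace_beats = 40, wavelength = 10,
                                     n_samples = 64,
                                     reference = electrolytes,
                                     mask = override_mask()) {
  g <- substrate$geometry
  Lx <- (g$nx - 1) * g$dx; Ly <- (g$ny - 1) * g$dx
  if (min(Lx, Ly) < 4)
    stop(sprintf("sheet (%.1f x %.1f cm) too small for 4 spiral cores (needs >= 4 cm across)",
                 Lx, Ly))
  pp <- prepace(crn_parameters(), electrolytes,
                pacing_spec(cl = 300, n_beats = n_prepace_beats),
                reference = reference, mask = mask)
  cyc <- .crn_cycle_states_cpp(.as_state(pp$state), .as_params(crn_parameters()),
                               .as_elec(electrolytes), .as_elec(reference),
                               .as_mask(mask), 300, as.integer(n_samples),
                               .DEFAULT_STIM_AMP, 2, .DEFAULT_DT)
  xs <- (seq_len(g$nx) - 1) * g$dx
  ys <- (seq_len(g$ny) - 1) * g$dx
  X <- matrix(xs, g$nx, g$ny)
  Y <- matrix(ys, g$nx, g$ny, byrow = TRUE)
  centers <- expand.grid(cx = c(0.25, 0.75) * Lx, cy = c(0.25, 0.75) * Ly)
  centers$chir <- ifelse((match(centers$cx, unique(centers$cx)) +
                          match(centers$cy, unique(centers$cy))) %% 2 == 0,
                         1, -1)
  # assign each node to its nearest core
  d2 <- lapply(seq_len(4), function(i)
    (X - centers$cx[i])^2 + (Y - centers$cy[i])^2)
  core <- matrix(max.col(-sapply(d2, as.numeric)), g$nx, g$ny)
  phase <- matrix(0, g$nx, g$ny)
  for (i in seq_len(4)) {
    selm <- core == i
    th <- atan2(Y - centers$cy[i], X - centers$cx[i])
    r <- sqrt(d2[[i]])
    ph <- (centers$chir[i] * th - 2 * pi * r / wavelength) %% (2 * pi)
    phase[selm] <- ph[selm]
  }
  idx <- pmin(floor(phase / (2 * pi) * n_samples) + 1, n_samples)
  states <- cyc[as.numeric(idx), , drop = FALSE]
  list(states = states, phase = phase, chirality = centers$chir,
       centers = centers[, c("cx", "cy")])
}

#' Classify an arrhythmia episode
#'
#' From the activation times of a tissue result: the episode counts as
#' induced when any node exhibits at least `min_activations` activations after
#' the final stimulus with mean cycle length below `cl_max`; it counts as
#' terminated when it was induced and the tissue is quiescent (no activations
#' and all sampled voltages within 10 mV of the local diastolic minimum)
#' during the final `quiescence_ms` of the window. The dominant frequency is
#' the reciprocal of the mean inter-activation interval over active nodes.
#'
#' @param result a `tissue_result` covering the full tracking window
#' @param final_stim_time end of the last stimulus, ms
#' @param min_activations,cl_max,quiescence_ms detection thresholds
#' @return list of class `endpoint_episode`: `induced`, `terminated`,
#'   `dominant_frequency` (Hz), `episode_duration_s`, `n_active_nodes`
#' @export
classify_episode <- function(result, final_stim_time = 0,
                             min_activations = 3, cl_max = 500,
                             quiescence_ms = 200) {
  t_end <- max(result$times)
  post <- lapply(result$activations, function(a) a[a > final_stim_time])
  nact <- vapply(post, length, 0L)
  mean_cl <- vapply(post, function(a)
    if (length(a) >= 2) mean(diff(a)) else NA_real_, 0)
  active <- nact >= min_activations & !is.na(mean_cl) & mean_cl < cl_max
  induced <- any(active)
  df <- if (any(active)) 1000 / mean(mean_cl[active]) else NA_real_
  last_act <- suppressWarnings(max(unlist(post), -Inf))
  terminated <- NA
  if (induced) {
    tq <- t_end - quiescence_ms
    no_acts <- !is.finite(last_act) || last_act < tq
    selq <- result$times >= tq
    vq <- result$vm[selq, , drop = FALSE]
    rmp <- apply(result$vm, 2, min)
    volt_quiet <- all(sweep(vq, 2, rmp + 10, "<"))
    terminated <- no_acts && volt_quiet
  }
  structure(list(induced = induced, terminated = terminated,
                 dominant_frequency = df,
                 episode_duration_s =
                   if (is.finite(last_act))
                     max(0, (last_act - final_stim_time)) / 1000 else 0,
                 n_active_nodes = sum(active)),
            class = "endpoint_episode")
}

#' Combine the two burst-site episodes into an endpoint record
#'
#' @param laa,roof `endpoint_episode` results from [classify_episode()] for
#'   the LAA- and roof-site burst protocols
#' @param excluded_single_stimulus logical flag from
#'   [screen_single_stimulus()]
#' @return one-row data.frame with the four binary endpoints
#'   (`induced_LAA`, `induced_AR`, `induced_any`, `terminated`), the dominant
#'   frequency and the exclusion flag
#' @export
endpoint_record <- function(laa, roof, excluded_single_stimulus = FALSE) {
  induced_any <- laa$induced || roof$induced
  # terminated = every induced episode failed to sustain for the window
  eps <- Filter(function(e) e$induced, list(laa, roof))
  term <- if (length(eps) == 0) NA else all(vapply(eps, function(e)
    isTRUE(e$terminated), TRUE))
  dfs <- c(laa$dominant_frequency, roof$dominant_frequency)
  data.frame(induced_LAA = laa$induced, induced_AR = roof$induced,
             induced_any = induced_any, terminated = term,
             dominant_frequency = if (all(is.na(dfs))) NA_real_
                                  else mean(dfs, na.rm = TRUE),
             excluded_single_stimulus = excluded_single_stimulus)
}

#' Screen for self-sustaining activity under single-stimulus pacing
#'
#' Runs the CS-analogue two-stimulus mapping protocol and reports whether
#' activity persists more than `persist_ms` after the second beat's expected
#' repolarisation. Substrate/electrolyte combinations flagged here are
#' excluded from the paced-activation QoI tables.
#'
#' @param substrate,electrolytes configuration
#' @param n_prepace_beats 0D pre-pacing beats at CL 1000 ms
#' @param apd_margin expected repolarisation allowance after the second
#'   stimulus, ms
#' @param persist_ms persistence horizon, ms
#' @param dt solver step, ms
#' @param reference,mask optional electrolyte override
#' @param result optional pre-computed mapping-run `tissue_result` (with
#'   attribute `stim2_onset`) to avoid re-simulation
#' @return logical: TRUE when self-sustaining activity was detected
#' @export
screen_single_stimulus <- function(substrate, electrolytes,
                                   n_prepace_beats = 30, apd_margin = 400,
                                   persist_ms = 1000, dt = 0.05,
                                   reference = electrolytes,
                                   mask = override_mask(), result = NULL) {
  if (is.null(result)) {
    result <- mapping_run(substrate, electrolytes,
                          n_prepace_beats = n_prepace_beats, dt = dt,
                          extra_ms = apd_margin + persist_ms + 200,
                          reference = reference, mask = mask)
  }
  stim2 <- attr(result, "stim2_onset")
  horizon <- stim2 + apd_margin + persist_ms
  any(vapply(result$activations, function(a) any(a > horizon), TRUE))
}

#' Paced-activation mapping run
#'
#' The protocol behind the tissue QoI maps: two CS-analogue stimuli 1000 ms
#' apart from the CL-1000 limit cycle; maps are computed from the activation
#' waveform of the second stimulus.
#'
#' @param substrate,electrolytes configuration
#' @param n_prepace_beats 0D pre-pacing beats
#' @param dt,out_dt solver steps, ms
#' @param extra_ms additional tracked time after the second beat window
#' @param reference,mask optional electrolyte override
#' @return `tissue_result` with attribute `stim2_onset` (= 1000) and
#'   `map_window`
#' @export
mapping_run <- function(substrate, electrolytes, n_prepace_beats = 30,
                        dt = 0.05, out_dt = 0.5, extra_ms = 0,
                        reference = electrolytes, mask = override_mask()) {
  pp <- prepace(crn_parameters(), electrolytes,
                pacing_spec(cl = 1000, n_beats = n_prepace_beats),
                reference = reference, mask = mask)
  stimuli <- list(
    stimulus_event(substrate$boxes$CS, onset = 0),
    stimulus_event(substrate$boxes$CS, onset = 1000))
  res <- solve_monodomain(substrate$geometry, substrate$params, electrolytes,
                          stimuli, t_end = 2000 + extra_ms, dt = dt,
                          out_dt = out_dt, initial_states = pp$state,
                          reference = reference, mask = mask)
  attr(res, "stim2_onset") <- 1000
  attr(res, "map_window") <- c(1000, 2000)
  res
}
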