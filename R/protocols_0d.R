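# Single-myocyte pacing protocols, limit-cycle attainment and action-potential
# biomarker extraction.

# Default stimulus amplitude (pA/pF): twice the diastolic threshold of the
# baseline model at its CL-1000 limit cycle for a 2-ms rectangular pulse
# (threshold 13.3 pA/pF, found once by bisection with
# find_diastolic_threshold); see the methods vignette.
.DEFAULT_STIM_AMP <- 26.6
.DEFAULT_DT <- 0.02   # ms, Rush-Larsen step

#' Pacing specification
#'
#' A rectangular stimulus train: cycle length, total duration (or beat
#' count), amplitude and pulse width.
#'
#' @param cl cycle length, ms
#' @param duration train duration, ms (rounded down to whole beats);
#'   give either `duration` or `n_beats`
#' @param n_beats number of beats (overrides `duration`)
#' @param amplitude stimulus amplitude, pA/pF (positive = depolarising);
#'   default twice the baseline diastolic threshold
#' @param width pulse width, ms
#' @return list of class `pacing_spec` with an `n_beats` field
#' @export
#' @examples
#' pacing_spec(cl = 1000, duration = 15 * 60 * 1000)$n_beats  # 900 stimuli
pacing_spec <- function(cl = 1000, duration = NULL, n_beats = NULL,
                        amplitude = .DEFAULT_STIM_AMP, width = 2) {
  if (width <= 0 || cl <= width)
    stop("need cycle_length > stimulus width > 0")
  if (is.null(n_beats)) {
    if (is.null(duration)) stop("give duration or n_beats")
    if (duration < 0) stop("duration must be >= 0")
    n_beats <- floor(duration / cl)
  }
  structure(list(cl = cl, n_beats = as.integer(n_beats),
                 amplitude = amplitude, width = width),
            class = "pacing_spec")
}

#' Diastolic stimulus threshold by bisection
#'
#' Smallest rectangular-pulse amplitude that elicits an action potential
#' (upstroke above 0 mV) from the resting state, found by bisection.
#'
#' @param params,electrolytes model configuration
#' @param width pulse width, ms
#' @param tol bisection tolerance, pA/pF
#' @return threshold amplitude, pA/pF
#' @export
find_diastolic_threshold <- function(params = crn_parameters(),
                                     electrolytes = electrolyte_reference(),
                                     width = 2, tol = 0.05) {
  state <- crn_initial_state()
  fires <- function(amp) {
    tr <- record_ap(state, params, electrolytes,
                    pacing_spec(cl = 400, n_beats = 1, amplitude = amp,
                                width = width),
                    n_beats = 1, out_dt = 0.5)
    max(tr$V) > 0
  }
  lo <- 0; hi <- 2
  while (!fires(hi)) { lo <- hi; hi <- hi * 2; if (hi > 200) stop("no capture") }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Pre-pace a myocyte towards its limit cycle
#'
#' Delivers `pacing$n_beats` stimuli at the given cycle length and returns the
#' end-of-train state together with the limit-cycle residual: the max-norm of
#' the relative state difference between the starts of the last two beats.
#'
#' @param params [crn_parameters()]
#' @param electrolytes [electrolyte_set()]
#' @param pacing [pacing_spec()]
#' @param initial initial state (default [crn_initial_state()])
#' @param reference,mask optional electrolyte override (see
#'   [crn_derivatives()])
#' @param dt integrator step, ms
#' @return list with `state`, `residual`, `residuals` (per beat) and
#'   `n_stimuli`
#' @export
prepace <- function(params, electrolytes, pacing,
                    initial = crn_initial_state(),
                    reference = electrolytes, mask = override_mask(),
                    dt = .DEFAULT_DT) {
  st <- .as_state(initial)
  if (pacing$n_beats == 0)
    return(list(state = structure(setNames(st, .STATE_NAMES), class = "crn_state"),
                residual = NA_real_, residuals = numeric(0), n_stimuli = 0L))
  out <- .crn_prepace_cpp(st, .as_params(params), .as_elec(electrolytes),
                          .as_elec(reference), .as_mask(mask),
                          pacing$cl, pacing$n_beats, pacing$amplitude,
                          pacing$width, dt)
  list(state = structure(setNames(out$state, .STATE_NAMES), class = "crn_state"),
       residual = tail(out$residuals, 1),
       residuals = out$residuals,
       n_stimuli = out$n_stimuli)
}

#' Record a dense action-potential trace
#'
#' Integrates `n_beats` paced beats from `state` and returns the voltage and
#' per-current trace sampled every `out_dt` ms.
#'
#' @inheritParams prepace
#' @param state starting state (usually near the limit cycle)
#' @param n_beats number of beats to record
#' @param out_dt output sampling interval, ms
#' @return data.frame with columns `time`, `V` and one column per current
#' @export
record_ap <- function(state, params, electrolytes, pacing, n_beats = 1,
                      reference = electrolytes, mask = override_mask(),
                      dt = .DEFAULT_DT, out_dt = 0.1) {
  if (n_beats == 0) {
    empty <- as.data.frame(matrix(numeric(0), ncol = 2 + length(current_names())))
    names(empty) <- c("time", "V", current_names())
    return(empty)
  }
  out <- .crn_record_cpp(.as_state(state), .as_params(params),
                         .as_elec(electrolytes), .as_elec(reference),
                         .as_mask(mask), pacing$cl, as.integer(n_beats),
                         pacing$amplitude, pacing$width, dt, out_dt)
  tr <- data.frame(time = out$time, V = out$V)
  cur <- as.data.frame(out$currents)
  names(cur) <- current_names()
  cbind(tr, cur)
}

#' Action-potential biomarkers from a single-beat trace
#'
#' Extracts resting membrane potential (pre-stimulus minimum), maximum
#' upstroke velocity and its time, peak, amplitude, plateau peak (maximum V in
#' a window after the spike peak) and APD at the requested repolarisation
#' fractions, measured from the upstroke time until V first recovers the
#' given percentage of (peak - RMP).
#'
#' @param trace data.frame with `time` and `V` columns covering exactly one
#'   stimulated action potential
#' @param apd_fractions repolarisation percentages (default 70 and 90)
#' @param plateau_window ms after the spike peak over which the plateau peak
#'   is sought (default 10..120 ms)
#' @return list with `valid`, `RMP`, `APD70`, `APD90` (or `APDx` per
#'   fraction), `plateau_peak`, `amplitude`, `dVdt_max`, `upstroke_time`
#' @export
ap_biomarkers <- function(trace, apd_fractions = c(70, 90),
                          plateau_window = c(10, 120)) {
  t <- trace$time; V <- trace$V
  if (length(t) < 5) stop("trace too short")
  dVdt <- diff(V) / diff(t)
  iup <- which.max(dVdt)
  upstroke_time <- t[iup]
  rmp <- if (iup > 1) min(V[seq_len(iup)]) else V[1]
  ipk <- which.max(V)
  peak <- V[ipk]
  amplitude <- peak - rmp
  out <- list(valid = amplitude >= 40, RMP = rmp, amplitude = amplitude,
              dVdt_max = max(dVdt), upstroke_time = upstroke_time)
  if (!out$valid) {
    for (p in apd_fractions) out[[paste0("APD", p)]] <- NA_real_
    out$plateau_peak <- NA_real_
    return(out)
  }
  # plateau peak: maximum V in a window after the spike peak
  wsel <- t >= t[ipk] + plateau_window[1] & t <= t[ipk] + plateau_window[2]
  out$plateau_peak <- if (any(wsel)) max(V[wsel]) else peak
  post <- seq(ipk, length(t))
  for (p in apd_fractions) {
    vthr <- peak - p / 100 * amplitude
    idx <- post[which(V[post] <= vthr)[1]]
    apd <- if (is.na(idx)) NA_real_ else {
      # linear interpolation of the crossing
      if (idx > 1 && V[idx - 1] > vthr) {
        tc <- t[idx - 1] + (V[idx - 1] - vthr) / (V[idx - 1] - V[idx]) *
          (t[idx] - t[idx - 1])
      } else tc <- t[idx]
      tc - upstroke_time
    }
    out[[paste0("APD", p)]] <- apd
  }
  out
}

# Convenience: pre-pace then record one beat and extract biomarkers.
#' Limit-cycle action-potential biomarkers
#'
#' Pre-paces the model, records one further beat and returns its biomarkers.
#' The workhorse behind the 0D sensitivity pipeline.
#'
#' @inheritParams prepace
#' @param n_prepace_beats beats of pre-pacing before recording
#' @param cl cycle length, ms
#' @param ... passed to [ap_biomarkers()]
#' @return list of biomarkers (see [ap_biomarkers()])
#' @export
limit_cycle_biomarkers <- function(params = crn_parameters(),
                                   electrolytes = electrolyte_reference(),
                                   cl = 1000, n_prepace_beats = 40,
                                   reference = electrolytes,
                                   mask = override_mask(),
                                   dt = .DEFAULT_DT, ...) {
  pp <- prepace(params, electrolytes,
                pacing_spec(cl = cl, n_beats = n_prepace_beats),
                reference = reference, mask = mask, dt = dt)
  tr <- record_ap(pp$state, params, electrolytes,
                  pacing_spec(cl = cl, n_beats = 1),
                  reference = reference, mask = mask, dt = dt, out_dt = 0.1)
  ap_biomarkers(tr, ...)
}
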