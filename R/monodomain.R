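# Monodomain tissue simulation: geometries, conductivity-to-diffusivity
# scaling, the operator-split solver wrapper, and strand conduction velocity.

# Monodomain scaling D = sigma / (beta * Cm), sigma in S/m, beta surface-to-
# volume ratio 1/cm, Cm membrane capacitance uF/cm^2. The default pair
# (beta = 1400 /cm, Cm = 1 uF/cm^2) together with the region-1 longitudinal
# conductivity below puts the healthy baseline strand CV in the physiological
# 0.6-0.8 m/s band (see the methods vignette).
.BETA_DEFAULT <- 1400   # 1/cm
.CM_DEFAULT <- 1        # uF/cm^2

#' Convert tissue conductivity to monodomain diffusivity
#'
#' `D = sigma / (beta * Cm)` returned in cm^2/ms.
#'
#' @param sigma conductivity, S/m
#' @param beta surface-to-volume ratio, 1/cm
#' @param Cm membrane capacitance, uF/cm^2
#' @return diffusivity, cm^2/ms
#' @export
sigma_to_diffusivity <- function(sigma, beta = .BETA_DEFAULT, Cm = .CM_DEFAULT) {
  # sigma S/m = sigma/100 S/cm; S cm^2 / uF = 1e6 cm^2/s = 1e3 cm^2/ms
  (sigma / 100) / (beta * Cm * 1e-6) / 1000
}

#' Default six-region conductivity table
#'
#' Longitudinal and transverse conductivities (S/m) for the six IIR-defined
#' tissue regions. Regions are ordered by increasing image-intensity ratio;
#' regions 5-6 (IIR above the 1.22 fibrotic boundary) carry strongly reduced
#' conductivities. These defaults are declared package configuration, fully
#' overridable per substrate.
#'
#' @return data.frame with columns `region`, `sigma_l`, `sigma_t`
#' @export
conductivity_table <- function() {
  data.frame(region = 1:6,
             sigma_l = c(0.300, 0.275, 0.250, 0.220, 0.105, 0.075),
             sigma_t = c(0.105, 0.096, 0.088, 0.077, 0.037, 0.026))
}

#' 1D strand geometry
#'
#' A homogeneous strand (single-cable equivalent of a thin tissue slab).
#' The default is the 1-cm strand at 100-um resolution (101 nodes).
#'
#' @param length strand length, cm
#' @param dx node spacing, um
#' @param sigma_l longitudinal conductivity, S/m
#' @param beta,Cm monodomain scaling constants
#' @return list of class `geometry` with `nx`, `ny = 1`, `dx` (cm), per-node
#'   region ids and per-region conductivities
#' @export
geometry_1d <- function(length = 1.0, dx = 100, sigma_l = 0.300,
                        beta = .BETA_DEFAULT, Cm = .CM_DEFAULT) {
  dx_cm <- dx * 1e-4
  n <- length / dx_cm
  if (abs(n - round(n)) > 1e-9 || round(n) + 1 < 3)
    stop("length/spacing must yield an integer node count >= 3")
  nx <- as.integer(round(n)) + 1L
  structure(list(nx = nx, ny = 1L, dx = dx_cm,
                 region = rep(1L, nx),
                 sigma_l = sigma_l, sigma_t = sigma_l,
                 fibre_angle = rep(0, nx), beta = beta, Cm = Cm),
            class = "geometry")
}

#' 2D sheet geometry
#'
#' Regular sheet with per-node region ids, per-region longitudinal and
#' transverse conductivities and an optional fibre-angle field.
#'
#' @param nx,ny node counts
#' @param dx node spacing, um
#' @param region integer vector (length nx*ny, column-major in x) of region
#'   ids indexing the conductivity rows; default all 1
#' @param sigma_l,sigma_t per-region conductivities, S/m (recycled)
#' @param fibre_angle per-node fibre angle, rad (default 0; longitudinal = x)
#' @param beta,Cm monodomain scaling constants
#' @return list of class `geometry`
#' @export
geometry_2d <- function(nx, ny, dx = 200, region = NULL,
                        sigma_l = 0.300, sigma_t = 0.105, fibre_angle = 0,
                        beta = .BETA_DEFAULT, Cm = .CM_DEFAULT) {
  nn <- as.integer(nx) * as.integer(ny)
  if (is.null(region)) region <- rep(1L, nn)
  if (length(region) != nn) stop("region must have nx*ny entries")
  nreg <- max(max(region), length(sigma_l), length(sigma_t))
  sigma_l <- rep_len(sigma_l, nreg); sigma_t <- rep_len(sigma_t, nreg)
  if (any(sigma_l <= 0) || any(sigma_t <= 0)) stop("conductivities must be > 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx * 1e-4,
                 region = as.integer(region),
                 sigma_l = sigma_l, sigma_t = sigma_t,
                 fibre_angle = rep_len(fibre_angle, nn),
                 beta = beta, Cm = Cm),
            class = "geometry")
}

# per-node diffusion tensor entries (cm^2/ms)
.diffusivity_fields <- function(geometry) {
  reg <- geometry$region
  Dl <- sigma_to_diffusivity(geometry$sigma_l, geometry$beta, geometry$Cm)[reg]
  Dt <- sigma_to_diffusivity(geometry$sigma_t, geometry$beta, geometry$Cm)[reg]
  a <- geometry$fibre_angle
  list(Dxx = Dl * cos(a)^2 + Dt * sin(a)^2,
       Dyy = Dl * sin(a)^2 + Dt * cos(a)^2,
       Dxy = (Dl - Dt) * sin(a) * cos(a))
}

#' Stimulus event for tissue simulations
#'
#' @param nodes integer node indices (1-based, column-major in x)
#' @param onset stimulus onset, ms (>= 0)
#' @param duration pulse duration, ms
#' @param amplitude pA/pF (positive = depolarising)
#' @return list of class `stimulus_event`
#' @export
stimulus_event <- function(nodes, onset, duration = 2,
                           amplitude = 2 * .DEFAULT_STIM_AMP) {
  if (length(nodes) == 0) stop("stimulus node mask must be non-empty")
  if (onset < 0) stop("onset must be >= 0")
  structure(list(nodes = as.integer(nodes), onset = onset,
                 duration = duration, amplitude = amplitude),
            class = "stimulus_event")
}

#' Solve the monodomain reaction-diffusion model
#'
#' Operator-split update: ionic reaction per node with Rush-Larsen exponential
#' gate integration, diffusion by flux-form finite differences with no-flux
#' boundaries. Deterministic for fixed inputs.
#'
#' @param geometry [geometry_1d()] or [geometry_2d()]
#' @param params a single [crn_parameters()] (homogeneous tissue) or a list of
#'   parameter sets, one per region id
#' @param electrolytes [electrolyte_set()]
#' @param stimuli list of [stimulus_event()]
#' @param t_end simulation end, ms
#' @param dt time step, ms; must satisfy the FTCS stability bound
#'   `dt <= dx^2 / (2 (max Dxx + max Dyy))`
#' @param out_dt voltage sampling interval, ms
#' @param initial_states either a single state vector (applied to every node)
#'   or an (nx*ny) x 21 matrix
#' @param record_nodes node indices to record (default all)
#' @param reference,mask optional electrolyte override
#' @param act_threshold,act_refractory activation-detection settings (mV, ms)
#' @param return_states also return the final state matrix
#' @return list of class `tissue_result`: `times`, `vm` (time x node matrix),
#'   `record_nodes`, `activations` (per-node activation times), solver
#'   metadata, and `states` if requested
#' @export
solve_monodomain <- function(geometry, params, electrolytes, stimuli,
                             t_end, dt = 0.02, out_dt = 1,
                             initial_states = crn_initial_state(),
                             record_nodes = NULL,
                             reference = electrolytes, mask = override_mask(),
                             act_threshold = -40, act_refractory = 60,
                             return_states = FALSE) {
  nn <- geometry$nx * geometry$ny
  D <- .diffusivity_fields(geometry)
  dt_max <- geometry$dx^2 /
    (2 * ((geometry$nx > 1) * max(D$Dxx) + (geometry$ny > 1) * max(D$Dyy)))
  if (dt > dt_max)
    stop(sprintf("CFL violation: dt = %g ms exceeds stability bound %.4g ms",
                 dt, dt_max))
  if (inherits(params, "crn_parameters")) params <- list(params)
  pm <- do.call(rbind, lapply(params, .as_params))
  if (max(geometry$region) > nrow(pm))
    stop("region ids exceed the number of parameter sets")
  if (is.matrix(initial_states)) {
    stopifnot(nrow(initial_states) == nn)
    st <- initial_states
  } else {
    st <- matrix(rep(.as_state(initial_states), each = nn), nrow = nn)
  }
  if (length(stimuli) > 0 && inherits(stimuli, "stimulus_event"))
    stimuli <- list(stimuli)
  sn <- lapply(stimuli, function(s) s$nodes)
  so <- vapply(stimuli, function(s) s$onset, 0)
  sd_ <- vapply(stimuli, function(s) s$duration, 0)
  sa <- vapply(stimuli, function(s) s$amplitude, 0)

  out <- .solve_monodomain_cpp(st, geometry$region, pm,
                               .as_elec(electrolytes), .as_elec(reference),
                               .as_mask(mask),
                               geometry$nx, geometry$ny, geometry$dx,
                               D$Dxx, D$Dyy, D$Dxy,
                               sn, so, sd_, sa,
                               t_end, dt, out_dt,
                               if (is.null(record_nodes)) integer(0)
                               else as.integer(record_nodes),
                               act_threshold, act_refractory, return_states)
  out$geometry <- geometry
  out$dt <- dt
  out$out_dt <- out_dt
  out$scheme <- "rush_larsen_ftcs"
  if (length(out$record_nodes) == 0) out$record_nodes <- seq_len(nn)
  class(out) <- "tissue_result"
  out
}

#' Strand conduction velocity from the two-point LAT formula
#'
#' `CV = 0.5 cm / (LAT(0.75 cm) - LAT(0.25 cm))`, in m/s, with LAT the time
#' of maximum dV/dt at each probe within the analysis window.
#'
#' @param result a `tissue_result` on a 1D geometry
#' @param window time window (ms, length 2) isolating the measured beat;
#'   default the last full beat heuristically = entire record
#' @return list with `cv` (m/s, NA under block), `block` flag and the two
#'   probe LATs
#' @export
strand_cv <- function(result, window = NULL) {
  g <- result$geometry
  if (g$ny != 1) stop("strand_cv needs a 1D result")
  probe_x <- c(0.25, 0.75)
  idx <- round(probe_x / g$dx) + 1
  pos <- match(idx, result$record_nodes)
  if (any(is.na(pos))) stop("probe nodes were not recorded")
  t <- result$times
  sel <- if (is.null(window)) rep(TRUE, length(t)) else
    t >= window[1] & t <= window[2]
  lats <- numeric(2); ok <- logical(2)
  for (i in 1:2) {
    V <- result$vm[sel, pos[i]]
    tt <- t[sel]
    amp <- max(V) - min(V)
    ok[i] <- amp >= 40
    dV <- diff(V) / diff(tt)
    j <- which.max(dV)
    tm <- (tt[-1] + tt[-length(tt)]) / 2   # derivative sample midpoints
    lat <- tm[j]
    if (j > 1 && j < length(dV)) {
      # parabolic refinement of the dV/dt peak (sub-sample precision)
      den <- dV[j - 1] - 2 * dV[j] + dV[j + 1]
      if (den < 0) lat <- lat + 0.5 * (dV[j - 1] - dV[j + 1]) / den *
          (tm[j + 1] - tm[j])
    }
    lats[i] <- lat
  }
  if (!all(ok) || lats[2] <= lats[1])
    return(list(cv = NA_real_, block = TRUE, lat = lats))
  list(cv = 0.5 / (lats[2] - lats[1]) * 10, block = FALSE, lat = lats)
}

#' Paced-strand CV protocol
#'
#' The strand protocol behind the CV sensitivity analyses: pre-pace a single
#' myocyte at the target cycle length, initialise every strand node from that
#' state, deliver paced beats at one end and measure CV on the last beat with
#' the two-point formula.
#'
#' @param params,electrolytes model configuration
#' @param cl pacing cycle length, ms
#' @param n_prepace_beats 0D pre-pacing beats
#' @param n_beats paced strand beats (CV measured on the last)
#' @param geometry strand geometry (default 1 cm / 100 um)
#' @param dt tissue time step, ms
#' @param reference,mask optional electrolyte override
#' @return list with `cv`, `block`, `lat` and the full `result`
#' @export
strand_cv_protocol <- function(params, electrolytes, cl = 1000,
                               n_prepace_beats = 40, n_beats = 2,
                               geometry = geometry_1d(), dt = 0.02,
                               reference = electrolytes,
                               mask = override_mask()) {
  pp <- prepace(params, electrolytes, pacing_spec(cl = cl, n_beats = n_prepace_beats),
                reference = reference, mask = mask)
  stim_nodes <- seq_len(max(2, round(0.05 / geometry$dx)))
  stimuli <- lapply(seq_len(n_beats) - 1, function(b)
    stimulus_event(stim_nodes, onset = b * cl, duration = 2,
                   amplitude = 2 * .DEFAULT_STIM_AMP))
  res <- solve_monodomain(geometry, params, electrolytes, stimuli,
                          t_end = n_beats * cl, dt = dt, out_dt = 0.2,
                          initial_states = pp$state,
                          reference = reference, mask = mask)
  cv <- strand_cv(res, window = c((n_beats - 1) * cl, n_beats * cl))
  c(cv, list(result = res))
}
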