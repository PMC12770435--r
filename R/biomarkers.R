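# Activation/repolarisation maps (LAT, LRT, APD90, CV) and cohort-style
# quantity-of-interest summaries from tissue simulations.

#' Activation and repolarisation maps from a tissue result
#'
#' Per recorded node, within a window isolating one beat: LAT = time of
#' maximum dV/dt; LRT = first time after the local peak at which V recovers
#' 90% of the local amplitude; APD90 = LRT - LAT. Nodes with local amplitude
#' below 40 mV are masked invalid.
#'
#' @param result a `tissue_result`
#' @param window numeric length-2 time window, ms (must be non-empty)
#' @return list of class `activation_maps` with `LAT`, `LRT`, `APD90` (ms),
#'   `valid` mask, `RMP`, `amplitude` and the geometry
#' @export
activation_repolarisation_maps <- function(result, window = range(result$times)) {
  t <- result$times
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 5) stop("empty or too-short analysis window")
  tt <- t[sel]
  vm <- result$vm[sel, , drop = FALSE]
  nnode <- ncol(vm)
  LAT <- LRT <- RMP <- AMP <- rep(NA_real_, nnode)
  valid <- logical(nnode)
  dtv <- diff(tt)
  for (k in seq_len(nnode)) {
    V <- vm[, k]
    dV <- diff(V) / dtv
    iup <- which.max(dV)
    rmp <- min(V[seq_len(max(iup, 1))])
    ipk <- which.max(V)
    amp <- V[ipk] - rmp
    RMP[k] <- rmp; AMP[k] <- amp
    if (amp < 40) next
    LAT[k] <- tt[iup]
    vthr <- V[ipk] - 0.9 * amp
    post <- seq(ipk, length(tt))
    irec <- post[which(V[post] <= vthr)[1]]
    if (is.na(irec)) next
    if (irec > 1 && V[irec - 1] > vthr) {
      LRT[k] <- tt[irec - 1] + (V[irec - 1] - vthr) / (V[irec - 1] - V[irec]) *
        (tt[irec] - tt[irec - 1])
    } else LRT[k] <- tt[irec]
    valid[k] <- TRUE
  }
  structure(list(LAT = LAT, LRT = LRT, APD90 = LRT - LAT,
                 valid = valid, RMP = RMP, amplitude = AMP,
                 geometry = result$geometry,
                 record_nodes = result$record_nodes),
            class = "activation_maps")
}

#' Local conduction-velocity map from the LAT gradient
#'
#' `CV = 1 / |grad LAT|` by central differences (one-sided at sheet edges),
#' in m/s. Gradient magnitudes below `grad_floor` (block/plateau regions) and
#' nodes adjacent to invalid nodes are masked.
#'
#' @param maps an `activation_maps` object covering the full sheet
#' @param geometry the sheet geometry (defaults to the one stored in `maps`)
#' @param grad_floor minimum |grad LAT| in ms/cm treated as propagation
#' @return numeric CV field (m/s) with NA where masked
#' @export
cv_map_from_lat <- function(maps, geometry = maps$geometry, grad_floor = 0.5) {
  nx <- geometry$nx; ny <- geometry$ny; dx <- geometry$dx
  if (length(maps$LAT) != nx * ny)
    stop("maps must cover the full sheet (record all nodes)")
  if (!any(maps$valid)) stop("all nodes invalid; no activation map")
  lat <- matrix(ifelse(maps$valid, maps$LAT, NA_real_), nx, ny)
  gx <- matrix(NA_real_, nx, ny); gy <- matrix(NA_real_, nx, ny)
  if (nx >= 3) {
    gx[2:(nx - 1), ] <- (lat[3:nx, ] - lat[1:(nx - 2), ]) / (2 * dx)
    gx[1, ] <- (lat[2, ] - lat[1, ]) / dx
    gx[nx, ] <- (lat[nx, ] - lat[nx - 1, ]) / dx
  } else gx[] <- 0
  if (ny >= 3) {
    gy[, 2:(ny - 1)] <- (lat[, 3:ny] - lat[, 1:(ny - 2)]) / (2 * dx)
    gy[, 1] <- (lat[, 2] - lat[, 1]) / dx
    gy[, ny] <- (lat[, ny] - lat[, ny - 1]) / dx
  } else gy[] <- 0
  gmag <- sqrt(gx^2 + gy^2)          # ms/cm
  cv <- ifelse(is.na(gmag) | gmag < grad_floor, NA_real_, 10 / gmag)  # m/s
  as.numeric(cv)
}

#' Cohort quantity-of-interest summary
#'
#' The four tissue QoIs: median APD90 (`mAPD`), median CV (`mCV`) and their
#' 2.5-97.5 inter-percentile ranges (`DAPD`, `DCV`) over valid nodes, plus
#' their relative variations `(x - x_ref)/x_ref` against an optional baseline
#' summary. Percentiles use linear interpolation between order statistics.
#'
#' @param maps an `activation_maps` object
#' @param cv_field CV values per node (e.g. from [cv_map_from_lat()]); for 1D
#'   strands a single CV may be supplied
#' @param baseline optional baseline `biomarker_summary` for relative QoIs
#' @return list of class `biomarker_summary`: `mAPD`, `mCV`, `DAPD`, `DCV`
#'   and, when `baseline` is given, `rel` (named vector of the four relative
#'   variations)
#' @export
summarise_qoi <- function(maps, cv_field, baseline = NULL) {
  apd <- maps$APD90[maps$valid]
  apd <- apd[is.finite(apd)]
  cvv <- cv_field[is.finite(cv_field)]
  if (length(apd) < 10) stop("fewer than 10 valid nodes")
  q <- function(x, p) unname(quantile(x, p, type = 7))
  out <- list(mAPD = median(apd), mCV = median(cvv),
              DAPD = q(apd, 0.975) - q(apd, 0.025),
              DCV = if (length(cvv) >= 10) q(cvv, 0.975) - q(cvv, 0.025) else 0)
  if (!is.null(baseline)) {
    ref <- unlist(baseline[c("mAPD", "mCV", "DAPD", "DCV")])
    if (any(ref == 0)) stop("baseline QoI equals zero; relative variation undefined")
    x <- unlist(out[c("mAPD", "mCV", "DAPD", "DCV")])
    out$rel <- (x - ref) / ref
  }
  structure(out, class = "biomarker_summary")
}
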