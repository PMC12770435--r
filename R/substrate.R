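# Synthetic atrial substrates: spatially correlated image-intensity-ratio
# (IIR) fields, six-region segmentation, fibrosis statistics matching the
# cohort distribution, and normalized-coordinate stimulus boxes.

#' Synthetic substrate configuration
#'
#' Defaults emulate the statistical structure of the LGE-MRI cohort: a smooth
#' IIR-like field segmented by five increasing thresholds into six regions
#' (1.22 the fibrotic boundary), with per-substrate fibrotic fraction drawn
#' from a normal distribution with mean 0.21 and sd 0.15, clipped to
#' \[0, 0.70\].
#'
#' @param size sheet edge length, cm
#' @param dx node spacing, um
#' @param correlation_length IIR field correlation length, mm
#' @param fib_mean,fib_sd,fib_clip target fibrotic-fraction distribution
#' @param thresholds five increasing IIR cut-points defining six classes;
#'   must include the 1.22 fibrotic boundary
#' @param conductivities per-region conductivity table
#'   (default [conductivity_table()])
#' @param sigma_scale global conductivity multiplier; induction sheets use
#'   0.5 to emulate the diffusely slowed bulk conduction of the AF-prone
#'   atrium
#' @param area_jitter_sd lognormal sd of the per-substrate surface-area
#'   feature
#' @param stim_boxes named list of normalized-coordinate boxes
#'   (x1, x2, y1, y2): coronary-sinus analogue, LAA analogue, roof analogue
#' @return list of class `substrate_config`
#' @export
substrate_config <- function(size = 2.0, dx = 250, correlation_length = 5,
                             fib_mean = 0.21, fib_sd = 0.15,
                             fib_clip = c(0, 0.70),
                             thresholds = c(0.90, 1.05, 1.15, 1.22, 1.32),
                             conductivities = conductivity_table(),
                             sigma_scale = 1,
                             area_jitter_sd = 0.15,
                             stim_boxes = list(
                               CS = c(0.5, 0.7, 0.8, 0.9),
                               LAA = c(0.9, 0.91, 0.9, 0.91),
                               roof = c(0.48, 0.49, 0.48, 0.49))) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (!any(abs(thresholds - 1.22) < 1e-9))
    stop("1.22 (the fibrotic boundary) must be one of the thresholds")
  if (length(thresholds) != 5) stop("need exactly five cut-points (six classes)")
  structure(list(size = size, dx = dx,
                 correlation_length = correlation_length,
                 fib_mean = fib_mean, fib_sd = fib_sd, fib_clip = fib_clip,
                 thresholds = thresholds, conductivities = conductivities,
                 sigma_scale = sigma_scale,
                 area_jitter_sd = area_jitter_sd, stim_boxes = stim_boxes),
            class = "substrate_config")
}

# smooth standardized Gaussian field by separable kernel convolution with
# edge renormalisation
.smooth_field <- function(z, kern) {
  conv1 <- function(m, k, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    half <- (length(k) - 1) / 2
    out <- matrix(0, nrow(m), ncol(m))
    wgt <- matrix(0, nrow(m), ncol(m))
    for (o in -half:half) {
      w <- k[o + half + 1]
      if (along == 1) {
        src <- pmin(pmax(seq_len(n) + o, 1), n)
        out <- out + w * m[src, , drop = FALSE]
      } else {
        src <- pmin(pmax(seq_len(n) + o, 1), n)
        out <- out + w * m[, src, drop = FALSE]
      }
      wgt <- wgt + w
    }
    out / wgt
  }
  conv1(conv1(z, kern, 1), kern, 2)
}

#' Generate a synthetic IIR field
#'
#' Filtered Gaussian noise (separable Gaussian kernel at the configured
#' correlation length), monotone-transformed so that the fraction of nodes
#' with IIR above 1.22 equals a per-substrate target drawn from the clipped
#' cohort distribution. Fully reproducible by seed.
#'
#' @param config a [substrate_config()]
#' @param seed integer seed
#' @param target_fraction optional fixed fibrotic fraction in
#'   `config$fib_clip`; by default drawn from the configured distribution
#' @return matrix (nx x ny) of IIR values, with attributes `target_fraction`
#'   and `seed`
#' @export
generate_iir_field <- function(config = substrate_config(), seed = 1,
                               target_fraction = NULL) {
  set.seed(seed)
  nx <- round(config$size / (config$dx * 1e-4)) + 1
  ny <- nx
  if (is.null(target_fraction)) {
    f <- rnorm(1, config$fib_mean, config$fib_sd)
    f <- min(max(f, config$fib_clip[1]), config$fib_clip[2])
  } else {
    f <- target_fraction
    if (f < config$fib_clip[1] || f > config$fib_clip[2])
      stop(sprintf("target fraction %.3f outside clipping bounds [%g, %g]",
                   f, config$fib_clip[1], config$fib_clip[2]))
  }
  z <- matrix(rnorm(nx * ny), nx, ny)
  # Gaussian kernel with sd = correlation length in nodes
  sd_nodes <- max(1, config$correlation_length / (config$dx * 1e-3))
  half <- ceiling(3 * sd_nodes)
  kern <- exp(-0.5 * ((-half:half) / sd_nodes)^2)
  z <- .smooth_field(z, kern)
  z <- (z - mean(z)) / sd(z)
  # monotone log map anchored so that P(IIR > 1.22) = f
  cut <- if (f <= 0) max(z) + 1 else if (f >= 1) min(z) - 1 else
    quantile(z, 1 - f, type = 1)
  iir <- 1.22 * exp(0.12 * (z - cut))
  attr(iir, "target_fraction") <- f
  attr(iir, "seed") <- seed
  iir
}

#' Fraction of fibrotic nodes in an IIR field
#' @param iir IIR field or substrate
#' @param threshold fibrotic boundary (default 1.22)
#' @return fraction in \[0, 1\]
#' @export
fibrosis_fraction <- function(iir, threshold = 1.22) {
  if (inherits(iir, "substrate")) iir <- iir$iir
  mean(iir > threshold)
}

#' Build a substrate from an IIR field
#'
#' Segments the field into six regions by the configured thresholds, attaches
#' per-region cell parameters (regions above the 1.22 boundary receive
#' [apply_fibrosis_remodelling()] parameters and reduced conductivities) and
#' places the three stimulus boxes in normalized sheet coordinates.
#'
#' @param iir field from [generate_iir_field()]
#' @param config the [substrate_config()] used to build the field
#' @return list of class `substrate`: `iir`, `region` (per node), `geometry`,
#'   `params` (list per region), `boxes` (node-index lists), `fib_fraction`,
#'   `area_cm2`
#' @export
build_substrate <- function(iir, config = substrate_config()) {
  if (any(!is.finite(iir))) stop("IIR field must be finite")
  nx <- nrow(iir); ny <- ncol(iir)
  thr <- config$thresholds
  region <- matrix(findInterval(iir, thr) + 1L, nx, ny)  # 1..6
  fibrotic_region <- (1:6) > (which(abs(thr - 1.22) < 1e-9))
  healthy <- crn_parameters()
  fibro <- apply_fibrosis_remodelling(crn_parameters())
  params <- lapply(1:6, function(r) if (fibrotic_region[r]) fibro else healthy)
  ct <- config$conductivities
  ss <- if (is.null(config$sigma_scale)) 1 else config$sigma_scale
  geometry <- geometry_2d(nx, ny, dx = config$dx, region = as.integer(region),
                          sigma_l = ct$sigma_l * ss, sigma_t = ct$sigma_t * ss)
  # stimulus boxes in normalized coordinates
  xs <- (seq_len(nx) - 1) / (nx - 1)
  ys <- (seq_len(ny) - 1) / (ny - 1)
  boxes <- lapply(config$stim_boxes, function(b) {
    inx <- which(xs >= b[1] & xs <= b[2])
    iny <- which(ys >= b[3] & ys <= b[4])
    if (length(inx) == 0 || length(iny) == 0) {
      # expand to the nearest node
      cx <- (b[1] + b[2]) / 2; cy <- (b[3] + b[4]) / 2
      inx <- which.min(abs(xs - cx)); iny <- which.min(abs(ys - cy))
      warning("empty stimulus box after discretisation; expanded to nearest node")
    }
    as.integer(outer(inx, (iny - 1) * nx, "+"))
  })
  structure(list(iir = iir, region = as.integer(region), geometry = geometry,
                 params = params, boxes = boxes,
                 fib_fraction = fibrosis_fraction(iir),
                 area_cm2 = config$size^2, config = config),
            class = "substrate")
}

#' Generate a cohort of synthetic substrates
#'
#' `n` substrates with independent seeds derived from the master seed;
#' per-substrate surface area is jittered lognormally to provide the
#' left-atrial surface-area feature used by the cohort classifiers.
#'
#' @param n cohort size (>= 0)
#' @param config a [substrate_config()]
#' @param seed master seed
#' @return list of `substrate` objects
#' @export
generate_cohort <- function(n, config = substrate_config(), seed = 1) {
  if (n == 0) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n)
  jit <- exp(rnorm(n, 0, config$area_jitter_sd))
  lapply(seq_len(n), function(i) {
    s <- build_substrate(generate_iir_field(config, seed = seeds[i]), config)
    s$area_cm2 <- s$area_cm2 * jit[i]
    s$seed <- seeds[i]
    s
  })
}
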