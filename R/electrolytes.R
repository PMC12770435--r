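# Extracellular electrolyte sets, reference values and ranges, and the
# per-current override mask used to attribute biomarker sensitivity to
# individual electrolyte-dependent currents.

# accepted simulation ranges (mM); outside these the ionic model is not trusted
.ELEC_LIMITS <- list(Ko = c(2, 10), Nao = c(80, 200), Cao = c(0.5, 5))

#' Extracellular electrolyte set
#'
#' The triple (\[K+\]o, \[Na+\]o, \[Ca2+\]o) in mM that parameterises the
#' ionic model and everything downstream. Values must be strictly positive
#' and inside the accepted simulation ranges Ko in \[2, 10\],
#' Nao in \[80, 200\], Cao in \[0.5, 5\] mM.
#'
#' @param Ko extracellular potassium, mM (reference 4.5)
#' @param Nao extracellular sodium, mM (reference 140)
#' @param Cao extracellular calcium, mM (reference 1.8)
#' @return a named numeric vector of class `electrolyte_set`
#' @export
#' @examples
#' electrolyte_set(4.5, 140, 1.8)
electrolyte_set <- function(Ko = 4.5, Nao = 140, Cao = 1.8) {
  vals <- c(Ko = Ko, Nao = Nao, Cao = Cao)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("electrolyte concentrations must be finite and strictly positive")
  for (nm in names(vals)) {
    lim <- .ELEC_LIMITS[[nm]]
    if (vals[[nm]] < lim[1] || vals[[nm]] > lim[2])
      stop(sprintf("%s = %g mM outside accepted simulation range [%g, %g]",
                   nm, vals[[nm]], lim[1], lim[2]))
  }
  structure(vals, class = "electrolyte_set")
}

#' Reference (baseline) electrolyte concentrations
#'
#' Plasma reference values: \[K+\]o = 4.5 mM, \[Na+\]o = 140 mM,
#' \[Ca2+\]o = 1.8 mM.
#' @return an `electrolyte_set`
#' @export
electrolyte_reference <- function() electrolyte_set(4.5, 140, 1.8)

#' Electrolyte variation ranges
#'
#' The clinically motivated study ranges: reference +/- 1.5 mM (33%) for
#' \[K+\]o and +/- 25% for \[Na+\]o and \[Ca2+\]o.
#'
#' @return a 2 x 3 matrix with rows `lo`, `hi` and columns Ko, Nao, Cao
#' @export
electrolyte_ranges <- function() {
  ref <- electrolyte_reference()
  lo <- c(Ko = ref[["Ko"]] - 1.5, Nao = ref[["Nao"]] * 0.75, Cao = ref[["Cao"]] * 0.75)
  hi <- c(Ko = ref[["Ko"]] + 1.5, Nao = ref[["Nao"]] * 1.25, Cao = ref[["Cao"]] * 1.25)
  rbind(lo = lo, hi = hi)
}

#' Names of the CRN++ transmembrane currents
#'
#' Canonical current ordering used throughout the package (parameter maxima,
#' current outputs and override masks all follow it).
#' @return character vector of 12 current names
#' @export
current_names <- function() {
  c("INa", "IK1", "Ito", "IKur", "IKr", "IKs",
    "ICaL", "INaK", "INaCa", "IbNa", "IbCa", "ICap")
}

#' Per-current electrolyte override mask
#'
#' Controls which electrolyte set each transmembrane current "sees": currents
#' marked `"perturbed"` are evaluated with the perturbed electrolyte set,
#' currents marked `"reference"` with the reference set. Used for per-current
#' sensitivity attribution, e.g. varying \[Na+\]o only inside the INaCa
#' expression while all other Na+-dependent currents keep the reference value.
#'
#' @param perturbed character vector of current names that see the perturbed
#'   electrolytes; the special value `"all"` (default) perturbs every current.
#' @return named integer vector (1 = perturbed, 0 = reference) of class
#'   `override_mask`, one entry per current
#' @export
#' @examples
#' override_mask("INaCa")  # only INaCa sees the perturbed electrolytes
override_mask <- function(perturbed = "all") {
  nm <- current_names()
  if (identical(perturbed, "all")) {
    m <- rep(1L, length(nm))
  } else {
    bad <- setdiff(perturbed, nm)
    if (length(bad) > 0)
      stop("unknown current name(s): ", paste(bad, collapse = ", "))
    m <- as.integer(nm %in% perturbed)
  }
  structure(setNames(m, nm), class = "override_mask")
}

.as_mask <- function(mask) {
  if (is.null(mask)) return(unclass(override_mask("all")))
  if (inherits(mask, "override_mask")) return(unclass(mask))
  if (is.numeric(mask) && length(mask) == length(current_names()))
    return(as.integer(mask))
  stop("mask must be an override_mask")
}

.as_elec <- function(e) {
  if (inherits(e, "electrolyte_set")) return(unclass(e))
  if (is.numeric(e) && length(e) == 3) {
    e <- setNames(as.numeric(e), c("Ko", "Nao", "Cao"))
    return(unclass(do.call(electrolyte_set, as.list(e))))
  }
  stop("expected an electrolyte_set")
}
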