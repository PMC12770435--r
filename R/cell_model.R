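# CRN++ cell model: parameter sets, state vectors, reversal potentials,
# K+o conductance scaling, the full right-hand side, and fibrosis remodelling.

.PARAM_NAMES <- c("gNa", "gK1", "gto", "gKr", "gKs", "gCaL", "gbCa", "gbNa",
                  "INaKmax", "INaCamax", "IpCamax", "gKur_scale",
                  "fibrotic", "variable_ECa", "k_anchor", "k_exponent",
                  "temperature")

.STATE_NAMES <- c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                  "d", "f", "fCa", "u", "v", "w",
                  "Nai", "Ki", "Cai", "Caup", "Carel")

#' CRN++ cell parameters
#'
#' Maximal conductances and carrier maxima of the modified
#' Courtemanche-Ramirez-Nattel human atrial myocyte model (units of the
#' original formulation: conductances nS/pF, INaKmax/IpCamax pA/pF,
#' INaCamax pA/pF scaling constant), plus the \[K+\]o-sensitivity parameters
#' of the IK1/IKr modification and two option flags.
#'
#' The conductances of IK1 and IKr are multiplied at evaluation time by
#' `(Ko / k_anchor)^k_exponent` (see [potassium_scaling()]), reproducing the
#' inward-rectifier "cross-over" sensitivity of resting potential and late
#' repolarisation to \[K+\]o. `variable_ECa` replaces the fixed +65 mV ICaL
#' driving term of the original model with the Nernst calcium reversal
#' potential.
#'
#' @param fibrotic logical; whether fibrosis remodelling has been applied.
#'   Set via [apply_fibrosis_remodelling()], not directly.
#' @param variable_ECa logical; let the ICaL reversal potential vary with
#'   \[Ca2+\]o (default FALSE = original fixed driving term)
#' @param k_anchor anchor \[K+\]o (mM) of the IK1/IKr conductance scaling
#' @param k_exponent exponent of the IK1/IKr conductance scaling
#' @param ... named overrides for individual maxima (e.g. `gNa = 7.8`)
#' @return named numeric vector of class `crn_parameters`
#' @export
crn_parameters <- function(fibrotic = FALSE, variable_ECa = FALSE,
                           k_anchor = 5.4, k_exponent = 0.5, ...) {
  p <- c(gNa = 7.8, gK1 = 0.09, gto = 0.1652, gKr = 0.029411765,
         gKs = 0.12941176, gCaL = 0.12375, gbCa = 0.001131,
         gbNa = 0.0006744375, INaKmax = 0.59933874, INaCamax = 1600,
         IpCamax = 0.275, gKur_scale = 1.0,
         fibrotic = as.numeric(fibrotic), variable_ECa = as.numeric(variable_ECa),
         k_anchor = k_anchor, k_exponent = k_exponent, temperature = 310)
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), .PARAM_NAMES)
    if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  cond <- p[c("gNa", "gK1", "gto", "gKr", "gKs", "gCaL", "gbCa", "gbNa",
              "INaKmax", "INaCamax", "IpCamax", "gKur_scale")]
  if (any(cond < 0)) stop("conductances and carrier maxima must be non-negative")
  if (p[["k_anchor"]] <= 0) stop("k_anchor must be positive")
  structure(p, class = "crn_parameters")
}

.as_params <- function(p) {
  if (inherits(p, "crn_parameters")) return(unclass(p)[.PARAM_NAMES])
  if (is.numeric(p) && all(.PARAM_NAMES %in% names(p)))
    return(as.numeric(p[.PARAM_NAMES]))
  stop("expected crn_parameters")
}

#' CRN resting initial state
#'
#' The published resting state of the CRN model: membrane potential, the 15
#' gating variables and the 5 intracellular concentrations, in the package's
#' frozen state layout (V, m, h, j, oa, oi, ua, ui, xr, xs, d, f, fCa, u, v,
#' w, Nai, Ki, Cai, Caup, Carel).
#'
#' @return named numeric vector of class `crn_state`
#' @export
crn_initial_state <- function() {
  s <- c(V = -81.18, m = 2.908e-3, h = 0.9649, j = 0.9775,
         oa = 3.043e-2, oi = 0.9992, ua = 4.966e-3, ui = 0.9986,
         xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 0.9996,
         fCa = 0.7755, u = 0, v = 1, w = 0.9992,
         Nai = 11.17, Ki = 139.0, Cai = 1.013e-4, Caup = 1.488, Carel = 1.488)
  structure(s, class = "crn_state")
}

.as_state <- function(s) {
  if (inherits(s, "crn_state")) s <- unclass(s)
  if (!is.numeric(s) || length(s) != length(.STATE_NAMES))
    stop("state must be a numeric vector of length ", length(.STATE_NAMES))
  if (!is.null(names(s))) s <- s[.STATE_NAMES]
  gates <- s[2:16]
  if (any(gates < -1e-9) || any(gates > 1 + 1e-9))
    stop("gating variables must lie in [0, 1]")
  if (any(s[17:21] <= 0))
    stop("intracellular concentrations must be positive")
  as.numeric(s)
}

#' Nernst equilibrium potential
#'
#' `E = (R T)/(z F) ln(conc_out / conc_in)` in mV, with R = 8.3143 J/(K mol)
#' and F = 96.4867 C/mmol (CRN constants).
#'
#' @param valence ionic valence z (non-zero integer)
#' @param conc_out extracellular concentration, mM
#' @param conc_in intracellular concentration, mM
#' @param temperature kelvin (default 310)
#' @return potential in mV
#' @export
#' @examples
#' nernst_potential(1, 5.4, 139)    # K+ reversal, approx -86.7 mV
nernst_potential <- function(valence, conc_out, conc_in, temperature = 310) {
  if (valence == 0) stop("valence must be non-zero")
  if (any(c(conc_out, conc_in) <= 0) || any(!is.finite(c(conc_out, conc_in))))
    stop("concentrations must be positive and finite")
  8.3143 * temperature / (valence * 96.4867) * log(conc_out / conc_in)
}

#' \[K+\]o conductance scaling for IK1 and IKr
#'
#' The CRN++ modification: inward-rectifier and rapid delayed-rectifier
#' conductances are multiplied by `(Ko/anchor)^exponent`. The default square
#' root anchored at the CRN value 5.4 mM is the standard \[K+\]o-dependence of
#' IK1-family conductances; anchor and exponent are exposed so an alternative
#' formulation can be substituted without code change.
#'
#' @param Ko extracellular potassium, mM
#' @param anchor anchor concentration, mM (default 5.4)
#' @param exponent dimensionless (default 0.5)
#' @return multiplicative scale factor
#' @export
potassium_scaling <- function(Ko, anchor = 5.4, exponent = 0.5) {
  if (any(Ko <= 0) || anchor <= 0) stop("Ko and anchor must be positive")
  (Ko / anchor)^exponent
}

#' CRN++ right-hand side and transmembrane currents
#'
#' Evaluates the full CRN++ kinetics at one state: time derivatives of all 21
#' state variables and the 12 membrane currents (pA/pF). Reversal potentials
#' are recomputed from the electrolytes each current sees under the override
#' `mask`; IK1/IKr conductances carry the \[K+\]o scaling.
#'
#' @param state a [crn_initial_state()]-layout state vector
#' @param params [crn_parameters()]
#' @param perturbed perturbed [electrolyte_set()]
#' @param reference reference [electrolyte_set()] seen by masked-out currents
#'   (default: the perturbed set, i.e. no masking effect)
#' @param mask an [override_mask()] (default: all currents perturbed)
#' @param stim stimulus current, pA/pF (positive = depolarising)
#' @return list with `deriv` (named state derivative, per ms), `currents`
#'   (named, pA/pF) and `total_current` (their sum)
#' @export
crn_derivatives <- function(state, params = crn_parameters(),
                            perturbed = electrolyte_reference(),
                            reference = perturbed,
                            mask = override_mask(), stim = 0) {
  out <- .crn_rhs_cpp(.as_state(state), .as_params(params),
                      .as_elec(perturbed), .as_elec(reference),
                      .as_mask(mask), stim)
  names(out$deriv) <- .STATE_NAMES
  names(out$currents) <- current_names()
  bad <- !is.finite(c(out$deriv, out$currents))
  if (any(bad)) {
    badcur <- current_names()[!is.finite(out$currents)]
    stop("non-finite rate/current in CRN++ evaluation",
         if (length(badcur)) paste0(" (currents: ",
                                    paste(badcur, collapse = ", "), ")"))
  }
  out
}

#' Apply fibrosis remodelling to a parameter set
#'
#' Fibrotic atrial tissue is modelled by down-regulating three maximal
#' conductances: GNa by 40%, GK1 by 50% and GCaL by 50%. The remodelling is
#' apply-once: the returned set is flagged `fibrotic` and re-application is an
#' error.
#'
#' @param params a non-fibrotic [crn_parameters()]
#' @return remodelled `crn_parameters` with `fibrotic = 1`
#' @export
apply_fibrosis_remodelling <- function(params) {
  p <- unclass(params)
  if (p[["fibrotic"]] != 0)
    stop("fibrosis remodelling already applied (apply-once semantics)")
  p[["gNa"]] <- p[["gNa"]] * 0.60
  p[["gK1"]] <- p[["gK1"]] * 0.50
  p[["gCaL"]] <- p[["gCaL"]] * 0.50
  p[["fibrotic"]] <- 1
  structure(p, class = "crn_parameters")
}
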