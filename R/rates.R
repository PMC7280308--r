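# Elementary rate laws. All reaction kinetics in the pathway model reduce to
# these four forms; enzyme_level is the relative functional level of the
# catalysing enzyme (baseline 1), so the effective Vmax of a reaction is the
# reference Vmax times the current enzyme level.

#' Irreversible Michaelis-Menten rate
#'
#' Saturable single-substrate rate law `v = E * Vmax * S / (Km + S)`, the
#' kinetic basis of every enzymatic conversion in the pathway model. The
#' enzyme level `E` is a dimensionless relative level (baseline 1) so that
#' HIF-1 induced changes in enzyme amount rescale the capacity of the step
#' linearly.
#'
#' @param Vmax maximal rate at baseline enzyme level (mM/min), >= 0.
#' @param S substrate concentration (mM), >= 0.
#' @param Km Michaelis constant (mM), strictly positive.
#' @param enzyme_level relative enzyme level (dimensionless), >= 0.
#' @return rate in mM/min, within `[0, enzyme_level * Vmax]`.
#' @examples
#' mm_rate(Vmax = 2, S = 0.1, Km = 0.1)        # half saturation: Vmax/2
#' mm_rate(2, 0.1, 0.1, enzyme_level = 1.5)    # linear in enzyme level
#' @export
mm_rate <- function(Vmax, S, Km, enzyme_level = 1) {
  if (any(Km <= 0)) {
    stop("parameter-domain error: Km must be > 0", call. = FALSE)
  }
  if (any(Vmax < 0) || any(S < 0) || any(enzyme_level < 0)) {
    stop("parameter-domain error: Vmax, S and enzyme_level must be >= 0",
         call. = FALSE)
  }
  enzyme_level * Vmax * S / (Km + S)
}

#' Reversible Michaelis-Menten rate
#'
#' One-substrate/one-product reversible rate law
#' `v = E * (Vf*S/Ks - Vr*P/Kp) / (1 + S/Ks + P/Kp)`.
#' The sign of the returned value encodes the net direction (positive:
#' substrate to product). Used for the bidirectional steps of the pathway
#' (transport, isomerases, mutases, the lower glycolytic chain and lactate
#' dehydrogenase).
#'
#' @param Vf,Vr forward and reverse limiting rates at baseline enzyme level
#'   (mM/min), >= 0.
#' @param Ks,Kp substrate- and product-side half-saturation constants (mM),
#'   strictly positive.
#' @param S,P substrate and product concentrations (mM), >= 0.
#' @param enzyme_level relative enzyme level (dimensionless), >= 0.
#' @return signed net rate in mM/min.
#' @examples
#' reversible_mm_rate(Vf = 1, Ks = 1, Vr = 1, Kp = 1, S = 2, P = 1)  # 0.25
#' @export
reversible_mm_rate <- function(Vf, Ks, Vr, Kp, S, P, enzyme_level = 1) {
  if (any(Ks <= 0) || any(Kp <= 0)) {
    stop("parameter-domain error: Ks and Kp must be > 0", call. = FALSE)
  }
  if (any(Vf < 0) || any(Vr < 0) || any(S < 0) || any(P < 0) ||
      any(enzyme_level < 0)) {
    stop("parameter-domain error: rates, concentrations and enzyme_level ",
         "must be >= 0", call. = FALSE)
  }
  enzyme_level * (Vf * S / Ks - Vr * P / Kp) / (1 + S / Ks + P / Kp)
}

#' HIF-1 coupling of an enzyme level
#'
#' Constructs the mass-action coupling between the HIF-1 concentration and
#' the rate of change of a specific enzyme's relative level:
#' `dE/dt = sign * K_Eh * [HIF-1]`. Under constant HIF-1 forcing the enzyme
#' level therefore ramps linearly, `E(t) = E(0) + sign * K_Eh * hif * t`.
#'
#' @param enzyme_id id of the enzyme species whose level is driven.
#' @param K_Eh induction constant in level/(uM*min), >= 0.
#' @param sign `+1` (HIF-1 induces the enzyme) or `-1` (represses).
#' @return an object of class `hif_coupling`.
#' @export
hif_coupling <- function(enzyme_id, K_Eh, sign = 1) {
  stopifnot(is.character(enzyme_id), length(enzyme_id) == 1L)
  if (!is.numeric(K_Eh) || length(K_Eh) != 1L || is.na(K_Eh) || K_Eh < 0) {
    stop("parameter-domain error: K_Eh must be a single number >= 0",
         call. = FALSE)
  }
  if (!sign %in% c(-1, 1)) {
    stop("parameter-domain error: sign must be +1 or -1", call. = FALSE)
  }
  structure(list(enzyme_id = enzyme_id, K_Eh = K_Eh, sign = sign),
            class = "hif_coupling")
}

#' Enzyme-level drift induced by HIF-1
#'
#' Evaluates the mass-action contribution `sign * K_Eh * hif` of a HIF-1
#' coupling to the ODE of the coupled enzyme's relative level.
#'
#' @param coupling a [hif_coupling()] object.
#' @param hif HIF-1 concentration (uM), >= 0.
#' @return drift in level/min.
#' @examples
#' hif_enzyme_drift(hif_coupling("LDH", K_Eh = 0.02), hif = 1)  # 0.02
#' @export
hif_enzyme_drift <- function(coupling, hif) {
  stopifnot(inherits(coupling, "hif_coupling"))
  if (!is.numeric(hif) || any(is.na(hif)) || any(hif < 0)) {
    stop("input-domain error: hif must be >= 0", call. = FALSE)
  }
  coupling$sign * coupling$K_Eh * hif
}
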