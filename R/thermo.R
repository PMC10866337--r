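#' Transition-state-theory conversions for kinetic solvent effects
#'
#' Conversions between solvation free energies of activation
#' (\eqn{\Delta\Delta G^\ddagger_{solv}}, kcal/mol) and relative rate
#' constants, plus the linear temperature extrapolation and the
#' Gibbs--Helmholtz finite-difference enthalpy estimator used to derive
#' \eqn{\Delta\Delta H^\ddagger_{solv}} from free energies at 297/298/299 K.
#'
#' Sign convention: a positive \eqn{\Delta\Delta G^\ddagger_{solv}} means the
#' transition state is destabilised by solvation relative to the reactants, so
#' the liquid-phase rate constant is smaller than the gas-phase one
#' (\code{log10RateRatioLiqGas} is then negative).
#'
#' @param R gas constant in kcal/(mol K).
#' @param T0 reference temperature in K.
#' @param T working temperature in K.
#' @return \code{thermoContext} returns a list with elements \code{R},
#'   \code{T0} and \code{T}.
#' @examples
#' ctx <- thermoContext()
#' log10RateRatioLiqGas(1.364, ctx)   # about -1 log10 unit
#' @export
thermoContext <- function(R = 1.98720425864083e-3, T0 = 298.0, T = 298.0) {
  if (!is.numeric(T) || T <= 0) stopUsage("temperature must be positive")
  list(R = R, T0 = T0, T = T)
}

#' Activation solvation energy from transition-state and reactant values
#'
#' The solvation free energy (or enthalpy) of activation is the difference
#' between the solvation energy of the transition state and the sum over all
#' reactants (for a bimolecular reaction the reactant term is the sum of both
#' reactants' solvation energies).
#'
#' @param dG_TS solvation free energy of the transition state (kcal/mol).
#' @param dG_reactants numeric vector of reactant solvation free energies,
#'   one entry per reactant (kcal/mol).
#' @return \eqn{\Delta\Delta G^\ddagger_{solv}} in kcal/mol.
#' @examples
#' ddGActivation(-5, c(-2, -3))  # 0
#' @export
ddGActivation <- function(dG_TS, dG_reactants) {
  if (length(dG_reactants) < 1L) stopUsage("at least one reactant required")
  dG_TS - sum(dG_reactants)
}

#' @rdname ddGActivation
#' @param dH_TS,dH_reactants enthalpy analogues of the free-energy arguments.
#' @export
ddHActivation <- function(dH_TS, dH_reactants) {
  if (length(dH_reactants) < 1L) stopUsage("at least one reactant required")
  dH_TS - sum(dH_reactants)
}

#' kcal/mol equivalent of one log10 unit of a rate ratio
#'
#' @param ctx a [thermoContext()].
#' @return \eqn{R T \ln 10} in kcal/mol per log10 unit (1.3636 at 298 K).
#' @export
kcalPerLog10 <- function(ctx = thermoContext()) {
  ctx$R * ctx$T * log(10)
}

#' Liquid/gas rate-constant ratio implied by an activation solvation energy
#'
#' Transition-state theory gives
#' \eqn{\log_{10}(k_{liq}/k_{gas}) = -\Delta\Delta G^\ddagger_{solv}/(RT\ln 10)}.
#' A \eqn{\Delta\Delta G^\ddagger_{solv}} of 40 kcal/mol at 298 K corresponds
#' to about 29 orders of magnitude; 10 kcal/mol to about 7.
#'
#' @param ddG activation solvation free energy in kcal/mol (vectorised).
#' @param ctx a [thermoContext()].
#' @return \eqn{\log_{10}(k_{liq}/k_{gas})}.
#' @export
log10RateRatioLiqGas <- function(ddG, ctx = thermoContext()) {
  -ddG / kcalPerLog10(ctx)
}

#' Relative rate constant between two solvents
#'
#' @param ddG1,ddG2 activation solvation free energies (kcal/mol) of the same
#'   reaction in solvent 1 and solvent 2.
#' @param ctx a [thermoContext()].
#' @return \eqn{\log_{10}(k^{s1}_{liq}/k^{s2}_{liq})}.
#' @export
log10RateRatioTwoSolvents <- function(ddG1, ddG2, ctx = thermoContext()) {
  -(ddG1 - ddG2) / kcalPerLog10(ctx)
}

#' Linear temperature extrapolation of the activation solvation free energy
#'
#' Assumes temperature-independent \eqn{\Delta\Delta H} and
#' \eqn{\Delta\Delta S} between roughly 250 and 400 K:
#' \deqn{\Delta\Delta G(T) = \Delta\Delta H_{298} -
#'   T\,(\Delta\Delta H_{298} - \Delta\Delta G_{298})/T_0.}
#' Outside 250--400 K a warning is issued (the linear form degrades there)
#' but the value is still returned.
#'
#' @param ddG298,ddH298 model outputs at 298 K (kcal/mol).
#' @param T target temperature in K.
#' @param ctx a [thermoContext()]; its \code{T0} is the reference temperature.
#' @return \eqn{\Delta\Delta G^\ddagger_{solv}(T)} in kcal/mol.
#' @export
extrapolateDdG <- function(ddG298, ddH298, T, ctx = thermoContext()) {
  if (any(T <= 0)) stopUsage("temperature must be positive")
  if (any(T < 250 | T > 400))
    warning("temperature outside the moderate range (250-400 K); ",
            "linear extrapolation may be inaccurate")
  ddH298 - T * (ddH298 - ddG298) / ctx$T0
}

#' Enthalpy of activation from a finite-difference temperature gradient
#'
#' Gibbs--Helmholtz estimator used when only free energies are available:
#' evaluate \eqn{\Delta\Delta G} at \eqn{T-1}, \eqn{T} and \eqn{T+1} K,
#' estimate the gradient by central difference, and use
#' \eqn{\Delta\Delta H = \Delta\Delta G(T) - T\,\partial\Delta\Delta G/\partial T}.
#' Exact whenever \eqn{\Delta\Delta G} is linear in \eqn{T}.
#'
#' @param ddG_Tm1,ddG_T,ddG_Tp1 free energies at \eqn{T-1}, \eqn{T},
#'   \eqn{T+1} K (kcal/mol).
#' @param T centre temperature in K.
#' @param ctx a [thermoContext()] (unused numerically; kept for interface
#'   symmetry).
#' @return \eqn{\Delta\Delta H^\ddagger_{solv}} in kcal/mol.
#' @export
ddHFromGradient <- function(ddG_Tm1, ddG_T, ddG_Tp1, T = 298,
                            ctx = thermoContext()) {
  ddG_T - T * (ddG_Tp1 - ddG_Tm1) / 2
}

#' Free-energy equivalent of the error between two relative rate constants
#'
#' \deqn{\Delta G^\ddagger_{rel}\ error =
#'   -RT(\ln k_{rel,expt} - \ln k_{rel,calc})}
#'
#' @param k_rel_expt,k_rel_calc experimental and calculated relative rate
#'   constants (both must be positive).
#' @param T temperature in K.
#' @param ctx a [thermoContext()].
#' @return error in kcal/mol.
#' @export
dGRelError <- function(k_rel_expt, k_rel_calc, T = 298, ctx = thermoContext()) {
  if (any(k_rel_expt <= 0) || any(k_rel_calc <= 0))
    stopUsage("rate ratios must be positive")
  -ctx$R * T * (log(k_rel_expt) - log(k_rel_calc))
}
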