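#' Growth rates adjusted for oxygen and caloric forcings
#'
#' Multiplies each group's intrinsic growth rate by a linear modulation of
#' the current oxygen level and the caloric intakes from HMOs and PDPs,
#' weighted by the group's metabolic preferences:
#' `lambda_adj = (1 + O2 phi_O2 + HMOs phi_HMO + PDPs phi_PDP) * lambda`.
#'
#' @param params A [default_params()] object.
#' @param O2,HMOs,PDPs Scalar forcings (`>= 0` for the caloric terms; `O2`
#'   in `[0, 1]`).
#' @return Named per-taxon vector of adjusted growth rates (1/day).
#' @export
adjusted_growth <- function(params, O2, HMOs, PDPs) {
  if (HMOs < 0 || PDPs < 0) stop("forcings must be >= 0", call. = FALSE)
  (1 + O2 * params$phi_O2 + HMOs * params$phi_HMO + PDPs * params$phi_PDP) *
    params$lambda
}

#' Microenvironmental stimulation
#'
#' The composite inflammatory-tone variable: unmasked (uncoated) bacteria
#' stimulate the epithelium in proportion to their immunostimulatory capacity
#' `kappa`, while taxa with inherent anti-inflammatory potential (`I = 1`)
#' reduce the tone in proportion to their total active abundance:
#' `sigma = sum_i kappa_i y_uc_i - sum_i I_i (y_uc_i + y_m_i)`. May be
#' negative in a net anti-inflammatory community.
#'
#' @param y_uc,y_m Per-taxon uncoated and masked abundances.
#' @param params A [default_params()] object.
#' @return Scalar stimulation value.
#' @export
microenv_stimulation <- function(y_uc, y_m, params) {
  sum(params$kappa * y_uc) - sum(params$I_anti * (y_uc + y_m))
}

# clamped inflammatory drive used by the selection-threshold dynamics;
# net anti-inflammatory environments contribute no drive
log_sigma_drive <- function(sigma, tau_s) {
  x <- 1 + tau_s * sigma
  if (x <= 0) return(0)
  max(log(x), 0)
}

# State-vector layout for the continuous subsystem (N = 4 taxa):
#   [1] mSIgA, [2] O2, then per-taxon blocks of length N:
#   y_uc, y_m, y_sn (cumulative neutralized), eSIgA, zS_uc, zS, Bn, Anew, delta
.state_index <- function(N = 4) {
  nm <- c("y_uc", "y_m", "y_sn", "eSIgA", "zS_uc", "zS", "Bn", "Anew", "delta")
  idx <- list(mSIgA = 1L, O2 = 2L)
  for (k in seq_along(nm)) idx[[nm[k]]] <- 2L + (k - 1L) * N + seq_len(N)
  idx
}

#' Right-hand side of the continuous subsystem
#'
#' Time-derivatives of the coupled community/humoral/threshold states:
#' generalized Lotka-Volterra growth with metabolic modulation, SIgA
#' masking/uncoating exchange and neutralization loss, oxygen depletion by
#' facultative anaerobes, maternal and endogenous SIgA concentration
#' kinetics, naive B-cell influx and activation, cumulative antigen-sampling
#' counters, and the selection-threshold drive. Used by the simulator via
#' `deSolve`; exposed for direct testing.
#'
#' @param t Time (day).
#' @param state Numeric state vector (see source for layout).
#' @param parms A [default_params()] object (named `parms` per the deSolve
#'   calling convention).
#' @param sched A [feeding_schedule()].
#' @param rho_p Per-taxon plasma mean affinities (held fixed within a
#'   germinal-center update interval).
#' @param active Logical; whether antigenic sampling has begun (`t >= t_m`).
#' @param msiga_on Logical; whether breastmilk carries SIgA.
#' @return List with the derivative vector (deSolve convention).
#' @export
community_rhs <- function(t, state, parms, sched, rho_p, active = FALSE,
                          msiga_on = TRUE) {
  params <- parms
  ix <- .state_index(length(params$taxa))
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  y_uc <- pmax(state[ix$y_uc], 0)
  y_m  <- pmax(state[ix$y_m], 0)
  eS   <- pmax(state[ix$eSIgA], 0)
  mS   <- max(state[ix$mSIgA], 0)
  O2   <- min(max(state[ix$O2], 0), 1)

  fd <- feeding_point(t, sched)
  yL <- y_uc + y_m
  lam <- (1 + O2 * params$phi_O2 + fd$HMOs * params$phi_HMO +
            fd$PDPs * params$phi_PDP) * params$lambda
  inter <- drop(params$beta %*% yL)

  mat <- siga_rates(params$rho_m, params$rd)
  end <- siga_rates(rho_p, params$rd)
  mask_coef <- mS * mat$omega * mat$mu_m + eS * end$omega * end$mu_m
  neut_coef <- mS * mat$omega * mat$mu_n + eS * end$omega * end$mu_n

  neut_flux <- neut_coef * y_uc
  dyL <- yL * (lam + inter) - neut_flux
  uncoat <- (1 / params$I_hl) * y_m
  mask_flux <- mask_coef * y_uc

  d <- numeric(length(state))
  d[ix$y_uc] <- dyL + uncoat - mask_flux
  d[ix$y_m]  <- -uncoat + mask_flux
  d[ix$y_sn] <- neut_flux
  d[ix$O2]   <- -params$mu_O2 * O2 * sum(yL[params$facultative])
  d[ix$mSIgA] <- (if (msiga_on) msiga_influx(t, sched) else 0) -
    params$I_hl * mS

  # endogenous SIgA per taxon, secreted by its plasma pool Bp (attached to
  # rho_p's companion attribute), logistic in concentration with capacity 1
  Bp <- attr(rho_p, "Bp")
  if (is.null(Bp)) Bp <- rep(0, length(rho_p))
  d[ix$eSIgA] <- params$C_I * Bp * (1 - (1 - params$I_hl / params$C_I) * eS) -
    params$I_hl * eS

  gc <- params$gc
  if (active) {
    sigma <- sum(params$kappa * y_uc) - sum(params$I_anti * yL)
    z_uc <- pmax(sigma, 0) * params$alpha * gc$eps_uc * y_uc
    z_m  <- gc$eps_m * y_m
    psi  <- gc$psi_m * z_m + gc$psi_uc * z_uc
    d[ix$zS_uc] <- z_uc
    d[ix$zS]    <- z_uc + z_m
    d[ix$Bn]    <- gc$C_B * exp(-gc$c_B * t) - psi * state[ix$Bn]
    d[ix$Anew]  <- psi * state[ix$Bn]
    # floored denominator: with too few cumulative samples there is no bias
    # information yet, and an unfloored quotient of two near-zero counters
    # makes the numerical Jacobian blow up like 1/zS
    ratio <- pmax(state[ix$zS_uc], 0) / pmax(state[ix$zS], gc$z_floor)
    ratio <- pmin(pmax(ratio, 0), 1)
    d[ix$delta] <- gc$tau_delta * gc$C_T * exp(-gc$c_T * t) *
      log_sigma_drive(sigma, tau_sigma(params)) * log1p(ratio)
  } else {
    d[ix$Bn] <- gc$C_B * exp(-gc$c_B * t)
    # zS_uc, zS, Anew, delta stay at zero before activation
  }
  list(d)
}

# scalar-time feeding forcings, avoiding data.frame overhead in the RHS
feeding_point <- function(t, sched) {
  H <- hmo_intake(t, sched)
  f <- total_intake(t, sched)
  P <- if (t < sched$t_MF) 0 else max(f - H, 0)
  list(HMOs = H, PDPs = P, fTOT = f)
}
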