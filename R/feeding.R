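#' Default exogenous-forcing constants
#'
#' Constants of the caloric and maternal-antibody forcing functions. Caloric
#' curves are dimensionless (normalized so the steady-phase total intake is
#' ~1); times are days of life. `K_H1` is the human-milk-oligosaccharide
#' (HMO) intake at birth, `V_0` and `c_H` shape its saturating rise over the
#' exclusive-breastfeeding (EBF) period; `K_C`, `c_C`, `t_C` shape the
#' logistic rise of the total intake to its steady value reached at `t_C`;
#' `t_MF_ref`/`T_MF_ref` are the fitting cohort's feeding durations (154 days
#' EBF, 308 days mixed feeding (MF)); `K_I`, `m_I`, `c_I` parameterize the
#' maternal-SIgA influx per unit milk volume, which peaks in early milk
#' (colostrum) and decays to the mature-milk rate; `I_hl` is the luminal SIgA
#' turnover rate. `K_C` is tied to the EBF curve so the total intake is
#' continuous at the reference weaning day; `K_I`, `m_I` and `I_hl` are
#' calibrated so that under the reference schedule the luminal maternal-SIgA
#' concentration peaks at ~1 and falls below half-peak at day of life 129.
#'
#' @return Named list of forcing constants.
#' @export
forcing_constants <- function() {
  cst <- list(
    K_H1 = 0.30, V_0 = 0.20, c_H = 0.10,
    c_C = 0.02, t_C = 462,
    t_MF_ref = 154, T_MF_ref = 308,
    K_I = 0.996442, m_I = 2.121580, c_I = 0.05,
    I_hl = 1.0
  )
  # total-intake saturation level making fTOT continuous at the reference
  # weaning day: K_C / 2 = K_H1 + V_0 (1 - exp(-c_H * t_MF_ref))
  cst$K_C <- 2 * (cst$K_H1 + cst$V_0 * (1 - exp(-cst$c_H * cst$t_MF_ref)))
  cst
}

#' Construct a feeding schedule
#'
#' A feeding schedule fixes the durations of exclusive breastfeeding (EBF)
#' and mixed feeding (MF); exclusive complementary feeding (ECF) follows MF.
#' Together with the forcing constants it determines the caloric forcings
#' (HMOs, plant-derived polysaccharides (PDPs), total) and the maternal SIgA
#' influx at any day of life.
#'
#' @param T_EBF EBF duration in days (`>= 0`). MF starts at `t_MF = T_EBF`.
#' @param T_MF MF duration in days (`>= 0`).
#' @param constants Forcing constants, see [forcing_constants()].
#' @return An object of class `"feeding_schedule"`.
#' @export
feeding_schedule <- function(T_EBF = 154, T_MF = 308,
                             constants = forcing_constants()) {
  if (T_EBF < 0 || T_MF < 0) stop("feeding durations must be >= 0", call. = FALSE)
  sched <- c(list(T_EBF = T_EBF, T_MF = T_MF, t_MF = T_EBF), constants)
  # HMO level entering MF; the MF branch decays from this value to 0
  if (T_EBF > 0) {
    sched$K_H2 <- (sched$K_H1 + sched$V_0 * (1 - exp(-sched$c_H * T_EBF))) /
      (1 - exp(-sched$c_H * T_EBF))
  } else {
    sched$K_H2 <- 0 # no breastfeeding: HMOs identically zero
  }
  structure(sched, class = "feeding_schedule")
}

#' @export
print.feeding_schedule <- function(x, ...) {
  cat(sprintf("Feeding schedule: EBF %g d, MF %g d (ECF from day %g)\n",
              x$T_EBF, x$T_MF, x$t_MF + x$T_MF))
  invisible(x)
}

#' Caloric forcing functions of a feeding schedule
#'
#' Evaluates, at days `t`, the caloric intake derived from human milk
#' oligosaccharides (HMOs), from plant-derived polysaccharides (PDPs), and in
#' total. HMOs rise with milk volume during EBF, then taper to zero over the
#' MF window via a mirrored time axis, reaching exactly zero when ECF starts;
#' PDPs are the complement of HMOs within the total once MF starts. The total
#' intake follows the fitting cohort's reference schedule regardless of the
#' simulated one, encoding the assumption that the infant's caloric
#' requirement is always met.
#'
#' @param t Day(s) of life, `>= 0`. Vectorized.
#' @param sched A [feeding_schedule()].
#' @return A data frame with columns `t`, `HMOs`, `PDPs`, `fTOT`.
#' @export
feeding_inputs <- function(t, sched) {
  stopifnot(inherits(sched, "feeding_schedule"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  HMOs <- hmo_intake(t, sched)
  fTOT <- total_intake(t, sched)
  PDPs <- ifelse(t < sched$t_MF, 0, pmax(fTOT - HMOs, 0))
  data.frame(t = t, HMOs = HMOs, PDPs = PDPs, fTOT = fTOT)
}

hmo_intake <- function(t, sched) {
  if (sched$T_EBF <= 0) return(rep(0, length(t)))
  out <- numeric(length(t))
  ebf <- t < sched$t_MF
  out[ebf] <- sched$K_H1 + sched$V_0 * (1 - exp(-sched$c_H * t[ebf]))
  mf <- !ebf
  if (any(mf)) {
    if (sched$T_MF > 0) {
      t_mirror <- sched$t_MF * (sched$T_MF - (t[mf] - sched$t_MF)) / sched$T_MF
      t_mirror <- pmax(t_mirror, 0) # zero beyond the switch to ECF
      out[mf] <- sched$K_H2 * (1 - exp(-sched$c_H * t_mirror))
    } else {
      out[mf] <- 0 # abrupt EBF -> ECF transition
    }
  }
  out
}

total_intake <- function(t, sched) {
  # defined on the reference schedule (t_MF_ref, T_MF_ref), not the simulated one
  ref <- sched
  ref$T_EBF <- ref$t_MF <- ref$t_MF_ref
  ref$T_MF <- ref$T_MF_ref
  out <- numeric(length(t))
  pre <- t < sched$t_MF_ref
  out[pre] <- sched$K_H1 + sched$V_0 * (1 - exp(-sched$c_H * t[pre]))
  mid <- !pre
  tt <- pmin(t[mid], sched$t_C) # logistic frozen at its t_C value thereafter
  out[mid] <- sched$K_C / (1 + exp(-sched$c_C * (tt - sched$t_MF_ref)))
  out
}

#' Maternal SIgA influx into the gut lumen
#'
#' The influx rate of maternal SIgA is the per-volume milk antibody content
#' `K_I + m_I exp(-c_I t)` (peaking in colostrum, decaying to the mature-milk
#' rate) scaled by `HMOs(t)`, which proxies the milk volume ingested. Zero
#' whenever no milk is consumed.
#'
#' @param t Day(s) of life. Vectorized.
#' @param sched A [feeding_schedule()].
#' @return Numeric vector of influx rates (`>= 0`).
#' @export
msiga_influx <- function(t, sched) {
  stopifnot(inherits(sched, "feeding_schedule"))
  hmo_intake(t, sched) * (sched$K_I + sched$m_I * exp(-sched$c_I * t))
}

#' Luminal maternal-SIgA concentration trajectory
#'
#' Integrates `d mSIgA/dt = HMOs(t) * influx_rate(t) - I_hl * mSIgA` on a
#' daily grid (closed-form exponential update with the influx held constant
#' within each sub-step).
#'
#' @param sched A [feeding_schedule()].
#' @param horizon Final day.
#' @param dt Integration sub-step in days.
#' @return Data frame with columns `t`, `mSIgA`.
#' @keywords internal
msiga_trajectory <- function(sched, horizon = 735, dt = 0.25) {
  times <- seq(0, horizon, by = dt)
  n <- length(times)
  m <- numeric(n)
  infl <- msiga_influx(times, sched)
  decay <- exp(-sched$I_hl * dt)
  for (k in seq_len(n - 1L)) {
    # exact update for constant influx over the sub-step
    m[k + 1L] <- m[k] * decay + infl[k] / sched$I_hl * (1 - decay)
  }
  data.frame(t = times, mSIgA = m)
}

#' Immune activation (M-cell opening) time
#'
#' Antigenic sampling through M cells begins once maternal factors wane.
#' `t50` is the first day the luminal maternal-SIgA concentration falls below
#' half of its peak; the activation day is `t_m = max(t50, 30)`, reflecting
#' that formula-fed infants start producing intestinal SIgA around four weeks
#' of age. With no breastmilk at all, `t50 = 0` and `t_m = 30`.
#'
#' @param sched A [feeding_schedule()].
#' @param horizon Simulation horizon in days.
#' @param rule Activation rule, a function of `t50` returning `t_m`; the
#'   default is `max(t50, 30)`.
#' @return A list with `t50` and `t_m` (days).
#' @export
immune_activation_time <- function(sched, horizon = 735,
                                   rule = function(t50) max(t50, 30)) {
  stopifnot(inherits(sched, "feeding_schedule"))
  traj <- msiga_trajectory(sched, horizon)
  peak <- max(traj$mSIgA)
  if (peak <= 0) {
    t50 <- 0
  } else {
    peak_at <- which.max(traj$mSIgA)
    below <- which(traj$mSIgA < 0.5 * peak & seq_along(traj$mSIgA) > peak_at)
    if (!length(below))
      stop("maternal SIgA never falls below half-peak within the horizon",
           call. = FALSE)
    t50 <- traj$t[below[1L]]
  }
  list(t50 = t50, t_m = rule(t50))
}
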