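#' Antigen uptake through M cells
#'
#' Per-taxon antigen transport into the gut-associated lymphoid tissue.
#' Uncoated antigens are sampled at rate `eps_uc`, gated by the (nonnegative
#' part of the) microenvironmental stimulation and the taxon's invasiveness;
#' masked (SIgA-bound) antigens are sampled consistently at the higher rate
#' `eps_m`, reflecting the M cells' affinity for IgA complexes. The B-cell
#' activation rate is the linear combination `psi = psi_m z_m + psi_uc z_uc`
#' with `psi_uc > psi_m` (uncoated antigens are more inflammatory and recruit
#' more strongly).
#'
#' @param y_uc,y_m Per-taxon uncoated and masked abundances.
#' @param sigma Microenvironmental stimulation (may be negative; its
#'   negative part does not drive uncoated sampling).
#' @param params A [default_params()] object.
#' @param active Logical; `FALSE` before the M-cell opening time returns all
#'   zeros.
#' @return List with per-taxon vectors `z_uc`, `z_m`, `psi`.
#' @export
antigen_uptake <- function(y_uc, y_m, sigma, params, active = TRUE) {
  n <- length(params$taxa)
  if (!active) {
    z <- stats::setNames(numeric(n), params$taxa)
    return(list(z_uc = z, z_m = z, psi = z))
  }
  gc <- params$gc
  z_uc <- max(sigma, 0) * params$alpha * gc$eps_uc * y_uc
  z_m  <- gc$eps_m * y_m
  list(z_uc = z_uc, z_m = z_m, psi = gc$psi_m * z_m + gc$psi_uc * z_uc)
}

#' Selection-threshold growth rate
#'
#' The rate of change of the per-taxon selection threshold `delta`, a proxy
#' for the follicular-helper:regulatory T-cell balance. It is the product of
#' a gain, the waning naive T-cell supply `C_T exp(-c_T t)`, the clamped
#' inflammatory drive `log(1 + tau_s * sigma)`, and the cumulative-sampling
#' bias `log(1 + zS_uc / zS)` (the share of sampled antigen that arrived
#' uncoated). Nonnegative by construction, so `delta` never decreases.
#'
#' @param t Day of life.
#' @param sigma Microenvironmental stimulation.
#' @param zS_uc,zS Cumulative uncoated and total sampled antigen
#'   (`0 <= zS_uc <= zS`).
#' @param params A [default_params()] object.
#' @param tau_s Stimulation normalizer, see [tau_sigma()].
#' @return Per-taxon nonnegative rate(s).
#' @export
delta_increment <- function(t, sigma, zS_uc, zS, params,
                            tau_s = tau_sigma(params)) {
  ratio <- pmin(pmax(pmax(zS_uc, 0) / pmax(zS, params$gc$z_floor), 0), 1)
  params$gc$tau_delta * params$gc$C_T * exp(-params$gc$c_T * t) *
    log_sigma_drive(sigma, tau_s) * log1p(ratio)
}

#' Plasma-cell death rate from the selection-threshold history
#'
#' Plasma cells exported while the selection threshold was still rising are
#' short-lived; once the threshold stabilizes the death rate vanishes:
#' `mu_p = 1 - delta(t - 1) / delta(t)`, clamped to `[0, 1]`, and 0 before
#' any threshold has accumulated.
#'
#' @param delta_prev,delta_now Threshold one update interval ago and now.
#' @return Per-taxon death rate(s) in `[0, 1]`.
#' @export
plasma_death_rate <- function(delta_prev, delta_now) {
  out <- ifelse(delta_now > 0, 1 - delta_prev / delta_now, 0)
  pmin(pmax(out, 0), 1)
}

# normal CDF with a point-mass limit at sd = 0; broadcasts all arguments
.phi <- function(q, mean, sd) {
  n <- max(length(q), length(mean), length(sd))
  q <- rep_len(q, n); mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  ifelse(sd > 0, stats::pnorm(q, mean, sd), as.numeric(q >= mean))
}

#' Four-fate partition of the circulating B-cell pool
#'
#' Splits a normally distributed B-cell-receptor affinity pool at the three
#' selection boundaries `th_apop * delta < th_high * delta < th_ang * delta`
#' into apoptotic (insufficient T-cell help), recirculating (continues to
#' the next proliferation/hypermutation round), plasma-fated (terminal
#' differentiation) and anergic (negatively selected) fractions. Fractions
#' sum to one; a zero-spread pool is treated as a point mass.
#'
#' @param rho_c,sig_c Mean and spread of the circulating affinity pool.
#' @param delta Selection threshold(s).
#' @param gc Germinal-center parameter sublist (see [default_params()]).
#' @return List of per-taxon fractions `apoptotic`, `recirculating`,
#'   `plasma`, `anergic`.
#' @export
fate_fractions <- function(rho_c, sig_c, delta, gc) {
  p_ap  <- .phi(gc$th_apop * delta, rho_c, sig_c)
  p_hi  <- .phi(gc$th_high * delta, rho_c, sig_c)
  p_ang <- .phi(gc$th_ang  * delta, rho_c, sig_c)
  list(apoptotic = p_ap, recirculating = p_hi - p_ap,
       plasma = p_ang - p_hi, anergic = 1 - p_ang)
}

#' One germinal-center proliferation--hypermutation--selection cycle
#'
#' Deterministic moment propagation of the per-taxon germinal-center state
#' over one update interval: (i) partition the circulating pool into the
#' four fates; (ii) reset the recirculating cells to the selection window's
#' midpoint mean and one-sixth-width spread (the normal re-approximation of
#' the truncated pool); (iii) proliferate them by `(1 + r_p)` and widen the
#' spread by the hypermutation term `tau_c |delta_now - rho_c|`; (iv) pool
#' with the newly activated cells (mean 0, spread `tau_new * n_new`) by
#' size-weighted mean and spread; (v) add the plasma-fated cells to the
#' plasma pool with logistic saturation at capacity 1, update the plasma
#' mean affinity by size-weighted pooling with incoming cells at affinity
#' `0.5 (th_ang + th_high) delta`, and apply the history-dependent plasma
#' death rate.
#'
#' @param st List with per-taxon vectors `Bc`, `rho_c`, `sig_c`, `Bp`,
#'   `rho_p`.
#' @param newcomers Per-taxon newly activated cell counts for this interval.
#' @param delta_now,delta_prev Selection threshold at the end of this and
#'   the previous interval.
#' @param params A [default_params()] object.
#' @return Updated state list (same shape as `st`).
#' @export
gc_cycle_update <- function(st, newcomers, delta_now, delta_prev, params) {
  gc <- params$gc
  f <- fate_fractions(st$rho_c, st$sig_c, delta_now, gc)
  n_sel    <- st$Bc * f$recirculating
  n_plasma <- st$Bc * f$plasma

  # survivors: truncated-to-normal re-approximation, proliferation, SHM
  m0  <- 0.5 * (gc$th_apop + gc$th_high) * delta_now
  sd0 <- (1 / 6) * (gc$th_high - gc$th_apop) * delta_now
  n_circ <- n_sel * (1 + gc$r_p)
  sd1 <- sd0 + gc$tau_c * abs(delta_now - st$rho_c)

  # floored spread: naive cohorts carry wide receptor diversity regardless
  # of their size, so the spread never falls below an absolute floor nor
  # below a fixed fraction of the current selection window; an unfloored
  # spread makes the reaction collapse irreversibly the moment the
  # threshold outruns a tiny founding pool
  sd_new <- pmax(gc$tau_new * newcomers, gc$sig_new_floor,
                 gc$found_frac * delta_now)
  Bc2 <- n_circ + newcomers
  # finite follicular niche: proportional down-scaling leaves moments intact
  scale <- ifelse(Bc2 > gc$B_max, gc$B_max / Bc2, 1)
  n_circ <- n_circ * scale
  newcomers <- newcomers * scale
  Bc2 <- n_circ + newcomers
  rho_c2 <- ifelse(Bc2 > 0, (n_circ * m0 + newcomers * 0) / Bc2, 0)
  sig_c2 <- ifelse(Bc2 > 0, (n_circ * sd1 + newcomers * sd_new) / Bc2, 0)

  # plasma pool: the carrying capacity of the lamina propria saturates the
  # pool *size* at 1, but differentiation continues and incoming cells keep
  # replacing resident ones, so the pool *mean* is pooled with the full
  # plasma-fated cohort
  w_in <- pmin(n_plasma, 1)
  inflow <- w_in * (1 - st$Bp)
  rho_in <- 0.5 * (gc$th_ang + gc$th_high) * delta_now
  tot <- st$Bp + inflow
  rho_p2 <- ifelse(w_in + st$Bp > 0,
                   (w_in * rho_in + st$Bp * st$rho_p) / (w_in + st$Bp),
                   st$rho_p)
  mu_p <- plasma_death_rate(delta_prev, delta_now)
  Bp2 <- pmax(tot - mu_p * st$Bp * gc$dt_gc, 0)
  Bp2 <- pmin(Bp2, 1)

  list(Bc = Bc2, rho_c = rho_c2, sig_c = pmax(sig_c2, 0),
       Bp = Bp2, rho_p = pmax(rho_p2, 0))
}
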