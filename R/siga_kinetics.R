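#' Affinity-dependent SIgA functional rates
#'
#' Maps an antibody affinity to the three quantities that govern SIgA action
#' in the gut lumen: the masking rate (non-neutralizing binding that shields a
#' commensal from immune sampling), the neutralizing rate (binding that drives
#' expulsion from the lumen), and the binding ability (how stably the antibody
#' stays attached, given its dissociation rate). Masking and neutralizing are
#' complementary faces of the same binding event, so their rates sum to one:
#' low-affinity SIgA predominantly masks, high-affinity SIgA predominantly
#' neutralizes, and the two rates cross at 0.5 when `rho == 1`.
#'
#' @param rho Antibody affinity (dimensionless, `>= 0`). Vectorized.
#' @param rd Dissociation rate of SIgA from its target, in `[0, 1]`.
#'
#' @return A list with components `mu_m` (masking rate `1 / (1 + rho)`),
#'   `mu_n` (neutralizing rate `1 - 1 / (1 + rho)`) and `omega` (binding
#'   ability `1 - rd / (1 + rho)`), each the same length as `rho` and each in
#'   `[0, 1]`.
#'
#' @examples
#' siga_rates(0)          # fully masking, full binding
#' siga_rates(1, rd = .5) # the 0.5/0.5 crossover
#' siga_rates(9)$mu_n     # a strongly neutralizing antibody
#' @export
siga_rates <- function(rho, rd = 0) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("'rho' must be finite and >= 0", call. = FALSE)
  if (length(rd) != 1L || !is.finite(rd) || rd < 0 || rd > 1)
    stop("'rd' must be a single value in [0, 1]", call. = FALSE)
  mu_m <- 1 / (1 + rho)
  list(mu_m = mu_m, mu_n = 1 - mu_m, omega = 1 - rd * mu_m)
}

#' Affinity implied by a neutralizing rate
#'
#' Inverts the neutralizing-rate map: `mu_n = 1 - 1/(1 + rho)` gives
#' `rho = mu_n / (1 - mu_n)`. Used to recover affinities from published
#' neutralizing-rate profiles.
#'
#' @param mu_n Neutralizing rate in `[0, 1)`. Vectorized.
#' @return Affinity `rho >= 0`.
#' @export
affinity_from_neutralizing <- function(mu_n) {
  if (any(mu_n < 0) || any(mu_n >= 1))
    stop("'mu_n' must lie in [0, 1)", call. = FALSE)
  mu_n / (1 - mu_n)
}

#' Per-taxon SIgA masking and neutralization flux coefficients
#'
#' Assembles the concentration-weighted mass-action coefficients that multiply
#' the uncoated subpopulation in the community dynamics. Maternal and
#' endogenous SIgA act additively; each contributes its concentration times
#' the affinity-determined binding ability times the masking (or neutralizing)
#' rate.
#'
#' @param rho_m Per-taxon maternal SIgA affinity (`>= 0`).
#' @param rho_p Per-taxon mean endogenous (plasma-derived) SIgA affinity
#'   (`>= 0`), same length as `rho_m`.
#' @param rd Dissociation rate shared by both antibody sources.
#' @param mSIgA Maternal SIgA concentration in the lumen (normalized, `>= 0`).
#' @param eSIgA Endogenous SIgA concentration in the lumen (normalized,
#'   `>= 0`).
#'
#' @return A list with per-taxon numeric vectors `masking` and
#'   `neutralization`, both `>= 0`.
#' @export
effective_flux_coefficients <- function(rho_m, rho_p, rd, mSIgA, eSIgA) {
  if (mSIgA < 0 || eSIgA < 0)
    stop("antibody concentrations must be >= 0", call. = FALSE)
  mat <- siga_rates(rho_m, rd)
  end <- siga_rates(rho_p, rd)
  list(
    masking        = mSIgA * mat$omega * mat$mu_m + eSIgA * end$omega * end$mu_m,
    neutralization = mSIgA * mat$omega * mat$mu_n + eSIgA * end$omega * end$mu_n
  )
}
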