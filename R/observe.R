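#' Fecal observation of the luminal community
#'
#' Maps the gut-lumen state to what a fecal sample would show. Each
#' antibody-defined subpopulation reaches the stool with its own observation
#' rate: the neutralized contribution is the instantaneous neutralization
#' flux (expelled cells) scaled by `s_n`, while the masked and uncoated
#' contributions are stocks scaled by `s_m` and `s_uc`. From the
#' reconstructed per-taxon abundances the relative abundances, per-taxon
#' IgA indexes and the community SIgA coating ratio follow.
#'
#' @param sim A `"sigadyn_sim"` object, or `NULL` when the raw components
#'   are supplied directly.
#' @param day Day of life at which to observe (matched to the stored grid).
#' @param y_uc,y_m,neut_flux Per-taxon raw components (used when `sim` is
#'   `NULL`).
#' @param params A [default_params()] object (defaulting to the
#'   simulation's).
#' @param index_method IgA-index definition: `"contrast"` (symmetric
#'   fraction contrast in `[-1, 1]`) or `"logratio"` (log of the SIgA+ to
#'   SIgA- fraction-share ratio).
#' @return A list of class `"fecal_observation"` with per-taxon `w_n`,
#'   `w_m`, `w_uc`, `w`, `rel_abund`, `iga_index`, and scalar
#'   `coating_ratio`. All-zero communities yield `NA` ratios.
#' @export
fecal_observation <- function(sim = NULL, day = NULL, y_uc = NULL, y_m = NULL,
                              neut_flux = NULL, params = NULL,
                              index_method = c("contrast", "logratio")) {
  index_method <- match.arg(index_method)
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sigadyn_sim"))
    k <- which.min(abs(sim$times - day))
    y_uc <- sim$y_uc[k, ]; y_m <- sim$y_m[k, ]
    neut_flux <- sim$neut_flux[k, ]
    if (is.null(params)) params <- sim$params
  }
  s <- params$obs
  w_n <- s$s_n * neut_flux
  w_m <- s$s_m * y_m
  w_uc <- s$s_uc * y_uc
  w <- w_n + w_m + w_uc
  tot <- sum(w)
  rel <- if (tot > 0) w / tot else rep(NA_real_, length(w))
  cr <- if (tot > 0) sum(w_n + w_m) / tot else NA_real_
  structure(list(w_n = w_n, w_m = w_m, w_uc = w_uc, w = w,
                 rel_abund = rel,
                 iga_index = iga_index(w_n, w_m, w_uc, method = index_method),
                 coating_ratio = cr),
            class = "fecal_observation")
}

#' @export
print.fecal_observation <- function(x, ...) {
  m <- rbind(rel_abund = x$rel_abund, iga_index = x$iga_index)
  print(round(m, 3))
  cat(sprintf("SIgA coating ratio: %.3f\n", x$coating_ratio))
  invisible(x)
}

#' Per-taxon IgA index
#'
#' Enrichment of a taxon in the SIgA-coated (SIgA+) sorted fraction of a
#' fecal sample relative to the uncoated (SIgA-) fraction, as IgA-seq
#' measures it. With `P_i` the taxon's share of the SIgA+ fraction (masked
#' plus neutralized, normalized across taxa) and `N_i` its share of the
#' SIgA- fraction, the default symmetric contrast is
#' `(P_i - N_i) / (P_i + N_i)`, in `[-1, 1]`; the `"logratio"` alternative
#' is `log(P_i / N_i)` with a small pseudo-share. Taxa absent from both
#' fractions get `NA`.
#'
#' @param w_n,w_m,w_uc Per-taxon neutralized, masked and uncoated observed
#'   abundances.
#' @param method `"contrast"` or `"logratio"`.
#' @param pseudo Pseudo-share for the log-ratio variant.
#' @return Per-taxon numeric index.
#' @export
iga_index <- function(w_n, w_m, w_uc, method = c("contrast", "logratio"),
                      pseudo = 1e-6) {
  method <- match.arg(method)
  pos <- w_n + w_m
  P <- if (sum(pos) > 0) pos / sum(pos) else rep(0, length(pos))
  N <- if (sum(w_uc) > 0) w_uc / sum(w_uc) else rep(0, length(w_uc))
  if (method == "contrast") {
    out <- ifelse(P + N > 0, (P - N) / (P + N), NA_real_)
  } else {
    out <- ifelse(P + N > 0, log((P + pseudo) / (N + pseudo)), NA_real_)
  }
  out
}

#' Tolerant versus hyperreactive phenotype
#'
#' A matured host is `"tolerant"` when its endogenous SIgA is predominantly
#' masking (masking rate above 0.5, equivalently mean plasma affinity below
#' 1) against every symbiotic commensal (Bifidobacteriaceae, Bacteroidaceae,
#' Clostridiales), and `"hyperreactive"` when at least one symbiont draws
#' predominantly neutralizing antibodies.
#'
#' @param sim A `"sigadyn_sim"` object, or a named per-taxon vector of
#'   matured plasma affinities.
#' @param symbionts Names of the symbiotic commensal groups.
#' @return `"tolerant"` or `"hyperreactive"`.
#' @export
classify_phenotype <- function(sim, symbionts = c("B", "BC", "C")) {
  rho <- if (inherits(sim, "sigadyn_sim"))
    sim$rho_p[length(sim$times), ] else sim
  stopifnot(all(symbionts %in% names(rho)))
  if (all(rho[symbionts] < 1)) "tolerant" else "hyperreactive"
}

#' Steady-phase SIgA coating ratio
#'
#' Average community coating ratio over a (late) observation window.
#'
#' @param sim A `"sigadyn_sim"` object.
#' @param days Days over which to average (default: the steady phase,
#'   720-735).
#' @return Scalar mean coating ratio.
#' @export
coating_ratio <- function(sim, days = 720:735) {
  mean(vapply(days, function(d) fecal_observation(sim, d)$coating_ratio,
              numeric(1)))
}
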