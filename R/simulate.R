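#' Scenario configuration
#'
#' Bundles everything a simulation run needs: the feeding schedule, the
#' maternal antibody profile, milk-composition flags, the inoculation plan
#' and the integrator settings. Named presets reproduce the five
#' breastfeeding scenarios of the analysis: `"control"` (breastfed by a
#' tolerant mother), `"hyperreactive_bm"` (breastmilk SIgA with high affinity
#' against the symbiotic commensals, an IBD-like maternal profile),
#' `"siga_deficient_bm"` (breastmilk supplying HMOs and Bifidobacteriaceae
#' but no SIgA), `"only_ecf"` (no breastfeeding: reduced Bifidobacteriaceae
#' seeding, post-weaning taxa introduced with complementary food), and
#' `"ecf_probiotics"` (no breastfeeding plus Bacteroidaceae/Clostridiales
#' supplementation from birth).
#'
#' @param scenario Preset name, or `"custom"` to take every field from the
#'   arguments.
#' @param T_EBF,T_MF Feeding durations in days (defaults: the preset's).
#' @param params A [default_params()] object.
#' @param horizon Simulation horizon in days.
#' @param hmo_multiplier Scales the HMO forcing (e.g. 0.25 for an
#'   HMO-depleted milk scenario).
#' @param msiga_present Does breastmilk carry SIgA?
#' @param probiotic Introduce Bacteroidaceae and Clostridiales at birth at
#'   full inoculum?
#' @param kappa_multiplier Named per-taxon multiplicative modifiers of the
#'   immunostimulatory capacity (e.g. `c(E = 0.1, BC = 0.1)` emulates a 90%
#'   reduction of TLR4 stimulation by gram-negative taxa).
#' @param rtol,atol,hmax Integrator tolerances and maximum step (days).
#' @param dt_obs Output grid spacing in days.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("control", "hyperreactive_bm",
                                         "siga_deficient_bm", "only_ecf",
                                         "ecf_probiotics", "custom"),
                            T_EBF = NULL, T_MF = NULL,
                            params = default_params(),
                            horizon = 735,
                            hmo_multiplier = 1,
                            msiga_present = NULL,
                            probiotic = FALSE,
                            kappa_multiplier = NULL,
                            rtol = 1e-8, atol = 1e-10, hmax = 0.1,
                            dt_obs = 1) {
  scenario <- match.arg(scenario)
  breastfed <- !scenario %in% c("only_ecf", "ecf_probiotics")
  if (is.null(T_EBF)) T_EBF <- if (breastfed) 154 else 0
  if (is.null(T_MF))  T_MF  <- if (breastfed) 308 else 0
  if (is.null(msiga_present))
    msiga_present <- breastfed && scenario != "siga_deficient_bm"
  if (scenario == "ecf_probiotics") probiotic <- TRUE
  if (scenario == "hyperreactive_bm")
    params$rho_m[] <- affinity_from_neutralizing(rep(0.90, length(params$taxa)))
  if (!is.null(kappa_multiplier)) {
    stopifnot(all(names(kappa_multiplier) %in% params$taxa))
    params$kappa[names(kappa_multiplier)] <-
      params$kappa[names(kappa_multiplier)] * kappa_multiplier
  }
  if (hmo_multiplier < 0) stop("'hmo_multiplier' must be >= 0", call. = FALSE)
  sched <- feeding_schedule(T_EBF, T_MF)
  structure(list(scenario = scenario, sched = sched, params = params,
                 horizon = horizon, hmo_multiplier = hmo_multiplier,
                 msiga_present = msiga_present, probiotic = probiotic,
                 rtol = rtol, atol = atol, hmax = hmax, dt_obs = dt_obs),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': EBF %g d, MF %g d, horizon %g d, mSIgA %s\n",
              x$scenario, x$sched$T_EBF, x$sched$T_MF, x$horizon,
              if (x$msiga_present) "present" else "absent"))
  invisible(x)
}

# apply the HMO multiplier by rescaling the milk-derived constants
.apply_hmo_multiplier <- function(sched, mult) {
  if (mult == 1) return(sched)
  sched$K_H1 <- sched$K_H1 * mult
  sched$V_0  <- sched$V_0 * mult
  sched$K_H2 <- sched$K_H2 * mult
  sched
}

#' Initial system state of a scenario
#'
#' Oxygen starts at its normalized maximum of 1; all antibody concentrations
#' and germinal-center pools are empty. Enterobacteriaceae and
#' Bifidobacteriaceae are inoculated at birth, the latter scaled by the
#' colostrum-transfer multiplier `floor + (1 - floor)(1 - exp(-rate T_EBF))`
#' (25% of the full transfer when there is no breastfeeding, saturating
#' within the first three days). Bacteroidaceae and Clostridiales are
#' scheduled for the start of mixed feeding with their inoculum scaled by
#' the ratio of the PDP intake one day after the simulated versus the
#' reference weaning day; the probiotic flag moves them to birth at full
#' inoculum.
#'
#' @param config A [scenario_config()].
#' @return List with the continuous state vector `state`, the discrete
#'   germinal-center state `gc_state`, and the pending inoculation plan.
#' @export
initialize_state <- function(config) {
  p <- config$params
  n <- length(p$taxa)
  ix <- .state_index(n)
  state <- numeric(2L + 9L * n)
  state[ix$O2] <- 1
  y0 <- stats::setNames(numeric(n), p$taxa)
  bt <- p$b_transfer
  mult_b <- min(bt$floor + (1 - bt$floor) *
                  (1 - exp(-bt$rate * config$sched$T_EBF)), 1)
  y0["E"] <- p$inocula$E
  y0["B"] <- p$inocula$B * mult_b
  pending <- list()
  sched_ref <- feeding_schedule(config$sched$t_MF_ref, config$sched$T_MF_ref)
  pdp_ref <- feeding_point(config$sched$t_MF_ref + 1, sched_ref)$PDPs
  if (config$probiotic) {
    y0["BC"] <- p$inocula$BC
    y0["C"]  <- p$inocula$C
  } else {
    t_in <- config$sched$t_MF
    scale <- feeding_point(t_in + 1, config$sched)$PDPs / pdp_ref
    if (t_in <= 0) {
      y0["BC"] <- p$inocula$BC * scale
      y0["C"]  <- p$inocula$C * scale
    } else if (t_in < config$horizon) {
      pending <- list(day = t_in,
                      add = c(BC = p$inocula$BC * scale,
                              C  = p$inocula$C * scale))
    }
  }
  state[ix$y_uc] <- y0
  z <- stats::setNames(numeric(n), p$taxa)
  gc_state <- list(Bc = z, rho_c = z, sig_c = z, Bp = z, rho_p = z)
  list(state = state, gc_state = gc_state, pending = pending)
}

#' Simulate the coupled microbiome--immunity system
#'
#' Runs the full hybrid integration over the scenario horizon: the
#' continuous subsystem (community, antibody concentrations, oxygen,
#' selection thresholds, naive-cell and sampling bookkeeping) is solved with
#' an adaptive stiff integrator within each day, and the germinal-center
#' proliferation--hypermutation--selection map is applied at the end of each
#' update interval. Inoculations and the M-cell opening are handled as
#' events at their exact times. The run is fully deterministic.
#'
#' @param config A [scenario_config()].
#' @return An object of class `"sigadyn_sim"`: a list with the daily `times`,
#'   matrices of per-taxon series (`y_uc`, `y_m`, `y_sn`, `eSIgA`, `delta`,
#'   `Bn`, `Bc`, `Bp`, `rho_p`, `rho_c`, `sig_c`, `neut_flux`), vectors
#'   `mSIgA`, `O2`, `sigma`, the forcing table, the activation times, and the
#'   config.
#' @export
simulate_ontogeny <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  n <- length(p$taxa)
  ix <- .state_index(n)
  sched <- .apply_hmo_multiplier(config$sched, config$hmo_multiplier)
  milk <- config$msiga_present && sched$T_EBF > 0

  act <- if (milk) immune_activation_time(sched, config$horizon)
         else list(t50 = 0, t_m = 30)
  t_m <- act$t_m

  init <- initialize_state(config)
  state <- init$state
  gcs <- init$gc_state
  pending <- init$pending

  days <- seq(0, config$horizon, by = 1)
  nd <- length(days)
  taxmat <- function() matrix(NA_real_, nd, n, dimnames = list(NULL, p$taxa))
  out <- list(times = days,
              y_uc = taxmat(), y_m = taxmat(), y_sn = taxmat(),
              eSIgA = taxmat(), delta = taxmat(), Bn = taxmat(),
              Bc = taxmat(), Bp = taxmat(), rho_p = taxmat(),
              rho_c = taxmat(), sig_c = taxmat(), neut_flux = taxmat(),
              mSIgA = numeric(nd), O2 = numeric(nd), sigma = numeric(nd))

  record <- function(k) {
    out$y_uc[k, ] <<- state[ix$y_uc]; out$y_m[k, ] <<- state[ix$y_m]
    out$y_sn[k, ] <<- state[ix$y_sn]; out$eSIgA[k, ] <<- state[ix$eSIgA]
    out$delta[k, ] <<- state[ix$delta]; out$Bn[k, ] <<- state[ix$Bn]
    out$Bc[k, ] <<- gcs$Bc; out$Bp[k, ] <<- gcs$Bp
    out$rho_p[k, ] <<- gcs$rho_p; out$rho_c[k, ] <<- gcs$rho_c
    out$sig_c[k, ] <<- gcs$sig_c
    out$mSIgA[k] <<- state[ix$mSIgA]; out$O2[k] <<- state[ix$O2]
    out$sigma[k] <<- microenv_stimulation(state[ix$y_uc], state[ix$y_m], p)
    end <- siga_rates(gcs$rho_p, p$rd)
    mat <- siga_rates(p$rho_m, p$rd)
    neut <- (state[ix$mSIgA] * mat$omega * mat$mu_n +
               state[ix$eSIgA] * end$omega * end$mu_n) * state[ix$y_uc]
    out$neut_flux[k, ] <<- neut
  }
  record(1L)

  delta_prev <- stats::setNames(numeric(n), p$taxa)
  for (k in seq_len(nd - 1L)) {
    d0 <- days[k]; d1 <- days[k + 1L]
    if (length(pending) && !is.null(pending$day) && pending$day <= d0 + 1e-9 &&
        pending$day > d0 - 1 + 1e-9) {
      # scheduled inoculation applied at the start of its day
      state[ix$y_uc[match(names(pending$add), p$taxa)]] <-
        state[ix$y_uc[match(names(pending$add), p$taxa)]] + pending$add
      pending <- list()
    }
    rho_p <- gcs$rho_p
    attr(rho_p, "Bp") <- gcs$Bp
    segs <- if (t_m > d0 && t_m < d1) list(c(d0, t_m, 0), c(t_m, d1, 1))
            else list(c(d0, d1, as.numeric(d0 >= t_m)))
    for (sg in segs) {
      if (sg[2] - sg[1] <= 1e-12) next
      sol <- deSolve::lsoda(
        y = state, times = c(sg[1], sg[2]), func = community_rhs,
        parms = p, sched = sched, rho_p = rho_p,
        active = sg[3] > 0, msiga_on = milk,
        rtol = config$rtol, atol = config$atol, hmax = config$hmax,
        maxsteps = 50000)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("integrator failure in day [%g, %g]", sg[1], sg[2]),
             call. = FALSE)
      state <- sol[nrow(sol), -1]
    }
    # nonnegativity guard against integrator round-off
    neg <- state < 0
    if (any(neg)) {
      if (any(state[neg] < -1e-6))
        stop(sprintf("state blow-up below zero at day %g (min %.3g)",
                     d1, min(state)), call. = FALSE)
      state[neg] <- 0
    }
    if (d1 > t_m) {
      newcomers <- state[ix$Anew]
      state[ix$Anew] <- 0
      delta_now <- state[ix$delta]
      gcs <- gc_cycle_update(gcs, newcomers, delta_now, delta_prev, p)
      delta_prev <- delta_now
    }
    record(k + 1L)
  }

  forc <- feeding_inputs(days, sched)
  forc$mSIgA_influx <- if (milk) msiga_influx(days, sched) else 0
  structure(c(out, list(forcings = forc, t50 = act$t50, t_m = t_m,
                        config = config, params = p)),
            class = "sigadyn_sim")
}

#' @export
print.sigadyn_sim <- function(x, ...) {
  cat(sprintf("sigadyn simulation: scenario '%s', %d days, activation day %g\n",
              x$config$scenario, max(x$times), x$t_m))
  nf <- length(x$times)
  yl <- x$y_uc[nf, ] + x$y_m[nf, ]
  cat("final active abundances:",
      paste(sprintf("%s=%.3g", colnames(x$y_uc), yl), collapse = ", "), "\n")
  cat("final plasma affinities:",
      paste(sprintf("%s=%.3g", colnames(x$rho_p), x$rho_p[nf, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sigadyn_sim <- function(object, ...) {
  nf <- length(object$times)
  fin_n <- siga_rates(object$rho_p[nf, ], object$params$rd)$mu_n
  obs <- fecal_observation(object, day = max(object$times))
  structure(list(scenario = object$config$scenario,
                 t50 = object$t50, t_m = object$t_m,
                 rho_p_final = object$rho_p[nf, ],
                 mu_n_final = fin_n,
                 phenotype = classify_phenotype(object),
                 coating_ratio = obs$coating_ratio,
                 iga_index = obs$iga_index),
            class = "summary.sigadyn_sim")
}

#' @export
print.summary.sigadyn_sim <- function(x, ...) {
  cat(sprintf("Scenario '%s' -- activation day %g (t50 = %g)\n",
              x$scenario, x$t_m, x$t50))
  cat("matured endogenous neutralizing rates:\n")
  print(round(x$mu_n_final, 3))
  cat(sprintf("phenotype: %s;  fecal SIgA coating ratio: %.3f\n",
              x$phenotype, x$coating_ratio))
  cat("IgA indexes:\n")
  print(round(x$iga_index, 3))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Four base-graphics panels: active abundances per taxon, antibody
#' concentrations, selection thresholds, and plasma mean affinities against
#' the maternal profile.
#'
#' @param x A `"sigadyn_sim"` object.
#' @param ... Unused.
#' @export
plot.sigadyn_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  taxa <- colnames(x$y_uc)
  cols <- c(E = "firebrick", B = "forestgreen", BC = "steelblue",
            C = "darkorange")[taxa]
  yl <- x$y_uc + x$y_m
  graphics::matplot(x$times, yl, type = "l", lty = 1, col = cols,
                    xlab = "day of life", ylab = "active abundance",
                    main = "community")
  graphics::legend("topright", taxa, col = cols, lty = 1, bty = "n", cex = .8)
  graphics::matplot(x$times, cbind(x$mSIgA, x$eSIgA), type = "l",
                    lty = c(2, rep(1, ncol(x$eSIgA))),
                    col = c("black", cols),
                    xlab = "day of life", ylab = "concentration",
                    main = "antibodies (dashed: maternal)")
  graphics::matplot(x$times, x$delta, type = "l", lty = 1, col = cols,
                    xlab = "day of life", ylab = expression(delta),
                    main = "selection thresholds")
  graphics::matplot(x$times, x$rho_p, type = "l", lty = 1, col = cols,
                    xlab = "day of life", ylab = "plasma mean affinity",
                    main = "affinity maturation")
  graphics::abline(h = x$params$rho_m, col = cols, lty = 3)
  invisible(x)
}

#' Export a trajectory as a tidy table
#'
#' @param sim A `"sigadyn_sim"` object.
#' @return A data frame with columns `day`, `variable`, `taxon`, `value`
#'   (taxon `NA` for community-level variables).
#' @export
trajectory_table <- function(sim) {
  stopifnot(inherits(sim, "sigadyn_sim"))
  taxa <- colnames(sim$y_uc)
  per_tax <- c("y_uc", "y_m", "y_sn", "eSIgA", "delta", "Bn", "Bc", "Bp",
               "rho_p", "neut_flux")
  rows <- lapply(per_tax, function(v)
    data.frame(day = rep(sim$times, length(taxa)),
               variable = v,
               taxon = rep(taxa, each = length(sim$times)),
               value = as.vector(sim[[v]])))
  glob <- lapply(c("mSIgA", "O2", "sigma"), function(v)
    data.frame(day = sim$times, variable = v, taxon = NA_character_,
               value = sim[[v]]))
  do.call(rbind, c(rows, glob))
}
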