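#' Construct an observed dataset for inference
#'
#' Bundles the four observation signals the two-stage inference consumes:
#' maternal-phase relative abundances (days 3-274 for the symbionts, 3-172
#' for Enterobacteriaceae), steady-phase relative abundances (days 721-735),
#' day-30 relative abundances under no breastfeeding, and steady-phase
#' per-taxon IgA indexes; plus the steady coating-ratio target and an
#' optional absolute-abundance conversion curve.
#'
#' @param maternal,steady,day30 Data frames with columns `day`, `taxon`,
#'   `value` (relative abundances in `[0, 1]`).
#' @param iga Data frame with columns `taxon`, `value` (steady IgA indexes).
#' @param coating_target Steady community coating-ratio target.
#' @param density Optional density-count curve: a function of day, or a
#'   data frame with columns `day`, `density` (interpolated linearly).
#' @return An object of class `"observed_dataset"`.
#' @export
observed_dataset <- function(maternal, steady, day30, iga,
                             coating_target = 0.488, density = NULL) {
  chk <- function(d, nm) {
    stopifnot(all(c("day", "taxon", "value") %in% names(d)))
    if (any(d$day < 0 | d$day > 735))
      stop(sprintf("'%s': days must lie in [0, 735]", nm), call. = FALSE)
    if (any(d$value < 0 | d$value > 1))
      stop(sprintf("'%s': relative abundances must lie in [0, 1]", nm),
           call. = FALSE)
    d
  }
  maternal <- chk(maternal, "maternal")
  if (any(maternal$taxon == "E" & maternal$day > 172))
    stop("maternal-phase window for Enterobacteriaceae ends at day 172",
         call. = FALSE)
  steady <- chk(steady, "steady")
  day30 <- chk(day30, "day30")
  stopifnot(all(c("taxon", "value") %in% names(iga)))
  if (is.data.frame(density))
    density <- stats::approxfun(density$day, density$density, rule = 2)
  structure(list(maternal = maternal, steady = steady, day30 = day30,
                 iga = iga, coating_target = coating_target,
                 density = density),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf(paste0("Observed dataset: %d maternal, %d steady, %d day-30 ",
                     "abundance records; %d IgA indexes; coating target %.3f\n"),
              nrow(x$maternal), nrow(x$steady), nrow(x$day30), nrow(x$iga),
              x$coating_target))
  invisible(x)
}

# logistic blending weight between maternal- and developmental-phase fits
.blend_weight <- function(day, center = 172, scale = 5) {
  stats::plogis((day - center) / scale)
}

#' Preprocess raw observational tables
#'
#' The data-curation pipeline: per-taxon local-regression smoothing of the
#' longitudinal relative abundances (loess, span 0.5), blending of the
#' maternal- and developmental-phase fits with a logistic weight centered at
#' day 172 with scale 5, optional conversion to absolute abundances through
#' a density-count curve, and filtering of IgA-index records by the
#' breastmilk:formula ratio (kept when the ratio exceeds 0.75 before the
#' weaning day and is below 0.5 after it).
#'
#' @param abund Data frame with columns `day`, `taxon`, `value` and
#'   optionally `phase` (`"maternal"`/`"developmental"`); when `phase` is
#'   present the two phases are smoothed separately and blended.
#' @param grid Days at which smoothed values are returned (default: the
#'   sorted unique observed days).
#' @param density Optional density curve as in [observed_dataset()].
#' @param iga Optional IgA-index records with columns `day`, `taxon`,
#'   `value`, `bf_ratio`.
#' @param t_MF Weaning day used by the IgA filter.
#' @param span Loess span.
#' @return List with `smoothed` (day, taxon, value and, with a density
#'   curve, `absolute`) and `iga` (filtered records, or `NULL`).
#' @export
preprocess_observations <- function(abund, grid = NULL, density = NULL,
                                    iga = NULL, t_MF = 154, span = 0.5) {
  stopifnot(all(c("day", "taxon", "value") %in% names(abund)))
  has_phase <- "phase" %in% names(abund)
  if (is.data.frame(density))
    density <- stats::approxfun(density$day, density$density, rule = 2)
  out <- lapply(split(abund, abund$taxon), function(d) {
    g <- if (is.null(grid)) sort(unique(d$day)) else grid
    fit_one <- function(dd) {
      if (nrow(dd) < 4)
        stop("need at least 4 time points per taxon (and phase) to smooth",
             call. = FALSE)
      fit <- stats::loess(value ~ day, data = dd, span = span,
                          control = stats::loess.control(surface = "direct"))
      stats::predict(fit, newdata = data.frame(day = g))
    }
    v <- if (has_phase) {
      w <- .blend_weight(g)
      (1 - w) * fit_one(d[d$phase == "maternal", ]) +
        w * fit_one(d[d$phase == "developmental", ])
    } else fit_one(d)
    data.frame(day = g, taxon = d$taxon[1], value = v)
  })
  smoothed <- do.call(rbind, out)
  rownames(smoothed) <- NULL
  if (!is.null(density)) smoothed$absolute <- smoothed$value * density(smoothed$day)
  if (!is.null(iga)) {
    stopifnot(all(c("day", "bf_ratio") %in% names(iga)))
    keep <- (iga$day < t_MF & iga$bf_ratio > 0.75) |
      (iga$day >= t_MF & iga$bf_ratio < 0.5)
    iga <- iga[keep, , drop = FALSE]
  }
  list(smoothed = smoothed, iga = iga)
}

# ---- free-parameter plumbing -------------------------------------------

# apply a named vector of free values onto a parameter object; names use a
# dotted path: "lambda.E", "alpha.BC", "gc.tau_delta", "mu_O2", ...
.apply_free <- function(params, theta) {
  for (nm in names(theta)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      if (is.null(params[[parts]]))
        stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
      params[[parts]] <- unname(theta[[nm]])
    } else if (length(parts) == 2) {
      if (is.null(params[[parts[1]]]) ||
          !(parts[2] %in% names(params[[parts[1]]])))
        stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
      params[[parts[1]]][[parts[2]]] <- unname(theta[[nm]])
    } else stop(sprintf("malformed parameter name '%s'", nm), call. = FALSE)
  }
  params
}

# read the current values of free parameters from a parameter object
.free_values <- function(params, free) {
  vapply(free, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    v <- if (length(parts) == 1) params[[parts]]
         else params[[parts[1]]][[parts[2]]]
    as.numeric(v)
  }, numeric(1))
}

# ---- stage-1 reduced simulator -----------------------------------------

# Stage 1 fits the Maternal and Steady phases with the germinal center
# bypassed: the maternal branch has no endogenous SIgA, the steady branch
# assumes the matured offspring shares the maternal affinities with the
# endogenous concentration at carrying capacity (rho_p = rho_m, Bp = 1).
.stage1_sim <- function(params, sched, mode = c("maternal", "steady"),
                        horizon = 735, msiga_on = TRUE,
                        rtol = 1e-6, atol = 1e-8, hmax = 5) {
  mode <- match.arg(mode)
  n <- length(params$taxa)
  ix <- .state_index(n)
  state <- numeric(2L + 9L * n)
  state[ix$O2] <- 1
  bt <- params$b_transfer
  mult_b <- min(bt$floor + (1 - bt$floor) * (1 - exp(-bt$rate * sched$T_EBF)), 1)
  state[ix$y_uc[1]] <- params$inocula$E
  state[ix$y_uc[2]] <- params$inocula$B * mult_b
  rho_p <- params$rho_m
  attr(rho_p, "Bp") <- rep(if (mode == "steady") 1 else 0, n)
  if (mode == "steady") state[ix$eSIgA] <- 1
  solve_seg <- function(state, t0, t1) {
    if (t1 - t0 <= 0) return(cbind(time = numeric(0)))
    out <- deSolve::lsoda(y = state, times = seq(t0, t1, by = 1),
                          func = community_rhs, parms = params, sched = sched,
                          rho_p = rho_p, active = FALSE, msiga_on = msiga_on,
                          rtol = rtol, atol = atol, hmax = hmax,
                          maxsteps = 50000)
    if (attr(out, "istate")[1] < 0)
      stop("stage-1 integration failed", call. = FALSE)
    out
  }
  t_in <- sched$t_MF
  sref <- feeding_schedule(sched$t_MF_ref, sched$T_MF_ref)
  pdp_ref <- feeding_point(sched$t_MF_ref + 1, sref)$PDPs
  scale_in <- feeding_point(t_in + 1, sched)$PDPs / pdp_ref
  if (t_in > 0 && t_in < horizon) {
    s1 <- solve_seg(state, 0, t_in)
    state <- s1[nrow(s1), -1]
    state[ix$y_uc[3]] <- state[ix$y_uc[3]] + params$inocula$BC * scale_in
    state[ix$y_uc[4]] <- state[ix$y_uc[4]] + params$inocula$C * scale_in
    s2 <- solve_seg(state, t_in, horizon)
    tab <- rbind(s1[-nrow(s1), , drop = FALSE], s2)
  } else {
    state[ix$y_uc[3]] <- state[ix$y_uc[3]] + params$inocula$BC * scale_in
    state[ix$y_uc[4]] <- state[ix$y_uc[4]] + params$inocula$C * scale_in
    tab <- solve_seg(state, 0, horizon)
  }
  # reconstruct the instantaneous neutralization flux on the output grid
  times <- tab[, 1]
  y_uc <- tab[, 1 + ix$y_uc, drop = FALSE]
  y_m  <- tab[, 1 + ix$y_m, drop = FALSE]
  eS   <- tab[, 1 + ix$eSIgA, drop = FALSE]
  mS   <- pmax(tab[, 1 + ix$mSIgA], 0)
  mat <- siga_rates(params$rho_m, params$rd)
  endr <- siga_rates(params$rho_m, params$rd) # steady branch shares rho_m
  nf <- matrix(0, nrow(tab), n, dimnames = list(NULL, params$taxa))
  for (k in seq_len(nrow(tab))) {
    neut_coef <- mS[k] * mat$omega * mat$mu_n +
      pmax(eS[k, ], 0) * endr$omega * endr$mu_n
    nf[k, ] <- neut_coef * pmax(y_uc[k, ], 0)
  }
  colnames(y_uc) <- colnames(y_m) <- params$taxa
  list(times = times, y_uc = pmax(y_uc, 0), y_m = pmax(y_m, 0),
       neut_flux = nf)
}

# observed-style relative abundances / indexes from a stage-1 run at `days`
.stage1_observe <- function(run, days, params) {
  idx <- match(days, run$times)
  if (anyNA(idx)) stop("requested day outside the simulated grid", call. = FALSE)
  obs <- lapply(idx, function(k)
    fecal_observation(y_uc = run$y_uc[k, ], y_m = run$y_m[k, ],
                      neut_flux = run$neut_flux[k, ], params = params))
  names(obs) <- days
  obs
}

#' Stage-1 capped composite likelihood
#'
#' Evaluates the joint Maternal + Steady objective over the four observation
#' signals. Each signal's Gaussian log-likelihood is normalized against its
#' precomputed upper bound (the likelihood of zero residuals at the stated
#' error SD and signal length) and capped at 1; the total is the sum of the
#' four normalized contributions, in `[0, 4]`. The maternal branch is
#' simulated under the cohort feeding schedule without endogenous SIgA; the
#' steady branch assumes matured offspring sharing the maternal affinities
#' with the endogenous SIgA concentration at carrying capacity; the day-30
#' signal uses a no-breastfeeding schedule.
#'
#' @param theta Named vector of free-parameter values (dotted paths, e.g.
#'   `c("lambda.E" = 1.4)`); may be empty.
#' @param data An [observed_dataset()].
#' @param params Baseline parameter object onto which `theta` is applied.
#' @param sd_signal Error SDs, recycled over the four signals (maternal,
#'   steady, day30, iga).
#' @param sched Cohort feeding schedule used for the maternal and steady
#'   branches.
#' @return The capped composite value in `[0, 4]`, with attributes
#'   `contrib` (the four normalized contributions) and `log_contrib` (their
#'   logs, used as the fitting objective). Simulator failure returns `-Inf`
#'   with a `diagnostic` attribute.
#' @export
stage1_loglik <- function(theta, data, params = default_params(),
                          sd_signal = 0.05,
                          sched = feeding_schedule(154, 308)) {
  stopifnot(inherits(data, "observed_dataset"))
  sd_signal <- rep_len(sd_signal, 4L)
  params <- tryCatch(.apply_free(params, theta), error = function(e) e)
  if (inherits(params, "error")) {
    out <- -Inf; attr(out, "diagnostic") <- conditionMessage(params)
    return(out)
  }
  res <- tryCatch({
    mat_days <- sort(unique(data$maternal$day))
    run_m <- .stage1_sim(params, sched, "maternal",
                         horizon = max(mat_days, sched$t_MF + 1))
    obs_m <- .stage1_observe(run_m, mat_days, params)
    r1 <- mapply(function(d, v, tx) {
      obs_m[[as.character(d)]]$rel_abund[tx] - v
    }, data$maternal$day, data$maternal$value, data$maternal$taxon)

    st_days <- sort(unique(data$steady$day))
    run_s <- .stage1_sim(params, sched, "steady", horizon = max(st_days))
    obs_s <- .stage1_observe(run_s, st_days, params)
    r2 <- mapply(function(d, v, tx) {
      obs_s[[as.character(d)]]$rel_abund[tx] - v
    }, data$steady$day, data$steady$value, data$steady$taxon)

    sched0 <- feeding_schedule(0, 0)
    run_0 <- .stage1_sim(params, sched0, "maternal", horizon = 31,
                         msiga_on = FALSE)
    obs_0 <- .stage1_observe(run_0, sort(unique(data$day30$day)), params)
    r3 <- mapply(function(d, v, tx) {
      obs_0[[as.character(d)]]$rel_abund[tx] - v
    }, data$day30$day, data$day30$value, data$day30$taxon)

    last <- obs_s[[length(obs_s)]]
    r4 <- last$iga_index[data$iga$taxon] - data$iga$value
    list(r1 = r1, r2 = r2, r3 = r3, r4 = r4)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out <- -Inf; attr(out, "diagnostic") <- conditionMessage(res)
    return(out)
  }
  lognorm <- vapply(1:4, function(j) {
    r <- res[[j]]
    sum(stats::dnorm(r, 0, sd_signal[j], log = TRUE)) -
      sum(stats::dnorm(rep(0, length(r)), 0, sd_signal[j], log = TRUE))
  }, numeric(1))
  lognorm <- pmin(lognorm, 0) # cap each normalized contribution at 1
  out <- sum(exp(lognorm))
  attr(out, "contrib") <- exp(lognorm)
  attr(out, "log_contrib") <- lognorm
  out
}

# ---- priors -------------------------------------------------------------

#' Default priors for the stage-1 free parameters
#'
#' Weakly informative priors centered on the reference values: normal for
#' growth rates and metabolic preferences, gamma for strictly positive
#' rates. Each entry is a list with `dist` (`"normal"`, `"gamma"`,
#' `"beta"`, `"uniform"`) and its parameters.
#'
#' @param free Character vector of free-parameter names (dotted paths).
#' @param params Reference parameter object supplying the centers.
#' @param rel_sd Relative prior SD around the reference value.
#' @return Named list of prior specifications.
#' @export
default_priors <- function(free, params = default_params(), rel_sd = 0.5) {
  vals <- .free_values(params, free)
  priors <- lapply(seq_along(free), function(i) {
    v <- vals[i]
    list(dist = "normal", mean = v, sd = max(abs(v) * rel_sd, 1e-3))
  })
  names(priors) <- free
  priors
}

.log_prior <- function(theta, priors) {
  sum(vapply(names(theta), function(nm) {
    p <- priors[[nm]]
    if (is.null(p)) return(0)
    x <- theta[[nm]]
    switch(p$dist,
      normal  = stats::dnorm(x, p$mean, p$sd, log = TRUE),
      gamma   = stats::dgamma(x, shape = p$shape, rate = p$rate, log = TRUE),
      beta    = stats::dbeta(x, p$shape1, p$shape2, log = TRUE),
      uniform = stats::dunif(x, p$min, p$max, log = TRUE),
      stop(sprintf("unknown prior family '%s'", p$dist), call. = FALSE))
  }, numeric(1)))
}

# ---- stage-1 fitting ----------------------------------------------------

#' Fit the stage-1 (Maternal + Steady) parameters
#'
#' Maximum a posteriori estimation followed by random-walk Metropolis
#' sampling of the posterior formed by the priors and the capped composite
#' likelihood (on the log scale). The sampler is deliberately simple and
#' fully seeded; convergence diagnostics (split R-hat, divergent-proposal
#' counts) are reported rather than silently ignored.
#'
#' @param data An [observed_dataset()].
#' @param free Free-parameter names (dotted paths); default: the four
#'   intrinsic growth rates.
#' @param priors Prior list as from [default_priors()].
#' @param params Baseline parameter object.
#' @param chains,warmup,iter Chain count, warm-up length and total
#'   iterations per chain.
#' @param seed RNG seed.
#' @param proposal_sd Random-walk proposal SDs (recycled over `free`);
#'   default 2% of each reference value.
#' @param sd_signal Per-signal error SDs, see [stage1_loglik()].
#' @param map_only Skip sampling and return the MAP with a Laplace
#'   (inverse-Hessian) uncertainty approximation.
#' @return An object of class `"sigadyn_stage1"` with elements `map`,
#'   `map_se`, `draws` (post-warmup, all chains stacked), `summary`,
#'   `diagnostics`, `lp`.
#' @export
fit_stage1 <- function(data, free = paste0("lambda.", c("E", "B", "BC", "C")),
                       priors = default_priors(free, params),
                       params = default_params(),
                       chains = 2, warmup = 500, iter = 1000, seed = 1,
                       proposal_sd = NULL, sd_signal = 0.05,
                       map_only = FALSE) {
  stopifnot(iter > warmup, chains >= 1)
  set.seed(seed)
  start <- .free_values(params, free)
  if (is.null(proposal_sd)) proposal_sd <- pmax(abs(start) * 0.02, 1e-3)
  proposal_sd <- rep_len(proposal_sd, length(free))
  lp <- function(x) {
    th <- stats::setNames(x, free)
    ll <- stage1_loglik(th, data, params, sd_signal = sd_signal)
    # large finite penalty so bounded optimizers can bracket failures
    if (!is.finite(ll)) return(-1e10)
    sum(attr(ll, "log_contrib")) + .log_prior(th, priors)
  }
  opt <- if (length(start) == 1L) {
    stats::optim(start, function(x) -lp(x), method = "Brent",
                 lower = min(0.25 * start, 4 * start),
                 upper = max(0.25 * start, 4 * start))
  } else {
    stats::optim(start, function(x) -lp(x), method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-8))
  }
  map <- stats::setNames(opt$par, free)
  # Laplace approximation at the MAP for quick uncertainty
  h <- stats::optimHess(opt$par, function(x) -lp(x))
  map_se <- tryCatch({
    v <- diag(solve(h))
    stats::setNames(sqrt(pmax(v, 0)), free)
  }, error = function(e) stats::setNames(rep(NA_real_, length(free)), free))
  if (map_only) {
    return(structure(list(map = map, map_se = map_se, draws = NULL,
                          summary = data.frame(parameter = free, mean = map,
                                               sd = map_se, rhat = NA_real_),
                          diagnostics = "MAP only (no sampling)",
                          lp = -opt$value, free = free),
                     class = "sigadyn_stage1"))
  }
  n_keep <- iter - warmup
  draws <- array(NA_real_, c(n_keep, chains, length(free)),
                 dimnames = list(NULL, NULL, free))
  n_div <- 0L; n_acc <- 0L
  for (ch in seq_len(chains)) {
    x <- map + stats::rnorm(length(free), 0, proposal_sd)
    lx <- lp(x)
    k <- 0L
    for (it in seq_len(iter)) {
      prop <- x + stats::rnorm(length(free), 0, proposal_sd)
      lprop <- lp(prop)
      if (!is.finite(lprop) || lprop <= -1e9) {
        n_div <- n_div + 1L
      } else if (log(stats::runif(1)) < lprop - lx) {
        x <- prop; lx <- lprop; n_acc <- n_acc + 1L
      }
      if (it > warmup) { k <- k + 1L; draws[k, ch, ] <- x }
    }
  }
  total <- chains * iter
  div_msg <- sprintf("%d of %d (%.1f%%) transitions ended with a divergence.",
                     n_div, total, 100 * n_div / total)
  rhat <- vapply(free, function(nm) .split_rhat(draws[, , nm, drop = FALSE]),
                 numeric(1))
  flat <- do.call(rbind, lapply(seq_len(chains), function(ch) draws[, ch, , drop = TRUE]))
  flat <- matrix(flat, ncol = length(free), dimnames = list(NULL, free))
  smry <- data.frame(parameter = free,
                     mean = colMeans(flat),
                     sd = apply(flat, 2, stats::sd),
                     q5 = apply(flat, 2, stats::quantile, 0.05),
                     q95 = apply(flat, 2, stats::quantile, 0.95),
                     rhat = rhat, row.names = NULL)
  structure(list(map = map, map_se = map_se, draws = flat, summary = smry,
                 diagnostics = paste0(div_msg, sprintf(
                   " Acceptance rate %.2f.", n_acc / total)),
                 lp = -opt$value, free = free),
            class = "sigadyn_stage1")
}

# split R-hat over an (iterations x chains x 1) array
.split_rhat <- function(a) {
  n <- dim(a)[1]; m <- dim(a)[2]
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  segs <- do.call(cbind, lapply(seq_len(m), function(ch)
    cbind(a[seq_len(half), ch, 1], a[half + seq_len(half), ch, 1])))
  nn <- half; mm <- ncol(segs)
  means <- colMeans(segs)
  B <- nn * stats::var(means)
  W <- mean(apply(segs, 2, stats::var))
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' @export
print.sigadyn_stage1 <- function(x, ...) {
  cat("Stage-1 fit (", length(x$free), " free parameters)\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat(x$diagnostics, "\n")
  invisible(x)
}

#' @export
summary.sigadyn_stage1 <- function(object, ...) object$summary

#' @export
coef.sigadyn_stage1 <- function(object, ...) object$map

#' @export
plot.sigadyn_stage1 <- function(x, ...) {
  if (is.null(x$draws)) { warning("no draws to plot"); return(invisible(x)) }
  k <- length(x$free)
  op <- graphics::par(mfrow = c(k, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (nm in x$free)
    graphics::plot(x$draws[, nm], type = "l", ylab = nm, xlab = "")
  invisible(x)
}

# ---- stage 2 ------------------------------------------------------------

#' Stage-2 grid-search calibration of developmental-phase parameters
#'
#' Exhaustively evaluates a parameter grid, simulating the full ontogeny for
#' each cell and scoring a composite objective: squared distance of the
#' matured endogenous affinities from the maternal values, plus squared
#' distance of the steady coating ratio from its target. Returns the argmin
#' and the full objective surface.
#'
#' @param grid Named list of candidate values per free parameter (dotted
#'   paths); the grid is their full cross product.
#' @param params Baseline parameter object (stage-1 values already applied).
#' @param targets List with `affinity` (per-taxon target affinities,
#'   default the maternal profile) and `coating` (default 0.488).
#' @param weights Length-2 weights for the affinity and coating terms.
#' @param scenario Scenario preset to simulate (default `"control"`).
#' @param horizon,rtol,atol,hmax Simulation settings (defaults trade
#'   accuracy for speed; see [scenario_config()]).
#' @return An object of class `"sigadyn_stage2"` with `best` (named
#'   values), `objective`, and `surface` (one row per grid cell).
#' @export
stage2_calibrate <- function(grid, params = default_params(),
                             targets = list(affinity = params$rho_m,
                                            coating = 0.488),
                             weights = c(1, 1), scenario = "control",
                             horizon = 735, rtol = 1e-6, atol = 1e-9,
                             hmax = 1) {
  if (!length(grid) || any(!vapply(grid, length, 1L)))
    stop("empty stage-2 grid", call. = FALSE)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  objs <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    th <- stats::setNames(as.numeric(cells[i, ]), names(grid))
    objs[i] <- tryCatch({
      p_i <- .apply_free(params, th)
      cfg <- scenario_config(scenario, params = p_i, horizon = horizon,
                             rtol = rtol, atol = atol, hmax = hmax)
      sim <- simulate_ontogeny(cfg)
      rp <- sim$rho_p[length(sim$times), ]
      cr <- coating_ratio(sim, days = seq(horizon - 15, horizon))
      weights[1] * sum((rp - targets$affinity)^2) +
        weights[2] * (cr - targets$coating)^2
    }, error = function(e) Inf)
  }
  best_i <- which.min(objs)
  surface <- cbind(cells, objective = objs)
  structure(list(best = stats::setNames(as.numeric(cells[best_i, ]),
                                        names(grid)),
                 objective = objs[best_i], surface = surface),
            class = "sigadyn_stage2")
}

#' @export
print.sigadyn_stage2 <- function(x, ...) {
  cat("Stage-2 grid search over", nrow(x$surface), "cells\n")
  cat("Best:", paste(names(x$best), signif(x$best, 5), sep = " = ",
                     collapse = ", "),
      sprintf("(objective %.4g)\n", x$objective))
  invisible(x)
}
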