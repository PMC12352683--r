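#' Feeding-duration sweep with phenotype classification
#'
#' Simulates the full ontogeny over a grid of exclusive-breastfeeding and
#' mixed-feeding durations, classifying each cell's matured phenotype and
#' archiving diagnostic-marker series (total and SIgA-bound fecal
#' Enterobacteriaceae). Cell-level failures are recorded, not fatal.
#'
#' @param ebf,mf Grids of EBF and MF durations in days (paper ranges: 0-180
#'   and 0-300; defaults are a reduced-resolution grid).
#' @param params Parameter object.
#' @param marker_days Days at which the marker series are sampled.
#' @param horizon,rtol,atol,hmax Simulation settings; the defaults trade a
#'   little accuracy for sweep speed.
#' @param progress Print one line per cell.
#' @return An object of class `"sigadyn_sweep"`: `cells` (one row per grid
#'   cell with durations, matured affinities, masking/neutralizing rates,
#'   phenotype), `markers` (long table: cell, day, total and bound
#'   Enterobacteriaceae), `tolerant_fraction`, and the grids.
#' @export
feeding_sweep <- function(ebf = seq(0, 180, by = 30),
                          mf = seq(0, 300, by = 50),
                          params = default_params(),
                          marker_days = seq(30, 720, by = 30),
                          horizon = 735, rtol = 1e-6, atol = 1e-9, hmax = 1,
                          progress = FALSE) {
  grid <- expand.grid(T_EBF = ebf, T_MF = mf, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  taxa <- params$taxa
  aff <- matrix(NA_real_, n, length(taxa), dimnames = list(NULL, taxa))
  mun <- aff
  pre <- aff
  sig_w <- rep(NA_real_, n)
  phen <- rep(NA_character_, n)
  markers <- vector("list", n)
  for (i in seq_len(n)) {
    Te <- grid$T_EBF[i]; Tm <- grid$T_MF[i]
    res <- tryCatch({
      cfg <- scenario_config("custom", T_EBF = Te, T_MF = Tm, params = params,
                             msiga_present = (Te + Tm) > 0, horizon = horizon,
                             rtol = rtol, atol = atol, hmax = hmax)
      sim <- simulate_ontogeny(cfg)
      rp <- sim$rho_p[length(sim$times), ]
      obs_days <- marker_days[marker_days <= horizon]
      mk <- do.call(rbind, lapply(obs_days, function(d) {
        ob <- fecal_observation(sim, d)
        data.frame(cell = i, day = d,
                   total_E = unname(ob$w["E"]),
                   bound_E = unname(ob$w_n["E"] + ob$w_m["E"]))
      }))
      kw <- which.min(abs(sim$times - Te)) # weaning day (start of MF)
      list(rp = rp, mun = siga_rates(rp, params$rd)$mu_n,
           pre = sim$y_uc[kw, ] + sim$y_m[kw, ], sig_w = sim$sigma[kw],
           phen = classify_phenotype(sim), mk = mk)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      phen[i] <- NA_character_
    } else {
      aff[i, ] <- res$rp; mun[i, ] <- res$mun; phen[i] <- res$phen
      pre[i, ] <- res$pre; sig_w[i] <- res$sig_w
      markers[[i]] <- res$mk
    }
    if (progress)
      cat(sprintf("cell %d/%d (EBF %g, MF %g): %s\n", i, n, Te, Tm,
                  if (is.na(phen[i])) "FAILED" else phen[i]))
  }
  cells <- cbind(grid,
                 stats::setNames(as.data.frame(aff), paste0("rho_p_", taxa)),
                 stats::setNames(as.data.frame(mun), paste0("mu_n_", taxa)),
                 stats::setNames(as.data.frame(pre), paste0("pre_", taxa)),
                 sigma_wean = sig_w,
                 phenotype = phen)
  ok <- !is.na(phen)
  structure(list(cells = cells,
                 markers = do.call(rbind, markers),
                 tolerant_fraction = mean(phen[ok] == "tolerant"),
                 ebf = ebf, mf = mf, n_failed = sum(!ok)),
            class = "sigadyn_sweep")
}

#' @export
print.sigadyn_sweep <- function(x, ...) {
  cat(sprintf("Feeding sweep: %d cells (EBF %g-%g x MF %g-%g days)\n",
              nrow(x$cells), min(x$ebf), max(x$ebf), min(x$mf), max(x$mf)))
  cat(sprintf("Tolerant fraction: %.3f (hyperreactive %.3f); %d failed cells\n",
              x$tolerant_fraction, 1 - x$tolerant_fraction, x$n_failed))
  invisible(x)
}

#' @export
plot.sigadyn_sweep <- function(x, ...) {
  z <- matrix(as.numeric(x$cells$phenotype == "tolerant"),
              nrow = length(x$ebf), ncol = length(x$mf))
  graphics::image(x$ebf, x$mf, z, xlab = "EBF duration (days)",
                  ylab = "MF duration (days)",
                  main = "Tolerant (light) vs hyperreactive (dark)", ...)
  invisible(x)
}

#' Balanced marker dataset from a sweep
#'
#' Builds the per-time-point diagnostic-marker dataset: each grid cell acts
#' as a subject with its total and SIgA-bound Enterobacteriaceae markers and
#' its day-735 phenotype outcome; classes are balanced per time point by
#' seeded subsampling (with replacement when a class is smaller than the
#' requested size).
#'
#' @param sweep A [feeding_sweep()] result.
#' @param days Sampling days (must be among the sweep's marker days).
#' @param n_per_class Balanced class size per time point.
#' @param seed RNG seed for the subsampling.
#' @return A data frame of class `"sigadyn_markers"` with columns `day`,
#'   `cell`, `total_E`, `bound_E`, `outcome`.
#' @export
marker_dataset <- function(sweep, days = unique(sweep$markers$day),
                           n_per_class = 100, seed = 1) {
  stopifnot(inherits(sweep, "sigadyn_sweep"))
  set.seed(seed)
  ph <- stats::setNames(sweep$cells$phenotype, seq_len(nrow(sweep$cells)))
  mk <- sweep$markers
  mk$outcome <- ph[as.character(mk$cell)]
  mk <- mk[!is.na(mk$outcome), ]
  out <- do.call(rbind, lapply(days, function(d) {
    md <- mk[mk$day == d, ]
    do.call(rbind, lapply(c("tolerant", "hyperreactive"), function(cl) {
      sub <- md[md$outcome == cl, ]
      if (!nrow(sub)) return(NULL)
      sub[sample(nrow(sub), n_per_class, replace = nrow(sub) < n_per_class), ]
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("sigadyn_markers", "data.frame")
  out
}

#' Phenotype contrast at one sampling day
#'
#' Two-sided Wilcoxon rank-sum test of a marker between tolerant and
#' hyperreactive subjects at one day, with the rank-biserial correlation as
#' the effect size and the caption-style significance stars.
#'
#' @param markers A [marker_dataset()] result (or compatible data frame).
#' @param day Sampling day.
#' @param feature `"total_E"` or `"bound_E"`.
#' @return List with `statistic`, `p_value`, `rank_biserial` (in
#'   `[-1, 1]`, positive when hyperreactive values are larger), `stars`,
#'   and the class sizes. Single-class input yields `NA` with a warning.
#' @export
phenotype_contrast <- function(markers, day,
                               feature = c("total_E", "bound_E")) {
  feature <- match.arg(feature)
  md <- markers[markers$day == day, ]
  x <- md[[feature]][md$outcome == "hyperreactive"]
  y <- md[[feature]][md$outcome == "tolerant"]
  if (!length(x) || !length(y)) {
    warning("both phenotype classes must be present at the requested day")
    return(list(statistic = NA_real_, p_value = NA_real_,
                rank_biserial = NA_real_, stars = "",
                n = c(hyperreactive = length(x), tolerant = length(y))))
  }
  wt <- stats::wilcox.test(x, y, exact = FALSE)
  U <- unname(wt$statistic)
  rb <- 2 * U / (length(x) * length(y)) - 1
  stars <- if (is.na(wt$p.value)) "" else if (wt$p.value < 0.001) "***"
           else if (wt$p.value < 0.01) "**" else if (wt$p.value < 0.05) "*"
           else ""
  list(statistic = U, p_value = wt$p.value, rank_biserial = rb,
       stars = stars, n = c(hyperreactive = length(x), tolerant = length(y)))
}

# stratified k-fold assignment: balanced folds within each class
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated AUC time-course of the diagnostic markers
#'
#' For each sampling day fits three logistic-regression models — total
#' Enterobacteriaceae, SIgA-bound Enterobacteriaceae, and both — under
#' stratified 5-fold cross-validation, and reports the mean held-out AUC
#' with its standard error across folds; a loess smooth (span 0.5) across
#' days is attached per feature set.
#'
#' @param markers A [marker_dataset()] result.
#' @param seed RNG seed for fold assignment.
#' @param k Number of folds.
#' @return Data frame of class `"sigadyn_auc"`: `day`, `features`, `auc`,
#'   `se`, `auc_smooth`.
#' @export
auc_timecourse <- function(markers, seed = 1, k = 5) {
  set.seed(seed)
  days <- sort(unique(markers$day))
  sets <- list(total = "total_E", bound = "bound_E",
               both = c("total_E", "bound_E"))
  rows <- list()
  for (d in days) {
    md <- markers[markers$day == d, ]
    y <- as.integer(md$outcome == "hyperreactive")
    fold <- .stratified_folds(md$outcome, k)
    for (s in names(sets)) {
      feats <- sets[[s]]
      degen <- any(vapply(feats, function(f) stats::sd(md[[f]]) == 0,
                          logical(1)))
      if (degen || length(unique(y)) < 2) {
        if (degen) warning(sprintf(
          "degenerate feature at day %g; AUC set to 0.5", d))
        rows[[length(rows) + 1L]] <-
          data.frame(day = d, features = s, auc = 0.5, se = NA_real_)
        next
      }
      aucs <- vapply(seq_len(k), function(f) {
        tr <- md[fold != f, ]; te <- md[fold == f, ]
        if (length(unique(tr$outcome)) < 2 ||
            length(unique(te$outcome)) < 2) return(NA_real_)
        fm <- stats::as.formula(paste("out ~", paste(feats, collapse = "+")))
        tr$out <- as.integer(tr$outcome == "hyperreactive")
        fit <- suppressWarnings(stats::glm(fm, data = tr, family = stats::binomial()))
        pr <- stats::predict(fit, newdata = te, type = "response")
        as.numeric(suppressMessages(pROC::auc(
          response = as.integer(te$outcome == "hyperreactive"),
          predictor = pr, quiet = TRUE)))
      }, numeric(1))
      aucs <- aucs[!is.na(aucs)]
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, features = s, auc = mean(aucs),
        se = stats::sd(aucs) / sqrt(length(aucs)))
    }
  }
  out <- do.call(rbind, rows)
  out$auc_smooth <- NA_real_
  for (s in names(sets)) {
    sel <- out$features == s
    if (sum(sel) >= 4) {
      fit <- stats::loess(auc ~ day, data = out[sel, ], span = 0.5)
      out$auc_smooth[sel] <- stats::predict(fit)
    } else out$auc_smooth[sel] <- out$auc[sel]
  }
  class(out) <- c("sigadyn_auc", "data.frame")
  out
}

#' Predictor-importance analysis
#'
#' Quantifies what shapes the matured endogenous affinities across the
#' feeding sweep. In `"durations"` mode, the relative importance of the EBF
#' versus MF durations is computed by averaging the incremental explained
#' variance over both predictor orderings (the standard decomposition for
#' correlated predictors). In `"mediators"` mode, a random forest predicts
#' each response from mechanistic mediators (the per-taxon total abundances
#' and the microenvironmental stimulation at each cell's weaning day) plus
#' a pure-noise negative-control predictor, using permutation importances
#' normalized to `[0, 1]` per response.
#'
#' @param sweep A [feeding_sweep()] result.
#' @param mode `"durations"` or `"mediators"`.
#' @param responses Response columns of `sweep$cells` (default: the matured
#'   affinities of the post-weaning symbionts BC and C).
#' @param seed RNG seed (forest and noise control).
#' @param num_trees Forest size in mediators mode.
#' @return Data frame of class `"sigadyn_importance"`: `response`,
#'   `predictor`, `importance` (normalized to `[0, 1]` within response).
#' @export
importance_analysis <- function(sweep, mode = c("durations", "mediators"),
                                responses = c("rho_p_BC", "rho_p_C"),
                                seed = 1, num_trees = 500) {
  mode <- match.arg(mode)
  stopifnot(inherits(sweep, "sigadyn_sweep"))
  cells <- sweep$cells[!is.na(sweep$cells$phenotype), ]
  rows <- list()
  if (mode == "durations") {
    for (resp in responses) {
      y <- cells[[resp]]
      if (stats::sd(y) == 0) {
        imp <- c(T_EBF = 0, T_MF = 0)
      } else {
        r2 <- function(vars) {
          fm <- stats::as.formula(paste(resp, "~", paste(vars, collapse = "+")))
          # perfect fits are legitimate here; silence the summary caveat
          suppressWarnings(summary(stats::lm(fm, data = cells))$r.squared)
        }
        r_e <- r2("T_EBF"); r_m <- r2("T_MF"); r_em <- r2(c("T_EBF", "T_MF"))
        # average incremental contribution over both orderings
        imp_e <- 0.5 * (r_e + (r_em - r_m))
        imp_m <- 0.5 * (r_m + (r_em - r_e))
        imp <- c(T_EBF = imp_e, T_MF = imp_m)
        if (max(imp) > 0) imp <- imp / max(imp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, predictor = names(imp), importance = unname(imp))
    }
  } else {
    set.seed(seed)
    preds <- c(grep("^pre_", names(cells), value = TRUE), "sigma_wean")
    for (resp in responses) {
      y <- cells[[resp]]
      df <- cells[, preds, drop = FALSE]
      df$noise_control <- stats::rnorm(nrow(df))
      if (stats::sd(y) == 0) {
        imp <- stats::setNames(rep(0, ncol(df)), names(df))
      } else {
        df$.y <- y
        rf <- ranger::ranger(stats::as.formula(".y ~ ."), data = df,
                             num.trees = num_trees, seed = seed,
                             importance = "permutation")
        imp <- rf$variable.importance
        imp <- pmax(imp, 0)
        if (max(imp) > 0) imp <- imp / max(imp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, predictor = names(imp), importance = unname(imp))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sigadyn_importance", "data.frame")
  out
}

#' Morris elementary-effects screening
#'
#' Hand-rolled Morris one-at-a-time global sensitivity screening: `r`
#' random trajectories on a `levels`-level grid in the unit hypercube,
#' each perturbing every parameter once by `delta = levels / (2 (levels -
#' 1))`, giving `r * (k + 1)` model evaluations. Reports the mean (`mu`),
#' mean absolute value (`mu_star`) and SD (`sigma`) of the elementary
#' effects per parameter, on the scale of the (range-rescaled) inputs.
#'
#' @param fn Scalar-valued function of a named parameter vector (natural
#'   units).
#' @param ranges Named list of `c(lo, hi)` ranges; degenerate ranges
#'   (`lo == hi`) are dropped with a warning.
#' @param r Number of trajectories.
#' @param levels Grid levels.
#' @param seed RNG seed.
#' @return Data frame of class `"sigadyn_morris"`: `parameter`, `mu`,
#'   `mu_star`, `sigma`, plus attribute `n_eval`.
#' @export
morris_screen <- function(fn, ranges, r = 10, levels = 4, seed = 1) {
  keep <- vapply(ranges, function(rg) diff(range(rg)) > 0, logical(1))
  if (any(!keep))
    warning("dropping degenerate ranges: ",
            paste(names(ranges)[!keep], collapse = ", "))
  ranges <- ranges[keep]
  k <- length(ranges)
  if (!k) stop("no non-degenerate parameters to screen", call. = FALSE)
  set.seed(seed)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  delta <- levels / (2 * (levels - 1))
  base_levels <- seq(0, 1 - delta, length.out = levels / 2)
  ee <- matrix(NA_real_, r, k, dimnames = list(NULL, names(ranges)))
  n_eval <- 0L
  to_nat <- function(u) stats::setNames(lo + u * (hi - lo), names(ranges))
  for (tr in seq_len(r)) {
    u <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
    f0 <- fn(to_nat(u)); n_eval <- n_eval + 1L
    for (j in sample.int(k)) {
      u2 <- u
      u2[j] <- if (u[j] + delta <= 1) u[j] + delta else u[j] - delta
      f1 <- fn(to_nat(u2)); n_eval <- n_eval + 1L
      ee[tr, j] <- (f1 - f0) / (u2[j] - u[j])
      u <- u2; f0 <- f1
    }
  }
  out <- data.frame(parameter = names(ranges),
                    mu = colMeans(ee),
                    mu_star = colMeans(abs(ee)),
                    sigma = apply(ee, 2, stats::sd), row.names = NULL)
  attr(out, "n_eval") <- n_eval
  class(out) <- c("sigadyn_morris", "data.frame")
  out
}

#' Default Morris output: mean matured symbiont affinity
#'
#' Convenience wrapper producing the scalar output screened in the global
#' sensitivity analysis: the mean matured endogenous SIgA affinity against
#' the symbiotic commensals at day 735 in the control scenario.
#'
#' @param params Baseline parameter object.
#' @param horizon,rtol,atol,hmax Simulation settings (speed-biased
#'   defaults).
#' @return A function mapping a named free-parameter vector (dotted paths)
#'   to the scalar output; simulation failures yield `NA`.
#' @export
morris_output_fn <- function(params = default_params(), horizon = 735,
                             rtol = 1e-6, atol = 1e-9, hmax = 1) {
  function(theta) {
    tryCatch({
      p <- .apply_free(params, theta)
      cfg <- scenario_config("control", params = p, horizon = horizon,
                             rtol = rtol, atol = atol, hmax = hmax)
      sim <- simulate_ontogeny(cfg)
      mean(sim$rho_p[length(sim$times), c("B", "BC", "C")])
    }, error = function(e) NA_real_)
  }
}
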