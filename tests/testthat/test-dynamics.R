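nontrivial_state <- function(params, y_uc, y_m, y_sn = 0, mS = 0, eS = 0,
                             O2 = 1) {
  ix <- sigadyn:::.state_index(length(params$taxa))
  state <- numeric(2 + 9 * length(params$taxa))
  state[ix$mSIgA] <- mS
  state[ix$O2] <- O2
  state[ix$y_uc] <- y_uc
  state[ix$y_m] <- y_m
  state[ix$y_sn] <- y_sn
  state[ix$eSIgA] <- eS
  state
}

test_that("a single uncoupled taxon follows the logistic closed form to 1e-6", {
  beta <- diag(-1, 4)
  p <- default_params(beta = beta,
                      phi_O2 = rep(0, 4), phi_HMO = rep(0, 4),
                      phi_PDP = rep(0, 4))
  sched <- feeding_schedule(154, 308)
  ix <- sigadyn:::.state_index(4)
  y0 <- 0.05
  state <- nontrivial_state(p, y_uc = c(y0, 0, 0, 0), y_m = 0)
  rho_p <- stats::setNames(numeric(4), p$taxa)
  attr(rho_p, "Bp") <- numeric(4)
  tt <- seq(0, 20, by = 1)
  sol <- deSolve::lsoda(state, tt, community_rhs, parms = p, sched = sched,
                        rho_p = rho_p, active = FALSE, msiga_on = FALSE,
                        rtol = 1e-10, atol = 1e-12)
  r <- unname(p$lambda["E"]); K <- r / 1 # carrying capacity lambda/|beta_EE|
  closed <- K * y0 * exp(r * tt) / (K + y0 * (exp(r * tt) - 1))
  expect_lt(max(abs(sol[, 1 + ix$y_uc[1]] - closed)), 1e-6)
})

test_that("uc/m/neutralized compartments balance mass against net growth", {
  p <- default_params()
  sched <- feeding_schedule(154, 308)
  ix <- sigadyn:::.state_index(4)
  y_uc <- c(0.4, 0.3, 0.05, 0.02)
  y_m <- c(0.1, 0.2, 0.01, 0.03)
  state <- nontrivial_state(p, y_uc, y_m, y_sn = 0.2, mS = 0.7, eS = 0.3,
                            O2 = 0.4)
  rho_p <- stats::setNames(c(2, 0.5, 0.2, 0.1), p$taxa)
  attr(rho_p, "Bp") <- rep(0.5, 4)
  t <- 40
  d <- community_rhs(t, state, p, sched, rho_p, active = TRUE,
                     msiga_on = TRUE)[[1]]
  yL <- y_uc + y_m
  fd <- feeding_inputs(t, sched)
  lam <- adjusted_growth(p, O2 = 0.4, HMOs = fd$HMOs, PDPs = fd$PDPs)
  net_growth <- yL * (lam + drop(p$beta %*% yL))
  expect_equal(d[ix$y_uc] + d[ix$y_m] + d[ix$y_sn], unname(net_growth),
               tolerance = 1e-12)
})

test_that("masking moves mass between subpopulations without loss", {
  p <- default_params()
  sched <- feeding_schedule(154, 308)
  ix <- sigadyn:::.state_index(4)
  state <- nontrivial_state(p, y_uc = rep(0.2, 4), y_m = rep(0.1, 4),
                            mS = 1, eS = 0)
  rho_p <- stats::setNames(numeric(4), p$taxa)
  attr(rho_p, "Bp") <- numeric(4)
  d <- community_rhs(10, state, p, sched, rho_p, active = FALSE,
                     msiga_on = TRUE)[[1]]
  # the masked compartment only exchanges with the uncoated one
  fx <- effective_flux_coefficients(p$rho_m, rho_p, p$rd, 1, 0)
  expect_equal(d[ix$y_m],
               as.vector(unname(fx$masking * 0.2 - (1 / p$I_hl) * 0.1)))
})

test_that("microenvironmental stimulation follows its defining formula", {
  p <- default_params()
  y_uc <- c(0.3, 0.1, 0.05, 0.02)
  y_m <- c(0.1, 0.3, 0.02, 0.01)
  expect_equal(microenv_stimulation(y_uc, y_m, p),
               sum(p$kappa * y_uc) - sum(p$I_anti * (y_uc + y_m)))
  # a net anti-inflammatory community can be negative
  expect_lt(microenv_stimulation(c(0, 1, 0, 0), c(0, 1, 0, 0), p), 0)
})

test_that("oxygen is depleted by facultative anaerobes only", {
  p <- default_params()
  sched <- feeding_schedule(154, 308)
  ix <- sigadyn:::.state_index(4)
  rho_p <- stats::setNames(numeric(4), p$taxa)
  attr(rho_p, "Bp") <- numeric(4)
  state <- nontrivial_state(p, y_uc = c(0, 0.5, 0.5, 0.5), y_m = 0)
  d <- community_rhs(5, state, p, sched, rho_p)[[1]]
  expect_equal(d[ix$O2], 0) # no facultative anaerobes present
  state2 <- nontrivial_state(p, y_uc = c(0.5, 0, 0, 0), y_m = 0, O2 = 0.8)
  d2 <- community_rhs(5, state2, p, sched, rho_p)[[1]]
  expect_equal(d2[ix$O2], -p$mu_O2 * 0.8 * 0.5)
})

test_that("adjusted growth validates forcings and matches its formula", {
  p <- default_params()
  g <- adjusted_growth(p, O2 = 0.5, HMOs = 0.3, PDPs = 0.1)
  expect_equal(unname(g["B"]),
               unname((1 + 0.5 * p$phi_O2["B"] + 0.3 * p$phi_HMO["B"] +
                         0.1 * p$phi_PDP["B"]) * p$lambda["B"]))
  expect_error(adjusted_growth(p, 0, -1, 0), ">= 0")
})

test_that("non-finite states are rejected by the right-hand side", {
  p <- default_params()
  state <- numeric(2 + 9 * 4); state[3] <- NaN
  rho_p <- stats::setNames(numeric(4), p$taxa)
  expect_error(community_rhs(1, state, p, feeding_schedule(154, 308), rho_p),
               "non-finite")
})
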