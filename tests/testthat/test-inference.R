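fixture_dir <- function(which = "example") {
  system.file("fixtures", which, package = "sigadyn")
}

test_that("observed datasets validate their tables", {
  ok <- data.frame(day = c(3, 10, 20, 40), taxon = "B",
                   value = c(0.1, 0.2, 0.3, 0.4))
  iga <- data.frame(taxon = c("E", "B"), value = c(0.3, -0.2))
  expect_s3_class(observed_dataset(ok, ok, ok[1, ], iga), "observed_dataset")
  bad_day <- ok; bad_day$day[1] <- 800
  expect_error(observed_dataset(bad_day, ok, ok, iga), "\\[0, 735\\]")
  bad_val <- ok; bad_val$value[1] <- 1.2
  expect_error(observed_dataset(ok, bad_val, ok, iga), "\\[0, 1\\]")
  late_E <- ok; late_E$taxon <- "E"; late_E$day[4] <- 200
  expect_error(observed_dataset(late_E, ok, ok, iga), "day 172")
})

test_that("preprocessing smooths, blends and filters as documented", {
  set.seed(1)
  days <- seq(0, 300, by = 10)
  truthfun <- function(d) 0.5 + 0.3 * sin(d / 60)
  ab <- data.frame(day = days, taxon = "B",
                   value = truthfun(days) + rnorm(length(days), 0, 0.01))
  out <- preprocess_observations(ab, grid = c(50, 150, 250))
  expect_equal(nrow(out$smoothed), 3)
  expect_lt(max(abs(out$smoothed$value - truthfun(c(50, 150, 250)))), 0.05)
  # density converts to absolute abundance
  dens <- data.frame(day = c(0, 300), density = c(1e10, 1e10))
  out2 <- preprocess_observations(ab, grid = 100, density = dens)
  expect_equal(out2$smoothed$absolute, out2$smoothed$value * 1e10)
  # the IgA filter keeps mostly-breastmilk records early, mostly-formula late
  iga <- data.frame(day = c(100, 100, 200, 200), taxon = "E",
                    value = 0, bf_ratio = c(0.9, 0.5, 0.4, 0.8))
  out3 <- preprocess_observations(ab, iga = iga)
  expect_equal(out3$iga$bf_ratio, c(0.9, 0.4))
  # too few points to smooth is an error, not a silent NA
  expect_error(preprocess_observations(ab[1:3, ]), "at least 4")
})

test_that("phase blending interpolates between maternal and developmental fits", {
  days <- seq(0, 700, by = 25)
  ab <- rbind(data.frame(day = days, taxon = "B", value = 0.2,
                         phase = "maternal"),
              data.frame(day = days, taxon = "B", value = 0.8,
                         phase = "developmental"))
  out <- preprocess_observations(ab, grid = c(50, 172, 600))
  expect_equal(out$smoothed$value, c(0.2, 0.5, 0.8), tolerance = 1e-3)
})

test_that("dotted free-parameter paths round-trip through a parameter object", {
  p <- default_params()
  th <- c("lambda.E" = 1.23, "gc.tau_delta" = 99, "mu_O2" = 0.33,
          "alpha.BC" = 0.05)
  p2 <- sigadyn:::.apply_free(p, th)
  expect_equal(unname(sigadyn:::.free_values(p2, names(th))), unname(th))
  expect_equal(unname(p2$lambda["E"]), 1.23)
  expect_equal(p2$gc$tau_delta, 99)
  expect_error(sigadyn:::.apply_free(p, c("nope.x" = 1)), "unknown parameter")
  expect_error(sigadyn:::.apply_free(p, c("a.b.c" = 1)), "malformed")
})

test_that("the capped composite likelihood attains its cap on a perfect fit", {
  dat <- read_observed_dataset(fixture_dir("noiseless"))
  ll <- stage1_loglik(c(), dat)
  expect_equal(as.numeric(ll), 4)
  expect_equal(unname(attr(ll, "contrib")), rep(1, 4))
})

test_that("mismatched parameters score strictly below the cap", {
  dat <- read_observed_dataset(fixture_dir("noiseless"))
  ll <- stage1_loglik(c("lambda.E" = 1.0), dat)
  expect_lt(as.numeric(ll), 4)
})

test_that("priors default to reference-centered normals and log-density adds up", {
  p <- default_params()
  pr <- default_priors(c("lambda.E", "mu_O2"), p)
  expect_equal(unname(pr[["lambda.E"]]$mean), unname(p$lambda["E"]))
  lp <- sigadyn:::.log_prior(c("lambda.E" = p$lambda[["E"]],
                               "mu_O2" = p$mu_O2), pr)
  expect_equal(lp, dnorm(0, 0, pr[["lambda.E"]]$sd, log = TRUE) +
                 dnorm(0, 0, pr[["mu_O2"]]$sd, log = TRUE))
})

test_that("a MAP fit on the packaged fixture recovers the generating value", {
  dat <- read_observed_dataset(fixture_dir("example"))
  truth <- attr(dat, "truth")
  fit <- fit_stage1(dat, free = names(truth), seed = 2, map_only = TRUE)
  expect_s3_class(fit, "sigadyn_stage1")
  expect_lt(abs(unname(fit$map - truth)), 3 * unname(fit$map_se) + 0.02)
  expect_output(print(fit), "MAP only")
  expect_equal(unname(coef(fit)), unname(fit$map))
})

test_that("stage-2 calibration rejects an empty grid", {
  expect_error(stage2_calibrate(list()), "empty")
})
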