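test_that("synthetic specs validate their fields", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(noise_sd = -0.1))
  expect_error(synthetic_spec(days_maternal = c(10, 900)))
  sp <- synthetic_spec(truth = c("lambda.E" = 1.2))
  expect_equal(unname(sp$params$lambda["E"]), 1.2)
  expect_output(print(sp), "Ground truth")
})

test_that("generation is deterministic per seed and seed-sensitive", {
  sp <- synthetic_spec(noise_sd = 0.02, seed = 5)
  d1 <- generate_observational_dataset(sp)
  d2 <- generate_observational_dataset(sp)
  expect_identical(d1$maternal, d2$maternal)
  expect_identical(d1$iga, d2$iga)
  sp2 <- sp; sp2$seed <- 6
  d3 <- generate_observational_dataset(sp2)
  expect_false(identical(d1$maternal$value, d3$maternal$value))
})

test_that("zero noise reproduces the reduced simulator's observations exactly", {
  sp <- synthetic_spec(noise_sd = 0, days_maternal = c(5, 30, 60, 100),
                       days_steady = c(730, 735))
  dat <- generate_observational_dataset(sp)
  p <- sp$params
  run <- sigadyn:::.stage1_sim(p, feeding_schedule(154, 308), "maternal",
                               horizon = 100)
  obs <- sigadyn:::.stage1_observe(run, c(5, 30, 60, 100), p)
  for (k in seq_along(obs)) {
    got <- dat$maternal$value[dat$maternal$day == sp$days_maternal[k]]
    want <- obs[[k]]$rel_abund
    want <- want[!(p$taxa == "E" & sp$days_maternal[k] > 172)]
    expect_equal(got, unname(want))
  }
})

test_that("the Enterobacteriaceae maternal window is truncated at day 172", {
  sp <- synthetic_spec(noise_sd = 0, days_maternal = c(100, 172, 200, 250))
  dat <- generate_observational_dataset(sp)
  e_days <- dat$maternal$day[dat$maternal$taxon == "E"]
  expect_true(all(e_days <= 172))
  b_days <- dat$maternal$day[dat$maternal$taxon == "B"]
  expect_true(any(b_days > 172))
})

test_that("noise families stay within the observation domain", {
  for (kind in c("gaussian", "logitnormal")) {
    sp <- synthetic_spec(noise_sd = 0.2, noise = kind, seed = 3)
    dat <- generate_observational_dataset(sp)
    expect_true(all(dat$maternal$value >= 0 & dat$maternal$value <= 1))
    expect_true(all(dat$steady$value >= 0 & dat$steady$value <= 1))
  }
})

test_that("fixture files round-trip through the delimited reader", {
  sp <- synthetic_spec(truth = c("lambda.B" = 0.7), noise_sd = 0.01, seed = 9)
  dir <- tempfile()
  files <- write_fixture_dir(sp, dir)
  expect_true(all(file.exists(files)))
  dat <- read_observed_dataset(dir)
  ref <- generate_observational_dataset(sp)
  expect_equal(dat$maternal$value, ref$maternal$value)
  expect_equal(dat$coating_target, ref$coating_target)
  expect_equal(attr(dat, "truth"), c("lambda.B" = 0.7))
  expect_s3_class(dat, "observed_dataset")
})

test_that("stronger noise lowers the capped likelihood at the truth", {
  lls <- vapply(c(0, 0.04, 0.12), function(sd) {
    sp <- synthetic_spec(noise_sd = sd, seed = 4)
    as.numeric(stage1_loglik(c(), generate_observational_dataset(sp)))
  }, numeric(1))
  expect_equal(lls[1], 4)
  expect_true(all(diff(lls) < 0))
})

test_that("the shuffled negative control reports failure rather than passing silently", {
  sp <- synthetic_spec(truth = c("lambda.E" = 1.4), noise_sd = 0.02, seed = 2)
  rec <- parameter_recovery(sp, n_rep = 2, seed = 3, shuffle = TRUE)
  expect_true(rec$shuffled)
  expect_match(rec$diagnostic, "negative control")
  expect_output(print(rec), "negative control")
})
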