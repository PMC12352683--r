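fake_sweep <- function(cells, markers = NULL) {
  structure(list(cells = cells, markers = markers,
                 tolerant_fraction = mean(cells$phenotype == "tolerant"),
                 ebf = unique(cells$T_EBF), mf = unique(cells$T_MF),
                 n_failed = 0),
            class = "sigadyn_sweep")
}

fake_markers <- function(n = 40, sep = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(c(30, 60), function(d) {
    data.frame(day = d, cell = seq_len(2 * n),
               total_E = c(rnorm(n, 0), rnorm(n, sep)),
               bound_E = c(rnorm(n, 0), rnorm(n, sep)),
               outcome = rep(c("tolerant", "hyperreactive"), each = n))
  }))
}

test_that("phenotype contrast is null on identical class distributions", {
  md <- fake_markers(n = 60, sep = 0)
  pc <- phenotype_contrast(md, day = 30)
  expect_gt(pc$p_value, 0.05)
  expect_lt(abs(pc$rank_biserial), 0.25)
})

test_that("complete separation drives the rank-biserial correlation to 1", {
  md <- rbind(data.frame(day = 1, cell = 1:5, total_E = 1:5, bound_E = 1,
                         outcome = "tolerant"),
              data.frame(day = 1, cell = 6:10, total_E = 11:15, bound_E = 1,
                         outcome = "hyperreactive"))
  pc <- phenotype_contrast(md, day = 1)
  expect_equal(pc$rank_biserial, 1)
  pc2 <- phenotype_contrast(md, day = 1, feature = "bound_E")
  expect_equal(pc2$rank_biserial, 0) # all tied
})

test_that("a 3-vs-3 contrast matches exhaustive pair enumeration", {
  x <- c(1.2, 3.4, 2.2) # hyperreactive
  y <- c(0.5, 2.0, 2.9) # tolerant
  md <- data.frame(day = 7, cell = 1:6, total_E = c(y, x), bound_E = 0,
                   outcome = rep(c("tolerant", "hyperreactive"), each = 3))
  pc <- phenotype_contrast(md, day = 7)
  U <- sum(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
  expect_equal(pc$statistic, U)
  expect_equal(pc$rank_biserial, 2 * U / 9 - 1)
})

test_that("a single-class day yields missing values with a warning", {
  md <- data.frame(day = 3, cell = 1:4, total_E = 1:4, bound_E = 1:4,
                   outcome = "tolerant")
  expect_warning(pc <- phenotype_contrast(md, day = 3), "both phenotype")
  expect_true(is.na(pc$p_value))
})

test_that("significance stars follow the caption thresholds", {
  md <- fake_markers(n = 100, sep = 2)
  pc <- phenotype_contrast(md, day = 30)
  expect_equal(pc$stars, "***")
})

test_that("marker datasets are balanced per day and class", {
  cells <- expand.grid(T_EBF = c(0, 90), T_MF = c(0, 100))
  cells$phenotype <- c("tolerant", "tolerant", "hyperreactive",
                       "hyperreactive")
  mk <- do.call(rbind, lapply(1:4, function(i)
    data.frame(cell = i, day = c(30, 60), total_E = runif(2),
               bound_E = runif(2))))
  sw <- fake_sweep(cells, mk)
  md <- marker_dataset(sw, n_per_class = 10, seed = 2)
  counts <- table(md$day, md$outcome)
  expect_true(all(counts == 10))
  md2 <- marker_dataset(sw, n_per_class = 10, seed = 2)
  expect_identical(md, md2) # fully seeded
})

test_that("AUC is near 0.5 without signal and 1 under perfect separation", {
  null_md <- fake_markers(n = 50, sep = 0, seed = 7)
  a0 <- auc_timecourse(null_md, seed = 1)
  expect_true(all(abs(a0$auc - 0.5) < 0.2))
  sep_md <- fake_markers(n = 50, sep = 8, seed = 7)
  a1 <- auc_timecourse(sep_md, seed = 1)
  expect_true(all(a1$auc > 0.99))
  expect_true(all(c("total", "bound", "both") %in% a1$features))
})

test_that("degenerate features give AUC 0.5 with a warning", {
  md <- fake_markers(n = 20, sep = 1)
  md$total_E <- 1
  w <- capture_warnings(a <- auc_timecourse(md, seed = 1))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(a$auc[a$features == "total"] == 0.5))
})

test_that("stratified folds balance classes", {
  labels <- rep(c("a", "b"), c(40, 20))
  set.seed(1)
  fold <- sigadyn:::.stratified_folds(labels, 5)
  expect_true(all(table(fold[labels == "a"]) == 8))
  expect_true(all(table(fold[labels == "b"]) == 4))
})

test_that("durations-mode importance isolates the driving duration", {
  grid <- expand.grid(T_EBF = seq(0, 180, 30), T_MF = seq(0, 300, 50))
  cells <- grid
  cells$rho_p_BC <- 0.01 * grid$T_MF          # pure function of T_MF
  cells$rho_p_C <- 0.5                        # constant response
  cells$phenotype <- "tolerant"
  sw <- fake_sweep(cells)
  imp <- importance_analysis(sw, mode = "durations",
                             responses = c("rho_p_BC", "rho_p_C"))
  bc <- imp[imp$response == "rho_p_BC", ]
  expect_equal(bc$importance[bc$predictor == "T_MF"], 1)
  expect_lt(bc$importance[bc$predictor == "T_EBF"], 0.01)
  cc <- imp[imp$response == "rho_p_C", ]
  expect_true(all(cc$importance == 0))
})

test_that("mediators-mode importance ranks the noise control last", {
  set.seed(3)
  n <- 60
  cells <- data.frame(T_EBF = runif(n, 0, 180), T_MF = runif(n, 0, 300),
                      pre_E = runif(n), pre_B = runif(n), pre_BC = runif(n),
                      pre_C = runif(n), sigma_wean = runif(n),
                      phenotype = "tolerant")
  cells$rho_p_BC <- cells$pre_E + 2 * cells$pre_B + cells$pre_BC +
    cells$pre_C + 0.5 * cells$sigma_wean + rnorm(n, 0, 0.01)
  sw <- fake_sweep(cells)
  imp <- importance_analysis(sw, mode = "mediators",
                             responses = "rho_p_BC", seed = 4)
  ord <- imp$importance[order(imp$importance)]
  noise <- imp$importance[imp$predictor == "noise_control"]
  expect_equal(unname(noise), unname(ord[1]))
  expect_equal(max(imp$importance), 1)
  expect_equal(imp$importance[imp$predictor == "pre_B"], 1)
})

test_that("Morris screening matches analytic elementary effects on a linear function", {
  f <- function(th) 3 * th[["a"]] + 0 * th[["b"]]
  ms <- morris_screen(f, ranges = list(a = c(0, 2), b = c(-1, 1)),
                      r = 4, seed = 1)
  # on the rescaled unit inputs the slope is 3 * (hi - lo) = 6
  expect_equal(ms$mu[ms$parameter == "a"], 6)
  expect_equal(ms$mu_star[ms$parameter == "a"], 6)
  expect_equal(ms$sigma[ms$parameter == "a"], 0)
  expect_equal(ms$mu_star[ms$parameter == "b"], 0)
  expect_equal(attr(ms, "n_eval"), 4 * (2 + 1))
})

test_that("degenerate Morris ranges are excluded with a warning", {
  f <- function(th) sum(unlist(th))
  expect_warning(ms <- morris_screen(f, ranges = list(a = c(0, 1),
                                                      b = c(2, 2)), r = 2),
                 "degenerate")
  expect_equal(ms$parameter, "a")
  expect_error(suppressWarnings(
    morris_screen(f, ranges = list(b = c(2, 2)))), "no non-degenerate")
})

test_that("Morris screening is deterministic per seed", {
  f <- function(th) th[["a"]]^2 + sin(th[["b"]])
  m1 <- morris_screen(f, list(a = c(0, 1), b = c(0, 3)), r = 3, seed = 9)
  m2 <- morris_screen(f, list(a = c(0, 1), b = c(0, 3)), r = 3, seed = 9)
  expect_identical(m1, m2)
})
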