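# Objective, reconciliation, BIC, and the multi-start scenario fits.

test_that("objective reproduces the per-cohort relative-error decomposition", {
  tr <- default_truth()
  pred <- predict_panel(tr$params, tr$sig)
  data0 <- gen_activity_panel(tr, cv = 0, replicates = 1, seed = 1)
  obj0 <- objective(pred, data0)
  expect_equal(obj0$E, 0)
  expect_equal(obj0$E, obj0$Ev + obj0$Es + obj0$Evs)

  data <- gen_activity_panel(tr, cv = 0.05, replicates = 3, seed = 2)
  obj <- objective(pred, data)
  ora <- oracle_objective(pred, data)
  expect_equal(obj$E, ora$E, tolerance = 1e-12)
  expect_equal(obj$Ev, ora$Ev, tolerance = 1e-12)
  expect_equal(obj$Es, ora$Es, tolerance = 1e-12)
  expect_equal(obj$Evs, ora$Evs, tolerance = 1e-12)
  # invariance under common rescaling of predictions and data
  pred2 <- pred
  pred2$veff <- pred2$veff * 37
  data2 <- data
  data2$activity <- data2$activity * 37
  expect_equal(objective(pred2, data2)$E, obj$E, tolerance = 1e-12)
})

test_that("a single unit relative residual yields a cohort term of one", {
  tr <- default_truth()
  pred <- predict_panel(tr$params, tr$sig)
  data <- gen_activity_panel(tr, cv = 0, replicates = 1, seed = 1)
  # one point of the Pv cohort at twice its measured value: that squared
  # relative residual is 1, averaged over the 64 cohort points
  i <- which(pred$cohort == "Pv" & pred$boxes == "12" & pred$time_h == 5)
  j <- which(data$cohort == "Pv" & data$boxes == "12" & data$time_h == 5)
  pred$veff[i] <- 2 * data$activity[j]
  expect_equal(objective(pred, data)$Ev, 1 / 64)
  # zero measurement is rejected
  data$activity[j] <- 0
  expect_error(objective(pred, data), "zero")
})

test_that("reconcile_kh scales affinities and preserves their ordering", {
  kh <- c("0A1" = 0.2, "0A2" = 0.4, "0A3" = 0.1)
  expect_equal(reconcile_kh(kh, 1), kh)
  expect_equal(unname(reconcile_kh(kh, 2)), c(0.4, 0.8, 0.2))
  expect_error(reconcile_kh(kh, 0), "> 0")
  for (lam in c(0.05, 0.7, 13)) {
    s <- reconcile_kh(kh, lam)
    expect_lt(s[["0A3"]], s[["0A1"]])
    expect_lt(s[["0A1"]], s[["0A2"]])
  }
})

test_that("BIC penalizes parameters and matches its closed form", {
  expect_equal(bic(192, n_obs = 192, k = 10), 10 * log(192))
  expect_gt(bic(100, n_obs = 192, k = 12), bic(100, n_obs = 192, k = 10))
  b0 <- bic(0, n_obs = 192, k = 5)
  expect_identical(as.numeric(b0), -Inf)
  expect_true(attr(b0, "perfect_fit"))
})

test_that("compiled and closed-form prediction paths agree", {
  set.seed(41)
  for (sc in c("KK", "TT", "TK", "KT")) {
    tr <- default_truth()
    X <- activity_means(gen_activity_panel(tr, seed = 4))
    lay <- spo0Areg:::theta_layout(sc, max(X))
    cspec <- spo0Areg:::build_fit_spec(X, tr$kh_vitro, 4, sc, tr$sig$conc,
                                       lay)
    for (rep in 1:5) {
      th <- spo0Areg:::init_theta(lay, X, jitter = 0.5)
      pf <- spo0Areg:::params_from_theta(th, lay, tr$kh_vitro, 4, 4)
      predR <- activity_means(predict_panel(pf$params, tr$sig))
      predC <- spo0Areg:::panel_predict_cpp(th, cspec)
      expect_equal(unname(predR), unname(predC), tolerance = 1e-10)
    }
  }
})

test_that("a fit started at the generating truth is a fixed point", {
  tr <- default_truth()
  emsa <- list(kh = tr$kh_vitro, n = tr$n)
  data0 <- gen_activity_panel(tr, cv = 0, replicates = 1, seed = 1)
  f <- fit_scenario(data0, emsa, tr$sig, "KK", n_restarts = 1, seed = 1,
                    maxit = 3, maxit_explore = 3, init = tr$params)
  expect_lt(f$E, 1e-12)
  expect_equal(f$params$rho$Pv, tr$params$rho$Pv, tolerance = 1e-6)
  expect_equal(f$params$rho$Ps, tr$params$rho$Ps, tolerance = 1e-6)
  expect_equal(f$lambda, 1, tolerance = 1e-6)
})

test_that("scenario fitting is deterministic given the seed", {
  tr <- default_truth()
  emsa <- list(kh = tr$kh_vitro, n = tr$n)
  data <- gen_activity_panel(tr, seed = 5)
  f1 <- fit_scenario(data, emsa, tr$sig, "KK", n_restarts = 3, seed = 7,
                     maxit = 40, maxit_explore = 30)
  f2 <- fit_scenario(data, emsa, tr$sig, "KK", n_restarts = 3, seed = 7,
                     maxit = 40, maxit_explore = 30)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$restart_errors, f2$restart_errors)
  expect_equal(f1$E, f2$E)
  # reported E equals the R-side objective on the reconstructed parameters
  pred <- predict_panel(f1$params, tr$sig)
  expect_equal(objective(pred, data)$E, f1$E, tolerance = 1e-12)
})

test_that("KK fits recover rho, A dynamics, interaction signs and lambda", {
  tr <- default_truth()
  emsa <- list(kh = tr$kh_vitro, n = tr$n)
  data <- gen_activity_panel(tr, cv = 0.05, seed = 42)
  f <- fit_scenario(data, emsa, tr$sig, "KK", n_restarts = 12, seed = 3)
  rel <- abs(c(f$params$rho$Pv[-1], f$params$rho$Ps[-1]) -
               c(tr$params$rho$Pv[-1], tr$params$rho$Ps[-1])) /
    c(tr$params$rho$Pv[-1], tr$params$rho$Ps[-1])
  expect_lt(median(rel), 0.15)
  expect_gt(cor(f$params$A["Pv", ], tr$params$A["Pv", ]), 0.95)
  expect_gt(cor(f$params$A["Ps", ], tr$params$A["Ps", ]), 0.95)
  expect_true(all(f$params$binding$eps < 0))
  expect_lt(abs(f$lambda - 1), 0.25)
})

test_that("constrained interaction fits degrade when true couplings exist", {
  tr <- default_truth()
  emsa <- list(kh = tr$kh_vitro, n = tr$n)
  data <- gen_activity_panel(tr, cv = 0.05, seed = 8)
  free <- fit_scenario(data, emsa, tr$sig, "KK", n_restarts = 8, seed = 2)
  pin <- fit_constrained_interactions(data, emsa, tr$sig,
                                      zero_set = c("12", "13", "23"),
                                      scenario = "KK", n_restarts = 8,
                                      seed = 2)
  expect_gt(pin$E, free$E)
  expect_equal(unname(pin$params$binding$eps), c(0, 0, 0))
  expect_identical(pin$k, free$k - 3L)
  # the richer model also wins on BIC when the couplings are real
  expect_lt(free$bic, pin$bic)
  # empty zero set is the unconstrained fit
  same <- fit_constrained_interactions(data, emsa, tr$sig,
                                       zero_set = character(0),
                                       scenario = "KK", n_restarts = 8,
                                       seed = 2)
  expect_identical(same$theta, free$theta)
})

test_that("pinning interactions is harmless when the truth has none", {
  tr <- default_truth()
  # regenerate the panel from a truth without box-box couplings
  b0 <- binding_params(tr$n, tr$kh_vitro)
  p0 <- scenario_params("KK", b0, tr$params$A, rho = tr$params$rho)
  tr0 <- tr
  tr0$params <- p0
  data <- gen_activity_panel(tr0, cv = 0.05, seed = 9)
  emsa <- list(kh = tr$kh_vitro, n = tr$n)
  free <- fit_scenario(data, emsa, tr$sig, "KK", n_restarts = 8, seed = 4)
  pin <- fit_constrained_interactions(data, emsa, tr$sig,
                                      zero_set = c("12", "13", "23"),
                                      scenario = "KK", n_restarts = 8,
                                      seed = 4)
  # indistinguishable errors (within the noise floor), and BIC prefers
  # the smaller model
  expect_lt(abs(pin$E - free$E) / free$E, 0.25)
  expect_lt(pin$bic, free$bic)
})

test_that("scenario ranking orders by error with deterministic tiebreaks", {
  mk <- function(sc, E, k) {
    structure(list(scenario = sc, E = E, k = as.integer(k), bic = E),
              class = "scenario_fit")
  }
  r <- compare_scenarios(list(mk("TT", 0.03, 28), mk("KK", 0.002, 34),
                              mk("KT", 0.025, 31), mk("TK", 0.004, 31)))
  expect_identical(r$best, "KK")
  expect_identical(r$ranking$scenario, c("KK", "TK", "KT", "TT"))
  # equal errors: fewer parameters wins, then tag order
  r2 <- compare_scenarios(list(mk("TT", 0.01, 28), mk("KK", 0.01, 34)))
  expect_identical(r2$best, "TT")
  r3 <- compare_scenarios(list(mk("TK", 0.01, 31), mk("KT", 0.01, 31)))
  expect_identical(r3$best, "KT")
  # permutation invariance
  fits <- list(mk("KK", 0.2, 34), mk("TT", 0.1, 28), mk("KT", 0.3, 31))
  expect_identical(compare_scenarios(fits)$ranking,
                   compare_scenarios(rev(fits))$ranking)
})
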