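# Configuration weights, occupancy, and effective transcription rates.

test_that("configuration weights follow the Boltzmann product form", {
  b <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2),
                      eps = c("23" = -1.5))
  for (conc in c(0, 0.3, 1)) {
    expect_equal(config_weight("000", conc, b), 1)
  }
  expect_equal(config_weight("100", 0.4, b), 1)  # conc = Kh(0A1), weight 1
  # independent term-by-term evaluation of the "011" weight
  expect_equal(config_weight("011", 0.3, b),
               (0.3 / 0.6)^4 * (0.3 / 0.2)^4 * exp(1.5))
  expect_equal(config_weight("011", 0.3, b), 1.418034432411653,
               tolerance = 1e-12)
})

test_that("box occupancy normalizes, localizes at conc 0, and matches enumeration", {
  b <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2),
                      eps = c("12" = -1, "13" = 0.5, "23" = -2))
  p0 <- box_occupancy(0, b)
  expect_equal(p0[["000"]], 1)
  set.seed(11)
  for (i in 1:60) {
    kh <- setNames(runif(3, 0.05, 2), c("0A1", "0A2", "0A3"))
    eps <- setNames(runif(3, -4, 2), c("12", "13", "23"))
    bb <- binding_params(sample(1:5, 1), kh, eps = eps)
    present <- spo0Areg:::label_to_boxes(
      sample(c("1", "2", "3", "12", "13", "23", "123"), 1))
    conc <- runif(1, 0, 2)
    occ <- box_occupancy(conc, bb, present)
    expect_equal(sum(occ), 1, tolerance = 1e-12)
    expect_equal(occ, oracle_occupancy(conc, bb, present), tolerance = 1e-12)
  }
})

test_that("without interactions the marginal occupancy is the single-box curve", {
  b <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2))
  for (conc in c(0.1, 0.3, 0.8)) {
    marg <- spo0Areg:::box_marginals(conc, b)
    expect_equal(marg[["0A1"]], fraction_bound_single(conc, 0.4, 4))
    expect_equal(marg[["0A2"]], fraction_bound_single(conc, 0.6, 4))
    expect_equal(marg[["0A3"]], fraction_bound_single(conc, 0.2, 4))
  }
})

test_that("attractive 0A2-0A3 coupling boosts co-bound configurations", {
  kh <- c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2)
  b0 <- binding_params(4, kh)
  b8 <- binding_params(4, kh, eps = c("23" = -8))
  conc <- 0.4
  co0 <- sum(box_occupancy(conc, b0)[c("011", "111")])
  co8 <- sum(box_occupancy(conc, b8)[c("011", "111")])
  expect_gt(co8, co0)
  expect_equal(co8, sum(oracle_occupancy(conc, b8, names(kh))[c("011", "111")]),
               tolerance = 1e-12)
})

test_that("kinetic veff interpolates A*rho and hits its limits", {
  b <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2),
                      eps = c("12" = -1, "23" = -2))
  A <- matrix(rep(c(10, 30), 8), 2, 8, dimnames = list(c("Pv", "Ps"), 2:9))
  rho_flat <- list(Pv = setNames(rep(1, 8), config_ids()),
                   Ps = setNames(rep(1, 8), config_ids()))
  p_flat <- scenario_params("KK", b, A, rho = rho_flat)
  st <- strain_spec("Pv", "123")
  # rho = 1: unregulated, veff = A at every concentration
  for (conc in c(0, 0.2, 1.5)) {
    expect_equal(veff_single(st, p_flat, conc, 5), 10)
  }
  rho <- list(Pv = setNames(c(1, 0.9, 0.8, 0.7, 0.5, 0.45, 0.4, 0.3),
                            config_ids()),
              Ps = setNames(c(1, 1.5, 0.6, 0.5, 1.2, 1.6, 0.7, 0.28),
                            config_ids()))
  p <- scenario_params("KK", b, A, rho = rho)
  # saturation: all boxes bound, veff -> A * rho("111")
  expect_equal(veff_single(st, p, 1e3, 5), 10 * 0.3, tolerance = 1e-9)
  # convex combination bounds
  set.seed(3)
  for (conc in runif(20, 0, 2)) {
    v <- veff_single(st, p, conc, 5)
    expect_gte(v, 10 * min(rho$Pv))
    expect_lte(v, 10 * max(rho$Pv))
  }
})

test_that("thermodynamic veff without interactions is the bare occupancy rate", {
  b <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2))
  A <- matrix(rep(c(2, 0.5), 8), 2, 8, dimnames = list(c("Pv", "Ps"), 2:9))
  boxes <- c("0A1", "0A2", "0A3")
  p <- scenario_params("TT", b, A,
                       eta = list(Pv = setNames(numeric(3), boxes),
                                  Ps = setNames(numeric(3), boxes)),
                       vmax_scale = c(Pv = 50, Ps = 80))
  st <- strain_spec("Pv", "123")
  for (conc in c(0, 0.4, 2)) {
    expect_equal(veff_single(st, p, conc, 4), 50 * 2 / 3)
  }
})

test_that("dual-promoter rates: exact kinetic additivity, eta = 0 additivity", {
  set.seed(23)
  for (i in 1:50) {
    p <- random_scenario("KK")
    st <- random_strain("PvPs")
    conc <- runif(1, 0, 2)
    t <- sample(2:9, 1)
    vv <- veff_single(strain_spec("Pv", st$label), p, conc, t)
    vs <- veff_single(strain_spec("Ps", st$label), p, conc, t)
    expect_equal((vv + vs) / veff_dual(st, p, conc, t), 1, tolerance = 1e-12)
  }
  # TT with eta = 0 reduces to independent promoters
  b <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2),
                      eps = c("23" = -2))
  A <- matrix(runif(16, 0.1, 4), 2, 8, dimnames = list(c("Pv", "Ps"), 2:9))
  p0 <- scenario_params("TT", b, A, vmax_scale = c(Pv = 30, Ps = 70))
  st <- strain_spec("PvPs", "123")
  vd <- veff_dual(st, p0, 0.5, 6)
  vv <- veff_single(strain_spec("Pv", "123"), p0, 0.5, 6)
  vs <- veff_single(strain_spec("Ps", "123"), p0, 0.5, 6)
  expect_equal(vd, vv + vs, tolerance = 1e-12)
})

test_that("closed-form rates match the exhaustive joint-state oracle", {
  set.seed(31)
  for (i in 1:120) {
    sc <- sample(c("KK", "TT", "TK", "KT"), 1)
    p <- random_scenario(sc)
    st <- random_strain()
    conc <- runif(1, 0, 2)
    t <- sample(2:9, 1)
    fun <- if (st$cohort == "PvPs") veff_dual else veff_single
    v <- fun(st, p, conc, t)
    expect_equal(v, veff_enumerate(st, p, conc, t), tolerance = 1e-12)
  }
})

test_that("predicted time courses track A and respond to repression", {
  tr <- default_truth()
  # box-free strain under kinetic control reproduces the RNAP activity
  tc <- predict_timecourse(strain_spec("Pv", "none"), tr$params, tr$sig)
  expect_equal(tc$veff, unname(tr$params$A["Pv", ]))
  # constant A + repressive rho + rising signal: monotone non-increasing
  b <- tr$params$binding
  A <- matrix(rep(c(10, 10), 8), 2, 8, dimnames = list(c("Pv", "Ps"), 2:9))
  rho <- list(Pv = setNames(c(1, rep(0.4, 7)), config_ids()),
              Ps = setNames(c(1, rep(0.4, 7)), config_ids()))
  p <- scenario_params("KK", b, A, rho = rho)
  tc2 <- predict_timecourse(strain_spec("Pv", "123"), p, tr$sig)
  expect_true(all(diff(tc2$veff) <= 1e-12))
  # out-of-grid timepoint rejected
  expect_error(veff_single(strain_spec("Pv", "1"), tr$params, 0.5, 11),
               "grid")
})
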