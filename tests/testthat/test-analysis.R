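# Derived regulatory statistics: collapses, strength, saturation, RNAP
# decomposition, shared-sigma fits.

test_that("additivity ratio arithmetic and the kinetic-model identity", {
  mk <- function(vv, vs, vvs) {
    data.frame(cohort = c("Pv", "Ps", "PvPs"), boxes = "1", time_h = 2,
               veff = c(vv, vs, vvs))
  }
  expect_equal(additivity_ratio(mk(0.5, 0.5, 1))$ratio, 1)
  expect_equal(additivity_ratio(mk(1, 2, 4))$ratio, 0.75)
  z <- additivity_ratio(mk(1, 2, 0))
  expect_true(is.na(z$ratio))
  expect_equal(attr(z, "n_undefined"), 1)

  # purely kinetic predictions are exactly additive at all times
  tr <- default_truth()
  pred <- predict_panel(tr$params, tr$sig)
  ar <- additivity_ratio(pred)
  expect_equal(nrow(ar), 8 * 8)
  expect_true(all(abs(ar$ratio - 1) < 1e-12))

  # thermodynamic coupling breaks additivity
  set.seed(19)
  dev <- replicate(20, {
    p <- random_scenario("TT")
    max(abs(additivity_ratio(predict_panel(p, tr$sig))$ratio - 1))
  })
  expect_gt(mean(dev > 1e-6), 0.8)
})

test_that("endpoint/none normalization collapses RNAP-driven dynamics", {
  tr <- default_truth()
  data0 <- gen_activity_panel(tr, cv = 0, replicates = 1, seed = 1)
  nc <- normalize_collapse(data0)
  # the reference strain and the final timepoint are exactly 1
  expect_true(all(abs(nc$norm[nc$boxes == "none"] - 1) < 1e-12))
  expect_true(all(abs(nc$norm[nc$time_h == 9] - 1) < 1e-12))

  # with boxes saturated from the start, the RNAP rise is the only driver
  # and every single-promoter strain collapses onto 1 exactly
  sat_sig <- signal_0ap(2:9, rep(500, 8))
  pred <- predict_panel(tr$params, sat_sig)
  ncs <- normalize_collapse(pred)
  single <- ncs$cohort %in% c("Pv", "Ps")
  expect_true(all(abs(ncs$norm[single] - 1) < 1e-9))
  # dual-promoter strains mix the two RNAP time shapes, so their collapse
  # is exact only when Pv and Ps activities share one shape
  A_shared <- rbind(Pv = 30 * (1:8), Ps = 5 * (1:8))
  rownames(A_shared) <- c("Pv", "Ps")
  p_shared <- scenario_params("KK", tr$params$binding, A_shared,
                              rho = tr$params$rho)
  nc2 <- normalize_collapse(predict_panel(p_shared, sat_sig))
  expect_true(all(abs(nc2$norm - 1) < 1e-9))
})

test_that("regulation strength reduces to the initiation-rate ratios at saturation", {
  tr <- default_truth()
  # saturating signal: occupancy of the intact boxes is essentially 1
  sat_sig <- signal_0ap(2:9, rep(100, 8))
  st <- regulation_strength(tr$params, sat_sig)
  expect_true(all(st$strength_pct[st$boxes == "none"] == 0))
  # single-promoter strains: strength = 100 * (rho(bound config) - 1)
  expect_equal(st$strength_pct[st$cohort == "Ps" & st$boxes == "123"],
               100 * (0.284 - 1), tolerance = 1e-6)
  expect_equal(st$strength_pct[st$cohort == "Pv" & st$boxes == "123"],
               100 * (0.35 - 1), tolerance = 1e-6)
  expect_equal(st$strength_pct[st$cohort == "Ps" & st$boxes == "3"],
               100 * (1.50 - 1), tolerance = 1e-6)
  # dual strength is a weighted mean: it lies between the single strengths
  for (lab in c("1", "23", "123")) {
    s_v <- st$strength_pct[st$cohort == "Pv" & st$boxes == lab]
    s_s <- st$strength_pct[st$cohort == "Ps" & st$boxes == lab]
    s_d <- st$strength_pct[st$cohort == "PvPs" & st$boxes == lab]
    expect_gte(s_d, min(s_v, s_s) - 1e-9)
    expect_lte(s_d, max(s_v, s_s) + 1e-9)
  }
  # no regulation, no strength
  flat <- list(Pv = setNames(rep(1, 8), config_ids()),
               Ps = setNames(rep(1, 8), config_ids()))
  p1 <- scenario_params("KK", tr$params$binding, tr$params$A, rho = flat)
  expect_true(all(abs(regulation_strength(p1, sat_sig)$strength_pct) < 1e-9))
})

test_that("saturation timing follows the signal and the couplings", {
  tr <- default_truth()
  st123 <- strain_spec("Pv", "123")
  # no ligand: never saturates
  off <- signal_0ap(2:9, rep(0, 8))
  expect_true(all(is.na(saturation_time(tr$params, st123, off))))
  # step signal far above Kh at t = 4: saturation exactly at the step
  step <- signal_0ap(2:9, c(0, 0, 10 * 0.6, rep(10 * 0.6, 5)))
  b0 <- binding_params(4, c("0A1" = 0.4, "0A2" = 0.6, "0A3" = 0.2))
  p0 <- scenario_params("KK", b0, tr$params$A, rho = tr$params$rho)
  sat <- saturation_time(p0, st123, step)
  expect_equal(unname(sat), c(4, 4, 4))
  # attractive couplings can only advance saturation
  sat_eps <- saturation_time(tr$params, st123, tr$sig)
  sat_no <- saturation_time(p0, st123, tr$sig)
  both <- !is.na(sat_eps) & !is.na(sat_no)
  expect_true(all(sat_eps[both] <= sat_no[both]))
  expect_true(any(!is.na(sat_eps)))
})

test_that("RNAP freezing isolates the holoenzyme contribution", {
  tr <- default_truth()
  # constant-A parameters: freezing changes nothing
  Ac <- matrix(rep(c(30, 15), 8), 2, 8, dimnames = list(c("Pv", "Ps"), 2:9))
  pc <- scenario_params("KK", tr$params$binding, Ac, rho = tr$params$rho)
  rc <- rnap_contribution(pc, strain_spec("PvPs", "123"), tr$sig)
  expect_equal(rc$veff_dynamic, rc$veff_frozen)
  # a box-free strain under frozen RNAP is flat
  rn <- rnap_contribution(tr$params, strain_spec("Ps", "none"), tr$sig)
  expect_true(all(abs(diff(rn$veff_frozen)) < 1e-12))
  expect_true(all(diff(rn$veff_dynamic) > 0))
  # a saturated-box strain under frozen RNAP is flat after saturation
  rs <- rnap_contribution(tr$params, strain_spec("Ps", "123"), tr$sig)
  sat <- saturation_time(tr$params, strain_spec("Ps", "123"), tr$sig)
  after <- rs$time_h >= max(sat) + 1
  if (sum(after) >= 2) {
    # saturation threshold is 0.99, so residual drift up to ~1% remains
    vals <- rs$veff_frozen[after]
    expect_lt(max(abs(diff(vals))) / vals[1], 0.01)
  }
})

test_that("shared-sigma joint fit recovers a common shape and scales", {
  g_true <- c(1, 1.3, 1.9, 2.8, 4.1, 5.6, 7.0, 8.2)
  f <- joint_shared_sigma_fit(3 * g_true, 0.4 * g_true)
  expect_equal(f$sse, 0, tolerance = 1e-20)
  expect_equal(unname(f$scales), c(3, 0.4), tolerance = 1e-12)
  expect_equal(f$shape$g, g_true, tolerance = 1e-12)
  # different shapes leave a residual
  f2 <- joint_shared_sigma_fit(g_true, rev(g_true))
  expect_gt(f2$sse, 1)
  # noisy recovery: shape error comparable to the noise level
  set.seed(77)
  y1 <- 5 * g_true * exp(rnorm(8, 0, 0.05))
  y2 <- 0.8 * g_true * exp(rnorm(8, 0, 0.05))
  f3 <- joint_shared_sigma_fit(y1, y2)
  expect_lt(max(abs(f3$shape$g - g_true) / g_true), 0.15)
  expect_error(joint_shared_sigma_fit(rep(0, 8), g_true), "zero")
})
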