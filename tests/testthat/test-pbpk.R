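test_that("physiology and parameter containers validate their invariants", {
  expect_error(pbpk_physiology(0, physiology_mouse()$volumes,
                               physiology_mouse()$flows), "positive")
  expect_error(pbpk_params(P = c(liver = 0, spleen = 1, lungs = 1,
                                 kidneys = 1, others = 1)), "positive")
  expect_error(pbpk_params(P = setNames(rep(1, 5), nanotox:::PBPK_ORGANS),
                           F_bio = 1.2), "F_bio")
  expect_error(pbpk_doses("IV", -5), "positive")
  phys <- physiology_mouse()
  expect_equal(phys$cardiac_plasma_flow, sum(phys$flows))
})

test_that("mass is conserved for every route: body + excreted = F x dose", {
  phys <- physiology_mouse()
  for (i in 1:12) {
    draw <- withr::with_seed(100 + i, list(
      P = setNames(10^runif(5, -1, 1.5), nanotox:::PBPK_ORGANS),
      kb = runif(1, 0, 0.3), ku = runif(1, 0, 0.3),
      ka = runif(1, 0.2, 2), F = runif(1, 0.3, 1),
      route = sample(c("IV", "SC", "PO"), 1), dose = runif(1, 50, 500)))
    pp <- pbpk_params(P = draw$P, k_bile = draw$kb, k_urine = draw$ku,
                      k_a = draw$ka, F_bio = draw$F)
    sim <- pbpk_simulate(pp, phys, pbpk_doses(draw$route, draw$dose),
                         seq(0, 48, length.out = 40))
    expected <- if (draw$route == "IV") draw$dose else draw$dose * draw$F
    total <- rowSums(sim$amounts)
    expect_lt(max(abs(total - expected)) / expected, 0.001)
    expect_true(all(sim$conc >= -1e-10))
    expect_true(all(diff(sim$time) > 0))
  }
})

test_that("decoupled organs leave plasma constant; dose scales linearly", {
  phys0 <- pbpk_physiology(V_p = 1,
    volumes = setNames(rep(1, 5), nanotox:::PBPK_ORGANS),
    flows = setNames(rep(0, 5), nanotox:::PBPK_ORGANS))
  pp <- pbpk_params(P = setNames(rep(1, 5), nanotox:::PBPK_ORGANS))
  sim <- pbpk_simulate(pp, phys0, pbpk_doses("IV", 50), seq(0, 10, 1))
  expect_equal(max(abs(sim$conc[, "plasma"] - 50)), 0)
  expect_equal(max(abs(sim$conc[, 2:6])), 0)
  # linearity in dose (the model is linear in amount)
  phys <- physiology_mouse()
  pp2 <- ref_pbpk_truth()
  s1 <- pbpk_simulate(pp2, phys, pbpk_doses("IV", 100), seq(0, 24, 0.5))
  s2 <- pbpk_simulate(pp2, phys, pbpk_doses("IV", 200), seq(0, 24, 0.5))
  expect_lt(max(abs(s2$conc - 2 * s1$conc) / pmax(2 * s1$conc, 1e-9)), 1e-8)
})

test_that("the linear-systems fast path agrees with the stiff ODE solver", {
  phys <- physiology_mouse()
  obs <- expand.grid(organ = c("plasma", nanotox:::PBPK_ORGANS),
                     time_h = 10^seq(log10(0.25), log10(48), length.out = 8),
                     stringsAsFactors = FALSE)
  for (i in 1:5) {
    pp <- withr::with_seed(i, pbpk_params(
      P = setNames(10^runif(5, -1, 1.5), nanotox:::PBPK_ORGANS),
      k_bile = runif(1, 0, 0.3), k_urine = runif(1, 0, 0.3),
      k_a = 0.8, F_bio = 0.7))
    doses <- if (i %% 2 == 0) pbpk_doses("SC", 150) else pbpk_doses("IV", 150)
    lin <- nanotox:::pbpk_predict_obs(pp, phys, doses, obs, method = "linear")
    ode <- nanotox:::pbpk_predict_obs(pp, phys, doses, obs, method = "ode")
    expect_lt(max(abs(lin - ode) / pmax(abs(ode), 1e-9)), 1e-6)
  }
})

test_that("an absorbing-sink reduction reproduces the mono-exponential", {
  # one perfused organ with a huge partition coefficient acts as pure
  # first-order elimination from plasma at rate Q/V_p
  phys <- pbpk_physiology(V_p = 2,
    volumes = setNames(rep(1, 5), nanotox:::PBPK_ORGANS),
    flows = c(liver = 0, spleen = 0, lungs = 0, kidneys = 1, others = 0))
  pp <- pbpk_params(P = c(liver = 1, spleen = 1, lungs = 1, kidneys = 1e12,
                          others = 1))
  sim <- pbpk_simulate(pp, phys, pbpk_doses("IV", 100), seq(0, 8, by = 0.05))
  k <- 1 / 2; C0 <- 100 / 2
  expect_lt(max(abs(sim$conc[, "plasma"] - C0 * exp(-k * sim$time))) / C0,
            1e-6)
  ex <- exposure(sim, "plasma", 6, n_intervals = 4096)
  closed <- C0 * (1 - exp(-k * 6)) / (k * 6)
  expect_lt(abs(ex$c_hat - closed) / closed, 1e-6)
})

test_that("exposure averages correctly and is bounded by the peak", {
  phys0 <- pbpk_physiology(V_p = 1,
    volumes = setNames(rep(1, 5), nanotox:::PBPK_ORGANS),
    flows = setNames(rep(0, 5), nanotox:::PBPK_ORGANS))
  pp <- pbpk_params(P = setNames(rep(1, 5), nanotox:::PBPK_ORGANS))
  sim <- pbpk_simulate(pp, phys0, pbpk_doses("IV", 80), seq(0, 20, 1))
  ex <- exposure(sim, "plasma", 12)
  expect_equal(ex$c_hat, 80, tolerance = 1e-9)   # constant profile
  expect_equal(ex$auc, 80 * 12, tolerance = 1e-6)
  real <- pbpk_simulate(ref_pbpk_truth(), physiology_mouse(),
                        pbpk_doses("IV", 100), seq(0, 48, 0.5))
  ex2 <- exposure(real, "liver", 24)
  expect_lte(ex2$c_hat, max(real$conc[, "liver"]))
  expect_error(exposure(real, "liver", -1), "positive")
  expect_error(exposure(real, "liver", 100), "horizon")
  # trapezoid refinement converges at second order on a smooth profile
  # (an IV bolus has a fast distribution layer near t = 0, so the clean
  # mono-exponential reduction is the right place to read off the order)
  smooth_phys <- pbpk_physiology(V_p = 2,
    volumes = setNames(rep(1, 5), nanotox:::PBPK_ORGANS),
    flows = c(liver = 0, spleen = 0, lungs = 0, kidneys = 1, others = 0))
  smooth <- pbpk_simulate(
    pbpk_params(P = c(liver = 1, spleen = 1, lungs = 1, kidneys = 1e12,
                      others = 1)),
    smooth_phys, pbpk_doses("IV", 100), seq(0, 8, 0.5))
  fine <- exposure(smooth, "plasma", 6, n_intervals = 8192)$auc
  e1 <- abs(exposure(smooth, "plasma", 6, n_intervals = 64)$auc - fine)
  e2 <- abs(exposure(smooth, "plasma", 6, n_intervals = 128)$auc - fine)
  expect_gt(e1 / e2, 3.5)
})

test_that("calibration is a fixed point on noiseless data from known truth", {
  phys <- physiology_mouse()
  truep <- ref_pbpk_truth()
  doses <- pbpk_doses("IV", 200)
  obs <- gen_biodist(truep, phys, doses, n_timepoints = 8, noise_cv = 0,
                     seed = 1)
  init <- c(truep$P, k_bile = truep$k_bile, k_urine = truep$k_urine)
  names(init) <- c(paste0("P_", nanotox:::PBPK_ORGANS), "k_bile", "k_urine")
  fit <- pbpk_fit(obs, phys, doses, init = init, n_starts = 1, seed = 3)
  expect_lt(fit$ssr, 1e-10)
  expect_gt(fit$r_overall, 0.99999)
  expect_lt(max(abs(coef(fit) - unname(init)) / unname(init)), 1e-4)
  expect_error(pbpk_fit(obs[obs$time_h == obs$time_h[1], ], phys, doses),
               "three distinct time points")
})

test_that("fit acceptance uses the strict R > 0.9 rule", {
  expect_true(accept_fit(list(r_overall = 0.95)))
  expect_false(accept_fit(list(r_overall = 0.90)))
  expect_false(accept_fit(list(r_overall = 0.89)))
})

test_that("the in vivo design matrix uses log10 exposure and drops rejects", {
  phys <- physiology_mouse()
  truep <- ref_pbpk_truth()
  doses <- pbpk_doses("IV", 200)
  obs <- gen_biodist(truep, phys, doses, noise_cv = 0, seed = 1)
  init <- setNames(c(truep$P, truep$k_bile, truep$k_urine),
                   c(paste0("P_", nanotox:::PBPK_ORGANS), "k_bile", "k_urine"))
  good <- pbpk_fit(obs, phys, doses, init = init, n_starts = 1, seed = 3)
  expect_true(accept_fit(good))
  bad <- good; bad$r_overall <- 0.5
  records <- data.frame(
    study_id = c("s1", "s1", "s2"), organ = c("liver", "kidneys", "liver"),
    time_h = 24, size_nm = c(30, 30, 80),
    composition = "Au", coating = "PEG", shape = "Sphere",
    zeta_class = "negative", species = "mouse", label = c(1, 0, 0),
    stringsAsFactors = FALSE)
  mat <- build_invivo_features(records, list(s1 = good, s2 = bad))
  expect_equal(nrow(mat$x), 2)                    # s2 rejected
  expect_true(any(grepl("rejected", attr(mat, "log"))))
  chat <- exposure(good, "liver", 24)$c_hat
  expect_equal(unname(mat$x[1, "conc_ug_per_ml"]), log10(chat),
               tolerance = 1e-9)
})
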