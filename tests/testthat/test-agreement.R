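test_that("constant differences give a degenerate fit with that bias", {
  p <- toy_paired(rep(-3.5, 24), subjects = rep(1:3, each = 8),
                  phases = rep(c("relaxation", "oral"), 12))
  fit <- fit_difference_model(p)
  expect_true(fit$degenerate)
  expect_equal(fit$bias, -3.5)
  expect_equal(unname(fit$vc_diff), c(0, 0, 0))
  expect_equal(unname(loa_mixed(fit)), c(-3.5, -3.5, -3.5))
  expect_equal(msd(fit), 3.5^2)
})

test_that("sign-flipping the differences negates the bias, not the variances", {
  set.seed(23)
  p <- bivariate_paired(10, 15, sigma2_subject = 20, sigma2_e = 8,
                        bias = -2, seed = 23)
  f1 <- fit_difference_model(p)
  p2 <- p
  p2$hr_ref <- p$hr_test
  p2$hr_test <- p$hr_ref
  p2$diff <- -p$diff
  f2 <- fit_difference_model(p2)
  expect_equal(f2$bias, -f1$bias, tolerance = 1e-8)
  expect_equal(f2$vc_diff, f1$vc_diff, tolerance = 1e-6)
})

test_that("limits of agreement follow the closed form and widen with level", {
  # bias -1.91 with SD(diff) = 8.40 reproduces the familiar (-18.4, 14.6) shape
  fit <- difference_fit(-1.91, sigma2_subject = 40, sigma2_interaction = 10,
                        sigma2_resid = 20.56)
  loa <- loa_mixed(fit, level = 0.95)
  expect_equal(unname(loa["bias"]), -1.91)
  expect_equal(unname(loa["lower"]), -1.91 - stats::qnorm(0.975) * 8.4,
               tolerance = 1e-9)
  expect_equal(unname(loa["lower"]), -18.37, tolerance = 0.01)
  expect_equal(unname(loa["upper"]), 14.55, tolerance = 0.01)
  wide <- loa_mixed(fit, level = 0.99)
  expect_lt(wide["lower"], loa["lower"])
  expect_gt(wide["upper"], loa["upper"])
  expect_error(loa_mixed(fit, level = 1.2), "level")

  zero <- difference_fit(0)
  expect_equal(unname(loa_mixed(zero)), c(0, 0, 0))
})

test_that("msd equals bias^2 plus total variance and matches mean(diff^2)", {
  expect_equal(msd(difference_fit(3)), 9)
  expect_equal(msd(difference_fit(0, sigma2_resid = 25)), 25)

  p <- bivariate_paired(60, 40, sigma2_subject = 6, sigma2_e = 12.5,
                        bias = -2, seed = 31)
  fit <- fit_difference_model(p)
  expect_equal(msd(fit), mean(p$diff^2), tolerance = 0.03)
})

test_that("coverage probability reproduces the printed value and its limits", {
  expect_equal(round(coverage_probability(-1.91, 85.69, 10), 2), 0.72)
  expect_equal(coverage_probability(-1.91, 85.69, 1e6), 1, tolerance = 1e-12)
  expect_equal(coverage_probability(0, 1, stats::qnorm(0.975)), 0.95,
               tolerance = 1e-9)
  # sigma = 0 degenerates to the indicator of |bias| <= cad
  expect_equal(coverage_probability(4, 16, 10), 1)
  expect_equal(coverage_probability(12, 144, 10), 0)
  expect_error(coverage_probability(5, 16, 10), "bias")
  expect_error(coverage_probability(0, 10, -1), "cad")
})

test_that("TDI and the repeatability coefficient match their closed forms", {
  expect_equal(round(total_deviation_index(85.69, 0.95), 2), 18.14)
  expect_equal(total_deviation_index(0, 0.95), 0)
  expect_equal(total_deviation_index(25, 0.95), 9.80, tolerance = 0.005)
  expect_error(total_deviation_index(-1), "msd")
  expect_error(total_deviation_index(25, 1.5), "p")

  expect_equal(round(repeatability_coefficient(29.72), 2), 15.11)
  expect_equal(repeatability_coefficient(0), 0)
  expect_equal(repeatability_coefficient(2), 3.92, tolerance = 0.005)
})

test_that("CIA reproduces the printed value and its degenerate cases", {
  expect_equal(round(cia(29.72, 85.69), 2), 0.69)
  expect_equal(cia(0, 0), 1)
  expect_error(cia(5, 0), "zero")

  # devices identical up to iid noise: msd = 2 sigma^2, so cia ~ 1
  p <- bivariate_paired(40, 30, sigma2_subject = 50, sigma2_e = 9, seed = 41)
  fit <- fit_difference_model(p)
  cc <- ccc_vc(p)
  expect_equal(cia(cc$sigma2_resid, msd(fit)), 1, tolerance = 0.1)
})

test_that("CIA decreases monotonically as device-specific bias grows", {
  vals <- vapply(c(0, 3, 6, 9), function(b) {
    p <- bivariate_paired(40, 20, sigma2_subject = 40, sigma2_e = 9,
                          bias = b, seed = 51)
    cia(ccc_vc(p)$sigma2_resid, msd(fit_difference_model(p)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the variance-components CCC matches the analytic bivariate values", {
  # sigma2_subject 3, sigma2_e 1, no bias: CCC = 3/4
  p1 <- bivariate_paired(150, 20, sigma2_subject = 3, sigma2_e = 1, seed = 61)
  cc1 <- ccc_vc(p1)
  expect_equal(cc1$ccc, 0.75, tolerance = 0.03)
  # plus a device shift with b^2/2 = 1: CCC = 3/5
  p2 <- bivariate_paired(150, 20, sigma2_subject = 3, sigma2_e = 1,
                         bias = sqrt(2), seed = 61)
  cc2 <- ccc_vc(p2)
  expect_equal(cc2$ccc, 0.6, tolerance = 0.03)
})

test_that("ccc_vc agrees with Lin's moment CCC on balanced two-device data", {
  p <- bivariate_paired(120, 25, sigma2_subject = 40, sigma2_e = 12,
                        bias = 1.5, seed = 71)
  vc_est <- ccc_vc(p)$ccc
  moment <- lin_ccc(p$hr_ref, p$hr_test)
  expect_equal(vc_est, moment, tolerance = 0.02)
})

test_that("CCC interpretation bands follow the guideline cut-points", {
  expect_equal(classify_ccc(0.76), "poor")
  expect_equal(classify_ccc(0.92), "moderate")
  expect_equal(classify_ccc(0.97), "substantial")
  expect_equal(classify_ccc(0.995), "perfect")
})

test_that("difference-model preconditions are enforced", {
  one <- toy_paired(rnorm(10), subjects = rep(1, 10))
  expect_error(fit_difference_model(one), "2 subjects")
  thin <- toy_paired(rnorm(3), subjects = c(1, 1, 2))
  expect_error(fit_difference_model(thin), "2 paired epochs")
})

test_that("TDI and CP are mutually consistent and monotone", {
  for (m in c(10, 85.69, 200)) {
    # exact at zero bias: P(|D| <= tdi(p)) = p
    expect_equal(coverage_probability(0, m, total_deviation_index(m, 0.95)),
                 0.95, tolerance = 1e-9)
    expect_lt(total_deviation_index(m, 0.90), total_deviation_index(m, 0.95))
  }
  cps <- vapply(c(5, 10, 20), function(cad)
    coverage_probability(-1.91, 85.69, cad), numeric(1))
  expect_true(all(diff(cps) > 0))
  tdis <- vapply(c(10, 85.69, 200), total_deviation_index, numeric(1),
                 p = 0.95)
  expect_true(all(diff(tdis) > 0))
})

test_that("per-phase reports isolate a high-HR error to the stress phases", {
  cfg <- simulation_config(n_subjects = 20, seed = 19)
  p <- paired_from_models(
    cfg, identity_model("ecg"),
    device_error_model("fb", bias_hr_slope = -0.4, knee = 90, noise_sd = 1))
  byp <- agreement_by_phase(p)
  get <- function(ph, col) byp[byp$phase == ph, col]
  expect_gt(get("relaxation", "cia"), get("oral", "cia"))
  expect_gt(get("relaxation", "cp"), get("oral", "cp"))
  # CP ordering is the inverse of the MSD ordering (small per-phase bias)
  expect_equal(order(byp$cp), rev(order(byp$msd)))
})

test_that("identical devices give the perfect-agreement row everywhere", {
  cfg <- quick_config(n_subjects = 4, seed = 29)
  p <- paired_from_models(cfg, identity_model("ecg"), identity_model("fb"))
  byp <- agreement_by_phase(p)
  expect_equal(byp$bias, rep(0, 4))
  expect_equal(byp$cp, rep(1, 4))
  expect_equal(byp$ccc, rep(1, 4))
  expect_equal(byp$cia, rep(1, 4))
  expect_equal(byp$msd, rep(0, 4))
})

test_that("agreement_report returns coherent intervals when bootstrapped", {
  cfg <- quick_config(n_subjects = 8, seed = 37,
                      durations = c(40, 20, 40, 40, 40))
  p <- paired_from_models(
    cfg, device_error_model("ecg", noise_sd = 1),
    device_error_model("fb", noise_sd = 3, bias_intercept = -2,
                       subject_bias_sd = 2))
  rep <- agreement_report(p, conf = TRUE, B = 120, seed = 3)
  expect_true(all(rep$ci[, "lower"] <= rep$overall + 1e-9))
  expect_true(all(rep$ci[, "upper"] >= rep$overall - 1e-9))
  expect_equal(rownames(rep$ci),
               c("bias", "loa_lower", "loa_upper", "msd", "cp", "tdi",
                 "ccc", "cia", "rc"))
})
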