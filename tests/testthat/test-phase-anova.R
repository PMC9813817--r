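# Small balanced random-effects dataset built directly (not via the study
# generator) so the fitted model matches the generating model exactly.
anova_data <- function(n_subjects = 10, epochs = 6,
                       means = c(relaxation = 72, anticipation = 80,
                                 arithmetic = 86, oral = 90),
                       s2_subj = 30, s2_int = 10, s2_e = 25, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(s) {
    a <- rnorm(1, 0, sqrt(s2_subj))
    g <- rnorm(length(means), 0, sqrt(s2_int))
    do.call(rbind, lapply(seq_along(means), function(p) {
      data.frame(subject = s, phase = names(means)[p],
                 bpm = means[p] + a + g[p] + rnorm(epochs, 0, sqrt(s2_e)))
    }))
  })
  do.call(rbind, rows)
}

test_that("the phase model enforces its preconditions", {
  d <- anova_data(n_subjects = 4, epochs = 3)
  expect_error(fit_phase_model(d[d$phase == "oral", ]), "2 phases")
  expect_error(fit_phase_model(d[d$subject == 1, ]), "2 subjects")
  thin <- d[!(d$subject == 1 & d$phase == "oral"), ]
  thin <- rbind(thin, data.frame(subject = 1, phase = "oral", bpm = 80))
  expect_error(fit_phase_model(thin), "2 observations")
})

test_that("a near-noiseless design recovers phase contrasts with no interaction", {
  cfg <- quick_config(n_subjects = 6, seed = 2, sigma2_interaction = 0,
                      sigma2_resid = 1e-4)
  study <- generate_study(cfg, identity_model("ecg"), identity_model("fb"))
  lab <- label_and_merge(study, phase_schedule_from_config(cfg))
  fit <- suppressWarnings(fit_phase_model(lab, device = "ecg"))
  expect_lt(fit$vc[["interaction"]], 0.01)
  # the intercept absorbs the average subject effect, so phase means are
  # identified up to that shared offset: differences recover exactly
  ph <- c("relaxation", "anticipation", "arithmetic", "oral")
  est <- fit$fixed_effects[ph]
  expect_equal(unname(est - est["relaxation"]),
               unname(cfg$phase_means[ph] - cfg$phase_means["relaxation"]),
               tolerance = 1e-3)
  # and with no between-subject variance either, means come back exactly
  cfg0 <- quick_config(n_subjects = 4, seed = 2, sigma2_subject = 1e-6,
                       sigma2_interaction = 0, sigma2_resid = 1e-4)
  study0 <- generate_study(cfg0, identity_model("ecg"), identity_model("fb"))
  lab0 <- label_and_merge(study0, phase_schedule_from_config(cfg0))
  fit0 <- suppressWarnings(fit_phase_model(lab0, device = "ecg"))
  expect_equal(unname(fit0$fixed_effects[ph]), unname(cfg0$phase_means[ph]),
               tolerance = 0.005)
})

test_that("omnibus test uses 3 numerator df for four phases and a sane eta2", {
  fit <- fit_phase_model(anova_data(seed = 5))
  omn <- omnibus_test(fit)
  expect_equal(omn$df_num, 3)
  expect_gt(omn$df_den, 0)
  expect_lt(omn$p, 0.001)
  expect_true(omn$eta2_partial > 0 && omn$eta2_partial < 1)
  expect_true(omn$eta2_ci["lower"] <= omn$eta2_partial)
  expect_true(omn$eta2_ci["upper"] >= omn$eta2_partial)
})

test_that("partial eta squared and its CI match the F-statistic convention", {
  # F(3,103) = 44.03 corresponds to eta2 = .56 with 90% CI (.45, .64)
  f <- 44.03; df1 <- 3; df2 <- 103
  eta <- f * df1 / (f * df1 + df2)
  expect_equal(eta, 0.56, tolerance = 0.005)
  ci <- eta_squared_ci(f, df1, df2, level = 0.90)
  expect_lt(abs(ci[["lower"]] - 0.45), 0.015)
  expect_lt(abs(ci[["upper"]] - 0.64), 0.015)
})

test_that("REML results are invariant to phase relabeling", {
  d <- anova_data(seed = 8)
  fit1 <- fit_phase_model(d)
  d2 <- d
  # map to labels whose alphabetical order differs from the original
  map <- c(relaxation = "z_relax", anticipation = "a_anticip",
           arithmetic = "m_arith", oral = "b_oral")
  d2$phase <- unname(map[d2$phase])
  fit2 <- fit_phase_model(d2)
  expect_equal(fit1$vc, fit2$vc, tolerance = 1e-5)
  expect_equal(omnibus_test(fit1)$F, omnibus_test(fit2)$F, tolerance = 1e-5)
  expect_equal(sort(unname(fit1$fixed_effects)),
               sort(unname(fit2$fixed_effects)), tolerance = 1e-5)
})

test_that("adding a constant shifts means but not components, F or eta2", {
  d <- anova_data(seed = 9)
  fit1 <- fit_phase_model(d)
  d2 <- d; d2$bpm <- d2$bpm + 10
  fit2 <- fit_phase_model(d2)
  expect_equal(fit2$fixed_effects, fit1$fixed_effects + 10, tolerance = 1e-5)
  expect_equal(fit1$vc, fit2$vc, tolerance = 1e-4)
  o1 <- omnibus_test(fit1); o2 <- omnibus_test(fit2)
  expect_equal(o1$F, o2$F, tolerance = 1e-4)
  expect_equal(o1$eta2_partial, o2$eta2_partial, tolerance = 1e-5)
})

test_that("pairwise contrasts cover all pairs and Tukey never helps", {
  fit <- fit_phase_model(anova_data(seed = 3))
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 6)
  pairs <- apply(ct[, c("phase_i", "phase_j")], 1,
                 function(r) paste(sort(r), collapse = "|"))
  expect_equal(length(unique(pairs)), 6)

  emm <- emmeans::emmeans(fit$model, "phase", lmer.df = "satterthwaite")
  raw <- summary(emmeans::contrast(emm, "pairwise", adjust = "none"))
  expect_true(all(ct$adjusted_p >= raw$p.value - 1e-12))
})

test_that("a strongly ordered design makes all six contrasts significant", {
  d <- anova_data(n_subjects = 20, epochs = 8, s2_int = 2, s2_e = 9, seed = 12)
  ct <- pairwise_contrasts(fit_phase_model(d))
  expect_true(all(ct$adjusted_p < 0.01))
})
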