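# Shared builders for small synthetic fixtures (everything is generated in
# code; no stored data).

# A shortened TSST schedule keeps unit-test fits fast.
quick_config <- function(n_subjects = 8, seed = 1,
                         durations = c(60, 30, 60, 60, 60), ...) {
  sched <- tsst_schedule()
  sched$duration_s <- durations
  simulation_config(n_subjects = n_subjects, phase_schedule = sched,
                    seed = seed, ...)
}

identity_model <- function(label) device_error_model(label)

# Generate, label and pair a small two-device study in one call.
paired_from_models <- function(config, ref_model, test_model, epoch_s = 5) {
  study <- generate_study(config, ref_model, test_model)
  labeled <- label_and_merge(study, phase_schedule_from_config(config))
  pair_epochs(labeled, ref_model$device_label, test_model$device_label,
              epoch_s = epoch_s)
}

# Hand-built paired-epochs table from a vector of differences.
toy_paired <- function(diffs, subjects = rep(1, length(diffs)),
                       phases = rep("relaxation", length(diffs)),
                       hr_ref = rep(80, length(diffs))) {
  data.frame(subject = subjects, phase = phases,
             epoch_index = stats::ave(seq_along(diffs), subjects, phases,
                                      FUN = seq_along),
             hr_ref = hr_ref, hr_test = hr_ref + diffs, diff = diffs,
             stringsAsFactors = FALSE)
}

# Balanced two-device data from the classic bivariate model
# X = mu + alpha_s + e1, Y = mu + bias + alpha_s + e2.
bivariate_paired <- function(n_subjects, n_epochs, sigma2_subject, sigma2_e,
                             bias = 0, mu = 80, seed = 1) {
  set.seed(seed)
  alpha <- rnorm(n_subjects, 0, sqrt(sigma2_subject))
  rows <- lapply(seq_len(n_subjects), function(s) {
    x <- mu + alpha[s] + rnorm(n_epochs, 0, sqrt(sigma2_e))
    y <- mu + bias + alpha[s] + rnorm(n_epochs, 0, sqrt(sigma2_e))
    data.frame(subject = s, phase = "relaxation",
               epoch_index = seq_len(n_epochs), hr_ref = x, hr_test = y,
               diff = y - x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Lin's moment-based sample CCC (independent oracle for ccc_vc).
lin_ccc <- function(x, y) {
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * sxy / (mean((x - mean(x))^2) + mean((y - mean(y))^2) +
               (mean(x) - mean(y))^2)
}
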