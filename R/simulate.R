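# Synthetic TSST study generator: latent heart-rate trajectories shared by
# both devices, plus a configurable wearable sensing model layered on top.

.protocol_phases <- c("relaxation_pre", "anticipation", "oral", "arithmetic",
                      "relaxation_post")
.analysis_phases <- c("relaxation", "anticipation", "oral", "arithmetic")

#' Standard Trier Social Stress Test phase schedule
#'
#' Five protocol blocks: a 5-minute relaxation, a 3-minute anticipatory
#' stress period, a 5-minute oral (speech) task, a 5-minute mental
#' arithmetic task, and a closing 5-minute relaxation. The two relaxation
#' blocks are kept separate here; the analysis merges them into a single
#' "relaxation" phase (see [label_and_merge()]).
#'
#' @return A data.frame with columns `phase` and `duration_s`.
#' @export
tsst_schedule <- function() {
  data.frame(
    phase = .protocol_phases,
    duration_s = c(300, 180, 300, 300, 300),
    stringsAsFactors = FALSE
  )
}

#' Collapse the two relaxation blocks into one analysis phase
#'
#' @param phase character vector of protocol phase labels.
#' @return character vector with `relaxation_pre`/`relaxation_post` both
#'   relabelled `relaxation`.
#' @export
merge_phase <- function(phase) {
  sub("^relaxation_(pre|post)$", "relaxation", phase)
}

# Deterministic per-subject (and per-stream) seed derivation: adding subjects
# never perturbs earlier subjects' draws. Multiplicative mixing keeps nested
# derivations (study -> device -> subject) from colliding, unlike a plain
# additive scheme. All intermediates stay below 2^53, so doubles are exact.
derive_seed <- function(seed, unit, stream = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(as.numeric(stream), as.numeric(unit))) {
    h <- (h * 69069 + k * 1000003 + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Simulation design for a synthetic paired heart-rate study
#'
#' Defines the study conditions a generated dataset emulates: number of
#' subjects, phase schedule, phase mean heart rates and the between-subject,
#' subject-by-phase and within-phase variance components on the bpm^2 scale.
#' Defaults mirror a 34-subject TSST protocol with variance components
#' 116.57 (subject), 14.47 (subject x phase) and 29.72 (within-phase).
#'
#' The within-phase signal is a stationary AR(1) wander on the sampling grid
#' with autocorrelation `ar1_rho` and stationary variance `sigma2_resid`, so
#' the marginal per-epoch variance matches the residual component while
#' adjacent epochs remain positively correlated.
#'
#' @param n_subjects number of subjects (default 34).
#' @param phase_schedule data.frame of `phase`, `duration_s` in protocol
#'   order; see [tsst_schedule()].
#' @param phase_means named bpm means per merged analysis phase. The defaults
#'   respect the ordering relaxation < anticipation < arithmetic < oral that
#'   the protocol induces.
#' @param sigma2_subject between-subject variance (bpm^2).
#' @param sigma2_interaction subject-by-phase variance (bpm^2).
#' @param sigma2_resid within-phase (residual) variance (bpm^2).
#' @param ar1_rho lag-one autocorrelation of the within-phase wander on the
#'   sampling grid, in `[0, 1)`.
#' @param sample_interval_s sampling grid step in seconds.
#' @param seed master integer seed; per-subject streams are derived from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 34,
                              phase_schedule = tsst_schedule(),
                              phase_means = c(relaxation = 72, anticipation = 80,
                                              arithmetic = 86, oral = 90),
                              sigma2_subject = 116.57,
                              sigma2_interaction = 14.47,
                              sigma2_resid = 29.72,
                              ar1_rho = 0.3,
                              sample_interval_s = 5,
                              seed = 1L) {
  for (fld in c("sigma2_subject", "sigma2_interaction", "sigma2_resid")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", fld))
    }
  }
  if (n_subjects < 1) stop("`n_subjects` must be at least 1")
  if (!all(c("phase", "duration_s") %in% names(phase_schedule))) {
    stop("`phase_schedule` needs columns `phase` and `duration_s`")
  }
  if (any(phase_schedule$duration_s <= 0)) {
    stop("all phase durations must be positive")
  }
  needed <- unique(merge_phase(phase_schedule$phase))
  absent <- setdiff(needed, names(phase_means))
  if (length(absent)) {
    stop("`phase_means` missing phases: ", paste(absent, collapse = ", "))
  }
  canon <- c("relaxation", "anticipation", "arithmetic", "oral")
  present <- canon[canon %in% names(phase_means)]
  if (length(present) > 1 && !all(diff(phase_means[present]) > 0)) {
    stop("`phase_means` must be ordered relaxation < anticipation < arithmetic < oral")
  }
  if (ar1_rho < 0 || ar1_rho >= 1) stop("`ar1_rho` must lie in [0, 1)")
  if (sample_interval_s <= 0) stop("`sample_interval_s` must be positive")
  structure(
    list(n_subjects = as.integer(n_subjects),
         phase_schedule = phase_schedule,
         phase_means = phase_means,
         sigma2_subject = sigma2_subject,
         sigma2_interaction = sigma2_interaction,
         sigma2_resid = sigma2_resid,
         ar1_rho = ar1_rho,
         sample_interval_s = sample_interval_s,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Stationary AR(1) with given marginal sd.
ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  }
  x
}

#' Generate latent (true) heart-rate trajectories
#'
#' Draws, for every subject, a subject intercept `a_s ~ N(0, sigma2_subject)`,
#' one subject-by-phase deviation `g_sp ~ N(0, sigma2_interaction)` per merged
#' phase (shared by the two relaxation blocks), and a stationary AR(1) wander
#' per protocol block, giving
#' `true_hr(s, p, t) = phase_means[p] + a_s + g_sp + w_spt`.
#' Deterministic given the config seed; each subject has its own derived
#' stream, so enlarging the study leaves earlier subjects unchanged.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `subject`, `phase` (protocol block label),
#'   `time_s` (protocol-relative seconds) and `true_hr` (bpm).
#' @export
generate_latent <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a `sim_config`")
  sched <- config$phase_schedule
  step <- config$sample_interval_s
  starts <- cumsum(c(0, utils::head(sched$duration_s, -1)))
  merged <- unique(merge_phase(sched$phase))
  per_subject <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, i, stream = 0L))
    a_i <- stats::rnorm(1, 0, sqrt(config$sigma2_subject))
    g <- stats::rnorm(length(merged), 0, sqrt(config$sigma2_interaction))
    names(g) <- merged
    blocks <- vector("list", nrow(sched))
    for (b in seq_len(nrow(sched))) {
      n_pts <- floor(sched$duration_s[b] / step)
      mp <- merge_phase(sched$phase[b])
      w <- ar1_series(n_pts, config$ar1_rho, sqrt(config$sigma2_resid))
      blocks[[b]] <- data.frame(
        subject = i,
        phase = sched$phase[b],
        time_s = starts[b] + seq(0, by = step, length.out = n_pts),
        true_hr = config$phase_means[[mp]] + a_i + g[[mp]] + w,
        stringsAsFactors = FALSE
      )
    }
    per_subject[[i]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, per_subject)
  rownames(out) <- NULL
  if (any(out$true_hr <= 0)) {
    stop("generated heart rate fell to zero or below; check variance settings")
  }
  attr(out, "config") <- config
  out
}

#' Wearable/reference device sensing model
#'
#' Describes how a device distorts the latent heart rate it observes: a
#' constant calibration bias, a proportional under/over-read above a knee
#' (wrist optical sensors typically under-read at high heart rates), white
#' measurement noise, a reporting lag, random epoch dropout, integer
#' quantization, a per-subject calibration offset (wear position/anatomy),
#' and optional phase-specific effects (e.g. motion artefact during a
#' specific task) given as extra per-subject bias and a noise multiplier.
#'
#' @param device_label identifier, e.g. `"ecg"` or `"fitbit"`.
#' @param bias_intercept constant bias (bpm).
#' @param bias_hr_slope slope applied to `max(0, true_hr - knee)` (bpm/bpm).
#' @param knee heart rate above which the proportional bias engages (bpm).
#' @param noise_sd white measurement noise SD (bpm), `>= 0`.
#' @param lag_s reporting lag in seconds (the device reports the latent value
#'   `lag_s` earlier).
#' @param dropout_prob per-epoch probability a reading is missing, in `[0, 1)`.
#' @param quantize if `TRUE`, output is rounded to integer bpm.
#' @param subject_bias_sd SD of a per-subject constant calibration offset (bpm).
#' @param phase_effects optional named list, one entry per merged phase, each
#'   a list with any of `bias_mean`, `bias_sd` (bpm; an extra per-subject bias
#'   drawn once per subject and phase) and `noise_scale` (multiplier on
#'   `noise_sd` within that phase).
#' @return An object of class `device_model`.
#' @export
device_error_model <- function(device_label,
                               bias_intercept = 0,
                               bias_hr_slope = 0,
                               knee = 90,
                               noise_sd = 0,
                               lag_s = 0,
                               dropout_prob = 0,
                               quantize = FALSE,
                               subject_bias_sd = 0,
                               phase_effects = NULL) {
  if (missing(device_label) || !nzchar(device_label)) {
    stop("`device_label` is required")
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("`dropout_prob` must lie in [0, 1)")
  }
  if (subject_bias_sd < 0) stop("`subject_bias_sd` must be non-negative")
  if (lag_s < 0) stop("`lag_s` must be non-negative")
  if (!is.null(phase_effects)) {
    if (is.null(names(phase_effects)) || any(!nzchar(names(phase_effects)))) {
      stop("`phase_effects` must be a named list keyed by phase")
    }
    phase_effects <- lapply(phase_effects, function(pe) {
      list(bias_mean = pe$bias_mean %||% 0,
           bias_sd = pe$bias_sd %||% 0,
           noise_scale = pe$noise_scale %||% 1)
    })
  }
  structure(
    list(device_label = device_label, bias_intercept = bias_intercept,
         bias_hr_slope = bias_hr_slope, knee = knee, noise_sd = noise_sd,
         lag_s = lag_s, dropout_prob = dropout_prob, quantize = quantize,
         subject_bias_sd = subject_bias_sd, phase_effects = phase_effects),
    class = "device_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observe latent trajectories through a device
#'
#' Applies the sensing model:
#' `observed(t) = true_hr(t - lag) + bias_intercept +
#'   bias_hr_slope * max(0, true_hr(t - lag) - knee) + subject/phase offsets +
#'   N(0, noise_sd^2)`, followed by dropout and optional integer quantization.
#' Dropout draws come from a stream keyed by `dropout_seed` and subject only,
#' never by device, so two devices run with the same `dropout_seed` and the
#' same `dropout_prob` lose exactly the same epochs.
#'
#' @param latent output of [generate_latent()].
#' @param model a [device_error_model()].
#' @param seed integer seed for the device's noise and bias draws.
#' @param dropout_seed seed for the dropout stream (default `seed`); share it
#'   across devices of one study.
#' @return data.frame with columns `subject`, `device`, `phase`,
#'   `epoch_time_s`, `bpm`.
#' @export
apply_device <- function(latent, model, seed, dropout_seed = seed) {
  if (!inherits(model, "device_model")) stop("`model` must be a `device_model`")
  if (is.null(latent) || !nrow(latent)) stop("latent trajectories are empty")
  cfg <- attr(latent, "config")
  step <- if (!is.null(cfg)) cfg$sample_interval_s else {
    stats::median(diff(sort(unique(latent$time_s[latent$subject == latent$subject[1]]))))
  }
  block_len <- tapply(latent$time_s, list(latent$subject, latent$phase), length)
  shortest <- min(block_len, na.rm = TRUE) * step
  if (model$lag_s >= shortest) {
    stop(sprintf("`lag_s` (%gs) is not shorter than the shortest phase (%gs)",
                 model$lag_s, shortest))
  }
  k <- round(model$lag_s / step)
  subjects <- unique(latent$subject)
  out <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    rows <- latent[latent$subject == subjects[j], , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    hr <- rows$true_hr
    lagged <- hr[pmax(seq_along(hr) - k, 1L)]
    mphase <- merge_phase(rows$phase)
    set.seed(derive_seed(seed, j, stream = 1L))
    subj_bias <- if (model$subject_bias_sd > 0) {
      stats::rnorm(1, 0, model$subject_bias_sd)
    } else 0
    extra_bias <- numeric(length(hr))
    scale <- rep(1, length(hr))
    if (!is.null(model$phase_effects)) {
      for (p in names(model$phase_effects)) {
        pe <- model$phase_effects[[p]]
        b_p <- stats::rnorm(1, pe$bias_mean, pe$bias_sd)
        sel <- mphase == p
        extra_bias[sel] <- b_p
        scale[sel] <- pe$noise_scale
      }
    }
    noise <- if (model$noise_sd > 0) {
      stats::rnorm(length(hr), 0, model$noise_sd) * scale
    } else numeric(length(hr))
    obs <- lagged + model$bias_intercept +
      model$bias_hr_slope * pmax(0, lagged - model$knee) +
      subj_bias + extra_bias + noise
    if (model$quantize) obs <- round(obs)
    keep <- rep(TRUE, length(obs))
    if (model$dropout_prob > 0) {
      set.seed(derive_seed(dropout_seed, j, stream = 2L))
      keep <- stats::runif(length(obs)) >= model$dropout_prob
    }
    out[[j]] <- data.frame(
      subject = rows$subject[keep],
      device = model$device_label,
      phase = rows$phase[keep],
      epoch_time_s = rows$time_s[keep],
      bpm = obs[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a full paired two-device study
#'
#' Draws one set of latent trajectories and observes it through a reference
#' and a test device model. Both devices share the latent signal and the
#' dropout stream; their measurement-noise streams are independent.
#'
#' @param config a [simulation_config()].
#' @param ref_model,test_model [device_error_model()]s with distinct labels.
#' @return Long-format data.frame (`subject`, `device`, `phase`,
#'   `epoch_time_s`, `bpm`) with the config attached as attribute `"config"`.
#' @export
generate_study <- function(config, ref_model, test_model) {
  if (identical(ref_model$device_label, test_model$device_label)) {
    stop("reference and test device labels must differ")
  }
  latent <- generate_latent(config)
  drop_seed <- derive_seed(config$seed, 7L, stream = 3L)
  ref <- apply_device(latent, ref_model,
                      seed = derive_seed(config$seed, 101L, stream = 3L),
                      dropout_seed = drop_seed)
  tst <- apply_device(latent, test_model,
                      seed = derive_seed(config$seed, 202L, stream = 3L),
                      dropout_seed = drop_seed)
  study <- rbind(ref, tst)
  rownames(study) <- NULL
  attr(study, "config") <- config
  study
}

#' Write a generated study to CSV with a JSON sidecar
#'
#' Emits the long-format dialect consumed by [read_hr_csv()] (header
#' `subject,device,phase,epoch_time_s,bpm`) plus `<path>.json` echoing the
#' full simulation configuration and seed.
#'
#' @param study output of [generate_study()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  utils::write.csv(study[, c("subject", "device", "phase", "epoch_time_s", "bpm")],
                   path, row.names = FALSE)
  cfg <- attr(study, "config")
  if (!is.null(cfg)) {
    side <- paste0(sub("\\.csv$", "", path), ".json")
    jsonlite::write_json(unclass(cfg), side, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Phase schedule implied by a simulation config
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `phase`, `start_s`, `end_s` (half-open
#'   protocol-relative windows), suitable for [label_and_merge()].
#' @export
phase_schedule_from_config <- function(config) {
  sched <- config$phase_schedule
  starts <- cumsum(c(0, utils::head(sched$duration_s, -1)))
  data.frame(phase = sched$phase, start_s = starts,
             end_s = starts + sched$duration_s, stringsAsFactors = FALSE)
}
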