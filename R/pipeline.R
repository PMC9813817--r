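# End-to-end orchestration: from a run configuration (simulated study or
# CSV inputs) to a report bundle of CSV/JSON tables and figures.

#' Build a run configuration
#'
#' Exactly one of `simulation` (a list with `config`, `ref_model`,
#' `test_model`) or `input` (a list with `hr_csv` and `schedule_csv`) must
#' be supplied.
#'
#' @param simulation list with a [simulation_config()] and two
#'   [device_error_model()]s (`ref_model`, `test_model`).
#' @param input list with paths `hr_csv` and `schedule_csv`.
#' @param ref_device,test_device device labels; default to the simulation
#'   models' labels when simulating.
#' @param epoch_s pairing epoch length in seconds.
#' @param cad clinically acceptable difference (bpm).
#' @param mape_threshold MAPE acceptability threshold (percent).
#' @param tdi_p TDI containment probability.
#' @param loa_level limits-of-agreement level.
#' @param bootstrap list with `B`, `seed`, `method`.
#' @param seed master seed echoed into the run log.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, input = NULL,
                       ref_device = NULL, test_device = NULL,
                       epoch_s = 5, cad = 10, mape_threshold = 10,
                       tdi_p = 0.95, loa_level = 0.95,
                       bootstrap = list(B = 5000, seed = 1, method = "bca"),
                       seed = 1L) {
  if (is.null(simulation) == is.null(input)) {
    stop("exactly one of `simulation` or `input` must be given")
  }
  if (!is.null(simulation)) {
    need <- c("config", "ref_model", "test_model")
    absent <- setdiff(need, names(simulation))
    if (length(absent)) {
      stop("`simulation` missing: ", paste(absent, collapse = ", "))
    }
    ref_device <- ref_device %||% simulation$ref_model$device_label
    test_device <- test_device %||% simulation$test_model$device_label
  } else {
    need <- c("hr_csv", "schedule_csv")
    absent <- setdiff(need, names(input))
    if (length(absent)) stop("`input` missing: ", paste(absent, collapse = ", "))
    if (is.null(ref_device) || is.null(test_device)) {
      stop("`ref_device` and `test_device` are required with file input")
    }
  }
  bootstrap$B <- bootstrap$B %||% 5000
  bootstrap$seed <- bootstrap$seed %||% 1
  bootstrap$method <- bootstrap$method %||% "bca"
  structure(
    list(simulation = simulation, input = input, ref_device = ref_device,
         test_device = test_device, epoch_s = epoch_s, cad = cad,
         mape_threshold = mape_threshold, tdi_p = tdi_p,
         loa_level = loa_level, bootstrap = bootstrap,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' File-based runs only (`input:` block with `hr_csv`, `schedule_csv`,
#' `ref_device`, `test_device`, plus any of the analysis settings accepted
#' by [run_config()]).
#'
#' @param path YAML file path.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    input = y$input,
    ref_device = y$ref_device %||% y$input$ref_device,
    test_device = y$test_device %||% y$input$test_device,
    epoch_s = y$epoch_s %||% 5,
    cad = y$cad %||% 10,
    mape_threshold = y$mape_threshold %||% 10,
    tdi_p = y$tdi_p %||% 0.95,
    loa_level = y$loa_level %||% 0.95,
    bootstrap = y$bootstrap %||% list(B = 5000, seed = 1, method = "bca"),
    seed = y$seed %||% 1L
  )
}

#' Default synthetic study scenario
#'
#' A ready-made [run_config()] emulating a 34-subject TSST validation
#' study: an essentially exact reference electrocardiogram and a wrist
#' wearable that under-reads above 90 bpm, carries a per-subject
#' calibration offset, quantizes to integer bpm, occasionally drops epochs,
#' and suffers extra systematic error plus inflated noise during the
#' anticipation phase (motion and speech-preparation artefacts), the phase
#' the wearable handles worst.
#'
#' @param n_subjects number of subjects.
#' @param seed master seed.
#' @param B bootstrap replicates for the report CIs (`0` disables).
#' @return An object of class `run_config`.
#' @export
tsst_study_config <- function(n_subjects = 34, seed = 1L, B = 5000) {
  cfg <- simulation_config(n_subjects = n_subjects, seed = seed)
  ref <- device_error_model("ecg", noise_sd = 1.5)
  tst <- device_error_model(
    "fitbit",
    bias_hr_slope = -0.30, knee = 90, noise_sd = 5,
    subject_bias_sd = 3, dropout_prob = 0.02, quantize = TRUE,
    phase_effects = list(
      anticipation = list(bias_mean = -6, bias_sd = 7, noise_scale = 1.5)
    )
  )
  run_config(
    simulation = list(config = cfg, ref_model = ref, test_model = tst),
    bootstrap = list(B = B, seed = seed, method = "bca"),
    seed = seed
  )
}

#' Bland-Altman plot of paired epochs
#'
#' Between-device difference against the pair mean, with solid lines at the
#' bias and limits of agreement and optional dashed confidence bounds.
#'
#' @param paired output of [pair_epochs()].
#' @param loa named vector `c(bias, lower, upper)` from [loa_mixed()].
#' @param ci optional matrix of CI bounds with rows `bias`, `loa_lower`,
#'   `loa_upper` and columns `lower`, `upper`.
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(paired, loa, ci = NULL) {
  d <- data.frame(avg = (paired$hr_ref + paired$hr_test) / 2,
                  diff = paired$diff)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = unname(loa["bias"])) +
    ggplot2::geom_hline(yintercept = unname(loa["lower"])) +
    ggplot2::geom_hline(yintercept = unname(loa["upper"])) +
    ggplot2::labs(x = "Mean of devices (bpm)",
                  y = "Test - reference (bpm)")
  if (!is.null(ci)) {
    for (r in intersect(rownames(ci), c("bias", "loa_lower", "loa_upper"))) {
      p <- p +
        ggplot2::geom_hline(yintercept = ci[r, "lower"], linetype = "dashed") +
        ggplot2::geom_hline(yintercept = ci[r, "upper"], linetype = "dashed")
    }
  }
  p
}

#' Boxplots of heart rate by phase and device
#'
#' @param labeled output of [label_and_merge()].
#' @return a ggplot object.
#' @export
phase_boxplot <- function(labeled) {
  d <- labeled
  canon <- .analysis_phases[.analysis_phases %in% unique(d$phase)]
  d$phase <- factor(d$phase, levels = union(canon, unique(d$phase)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = .data$bpm,
                                  fill = .data$device)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Experimental phase", y = "Heart rate (bpm)")
}

write_fig <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
}

#' Run the full validation pipeline
#'
#' Simulates (or reads) the paired study, labels phases and merges the two
#' relaxations, aligns the devices on shared epochs, and runs the phase
#' ANOVA, the accuracy report and the agreement report, writing all tables
#' (CSV/JSON), the Bland-Altman and phase-boxplot figures with their
#' underlying CSVs, and a run log with every seed. Outputs are
#' deterministic given the configuration: re-running the same config
#' reproduces the bundle byte for byte (figures aside).
#'
#' A stage failure marks the bundle as failed and records the stage's
#' diagnostic; earlier outputs are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the computed objects, the written file
#'   paths, `failed` and `errors`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(files = character(), failed = FALSE, errors = list())
  stage <- function(name, expr) {
    if (bundle$failed) return(NULL)
    tryCatch(expr, error = function(e) {
      bundle$failed <<- TRUE
      bundle$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  emit <- function(name) {
    bundle$files <<- c(bundle$files, file.path(out_dir, name))
    file.path(out_dir, name)
  }

  # -- data stage ----------------------------------------------------------
  dat <- stage("data", {
    if (!is.null(config$simulation)) {
      study <- generate_study(config$simulation$config,
                              config$simulation$ref_model,
                              config$simulation$test_model)
      write_study_csv(study, emit("study.csv"))
      list(hr = study,
           schedule = phase_schedule_from_config(config$simulation$config))
    } else {
      list(hr = read_hr_csv(config$input$hr_csv,
                            devices = c(config$ref_device,
                                        config$test_device)),
           schedule = utils::read.csv(config$input$schedule_csv,
                                      stringsAsFactors = FALSE))
    }
  })
  bundle$schedule <- dat$schedule

  labeled <- stage("label", label_and_merge(dat$hr, dat$schedule))
  paired <- stage("pair", {
    p <- pair_epochs(labeled, config$ref_device, config$test_device,
                     epoch_s = config$epoch_s)
    utils::write.csv(p, emit("paired_epochs.csv"), row.names = FALSE)
    p
  })

  anova_res <- stage("anova", {
    fit <- fit_phase_model(labeled, device = config$test_device)
    omn <- omnibus_test(fit)
    ctr <- pairwise_contrasts(fit)
    jsonlite::write_json(
      list(omnibus = omn, variance_components = as.list(fit$vc),
           fixed_effects = as.list(fit$fixed_effects),
           n_obs = fit$n_obs, n_subjects = fit$n_subjects,
           singular = fit$singular),
      emit("anova.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(ctr, emit("contrasts.csv"), row.names = FALSE)
    list(fit = fit, omnibus = omn, contrasts = ctr)
  })

  acc <- stage("accuracy", {
    a <- accuracy_by_phase(paired, cad = config$cad,
                           mape_threshold = config$mape_threshold,
                           B = config$bootstrap$B,
                           seed = config$bootstrap$seed)
    utils::write.csv(a, emit("accuracy.csv"), row.names = FALSE)
    a
  })

  agree <- stage("agreement", {
    rep <- agreement_report(paired, cad = config$cad, tdi_p = config$tdi_p,
                            loa_level = config$loa_level,
                            conf = config$bootstrap$B > 0,
                            B = config$bootstrap$B,
                            seed = config$bootstrap$seed)
    jsonlite::write_json(
      list(overall = as.list(rep$overall),
           ci = if (!is.null(rep$ci)) {
             stats::setNames(apply(rep$ci, 1, as.list), rownames(rep$ci))
           },
           by_phase = rep$by_phase,
           settings = list(cad = rep$cad, tdi_p = rep$tdi_p,
                           loa_level = rep$loa_level, B = rep$B,
                           seed = rep$seed)),
      emit("agreement.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(rep$by_phase, emit("agreement.csv"), row.names = FALSE)
    rep
  })

  stage("figures", {
    loa <- c(bias = unname(agree$overall["bias"]),
             lower = unname(agree$overall["loa_lower"]),
             upper = unname(agree$overall["loa_upper"]))
    ba <- data.frame(avg = (paired$hr_ref + paired$hr_test) / 2,
                     diff = paired$diff)
    utils::write.csv(ba, emit("bland_altman.csv"), row.names = FALSE)
    ba_ci <- if (!is.null(agree$ci)) {
      agree$ci[c("bias", "loa_lower", "loa_upper"), , drop = FALSE]
    }
    write_fig(bland_altman_plot(paired, loa, ci = ba_ci),
              emit("bland_altman.png"))
    write_fig(phase_boxplot(labeled), emit("phase_boxplot.png"))
    NULL
  })

  stage("log", {
    jsonlite::write_json(
      list(seed = config$seed, bootstrap = config$bootstrap,
           epoch_s = config$epoch_s, cad = config$cad,
           mape_threshold = config$mape_threshold, tdi_p = config$tdi_p,
           loa_level = config$loa_level,
           ref_device = config$ref_device, test_device = config$test_device,
           simulated = !is.null(config$simulation),
           simulation = if (!is.null(config$simulation)) {
             unclass(config$simulation$config)
           },
           device_models = if (!is.null(config$simulation)) {
             list(ref = unclass(config$simulation$ref_model),
                  test = unclass(config$simulation$test_model))
           },
           package_version = as.character(utils::packageVersion("hragree"))),
      emit("run_log.json"), auto_unbox = TRUE, digits = NA)
    NULL
  })

  bundle$labeled <- labeled
  bundle$paired <- paired
  bundle$anova <- anova_res
  bundle$accuracy <- acc
  bundle$agreement <- agree
  invisible(bundle)
}
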