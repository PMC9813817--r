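# Measurement-error indices of the test device against the reference:
# MAE and MAPE per phase and overall, judged against a clinically
# acceptable difference (CAD, default +/-10 bpm) and a 10% MAPE threshold.

#' Mean absolute error with a cluster-bootstrap CI
#'
#' @param paired output of [pair_epochs()].
#' @param conf compute a subject-level BCa bootstrap CI (default TRUE).
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return list with `mae`, `sd` (SD of the absolute errors) and `ci`.
#' @export
mae <- function(paired, conf = TRUE, B = 1000, seed = 1, level = 0.95) {
  if (is.null(paired) || !nrow(paired)) stop("no paired epochs")
  if (nrow(paired) < 2) stop("need at least 2 paired epochs")
  abs_err <- abs(paired$diff)
  ci <- c(lower = NA_real_, upper = NA_real_)
  if (conf && length(unique(paired$subject)) >= 2) {
    bc <- boot_ci(paired, function(d) mean(abs(d$diff)), B = B, seed = seed,
                  level = level)
    ci <- c(lower = unname(bc$ci[1, "lower"]),
            upper = unname(bc$ci[1, "upper"]))
  }
  list(mae = mean(abs_err), sd = stats::sd(abs_err), ci = ci)
}

#' Mean absolute percentage error
#'
#' `mean(|test - ref| / ref) * 100`, requiring strictly positive reference
#' heart rates.
#'
#' @param paired output of [pair_epochs()].
#' @return percentage (scalar).
#' @export
mape <- function(paired) {
  if (is.null(paired) || !nrow(paired)) stop("no paired epochs")
  if (any(paired$hr_ref <= 0)) {
    stop("all reference heart rates must be positive for MAPE")
  }
  mean(abs(paired$diff) / paired$hr_ref) * 100
}

#' Accuracy report per phase and overall
#'
#' One row per phase plus a pooled `overall` row, each with MAE, the SD of
#' the absolute error, a subject-level BCa bootstrap CI for the MAE, MAPE,
#' and a pass flag requiring `MAE < cad` and `MAPE < mape_threshold`.
#' Phases observed in fewer than 2 subjects get an `NA` interval.
#'
#' @param paired output of [pair_epochs()].
#' @param cad clinically acceptable difference in bpm (default 10).
#' @param mape_threshold MAPE acceptability threshold in percent (default 10).
#' @param B,seed,level bootstrap settings for the MAE interval; `B = 0`
#'   skips interval computation.
#' @return data.frame of class `accuracy_report`.
#' @export
accuracy_by_phase <- function(paired, cad = 10, mape_threshold = 10,
                              B = 1000, seed = 1, level = 0.95) {
  if (length(unique(paired$phase)) < 2) {
    stop("need at least 2 phases for a per-phase accuracy report")
  }
  groups <- c(sort(unique(paired$phase)), "overall")
  rows <- lapply(groups, function(g) {
    d <- if (g == "overall") paired else paired[paired$phase == g, , drop = FALSE]
    n_subj <- length(unique(d$subject))
    conf <- B > 0 && n_subj >= 2
    m <- mae(d, conf = conf, B = B, seed = seed, level = level)
    mp <- mape(d)
    data.frame(phase = g, n_epochs = nrow(d), n_subjects = n_subj,
               mae = m$mae, sd_abs_err = m$sd,
               ci_lower = unname(m$ci["lower"]),
               ci_upper = unname(m$ci["upper"]),
               mape = mp,
               pass = m$mae < cad && mp < mape_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cad") <- cad
  attr(out, "mape_threshold") <- mape_threshold
  class(out) <- c("accuracy_report", "data.frame")
  out
}
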