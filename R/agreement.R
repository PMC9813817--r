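# Repeated-measures agreement metrics for paired device readings, all
# derived from mixed-model variance components: mixed-effects limits of
# agreement, mean squared deviation (MSD), coverage probability (CP),
# total deviation index (TDI), coefficient of individual agreement (CIA),
# repeatability coefficient (RC) and the variance-components concordance
# correlation coefficient (CCC).

#' Construct a difference-model fit from known components
#'
#' Lightweight constructor for desk calculations and testing: packages a
#' bias and difference-scale variance components into the object
#' [loa_mixed()] and [msd()] consume, without fitting anything.
#'
#' @param bias mean between-device difference (bpm).
#' @param sigma2_subject,sigma2_interaction,sigma2_resid variance components
#'   of the differences (bpm^2): subject, subject-by-phase, residual.
#' @return An object of class `diff_fit`.
#' @export
difference_fit <- function(bias, sigma2_subject = 0, sigma2_interaction = 0,
                           sigma2_resid = 0) {
  vc <- c(subject = sigma2_subject, interaction = sigma2_interaction,
          resid = sigma2_resid)
  if (any(vc < 0)) stop("variance components must be non-negative")
  structure(
    list(bias = bias, vc_diff = vc, total_var_diff = sum(vc), model = NULL,
         degenerate = sum(vc) == 0, singular = FALSE,
         n_subjects = NA_integer_, n_obs = NA_integer_),
    class = "diff_fit"
  )
}

#' Mixed-effects model of the between-device differences
#'
#' REML fit of `diff ~ 1 + (1 | subject) + (1 | subject:phase)` (the
#' interaction term is dropped for single-phase data), accounting for the
#' repeated-measures structure of the differences. The bias is the fixed
#' intercept. Exactly constant differences short-circuit to a degenerate
#' fit with all components zero.
#'
#' @param paired output of [pair_epochs()].
#' @return An object of class `diff_fit`; see [difference_fit()].
#' @export
fit_difference_model <- function(paired) {
  if (is.null(paired) || !nrow(paired)) stop("no paired epochs")
  subs <- table(paired$subject)
  if (length(subs) < 2) stop("need at least 2 subjects")
  if (any(subs < 2)) stop("every subject needs at least 2 paired epochs")
  if (stats::var(paired$diff) < 1e-12) {
    out <- difference_fit(mean(paired$diff))
    out$n_subjects <- length(subs)
    out$n_obs <- nrow(paired)
    return(out)
  }
  d <- paired
  d$subject <- factor(d$subject)
  d$phase <- factor(d$phase)
  multi_phase <- nlevels(d$phase) >= 2
  form <- if (multi_phase) {
    diff ~ 1 + (1 | subject) + (1 | subject:phase)
  } else {
    diff ~ 1 + (1 | subject)
  }
  m <- lmerTest::lmer(form, data = d, REML = TRUE)
  if (!is.null(m@optinfo$conv$opt) && m@optinfo$conv$opt != 0) {
    stop("difference model did not converge: ",
         paste(unlist(m@optinfo$conv$lme4$messages), collapse = "; "))
  }
  vc <- extract_vc(m)
  structure(
    list(bias = unname(lme4::fixef(m)[1]), vc_diff = vc,
         total_var_diff = sum(vc), model = m, degenerate = FALSE,
         singular = lme4::isSingular(m),
         n_subjects = nlevels(d$subject), n_obs = nrow(d)),
    class = "diff_fit"
  )
}

#' Mixed-effects limits of agreement
#'
#' `bias +/- z * sqrt(total_var_diff)` with `z` the standard normal quantile
#' at `(1 + level) / 2`, the total variance pooling all difference-scale
#' components from the mixed model.
#'
#' @param fit a `diff_fit`.
#' @param level LoA level (default 0.95).
#' @return named vector `c(bias, lower, upper)` in bpm.
#' @export
loa_mixed <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "diff_fit"))
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(fit$total_var_diff)
  c(bias = fit$bias, lower = fit$bias - half, upper = fit$bias + half)
}

#' Mean squared deviation
#'
#' Expected squared between-device difference for the same subject at the
#' same moment: `bias^2 + total_var_diff`.
#'
#' @param fit a `diff_fit`.
#' @return MSD in bpm^2.
#' @export
msd <- function(fit) {
  stopifnot(inherits(fit, "diff_fit"))
  fit$bias^2 + fit$total_var_diff
}

#' Coverage probability of the clinically acceptable difference
#'
#' Probability that a between-device difference lies within `[-cad, cad]`
#' under a normal model with mean `bias` and variance `msd - bias^2`:
#' `CP = Phi((cad - bias)/sigma) - Phi((-cad - bias)/sigma)`. A zero
#' variance degenerates to the indicator of `|bias| <= cad`.
#'
#' @param bias mean difference (bpm).
#' @param msd mean squared deviation (bpm^2), at least `bias^2`.
#' @param cad clinically acceptable difference (bpm), positive.
#' @return probability in `[0, 1]`.
#' @export
coverage_probability <- function(bias, msd, cad) {
  if (cad <= 0) stop("`cad` must be positive")
  if (msd < bias^2 - 1e-9) stop("`msd` must be at least bias^2")
  s2 <- max(msd - bias^2, 0)
  if (s2 == 0) return(as.numeric(abs(bias) <= cad))
  s <- sqrt(s2)
  stats::pnorm((cad - bias) / s) - stats::pnorm((-cad - bias) / s)
}

#' Total deviation index
#'
#' Normal-approximation boundary containing `p * 100%` of the absolute
#' between-device differences: `TDI = z_{(1+p)/2} * sqrt(MSD)`.
#'
#' @param msd mean squared deviation (bpm^2), non-negative.
#' @param p containment probability in (0, 1) (default 0.95).
#' @return TDI in bpm.
#' @export
total_deviation_index <- function(msd, p = 0.95) {
  if (msd < 0) stop("`msd` must be non-negative")
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  stats::qnorm((1 + p) / 2) * sqrt(msd)
}

#' Bland-Altman repeatability coefficient
#'
#' `RC = 1.96 * sqrt(2 * sigma2_resid)`: with ~95% probability two repeated
#' readings by the same device on the same subject differ by less than RC.
#'
#' @param sigma2_resid within-device replication (residual) variance (bpm^2).
#' @return RC in bpm.
#' @export
repeatability_coefficient <- function(sigma2_resid) {
  if (sigma2_resid < 0) stop("`sigma2_resid` must be non-negative")
  stats::qnorm(0.975) * sqrt(2 * sigma2_resid)
}

#' Coefficient of individual agreement
#'
#' Within-device replication disagreement relative to the between-device
#' disagreement, with the mean squared deviation as disagreement index:
#' `CIA = 2 * sigma2_resid / MSD`. Equals 1 when switching devices adds
#' nothing beyond replication error; values below ~0.8 are conventionally
#' read as poor individual-level interchangeability.
#'
#' @param sigma2_resid within-device replication (residual) variance (bpm^2).
#' @param msd mean squared deviation (bpm^2).
#' @return CIA (unitless, ~0 to 1).
#' @export
cia <- function(sigma2_resid, msd) {
  if (sigma2_resid < 0) stop("`sigma2_resid` must be non-negative")
  if (msd < 0) stop("`msd` must be non-negative")
  if (msd == 0) {
    if (sigma2_resid > 0) {
      stop("`msd` is zero but the residual variance is positive")
    }
    return(1)  # identical devices: perfect individual agreement
  }
  2 * sigma2_resid / msd
}

#' Interpretation band for a concordance correlation coefficient
#'
#' @param ccc CCC value.
#' @return `"poor"` (<0.90), `"moderate"` (0.90-0.95), `"substantial"`
#'   (0.95-0.99) or `"perfect"` (>0.99).
#' @export
classify_ccc <- function(ccc) {
  if (ccc < 0.90) "poor"
  else if (ccc < 0.95) "moderate"
  else if (ccc < 0.99) "substantial"
  else "perfect"
}

# Stack paired epochs into one long two-device frame.
stack_devices <- function(paired) {
  n <- nrow(paired)
  data.frame(
    subject = rep(paired$subject, 2),
    phase = rep(paired$phase, 2),
    epoch_index = rep(paired$epoch_index, 2),
    device = rep(c("ref", "test"), each = n),
    bpm = c(paired$hr_ref, paired$hr_test),
    stringsAsFactors = FALSE
  )
}

# Variance-components CCC point estimate plus the stacked-model residual
# variance (the within-device replication variance used by CIA and RC).
ccc_point <- function(paired) {
  if (max(abs(paired$diff)) < 1e-10) {
    return(list(ccc = 1, sigma2_resid = 0, sigma2_beta = 0,
                components = c(subject = NA_real_, interaction = NA_real_,
                               epoch = NA_real_, subject_device = NA_real_,
                               resid = 0)))
  }
  s <- stack_devices(paired)
  s$subject <- factor(s$subject)
  s$phase <- factor(s$phase)
  s$device <- factor(s$device, levels = c("ref", "test"))
  s$epoch_id <- interaction(s$subject, s$phase, s$epoch_index, drop = TRUE)
  multi_phase <- nlevels(s$phase) >= 2
  min_epochs <- min(table(paired$subject))
  terms <- c("(1 | subject)",
             if (multi_phase) "(1 | subject:phase)",
             if (min_epochs >= 2) "(1 | subject:device)",
             "(1 | epoch_id)")
  if (min_epochs < 2) {
    warning("fewer than 2 epochs per subject: subject-by-device term dropped")
  }
  rhs <- paste(c("device", if (multi_phase) "phase", terms), collapse = " + ")
  m <- lme4::lmer(stats::as.formula(paste("bpm ~", rhs)), data = s,
                  REML = TRUE,
                  control = lme4::lmerControl(calc.derivs = FALSE,
                                              check.conv.singular = "ignore"))
  vcdf <- as.data.frame(lme4::VarCorr(m))
  get1 <- function(grp) {
    v <- vcdf$vcov[vcdf$grp == grp]
    if (length(v)) v[1] else 0
  }
  s_subj <- get1("subject")
  s_int <- get1("subject:phase")
  s_sd <- get1("subject:device")
  s_ep <- get1("epoch_id")
  s_e <- get1("Residual")
  dcoef <- lme4::fixef(m)[["devicetest"]]
  s_beta <- dcoef^2 / 2
  ccc <- (s_subj + s_int + s_ep) /
    (s_subj + s_int + s_ep + s_sd + s_beta + s_e)
  list(ccc = ccc, sigma2_resid = s_e, sigma2_beta = s_beta,
       components = c(subject = s_subj, interaction = s_int, epoch = s_ep,
                      subject_device = s_sd, resid = s_e))
}

#' Concordance correlation coefficient from variance components
#'
#' Stacks the two devices and fits
#' `bpm ~ device + phase + (1|subject) + (1|subject:phase) +
#'  (1|subject:device) + (1|subject:phase:epoch)` by REML. The shared
#' epoch-level term captures the common temporal fluctuation both devices
#' track; as in the longitudinal variance-components CCC it counts as
#' agreement:
#' `CCC = (s2_subject + s2_subject.phase + s2_epoch) /
#'  (s2_subject + s2_subject.phase + s2_epoch + s2_subject.device +
#'   s2_beta + s2_e)`, with `s2_beta = (beta_test - beta_ref)^2 / 2` the
#' systematic device shift. The residual `s2_e` is the within-device
#' replication variance reused by [cia()] and
#' [repeatability_coefficient()].
#'
#' @param paired output of [pair_epochs()].
#' @param conf compute a subject-level BCa bootstrap CI.
#' @param B,seed,level bootstrap settings.
#' @return list with `ccc`, `band` (see [classify_ccc()]), `sigma2_resid`,
#'   `sigma2_beta`, `components`, and `ci` when requested.
#' @export
ccc_vc <- function(paired, conf = FALSE, B = 1000, seed = 1, level = 0.95) {
  subs <- unique(paired$subject)
  if (length(subs) < 2) stop("need at least 2 subjects")
  pt <- ccc_point(paired)
  ci <- NULL
  if (conf) {
    bc <- boot_ci(paired, function(d) ccc_point(d)$ccc, B = B, seed = seed,
                  level = level)
    ci <- c(lower = unname(bc$ci[1, "lower"]),
            upper = unname(bc$ci[1, "upper"]))
  }
  list(ccc = pt$ccc, band = classify_ccc(pt$ccc),
       sigma2_resid = pt$sigma2_resid, sigma2_beta = pt$sigma2_beta,
       components = pt$components, ci = ci)
}

# All agreement statistics as one named vector (used as the bootstrap
# statistic so every metric shares the same replicate datasets).
agreement_stats <- function(paired, cad = 10, tdi_p = 0.95,
                            loa_level = 0.95) {
  dfit <- fit_difference_model(paired)
  loa <- loa_mixed(dfit, level = loa_level)
  m <- msd(dfit)
  cc <- ccc_point(paired)
  c(bias = dfit$bias, loa_lower = unname(loa["lower"]),
    loa_upper = unname(loa["upper"]), msd = m,
    cp = coverage_probability(dfit$bias, m, cad),
    tdi = total_deviation_index(m, tdi_p),
    ccc = cc$ccc,
    cia = cia(cc$sigma2_resid, m),
    rc = repeatability_coefficient(cc$sigma2_resid))
}

#' Per-phase agreement metrics
#'
#' Recomputes every agreement statistic within each phase separately
#' (difference model with a subject random intercept; stacked CCC model
#' without the phase terms). Phases failing the fit preconditions yield a
#' row of `NA`s.
#'
#' @inheritParams agreement_report
#' @return data.frame with one row per phase.
#' @export
agreement_by_phase <- function(paired, cad = 10, tdi_p = 0.95,
                               loa_level = 0.95) {
  phases <- .analysis_phases[.analysis_phases %in% unique(paired$phase)]
  phases <- union(phases, sort(unique(paired$phase)))
  rows <- lapply(phases, function(p) {
    d <- paired[paired$phase == p, , drop = FALSE]
    st <- tryCatch(agreement_stats(d, cad = cad, tdi_p = tdi_p,
                                   loa_level = loa_level),
                   error = function(e) NULL)
    if (is.null(st)) {
      st <- c(bias = NA_real_, loa_lower = NA_real_, loa_upper = NA_real_,
              msd = NA_real_, cp = NA_real_, tdi = NA_real_, ccc = NA_real_,
              cia = NA_real_, rc = NA_real_)
    }
    cbind(data.frame(phase = p, n_epochs = nrow(d),
                     n_subjects = length(unique(d$subject)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(st)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full agreement report (overall and per phase)
#'
#' Computes bias, limits of agreement, MSD, coverage probability, TDI, CCC,
#' CIA and the repeatability coefficient on the pooled data and within each
#' phase, with optional subject-level BCa cluster-bootstrap confidence
#' intervals for the overall metrics (every metric is re-derived on each
#' replicate by refitting both mixed models).
#'
#' @param paired output of [pair_epochs()].
#' @param cad clinically acceptable difference in bpm (default 10).
#' @param tdi_p TDI containment probability (default 0.95).
#' @param loa_level limits-of-agreement level (default 0.95).
#' @param conf compute bootstrap CIs for the overall metrics.
#' @param B bootstrap replicates (default 5000); `B = 0` disables CIs.
#' @param seed bootstrap seed.
#' @param level CI level.
#' @return An object of class `agreement_report`: `overall` (named
#'   estimates), `ci` (matrix or NULL), `by_phase` (data.frame), and the
#'   settings used.
#' @export
agreement_report <- function(paired, cad = 10, tdi_p = 0.95,
                             loa_level = 0.95, conf = TRUE, B = 5000,
                             seed = 1, level = 0.95) {
  overall <- agreement_stats(paired, cad = cad, tdi_p = tdi_p,
                             loa_level = loa_level)
  ci <- NULL
  if (conf && B > 0) {
    bc <- boot_ci(paired,
                  function(d) agreement_stats(d, cad = cad, tdi_p = tdi_p,
                                              loa_level = loa_level),
                  B = B, seed = seed, level = level)
    ci <- bc$ci
  }
  structure(
    list(overall = overall, ci = ci,
         by_phase = agreement_by_phase(paired, cad = cad, tdi_p = tdi_p,
                                       loa_level = loa_level),
         cad = cad, tdi_p = tdi_p, loa_level = loa_level, B = B,
         seed = seed, level = level),
    class = "agreement_report"
  )
}
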