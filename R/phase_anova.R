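# Mixed-effects test of heart-rate differences across experimental phases
# for a single device: REML fit, Satterthwaite omnibus F with partial
# eta^2, and Tukey-adjusted pairwise contrasts.

#' Fit the phase mixed model for one device
#'
#' REML fit of `bpm ~ phase + (1 | subject) + (1 | subject:phase)`: phases as
#' a fixed effect, subjects and the subject-by-phase interaction as random
#' effects.
#'
#' @param data data.frame with columns `subject`, `phase`, `bpm` (and
#'   optionally `device`).
#' @param device optional device label to filter on before fitting.
#' @return An object of class `phase_fit`: the `lmerModLmerTest` model,
#'   per-phase fixed-effect means, variance components
#'   (`subject`, `interaction`, `resid`, in bpm^2), log-likelihood, sizes,
#'   and a `singular` flag.
#' @export
fit_phase_model <- function(data, device = NULL) {
  if (!is.null(device)) data <- data[data$device == device, , drop = FALSE]
  req <- c("subject", "phase", "bpm")
  absent <- setdiff(req, names(data))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  data$subject <- factor(data$subject)
  canon <- .analysis_phases[.analysis_phases %in% unique(data$phase)]
  data$phase <- factor(data$phase,
                       levels = union(canon, unique(data$phase)))
  if (nlevels(data$subject) < 2) stop("need at least 2 subjects")
  if (nlevels(data$phase) < 2) stop("need at least 2 phases")
  cell <- table(data$subject, data$phase)
  if (any(cell < 2)) {
    stop("need at least 2 observations in every subject-phase cell")
  }
  m <- lmerTest::lmer(bpm ~ phase + (1 | subject) + (1 | subject:phase),
                      data = data, REML = TRUE)
  if (!is.null(m@optinfo$conv$opt) && m@optinfo$conv$opt != 0) {
    stop("mixed model did not converge: ",
         paste(unlist(m@optinfo$conv$lme4$messages), collapse = "; "))
  }
  singular <- lme4::isSingular(m)
  if (singular) {
    warning("singular fit: one or more variance components estimated as zero")
  }
  vc <- extract_vc(m)
  beta <- lme4::fixef(m)
  means <- beta[1] + c(0, beta[-1])
  names(means) <- levels(data$phase)
  structure(
    list(model = m, fixed_effects = means, vc = vc,
         loglik = as.numeric(stats::logLik(m)), n_obs = nrow(data),
         n_subjects = nlevels(data$subject), singular = singular),
    class = "phase_fit"
  )
}

extract_vc <- function(m) {
  vcdf <- as.data.frame(lme4::VarCorr(m))
  get1 <- function(grp) {
    v <- vcdf$vcov[vcdf$grp == grp]
    if (length(v)) v[1] else 0
  }
  c(subject = get1("subject"), interaction = get1("subject:phase"),
    resid = get1("Residual"))
}

#' Omnibus F-test of the phase effect with partial eta squared
#'
#' Type III F-test of the phase fixed effect with Satterthwaite denominator
#' degrees of freedom, plus partial eta^2 with a 90% CI obtained by
#' inverting the noncentral-F distribution.
#'
#' @param fit a [fit_phase_model()] result.
#' @param ci_level confidence level for the eta^2 interval (default 0.90,
#'   the reporting convention for variance-explained effect sizes).
#' @return list with `F`, `df_num`, `df_den`, `p`, `eta2_partial`,
#'   `eta2_ci`, `ci_level`.
#' @export
omnibus_test <- function(fit, ci_level = 0.90) {
  stopifnot(inherits(fit, "phase_fit"))
  if (fit$vc[["resid"]] <= 1e-10) {
    stop("residual variance is zero; the omnibus F-test is undefined")
  }
  at <- stats::anova(fit$model)  # lmerTest: Satterthwaite ddf
  Fv <- at[["F value"]][1]
  df1 <- at[["NumDF"]][1]
  df2 <- at[["DenDF"]][1]
  p <- at[["Pr(>F)"]][1]
  eta <- (Fv * df1) / (Fv * df1 + df2)
  list(F = Fv, df_num = df1, df_den = df2, p = p,
       eta2_partial = eta,
       eta2_ci = eta_squared_ci(Fv, df1, df2, level = ci_level),
       ci_level = ci_level)
}

#' Confidence interval for partial eta squared from an F statistic
#'
#' Inverts the noncentral-F CDF to bound the noncentrality parameter, then
#' maps `lambda` to `eta^2 = lambda / (lambda + df1 + df2 + 1)`.
#'
#' @param f observed F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param level confidence level (default 0.90).
#' @return named vector `c(lower, upper)`.
#' @export
eta_squared_ci <- function(f, df1, df2, level = 0.90) {
  stopifnot(f >= 0, df1 > 0, df2 > 0, level > 0, level < 1)
  ncp_limit <- function(target) {
    g <- function(ncp) stats::pf(f, df1, df2, ncp = ncp) - target
    if (g(0) <= 0) return(0)
    upper <- max(10, 4 * f * df1)
    while (g(upper) > 0) upper <- upper * 2
    stats::uniroot(g, c(0, upper), tol = 1e-8)$root
  }
  lo <- ncp_limit((1 + level) / 2)
  hi <- ncp_limit((1 - level) / 2)
  tot <- df1 + df2 + 1
  c(lower = lo / (lo + tot), upper = hi / (hi + tot))
}

#' Tukey-adjusted pairwise phase contrasts
#'
#' Estimated marginal mean differences between all phase pairs with
#' Satterthwaite degrees of freedom and p-values adjusted by the Tukey
#' (studentized range) method. With fewer than 3 phases the adjustment is
#' dropped with a warning.
#'
#' @param fit a [fit_phase_model()] result.
#' @return data.frame with columns `phase_i`, `phase_j`, `estimate`, `se`,
#'   `df`, `t_ratio`, `adjusted_p`.
#' @export
pairwise_contrasts <- function(fit) {
  stopifnot(inherits(fit, "phase_fit"))
  nph <- nlevels(fit$model@frame$phase)
  adjust <- "tukey"
  if (nph < 3) {
    warning("fewer than 3 phases; p-values are unadjusted")
    adjust <- "none"
  }
  emm <- emmeans::emmeans(fit$model, "phase", lmer.df = "satterthwaite",
                          lmerTest.limit = fit$n_obs + 1)
  ct <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  pair <- strsplit(as.character(ct$contrast), " - ", fixed = TRUE)
  data.frame(
    phase_i = vapply(pair, `[`, "", 1),
    phase_j = vapply(pair, `[`, "", 2),
    estimate = ct$estimate,
    se = ct$SE,
    df = ct$df,
    t_ratio = ct$t.ratio,
    adjusted_p = ct$p.value,
    stringsAsFactors = FALSE
  )
}
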