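# Seeded subject-level (cluster) bootstrap with BCa intervals. Resampling
# whole subjects preserves the within-subject correlation that epoch-level
# resampling would destroy.

#' Cluster bootstrap over subjects
#'
#' Draws `B` datasets by resampling subjects with replacement, keeping every
#' epoch of a drawn subject and relabelling duplicates as distinct clusters,
#' then evaluates `statistic` on each. Deterministic given `seed`. The
#' statistic may return a named numeric vector; replicates are collected
#' row-wise.
#'
#' @param data data.frame with a subject identifier column.
#' @param statistic function `data -> numeric` (scalar or vector).
#' @param B number of replicates (default 5000).
#' @param seed integer seed.
#' @param subject_col name of the cluster column (default `"subject"`).
#' @return An object of class `cluster_boot`: `point`, `replicates`
#'   (matrix, one row per successful replicate), `B`, `seed`, `n_subjects`,
#'   `failed`.
#' @export
cluster_bootstrap <- function(data, statistic, B = 5000, seed = 1,
                              subject_col = "subject") {
  subs <- unique(data[[subject_col]])
  if (length(subs) < 2) stop("need at least 2 subjects to bootstrap")
  point <- statistic(data)
  if (!all(is.finite(point))) {
    stop("statistic is not finite on the full dataset")
  }
  idx <- split(seq_len(nrow(data)), as.character(data[[subject_col]]))
  idx <- idx[as.character(subs)]
  set.seed(seed)
  draws <- matrix(sample.int(length(subs), length(subs) * B, replace = TRUE),
                  nrow = B)
  reps <- matrix(NA_real_, B, length(point))
  colnames(reps) <- names(point)
  failed <- 0L
  for (b in seq_len(B)) {
    rows <- idx[draws[b, ]]
    d <- data[unlist(rows, use.names = FALSE), , drop = FALSE]
    d[[subject_col]] <- rep(seq_along(rows), lengths(rows))
    val <- tryCatch(statistic(d), error = function(e) NULL)
    if (is.null(val) || !all(is.finite(val))) failed <- failed + 1L
    else reps[b, ] <- val
  }
  if (failed > max(1, 0.01 * B)) {
    stop(sprintf("statistic failed on %d of %d bootstrap replicates",
                 failed, B))
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  structure(list(point = point, replicates = reps, B = B, seed = seed,
                 n_subjects = length(subs), failed = failed),
            class = "cluster_boot")
}

#' Leave-one-subject-out jackknife values of a statistic
#'
#' @inheritParams cluster_bootstrap
#' @return matrix with one row per left-out subject.
#' @export
jackknife_subjects <- function(data, statistic, subject_col = "subject") {
  subs <- unique(data[[subject_col]])
  out <- lapply(subs, function(s) {
    statistic(data[data[[subject_col]] != s, , drop = FALSE])
  })
  do.call(rbind, out)
}

#' Percentile bootstrap interval (order statistics, no extrapolation)
#'
#' @param replicates numeric vector of bootstrap replicates.
#' @param level confidence level in (0, 1).
#' @return named vector `c(lower, upper)`.
#' @export
percentile_interval <- function(replicates, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  r <- sort(replicates[is.finite(replicates)])
  B <- length(r)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  ks <- pmin(pmax(ceiling(probs * B - 1e-9), 1L), B)
  c(lower = r[ks[1]], upper = r[ks[2]])
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa: the bias correction `z0` comes from the fraction of
#' replicates below the point estimate (ties counted half), the acceleration
#' `a` from the skewness of leave-one-subject-out jackknife values, and the
#' endpoints are order statistics of the replicate vector at the adjusted
#' quantiles. With `z0 = a = 0` it reduces to the percentile interval.
#'
#' @param point point estimate on the full data.
#' @param replicates numeric vector of bootstrap replicates.
#' @param jackknife optional numeric vector of jackknife values (`a = 0`
#'   when omitted).
#' @param level confidence level in (0, 1).
#' @return named vector `c(lower, upper)`.
#' @export
bca_interval <- function(point, replicates, jackknife = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  r <- replicates[is.finite(replicates)]
  B <- length(r)
  if (B < 100) stop("need at least 100 replicates for a CI")
  if (diff(range(r)) == 0) {
    warning("all bootstrap replicates identical; interval collapses to the point")
    return(c(lower = point, upper = point))
  }
  p0 <- (sum(r < point) + 0.5 * sum(r == point)) / B
  p0 <- min(max(p0, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(p0)
  a <- 0
  if (!is.null(jackknife)) {
    d <- mean(jackknife) - jackknife
    denom <- sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / (6 * denom)
  }
  zal <- stats::qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  sorted <- sort(r)
  ks <- pmin(pmax(ceiling(adj * B - 1e-9), 1L), B)
  c(lower = sorted[ks[1]], upper = sorted[ks[2]])
}

#' Cluster-bootstrap confidence interval for a statistic
#'
#' Convenience wrapper tying together [cluster_bootstrap()],
#' [jackknife_subjects()] and [bca_interval()] / [percentile_interval()].
#' Supports vector-valued statistics (one interval per component).
#'
#' @inheritParams cluster_bootstrap
#' @param level confidence level.
#' @param method `"bca"` (default) or `"percentile"`.
#' @return list with `point`, `ci` (matrix with `lower`/`upper` columns),
#'   `method`, `B`, `seed` and the underlying `cluster_boot` object.
#' @export
boot_ci <- function(data, statistic, B = 5000, seed = 1, level = 0.95,
                    method = c("bca", "percentile"), subject_col = "subject") {
  method <- match.arg(method)
  bt <- cluster_bootstrap(data, statistic, B = B, seed = seed,
                          subject_col = subject_col)
  jk <- if (method == "bca") {
    jackknife_subjects(data, statistic, subject_col = subject_col)
  } else NULL
  k <- length(bt$point)
  ci <- matrix(NA_real_, k, 2, dimnames = list(names(bt$point),
                                               c("lower", "upper")))
  for (i in seq_len(k)) {
    ci[i, ] <- if (method == "bca") {
      bca_interval(bt$point[i], bt$replicates[, i], jk[, i], level = level)
    } else {
      percentile_interval(bt$replicates[, i], level = level)
    }
  }
  list(point = bt$point, ci = ci, method = method, B = B, seed = seed,
       boot = bt)
}
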