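# Own-implementation inference layer: Fisher discriminant analysis with
# Wilks' lambda, exact/asymptotic Wilcoxon tests with rank-biserial effect
# sizes, Brown-Forsythe variance test, Cohen's d, rank-based ROC AUC, and
# the state-space dispersion (covariance-trace) measure of consolidation.

new_assay_test <- function(statistic, p_value, method, alternative, n,
                           effect_size_rrb = NA_real_,
                           effect_size_d = NA_real_, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   alternative = alternative, n = n,
                   effect_size_rrb = effect_size_rrb,
                   effect_size_d = effect_size_d), extra),
            class = "assay_test")
}

#' @export
print.assay_test <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g (%s), n = %d", x$method,
              x$statistic, x$p_value, x$alternative, x$n))
  if (!is.na(x$effect_size_rrb)) cat(sprintf(", r_rb = %.3f", x$effect_size_rrb))
  if (!is.na(x$effect_size_d)) cat(sprintf(", d = %.3f", x$effect_size_d))
  cat(">\n")
  invisible(x)
}

midranks <- function(x) rank(x, ties.method = "average")

# ---------------------------------------------------------------------------
# Fisher discriminant analysis / Wilks' lambda

#' Two-group Fisher discriminant analysis with Wilks' lambda
#'
#' Computes Wilks' lambda as `det(W) / det(W + B)` from the within-group
#' (`W`) and between-group (`B`) cross-product matrices, the exact two-group
#' F transform `F = (1 - lambda)/lambda * (N - p - 1)/p` on
#' `(p, N - p - 1)` degrees of freedom, the canonical discriminant
#' direction, resubstitution misclassification under the linear
#' (pooled-covariance) rule with proportional priors, the ROC AUC of the
#' canonical score, and the -2 log likelihood of the Gaussian discriminant
#' model.
#'
#' @param x Numeric matrix or data.frame of features (rows = observations).
#' @param labels Two-level grouping vector.
#' @return An object of class `da_result`.
#' @export
fisher_da <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("fisher_da requires exactly 2 groups")
  if (any(table(labels) < 2L)) stop("each group needs >= 2 rows")
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant feature detected; remove it before discriminant analysis")
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  groups <- levels(labels)
  centroids <- t(vapply(groups, function(g) colMeans(x[labels == g, , drop = FALSE]),
                        numeric(p)))
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- sweep(xg, 2, colMeans(xg))
    W <- W + crossprod(cg)
    dg <- colMeans(xg) - mu
    B <- B + nrow(xg) * tcrossprod(dg)
  }
  dW <- det(W)
  if (!is.finite(dW) || dW <= 0)
    stop("singular within-group matrix; consider removing a collinear feature")
  lambda <- dW / det(W + B)
  df1 <- p
  df2 <- n - p - 1L
  F_stat <- (1 - lambda) / lambda * df2 / df1
  p_value <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)

  S <- W / (n - 2)                      # pooled covariance
  a <- solve(S, centroids[1, ] - centroids[2, ])   # canonical direction
  scores <- drop(x %*% a)
  auc <- roc_auc(scores, labels, positive = groups[1])

  # linear classification rule, proportional priors, resubstitution
  priors <- as.numeric(table(labels)[groups]) / n
  delta <- vapply(seq_along(groups), function(k) {
    m <- centroids[k, ]
    drop(x %*% solve(S, m)) - drop(m %*% solve(S, m)) / 2 + log(priors[k])
  }, numeric(n))
  pred <- groups[max.col(delta)]
  misclassification <- mean(pred != as.character(labels))

  logdetS <- determinant(S, logarithm = TRUE)$modulus
  Sinv <- solve(S)
  m2ll <- 0
  for (k in seq_along(groups)) {
    xg <- x[labels == groups[k], , drop = FALSE]
    cg <- sweep(xg, 2, centroids[k, ])
    m2ll <- m2ll + nrow(xg) * (p * log(2 * pi) + as.numeric(logdetS)) +
      sum((cg %*% Sinv) * cg)
  }

  structure(list(wilks_lambda = lambda, F_stat = F_stat, df1 = df1,
                 df2 = df2, p_value = p_value,
                 group_centroids = centroids,
                 canonical_loadings = stats::setNames(a, colnames(x)),
                 misclassification_rate = misclassification, auc = auc,
                 minus2_log_likelihood = m2ll, n = n, groups = groups),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("<da_result: Wilks' lambda = %.4f, F(%d, %d) = %.3f, p = %.4g>\n",
              x$wilks_lambda, x$df1, x$df2, x$F_stat, x$p_value))
  cat(sprintf("  AUC = %.3f, misclassification = %.1f%%, -2logLik = %.2f, n = %d\n",
              x$auc, 100 * x$misclassification_rate,
              x$minus2_log_likelihood, x$n))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rank tests

# exact null distribution of the positive-rank sum for given |d| ranks
signed_rank_exact_p <- function(W, r, alternative) {
  n <- length(r)
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)   # all 2^n subset sums
  cdf_le <- mean(sums <= W + 1e-9)
  cdf_ge <- mean(sums >= W - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(cdf_le, cdf_ge)),
         greater = cdf_ge,
         less = cdf_le)
}

#' Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Zeros are dropped; ties get mid-ranks. The statistic is the sum of
#' positive ranks `W`. The p-value is exact (full enumeration of the `2^n`
#' sign assignments) for `n <= 12` non-zero differences, and a tie-corrected
#' normal approximation with continuity correction otherwise. The
#' rank-biserial effect size is `(2W - SR)/SR` with `SR = n(n+1)/2`; Cohen's
#' d of the differences against zero is also reported.
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @return An `assay_test`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: signed-rank test undefined")
  r <- midranks(abs(d))
  W <- sum(r[d > 0])
  SR <- n * (n + 1) / 2
  if (n <= 12L) {
    p <- signed_rank_exact_p(W, r, alternative)
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- SR / 2
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_g <- (W - mu - cc) / sqrt(sigma2)
    z_l <- (W - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_l),
                                           stats::pnorm(z_g, lower.tail = FALSE))),
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  sd_d <- stats::sd(d)
  new_assay_test(W, p, method, alternative, n,
                 effect_size_rrb = (2 * W - SR) / SR,
                 effect_size_d = if (n > 1 && sd_d > 0) mean(d) / sd_d
                 else NA_real_)
}

rank_sum_exact_p <- function(Ra, r, n_a, alternative) {
  idx <- utils::combn(length(r), n_a)
  sums <- colSums(matrix(r[idx], nrow = n_a))
  cdf_le <- mean(sums <= Ra + 1e-9)
  cdf_ge <- mean(sums >= Ra - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(cdf_le, cdf_ge)),
         greater = cdf_ge,
         less = cdf_le)
}

#' Wilcoxon two-sample rank-sum test
#'
#' The statistic is the rank sum of the first sample. Exact p by full
#' enumeration of all label assignments for `n_a + n_b <= 12`, tie-corrected
#' normal approximation with continuity correction otherwise. Reports the
#' rank-biserial effect size `2*AUC - 1` (with `AUC = U/(n_a*n_b)`) and
#' Cohen's d.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (`a` shifted up) or
#'   `"less"`.
#' @return An `assay_test` with extra fields `U` and `auc`.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0L || n_b == 0L) stop("both samples must be non-empty")
  r <- midranks(c(a, b))
  Ra <- sum(r[seq_len(n_a)])
  U <- Ra - n_a * (n_a + 1) / 2
  N <- n_a + n_b
  if (N <= 12L) {
    p <- rank_sum_exact_p(Ra, r, n_a, alternative)
    method <- "Wilcoxon rank-sum (exact)"
  } else {
    mu <- n_a * (N + 1) / 2
    tie_tab <- table(r)
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    cc <- 0.5
    z_g <- (Ra - mu - cc) / sqrt(sigma2)
    z_l <- (Ra - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_l),
                                           stats::pnorm(z_g, lower.tail = FALSE))),
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l))
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  auc <- U / (n_a * n_b)
  d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
  new_assay_test(Ra, p, method, alternative, N,
                 effect_size_rrb = 2 * auc - 1, effect_size_d = d,
                 extra = list(U = U, auc = auc, n_a = n_a, n_b = n_b))
}

#' Brown-Forsythe / Levene test for equality of variances
#'
#' One-way ANOVA F on absolute deviations from the group center
#' (median by default — the Brown-Forsythe variant — or mean).
#'
#' @param a,b Numeric samples (>= 2 values each).
#' @param center `"median"` or `"mean"`.
#' @return An `assay_test` with extra fields `df1`, `df2`.
#' @export
levene_test <- function(a, b, center = c("median", "mean")) {
  center <- match.arg(center)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  cf <- if (center == "median") stats::median else mean
  za <- abs(a - cf(a)); zb <- abs(b - cf(b))
  n_a <- length(za); n_b <- length(zb); N <- n_a + n_b
  zbar <- mean(c(za, zb))
  ssb <- n_a * (mean(za) - zbar)^2 + n_b * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw == 0) {
    F_stat <- if (ssb == 0) 0 else Inf
  } else F_stat <- (ssb / 1) / (ssw / (N - 2))
  p <- if (is.infinite(F_stat)) 0 else
    stats::pf(F_stat, 1, N - 2, lower.tail = FALSE)
  if (ssb == 0 && ssw == 0) p <- 1
  new_assay_test(F_stat, p,
                 sprintf("Levene test (%s-centered)", center),
                 "two.sided", N, extra = list(df1 = 1L, df2 = N - 2L))
}

#' Cohen's d for two samples
#'
#' `(mean(a) - mean(b)) / s_pooled`, pooling variances with `n - 1` weights.
#'
#' @param a,b Numeric samples (>= 2 values each).
#' @return The standardized mean difference.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled SD: Cohen's d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Rank-based ROC area under the curve
#'
#' Mann-Whitney identity: `AUC = P(score_pos > score_neg)`, with ties
#' counted half.
#'
#' @param scores Numeric scores.
#' @param labels Two-level class labels.
#' @param positive Label of the positive class (default: first level).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("roc_auc requires both classes present")
  if (is.null(positive)) positive <- levels(labels)[1]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("roc_auc requires both classes present")
  r <- midranks(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---------------------------------------------------------------------------
# Second-level (per-fish) tests and consolidation

#' Second-level per-fish test of cue discrimination
#'
#' Collapses a feature table to one median per (fish, cue), forms the
#' per-fish NCF - DFM difference, and runs a signed-rank test across fish —
#' the independent-sample route around frame-level pseudo-replication.
#' Fish missing either cue are excluded (with a message).
#'
#' @param features Feature table with columns `fish_id`, `cue` and the
#'   metric.
#' @param metric Column name to test.
#' @param alternative Passed to [wilcoxon_signed_rank()].
#' @return An `assay_test` with extra field `n_fish`.
#' @export
per_fish_second_level <- function(features, metric = "distance_from_screen",
                                  alternative = "two.sided") {
  stopifnot(metric %in% names(features))
  med <- stats::aggregate(features[[metric]],
                          by = list(fish_id = features$fish_id,
                                    cue = features$cue),
                          FUN = stats::median, na.rm = TRUE)
  wide <- merge(med[med$cue == "NCF", c("fish_id", "x")],
                med[med$cue == "DFM", c("fish_id", "x")],
                by = "fish_id", suffixes = c("_ncf", "_dfm"))
  all_fish <- unique(features$fish_id)
  dropped <- setdiff(all_fish, wide$fish_id)
  if (length(dropped))
    message("excluding fish without both cues: ", paste(dropped, collapse = ", "))
  if (nrow(wide) < 5L)
    stop("per-fish second-level test needs >= 5 fish with both cues")
  diffs <- wide$x_ncf - wide$x_dfm
  out <- if (all(diffs == 0)) {
    # identical cue behavior in every fish: no evidence either way
    new_assay_test(0, 1, "Wilcoxon signed-rank (degenerate)", alternative,
                   length(diffs), effect_size_rrb = 0)
  } else wilcoxon_signed_rank(diffs, alternative = alternative)
  out$n_fish <- nrow(wide)
  out
}

#' State-space dispersion (covariance trace)
#'
#' Covariance of (proximity to the conditioned goal, yaw) over a block of
#' frames, summarized by its trace — a scalar measure of total behavioral
#' variance. Proximity is the distance to the goal wall: the screen for an
#' approach-conditioned (NCF) fish, the back wall for an avoidance-
#' conditioned (DFM) fish. With `standardize = TRUE` both variables are
#' z-scored first (trace then counts dimensionless variance).
#'
#' @param series Frames with `distance` and `yaw` columns (>= 10 rows; see
#'   [compute_series()]).
#' @param conditioned_direction `+1` (goal = screen) or `-1` (goal = back
#'   wall).
#' @param tank A [tank_geometry()].
#' @param standardize z-score proximity and yaw before the covariance?
#' @return An object of class `dispersion_result` with `trace`,
#'   `var_proximity`, `var_yaw`, `covariance` (2x2) and `n`.
#' @export
state_space_dispersion <- function(series, conditioned_direction = +1,
                                   tank = tank_geometry(),
                                   standardize = FALSE) {
  stopifnot(conditioned_direction %in% c(-1, 1))
  if (nrow(series) < 10L) stop("state_space_dispersion needs >= 10 frames")
  prox <- if (conditioned_direction > 0) series$distance
  else tank$length - series$distance
  yaw <- series$yaw
  ok <- !is.na(prox) & !is.na(yaw)
  m <- cbind(proximity = prox[ok], yaw = yaw[ok])
  if (standardize) m <- scale(m)
  cv <- stats::cov(m)
  cv[!is.finite(cv)] <- 0
  structure(list(trace = sum(diag(cv)), var_proximity = cv[1, 1],
                 var_yaw = cv[2, 2], covariance = cv, n = nrow(m)),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result: trace = %.3f (proximity %.3f mm^2 + yaw %.4f rad^2), n = %d>\n",
              x$trace, x$var_proximity, x$var_yaw, x$n))
  invisible(x)
}

#' Block-1 dispersion of a session
#'
#' Convenience wrapper: computes the state-space dispersion over the CS and
#' gap frames of Block-1 runs (the nascent-state trials), with the
#' conditioned direction taken from the Block-1 cue.
#'
#' @param session A `simulated_session` or annotated tracking data.frame.
#' @param config An [experiment_config()].
#' @param standardize Passed to [state_space_dispersion()].
#' @return A `dispersion_result`.
#' @export
block1_dispersion <- function(session, config = experiment_config(),
                              standardize = FALSE) {
  frames <- if (inherits(session, "simulated_session")) session$frames else session
  if (!"speed" %in% names(frames)) frames <- compute_series(frames, config$fps)
  b1 <- frames[!is.na(frames$block_id) & frames$block_id == 1L &
                 frames$epoch_kind %in% c("cs", "gap"), , drop = FALSE]
  cue <- b1$cue[b1$cue != "none"][1]
  dir <- if (identical(cue, "DFM")) -1 else +1
  state_space_dispersion(b1, conditioned_direction = dir, tank = config$tank,
                         standardize = standardize)
}

#' Compare day-1 and day-2 dispersion (consolidation test)
#'
#' Signed-rank test on per-fish trace differences (day 1 - day 2; positive
#' differences mean reduced dispersion after the overnight period), with the
#' rank-biserial correlation as the headline effect size.
#'
#' @param day1,day2 Lists of `dispersion_result` (or numeric traces), paired
#'   by fish; names are used for pairing when present.
#' @param alternative Passed to [wilcoxon_signed_rank()]; `"greater"` tests
#'   for a day-2 reduction.
#' @return An `assay_test` with extra field `n_pairs`.
#' @export
consolidation_compare <- function(day1, day2, alternative = "two.sided") {
  tr <- function(x) vapply(x, function(e)
    if (inherits(e, "dispersion_result")) e$trace else as.numeric(e),
    numeric(1))
  t1 <- tr(day1); t2 <- tr(day2)
  if (!is.null(names(t1)) && !is.null(names(t2))) {
    common <- intersect(names(t1), names(t2))
    dropped <- setdiff(union(names(t1), names(t2)), common)
    if (length(dropped))
      message("excluding unpaired fish: ", paste(dropped, collapse = ", "))
    t1 <- t1[common]; t2 <- t2[common]
  } else if (length(t1) != length(t2))
    stop("day1 and day2 must be paired (same length or shared names)")
  if (all(t1 == t2)) {
    out <- new_assay_test(NA_real_, 1, "Wilcoxon signed-rank (degenerate)",
                          alternative, length(t1), effect_size_rrb = 0)
  } else {
    out <- wilcoxon_signed_rank(t1 - t2, alternative = alternative)
  }
  out$n_pairs <- length(t1)
  out
}
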