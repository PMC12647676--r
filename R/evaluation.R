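#' Participant k-fold split
#'
#' Seeded shuffle followed by a near-equal partition (fold sizes differ by
#' at most one, larger folds first).
#'
#' @param participant_ids vector of ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of class `tes_fold_plan`: `k`, `seed`, `assignments`
#'   (integer fold per participant, named).
#' @export
kfold_split <- function(participant_ids, k = 5L, seed = 1L) {
  n <- length(participant_ids)
  if (n < k) stop("need at least k participants", call. = FALSE)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  structure(list(k = as.integer(k), seed = seed,
                 assignments = stats::setNames(fold, participant_ids)),
            class = "tes_fold_plan")
}

#' Adjusted R-squared on an evaluation set
#'
#' `1 - (1 - R^2) * (n - 1) / (n - p - 1)` with
#' `R^2 = 1 - SS_res / SS_tot`, where `SS_tot` is taken about the
#' evaluation set's own mean.
#'
#' @param y_true observed outcomes.
#' @param y_pred predictions.
#' @param p number of predictors in the model.
#' @return adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(y_true, y_pred, p) {
  n <- length(y_true)
  stopifnot(length(y_pred) == n)
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0)
    stop("degenerate outcome: zero total sum of squares", call. = FALSE)
  r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the mean of the observed outcomes (default) or by
#' their range. The normalizer convention is recorded in every report.
#'
#' @inheritParams adjusted_r2
#' @param normalizer `"mean"` (default) or `"range"`.
#' @return NRMSE (dimensionless, >= 0 for positive normalizers).
#' @export
nrmse <- function(y_true, y_pred, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0L)
  rmse <- sqrt(mean((y_true - y_pred)^2))
  denom <- switch(normalizer, mean = mean(y_true),
                  range = diff(range(y_true)))
  if (abs(denom) < .Machine$double.eps)
    stop("degenerate outcome: zero ", normalizer, " normalizer",
         call. = FALSE)
  rmse / denom
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA F test on absolute deviations from the group center. The
#' default center is the median (the Brown-Forsythe form, robust for
#' heavy-tailed dose distributions); the classic mean-centered test is
#' selectable.
#'
#' @param groups list of >= 2 numeric samples, each with >= 2 values.
#' @param center `"median"` (default) or `"mean"`.
#' @return list with `statistic` (F), `p_value`, `df`, `center`.
#' @export
levene_test <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("insufficient data: every group needs >= 2 observations",
         call. = FALSE)
  cfun <- if (center == "median") stats::median else mean
  absdev <- lapply(groups, function(g) abs(g - cfun(g)))
  z <- unlist(absdev, use.names = FALSE)
  grp <- factor(rep(seq_along(groups),
                    vapply(absdev, length, integer(1))))
  k <- nlevels(grp)
  n <- length(z)
  zbar <- mean(z)
  gm <- tapply(z, grp, mean)
  gn <- tapply(z, grp, length)
  ss_between <- sum(gn * (gm - zbar)^2)
  ss_within <- sum((z - gm[grp])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ss_within <= 0) {
    fstat <- if (ss_between <= 0) 0 else Inf
  } else {
    fstat <- (ss_between / df1) / (ss_within / df2)
  }
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  list(statistic = fstat, p_value = p, df = c(df1, df2), center = center)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)`, order-preserving.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m comparison (family) count, `>= length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("family size m must be >= number of p-values", call. = FALSE)
  pmin(1, m * p_values)
}

#' Partial Spearman rank correlation
#'
#' All variables are rank-transformed (average ranks for ties); the
#' partial correlation between the target predictor and the outcome given
#' the remaining predictors is the Pearson correlation of the residuals of
#' linear fits on the control ranks. The p-value uses the t approximation
#' with `df = n - n_controls - 2`.
#'
#' @param X predictor matrix (columns include the target predictor).
#' @param y outcome vector.
#' @param target_index column of `X` whose partial association is wanted.
#' @return list with `rho`, `p_value`, `df`.
#' @export
partial_spearman <- function(X, y, target_index) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, target_index >= 1, target_index <= ncol(X))
  n_ctrl <- ncol(X) - 1L
  if (n <= n_ctrl + 2L) stop("need n > controls + 2", call. = FALSE)
  if (any(apply(X, 2L, stats::sd) == 0) || stats::sd(y) == 0)
    stop("constant column", call. = FALSE)
  rk <- function(v) rank(v, ties.method = "average")
  rx <- rk(X[, target_index])
  ry <- rk(y)
  if (n_ctrl == 0L) {
    rho <- stats::cor(rx, ry)
  } else {
    ctrl <- apply(X[, -target_index, drop = FALSE], 2L, rk)
    Z <- cbind(1, ctrl)
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stop("singular design: collinear controls", call. = FALSE)
    rho <- stats::cor(qr.resid(qz, rx), qr.resid(qz, ry))
  }
  df <- n - n_ctrl - 2L
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(rho = rho, p_value = p, df = df)
}

#' Per-montage correlation battery
#'
#' For each montage: Pearson correlations of peak E-field strength with
#' head circumference and cephalic index (approximately normal), Spearman
#' correlations with age and BMI (non-normal), and a two-sample t-test
#' between genders. P-values are Bonferroni-adjusted across the whole
#' battery.
#'
#' @param cohort cohort table (complete BMI).
#' @param efields peak E-field table.
#' @return data frame with `montage_id`, `test`, `estimate`, `p_value`,
#'   `p_adjusted`.
#' @export
correlation_battery <- function(cohort, efields) {
  rows <- list()
  for (m in unique(efields$montage_id)) {
    ef <- efields[efields$montage_id == m, ]
    idx <- match(ef$participant_id, cohort$participant_id)
    if (anyNA(idx))
      stop("efields reference unknown participants", call. = FALSE)
    coh <- cohort[idx, ]
    e <- ef$peak_e
    pe <- function(x) stats::cor.test(x, e, method = "pearson")
    sp <- function(x) suppressWarnings(
      stats::cor.test(x, e, method = "spearman", exact = FALSE))
    tt <- stats::t.test(e[coh$gender == "male"], e[coh$gender == "female"])
    res <- list(
      pearson_hc = pe(coh$head_circumference),
      pearson_ci = pe(coh$cephalic_index),
      spearman_age = sp(coh$age),
      spearman_bmi = sp(coh$bmi),
      ttest_gender = tt
    )
    for (nm in names(res))
      rows[[length(rows) + 1L]] <- data.frame(
        montage_id = m, test = nm,
        estimate = unname(res[[nm]]$estimate[1L]),
        p_value = res[[nm]]$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_value, m = nrow(out))
  out
}

#' Compare demographics of an original and a reduced cohort
#'
#' Selection-bias check after attrition: chi-squared test on gender
#' counts, two-sample Kolmogorov-Smirnov test on age, Mann-Whitney U test
#' on BMI (rows with missing BMI excluded).
#'
#' @param original,reduced cohort tables.
#' @return data frame with `test`, `statistic`, `p_value`.
#' @export
cohort_comparison <- function(original, reduced) {
  stopifnot(nrow(original) > 0L, nrow(reduced) > 0L)
  counts <- rbind(table(factor(original$gender, c("female", "male"))),
                  table(factor(reduced$gender, c("female", "male"))))
  chi <- suppressWarnings(stats::chisq.test(counts))
  ks <- suppressWarnings(stats::ks.test(original$age, reduced$age))
  b1 <- original$bmi[!is.na(original$bmi)]
  b2 <- reduced$bmi[!is.na(reduced$bmi)]
  if (!length(b1) || !length(b2))
    stop("insufficient data: no calculable BMI after exclusion",
         call. = FALSE)
  mw <- suppressWarnings(stats::wilcox.test(b1, b2))
  data.frame(
    test = c("chisq_gender", "ks_age", "mannwhitney_bmi"),
    statistic = c(unname(chi$statistic), unname(ks$statistic),
                  unname(mw$statistic)),
    p_value = c(chi$p.value, ks$p.value, mw$p.value),
    stringsAsFactors = FALSE)
}
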