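#' Configuration of the robust IRLS fit
#'
#' @param k bisquare tuning constant (default 4.685, ~95% Gaussian
#'   efficiency).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param max_iter iteration cap.
#' @return list of class `tes_robust_config`.
#' @export
robust_config <- function(k = 4.685, tol = 1e-8, max_iter = 50L) {
  stopifnot(k > 0, tol > 0, max_iter >= 1)
  structure(list(k = k, tol = tol, max_iter = as.integer(max_iter)),
            class = "tes_robust_config")
}

#' Ordinary least squares fit
#'
#' QR-based least squares; also the initializer of the robust fit.
#'
#' @param X design matrix including the intercept column.
#' @param y outcome vector.
#' @return named coefficient vector.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X))
    stop("need more observations than coefficients", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular design: rank ", qx$rank, " < ", ncol(X), " columns",
         call. = FALSE)
  stats::setNames(drop(qr.coef(qx, y)), colnames(X))
}

#' Robust linear regression by IRLS with Tukey's bisquare weights
#'
#' Iteratively reweighted least squares with the bisquare weight function
#' `w(u) = (1 - (u/k)^2)^2` for `|u| < k` and 0 otherwise, where
#' `u = r / (s * sqrt(1 - h))`, `r` the current residual, `h` the design
#' leverage, and `s = median(|r|) / 0.6745` the robust residual scale,
#' re-estimated each iteration. The fit starts at the OLS solution and
#' stops when the maximum absolute coefficient change drops below `tol`.
#'
#' @inheritParams ols_fit
#' @param cfg a [robust_config()].
#' @return list of class `tes_robust_fit` with `coefficients`, `scale`,
#'   `weights` (in `[0, 1]`), `iterations`, `converged`.
#' @export
robust_fit_bisquare <- function(X, y, cfg = robust_config()) {
  stopifnot(inherits(cfg, "tes_robust_config"))
  X <- as.matrix(X)
  beta <- ols_fit(X, y)
  qx <- qr(X)
  h <- pmin(rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2), 1 - 1e-8)
  adj <- sqrt(1 - h)
  n <- nrow(X)
  weights <- rep(1, n)
  scale <- NA_real_
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    r <- y - drop(X %*% beta)
    scale <- stats::median(abs(r)) / 0.6745
    if (scale < .Machine$double.eps^0.75 * max(1, stats::median(abs(y)))) {
      # (near-)exact fit: residuals are numerically zero
      weights <- rep(1, n)
      converged <- TRUE
      break
    }
    u <- r / (scale * adj)
    weights <- ifelse(abs(u) < cfg$k, (1 - (u / cfg$k)^2)^2, 0)
    if (all(weights == 0))
      stop("degenerate weighting: all observations received zero weight",
           call. = FALSE)
    fit <- stats::lm.wfit(X, y, w = weights)
    new_beta <- stats::setNames(fit$coefficients, colnames(X))
    if (anyNA(new_beta))
      stop("singular design in reweighted step", call. = FALSE)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(coefficients = beta, scale = scale, weights = weights,
                 iterations = iter, converged = converged, config = cfg),
            class = "tes_robust_fit")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the
#' remaining predictors (with intercept). Values below 2.5 are considered
#' acceptable; exceedance triggers a warning, never an abort. Perfect
#' collinearity reports `Inf`.
#'
#' @param X predictor matrix without the intercept column (>= 2 columns).
#' @param threshold acceptability threshold (default 2.5).
#' @return list of class `tes_vif` with `vif` (named) and `acceptable`.
#' @export
vif <- function(X, threshold = 2.5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 predictors", call. = FALSE)
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("a predictor has zero variance", call. = FALSE)
  vals <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    res <- stats::lm.fit(Zj, yj)$residuals
    ss_tot <- sum((yj - mean(yj))^2)
    r2 <- 1 - sum(res^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vals) <- colnames(X)
  out <- list(vif = vals, acceptable = all(vals < threshold),
              threshold = threshold)
  if (!out$acceptable)
    warning("VIF exceeds ", threshold, " for: ",
            paste(names(vals)[vals >= threshold], collapse = ", "),
            call. = FALSE)
  structure(out, class = "tes_vif")
}

ms_design <- function(features, include_ed = FALSE) {
  cols <- c("x_age", "x_hc", "x_ci", "x_bmi", "x_gender")
  nm <- c("age", "hc", "ci", "bmi", "gender")
  if (include_ed) {
    cols <- c(cols, "x_ed")
    nm <- c(nm, "ed")
  }
  miss <- setdiff(cols, names(features))
  if (length(miss))
    stop("encoding error: missing feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(1, as.matrix(features[, cols]))
  colnames(X) <- c("intercept", nm)
  X
}

#' Fit a montage-specific peak E-field model
#'
#' Robust regression of the standardized per-montage peak E-field on the
#' five standardized predictors (age, head circumference, cephalic index,
#' BMI, gender), with a multicollinearity (VIF) screen.
#'
#' @param features standardized feature data frame
#'   ([standardize_features()]).
#' @param y standardized peak E-field outcomes for one montage.
#' @param standardizer the `tes_standardizer` the features/outcome assume.
#' @param montage_id montage identifier.
#' @param cfg a [robust_config()].
#' @param include_ed also include the standardized inter-electrode
#'   distance as a sixth predictor (used by the linear montage-agnostic
#'   variant before coefficient averaging).
#' @return object of class `tes_ms_model`.
#' @export
fit_montage_specific <- function(features, y, standardizer = NULL,
                                 montage_id = "montage",
                                 cfg = robust_config(),
                                 include_ed = FALSE) {
  X <- ms_design(features, include_ed = include_ed)
  if (include_ed && stats::sd(X[, "ed"]) < 1e-10) {
    # constant within-montage distance: the ED term is indistinguishable
    # from the intercept, so it is dropped and reported as 0
    fit <- robust_fit_bisquare(X[, colnames(X) != "ed", drop = FALSE], y,
                               cfg)
    fit$coefficients <- c(fit$coefficients, ed = 0)[colnames(X)]
  } else {
    fit <- robust_fit_bisquare(X, y, cfg)
  }
  P <- X[, -1L, drop = FALSE]
  P <- P[, apply(P, 2L, stats::sd) > 1e-10, drop = FALSE]
  vrep <- vif(P)
  structure(list(montage_id = montage_id, coefficients = fit$coefficients,
                 fit = fit, vif = vrep, standardizer = standardizer,
                 config = unclass(cfg), include_ed = include_ed),
            class = "tes_ms_model")
}

#' Predict from a montage-specific model
#'
#' @param model a `tes_ms_model`.
#' @param features standardized feature data frame.
#' @param units `"standardized"` (default) or `"vm"`; V/m output applies
#'   the stored per-montage inverse outcome transform.
#' @return numeric vector of predictions.
#' @export
predict_montage_specific <- function(model, features,
                                     units = c("standardized", "vm")) {
  units <- match.arg(units)
  X <- ms_design(features, include_ed = isTRUE(model$include_ed))
  z <- drop(X %*% model$coefficients[colnames(X)])
  if (units == "standardized") return(z)
  unstandardize_outcome(z, model$standardizer, model$montage_id)
}

#' Average regression coefficients across montages
#'
#' @param coef_list list of identically named/ordered coefficient vectors.
#' @return element-wise arithmetic mean, same names.
#' @export
average_coefficients <- function(coef_list) {
  stopifnot(length(coef_list) >= 1L)
  ref <- names(coef_list[[1L]])
  for (b in coef_list)
    if (!identical(names(b), ref) || length(b) != length(coef_list[[1L]]))
      stop("shape error: coefficient vectors differ in design order",
           call. = FALSE)
  Reduce(`+`, coef_list) / length(coef_list)
}

agnostic_inner <- function(features, beta_bar, variant) {
  X <- ms_design(features, include_ed = (variant == "linear"))
  miss <- setdiff(colnames(X), names(beta_bar))
  if (length(miss))
    stop("shape error: averaged coefficients lack ",
         paste(miss, collapse = ", "), call. = FALSE)
  drop(X %*% beta_bar[colnames(X)])
}

#' Fit the distance-scaling coefficients of a montage-agnostic model
#'
#' With the averaged coefficients frozen, the scaling coefficients `S` are
#' the least-squares solution of the product model: the linear variant
#' minimizes `sum((y - S * d * L)^2)` and the quadratic variant
#' `sum((y - (S1*d^2 + S2*d + S3) * L)^2)`, where `L` is the inner
#' averaged-coefficient term and `d` the raw inter-electrode distance in
#' mm (kept raw so the scaling factor cannot flip sign). The inner term of
#' the linear variant includes the standardized-distance coefficient; the
#' quadratic variant's inner term has no distance coefficient.
#'
#' @param features standardized features including `x_ed` and `ed_raw`.
#' @param y standardized outcomes (pooled across training montages).
#' @param beta_bar averaged coefficients ([average_coefficients()]).
#' @param variant `"linear"` or `"quadratic"`.
#' @return named numeric vector of S coefficients (`S` for linear;
#'   `S1`, `S2`, `S3` for quadratic).
#' @export
fit_distance_scaling <- function(features, y, beta_bar,
                                 variant = c("linear", "quadratic")) {
  variant <- match.arg(variant)
  if (is.null(features$ed_raw))
    stop("encoding error: features lack ed_raw", call. = FALSE)
  d <- features$ed_raw
  L <- agnostic_inner(features, beta_bar, variant)
  if (all(abs(L) < .Machine$double.eps))
    stop("degenerate inner term: averaged model is identically zero",
         call. = FALSE)
  n_d <- length(unique(signif(d, 12)))
  if (variant == "linear") {
    if (n_d < 2L)
      stop("identifiability error: need >= 2 distinct distances",
           call. = FALSE)
    z <- d * L
    c(S = sum(z * y) / sum(z^2))
  } else {
    if (n_d < 3L)
      stop("identifiability error: need >= 3 distinct distances for the ",
           "quadratic variant", call. = FALSE)
    Z <- cbind(d^2 * L, d * L, L)
    fit <- stats::lm.fit(Z, y)
    if (anyNA(fit$coefficients))
      stop("identifiability error: singular quadratic scaling design",
           call. = FALSE)
    stats::setNames(fit$coefficients, c("S1", "S2", "S3"))
  }
}

#' Fit a montage-agnostic model
#'
#' Two-stage procedure: per-montage robust models are fit on the training
#' montages (with the standardized inter-electrode distance as an extra
#' predictor for the linear variant), their coefficients averaged, and the
#' distance-scaling coefficients estimated on the pooled training rows
#' with the averaged coefficients frozen.
#'
#' @param train data frame of training rows: standardized features
#'   (`x_*`, `ed_raw`), `montage_id` and standardized outcome `y`.
#' @param variant `"linear"` or `"quadratic"`.
#' @param cfg a [robust_config()].
#' @param standardizer the `tes_standardizer` the rows assume.
#' @return object of class `tes_agnostic_model`.
#' @export
fit_montage_agnostic <- function(train, variant = c("linear", "quadratic"),
                                 cfg = robust_config(), standardizer = NULL) {
  variant <- match.arg(variant)
  ids <- unique(train$montage_id)
  if (length(ids) < 1L) stop("no training montages", call. = FALSE)
  coefs <- lapply(ids, function(m) {
    rows <- train[train$montage_id == m, , drop = FALSE]
    fit_montage_specific(rows, rows$y, montage_id = m, cfg = cfg,
                         include_ed = (variant == "linear"))$coefficients
  })
  beta_bar <- average_coefficients(coefs)
  S <- fit_distance_scaling(train, train$y, beta_bar, variant)
  structure(list(variant = variant, beta_bar = beta_bar, S = S,
                 trained_montages = ids, config = unclass(cfg),
                 standardizer = standardizer),
            class = "tes_agnostic_model")
}

#' Predict from a montage-agnostic model
#'
#' Evaluates the product form: scaling factor (linear `S * d`; quadratic
#' `S1*d^2 + S2*d + S3`, `d` the raw inter-electrode distance in mm) times
#' the averaged-coefficient inner term.
#'
#' @param model a `tes_agnostic_model`.
#' @param features standardized features including `x_ed` and `ed_raw`.
#' @param units `"standardized"` (default) or `"vm"`; V/m requires
#'   `montage_id` with outcome statistics in the stored standardizer.
#' @param montage_id montage whose inverse outcome transform to use for
#'   V/m output.
#' @return numeric vector of predictions.
#' @export
predict_agnostic <- function(model, features,
                             units = c("standardized", "vm"),
                             montage_id = NULL) {
  units <- match.arg(units)
  if (is.null(features$ed_raw))
    stop("encoding error: features lack ed_raw", call. = FALSE)
  d <- features$ed_raw
  L <- agnostic_inner(features, model$beta_bar, model$variant)
  fac <- if (model$variant == "linear") model$S[["S"]] * d
         else model$S[["S1"]] * d^2 + model$S[["S2"]] * d + model$S[["S3"]]
  z <- fac * L
  if (units == "standardized") return(z)
  if (is.null(montage_id))
    stop("montage_id required for V/m output", call. = FALSE)
  unstandardize_outcome(z, model$standardizer, montage_id)
}
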