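test_that("OLS matches the normal-equations oracle", {
  x <- seq(-3, 3, length.out = 20)
  X <- cbind(intercept = 1, x = x)
  expect_equal(unname(ols_fit(X, 2 * x)), c(0, 2), tolerance = 1e-12)
  expect_equal(unname(ols_fit(X, rep(5, 20))), c(5, 0), tolerance = 1e-12)

  set.seed(21)
  Xr <- cbind(1, matrix(rnorm(300), ncol = 3))
  y <- rnorm(100)
  oracle <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  expect_equal(unname(ols_fit(Xr, y)), drop(oracle), tolerance = 1e-8)
  r <- y - Xr %*% ols_fit(Xr, y)
  expect_lt(max(abs(t(Xr) %*% r)), 1e-8)

  expect_error(ols_fit(cbind(1, x, x), 2 * x), "singular")
})

test_that("bisquare IRLS agrees with OLS on clean data and resists outliers", {
  set.seed(33)
  agree <- replicate(20, {
    X <- cbind(1, scale(matrix(rnorm(3000), ncol = 3)))
    y <- drop(X %*% c(0.2, 1, -0.5, 0.3)) + rnorm(1000)
    max(abs(robust_fit_bisquare(X, y)$coefficients - ols_fit(X, y)))
  })
  expect_true(all(agree < 0.02))

  wins <- replicate(30, {
    x <- rnorm(200)
    y <- 2 * x + rnorm(200)
    out <- sample(200, 10)
    y[out] <- y[out] + 10          # gross one-directional shift
    X <- cbind(1, x)
    truth <- c(0, 2)
    sqrt(sum((robust_fit_bisquare(X, y)$coefficients - truth)^2)) <
      sqrt(sum((ols_fit(X, y) - truth)^2))
  })
  expect_gte(mean(wins), 0.9)
})

test_that("exact data converges immediately with unit weights", {
  x <- 1:50
  fit <- robust_fit_bisquare(cbind(1, x), 2 * x)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-10)
  expect_lte(fit$iterations, 2L)
  expect_true(fit$converged)
  expect_true(all(fit$weights == 1))
})

test_that("IRLS approaches OLS as the tuning constant grows", {
  set.seed(44)
  x <- rnorm(300)
  y <- 1 + 0.7 * x + rt(300, df = 3)
  X <- cbind(1, x)
  big_k <- robust_fit_bisquare(X, y, robust_config(k = 1e6))
  expect_equal(unname(big_k$coefficients), unname(ols_fit(X, y)),
               tolerance = 1e-6)
})

test_that("IRLS coefficients track an independent robust fitter", {
  skip_if_not_installed("MASS")
  set.seed(55)
  x1 <- rnorm(500); x2 <- rnorm(500)
  y <- 1 - 0.8 * x1 + 0.4 * x2 + rnorm(500)
  y[1:15] <- y[1:15] + 12
  ours <- robust_fit_bisquare(cbind(1, x1, x2), y)$coefficients
  theirs <- MASS::rlm(y ~ x1 + x2, psi = MASS::psi.bisquare, c = 4.685,
                      maxit = 100)$coefficients
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("robust fit weights stay in [0,1] and flag convergence", {
  set.seed(66)
  x <- rnorm(100)
  fit <- robust_fit_bisquare(cbind(1, x), x + rnorm(100))
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_true(fit$converged)
})

test_that("VIF matches the closed form and flags collinearity", {
  ortho <- unclass(poly(1:100, 4))   # orthonormal and mean-centered
  v <- vif(ortho)
  expect_equal(unname(v$vif), rep(1, 4), tolerance = 1e-9)
  expect_true(v$acceptable)

  x <- rnorm(100)
  expect_warning(dup <- vif(cbind(a = x, b = x)), "VIF")
  expect_true(all(is.infinite(dup$vif)))
  expect_false(dup$acceptable)

  for (r_target in c(0.3, 0.8)) {
    z <- rnorm(2000)
    a <- r_target * z + sqrt(1 - r_target^2) * rnorm(2000)
    r <- cor(a, z)
    v2 <- vif(cbind(a = a, z = z))
    expect_equal(unname(v2$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-9)
  }
})

test_that("the default synthetic cohort design is acceptably collinear", {
  # head circumference and gender are genuinely correlated (per-gender
  # means differ), but the design stays under the VIF 2.5 rule
  fx <- standardized_fixture(seed = 30L, n = 4000L)
  v <- vif(as.matrix(fx$features[, c("x_age", "x_hc", "x_ci", "x_bmi",
                                     "x_gender")]))
  expect_true(v$acceptable)
  expect_true(all(v$vif >= 1))
})

test_that("montage-specific fit recovers zero-noise coefficients exactly", {
  fx <- standardized_fixture(seed = 2L, n = 418L)
  beta <- c(intercept = 0.1, age = -0.9, hc = -0.55, ci = -0.2,
            bmi = -0.15, gender = -0.3)
  X <- cbind(intercept = 1, age = fx$features$x_age, hc = fx$features$x_hc,
             ci = fx$features$x_ci, bmi = fx$features$x_bmi,
             gender = fx$features$x_gender)
  y <- drop(X %*% beta)
  model <- fit_montage_specific(fx$features, y, montage_id = "syn")
  expect_equal(model$coefficients, beta, tolerance = 1e-6)
  expect_true(model$vif$acceptable)
})

test_that("fitting permuted outcomes yields no out-of-sample signal", {
  fx <- standardized_fixture(seed = 6L, n = 418L)
  set.seed(77)
  r2 <- replicate(20, {
    y <- drop(as.matrix(fx$features[, 1:5]) %*% c(-0.9, -0.55, -0.2, -0.15,
                                                  -0.3)) + rnorm(418, 0, 0.8)
    perm <- sample(418)
    train <- 1:209; test <- 210:418
    m <- fit_montage_specific(fx$features[train, ], y[perm][train])
    adjusted_r2(y[perm][test],
                predict_montage_specific(m, fx$features[test, ]), p = 5)
  })
  expect_gte(mean(r2 <= 0.05), 0.95)
})

test_that("montage-specific predictions are the stated linear combination", {
  fv <- data.frame(x_age = 0.5, x_hc = 1.2, x_ci = -0.4, x_bmi = 0.3,
                   x_gender = 1)
  beta <- c(intercept = 0.25, age = -1, hc = -0.5, ci = 0.2, bmi = -0.1,
            gender = -0.3)
  model <- structure(list(montage_id = "m", coefficients = beta,
                          include_ed = FALSE), class = "tes_ms_model")
  hand <- 0.25 - 1 * 0.5 - 0.5 * 1.2 + 0.2 * (-0.4) - 0.1 * 0.3 - 0.3
  expect_equal(predict_montage_specific(model, fv), hand)

  zero <- model; zero$coefficients[] <- 0
  expect_equal(predict_montage_specific(zero, fv), 0)
  intercept_only <- model
  expect_equal(predict_montage_specific(model, transform(fv, x_age = 0,
    x_hc = 0, x_ci = 0, x_bmi = 0, x_gender = 0)), 0.25)
})

test_that("coefficient averaging is the element-wise mean", {
  b1 <- c(intercept = 1, age = 1); b2 <- c(intercept = 3, age = 3)
  expect_equal(average_coefficients(list(b1, b2)),
               c(intercept = 2, age = 2))
  expect_equal(average_coefficients(list(b1, b1, b1)), b1)
  set.seed(3)
  vs <- lapply(1:5, function(i)
    setNames(rnorm(4), c("intercept", "a", "b", "c")))
  expect_equal(average_coefficients(vs),
               Reduce(`+`, vs) / 5, tolerance = 1e-12)
  expect_error(average_coefficients(list(b1, c(age = 1, intercept = 1))),
               "shape")
})

agnostic_fixture <- function(seed, n = 418L) {
  fx <- standardized_fixture(seed = seed, n = n)
  set.seed(seed + 1000)
  ed <- runif(n, 30, 180)
  feats <- fx$features
  feats$ed_raw <- ed
  feats$x_ed <- (ed - mean(ed)) / sd(ed)
  feats
}

test_that("distance scaling recovers zero-noise S exactly (linear form)", {
  feats <- agnostic_fixture(12L)
  beta_bar <- c(intercept = 0.4, age = -0.8, hc = -0.5, ci = -0.2,
                bmi = -0.1, gender = -0.25, ed = -0.15)
  X <- cbind(intercept = 1, age = feats$x_age, hc = feats$x_hc,
             ci = feats$x_ci, bmi = feats$x_bmi, gender = feats$x_gender,
             ed = feats$x_ed)
  L <- drop(X %*% beta_bar)
  y <- 0.012 * feats$ed_raw * L
  S <- fit_distance_scaling(feats, y, beta_bar, variant = "linear")
  expect_equal(unname(S), 0.012, tolerance = 1e-6)
  expect_equal(unname(fit_distance_scaling(feats, rep(0, nrow(feats)),
                                           beta_bar, "linear")), 0)
})

test_that("distance scaling recovers zero-noise S exactly (quadratic form)", {
  feats <- agnostic_fixture(13L)
  beta_bar <- c(intercept = 0.4, age = -0.8, hc = -0.5, ci = -0.2,
                bmi = -0.1, gender = -0.25)
  X <- cbind(intercept = 1, age = feats$x_age, hc = feats$x_hc,
             ci = feats$x_ci, bmi = feats$x_bmi, gender = feats$x_gender)
  L <- drop(X %*% beta_bar)
  S_true <- c(S1 = -2e-5, S2 = 0.004, S3 = 0.6)
  y <- (S_true[1] * feats$ed_raw^2 + S_true[2] * feats$ed_raw +
          S_true[3]) * L
  S <- fit_distance_scaling(feats, y, beta_bar, variant = "quadratic")
  expect_equal(S, S_true, tolerance = 1e-6)

  feats2 <- feats; feats2$ed_raw <- rep(c(40, 90), length.out = nrow(feats))
  expect_error(fit_distance_scaling(feats2, y, beta_bar, "quadratic"),
               "identifiability")
  zeroL <- c(beta_bar, ed = 0); zeroL[] <- 0
  expect_error(fit_distance_scaling(feats, y, zeroL, "linear"),
               "degenerate inner term")
  expect_error(fit_distance_scaling(feats, y, beta_bar, "linear"),
               "shape error")
})

test_that("agnostic predictions evaluate the printed product form", {
  fv <- data.frame(x_age = 0.5, x_hc = -1, x_ci = 0.2, x_bmi = 0,
                   x_gender = 0, x_ed = 0.3, ed_raw = 80)
  beta_bar <- c(intercept = 0.4, age = -0.8, hc = -0.5, ci = -0.2,
                bmi = -0.1, gender = -0.25, ed = -0.15)
  L <- 0.4 - 0.8 * 0.5 - 0.5 * (-1) - 0.2 * 0.2 - 0.15 * 0.3
  model <- structure(list(variant = "linear", beta_bar = beta_bar,
                          S = c(S = 0.01)), class = "tes_agnostic_model")
  expect_equal(predict_agnostic(model, fv), 0.01 * 80 * L)

  double_S <- model; double_S$S <- c(S = 0.02)
  expect_equal(predict_agnostic(double_S, fv),
               2 * predict_agnostic(model, fv))

  qmodel <- structure(list(variant = "quadratic",
                           beta_bar = beta_bar[1:6],
                           S = c(S1 = 1e-5, S2 = -0.002, S3 = 0.9)),
                      class = "tes_agnostic_model")
  Lq <- 0.4 - 0.8 * 0.5 - 0.5 * (-1) - 0.2 * 0.2
  expect_equal(predict_agnostic(qmodel, fv),
               (1e-5 * 6400 - 0.002 * 80 + 0.9) * Lq)

  # inner term zero -> prediction zero for both variants
  fv0 <- fv; fv0[c("x_age", "x_hc", "x_ci", "x_bmi", "x_gender",
                   "x_ed")] <- 0
  model0 <- model; model0$beta_bar[] <- 0
  expect_equal(predict_agnostic(model0, fv), 0)
})

test_that("leave-one-montage-out is exact when montages share one truth", {
  # montage-level distances (constant within montage, as in the generative
  # model) and a zero inner-distance coefficient: the two-stage estimator
  # is then exactly identified and the held-out montage is predicted
  # without error
  fx <- standardized_fixture(seed = 20L, n = 200L)
  beta_bar <- c(intercept = 0.5, age = -0.8, hc = -0.5, ci = -0.2,
                bmi = -0.1, gender = -0.25, ed = 0)
  S_true <- 0.01
  eds <- c(A = 60, B = 100, C = 150, D = 45)
  mu <- mean(rep(eds, each = 200)); sdv <- sd(rep(eds, each = 200))
  rows <- lapply(names(eds), function(m) {
    f <- fx$features
    f$ed_raw <- rep(eds[[m]], 200)
    f$x_ed <- (f$ed_raw - mu) / sdv
    f$montage_id <- m
    X <- cbind(1, f$x_age, f$x_hc, f$x_ci, f$x_bmi, f$x_gender, f$x_ed)
    f$y <- S_true * f$ed_raw * drop(X %*% beta_bar)
    f
  })
  train <- do.call(rbind, rows[1:3])
  held <- rows[[4]]
  model <- fit_montage_agnostic(train, variant = "linear")
  expect_equal(predict_agnostic(model, held), held$y, tolerance = 1e-6)

  # quadratic variant, same construction
  S_q <- c(S1 = -1e-5, S2 = 0.006, S3 = 0.3)
  rows_q <- lapply(rows, function(f) {
    X <- cbind(1, f$x_age, f$x_hc, f$x_ci, f$x_bmi, f$x_gender)
    f$y <- (S_q[1] * f$ed_raw^2 + S_q[2] * f$ed_raw + S_q[3]) *
      drop(X %*% beta_bar[1:6])
    f
  })
  model_q <- fit_montage_agnostic(do.call(rbind, rows_q[1:3]),
                                  variant = "quadratic")
  held_q <- rows_q[[4]]
  expect_equal(predict_agnostic(model_q, held_q), held_q$y,
               tolerance = 1e-6)
})
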