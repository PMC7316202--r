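test_that("noiseless log-linear data is recovered exactly", {
  set.seed(61)
  X <- data.frame(T_RN2 = runif(50, 0.15, 0.35), Trr = runif(50, 0.6, 1.1))
  y <- exp(4.8 + 2.0 * X$T_RN2 - 1.5 * X$Trr)
  m <- fit_log_linear(X, y, "sbp")
  expect_equal(m$beta0, 4.8, tolerance = 1e-8)
  expect_equal(unname(m$betas), c(2.0, -1.5), tolerance = 1e-8)
  # in-sample round trip is numerically exact
  expect_lt(max(abs(predict(m, X) - y)), 1e-6)

  # constant response: zero slopes, intercept = log level
  yc <- rep(123, 50)
  mc <- fit_log_linear(X["T_RN2"], yc, "sbp")
  expect_equal(unname(mc$betas), 0, tolerance = 1e-10)
  expect_equal(mc$beta0, log(123), tolerance = 1e-10)
})

test_that("degenerate designs and responses are rejected with names", {
  X <- data.frame(T_RN2 = runif(20), Trr = runif(20))
  X$Tpt <- X$T_RN2                     # exact duplicate
  y <- exp(4.8 + X$T_RN2)
  expect_error(fit_log_linear(X, y), "Tpt")
  expect_error(fit_log_linear(X[1:2], c(y[-1], -5)), "positive")
  expect_error(fit_log_linear(data.frame(bogus = 1:20), y), "unknown feature")
  m <- fit_log_linear(X[1:2], y)
  expect_error(predict(m, data.frame(T_RN2 = 0.2)), "Trr")
  expect_error(predict(m, c(T_RN2 = 0.2, Trr = NA)), "Trr")
})

test_that("coefficient error shrinks with sample size", {
  set.seed(62)
  rmse <- function(n, n_rep = 60) {
    errs <- replicate(n_rep, {
      X <- data.frame(T_RN2 = runif(n, 0.15, 0.35), Trr = runif(n, 0.6, 1.1))
      y <- exp(4.8 - 1.2 * X$T_RN2 + 0.4 * X$Trr + rnorm(n, 0, 0.03))
      m <- fit_log_linear(X, y)
      sqrt(mean((c(m$betas) - c(-1.2, 0.4))^2))
    })
    mean(errs)
  }
  expect_lt(rmse(200), rmse(50))
})

test_that("agreement statistics match hand values and a scalar-loop oracle", {
  ev <- evaluate_bp(c(120, 130), c(118, 133))
  expect_equal(ev$me, -0.5)
  expect_equal(ev$mae, 2.5)
  expect_equal(ev$sd, 3.5355, tolerance = 1e-4)

  perfect <- evaluate_bp(c(120, 80, 95), c(120, 80, 95))
  expect_equal(perfect$me, 0); expect_equal(perfect$mae, 0)
  expect_equal(perfect$sd, 0)
  expect_equal(perfect$bhs$grade, "A")
  expect_true(perfect$aami_pass)

  offset <- evaluate_bp(c(120, 80, 95) + 6, c(120, 80, 95))
  expect_equal(offset$me, 6); expect_equal(offset$sd, 0)
  expect_false(offset$aami_pass)

  set.seed(63)
  for (rep in 1:20) {
    p <- rnorm(40, 120, 10); y <- rnorm(40, 120, 10)
    want <- oracle_eval(p, y)
    got <- evaluate_bp(p, y)
    expect_equal(got$me, want$me, tolerance = 1e-12)
    expect_equal(got$mae, want$mae, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(got$ba_pairs$mean, (p + y) / 2)
    expect_equal(got$ba_pairs$difference, p - y)
    expect_true(got$mae >= abs(got$me))
    ws <- unlist(got$bhs[c("within5", "within10", "within15")])
    expect_true(all(diff(ws) >= 0))
  }
})

test_that("grading degrades monotonically with a growing constant error", {
  y <- rep(120, 100)
  grades <- character(0); aami <- logical(0)
  for (off in c(0, 4, 7, 12, 20)) {
    ev <- evaluate_bp(y + off, y)
    grades <- c(grades, ev$bhs$grade)
    aami <- c(aami, ev$aami_pass)
  }
  expect_equal(grades[1], "A")
  expect_false(is.unsorted(match(grades, c("A", "B", "C", "D"))))
  expect_true(aami[1]); expect_false(any(aami[-(1:2)]))
  expect_equal(bhs_grade(50, 75, 90), "B")
  expect_equal(bhs_grade(40, 65, 85), "C")
  expect_equal(bhs_grade(39, 65, 85), "D")
})

test_that("univariate screening keeps informative features only", {
  set.seed(64)
  n <- 500
  X <- data.frame(T_RN2 = runif(n), Trr = runif(n))
  y <- exp(2 * X$T_RN2 + 3)
  X$Tab <- sample(X$T_RN2)             # permuted: same marginal, no link
  keep <- screen_features_r2(X, y)
  expect_true("T_RN2" %in% keep)
  expect_false("Tab" %in% keep)
  expect_equal(attr(keep, "r2")[["T_RN2"]], 1, tolerance = 1e-9)
  expect_length(screen_features_r2(X, y, threshold = 1.1), 0)
})

test_that("greedy wrapper selection finds the generating features", {
  hits <- 0L
  for (seed in 1:25) {
    set.seed(seed + 700)
    n <- 120
    X <- data.frame(T_RN2 = runif(n, 0.15, 0.35), Trr = runif(n, 0.6, 1.1),
                    Tab = runif(n), Taa = runif(n))
    y <- exp(4.8 - 2 * X$T_RN2 + 0.8 * X$Trr + rnorm(n, 0, 0.01))
    sel <- wrapper_select(X, y, names(X), cv_folds = 5, seed = seed)
    if (all(c("T_RN2", "Trr") %in% sel$features) &&
        !any(c("Tab", "Taa") %in% sel$features)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 23)  # >= 90% of seeded runs

  # duplicated feature: exactly one of the pair enters
  set.seed(65)
  X2 <- data.frame(T_RN2 = runif(80, 0.15, 0.35))
  X2$Tpt <- X2$T_RN2
  y2 <- exp(4.8 - 2 * X2$T_RN2 + rnorm(80, 0, 0.01))
  sel2 <- wrapper_select(X2, y2, names(X2), seed = 1)
  expect_equal(sum(c("T_RN2", "Tpt") %in% sel2$features), 1)
  expect_equal(sel2$features[1], "T_RN2")  # tie prefers the first candidate

  # single informative candidate beats the intercept-only model
  sel3 <- wrapper_select(X2["T_RN2"], y2, "T_RN2", seed = 1)
  expect_equal(sel3$features, "T_RN2")
  # single uninformative candidate does not enter
  set.seed(66)
  sel4 <- wrapper_select(data.frame(Tab = runif(80)), y2, "Tab", seed = 1)
  expect_length(sel4$features, 0)
})

test_that("published feature sets have the documented sizes and nesting", {
  sets <- default_feature_sets()
  expect_length(sets$sbp, 9)
  expect_length(sets$dbp, 14)
  expect_true(all(sets$sbp %in% sets$dbp))
  expect_true(all(sets$dbp %in% feature_names()))
})

test_that("models serialize to JSON and back unchanged", {
  set.seed(67)
  X <- data.frame(T_RN2 = runif(30, 0.15, 0.35), Trr = runif(30, 0.6, 1.1))
  m <- fit_log_linear(X, exp(4.8 - X$T_RN2 + 0.2 * X$Trr), "dbp")
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  expect_equal(m2$target, "dbp")
  expect_equal(m2$beta0, m$beta0)
  expect_equal(m2$betas, m$betas)
  expect_equal(predict(m2, X), predict(m, X))
})
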