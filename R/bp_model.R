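#' Fit a log-linear blood-pressure model
#'
#' Ordinary least squares of `ln(BP)` on the supplied features with an
#' intercept.  The semi-log form reflects the inverse-exponential
#' relation between pulse transit time and pressure, keeps predictions
#' strictly positive, and puts the millisecond-scale timing features
#' and the ~100 mmHg response on comparable scales.
#'
#' @param X Data frame (or matrix) of feature columns; names must be
#'   among the 32 canonical [feature_names()].
#' @param y Reference blood pressures in mmHg, all positive; one per
#'   row of `X`.
#' @param target `"sbp"` or `"dbp"` (label only).
#' @return An object of class `log_linear_model`: `target`,
#'   `feature_names`, `beta0`, `betas` (per-feature, units 1/seconds)
#'   and `fit_diagnostics` (n, residual SD on the log scale, R^2).
#' @export
fit_log_linear <- function(X, y, target = c("sbp", "dbp")) {
  target <- match.arg(target)
  X <- as.data.frame(X)
  if (!all(names(X) %in% feature_names())) {
    stop("fit_log_linear: unknown feature columns: ",
         paste(setdiff(names(X), feature_names()), collapse = ", "))
  }
  if (nrow(X) != length(y)) stop("fit_log_linear: nrow(X) != length(y)")
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("fit_log_linear: all reference BP values must be positive")
  }
  if (nrow(X) < ncol(X) + 1L) {
    stop("fit_log_linear: need at least ", ncol(X) + 1L, " rows for ",
         ncol(X), " features")
  }
  dat <- cbind(X, .logy = log(y))
  fit <- stats::lm(.logy ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("fit_log_linear: design is rank deficient; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  structure(
    list(target = target,
         feature_names = names(X),
         beta0 = unname(cf[1L]),
         betas = stats::setNames(unname(cf[-1L]), names(X)),
         fit_diagnostics = list(
           n = nrow(X),
           sigma_log = stats::sigma(fit),
           r_squared = suppressWarnings(summary(fit)$r.squared)
         )),
    class = "log_linear_model"
  )
}

#' @export
print.log_linear_model <- function(x, ...) {
  cat(sprintf("<log_linear_model> target %s, %d features, n = %d\n",
              toupper(x$target), length(x$feature_names),
              x$fit_diagnostics$n))
  cat(sprintf("  ln(%s) = %.4f %s\n", toupper(x$target), x$beta0,
              paste(sprintf("%+.4f*%s", x$betas, x$feature_names),
                    collapse = " ")))
  invisible(x)
}

#' Predict blood pressure from a feature vector
#'
#' @param object A `log_linear_model`.
#' @param newdata A named numeric vector / `feature_vector`, or a data
#'   frame of such rows, supplying every model feature non-missing.
#' @param ... Unused.
#' @return Predicted BP in mmHg (always positive).
#' @export
predict.log_linear_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    Xm <- newdata
  } else {
    Xm <- as.data.frame(as.list(newdata))
  }
  missing_f <- setdiff(object$feature_names, names(Xm))
  if (length(missing_f)) {
    stop("predict: feature(s) missing from input: ",
         paste(missing_f, collapse = ", "))
  }
  Xm <- Xm[object$feature_names]
  if (anyNA(Xm)) {
    bad <- names(Xm)[vapply(Xm, anyNA, logical(1))]
    stop("predict: feature(s) with missing values: ",
         paste(bad, collapse = ", "))
  }
  lp <- object$beta0 + as.numeric(as.matrix(Xm) %*% object$betas)
  exp(lp)
}

#' Agreement statistics between estimated and reference BP
#'
#' Computes the mean error `ME = sum(p - y)/n`, mean absolute error
#' `MAE = sum(|p - y|)/n` and the standard deviation of errors
#' `SD = sqrt(sum(((p - y) - ME)^2) / (n - 1))`, together with
#' Bland-Altman pairs `((p + y)/2, p - y)`, the BHS cumulative
#' percentages of absolute errors within 5, 10 and 15 mmHg with the
#' corresponding grade, and the AAMI criterion (`|ME| <= 5` and
#' `SD <= 8` mmHg).
#'
#' @param p Estimated BP values (mmHg).
#' @param y Reference BP values (mmHg), same length (>= 2).
#' @return An object of class `eval_report`: `me`, `mae`, `sd`, `n`,
#'   `ba_pairs` (data.frame `mean`, `difference`), `bhs` (list
#'   `within5/10/15`, `grade`), `aami_pass`.
#' @export
#' @examples
#' evaluate_bp(c(120, 130), c(118, 133)) # ME -0.5, MAE 2.5, SD 3.5355
evaluate_bp <- function(p, y) {
  if (length(p) != length(y)) stop("evaluate_bp: length mismatch")
  if (length(p) < 2L) stop("evaluate_bp: need at least 2 value pairs")
  e <- p - y
  me <- sum(e) / length(e)
  mae <- sum(abs(e)) / length(e)
  sdv <- sqrt(sum((e - me)^2) / (length(e) - 1))
  within <- function(thr) 100 * mean(abs(e) <= thr)
  bhs <- list(within5 = within(5), within10 = within(10),
              within15 = within(15))
  bhs$grade <- bhs_grade(bhs$within5, bhs$within10, bhs$within15)
  structure(
    list(me = me, mae = mae, sd = sdv, n = length(e),
         ba_pairs = data.frame(mean = (p + y) / 2, difference = e),
         bhs = bhs,
         aami_pass = aami_check(me, sdv)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d: ME %.2f, MAE %.2f, SD %.2f mmHg | BHS %0.f/%0.f/%0.f%% grade %s | AAMI %s\n",
    x$n, x$me, x$mae, x$sd, x$bhs$within5, x$bhs$within10, x$bhs$within15,
    x$bhs$grade, if (x$aami_pass) "pass" else "fail"))
  invisible(x)
}

#' BHS cumulative-error grade
#'
#' British Hypertension Society protocol grades from the cumulative
#' percentages of absolute errors within 5, 10 and 15 mmHg:
#' A requires 60/85/95, B 50/75/90, C 40/65/85; anything less is D.
#' Thresholds are configurable.
#'
#' @param within5,within10,within15 Cumulative percentages (0-100).
#' @param thresholds Named list of `c(p5, p10, p15)` rows per grade.
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
bhs_grade <- function(within5, within10, within15,
                      thresholds = list(A = c(60, 85, 95),
                                        B = c(50, 75, 90),
                                        C = c(40, 65, 85))) {
  got <- c(within5, within10, within15)
  for (g in names(thresholds)) {
    if (all(got >= thresholds[[g]])) return(g)
  }
  "D"
}

#' AAMI mean-error criterion
#'
#' A device passes when the mean error is within +/- 5 mmHg and the
#' error standard deviation is at most 8 mmHg.
#'
#' @param me Mean error (mmHg).
#' @param sd Error standard deviation (mmHg).
#' @param me_limit,sd_limit Criterion limits (defaults 5 and 8 mmHg).
#' @return Logical.
#' @export
aami_check <- function(me, sd, me_limit = 5, sd_limit = 8) {
  abs(me) <= me_limit && sd <= sd_limit
}

#' Univariate R-squared screening of candidate features
#'
#' For each feature column, the coefficient of determination of the
#' simple regression of `ln(y)` on that feature alone is computed;
#' features with `R^2` above the threshold are retained.  This is the
#' variance-explained screen applied before wrapper selection.
#'
#' @param X Data frame of feature columns.
#' @param y Reference BP values (mmHg, positive).
#' @param threshold Retention threshold on `R^2` (default 0.3).
#' @return Character vector of retained feature names; attribute `r2`
#'   holds all per-feature values.
#' @export
screen_features_r2 <- function(X, y, threshold = 0.3) {
  X <- as.data.frame(X)
  ly <- log(y)
  r2 <- vapply(X, function(col) {
    ok <- is.finite(col) & is.finite(ly)
    if (sum(ok) < 3L || stats::sd(col[ok]) == 0) return(0)
    stats::cor(col[ok], ly[ok])^2
  }, numeric(1))
  keep <- names(r2)[r2 > threshold]
  attr(keep, "r2") <- r2
  keep
}

#' Greedy forward wrapper selection by cross-validated MAE
#'
#' Starting from the empty set, repeatedly adds the candidate feature
#' that most reduces the cross-validated mean absolute error (mmHg) of
#' the log-linear fit, stopping when no candidate improves it by at
#' least `min_improve` (relative; cross-validation scores fluctuate, so
#' a parsimony margin keeps pure-noise candidates out).  Candidates
#' that make the design rank deficient score infinitely badly and are
#' never taken.  Fold assignment is drawn once from `seed`, so the
#' result is deterministic; ties prefer the earlier candidate.
#'
#' @param X Data frame of feature columns.
#' @param y Reference BP values.
#' @param candidates Candidate feature names (non-empty subset of
#'   `names(X)`).
#' @param cv_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param min_improve Minimum relative CV-MAE improvement to accept a
#'   feature (default 0.01).
#' @return A list with `features` (selected names, possibly empty) and
#'   `cv_mae` (score of the selected set; intercept-only if empty).
#' @export
wrapper_select <- function(X, y, candidates = names(X), cv_folds = 5L,
                           seed = 1L, min_improve = 0.01) {
  X <- as.data.frame(X)
  stopifnot(length(candidates) > 0L, all(candidates %in% names(X)))
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_mae <- function(feats) {
    errs <- numeric(0)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      te <- !tr
      if (length(feats) == 0L) {
        pred <- rep(exp(mean(log(y[tr]))), sum(te))
      } else {
        m <- tryCatch(fit_log_linear(X[tr, feats, drop = FALSE], y[tr]),
                      error = function(e) NULL)
        if (is.null(m)) return(Inf)
        pred <- predict(m, X[te, feats, drop = FALSE])
      }
      errs <- c(errs, abs(pred - y[te]))
    }
    mean(errs)
  }
  selected <- character(0)
  best <- cv_mae(selected)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    scores <- vapply(remaining, function(f) cv_mae(c(selected, f)),
                     numeric(1))
    i <- which.min(scores)          # ties: first index
    if (scores[i] >= best * (1 - min_improve)) break
    selected <- c(selected, remaining[i])
    best <- scores[i]
  }
  list(features = selected, cv_mae = best)
}

#' Published default feature sets for SBP and DBP estimation
#'
#' The 9-feature SBP set (P-DN, P-EB, R-DN, R-EB, P-R, QRS, S-T, P-T,
#' R-R) and the 14-feature DBP set, which adds the five PPG intervals
#' DN-EB, SP-DN, SP-DP, SP-EB and EB-EB to the SBP set.
#'
#' @return A list with character vectors `sbp` (9 names) and `dbp`
#'   (14 names, a superset of `sbp`).
#' @export
default_feature_sets <- function() {
  sbp <- c("T_PN1", "T_PB", "T_RN1", "T_RB",
           "Tpr", "Tqrs", "Tst", "Tpt", "Trr")
  dbp <- c(sbp, "Tn1b", "Tn2n1", "Tn2a", "Tn2b", "Tbb")
  list(sbp = sbp, dbp = dbp)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model A `log_linear_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "log_linear_model"))
  jsonlite::write_json(
    list(target = model$target, feature_names = model$feature_names,
         beta0 = model$beta0, betas = as.list(model$betas),
         fit_diagnostics = model$fit_diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(target = obj$target,
         feature_names = obj$feature_names,
         beta0 = obj$beta0,
         betas = stats::setNames(unlist(obj$betas), names(obj$betas)),
         fit_diagnostics = obj$fit_diagnostics),
    class = "log_linear_model"
  )
}
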