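#' Maximum-likelihood logistic regression via IRLS
#'
#' Binary logistic regression fitted by iteratively reweighted least
#' squares, converging when the log-likelihood changes by less than `tol`
#' (default 1e-8) with at most `max_iter` (default 100) iterations.
#' Standard errors come from the inverse observed information at the
#' optimum. This is the package's own fit — the prognosis workflow and its
#' Wald inference are built on it, and the test suite checks it against an
#' independent direct optimiser of the likelihood.
#'
#' @param x Numeric design matrix WITHOUT intercept column (may have zero
#'   columns for the null model).
#' @param y 0/1 response vector.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum IRLS iterations.
#' @return List with `coefficients` (intercept first), `se`, `vcov`,
#'   `loglik`, `iterations`, `converged`, `fitted`, `separation`.
#' @export
logistic_irls <- function(x, y, tol = 1e-8, max_iter = 100) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  x <- as.matrix(x)
  X <- cbind(`(Intercept)` = 1, x)
  n <- length(y)
  stopifnot(nrow(X) == n)
  beta <- rep(0, ncol(X))
  # intercept start at the empirical logit keeps early steps stable
  pbar <- min(max(mean(y), 1e-3), 1 - 1e-3)
  beta[1] <- log(pbar / (1 - pbar))
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  trace <- ll_old
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) {
      stop("singular design matrix in logistic fit (aliased columns: ",
           paste(colnames(X)[is.na(beta_new)], collapse = ", "), ")")
    }
    ll_new <- ll(beta_new)
    # step-halving keeps IRLS monotone near separation
    step <- 1
    while (ll_new < ll_old - 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      ll_new <- ll(beta_new)
    }
    beta <- beta_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  if (!converged) {
    stop(sprintf(
      "logistic fit did not converge in %d iterations; log-likelihood trace: %s",
      max_iter, paste(sprintf("%.6f", utils::tail(trace, 6)), collapse = " -> ")))
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  separation <- ncol(X) > 1 &&
    (all(pmin(p, 1 - p)[w > 0] < 1e-6) ||
       max(abs(beta[-1])) > 20 && any(pmin(p, 1 - p) < 1e-8))
  if (separation) {
    warning("possible complete separation; Wald statistics are unreliable")
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = sqrt(pmax(diag(vc), 0)), vcov = vc, loglik = ll_old,
       iterations = it, converged = converged, fitted = p,
       separation = separation)
}

#' Nagelkerke pseudo R-squared
#'
#' `R2 = (1 - exp((2/n) (l0 - l1))) / (1 - exp((2/n) l0))`, the
#' Cox-Snell ratio rescaled to the unit interval; 0 for the null model.
#'
#' @param ll_null,ll_model Log-likelihoods of the intercept-only and fitted
#'   models.
#' @param n Number of observations.
#' @return Value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(ll_null, ll_model, n) {
  r2 <- (1 - exp((2 / n) * (ll_null - ll_model))) /
    (1 - exp((2 / n) * ll_null))
  min(max(r2, 0), 1)
}

# Mann-Whitney rank AUC with midrank tie handling
auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # ties.method = "average" = midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall curve by step-wise summation over
# descending unique score thresholds
auprc_step <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for probability scores
#'
#' ROC AUC by the Mann-Whitney rank formulation with midrank tie handling,
#' AUPRC by step-wise precision-recall summation, and accuracy, sensitivity
#' and specificity at the fixed threshold 0.5. All metrics are missing (with
#' `reason`) when only one class is present.
#'
#' @param scores Numeric scores or probabilities (higher = more positive).
#' @param labels 0/1 (or logical) reference labels.
#' @param threshold Classification threshold (default 0.5).
#' @return List `auc`, `auprc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
roc_and_accuracy <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    return(list(auc = NA_real_, auprc = NA_real_, accuracy = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                reason = "only one class present"))
  }
  pred <- as.numeric(scores >= threshold)
  list(auc = auc_rank(scores, labels),
       auprc = auprc_step(scores, labels),
       accuracy = mean(pred == labels),
       sensitivity = mean(pred[labels == 1] == 1),
       specificity = mean(pred[labels == 0] == 0))
}

#' Wald inference table from coefficients and standard errors
#'
#' The closed-form per-coefficient arithmetic of a logistic model report:
#' Wald statistic `(B/SE)^2` with a 1-df chi-square P value, odds ratio
#' `exp(B)`, and normal-approximation 95 percent confidence limits
#' `exp(B -/+ 1.96 SE)`.
#'
#' @param b,se Numeric vectors of coefficients and standard errors.
#' @return Data frame `B`, `SE`, `wald`, `p`, `or`, `ci_lo`, `ci_hi`.
#' @examples
#' wald_table(-0.033, 0.014)  # OR 0.968, CI 0.941-0.994
#' @export
wald_table <- function(b, se) {
  wald <- (b / se)^2
  data.frame(
    B = unname(b), SE = unname(se), wald = unname(wald),
    p = unname(stats::pchisq(wald, df = 1, lower.tail = FALSE)),
    or = unname(exp(b)),
    ci_lo = unname(exp(b - 1.96 * se)),
    ci_hi = unname(exp(b + 1.96 * se)),
    stringsAsFactors = FALSE
  )
}

#' Fit the prognosis logistic model and assemble its report
#'
#' Fits `superior ~ predictors` by [logistic_irls()] and reports, per
#' predictor: the coefficient B, its standard error, the Wald statistic
#' `(B/SE)^2` with a 1-df chi-square P value, the odds ratio `exp(B)` and
#' its normal-approximation 95 percent CI `exp(B +/- 1.96 SE)`; and at model
#' level: n, null and fitted log-likelihoods, Nagelkerke R-squared, and the
#' in-sample ROC summary at threshold 0.5.
#'
#' @param table Data frame of predictors (numeric columns, no missing cells).
#' @param labels 0/1 (or logical) outcome vector aligned with `table` rows.
#' @param predictors Character vector of predictor columns; may be empty for
#'   the null model.
#' @return Object of class `model_report`.
#' @export
fit_logistic <- function(table, labels, predictors = colnames(table)) {
  labels <- as.numeric(labels)
  stopifnot(nrow(table) == length(labels))
  x <- as.matrix(as.data.frame(table)[, predictors, drop = FALSE])
  if (anyNA(x) || anyNA(labels)) stop("missing cells in model input")
  fit <- logistic_irls(x, labels)
  null_fit <- logistic_irls(x[, 0, drop = FALSE], labels)
  coefs <- cbind(term = names(fit$coefficients),
                 wald_table(fit$coefficients, fit$se),
                 stringsAsFactors = FALSE)
  roc <- roc_and_accuracy(fit$fitted, labels)
  structure(list(
    coefficients = coefs, n = length(labels),
    ll_null = null_fit$loglik, ll_model = fit$loglik,
    nagelkerke_r2 = nagelkerke_r2(null_fit$loglik, fit$loglik, length(labels)),
    roc = roc, predictors = predictors, iterations = fit$iterations,
    separation = fit$separation, fit = fit
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> n = %d, Nagelkerke R2 = %.3f, AUC = %.3f\n",
              x$n, x$nagelkerke_r2, x$roc$auc))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predict probabilities from a fitted model report
#'
#' @param object A `model_report`.
#' @param newdata Data frame containing the model's predictor columns.
#' @param ... Unused.
#' @return Vector of predicted probabilities.
#' @export
predict.model_report <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(as.data.frame(newdata)[, object$predictors,
                                                 drop = FALSE]))
  stats::plogis(drop(X %*% object$fit$coefficients))
}

#' Plain-language odds ratio interpretation
#'
#' Converts an odds ratio into the percent-change phrasing used in clinical
#' reporting: per one-unit increase of the predictor, the odds of the
#' outcome `increased by 100 (OR - 1)` percent when OR > 1, or
#' `decreased by 100 (1 - OR)` percent when OR < 1.
#'
#' @param or_value Odds ratio (> 0).
#' @param unit Optional unit phrase for the statement.
#' @return List `percent`, `direction`, `statement`.
#' @examples
#' interpret_or(0.968)  # decreased by 3.2%
#' @export
interpret_or <- function(or_value, unit = "1.0-unit") {
  stopifnot(or_value > 0)
  if (or_value >= 1) {
    pct <- 100 * (or_value - 1)
    dir <- if (or_value == 1) "unchanged" else "increased"
  } else {
    pct <- 100 * (1 - or_value)
    dir <- "decreased"
  }
  list(percent = pct, direction = dir,
       statement = sprintf(
         "for each additional %s increase, the likelihood %s by approximately %.1f%%",
         unit, if (dir == "unchanged") "changed" else dir, pct))
}
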