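#' Label postoperative visual recovery outcomes
#'
#' An eye shows superior recovery at a follow-up stage when its ETDRS letter
#' score gained 20 or more letters over the preoperative score
#' (`delta >= 20`, boundary inclusive). A missing ETDRS at either end makes
#' the label missing.
#'
#' @param clinical Clinical table (see [read_clinical_table()]).
#' @param stage Postoperative stage (`"wk2"`, `"mo3"`, `"mo6"`, `"mo12"`).
#' @param threshold Letter gain defining superior recovery (default 20).
#' @return Data frame `eye_id`, `stage`, `delta_etdrs`, `superior`.
#' @export
label_outcomes <- function(clinical, stage, threshold = 20) {
  stage <- match.arg(stage, setdiff(stage_levels(), "pre"))
  delta <- clinical[[paste0("etdrs_", stage)]] - clinical$etdrs_pre
  data.frame(eye_id = clinical$eye_id, stage = stage,
             delta_etdrs = delta, superior = delta >= threshold,
             stringsAsFactors = FALSE)
}

#' Mean imputation with a strict missingness cap
#'
#' Numeric columns with a missing fraction strictly below
#' `max_missing_frac` (default 10 percent) are imputed with the column
#' mean; columns at or above the cap are dropped to limit imputation bias.
#' Both sets are reported so the preprocessing trail is auditable.
#'
#' @param table Data frame.
#' @param max_missing_frac Strict upper bound on the imputable missing
#'   fraction.
#' @return List `table`, `dropped_vars`, `imputed_vars`.
#' @export
impute_missing <- function(table, max_missing_frac = 0.10) {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  dropped <- character(0)
  imputed <- character(0)
  for (cn in num) {
    frac <- mean(is.na(table[[cn]]))
    if (frac == 0) next
    if (frac < max_missing_frac) {
      table[[cn]][is.na(table[[cn]])] <- mean(table[[cn]], na.rm = TRUE)
      imputed <- c(imputed, cn)
    } else {
      table[[cn]] <- NULL
      dropped <- c(dropped, cn)
    }
  }
  list(table = table, dropped_vars = dropped, imputed_vars = imputed)
}

#' Distribution-guided correlation screen
#'
#' Shapiro-Wilk normality tests decide the correlation method per variable:
#' Pearson when both the variable and the outcome pass at alpha = 0.05,
#' Spearman otherwise. Constant columns get a missing correlation and a
#' flag.
#'
#' @param table Data frame of numeric variables.
#' @param bcva Numeric outcome vector (e.g. ETDRS letter gain).
#' @param alpha Normality test level.
#' @return Data frame `variable`, `sw_p`, `method`, `r`, `p`, `note`.
#' @export
normality_and_correlation <- function(table, bcva, alpha = 0.05) {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  sw <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3 || length(unique(x)) == 1L) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  sw_out <- sw(bcva)
  rows <- lapply(num, function(cn) {
    x <- table[[cn]]
    sw_p <- sw(x)
    if (length(unique(x[!is.na(x)])) <= 1L) {
      return(data.frame(variable = cn, sw_p = sw_p, method = NA_character_,
                        r = NA_real_, p = NA_real_, note = "constant column",
                        stringsAsFactors = FALSE))
    }
    method <- if (!is.na(sw_p) && !is.na(sw_out) &&
                  sw_p > alpha && sw_out > alpha) "pearson" else "spearman"
    ct <- suppressWarnings(
      stats::cor.test(x, bcva, method = method, exact = FALSE))
    data.frame(variable = cn, sw_p = sw_p, method = method,
               r = unname(ct$estimate), p = ct$p.value, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Iterative variance-inflation-factor filter
#'
#' `VIF_j = 1 / (1 - R2_j)` from the least-squares regression of predictor
#' j on all remaining predictors. The predictor with the highest VIF is
#' dropped, VIFs are recomputed, and the loop repeats until every VIF is at
#' or below `threshold` (default 5). Exact collinearity (infinite VIF) is
#' handled the same way, so duplicated columns lose exactly one copy.
#'
#' @param table Data frame of numeric predictors (>= 2 columns).
#' @param threshold Maximum tolerated VIF.
#' @return List `kept` (column names) and `dropped` (data frame
#'   `variable`, `vif` in drop order).
#' @export
vif_filter <- function(table, threshold = 5) {
  vars <- names(table)[vapply(table, is.numeric, TRUE)]
  stopifnot(length(vars) >= 2L)
  x <- as.matrix(as.data.frame(table)[vars])
  dropped <- data.frame(variable = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  vif_one <- function(j, keep) {
    others <- x[, setdiff(keep, j), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), x[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((x[, j] - mean(x[, j]))^2), .Machine$double.eps)
    1 / max(1 - r2, .Machine$double.eps)
  }
  keep <- vars
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(keep, vif_one, numeric(1), keep = keep)
    if (max(vifs) <= threshold) break
    worst <- names(which.max(vifs))
    dropped <- rbind(dropped, data.frame(variable = worst,
                                         vif = unname(max(vifs))))
    keep <- setdiff(keep, worst)
  }
  list(kept = keep, dropped = dropped)
}

#' Univariate logistic screening
#'
#' One single-predictor logistic fit per variable; variables whose Wald P
#' value is below `alpha` (default 0.10) are retained. Constant predictors
#' are excluded with a warning; predictors causing complete separation are
#' retained but flagged, because their Wald P is unreliable.
#'
#' @param table Data frame of numeric predictors.
#' @param labels 0/1 outcome vector.
#' @param alpha Screening level on the Wald P value.
#' @return List `kept` and `results` (per-variable B, SE, P, flag).
#' @export
univariate_screen <- function(table, labels, alpha = 0.10) {
  labels <- as.numeric(labels)
  vars <- names(table)[vapply(table, is.numeric, TRUE)]
  rows <- lapply(vars, function(cn) {
    x <- table[[cn]]
    if (length(unique(x)) <= 1L) {
      warning("constant predictor excluded from screen: ", cn)
      return(data.frame(variable = cn, B = NA_real_, SE = NA_real_,
                        p = NA_real_, kept = FALSE, flag = "constant",
                        stringsAsFactors = FALSE))
    }
    fit <- withCallingHandlers(
      logistic_irls(matrix(x, ncol = 1), labels),
      warning = function(w) invokeRestart("muffleWarning"))
    wald <- (fit$coefficients[2] / fit$se[2])^2
    p <- stats::pchisq(wald, 1, lower.tail = FALSE)
    kept <- isTRUE(fit$separation) || (!is.na(p) && p < alpha)
    data.frame(variable = cn, B = unname(fit$coefficients[2]),
               SE = unname(fit$se[2]), p = unname(p), kept = kept,
               flag = if (fit$separation) "separation" else "",
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(kept = results$variable[results$kept], results = results)
}

# stratified train/test split; returns logical "in training set"
stratified_split <- function(labels, split = 0.8) {
  train <- logical(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    n_tr <- round(split * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# stratified fold assignment 1..folds
stratified_folds <- function(labels, folds = 5) {
  minority <- min(table(labels))
  if (minority < folds) {
    folds <- max(2L, as.integer(minority))
    warning("too few minority cases; reducing to ", folds, " folds")
  }
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# preprocessing + screening + fit + evaluation for one predictor set
fit_arm <- function(table, labels, train, folds, alpha_screen, vif_threshold) {
  imp <- impute_missing(table)
  tab <- imp$table
  vars <- names(tab)[vapply(tab, is.numeric, TRUE)]
  vars <- vars[vapply(tab[vars], function(x) length(unique(x)) > 1L, TRUE)]
  tab <- tab[vars]
  if (length(vars) >= 2L) {
    vf <- vif_filter(tab, vif_threshold)
    tab <- tab[vf$kept]
  } else {
    vf <- list(kept = vars, dropped = NULL)
  }
  scr <- suppressWarnings(
    univariate_screen(tab[train, , drop = FALSE], labels[train], alpha_screen))
  kept <- scr$kept
  report <- fit_logistic(tab[train, , drop = FALSE], labels[train], kept)
  # stratified CV on the training set (threshold-free sanity check)
  fold <- stratified_folds(labels[train], folds)
  tr_tab <- tab[train, , drop = FALSE]
  tr_lab <- labels[train]
  cv_auc <- vapply(seq_len(max(fold)), function(k) {
    fit_k <- fit_logistic(tr_tab[fold != k, , drop = FALSE],
                          tr_lab[fold != k], kept)
    auc_rank(predict(fit_k, tr_tab[fold == k, , drop = FALSE]),
             tr_lab[fold == k])
  }, numeric(1))
  test_scores <- predict(report, tab[!train, , drop = FALSE])
  list(report = report, screening = scr$results, vif_dropped = vf$dropped,
       imputed = imp$imputed_vars, dropped_missing = imp$dropped_vars,
       cv_auc = cv_auc,
       test = roc_and_accuracy(test_scores, labels[!train]))
}

#' Compare prognosis models with and without dynamic parameters
#'
#' Runs the full protocol twice on identically split data: mean imputation
#' (<10 percent rule), iterative VIF filtering (threshold 5), univariate
#' logistic screening (P < 0.10) on the training set, an IRLS logistic fit,
#' stratified 5-fold cross-validation on the 80 percent training split, and
#' held-out evaluation on the 20 percent test split. The only difference
#' between the arms is whether the dynamic recovery-rate columns enter the
#' candidate predictor set; `delta_auc` is the test-set AUC gain of the
#' dynamics arm.
#'
#' @param features Feature table ([build_feature_table()]); preoperative
#'   rows are used as baseline predictors.
#' @param dynamics Dynamics table ([compute_dynamics()]).
#' @param clinical Clinical table.
#' @param stage Outcome stage.
#' @param split Training fraction (default 0.8).
#' @param folds CV folds (default 5).
#' @param seed Mandatory RNG seed for the split and folds.
#' @param alpha_screen,vif_threshold Protocol parameters.
#' @return List `with_dynamics`, `without_dynamics` (each a [fit_arm] result
#'   containing a `model_report`), `delta_auc`, `labels`, `seed`.
#' @export
compare_with_without_dynamics <- function(features, dynamics, clinical, stage,
                                          split = 0.8, folds = 5, seed,
                                          alpha_screen = 0.10,
                                          vif_threshold = 5) {
  stopifnot(!missing(seed))
  labels_df <- label_outcomes(clinical, stage)
  pre <- features[features$stage == "pre", , drop = FALSE]
  base_cols <- c("mld_um", "bd_um", "e_um", "height_um", "mh_area_um2",
                 "pseudocyst_area_um2", "elm_defect_um", "ez_defect_um",
                 "mhi", "thi", "dhi", "mh_pc_area_ratio")
  dyn_cols <- intersect(c("rate_mh", "rate_pc", "rate_pct_elm", "rate_pct_ez",
                          "rate_w_mh", "rate_w_pc"), names(dynamics))
  tab <- merge(clinical[c("eye_id", "age", "duration_days")],
               pre[c("eye_id", base_cols)], by = "eye_id")
  tab <- merge(tab, dynamics[c("eye_id", dyn_cols)], by = "eye_id")
  tab <- merge(tab, labels_df[c("eye_id", "superior")], by = "eye_id")
  tab <- tab[!is.na(tab$superior), , drop = FALSE]
  if (nrow(tab) < 50) stop("need at least 50 labelled eyes, have ", nrow(tab))
  labels <- as.numeric(tab$superior)
  set.seed(seed)
  train <- stratified_split(labels, split)
  fold_seed <- sample.int(.Machine$integer.max, 1)
  base_tab <- tab[c("age", "duration_days", base_cols)]
  dyn_tab <- tab[c("age", "duration_days", base_cols, dyn_cols)]
  set.seed(fold_seed)
  arm_without <- fit_arm(base_tab, labels, train, folds,
                         alpha_screen, vif_threshold)
  set.seed(fold_seed)
  arm_with <- fit_arm(dyn_tab, labels, train, folds,
                      alpha_screen, vif_threshold)
  list(with_dynamics = arm_with, without_dynamics = arm_without,
       delta_auc = arm_with$test$auc - arm_without$test$auc,
       n = nrow(tab), stage = stage, seed = seed)
}
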