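test_that("outcome labels apply the inclusive 20-letter rule", {
  clin <- toy_clinical()
  labs <- label_outcomes(clin, "wk2")
  expect_equal(labs$delta_etdrs, c(20, 5))
  expect_equal(labs$superior, c(TRUE, FALSE))   # boundary: 20 is superior
  labs3 <- label_outcomes(clin, "mo3")
  expect_equal(labs3$delta_etdrs[1], 19)
  expect_false(labs3$superior[1])               # 19 is not
  expect_true(is.na(labs3$superior[2]))         # missing propagates
  clin$etdrs_pre[1] <- NA
  expect_true(is.na(label_outcomes(clin, "wk2")$superior[1]))
  expect_error(label_outcomes(clin, "pre"))
})

test_that("mean imputation applies the strict <10% rule", {
  set.seed(2)
  tab <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  tab$a[1] <- NA          # 5%  -> imputed
  tab$b[1:3] <- NA        # 15% -> dropped
  out <- impute_missing(tab)
  expect_equal(out$imputed_vars, "a")
  expect_equal(out$dropped_vars, "b")
  expect_equal(out$table$a[1], mean(tab$a, na.rm = TRUE))
  expect_false("b" %in% names(out$table))
  # exactly 10% missing is dropped (strict inequality)
  tab2 <- data.frame(a = c(NA, rnorm(9)))
  expect_equal(impute_missing(tab2)$dropped_vars, "a")
  # identity on complete data
  tab3 <- data.frame(a = 1:5)
  out3 <- impute_missing(tab3)
  expect_identical(out3$table, tab3)
  expect_length(out3$imputed_vars, 0)
})

test_that("Shapiro-Wilk decides between Pearson and Spearman", {
  set.seed(8)
  n <- 200
  bcva <- rnorm(n)
  tab <- data.frame(
    self = bcva,                       # identical to the outcome
    gauss = bcva + rnorm(n, 0, 0.5),
    heavy = rt(n, df = 1),             # heavy tails fail normality
    const = rep(1, n)
  )
  res <- normality_and_correlation(tab, bcva)
  expect_equal(res$r[res$variable == "self"], 1)
  expect_equal(res$method[res$variable == "gauss"], "pearson")
  expect_equal(res$method[res$variable == "heavy"], "spearman")
  expect_lt(res$sw_p[res$variable == "heavy"], 0.05)
  cr <- res[res$variable == "const", ]
  expect_true(is.na(cr$r))
  expect_match(cr$note, "constant")
})

test_that("VIF filter drops collinear predictors, oracle-checked", {
  set.seed(13)
  n <- 120
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  out <- vif_filter(tab)
  expect_equal(sort(out$kept), c("x1", "x2", "x3"))
  expect_equal(nrow(out$dropped), 0)
  # duplicated column: exactly one copy goes
  tab$dup <- tab$x1
  out2 <- vif_filter(tab)
  expect_length(out2$kept, 3)
  expect_equal(nrow(out2$dropped), 1)
  expect_true(out2$dropped$variable %in% c("x1", "dup"))
  # near-collinear triple: oracle VIF from lm R^2 by definition
  tab3 <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tab3$x3 <- tab3$x1 + tab3$x2 + rnorm(n, 0, 0.05)
  oracle_vif <- function(j) {
    r2 <- summary(lm(reformulate(setdiff(names(tab3), j), j),
                     data = tab3))$r.squared
    1 / (1 - r2)
  }
  vifs <- vapply(names(tab3), oracle_vif, numeric(1))
  out3 <- vif_filter(tab3)
  expect_equal(nrow(out3$dropped), 1)
  expect_equal(out3$dropped$variable, names(which.max(vifs)))
  expect_equal(out3$dropped$vif, max(vifs), tolerance = 1e-6)
})

test_that("univariate screen keeps real effects, drops constants", {
  set.seed(17)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(log(2) * x))   # OR 2 per SD
  tab <- data.frame(strong = x, flat = rep(2, n))
  expect_warning(out <- univariate_screen(tab, y), "constant predictor")
  expect_true("strong" %in% out$kept)
  expect_false("flat" %in% out$kept)
  expect_equal(out$results$flag[out$results$variable == "flat"], "constant")
})

test_that("with/without-dynamics comparison is seeded and coherent", {
  co <- simulate_cohort(phantom_params(n_eyes = 250, seed = 77))
  dyn <- compute_dynamics(co$features)
  cmp <- compare_with_without_dynamics(co$features, dyn, co$clinical,
                                       "mo3", seed = 5)
  cmp2 <- compare_with_without_dynamics(co$features, dyn, co$clinical,
                                        "mo3", seed = 5)
  expect_equal(cmp$delta_auc, cmp2$delta_auc)   # determinism
  expect_equal(cmp$with_dynamics$test$auc,
               cmp2$with_dynamics$test$auc)
  expect_length(cmp$with_dynamics$cv_auc, 5)
  # identical predictor sets (dynamics table without rate columns) => 0
  dyn_null <- dyn[c("eye_id", "t_resolved_mh")]
  cmp0 <- compare_with_without_dynamics(co$features, dyn_null, co$clinical,
                                        "mo3", seed = 5)
  expect_identical(cmp0$delta_auc, 0)
  # too few labelled eyes is an explicit error
  expect_error(
    compare_with_without_dynamics(co$features[1:50, ], dyn[1:10, ],
                                  co$clinical[1:10, ], "mo3", seed = 1),
    "at least 50")
})
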