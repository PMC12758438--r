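series_of <- function(...) {
  stats::setNames(c(...), stage_levels())
}

test_that("resolution time is the first postoperative zero", {
  r <- resolution_time(series_of(80000, 0, 0, 0, 0))
  expect_equal(r$t_resolved_weeks, 2)
  expect_true(r$resolved)
  expect_equal(resolution_time(series_of(80000, 50000, 0, 0, 0))$t_resolved_weeks, 13)
  cens <- resolution_time(series_of(80000, 50000, 30000, 20000, 10000))
  expect_false(cens$resolved)
  expect_true(is.na(cens$t_resolved_weeks))
  # recurrence still resolves at the first zero, loudly
  expect_warning(rec <- resolution_time(series_of(80000, 0, 5000, 0, 0)),
                 "recurrence")
  expect_equal(rec$t_resolved_weeks, 2)
  # preoperative zero: dynamics undefined, not zero
  und <- resolution_time(series_of(0, 0, 0, 0, 0))
  expect_false(und$defined)
  # missing visits are skipped
  expect_equal(resolution_time(series_of(80000, NA, 0, 0, 0))$t_resolved_weeks, 13)
})

test_that("recovery rate follows the ratio definition and censored fallback", {
  expect_equal(recovery_rate(80000, 13, TRUE), 80000 / 13)
  s <- series_of(80000, 50000, 30000, 20000, 10000)
  expect_equal(recovery_rate(80000, NA, FALSE, s, mode = "extended"),
               (80000 - 10000) / 52)
  expect_true(is.na(recovery_rate(80000, NA, FALSE, s, mode = "paper")))
  expect_true(is.na(recovery_rate(0, 13, TRUE)))
})

test_that("rate invariants: exact ratio, visit invariance, monotonicity", {
  set.seed(21)
  sched <- visit_schedule()
  for (i in 1:30) {
    init <- runif(1, 1e4, 2e5)
    k <- sample(2:5, 1)  # resolve at k-th stage
    sizes <- c(init, init * 0.6^(1:4))
    sizes[k:5] <- 0
    s <- series_of(sizes[1], sizes[2], sizes[3], sizes[4], sizes[5])
    r <- resolution_time(s, sched)
    rate <- recovery_rate(init, r$t_resolved_weeks, r$resolved, s, sched)
    expect_equal(rate * r$t_resolved_weeks, init)   # exact ratio
  }
  # earlier resolution => strictly larger rate at fixed initial size
  rates <- vapply(c(2, 13, 26, 52), function(t)
    recovery_rate(80000, t, TRUE), numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("shape factor behaves like inverse circularity", {
  r <- 40; n <- 101
  disc <- matrix(0L, n, n)
  disc[outer(1:n, 1:n, function(i, j) (i - 51)^2 + (j - 51)^2 <= r^2)] <- 1L
  phi_disc <- shape_factor(mk_scan(disc, spacing = c(1, 1)), "macular_hole")
  expect_gte(phi_disc, 1.0)
  expect_lte(phi_disc, 1.15)
  sq <- matrix(0L, 120, 120); sq[11:90, 11:90] <- 2L
  phi_sq <- shape_factor(mk_scan(sq, spacing = c(1, 1)), "pseudocyst")
  expect_equal(phi_sq, 4 / pi, tolerance = 0.02)
  # 2:1 rectangle of equal area scores higher than the square
  re <- matrix(0L, 150, 150)
  re[31:87, 11:123] <- 2L  # 57 x 113 ~ 2:1, area ~ square 80x80
  phi_re <- shape_factor(mk_scan(re, spacing = c(1, 1)), "pseudocyst")
  expect_gt(phi_re, phi_sq)
  expect_true(is.na(shape_factor(mk_scan(matrix(0L, 5, 5)), "pseudocyst")))
})

test_that("weighted rate is identity at phi = 1 or kappa = 0, monotone else", {
  expect_equal(weighted_recovery_rate(6000, 1, 0.7), 6000)
  expect_equal(weighted_recovery_rate(6000, 1.8, 0), 6000)
  expect_equal(weighted_recovery_rate(6000, 1.4, 0.5), 7200)
  phis <- seq(1, 2, by = 0.1)
  expect_true(all(diff(weighted_recovery_rate(6000, phis, 0.5)) > 0))
  kappas <- seq(0, 1, by = 0.1)
  expect_true(all(diff(weighted_recovery_rate(6000, 1.3, kappas)) > 0))
})

test_that("compute_dynamics recovers generator resolution times exactly", {
  co <- simulate_cohort(phantom_params(n_eyes = 200, seed = 404))
  dyn <- compute_dynamics(co$features)
  tr <- co$truth[match(dyn$eye_id, co$truth$eye_id), ]
  for (lesion in c("mh", "ez", "elm")) {
    got <- dyn[[paste0("t_resolved_", lesion)]]
    want <- tr[[paste0("t_", lesion)]]
    expect_identical(is.na(got), is.na(want))
    expect_equal(got[!is.na(got)], want[!is.na(want)])
  }
  # pseudocyst times only defined where pseudocysts existed preoperatively
  has_pc <- tr$pc_area_um2 > 0
  expect_equal(dyn$t_resolved_pc[has_pc & !is.na(tr$t_pc)],
               tr$t_pc[has_pc & !is.na(tr$t_pc)])
  # extended-mode rates match the generator truth within observation noise
  expect_equal(dyn$rate_ez, tr$rate_ez, tolerance = 0.05)
  expect_equal(dyn$rate_mh, tr$rate_mh, tolerance = 0.05)
})
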