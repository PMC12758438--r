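test_that("render_scan reproduces requested geometry exactly", {
  geo <- list(bd_um = 200, mld_um = 100, height_um = 55,
              ez_defect_um = 400, elm_defect_um = 300, pc_area_um2 = 0,
              erm = FALSE, space = FALSE)
  out <- render_scan(geo, rows = 160, cols = 384, spacing_um = c(5, 10))
  g <- extract_hole_geometry(out$scan)
  expect_equal(g$bd_um, 200)
  expect_equal(g$mld_um, 100)
  expect_equal(g$height_um, 55)
  expect_equal(extract_band_defect(out$scan, "EZ")$defect_length_um, 400)
  expect_equal(extract_band_defect(out$scan, "ELM")$defect_length_um, 300)
  # contiguous bands and absent pseudocysts when so requested
  geo0 <- utils::modifyList(geo, list(bd_um = NA, mld_um = NA,
                                      height_um = NA, ez_defect_um = 0,
                                      elm_defect_um = 0))
  out0 <- render_scan(geo0)
  expect_equal(extract_band_defect(out0$scan, "EZ")$defect_length_um, 0)
  expect_false(extract_hole_geometry(out0$scan)$present)
  expect_equal(sum(out0$scan$grid == label_schema()[["pseudocyst"]]), 0)
  expect_error(render_scan(utils::modifyList(geo, list(bd_um = 5000))),
               "exceeds the grid")
})

test_that("series follow their resolution stage", {
  p <- phantom_params(n_eyes = 1, seed = 1)
  set.seed(101)
  repeat {  # find an eye resolving at wk2
    s <- simulate_series(p)
    if (s$eye$k_mh == 1) break
  }
  post <- s$visit_truth[s$visit_truth$stage != "pre", ]
  expect_true(all(post$mh_area_um2 == 0))
  set.seed(202)
  repeat {  # and one that never resolves
    s2 <- simulate_series(p)
    if (s2$eye$k_mh >= 5) break
  }
  expect_gt(s2$visit_truth$mh_area_um2[s2$visit_truth$stage == "mo12"], 0)
})

test_that("rendered cohorts match their truth within one pixel spacing", {
  p <- phantom_params(n_eyes = 8, seed = 31, jitter_um = 5)
  co <- simulate_cohort(p, render = TRUE)
  feats <- build_feature_table(co$scans)
  key <- function(d) paste(d$eye_id, d$stage)
  tr <- co$features[match(key(feats), key(co$features)), ]
  for (col in c("mld_um", "bd_um", "e_um", "height_um", "mh_area_um2",
                "pseudocyst_area_um2", "elm_defect_um", "ez_defect_um")) {
    expect_identical(is.na(feats[[col]]), is.na(tr[[col]]))
    expect_equal(feats[[col]], tr[[col]], tolerance = 1e-12)
  }
})

test_that("same seed gives byte-identical cohorts, classes stay balanced", {
  p <- phantom_params(n_eyes = 5, seed = 99)
  a <- simulate_cohort(p, render = TRUE)
  b <- simulate_cohort(p, render = TRUE)
  expect_identical(lapply(a$scans, `[[`, "grid"),
                   lapply(b$scans, `[[`, "grid"))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$features, b$features)
  # default cohorts keep the minority class above 20% at every stage
  for (seed in 1:5) {
    co <- simulate_cohort(phantom_params(n_eyes = 400, seed = seed))
    for (st in c("wk2", "mo3", "mo6", "mo12")) {
      y <- label_outcomes(co$clinical, st)$superior
      frac <- mean(y, na.rm = TRUE)
      expect_gte(min(frac, 1 - frac), 0.20)
    }
  }
})

test_that("cohorts write to disk in the documented formats", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(phantom_params(n_eyes = 2, seed = 8),
                        render = TRUE, out_dir = dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  masks <- list.files(file.path(dir, "masks"), pattern = "\\.png$")
  expect_length(masks, 2 * 5 * 2)
  back <- read_scan(file.path(dir, "masks", masks[1]))
  expect_s3_class(back, "labeled_bscan")
  clin <- read_clinical_table(file.path(dir, "clinical.csv"))
  expect_equal(clin$eye_id, co$clinical$eye_id)
})
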