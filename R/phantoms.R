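#' Parameters of the longitudinal phantom cohort generator
#'
#' The generator emulates the structure of a longitudinal macular-hole OCT
#' dataset: five follow-up stages (preoperative, 2 weeks, 3, 6 and 12
#' months), two orthogonal B-scans per examination, per-eye clinical
#' covariates and ETDRS letter scores, and ground-truth lesion geometry and
#' healing trajectories known by construction. Defaults state the simulated
#' world once: hole base diameter uniform on 300-900 um, DHI on 0.3-0.7,
#' height on 250-450 um; outer-band defects proportional to BD; a per-eye
#' latent healing score mapped to resolution stages with probabilities
#' wk2 .25, mo3 .35, mo6 .20, mo12 .10, never .10 (band restoration never
#' precedes hole closure); and a logistic outcome model on fixed-scale
#' standardised true features with coefficients
#' `beta = (0.3, -0.8 BD, -0.5 log-duration, +0.8 EZ rate, +0.4 hole rate)`.
#'
#' @param n_eyes Number of eyes.
#' @param rows,cols,spacing_um Mask grid and axial/lateral um-per-pixel.
#' @param bd_range,dhi_range,height_range Preoperative hole geometry ranges.
#' @param pc_prob,pc_area_range Pseudocyst presence probability and total
#'   area range (um^2).
#' @param ez_factor,elm_factor,defect_noise_um Band defect length =
#'   BD x factor + N(0, noise), clamped to exceed the hole width.
#' @param erm_prob,space_prob Qualitative flag prevalences.
#' @param stage_probs Resolution-stage probabilities (wk2, mo3, mo6, mo12,
#'   never); must sum to 1.
#' @param beta Outcome coefficients (intercept, z_bd, z_dur, z_ez, z_mh).
#' @param stage_offsets Stage-specific intercept offsets.
#' @param etdrs_missing_prob Per-cell missingness of postoperative ETDRS.
#' @param jitter_um Between-axis rendering jitter (sd, um).
#' @param feature_noise_um Measurement noise on truth-level feature tables.
#' @param seed Mandatory seed for [simulate_cohort()].
#' @return List of class `phantom_params`.
#' @export
phantom_params <- function(n_eyes = 400, rows = 160, cols = 384,
                           spacing_um = c(5, 10),
                           bd_range = c(300, 900), dhi_range = c(0.3, 0.7),
                           height_range = c(250, 450),
                           pc_prob = 0.7, pc_area_range = c(5000, 40000),
                           ez_factor = 1.3, elm_factor = 1.15,
                           defect_noise_um = 30,
                           erm_prob = 0.4, space_prob = 0.25,
                           stage_probs = c(wk2 = 0.25, mo3 = 0.35,
                                           mo6 = 0.20, mo12 = 0.10,
                                           never = 0.10),
                           beta = c(intercept = 0.3, z_bd = -0.8,
                                    z_dur = -0.5, z_ez = 0.8, z_mh = 0.4),
                           stage_offsets = c(wk2 = -0.5, mo3 = 0,
                                             mo6 = 0.3, mo12 = 0.5),
                           etdrs_missing_prob = 0.05,
                           jitter_um = 5, feature_noise_um = 3,
                           seed = NULL) {
  stopifnot(bd_range[1] > 0, diff(bd_range) > 0, diff(dhi_range) > 0,
            dhi_range[1] > 0, dhi_range[2] < 1, diff(height_range) > 0,
            abs(sum(stage_probs) - 1) < 1e-12, length(beta) == 5,
            all(spacing_um > 0))
  structure(as.list(environment()), class = "phantom_params")
}

# linear shrink factors over the four postoperative visits
shrink_factors <- function(stage_idx, base = 0.7,
                           never = c(0.87, 0.74, 0.67, 0.63)) {
  if (stage_idx >= 5) return(never)
  f <- base^(1:4)
  f[1:4 >= stage_idx] <- 0
  f
}

post_times <- function() c(wk2 = 2, mo3 = 13, mo6 = 26, mo12 = 52)

# draw the per-eye ground truth for a whole cohort (vectorised; uses the
# current RNG stream)
draw_cohort_truth <- function(params) {
  p <- params
  n <- p$n_eyes
  eye_id <- sprintf("eye%04d", seq_len(n))
  bd <- stats::runif(n, p$bd_range[1], p$bd_range[2])
  dhi <- stats::runif(n, p$dhi_range[1], p$dhi_range[2])
  mld <- bd * dhi
  height <- stats::runif(n, p$height_range[1], p$height_range[2])
  area0 <- (bd + mld) / 2 * height
  ez0 <- pmax(bd * p$ez_factor + stats::rnorm(n, 0, p$defect_noise_um),
              bd + 30)
  elm0 <- pmax(bd * p$elm_factor + stats::rnorm(n, 0, p$defect_noise_um),
               bd + 20)
  pc_present <- stats::runif(n) < p$pc_prob
  pc0 <- ifelse(pc_present,
                stats::runif(n, p$pc_area_range[1], p$pc_area_range[2]), 0)
  erm <- stats::runif(n) < p$erm_prob
  space <- stats::runif(n) < p$space_prob
  # latent healing score -> correlated per-lesion resolution stages
  z <- stats::rnorm(n)
  thresholds <- stats::qnorm(cumsum(p$stage_probs), sd = sqrt(1.25))
  stage_of <- function(score) findInterval(score, thresholds) + 1L
  k_mh <- stage_of(z + stats::rnorm(n, 0, 0.5))
  k_pc <- stage_of(z + stats::rnorm(n, 0, 0.5))
  # outer bands restore after (never before) hole closure
  k_ez <- pmax(stage_of(z + stats::rnorm(n, 0, 0.5)), k_mh)
  k_elm <- pmax(stage_of(z + stats::rnorm(n, 0, 0.5)), k_mh)
  times <- post_times()
  t_of <- function(k) ifelse(k >= 5, NA_real_, times[pmin(k, 4)])
  t_mh <- t_of(k_mh); t_pc <- t_of(k_pc)
  t_ez <- t_of(k_ez); t_elm <- t_of(k_elm)
  # extended-mode truth rates (equal the strict ratio when resolved)
  rate_mh <- ifelse(k_mh >= 5, area0 * (1 - 0.63^2) / 52, area0 / t_mh)
  rate_pc <- ifelse(pc0 == 0, NA_real_,
                    ifelse(k_pc >= 5, pc0 * (1 - 0.40) / 52, pc0 / t_pc))
  rate_ez <- ifelse(k_ez >= 5, ez0 * (1 - 0.40) / 52, ez0 / t_ez)
  rate_elm <- ifelse(k_elm >= 5, elm0 * (1 - 0.40) / 52, elm0 / t_elm)
  rate_pct_ez <- 100 * rate_ez / ez0
  rate_pct_elm <- 100 * rate_elm / elm0
  age <- stats::rnorm(n, 68, 8)
  duration <- stats::rlnorm(n, log(60), 0.6)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  z_bd <- (bd - 600) / 150
  z_dur <- (log(duration) - log(60)) / 0.6
  z_ez <- (log(rate_pct_ez) - log(8)) / 1.2
  z_mh <- (log(rate_mh) - log(8000)) / 1.0
  eta <- p$beta[["intercept"]] + p$beta[["z_bd"]] * z_bd +
    p$beta[["z_dur"]] * z_dur + p$beta[["z_ez"]] * z_ez +
    p$beta[["z_mh"]] * z_mh
  truth <- data.frame(
    eye_id = eye_id, bd_um = bd, mld_um = mld, height_um = height,
    mh_area_um2 = area0, ez_defect_um = ez0, elm_defect_um = elm0,
    pc_area_um2 = pc0, erm = erm, space = space,
    k_mh = k_mh, k_pc = k_pc, k_ez = k_ez, k_elm = k_elm,
    t_mh = t_mh, t_pc = t_pc, t_ez = t_ez, t_elm = t_elm,
    rate_mh = rate_mh, rate_pc = rate_pc, rate_ez = rate_ez,
    rate_elm = rate_elm, rate_pct_ez = rate_pct_ez,
    rate_pct_elm = rate_pct_elm,
    age = age, duration_days = duration, sex = sex,
    z_bd = z_bd, z_dur = z_dur, z_ez = z_ez, z_mh = z_mh, eta = eta,
    stringsAsFactors = FALSE
  )
  etdrs_pre <- round(stats::runif(n, 25, 60))
  truth$etdrs_pre <- etdrs_pre
  for (st in names(post_times())) {
    pk <- stats::plogis(eta + p$stage_offsets[[st]])
    sup <- stats::runif(n) < pk
    margin <- sample(1:15, n, replace = TRUE)
    delta <- ifelse(sup, 20 + margin, 19 - margin)
    truth[[paste0("p_", st)]] <- pk
    truth[[paste0("superior_", st)]] <- sup
    truth[[paste0("etdrs_", st)]] <- ifelse(
      stats::runif(n) < p$etdrs_missing_prob, NA_real_, etdrs_pre + delta)
  }
  truth
}

# continuous per-stage lesion sizes for one eye (list of 5 geometry lists)
stage_geometry <- function(tr, params) {
  lin_mh <- c(1, shrink_factors(tr$k_mh))
  lin_ez <- c(1, shrink_factors(tr$k_ez))
  lin_elm <- c(1, shrink_factors(tr$k_elm))
  a_pc <- c(1, shrink_factors(tr$k_pc, base = 0.5,
                              never = c(0.75, 0.55, 0.45, 0.40)))
  lapply(seq_along(stage_levels()), function(j) {
    hole <- lin_mh[j] > 0
    list(
      bd_um = if (hole) tr$bd_um * lin_mh[j] else NA_real_,
      mld_um = if (hole) tr$mld_um * lin_mh[j] else NA_real_,
      height_um = if (hole) tr$height_um * lin_mh[j] else NA_real_,
      ez_defect_um = tr$ez_defect_um * lin_ez[j],
      elm_defect_um = tr$elm_defect_um * lin_elm[j],
      pc_area_um2 = tr$pc_area_um2 * a_pc[j],
      erm = tr$erm, space = tr$space
    )
  })
}

#' Render one phantom B-scan from known geometry
#'
#' Paints a schematic macular B-scan: a two-pixel RPE line near the bottom,
#' ELM and EZ bands above it (each with a centred gap of the requested
#' defect length), a trapezoidal full-thickness hole standing on the RPE
#' (base width BD, top width MLD, the requested height), optional
#' elliptical pseudocysts flanking the hole, and optional ERM/space pixels
#' near the inner surface. The returned `truth` holds the *rendered*
#' geometry (after pixel quantisation), against which the morphometry
#' extractors are exact; band gaps are clamped to at least the hole width
#' plus two pixels at the band rows, since an outer-band defect cannot be
#' narrower than the full-thickness hole crossing it.
#'
#' @param geometry List with `bd_um`, `mld_um`, `height_um` (all `NA` for a
#'   closed hole), `ez_defect_um`, `elm_defect_um` (0 = contiguous band),
#'   `pc_area_um2`, and logical `erm`, `space`.
#' @param rows,cols,spacing_um Grid specification.
#' @param eye_id,stage,axis Scan metadata.
#' @return List `scan` (a [labeled_bscan()]) and `truth` (rendered
#'   geometry in physical units).
#' @export
render_scan <- function(geometry, rows = 160, cols = 384,
                        spacing_um = c(5, 10), eye_id = "eye0001",
                        stage = "pre", axis = "horizontal") {
  ax <- spacing_um[1]; lat <- spacing_um[2]
  g <- matrix(0L, rows, cols)
  sch <- label_schema()
  r_rpe <- rows - 11
  cc <- cols %/% 2
  g[r_rpe:(r_rpe + 1), ] <- sch[["RPE"]]
  hole <- !is.na(geometry$bd_um) && geometry$bd_um > 0
  w_px <- integer(0)
  if (hole) {
    bd_px <- max(1L, as.integer(round(geometry$bd_um / lat)))
    mld_px <- min(bd_px, max(1L, as.integer(round(geometry$mld_um / lat))))
    h_px <- max(1L, as.integer(round(geometry$height_um / ax)))
    if (h_px + 12 >= r_rpe || bd_px >= cols - 4) {
      stop("hole geometry exceeds the grid")
    }
    i <- seq_len(h_px) - 1
    w_px <- if (h_px == 1) bd_px else {
      as.integer(round(bd_px + (mld_px - bd_px) * i / (h_px - 1)))
    }
  }
  span_cols <- function(w) {
    left <- cc - w %/% 2
    left:(left + w - 1)
  }
  paint_band <- function(g, rows_band, defect_um, code, hole_w_at) {
    gap_px <- as.integer(round(defect_um / lat))
    if (hole && hole_w_at > 0) gap_px <- max(gap_px, hole_w_at + 2L)
    if (gap_px >= cols - 4) stop("band defect exceeds the grid")
    g[rows_band, ] <- code
    if (gap_px > 0) g[rows_band, span_cols(gap_px)] <- 0L
    attr(g, "gap_px") <- gap_px
    g
  }
  hole_w_at <- function(i) if (hole && i + 1 <= length(w_px)) w_px[i + 1] else 0L
  g <- paint_band(g, (r_rpe - 3):(r_rpe - 2), geometry$ez_defect_um,
                  sch[["EZ"]], max(hole_w_at(1), hole_w_at(2)))
  gap_ez <- attr(g, "gap_px")
  g <- paint_band(g, (r_rpe - 6):(r_rpe - 5), geometry$elm_defect_um,
                  sch[["ELM"]], max(hole_w_at(4), hole_w_at(5)))
  gap_elm <- attr(g, "gap_px")
  if (hole) {
    r_base <- r_rpe - 1
    for (j in seq_along(w_px)) {
      g[r_base - j + 1, span_cols(w_px[j])] <- sch[["macular_hole"]]
    }
  }
  pc_painted <- 0L
  if (!is.na(geometry$pc_area_um2) && geometry$pc_area_um2 > 0) {
    a_target <- geometry$pc_area_um2 / (ax * lat) / 2  # pixels per ellipse
    b_px <- max(2, round(sqrt(a_target / (2 * pi))))
    a_px <- 2 * b_px
    r_c <- r_rpe - 8 - b_px
    offset <- (if (hole) w_px[1] %/% 2 else 15L) + a_px + 4L
    for (sgn in c(-1L, 1L)) {
      col_c <- cc + sgn * offset
      rr <- max(1, r_c - b_px):min(r_rpe - 1, r_c + b_px)
      ccol <- max(1, col_c - a_px):min(cols, col_c + a_px)
      inside <- outer(rr, ccol, function(r, co)
        ((r - r_c) / b_px)^2 + ((co - col_c) / a_px)^2 <= 1)
      blank <- g[rr, ccol, drop = FALSE] == 0L
      sel <- inside & blank
      g[rr, ccol][sel] <- sch[["pseudocyst"]]
      pc_painted <- pc_painted + sum(sel)
    }
  }
  if (isTRUE(geometry$erm)) g[24:25, (cc - 40):(cc + 40)] <- sch[["ERM"]]
  if (isTRUE(geometry$space)) g[27:28, (cc - 20):(cc + 20)] <- sch[["space"]]
  truth <- list(
    mld_um = if (hole) min(w_px) * lat else NA_real_,
    bd_um = if (hole) w_px[1] * lat else NA_real_,
    e_um = if (hole) (min(which(w_px == min(w_px))) - 1) * ax else NA_real_,
    height_um = if (hole) length(w_px) * ax else NA_real_,
    mh_area_um2 = if (hole) sum(w_px) * ax * lat else 0,
    ez_defect_um = gap_ez * lat,
    elm_defect_um = gap_elm * lat,
    pc_area_um2 = pc_painted * ax * lat,
    erm_present = isTRUE(geometry$erm),
    space_present = isTRUE(geometry$space)
  )
  list(scan = labeled_bscan(g, spacing_um, eye_id, stage, axis),
       truth = truth)
}

#' Simulate the five-stage scan series of one phantom eye
#'
#' Draws (or takes) one eye's ground truth, shrinks its lesions along the
#' eye's healing trajectory, and renders the horizontal and vertical B-scan
#' of every stage with small independent geometric jitter. Uses the current
#' RNG stream.
#'
#' @param params A [phantom_params()].
#' @param eye Optional 1-row truth data frame (drawn if omitted).
#' @return List `eye` (truth row), `scans` (list of [labeled_bscan()]),
#'   `visit_truth` (data frame of rendered per-visit truth, averaged over
#'   the two axes as the feature aggregation does).
#' @export
simulate_series <- function(params = phantom_params(), eye = NULL) {
  if (is.null(eye)) {
    p1 <- params
    p1$n_eyes <- 1L
    eye <- draw_cohort_truth(p1)
  }
  geoms <- stage_geometry(eye, params)
  scans <- list()
  visit_rows <- list()
  for (j in seq_along(stage_levels())) {
    st <- stage_levels()[j]
    per_axis <- lapply(axis_levels(), function(axn) {
      gm <- geoms[[j]]
      jit <- function(x) if (is.na(x) || x == 0) x else
        max(x + stats::rnorm(1, 0, params$jitter_um), params$spacing_um[2])
      gm$bd_um <- jit(gm$bd_um); gm$mld_um <- jit(gm$mld_um)
      gm$height_um <- jit(gm$height_um)
      gm$ez_defect_um <- jit(gm$ez_defect_um)
      gm$elm_defect_um <- jit(gm$elm_defect_um)
      if (!is.na(gm$mld_um) && !is.na(gm$bd_um)) {
        gm$mld_um <- min(gm$mld_um, gm$bd_um)
      }
      render_scan(gm, params$rows, params$cols, params$spacing_um,
                  eye$eye_id, st, axn)
    })
    scans <- c(scans, lapply(per_axis, `[[`, "scan"))
    tr <- lapply(per_axis, `[[`, "truth")
    avg <- function(f) {
      v <- c(tr[[1]][[f]], tr[[2]][[f]])
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    visit_rows[[st]] <- data.frame(
      eye_id = eye$eye_id, stage = st,
      mld_um = avg("mld_um"), bd_um = avg("bd_um"), e_um = avg("e_um"),
      height_um = avg("height_um"), mh_area_um2 = avg("mh_area_um2"),
      pseudocyst_area_um2 = avg("pc_area_um2"),
      elm_defect_um = avg("elm_defect_um"),
      ez_defect_um = avg("ez_defect_um"),
      erm_present = tr[[1]]$erm_present | tr[[2]]$erm_present,
      space_present = tr[[1]]$space_present | tr[[2]]$space_present,
      stringsAsFactors = FALSE
    )
  }
  visit_truth <- do.call(rbind, visit_rows)
  rownames(visit_truth) <- NULL
  list(eye = eye, scans = scans, visit_truth = visit_truth)
}

# truth-level feature table (no rasterisation); small measurement noise on
# nonzero sizes emulates extraction quantisation, exact zeros stay exact
truth_features <- function(truth, params) {
  noise_len <- function(x) {
    out <- x
    nz <- !is.na(x) & x > 0
    out[nz] <- pmax(x[nz] + stats::rnorm(sum(nz), 0, params$feature_noise_um),
                    params$spacing_um[2])
    out
  }
  rows <- list()
  for (j in seq_along(stage_levels())) {
    st <- stage_levels()[j]
    lin_mh <- vapply(seq_len(nrow(truth)), function(i)
      c(1, shrink_factors(truth$k_mh[i]))[j], numeric(1))
    lin_ez <- vapply(seq_len(nrow(truth)), function(i)
      c(1, shrink_factors(truth$k_ez[i]))[j], numeric(1))
    lin_elm <- vapply(seq_len(nrow(truth)), function(i)
      c(1, shrink_factors(truth$k_elm[i]))[j], numeric(1))
    a_pc <- vapply(seq_len(nrow(truth)), function(i)
      c(1, shrink_factors(truth$k_pc[i], base = 0.5,
                          never = c(0.75, 0.55, 0.45, 0.40)))[j], numeric(1))
    hole <- lin_mh > 0
    bd <- ifelse(hole, noise_len(truth$bd_um * lin_mh), NA_real_)
    mld <- ifelse(hole, noise_len(truth$mld_um * lin_mh), NA_real_)
    mld <- pmin(mld, bd)
    height <- ifelse(hole, noise_len(truth$height_um * lin_mh), NA_real_)
    area <- ifelse(hole, (bd + mld) / 2 * height, 0)
    pc <- truth$pc_area_um2 * a_pc
    pc <- ifelse(pc > 0, pc * (1 + stats::rnorm(nrow(truth), 0, 0.01)), 0)
    ez <- noise_len(truth$ez_defect_um * lin_ez)
    elm <- noise_len(truth$elm_defect_um * lin_elm)
    rows[[st]] <- data.frame(
      eye_id = truth$eye_id, stage = st, mld_um = mld, bd_um = bd,
      e_um = ifelse(hole, height, NA_real_), height_um = height,
      mh_area_um2 = area, pseudocyst_area_um2 = pc,
      elm_defect_um = elm, ez_defect_um = ez,
      mhi = height / bd, thi = height / mld, dhi = mld / bd,
      mh_pc_area_ratio = ifelse(hole & pc > 0, area / pc, NA_real_),
      erm_present = truth$erm, space_present = truth$space,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$eye_id, match(out$stage, stage_levels())), ]
  rownames(out) <- NULL
  out
}

#' Simulate a complete phantom cohort
#'
#' Draws eyes, healing trajectories, clinical covariates and outcomes;
#' assembles the clinical table and the longitudinal feature table; and
#' optionally renders every B-scan (2 per eye and stage) or writes the
#' whole cohort to disk (masks + JSON sidecars + clinical CSV + truth
#' JSON). The seed in `params` is mandatory so cohorts are byte-identical
#' across runs.
#'
#' @param params A [phantom_params()] with non-`NULL` `seed`.
#' @param render Render the B-scans (slow; intended for modest `n_eyes`).
#'   Without rendering, the feature table carries truth-level measurements
#'   with small observation noise.
#' @param out_dir Optional output directory.
#' @return List `clinical`, `features`, `truth`, `params`, and — when
#'   rendered — `scans`.
#' @export
simulate_cohort <- function(params = phantom_params(), render = FALSE,
                            out_dir = NULL) {
  if (is.null(params$seed)) stop("phantom_params$seed is mandatory")
  set.seed(params$seed)
  truth <- draw_cohort_truth(params)
  clinical <- data.frame(
    eye_id = truth$eye_id, age = truth$age, sex = truth$sex,
    duration_days = truth$duration_days, etdrs_pre = truth$etdrs_pre,
    etdrs_wk2 = truth$etdrs_wk2, etdrs_mo3 = truth$etdrs_mo3,
    etdrs_mo6 = truth$etdrs_mo6, etdrs_mo12 = truth$etdrs_mo12,
    stringsAsFactors = FALSE
  )
  class(clinical) <- c("clinical_table", "data.frame")
  scans <- NULL
  if (render) {
    series <- lapply(seq_len(nrow(truth)), function(i) {
      simulate_series(params, truth[i, , drop = FALSE])
    })
    scans <- do.call(c, lapply(series, `[[`, "scans"))
    features <- do.call(rbind, lapply(series, `[[`, "visit_truth"))
    comp <- t(apply(features, 1, function(r) {
      h <- as.numeric(r[["height_um"]]); b <- as.numeric(r[["bd_um"]])
      m <- as.numeric(r[["mld_um"]]); a <- as.numeric(r[["mh_area_um2"]])
      pcv <- as.numeric(r[["pseudocyst_area_um2"]])
      c(mhi = h / b, thi = h / m, dhi = m / b,
        mh_pc_area_ratio = if (!is.na(a) && a > 0 && pcv > 0) a / pcv
                           else NA_real_)
    }))
    features <- cbind(features, as.data.frame(comp))
    features <- features[c(feature_columns())]
    rownames(features) <- NULL
  } else {
    features <- truth_features(truth, params)
  }
  out <- list(clinical = clinical, features = features, truth = truth,
              params = params, scans = scans)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# write a cohort to disk in the external interface formats
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_clinical_table(cohort$clinical, file.path(out_dir, "clinical.csv"))
  utils::write.csv(cohort$features, file.path(out_dir, "features_truth.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  if (!is.null(cohort$scans)) {
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (sc in cohort$scans) {
      stem <- sprintf("%s_%s_%s", sc$eye_id, sc$stage, sc$axis)
      write_scan(sc, file.path(mask_dir, paste0(stem, ".png")))
    }
  }
  invisible(out_dir)
}
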