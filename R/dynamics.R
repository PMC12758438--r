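#' Follow-up visit schedule
#'
#' Maps the five follow-up stages to time in weeks: preoperative at 0, then
#' 2 weeks, 3 months (13 wk), 6 months (26 wk) and 12 months (52 wk) after
#' surgery. Times must be strictly increasing with `pre = 0`.
#'
#' @param times Named numeric vector overriding the default mapping.
#' @return Named numeric vector of times in weeks.
#' @export
visit_schedule <- function(times = c(pre = 0, wk2 = 2, mo3 = 13,
                                     mo6 = 26, mo12 = 52)) {
  stopifnot(identical(names(times), stage_levels()),
            times[["pre"]] == 0, all(diff(times) > 0))
  times
}

#' Time of first observed lesion resolution
#'
#' A lesion (hole/pseudocyst area, or ELM/EZ defect length) is resolved at
#' the FIRST postoperative visit whose size is zero. A later nonzero after a
#' zero — recurrence — still resolves at the first zero, with a warning.
#' A lesion never observed at zero is censored (`resolved = FALSE`, time
#' missing). Dynamics are undefined when the preoperative size is missing or
#' zero.
#'
#' @param series Numeric vector of sizes named by stage (missing visits as
#'   `NA`); must include `pre`.
#' @param schedule Stage-to-week mapping from [visit_schedule()].
#' @return List `t_resolved_weeks`, `resolved`, plus `defined` (FALSE when
#'   the preoperative size is absent or zero).
#' @export
resolution_time <- function(series, schedule = visit_schedule()) {
  stopifnot("pre" %in% names(series))
  pre <- series[["pre"]]
  if (is.na(pre) || pre <= 0) {
    return(list(t_resolved_weeks = NA_real_, resolved = FALSE,
                defined = FALSE))
  }
  post_stages <- setdiff(stage_levels(), "pre")
  post <- series[intersect(post_stages, names(series))]
  obs <- post[!is.na(post)]
  zero <- which(obs == 0)
  if (length(zero) == 0L) {
    return(list(t_resolved_weeks = NA_real_, resolved = FALSE,
                defined = TRUE))
  }
  first <- zero[1]
  if (any(obs[seq_along(obs) > first] > 0)) {
    warning("lesion recurrence after resolution; using first zero")
  }
  list(t_resolved_weeks = unname(schedule[names(obs)[first]]),
       resolved = TRUE, defined = TRUE)
}

#' Lesion recovery rate
#'
#' The recovery rate of a lesion is the ratio between its initial
#' (preoperative) size and the time at which it was first observed fully
#' resolved, in size units per week. In `mode = "paper"` the rate is defined
#' only for resolved lesions (censored eyes get a missing rate). The default
#' `mode = "extended"` supplies a principled fallback for censored lesions:
#' the mean shrinkage rate over follow-up,
#' `(initial - last observed size) / t_last`.
#'
#' @param initial_size Preoperative lesion size (> 0).
#' @param t_resolved,resolved Output of [resolution_time()].
#' @param series,schedule Needed only for the censored fallback.
#' @param mode `"extended"` (default) or `"paper"`.
#' @return Rate in size units per week, or `NA`.
#' @export
recovery_rate <- function(initial_size, t_resolved, resolved,
                          series = NULL, schedule = visit_schedule(),
                          mode = c("extended", "paper")) {
  mode <- match.arg(mode)
  if (is.na(initial_size) || initial_size <= 0) return(NA_real_)
  if (isTRUE(resolved)) return(initial_size / t_resolved)
  if (mode == "paper") return(NA_real_)
  post <- series[intersect(setdiff(stage_levels(), "pre"), names(series))]
  obs <- post[!is.na(post)]
  if (length(obs) == 0L) return(NA_real_)
  last_stage <- names(obs)[length(obs)]
  (initial_size - obs[[length(obs)]]) / unname(schedule[last_stage])
}

#' Shape complexity factor of a lesion
#'
#' Inverse circularity `phi = P^2 / (4 pi A)` of the largest component of a
#' labelled region, in physical units: `A` is the pixel-count area and `P`
#' the length of the 0.5-level marching-squares contour of the component
#' mask (sub-pixel boundary, so a rasterised disc stays close to the
#' continuum value `phi = 1`). A square tends to `4 / pi`; elongated or
#' irregular lesions score higher. Missing when the region is absent.
#'
#' This factor and its use in [weighted_recovery_rate()] are this package's
#' reconstruction of a shape-weighted adjustment whose exact published form
#' is unavailable; both are configuration-exposed.
#'
#' @param scan A [labeled_bscan()] (typically the preoperative scan).
#' @param label Structure name, usually `"macular_hole"` or `"pseudocyst"`.
#' @param connectivity Component connectivity.
#' @return `phi` (>= about 1 for compact shapes), or `NA` if absent.
#' @export
shape_factor <- function(scan, label, connectivity = 8) {
  stopifnot(inherits(scan, "labeled_bscan"))
  comp <- largest_component(label_mask(scan, label), connectivity)
  if (is.null(comp)) return(NA_real_)
  ax <- scan$spacing_um[1]; lat <- scan$spacing_um[2]
  area <- sum(comp) * ax * lat
  # pad so border-touching components still close
  z <- matrix(0, nrow(comp) + 2, ncol(comp) + 2)
  z[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
  lines <- grDevices::contourLines(x = seq_len(nrow(z)) * ax,
                                   y = seq_len(ncol(z)) * lat,
                                   z = z, levels = 0.5)
  per <- sum(vapply(lines, function(cl) {
    xs <- c(cl$x, cl$x[1]); ys <- c(cl$y, cl$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1)))
  per^2 / (4 * pi * area)
}

#' Shape-weighted recovery rate
#'
#' Linear coefficient-weighted adjustment of a recovery rate for
#' pre-resolution morphological complexity:
#' `rate_w = rate * (1 + kappa * (phi - 1))`. A circular lesion
#' (`phi = 1`) or `kappa = 0` leaves the rate unchanged; the adjustment is
#' non-decreasing in both `phi` and `kappa`.
#'
#' @param rate Recovery rate from [recovery_rate()].
#' @param phi Shape factor from [shape_factor()].
#' @param kappa Weighting coefficient (>= 0, default 0.5).
#' @return Adjusted rate.
#' @export
weighted_recovery_rate <- function(rate, phi, kappa = 0.5) {
  stopifnot(kappa >= 0)
  rate * (1 + kappa * (phi - 1))
}

dynamics_lesions <- function() {
  c(mh = "mh_area_um2", pc = "pseudocyst_area_um2",
    elm = "elm_defect_um", ez = "ez_defect_um")
}

#' Per-eye dynamic recovery parameters from the longitudinal feature table
#'
#' For each eye and each of four lesions — macular hole area, pseudocyst
#' area, ELM defect length, EZ defect length — computes the initial
#' (preoperative) size, resolution time, resolution flag and recovery rate.
#' Band defects are additionally emitted on a percentage scale
#' (`rate_pct_* = 100 * rate / initial`, i.e. percent of the initial defect
#' recovered per week), and the hole and pseudocyst rates in shape-weighted
#' form when shape factors are supplied.
#'
#' @param features Feature table from [build_feature_table()].
#' @param schedule Visit schedule in weeks.
#' @param mode Censoring mode of [recovery_rate()].
#' @param kappa Shape-weighting coefficient.
#' @param shape_factors Optional data frame with columns `eye_id`,
#'   `phi_mh`, `phi_pc` (e.g. computed from preoperative scans via
#'   [shape_factor()]).
#' @return Data frame, one row per eye.
#' @export
compute_dynamics <- function(features, schedule = visit_schedule(),
                             mode = c("extended", "paper"), kappa = 0.5,
                             shape_factors = NULL) {
  mode <- match.arg(mode)
  rows <- lapply(split(features, features$eye_id), function(fe) {
    out <- list(eye_id = fe$eye_id[1])
    for (lesion in names(dynamics_lesions())) {
      col <- dynamics_lesions()[[lesion]]
      series <- stats::setNames(rep(NA_real_, 5), stage_levels())
      series[fe$stage] <- fe[[col]]
      res <- resolution_time(series, schedule)
      init <- if (res$defined) series[["pre"]] else NA_real_
      rate <- if (res$defined) {
        recovery_rate(init, res$t_resolved_weeks, res$resolved,
                      series, schedule, mode)
      } else NA_real_
      out[[paste0("initial_", lesion)]] <- init
      out[[paste0("t_resolved_", lesion)]] <- res$t_resolved_weeks
      out[[paste0("resolved_", lesion)]] <- res$resolved
      out[[paste0("rate_", lesion)]] <- unname(rate)
      if (lesion %in% c("elm", "ez")) {
        out[[paste0("rate_pct_", lesion)]] <-
          if (is.na(rate)) NA_real_ else unname(100 * rate / init)
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  dyn <- do.call(rbind, rows)
  rownames(dyn) <- NULL
  dyn$phi_mh <- NA_real_
  dyn$phi_pc <- NA_real_
  if (!is.null(shape_factors)) {
    m <- match(dyn$eye_id, shape_factors$eye_id)
    if ("phi_mh" %in% names(shape_factors)) dyn$phi_mh <- shape_factors$phi_mh[m]
    if ("phi_pc" %in% names(shape_factors)) dyn$phi_pc <- shape_factors$phi_pc[m]
  }
  dyn$rate_w_mh <- weighted_recovery_rate(dyn$rate_mh, dyn$phi_mh, kappa)
  dyn$rate_w_pc <- weighted_recovery_rate(dyn$rate_pc, dyn$phi_pc, kappa)
  dyn
}
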