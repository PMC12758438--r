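feature_columns <- function() {
  c("eye_id", "stage", "mld_um", "bd_um", "e_um", "height_um",
    "mh_area_um2", "pseudocyst_area_um2", "elm_defect_um", "ez_defect_um",
    "mhi", "thi", "dhi", "mh_pc_area_ratio", "erm_present", "space_present")
}

#' Composite macular hole indices
#'
#' Ratio indices of hole geometry used as prognostic descriptors:
#' MHI = height / BD, THI = height / MLD, DHI = MLD / BD, and the area ratio
#' between the macular hole and the surrounding pseudocysts. All composites
#' are missing when the hole is absent; the area ratio is additionally
#' missing when the pseudocyst area is zero. A present hole with a zero MLD
#' or BD is degenerate and raises an error.
#'
#' @param geom A `hole_geometry` from [extract_hole_geometry()].
#' @param pc_area_um2 Pseudocyst area in square micrometres.
#' @return List with `mhi`, `thi`, `dhi`, `mh_pc_area_ratio`.
#' @examples
#' g <- structure(list(mld_um = 500, bd_um = 1000, e_um = 0, height_um = 400,
#'                     area_um2 = 3e5, present = TRUE), class = "hole_geometry")
#' composite_indices(g, 4000)
#' @export
composite_indices <- function(geom, pc_area_um2) {
  if (!isTRUE(geom$present)) {
    return(list(mhi = NA_real_, thi = NA_real_, dhi = NA_real_,
                mh_pc_area_ratio = NA_real_))
  }
  if (geom$mld_um == 0 || geom$bd_um == 0) {
    stop("degenerate geometry: present hole with zero MLD or BD")
  }
  list(
    mhi = geom$height_um / geom$bd_um,
    thi = geom$height_um / geom$mld_um,
    dhi = geom$mld_um / geom$bd_um,
    mh_pc_area_ratio = if (is.na(pc_area_um2) || pc_area_um2 == 0) NA_real_
                       else geom$area_um2 / pc_area_um2
  )
}

#' Morphometric primitives of one B-scan
#'
#' Runs all single-scan extractors and returns the primitive measurements as
#' a one-row data frame (no composites; those are recomputed after
#' aggregation across the orthogonal scans of one visit).
#'
#' @param scan A [labeled_bscan()].
#' @param min_pixels Presence threshold for qualitative flags.
#' @param gap_mode Interior gap mode for band defects, see
#'   [extract_band_defect()].
#' @param connectivity Component connectivity for the hole.
#' @return One-row data frame of primitives.
#' @export
scan_features <- function(scan, min_pixels = 20, gap_mode = "largest",
                          connectivity = 8) {
  geom <- extract_hole_geometry(scan, connectivity)
  qual <- extract_qualitative(scan, min_pixels)
  data.frame(
    eye_id = scan$eye_id, stage = scan$stage, axis = scan$axis,
    mld_um = geom$mld_um, bd_um = geom$bd_um, e_um = geom$e_um,
    height_um = geom$height_um,
    # hole area from the full label so a closed hole is a true zero
    mh_area_um2 = extract_region_area(scan, "macular_hole")$area_um2,
    pseudocyst_area_um2 = extract_region_area(scan, "pseudocyst")$area_um2,
    elm_defect_um = extract_band_defect(scan, "ELM", gap_mode)$defect_length_um,
    ez_defect_um = extract_band_defect(scan, "EZ", gap_mode)$defect_length_um,
    erm_present = qual$erm_present, space_present = qual$space_present,
    stringsAsFactors = FALSE
  )
}

#' Aggregate the orthogonal scans of one visit into a feature record
#'
#' Each examination contributes up to two orthogonal B-scans (horizontal and
#' vertical). Lengths and areas are aggregated by arithmetic mean over the
#' scans on which they are measurable, presence flags by logical OR, and the
#' composite indices are then recomputed from the aggregated primitives
#' (ratio of means, so DHI x THI = MHI holds exactly). The aggregation rule
#' is configurable because merging of the two axes is a reporting choice,
#' not a measurement.
#'
#' @param scans List of 1-2 [labeled_bscan()] of the same eye and stage.
#' @param size_agg Aggregation for sizes: `"mean"` (default), `"min"`, `"max"`.
#' @param min_pixels,gap_mode,connectivity Passed to [scan_features()].
#' @return One-row data frame with the columns of the feature table.
#' @export
aggregate_visit <- function(scans, size_agg = c("mean", "min", "max"),
                            min_pixels = 20, gap_mode = "largest",
                            connectivity = 8) {
  size_agg <- match.arg(size_agg)
  if (inherits(scans, "labeled_bscan")) scans <- list(scans)
  stopifnot(length(scans) >= 1L, length(scans) <= 2L)
  if (length(unique(vapply(scans, `[[`, "", "eye_id"))) != 1L ||
      length(unique(vapply(scans, `[[`, "", "stage"))) != 1L) {
    stop("scans of one visit must share eye_id and stage")
  }
  per <- do.call(rbind, lapply(scans, scan_features, min_pixels = min_pixels,
                               gap_mode = gap_mode,
                               connectivity = connectivity))
  agg <- switch(size_agg,
                mean = function(x) mean(x, na.rm = TRUE),
                min = function(x) min(x, na.rm = TRUE),
                max = function(x) max(x, na.rm = TRUE))
  num <- function(col) {
    x <- per[[col]]
    if (all(is.na(x))) NA_real_ else agg(x)
  }
  rec <- data.frame(
    eye_id = per$eye_id[1], stage = per$stage[1],
    mld_um = num("mld_um"), bd_um = num("bd_um"), e_um = num("e_um"),
    height_um = num("height_um"), mh_area_um2 = num("mh_area_um2"),
    pseudocyst_area_um2 = num("pseudocyst_area_um2"),
    elm_defect_um = num("elm_defect_um"), ez_defect_um = num("ez_defect_um"),
    stringsAsFactors = FALSE
  )
  geom <- structure(list(mld_um = rec$mld_um, bd_um = rec$bd_um,
                         e_um = rec$e_um, height_um = rec$height_um,
                         area_um2 = rec$mh_area_um2,
                         present = !is.na(rec$mld_um)),
                    class = "hole_geometry")
  comp <- composite_indices(geom, rec$pseudocyst_area_um2)
  rec$mhi <- comp$mhi; rec$thi <- comp$thi; rec$dhi <- comp$dhi
  rec$mh_pc_area_ratio <- comp$mh_pc_area_ratio
  rec$erm_present <- any(per$erm_present)
  rec$space_present <- any(per$space_present)
  rec$n_scans <- nrow(per)
  rec[c(feature_columns(), "n_scans")]
}

#' Build the per-visit feature table from a set of scans
#'
#' Groups scans by eye and stage, aggregates each visit with
#' [aggregate_visit()], and returns the feature table (one row per
#' eye x stage).
#'
#' @param scans List of [labeled_bscan()].
#' @inheritParams aggregate_visit
#' @return Data frame, one row per eye and stage.
#' @export
build_feature_table <- function(scans, size_agg = "mean", min_pixels = 20,
                                gap_mode = "largest", connectivity = 8) {
  key <- paste(vapply(scans, `[[`, "", "eye_id"),
               vapply(scans, `[[`, "", "stage"), sep = "\r")
  out <- lapply(split(scans, key), aggregate_visit, size_agg = size_agg,
                min_pixels = min_pixels, gap_mode = gap_mode,
                connectivity = connectivity)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$eye_id, match(out$stage, stage_levels())), ]
  rownames(out) <- NULL
  out
}
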