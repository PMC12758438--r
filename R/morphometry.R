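#' Calliper-style macular hole geometry from one labelled B-scan
#'
#' Measures the macular hole on a single B-scan the way a clinician places
#' callipers on the display: per-row widths are lateral *extents* (span from
#' first to last hole pixel, so interior islands such as operculum remnants
#' never shrink a width), all measurements are strictly horizontal or
#' vertical, and only the largest 8-connected hole component is measured
#' (stray annotation islands are discarded with a message).
#'
#' Definitions, with `r_base` the bottommost (choroid-side) hole row:
#' * `bd_um` — base diameter, the width at `r_base`;
#' * `mld_um` — minimum linear diameter, the minimum row width, ties broken
#'   toward the base row so the offset `e` is deterministic;
#' * `e_um` — vertical offset between the MLD row and the base row;
#' * `height_um` — vertical extent of the hole (inclusive row count);
#' * `area_um2` — component pixel count times the pixel area.
#'
#' @param scan A [labeled_bscan()].
#' @param connectivity Pixel connectivity for component selection (8 or 4).
#' @return A `hole_geometry` list with fields `mld_um`, `bd_um`, `e_um`,
#'   `height_um`, `area_um2` and the flag `present`. When no hole pixels
#'   exist `present` is `FALSE` and every numeric field is `NA`.
#' @examples
#' g <- matrix(0L, 30, 40)
#' g[5:24, 11:20] <- 1L   # 10 px wide, 20 rows tall
#' sc <- labeled_bscan(g, c(5, 10), "e1", "pre", "horizontal")
#' extract_hole_geometry(sc)
#' @export
extract_hole_geometry <- function(scan, connectivity = 8) {
  stopifnot(inherits(scan, "labeled_bscan"))
  mask <- label_mask(scan, "macular_hole")
  comp <- largest_component(mask, connectivity)
  ax <- scan$spacing_um[1]; lat <- scan$spacing_um[2]
  if (is.null(comp)) {
    return(structure(list(mld_um = NA_real_, bd_um = NA_real_, e_um = NA_real_,
                          height_um = NA_real_, area_um2 = NA_real_,
                          present = FALSE),
                     class = "hole_geometry"))
  }
  idx <- which(comp, arr.ind = TRUE)
  rows <- sort(unique(idx[, 1]))
  # lateral extent per occupied row, in pixels
  w_px <- vapply(rows, function(r) {
    cols <- idx[idx[, 1] == r, 2]
    diff(range(cols)) + 1
  }, numeric(1))
  r_base <- rows[length(rows)]
  r_top <- rows[1]
  bd_px <- w_px[length(rows)]
  mld_px <- min(w_px)
  r_mld <- max(rows[w_px == mld_px])  # tie toward base
  structure(list(
    mld_um = mld_px * lat,
    bd_um = bd_px * lat,
    e_um = (r_base - r_mld) * ax,
    height_um = (r_base - r_top + 1) * ax,
    area_um2 = sum(comp) * ax * lat,
    present = TRUE
  ), class = "hole_geometry")
}

# largest connected component of a logical mask; NULL when empty.
# Messages the number of discarded pixels so audits can trace them.
largest_component <- function(mask, connectivity = 8) {
  if (!any(mask)) return(NULL)
  lab <- .cc_label(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  if (length(sizes) > 1L) {
    message(sprintf("discarding %d pixel(s) in %d stray component(s)",
                    sum(sizes) - sizes[keep], length(sizes) - 1L))
  }
  lab == keep
}

#' Outer retinal band defect length
#'
#' The defect of a hyper-reflective outer-retinal band (ELM or EZ) is the
#' largest run of consecutive columns with no band pixel, measured strictly
#' inside the band's lateral footprint `[min col, max col]` and converted to
#' micrometres with the lateral spacing. A contiguous band has defect 0; an
#' entirely absent band yields `band_present = FALSE` and a missing defect
#' (absence of the band is not a zero-length defect). `mode = "sum"` instead
#' totals all interior gaps.
#'
#' @param scan A [labeled_bscan()].
#' @param band `"ELM"` or `"EZ"`.
#' @param mode `"largest"` (default) or `"sum"` interior gap length.
#' @return A `band_defect` list: `band`, `defect_length_um`, `band_present`.
#' @export
extract_band_defect <- function(scan, band = c("ELM", "EZ"),
                                mode = c("largest", "sum")) {
  stopifnot(inherits(scan, "labeled_bscan"))
  band <- match.arg(band)
  mode <- match.arg(mode)
  present_cols <- which(apply(label_mask(scan, band), 2, any))
  if (length(present_cols) == 0L) {
    return(structure(list(band = band, defect_length_um = NA_real_,
                          band_present = FALSE), class = "band_defect"))
  }
  span <- seq(min(present_cols), max(present_cols))
  absent <- !(span %in% present_cols)
  gap_px <- if (!any(absent)) 0 else {
    runs <- rle(absent)
    gaps <- runs$lengths[runs$values]
    if (mode == "largest") max(gaps) else sum(gaps)
  }
  structure(list(band = band,
                 defect_length_um = gap_px * scan$spacing_um[2],
                 band_present = TRUE), class = "band_defect")
}

#' Total area of a labelled region
#'
#' Pixel count of the label (all components) times the pixel area. Unlike
#' band defects, a region area is legitimately zero when the label is absent.
#'
#' @param scan A [labeled_bscan()].
#' @param label A structure name from [label_schema()].
#' @return A `region_area` list: `label`, `area_um2`.
#' @export
extract_region_area <- function(scan, label) {
  stopifnot(inherits(scan, "labeled_bscan"))
  n <- sum(label_mask(scan, label))
  structure(list(label = label,
                 area_um2 = n * scan$spacing_um[1] * scan$spacing_um[2]),
            class = "region_area")
}

#' Qualitative vitreoretinal interface flags
#'
#' Presence of an epiretinal membrane and of a tractional space between the
#' ERM and the inner retinal surface, called present when the label's pixel
#' count reaches `min_pixels` (default 20, suppressing annotation speckle).
#'
#' @param scan A [labeled_bscan()].
#' @param min_pixels Minimum pixel count to call a structure present (>= 1).
#' @return List of logical flags `erm_present`, `space_present`.
#' @export
extract_qualitative <- function(scan, min_pixels = 20) {
  stopifnot(inherits(scan, "labeled_bscan"), min_pixels >= 1)
  list(erm_present = sum(label_mask(scan, "ERM")) >= min_pixels,
       space_present = sum(label_mask(scan, "space")) >= min_pixels)
}
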