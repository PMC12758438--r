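#' Label schema for macular-hole OCT segmentation masks
#'
#' The fixed ten-code schema used throughout the package: background plus the
#' nine vitreoretinal structures annotated on macular-hole B-scans. Codes are
#' contiguous from 0 and never remapped; any mask value outside this set is a
#' hard error at read time.
#'
#' @return Named integer vector mapping structure name to label code.
#' @examples
#' label_schema()["macular_hole"]
#' @export
label_schema <- function() {
  c(background = 0L, macular_hole = 1L, pseudocyst = 2L, ERM = 3L,
    space = 4L, VMT = 5L, PVD = 6L, ELM = 7L, EZ = 8L, RPE = 9L)
}

#' @rdname label_schema
#' @export
stage_levels <- function() c("pre", "wk2", "mo3", "mo6", "mo12")

#' @rdname label_schema
#' @export
axis_levels <- function() c("horizontal", "vertical")

#' Construct a labelled B-scan
#'
#' A `labeled_bscan` is one OCT B-scan reduced to its segmentation labels:
#' an integer matrix (rows = axial direction, row 1 at the vitreous side;
#' columns = lateral direction), physical pixel spacing, and visit metadata.
#'
#' @param grid Integer matrix of label codes (see [label_schema()]).
#' @param spacing_um Numeric length-2 vector: axial then lateral spacing in
#'   micrometres per pixel; both must be positive.
#' @param eye_id Opaque eye identifier.
#' @param stage Follow-up stage, one of `r paste(stage_levels(), collapse=", ")`.
#' @param axis Scan axis, `"horizontal"` or `"vertical"`.
#' @return Object of class `labeled_bscan`.
#' @examples
#' g <- matrix(0L, 4, 4)
#' labeled_bscan(g, c(5, 10), "eye1", "pre", "horizontal")
#' @export
labeled_bscan <- function(grid, spacing_um, eye_id, stage, axis) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  storage.mode(grid) <- "integer"
  if (anyNA(grid)) stop("grid contains NA label values")
  bad <- setdiff(unique(as.vector(grid)), unname(label_schema()))
  if (length(bad) > 0L) {
    stop(sprintf("unknown label %s", paste(sort(bad), collapse = ", ")))
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 2L || anyNA(spacing_um) || any(spacing_um <= 0)) {
    stop("spacing_um must be two positive numbers (axial, lateral)")
  }
  stage <- match.arg(stage, stage_levels())
  axis <- match.arg(axis, axis_levels())
  structure(
    list(grid = grid, spacing_um = spacing_um,
         eye_id = as.character(eye_id), stage = stage, axis = axis),
    class = "labeled_bscan"
  )
}

#' @export
print.labeled_bscan <- function(x, ...) {
  counts <- tabulate(as.vector(x$grid) + 1L, nbins = 10L)
  present <- names(label_schema())[counts > 0 & label_schema() != 0L]
  cat(sprintf("<labeled_bscan> eye %s, stage %s, %s axis\n",
              x$eye_id, x$stage, x$axis))
  cat(sprintf("  grid %d x %d px, spacing %.3g x %.3g um (axial x lateral)\n",
              nrow(x$grid), ncol(x$grid), x$spacing_um[1], x$spacing_um[2]))
  cat("  structures:", if (length(present)) paste(present, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

# pixel mask for one named label
label_mask <- function(scan, label) {
  code <- label_schema()[[match.arg(label, names(label_schema()))]]
  scan$grid == code
}
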