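#' Read and write labelled B-scan masks
#'
#' Masks are stored as single-channel 8-bit PNG files whose pixel values are
#' the raw label codes of [label_schema()]. Physical spacing and visit
#' metadata live in a JSON sidecar (keys `eye_id`, `stage`, `axis`,
#' `spacing_um` with axial then lateral micrometres per pixel); the sidecar,
#' not the filename, is the source of truth.
#'
#' @param mask_path Path to the PNG mask.
#' @param sidecar_path Path to the JSON sidecar; defaults to the mask path
#'   with extension replaced by `.json`.
#' @return [read_scan()] returns a [labeled_bscan()]; [write_scan()] returns
#'   `mask_path` invisibly.
#' @export
read_scan <- function(mask_path, sidecar_path = sub("\\.png$", ".json", mask_path)) {
  if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
  if (!file.exists(sidecar_path)) stop("sidecar file not found: ", sidecar_path)
  img <- png::readPNG(mask_path)
  if (length(dim(img)) != 2L) {
    stop("mask must be single-channel 8-bit: ", mask_path)
  }
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("eye_id", "stage", "axis", "spacing_um")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("sidecar %s is missing field '%s'", sidecar_path, key))
    }
  }
  labeled_bscan(grid, meta$spacing_um, meta$eye_id, meta$stage, meta$axis)
}

#' @param scan A [labeled_bscan()].
#' @rdname read_scan
#' @export
write_scan <- function(scan, mask_path,
                       sidecar_path = sub("\\.png$", ".json", mask_path)) {
  stopifnot(inherits(scan, "labeled_bscan"))
  png::writePNG(scan$grid / 255, mask_path)
  jsonlite::write_json(
    list(eye_id = scan$eye_id, stage = scan$stage, axis = scan$axis,
         spacing_um = scan$spacing_um),
    sidecar_path, auto_unbox = TRUE, digits = NA
  )
  invisible(mask_path)
}

clinical_columns <- function() {
  c("eye_id", "age", "sex", "duration_days",
    paste0("etdrs_", stage_levels()))
}

#' Read and write the clinical table
#'
#' The clinical table is a CSV with one row per eye and columns `eye_id`,
#' `age`, `sex`, `duration_days`, and `etdrs_<stage>` for the five follow-up
#' stages. Empty cells are missing values, never zeros; ETDRS letter scores
#' must lie in \[0, 100\] when present and symptom duration must be
#' non-negative. Duplicate eye ids are an error.
#'
#' @param csv_path Path to the CSV file.
#' @return A data frame with the documented columns, class
#'   `clinical_table`.
#' @export
read_clinical_table <- function(csv_path) {
  if (!file.exists(csv_path)) stop("clinical table not found: ", csv_path)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(clinical_columns(), names(tab))
  if (length(missing_cols) > 0L) {
    stop("clinical table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[clinical_columns()]
  tab$eye_id <- as.character(tab$eye_id)
  if (anyDuplicated(tab$eye_id)) {
    stop("duplicate eye_id in clinical table: ",
         paste(unique(tab$eye_id[duplicated(tab$eye_id)]), collapse = ", "))
  }
  num_cols <- setdiff(clinical_columns(), c("eye_id", "sex"))
  for (cn in num_cols) tab[[cn]] <- as.numeric(tab[[cn]])
  etdrs <- as.matrix(tab[paste0("etdrs_", stage_levels())])
  if (any(etdrs < 0 | etdrs > 100, na.rm = TRUE)) {
    stop("ETDRS letter scores must lie in [0, 100]")
  }
  if (any(tab$duration_days < 0, na.rm = TRUE)) {
    stop("duration_days must be non-negative")
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' @param clinical A clinical table as returned by [read_clinical_table()].
#' @rdname read_clinical_table
#' @export
write_clinical_table <- function(clinical, csv_path) {
  stopifnot(all(clinical_columns() %in% names(clinical)))
  utils::write.csv(as.data.frame(clinical)[clinical_columns()], csv_path,
                   row.names = FALSE, na = "")
  invisible(csv_path)
}
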