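# Reading, validating and writing the two-file plate format:
#   layout.csv — one row per well (roles, conditions, replicate pairing)
#   scans.csv  — long form, one row per grid point per scan per well
# Empty string in a character column means "not applicable" and maps to NA.

.pife_roles <- c("sample", "buffer_control", "blank")

.layout_cols <- c(
  "well_id", "role", "probe_id", "protein_id", "protein_pmol",
  "competitor_id", "competitor_excess", "buffer_id",
  "replicate_group", "control_group", "volume_ul"
)

.scan_cols <- c("well_id", "scan_index", "point_row", "point_col", "intensity")

#' Assemble a plate object from a layout table and a long-form scan table
#'
#' @param layout data.frame with the layout columns (see [read_plate()]).
#' @param scans data.frame with columns well_id, scan_index, point_row,
#'   point_col, intensity.
#' @param validate Run [validate_plate()] before returning. Default TRUE.
#' @return An object of class \code{pife_plate}: a list with elements
#'   \code{layout} and \code{scans}.
#' @export
pife_plate <- function(layout, scans, validate = TRUE) {
  layout <- as.data.frame(layout, stringsAsFactors = FALSE)
  scans <- as.data.frame(scans, stringsAsFactors = FALSE)
  plate <- structure(list(layout = layout, scans = scans),
                     class = "pife_plate")
  if (validate) validate_plate(plate)
  plate
}

#' @export
print.pife_plate <- function(x, ...) {
  n_scan <- length(unique(x$scans$scan_index))
  cat(sprintf(
    "mwPIFE plate: %d wells (%d sample, %d buffer_control), %d scan(s)\n",
    nrow(x$layout), sum(x$layout$role == "sample"),
    sum(x$layout$role == "buffer_control"), n_scan
  ))
  invisible(x)
}

#' Validate a plate against the layout and scan invariants
#'
#' Checks, with hard errors naming the offending well/group/row:
#' well_id uniqueness; roles drawn from sample/buffer_control/blank;
#' non-negative amounts and excesses, positive volumes; every sample
#' replicate group paired with an existing buffer_control group; every scan
#' row matched to a layout well; finite non-negative intensities; scan
#' indices in 1..3 with scan 1 present for every scanned well; complete
#' square grids of one common size across the plate.
#'
#' @param plate A \code{pife_plate} (or a list with layout and scans).
#' @return Invisibly TRUE; stops on the first violation.
#' @export
validate_plate <- function(plate) {
  layout <- plate$layout
  scans <- plate$scans

  missing_cols <- setdiff(.layout_cols, names(layout))
  if (length(missing_cols)) {
    stop("layout is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  missing_cols <- setdiff(.scan_cols, names(scans))
  if (length(missing_cols)) {
    stop("scans table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  if (anyDuplicated(layout$well_id)) {
    stop("duplicated well_id in layout: ",
         paste(unique(layout$well_id[duplicated(layout$well_id)]),
               collapse = ", "))
  }
  bad_role <- setdiff(unique(layout$role), .pife_roles)
  if (length(bad_role)) {
    stop("unknown role(s) in layout: ", paste(bad_role, collapse = ", "))
  }
  if (any(!is.na(layout$protein_pmol) & layout$protein_pmol < 0)) {
    stop("protein_pmol must be >= 0")
  }
  if (any(!is.na(layout$competitor_excess) & layout$competitor_excess < 0)) {
    stop("competitor_excess must be >= 0")
  }
  if (any(!is.finite(layout$volume_ul) | layout$volume_ul <= 0)) {
    stop("volume_ul must be positive for every well")
  }

  # every sample replicate group must point at an existing buffer_control group
  ctrl_groups <- unique(layout$replicate_group[layout$role == "buffer_control"])
  smp <- layout[layout$role == "sample", , drop = FALSE]
  unpaired <- unique(smp$replicate_group[
    is.na(smp$control_group) | !(smp$control_group %in% ctrl_groups)
  ])
  if (length(unpaired)) {
    stop("unpaired sample group (no buffer_control group): ",
         paste(unpaired, collapse = ", "))
  }

  bad_num <- which(!is.finite(scans$intensity) | scans$intensity < 0)
  if (length(bad_num)) {
    stop("non-finite or negative intensity in scans row(s): ",
         paste(utils::head(bad_num, 5), collapse = ", "))
  }
  orphan <- setdiff(unique(scans$well_id), layout$well_id)
  if (length(orphan)) {
    stop("scan rows reference well(s) missing from layout: ",
         paste(orphan, collapse = ", "))
  }
  if (any(!scans$scan_index %in% 1:3)) stop("scan_index must be 1, 2 or 3")

  # per-well scan presence: scan 1 mandatory, indices a prefix-free set is not
  # required, but every present scan must be a complete square grid of the
  # plate-wide grid size
  g <- length(unique(scans$point_row))
  if (!all(sort(unique(scans$point_row)) == seq_len(g)) ||
      !all(sort(unique(scans$point_col)) == seq_len(g))) {
    stop("grid points must cover 1..grid_size in both point_row and point_col")
  }
  cnt <- table(scans$well_id, scans$scan_index)
  if (any(cnt != 0 & cnt != g * g)) {
    stop("incomplete scan grid (expected ", g * g, " points per well-scan)")
  }
  wells_scanned <- rownames(cnt)
  if ("1" %in% colnames(cnt)) {
    no_scan1 <- wells_scanned[cnt[, "1"] == 0]
  } else {
    no_scan1 <- wells_scanned
  }
  if (length(no_scan1)) {
    stop("well(s) without a first (reference) scan: ",
         paste(no_scan1, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a plate from layout.csv and scans.csv
#'
#' @param layout_path Path to the layout CSV (columns: well_id, role,
#'   probe_id, protein_id, protein_pmol, competitor_id, competitor_excess,
#'   buffer_id, replicate_group, control_group, volume_ul).
#' @param scans_path Path to the long-form scans CSV (columns: well_id,
#'   scan_index, point_row, point_col, intensity). Wells without a third
#'   scan simply have no scan_index-3 rows.
#' @param validate Run [validate_plate()]. Default TRUE.
#' @return A \code{pife_plate}.
#' @export
read_plate <- function(layout_path, scans_path, validate = TRUE) {
  if (!file.exists(layout_path)) stop("layout file not found: ", layout_path)
  if (!file.exists(scans_path)) stop("scans file not found: ", scans_path)

  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(.layout_cols, names(layout))
  if (length(missing_cols)) {
    stop("layout is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("protein_pmol", "competitor_excess", "volume_ul")) {
    v <- layout[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("non-numeric ", col, " in layout row(s): ",
           paste(bad, collapse = ", "))
    }
    layout[[col]] <- num
  }
  for (col in c("probe_id", "protein_id", "competitor_id", "buffer_id",
                "control_group")) {
    layout[[col]][layout[[col]] == ""] <- NA_character_
  }

  scans <- utils::read.csv(scans_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(.scan_cols, names(scans))
  if (length(missing_cols)) {
    stop("scans table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("scan_index", "point_row", "point_col", "intensity")) {
    num <- suppressWarnings(as.numeric(scans[[col]]))
    bad <- which(is.na(num) & !is.na(scans[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " in scans row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    scans[[col]] <- if (col == "intensity") num else as.integer(num)
  }

  pife_plate(layout, scans, validate = validate)
}

# full-precision decimal rendering so numeric round trips are bit-identical
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a plate to layout.csv and scans.csv in a directory
#'
#' Numeric values are written with 17 significant digits so that
#' \code{read_plate(write_plate(x))} reproduces every double bit-identically.
#' Missing third scans are encoded by absence of rows, never by zeros.
#'
#' @param plate A \code{pife_plate}.
#' @param dir Output directory (created if needed).
#' @return Named character vector with the two file paths.
#' @export
write_plate <- function(plate, dir) {
  validate_plate(plate)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  layout_path <- file.path(dir, "layout.csv")
  scans_path <- file.path(dir, "scans.csv")

  lay <- plate$layout[, .layout_cols, drop = FALSE]
  for (col in c("protein_pmol", "competitor_excess", "volume_ul")) {
    lay[[col]] <- .fmt_num(lay[[col]])
  }
  for (col in names(lay)) {
    lay[[col]][is.na(lay[[col]])] <- ""
  }
  utils::write.csv(lay, layout_path, row.names = FALSE, quote = TRUE)

  sc <- plate$scans[, .scan_cols, drop = FALSE]
  sc$scan_index <- as.integer(sc$scan_index)
  sc$point_row <- as.integer(sc$point_row)
  sc$point_col <- as.integer(sc$point_col)
  sc$intensity <- .fmt_num(sc$intensity)
  utils::write.csv(sc, scans_path, row.names = FALSE, quote = TRUE)

  c(layout = layout_path, scans = scans_path)
}

#' Extract one scan of one well as an intensity matrix
#'
#' @param plate A \code{pife_plate}.
#' @param well_id Well label.
#' @param scan_index Scan number (1-3).
#' @return grid_size x grid_size numeric matrix, or NULL when the scan is
#'   absent for that well.
#' @export
scan_grid <- function(plate, well_id, scan_index) {
  sc <- plate$scans
  rows <- sc$well_id == well_id & sc$scan_index == scan_index
  if (!any(rows)) return(NULL)
  sub <- sc[rows, , drop = FALSE]
  g <- max(sub$point_row)
  m <- matrix(NA_real_, g, g)
  m[cbind(sub$point_row, sub$point_col)] <- sub$intensity
  m
}
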