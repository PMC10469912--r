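# Cohort-table and landmark-file I/O.
#
# Cohort table: CSV with header
#   patient_id,photo_id,side,age,gender,group,genotype_class,marx_grade,landmark_file
# Landmark files: JSON {"version": 1, "side": ..., "points": [[x, y], ...]}
# or a delimited fallback of 41 "x<TAB>y" lines.

cohort_columns <- c("patient_id", "photo_id", "side", "age", "gender",
                    "group", "genotype_class", "marx_grade", "landmark_file")

#' Read and validate a cohort table
#'
#' Reads a delimited cohort table, loads any referenced landmark files and
#' validates every record: sides and groups from their fixed vocabularies,
#' ages non-negative, Marx grades 0-4, unique photo ids, landmarks present if
#' and only if the grade is 0-I (grade II-IV ears lack the structures needed
#' for annotation), genotype classes other than `none` only in the MFDM
#' group, and — for validation cohorts — at most one photograph per patient
#' and side. Violations are reported with the offending row numbers.
#'
#' @param path CSV file path.
#' @param template template used to validate landmark files.
#' @param role `"training"` or `"validation"`.
#' @return A cohort tibble (same shape as [simulate_cohort()] output).
#' @export
read_cohort_table <- function(path, template = default_template(),
                              role = c("training", "validation")) {
  role <- match.arg(role)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(setdiff(cohort_columns, "landmark_file"), names(tbl))
  if (length(missing_cols) > 0)
    stop("cohort table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"landmark_file" %in% names(tbl)) tbl$landmark_file <- NA_character_

  err <- function(rows, msg) {
    stop(sprintf("invalid cohort rows [%s]: %s",
                 paste(utils::head(rows, 10), collapse = ", "), msg),
         call. = FALSE)
  }
  n <- nrow(tbl)
  rowno <- seq_len(n)
  bad <- rowno[!tbl$side %in% c("left", "right")]
  if (length(bad)) err(bad, "side must be 'left' or 'right'")
  bad <- rowno[!tbl$gender %in% c("female", "male")]
  if (length(bad)) err(bad, "gender must be 'female' or 'male'")
  bad <- rowno[!tbl$group %in% sim_groups]
  if (length(bad)) err(bad, "unknown diagnostic group")
  bad <- rowno[!is.finite(tbl$age) | tbl$age < 0]
  if (length(bad)) err(bad, "age must be a finite value >= 0")
  bad <- rowno[!tbl$marx_grade %in% 0:4]
  if (length(bad)) err(bad, "marx_grade must be an integer in 0-4")
  gt <- c("none", "splice", "frameshift", "nonsense", "deletion")
  bad <- rowno[!tbl$genotype_class %in% gt]
  if (length(bad)) err(bad, "unknown genotype_class")
  bad <- rowno[tbl$genotype_class != "none" & tbl$group != "MFDM"]
  if (length(bad)) err(bad, "genotype_class other than 'none' outside MFDM")
  dup <- duplicated(tbl$photo_id)
  if (any(dup)) err(rowno[dup], "duplicate photo_id")
  has_file <- !is.na(tbl$landmark_file) & nzchar(tbl$landmark_file)
  bad <- rowno[tbl$marx_grade >= 2 & has_file]
  if (length(bad)) err(bad, "grade II-IV ears cannot carry landmarks")
  bad <- rowno[tbl$marx_grade <= 1 & !has_file]
  if (length(bad)) err(bad, "grade 0-I ears must reference a landmark file")
  if (role == "validation") {
    key <- paste(tbl$patient_id, tbl$side)
    if (anyDuplicated(key))
      err(rowno[duplicated(key)],
          "validation cohorts allow one photograph per patient and side")
  }

  dir <- dirname(path)
  tbl$landmarks <- purrr::map2(tbl$landmark_file, tbl$side, function(f, s) {
    if (is.na(f) || !nzchar(f)) return(NULL)
    fp <- if (file.exists(f)) f else file.path(dir, f)
    lm <- read_landmarks(fp, template)
    lm$side <- s
    lm
  })
  tbl$marx_grade <- as.integer(tbl$marx_grade)
  out <- tibble::as_tibble(tbl[, c(setdiff(cohort_columns, "landmark_file"),
                                   "landmarks")])
  attr(out, "role") <- role
  out
}

#' Write a cohort to a directory
#'
#' Writes the cohort CSV plus one landmark JSON file per annotated ear,
#' the inverse of [read_cohort_table()].
#'
#' @param cohort cohort tibble with a `landmarks` list-column.
#' @param dir output directory (created if needed).
#' @return The CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lm_dir <- file.path(dir, "landmarks")
  dir.create(lm_dir, showWarnings = FALSE)
  files <- purrr::map2_chr(cohort$landmarks, cohort$photo_id, function(lm, id) {
    if (is.null(lm)) return(NA_character_)
    f <- file.path("landmarks", paste0(id, ".json"))
    write_landmarks(lm, file.path(dir, f))
    f
  })
  tab <- cohort[, setdiff(cohort_columns, "landmark_file")]
  tab$landmark_file <- files
  csv <- file.path(dir, "cohort.csv")
  readr::write_csv(tab, csv)
  invisible(csv)
}

#' Read a landmark file
#'
#' Accepts the JSON dialect (`{"version":1, "points": [[x,y], ...]}`) or a
#' two-column delimited fallback of one `x<TAB>y` line per point. Point order
#' follows the template order.
#'
#' @param path file path; format chosen by `.json` extension or content.
#' @param template an [default_template()] object.
#' @return An [ear_landmarks()] object (side defaults to `"right"` unless the
#'   JSON carries a `side` field).
#' @export
read_landmarks <- function(path, template = default_template()) {
  if (!file.exists(path))
    stop("landmark file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE) ||
    grepl("^\\s*\\{", first)
  side <- "right"
  if (is_json) {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    pts <- obj$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    pts <- as.matrix(pts)
    if (!is.null(obj$side)) side <- obj$side
  } else {
    pts <- as.matrix(utils::read.table(path, header = FALSE,
                                       col.names = c("x", "y")))
  }
  n <- length(template$point_names)
  if (!is.numeric(pts) || is.null(dim(pts)) || ncol(pts) != 2L)
    stop("landmark file must contain two columns (x, y): ", path, call. = FALSE)
  if (nrow(pts) != n)
    stop(sprintf("landmark file %s has %d points, expected %d.",
                 path, nrow(pts), n), call. = FALSE)
  if (!all(is.finite(pts)))
    stop("non-finite coordinate in landmark file: ", path, call. = FALSE)
  ear_landmarks(pts, side = side, template = template)
}

#' Write a landmark file
#'
#' @param landmarks an [ear_landmarks()] object.
#' @param path output path; `.json` writes the JSON dialect, anything else
#'   the tab-delimited fallback.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "ear_landmarks"))
  pts <- unname(landmarks$points)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(version = 1L, side = landmarks$side, points = pts),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    utils::write.table(format(pts, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
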