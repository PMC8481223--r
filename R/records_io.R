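#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

#' Age, sex and flank codes used in photo-record annotations
#'
#' Age classes follow the field convention for spiral-horned antelope:
#' `AD` adults (three or more years), `2Y` and `1Y` subadults, `JUV`
#' juveniles up to one year, `UNK` animals whose age could not be judged.
#' Sex is `M`, `F` or `U` (unspecified). The flank visible in the images is
#' `L`, `R`, `BOTH` or `NONE`; individual identification from coat pattern
#' requires a usable flank, so an `individual_id` implies a side other than
#' `NONE`.
#'
#' @name annotation-codes
#' @keywords internal
AGE_CODES <- c("AD", "2Y", "1Y", "JUV", "UNK")

#' @rdname annotation-codes
#' @keywords internal
SEX_CODES <- c("M", "F", "U")

#' @rdname annotation-codes
#' @keywords internal
SIDE_CODES <- c("L", "R", "BOTH", "NONE")

PHOTO_COLS <- c("image_id", "camera_id", "timestamp",
                "age_class", "sex", "individual_id", "side")

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  trimws(x)
}

parse_timestamp <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in formats) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  out
}

#' Read a photo-record table
#'
#' Reads the survey's interchange CSV: one row per annotated animal per
#' image, columns `image_id, camera_id, timestamp, age_class, sex,
#' individual_id, side`. A row whose annotation fields are all blank stands
#' for an image with no annotatable animal; an animal of unknown age must be
#' written explicitly with `age_class = "UNK"`. Timestamps are naive local
#' time in ISO-8601 (`YYYY-MM-DDTHH:MM[:SS]` or with a space); the day
#' boundary is local midnight.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the columns above, `timestamp` as POSIXct, sorted
#'   by (`camera_id`, `timestamp`); annotation blanks become `NA`.
#' @details Unknown extra columns are dropped with a warning. The reader
#'   rejects: unparseable timestamps, age/sex/side codes outside the
#'   documented sets, an `individual_id` without a visible flank, and an
#'   `image_id` that reappears with a different camera or timestamp.
#' @seealso [write_photo_records()], [aggregate_events()]
#' @export
read_photo_records <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(PHOTO_COLS, names(raw))
  if (length(missing)) {
    ct_stop("photo-record file is missing column(s): %s",
            paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), PHOTO_COLS)
  if (length(extra)) {
    ct_warn("ignoring unknown column(s): %s", paste(extra, collapse = ", "))
  }
  rec <- as_tibble(raw[PHOTO_COLS])
  for (col in setdiff(PHOTO_COLS, "timestamp")) rec[[col]] <- blank_to_na(rec[[col]])
  validate_photo_records(rec)
}

#' Validate and normalise an in-memory photo-record table
#'
#' Applies the same checks as [read_photo_records()] to a data frame built
#' in code, returning it sorted by (`camera_id`, `timestamp`).
#'
#' @param rec Data frame with the photo-record columns.
#' @return A validated tibble.
#' @export
validate_photo_records <- function(rec) {
  rec <- as_tibble(rec)[PHOTO_COLS]
  if (!inherits(rec$timestamp, "POSIXct")) {
    orig <- blank_to_na(as.character(rec$timestamp))
    ts <- parse_timestamp(orig)
    bad <- which(is.na(ts))
    if (length(bad)) {
      ct_stop("malformed or missing timestamp in row(s): %s",
              paste(utils::head(bad, 5), collapse = ", "))
    }
    rec$timestamp <- ts
  }
  check_codes <- function(x, codes, what) {
    bad <- which(!is.na(x) & !(x %in% codes))
    if (length(bad)) {
      ct_stop("unknown %s code %s in row(s): %s (allowed: %s)",
              what, paste(unique(x[bad]), collapse = ", "),
              paste(utils::head(bad, 5), collapse = ", "),
              paste(codes, collapse = ", "))
    }
  }
  check_codes(rec$age_class, AGE_CODES, "age")
  check_codes(rec$sex, SEX_CODES, "sex")
  check_codes(rec$side, SIDE_CODES, "side")
  bad_side <- which(!is.na(rec$individual_id) &
                      (is.na(rec$side) | rec$side == "NONE"))
  if (length(bad_side)) {
    ct_stop("individual_id without a visible flank (side L/R/BOTH) in row(s): %s",
            paste(utils::head(bad_side, 5), collapse = ", "))
  }
  if (any(is.na(rec$image_id)) || any(is.na(rec$camera_id))) {
    ct_stop("image_id and camera_id must be non-blank in every row")
  }
  key <- paste(rec$camera_id, format(rec$timestamp, "%Y-%m-%d %H:%M:%S"))
  dup <- tapply(key, rec$image_id, function(k) length(unique(k)) > 1L)
  if (any(dup)) {
    ct_stop("image_id reused across cameras or timestamps: %s",
            paste(utils::head(names(dup)[dup], 5), collapse = ", "))
  }
  rec[order(rec$camera_id, rec$timestamp, rec$image_id), ]
}

#' Write a photo-record table
#'
#' Inverse of [read_photo_records()]: writes the interchange CSV with
#' ISO-8601 timestamps so that a read-back reproduces the records
#' field-by-field.
#'
#' @param rec Photo-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_photo_records <- function(rec, path) {
  out <- rec[PHOTO_COLS]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a detector (camera-trap) layout
#'
#' Columns `detector_id, x, y` and optional `zone`; coordinates are planar
#' projected metres (UTM-like). One row per detector.
#'
#' @param path Path to a CSV file.
#' @return Tibble `detector_id, x, y, zone` (zone `NA` when absent).
#' @export
read_detectors <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  validate_detectors(raw)
}

#' Validate a detector layout built in code
#'
#' @param det Data frame with columns `detector_id, x, y` and optional `zone`.
#' @return Validated tibble with a `zone` column.
#' @export
validate_detectors <- function(det) {
  need <- c("detector_id", "x", "y")
  missing <- setdiff(need, names(det))
  if (length(missing)) {
    ct_stop("detector file is missing column(s): %s", paste(missing, collapse = ", "))
  }
  det <- as_tibble(det)
  det$detector_id <- as.character(det$detector_id)
  if (!("zone" %in% names(det))) det$zone <- NA_character_
  det <- det[c("detector_id", "x", "y", "zone")]
  det$x <- suppressWarnings(as.numeric(det$x))
  det$y <- suppressWarnings(as.numeric(det$y))
  if (any(!is.finite(det$x)) || any(!is.finite(det$y))) {
    ct_stop("non-numeric or non-finite detector coordinate(s) for: %s",
            paste(det$detector_id[!is.finite(det$x) | !is.finite(det$y)],
                  collapse = ", "))
  }
  if (anyDuplicated(det$detector_id)) {
    ct_stop("duplicate detector id(s): %s",
            paste(unique(det$detector_id[duplicated(det$detector_id)]),
                  collapse = ", "))
  }
  det
}

#' Write a detector layout
#' @param det Detector tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detectors <- function(det, path) {
  out <- det
  if (all(is.na(out$zone))) out$zone <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Expand deployment intervals to per-camera deployed days
#'
#' Deployment intervals are half-open `[start, end)` dates, so a camera
#' collected on its start date but not on its end date; this avoids double
#' counting when intervals abut.
#'
#' @param deployments Data frame `detector_id, start, end` (Dates or
#'   ISO date strings); multiple rows per camera allowed but intervals of
#'   one camera must not overlap.
#' @return Tibble `detector_id, date` with one row per deployed camera-day.
#' @export
deployment_days <- function(deployments) {
  dep <- as_tibble(deployments)
  dep$start <- as.Date(dep$start)
  dep$end <- as.Date(dep$end)
  if (any(is.na(dep$start)) || any(is.na(dep$end)) || any(dep$end < dep$start)) {
    ct_stop("deployment intervals must be valid [start, end) date ranges")
  }
  for (id in unique(dep$detector_id)) {
    iv <- dep[dep$detector_id == id, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      ct_stop("overlapping deployment intervals for detector %s", id)
    }
  }
  days <- lapply(seq_len(nrow(dep)), function(i) {
    if (dep$end[i] == dep$start[i]) return(NULL)
    tibble(detector_id = as.character(dep$detector_id[i]),
           date = seq(dep$start[i], dep$end[i] - 1L, by = "day"))
  })
  do.call(rbind, days)
}

#' Build a survey-effort calendar under a minimum-operational-fraction filter
#'
#' A calendar day enters the effort total only when the fraction of deployed
#' cameras that were actually working that day is at least `min_fraction`
#' (0.75 in the source survey protocol). Per-camera operational days are then
#' counted over retained days only, and total effort is their sum.
#'
#' @param deployments Data frame `detector_id, start, end` of deployment
#'   intervals (half-open dates).
#' @param min_fraction Minimum proportion of deployed cameras working for a
#'   day to be retained; in `[0, 1]`, default 0.75.
#' @param operational Optional data frame `detector_id, date` of camera-days
#'   on which each camera actually worked. Default: every deployed day.
#'   Must be a subset of the deployed days.
#' @return An object of class `survey_effort`: a list with
#'   \describe{
#'     \item{days}{tibble `date, n_deployed, n_operational, retained`}
#'     \item{camera_days}{tibble `detector_id, days` over retained days}
#'     \item{total_days}{total operational camera-days over retained days}
#'     \item{min_fraction}{the filter used}
#'   }
#' @examples
#' dep <- data.frame(detector_id = c("A", "B"),
#'                   start = "2018-01-09", end = "2018-01-12")
#' effort_calendar(dep, min_fraction = 0)$total_days # 6
#' @export
effort_calendar <- function(deployments, min_fraction = 0.75, operational = NULL) {
  check_prob(min_fraction, "min_fraction")
  dd <- deployment_days(deployments)
  if (is.null(dd) || nrow(dd) == 0L) ct_stop("empty deployment set")
  if (is.null(operational)) {
    op <- dd
  } else {
    op <- as_tibble(operational)
    op$detector_id <- as.character(op$detector_id)
    op$date <- as.Date(op$date)
    key_dd <- paste(dd$detector_id, dd$date)
    key_op <- paste(op$detector_id, op$date)
    if (!all(key_op %in% key_dd)) {
      ct_stop("operational days must be a subset of deployed days (%d stray day(s))",
              sum(!(key_op %in% key_dd)))
    }
    op <- op[!duplicated(key_op), c("detector_id", "date")]
  }
  all_dates <- sort(unique(dd$date))
  n_dep <- as.integer(table(factor(dd$date, levels = as.character(all_dates))))
  n_op <- as.integer(table(factor(op$date, levels = as.character(all_dates))))
  retained <- n_op / n_dep >= min_fraction
  days <- tibble(date = all_dates, n_deployed = n_dep,
                 n_operational = n_op, retained = retained)
  op_kept <- op[op$date %in% all_dates[retained], ]
  ids <- sort(unique(dd$detector_id))
  cam <- tibble(detector_id = ids,
                days = as.integer(table(factor(op_kept$detector_id, levels = ids))))
  structure(list(days = days, camera_days = cam,
                 total_days = sum(cam$days), min_fraction = min_fraction),
            class = "survey_effort")
}

#' @export
print.survey_effort <- function(x, ...) {
  cat(sprintf(
    "Survey effort: %d camera-days over %d retained days (of %d; min fraction %.2f), %d cameras\n",
    x$total_days, sum(x$days$retained), nrow(x$days), x$min_fraction,
    nrow(x$camera_days)))
  invisible(x)
}

#' Restrict a survey-effort calendar to a subset of cameras
#'
#' Keeps the day filter already applied (days are not re-filtered, matching
#' the survey protocol in which the 75% rule is park-wide) and recounts
#' per-camera days and the total for the subset.
#'
#' @param effort A `survey_effort` object.
#' @param detector_ids Character vector of camera ids to keep.
#' @return A `survey_effort` object for the subset.
#' @export
subset_effort <- function(effort, detector_ids) {
  stopifnot(inherits(effort, "survey_effort"))
  cam <- effort$camera_days
  cam <- cam[cam$detector_id %in% detector_ids, ]
  structure(list(days = effort$days, camera_days = cam,
                 total_days = sum(cam$days), min_fraction = effort$min_fraction),
            class = "survey_effort")
}
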