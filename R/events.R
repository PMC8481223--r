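#' The eleven age-sex tally categories
#'
#' Order used throughout: adult males/females/unsexed, two-year-olds,
#' one-year-olds (each by sex), juveniles pooled across sex, and animals of
#' unknown age. Juveniles are tallied as one class regardless of sex because
#' calves can rarely be sexed from images; `UNK` stays its own class and
#' never enters sexed ratios.
#'
#' @export
CT_CATEGORIES <- c("ADM", "ADF", "ADU", "2YM", "2YF", "2YU",
                   "1YM", "1YF", "1YU", "JUV", "UNK")

#' Map age and sex annotations to a tally category
#'
#' @param age_class,sex Character vectors of annotation codes (`NA` allowed).
#' @return Character vector of categories; `NA` where the row carries no
#'   animal (all-blank annotation).
#' @examples
#' annotation_category(c("AD", "JUV", "UNK", "2Y"), c("M", "U", NA, NA))
#' @export
annotation_category <- function(age_class, sex) {
  out <- rep(NA_character_, length(age_class))
  has_animal <- !is.na(age_class)
  out[has_animal & age_class == "JUV"] <- "JUV"
  out[has_animal & age_class == "UNK"] <- "UNK"
  plain <- has_animal & !(age_class %in% c("JUV", "UNK"))
  sx <- ifelse(is.na(sex) | sex == "U", "U", sex)
  out[plain] <- paste0(age_class[plain], sx[plain])
  out
}

#' Assign photo records to independent detection events
#'
#' Within a camera, a record opens a new event when its timestamp is at
#' least `gap_min` minutes after the *previous record* at that camera
#' (rolling gap), so a herd lingering in front of a camera stays one event
#' however long the total span. Events never span cameras.
#'
#' @param records Photo-record tibble (see [read_photo_records()]); must be
#'   time-sorted within each camera — unsorted input is an error, never
#'   silently re-sorted.
#' @param gap_min Independence gap in minutes (> 0); default 60.
#' @return `records` with an `event_id` column (`<camera>_<k>`).
#' @export
event_assignments <- function(records, gap_min = 60) {
  if (!is.numeric(gap_min) || length(gap_min) != 1L || gap_min <= 0) {
    ct_stop("`gap_min` must be a single positive number of minutes")
  }
  rec <- tibble::as_tibble(records)
  rec$event_id <- NA_character_
  for (cam in unique(rec$camera_id)) {
    i <- which(rec$camera_id == cam)
    ts <- as.numeric(rec$timestamp[i])
    if (is.unsorted(ts)) {
      ct_stop("records for camera %s are not time-sorted; sort within cameras first",
              cam)
    }
    new_event <- c(TRUE, diff(ts) >= gap_min * 60)
    rec$event_id[i] <- sprintf("%s_%d", cam, cumsum(new_event))
  }
  rec
}

#' Minimum herd composition of one event
#'
#' Per category, the event-level count is the larger of (a) the maximum
#' number of animals of that category visible in any single image and
#' (b) the number of distinct identified individuals of that category seen
#' across the event's images. Group size is the sum over categories — a
#' "minimum group size", since animals outside the frame are never counted.
#'
#' @param event_records Photo-record rows of a single event.
#' @return Named integer vector over [CT_CATEGORIES].
#' @export
event_composition <- function(event_records) {
  rec <- event_records
  cat <- annotation_category(rec$age_class, rec$sex)
  keep <- !is.na(cat)
  counts <- setNames(integer(length(CT_CATEGORIES)), CT_CATEGORIES)
  if (!any(keep)) return(counts)
  rec <- rec[keep, ]
  cat <- cat[keep]
  per_image <- table(factor(cat, levels = CT_CATEGORIES), rec$image_id)
  max_simul <- apply(per_image, 1L, max)
  has_id <- !is.na(rec$individual_id)
  n_ids <- vapply(CT_CATEGORIES, function(cc) {
    length(unique(rec$individual_id[has_id & cat == cc]))
  }, integer(1))
  pmax(as.integer(max_simul), n_ids) |> setNames(CT_CATEGORIES)
}

#' Aggregate photo records into independent detection events
#'
#' Applies the rolling independence gap of [event_assignments()] and
#' summarises each event: time span, image count, minimum herd composition
#' ([event_composition()]), group size and the identified individuals.
#'
#' @inheritParams event_assignments
#' @return Tibble with one row per event: `event_id, camera_id, start, end,
#'   year, n_images, group_size`, one integer column per category in
#'   [CT_CATEGORIES], and `ids` (semicolon-joined individual ids).
#' @examples
#' rec <- tibble::tibble(
#'   image_id = c("i1", "i2"), camera_id = "c1",
#'   timestamp = as.POSIXct(c("2018-02-01 16:00", "2018-02-01 16:59"), tz = "UTC"),
#'   age_class = "AD", sex = "F", individual_id = NA, side = NA)
#' aggregate_events(rec)   # one event: 59 min < 60 min gap
#' @export
aggregate_events <- function(records, gap_min = 60) {
  rec <- event_assignments(records, gap_min = gap_min)
  ev_ids <- unique(rec$event_id)
  rows <- lapply(ev_ids, function(ev) {
    er <- rec[rec$event_id == ev, ]
    comp <- event_composition(er)
    ids <- sort(unique(er$individual_id[!is.na(er$individual_id)]))
    out <- tibble::tibble(
      event_id = ev,
      camera_id = er$camera_id[1],
      start = min(er$timestamp),
      end = max(er$timestamp),
      year = as.integer(format(min(er$timestamp), "%Y")),
      n_images = length(unique(er$image_id)),
      group_size = sum(comp),
      ids = paste(ids, collapse = ";"))
    for (cc in CT_CATEGORIES) out[[cc]] <- comp[[cc]]
    out
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$camera_id, ev$start), ]
}

#' Trapping rate per 100 camera-days
#'
#' A relative abundance index: `100 * n_events / effort_days`.
#'
#' @param n_events Number of independent detection events.
#' @param effort A `survey_effort` object or a positive number of
#'   operational camera-days.
#' @return Events per 100 camera-days.
#' @examples
#' trapping_rate(32, 1328) # 2.41 per 100 camera-days
#' @export
trapping_rate <- function(n_events, effort) {
  days <- if (inherits(effort, "survey_effort")) effort$total_days else effort
  if (!is.numeric(days) || length(days) != 1L || days <= 0) {
    ct_stop("effort must be positive (got %s camera-days)", format(days))
  }
  100 * n_events / days
}

#' Naive occupancy
#'
#' Fraction of camera sites with at least one detection, uncorrected for
#' imperfect detection (one camera = one site).
#'
#' @param detected_sites Character vector (or set) of sites with detections.
#' @param all_sites Character vector of all surveyed sites (non-empty).
#' @return Proportion in `[0, 1]`.
#' @export
naive_occupancy <- function(detected_sites, all_sites) {
  all_sites <- unique(as.character(all_sites))
  detected_sites <- unique(as.character(detected_sites))
  if (length(all_sites) == 0L) ct_stop("`all_sites` must be non-empty")
  stray <- setdiff(detected_sites, all_sites)
  if (length(stray)) {
    ct_stop("detected site(s) not in the site list: %s", paste(stray, collapse = ", "))
  }
  length(detected_sites) / length(all_sites)
}

#' Detection summary for the whole survey or one zone
#'
#' @param events Event tibble from [aggregate_events()].
#' @param effort A `survey_effort` object covering the cameras in scope.
#' @param detectors Detector tibble (with `zone` column for zone scopes).
#' @param zone Optional zone label; default `NULL` summarises the whole
#'   survey. Unknown zones are an error.
#' @return One-row tibble `scope, n_events, effort_days, trapping_rate,
#'   naive_occupancy`.
#' @export
detection_summary <- function(events, effort, detectors, zone = NULL) {
  det <- validate_detectors(detectors)
  if (!is.null(zone)) {
    if (!(zone %in% det$zone)) ct_stop("unknown zone: %s", zone)
    det <- det[!is.na(det$zone) & det$zone == zone, ]
    effort <- subset_effort(effort, det$detector_id)
    scope <- zone
  } else {
    scope <- "survey"
  }
  ev <- events[events$camera_id %in% det$detector_id, ]
  n_events <- nrow(ev)
  occ <- naive_occupancy(unique(ev$camera_id), det$detector_id)
  rate <- if (n_events == 0L && effort$total_days == 0) 0 else
    trapping_rate(n_events, effort)
  tibble::tibble(scope = scope, n_events = n_events,
                 effort_days = effort$total_days,
                 trapping_rate = rate, naive_occupancy = occ)
}

#' @rdname detection_summary
#' @export
zone_summary <- function(events, effort, detectors, zone) {
  detection_summary(events, effort, detectors, zone = zone)
}

#' Write the events table
#'
#' @param events Event tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%S")
  out$end <- format(out$end, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
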