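#' Published Niokolo Koba herd-composition tallies
#'
#' The per-year totals and right-side identification counts of the eleven
#' age-sex categories for the 2017 and 2018 Niokolo Koba camera-trap
#' surveys, packaged as a fixture so the demographic arithmetic can be run
#' without the (unreleased) raw photo records. Group statistics for these
#' tallies are over 16 events (2017) and 32 events (2018).
#'
#' @return Tibble `year, category, n, n_id_right`.
#' @seealso [table2_counts()], [table2_n_events()]
#' @export
niokolo_table2 <- function() {
  path <- system.file("extdata", "table2_composition.csv", package = "ctdemog")
  tbl <- tibble::as_tibble(utils::read.csv(path))
  tbl$category <- factor(tbl$category, levels = CT_CATEGORIES)
  tbl[order(tbl$year, tbl$category), ]
}

#' @rdname niokolo_table2
#' @param year `2017` or `2018`.
#' @export
table2_counts <- function(year) {
  tbl <- niokolo_table2()
  tbl <- tbl[tbl$year == year, ]
  if (nrow(tbl) == 0L) ct_stop("no tallies for year %s", format(year))
  setNames(tbl$n, as.character(tbl$category))[CT_CATEGORIES]
}

#' @rdname niokolo_table2
#' @export
table2_n_events <- function(year) {
  c(`2017` = 16L, `2018` = 32L)[[as.character(year)]]
}

#' Validate a category-count vector
#'
#' @param counts Named numeric vector covering all of [CT_CATEGORIES]
#'   (extra names are an error); non-negative.
#' @return The counts, ordered as [CT_CATEGORIES].
#' @export
as_category_counts <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1L)
    counts <- unlist(counts[intersect(names(counts), CT_CATEGORIES)])
  }
  missing <- setdiff(CT_CATEGORIES, names(counts))
  if (length(missing)) ct_stop("missing categories: %s", paste(missing, collapse = ", "))
  extra <- setdiff(names(counts), CT_CATEGORIES)
  if (length(extra)) ct_stop("unknown categories: %s", paste(extra, collapse = ", "))
  if (any(counts < 0)) ct_stop("category counts must be non-negative")
  counts[CT_CATEGORIES]
}

#' Tally event compositions into category counts
#'
#' Sums the per-event minimum herd compositions, overall or per year.
#' Conservation: the total equals the sum of event group sizes.
#'
#' @param events Event tibble from [aggregate_events()].
#' @param by_year Split by calendar year of the event start?
#' @return Tibble with `year` (`"all"` when pooled), one column per
#'   category, and `total`.
#' @export
tally <- function(events, by_year = FALSE) {
  if (nrow(events) == 0L) ct_stop("no events to tally")
  groups <- if (by_year) split(events, events$year) else list(all = events)
  rows <- lapply(names(groups), function(y) {
    ev <- groups[[y]]
    counts <- vapply(CT_CATEGORIES, function(cc) sum(ev[[cc]]), numeric(1))
    out <- tibble::tibble(year = y)
    for (cc in CT_CATEGORIES) out[[cc]] <- counts[[cc]]
    out$total <- sum(counts)
    out
  })
  do.call(rbind, rows)
}

# pooled class and sex totals used by several summaries
class_totals <- function(counts) {
  counts <- as_category_counts(counts)
  list(
    JUV = counts[["JUV"]],
    Y1 = counts[["1YM"]] + counts[["1YF"]] + counts[["1YU"]],
    Y2 = counts[["2YM"]] + counts[["2YF"]] + counts[["2YU"]],
    AD = counts[["ADM"]] + counts[["ADF"]] + counts[["ADU"]],
    UNK = counts[["UNK"]],
    M = counts[["ADM"]] + counts[["2YM"]] + counts[["1YM"]],
    F = counts[["ADF"]] + counts[["2YF"]] + counts[["1YF"]],
    SUBM = counts[["2YM"]] + counts[["1YM"]],
    SUBF = counts[["2YF"]] + counts[["1YF"]]
  )
}

#' Sex ratio (males per female)
#'
#' `overall` pools all sexed animals (adults and subadults; juveniles and
#' unknowns carry no sex information here); `adult` uses adults only.
#' The reported ratio is rounded half-up to one decimal, the field's
#' printing convention; the exact value is also returned.
#'
#' @param counts Category counts (see [as_category_counts()]).
#' @param scope `"overall"` or `"adult"`.
#' @return One-row tibble `scope, n_m, n_f, ratio, ratio_1dp`.
#' @examples
#' sex_ratio(table2_counts(2017), "adult") # 12/17 -> 0.7
#' @export
sex_ratio <- function(counts, scope = c("overall", "adult")) {
  scope <- match.arg(scope)
  ct <- class_totals(counts)
  counts <- as_category_counts(counts)
  n_m <- if (scope == "overall") ct$M else counts[["ADM"]]
  n_f <- if (scope == "overall") ct$F else counts[["ADF"]]
  if (n_f == 0) ct_stop("sex ratio undefined: no females in scope '%s'", scope)
  ratio <- n_m / n_f
  tibble::tibble(scope = scope, n_m = n_m, n_f = n_f,
                 ratio = ratio, ratio_1dp = round_half_up(ratio, 1))
}

#' Age structure as percentages
#'
#' Shares of juveniles, one-year-olds, two-year-olds and adults. By default
#' animals of unknown age are excluded from the denominator (the convention
#' of published structure tables); with `include_unknown = TRUE` they form
#' their own class and enter the denominator.
#'
#' @param counts Category counts.
#' @param include_unknown Include the unknown-age class?
#' @return Tibble `class, n, pct, pct_int` (`pct` unrounded, summing to
#'   100; `pct_int` rounded half-up to integers).
#' @export
age_structure <- function(counts, include_unknown = FALSE) {
  ct <- class_totals(counts)
  n <- c(JUV = ct$JUV, `1Y` = ct$Y1, `2Y` = ct$Y2, AD = ct$AD)
  if (include_unknown) n <- c(n, UNK = ct$UNK)
  denom <- sum(n)
  if (denom == 0) ct_stop("no classified animals")
  tibble::tibble(class = names(n), n = unname(n),
                 pct = unname(100 * n / denom),
                 pct_int = unname(round_half_up(100 * n / denom)))
}

#' Adult females adjusted for unsexed adults
#'
#' Allocates the unsexed adults to sex in proportion to the observed adult
#' sex ratio: `ADF + ADU * ADF / (ADM + ADF)`.
#'
#' @param counts Category counts with `ADM + ADF > 0`.
#' @return The adjusted (real-valued) number of adult females.
#' @examples
#' adjusted_adult_females(table2_counts(2017)) # 17 + 23*17/29 = 30.48
#' @export
adjusted_adult_females <- function(counts) {
  counts <- as_category_counts(counts)
  adm <- counts[["ADM"]]; adf <- counts[["ADF"]]
  if (adm + adf == 0) ct_stop("no sexed adults")
  adf + counts[["ADU"]] * adf / (adm + adf)
}

#' Age-specific vital rates from standing age-sex counts
#'
#' Under a stationary age distribution and equal detectability across
#' classes, annual juvenile mortality is the proportional drop from the
#' juvenile to the yearling class,
#' `M_anJUV = (N_JUV - N_1Y) / N_JUV` (with `N_1Y` including unsexed
#' yearlings), and the annual adult mortalities balance the flow of sexed
#' subadults into the adult classes:
#' `M_anADF = N_SUBF * (1 - M_anJUV) / N_ADF` and likewise for males, where
#' `N_SUBF = N_2YF + N_1YF` uses sexed subadults only. The breeding rate is
#' juveniles per adjusted adult female ([adjusted_adult_females()]).
#'
#' @param counts Category counts with `N_JUV`, `N_ADM`, `N_ADF` positive.
#' @return List of class `vital_rates`: `M_anJUV, M_anADF, M_anADM`,
#'   the survival complements `S_JUV, S_ADF, S_ADM`, `ADF_adjusted`,
#'   `breeding_rate`, and the inputs `N_JUV, N_1Y, N_SUBF, N_SUBM`.
#'   If `N_1Y > N_JUV` (a sampling artifact), juvenile mortality is clamped
#'   at 0 with a warning.
#' @examples
#' vital_rates(table2_counts(2017))$S_JUV # 0.3125 -> printed 31%
#' @export
vital_rates <- function(counts) {
  counts <- as_category_counts(counts)
  ct <- class_totals(counts)
  if (ct$JUV <= 0) ct_stop("vital rates need N_JUV > 0")
  if (counts[["ADM"]] <= 0 || counts[["ADF"]] <= 0) {
    ct_stop("vital rates need adults of both sexes")
  }
  m_juv <- (ct$JUV - ct$Y1) / ct$JUV
  if (m_juv < 0) {
    ct_warn("more yearlings than juveniles (N_1Y = %d > N_JUV = %d); juvenile mortality clamped at 0",
            ct$Y1, ct$JUV)
    m_juv <- 0
  }
  m_adf <- ct$SUBF * (1 - m_juv) / counts[["ADF"]]
  m_adm <- ct$SUBM * (1 - m_juv) / counts[["ADM"]]
  adf_adj <- adjusted_adult_females(counts)
  structure(list(
    M_anJUV = m_juv, M_anADF = m_adf, M_anADM = m_adm,
    S_JUV = 1 - m_juv, S_ADF = 1 - m_adf, S_ADM = 1 - m_adm,
    ADF_adjusted = adf_adj, breeding_rate = ct$JUV / adf_adj,
    N_JUV = ct$JUV, N_1Y = ct$Y1, N_SUBF = ct$SUBF, N_SUBM = ct$SUBM
  ), class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Vital rates (stationary-age-distribution estimators)\n")
  cat(sprintf("  juvenile survival: %d%%  (N_JUV = %d, N_1Y = %d)\n",
              round_half_up(100 * x$S_JUV), x$N_JUV, x$N_1Y))
  cat(sprintf("  adult survival:    F %d%%, M %d%% (sexed subadults %d F, %d M)\n",
              round_half_up(100 * x$S_ADF), round_half_up(100 * x$S_ADM),
              x$N_SUBF, x$N_SUBM))
  cat(sprintf("  breeding rate:     %.2f juveniles per adjusted adult female (ADF_adj = %.2f)\n",
              x$breeding_rate, x$ADF_adjusted))
  invisible(x)
}

#' Group-size statistics over events
#'
#' Arithmetic mean, sample SD, range and count of the minimum group sizes,
#' after removing an explicit exclusion list of event ids (the published
#' analysis excluded a handful of events without naming them, so exclusions
#' are caller-supplied, never guessed). SD is `NA` for a single event.
#'
#' @param events Event tibble.
#' @param exclusions Character vector of `event_id`s to drop.
#' @return One-row tibble `mean, sd, min, max, n`.
#' @export
group_size_stats <- function(events, exclusions = character()) {
  ev <- events[!(events$event_id %in% exclusions), ]
  if (nrow(ev) == 0L) ct_stop("no events left after exclusions")
  sizes <- ev$group_size
  tibble::tibble(mean = mean(sizes),
                 sd = if (length(sizes) > 1L) stats::sd(sizes) else NA_real_,
                 min = min(sizes), max = max(sizes), n = length(sizes))
}

#' Classify herd type from event composition
#'
#' Based on sexed, non-juvenile animals: both sexes present gives `MIX`,
#' one sex `UNI-M`/`UNI-F`; events of a single animal are `SOLITARY`
#' whatever its sex; multi-animal events with no sexed member are
#' `UNSEXED`.
#'
#' @param events Event tibble (one or more rows).
#' @return Tibble `event_id, herd_type, group_size`.
#' @export
classify_herd <- function(events) {
  n_m <- events[["ADM"]] + events[["2YM"]] + events[["1YM"]]
  n_f <- events[["ADF"]] + events[["2YF"]] + events[["1YF"]]
  type <- ifelse(events$group_size == 1, "SOLITARY",
          ifelse(n_m > 0 & n_f > 0, "MIX",
          ifelse(n_m > 0, "UNI-M",
          ifelse(n_f > 0, "UNI-F", "UNSEXED"))))
  tibble::tibble(event_id = events$event_id, herd_type = type,
                 group_size = events$group_size)
}

#' Identification success rate for one age-sex category
#'
#' Identified animals in the category divided by the total recorded in the
#' category, pooled over all events (and hence years). Totals are the
#' event-level minimum counts; identified animals are distinct individual
#' ids per event, restricted to the requested flank.
#'
#' @param records Photo-record tibble.
#' @param category One of [CT_CATEGORIES].
#' @param gap_min Event gap in minutes (default 60).
#' @param side Flanks that count as identified: `"R"` (right side plus
#'   `BOTH`, the default, matching the side used in published tallies),
#'   `"L"`, or `"any"`.
#' @return Proportion in `[0, 1]`.
#' @export
id_success_rate <- function(records, category, gap_min = 60, side = c("R", "L", "any")) {
  side <- match.arg(side)
  if (!(category %in% CT_CATEGORIES)) ct_stop("unknown category: %s", category)
  rec <- event_assignments(records, gap_min = gap_min)
  cat <- annotation_category(rec$age_class, rec$sex)
  ok_side <- if (side == "any") !is.na(rec$individual_id) else
    !is.na(rec$individual_id) & rec$side %in% c(side, "BOTH")
  total <- 0L; ided <- 0L
  for (ev in unique(rec$event_id)) {
    i <- rec$event_id == ev
    comp <- event_composition(rec[i, ])
    total <- total + comp[[category]]
    ided <- ided + length(unique(rec$individual_id[i & ok_side & cat == category]))
  }
  if (total == 0) ct_stop("no animals recorded in category %s", category)
  ided / total
}

#' Identification success from published tally cells
#'
#' @param table2 Tibble in the shape of [niokolo_table2()].
#' @param category One of [CT_CATEGORIES].
#' @return `sum(n_id_right) / sum(n)` pooled over years.
#' @examples
#' id_success_from_table(niokolo_table2(), "ADM") # (1+11)/(12+30)
#' @export
id_success_from_table <- function(table2, category) {
  rows <- table2[table2$category == category, ]
  if (nrow(rows) == 0L || sum(rows$n) == 0) ct_stop("no animals in category %s", category)
  sum(rows$n_id_right) / sum(rows$n)
}

#' Recapture summary over identified individuals
#'
#' An individual is a recapture when it appears in two or more events.
#' Proportions are reported separately for right- and left-flank
#' identifications (`BOTH` counts for each); gaps are day differences
#' between successive events of the same individual.
#'
#' @param records Photo-record tibble with `individual_id` and `side`.
#' @param gap_min Event gap in minutes (default 60).
#' @return List with `by_side` (tibble `side, n_individuals, n_recaptured,
#'   proportion`) and `gaps` (tibble `mean, min, max, n_gaps` in days; all
#'   `NA` when there are no recaptures).
#' @export
recapture_summary <- function(records, gap_min = 60) {
  rec <- event_assignments(records, gap_min = gap_min)
  rec <- rec[!is.na(rec$individual_id), ]
  if (nrow(rec) == 0L) ct_stop("no identified individuals in the records")
  by_side <- lapply(c("R", "L"), function(s) {
    ids <- unique(rec$individual_id[rec$side %in% c(s, "BOTH")])
    n_rec <- sum(vapply(ids, function(id) {
      length(unique(rec$event_id[rec$individual_id == id])) >= 2L
    }, logical(1)))
    tibble::tibble(side = s, n_individuals = length(ids), n_recaptured = n_rec,
                   proportion = if (length(ids)) n_rec / length(ids) else NA_real_)
  })
  gaps <- unlist(lapply(unique(rec$individual_id), function(id) {
    dates <- sort(unique(as.Date(rec$timestamp[rec$individual_id == id])))
    # one date per event-day; successive-event gaps in days
    ev_dates <- sort(unique(vapply(unique(rec$event_id[rec$individual_id == id]),
                                   function(ev) min(as.Date(rec$timestamp[rec$event_id == ev &
                                                                            rec$individual_id == id])),
                                   numeric(1))))
    if (length(ev_dates) < 2L) return(NULL)
    diff(ev_dates)
  }))
  gap_tbl <- if (is.null(gaps) || length(gaps) == 0L) {
    tibble::tibble(mean = NA_real_, min = NA_real_, max = NA_real_, n_gaps = 0L)
  } else {
    tibble::tibble(mean = mean(gaps), min = min(gaps), max = max(gaps),
                   n_gaps = length(gaps))
  }
  list(by_side = do.call(rbind, by_side), gaps = gap_tbl)
}
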