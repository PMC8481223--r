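LT_CLASSES <- c("JUV", "1Y", "2Y", "AD")

#' Read a reference mortality schedule
#'
#' Columns `age_class` (JUV, 1Y, 2Y, AD), `sex` (M/F) and `qx` (annual
#' mortality in `[0, 1]`), one row per class and sex. The packaged file
#' `mortality_schedule_synthetic.csv` is an *illustrative* schedule shaped
#' like that of an unpredated fenced population; it carries no field-derived
#' numbers.
#'
#' @param path CSV path; default the packaged illustrative schedule.
#' @return Tibble `age_class, sex, qx`.
#' @export
read_mortality_schedule <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mortality_schedule_synthetic.csv",
                        package = "ctdemog")
  }
  sched <- tibble::as_tibble(utils::read.csv(path))
  need <- c("age_class", "sex", "qx")
  if (!all(need %in% names(sched))) {
    ct_stop("mortality schedule needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(sched$qx < 0 | sched$qx > 1)) ct_stop("qx must lie in [0, 1]")
  if (anyDuplicated(sched[c("age_class", "sex")])) {
    ct_stop("one qx row per (age_class, sex)")
  }
  sched
}

sched_qx <- function(sched, age, sex) {
  row <- sched[sched$age_class == age & sched$sex == sex, ]
  if (nrow(row) != 1L) ct_stop("mortality schedule has no row for (%s, %s)", age, sex)
  row$qx
}

# per-sex class counts with the chosen allocation of unsexed animals
sexed_class_counts <- function(counts, sex, unsexed = c("proportional", "sexed_only"),
                               juvenile_share = 0.5) {
  unsexed <- match.arg(unsexed)
  counts <- as_category_counts(counts)
  pick <- function(cls) {
    own <- counts[[paste0(cls, sex)]]
    if (unsexed == "sexed_only") return(own)
    other <- counts[[paste0(cls, if (sex == "M") "F" else "M")]]
    un <- counts[[paste0(cls, "U")]]
    share <- if (own + other > 0) own / (own + other) else 0.5
    own + un * share
  }
  c(JUV = unname(counts[["JUV"]] * juvenile_share),
    `1Y` = pick("1Y"), `2Y` = pick("2Y"), AD = pick("AD"))
}

#' Scenario life table anchored on observed juvenile cohorts
#'
#' Builds a one-sex life table for the age classes JUV, 1Y, 2Y, AD from
#' observed standing counts and a reference mortality schedule. Scenario
#' `"JUV+1Y"` anchors the observed JUV and 1Y classes and models 2Y by
#' projecting the yearlings forward (`n_2Y = n_1Y * (1 - qx_1Y)`);
#' scenario `"JUV+2Y"` anchors JUV and 2Y and models 1Y from the juveniles
#' (`n_1Y = n_JUV * (1 - qx_JUV)`). Recruits to adulthood are
#' `n_2Y * (1 - qx_2Y)`; under a stationary age distribution with constant
#' adult survival `s = 1 - qx_AD`, the expected standing number of adults is
#' `recruits / (1 - s) = recruits / qx_AD`. Comparing that expectation with
#' the observed adult count gives the implied adult survival via
#' [implied_adult_survival()].
#'
#' Unsexed subadults and adults are allocated to the focal sex in
#' proportion to the sexed animals of their class (`unsexed =
#' "proportional"`, the default) or dropped (`"sexed_only"`); juveniles are
#' split by `juvenile_share` (default 0.5) since calves are unsexed.
#'
#' @param counts Category counts (e.g. [table2_counts()]).
#' @param sched Mortality schedule tibble ([read_mortality_schedule()]).
#' @param scenario `"JUV+1Y"` or `"JUV+2Y"`.
#' @param sex `"M"` or `"F"`.
#' @param unsexed Allocation of unsexed animals; see Details.
#' @param juvenile_share Share of juveniles assigned to the focal sex.
#' @return Object of class `life_table`: list with `table` (tibble
#'   `age_class, n, observed, qx, survivors_next`), `scenario`, `sex`,
#'   `recruits_per_year`, `expected_N_AD`, `observed_N_AD`,
#'   `implied_adult_survival`.
#' @export
build_life_table <- function(counts, sched, scenario = c("JUV+1Y", "JUV+2Y"),
                             sex = c("M", "F"),
                             unsexed = c("proportional", "sexed_only"),
                             juvenile_share = 0.5) {
  scenario <- match.arg(scenario)
  sex <- match.arg(sex)
  n_obs <- sexed_class_counts(counts, sex, unsexed = unsexed,
                              juvenile_share = juvenile_share)
  qx <- vapply(LT_CLASSES, function(a) sched_qx(sched, a, sex), numeric(1))
  anchored <- if (scenario == "JUV+1Y") c("JUV", "1Y") else c("JUV", "2Y")
  if (any(n_obs[anchored] <= 0)) {
    ct_stop("anchor classes (%s) must have positive counts",
            paste(anchored, collapse = ", "))
  }
  n <- n_obs
  if (scenario == "JUV+1Y") {
    n[["2Y"]] <- n[["1Y"]] * (1 - qx[["1Y"]])
  } else {
    n[["1Y"]] <- n[["JUV"]] * (1 - qx[["JUV"]])
  }
  recruits <- n[["2Y"]] * (1 - qx[["2Y"]])
  if (qx[["AD"]] <= 0) {
    ct_warn("zero reference adult mortality: stationary adult expectation is unbounded")
    expected_ad <- Inf
  } else {
    expected_ad <- recruits / qx[["AD"]]
  }
  observed_ad <- n_obs[["AD"]]
  tab <- tibble::tibble(
    age_class = LT_CLASSES,
    n = unname(n[LT_CLASSES]),
    observed = LT_CLASSES %in% c(anchored, "AD"),
    qx = unname(qx[LT_CLASSES]),
    survivors_next = unname(n[LT_CLASSES] * (1 - qx[LT_CLASSES])))
  structure(list(table = tab, scenario = scenario, sex = sex,
                 recruits_per_year = unname(recruits),
                 expected_N_AD = unname(expected_ad),
                 observed_N_AD = unname(observed_ad),
                 implied_adult_survival =
                   if (observed_ad > 0)
                     implied_adult_survival(recruits, observed_ad) else NA_real_),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table, scenario %s, sex %s\n", x$scenario, x$sex))
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("  recruits/year %.2f; expected N_AD %.1f (observed %.1f); implied adult survival %.2f\n",
              x$recruits_per_year, x$expected_N_AD, x$observed_N_AD,
              x$implied_adult_survival))
  invisible(x)
}

#' Adult survival implied by stationary recruitment balance
#'
#' In a stationary population the standing adult count balances annual
#' recruitment against adult mortality: `N_AD = recruits / (1 - s)`, so
#' `s = 1 - recruits / N_AD`, clamped into `[0, 1)`. If recruits exceed the
#' adult count the implied survival is 0, flagged with a warning (the
#' population cannot be stationary with those numbers).
#'
#' @param recruits_per_year New adults per year (> 0).
#' @param N_AD Observed standing adult count (> 0).
#' @return Implied annual adult survival in `[0, 1)`.
#' @examples
#' implied_adult_survival(10, 20) # 0.5
#' @export
implied_adult_survival <- function(recruits_per_year, N_AD) {
  if (recruits_per_year <= 0) ct_stop("recruits_per_year must be positive")
  if (N_AD <= 0) ct_stop("N_AD must be positive")
  s <- 1 - recruits_per_year / N_AD
  if (s < 0) {
    ct_warn("recruits (%.2f) exceed adults (%.2f); implied survival clamped at 0",
            recruits_per_year, N_AD)
    s <- 0
  }
  s
}
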