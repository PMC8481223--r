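#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the circular
#' uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Angles in radians on `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) ct_stop("`kappa` must be non-negative")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- min(sum(ok), n - got)
      out[(got + 1):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  (mu + out) %% (2 * pi)
}

#' Parameters of a zero-truncated negative binomial with given moments
#'
#' Finds the underlying negative binomial `(mu, size)` whose
#' zero-truncated law has the requested mean and standard deviation
#' (matching moments numerically). Overdispersed group sizes with SD above
#' the mean rule out a (truncated) Poisson.
#'
#' @param mean_t,sd_t Target mean and SD of the truncated distribution.
#' @return List `mu, size, p0` of the underlying negative binomial.
#' @export
ztnb_params <- function(mean_t, sd_t) {
  if (sd_t <= sqrt(mean_t - mean_t^2 / 1e6)) {
    ct_stop("target SD too small for a zero-truncated negative binomial")
  }
  moments <- function(logpar) {
    mu <- exp(logpar[1]); size <- exp(logpar[2])
    p0 <- (size / (size + mu))^size
    m <- mu / (1 - p0)
    ex2 <- (mu + mu^2 * (1 + 1 / size)) / (1 - p0)
    c(m, sqrt(pmax(ex2 - m^2, 1e-12)))
  }
  loss <- function(logpar) sum((moments(logpar) - c(mean_t, sd_t))^2)
  opt <- stats::optim(c(log(mean_t), 0), loss, control = list(reltol = 1e-14, maxit = 2000))
  mu <- exp(opt$par[1]); size <- exp(opt$par[2])
  list(mu = mu, size = size, p0 = (size / (size + mu))^size)
}

#' Draw zero-truncated negative binomial group sizes
#'
#' @param n Number of draws.
#' @param mean_t,sd_t Mean and SD of the truncated law (see [ztnb_params()]).
#' @return Integer group sizes (>= 1).
#' @export
rztnbinom <- function(n, mean_t, sd_t) {
  par <- ztnb_params(mean_t, sd_t)
  out <- integer(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / (1 - par$p0) * 1.2) + 10
    x <- stats::rnbinom(m, mu = par$mu, size = par$size)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Lay detectors on a near-square grid
#'
#' @param n Number of detectors.
#' @param spacing Grid spacing in metres.
#' @param core_n Number of detectors, nearest the grid centroid, labelled
#'   as the `"core"` zone (the occupied core emulating a within-park
#'   hotspot); the rest are zone `"park"`. Default 10, 0 for no zones.
#' @return Detector tibble `detector_id, x, y, zone`.
#' @export
detector_grid <- function(n, spacing, core_n = 10) {
  ncol_ <- ceiling(sqrt(n))
  ij <- cbind((seq_len(n) - 1) %% ncol_, (seq_len(n) - 1) %/% ncol_)
  det <- tibble::tibble(detector_id = sprintf("CT%02d", seq_len(n)),
                        x = ij[, 1] * spacing, y = ij[, 2] * spacing,
                        zone = "park")
  if (core_n > 0) {
    ctr <- c(mean(det$x), mean(det$y))
    d <- sqrt((det$x - ctr[1])^2 + (det$y - ctr[2])^2)
    det$zone[order(d)[seq_len(min(core_n, n))]] <- "core"
  }
  det
}

#' Default configuration of the synthetic camera-trap survey
#'
#' The defaults emulate the study conditions of the source survey: 71
#' detectors on a grid with 2315 m spacing, a dry-season window of 173
#' daily occasions from 9 January, true density 0.138 animals/km2 with
#' home-range centres from a homogeneous planar Poisson process, trimodal
#' diel activity (morning, hot-afternoon and pre-midnight peaks),
#' zero-truncated negative binomial group sizes with mean 7.58 and SD 8.90,
#' age-sex composition proportional to the 2018 survey tallies, a
#' November-December birth pulse, and category-dependent individual
#' identification success. The detection function defaults to a half-normal
#' with `g0 = 0.05`, `sigma = 2000` m, a calibration that yields
#' informative capture histories at desk scale (see the methods vignette).
#'
#' @param ... Named overrides of any default element.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_detectors = 71,
    detector_spacing = 2315,
    core_n = 10,
    n_occasions = 173,
    start_date = as.Date("2018-01-09"),
    density = 0.138,
    detfn = list(kind = "HN", g0 = 0.05, sigma = 2000, z = 2.5),
    buffer = 4 * 2000,
    n_events = 49,
    activity = list(means = time_to_angle(c("09:30", "16:30", "23:30")),
                    kappa = c(2, 3, 1.5),
                    weights = c(0.30, 0.45, 0.25)),
    group_size = list(mean = 7.58, sd = 8.90),
    composition = c(ADM = 30, ADF = 32, ADU = 12, `2YM` = 15, `2YF` = 2,
                    `2YU` = 8, `1YM` = 8, `1YF` = 6, `1YU` = 8, JUV = 48,
                    UNK = 36) / 205,
    id_success = c(ADM = 0.286, ADF = 0.388, ADU = 0, `2YM` = 0.227,
                   `2YF` = 0.286, `2YU` = 0, `1YM` = 0.05, `1YF` = 0.3,
                   `1YU` = 0.077, JUV = 0.0375, UNK = 0.013),
    birth_pulse_months = c(11, 12),
    images_per_trigger = 3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) ct_stop("unknown config element(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(abs(sum(cfg$activity$weights) - 1) < 1e-8,
            all(cfg$composition >= 0), cfg$density >= 0)
  cfg$composition <- cfg$composition / sum(cfg$composition)
  cfg
}

# simulation region: detector bounding box plus the buffer on every side
sim_region <- function(detectors, buffer) {
  c(xmin = min(detectors$x) - buffer, xmax = max(detectors$x) + buffer,
    ymin = min(detectors$y) - buffer, ymax = max(detectors$y) + buffer)
}

#' Simulate home-range centres from a planar Poisson process
#'
#' The number of centres is Poisson with mean `density x area` and
#' locations are uniform over the region.
#'
#' @param detectors Detector tibble defining the region.
#' @param density Animals per km2.
#' @param buffer Region margin beyond the detector hull, metres.
#' @param seed Optional RNG seed.
#' @return Matrix of centre coordinates (metres), possibly 0 rows.
#' @export
simulate_centres <- function(detectors, density, buffer, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reg <- sim_region(detectors, buffer)
  area_km2 <- (reg["xmax"] - reg["xmin"]) * (reg["ymax"] - reg["ymin"]) / 1e6
  n <- stats::rpois(1, density * area_km2)
  cbind(x = stats::runif(n, reg["xmin"], reg["xmax"]),
        y = stats::runif(n, reg["ymin"], reg["ymax"]))
}

#' Simulate SECR detections of individuals at proximity detectors
#'
#' Each (individual, occasion, detector) triple is detected independently
#' with probability `g(distance)`; when an individual trips several
#' detectors on one occasion only the detector nearest its centre is kept,
#' so each individual is captured at most once per occasion. Detection
#' timestamps are drawn from the diel activity mixture.
#'
#' @param centres Matrix of home-range centres (metres).
#' @param detectors Detector tibble.
#' @param detfn List `kind, g0, sigma[, z]`.
#' @param n_occasions Number of daily occasions.
#' @param start_date First occasion date.
#' @param activity Activity mixture (`means`, `kappa`, `weights`) for
#'   timestamps; `NULL` for uniform times.
#' @param seed Optional RNG seed.
#' @return List with `detections` (tibble `individual, date, detector,
#'   timestamp`) and `ch` (`capthist_ct` over the full occasion calendar;
#'   `NULL` when nothing was detected).
#' @export
simulate_detections <- function(centres, detectors, detfn, n_occasions,
                                start_date = as.Date("2018-01-09"),
                                activity = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  det <- validate_detectors(detectors)
  occasions <- seq(start_date, by = "day", length.out = n_occasions)
  if (nrow(centres) == 0L || detfn$g0 == 0) {
    return(list(detections = tibble::tibble(individual = character(0),
                                            date = as.Date(character(0)),
                                            detector = character(0),
                                            timestamp = as.POSIXct(character(0), tz = "UTC")),
                ch = NULL, occasions = occasions))
  }
  G <- detection_probability(edist(centres, cbind(det$x, det$y)), detfn$kind,
                             g0 = detfn$g0, sigma = detfn$sigma,
                             z = if (detfn$kind == "HR") detfn$z else NULL)
  N <- nrow(centres); K <- nrow(det)
  rows <- vector("list", n_occasions)
  dmat <- edist(centres, cbind(det$x, det$y))
  for (s in seq_len(n_occasions)) {
    hit <- matrix(stats::runif(N * K) < G, N, K)
    ind <- which(rowSums(hit) > 0)
    if (!length(ind)) next
    kk <- vapply(ind, function(i) {
      k <- which(hit[i, ])
      k[which.min(dmat[i, k])]        # nearest-detector tie-break
    }, integer(1))
    rows[[s]] <- tibble::tibble(individual = sprintf("IND%04d", ind),
                                date = occasions[s],
                                detector = det$detector_id[kk])
  }
  dd <- do.call(rbind, rows)
  if (is.null(dd)) {
    return(list(detections = tibble::tibble(individual = character(0),
                                            date = as.Date(character(0)),
                                            detector = character(0),
                                            timestamp = as.POSIXct(character(0), tz = "UTC")),
                ch = NULL, occasions = occasions))
  }
  theta <- if (is.null(activity)) stats::runif(nrow(dd), 0, 2 * pi) else
    sample_activity(nrow(dd), activity)
  secs <- round(theta / (2 * pi) * 86400)
  dd$timestamp <- as.POSIXct(paste(dd$date), tz = "UTC") + secs
  ch <- build_capture_histories(dd[c("individual", "date", "detector")],
                                det, occasions = occasions)
  list(detections = dd, ch = ch, occasions = occasions)
}

# draw times of day (radians) from the trimodal von Mises mixture
sample_activity <- function(n, activity) {
  comp <- sample.int(length(activity$weights), n, replace = TRUE,
                     prob = activity$weights)
  theta <- numeric(n)
  for (j in seq_along(activity$weights)) {
    i <- comp == j
    if (any(i)) theta[i] <- rvonmises(sum(i), activity$means[j], activity$kappa[j])
  }
  theta
}

#' Simulate a photo-record survey with herds, annotations and identities
#'
#' Generates the record-level survey the pipeline consumes: independent
#' herd events placed at core-zone cameras on random survey days, times
#' from the trimodal activity mixture, zero-truncated negative binomial
#' group sizes, multinomial age-sex composition, per-member individual
#' identification with category-specific success (ids drawn from a
#' finite per-category pool, so recaptures arise naturally), and
#' three-image trigger sequences. Juvenile members only appear in events
#' dated after the birth-pulse window opens. The first image of each event
#' shows the whole herd (the crossing caught in full frame); later images
#' show random subsets, so the event-level minimum-group-size rule is
#' exercised.
#'
#' @param config A [sim_config()] list.
#' @param seed RNG seed (simulations are bit-reproducible given
#'   `(seed, config)`).
#' @return List with `records` (photo-record tibble), `detectors`,
#'   `truth` (true parameters, event table, population composition).
#' @export
simulate_photo_records <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  det <- detector_grid(config$n_detectors, config$detector_spacing,
                       core_n = config$core_n)
  core <- det$detector_id[det$zone == "core"]
  n_ev <- config$n_events
  # a few favoured cameras inside the core, as in a real hotspot
  cam_w <- stats::rexp(length(core))^2
  cameras <- sample(core, n_ev, replace = TRUE, prob = cam_w / sum(cam_w))
  dates <- config$start_date + sample.int(config$n_occasions, n_ev, replace = TRUE) - 1L
  theta <- sample_activity(n_ev, config$activity)
  secs <- round(theta / (2 * pi) * 86400)
  sizes <- rztnbinom(n_ev, config$group_size$mean, config$group_size$sd)
  cats <- names(config$composition)
  pool_size <- pmax(2L, round(200 * config$composition))
  pools <- lapply(seq_along(cats), function(j) {
    sprintf("%s-%03d", cats[j], seq_len(pool_size[j]))
  })
  names(pools) <- cats
  # calves are on the ground from the birth pulse through the first half-year
  after_pulse <- function(d) {
    m <- as.integer(format(d, "%m"))
    m %in% c(config$birth_pulse_months, 1:6)
  }
  all_rows <- vector("list", n_ev)
  truth_ev <- vector("list", n_ev)
  cat_totals <- setNames(integer(length(cats)), cats)
  img_counter <- 0L
  for (e in seq_len(n_ev)) {
    gs <- sizes[e]
    member_cat <- sample(cats, gs, replace = TRUE, prob = config$composition)
    cat_totals <- cat_totals + tabulate(match(member_cat, cats), nbins = length(cats))
    if (!after_pulse(dates[e])) {
      member_cat[member_cat == "JUV"] <- "UNK"
    }
    ided <- stats::runif(gs) < config$id_success[member_cat]
    member_id <- rep(NA_character_, gs)
    for (i in which(ided)) member_id[i] <- sample(pools[[member_cat[i]]], 1)
    # an individual appears once per herd
    dup <- duplicated(member_id) & !is.na(member_id)
    member_id[dup] <- NA_character_
    ided <- !is.na(member_id)
    side <- ifelse(ided, sample(c("R", "L", "BOTH"), gs, replace = TRUE,
                                prob = c(0.45, 0.35, 0.20)), NA)
    age <- ifelse(member_cat %in% c("JUV", "UNK"), member_cat,
                  substr(member_cat, 1, 2))
    sex <- ifelse(member_cat %in% c("JUV", "UNK"), "U",
                  substr(member_cat, 3, 3))
    t0 <- as.POSIXct(paste(dates[e]), tz = "UTC") + secs[e]
    n_triggers <- max(1L, ceiling(gs / 4))
    ev_rows <- vector("list", 0)
    for (tr in seq_len(n_triggers)) {
      for (im in seq_len(config$images_per_trigger)) {
        img_counter <- img_counter + 1L
        shown <- if (tr == 1L && im == 1L) rep(TRUE, gs) else stats::runif(gs) < 0.6
        if (!any(shown)) next
        ts <- t0 + (tr - 1) * 180 + (im - 1) * 12
        ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
          image_id = sprintf("IMG%06d", img_counter),
          camera_id = cameras[e],
          timestamp = ts,
          age_class = age[shown], sex = sex[shown],
          individual_id = member_id[shown],
          side = side[shown])
      }
    }
    all_rows[[e]] <- do.call(rbind, ev_rows)
    truth_ev[[e]] <- tibble::tibble(event = e, camera_id = cameras[e],
                                    date = dates[e],
                                    time_rad = theta[e], group_size = gs,
                                    n_identified = sum(ided))
  }
  records <- do.call(rbind, all_rows)
  records <- records[order(records$camera_id, records$timestamp, records$image_id), ]
  list(records = validate_photo_records(records),
       detectors = det,
       truth = list(config = config, seed = seed,
                    member_categories = cat_totals,
                    events = do.call(rbind, truth_ev)))
}

#' Simulate a full survey and optionally write it to disk
#'
#' Runs [simulate_photo_records()] and, when `dir` is given, writes
#' `records.csv`, `detectors.csv` and `truth.json`.
#'
#' @param config A [sim_config()] list.
#' @param seed RNG seed.
#' @param dir Optional output directory (created if needed).
#' @return The [simulate_photo_records()] list, invisibly when writing.
#' @export
simulate_survey <- function(config = sim_config(), seed = 1, dir = NULL) {
  sim <- simulate_photo_records(config, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_photo_records(sim$records, file.path(dir, "records.csv"))
    write_detectors(sim$detectors, file.path(dir, "detectors.csv"))
    truth <- sim$truth
    truth$config$start_date <- as.character(truth$config$start_date)
    truth$events <- as.data.frame(truth$events)
    truth$events$date <- as.character(truth$events$date)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(sim))
  }
  sim
}
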