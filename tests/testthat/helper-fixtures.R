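# Builders and independent oracles shared across the suite.
# Oracles deliberately use naive loops, never the package's vectorised path.

# photo-record tibble from minute offsets at one or more cameras
make_records <- function(minutes, camera = "c1", date = "2018-02-01",
                         age = "AD", sex = "F", id = NA_character_,
                         side = NA_character_) {
  n <- length(minutes)
  tibble::tibble(
    image_id = sprintf("%s_i%03d", camera, seq_len(n)),
    camera_id = camera,
    timestamp = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + minutes * 60,
    age_class = rep_len(age, n), sex = rep_len(sex, n),
    individual_id = rep_len(id, n), side = rep_len(side, n))
}

# brute-force chain splitting: walk the sorted times, cut at gaps >= gap_min
oracle_split_count <- function(minutes, gap_min) {
  m <- sort(minutes)
  if (length(m) == 0) return(0L)
  k <- 1L
  for (i in seq_along(m)[-1]) if (m[i] - m[i - 1] >= gap_min) k <- k + 1L
  k
}

# brute-force SECR negative log-likelihood: explicit loops over individuals,
# occasions, detectors and mask points
oracle_secr_nll <- function(ch, mask, kind, g0, sigma, z = NULL) {
  y <- ch$y; u <- ch$usage
  n <- dim(y)[1]; S <- dim(y)[2]; K <- dim(y)[3]
  w <- mask$cell_area_km2
  M <- nrow(mask$points)
  gk <- function(X, k) {
    d <- sqrt((mask$points[X, 1] - ch$detectors$x[k])^2 +
                (mask$points[X, 2] - ch$detectors$y[k])^2)
    detection_probability(d, kind, g0 = g0, sigma = sigma, z = z)
  }
  sump <- 0
  for (X in seq_len(M)) {
    pr_nodet <- 1
    for (s in seq_len(S)) for (k in seq_len(K)) {
      pr_nodet <- pr_nodet * (1 - u[k, s] * gk(X, k))
    }
    sump <- sump + (1 - pr_nodet) * w
  }
  ll <- 0
  for (i in seq_len(n)) {
    integ <- 0
    for (X in seq_len(M)) {
      pr <- 1
      for (s in seq_len(S)) for (k in seq_len(K)) {
        p <- u[k, s] * gk(X, k)
        pr <- pr * if (y[i, s, k] == 1) p else 1 - p
      }
      integ <- integ + pr * w
    }
    ll <- ll + log(integ)
  }
  -ll + n * log(sump)
}

# random small SECR instance (<= 3 detectors, <= 3 occasions, <= 9 mask points)
random_secr_instance <- function() {
  K <- sample(1:3, 1); S <- sample(1:3, 1)
  det <- tibble::tibble(detector_id = paste0("d", seq_len(K)),
                        x = stats::runif(K, 0, 2000),
                        y = stats::runif(K, 0, 2000))
  m <- sample(1:9, 1)
  mask <- structure(list(points = cbind(stats::runif(m, -500, 2500),
                                        stats::runif(m, -500, 2500)),
                         spacing = 500, cell_area_km2 = 0.25,
                         area_km2 = m * 0.25, buffer = 1000),
                    class = "habitat_mask")
  usage <- matrix(rbinom(K * S, 1, 0.8), K, S)
  n <- sample(1:4, 1)
  rows <- list()
  occ <- as.Date("2018-01-01") + seq_len(S) - 1
  for (i in seq_len(n)) {
    live <- which(usage == 1, arr.ind = TRUE)
    take <- live[sample(nrow(live), sample(1:min(3, nrow(live)), 1)), , drop = FALSE]
    rows[[i]] <- tibble::tibble(individual = paste0("i", i),
                                date = occ[take[, 2]],
                                detector = det$detector_id[take[, 1]])
  }
  dd <- unique(do.call(rbind, rows))
  ch <- build_capture_histories(dd, det, occasions = occ, usage = usage)
  list(ch = ch, mask = mask)
}

# hand-built one-point habitat mask (grid construction cannot give one cell)
point_mask <- function(x = 0, y = 0, spacing = 100) {
  structure(list(points = cbind(x, y), spacing = spacing,
                 cell_area_km2 = spacing^2 / 1e6,
                 area_km2 = spacing^2 / 1e6, buffer = spacing),
            class = "habitat_mask")
}
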