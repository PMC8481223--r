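#' Map clock times to angles on the 24-h circle
#'
#' Midnight maps to 0 and the circle runs clockwise through the day:
#' `angle = 2*pi * seconds_since_midnight / 86400`.
#'
#' @param t Times of day: POSIXct (the date part is discarded), `"HH:MM"` /
#'   `"HH:MM:SS"` strings, or numeric seconds since midnight.
#' @return Angles in radians on `[0, 2*pi)`.
#' @examples
#' time_to_angle("12:00") # pi
#' @export
time_to_angle <- function(t) {
  if (inherits(t, "POSIXct")) {
    lt <- as.POSIXlt(t)
    sec <- lt$hour * 3600 + lt$min * 60 + lt$sec
  } else if (is.character(t)) {
    parts <- strsplit(t, ":", fixed = TRUE)
    sec <- vapply(parts, function(p) {
      p <- as.numeric(p)
      if (any(is.na(p)) || length(p) < 2L) ct_stop("unparseable time of day: use HH:MM[:SS]")
      p[1] * 3600 + p[2] * 60 + if (length(p) > 2L) p[3] else 0
    }, numeric(1))
  } else {
    sec <- as.numeric(t)
  }
  if (any(sec < 0 | sec >= 86400)) ct_stop("times of day must lie in [00:00, 24:00)")
  2 * pi * sec / 86400
}

#' Format an angle on the 24-h circle as "HH:MM"
#'
#' @param theta Angles in radians.
#' @return Character "HH:MM" (minutes rounded half up).
#' @export
angle_to_hhmm <- function(theta) {
  minutes <- round_half_up(theta %% (2 * pi) / (2 * pi) * 1440) %% 1440
  sprintf("%02d:%02d", minutes %/% 60, minutes %% 60)
}

wrap_angle <- function(theta) theta %% (2 * pi)

# mean circular distance from each candidate to all sample points
circ_mean_dist <- function(candidates, theta) {
  vapply(candidates, function(a) {
    d <- abs(theta - a) %% (2 * pi)
    mean(pmin(d, 2 * pi - d))
  }, numeric(1))
}

#' Circular summary: mean direction, resultant length, CSD, median
#'
#' The mean direction `mu` is the angle of the vector mean of the unit
#' vectors; `R` is its length (0 uniform, 1 fully concentrated); the
#' circular standard deviation is `sqrt(-2 log R)`. The circular median
#' minimises the mean circular distance to the sample; ties are broken by
#' the smallest angle among minimisers (candidates are the sample points).
#'
#' @param theta Angles in radians (n >= 1), e.g. from [time_to_angle()].
#' @return Object of class `circ_summary`: list with `n`, `mu`, `R`, `csd`,
#'   `median` (radians; `mu` and `csd` are `NA` when `R` is numerically 0,
#'   signalled with a warning).
#' @examples
#' s <- circular_summary(time_to_angle(c("06:00", "18:00", "12:00")))
#' angle_to_hhmm(s$median)
#' @export
circular_summary <- function(theta) {
  theta <- wrap_angle(theta)
  n <- length(theta)
  if (n < 1L) ct_stop("need at least one angle")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12) {
    ct_warn("mean resultant length is 0; mean direction undefined")
    mu <- NA_real_; csd <- NA_real_
  } else {
    mu <- wrap_angle(atan2(S, C))
    csd <- sqrt(-2 * log(R))
  }
  dist <- circ_mean_dist(theta, theta)
  med <- min(theta[dist <= min(dist) + 1e-12])
  structure(list(n = n, mu = mu, R = R, csd = csd, median = med),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("Circular summary (n = %d)\n", x$n))
  if (is.na(x$mu)) {
    cat("  mean direction undefined (R = 0)\n")
  } else {
    cat(sprintf("  mu     = %s  (%.3f rad)\n", angle_to_hhmm(x$mu), x$mu))
    cat(sprintf("  R      = %.4f\n", x$R))
    cat(sprintf("  CSD    = %s  (%.3f rad)\n", angle_to_hhmm(x$csd), x$csd))
  }
  cat(sprintf("  median = %s  (%.3f rad)\n", angle_to_hhmm(x$median), x$median))
  invisible(x)
}

#' P-value of the Rayleigh uniformity test (series approximation)
#'
#' Zar's series refinement of the first-order `exp(-Z)` approximation:
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]`,
#' clamped into `(0, 1]`. Accurate to two decimals over the range met in
#' activity analyses.
#'
#' @param Z Rayleigh statistic `n * R^2` (>= 0).
#' @param n Sample size (>= 2).
#' @return The approximate p-value.
#' @examples
#' rayleigh_pvalue(1.32, 49) # 0.268
#' @export
rayleigh_pvalue <- function(Z, n) {
  if (n < 2) ct_stop("Rayleigh test needs n >= 2")
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Rayleigh test of circular uniformity
#'
#' Tests uniformity against a unimodal alternative via the mean resultant
#' length: `Z = n R^2`. Insensitive to multimodal departures whose modes
#' cancel (e.g. balanced bimodal activity). The p-value uses the series
#' approximation of [rayleigh_pvalue()] by default; `method = "simulate"`
#' draws the null distribution of `Z` by Monte Carlo instead.
#'
#' @param theta Angles in radians (n >= 2).
#' @param method `"series"` (default) or `"simulate"`.
#' @param nsim Number of null samples for `method = "simulate"`.
#' @return List of class `rayleigh_test` with `Z`, `p`, `n`, `method`.
#' @export
rayleigh_test <- function(theta, method = c("series", "simulate"), nsim = 1e4) {
  method <- match.arg(method)
  theta <- wrap_angle(theta)
  n <- length(theta)
  if (n < 2L) ct_stop("Rayleigh test needs n >= 2")
  R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  Z <- n * R^2
  p <- if (method == "series") {
    rayleigh_pvalue(Z, n)
  } else {
    z0 <- replicate(nsim, {
      u <- stats::runif(n, 0, 2 * pi)
      n * (mean(cos(u))^2 + mean(sin(u))^2)
    })
    (sum(z0 >= Z) + 1) / (nsim + 1)
  }
  structure(list(Z = Z, p = p, n = n, method = method), class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh uniformity test: Z = %.3f, n = %d, P = %.3g (%s)\n",
              x$Z, x$n, x$p, x$method))
  invisible(x)
}

#' Rao's spacing statistic
#'
#' With sorted angles, arc lengths `T_i` between neighbours (including the
#' wrap-around arc) and the even spacing `lambda = 360/n`,
#' `U = 0.5 * sum(|T_i - lambda|)` in degrees. `U = 0` for perfectly even
#' spacing; large `U` indicates clumping.
#'
#' @param theta Angles in radians.
#' @return `U` in degrees.
#' @export
rao_statistic <- function(theta) {
  n <- length(theta)
  a <- sort(wrap_angle(theta)) * 180 / pi
  spacings <- c(diff(a), 360 - a[n] + a[1])
  0.5 * sum(abs(spacings - 360 / n))
}

#' Critical values for Rao's spacing test
#'
#' Returns the packaged critical-value table: columns `n`, `alpha`,
#' `u_crit` (degrees). The table was generated by Monte Carlo simulation of
#' the exact null (circular spacings of `n` uniform points are `n` iid
#' exponentials normalised to 360 degrees) with 2e6 samples per `n` up to 100 (1e6 beyond), via
#' [simulate_rao_critical_values()]; see the packaged file's provenance in
#' the methods vignette. Tabulated `n`: 4-100, then 150, 200, 300, 500, 1000.
#'
#' @return Tibble `n, alpha, u_crit`.
#' @export
rao_critical_table <- function() {
  path <- system.file("extdata", "rao_critical_values_mc.csv", package = "ctdemog")
  tibble::as_tibble(utils::read.csv(path))
}

#' Monte-Carlo critical values for Rao's spacing statistic
#'
#' Simulates the null distribution of `U` for uniform circular samples using
#' the exponential-spacings representation (no sorting required) and returns
#' upper-tail quantiles. This regenerates the packaged table.
#'
#' @param n_values Integer sample sizes to tabulate.
#' @param alphas Upper-tail probabilities.
#' @param nrep Null samples per `n`.
#' @param seed Base RNG seed; each sample size uses `seed + n`, so the
#'   table can be (re)built for any subset of `n` and agree row-for-row.
#' @param chunk Matrix-element budget per block (memory control); the
#'   per-block sample count is `chunk / n`.
#' @return Tibble `n, alpha, u_crit`.
#' @export
simulate_rao_critical_values <- function(n_values, alphas = c(0.10, 0.05, 0.01, 0.001),
                                         nrep = 1e7, seed = 20260923, chunk = 1e8) {
  rows <- lapply(n_values, function(n) {
    set.seed(seed + n)
    u <- numeric(0); done <- 0
    while (done < nrep) {
      m <- as.integer(min(max(1, floor(chunk / n)), nrep - done))
      E <- matrix(stats::rexp(m * n), m, n)
      sp <- 360 * E / rowSums(E)
      u <- c(u, 0.5 * rowSums(abs(sp - 360 / n)))
      done <- done + m
    }
    tibble::tibble(n = n, alpha = alphas,
                   u_crit = unname(stats::quantile(u, 1 - alphas)))
  })
  do.call(rbind, rows)
}

#' Classify a Rao spacing statistic against the critical-value table
#'
#' Brackets the p-value of an already-computed `U` at sample size `n` using
#' the nearest tabulated `n` (ties towards the smaller, more conservative
#' sample size).
#'
#' @param U Rao spacing statistic in degrees.
#' @param n Sample size (>= 4).
#' @param table Critical-value table (default [rao_critical_table()]).
#' @return List `U, n, n_table, p_low, p_high` of class `rao_test`.
#' @export
rao_classify <- function(U, n, table = rao_critical_table()) {
  if (n < 4L) ct_stop("Rao's spacing test needs n >= 4 (table minimum)")
  ns <- sort(unique(table$n))
  if (n < min(ns)) ct_stop("n below the tabulated minimum (%d)", min(ns))
  gap <- abs(ns - n)
  n_tab <- min(ns[gap == min(gap)])
  crit <- table[table$n == n_tab, ]
  crit <- crit[order(crit$alpha, decreasing = TRUE), ] # 0.10 first
  alphas <- crit$alpha
  k <- sum(U >= crit$u_crit)                # thresholds passed, in order
  p_high <- if (k == 0L) 1 else alphas[k]
  p_low <- if (k == 0L) alphas[1L] else if (k == length(alphas)) 0 else alphas[k + 1L]
  structure(list(U = U, n = n, n_table = n_tab, p_low = p_low, p_high = p_high),
            class = "rao_test")
}

#' Rao's spacing test of circular uniformity
#'
#' Computes `U` ([rao_statistic()]) and brackets its p-value against the
#' packaged critical-value table at the nearest tabulated sample size
#' (ties towards the smaller, more conservative `n`). The bracket
#' `(p_low, p_high)` is the narrowest interval the table supports;
#' `p_high = 1` when `U` is below the 0.10 critical value and
#' `p_low = 0` when `U` exceeds the 0.001 value.
#'
#' @param theta Angles in radians (n >= 4).
#' @param table Critical-value table (default [rao_critical_table()]).
#' @return List of class `rao_test`: `U`, `n`, `n_table` (the row used),
#'   `p_low`, `p_high`.
#' @export
rao_spacing_test <- function(theta, table = rao_critical_table()) {
  n <- length(theta)
  if (n < 4L) ct_stop("Rao's spacing test needs n >= 4 (table minimum)")
  rao_classify(rao_statistic(theta), n, table = table)
}

#' @export
print.rao_test <- function(x, ...) {
  cat(sprintf("Rao's spacing test: U = %.2f deg, n = %d (table n = %d), %s\n",
              x$U, x$n, x$n_table,
              if (x$p_high >= 1) sprintf("P > %.2g", x$p_low)
              else if (x$p_low <= 0) sprintf("P < %.3g", x$p_high)
              else sprintf("%.3g < P < %.3g", x$p_low, x$p_high)))
  invisible(x)
}

#' Hourly (or other) activity histogram on the 24-h clock
#'
#' Half-open bins `[start, start + width)`; counts sum to the sample size.
#'
#' @param theta Angles in radians.
#' @param bin_hours Bin width in hours; must divide 24. Default 1.
#' @return Tibble `bin_start` (hours), `count`.
#' @export
activity_histogram <- function(theta, bin_hours = 1) {
  if (24 %% bin_hours != 0) ct_stop("`bin_hours` must divide 24")
  hrs <- wrap_angle(theta) / (2 * pi) * 24
  starts <- seq(0, 24 - bin_hours, by = bin_hours)
  idx <- floor(hrs / bin_hours) + 1L
  tibble::tibble(bin_start = starts,
                 count = as.integer(tabulate(idx, nbins = length(starts))))
}
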