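#' Pairwise Euclidean distances between two point sets
#'
#' @param a,b Two-column matrices (x, y) in projected metres.
#' @return `nrow(a) x nrow(b)` distance matrix.
#' @keywords internal
edist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Distance-dependent detection functions
#'
#' Probability that a detector at distance `d` (metres) from an animal's
#' home-range centre records it on one occasion:
#' \describe{
#'   \item{HN}{half-normal, `g0 * exp(-d^2 / (2 sigma^2))`}
#'   \item{EX}{negative exponential, `g0 * exp(-d / sigma)`}
#'   \item{HR}{hazard rate, `g0 * (1 - exp(-(d / sigma)^(-z)))`, `z > 1`}
#' }
#' All reach `g0` at the centre and decay with `d`; `sigma` (metres) scales
#' the decline and proxies home-range extent.
#'
#' @param d Distances in metres (vector or matrix, >= 0).
#' @param kind `"HN"`, `"EX"` or `"HR"`.
#' @param g0 Detection probability at the centre, in (0, 1).
#' @param sigma Spatial scale in metres (> 0).
#' @param z Hazard-rate shape (> 1); ignored for HN and EX.
#' @return Detection probabilities, same shape as `d`.
#' @examples
#' detection_probability(2000, "HN", g0 = 0.5, sigma = 2000) # 0.5 * exp(-1/2)
#' @export
detection_probability <- function(d, kind = c("HN", "EX", "HR"),
                                  g0, sigma, z = NULL) {
  kind <- match.arg(kind)
  check_prob(g0, "g0")
  if (g0 <= 0) ct_stop("`g0` must be positive")
  if (!is.numeric(sigma) || sigma <= 0) ct_stop("`sigma` must be positive")
  if (any(d < 0)) ct_stop("distances must be non-negative")
  switch(kind,
    HN = g0 * exp(-d^2 / (2 * sigma^2)),
    EX = g0 * exp(-d / sigma),
    HR = {
      if (is.null(z) || !is.numeric(z) || z <= 1) {
        ct_stop("hazard-rate needs shape z > 1")
      }
      g0 * (1 - exp(-(d / sigma)^(-z)))
    })
}

#' Build a habitat mask around a detector layout
#'
#' A square grid of candidate home-range centres clipped to the points
#' within `buffer` metres of the nearest detector. The mask discretises the
#' integral in the SECR likelihood; its area scales abundance.
#'
#' @param detectors Detector tibble (`detector_id, x, y`).
#' @param buffer Buffer radius in metres (> 0); the conventional default is
#'   4 x a pilot `sigma`.
#' @param spacing Grid spacing in metres (> 0). A spacing larger than the
#'   buffer triggers a coarse-mask warning.
#' @return Object of class `habitat_mask`: list with `points` (M x 2
#'   matrix), `spacing`, `cell_area_km2` (`spacing^2 / 1e6`), `area_km2`,
#'   `buffer`.
#' @examples
#' det <- tibble::tibble(detector_id = "d1", x = 0, y = 0)
#' make_mask(det, buffer = 100, spacing = 100)$area_km2 # 5 cells -> 0.05
#' @export
make_mask <- function(detectors, buffer, spacing) {
  det <- validate_detectors(detectors)
  if (!is.numeric(buffer) || buffer <= 0) ct_stop("`buffer` must be positive")
  if (!is.numeric(spacing) || spacing <= 0) ct_stop("`spacing` must be positive")
  if (spacing > buffer) ct_warn("mask spacing exceeds buffer; the mask will be coarse")
  xy <- cbind(det$x, det$y)
  xs <- seq(min(det$x) - buffer, max(det$x) + buffer, by = spacing)
  ys <- seq(min(det$y) - buffer, max(det$y) + buffer, by = spacing)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  dmin <- apply(edist(grid, xy), 1L, min)
  pts <- grid[dmin <= buffer, , drop = FALSE]
  structure(list(points = pts, spacing = spacing,
                 cell_area_km2 = spacing^2 / 1e6,
                 area_km2 = nrow(pts) * spacing^2 / 1e6,
                 buffer = buffer),
            class = "habitat_mask")
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat(sprintf("Habitat mask: %d points, spacing %g m, area %.2f km2 (buffer %g m)\n",
              nrow(x$points), x$spacing, x$area_km2, x$buffer))
  invisible(x)
}

#' Assemble binary capture histories for proximity detectors
#'
#' One day is one capture occasion; a detector either did or did not record
#' an identified individual on an occasion. Multiple records of the same
#' individual at the same detector on one day collapse to a single
#' detection (with a message). Detections at a detector-occasion with zero
#' usage are an error.
#'
#' @param detections Tibble `individual, date, detector` (one row per
#'   detection; `date` coercible to `Date`).
#' @param detectors Detector tibble; every `detector` must match.
#' @param occasions Vector of occasion dates; default the full range of
#'   detection dates.
#' @param usage Optional binary detector x occasion matrix (rows in
#'   detector order, columns in occasion order); default all 1.
#' @return Object of class `capthist_ct`: list with `y` (individual x
#'   occasion x detector binary array), `individuals`, `occasions`,
#'   `detectors`, `usage`.
#' @export
build_capture_histories <- function(detections, detectors, occasions = NULL,
                                    usage = NULL) {
  det <- validate_detectors(detectors)
  dd <- tibble::as_tibble(detections)
  need <- c("individual", "date", "detector")
  if (!all(need %in% names(dd))) {
    ct_stop("detections need columns: %s", paste(need, collapse = ", "))
  }
  dd$date <- as.Date(dd$date)
  dd$detector <- as.character(dd$detector)
  stray <- setdiff(dd$detector, det$detector_id)
  if (length(stray)) ct_stop("unknown detector id(s): %s", paste(stray, collapse = ", "))
  if (is.null(occasions)) occasions <- seq(min(dd$date), max(dd$date), by = "day")
  occasions <- as.Date(occasions)
  if (!all(dd$date %in% occasions)) ct_stop("detection date outside the occasion calendar")
  K <- nrow(det); S <- length(occasions)
  if (is.null(usage)) usage <- matrix(1L, K, S)
  stopifnot(nrow(usage) == K, ncol(usage) == S)
  ids <- sort(unique(dd$individual))
  y <- array(0L, dim = c(length(ids), S, K),
             dimnames = list(ids, as.character(occasions), det$detector_id))
  i <- match(dd$individual, ids)
  s <- match(dd$date, occasions)
  k <- match(dd$detector, det$detector_id)
  dup <- duplicated(cbind(i, s, k))
  if (any(dup)) {
    message(sprintf("collapsed %d same-day duplicate detection(s)", sum(dup)))
  }
  y[cbind(i, s, k)] <- 1L
  bad <- which(usage[cbind(k, s)] == 0)
  if (length(bad)) {
    ct_stop("detection(s) at detector-occasions with zero usage (e.g. %s on %s)",
            dd$detector[bad[1]], format(dd$date[bad[1]]))
  }
  structure(list(y = y, individuals = ids, occasions = occasions,
                 detectors = det, usage = usage),
            class = "capthist_ct")
}

#' @export
print.capthist_ct <- function(x, ...) {
  cat(sprintf("Capture histories: %d individuals, %d occasions, %d detectors, %d detections\n",
              dim(x$y)[1], dim(x$y)[2], dim(x$y)[3], sum(x$y)))
  invisible(x)
}

# compact sufficient statistics for the conditional likelihood:
# counts[i, k] = detection-occasions of individual i at detector k,
# udays[k] = active occasions of detector k
ch_counts <- function(ch) {
  y <- ch$y
  n <- dim(y)[1]; K <- dim(y)[3]
  counts <- matrix(0L, n, K)
  for (k in seq_len(K)) counts[, k] <- rowSums(y[, , k, drop = FALSE])
  list(counts = counts, udays = rowSums(ch$usage), n = n)
}

link_to_natural <- function(par, kind) {
  out <- c(g0 = stats::plogis(par[1]), sigma = exp(par[2]))
  if (kind == "HR") out <- c(out, z = 1 + exp(par[3]))
  out
}

natural_to_link <- function(g0, sigma, z = NULL, kind = "HN") {
  par <- c(stats::qlogis(g0), log(sigma))
  if (kind == "HR") par <- c(par, log(z - 1))
  par
}

# negative conditional log-likelihood given precomputed pieces
secr_nll_core <- function(par, kind, counts, udays, distmat, cell_area) {
  nat <- link_to_natural(par, kind)
  G <- detection_probability(distmat, kind, g0 = nat[["g0"]],
                             sigma = nat[["sigma"]],
                             z = if (kind == "HR") nat[["z"]] else NULL)
  G <- pmin(pmax(G, 1e-300), 1 - 1e-12)
  logG <- log(G)
  log1m <- log1p(-G)
  logprod0 <- as.vector(crossprod(log1m, udays))       # M: sum_k udays_k log(1-g)
  A <- counts %*% (logG - log1m)                        # n x M
  A <- sweep(A, 2L, logprod0, "+")
  li <- matrixStats::rowLogSumExps(A) + log(cell_area)  # log integral per individual
  if (any(!is.finite(li))) {
    ct_stop("an individual's detection probability underflows to zero over the whole mask")
  }
  pdot <- -expm1(logprod0)
  n <- nrow(counts)
  -sum(li) + n * log(sum(pdot) * cell_area)
}

#' Negative conditional log-likelihood of an SECR model
#'
#' Conditional-on-capture likelihood for proximity detectors with
#' home-range centres following a homogeneous planar Poisson process: for
#' each detected individual the probability of its history given a centre
#' `X` is the product of independent Bernoulli detections over occasions
#' and detectors, `p_sk(X) = usage_ks * g(||X - x_k||)`; the overall
#' detection probability is `p.(X) = 1 - prod(1 - p_sk(X))`; and
#' `-logL = -sum_i log[ sum_X Pr(w_i | X) w ] + n log[ sum_X p.(X) w ]`
#' with `w` the mask cell area. Computed in log space throughout.
#'
#' @param ch `capthist_ct` object.
#' @param mask `habitat_mask` object.
#' @param kind Detection function, `"HN"`, `"EX"` or `"HR"`.
#' @param g0,sigma,z Detection-function parameters on the natural scale.
#' @return The negative log-likelihood (a single number).
#' @export
secr_nll <- function(ch, mask, kind = c("HN", "EX", "HR"), g0, sigma, z = NULL) {
  kind <- match.arg(kind)
  cc <- ch_counts(ch)
  distmat <- edist(cbind(ch$detectors$x, ch$detectors$y), mask$points)
  par <- natural_to_link(g0, sigma, z, kind)
  secr_nll_core(par, kind, cc$counts, cc$udays, distmat, mask$cell_area_km2)
}

# data fingerprint so model ranking can refuse mixed datasets
ch_tag <- function(ch) {
  paste(dim(ch$y), collapse = "x") |>
    paste(sum(ch$y), sum(ch$usage), sep = "|")
}

#' Effective sampling area
#'
#' `a(theta) = sum_X p.(X) w`: the mask integral of the overall detection
#' probability. Saturated detection (`p. = 1` everywhere) gives the mask
#' area itself, so `D = n / esa` reduces to a census density.
#'
#' @param ch `capthist_ct` object (only its detectors and usage are used).
#' @param mask `habitat_mask` object.
#' @inheritParams secr_nll
#' @return Effective sampling area in km2.
#' @export
esa <- function(ch, mask, kind = c("HN", "EX", "HR"), g0, sigma, z = NULL) {
  kind <- match.arg(kind)
  udays <- rowSums(ch$usage)
  distmat <- edist(cbind(ch$detectors$x, ch$detectors$y), mask$points)
  G <- detection_probability(distmat, kind, g0 = g0, sigma = sigma,
                             z = if (kind == "HR") z else NULL)
  pdot <- -expm1(as.vector(crossprod(log1p(-pmin(G, 1 - 1e-12)), udays)))
  sum(pdot) * mask$cell_area_km2
}

#' Fit an SECR model by conditional maximum likelihood
#'
#' Maximises the conditional likelihood of [secr_nll()] on link scales
#' (logit `g0`, log `sigma`, and log(`z` - 1) for the hazard-rate model, so
#' `z > 1` keeps the function finite at the centre). Standard errors come
#' from the inverse numerical Hessian; the effective sampling area
#' `a(theta) = sum_X p.(X) w` is evaluated at the MLE. AICc uses the number
#' of individuals as the sample size.
#'
#' @param ch `capthist_ct` object with at least 2 individuals.
#' @param mask `habitat_mask` object.
#' @param kind Detection function, `"HN"`, `"EX"` or `"HR"`.
#' @param start Optional start values on the natural scale,
#'   `c(g0, sigma[, z])`; default is a data-driven heuristic.
#' @return Object of class `secr_fit`: list with `kind`, `par` (link-scale
#'   MLE), `vcov` (link scale), `estimates` (tibble of natural-scale
#'   estimates with SEs), `logLik`, `K`, `n`, `AICc`, `esa` (km2),
#'   `mask_area`, `convergence` (0 = converged), `data_tag`.
#' @export
fit_secr <- function(ch, mask, kind = c("HN", "EX", "HR"), start = NULL) {
  kind <- match.arg(kind)
  cc <- ch_counts(ch)
  if (cc$n < 2L) ct_stop("SECR fit needs at least 2 individuals")
  xy <- cbind(ch$detectors$x, ch$detectors$y)
  distmat <- edist(xy, mask$points)
  if (is.null(start)) {
    sigma0 <- start_sigma(ch)
    rate <- sum(cc$counts) / (cc$n * sum(cc$udays))
    g0_0 <- min(max(5 * rate, 0.01), 0.8)
    start <- c(g0_0, sigma0, if (kind == "HR") 2.5)
  }
  par0 <- natural_to_link(start[1], start[2],
                          if (kind == "HR") start[3] else NULL, kind)
  obj <- function(p) secr_nll_core(p, kind, cc$counts, cc$udays, distmat,
                                   mask$cell_area_km2)
  fit1 <- stats::optim(par0, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
  fit2 <- stats::optim(fit1$par, obj, method = "BFGS", hessian = TRUE,
                       control = list(maxit = 500, reltol = 1e-12))
  par <- fit2$par
  vcov <- tryCatch(solve(fit2$hessian), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    ct_warn("singular or indefinite Hessian; SEs unavailable")
    vcov <- matrix(NA_real_, length(par), length(par))
  }
  nat <- link_to_natural(par, kind)
  # delta method on each link transform
  deriv <- c(nat[["g0"]] * (1 - nat[["g0"]]), nat[["sigma"]],
             if (kind == "HR") nat[["z"]] - 1)
  se <- sqrt(diag(vcov)) * abs(deriv)
  nll <- fit2$value
  Kpar <- length(par)
  est <- tibble::tibble(param = names(nat), estimate = unname(nat), se = unname(se))
  g0 <- nat[["g0"]]
  G <- detection_probability(distmat, kind, g0 = g0, sigma = nat[["sigma"]],
                             z = if (kind == "HR") nat[["z"]] else NULL)
  pdot <- -expm1(as.vector(crossprod(log1p(-pmin(G, 1 - 1e-12)), cc$udays)))
  esa <- sum(pdot) * mask$cell_area_km2
  structure(list(kind = kind, par = par, vcov = vcov, estimates = est,
                 logLik = -nll, K = Kpar, n = cc$n,
                 AICc = aicc(-nll, Kpar, cc$n),
                 esa = esa, mask_area = mask$area_km2,
                 mask = mask, counts = cc, distmat_dim = dim(distmat),
                 detectors = ch$detectors,
                 convergence = fit2$convergence, data_tag = ch_tag(ch)),
            class = "secr_fit")
}

# pooled spatial spread of each individual's detection locations; fallback
# to half the mean nearest-detector spacing when nobody moved
start_sigma <- function(ch) {
  xy <- cbind(ch$detectors$x, ch$detectors$y)
  cc <- ch_counts(ch)
  devs <- numeric(0)
  for (i in seq_len(cc$n)) {
    k <- which(cc$counts[i, ] > 0)
    if (length(k) >= 2L) {
      w <- cc$counts[i, k]
      cx <- sum(xy[k, 1] * w) / sum(w); cy <- sum(xy[k, 2] * w) / sum(w)
      devs <- c(devs, rep(sqrt((xy[k, 1] - cx)^2 + (xy[k, 2] - cy)^2), w))
    }
  }
  if (length(devs) >= 3L) return(max(stats::sd(devs) * 2, 1))
  d <- edist(xy, xy); diag(d) <- Inf
  mean(apply(d, 1L, min)) / 2
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("SECR fit (%s detection function), n = %d individuals\n", x$kind, x$n))
  print(as.data.frame(x$estimates), row.names = FALSE)
  cat(sprintf("  logLik %.3f, K %d, AICc %.3f, esa %.2f km2%s\n",
              x$logLik, x$K, x$AICc, x$esa,
              if (x$convergence != 0) " [did not converge]" else ""))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2K + 2K(K+1) / (n - K - 1)` with `n` the number of
#' detected individuals (the convention of SECR software).
#'
#' @param logLik Maximised log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Number of individuals.
#' @return AICc.
#' @examples
#' aicc(0, 2, 30) # 4 + 12/27
#' @export
aicc <- function(logLik, K, n) {
  if (n - K - 1 <= 0) ct_stop("AICc undefined for n <= K + 1")
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank SECR fits by AICc
#'
#' @param fits List of `secr_fit` objects on the same data (mixing datasets
#'   is an error).
#' @return Tibble `kind, K, logLik, AICc, dAICc, weight` sorted by AICc;
#'   weights are Akaike weights.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  tags <- vapply(fits, function(f) f$data_tag, character(1))
  if (length(unique(tags)) > 1L) ct_stop("fits are not all on the same data")
  tbl <- tibble::tibble(
    kind = vapply(fits, function(f) f$kind, character(1)),
    K = vapply(fits, function(f) f$K, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)))
  tbl <- tbl[order(tbl$AICc), ]
  tbl$dAICc <- tbl$AICc - tbl$AICc[1]
  w <- exp(-tbl$dAICc / 2)
  tbl$weight <- w / sum(w)
  tbl
}

#' Density and abundance derived from an SECR fit
#'
#' Horvitz-Thompson-style derived density `D = n / a(theta)` with the
#' effective sampling area `a` evaluated at the MLE. The variance combines
#' Poisson variation in `n` with parameter uncertainty by the delta method,
#' `Var(D)/D^2 = 1/n + grad(log a)' V grad(log a)`; the 95% interval is
#' lognormal, `(D/C, D*C)` with `C = exp(1.96 sqrt(log(1 + CV^2)))`.
#' Abundance is the volume under the flat density surface over the mask,
#' `N = D * A_mask`, with the interval scaled likewise.
#'
#' @param fit `secr_fit` object.
#' @param mask Optional mask over which to report abundance; default the
#'   fitting mask.
#' @return One-row tibble `D, SE_D, D_lcl, D_ucl, CV, esa_km2, area_km2,
#'   N_hat, N_lcl, N_ucl`.
#' @export
derive_density <- function(fit, mask = NULL) {
  if (is.null(mask)) mask <- fit$mask
  if (fit$esa <= 0) ct_stop("effective sampling area must be positive")
  n <- fit$n
  D <- n / fit$esa
  grad <- esa_loggrad(fit)
  var_par <- if (any(is.na(fit$vcov))) 0 else
    as.numeric(t(grad) %*% fit$vcov %*% grad)
  cv2 <- 1 / n + max(var_par, 0)
  se <- D * sqrt(cv2)
  C <- exp(1.96 * sqrt(log(1 + cv2)))
  tibble::tibble(D = D, SE_D = se, D_lcl = D / C, D_ucl = D * C,
                 CV = sqrt(cv2), esa_km2 = fit$esa, area_km2 = mask$area_km2,
                 N_hat = D * mask$area_km2,
                 N_lcl = D / C * mask$area_km2, N_ucl = D * C * mask$area_km2)
}

# numerical gradient of log esa with respect to the link parameters
esa_loggrad <- function(fit) {
  cc <- fit$counts
  distmat <- edist(cbind(fit$detectors$x, fit$detectors$y), fit$mask$points)
  esa_at <- function(p) {
    nat <- link_to_natural(p, fit$kind)
    G <- detection_probability(distmat, fit$kind, g0 = nat[["g0"]],
                               sigma = nat[["sigma"]],
                               z = if (fit$kind == "HR") nat[["z"]] else NULL)
    pdot <- -expm1(as.vector(crossprod(log1p(-pmin(G, 1 - 1e-12)), cc$udays)))
    sum(pdot) * fit$mask$cell_area_km2
  }
  vapply(seq_along(fit$par), function(j) {
    h <- 1e-4 * max(1, abs(fit$par[j]))
    pp <- fit$par; pm <- fit$par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (log(esa_at(pp)) - log(esa_at(pm))) / (2 * h)
  }, numeric(1))
}

#' Abundance from a density and a mask area
#'
#' The volume under a flat density surface: `N = D * area`.
#'
#' @param D Density in animals per km2.
#' @param area_km2 Mask area in km2.
#' @return Expected abundance (not rounded).
#' @examples
#' abundance_from_density(0.138, 1413) # 195 after rounding
#' @export
abundance_from_density <- function(D, area_km2) {
  if (D < 0 || area_km2 <= 0) ct_stop("need D >= 0 and area > 0")
  D * area_km2
}

#' Write capture histories in the flat text convention
#'
#' One row per detection: `session, individual, occasion, detector`.
#'
#' @param ch `capthist_ct` object.
#' @param path Output CSV path.
#' @param session Session label.
#' @return `path`, invisibly.
#' @export
write_capture_histories <- function(ch, path, session = "survey") {
  idx <- which(ch$y == 1L, arr.ind = TRUE)
  out <- tibble::tibble(session = session,
                        individual = ch$individuals[idx[, 1]],
                        occasion = as.character(ch$occasions[idx[, 2]]),
                        detector = ch$detectors$detector_id[idx[, 3]])
  out <- out[order(out$individual, out$occasion, out$detector), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
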