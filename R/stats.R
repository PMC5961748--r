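#' Is a cell polarized against the flow?
#'
#' A cell counts as polarized against the flow when its polarity vector sits
#' within `tolerance_deg` of the anti-flow direction, i.e. the relative
#' angle satisfies |theta| >= 180 - tolerance (boundary inclusive). The
#' default 45 degree tolerance makes the against-flow window a quarter of
#' the circle.
#'
#' @param theta signed relative angle(s), degrees in (-180, 180].
#' @param tolerance_deg half-width of the against-flow window (default 45).
#' @return logical vector.
#' @export
against_flow <- function(theta, tolerance_deg = 45) {
  stopifnot(all(abs(theta) <= 180, na.rm = TRUE))
  abs(theta) >= 180 - tolerance_deg
}

#' Directionality table
#'
#' Number and ratio of cells polarized against the flow direction, overall
#' and per group (typically the vascular-bed region).
#'
#' @param pairs a `cell_flow_pairs` table; only matched cells with defined
#'   angles are counted.
#' @param group_by optional column name to group on (e.g. `"region"`).
#' @param tolerance_deg forwarded to [against_flow()].
#' @return data frame `group`, `n_cells`, `n_against`, `ratio` (`NA` ratio
#'   for empty groups), with the `"all"` row last.
#' @export
directionality_table <- function(pairs, group_by = NULL, tolerance_deg = 45) {
  ok <- pairs$matched & !is.na(pairs$theta_deg)
  use <- pairs[ok, , drop = FALSE]
  agx <- against_flow(use$theta_deg, tolerance_deg)
  rows <- list()
  if (!is.null(group_by)) {
    groups <- unique(pairs[[group_by]])
    for (g in groups) {
      sel <- use[[group_by]] == g
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, n_cells = n, n_against = sum(agx[sel]),
        ratio = if (n > 0) sum(agx[sel]) / n else NA_real_)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    group = "all", n_cells = nrow(use), n_against = sum(agx),
    ratio = if (nrow(use) > 0) mean(agx) else NA_real_)
  do.call(rbind, rows)
}

#' Polar histogram of relative angles
#'
#' Bins signed angles over (-180, 180] into `n_bins` equal sectors
#' (default 24 sectors of 15 degrees). An absolute-angle variant folded to
#' [0, 180] is also returned.
#'
#' @param theta signed angles in degrees.
#' @param n_bins number of sectors.
#' @return list with `breaks`, `counts`, `folded_breaks`, `folded_counts`.
#' @export
polar_histogram <- function(theta, n_bins = 24) {
  theta <- theta[!is.na(theta)]
  breaks <- seq(-180, 180, length.out = n_bins + 1L)
  # (-180, 180] sectors: shift exact -180 representations
  th <- theta; th[th <= -180] <- 180
  bin <- findInterval(th, breaks, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  fb <- seq(0, 180, length.out = n_bins / 2 + 1L)
  fbin <- findInterval(abs(th), fb, all.inside = TRUE)
  structure(list(breaks = breaks, counts = counts,
                 folded_breaks = fb,
                 folded_counts = tabulate(fbin, nbins = length(fb) - 1L)),
            class = "polar_histogram")
}

# Kuiper excursion statistic of unit-interval sample vs the uniform CDF
kuiper_stat_uniform <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  max(dplus, 0) + max(dminus, 0)
}

# asymptotic tail probability with Stephens' finite-n correction
kuiper_pvalue_asymptotic <- function(V, neff) {
  lam <- (sqrt(neff) + 0.155 + 0.24 / sqrt(neff)) * V
  if (lam < 0.4) return(1)
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  min(max(p, 0), 1)
}

angles_to_unit <- function(theta) ((theta + 180) / 360) %% 1

#' One-sample Kuiper test against the uniform circular distribution
#'
#' The Kuiper statistic V = D+ + D- is the rotation-invariant analogue of
#' Kolmogorov-Smirnov, which makes it the appropriate randomness test for
#' angles: no direction on the circle is privileged. Angles (degrees) are
#' mapped to the unit interval via (theta + 180)/360.
#'
#' @param angles_deg sample of angles in degrees.
#' @param method `"auto"` (Monte Carlo for n < 8, else asymptotic),
#'   `"asymptotic"` or `"monte_carlo"`.
#' @param n_mc Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo null (used locally; the global RNG
#'   state is restored).
#' @return list of class `kuiper_result`: `statistic` (V), `p_value`, `n`,
#'   `method`.
#' @export
kuiper_one_sample <- function(angles_deg, method = c("auto", "asymptotic",
                                                     "monte_carlo"),
                              n_mc = 2000, seed = 1L) {
  method <- match.arg(method)
  if (!length(angles_deg)) stop("empty sample")
  u <- angles_to_unit(angles_deg)
  n <- length(u)
  V <- kuiper_stat_uniform(u)
  if (method == "auto") method <- if (n < 8) "monte_carlo" else "asymptotic"
  p <- if (method == "asymptotic") {
    kuiper_pvalue_asymptotic(V, n)
  } else {
    vnull <- with_local_seed(seed, vapply(
      seq_len(n_mc), function(i) kuiper_stat_uniform(stats::runif(n)), 0))
    (1 + sum(vnull >= V)) / (n_mc + 1)
  }
  structure(list(statistic = V, p_value = p, n = n, method = method),
            class = "kuiper_result")
}

# two-sample Kuiper excursions evaluated at the sorted pooled points,
# right-continuous ECDFs; the implicit baseline 0 (before the first pooled
# point) is included, which makes V rotation invariant
kuiper_stat_two <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pool)
  fb <- stats::ecdf(b)(pool)
  d <- fa - fb
  max(c(d, 0)) - min(c(d, 0))
}

#' Two-sample Kuiper test
#'
#' Compares two angular samples (degrees, mapped to the unit interval) via
#' the Kuiper excursion of their ECDF difference. The asymptotic p-value
#' uses the effective size nm/(n+m); `method = "monte_carlo"` gives a pooled
#' permutation p-value instead.
#'
#' @param a,b angle samples in degrees.
#' @param method `"asymptotic"` or `"monte_carlo"` (permutation).
#' @param n_perm number of permutations.
#' @param seed permutation seed (used locally).
#' @return list of class `kuiper_result`: `statistic`, `p_value`, `n`, `m`,
#'   `method`.
#' @export
kuiper_two_sample <- function(a, b, method = c("asymptotic", "monte_carlo"),
                              n_perm = 1e4, seed = 1L) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("empty sample")
  ua <- angles_to_unit(a); ub <- angles_to_unit(b)
  n <- length(ua); m <- length(ub)
  V <- kuiper_stat_two(ua, ub)
  if (method == "asymptotic") {
    p <- kuiper_pvalue_asymptotic(V, n * m / (n + m))
  } else {
    pool <- c(ua, ub)
    vperm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n + m, n)
      kuiper_stat_two(pool[idx], pool[-idx])
    }, 0))
    p <- (1 + sum(vperm >= V - 1e-12)) / (n_perm + 1)
  }
  structure(list(statistic = V, p_value = p, n = n, m = m, method = method),
            class = "kuiper_result")
}

#' Rayleigh test for circular uniformity
#'
#' Secondary randomness test (sensitive to unimodal departures only; the
#' Kuiper test is the primary one here).
#'
#' @param angles_deg angles in degrees.
#' @return list: `r_bar` (mean resultant length), `z`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles_deg) {
  if (!length(angles_deg)) stop("empty sample")
  th <- angles_deg * pi / 180
  n <- length(th)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r_bar = rbar, z = z, p_value = min(max(p, 0), 1), n = n)
}

#' WSS sensor-threshold analysis
#'
#' Bins matched cells by the WSS magnitude they experience and computes the
#' against-flow fraction per bin (an exact binomial proportion), then
#' reports the polarization threshold tau*: the WSS value at which the
#' curve first crosses `threshold_frac` (default 60%), linearly
#' interpolated between consecutive bin medians (or, with
#' `interpolate = FALSE`, the median of the first bin at or above the
#' threshold). If the curve never crosses, `tau_star` is `NA` with a
#' reason.
#'
#' @param pairs a `cell_flow_pairs` table.
#' @param n_bins number of WSS bins (default 8).
#' @param binning `"quantile"` (equal-count, default), `"width"` or `"log"`.
#' @param tolerance_deg against-flow window half-width.
#' @param threshold_frac crossing level (default 0.60).
#' @param interpolate interpolate the crossing linearly (default) or take
#'   the first bin median at/above threshold.
#' @return list of class `sensor_curve`: `bins` data frame (`tau_lo`,
#'   `tau_hi`, `tau_median`, `n`, `frac_against`), `tau_star`, `reason`,
#'   and the parameters used.
#' @export
sensor_analysis <- function(pairs, n_bins = 8,
                            binning = c("quantile", "width", "log"),
                            tolerance_deg = 45, threshold_frac = 0.60,
                            interpolate = TRUE) {
  binning <- match.arg(binning)
  ok <- pairs$matched & !is.na(pairs$theta_deg)
  tau <- pairs$t_mag_pa[ok]
  agx <- against_flow(pairs$theta_deg[ok], tolerance_deg)
  if (length(tau) < n_bins)
    stop("fewer cells (", length(tau), ") than bins (", n_bins,
         "); reduce n_bins")
  breaks <- switch(binning,
    quantile = unique(stats::quantile(tau, probs = seq(0, 1,
                                                       length.out = n_bins + 1L),
                                      names = FALSE)),
    width = seq(min(tau), max(tau), length.out = n_bins + 1L),
    log = {
      lo <- max(min(tau), 1e-6)
      exp(seq(log(lo), log(max(tau)), length.out = n_bins + 1L))
    })
  if (length(breaks) < 3L) stop("WSS values too tied for ", n_bins, " bins")
  bin <- findInterval(tau, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(breaks) - 1L
  bins <- data.frame(
    tau_lo = breaks[-length(breaks)], tau_hi = breaks[-1L],
    tau_median = vapply(seq_len(nb),
                        function(b) stats::median(tau[bin == b]), 0),
    n = vapply(seq_len(nb), function(b) sum(bin == b), 0L),
    frac_against = vapply(seq_len(nb),
                          function(b) mean(agx[bin == b]), 0))
  tau_star <- NA_real_; reason <- NULL
  hit <- which(bins$frac_against >= threshold_frac)
  if (!length(hit)) {
    reason <- sprintf("curve never reaches %.0f%% against-flow",
                      100 * threshold_frac)
  } else {
    i <- hit[1L]
    if (i == 1L || !interpolate) {
      tau_star <- bins$tau_median[i]
    } else {
      x0 <- bins$tau_median[i - 1L]; y0 <- bins$frac_against[i - 1L]
      x1 <- bins$tau_median[i]; y1 <- bins$frac_against[i]
      tau_star <- x0 + (threshold_frac - y0) / (y1 - y0) * (x1 - x0)
    }
  }
  structure(list(bins = bins, tau_star = tau_star, reason = reason,
                 threshold_frac = threshold_frac,
                 tolerance_deg = tolerance_deg, binning = binning),
            class = "sensor_curve")
}

#' Scalar-product slope regression
#'
#' Regresses the polarity-flow scalar product s = p . t = |p||t|cos(theta)
#' on the WSS magnitude |t|, separately for the positive and negative
#' subgroups of s (s = 0 counted apart). The slope estimates |p|cos(theta);
#' a larger negative slope means a stronger against-flow polarization
#' response per unit WSS, a surrogate for flow sensitivity.
#'
#' @param pairs a `cell_flow_pairs` table.
#' @return list of class `slope_fits` with elements `positive`, `negative`
#'   (each `slope`, `intercept`, `pearson_r`, `n`, or `NULL` when n < 3)
#'   and `n_zero`.
#' @export
scalar_product_slopes <- function(pairs) {
  ok <- pairs$matched & !is.na(pairs$s)
  s <- pairs$s[ok]; tm <- pairs$t_mag_pa[ok]
  fit_one <- function(sel) {
    n <- sum(sel)
    if (n < 3L) return(list(slope = NA_real_, intercept = NA_real_,
                            pearson_r = NA_real_, n = n,
                            skipped = "fewer than 3 cells"))
    co <- stats::coef(stats::lm(s[sel] ~ tm[sel]))
    r <- if (stats::sd(tm[sel]) == 0 || stats::sd(s[sel]) == 0) NA_real_
         else stats::cor(tm[sel], s[sel])
    list(slope = unname(co[2L]), intercept = unname(co[1L]),
         pearson_r = r, n = n)
  }
  structure(list(positive = fit_one(s > 0),
                 negative = fit_one(s < 0),
                 n_zero = sum(s == 0)),
            class = "slope_fits")
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
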