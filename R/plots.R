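# Figure helpers. All draw into the currently open device; the pipeline
# wraps them in pdf() for deterministic headless rendering.

#' Overlay of mask, polarity vectors and WSS vectors
#'
#' Mirrors the canonical overlay view: lumen in grey, polarity vectors in
#' blue, WSS vectors (scaled by magnitude) in red.
#'
#' @param mask a [binary_mask].
#' @param cells a `cell_records` table (may be `NULL`).
#' @param wss_samples output of [wss_vector_field()] (may be `NULL`).
#' @param wss_scale arrow length per Pa, in micrometres.
#' @param thin draw every `thin`-th WSS sample.
#' @return invisibly `NULL`.
#' @export
plot_overlay <- function(mask, cells = NULL, wss_samples = NULL,
                         wss_scale = 10, thin = 5L) {
  ps <- mask$pixel_size
  h <- nrow(mask$pixels); w <- ncol(mask$pixels)
  graphics::plot(NA, xlim = c(0, w * ps), ylim = c(h * ps, 0), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = "lumen / polarity / WSS")
  idx <- which(mask$pixels, arr.ind = TRUE)
  graphics::points((idx[, 2L] - 0.5) * ps, (idx[, 1L] - 0.5) * ps,
                   pch = 15, cex = 0.2, col = "grey80")
  if (!is.null(wss_samples) && nrow(wss_samples)) {
    sm <- wss_samples[seq(1L, nrow(wss_samples), by = thin), , drop = FALSE]
    nz <- sm$tau_pa > 0
    suppressWarnings(  # sub-pixel arrows have indeterminate heads
      graphics::arrows(sm$x_um[nz], sm$y_um[nz],
                       sm$x_um[nz] + sm$tx[nz] * wss_scale,
                       sm$y_um[nz] + sm$ty[nz] * wss_scale,
                       length = 0.03, col = "red"))
  }
  if (!is.null(cells) && nrow(cells)) {
    suppressWarnings(
      graphics::arrows(cells$nucleus_x_um, cells$nucleus_y_um,
                       cells$golgi_x_um, cells$golgi_y_um,
                       length = 0.03, col = "blue"))
  }
  invisible(NULL)
}

#' Polar histogram plot
#'
#' @param ph a [polar_histogram()] result.
#' @param main plot title.
#' @return invisibly `NULL`.
#' @export
plot_polar_histogram <- function(ph, main = "polarity angle vs flow") {
  n <- length(ph$counts)
  mid <- (ph$breaks[-1L] + ph$breaks[-(n + 1L)]) / 2 * pi / 180
  r <- ph$counts / max(1, max(ph$counts))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  hw <- pi / n
  for (i in seq_len(n)) {
    a <- seq(mid[i] - hw, mid[i] + hw, length.out = 8L)
    graphics::polygon(c(0, r[i] * cos(a)), c(0, r[i] * sin(a)),
                      col = "steelblue", border = "white")
  }
  graphics::text(c(1.08, 0, -1.08, 0), c(0, 1.08, 0, -1.08),
                 c("0", "90", "180", "-90"), cex = 0.8)
  invisible(NULL)
}

#' Sensor-curve plot
#'
#' @param sc a [sensor_analysis()] result.
#' @return invisibly `NULL`.
#' @export
plot_sensor_curve <- function(sc) {
  graphics::plot(sc$bins$tau_median, 100 * sc$bins$frac_against, type = "b",
                 pch = 19, col = "steelblue",
                 xlab = "WSS magnitude (Pa)", ylab = "% cells against flow",
                 ylim = c(0, 100), main = "WSS sensor analysis")
  graphics::abline(h = 100 * sc$threshold_frac, lty = 2)
  if (!is.na(sc$tau_star)) graphics::abline(v = sc$tau_star, lty = 3)
  invisible(NULL)
}

#' Scalar-product scatter with subgroup fits
#'
#' @param pairs a `cell_flow_pairs` table.
#' @param fits a [scalar_product_slopes()] result.
#' @return invisibly `NULL`.
#' @export
plot_slope_scatter <- function(pairs, fits) {
  ok <- pairs$matched & !is.na(pairs$s)
  graphics::plot(pairs$t_mag_pa[ok], pairs$s[ok], pch = 16, cex = 0.4,
                 col = ifelse(pairs$s[ok] < 0, "firebrick", "steelblue"),
                 xlab = "|t| (Pa)", ylab = "p . t (Pa um)",
                 main = "scalar product vs WSS")
  graphics::abline(h = 0, col = "grey60")
  for (f in list(fits$positive, fits$negative))
    if (!is.na(f$slope)) graphics::abline(f$intercept, f$slope, lty = 2)
  invisible(NULL)
}

plot_weighted_hist <- function(hst, xlab, main) {
  n <- length(hst$counts)
  graphics::plot(NA, xlim = range(hst$breaks), ylim = c(0, max(hst$counts)),
                 xlab = xlab, ylab = "vessel length (um)", main = main)
  graphics::rect(hst$breaks[-(n + 1L)], 0, hst$breaks[-1L], hst$counts,
                 col = "grey70")
  invisible(NULL)
}
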