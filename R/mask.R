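#' Binary lumen mask
#'
#' Container for a single-plane binary mask of the vessel lumen, as produced
#' by thresholding a maximal-intensity z-projection of the luminal staining.
#' Pixels are stored row-major as a logical matrix; the x coordinate is the
#' column index and y the row index, both 0-based in all exported tables,
#' with the origin at the top-left corner.
#'
#' @param pixels logical (or 0/1 numeric) matrix; `TRUE`/nonzero = lumen.
#' @param pixel_size physical size of one pixel in micrometres (> 0).
#' @return an object of class `binary_mask` with elements `pixels` and
#'   `pixel_size`.
#' @examples
#' m <- binary_mask(matrix(1, 5, 20), pixel_size = 2)
#' sum(m$pixels)
#' @export
binary_mask <- function(pixels, pixel_size) {
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical or 0/1 numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (micrometres per pixel)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, pixel_size %.4g um, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, sum(x$pixels)))
  invisible(x)
}

assert_nonempty_mask <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("expected a `binary_mask`")
  if (!any(mask$pixels)) stop("no foreground")
  invisible(mask)
}

#' Read a binary mask from a plain-text file
#'
#' Supported formats: ASCII PBM (`P1`, nonzero = lumen) and CSV/TSV grids of
#' 0/1 values (one image row per line). Binary image formats are deliberately
#' not supported; masks travel as text.
#'
#' @param path file path (`.pbm`, `.csv`, `.tsv`/`.txt`).
#' @param pixel_size micrometres per pixel.
#' @return a [binary_mask].
#' @export
read_mask <- function(path, pixel_size) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pbm") {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[!grepl("^\\s*#", txt)]
    toks <- scan(text = paste(txt, collapse = " "), what = character(),
                 quiet = TRUE)
    if (toks[1] != "P1") stop("only ASCII PBM (P1) is supported")
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    bits <- as.integer(toks[-(1:3)])
    if (length(bits) != w * h) stop("PBM pixel count mismatch")
    px <- matrix(bits, nrow = h, ncol = w, byrow = TRUE) != 0
  } else {
    sep <- if (ext == "csv") "," else ""
    px <- as.matrix(utils::read.table(path, sep = sep, header = FALSE)) != 0
    dimnames(px) <- NULL
  }
  binary_mask(px, pixel_size)
}

#' Write a binary mask as ASCII PBM or CSV
#'
#' @param mask a [binary_mask].
#' @param path destination; format chosen from the extension (`.pbm` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  ext <- tolower(tools::file_ext(path))
  px <- mask$pixels * 1L
  if (ext == "pbm") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P1", paste(ncol(px), nrow(px))), con)
    apply(px, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  } else {
    utils::write.table(px, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

# Connected-component labelling (8-connectivity) of a logical matrix.
# Row runs of foreground become vertices; runs in adjacent image rows that
# overlap (with one-column slack, for diagonal adjacency) are joined; the
# component structure is then read off the run graph. Returns an integer
# matrix, 0 = background, components numbered from 1 in raster order.
label_components <- function(pixels) {
  stopifnot(is.logical(pixels))
  lab <- matrix(0L, nrow(pixels), ncol(pixels))
  if (!any(pixels)) return(lab)
  runs <- do.call(rbind, lapply(seq_len(nrow(pixels)), function(r) {
    v <- pixels[r, ]
    if (!any(v)) return(NULL)
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    cbind(row = r, start = starts[keep], end = ends[keep])
  }))
  nr <- nrow(runs)
  edges <- NULL
  if (nr > 1L) {
    by_row <- split(seq_len(nr), runs[, "row"])
    pairs <- list()
    for (rw in names(by_row)) {
      nxt <- by_row[[as.character(as.integer(rw) + 1L)]]
      if (is.null(nxt)) next
      cur <- by_row[[rw]]
      # 8-connectivity: runs touch if column intervals overlap with slack 1
      for (i in cur) {
        hit <- nxt[runs[nxt, "start"] <= runs[i, "end"] + 1L &
                   runs[nxt, "end"] >= runs[i, "start"] - 1L]
        if (length(hit)) pairs[[length(pairs) + 1L]] <- cbind(i, hit)
      }
    }
    if (length(pairs)) edges <- do.call(rbind, pairs)
  }
  g <- igraph::make_empty_graph(n = nr, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber components in raster order of their first run
  first <- tapply(seq_len(nr), memb, min)
  ord <- order(runs[first, "row"], runs[first, "start"])
  renum <- integer(length(first)); renum[ord] <- seq_along(ord)
  for (i in seq_len(nr))
    lab[runs[i, "row"], runs[i, "start"]:runs[i, "end"]] <- renum[memb[i]]
  lab
}

n_components <- function(pixels) max(label_components(pixels))

#' Exact Euclidean distance transform
#'
#' Per-pixel Euclidean distance (in pixels) to the nearest background pixel,
#' computed with the separable lower-envelope algorithm on squared distances.
#' The image border is treated as background, so a mask touching the frame is
#' measured against the frame.
#'
#' @param pixels logical matrix (`TRUE` = foreground).
#' @return numeric matrix of distances; 0 on background.
#' @export
distance_transform <- function(pixels) {
  stopifnot(is.logical(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  BIG <- (h + w + 2)^2  # exceeds any attainable squared distance
  # pad with a background frame
  f <- matrix(BIG, h + 2L, w + 2L)
  f[] <- 0
  f[2:(h + 1L), 2:(w + 1L)][pixels] <- BIG
  for (i in seq_len(nrow(f))) f[i, ] <- edt_1d(f[i, ])
  for (j in seq_len(ncol(f))) f[, j] <- edt_1d(f[, j])
  sqrt(f[2:(h + 1L), 2:(w + 1L)])
}

# 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope)
edt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}
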