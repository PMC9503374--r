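#' CLAHE parameters
#'
#' Parameters of contrast-limited adaptive histogram equalization: the
#' frame is divided into a grid of equal, non-overlapping tiles, each
#' tile's gray-level histogram is clipped at the Reza limit and
#' re-equalised, and per-pixel output is blended bilinearly between the
#' neighbouring tiles' mappings.
#'
#' @param tiles_x,tiles_y Tile grid size (columns, rows), default 8 x 8.
#' @param alpha Clip factor in `[0, 100]`; 0 collapses the clip limit to
#'   its floor `M/N` (a flat histogram), 100 allows the maximum slope.
#' @param s_max Maximum slope of the tile transformation function,
#'   `>= 1`.
#' @param n_gray Number of gray levels, default 256.
#' @return An object of class `clahe_params`.
#' @examples
#' clahe_params(alpha = 50, s_max = 4)
#' @export
clahe_params <- function(tiles_x = 8L, tiles_y = 8L, alpha = 50,
                         s_max = 4, n_gray = 256L) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 100)
    stop("alpha must lie in [0, 100]", call. = FALSE)
  if (!is.finite(s_max) || s_max < 1)
    stop("s_max must be >= 1", call. = FALSE)
  if (n_gray < 2L) stop("n_gray must be >= 2", call. = FALSE)
  if (tiles_x < 1L || tiles_y < 1L)
    stop("tile counts must be >= 1", call. = FALSE)
  structure(list(tiles_x = as.integer(tiles_x), tiles_y = as.integer(tiles_y),
                 alpha = alpha, s_max = s_max, n_gray = as.integer(n_gray)),
            class = "clahe_params")
}

#' Reza clip limit for one tile
#'
#' Evaluates the clip limit
#' `beta = (M/N) * (1 + (alpha/100) * (s_max - 1))`, where `M` is the
#' pixel count of the tile and `N` the number of gray levels. `beta` is
#' monotone non-decreasing in both `alpha` and `s_max`, with floor `M/N`
#' at `alpha = 0`.
#'
#' @param params A [clahe_params()].
#' @param region_pixels Pixel count `M` of the tile, `>= 1`.
#' @return An object of class `clip_limit`: list with `beta` (counts per
#'   bin) and `region_pixels`.
#' @examples
#' compute_clip_limit(clahe_params(alpha = 100, s_max = 4), 4096)$beta # 64
#' @export
compute_clip_limit <- function(params, region_pixels) {
  stopifnot(inherits(params, "clahe_params"))
  region_pixels <- as.integer(region_pixels)
  if (region_pixels < 1L) stop("region_pixels must be >= 1", call. = FALSE)
  beta <- (region_pixels / params$n_gray) *
    (1 + (params$alpha / 100) * (params$s_max - 1))
  structure(list(beta = beta, region_pixels = region_pixels,
                 n_gray = params$n_gray), class = "clip_limit")
}

#' Clip a tile histogram and redistribute the excess
#'
#' Caps every bin at the clip limit and spreads the clipped mass
#' uniformly over all bins, iterating (re-clipping what the
#' redistribution pushed back over the cap) until no bin exceeds
#' `ceiling(beta)` or the remaining excess is below one count. The total
#' count is conserved exactly.
#'
#' @param hist Integer histogram with `n_gray` non-negative bins.
#' @param limit A [compute_clip_limit()] result.
#' @return The clipped, redistributed histogram (integer counts, same
#'   length, same total).
#' @examples
#' h <- clip_and_redistribute(c(10, 0, 0, 0),
#'   structure(list(beta = 4), class = "clip_limit"))
#' sum(h) # 10
#' @export
clip_and_redistribute <- function(hist, limit) {
  stopifnot(inherits(limit, "clip_limit"))
  if (any(hist < 0)) stop("histogram bins must be non-negative", call. = FALSE)
  n <- length(hist)
  total <- sum(hist)
  if (total == 0) return(hist)
  cap <- ceiling(limit$beta)
  if (cap * n < total)
    stop("clip limit too small: capacity below the histogram total",
         call. = FALSE)
  h <- as.numeric(hist)
  for (iter in 1:256) {
    over <- pmax(h - cap, 0)
    excess <- sum(over)
    if (excess < 1) break
    h <- pmin(h, cap)
    share <- excess %/% n
    rem <- excess %% n
    h <- h + share
    if (rem > 0) {
      # remainder goes one count each to the lowest-index bins with room
      room <- which(h < cap)
      if (length(room) == 0L) room <- seq_len(n)
      pick <- rep_len(room, rem)
      add <- tabulate(pick, nbins = n)
      h <- h + add
    }
  }
  # any sub-unit residue stays in the lowest bin so the total is exact
  over <- pmax(h - cap, 0)
  if (sum(over) >= 1) {
    h <- pmin(h, cap)
    room <- which(h < cap)
    for (i in seq_len(sum(over))) {
      h[room[1L]] <- h[room[1L]] + 1
      if (h[room[1L]] >= cap) room <- room[-1L]
    }
  }
  h
}

# per-tile gray-level mapping: clipped-histogram CDF stretched over the
# full range; a degenerate (single-level) tile maps identically so that
# constant regions are fixed points
tile_mapping <- function(counts, params, M) {
  nz <- which(counts > 0)
  if (length(nz) <= 1L) return(seq_len(params$n_gray) - 1L)
  lim <- compute_clip_limit(params, M)
  h <- clip_and_redistribute(counts, lim)
  cdf <- cumsum(h)
  round((params$n_gray - 1) * cdf / sum(h))
}

reflect_pad <- function(m, right, bottom) {
  if (right > 0) m <- rbind(m, m[nrow(m):(nrow(m) - right + 1L), , drop = FALSE])
  if (bottom > 0) m <- cbind(m, m[, ncol(m):(ncol(m) - bottom + 1L), drop = FALSE])
  m
}

# CLAHE on a single integer gray-level image (values 0 .. n_gray-1)
equalize_gray_int <- function(img, params) {
  h0 <- nrow(img); w0 <- ncol(img)
  ty <- params$tiles_y; tx <- params$tiles_x
  if (h0 < ty || w0 < tx)
    stop("frame (", h0, " x ", w0, ") smaller than the tile grid",
         call. = FALSE)
  th <- ceiling(h0 / ty); tw <- ceiling(w0 / tx)
  img <- reflect_pad(img, ty * th - h0, tx * tw - w0)
  hh <- nrow(img); ww <- ncol(img)
  M <- th * tw
  ng <- params$n_gray
  maps <- array(0L, c(ng, ty, tx))
  for (j in seq_len(tx)) for (i in seq_len(ty)) {
    tile <- img[((i - 1L) * th + 1L):(i * th), ((j - 1L) * tw + 1L):(j * tw)]
    counts <- tabulate(as.vector(tile) + 1L, nbins = ng)
    maps[, i, j] <- tile_mapping(counts, params, M)
  }
  # bilinear blend between the four neighbouring tile mappings; border
  # and corner regions fall back to two / one mapping via clamping
  gy <- (seq_len(hh) - 0.5) / th - 0.5
  gx <- (seq_len(ww) - 0.5) / tw - 0.5
  y0 <- floor(gy); fy <- gy - y0
  x0 <- floor(gx); fx <- gx - x0
  y0c <- pmin(pmax(y0, 0), ty - 1L); y1c <- pmin(pmax(y0 + 1, 0), ty - 1L)
  x0c <- pmin(pmax(x0, 0), tx - 1L); x1c <- pmin(pmax(x0 + 1, 0), tx - 1L)
  v <- as.vector(img) + 1L
  ri <- rep(seq_len(hh), times = ww)
  ci <- rep(seq_len(ww), each = hh)
  m00 <- maps[cbind(v, y0c[ri] + 1L, x0c[ci] + 1L)]
  m10 <- maps[cbind(v, y1c[ri] + 1L, x0c[ci] + 1L)]
  m01 <- maps[cbind(v, y0c[ri] + 1L, x1c[ci] + 1L)]
  m11 <- maps[cbind(v, y1c[ri] + 1L, x1c[ci] + 1L)]
  wy <- fy[ri]; wx <- fx[ci]
  out <- (1 - wy) * (1 - wx) * m00 + wy * (1 - wx) * m10 +
    (1 - wy) * wx * m01 + wy * wx * m11
  out <- matrix(as.integer(round(out)), hh, ww)
  out[seq_len(h0), seq_len(w0), drop = FALSE]
}

#' Contrast-limited adaptive histogram equalization of a frame
#'
#' Applies CLAHE to an RGB frame. In `"lab"` mode (default) the frame is
#' converted sRGB to Lab, the lightness channel alone is quantised to
#' `n_gray` levels and equalised, and the result converted back,
#' preserving the hue of the mucosa. In `"rgb"` mode each channel is
#' equalised independently.
#'
#' @param frame Numeric `(h, w, 3)` array in `[0, 1]` (or 0..255; the
#'   input scale is preserved), or an `(h, w)` matrix treated as a
#'   single gray channel.
#' @param params A [clahe_params()].
#' @param mode `"lab"` or `"rgb"`.
#' @return Equalised frame, same dimensions and scale as the input.
#' @examples
#' f <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' g <- equalize_frame(f, clahe_params(tiles_x = 4, tiles_y = 4))
#' dim(g)
#' @export
equalize_frame <- function(frame, params = clahe_params(),
                           mode = c("lab", "rgb")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "clahe_params"))
  d <- dim(frame)
  if (is.null(d) || length(frame) == 0L)
    stop("frame must be a non-empty matrix or array", call. = FALSE)
  gray_only <- length(d) == 2L
  if (gray_only) { frame <- array(frame, c(d, 1L)); d <- dim(frame) }
  scale255 <- max(frame) > 1
  f01 <- if (scale255) frame / 255 else frame
  ng <- params$n_gray
  if (mode == "rgb" || gray_only || d[3] == 1L) {
    out <- f01
    for (ch in seq_len(d[3])) {
      q <- matrix(as.integer(round(f01[, , ch] * (ng - 1))), d[1], d[2])
      out[, , ch] <- equalize_gray_int(q, params) / (ng - 1)
    }
  } else {
    px <- matrix(f01, d[1] * d[2], 3)
    lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
    q <- matrix(as.integer(round(pmin(pmax(lab[, 1] / 100, 0), 1) * (ng - 1))),
                d[1], d[2])
    lab[, 1] <- as.vector(equalize_gray_int(q, params)) / (ng - 1) * 100
    rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
    out <- array(pmin(pmax(rgb, 0), 1), d)
  }
  if (gray_only) out <- out[, , 1L]
  if (scale255) out * 255 else out
}

#' Equalize every frame of a dataset folder
#'
#' Reads each image in `in_dir`, applies [equalize_frame()] and writes
#' the result under the same filename in `out_dir`. Masks are never
#' touched by this step: preprocessing applies to the images folder
#' only, as an explicit stage. Unreadable files are skipped with a
#' warning and excluded from the returned count.
#'
#' @param in_dir Folder of input frames (PNG/JPEG).
#' @param out_dir Output folder, created if missing.
#' @param params A [clahe_params()].
#' @param mode Passed to [equalize_frame()].
#' @return Number of frames written.
#' @export
preprocess_dataset <- function(in_dir, out_dir, params = clahe_params(),
                               mode = c("lab", "rgb")) {
  mode <- match.arg(mode)
  if (!dir.exists(in_dir)) stop("no such directory: ", in_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list_image_files(in_dir)
  written <- 0L
  for (f in files) {
    ok <- tryCatch({
      img <- read_frame(file.path(in_dir, f))
      eq <- equalize_frame(img, params, mode)
      write_frame(eq, file.path(out_dir, f))
      TRUE
    }, error = function(e) {
      warning("skipping unreadable frame ", f, ": ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) written <- written + 1L
  }
  written
}
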