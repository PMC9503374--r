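# Independent oracles used by the tests. Deliberately written in the
# most literal way possible (scalar loops, direct formula evaluation)
# so they share no code path with the package implementation.

# Unclipped tile-adaptive histogram equalization: per-tile CDF mapping
# (identity for single-level tiles), bilinear blending between the four
# neighbouring tile mappings, all with explicit per-pixel loops.
# Requires image dimensions that are exact multiples of the tile grid.
oracle_tile_ahe <- function(img, tiles_y, tiles_x, n_gray = 256L) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(h %% tiles_y == 0, w %% tiles_x == 0)
  th <- h %/% tiles_y; tw <- w %/% tiles_x
  M <- th * tw
  maps <- vector("list", tiles_y * tiles_x)
  for (i in seq_len(tiles_y)) for (j in seq_len(tiles_x)) {
    tile <- img[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
    counts <- rep(0L, n_gray)
    for (v in as.vector(tile)) counts[v + 1] <- counts[v + 1] + 1L
    if (sum(counts > 0) <= 1) {
      mp <- 0:(n_gray - 1)
    } else {
      cdf <- cumsum(counts)
      mp <- round((n_gray - 1) * cdf / M)
    }
    maps[[(i - 1) * tiles_x + j]] <- mp
  }
  getmap <- function(ti, tj, v) maps[[(ti - 1) * tiles_x + tj]][v + 1]
  out <- img
  for (y in seq_len(h)) for (x in seq_len(w)) {
    gy <- (y - 0.5) / th - 0.5
    gx <- (x - 0.5) / tw - 0.5
    y0 <- floor(gy); fy <- gy - y0
    x0 <- floor(gx); fx <- gx - x0
    cl <- function(t, lim) min(max(t, 0), lim - 1)
    y0c <- cl(y0, tiles_y); y1c <- cl(y0 + 1, tiles_y)
    x0c <- cl(x0, tiles_x); x1c <- cl(x0 + 1, tiles_x)
    v <- img[y, x]
    val <- (1 - fy) * (1 - fx) * getmap(y0c + 1, x0c + 1, v) +
      fy * (1 - fx) * getmap(y1c + 1, x0c + 1, v) +
      (1 - fy) * fx * getmap(y0c + 1, x1c + 1, v) +
      fy * fx * getmap(y1c + 1, x1c + 1, v)
    out[y, x] <- round(val)
  }
  out
}

# Brute-force iterative clip-and-redistribute on integer histograms.
oracle_redistribute <- function(hist, beta) {
  cap <- ceiling(beta)
  h <- hist
  for (iter in 1:10000) {
    excess <- sum(pmax(h - cap, 0))
    if (excess < 1) break
    h <- pmin(h, cap)
    while (excess >= 1) {
      placed <- FALSE
      for (i in seq_along(h)) {
        if (excess < 1) break
        if (h[i] < cap) { h[i] <- h[i] + 1; excess <- excess - 1; placed <- TRUE }
      }
      if (!placed) break
    }
  }
  h
}

# Direct-summation 3x3 same convolution on a (h, w, cin) array.
oracle_conv3 <- function(x, w4, bias) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(w4)[4]
  xp <- array(0, c(h + 2, w + 2, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  out <- array(0, c(h, w, cout))
  for (co in seq_len(cout)) for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- bias[co]
    for (ci in seq_len(cin)) for (di in 0:2) for (dj in 0:2)
      s <- s + xp[i + di, j + dj, ci] * w4[di + 1, dj + 1, ci, co]
    out[i, j, co] <- s
  }
  out
}

# Inference-mode batch norm + ReLU, straight from the formulas.
oracle_bn_eval <- function(x, run_mean, run_var, scale, shift, eps = 1e-5) {
  out <- x
  for (ch in seq_len(dim(x)[3]))
    out[, , ch] <- (x[, , ch] - run_mean[ch]) / sqrt(run_var[ch] + eps) *
      scale[ch] + shift[ch]
  out
}

# Boundary pixel count by explicit neighbour scan (8-neighbourhood,
# outside the frame counts as background).
oracle_boundary_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  cnt <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] != 1) next
    edge <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w || mask[ii, jj] == 0)
        edge <- TRUE
    }
    if (edge) cnt <- cnt + 1L
  }
  cnt
}

# Metrics from first principles on a pooled pixel vector.
oracle_pooled_metrics <- function(pred_pixels, gt_pixels, threshold) {
  p <- pred_pixels >= threshold
  g <- gt_pixels == 1
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  c(mdice = 2 * tp / (2 * tp + fp + fn), miou = tp / (tp + fp + fn),
    recall = tp / (tp + fn), precision = tp / (tp + fp),
    f2 = 5 * (tp / (tp + fp)) * (tp / (tp + fn)) /
      (4 * (tp / (tp + fp)) + tp / (tp + fn)),
    accuracy = (tp + tn) / (tp + fp + fn + tn))
}

make_index <- function(names, images, masks) {
  structure(data.frame(name = names, image = images, mask = masks,
                       stringsAsFactors = FALSE),
            class = c("dataset_index", "data.frame"),
            source_layout = "paired-folders")
}
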