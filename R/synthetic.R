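#' Synthetic colonoscopy-frame generator configuration
#'
#' Recipe for colonoscopy-like test frames: a pink-red low-frequency
#' mucosa background darkened toward one corner (the lumen), optional
#' specular highlights, and 1-3 raised polyp blobs per frame, each a
#' smoothly perturbed ellipse brighter and redder than the surrounding
#' mucosa, with a pixel-exact binary mask. The generator emulates the
#' paired-folder structure of real polyp datasets so that every other
#' module can be exercised without external downloads; it does not
#' attempt photorealism.
#'
#' @param n_frames Number of frames to generate.
#' @param frame_size Square frame side in pixels (64 at test scale, up
#'   to 512).
#' @param polyps_per_frame Integer range `c(min, max)` of polyps drawn
#'   per frame.
#' @param polyp_radius_frac Range of the polyp semi-axis as a fraction
#'   of the frame side.
#' @param highlight_prob Probability that a frame carries bright
#'   specular spots (these are never part of the mask).
#' @param noise_sd Additive Gaussian noise standard deviation in gray
#'   levels (0-255 scale).
#' @param min_contrast Guaranteed minimum difference between the mean
#'   luminance inside and outside the mask, on the `[0, 1]` scale; this
#'   floor is what makes the segmentation task learnable by
#'   construction.
#' @param seed Base seed; frame `i` is drawn with seed `seed + i`, so a
#'   dataset is bit-reproducible and any single frame can be recreated.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_frames = 20L, frame_size = 64L,
                             polyps_per_frame = c(1L, 3L),
                             polyp_radius_frac = c(0.08, 0.25),
                             highlight_prob = 0.3, noise_sd = 5,
                             min_contrast = 0.10, seed = 1L) {
  if (frame_size < 8L) stop("frame_size must be >= 8", call. = FALSE)
  if (length(polyps_per_frame) != 2L || any(polyps_per_frame < 0L) ||
      polyps_per_frame[1] > polyps_per_frame[2])
    stop("polyps_per_frame must be a c(min, max) range", call. = FALSE)
  if (any(polyp_radius_frac <= 0) || any(polyp_radius_frac >= 0.5))
    stop("polyp_radius_frac must lie in (0, 0.5)", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames),
                 frame_size = as.integer(frame_size),
                 polyps_per_frame = as.integer(polyps_per_frame),
                 polyp_radius_frac = polyp_radius_frac,
                 highlight_prob = highlight_prob, noise_sd = noise_sd,
                 min_contrast = min_contrast, seed = as.integer(seed)),
            class = "synthetic_config")
}

luminance <- function(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]

# support of one blob: ellipse with a low-order radial Fourier
# perturbation, evaluated on the pixel grid
blob_support <- function(s, cx, cy, a, b, phi) {
  ks <- 2:4
  amp <- runif(3, 0, 0.12)
  psi <- runif(3, 0, 2 * pi)
  x <- rep(seq_len(s), times = s) - cx
  y <- rep(seq_len(s), each = s) - cy
  u <- cos(phi) * x + sin(phi) * y
  v <- -sin(phi) * x + cos(phi) * y
  rho <- sqrt((u / a)^2 + (v / b)^2)
  theta <- atan2(v / b, u / a)
  rmax <- 1 + amp[1] * cos(ks[1] * theta + psi[1]) +
    amp[2] * cos(ks[2] * theta + psi[2]) +
    amp[3] * cos(ks[3] * theta + psi[3])
  matrix(rho <= rmax, s, s)  # rho normalised by rmax gives the shading
}

#' Generate one synthetic frame and its mask
#'
#' Draws a mucosa background, the configured number of polyp blobs and
#' optional specular highlights, then adds pixel noise. The mask is the
#' exact union of the polyp supports; highlights and noise never enter
#' it. The polyp cores are shifted towards a brighter, redder tone by at
#' least `min_contrast` luminance over the local background.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Optional seed; when given, the global RNG state is left
#'   untouched and the frame is a pure function of `(cfg, seed)`.
#' @return List with `image` (`(s, s, 3)` array in `[0, 1]`) and `mask`
#'   (`(s, s)` matrix in `{0, 1}`).
#' @export
generate_frame <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  s <- cfg$frame_size
  xg <- matrix(rep(seq_len(s), times = s), s, s) / s
  yg <- matrix(rep(seq_len(s), each = s), s, s) / s
  base <- c(0.72, 0.38, 0.34) + runif(3, -0.05, 0.05)
  # low-frequency tint variation
  w1 <- runif(2, 1, 2.5); ph <- runif(2, 0, 2 * pi)
  mod <- 0.06 * sin(2 * pi * w1[1] * xg + ph[1]) +
    0.06 * sin(2 * pi * w1[2] * yg + ph[2])
  # vignette: darken towards a random corner (the lumen)
  corner <- c(sample(c(0, 1), 1), sample(c(0, 1), 1))
  dist <- sqrt((xg - corner[1])^2 + (yg - corner[2])^2)
  vign <- 0.78 + 0.22 * pmin(dist / 0.9, 1)
  img <- array(0, c(s, s, 3))
  for (ch in 1:3) img[, , ch] <- pmin(pmax((base[ch] + mod) * vign, 0), 1)

  mask <- matrix(0, s, s)
  n_pol <- if (cfg$polyps_per_frame[1] == cfg$polyps_per_frame[2])
    cfg$polyps_per_frame[1] else
      sample(cfg$polyps_per_frame[1]:cfg$polyps_per_frame[2], 1L)
  # the core shift exceeds the floor by enough to absorb rim shading and
  # the lumen-side vignette, keeping the inside/outside contrast guarantee
  shift <- cfg$min_contrast + 0.12
  for (p in seq_len(n_pol)) {
    a <- runif(1, cfg$polyp_radius_frac[1], cfg$polyp_radius_frac[2]) * s
    b <- runif(1, cfg$polyp_radius_frac[1], cfg$polyp_radius_frac[2]) * s
    m <- max(a, b)
    cx <- runif(1, 1 + m, s - m); cy <- runif(1, 1 + m, s - m)
    phi <- runif(1, 0, pi)
    sup <- blob_support(s, cx, cy, a, b, phi)
    if (!any(sup)) next
    # dome shading: bright centre, softly darker rim, all inside support
    dx <- (matrix(rep(seq_len(s), times = s), s, s) - cx) / a
    dy <- (matrix(rep(seq_len(s), each = s), s, s) - cy) / b
    r2 <- pmin(dx^2 + dy^2, 1)
    dome <- 1 - 0.35 * r2
    tone <- c(shift * 1.45, shift * 0.7, shift * 0.35)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[sup] <- pmin(pl[sup] + tone[ch] * dome[sup] + 0.02, 1)
      img[, , ch] <- pl
    }
    mask[sup] <- 1
  }
  if (runif(1) < cfg$highlight_prob) {
    for (hgl in seq_len(sample(1:3, 1L))) {
      hr <- runif(1, 0.015, 0.04) * s + 1
      hx <- runif(1, 1, s); hy <- runif(1, 1, s)
      d2 <- ((matrix(rep(seq_len(s), times = s), s, s) - hx) / hr)^2 +
        ((matrix(rep(seq_len(s), each = s), s, s) - hy) / (0.6 * hr))^2
      spot <- d2 <= 1
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[spot] <- pmin(pl[spot] + 0.45, 1)
        img[, , ch] <- pl
      }
    }
  }
  # enforce the advertised contrast floor: if shading, vignette or
  # highlights ate into the inside/outside luminance separation, lift the
  # whole polyp region uniformly (margin absorbs the zero-mean noise)
  if (any(mask == 1) && any(mask == 0)) {
    lum <- luminance(img)
    deficit <- (cfg$min_contrast + 0.04) -
      (mean(lum[mask == 1]) - mean(lum[mask == 0]))
    if (deficit > 0) {
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[mask == 1] <- pmin(pl[mask == 1] + deficit, 1)
        img[, , ch] <- pl
      }
    }
  }
  if (cfg$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd / 255), dim(img))
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, mask = mask)
}

#' Write a synthetic dataset in the paired-folder layout
#'
#' Generates `cfg$n_frames` frame/mask pairs and writes them as PNGs
#' with identical filenames into the two folders, ready for
#' [index_dataset()]. Masks are written as 0/255 grayscale.
#'
#' @param cfg A [synthetic_config()].
#' @param out_images_dir,out_masks_dir Output folders (created if
#'   missing).
#' @return The [index_dataset()] of the written pairs.
#' @export
generate_dataset <- function(cfg, out_images_dir, out_masks_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_images_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(out_masks_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(cfg$n_frames)) {
    fr <- generate_frame(cfg, seed = cfg$seed + i)
    nm <- sprintf("synth_%04d.png", i)
    write_frame(fr$image, file.path(out_images_dir, nm))
    write_frame(fr$mask, file.path(out_masks_dir, nm))
  }
  index_dataset(out_images_dir, out_masks_dir)
}
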