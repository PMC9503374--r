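test_that("clip limit follows the Reza formula and its alpha = 0 floor", {
  cases <- list(
    list(alpha = 0, smax = 4, beta = 16),    # floor M/N
    list(alpha = 100, smax = 4, beta = 64),
    list(alpha = 50, smax = 3, beta = 32))
  for (cs in cases) {
    cl <- compute_clip_limit(clahe_params(alpha = cs$alpha, s_max = cs$smax),
                             region_pixels = 4096)
    expect_equal(cl$beta, cs$beta)
    expect_gte(cl$beta, 4096 / 256)
  }
})

test_that("clip limit is monotone in alpha and s_max", {
  for (sm in c(1, 2, 4, 8)) {
    betas <- vapply(seq(0, 100, by = 10), function(a)
      compute_clip_limit(clahe_params(alpha = a, s_max = sm), 1000)$beta,
      numeric(1))
    expect_true(all(diff(betas) >= 0))
  }
  for (a in c(0, 30, 100)) {
    betas <- vapply(c(1, 2, 4, 10), function(sm)
      compute_clip_limit(clahe_params(alpha = a, s_max = sm), 1000)$beta,
      numeric(1))
    expect_true(all(diff(betas) >= 0))
  }
})

test_that("parameter domains are enforced", {
  expect_error(clahe_params(alpha = -1), "alpha")
  expect_error(clahe_params(alpha = 101), "alpha")
  expect_error(clahe_params(s_max = 0.5), "s_max")
  expect_error(clahe_params(n_gray = 1), "n_gray")
  expect_error(compute_clip_limit(clahe_params(), 0), "region_pixels")
})

test_that("clip-and-redistribute conserves mass and caps bins", {
  lim <- function(beta) structure(list(beta = beta), class = "clip_limit")
  # nothing to clip
  h <- c(2, 3, 1, 0)
  expect_equal(clip_and_redistribute(h, lim(4)), h, ignore_attr = TRUE)
  # all-zero histogram unchanged
  expect_equal(clip_and_redistribute(rep(0, 8), lim(1)), rep(0, 8))
  # concentrated bin: conserved, capped, and every other bin receives
  # redistributed mass (cross-checked against the brute-force oracle)
  h <- c(10, 0, 0, 0)
  out <- clip_and_redistribute(h, lim(4))
  expect_equal(sum(out), 10)
  expect_true(all(out <= 4))
  expect_true(all(out[2:4] > 0))
  orc <- oracle_redistribute(h, 4)
  expect_equal(sum(orc), 10)
  expect_true(all(orc <= 4) && all(orc[2:4] > 0))
  # randomized: exact conservation, cap respected
  set.seed(5)
  for (rep_i in 1:25) {
    n <- sample(c(8, 16, 64), 1)
    h <- rpois(n, lambda = sample(1:30, 1))
    beta <- max(sum(h) / n, mean(h) * runif(1, 1, 3))
    out <- clip_and_redistribute(h, lim(beta))
    expect_equal(sum(out), sum(h))
    expect_true(all(out <= ceiling(beta)))
  }
})

test_that("constant frames are fixed points of equalization", {
  f <- array(100 / 255, c(32, 32, 3))
  p <- clahe_params(tiles_x = 4, tiles_y = 4, alpha = 20, s_max = 4)
  expect_equal(equalize_frame(f, p, mode = "rgb"), f)
  # lab mode round-trips through a colour space; constancy is preserved
  g <- equalize_frame(f, p, mode = "lab")
  for (ch in 1:3) expect_lt(diff(range(g[, , ch])), 1e-12)
})

test_that("unclipped equalization matches the independent tile-AHE oracle", {
  set.seed(7)
  for (sz in c(24, 32)) {
    img <- matrix(sample(0:255, sz * sz, replace = TRUE,
                         prob = (1:256)^-0.5), sz, sz)
    p <- clahe_params(tiles_x = 4, tiles_y = 4, alpha = 100, s_max = 256)
    got <- equalize_frame(array(img / 255, c(sz, sz, 3)), p, mode = "rgb")
    want <- oracle_tile_ahe(img, 4, 4)
    for (ch in 1:3)
      expect_equal(round(got[, , ch] * 255), want, ignore_attr = TRUE)
  }
})

test_that("equalization raises the contrast of low-contrast frames", {
  set.seed(11)
  base <- matrix(120 + 8 * sin(seq(0, 4, length.out = 48)), 48, 48)
  img <- pmin(pmax(round(base + matrix(rnorm(48 * 48, 0, 3), 48, 48)), 0), 255)
  f <- array(img / 255, c(48, 48, 3))
  g <- equalize_frame(f, clahe_params(tiles_x = 4, tiles_y = 4), mode = "rgb")
  expect_gte(sd(g[, , 1]), sd(f[, , 1]))
})

test_that("frames that do not fit the tile grid are padded and cropped back", {
  set.seed(3)
  f <- array(runif(37 * 45 * 3), c(37, 45, 3))
  g <- equalize_frame(f, clahe_params(tiles_x = 4, tiles_y = 4))
  expect_identical(dim(g), dim(f))
  expect_error(equalize_frame(array(0.5, c(3, 3, 3)),
                              clahe_params(tiles_x = 8, tiles_y = 8)),
               "tile grid")
})

test_that("dataset preprocessing writes equalized copies and skips junk", {
  src <- file.path(tempdir(), "pp_in"); dst <- file.path(tempdir(), "pp_out")
  unlink(c(src, dst), recursive = TRUE)
  dir.create(src)
  cfg <- synthetic_config(n_frames = 1, frame_size = 32, seed = 2)
  for (i in 1:3) {
    fr <- generate_frame(cfg, seed = i)
    graftunet:::write_frame(fr$image, file.path(src, sprintf("f%d.png", i)))
  }
  writeLines("not a png", file.path(src, "broken.png"))
  expect_warning(n <- preprocess_dataset(src, dst,
                                         clahe_params(tiles_x = 4, tiles_y = 4)),
                 "broken")
  expect_identical(n, 3L)
  expect_setequal(list.files(dst), sprintf("f%d.png", 1:3))
})
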