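small_arch <- function() arch_config(input_h = 64, input_w = 64,
                                     filter_depths = c(2L, 3L, 4L, 6L, 2L))

# neutralise a BN layer so that inference-mode normalisation is the
# exact identity: 1/sqrt((1 - eps) + eps) = 1
neutral_bn <- function(m, nm) {
  pr <- m$params[[nm]]
  pr$run_mean[] <- 0; pr$run_var[] <- 1 - pr$eps
  pr$scale[] <- 1; pr$shift[] <- 0
  m$params[[nm]] <- pr
}

test_that("batch normalisation centres and scales as the formulas say", {
  out <- batch_normalize(c(1, 3), eps = 1e-12)
  expect_equal(out, c(-1, 1), tolerance = 1e-6)
  expect_equal(batch_normalize(rep(5, 10)), rep(0, 10))
  set.seed(1)
  x <- matrix(rnorm(200, mean = 7, sd = 3), 50, 4)
  y <- batch_normalize(x)
  expect_true(all(abs(colMeans(y)) < 1e-6))
  expect_true(all(abs(apply(y, 2, function(v)
    mean(v^2) - mean(v)^2) - 1) < 1e-3))
})

test_that("squeeze-excitation gates are bounded and exactly computable", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  # near-unit gate: zero weights, large expansion bias
  w_id <- list(w1 = matrix(0, 4, 2), b1 = rep(0, 2),
               w2 = matrix(0, 2, 4), b2 = rep(30, 4))
  expect_equal(squeeze_excite(x, weights = w_id), x,
               tolerance = 1e-10, ignore_attr = TRUE)
  # random gate: per-channel magnitudes never grow
  y <- squeeze_excite(x, reduction = 2)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  g <- attr(y, "gates")
  expect_true(all(g > 0 & g < 1))
  # 1x1x4 input: hand-computed two-layer gate
  v <- c(0.5, -1, 2, 0.25)
  w1 <- matrix(c(0.2, -0.1, 0.3, 0.4, -0.5, 0.6, 0.1, 0.2), 4, 2)
  b1 <- c(0.05, -0.02)
  w2 <- matrix(seq(-0.4, 0.3, length.out = 8), 2, 4)
  b2 <- c(0.1, 0.2, -0.1, 0)
  z1 <- pmax(as.vector(v %*% w1) + b1, 0)
  gate <- 1 / (1 + exp(-(as.vector(z1 %*% w2) + b2)))
  got <- squeeze_excite(array(v, c(1, 1, 4)),
                        weights = list(w1 = w1, b1 = b1, w2 = w2, b2 = b2))
  expect_equal(as.vector(got), v * gate, tolerance = 1e-12)
})

test_that("a graft block is the exact sum of its two branches", {
  m <- build_network(small_arch(), seed = 3)
  set.seed(4)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))  # stage-4 input
  h_full <- graft_block_forward(m, x, stage = 4)

  zero_conv <- function(m, nm) {
    pr <- m$params[[nm]]; pr$w[] <- 0; pr$b[] <- 0; m$params[[nm]] <- pr
  }
  m_conv <- build_network(small_arch(), seed = 3)
  zero_conv(m_conv, "C12")  # graft branch off
  h_conv <- graft_block_forward(m_conv, x, stage = 4)
  m_graft <- build_network(small_arch(), seed = 3)
  zero_conv(m_graft, "C11")  # conventional branch off
  h_graft <- graft_block_forward(m_graft, x, stage = 4)
  expect_equal(h_full, h_conv + h_graft, tolerance = 1e-12)
})

test_that("graft block forward matches an independent per-element reference", {
  m <- build_network(small_arch(), seed = 5)
  set.seed(6)
  # randomise the batch-norm statistics so inference mode is non-trivial
  for (nm in c("BN10", "BN11", "BN12")) {
    pr <- m$params[[nm]]
    pr$run_mean <- rnorm(pr$c, 0, 0.3)
    pr$run_var <- runif(pr$c, 0.5, 2)
    pr$scale <- runif(pr$c, 0.5, 1.5)
    pr$shift <- rnorm(pr$c, 0, 0.2)
    m$params[[nm]] <- pr
  }
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  ref_cba <- function(x, conv, bn) {
    w4 <- array(conv$w, c(3, 3, conv$cin, conv$cout))
    z <- oracle_conv3(x, w4, conv$b)
    z <- oracle_bn_eval(z, bn$run_mean, bn$run_var, bn$scale, bn$shift, bn$eps)
    pmax(z, 0)
  }
  stem <- ref_cba(x, m$params$C10, m$params$BN10)
  want <- ref_cba(stem, m$params$C11, m$params$BN11) +
    ref_cba(stem, m$params$C12, m$params$BN12)
  got <- graft_block_forward(m, x, stage = 4)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("identity branches double the stem output", {
  m <- build_network(small_arch(), seed = 7)
  d <- 6L  # stage-4 depth
  for (nm in c("C11", "C12")) {
    pr <- m$params[[nm]]
    w4 <- array(0, c(3, 3, d, d))
    for (ch in seq_len(d)) w4[2, 2, ch, ch] <- 1
    pr$w <- matrix(w4, 9 * d, d); pr$b[] <- 0
    m$params[[nm]] <- pr
  }
  for (nm in c("BN11", "BN12")) neutral_bn(m, nm)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  stem <- {
    ref <- function(x, conv, bn) {
      w4 <- array(conv$w, c(3, 3, conv$cin, conv$cout))
      pmax(oracle_bn_eval(oracle_conv3(x, w4, conv$b), bn$run_mean,
                          bn$run_var, bn$scale, bn$shift, bn$eps), 0)
    }
    ref(x, m$params$C10, m$params$BN10)
  }
  expect_equal(graft_block_forward(m, x, stage = 4), 2 * stem,
               tolerance = 1e-6)
})

test_that("prediction is a pure function with outputs strictly in (0, 1)", {
  m <- build_network(small_arch(), seed = 8)
  set.seed(9)
  f <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- predict(m, f)
  expect_identical(dim(p1), c(64L, 64L))
  expect_true(all(p1 > 0 & p1 < 1))
  # duplicated frame in one batch: identical maps
  ps <- predict(m, list(f, f))
  expect_identical(ps[[1]], ps[[2]])
  # and across calls
  expect_identical(p1, predict(m, f))
  expect_error(predict(m, array(0.5, c(32, 32, 3))), "dimensions")
})

test_that("model checkpoints round-trip through save and load", {
  m <- build_network(small_arch(), seed = 10)
  f <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p0 <- predict(m, f)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, f), p0)
})
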