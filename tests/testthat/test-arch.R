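test_that("the window output-extent formula matches hand arithmetic", {
  expect_identical(conv_output_extent(512, 3, pad = 1, stride = 1), 512L)
  expect_identical(conv_output_extent(512, 3, pad = 1, stride = 2), 256L)
  expect_identical(conv_output_extent(512, 3, pad = 0, stride = 1), 510L)
  expect_error(conv_output_extent(2, 5, pad = 0), "padded input")
  expect_error(conv_output_extent(8, 3, stride = 0), "stride")
})

test_that("encoder stages propagate shapes as tabulated", {
  cfg <- arch_config()
  s1 <- build_encoder_stage(cfg, 1, c(h = 512, w = 512, c = 3))
  expect_equal(s1$pre_pool_shape, c(h = 512L, w = 512L, c = 8L))
  expect_equal(s1$post_pool_shape, c(h = 256L, w = 256L, c = 8L))
  s5 <- build_encoder_stage(cfg, 5, c(h = 32, w = 32, c = 48))
  expect_equal(s5$post_pool_shape, c(h = 16L, w = 16L, c = 64L))
  # small-input variant, shapes still governed by the same formula
  t1 <- build_encoder_stage(cfg, 1, c(h = 32, w = 32, c = 3))
  expect_equal(t1$post_pool_shape, c(h = 16L, w = 16L, c = 8L))
  expect_identical(s1$spec$branch_graft, "C3")
  expect_error(build_encoder_stage(cfg, 1, c(h = 2, w = 2, c = 3)),
               "pooling window")
})

test_that("decoder stages concatenate channels additively", {
  cfg <- arch_config()
  d1 <- build_decoder_stage(cfg, 1, c(h = 16, w = 16, c = 64),
                            c(h = 32, w = 32, c = 64))
  expect_equal(d1$cnc_shape, c(h = 32L, w = 32L, c = 128L))
  expect_equal(d1$out_shape, c(h = 32L, w = 32L, c = 64L))
  d5 <- build_decoder_stage(cfg, 5, c(h = 256, w = 256, c = 16),
                            c(h = 512, w = 512, c = 8))
  expect_equal(d5$cnc_shape, c(h = 512L, w = 512L, c = 24L))
  expect_equal(d5$out_shape, c(h = 512L, w = 512L, c = 8L))
  expect_error(build_decoder_stage(cfg, 2, c(h = 16, w = 16, c = 64),
                                   c(h = 64, w = 64, c = 48)),
               "stage 2")
})

test_that("the default trace reproduces the published table exactly", {
  m <- build_network(arch_config(), seed = 1)
  expect_identical(nrow(m$trace), 81L)
  expect_identical(nrow(verify_against_table2(m$trace)), 0L)
  cnc <- m$trace[m$trace$kind == "CNC", "channels"]
  expect_identical(cnc, c(128L, 112L, 80L, 48L, 24L))
  last <- m$trace[81, ]
  expect_identical(c(last$height, last$width, last$channels),
                   c(512L, 512L, 1L))
})

test_that("perturbed traces produce localized mismatches", {
  # simulate stride-1 pooling: the first MP row no longer halves
  m_bad <- build_network(arch_config(), seed = 1)
  mp1 <- which(m_bad$trace$kind == "MP")[1]
  m_bad$trace[mp1, c("height", "width")] <- c(512L, 512L)
  mm <- verify_against_table2(m_bad$trace)
  expect_gt(nrow(mm), 0)
  expect_true(all(mm$layer_no == mp1))
  # depth change in stage 4 only: first mismatch at the stage-4 rows
  m_d <- build_network(arch_config(filter_depths = c(8, 16, 32, 64, 64)),
                       seed = 1)
  md <- verify_against_table2(m_d$trace)
  expect_gt(nrow(md), 0)
  expect_true(all(md$layer_no >= 32))  # C10 group starts the stage-4 block
  expect_true(all(!grepl("^(C[1-9]|BN[1-9]|A[1-9])$", md$layer)))
})

test_that("networks scale to smaller inputs with the same topology", {
  m <- build_network(arch_config(input_h = 64, input_w = 64), seed = 1)
  last <- m$trace[nrow(m$trace), ]
  expect_identical(c(last$height, last$width, last$channels), c(64L, 64L, 1L))
  cnc <- m$trace[m$trace$kind == "CNC", ]
  expect_identical(cnc$channels, c(128L, 112L, 80L, 48L, 24L))
  expect_identical(cnc$height[1], 4L)
  expect_error(arch_config(input_h = 100, input_w = 100), "divisible")
})

test_that("every conv and pool extent in the graph obeys the closed form", {
  for (inp in c(512L, 64L)) {
    m <- build_network(arch_config(input_h = inp, input_w = inp), seed = 1)
    for (node in m$nodes) {
      if (!node$kind %in% c("conv", "maxpool")) next
      src <- m$nodes[[node$inputs[1]]]$shape
      expect_identical(node$shape[["h"]],
                       conv_output_extent(src[["h"]], node$ksz, node$pad,
                                          node$stride))
      expect_identical(node$shape[["w"]],
                       conv_output_extent(src[["w"]], node$ksz, node$pad,
                                          node$stride))
    }
  }
})

test_that("parameter counts match the per-layer formula oracle", {
  m <- build_network(arch_config(input_h = 64, input_w = 64), seed = 1)
  oracle <- 0L
  for (nm in ls(m$params)) {
    pr <- m$params[[nm]]
    oracle <- oracle + switch(pr$kind,
      conv = pr$k * pr$k * pr$cin * pr$cout + pr$cout,
      bn = 2L * pr$c,
      stop("unexpected param kind in default model"))
  }
  expect_identical(count_parameters(m), as.integer(oracle))
  # single conv layer: 3*3*3*8 + 8
  c1 <- m$params[["C1"]]
  expect_identical(length(c1$w) + length(c1$b), 224L)
  bn1 <- m$params[["BN1"]]
  expect_identical(2L * bn1$c, 16L)
})
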