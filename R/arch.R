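#' Network architecture configuration
#'
#' Describes the Graft-U-Net layer graph: a five-stage encoder whose
#' down-sample blocks each hold a stem convolution feeding two parallel
#' convolution branches (the conventional branch and the graft branch)
#' whose outputs are summed element-wise, a single-convolution bottleneck,
#' and a five-stage decoder of 2x up-sampling, skip concatenation and
#' convolution, closed by a 1-channel sigmoid head.
#'
#' @param input_h,input_w Input spatial extent in pixels. Both must be
#'   divisible by 32 so that five exact halvings are possible.
#' @param input_c Input channel count (3 for RGB frames).
#' @param filter_depths Channel depths of the five encoder stages. The
#'   decoder mirrors them in reverse.
#' @param kernel Convolution window side (square kernels).
#' @param pool_window,pool_stride Max-pooling window side and stride. The
#'   default 3x3 window with stride 2 and same padding halves each spatial
#'   dimension exactly.
#' @param se_enabled Add a squeeze-and-excitation gate after each encoder
#'   stage's branch addition. Off by default so the layer trace matches
#'   the published table, which does not list these layers.
#' @param se_reduction Channel reduction factor inside the gate.
#' @param upsample `"nearest"` for parameter-free nearest-neighbour 2x
#'   up-sampling (channel counts are preserved, matching the published
#'   shape table) or `"transposed"` for a learned 2x2 stride-2 transposed
#'   convolution.
#' @return An object of class `arch_config`.
#' @examples
#' cfg <- arch_config(input_h = 64, input_w = 64)
#' cfg$filter_depths
#' @export
arch_config <- function(input_h = 512L, input_w = 512L, input_c = 3L,
                        filter_depths = c(8L, 16L, 32L, 48L, 64L),
                        kernel = 3L, pool_window = 3L, pool_stride = 2L,
                        se_enabled = FALSE, se_reduction = 4L,
                        upsample = c("nearest", "transposed")) {
  upsample <- match.arg(upsample)
  input_h <- as.integer(input_h); input_w <- as.integer(input_w)
  input_c <- as.integer(input_c)
  filter_depths <- as.integer(filter_depths)
  if (length(filter_depths) != 5L || any(filter_depths < 1L))
    stop("`filter_depths` must be 5 positive integers", call. = FALSE)
  if (input_h %% 32L != 0L || input_w %% 32L != 0L)
    stop("input_h and input_w must be divisible by 2^5 = 32 so that ",
         "five poolings halve the frame exactly", call. = FALSE)
  if (input_c < 1L) stop("input_c must be >= 1", call. = FALSE)
  if (kernel < 1L || kernel %% 2L != 1L)
    stop("kernel must be an odd positive integer (same padding)", call. = FALSE)
  if (se_reduction < 1L) stop("se_reduction must be >= 1", call. = FALSE)
  structure(list(input_h = input_h, input_w = input_w, input_c = input_c,
                 filter_depths = filter_depths, kernel = as.integer(kernel),
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride),
                 se_enabled = isTRUE(se_enabled),
                 se_reduction = as.integer(se_reduction),
                 upsample = upsample),
            class = "arch_config")
}

#' Output extent of a convolution or pooling window
#'
#' Closed-form spatial output size `floor((i - f + 2p)/s) + 1` for a
#' window of side `f_size` slid with stride `stride` over an input of
#' side `i_size` padded by `pad` on each border. All conv and pool
#' extents in the layer trace are instances of this formula.
#'
#' @param i_size Input spatial extent (pixels).
#' @param f_size Window extent (pixels).
#' @param pad Padding per border (pixels).
#' @param stride Window stride.
#' @return Integer output extent.
#' @examples
#' conv_output_extent(512, 3, pad = 1, stride = 1) # 512, "same" conv
#' conv_output_extent(512, 3, pad = 1, stride = 2) # 256, halving pool
#' @export
conv_output_extent <- function(i_size, f_size, pad = 0L, stride = 1L) {
  if (any(stride < 1L)) stop("stride must be >= 1", call. = FALSE)
  if (any(pad < 0L)) stop("pad must be >= 0", call. = FALSE)
  num <- i_size - f_size + 2L * pad
  if (any(num < 0L))
    stop("window larger than padded input (i - f + 2p < 0)", call. = FALSE)
  as.integer(num %/% stride + 1L)
}

shape3 <- function(h, w, c) c(h = as.integer(h), w = as.integer(w), c = as.integer(c))

fmt_shape <- function(s) sprintf("%d x %d x %d", s[["h"]], s[["w"]], s[["c"]])

#' Describe one encoder down-sample block
#'
#' Resolves the layer names and feature-map shapes of encoder stage
#' `stage`: a stem convolution raising the channel count to the stage
#' depth, two parallel convolution branches fed from the stem (the
#' conventional branch and the graft branch), their element-wise sum, an
#' optional squeeze-and-excitation gate, and a halving max-pool. The
#' pre-pool sum is what the mirrored decoder stage later receives as its
#' skip connection.
#'
#' @param cfg An [arch_config()].
#' @param stage Encoder stage index, 1 to 5.
#' @param in_shape Named vector `c(h=, w=, c=)` of the incoming feature map.
#' @return A list with `spec` (a `graft_block_spec`), `pre_pool_shape`
#'   and `post_pool_shape`.
#' @examples
#' st <- build_encoder_stage(arch_config(), 1, c(h = 512, w = 512, c = 3))
#' st$post_pool_shape
#' @export
build_encoder_stage <- function(cfg, stage, in_shape) {
  stopifnot(inherits(cfg, "arch_config"), stage %in% 1:5)
  depth <- cfg$filter_depths[stage]
  k <- cfg$kernel; p <- (k - 1L) %/% 2L
  if (in_shape[["h"]] < cfg$pool_window || in_shape[["w"]] < cfg$pool_window)
    stop("stage ", stage, ": spatial dims smaller than the pooling window",
         call. = FALSE)
  if (in_shape[["h"]] %% 2L != 0L || in_shape[["w"]] %% 2L != 0L)
    stop("stage ", stage, ": spatial dims must be even for an exact halving",
         call. = FALSE)
  hs <- conv_output_extent(in_shape[["h"]], k, p, 1L)
  ws <- conv_output_extent(in_shape[["w"]], k, p, 1L)
  body_shape <- shape3(hs, ws, depth)
  pp <- (cfg$pool_window - 1L) %/% 2L
  post <- shape3(conv_output_extent(hs, cfg$pool_window, pp, cfg$pool_stride),
                 conv_output_extent(ws, cfg$pool_window, pp, cfg$pool_stride),
                 depth)
  base <- (stage - 1L) * 3L
  spec <- structure(list(
    stage_index = stage, depth = depth,
    stem = sprintf("C%d", base + 1L),
    branch_conventional = sprintf("C%d", base + 2L),
    branch_graft = sprintf("C%d", base + 3L),
    in_shape = in_shape, body_shape = body_shape,
    se = cfg$se_enabled), class = "graft_block_spec")
  list(spec = spec, pre_pool_shape = body_shape, post_pool_shape = post)
}

#' Describe one decoder up-sample block
#'
#' Resolves the shapes of decoder stage `stage`: 2x up-sampling of the
#' incoming stream, channel concatenation with the mirrored encoder
#' stage's pre-pool feature map, and a convolution down to the stage
#' depth. The concatenated channel count is always the sum of its two
#' inputs' channel counts.
#'
#' @inheritParams build_encoder_stage
#' @param stage Decoder stage index, 1 (deepest) to 5 (full resolution).
#' @param in_shape Shape of the incoming decoder stream.
#' @param skip_shape Shape of the encoder skip feature map; its spatial
#'   dims must equal the up-sampled spatial dims.
#' @return A list with `spec`, `ups_shape`, `cnc_shape`, `out_shape`.
#' @examples
#' dec <- build_decoder_stage(arch_config(), 1,
#'                            c(h = 16, w = 16, c = 64),
#'                            c(h = 32, w = 32, c = 64))
#' dec$cnc_shape # 32 x 32 x 128
#' @export
build_decoder_stage <- function(cfg, stage, in_shape, skip_shape) {
  stopifnot(inherits(cfg, "arch_config"), stage %in% 1:5)
  depth <- rev(cfg$filter_depths)[stage]
  ups <- shape3(2L * in_shape[["h"]], 2L * in_shape[["w"]], in_shape[["c"]])
  if (ups[["h"]] != skip_shape[["h"]] || ups[["w"]] != skip_shape[["w"]])
    stop("decoder stage ", stage, ": up-sampled map is ",
         fmt_shape(ups), " but the skip is ", fmt_shape(skip_shape),
         call. = FALSE)
  cnc <- shape3(ups[["h"]], ups[["w"]], ups[["c"]] + skip_shape[["c"]])
  out <- shape3(cnc[["h"]], cnc[["w"]], depth)
  spec <- list(stage_index = stage, depth = depth,
               ups = sprintf("UPS%d", stage), cnc = sprintf("CNC%d", stage),
               conv = sprintf("C%d", 16L + stage))
  list(spec = spec, ups_shape = ups, cnc_shape = cnc, out_shape = out)
}

he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  runif(n, -lim, lim)
}

new_conv_param <- function(k, cin, cout) {
  list(kind = "conv", k = k, cin = cin, cout = cout,
       w = matrix(he_uniform(k * k * cin * cout, k * k * cin), k * k * cin, cout),
       b = numeric(cout))
}

new_bn_param <- function(c, eps = 1e-5) {
  list(kind = "bn", c = c, eps = eps,
       scale = rep(1, c), shift = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

new_se_param <- function(c, reduction) {
  cr <- max(1L, c %/% reduction)
  list(kind = "se", c = c, cr = cr,
       w1 = matrix(he_uniform(c * cr, c), c, cr), b1 = numeric(cr),
       w2 = matrix(he_uniform(cr * c, cr), cr, c), b2 = numeric(c))
}

new_tconv_param <- function(c) {
  list(kind = "tconv", k = 2L, cin = c, cout = c,
       w = matrix(he_uniform(4L * c * c, c), 4L * c, c), b = numeric(c))
}

#' Build the Graft-U-Net model and its layer-shape trace
#'
#' Constructs the full layer graph (encoder graft blocks, bottleneck,
#' decoder with skip concatenations, sigmoid head), initialises all
#' weights (He-uniform, reproducible through `seed`), and symbolically
#' propagates the input shape through every layer to produce the ordered
#' layer trace. With the default configuration the trace reproduces the
#' published 81-row layer table, ending in a 1-channel sigmoid output at
#' the input resolution.
#'
#' @param cfg An [arch_config()].
#' @param seed Optional integer seed for weight initialisation.
#' @return An object of class `graftunet_model` with elements `cfg`,
#'   `nodes` (the executable layer graph), `params` (an environment of
#'   weight tensors) and `trace` (a data frame of layer shapes; the
#'   element-wise branch additions and optional squeeze-excitation gates
#'   are part of the graph but, like in the published table, not rows of
#'   the trace).
#' @examples
#' m <- build_network(arch_config(input_h = 64, input_w = 64), seed = 1)
#' subset(m$trace, kind == "CNC")
#' @export
build_network <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "arch_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$kernel; p <- (k - 1L) %/% 2L
  pw <- cfg$pool_window; ps <- cfg$pool_stride; pp <- (pw - 1L) %/% 2L
  params <- new.env(parent = emptyenv())
  nodes <- list()
  trace <- list()
  add_node <- function(name, kind, inputs, shape, param = NULL,
                       traced = TRUE, trace_name = name, ...) {
    nodes[[name]] <<- list(name = name, kind = kind, inputs = inputs,
                           shape = shape, param = param, ...)
    if (traced)
      trace[[length(trace) + 1L]] <<-
        data.frame(layer = trace_name, kind = kind_label(kind),
                   height = shape[["h"]], width = shape[["w"]],
                   channels = shape[["c"]], stringsAsFactors = FALSE)
    invisible(name)
  }
  kind_label <- function(kind)
    switch(kind, input = "input", conv = "C", bn = "BN", relu = "A",
           maxpool = "MP", ups_nearest = "UPS", ups_transposed = "UPS",
           concat = "CNC", sigmoid = "A", stop("unknown kind ", kind))
  cba <- function(idx, input, cin, cout, shape, final_act = "relu") {
    cname <- sprintf("C%d", idx)
    params[[cname]] <- new_conv_param(k, cin, cout)
    add_node(cname, "conv", input, shape, param = cname, ksz = k, pad = p,
             stride = 1L)
    last <- cname
    if (final_act == "relu") {
      bname <- sprintf("BN%d", idx)
      params[[bname]] <- new_bn_param(cout)
      add_node(bname, "bn", cname, shape, param = bname)
      add_node(sprintf("A%d", idx), "relu", bname, shape)
      last <- sprintf("A%d", idx)
    } else {
      add_node(sprintf("A%d", idx), "sigmoid", cname, shape)
      last <- sprintf("A%d", idx)
    }
    last
  }

  in_shape <- shape3(cfg$input_h, cfg$input_w, cfg$input_c)
  add_node("input", "input", character(), in_shape)
  cur <- "input"; cur_shape <- in_shape
  skips <- character(5); skip_shapes <- vector("list", 5)
  for (s in 1:5) {
    st <- build_encoder_stage(cfg, s, cur_shape)
    d <- st$spec$depth
    body <- st$pre_pool_shape
    base <- (s - 1L) * 3L
    stem <- cba(base + 1L, cur, cur_shape[["c"]], d, body)
    conv_b <- cba(base + 2L, stem, d, d, body)
    graft_b <- cba(base + 3L, stem, d, d, body)
    addn <- sprintf("ADD%d", s)
    add_node(addn, "add", c(conv_b, graft_b), body, traced = FALSE)
    pre_pool <- addn
    if (cfg$se_enabled) {
      sen <- sprintf("SE%d", s)
      params[[sen]] <- new_se_param(d, cfg$se_reduction)
      add_node(sen, "se", addn, body, param = sen, traced = FALSE)
      pre_pool <- sen
    }
    skips[s] <- pre_pool; skip_shapes[[s]] <- body
    mpn <- sprintf("MP%d", s)
    add_node(mpn, "maxpool", pre_pool, st$post_pool_shape, ksz = pw, pad = pp,
             stride = ps, trace_name = "MP")
    cur <- mpn; cur_shape <- st$post_pool_shape
  }
  # bottleneck: one conv group, no graft pair
  cur <- cba(16L, cur, cur_shape[["c"]], cur_shape[["c"]],
             shape3(cur_shape[["h"]], cur_shape[["w"]], cur_shape[["c"]]))
  for (s in 1:5) {
    dec <- build_decoder_stage(cfg, s, cur_shape, skip_shapes[[6L - s]])
    upsn <- sprintf("UPS%d", s)
    if (cfg$upsample == "nearest") {
      add_node(upsn, "ups_nearest", cur, dec$ups_shape, scale = 2L)
    } else {
      params[[upsn]] <- new_tconv_param(cur_shape[["c"]])
      add_node(upsn, "ups_transposed", cur, dec$ups_shape, param = upsn,
               scale = 2L)
    }
    cncn <- sprintf("CNC%d", s)
    add_node(cncn, "concat", c(upsn, skips[6L - s]), dec$cnc_shape)
    cur <- cba(16L + s, cncn, dec$cnc_shape[["c"]], dec$spec$depth,
               dec$out_shape)
    cur_shape <- dec$out_shape
  }
  head_shape <- shape3(cur_shape[["h"]], cur_shape[["w"]], 1L)
  cba(22L, cur, cur_shape[["c"]], 1L, head_shape, final_act = "sigmoid")

  trace_df <- do.call(rbind, trace)
  trace_df <- cbind(layer_no = seq_len(nrow(trace_df)), trace_df)
  structure(list(cfg = cfg, nodes = nodes, params = params,
                 trace = trace_df),
            class = "graftunet_model")
}

#' @export
print.graftunet_model <- function(x, ...) {
  cat("Graft-U-Net model:", x$cfg$input_h, "x", x$cfg$input_w, "x",
      x$cfg$input_c, "input,",
      paste(x$cfg$filter_depths, collapse = "/"), "encoder depths,",
      nrow(x$trace), "traced layers,",
      format(count_parameters(x), big.mark = ","), "parameters\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums trainable weights over all layers: each convolution contributes
#' `f*f*c_in*c_out + c_out`, each batch-normalisation layer a scale and a
#' shift per channel (`2c`; running statistics are not trainable), and
#' each optional squeeze-excitation gate its two dense maps.
#'
#' @param model A [build_network()] model.
#' @return Non-negative integer count.
#' @examples
#' count_parameters(build_network(arch_config(input_h = 64, input_w = 64)))
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "graftunet_model"))
  total <- 0
  for (nm in ls(model$params)) {
    pr <- model$params[[nm]]
    total <- total + switch(pr$kind,
      conv = , tconv = length(pr$w) + length(pr$b),
      bn = 2L * pr$c,
      se = length(pr$w1) + length(pr$b1) + length(pr$w2) + length(pr$b2),
      stop("unknown param kind ", pr$kind))
  }
  as.integer(total)
}

table2_reference <- function() {
  path <- system.file("extdata", "table2.json", package = "graftunet")
  ref <- jsonlite::fromJSON(path)
  ref$layers
}

#' Check a layer trace against the published layer table
#'
#' Compares every traced layer's kind and output shape against the
#' machine-readable copy of the published 81-row layer table shipped with
#' the package. Mismatches are returned as data, not raised as errors.
#'
#' @param trace The `trace` data frame of a [build_network()] model built
#'   with the default configuration.
#' @return A data frame of mismatches (zero rows on full conformance)
#'   with columns `layer_no`, `layer`, `field`, `expected`, `actual`.
#' @examples
#' m <- build_network(arch_config())
#' nrow(verify_against_table2(m$trace)) == 0
#' @export
verify_against_table2 <- function(trace) {
  ref <- table2_reference()
  out <- data.frame(layer_no = integer(), layer = character(),
                    field = character(), expected = character(),
                    actual = character(), stringsAsFactors = FALSE)
  n <- max(nrow(ref), nrow(trace))
  for (i in seq_len(n)) {
    if (i > nrow(trace)) {
      out[nrow(out) + 1L, ] <- list(i, ref$layer[i], "presence",
                                    ref$layer[i], "<missing>")
      next
    }
    if (i > nrow(ref)) {
      out[nrow(out) + 1L, ] <- list(i, trace$layer[i], "presence",
                                    "<absent from table>", trace$layer[i])
      next
    }
    for (f in c("kind", "height", "width", "channels")) {
      ev <- as.character(ref[[f]][i]); av <- as.character(trace[[f]][i])
      if (!identical(ev, av))
        out[nrow(out) + 1L, ] <- list(i, ref$layer[i], f, ev, av)
    }
  }
  out
}
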