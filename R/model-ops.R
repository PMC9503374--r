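#' Batch-normalise a feature batch
#'
#' Centers each channel (column) at its batch mean and scales by the
#' inverse of `sqrt(variance + eps)`, where the variance is the
#' population variance over the batch, then applies the learnable
#' per-channel scale and shift. The stability constant `eps` keeps the
#' operation finite on zero-variance (constant) batches, which normalise
#' to all zeros.
#'
#' @param x Numeric matrix (rows = batch elements, columns = channels)
#'   or a plain numeric vector treated as a single channel.
#' @param scale,shift Per-channel affine parameters (recycled).
#' @param eps Stability constant added to the variance, default `1e-5`.
#' @return Normalised features, same shape as `x`.
#' @examples
#' batch_normalize(c(1, 3)) # close to -1, +1
#' @export
batch_normalize <- function(x, scale = 1, shift = 0, eps = 1e-5) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (nrow(x) < 1L) stop("batch must contain at least one element", call. = FALSE)
  c <- ncol(x)
  scale <- rep_len(scale, c); shift <- rep_len(shift, c)
  res <- bn_train_forward(x, list(eps = eps, scale = scale, shift = shift))
  if (vec) drop(res$y) else res$y
}

#' Squeeze-and-excitation channel gating
#'
#' Pools each channel of `x` to a scalar by a global max (the squeeze),
#' maps the resulting channel vector through a two-layer bottleneck gate
#' (reduce to `max(1, c/reduction)` units, ReLU, expand back, sigmoid),
#' and multiplies every channel of `x` by its gate in (0, 1). Output
#' shape equals input shape.
#'
#' @param x A `(h, w, c)` numeric array.
#' @param reduction Channel reduction factor of the bottleneck.
#' @param weights Optional list with `w1` (`c x cr`), `b1`, `w2`
#'   (`cr x c`), `b2` to make the gate deterministic; freshly initialised
#'   (He-uniform, consuming the R RNG stream) when omitted.
#' @return Gated array, same shape as `x`, with the per-channel gates
#'   attached as attribute `"gates"`.
#' @examples
#' x <- array(runif(4 * 4 * 2), c(4, 4, 2))
#' y <- squeeze_excite(x, reduction = 2)
#' all(abs(y) <= abs(x))
#' @export
squeeze_excite <- function(x, reduction = 4L, weights = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  c <- d[3]
  if (is.null(weights)) {
    pr <- new_se_param(c, as.integer(reduction))
  } else {
    pr <- c(weights, list(kind = "se", c = c))
  }
  xmat <- matrix(x, d[1] * d[2], c)
  res <- se_forward(xmat, pr, d[1], d[2], 1L)
  out <- array(res$y, d)
  attr(out, "gates") <- drop(res$g)
  out
}

#' Run one encoder graft block
#'
#' Applies encoder stage `stage` of a built model up to the element-wise
#' branch addition: the stem convolution group, then the conventional
#' and graft convolution branches both fed the stem output, then their
#' sum `H(x)`. Batch normalisation runs in inference mode (running
#' statistics), so the operation is a pure function of `x`.
#'
#' @param model A [build_network()] model.
#' @param x A `(h, w, c)` array matching the stage's input shape.
#' @param stage Encoder stage index, 1 to 5.
#' @return The summed feature map as a `(h, w, depth)` array.
#' @examples
#' m <- build_network(arch_config(input_h = 64, input_w = 64), seed = 1)
#' h1 <- graft_block_forward(m, array(0.5, c(64, 64, 3)), stage = 1)
#' dim(h1)
#' @export
graft_block_forward <- function(model, x, stage = 1L) {
  stopifnot(inherits(model, "graftunet_model"), stage %in% 1:5)
  d <- dim(x)
  base <- (stage - 1L) * 3L
  stem_conv <- sprintf("C%d", base + 1L)
  want <- model$nodes[[model$nodes[[stem_conv]]$inputs[1]]]$shape
  if (length(d) != 3L || d[1] != want[["h"]] || d[2] != want[["w"]] ||
      d[3] != want[["c"]])
    stop("x must be a ", fmt_shape(want), " array for stage ", stage,
         call. = FALSE)
  run <- c(sprintf("%s%d", rep(c("C", "BN", "A"), 3L),
                   rep(base + 1:3, each = 3L)), sprintf("ADD%d", stage))
  acts <- new.env(parent = emptyenv())
  feed <- model$nodes[[stem_conv]]$inputs[1]
  acts[[feed]] <- matrix(x, d[1] * d[2], d[3])
  for (nm in run) {
    node <- model$nodes[[nm]]
    xin <- acts[[node$inputs[1]]]
    inshape <- model$nodes[[node$inputs[1]]]$shape
    acts[[nm]] <- switch(node$kind,
      conv = {
        pr <- model$params[[nm]]
        xc <- nk_im2col(xin, inshape[["h"]], inshape[["w"]], 1L,
                        node$ksz, node$pad, node$stride)
        addv(xc %*% pr$w, pr$b)
      },
      bn = bn_eval_forward(xin, model$params[[nm]]),
      relu = pmax(xin, 0),
      add = xin + acts[[node$inputs[2]]])
  }
  out <- acts[[sprintf("ADD%d", stage)]]
  array(out, c(want[["h"]], want[["w"]], ncol(out)))
}
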