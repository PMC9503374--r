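#' Training configuration
#'
#' Hyper-parameters of the CPU training loop. The loss is binary
#' cross-entropy on the sigmoid output by default; a soft Dice loss is
#' available. The optimiser is Adam.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Frames per gradient step.
#' @param learning_rate Adam step size.
#' @param loss `"bce"` (binary cross-entropy, default) or `"dice"`
#'   (one minus the soft Dice coefficient).
#' @param seed Integer seed controlling weight initialisation and batch
#'   shuffling; fixing it makes training bit-reproducible.
#' @param input_size Optional square input extent; must equal the
#'   architecture's input size when given (frames are resized to it).
#' @param preprocess Apply CLAHE to every frame at load time.
#' @param clahe [clahe_params()] used when `preprocess` is `TRUE`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 4L, learning_rate = 1e-4,
                         loss = c("bce", "dice"), seed = 1L,
                         input_size = NULL, preprocess = FALSE,
                         clahe = clahe_params()) {
  loss <- match.arg(loss)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed), input_size = input_size,
                 preprocess = isTRUE(preprocess), clahe = clahe),
            class = "train_config")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in ls(grads)) {
    g <- grads[[nm]]
    pr <- params[[nm]]
    st <- state[[nm]]
    if (is.null(st)) st <- list()
    for (f in names(g)) {
      gf <- g[[f]]
      if (is.null(st[[f]])) st[[f]] <- list(m = gf * 0, v = gf * 0)
      st[[f]]$m <- beta1 * st[[f]]$m + (1 - beta1) * gf
      st[[f]]$v <- beta2 * st[[f]]$v + (1 - beta2) * gf * gf
      mhat <- st[[f]]$m / (1 - beta1^t)
      vhat <- st[[f]]$v / (1 - beta2^t)
      pr[[f]] <- pr[[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
    params[[nm]] <- pr
    state[[nm]] <- st
  }
  invisible(NULL)
}

load_training_set <- function(index, h, w, cfg) {
  pairs <- as.data.frame(index)
  imgs <- vector("list", nrow(pairs))
  msks <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lr <- load_and_resize(pairs[i, ], h, w)
    img <- lr$image
    if (cfg$preprocess) img <- equalize_frame(img, cfg$clahe)
    imgs[[i]] <- matrix(img, h * w, dim(img)[3])
    msks[[i]] <- as.numeric(lr$mask)
  }
  list(x = imgs, y = msks)
}

loss_grad <- function(z, y, loss) {
  p <- sigmoid(z)
  n <- length(z)
  if (loss == "bce") {
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    list(loss = -mean(y * log(pc) + (1 - y) * log(1 - pc)),
         dz = (p - y) / n)
  } else {
    eps <- 1
    num <- 2 * sum(p * y) + eps
    den <- sum(p) + sum(y) + eps
    dp <- -(2 * y * den - num) / den^2
    list(loss = 1 - num / den, dz = dp * p * (1 - p))
  }
}

#' Train a Graft-U-Net model
#'
#' Loads every frame/mask pair of `index` at the architecture's input
#' size, then minimises the configured loss with Adam over shuffled
#' mini-batches. All randomness (weight initialisation, shuffling) is
#' driven by `cfg$seed`, so a fixed seed reproduces the run exactly.
#'
#' @param index A [index_dataset()] / [generate_dataset()] index of
#'   training pairs.
#' @param arch An [arch_config()]; frames are resized to its input size.
#' @param cfg A [train_config()].
#' @param checkpoint Optional file path; the trained model is serialised
#'   there with [save_model()].
#' @param verbose Print the per-epoch loss.
#' @return A list with `model` (the trained `graftunet_model`) and
#'   `report`: per-epoch mean training loss, the configuration echo and
#'   the wall-clock time in seconds.
#' @export
train <- function(index, arch = arch_config(input_h = 64L, input_w = 64L),
                  cfg = train_config(), checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(arch, "arch_config"), inherits(cfg, "train_config"))
  if (!is.null(cfg$input_size) &&
      (cfg$input_size != arch$input_h || cfg$input_size != arch$input_w))
    stop("cfg$input_size disagrees with the architecture input size",
         call. = FALSE)
  pairs <- as.data.frame(index)
  if (nrow(pairs) == 0L) stop("empty dataset index", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  set.seed(cfg$seed)
  model <- build_network(arch)
  ds <- load_training_set(index, arch$input_h, arch$input_w, cfg)
  n <- length(ds$x)
  state <- new.env(parent = emptyenv())
  step <- 0L
  epoch_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      sel <- perm[start:min(start + cfg$batch_size - 1L, n)]
      b <- length(sel)
      xb <- do.call(rbind, ds$x[sel])
      yb <- unlist(ds$y[sel], use.names = FALSE)
      fwd <- model_forward(model, xb, b, training = TRUE)
      lg <- loss_grad(fwd$acts$C22, yb, cfg$loss)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep, ", step ", step + 1L,
             call. = FALSE)
      grads <- model_backward(model, fwd, "C22", matrix(lg$dz, ncol = 1L))
      step <- step + 1L
      adam_step(model$params, grads, state, cfg$learning_rate, step)
      losses <- c(losses, lg$loss)
    }
    epoch_loss[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.5f", ep, cfg$epochs, epoch_loss[ep]))
  }
  report <- list(per_epoch_loss = epoch_loss, config = unclass(cfg),
                 arch = unclass(arch), n_train = n,
                 wall_clock_sec = proc.time()[["elapsed"]] - t0)
  if (!is.null(checkpoint)) save_model(model, checkpoint)
  list(model = model, report = report)
}

#' Predict polyp probability maps
#'
#' Runs the network in inference mode (batch normalisation uses running
#' statistics) on one or more frames and returns per-pixel polyp
#' probabilities, strictly inside (0, 1), at the input resolution.
#'
#' @param object A trained (or freshly built) `graftunet_model`.
#' @param frames A single `(h, w, c)` array or a list of such arrays,
#'   already at the model input size and scaled to `[0, 1]`.
#' @param ... Unused.
#' @return A `(h, w)` probability matrix, or a list of them when
#'   `frames` is a list.
#' @export
predict.graftunet_model <- function(object, frames, ...) {
  single <- !is.list(frames)
  if (single) frames <- list(frames)
  cfg <- object$cfg
  for (f in frames) {
    d <- dim(f)
    if (length(d) != 3L || d[1] != cfg$input_h || d[2] != cfg$input_w ||
        d[3] != cfg$input_c)
      stop("frame dimensions must be ", cfg$input_h, " x ", cfg$input_w,
           " x ", cfg$input_c, call. = FALSE)
  }
  b <- length(frames)
  fwd <- model_forward(object, imgs_to_mat(frames), b, training = FALSE)
  maps <- mat_to_imgs(fwd$acts$A22, cfg$input_h, cfg$input_w, b)
  maps <- lapply(maps, function(m) m[, , 1L])
  if (single) maps[[1L]] else maps
}

#' Save or load a model checkpoint
#'
#' Serialises the model (configuration, layer graph and weights) to an
#' RDS file, the package's native checkpoint format.
#'
#' @param model A `graftunet_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "graftunet_model"))
  pl <- as.list(model$params)
  saveRDS(list(cfg = model$cfg, params = pl), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_network(obj$cfg)
  for (nm in names(obj$params)) model$params[[nm]] <- obj$params[[nm]]
  model
}
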