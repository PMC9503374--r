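# Internal forward/backward executor for the layer graph.
#
# Activations travel as (h*w*b) x c matrices: pixel index column-major
# within each image, images stacked along rows, channels as columns.
# Convolutions are im2col gathers (C code) followed by one BLAS matmul;
# the input gradient of a stride-1 same convolution is computed as
# another same convolution with spatially flipped, transposed kernels,
# so the backward pass needs no scatter except for max-pooling.

sigmoid <- function(x) 1 / (1 + exp(-x))

# stack a list of (h,w,c) arrays into the (h*w*b) x c matrix form
imgs_to_mat <- function(imgs) {
  b <- length(imgs)
  d <- dim(imgs[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  c <- d[3]
  out <- matrix(0, d[1] * d[2] * b, c)
  hw <- d[1] * d[2]
  for (i in seq_len(b)) {
    xi <- imgs[[i]]
    if (length(dim(xi)) == 2L) dim(xi) <- c(dim(xi), 1L)
    out[((i - 1L) * hw + 1L):(i * hw), ] <- matrix(xi, hw, c)
  }
  out
}

mat_to_imgs <- function(m, h, w, b) {
  hw <- h * w
  lapply(seq_len(b), function(i) {
    block <- m[((i - 1L) * hw + 1L):(i * hw), , drop = FALSE]
    array(block, c(h, w, ncol(m)))
  })
}

# nearest-neighbour 2x upsampling row index map (out row -> in row)
ups2_index <- function(h, w, b) {
  ci <- ceiling(seq_len(2L * h) / 2)
  cj <- ceiling(seq_len(2L * w) / 2)
  one <- rep(ci, times = 2L * w) + (rep(cj, each = 2L * h) - 1L) * h
  rep(one, times = b) + rep((seq_len(b) - 1L) * h * w, each = 4L * h * w)
}

# rows of the 2x2-offset sub-lattices of the transposed-conv output
tconv2_index <- function(h, w, b, di, dj) {
  oi <- 2L * seq_len(h) - 1L + di
  oj <- 2L * seq_len(w) - 1L + dj
  one <- rep(oi, times = w) + (rep(oj, each = h) - 1L) * 2L * h
  rep(one, times = b) + rep((seq_len(b) - 1L) * 4L * h * w, each = h * w)
}

addv <- function(x, v) x + rep(v, each = nrow(x))  # add per-column vector

bn_train_forward <- function(x, pr) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- colMeans(x * x) - m * m
  v[v < 0] <- 0
  inv_sd <- 1 / sqrt(v + pr$eps)
  xhat <- addv(x, -m) * rep(inv_sd, each = n)
  y <- addv(xhat * rep(pr$scale, each = n), pr$shift)
  list(y = y, xhat = xhat, inv_sd = inv_sd, mean = m, var = v)
}

bn_eval_forward <- function(x, pr) {
  n <- nrow(x)
  inv_sd <- 1 / sqrt(pr$run_var + pr$eps)
  addv(addv(x, -pr$run_mean) * rep(inv_sd * pr$scale, each = n), pr$shift)
}

se_forward <- function(x, pr, h, w, b, need_cache = FALSE) {
  hw <- h * w
  c <- ncol(x)
  M <- matrix(0, b, c)
  amax <- if (need_cache) matrix(0L, b, c) else NULL
  for (ch in seq_len(c)) {
    mt <- matrix(x[, ch], hw, b)
    if (need_cache) {
      idx <- max.col(t(mt), ties.method = "first")
      amax[, ch] <- idx
      M[, ch] <- mt[cbind(idx, seq_len(b))]
    } else {
      M[, ch] <- apply(mt, 2L, max)
    }
  }
  z1 <- addv(M %*% pr$w1, pr$b1)
  r1 <- pmax(z1, 0)
  g <- sigmoid(addv(r1 %*% pr$w2, pr$b2))
  gx <- g[rep(seq_len(b), each = hw), , drop = FALSE]
  list(y = x * gx, M = M, amax = amax, r1 = r1, g = g)
}

se_backward <- function(dy, x, cc, pr, h, w, b) {
  hw <- h * w
  c <- ncol(x)
  gx <- cc$g[rep(seq_len(b), each = hw), , drop = FALSE]
  dx <- dy * gx
  # gradient into the gate vector: per image-channel sum of dy * x
  dg <- matrix(0, b, c)
  prod_ <- dy * x
  for (ch in seq_len(c))
    dg[, ch] <- colSums(matrix(prod_[, ch], hw, b))
  dz2 <- dg * cc$g * (1 - cc$g)
  dw2 <- crossprod(cc$r1, dz2)
  db2 <- colSums(dz2)
  dr1 <- dz2 %*% t(pr$w2)
  dz1 <- dr1 * (cc$r1 > 0)
  dw1 <- crossprod(cc$M, dz1)
  db1 <- colSums(dz1)
  dM <- dz1 %*% t(pr$w1)
  # route the squeeze gradient to each channel's argmax pixel
  for (ch in seq_len(c)) {
    rows <- (seq_len(b) - 1L) * hw + cc$amax[, ch]
    dx[rows, ch] <- dx[rows, ch] + dM[, ch]
  }
  list(dx = dx, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

# flipped, transposed kernel matrix for the conv input gradient
conv_flip_weights <- function(pr) {
  a <- array(pr$w, c(pr$k, pr$k, pr$cin, pr$cout))
  a <- a[pr$k:1, pr$k:1, , , drop = FALSE]
  a <- aperm(a, c(1, 2, 4, 3))
  matrix(a, pr$k * pr$k * pr$cout, pr$cin)
}

# Execute the graph. Returns an environment of activations plus the
# per-node caches needed for the backward pass when training = TRUE.
model_forward <- function(model, xmat, b, training = FALSE) {
  acts <- new.env(parent = emptyenv())
  extra <- new.env(parent = emptyenv())
  params <- model$params
  for (node in model$nodes) {
    nm <- node$name
    kind <- node$kind
    if (kind == "input") { acts[[nm]] <- xmat; next }
    xin <- acts[[node$inputs[1]]]
    inshape <- model$nodes[[node$inputs[1]]]$shape
    h <- inshape[["h"]]; w <- inshape[["w"]]
    y <- switch(kind,
      conv = {
        pr <- params[[nm]]
        xc <- nk_im2col(xin, h, w, b, node$ksz, node$pad, node$stride)
        if (training) extra[[nm]] <- list(xcol = xc, h = h, w = w)
        addv(xc %*% pr$w, pr$b)
      },
      bn = {
        pr <- params[[nm]]
        if (training) {
          res <- bn_train_forward(xin, pr)
          extra[[nm]] <- res[c("xhat", "inv_sd")]
          # running statistics for inference
          mom <- 0.9
          pr$run_mean <- mom * pr$run_mean + (1 - mom) * res$mean
          pr$run_var <- mom * pr$run_var + (1 - mom) * res$var
          params[[nm]] <- pr
          res$y
        } else bn_eval_forward(xin, pr)
      },
      relu = pmax(xin, 0),
      sigmoid = sigmoid(xin),
      add = xin + acts[[node$inputs[2]]],
      concat = {
        if (training) extra[[nm]] <- ncol(xin)
        cbind(xin, acts[[node$inputs[2]]])
      },
      maxpool = {
        res <- nk_maxpool(xin, h, w, b, node$ksz, node$pad, node$stride)
        if (training) extra[[nm]] <- list(argmax = res$argmax,
                                          in_rows = nrow(xin))
        res$values
      },
      ups_nearest = {
        idx <- ups2_index(h, w, b)
        if (training) extra[[nm]] <- list(idx = idx, in_rows = nrow(xin))
        xin[idx, , drop = FALSE]
      },
      ups_transposed = {
        pr <- params[[nm]]
        cin <- pr$cin
        out <- matrix(0, 4L * h * w * b, pr$cout)
        pos <- 0L
        for (dj in 0:1) for (di in 0:1) {
          pos <- pos + 1L
          wp <- pr$w[((pos - 1L) * cin + 1L):(pos * cin), , drop = FALSE]
          out[tconv2_index(h, w, b, di, dj), ] <- xin %*% wp
        }
        if (training) extra[[nm]] <- list(h = h, w = w)
        addv(out, pr$b)
      },
      se = {
        pr <- params[[nm]]
        res <- se_forward(xin, pr, h, w, b, need_cache = training)
        if (training) extra[[nm]] <- res[c("M", "amax", "r1", "g")]
        res$y
      },
      stop("unknown node kind ", kind))
    acts[[nm]] <- y
  }
  list(acts = acts, extra = extra, b = b)
}

# Backward from `from_node` given its output gradient. Returns an
# environment of parameter gradients keyed by parameter name.
model_backward <- function(model, fwd, from_node, dout) {
  acts <- fwd$acts; extra <- fwd$extra; b <- fwd$b
  params <- model$params
  grads <- new.env(parent = emptyenv())
  dmap <- new.env(parent = emptyenv())
  dmap[[from_node]] <- dout
  names_rev <- rev(names(model$nodes))
  started <- FALSE
  for (nm in names_rev) {
    if (!started) {
      if (nm == from_node) started <- TRUE else next
    }
    if (is.null(dmap[[nm]])) next
    node <- model$nodes[[nm]]
    kind <- node$kind
    dy <- dmap[[nm]]
    dmap[[nm]] <- NULL
    if (kind == "input") next
    push <- function(target, g) {
      cur <- dmap[[target]]
      dmap[[target]] <- if (is.null(cur)) g else cur + g
    }
    xin_name <- node$inputs[1]
    switch(kind,
      conv = {
        pr <- params[[nm]]
        cc <- extra[[nm]]
        grads[[nm]] <- list(w = crossprod(cc$xcol, dy), b = colSums(dy))
        dyc <- nk_im2col(dy, node$shape[["h"]], node$shape[["w"]], b,
                         node$ksz, node$pad, 1L)
        push(xin_name, dyc %*% conv_flip_weights(pr))
      },
      bn = {
        pr <- params[[nm]]
        cc <- extra[[nm]]
        n <- nrow(dy)
        dxhat <- dy * rep(pr$scale, each = n)
        s1 <- colMeans(dxhat)
        s2 <- colMeans(dxhat * cc$xhat)
        dx <- (dxhat - rep(s1, each = n) - cc$xhat * rep(s2, each = n)) *
          rep(cc$inv_sd, each = n)
        grads[[nm]] <- list(scale = colSums(dy * cc$xhat),
                            shift = colSums(dy))
        push(xin_name, dx)
      },
      relu = push(xin_name, dy * (acts[[nm]] > 0)),
      sigmoid = {
        yv <- acts[[nm]]
        push(xin_name, dy * yv * (1 - yv))
      },
      add = {
        push(xin_name, dy)
        push(node$inputs[2], dy)
      },
      concat = {
        c1 <- extra[[nm]]
        push(xin_name, dy[, seq_len(c1), drop = FALSE])
        push(node$inputs[2], dy[, -seq_len(c1), drop = FALSE])
      },
      maxpool = {
        cc <- extra[[nm]]
        push(xin_name, nk_maxpool_backward(dy, cc$argmax, cc$in_rows))
      },
      ups_nearest = {
        cc <- extra[[nm]]
        push(xin_name, rowsum(dy, cc$idx, reorder = TRUE))
      },
      ups_transposed = {
        pr <- params[[nm]]
        cc <- extra[[nm]]
        xin <- acts[[xin_name]]
        cin <- pr$cin
        dw <- matrix(0, 4L * cin, pr$cout)
        dx <- matrix(0, nrow(xin), cin)
        pos <- 0L
        for (dj in 0:1) for (di in 0:1) {
          pos <- pos + 1L
          rows <- ((pos - 1L) * cin + 1L):(pos * cin)
          dpos <- dy[tconv2_index(cc$h, cc$w, b, di, dj), , drop = FALSE]
          dw[rows, ] <- crossprod(xin, dpos)
          dx <- dx + dpos %*% t(pr$w[rows, , drop = FALSE])
        }
        grads[[nm]] <- list(w = dw, b = colSums(dy))
        push(xin_name, dx)
      },
      se = {
        pr <- params[[nm]]
        cc <- extra[[nm]]
        inshape <- model$nodes[[xin_name]]$shape
        res <- se_backward(dy, acts[[xin_name]], cc, pr,
                           inshape[["h"]], inshape[["w"]], b)
        grads[[nm]] <- res$grads
        push(xin_name, res$dx)
      },
      stop("no backward for node kind ", kind))
  }
  grads
}
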