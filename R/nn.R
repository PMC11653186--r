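# Minimal CPU training backend for the architecture search.
#
# Tensors are R arrays laid out (H, W, N, C) — channels last so that the
# im2col expansion, batch normalization and the conv gradients are plain
# dim<- reshapes with no transposition, and the heavy lifting is a single
# BLAS matrix product per layer.  Supports same-padded stride-1 conv
# (rectifier), batch normalization, 2x2/stride-2 max pooling, flatten,
# dropout, dense layers and a sigmoid output trained with binary
# cross-entropy and Adam.  Internal plumbing behind train_and_score().

NN_BN_EPS <- 1e-5
NN_BN_MOMENTUM <- 0.9

# --- tensor helpers ---------------------------------------------------------

# Stack a list of HxW matrices into an (H, W, N, 1) array.
stack_images <- function(imgs) {
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), dim = c(h, w, length(imgs), 1L))
}

# Zero-pad the two spatial dims for a same-padded kernel k (the extra
# pixel of an even kernel goes bottom/right).
pad_same <- function(x, k) {
  if (k == 1L) return(x)
  d <- dim(x)
  pt <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(d[1] + k - 1L, d[2] + k - 1L, d[3], d[4]))
  xp[(pt + 1L):(pt + d[1]), (pt + 1L):(pt + d[2]), , ] <- x
  xp
}

# im2col on an (Hp, Wp, N, C) padded array: rows ordered (h, w, n),
# columns ordered ((kj, ki), c) to match the conv weight matrix.
# The block copies are done in C++ (src/conv_ops.cpp).
im2col <- function(xp, k, H, W) {
  d <- dim(xp); N <- d[3]; C <- d[4]
  if (k == 1L) { dim(xp) <- c(H * W * N, C); return(xp) }
  im2col_cpp(xp, d[1], d[2], N, C, k, H, W)
}

# Scatter-add the columns gradient back onto the padded input array.
col2im <- function(dcols, k, H, W, N, C) {
  if (k == 1L) { dim(dcols) <- c(H, W, N, C); return(dcols) }
  dxp <- col2im_cpp(dcols, N, C, k, H, W)
  dim(dxp) <- c(H + k - 1L, W + k - 1L, N, C)
  dxp
}

# --- network construction ---------------------------------------------------

he_init <- function(nrow_, ncol_, fan_in) {
  matrix(stats::rnorm(nrow_ * ncol_, sd = sqrt(2 / fan_in)), nrow_, ncol_)
}

# Build trainable state from an arch_spec.  Uses the current RNG stream.
nn_build <- function(spec) {
  c_in <- spec$input_shape[3]
  flat_in <- NA_integer_
  layers <- list()
  for (ly in spec$layers) {
    st <- ly
    if (ly$kind == "conv") {
      fan_in <- ly$kernel^2 * c_in
      st$W <- he_init(fan_in, ly$filters, fan_in)
      st$b <- numeric(ly$filters)
      st$C_in <- c_in
      c_in <- ly$filters
    } else if (ly$kind == "batch_norm") {
      st$gamma <- rep(1, ly$channels); st$beta <- numeric(ly$channels)
      st$run_mean <- numeric(ly$channels); st$run_var <- numeric(ly$channels)
      st$bn_steps <- 0L  # for bias-corrected running statistics
    } else if (ly$kind == "flatten") {
      flat_in <- ly$output_shape
    } else if (ly$kind %in% c("dense", "output")) {
      st$W <- he_init(flat_in, ly$units, flat_in)
      st$b <- numeric(ly$units)
      st$D_in <- flat_in
      flat_in <- ly$units
    }
    layers[[length(layers) + 1L]] <- st
  }
  list(layers = layers, input_shape = spec$input_shape)
}

# --- forward / backward -----------------------------------------------------

nn_forward <- function(net, x, train = TRUE) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (ly$kind == "conv") {
      d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]
      cols <- im2col(pad_same(x, ly$kernel), ly$kernel, H, W)
      z <- cols %*% ly$W
      z <- z + rep(ly$b, each = nrow(z))
      relu_mask <- z > 0
      z <- z * relu_mask
      dim(z) <- c(H, W, N, ly$filters)
      x <- z
      caches[[li]] <- list(cols = cols, relu_mask = relu_mask, H = H, W = W, N = N)
    } else if (ly$kind == "batch_norm") {
      d <- dim(x)
      M <- prod(d[1:3])
      xm <- x; dim(xm) <- c(M, d[4])
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        net$layers[[li]]$run_mean <- NN_BN_MOMENTUM * ly$run_mean + (1 - NN_BN_MOMENTUM) * mu
        net$layers[[li]]$run_var <- NN_BN_MOMENTUM * ly$run_var + (1 - NN_BN_MOMENTUM) * v
        net$layers[[li]]$bn_steps <- ly$bn_steps + 1L
      } else {
        # bias-corrected running statistics (exact average over the first
        # steps, exponential thereafter), so short trainings are usable
        corr <- 1 - NN_BN_MOMENTUM^max(ly$bn_steps, 1L)
        mu <- ly$run_mean / corr
        v <- ly$run_var / corr
      }
      inv_sd <- 1 / sqrt(v + NN_BN_EPS)
      xhat <- (xm - rep(mu, each = M)) * rep(inv_sd, each = M)
      ym <- xhat * rep(ly$gamma, each = M) + rep(ly$beta, each = M)
      dim(ym) <- d
      x <- ym
      caches[[li]] <- list(xhat = xhat, inv_sd = inv_sd, dims = d)
    } else if (ly$kind == "max_pool") {
      d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
      xe <- x[seq_len(2L * H2), seq_len(2L * W2), , , drop = FALSE]
      c00 <- xe[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE]
      c10 <- xe[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE]
      c01 <- xe[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE]
      c11 <- xe[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE]
      mx <- pmax(c00, c10, c01, c11)
      w00 <- c00 == mx
      w10 <- (c10 == mx) & !w00
      w01 <- (c01 == mx) & !(w00 | w10)
      w11 <- !(w00 | w10 | w01)
      caches[[li]] <- list(w00 = w00, w10 = w10, w01 = w01, w11 = w11,
                           in_dim = d, H2 = H2, W2 = W2)
      x <- mx
    } else if (ly$kind == "flatten") {
      d <- dim(x)
      caches[[li]] <- list(in_dim = d)
      # per-sample feature order (h, w, c): bring N last, then reshape
      x <- aperm(x, c(1, 2, 4, 3))
      dim(x) <- c(d[1] * d[2] * d[4], d[3])
      x <- t(x)
    } else if (ly$kind == "dropout") {
      if (train && ly$rate > 0) {
        mask <- (matrix(stats::runif(length(x)), nrow(x)) >= ly$rate) / (1 - ly$rate)
        x <- x * mask
        caches[[li]] <- list(mask = mask)
      } else caches[[li]] <- list(mask = NULL)
    } else if (ly$kind == "dense") {
      z <- sweep(x %*% ly$W, 2L, ly$b, "+")
      relu_mask <- z > 0
      z <- z * relu_mask
      caches[[li]] <- list(x_in = x, relu_mask = relu_mask)
      x <- z
    } else if (ly$kind == "output") {
      z <- sweep(x %*% ly$W, 2L, ly$b, "+")
      caches[[li]] <- list(x_in = x)
      x <- 1 / (1 + exp(-z))
    }
  }
  list(out = as.numeric(x), caches = caches, net = net)
}

# dout enters as d loss / d pre-sigmoid logits of the output layer
# (the BCE + sigmoid gradient (p - y) / N), an N x 1 matrix.
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    cc <- caches[[li]]
    if (ly$kind == "output") {
      grads[[li]] <- list(W = crossprod(cc$x_in, dx), b = colSums(dx))
      dx <- dx %*% t(ly$W)
    } else if (ly$kind == "dense") {
      dz <- dx * cc$relu_mask
      grads[[li]] <- list(W = crossprod(cc$x_in, dz), b = colSums(dz))
      dx <- dz %*% t(ly$W)
    } else if (ly$kind == "dropout") {
      if (!is.null(cc$mask)) dx <- dx * cc$mask
    } else if (ly$kind == "flatten") {
      d <- cc$in_dim
      dx <- t(dx)
      dim(dx) <- c(d[1], d[2], d[4], d[3])
      dx <- aperm(dx, c(1, 2, 4, 3))
    } else if (ly$kind == "max_pool") {
      d <- cc$in_dim; H2 <- cc$H2; W2 <- cc$W2
      full <- array(0, dim = d)
      full[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , ] <- dx * cc$w00
      full[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , ] <- dx * cc$w10
      full[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , ] <- dx * cc$w01
      full[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , ] <- dx * cc$w11
      dx <- full
    } else if (ly$kind == "batch_norm") {
      d <- cc$dims
      M <- prod(d[1:3])
      dym <- dx; dim(dym) <- c(M, d[4])
      dgamma <- colSums(dym * cc$xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(ly$gamma, each = M)
      # dx = inv_sd/M * (M*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
      t2 <- rep(colSums(dxhat), each = M)
      t3 <- cc$xhat * rep(colSums(dxhat * cc$xhat), each = M)
      dxm <- (M * dxhat - t2 - t3) * rep(cc$inv_sd / M, each = M)
      grads[[li]] <- list(gamma = dgamma, beta = dbeta)
      dim(dxm) <- d
      dx <- dxm
    } else if (ly$kind == "conv") {
      H <- cc$H; W <- cc$W; N <- cc$N
      dym <- dx; dim(dym) <- c(H * W * N, ly$filters)
      dym <- dym * cc$relu_mask
      grads[[li]] <- list(W = crossprod(cc$cols, dym), b = colSums(dym))
      dcols <- dym %*% t(ly$W)
      dxp <- col2im(dcols, ly$kernel, H, W, N, ly$C_in)
      if (ly$kernel > 1L) {
        pt <- (ly$kernel - 1L) %/% 2L
        dx <- dxp[(pt + 1L):(pt + H), (pt + 1L):(pt + W), , , drop = FALSE]
      } else dx <- dxp
    }
  }
  grads
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(ly))
    if (!length(nm)) return(NULL)
    st <- lapply(ly[nm], function(p) list(m = p * 0, v = p * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(net, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- opt[[li]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      net$layers[[li]][[nm]] <- net$layers[[li]][[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      opt[[li]][[nm]] <- st
    }
  }
  list(net = net, opt = opt)
}

# --- training loop ----------------------------------------------------------

train_failure <- function(msg) {
  stop(structure(class = c("evocnn_train_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# x: (H, W, N, C) array; y: 0/1 vector.  Returns list(net, final_loss).
nn_fit <- function(spec, x, y, epochs, batch_size, lr) {
  d <- dim(x)
  if (!all(c(d[1], d[2], d[4]) == spec$input_shape))
    train_failure(sprintf("input shape %s does not match spec input %s",
                          paste(c(d[1], d[2], d[4]), collapse = "x"),
                          paste(spec$input_shape, collapse = "x")))
  net <- nn_build(spec)
  opt <- adam_init(net)
  n <- d[3]
  t_step <- 0L
  final_loss <- NA_real_
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, n)]
      xb <- x[, , bi, , drop = FALSE]
      yb <- y[bi]
      fw <- nn_forward(net, xb, train = TRUE)
      net <- fw$net  # running BN stats
      p <- fw$out
      loss <- bce_loss(yb, p)
      if (!is.finite(loss)) train_failure("non-finite training loss")
      # combined sigmoid + BCE gradient wrt logits
      dlogit <- matrix((p - yb) / length(yb), ncol = 1L)
      grads <- nn_backward(net, fw$caches, dlogit)
      t_step <- t_step + 1L
      upd <- adam_step(net, grads, opt, lr, t_step)
      net <- upd$net; opt <- upd$opt
      losses <- c(losses, loss)
    }
    final_loss <- mean(losses)
  }
  list(net = net, final_loss = final_loss)
}

# Predict class-1 probabilities in inference mode (running BN stats).
nn_predict <- function(net, x, batch_size = 64L) {
  n <- dim(x)[3]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    out[bi] <- nn_forward(net, x[, , bi, , drop = FALSE], train = FALSE)$out
  }
  out
}

# --- stand-in frozen backbone ----------------------------------------------

#' Create a stand-in frozen convolutional feature extractor
#'
#' A small fixed (never-trained) convolutional stack — two same-padded conv
#' + rectifier + 2x2 max-pool blocks with seeded random weights — playing
#' the role of a pretrained backbone for dense-head search, so no weight
#' download is required.  Swapping in a genuinely pretrained extractor is a
#' configuration choice; the head-search code is agnostic to it.
#'
#' @param input_shape `c(height, width, channels)` of the images.
#' @param filters Filter counts of the two blocks (default `c(8, 16)`).
#' @param seed Seed fixing the (frozen) weights.
#' @return An object of class `frozen_backbone` with the extractor state
#'   and its `feature_shape`.
#' @export
standin_backbone <- function(input_shape = c(32, 32, 1), filters = c(8L, 16L),
                             seed = 42L) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  input_shape <- as.integer(input_shape)
  c_in <- input_shape[3]
  blocks <- list()
  h <- input_shape[1]; w <- input_shape[2]
  for (f in filters) {
    fan_in <- 9L * c_in
    blocks[[length(blocks) + 1L]] <- list(W = he_init(fan_in, f, fan_in),
                                          b = numeric(f), kernel = 3L, C_in = c_in,
                                          filters = f)
    c_in <- f; h <- h %/% 2L; w <- w %/% 2L
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(blocks = blocks, input_shape = as.integer(input_shape),
                 feature_shape = c(h, w, c_in)),
            class = "frozen_backbone")
}

#' Extract frozen-backbone features
#'
#' @param backbone A [standin_backbone()].
#' @param x Image array `(H, W, N, C)` or a list of matrices.
#' @return Feature array `(h', w', N, c')`.
#' @export
backbone_features <- function(backbone, x) {
  if (is.list(x) && !is.array(x)) x <- stack_images(x)
  for (bl in backbone$blocks) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]
    cols <- im2col(pad_same(x, bl$kernel), bl$kernel, H, W)
    z <- sweep(cols %*% bl$W, 2L, bl$b, "+")
    z <- z * (z > 0)
    dim(z) <- c(H, W, N, bl$filters)
    # 2x2 max pool
    H2 <- H %/% 2L; W2 <- W %/% 2L
    xe <- z[seq_len(2L * H2), seq_len(2L * W2), , , drop = FALSE]
    x <- pmax(xe[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
              xe[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
              xe[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE],
              xe[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE])
  }
  x
}
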