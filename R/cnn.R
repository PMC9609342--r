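# 1-D convolutional network for spectral regression, implemented directly
# on BLAS matrix products (im2col convolutions) with an Adam optimizer.
# The architecture follows the process-calibration design: a 32-filter
# convolution, batch normalization, an optional length-2/stride-1 max
# pool, four 16-filter convolutions, then 32- and 64-filter convolutions
# (all kernel 3, stride 1, ReLU), a flatten, a small tapering dense stack,
# and a single linear output neuron. Per-attribute variants: no pooling
# layer for ferulic acid; three dense layers for ferulic and rosmarinic
# acid, two otherwise.

#' CNN architecture and training specification
#'
#' @param attribute Attribute label; `"ferulic_acid"` drops the pooling
#'   layer and, with `"rosmarinic_acid"`, uses three dense layers.
#' @param use_maxpool Override the pooling flag.
#' @param n_dense Override the dense-layer count (2 or 3).
#' @param dense_widths Hidden dense widths; defaults `(64, 16)` for two
#'   layers, `(64, 32, 16)` for three.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 50).
#' @param max_epochs Training epoch cap (default 200).
#' @param patience Early-stopping patience in epochs without improvement
#'   of the (training) loss (default 40).
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(attribute = "generic",
                     use_maxpool = !identical(attribute, "ferulic_acid"),
                     n_dense = if (attribute %in%
                                   c("ferulic_acid", "rosmarinic_acid"))
                       3L else 2L,
                     dense_widths = if (n_dense == 3L) c(64L, 32L, 16L) else
                       c(64L, 16L),
                     learning_rate = 1e-4, batch_size = 50L,
                     max_epochs = 200L, patience = 40L) {
  if (length(dense_widths) != n_dense) {
    stop("dense_widths must have n_dense entries", call. = FALSE)
  }
  structure(list(attribute = attribute, use_maxpool = use_maxpool,
                 n_dense = as.integer(n_dense),
                 dense_widths = as.integer(dense_widths),
                 conv_stack = list(
                   list(filters = 32L, kernel = 3L, stride = 1L),
                   list(filters = 16L, kernel = 3L, stride = 1L),
                   list(filters = 16L, kernel = 3L, stride = 1L),
                   list(filters = 16L, kernel = 3L, stride = 1L),
                   list(filters = 16L, kernel = 3L, stride = 1L),
                   list(filters = 32L, kernel = 3L, stride = 1L),
                   list(filters = 64L, kernel = 3L, stride = 1L)),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "cnn_spec")
}

#' Build the (untrained) network graph
#'
#' Resolves the layer sequence of a [cnn_spec()] against an input length,
#' checking that the input is at least as long as the stack's receptive
#' field, and reports the parameter count.
#'
#' @param spec A [cnn_spec()].
#' @param n_channels Input spectrum length (number of spectral channels).
#' @return A `cnn_graph`: list of layer descriptors with resolved shapes,
#'   plus `n_parameters`.
#' @export
build_cnn <- function(spec, n_channels) {
  stopifnot(inherits(spec, "cnn_spec"))
  n_channels <- as.integer(n_channels)
  receptive <- 7L * 2L + if (spec$use_maxpool) 1L else 0L
  if (n_channels <= receptive) {
    stop(sprintf("input length %d is within the stack's receptive field (%d)",
                 n_channels, receptive + 1L), call. = FALSE)
  }
  layers <- list()
  L <- n_channels
  C <- 1L
  add <- function(layers, layer) c(layers, list(layer))
  for (i in seq_along(spec$conv_stack)) {
    cs <- spec$conv_stack[[i]]
    layers <- add(layers, list(type = "conv", in_ch = C, out_ch = cs$filters,
                               kernel = cs$kernel, L_in = L,
                               L_out = L - cs$kernel + 1L))
    L <- L - cs$kernel + 1L
    C <- cs$filters
    layers <- add(layers, list(type = "relu"))
    if (i == 1L) {
      layers <- add(layers, list(type = "batchnorm", channels = C))
      if (spec$use_maxpool) {
        layers <- add(layers, list(type = "maxpool", kernel = 2L,
                                   L_in = L, L_out = L - 1L))
        L <- L - 1L
      }
    }
  }
  layers <- add(layers, list(type = "flatten", L = L, channels = C,
                             width = L * C))
  width <- L * C
  for (w in spec$dense_widths) {
    layers <- add(layers, list(type = "dense", in_w = width, out_w = w))
    layers <- add(layers, list(type = "relu"))
    width <- w
  }
  layers <- add(layers, list(type = "dense", in_w = width, out_w = 1L,
                             output = TRUE))
  n_par <- 0L
  for (l in layers) {
    n_par <- n_par + switch(l$type,
      conv = (l$kernel * l$in_ch + 1L) * l$out_ch,
      batchnorm = 2L * l$channels,
      dense = (l$in_w + 1L) * l$out_w,
      0L)
  }
  structure(list(layers = layers, spec = spec, n_channels = n_channels,
                 n_parameters = n_par),
            class = "cnn_graph")
}

#' @export
print.cnn_graph <- function(x, ...) {
  cat(sprintf("<cnn_graph> input %d channels, %d layers, %d parameters\n",
              x$n_channels, length(x$layers), x$n_parameters))
  for (l in x$layers) {
    cat("  ", switch(l$type,
      conv = sprintf("conv(%d -> %d filters, k%d) -> length %d", l$in_ch,
                     l$out_ch, l$kernel, l$L_out),
      relu = "relu",
      batchnorm = sprintf("batchnorm(%d)", l$channels),
      maxpool = sprintf("maxpool(k2, s1) -> length %d", l$L_out),
      flatten = sprintf("flatten -> %d", l$width),
      dense = sprintf("dense(%d -> %d)%s", l$in_w, l$out_w,
                      if (isTRUE(l$output)) " [linear output]" else "")),
      "\n")
  }
  invisible(x)
}

# He-normal initialization of all trainable tensors.
cnn_init <- function(graph) {
  params <- list()
  for (i in seq_along(graph$layers)) {
    l <- graph$layers[[i]]
    key <- paste0("L", i)
    if (l$type == "conv") {
      fan_in <- l$kernel * l$in_ch
      params[[key]] <- list(
        W = matrix(stats::rnorm(fan_in * l$out_ch, 0, sqrt(2 / fan_in)),
                   fan_in, l$out_ch),
        b = numeric(l$out_ch))
    } else if (l$type == "dense") {
      sdv <- if (isTRUE(l$output)) sqrt(1 / l$in_w) else sqrt(2 / l$in_w)
      params[[key]] <- list(
        W = matrix(stats::rnorm(l$in_w * l$out_w, 0, sdv), l$in_w, l$out_w),
        b = numeric(l$out_w))
    } else if (l$type == "batchnorm") {
      params[[key]] <- list(W = rep(1, l$channels),   # gamma
                            b = rep(0, l$channels))   # beta
    }
  }
  params
}

# im2col for kernel 3, stride 1, offset-major column layout: column block
# o (of 3) holds all Cin input channels shifted by o-1. One slab reshape
# per offset keeps the R-level overhead at 3 operations per conv.
im2col3 <- function(A, Lout) {
  B <- dim(A)[1]
  Cin <- dim(A)[3]
  cols <- matrix(0, B * Lout, 3L * Cin)
  for (o in 1:3) {
    slab <- A[, o:(Lout + o - 1L), , drop = FALSE]     # B x Lout x Cin
    cols[, ((o - 1L) * Cin + 1L):(o * Cin)] <- matrix(slab, B * Lout, Cin)
  }
  cols
}

# Forward pass. `training` toggles batch-norm statistics; caches for the
# backward pass are returned when `training` is TRUE.
cnn_forward <- function(graph, params, state, X, training = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", length(graph$layers))
  bn_eps <- 1e-5
  for (i in seq_along(graph$layers)) {
    l <- graph$layers[[i]]
    key <- paste0("L", i)
    if (l$type == "conv") {
      cols <- im2col3(A, l$L_out)
      Z <- sweep(cols %*% params[[key]]$W, 2, params[[key]]$b, `+`)
      if (training) caches[[i]] <- list(cols = cols, dimA = dim(A))
      A <- array(Z, c(B, l$L_out, l$out_ch))
    } else if (l$type == "relu") {
      mask <- A > 0
      if (training) caches[[i]] <- list(mask = mask)
      A <- A * mask
    } else if (l$type == "batchnorm") {
      C <- l$channels
      M <- matrix(A, ncol = C)              # (B*L) x C
      if (training) {
        mu <- colMeans(M)
        va <- colMeans(sweep(M, 2, mu)^2)
        state[[key]]$mean <- 0.9 * state[[key]]$mean + 0.1 * mu
        state[[key]]$var <- 0.9 * state[[key]]$var + 0.1 * va
      } else {
        mu <- state[[key]]$mean
        va <- state[[key]]$var
      }
      xhat <- sweep(sweep(M, 2, mu), 2, sqrt(va + bn_eps), `/`)
      out <- sweep(sweep(xhat, 2, params[[key]]$W, `*`), 2, params[[key]]$b,
                   `+`)
      if (training) {
        caches[[i]] <- list(xhat = xhat, va = va, mu = mu, M = M,
                            dimA = dim(A))
      }
      A <- array(out, dim(A))
    } else if (l$type == "maxpool") {
      left <- A[, 1:l$L_out, , drop = FALSE]
      right <- A[, 2:(l$L_out + 1L), , drop = FALSE]
      mask <- left >= right
      if (training) caches[[i]] <- list(mask = mask, dimA = dim(A))
      A <- pmax(left, right)
    } else if (l$type == "flatten") {
      if (training) caches[[i]] <- list(dimA = dim(A))
      A <- matrix(A, nrow = B)
    } else if (l$type == "dense") {
      if (training) caches[[i]] <- list(A_in = A)
      A <- sweep(A %*% params[[key]]$W, 2, params[[key]]$b, `+`)
    }
  }
  list(out = as.vector(A), caches = caches, state = state)
}

cnn_backward <- function(graph, params, caches, dout) {
  grads <- list()
  G <- matrix(dout, ncol = 1)
  bn_eps <- 1e-5
  for (i in rev(seq_along(graph$layers))) {
    l <- graph$layers[[i]]
    key <- paste0("L", i)
    if (l$type == "dense") {
      A_in <- caches[[i]]$A_in
      grads[[key]] <- list(W = crossprod(A_in, G), b = colSums(G))
      G <- G %*% t(params[[key]]$W)
    } else if (l$type == "flatten") {
      G <- array(G, caches[[i]]$dimA)
    } else if (l$type == "relu") {
      G <- G * caches[[i]]$mask
    } else if (l$type == "maxpool") {
      ca <- caches[[i]]
      dA <- array(0, ca$dimA)
      Lout <- l$L_out
      dA[, 1:Lout, ] <- G * ca$mask
      dA[, 2:(Lout + 1L), ] <- dA[, 2:(Lout + 1L), , drop = FALSE] +
        G * !ca$mask
      G <- dA
    } else if (l$type == "batchnorm") {
      ca <- caches[[i]]
      C <- l$channels
      dM <- matrix(G, ncol = C)
      m <- nrow(dM)
      grads[[key]] <- list(W = colSums(dM * ca$xhat), b = colSums(dM))
      inv_sd <- 1 / sqrt(ca$va + bn_eps)
      dxhat <- sweep(dM, 2, params[[key]]$W, `*`)
      xc <- sweep(ca$M, 2, ca$mu)
      dvar <- colSums(dxhat * xc) * (-0.5) * inv_sd^3
      dmu <- colSums(dxhat) * (-inv_sd) + dvar * colMeans(-2 * xc)
      dX <- sweep(dxhat, 2, inv_sd, `*`) +
        sweep(2 * xc, 2, dvar / m, `*`) +
        matrix(dmu / m, m, C, byrow = TRUE)
      G <- array(dX, ca$dimA)
    } else if (l$type == "conv") {
      ca <- caches[[i]]
      B <- ca$dimA[1]
      Cin <- l$in_ch
      Lout <- l$L_out
      dZ <- matrix(G, B * Lout, l$out_ch)
      grads[[key]] <- list(W = crossprod(ca$cols, dZ), b = colSums(dZ))
      dcols <- dZ %*% t(params[[key]]$W)
      dA <- array(0, ca$dimA)
      for (o in 1:3) {
        dA[, o:(Lout + o - 1L), ] <- dA[, o:(Lout + o - 1L), , drop = FALSE] +
          array(dcols[, ((o - 1L) * Cin + 1L):(o * Cin)], c(B, Lout, Cin))
      }
      G <- dA
    }
  }
  grads
}

#' Fit the CNN calibration model
#'
#' Trains the [build_cnn()] network by mini-batch Adam on the
#' mean-squared-error loss: learning rate 1e-4, batch size 50, at most
#' 200 epochs, early stopping when the training loss has not improved for
#' 40 epochs. Targets are z-scored internally; inputs are expected on the
#' preprocessed [0, 1] scale. Fully seeded (initialization and batch
#' shuffling), so identical seeds give identical models.
#'
#' @param X Calibration spectra (samples x channels).
#' @param y Reference values.
#' @param spec A [cnn_spec()]; its `attribute` decides the pooling/dense
#'   variant.
#' @param seed Integer seed.
#' @param verbose Print the loss every 20 epochs.
#' @return A `raman_model` (engine `"cnn"`) with the training history.
#' @export
fit_cnn <- function(X, y, spec = cnn_spec(), seed = 1L, verbose = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  graph <- build_cnn(spec, ncol(X))
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  with_seed(seed, {
    params <- cnn_init(graph)
    state <- list()
    for (i in seq_along(graph$layers)) {
      l <- graph$layers[[i]]
      if (l$type == "batchnorm") {
        state[[paste0("L", i)]] <- list(mean = numeric(l$channels),
                                        var = rep(1, l$channels))
      }
    }
    adam_m <- rapply(params, function(x) x * 0, how = "replace")
    adam_v <- adam_m
    lr <- spec$learning_rate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    history <- numeric(0)
    best_loss <- Inf
    stall <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + spec$batch_size - 1L, n)]
        fw <- cnn_forward(graph, params, state, X[idx, , drop = FALSE],
                          training = TRUE)
        state <- fw$state
        resid <- fw$out - ys[idx]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop(sprintf("CNN training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- cnn_backward(graph, params, fw$caches,
                              2 * resid / length(idx))
        t_step <- t_step + 1L
        corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
        for (key in names(grads)) {
          for (part in c("W", "b")) {
            g <- grads[[key]][[part]]
            adam_m[[key]][[part]] <- b1 * adam_m[[key]][[part]] + (1 - b1) * g
            adam_v[[key]][[part]] <- b2 * adam_v[[key]][[part]] +
              (1 - b2) * g^2
            params[[key]][[part]] <- params[[key]][[part]] -
              lr * corr * adam_m[[key]][[part]] /
              (sqrt(adam_v[[key]][[part]]) + eps)
          }
        }
      }
      ep_loss <- ep_loss / n
      history <- c(history, ep_loss)
      if (verbose && epoch %% 20L == 0L) {
        message(sprintf("epoch %d: loss %.6f", epoch, ep_loss))
      }
      if (ep_loss < best_loss - 1e-12) {
        best_loss <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec$patience) break
      }
    }
    train_pred <- cnn_forward(graph, params, state, X)$out * y_sd + y_mean
    structure(list(engine = "cnn", graph = graph, spec = spec,
                   params = params, state = state,
                   y_center = y_mean, y_scale = y_sd,
                   n_channels = ncol(X), seed = seed,
                   history = history,
                   training = list(predictions = train_pred, y = y)),
              class = "raman_model")
  })
}

predict_cnn <- function(model, X_new) {
  cnn_forward(model$graph, model$params, model$state, X_new)$out *
    model$y_scale + model$y_center
}
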