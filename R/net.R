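# Minimal convolutional network engine used by the tiny multibox detector.
#
# Activations are stored as 4-D arrays with dimension order [H, W, N, C]
# (rows, columns, batch, channels). That order lets a convolution be computed
# as k*k shifted matrix products against (H*W*N) x C matrices without any
# aperm in the inner loop, which is what keeps pure-R training tractable.
# All layers provide an exact analytic backward pass; the loss gradients are
# verified against central finite differences in the test suite.

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

conv_forward <- function(x, W, b, stride = 1L, pad = 1L) {
  out <- conv_fw_cpp(x, dim(x), W, dim(W), b, stride, pad)
  list(out = out, x = x, stride = stride, pad = pad, k = dim(W)[1],
       in_dim = dim(x))
}

conv_backward <- function(dout, cache, W) {
  conv_bw_cpp(cache$x, cache$in_dim, W, dim(W), dout, cache$stride, cache$pad)
}

# Pure-R reference implementations of the convolution kernels (shift-and-
# multiply). Retained as the independent cross-check for the compiled path.
conv_forward_ref <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  if (pad > 0L) {
    xp <- array(0, c(Hp, Wp, N, Cin))
    xp[pad + seq_len(H), pad + seq_len(Wd), , ] <- x
  } else xp <- x
  Ho <- conv_out_dim(H, k, stride, pad); Wo <- conv_out_dim(Wd, k, stride, pad)
  out <- matrix(rep(b, each = Ho * Wo * N), Ho * Wo * N, Cout)
  for (di in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    for (dj in seq_len(k)) {
      cj <- seq.int(dj, by = stride, length.out = Wo)
      xs <- xp[ri, cj, , , drop = FALSE]
      Ws <- matrix(W[di, dj, , ], Cin, Cout)
      out <- out + as_mat(xs) %*% Ws
    }
  }
  dim(out) <- c(Ho, Wo, N, Cout)
  list(out = out, xp = xp, stride = stride, pad = pad, k = k,
       in_dim = c(H, Wd, N, Cin))
}

conv_backward_ref <- function(dout, cache, W) {
  d <- dim(dout); Ho <- d[1]; Wo <- d[2]; N <- d[3]; Cout <- d[4]
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  idm <- cache$in_dim; Cin <- idm[4]
  dmat <- as_mat(dout)
  db <- colSums(dmat)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cache$xp))
  for (di in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = Ho)
    for (dj in seq_len(k)) {
      cj <- seq.int(dj, by = stride, length.out = Wo)
      xs <- as_mat(cache$xp[ri, cj, , , drop = FALSE])
      dW[di, dj, , ] <- crossprod(xs, dmat)
      Ws <- matrix(W[di, dj, , ], Cin, Cout)
      dpatch <- dmat %*% t(Ws)
      dim(dpatch) <- c(Ho, Wo, N, Cin)
      dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] + dpatch
    }
  }
  dx <- if (pad > 0L) {
    dxp[pad + seq_len(idm[1]), pad + seq_len(idm[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)

relu_backward <- function(dout, cache) dout * cache$mask

# 2x2 max pooling, stride 2. Ties route the gradient to the first window
# position in (top-left, bottom-left, top-right, bottom-right) order.
pool_forward <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  ri <- seq.int(1L, H, by = 2L); ci <- seq.int(1L, Wd, by = 2L)
  x11 <- x[ri, ci, , , drop = FALSE]
  x21 <- x[ri + 1L, ci, , , drop = FALSE]
  x12 <- x[ri, ci + 1L, , , drop = FALSE]
  x22 <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  w11 <- x11 == m
  w21 <- x21 == m & !w11
  w12 <- x12 == m & !w11 & !w21
  w22 <- !(w11 | w21 | w12)
  list(out = m, masks = list(w11, w21, w12, w22), in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  ri <- seq.int(1L, d[1], by = 2L); ci <- seq.int(1L, d[2], by = 2L)
  dx[ri, ci, , ] <- dout * cache$masks[[1]]
  dx[ri + 1L, ci, , ] <- dout * cache$masks[[2]]
  dx[ri, ci + 1L, , ] <- dout * cache$masks[[3]]
  dx[ri + 1L, ci + 1L, , ] <- dout * cache$masks[[4]]
  dx
}

init_conv_params <- function(k, cin, cout) {
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

# Run the backbone; returns activations after every layer (named by layer)
# so detection heads and Grad-CAM can tap arbitrary points.
backbone_forward <- function(params, layers, x) {
  acts <- list(.input = x)
  caches <- list()
  cur <- x
  for (ly in layers) {
    res <- switch(ly$type,
      conv = conv_forward(cur, params[[ly$name]]$W, params[[ly$name]]$b,
                          ly$stride, ly$pad),
      relu = relu_forward(cur),
      pool = pool_forward(cur),
      stop("unknown layer type: ", ly$type))
    cur <- res$out
    acts[[ly$name]] <- cur
    caches[[ly$name]] <- res
  }
  list(acts = acts, caches = caches)
}

# Backpropagate `dacts` (a named list of gradients w.r.t. layer outputs,
# injected where present) down the backbone. Returns parameter gradients and
# gradients w.r.t. every layer activation, including the input.
backbone_backward <- function(params, layers, fw, dacts) {
  n <- length(layers)
  grads <- list()
  dact_out <- list()
  cur <- NULL
  for (i in rev(seq_len(n))) {
    ly <- layers[[i]]
    top <- dacts[[ly$name]]
    if (!is.null(top)) cur <- if (is.null(cur)) top else cur + top
    if (is.null(cur)) next
    dact_out[[ly$name]] <- cur
    cache <- fw$caches[[ly$name]]
    cur <- switch(ly$type,
      conv = {
        bk <- conv_backward(cur, cache, params[[ly$name]]$W)
        grads[[ly$name]] <- list(W = bk$dW, b = bk$db)
        bk$dx
      },
      relu = relu_backward(cur, cache),
      pool = pool_backward(cur, cache))
  }
  dact_out$.input <- cur
  list(grads = grads, dacts = dact_out)
}
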