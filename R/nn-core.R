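# Minimal convolutional-network engine: layers are mutable environments
# holding parameters, gradients and forward caches; networks are (possibly
# nested) lists of layers.  Feature maps are numeric arrays dim (H, W, C).
# Convolution kernels live in src/conv_ops.cpp.

.nn_state <- new.env(parent = emptyenv())
.nn_state$counter <- 0L

new_layer <- function(type, params = character(0)) {
  l <- new.env(parent = emptyenv())
  .nn_state$counter <- .nn_state$counter + 1L
  l$id <- .nn_state$counter
  l$type <- type
  l$params <- params
  l
}

as_fmap <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

reflect_idx <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  c(seq(p + 1L, 2L), seq_len(n), seq(n - 1L, n - p))
}

reflect_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  x[reflect_idx(d[1L], p), reflect_idx(d[2L], p), , drop = FALSE]
}

# Adjoint of reflect_pad: fold gradient contributions of reflected border
# rows/columns back onto their source positions.
reflect_pad_adjoint <- function(dyp, p, H, W) {
  if (p == 0L) return(dyp)
  C <- dim(dyp)[3L]
  ir <- reflect_idx(H, p)
  tmp <- array(0, c(H, W + 2L * p, C))
  for (r in seq_along(ir)) tmp[ir[r], , ] <- tmp[ir[r], , ] + dyp[r, , ]
  ic <- reflect_idx(W, p)
  dx <- array(0, c(H, W, C))
  for (cc in seq_along(ic)) dx[, ic[cc], ] <- dx[, ic[cc], ] + tmp[, cc, ]
  dx
}

# --- convolution ------------------------------------------------------------

new_conv <- function(cin, cout, k, stride = 1L, pad0 = 0L, pad1 = pad0,
                     pad_mode = c("zero", "reflect"), init_sd = 0.02) {
  pad_mode <- match.arg(pad_mode)
  l <- new_layer("conv", c("W", "b"))
  l$cin <- cin; l$cout <- cout; l$k <- as.integer(k)
  l$stride <- as.integer(stride)
  l$pad0 <- as.integer(pad0); l$pad1 <- as.integer(pad1)
  l$pad_mode <- pad_mode
  l$W <- matrix(stats::rnorm(k * k * cin * cout, sd = init_sd),
                k * k * cin, cout)
  l$b <- rep(0, cout)
  l
}

conv_forward <- function(l, x) {
  if (l$pad_mode == "reflect") {
    l$orig_dim <- dim(x)
    x <- reflect_pad(x, l$pad0)
    l$x <- x
    nn_conv_fwd(x, l$W, l$b, l$k, l$stride, 0L, 0L)
  } else {
    l$x <- x
    nn_conv_fwd(x, l$W, l$b, l$k, l$stride, l$pad0, l$pad1)
  }
}

conv_backward <- function(l, dy) {
  if (l$pad_mode == "reflect") {
    g <- nn_conv_bwd(l$x, l$W, dy, l$k, l$stride, 0L, 0L)
    dx <- reflect_pad_adjoint(g$dx, l$pad0, l$orig_dim[1L], l$orig_dim[2L])
  } else {
    g <- nn_conv_bwd(l$x, l$W, dy, l$k, l$stride, l$pad0, l$pad1)
    dx <- g$dx
  }
  l$g_W <- if (is.null(l$g_W)) g$dw else l$g_W + g$dw
  l$g_b <- if (is.null(l$g_b)) as.numeric(g$db) else l$g_b + as.numeric(g$db)
  dx
}

# --- transposed convolution (fractionally strided) --------------------------

new_convt <- function(cin, cout, k = 3L, stride = 2L, pad = 1L, out_pad = 1L,
                      init_sd = 0.02) {
  l <- new_layer("convt", c("W", "b"))
  l$cin <- cin; l$cout <- cout
  l$k <- as.integer(k); l$stride <- as.integer(stride)
  l$pad0 <- as.integer(pad); l$pad1 <- as.integer(pad - out_pad)
  l$W <- matrix(stats::rnorm(k * k * cout * cin, sd = 0.02),
                k * k * cout, cin)
  l$b <- rep(0, cout)
  l
}

convt_forward <- function(l, x) {
  l$x <- x
  d <- dim(x)
  ho <- (d[1L] - 1L) * l$stride - (l$pad0 + l$pad1) + l$k
  wo <- (d[2L] - 1L) * l$stride - (l$pad0 + l$pad1) + l$k
  nn_convt_fwd(x, l$W, l$b, l$k, l$stride, l$pad0, l$pad1, ho, wo)
}

convt_backward <- function(l, dy) {
  g <- nn_convt_bwd(l$x, l$W, dy, l$k, l$stride, l$pad0, l$pad1)
  l$g_W <- if (is.null(l$g_W)) g$dw else l$g_W + g$dw
  l$g_b <- if (is.null(l$g_b)) as.numeric(g$db) else l$g_b + as.numeric(g$db)
  g$dx
}

# --- instance normalization -------------------------------------------------

new_inorm <- function(channels, eps = 1e-5) {
  l <- new_layer("inorm", c("gamma", "beta"))
  l$channels <- channels
  l$eps <- eps
  l$gamma <- rep(1, channels)
  l$beta <- rep(0, channels)
  l
}

inorm_forward <- function(l, x) {
  out <- nn_inorm_fwd(x, l$gamma, l$beta, l$eps)
  l$xhat <- out$xhat
  l$istd <- as.numeric(out$istd)
  out$y
}

inorm_backward <- function(l, dy) {
  g <- nn_inorm_bwd(l$xhat, l$istd, l$gamma, dy)
  l$g_gamma <- if (is.null(l$g_gamma)) as.numeric(g$g_gamma) else l$g_gamma + as.numeric(g$g_gamma)
  l$g_beta <- if (is.null(l$g_beta)) as.numeric(g$g_beta) else l$g_beta + as.numeric(g$g_beta)
  g$dx
}

# --- activations ------------------------------------------------------------

new_act <- function(kind, slope = 0.2) {
  l <- new_layer(kind)
  l$slope <- slope
  l
}

act_forward <- function(l, x) {
  switch(l$type,
    relu = { l$mask <- x > 0; x * l$mask },
    lrelu = { l$mask <- x > 0; x * (l$slope + (1 - l$slope) * l$mask) },
    tanh = { l$y <- tanh(x); l$y },
    ctmr_abort(paste("unknown activation", l$type), "ctmrsyn_config_error")
  )
}

act_backward <- function(l, dy) {
  switch(l$type,
    relu = dy * l$mask,
    lrelu = dy * (l$slope + (1 - l$slope) * l$mask),
    tanh = dy * (1 - l$y^2)
  )
}

# --- nearest-neighbour 2x upsampling (resize-conv alternative) --------------

new_upsample2 <- function() new_layer("upsample2")

upsample2_forward <- function(l, x) {
  d <- dim(x)
  l$dims <- d
  idx_r <- rep(seq_len(d[1L]), each = 2L)
  idx_c <- rep(seq_len(d[2L]), each = 2L)
  x[idx_r, idx_c, , drop = FALSE]
}

upsample2_backward <- function(l, dy) {
  d <- l$dims
  dx <- array(0, d)
  for (a in 1:2) for (b in 1:2) {
    dx <- dx + dy[seq(a, 2L * d[1L], by = 2L), seq(b, 2L * d[2L], by = 2L), ,
                  drop = FALSE]
  }
  dx
}

# --- residual block ---------------------------------------------------------

new_resblock <- function(channels, use_norm = TRUE) {
  l <- new_layer("resblock")
  inner <- list(new_conv(channels, channels, 3L, 1L, 1L))
  if (use_norm) inner <- c(inner, list(new_inorm(channels)))
  inner <- c(inner, list(new_act("relu")),
             list(new_conv(channels, channels, 3L, 1L, 1L)))
  if (use_norm) inner <- c(inner, list(new_inorm(channels)))
  l$layers <- inner
  l
}

# --- dispatch ---------------------------------------------------------------

layer_forward <- function(l, x) {
  switch(l$type,
    conv = conv_forward(l, x),
    convt = convt_forward(l, x),
    inorm = inorm_forward(l, x),
    relu = , lrelu = , tanh = act_forward(l, x),
    upsample2 = upsample2_forward(l, x),
    resblock = x + seq_forward(l$layers, x)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = conv_backward(l, dy),
    convt = convt_backward(l, dy),
    inorm = inorm_backward(l, dy),
    relu = , lrelu = , tanh = act_backward(l, dy),
    upsample2 = upsample2_backward(l, dy),
    resblock = dy + seq_backward(l$layers, dy)
  )
}

seq_forward <- function(layers, x) {
  for (l in layers) x <- layer_forward(l, x)
  x
}

seq_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

# --- parameter bookkeeping ---------------------------------------------------

# Flatten nested layer structures to a list of unique layer environments
# (shared trunks appear once: identity by layer id).
collect_layers <- function(x) {
  out <- list()
  walk <- function(obj) {
    if (is.environment(obj)) {
      if (identical(obj$type, "resblock")) {
        for (s in obj$layers) walk(s)
      }
      if (length(obj$params) > 0) out[[length(out) + 1L]] <<- obj
    } else if (is.list(obj)) {
      for (el in obj) walk(el)
    }
  }
  walk(x)
  ids <- vapply(out, function(l) l$id, integer(1))
  out[!duplicated(ids)]
}

zero_grads <- function(layers) {
  for (l in layers) for (p in l$params) l[[paste0("g_", p)]] <- NULL
  invisible(NULL)
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(l$params, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

# Serialize parameters (and optionally Adam state) to plain lists.
export_params <- function(layers, with_opt = FALSE) {
  lapply(layers, function(l) {
    out <- list(id = l$id, type = l$type)
    for (p in l$params) out[[p]] <- l[[p]]
    if (with_opt) {
      for (p in l$params) {
        out[[paste0("m_", p)]] <- l[[paste0("m_", p)]]
        out[[paste0("v_", p)]] <- l[[paste0("v_", p)]]
        out[[paste0("t_", p)]] <- l[[paste0("t_", p)]]
      }
    }
    out
  })
}

import_params <- function(layers, stored, with_opt = FALSE) {
  if (length(layers) != length(stored)) {
    version_error("checkpoint layer count does not match network architecture")
  }
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    s <- stored[[i]]
    for (p in l$params) {
      if (is.null(s[[p]]) || length(s[[p]]) != length(l[[p]])) {
        version_error(sprintf("checkpoint parameter '%s' incompatible with layer %d (%s)",
                              p, i, l$type))
      }
      l[[p]] <- s[[p]]
      if (with_opt) {
        l[[paste0("m_", p)]] <- s[[paste0("m_", p)]]
        l[[paste0("v_", p)]] <- s[[paste0("v_", p)]]
        l[[paste0("t_", p)]] <- s[[paste0("t_", p)]]
      }
    }
  }
  invisible(layers)
}

# --- Adam -------------------------------------------------------------------

adam_step <- function(layers, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    for (p in l$params) {
      g <- l[[paste0("g_", p)]]
      if (is.null(g)) next
      mkey <- paste0("m_", p); vkey <- paste0("v_", p); tkey <- paste0("t_", p)
      if (is.null(l[[mkey]])) {
        l[[mkey]] <- g * 0
        l[[vkey]] <- g * 0
        l[[tkey]] <- 0L
      }
      l[[tkey]] <- l[[tkey]] + 1L
      l[[mkey]] <- beta1 * l[[mkey]] + (1 - beta1) * g
      l[[vkey]] <- beta2 * l[[vkey]] + (1 - beta2) * g^2
      mhat <- l[[mkey]] / (1 - beta1^l[[tkey]])
      vhat <- l[[vkey]] / (1 - beta2^l[[tkey]])
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}
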