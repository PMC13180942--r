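# Minimal convolutional network engine: im2col-based conv layers with
# stride and zero padding (C++ kernels for the gather/scatter, BLAS for
# the matrix products), ReLU, global average pooling, and Adam. Layout
# conventions:
#   activations  : H x W x C x B arrays (batch last)
#   conv weights : Cout x (k*k*Cin) matrices, plus Cout bias vector
#   im2col       : (k*k*Cin) x (Hout*Wout*B) with sample-contiguous blocks

conv_geom <- function(h, w, cin, k, stride, pad) {
  hout <- (h + 2 * pad - k) %/% stride + 1L
  wout <- (w + 2 * pad - k) %/% stride + 1L
  list(h = h, w = w, cin = cin, k = k, stride = stride, pad = pad,
       hout = hout, wout = wout)
}

# Batched forward pass of one conv layer: returns pre-activations
# (Hout x Wout x Cout x B) and the im2col matrix for the backward pass.
conv_forward <- function(x, W, b, g) {
  B <- dim(x)[4]
  xcol <- cpp_im2col(x, g$h, g$w, g$cin, B, g$k, g$stride, g$pad,
                     g$hout, g$wout)
  y <- W %*% xcol + b  # Cout x (P*B)
  out <- aperm(array(y, c(nrow(W), g$hout, g$wout, B)), c(2, 3, 1, 4))
  list(out = out, xcol = xcol)
}

# Batched backward pass: given dY (Hout x Wout x Cout x B pre-activation
# gradients), returns batch-summed gradients for W and b and (if need_dx)
# the per-sample input gradients.
conv_backward <- function(dy, xcol, W, g, need_dx = TRUE) {
  B <- dim(dy)[4]
  P <- g$hout * g$wout
  dy_m <- matrix(aperm(dy, c(3, 1, 2, 4)), dim(dy)[3], P * B)
  dW <- tcrossprod(dy_m, xcol)
  db <- rowSums(dy_m)
  if (!need_dx) return(list(dW = dW, db = db, dx = NULL))
  dxcol <- crossprod(W, dy_m)  # K x (P*B)
  dx <- cpp_col2im(dxcol, g$h, g$w, g$cin, B, g$k, g$stride, g$pad,
                   g$hout, g$wout)
  list(dW = dW, db = db, dx = dx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Adam state and update (step counter per state object).
adam_init <- function(params) {
  # zero states shaped exactly like the parameters (keeps vectors vectors)
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
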