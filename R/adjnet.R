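# The adjudication network: a compact convolutional feature extractor, an
# L2-normalized embedding, and a two-layer head over the embedding
# concatenated with the detector confidence. Trained with focal loss,
# mini-batch Adam, optional per-epoch hard-negative mining, and early
# stopping on validation F1.

#' Construct an adjudicator model
#'
#' The backbone is a stack of 3x3 stride-2 zero-padded convolutions with
#' ReLU, followed by global average pooling into a d-dimensional embedding
#' (d = last channel count). The embedding is L2-normalized, concatenated
#' with the detector confidence, and passed through a two-layer perceptron
#' (ReLU hidden layer, sigmoid output). The framework is backbone-agnostic:
#' any feature extractor exposing the same contract could stand behind
#' \code{embed}; the default compact stack keeps a full benchmark run
#' desk-scale. Weights use He-style initialization from \code{seed}.
#'
#' @param patch_size Input patch side length.
#' @param channels Integer vector of conv output channels per stage.
#' @param kernel,stride Convolution kernel size and stride (zero padding
#'   \code{(kernel - 1) / 2}).
#' @param hidden Hidden width of the classification head.
#' @param use_confidence If \code{FALSE}, the detector confidence input is
#'   ablated (replaced by 0), giving a plain patch classifier with the same
#'   capacity.
#' @param input_mean,input_sd Input standardization applied to every patch
#'   before the first convolution (patches arrive as raw intensities in
#'   \code{[0, 1]}; defaults center them near zero at unit-ish scale).
#' @param seed Integer seed for initialization.
#' @return An \code{adjudicator_model} object.
#' @export
adjudicator_model <- function(patch_size = 64L, channels = c(8L, 16L, 32L, 64L),
                              kernel = 3L, stride = 2L, hidden = 64L,
                              use_confidence = TRUE, input_mean = 0.5,
                              input_sd = 0.25, seed = 1L) {
  pad <- (kernel - 1L) %/% 2L
  geoms <- list()
  h <- patch_size; w <- patch_size; cin <- 1L
  for (l in seq_along(channels)) {
    g <- conv_geom(h, w, cin, kernel, stride, pad)
    geoms[[l]] <- g
    h <- g$hout; w <- g$wout; cin <- channels[l]
  }
  d <- channels[length(channels)]
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_along(channels)) {
      fan_in <- kernel * kernel * cin
      p[[paste0("Wc", l)]] <- matrix(
        stats::rnorm(channels[l] * fan_in, 0, sqrt(2 / fan_in)),
        channels[l], fan_in)
      p[[paste0("bc", l)]] <- numeric(channels[l])
      cin <- channels[l]
    }
    p$W1 <- matrix(stats::rnorm(hidden * (d + 1L), 0, sqrt(2 / (d + 1L))),
                   hidden, d + 1L)
    p$b1 <- numeric(hidden)
    p$W2 <- matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), 1L, hidden)
    p$b2 <- 0
    p
  })
  structure(list(patch_size = as.integer(patch_size),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 stride = as.integer(stride), pad = pad,
                 hidden = as.integer(hidden), d = as.integer(d),
                 use_confidence = isTRUE(use_confidence),
                 input_mean = input_mean, input_sd = input_sd,
                 params = params, geoms = geoms,
                 seed = as.integer(seed)),
            class = "adjudicator_model")
}

# Batched forward pass over B patches; with cache = TRUE also returns
# everything backward passes need (im2col matrices, pre-activations,
# embedding internals). `patches` is a list of matrices or an
# H x W x B array; `s` a length-B confidence vector.
model_forward_batch <- function(model, patches, s, cache = FALSE) {
  p <- model$params
  psz <- model$patch_size
  if (is.list(patches)) {
    B <- length(patches)
    x <- array(unlist(patches, use.names = FALSE), c(psz, psz, 1L, B))
  } else {
    B <- if (length(dim(patches)) == 3L) dim(patches)[3] else 1L
    x <- array(patches, c(psz, psz, 1L, B))
  }
  x <- (x - model$input_mean) / model$input_sd
  nl <- length(model$channels)
  pre <- vector("list", nl); xcols <- vector("list", nl)
  a <- x
  for (l in seq_len(nl)) {
    cf <- conv_forward(a, p[[paste0("Wc", l)]], p[[paste0("bc", l)]],
                       model$geoms[[l]])
    pre[[l]] <- cf$out
    xcols[[l]] <- cf$xcol
    a <- relu(cf$out)
  }
  A <- a  # last-stage activation maps (Grad-CAM target by default)
  g_last <- model$geoms[[nl]]
  zsp <- g_last$hout * g_last$wout
  Fm <- matrix(colMeans(matrix(A, zsp, model$d * B)), model$d, B)
  nrm <- sqrt(colSums(Fm^2))
  scale <- ifelse(nrm > 1e-12, 1 / nrm, 0)
  psi <- Fm * rep(scale, each = model$d)
  s_eff <- if (model$use_confidence) s else numeric(B)
  z <- rbind(psi, s_eff)
  h1 <- p$W1 %*% z + p$b1
  h <- relu(h1)
  logit <- as.vector(p$W2 %*% h + p$b2)
  yhat <- 1 / (1 + exp(-logit))
  if (!cache) return(yhat)
  list(yhat = yhat, logit = logit, psi = psi, f = Fm, nrm = nrm, z = z,
       h1 = h1, h = h, A = A, pre = pre, xcols = xcols, B = B)
}

# Single-sample convenience wrapper.
model_forward <- function(model, patch, s, cache = FALSE) {
  fw <- model_forward_batch(model, list(patch), s, cache = cache)
  if (!cache) return(fw[1])
  fw
}

# Batched backward pass from per-sample gradients on the logits. Returns
# batch-summed parameter gradients or, if `wrt_activation` is given, the
# per-sample gradients with respect to that conv stage's post-ReLU
# activation maps (for Grad-CAM).
model_backward_batch <- function(model, fw, dlogit, wrt_activation = NULL) {
  p <- model$params
  nl <- length(model$channels)
  B <- fw$B
  grads <- list()
  grads$W2 <- matrix(as.vector(fw$h %*% dlogit), 1L)
  grads$b2 <- sum(dlogit)
  dh <- (as.vector(p$W2) %o% dlogit) * (fw$h1 > 0)
  grads$W1 <- tcrossprod(dh, fw$z)
  grads$b1 <- rowSums(dh)
  dz <- crossprod(p$W1, dh)
  dpsi <- dz[seq_len(model$d), , drop = FALSE]
  scale <- ifelse(fw$nrm > 1e-12, 1 / fw$nrm, 0)
  dot <- colSums(fw$psi * dpsi)
  df <- (dpsi - fw$psi * rep(dot, each = model$d)) *
    rep(scale, each = model$d)
  g_last <- model$geoms[[nl]]
  zsp <- g_last$hout * g_last$wout
  dA <- array(matrix(rep(as.vector(df) / zsp, each = zsp), zsp,
                     model$d * B),
              c(g_last$hout, g_last$wout, model$d, B))
  if (identical(wrt_activation, nl)) {
    return(list(dA = dA))
  }
  da <- dA
  for (l in rev(seq_len(nl))) {
    dz_l <- da * (fw$pre[[l]] > 0)
    bk <- conv_backward(dz_l, fw$xcols[[l]], p[[paste0("Wc", l)]],
                        model$geoms[[l]],
                        need_dx = l > 1L ||
                          identical(wrt_activation, 0L))
    grads[[paste0("Wc", l)]] <- bk$dW
    grads[[paste0("bc", l)]] <- bk$db
    da <- bk$dx
    if (!is.null(wrt_activation) && wrt_activation == l - 1L) {
      return(list(dA = da))
    }
  }
  grads
}

# Single-sample wrapper returning gradients in the same shapes.
model_backward <- function(model, fw, dlogit, wrt_activation = NULL) {
  out <- model_backward_batch(model, fw, dlogit, wrt_activation)
  if (!is.null(out$dA)) {
    d <- dim(out$dA)
    out$dA <- array(out$dA, d[1:3])
  }
  out
}

#' L2-normalized feature embedding of a patch
#'
#' @param model An \code{adjudicator_model}.
#' @param patch Square numeric matrix of side \code{model$patch_size}.
#' @return Unit-norm numeric vector of length \code{model$d}.
#' @export
embed <- function(model, patch) {
  stopifnot(inherits(model, "adjudicator_model"))
  fw <- model_forward(model, patch, 0, cache = TRUE)
  if (fw$nrm[1] < 1e-12) {
    abort_input("degenerate embedding: feature vector has (near-)zero norm")
  }
  as.vector(fw$f) / fw$nrm[1]
}

#' Adjudicator probability for one ROI
#'
#' @param model An \code{adjudicator_model}.
#' @param patch Square numeric matrix of side \code{model$patch_size}.
#' @param s Detector confidence in \code{[0, 1]}.
#' @return Estimated probability in \code{(0, 1)} that the ROI contains a
#'   true fracture.
#' @export
adjudicate <- function(model, patch, s) {
  stopifnot(inherits(model, "adjudicator_model"))
  if (!is_prob(s)) abort_input("detector confidence s must lie in [0, 1]")
  model_forward(model, patch, s)
}

#' Adjudicator probabilities for a list of ROI records
#'
#' @param model An \code{adjudicator_model}.
#' @param records List of ROI records (elements \code{patch} and \code{s}).
#' @return Numeric vector of probabilities.
#' @export
predict_records <- function(model, records, chunk = 64L) {
  n <- length(records)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- model_forward_batch(
      model, lapply(records[idx], function(r) r$patch),
      vapply(records[idx], function(r) r$s, numeric(1)))
  }
  out
}

#' Focal loss
#'
#' Mean of \code{-[(1 - p)^gamma * y * log(p) + p^gamma * (1 - y) *
#' log(1 - p)]}. At \code{gamma = 0} this reduces to binary cross-entropy.
#' Probabilities are clamped to \code{[1e-7, 1 - 1e-7]} before logs.
#'
#' @param y_hat Predicted probabilities.
#' @param y Binary labels (0/1).
#' @param gamma Focusing exponent, \code{gamma >= 0}.
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(y_hat, y, gamma = 2) {
  if (gamma < 0) abort_input("gamma must be non-negative")
  check_scores_labels(y_hat, y)
  p <- clamp(y_hat, 1e-7, 1 - 1e-7)
  -mean((1 - p)^gamma * y * log(p) + p^gamma * (1 - y) * log(1 - p))
}

# d(focal)/d(logit), vectorized (p already sigmoid(logit)).
focal_grad_logit <- function(p, y, gamma) {
  pc <- clamp(p, 1e-7, 1 - 1e-7)
  dldp <- ifelse(y == 1,
                 gamma * (1 - pc)^(gamma - 1) * log(pc) - (1 - pc)^gamma / pc,
                 -gamma * pc^(gamma - 1) * log(1 - pc) + pc^gamma / (1 - pc))
  dldp * pc * (1 - pc)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe for the adjudicator: Adam
#' at learning rate 1e-4, batch size 32, up to 50 epochs, focal loss with
#' gamma = 2, early stopping on validation F1.
#'
#' @param max_epochs,batch_size,learning_rate,gamma,patience,seed See
#'   details; \code{patience} is the number of non-improving epochs
#'   tolerated before stopping.
#' @param optimizer Only \code{"adam"} is implemented.
#' @return A \code{train_config} list.
#' @export
train_config <- function(max_epochs = 50L, batch_size = 32L,
                         learning_rate = 1e-4, optimizer = "adam",
                         gamma = 2, patience = 10L, seed = 1L) {
  if (gamma < 0) abort_input("gamma must be non-negative")
  if (learning_rate <= 0) abort_input("learning_rate must be positive")
  if (!identical(optimizer, "adam")) abort_input("only adam is implemented")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 gamma = gamma, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

pool_sizes <- function(records) {
  prov <- vapply(records, function(r) r$provenance, character(1))
  c(P = sum(prov == "orig_pos"), N0 = sum(prov == "orig_neg"),
    Nh = sum(prov == "mined_neg"))
}

#' Train the adjudicator
#'
#' Mini-batch Adam on the focal loss. After every epoch the optional
#' \code{mining_hook(model, epoch)} may return additional hard-negative
#' records (provenance \code{mined_neg}), which are appended to the
#' training pool for subsequent epochs. Validation F1 (adjudicator
#' probability thresholded at 0.5; the fused operating point is selected
#' only after training) drives best-epoch retention and early stopping.
#' Patient disjointness between the training and validation records is
#' asserted up front.
#'
#' @param model An \code{adjudicator_model}.
#' @param train_records,val_records Lists of ROI records.
#' @param config A \code{\link{train_config}}.
#' @param mining_hook \code{NULL}, or \code{function(model, epoch)}
#'   returning a (possibly empty) list of mined-negative records.
#' @param augmentation \code{NULL}, or an \code{\link{aug_config}} applied
#'   to training patches (validation is always evaluated un-augmented).
#' @return List with \code{model} (parameters of the best-validation-F1
#'   epoch) and \code{history} (data frame: epoch, train_loss, val_f1,
#'   n_P, n_N0, n_Nh; attribute \code{selected_epoch}).
#' @export
train_adjudicator <- function(model, train_records, val_records, config,
                              mining_hook = NULL, augmentation = NULL) {
  stopifnot(inherits(model, "adjudicator_model"),
            inherits(config, "train_config"))
  if (length(train_records) == 0L) abort_input("empty training set")
  assert_patient_disjoint(list(train = train_records, val = val_records))
  val_y <- vapply(val_records, function(r) r$y, numeric(1))

  pool <- train_records
  opt <- adam_init(model$params)
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  history <- data.frame()
  bad_epochs <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, epoch), sample(length(pool)))
    total_loss <- 0; n_seen <- 0L
    for (start in seq(1L, length(pool), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(pool))]
      patches <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        patch <- pool[[idx[j]]]$patch
        if (!is.null(augmentation)) {
          patch <- augment(patch, augmentation,
                           seed = derive_seed(config$seed,
                                              epoch * 100003 + idx[j]))
        }
        patches[[j]] <- patch
      }
      ys <- vapply(pool[idx], function(r) r$y, numeric(1))
      ss <- vapply(pool[idx], function(r) r$s, numeric(1))
      fw <- model_forward_batch(model, patches, ss, cache = TRUE)
      total_loss <- total_loss + focal_loss(fw$yhat, ys, config$gamma) *
        length(idx)
      n_seen <- n_seen + length(idx)
      dlogit <- focal_grad_logit(fw$yhat, ys, config$gamma) / length(idx)
      gsum <- model_backward_batch(model, fw, dlogit)
      if (!all(vapply(gsum, function(x) all(is.finite(x)), logical(1)))) {
        stop("divergence: non-finite gradient", call. = FALSE)
      }
      up <- adam_step(model$params, gsum, opt, config$learning_rate)
      model$params <- up$params
      opt <- up$state
    }
    mean_loss <- total_loss / max(n_seen, 1L)
    if (!is.finite(mean_loss)) stop("divergence: non-finite loss", call. = FALSE)

    val_f1 <- if (length(val_records) > 0L) {
      f1_at_threshold(predict_records(model, val_records), val_y, 0.5)
    } else {
      NA_real_
    }

    if (!is.null(mining_hook)) {
      mined <- mining_hook(model, epoch)
      if (length(mined) > 0L) pool <- c(pool, mined)
    }
    ps <- pool_sizes(pool)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean_loss, val_f1 = val_f1,
      n_P = ps[["P"]], n_N0 = ps[["N0"]], n_Nh = ps[["Nh"]]))

    if (is.na(val_f1) || val_f1 >= best$f1) {
      best <- list(f1 = ifelse(is.na(val_f1), -Inf, val_f1),
                   params = model$params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model$params <- best$params
  attr(history, "selected_epoch") <- best$epoch
  list(model = model, history = history)
}
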