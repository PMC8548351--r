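# The torsion-angle network: a unidirectional LSTM in parallel with a
# BiLSTM, their per-position outputs concatenated into a second BiLSTM,
# then FC-1 (ReLU, dropout) and FC-2 (4 sigmoid outputs). Implemented
# natively: forward pass, backpropagation through time, Adam. Variable
# chain lengths are handled by zeroing the recurrent state at padded
# steps, so padding never influences real positions in either direction.

sigmoid <- function(x) 1 / (1 + exp(-x))

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Model configuration
#'
#' @param input_width Feature width (default 232).
#' @param lstm1_hidden Hidden size of the unidirectional LSTM.
#' @param bilstm_hidden Hidden size per direction of the first BiLSTM.
#' @param bilstm2_hidden Hidden size per direction of the second BiLSTM.
#' @param fc1_units Units in the first fully connected layer (ReLU).
#' @param fc1_dropout Drop probability applied after FC-1 during training.
#' @param seed Integer seed for weight initialization.
#' @return A `model_config` list. The defaults (hidden size 352
#'   throughout, FC-1 256) give 6,620,292 learnable parameters.
#' @export
model_config <- function(input_width = 232L, lstm1_hidden = 352L,
                         bilstm_hidden = 352L, bilstm2_hidden = 352L,
                         fc1_units = 256L, fc1_dropout = 0.8, seed = 1L) {
  stopifnot(input_width > 0, lstm1_hidden > 0, bilstm_hidden > 0,
            bilstm2_hidden > 0, fc1_units > 0,
            fc1_dropout >= 0, fc1_dropout < 1)
  structure(list(input_width = as.integer(input_width),
                 lstm1_hidden = as.integer(lstm1_hidden),
                 bilstm_hidden = as.integer(bilstm_hidden),
                 bilstm2_hidden = as.integer(bilstm2_hidden),
                 fc1_units = as.integer(fc1_units),
                 fc1_dropout = fc1_dropout,
                 output_units = 4L,
                 seed = as.integer(seed)),
            class = "model_config")
}

init_lstm <- function(input, hidden) {
  k <- 1 / sqrt(hidden)
  W <- matrix(stats::runif((input + hidden) * 4 * hidden, -k, k),
              input + hidden, 4 * hidden)
  b <- stats::runif(4 * hidden, -k, k)
  b[(hidden + 1):(2 * hidden)] <- b[(hidden + 1):(2 * hidden)] + 1  # forget bias
  list(W = W, b = b)
}

init_fc <- function(input, output) {
  k <- 1 / sqrt(input)
  list(W = matrix(stats::runif(input * output, -k, k), input, output),
       b = stats::runif(output, -k, k))
}

#' Build the torsion-angle network
#'
#' Initializes all weights (uniform in `+-1/sqrt(hidden)`, forget-gate
#' bias offset +1) from `config$seed`.
#'
#' @param config A [model_config()].
#' @param scaler Optional `channel_scaler` carried with the model.
#' @return An `esiden_model`: list with `config`, `weights`, `scaler`.
#' @export
build_model <- function(config = model_config(), scaler = NULL) {
  stopifnot(inherits(config, "model_config"))
  I <- config$input_width
  H1 <- config$lstm1_hidden; H2 <- config$bilstm_hidden
  H3 <- config$bilstm2_hidden; Fu <- config$fc1_units
  weights <- with_seed(config$seed, list(
    l1 = init_lstm(I, H1),
    l2f = init_lstm(I, H2),
    l2b = init_lstm(I, H2),
    l3f = init_lstm(H1 + 2L * H2, H3),
    l3b = init_lstm(H1 + 2L * H2, H3),
    fc1 = init_fc(2L * H3, Fu),
    fc2 = init_fc(Fu, 4L)
  ))
  structure(list(config = config, weights = weights, scaler = scaler),
            class = "esiden_model")
}

#' @export
print.esiden_model <- function(x, ...) {
  cat(sprintf(
    "<esiden_model> input %d | LSTM %d + BiLSTM 2x%d -> BiLSTM 2x%d | FC %d -> 4 (%s parameters)\n",
    x$config$input_width, x$config$lstm1_hidden, x$config$bilstm_hidden,
    x$config$bilstm2_hidden, x$config$fc1_units,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count learnable parameters
#'
#' @param model An `esiden_model`.
#' @return Integer-valued count of all learnable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$weights, function(layer) {
    sum(vapply(layer, length, integer(1)))
  }, numeric(1)))
}

# ---- LSTM forward / backward -------------------------------------------

# xs: list over time of [B x I]; mask: [B x T] (1 real, 0 padded).
lstm_forward <- function(xs, layer, mask, reverse = FALSE, keep_cache = FALSE) {
  T <- length(xs)
  B <- nrow(xs[[1]])
  H <- length(layer$b) / 4L
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_g <- (2 * H + 1):(3 * H); idx_o <- (3 * H + 1):(4 * H)
  order_t <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", T)
  cache <- if (keep_cache) vector("list", T) else NULL
  for (t in order_t) {
    inp <- cbind(xs[[t]], h)
    z <- inp %*% layer$W
    z <- sweep(z, 2, layer$b, "+")
    gi <- sigmoid(z[, idx_i, drop = FALSE])
    gf <- sigmoid(z[, idx_f, drop = FALSE])
    gg <- tanh(z[, idx_g, drop = FALSE])
    go <- sigmoid(z[, idx_o, drop = FALSE])
    c_raw <- gf * cc + gi * gg
    tc <- tanh(c_raw)
    h_raw <- go * tc
    m <- mask[, t]
    if (keep_cache) {
      cache[[t]] <- list(inp = inp, gi = gi, gf = gf, gg = gg, go = go,
                         c_prev = cc, tc = tc, m = m)
    }
    h <- h_raw * m
    cc <- c_raw * m
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache, order = order_t)
}

# dhs: list over time of [B x H] external gradients on the (masked) outputs.
lstm_backward <- function(dhs, layer, fwd) {
  T <- length(dhs)
  B <- nrow(dhs[[1]])
  H <- length(layer$b) / 4L
  I <- nrow(layer$W) - H
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- numeric(length(layer$b))
  dxs <- vector("list", T)
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  for (t in rev(fwd$order)) {
    ca <- fwd$cache[[t]]
    m <- ca$m
    dh_raw <- (dhs[[t]] + dh_carry) * m
    dc_raw <- dc_carry * m + dh_raw * ca$go * (1 - ca$tc^2)
    dzo <- dh_raw * ca$tc * ca$go * (1 - ca$go)
    dzi <- dc_raw * ca$gg * ca$gi * (1 - ca$gi)
    dzf <- dc_raw * ca$c_prev * ca$gf * (1 - ca$gf)
    dzg <- dc_raw * ca$gi * (1 - ca$gg^2)
    dz <- cbind(dzi, dzf, dzg, dzo)
    dW <- dW + crossprod(ca$inp, dz)
    db <- db + colSums(dz)
    dinp <- tcrossprod(dz, layer$W)
    dxs[[t]] <- dinp[, seq_len(I), drop = FALSE]
    dh_carry <- dinp[, I + seq_len(H), drop = FALSE]
    dc_carry <- dc_raw * ca$gf
  }
  list(dW = dW, db = db, dxs = dxs)
}

# ---- full network forward / backward -----------------------------------

# X: list over time of [B x I]; mask [B x T].
net_forward <- function(model, X, mask, training = FALSE,
                        dropout_rng = NULL, keep_cache = FALSE) {
  w <- model$weights
  T <- length(X); B <- nrow(X[[1]])
  f1 <- lstm_forward(X, w$l1, mask, reverse = FALSE, keep_cache = keep_cache)
  f2f <- lstm_forward(X, w$l2f, mask, reverse = FALSE, keep_cache = keep_cache)
  f2b <- lstm_forward(X, w$l2b, mask, reverse = TRUE, keep_cache = keep_cache)
  U <- vector("list", T)
  for (t in seq_len(T)) U[[t]] <- cbind(f1$hs[[t]], f2f$hs[[t]], f2b$hs[[t]])
  f3f <- lstm_forward(U, w$l3f, mask, reverse = FALSE, keep_cache = keep_cache)
  f3b <- lstm_forward(U, w$l3b, mask, reverse = TRUE, keep_cache = keep_cache)
  V <- matrix(0, B * T, 2L * model$config$bilstm2_hidden)
  for (t in seq_len(T)) {
    V[(t - 1L) * B + seq_len(B), ] <- cbind(f3f$hs[[t]], f3b$hs[[t]])
  }
  Z1 <- sweep(V %*% w$fc1$W, 2, w$fc1$b, "+")
  A1 <- pmax(Z1, 0)
  drop_mask <- NULL
  p <- model$config$fc1_dropout
  if (training && p > 0) {
    stopifnot(!is.null(dropout_rng))
    keep <- 1 - p
    drop_mask <- matrix(stats::rbinom(length(A1), 1L, keep), nrow(A1)) / keep
    A1 <- A1 * drop_mask
  }
  Z2 <- sweep(A1 %*% w$fc2$W, 2, w$fc2$b, "+")
  Y <- sigmoid(Z2)  # [B*T x 4], row block t holds batch rows at time t
  out <- list(Y = Y, B = B, T = T)
  if (keep_cache) {
    out <- c(out, list(f1 = f1, f2f = f2f, f2b = f2b, f3f = f3f, f3b = f3b,
                       U = U, V = V, Z1 = Z1, A1 = A1, drop_mask = drop_mask))
  }
  out
}

# dY: [B*T x 4] gradient of the loss wrt the sigmoid outputs.
net_backward <- function(model, fwd, dY) {
  w <- model$weights
  B <- fwd$B; T <- fwd$T
  H1 <- model$config$lstm1_hidden
  H2 <- model$config$bilstm_hidden
  H3 <- model$config$bilstm2_hidden
  dZ2 <- dY * fwd$Y * (1 - fwd$Y)
  g_fc2 <- list(W = crossprod(fwd$A1, dZ2), b = colSums(dZ2))
  dA1 <- tcrossprod(dZ2, w$fc2$W)
  if (!is.null(fwd$drop_mask)) dA1 <- dA1 * fwd$drop_mask
  dZ1 <- dA1 * (fwd$Z1 > 0)
  g_fc1 <- list(W = crossprod(fwd$V, dZ1), b = colSums(dZ1))
  dV <- tcrossprod(dZ1, w$fc1$W)
  d3f <- vector("list", T); d3b <- vector("list", T)
  for (t in seq_len(T)) {
    rows <- (t - 1L) * B + seq_len(B)
    d3f[[t]] <- dV[rows, seq_len(H3), drop = FALSE]
    d3b[[t]] <- dV[rows, H3 + seq_len(H3), drop = FALSE]
  }
  b3f <- lstm_backward(d3f, w$l3f, fwd$f3f)
  b3b <- lstm_backward(d3b, w$l3b, fwd$f3b)
  d1 <- vector("list", T); d2f <- vector("list", T); d2b <- vector("list", T)
  for (t in seq_len(T)) {
    dU <- b3f$dxs[[t]] + b3b$dxs[[t]]
    d1[[t]] <- dU[, seq_len(H1), drop = FALSE]
    d2f[[t]] <- dU[, H1 + seq_len(H2), drop = FALSE]
    d2b[[t]] <- dU[, H1 + H2 + seq_len(H2), drop = FALSE]
  }
  b1 <- lstm_backward(d1, w$l1, fwd$f1)
  b2f <- lstm_backward(d2f, w$l2f, fwd$f2f)
  b2b <- lstm_backward(d2b, w$l2b, fwd$f2b)
  list(l1 = list(W = b1$dW, b = b1$db),
       l2f = list(W = b2f$dW, b = b2f$db),
       l2b = list(W = b2b$dW, b = b2b$db),
       l3f = list(W = b3f$dW, b = b3f$db),
       l3b = list(W = b3b$dW, b = b3b$db),
       fc1 = g_fc1, fc2 = g_fc2)
}

# ---- target encoding ----------------------------------------------------

#' Encode torsion angles as sigmoid-range targets
#'
#' Maps each angle to `(sin, cos)` and then affinely to `[0, 1]` via
#' `t = (x + 1) / 2`, matching the network's sigmoid outputs. Target
#' order per residue: sin(phi), cos(phi), sin(psi), cos(psi). Masks
#' propagate from the torsion series.
#'
#' @param torsions A `torsion_series`.
#' @return An `angle_encoding`: list with `targets` (L x 4 in `[0, 1]`)
#'   and `mask` (L x 4 logical).
#' @export
encode_targets <- function(torsions) {
  rad <- pi / 180
  phi <- torsions$phi * rad
  psi <- torsions$psi * rad
  targets <- cbind((sin(phi) + 1) / 2, (cos(phi) + 1) / 2,
                   (sin(psi) + 1) / 2, (cos(psi) + 1) / 2)
  mask <- cbind(torsions$phi_mask, torsions$phi_mask,
                torsions$psi_mask, torsions$psi_mask)
  colnames(targets) <- colnames(mask) <- c("sin_phi", "cos_phi",
                                           "sin_psi", "cos_psi")
  structure(list(targets = targets, mask = mask), class = "angle_encoding")
}

#' Decode network outputs to torsion angles
#'
#' Inverts the affine target map and applies the quadrant-aware
#' two-argument arctangent (the single-argument ratio form loses the
#' quadrant), giving degrees in `[-180, 180)`. Positions where both the
#' recovered sine and cosine are within `eps` of zero are masked with a
#' warning.
#'
#' @param outputs L x 4 matrix in `(0, 1)`, columns ordered sin(phi),
#'   cos(phi), sin(psi), cos(psi).
#' @param eps Degeneracy threshold on the recovered (sin, cos) pair.
#' @param aa Optional residue letters.
#' @return A `torsion_series` tibble (terminal phi/psi masked).
#' @export
decode_predictions <- function(outputs, eps = 1e-6, aa = NULL) {
  outputs <- as.matrix(outputs)
  stopifnot(ncol(outputs) == 4L)
  s_phi <- 2 * outputs[, 1] - 1; c_phi <- 2 * outputs[, 2] - 1
  s_psi <- 2 * outputs[, 3] - 1; c_psi <- 2 * outputs[, 4] - 1
  L <- nrow(outputs)
  phi <- wrap_angle(atan2(s_phi, c_phi) * 180 / pi)
  psi <- wrap_angle(atan2(s_psi, c_psi) * 180 / pi)
  phi_mask <- c(FALSE, rep(TRUE, L - 1L))
  psi_mask <- c(rep(TRUE, L - 1L), FALSE)
  deg_phi <- abs(s_phi) < eps & abs(c_phi) < eps
  deg_psi <- abs(s_psi) < eps & abs(c_psi) < eps
  if (any(deg_phi & phi_mask) || any(deg_psi & psi_mask)) {
    warning("degenerate (sin, cos) near zero at ",
            sum(deg_phi & phi_mask) + sum(deg_psi & psi_mask),
            " position(s); masking them")
  }
  new_torsion_series(phi, psi, phi_mask & !deg_phi, psi_mask & !deg_psi,
                     aa = aa)
}

# ---- training -----------------------------------------------------------

adam_init <- function(weights) {
  list(m = rapply(weights, function(x) x * 0, how = "replace"),
       v = rapply(weights, function(x) x * 0, how = "replace"),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(weights, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (layer in names(weights)) {
    for (p in names(weights[[layer]])) {
      g <- grads[[layer]][[p]]
      state$m[[layer]][[p]] <- beta1 * state$m[[layer]][[p]] + (1 - beta1) * g
      state$v[[layer]][[p]] <- beta2 * state$v[[layer]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[layer]][[p]] / bc1
      vhat <- state$v[[layer]][[p]] / bc2
      weights[[layer]][[p]] <- weights[[layer]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, state = state)
}

# Pad a set of examples into batch tensors. Examples: list of
# list(x = L x I, y = L x 4, mask = L x 4 logical).
make_batch <- function(examples, pad_to = NULL) {
  B <- length(examples)
  lens <- vapply(examples, function(e) nrow(e$x), integer(1))
  T <- pad_to %||% max(lens)
  I <- ncol(examples[[1]]$x)
  X <- lapply(seq_len(T), function(t) matrix(0, B, I))
  Ymask <- matrix(FALSE, B * T, 4L)
  Ytar <- matrix(0, B * T, 4L)
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    e <- examples[[b]]
    for (t in seq_len(lens[b])) X[[t]][b, ] <- e$x[t, ]
    mask[b, seq_len(lens[b])] <- 1
    rows <- (seq_len(lens[b]) - 1L) * B + b
    Ytar[rows, ] <- e$y
    Ymask[rows, ] <- e$mask
  }
  list(X = X, mask = mask, Ytar = Ytar, Ymask = Ymask, lens = lens)
}

batch_loss_grad <- function(model, batch, training = TRUE) {
  fwd <- net_forward(model, batch$X, batch$mask, training = training,
                     dropout_rng = TRUE, keep_cache = TRUE)
  n <- sum(batch$Ymask)
  if (n == 0) stop("batch has no unmasked target entries")
  diff <- (fwd$Y - batch$Ytar) * batch$Ymask
  loss <- sum(diff^2) / n
  dY <- 2 * diff / n
  grads <- net_backward(model, fwd, dY)
  list(loss = loss, grads = grads)
}

# mean squared error on unmasked entries, dropout off
dataset_mse <- function(model, examples) {
  tot <- 0; n <- 0
  for (e in examples) {
    b <- make_batch(list(e))
    fwd <- net_forward(model, b$X, b$mask, training = FALSE)
    d <- (fwd$Y - b$Ytar) * b$Ymask
    tot <- tot + sum(d^2)
    n <- n + sum(b$Ymask)
  }
  tot / n
}

predict_example <- function(model, x) {
  b <- make_batch(list(list(x = x, y = matrix(0, nrow(x), 4),
                            mask = matrix(FALSE, nrow(x), 4))))
  fwd <- net_forward(model, b$X, b$mask, training = FALSE)
  fwd$Y  # B = 1, so row t is time t directly
}

dataset_val_mae <- function(model, examples) {
  preds <- vector("list", length(examples))
  refs <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    e <- examples[[i]]
    Y <- predict_example(model, e$x)
    preds[[i]] <- suppressWarnings(decode_predictions(Y))
    refs[[i]] <- decode_predictions(e$y)
    # restrict to the example's own masks
    refs[[i]]$phi_mask <- e$mask[, 1]
    refs[[i]]$psi_mask <- e$mask[, 3]
  }
  rep <- mae(preds, refs)
  (rep$mae_phi + rep$mae_psi) / 2
}

#' Train the torsion-angle network
#'
#' Minimizes the mean squared error over unmasked sin/cos target entries
#' with Adam (learning rate 0.001 by default), batch size 32 with
#' length-bucketed padding, up to `max_steps` optimizer steps. The best
#' weights by validation MAE are kept. Fully reproducible given
#' `config$seed` and `seed`.
#'
#' @param model An `esiden_model` from [build_model()].
#' @param dataset List of examples, each `list(x, y, mask)` with `x` an
#'   L x input_width matrix, `y` an L x 4 target matrix, `mask` an L x 4
#'   logical (e.g. from [make_toy_dataset()]).
#' @param val_dataset Optional held-out examples for validation MAE; if
#'   `NULL`, `val_fraction` of `dataset` is split off (seeded).
#' @param max_steps Maximum optimizer steps (default 5000).
#' @param batch_size Chains per batch (default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param eval_every Steps between validation evaluations.
#' @param val_fraction Fraction split off when `val_dataset` is `NULL`.
#' @param seed Seed for shuffling, dropout and the validation split.
#' @param verbose Print progress.
#' @return A `train_state`: list with the trained `model` (best weights),
#'   `loss_history` (tibble of step/loss), `val_history` (tibble of
#'   step/mae), `best_step`, `best_val_mae`, and the settings used.
#' @export
train_model <- function(model, dataset, val_dataset = NULL, max_steps = 5000L,
                        batch_size = 32L, lr = 1e-3, eval_every = 50L,
                        val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(length(dataset) > 0)
  if (!any(vapply(dataset, function(e) any(e$mask), logical(1)))) {
    stop("dataset has no unmasked target entries")
  }
  with_seed(seed, {
    if (is.null(val_dataset)) {
      n_val <- max(1L, round(val_fraction * length(dataset)))
      if (length(dataset) > n_val) {
        idx <- sample.int(length(dataset), n_val)
        val_dataset <- dataset[idx]
        dataset <- dataset[-idx]
      } else {
        val_dataset <- dataset
      }
    }
    weights <- model$weights
    state <- adam_init(weights)
    lens <- vapply(dataset, function(e) nrow(e$x), integer(1))
    len_order <- order(lens)
    n_batches <- ceiling(length(dataset) / batch_size)
    buckets <- split(len_order,
                     rep(seq_len(n_batches), each = batch_size,
                         length.out = length(dataset)))
    loss_hist <- numeric(0)
    val_steps <- integer(0); val_maes <- numeric(0)
    best_val <- Inf; best_weights <- weights; best_step <- 0L
    step <- 0L
    while (step < max_steps) {
      for (bi in sample(seq_along(buckets))) {
        if (step >= max_steps) break
        step <- step + 1L
        batch <- make_batch(dataset[buckets[[bi]]])
        model$weights <- weights
        lg <- batch_loss_grad(model, batch, training = TRUE)
        upd <- adam_step(weights, lg$grads, state, lr = lr)
        weights <- upd$weights
        state <- upd$state
        loss_hist[step] <- lg$loss
        if (step %% eval_every == 0L || step == max_steps) {
          model$weights <- weights
          vm <- dataset_val_mae(model, val_dataset)
          val_steps <- c(val_steps, step)
          val_maes <- c(val_maes, vm)
          if (vm < best_val) {
            best_val <- vm; best_weights <- weights; best_step <- step
          }
          if (verbose) {
            message(sprintf("step %d: train MSE %.5f, val MAE %.2f deg",
                            step, lg$loss, vm))
          }
        }
      }
    }
    model$weights <- best_weights
    structure(list(
      model = model,
      final_weights = weights,
      loss_history = tibble::tibble(step = seq_along(loss_hist),
                                    mse = loss_hist),
      val_history = tibble::tibble(step = val_steps, mae = val_maes),
      best_step = best_step, best_val_mae = best_val,
      settings = list(max_steps = max_steps, batch_size = batch_size,
                      lr = lr, seed = seed)
    ), class = "train_state")
  })
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(
    "<train_state> %d steps; best val MAE %.2f deg at step %d\n",
    nrow(x$loss_history), x$best_val_mae, x$best_step))
  invisible(x)
}

#' Predict torsion angles for one chain
#'
#' Runs the network in evaluation mode (dropout inactive) on a scaled
#' feature matrix and decodes the four sigmoid outputs to (phi, psi) with
#' terminal masks set.
#'
#' @param object An `esiden_model`.
#' @param features An L x input_width `feature_matrix` (already scaled
#'   with the model's scaler).
#' @param aa Optional residue letters carried into the output.
#' @param ... Unused.
#' @return A `torsion_series` tibble.
#' @export
predict.esiden_model <- function(object, features, aa = NULL, ...) {
  x <- unclass(as.matrix(features))
  if (ncol(x) != object$config$input_width) {
    stop("feature width ", ncol(x), " does not match model input width ",
         object$config$input_width)
  }
  Y <- predict_example(object, x)
  decode_predictions(Y, aa = aa)
}

# ---- checkpointing ------------------------------------------------------

#' Save a model checkpoint as JSON
#'
#' Stores the configuration, all weights and the channel scaler (if any)
#' in a versioned JSON container; numbers are written at full precision so
#' the checkpoint round-trips exactly.
#'
#' @param model An `esiden_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    version = 1L,
    config = unclass(model$config),
    weights = model$weights,
    scaler = if (!is.null(model$scaler)) unclass(model$scaler)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model checkpoint written by [write_model()]
#'
#' @param path Input path.
#' @return An `esiden_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, p$config[c("input_width", "lstm1_hidden",
                                          "bilstm_hidden", "bilstm2_hidden",
                                          "fc1_units", "fc1_dropout", "seed")])
  weights <- lapply(p$weights, function(layer) {
    list(W = if (is.matrix(layer$W)) layer$W else do.call(rbind, layer$W),
         b = as.numeric(layer$b))
  })
  scaler <- NULL
  if (!is.null(p$scaler)) {
    scaler <- structure(list(min = as.numeric(p$scaler$min),
                             max = as.numeric(p$scaler$max),
                             identity = as.logical(p$scaler$identity)),
                        class = "channel_scaler")
  }
  structure(list(config = cfg, weights = weights, scaler = scaler),
            class = "esiden_model")
}
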