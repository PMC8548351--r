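ns <- asNamespace("esiden")

test_that("target encoding maps angles onto the sigmoid range with masks", {
  ts <- new_torsion_series(c(0, 90, -60), c(-45, 130, 0))
  enc <- encode_targets(ts)
  expect_equal(dim(enc$targets), c(3L, 4L))
  expect_true(all(enc$targets >= 0 & enc$targets <= 1))
  # phi = 90 -> (sin, cos) = (1, 0) -> encoded (1.0, 0.5)
  expect_equal(unname(enc$targets[2, 1:2]), c(1.0, 0.5))
  # phi = 0 -> encoded (0.5, 1.0); row 1 phi is masked but values encode
  expect_equal(unname(enc$targets[1, 1:2]), c(0.5, 1.0))
  expect_false(enc$mask[1, 1])  # N-terminal phi fixed
  expect_false(enc$mask[3, 3])  # C-terminal psi fixed
  expect_true(enc$mask[2, 1])
})

test_that("decoding inverts encoding through the two-argument arctangent", {
  two <- decode_predictions(rbind(c(1.0, 0.5, 0.5, 1.0), c(1.0, 0.5, 0.5, 1.0)))
  expect_equal(two$phi[2], 90)
  # sin = 0, cos = -1 -> the wrap seam, normalized to -180
  out <- decode_predictions(rbind(c(0.5, 0, 0.5, 1), c(0.5, 0, 0.5, 1)))
  expect_equal(out$phi[2], -180)
  set.seed(19)
  theta <- stats::runif(1000, -180, 179.999)
  enc <- cbind((sin(theta * pi / 180) + 1) / 2, (cos(theta * pi / 180) + 1) / 2,
               0.5, 0.6)
  dec <- decode_predictions(enc)
  expect_lt(max(angdiff(dec$phi[-1], theta[-1])), 1e-6)
})

test_that("degenerate near-zero (sin, cos) pairs are masked with a warning", {
  out <- rbind(c(0.5, 0.5, 0.5, 1), c(0.5, 0.5, 0.5, 1))
  expect_warning(dec <- decode_predictions(out, eps = 1e-3), "degenerate")
  expect_false(dec$phi_mask[2])
})

test_that("model outputs have shape L x 4 inside (0, 1)", {
  m <- build_model(tiny_config())
  x <- matrix(stats::rnorm(30 * 232), 30, 232)
  Y <- ns$predict_example(m, x)
  expect_equal(dim(Y), c(30L, 4L))
  expect_true(all(Y > 0 & Y < 1))
  ts <- predict(m, x)
  expect_equal(nrow(ts), 30L)
  expect_false(ts$phi_mask[1])
  expect_false(ts$psi_mask[30])
  expect_true(all(ts$phi >= -180 & ts$phi < 180))
  expect_error(predict(m, x[, 1:100]), "width")
})

test_that("padding never influences per-position outputs", {
  m <- build_model(tiny_config())
  x <- matrix(stats::rnorm(25 * 232), 25, 232)
  ex <- list(x = x, y = matrix(0, 25, 4), mask = matrix(FALSE, 25, 4))
  for (pad in c(40L, 120L)) {
    b <- ns$make_batch(list(ex), pad_to = pad)
    fwd <- ns$net_forward(m, b$X, b$mask, training = FALSE)
    expect_lt(max(abs(fwd$Y[1:25, ] - ns$predict_example(m, x))), 1e-6)
  }
})

test_that("parameter counts match the analytic gate formula", {
  cfg <- tiny_config()
  expect_equal(count_parameters(build_model(cfg)), oracle_param_count(cfg))
  # single LSTM layer: input 2, hidden 1 -> 4 (2 + 1 + 1) = 16
  layer <- ns$with_seed(1, ns$init_lstm(2, 1))
  expect_equal(length(layer$W) + length(layer$b), 16L)
  # FC 256 -> 4 with bias
  fc <- ns$with_seed(1, ns$init_fc(256, 4))
  expect_equal(length(fc$W) + length(fc$b), 1028L)
  # counts are seed-invariant
  cfg2 <- tiny_config(seed = 99)
  expect_equal(count_parameters(build_model(cfg2)),
               count_parameters(build_model(cfg)))
})

test_that("the default configuration lands near 6.6M parameters", {
  cfg <- model_config()
  n <- oracle_param_count(cfg)
  expect_equal(count_parameters(build_model(cfg)), n)
  expect_lt(abs(n - 6.6e6) / 6.6e6, 0.02)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(input_width = 5, lstm1_hidden = 3, bilstm_hidden = 2,
                      bilstm2_hidden = 3, fc1_units = 4, fc1_dropout = 0,
                      seed = 7)
  m <- build_model(cfg)
  set.seed(3)
  ex <- list(
    list(x = matrix(stats::rnorm(4 * 5), 4, 5),
         y = matrix(stats::runif(16), 4, 4),
         mask = matrix(c(FALSE, rep(TRUE, 15)), 4, 4)),
    list(x = matrix(stats::rnorm(6 * 5), 6, 5),
         y = matrix(stats::runif(24), 6, 4),
         mask = matrix(TRUE, 6, 4)))
  batch <- ns$make_batch(ex)
  lg <- ns$batch_loss_grad(m, batch, training = FALSE)
  eps <- 1e-6
  for (layer in names(m$weights)) {
    for (p in names(m$weights[[layer]])) {
      idx <- sample(length(m$weights[[layer]][[p]]),
                    min(4L, length(m$weights[[layer]][[p]])))
      for (i in idx) {
        mp <- m; mp$weights[[layer]][[p]][i] <- mp$weights[[layer]][[p]][i] + eps
        mm <- m; mm$weights[[layer]][[p]][i] <- mm$weights[[layer]][[p]][i] - eps
        num <- (ns$batch_loss_grad(mp, batch, training = FALSE)$loss -
                  ns$batch_loss_grad(mm, batch, training = FALSE)$loss) / (2 * eps)
        ana <- lg$grads[[layer]][[p]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("grad", layer, p))
      }
    }
  }
})

test_that("masked positions contribute exactly zero gradient and loss", {
  m <- build_model(tiny_config())
  set.seed(8)
  x <- matrix(stats::rnorm(10 * 232), 10, 232)
  y <- matrix(stats::runif(40), 10, 4)
  mask <- matrix(TRUE, 10, 4)
  mask[4, ] <- FALSE
  ex <- list(x = x, y = y, mask = mask)
  l1 <- ns$batch_loss_grad(m, ns$make_batch(list(ex)), training = FALSE)
  # perturb the target at the masked position only
  ex2 <- ex; ex2$y[4, ] <- stats::runif(4)
  l2 <- ns$batch_loss_grad(m, ns$make_batch(list(ex2)), training = FALSE)
  expect_identical(l1$loss, l2$loss)
  expect_identical(l1$grads, l2$grads)
  allmask <- ex; allmask$mask[] <- FALSE
  expect_error(ns$batch_loss_grad(m, ns$make_batch(list(allmask))),
               "no unmasked")
})

test_that("training is reproducible and prediction is dropout-free", {
  ds <- tiny_dataset()
  m <- build_model(tiny_config(dropout = 0.5))
  s1 <- train_model(m, ds, val_dataset = ds[1], max_steps = 12,
                    batch_size = 2, eval_every = 6, seed = 3)
  s2 <- train_model(m, ds, val_dataset = ds[1], max_steps = 12,
                    batch_size = 2, eval_every = 6, seed = 3)
  expect_identical(s1$loss_history, s2$loss_history)
  expect_identical(s1$val_history, s2$val_history)
  p1 <- predict(s1$model, ds[[1]]$x)
  p2 <- predict(s1$model, ds[[1]]$x)
  expect_identical(p1, p2)  # dropout inactive at prediction
  expect_identical(p1$phi, predict(s2$model, ds[[1]]$x)$phi)
})

test_that("a few Adam steps reduce the training loss", {
  ds <- tiny_dataset(n = 2, L = 10)
  m <- build_model(tiny_config())
  st <- train_model(m, ds, val_dataset = ds, max_steps = 60, batch_size = 2,
                    eval_every = 30, seed = 5)
  expect_lt(mean(tail(st$loss_history$mse, 5)),
            mean(head(st$loss_history$mse, 5)))
  expect_error(train_model(m, list()), "length")
})

test_that("train_state tidiers expose history and summary", {
  ds <- tiny_dataset(n = 2, L = 8)
  st <- train_model(build_model(tiny_config()), ds, val_dataset = ds,
                    max_steps = 6, batch_size = 2, eval_every = 3, seed = 1)
  td <- generics::tidy(st)
  expect_equal(nrow(td), 6L)
  expect_true(all(c("step", "mse", "mae") %in% names(td)))
  gl <- generics::glance(st)
  expect_equal(gl$steps, 6L)
  expect_s3_class(ggplot2::autoplot(st), "ggplot")
})
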