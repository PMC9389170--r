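# Loss, optimiser, training loop with checkpointing, oversampling and
# fine-tuning.

test_that("binary cross-entropy matches its closed forms", {
  y <- c(0, 1, 1, 0)
  expect_lt(bce_loss(y, y), 1e-6)
  expect_equal(bce_loss(y, rep(0.5, 4)), log(2), tolerance = 1e-12)
  set.seed(13)
  yy <- sample(0:1, 10, replace = TRUE)
  ph <- runif(10, 0.01, 0.99)
  direct <- -mean(yy * log(ph) + (1 - yy) * log(1 - ph))
  expect_equal(bce_loss(yy, ph), direct, tolerance = 1e-12)
  expect_error(bce_loss(c(0, 1), 0.5), "length")
})

test_that("Adam leaves parameters untouched at zero gradient", {
  p <- list(a = matrix(1:4, 2), b = c(0.5, -0.5))
  g <- list(a = matrix(0, 2, 2), b = c(0, 0))
  upd <- adam_update(p, g)
  expect_equal(upd$params$a, p$a)
  expect_equal(upd$params$b, p$b)
  expect_identical(upd$state$t, 1L)
})

test_that("first Adam step has magnitude about alpha", {
  ctl <- train_control()
  upd <- adam_update(1, 1, control = ctl)
  step <- 1 - upd$params
  # bias-corrected first step: alpha * sqrt(1-b2)/(1-b1) * m1/(sqrt(v1)+eps)
  expect_equal(step, ctl$learning_rate, tolerance = 1e-3)
})

test_that("Adam trajectory matches a scalar re-implementation", {
  ctl <- train_control(learning_rate = 0.003)
  set.seed(14)
  gs <- rnorm(100)
  # independent scalar oracle of the printed update
  theta_o <- 2; m <- 0; v <- 0
  for (t in 1:100) {
    m <- ctl$beta1 * m + (1 - ctl$beta1) * gs[t]
    v <- ctl$beta2 * v + (1 - ctl$beta2) * gs[t]^2
    theta_o <- theta_o - ctl$learning_rate * sqrt(1 - ctl$beta2^t) /
      (1 - ctl$beta1^t) * m / (sqrt(v) + ctl$epsilon)
  }
  theta <- 2; st <- NULL
  for (t in 1:100) {
    upd <- adam_update(theta, gs[t], st, ctl)
    theta <- upd$params; st <- upd$state
  }
  expect_equal(theta, theta_o, tolerance = 1e-10)
  expect_identical(st$t, 100L)
})

test_that("training reaches high validation accuracy on separable data", {
  wins <- toy_windows(n = 60, len = 60, shift = 1.5, seed = 1)
  tr <- wins[1:40]; va <- wins[41:60]
  m <- build_model(model_spec(n_blocks = 1, filters = 4, units = 4),
                   c(60, 2), seed = 7)
  ctl <- train_control(epochs = 5, learning_rate = 0.01, batch_size = 8,
                       seed = 7)
  out <- train(m, tr, va, ctl)
  expect_gte(out$best_val_accuracy, 0.95)
  expect_identical(nrow(out$history), 5L)

  # checkpoint self-consistency: returned weights reproduce the recorded
  # best accuracy
  p <- model_forward(out$model, va)
  acc <- mean(as.integer(p[, "sa"] >= 0.5) ==
                vapply(va, `[[`, integer(1), "label"))
  expect_equal(acc, out$best_val_accuracy)
})

test_that("training loss trends down on the separable task", {
  wins <- toy_windows(n = 48, len = 60, shift = 1.5, seed = 2)
  m <- build_model(model_spec(n_blocks = 1, filters = 4, units = 4),
                   c(60, 2), seed = 8)
  ctl <- train_control(epochs = 6, learning_rate = 0.01, batch_size = 8,
                       seed = 8)
  out <- train(m, wins[1:36], wins[37:48], ctl)
  drops <- diff(out$history$train_loss) < 0
  expect_gte(sum(drops), 4)
})

test_that("fixed seeds fix the whole training trajectory", {
  wins <- toy_windows(n = 24, len = 40, seed = 3)
  ctl <- train_control(epochs = 3, learning_rate = 0.01, batch_size = 8,
                       seed = 5)
  run <- function() {
    m <- build_model(model_spec(n_blocks = 1, filters = 3, units = 3),
                     c(40, 2), seed = 5)
    train(m, wins[1:16], wins[17:24], ctl)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(apneanet:::net_params(a$model$layers),
                   apneanet:::net_params(b$model$layers))
})

test_that("training rejects empty sets", {
  wins <- toy_windows(n = 8, len = 40)
  m <- build_model(model_spec(n_blocks = 1, filters = 3, units = 3),
                   c(40, 2), seed = 1)
  expect_error(train(m, list(), wins), "empty")
})

test_that("minority oversampling balances classes exactly", {
  wins <- toy_windows(n = 12, len = 20)
  y <- vapply(wins, `[[`, integer(1), "label")
  unbal <- c(wins[y == 0], wins[y == 1][1:2])   # 6 normal, 2 apneic
  bal <- oversample_minority(unbal, seed = 4)
  yb <- vapply(bal, `[[`, integer(1), "label")
  expect_length(bal, 12)
  expect_identical(sum(yb == 1L), 6L)

  even <- oversample_minority(wins, seed = 4)
  key <- function(w) paste(w$center_minute, w$label)
  expect_setequal(vapply(even, key, character(1)),
                  vapply(wins, key, character(1)))
  expect_length(even, length(wins))

  set.seed(30)
  for (n1 in c(1, 3, 5)) {
    ub <- c(wins[y == 0], wins[y == 1][seq_len(n1)])
    yb2 <- vapply(oversample_minority(ub, seed = n1), `[[`, integer(1),
                  "label")
    expect_equal(sum(yb2 == 1) / sum(yb2 == 0), 1.0)
  }
  expect_error(oversample_minority(wins[y == 0], seed = 1),
               "both classes")
})

test_that("fine-tuning with zero epochs returns the weights unchanged", {
  wins <- toy_windows(n = 16, len = 40, seed = 6)
  m <- build_model(model_spec(n_blocks = 1, filters = 3, units = 3),
                   c(40, 2), seed = 9)
  out <- finetune(m, wins[1:10], wins[11:16],
                  train_control(epochs = 0, seed = 9))
  expect_identical(apneanet:::net_params(out$model$layers),
                   apneanet:::net_params(m$layers))
  expect_identical(nrow(out$history), 0L)
})

test_that("fine-tuning adapts a pretrained model to shifted data", {
  base <- toy_windows(n = 40, len = 40, shift = 1.5, seed = 7)
  # domain shift: same class structure, channels scaled and offset
  shifted <- lapply(toy_windows(n = 40, len = 40, shift = 1.5, seed = 17),
                    function(w) {
                      w$rr_channel <- 0.5 * w$rr_channel + 2
                      w$amp_channel <- 0.5 * w$amp_channel - 2
                      w
                    })
  m <- build_model(model_spec(n_blocks = 1, filters = 4, units = 4),
                   c(40, 2), seed = 10)
  ctl <- train_control(epochs = 4, learning_rate = 0.01, batch_size = 8,
                       seed = 10)
  pre <- train(m, base[1:30], base[31:40], ctl)

  eval_acc <- function(model, wins) {
    p <- model_forward(model, wins)
    mean(as.integer(p[, "sa"] >= 0.5) ==
           vapply(wins, `[[`, integer(1), "label"))
  }
  acc_before <- eval_acc(pre$model, shifted[31:40])
  ft <- finetune(pre$model, shifted[1:30], shifted[31:40], ctl)
  expect_gte(eval_acc(ft$model, shifted[31:40]), acc_before)

  expect_error(finetune(pre$model, toy_windows(n = 6, len = 20),
                        toy_windows(n = 6, len = 20), ctl),
               "incompatible")
})

test_that("window splitting respects proportions and granularity", {
  wins <- toy_windows(n = 100, len = 20, seed = 31,
                      record_ids = rep(sprintf("r%02d", 1:10), each = 10))
  sp <- split_windows(wins, c(0.8, 0.1, 0.1), by = "segment", seed = 2)
  expect_identical(length(sp$train) + length(sp$val) + length(sp$test),
                   100L)
  expect_identical(length(sp$train), 80L)
  # stratified: class balance preserved in the training part
  ytr <- vapply(sp$train, `[[`, integer(1), "label")
  expect_identical(sum(ytr == 1L), 40L)

  sr <- split_windows(wins, c(0.8, 0.1, 0.1), by = "recording", seed = 2)
  # recording-level: no record id appears in two parts
  id_of <- function(p) unique(vapply(p, `[[`, character(1), "record_id"))
  expect_length(intersect(id_of(sr$train), id_of(sr$val)), 0)
  expect_length(intersect(id_of(sr$train), id_of(sr$test)), 0)
  expect_length(intersect(id_of(sr$val), id_of(sr$test)), 0)
  expect_error(split_windows(wins, c(0.5, 0.5, 0.5)), "summing to 1")
})
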