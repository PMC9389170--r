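# Architecture assembly, shape algebra, forward-pass validity, and
# equivalence of the batched engine with the reference operations.

test_that("default 3-block build matches the published layer table", {
  m <- build_model(model_spec(), c(900, 2), seed = 1)
  types <- vapply(m$layers, `[[`, character(1), "type")
  expect_length(types, 21)
  expect_identical(types, c(
    "conv",
    "conv", "maxpool", "dropout", "bigru", "dropout",
    "conv", "maxpool", "dropout", "bigru", "dropout",
    "conv", "maxpool", "dropout", "bigru",
    "attention", "flatten", "dense", "dropout", "dense", "dense"))
  for (ly in m$layers) {
    if (ly$type == "conv") {
      expect_identical(dim(ly$W)[c(1, 3)], c(3L, 128L))
    } else if (ly$type == "bigru") {
      expect_identical(nrow(ly$fwd$Wr), 128L)
    }
  }
  dense_sizes <- vapply(Filter(function(l) l$type == "dense", m$layers),
                        function(l) nrow(l$W), integer(1))
  expect_identical(dense_sizes, c(64L, 64L, 2L))
})

test_that("sequence lengths follow the 900 -> 300 -> 100 -> 33 algebra", {
  m <- build_model(model_spec(), c(900, 2), seed = 1)
  expect_identical(m$seq_lengths, c(300L, 100L, 33L))
})

test_that("parameter count of the default model is stable", {
  m1 <- build_model(model_spec(), c(900, 2), seed = 1)
  m2 <- build_model(model_spec(), c(900, 2), seed = 2)
  expect_identical(m1$param_count, 1113858)
  expect_identical(m2$param_count, m1$param_count)
})

test_that("single-block build is stem conv plus one block and the head", {
  m <- build_model(model_spec(n_blocks = 1, filters = 8, units = 8),
                   c(900, 2), seed = 3)
  expect_identical(vapply(m$layers, `[[`, character(1), "type"),
                   c("conv", "conv", "maxpool", "dropout", "bigru",
                     "attention", "flatten", "dense", "dropout",
                     "dense", "dense"))
})

test_that("builder rejects inputs that pooling would collapse", {
  expect_error(build_model(model_spec(n_blocks = 3, filters = 4,
                                      units = 4), c(20, 2), seed = 1),
               "block 3")
})

test_that("forward pass emits valid probability pairs", {
  m <- build_model(model_spec(n_blocks = 1, filters = 4, units = 4),
                   c(120, 2), seed = 4)
  set.seed(9)
  x <- array(rnorm(8 * 120 * 2), c(8, 120, 2))
  p <- model_forward(m, x)
  expect_identical(dim(p), c(8L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_identical(p, model_forward(m, x))   # inference determinism
  expect_error(model_forward(m, array(0, c(2, 60, 2))), "shape")
})

test_that("batched engine agrees with the reference operation chain", {
  spec <- model_spec(n_blocks = 1, filters = 4, kernel = 3, units = 2,
                     dense_units = c(4, 4))
  m <- build_model(spec, c(27, 2), seed = 5)
  set.seed(10)
  x <- array(rnorm(27 * 2), c(1, 27, 2))

  # reference composition, layer by layer (biases are zero at init)
  xm <- matrix(x[1, , ], 27, 2)
  h <- pmax(conv1d(xm, m$layers[[1]]$W, padding = "same"), 0)
  h <- pmax(conv1d(h, m$layers[[2]]$W, padding = "same"), 0)
  h <- max_pool(h, k = 3)
  as_gp <- function(d) gru_params(d$Wr, d$Ur, d$Wz, d$Uz, d$Wx, d$Ux)
  gr <- bigru_run(as_gp(m$layers[[5]]$fwd), as_gp(m$layers[[5]]$bwd), h)
  at <- dot_attention(gr$F, gr$B)
  flat <- as.numeric(at)                      # column-major = engine order
  d1 <- pmax(drop(m$layers[[8]]$W %*% flat), 0)
  d2 <- pmax(drop(m$layers[[10]]$W %*% d1), 0)
  logits <- drop(m$layers[[11]]$W %*% d2)
  ref <- exp(logits - max(logits))
  ref <- ref / sum(ref)

  eng <- model_forward(m, x)
  expect_lt(max(abs(drop(eng) - ref)), 1e-5)
})

test_that("analytic gradients match finite differences", {
  spec <- model_spec(n_blocks = 1, filters = 3, kernel = 3, units = 2,
                     dense_units = c(4, 4), dropout_rate = 0)
  m <- build_model(spec, c(27, 2), seed = 6)
  # nudge biases off zero so no ReLU sits exactly on its kink
  set.seed(11)
  for (i in seq_along(m$layers)) {
    if (m$layers[[i]]$type %in% c("conv", "dense"))
      m$layers[[i]]$b <- rnorm(length(m$layers[[i]]$b), 0, 0.05)
  }
  x <- array(rnorm(3 * 27 * 2), c(3, 27, 2))
  y <- c(0L, 1L, 1L)
  loss_fn <- function(layers)
    bce_loss(y, apneanet:::net_forward(layers, x, FALSE)$out[, 2])

  fw <- apneanet:::net_forward(m$layers, x, TRUE)
  dZ <- (fw$out - cbind(1 - y, y)) / length(y)
  grads <- apneanet:::net_backward(m$layers, fw$caches, dZ)
  params <- apneanet:::net_params(m$layers)
  pvec <- unlist(params)
  gvec <- unlist(grads)
  expect_identical(length(pvec), length(gvec))

  restore <- function(vec) {
    out <- utils::relist(vec, skeleton = params)
    copy_dims <- function(a, b) {
      if (is.list(a)) return(mapply(copy_dims, a, b, SIMPLIFY = FALSE))
      if (!is.null(dim(b))) dim(a) <- dim(b)
      a
    }
    copy_dims(out, params)
  }

  set.seed(12)
  idx <- sample(length(pvec), 40)
  eps <- 1e-6
  for (i in idx) {
    vp <- pvec; vp[i] <- vp[i] + eps
    vm <- pvec; vm[i] <- vm[i] - eps
    num <- (loss_fn(apneanet:::net_set_params(m$layers, restore(vp))) -
              loss_fn(apneanet:::net_set_params(m$layers, restore(vm)))) /
      (2 * eps)
    expect_lt(abs(num - gvec[i]) / max(1e-6, abs(num) + abs(gvec[i])),
              1e-3)
  }
})
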