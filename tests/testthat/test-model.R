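test_that("GEMM convolution matches a naive direct convolution", {
  withr::local_seed(31)
  for (rep in 1:6) {
    h <- sample(3:9, 1); w <- sample(3:9, 1)
    cin <- sample(1:4, 1); cout <- sample(1:4, 1)
    k <- sample(1:3, 1); stride <- sample(1:2, 1)
    x <- array(rnorm(h * w * cin), c(h, w, cin))
    ww <- array(rnorm(k * k * cin * cout), c(k, k, cin, cout))
    xb <- array(x, c(h, w, 1, cin))
    xb[, , 1, ] <- x
    got <- skelgait:::conv_fwd(xb, ww, stride)$out
    want <- naive_conv(x, ww, stride)
    expect_equal(got[, , 1, ], want, tolerance = 1e-12)
  }
})

test_that("forward pass yields softmax probabilities for any cycle length", {
  cfg <- model_config(classes = 30)
  m <- build_model(cfg, seed = 1)
  x30 <- array(rnorm(30 * 20 * 3), c(30, 20, 3))
  p30 <- predict(m, x30)
  expect_equal(dim(p30), c(1L, 30L))
  expect_equal(sum(p30), 1, tolerance = 1e-6)
  expect_true(all(p30 >= 0))
  # a different Nf is accepted and gives the same output length
  x45 <- array(rnorm(45 * 20 * 3), c(45, 20, 3))
  p45 <- predict(m, x45)
  expect_equal(dim(p45), dim(p30))
  # mixed lengths in one call keep input order
  both <- predict(m, list(x45, x30, x45))
  expect_equal(both[2, ], p30[1, ], tolerance = 1e-12)
  expect_equal(both[1, ], both[3, ], tolerance = 1e-12)
})

test_that("identity residual block with zeroed main path passes x through", {
  pars <- residual_block_params(8, 8, kernel = 3, proj = FALSE)
  pars$conv1.w[] <- 0
  pars$conv2.w[] <- 0
  x <- array(abs(rnorm(10 * 6 * 8)), c(10, 6, 8))  # non-negative input
  out <- residual_block(x, pars, stride = 1, training = FALSE)
  expect_equal(out, x, tolerance = 1e-12)
  expect_equal(dim(out), dim(x))  # shape preserved
  # final ReLU: output is non-negative even for signed input
  x2 <- array(rnorm(10 * 6 * 8), c(10, 6, 8))
  pars2 <- residual_block_params(8, 8, proj = FALSE)
  expect_true(all(residual_block(x2, pars2, 1) >= 0))
})

test_that("stride-2 block halves both axes and reduces to its shortcut when zeroed", {
  pars <- residual_block_params(4, 6, kernel = 3, proj = TRUE)
  x <- array(rnorm(30 * 20 * 4), c(30, 20, 4))
  out <- residual_block(x, pars, stride = 2)
  expect_equal(dim(out), c(15L, 10L, 6L))
  # odd input: ceiling division under same-padding
  x31 <- array(rnorm(31 * 20 * 4), c(31, 20, 4))
  expect_equal(dim(residual_block(x31, pars, stride = 2)), c(16L, 10L, 6L))

  # zero the main path: output must equal ReLU(BN(1x1 conv(x))),
  # computed here independently with the naive convolution oracle
  pars$conv1.w[] <- 0
  pars$conv2.w[] <- 0
  got <- residual_block(x, pars, stride = 2, training = FALSE)
  sc <- naive_conv(x, pars$proj.w, stride = 2)
  want <- array(0, dim(sc))
  for (c in 1:6) {
    want[, , c] <- pmax((sc[, , c] - pars$bnp.mean[c]) /
                          sqrt(pars$bnp.var[c] + 1e-3) * pars$bnp.gamma[c] +
                          pars$bnp.beta[c], 0)
  }
  expect_equal(got, want, tolerance = 1e-10)

  # identity block rejects mismatched channels
  bad <- residual_block_params(6, 6, proj = FALSE)
  expect_error(residual_block(x, bad, stride = 1), "channels")
})

test_that("pooling oracles: gap mean, gmp max, spp adaptive partition", {
  m <- array(c(1, 3, 2, 4), c(2, 2, 1))  # [[1,2],[3,4]], one channel
  expect_equal(pool_features(m, "gap"), 2.5)
  expect_equal(pool_features(m, "gmp"), 4)
  expect_equal(pool_features(m, "spp", levels = c(1, 2)), c(2.5, 1, 2, 3, 4))
  # gap of a constant channel is that constant
  k <- array(7, c(5, 3, 2))
  expect_equal(pool_features(k, "gap"), c(7, 7))
  # spp on an uneven size: explicit-partition oracle at level 2
  # (cell i covers rows floor((i-1)*H/l)+1 .. floor(i*H/l): 1:2 and 3:5)
  x <- array(rnorm(5 * 4 * 1), c(5, 4, 1))
  got <- pool_features(x, "spp", levels = 2)
  want <- c(mean(x[1:2, 1:2, 1]), mean(x[1:2, 3:4, 1]),
            mean(x[3:5, 1:2, 1]), mean(x[3:5, 3:4, 1]))
  expect_equal(got, want)
  # spatial size below the largest level errors
  expect_error(pool_features(array(1, c(1, 4, 1)), "spp", levels = c(1, 2)),
               "smaller than")
})

test_that("closed-form parameter count equals the built model's count", {
  withr::local_seed(99)
  for (rep in 1:20) {
    filters <- sample(2:17, 5, replace = TRUE)
    strides <- sample(c(1L, 2L), 5, replace = TRUE)
    # keep identity-skip stages channel-consistent
    cin <- f0 <- sample(2:12, 1)
    blocks <- vector("list", 5)
    for (i in 1:5) {
      f <- if (strides[i] == 1L && runif(1) < 0.5) cin else filters[i]
      blocks[[i]] <- block_spec(sample(1:3, 1), f, strides[i],
                                repeats = sample(1:2, 1))
      cin <- f
    }
    cfg <- model_config(classes = sample(2:20, 1),
                        stem = list(kernel = sample(1:3, 1), filters = f0),
                        blocks = blocks,
                        pooling = sample(c("gap", "gmp", "spp"), 1),
                        spp_levels = c(1, 2))
    m <- build_model(cfg, seed = rep)
    expect_equal(count_params(m), param_count(cfg))
    expect_equal(count_params(m)$total,
                 count_params(m)$trainable + count_params(m)$non_trainable)
  }
})

test_that("reference architecture has the derived parameter counts", {
  pc <- param_count(model_config(classes = 30))
  expect_equal(pc$trainable, 171886L)
  expect_equal(pc$non_trainable, 1056L)
  # layer-style closed forms for single layers
  expect_equal(64 * 30 + 30, 1950)          # dense 64 -> 30 with bias
  cfg <- model_config(classes = 30)
  m <- build_model(cfg, seed = 1)
  expect_equal(length(m$params[["stem.conv.w"]]), 3 * 3 * 3 * 16)  # 432
  expect_equal(length(m$params[["head.w"]]) + length(m$params[["head.b"]]), 1950)
  # head-size arithmetic: growing the head from 30 to 164 classes adds
  # 134 * (D + 1) trainable parameters with the 64-dim embedding
  pc164 <- param_count(model_config(classes = 164))
  expect_equal(pc164$trainable - pc$trainable, 134 * 65)
  expect_equal(pc164$non_trainable, pc$non_trainable)
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- model_config(classes = 3,
                      stem = list(kernel = 2, filters = 2),
                      blocks = list(block_spec(2, 2, 1), block_spec(2, 3, 2),
                                    block_spec(2, 3, 1), block_spec(2, 4, 2),
                                    block_spec(2, 4, 1)),
                      pooling = "gap")
  m <- build_model(cfg, seed = 7)
  withr::local_seed(13)
  x <- array(rnorm(9 * 5 * 2 * 3), c(9, 5, 2, 3))
  y <- one_hot(c(0L, 2L), 3)
  fw <- skelgait:::net_forward(m, x, training = TRUE)
  ls <- skelgait:::xent_loss(fw$probs, y)
  gr <- skelgait:::net_backward(m, fw$caches, ls$dlogits)
  lossfun <- function(mm) {
    f <- skelgait:::net_forward(mm, x, training = TRUE)
    skelgait:::xent_loss(f$probs, y)$loss
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (ii in sample.int(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      m2 <- m; m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
      m3 <- m; m3$params[[nm]][ii] <- m3$params[[nm]][ii] - eps
      fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(gr[[nm]][ii], fd, tolerance = 1e-4,
                   label = paste0("d loss / d ", nm, "[", ii, "]"))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(classes = 1), ">= 2")
  expect_error(model_config(classes = 3, blocks = list(block_spec(3, 8, 1))),
               "five")
  expect_error(block_spec(3, 8, stride = 3))
})
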