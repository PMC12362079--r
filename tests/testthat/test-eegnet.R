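test_that("network gradients match finite differences", {
  set.seed(42)
  B <- 4; C <- 3; T0 <- 32
  x <- array(rnorm(B * C * T0), c(B, C, T0))
  y <- c(0, 1, 1, 0)
  net <- eegmvpa:::eegnet_init(C, T0, sfreq = 16)
  net$drop_p <- 1e-9                      # dropout ~ off, still exercised
  net$params$Wo <- matrix(rnorm(length(net$params$Wo), sd = 0.1), ncol = 1)
  set.seed(1)
  lg <- eegmvpa:::eegnet_loss_grad(net, x, y)
  eps <- 1e-6
  for (nm in names(lg$grads)) {
    g <- lg$grads[[nm]]
    idx <- sample(length(net$params[[nm]]), min(4, length(net$params[[nm]])))
    for (i in idx) {
      np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
      set.seed(1); lp <- eegmvpa:::eegnet_loss_grad(np, x, y)$loss
      nn <- net; nn$params[[nm]][i] <- nn$params[[nm]][i] - eps
      set.seed(1); lm <- eegmvpa:::eegnet_loss_grad(nn, x, y)$loss
      fd <- (lp - lm) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-3,
                   label = paste0("analytic grad ", nm, "[", i, "]"))
    }
  }
})

test_that("network overfits a tiny separable problem", {
  set.seed(3)
  n <- 24; C <- 4; T0 <- 64
  y <- rep(c(0, 1), each = n / 2)
  x <- array(rnorm(n * C * T0, sd = 0.5), c(n, C, T0))
  x[, 2, 20:50] <- x[, 2, 20:50] + outer(2 * (y - 0.5) * 3, rep(1, 31))
  cfg <- trialwise_config(decoder = "compact_cnn", cycles = 30, seed = 1)
  net <- eegmvpa:::with_seed(5, eegmvpa:::eegnet_train(x, y, sfreq = 32, cfg))
  pred <- eegmvpa:::eegnet_predict(net, x)
  expect_gte(mean(pred == y), 0.9)
})

test_that("network training is deterministic given the seed", {
  set.seed(2)
  x <- array(rnorm(20 * 3 * 32), c(20, 3, 32))
  y <- rep(c(0, 1), 10)
  cfg <- trialwise_config(decoder = "compact_cnn", cycles = 2, seed = 7)
  n1 <- eegmvpa:::with_seed(9, eegmvpa:::eegnet_train(x, y, sfreq = 16, cfg))
  n2 <- eegmvpa:::with_seed(9, eegmvpa:::eegnet_train(x, y, sfreq = 16, cfg))
  expect_identical(n1$params, n2$params)
})

test_that("max-norm constraints hold after training", {
  set.seed(4)
  x <- array(rnorm(20 * 3 * 32), c(20, 3, 32))
  y <- rep(c(0, 1), 10)
  cfg <- trialwise_config(decoder = "compact_cnn", cycles = 3, seed = 2)
  net <- eegmvpa:::with_seed(1, eegmvpa:::eegnet_train(x, y, sfreq = 16, cfg))
  expect_true(all(sqrt(rowSums(net$params$Wd^2)) <= 1 + 1e-9))
  expect_lte(sqrt(sum(net$params$Wo^2)), 0.25 + 1e-9)
})
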