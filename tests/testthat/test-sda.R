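toy_grid <- function(n_ep = 5, n_ch = 22) {
  structure(list(scores = array(1 / 6, c(n_ep, n_ch, 6)), epoch_duration = 1),
            class = "epoch_posterior_grid")
}

test_that("epoch supervectors are 132-dim and channel-major", {
  v <- build_epoch_vectors(toy_grid(100))
  expect_identical(dim(v), c(100L, 132L))
  expect_true(all(v == 1 / 6))
  # channel-major layout: block ch holds that channel's six class scores
  g <- toy_grid(2)
  g$scores[1, 3, ] <- c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1)
  v2 <- build_epoch_vectors(g)
  expect_equal(v2[1, 13:18], c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
  bad <- toy_grid(2, 5)
  bad$scores <- bad$scores[, , 1:4]
  expect_error(build_epoch_vectors(bad), "classes")
})

test_that("window stacking replicates boundaries and hits 5412 dims at w=41", {
  v <- matrix(stats::rnorm(10 * 132), 10)
  expect_length(stack_window(v, 5, 41), 5412L)
  expect_equal(stack_window(v, 4, 1), v[4, ])
  w <- stack_window(v, 1, 3)
  expect_equal(w[1:132], w[133:264])          # left edge replicated
  expect_error(stack_window(v, 2, 4), "odd")
})

test_that("PCA projects orthonormally, scales to [0,1], and is near-optimal", {
  set.seed(31)
  # data in an exact 2-d subspace reconstructs exactly
  basis <- qr.Q(qr(matrix(stats::rnorm(10 * 2), 10)))
  x <- matrix(stats::rnorm(50 * 2), 50) %*% t(basis)
  p <- fit_pca(x, 2)
  expect_equal(t(p$rotation) %*% p$rotation, diag(2), tolerance = 1e-9)
  centered <- sweep(x, 2, p$mean)
  recon <- centered %*% p$rotation %*% t(p$rotation)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # output dimension and [0,1] range
  x2 <- matrix(stats::runif(200 * 132), 200)
  p13 <- fit_pca(x2, 13)
  red <- apply_pca(p13, x2)
  expect_identical(dim(red), c(200L, 13L))
  expect_true(all(red >= 0 & red <= 1))
  expect_error(fit_pca(x2, 200), "exceeds")
  # oracle: PCA reconstruction beats random rank-13 projections
  centered2 <- sweep(x2, 2, colMeans(x2))
  pca_err <- sum((centered2 - centered2 %*% p13$rotation %*% t(p13$rotation))^2)
  rand_errs <- replicate(100, {
    q <- qr.Q(qr(matrix(stats::rnorm(132 * 13), 132)))
    sum((centered2 - centered2 %*% q %*% t(q))^2)
  })
  expect_true(all(pca_err <= rand_errs))
})

test_that("triplet averaging is a clipped sliding mean", {
  x <- matrix(5, 4, 3)
  expect_equal(average_triplets(x), x)
  imp <- matrix(0, 3, 2); imp[2, ] <- 1
  expect_equal(average_triplets(imp)[2, ], c(1 / 3, 1 / 3))
  expect_identical(nrow(average_triplets(matrix(stats::rnorm(26), 13))), 13L)
})

test_that("rare-class augmentation multiplies counts without touching originals", {
  set.seed(32)
  x <- matrix(stats::runif(100 * 5), 100)
  labs <- rep(c(1L, 2L), each = 50)
  out <- augment_rare_class(x, labs, 1L, 5L, seed = 7)
  expect_identical(sum(out$labels == 1L), 250L)
  expect_identical(sum(out$labels == 2L), 50L)
  expect_equal(out$x[1:100, ], x)
  expect_identical(augment_rare_class(x, labs, 1L, 1L)$x, x)
  # degenerate: two identical examples synthesize (near-)copies
  xx <- rbind(matrix(0.3, 2, 4), matrix(0.9, 3, 4))
  aug <- augment_rare_class(xx, c(1, 1, 2, 2, 2), 1, 3, seed = 8)
  synth <- aug$x[6:9, , drop = FALSE]
  expect_lt(max(abs(synth - 0.3)), 1e-8)      # zero class spread, zero jitter
  expect_error(augment_rare_class(xx, c(1, 2, 2, 2, 2), 1, 2), "fewer than 2")
})

test_that("masking corruption hits its level and its edge cases", {
  x <- matrix(stats::runif(1000), 50)
  set.seed(33)
  expect_identical(corrupt(x, 0), x)
  expect_true(all(corrupt(x, 1) == 0))
  big <- rep(1, 1e5)
  masked <- corrupt(big, 0.3)
  expect_lt(abs(mean(masked == 0) - 0.3), 0.01)
})

test_that("reconstruction cross-entropy matches closed forms and gradients", {
  x <- c(1, 0, 1, 1, 0)
  expect_lt(dae_loss(x, x), 1e-5)
  expect_equal(dae_loss(0.5, 0.5), log(2), tolerance = 1e-12)
  # analytic tied-weight gradients vs central finite differences
  set.seed(34)
  layer <- eegevents:::init_layer(5L, 3L)
  xb <- matrix(stats::runif(10), 5, 2)        # columns = samples
  xc <- xb; xc[2, ] <- 0                      # fixed corruption pattern
  g <- eegevents:::dae_gradients(layer, xb, xc)
  loss_at <- function(W) {
    l2 <- layer; l2$W <- W
    y <- eegevents:::sigmoid(l2$W %*% xc + l2$b)
    z <- eegevents:::sigmoid(t(l2$W) %*% y + l2$b_prime)
    dae_loss(t(xb), t(z))
  }
  h <- 1e-6
  num <- matrix(0, 3, 5)
  for (i in 1:3) for (j in 1:5) {
    Wp <- layer$W; Wp[i, j] <- Wp[i, j] + h
    Wm <- layer$W; Wm[i, j] <- Wm[i, j] - h
    num[i, j] <- (loss_at(Wp) - loss_at(Wm)) / (2 * h)
  }
  expect_lt(max(abs(g$dW - num)) / max(abs(num)), 1e-5)
})

test_that("pre-training reduces held-out reconstruction loss, deterministically", {
  set.seed(35)
  x <- matrix(stats::runif(300 * 12), 300)
  net <- sda_network("spsw", 12L, 2L, c(8L, 8L), 3L, seed = 3)
  hp <- sda_hyperparams(0.05, 8L, 30L, seed = 4)
  tr <- pretrain_sda(net, x, hp)
  hist <- attr(tr, "pretrain_history")
  expect_lt(hist[[1]][8], hist[[1]][1])
  # zero learning rate leaves weights untouched
  frozen <- pretrain_sda(net, x, sda_hyperparams(0, 3L, 30L, seed = 4))
  expect_identical(frozen$layers[[1]]$W, net$layers[[1]]$W)
  # fixed seed: bit-identical weights across runs
  tr2 <- pretrain_sda(net, x, hp)
  expect_identical(tr$layers[[2]]$W, tr2$layers[[2]]$W)
})

test_that("fine-tuning separates Gaussian clouds and outputs softmax posteriors", {
  set.seed(36)
  n <- 150
  x <- rbind(matrix(stats::runif(n * 8, 0, 0.42), n),
             matrix(stats::runif(n * 8, 0.58, 1), n))
  y <- rep(1:2, each = n)
  hold <- c(1:30, (n + 1):(n + 30))
  net <- sda_network("spsw", 8L, 2L, c(12L, 12L), 3L, seed = 5)
  net <- pretrain_sda(net, x[-hold, ], sda_hyperparams(0.05, 5L, 30L, seed = 6))
  net <- finetune_sda(net, x[-hold, ], y[-hold],
                      sda_hyperparams(0.3, 60L, 30L, seed = 7))
  p <- predict_sda(net, x[hold, ])
  expect_equal(rowSums(p), rep(1, 60), tolerance = 1e-6)
  expect_gte(mean(max.col(p) == y[hold]), 0.95)
  expect_error(finetune_sda(net, x, rep(3L, nrow(x)), sda_hyperparams()),
               "labels")
})

test_that("the enhancer reallocates detector mass and stays normalized", {
  p6 <- c(0.05, 0.1, 0.05, 0.1, 0.1, 0.6)
  # detectors agree (no trigger): output unchanged
  expect_equal(enhancer_combine(p6, c(0.2, 0.8), c(0.3, 0.7)), p6)
  # uniform 6-way + confident epileptiform detector: block mass 0.9, 0.3 each
  out <- enhancer_combine(rep(1 / 6, 6), c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(out[class_labels() %in% c("SPSW", "PLED", "GPED")],
               rep(0.3, 3), tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # eye-movement override pushes mass onto EYEM
  out2 <- enhancer_combine(p6, c(0.1, 0.9), c(0.8, 0.2))
  expect_equal(out2[class_labels() == "EYEM"], 0.8, tolerance = 1e-12)
  # random inputs remain normalized
  set.seed(37)
  for (i in 1:20) {
    p <- stats::runif(6); p <- p / sum(p)
    o <- enhancer_combine(p, stats::runif(2), stats::runif(2))
    expect_equal(sum(o), 1, tolerance = 1e-9)
  }
})

test_that("default architectures satisfy the reference dimensions", {
  net6 <- sda_network("sixway", 820L, 6L, c(800L, 500L, 300L), 41L)
  expect_identical(net6$n_in, 820L)
  expect_identical(dim(net6$layers[[1]]$W), c(800L, 820L))
  netb <- sda_network("spsw", 39L, 2L, c(100L, 100L, 100L), 3L)
  expect_identical(netb$n_in, 39L)
  expect_identical(netb$n_out, 2L)
})
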