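test_that("the mixture density matches closed forms", {
  # standard normal at its mode
  expect_equal(gaussian_mixture_density(0, 1, matrix(0, 1, 1), matrix(1, 1, 1)),
               1 / sqrt(2 * pi), tolerance = 1e-12)
  # two identical equal-weight components collapse to one
  expect_equal(
    gaussian_mixture_density(0.7, c(0.5, 0.5), matrix(0, 2, 1), matrix(1, 2, 1)),
    gaussian_mixture_density(0.7, 1, matrix(0, 1, 1), matrix(1, 1, 1)),
    tolerance = 1e-12)
  # 26-dim identity covariance at the mean
  expect_equal(
    gaussian_mixture_density(rep(0, 26), 1, matrix(0, 1, 26), matrix(1, 1, 26)),
    (2 * pi)^(-13), tolerance = 1e-12)
})

test_that("forward-backward matches single-path and brute-force oracles", {
  set.seed(21)
  m1 <- random_ltr_model(1L)
  obs <- matrix(stats::rnorm(10), 5, 2)
  fb <- forward_backward(m1, obs)
  lb <- eegevents:::log_emissions(m1, obs)
  expect_equal(fb$loglik, sum(lb), tolerance = 1e-10)
  # scaled alpha/beta consistency: sum_i alpha*beta == 1 at every t
  m <- random_ltr_model(3L)
  obs3 <- matrix(stats::rnorm(12), 6, 2)
  tr <- forward_backward(m, obs3)
  expect_equal(rowSums(tr$alpha * tr$beta), rep(1, 6), tolerance = 1e-9)
  # brute force over random small instances
  for (i in 1:60) {
    N <- sample(1:3, 1); Tn <- sample(1:6, 1)
    mm <- random_ltr_model(N)
    oo <- matrix(stats::rnorm(Tn * 2), Tn, 2)
    expect_equal(forward_backward(mm, oo)$loglik, brute_loglik(mm, oo)$loglik,
                 tolerance = 1e-9)
  }
})

test_that("transition posteriors are normalized and respect the topology", {
  set.seed(22)
  m1 <- random_ltr_model(1L)
  obs <- matrix(stats::rnorm(8), 4, 2)
  xi1 <- transition_posteriors(forward_backward(m1, obs), m1, obs)
  expect_true(all(xi1 == 1))
  m <- random_ltr_model(3L)
  obs <- matrix(stats::rnorm(12), 6, 2)
  xi <- transition_posteriors(forward_backward(m, obs), m, obs)
  expect_equal(apply(xi, 1L, sum), rep(1, 5), tolerance = 1e-9)
  # forbidden (zero-probability) transitions have zero posterior
  expect_true(all(xi[, 2, 1] == 0) && all(xi[, 3, 1] == 0) &&
                all(xi[, 3, 2] == 0) && all(xi[, 1, 3] == 0))
})

test_that("Baum-Welch is monotone and preserves the left-to-right mask", {
  set.seed(23)
  obs_list <- lapply(1:20, function(i) matrix(stats::rnorm(20), 10, 2))
  m <- eegevents:::flat_start_model("BCKG", do.call(rbind, obs_list),
                                    hmm_config(n_states = 3))
  lls <- numeric(8)
  for (k in 1:8) {
    up <- baum_welch_update(m, obs_list)
    lls[k] <- up$loglik
    m <- up$model
    expect_true(all(m$trans[lower.tri(m$trans)] == 0))
    expect_true(all(m$trans[cbind(1, 3)] == 0))
    expect_equal(rowSums(m$trans), rep(1, 3), tolerance = 1e-9)
  }
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("parameter recovery error shrinks with more data", {
  set.seed(24)
  truth <- hmm_model("BCKG",
                     matrix(c(0.8, 0.2, 0, 1), 2, byrow = TRUE),
                     matrix(1, 2, 1),
                     array(c(0, 3), c(2, 1, 1)), array(1, c(2, 1, 1)),
                     1e-4)
  err_of <- function(n_seq) {
    obs <- simulate_hmm(truth, n_seq, 20L)
    fit <- train_hmm("BCKG", obs, hmm_config(n_states = 2, n_mixtures = 1,
                                             max_iter = 15))
    mean(abs(sort(fit$means[, 1, 1]) - c(0, 3))) +
      abs(fit$trans[1, 1] - 0.8)
  }
  e_small <- err_of(50)
  e_large <- err_of(400)
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.15)
})

test_that("Viterbi agrees with enumeration and never beats the forward score", {
  set.seed(25)
  m1 <- random_ltr_model(1L)
  obs <- matrix(stats::rnorm(8), 4, 2)
  v1 <- viterbi(m1, obs)
  expect_identical(v1$path, rep(1L, 4))
  expect_equal(v1$logprob, sum(eegevents:::log_emissions(m1, obs)),
               tolerance = 1e-10)
  for (i in 1:40) {
    N <- sample(2:3, 1); Tn <- sample(2:5, 1)
    mm <- random_ltr_model(N)
    oo <- matrix(stats::rnorm(Tn * 2), Tn, 2)
    br <- brute_loglik(mm, oo)
    vv <- viterbi(mm, oo)
    expect_equal(vv$logprob, br$best_score, tolerance = 1e-9)
    expect_identical(vv$path, as.integer(br$best_path))
    expect_lte(vv$logprob, forward_backward(mm, oo)$loglik + 1e-9)
  }
})

test_that("epoch scoring returns normalized grids, symmetric under class ties", {
  set.seed(26)
  feats <- lapply(1:3, function(ch) {
    structure(list(frames = matrix(stats::rnorm(40), 20, 2),
                   frame_step = 0.1, channel_index = ch - 1L),
              class = "feature_sequence")
  })
  m <- random_ltr_model(2L)
  same <- stats::setNames(rep(list(m), 6), class_labels())
  grid <- score_epochs(same, feats)
  expect_identical(dim(grid$scores), c(2L, 3L, 6L))
  expect_equal(as.vector(grid$scores), rep(1 / 6, 36), tolerance = 1e-9)
  # distinct models: rows normalized, grid invariant to channel permutation
  models <- stats::setNames(lapply(1:6, function(i) {
    set.seed(100 + i); random_ltr_model(2L)
  }), class_labels())
  g1 <- score_epochs(models, feats)
  expect_equal(apply(g1$scores, c(1, 2), sum), matrix(1, 2, 3),
               tolerance = 1e-9)
  g2 <- score_epochs(models, feats[c(3, 1, 2)])
  expect_equal(g2$scores[, 1, ], g1$scores[, 3, ], tolerance = 1e-12)
})

test_that("class-model training requires data for every class", {
  set.seed(27)
  feats <- list(structure(list(frames = matrix(stats::rnorm(200), 100, 2),
                               frame_step = 0.1, channel_index = 0L),
                          class = "feature_sequence"))
  grid <- matrix("BCKG", 10, 1)
  grid[3, 1] <- "PLED"
  expect_error(train_class_models(feats, grid,
                                  hmm_config(n_states = 2, n_mixtures = 1)),
               "SPSW")
})

test_that("training on a single segment per class still converges", {
  set.seed(28)
  feats <- list(structure(list(frames = matrix(stats::rnorm(120), 60, 2),
                               frame_step = 0.1, channel_index = 0L),
                          class = "feature_sequence"))
  grid <- matrix(class_labels(), 6, 1)
  models <- train_class_models(feats, grid,
                               hmm_config(n_states = 2, n_mixtures = 1,
                                          max_iter = 3, split_iters = 2))
  expect_named(models, class_labels())
  expect_s3_class(models$SPSW, "hmm_model")
})
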