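# Left-to-right GMM-HMMs with diagonal covariances, trained by scaled
# Baum-Welch. One model per event class; decoding emits per-epoch,
# per-channel class posteriors that feed the second pass.

#' HMM training configuration
#'
#' @param n_states number of emitting states (left-to-right with self-loops).
#' @param n_mixtures Gaussian components per state after mixture growth.
#' @param max_iter Baum-Welch iterations at the final mixture count.
#' @param split_iters Baum-Welch iterations after each binary mixture split.
#' @param tol stop when the gain in total log-likelihood falls below this.
#' @param var_floor_frac covariance floor as a fraction of the global
#'   per-dimension variance.
#' @param max_epochs_per_class cap on training epochs pooled per class
#'   (keeps training cost bounded on large corpora; epochs beyond the cap
#'   are dropped deterministically from the end).
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(n_states = 3L, n_mixtures = 8L, max_iter = 10L,
                       split_iters = 5L, tol = 1e-3, var_floor_frac = 1e-3,
                       max_epochs_per_class = 1000L) {
  structure(list(n_states = as.integer(n_states),
                 n_mixtures = as.integer(n_mixtures),
                 max_iter = as.integer(max_iter),
                 split_iters = as.integer(split_iters), tol = tol,
                 var_floor_frac = var_floor_frac,
                 max_epochs_per_class = as.integer(max_epochs_per_class)),
            class = "hmm_config")
}

#' Construct a GMM-HMM model object
#'
#' @param class class label the model represents.
#' @param trans `n_states x n_states` transition matrix (left-to-right:
#'   only `a_ii` and `a_i,i+1` may be non-zero; rows sum to 1).
#' @param weights `n_states x L` mixture weights (rows sum to 1).
#' @param means,vars arrays `n_states x L x dim` of component means and
#'   diagonal variances.
#' @param var_floor per-dimension variance floor vector.
#' @return object of class `hmm_model`.
#' @export
hmm_model <- function(class, trans, weights, means, vars, var_floor) {
  N <- nrow(trans)
  stopifnot(ncol(trans) == N, nrow(weights) == N,
            dim(means)[1] == N, all(dim(means) == dim(vars)))
  if (any(abs(rowSums(trans) - 1) > 1e-6)) stop("transition rows must sum to 1")
  mask <- ltr_mask(N)
  if (any(trans[!mask] != 0)) stop("transition matrix violates left-to-right structure")
  structure(list(class = class, n_states = N, trans = trans,
                 weights = weights, means = means, vars = vars,
                 var_floor = var_floor),
            class = "hmm_model")
}

ltr_mask <- function(N) {
  m <- diag(TRUE, N)
  if (N > 1L) m[cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)] <- TRUE
  m
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gaussian mixture emission density
#'
#' Diagonal-covariance mixture density of one observation under one state's
#' mixture, computed in log space.
#'
#' @param o observation vector.
#' @param weights component weights (length L).
#' @param means,vars `L x dim` matrices of component means and variances.
#' @param log return the log-density instead of the density?
#' @return scalar density (or log-density).
#' @export
gaussian_mixture_density <- function(o, weights, means, vars, log = FALSE) {
  means <- rbind(means); vars <- rbind(vars)
  d <- ncol(means)
  comp <- vapply(seq_along(weights), function(l) {
    -0.5 * (d * base::log(2 * pi) + sum(base::log(vars[l, ])) +
              sum((o - means[l, ])^2 / vars[l, ]))
  }, 0)
  ll <- logsumexp(base::log(weights) + comp)
  if (log) ll else exp(ll)
}

# T x N matrix of per-state log mixture densities for all frames at once
log_emissions <- function(model, obs) {
  obs <- rbind(obs)
  Tn <- nrow(obs); N <- model$n_states
  L <- dim(model$means)[2]; d <- dim(model$means)[3]
  out <- matrix(-Inf, Tn, N)
  for (i in seq_len(N)) {
    comp <- matrix(-Inf, Tn, L)
    for (l in seq_len(L)) {
      if (model$weights[i, l] <= 0) next
      mu <- model$means[i, l, ]; v <- model$vars[i, l, ]
      quad <- colSums((t(obs) - mu)^2 / v)
      comp[, l] <- log(model$weights[i, l]) -
        0.5 * (d * log(2 * pi) + sum(log(v)) + quad)
    }
    m <- apply(comp, 1L, max)
    out[, i] <- m + log(rowSums(exp(comp - m)))
  }
  out
}

#' Scaled forward-backward pass
#'
#' Computes scaled forward and backward probabilities and the sequence
#' log-likelihood `log P(O|M)` from the per-frame scale factors. The model
#' starts deterministically in state 1.
#'
#' @param model an [hmm_model()].
#' @param obs observation matrix `T x dim` (a feature-sequence segment).
#' @param log_b optional precomputed `T x N` log-emission matrix.
#' @return list with `alpha`, `beta` (`T x N`, scaled), `scale` (length T),
#'   `loglik`, and `log_b`.
#' @export
forward_backward <- function(model, obs, log_b = NULL) {
  obs <- rbind(obs)
  if (is.null(log_b)) log_b <- log_emissions(model, obs)
  Tn <- nrow(log_b); N <- model$n_states
  A <- model$trans
  b <- exp(log_b - apply(log_b, 1L, max))           # per-row rescaled
  brow_max <- apply(log_b, 1L, max)
  alpha <- matrix(0, Tn, N); scale <- numeric(Tn)
  a1 <- c(b[1, 1], numeric(N - 1L))                 # start in state 1
  scale[1] <- sum(a1)
  if (scale[1] <= 0 || !is.finite(scale[1])) {
    stop("numerical underflow in forward pass; consider raising the variance floor")
  }
  alpha[1, ] <- a1 / scale[1]
  if (Tn > 1L) for (t in 2:Tn) {
    at <- as.vector(alpha[t - 1L, ] %*% A) * b[t, ]
    scale[t] <- sum(at)
    if (scale[t] <= 0 || !is.finite(scale[t])) {
      stop("numerical underflow in forward pass; consider raising the variance floor")
    }
    alpha[t, ] <- at / scale[t]
  }
  beta <- matrix(0, Tn, N)
  beta[Tn, ] <- 1
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    beta[t, ] <- as.vector(A %*% (b[t + 1L, ] * beta[t + 1L, ])) / scale[t + 1L]
  }
  loglik <- sum(log(scale)) + sum(brow_max)
  list(alpha = alpha, beta = beta, scale = scale, loglik = loglik,
       log_b = log_b)
}

#' Transition posteriors from a trellis
#'
#' The posterior probability of a transition from state i to state j at
#' frame t, `xi_t(i,j)`; each slice sums to 1.
#'
#' @param trellis result of [forward_backward()].
#' @param model the [hmm_model()] used.
#' @param obs the observation matrix used (only its length is needed).
#' @return array `(T-1) x N x N` (entry `[t,i,j]` is the posterior of the
#'   transition taken between frames t and t+1); for single-frame
#'   observations, the `0 x N x N` empty array.
#' @export
transition_posteriors <- function(trellis, model, obs) {
  obs <- rbind(obs)
  Tn <- nrow(obs); N <- model$n_states
  xi <- array(0, c(max(Tn - 1L, 0L), N, N))
  if (Tn < 2L) return(xi)
  A <- model$trans
  b <- exp(trellis$log_b - apply(trellis$log_b, 1L, max))
  for (t in 2:Tn) {
    m <- (trellis$alpha[t - 1L, ] %o% (b[t, ] * trellis$beta[t, ])) * A
    xi[t - 1L, , ] <- m / sum(m)
  }
  xi
}

flat_start_model <- function(class, obs_all, config) {
  d <- ncol(obs_all)
  g_mean <- colMeans(obs_all)
  g_var <- apply(obs_all, 2L, stats::var)
  g_var[!is.finite(g_var) | g_var <= 0] <- 1
  floor_v <- config$var_floor_frac * g_var
  N <- config$n_states
  means <- array(0, c(N, 1L, d)); vars <- array(0, c(N, 1L, d))
  for (i in seq_len(N)) {
    # deterministic stagger so states are not exactly symmetric
    means[i, 1L, ] <- g_mean + 0.1 * sqrt(g_var) * (i - (N + 1) / 2) / N
    vars[i, 1L, ] <- g_var
  }
  trans <- matrix(0, N, N)
  for (i in seq_len(N)) {
    if (i < N) { trans[i, i] <- 0.6; trans[i, i + 1L] <- 0.4 }
    else trans[i, i] <- 1
  }
  hmm_model(class, trans, matrix(1, N, 1L), means, vars, floor_v)
}

split_mixtures <- function(model) {
  N <- model$n_states; L <- dim(model$means)[2]; d <- dim(model$means)[3]
  means <- array(0, c(N, 2L * L, d)); vars <- array(0, c(N, 2L * L, d))
  weights <- matrix(0, N, 2L * L)
  for (i in seq_len(N)) for (l in seq_len(L)) {
    sd_l <- sqrt(model$vars[i, l, ])
    means[i, 2L * l - 1L, ] <- model$means[i, l, ] + 0.2 * sd_l
    means[i, 2L * l, ] <- model$means[i, l, ] - 0.2 * sd_l
    vars[i, 2L * l - 1L, ] <- vars[i, 2L * l, ] <- model$vars[i, l, ]
    weights[i, 2L * l - 1L] <- weights[i, 2L * l] <- model$weights[i, l] / 2
  }
  hmm_model(model$class, model$trans, weights, means, vars, model$var_floor)
}

#' One Baum-Welch reestimation step over a batch of observation sequences
#'
#' Accumulates state/component occupancies and transition posteriors over
#' all sequences, then reestimates the transition matrix (restricted to the
#' left-to-right mask), mixture weights, means and floored diagonal
#' covariances. States with no occupancy keep their previous parameters
#' (with a warning).
#'
#' @param model an [hmm_model()].
#' @param obs_list list of observation matrices (`T x dim` each).
#' @return list with `model` (updated) and `loglik` (total log-likelihood of
#'   the batch under the *input* model).
#' @export
baum_welch_update <- function(model, obs_list) {
  if (length(obs_list) == 0L) stop("empty training batch")
  N <- model$n_states; L <- dim(model$means)[2]; d <- dim(model$means)[3]
  occ <- matrix(0, N, L)                       # sum_t gamma_{t,i,l}
  mu_acc <- array(0, c(N, L, d))
  sq_acc <- array(0, c(N, L, d))
  tr_acc <- matrix(0, N, N)
  st_occ_t <- numeric(N)                       # sum over t=1..T-1 of gamma_i
  total_ll <- 0
  for (obs in obs_list) {
    obs <- rbind(obs)
    tr <- forward_backward(model, obs)
    total_ll <- total_ll + tr$loglik
    gamma <- tr$alpha * tr$beta                # T x N, rows sum to 1
    gamma <- gamma / rowSums(gamma)
    # per-component responsibilities within each state
    for (i in seq_len(N)) {
      comp <- matrix(-Inf, nrow(obs), L)
      for (l in seq_len(L)) {
        if (model$weights[i, l] <= 0) next
        mu <- model$means[i, l, ]; v <- model$vars[i, l, ]
        comp[, l] <- log(model$weights[i, l]) -
          0.5 * (d * log(2 * pi) + sum(log(v)) + colSums((t(obs) - mu)^2 / v))
      }
      m <- apply(comp, 1L, max)
      resp <- exp(comp - m)
      resp <- resp / rowSums(resp)
      g_il <- resp * gamma[, i]                # T x L
      occ[i, ] <- occ[i, ] + colSums(g_il)
      mu_acc[i, , ] <- mu_acc[i, , ] + t(g_il) %*% obs
      sq_acc[i, , ] <- sq_acc[i, , ] + t(g_il) %*% (obs^2)
    }
    if (nrow(obs) > 1L) {
      xi <- transition_posteriors(tr, model, obs)
      tr_acc <- tr_acc + apply(xi, c(2L, 3L), sum)
      st_occ_t <- st_occ_t + colSums(gamma[-nrow(obs), , drop = FALSE])
    }
  }
  new <- model
  mask <- ltr_mask(N)
  for (i in seq_len(N)) {
    tot <- sum(occ[i, ])
    if (tot < 1e-8) {
      warning("state ", i, " of class ", model$class,
              " has no occupancy; keeping previous parameters")
      next
    }
    if (st_occ_t[i] > 1e-8) {
      row <- tr_acc[i, ] / st_occ_t[i]
      row[!mask[i, ]] <- 0
      if (sum(row) > 0) new$trans[i, ] <- row / sum(row)
    }
    for (l in seq_len(L)) {
      if (occ[i, l] < 1e-8) next
      mu <- mu_acc[i, l, ] / occ[i, l]
      v <- sq_acc[i, l, ] / occ[i, l] - mu^2
      new$means[i, l, ] <- mu
      new$vars[i, l, ] <- pmax(v, model$var_floor)
    }
    new$weights[i, ] <- occ[i, ] / tot
  }
  list(model = new, loglik = total_ll)
}

total_loglik <- function(model, obs_list) {
  sum(vapply(obs_list, function(o) forward_backward(model, o)$loglik, 0))
}

#' Train one left-to-right GMM-HMM on a pool of sequences
#'
#' Flat start from the global mean/variance, then binary mixture splitting
#' (1 -> 2 -> 4 -> ... -> `n_mixtures`) with a few Baum-Welch iterations per
#' stage, then Baum-Welch to convergence.
#'
#' @param class class label for the model.
#' @param obs_list list of `T x dim` observation matrices.
#' @param config an [hmm_config()].
#' @return a trained [hmm_model()].
#' @export
train_hmm <- function(class, obs_list, config = hmm_config()) {
  if (length(obs_list) == 0L) stop("no training data for class ", class)
  obs_all <- do.call(rbind, obs_list)
  model <- flat_start_model(class, obs_all, config)
  run_bw <- function(model, iters) {
    prev <- -Inf
    for (k in seq_len(iters)) {
      up <- baum_welch_update(model, obs_list)
      model <- up$model
      if (is.finite(prev) && up$loglik - prev < config$tol) break
      prev <- up$loglik
    }
    model
  }
  model <- run_bw(model, config$split_iters)
  while (dim(model$means)[2] < config$n_mixtures) {
    model <- split_mixtures(model)
    model <- run_bw(model, config$split_iters)
  }
  run_bw(model, config$max_iter)
}

#' Train the six per-class HMMs from features and a reference label grid
#'
#' Channel-independent training: each channel's frame sequence is cut into
#' 1 s epochs, epochs are pooled across channels by their reference label,
#' and one model per class is trained on its pool.
#'
#' @param features list of feature sequences from [extract_features()]
#'   (or a list of such lists, one per record).
#' @param label_grids character matrix `n_epochs x n_channels` from
#'   [annotation_label_grid()] (or a list of such matrices, matching
#'   `features`).
#' @param config an [hmm_config()].
#' @param epoch_duration scoring epoch length in seconds.
#' @return named list of six [hmm_model()] objects in canonical class order.
#' @export
train_class_models <- function(features, label_grids, config = hmm_config(),
                               epoch_duration = 1) {
  if (!is.list(features[[1]]) || inherits(features[[1]], "feature_sequence")) {
    features <- list(features); label_grids <- list(label_grids)
  }
  pools <- stats::setNames(vector("list", n_classes()), class_labels())
  for (r in seq_along(features)) {
    feats <- features[[r]]; grid <- label_grids[[r]]
    fpe <- round(epoch_duration / feats[[1]]$frame_step)
    n_ep <- min(nrow(grid), floor(nrow(feats[[1]]$frames) / fpe))
    for (ch in seq_along(feats)) {
      fr <- feats[[ch]]$frames
      for (e in seq_len(n_ep)) {
        lab <- grid[e, ch]
        seg <- fr[((e - 1L) * fpe + 1L):(e * fpe), , drop = FALSE]
        pools[[lab]] <- c(pools[[lab]], list(seg))
      }
    }
  }
  empty <- names(pools)[vapply(pools, length, 0L) == 0L]
  if (length(empty) > 0L) {
    stop("no training epochs for class(es): ", paste(empty, collapse = ", "))
  }
  lapply(stats::setNames(class_labels(), class_labels()), function(cl) {
    pool <- pools[[cl]]
    if (length(pool) > config$max_epochs_per_class) {
      pool <- pool[seq_len(config$max_epochs_per_class)]
    }
    train_hmm(cl, pool, config)
  })
}

#' Viterbi decoding
#'
#' Most probable state path and its joint log-probability; ties broken
#' toward the lower state index.
#'
#' @param model an [hmm_model()].
#' @param obs observation matrix `T x dim`.
#' @return list with `path` (integer state indices) and `logprob`.
#' @export
viterbi <- function(model, obs) {
  obs <- rbind(obs)
  log_b <- log_emissions(model, obs)
  Tn <- nrow(log_b); N <- model$n_states
  logA <- suppressWarnings(log(model$trans))
  delta <- matrix(-Inf, Tn, N)
  psi <- matrix(0L, Tn, N)
  delta[1, 1] <- log_b[1, 1]                    # start in state 1
  if (Tn > 1L) for (t in 2:Tn) for (j in seq_len(N)) {
    cand <- delta[t - 1L, ] + logA[, j]
    psi[t, j] <- which.max(cand)                # first max = lower index
    delta[t, j] <- cand[psi[t, j]] + log_b[t, j]
  }
  last <- which.max(delta[Tn, ])
  path <- integer(Tn)
  path[Tn] <- last
  if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  list(path = path, logprob = delta[Tn, last])
}

#' Per-epoch, per-channel class posteriors from the six HMMs
#'
#' Each 1 s epoch of each channel is scored by all six class models; the
#' per-model log-likelihoods are converted to a posterior vector with a
#' log-sum-exp normalization (flat class prior).
#'
#' @param models named list of six [hmm_model()] objects.
#' @param features list of feature sequences from [extract_features()].
#' @param epoch_duration epoch length in seconds (default 1).
#' @return an `epoch_posterior_grid`: list with `scores` (array
#'   `n_epochs x n_channels x 6`) and `epoch_duration`.
#' @export
score_epochs <- function(models, features, epoch_duration = 1) {
  stopifnot(all(class_labels() %in% names(models)))
  models <- models[class_labels()]
  fpe <- round(epoch_duration / features[[1]]$frame_step)
  n_ch <- length(features)
  n_ep <- floor(nrow(features[[1]]$frames) / fpe)
  scores <- array(0, c(n_ep, n_ch, n_classes()))
  for (ch in seq_len(n_ch)) {
    fr <- features[[ch]]$frames
    # per-class log-emissions for the whole channel, sliced per epoch
    lb <- lapply(models, function(m) log_emissions(m, fr))
    for (e in seq_len(n_ep)) {
      rows <- ((e - 1L) * fpe + 1L):(e * fpe)
      ll <- vapply(seq_len(n_classes()), function(k) {
        m <- models[[k]]
        forward_backward(m, fr[rows, , drop = FALSE],
                         log_b = lb[[k]][rows, , drop = FALSE])$loglik
      }, 0)
      scores[e, ch, ] <- exp(ll - logsumexp(ll))
    }
  }
  structure(list(scores = scores, epoch_duration = epoch_duration),
            class = "epoch_posterior_grid")
}
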