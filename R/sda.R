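# Second pass: the per-epoch 132-score supervector (6 classes x 22 channels)
# is PCA-reduced, windowed in time, and classified by three stacked
# denoising autoencoders — two short-window binary detectors (epileptiform,
# eye movement) and one long-window 6-way classifier — whose outputs an
# enhancer merges into the final per-epoch posterior.

#' Flatten an epoch posterior grid into per-epoch supervectors
#'
#' Channel-major concatenation: entries 1..6 are channel 1's class scores in
#' canonical order, entries 7..12 channel 2's, and so on (132 values for the
#' standard 22-channel montage).
#'
#' @param grid an `epoch_posterior_grid` from [score_epochs()].
#' @return numeric matrix `n_epochs x (n_channels * 6)`.
#' @export
build_epoch_vectors <- function(grid) {
  sc <- grid$scores
  n_ep <- dim(sc)[1]; n_ch <- dim(sc)[2]; n_cl <- dim(sc)[3]
  if (n_cl != n_classes()) {
    stop("posterior grid has ", n_cl, " classes; expected ", n_classes())
  }
  out <- matrix(0, n_ep, n_ch * n_cl)
  for (ch in seq_len(n_ch)) {
    out[, ((ch - 1L) * n_cl + 1L):(ch * n_cl)] <- sc[, ch, ]
  }
  out
}

#' Stack a centered window of epoch vectors into one context vector
#'
#' Concatenates the vectors of epochs `k-(w-1)/2 .. k+(w-1)/2`; epochs
#' beyond the record edges are replaced by the boundary epoch (replication
#' padding). With the 41-epoch window on 132-dim vectors this yields the
#' 5412-dim second-pass input.
#'
#' @param vectors matrix `n_epochs x d`.
#' @param k center epoch index (1-based).
#' @param w odd window length in epochs.
#' @return numeric vector of length `w * d`.
#' @export
stack_window <- function(vectors, k, w) {
  if (w %% 2L != 1L) stop("window length must be odd")
  n <- nrow(vectors)
  half <- (w - 1L) %/% 2L
  idx <- pmin(pmax(k + (-half):half, 1L), n)
  as.vector(t(vectors[idx, , drop = FALSE]))
}

stack_all_windows <- function(vectors, w) {
  t(vapply(seq_len(nrow(vectors)), function(k) stack_window(vectors, k, w),
           numeric(w * ncol(vectors))))
}

#' Fit a PCA dimensionality reduction with [0,1] output scaling
#'
#' Mean-centered orthonormal projection onto the leading `out_dim`
#' principal axes, followed by per-dimension min-max scaling to `[0, 1]`
#' using the training bounds (sigmoid autoencoders with a cross-entropy
#' loss need inputs in the unit interval).
#'
#' @param x training matrix `n x d`.
#' @param out_dim target dimensionality (13 for the binary detectors, 20 for
#'   the 6-way classifier at the defaults).
#' @return list of class `pca_transform`.
#' @export
fit_pca <- function(x, out_dim) {
  x <- as.matrix(x)
  if (out_dim > ncol(x)) stop("out_dim (", out_dim, ") exceeds input dim (",
                              ncol(x), ")")
  if (nrow(x) < out_dim) stop("need at least out_dim training vectors")
  mu <- colMeans(x)
  sv <- svd(sweep(x, 2L, mu), nu = 0L, nv = out_dim)
  rot <- sv$v                                   # d x out_dim, orthonormal
  proj <- sweep(x, 2L, mu) %*% rot
  lo <- apply(proj, 2L, min); hi <- apply(proj, 2L, max)
  hi <- pmax(hi, lo + 1e-12)
  structure(list(mean = mu, rotation = rot, lo = lo, hi = hi,
                 out_dim = out_dim),
            class = "pca_transform")
}

#' Apply a fitted PCA transform
#'
#' @param transform a `pca_transform` from [fit_pca()].
#' @param x matrix (or vector) of raw supervectors.
#' @return projected matrix, min-max scaled into `[0, 1]` (clipped at the
#'   training bounds).
#' @export
apply_pca <- function(transform, x) {
  x <- rbind(x)
  proj <- sweep(x, 2L, transform$mean) %*% transform$rotation
  scaled <- sweep(sweep(proj, 2L, transform$lo), 2L,
                  transform$hi - transform$lo, `/`)
  pmin(pmax(scaled, 0), 1)
}

#' Sliding three-epoch average of a reduced-vector sequence
#'
#' Output row t is the mean of input rows t-1, t, t+1 (edges clipped); same
#' length and dimension as the input. Used ahead of the short-window
#' detectors.
#'
#' @param x matrix `n_epochs x d`.
#' @return matrix of the same shape.
#' @export
average_triplets <- function(x) {
  x <- rbind(x)
  n <- nrow(x)
  t(vapply(seq_len(n), function(t) {
    colMeans(x[max(1L, t - 1L):min(n, t + 1L), , drop = FALSE])
  }, numeric(ncol(x))))
}

#' Out-of-sample augmentation of a rare class
#'
#' Synthesizes additional examples of one class by convex interpolation
#' between same-class nearest neighbors plus small Gaussian jitter
#' (sd = 0.05 of the class per-dimension standard deviation). Original
#' rows are untouched; the target class count is multiplied by `factor`.
#'
#' @param x feature matrix `n x d`.
#' @param labels vector of labels, length `n`.
#' @param target class label to augment (needs >= 2 examples).
#' @param factor integer multiplier for the target-class count.
#' @param seed RNG seed for reproducibility.
#' @return list with augmented `x` and `labels`.
#' @export
augment_rare_class <- function(x, labels, target, factor, seed = 1L) {
  x <- as.matrix(x)
  idx <- which(labels == target)
  if (factor <= 1L) return(list(x = x, labels = labels))
  if (length(idx) < 2L) {
    stop("cannot augment class ", target, ": fewer than 2 examples")
  }
  cls <- x[idx, , drop = FALSE]
  jitter_sd <- 0.05 * apply(cls, 2L, stats::sd)
  jitter_sd[!is.finite(jitter_sd)] <- 0
  dmat <- as.matrix(stats::dist(cls))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1L, which.min)
  n_new <- (factor - 1L) * length(idx)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  picks <- sample.int(length(idx), n_new, replace = TRUE)
  lam <- stats::runif(n_new)
  synth <- cls[picks, , drop = FALSE] * lam +
    cls[nn[picks], , drop = FALSE] * (1 - lam) +
    matrix(stats::rnorm(n_new * ncol(x)), n_new) %*% diag(jitter_sd, ncol(x))
  list(x = rbind(x, synth),
       labels = c(labels, rep(target, n_new)))
}

set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Masking corruption of autoencoder inputs
#'
#' Each coordinate is independently zeroed with probability `q` (the
#' denoising-autoencoder masking noise); deterministic under a fixed RNG
#' state.
#'
#' @param x numeric vector or matrix.
#' @param q corruption level in `[0, 1]`.
#' @return corrupted copy of `x`.
#' @export
corrupt <- function(x, q) {
  if (q < 0 || q > 1) stop("corruption level must be in [0, 1]")
  if (q == 0) return(x)
  mask <- stats::runif(length(x)) >= q
  x * mask
}

#' Reconstruction cross-entropy loss
#'
#' `L = -sum_d [x log z + (1-x) log(1-z)]`, averaged over the batch;
#' reconstructions are clipped to `[eps, 1-eps]`.
#'
#' @param x clean inputs in `[0,1]` (vector or matrix, rows = examples).
#' @param z reconstructions of the same shape.
#' @param eps clipping constant (default 1e-7).
#' @return scalar mean loss.
#' @export
dae_loss <- function(x, z, eps = 1e-7) {
  x <- rbind(x); z <- rbind(z)
  z <- pmin(pmax(z, eps), 1 - eps)
  mean(rowSums(-(x * log(z) + (1 - x) * log(1 - z))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

init_layer <- function(n_in, n_out) {
  lim <- 4 * sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in),
       b = numeric(n_out), b_prime = numeric(n_in))
}

#' Construct an (untrained) stacked denoising autoencoder network
#'
#' @param role one of "spsw", "eyem" (binary detectors, 39 inputs / 2
#'   outputs at the defaults) or "sixway" (820 inputs / 6 outputs).
#' @param n_in input dimension.
#' @param n_out output classes (head size).
#' @param hidden integer vector of hidden-layer widths.
#' @param window_length context window in epochs.
#' @param corruption per-layer masking level (default 0.3).
#' @param seed RNG seed for weight initialization.
#' @return list of class `sda_network`.
#' @export
sda_network <- function(role, n_in, n_out, hidden, window_length,
                        corruption = 0.3, seed = 1L) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  dims <- c(n_in, hidden)
  layers <- lapply(seq_along(hidden), function(i) init_layer(dims[i], dims[i + 1L]))
  head_lim <- sqrt(6 / (hidden[length(hidden)] + n_out))
  head <- list(W = matrix(stats::runif(n_out * hidden[length(hidden)],
                                       -head_lim, head_lim),
                          n_out, hidden[length(hidden)]),
               b = numeric(n_out))
  structure(list(role = role, n_in = n_in, n_out = n_out, hidden = hidden,
                 layers = layers, head = head,
                 window_length = window_length, corruption = corruption),
            class = "sda_network")
}

#' SdA training hyperparameters
#'
#' Full-scale defaults (pre-training learning rate
#' 0.5, 150-200 epochs, batch 300; fine-tuning rates 0.1-0.2). Tests and
#' examples use a scaled-down profile via these arguments.
#'
#' @param learning_rate SGD step size.
#' @param n_epochs passes over the training data.
#' @param batch_size minibatch size.
#' @param seed RNG seed for corruption/shuffling.
#' @return list of class `sda_hyperparams`.
#' @export
sda_hyperparams <- function(learning_rate = 0.5, n_epochs = 200L,
                            batch_size = 300L, seed = 1L) {
  structure(list(learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "sda_hyperparams")
}

encode_through <- function(layers, x) {
  # x: rows = examples
  h <- t(rbind(x))
  for (ly in layers) h <- sigmoid(ly$W %*% h + ly$b)
  t(h)
}

# gradient of the tied-weight DAE loss for one minibatch (columns = samples)
dae_gradients <- function(layer, x_clean, x_corrupt) {
  a <- layer$W %*% x_corrupt + layer$b
  y <- sigmoid(a)
  z <- sigmoid(t(layer$W) %*% y + layer$b_prime)
  m <- ncol(x_clean)
  dz <- (z - x_clean)                          # dL/d(pre-sigmoid of z)
  dy <- (layer$W %*% dz) * y * (1 - y)
  list(dW = (dy %*% t(x_corrupt) + y %*% t(dz)) / m,
       db = rowMeans(dy),
       db_prime = rowMeans(dz),
       loss = dae_loss(t(x_clean), t(z)))
}

#' Greedy layer-wise pre-training of an SdA
#'
#' Each layer is trained as a denoising autoencoder (masking corruption,
#' tied weights, cross-entropy reconstruction loss, plain minibatch SGD) on
#' the encoding produced by the layers below. Labels are never consulted.
#'
#' @param network an [sda_network()].
#' @param x unlabeled training inputs in `[0,1]`, rows = examples.
#' @param hyper an [sda_hyperparams()].
#' @param holdout_frac fraction of rows held out to monitor reconstruction
#'   loss (reported in the returned `pretrain_history` attribute).
#' @return the network with pre-trained layers.
#' @export
pretrain_sda <- function(network, x, hyper = sda_hyperparams(),
                         holdout_frac = 0.1) {
  x <- as.matrix(x)
  if (ncol(x) != network$n_in) {
    stop("input dim ", ncol(x), " does not match network input ", network$n_in)
  }
  old <- set_local_seed(hyper$seed)
  on.exit(restore_seed(old))
  n_hold <- max(1L, floor(nrow(x) * holdout_frac))
  hold_idx <- seq_len(n_hold)                  # deterministic split
  history <- list()
  for (li in seq_along(network$layers)) {
    inp <- if (li == 1L) x else encode_through(network$layers[seq_len(li - 1L)], x)
    train <- t(inp[-hold_idx, , drop = FALSE]) # columns = samples
    hold <- t(inp[hold_idx, , drop = FALSE])
    layer <- network$layers[[li]]
    losses <- numeric(hyper$n_epochs)
    n <- ncol(train)
    for (ep in seq_len(hyper$n_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = hyper$batch_size)) {
        cols <- ord[start:min(start + hyper$batch_size - 1L, n)]
        xb <- train[, cols, drop = FALSE]
        xc <- corrupt(xb, network$corruption)
        g <- dae_gradients(layer, xb, xc)
        if (!is.finite(g$loss)) {
          stop("divergence (non-finite loss) in layer ", li, ", epoch ", ep)
        }
        layer$W <- layer$W - hyper$learning_rate * g$dW
        layer$b <- layer$b - hyper$learning_rate * g$db
        layer$b_prime <- layer$b_prime - hyper$learning_rate * g$db_prime
      }
      zc <- sigmoid(t(layer$W) %*% sigmoid(layer$W %*% hold + layer$b) +
                      layer$b_prime)
      losses[ep] <- dae_loss(t(hold), t(zc))
    }
    network$layers[[li]] <- layer
    history[[li]] <- losses
  }
  attr(network, "pretrain_history") <- history
  network
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Posterior predictions of a (fine-tuned) SdA
#'
#' @param network an [sda_network()].
#' @param x input matrix, rows = examples.
#' @return matrix `n x n_out` of softmax posteriors (rows sum to 1).
#' @export
predict_sda <- function(network, x) {
  h <- encode_through(network$layers, x)
  softmax_rows(sweep(h %*% t(network$head$W), 2L, -network$head$b))
}

#' Supervised fine-tuning of an SdA with a softmax head
#'
#' The encoder stack plus logistic-regression head is trained end-to-end by
#' plain minibatch SGD on the negative log-likelihood, starting from the
#' pre-trained weights.
#'
#' @param network a pre-trained [sda_network()].
#' @param x training inputs, rows = examples.
#' @param labels integer class labels in `1..n_out`.
#' @param hyper an [sda_hyperparams()].
#' @return the fine-tuned network.
#' @export
finetune_sda <- function(network, x, labels, hyper = sda_hyperparams()) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > network$n_out)) {
    stop("labels must lie in 1..", network$n_out)
  }
  old <- set_local_seed(hyper$seed + 1L)
  on.exit(restore_seed(old))
  n <- nrow(x)
  target <- matrix(0, n, network$n_out)
  target[cbind(seq_len(n), labels)] <- 1
  for (ep in seq_len(hyper$n_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = hyper$batch_size)) {
      rows <- ord[start:min(start + hyper$batch_size - 1L, n)]
      xb <- t(x[rows, , drop = FALSE])         # columns = samples
      m <- ncol(xb)
      acts <- list(xb)
      h <- xb
      for (ly in network$layers) {
        h <- sigmoid(ly$W %*% h + ly$b)
        acts[[length(acts) + 1L]] <- h
      }
      logits <- network$head$W %*% h + network$head$b
      p <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
      p <- sweep(p, 2L, colSums(p), `/`)
      dlogits <- (p - t(target[rows, , drop = FALSE])) / m
      gW_head <- dlogits %*% t(h)
      gb_head <- rowSums(dlogits)
      dh <- t(network$head$W) %*% dlogits
      for (li in rev(seq_along(network$layers))) {
        a <- acts[[li + 1L]]
        da <- dh * a * (1 - a)
        gW <- da %*% t(acts[[li]])
        gb <- rowSums(da)
        dh <- t(network$layers[[li]]$W) %*% da
        network$layers[[li]]$W <- network$layers[[li]]$W -
          hyper$learning_rate * gW
        network$layers[[li]]$b <- network$layers[[li]]$b -
          hyper$learning_rate * gb
      }
      network$head$W <- network$head$W - hyper$learning_rate * gW_head
      network$head$b <- network$head$b - hyper$learning_rate * gb_head
    }
  }
  network
}

#' Merge the three second-pass outputs into a final epoch posterior
#'
#' The 6-way posterior initializes the output. If the epileptiform detector
#' fires (`p_spsw[1] > 0.5`) while the 6-way classifier does not agree —
#' i.e. it places no more than half of its mass on the {SPSW, PLED, GPED}
#' block — that block is rescaled to carry the detector's probability mass
#' (internal ratios preserved; an all-zero block is split equally) and the
#' complement carries the remainder. The analogous rule applies for the
#' eye-movement detector with block {EYEM}.
#'
#' @param p6 6-way posterior vector (canonical class order).
#' @param p_spsw length-2 vector `(epileptiform, other)`.
#' @param p_eyem length-2 vector `(eyem, other)`.
#' @return normalized 6-vector.
#' @export
enhancer_combine <- function(p6, p_spsw, p_eyem) {
  labs <- class_labels()
  out <- p6 / sum(p6)
  epi <- labs %in% c("SPSW", "PLED", "GPED")
  if (p_spsw[1] > 0.5 && sum(out[epi]) <= 0.5) {
    out <- reallocate_block(out, epi, p_spsw[1])
  }
  eye <- labs == "EYEM"
  if (p_eyem[1] > 0.5 && sum(out[eye]) <= 0.5) {
    out <- reallocate_block(out, eye, p_eyem[1])
  }
  out / sum(out)
}

reallocate_block <- function(p, block, mass) {
  inb <- p[block]; outb <- p[!block]
  p[block] <- if (sum(inb) > 0) inb / sum(inb) * mass else mass / sum(block)
  p[!block] <- if (sum(outb) > 0) outb / sum(outb) * (1 - mass) else
    (1 - mass) / sum(!block)
  p
}
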