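# Independent oracles and small builders used across the suite.

# exhaustive path-sum log-likelihood (brute-force oracle for the forward pass)
brute_loglik <- function(model, obs) {
  obs <- rbind(obs)
  N <- model$n_states; Tn <- nrow(obs)
  lb <- matrix(0, Tn, N)
  for (i in seq_len(N)) for (t in seq_len(Tn)) {
    lb[t, i] <- gaussian_mixture_density(obs[t, ], model$weights[i, ],
                                         rbind(model$means[i, , ]),
                                         rbind(model$vars[i, , ]), log = TRUE)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  lp <- apply(paths, 1L, function(p) {
    v <- if (p[1] == 1L) lb[1, p[1]] else -Inf
    if (Tn > 1L) for (t in 2:Tn) {
      a <- model$trans[p[t - 1L], p[t]]
      v <- v + (if (a > 0) log(a) else -Inf) + lb[t, p[t]]
    }
    v
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_path = paths[which.max(lp), ], best_score = max(lp))
}

# random left-to-right GMM-HMM with L components in d dimensions
random_ltr_model <- function(N, L = 2L, d = 2L) {
  trans <- matrix(0, N, N)
  for (i in seq_len(N)) {
    if (i < N) { a <- stats::runif(1, 0.3, 0.9); trans[i, i] <- a; trans[i, i + 1L] <- 1 - a }
    else trans[i, i] <- 1
  }
  w <- matrix(stats::runif(N * L), N, L); w <- w / rowSums(w)
  hmm_model("BCKG", trans, w,
            array(stats::rnorm(N * L * d), c(N, L, d)),
            array(stats::runif(N * L * d, 0.5, 2), c(N, L, d)),
            rep(1e-4, d))
}

# sample observation sequences from a 1-component LTR GMM-HMM
simulate_hmm <- function(model, n_seq, len) {
  d <- dim(model$means)[3]
  lapply(seq_len(n_seq), function(s) {
    st <- 1L
    obs <- matrix(0, len, d)
    for (t in seq_len(len)) {
      obs[t, ] <- stats::rnorm(d, model$means[st, 1L, ],
                               sqrt(model$vars[st, 1L, ]))
      st <- sample.int(model$n_states, 1L, prob = model$trans[st, ])
    }
    obs
  })
}

# sine-wave test record
sine_record <- function(freq, duration = 10, rate = 250, amp = 50,
                        n_channels = 1L) {
  t <- (seq_len(duration * rate) - 1L) / rate
  eeg_record(matrix(rep(amp * sin(2 * pi * freq * t), n_channels),
                    ncol = n_channels),
             rate, paste0("CH", seq_len(n_channels)))
}

# frozen copy of the bigram transition table, written out independently of
# R/grammar.R so packaging regressions are caught
reference_bigram <- function() {
  matrix(c(0.40, 0.00, 0.00, 0.10, 0.20, 0.30,
           0.00, 0.90, 0.00, 0.00, 0.05, 0.05,
           0.00, 0.00, 0.60, 0.00, 0.20, 0.20,
           0.10, 0.00, 0.00, 0.40, 0.10, 0.40,
           0.23, 0.05, 0.05, 0.23, 0.23, 0.23,
           0.33, 0.05, 0.05, 0.23, 0.13, 0.23),
         nrow = 6L, byrow = TRUE,
         dimnames = list(class_labels(), class_labels()))
}
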