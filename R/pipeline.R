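# End-to-end orchestration: train the three passes on an annotated corpus
# directory (EDF + CSV pairs with a manifest) and decode new records.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a single seed from which all
#' stochastic stages derive theirs. The `"full"` SdA profile uses the
#' full-scale network sizes and training schedules (sized for large annotated corpora); the `"test"` profile is
#' a scaled-down configuration (smaller hidden layers, fewer training
#' epochs, 2 HMM mixture components) for fast experimentation and testing.
#' The scoring epoch duration is fixed pipeline-wide at 1 s.
#'
#' @param seed master RNG seed.
#' @param features a [feature_config()].
#' @param hmm an [hmm_config()]; defaults depend on `sda_profile`.
#' @param grammar_cfg a [grammar_config()].
#' @param sda_profile `"full"` (full-scale architectures and schedules) or `"test"` (scaled down).
#' @param pca_dim_binary,pca_dim_sixway PCA output dims (13 / 20).
#' @param window_binary,window_sixway context windows in epochs (3 / 41).
#' @param augment_factor out-of-sample augmentation multiplier for the rare
#'   classes (SPSW, EYEM) in the fine-tuning sets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, features = feature_config(),
                            hmm = NULL, grammar_cfg = grammar_config(),
                            sda_profile = c("full", "test"),
                            pca_dim_binary = 13L, pca_dim_sixway = 20L,
                            window_binary = 3L, window_sixway = 41L,
                            augment_factor = 4L) {
  sda_profile <- match.arg(sda_profile)
  if (is.null(hmm)) {
    hmm <- if (sda_profile == "full") hmm_config() else
      hmm_config(n_mixtures = 2L, max_iter = 6L, split_iters = 3L,
                 max_epochs_per_class = 300L)
  }
  sda <- if (sda_profile == "full") {
    list(binary_hidden = c(100L, 100L, 100L),
         sixway_hidden = c(800L, 500L, 300L),
         pretrain = sda_hyperparams(0.5, 200L, 300L),
         pretrain_sixway = sda_hyperparams(0.5, 150L, 300L),
         finetune_spsw = sda_hyperparams(0.2, 800L, 100L),
         finetune_eyem = sda_hyperparams(0.2, 100L, 100L),
         finetune_sixway = sda_hyperparams(0.1, 300L, 100L))
  } else {
    list(binary_hidden = c(40L, 40L),
         sixway_hidden = c(100L, 60L),
         pretrain = sda_hyperparams(0.05, 15L, 50L),
         pretrain_sixway = sda_hyperparams(0.05, 15L, 50L),
         finetune_spsw = sda_hyperparams(0.1, 300L, 50L),
         finetune_eyem = sda_hyperparams(0.1, 300L, 50L),
         finetune_sixway = sda_hyperparams(0.1, 600L, 50L))
  }
  structure(list(seed = as.integer(seed), features = features, hmm = hmm,
                 grammar_cfg = grammar_cfg, sda_profile = sda_profile,
                 sda = sda, pca_dim_binary = as.integer(pca_dim_binary),
                 pca_dim_sixway = as.integer(pca_dim_sixway),
                 window_binary = as.integer(window_binary),
                 window_sixway = as.integer(window_sixway),
                 augment_factor = as.integer(augment_factor),
                 epoch_duration = 1),
            class = "pipeline_config")
}

read_corpus_split <- function(corpus_dir, split) {
  manifest <- jsonlite::read_json(file.path(corpus_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  bases <- manifest[[split]]
  lapply(bases, function(b) {
    list(base = b,
         edf = file.path(corpus_dir, paste0(b, ".edf")),
         csv = file.path(corpus_dir, paste0(b, ".csv")))
  })
}

prep_record <- function(edf_path, csv_path, config) {
  rec <- read_edf(edf_path)
  if (abs(rec$rate - 250) > 1e-9) rec <- resample_record(rec, 250)
  feats <- extract_features(rec, config$features)
  n_ep <- floor(nrow(feats[[1]]$frames) *
                  feats[[1]]$frame_step / config$epoch_duration)
  ann <- if (!is.null(csv_path)) read_annotations(csv_path) else NULL
  grid <- if (!is.null(ann)) {
    annotation_label_grid(ann, n_ep, length(feats), config$epoch_duration)
  } else NULL
  list(features = feats, label_grid = grid, n_epochs = n_ep)
}

# second-pass input construction shared by training and decoding
sda_inputs <- function(epoch_vectors, pca13, pca20, config) {
  red13 <- average_triplets(apply_pca(pca13, epoch_vectors))
  red20 <- apply_pca(pca20, epoch_vectors)
  list(binary = stack_all_windows(red13, config$window_binary),
       sixway = stack_all_windows(red20, config$window_sixway))
}

#' Train the full three-pass pipeline on a corpus directory
#'
#' Trains the six per-class HMMs on the training split, generates pass-1
#' posterior grids on the same split, fits the two global PCA transforms,
#' trains the three stacked denoising autoencoders (with rare-class
#' augmentation of the fine-tuning sets), and packages the bigram grammar.
#'
#' @param corpus_dir directory from [generate_corpus()] (or with the same
#'   layout: `recNNN.edf` + `recNNN.csv` + `manifest.json`).
#' @param config a [pipeline_config()].
#' @param verbose print stage progress?
#' @return a model bundle (list of class `pipeline_bundle`).
#' @export
run_train <- function(corpus_dir, config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- "reading training corpus"
  result <- tryCatch({
    train <- read_corpus_split(corpus_dir, "train")
    say("preparing ", length(train), " training records")
    prepped <- lapply(train, function(f) prep_record(f$edf, f$csv, config))

    stage <- "training HMMs"
    say(stage)
    models <- train_class_models(lapply(prepped, `[[`, "features"),
                                 lapply(prepped, `[[`, "label_grid"),
                                 config$hmm, config$epoch_duration)

    stage <- "generating pass-1 posteriors"
    say(stage)
    grids <- lapply(prepped, function(p)
      score_epochs(models, p$features, config$epoch_duration))
    vec_list <- lapply(grids, build_epoch_vectors)
    all_vec <- do.call(rbind, vec_list)

    stage <- "fitting PCA"
    say(stage)
    pca13 <- fit_pca(all_vec, config$pca_dim_binary)
    pca20 <- fit_pca(all_vec, config$pca_dim_sixway)

    stage <- "building second-pass training sets"
    inputs <- lapply(vec_list, sda_inputs, pca13 = pca13, pca20 = pca20,
                     config = config)
    x_bin <- do.call(rbind, lapply(inputs, `[[`, "binary"))
    x_six <- do.call(rbind, lapply(inputs, `[[`, "sixway"))
    ep_labels <- unlist(lapply(prepped, function(p)
      epoch_priority_labels(p$label_grid)))
    stopifnot(length(ep_labels) == nrow(x_six))
    y_six <- label_index(ep_labels)
    y_spsw <- ifelse(ep_labels %in% c("SPSW", "PLED", "GPED"), 1L, 2L)
    y_eyem <- ifelse(ep_labels == "EYEM", 1L, 2L)

    stage <- "training SdA networks"
    say(stage)
    sc <- config$sda
    nets <- list()
    net_specs <- list(
      spsw = list(x = x_bin, y = y_spsw, n_out = 2L,
                  hidden = sc$binary_hidden, w = config$window_binary,
                  pre = sc$pretrain, fine = sc$finetune_spsw,
                  augment_class = 1L),
      eyem = list(x = x_bin, y = y_eyem, n_out = 2L,
                  hidden = sc$binary_hidden, w = config$window_binary,
                  pre = sc$pretrain, fine = sc$finetune_eyem,
                  augment_class = 1L),
      sixway = list(x = x_six, y = y_six, n_out = 6L,
                    hidden = sc$sixway_hidden, w = config$window_sixway,
                    pre = sc$pretrain_sixway, fine = sc$finetune_sixway,
                    augment_class = label_index(c("SPSW", "EYEM"))))
    for (role in names(net_specs)) {
      ns <- net_specs[[role]]
      say("  ", role, " SdA (", ncol(ns$x), " inputs)")
      net <- sda_network(role, n_in = ncol(ns$x), n_out = ns$n_out,
                         hidden = ns$hidden, window_length = ns$w,
                         corruption = 0.3,
                         seed = config$seed + match(role, names(net_specs)))
      pre <- ns$pre; pre$seed <- config$seed + 10L
      net <- pretrain_sda(net, ns$x, pre)
      xa <- ns$x; ya <- ns$y
      if (config$augment_factor > 1L) {
        for (cls in ns$augment_class) {
          if (sum(ya == cls) >= 2L) {
            aug <- augment_rare_class(xa, ya, cls, config$augment_factor,
                                      seed = config$seed + 20L + cls)
            xa <- aug$x; ya <- aug$labels
          }
        }
      }
      fine <- ns$fine; fine$seed <- config$seed + 30L
      nets[[role]] <- finetune_sda(net, xa, ya, fine)
    }

    structure(list(models = models, pca13 = pca13, pca20 = pca20,
                   nets = nets, grammar = bigram_grammar(),
                   config = config,
                   provenance = list(seed = config$seed,
                                     profile = config$sda_profile,
                                     n_train_records = length(train),
                                     trained = format(Sys.time(), "%Y-%m-%d"))),
              class = "pipeline_bundle")
  }, error = function(e) {
    stop("pipeline training failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  result
}

#' Decode one record through all three passes
#'
#' @param edf an EDF file path or an [eeg_record()] (must be the 22-channel
#'   montage the bundle was trained on).
#' @param bundle a `pipeline_bundle` from [run_train()].
#' @param out_csv optional path: write the final epoch-level hypothesis as
#'   annotations (one row per channel per contiguous label run).
#' @return list with `pass1` (the epoch posterior grid), `pass1_labels`
#'   (epoch-level labels from pass 1 alone, via per-channel argmax and
#'   priority vote), `pass2` (enhanced epoch posterior matrix),
#'   `pass2_labels`, `pass3` (`smoothed_sequence`), and `labels` (final
#'   per-epoch labels).
#' @export
run_decode <- function(edf, bundle, out_csv = NULL) {
  config <- bundle$config
  rec <- if (inherits(edf, "eeg_record")) edf else read_edf(edf)
  if (abs(rec$rate - 250) > 1e-9) rec <- resample_record(rec, 250)
  if (ncol(rec$samples) != 22L) {
    stop("record has ", ncol(rec$samples),
         " channels; the bundle expects the 22-channel montage")
  }
  feats <- extract_features(rec, config$features)
  grid <- score_epochs(bundle$models, feats, config$epoch_duration)
  vecs <- build_epoch_vectors(grid)
  inputs <- sda_inputs(vecs, bundle$pca13, bundle$pca20, config)
  p_spsw <- predict_sda(bundle$nets$spsw, inputs$binary)
  p_eyem <- predict_sda(bundle$nets$eyem, inputs$binary)
  p6 <- predict_sda(bundle$nets$sixway, inputs$sixway)
  pass2 <- t(vapply(seq_len(nrow(p6)), function(e)
    enhancer_combine(p6[e, ], p_spsw[e, ], p_eyem[e, ]), numeric(6L)))
  pass3 <- run_grammar_pass(pass2, bundle$grammar, config$grammar_cfg)

  ch_argmax <- apply(grid$scores, c(1L, 2L), which.max)
  pass1_grid <- matrix(class_labels()[ch_argmax], nrow(ch_argmax))
  out <- list(pass1 = grid,
              pass1_labels = epoch_priority_labels(pass1_grid),
              pass2 = pass2,
              pass2_labels = class_labels()[apply(pass2, 1L, which.max)],
              pass3 = pass3, labels = pass3$labels)
  if (!is.null(out_csv)) {
    write_annotations(labels_to_annotations(out$labels, 22L,
                                            config$epoch_duration), out_csv)
  }
  out
}

# epoch-level hypothesis labels -> per-channel annotation rows (runs merged)
labels_to_annotations <- function(labels, n_channels, epoch_duration = 1) {
  runs <- rle(labels)
  stops <- cumsum(runs$lengths) * epoch_duration
  starts <- c(0, stops[-length(stops)])
  rows <- do.call(rbind, lapply(seq_along(runs$values), function(i) {
    data.frame(channel_index = seq_len(n_channels) - 1L,
               start = starts[i], stop = stops[i], label = runs$values[i],
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$channel_index, rows$start), ]
  rownames(rows) <- NULL
  validate_annotations(rows)
}
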