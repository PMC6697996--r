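# Turn-based two-dataset training: batching, the learning-rate schedule,
# RMSprop with global gradient clipping, and grid search over the
# adversarial loss weights.

#' Default training configuration
#'
#' Reference settings: 80 epochs, batch size 16, RMSprop with decay 0.95
#' and zero momentum, initial learning rate 0.001 decaying 3% per epoch,
#' global gradient L2 norm clipped at 5.0, dropout 0.5.
#'
#' @param epochs,batch_size,initial_lr,lr_decay,rmsprop_decay,momentum
#'   optimizer schedule settings.
#' @param grad_clip_l2 maximum global gradient L2 norm.
#' @param dropout dropout rate used by every dropout layer.
#' @param seed integer seed governing all randomness of a run.
#' @param alpha,beta adversarial and orthogonality loss weights (used by
#'   the `adv` architecture).
#' @param select `"best_dev"` (default) keeps the epoch with the best
#'   main-dataset dev macro-F1; `"final"` keeps the last epoch.
#' @return named list, class `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = 16L, initial_lr = 0.001,
                         lr_decay = 0.03, rmsprop_decay = 0.95,
                         momentum = 0, grad_clip_l2 = 5.0, dropout = 0.5,
                         seed = 1L, alpha = 0, beta = 0,
                         select = c("best_dev", "final")) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_lr > 0,
            lr_decay >= 0, lr_decay < 1, rmsprop_decay > 0,
            rmsprop_decay < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 rmsprop_decay = rmsprop_decay, momentum = momentum,
                 grad_clip_l2 = grad_clip_l2, dropout = dropout,
                 seed = as.integer(seed), alpha = alpha, beta = beta,
                 select = match.arg(select)),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' `lr = initial_lr * (1 - lr_decay)^e`: the rate decays by `lr_decay`
#' (3% by default) at the end of every epoch.
#'
#' @param e epoch index from 0.
#' @param config a [train_config()].
#' @return learning rate for epoch `e`.
#' @export
lr_at_epoch <- function(e, config = train_config()) {
  stopifnot(all(e >= 0))
  config$initial_lr * (1 - config$lr_decay)^e
}

#' Build the turn schedule of one epoch
#'
#' One epoch holds exactly as many turns as the main dataset has training
#' batches, so the main dataset is fully trained each epoch; every turn
#' pairs one main batch (each appearing exactly once, in random order)
#' with one auxiliary batch drawn at random with replacement.
#'
#' @param n_main_batches,n_aux_batches batch counts (>= 1).
#' @param seed reproducibility seed.
#' @return data.frame with columns `main`, `aux`, one row per turn.
#' @export
make_turn_schedule <- function(n_main_batches, n_aux_batches, seed) {
  if (n_main_batches < 1 || n_aux_batches < 1)
    stop("batch counts must be >= 1")
  with_local_seed(seed, data.frame(
    main = sample.int(n_main_batches),
    aux = sample.int(n_aux_batches, n_main_batches, replace = TRUE)))
}

# ---- batch assembly ------------------------------------------------------

# Encode sentences into index form against a vocabulary + one tagset.
encode_sentences <- function(sentences, vocab, dataset_name,
                             require_tags = TRUE) {
  tag_idx <- vocab$tag_index[[dataset_name]]
  lapply(sentences, function(s) {
    y <- NULL
    if (!is.null(s$tags)) {
      y <- unname(tag_idx[s$tags])
      if (require_tags && anyNA(y))
        stop("tag not in inventory of '", dataset_name, "': ",
             paste(unique(s$tags[is.na(y)]), collapse = ", "))
    } else if (require_tags) stop("sentence without tags")
    list(w = lookup_words(s$tokens, vocab$word_index),
         chars = lapply(s$tokens, lookup_chars,
                        char_index = vocab$char_index),
         y = y, len = length(s$tokens))
  })
}

# Pad a list of sentences (raw or encoded) into one batch structure.
make_batch <- function(sentences, vocab = NULL, dataset_name = NULL,
                       require_tags = TRUE) {
  enc <- if (!is.null(vocab))
    encode_sentences(sentences, vocab, dataset_name, require_tags)
  else sentences
  B <- length(enc)
  lens <- vapply(enc, `[[`, integer(1), "len")
  TT <- max(lens)
  word_ids <- matrix(1L, B, TT)   # PAD
  mask <- matrix(0, B, TT)
  char_list <- list()
  real_idx <- integer(0)
  for (b in seq_len(B)) {
    word_ids[b, seq_len(lens[b])] <- enc[[b]]$w
    mask[b, seq_len(lens[b])] <- 1
  }
  # real tokens in column-major (b fastest) order to match array layout
  for (t in seq_len(TT)) for (b in seq_len(B)) {
    if (t <= lens[b]) {
      real_idx <- c(real_idx, (t - 1L) * B + b)
      char_list[[length(char_list) + 1L]] <- enc[[b]]$chars[[t]]
    }
  }
  pk <- pack_char_ids(char_list)
  list(word_ids = word_ids, mask = mask, lens = lens,
       char_ids = pk$ids, char_lens = pk$lens, real_idx = real_idx,
       tags = lapply(enc, `[[`, "y"))
}

# Bucket encoded sentences by length, cut into batches, shuffle batch order.
# Bucketing limits padding; the seeded shuffle decorrelates batch order
# from sentence length.
bucket_batches <- function(enc, batch_size, seed) {
  ord <- order(vapply(enc, `[[`, integer(1), "len"))
  groups <- split(ord, ceiling(seq_along(ord) / batch_size))
  groups <- with_local_seed(seed, sample(groups))
  lapply(groups, function(ix) make_batch(enc[ix]))
}

# ---- optimizer -----------------------------------------------------------

new_rmsprop_state <- function() new.env(parent = emptyenv())

# RMSprop update over flat gradient list; epsilon 1e-8, momentum 0.
rmsprop_update <- function(params, flat_grads, state, lr, decay,
                           eps = 1e-8) {
  for (nm in names(flat_grads)) {
    g <- flat_grads[[nm]]
    v <- state[[nm]] %||% array(0, dim = dim(g) %||% length(g))
    v <- decay * v + (1 - decay) * g * g
    state[[nm]] <- v
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    upd <- lr * g / (sqrt(v) + eps)
    if (is.null(dim(params[[path]]))) upd <- as.vector(upd)
    params[[path]] <- params[[path]] - upd
  }
  params
}

#' One optimization step on a single-source batch
#'
#' Computes the architecture's loss and gradients on the batch, clips the
#' global gradient L2 norm, and applies an RMSprop update in place on the
#' model.
#'
#' @param model a [build_model()] model.
#' @param batch a padded batch (see [make_batch()]).
#' @param d dataset index of the batch (1 or 2).
#' @param config a [train_config()].
#' @param opt_state RMSprop accumulator environment
#'   (from `new_rmsprop_state()`); updated in place.
#' @param lr learning rate for this step.
#' @return list with the updated `model` and the loss `breakdown`.
#' @export
train_step <- function(model, batch, d, config, opt_state, lr) {
  res <- compute_batch(model, batch, d = d, train = TRUE, grad = TRUE,
                       alpha = config$alpha, beta = config$beta)
  if (!is.finite(res$loss))
    stop("non-finite loss (", res$loss, ") on dataset ", d,
         "; breakdown: ", paste(names(res$breakdown),
                                unlist(res$breakdown), sep = "=",
                                collapse = " "))
  flat <- collect_leaves(res$grads)
  flat <- clip_gradients(flat, config$grad_clip_l2)
  model$params <- rmsprop_update(model$params, flat, opt_state, lr,
                                 config$rmsprop_decay)
  list(model = model, breakdown = res$breakdown,
       grad_norm = attr(flat, "norm"))
}

# Macro-F1 of a model over a list of sentences (tag-level, percent scale).
evaluate_split <- function(model, sentences, d = 1L) {
  if (!length(sentences)) return(NA_real_)
  pred <- predict_tags(model, sentences, d = d)
  gold <- lapply(sentences, `[[`, "tags")
  scheme_labels <- names(model$vocab$tag_index[[model$datasets[d]]])
  sch <- tag_scheme(scheme_labels)
  tag_metrics(pred, gold, sch)$macro["f1"]
}

#' Predict tags for sentences
#'
#' Deterministic Viterbi decoding with dropout off.
#'
#' @param model a trained model.
#' @param sentences list of sentences (tags not required).
#' @param d dataset index selecting the CRF head and tag inventory.
#' @return list of character tag vectors, one per sentence.
#' @export
predict_tags <- function(model, sentences, d = 1L) {
  out <- vector("list", length(sentences))
  # decode in modest chunks to bound padding waste
  chunk <- 32L
  i <- 1L
  while (i <= length(sentences)) {
    j <- min(i + chunk - 1L, length(sentences))
    fw <- model_forward(model, sentences[i:j], d = d, decode = TRUE)
    out[i:j] <- fw$tags
    i <- j + 1L
  }
  out
}

#' Train a model
#'
#' Runs the turn-based optimization loop: every epoch visits each
#' main-dataset batch exactly once and, for the multi-task architectures,
#' pairs each with a randomly drawn auxiliary batch (one step on the main
#' batch, one on the auxiliary batch per turn).  Dev macro-F1 on the main
#' dataset is recorded each epoch; the returned model is the best-dev
#' epoch snapshot (or the final epoch, per `config$select`).
#'
#' @param main main-dataset [tagged_corpus()].
#' @param aux auxiliary [tagged_corpus()] (required for the multi-task
#'   architectures, must be absent for `stm`).
#' @param architecture one of `"stm"`, `"fs"`, `"sp"`, `"adv"`, `"cs"`.
#' @param config a [train_config()].
#' @param model_cfg a [model_config()]; its seed is taken from
#'   `config$seed`.
#' @param pretrained optional pretrained word-vector list.
#' @param verbose print one line per epoch.
#' @return object of class `ner_fit`: `model`, `history` (one row per
#'   epoch), `config`, `best_epoch`.
#' @export
train <- function(main, aux = NULL, architecture = "stm",
                  config = train_config(), model_cfg = NULL,
                  pretrained = NULL, verbose = FALSE) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  multitask <- architecture != "stm"
  if (multitask && is.null(aux))
    stop("architecture '", architecture, "' requires an auxiliary corpus")
  if (!multitask && !is.null(aux)) {
    warning("stm ignores the auxiliary corpus")
    aux <- NULL
  }
  corpora <- c(list(main), if (multitask) list(aux))
  vocab <- build_vocab(corpora, pretrained_words = names(pretrained))
  if (is.null(model_cfg)) model_cfg <- model_config()
  model_cfg$seed <- config$seed
  model_cfg$dropout <- config$dropout
  model <- build_model(architecture, vocab, model_cfg, pretrained)

  enc_main <- encode_sentences(main$splits$train, vocab, main$name)
  enc_aux <- if (multitask)
    encode_sentences(aux$splits$train, vocab, aux$name)
  set.seed(config$seed)
  opt_state <- new_rmsprop_state()
  history <- data.frame()
  best_f1 <- -Inf; best_epoch <- NA_integer_; best_params <- NULL
  for (e in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(e, config)
    main_batches <- bucket_batches(enc_main, config$batch_size,
                                   seed = config$seed + 31L * e)
    sums <- c(L_task = 0, L_adv = 0, L_diff = 0)
    nsteps <- 0L
    if (multitask) {
      aux_batches <- bucket_batches(enc_aux, config$batch_size,
                                    seed = config$seed + 31L * e + 7L)
      sched <- make_turn_schedule(length(main_batches),
                                  length(aux_batches),
                                  seed = config$seed + 31L * e + 13L)
      for (r in seq_len(nrow(sched))) {
        st <- train_step(model, main_batches[[sched$main[r]]], 1L, config,
                         opt_state, lr)
        model <- st$model
        sums <- sums + unlist(st$breakdown[c("L_task", "L_adv", "L_diff")])
        st <- train_step(model, aux_batches[[sched$aux[r]]], 2L, config,
                         opt_state, lr)
        model <- st$model
        sums <- sums + unlist(st$breakdown[c("L_task", "L_adv", "L_diff")])
        nsteps <- nsteps + 2L
      }
    } else {
      for (bt in main_batches) {
        st <- train_step(model, bt, 1L, config, opt_state, lr)
        model <- st$model
        sums <- sums + unlist(st$breakdown[c("L_task", "L_adv", "L_diff")])
        nsteps <- nsteps + 1L
      }
    }
    dev_f1 <- evaluate_split(model, main$splits$dev, d = 1L)
    history <- rbind(history, data.frame(
      epoch = e, lr = lr, L_task = sums[["L_task"]] / nsteps,
      L_adv = sums[["L_adv"]] / nsteps, L_diff = sums[["L_diff"]] / nsteps,
      dev_f1_main = unname(dev_f1)))
    if (verbose)
      message(sprintf("epoch %d lr %.6f task %.4f dev F1 %.2f", e, lr,
                      sums[["L_task"]] / nsteps, dev_f1))
    if (!is.na(dev_f1) && dev_f1 > best_f1) {
      best_f1 <- dev_f1; best_epoch <- e; best_params <- model$params
    }
  }
  if (config$select == "best_dev" && !is.null(best_params))
    model$params <- best_params
  structure(list(model = model, history = history, config = config,
                 best_epoch = best_epoch, best_dev_f1 = best_f1),
            class = "ner_fit")
}

#' @export
print.ner_fit <- function(x, ...) {
  cat("<ner_fit> ", x$model$arch, " | epochs: ", nrow(x$history),
      " | best dev F1: ", round(x$best_dev_f1, 2),
      " (epoch ", x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' Grid search over the adversarial loss weights
#'
#' Trains one adversarial model per (alpha, beta) combination and returns
#' the pair with the best main-dataset dev macro-F1.  Ties break toward
#' the smaller (alpha, beta) in lexicographic order.  The reference grid
#' is alpha in {0, 0.1, 0.01} and beta in {0, 0.01, 0.001}.
#'
#' @param main,aux corpora as in [train()].
#' @param alphas,betas candidate sets (non-empty).
#' @param config,model_cfg,verbose passed to [train()].
#' @return list with `best` (alpha, beta), `table` (one row per
#'   combination with its dev F1), `fit` (the winning [train()] result).
#' @export
grid_search_adv <- function(main, aux, alphas = c(0, 0.1, 0.01),
                            betas = c(0, 0.01, 0.001),
                            config = train_config(), model_cfg = NULL,
                            verbose = FALSE) {
  if (!length(alphas) || !length(betas)) stop("empty candidate sets")
  grid <- expand.grid(alpha = alphas, beta = betas,
                      KEEP.OUT.ATTRS = FALSE)
  # lexicographic (alpha, beta) order for deterministic tie-breaking
  grid <- grid[order(grid$alpha, grid$beta), , drop = FALSE]
  fits <- vector("list", nrow(grid))
  f1 <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    cfg$alpha <- grid$alpha[r]; cfg$beta <- grid$beta[r]
    fits[[r]] <- train(main, aux, "adv", cfg, model_cfg,
                       verbose = verbose)
    f1[r] <- fits[[r]]$best_dev_f1
  }
  best <- which.max(f1)  # first max = smallest (alpha, beta)
  list(best = list(alpha = grid$alpha[best], beta = grid$beta[best]),
       table = cbind(grid, dev_f1 = f1),
       fit = fits[[best]])
}
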