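#' Fine-tuning configuration
#'
#' Defaults are the standard relation-classification fine-tuning recipe:
#' AdamW with linear warmup over the first tenth of the steps and linear
#' decay to zero, gradient clipping at global norm 1, batch size 16, ten
#' epochs at learning rate 5e-5. All randomness in a run (batch order,
#' dropout) flows from \code{seed}; batch order is reshuffled each epoch
#' from a per-epoch derived seed.
#'
#' @param num_train_epochs number of passes over the training set.
#' @param learning_rate peak AdamW learning rate.
#' @param train_batch_size,eval_batch_size batch sizes.
#' @param warmup_ratio fraction of total steps spent warming up, in [0,1].
#' @param weight_decay decoupled weight-decay coefficient.
#' @param adam_beta1,adam_beta2,adam_epsilon AdamW moment parameters.
#' @param max_grad_norm global gradient-norm clip.
#' @param seed integer run seed.
#' @param selection_metric history column used by \code{\link{select_best}}
#'   (default \code{"macro_f1"} on the evaluation split).
#' @return a list of class \code{train_config}.
#' @export
train_config <- function(num_train_epochs = 10L, learning_rate = 5e-5,
                         train_batch_size = 16L, eval_batch_size = 64L,
                         warmup_ratio = 0.1, weight_decay = 0.01,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_epsilon = 1e-8, max_grad_norm = 1.0,
                         seed = 42L, selection_metric = "macro_f1") {
  stopifnot(learning_rate > 0, train_batch_size > 0, eval_batch_size > 0,
            warmup_ratio >= 0, warmup_ratio <= 1, num_train_epochs >= 0,
            weight_decay >= 0, max_grad_norm > 0)
  structure(as.list(environment()), class = "train_config")
}

#' Linear warmup / linear decay learning-rate schedule
#'
#' The rate is 0 at step 0, climbs linearly to \code{learning_rate} at
#' step \code{floor(warmup_ratio * total_steps)}, then decays linearly to
#' 0 at \code{total_steps}.
#'
#' @param step 0-based optimizer step index (vectorized).
#' @param total_steps total number of optimizer steps in the run.
#' @param learning_rate peak rate.
#' @param warmup_ratio warmup fraction.
#' @return numeric vector of learning rates.
#' @export
lr_schedule <- function(step, total_steps, learning_rate,
                        warmup_ratio = 0.1) {
  warm <- floor(warmup_ratio * total_steps)
  up <- if (warm > 0) step / warm else 1
  down <- if (total_steps > warm) {
    pmax(0, (total_steps - step) / (total_steps - warm))
  } else 0
  learning_rate * ifelse(step < warm, up, down)
}

# one AdamW update over flat parameter/gradient lists; state holds m, v, t
adamw_step <- function(params, grads, state, lr, config) {
  if (is.null(state$t)) {
    state$t <- 0L
    state$m <- lapply(params, function(p) p * 0)
    state$v <- lapply(params, function(p) p * 0)
  }
  state$t <- state$t + 1L
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + config$adam_epsilon) +
              config$weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# clip the global gradient norm in place (environment of arrays)
clip_gradients <- function(gr, max_norm) {
  nms <- ls(gr)
  total <- sqrt(sum(vapply(nms, function(nm) sum(gr[[nm]]^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    for (nm in nms) gr[[nm]] <- gr[[nm]] * sc
  }
  total
}

#' Stratified k-fold splits
#'
#' Indices of each class are shuffled (deterministically from
#' \code{seed}) and dealt to folds so that per-fold class counts differ
#' from exact proportionality by at most one. Classes with fewer
#' instances than \code{k} folds trigger a warning and are assigned
#' best-effort.
#'
#' @param labels character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of \code{k} fold objects: \code{list(k, train, test)} with
#'   integer index vectors; the test sets partition \code{seq_along(labels)}.
#' @export
make_folds <- function(labels, k = 5L, seed = 42L) {
  n <- length(labels)
  if (k > n) stop("more folds than instances", call. = FALSE)
  assign_fold <- integer(n)
  load <- integer(k)  # current test-set size per fold
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        warning("class '", cl, "' has fewer instances (", length(idx),
                ") than folds (", k, "); best-effort assignment",
                call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      ord <- order(load, seq_len(k))  # least-loaded folds first
      f <- rep(ord, length.out = length(idx))
      assign_fold[idx] <- f
      load <- load + tabulate(f, nbins = k)
    }
  })
  lapply(seq_len(k), function(i) {
    list(k = i, train = which(assign_fold != i),
         test = which(assign_fold == i))
  })
}

#' Pick the best epoch from a training history
#'
#' @param history data.frame with one row per epoch, as returned in
#'   \code{\link{train}}'s \code{$history}.
#' @param selection_metric name of the history column to maximize.
#' @return 1-based epoch index of the maximum; ties break to the earlier
#'   epoch.
#' @export
select_best <- function(history, selection_metric = "macro_f1") {
  if (!NROW(history)) stop("empty training history", call. = FALSE)
  if (!selection_metric %in% names(history)) {
    stop("unknown selection metric '", selection_metric, "'", call. = FALSE)
  }
  which.max(history[[selection_metric]])
}

labels_to_class <- function(model, examples) {
  lab <- vapply(examples, function(e) e$label, character(1))
  cls <- match(lab, model$classes)
  if (anyNA(cls)) stop("label outside the model's class set", call. = FALSE)
  cls
}

#' Fine-tune a relation classifier
#'
#' Minimizes mean cross-entropy with AdamW under a linear
#' warmup/decay schedule and global gradient clipping, evaluating on
#' \code{eval_examples} after every epoch. The returned model carries the
#' parameters of the best epoch under \code{config$selection_metric}
#' (ties to the earlier epoch), mirroring best-epoch checkpointing.
#'
#' @param model an \code{\link{classifier_model}}.
#' @param train_examples,eval_examples lists of labelled
#'   \code{encoded_example}s.
#' @param config a \code{\link{train_config}}.
#' @return list of class \code{rex_fit}: \code{model} (best parameters),
#'   \code{history} (data.frame: epoch, train_loss, accuracy,
#'   macro_precision, macro_recall, macro_f1), \code{best_epoch}.
#' @export
train <- function(model, train_examples, eval_examples, config) {
  if (!length(train_examples)) stop("empty training set", call. = FALSE)
  if (config$num_train_epochs == 0L) {
    return(structure(list(model = model,
                          history = data.frame(),
                          best_epoch = NA_integer_),
                     class = "rex_fit"))
  }
  n <- length(train_examples)
  cls <- labels_to_class(model, train_examples)
  bs <- config$train_batch_size
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- steps_per_epoch * config$num_train_epochs
  state <- new.env(parent = emptyenv())
  step <- 0L
  history <- NULL
  best_metric <- -Inf
  best_params <- model$params
  best_epoch <- NA_integer_
  for (epoch in seq_len(config$num_train_epochs)) {
    epoch_seed <- (config$seed + 7919L * epoch) %% 2147483647L
    set.seed(epoch_seed)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b in seq_len(steps_per_epoch)) {
      take <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      fo <- model_forward(model, train_examples[take], train = TRUE)
      loss <- cross_entropy_loss(fo$scores, cls[take])
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", step ", b,
             " (loss = ", loss, "); check learning rate and inputs",
             call. = FALSE)
      }
      losses <- c(losses, loss)
      gr <- model_backward(model, fo, cls[take])
      clip_gradients(gr, config$max_grad_norm)
      lr <- lr_schedule(step, total_steps, config$learning_rate,
                        config$warmup_ratio)
      grl <- mget(ls(gr), envir = gr)
      upd <- adamw_step(model$params, grl[names(model$params)], state,
                        lr, config)
      model$params <- upd$params
      state <- upd$state
      step <- step + 1L
    }
    rep_ <- evaluate_model(model, eval_examples)
    row <- data.frame(epoch = epoch, train_loss = mean(losses),
                      accuracy = rep_$accuracy,
                      macro_precision = rep_$macro_precision,
                      macro_recall = rep_$macro_recall,
                      macro_f1 = rep_$macro_f1)
    history <- rbind(history, row)
    m <- row[[config$selection_metric]]
    if (m > best_metric) {
      best_metric <- m
      best_params <- model$params
      best_epoch <- epoch
    }
  }
  model$params <- best_params
  structure(list(model = model, history = history, best_epoch = best_epoch),
            class = "rex_fit")
}

#' @export
print.rex_fit <- function(x, ...) {
  cat("<rex_fit> best epoch:", x$best_epoch, "\n")
  if (NROW(x$history)) print(x$history, row.names = FALSE)
  invisible(x)
}

#' Evaluate a classifier on encoded examples
#'
#' @param model an \code{rex_classifier}.
#' @param examples labelled \code{encoded_example}s.
#' @return an \code{eval_report} (see \code{\link{aggregate_report}}).
#' @export
evaluate_model <- function(model, examples) {
  truth <- vapply(examples, function(e) e$label, character(1))
  pred <- predict_labels(model, examples)
  aggregate_report(confusion_matrix(truth, pred, classes = model$classes))
}

#' K-fold cross-validation of the full pipeline
#'
#' For each stratified fold: a fresh tokenizer vocabulary is built from
#' the training split only (held-out entity surfaces can therefore be
#' out-of-vocabulary, as at deployment), a fresh seeded encoder and head
#' are initialized, the model is fine-tuned, and the best-epoch model is
#' evaluated on the test fold.
#'
#' @param corpus a corpus data.frame.
#' @param method input-construction method (see
#'   \code{\link{encode_instance}}).
#' @param head_variant classification head (see
#'   \code{\link{head_input_dim}}).
#' @param config a \code{\link{train_config}}.
#' @param k number of folds.
#' @param encoder_opts list of \code{\link{tiny_encoder}} arguments
#'   (\code{hidden_size}, \code{n_layers}, \code{ffn_size},
#'   \code{max_len}).
#' @param max_len encoding length cap.
#' @return list of class \code{rex_cv}: \code{folds} (per-fold
#'   \code{eval_report}s), \code{summary} (data.frame of mean and sample
#'   sd per metric), \code{formatted} (named character,
#'   \code{"m.mmm (s.sss)"} cells).
#' @export
crossval <- function(corpus, method, head_variant, config, k = 5L,
                     encoder_opts = list(hidden_size = 64L, n_layers = 2L),
                     max_len = 128L) {
  viol <- validate_corpus(corpus)
  if (nrow(viol)) {
    stop("corpus has ", nrow(viol), " validation violation(s)",
         call. = FALSE)
  }
  folds <- make_folds(corpus$label, k = k, seed = config$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- corpus[folds[[f]]$train, ]
    te <- corpus[folds[[f]]$test, ]
    tk <- whitespace_tokenizer()
    build_vocab(tk, tr)
    enc <- do.call(tiny_encoder, c(
      list(vocab_size = tk$vocab_size(), seed = config$seed + f,
           max_len = max_len), encoder_opts))
    model <- classifier_model(enc, tk, head_variant,
                              seed = config$seed + f)
    ex_tr <- encode_corpus(tr, method, tk, max_len)
    ex_te <- encode_corpus(te, method, tk, max_len)
    fit <- train(model, ex_tr, ex_te, config)
    reports[[f]] <- evaluate_model(fit$model, ex_te)
  }
  metrics <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) r[[m]], numeric(1)))
  vals <- matrix(vals, nrow = k, dimnames = list(NULL, metrics))
  mean_ <- colMeans(vals)
  sd_ <- if (k > 1) apply(vals, 2, stats::sd) else
    stats::setNames(rep(0, length(metrics)), metrics)
  summary <- data.frame(metric = metrics, mean = mean_, sd = sd_,
                        row.names = NULL)
  formatted <- stats::setNames(
    sprintf("%.3f (%.3f)", mean_, sd_), metrics)
  structure(list(folds = reports, summary = summary, formatted = formatted,
                 k = k, sd_defined = k > 1),
            class = "rex_cv")
}

#' @export
print.rex_cv <- function(x, ...) {
  cat("Cross-validation over", x$k, "folds (mean (sd)):\n")
  for (m in names(x$formatted)) {
    cat(sprintf("  %-16s %s\n", m, x$formatted[[m]]))
  }
  if (!x$sd_defined) cat("  (single fold: sd undefined, reported as 0)\n")
  invisible(x)
}
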