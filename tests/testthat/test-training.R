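test_that("the learning-rate schedule is piecewise linear: warmup then decay", {
  total <- 200; lr <- 5e-5; ratio <- 0.1
  steps <- 0:total
  rates <- lr_schedule(steps, total, lr, ratio)
  warm <- floor(ratio * total)
  expect_identical(rates[1], 0)                      # step 0
  expect_equal(rates[warm + 1], lr)                  # peak exactly at warmup
  expect_equal(rates[total + 1], 0)                  # zero at the last step
  expect_true(all(rates <= lr + 1e-15))
  # linear on each side: second differences vanish
  expect_true(all(abs(diff(diff(rates[1:(warm + 1)]))) < 1e-18))
  expect_true(all(abs(diff(diff(rates[(warm + 1):(total + 1)]))) < 1e-18))
  expect_true(all(diff(rates[1:(warm + 1)]) > 0))
  expect_true(all(diff(rates[(warm + 1):(total + 1)]) < 0))
})

test_that("the first AdamW step moves a zero weight by -lr in the gradient sign", {
  cfg <- train_config(learning_rate = 0.01)
  params <- list(w = 0)
  grads <- list(w = 3.7)  # any positive gradient
  state <- new.env(parent = emptyenv())
  upd <- relexr:::adamw_step(params, grads, state, cfg$learning_rate, cfg)
  # first-step Adam direction is sign(g); weight decay vanishes at w = 0
  expect_equal(upd$params$w, -cfg$learning_rate, tolerance = 1e-6)
  # and a negative gradient moves it the other way
  upd2 <- relexr:::adamw_step(list(w = 0), list(w = -0.2),
                              new.env(parent = emptyenv()),
                              cfg$learning_rate, cfg)
  expect_equal(upd2$params$w, cfg$learning_rate, tolerance = 1e-6)
})

test_that("training for zero epochs returns the initial parameters", {
  syn <- small_synthetic(12, seed = 3)$corpus
  pl <- tiny_pipeline(syn)
  fit <- train(pl$model, pl$examples, pl$examples,
               train_config(num_train_epochs = 0))
  expect_identical(fit$model$params, pl$model$params)
  expect_identical(NROW(fit$history), 0L)
  expect_true(is.na(fit$best_epoch))
  expect_error(train(pl$model, list(), pl$examples, train_config()),
               "empty training set")
})

test_that("a training run is fully reproducible from its seed", {
  syn <- small_synthetic(30, seed = 8)$corpus
  cfg <- train_config(num_train_epochs = 2, learning_rate = 1e-3,
                      seed = 5)
  run <- function() {
    pl <- tiny_pipeline(syn, method = "masked", hidden = 16, layers = 1,
                        seed = 5)
    fit <- train(pl$model, pl$examples, pl$examples, cfg)
    classify(fit$model, pl$examples)
  }
  expect_identical(run(), run())
})

test_that("stratified folds partition the data with near-proportional classes", {
  # 10 items, k = 5 -> five test sets of size 2
  folds <- make_folds(rep(c("a", "b"), 5), k = 5, seed = 1)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:10)
  expect_true(all(lengths(tests) == 2))
  # balanced 50/50 labels, k = 2 -> each fold 50/50 (+/- 1)
  labs <- rep(c("x", "y"), each = 50)
  folds <- make_folds(labs, k = 2, seed = 3)
  for (f in folds) {
    expect_lte(abs(sum(labs[f$test] == "x") - 25), 1)
    expect_identical(sort(c(f$train, f$test)), seq_along(labs))
  }
  # per-fold class counts within 1 of proportional on a skewed corpus
  syn <- small_synthetic(200, seed = 41)$corpus
  folds <- suppressWarnings(make_folds(syn$label, k = 5, seed = 2))
  for (cl in unique(syn$label)) {
    per <- vapply(folds, function(f) sum(syn$label[f$test] == cl),
                  numeric(1))
    expect_lte(max(per) - min(per), 1)
  }
  # determinism and the small-class warning
  expect_identical(make_folds(syn$label, k = 2, seed = 9),
                   make_folds(syn$label, k = 2, seed = 9))
  expect_warning(make_folds(c("a", "a", "b"), k = 2, seed = 1),
                 "fewer instances")
  expect_error(make_folds(c("a", "b"), k = 3), "more folds")
})

test_that("best-epoch selection takes the argmax with ties to the earlier epoch", {
  h <- data.frame(macro_f1 = c(0.5, 0.9, 0.7))
  expect_identical(select_best(h), 2L)
  expect_identical(select_best(data.frame(macro_f1 = c(0.9, 0.9))), 1L)
  expect_error(select_best(data.frame()), "empty")
  expect_error(select_best(h, "auc"), "unknown selection metric")
})

test_that("cross-validation summarises folds as mean (sample sd)", {
  syn <- small_synthetic(60, seed = 19)$corpus
  cfg <- train_config(num_train_epochs = 1, learning_rate = 1e-3, seed = 4)
  cv <- suppressWarnings(crossval(
    syn, "masked", "two_token", cfg, k = 2,
    encoder_opts = list(hidden_size = 16, n_layers = 1), max_len = 64))
  expect_length(cv$folds, 2)
  accs <- vapply(cv$folds, `[[`, numeric(1), "accuracy")
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(accs))
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"],
               sd(accs))  # n - 1 denominator
  expect_match(cv$formatted[["accuracy"]],
               "^[0-9]\\.[0-9]{3} \\([0-9]\\.[0-9]{3}\\)$")
  # hand arithmetic for the reporting convention
  expect_equal(sd(c(0.8, 0.9)), 0.0707, tolerance = 1e-3)
  expect_equal(sd(c(0.85, 0.85)), 0)
})
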