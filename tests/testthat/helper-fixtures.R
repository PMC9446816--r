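# shared fixture builders; everything is generated in code

# the spec-level worked sentence used across encoding tests
worked_instance <- function() {
  relation_instance("doc1", 0, "A activates B C",
                    "A", 0, 1, "gene",
                    "B C", 12, 15, "protein",
                    "positive_cause")
}

small_synthetic <- function(n = 50, seed = 7, ...) {
  generate_corpus(generator_config(n_instances = n, seed = seed, ...))
}

# a tiny trained-from-scratch pipeline for mechanism tests
tiny_pipeline <- function(corpus, method = "masked",
                          head = "two_token", hidden = 16, layers = 1,
                          seed = 1) {
  tk <- whitespace_tokenizer()
  build_vocab(tk, corpus)
  enc <- tiny_encoder(tk$vocab_size(), hidden_size = hidden,
                      n_layers = layers, max_len = 64, seed = seed)
  model <- classifier_model(enc, tk, head, seed = seed)
  list(tk = tk, model = model,
       examples = encode_corpus(corpus, method, tk, 64))
}

# brute-force metric oracle: direct counting over (truth, pred) pairs
oracle_prf <- function(truth, pred, classes) {
  res <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f, support = sum(truth == cl))
  })
  do.call(rbind, res)
}
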