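# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

rnorm_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Input dimension of a classification head
#'
#' The head is a single affine layer over gathered encoder vectors: the
#' \code{[CLS]} vector alone (\code{cls_token}), the two
#' entity-representative vectors (\code{two_token}), or all three
#' (\code{three_token}); its input width is therefore \code{H}, \code{2H}
#' or \code{3H} for encoder hidden size \code{H}.
#'
#' @param variant \code{"cls_token"}, \code{"two_token"} or
#'   \code{"three_token"}.
#' @param hidden_size encoder hidden size H.
#' @return integer input dimension.
#' @examples
#' head_input_dim("two_token", 512)  # 1024
#' @export
head_input_dim <- function(variant, hidden_size) {
  variant <- match.arg(variant, c("cls_token", "two_token", "three_token"))
  stopifnot(hidden_size > 0)
  as.integer(hidden_size * switch(variant, cls_token = 1L,
                                  two_token = 2L, three_token = 3L))
}

#' Gather the head input vector from per-token encoder output
#'
#' Concatenation order is fixed: \code{[CLS]}, then entity 1, then entity
#' 2.
#'
#' @param hidden numeric matrix, one row per token (L x H).
#' @param example an \code{encoded_example} (supplies \code{cls_index},
#'   \code{e1_index}, \code{e2_index}).
#' @param variant head variant, see \code{\link{head_input_dim}}.
#' @return numeric vector of length \code{head_input_dim(variant, H)}.
#' @export
gather_features <- function(hidden, example, variant) {
  variant <- match.arg(variant, c("cls_token", "two_token", "three_token"))
  idx <- switch(variant,
    cls_token = example$cls_index,
    two_token = c(example$e1_index, example$e2_index),
    three_token = c(example$cls_index, example$e1_index, example$e2_index))
  if (any(idx < 1L | idx > nrow(hidden))) {
    stop("representative token index out of range", call. = FALSE)
  }
  as.numeric(t(hidden[idx, , drop = FALSE]))
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Mean cross-entropy loss over per-class scores
#'
#' @param scores numeric matrix (n x n_classes) of unnormalized scores, or
#'   a vector for a single example.
#' @param true_class integer vector of 1-based true class indices.
#' @return mean of \code{-log softmax(score)[true_class]}; non-negative.
#' @examples
#' cross_entropy_loss(rep(0, 8), 1)  # log(8)
#' @export
cross_entropy_loss <- function(scores, true_class) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(length(true_class) == nrow(scores))
  if (any(true_class < 1L | true_class > ncol(scores))) {
    stop("true class index outside the schema", call. = FALSE)
  }
  p <- softmax_rows(scores)
  -mean(log(p[cbind(seq_len(nrow(p)), true_class)]))
}

#' A tiny seeded transformer encoder
#'
#' A from-scratch, deterministic token encoder for desk-scale experiments:
#' token + position + segment embeddings followed by \code{n_layers}
#' pre-activation residual blocks, each a single-head scaled dot-product
#' self-attention sublayer and a ReLU feed-forward sublayer. No layer
#' normalisation is used; initialisation is N(0, 0.02^2) throughout, which
#' keeps the residual stream well-scaled at this depth. The same contract
#' (per-token vectors of width \code{hidden_size}) is what an adapter over
#' a pretrained transformer checkpoint would provide.
#'
#' @param vocab_size number of token ids the embedding table covers.
#' @param hidden_size H, the per-token vector width.
#' @param n_layers number of residual blocks.
#' @param ffn_size feed-forward inner width (default \code{2 * H}).
#' @param max_len maximum sequence length (position table size).
#' @param seed integer; parameter initialisation is fully determined by it.
#' @return an object of class \code{rex_encoder} with the architecture
#'   fields and a \code{params} list of weight matrices.
#' @export
tiny_encoder <- function(vocab_size, hidden_size = 64L, n_layers = 2L,
                         ffn_size = 2L * hidden_size, max_len = 128L,
                         seed = 1L) {
  H <- as.integer(hidden_size)
  params <- with_seed(seed, {
    p <- list(
      emb = rnorm_mat(vocab_size, H),
      pos = rnorm_mat(max_len, H),
      seg = rnorm_mat(2L, H)
    )
    for (l in seq_len(n_layers)) {
      p[[paste0("L", l, ".Wq")]] <- rnorm_mat(H, H)
      p[[paste0("L", l, ".Wk")]] <- rnorm_mat(H, H)
      p[[paste0("L", l, ".Wv")]] <- rnorm_mat(H, H)
      p[[paste0("L", l, ".Wo")]] <- rnorm_mat(H, H)
      p[[paste0("L", l, ".W1")]] <- rnorm_mat(H, ffn_size)
      p[[paste0("L", l, ".b1")]] <- rep(0, ffn_size)
      p[[paste0("L", l, ".W2")]] <- rnorm_mat(ffn_size, H)
      p[[paste0("L", l, ".b2")]] <- rep(0, H)
    }
    p
  })
  structure(
    list(vocab_size = as.integer(vocab_size), hidden_size = H,
         n_layers = as.integer(n_layers), ffn_size = as.integer(ffn_size),
         max_len = as.integer(max_len), seed = as.integer(seed),
         params = params),
    class = "rex_encoder"
  )
}

# forward pass for one sequence; returns final hidden states and, when
# cache = TRUE, the intermediates needed for backprop
encoder_forward <- function(enc, params, ids, seg, cache = FALSE) {
  L <- length(ids)
  if (L > enc$max_len) stop("sequence longer than encoder max_len", call. = FALSE)
  if (any(ids < 1L | ids > nrow(params$emb))) {
    stop("token id outside the encoder's embedding table; build the ",
         "tokenizer vocabulary before constructing the encoder",
         call. = FALSE)
  }
  H <- enc$hidden_size
  X <- params$emb[ids, , drop = FALSE] +
    params$pos[seq_len(L), , drop = FALSE] +
    params$seg[seg + 1L, , drop = FALSE]
  caches <- if (cache) vector("list", enc$n_layers) else NULL
  for (l in seq_len(enc$n_layers)) {
    nm <- function(s) params[[paste0("L", l, ".", s)]]
    Q <- X %*% nm("Wq"); K <- X %*% nm("Wk"); V <- X %*% nm("Wv")
    S <- tcrossprod(Q, K) / sqrt(H)
    A <- softmax_rows(S)
    Cm <- A %*% V
    X1 <- X + Cm %*% nm("Wo")
    H1 <- X1 %*% nm("W1")
    H1 <- H1 + matrix(nm("b1"), nrow(H1), length(nm("b1")), byrow = TRUE)
    Hr <- pmax(H1, 0)
    F2 <- Hr %*% nm("W2")
    F2 <- F2 + matrix(nm("b2"), nrow(F2), length(nm("b2")), byrow = TRUE)
    Xout <- X1 + F2
    if (cache) caches[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A,
                                   Cm = Cm, X1 = X1, H1 = H1, Hr = Hr)
    X <- Xout
  }
  list(hidden = X, caches = caches, ids = ids, seg = seg)
}

# backprop through the encoder for one sequence; dX is the gradient
# w.r.t. the final hidden states. Accumulates into the flat gradient
# environment `gr` (matrices keyed like params).
encoder_backward <- function(enc, params, fwd, dX, gr) {
  H <- enc$hidden_size
  for (l in rev(seq_len(enc$n_layers))) {
    nm <- function(s) params[[paste0("L", l, ".", s)]]
    key <- function(s) paste0("L", l, ".", s)
    cc <- fwd$caches[[l]]
    # FFN sublayer
    dF2 <- dX
    dX1 <- dX
    gr[[key("W2")]] <- gr[[key("W2")]] + crossprod(cc$Hr, dF2)
    gr[[key("b2")]] <- gr[[key("b2")]] + colSums(dF2)
    dHr <- tcrossprod(dF2, nm("W2"))
    dH1 <- dHr * (cc$H1 > 0)
    gr[[key("W1")]] <- gr[[key("W1")]] + crossprod(cc$X1, dH1)
    gr[[key("b1")]] <- gr[[key("b1")]] + colSums(dH1)
    dX1 <- dX1 + tcrossprod(dH1, nm("W1"))
    # attention sublayer
    dXin <- dX1
    dattn <- dX1
    gr[[key("Wo")]] <- gr[[key("Wo")]] + crossprod(cc$Cm, dattn)
    dCm <- tcrossprod(dattn, nm("Wo"))
    dA <- tcrossprod(dCm, cc$V)
    dV <- crossprod(cc$A, dCm)
    dS <- cc$A * (dA - rowSums(cc$A * dA))
    dQ <- (dS %*% cc$K) / sqrt(H)
    dK <- (crossprod(dS, cc$Q)) / sqrt(H)
    dXin <- dXin + tcrossprod(dQ, nm("Wq")) + tcrossprod(dK, nm("Wk")) +
      tcrossprod(dV, nm("Wv"))
    gr[[key("Wq")]] <- gr[[key("Wq")]] + crossprod(cc$X, dQ)
    gr[[key("Wk")]] <- gr[[key("Wk")]] + crossprod(cc$X, dK)
    gr[[key("Wv")]] <- gr[[key("Wv")]] + crossprod(cc$X, dV)
    dX <- dXin
  }
  # embeddings (aggregate repeated ids before scattering)
  L <- length(fwd$ids)
  agg <- rowsum(dX, group = fwd$ids)
  uid <- as.integer(rownames(agg))
  gr$emb[uid, ] <- gr$emb[uid, , drop = FALSE] + agg
  aggs <- rowsum(dX, group = fwd$seg)
  us <- as.integer(rownames(aggs)) + 1L
  gr$seg[us, ] <- gr$seg[us, , drop = FALSE] + aggs
  gr$pos[seq_len(L), ] <- gr$pos[seq_len(L), , drop = FALSE] + dX
  invisible(gr)
}

#' Build a relation classifier: encoder + classification head
#'
#' Couples a token-level encoder with one of three affine classification
#' heads (see \code{\link{head_input_dim}}) over an 8-class (by default)
#' output with optional dropout on the gathered features.
#'
#' @param encoder an \code{\link{tiny_encoder}} (or any object with the
#'   same contract and \code{params}).
#' @param tokenizer the tokenizer whose vocabulary the encoder was built
#'   over.
#' @param head_variant \code{"cls_token"}, \code{"two_token"} or
#'   \code{"three_token"}.
#' @param n_classes number of output classes (8 relation types).
#' @param classes character vector of class names in output order;
#'   defaults to the schema's relation labels.
#' @param dropout_rate dropout probability on the gathered feature vector
#'   during training.
#' @param seed seed for head initialisation.
#' @return an object of class \code{rex_classifier}.
#' @export
classifier_model <- function(encoder, tokenizer,
                             head_variant = c("two_token", "cls_token",
                                              "three_token"),
                             n_classes = 8L,
                             classes = relation_schema()$relation_labels,
                             dropout_rate = 0.1, seed = 1L) {
  head_variant <- match.arg(head_variant)
  stopifnot(length(classes) == n_classes)
  D <- head_input_dim(head_variant, encoder$hidden_size)
  head <- with_seed(seed + 1L, list(
    W = rnorm_mat(D, n_classes),
    b = rep(0, n_classes)
  ))
  params <- encoder$params
  params$head.W <- head$W
  params$head.b <- head$b
  structure(
    list(encoder = encoder, tokenizer = tokenizer,
         head_variant = head_variant, n_classes = as.integer(n_classes),
         classes = classes, dropout_rate = dropout_rate,
         params = params),
    class = "rex_classifier"
  )
}

#' @export
print.rex_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<rex_classifier> ", x$head_variant, " head, H = ",
      x$encoder$hidden_size, ", ", x$encoder$n_layers, " layers, ",
      x$n_classes, " classes, ", format(np, big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

example_ids <- function(model, ex) {
  list(ids = model$tokenizer$to_ids(ex$tokens), seg = ex$segment_ids)
}

# forward over a batch; returns scores and (if train) the per-example
# state needed for backprop
model_forward <- function(model, examples, train = FALSE) {
  n <- length(examples)
  D <- head_input_dim(model$head_variant, model$encoder$hidden_size)
  Fm <- matrix(0, n, D)
  fwds <- if (train) vector("list", n) else NULL
  masks <- if (train) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ex <- examples[[i]]
    io <- example_ids(model, ex)
    fw <- encoder_forward(model$encoder, model$params, io$ids, io$seg,
                          cache = train)
    f <- gather_features(fw$hidden, ex, model$head_variant)
    if (train && model$dropout_rate > 0) {
      keep <- stats::runif(D) >= model$dropout_rate
      f <- f * keep / (1 - model$dropout_rate)
      masks[[i]] <- keep
    }
    Fm[i, ] <- f
    if (train) fwds[[i]] <- fw
  }
  scores <- Fm %*% model$params$head.W +
    matrix(model$params$head.b, n, model$n_classes, byrow = TRUE)
  colnames(scores) <- model$classes
  list(scores = scores, F = Fm, fwds = fwds, masks = masks,
       examples = examples)
}

#' Score and predict relation labels
#'
#' @param model an \code{rex_classifier}.
#' @param examples list of \code{encoded_example}s.
#' @return \code{classify}: numeric score matrix (examples x classes);
#'   \code{predict_labels}: character vector of predicted labels (argmax,
#'   ties to the earlier class).
#' @export
classify <- function(model, examples) {
  model_forward(model, examples, train = FALSE)$scores
}

#' @rdname classify
#' @export
predict_labels <- function(model, examples) {
  sc <- classify(model, examples)
  model$classes[apply(sc, 1, which.max)]
}

# gradient of the mean cross-entropy over a forward pass; returns the
# flat gradient environment
model_backward <- function(model, fwd_out, true_class) {
  n <- nrow(fwd_out$scores)
  P <- softmax_rows(fwd_out$scores)
  Y <- matrix(0, n, model$n_classes)
  Y[cbind(seq_len(n), true_class)] <- 1
  dZ <- (P - Y) / n
  gr <- new.env(parent = emptyenv())
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    gr[[nm]] <- if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else
      rep(0, length(p))
  }
  gr$head.W <- crossprod(fwd_out$F, dZ)
  gr$head.b <- colSums(dZ)
  dF <- tcrossprod(dZ, model$params$head.W)
  H <- model$encoder$hidden_size
  for (i in seq_len(n)) {
    ex <- fwd_out$examples[[i]]
    df <- dF[i, ]
    if (!is.null(fwd_out$masks) && !is.null(fwd_out$masks[[i]])) {
      df <- df * fwd_out$masks[[i]] / (1 - model$dropout_rate)
    }
    fw <- fwd_out$fwds[[i]]
    dX <- matrix(0, nrow(fw$hidden), H)
    idx <- switch(model$head_variant,
      cls_token = ex$cls_index,
      two_token = c(ex$e1_index, ex$e2_index),
      three_token = c(ex$cls_index, ex$e1_index, ex$e2_index))
    for (j in seq_along(idx)) {
      dX[idx[j], ] <- dX[idx[j], ] + df[((j - 1) * H + 1):(j * H)]
    }
    encoder_backward(model$encoder, model$params, fw, dX, gr)
  }
  gr
}
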