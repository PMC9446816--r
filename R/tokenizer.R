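#' A whitespace tokenizer satisfying the tokenizer contract
#'
#' The package's encoding and model layers are written against a small
#' tokenizer contract: a \code{tokenize} function returning tokens with
#' 0-based half-open character offsets, the special tokens \code{[CLS]},
#' \code{[SEP]}, \code{[MASK]} and \code{[UNK]}, a vocabulary with
#' \code{register_tokens}/\code{to_ids}, and pre-registered entity marker
#' tokens \code{[E1]}, \code{[/E1]}, \code{[E2]}, \code{[/E2]}. Any
#' tokenizer honouring this contract (e.g. an adapter over a wordpiece
#' vocabulary) can be dropped in; this constructor builds the
#' whitespace-splitting reference implementation used for synthetic
#' corpora and tests.
#'
#' Tokens unseen by \code{register_tokens} map to the \code{[UNK]} id, so
#' out-of-vocabulary entity surfaces are representable without growing the
#' vocabulary at prediction time.
#'
#' @return an object of class \code{rex_tokenizer}: a list with elements
#'   \code{tokenize(text)} (data.frame \code{token}, \code{start},
#'   \code{end}), \code{cls_token}, \code{sep_token}, \code{mask_token},
#'   \code{unk_token}, \code{marker_tokens},
#'   \code{register_tokens(tokens)}, \code{to_ids(tokens)},
#'   \code{vocab_size()} and \code{vocab()} (named id vector).
#' @examples
#' tk <- whitespace_tokenizer()
#' tk$tokenize("A activates B")
#' @export
whitespace_tokenizer <- function() {
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]",
                "[E1]", "[/E1]", "[E2]", "[/E2]")
  vocab <- new.env(parent = emptyenv())
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  register <- function(tokens) {
    for (t in tokens) {
      if (is.null(vocab[[t]])) {
        counter$n <- counter$n + 1L
        vocab[[t]] <- counter$n
      }
    }
    invisible(NULL)
  }
  register(specials)
  tok <- list(
    tokenize = function(text) {
      m <- gregexpr("\\S+", text)[[1]]
      if (m[1] == -1L) {
        return(data.frame(token = character(0), start = integer(0),
                          end = integer(0)))
      }
      st <- as.integer(m) - 1L  # to 0-based
      len <- attr(m, "match.length")
      data.frame(token = substring(text, m, m + len - 1L),
                 start = st, end = st + len, stringsAsFactors = FALSE)
    },
    cls_token = "[CLS]", sep_token = "[SEP]", mask_token = "[MASK]",
    unk_token = "[UNK]", pad_token = "[PAD]",
    marker_tokens = c("[E1]", "[/E1]", "[E2]", "[/E2]"),
    register_tokens = register,
    to_ids = function(tokens) {
      vapply(tokens, function(t) {
        id <- vocab[[t]]
        if (is.null(id)) vocab[["[UNK]"]] else id
      }, integer(1), USE.NAMES = FALSE)
    },
    vocab_size = function() counter$n,
    vocab = function() {
      nm <- ls(vocab)
      ids <- vapply(nm, function(t) vocab[[t]], integer(1))
      sort(ids)
    }
  )
  class(tok) <- "rex_tokenizer"
  tok
}

#' Register every token of a corpus in a tokenizer's vocabulary
#'
#' @param tokenizer an \code{rex_tokenizer}.
#' @param corpus a corpus data.frame (see \link{relation-corpus}).
#' @return the tokenizer, invisibly (its vocabulary is mutated in place).
#' @export
build_vocab <- function(tokenizer, corpus) {
  for (s in unique(corpus$sentence)) {
    tokenizer$register_tokens(tokenizer$tokenize(s)$token)
  }
  invisible(tokenizer)
}
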