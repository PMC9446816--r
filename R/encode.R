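#' Map a character span to the covering token range
#'
#' Finds the smallest contiguous run of tokens covering every character of
#' a 0-based half-open span; a span that partially overlaps a token expands
#' to include the whole token.
#'
#' @param tokens data.frame with columns \code{token}, \code{start},
#'   \code{end} (0-based half-open offsets), as returned by a tokenizer.
#' @param start,end the character span.
#' @return integer vector \code{c(first, last)}: 1-based inclusive token
#'   indices of the covering range.
#' @export
align_spans_to_tokens <- function(tokens, start, end) {
  hit <- which(tokens$end > start & tokens$start < end)
  if (!length(hit)) {
    stop("span [", start, ", ", end, ") covers zero tokens", call. = FALSE)
  }
  c(min(hit), max(hit))
}

ENCODING_METHODS <- c("default", "entity_marker", "masked",
                      "two_masked_sentence", "two_sentence_entity_token")

# Render one sentence copy with the two entity token ranges transformed.
# op_e1/op_e2: "keep", "mask" (replace whole range by one replacement
# token) or "wrap" (surround range with start/end markers). Returns the
# token vector plus the 1-based position, within the copy, of each
# entity's representative token (range start for "keep", the replacement
# token for "mask", the opening marker for "wrap").
render_copy <- function(toks, r1, r2, op_e1, op_e2,
                        repl_e1 = NULL, repl_e2 = NULL,
                        wrap_e1 = NULL, wrap_e2 = NULL) {
  n <- length(toks)
  ranges <- list(e1 = r1, e2 = r2)
  ops <- list(e1 = op_e1, e2 = op_e2)
  repl <- list(e1 = repl_e1, e2 = repl_e2)
  wrap <- list(e1 = wrap_e1, e2 = wrap_e2)
  out <- character(0)
  rep_pos <- c(e1 = NA_integer_, e2 = NA_integer_)
  i <- 1L
  while (i <= n) {
    ent <- NULL
    for (e in c("e1", "e2")) if (i == ranges[[e]][1]) ent <- e
    if (is.null(ent)) {
      out <- c(out, toks[i])
      i <- i + 1L
      next
    }
    r <- ranges[[ent]]
    if (ops[[ent]] == "keep") {
      rep_pos[[ent]] <- length(out) + 1L
      out <- c(out, toks[r[1]:r[2]])
    } else if (ops[[ent]] == "mask") {
      rep_pos[[ent]] <- length(out) + 1L
      out <- c(out, repl[[ent]])
    } else {  # wrap
      rep_pos[[ent]] <- length(out) + 1L
      out <- c(out, wrap[[ent]][1], toks[r[1]:r[2]], wrap[[ent]][2])
    }
    i <- r[2] + 1L
  }
  list(tokens = out, e1 = rep_pos[["e1"]], e2 = rep_pos[["e2"]])
}

#' Encode a relation instance under one of five input-construction methods
#'
#' Converts a sentence with two typed entity mentions into the token
#' sequence fed to an encoder, recording the positions of the two
#' entity-representative tokens. Entity roles follow annotation order
#' (entity 1 = subject), not textual order. A multi-token entity is always
#' replaced by a \emph{single} \code{[MASK]}/\code{[E1]}/\code{[E2]} token
#' so that each entity has exactly one representative position.
#'
#' The methods (\code{S} = sentence tokens, \code{e1}/\code{e2} = entity
#' token ranges):
#' \describe{
#'   \item{default}{\code{[CLS] S [SEP]}; representatives are each
#'     entity's first token.}
#'   \item{entity_marker}{\code{[CLS]} S with \code{[E1]...[/E1]} wrapped
#'     around e1 and \code{[E2]...[/E2]} around e2 \code{[SEP]};
#'     representatives are the opening markers (entity-start convention).}
#'   \item{masked}{\code{[CLS]} S with each entity replaced by one
#'     \code{[MASK]} \code{[SEP]}; representatives are the two masks.}
#'   \item{two_masked_sentence}{the sentence twice across a \code{[SEP]}:
#'     e1 masked in the first copy, e2 masked in the second, each mask
#'     being that copy's representative; the other entity stays verbatim.
#'     Segment ids are 0 up to and including the first \code{[SEP]}, 1
#'     after.}
#'   \item{two_sentence_entity_token}{the same two-copy layout with the
#'     replacement tokens \code{[E1]} (first copy) and \code{[E2]}
#'     (second).}
#' }
#'
#' @param instance a one-row corpus data.frame (validated; entities must
#'   not overlap).
#' @param method one of \code{"default"}, \code{"entity_marker"},
#'   \code{"masked"}, \code{"two_masked_sentence"},
#'   \code{"two_sentence_entity_token"}.
#' @param tokenizer an \code{\link{whitespace_tokenizer}}-contract object.
#' @param max_len maximum token length. Overlong encodings are truncated
#'   from the sentence tail (just before the final \code{[SEP]}); if a
#'   representative token or a structural \code{[SEP]} would be cut, an
#'   error is raised rather than degrading silently.
#' @return an object of class \code{encoded_example}: list with
#'   \code{tokens}, \code{segment_ids} (0/1), \code{e1_index},
#'   \code{e2_index}, \code{cls_index} (always 1), \code{method},
#'   \code{label} (1-based token indices).
#' @export
encode_instance <- function(instance, method, tokenizer,
                            max_len = 256L) {
  method <- match.arg(method, ENCODING_METHODS)
  x <- as.list(instance)
  viol <- validate_instance(instance)
  if (length(viol)) {
    stop("invalid instance: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  td <- tokenizer$tokenize(x$sentence)
  r1 <- align_spans_to_tokens(td, x$e1_start, x$e1_end)
  r2 <- align_spans_to_tokens(td, x$e2_start, x$e2_end)
  if (r1[1] <= r2[2] && r2[1] <= r1[2]) {
    stop("entity token ranges overlap after covering expansion",
         call. = FALSE)
  }
  toks <- td$token
  CLS <- tokenizer$cls_token; SEP <- tokenizer$sep_token
  MASK <- tokenizer$mask_token
  two_sentence <- method %in% c("two_masked_sentence",
                                "two_sentence_entity_token")
  if (!two_sentence) {
    cp <- switch(method,
      default = render_copy(toks, r1, r2, "keep", "keep"),
      entity_marker = render_copy(toks, r1, r2, "wrap", "wrap",
                                  wrap_e1 = c("[E1]", "[/E1]"),
                                  wrap_e2 = c("[E2]", "[/E2]")),
      masked = render_copy(toks, r1, r2, "mask", "mask",
                           repl_e1 = MASK, repl_e2 = MASK))
    tokens <- c(CLS, cp$tokens, SEP)
    seg <- rep(0L, length(tokens))
    e1_index <- cp$e1 + 1L
    e2_index <- cp$e2 + 1L
  } else {
    repl <- if (method == "two_masked_sentence") c(MASK, MASK) else
      c("[E1]", "[E2]")
    cp1 <- render_copy(toks, r1, r2, "mask", "keep", repl_e1 = repl[1])
    cp2 <- render_copy(toks, r1, r2, "keep", "mask", repl_e2 = repl[2])
    tokens <- c(CLS, cp1$tokens, SEP, cp2$tokens, SEP)
    n1 <- 1L + length(cp1$tokens) + 1L
    seg <- c(rep(0L, n1), rep(1L, length(cp2$tokens) + 1L))
    e1_index <- cp1$e1 + 1L
    e2_index <- cp2$e2 + n1
  }
  # truncate from the tail, keeping the final [SEP]
  while (length(tokens) > max_len) {
    drop <- length(tokens) - 1L
    if (drop %in% c(e1_index, e2_index) || tokens[drop] == SEP ||
        drop <= 1L) {
      stop("encoding exceeds max_len = ", max_len,
           " and truncation would cut a representative or structural token",
           call. = FALSE)
    }
    tokens <- tokens[-drop]
    seg <- seg[-drop]
  }
  structure(
    list(tokens = tokens, segment_ids = seg,
         e1_index = e1_index, e2_index = e2_index, cls_index = 1L,
         method = method, label = normalize_label(x$label)),
    class = "encoded_example"
  )
}

#' @export
print.encoded_example <- function(x, ...) {
  cat("<encoded_example> method =", x$method, "\n")
  disp <- x$tokens
  disp[x$e1_index] <- paste0(disp[x$e1_index], "*e1")
  disp[x$e2_index] <- paste0(disp[x$e2_index], "*e2")
  cat(" ", paste(disp, collapse = " "), "\n")
  cat("  segments:", paste(x$segment_ids, collapse = ""), "\n")
  invisible(x)
}

#' Encode every row of a corpus
#'
#' @inheritParams encode_instance
#' @param corpus a corpus data.frame.
#' @return list of \code{encoded_example} objects.
#' @export
encode_corpus <- function(corpus, method, tokenizer, max_len = 256L) {
  lapply(seq_len(nrow(corpus)), function(i) {
    encode_instance(corpus[i, ], method, tokenizer, max_len)
  })
}
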