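#' Lexicons of the synthetic cue grammar
#'
#' Small, versioned lexicons so generated corpora are stable across
#' releases: relational verbs grouped by causal polarity
#' (positive-causal, negative-causal, causal with unspecified direction,
#' neutral-associative), polarity-flipping negation modifiers
#' ("knockdown of" ...), and quantity phrases that select the third
#' hierarchy level.
#'
#' @return named list of character vectors.
#' @export
relation_lexicons <- function() {
  list(
    verbs_positive = c("activates", "induces", "upregulates", "stimulates"),
    verbs_negative = c("inhibits", "suppresses", "downregulates"),
    verbs_unspecified = c("regulates", "modulates"),
    verbs_neutral = c("binds", "interacts with", "correlates with"),
    modifiers = c("knockdown of", "inhibition of", "silencing of",
                  "loss of"),
    quantity_increase = c("an increase in", "elevated levels of"),
    quantity_decrease = c("a decrease in", "reduced levels of"),
    tails_plain = c("in tumor cells", "in mouse models"),
    tails_quantity_flavored = c("in a dose dependent manner"),
    entity_suffixes = c("expression", "levels")
  )
}

table5_class_weights <- function() {
  counts <- c(undirected_link = 1396, directed_link = 833,
              positive_cause = 1087, negative_cause = 700,
              positive_increase = 273, negative_decrease = 364,
              positive_decrease = 133, negative_increase = 245)
  counts[relation_schema()$relation_labels] / sum(counts)
}

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the real eight-class imbalance: \code{class_weights}
#' are proportional to the annotated corpus's per-label totals
#' (undirected_link 1396/5031 and so on). \code{negation_rate} is the
#' probability that a causal instance carries a polarity-flipping
#' modifier; \code{quantity_rate} the probability that an instance whose
#' label does not require a quantity phrase still gets a
#' quantity-flavoured distractor tail (so mere presence of quantity
#' wording cannot identify third-level labels);
#' \code{oov_fraction_heldout} the probability that an instance draws its
#' entity surfaces from a surface pool disjoint from the in-vocabulary
#' pool (for out-of-vocabulary robustness experiments).
#'
#' @param n_instances number of relation instances to generate.
#' @param class_weights named probabilities over the 8 relation labels
#'   (must sum to 1).
#' @param n_entity_symbols size of the in-vocabulary entity surface pool.
#' @param negation_rate,quantity_rate,oov_fraction_heldout probabilities
#'   in [0, 1].
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_instances = 1000L,
                             class_weights = table5_class_weights(),
                             n_entity_symbols = 200L,
                             negation_rate = 0.3, quantity_rate = 0.2,
                             oov_fraction_heldout = 0, seed = 1L) {
  schema <- relation_schema()
  bad <- setdiff(names(class_weights), schema$relation_labels)
  if (length(bad)) {
    stop("class_weights name unknown label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_instances > 0, abs(sum(class_weights) - 1) < 1e-8,
            negation_rate >= 0, negation_rate <= 1,
            quantity_rate >= 0, quantity_rate <= 1,
            oov_fraction_heldout >= 0, oov_fraction_heldout <= 1)
  structure(as.list(environment())[c(
    "n_instances", "class_weights", "n_entity_symbols", "negation_rate",
    "quantity_rate", "oov_fraction_heldout", "seed")],
    class = "generator_config")
}

#' Deterministic label of a cue record
#'
#' The generator's documented cue-to-label mapping: neutral verbs give
#' \code{undirected_link}; causal verbs with unspecified direction give
#' \code{directed_link}; otherwise the effective polarity is the verb's
#' polarity XOR the presence of a flipping modifier, selecting
#' \code{positive_cause}/\code{negative_cause}; a quantity phrase on the
#' object entity then descends to the third level (increase under a
#' positive parent = \code{positive_increase}, decrease =
#' \code{negative_decrease}; decrease under a negative parent =
#' \code{positive_decrease}, increase = \code{negative_increase}).
#'
#' @param cue list or one-row data.frame with \code{verb_class}
#'   (\code{"positive"}, \code{"negative"}, \code{"unspecified"},
#'   \code{"neutral"}), \code{flip} (logical) and \code{quantity}
#'   (\code{"none"}, \code{"increase"}, \code{"decrease"}).
#' @return a relation label.
#' @export
oracle_label <- function(cue) {
  cue <- as.list(cue)
  vc <- match.arg(cue$verb_class,
                  c("positive", "negative", "unspecified", "neutral"))
  q <- match.arg(cue$quantity, c("none", "increase", "decrease"))
  if (vc == "neutral") return("undirected_link")
  if (vc == "unspecified") return("directed_link")
  positive <- (vc == "positive") != isTRUE(cue$flip)  # XOR
  if (q == "none") {
    return(if (positive) "positive_cause" else "negative_cause")
  }
  if (positive) {
    if (q == "increase") "positive_increase" else "negative_decrease"
  } else {
    if (q == "decrease") "positive_decrease" else "negative_increase"
  }
}

make_symbol_pool <- function(n, oov = FALSE) {
  prefixes <- c(GENE = "gene", PROT = "protein", MIR = "rna",
                CMPD = "compound")
  i <- seq_len(n)
  pre <- names(prefixes)[(i - 1L) %% length(prefixes) + 1L]
  surface <- paste0(if (oov) "NOV" else "", pre, i)
  data.frame(surface = surface, type = unname(prefixes[pre]),
             stringsAsFactors = FALSE)
}

# draw the cue record consistent with a target label
cues_for_label <- function(label, lex, negation_rate) {
  if (label == "undirected_link") {
    return(list(verb_class = "neutral", flip = FALSE, quantity = "none",
                verb = sample(lex$verbs_neutral, 1)))
  }
  if (label == "directed_link") {
    return(list(verb_class = "unspecified", flip = FALSE,
                quantity = "none", verb = sample(lex$verbs_unspecified, 1)))
  }
  parent_positive <- label %in% c("positive_cause", "positive_increase",
                                  "negative_decrease")
  quantity <- switch(label,
    positive_cause = , negative_cause = "none",
    positive_increase = "increase", negative_decrease = "decrease",
    positive_decrease = "decrease", negative_increase = "increase")
  flip <- stats::runif(1) < negation_rate
  verb_positive <- parent_positive != flip  # XOR back to verb polarity
  list(verb_class = if (verb_positive) "positive" else "negative",
       flip = flip,
       quantity = quantity,
       verb = sample(if (verb_positive) lex$verbs_positive else
                       lex$verbs_negative, 1))
}

#' Generate a synthetic relation corpus
#'
#' Each instance realises the template
#' \code{<modifier?> <E1> <verb phrase> <quantity phrase?> <E2> <tail?>}
#' from the fixed \code{\link{relation_lexicons}}; the recorded label is
#' \code{\link{oracle_label}} of the instance's cues by construction.
#' Labels are drawn i.i.d. from \code{class_weights}; cues are then drawn
#' consistently with the label. Entity spans are exact character offsets
#' into the composed sentence; instances are grouped four per synthetic
#' document (sentence id 0 = title). Generation is byte-reproducible
#' given the seed.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list of class \code{synthetic_corpus}: \code{corpus} (a corpus
#'   data.frame) and \code{cues} (one row per instance: verb class, verb,
#'   modifier, flip, quantity, oov, label).
#' @export
generate_corpus <- function(config) {
  lex <- relation_lexicons()
  labels <- relation_schema()$relation_labels
  w <- config$class_weights[labels]
  w[is.na(w)] <- 0
  pool <- make_symbol_pool(config$n_entity_symbols)
  pool_oov <- make_symbol_pool(config$n_entity_symbols, oov = TRUE)
  rows <- vector("list", config$n_instances)
  cues_out <- vector("list", config$n_instances)
  with_seed(config$seed, {
    for (i in seq_len(config$n_instances)) {
      label <- sample(labels, 1, prob = w)
      cue <- cues_for_label(label, lex, config$negation_rate)
      oov <- stats::runif(1) < config$oov_fraction_heldout
      p <- if (oov) pool_oov else pool
      pick <- sample.int(nrow(p), 2)
      surf <- p$surface[pick]; ety <- p$type[pick]
      # occasional multi-token entity surfaces
      for (j in 1:2) {
        if (stats::runif(1) < 0.25) {
          surf[j] <- paste(surf[j], sample(lex$entity_suffixes, 1))
        }
      }
      modifier <- if (cue$flip) sample(lex$modifiers, 1) else ""
      qphrase <- switch(cue$quantity,
        none = "",
        increase = sample(lex$quantity_increase, 1),
        decrease = sample(lex$quantity_decrease, 1))
      tail <- if (cue$quantity == "none" &&
                  stats::runif(1) < config$quantity_rate) {
        sample(lex$tails_quantity_flavored, 1)
      } else if (stats::runif(1) < 0.3) {
        sample(lex$tails_plain, 1)
      } else ""
      # compose the sentence, tracking 0-based offsets
      parts <- character(0); cursor <- 0L
      e1_start <- e2_start <- NA_integer_
      add <- function(s) {
        if (!nzchar(s)) return(invisible(NULL))
        if (length(parts)) cursor <<- cursor + 1L  # joining space
        parts <<- c(parts, s)
        start <- cursor
        cursor <<- cursor + nchar(s)
        start
      }
      add(modifier)
      e1_start <- add(surf[1])
      add(cue$verb)
      add(qphrase)
      e2_start <- add(surf[2])
      add(tail)
      sentence <- paste(parts, collapse = " ")
      rows[[i]] <- relation_instance(
        sprintf("SYN%05d", (i - 1L) %/% 4L + 1L), (i - 1L) %% 4L,
        sentence,
        surf[1], e1_start, e1_start + nchar(surf[1]), ety[1],
        surf[2], e2_start, e2_start + nchar(surf[2]), ety[2],
        label)
      cues_out[[i]] <- data.frame(
        verb_class = cue$verb_class, verb = cue$verb,
        modifier = modifier, flip = cue$flip, quantity = cue$quantity,
        oov = oov, label = label, stringsAsFactors = FALSE)
    }
  })
  structure(
    list(corpus = do.call(rbind, rows), cues = do.call(rbind, cues_out)),
    class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$corpus), "instances,",
      length(unique(x$corpus$pmid)), "documents\n")
  print(utils::head(x$corpus[, c("sentence", "label")], 5),
        row.names = FALSE)
  invisible(x)
}
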