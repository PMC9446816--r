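tk <- whitespace_tokenizer()

test_that("character spans align to the smallest covering token range", {
  toks <- tk$tokenize("A activates B")
  expect_identical(toks$start, c(0L, 2L, 12L))
  expect_identical(toks$end, c(1L, 11L, 13L))
  expect_identical(align_spans_to_tokens(toks, 0, 1), c(1L, 1L))
  expect_identical(align_spans_to_tokens(toks, 2, 11), c(2L, 2L))
  # partial overlap expands to the covering token
  expect_identical(align_spans_to_tokens(toks, 3, 8), c(2L, 2L))
  expect_identical(align_spans_to_tokens(toks, 0, 5), c(1L, 2L))
  expect_error(align_spans_to_tokens(toks, 1, 2), "zero tokens")
})

test_that("the five input-construction layouts match their contracts", {
  inst <- worked_instance()  # "A activates B C", e1 = "A", e2 = "B C"
  e <- encode_instance(inst, "default", tk)
  expect_identical(e$tokens, c("[CLS]", "A", "activates", "B", "C", "[SEP]"))
  expect_identical(c(e$e1_index, e$e2_index), c(2L, 4L))
  expect_true(all(e$segment_ids == 0L))

  e <- encode_instance(inst, "entity_marker", tk)
  expect_identical(e$tokens, c("[CLS]", "[E1]", "A", "[/E1]", "activates",
                               "[E2]", "B", "C", "[/E2]", "[SEP]"))
  expect_identical(c(e$e1_index, e$e2_index), c(2L, 6L))

  e <- encode_instance(inst, "masked", tk)
  expect_identical(e$tokens, c("[CLS]", "[MASK]", "activates", "[MASK]",
                               "[SEP]"))
  expect_identical(c(e$e1_index, e$e2_index), c(2L, 4L))

  e <- encode_instance(inst, "two_masked_sentence", tk)
  expect_identical(e$tokens, c("[CLS]", "[MASK]", "activates", "B", "C",
                               "[SEP]", "A", "activates", "[MASK]", "[SEP]"))
  expect_identical(c(e$e1_index, e$e2_index), c(2L, 9L))
  expect_identical(e$segment_ids, c(rep(0L, 6), rep(1L, 4)))

  e <- encode_instance(inst, "two_sentence_entity_token", tk)
  expect_identical(e$tokens, c("[CLS]", "[E1]", "activates", "B", "C",
                               "[SEP]", "A", "activates", "[E2]", "[SEP]"))
  expect_identical(c(e$e1_index, e$e2_index), c(2L, 9L))
  expect_error(encode_instance(inst, "sliding_window", tk))
})

test_that("layout invariants hold across generated corpora", {
  syn <- small_synthetic(40, seed = 13)$corpus
  for (m in c("default", "entity_marker", "masked", "two_masked_sentence",
              "two_sentence_entity_token")) {
    exs <- encode_corpus(syn, m, tk, 128)
    two_sentence <- m %in% c("two_masked_sentence",
                             "two_sentence_entity_token")
    for (e in exs) {
      expect_identical(e$tokens[1], "[CLS]")
      expect_identical(e$tokens[length(e$tokens)], "[SEP]")
      expect_identical(sum(e$tokens == "[SEP]"),
                       if (two_sentence) 2L else 1L)
      expect_true(all(diff(e$segment_ids) >= 0))  # non-decreasing
      expect_identical(any(e$segment_ids == 1L), two_sentence)
      expect_true(e$e1_index > 1 && e$e1_index < length(e$tokens))
      expect_true(e$e2_index > 1 && e$e2_index < length(e$tokens))
      expect_true(e$e1_index != e$e2_index)
      if (m == "masked") {
        expect_identical(sum(e$tokens == "[MASK]"), 2L)
      }
      if (m == "two_masked_sentence") {
        sep1 <- which(e$tokens == "[SEP]")[1]
        expect_identical(sum(e$tokens[1:sep1] == "[MASK]"), 1L)
        expect_identical(sum(e$tokens[-(1:sep1)] == "[MASK]"), 1L)
      }
    }
  }
})

test_that("removing markers and unmasking recovers the sentence tokens", {
  syn <- small_synthetic(25, seed = 17)$corpus
  specials <- c("[CLS]", "[SEP]", "[E1]", "[/E1]", "[E2]", "[/E2]")
  for (i in seq_len(nrow(syn))) {
    inst <- syn[i, ]
    toks <- tk$tokenize(inst$sentence)$token
    # marker method: drop special tokens
    e <- encode_instance(inst, "entity_marker", tk)
    expect_identical(e$tokens[!e$tokens %in% specials], toks)
    # masked: restore each mask with its entity's token span
    e <- encode_instance(inst, "masked", tk)
    r1 <- align_spans_to_tokens(tk$tokenize(inst$sentence),
                                inst$e1_start, inst$e1_end)
    r2 <- align_spans_to_tokens(tk$tokenize(inst$sentence),
                                inst$e2_start, inst$e2_end)
    body <- as.list(e$tokens[-c(1, length(e$tokens))])
    pos <- which(unlist(body) == "[MASK]")
    first_is_e1 <- r1[1] < r2[1]
    body[[pos[1]]] <- toks[if (first_is_e1) r1[1]:r1[2] else r2[1]:r2[2]]
    body[[pos[2]]] <- toks[if (first_is_e1) r2[1]:r2[2] else r1[1]:r1[2]]
    expect_identical(unlist(body), toks)
    # both copies of the two-sentence layout restore independently
    e <- encode_instance(inst, "two_masked_sentence", tk)
    seps <- which(e$tokens == "[SEP]")
    copy1 <- as.list(e$tokens[2:(seps[1] - 1)])
    copy2 <- as.list(e$tokens[(seps[1] + 1):(seps[2] - 1)])
    copy1[[which(unlist(copy1) == "[MASK]")]] <- toks[r1[1]:r1[2]]
    copy2[[which(unlist(copy2) == "[MASK]")]] <- toks[r2[1]:r2[2]]
    expect_identical(unlist(copy1), toks)
    expect_identical(unlist(copy2), toks)
  }
})

test_that("masked positions are invariant to the entity surface; the unmasked copy is not", {
  mk <- function(surface) {
    s <- sprintf("%s activates TARGET9", surface)
    relation_instance("d", 0, s, surface, 0, nchar(surface), "gene",
                      "TARGET9", nchar(s) - 7, nchar(s), "protein",
                      "positive_cause")
  }
  a <- encode_instance(mk("GENE1"), "masked", tk)
  b <- encode_instance(mk("ZZZUNSEEN147"), "masked", tk)
  expect_identical(a$tokens, b$tokens)
  expect_identical(c(a$e1_index, a$e2_index), c(b$e1_index, b$e2_index))
  # two_masked_sentence: first copy masked (identical), second copy keeps
  # the surface verbatim (differs)
  a2 <- encode_instance(mk("GENE1"), "two_masked_sentence", tk)
  b2 <- encode_instance(mk("ZZZUNSEEN147"), "two_masked_sentence", tk)
  sep1 <- which(a2$tokens == "[SEP]")[1]
  expect_identical(a2$tokens[1:sep1], b2$tokens[1:sep1])
  expect_false(identical(a2$tokens, b2$tokens))
})

test_that("encoding is deterministic and truncation refuses to cut representatives", {
  inst <- worked_instance()
  e1 <- encode_instance(inst, "two_masked_sentence", tk)
  e2 <- encode_instance(inst, "two_masked_sentence", tk)
  expect_identical(e1, e2)
  long <- relation_instance(
    "d", 0, paste(c("GENE1 activates GENE2",
                    rep("tailword", 30)), collapse = " "),
    "GENE1", 0, 5, "gene", "GENE2", 16, 21, "gene", "positive_cause")
  # tail truncation succeeds when representatives survive
  e <- encode_instance(long, "masked", tk, max_len = 10)
  expect_length(e$tokens, 10)
  expect_identical(e$tokens[10], "[SEP]")
  # but errors out rather than cutting a representative token
  expect_error(encode_instance(long, "two_masked_sentence", tk,
                               max_len = 10), "max_len")
})
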