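#' Relation-annotated corpora
#'
#' A corpus is a plain \code{data.frame} with one row per relation instance
#' and the canonical columns \code{pmid}, \code{sent_id}, \code{sentence},
#' \code{e1_text}, \code{e1_start}, \code{e1_end}, \code{e1_type},
#' \code{e2_text}, \code{e2_start}, \code{e2_end}, \code{e2_type},
#' \code{label}, plus an optional \code{split} column (one of
#' \code{"train"}, \code{"validate"}, \code{"test"}). Character offsets are
#' 0-based and half-open: \code{[start, end)} indexes the sentence so that
#' the slice equals the surface string. Entity 1 is the subject role and
#' entity 2 the object role, in annotation order (which need not be textual
#' order).
#'
#' @name relation-corpus
NULL

REL_TABLE_COLS <- c(
  "pmid", "sent_id", "sentence",
  "e1_text", "e1_start", "e1_end", "e1_type",
  "e2_text", "e2_start", "e2_end", "e2_type",
  "label"
)

# substring under the 0-based half-open convention
slice_sentence <- function(s, start, end) substring(s, start + 1L, end)

#' Construct a single relation instance
#'
#' @param pmid document identifier.
#' @param sent_id non-negative sentence index within the document (0 is the
#'   title).
#' @param sentence sentence text.
#' @param e1_text,e1_start,e1_end,e1_type surface string, 0-based half-open
#'   character span, and entity type of the subject entity.
#' @param e2_text,e2_start,e2_end,e2_type the same for the object entity.
#' @param label relation label (any display form; normalized).
#' @return a one-row corpus \code{data.frame} (see
#'   \link{relation-corpus}).
#' @export
relation_instance <- function(pmid, sent_id, sentence,
                              e1_text, e1_start, e1_end, e1_type,
                              e2_text, e2_start, e2_end, e2_type,
                              label) {
  data.frame(
    pmid = as.character(pmid), sent_id = as.integer(sent_id),
    sentence = as.character(sentence),
    e1_text = as.character(e1_text), e1_start = as.integer(e1_start),
    e1_end = as.integer(e1_end), e1_type = normalize_label(e1_type),
    e2_text = as.character(e2_text), e2_start = as.integer(e2_start),
    e2_end = as.integer(e2_end), e2_type = normalize_label(e2_type),
    label = normalize_label(label),
    stringsAsFactors = FALSE
  )
}

empty_corpus <- function() {
  relation_instance("", 0L, "", "", 0L, 0L, "gene",
                    "", 0L, 0L, "gene", "undirected_link")[0, ]
}

#' Validate a relation instance against the schema
#'
#' Checks every structural invariant of an instance: the label and entity
#' types belong to the schema, spans are well-formed 0-based half-open
#' intervals inside the sentence, each surface string equals the sentence
#' slice at its span, the two spans do not overlap, and \code{sent_id} is
#' non-negative. Violations are returned as data, not raised.
#'
#' @param instance a one-row corpus data.frame (or a list with the same
#'   fields).
#' @param schema a \code{\link{relation_schema}}.
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_instance <- function(instance, schema = relation_schema()) {
  x <- as.list(instance)
  v <- character(0)
  n <- nchar(x$sentence)
  if (!is.na(x$sent_id) && x$sent_id < 0) {
    v <- c(v, "sent_id: must be non-negative")
  }
  if (!normalize_label(x$label) %in% schema$relation_labels) {
    v <- c(v, sprintf("label: '%s' not in schema", x$label))
  }
  for (e in c("e1", "e2")) {
    st <- x[[paste0(e, "_start")]]; en <- x[[paste0(e, "_end")]]
    ty <- x[[paste0(e, "_type")]]; tx <- x[[paste0(e, "_text")]]
    if (!normalize_label(ty) %in% schema$entity_types) {
      v <- c(v, sprintf("%s_type: '%s' not in schema", e, ty))
    }
    if (is.na(st) || is.na(en) || st >= en) {
      v <- c(v, sprintf("%s span: start < end violated (%s, %s)", e, st, en))
    } else if (st < 0 || en > n) {
      v <- c(v, sprintf("%s span: [%d, %d) outside sentence of length %d",
                        e, st, en, n))
    } else if (slice_sentence(x$sentence, st, en) != tx) {
      v <- c(v, sprintf(
        "%s_text: surface '%s' != sentence slice '%s'",
        e, tx, slice_sentence(x$sentence, st, en)))
    }
  }
  ok_spans <- !anyNA(c(x$e1_start, x$e1_end, x$e2_start, x$e2_end)) &&
    x$e1_start < x$e1_end && x$e2_start < x$e2_end
  if (ok_spans && x$e1_start < x$e2_end && x$e2_start < x$e1_end) {
    v <- c(v, "entity spans overlap")
  }
  v
}

#' Validate a whole corpus
#'
#' @param corpus a corpus data.frame.
#' @inheritParams validate_instance
#' @return a data.frame with columns \code{row} and \code{violation}; zero
#'   rows when the corpus is valid.
#' @export
validate_corpus <- function(corpus, schema = relation_schema()) {
  out <- list()
  for (i in seq_len(nrow(corpus))) {
    v <- validate_instance(corpus[i, ], schema)
    if (length(v)) out[[length(out) + 1L]] <-
      data.frame(row = i, violation = v, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), violation = character(0)))
  }
  do.call(rbind, out)
}

#' Read a TextAE-dialect JSON annotation document
#'
#' Parses the JSON dialect exported by TextAE-style annotation editors:
#' each document carries a \code{text} field, \code{denotations} (entity
#' spans: \code{id}, \code{span\{begin, end\}}, \code{obj} = entity type)
#' and \code{relations} (\code{pred} = relation label, \code{subj},
#' \code{obj} referencing denotation ids). The file may contain one
#' document object or an array of them. Optional \code{pmid} (or
#' \code{sourceid}) and \code{sent_id} fields key the sentence; they
#' default to \code{""} and 0.
#'
#' The relation's \code{subj} becomes entity 1 and \code{obj} entity 2.
#' Labels and entity types are normalized to canonical snake_case.
#'
#' @param path path to a JSON file, or a JSON string.
#' @param schema a \code{\link{relation_schema}}.
#' @return a corpus data.frame with one row per relation record.
#' @export
read_textae_json <- function(path, schema = relation_schema()) {
  docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(docs$text)) docs <- list(docs)  # single document
  out <- vector("list", 0L)
  for (doc in docs) {
    if (is.null(doc$text)) stop("TextAE document has no 'text' field", call. = FALSE)
    pmid <- as.character(doc$pmid %||% doc$sourceid %||% "")
    sent_id <- as.integer(doc$sent_id %||% 0L)
    dens <- list()
    for (d in doc$denotations %||% list()) {
      if (is.null(d$id) || is.null(d$span) || is.null(d$obj)) {
        stop("denotation missing id/span/obj", call. = FALSE)
      }
      ty <- normalize_label(d$obj)
      if (!ty %in% schema$entity_types) {
        stop("unknown entity type '", d$obj, "' in denotation ", d$id,
             call. = FALSE)
      }
      b <- as.integer(d$span$begin); e <- as.integer(d$span$end)
      if (is.na(b) || is.na(e) || b < 0 || e > nchar(doc$text) || b >= e) {
        stop("denotation ", d$id, ": span [", b, ", ", e,
             ") invalid for text of length ", nchar(doc$text), call. = FALSE)
      }
      dens[[d$id]] <- list(begin = b, end = e, type = ty)
    }
    for (r in doc$relations %||% list()) {
      pred <- normalize_label(r$pred)
      if (!pred %in% schema$relation_labels) {
        stop("unknown relation label '", r$pred, "'", call. = FALSE)
      }
      for (ref in c(r$subj, r$obj)) {
        if (is.null(dens[[ref]])) {
          stop("relation references missing denotation id '", ref, "'",
               call. = FALSE)
        }
      }
      d1 <- dens[[r$subj]]; d2 <- dens[[r$obj]]
      out[[length(out) + 1L]] <- relation_instance(
        pmid, sent_id, doc$text,
        slice_sentence(doc$text, d1$begin, d1$end), d1$begin, d1$end, d1$type,
        slice_sentence(doc$text, d2$begin, d2$end), d2$begin, d2$end, d2$type,
        pred)
    }
  }
  if (!length(out)) return(empty_corpus())
  do.call(rbind, out)
}

#' Write a corpus as TextAE-dialect JSON
#'
#' One JSON document per corpus row (each row carries its own sentence
#' text), written as a JSON array.
#'
#' @param corpus a corpus data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_textae_json <- function(corpus, path) {
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    x <- corpus[i, ]
    list(
      pmid = x$pmid, sent_id = x$sent_id, text = x$sentence,
      denotations = list(
        list(id = "T1", span = list(begin = x$e1_start, end = x$e1_end),
             obj = x$e1_type),
        list(id = "T2", span = list(begin = x$e2_start, end = x$e2_end),
             obj = x$e2_type)
      ),
      relations = list(
        list(id = "R1", pred = x$label, subj = "T1", obj = "T2")
      )
    )
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write the canonical tab-separated relation table
#'
#' The exchange format for relation corpora: UTF-8, tab-separated, LF line
#' endings, a fixed header (\code{pmid}, \code{sent_id}, \code{sentence},
#' \code{e1_text}, \code{e1_start}, \code{e1_end}, \code{e1_type},
#' \code{e2_text}, \code{e2_start}, \code{e2_end}, \code{e2_type},
#' \code{label}), and optionally a trailing \code{split} column. Fields may
#' not contain tabs or newlines; such rows are rejected rather than
#' escaped. Writing then reading recovers the corpus exactly.
#'
#' @param path file path.
#' @param schema a \code{\link{relation_schema}}; read validates each row.
#' @return \code{read_relation_table}: a corpus data.frame.
#' @export
read_relation_table <- function(path, schema = relation_schema()) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: no header row", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(REL_TABLE_COLS, header)
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(lines[-1], function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  out <- empty_corpus()
  if ("split" %in% header) out$split <- character(0)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != length(header)) {
      stop("row ", i, ": expected ", length(header), " fields, got ",
           length(f), call. = FALSE)
    }
    names(f) <- header
    ints <- suppressWarnings(as.integer(
      f[c("sent_id", "e1_start", "e1_end", "e2_start", "e2_end")]))
    if (anyNA(ints)) {
      stop("row ", i, ": offsets/sent_id not parseable as integers",
           call. = FALSE)
    }
    inst <- relation_instance(
      f[["pmid"]], ints[1], f[["sentence"]],
      f[["e1_text"]], ints[2], ints[3], f[["e1_type"]],
      f[["e2_text"]], ints[4], ints[5], f[["e2_type"]],
      f[["label"]])
    v <- validate_instance(inst, schema)
    if (length(v)) {
      stop("row ", i, ": ", paste(v, collapse = "; "), call. = FALSE)
    }
    if ("split" %in% header) inst$split <- f[["split"]]
    out <- rbind(out, inst)
  }
  out
}

#' @rdname read_relation_table
#' @param corpus a corpus data.frame.
#' @return \code{write_relation_table}: \code{path}, invisibly.
#' @export
write_relation_table <- function(corpus, path) {
  cols <- REL_TABLE_COLS
  if ("split" %in% names(corpus)) cols <- c(cols, "split")
  chr <- vapply(corpus[cols], is.character, logical(1))
  for (cn in cols[chr]) {
    bad <- grepl("[\t\n\r]", corpus[[cn]])
    if (any(bad)) {
      stop("field '", cn, "' contains tab/newline in row(s) ",
           paste(which(bad), collapse = ", "), "; refusing to escape",
           call. = FALSE)
    }
  }
  mat <- vapply(corpus[cols], as.character, character(nrow(corpus)))
  if (nrow(corpus) == 1L) mat <- matrix(mat, nrow = 1)
  lines <- c(paste(cols, collapse = "\t"),
             apply(mat, 1, paste, collapse = "\t"))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Corpus summary statistics
#'
#' Counts documents, relations and entity mentions, per-label relation
#' counts per split, and per-entity-type mention counts split by side
#' (entity 1 = left/subject column, entity 2 = right/object column), in the
#' layout of a dataset-overview table.
#'
#' @param corpus a corpus data.frame; an optional \code{split} column must
#'   take values in \code{train}, \code{validate}, \code{test}. Without a
#'   split column all instances are counted under \code{train}.
#' @param schema a \code{\link{relation_schema}}.
#' @return an object of class \code{corpus_stats}: a list with
#'   \code{n_documents}, \code{n_relations}, \code{n_entity_mentions},
#'   \code{per_label_counts} (labels x splits+total matrix) and
#'   \code{per_entity_type_counts} (types x split:side matrix with a
#'   \code{total} column).
#' @export
corpus_stats <- function(corpus, schema = relation_schema()) {
  splits <- c("train", "validate", "test")
  sp <- if ("split" %in% names(corpus)) corpus$split else
    rep("train", nrow(corpus))
  bad <- setdiff(unique(sp), splits)
  if (length(bad)) {
    stop("unknown split name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sp <- factor(sp, levels = splits)
  lab <- factor(normalize_label(corpus$label),
                levels = schema$relation_labels)
  lab_tab <- table(lab, sp)
  per_label <- cbind(unclass(lab_tab),
                     total = as.integer(rowSums(lab_tab)))
  ty <- schema$entity_types
  ent <- matrix(0L, nrow = length(ty),
                ncol = 2L * length(splits),
                dimnames = list(ty, paste(rep(splits, each = 2),
                                          c("left", "right"), sep = ".")))
  t1 <- table(factor(normalize_label(corpus$e1_type), levels = ty), sp)
  t2 <- table(factor(normalize_label(corpus$e2_type), levels = ty), sp)
  for (s in splits) {
    ent[, paste0(s, ".left")] <- t1[, s]
    ent[, paste0(s, ".right")] <- t2[, s]
  }
  ent <- cbind(ent, total = as.integer(rowSums(ent)))
  structure(
    list(
      n_documents = length(unique(corpus$pmid)),
      n_relations = nrow(corpus),
      n_entity_mentions = 2L * nrow(corpus),
      per_label_counts = per_label,
      per_entity_type_counts = ent
    ),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("Corpus overview\n")
  cat("  documents:       ", x$n_documents, "\n")
  cat("  relations:       ", x$n_relations, "\n")
  cat("  entity mentions: ", x$n_entity_mentions, "\n\n")
  cat("Relations per label:\n")
  print(x$per_label_counts)
  cat("\nEntity mentions per type (left = entity 1, right = entity 2):\n")
  print(x$per_entity_type_counts)
  invisible(x)
}
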