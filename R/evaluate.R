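#' Confusion matrix over a fixed class set
#'
#' @param truth,pred equal-length character vectors of class labels.
#' @param classes class names fixing row/column order; defaults to the
#'   eight relation labels.
#' @return integer matrix, entry (i, j) = number of instances with true
#'   class i predicted as class j.
#' @export
confusion_matrix <- function(truth, pred,
                             classes = relation_schema()$relation_labels) {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths", call. = FALSE)
  }
  truth <- normalize_label(truth); pred <- normalize_label(pred)
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) {
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Per-class precision, recall, F1 and support
#'
#' For each class c: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R); any 0/0 is defined as 0 so degenerate folds aggregate
#' cleanly. Support is the number of true instances of the class.
#'
#' @param confusion a square count matrix (rows = truth, columns =
#'   predictions).
#' @return data.frame with columns \code{class}, \code{precision},
#'   \code{recall}, \code{f1}, \code{support}.
#' @export
per_class_prf <- function(confusion) {
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- f1_score(p, r)
  data.frame(class = rownames(confusion) %||%
               as.character(seq_len(nrow(confusion))),
             precision = unname(p), recall = unname(r), f1 = unname(f1),
             support = as.integer(unname(rowSums(confusion))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall numeric vectors.
#' @return \code{2 * precision * recall / (precision + recall)}, with 0
#'   where \code{precision + recall == 0}.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Full evaluation report from a confusion matrix
#'
#' Accuracy is trace/total; the summary precision, recall and F1 are
#' macro averages — the unweighted mean of the per-class values.
#'
#' @param confusion a square count matrix (rows = truth).
#' @return an object of class \code{eval_report}: list with
#'   \code{confusion}, \code{per_class} (see \code{\link{per_class_prf}}),
#'   \code{accuracy}, \code{macro_precision}, \code{macro_recall},
#'   \code{macro_f1}, \code{n}.
#' @export
aggregate_report <- function(confusion) {
  pc <- per_class_prf(confusion)
  total <- sum(confusion)
  structure(
    list(confusion = confusion, per_class = pc,
         accuracy = if (total > 0) sum(diag(confusion)) / total else 0,
         macro_precision = mean(pc$precision),
         macro_recall = mean(pc$recall),
         macro_f1 = mean(pc$f1),
         n = total),
    class = "eval_report"
  )
}

#' Render a per-class performance table
#'
#' The classic per-class report layout: one row per class with precision,
#' recall, F1 (3 decimals) and support, and a bottom row with the macro
#' F1 and total support.
#'
#' @param report an \code{eval_report}.
#' @return character vector of report lines (also printed by the
#'   \code{print} method).
#' @export
format_per_class <- function(report) {
  pc <- report$per_class
  lines <- c(
    sprintf("%-22s %9s %9s %9s %9s", "Class", "Precision", "Recall",
            "F1-score", "Support"),
    sprintf("%-22s %9.3f %9.3f %9.3f %9d", pc$class, pc$precision,
            pc$recall, pc$f1, pc$support),
    sprintf("%-22s %9s %9s %9.3f %9d", "macro", "", "",
            report$macro_f1, report$n)
  )
  lines
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_per_class(x), sep = "\n")
  cat(sprintf("accuracy: %.3f\n", x$accuracy))
  invisible(x)
}
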