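#' Four-way confusion matrix
#'
#' Entry `(g, p)` counts posts with gold label `g` predicted as `p`, over
#' the categories in [triage_levels()] order.
#'
#' @param gold,pred Label vectors (factor or character) of equal length.
#' @return 4x4 integer matrix with dimnames `gold` x `pred`.
#' @export
confusion_matrix <- function(gold, pred) {
  if (length(gold) != length(pred) || length(gold) < 1L) {
    stop("gold and pred must be non-empty and of equal length", call. = FALSE)
  }
  gold <- as_triage_factor(gold, "gold label")
  pred <- as_triage_factor(pred, "predicted label")
  if (anyNA(gold) || anyNA(pred)) {
    stop("labels are required for evaluation", call. = FALSE)
  }
  m <- table(gold = gold, pred = pred)
  matrix(as.integer(m), 4L, 4L,
         dimnames = list(gold = triage_levels(), pred = triage_levels()))
}

# Positive-class F1 of a binary collapse; 0/0 precision or recall -> 0.
binary_f1 <- function(gold_pos, pred_pos) {
  tp <- sum(gold_pos & pred_pos)
  prec <- if (sum(pred_pos) == 0L) 0 else tp / sum(pred_pos)
  rec <- if (sum(gold_pos) == 0L) 0 else tp / sum(gold_pos)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Triage evaluation report
#'
#' Computes the CLPsych-style indicator set from gold and predicted labels:
#' per-class F1 (harmonic mean of precision and recall, with the
#' never-predicted convention that 0/0 scores 0), `all_f1` (unweighted mean
#' of the four per-class F1s), `all_acc` (4-way accuracy), `non_green_f1`
#' (unweighted mean over amber/red/crisis), and two binary collapses:
#' *flagged* (positive = amber/red/crisis vs green) and *urgent* (positive
#' = red/crisis vs green/amber), each reported as positive-class F1 and
#' binary accuracy.
#'
#' @inheritParams confusion_matrix
#' @return An `eval_report`: list with the seven scores, `per_class_f1` and
#'   the `confusion` matrix.
#' @export
evaluate_triage <- function(gold, pred) {
  conf <- confusion_matrix(gold, pred)
  gold <- as_triage_factor(gold, "gold label")
  pred <- as_triage_factor(pred, "predicted label")

  per_class <- vapply(triage_levels(), function(lv) {
    binary_f1(gold == lv, pred == lv)
  }, 0)
  flagged_set <- c("amber", "red", "crisis")
  urgent_set <- urgent_levels()
  rep <- list(
    non_green_f1 = mean(per_class[flagged_set]),
    flagged_f1 = binary_f1(gold %in% flagged_set, pred %in% flagged_set),
    flagged_acc = mean((gold %in% flagged_set) == (pred %in% flagged_set)),
    urgent_f1 = binary_f1(gold %in% urgent_set, pred %in% urgent_set),
    urgent_acc = mean((gold %in% urgent_set) == (pred %in% urgent_set)),
    all_f1 = mean(per_class),
    all_acc = mean(gold == pred),
    per_class_f1 = per_class,
    confusion = conf)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Triage evaluation\n")
  cat(sprintf("  Non-green F1 %.4f | Flagged F1 %.4f Acc %.4f | Urgent F1 %.4f Acc %.4f | All F1 %.4f Acc %.4f\n",
              x$non_green_f1, x$flagged_f1, x$flagged_acc, x$urgent_f1,
              x$urgent_acc, x$all_f1, x$all_acc))
  cat("  Confusion (gold rows x pred cols):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- report[c("non_green_f1", "flagged_f1", "flagged_acc", "urgent_f1",
                  "urgent_acc", "all_f1", "all_acc")]
  out$confusion <- unclass(report$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
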