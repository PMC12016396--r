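# The seven evaluation metrics and the fivefold cross-validation driver.

#' Confusion-matrix metrics at a threshold
#'
#' Standard definitions from TP/FP/TN/FN with predictions
#' `p >= threshold`. Ratios with a zero denominator are reported as 0 and
#' flagged in the `degenerate` field.
#'
#' @param y 0/1 labels.
#' @param p scores/probabilities.
#' @param threshold classification threshold (default 0.5 on the sigmoid
#'   score).
#' @return named list: `specificity`, `precision`, `sensitivity`, `mcc`,
#'   `accuracy`, plus `degenerate` (TRUE when any ratio was 0/0).
#' @export
confusion_metrics <- function(y, p, threshold = 0.5) {
  if (length(y) != length(p)) stopf("labels and scores differ in length")
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(specificity = safe(tn, tn + fp),
       precision = safe(tp, tp + fp),
       sensitivity = safe(tp, tp + fn),
       mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
       accuracy = safe(tp + tn, tp + fp + tn + fn),
       degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive
#' outranks a random negative, with ties counted one half (midrank
#' formula).
#'
#' @param y 0/1 labels (both classes must be present).
#' @param p scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y, p) {
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stopf("AUC is undefined with a single class")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-curve convention: scores are swept in descending order (tied
#' scores enter as one group) and the area accumulates
#' `(recall_i - recall_{i-1}) * precision_i` — no linear interpolation of
#' precision, so the value agrees exactly with an exhaustive threshold
#' sweep.
#'
#' @param y 0/1 labels (at least one positive).
#' @param p scores.
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(y, p) {
  n_pos <- sum(y == 1)
  if (n_pos == 0) stopf("AUPR is undefined without positives")
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]; p <- p[ord]
  grp_end <- which(diff(p) != 0)
  grp_end <- c(grp_end, length(p))
  tp <- cumsum(y)[grp_end]
  pred_pos <- grp_end
  prec <- tp / pred_pos
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Assemble a metrics report
#'
#' @param y 0/1 labels.
#' @param p scores.
#' @param threshold classification threshold.
#' @param fold fold identifier (integer or `"mean"`).
#' @return list of class `metrics_report` with the seven metrics,
#'   `threshold` and `fold`.
#' @export
metrics_report <- function(y, p, threshold = 0.5, fold = NA) {
  cm <- confusion_metrics(y, p, threshold)
  structure(list(specificity = cm$specificity, precision = cm$precision,
                 sensitivity = cm$sensitivity, mcc = cm$mcc,
                 accuracy = cm$accuracy,
                 auc = roc_auc(y, p), aupr = pr_auc(y, p),
                 threshold = threshold, fold = fold,
                 degenerate = cm$degenerate),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("fold %s | Spec %.4f Prec %.4f Sens %.4f MCC %.4f Accu %.4f AUC %.4f AUPR %.4f\n",
              as.character(x$fold), x$specificity, x$precision,
              x$sensitivity, x$mcc, x$accuracy, x$auc, x$aupr))
  invisible(x)
}

metric_fields <- c("specificity", "precision", "sensitivity", "mcc",
                   "accuracy", "auc", "aupr")

#' Fivefold cross-validation of the joint model
#'
#' Splits the pooled labeled pairs into `k` label-stratified folds. For
#' each fold the propagation graph is rebuilt from that fold's training
#' positives only (held-out pairs never enter the propagation operator —
#' asserted), the model is trained from scratch on the training pairs, the
#' held-out pairs are scored, and the seven metrics are reported. The mean
#' report is the unweighted average over folds; a fold whose test split
#' contains a single class is flagged and excluded from the mean with a
#' warning.
#'
#' @param sequences a `cmi_sequences` table (both kinds pooled).
#' @param table a `cmi_interactions` table (positives and negatives).
#' @param k number of folds (default 5).
#' @param seed integer seed (folds, initialization, training).
#' @param cfg a [train_config()].
#' @param encoder an [encoder_config()].
#' @param base optional pretrained base-embedding table shared across
#'   folds (default: trained once on the full corpus — sequences carry no
#'   labels, so this does not leak interaction information).
#' @param threshold classification threshold for the confusion metrics.
#' @param verbose print per-fold reports.
#' @return list of class `cmi_cv`: `folds` (list of `metrics_report`),
#'   `mean` (`metrics_report`-like list with `fold = "mean"`),
#'   `assignments` (the `cmi_folds` object), `models` (per-fold models).
#' @export
cross_validate <- function(sequences, table, k = 5L, seed = 1L,
                           cfg = train_config(), encoder = encoder_config(),
                           base = NULL, threshold = 0.5, verbose = FALSE) {
  folds <- make_folds(nrow(table), k, seed, stratify_labels = table$label)
  circ_ids <- sort(unique(table$circRNA))
  mir_ids <- sort(unique(table$miRNA))
  base <- base %||% train_base_embeddings(
    sequences, skipgram_config(dim = encoder$input_dim, seed = seed))
  reports <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds$assignments == f
    train_tab <- table[!test_idx, , drop = FALSE]
    test_tab <- table[test_idx, , drop = FALSE]
    class(train_tab) <- class(table)
    graph <- build_graph(train_tab, circ_ids, mir_ids)
    held_keys <- paste(test_tab$miRNA, test_tab$circRNA)
    edge_idx <- which(graph$R == 1)
    edge_keys <- paste(rep(graph$mir_ids, times = graph$m)[edge_idx],
                       rep(graph$circ_ids, each = graph$n)[edge_idx])
    if (any(held_keys %in% edge_keys)) {
      stopf("leakage: held-out pair(s) present as graph edges in fold %d", f)
    }
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- train_model(train_tab, graph, sequences, cfg = fold_cfg,
                         encoder = encoder, base = base)
    p <- predict_pairs(model, graph, sequences, test_tab)
    models[[f]] <- model
    if (length(unique(test_tab$label)) < 2) {
      warning(sprintf("fold %d has a single class in its test split; excluded from the mean", f))
      reports[[f]] <- structure(list(fold = f, degenerate = TRUE,
                                     excluded = TRUE),
                                class = "metrics_report")
      next
    }
    reports[[f]] <- metrics_report(test_tab$label, p, threshold, fold = f)
    if (verbose) print(reports[[f]])
  }
  ok <- !vapply(reports, function(r) isTRUE(r$excluded), logical(1))
  mean_rep <- lapply(metric_fields, function(fname) {
    mean(vapply(reports[ok], `[[`, numeric(1), fname))
  })
  names(mean_rep) <- metric_fields
  mean_rep$threshold <- threshold
  mean_rep$fold <- "mean"
  class(mean_rep) <- "metrics_report"
  structure(list(folds = reports, mean = mean_rep, assignments = folds,
                 models = models),
            class = "cmi_cv")
}

#' Flatten a cross-validation result into a table
#'
#' One row per fold plus the mean row, in the seven-metric column order
#' (specificity, precision, sensitivity, mcc, accuracy, auc, aupr);
#' convenient for `write.csv()`.
#'
#' @param cv a `cmi_cv` object from [cross_validate()].
#' @return a `data.frame` with a `fold` column and the seven metrics.
#' @export
cv_report_table <- function(cv) {
  rows <- c(cv$folds[!vapply(cv$folds, function(r) isTRUE(r$excluded),
                             logical(1))],
            list(cv$mean))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(fold = as.character(r$fold),
               as.data.frame(r[metric_fields]))
  }))
  rownames(out) <- NULL
  out
}
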