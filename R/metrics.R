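METRIC_FIELDS <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1", "mcc", "auprc", "auroc", "pos_pref",
                   "ties_fraction")

#' Confusion counts for parent-of-origin predictions
#'
#' Tallies TP/FP/TN/FN with a configurable positive class (P2 by
#' convention; studies typically designate one species the positive
#' class for directional statistics).
#'
#' @param pred Predicted labels, or a prediction data.frame with
#'   `read_id` and `predicted_parent` columns.
#' @param truth True labels, or a data.frame with `read_id` and `label`
#'   columns (matched by read id).
#' @param positive The positive class label.
#' @return A `po_confusion` list: TP, FP, TN, FN.
#' @export
confusion <- function(pred, truth, positive = "P2") {
  if (is.data.frame(pred)) {
    if (is.data.frame(truth)) {
      hit <- match(pred$read_id, truth$read_id)
      if (anyNA(hit))
        stop("prediction read id(s) without a truth label: ",
             paste(head(pred$read_id[is.na(hit)], 5L), collapse = ", "))
      truth <- truth$label[hit]
    }
    pred <- pred$predicted_parent
  }
  stopifnot(length(pred) == length(truth))
  pos_p <- pred == positive
  pos_t <- truth == positive
  structure(list(TP = sum(pos_p & pos_t), FP = sum(pos_p & !pos_t),
                 TN = sum(!pos_p & !pos_t), FN = sum(!pos_p & pos_t)),
            class = "po_confusion")
}

#' Area under the ROC curve
#'
#' Probability-ranking (Mann-Whitney) definition with midrank handling
#' of score ties.
#'
#' @param scores Classifier scores (higher favours the positive class).
#' @param is_pos Logical, TRUE for positive-class truth.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function area: thresholds are placed at distinct score values
#' (tied scores enter together) scanning from the highest score down;
#' each recall increment contributes at the precision reached at that
#' threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  if (n1 == 0L || all(is_pos)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- is_pos[o]
  cum_tp <- cumsum(p)
  cum_n <- seq_along(p)
  last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cum_tp[last]
  prec <- tp / cum_n[last]
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' The evaluation metrics panel
#'
#' Derives the full panel from confusion counts: accuracy,
#' sensitivity (= recall), specificity, precision, F1 and positive
#' preference as percentages, MCC on its natural [-1, 1] scale, and —
#' when classifier scores are supplied — AUROC and AUPRC reported as
#' percentages to match conventional result tables. Positive
#' preference, (TP+FP)/(TP+FP+TN+FN), reads 50% when the predictions
#' show no class bias. An MCC denominator factor of zero yields MCC 0
#' (flagged via attribute `mcc_undefined`). Deciders without scores
#' leave AUROC/AUPRC as NA.
#'
#' @param counts A `po_confusion` from [confusion()].
#' @param scores Optional score column (e.g. model P2 probability).
#' @param truth Optional truth labels aligned with `scores` (required
#'   for AUROC/AUPRC).
#' @param positive Positive class label for `truth`.
#' @param ties_fraction Optional fraction of score-comparison ties,
#'   reported as a percentage.
#' @return A `po_metrics` list.
#' @export
metrics_panel <- function(counts, scores = NULL, truth = NULL,
                          positive = "P2", ties_fraction = NULL) {
  # numeric from the outset: MCC factors overflow integer range easily
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  tot <- TP + FP + TN + FN
  if (tot == 0L) stop("empty confusion counts")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  den <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc_undef <- any(den == 0)
  mcc <- if (mcc_undef) 0 else
    (TP * TN - FP * FN) / sqrt(prod(den))
  au_roc <- au_prc <- NA_real_
  if (!is.null(scores) && !is.null(truth) && !all(is.na(scores))) {
    is_pos <- truth == positive
    au_roc <- 100 * auroc(scores, is_pos)
    au_prc <- 100 * auprc(scores, is_pos)
  }
  structure(list(
    accuracy = 100 * (TP + TN) / tot,
    sensitivity = pct(TP, TP + FN),
    specificity = pct(TN, TN + FP),
    precision = pct(TP, TP + FP),
    f1 = if (2 * TP + FP + FN == 0) NA_real_ else
      200 * TP / (2 * TP + FP + FN),
    mcc = mcc,
    auprc = au_prc,
    auroc = au_roc,
    pos_pref = 100 * (TP + FP) / tot,
    ties_fraction = if (is.null(ties_fraction)) NA_real_ else
      100 * ties_fraction,
    counts = counts),
    class = "po_metrics", mcc_undefined = mcc_undef)
}

#' @export
print.po_metrics <- function(x, ...) {
  fmt <- function(v, d = 1) ifelse(is.na(v), "-",
                                   formatC(v, format = "f", digits = d))
  cat(sprintf(
    "accuracy %s%%  sens %s%%  spec %s%%  prec %s%%  F1 %s%%  MCC %s\n",
    fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
    fmt(x$precision), fmt(x$f1), fmt(x$mcc, 3)))
  cat(sprintf("AUPRC %s%%  AUROC %s%%  PosPref %s%%  Ties %s%%\n",
              fmt(x$auprc), fmt(x$auroc), fmt(x$pos_pref),
              fmt(x$ties_fraction)))
  invisible(x)
}

#' Side-by-side comparison table of deciders
#'
#' Formats one metrics panel per decider with methods as columns and
#' statistics as rows (percentages to one decimal, MCC to three), the
#' conventional layout of classification result tables.
#'
#' @param panels Named list of `po_metrics`.
#' @return A character data.frame.
#' @export
format_comparison_table <- function(panels) {
  fmt <- function(p) {
    v <- unlist(p[METRIC_FIELDS])
    out <- ifelse(is.na(v), "-",
                  paste0(formatC(v, format = "f", digits = 1), "%"))
    out[METRIC_FIELDS == "mcc"] <-
      ifelse(is.na(v[METRIC_FIELDS == "mcc"]), "-",
             formatC(v[METRIC_FIELDS == "mcc"], format = "f", digits = 3))
    out
  }
  df <- data.frame(statistic = c("Accuracy", "Sensitivity", "Specificity",
                                 "Precision", "F1-score", "MCC", "AUPRC",
                                 "AUROC", "Pos Pref", "Ties"),
                   stringsAsFactors = FALSE)
  for (nm in names(panels)) df[[nm]] <- fmt(panels[[nm]])
  df
}

#' Compare hybrid class preference against a parental baseline
#'
#' When a decider shows class bias on reads of known parental origin,
#' that preference — not 50% — is the no-ASE baseline for the hybrid.
#' Reports the deviation of the observed hybrid preference from the
#' parental baseline and an exact binomial confidence interval for the
#' hybrid preference; the null hypothesis of no allele-specific
#' expression is retained when the baseline lies inside the interval.
#'
#' @param parental_pos_pref Positive-class preference (percent)
#'   measured on reads of known parental origin.
#' @param hybrid_pos_pref Positive-class preference (percent) observed
#'   on hybrid reads.
#' @param n_hybrid Number of hybrid read pairs, positive.
#' @param conf Confidence level for the binomial interval.
#' @return A list: deviation (percentage points), conf_int (percent),
#'   baseline_inside, consistent_with_no_ase.
#' @export
bias_baseline_compare <- function(parental_pos_pref, hybrid_pos_pref,
                                  n_hybrid, conf = 0.95) {
  stopifnot(parental_pos_pref >= 0, parental_pos_pref <= 100,
            hybrid_pos_pref >= 0, hybrid_pos_pref <= 100)
  if (n_hybrid <= 0) stop("n_hybrid must be positive")
  x <- round(hybrid_pos_pref / 100 * n_hybrid)
  ci <- 100 * binom.test(x, n_hybrid, conf.level = conf)$conf.int
  inside <- parental_pos_pref >= ci[1] && parental_pos_pref <= ci[2]
  list(parental_pos_pref = parental_pos_pref,
       hybrid_pos_pref = hybrid_pos_pref,
       deviation = hybrid_pos_pref - parental_pos_pref,
       conf_int = as.numeric(ci), baseline_inside = inside,
       consistent_with_no_ase = inside)
}

#' Write metrics as JSON or TSV
#'
#' @param panels Named list of `po_metrics`.
#' @param path Output path (`.json` or `.tsv`).
#' @export
write_metrics <- function(panels, path) {
  if (grepl("\\.json$", path)) {
    vals <- lapply(panels, function(p) p[METRIC_FIELDS])
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    write.table(format_comparison_table(panels), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
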