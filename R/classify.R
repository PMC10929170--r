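#' Random forest configuration
#'
#' Defaults follow the standard library configuration of a random
#' forest classifier: 100 trees, Gini impurity splits, square-root of
#' the feature count candidate features per split, fully grown trees.
#' More trees were not found to help this task, so the defaults are a
#' sensible fixed point; all are configurable.
#'
#' @param n_trees Number of trees, at least 1.
#' @param mtry Candidate features per split; `NULL` means
#'   `floor(sqrt(p))`.
#' @param min_node_size Minimal terminal node size (1 = fully grown).
#' @param class_weights Optional named weights (`P1`, `P2`) for
#'   bias mitigation; off by default.
#' @param seed Integer seed for training and for the 0.5-probability
#'   tie-break coin.
#' @return A `po_model_config` list.
#' @export
model_config <- function(n_trees = 100L, mtry = NULL, min_node_size = 1L,
                         class_weights = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "po_model_config")
}

#' Parent-of-origin from the aligner's choice on concatenated references
#'
#' Baseline A: the aligner is run once against the concatenation of the
#' two parental references and its primary alignment per read pair
#' decides the parent. This decider reads nothing but the reference
#' identity of the primary alignment; ties are impossible.
#'
#' @param alignments Filtered alignment records from a run against the
#'   concatenated references.
#' @param parent_of_ref Named character vector mapping each reference
#'   sequence name to `"P1"` or `"P2"`, or a function of ref names.
#' @return A prediction data.frame: read_id, predicted_parent, score
#'   (NA; baselines carry no probability), was_tie (FALSE).
#' @export
concat_reference_choice <- function(alignments, parent_of_ref) {
  r1 <- alignments[alignments$mate == "R1", , drop = FALSE]
  parent <- if (is.function(parent_of_ref)) {
    parent_of_ref(r1$ref_name)
  } else {
    unname(parent_of_ref[r1$ref_name])
  }
  bad <- unique(r1$ref_name[is.na(parent)])
  if (length(bad) > 0L)
    stop("reference name(s) not resolvable to a parent: ",
         paste(head(bad, 5L), collapse = ", "))
  if (!all(parent %in% c("P1", "P2")))
    stop("parent_of_ref must map to 'P1' or 'P2'")
  data.frame(read_id = r1$read_id, predicted_parent = parent,
             score = NA_real_, was_tie = FALSE, stringsAsFactors = FALSE)
}

#' Parent-of-origin from alignment-score comparison
#'
#' Baseline B: for each read pair aligned to both parents, the summed
#' alignment score AS(R1) + AS(R2) per parent decides; strictly greater
#' wins, equal scores are a tie broken uniformly at random (so the
#' statistics stay comparable across deciders). This decider reads
#' nothing but the four AS values.
#'
#' @param features A feature table from [build_feature_table()] (only
#'   the four AS columns are consulted).
#' @param seed Seed for the tie-break coin.
#' @return Prediction data.frame (read_id, predicted_parent, score = NA,
#'   was_tie) with attribute `ties_fraction`.
#' @export
score_comparison_choice <- function(features, seed = 1L) {
  s1 <- features$P1_R1_AS + features$P1_R2_AS
  s2 <- features$P2_R1_AS + features$P2_R2_AS
  pred <- ifelse(s2 > s1, "P2", "P1")
  tie <- s2 == s1
  if (any(tie)) {
    rs <- local_seed(seed, runif(sum(tie)))
    pred[tie] <- ifelse(rs < 0.5, "P1", "P2")
  }
  out <- data.frame(read_id = features$read_id, predicted_parent = pred,
                    score = NA_real_, was_tie = tie,
                    stringsAsFactors = FALSE)
  attr(out, "ties_fraction") <- mean(tie)
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

feature_cols <- function(table) {
  fn <- feature_names()
  missing <- setdiff(fn, colnames(table))
  if (length(missing) > 0L)
    stop("table is missing feature column(s): ",
         paste(head(missing, 5L), collapse = ", "))
  table[, fn, drop = FALSE]
}

#' Train the random forest post-processor
#'
#' Fits a probability random forest over the 53 alignment features to
#' predict the parent of origin. The fitted model carries its feature
#' schema, configuration and seed, and refuses to predict on tables
#' whose schema differs.
#'
#' @param train_table Feature table with a `label` column containing
#'   both `"P1"` and `"P2"`.
#' @param cfg A [model_config()].
#' @return A `po_model` object.
#' @export
train_model <- function(train_table, cfg = model_config()) {
  x <- feature_cols(train_table)
  bad <- vapply(x, function(col) any(!is.finite(col)), logical(1L))
  if (any(bad))
    stop("non-finite values in feature column(s): ",
         paste(names(x)[bad], collapse = ", "))
  y <- train_table$label
  if (!all(c("P1", "P2") %in% y))
    stop("training data must contain both classes (P1 and P2)")
  mtry <- if (is.null(cfg$mtry)) floor(sqrt(ncol(x))) else cfg$mtry
  fit <- ranger::ranger(
    x = x, y = factor(y, levels = c("P1", "P2")),
    num.trees = cfg$n_trees, mtry = mtry, splitrule = "gini",
    min.node.size = cfg$min_node_size, probability = TRUE,
    importance = "impurity", class.weights = cfg$class_weights,
    seed = cfg$seed, num.threads = 1L)
  structure(list(forest = fit, schema = feature_names(), config = cfg,
                 seed = cfg$seed),
            class = "po_model")
}

#' @export
print.po_model <- function(x, ...) {
  cat("Parent-of-origin random forest:", x$config$n_trees, "trees,",
      length(x$schema), "features, seed", x$seed, "\n")
  invisible(x)
}

#' Predict parent of origin with a trained model
#'
#' The predicted parent is P2 when the forest's P2 probability exceeds
#' 0.5; a probability of exactly 0.5 is broken by a seeded coin and
#' recorded. Probabilities are retained for AUROC/AUPRC.
#'
#' @param object A `po_model`.
#' @param table A feature table matching the model's schema.
#' @param ... Unused.
#' @return Prediction data.frame: read_id, predicted_parent, score (the
#'   P2 probability), was_tie (FALSE; attribute `coin_broken` flags rows
#'   decided by the 0.5 coin).
#' @export
predict.po_model <- function(object, table, ...) {
  if (nrow(table) == 0L)
    return(data.frame(read_id = character(0),
                      predicted_parent = character(0),
                      score = numeric(0), was_tie = logical(0)))
  have <- colnames(table)
  differ <- c(setdiff(object$schema, have))
  if (length(differ) > 0L)
    stop("feature schema mismatch; missing column(s): ",
         paste(head(differ, 5L), collapse = ", "))
  x <- table[, object$schema, drop = FALSE]
  p <- predict(object$forest, data = x, num.threads = 1L)$predictions
  p2 <- p[, "P2"]
  pred <- ifelse(p2 > 0.5, "P2", "P1")
  at_half <- p2 == 0.5
  if (any(at_half)) {
    rs <- local_seed(object$seed + 1L, runif(sum(at_half)))
    pred[at_half] <- ifelse(rs < 0.5, "P1", "P2")
  }
  out <- data.frame(read_id = table$read_id, predicted_parent = pred,
                    score = p2, was_tie = FALSE, stringsAsFactors = FALSE)
  attr(out, "coin_broken") <- at_half
  out
}

#' Feature importance (mean decrease in impurity)
#'
#' Gini impurity importances of the trained forest, normalized to sum
#' to one and sorted in descending order.
#'
#' @param model A `po_model`.
#' @param k Report the top k features (default: all).
#' @return A data.frame: feature, importance.
#' @export
feature_importance <- function(model, k = Inf) {
  if (!inherits(model, "po_model"))
    stop("model must be a trained po_model")
  imp <- model$forest$variable.importance
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  imp <- sort(imp, decreasing = TRUE)
  head(data.frame(feature = names(imp), importance = unname(imp),
                  stringsAsFactors = FALSE), k)
}

#' Stratified k-fold cross-validation
#'
#' Splits the labeled table into k stratified folds, trains on k-1 and
#' evaluates the metrics panel on the held-out fold.
#'
#' @param table Labeled feature table.
#' @param k Number of folds, at least 2.
#' @param cfg A [model_config()].
#' @return A list with `folds` (per-fold metric data.frame), `mean` and
#'   `sd` rows.
#' @export
cross_validate <- function(table, k = 5L, cfg = model_config()) {
  stopifnot(k >= 2L)
  y <- table$label
  if (min(table(y)) < k)
    stop("each class needs at least k = ", k, " members")
  fold <- integer(nrow(table))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  rows <- lapply(seq_len(k), function(f) {
    fit <- train_model(table[fold != f, , drop = FALSE], cfg)
    te <- table[fold == f, , drop = FALSE]
    pr <- predict(fit, te)
    cm <- confusion(pr$predicted_parent, te$label)
    as.data.frame(metrics_panel(cm, scores = pr$score,
                                truth = te$label)[METRIC_FIELDS])
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = colMeans(folds, na.rm = TRUE),
       sd = apply(folds, 2, sd, na.rm = TRUE))
}
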