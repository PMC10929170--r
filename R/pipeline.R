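#' Run the full parent-of-origin pipeline on a simulated scenario
#'
#' Generates the scenario's references and reads, writes ground-truth
#' SAM files (one per parental reference, plus the concatenated-
#' reference run), loads and filters them back through the SAM reader,
#' joins read pairs across parents, extracts the 53-feature table,
#' mixes the two parental streams into a balanced interleaved hybrid,
#' splits train/test, trains the random forest, and evaluates all three
#' deciders side by side on the held-out test set.
#'
#' @param scenario A [sim_scenario()] (or a preset from
#'   [scenario_suite()]).
#' @param cfg A [model_config()]; defaults to the scenario seed.
#' @param split A [split_config()].
#' @param dir Working directory for SAM files (a temporary directory by
#'   default, removed afterwards unless supplied).
#' @return A list: `features` (full labeled feature table), `split`,
#'   `model`, `predictions` (per decider), `panels` (per decider
#'   metrics), `comparison` (formatted table), `ties_fraction`,
#'   `counts`, `sim`.
#' @export
run_pipeline <- function(scenario, cfg = model_config(seed = scenario$seed),
                         split = split_config(), dir = NULL) {
  cleanup <- is.null(dir)
  if (is.null(dir)) dir <- tempfile("po_run")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (cleanup) on.exit(unlink(dir, recursive = TRUE), add = TRUE)

  sim <- simulate_hybrid_reads(scenario)
  sam1 <- file.path(dir, "vsP1.sam")
  sam2 <- file.path(dir, "vsP2.sam")
  samc <- file.path(dir, "concat.sam")
  emit_truth_sam(sim, "P1", sam1)
  emit_truth_sam(sim, "P2", sam2)
  emit_concat_sam(sim, samc)

  al1 <- load_filtered_alignments(sam1)
  al2 <- load_filtered_alignments(sam2)
  joined <- join_by_read(al1, al2)
  labels <- setNames(sim$pairs$origin, sim$pairs$read_id)
  features <- build_feature_table(joined$both, max_q = scenario$max_q_char,
                                  labels = labels)

  mixed <- mix_hybrid(features[features$label == "P1", , drop = FALSE],
                      features[features$label == "P2", , drop = FALSE],
                      ratio = scenario$mix_ratio)
  sp <- split_train_test(mixed, split)
  model <- train_model(sp$train, cfg)
  truth <- sp$test$label

  pred_rf <- predict(model, sp$test)
  pred_as <- score_comparison_choice(sp$test, seed = cfg$seed + 7L)
  alc <- load_filtered_alignments(samc)
  pred_al <- concat_reference_choice(alc,
                                     function(rn) substr(rn, 1L, 2L))
  pred_al <- pred_al[match(sp$test$read_id, pred_al$read_id), ,
                     drop = FALSE]

  panels <- list(
    aligner = metrics_panel(confusion(pred_al$predicted_parent, truth)),
    score = metrics_panel(confusion(pred_as$predicted_parent, truth),
                          ties_fraction = attr(pred_as, "ties_fraction")),
    model = metrics_panel(confusion(pred_rf$predicted_parent, truth),
                          scores = pred_rf$score, truth = truth))

  list(scenario = scenario, features = features, split = sp,
       model = model,
       predictions = list(aligner = pred_al, score = pred_as,
                          model = pred_rf),
       panels = panels,
       comparison = format_comparison_table(panels),
       ties_fraction = attr(pred_as, "ties_fraction"),
       counts = c(joined$counts,
                  n_train = nrow(sp$train), n_test = nrow(sp$test)),
       sim = sim)
}
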