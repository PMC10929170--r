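#' Join alignments to the two parents by read pair
#'
#' Pairs the filtered alignment streams from the two parental references
#' by read id (mates resolved from the SAM flag, never file adjacency).
#' Read pairs with complete alignments (both mates) to both references
#' go to the joined stream that feeds feature extraction; pairs aligning
#' to exactly one parent are reported separately — exclusive maps are
#' poor indicators of the true parent and never enter the model.
#'
#' Joined read ids follow the order of first appearance in the
#' parent-1 stream ("first N" is defined on this order).
#'
#' @param p1_alignments,p2_alignments Filtered alignment records from
#'   [load_filtered_alignments()], one per parental reference.
#' @return A list with `both` (a `po_joined` object: `read_id` plus
#'   aligned record frames `p1r1`, `p1r2`, `p2r1`, `p2r2`), `single`
#'   (data.frame read_id, side), and `counts`.
#' @export
join_by_read <- function(p1_alignments, p2_alignments) {
  split_mates <- function(al, which_parent) {
    for (m in c("R1", "R2")) {
      ids <- al$read_id[al$mate == m]
      if (anyDuplicated(ids))
        stop("duplicate primary alignment for read '",
             ids[duplicated(ids)][1L], "' (", m, ") in the ",
             which_parent, " stream; input violates the one primary ",
             "alignment per read pair assumption")
    }
    list(R1 = al[al$mate == "R1", , drop = FALSE],
         R2 = al[al$mate == "R2", , drop = FALSE])
  }
  p1 <- split_mates(p1_alignments, "P1")
  p2 <- split_mates(p2_alignments, "P2")
  complete <- function(side)
    intersect(side$R1$read_id, side$R2$read_id)
  ids1 <- complete(p1)
  ids2 <- complete(p2)
  # preserve P1-file order of first appearance
  ids1 <- ids1[order(match(ids1, p1_alignments$read_id))]
  both_ids <- ids1[ids1 %in% ids2]
  pick <- function(df, ids) {
    out <- df[match(ids, df$read_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  both <- structure(list(read_id = both_ids,
                         p1r1 = pick(p1$R1, both_ids),
                         p1r2 = pick(p1$R2, both_ids),
                         p2r1 = pick(p2$R1, both_ids),
                         p2r2 = pick(p2$R2, both_ids)),
                    class = "po_joined")
  only1 <- setdiff(ids1, ids2)
  only2 <- setdiff(ids2, ids1)
  single <- data.frame(
    read_id = c(only1, only2),
    side = rep(c("P1", "P2"), c(length(only1), length(only2))),
    stringsAsFactors = FALSE)
  list(both = both, single = single,
       counts = c(both_parents = length(both_ids),
                  p1_only = length(only1), p2_only = length(only2)))
}

#' Mix labeled parental read pairs into a simulated hybrid
#'
#' Combines two labeled streams (e.g. feature-table rows for read pairs
#' of known parent 1 and parent 2 origin) at the given mixing ratio,
#' balanced to the available supply. At the default 50:50 ratio with
#' interleaving, even and odd positions come from different parents, so
#' any prefix of the stream is class-balanced.
#'
#' @param p1_rows,p2_rows Data.frames of labeled read pairs (stream
#'   order respected; the first rows of each are used).
#' @param ratio Fraction of the output drawn from `p1_rows`, in (0,1).
#' @param interleave Alternate parents along the output stream.
#' @return A data.frame; deterministic given the inputs.
#' @export
mix_hybrid <- function(p1_rows, p2_rows, ratio = 0.5, interleave = TRUE) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1")
  if (nrow(p1_rows) == 0L || nrow(p2_rows) == 0L)
    stop("both parental streams must be non-empty")
  total <- min(floor(nrow(p1_rows) / ratio),
               floor(nrow(p2_rows) / (1 - ratio)))
  n1 <- floor(total * ratio)
  n2 <- total - n1
  if (abs(ratio - 0.5) < 1e-12) n1 <- n2 <- min(n1, n2)  # exact balance
  if (n1 < nrow(p1_rows) || n2 < nrow(p2_rows))
    message("mix_hybrid: balanced to supply, using ", n1, " + ", n2,
            " pairs")
  a <- p1_rows[seq_len(n1), , drop = FALSE]
  b <- p2_rows[seq_len(n2), , drop = FALSE]
  out <- rbind(a, b)
  if (interleave) {
    # generalized round robin: spread each stream evenly along the output
    key <- c((seq_len(n1) - 0.5) / n1, (seq_len(n2) - 0.25) / n2)
    out <- out[order(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Train/test split configuration
#'
#' @param n Total number of read pairs used (the first `n` of the
#'   stream); `NULL` uses all.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param holdout_refs Optional reference sequence names; pairs whose
#'   alignment to either parent hits one of these go to the test set
#'   regardless of position (group holdout for generalization checks).
#' @param seed Integer seed recorded with the split.
#' @return A `po_split_config` list.
#' @export
split_config <- function(n = NULL, train_fraction = 0.8,
                         holdout_refs = NULL, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(n)) stopifnot(n >= 2L)
  structure(list(n = n, train_fraction = train_fraction,
                 holdout_refs = holdout_refs, seed = as.integer(seed)),
            class = "po_split_config")
}

#' Split a labeled stream into training and testing sets
#'
#' Deterministic positional split: the first
#' `floor(train_fraction * n)` pairs train, the remainder test, in
#' stream order (input order is FASTQ order, essentially random). When
#' `holdout_refs` is set, all pairs whose parent-1 or parent-2
#' reference name is listed are moved to the test set regardless of
#' position, so no held-out reference sequence leaks into training.
#'
#' @param rows A feature table (or any data.frame with `p1_ref`/`p2_ref`
#'   columns when holdout is used).
#' @param cfg A [split_config()].
#' @return A list with `train` and `test` data.frames.
#' @export
split_train_test <- function(rows, cfg = split_config()) {
  n_avail <- nrow(rows)
  n <- cfg$n
  if (is.null(n)) n <- n_avail
  if (n > n_avail) {
    warning("requested n = ", n, " but only ", n_avail,
            " pairs available; using all")
    n <- n_avail
  }
  rows <- rows[seq_len(n), , drop = FALSE]
  held <- rep(FALSE, n)
  if (!is.null(cfg$holdout_refs)) {
    held <- rows$p1_ref %in% cfg$holdout_refs |
            rows$p2_ref %in% cfg$holdout_refs
  }
  main <- which(!held)
  n_train <- floor(cfg$train_fraction * length(main))
  if (n_train < 1L)
    stop("holdout leaves no training data")
  train <- rows[main[seq_len(n_train)], , drop = FALSE]
  test <- rows[sort(c(main[-seq_len(n_train)], which(held))), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Write a JSON run manifest
#'
#' Records counts, seeds and configuration sufficient to replay a run.
#'
#' @param path Output path.
#' @param ... Named entries (scalars, vectors or lists).
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
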