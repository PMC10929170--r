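ALIGNER_FACING <- c("AS", "ED", "MM", "HQMM", "GO", "GE", "INS", "HQINS",
                    "DEL", "HQDEL")
BLOCKS <- c("P1_R1", "P1_R2", "P2_R1", "P2_R2")
DIFF_FEATURES <- c("AS", "ED", "MM", "HQMM", "GO", "GE", "INS", "DEL",
                   "HQINS", "HQDEL", "MAT")

#' The frozen 53-feature schema
#'
#' Column names of the feature vector, in fixed order: the 10
#' aligner-facing counts (AS, ED, MM, HQMM, GO, GE, INS, HQINS, DEL,
#' HQDEL) for each of the four read-to-reference alignments (P1 R1,
#' P1 R2, P2 R1, P2 R2; 40 features), then the 11 parent-2-minus-parent-1
#' differences (the above plus MAT, the matched-base count), the span
#' difference, and PARENT, the better-alignment-score indicator (+1 when
#' parent 2's summed alignment score is greater, -1 when parent 1's is,
#' 0 when tied). Raw match counts, raw spans and read lengths are never
#' features — only their differences — so a model cannot key on
#' library-specific read geometry.
#'
#' @return Character vector of length 53 with attribute `n_per_read`
#'   (40), the number of per-read-alignment features.
#' @export
feature_names <- function() {
  per_read <- as.vector(t(outer(BLOCKS, ALIGNER_FACING, paste, sep = "_")))
  nm <- c(per_read, paste0(DIFF_FEATURES, "_diff"), "SPAN_diff", "PARENT")
  stopifnot(length(nm) == 53L)
  attr(nm, "n_per_read") <- length(per_read)
  nm
}

#' Count alignment events from CIGAR, MD and base qualities
#'
#' Parses the CIGAR string and (when present) the MD string of one or
#' more alignments and counts mismatches (MM), high-quality mismatches
#' (HQMM), gap opens (GO, the number of distinct indel runs), gap
#' extends (GE, total bases in indel runs), inserted and deleted bases
#' (INS/DEL) with their high-quality variants, and matched bases (MAT).
#' High-quality means the base-call quality equals `max_q` for the one
#' read base involved in a mismatch or insertion, and for both read
#' bases flanking a deletion (a deletion at the alignment edge, with
#' only one flanking base, is never high-quality). Soft-clipped bases
#' are treated as aligned-and-mismatched: each S base increments MM
#' (and HQMM when maximal quality) and the aligned length, never MAT —
#' so MM can exceed the NM tag. N (skipped intron) operations consume
#' reference span only.
#'
#' When MD is absent, MM falls back to `max(0, NM - INS - DEL)`; the
#' mismatch positions are then unknown, so those mismatches contribute
#' nothing to HQMM (only soft-clipped bases, whose qualities are known,
#' still can).
#'
#' @param cigar Character vector of CIGAR strings.
#' @param md Character vector of MD strings (NA when absent).
#' @param base_quals Character vector of quality strings (`"*"` or NA
#'   when absent; then no event is high-quality).
#' @param nm Integer vector of NM tag values (used only for the
#'   MD-absent fallback).
#' @param max_q Maximal quality character, e.g. `"F"`.
#' @return A data.frame with columns MM, HQMM, GO, GE, INS, HQINS, DEL,
#'   HQDEL, MAT, aligned_len, span and err (0 = ok, 1 = MD inconsistent
#'   with CIGAR, 2 = invalid CIGAR/quality length).
#' @export
parse_alignment_events <- function(cigar, md = NA_character_,
                                   base_quals = NA_character_,
                                   nm = NA_integer_, max_q = "F") {
  n <- length(cigar)
  md <- rep_len(as.character(md), n)
  base_quals <- rep_len(as.character(base_quals), n)
  nm <- rep_len(as.integer(nm), n)
  m <- as.data.frame(parse_events_cpp(as.character(cigar), md, base_quals,
                                      nm, max_q))
  rownames(m) <- NULL
  data.frame(m[c("MM", "HQMM", "GO", "GE", "INS", "HQINS", "DEL",
                 "HQDEL", "MAT")],
             aligned_len = m$ALN, span = m$SPAN, err = m$ERR)
}

#' Per-read-alignment feature block
#'
#' Converts filtered alignment records into the 10 aligner-facing
#' features plus MAT and reference span. AS and ED are copied verbatim
#' from the AS and NM tags (ED is not recomputed; the extractor's own
#' mismatch count can exceed it under the soft-clip rule); the event
#' counts come from [parse_alignment_events()].
#'
#' @param records A data.frame of alignment records
#'   (see [load_filtered_alignments()]).
#' @param max_q Maximal quality character.
#' @return A data.frame with one row per record: read_id, mate,
#'   ref_name, ref_pos, AS, ED, MM, HQMM, GO, GE, INS, HQINS, DEL,
#'   HQDEL, MAT, span.
#' @export
read_block <- function(records, max_q = "F") {
  ev <- parse_alignment_events(records$cigar, records$md,
                               records$base_quals,
                               records$edit_distance_tag, max_q)
  if (any(ev$err == 1L))
    warning(sum(ev$err == 1L),
            " record(s) with MD inconsistent with CIGAR, e.g. ",
            records$read_id[which(ev$err == 1L)[1L]])
  out <- data.frame(read_id = records$read_id, mate = records$mate,
                    ref_name = records$ref_name, ref_pos = records$ref_pos,
                    AS = records$align_score,
                    ED = records$edit_distance_tag,
                    ev[c("MM", "HQMM", "GO", "GE", "INS", "HQINS",
                         "DEL", "HQDEL", "MAT", "span")],
                    err = ev$err,
                    stringsAsFactors = FALSE)
  out
}

block_matrix <- function(block) {
  as.matrix(block[, ALIGNER_FACING, drop = FALSE])
}

#' Build the 53-feature table for joined read pairs
#'
#' Lays out, for every read pair aligned to both parents, the feature
#' vector defined by [feature_names()]: four 10-feature blocks, eleven
#' parent-2-minus-parent-1 differences (each the sum over the pair's
#' alignments to parent 2 minus the equivalent sum for parent 1), the
#' span difference, and the better-alignment-score indicator. The pair
#' span per parent is the length of the read pair's projection onto the
#' reference, computed from coordinates (rightmost alignment end minus
#' leftmost start, inclusive), which equals |TLEN| for proper pairs.
#'
#' @param joined A `po_joined` object from [join_by_read()].
#' @param max_q Maximal quality character.
#' @param labels Optional named character vector (names = read ids)
#'   giving the true parent (`"P1"`/`"P2"`); pairs without an entry get
#'   label `"unknown"`.
#' @return A data.frame: read_id, label, p1_ref, p2_ref, then the 53
#'   feature columns in frozen order.
#' @export
build_feature_table <- function(joined, max_q = "F", labels = NULL) {
  stopifnot(inherits(joined, "po_joined"))
  blocks <- lapply(joined[c("p1r1", "p1r2", "p2r1", "p2r2")],
                   read_block, max_q = max_q)
  n <- length(joined$read_id)
  feats <- matrix(0L, nrow = n, ncol = 53L,
                  dimnames = list(NULL, feature_names()))
  for (b in seq_along(BLOCKS))
    feats[, ((b - 1L) * 10L + 1L):(b * 10L)] <- block_matrix(blocks[[b]])
  p2sum <- function(col) blocks$p2r1[[col]] + blocks$p2r2[[col]]
  p1sum <- function(col) blocks$p1r1[[col]] + blocks$p1r2[[col]]
  for (f in DIFF_FEATURES)
    feats[, paste0(f, "_diff")] <- p2sum(f) - p1sum(f)
  span_pair <- function(a, b) {
    pmax(a$ref_pos + a$span - 1L, b$ref_pos + b$span - 1L) -
      pmin(a$ref_pos, b$ref_pos) + 1L
  }
  feats[, "SPAN_diff"] <- span_pair(blocks$p2r1, blocks$p2r2) -
                          span_pair(blocks$p1r1, blocks$p1r2)
  feats[, "PARENT"] <- sign(p2sum("AS") - p1sum("AS"))
  lab <- rep("unknown", n)
  if (!is.null(labels)) {
    hit <- match(joined$read_id, names(labels))
    lab[!is.na(hit)] <- unname(labels[hit[!is.na(hit)]])
  }
  data.frame(read_id = joined$read_id, label = lab,
             p1_ref = blocks$p1r1$ref_name, p2_ref = blocks$p2r1$ref_name,
             feats, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Feature vector for a single read pair
#'
#' Convenience wrapper over [build_feature_table()] for one quartet of
#' alignment records (one row each for R1 and R2 against each parent).
#'
#' @param p1r1,p1r2,p2r1,p2r2 Single-row alignment record data.frames.
#' @param max_q Maximal quality character.
#' @return A one-row feature table.
#' @export
pair_feature_vector <- function(p1r1, p1r2, p2r1, p2r2, max_q = "F") {
  joined <- structure(list(read_id = p1r1$read_id,
                           p1r1 = p1r1, p1r2 = p1r2,
                           p2r1 = p2r1, p2r2 = p2r2),
                      class = "po_joined")
  build_feature_table(joined, max_q = max_q)
}

#' Write a feature table as TSV
#'
#' One row per read pair: read_id, label, then the 53 named feature
#' columns in frozen order (the header line carries the schema).
#'
#' @param table A feature table from [build_feature_table()].
#' @param path Output path; a `.gz` suffix gzips the output.
#' @export
write_feature_table <- function(table, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
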