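#' Alignment filter policy
#'
#' Mirrors the samtools filtering applied ahead of feature extraction:
#' `-f 2` (proper pair), `-F 256` (drop secondary alignments; supplementary
#' alignments are dropped with them so no read is double-counted) and
#' `-q 1` (minimum mapping quality). Aligners that report MAPQ 255
#' ("unavailable") pass the numeric threshold and are accepted.
#'
#' @param require_proper_pair Keep only reads mapped in a proper pair.
#' @param primary_only Drop secondary (0x100) and supplementary (0x800)
#'   alignments.
#' @param min_mapq Minimum mapping quality, non-negative integer.
#' @return A `po_filter_policy` list.
#' @export
filter_policy <- function(require_proper_pair = TRUE, primary_only = TRUE,
                          min_mapq = 1L) {
  min_mapq <- as.integer(min_mapq)
  stopifnot(length(min_mapq) == 1L, !is.na(min_mapq), min_mapq >= 0L)
  structure(list(require_proper_pair = isTRUE(require_proper_pair),
                 primary_only = isTRUE(primary_only),
                 min_mapq = min_mapq),
            class = "po_filter_policy")
}

#' Load and filter alignments from a SAM or BAM file
#'
#' Reads a SAM (text) or BAM file and returns one row per retained
#' alignment with the fields and optional tags (AS, NM, MD, XM, XO, XG)
#' that feature extraction needs. Unmapped, secondary, supplementary,
#' non-proper-pair and low-MAPQ records are removed according to
#' `policy`. Records missing the required AS or NM tags, and records
#' whose CIGAR query length disagrees with the stored sequence, cannot
#' feed feature extraction; they are skipped and counted. Input order is
#' preserved.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param policy A [filter_policy()].
#' @return A data.frame of alignment records (columns `read_id`, `mate`,
#'   `ref_name`, `ref_pos`, `mapq`, `flag`, `cigar`, `tlen`,
#'   `align_score`, `edit_distance_tag`, `md`, `base_quals`, `seq_len`),
#'   with attribute `skip_counts` recording how many records each filter
#'   removed.
#' @export
load_filtered_alignments <- function(path, policy = filter_policy()) {
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to parse SAM/BAM file '", path,
                               "': ", conditionMessage(e)))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize",
            "seq", "qual")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = c("AS", "NM", "MD", "XM", "XO", "XG"))
  res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e) stop("failed to read '", path, "': ",
                                           conditionMessage(e)))
  tg <- res$tag
  n <- length(res$qname)
  as_int <- function(x) if (is.null(x)) rep(NA_integer_, n) else as.integer(x)
  as_chr <- function(x) if (is.null(x)) rep(NA_character_, n) else as.character(x)
  df <- data.frame(
    read_id = as.character(res$qname),
    mate = ifelse(bitwAnd(res$flag, 0x40L) > 0L, "R1",
                  ifelse(bitwAnd(res$flag, 0x80L) > 0L, "R2", NA_character_)),
    ref_name = as.character(res$rname),
    ref_pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    flag = as.integer(res$flag),
    cigar = as.character(res$cigar),
    tlen = as.integer(res$isize),
    align_score = as_int(tg$AS),
    edit_distance_tag = as_int(tg$NM),
    md = as_chr(tg$MD),
    xm = as_int(tg$XM),
    xo = as_int(tg$XO),
    xg = as_int(tg$XG),
    base_quals = as.character(res$qual),
    seq_len = nchar(as.character(res$seq)),
    stringsAsFactors = FALSE
  )
  filter_alignments(df, policy)
}

#' Apply a filter policy to alignment records
#'
#' The record-level counterpart of [load_filtered_alignments()]; applying
#' it to its own output changes nothing (filtering is idempotent).
#'
#' @param records A data.frame of alignment records.
#' @param policy A [filter_policy()].
#' @return The retained records, input order preserved, with attribute
#'   `skip_counts`.
#' @export
filter_alignments <- function(records, policy = filter_policy()) {
  n0 <- nrow(records)
  keep <- bitwAnd(records$flag, 0x4L) == 0L          # mapped
  n_unmapped <- n0 - sum(keep)
  n_secondary <- 0L
  if (policy$primary_only) {
    pre <- sum(keep)
    keep <- keep & bitwAnd(records$flag, 0x100L) == 0L &
                   bitwAnd(records$flag, 0x800L) == 0L
    n_secondary <- pre - sum(keep)
  }
  n_improper <- 0L
  if (policy$require_proper_pair) {
    pre <- sum(keep)
    keep <- keep & bitwAnd(records$flag, 0x2L) > 0L
    n_improper <- pre - sum(keep)
  }
  pre <- sum(keep)
  keep <- keep & !is.na(records$mapq) & records$mapq >= policy$min_mapq
  n_mapq <- pre - sum(keep)
  # records without AS or NM cannot feed feature extraction
  tagless <- keep & (is.na(records$align_score) |
                     is.na(records$edit_distance_tag))
  keep <- keep & !tagless
  # CIGAR query length must agree with SEQ
  qlen <- cigar_query_length(records$cigar)
  bad <- keep & !is.na(records$seq_len) & records$seq_len > 0L &
         (is.na(qlen) | qlen != records$seq_len)
  if (any(bad))
    warning("skipping ", sum(bad),
            " record(s) whose CIGAR length disagrees with SEQ, e.g. ",
            records$read_id[which(bad)[1L]])
  keep <- keep & !bad
  bad_mate <- keep & is.na(records$mate)
  keep <- keep & !bad_mate
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skip_counts") <- c(
    total = n0, kept = nrow(out), unmapped = n_unmapped,
    secondary_or_supplementary = n_secondary, improper_pair = n_improper,
    mapq = n_mapq, missing_as_nm = sum(tagless), bad_cigar = sum(bad),
    bad_mate_flag = sum(bad_mate))
  out
}

# Query-consuming CIGAR length (M/I/S/=/X), vectorised.
cigar_query_length <- function(cigar) {
  m <- parse_events_cpp(cigar, rep(NA_character_, length(cigar)),
                        rep(NA_character_, length(cigar)),
                        rep(0L, length(cigar)), "F")
  len <- m[, "ALN"]
  len[m[, "ERR"] == 2L] <- NA_integer_
  len
}

#' Detect the maximal base-call quality character
#'
#' Scans a sample of quality strings and returns the maximum quality
#' character observed. The maximal quality encoding (e.g. `'F'` for
#' modern Illumina, `'K'` for some older chemistry) parameterises the
#' high-quality event counts; auto-detection is a convenience and can
#' always be overridden by supplying the character explicitly.
#'
#' @param records Alignment records (or a character vector of quality
#'   strings).
#' @param n_sample Number of records to inspect, at least 1.
#' @return A single character.
#' @export
detect_max_quality_char <- function(records, n_sample = 1000L) {
  stopifnot(n_sample >= 1L)
  qs <- if (is.character(records)) records else records$base_quals
  qs <- head(qs, n_sample)
  qs <- qs[!is.na(qs) & qs != "*" & nzchar(qs)]
  if (length(qs) == 0L)
    stop("no quality strings available (all '*'); supply the maximum ",
         "quality character explicitly")
  ints <- unlist(lapply(qs, utf8ToInt), use.names = FALSE)
  intToUtf8(max(ints))
}
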