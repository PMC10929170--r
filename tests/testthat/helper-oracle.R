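# Independent padded-alignment oracle: builds a random alignment
# column-by-column, derives the CIGAR/MD/quality encoding from the
# columns, and counts events directly from the column states. Used to
# cross-check the package's CIGAR/MD parser on randomized cases.

ORACLE_BASES <- c("A", "C", "G", "T")

# One random alignment. Column types: match, mm (mismatch), ins, del;
# optional soft clips at either end. Deletions never touch the
# alignment edges (aligners do not emit leading/trailing D).
random_alignment <- function(max_q = "F", low_q = "#", p_hq = 0.6) {
  repeat {
    n_col <- sample(5:60, 1)
    type <- sample(c("match", "mm", "ins", "del"), n_col, replace = TRUE,
                   prob = c(0.7, 0.12, 0.09, 0.09))
    if (type[1] == "del" || type[n_col] == "del") next
    # adjacent I/D runs are never emitted by real aligners and have no
    # canonical MD encoding; keep indel runs separated by aligned bases
    adj <- (type[-1] == "ins" & type[-n_col] == "del") |
           (type[-1] == "del" & type[-n_col] == "ins")
    if (!any(adj)) break
  }
  s_lead <- sample(0:3, 1, prob = c(0.6, 0.2, 0.1, 0.1))
  s_trail <- sample(0:3, 1, prob = c(0.6, 0.2, 0.1, 0.1))

  ref <- character(0)     # reference base per non-ins column
  read <- character(0)    # read bases in order (incl. soft clips)
  qual <- character(0)
  ops <- character(0)     # per-column op for cigar construction

  rand_base <- function() sample(ORACLE_BASES, 1)
  rand_q <- function() if (runif(1) < p_hq) max_q else low_q

  for (i in seq_len(s_lead)) {
    read <- c(read, rand_base()); qual <- c(qual, rand_q())
    ops <- c(ops, "S")
  }
  col_type <- character(0)
  col_ref <- character(0)
  col_qual <- character(0)  # quality of the read base (NA for del)
  for (i in seq_len(n_col)) {
    if (type[i] == "match") {
      b <- rand_base()
      q <- rand_q()
      read <- c(read, b); qual <- c(qual, q)
      col_type <- c(col_type, "match"); col_ref <- c(col_ref, b)
      col_qual <- c(col_qual, q)
      ops <- c(ops, "M")
    } else if (type[i] == "mm") {
      rb <- rand_base()
      qb <- sample(setdiff(ORACLE_BASES, rb), 1)
      q <- rand_q()
      read <- c(read, qb); qual <- c(qual, q)
      col_type <- c(col_type, "mm"); col_ref <- c(col_ref, rb)
      col_qual <- c(col_qual, q)
      ops <- c(ops, "M")
    } else if (type[i] == "ins") {
      q <- rand_q()
      read <- c(read, rand_base()); qual <- c(qual, q)
      col_type <- c(col_type, "ins"); col_ref <- c(col_ref, NA)
      col_qual <- c(col_qual, q)
      ops <- c(ops, "I")
    } else {
      col_type <- c(col_type, "del"); col_ref <- c(col_ref, rand_base())
      col_qual <- c(col_qual, NA)
      ops <- c(ops, "D")
    }
  }
  for (i in seq_len(s_trail)) {
    read <- c(read, rand_base()); qual <- c(qual, rand_q())
    ops <- c(ops, "S")
  }

  r <- rle(ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")

  # MD from the non-ins columns
  md <- ""
  m_run <- 0L
  i <- 1L
  keep <- col_type != "ins"
  ct <- col_type[keep]; cr <- col_ref[keep]
  while (i <= length(ct)) {
    if (ct[i] == "match") {
      m_run <- m_run + 1L
      i <- i + 1L
    } else if (ct[i] == "mm") {
      md <- paste0(md, m_run, cr[i])
      m_run <- 0L
      i <- i + 1L
    } else {  # del run
      j <- i
      while (j <= length(ct) && ct[j] == "del") j <- j + 1L
      md <- paste0(md, m_run, "^", paste(cr[i:(j - 1L)], collapse = ""))
      m_run <- 0L
      i <- j
    }
  }
  md <- paste0(md, m_run)

  # expected counts, straight from the column states
  is_hq <- function(q) !is.na(q) & q == max_q
  mm_cols <- col_type == "mm"
  ins_cols <- col_type == "ins"
  del_cols <- col_type == "del"
  # quality of read bases flanking each del run: read index per column
  ridx <- cumsum(col_type != "del") + s_lead  # read pos after this column
  readlen <- length(read)
  runs <- rle(col_type)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hqdel <- 0L
  for (k in which(runs$values == "del")) {
    left <- if (starts[k] == 1L) s_lead else ridx[starts[k] - 1L]
    right <- left + 1L
    if (left >= 1L && right <= readlen &&
        qual[left] == max_q && qual[right] == max_q)
      hqdel <- hqdel + runs$lengths[k]
  }
  indel_runs <- sum(runs$values %in% c("ins", "del"))

  expected <- list(
    MM = sum(mm_cols) + s_lead + s_trail,
    HQMM = sum(is_hq(col_qual[mm_cols])) +
      sum(qual[seq_len(s_lead)] == max_q) +
      sum(qual[seq(length.out = s_trail,
                   from = length(qual) - s_trail + 1L)] == max_q),
    GO = indel_runs,
    GE = sum(ins_cols) + sum(del_cols),
    INS = sum(ins_cols),
    HQINS = sum(is_hq(col_qual[ins_cols])),
    DEL = sum(del_cols),
    HQDEL = hqdel,
    MAT = sum(col_type == "match"),
    aligned_len = length(read),
    span = sum(col_type != "ins"))

  list(cigar = cigar, md = md, qual = paste(qual, collapse = ""),
       read = paste(read, collapse = ""),
       nm = sum(mm_cols) + sum(ins_cols) + sum(del_cols),
       expected = expected)
}

# --- independent metric oracles ----------------------------------------

# closed-form implementations of the printed metric formulas
oracle_panel <- function(TP, FP, TN, FN) {
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  tot <- TP + FP + TN + FN
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(accuracy = 100 * (TP + TN) / tot,
       sensitivity = 100 * TP / (TP + FN),
       specificity = 100 * TN / (TN + FP),
       precision = 100 * TP / (TP + FP),
       f1 = 200 * TP / (2 * TP + FP + FN),
       mcc = if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den),
       pos_pref = 100 * (TP + FP) / tot)
}

# O(n^2) rank-free AUROC oracle: fraction of (positive, negative) pairs
# ranked correctly, ties counted half
oracle_auroc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# --- minimal record builders -------------------------------------------

make_record <- function(read_id = "r1", mate = "R1", ref_name = "t1",
                        ref_pos = 1L, mapq = 42L, flag = 99L,
                        cigar = "100M", tlen = 250L, align_score = 0L,
                        edit_distance_tag = 0L, md = "100",
                        base_quals = strrep("F", 100L), seq_len = 100L) {
  data.frame(read_id = read_id, mate = mate, ref_name = ref_name,
             ref_pos = ref_pos, mapq = mapq, flag = flag, cigar = cigar,
             tlen = tlen, align_score = align_score,
             edit_distance_tag = edit_distance_tag, md = md,
             base_quals = base_quals, seq_len = seq_len,
             stringsAsFactors = FALSE)
}

# A tiny SAM file with controllable records; returns the path.
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           refs = c(t1 = 2000L, t2 = 2000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(hdr, records), path)
  path
}

# One SAM line; tags supplied ready-formatted, seq generated to length.
sam_line <- function(qname = "r1", flag = 99L, rname = "t1", pos = 1L,
                     mapq = 42L, cigar = "10M", rnext = "=", pnext = 200L,
                     tlen = 250L, seq = strrep("A", 10L),
                     qual = strrep("F", 10L),
                     tags = "AS:i:0\tNM:i:0\tMD:Z:10") {
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
        qual, tags, sep = "\t")
}

# Hand-built alignment quartet: P1 alignments clean, P2 degraded.
quartet_records <- function() {
  p1r1 <- make_record(mate = "R1", ref_name = "P1_t001", ref_pos = 101L,
                      align_score = 0L, edit_distance_tag = 0L,
                      md = "100")
  p1r2 <- make_record(mate = "R2", ref_name = "P1_t001", ref_pos = 251L,
                      flag = 147L, align_score = -6L,
                      edit_distance_tag = 1L, md = "40T59",
                      base_quals = paste0(strrep("F", 40L), ",",
                                          strrep("F", 59L)))
  p2r1 <- make_record(mate = "R1", ref_name = "P2_t001", ref_pos = 98L,
                      cigar = "60M2D40M", align_score = -23L,
                      edit_distance_tag = 3L, md = "10A49^CA40")
  p2r2 <- make_record(mate = "R2", ref_name = "P2_t001", ref_pos = 260L,
                      flag = 147L, align_score = -12L,
                      edit_distance_tag = 2L, md = "5G5G88")
  list(p1r1 = p1r1, p1r2 = p1r2, p2r1 = p2r1, p2r2 = p2r2)
}

# Toy labeled 53-feature table for classifier tests.
make_toy_table <- function(n = 200L, informative = TRUE, seed = 42L) {
  withr::with_seed(seed, {
    fn <- feature_names()
    label <- rep(c("P1", "P2"), length.out = n)
    feats <- matrix(rnorm(n * 53L), nrow = n, dimnames = list(NULL, fn))
    if (informative)
      feats[, "PARENT"] <- ifelse(label == "P2", 1, -1)
    data.frame(read_id = sprintf("t%05d", seq_len(n)), label = label,
               p1_ref = "P1_t001", p2_ref = "P2_t001", feats,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
}
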