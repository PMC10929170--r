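test_that("event parsing matches the worked examples", {
  allF <- strrep("F", 100L)
  # perfect alignment
  ev <- parse_alignment_events("100M", "100", allF, 0L, "F")
  expect_equal(ev[c("MM", "GO", "GE", "MAT", "span")],
               data.frame(MM = 0L, GO = 0L, GE = 0L, MAT = 100L,
                          span = 100L))
  # soft clip counts as an aligned mismatch
  ev <- parse_alignment_events("1S99M", "99", allF, 0L, "F")
  expect_equal(ev$MM, 1L)
  expect_equal(ev$HQMM, 1L)
  expect_equal(ev$MAT, 99L)
  expect_equal(ev$aligned_len, 100L)
  # deletion with both flanking read bases at max quality
  ev <- parse_alignment_events("50M2D50M", "50^AC50", allF, 2L, "F")
  expect_equal(ev[c("DEL", "HQDEL", "GO", "GE", "MM")],
               data.frame(DEL = 2L, HQDEL = 2L, GO = 1L, GE = 2L, MM = 0L))
  # same deletion with one low-quality flank is not high-quality
  q <- paste0(strrep("F", 49L), ",", strrep("F", 50L))
  ev <- parse_alignment_events("50M2D50M", "50^AC50", q, 2L, "F")
  expect_equal(ev$HQDEL, 0L)
  # insertion below max quality
  q <- paste0(strrep("F", 30L), ",", strrep("F", 30L))
  ev <- parse_alignment_events("30M1I30M", "60", q, 1L, "F")
  expect_equal(ev[c("INS", "HQINS", "GO", "GE")],
               data.frame(INS = 1L, HQINS = 0L, GO = 1L, GE = 1L))
})

test_that("edge deletions are never high-quality", {
  # trailing deletion: only one flanking read base exists
  ev <- parse_alignment_events("100M2D", "100^AC", strrep("F", 100L),
                               2L, "F")
  expect_equal(ev$DEL, 2L)
  expect_equal(ev$HQDEL, 0L)
})

test_that("spliced and =/X CIGARs are handled", {
  ev <- parse_alignment_events("50M200N50M", "100", strrep("F", 100L),
                               0L, "F")
  expect_equal(ev$span, 300L)
  expect_equal(ev$MAT, 100L)
  ev <- parse_alignment_events("30=1X69=", "30A69", strrep("F", 100L),
                               1L, "F")
  expect_equal(ev$MM, 1L)
  expect_equal(ev$MAT, 99L)
})

test_that("MD-absent fallback is NM-consistent", {
  ev <- parse_alignment_events("50M1I49M", NA, strrep("F", 100L), 4L, "F")
  expect_equal(ev$MM, 3L)   # NM - INS - DEL
  expect_equal(ev$HQMM, 0L)
  ev <- parse_alignment_events("100M", NA, strrep("F", 100L), 0L, "F")
  expect_equal(ev$MM, 0L)
})

test_that("inconsistent MD is flagged, invalid CIGAR rejected", {
  ev <- parse_alignment_events("100M", "90", strrep("F", 100L), 0L, "F")
  expect_equal(ev$err, 1L)
  ev <- parse_alignment_events("100M", "50^A49", strrep("F", 100L), 1L, "F")
  expect_equal(ev$err, 1L)
  ev <- parse_alignment_events("abc", "100", strrep("F", 100L), 0L, "F")
  expect_equal(ev$err, 2L)
  ev <- parse_alignment_events("90M", "90", strrep("F", 100L), 0L, "F")
  expect_equal(ev$err, 2L)  # quality length disagrees
})

test_that("parser agrees with the padded-alignment oracle on random cases", {
  withr::with_seed(7, {
    for (i in 1:300) {
      a <- random_alignment()
      ev <- parse_alignment_events(a$cigar, a$md, a$qual, a$nm, "F")
      expect_equal(ev$err, 0L, info = a$cigar)
      got <- as.list(ev[names(a$expected)])
      expect_equal(got, lapply(a$expected, as.integer),
                   info = paste(a$cigar, a$md), ignore_attr = TRUE)
      # MD-absent fallback recovers the same mismatch total
      ev2 <- parse_alignment_events(a$cigar, NA, a$qual, a$nm, "F")
      expect_equal(ev2$MM, ev$MM, info = a$cigar)
      expect_equal(ev2$MAT, ev$MAT, info = a$cigar)
    }
  })
})

test_that("no-clip invariant: MM + GE equals the recomputed edit distance", {
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- random_alignment()
      if (grepl("S", a$cigar)) next
      ev <- parse_alignment_events(a$cigar, a$md, a$qual, a$nm, "F")
      expect_equal(ev$MM + ev$GE, a$nm)
    }
  })
})

test_that("read_block copies AS and ED verbatim from tags", {
  rec <- make_record(cigar = "1S99M", md = "99", align_score = -5L,
                     edit_distance_tag = 0L)
  blk <- read_block(rec)
  expect_equal(blk$AS, -5L)
  expect_equal(blk$ED, 0L)   # NM verbatim
  expect_equal(blk$MM, 1L)   # soft-clip rule: MM exceeds NM
  expect_gt(blk$MM, blk$ED)
  # spliced span
  rec <- make_record(cigar = "50M200N50M", md = "100")
  expect_equal(read_block(rec)$span, 300L)
})

test_that("the feature schema is frozen at 53 named columns", {
  fn <- feature_names()
  expect_length(fn, 53L)
  expect_equal(attr(fn, "n_per_read"), 40L)
  expect_equal(fn[1], "P1_R1_AS")
  expect_equal(fn[41], "AS_diff")
  expect_equal(fn[52], "SPAN_diff")
  expect_equal(fn[53], "PARENT")
  # raw matched counts, spans and read lengths are never features
  expect_false(any(grepl("MAT$", fn[1:40])))
  expect_false("MAT" %in% fn)
  expect_false("SPAN" %in% fn)
  expect_equal(sum(grepl("^SPAN", fn)), 1L)
})

test_that("pair feature vector lays out Table-style features exactly", {
  q <- quartet_records()
  fv <- pair_feature_vector(q$p1r1, q$p1r2, q$p2r1, q$p2r2)
  expect_equal(ncol(fv) - 4L, 53L)  # read_id, label, p1_ref, p2_ref + 53
  # spreadsheet-style expectations
  expect_equal(fv$P1_R1_AS, 0)
  expect_equal(fv$P2_R1_AS, -23)
  expect_equal(fv$AS_diff, (-23 + -12) - (0 + -6))       # -29
  expect_equal(fv$ED_diff, (3 + 2) - (0 + 1))            # 4
  expect_equal(fv$MM_diff, (1 + 2) - (0 + 1))            # 2
  expect_equal(fv$HQMM_diff, (1 + 2) - (0 + 0))          # P1 R2 mm low qual
  expect_equal(fv$GO_diff, 1)
  expect_equal(fv$GE_diff, 2)
  expect_equal(fv$DEL_diff, 2)
  expect_equal(fv$HQDEL_diff, 2)                          # flanks all F
  expect_equal(fv$MAT_diff, (99 + 98) - (100 + 99))      # -2
  # spans: P1 = (251+100-1) - 101 + 1 = 250 ; P2 = (260+100-1) - 98 + 1 = 262
  expect_equal(fv$SPAN_diff, 262 - 250)
  expect_equal(fv$PARENT, -1)                             # P1 score greater
})

test_that("swapping the parents negates diffs and swaps the blocks", {
  q <- quartet_records()
  fv <- pair_feature_vector(q$p1r1, q$p1r2, q$p2r1, q$p2r2)
  sw <- pair_feature_vector(q$p2r1, q$p2r2, q$p1r1, q$p1r2)
  for (f in c(paste0(c("AS", "ED", "MM", "HQMM", "GO", "GE", "INS", "DEL",
                       "HQINS", "HQDEL", "MAT"), "_diff"), "SPAN_diff",
              "PARENT"))
    expect_equal(sw[[f]], -fv[[f]], info = f)
  for (f in c("AS", "ED", "MM", "HQMM", "GO", "GE", "INS", "HQINS",
              "DEL", "HQDEL")) {
    expect_equal(sw[[paste0("P1_R1_", f)]], fv[[paste0("P2_R1_", f)]])
    expect_equal(sw[[paste0("P2_R2_", f)]], fv[[paste0("P1_R2_", f)]])
  }
})

test_that("identical alignments to both parents zero out every comparison", {
  r1 <- make_record(mate = "R1")
  r2 <- make_record(mate = "R2", flag = 147L, ref_pos = 251L)
  fv <- pair_feature_vector(r1, r2, r1, r2)
  diffs <- grep("_diff$|^PARENT$", feature_names(), value = TRUE)
  expect_true(all(unlist(fv[diffs]) == 0))
})

test_that("feature tables round-trip through TSV", {
  tab <- make_toy_table(10L)
  p <- tempfile(fileext = ".tsv")
  write_feature_table(tab, p)
  back <- read.delim(p, check.names = FALSE)
  expect_equal(colnames(back), colnames(tab))
  expect_equal(back$PARENT, tab$PARENT)
})
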