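small_scenario <- function(...) {
  sim_scenario(n_transcripts = 12L, transcript_len = 800L,
               n_pairs_per_parent = 60L, ...)
}

modifyList2 <- function(sc, ...) {
  args <- list(...)
  for (nm in names(args)) sc[[nm]] <- args[[nm]]
  sc
}

test_that("reference construction is deterministic and rate-faithful", {
  sc <- small_scenario(seed = 55L)
  r1 <- make_parent_references(sc)
  r2 <- make_parent_references(sc)
  expect_identical(vapply(r1$transcripts, parent_seq, "", parent = "P1"),
                   vapply(r2$transcripts, parent_seq, "", parent = "P1"))
  # substitution count within binomial error of expectation
  sc2 <- sim_scenario(n_transcripts = 40L, transcript_len = 2500L,
                      divergence_snp_rate = 0.05,
                      divergence_indel_rate = 0, seed = 56L)
  refs <- make_parent_references(sc2)
  L <- 40L * 2500L
  n_snp <- sum(refs$variants$type == "snp")
  expect_lt(abs(n_snp - L * 0.05), 4 * sqrt(L * 0.05 * 0.95))
})

test_that("zero divergence yields byte-identical parents", {
  sc <- small_scenario(divergence_snp_rate = 0, divergence_indel_rate = 0)
  refs <- make_parent_references(sc)
  expect_identical(vapply(refs$transcripts, parent_seq, "", parent = "P1"),
                   vapply(refs$transcripts, parent_seq, "", parent = "P2"))
  expect_equal(nrow(refs$variants), 0L)
})

test_that("FASTA output matches the internal sequences", {
  sc <- small_scenario(seed = 60L)
  refs <- make_parent_references(sc)
  d <- tempfile()
  paths <- write_references(refs, d)
  fa <- readLines(paths[1])
  expect_equal(sum(startsWith(fa, ">")), sc$n_transcripts)
  expect_equal(fa[2], parent_seq(refs$transcripts[[1]], "P1"))
})

test_that("error-free reads are exact reference substrings", {
  sc <- small_scenario(seq_error_rate = 0, seed = 57L)
  sim <- simulate_hybrid_reads(sc)
  own <- sim$ledger[sim$ledger$target == sim$ledger$origin, ]
  expect_true(all(own$MM == 0))
  expect_true(all(own$AS == 0))
  # spot-check a read against the reference sequence
  refs <- sim$refs
  i <- which(sim$ledger$origin == "P1" & sim$ledger$target == "P1")[1]
  row <- sim$ledger[i, ]
  t <- sim$pairs$transcript[match(row$read_id, sim$pairs$read_id)]
  seq <- parent_seq(refs$transcripts[[t]], "P1")
  rd <- sim$reads$seq[sim$reads$read_id == row$read_id &
                      sim$reads$mate == row$mate]
  expect_equal(substr(seq, row$pos, row$pos + sc$read_len - 1L), rd)
})

test_that("sequencing error counts track the configured rate", {
  sc <- sim_scenario(n_transcripts = 20L, transcript_len = 1500L,
                     n_pairs_per_parent = 1000L, seq_error_rate = 0.01,
                     divergence_snp_rate = 0.02, seed = 58L)
  sim <- simulate_hybrid_reads(sc)
  own <- sim$ledger[sim$ledger$target == sim$ledger$origin, ]
  n_bases <- nrow(own) * sc$read_len
  observed <- sum(own$MM)
  expect_lt(abs(observed - n_bases * 0.01),
            4 * sqrt(n_bases * 0.01 * 0.99))
})

test_that("simulation is reproducible under the seed", {
  sc <- small_scenario(seed = 59L)
  s1 <- simulate_hybrid_reads(sc)
  s2 <- simulate_hybrid_reads(sc)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$reads, s2$reads)
})

test_that("SAM output carries proper FR pair flags and consistent TLEN", {
  sc <- small_scenario(seed = 61L)
  sim <- simulate_hybrid_reads(sc)
  p <- tempfile(fileext = ".sam")
  emit_truth_sam(sim, "P1", p)
  lines <- grep("^@", readLines(p), invert = TRUE, value = TRUE)
  f <- read.delim(text = lines, header = FALSE)
  expect_setequal(unique(f$V2), c(99L, 147L))
  r1 <- f[f$V2 == 99L, ]; r2 <- f[f$V2 == 147L, ]
  expect_equal(r1$V9, -r2$V9)             # opposite TLEN signs
  expect_equal(r1$V8, r2$V4)              # PNEXT points at the mate
  expect_true(all(abs(r1$V9) >= 2L * sc$read_len - 20L))
  expect_true(all(nchar(f$V10) == sc$read_len))
  expect_true(all(nchar(f$V11) == sc$read_len))
})

test_that("alignments to the non-true parent accrue the variant differences", {
  sc <- small_scenario(divergence_snp_rate = 0.03,
                       divergence_indel_rate = 0,
                       seq_error_rate = 0, seed = 62L)
  sim <- simulate_hybrid_reads(sc)
  refs <- sim$refs
  cross <- sim$ledger[sim$ledger$target != sim$ledger$origin &
                      sim$ledger$aligned, ]
  # per read: mismatches against the wrong parent equal the number of
  # variant positions inside the read window (no indels, no errors)
  for (i in head(seq_len(nrow(cross)), 50L)) {
    row <- cross[i, ]
    t <- sim$pairs$transcript[match(row$read_id, sim$pairs$read_id)]
    v <- refs$variants
    v <- v[v$transcript == t & v$type == "snp", ]
    pos_col <- if (row$target == "P2") "p2_pos" else "p1_pos"
    k <- sum(v[[pos_col]] >= row$pos &
             v[[pos_col]] <= row$pos + sc$read_len - 1L)
    expect_equal(row$MM, k, info = row$read_id)
  }
})

test_that("FASTQ mates are emitted in sequencing orientation", {
  sc <- small_scenario(seq_error_rate = 0, seed = 63L)
  sim <- simulate_hybrid_reads(sc)
  pre <- tempfile()
  paths <- emit_fastq(sim, pre)
  fq2 <- readLines(paths[2])
  id <- sub("^@", "", sub("/2$", "", fq2[1]))
  stored <- sim$reads$seq[sim$reads$read_id == id & sim$reads$mate == "R2"]
  revcomp <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(stored, "")[[1]]), collapse = ""))
  expect_equal(fq2[2], revcomp)
})

test_that("presets are reproducible and declare their mechanisms", {
  suite <- scenario_suite()
  expect_named(suite, c("zero_divergence", "low_divergence", "congeneric"))
  expect_equal(suite$zero_divergence$divergence_snp_rate, 0)
  expect_gt(suite$congeneric$tie_rate, 0)
  expect_match(suite$congeneric$tie_mechanism, "planted")
  s1 <- simulate_hybrid_reads(
    modifyList2(suite$low_divergence, n_pairs_per_parent = 30L))
  s2 <- simulate_hybrid_reads(
    modifyList2(suite$low_divergence, n_pairs_per_parent = 30L))
  expect_identical(s1$ledger, s2$ledger)
})

test_that("planted ties produce exact alignment-score ties with signal", {
  sc <- sim_scenario(n_transcripts = 20L, transcript_len = 1500L,
                     n_pairs_per_parent = 300L, tie_rate = 0.9,
                     divergence_snp_rate = 0.05,
                     divergence_indel_rate = 0.002, seed = 64L)
  sim <- simulate_hybrid_reads(sc)
  planted <- sim$pairs$read_id[sim$pairs$tie_planted]
  led <- sim$ledger[sim$ledger$aligned & sim$ledger$read_id %in% planted, ]
  s <- tapply(led$AS, list(led$read_id, led$target), sum)
  complete <- rowSums(is.na(s)) == 0
  expect_gt(sum(complete), 200L)
  expect_true(all(s[complete, 1] == s[complete, 2]))
})
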