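SIM_BASES <- c("A", "C", "G", "T")

#' Synthetic hybrid benchmark scenario
#'
#' Parameters of a simulated hybrid RNA-seq benchmark: two parental
#' transcriptome references diverged from a common ancestor at given
#' substitution and indel rates, paired 2 x `read_len` reads with
#' sequencing errors, a two-level base-quality model (maximal quality
#' character versus one lower character, so high-quality event counts
#' are binary-testable), and an optional planted alignment-score-tie
#' mechanism (see [scenario_suite()]).
#'
#' Sequencing-error bases receive the low quality character with
#' probability `1 - error_hq_prob`: quality is informative about error,
#' the idealisation that lets quality-aware features separate true
#' sequence divergence from sequencing noise.
#'
#' @param n_transcripts Number of transcripts per parent.
#' @param transcript_len Transcript length (scalar, or length-2 range).
#' @param divergence_snp_rate Substitutions per site between parents.
#' @param divergence_indel_rate Indel events per site between parents.
#' @param indel_len_geometric_p Geometric parameter of indel lengths.
#' @param read_len Read length (default 100).
#' @param insert_mean,insert_sd Fragment length distribution; fragments
#'   are truncated below at `2 * read_len` so mates never overlap.
#' @param seq_error_rate Per-base substitution error rate.
#' @param hq_fraction Fraction of (error-free) bases at maximal quality.
#' @param error_hq_prob Probability an error base keeps maximal quality.
#' @param max_q_char,low_q_char The two quality characters.
#' @param n_pairs_per_parent Read pairs simulated per parent.
#' @param mix_ratio Hybrid mixing ratio (fraction from parent 1).
#' @param tie_rate Fraction of pairs with a planted alignment-score tie.
#' @param seed Integer seed; every simulator draw derives from it.
#' @param name Scenario name.
#' @return A `po_scenario` list.
#' @export
sim_scenario <- function(n_transcripts = 80L, transcript_len = 1200L,
                         divergence_snp_rate = 0.05,
                         divergence_indel_rate = 0.002,
                         indel_len_geometric_p = 0.5,
                         read_len = 100L, insert_mean = 250,
                         insert_sd = 30, seq_error_rate = 0.005,
                         hq_fraction = 0.9, error_hq_prob = 0.05,
                         max_q_char = "F", low_q_char = ",",
                         n_pairs_per_parent = 1000L, mix_ratio = 0.5,
                         tie_rate = 0, seed = 1L, name = "custom") {
  rates <- c(divergence_snp_rate, divergence_indel_rate, seq_error_rate,
             tie_rate)
  stopifnot(all(rates >= 0), all(rates < 1),
            indel_len_geometric_p > 0, indel_len_geometric_p <= 1,
            hq_fraction >= 0, hq_fraction <= 1,
            error_hq_prob >= 0, error_hq_prob <= 1,
            read_len > 0, read_len <= insert_mean,
            n_pairs_per_parent >= 1L, mix_ratio > 0, mix_ratio < 1,
            all(transcript_len > 0), n_transcripts >= 1L,
            nchar(max_q_char) == 1L, nchar(low_q_char) == 1L)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 transcript_len = as.integer(transcript_len),
                 divergence_snp_rate = divergence_snp_rate,
                 divergence_indel_rate = divergence_indel_rate,
                 indel_len_geometric_p = indel_len_geometric_p,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 seq_error_rate = seq_error_rate,
                 hq_fraction = hq_fraction,
                 error_hq_prob = error_hq_prob,
                 max_q_char = max_q_char, low_q_char = low_q_char,
                 n_pairs_per_parent = as.integer(n_pairs_per_parent),
                 mix_ratio = mix_ratio, tie_rate = tie_rate,
                 seed = as.integer(seed), name = name),
            class = "po_scenario")
}

#' Named benchmark presets
#'
#' Three fully seeded presets spanning the divergence regimes of
#' interest:
#' \describe{
#'   \item{zero_divergence}{Identical parents — the null control. Every
#'     pair's alignments to the two references are identical, the
#'     PARENT feature is identically zero, and no decider can beat
#'     coin-flipping.}
#'   \item{low_divergence}{Within-species-like divergence (0.05\%
#'     substitutions per site), where most read pairs cover no variant
#'     site and score comparison sits barely above 50\%.}
#'   \item{congeneric}{Between-congener-like divergence (5\%
#'     substitutions, plus indels) with a planted alignment-score tie
#'     in 15\% of pairs. The planted mechanism (declared in
#'     `$tie_mechanism`): sequencing errors are placed at covered
#'     variant sites so the mismatch counts against the two parents are
#'     exactly equal — an alignment-score tie — while the surviving
#'     variant mismatches against the wrong parent keep their natural
#'     (mostly maximal) base qualities. Score comparison must
#'     coin-flip these pairs; quality-aware features remain
#'     informative, the regime where the post-processor helps most.}
#' }
#'
#' @return Named list of `po_scenario` objects.
#' @export
scenario_suite <- function() {
  list(
    zero_divergence = sim_scenario(divergence_snp_rate = 0,
                                   divergence_indel_rate = 0,
                                   tie_rate = 0, seed = 101L,
                                   name = "zero_divergence"),
    low_divergence = sim_scenario(divergence_snp_rate = 5e-4,
                                  divergence_indel_rate = 1e-5,
                                  tie_rate = 0, seed = 102L,
                                  name = "low_divergence"),
    congeneric = local({
      s <- sim_scenario(divergence_snp_rate = 0.05,
                        divergence_indel_rate = 0.002,
                        tie_rate = 0.15, seed = 103L,
                        name = "congeneric")
      s$tie_mechanism <- paste(
        "planted: errors at covered variant sites equalise the",
        "per-parent mismatch counts (2c + h = k), so alignment scores",
        "tie while quality-aware features stay informative")
      s
    })
  )
}

#' Build the two diverged parental references
#'
#' Mutates an ancestral sequence per site into the two parents:
#' substitutions at `divergence_snp_rate` (the derived allele assigned
#' to a random parent) and indel events at `divergence_indel_rate` with
#' geometric lengths (the extra bases assigned to a random parent).
#' The construction keeps an explicit column-wise pairwise alignment of
#' the parents, from which both sequences, coordinate maps, the variant
#' table, and the exact homologous alignment of any read window are
#' derived. Deterministic under the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return A `po_references` object: per-transcript column alignment
#'   plus a `variants` data.frame.
#' @export
make_parent_references <- function(scenario) {
  stopifnot(inherits(scenario, "po_scenario"))
  local_seed(scenario$seed, {
    nt <- scenario$n_transcripts
    tl <- scenario$transcript_len
    transcripts <- vector("list", nt)
    varlist <- vector("list", nt)
    for (t in seq_len(nt)) {
      L <- if (length(tl) == 2L) sample(tl[1]:tl[2], 1L) else tl
      if (L <= 0L) stop("zero-length transcript")
      anc <- sample(SIM_BASES, L, replace = TRUE)
      a1 <- a2 <- anc
      snp <- which(runif(L) < scenario$divergence_snp_rate)
      if (length(snp) > 0L) {
        derived <- other_base(anc[snp])
        to_p2 <- runif(length(snp)) < 0.5
        a1[snp[!to_p2]] <- derived[!to_p2]
        a2[snp[to_p2]] <- derived[to_p2]
      }
      ev <- which(runif(L) < scenario$divergence_indel_rate)
      if (length(ev) > 0L) {
        lens <- rgeom(length(ev), scenario$indel_len_geometric_p) + 1L
        in_p1 <- runif(length(ev)) < 0.5
        for (j in rev(seq_along(ev))) {  # descending keeps indices valid
          g <- lens[j]
          extra <- sample(SIM_BASES, g, replace = TRUE)
          if (in_p1[j]) {
            a1 <- append(a1, extra, after = ev[j])
            a2 <- append(a2, rep("-", g), after = ev[j])
          } else {
            a1 <- append(a1, rep("-", g), after = ev[j])
            a2 <- append(a2, extra, after = ev[j])
          }
        }
      }
      h1 <- a1 != "-"
      h2 <- a2 != "-"
      var_col <- a1 != a2
      cum1 <- cumsum(h1)
      cum2 <- cumsum(h2)
      transcripts[[t]] <- list(
        a1 = a1, a2 = a2,
        has = list(P1 = h1, P2 = h2),
        col = list(P1 = which(h1), P2 = which(h2)),
        cum = list(P1 = cum1, P2 = cum2),
        len = c(P1 = sum(h1), P2 = sum(h2)),
        var_col = var_col,
        snp_col = var_col & h1 & h2,
        indel_col = xor(h1, h2))
      vc <- which(var_col)
      if (length(vc) > 0L)
        varlist[[t]] <- data.frame(
          transcript = t, column = vc,
          p1_pos = cum1[vc], p2_pos = cum2[vc],
          p1_allele = a1[vc], p2_allele = a2[vc],
          type = ifelse(h1[vc] & h2[vc], "snp",
                        ifelse(h1[vc], "ins_p1", "ins_p2")),
          stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, varlist[!vapply(varlist, is.null,
                                               logical(1L))])
    if (is.null(variants))
      variants <- data.frame(transcript = integer(0), column = integer(0),
                             p1_pos = integer(0), p2_pos = integer(0),
                             p1_allele = character(0),
                             p2_allele = character(0),
                             type = character(0))
    structure(list(transcripts = transcripts, variants = variants,
                   names = list(
                     P1 = sprintf("P1_t%03d", seq_len(nt)),
                     P2 = sprintf("P2_t%03d", seq_len(nt))),
                   scenario = scenario),
              class = "po_references")
  })
}

# one random base different from each element of `b`
other_base <- function(b) {
  alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                  "A", "C", "T",  "A", "C", "G"),
                nrow = 3L,
                dimnames = list(NULL, SIM_BASES))
  alt[cbind(sample.int(3L, length(b), replace = TRUE),
            match(b, SIM_BASES))]
}

# one random base different from both of a pair (b1 != b2 assumed)
neither_base <- function(b1, b2) {
  vapply(seq_along(b1), function(i) {
    sample(setdiff(SIM_BASES, c(b1[i], b2[i])), 1L)
  }, character(1L))
}

parent_seq <- function(tr, parent) {
  a <- if (parent == "P1") tr$a1 else tr$a2
  paste(a[tr$has[[parent]]], collapse = "")
}

#' Write the parental references as FASTA
#'
#' @param refs A `po_references`.
#' @param dir Output directory.
#' @return Paths of the two FASTA files (`P1.fa`, `P2.fa`).
#' @export
write_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(2L)
  for (p in c("P1", "P2")) {
    seqs <- vapply(refs$transcripts, parent_seq, character(1L), parent = p)
    names(seqs) <- refs$names[[p]]
    path <- file.path(dir, paste0(p, ".fa"))
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
    out[if (p == "P1") 1L else 2L] <- path
  }
  out
}

# MD string from mismatch read positions within an all-M alignment
md_from_mm <- function(rl, pos, refb) {
  if (length(pos) == 0L) return(as.character(rl))
  runs <- diff(c(0L, pos)) - 1L
  paste0(paste0(runs, refb, collapse = ""), rl - pos[length(pos)])
}

# MD string from a per-column classification (M/I/D), reference base per
# column and mismatch flag per column
md_from_cols <- function(cls, refb, mmflag) {
  r <- rle(cls)
  out <- character(0)
  m <- 0L
  pos <- 1L
  for (j in seq_along(r$values)) {
    len <- r$lengths[j]
    idx <- pos:(pos + len - 1L)
    if (r$values[j] == "M") {
      mm <- which(mmflag[idx])
      prev <- 0L
      for (q in mm) {
        out <- c(out, as.character(m + q - prev - 1L), refb[idx[q]])
        m <- 0L
        prev <- q
      }
      m <- m + len - (if (length(mm) > 0L) mm[length(mm)] else 0L)
    } else if (r$values[j] == "D") {
      out <- c(out, as.character(m),
               paste0("^", paste(refb[idx], collapse = "")))
      m <- 0L
    }
    pos <- pos + len
  }
  paste0(paste(out, collapse = ""), m)
}

cigar_from_cls <- function(cls) {
  r <- rle(cls)
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate hybrid read pairs with an exact ground-truth ledger
#'
#' Draws `n_pairs_per_parent` fragments from each parent's transcripts,
#' injects sequencing errors and two-level qualities, and constructs the
#' true alignment of every read against both parental references
#' directly from the reference column alignment — no realignment search,
#' so ground truth is exact. Event counts in the ledger are computed
#' column-by-column from the planted variants and errors, independently
#' of the CIGAR/MD text emitted to SAM. Against the true parent, event
#' counts reflect only sequencing errors. Alignment scores follow
#' end-to-end short-read scoring: 0 minus 6 per mismatch, 5 per gap
#' open, 3 per gap base.
#'
#' With `tie_rate > 0`, the designated fraction of pairs receives the
#' planted score-tie treatment described in [scenario_suite()].
#'
#' @param scenario A [sim_scenario()].
#' @param refs References from [make_parent_references()] (rebuilt when
#'   omitted).
#' @return A `po_sim` list: `pairs` (read_id, origin, transcript,
#'   tie_planted, aligned_both), `reads` (per-mate sequence and quality,
#'   fragment orientation), `ledger` (one row per read, mate and target
#'   parent with position, CIGAR, MD, AS, NM and every event count),
#'   `refs`, `scenario`.
#' @export
simulate_hybrid_reads <- function(scenario, refs = NULL) {
  stopifnot(inherits(scenario, "po_scenario"))
  if (is.null(refs)) refs <- make_parent_references(scenario)
  local_seed(scenario$seed + 1L, simulate_hybrid_reads_impl(scenario, refs))
}

simulate_hybrid_reads_impl <- function(scenario, refs) {
  n <- scenario$n_pairs_per_parent
  N <- 2L * n
  rl <- scenario$read_len
  e_rate <- scenario$seq_error_rate
  origins <- rep(c("P1", "P2"), each = n)
  read_id <- sprintf("rp%07d", seq_len(N))
  tie_planted <- runif(N) < scenario$tie_rate

  # per-mate stores (2 rows per pair: R1 then R2)
  seq_chr <- qual_chr <- character(2L * N)
  # ledger stores (4 rows per pair: R1/R2 x target P1/P2)
  ncol_led <- 4L * N
  led <- list(read_id = character(ncol_led), mate = character(ncol_led),
              origin = character(ncol_led), target = character(ncol_led),
              rname = character(ncol_led), pos = integer(ncol_led),
              cigar = character(ncol_led), md = character(ncol_led),
              AS = integer(ncol_led), NM = integer(ncol_led),
              MM = integer(ncol_led), HQMM = integer(ncol_led),
              GO = integer(ncol_led), GE = integer(ncol_led),
              INS = integer(ncol_led), HQINS = integer(ncol_led),
              DEL = integer(ncol_led), HQDEL = integer(ncol_led),
              MAT = integer(ncol_led), span = integer(ncol_led),
              aligned = logical(ncol_led))
  transcript_of <- integer(N)
  aligned_both <- logical(N)

  for (i in seq_len(N)) {
    o <- origins[i]
    x <- if (o == "P1") "P2" else "P1"
    planted <- tie_planted[i]
    tr <- NULL
    for (attempt in seq_len(80L)) {
      t <- sample.int(scenario$n_transcripts, 1L)
      cand <- refs$transcripts[[t]]
      Lo <- cand$len[[o]]
      ins <- max(2L * rl,
                 as.integer(round(rnorm(1L, scenario$insert_mean,
                                        scenario$insert_sd))))
      if (ins > Lo) next
      s <- sample.int(Lo - ins + 1L, 1L)
      w1 <- s:(s + rl - 1L)
      w2 <- (s + ins - rl):(s + ins - 1L)
      if (planted) {
        # the full column span of both read windows (including columns
        # where only the other parent has bases) must be indel-free to
        # keep the tie arithmetic exact
        cw1 <- cand$col[[o]][w1]
        cw2 <- cand$col[[o]][w2]
        span_cols <- c(cw1[1L]:cw1[rl], cw2[1L]:cw2[rl])
        if (any(cand$indel_col[span_cols])) next
      }
      tr <- cand
      break
    }
    if (is.null(tr))
      stop("could not place a fragment after 80 attempts; transcripts ",
           "too short for the insert distribution")
    transcript_of[i] <- t
    ao <- if (o == "P1") tr$a1 else tr$a2
    ax <- if (o == "P1") tr$a2 else tr$a1

    windows <- list(R1 = w1, R2 = w2)
    b <- b0 <- hq <- err <- cols <- list()
    for (m in c("R1", "R2")) {
      w <- windows[[m]]
      cw <- tr$col[[o]][w]
      cols[[m]] <- cw
      b0[[m]] <- ao[cw]
      hq[[m]] <- runif(rl) < scenario$hq_fraction
      cand_err <- if (planted) which(!tr$var_col[cw]) else seq_len(rl)
      ep <- cand_err[runif(length(cand_err)) < e_rate]
      bm <- b0[[m]]
      if (length(ep) > 0L) {
        bm[ep] <- other_base(bm[ep])
        hq[[m]][ep] <- runif(length(ep)) < scenario$error_hq_prob
      }
      b[[m]] <- bm
      err[[m]] <- ep
    }

    if (planted) {
      # positions (mate, read offset) of covered substitution variants
      sv <- lapply(c("R1", "R2"), function(m) {
        p <- which(tr$snp_col[cols[[m]]])
        if (length(p) > 0L) cbind(match(m, c("R1", "R2")), p) else NULL
      })
      sv <- do.call(rbind, sv)
      k <- if (is.null(sv)) 0L else nrow(sv)
      if (k > 0L) {
        ord <- sample.int(k)
        n_conv <- k %/% 2L
        conv <- sv[ord[seq_len(n_conv)], , drop = FALSE]
        neither <- if (k %% 2L == 1L) sv[ord[k], , drop = FALSE] else
          sv[0L, , drop = FALSE]
        for (j in seq_len(nrow(conv))) {
          m <- c("R1", "R2")[conv[j, 1L]]
          p <- conv[j, 2L]
          b[[m]][p] <- ax[cols[[m]][p]]
          hq[[m]][p] <- runif(1L) < scenario$error_hq_prob
          err[[m]] <- c(err[[m]], p)
        }
        for (j in seq_len(nrow(neither))) {
          m <- c("R1", "R2")[neither[j, 1L]]
          p <- neither[j, 2L]
          cc <- cols[[m]][p]
          b[[m]][p] <- neither_base(ao[cc], ax[cc])
          hq[[m]][p] <- runif(1L) < scenario$error_hq_prob
          err[[m]] <- c(err[[m]], p)
        }
        err <- lapply(err, sort)
      }
    }

    pair_aligned <- TRUE
    row0 <- (i - 1L) * 4L
    mate_row0 <- (i - 1L) * 2L
    for (mi in 1:2) {
      m <- c("R1", "R2")[mi]
      w <- windows[[m]]
      cw <- cols[[m]]
      ep <- err[[m]]
      hqm <- hq[[m]]
      seq_chr[mate_row0 + mi] <- paste(b[[m]], collapse = "")
      qual_chr[mate_row0 + mi] <- paste(
        ifelse(hqm, scenario$max_q_char, scenario$low_q_char),
        collapse = "")

      # alignment to the true parent: full-length match block
      E <- length(ep)
      r <- row0 + mi
      led$read_id[r] <- read_id[i]; led$mate[r] <- m
      led$origin[r] <- o; led$target[r] <- o
      led$rname[r] <- refs$names[[o]][t]
      led$pos[r] <- w[1L]
      led$cigar[r] <- paste0(rl, "M")
      led$md[r] <- md_from_mm(rl, ep, b0[[m]][ep])
      led$MM[r] <- E
      led$HQMM[r] <- sum(hqm[ep])
      led$MAT[r] <- rl - E
      led$span[r] <- rl
      led$NM[r] <- E
      led$AS[r] <- -6L * E
      led$aligned[r] <- TRUE

      # alignment to the other parent through the column alignment
      cwf <- cw[1L]:cw[rl]
      oh <- tr$has[[o]][cwf]
      xh <- tr$has[[x]][cwf]
      cls <- ifelse(oh, ifelse(xh, "M", "I"), "D")
      r <- row0 + 2L + mi
      led$read_id[r] <- read_id[i]; led$mate[r] <- m
      led$origin[r] <- o; led$target[r] <- x
      led$rname[r] <- refs$names[[x]][t]
      if (!any(xh)) {
        pair_aligned <- FALSE
        next
      }
      ridx <- cumsum(oh)
      xb <- ax[cwf]
      readb <- b[[m]][pmax(ridx, 1L)]
      is_m <- cls == "M"
      mmflag <- is_m & readb != xb
      is_i <- cls == "I"
      rles <- rle(cls)
      starts <- cumsum(c(1L, rles$lengths))[seq_along(rles$lengths)]
      MM <- sum(mmflag)
      HQMM <- sum(hqm[ridx[mmflag]])
      INS <- sum(is_i)
      HQINS <- sum(hqm[ridx[is_i]])
      DEL <- sum(cls == "D")
      GO <- sum(rles$values != "M")
      GE <- INS + DEL
      HQDEL <- 0L
      for (j in which(rles$values == "D")) {
        left <- ridx[starts[j]]
        if (left >= 1L && left + 1L <= rl && hqm[left] && hqm[left + 1L])
          HQDEL <- HQDEL + rles$lengths[j]
      }
      led$pos[r] <- tr$cum[[x]][cwf[which(xh)[1L]]]
      led$cigar[r] <- cigar_from_cls(cls)
      led$md[r] <- md_from_cols(cls, xb, mmflag)
      led$MM[r] <- MM; led$HQMM[r] <- HQMM
      led$GO[r] <- GO; led$GE[r] <- GE
      led$INS[r] <- INS; led$HQINS[r] <- HQINS
      led$DEL[r] <- DEL; led$HQDEL[r] <- HQDEL
      led$MAT[r] <- sum(is_m) - MM
      led$span[r] <- sum(cls != "I")
      led$NM[r] <- MM + INS + DEL
      led$AS[r] <- -6L * MM - 5L * GO - 3L * GE
      led$aligned[r] <- TRUE
    }
    aligned_both[i] <- pair_aligned
  }

  ledger <- as.data.frame(led, stringsAsFactors = FALSE)
  # a pair is usable against a parent only if both mates aligned
  structure(list(
    pairs = data.frame(read_id = read_id, origin = origins,
                       transcript = transcript_of,
                       tie_planted = tie_planted,
                       aligned_both = aligned_both,
                       stringsAsFactors = FALSE),
    reads = data.frame(read_id = rep(read_id, each = 2L),
                       mate = rep(c("R1", "R2"), N),
                       seq = seq_chr, qual = qual_chr,
                       stringsAsFactors = FALSE),
    ledger = ledger, refs = refs, scenario = scenario),
    class = "po_sim")
}

sam_header <- function(refs, parents) {
  sq <- character(0)
  for (p in parents) {
    lens <- vapply(refs$transcripts, function(tr) tr$len[[p]], numeric(1L))
    sq <- c(sq, sprintf("@SQ\tSN:%s\tLN:%d", refs$names[[p]],
                        as.integer(lens)))
  }
  c("@HD\tVN:1.6\tSO:unsorted", sq)
}

# rows: ledger rows for one target in pair order (R1,R2,R1,R2,...)
sam_body <- function(sim, rows) {
  rdkey <- paste(sim$reads$read_id, sim$reads$mate)
  r1 <- rows[rows$mate == "R1", , drop = FALSE]
  r2 <- rows[rows$mate == "R2", , drop = FALSE]
  stopifnot(all(r1$read_id == r2$read_id))
  plen <- pmax(r1$pos + r1$span, r2$pos + r2$span) - pmin(r1$pos, r2$pos)
  tlen1 <- ifelse(r1$pos <= r2$pos, plen, -plen)
  line <- function(rw, flag, pnext, tlen) {
    sr <- sim$reads[match(paste(rw$read_id, rw$mate), rdkey), ,
                    drop = FALSE]
    sprintf("%s\t%d\t%s\t%d\t42\t%s\t=\t%d\t%d\t%s\t%s\tAS:i:%d\tNM:i:%d\tMD:Z:%s",
            rw$read_id, flag, rw$rname, rw$pos, rw$cigar, pnext, tlen,
            sr$seq, sr$qual, rw$AS, rw$NM, rw$md)
  }
  l1 <- line(r1, 99L, r2$pos, tlen1)
  l2 <- line(r2, 147L, r1$pos, -tlen1)
  as.vector(rbind(l1, l2))  # interleave R1/R2 per pair
}

#' Emit a ground-truth SAM file
#'
#' Writes the simulated alignments of every read pair against one
#' parental reference: proper-pair primary records (flags 99/147), MAPQ
#' 42, exact POS/CIGAR/TLEN and AS/NM/MD tags consistent with the
#' planted events. Pairs the target parent cannot place (the homologous
#' window falls entirely in an indel) are omitted.
#'
#' @param sim A `po_sim` from [simulate_hybrid_reads()].
#' @param target `"P1"` or `"P2"`: which reference the records align to.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
emit_truth_sam <- function(sim, target, path) {
  stopifnot(target %in% c("P1", "P2"))
  rows <- sim$ledger[sim$ledger$target == target & sim$ledger$aligned, ,
                     drop = FALSE]
  ok <- rows$read_id %in% rows$read_id[duplicated(rows$read_id)]
  rows <- rows[ok, , drop = FALSE]  # both mates present
  writeLines(c(sam_header(sim$refs, target), sam_body(sim, rows)), path)
  invisible(path)
}

#' Emit a SAM of the aligner's choice on concatenated references
#'
#' Emulates running the aligner once against the concatenation of both
#' parental references: for every pair the side with the higher summed
#' alignment score is reported as the primary alignment; equal scores
#' go to the parent-1 reference, reproducing the reference-order bias
#' real aligners show when two targets are equally good.
#'
#' @inheritParams emit_truth_sam
#' @export
emit_concat_sam <- function(sim, path) {
  led <- sim$ledger
  # per pair: AS sums where both mates aligned to the target
  usable <- function(target) {
    rows <- led[led$target == target & led$aligned, , drop = FALSE]
    ids <- rows$read_id[duplicated(rows$read_id)]
    rows <- rows[rows$read_id %in% ids, , drop = FALSE]
    tapply(rows$AS, rows$read_id, sum)
  }
  s1 <- usable("P1")
  s2 <- usable("P2")
  ids <- union(names(s1), names(s2))
  a1 <- as.numeric(s1[ids]); a1[is.na(a1)] <- -Inf
  a2 <- as.numeric(s2[ids]); a2[is.na(a2)] <- -Inf
  choice <- ifelse(a2 > a1, "P2", "P1")  # ties fall to P1 deliberately
  pick <- paste(led$read_id, led$target) %in% paste(ids, choice)
  rows <- led[pick & led$aligned, , drop = FALSE]
  writeLines(c(sam_header(sim$refs, c("P1", "P2")), sam_body(sim, rows)),
             path)
  invisible(path)
}

#' Emit the simulated reads as FASTQ
#'
#' R2 is written as sequenced (reverse complement of the fragment
#' segment, reversed qualities).
#'
#' @param sim A `po_sim`.
#' @param prefix Output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @export
emit_fastq <- function(sim, prefix) {
  revcomp <- function(s)
    vapply(s, function(x) {
      chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]),
                                   collapse = ""))
    }, character(1L), USE.NAMES = FALSE)
  revstr <- function(s)
    vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
           character(1L), USE.NAMES = FALSE)
  out <- character(2L)
  for (mi in 1:2) {
    m <- c("R1", "R2")[mi]
    rd <- sim$reads[sim$reads$mate == m, , drop = FALSE]
    sq <- rd$seq
    qs <- rd$qual
    if (m == "R2") {
      sq <- revcomp(sq)
      qs <- revstr(qs)
    }
    path <- paste0(prefix, "_", m, ".fastq")
    writeLines(as.vector(rbind(paste0("@", rd$read_id, "/", mi),
                               sq, "+", qs)), path)
    out[mi] <- path
  }
  out
}
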