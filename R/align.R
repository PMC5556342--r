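#' Alignment strategies
#'
#' The four strategies compared by the evaluation framework:
#' * `best` - one best placement per read; among equally good placements one
#'   is chosen at random (seeded, per-read, order-independent).
#' * `best_ties` - all minimum-mismatch placements are kept and each read's
#'   contribution is later divided by the number of loci (multiread
#'   correction).
#' * `all_crop36` - reads are cropped to their first 36 bases and every
#'   placement within 2 mismatches is reported (the classic align-all
#'   protocol for duplicated sequence).
#' * `all` - every full-length placement within the mismatch cap.
#'
#' @return Character vector of strategy names.
#' @export
alignment_strategies <- function() c("best", "best_ties", "all_crop36", "all")

# Reference span of a CIGAR string (M/D/N/=/X operations).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    sum(n[grepl("[MDN=X]", ops)])
  }, integer(1), USE.NAMES = FALSE)
}

# Exhaustively enumerate placements of reads on a small reference with at
# most `max_mismatches` substitutions, on both strands.  Pigeonhole
# seed-and-verify: a placement with <= m mismatches must contain an exact
# match of at least one of m+1 disjoint read segments; candidate positions
# from exact segment hits (matchPDict) are verified with neditStartingAt.
# Returns data.frame(read, chrom, start, end, strand, mismatches).
enumerate_placements <- function(seqs, reference, max_mismatches = 2L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (!length(seqs)) {
    return(data.frame(read = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- list()
  widths <- nchar(seqs)
  for (L in unique(widths)) {
    sel <- which(widths == L)
    fwd <- seqs[sel]
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
    k <- max_mismatches + 1L
    w <- L %/% k
    if (w < 4L) stopf("reads of length %d are too short for %d mismatches",
                      L, max_mismatches)
    offsets <- c(seq(0L, by = w, length.out = k - 1L), L - w)
    for (str in c("+", "-")) {
      qry <- if (str == "+") fwd else rev
      # seed table: one row per (read, offset), N-containing seeds dropped
      seed_read <- rep(seq_along(qry), each = length(offsets))
      seed_off <- rep(offsets, times = length(qry))
      seed_seq <- substring(qry[seed_read], seed_off + 1L, seed_off + w)
      clean <- !grepl("[^ACGT]", seed_seq)
      seed_read <- seed_read[clean]; seed_off <- seed_off[clean]
      seed_seq <- seed_seq[clean]
      if (!length(seed_seq)) next
      pd <- Biostrings::PDict(unname(seed_seq))
      for (chrom in names(reference)) {
        subject <- reference[[chrom]]
        slen <- length(subject)
        chrom_str <- as.character(subject)
        mi <- Biostrings::matchPDict(pd, subject)
        starts <- Biostrings::startIndex(mi)
        nh <- lengths(starts)
        if (!sum(nh)) next
        hit_seed <- rep.int(seq_along(starts), nh)
        hit_start <- unlist(starts, use.names = FALSE)
        cand_read <- seed_read[hit_seed]
        cand_pos <- hit_start - seed_off[hit_seed]
        ok <- cand_pos >= 1L & cand_pos + L - 1L <= slen
        cand_read <- cand_read[ok]; cand_pos <- cand_pos[ok]
        if (!length(cand_read)) next
        dup <- duplicated(as.double(cand_read) * (slen + 1) + cand_pos)
        cand_read <- cand_read[!dup]; cand_pos <- cand_pos[!dup]
        # vectorised mismatch count over all candidates, one position at a
        # time (N on either side counts as a mismatch)
        qv <- qry[cand_read]
        wv <- substring(chrom_str, cand_pos, cand_pos + L - 1L)
        mm <- integer(length(qv))
        for (j in seq_len(L)) {
          ra <- substring(qv, j, j)
          mm <- mm + ((ra != substring(wv, j, j)) | ra == "N")
        }
        keep <- mm <= max_mismatches
        if (!any(keep)) next
        res[[length(res) + 1L]] <- data.frame(
          read = names(fwd)[cand_read[keep]], chrom = chrom,
          start = cand_pos[keep], end = cand_pos[keep] + L - 1L,
          strand = str, mismatches = as.integer(mm[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(read = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(read = character(0), mate = integer(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), n_loci = integer(0), combo = integer(0),
             proper_pair = logical(0), stringsAsFactors = FALSE)
}

# Apply a single-end strategy to an enumerated placement table.
select_placements <- function(pl, strategy, seed = 0L, mate = 0L) {
  if (!nrow(pl)) return(empty_records())
  pl <- pl[order(pl$read, pl$chrom, pl$start, pl$strand), , drop = FALSE]
  if (strategy %in% c("best", "best_ties")) {
    best_mm <- stats::ave(pl$mismatches, pl$read, FUN = min)
    pl <- pl[pl$mismatches == best_mm, , drop = FALSE]
  }
  grp_n <- stats::ave(seq_len(nrow(pl)), pl$read, FUN = length)
  if (strategy == "best") {
    within <- stats::ave(seq_len(nrow(pl)), pl$read, FUN = seq_along)
    u <- hash_runif(pl$read, seed)
    pick <- floor(u * grp_n) + 1
    pl <- pl[within == pick, , drop = FALSE]
    grp_n <- rep(1L, nrow(pl))
  }
  data.frame(read = pl$read, mate = mate, chrom = pl$chrom, start = pl$start,
             end = pl$end, strand = pl$strand, mismatches = pl$mismatches,
             n_loci = as.integer(grp_n),
             combo = as.integer(stats::ave(seq_len(nrow(pl)), pl$read,
                                           FUN = seq_along)),
             proper_pair = FALSE, stringsAsFactors = FALSE)
}

#' Exhaustively align single-end reads on a small reference
#'
#' The built-in oracle mapper: every substitution-only placement on both
#' strands with at most `max_mismatches` mismatches is enumerated, then the
#' chosen strategy decides which placements are reported.  `N` counts as a
#' mismatch; unplaced reads are omitted.  Intended for references up to a
#' few Mbp; it doubles as the test oracle for external aligners.
#'
#' @param reads Named character vector, `DNAStringSet`, or single-end
#'   `read_set`.
#' @param reference `DNAStringSet` reference.
#' @param strategy One of [alignment_strategies()].
#' @param max_mismatches Mismatch cap.  `NULL` (default) mimics the
#'   published tools: the align-all and best-ties protocols cap at 2
#'   mismatches (`-v 2`); `best` emulates a quality-aware end-to-end
#'   aligner with no hard cap, so the cap scales with read length
#'   (`2 + ceiling(L / 75)`).
#' @param seed Tie-break seed; ties are broken per read id so results are
#'   independent of read order.
#' @return `data.frame` of alignment records with columns `read`, `mate`,
#'   `chrom`, `start`, `end`, `strand`, `mismatches`, `n_loci`, `combo`,
#'   `proper_pair`.
#' @export
oracle_align <- function(reads, reference, strategy = "best",
                         max_mismatches = NULL, seed = 0L) {
  strategy <- match.arg(strategy, alignment_strategies())
  if (inherits(reads, "read_set")) reads <- reads$seq1
  if (is(reads, "DNAStringSet")) reads <- stats::setNames(as.character(reads), names(reads))
  if (strategy == "all_crop36") {
    reads <- stats::setNames(substring(reads, 1L, 36L), names(reads))
    max_mismatches <- 2L
  }
  if (is.null(max_mismatches))
    max_mismatches <- default_mismatch_cap(strategy, max(nchar(reads), 0L))
  pl <- enumerate_placements(reads, reference, max_mismatches)
  select_placements(pl, strategy, seed)
}

# Published mismatch caps: -v 2 for the bowtie1-based protocols; the best
# strategy (bowtie2-like) has no hard cap, approximated by a read-length
# scaled cap.
default_mismatch_cap <- function(strategy, read_length) {
  if (strategy == "best") 2L + as.integer(ceiling(read_length / 75))
  else 2L
}

#' Exhaustively align read pairs on a small reference
#'
#' Both mates are enumerated as in [oracle_align()], then combined into
#' proper-pair candidates (same chromosome, forward/reverse orientation,
#' implied fragment at most `max_insert` bp).  Under `best` the proper
#' combination with the fewest total mismatches wins (seeded random
#' tie-break); under `best_ties` all minimum-mismatch proper combinations
#' are kept with `n_loci` set.  Reads without any proper combination fall
#' back to independent single-end treatment (discordant).  `all_crop36`
#' crops each mate to 36 bases and treats it as single-end; `all` reports
#' every placement of each mate.
#'
#' @param reads A paired `read_set` (or list with `seq1`, `seq2`).
#' @param reference `DNAStringSet`.
#' @inheritParams oracle_align
#' @param max_insert Maximum implied fragment length for a proper pair.
#' @return Alignment records; proper combinations share a `combo` index
#'   across the two mates of a read.
#' @export
oracle_align_pairs <- function(reads, reference, strategy = "best",
                               max_mismatches = NULL, seed = 0L,
                               max_insert = 800L) {
  strategy <- match.arg(strategy, alignment_strategies())
  s1 <- reads$seq1; s2 <- reads$seq2
  if (is.null(s2)) return(oracle_align(s1, reference, strategy, max_mismatches, seed))
  if (strategy == "all_crop36") {
    r1 <- oracle_align(s1, reference, "all_crop36", seed = seed)
    r2 <- oracle_align(s2, reference, "all_crop36", seed = seed)
    r1$mate <- 1L; r2$mate <- 2L
    return(rbind(r1, r2))
  }
  if (is.null(max_mismatches))
    max_mismatches <- default_mismatch_cap(strategy, max(nchar(s1), 0L))
  p1 <- enumerate_placements(s1, reference, max_mismatches)
  p2 <- enumerate_placements(s2, reference, max_mismatches)
  if (strategy == "all") {
    r1 <- select_placements(p1, "all", seed, mate = 1L)
    r2 <- select_placements(p2, "all", seed, mate = 2L)
    return(rbind(r1, r2))
  }
  # proper-pair candidates
  m <- merge(p1, p2, by = c("read", "chrom"), suffixes = c(".1", ".2"))
  if (nrow(m)) {
    fr <- m$strand.1 == "+" & m$strand.2 == "-" & m$start.1 <= m$start.2 &
      (m$end.2 - m$start.1 + 1L) <= max_insert
    rf <- m$strand.2 == "+" & m$strand.1 == "-" & m$start.2 <= m$start.1 &
      (m$end.1 - m$start.2 + 1L) <= max_insert
    m <- m[fr | rf, , drop = FALSE]
  }
  paired_rec <- empty_records()
  if (nrow(m)) {
    m$total_mm <- m$mismatches.1 + m$mismatches.2
    m <- m[order(m$read, m$chrom, m$start.1, m$start.2), , drop = FALSE]
    best <- stats::ave(m$total_mm, m$read, FUN = min)
    m <- m[m$total_mm == best, , drop = FALSE]
    grp_n <- stats::ave(seq_len(nrow(m)), m$read, FUN = length)
    if (strategy == "best") {
      within <- stats::ave(seq_len(nrow(m)), m$read, FUN = seq_along)
      pick <- floor(hash_runif(m$read, seed) * grp_n) + 1
      m <- m[within == pick, , drop = FALSE]
      grp_n <- rep(1L, nrow(m))
    }
    combo <- as.integer(stats::ave(seq_len(nrow(m)), m$read, FUN = seq_along))
    mk <- function(mate) {
      sfx <- if (mate == 1L) ".1" else ".2"
      data.frame(read = m$read, mate = mate, chrom = m$chrom,
                 start = m[[paste0("start", sfx)]],
                 end = m[[paste0("end", sfx)]],
                 strand = m[[paste0("strand", sfx)]],
                 mismatches = m[[paste0("mismatches", sfx)]],
                 n_loci = as.integer(grp_n), combo = combo,
                 proper_pair = TRUE, stringsAsFactors = FALSE)
    }
    paired_rec <- rbind(mk(1L), mk(2L))
  }
  # discordant fallback: reads with no proper combination
  proper_ids <- unique(paired_rec$read)
  d1 <- p1[!p1$read %in% proper_ids, , drop = FALSE]
  d2 <- p2[!p2$read %in% proper_ids, , drop = FALSE]
  single_strategy <- if (strategy == "best") "best" else "best_ties"
  r1 <- select_placements(d1, single_strategy, seed, mate = 1L)
  r2 <- select_placements(d2, single_strategy, seed, mate = 2L)
  out <- rbind(paired_rec, r1, r2)
  rownames(out) <- NULL
  out
}

#' Resolve proper-pair flags on alignment records
#'
#' Marks a pair as proper when the two mates' placements share a chromosome,
#' are on opposite strands in forward/reverse orientation, and the implied
#' fragment is at most `max_insert` bp.  Operates on records with one
#' placement per mate (e.g. parsed from an external aligner's BAM).
#'
#' @param records Alignment records.
#' @param max_insert Maximum implied fragment length.
#' @return `records` with `proper_pair` updated and `combo` matched across
#'   mates of proper pairs.
#' @export
pair_resolve <- function(records, max_insert = 800L) {
  records$proper_pair <- FALSE
  m1 <- records[records$mate == 1L, , drop = FALSE]
  m2 <- records[records$mate == 2L, , drop = FALSE]
  if (!nrow(m1) || !nrow(m2)) return(records)
  j <- merge(m1[c("read", "chrom", "start", "end", "strand")],
             m2[c("read", "chrom", "start", "end", "strand")],
             by = c("read", "chrom"), suffixes = c(".1", ".2"))
  if (!nrow(j)) return(records)
  fr <- j$strand.1 == "+" & j$strand.2 == "-" & j$start.1 <= j$start.2 &
    (j$end.2 - j$start.1 + 1L) <= max_insert
  rf <- j$strand.2 == "+" & j$strand.1 == "-" & j$start.2 <= j$start.1 &
    (j$end.1 - j$start.2 + 1L) <= max_insert
  good <- unique(j$read[fr | rf])
  records$proper_pair <- records$read %in% good & records$mate %in% c(1L, 2L)
  records
}

#' Build (and optionally run) an external aligner command
#'
#' Command lines follow the published protocols for each strategy: bowtie2
#' `--very-sensitive -X 800` for `best`; mrsFast `--crop 36 -e 2` for
#' `all_crop36`; bowtie `--all -v 2 -X 800` for `all`; bowtie
#' `--best --strata --all -v 2` for `best_ties`.  A `bwa` backend (bwa mem)
#' is also provided for the `best` strategy so the oracle mapper can be
#' cross-checked on hosts where the historical aligners are unavailable.
#'
#' @param fastq1,fastq2 Input FASTQ path(s) (`fastq2 = NULL` for
#'   single-end).
#' @param reference_fasta Reference FASTA (an index is built if missing, for
#'   backends that support it).
#' @param strategy One of [alignment_strategies()].
#' @param out_bam Output BAM path.
#' @param aligner Backend: `bowtie2`, `bowtie`, `mrsfast` or `bwa`;
#'   `"auto"` picks the published backend for the strategy.
#' @param dry_run Print and return the command without executing.
#' @param max_insert Maximum insert size passed to the aligner.
#' @return The command string (dry run) or `out_bam`.
#' @export
external_align <- function(fastq1, fastq2 = NULL, reference_fasta, strategy,
                           out_bam, aligner = "auto", dry_run = FALSE,
                           max_insert = 800L) {
  strategy <- match.arg(strategy, alignment_strategies())
  if (aligner == "auto") {
    aligner <- switch(strategy, best = "bowtie2", all_crop36 = "mrsfast",
                      all = "bowtie", best_ties = "bowtie")
  }
  idx <- sub("\\.(fa|fasta)$", "", reference_fasta)
  pair <- function(se, pe) if (is.null(fastq2)) se else pe
  cmd <- switch(aligner,
    bowtie2 = sprintf(
      "bowtie2 --very-sensitive -X %d -x %s %s | samtools sort -o %s -", max_insert,
      idx, pair(sprintf("-U %s", fastq1),
                sprintf("-1 %s -2 %s", fastq1, fastq2)), out_bam),
    bowtie = sprintf(
      "bowtie %s -S %s %s | samtools sort -o %s -",
      if (strategy == "best_ties") "--best --strata --all -v 2"
      else sprintf("--all -v 2 -X %d", max_insert),
      idx, pair(fastq1, sprintf("-1 %s -2 %s", fastq1, fastq2)), out_bam),
    mrsfast = sprintf(
      "mrsfast --search %s --crop 36 -e 2 --seq %s -o %s",
      reference_fasta, fastq1, sub("\\.bam$", ".sam", out_bam)),
    bwa = sprintf(
      "bwa mem -v 1 %s %s | samtools sort -o %s -", reference_fasta,
      pair(fastq1, paste(fastq1, fastq2)), out_bam),
    stopf("unknown aligner backend '%s'", aligner))
  if (dry_run) {
    message(cmd)
    return(cmd)
  }
  exe <- strsplit(cmd, " ")[[1]][1]
  if (Sys.which(exe) == "")
    stopf("aligner executable '%s' not found on PATH; install it or use the oracle mapper", exe)
  if (aligner == "bwa" && !file.exists(paste0(reference_fasta, ".bwt"))) {
    system2("bwa", c("index", reference_fasta), stdout = FALSE, stderr = FALSE)
  }
  message("running: ", cmd)
  err <- system(paste(cmd, "2>/tmp/dupdepth_align.err"))
  if (err != 0)
    stopf("aligner exited with status %d: %s", err,
          paste(readLines("/tmp/dupdepth_align.err"), collapse = "\n"))
  out_bam
}

#' Read alignment records from a BAM file
#'
#' Parses a (possibly multi-placement) BAM into the package's alignment
#' record table: `n_loci` is the number of placements observed per read and
#' mate, `proper_pair` comes from flag 0x2, and the reference span is
#' derived from the CIGAR.
#'
#' @param bam Path to a BAM file.
#' @param min_mapq Drop placements below this mapping quality (0 keeps all).
#' @param include_secondary Keep secondary/supplementary placements (needed
#'   for multi-placement protocols).
#' @return Alignment records `data.frame`.
#' @export
read_alignments_bam <- function(bam, min_mapq = 0L, include_secondary = FALSE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("Rsamtools is required to read BAM files")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"), tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  mapped <- !bitwAnd(flag, 0x4)
  keep <- mapped & !is.na(b$pos) & (is.na(b$mapq) | b$mapq >= min_mapq)
  if (!include_secondary) keep <- keep & !bitwAnd(flag, 0x100) & !bitwAnd(flag, 0x800)
  mate <- ifelse(bitwAnd(flag[keep], 0x40) > 0, 1L,
                 ifelse(bitwAnd(flag[keep], 0x80) > 0, 2L, 0L))
  w <- cigar_ref_width(b$cigar[keep])
  nm <- b$tag$NM[keep] %||% rep(NA_integer_, sum(keep))
  rec <- data.frame(
    read = b$qname[keep], mate = mate,
    chrom = as.character(b$rname[keep]), start = b$pos[keep],
    end = b$pos[keep] + w - 1L,
    strand = ifelse(bitwAnd(flag[keep], 0x10) > 0, "-", "+"),
    mismatches = as.integer(nm),
    n_loci = 1L, combo = 1L,
    proper_pair = bitwAnd(flag[keep], 0x2) > 0,
    stringsAsFactors = FALSE)
  key <- paste(rec$read, rec$mate)
  rec$n_loci <- as.integer(stats::ave(seq_len(nrow(rec)), key, FUN = length))
  rec$combo <- as.integer(stats::ave(seq_len(nrow(rec)), key, FUN = seq_along))
  rec
}
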