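#' Insert-size model
#'
#' Paired-end fragment lengths are drawn from a normal distribution matching
#' typical short-insert WGS libraries (mean 350 bp, sd 50 bp by default).
#'
#' @param mean Mean insert (fragment) size in bp.
#' @param sd Standard deviation in bp.
#' @return An `insert_model` object.
#' @export
insert_model <- function(mean = 350, sd = 50) {
  stopifnot(mean > 0, sd >= 0)
  structure(list(mean = mean, sd = sd), class = "insert_model")
}

#' Sequencing-error model
#'
#' Substitution errors with a mate-specific mean rate and a linear
#' positional ramp: errors are half as likely at the first base and 1.5
#' times as likely at the last base as the mean, so the end-to-start rate
#' ratio is 3.  Defaults (0.0026 for mate 1, 0.004 for mate 2) reproduce
#' rates typical of Illumina 100 bp data.
#'
#' @param mean_rate_mate1,mean_rate_mate2 Mean per-base substitution
#'   probability for each mate.
#' @param ramp Start and end multipliers of the linear ramp.
#' @return An `error_model` object.
#' @export
error_model <- function(mean_rate_mate1 = 0.0026, mean_rate_mate2 = 0.004,
                        ramp = c(0.5, 1.5)) {
  stopifnot(mean_rate_mate1 >= 0, mean_rate_mate1 <= 1,
            mean_rate_mate2 >= 0, mean_rate_mate2 <= 1,
            length(ramp) == 2, all(ramp > 0))
  structure(list(mean_rate_mate1 = mean_rate_mate1,
                 mean_rate_mate2 = mean_rate_mate2, ramp = ramp),
            class = "error_model")
}

#' Position-wise substitution probabilities
#'
#' Linear ramp from `ramp[1] * c` to `ramp[2] * c` whose arithmetic mean is
#' exactly the mate's mean rate `c`.  A length-1 read degenerates to the
#' mean rate.
#'
#' @param model An [error_model()].
#' @param read_length Read length in bp.
#' @param mate Mate number (1 or 2).
#' @return Numeric vector of per-position error probabilities.
#' @export
positionwise_error <- function(model, read_length, mate = 1L) {
  stopifnot(read_length >= 1, mate %in% c(1L, 2L))
  rate <- if (mate == 1L) model$mean_rate_mate1 else model$mean_rate_mate2
  if (read_length == 1) return(rate)
  mult <- seq(model$ramp[1], model$ramp[2], length.out = read_length)
  rate * mult / mean(mult)
}

#' Fit a smoothed per-position quality profile
#'
#' Models the per-position mean Phred quality of each mate with a loess
#' smoother and records the linear trend of the fitted tail so the profile
#' can be extended to arbitrary read lengths (each simulated read length
#' then sees the same quality drop-off shape).  Qualities are clamped to
#' [2, 41].
#'
#' @param observed Numeric vector of observed mean qualities per position
#'   (mate 1), or a list with elements `mate1` and `mate2`.
#' @param target_length Minimum length the profile must support.
#' @param span Loess span.
#' @param positions Optional explicit positions; must be strictly
#'   increasing.
#' @return A `quality_profile` object.
#' @export
fit_quality_profile <- function(observed, target_length = 300L, span = 0.75,
                                positions = NULL) {
  if (!is.list(observed)) observed <- list(mate1 = observed, mate2 = observed)
  fit_one <- function(q) {
    n <- length(q)
    if (n < 10) stopf("need at least 10 observed positions, got %d", n)
    pos <- positions %||% seq_len(n)
    if (length(pos) != n || any(diff(pos) <= 0))
      stopf("positions must be strictly increasing")
    fit <- stats::loess(q ~ pos, span = span,
                        control = stats::loess.control(surface = "direct"))
    smoothed <- stats::predict(fit, data.frame(pos = seq_len(max(pos))))
    # continue the fitted trend: slope over the last quarter of the profile
    tailn <- max(2L, length(smoothed) %/% 4L)
    ti <- seq(length(smoothed) - tailn + 1L, length(smoothed))
    slope <- stats::coef(stats::lm(smoothed[ti] ~ ti))[[2]]
    list(base = pmin(41, pmax(2, smoothed)), slope = slope)
  }
  p <- structure(list(mate1 = fit_one(observed$mate1),
                      mate2 = fit_one(observed$mate2 %||% observed$mate1)),
                 class = "quality_profile")
  stopifnot(length(quality_at(p, target_length, 1L)) == target_length)
  p
}

#' Default quality profile
#'
#' A mildly declining profile (mate 1: Phred 38 down to 32 over 100 bp;
#' mate 2 two points lower throughout, reflecting the typical lower quality
#' of second reads), extendable to any read length.
#'
#' @return A `quality_profile` object.
#' @export
default_quality_profile <- function() {
  structure(list(
    mate1 = list(base = seq(38, 32, length.out = 100), slope = -6 / 99),
    mate2 = list(base = seq(36, 30, length.out = 100), slope = -6 / 99)),
    class = "quality_profile")
}

#' Evaluate a quality profile at a read length
#'
#' @param profile A `quality_profile`.
#' @param read_length Requested length.
#' @param mate Mate number.
#' @return Numeric vector of Phred qualities, clamped to [2, 41].
#' @export
quality_at <- function(profile, read_length, mate = 1L) {
  m <- if (mate == 1L) profile$mate1 else profile$mate2
  q <- m$base
  if (read_length > length(q)) {
    extra <- q[length(q)] + m$slope * seq_len(read_length - length(q))
    q <- c(q, extra)
  }
  pmin(41, pmax(2, q[seq_len(read_length)]))
}

#' Full simulation specification
#'
#' Bundles every knob of the read simulator: read length and pairing,
#' haploid coverage (15x by default, i.e. 30x diploid), the spike-in copy
#' count, insert, error and quality models, and the RNG seed.
#'
#' @param read_length Read length in bp (36, 100, 150 and 300 are the
#'   standard evaluation lengths; any length >= 20 is accepted).
#' @param paired Simulate read pairs.
#' @param haploid_coverage Expected per-copy (haploid) depth over the
#'   simulated region.
#' @param copies Number of copies to spike in (0 allowed; gives no reads).
#' @param seed RNG seed (NULL = use current stream).
#' @param insert An [insert_model()].
#' @param errors An [error_model()].
#' @param quality A `quality_profile`.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(read_length = 100L, paired = TRUE, haploid_coverage = 15,
                     copies = 1L, seed = NULL, insert = insert_model(),
                     errors = error_model(), quality = default_quality_profile()) {
  stopifnot(read_length >= 20, haploid_coverage > 0, copies >= 0)
  structure(list(read_length = as.integer(read_length), paired = paired,
                 haploid_coverage = haploid_coverage, copies = as.integer(copies),
                 seed = seed, insert = insert, errors = errors,
                 quality = quality), class = "sim_spec")
}

# -- truth tags ---------------------------------------------------------------

#' Encode / decode truth tags
#'
#' Every simulated read carries its origin in its name:
#' `origin|<domain>|<chrom>:<start>-<end>|<copy>|r<serial>`.
#'
#' @param name Origin domain name.
#' @param chrom,start,end Origin fragment interval (1-based closed).
#' @param copy Copy index.
#' @param serial Read serial number (makes names unique).
#' @return Character vector of read names.
#' @export
make_truth_tag <- function(name, chrom, start, end, copy, serial) {
  sprintf("origin|%s|%s:%d-%d|%d|r%d", name, chrom, start, end, copy, serial)
}

#' @rdname make_truth_tag
#' @param ids Read names to decode.
#' @return For `parse_truth_tag`, a `data.frame` with columns `id`, `name`,
#'   `chrom`, `start`, `end`, `copy`.
#' @export
parse_truth_tag <- function(ids) {
  m <- regmatches(ids, regexec(
    "^origin\\|([^|]+)\\|([^|:]+):(\\d+)-(\\d+)\\|(\\d+)\\|r(\\d+)$", ids))
  bad <- which(lengths(m) != 7)
  if (length(bad)) stopf("read name is not a valid truth tag: %s", ids[bad[1]])
  data.frame(id = ids,
             name = vapply(m, `[`, character(1), 2),
             chrom = vapply(m, `[`, character(1), 3),
             start = as.integer(vapply(m, `[`, character(1), 4)),
             end = as.integer(vapply(m, `[`, character(1), 5)),
             copy = as.integer(vapply(m, `[`, character(1), 6)),
             stringsAsFactors = FALSE)
}

# -- fragment sampling --------------------------------------------------------

#' Sample truth-tagged fragments over a region
#'
#' Fragment start positions are uniform over the region extended by one
#' buffer length upstream; only fragments overlapping the region are kept.
#' The number of draws is chosen so the expected depth at every base of the
#' region equals `copies * haploid_coverage`.  Paired specs draw fragment
#' lengths from the insert model (clamped to at least the read length);
#' single-end fragments have the read length.
#'
#' @param region Length-1 `GRanges`.
#' @param spec A [sim_spec()].
#' @return `data.frame` with columns `start`, `end`, `orient` (`+`: mate 1
#'   on the forward strand), `copy`.  Deterministic given `spec$seed`.
#' @export
sample_fragments <- function(region, spec) {
  stopifnot(length(region) == 1)
  L <- spec$read_length
  if (GenomicRanges::width(region) < L)
    stopf("region width %d is shorter than the read length %d",
          GenomicRanges::width(region), L)
  if (spec$copies == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      orient = character(0), copy = integer(0)))
  depth <- spec$copies * spec$haploid_coverage
  mean_len <- if (spec$paired) spec$insert$mean else L
  buffer <- if (spec$paired) ceiling(spec$insert$mean + 4 * spec$insert$sd) else L
  rstart <- GenomicRanges::start(region); rend <- GenomicRanges::end(region)
  window <- c(rstart - buffer, rend)
  W <- window[2] - window[1] + 1
  n <- round(depth * W / mean_len)
  with_seed(spec$seed, {
    starts <- window[1] + floor(stats::runif(n) * W)
    lens <- if (spec$paired) {
      pmax(L, round(stats::rnorm(n, spec$insert$mean, spec$insert$sd)))
    } else rep(L, n)
    orient <- ifelse(stats::runif(n) < 0.5, "+", "-")
    keep <- (starts + lens - 1L >= rstart) & (starts <= rend)
    data.frame(start = as.integer(starts[keep]),
               end = as.integer(starts[keep] + lens[keep] - 1L),
               orient = orient[keep],
               copy = (which(keep) - 1L) %% spec$copies + 1L)
  })
}

# -- base substitution --------------------------------------------------------

#' Introduce substitution errors into a read
#'
#' Each base is substituted with its position's error probability; the
#' replacement is uniform over the three alternative bases.  `N` bases pass
#' through unchanged and are never introduced.  The quality string is the
#' profile's expected quality (Phred+33).
#'
#' @param seq Nucleotide string.
#' @param probs Per-position error probabilities (same length as `seq`).
#' @param quals Per-position Phred qualities (numeric) for the read.
#' @return List with elements `seq` and `qual`.
#' @export
mutate_read <- function(seq, probs, quals) {
  stopifnot(nchar(seq) == length(probs))
  out <- mutate_read_block(seq, matrix(probs, nrow = 1, byrow = TRUE))
  list(seq = out, qual = phred_to_char(quals))
}

# Vectorised substitution over a block of same-length reads.
# seqs: character vector; probs: either a vector (recycled per read) or an
# n x L matrix.  Uses the current RNG stream.
mutate_read_block <- function(seqs, probs) {
  n <- length(seqs)
  if (!n) return(seqs)
  L <- nchar(seqs[1])
  if (is.matrix(probs)) p <- probs else p <- matrix(probs, n, L, byrow = TRUE)
  err <- matrix(stats::runif(n * L), n, L) < p
  hits <- which(err, arr.ind = TRUE)
  if (!nrow(hits)) return(seqs)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  ord <- order(hits[, 1])
  hits <- hits[ord, , drop = FALSE]
  cur <- substring(seqs[hits[, 1]], hits[, 2], hits[, 2])
  ok <- cur %in% names(alts)
  hits <- hits[ok, , drop = FALSE]; cur <- cur[ok]
  if (!nrow(hits)) return(seqs)
  pick <- ceiling(stats::runif(nrow(hits)) * 3)
  repl <- vapply(seq_along(cur), function(k) alts[[cur[k]]][pick[k]], character(1))
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1]; j <- hits[k, 2]
    substr(seqs[i], j, j) <- repl[k]
  }
  seqs
}

# -- read sets ----------------------------------------------------------------

new_read_set <- function(seq1, qual1, seq2 = NULL, qual2 = NULL, paired,
                         truth) {
  structure(list(seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
                 paired = paired, truth = truth), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d %s reads, length %s\n", length(x$seq1),
              if (x$paired) "paired-end" else "single-end",
              if (length(x$seq1)) nchar(x$seq1[1]) else "-"))
  invisible(x)
}

#' Number of read units in a read set
#' @param x A `read_set`.
#' @return Integer count (pairs count once).
#' @export
n_reads <- function(x) length(x$seq1)

#' Combine read sets
#' @param sets List of `read_set` objects with identical layout.
#' @return A single `read_set`.
#' @export
combine_read_sets <- function(sets) {
  sets <- Filter(function(s) length(s$seq1) > 0, sets)
  if (!length(sets)) {
    return(new_read_set(character(0), character(0), paired = TRUE,
                        truth = parse_truth_tag(character(0))))
  }
  paired <- sets[[1]]$paired
  new_read_set(
    seq1 = unlist(lapply(sets, `[[`, "seq1"), use.names = TRUE),
    qual1 = unlist(lapply(sets, `[[`, "qual1"), use.names = FALSE),
    seq2 = if (paired) unlist(lapply(sets, `[[`, "seq2"), use.names = TRUE),
    qual2 = if (paired) unlist(lapply(sets, `[[`, "qual2"), use.names = FALSE),
    paired = paired,
    truth = do.call(rbind, lapply(sets, `[[`, "truth")))
}

#' Simulate spike-in reads from one domain
#'
#' Samples fragments over the domain's quantification region at
#' `copies * haploid_coverage` expected depth, extracts the read sequences
#' (both orientations equally likely), applies the substitution error model
#' and quality profile, and truth-tags every read name with its origin.
#'
#' @param domain Length-1 named `GRanges` (the quantification region).
#' @param copies Copy count to simulate (overrides `spec$copies` when
#'   given).
#' @param spec A [sim_spec()].
#' @param genome `DNAStringSet` reference.
#' @param serial_offset Starting read serial (used when combining sets).
#' @return A `read_set`.
#' @export
simulate_spike_in <- function(domain, copies = NULL, spec, genome,
                              serial_offset = 0L) {
  if (!is.null(copies)) spec$copies <- as.integer(copies)
  frags <- sample_fragments(domain, spec)
  chrom <- as.character(GenomicRanges::seqnames(domain))
  seqlen <- length(genome[[chrom]])
  dname <- names(domain) %||% S4Vectors::mcols(domain)$name
  if (is.null(dname)) stopf("domain must be named")
  L <- spec$read_length
  n <- nrow(frags)
  empty <- new_read_set(character(0), character(0),
                        seq2 = if (spec$paired) character(0),
                        qual2 = if (spec$paired) character(0),
                        paired = spec$paired,
                        truth = parse_truth_tag(character(0)))
  if (!n) return(empty)
  # clip fragments at chromosome bounds (region flanks must exist)
  fs <- pmax(1L, frags$start); fe <- pmin(seqlen, frags$end)
  ok <- fe - fs + 1L >= L
  frags <- frags[ok, , drop = FALSE]; fs <- fs[ok]; fe <- fe[ok]
  n <- nrow(frags)
  if (!n) return(empty)
  fragseq <- as.character(Biostrings::DNAStringSet(genome[[chrom]],
                                                   start = fs, end = fe))
  left <- substring(fragseq, 1L, L)
  if (spec$paired) {
    right <- substring(fragseq, nchar(fragseq) - L + 1L, nchar(fragseq))
    rc <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x)))
    fwd <- frags$orient == "+"
    r1 <- ifelse(fwd, left, rc(right))
    r2 <- ifelse(fwd, rc(right), left)
  } else {
    rc1 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(left)))
    r1 <- ifelse(frags$orient == "+", left, rc1)
    r2 <- NULL
  }
  p1 <- positionwise_error(spec$errors, L, 1L)
  q1 <- quality_at(spec$quality, L, 1L)
  seed2 <- if (is.null(spec$seed)) NULL else spec$seed + 104729L
  with_seed(seed2, {
    r1 <- mutate_read_block(r1, p1)
    if (spec$paired) {
      p2 <- positionwise_error(spec$errors, L, 2L)
      r2 <- mutate_read_block(r2, p2)
    }
  })
  ids <- make_truth_tag(dname, chrom, fs, fe, frags$copy,
                        serial_offset + seq_len(n))
  names(r1) <- ids
  qs1 <- rep(phred_to_char(q1), n)
  if (spec$paired) {
    names(r2) <- ids
    qs2 <- rep(phred_to_char(quality_at(spec$quality, L, 2L)), n)
    rs <- new_read_set(r1, qs1, r2, qs2, paired = TRUE,
                       truth = parse_truth_tag(ids))
  } else {
    rs <- new_read_set(r1, qs1, paired = FALSE, truth = parse_truth_tag(ids))
  }
  rs
}

#' Simulate a diploid baseline over an annotation
#'
#' Every domain is simulated at diploid copy number (2 by default) so the
#' whole family is present at `2 * haploid_coverage` expected depth; the
#' per-domain read sets are concatenated.  Per-domain seeds are derived from
#' `spec$seed` so the result is reproducible and independent of domain
#' order.
#'
#' @param domains Named `GRanges` annotation (quantification regions).
#' @param spec A [sim_spec()].
#' @param genome `DNAStringSet` reference.
#' @param copies Per-domain copy number (scalar or named vector; default 2).
#' @return A `read_set`.
#' @export
simulate_baseline <- function(domains, spec, genome, copies = 2L) {
  if (!length(domains)) {
    return(new_read_set(character(0), character(0),
                        seq2 = if (spec$paired) character(0),
                        qual2 = if (spec$paired) character(0),
                        paired = spec$paired,
                        truth = parse_truth_tag(character(0))))
  }
  if (length(copies) == 1) {
    copies <- stats::setNames(rep(copies, length(domains)), names(domains))
  }
  sets <- lapply(seq_along(domains), function(i) {
    sp <- spec
    if (!is.null(spec$seed))
      sp$seed <- as.integer((spec$seed +
                               7919 * as.double(hash31(names(domains)[i])[1])) %%
                              2147483647)
    # serials restart per domain; names stay unique because they carry the
    # domain, so the result is independent of domain order
    simulate_spike_in(domains[i], copies[[names(domains)[i]]], sp, genome)
  })
  combine_read_sets(sets)
}

# -- FASTQ I/O ----------------------------------------------------------------

#' Write a read set as FASTQ
#'
#' Truth tags are the read names; qualities are Phred+33.
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ for mate 1 (or the single-end reads).
#' @param path2 Output FASTQ for mate 2 (required when paired).
#' @param compress Gzip the output.
#' @return Paths written, invisibly.
#' @export
write_fastq <- function(reads, path, path2 = NULL, compress = FALSE) {
  write_one <- function(seqs, quals, p) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, p, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = compress)
  }
  write_one(reads$seq1, reads$qual1, path)
  if (reads$paired) {
    if (is.null(path2)) stopf("paired reads need path2")
    write_one(reads$seq2, reads$qual2, path2)
  }
  invisible(c(path, path2))
}

#' Read FASTQ into a read set
#'
#' @param path Mate-1 (or single-end) FASTQ.
#' @param path2 Optional mate-2 FASTQ.
#' @param truth_tagged Parse read names as truth tags.
#' @return A `read_set`.
#' @export
read_fastq <- function(path, path2 = NULL, truth_tagged = TRUE) {
  read_one <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    list(seq = stats::setNames(as.character(x), names(x)),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- read_one(path)
  b <- if (!is.null(path2)) read_one(path2)
  truth <- if (truth_tagged) parse_truth_tag(names(a$seq)) else NULL
  new_read_set(a$seq, a$qual, b$seq, b$qual, paired = !is.null(path2),
               truth = truth)
}
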