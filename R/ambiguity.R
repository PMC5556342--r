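#' Measurement levels
#'
#' Copy number (and read ambiguity) can be resolved at four levels:
#' individual domain, clade within a gene, clade within a group of related
#' genes, and genome-wide clade; `gene` additionally sums all clades of a
#' gene.
#'
#' @return Character vector of level names.
#' @export
measurement_levels <- function() c("domain", "gene-clade", "group-clade", "clade")

# Map domain names to their unit label at a measurement level.
unit_of_domains <- function(annotation, level, groups = NULL) {
  mc <- S4Vectors::mcols(annotation)
  u <- switch(level,
    "domain" = mc$name,
    "gene-clade" = paste(mc$gene, mc$clade, sep = "_"),
    "group-clade" = {
      grp <- if (!is.null(groups)) group_of(groups, mc$gene, mc$clade) else mc$gene
      paste(grp, mc$clade, sep = "_")
    },
    "clade" = mc$clade,
    "gene" = mc$gene,
    stopf("unknown level '%s'", level))
  stats::setNames(u, mc$name)
}

#' Read-ambiguity matrix from truth-tagged alignments
#'
#' For reads simulated from each source unit, the percentage (by weight) of
#' aligned reads landing in each target unit.  Fragments are assigned to
#' the domain quantification region they overlap most; multi-locus reads
#' contribute `1/n_loci` per landing (set `fractional = FALSE` to count
#' each landing fully, the align-all convention).  Reads aligning outside
#' every unit stay in the denominator, so row sums are at most 100.
#'
#' @param records Truth-tagged alignment records.
#' @param annotation Named annotated `GRanges`.
#' @param level One of [measurement_levels()].
#' @param groups Optional `gene_groups` (needed for level `group-clade`).
#' @param fractional Weight landings by `1/n_loci`.
#' @param sample_mean_insert Passed to [reads_to_fragments()].
#' @return An `ambiguity_matrix`: source x target percentages with
#'   attributes `level`, `row_weight` (aligned weight per source) and
#'   `flagged` (sources with no aligned reads).
#' @export
ambiguity_matrix <- function(records, annotation, level = "domain",
                             groups = NULL, fractional = TRUE,
                             sample_mean_insert = 350) {
  units <- unit_of_domains(annotation, level, groups)
  all_units <- unique(units)
  frags <- reads_to_fragments(records, sample_mean_insert,
                              multiread_correction = fractional)
  truth <- parse_truth_tag(as.character(S4Vectors::mcols(frags)$read))
  src <- units[truth$name]
  if (anyNA(src)) stopf("truth tag names a domain missing from the annotation")
  # target: domain region with the largest overlap (regions are disjoint)
  tgt <- rep(NA_character_, length(frags))
  ov <- GenomicRanges::findOverlaps(frags, annotation, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(frags)[q], GenomicRanges::ranges(annotation)[s]))
    o <- order(q, -w)
    q <- q[o]; s <- s[o]
    first <- !duplicated(q)
    tgt[q[first]] <- units[S4Vectors::mcols(annotation)$name[s[first]]]
  }
  wt <- S4Vectors::mcols(frags)$weight
  denom <- rowsum(wt, src)                      # aligned weight per source
  mat <- matrix(0, length(all_units), length(all_units),
                dimnames = list(all_units, all_units))
  landed <- !is.na(tgt)
  if (any(landed)) {
    cell <- rowsum(wt[landed], paste(src[landed], tgt[landed], sep = "\r"))
    parts <- strsplit(rownames(cell), "\r", fixed = TRUE)
    ri <- vapply(parts, `[`, character(1), 1)
    ci <- vapply(parts, `[`, character(1), 2)
    mat[cbind(match(ri, all_units), match(ci, all_units))] <- cell[, 1]
  }
  rw <- stats::setNames(rep(0, length(all_units)), all_units)
  rw[rownames(denom)] <- denom[, 1]
  pct <- mat
  nz <- rw > 0
  pct[nz, ] <- 100 * mat[nz, , drop = FALSE] / rw[nz]
  structure(pct, class = c("ambiguity_matrix", "matrix"), level = level,
            row_weight = rw, flagged = all_units[!nz])
}

#' Off-target alignment percentages
#'
#' The off-target rate of a source unit is 100 minus its on-target
#' percentage (the diagonal of the ambiguity matrix).  Clade summaries are
#' read-weighted averages over the clade's sources.
#'
#' @param mat An `ambiguity_matrix`.
#' @param clades Named vector mapping each source unit to its clade (for
#'   the clade summary); inferred from unit names of the form `..._CLADE`
#'   or plain clade labels when omitted.
#' @return List with `source` (per-unit `data.frame`) and `clade`
#'   (read-weighted per-clade summary).
#' @export
off_target <- function(mat, clades = NULL) {
  units <- rownames(mat)
  on <- diag(as.matrix(mat))
  off <- 100 - on
  rw <- attr(mat, "row_weight")
  if (is.null(clades)) {
    clades <- vapply(units, function(u) {
      if (u %in% clade_labels()) return(u)
      m <- regmatches(u, regexec("_([A-Z]+\\d*)(_\\d+)?$", u))[[1]]
      if (length(m) >= 2 && m[2] %in% clade_labels()) m[2] else "all"
    }, character(1))
  }
  src <- data.frame(unit = units, clade = unname(clades[units]),
                    off_target = unname(off), stringsAsFactors = FALSE)
  agg <- lapply(split(seq_along(units), src$clade), function(i) {
    w <- rw[units[i]]
    if (sum(w) == 0) return(NA_real_)
    sum(off[i] * w) / sum(w)
  })
  cl <- data.frame(clade = names(agg), off_target = unlist(agg),
                   stringsAsFactors = FALSE, row.names = NULL)
  list(source = src, clade = cl)
}

#' Group genes by shared read ambiguity
#'
#' Two genes are connected (per clade) when either direction of their
#' gene-clade ambiguity entries reaches the sharing threshold; groups are
#' the connected components, so sharing chains merge transitively.  The
#' result is invariant to gene ordering.
#'
#' @param gene_matrix An `ambiguity_matrix` at level `gene-clade`.
#' @param threshold Sharing threshold in percent (default 5).
#' @return A `gene_groups` object: `data.frame` with columns `clade`,
#'   `gene`, `group` (group label = sorted member genes joined by `.`).
#' @export
derive_groups <- function(gene_matrix, threshold = 5) {
  stopifnot(attr(gene_matrix, "level") == "gene-clade")
  units <- rownames(gene_matrix)
  parts <- regmatches(units, regexec("^(.*)_([A-Z]+\\d*)$", units))
  gene <- vapply(parts, `[`, character(1), 2)
  clade <- vapply(parts, `[`, character(1), 3)
  res <- list()
  for (cl in unique(clade)) {
    sel <- which(clade == cl)
    g <- gene[sel]
    sub <- gene_matrix[sel, sel, drop = FALSE]
    share <- pmax(sub, t(sub)) >= threshold
    diag(share) <- TRUE
    gr <- igraph::graph_from_adjacency_matrix(share, mode = "undirected")
    comp <- igraph::components(gr)$membership
    grp_label <- vapply(comp, function(k) {
      paste(sort(g[comp == k]), collapse = ".")
    }, character(1))
    res[[cl]] <- data.frame(clade = cl, gene = g, group = unname(grp_label),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("gene_groups", "data.frame"),
            threshold = threshold)
}

#' Look up the group of genes
#'
#' @param groups A `gene_groups` object.
#' @param gene,clade Vectors of gene symbols and clades.
#' @return Group labels; genes absent from the table form their own group.
#' @export
group_of <- function(groups, gene, clade) {
  key <- paste(groups$clade, groups$gene, sep = "\r")
  i <- match(paste(clade, gene, sep = "\r"), key)
  out <- groups$group[i]
  out[is.na(i)] <- gene[is.na(i)]
  out
}

#' Discover uniquely mappable regions
#'
#' Slides an error-free read of `read_length` across the reference and
#' keeps the bases covered only by reads that map back to a single location
#' within `max_mismatches` mismatches.  With `gene_windows` supplied the
#' result is intersected with each window (inheriting its `gene`), and
#' `exclude` regions (e.g. domain coding sequence and flagged UTR exons)
#' are subtracted.
#'
#' @param reference `DNAStringSet` (small enough for the oracle mapper).
#' @param read_length Probe read length (default 100).
#' @param max_mismatches Uniqueness tolerance (default 1).
#' @param step Probe start stride (1 = every base).
#' @param gene_windows Optional `GRanges` with a `gene` metadata column.
#' @param exclude Optional `GRanges` to subtract.
#' @return `GRanges` of unique regions (with `gene` when windows given).
#' @export
find_unique_regions <- function(reference, read_length = 100L,
                                max_mismatches = 1L, step = 1L,
                                gene_windows = NULL, exclude = NULL) {
  out <- list()
  for (chrom in names(reference)) {
    len <- length(reference[[chrom]])
    if (len < read_length) next
    starts <- seq(1L, len - read_length + 1L, by = step)
    reads <- as.character(Biostrings::DNAStringSet(
      reference[[chrom]], start = starts, width = read_length))
    names(reads) <- sprintf("p%09d", starts)
    pl <- enumerate_placements(reads, reference, max_mismatches)
    nhits <- table(pl$read)
    uniq <- rep(FALSE, length(starts))
    uniq[match(names(nhits)[nhits == 1], names(reads))] <- TRUE
    # a base is unique-mappable iff every probe covering it is unique
    bad_start <- starts[!uniq]
    if (length(bad_start)) {
      bad <- IRanges::reduce(IRanges::IRanges(bad_start,
                                              bad_start + read_length - 1L))
    } else bad <- IRanges::IRanges()
    covered <- IRanges::reduce(IRanges::IRanges(starts, starts + read_length - 1L))
    good <- IRanges::setdiff(covered, bad)
    if (length(good)) {
      out[[chrom]] <- data.frame(chrom = chrom, start = IRanges::start(good),
                                 end = IRanges::end(good))
    }
  }
  gr <- if (length(out)) {
    d <- do.call(rbind, out)
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
  } else GenomicRanges::GRanges()
  if (!is.null(exclude) && length(gr)) {
    gr <- GenomicRanges::setdiff(gr, exclude, ignore.strand = TRUE)
  }
  if (!is.null(gene_windows) && length(gr)) {
    ov <- GenomicRanges::findOverlaps(gr, gene_windows, ignore.strand = TRUE)
    pieces <- GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(ov)], gene_windows[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE)
    S4Vectors::mcols(pieces) <- NULL
    S4Vectors::mcols(pieces)$gene <-
      S4Vectors::mcols(gene_windows)$gene[S4Vectors::subjectHits(ov)]
    gr <- pieces
  }
  gr
}

#' Root summed squared error of copy estimates
#'
#' `sqrt(sum((measured - expected)^2))` over matched units - the summed
#' convention; `mean = TRUE` uses the root mean squared error instead.
#'
#' @param measured,expected Named numeric vectors over the same units (or
#'   unnamed vectors of equal length).
#' @param mean Use the mean instead of the sum of squared errors.
#' @return Numeric scalar.
#' @export
rmse <- function(measured, expected, mean = FALSE) {
  if (!is.null(names(measured)) && !is.null(names(expected))) {
    if (!setequal(names(measured), names(expected)))
      stopf("measured and expected cover different unit sets")
    expected <- expected[names(measured)]
  } else if (length(measured) != length(expected)) {
    stopf("measured and expected lengths differ")
  }
  sq <- (measured - expected)^2
  if (mean) sqrt(base::mean(sq)) else sqrt(sum(sq))
}

#' Spike-in evaluation experiment
#'
#' The full evaluation driver: for every combination of read length,
#' pairing and strategy, reads are simulated from every domain at each
#' spiked copy number, aligned with the oracle mapper, and quantified.
#' Measured copies of a source's unit are compared with the copies the same
#' reads would give under perfect (truth-tag) assignment, so the error
#' isolates misalignment from sampling noise; RMSE is accumulated per
#' level and clade in both the summed and mean conventions, and off-target
#' percentages are reported per level.  Align-all strategies count every
#' landing fully and divide clade totals by the clade's domain count.
#'
#' @param genome `DNAStringSet` reference.
#' @param annotation Named annotated `GRanges`.
#' @param read_lengths Read lengths to evaluate.
#' @param paired Logical vector of pairing modes to evaluate.
#' @param copies Spiked copy numbers.
#' @param replicates Replicate simulations per configuration.
#' @param strategies Alignment strategies to evaluate.
#' @param groups Optional `gene_groups` for the group-clade level.
#' @param seed Base RNG seed.
#' @param haploid_coverage Expected haploid coverage.
#' @return List with `rmse` and `off_target` data frames.
#' @export
spike_in_experiment <- function(genome, annotation, read_lengths = c(36L, 100L),
                                paired = c(FALSE, TRUE), copies = c(1L, 5L),
                                replicates = 1L, strategies = "best",
                                groups = NULL, seed = 1L,
                                haploid_coverage = 15) {
  levels <- measurement_levels()
  rmse_rows <- list(); off_rows <- list()
  for (L in read_lengths) for (pe in paired) for (strat in strategies) {
    errs <- list()   # per level: named list of (measured - expected) vectors
    offacc <- list()
    for (rep_i in seq_len(replicates)) for (cc in copies) {
      sp <- sim_spec(read_length = L, paired = pe,
                     haploid_coverage = haploid_coverage,
                     seed = (seed + 1009L * rep_i + 101L * cc + 7L * L +
                               as.integer(pe)) %% 2147483647L)
      rs <- simulate_baseline(annotation, sp, genome, copies = cc)
      rec <- if (pe) oracle_align_pairs(rs, genome, strat, seed = sp$seed)
             else oracle_align(rs, genome, strat, seed = sp$seed)
      fractional <- !strat %in% c("all", "all_crop36")
      frags <- reads_to_fragments(rec, sp$insert$mean,
                                  multiread_correction = fractional)
      truth <- rs$truth
      for (level in levels) {
        cmp <- spike_errors(frags, truth, annotation, level, groups,
                            haploid_coverage, strat)
        key <- sprintf("L%d_%s_c%d_r%d", L, if (pe) "PE" else "SE", cc, rep_i)
        errs[[level]][[key]] <- cmp
      }
      for (level in levels) {
        m <- ambiguity_matrix(rec, annotation, level, groups,
                              fractional = fractional,
                              sample_mean_insert = sp$insert$mean)
        offacc[[level]][[length(offacc[[level]]) + 1L]] <-
          off_target(m)$clade
      }
    }
    for (level in levels) {
      e <- do.call(rbind, errs[[level]])
      for (cl in c("total", unique(e$clade))) {
        sel <- if (cl == "total") rep(TRUE, nrow(e)) else e$clade == cl
        rmse_rows[[length(rmse_rows) + 1L]] <- data.frame(
          read_length = L, paired = pe, strategy = strat, level = level,
          clade = cl,
          rmse_sum = sqrt(sum(e$err[sel]^2)),
          rmse_mean = sqrt(mean(e$err[sel]^2)),
          n = sum(sel), stringsAsFactors = FALSE)
      }
      om <- do.call(rbind, offacc[[level]])
      agg <- tapply(om$off_target, om$clade, mean, na.rm = TRUE)
      off_rows[[length(off_rows) + 1L]] <- data.frame(
        read_length = L, paired = pe, strategy = strat, level = level,
        clade = names(agg), off_target = as.numeric(agg),
        stringsAsFactors = FALSE)
    }
  }
  list(rmse = do.call(rbind, rmse_rows), off_target = do.call(rbind, off_rows))
}

# Measured-vs-expected copy errors for one alignment, at one level.
# measured: coverage of the source's own unit from the source's fragments;
# expected: same quantity under perfect (truth interval) placement.
spike_errors <- function(frags, truth, annotation, level, groups,
                         haploid_coverage, strategy = "best") {
  units <- unit_of_domains(annotation, level, groups)
  mc <- S4Vectors::mcols(annotation)
  unit_len <- tapply(GenomicRanges::width(annotation), units[mc$name], sum)
  clade_of_unit <- tapply(mc$clade, units[mc$name], function(x) x[1])
  nd_unit <- tapply(mc$name, units[mc$name], length)
  ft <- parse_truth_tag(as.character(S4Vectors::mcols(frags)$read))
  src_u <- units[ft$name]
  # overlap of each fragment with each unit's regions
  per_unit_cov <- function(gr, wt, src) {
    ov <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
    if (!length(ov)) return(NULL)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[q], GenomicRanges::ranges(annotation)[s]))
    tgt_u <- units[mc$name[s]]
    on <- src[q] == tgt_u          # only the source's own unit
    rowsum((w * wt[q])[on], src[q][on])
  }
  meas <- per_unit_cov(frags, S4Vectors::mcols(frags)$weight, src_u)
  tgr <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end))
  tsrc <- units[truth$name]
  expc <- per_unit_cov(tgr, rep(1, length(tgr)), tsrc)
  all_u <- unique(units)
  val <- function(m) {
    v <- stats::setNames(rep(0, length(all_u)), all_u)
    if (!is.null(m)) v[rownames(m)] <- m[, 1]
    v / (unit_len[all_u] * haploid_coverage)
  }
  mv <- val(meas); ev <- val(expc)
  if (strategy %in% c("all", "all_crop36")) {
    # align-all: landings counted fully, so the measurement is normalized by
    # the number of reference domains in the unit (the expected side is a
    # per-read truth placement and needs no correction)
    mv <- mv / nd_unit[all_u]
  }
  data.frame(unit = all_u, clade = unname(clade_of_unit[all_u]),
             err = unname(mv - ev), stringsAsFactors = FALSE)
}
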