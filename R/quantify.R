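#' Convert alignment records to weighted genomic fragments
#'
#' Proper pairs are joined into a single fragment spanning the outermost
#' mate coordinates.  Discordant mates of paired data become single
#' fragments extended 3'-ward to half the sample mean insert size
#' (deterministically; a read already longer than that keeps its length);
#' genuinely single-end reads (mate 0) keep their own length, since no
#' insert exists for them.  Every fragment carries weight `1 / n_loci` so
#' multi-mapping reads contribute one read-unit in total (multiread
#' correction).
#'
#' @param records Alignment records (see [oracle_align()]).
#' @param sample_mean_insert Sample mean insert size in bp.
#' @param multiread_correction Weight each landing by `1/n_loci` (the
#'   multiread correction).  `FALSE` counts every landing fully, the
#'   align-all convention (pair it with the clade-count normalization).
#' @return `GRanges` with metadata columns `weight` and `read`.
#' @export
reads_to_fragments <- function(records, sample_mean_insert = 350,
                               multiread_correction = TRUE) {
  if (!nrow(records)) {
    return(GenomicRanges::GRanges(weight = numeric(0), read = character(0)))
  }
  pro <- records[records$proper_pair, , drop = FALSE]
  sing <- records[!records$proper_pair, , drop = FALSE]
  out <- list()
  if (nrow(pro)) {
    key <- paste(pro$read, pro$combo, sep = "\r")
    o <- order(key)
    pro <- pro[o, , drop = FALSE]; key <- key[o]
    first <- !duplicated(key)
    fs <- tapply(pro$start, key, min)[key[first]]
    fe <- tapply(pro$end, key, max)[key[first]]
    out$pairs <- GenomicRanges::GRanges(
      pro$chrom[first], IRanges::IRanges(as.integer(fs), as.integer(fe)),
      weight = if (multiread_correction) 1 / pro$n_loci[first]
               else rep(1, sum(first)),
      read = pro$read[first])
  }
  if (nrow(sing)) {
    ext <- as.integer(round(sample_mean_insert / 2))
    len <- ifelse(sing$mate == 0L, sing$end - sing$start + 1L,
                  pmax(sing$end - sing$start + 1L, ext))
    s <- ifelse(sing$strand == "+", sing$start, sing$end - len + 1L)
    e <- ifelse(sing$strand == "+", sing$start + len - 1L, sing$end)
    out$singles <- GenomicRanges::GRanges(
      sing$chrom, IRanges::IRanges(pmax(1L, as.integer(s)), as.integer(e)),
      weight = if (multiread_correction) 1 / sing$n_loci
               else rep(1, nrow(sing)),
      read = sing$read)
  }
  cat_granges(out)
}

#' Weighted coverage of quantification regions
#'
#' For each region, `covered_bases` is the sum over fragments of
#' (overlap length x fragment weight); `coverage` divides by the region
#' length.
#'
#' @param fragments Weighted fragment `GRanges` from [reads_to_fragments()].
#' @param regions Named `GRanges` of disjoint quantification regions.
#' @return `data.frame` with columns `name`, `length`, `covered_bases`,
#'   `coverage`, `n_fragments`.
#' @export
domain_coverage <- function(fragments, regions) {
  n <- length(regions)
  covered <- numeric(n); nfrag <- numeric(n)
  if (length(fragments)) {
    ov <- GenomicRanges::findOverlaps(fragments, regions, ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(fragments)[q], GenomicRanges::ranges(regions)[s]))
      wt <- S4Vectors::mcols(fragments)$weight[q]
      agg <- rowsum(w * wt, s)
      covered[as.integer(rownames(agg))] <- agg[, 1]
      aggn <- rowsum(wt, s)
      nfrag[as.integer(rownames(aggn))] <- aggn[, 1]
    }
  }
  data.frame(name = names(regions) %||% as.character(seq_len(n)),
             length = GenomicRanges::width(regions),
             covered_bases = covered,
             coverage = covered / GenomicRanges::width(regions),
             n_fragments = nfrag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Copy number from coverage
#'
#' Copies are coverage divided by the expected haploid coverage (15x for
#' the standard simulations; for real samples use half the background mean).
#'
#' @param coverage `data.frame` from [domain_coverage()].
#' @param expected_haploid Expected haploid coverage.
#' @return The input with a `copies` column added.
#' @export
copies_from_coverage <- function(coverage, expected_haploid = 15) {
  stopifnot(expected_haploid > 0)
  coverage$copies <- coverage$coverage / expected_haploid
  coverage
}

#' Aggregate domain copies to all measurement levels
#'
#' Builds the copy-number table at the five levels of resolution: domain,
#' gene-specific clade, group-specific clade, clade and gene.  Every level
#' is the sum of its constituent domain copies, so totals are conserved
#' across levels.  Under the align-all strategies the values of each clade
#' are further divided by that clade's (haploid) reference domain count,
#' applied uniformly at every level so that conservation still holds.
#'
#' @param domain_copies `data.frame` with columns `name` and `copies`
#'   (from [copies_from_coverage()]).
#' @param annotation Named annotated `GRanges` (provides gene and clade per
#'   domain).
#' @param groups Optional `gene_groups` object from [derive_groups()]; when
#'   absent each gene forms its own group.
#' @param strategy Alignment strategy used (enables the align-all clade
#'   normalization for `all` / `all_crop36`).
#' @return `data.frame` with columns `level`, `unit`, `clade`, `copies`.
#' @export
aggregate_copies <- function(domain_copies, annotation, groups = NULL,
                             strategy = "best") {
  mc <- S4Vectors::mcols(annotation)
  i <- match(domain_copies$name, mc$name)
  if (anyNA(i)) stopf("domains missing from annotation: %s",
                      paste(domain_copies$name[is.na(i)], collapse = ", "))
  gene <- mc$gene[i]; clade <- mc$clade[i]
  copies <- domain_copies$copies
  if (strategy %in% c("all", "all_crop36")) {
    nclade <- table(mc$clade)
    copies <- copies / as.numeric(nclade[clade])
  }
  grp <- if (!is.null(groups)) group_of(groups, gene, clade) else gene
  if (anyNA(grp)) stopf("domain without a gene group: %s",
                        paste(domain_copies$name[is.na(grp)], collapse = ", "))
  lvl <- function(level, unit, cl) {
    agg <- rowsum(copies, paste(unit, cl, sep = "\r"))
    key <- rownames(agg)
    parts <- strsplit(key, "\r", fixed = TRUE)
    data.frame(level = level,
               unit = vapply(parts, `[`, character(1), 1),
               clade = vapply(parts, `[`, character(1), 2),
               copies = as.numeric(agg), stringsAsFactors = FALSE)
  }
  out <- rbind(
    lvl("domain", domain_copies$name, clade),
    lvl("gene-clade", paste(gene, clade, sep = "_"), clade),
    lvl("group-clade", paste(grp, clade, sep = "_"), clade),
    lvl("clade", clade, clade),
    lvl("gene", gene, "all"))
  rownames(out) <- NULL
  out
}

#' Fit a GC-bias correction model
#'
#' Read depth per 1 kb window is regressed on window GC content with a
#' loess smoother; the correction factor at a GC value is the global mean
#' depth divided by the fitted depth, so multiplying observed depth by the
#' factor removes the GC trend.  A degenerate GC range yields an identity
#' model with a warning.
#'
#' @param depth Numeric depth per bin.
#' @param gc GC fraction per bin (0-1).
#' @param span Loess span.
#' @return A `gc_model` object; evaluate with [gc_factor()].
#' @export
fit_gc_model <- function(depth, gc, span = 0.75) {
  stopifnot(length(depth) == length(gc))
  ok <- is.finite(depth) & is.finite(gc)
  depth <- depth[ok]; gc <- gc[ok]
  if (length(unique(round(gc, 6))) < 3) {
    warnf("degenerate GC range; returning identity GC model")
    return(structure(list(identity = TRUE, mean_depth = mean(depth)),
                     class = "gc_model"))
  }
  fit <- stats::loess(depth ~ gc, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(gc), max(gc), length.out = 101)
  fitted <- stats::predict(fit, data.frame(gc = grid))
  fitted <- pmax(fitted, 1e-8 + 0.01 * mean(depth))
  structure(list(identity = FALSE, mean_depth = mean(depth), grid = grid,
                 fitted = fitted, range = range(gc)), class = "gc_model")
}

#' Evaluate a GC model's correction factor
#'
#' @param model A `gc_model` from [fit_gc_model()].
#' @param gc GC fraction(s); values outside the fitted range use the
#'   nearest fitted value.
#' @return Numeric correction factor(s) (1 where depth equals the mean).
#' @export
gc_factor <- function(model, gc) {
  if (model$identity) return(rep(1, length(gc)))
  gc <- pmin(pmax(gc, model$range[1]), model$range[2])
  f <- stats::approx(model$grid, model$fitted, xout = gc, rule = 2)$y
  model$mean_depth / f
}

#' GC content and depth per genomic window
#'
#' Tiles the reference into fixed-width windows and reports each window's
#' GC fraction; with fragments supplied, also the weighted depth.
#'
#' @param genome `DNAStringSet`.
#' @param binsize Window size in bp (1 kb is the standard choice).
#' @param fragments Optional weighted fragment `GRanges`.
#' @return `GRanges` of windows with metadata columns `gc` (and `depth`).
#' @export
gc_bins <- function(genome, binsize = 1000L, fragments = NULL) {
  bins <- list()
  for (chrom in names(genome)) {
    len <- length(genome[[chrom]])
    starts <- seq(1L, len, by = binsize)
    ends <- pmin(starts + binsize - 1L, len)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
    views <- Biostrings::Views(genome[[chrom]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(views, letters = c("GC"), as.prob = TRUE)
    S4Vectors::mcols(gr)$gc <- as.numeric(freq)
    bins[[chrom]] <- gr
  }
  bins <- cat_granges(bins)
  if (!is.null(fragments)) {
    names(bins) <- sprintf("bin%06d", seq_along(bins))
    cov <- domain_coverage(fragments, bins)
    S4Vectors::mcols(bins)$depth <- cov$coverage
    names(bins) <- NULL
  }
  bins
}

#' Normalize sample coverage against background regions
#'
#' Region coverage is divided by the mean coverage of the background
#' (highly conserved, uniquely mappable) regions and multiplied by the GC
#' correction factor of the region; diploid copies are twice the
#' normalized value.
#'
#' @param coverage `data.frame` from [domain_coverage()] for the regions of
#'   interest.
#' @param background_coverage `data.frame` from [domain_coverage()] for the
#'   background regions (its length-weighted mean coverage is the
#'   denominator).
#' @param gc_model Optional `gc_model`.
#' @param region_gc Optional per-region GC fractions (required with
#'   `gc_model`).
#' @return `coverage` with `normalized` and `copies` (diploid) columns.
#' @export
normalize_sample <- function(coverage, background_coverage, gc_model = NULL,
                             region_gc = NULL) {
  bg <- sum(background_coverage$covered_bases) / sum(background_coverage$length)
  if (!is.finite(bg) || bg <= 0) stopf("background regions have zero coverage")
  f <- 1
  if (!is.null(gc_model)) {
    if (is.null(region_gc)) stopf("region_gc required when gc_model is given")
    f <- gc_factor(gc_model, region_gc)
  }
  coverage$normalized <- coverage$coverage / bg * f
  coverage$copies <- 2 * coverage$normalized
  coverage
}

#' Gene copy number from unique regions
#'
#' The diploid copy number of a gene is twice the length-weighted mean
#' normalized depth over its unique (single-mappable, non-domain) regions.
#' Genes without any unique region are reported as unmeasurable (`NA`).
#'
#' @param fragments Weighted fragment `GRanges`.
#' @param unique_regions `GRanges` with a `gene` metadata column.
#' @param background_coverage Background coverage table (see
#'   [normalize_sample()]).
#' @param gc_model,region_gc Optional GC correction.
#' @return `data.frame` with columns `gene`, `copies`, `measurable`.
#' @export
gene_copy_number <- function(fragments, unique_regions, background_coverage,
                             gc_model = NULL, region_gc = NULL) {
  genes <- unique(S4Vectors::mcols(unique_regions)$gene)
  names(unique_regions) <- sprintf("u%06d", seq_along(unique_regions))
  cov <- domain_coverage(fragments, unique_regions)
  cov <- normalize_sample(cov, background_coverage, gc_model, region_gc)
  res <- lapply(genes, function(g) {
    sel <- S4Vectors::mcols(unique_regions)$gene == g
    if (!any(sel) || sum(cov$length[sel]) == 0) {
      return(data.frame(gene = g, copies = NA_real_, measurable = FALSE))
    }
    copies <- 2 * sum(cov$normalized[sel] * cov$length[sel]) / sum(cov$length[sel])
    data.frame(gene = g, copies = copies, measurable = TRUE)
  })
  do.call(rbind, res)
}

#' Quality-trim and length-filter reads
#'
#' Low-quality 3' tails are removed with the standard partial-sum rule
#' (trim at the position minimising the cumulative `quality - threshold`
#' from the 3' end, as in cutadapt/BWA); reads trimmed below `min_length`
#' are dropped, and a paired read set drops both mates together.
#'
#' @param reads A `read_set`.
#' @param qual_threshold Phred threshold (default 10).
#' @param min_length Minimum surviving read length (default 80).
#' @return List with the filtered `read_set` (`reads`) and a `stats` list
#'   (`n_in`, `n_out`, `n_dropped`).
#' @export
filter_reads <- function(reads, qual_threshold = 10L, min_length = 80L) {
  trim_point <- function(qual) {
    q <- char_to_phred(qual)
    s <- rev(cumsum(rev(q - qual_threshold)))   # s[i] = sum_{j>=i}(q_j - thr)
    cut <- which(s == min(s, na.rm = TRUE))
    if (min(s) >= 0) length(q) else max(0L, cut[length(cut)] - 1L)
  }
  n <- length(reads$seq1)
  if (!n) return(list(reads = reads, stats = list(n_in = 0L, n_out = 0L, n_dropped = 0L)))
  t1 <- vapply(reads$qual1, trim_point, integer(1), USE.NAMES = FALSE)
  keep <- t1 >= min_length
  if (reads$paired) {
    t2 <- vapply(reads$qual2, trim_point, integer(1), USE.NAMES = FALSE)
    keep <- keep & t2 >= min_length
  }
  out <- reads
  out$seq1 <- substring(reads$seq1, 1L, t1)[keep]
  names(out$seq1) <- names(reads$seq1)[keep]
  out$qual1 <- substring(reads$qual1, 1L, t1)[keep]
  if (reads$paired) {
    out$seq2 <- substring(reads$seq2, 1L, t2)[keep]
    names(out$seq2) <- names(reads$seq2)[keep]
    out$qual2 <- substring(reads$qual2, 1L, t2)[keep]
  }
  if (!is.null(out$truth)) out$truth <- reads$truth[keep, , drop = FALSE]
  list(reads = out,
       stats = list(n_in = n, n_out = sum(keep), n_dropped = n - sum(keep)))
}

#' Estimate genome-wide coverage from read counts
#'
#' Coverage is the number of filtered reads times the insert size divided
#' by the genome size; samples below 10x are flagged for removal.
#'
#' @param n_filtered_reads Number of reads surviving [filter_reads()].
#' @param insert Insert size in bp.
#' @param genome_size Reference size in bp.
#' @param min_coverage Flagging threshold (default 10).
#' @return List with `coverage` and `flagged`.
#' @export
estimate_genome_coverage <- function(n_filtered_reads, insert, genome_size,
                                     min_coverage = 10) {
  stopifnot(n_filtered_reads > 0, insert > 0, genome_size > 0)
  cov <- n_filtered_reads * insert / genome_size
  list(coverage = cov, flagged = cov < min_coverage)
}

#' Write a copy-number table as TSV
#'
#' @param tab `data.frame` from [aggregate_copies()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_copy_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Records the headline numbers of a quantification run (strategy, read and
#' fragment counts, background mean, totals per level) in a single JSON
#' object for downstream bookkeeping.
#'
#' @param path Output file.
#' @param strategy Alignment strategy used.
#' @param n_reads,n_fragments Input read units and resulting fragments.
#' @param copy_table `data.frame` from [aggregate_copies()].
#' @param extra Optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(path, strategy, n_reads, n_fragments,
                             copy_table, extra = list()) {
  totals <- tapply(copy_table$copies, copy_table$level, sum)
  report <- c(list(strategy = strategy, n_reads = n_reads,
                   n_fragments = n_fragments,
                   total_copies = as.list(totals)), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
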