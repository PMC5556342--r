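rec_row <- function(read, mate, chrom, start, end, strand = "+", n_loci = 1L,
                    combo = 1L, proper = FALSE) {
  data.frame(read = read, mate = mate, chrom = chrom, start = start, end = end,
             strand = strand, mismatches = 0L, n_loci = n_loci, combo = combo,
             proper_pair = proper, stringsAsFactors = FALSE)
}

test_that("fragments join proper pairs and extend discordant mates 3'-ward", {
  rec <- rbind(
    rec_row("p", 1L, "chr1", 100L, 200L, "+", proper = TRUE),
    rec_row("p", 2L, "chr1", 400L, 500L, "-", proper = TRUE),
    rec_row("d", 1L, "chr1", 1000L, 1099L, "+"),
    rec_row("e", 2L, "chr1", 2000L, 2099L, "-"),
    rec_row("s", 0L, "chr1", 3000L, 3035L, "+"))
  fr <- reads_to_fragments(rec, 350)
  w <- stats::setNames(GenomicRanges::width(fr), S4Vectors::mcols(fr)$read)
  expect_equal(GenomicRanges::start(fr)[S4Vectors::mcols(fr)$read == "p"], 100L)
  expect_equal(GenomicRanges::end(fr)[S4Vectors::mcols(fr)$read == "p"], 500L)
  expect_equal(unname(w["d"]), 175L)   # extended from 100 to half insert
  # minus-strand discordant extends toward lower coordinates
  expect_equal(GenomicRanges::start(fr)[S4Vectors::mcols(fr)$read == "e"], 1925L)
  expect_equal(GenomicRanges::end(fr)[S4Vectors::mcols(fr)$read == "e"], 2099L)
  # genuine single-end reads keep their length
  expect_equal(unname(w["s"]), 36L)
})

test_that("multi-locus reads yield fractional fragments that conserve weight", {
  rec <- do.call(rbind, lapply(1:4, function(k) {
    rec_row("m", 1L, "chr1", 1000L * k, 1000L * k + 99L, n_loci = 4L,
            combo = k)
  }))
  fr <- reads_to_fragments(rec, 350)
  expect_length(fr, 4)
  expect_equal(S4Vectors::mcols(fr)$weight, rep(0.25, 4))
  fr_full <- reads_to_fragments(rec, 350, multiread_correction = FALSE)
  expect_equal(S4Vectors::mcols(fr_full)$weight, rep(1, 4))
})

test_that("weight conservation holds across strategies on a fixtures run", {
  bb <- baseline_best()
  for (strat in c("best", "best_ties", "all")) {
    rec <- if (strat == "best") bb$records
           else oracle_align_pairs(bb$reads, bb$truth$genome, strat, seed = 1234L)
    fr <- reads_to_fragments(rec, 350)
    units <- length(unique(ifelse(rec$proper_pair, rec$read,
                                  paste(rec$read, rec$mate))))
    expect_equal(sum(S4Vectors::mcols(fr)$weight), units, tolerance = 1e-9)
  }
})

test_that("coverage is weighted overlap divided by region length", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  names(regions) <- "R"
  fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
                               weight = 1, read = "a")
  expect_equal(domain_coverage(fr, regions)$coverage, 1)
  fr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 1500),
                                weight = 0.5, read = "b")
  expect_equal(domain_coverage(fr2, regions)$coverage, 0.25)
  none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100),
                                 weight = 1, read = "c")
  expect_equal(domain_coverage(none, regions)$coverage, 0)
  expect_equal(copies_from_coverage(domain_coverage(fr, regions), 15)$copies,
               1 / 15)
  cov <- data.frame(name = "R", length = 1000, covered_bases = c(15000, 45000),
                    coverage = c(15, 45), n_fragments = 1)
  expect_equal(copies_from_coverage(cov, 15)$copies, c(1, 3))
})

test_that("diploid baseline coverage recovers ~30x over each domain", {
  bb <- baseline_best()
  fr <- reads_to_fragments(bb$records, 350)
  cov <- domain_coverage(fr, bb$truth$annotation)
  cp <- copies_from_coverage(cov, 15)
  expect_lt(abs(mean(cp$copies) - 2), 0.1)
  expect_true(all(abs(cp$copies - 2) < 0.6))
})

test_that("GC model factors invert the fitted depth trend", {
  gc <- seq(0.3, 0.7, length.out = 100)
  flat <- fit_gc_model(rep(20, 100), gc)
  expect_equal(gc_factor(flat, c(0.35, 0.5)), c(1, 1), tolerance = 1e-6)
  biased <- fit_gc_model(ifelse(gc > 0.55, 40, 20), gc)
  expect_lt(gc_factor(biased, 0.65), 0.75)
  # sinusoidal bias + sampling noise: corrected depth has no residual GC trend
  gc2 <- seq(0.3, 0.7, length.out = 200)
  depth <- withr::with_seed(6, 30 * (1 + 0.4 * sin(8 * gc2)) + rnorm(200, 0, 1.5))
  m <- fit_gc_model(depth, gc2, span = 0.3)
  corrected <- depth * gc_factor(m, gc2)
  expect_gt(abs(stats::cor(depth, gc2)), 0.5)
  expect_lt(abs(stats::cor(corrected, gc2)), 0.1)
  expect_warning(ident <- fit_gc_model(rep(20, 50), rep(0.5, 50)), "degenerate")
  expect_equal(gc_factor(ident, 0.2), 1)
})

test_that("gc_bins reports GC fraction and weighted depth per window", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("AT", 500), strrep("GC", 500))))
  fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), weight = 1,
                               read = "x")
  b <- gc_bins(g, 1000L, fr)
  expect_equal(S4Vectors::mcols(b)$gc, c(0, 1))
  expect_equal(S4Vectors::mcols(b)$depth, c(1, 0))
})

test_that("background normalization yields diploid copies", {
  cov <- data.frame(name = "R", length = 1000, covered_bases = 60000,
                    coverage = 60, n_fragments = 1)
  bg <- data.frame(name = "B", length = 1000, covered_bases = 30000,
                   coverage = 30, n_fragments = 1)
  out <- normalize_sample(cov, bg)
  expect_equal(out$normalized, 2)
  expect_equal(out$copies, 4)
  expect_equal(normalize_sample(bg, bg)$normalized, 1)
  bg0 <- bg; bg0$covered_bases <- 0
  expect_error(normalize_sample(cov, bg0), "zero coverage")
})

test_that("aggregation conserves totals at every level", {
  bb <- baseline_best()
  fr <- reads_to_fragments(bb$records, 350)
  cp <- copies_from_coverage(domain_coverage(fr, bb$truth$annotation), 15)
  tab <- aggregate_copies(cp, bb$truth$annotation)
  tot <- tapply(tab$copies, tab$level, sum)
  expect_equal(unname(diff(range(tot))), 0, tolerance = 1e-9)
  # clade totals equal the sum of their gene-clade entries
  gc_tab <- tab[tab$level == "gene-clade", ]
  cl_tab <- tab[tab$level == "clade", ]
  by_clade <- tapply(gc_tab$copies, gc_tab$clade, sum)
  expect_equal(as.numeric(by_clade[cl_tab$unit]), cl_tab$copies,
               tolerance = 1e-9)
  # a single-gene group carries the gene's value
  expect_equal(sort(tab$copies[tab$level == "group-clade"]),
               sort(gc_tab$copies), tolerance = 1e-9)
  expect_error(aggregate_copies(data.frame(name = "nope", copies = 1),
                                bb$truth$annotation), "missing from annotation")
})

test_that("quality filtering trims 3' tails and drops short survivors in pairs", {
  q40 <- dupdepth:::phred_to_char(rep(40, 100))
  tail5 <- dupdepth:::phred_to_char(c(rep(40, 70), rep(5, 30)))
  rs <- structure(list(
    seq1 = stats::setNames(rep(strrep("A", 100), 3), c("a", "b", "c")),
    qual1 = c(q40, tail5, q40),
    seq2 = stats::setNames(rep(strrep("C", 100), 3), c("a", "b", "c")),
    qual2 = c(q40, q40, tail5),
    paired = TRUE, truth = NULL), class = "read_set")
  out <- filter_reads(rs, 10L, 80L)
  # b: mate1 trimmed to 70 -> dropped; c: mate2 trimmed -> pair dropped too
  expect_equal(out$stats$n_out, 1L)
  expect_equal(names(out$reads$seq1), "a")
  expect_equal(nchar(out$reads$seq1[[1]]), 100L)
  # single-end: partial trim survives when long enough
  se <- structure(list(
    seq1 = stats::setNames(strrep("A", 100), "s"),
    qual1 = dupdepth:::phred_to_char(c(rep(40, 90), rep(5, 10))),
    seq2 = NULL, qual2 = NULL, paired = FALSE, truth = NULL),
    class = "read_set")
  out2 <- filter_reads(se, 10L, 80L)
  expect_equal(nchar(out2$reads$seq1[[1]]), 90L)
})

test_that("genome coverage estimate applies the insert formula and 10x flag", {
  est <- estimate_genome_coverage(1e6, 350, 3.5e8)
  expect_equal(est$coverage, 1)
  # 9.5x: below the 10x threshold, flagged for removal
  expect_true(estimate_genome_coverage(9.5e6, 350, 3.5e8)$flagged)
  expect_false(estimate_genome_coverage(2e7, 350, 3.5e8)$flagged)
  expect_equal(estimate_genome_coverage(2e7, 350, 3.5e8)$coverage, 20)
})

test_that("run reports record per-level totals as JSON", {
  tab <- data.frame(level = c("domain", "domain", "clade"),
                    unit = c("A_CON1_1", "A_CON2_1", "CON1"),
                    clade = c("CON1", "CON2", "CON1"),
                    copies = c(2, 2.5, 2))
  f <- tempfile(fileext = ".json")
  write_run_report(f, "best", n_reads = 100, n_fragments = 99, tab)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$strategy, "best")
  expect_equal(rep$total_copies$domain, 4.5)
  expect_equal(rep$n_fragments, 99)
})

test_that("gene copy number from unique flanks tracks gene dosage", {
  ts <- toy_distinct()
  cnv <- make_cnv_sample(ts, data.frame(unit = "SYN2", copies = 4),
                         sim_spec(seed = 31L))
  rec <- oracle_align_pairs(cnv$reads, ts$genome, "best", seed = 31L)
  fr <- reads_to_fragments(rec, 350)
  # background: flanks of genes untouched by events
  bgsel <- !S4Vectors::mcols(ts$flanks)$gene %in% "SYN2"
  bg <- domain_coverage(fr, ts$flanks[bgsel])
  gcn <- gene_copy_number(fr, ts$flanks, bg)
  expect_equal(gcn$copies[gcn$gene == "SYN2"], 4, tolerance = 0.35)
  expect_lt(max(abs(gcn$copies[gcn$gene != "SYN2"] - 2)), 0.35)
  # a gene with no unique region is reported unmeasurable
  empty <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 0), gene = "GHOST")
  gcn2 <- gene_copy_number(fr, c(ts$flanks, empty), bg)
  expect_false(gcn2$measurable[gcn2$gene == "GHOST"])
  expect_true(is.na(gcn2$copies[gcn2$gene == "GHOST"]))
})
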