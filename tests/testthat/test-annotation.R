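test_that("domain hit parsing filters by E-value and sorts hits", {
  lines <- c("# comment",
             domtbl_line("chr1", 5000, 5400, 1e-12),
             domtbl_line("chr1", 1000, 1400, 9.9e-11),
             domtbl_line("chr1", 3000, 3400, 1e-11),
             domtbl_line("chr1", 7000, 7400, 1e-9),
             domtbl_line("chr1", 9000, 9400, 1e-10))   # not strictly below
  hits <- parse_domain_hits(lines, 1e-10)
  expect_length(hits, 3)
  expect_true(all(S4Vectors::mcols(hits)$evalue < 1e-10))
  expect_equal(GenomicRanges::start(hits), c(1000L, 3000L, 5000L))

  expect_length(parse_domain_hits(character(0)), 0)
  expect_length(parse_domain_hits("# only comments"), 0)
  expect_error(parse_domain_hits("chr1 broken line", 1e-10),
               "malformed.*line 1")
  expect_error(parse_domain_hits(domtbl_line("chrZ", 1, 400, 1e-12), 1e-10,
                                 reference = c(chr1 = 1e5)),
               "unknown sequence")
})

test_that("nhmmer-style stranded lines are parsed onto the forward strand", {
  ln <- "chr1 - Q - 1 65 1400 1000 1390 1010 100000 - 1e-12 90.0 0.1 -"
  h <- parse_domain_hits(ln, 1e-10)
  expect_equal(GenomicRanges::start(h), 1000L)
  expect_equal(GenomicRanges::end(h), 1400L)
  expect_equal(as.character(GenomicRanges::strand(h)), "-")
})

test_that("exon pairing finds the short upstream exon or flags its absence", {
  ex <- doublet_exons()
  hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3310, 3660))
  ann <- pair_exons(hit, ex)
  expect_false(S4Vectors::mcols(ann)$short_missing)
  expect_equal(S4Vectors::mcols(ann)$short_start, 3000L)
  expect_equal(GenomicRanges::start(ann), 3000L)      # span covers both exons

  # only preceding exon is 130 bp: outside 50-111, flagged absent
  ex2 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1000L, 2000L), width = c(130L, 372L)),
                                strand = "+", gene = "G")
  ann2 <- pair_exons(GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2371)), ex2)
  expect_true(S4Vectors::mcols(ann2)$short_missing)

  expect_error(pair_exons(GenomicRanges::GRanges("chr1", IRanges::IRanges(9e5, 9e5 + 100)),
                          ex), "not contained")
})

test_that("a three-doublet gene pairs all domains without flags", {
  ex <- doublet_exons()
  hits <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1300, 3300, 5300), width = 372))
  S4Vectors::mcols(ex)$gene <- "GENEA"
  anns <- annotate_domains(hits, ex)
  expect_length(anns, 3)
  expect_false(any(S4Vectors::mcols(anns)$short_missing))
})

test_that("minus-strand genes pick the short exon downstream in coordinates", {
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(2000L, 3000L), width = c(372L, 78L)),
    strand = "-", gene = "G")
  ann <- pair_exons(GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2371),
                                           strand = "-"), ex)
  expect_false(S4Vectors::mcols(ann)$short_missing)
  expect_equal(S4Vectors::mcols(ann)$short_start, 3000L)
})

test_that("clade assignment follows motif logic including hybrids", {
  motifs <- toy_motif_table()
  s_hls1 <- motifs$motif[motifs$clade == "HLS1" & motifs$exon == "short"]
  l_hls1 <- motifs$motif[motifs$clade == "HLS1" & motifs$exon == "long"]
  l_hls2 <- motifs$motif[motifs$clade == "HLS2" & motifs$exon == "long"]
  l_con1 <- motifs$motif[motifs$clade == "CON1" & motifs$exon == "long"]

  expect_equal(assign_clade(paste0("AAAA", l_con1, "AAAA"), motifs), "CON1")
  expect_equal(assign_clade(list(short = s_hls1, long = l_hls1), motifs), "HLS1")
  expect_equal(assign_clade(list(short = s_hls1, long = l_hls2), motifs), "HYBRID")
  expect_equal(assign_clade("MKLVNPEWRTSGAD", motifs), "UNASSIGNED")
  expect_error(assign_clade(list(short = NA, long = paste0(l_hls1, l_hls2)), motifs),
               "conflicting")
})

test_that("domain naming numbers each (gene, clade) independently in gene order", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 500, 900, 1300, 1700), width = 50), strand = "+",
    gene = "NBPF1", clade = c("CON1", "HLS1", "CON1", "HLS1", "CON1"))
  named <- name_domains(gr)
  expect_equal(S4Vectors::mcols(named)$name,
               c("NBPF1_CON1_1", "NBPF1_HLS1_1", "NBPF1_CON1_2",
                 "NBPF1_HLS1_2", "NBPF1_CON1_3"))
  expect_equal(S4Vectors::mcols(named)$name[5], "NBPF1_CON1_3")
  # idempotent
  expect_identical(S4Vectors::mcols(name_domains(named))$name,
                   S4Vectors::mcols(named)$name)
  # minus strand: numbering runs against coordinates
  GenomicRanges::strand(gr) <- "-"
  rev_named <- name_domains(gr)
  expect_equal(S4Vectors::mcols(rev_named)$name[1], "NBPF1_CON1_3")
})

test_that("quantification regions extend by the gap rule and stay disjoint", {
  mk <- function(starts) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 500),
                                 strand = "+", gene = "G",
                                 clade = "CON1")
    name_domains(gr)
  }
  # 3 kb apart: full 250 bp extension on the facing sides
  q <- build_quant_regions(mk(c(10000L, 13500L)))
  expect_equal(GenomicRanges::end(q)[1], 10499L + 250L)
  expect_equal(GenomicRanges::start(q)[2], 13500L - 250L)
  # 100 bp apart: no extension between them
  q2 <- build_quant_regions(mk(c(10000L, 10600L)))
  expect_equal(GenomicRanges::end(q2)[1], 10499L)
  expect_equal(GenomicRanges::start(q2)[2], 10600L)
  # 1.2 kb gap: extension capped at 100 bp so the extended regions stay
  # a full gap-threshold apart
  q3 <- build_quant_regions(mk(c(10000L, 11700L)))
  expect_equal(GenomicRanges::end(q3)[1], 10499L + 100L)
  expect_equal(GenomicRanges::start(q3)[2], 11700L - 100L)
  # disjointness on the toy annotation
  ann <- toy()$annotation
  expect_length(IRanges::findOverlaps(GenomicRanges::ranges(ann),
                                      drop.self = TRUE), 0)
})

test_that("canonical filtering drops non-canonical clades unless asked", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100, 200), width = 50),
                               gene = "G", clade = c("CON1", "CON7", "HYBRID"),
                               name = c("a", "b", "c"))
  expect_length(canonical_domains(gr), 1)
  expect_length(canonical_domains(gr, include_noncanonical = TRUE), 3)
})

test_that("exon-annotation choice prefers doublet structure, then UTR count", {
  good <- doublet_exons()
  bad <- good[GenomicRanges::width(good) > 100]      # drop the short exons
  hits <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1300, 3300, 5300),
                                                          width = 372))
  expect_identical(choose_exon_annotation(bad, good, hits), good)
  # tie on doublets: more UTR exons wins
  a <- good; S4Vectors::mcols(a)$utr <- FALSE
  b <- good; S4Vectors::mcols(b)$utr <- c(TRUE, rep(FALSE, 5))
  expect_identical(choose_exon_annotation(a, b, hits), b)
})

test_that("annotation pipeline reproduces the truth BED byte for byte", {
  ts <- toy()
  hits <- parse_domain_hits(truth_domtbl(ts), 1e-10, reference = ts$genome)
  expect_length(hits, length(ts$annotation))
  dom <- annotate_domains(hits, ts$exons)
  dom <- assign_clades(dom, ts$genome, ts$motifs)
  dom <- name_domains(dom)
  dom <- build_quant_regions(dom, seqlengths = c(chr1 = ts$spec$genome_size))
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_domain_bed(ts$annotation, f1)
  write_domain_bed(dom, f2)
  expect_identical(readLines(f2), readLines(f1))
  # name -> domain is a bijection
  expect_false(anyDuplicated(S4Vectors::mcols(dom)$name) > 0)
  # BED round trip preserves coordinates and name decomposition
  back <- read_domain_bed(f2)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(dom))
  expect_equal(S4Vectors::mcols(back)$gene, S4Vectors::mcols(dom)$gene)
})

test_that("parser reads genuine hmmsearch domtblout", {
  skip_if(Sys.which("hmmbuild") == "" || Sys.which("hmmsearch") == "",
          "HMMER not on PATH")
  dir <- tempfile(); dir.create(dir)
  pep <- "MKLVNDAKTYNEWQRHPFMESVKGA"
  msa <- file.path(dir, "seed.sto")
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("seq1 %s", pep), sprintf("seq2 %s", pep),
               sprintf("seq3 %s", pep), "//"), msa)
  hmm <- file.path(dir, "m.hmm")
  system2("hmmbuild", c("--amino", hmm, msa), stdout = FALSE, stderr = FALSE)
  tgt <- file.path(dir, "t.fa")
  writeLines(c(">prot1", paste0("GGGGG", pep, "AAAAA")), tgt)
  out <- file.path(dir, "hits.domtbl")
  system2("hmmsearch", c("--domtblout", out, hmm, tgt),
          stdout = FALSE, stderr = FALSE)
  hits <- parse_domain_hits(out, max_evalue = 1e-5)
  expect_length(hits, 1)
  expect_equal(as.character(GenomicRanges::seqnames(hits)), "prot1")
  expect_lt(abs(GenomicRanges::start(hits) - 6), 3)
})
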