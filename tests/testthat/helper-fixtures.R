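# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# Standard toy genome (clustered genes, 1% within / 10% between divergence),
# scaled to 600 kb so the whole suite stays fast.
toy <- function() memo("toy", function() {
  make_toy_genome(family_spec(genome_size = 6e5))
})

# Toy genome with singleton clusters: every gene >= 10% diverged from all
# others, so every domain is uniquely mappable at 100 bp.
toy_distinct <- function() memo("toy_distinct", function() {
  make_toy_genome(family_spec(clusters = as.list(1:6), genome_size = 6e5,
                              seed = 3L))
})

worked <- function() memo("worked", function() make_worked_example())

# Diploid 100 bp PE baseline on toy(), aligned with best.
baseline_best <- function() memo("baseline_best", function() {
  ts <- toy()
  sp <- sim_spec(seed = 1234L)
  rs <- simulate_baseline(ts$annotation, sp, ts$genome)
  rec <- oracle_align_pairs(rs, ts$genome, "best", seed = 1234L)
  list(truth = ts, spec = sp, reads = rs, records = rec)
})

# 36 bp SE diploid baseline on toy() (heavy read sharing), aligned with best.
baseline_se36 <- function() memo("baseline_se36", function() {
  ts <- toy()
  sp <- sim_spec(read_length = 36L, paired = FALSE, seed = 77L)
  rs <- simulate_baseline(ts$annotation, sp, ts$genome)
  rec <- oracle_align(rs, ts$genome, "best", seed = 77L)
  list(truth = ts, spec = sp, reads = rs, records = rec)
})

# A small hand-made exon model: gene with three short/long doublets.
doublet_exons <- function(gene = "GENEA", chrom = "chr1", strand = "+") {
  starts <- c(1000L, 1300L, 3000L, 3300L, 5000L, 5300L)
  widths <- c(78L, 372L, 78L, 372L, 78L, 372L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = widths),
                         strand = strand, gene = gene)
}

# domtblout lines for hand-made hits (hmmsearch 22+ column layout).
domtbl_line <- function(target, from, to, evalue) {
  sprintf("%s - 100000 Q - 65 %.2e 99.0 0.1 1 1 %.2e %.2e 90.0 0.1 1 65 %d %d %d %d 0.95 -",
          target, evalue, evalue / 10, evalue, from, to, from, to)
}
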