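test_that("unique domains sit on the ambiguity matrix diagonal", {
  bd <- baseline_best()   # 100 bp PE: within-cluster sharing is small
  m <- ambiguity_matrix(bd$records, bd$truth$annotation, "domain")
  expect_equal(attr(m, "level"), "domain")
  expect_true(all(diag(as.matrix(m)) > 85))
  expect_true(all(m >= 0 & m <= 100))
  expect_true(all(rowSums(as.matrix(m)) <= 100 + 1e-9))
  # untagged reads are rejected
  bad <- bd$records
  bad$read <- sub("^origin\\|", "x|", bad$read)
  expect_error(ambiguity_matrix(bad, bd$truth$annotation, "domain"),
               "truth tag")
})

test_that("reads from identical loci split rows evenly and flag silent rows", {
  we <- worked()
  # simulate only from the focal domain; the duplicated segment is the
  # only off-target sink, so off-diagonal mass equals the tie loss
  sp <- sim_spec(copies = 4L, seed = 17L)
  rs <- simulate_spike_in(we$annotation[1], 4, sp, we$genome)
  rec <- oracle_align_pairs(rs, we$genome, "best", seed = 17L)
  m <- ambiguity_matrix(rec, we$annotation, "domain")
  expect_equal(dim(m), c(1L, 1L))
  ot <- off_target(m)
  expect_equal(ot$source$off_target, 100 - m[1, 1])
  # ~20% of fragments tie and half of those land off target
  expect_lt(abs(ot$source$off_target - 10), 1.5)
  # a source with no aligned reads is flagged
  empty <- rec[0, ]
  m0 <- ambiguity_matrix(empty, we$annotation, "domain")
  expect_true("FOCAL_CON1_1" %in% attr(m0, "flagged"))
})

test_that("off-target summaries are zero on diagonal matrices and weighted by reads", {
  m <- matrix(c(100, 0, 0, 100), 2, 2,
              dimnames = list(c("A_CON1_1", "B_CON1_1"),
                              c("A_CON1_1", "B_CON1_1")))
  m <- structure(m, class = c("ambiguity_matrix", "matrix"), level = "domain",
                 row_weight = c(A_CON1_1 = 100, B_CON1_1 = 300),
                 flagged = character(0))
  ot <- off_target(m)
  expect_equal(ot$source$off_target, c(0, 0))
  expect_equal(ot$clade$off_target, 0)
  m2 <- m; m2[1, ] <- c(90, 10)
  ot2 <- off_target(m2)
  expect_equal(ot2$source$off_target[1], 10)
  expect_equal(ot2$clade$off_target, 10 * 100 / 400)  # read-weighted
})

test_that("off-target rates never increase as levels coarsen", {
  bd <- baseline_se36()   # heavy sharing at 36 bp
  groups <- derive_groups(
    ambiguity_matrix(bd$records, bd$truth$annotation, "gene-clade"),
    threshold = 5)
  overall <- sapply(measurement_levels(), function(level) {
    m <- ambiguity_matrix(bd$records, bd$truth$annotation, level, groups)
    ot <- off_target(m)$source
    w <- attr(m, "row_weight")[ot$unit]
    sum(ot$off_target * w) / sum(w)
  })
  expect_true(all(diff(unname(overall)) <= 1e-9))
  expect_gt(overall[["domain"]], overall[["clade"]])
})

test_that("gene grouping follows shared ambiguity components", {
  # zero off-diagonal: every gene its own group
  units <- c("A_CON1", "B_CON1", "C_CON1")
  mk <- function(vals) structure(
    matrix(vals, 3, 3, byrow = TRUE, dimnames = list(units, units)),
    class = c("ambiguity_matrix", "matrix"), level = "gene-clade",
    row_weight = stats::setNames(rep(100, 3), units), flagged = character(0))
  g0 <- derive_groups(mk(diag(3) * 100), threshold = 5)
  expect_equal(sort(unique(g0$group)), c("A", "B", "C"))
  # chain A<->B, B<->C merges all three transitively
  chain <- mk(c(90, 10, 0,  10, 80, 10,  0, 10, 90))
  g1 <- derive_groups(chain, threshold = 5)
  expect_equal(unique(g1$group), "A.B.C")
  # one-directional sharing suffices
  oneway <- mk(c(90, 10, 0,  0, 100, 0,  0, 0, 100))
  g2 <- derive_groups(oneway, threshold = 5)
  expect_equal(sort(unique(g2$group)), c("A.B", "C"))
  # invariant to gene ordering
  perm <- chain[c(3, 1, 2), c(3, 1, 2)]
  perm <- structure(perm, class = c("ambiguity_matrix", "matrix"),
                    level = "gene-clade",
                    row_weight = attr(chain, "row_weight")[c(3, 1, 2)],
                    flagged = character(0))
  expect_equal(unique(derive_groups(perm, 5)$group), "A.B.C")
})

test_that("95%-identical genes group together under 36 bp reads", {
  # domain_spacing below the extension threshold keeps quantification
  # regions equal to the domains, so most reads lie in shared sequence
  ts <- make_toy_genome(family_spec(n_genes = 2L, clusters = list(1:2),
                                    divergence_within = 0.05,
                                    domain_spacing = 800L, long_exon = 1600L,
                                    genome_size = 1e5, seed = 8L))
  sp <- sim_spec(read_length = 36L, paired = FALSE, seed = 8L)
  rs <- simulate_baseline(ts$annotation, sp, ts$genome)
  rec <- oracle_align(rs, ts$genome, "best", seed = 8L)
  m <- ambiguity_matrix(rec, ts$annotation, "gene-clade")
  g <- derive_groups(m, threshold = 5)
  expect_equal(unique(g$group), "SYN1.SYN2")
})

test_that("realized within-cluster identity matches the 95% divergence target", {
  ts <- make_toy_genome(family_spec(n_genes = 2L, clusters = list(1:2),
                                    divergence_within = 0.05,
                                    genome_size = 1e5, seed = 8L))
  ann <- ts$annotation
  mc <- S4Vectors::mcols(ann)
  idents <- sapply(unique(mc$clade), function(cl) {
    idx <- which(mc$clade == cl)
    a <- Biostrings::subseq(ts$genome[[1]], mc$short_start[idx[1]],
                            mc$long_end[idx[1]])
    b <- Biostrings::subseq(ts$genome[[1]], mc$short_start[idx[2]],
                            mc$long_end[idx[2]])
    1 - Biostrings::neditStartingAt(a, b, starting.at = 1L) / length(a)
  })
  expect_lt(abs(mean(idents) - 0.95), 0.005)
})

test_that("unique-region discovery excludes duplications even at 1 mismatch", {
  withr::with_seed(12, {
    seg <- dupdepth:::random_dna(200)
    seg1mm <- seg
    substr(seg1mm, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                        substr(seg, 100, 100))[1]
    ref <- Biostrings::DNAStringSet(c(
      chrU = dupdepth:::random_dna(3000),
      chrD = paste0(dupdepth:::random_dna(1500), seg,
                    dupdepth:::random_dna(1500), seg1mm,
                    dupdepth:::random_dna(1500))))
  })
  u <- find_unique_regions(ref, read_length = 60L, max_mismatches = 1L)
  uU <- u[GenomicRanges::seqnames(u) == "chrU"]
  expect_equal(GenomicRanges::start(uU), 1L)
  expect_equal(GenomicRanges::end(uU), 3000L)
  dups <- GenomicRanges::GRanges("chrD", IRanges::IRanges(
    c(1501L, 1501L + 200L + 1500L), width = 200L))
  expect_length(GenomicRanges::findOverlaps(u, dups), 0)
  # exclusion and gene windows
  win <- GenomicRanges::GRanges("chrU", IRanges::IRanges(1, 1000), gene = "G1")
  u2 <- find_unique_regions(ref, 60L, 1L, gene_windows = win,
                            exclude = GenomicRanges::GRanges("chrU",
                                                             IRanges::IRanges(1, 500)))
  expect_equal(S4Vectors::mcols(u2)$gene, "G1")
  expect_equal(GenomicRanges::start(u2), 501L)
  expect_equal(GenomicRanges::end(u2), 1000L)
})

test_that("rmse follows the summed formula with a mean variant", {
  expect_equal(rmse(c(a = 1, b = 2), c(a = 1, b = 2)), 0)
  expect_equal(rmse(c(a = 4, b = 6), c(a = 1, b = 2)), 5)
  expect_equal(rmse(c(a = 4, b = 6), c(a = 1, b = 2), mean = TRUE),
               5 / sqrt(2))
  expect_error(rmse(c(a = 1), c(b = 1)), "different unit sets")
  expect_error(rmse(1:3, 1:2), "lengths differ")
})

test_that("grouping reduces copy-number error on shared-read simulations", {
  bd <- baseline_se36()
  groups <- derive_groups(
    ambiguity_matrix(bd$records, bd$truth$annotation, "gene-clade"), 5)
  fr <- reads_to_fragments(bd$records, 350)
  gene_err <- dupdepth:::spike_errors(fr, bd$reads$truth, bd$truth$annotation,
                                      "gene-clade", NULL, 15)
  grp_err <- dupdepth:::spike_errors(fr, bd$reads$truth, bd$truth$annotation,
                                     "group-clade", groups, 15)
  expect_lt(sqrt(sum(grp_err$err^2)), sqrt(sum(gene_err$err^2)))
})
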