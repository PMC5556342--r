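# Synthetic reference genomes with controlled duplication structure.  The
# generator emulates the similarity structure of a highly duplicated domain
# family: clade-specific conserved motifs, tight within-cluster gene
# similarity, and unique intergenic flanks usable for gene-level copy number.

# One codon per amino acid (first codon alphabetically), used to embed
# conserved protein motifs in the nucleotide ancestors.
aa_codon <- c(A = "GCA", C = "TGC", D = "GAC", E = "GAA", F = "TTC",
              G = "GGA", H = "CAC", I = "ATA", K = "AAA", L = "CTA",
              M = "ATG", N = "AAC", P = "CCA", Q = "CAA", R = "AGA",
              S = "AGC", T = "ACA", V = "GTA", W = "TGG", Y = "TAC")

encode_peptide <- function(aa) {
  paste(aa_codon[strsplit(aa, "")[[1]]], collapse = "")
}

#' Built-in clade motif table for synthetic genomes
#'
#' Eight-residue peptides, one per clade and exon kind, embedded conserved
#' in every synthetic domain of that clade.
#'
#' @return Motif `data.frame` (columns `clade`, `exon`, `motif`).
#' @export
toy_motif_table <- function() {
  short <- c(CON1 = "WDAKTYNE", CON2 = "FHQLMRVS", CON3 = "YGTWNPKD",
             HLS1 = "MKRFEQYA", HLS2 = "QVNDHWTC", HLS3 = "ERLYSKMF")
  long <- c(CON1 = "HPFMESVK", CON2 = "TYWAKDNQ", CON3 = "LRQHVGEM",
            HLS1 = "SNEYFPWR", HLS2 = "KMTHQALV", HLS3 = "VWGDNRYE")
  rbind(data.frame(clade = names(short), exon = "short", motif = unname(short)),
        data.frame(clade = names(long), exon = "long", motif = unname(long)))
}

# Expected pairwise mismatch fraction between two sequences independently
# mutated from a common ancestor at per-site rate r (uniform substitution to
# the three alternatives).
pairwise_mismatch <- function(r) 2 * r * (1 - r) + (2 / 3) * r^2

# Per-branch rate that realises a target pairwise divergence over the
# mutable fraction u of the sequence.
rate_for_divergence <- function(d, mutable_fraction) {
  if (d <= 0) return(0)
  target <- d / mutable_fraction
  if (target >= 0.74) stopf("divergence target %.3f is not attainable", d)
  stats::uniroot(function(r) pairwise_mismatch(r) - target, c(0, 0.5))$root
}

# Substitute an exact count of positions (rate x mutable length, rounded),
# uniformly placed outside the mask.  The fixed count keeps every realised
# pairwise divergence within a fraction of a percent of its target, instead
# of scattering binomially (which occasionally yields near-identical pairs).
mutate_seq <- function(seq, rate, mask = integer(0)) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  mutable <- setdiff(seq_along(ch), mask)
  x <- rate * length(mutable)
  k <- floor(x) + (stats::runif(1) < x - floor(x))   # unbiased rounding
  if (k > 0) {
    hit <- sample(mutable, k)
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(hit, function(i) sample(alts[[ch[i]]], 1), character(1))
  }
  paste(ch, collapse = "")
}

#' Specification of a synthetic domain family
#'
#' Defines the duplication structure the toy genome realises: genes fall in
#' similarity clusters; same-clade domains of genes within a cluster differ
#' by `divergence_within` substitutions per bp, across clusters by about
#' `divergence_between`.  Each domain is a short exon + intron + long exon
#' triplet, with clade motifs held conserved.  Defaults give a 2 Mb genome
#' with 6 genes x 6 domains (one per clade, in the canonical CON1, CON2,
#' HLS1, HLS2, HLS3, CON3 order) that runs end to end in minutes.
#'
#' @param n_genes Number of genes.
#' @param clades Clade of each domain, in within-gene order.
#' @param clusters Partition of gene indices into similarity clusters.
#' @param divergence_within,divergence_between Pairwise divergence targets
#'   (substitutions per bp) for same-clade domains within / across clusters.
#' @param short_exon,intron,long_exon Domain part lengths in bp.
#' @param domain_spacing Gap between domains within a gene.
#' @param genome_size Total chromosome length.
#' @param flank Length of the unique flank window recorded for each gene.
#' @param seed RNG seed (the generator is fully deterministic given it).
#' @return A `family_spec` object.
#' @export
family_spec <- function(n_genes = 6L,
                        clades = c("CON1", "CON2", "HLS1", "HLS2", "HLS3", "CON3"),
                        clusters = list(1:3, 4:6),
                        divergence_within = 0.01, divergence_between = 0.10,
                        short_exon = 78L, intron = 150L, long_exon = 372L,
                        domain_spacing = 1500L, genome_size = 2e6,
                        flank = 1000L, seed = 1L) {
  stopifnot(divergence_within >= 0, divergence_within <= 0.5,
            divergence_between >= divergence_within, divergence_between <= 0.5,
            short_exon >= 50, short_exon <= 111,
            all(unlist(clusters) %in% seq_len(n_genes)))
  structure(list(n_genes = n_genes, clades = clades, clusters = clusters,
                 divergence_within = divergence_within,
                 divergence_between = divergence_between,
                 short_exon = short_exon, intron = intron,
                 long_exon = long_exon, domain_spacing = domain_spacing,
                 genome_size = genome_size, flank = flank, seed = seed),
            class = "family_spec")
}

#' Generate a synthetic genome with a known domain family
#'
#' Builds the reference, exon model and truth annotation for a
#' [family_spec()]: clade ancestors carry conserved short/long-exon motifs;
#' cluster and gene copies are derived by independent per-branch
#' substitution calibrated so realised pairwise identities hit the
#' divergence targets; domains are laid out on one chromosome with unique
#' random intergenic sequence.  Deterministic given `spec$seed`.
#'
#' @param spec A [family_spec()].
#' @return A `truth_set`: list with `genome` (`DNAStringSet`), `annotation`
#'   (named `GRanges` with quantification regions), `exons` (`GRanges` with
#'   `gene`), `flanks` (named `GRanges`, per-gene unique windows),
#'   `gene_windows`, `motifs`, `truth_copies` (named diploid copies, all 2),
#'   `clusters` (gene symbols) and `spec`.
#' @export
make_toy_genome <- function(spec = family_spec()) {
  motifs <- toy_motif_table()
  dlen <- spec$short_exon + spec$intron + spec$long_exon
  u <- (dlen - 48) / dlen            # 2 x 24 nt of motif are immutable
  r_within <- rate_for_divergence(spec$divergence_within, u)
  r_between <- rate_for_divergence(
    max(0, spec$divergence_between - spec$divergence_within), u)
  genes <- sprintf("SYN%d", seq_len(spec$n_genes))
  with_seed(spec$seed, {
    # clade ancestors with embedded motifs (codon-aligned)
    anc <- lapply(spec$clades, function(cl) {
      sm <- encode_peptide(motifs$motif[motifs$clade == cl & motifs$exon == "short"])
      lm <- encode_peptide(motifs$motif[motifs$clade == cl & motifs$exon == "long"])
      se <- random_dna(spec$short_exon)
      substr(se, 13, 12 + nchar(sm)) <- sm
      le <- random_dna(spec$long_exon)
      substr(le, 31, 30 + nchar(lm)) <- lm
      list(short = se, intron = random_dna(spec$intron), long = le,
           mask_short = 13:(12 + nchar(sm)),
           mask_long = 31:(30 + nchar(lm)))
    })
    names(anc) <- spec$clades
    # cluster ancestors, then per-gene domain copies
    cluster_of <- integer(spec$n_genes)
    for (k in seq_along(spec$clusters)) cluster_of[spec$clusters[[k]]] <- k
    clanc <- lapply(seq_along(spec$clusters), function(k) {
      lapply(anc, function(a) {
        list(short = mutate_seq(a$short, r_between, a$mask_short),
             intron = mutate_seq(a$intron, r_between),
             long = mutate_seq(a$long, r_between, a$mask_long))
      })
    })
    gene_dom <- lapply(seq_len(spec$n_genes), function(g) {
      base <- clanc[[cluster_of[g]]]
      lapply(seq_along(spec$clades), function(ci) {
        a <- anc[[ci]]; b <- base[[ci]]
        list(short = mutate_seq(b$short, r_within, a$mask_short),
             intron = mutate_seq(b$intron, r_within),
             long = mutate_seq(b$long, r_within, a$mask_long))
      })
    })
    # layout
    nd <- length(spec$clades)
    gene_len <- nd * dlen + (nd - 1) * spec$domain_spacing
    gene_spacing <- floor((spec$genome_size - spec$n_genes * gene_len) /
                            (spec$n_genes + 1))
    if (gene_spacing < 2 * (spec$flank + 1000L) + 200L)
      stopf("genome_size too small for the requested layout")
    pieces <- character(0); pos <- 1L
    rows <- list(); exon_rows <- list()
    for (g in seq_len(spec$n_genes)) {
      pieces <- c(pieces, random_dna(gene_spacing)); pos <- pos + gene_spacing
      for (ci in seq_len(nd)) {
        d <- gene_dom[[g]][[ci]]
        ss <- pos; se <- pos + spec$short_exon - 1L
        ls <- se + spec$intron + 1L; le <- ls + spec$long_exon - 1L
        pieces <- c(pieces, d$short, d$intron, d$long)
        pos <- pos + dlen
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[g], clade = spec$clades[ci],
          short_start = ss, short_end = se, long_start = ls, long_end = le)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          gene = genes[g], start = c(ss, ls), end = c(se, le),
          kind = c("short", "long"))
        if (ci < nd) {
          pieces <- c(pieces, random_dna(spec$domain_spacing))
          pos <- pos + spec$domain_spacing
        }
      }
    }
    tail_len <- spec$genome_size - (pos - 1L)
    if (tail_len > 0) pieces <- c(pieces, random_dna(tail_len))
    genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(genome) <- "chr1"
  })
  d <- do.call(rbind, rows)
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(d$short_start, d$long_end),
                                strand = "+",
                                gene = d$gene, clade = d$clade,
                                long_start = d$long_start, long_end = d$long_end,
                                short_start = d$short_start, short_end = d$short_end,
                                short_missing = FALSE)
  ann <- name_domains(ann)
  ann <- build_quant_regions(ann, seqlengths = c(chr1 = spec$genome_size))
  ex <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ex$start, ex$end),
                                  strand = "+", gene = ex$gene, kind = ex$kind)
  gene_span <- sapply(split(seq_len(nrow(d)), d$gene)[genes], function(i) {
    c(min(d$short_start[i]), max(d$long_end[i]))
  })
  # flanks sit one full fragment reach (insert mean + 4 sd + extension)
  # away from the gene span so flank fragments never touch domain regions
  gap <- 1000L
  flank_l <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    gene_span[1, ] - gap - spec$flank, gene_span[1, ] - gap - 1L),
    gene = genes)
  flank_r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    gene_span[2, ] + gap + 1L, gene_span[2, ] + gap + spec$flank),
    gene = genes)
  flanks <- c(flank_l, flank_r)
  names(flanks) <- sprintf("%s.%s_FLANK_1", S4Vectors::mcols(flanks)$gene,
                           rep(c("L", "R"), each = spec$n_genes))
  windows <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    gene_span[1, ] - gap - spec$flank, gene_span[2, ] + gap + spec$flank),
    gene = genes)
  structure(list(genome = genome, annotation = ann, exons = exons,
                 flanks = flanks, gene_windows = windows, motifs = motifs,
                 truth_copies = stats::setNames(rep(2L, length(ann)), names(ann)),
                 clusters = lapply(spec$clusters, function(i) genes[i]),
                 spec = spec),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d bp genome, %d domains in %d genes\n",
              sum(Biostrings::width(x$genome)), length(x$annotation),
              length(unique(S4Vectors::mcols(x$annotation)$gene))))
  invisible(x)
}

#' HMMER-style domain hit lines for a truth set
#'
#' Emits hmmsearch `--domtblout` formatted lines for the long exon of every
#' domain in the truth annotation, enabling end-to-end tests of the
#' annotation pipeline (parse, pair, assign, name) against the truth BED.
#'
#' @param truth A `truth_set`.
#' @param evalue E-value written for each hit.
#' @return Character vector of domtblout lines (with header comments).
#' @export
truth_domtbl <- function(truth, evalue = 1e-40) {
  ann <- truth$annotation
  mc <- S4Vectors::mcols(ann)
  tlen <- sum(Biostrings::width(truth$genome))
  lines <- sprintf(
    "%s - %d DUF_nt - %d %.1e 99.9 0.1 1 1 %.1e %.1e 95.0 0.1 1 %d %d %d %d %d 0.98 -",
    as.character(GenomicRanges::seqnames(ann)), tlen,
    mc$long_end - mc$long_start + 1L,
    evalue, evalue / 10, evalue,
    mc$long_end - mc$long_start + 1L,
    mc$long_start, mc$long_end, mc$long_start, mc$long_end)
  c("# synthetic domtblout", lines)
}

#' Build the worked-example duplication scenario
#'
#' A single focal domain on `chrA` whose central segment is duplicated
#' exactly once on `chrB`.  The duplicated length is chosen so that, with
#' the given insert model, the expected weighted coverage lost to off-target
#' ties is exactly 10% of the focal domain's coverage under the `best`
#' strategy: read pairs falling entirely inside the shared segment tie
#' between the two loci and land off target half the time.  Measured copy
#' number is therefore 0.9 x the simulated copy number in expectation
#' (0.9 for 1 copy, 4.5 for 5).
#'
#' @param region_length Focal domain length in bp (large enough that
#'   Monte-Carlo depth noise is small against the 10% effect).
#' @param flank Unique flank around the focal domain.
#' @param insert An [insert_model()] (the scenario calibration depends on
#'   its mean and sd).
#' @param off_target_fraction Expected off-target read fraction.
#' @param seed Seed for the random background sequence.
#' @return A `truth_set`-like list: `genome`, `annotation` (one domain,
#'   quantification region = the domain), `duplicate` (`GRanges` of the
#'   copy), `truth_copies`, `insert`.
#' @export
make_worked_example <- function(region_length = 30000L, flank = 5000L,
                                insert = insert_model(),
                                off_target_fraction = 0.1, seed = 99L) {
  M <- as.integer(region_length)
  mu <- insert$mean; sg <- insert$sd
  # E[f*(s+1-f)] = (s+1)*mu - (mu^2+sg^2)  must equal  2*off*M*mu
  s <- as.integer(floor((2 * off_target_fraction * M * mu + mu^2 + sg^2) / mu) - 1L)
  stopifnot(s > 2 * mu, s < M - 2 * mu)
  with_seed(seed, {
    dom <- random_dna(M)
    chrA <- paste0(random_dna(flank), dom, random_dna(flank))
    seg_start <- (M - s) %/% 2L
    seg <- substr(dom, seg_start + 1L, seg_start + s)
    chrB <- paste0(random_dna(2000L), seg, random_dna(2000L))
  })
  genome <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB))
  ann <- GenomicRanges::GRanges("chrA",
                                IRanges::IRanges(flank + 1L, flank + M),
                                strand = "+", gene = "FOCAL", clade = "CON1",
                                long_start = flank + 1L, long_end = flank + M,
                                short_start = NA_integer_, short_end = NA_integer_,
                                short_missing = TRUE)
  ann <- name_domains(ann)
  dup <- GenomicRanges::GRanges("chrB", IRanges::IRanges(2001L, 2000L + s))
  structure(list(genome = genome, annotation = ann, duplicate = dup,
                 truth_copies = stats::setNames(2L, names(ann)),
                 insert = insert, shared_length = s,
                 off_target_fraction = off_target_fraction),
            class = "truth_set")
}

#' Measure the worked-example scenario once
#'
#' Simulates the focal domain at the given copy number, aligns with the
#' oracle `best` strategy and quantifies: the full spike-in measurement
#' pipeline in one call.
#'
#' @param we Scenario from [make_worked_example()].
#' @param copies Simulated copy number.
#' @param seed RNG seed for simulation and tie-breaking.
#' @param haploid_coverage Expected haploid coverage (15x).
#' @return Measured copy number of the focal domain (numeric).
#' @export
measure_worked_example <- function(we, copies = 1L, seed = 1L,
                                   haploid_coverage = 15) {
  sp <- sim_spec(copies = copies, seed = seed, insert = we$insert,
                 haploid_coverage = haploid_coverage)
  rs <- simulate_spike_in(we$annotation[1], copies, sp, we$genome)
  rec <- oracle_align_pairs(rs, we$genome, "best", seed = seed)
  frags <- reads_to_fragments(rec, sp$insert$mean)
  cov <- domain_coverage(frags, we$annotation)
  copies_from_coverage(cov, haploid_coverage)$copies[1]
}

#' Simulate a copy-number-variant sample
#'
#' Scales per-region read counts to emulate duplication/deletion events on
#' top of the diploid baseline.  An event unit may be a gene symbol (gene
#' dosage: all its domains and its unique flanks change together), a
#' `GENE_CLADE` pair (intragenic expansion/contraction: only those domains
#' change) or a single domain name.
#'
#' @param truth A `truth_set` from [make_toy_genome()].
#' @param events `data.frame` with columns `unit` and `copies` (diploid).
#' @param spec A [sim_spec()] (its `seed` drives the whole sample).
#' @param include_flanks Also simulate the per-gene unique flank windows
#'   (needed for gene-level copy number).
#' @return List with `reads` (`read_set`), `domain_copies` and
#'   `gene_copies` (named truth vectors), and `regions` (the simulated
#'   `GRanges`).
#' @export
make_cnv_sample <- function(truth, events = NULL, spec = sim_spec(seed = 1L),
                            include_flanks = TRUE) {
  ann <- truth$annotation
  mc <- S4Vectors::mcols(ann)
  dom_copies <- truth$truth_copies + 0
  genes <- unique(mc$gene)
  gene_copies <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      u <- events$unit[i]; k <- events$copies[i]
      if (k < 0) stopf("negative copy count for unit '%s'", u)
      if (u %in% genes) {
        dom_copies[mc$gene == u] <- k
        gene_copies[u] <- k
      } else if (u %in% names(dom_copies)) {
        dom_copies[u] <- k
      } else if (u %in% paste(mc$gene, mc$clade, sep = "_")) {
        dom_copies[paste(mc$gene, mc$clade, sep = "_") == u] <- k
      } else stopf("event unit '%s' matches no gene, gene-clade or domain", u)
    }
  }
  regions <- ann
  copies <- dom_copies
  if (include_flanks && !is.null(truth$flanks)) {
    fl <- truth$flanks
    fl_copies <- gene_copies[S4Vectors::mcols(fl)$gene]
    names(fl_copies) <- names(fl)
    keep_cols <- c("gene")
    S4Vectors::mcols(fl) <- S4Vectors::mcols(fl)[keep_cols]
    ann2 <- ann
    S4Vectors::mcols(ann2) <- S4Vectors::mcols(ann2)["gene"]
    regions <- c(ann2, fl)
    copies <- c(dom_copies, fl_copies)
  }
  reads <- simulate_baseline(regions, spec, truth$genome, copies = copies)
  list(reads = reads, domain_copies = dom_copies, gene_copies = gene_copies,
       regions = regions)
}

#' Write a truth set to disk
#'
#' Emits the FASTA reference, the BED6 truth annotation and a TSV of true
#' copies, for use with external tools.
#'
#' @param truth A `truth_set`.
#' @param dir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "domains.bed")
  tsv <- file.path(dir, "truth_copies.tsv")
  Biostrings::writeXStringSet(truth$genome, fa)
  write_domain_bed(truth$annotation, bed)
  utils::write.table(
    data.frame(name = names(truth$truth_copies), copies = truth$truth_copies),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, bed = bed, truth = tsv))
}
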