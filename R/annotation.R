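#' Clade labels recognised by the annotation model
#'
#' Six canonical clades (three conserved, `CON1`-`CON3`, and three
#' human-lineage-specific, `HLS1`-`HLS3`), five non-canonical clades
#' (`CON4`-`CON8`), plus `HYBRID` (short exon of one clade with the long exon
#' of another) and `UNASSIGNED` (no motif match).
#'
#' @return Character vector of valid clade labels.
#' @export
clade_labels <- function() {
  c("CON1", "CON2", "CON3", "HLS1", "HLS2", "HLS3",
    paste0("CON", 4:8), "HYBRID", "UNASSIGNED")
}

canonical_clades <- function() c("CON1", "CON2", "CON3", "HLS1", "HLS2", "HLS3")

#' Parse profile-HMM domain hits from HMMER tabular output
#'
#' Reads HMMER `--domtblout` (22+ column) or nhmmer `--tblout` (15+ column,
#' stranded) text and returns the hits passing the E-value filter as a sorted
#' `GRanges`.  HMMER coordinates are 1-based inclusive and are kept as such
#' (the `GRanges` convention); minus-strand nhmmer hits (alignment `from` >
#' `to`) are flipped onto the forward coordinate system with strand `-`.
#'
#' @param domtbl Path to a HMMER tabular file, or a character vector of its
#'   lines.
#' @param max_evalue Retain hits with E-value strictly below this threshold
#'   (default `1e-10`, the conventional genome-search cutoff for this domain
#'   family).
#' @param reference Optional `DNAStringSet` (or named vector of sequence
#'   lengths) used to validate target sequence names.
#' @return `GRanges` with metadata columns `evalue` and `score`, sorted by
#'   position.
#' @export
parse_domain_hits <- function(domtbl, max_evalue = 1e-10, reference = NULL) {
  stopifnot(is.numeric(max_evalue), max_evalue > 0)
  lines <- if (length(domtbl) == 1 && file.exists(domtbl)) readLines(domtbl) else domtbl
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(GenomicRanges::GRanges(evalue = numeric(0), score = numeric(0)))
  }
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 22 && !f[12] %in% c("+", "-")) {
      # hmmsearch domtblout: target coords in 'ali from/to' (cols 18/19),
      # per-domain independent E-value in col 13
      v <- suppressWarnings(list(ev = as.numeric(f[13]), sc = as.numeric(f[14]),
                                 from = as.integer(f[18]), to = as.integer(f[19])))
      strand <- "+"
    } else if (length(f) >= 15 && f[12] %in% c("+", "-")) {
      # nhmmer tblout: ali from/to in cols 7/8, strand col 12, E-value col 13
      v <- suppressWarnings(list(ev = as.numeric(f[13]), sc = as.numeric(f[14]),
                                 from = as.integer(f[7]), to = as.integer(f[8])))
      strand <- f[12]
    } else {
      stopf("malformed HMMER tabular line %d: %s", i, lines[i])
    }
    if (anyNA(unlist(v))) stopf("malformed HMMER tabular line %d: %s", i, lines[i])
    data.frame(target = f[1], start = min(v$from, v$to), end = max(v$from, v$to),
               strand = strand, evalue = v$ev, score = v$sc,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (!is.null(reference)) {
    refnames <- if (is.character(reference) || is.numeric(reference)) names(reference)
                else names(reference)
    bad <- setdiff(unique(d$target), refnames)
    if (length(bad)) stopf("unknown sequence name(s) in HMMER output: %s",
                           paste(bad, collapse = ", "))
  }
  d <- d[d$evalue < max_evalue, , drop = FALSE]
  gr <- GenomicRanges::GRanges(d$target, IRanges::IRanges(d$start, d$end),
                               strand = d$strand, evalue = d$evalue, score = d$score)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Pair a domain hit with its short upstream exon
#'
#' A domain is encoded by an exon doublet: the profile-HMM hit identifies the
#' long exon; the short N-terminal exon is the nearest exon upstream (in
#' transcription order) whose length falls in the characteristic 50-111 bp
#' range.  If no upstream exon qualifies the short exon is recorded as absent
#' and the domain flagged.
#'
#' @param hit Length-1 `GRanges` from [parse_domain_hits()].
#' @param gene_exons `GRanges` of the gene's exons, any order; transcription
#'   order is derived from the gene strand.
#' @param short_range Allowed short-exon length range in bp.
#' @return Length-1 `GRanges` spanning both exons, with metadata columns
#'   `long_start`, `long_end`, `short_start`, `short_end` (NA when absent) and
#'   `short_missing`.
#' @export
pair_exons <- function(hit, gene_exons, short_range = c(50L, 111L)) {
  stopifnot(length(hit) == 1)
  ov <- IRanges::findOverlaps(hit, gene_exons, type = "within", ignore.strand = TRUE)
  if (!length(ov)) stopf("domain hit at %s:%d-%d is not contained in any exon",
                         as.character(GenomicRanges::seqnames(hit)),
                         GenomicRanges::start(hit), GenomicRanges::end(hit))
  long <- gene_exons[S4Vectors::subjectHits(ov)[1]]
  minus <- as.character(GenomicRanges::strand(long)) == "-"
  # exons strictly upstream of the long exon, transcription order
  if (minus) {
    prev <- gene_exons[GenomicRanges::start(gene_exons) > GenomicRanges::end(long)]
    prev <- prev[order(GenomicRanges::start(prev))]          # nearest first
  } else {
    prev <- gene_exons[GenomicRanges::end(gene_exons) < GenomicRanges::start(long)]
    prev <- prev[order(-GenomicRanges::end(prev))]
  }
  w <- GenomicRanges::width(prev)
  ok <- which(w >= short_range[1] & w <= short_range[2])
  out <- GenomicRanges::granges(long)
  S4Vectors::mcols(out)$long_start <- GenomicRanges::start(long)
  S4Vectors::mcols(out)$long_end <- GenomicRanges::end(long)
  if (length(ok)) {
    short <- prev[ok[1]]
    S4Vectors::mcols(out)$short_start <- GenomicRanges::start(short)
    S4Vectors::mcols(out)$short_end <- GenomicRanges::end(short)
    S4Vectors::mcols(out)$short_missing <- FALSE
    GenomicRanges::ranges(out) <- IRanges::IRanges(
      min(GenomicRanges::start(short), GenomicRanges::start(long)),
      max(GenomicRanges::end(short), GenomicRanges::end(long)))
  } else {
    S4Vectors::mcols(out)$short_start <- NA_integer_
    S4Vectors::mcols(out)$short_end <- NA_integer_
    S4Vectors::mcols(out)$short_missing <- TRUE
  }
  out
}

#' Annotate all domain hits against an exon model
#'
#' Vectorised driver over [pair_exons()]: assigns each hit to the gene whose
#' exons contain it, pairs the exon doublet and returns one annotated range
#' per hit.
#'
#' @param hits `GRanges` from [parse_domain_hits()].
#' @param exons `GRanges` of exons with a `gene` metadata column.
#' @return `GRanges` with `gene`, exon coordinate and `short_missing`
#'   metadata columns, sorted by position.
#' @export
annotate_domains <- function(hits, exons) {
  stopifnot(!is.null(S4Vectors::mcols(exons)$gene))
  out <- lapply(seq_along(hits), function(i) {
    ov <- IRanges::findOverlaps(hits[i], exons, type = "within", ignore.strand = TRUE)
    if (!length(ov)) stopf("domain hit %d is not contained in any exon", i)
    gene <- S4Vectors::mcols(exons)$gene[S4Vectors::subjectHits(ov)[1]]
    ann <- pair_exons(hits[i], exons[S4Vectors::mcols(exons)$gene == gene])
    S4Vectors::mcols(ann)$gene <- gene
    ann
  })
  GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Read or build a clade motif table
#'
#' Clades are distinguished by short amino-acid motifs specific to the short
#' and long exon of each clade.  The table has columns `clade`, `exon`
#' (`"short"` or `"long"`) and `motif` (exact amino-acid substring).
#'
#' @param path TSV file with columns `clade`, `exon`, `motif`.
#' @return `data.frame` motif table.
#' @export
read_motif_table <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("clade", "exon", "motif") %in% names(m)))
  m
}

#' Assign a domain to a clade from its protein sequence motifs
#'
#' A unique motif match gives that clade; a short-exon motif of one clade
#' combined with the long-exon motif of a different clade gives `HYBRID`; no
#' match gives `UNASSIGNED`.  Two different clades' motifs matching within
#' the same exon is an error.
#'
#' @param protein Either a single amino-acid string (both exons searched in
#'   it) or a list with elements `short` and `long` (either may be `NA`).
#' @param motifs Motif table (see [read_motif_table()]).
#' @param max_mismatch Allowed mismatches in a motif match (default 0).
#' @return A single clade label.
#' @export
assign_clade <- function(protein, motifs, max_mismatch = 0L) {
  if (!is.list(protein)) protein <- list(short = protein, long = protein)
  find_matches <- function(seqs, exon_kind) {
    tab <- motifs[motifs$exon == exon_kind, , drop = FALSE]
    hits <- character(0)
    for (s in seqs) {
      if (is.na(s) || !nzchar(s)) next
      subject <- Biostrings::AAString(s)
      for (k in seq_len(nrow(tab))) {
        n <- Biostrings::countPattern(tab$motif[k], subject,
                                      max.mismatch = max_mismatch)
        if (n > 0) hits <- c(hits, tab$clade[k])
      }
    }
    unique(hits)
  }
  short_clades <- find_matches(protein["short"], "short")
  long_clades <- find_matches(protein["long"], "long")
  if (length(short_clades) > 1)
    stopf("conflicting short-exon motif matches: %s", paste(short_clades, collapse = ", "))
  if (length(long_clades) > 1)
    stopf("conflicting long-exon motif matches: %s", paste(long_clades, collapse = ", "))
  if (length(short_clades) && length(long_clades)) {
    if (short_clades == long_clades) return(short_clades)
    return("HYBRID")
  }
  if (length(long_clades)) return(long_clades)
  if (length(short_clades)) return(short_clades)
  "UNASSIGNED"
}

# Extract and translate the short/long exon protein sequences of one domain.
domain_proteins <- function(domain, genome) {
  get_aa <- function(chrom, s, e, minus) {
    if (is.na(s)) return(NA_character_)
    nt <- Biostrings::subseq(genome[[chrom]], s, e)
    if (minus) nt <- Biostrings::reverseComplement(nt)
    nt <- Biostrings::subseq(nt, 1, 3L * (length(nt) %/% 3L))
    as.character(suppressWarnings(Biostrings::translate(nt, if.fuzzy.codon = "X")))
  }
  mc <- S4Vectors::mcols(domain)
  chrom <- as.character(GenomicRanges::seqnames(domain))
  minus <- as.character(GenomicRanges::strand(domain)) == "-"
  list(short = get_aa(chrom, mc$short_start, mc$short_end, minus),
       long = get_aa(chrom, mc$long_start, mc$long_end, minus))
}

#' Assign clades to every annotated domain
#'
#' @param domains `GRanges` from [annotate_domains()].
#' @param genome `DNAStringSet` reference.
#' @param motifs Motif table.
#' @param max_mismatch Allowed motif mismatches.
#' @return `domains` with a `clade` metadata column added.
#' @export
assign_clades <- function(domains, genome, motifs, max_mismatch = 0L) {
  cl <- vapply(seq_along(domains), function(i) {
    assign_clade(domain_proteins(domains[i], genome), motifs, max_mismatch)
  }, character(1))
  S4Vectors::mcols(domains)$clade <- cl
  domains
}

#' Name domains as GENE_CLADE_INDEX
#'
#' Within each (gene, clade) pair, domains are numbered 1..n in transcription
#' order along the gene (genomic order, reversed for minus-strand genes), so
#' e.g. the third CON1 domain of NBPF1 becomes `NBPF1_CON1_3`.  Renaming is
#' idempotent.
#'
#' @param domains `GRanges` with `gene` and `clade` metadata columns.
#' @return `domains` with `index` and `name` metadata columns and range names
#'   set to the domain names.
#' @export
name_domains <- function(domains) {
  mc <- S4Vectors::mcols(domains)
  stopifnot(!is.null(mc$gene), !is.null(mc$clade))
  minus <- as.character(GenomicRanges::strand(domains)) == "-"
  pos <- ifelse(minus, -GenomicRanges::start(domains), GenomicRanges::start(domains))
  key <- paste(mc$gene, mc$clade, sep = "\r")
  idx <- integer(length(domains))
  for (k in unique(key)) {
    sel <- which(key == k)
    idx[sel][order(pos[sel])] <- seq_along(sel)
  }
  nm <- sprintf("%s_%s_%d", mc$gene, mc$clade, idx)
  if (anyDuplicated(nm)) stopf("duplicate domain names: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  S4Vectors::mcols(domains)$index <- idx
  S4Vectors::mcols(domains)$name <- nm
  names(domains) <- nm
  domains
}

#' Build disjoint quantification regions
#'
#' The quantification region of a domain spans its exon doublet; where the
#' gap to the nearest neighbouring domain on the same chromosome exceeds
#' `gap_threshold`, the facing boundary is extended by up to `max_extension`
#' bp of flanking sequence, capped so that extended regions remain at least
#' `gap_threshold` apart (hence always disjoint).  Chromosome ends count as
#' open gaps.
#'
#' @param domains Named `GRanges` from [name_domains()] (ranges = exon spans).
#' @param max_extension Maximum extension per side in bp (default 250).
#' @param gap_threshold Minimum inter-domain gap in bp before any extension
#'   is applied (default 1000).
#' @param seqlengths Optional named vector of chromosome lengths used to clip
#'   extensions at chromosome ends.
#' @return `domains` with ranges replaced by the quantification regions.
#' @export
build_quant_regions <- function(domains, max_extension = 250L,
                                gap_threshold = 1000L, seqlengths = NULL) {
  ext_for_gap <- function(gap) {
    if (gap <= gap_threshold) return(0L)
    as.integer(min(max_extension, floor((gap - gap_threshold) / 2)))
  }
  new_start <- GenomicRanges::start(domains)
  new_end <- GenomicRanges::end(domains)
  for (chrom in unique(as.character(GenomicRanges::seqnames(domains)))) {
    sel <- which(as.character(GenomicRanges::seqnames(domains)) == chrom)
    sel <- sel[order(GenomicRanges::start(domains)[sel])]
    s <- GenomicRanges::start(domains)[sel]
    e <- GenomicRanges::end(domains)[sel]
    n <- length(sel)
    left_gap <- c(Inf, s[-1] - e[-n] - 1)
    right_gap <- c(s[-1] - e[-n] - 1, Inf)
    ls <- vapply(left_gap, ext_for_gap, integer(1))
    rs <- vapply(right_gap, ext_for_gap, integer(1))
    new_start[sel] <- pmax(1L, s - ls)
    lim <- if (!is.null(seqlengths)) seqlengths[[chrom]] else Inf
    new_end[sel] <- as.integer(pmin(lim, e + rs))
  }
  GenomicRanges::ranges(domains) <- IRanges::IRanges(new_start, new_end,
                                                     names = names(domains))
  domains
}

#' Restrict an annotation to canonical domains
#'
#' Non-canonical clades (CON4-CON8), hybrid and unassigned domains are
#' annotated but excluded from quantification by default.
#'
#' @param domains Annotated `GRanges`.
#' @param include_noncanonical Keep CON4-8, HYBRID and UNASSIGNED domains.
#' @return Filtered `GRanges`.
#' @export
canonical_domains <- function(domains, include_noncanonical = FALSE) {
  if (include_noncanonical) return(domains)
  domains[S4Vectors::mcols(domains)$clade %in% canonical_clades()]
}

#' Choose between two exon annotations for a gene
#'
#' When alternative exon models (e.g. RefSeq vs Ensembl) disagree, prefer the
#' one for which more domain hits sit in a proper short/long exon doublet;
#' break ties by the larger number of annotated UTR exons (metadata column
#' `utr`, if present).
#'
#' @param exons_a,exons_b Candidate exon `GRanges` for the same gene.
#' @param hits Domain hits falling in the gene.
#' @return The preferred exon `GRanges`.
#' @export
choose_exon_annotation <- function(exons_a, exons_b, hits) {
  doublet_score <- function(ex) {
    sum(vapply(seq_along(hits), function(i) {
      ok <- tryCatch(!S4Vectors::mcols(pair_exons(hits[i], ex))$short_missing,
                     error = function(e) FALSE)
      isTRUE(ok)
    }, logical(1)))
  }
  utr_count <- function(ex) {
    u <- S4Vectors::mcols(ex)$utr
    if (is.null(u)) 0L else sum(u, na.rm = TRUE)
  }
  sa <- doublet_score(exons_a); sb <- doublet_score(exons_b)
  if (sa > sb) return(exons_a)
  if (sb > sa) return(exons_b)
  if (utr_count(exons_a) >= utr_count(exons_b)) exons_a else exons_b
}

#' Write a domain annotation as BED6
#'
#' Coordinates are converted to the BED 0-based half-open convention; the
#' name column carries `GENE_CLADE_INDEX`, the score column the domain index.
#'
#' @param domains Named annotated `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_domain_bed <- function(domains, path) {
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(domains)),
    start = GenomicRanges::start(domains) - 1L,
    end = GenomicRanges::end(domains),
    name = S4Vectors::mcols(domains)$name,
    score = S4Vectors::mcols(domains)$index %||% 0L,
    strand = as.character(GenomicRanges::strand(domains)))
  d$strand[d$strand == "*"] <- "+"
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 domain annotation
#'
#' Inverse of [write_domain_bed()]: BED half-open coordinates become 1-based
#' closed, and `GENE_CLADE_INDEX` names are split back into `gene`, `clade`
#' and `index` metadata columns.
#'
#' @param path BED file.
#' @return Named annotated `GRanges`.
#' @export
read_domain_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  parts <- regmatches(d$name, regexec("^(.*)_([A-Z0-9]+)_(\\d+)$", d$name))
  bad <- which(lengths(parts) != 4)
  if (length(bad)) stopf("BED name not GENE_CLADE_INDEX at line %d", bad[1])
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                               strand = d$strand)
  S4Vectors::mcols(gr)$name <- d$name
  S4Vectors::mcols(gr)$gene <- vapply(parts, `[`, character(1), 2)
  S4Vectors::mcols(gr)$clade <- vapply(parts, `[`, character(1), 3)
  S4Vectors::mcols(gr)$index <- as.integer(vapply(parts, `[`, character(1), 4))
  names(gr) <- d$name
  gr
}
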