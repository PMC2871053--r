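# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive re-implementations, kept free of the package's index /
# caller code paths.

# Reverse complement without Biostrings (test-local).
oracle_rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Naive both-strand sliding-window scan for every exact occurrence.
oracle_scan <- function(q, genome) {
  rows <- list()
  n <- nchar(q)
  rq <- oracle_rc(q)
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    L <- nchar(g)
    if (L < n) next
    subs <- substring(g, 1:(L - n + 1), n:L)
    fw <- which(subs == q)
    rv <- which(subs == rq)
    if (length(fw)) rows[[length(rows) + 1]] <-
      data.frame(chrom = chrom, start = fw, strand = "+",
                 stringsAsFactors = FALSE)
    if (length(rv)) rows[[length(rows) + 1]] <-
      data.frame(chrom = chrom, start = rv, strand = "-",
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest genomic prefix by testing every prefix length explicitly.
oracle_longest_prefix <- function(seq, genome) {
  best <- 0L
  for (L in seq_len(nchar(seq))) {
    if (nrow(oracle_scan(substr(seq, 1, L), genome)) > 0) best <- L else break
  }
  best
}

# Minimum mismatches of q against every window of ref (full enumeration).
oracle_min_mismatch <- function(q, ref) {
  n <- nchar(q); L <- nchar(ref)
  if (L < n) return(Inf)
  best <- Inf
  for (o in 0:(L - n)) {
    w <- substr(ref, o + 1, o + n)
    mm <- sum(strsplit(q, "")[[1]] != strsplit(w, "")[[1]])
    best <- min(best, mm)
  }
  best
}

# Brute-force trailer caller: test every record against every region at the
# allowed offsets.
oracle_trailers <- function(seqs, regions, offsets = c(1, 2)) {
  rows <- list()
  for (s in seqs) {
    for (i in seq_len(nrow(regions))) {
      for (off in offsets) {
        if (substr(regions$region_seq[i], off, off + nchar(s) - 1) == s &&
            off + nchar(s) - 1 <= nchar(regions$region_seq[i])) {
          rows[[length(rows) + 1]] <- data.frame(
            trna_name = regions$trna_name[i], sequence = s,
            start_offset = off, stringsAsFactors = FALSE)
          break  # smallest offset per (gene, sequence)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(trna_name = character(0), sequence = character(0),
                      start_offset = integer(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$trna_name, out$sequence), , drop = FALSE]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny handcrafted bundle used across module tests.
make_toy_bundle <- function(seed = 42) {
  withr::with_seed(seed, {
    trna <- rand_dna(72)
    region_plus <- paste0("GAAGCGGGTGCTCTTATTT", rand_dna(21))  # 40 nt
    trna2 <- rand_dna(72)
    region_minus <- rand_dna(40)
    mir_arm <- rand_dna(22)
    hairpin <- paste0(mir_arm, rand_dna(16), oracle_rc(mir_arm))
    exons <- replicate(3, rand_dna(60))
    introns <- replicate(2, rand_dna(50))
    gene_block <- paste0(exons[1], introns[1], exons[2], introns[2], exons[3])
    rep_unit <- rand_dna(80)
    gaps <- replicate(8, rand_dna(70))
    chr1 <- paste0(gaps[1], trna, region_plus,
                   gaps[2], oracle_rc(region_minus), oracle_rc(trna2),
                   gaps[3], hairpin,
                   gaps[4], gene_block,
                   gaps[5], rep_unit, gaps[6], rep_unit,
                   gaps[7])
    off <- function(...) sum(nchar(c(...)))
    t1_start <- off(gaps[1]) + 1
    t2_region_start <- off(gaps[1], trna, region_plus, gaps[2]) + 1
    t2_start <- t2_region_start + 40
    hp_start <- off(gaps[1], trna, region_plus, gaps[2], oracle_rc(region_minus),
                    oracle_rc(trna2), gaps[3]) + 1
    gene_start <- hp_start + nchar(hairpin) + nchar(gaps[4])
    rep1_start <- gene_start + nchar(gene_block) + nchar(gaps[5])
    rep2_start <- rep1_start + 80 + nchar(gaps[6])

    genome <- c(chr1 = chr1, chrM = rand_dna(300))
    mito_seq <- substr(genome[["chrM"]], 50, 250)
    rrna_seq <- rand_dna(200)  # reference-only: not in the genome
    ref_rnas <- data.frame(
      class = c("tRNA", "tRNA", "miRNA", "rRNA", "mitochondrial RNA"),
      ref_id = c("tRNA-A", "tRNA-B", "hairpin-1", "rRNA-1", "mito-1"),
      seq = c(trna, trna2, hairpin, rrna_seq, mito_seq),
      stringsAsFactors = FALSE)
    trna_loci <- data.frame(
      chrom = "chr1",
      start = c(t1_start, t2_start),
      end = c(t1_start + 71, t2_start + 71),
      strand = c("+", "-"),
      name = c("tRNA-A", "tRNA-B"), stringsAsFactors = FALSE)
    repeat_loci <- data.frame(
      chrom = "chr1", start = c(rep1_start, rep2_start),
      end = c(rep1_start + 79, rep2_start + 79), strand = "+",
      family = "toyRep", stringsAsFactors = FALSE)
    ex_tab <- data.frame(
      chrom = "chr1",
      start = gene_start + c(0, 60 + 50, 60 + 50 + 60 + 50),
      end = gene_start + c(59, 60 + 50 + 59, 60 + 50 + 60 + 50 + 59),
      strand = "+", stringsAsFactors = FALSE)
    bundle <- reference_bundle(genome, ref_rnas, trna_loci,
                               mrna_models = list("gene-1" = ex_tab),
                               repeat_loci = repeat_loci)
    list(bundle = bundle, trna = trna, trna2 = trna2,
         region_plus = region_plus, region_minus = region_minus,
         mir_arm = mir_arm, hairpin = hairpin, exons = exons,
         rep_unit = rep_unit, rrna_seq = rrna_seq, mito_seq = mito_seq,
         gene_start = gene_start, hp_start = hp_start)
  })
}

example_path <- function(name) {
  system.file("extdata", name, package = "srnaloc", mustWork = TRUE)
}
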