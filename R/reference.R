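# Reference bundle: genome, class-labeled reference RNAs, gene loci, and the
# derived auxiliary references (trailer regions, CCA-tailed tRNAs, splice
# junction library) used by the rescue and trailer stages.

#' Ordered RNA class vocabulary
#'
#' The fixed, ordered vocabulary of small-RNA classes. The order of the first
#' twenty entries is the annotation cascade priority: a sequence is assigned to
#' the first class whose reference set matches it and is then removed from the
#' pool. `genomic repeat` and `unknown` are terminal fallback labels assigned
#' by genomic-locus overlap and by elimination respectively; they are never
#' matched against reference sequences.
#'
#' @format Character vector of 22 class labels.
#' @export
CLASS_LABELS <- c(
  "miRNA", "mitochondrial RNA", "rRNA", "ITS", "ETS",
  "box H/ACA snoRNA", "box C/D snoRNA", "scaRNA", "tRNA", "snRNA",
  "RNaseP", "SRP RNA", "Xist", "7SK", "H19", "vRNA", "hY RNA", "RNaseMRP",
  "mRNA", "tRNA 3' trailer",
  "genomic repeat", "unknown"
)

# Classes matched by reference sequence (cascade stages), in priority order.
SEQUENCE_CLASSES <- CLASS_LABELS[1:20]

#' Construct a reference bundle from in-memory components
#'
#' The internal coordinate convention is 1-based closed on both ends; strand
#' is '+' or '-'. Validation enforces the class vocabulary and chromosome
#' bounds.
#'
#' @param genome Named character vector of chromosome sequences (A/C/G/T/N).
#' @param ref_rnas data.frame with columns `class`, `ref_id`, `seq`.
#' @param trna_loci data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name` (1-based closed), or NULL.
#' @param mrna_models Named list of exon tables; each element is a data.frame
#'   with columns `chrom`, `start`, `end`, `strand`, exons ordered 5' to 3'
#'   along the transcript. NULL for none.
#' @param repeat_loci data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `family`, or NULL.
#' @return An object of class `ReferenceBundle`.
#' @export
reference_bundle <- function(genome, ref_rnas, trna_loci = NULL,
                             mrna_models = NULL, repeat_loci = NULL) {
  stopifnot(is.character(genome), length(genome) > 0, !is.null(names(genome)))
  genome <- vapply(genome, toupper, character(1))
  ref_rnas$seq <- dna_norm(ref_rnas$seq)
  bad <- setdiff(unique(ref_rnas$class), CLASS_LABELS)
  if (length(bad) > 0) {
    stop("unknown class label(s) in reference RNAs: ", paste(bad, collapse = ", "))
  }
  if (any(ref_rnas$class %in% c("genomic repeat", "unknown"))) {
    stop("'genomic repeat' and 'unknown' are fallback labels, not reference classes")
  }
  chrom_len <- nchar(genome)
  check_loci <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    if (!all(df$chrom %in% names(genome))) {
      stop(what, ": locus on unknown chromosome")
    }
    if (!all(df$strand %in% c("+", "-"))) stop(what, ": strand must be '+' or '-'")
    if (any(df$start < 1) || any(df$end > chrom_len[df$chrom]) ||
        any(df$start > df$end)) {
      stop(what, ": locus out of chromosome bounds")
    }
    invisible(NULL)
  }
  check_loci(trna_loci, "trna_loci")
  check_loci(repeat_loci, "repeat_loci")
  if (!is.null(mrna_models)) {
    for (nm in names(mrna_models)) {
      ex <- mrna_models[[nm]]
      check_loci(ex, paste0("mrna_models[", nm, "]"))
      if (length(unique(ex$strand)) != 1) stop("gene model ", nm, ": mixed strands")
      gs <- if (ex$strand[1] == "+") ex$start else rev(ex$start)
      if (is.unsorted(gs, strictly = TRUE) && nrow(ex) > 1) {
        stop("gene model ", nm, ": exons must be ordered 5' to 3'")
      }
      o <- order(ex$start)
      if (nrow(ex) > 1 && any(ex$start[o][-1] <= ex$end[o][-nrow(ex)])) {
        stop("gene model ", nm, ": overlapping exons")
      }
    }
  }
  structure(list(genome = genome, ref_rnas = ref_rnas,
                 trna_loci = trna_loci, mrna_models = mrna_models,
                 repeat_loci = repeat_loci),
            class = "ReferenceBundle")
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat("ReferenceBundle:",
      length(x$genome), "chromosome(s),",
      nrow(x$ref_rnas), "reference RNAs,",
      if (is.null(x$trna_loci)) 0 else nrow(x$trna_loci), "tRNA loci,",
      length(x$mrna_models %||% list()), "gene models,",
      if (is.null(x$repeat_loci)) 0 else nrow(x$repeat_loci), "repeat loci\n")
  invisible(x)
}

#' Load a reference bundle from files
#'
#' Reads a genome FASTA, a class-labeled reference RNA FASTA (headers must
#' carry a `class=<label>` key, e.g. `>let-7a class=miRNA`), and a locus file
#' (BED6 or GFF3) describing tRNA genes, multi-exon gene models and repeat
#' intervals. BED input is parsed with its native 0-based half-open
#' convention and GFF with 1-based closed coordinates; both are converted to
#' the internal 1-based closed model. In BED6, locus type is encoded in the
#' name field as `tRNA:<name>` or `repeat:<family>` (exon chains require
#' GFF3). In GFF3 the recognized types are `tRNA`, `exon` (grouped by
#' `Parent`) and `repeat_region`.
#'
#' @param genome_path Path to genome FASTA.
#' @param rnas_path Path to reference RNA FASTA with `class=` header keys.
#' @param loci_path Path to BED6 or GFF3 locus file (optional).
#' @return A validated [reference_bundle()].
#' @export
load_bundle <- function(genome_path, rnas_path, loci_path = NULL) {
  for (p in c(genome_path, rnas_path, loci_path)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  gset <- Biostrings::readDNAStringSet(genome_path)
  genome <- as.character(gset)
  names(genome) <- sub("\\s.*$", "", names(gset))

  rset <- Biostrings::readDNAStringSet(rnas_path)
  headers <- names(rset)
  ids <- sub("\\s.*$", "", headers)
  cls <- rep(NA_character_, length(headers))
  has <- grepl("class=", headers, fixed = TRUE)
  cls[has] <- sub('^.*class=(("[^"]*")|([^ \t]+)).*$', "\\1", headers[has])
  cls <- gsub('"', "", cls)
  if (anyNA(cls)) {
    stop("reference RNA record(s) lacking class= header key: ",
         paste(ids[is.na(cls)], collapse = ", "))
  }
  ref_rnas <- data.frame(class = cls, ref_id = ids,
                         seq = as.character(rset), stringsAsFactors = FALSE)
  rownames(ref_rnas) <- NULL

  trna_loci <- NULL; mrna_models <- NULL; repeat_loci <- NULL
  if (!is.null(loci_path)) {
    loc <- .parse_loci(loci_path)
    trna_loci <- loc$trna_loci
    mrna_models <- loc$mrna_models
    repeat_loci <- loc$repeat_loci
  }
  reference_bundle(genome, ref_rnas, trna_loci, mrna_models, repeat_loci)
}

# Parse BED6 / GFF3 loci through rtracklayer; returns internal 1-based tables.
.parse_loci <- function(path) {
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  gr <- if (is_bed) rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  trna <- NULL; models <- NULL; reps <- NULL
  if (is_bed) {
    nm <- gr$name
    if (is.null(nm)) stop("BED loci need a name field (tRNA:<id> or repeat:<family>)")
    is_t <- startsWith(nm, "tRNA:")
    is_r <- startsWith(nm, "repeat:")
    if (!all(is_t | is_r)) {
      stop("BED name field must be tRNA:<id> or repeat:<family>; exon chains need GFF3")
    }
    if (any(is_t)) trna <- cbind(df[is_t, ], name = sub("^tRNA:", "", nm[is_t]))
    if (any(is_r)) reps <- cbind(df[is_r, ], family = sub("^repeat:", "", nm[is_r]))
  } else {
    type <- as.character(gr$type)
    if (any(type == "tRNA")) {
      i <- type == "tRNA"
      trna <- cbind(df[i, ], name = as.character(gr$ID[i]))
    }
    if (any(type == "repeat_region")) {
      i <- type == "repeat_region"
      fam <- if (!is.null(gr$family)) as.character(gr$family[i]) else as.character(gr$ID[i])
      reps <- cbind(df[i, ], family = fam)
    }
    if (any(type == "exon")) {
      i <- which(type == "exon")
      parent <- vapply(gr$Parent[i], function(p) as.character(p)[1], character(1))
      models <- lapply(split(i, parent), function(idx) {
        ex <- df[idx, , drop = FALSE]
        ex <- ex[order(ex$start), , drop = FALSE]
        if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
        rownames(ex) <- NULL
        ex
      })
    }
  }
  if (!is.null(trna)) rownames(trna) <- NULL
  if (!is.null(reps)) rownames(reps) <- NULL
  list(trna_loci = trna, mrna_models = models, repeat_loci = reps)
}

# Extract a 1-based closed genomic interval on the given strand.
extract_genomic <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start, end)
  if (strand == "-") rc_seq(s) else s
}

#' Build tRNA 3' trailer regions
#'
#' For every tRNA gene, extracts the `length` nucleotides immediately
#' downstream of the gene's 3' end, read on the gene strand (minus-strand
#' regions are taken upstream of the genomic start and reverse-complemented).
#' Regions truncated by a chromosome end are kept and flagged.
#'
#' @param bundle A [reference_bundle()] with `trna_loci`.
#' @param length Region length in nucleotides (default 40).
#' @return data.frame with columns `trna_name`, `chrom`, `strand`,
#'   `region_seq`, `truncated`.
#' @export
build_trailer_regions <- function(bundle, length = 40) {
  loci <- bundle$trna_loci
  if (is.null(loci) || nrow(loci) == 0) stop("bundle has no tRNA loci")
  chrom_len <- nchar(bundle$genome)
  out <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    if (l$strand == "+") {
      a <- l$end + 1
      b <- min(l$end + length, chrom_len[[l$chrom]])
      trunc <- b - a + 1 < length
      seq <- if (b >= a) extract_genomic(bundle$genome, l$chrom, a, b, "+") else ""
    } else {
      b <- l$start - 1
      a <- max(l$start - length, 1)
      trunc <- b - a + 1 < length
      seq <- if (b >= a) extract_genomic(bundle$genome, l$chrom, a, b, "-") else ""
    }
    data.frame(trna_name = l$name, chrom = l$chrom, strand = l$strand,
               region_seq = seq, truncated = trunc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build CCA-tailed tRNA reference sequences
#'
#' Appends the post-transcriptionally added CCA trinucleotide to every
#' tRNA-class reference sequence, so reads spanning the mature tRNA 3' end
#' (which is absent from the genome) can be rescued by exact matching.
#'
#' @param bundle A [reference_bundle()].
#' @return data.frame with columns `ref_id`, `seq` (possibly zero rows).
#' @export
build_cca_trnas <- function(bundle) {
  tr <- bundle$ref_rnas[bundle$ref_rnas$class == "tRNA", , drop = FALSE]
  out <- data.frame(ref_id = tr$ref_id,
                    seq = if (nrow(tr)) paste0(tr$seq, "CCA") else character(0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the exon-exon junction library
#'
#' For every adjacent exon pair of every gene model, concatenates the last
#' `flank` nt of the upstream exon with the first `flank` nt of the downstream
#' exon (both read on the gene strand). With the default flank of 29 nt, any
#' read of at most 30 nt spanning a junction is an exact substring of the
#' junction sequence.
#'
#' @param bundle A [reference_bundle()] with `mrna_models`.
#' @param flank Flank length in nt on each side (default 29).
#' @return data.frame with columns `ref_id` (`<gene>|junction<k>`), `seq`.
#' @export
build_junction_library <- function(bundle, flank = 29) {
  models <- bundle$mrna_models
  empty <- data.frame(ref_id = character(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(models) || length(models) == 0) return(empty)
  rows <- list()
  for (gene in names(models)) {
    ex <- models[[gene]]
    n <- nrow(ex)
    if (n < 2) next
    seqs <- vapply(seq_len(n), function(j) {
      extract_genomic(bundle$genome, ex$chrom[j], ex$start[j], ex$end[j],
                      ex$strand[j])
    }, character(1))
    for (j in seq_len(n - 1)) {
      up <- seqs[j]; dn <- seqs[j + 1]
      a <- substr(up, max(1, nchar(up) - flank + 1), nchar(up))
      b <- substr(dn, 1, min(flank, nchar(dn)))
      rows[[length(rows) + 1]] <- data.frame(
        ref_id = paste0(gene, "|junction", j), seq = paste0(a, b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spliced transcript sequences for all gene models
#'
#' @param bundle A [reference_bundle()].
#' @return Named character vector of spliced transcript sequences.
#' @export
spliced_transcripts <- function(bundle) {
  models <- bundle$mrna_models
  if (is.null(models) || length(models) == 0) return(character(0))
  vapply(models, function(ex) {
    paste(vapply(seq_len(nrow(ex)), function(j) {
      extract_genomic(bundle$genome, ex$chrom[j], ex$start[j], ex$end[j],
                      ex$strand[j])
    }, character(1)), collapse = "")
  }, character(1))
}

#' Write derived auxiliary references as FASTA
#'
#' @param x data.frame with `ref_id`/`seq` (or `trna_name`/`region_seq`).
#' @param path Output FASTA path.
#' @param what Provenance tag written into each header.
#' @return `path`, invisibly.
#' @export
write_aux_fasta <- function(x, path, what = "derived") {
  ids <- if ("ref_id" %in% names(x)) x$ref_id else x$trna_name
  seqs <- if ("seq" %in% names(x)) x$seq else x$region_seq
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- paste0(ids, " source=", what)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
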