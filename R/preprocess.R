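# Read cleanup: 3' adapter trimming, contaminant filtering, collapsing raw
# reads into unique 16-30 nt sequences with per-library counts.

#' Trim the 3' adapter from reads
#'
#' Returns, for each read, the prefix preceding the leftmost exact occurrence
#' of an adapter prefix of length >= `min_overlap` that either extends to the
#' read's 3' end or is the full adapter; reads with no such occurrence get
#' `NA` (no-adapter flag). Trimming an already-trimmed insert is a no-op only
#' if the insert does not itself contain a terminal adapter-prefix match, so
#' callers should trim once.
#'
#' @param reads Character vector of read sequences (DNA space).
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum terminal overlap in nt (default 5).
#' @return Character vector of inserts; `NA` where no adapter was found.
#' @export
trim_3prime_adapter <- function(reads, adapter, min_overlap = 5) {
  stopifnot(nchar(adapter) > 0, min_overlap >= 1)
  reads <- dna_norm(reads)
  adapter <- dna_norm(adapter)
  n <- nchar(reads)
  alen <- nchar(adapter)
  out <- rep(NA_character_, length(reads))
  done <- rep(FALSE, length(reads))
  if (length(reads) == 0) return(out)
  for (i in seq_len(max(n) - min_overlap + 1)) {
    active <- which(!done & (n - i + 1) >= min_overlap)
    if (length(active) == 0) next
    m <- pmin(n[active] - i + 1L, alen)
    frag <- substr(reads[active], i, i + m - 1L)
    ok <- frag == substr(rep(adapter, length(m)), 1L, m)
    hit <- active[ok]
    if (length(hit) > 0) {
      out[hit] <- substr(reads[hit], 1L, i - 1L)
      done[hit] <- TRUE
    }
  }
  out
}

#' Filter adapter-trimmed inserts
#'
#' Applies the contaminant and size filters to trimmed inserts and returns a
#' reason code per insert: `"keep"`, `"poly_a"` (>= `polya_frac` adenine),
#' `"adapter5"` (insert starts with a >= `contam_len` nt exact match to the 3'
#' end of the 5' adapter, the signature of adapter-dimer ligation), or
#' `"too_short"` / `"too_long"` (outside the `min_len`..`max_len` window).
#'
#' @param inserts Character vector of trimmed inserts.
#' @param five_prime_adapter 5' adapter sequence (may be `NULL` to skip the
#'   contaminant check).
#' @param min_len,max_len Retained size window (defaults 16 and 30 nt).
#' @param polya_frac Adenine fraction at or above which an insert is a poly-A
#'   artifact (default 0.9, tolerating single sequencing errors).
#' @param contam_len Anchored match length for the 5'-adapter contaminant rule
#'   (default 10 nt).
#' @return Character vector of reason codes, same length as `inserts`.
#' @export
filter_insert <- function(inserts, five_prime_adapter = NULL,
                          min_len = 16, max_len = 30,
                          polya_frac = 0.9, contam_len = 10) {
  inserts <- dna_norm(inserts)
  n <- nchar(inserts)
  reason <- rep("keep", length(inserts))
  a_frac <- ifelse(n > 0, nchar(gsub("[^A]", "", inserts)) / n, 0)
  reason[n > 0 & a_frac >= polya_frac] <- "poly_a"
  if (!is.null(five_prime_adapter) && nchar(five_prime_adapter) >= contam_len) {
    ad5 <- dna_norm(five_prime_adapter)
    sfx <- substr(ad5, nchar(ad5) - contam_len + 1, nchar(ad5))
    contam <- reason == "keep" & n >= contam_len &
      substr(inserts, 1, contam_len) == sfx
    reason[contam] <- "adapter5"
  }
  reason[reason == "keep" & n < min_len] <- "too_short"
  reason[reason == "keep" & n > max_len] <- "too_long"
  reason
}

#' Collapse kept inserts into unique sequences with per-library counts
#'
#' @param inserts Character vector of kept insert sequences.
#' @param library_id Character vector of library names, parallel to `inserts`.
#' @param weights Optional integer multiplicities (default 1 per insert).
#' @param libraries Library column order; defaults to sorted unique values of
#'   `library_id`.
#' @return data.frame with column `sequence` (lexicographic order) and one
#'   integer count column per library.
#' @export
collapse_reads <- function(inserts, library_id, weights = NULL,
                           libraries = NULL) {
  if (is.null(libraries)) libraries <- sort(unique(library_id))
  if (is.null(weights)) weights <- rep(1L, length(inserts))
  if (length(inserts) == 0) {
    out <- data.frame(sequence = character(0))
    for (lib in libraries) out[[lib]] <- integer(0)
    return(out)
  }
  seqs <- sort(unique(inserts))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in libraries) {
    sel <- library_id == lib
    agg <- tapply(weights[sel], factor(inserts[sel], levels = seqs), sum)
    cnt <- as.integer(agg)
    cnt[is.na(cnt)] <- 0L
    out[[lib]] <- cnt
  }
  rownames(out) <- NULL
  out
}

#' Preprocess raw small-RNA reads
#'
#' Full cleanup stage: normalizes to DNA space, discards reads containing N
#' (exact-match mapping cannot place them), trims the 3' adapter, applies the
#' contaminant and size filters, and collapses survivors into unique
#' sequences with per-library counts.
#'
#' @param reads data.frame with columns `read`, `library` and optionally
#'   `count` (pre-collapsed multiplicities).
#' @param adapter3 3' adapter sequence.
#' @param adapter5 5' adapter sequence (optional).
#' @param min_overlap Minimum adapter overlap (default 5).
#' @param min_len,max_len Size window (defaults 16, 30).
#' @param libraries Library column order for the collapsed table.
#' @return List with `records` (collapsed table from [collapse_reads()]) and
#'   `discard_log` (data.frame `library`, `reason`, `n` counting `contains_n`,
#'   `no_adapter`, `poly_a`, `adapter5`, `too_short`, `too_long`).
#' @export
preprocess_reads <- function(reads, adapter3, adapter5 = NULL,
                             min_overlap = 5, min_len = 16, max_len = 30,
                             libraries = NULL) {
  stopifnot(all(c("read", "library") %in% names(reads)))
  if (is.null(reads$count)) reads$count <- 1L
  if (is.null(libraries)) libraries <- sort(unique(reads$library))
  reads$read <- dna_norm(reads$read)

  # work on unique (read, library) pairs for speed; counts carry multiplicity
  key <- paste(reads$read, reads$library, sep = "\r")
  agg <- rowsum(reads$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  u <- data.frame(read = vapply(parts, `[`, character(1), 1),
                  library = vapply(parts, `[`, character(1), 2),
                  count = as.integer(agg[, 1]), stringsAsFactors = FALSE)

  fate <- rep(NA_character_, nrow(u))
  has_n <- grepl("N", u$read, fixed = TRUE)
  fate[has_n] <- "contains_n"

  insert <- rep(NA_character_, nrow(u))
  idx <- which(!has_n)
  if (length(idx) > 0) {
    tr <- trim_3prime_adapter(u$read[idx], adapter3, min_overlap)
    insert[idx] <- tr
    fate[idx][is.na(tr)] <- "no_adapter"
  }
  idx <- which(is.na(fate))
  if (length(idx) > 0) {
    reason <- filter_insert(insert[idx], adapter5,
                            min_len = min_len, max_len = max_len)
    fate[idx] <- ifelse(reason == "keep", "kept", reason)
  }

  kept <- fate == "kept"
  records <- collapse_reads(insert[kept], u$library[kept],
                            weights = u$count[kept], libraries = libraries)
  log_df <- expand.grid(library = libraries,
                        reason = c("contains_n", "no_adapter", "poly_a",
                                   "adapter5", "too_short", "too_long"),
                        stringsAsFactors = FALSE)
  log_df$n <- mapply(function(lib, rs) {
    sum(u$count[u$library == lib & fate == rs])
  }, log_df$library, log_df$reason)
  list(records = records, discard_log = log_df)
}

#' Read a small-RNA library from FASTA/FASTQ or a two-column table
#'
#' FASTA/FASTQ records contribute one read each unless the header carries a
#' `count=<int>` key. TSV input needs columns `sequence` and `count` (a header
#' line is auto-detected).
#'
#' @param path Input file.
#' @param library Library name attached to every read.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`, `"tsv"`.
#' @return data.frame with columns `read`, `library`, `count`.
#' @export
read_small_rna <- function(path, library, format = "auto") {
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq"
      else if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) "fasta"
      else "tsv"
  }
  if (format %in% c("fasta", "fastq")) {
    set <- Biostrings::readDNAStringSet(path, format = format)
    cnt <- rep(1L, length(set))
    has <- grepl("count=", names(set))
    cnt[has] <- as.integer(sub("^.*count=([0-9]+).*$", "\\1", names(set)[has]))
    return(data.frame(read = as.character(set), library = library,
                      count = cnt, stringsAsFactors = FALSE))
  }
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- length(first) < 2 ||
    is.na(suppressWarnings(as.numeric(first[2])))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("sequence", "count")
  data.frame(read = tab$sequence, library = library,
             count = as.integer(tab$count), stringsAsFactors = FALSE)
}
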