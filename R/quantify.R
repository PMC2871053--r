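# Normalization and subcellular-enrichment statistics: reads-per-million,
# N/C ratios with exclusivity flags, isomiR grouping with per-library
# representatives, nuclear-cytoplasmic correlation, 3'-end hexanucleotide
# motif association, and length distributions.

#' Reads-per-million normalization
#'
#' @param raw Raw read count(s).
#' @param library_mapped_total Total mapped read count of the library.
#' @return `raw / total * 1e6`.
#' @export
rpm_normalize <- function(raw, library_mapped_total) {
  if (any(library_mapped_total <= 0)) stop("mapped total must be positive")
  raw / library_mapped_total * 1e6
}

#' Nuclear/cytoplasmic enrichment ratio
#'
#' `nc = nuclear_rpm / cytoplasmic_rpm` when both abundances are positive.
#' A sequence seen in only one compartment gets an exclusivity flag instead of
#' a numeric ratio (the two exclusive categories are reported as separate
#' fractions, never as 0 or infinity).
#'
#' @param nuclear_rpm,cytoplasmic_rpm Non-negative abundances (vectorized).
#' @return List with `nc` (numeric, NA where exclusive) and `flag`
#'   (`"both"`, `"nuclear-only"`, `"cytoplasmic-only"`).
#' @export
nc_ratio <- function(nuclear_rpm, cytoplasmic_rpm) {
  if (any(nuclear_rpm < 0) || any(cytoplasmic_rpm < 0)) {
    stop("abundances must be non-negative")
  }
  if (any(nuclear_rpm == 0 & cytoplasmic_rpm == 0)) {
    stop("N/C undefined: both abundances zero")
  }
  flag <- ifelse(nuclear_rpm > 0 & cytoplasmic_rpm > 0, "both",
                 ifelse(cytoplasmic_rpm == 0, "nuclear-only",
                        "cytoplasmic-only"))
  nc <- ifelse(flag == "both", nuclear_rpm / cytoplasmic_rpm, NA_real_)
  list(nc = nc, flag = flag)
}

#' Per-sequence N/C table
#'
#' Builds the per-unique-sequence enrichment table: RPM per library, N/C ratio
#' or exclusivity flag, and eligibility (raw count strictly greater than
#' `min_count` in at least one library; eligibility always uses raw counts,
#' never RPM).
#'
#' @param records Annotated records (e.g. from [annotate_cascade()]) with a
#'   `sequence` column, raw count columns, and optionally `label`.
#' @param mapped_totals Named numeric vector of per-library mapped totals.
#' @param nc_libraries Numerator and denominator library names.
#' @param min_count Strict raw-count eligibility threshold (default 10).
#' @return data.frame: `sequence`, `label` (if present), raw counts,
#'   `<lib>_rpm`, `nc`, `nc_flag`, `eligible`.
#' @export
nc_table <- function(records, mapped_totals,
                     nc_libraries = c("nuclear", "cytoplasmic"),
                     min_count = 10) {
  libs <- names(mapped_totals)
  out <- data.frame(sequence = records$sequence, stringsAsFactors = FALSE)
  if (!is.null(records$label)) out$label <- records$label
  for (l in libs) out[[l]] <- records[[l]]
  for (l in libs) {
    out[[paste0(l, "_rpm")]] <- rpm_normalize(records[[l]], mapped_totals[[l]])
  }
  keep <- rowSums(as.matrix(out[, libs, drop = FALSE])) > 0
  out <- out[keep, , drop = FALSE]
  ncr <- nc_ratio(out[[paste0(nc_libraries[1], "_rpm")]],
                  out[[paste0(nc_libraries[2], "_rpm")]])
  out$nc <- ncr$nc
  out$nc_flag <- ncr$flag
  out$eligible <- Reduce(`|`, lapply(nc_libraries, function(l) out[[l]] > min_count))
  rownames(out) <- NULL
  out
}

#' Summary of the N/C distribution
#'
#' Over eligible records: the fraction with numeric N/C inside `range`, the
#' fractions exclusive to each compartment, and a histogram of log10(N/C) on
#' logarithmic bins.
#'
#' @param records N/C table from [nc_table()] (eligibility already encoded;
#'   only `eligible` rows are summarized).
#' @param range In-range window for the headline fraction (default
#'   `c(0.02, 5)`, closed).
#' @param bins Histogram bin edges on the log10 scale.
#' @param by_class Also return per-class histograms keyed by `label`.
#' @return List: `n`, `fraction_in_range`, `fraction_nuclear_only`,
#'   `fraction_cytoplasmic_only`, `histogram` (data.frame), and optionally
#'   `by_class`.
#' @export
nc_summary <- function(records, range = c(0.02, 5),
                       bins = seq(-4, 4, by = 0.5), by_class = FALSE) {
  rec <- records[records$eligible, , drop = FALSE]
  if (nrow(rec) == 0) stop("no eligible records")
  n <- nrow(rec)
  hist_of <- function(x) {
    lx <- log10(x)
    lx <- pmin(pmax(lx, min(bins)), max(bins))
    cut_bins <- cut(lx, bins, include.lowest = TRUE)
    data.frame(bin = levels(cut_bins), count = as.integer(table(cut_bins)),
               stringsAsFactors = FALSE)
  }
  res <- list(
    n = n,
    fraction_in_range = sum(!is.na(rec$nc) & rec$nc >= range[1] &
                              rec$nc <= range[2]) / n,
    fraction_nuclear_only = sum(rec$nc_flag == "nuclear-only") / n,
    fraction_cytoplasmic_only = sum(rec$nc_flag == "cytoplasmic-only") / n,
    histogram = hist_of(rec$nc[!is.na(rec$nc)])
  )
  if (by_class && !is.null(rec$label)) {
    res$by_class <- lapply(split(rec$nc[!is.na(rec$nc)],
                                 rec$label[!is.na(rec$nc)]), hist_of)
  }
  res
}

#' Group miRNA-annotated sequences into isomiR families
#'
#' Each miRNA-labeled sequence is located inside its matched hairpin reference
#' (first exact occurrence of its genomic prefix) and assigned to the mature
#' miRNA whose annotated arm it overlaps most (ties to the 5'-most arm;
#' sequences not overlapping any arm are dropped). Per library, the
#' representative isomiR is the most abundant member (ties broken by
#' lexicographically smallest sequence). Groups whose representatives differ
#' between the two libraries are flagged discordant and excluded from
#' representative-level analyses.
#'
#' @param records Annotated records with `sequence`, `match_seq`,
#'   `matched_ref`, `label == "miRNA"` rows, and count columns.
#' @param catalog data.frame mapping mature miRNAs to hairpin coordinates:
#'   columns `mirna_id`, `hairpin_id`, `start`, `end` (1-based within the
#'   hairpin reference sequence).
#' @param hairpins Named character vector of hairpin reference sequences.
#' @param libraries Count column names (first two define the discordance
#'   comparison).
#' @return data.frame, one row per group: `mirna_id`, `n_members`, per-library
#'   `<lib>_rep_seq` and `<lib>_rep_count`, `discordant`; the member table of
#'   each group is attached as attribute `members` (named list).
#' @export
group_isomirs <- function(records, catalog, hairpins, libraries) {
  mir <- records[records$label == "miRNA", , drop = FALSE]
  if (nrow(mir) == 0) {
    return(data.frame(mirna_id = character(0), n_members = integer(0),
                      discordant = logical(0), stringsAsFactors = FALSE))
  }
  assign_id <- rep(NA_character_, nrow(mir))
  for (i in seq_len(nrow(mir))) {
    hp_id <- mir$matched_ref[i]
    hp <- hairpins[[hp_id]]
    if (is.null(hp)) next
    pos <- regexpr(mir$match_seq[i], hp, fixed = TRUE)
    if (pos < 0) next
    s <- as.integer(pos); e <- s + nchar(mir$match_seq[i]) - 1L
    arms <- catalog[catalog$hairpin_id == hp_id, , drop = FALSE]
    if (nrow(arms) == 0) next
    ov <- pmax(0, pmin(e, arms$end) - pmax(s, arms$start) + 1)
    if (max(ov) == 0) next
    best <- arms[order(-ov, arms$start), , drop = FALSE]
    assign_id[i] <- best$mirna_id[1]
  }
  mir <- mir[!is.na(assign_id), , drop = FALSE]
  assign_id <- assign_id[!is.na(assign_id)]
  groups <- split(seq_len(nrow(mir)), assign_id)
  members <- list()
  rows <- lapply(names(groups), function(gid) {
    g <- mir[groups[[gid]], , drop = FALSE]
    row <- data.frame(mirna_id = gid, n_members = nrow(g),
                      stringsAsFactors = FALSE)
    reps <- character(length(libraries))
    for (k in seq_along(libraries)) {
      lib <- libraries[k]
      o <- order(-g[[lib]], g$sequence)
      reps[k] <- g$sequence[o[1]]
      row[[paste0(lib, "_rep_seq")]] <- reps[k]
      row[[paste0(lib, "_rep_count")]] <- g[[lib]][o[1]]
    }
    row$discordant <- length(unique(reps[1:2])) > 1
    members[[gid]] <<- g
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Squared Pearson correlation of per-library miRNA abundances
#'
#' @param nuclear,cytoplasmic Representative abundances (RPM) of concordant
#'   isomiR groups, paired.
#' @param log_transform Correlate on log10(x + 1) instead of raw RPM
#'   (default FALSE).
#' @return R squared (scalar).
#' @export
mirna_correlation <- function(nuclear, cytoplasmic, log_transform = FALSE) {
  stopifnot(length(nuclear) == length(cytoplasmic))
  if (length(nuclear) < 2) stop("need at least 2 paired groups")
  if (stats::sd(nuclear) == 0 || stats::sd(cytoplasmic) == 0) {
    stop("zero variance in one library")
  }
  if (log_transform) {
    nuclear <- log10(nuclear + 1); cytoplasmic <- log10(cytoplasmic + 1)
  }
  stats::cor(nuclear, cytoplasmic)^2
}

#' Extract the 3'-end hexanucleotide
#'
#' @param seq Character vector of sequences, each at least 6 nt.
#' @return Last 6 nt of each sequence (same alphabet as the input).
#' @export
hexamer_extract <- function(seq) {
  n <- nchar(seq)
  if (any(n < 6)) stop("sequence shorter than 6 nt")
  substr(seq, n - 5, n)
}

#' Association between a terminal motif and N/C enrichment
#'
#' Splits eligible records with a numeric N/C into carriers of the terminal
#' motif (3'-end suffix match, motif length 3-7 nt) and non-carriers, and
#' summarizes the two N/C distributions: group sizes, medians, the ratio of
#' medians, and a Wilcoxon rank-sum p-value where both groups are non-empty.
#'
#' @param records N/C table rows with `sequence`, `nc`, `eligible`.
#' @param motif Terminal motif (RNA or DNA alphabet, 3-7 nt).
#' @return List: `motif`, `n_with`, `n_without`, `median_nc_with`,
#'   `median_nc_without`, `median_ratio`, `wilcox_p`.
#' @export
motif_nc_association <- function(records, motif) {
  if (nchar(motif) < 3 || nchar(motif) > 7) stop("motif length must be 3-7 nt")
  rec <- records[records$eligible & !is.na(records$nc), , drop = FALSE]
  motif_dna <- dna_norm(motif)
  carrier <- endsWith(dna_norm(rec$sequence), motif_dna)
  with_nc <- rec$nc[carrier]; without_nc <- rec$nc[!carrier]
  p <- if (length(with_nc) >= 1 && length(without_nc) >= 1 &&
           (length(with_nc) + length(without_nc)) >= 3) {
    suppressWarnings(stats::wilcox.test(with_nc, without_nc)$p.value)
  } else NA_real_
  list(motif = motif, n_with = length(with_nc), n_without = length(without_nc),
       median_nc_with = if (length(with_nc)) stats::median(with_nc) else NA_real_,
       median_nc_without = if (length(without_nc)) stats::median(without_nc) else NA_real_,
       median_ratio = if (length(with_nc) && length(without_nc)) {
         stats::median(with_nc) / stats::median(without_nc)
       } else NA_real_,
       wilcox_p = p)
}

#' Count-weighted read length distribution
#'
#' @param records Annotated records with `sequence`, `label` and count
#'   columns.
#' @param library Count column to weight by.
#' @param class_label Restrict to one class (NULL for all).
#' @param lengths Histogram support (default 16:30).
#' @return data.frame `length`, `count`, with the modal length in attribute
#'   `mode`; empty classes give an all-zero histogram with a warning.
#' @export
length_distribution <- function(records, library, class_label = NULL,
                                lengths = 16:30) {
  rec <- records
  if (!is.null(class_label)) rec <- rec[rec$label == class_label, , drop = FALSE]
  w <- if (nrow(rec)) rec[[library]] else numeric(0)
  ln <- nchar(rec$sequence)
  counts <- vapply(lengths, function(L) sum(w[ln == L]), numeric(1))
  out <- data.frame(length = lengths, count = counts)
  if (sum(counts) == 0) {
    warning("empty length distribution",
            if (!is.null(class_label)) paste0(" for class ", class_label))
    attr(out, "mode") <- NA_integer_
  } else {
    attr(out, "mode") <- lengths[which.max(counts)]
  }
  out
}
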