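# tRNA 3' trailer calling. A trailer small RNA is a sequence that perfectly
# matches the 40-nt region immediately downstream of a tRNA gene starting at
# the region's first or second nucleotide (the RNase Z cleavage product, with
# polymerase III 3'-end heterogeneity). Variants from the same gene are
# "isotrailers" and are aggregated per gene.

#' Call tRNA 3' trailers
#'
#' A sequence is a trailer of gene `g` iff it equals
#' `region_seq(g)[s .. s+len-1]` for start offset `s` in {1, 2}. A sequence
#' matching several genes' regions is assigned to every matching gene (the
#' per-gene view double-counts it by design; the annotation cascade counts it
#' once in the class total).
#'
#' @param records data.frame with a `sequence` column and optionally count
#'   columns per library.
#' @param regions Trailer regions from [build_trailer_regions()].
#' @param offsets Allowed start offsets (default `c(1, 2)`).
#' @return data.frame of isotrailer calls: `trna_name`, `sequence`,
#'   `start_offset`, `end_offset`, plus any count columns carried over from
#'   `records`.
#' @export
call_trailers <- function(records, regions, offsets = c(1L, 2L)) {
  count_cols <- setdiff(names(records), "sequence")
  empty <- data.frame(trna_name = character(0), sequence = character(0),
                      start_offset = integer(0), end_offset = integer(0),
                      stringsAsFactors = FALSE)
  for (cc in count_cols) empty[[cc]] <- records[[cc]][0]
  if (nrow(records) == 0 || nrow(regions) == 0) return(empty)

  lens <- sort(unique(nchar(records$sequence)))
  cand <- list()
  for (i in seq_len(nrow(regions))) {
    rs <- regions$region_seq[i]
    for (s in offsets) {
      for (len in lens) {
        if (s + len - 1L > nchar(rs)) next
        cand[[length(cand) + 1]] <- data.frame(
          trna_name = regions$trna_name[i],
          cand_seq = substr(rs, s, s + len - 1L),
          start_offset = s, end_offset = s + len - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  m <- merge(cand, records, by.x = "cand_seq", by.y = "sequence")
  if (nrow(m) == 0) return(empty)
  out <- data.frame(trna_name = m$trna_name, sequence = m$cand_seq,
                    start_offset = m$start_offset, end_offset = m$end_offset,
                    stringsAsFactors = FALSE)
  for (cc in count_cols) out[[cc]] <- m[[cc]]
  out <- out[order(out$trna_name, out$sequence, out$start_offset), ,
             drop = FALSE]
  # a sequence matching one gene at both offsets is one isotrailer (smallest
  # offset wins); matches to different genes are kept
  out <- out[!duplicated(out[, c("trna_name", "sequence")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate isotrailers per tRNA gene and apply the abundance filter
#'
#' The read count of a trailer is the total count of all its isotrailers. A
#' trailer is kept if that total is strictly greater than `min_total` in at
#' least one library. The representative sequence is the most abundant
#' isotrailer in `rep_library` (ties broken lexicographically); the U-tail
#' flag ([classify_u_tail()]) and the N/C ratio are computed on the
#' representative and the aggregate RPM respectively.
#'
#' @param calls Isotrailer calls from [call_trailers()] carrying one raw
#'   count column per library.
#' @param mapped_totals Named numeric vector of per-library mapped totals
#'   (RPM denominators).
#' @param min_total Eligibility threshold on raw totals; strict (default 10,
#'   i.e. "more than 10").
#' @param rep_library Library whose most abundant isotrailer is the
#'   representative (default `"cytoplasmic"`).
#' @param nc_libraries Length-2 character vector naming the numerator and
#'   denominator libraries of the N/C ratio (default nuclear, cytoplasmic).
#' @return data.frame, one row per kept trailer: `trna_name`,
#'   `n_isotrailers`, raw counts and `<lib>_rpm` per library,
#'   `representative_seq`, `u_tail`, `nc` (NA for exclusive cases) and
#'   `nc_flag` (`both`, `nuclear-only`, `cytoplasmic-only`), sorted by
#'   descending RPM in `rep_library`.
#' @export
aggregate_isotrailers <- function(calls, mapped_totals, min_total = 10,
                                  rep_library = "cytoplasmic",
                                  nc_libraries = c("nuclear", "cytoplasmic")) {
  libs <- names(mapped_totals)
  stopifnot(all(libs %in% names(calls)) || nrow(calls) == 0,
            rep_library %in% libs, all(nc_libraries %in% libs))
  genes <- unique(calls$trna_name)
  rows <- list()
  for (g in genes) {
    sub <- calls[calls$trna_name == g, , drop = FALSE]
    totals <- vapply(libs, function(l) sum(sub[[l]]), numeric(1))
    if (!any(totals > min_total)) next
    o <- order(-sub[[rep_library]], sub$sequence)
    rep_seq <- sub$sequence[o[1]]
    rpm <- vapply(libs, function(l) {
      rpm_normalize(totals[[l]], mapped_totals[[l]])
    }, numeric(1))
    ncr <- nc_ratio(rpm[[nc_libraries[1]]], rpm[[nc_libraries[2]]])
    row <- data.frame(trna_name = g, n_isotrailers = nrow(sub),
                      stringsAsFactors = FALSE)
    for (l in libs) row[[l]] <- totals[[l]]
    for (l in libs) row[[paste0(l, "_rpm")]] <- rpm[[l]]
    row$representative_seq <- rep_seq
    row$u_tail <- classify_u_tail(rep_seq)
    row$nc <- ncr$nc
    row$nc_flag <- ncr$flag
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) {
    return(data.frame(trna_name = character(0), n_isotrailers = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out[[paste0(rep_library, "_rpm")]], out$trna_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' U-tail classification
#'
#' TRUE iff the sequence terminates in a stretch of at least two uridines
#' (T in DNA space) - the signature of RNA polymerase III termination.
#'
#' @param seq Character vector (RNA or DNA alphabet).
#' @return Logical vector.
#' @export
classify_u_tail <- function(seq) {
  grepl("TT$", dna_norm(seq))
}

#' 5' and 3' end heterogeneity of isotrailers
#'
#' Per tRNA gene, the count-weighted distributions of isotrailer start offsets
#' (support {1, 2}) and end offsets within the trailer region, summarized as
#' Shannon entropy (bits) and the number of distinct ends. Counts are summed
#' over all count columns present in `calls`.
#'
#' @param calls Isotrailer calls from [call_trailers()].
#' @return data.frame: `trna_name`, `five_prime_entropy`,
#'   `three_prime_entropy`, `n_distinct_5p`, `n_distinct_3p`.
#' @export
end_heterogeneity <- function(calls) {
  count_cols <- setdiff(names(calls),
                        c("trna_name", "sequence", "start_offset", "end_offset"))
  w <- if (length(count_cols) == 0) rep(1, nrow(calls))
       else rowSums(calls[, count_cols, drop = FALSE])
  genes <- unique(calls$trna_name)
  out <- lapply(genes, function(g) {
    i <- calls$trna_name == g
    w5 <- tapply(w[i], calls$start_offset[i], sum)
    w3 <- tapply(w[i], calls$end_offset[i], sum)
    data.frame(trna_name = g,
               five_prime_entropy = shannon_entropy(w5),
               three_prime_entropy = shannon_entropy(w3),
               n_distinct_5p = length(w5), n_distinct_3p = length(w3),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
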