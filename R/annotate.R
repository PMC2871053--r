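# Hierarchical class annotation: each mapped unique sequence is assigned to
# the first class (in the fixed cascade order) whose reference set matches it,
# then removed from the pool. Genomic repeats and unknowns are terminal
# fallbacks decided by locus overlap and by elimination.

# First reference of `refs` (named seqs) containing `q` as an exact
# sense-strand substring; NA if none.
.first_containing <- function(q, refs) {
  if (length(refs) == 0) return(NA_character_)
  hit <- which(grepl(q, refs, fixed = TRUE))
  if (length(hit) == 0) NA_character_ else names(refs)[hit[1]]
}

# Does any genomic hit of width `w` overlap a repeat locus by >= 1 nt?
.overlaps_repeat <- function(hits, w, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0 || nrow(hits) == 0) return(FALSE)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- s + w - 1L
    if (any(repeats$chrom == hits$chrom[i] & repeats$start <= e &
            repeats$end >= s)) return(TRUE)
  }
  FALSE
}

#' Annotate mapped sequences by the ordered class cascade
#'
#' For each class in the cascade order, unlabeled sequences that are exact
#' sense-strand substrings of any reference of that class receive the label
#' and leave the pool (tRNA also matches via the CCA-tailed form; the trailer
#' class matches the 40-nt downstream regions at start offsets 1 or 2).
#' Records rescued by the one-mismatch tRNA stage are pre-labeled tRNA. After
#' the sequence-matched classes, unlabeled sequences with a genomic hit
#' overlapping a repeat locus become `genomic repeat`; the rest are `unknown`.
#' Trimmed records are matched through their genomic prefix.
#'
#' @param map_result Mapped records from [map_sequences()], joined with a
#'   count column per library (see [collapse_reads()]); only rows with
#'   `status == "mapped"` are annotated.
#' @param bundle A [reference_bundle()].
#' @param trailer_regions Regions from [build_trailer_regions()] (optional;
#'   without them the trailer class is skipped).
#' @param libraries Names of the count columns in `map_result`.
#' @param cascade Class order (default the fixed 20-class cascade).
#' @param warn_missing Warn once about cascade classes with no references.
#' @return List of class `srna_annotation`: `records` (the mapped rows plus
#'   `label` and `matched_ref`) and `class_counts` (per-class raw totals per
#'   library, one row per class label plus a `total` row).
#' @export
annotate_cascade <- function(map_result, bundle, trailer_regions = NULL,
                             libraries, cascade = SEQUENCE_CLASSES,
                             warn_missing = FALSE) {
  rec <- map_result[map_result$status == "mapped", , drop = FALSE]
  rec <- rec[order(rec$sequence), , drop = FALSE]  # order-independent output
  rownames(rec) <- NULL
  n <- nrow(rec)
  label <- rep(NA_character_, n)
  matched <- rec$matched_ref

  # one-mismatch tRNA rescues are tRNA by construction
  pre <- !is.na(rec$prelabel)
  label[pre] <- rec$prelabel[pre]

  refs_of <- function(cl) {
    r <- bundle$ref_rnas[bundle$ref_rnas$class == cl, , drop = FALSE]
    out <- stats::setNames(r$seq, r$ref_id)
    if (cl == "tRNA" && nrow(bundle$ref_rnas[bundle$ref_rnas$class == "tRNA", ]) > 0) {
      cca <- build_cca_trnas(bundle)
      out <- c(out, stats::setNames(cca$seq, paste0(cca$ref_id, "|CCA")))
    }
    if (cl == "mRNA") {
      tx <- spliced_transcripts(bundle)
      out <- c(out, tx)
    }
    out
  }

  missing_classes <- character(0)
  for (cl in cascade) {
    if (cl == "tRNA 3' trailer") {
      if (is.null(trailer_regions) || nrow(trailer_regions) == 0) {
        missing_classes <- c(missing_classes, cl)
        next
      }
      open <- which(is.na(label))
      if (length(open) == 0) next
      calls <- call_trailers(
        data.frame(sequence = rec$match_seq[open], stringsAsFactors = FALSE),
        trailer_regions)
      is_tr <- rec$match_seq[open] %in% calls$sequence
      label[open[is_tr]] <- cl
      m <- match(rec$match_seq[open[is_tr]], calls$sequence)
      matched[open[is_tr]] <- calls$trna_name[m]
      next
    }
    refs <- refs_of(cl)
    if (length(refs) == 0) {
      missing_classes <- c(missing_classes, cl)
      next
    }
    open <- which(is.na(label))
    if (length(open) == 0) break
    big <- paste(refs, collapse = "\r")
    q <- rec$match_seq[open]
    cand <- vapply(q, function(s) grepl(s, big, fixed = TRUE), logical(1),
                   USE.NAMES = FALSE)
    for (j in open[cand]) {
      mr <- .first_containing(rec$match_seq[j], refs)
      if (!is.na(mr)) {
        label[j] <- cl
        matched[j] <- sub("\\|CCA$", "", mr)
      }
    }
  }
  if (warn_missing && length(missing_classes) > 0) {
    warning("cascade classes with no references (skipped): ",
            paste(missing_classes, collapse = ", "))
  }

  open <- which(is.na(label))
  for (j in open) {
    w <- nchar(rec$match_seq[j])
    if (.overlaps_repeat(rec$hits[[j]], w, bundle$repeat_loci)) {
      label[j] <- "genomic repeat"
    } else {
      label[j] <- "unknown"
    }
  }
  rec$label <- label
  rec$matched_ref <- matched

  cc <- data.frame(class = CLASS_LABELS, stringsAsFactors = FALSE)
  for (lib in libraries) {
    cc[[lib]] <- vapply(CLASS_LABELS, function(cl) {
      sum(rec[[lib]][label == cl])
    }, numeric(1))
  }
  total <- data.frame(class = "total", stringsAsFactors = FALSE)
  for (lib in libraries) total[[lib]] <- sum(rec[[lib]])
  cc <- rbind(total, cc)
  rownames(cc) <- NULL
  structure(list(records = rec, class_counts = cc, libraries = libraries),
            class = "srna_annotation")
}

#' @export
print.srna_annotation <- function(x, ...) {
  cat("srna_annotation:", nrow(x$records), "mapped unique sequences,",
      "libraries:", paste(x$libraries, collapse = ", "), "\n")
  invisible(x)
}

#' Per-class composition table
#'
#' Computes per-class raw counts and percentages of the mapped library total,
#' per library. Percentages are printed at one decimal, or two decimals below
#' 1%. `mode = "rpm_combined"` instead reports each class's share of the
#' combined pool after per-library RPM normalization (a single percentage
#' column over both libraries).
#'
#' @param x An `srna_annotation` object, or a `class_counts`-shaped
#'   data.frame (first row `total`, one column per library).
#' @param mode `"raw"` (default) or `"rpm_combined"`.
#' @param miscrna_rollup Roll the individual miscRNA classes (7SK, vRNA,
#'   RNaseMRP, RNaseP, Xist, H19) into a single `miscRNA` reporting row.
#' @param split_aca45 If TRUE and `x` is an annotation object, sequences
#'   matched to a reference whose id contains "ACA45" are reported as a
#'   separate `scaRNA (ACA45)` row.
#' @return data.frame with `class`, per-library counts and `<lib>_pct`
#'   percentage columns (or `combined_pct`).
#' @export
composition_table <- function(x, mode = c("raw", "rpm_combined"),
                              miscrna_rollup = FALSE, split_aca45 = FALSE) {
  mode <- match.arg(mode)
  misc <- c("7SK", "vRNA", "RNaseMRP", "RNaseP", "Xist", "H19")
  if (inherits(x, "srna_annotation")) {
    cc <- x$class_counts
    libraries <- x$libraries
    if (split_aca45) {
      rec <- x$records
      aca <- rec$label == "scaRNA" & grepl("ACA45", rec$matched_ref)
      extra <- data.frame(class = "scaRNA (ACA45)", stringsAsFactors = FALSE)
      for (lib in libraries) {
        extra[[lib]] <- sum(rec[[lib]][aca])
        cc[[lib]][cc$class == "scaRNA"] <-
          cc[[lib]][cc$class == "scaRNA"] - extra[[lib]]
      }
      cc <- rbind(cc, extra)
    }
  } else {
    cc <- x
    libraries <- setdiff(names(cc), "class")
  }
  totals <- vapply(libraries, function(lib) cc[[lib]][cc$class == "total"],
                   numeric(1))
  if (any(totals == 0)) stop("zero mapped total in library")
  body <- cc[cc$class != "total", , drop = FALSE]
  if (miscrna_rollup && any(body$class %in% misc)) {
    roll <- data.frame(class = "miscRNA", stringsAsFactors = FALSE)
    for (lib in libraries) roll[[lib]] <- sum(body[[lib]][body$class %in% misc])
    body <- rbind(body[!body$class %in% misc, , drop = FALSE], roll)
  }
  if (mode == "raw") {
    for (lib in libraries) {
      body[[paste0(lib, "_pct")]] <- round_pct(body[[lib]] / totals[[lib]] * 100)
    }
  } else {
    rpm <- sapply(libraries, function(lib) body[[lib]] / totals[[lib]] * 1e6)
    comb <- rowSums(rpm)
    body$combined_pct <- round_pct(comb / sum(comb) * 100)
  }
  rownames(body) <- NULL
  body
}
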