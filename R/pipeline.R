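# Pipeline orchestration: preprocess -> map -> annotate -> trailers ->
# quantify, with a run manifest and the report tables (class composition,
# top miRNAs by N/C, top trailers by cytoplasmic abundance).

#' Run the full analysis pipeline
#'
#' Executes every stage on a pair (or more) of libraries and returns all
#' intermediate and final tables plus a run manifest with per-stage record
#' counts. Inputs may be given in memory (`bundle`, `reads`) or as file paths
#' (`genome_path`/`rnas_path`/`loci_path`, `read_paths` named by library);
#' paths are validated before any stage runs.
#'
#' @param config List with fields: `bundle` or (`genome_path`, `rnas_path`,
#'   `loci_path`); `reads` (data.frame `read`,`count`,`library`) or
#'   `read_paths` (named character vector); `adapter3`; optional `adapter5`,
#'   `min_overlap` (5), `min_len` (16), `max_len` (30), `min_prefix` (17),
#'   `min_count` (10), `trailer_length` (40), `junction_flank` (29),
#'   `nc_libraries` (`c("nuclear","cytoplasmic")`), `seed`.
#' @return List of class `srnaloc_run`: `records` (annotated unique
#'   sequences), `class_counts`, `composition`, `nc`, `isomir_groups`,
#'   `trailer_calls`, `trailer_table`, `mirna_table`, `discard_log`,
#'   `mapped_totals`, `manifest`.
#' @export
run_pipeline <- function(config) {
  get_cfg <- function(name, default) config[[name]] %||% default
  # validate before any stage runs
  for (p in c(config$genome_path, config$rnas_path, config$loci_path,
              config$read_paths)) {
    if (!file.exists(p)) stop("config error: input file not found: ", p)
  }
  if (is.null(config$adapter3)) stop("config error: adapter3 is required")
  if (is.null(config$bundle) && is.null(config$genome_path)) {
    stop("config error: provide bundle or genome_path/rnas_path")
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  bundle <- run_stage("reference", {
    if (!is.null(config$bundle)) config$bundle
    else load_bundle(config$genome_path, config$rnas_path, config$loci_path)
  })
  reads <- if (!is.null(config$reads)) config$reads else {
    do.call(rbind, lapply(names(config$read_paths), function(lib) {
      read_small_rna(config$read_paths[[lib]], lib)
    }))
  }
  libraries <- sort(unique(reads$library))
  nc_libs <- get_cfg("nc_libraries", c("nuclear", "cytoplasmic"))

  pre <- run_stage("preprocess", preprocess_reads(
    reads, adapter3 = config$adapter3, adapter5 = config$adapter5,
    min_overlap = get_cfg("min_overlap", 5),
    min_len = get_cfg("min_len", 16), max_len = get_cfg("max_len", 30),
    libraries = libraries))

  index <- run_stage("index", build_genome_index(bundle$genome))
  aux <- run_stage("rescue-aux",
                   build_rescue_aux(bundle, get_cfg("junction_flank", 29)))
  mapped <- run_stage("map", {
    mr <- map_sequences(pre$records$sequence, index, aux,
                        min_prefix = get_cfg("min_prefix", 17))
    for (lib in libraries) mr[[lib]] <- pre$records[[lib]]
    mr
  })

  trailer_regions <- run_stage("trailer-regions", {
    if (is.null(bundle$trna_loci)) NULL
    else build_trailer_regions(bundle, get_cfg("trailer_length", 40))
  })
  ann <- run_stage("annotate", annotate_cascade(
    mapped, bundle, trailer_regions, libraries = libraries))

  mapped_totals <- stats::setNames(
    vapply(libraries, function(l) sum(ann$records[[l]]), numeric(1)),
    libraries)

  nc <- run_stage("quantify", nc_table(
    ann$records, mapped_totals, nc_libraries = nc_libs,
    min_count = get_cfg("min_count", 10)))

  trailer_calls <- NULL; trailer_table <- NULL
  if (!is.null(trailer_regions)) {
    tr_rec <- ann$records[ann$records$label == "tRNA 3' trailer", ,
                          drop = FALSE]
    trailer_calls <- run_stage("trailers", call_trailers(
      tr_rec[, c("sequence", libraries)], trailer_regions))
    trailer_table <- run_stage("trailers", aggregate_isotrailers(
      trailer_calls, mapped_totals, min_total = get_cfg("min_count", 10),
      rep_library = nc_libs[2], nc_libraries = nc_libs))
  }

  isomir_groups <- NULL; mirna_table <- NULL
  if (!is.null(config$mirna_catalog)) {
    isomir_groups <- run_stage("isomirs", group_isomirs(
      ann$records, config$mirna_catalog, config$hairpins, libraries))
    mirna_table <- run_stage("isomirs", .mirna_rep_table(
      isomir_groups, mapped_totals, nc_libs,
      min_count = get_cfg("min_count", 10)))
  }

  manifest <- list(
    tool = "srnaloc",
    version = as.character(utils::packageVersion("srnaloc")),
    seed = config$seed %||% NA,
    libraries = libraries,
    parameters = list(
      adapter3 = config$adapter3, adapter5 = config$adapter5,
      min_overlap = get_cfg("min_overlap", 5),
      min_len = get_cfg("min_len", 16), max_len = get_cfg("max_len", 30),
      min_prefix = get_cfg("min_prefix", 17),
      min_count = get_cfg("min_count", 10),
      trailer_length = get_cfg("trailer_length", 40),
      junction_flank = get_cfg("junction_flank", 29)),
    stage_counts = list(
      input_reads = sum(reads$count %||% rep(1, nrow(reads))),
      kept_reads = sum(vapply(libraries, function(l) sum(pre$records[[l]]),
                              numeric(1))),
      discarded_reads = sum(pre$discard_log$n),
      unique_sequences = nrow(pre$records),
      mapped_unique = sum(mapped$status == "mapped"),
      unmapped_unique = sum(mapped$status == "unmapped"),
      mapped_totals = as.list(mapped_totals)))

  structure(list(records = ann$records, class_counts = ann$class_counts,
                 composition = composition_table(ann),
                 nc = nc, isomir_groups = isomir_groups,
                 mirna_table = mirna_table,
                 trailer_calls = trailer_calls, trailer_table = trailer_table,
                 discard_log = pre$discard_log,
                 mapped_totals = mapped_totals, manifest = manifest),
            class = "srnaloc_run")
}

#' @export
print.srnaloc_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("srnaloc run:", sc$input_reads, "input reads,", sc$kept_reads,
      "kept,", sc$unique_sequences, "unique sequences,",
      sc$mapped_unique, "mapped\n")
  invisible(x)
}

# miRNA representative-level table: concordant groups, RPM, N/C.
.mirna_rep_table <- function(groups, mapped_totals, nc_libs, min_count = 10) {
  g <- groups[!groups$discordant, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  nuc <- g[[paste0(nc_libs[1], "_rep_count")]]
  cyt <- g[[paste0(nc_libs[2], "_rep_count")]]
  out <- data.frame(
    mirna_id = g$mirna_id,
    sequence = g[[paste0(nc_libs[1], "_rep_seq")]],
    stringsAsFactors = FALSE)
  out$hexamer <- ifelse(nchar(out$sequence) >= 6,
                        hexamer_extract(out$sequence), NA_character_)
  out[[paste0(nc_libs[1], "_rpm")]] <-
    rpm_normalize(nuc, mapped_totals[[nc_libs[1]]])
  out[[paste0(nc_libs[2], "_rpm")]] <-
    rpm_normalize(cyt, mapped_totals[[nc_libs[2]]])
  keep <- nuc + cyt > 0
  out <- out[keep, , drop = FALSE]
  ncr <- nc_ratio(out[[paste0(nc_libs[1], "_rpm")]],
                  out[[paste0(nc_libs[2], "_rpm")]])
  out$nc <- ncr$nc
  out$nc_flag <- ncr$flag
  out$eligible <- nuc[keep] > min_count | cyt[keep] > min_count
  rownames(out) <- NULL
  out
}

#' Render the report tables
#'
#' Produces the three paper-shaped report tables: per-class composition,
#' top-k miRNAs ranked by descending N/C among eligible concordant miRNAs
#' (representative raw count > `min_count` in at least one library; N/C ties
#' broken by descending nuclear RPM), and top-k trailers ranked by descending
#' cytoplasmic aggregate RPM.
#'
#' @param results An `srnaloc_run` from [run_pipeline()].
#' @param k_mirna,k_trailer Row caps (defaults 10 and 5); fewer rows are
#'   returned without padding when fewer qualify.
#' @return List with `composition`, `top_mirna`, `top_trailers`.
#' @export
render_tables <- function(results, k_mirna = 10, k_trailer = 5) {
  top_mirna <- NULL
  if (!is.null(results$mirna_table)) {
    mt <- results$mirna_table
    mt <- mt[mt$eligible & !is.na(mt$nc), , drop = FALSE]
    nuc_col <- grep("_rpm$", names(mt), value = TRUE)[1]
    mt <- mt[order(-mt$nc, -mt[[nuc_col]]), , drop = FALSE]
    mt$nc <- round_half_up(mt$nc, 2)
    for (col in grep("_rpm$", names(mt), value = TRUE)) {
      mt[[col]] <- round_half_up(mt[[col]], 1)
    }
    top_mirna <- utils::head(mt, k_mirna)
    rownames(top_mirna) <- NULL
  }
  top_trailers <- NULL
  if (!is.null(results$trailer_table) && nrow(results$trailer_table) > 0) {
    tt <- results$trailer_table
    tt$nc <- round_half_up(tt$nc, 5)
    for (col in grep("_rpm$", names(tt), value = TRUE)) {
      tt[[col]] <- round_half_up(tt[[col]], 1)
    }
    top_trailers <- utils::head(tt, k_trailer)
    rownames(top_trailers) <- NULL
  }
  list(composition = results$composition, top_mirna = top_mirna,
       top_trailers = top_trailers)
}

#' Write pipeline results to a directory
#'
#' Emits the per-sequence annotation table, class composition, N/C table,
#' discard log, report tables and a manifest (run metadata, stage counts and
#' MD5 checksums of every written file).
#'
#' @param results An `srnaloc_run`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    df2 <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df2, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  tabs <- render_tables(results)
  paths <- c(
    annotation = wr(results$records, "annotation.tsv"),
    class_counts = wr(results$class_counts, "class_counts.tsv"),
    composition = wr(results$composition, "composition.tsv"),
    nc = wr(results$nc, "nc_table.tsv"),
    discard_log = wr(results$discard_log, "discard_log.tsv"))
  if (!is.null(tabs$top_mirna)) {
    paths[["top_mirna"]] <- wr(tabs$top_mirna, "top_mirna.tsv")
  }
  if (!is.null(tabs$top_trailers)) {
    paths[["top_trailers"]] <- wr(tabs$top_trailers, "top_trailers.tsv")
  }
  if (!is.null(results$trailer_calls)) {
    paths[["isotrailers"]] <- wr(results$trailer_calls, "isotrailers.tsv")
  }
  man <- results$manifest
  man$checksums <- as.list(tools::md5sum(paths))
  mp <- file.path(dir, "manifest.txt")
  writeLines(c(paste0("tool\t", man$tool),
               paste0("version\t", man$version),
               paste0("seed\t", man$seed),
               paste0("libraries\t", paste(man$libraries, collapse = ",")),
               vapply(names(man$parameters), function(k) {
                 paste0("param:", k, "\t",
                        paste(man$parameters[[k]] %||% "", collapse = ","))
               }, character(1)),
               vapply(names(man$stage_counts), function(k) {
                 paste0("count:", k, "\t",
                        paste(unlist(man$stage_counts[[k]]), collapse = ","))
               }, character(1)),
               vapply(names(man$checksums), function(k) {
                 paste0("md5:", basename(names(man$checksums[[k]]) %||% k),
                        "\t", man$checksums[[k]])
               }, character(1))),
             mp)
  paths[["manifest"]] <- mp
  invisible(paths)
}
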