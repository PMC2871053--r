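# Seeded synthetic-data generator: a toy genome with planted features, a
# matching reference bundle, and paired nuclear/cytoplasmic read libraries
# with per-sequence ground truth, so every pipeline stage can be validated
# against known answers.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe two libraries of 16-30 nt reads drawn from planted
#' miRNA, tRNA, tRNA-trailer, snoRNA, scaRNA, snRNA, mitochondrial, rRNA
#' (with ITS/ETS spacers), mRNA, repeat and intergenic sources, with
#' per-feature compartment mixing ratios, isomiR 3'-end heterogeneity,
#' CCA-tailed tRNA fragments, single-mismatch tRNA reads, 3' untemplated
#' additions, ligated 3' adapters, and poly-A / 5'-adapter contaminants.
#' Class mixing ratios follow the qualitative compartment biology the design
#' emulates: box C/D snoRNA and ETS strongly nuclear, mitochondrial RNA and
#' tRNA trailers strongly cytoplasmic, miRNAs near parity.
#'
#' @param seed Integer seed; same config + seed gives identical output.
#' @param genome_size Main chromosome length in nt (error if the planted
#'   features do not fit).
#' @param depth Named expected read depths per library.
#' @param ... Overrides for any default listed below.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_size = 50000L,
                       depth = c(nuclear = 1e5, cytoplasmic = 1e5), ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_size = as.integer(genome_size),
    mito_size = 2000L,
    depth = depth,
    n_mirna = 8L, n_trna = 6L, n_cd = 2L, n_haca = 2L, n_scarna = 2L,
    n_snrna = 2L, n_mrna = 3L, n_repeat_loci = 3L, n_mito_rna = 3L,
    n_unknown = 4L,
    rrna_segments = c(ETS5 = 150L, S18 = 300L, ITS1 = 150L, S58 = 120L,
                      ITS2 = 150L, S28 = 400L, ETS3 = 150L),
    class_nc = c("miRNA" = 1.5, "mitochondrial RNA" = 0.08, "rRNA" = 0.6,
                 "ITS" = 2, "ETS" = 8, "box H/ACA snoRNA" = 4,
                 "box C/D snoRNA" = 40, "scaRNA" = 2, "tRNA" = 0.25,
                 "snRNA" = 1.2, "mRNA" = 1.5, "tRNA 3' trailer" = 0.05,
                 "genomic repeat" = 0.6, "unknown" = 0.6),
    class_weights = c("miRNA" = 0.50, "tRNA" = 0.12, "rRNA" = 0.08,
                      "mitochondrial RNA" = 0.08, "tRNA 3' trailer" = 0.04,
                      "mRNA" = 0.06, "snRNA" = 0.01, "box C/D snoRNA" = 0.02,
                      "box H/ACA snoRNA" = 0.01, "scaRNA" = 0.01,
                      "ITS" = 0.005, "ETS" = 0.01, "genomic repeat" = 0.03,
                      "unknown" = 0.025),
    ratio_jitter_sd = 0.5,
    isomir_offset_probs = c("-2" = 0.05, "-1" = 0.15, "0" = 0.60,
                            "1" = 0.15, "2" = 0.05),
    untemplated_rate = 0.05,
    tail_len_probs = c(0.6, 0.3, 0.1),
    cca_rate = 0.15, mismatch_rate = 0.05,
    trailer_len_probs = c("17" = 0.25, "18" = 0.50, "19" = 0.25),
    trailer_offset2_prob = 0.15,
    utail_gene_frac = 0.8,
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    polya_rate = 0.003, adapter5_rate = 0.003, no_adapter_rate = 0.004,
    read_len = 35L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(all(cfg$depth > 0))
  structure(cfg, class = "sim_config")
}

# Random DNA avoiding 'TT' anywhere (used for trailer regions of genes
# planted without a U-tail, so the U-tail call is exactly recoverable).
.random_dna_no_tt <- function(n) {
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    alpha <- if (prev == "T") c("A", "C", "G") else c("A", "C", "G", "T")
    out[i] <- sample(alpha, 1)
    prev <- out[i]
  }
  paste(out, collapse = "")
}

#' Simulate a reference bundle with planted features
#'
#' Builds a random genome hosting non-overlapping planted features: miRNA
#' hairpins with designated mature arms, tRNA genes (alternating strands)
#' each followed by a designed 40-nt trailer region whose planted trailer
#' does or does not end in a uridine stretch, box C/D and H/ACA snoRNAs,
#' scaRNAs (one ACA45-like), snRNAs, multi-exon mRNA gene models, repeated
#' copies of one repeat unit, a mitochondrial contig with transcript
#' references, and an rRNA transcription unit (ETS-18S-ITS1-5.8S-ITS2-28S-ETS)
#' that is deliberately absent from the genome assembly so rRNA-derived reads
#' exercise the rescue stage. Intergenic windows are recorded as sources of
#' "unknown" reads.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (a [reference_bundle()]) and `truth` (feature
#'   table, mature-miRNA catalog, hairpin sequences, trailer truth, unknown
#'   windows, repeat unit, config).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    blocks <- list()   # list of (seq, type, payload)
    add_block <- function(seq, meta) {
      blocks[[length(blocks) + 1]] <<- c(list(seq = seq), meta)
    }
    gap <- function() random_dna(sample(60:150, 1))

    features <- list()
    mirna_catalog <- list()
    hairpins <- character(0)
    trailer_truth <- list()
    ref_rnas <- list()
    add_ref <- function(class, ref_id, seq) {
      ref_rnas[[length(ref_rnas) + 1]] <<- data.frame(
        class = class, ref_id = ref_id, seq = seq, stringsAsFactors = FALSE)
    }

    # miRNA hairpins: 22-nt mature 5' arm + loop + reverse-complement arm
    for (i in seq_len(config$n_mirna)) {
      arm <- random_dna(22)
      hp <- paste0(arm, random_dna(16), rc_seq(arm))
      hid <- sprintf("hairpin-%d", i)
      hairpins[[hid]] <- hp
      mirna_catalog[[i]] <- data.frame(mirna_id = sprintf("mir-%d", i),
                                       hairpin_id = hid, start = 1L, end = 22L,
                                       stringsAsFactors = FALSE)
      add_ref("miRNA", hid, hp)
      add_block(hp, list(type = "miRNA", id = hid, strand = "+"))
    }

    # tRNA genes with designed trailer regions; alternate strands
    for (i in seq_len(config$n_trna)) {
      trna <- random_dna(72)
      u_tail <- i <= round(config$utail_gene_frac * config$n_trna)
      region <- if (u_tail) {
        paste0(.random_dna_no_tt(15), "TTTT", .random_dna_no_tt(21))
      } else {
        .random_dna_no_tt(40)
      }
      # CCA-tailed fragments must stay non-genomic
      if (startsWith(region, "CCA")) {
        region <- paste0("GA", substr(region, 3, 40))
      }
      strand <- if (i %% 2 == 1) "+" else "-"
      tid <- sprintf("tRNA-%d", i)
      add_ref("tRNA", tid, trna)
      seq <- if (strand == "+") paste0(trna, region)
             else paste0(rc_seq(region), rc_seq(trna))
      add_block(seq, list(type = "tRNA", id = tid, strand = strand,
                          trna_len = 72L, region_len = 40L))
      trailer_truth[[i]] <- data.frame(trna_name = tid, region_seq = region,
                                       u_tail = u_tail, strand = strand,
                                       stringsAsFactors = FALSE)
    }

    plant_simple <- function(n, len, class, prefix) {
      for (i in seq_len(n)) {
        s <- random_dna(len)
        id <- sprintf("%s-%d", prefix, i)
        if (prefix == "scaRNA" && i == 1) id <- "ACA45"
        add_ref(class, id, s)
        add_block(s, list(type = class, id = id, strand = "+"))
      }
    }
    plant_simple(config$n_cd, 80, "box C/D snoRNA", "snoCD")
    plant_simple(config$n_haca, 130, "box H/ACA snoRNA", "snoHACA")
    plant_simple(config$n_scarna, 140, "scaRNA", "scaRNA")
    plant_simple(config$n_snrna, 150, "snRNA", "snRNA")

    # multi-exon mRNA gene models (3 exons of 150 nt, 120-nt introns)
    for (i in seq_len(config$n_mrna)) {
      ex <- replicate(3, random_dna(150))
      intr <- replicate(2, random_dna(120))
      gid <- sprintf("gene-%d", i)
      add_block(paste0(ex[1], intr[1], ex[2], intr[2], ex[3]),
                list(type = "mRNA", id = gid, strand = "+",
                     exon_len = c(150L, 150L, 150L), intron_len = c(120L, 120L)))
    }

    # one repeat unit planted at several loci
    repeat_unit <- random_dna(200)
    for (i in seq_len(config$n_repeat_loci)) {
      add_block(repeat_unit, list(type = "repeat", id = sprintf("rep-%d", i),
                                  strand = "+"))
    }

    # assemble chr1 with random gaps; record intergenic "unknown" windows
    chr1 <- character(0)
    pos <- 0L
    unknown_windows <- list()
    feature_rows <- list()
    trna_loci <- list(); repeat_loci <- list(); mrna_models <- list()
    for (b in blocks) {
      g <- gap()
      if (length(unknown_windows) < config$n_unknown && nchar(g) >= 80) {
        unknown_windows[[length(unknown_windows) + 1]] <-
          data.frame(chrom = "chr1", start = pos + 11L, end = pos + 70L,
                     seq = substr(g, 11, 70), stringsAsFactors = FALSE)
      }
      chr1 <- c(chr1, g); pos <- pos + nchar(g)
      start <- pos + 1L
      chr1 <- c(chr1, b$seq); pos <- pos + nchar(b$seq)
      end <- pos
      feature_rows[[length(feature_rows) + 1]] <- data.frame(
        feature_id = b$id, class = b$type, chrom = "chr1",
        start = start, end = end, strand = b$strand, stringsAsFactors = FALSE)
      if (b$type == "tRNA") {
        if (b$strand == "+") {
          trna_loci[[length(trna_loci) + 1]] <- data.frame(
            chrom = "chr1", start = start, end = start + b$trna_len - 1L,
            strand = "+", name = b$id, stringsAsFactors = FALSE)
        } else {
          trna_loci[[length(trna_loci) + 1]] <- data.frame(
            chrom = "chr1", start = start + b$region_len,
            end = end, strand = "-", name = b$id, stringsAsFactors = FALSE)
        }
      }
      if (b$type == "repeat") {
        repeat_loci[[length(repeat_loci) + 1]] <- data.frame(
          chrom = "chr1", start = start, end = end, strand = "+",
          family = "SimRep", stringsAsFactors = FALSE)
      }
      if (b$type == "mRNA") {
        s <- start
        exs <- list()
        for (j in seq_along(b$exon_len)) {
          exs[[j]] <- data.frame(chrom = "chr1", start = s,
                                 end = s + b$exon_len[j] - 1L, strand = "+",
                                 stringsAsFactors = FALSE)
          s <- s + b$exon_len[j] + if (j <= length(b$intron_len)) b$intron_len[j] else 0L
        }
        mrna_models[[b$id]] <- do.call(rbind, exs)
      }
    }
    chr1 <- paste(c(chr1, gap()), collapse = "")
    if (nchar(chr1) > config$genome_size) {
      stop("genome too small to place features: need ", nchar(chr1),
           " nt, genome_size is ", config$genome_size)
    }
    chr1 <- paste0(chr1, random_dna(config$genome_size - nchar(chr1)))

    chrM <- random_dna(config$mito_size)
    mito_bounds <- list(c(1, 600), c(700, 1300), c(1400, 1950))
    for (i in seq_len(min(config$n_mito_rna, length(mito_bounds)))) {
      bd <- mito_bounds[[i]]
      add_ref("mitochondrial RNA", sprintf("mito-%d", i),
              substr(chrM, bd[1], bd[2]))
    }

    # rRNA transcription unit: references only, absent from the assembly
    segs <- lapply(config$rrna_segments, random_dna)
    add_ref("rRNA", "rRNA-18S", segs$S18)
    add_ref("rRNA", "rRNA-5.8S", segs$S58)
    add_ref("rRNA", "rRNA-28S", segs$S28)
    add_ref("ITS", "ITS1", segs$ITS1)
    add_ref("ITS", "ITS2", segs$ITS2)
    add_ref("ETS", "ETS5", segs$ETS5)
    add_ref("ETS", "ETS3", segs$ETS3)

    genome <- c(chr1 = chr1, chrM = chrM)
    bundle <- reference_bundle(
      genome,
      do.call(rbind, ref_rnas),
      trna_loci = do.call(rbind, trna_loci),
      mrna_models = mrna_models,
      repeat_loci = do.call(rbind, repeat_loci))

    truth <- list(
      features = do.call(rbind, feature_rows),
      mirna_catalog = do.call(rbind, mirna_catalog),
      hairpins = hairpins,
      trailer_truth = do.call(rbind, trailer_truth),
      unknown_windows = do.call(rbind, unknown_windows),
      repeat_unit = repeat_unit,
      config = config)
    list(bundle = bundle, truth = truth)
  })
}

# Sample a window (sub-sequence) of length in len_range from seq.
.window <- function(seq, len_range = c(18, 26)) {
  L <- nchar(seq)
  lens <- seq(len_range[1], min(len_range[2], L))
  len <- if (length(lens) == 1) lens else sample(lens, 1)
  s <- sample.int(L - len + 1, 1)
  substr(seq, s, s + len - 1)
}

#' Simulate paired nuclear and cytoplasmic read libraries
#'
#' Draws reads per planted feature with planted compartment mixing ratios
#' (per-feature expected N:C RPM ratio = the class ratio times a log-normal
#' jitter; read counts are Poisson at the configured depths, with each
#' library's expected totals scaled to its depth). Sequence-level structure
#' follows the feature class: isomiR 3'-end offsets for miRNAs plus optional
#' untemplated tails that break the genomic match beyond the anchored prefix,
#' tRNA internal fragments plus CCA-tailed 3' fragments and single-mismatch
#' variants, trailer-region prefixes at start offsets 1/2, and plain windows
#' for the remaining classes. The 3' adapter is appended (reads fixed at
#' `read_len` nt) and poly-A, 5'-adapter and adapter-less contaminants are
#' injected at the configured rates.
#'
#' @param bundle,truth Output of [simulate_reference()].
#' @param config The same [sim_config()].
#' @return List with `reads` (data.frame `read`, `count`, `library`) and
#'   `truth_seq` (per-insert ground truth: `sequence`, `feature_id`, `class`,
#'   `planted_nc`, `expected_nuclear`, `expected_cytoplasmic`).
#' @export
simulate_libraries <- function(bundle, truth, config) {
  with_seed(config$seed + 1L, {
    rows <- list()
    add_variant <- function(feature_id, class, insert, vw) {
      rows[[length(rows) + 1]] <<- data.frame(
        feature_id = feature_id, class = class, sequence = insert,
        vweight = vw, stringsAsFactors = FALSE)
    }

    genome <- bundle$genome
    feats <- truth$features

    # miRNA isomiR families
    offs <- as.integer(names(config$isomir_offset_probs))
    for (hid in names(truth$hairpins)) {
      hp <- truth$hairpins[[hid]]
      cat_row <- truth$mirna_catalog[truth$mirna_catalog$hairpin_id == hid, ]
      for (k in seq_along(offs)) {
        len <- cat_row$end + offs[k]
        v <- substr(hp, cat_row$start, len)
        w <- config$isomir_offset_probs[k]
        if (config$untemplated_rate > 0) {
          tl <- sample(seq_along(config$tail_len_probs), 1,
                       prob = config$tail_len_probs)
          # first tail base must not extend the genomic match on either
          # strand of the hairpin locus
          blocked <- Filter(function(b) {
            grepl(paste0(v, b), hp, fixed = TRUE) ||
              grepl(rc_seq(paste0(v, b)), hp, fixed = TRUE)
          }, c("A", "C", "G", "T"))
          first <- sample(setdiff(c("A", "C", "G", "T"), blocked), 1)
          tail <- paste0(first, if (tl > 1) random_dna(tl - 1) else "")
          add_variant(hid, "miRNA", paste0(v, tail),
                      w * config$untemplated_rate)
          w <- w * (1 - config$untemplated_rate)
        }
        add_variant(hid, "miRNA", v, w)
      }
    }

    # tRNA fragments: internal windows, CCA-tailed 3' fragments, 1-mm reads
    trna_refs <- bundle$ref_rnas[bundle$ref_rnas$class == "tRNA", ]
    for (i in seq_len(nrow(trna_refs))) {
      ts <- trna_refs$seq[i]; tid <- trna_refs$ref_id[i]
      w_frag <- 1 - config$cca_rate - config$mismatch_rate
      frs <- unique(replicate(3, .window(ts, c(16, 26))))
      for (fr in frs) add_variant(tid, "tRNA", fr, w_frag / length(frs))
      if (config$cca_rate > 0) {
        cca <- paste0(substr(ts, nchar(ts) - 16, nchar(ts)), "CCA")
        add_variant(tid, "tRNA", cca, config$cca_rate)
      }
      if (config$mismatch_rate > 0) {
        wv <- .window(ts, c(20, 20))
        b <- substr(wv, 10, 10)
        substr(wv, 10, 10) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        add_variant(tid, "tRNA", wv, config$mismatch_rate)
      }
    }

    # tRNA 3' trailers: region prefixes at offsets 1 and 2
    tt <- truth$trailer_truth
    for (i in seq_len(nrow(tt))) {
      lens <- as.integer(names(config$trailer_len_probs))
      p2 <- config$trailer_offset2_prob
      for (k in seq_along(lens)) {
        add_variant(tt$trna_name[i], "tRNA 3' trailer",
                    substr(tt$region_seq[i], 1, lens[k]),
                    config$trailer_len_probs[k] * (1 - p2))
      }
      if (p2 > 0) {
        add_variant(tt$trna_name[i], "tRNA 3' trailer",
                    substr(tt$region_seq[i], 2, 19), p2)
      }
    }

    # window-sampled classes from their reference sequences
    window_class <- function(class, n_windows = 3) {
      refs <- bundle$ref_rnas[bundle$ref_rnas$class == class, ]
      for (i in seq_len(nrow(refs))) {
        ws <- unique(replicate(n_windows, .window(refs$seq[i])))
        for (wv in ws) add_variant(refs$ref_id[i], class, wv, 1 / length(ws))
      }
    }
    for (cl in c("box C/D snoRNA", "box H/ACA snoRNA", "scaRNA", "snRNA",
                 "mitochondrial RNA", "rRNA", "ITS", "ETS")) {
      window_class(cl)
    }

    # mRNA: windows of the spliced transcript plus a forced junction-spanning
    # read per gene
    tx <- spliced_transcripts(bundle)
    for (gid in names(tx)) {
      ws <- unique(replicate(3, .window(tx[[gid]])))
      for (wv in ws) add_variant(gid, "mRNA", wv, 0.8 / length(ws))
      jstart <- 150 - 8  # span the first junction by >= 8 nt each side
      add_variant(gid, "mRNA", substr(tx[[gid]], jstart, jstart + 18), 0.2)
    }

    # repeats: windows of the shared unit (multi-locus genomic hits)
    reps <- unique(replicate(4, .window(truth$repeat_unit)))
    for (wv in reps) {
      add_variant("rep-unit", "genomic repeat", wv, 1 / length(reps))
    }

    # unknown: intergenic windows
    uw <- truth$unknown_windows
    for (i in seq_len(nrow(uw))) {
      ws <- unique(replicate(2, .window(uw$seq[i], c(18, 24))))
      for (wv in ws) {
        add_variant(sprintf("intergenic-%d", i), "unknown", wv, 1 / length(ws))
      }
    }

    variants <- do.call(rbind, rows)
    # drop rare cross-feature sequence collisions (ambiguous truth)
    dup <- variants$sequence[duplicated(variants$sequence)]
    variants <- variants[!variants$sequence %in% dup, , drop = FALSE]

    # per-feature expected-RPM mixing ratio and library weights; feature
    # weights are jittered but renormalized within each class, so class
    # shares of the expected cytoplasmic pool equal the configured weights
    feats_u <- unique(variants[, c("feature_id", "class")])
    feats_u$fweight <- stats::rexp(nrow(feats_u)) + 0.25
    feats_u$fw_norm <- stats::ave(feats_u$fweight, feats_u$class,
                                  FUN = function(x) x / sum(x))
    feats_u$ratio <- config$class_nc[feats_u$class] *
      2^stats::rnorm(nrow(feats_u), 0, config$ratio_jitter_sd)
    cw <- config$class_weights / sum(config$class_weights)
    feats_u$cweight <- as.numeric(cw[feats_u$class]) * feats_u$fw_norm

    # features are keyed by (id, class): a tRNA gene and its 3' trailer are
    # distinct sources sharing the gene name
    vkey <- paste(variants$feature_id, variants$class, sep = "\r")
    fkey <- paste(feats_u$feature_id, feats_u$class, sep = "\r")
    m <- match(vkey, fkey)
    # normalize variant weights within each feature
    vw_sum <- tapply(variants$vweight, vkey, sum)
    variants$vw_norm <- variants$vweight / vw_sum[vkey]
    e_c0 <- feats_u$cweight[m] * variants$vw_norm
    e_n0 <- e_c0 * feats_u$ratio[m]
    e_c <- e_c0 / sum(e_c0) * config$depth[["cytoplasmic"]]
    e_n <- e_n0 / sum(e_n0) * config$depth[["nuclear"]]
    # expected mapped totals equal the depths, so the expected-RPM mixing
    # ratio realized after per-library scaling is the class ratio times a
    # global constant shared by all sequences
    planted_nc <- feats_u$ratio[m] * sum(e_c0) / sum(e_n0)

    n_c <- stats::rpois(length(e_c), e_c)
    n_n <- stats::rpois(length(e_n), e_n)

    truth_seq <- data.frame(sequence = variants$sequence,
                            feature_id = variants$feature_id,
                            class = variants$class,
                            planted_nc = planted_nc,
                            expected_nuclear = e_n,
                            expected_cytoplasmic = e_c,
                            stringsAsFactors = FALSE)

    mk_read <- function(ins) {
      substr(paste0(ins, config$adapter3), 1, config$read_len)
    }
    lib_reads <- function(counts, lib) {
      keep <- counts > 0
      data.frame(read = mk_read(variants$sequence[keep]),
                 count = counts[keep], library = lib,
                 stringsAsFactors = FALSE)
    }
    reads <- rbind(lib_reads(n_n, "nuclear"), lib_reads(n_c, "cytoplasmic"))

    # contaminants
    contam <- list()
    add_contam <- function(read, count, lib) {
      if (count > 0) {
        contam[[length(contam) + 1]] <<- data.frame(
          read = read, count = count, library = lib, stringsAsFactors = FALSE)
      }
    }
    for (lib in names(config$depth)) {
      d <- config$depth[[lib]]
      add_contam(mk_read(paste(rep("A", 24), collapse = "")),
                 stats::rpois(1, config$polya_rate * d), lib)
      ad5 <- config$adapter5
      a5ins <- paste0(substr(ad5, nchar(ad5) - 11, nchar(ad5)), random_dna(10))
      add_contam(mk_read(a5ins), stats::rpois(1, config$adapter5_rate * d), lib)
      n_na <- stats::rpois(1, config$no_adapter_rate * d)
      if (n_na > 0) {
        repeat {
          r <- random_dna(config$read_len)
          if (is.na(trim_3prime_adapter(r, config$adapter3)[1])) break
        }
        add_contam(r, n_na, lib)
      }
    }
    if (length(contam) > 0) reads <- rbind(reads, do.call(rbind, contam))
    rownames(reads) <- NULL
    list(reads = reads, truth_seq = truth_seq)
  })
}

#' Run a complete seeded simulation
#'
#' Convenience wrapper: [simulate_reference()] then [simulate_libraries()].
#'
#' @param config A [sim_config()].
#' @return List with `bundle`, `truth`, `reads`, `truth_seq`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  lib <- simulate_libraries(ref$bundle, ref$truth, config)
  list(bundle = ref$bundle, truth = ref$truth,
       reads = lib$reads, truth_seq = lib$truth_seq)
}

#' Write a simulated experiment to disk
#'
#' Emits the genome FASTA, the class-labeled reference FASTA, a GFF3 locus
#' file, one collapsed FASTA per library (`count=` header keys), the
#' per-sequence ground-truth TSV, and the resolved configuration.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             rnas = file.path(dir, "reference_rnas.fa"),
             loci = file.path(dir, "loci.gff3"),
             truth = file.path(dir, "truth_sequences.tsv"),
             config = file.path(dir, "sim_config.txt"))
  g <- Biostrings::DNAStringSet(sim$bundle$genome)
  Biostrings::writeXStringSet(g, paths[["genome"]])
  r <- Biostrings::DNAStringSet(sim$bundle$ref_rnas$seq)
  names(r) <- sprintf('%s class="%s"', sim$bundle$ref_rnas$ref_id,
                      sim$bundle$ref_rnas$class)
  Biostrings::writeXStringSet(r, paths[["rnas"]])
  .write_loci_gff3(sim$bundle, paths[["loci"]])
  for (lib in unique(sim$reads$library)) {
    p <- file.path(dir, paste0("reads_", lib, ".fa"))
    sub <- sim$reads[sim$reads$library == lib, ]
    agg <- rowsum(sub$count, sub$read)
    set <- Biostrings::DNAStringSet(rownames(agg))
    names(set) <- sprintf("%s_read%06d count=%d", lib, seq_len(nrow(agg)),
                          as.integer(agg[, 1]))
    Biostrings::writeXStringSet(set, p)
    paths[[paste0("reads_", lib)]] <- p
  }
  utils::write.table(sim$truth_seq, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(deparse(unclass(sim$truth$config)), paths[["config"]])
  invisible(paths)
}

.write_loci_gff3 <- function(bundle, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, src, type, s, e, strand, attr) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type, s, e,
            strand, attr)
  }
  tl <- bundle$trna_loci
  for (i in seq_len(if (is.null(tl)) 0 else nrow(tl))) {
    lines <- c(lines, fmt(tl$chrom[i], "sim", "tRNA", tl$start[i], tl$end[i],
                          tl$strand[i], paste0("ID=", tl$name[i])))
  }
  for (gid in names(bundle$mrna_models %||% list())) {
    ex <- bundle$mrna_models[[gid]]
    lines <- c(lines, fmt(ex$chrom[1], "sim", "mRNA", min(ex$start),
                          max(ex$end), ex$strand[1], paste0("ID=", gid)))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, fmt(ex$chrom[j], "sim", "exon", ex$start[j], ex$end[j],
                            ex$strand[j],
                            sprintf("ID=%s.e%d;Parent=%s", gid, j, gid)))
    }
  }
  rl <- bundle$repeat_loci
  for (i in seq_len(if (is.null(rl)) 0 else nrow(rl))) {
    lines <- c(lines, fmt(rl$chrom[i], "sim", "repeat_region", rl$start[i],
                          rl$end[i], rl$strand[i],
                          sprintf("ID=rep%d;family=%s", i, rl$family[i])))
  }
  writeLines(lines, path)
}
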