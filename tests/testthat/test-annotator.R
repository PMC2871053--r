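# Minimal mapped-record table for cascade tests (no genomic hits needed
# unless repeat labeling is under test).
mock_mapped <- function(seqs, counts_n = 1, counts_c = 1, hits = NULL,
                        prelabel = NA_character_) {
  n <- length(seqs)
  df <- data.frame(sequence = seqs, status = "mapped", via = "genome",
                   n_hits = 1L, matched_ref = NA_character_,
                   trimmed_tail = "", match_seq = seqs,
                   prelabel = rep(prelabel, length.out = n),
                   stringsAsFactors = FALSE)
  df$hits <- if (is.null(hits)) {
    replicate(n, data.frame(chrom = character(0), start = integer(0),
                            strand = character(0)), simplify = FALSE)
  } else hits
  df$nuclear <- rep(counts_n, length.out = n)
  df$cytoplasmic <- rep(counts_c, length.out = n)
  df
}

test_that("earlier cascade classes win: miRNA beats mRNA for shared reads", {
  withr::with_seed(301, {
    shared <- rand_dna(20)
    genome <- c(chr1 = paste0(rand_dna(30), shared, rand_dna(30)))
    refs <- data.frame(
      class = c("miRNA", "mRNA"),
      ref_id = c("mir-x", "gene-x"),
      seq = c(paste0(rand_dna(10), shared, rand_dna(10)),
              paste0(rand_dna(40), shared, rand_dna(40))),
      stringsAsFactors = FALSE)
    b <- reference_bundle(genome, refs)
    ann <- annotate_cascade(mock_mapped(shared), b, NULL,
                            libraries = c("nuclear", "cytoplasmic"))
    expect_equal(ann$records$label, "miRNA")
    expect_equal(ann$records$matched_ref, "mir-x")
  })
})

test_that("unmatched mapped sequences fall back to repeat or unknown", {
  withr::with_seed(302, {
    genome <- c(chr1 = rand_dna(400))
    refs <- data.frame(class = "miRNA", ref_id = "mir-1", seq = rand_dna(60),
                       stringsAsFactors = FALSE)
    reps <- data.frame(chrom = "chr1", start = 100, end = 180, strand = "+",
                       family = "fam", stringsAsFactors = FALSE)
    b <- reference_bundle(genome, refs, repeat_loci = reps)
    seqs <- c(substr(genome[[1]], 150, 170),  # inside the repeat locus
              substr(genome[[1]], 300, 320))  # plain genomic
    hits <- list(data.frame(chrom = "chr1", start = 150, strand = "+"),
                 data.frame(chrom = "chr1", start = 300, strand = "+"))
    ann <- annotate_cascade(mock_mapped(seqs, hits = hits), b, NULL,
                            libraries = c("nuclear", "cytoplasmic"))
    lab <- setNames(ann$records$label, ann$records$sequence)
    expect_equal(unname(lab[seqs[1]]), "genomic repeat")
    expect_equal(unname(lab[seqs[2]]), "unknown")
  })
})

test_that("tRNA label precedes the trailer class for CCA-rescued fragments", {
  # construct a trailer region that begins with a CCA-tailed tRNA fragment so
  # the read matches both the tRNA (via CCA) and the trailer region
  withr::with_seed(303, {
    trna <- rand_dna(72)
    frag <- paste0(substr(trna, 56, 72), "CCA")  # 20 nt
    region <- paste0(frag, rand_dna(20))
    genome <- c(chr1 = rand_dna(200))
    refs <- data.frame(class = "tRNA", ref_id = "tRNA-z", seq = trna,
                       stringsAsFactors = FALSE)
    b <- reference_bundle(genome, refs)
    regions <- data.frame(trna_name = "tRNA-z", chrom = "chr1", strand = "+",
                          region_seq = region, truncated = FALSE,
                          stringsAsFactors = FALSE)
    rec <- mock_mapped(frag)
    rec$via <- "tRNA-CCA"
    ann <- annotate_cascade(rec, b, regions,
                            libraries = c("nuclear", "cytoplasmic"))
    expect_equal(ann$records$label, "tRNA")
    # toggle oracle: with tRNA removed from the cascade, the same read is
    # called a trailer
    ann2 <- annotate_cascade(rec, b, regions,
                             libraries = c("nuclear", "cytoplasmic"),
                             cascade = setdiff(SEQUENCE_CLASSES, "tRNA"))
    expect_equal(ann2$records$label, "tRNA 3' trailer")
  })
})

test_that("one-mismatch-rescued records keep their tRNA pre-label", {
  withr::with_seed(304, {
    genome <- c(chr1 = rand_dna(300))
    refs <- data.frame(class = c("tRNA", "mRNA"),
                       ref_id = c("tRNA-q", "gene-q"),
                       seq = c(rand_dna(72), rand_dna(120)),
                       stringsAsFactors = FALSE)
    b <- reference_bundle(genome, refs)
    rec <- mock_mapped(rand_dna(20), prelabel = "tRNA")
    rec$via <- "tRNA-1mm"
    ann <- annotate_cascade(rec, b, NULL, libraries = c("nuclear", "cytoplasmic"))
    expect_equal(ann$records$label, "tRNA")
  })
})

test_that("class totals conserve the mapped totals and ignore input order", {
  toy <- make_toy_bundle()
  idx <- build_genome_index(toy$bundle$genome)
  aux <- build_rescue_aux(toy$bundle)
  withr::with_seed(305, {
    seqs <- c(substr(toy$trna, 10, 33), substr(toy$hairpin, 1, 22),
              substr(toy$mito_seq, 5, 26), substr(toy$rrna_seq, 50, 70),
              substr(toy$region_plus, 1, 19), substr(toy$rep_unit, 11, 30),
              substr(toy$exons[1], 20, 40))
    mp <- map_sequences(seqs, idx, aux)
    mp$nuclear <- c(5L, 10L, 2L, 8L, 1L, 4L, 3L)
    mp$cytoplasmic <- c(1L, 20L, 9L, 2L, 12L, 5L, 2L)
    regions <- build_trailer_regions(toy$bundle)
    ann <- annotate_cascade(mp, toy$bundle, regions,
                            libraries = c("nuclear", "cytoplasmic"))
    cc <- ann$class_counts
    for (lib in c("nuclear", "cytoplasmic")) {
      expect_equal(sum(cc[[lib]][cc$class != "total"]),
                   cc[[lib]][cc$class == "total"])
    }
    expect_equal(ann$records$label[ann$records$sequence == substr(toy$region_plus, 1, 19)],
                 "tRNA 3' trailer")
    expect_equal(ann$records$label[ann$records$sequence == substr(toy$rep_unit, 11, 30)],
                 "genomic repeat")
    # permuting input order leaves the result unchanged
    perm <- sample(nrow(mp))
    ann2 <- annotate_cascade(mp[perm, ], toy$bundle, regions,
                             libraries = c("nuclear", "cytoplasmic"))
    expect_identical(ann$records$label, ann2$records$label)
    expect_identical(ann$class_counts, ann2$class_counts)
  })
})

test_that("adding references to a later class never changes earlier labels", {
  withr::with_seed(306, {
    mir_seq <- rand_dna(60)
    read <- substr(mir_seq, 20, 41)
    genome <- c(chr1 = paste0(rand_dna(20), mir_seq, rand_dna(20)))
    refs1 <- data.frame(class = "miRNA", ref_id = "mir-1", seq = mir_seq,
                        stringsAsFactors = FALSE)
    b1 <- reference_bundle(genome, refs1)
    ann1 <- annotate_cascade(mock_mapped(read), b1, NULL,
                             libraries = c("nuclear", "cytoplasmic"))
    # add an mRNA reference that also contains the read
    refs2 <- rbind(refs1, data.frame(class = "mRNA", ref_id = "gene-1",
                                     seq = paste0(rand_dna(30), read,
                                                  rand_dna(30))))
    b2 <- reference_bundle(genome, refs2)
    ann2 <- annotate_cascade(mock_mapped(read), b2, NULL,
                             libraries = c("nuclear", "cytoplasmic"))
    expect_equal(ann1$records$label, ann2$records$label)
    expect_equal(ann1$records$matched_ref, ann2$records$matched_ref)
  })
})

test_that("composition percentages follow the print rule and error on zero totals", {
  cc <- data.frame(class = c("total", "miRNA", "rest"),
                   nuclear = c(1000, 1000, 0),
                   cytoplasmic = c(2000, 500, 1500), stringsAsFactors = FALSE)
  tab <- composition_table(cc)
  expect_equal(tab$nuclear_pct[tab$class == "miRNA"], 100.0)
  expect_equal(tab$cytoplasmic_pct[tab$class == "miRNA"], 25.0)
  cc0 <- cc; cc0$nuclear[1] <- 0
  expect_error(composition_table(cc0), "zero")
})
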