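test_that("exact mapping finds planted sequences with correct strand", {
  withr::with_seed(201, {
    q <- rand_dna(20)
    genome <- c(chr1 = paste0(rand_dna(100), q, rand_dna(80)))
    idx <- build_genome_index(genome)
    h <- map_exact_all(q, idx)
    expect_equal(nrow(h), 1)
    expect_equal(h$start, 101)
    expect_equal(h$strand, "+")
    # reverse complement hits the same locus on the minus strand
    h2 <- map_exact_all(oracle_rc(q), idx)
    expect_equal(nrow(h2), 1)
    expect_equal(h2$start, 101)
    expect_equal(h2$strand, "-")
    # strand-corrected re-extraction reproduces the query
    span <- substr(genome[["chr1"]], h2$start, h2$start + nchar(q) - 1)
    expect_equal(oracle_rc(span), oracle_rc(q))
  })
})

test_that("multi-locus sequences report every hit, matching the naive scan", {
  withr::with_seed(202, {
    q <- rand_dna(18)
    genome <- c(chr1 = paste0(rand_dna(50), q, rand_dna(40), q, rand_dna(30)),
                chr2 = paste0(rand_dna(20), oracle_rc(q), rand_dna(25)))
    idx <- build_genome_index(genome)
    got <- map_exact_all(q, idx)
    expect_equal(nrow(got), 3)
    expect_identical(got, oracle_scan(q, genome))
  })
})

test_that("exact mapping equals the naive both-strand scan on random genomes", {
  withr::with_seed(203, {
    for (rep in 1:5) {
      genome <- c(chrA = rand_dna(sample(2000:8000, 1)),
                  chrB = rand_dna(sample(500:2000, 1)))
      idx <- build_genome_index(genome)
      queries <- c(
        vapply(1:4, function(i) {  # planted
          s <- sample(1000, 1)
          substr(genome[["chrA"]], s, s + sample(16:28, 1))
        }, character(1)),
        vapply(1:3, function(i) rand_dna(sample(16:28, 1)), character(1)),
        oracle_rc(substr(genome[["chrB"]], 101, 120)))
      for (q in queries) {
        expect_identical(map_exact_all(q, idx), oracle_scan(q, genome))
      }
    }
  })
})

test_that("rescue stages fire in order with correct via tags", {
  toy <- make_toy_bundle()
  aux <- build_rescue_aux(toy$bundle)
  # rRNA window (reference-only sequence, absent from the genome)
  r <- rescue_unmapped(substr(toy$rrna_seq, 30, 50), aux)
  expect_equal(r$via, "rRNA")
  expect_equal(r$matched_ref, "rRNA-1")
  # read spanning an exon-exon boundary by 8 nt each side
  tx <- spliced_transcripts(toy$bundle)[["gene-1"]]
  jread <- substr(tx, 60 - 7, 60 + 8)
  r <- rescue_unmapped(jread, aux)
  expect_equal(r$via, "junction")
  # last 17 tRNA nt + CCA
  cca_read <- paste0(substr(toy$trna, 56, 72), "CCA")
  r <- rescue_unmapped(cca_read, aux)
  expect_equal(r$via, "tRNA-CCA")
  # tRNA substring with one internal substitution
  w <- substr(toy$trna, 21, 40)
  sub1 <- w
  substr(sub1, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(w, 10, 10))[1]
  r <- rescue_unmapped(sub1, aux)
  expect_equal(r$via, "tRNA-1mm")
  expect_equal(r$prelabel, "tRNA")
  expect_equal(oracle_min_mismatch(sub1, toy$trna), 1)
  # two substitutions are not rescued
  sub2 <- sub1
  substr(sub2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(sub1, 3, 3))[1]
  expect_null(rescue_unmapped(sub2, aux))
  expect_equal(oracle_min_mismatch(sub2, toy$trna), 2)
})

test_that("disabling later rescue stages never changes earlier outcomes", {
  toy <- make_toy_bundle()
  aux <- build_rescue_aux(toy$bundle)
  rr_read <- substr(toy$rrna_seq, 30, 50)
  tx <- spliced_transcripts(toy$bundle)[["gene-1"]]
  jread <- substr(tx, 60 - 7, 60 + 8)
  cases <- list(c(seq = rr_read, stage = 1), c(seq = jread, stage = 2),
                c(seq = paste0(substr(toy$trna, 56, 72), "CCA"), stage = 3))
  for (case in cases) {
    k <- as.integer(case[["stage"]])
    full <- rescue_unmapped(case[["seq"]], aux)
    ablated <- rescue_unmapped(case[["seq"]], aux,
                               stages = seq_len(k))  # stages > k disabled
    expect_identical(full, ablated)
  }
})

test_that("untemplated 3' trimming returns the longest genomic prefix", {
  withr::with_seed(204, {
    genome <- c(chr1 = rand_dna(4000))
    idx <- build_genome_index(genome)
    prefix <- substr(genome[["chr1"]], 501, 520)  # 20-nt genomic prefix
    nxt <- substr(genome[["chr1"]], 521, 521)
    tail_base <- setdiff(c("A", "C", "G", "T"), nxt)[1]
    seq <- paste0(prefix, tail_base, "T")
    t <- trim_untemplated_3prime(seq, idx)
    expect_equal(t$prefix, prefix)
    expect_equal(t$tail, paste0(tail_base, "T"))
    expect_equal(oracle_longest_prefix(seq, genome), 20)
    # prefix retained satisfies exact mapping; the original never does
    expect_gt(nrow(map_exact_all(t$prefix, idx)), 0)
    expect_equal(nrow(map_exact_all(seq, idx)), 0)
    # 16-nt longest prefix is below the 17-nt floor
    prefix16 <- substr(genome[["chr1"]], 801, 816)
    nxt <- substr(genome[["chr1"]], 817, 817)
    b <- setdiff(c("A", "C", "G", "T"), nxt)[1]
    short <- paste0(prefix16, b, rand_dna(4))
    expect_equal(oracle_longest_prefix(short, genome), 16)
    expect_null(trim_untemplated_3prime(short, idx))
    # fully genomic sequences are not trimmed (precondition case)
    expect_null(trim_untemplated_3prime(substr(genome[["chr1"]], 101, 125), idx))
  })
})

test_that("every sequence ends mapped or unmapped, with hits verifiable", {
  toy <- make_toy_bundle()
  idx <- build_genome_index(toy$bundle$genome)
  aux <- build_rescue_aux(toy$bundle)
  withr::with_seed(205, {
    seqs <- c(substr(toy$trna, 10, 30),        # genomic
              substr(toy$rrna_seq, 10, 30),    # rescue
              paste0(substr(toy$hairpin, 1, 20), "GGGG"),  # likely trimmed
              rand_dna(24))                    # unmapped (almost surely)
    res <- map_sequences(seqs, idx, aux)
    expect_true(all(res$status %in% c("mapped", "unmapped")))
    expect_equal(res$status[1:3], rep("mapped", 3))
    expect_equal(res$via[2], "rRNA")
    # trimmed record: match_seq maps, original does not
    tr <- res[res$via == "trimmed", ]
    if (nrow(tr) > 0) {
      expect_gt(nrow(map_exact_all(tr$match_seq[1], idx)), 0)
      expect_equal(nrow(map_exact_all(tr$sequence[1], idx)), 0)
      expect_equal(paste0(tr$match_seq[1], tr$trimmed_tail[1]), tr$sequence[1])
    }
  })
})
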