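test_that("RPM normalization is exact and rejects zero totals", {
  expect_equal(rpm_normalize(5321867, 5321867), 1e6)
  expect_equal(rpm_normalize(0, 100), 0)
  expect_equal(round(rpm_normalize(6295, 5321867), 1), 1182.9)
  expect_error(rpm_normalize(10, 0), "positive")
})

test_that("N/C ratios reproduce the published miRNA worked examples", {
  tab <- read.delim(example_path("example_mirna_abundance.tsv"))
  nc <- nc_ratio(tab$nuclear_rpm, tab$cytoplasmic_rpm)
  got <- round(nc$nc, 2)
  expect_equal(got, c(6.24, 4.87, 4.54, 3.72, 3.47, 3.22, 2.89, 2.84, 2.75,
                      2.65))
  expect_true(all(nc$flag == "both"))
})

test_that("exclusivity is a flag, not a number, and both-zero errors", {
  r <- nc_ratio(c(12, 0, 3), c(0, 5, 4))
  expect_equal(r$flag, c("nuclear-only", "cytoplasmic-only", "both"))
  expect_true(is.na(r$nc[1]) && is.na(r$nc[2]))
  expect_equal(r$nc[3], 0.75)
  expect_error(nc_ratio(0, 0), "both")
})

test_that("N/C is scale-invariant and monotone in nuclear abundance", {
  withr::with_seed(501, {
    n <- runif(50, 1, 1000); c <- runif(50, 1, 1000)
    base <- nc_ratio(n, c)$nc
    scaled <- nc_ratio(n * 7.3, c * 7.3)$nc
    expect_equal(base, scaled)
    ord <- nc_ratio(sort(n), rep(100, 50))$nc
    expect_true(all(diff(ord) > 0))
  })
})

test_that("nc_summary computes in-range and exclusivity fractions", {
  rec <- data.frame(
    sequence = paste0("s", 1:4),
    nc = c(0.5, 1, 10, NA),
    nc_flag = c("both", "both", "both", "nuclear-only"),
    eligible = TRUE, stringsAsFactors = FALSE)
  s <- nc_summary(rec)
  expect_equal(s$fraction_in_range, 0.5)
  expect_equal(s$fraction_nuclear_only, 0.25)
  expect_equal(s$fraction_cytoplasmic_only, 0)
  rec2 <- data.frame(sequence = "s", nc = NA, nc_flag = "nuclear-only",
                     eligible = TRUE, stringsAsFactors = FALSE)
  s2 <- nc_summary(rec2)
  expect_equal(s2$fraction_in_range, 0)
  expect_equal(s2$fraction_nuclear_only, 1)
  expect_error(nc_summary(rec[rec$eligible == FALSE, ]), "eligible")
})

test_that("nc_table eligibility uses strict raw counts, not RPM", {
  rec <- data.frame(sequence = c("A1", "A2", "A3"),
                    nuclear = c(11L, 10L, 0L), cytoplasmic = c(0L, 10L, 500L),
                    stringsAsFactors = FALSE)
  # wildly different totals so RPM would give a different answer
  tab <- nc_table(rec, c(nuclear = 100, cytoplasmic = 1e6))
  expect_equal(tab$eligible, c(TRUE, FALSE, TRUE))
  expect_equal(tab$nc_flag, c("nuclear-only", "both", "cytoplasmic-only"))
})

test_that("isomiR groups pick per-library representatives and flag discordance", {
  hairpins <- c("hp1" = paste0("ACGTACGTACGTACGTACGTAC",
                               "GGGTTTCCCAAAGGGTT",
                               "GTACGCTACGTACGTACGTACG"))
  catalog <- data.frame(mirna_id = "mir-1", hairpin_id = "hp1",
                        start = 1, end = 22, stringsAsFactors = FALSE)
  mk <- function(seqs, n_counts, c_counts) {
    data.frame(sequence = seqs, match_seq = seqs, matched_ref = "hp1",
               label = "miRNA", nuclear = n_counts, cytoplasmic = c_counts,
               stringsAsFactors = FALSE)
  }
  # concordant group: same argmax in both libraries
  rec <- mk(c(substr(hairpins[[1]], 1, 22), substr(hairpins[[1]], 1, 20)),
            c(50L, 3L), c(40L, 5L))
  g <- group_isomirs(rec, catalog, hairpins, c("nuclear", "cytoplasmic"))
  expect_equal(nrow(g), 1)
  expect_false(g$discordant)
  expect_equal(g$nuclear_rep_seq, substr(hairpins[[1]], 1, 22))
  expect_equal(g$nuclear_rep_count, 50L)
  # discordant: different argmax per library
  rec2 <- mk(c(substr(hairpins[[1]], 1, 22), substr(hairpins[[1]], 1, 20)),
             c(50L, 3L), c(5L, 40L))
  g2 <- group_isomirs(rec2, catalog, hairpins, c("nuclear", "cytoplasmic"))
  expect_true(g2$discordant)
  # tie: lexicographically smallest sequence wins
  s1 <- substr(hairpins[[1]], 1, 22); s2 <- substr(hairpins[[1]], 2, 23)
  rec3 <- mk(c(s1, s2), c(10L, 10L), c(10L, 10L))
  g3 <- group_isomirs(rec3, catalog, hairpins, c("nuclear", "cytoplasmic"))
  expect_equal(g3$nuclear_rep_seq, min(s1, s2))
})

test_that("correlation matches closed forms and recovers planted correlation", {
  expect_equal(mirna_correlation(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4)), 1.0)
  expect_equal(mirna_correlation(c(1, 2), c(2, 1)), 1.0)  # two points
  expect_error(mirna_correlation(1, 2), "at least 2")
  expect_error(mirna_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  withr::with_seed(502, {
    rho <- 0.9; n <- 300
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r2 <- mirna_correlation(x, y)
    se_r2 <- 2 * rho * (1 - rho^2) / sqrt(n)  # delta-method SE of r^2
    expect_lt(abs(r2 - rho^2), 3 * se_r2)
  })
})

test_that("hexamer extraction matches the published 3' ends", {
  expect_equal(hexamer_extract("UAGCACCAUUUGAAAUCAGUGUU"), "AGUGUU")
  expect_equal(hexamer_extract("UCAGUGCACUACAGAACUUUGU"), "CUUUGU")
  expect_error(hexamer_extract("ACGUA"), "shorter")
})

test_that("motif association separates planted carrier enrichment", {
  rec <- data.frame(
    sequence = c("AAACCCGGGAGTGTT", "CCCGGGAAAAGTGTT",
                 "AAACCCGGGTTTCCC", "GGGTTTAAACCCGGG"),
    nc = c(4.5, 4.4, 1.0, 0.9),
    eligible = TRUE, stringsAsFactors = FALSE)
  a <- motif_nc_association(rec, "AGUGUU")
  expect_equal(a$n_with, 2)
  expect_equal(a$n_without, 2)
  expect_gte(a$median_ratio, 4.5)
  # single carrier reported as non-enriched (the miR-92b* style case)
  rec2 <- data.frame(sequence = c("AAACCCGGGAGTGTT", "GGGTTTAAACCCGGG"),
                     nc = c(0.84, 1.0), eligible = TRUE,
                     stringsAsFactors = FALSE)
  a2 <- motif_nc_association(rec2, "AGUGUU")
  expect_equal(a2$n_with, 1)
  expect_lt(a2$median_nc_with, 1)
  withr::with_seed(503, {
    # planted 5x carrier effect recovered in the median ratio
    carriers <- data.frame(
      sequence = vapply(1:40, function(i) paste0(rand_dna(14), "AGTGTT"),
                        character(1)),
      nc = 5 * exp(rnorm(40, 0, 0.3)), eligible = TRUE)
    others <- data.frame(
      sequence = vapply(1:40, function(i) paste0(rand_dna(14), "CCCAAA"),
                        character(1)),
      nc = exp(rnorm(40, 0, 0.3)), eligible = TRUE)
    a3 <- motif_nc_association(rbind(carriers, others), "AGUGUU")
    expect_gt(a3$median_ratio, 2.5)
    expect_lt(a3$median_ratio, 10)
    expect_lt(a3$wilcox_p, 0.01)
  })
})

test_that("length distributions recover planted modes and warn when empty", {
  rec <- data.frame(sequence = c(strrep("A", 22), strrep("C", 22),
                                 strrep("G", 19)),
                    label = c("miRNA", "miRNA", "tRNA 3' trailer"),
                    nuclear = c(10L, 5L, 7L), stringsAsFactors = FALSE)
  h <- length_distribution(rec, "nuclear", "miRNA")
  expect_equal(attr(h, "mode"), 22)
  expect_equal(h$count[h$length == 22], 15)
  expect_equal(sum(h$count), 15)
  expect_warning(length_distribution(rec, "nuclear", "snRNA"), "empty")
  withr::with_seed(504, {
    lens <- sample(16:30, 500, replace = TRUE,
                   prob = dnorm(16:30, mean = 22, sd = 1.5))
    rec2 <- data.frame(sequence = vapply(lens, rand_dna, character(1)),
                       label = "miRNA", nuclear = 1L,
                       stringsAsFactors = FALSE)
    h2 <- length_distribution(rec2, "nuclear", "miRNA")
    expect_equal(attr(h2, "mode"), 22)
  })
})

test_that("per-library RPM over mapped records sums to one million", {
  withr::with_seed(505, {
    counts <- rpois(200, 50)
    total <- sum(counts)
    expect_equal(sum(rpm_normalize(counts, total)), 1e6, tolerance = 1e-9)
  })
})
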