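test_that("primer_matches finds verbatim sites and honors the 3' exact zone", {
  tpl <- paste0(random_dna(0), "TTTTTTTTTT", "ACGTACGTAC", "TTTTTTTTTT")
  hits <- primer_matches("ACGTACGTAC", tpl)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 20L)
  expect_equal(hits$mismatches, 0L)

  # single mismatch at the 3'-terminal base: rejected even at max_mm = 1
  tpl2 <- paste0("TTTTTTTTTT", "ACGTACGTAG", "TTTTTTTTTT")
  expect_equal(nrow(primer_matches("ACGTACGTAC", tpl2,
                                   match_policy(max_mismatches = 1))), 0L)
  # the same mismatch at the 5' end is tolerated
  tpl3 <- paste0("TTTTTTTTTT", "GCGTACGTAC", "TTTTTTTTTT")
  expect_equal(primer_matches("ACGTACGTAC", tpl3,
                              match_policy(max_mismatches = 1))$mismatches, 1L)
})

test_that("degenerate primer codes match template bases in their set", {
  tpl <- paste0("AAAAAAAAAA", "ACGTACGTAG", "AAAAAAAAAA")
  expect_equal(nrow(primer_matches("ACGTACGTAR", tpl)), 1L)  # R covers G
  expect_equal(nrow(primer_matches("ACGTACGTAY", tpl)), 0L)  # Y does not
  # degenerate template base is a mismatch under the strict policy...
  tplN <- paste0("AAAAAAAAAA", "ACGTACGTNG", "AAAAAAAAAA")
  expect_equal(nrow(primer_matches("ACGTACGTAG", tplN)), 0L)
  # ...but matches on set intersection under the permissive one
  expect_equal(nrow(primer_matches("ACGTACGTAG", tplN,
    match_policy(allow_degenerate_template = TRUE))), 1L)
})

test_that("reverse primers match as their reverse complement on + strand", {
  site <- "GATCGGATCGGATCGG"
  tpl <- paste0("CCCCCCCCCC", site, "CCCCCCCCCC")
  rv <- reverse_complement(site)
  hits <- primer_matches(rv, tpl, orientation = "reverse")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)
  expect_equal(hits$strand, "-")
  # a mutation at the site's left edge hits the reverse primer's 3' zone
  tpl_mut <- tpl
  substr(tpl_mut, 11, 11) <- "A"   # site starts with G
  expect_equal(nrow(primer_matches(rv, tpl_mut,
                                   match_policy(max_mismatches = 2),
                                   orientation = "reverse")), 0L)
})

test_that("simulate_pair predicts amplicons with footprint-inclusive length", {
  fw <- "ACGGCTAGCTAAGCTA"
  rv_site_start <- 145
  fw_site <- 11
  rv <- reverse_complement("GGATCCGATTGCAAGG")
  tpl <- random_dna(220)
  substr(tpl, fw_site, fw_site + nchar(fw) - 1) <- fw
  substr(tpl, rv_site_start, rv_site_start + 15) <- "GGATCCGATTGCAAGG"
  pair <- list(fw = list(sequence = fw, orientation = "forward"),
               rv = list(sequence = rv, orientation = "reverse"))
  hits <- simulate_pair(pair, c(t1 = tpl))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$amplicon_len, (rv_site_start + 15) - fw_site + 1)
  expect_equal(hits$amplicon_len, hits$rv_end - hits$fw_start + 1)
  # forward site alone yields nothing
  tpl_no_rv <- random_dna(220)
  substr(tpl_no_rv, fw_site, fw_site + nchar(fw) - 1) <- fw
  expect_equal(nrow(simulate_pair(pair, c(t1 = tpl_no_rv))), 0L)
})

test_that("simulate_pair equals the brute-force oracle on random instances", {
  set.seed(53)
  policy <- match_policy(max_mismatches = 1)
  for (i in 1:40) {
    tpl <- random_dna(sample(150:400, 1))
    fw <- random_dna(12)
    rv <- random_dna(12)
    # plant near-sites to make hits likely
    p1 <- sample(10:100, 1); p2 <- sample(180:320, 1)
    substr(tpl, p1, p1 + 11) <- fw
    substr(tpl, p2, p2 + 11) <- reverse_complement(rv)
    pair <- list(fw = list(sequence = fw), rv = list(sequence = rv))
    got <- simulate_pair(pair, c(t = tpl), policy)
    want <- oracle_simulate(fw, rv, tpl, max_mm = 1, zone = 5)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      got <- got[order(got$fw_start, got$rv_end), ]
      expect_equal(got$fw_start, want$fw_start)
      expect_equal(got$rv_end, want$rv_end)
      expect_equal(got$amplicon_len, want$amplicon_len)
    }
  }
})

test_that("coverage is monotone non-decreasing in allowed mismatches", {
  set.seed(59)
  panel <- read_panel(panel_path())
  pair <- panel_pair(panel, "Colwellia")
  refs <- read_fasta(synthetic_refs_path())
  recs <- seq_records(paste0("v", 1:12),
                      vapply(1:12, function(i) {
                        s <- refs$residues[refs$id == "Colwellia_synthetic_type_strain_16S"]
                        # sprinkle mutations to spread coverage across policies
                        v <- strsplit(s, "")[[1]]
                        idx <- sample(seq_along(v), 25)
                        v[idx] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
                        paste(v, collapse = "")
                      }, character(1)),
                      genus = "Colwellia")
  covs <- vapply(0:3, function(mm) {
    rep <- coverage_report(pair, recs, match_policy(max_mismatches = mm))
    rep$by_genus$coverage[rep$by_genus$genus == "Colwellia"]
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("coverage_report counts per genus and flags off-target genera", {
  fw <- "ACGGCTAGCTAAGCTA"
  rv_site <- "GGATCCGATTGCAAGG"
  make_tpl <- function(with_sites) {
    tpl <- random_dna(200)
    if (with_sites) {
      substr(tpl, 21, 36) <- fw
      substr(tpl, 141, 156) <- rv_site
    }
    tpl
  }
  set.seed(61)
  recs <- seq_records(
    paste0("s", 1:6),
    c(make_tpl(TRUE), make_tpl(TRUE), make_tpl(FALSE),   # target: 2/3
      make_tpl(TRUE), make_tpl(FALSE), make_tpl(FALSE)), # other genera
    genus = c("Target", "Target", "Target", "Other", "Other", ""))
  pair <- list(genus = "Target",
               fw = list(sequence = fw),
               rv = list(sequence = reverse_complement(rv_site)))
  rep <- coverage_report(pair, recs)
  tg <- rep$by_genus[rep$by_genus$genus == "Target", ]
  expect_equal(tg$n_sequences, 3L)
  expect_equal(tg$n_amplified, 2L)
  expect_equal(tg$coverage, 2 / 3, tolerance = 1e-12)
  expect_equal(rep$off_target, "Other")
  # dropping one covered sequence decreases n_amplified by exactly one
  rep2 <- coverage_report(pair, recs[-1, ])
  expect_equal(rep2$by_genus$n_amplified[rep2$by_genus$genus == "Target"], 1L)
})

test_that("minimum-length filtering is inclusive at the boundary", {
  recs <- seq_records(c("a", "b", "c"),
                      c(random_dna(899), random_dna(900), random_dna(1500)))
  expect_equal(filter_min_length(recs, 900)$id, c("b", "c"))
  expect_equal(nrow(filter_min_length(recs, 0)), 3L)
  expect_equal(nrow(filter_min_length(recs[0, ], 900)), 0L)
})

test_that("compare_primer_sets partitions records into a 2x2 contingency", {
  fw_a <- "ACGGCTAGCTAAGCTA"; rv_a_site <- "GGATCCGATTGCAAGG"
  fw_b <- "TTGACCGGTTAACGGA"; rv_b_site <- "CCTTAAGGCATGCAAT"
  set.seed(67)
  n <- 8
  seqs <- character(n)
  for (i in 1:n) {
    tpl <- random_dna(260)
    substr(tpl, 11, 26) <- fw_a
    substr(tpl, 181, 196) <- rv_a_site
    substr(tpl, 41, 56) <- fw_b
    if (i <= n / 2) {
      substr(tpl, 151, 166) <- rv_b_site
    } else {
      # kill pair B's reverse 3' zone only
      broken <- rv_b_site
      substr(broken, 1, 1) <- "G"  # left edge = rv 3' end on + strand
      substr(tpl, 151, 166) <- broken
    }
    seqs[i] <- tpl
  }
  recs <- seq_records(paste0("r", 1:n), seqs, genus = "G")
  pair_a <- list(genus = "G", fw = list(sequence = fw_a),
                 rv = list(sequence = reverse_complement(rv_a_site)))
  pair_b <- list(genus = "G", fw = list(sequence = fw_b),
                 rv = list(sequence = reverse_complement(rv_b_site)))
  cmp <- compare_primer_sets(pair_a, pair_b, recs)
  expect_equal(sum(cmp$contingency), n)
  expect_equal(unname(cmp$contingency["both"]), n / 2)
  expect_equal(unname(cmp$contingency["a_only"]), n / 2)
  expect_equal(unname(cmp$contingency["b_only"]), 0L)
  # identical pairs have empty off-diagonals
  cmp_same <- compare_primer_sets(pair_a, pair_a, recs)
  expect_equal(unname(cmp_same$contingency["a_only"]), 0L)
  expect_equal(unname(cmp_same$contingency["b_only"]), 0L)
})

test_that("coverage over a union of disjoint sets combines by weight", {
  set.seed(71)
  fw <- "ACGGCTAGCTAAGCTA"; rv_site <- "GGATCCGATTGCAAGG"
  mk <- function(ids, hit_frac) {
    n <- length(ids)
    seqs <- vapply(1:n, function(i) {
      tpl <- random_dna(200)
      if (i <= round(hit_frac * n)) {
        substr(tpl, 21, 36) <- fw
        substr(tpl, 141, 156) <- rv_site
      }
      tpl
    }, character(1))
    seq_records(ids, seqs, genus = "G")
  }
  a <- mk(paste0("a", 1:4), 1)
  b <- mk(paste0("b", 1:4), 0.5)
  pair <- list(genus = "G", fw = list(sequence = fw),
               rv = list(sequence = reverse_complement(rv_site)))
  both <- seq_records(c(a$id, b$id), c(a$residues, b$residues), genus = "G")
  cov_u <- coverage_report(pair, both)$by_genus
  cov_a <- coverage_report(pair, a)$by_genus
  cov_b <- coverage_report(pair, b)$by_genus
  expect_equal(cov_u$n_amplified, cov_a$n_amplified + cov_b$n_amplified)
  expect_equal(cov_u$coverage,
               (4 * cov_a$coverage + 4 * cov_b$coverage) / 8)
})
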