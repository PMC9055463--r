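# A small hand-built alignment with one planted genus-private window keeps
# these tests fast: 3 target and 3 background sequences share a conserved
# backbone except for a divergent 24-column block.

make_planted_family <- function(seed = 101, L = 160, sig_start = 61,
                                sig_len = 24) {
  set.seed(seed)
  backbone <- strsplit(random_dna(L), "")[[1]]
  target_sig <- strsplit(random_dna(sig_len), "")[[1]]
  bg_sig <- strsplit(random_dna(sig_len), "")[[1]]
  mk <- function(sig) {
    v <- backbone
    v[sig_start:(sig_start + sig_len - 1)] <- sig
    paste(v, collapse = "")
  }
  seq_records(c(paste0("t", 1:3), paste0("b", 1:3)),
              c(rep(mk(target_sig), 3), rep(mk(bg_sig), 3)),
              genus = c(rep("Target", 3), rep("Bg", 3)),
              is_aligned = TRUE)
}

test_that("conservation_profile separates target and background frequencies", {
  recs <- seq_records(c("t1", "t2", "b1"),
                      c("AAC-T", "ACC-T", "GGGGT"),
                      genus = c("T", "T", "B"), is_aligned = TRUE)
  prof <- conservation_profile(recs, "T")
  expect_equal(prof$n_target, 2L)
  expect_equal(prof$n_background, 1L)
  expect_equal(unname(prof$target["A", 1]), 1)           # all-A column
  expect_equal(unname(prof$target["A", 2]), 0.5)         # A/C split
  expect_equal(unname(prof$target["C", 2]), 0.5)
  expect_equal(unname(prof$target["-", 4]), 1)           # gap column
  expect_equal(unname(prof$background["G", 1]), 1)
  expect_equal(colSums(prof$target), rep(1, 5), ignore_attr = TRUE)
  expect_error(conservation_profile(recs, "Missing"), "no records")
  # empty background: vectors all zero and flagged
  only_t <- recs[recs$genus == "T", ]
  attr(only_t, "is_aligned") <- TRUE
  prof2 <- conservation_profile(only_t, "T")
  expect_true(prof2$background_empty)
  expect_true(all(prof2$background == 0))
})

test_that("window_consensus builds minimal IUPAC codes under the floor", {
  recs <- seq_records(c("t1", "t2"), c("AAAGT-", "AAAAT-"),
                      genus = "T", is_aligned = TRUE)
  prof <- conservation_profile(recs, "T")
  expect_equal(window_consensus(prof, c(1, 3)), "AAA")
  expect_equal(window_consensus(prof, c(1, 5)), "AAART")  # A/G column -> R
  # degeneracy cap: 2 two-fold columns exceed max_degeneracy 2
  recs2 <- seq_records(c("t1", "t2"), c("ARAR", "ARAR"), genus = "T",
                       is_aligned = TRUE)
  prof2 <- conservation_profile(recs2, "T")
  cons <- window_consensus(prof2, c(1, 4), max_degeneracy = 2)
  expect_true(is.na(cons))
  expect_equal(attr(cons, "reason"), "degeneracy")
  # majority-gap columns are rejected
  prof3 <- conservation_profile(recs, "T")
  gap_cons <- window_consensus(prof3, c(4, 6))
  expect_true(is.na(gap_cons))
  expect_equal(attr(gap_cons, "reason"), "majority_gap")
})

test_that("enumeration recovers a planted genus-private window", {
  recs <- make_planted_family()
  cfg <- design_config(primer_len = c(17, 20))
  cand <- enumerate_candidates(recs, "Target", cfg, max_candidates = 100)
  expect_gt(nrow(cand), 0)
  # every candidate overlaps the planted 24-column signature
  expect_true(all(cand$start <= 84 & cand$end >= 61))
  expect_true(all(cand$target_coverage == 1))
  expect_true(all(cand$background_fraction == 0))
  # the top candidate overlaps the planted window (brute-force check: no
  # fully-conserved window can survive the specificity screen)
  expect_true(cand$start[1] <= 84 && cand$end[1] >= 61)
})

test_that("enumeration is deterministic and empty for unseparable targets", {
  recs <- make_planted_family()
  cfg <- design_config(primer_len = c(17, 20))
  c1 <- enumerate_candidates(recs, "Target", cfg)
  c2 <- enumerate_candidates(recs, "Target", cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # target identical to background: specificity unattainable
  same <- seq_records(c("t1", "b1"),
                      rep(random_dna(60), 2), genus = c("T", "B"),
                      is_aligned = TRUE)
  none <- enumerate_candidates(same, "T", design_config(primer_len = c(17, 18)))
  expect_equal(nrow(none), 0L)
  expect_gt(attr(none, "rejections")[["background"]], 0)
})

test_that("relaxing the coverage threshold never shrinks the candidate set", {
  set.seed(131)
  recs <- make_planted_family()
  # introduce noise so some windows drop below high coverage thresholds
  v <- strsplit(recs$residues[1], "")[[1]]
  v[65:70] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
  recs$residues[1] <- paste(v, collapse = "")
  cfg_strict <- design_config(primer_len = c(17, 20), min_target_coverage = 0.9)
  cfg_loose <- design_config(primer_len = c(17, 20), min_target_coverage = 0.5)
  n_strict <- nrow(enumerate_candidates(recs, "Target", cfg_strict,
                                        max_candidates = 1000))
  n_loose <- nrow(enumerate_candidates(recs, "Target", cfg_loose,
                                       max_candidates = 1000))
  expect_gte(n_loose, n_strict)
})

test_that("pairing respects the inclusive amplicon window on every template", {
  # two planted windows 150 apart allow an in-range pair; verify bounds
  set.seed(151)
  L <- 300
  backbone <- strsplit(random_dna(L), "")[[1]]
  sigA <- strsplit(random_dna(20), "")[[1]]
  sigB <- strsplit(random_dna(20), "")[[1]]
  bgA <- strsplit(random_dna(20), "")[[1]]
  bgB <- strsplit(random_dna(20), "")[[1]]
  mk <- function(a, b) {
    v <- backbone; v[41:60] <- a; v[171:190] <- b
    paste(v, collapse = "")
  }
  recs <- seq_records(c("t1", "t2", "b1", "b2"),
                      c(rep(mk(sigA, sigB), 2), rep(mk(bgA, bgB), 2)),
                      genus = c("T", "T", "B", "B"), is_aligned = TRUE)
  cfg <- design_config(primer_len = c(17, 20))
  cand <- enumerate_candidates(recs, "T", cfg, max_candidates = 60)
  pairs <- pair_candidates(cand, recs, cfg)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$amplicon_min >= 85 & pairs$amplicon_max <= 250))
  expect_true(all(pairs$pair_coverage <= 1))
  # pair coverage never exceeds either primer's own coverage
  for (k in seq_len(min(nrow(pairs), 10))) {
    fw_cov <- cand$target_coverage[cand$consensus == pairs$fw_consensus[k]][1]
    rv_cov <- cand$target_coverage[cand$consensus == pairs$rv_consensus[k]][1]
    expect_lte(pairs$pair_coverage[k], min(fw_cov, rv_cov) + 1e-12)
  }
  # windows ~110 columns apart cannot reach the 85 bp minimum with the
  # footprints excluded -> move windows closer and the pair vanishes
  mk2 <- function(a, b) {
    v <- backbone; v[41:60] <- a; v[81:100] <- b
    paste(v, collapse = "")
  }
  recs2 <- seq_records(c("t1", "t2", "b1", "b2"),
                       c(rep(mk2(sigA, sigB), 2), rep(mk2(bgA, bgB), 2)),
                       genus = c("T", "T", "B", "B"), is_aligned = TRUE)
  cand2 <- enumerate_candidates(recs2, "T", cfg, max_candidates = 60)
  pairs2 <- pair_candidates(cand2, recs2, cfg)
  if (nrow(pairs2)) {
    expect_true(all(pairs2$amplicon_min >= 85))
  }
})

test_that("design_panel reports failures for absent or unseparable genera", {
  recs <- make_planted_family()
  res <- design_panel(recs, genera = c("Target", "Ghost"),
                      config = design_config(primer_len = c(17, 20),
                                             amplicon_range = c(30, 120)))
  expect_true("Ghost" %in% res$failures$genus)
  expect_match(res$failures$reason[res$failures$genus == "Ghost"],
               "no target sequences")
})
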