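# Degenerate genus-specific primer design from a labelled 16S alignment.
#
# The search formalizes "amplify the maximum number of species with maximum
# specificity": every alignment window of the configured primer lengths is
# scanned in both orientations, its minimal degenerate consensus over the
# target genus is built, and windows are kept when they pass degeneracy,
# within-genus coverage, background-specificity and thermodynamic filters.
# Survivors are ranked by a weighted score and paired under the amplicon
# size window.

#' Primer design configuration
#'
#' @param primer_len inclusive range of primer lengths scanned.
#' @param max_degeneracy maximum degeneracy of a candidate consensus.
#' @param min_target_coverage minimum fraction of target sequences a window
#'   must match exactly.
#' @param max_background_match_fraction maximum fraction of background
#'   sequences that may contain an exact (0-mismatch) site for the
#'   candidate.
#' @param amplicon_range inclusive product-size window in bp, measured on
#'   gap-stripped templates from the forward primer's first base to the
#'   reverse primer's last.
#' @param consensus_floor minimum within-target base frequency for a base to
#'   enter the consensus code at a column (screens sequencing-noise
#'   singletons in large sets).
#' @param weights numeric vector `c(coverage, background, thermo)` for the
#'   ranking score `w1*coverage - w2*background_fraction -
#'   w3*soft_violations`.
#' @return a `design_config` list.
#' @export
design_config <- function(primer_len = c(17L, 25L), max_degeneracy = 8L,
                          min_target_coverage = 0.8,
                          max_background_match_fraction = 0,
                          amplicon_range = c(85L, 250L),
                          consensus_floor = 0.05,
                          weights = c(coverage = 1, background = 1, thermo = 0.2)) {
  stopifnot(primer_len[1] >= 10L, primer_len[1] <= primer_len[2],
            max_degeneracy >= 1L,
            min_target_coverage >= 0, min_target_coverage <= 1,
            amplicon_range[1] <= amplicon_range[2],
            consensus_floor >= 0, consensus_floor < 1)
  structure(list(primer_len = as.integer(primer_len),
                 max_degeneracy = as.integer(max_degeneracy),
                 min_target_coverage = min_target_coverage,
                 max_background_match_fraction = max_background_match_fraction,
                 amplicon_range = as.integer(amplicon_range),
                 consensus_floor = consensus_floor,
                 weights = weights),
            class = "design_config")
}

alignment_matrix <- function(records) {
  if (!is_aligned(records)) stop("records must be aligned")
  do.call(rbind, strsplit(records$residues, "", fixed = TRUE))
}

#' Per-column base frequencies for a target genus vs the background
#'
#' @param records aligned, labelled `seq_records`.
#' @param target_genus genus whose sequences form the target set; all other
#'   records (labelled or not) are background.
#' @return a `conservation_profile`: matrices `target` and `background`
#'   (5 x L, rows A/C/G/T/-, columns alignment positions; frequencies sum to
#'   1 per column, background all-zero and flagged when empty), counts
#'   `n_target`, `n_background`.
#' @export
conservation_profile <- function(records, target_genus) {
  if (!is_aligned(records)) stop("conservation_profile needs aligned records")
  is_target <- records$genus == target_genus
  if (!any(is_target)) stop("no records labelled '", target_genus, "'")
  mat <- alignment_matrix(records)
  levels <- c("A", "C", "G", "T", "-")
  col_freq <- function(m) {
    if (!nrow(m)) {
      return(matrix(0, nrow = 5L, ncol = ncol(mat),
                    dimnames = list(levels, NULL)))
    }
    # ambiguity codes are spread uniformly over their base sets
    counts <- matrix(0, nrow = 5L, ncol = ncol(m), dimnames = list(levels, NULL))
    for (lv in levels) counts[lv, ] <- colSums(m == lv)
    other <- colSums(!matrix(m %in% levels, nrow = nrow(m)))
    if (any(other > 0)) {
      for (j in which(other > 0)) {
        amb <- m[!(m[, j] %in% levels), j]
        for (a in amb) {
          bases <- names(BASE_BITS)[bitwAnd(IUPAC_BITS[[a]], BASE_BITS) > 0L]
          counts[bases, j] <- counts[bases, j] + 1 / length(bases)
        }
      }
    }
    sweep(counts, 2L, nrow(m), "/")
  }
  structure(list(target = col_freq(mat[is_target, , drop = FALSE]),
                 background = col_freq(mat[!is_target, , drop = FALSE]),
                 n_target = sum(is_target), n_background = sum(!is_target),
                 background_empty = !any(!is_target),
                 target_genus = target_genus),
            class = "conservation_profile")
}

#' Minimal degenerate consensus of an alignment window
#'
#' Per column, the smallest IUPAC code covering every base whose
#' within-target frequency is at least `floor`. Fails (returns `NA` with a
#' `reason` attribute) when the window overlaps a column that is
#' majority-gap in the targets, when a column has no base above the floor,
#' or when the total degeneracy exceeds `max_degeneracy`.
#'
#' @param profile a [conservation_profile()].
#' @param window integer `c(start, end)` alignment columns, 1-based closed.
#' @param max_degeneracy degeneracy cap.
#' @param floor consensus frequency floor.
#' @return degenerate IUPAC string, or `NA` with attribute `reason`.
#' @export
window_consensus <- function(profile, window, max_degeneracy = 8L,
                             floor = 0.05) {
  cols <- window[1]:window[2]
  tf <- profile$target[, cols, drop = FALSE]
  if (any(tf["-", ] >= 0.5)) {
    return(structure(NA_character_, reason = "majority_gap"))
  }
  bits <- integer(length(cols))
  for (k in seq_along(cols)) {
    keep <- tf[1:4, k] >= max(floor, 1e-12)
    if (!any(keep)) return(structure(NA_character_, reason = "no_base_above_floor"))
    bits[k] <- sum(BASE_BITS[keep])
  }
  if (prod(POPCOUNT4[bits]) > max_degeneracy) {
    return(structure(NA_character_, reason = "degeneracy"))
  }
  bits_to_string(bits)
}

# Precomputed per-sequence/per-column compatibility against the per-column
# consensus codes lets window coverage be computed from cumulative mismatch
# sums in O(n_sequences) per window.
profile_codes <- function(profile, floor) {
  L <- ncol(profile$target)
  bits <- integer(L)
  ok <- logical(L)
  for (j in seq_len(L)) {
    keep <- profile$target[1:4, j] >= max(floor, 1e-12)
    ok[j] <- any(keep) && profile$target["-", j] < 0.5
    bits[j] <- if (any(keep)) sum(BASE_BITS[keep]) else 0L
  }
  list(bits = bits, col_ok = ok, log_deg = ifelse(bits > 0L, log(POPCOUNT4[pmax(bits, 1L)]), Inf))
}

#' Enumerate ranked candidate primers for one genus
#'
#' Two-phase scan. Phase 1 applies the cheap, orientation-independent
#' filters to every alignment window of every configured length: no
#' majority-gap column, consensus degeneracy cap, within-genus coverage,
#' and the in-place specificity screen (exact background match at the
#' homologous columns). Phase 2 walks the survivors in provisional order
#' (coverage descending, then leftmost, then shortest) and applies the
#' expensive filters - thermodynamic profile and a full off-site background
#' scan - until `max_candidates` survivors per orientation are collected.
#' The returned set is ranked by final score with deterministic tie-breaks
#' (leftmost, forward before reverse, shortest).
#'
#' @param records aligned, labelled `seq_records`.
#' @param target_genus genus to design for.
#' @param config a [design_config()].
#' @param thermo a [thermo_config()].
#' @param orientations orientations scanned.
#' @param max_candidates cap on fully evaluated survivors per orientation
#'   (performance valve; raise it for exhaustive small-alignment searches).
#' @return a `candidate_set`: data.frame of candidates (aligned window,
#'   orientation, consensus, degeneracy, target_coverage,
#'   background_fraction, thermo fields, score), plus attributes
#'   `rejections` (named tally per filter) and `profile`.
#' @export
enumerate_candidates <- function(records, target_genus,
                                 config = design_config(),
                                 thermo = thermo_config(),
                                 orientations = c("forward", "reverse"),
                                 max_candidates = 40L) {
  profile <- conservation_profile(records, target_genus)
  codes <- profile_codes(profile, config$consensus_floor)
  mat <- alignment_matrix(records)
  is_target <- records$genus == target_genus
  L <- ncol(mat)
  n_t <- sum(is_target); n_b <- sum(!is_target)
  bg_strings <- gsub("-", "", records$residues[!is_target], fixed = TRUE)

  char_bits <- function(m) {
    b <- matrix(0L, nrow(m), ncol(m))
    if (nrow(m)) {
      b[] <- IUPAC_BITS[m]
      b[is.na(b)] <- 0L           # gaps
    }
    b
  }
  tbits <- char_bits(mat[is_target, , drop = FALSE])
  bbits <- char_bits(mat[!is_target, , drop = FALSE])

  # per-column: does sequence i's (concrete) base fall in the consensus code?
  code_mat <- matrix(rep(codes$bits, each = max(n_t, 1L)), nrow = max(n_t, 1L))
  t_match <- tbits > 0L & POPCOUNT4[pmax(tbits, 1L)] == 1L &
    bitwAnd(tbits, code_mat) > 0L
  t_miss_cum <- cbind(0L, t(apply(!t_match, 1L, cumsum)))
  if (n_b) {
    bcode <- matrix(rep(codes$bits, each = n_b), nrow = n_b)
    b_match <- bbits > 0L & POPCOUNT4[pmax(bbits, 1L)] == 1L &
      bitwAnd(bbits, bcode) > 0L
    b_miss_cum <- cbind(0L, t(apply(!b_match, 1L, cumsum)))
  }
  colok_cum <- c(0L, cumsum(!codes$col_ok))
  logdeg_cum <- c(0, cumsum(ifelse(is.finite(codes$log_deg), codes$log_deg, 1e6)))

  rejections <- c(window = 0L, degeneracy = 0L, coverage = 0L,
                  background = 0L, thermo = 0L, unevaluated = 0L)

  # phase 1: cheap, orientation-independent filters
  prov <- list()
  for (len in config$primer_len[1]:config$primer_len[2]) {
    if (len > L) next
    for (start in seq_len(L - len + 1L)) {
      end <- start + len - 1L
      if (colok_cum[end + 1L] - colok_cum[start] > 0L) {
        rejections["window"] <- rejections["window"] + 1L
        next
      }
      if (logdeg_cum[end + 1L] - logdeg_cum[start] >
          log(config$max_degeneracy) + 1e-9) {
        rejections["degeneracy"] <- rejections["degeneracy"] + 1L
        next
      }
      coverage <- mean(t_miss_cum[, end + 1L] - t_miss_cum[, start] == 0L)
      if (coverage < config$min_target_coverage) {
        rejections["coverage"] <- rejections["coverage"] + 1L
        next
      }
      bg_inplace <- if (n_b) {
        mean(b_miss_cum[, end + 1L] - b_miss_cum[, start] == 0L)
      } else 0
      if (bg_inplace > config$max_background_match_fraction) {
        rejections["background"] <- rejections["background"] + 1L
        next
      }
      prov[[length(prov) + 1L]] <- c(start, end, len, coverage, bg_inplace)
    }
  }
  cand_cols <- function() data.frame(
    start = integer(), end = integer(), length = integer(),
    orientation = character(), consensus = character(),
    degeneracy = integer(), target_coverage = numeric(),
    background_fraction = numeric(), tm_min = numeric(),
    tm_max = numeric(), hairpin_dg = numeric(), self_dimer_dg = numeric(),
    soft_violations = integer(), score = numeric(), stringsAsFactors = FALSE)

  if (!length(prov)) {
    return(structure(cand_cols(), rejections = rejections, profile = profile,
                     target_genus = target_genus,
                     class = c("candidate_set", "data.frame")))
  }
  prov <- do.call(rbind, prov)
  colnames(prov) <- c("start", "end", "len", "coverage", "bg_inplace")
  # group survivors into positional clusters (windows further than 40
  # columns apart belong to different candidate regions) so the evaluation
  # cap is spread over regions instead of exhausted on the leftmost one
  ord_s <- order(prov[, "start"])
  breaks <- c(0L, cumsum(diff(prov[ord_s, "start"]) > 40L))
  cluster <- integer(nrow(prov))
  cluster[ord_s] <- breaks + 1L
  prov <- cbind(prov, cluster = cluster)
  prov <- prov[order(-prov[, "coverage"], prov[, "start"], prov[, "len"]),
               , drop = FALSE]

  # phase 2: thermodynamics and full off-site background scan, in
  # provisional order, until the per-orientation cap is filled
  bg_policy <- match_policy(max_mismatches = 0L)
  rows <- list()
  n_kept <- stats::setNames(integer(length(orientations)), orientations)
  n_clusters <- max(prov[, "cluster"])
  per_cluster_cap <- max(3L, ceiling(max_candidates / n_clusters))
  kept_cluster <- matrix(0L, nrow = n_clusters, ncol = length(orientations),
                         dimnames = list(NULL, orientations))
  for (r in seq_len(nrow(prov))) {
    if (all(n_kept >= max_candidates)) {
      rejections["unevaluated"] <- rejections["unevaluated"] +
        (nrow(prov) - r + 1L)
      break
    }
    start <- prov[r, "start"]; end <- prov[r, "end"]
    cl <- prov[r, "cluster"]
    consensus_template <- bits_to_string(codes$bits[start:end])
    for (orient in orientations) {
      if (n_kept[[orient]] >= max_candidates) next
      if (kept_cluster[cl, orient] >= per_cluster_cap) next
      primer_seq <- if (orient == "forward") consensus_template else
        reverse_complement(consensus_template)
      prof <- tryCatch(evaluate_primer(primer_seq, thermo),
                       error = function(e) NULL)
      if (is.null(prof) || !prof$pass_all) {
        rejections["thermo"] <- rejections["thermo"] + 1L
        next
      }
      bg_frac <- prov[r, "bg_inplace"]
      if (n_b) {
        full_hits <- vapply(bg_strings, function(s) {
          nrow(primer_matches(primer_seq, s, bg_policy,
                              orientation = orient)) > 0L
        }, logical(1))
        bg_frac <- mean(full_hits)
        if (bg_frac > config$max_background_match_fraction) {
          rejections["background"] <- rejections["background"] + 1L
          next
        }
      }
      coverage <- prov[r, "coverage"]
      score <- config$weights[["coverage"]] * coverage -
        config$weights[["background"]] * bg_frac -
        config$weights[["thermo"]] * prof$soft_violations
      n_kept[[orient]] <- n_kept[[orient]] + 1L
      kept_cluster[cl, orient] <- kept_cluster[cl, orient] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start = as.integer(start), end = as.integer(end),
        length = as.integer(prov[r, "len"]), orientation = orient,
        consensus = primer_seq, degeneracy = prof$degeneracy,
        target_coverage = coverage, background_fraction = bg_frac,
        tm_min = prof$tm_min, tm_max = prof$tm_max,
        hairpin_dg = prof$hairpin_dg, self_dimer_dg = prof$self_dimer_dg,
        soft_violations = prof$soft_violations, score = score,
        stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else cand_cols()
  if (nrow(cand)) {
    ord <- order(-cand$score, cand$start,
                 match(cand$orientation, c("forward", "reverse")),
                 cand$length)
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(cand, rejections = rejections, profile = profile,
            target_genus = target_genus,
            class = c("candidate_set", "data.frame"))
}

#' Pair forward and reverse candidates under the amplicon-size window
#'
#' Every forward x reverse combination is kept when, on every template
#' covered by both primers, the forward site lies upstream of the reverse
#' site and the gap-stripped product length (both footprints included)
#' falls within `config$amplicon_range`. Pair coverage is re-measured by
#' in silico PCR at 0 mismatches on the gap-stripped target sequences.
#'
#' @param candidates a `candidate_set` from [enumerate_candidates()].
#' @param records the aligned records the candidates came from.
#' @param config a [design_config()].
#' @param max_pairs evaluation budget on fw x rv combinations (combinations
#'   whose alignment-coordinate span cannot yield an in-range amplicon are
#'   pre-filtered and do not consume budget).
#' @return data.frame of pairs ranked by combined score: fw/rv consensus and
#'   windows, `amplicon_min`/`amplicon_max`, `pair_coverage`, `score`.
#' @export
pair_candidates <- function(candidates, records, config = design_config(),
                            max_pairs = 200L) {
  target_genus <- attr(candidates, "target_genus")
  fw <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rv <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  empty <- data.frame(fw_consensus = character(), rv_consensus = character(),
                      fw_start = integer(), fw_end = integer(),
                      rv_start = integer(), rv_end = integer(),
                      amplicon_min = integer(), amplicon_max = integer(),
                      pair_coverage = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(fw) || !nrow(rv)) return(empty)
  targets <- strip_gaps(records[records$genus == target_genus, , drop = FALSE])
  policy <- match_policy(max_mismatches = 0L,
                         amplicon_guard = config$amplicon_range)
  # indel slack when translating the amplicon window into alignment columns
  slack <- 30L
  n_eval <- 0L
  rows <- list()
  for (i in seq_len(nrow(fw))) {
    if (n_eval >= max_pairs) break
    for (j in seq_len(nrow(rv))) {
      if (n_eval >= max_pairs) break
      if (rv$start[j] <= fw$end[i]) next  # rv window must lie downstream
      span <- rv$end[j] - fw$start[i] + 1L
      if (span < config$amplicon_range[1] - slack ||
          span > config$amplicon_range[2] + slack) next
      n_eval <- n_eval + 1L
      pair <- list(genus = target_genus,
                   fw = list(sequence = fw$consensus[i], orientation = "forward"),
                   rv = list(sequence = rv$consensus[j], orientation = "reverse"))
      hits <- simulate_pair(pair, targets, policy)
      if (!nrow(hits)) next
      per_template <- tapply(hits$amplicon_len, hits$template_id, min)
      pair_cov <- length(per_template) / nrow(targets)
      lens <- range(hits$amplicon_len)
      if (lens[1] < config$amplicon_range[1] ||
          lens[2] > config$amplicon_range[2]) next
      score <- config$weights[["coverage"]] * pair_cov -
        config$weights[["background"]] *
          max(fw$background_fraction[i], rv$background_fraction[j]) -
        config$weights[["thermo"]] *
          (fw$soft_violations[i] + rv$soft_violations[j])
      rows[[length(rows) + 1L]] <- data.frame(
        fw_consensus = fw$consensus[i], rv_consensus = rv$consensus[j],
        fw_start = fw$start[i], fw_end = fw$end[i],
        rv_start = rv$start[j], rv_end = rv$end[j],
        amplicon_min = lens[1], amplicon_max = lens[2],
        pair_coverage = pair_cov, score = score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  pairs <- do.call(rbind, rows)
  ord <- order(-pairs$score, pairs$fw_start, pairs$rv_start)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Design the best primer pair for each genus in a labelled alignment
#'
#' @param records aligned, labelled `seq_records`.
#' @param genera character vector of genera to design for (default: all
#'   non-empty labels present).
#' @param config a [design_config()].
#' @param thermo a [thermo_config()].
#' @return a `design_panel` list: `panel` data.frame (one row per genus with
#'   a successful pair, panel-TSV compatible columns plus pair metrics),
#'   `failures` data.frame (genus, reason, per-filter rejection tallies),
#'   `candidates` list keyed by genus.
#' @export
design_panel <- function(records, genera = NULL, config = design_config(),
                         thermo = thermo_config()) {
  if (is.null(genera)) genera <- sort(unique(records$genus[nzchar(records$genus)]))
  panel_rows <- list(); failures <- list(); cand_list <- list()
  for (g in genera) {
    if (!any(records$genus == g)) {
      failures[[g]] <- data.frame(genus = g, reason = "no target sequences",
                                  rejected = "", stringsAsFactors = FALSE)
      next
    }
    cand <- enumerate_candidates(records, g, config, thermo)
    cand_list[[g]] <- cand
    pairs <- pair_candidates(cand, records, config)
    if (!nrow(pairs)) {
      rej <- attr(cand, "rejections")
      failures[[g]] <- data.frame(
        genus = g,
        reason = if (!nrow(cand)) "no candidate window passed filters"
                 else "no compatible pair in amplicon window",
        rejected = paste(sprintf("%s=%d", names(rej), rej), collapse = ";"),
        stringsAsFactors = FALSE)
      next
    }
    best <- pairs[1, ]
    panel_rows[[g]] <- data.frame(
      genus = g,
      fw_sequence = best$fw_consensus, rv_sequence = best$rv_consensus,
      fw_window = sprintf("%d-%d", best$fw_start, best$fw_end),
      rv_window = sprintf("%d-%d", best$rv_start, best$rv_end),
      amplicon_min = best$amplicon_min, amplicon_max = best$amplicon_max,
      pair_coverage = best$pair_coverage, score = best$score,
      stringsAsFactors = FALSE)
  }
  structure(list(
    panel = if (length(panel_rows)) do.call(rbind, c(panel_rows, list(make.row.names = FALSE)))
            else NULL,
    failures = if (length(failures)) do.call(rbind, c(failures, list(make.row.names = FALSE)))
               else NULL,
    candidates = cand_list,
    config = config
  ), class = "design_panel")
}

#' @export
print.design_panel <- function(x, ...) {
  n_ok <- if (is.null(x$panel)) 0L else nrow(x$panel)
  n_bad <- if (is.null(x$failures)) 0L else nrow(x$failures)
  cat(sprintf("design panel: %d genus pair(s) designed, %d failure(s)\n",
              n_ok, n_bad))
  if (n_ok) print(x$panel[, c("genus", "fw_sequence", "rv_sequence",
                              "amplicon_min", "amplicon_max",
                              "pair_coverage")])
  if (n_bad) print(x$failures)
  invisible(x)
}

#' Convert a designed panel to a `primer_pair` for a genus
#'
#' @param design a `design_panel` result.
#' @param genus genus name.
#' @return a `primer_pair` usable with [simulate_pair()] /
#'   [coverage_report()].
#' @export
design_pair <- function(design, genus) {
  row <- design$panel[design$panel$genus == genus, , drop = FALSE]
  if (!nrow(row)) stop("no designed pair for genus '", genus, "'")
  structure(list(
    genus = genus,
    fw = list(name = paste0(genus, "-F"), sequence = row$fw_sequence,
              orientation = "forward"),
    rv = list(name = paste0(genus, "-R"), sequence = row$rv_sequence,
              orientation = "reverse"),
    amplicon_size = row$amplicon_max
  ), class = "primer_pair")
}
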