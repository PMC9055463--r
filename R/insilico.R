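# TestPrime-style in silico PCR: mismatch-tolerant IUPAC-aware primer
# matching with a 3'-exact zone, amplicon prediction, and per-genus
# coverage/specificity reports.

#' Primer-matching policy
#'
#' @param max_mismatches maximum mismatches allowed over the whole primer.
#' @param three_prime_exact_zone number of 3'-terminal primer bases in which
#'   no mismatch is tolerated.
#' @param allow_degenerate_template if FALSE (default), a non-ACGT template
#'   base counts as a mismatch; if TRUE, IUPAC codes match on set
#'   intersection.
#' @param min_template_len templates shorter than this are dropped before
#'   simulation (0 disables; genus-coverage comparisons against reference
#'   databases conventionally use 900).
#' @param amplicon_guard sanity window (bp) on predicted product length.
#' @param dedupe drop exact duplicate template strings before counting
#'   ("unique sequences" mode).
#' @return a `match_policy` list.
#' @export
match_policy <- function(max_mismatches = 0L, three_prime_exact_zone = 5L,
                         allow_degenerate_template = FALSE,
                         min_template_len = 0L,
                         amplicon_guard = c(50L, 2000L), dedupe = FALSE) {
  stopifnot(max_mismatches >= 0L, three_prime_exact_zone >= 0L,
            length(amplicon_guard) == 2L, amplicon_guard[1] <= amplicon_guard[2])
  structure(list(max_mismatches = as.integer(max_mismatches),
                 three_prime_exact_zone = as.integer(three_prime_exact_zone),
                 allow_degenerate_template = allow_degenerate_template,
                 min_template_len = as.integer(min_template_len),
                 amplicon_guard = as.integer(amplicon_guard),
                 dedupe = dedupe),
            class = "match_policy")
}

#' Find all annealing sites of one primer on one template
#'
#' A forward primer is matched as written against the + strand; a reverse
#' primer is matched by aligning its reverse complement to the + strand (so
#' its 3' end faces upstream). A site is reported when the total number of
#' mismatching positions is at most `policy$max_mismatches` and no mismatch
#' falls in the 3'-terminal `three_prime_exact_zone` bases of the primer.
#' Degenerate primer codes match a template base contained in their set.
#'
#' @param primer IUPAC DNA string, 5'->3'.
#' @param template IUPAC DNA string (gap-free).
#' @param policy a [match_policy()].
#' @param orientation "forward" or "reverse".
#' @return data.frame with columns `start`, `end` (1-based closed interval
#'   on the + strand), `mismatches`, `strand` ("+" for forward primers, "-"
#'   for reverse).
#' @export
primer_matches <- function(primer, template, policy = match_policy(),
                           orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  pb <- iupac_bits(primer)
  tb <- iupac_bits(template)
  m <- length(pb); n <- length(tb)
  empty <- data.frame(start = integer(), end = integer(),
                      mismatches = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (m > n || m == 0L) return(empty)
  if (orientation == "reverse") pb <- rev(comp_bits(pb))
  zone <- min(policy$three_prime_exact_zone, m)
  # columns of the match matrix holding the primer's 3'-terminal bases:
  # forward primers end at the site's right edge, reverse-complemented
  # reverse primers start at its left edge.
  zone_cols <- if (zone == 0L) integer() else if (orientation == "forward") {
    (m - zone + 1L):m
  } else {
    1L:zone
  }
  npos <- n - m + 1L
  idx <- outer(0:(npos - 1L), 1:m, `+`)  # npos x m template positions
  ok <- matrix(bits_compatible(tb[idx], rep(pb, each = npos),
                               policy$allow_degenerate_template),
               nrow = npos)
  mm <- rowSums(!ok)
  zone_ok <- if (length(zone_cols)) {
    rowSums(!ok[, zone_cols, drop = FALSE]) == 0L
  } else TRUE
  hit <- which(mm <= policy$max_mismatches & zone_ok)
  data.frame(start = hit, end = hit + m - 1L,
             mismatches = as.integer(mm[hit]),
             strand = rep(if (orientation == "forward") "+" else "-",
                          length(hit)),
             stringsAsFactors = FALSE)
}

#' Simulate PCR of a primer pair over a set of templates
#'
#' For each template, every forward-primer site is combined with every
#' reverse-primer site whose 3' interval ends downstream of the forward
#' start; products outside the policy's amplicon guard are discarded.
#' Amplicon length spans both primer footprints:
#' `rv_end - fw_start + 1`.
#'
#' @param pair a `primer_pair` (see [panel_pair()]) or a list with `fw` and
#'   `rv` elements each holding a `sequence`.
#' @param templates a `seq_records` collection (gap-free) or named character
#'   vector of sequences.
#' @param policy a [match_policy()].
#' @return data.frame of amplicon hits: `template_id`, `fw_start`, `fw_end`,
#'   `rv_start`, `rv_end`, `mismatches_fw`, `mismatches_rv`, `amplicon_len`.
#' @export
simulate_pair <- function(pair, templates, policy = match_policy()) {
  seqs <- template_vector(templates)
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    fw <- primer_matches(pair$fw$sequence, s, policy, "forward")
    if (!nrow(fw)) next
    rv <- primer_matches(pair$rv$sequence, s, policy, "reverse")
    if (!nrow(rv)) next
    combos <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
    len <- rv$end[combos$r] - fw$start[combos$f] + 1L
    keep <- fw$start[combos$f] < rv$end[combos$r] &
      len >= policy$amplicon_guard[1] & len <= policy$amplicon_guard[2]
    if (!any(keep)) next
    combos <- combos[keep, , drop = FALSE]
    out[[id]] <- data.frame(
      template_id = id,
      fw_start = fw$start[combos$f], fw_end = fw$end[combos$f],
      rv_start = rv$start[combos$r], rv_end = rv$end[combos$r],
      mismatches_fw = fw$mismatches[combos$f],
      mismatches_rv = rv$mismatches[combos$r],
      amplicon_len = len[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(template_id = character(), fw_start = integer(),
                      fw_end = integer(), rv_start = integer(),
                      rv_end = integer(), mismatches_fw = integer(),
                      mismatches_rv = integer(), amplicon_len = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

template_vector <- function(templates) {
  if (inherits(templates, "seq_records") || is.data.frame(templates)) {
    if (any(grepl("-", templates$residues, fixed = TRUE))) {
      stop("templates must be gap-free; call strip_gaps() first")
    }
    stats::setNames(templates$residues, templates$id)
  } else if (is.character(templates)) {
    if (is.null(names(templates))) {
      names(templates) <- paste0("template", seq_along(templates))
    }
    templates
  } else {
    stop("templates must be a seq_records collection or character vector")
  }
}

apply_policy_filters <- function(records, policy) {
  records <- filter_min_length(records, policy$min_template_len)
  if (policy$dedupe) {
    records <- records[!duplicated(records$residues), , drop = FALSE]
  }
  records
}

#' Keep records whose (gap-free) length is at least `min_len`
#'
#' The boundary is inclusive: a 900-bp sequence passes `min_len = 900`.
#'
#' @param records a `seq_records` collection.
#' @param min_len minimum length in bp.
#' @return the filtered collection.
#' @export
filter_min_length <- function(records, min_len) {
  keep <- nchar(gsub("-", "", records$residues, fixed = TRUE)) >= min_len
  out <- records[keep, , drop = FALSE]
  attr(out, "is_aligned") <- attr(records, "is_aligned")
  class(out) <- class(records)
  out
}

#' Per-genus coverage and specificity of a primer pair
#'
#' @param pair a `primer_pair`.
#' @param records gap-free `seq_records` with genus labels (empty genus =
#'   unlabelled background, reported under "(unlabelled)").
#' @param policy a [match_policy()]; its `min_template_len` and `dedupe`
#'   settings are applied before counting.
#' @param target_genus the pair's intended genus (defaults to
#'   `pair$genus`); all other amplified genera are listed off-target.
#' @return a `coverage_report` list: `by_genus` data.frame (genus,
#'   n_sequences, n_amplified, coverage), `off_target` character vector,
#'   `hits` (the amplicon table), `policy`.
#' @export
coverage_report <- function(pair, records, policy = match_policy(),
                            target_genus = pair$genus) {
  records <- apply_policy_filters(records, policy)
  hits <- simulate_pair(pair, records, policy)
  amplified_ids <- unique(hits$template_id)
  genus <- ifelse(nzchar(records$genus), records$genus, "(unlabelled)")
  amp <- records$id %in% amplified_ids
  levels <- sort(unique(genus))
  gfac <- factor(genus, levels = levels)
  by_genus <- data.frame(
    genus = levels,
    n_sequences = as.integer(table(gfac)),
    n_amplified = as.integer(tapply(as.integer(amp), gfac, sum,
                                    default = 0L)),
    stringsAsFactors = FALSE)
  by_genus$coverage <- by_genus$n_amplified / by_genus$n_sequences
  rownames(by_genus) <- NULL
  off <- sort(setdiff(by_genus$genus[by_genus$n_amplified > 0],
                      target_genus))
  structure(list(target_genus = target_genus, by_genus = by_genus,
                 off_target = off, hits = hits, policy = policy),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage report for genus '%s' (max mismatches %d, 3' zone %d)\n",
              x$target_genus, x$policy$max_mismatches,
              x$policy$three_prime_exact_zone))
  print(x$by_genus)
  cat("off-target genera:",
      if (length(x$off_target)) paste(x$off_target, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Head-to-head comparison of two primer pairs on the same templates
#'
#' @param pair_a,pair_b `primer_pair` objects.
#' @param records gap-free labelled `seq_records`.
#' @param policy a [match_policy()].
#' @return list with `report_a`, `report_b` (coverage reports) and
#'   `contingency`, a named vector `both`/`a_only`/`b_only`/`neither`
#'   partitioning the (filtered) record set.
#' @export
compare_primer_sets <- function(pair_a, pair_b, records,
                                policy = match_policy()) {
  records <- apply_policy_filters(records, policy)
  # reports re-filter harmlessly (idempotent)
  rep_a <- coverage_report(pair_a, records, policy)
  rep_b <- coverage_report(pair_b, records, policy)
  a_ids <- unique(rep_a$hits$template_id)
  b_ids <- unique(rep_b$hits$template_id)
  in_a <- records$id %in% a_ids
  in_b <- records$id %in% b_ids
  contingency <- c(both = sum(in_a & in_b), a_only = sum(in_a & !in_b),
                   b_only = sum(!in_a & in_b), neither = sum(!in_a & !in_b))
  list(report_a = rep_a, report_b = rep_b, contingency = contingency,
       n_records = nrow(records))
}
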