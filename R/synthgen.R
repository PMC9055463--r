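# Seeded generator of synthetic 16S-like genus families: a shared conserved
# backbone with genus-private "signature" windows (emulating hypervariable
# regions) at configurable divergence, plus within-genus point mutations and
# alignment-tracked indels outside the signature windows.

#' Synthetic family configuration
#'
#' Defaults produce the study conditions used throughout the test-suite:
#' three genera of ten sequences on a 1200-bp backbone, two signature
#' windows per genus (where genus variants diverge at 25% per site), 1%
#' within-genus point mutation, and a low indel rate confined to
#' non-signature regions so every genus retains a designable primer pair
#' with an amplicon in the 85-250 bp window.
#'
#' @param n_genera number of genera.
#' @param seqs_per_genus sequences per genus.
#' @param backbone_len conserved backbone length in bp.
#' @param n_signature_windows signature windows per genus (>= 2 so a
#'   forward/reverse pair exists).
#' @param signature_len_range signature window lengths (nt), sampled
#'   uniformly.
#' @param within_genus_mutation_rate per-site substitution probability
#'   applied independently to every sequence.
#' @param background_divergence per-site substitution probability used to
#'   derive each genus's private variant of every signature window from the
#'   backbone.
#' @param indel_rate per-site indel probability (half insertions, half
#'   single-base deletions), applied outside signature windows only.
#' @param amplicon_span inclusive range for the span from the first to the
#'   second signature window of a genus (primer footprints included), so a
#'   valid amplicon is guaranteed to exist.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genera = 3L, seqs_per_genus = 10L,
                         backbone_len = 1200L, n_signature_windows = 2L,
                         signature_len_range = c(18L, 25L),
                         within_genus_mutation_rate = 0.01,
                         background_divergence = 0.25,
                         indel_rate = 0.002,
                         amplicon_span = c(85L, 250L),
                         seed = 42L) {
  stopifnot(n_genera >= 1L, seqs_per_genus >= 1L,
            n_signature_windows >= 2L,
            within_genus_mutation_rate >= 0, within_genus_mutation_rate < 1,
            background_divergence >= 0, background_divergence < 1,
            indel_rate >= 0, indel_rate < 1,
            backbone_len > 2L * max(signature_len_range) + 300L)
  structure(list(n_genera = as.integer(n_genera),
                 seqs_per_genus = as.integer(seqs_per_genus),
                 backbone_len = as.integer(backbone_len),
                 n_signature_windows = as.integer(n_signature_windows),
                 signature_len_range = as.integer(signature_len_range),
                 within_genus_mutation_rate = within_genus_mutation_rate,
                 background_divergence = background_divergence,
                 indel_rate = indel_rate,
                 amplicon_span = as.integer(amplicon_span),
                 seed = as.integer(seed)),
            class = "synth_config")
}

random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

mutate_bases <- function(bases, rate) {
  if (rate <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  bases
}

#' Generate a synthetic labelled 16S-like family
#'
#' @param config a [synth_config()].
#' @return a `synth_family` list:
#'   \describe{
#'     \item{records}{unaligned `seq_records` with genus labels}
#'     \item{aligned}{the same sequences as an exact gapped alignment
#'       (built by construction, no aligner involved)}
#'     \item{taxonomy}{data.frame `id`, `genus`}
#'     \item{truth}{per genus: signature window coordinates on the backbone
#'       and on the alignment, and the genus-private window sequences}
#'   }
#' @export
synth_generate <- function(config = synth_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  L <- config$backbone_len
  backbone <- random_bases(L)

  # place each genus's signature windows: per genus a block of
  # n_signature_windows windows; the first and last window of a block are
  # separated so that (first window start .. last window end) spans a value
  # inside amplicon_span. Blocks of different genera do not overlap.
  windows <- list()   # per genus: data.frame start,end
  cursor <- 30L       # conserved margin at the 5' end
  for (g in seq_len(config$n_genera)) {
    lens <- sample(seq(config$signature_len_range[1],
                       config$signature_len_range[2]),
                   config$n_signature_windows, replace = TRUE)
    # sample the block span away from the window edges so per-template
    # indel drift between the two signature windows cannot push every
    # product outside the amplicon window
    margin <- min(10L, (config$amplicon_span[2] - config$amplicon_span[1]) %/% 4L)
    span <- sample(seq(config$amplicon_span[1] + margin,
                       config$amplicon_span[2] - margin), 1L)
    inner <- span - sum(lens)
    if (inner < 3L * (config$n_signature_windows - 1L)) {
      span <- sum(lens) + 3L * (config$n_signature_windows - 1L)
      inner <- span - sum(lens)
    }
    gaps <- rep(inner %/% (config$n_signature_windows - 1L),
                config$n_signature_windows - 1L)
    gaps[1] <- gaps[1] + inner %% (config$n_signature_windows - 1L)
    starts <- integer(config$n_signature_windows)
    s <- cursor
    for (w in seq_len(config$n_signature_windows)) {
      starts[w] <- s
      s <- s + lens[w] + if (w < config$n_signature_windows) gaps[w] else 0L
    }
    block_end <- starts[length(starts)] + lens[length(lens)] - 1L
    if (block_end > L - 30L) {
      stop("infeasible geometry: backbone_len ", L,
           " too short for ", config$n_genera, " genus blocks")
    }
    windows[[g]] <- data.frame(start = starts, end = starts + lens - 1L)
    cursor <- block_end + 60L   # conserved spacer between genus blocks
  }
  genus_names <- sprintf("Genus%02d", seq_len(config$n_genera))
  names(windows) <- genus_names

  # genus-private variant of every signature window (its own and the other
  # genera's): mutated copies of the backbone at background_divergence
  variants <- list()
  for (g in genus_names) {
    variants[[g]] <- list()
    for (h in genus_names) {
      win <- windows[[h]]
      variants[[g]][[h]] <- lapply(seq_len(nrow(win)), function(w) {
        mutate_bases(backbone[win$start[w]:win$end[w]],
                     config$background_divergence)
      })
    }
  }

  in_signature <- rep(FALSE, L)
  for (h in genus_names) {
    win <- windows[[h]]
    for (w in seq_len(nrow(win))) in_signature[win$start[w]:win$end[w]] <- TRUE
  }

  # per-sequence construction with alignment tracking: at each backbone
  # position a sequence contributes its (possibly substituted, possibly
  # deleted) base plus any insertion after it
  n_seqs <- config$n_genera * config$seqs_per_genus
  base_cell <- matrix("", nrow = n_seqs, ncol = L)  # "" = deleted
  ins_cell <- matrix("", nrow = n_seqs, ncol = L)
  ids <- character(n_seqs)
  genus_of <- character(n_seqs)
  row <- 0L
  for (g in genus_names) {
    # genus consensus: backbone with all signature windows replaced by this
    # genus's private variants
    consensus <- backbone
    for (h in genus_names) {
      win <- windows[[h]]
      for (w in seq_len(nrow(win))) {
        consensus[win$start[w]:win$end[w]] <- variants[[g]][[h]][[w]]
      }
    }
    for (k in seq_len(config$seqs_per_genus)) {
      row <- row + 1L
      ids[row] <- sprintf("%s_seq%02d", g, k)
      genus_of[row] <- g
      bases <- mutate_bases(consensus, config$within_genus_mutation_rate)
      base_cell[row, ] <- bases
      if (config$indel_rate > 0) {
        free <- which(!in_signature)
        free <- free[free > 20L & free < L - 20L]
        ev <- free[stats::runif(length(free)) < config$indel_rate]
        for (p in ev) {
          if (stats::runif(1) < 0.5) {
            base_cell[row, p] <- ""                  # deletion
          } else {
            ins_cell[row, p] <- sample(c("A", "C", "G", "T"), 1L)
          }
        }
      }
    }
  }

  # exact alignment: per backbone column, pad to max insertion length
  ins_len <- apply(nchar(ins_cell), 2L, max)
  aligned <- vapply(seq_len(n_seqs), function(i) {
    cols <- character(L)
    for (p in seq_len(L)) {
      b <- base_cell[i, p]
      if (b == "") b <- "-"
      ins <- ins_cell[i, p]
      if (ins_len[p] > 0L) {
        ins <- paste0(ins, strrep("-", ins_len[p] - nchar(ins)))
      }
      cols[p] <- paste0(b, ins)
    }
    paste(cols, collapse = "")
  }, character(1))
  unaligned <- gsub("-", "", aligned, fixed = TRUE)

  # backbone -> alignment coordinate map
  col_width <- 1L + ins_len
  aln_start_of <- cumsum(c(1L, col_width[-L]))
  truth <- lapply(genus_names, function(g) {
    win <- windows[[g]]
    list(windows = data.frame(
           start = win$start, end = win$end,
           aln_start = aln_start_of[win$start],
           aln_end = aln_start_of[win$end],
           stringsAsFactors = FALSE),
         private = vapply(variants[[g]][[g]], paste, character(1),
                          collapse = ""))
  })
  names(truth) <- genus_names

  structure(list(
    records = seq_records(ids, unaligned, genus = genus_of,
                          is_aligned = FALSE),
    aligned = seq_records(ids, aligned, genus = genus_of, is_aligned = TRUE),
    taxonomy = data.frame(id = ids, genus = genus_of,
                          stringsAsFactors = FALSE),
    truth = truth,
    backbone = paste(backbone, collapse = ""),
    config = config
  ), class = "synth_family")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic family to disk
#'
#' Writes `refs.fasta`, `refs.aln.fasta`, `tax.tsv` and `truth.json` into
#' `dir`.
#'
#' @param family a `synth_family` from [synth_generate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$records, file.path(dir, "refs.fasta"))
  write_fasta(family$aligned, file.path(dir, "refs.aln.fasta"))
  utils::write.table(family$taxonomy, file.path(dir, "tax.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(family$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate qPCR observations from known copy numbers
#'
#' Draws Cq values around the curve prediction with Gaussian noise:
#' `cq = predict_cq(curve, copies) + N(0, noise_sd)`, keeping the true
#' copies for parameter-recovery checks. By default copies span the
#' 1e2-1e7 six-level dilution series of a standard curve.
#'
#' @param curve a `standard_curve`.
#' @param copies true copy numbers (default `10^(2:7)`).
#' @param replicates technical replicates per copy level.
#' @param noise_sd Gaussian Cq noise standard deviation.
#' @param seed RNG seed.
#' @param genus,sample_prefix labels for the emitted observation table.
#' @return list with `observations` (data.frame `sample_id`, `genus`, `cq`,
#'   `replicate`) and `truth` (data.frame `sample_id`, `copies`).
#' @export
synth_cq <- function(curve, copies = 10^(2:7), replicates = 3L,
                     noise_sd = 0.2, seed = 1L, genus = "GenusA",
                     sample_prefix = "std") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample_id <- sprintf("%s%02d", sample_prefix, seq_along(copies))
  obs <- do.call(rbind, lapply(seq_along(copies), function(i) {
    data.frame(sample_id = sample_id[i], genus = genus,
               cq = predict_cq(curve, copies[i]) +
                 stats::rnorm(replicates, 0, noise_sd),
               replicate = seq_len(replicates), stringsAsFactors = FALSE)
  }))
  list(observations = obs,
       truth = data.frame(sample_id = sample_id, copies = copies,
                          stringsAsFactors = FALSE))
}
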