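# Primer compositional and thermodynamic evaluation.
#
# Nearest-neighbor energetics use the unified DNA/DNA parameter set
# (SantaLucia 1998 style): per-stack dH (kcal/mol) and dS (cal/mol/K),
# duplex initiation split by terminal base pair, entropy-based monovalent
# salt correction 0.368*(N-1)*ln[Na+], and dG at 37 C for dimer/hairpin
# screening.

# dH / dS indexed by the top-strand dinucleotide of a Watson-Crick stack;
# the complementary orientation (e.g. TT for AA) shares the same value.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# dG at 37 C (kcal/mol) for the same stacks
NN_DG37 <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
             CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
             CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
             CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
# initiation terms by terminal base pair
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_CONSTANT <- 1.9872  # cal/mol/K

# hairpin loop initiation dG37 (kcal/mol) by loop length; lengths beyond 30
# use the length-30 value (capped). Values interpolated between the
# tabulated anchors below.
HAIRPIN_LOOP_ANCHOR <- c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0,
                         `7` = 4.2, `8` = 4.3, `9` = 4.5, `10` = 4.4,
                         `12` = 4.6, `14` = 4.7, `16` = 4.8, `18` = 4.9,
                         `20` = 4.9, `25` = 5.2, `30` = 5.3)
HAIRPIN_LOOP_DG <- stats::approx(as.integer(names(HAIRPIN_LOOP_ANCHOR)),
                                 HAIRPIN_LOOP_ANCHOR, xout = 3:30)$y

hairpin_loop_penalty <- function(loop_len) {
  HAIRPIN_LOOP_DG[pmin(loop_len, 30L) - 2L]
}

#' Thermodynamic screening configuration
#'
#' @param dg_threshold kcal/mol at 37 C; hairpin/self-dimer/heterodimer
#'   structures more stable (more negative) than this fail the screen.
#' @param gc_range acceptable GC percentage window, inclusive.
#' @param gc_enforce "soft" (GC violations only penalize the design score)
#'   or "hard" (violations fail the primer).
#' @param na_mM monovalent salt concentration for the Tm salt correction.
#' @param oligo_nM total primer strand concentration for the Tm CT term.
#' @param tm_method method tag recorded in reports; only
#'   "nearest-neighbor-unified" is implemented.
#' @return a `thermo_config` list.
#' @export
thermo_config <- function(dg_threshold = -9, gc_range = c(50, 55),
                          gc_enforce = c("soft", "hard"), na_mM = 50,
                          oligo_nM = 200, tm_method = "nearest-neighbor-unified") {
  gc_enforce <- match.arg(gc_enforce)
  stopifnot(dg_threshold < 0, length(gc_range) == 2L,
            gc_range[1] <= gc_range[2], gc_range[1] >= 0, gc_range[2] <= 100,
            na_mM > 0, oligo_nM > 0)
  structure(list(dg_threshold = dg_threshold, gc_range = gc_range,
                 gc_enforce = gc_enforce, na_mM = na_mM, oligo_nM = oligo_nM,
                 tm_method = tm_method),
            class = "thermo_config")
}

#' GC content of a (possibly degenerate) primer
#'
#' @param sequence IUPAC DNA string.
#' @return for a concrete sequence, the GC percentage; for a degenerate one,
#'   a length-2 vector `c(min, max)` over all expansions.
#' @export
#' @examples
#' gc_content("ACCGCATACGTCCTACGG")  # 61.1
gc_content <- function(sequence) {
  bits <- iupac_bits(sequence)
  if (!length(bits)) stop("empty sequence")
  n <- length(bits)
  # per position: can the expansion place an A/T there? a G/C there?
  gc_possible <- bitwAnd(bits, 6L) > 0L   # C or G in code set
  at_possible <- bitwAnd(bits, 9L) > 0L   # A or T in code set
  gc_min <- 100 * sum(!at_possible) / n   # positions forced to G/C
  gc_max <- 100 * sum(gc_possible) / n
  if (gc_min == gc_max) gc_min else c(gc_min, gc_max)
}

#' GC clamp check
#'
#' Passes iff, in every expansion, at least one of the two 3'-terminal bases
#' is G/C and at most three of the five 3'-terminal bases are G/C (the
#' common "clamp but not GC-rich end" rule).
#'
#' @param sequence IUPAC DNA string, length >= 5, 5'->3'.
#' @return logical.
#' @export
gc_clamp <- function(sequence) {
  bits <- iupac_bits(sequence)
  n <- length(bits)
  if (n < 5L) stop("gc_clamp needs a primer of length >= 5")
  last2 <- bits[(n - 1L):n]
  last5 <- bits[(n - 4L):n]
  # worst case over expansions: clamp must hold even when ambiguous
  # positions resolve to A/T; the richness cap even when they resolve to G/C
  forced_gc <- function(b) bitwAnd(b, 9L) == 0L   # code set is within {C,G}
  can_gc <- function(b) bitwAnd(b, 6L) > 0L
  any(forced_gc(last2)) && sum(can_gc(last5)) <= 3L
}

# dH/dS/Tm for one concrete ACGT sequence
tm_concrete <- function(sequence, config) {
  n <- nchar(sequence)
  stacks <- substring(sequence, 1:(n - 1), 2:n)
  dh <- sum(NN_DH[stacks])
  ds <- sum(NN_DS[stacks])
  for (term in c(substr(sequence, 1, 1), substr(sequence, n, n))) {
    key <- if (term %in% c("G", "C")) "GC" else "AT"
    dh <- dh + INIT_DH[[key]]
    ds <- ds + INIT_DS[[key]]
  }
  selfcomp <- identical(sequence, reverse_complement(sequence))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1) * log(config$na_mM / 1000)
  ct <- config$oligo_nM * 1e-9 / if (selfcomp) 1 else 4
  1000 * dh / (ds + GAS_CONSTANT * log(ct)) - 273.15
}

#' Nearest-neighbor melting temperature
#'
#' Unified DNA/DNA nearest-neighbor parameters with duplex initiation,
#' self-complementarity correction, and entropy-based monovalent salt
#' correction. Degenerate primers are expanded and summarized over
#' expansions.
#'
#' @param sequence IUPAC DNA string, length >= 10; 'N' is rejected.
#' @param config a [thermo_config()].
#' @return list with `tm` (per-expansion values, named by expansion),
#'   `tm_min`, `tm_max`, `tm_mean` in degrees C.
#' @export
melting_temperature <- function(sequence, config = thermo_config()) {
  bits <- iupac_bits(sequence)
  if (length(bits) < 10L) stop("melting_temperature needs length >= 10")
  if (any(bits == 15L)) stop("sequence contains N: unbounded expansion")
  expansions <- expand_degenerate(sequence)
  tms <- vapply(expansions, tm_concrete, numeric(1), config = config)
  list(tm = tms, tm_min = min(tms), tm_max = max(tms), tm_mean = mean(tms))
}

#' Duplex (dimer) free energy at 37 C
#'
#' Slides `seq_b` antiparallel against `seq_a` over every ungapped offset,
#' finds contiguous runs of Watson-Crick complementary positions, and sums
#' nearest-neighbor stack dG37 within each run. Returns the most negative
#' total over all offsets, or 0 when no complementary dinucleotide stack
#' exists anywhere. Self-dimers use `seq_b = seq_a`.
#'
#' @param seq_a,seq_b concrete ACGT sequences, 5'->3'.
#' @return dG in kcal/mol, always <= 0.
#' @export
duplex_delta_g <- function(seq_a, seq_b = seq_a) {
  a <- iupac_bits(seq_a)
  b <- iupac_bits(seq_b)
  if (any(POPCOUNT4[c(a, b)] != 1L)) {
    stop("duplex_delta_g expects concrete ACGT sequences")
  }
  achars <- strsplit(toupper(seq_a), "")[[1]]
  na <- length(a); nb <- length(b)
  rb <- rev(comp_bits(b))  # b 3'->5', complemented: pairing test is equality
  best <- 0
  for (off in (-(nb - 1L)):(na - 1L)) {
    i1 <- max(1L, 1L + off); i2 <- min(na, nb + off)
    if (i2 <= i1) next  # need at least 2 paired positions for a stack
    ai <- i1:i2
    paired <- a[ai] == rb[ai - off]
    if (sum(paired) < 2L) next
    # dG over contiguous complementary runs at this offset
    total <- 0
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      pos <- ai[starts[k]:ends[k]]
      stacks <- paste0(achars[pos[-length(pos)]], achars[pos[-1]])
      total <- total + sum(NN_DG37[stacks])
    }
    if (total < best) best <- total
  }
  best
}

#' Hairpin free energy at 37 C
#'
#' Enumerates all stem/loop decompositions with stem length >= 3 bp and loop
#' length >= 3 nt; each decomposition scores the nearest-neighbor stack sum
#' of the stem plus a tabulated loop-initiation penalty (capped at the
#' 30-nt value). Returns the most negative total, or 0 if no decomposition
#' is stable.
#'
#' @param sequence concrete ACGT sequence.
#' @return dG in kcal/mol, always <= 0.
#' @export
hairpin_delta_g <- function(sequence) {
  bits <- iupac_bits(sequence)
  if (any(POPCOUNT4[bits] != 1L)) {
    stop("hairpin_delta_g expects a concrete ACGT sequence")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  cb <- comp_bits(bits)
  n <- length(bits)
  best <- 0
  if (n < 9L) return(0)  # 3 + 3 + 3 minimum geometry
  for (i in seq_len(n - 8L)) {              # 5' arm start
    for (t in 3L:((n - 3L) %/% 2L)) {       # stem length
      jmin <- i + 2L * t + 2L               # 3' arm end (loop >= 3)
      if (jmin > n) break
      for (j in jmin:n) {
        k <- 0:(t - 1L)
        if (all(bits[i + k] == cb[j - k])) {
          stacks <- paste0(chars[i + 0:(t - 2L)], chars[i + 1:(t - 1L)])
          dg <- sum(NN_DG37[stacks]) + hairpin_loop_penalty(j - i - 2L * t + 1L)
          if (dg < best) best <- dg
        }
      }
    }
  }
  best
}

#' Full thermodynamic profile of one primer
#'
#' Degenerate primers are scored pessimistically: the minimum Tm and the
#' most negative hairpin/self-dimer dG over all expansions drive the
#' pass/fail flags, since the worst oligo in the synthesis mix governs
#' artefact formation.
#'
#' @param sequence IUPAC DNA string (a primer, 5'->3').
#' @param config a [thermo_config()].
#' @param name optional primer name carried into the profile.
#' @return a `thermo_profile` list: length, degeneracy, gc_min/gc_max,
#'   tm_min/tm_max/tm_mean, hairpin_dg, self_dimer_dg, gc_clamp_ok, and a
#'   named logical `passes` (dg, gc, clamp) plus `pass_all`.
#' @export
evaluate_primer <- function(sequence, config = thermo_config(), name = NA_character_) {
  bits <- iupac_bits(sequence)
  if (length(bits) < 10L) stop("primer length must be >= 10")
  if (any(bits == 15L)) stop("primer contains N: rejected (unbounded degeneracy)")
  deg <- degeneracy(sequence)
  gc <- gc_content(sequence)
  gc_min <- gc[1]; gc_max <- gc[length(gc)]
  tm <- melting_temperature(sequence, config)
  expansions <- expand_degenerate(sequence)
  hp <- min(vapply(expansions, hairpin_delta_g, numeric(1)))
  sd <- min(vapply(expansions, function(e) duplex_delta_g(e, e), numeric(1)))
  clamp <- gc_clamp(sequence)
  dg_ok <- hp > config$dg_threshold && sd > config$dg_threshold
  gc_in_range <- gc_min >= config$gc_range[1] && gc_max <= config$gc_range[2]
  gc_ok <- if (config$gc_enforce == "hard") gc_in_range else TRUE
  passes <- c(dg = dg_ok, gc = gc_ok, clamp = TRUE)  # clamp is advisory
  structure(list(
    name = name, sequence = toupper(sequence), length = length(bits),
    degeneracy = deg, gc_min = gc_min, gc_max = gc_max,
    tm_min = tm$tm_min, tm_max = tm$tm_max, tm_mean = tm$tm_mean,
    hairpin_dg = hp, self_dimer_dg = sd, gc_clamp_ok = clamp,
    gc_in_range = gc_in_range,
    passes = passes, pass_all = all(passes),
    # soft penalties counted by the design score
    soft_violations = sum(!gc_in_range, !clamp)
  ), class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat(sprintf(
    "primer %s (%d nt, degeneracy %d)\n  GC %.1f-%.1f%%  Tm %.1f-%.1f C  hairpin %.2f  self-dimer %.2f kcal/mol\n  clamp %s  passes: %s\n",
    ifelse(is.na(x$name), x$sequence, x$name), x$length, x$degeneracy,
    x$gc_min, x$gc_max, x$tm_min, x$tm_max, x$hairpin_dg, x$self_dimer_dg,
    x$gc_clamp_ok, paste(names(x$passes)[x$passes], collapse = ",")))
  invisible(x)
}

#' Thermodynamic profiles for every primer in a panel
#'
#' @param panel data.frame from [read_panel()].
#' @param config a [thermo_config()].
#' @return data.frame with one row per primer.
#' @export
panel_thermo <- function(panel, config = thermo_config()) {
  profs <- lapply(seq_len(nrow(panel)), function(i) {
    p <- evaluate_primer(panel$sequence[i], config, name = panel$primer_name[i])
    data.frame(genus = panel$genus[i], primer_name = p$name,
               sequence = p$sequence, length = p$length,
               degeneracy = p$degeneracy, gc_min = p$gc_min, gc_max = p$gc_max,
               tm_min = p$tm_min, tm_max = p$tm_max, tm_mean = p$tm_mean,
               hairpin_dg = p$hairpin_dg, self_dimer_dg = p$self_dimer_dg,
               gc_clamp_ok = p$gc_clamp_ok, pass_all = p$pass_all,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, profs)
}
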