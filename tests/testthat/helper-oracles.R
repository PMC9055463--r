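# Independent brute-force oracles. These deliberately re-derive everything
# from their own literal tables and naive loops; they share no code with the
# package internals they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# naive per-position scan; degenerate primer code matches a template char
# iff the template char is concrete and inside the code's set (strict
# policy), or the two sets intersect (permissive)
oracle_matches <- function(primer, template, max_mm = 0L, zone = 5L,
                           orientation = "forward",
                           allow_degenerate_template = FALSE) {
  p <- strsplit(toupper(primer), "")[[1]]
  if (orientation == "reverse") {
    p <- strsplit(oracle_revcomp(paste(p, collapse = "")), "")[[1]]
  }
  tpl <- strsplit(toupper(template), "")[[1]]
  m <- length(p); n <- length(tpl)
  zone <- min(zone, m)
  zone_idx <- if (zone == 0L) integer(0) else if (orientation == "forward") {
    (m - zone + 1L):m
  } else seq_len(zone)
  hits <- NULL
  if (m > n) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  for (s in 1:(n - m + 1L)) {
    mism <- integer(0)
    for (k in 1:m) {
      tc <- tpl[s + k - 1L]
      pc_set <- ORACLE_IUPAC[[p[k]]]
      ok <- if (allow_degenerate_template) {
        length(intersect(ORACLE_IUPAC[[tc]], pc_set)) > 0L
      } else {
        tc %in% c("A", "C", "G", "T") && tc %in% pc_set
      }
      if (!ok) mism <- c(mism, k)
      if (length(mism) > max_mm) break   # cannot become a hit
    }
    if (length(mism) <= max_mm && !any(mism %in% zone_idx)) {
      hits <- rbind(hits, data.frame(start = s, end = s + m - 1L,
                                     mismatches = length(mism)))
    }
  }
  if (is.null(hits)) {
    data.frame(start = integer(), end = integer(), mismatches = integer())
  } else hits
}

oracle_simulate <- function(fw, rv, template, max_mm = 0L, zone = 5L,
                            guard = c(50L, 2000L)) {
  fh <- oracle_matches(fw, template, max_mm, zone, "forward")
  rh <- oracle_matches(rv, template, max_mm, zone, "reverse")
  out <- NULL
  if (nrow(fh) && nrow(rh)) {
    for (i in seq_len(nrow(fh))) {
      for (j in seq_len(nrow(rh))) {
        len <- rh$end[j] - fh$start[i] + 1L
        if (fh$start[i] < rh$end[j] && len >= guard[1] && len <= guard[2]) {
          out <- rbind(out, data.frame(fw_start = fh$start[i],
                                       rv_end = rh$end[j],
                                       amplicon_len = len))
        }
      }
    }
  }
  if (is.null(out)) {
    data.frame(fw_start = integer(), rv_end = integer(),
               amplicon_len = integer())
  } else out[order(out$fw_start, out$rv_end), , drop = FALSE]
}

# unified nearest-neighbor dG37 stack table (kcal/mol), own literal copy
ORACLE_DG37 <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
                 CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
                 CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
                 CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)

# most negative dG over all antiparallel offsets, naive double loop
oracle_duplex_dg <- function(a, b = a) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0
  for (off in (-(nb - 1L)):(na - 1L)) {
    paired <- logical(na)
    for (i in 1:na) {
      j <- nb - (i - off) + 1L  # antiparallel partner in b
      paired[i] <- j >= 1L && j <= nb && ORACLE_COMP[[av[i]]] == bv[j]
    }
    total <- 0
    run <- 0L
    for (i in 1:na) {
      if (paired[i]) run <- run + 1L else run <- 0L
      if (run >= 2L) total <- total + ORACLE_DG37[[paste0(av[i - 1L], av[i])]]
    }
    # runs scored cumulatively above: each adjacent paired duo adds a stack
    if (total < best) best <- total
  }
  best
}

ORACLE_LOOP_DG <- local({
  anchors_n <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
  anchors_g <- c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.4, 4.6, 4.7, 4.8,
                 4.9, 4.9, 5.2, 5.3)
  stats::approx(anchors_n, anchors_g, xout = 3:30)$y
})

# exhaustive stem/loop enumeration: stem >= 3 bp, loop >= 3 nt
oracle_hairpin_dg <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  n <- length(v)
  best <- 0
  for (i in seq_len(max(n - 8L, 0L))) {
    for (j in (i + 8L):n) {
      if (j > n) break
      max_t <- (j - i - 2L) %/% 2L
      for (t in 3L:max_t) {
        if (max_t < 3L) break
        loop <- j - i - 2L * t + 1L
        if (loop < 3L) next
        ok <- TRUE
        for (k in 0:(t - 1L)) {
          if (ORACLE_COMP[[v[i + k]]] != v[j - k]) { ok <- FALSE; break }
        }
        if (!ok) next
        dg <- ORACLE_LOOP_DG[min(loop, 30L) - 2L]
        for (k in 0:(t - 2L)) dg <- dg + ORACLE_DG37[[paste0(v[i + k], v[i + k + 1L])]]
        if (dg < best) best <- dg
      }
    }
  }
  best
}

# hand-summation nearest-neighbor Tm with its own literal dH/dS tables
oracle_tm <- function(s, na_mM = 50, oligo_nM = 200) {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  v <- strsplit(toupper(s), "")[[1]]
  n <- length(v)
  H <- 0; S <- 0
  for (i in 1:(n - 1L)) {
    H <- H + dH[[paste0(v[i], v[i + 1L])]]
    S <- S + dS[[paste0(v[i], v[i + 1L])]]
  }
  for (term in v[c(1L, n)]) {
    if (term %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  selfcomp <- identical(paste(v, collapse = ""), oracle_revcomp(s))
  if (selfcomp) S <- S - 1.4
  S <- S + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9 / if (selfcomp) 1 else 4
  1000 * H / (S + 1.9872 * log(ct)) - 273.15
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

panel_path <- function() {
  system.file("extdata", "genus_primer_panel.tsv", package = "genusprimer")
}

synthetic_refs_path <- function() {
  system.file("extdata", "synthetic_type_strain_16s.fasta",
              package = "genusprimer")
}
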