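# Reading/writing the external formats: FASTA (plain or gapped SILVA-style
# alignments), taxonomy TSV, the primer panel TSV, and report export.

#' Sequence record collections
#'
#' A `seq_records` object is a data.frame with columns `id`, `genus` and
#' `residues` plus an `is_aligned` attribute. Residues are uppercase IUPAC
#' DNA; `U` is normalized to `T` and the SILVA gap dialect `.` to `-` at
#' ingest. An empty `genus` marks an unlabelled/background sequence.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences.
#' @param genus genus labels ("" = unlabelled); recycled if length 1.
#' @param is_aligned logical; if NULL, inferred: TRUE iff any record contains
#'   a gap and all lengths are equal.
#' @return a `seq_records` data.frame.
#' @export
seq_records <- function(id, residues, genus = "", is_aligned = NULL) {
  id <- as.character(id)
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1])
  }
  residues <- normalize_residues(residues)
  genus <- rep_len(as.character(genus), length(id))
  genus[is.na(genus)] <- ""
  lens <- nchar(residues)
  if (is.null(is_aligned)) {
    is_aligned <- length(residues) > 0L &&
      any(grepl("-", residues, fixed = TRUE)) &&
      length(unique(lens)) == 1L
  }
  if (is_aligned && length(unique(lens)) > 1L) {
    stop("aligned records must all have equal length")
  }
  out <- data.frame(id = id, genus = genus, residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  attr(out, "is_aligned") <- is_aligned
  out
}

normalize_residues <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- gsub(".", "-", x, fixed = TRUE)
  bad <- regexpr("[^ACGTRYSWKMBDHVN-]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("invalid residue '", substr(x[i], bad[i], bad[i]),
         "' in sequence ", i)
  }
  x
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("seq_records: %d sequences (%s)\n", nrow(x),
              if (isTRUE(attr(x, "is_aligned"))) "aligned" else "unaligned"))
  NextMethod()
}

#' Is a record collection aligned?
#' @param records a `seq_records` object.
#' @return logical flag.
#' @export
is_aligned <- function(records) isTRUE(attr(records, "is_aligned"))

#' Read a FASTA file into a `seq_records` collection
#'
#' Accepts plain and gapped (aligned) FASTA; both `-` and the SILVA `.` are
#' treated as gaps, lowercase is uppercased and `U` becomes `T`. The
#' collection is flagged aligned iff any record contains a gap and all
#' records have equal length.
#'
#' @param path FASTA file.
#' @param taxonomy optional taxonomy map from [read_taxonomy()]; genus labels
#'   are attached by id (unmapped ids get the empty genus).
#' @return a `seq_records` collection.
#' @export
read_fasta <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  recs <- seq_records(id = ids, residues = as.character(set))
  if (!is.null(taxonomy)) {
    recs$genus <- taxonomy_lookup(taxonomy, recs$id)
  }
  recs
}

#' Write a `seq_records` collection as FASTA
#'
#' @param records a `seq_records` collection.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$residues[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a taxonomy map (id <TAB> genus)
#'
#' @param path two-column TSV, no header required (a header line
#'   `id<TAB>genus` is tolerated and skipped).
#' @return a named character vector usable with [taxonomy_lookup()].
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "genus"))
  if (nrow(tab) && identical(tolower(tab$id[1]), "id")) tab <- tab[-1, , drop = FALSE]
  if (any(!nzchar(tab$id))) stop("taxonomy map contains an empty id")
  stats::setNames(tab$genus, tab$id)
}

#' Look up genus labels for sequence ids
#'
#' Unmapped ids return the empty genus (background), never an error.
#'
#' @param taxonomy named character vector (id -> genus).
#' @param ids character vector of ids.
#' @return character vector of genus labels.
#' @export
taxonomy_lookup <- function(taxonomy, ids) {
  out <- unname(taxonomy[ids])
  out[is.na(out)] <- ""
  out
}

#' Map an alignment column to its position in the gap-stripped sequence
#'
#' Coordinates are 1-based: `aligned_col` indexes the gapped string and the
#' return value indexes the same residue in the gap-free sequence.
#'
#' @param record one row of an aligned `seq_records` collection (or any list
#'   with a `residues` string).
#' @param aligned_col 1-based alignment column; must not be a gap for this
#'   record.
#' @return 1-based position in the ungapped sequence.
#' @export
#' @examples
#' r <- seq_records("s1", "AC-GT", is_aligned = TRUE)
#' ungapped_position(r[1, ], 4)  # 3
ungapped_position <- function(record, aligned_col) {
  s <- record$residues[[1]]
  n <- nchar(s)
  if (aligned_col < 1L || aligned_col > n) {
    stop("aligned_col ", aligned_col, " outside alignment of length ", n)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (chars[aligned_col] == "-") {
    stop("alignment column ", aligned_col, " is a gap for record '",
         record$id[[1]], "'")
  }
  sum(chars[seq_len(aligned_col)] != "-")
}

#' Remove gaps from a record collection
#'
#' @param records a `seq_records` collection.
#' @return the same collection with gaps stripped and `is_aligned = FALSE`.
#' @export
strip_gaps <- function(records) {
  seq_records(records$id, gsub("-", "", records$residues, fixed = TRUE),
              genus = records$genus, is_aligned = FALSE)
}

# ---- primer panel ----------------------------------------------------------

PANEL_COLUMNS <- c("genus", "primer_name", "sequence", "amplicon_size",
                   "annealing_tm", "efficiency_pct", "r_squared")

#' Read a genus-specific primer panel TSV
#'
#' The panel lists two primers (forward, reverse) per genus with the
#' validated amplicon size, annealing temperature, qPCR efficiency and
#' standard-curve R-squared. The panel distributed with the package
#' (`system.file("extdata", "genus_primer_panel.tsv", package =
#' "genusprimer")`) carries the 11-genus fish-microbiome panel.
#'
#' @param path TSV with header columns
#'   genus/primer_name/sequence/amplicon_size/annealing_tm/efficiency_pct/r_squared.
#' @return data.frame of panel rows; primer names ending in `-F`/`-R` set the
#'   `orientation` column.
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  missing_cols <- setdiff(PANEL_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(tab))) {
    seqchars <- gsub("[ACGTRYSWKMBDHVN]", "", toupper(tab$sequence[i]))
    if (nzchar(seqchars)) {
      stop("panel row ", i, " (", tab$primer_name[i],
           "): non-IUPAC character(s) '", seqchars, "' in sequence")
    }
  }
  tab$sequence <- toupper(tab$sequence)
  for (col in c("amplicon_size", "annealing_tm", "efficiency_pct", "r_squared")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  if (any(!is.na(tab$amplicon_size) & tab$amplicon_size <= 0)) {
    stop("amplicon_size must be positive")
  }
  tab$orientation <- ifelse(grepl("[-_.]?(F|Fw|FWD)$", tab$primer_name, ignore.case = FALSE),
                            "forward",
                            ifelse(grepl("[-_.]?(R|Rv|REV)$", tab$primer_name),
                                   "reverse", NA_character_))
  tab
}

#' Extract one primer pair from a panel
#'
#' @param panel data.frame from [read_panel()].
#' @param genus genus to extract.
#' @return a `primer_pair` list with elements `fw` and `rv` (each a list with
#'   `name`, `sequence`, `orientation`) plus the panel's `amplicon_size`.
#' @export
panel_pair <- function(panel, genus) {
  rows <- panel[panel$genus == genus, , drop = FALSE]
  if (nrow(rows) != 2L) {
    stop("panel has ", nrow(rows), " rows for genus '", genus, "', expected 2")
  }
  fw <- rows[match("forward", rows$orientation), ]
  rv <- rows[match("reverse", rows$orientation), ]
  if (anyNA(fw$primer_name) || anyNA(rv$primer_name)) {
    stop("could not identify forward/reverse primer for genus '", genus, "'")
  }
  structure(list(
    genus = genus,
    fw = list(name = fw$primer_name, sequence = fw$sequence, orientation = "forward"),
    rv = list(name = rv$primer_name, sequence = rv$sequence, orientation = "reverse"),
    amplicon_size = fw$amplicon_size
  ), class = "primer_pair")
}

# ---- report export ---------------------------------------------------------

#' Write a tabular report as TSV or JSON
#'
#' Column order is fixed by the data.frame, writing is deterministic (no
#' timestamps, fixed number formatting), so writing the same object twice
#' yields byte-identical files.
#'
#' @param report a data.frame (any report produced by the design, insilico or
#'   quant modules).
#' @param path output file.
#' @param format "tsv" or "json".
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  report <- as.data.frame(report)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}
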