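# qPCR standard-curve fitting, efficiency QC, copy-number estimation and
# rank-correlation concordance against metagenomic relative abundance.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies). Replicate Cq values at the
#' same dilution level are averaged before fitting by default (set
#' `average_replicates = FALSE` to fit on raw replicates). Amplification
#' efficiency is the universal convention
#' `E% = 100 * (10^(-1/slope) - 1)`, so the textbook slope -3.3219
#' (= -1/log10(2)) gives 100%.
#'
#' @param log10_copies numeric vector of log10 template copies per reaction
#'   (e.g. 2:7 for a 1e2-1e7 dilution series).
#' @param cq matching Cq values.
#' @param average_replicates average Cq per level before fitting.
#' @return a `standard_curve`: slope, intercept, r_squared, efficiency_pct,
#'   n_points, `slope_se`, `valid` (FALSE for non-negative slopes), and the
#'   underlying `lm` fit.
#' @export
fit_standard_curve <- function(log10_copies, cq, average_replicates = TRUE) {
  stopifnot(length(log10_copies) == length(cq))
  keep <- is.finite(log10_copies) & is.finite(cq)
  log10_copies <- log10_copies[keep]; cq <- cq[keep]
  if (length(unique(log10_copies)) < 3L) {
    stop("standard curve needs at least 3 distinct log10 copy levels")
  }
  if (average_replicates) {
    lev <- sort(unique(log10_copies))
    cq <- as.numeric(tapply(cq, factor(log10_copies, levels = lev), mean))
    log10_copies <- lev
  }
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # exact dilution series legitimately fit perfectly; the summary warning
  # about it is noise here
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = slope, intercept = intercept,
    r_squared = sm$r.squared,
    efficiency_pct = 100 * (10^(-1 / slope) - 1),
    slope_se = sm$coefficients[2, 2],
    n_points = length(cq),
    valid = slope < 0,
    fit = fit
  ), class = "standard_curve")
}

#' Build a standard-curve object from known parameters
#'
#' Convenience constructor for simulation and for curves reported without
#' raw dilution data.
#'
#' @param slope Cq change per log10 copies (negative for a valid curve).
#' @param intercept Cq at 1 copy (log10 = 0).
#' @param r_squared optional fit quality.
#' @return a `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 efficiency_pct = 100 * (10^(-1 / slope) - 1),
                 slope_se = NA_real_, n_points = NA_integer_,
                 valid = slope < 0, fit = NULL),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: Cq = %.4f * log10(copies) + %.4f  (R2 %s, efficiency %.1f%%%s)\n",
    x$slope, x$intercept,
    if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
    x$efficiency_pct, if (x$valid) "" else ", INVALID slope"))
  invisible(x)
}

#' Efficiency quality control
#'
#' @param curve a `standard_curve`.
#' @param window inclusive acceptable efficiency window in percent; the
#'   default is the 92-105.5% band within which all primers of the
#'   distributed panel fall.
#' @return logical.
#' @export
efficiency_qc <- function(curve, window = c(92, 105.5)) {
  curve$efficiency_pct >= window[1] & curve$efficiency_pct <= window[2]
}

#' Predicted Cq for a given copy number
#'
#' @param curve a `standard_curve`.
#' @param copies template copies (> 0).
#' @return Cq values.
#' @export
predict_cq <- function(curve, copies) {
  stopifnot(all(copies > 0))
  curve$slope * log10(copies) + curve$intercept
}

#' Copy number from an observed Cq
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept)/slope)`.
#'
#' @param curve a valid `standard_curve`.
#' @param cq observed quantification cycles.
#' @return copy numbers (always positive).
#' @export
copies_from_cq <- function(curve, cq) {
  if (!isTRUE(curve$valid)) stop("standard curve is invalid (slope >= 0)")
  10^((cq - curve$intercept) / curve$slope)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive averaged ranks). A
#' constant input has no defined rank correlation and returns NA (not 0)
#' with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or NA for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("spearman_rho needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rank correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"), method = "pearson")
}

#' Mean copy number per sample and genus from qPCR observations
#'
#' @param observations data.frame with columns `sample_id`, `genus`, `cq`
#'   (replicates as repeated rows).
#' @param curves either one `standard_curve` applied to all genera or a
#'   named list of curves keyed by genus.
#' @return data.frame `sample_id`, `genus`, `mean_cq`, `copies` (copies are
#'   computed from the replicate-mean Cq).
#' @export
quantify_samples <- function(observations, curves) {
  stopifnot(all(c("sample_id", "genus", "cq") %in% names(observations)))
  key <- interaction(observations$sample_id, observations$genus, drop = TRUE)
  agg <- do.call(rbind, lapply(split(observations, key), function(d) {
    data.frame(sample_id = d$sample_id[1], genus = d$genus[1],
               mean_cq = mean(d$cq), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$copies <- vapply(seq_len(nrow(agg)), function(i) {
    curve <- if (inherits(curves, "standard_curve")) curves else
      curves[[agg$genus[i]]]
    if (is.null(curve)) stop("no standard curve for genus '", agg$genus[i], "'")
    copies_from_cq(curve, agg$mean_cq[i])
  }, numeric(1))
  agg[order(agg$genus, agg$sample_id), , drop = FALSE]
}

#' Concordance between qPCR copy number and metagenomic relative abundance
#'
#' Inner-joins the two tables on sample id for one genus and computes the
#' Spearman correlation between copy number (raw, or converted to per-sample
#' percentages across the genera present in the copy table with
#' `value = "percent"`) and relative abundance.
#'
#' @param copies_table data.frame `sample_id`, `genus`, `copies` (e.g. from
#'   [quantify_samples()]).
#' @param abundance_table data.frame `sample_id`, `genus`,
#'   `relative_abundance` (percent).
#' @param genus genus to correlate.
#' @param value "copies" (raw copy number) or "percent" (copies as a
#'   percentage of the per-sample total over all genera in `copies_table`).
#' @return a `concordance_result`: genus, n, spearman_rho, and the joined
#'   `pairs` table.
#' @export
concordance <- function(copies_table, abundance_table, genus,
                        value = c("copies", "percent")) {
  value <- match.arg(value)
  stopifnot(all(c("sample_id", "genus", "copies") %in% names(copies_table)),
            all(c("sample_id", "genus", "relative_abundance") %in%
                  names(abundance_table)))
  ct <- copies_table
  if (value == "percent") {
    tot <- tapply(ct$copies, ct$sample_id, sum)
    ct$copies <- 100 * ct$copies / as.numeric(tot[as.character(ct$sample_id)])
  }
  a <- ct[ct$genus == genus, c("sample_id", "copies")]
  b <- abundance_table[abundance_table$genus == genus,
                       c("sample_id", "relative_abundance")]
  joined <- merge(a, b, by = "sample_id")
  if (nrow(joined) < 3L) {
    stop("fewer than 3 shared samples for genus '", genus, "'")
  }
  joined <- joined[order(joined$sample_id), , drop = FALSE]
  rownames(joined) <- NULL
  structure(list(genus = genus, n = nrow(joined),
                 spearman_rho = spearman_rho(joined$copies,
                                             joined$relative_abundance),
                 value = value, pairs = joined),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance for %s (n = %d, %s): Spearman rho = %.3f\n",
              x$genus, x$n, x$value, x$spearman_rho))
  invisible(x)
}
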