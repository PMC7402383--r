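#' Fraction of a read's bases at or above a quality score
#'
#' For each read, \%HighQ(q) = (number of bases with Phred score >= q) /
#' (number of all bases). \%HighQ(0) is always 1, and \%HighQ(q) = 1 exactly
#' when the read's MinimalQ is >= q.
#'
#' @param reads A \code{ShortReadQ} of non-empty reads.
#' @param q Integer Phred threshold.
#' @return Numeric vector in [0, 1], one value per read.
#' @export
percent_high_q <- function(reads, q) {
  qm <- check_nonempty(reads)
  rowMeans(qm >= q, na.rm = TRUE)
}

#' Minimum base quality of each read
#'
#' MinimalQ, the minimum Phred score among a read's bases; equivalently the
#' largest q with \%HighQ(q) = 1.
#'
#' @inheritParams percent_high_q
#' @return Integer vector, one value per read.
#' @export
minimal_q <- function(reads) {
  qm <- check_nonempty(reads)
  as.integer(apply(qm, 1L, min, na.rm = TRUE))
}

#' Categorize reads into high/medium/poor quality groups
#'
#' A read is HIGH when every base scores Q20 or above (MinimalQ >= 20), POOR
#' when more than 10\% of its bases score Q14 or less, and MEDIUM otherwise.
#' The POOR cutoff is strict: exactly 10\% low bases is MEDIUM. "Less than
#' Q15" and "Q14 or less" coincide for integer Phred scores; the
#' implementation tests \code{score <= 14}.
#'
#' @inheritParams percent_high_q
#' @param high_q MinimalQ cutoff for the HIGH group (default 20).
#' @param poor_q low-base score cutoff for the POOR rule (default 14, i.e.
#'   scores < 15 count as low).
#' @param poor_frac strict low-base fraction above which a read is POOR
#'   (default 0.10).
#' @return Factor with levels HIGH, MEDIUM, POOR.
#' @export
categorize_reads <- function(reads, high_q = 20L, poor_q = 14L,
                             poor_frac = 0.10) {
  qm <- check_nonempty(reads)
  mq <- as.integer(apply(qm, 1L, min, na.rm = TRUE))
  low <- rowMeans(qm <= poor_q, na.rm = TRUE)
  cat <- ifelse(mq >= high_q, "HIGH", ifelse(low > poor_frac, "POOR", "MEDIUM"))
  factor(cat, levels = c("HIGH", "MEDIUM", "POOR"))
}

check_nonempty <- function(reads) {
  stopifnot(is(reads, "ShortReadQ"))
  if (length(reads) == 0L) stop("empty read collection")
  if (any(BiocGenerics::width(reads) == 0L)) stop("empty read (zero length)")
  phred_matrix(reads)
}

#' Summarize pre-assembly base-quality statistics
#'
#' Computes the full pre-assembly bundle: basic statistics (read/base counts,
#' length range, base composition, per-read GC), the distribution of all base
#' quality scores, the distribution of per-read MinimalQ, the \%HighQ(q)
#' distribution over a grid of q values, the HIGH/MEDIUM/POOR category
#' fractions and the percentage of bases at Q30 or above.
#'
#' GC fraction is computed over non-N bases only; N bases still contribute
#' their (typically low) quality scores to the quality statistics.
#'
#' @inheritParams percent_high_q
#' @param q_grid Phred grid at which the \%HighQ distribution is reported.
#' @return An object of class \code{preassembly_summary} (a list).
#' @export
summarize_preassembly <- function(reads, q_grid = c(10L, 15L, 20L, 25L, 30L, 35L, 40L)) {
  qm <- check_nonempty(reads)
  sr <- ShortRead::sread(reads)
  w <- BiocGenerics::width(sr)
  af <- Biostrings::alphabetFrequency(sr)
  base_comp <- colSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  n_bases <- sum(w)
  # every non-ACGT letter (N, other IUPAC ambiguity codes) counts as N
  base_comp <- c(base_comp, N = n_bases - sum(base_comp))

  non_n <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  gc_read <- ifelse(non_n > 0, rowSums(af[, c("C", "G"), drop = FALSE]) / non_n, NA_real_)

  scores <- as.vector(qm)
  scores <- scores[!is.na(scores)]
  bq_dist <- tabulate(scores + 1L, nbins = 94L)
  names(bq_dist) <- 0:93

  mq <- as.integer(apply(qm, 1L, min, na.rm = TRUE))
  mq_dist <- tabulate(mq + 1L, nbins = 94L)
  names(mq_dist) <- 0:93

  probs <- seq(0, 1, by = 0.05)
  highq <- lapply(q_grid, function(q) {
    v <- rowMeans(qm >= q, na.rm = TRUE)
    list(quantiles = setNames(unname(quantile(v, probs = probs, names = FALSE)),
                              paste0("p", probs * 100)),
         mean = mean(v),
         frac_reads_all_high = mean(v == 1))
  })
  names(highq) <- paste0("q", q_grid)

  cats <- categorize_reads(reads)
  cat_frac <- prop.table(table(cats))

  structure(list(
    n_reads = length(reads),
    n_bases = n_bases,
    read_length = list(min = min(w), max = max(w), mean = round(mean(w), 1)),
    base_composition = as.list(base_comp),
    gc_distribution = list(
      mean = mean(gc_read, na.rm = TRUE),
      quantiles = setNames(unname(quantile(gc_read, probs = probs, na.rm = TRUE,
                                           names = FALSE)),
                           paste0("p", probs * 100))),
    base_quality_distribution = as.list(bq_dist[bq_dist > 0]),
    minimalq_distribution = as.list(mq_dist[mq_dist > 0]),
    highq_cdf = highq,
    category_fractions = as.list(setNames(as.numeric(cat_frac), names(cat_frac))),
    pct_bases_ge_q30 = 100 * sum(scores >= 30L) / length(scores)
  ), class = "preassembly_summary")
}

#' @export
print.preassembly_summary <- function(x, ...) {
  cat("Pre-assembly quality summary\n")
  cat(sprintf("  reads: %d   bases: %.0f   length: %d-%d (mean %.1f)\n",
              x$n_reads, x$n_bases, x$read_length$min, x$read_length$max,
              x$read_length$mean))
  cat(sprintf("  %% bases >= Q30: %.1f\n", x$pct_bases_ge_q30))
  cf <- unlist(x$category_fractions)
  cat(sprintf("  reads: HIGH %.1f%%  MEDIUM %.1f%%  POOR %.1f%%\n",
              100 * cf[["HIGH"]], 100 * cf[["MEDIUM"]], 100 * cf[["POOR"]]))
  invisible(x)
}
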