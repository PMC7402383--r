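#' Simulate a reference/scaffold sequence
#'
#' A seeded random DNA sequence of configurable GC content, used as the
#' mapping target for synthetic SAM fixtures.
#'
#' @param length Sequence length in bp.
#' @param gc Target GC fraction (default 0.5).
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A \code{DNAStringSet} of length one.
#' @export
sim_reference <- function(length = 20000L, gc = 0.5, seed = 1L, name = "ref_1") {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  setNames(Biostrings::DNAStringSet(s), name)
}

# Largest-remainder apportionment of n items to fractions summing to 1,
# so category counts are deterministic and sum exactly to n.
apportion <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(mix))
}

#' Simulate reads with controlled quality categories
#'
#' Generates reads whose quality strings are constructed to satisfy an
#' assigned HIGH/MEDIUM/POOR category by the package's own definitions:
#' HIGH reads have every base at Q20+; POOR reads have
#' \code{floor(0.1 * length) + 1} bases at Q14 or below (strictly more than
#' 10\%); MEDIUM reads have one base in Q15--Q19 and the rest at Q20+.
#' Category assignment is deterministic by count (largest remainder), so a
#' requested mix is recovered exactly; set \code{stochastic = TRUE} for
#' Bernoulli assignment instead.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bases.
#' @param category_mix Named fractions over HIGH/MEDIUM/POOR, summing to 1.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @param stochastic Assign categories by sampling rather than by count.
#' @param path Optional FASTQ output path.
#' @return List with \code{reads} (a \code{ShortReadQ}) and \code{truth}
#'   (factor of assigned categories).
#' @export
sim_quality_reads <- function(n_reads, read_length = 100L,
                              category_mix = c(HIGH = 1/3, MEDIUM = 1/3, POOR = 1/3),
                              seed = 1L, stochastic = FALSE, path = NULL) {
  stopifnot(n_reads >= 1, read_length >= 1)
  category_mix <- category_mix[c("HIGH", "MEDIUM", "POOR")]
  category_mix[is.na(category_mix)] <- 0
  names(category_mix) <- c("HIGH", "MEDIUM", "POOR")
  if (abs(sum(category_mix) - 1) > 1e-9) stop("category_mix must sum to 1")

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  if (stochastic) {
    cats <- sample(names(category_mix), n_reads, replace = TRUE,
                   prob = category_mix)
  } else {
    counts <- apportion(n_reads, category_mix)
    cats <- sample(rep(names(counts), counts))   # interleave deterministically
  }

  L <- as.integer(read_length)
  n_low <- as.integer(floor(0.10 * L)) + 1L      # strictly > 10% of bases
  qual <- vapply(cats, function(cat) {
    hi <- sample(20:40, L, replace = TRUE)
    if (cat == "MEDIUM") {
      hi[sample.int(L, 1L)] <- sample(15:19, 1L)
    } else if (cat == "POOR") {
      hi[sample.int(L, n_low)] <- sample(2:14, n_low, replace = TRUE)
    }
    intToUtf8(hi + 33L)
  }, character(1), USE.NAMES = FALSE)

  bases <- vapply(seq_len(n_reads), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))

  reads <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(bases),
    quality = ShortRead::FastqQuality(Biostrings::BStringSet(qual)),
    id = Biostrings::BStringSet(sprintf("read_%d", seq_len(n_reads))))
  if (!is.null(path)) write_fastq(reads, path)
  list(reads = reads, truth = factor(cats, levels = c("HIGH", "MEDIUM", "POOR")))
}

default_ratio_params <- function() {
  list(S = list(lo = 0.02, hi = 0.40, frac_hi = 0.5),
       C = list(lo = 0.10, hi = 0.50, frac_hi = 0.5),
       N = list(lo = 0.05, hi = 0.50, frac_hi = 0.5),
       O = list(lo = 0.02, hi = 0.40, frac_hi = 0.5))
}

#' Simulate a SAM file with known ground-truth read labels
#'
#' Emits a syntactically valid single-end SAM file whose FLAG/CIGAR/MD/NM/
#' AS/XA fields are constructed so that each read must receive its assigned
#' label: P perfect unique match; S planted substitutions with a consistent
#' MD tag; C soft-clipped; O indel-only (insertions and deletions alternate,
#' exercising both CIGAR I/D and the MD deletion syntax); M multi-mapped
#' (alternating XA-tag hits and secondary FLAG-0x100 records); F unmapped
#' FLAG-4 records; N reads carrying ambiguous bases. NM always equals
#' substitutions plus indel bases, so both MD- and NM-based substitution
#' derivations are exercised.
#'
#' For the error-carrying labels S/C/N/O, each read's error-density ratio is
#' set to \code{lo} or \code{hi} from \code{ratio_params}, with a
#' deterministic count \code{round(frac_hi * n_label)} of reads at
#' \code{hi} -- placing reads exactly below/above a classification threshold
#' so PM\% is hand-computable. Alignment scores are drawn from label-specific
#' normal distributions whose means decline P to S to C.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bases.
#' @param label_mix Named fractions over P,S,C,O,M,F,N summing to 1;
#'   deterministic largest-remainder apportionment.
#' @param ratio_params Per-label \code{lo}/\code{hi}/\code{frac_hi} ratio
#'   settings; see \code{default_ratio_params()}.
#' @param reference A \code{DNAStringSet} mapping target; simulated when
#'   \code{NULL}. Must be longer than \code{read_length}.
#' @param seed Integer seed.
#' @param dir Output directory for the SAM, FASTQ and truth files.
#' @return List: \code{sam} (path), \code{reads} (\code{ShortReadQ} of the
#'   simulated reads), \code{truth} (factor of ground-truth labels),
#'   \code{truth_file} (tab-separated read_id/label path), \code{reference}.
#' @export
sim_labeled_sam <- function(n_reads = 700L, read_length = 100L,
                            label_mix = setNames(rep(1/7, 7), LABELS),
                            ratio_params = default_ratio_params(),
                            reference = NULL, seed = 1L,
                            dir = tempfile("fixture")) {
  stopifnot(n_reads >= 1, read_length >= 4)
  label_mix <- label_mix[LABELS]
  label_mix[is.na(label_mix)] <- 0
  names(label_mix) <- LABELS
  if (abs(sum(label_mix) - 1) > 1e-9) stop("label_mix must sum to 1")

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  if (is.null(reference))
    reference <- sim_reference(max(20000L, 20L * read_length), seed = seed + 1L)
  ref_name <- names(reference)[1]
  ref_seq <- as.character(reference[[1]])
  ref_len <- nchar(ref_seq)
  L <- as.integer(read_length)
  if (ref_len < 2L * L) stop("reference too short to place reads")

  counts <- apportion(n_reads, label_mix)
  labels <- sample(rep(LABELS, counts))
  ids <- sprintf("read_%d", seq_len(n_reads))

  # per-label hi/lo ratio assignment, deterministic by count
  ratio <- numeric(n_reads)
  for (L2 in c("S", "C", "N", "O")) {
    idx <- which(labels == L2)
    if (!length(idx)) next
    rp <- ratio_params[[L2]]
    n_hi <- round(rp$frac_hi * length(idx))
    hi_idx <- idx[sample.int(length(idx), n_hi)]
    ratio[idx] <- rp$lo
    ratio[hi_idx] <- rp$hi
  }

  as_mean <- c(P = 0.98, S = 0.85, C = 0.70, O = 0.80, M = 0.98, N = 0.80)
  as_sd <- c(P = 0.02, S = 0.04, C = 0.05, O = 0.04, M = 0.02, N = 0.04)

  # leave L + max-indel headroom on the right for deletion-type O reads
  starts <- sample.int(ref_len - 2L * L, n_reads, replace = TRUE)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  qual <- strrep("I", L)
  alpha <- c("A", "C", "G", "T")
  lines <- character(0)
  bases_out <- character(n_reads)

  draw_as <- function(lab) {
    s <- round(rnorm(1, as_mean[[lab]] * L, as_sd[[lab]] * L))
    max(0L, min(L, as.integer(s)))
  }

  for (i in seq_len(n_reads)) {
    lab <- labels[i]
    pos <- starts[i]
    seg <- substr(ref_seq, pos, pos + L - 1L)
    id <- ids[i]
    rec2 <- NULL
    if (lab == "F") {
      read <- paste(sample(alpha, L, replace = TRUE), collapse = "")
      line <- paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, read, qual,
                    sep = "\t")
    } else if (lab == "P" || lab == "M") {
      read <- seg
      opt <- c("NM:i:0", sprintf("MD:Z:%d", L), sprintf("AS:i:%d", draw_as(lab)))
      if (lab == "M") {
        alt_pos <- sample.int(ref_len - L, 1L)
        if (i %% 2L == 0L) {
          opt <- c(opt, sprintf("XA:Z:%s,+%d,%dM,0;", ref_name, alt_pos, L))
        } else {
          rec2 <- paste(id, 256L, ref_name, alt_pos, 0L, sprintf("%dM", L),
                        "*", 0L, 0L, "*", "*", "NM:i:0", sep = "\t")
        }
      }
      line <- paste(id, 0L, ref_name, pos, 60L, sprintf("%dM", L), "*", 0L,
                    0L, read, qual, paste(opt, collapse = "\t"), sep = "\t")
    } else if (lab == "S" || lab == "N") {
      k <- max(1L, round(ratio[i] * L))
      at <- sort(sample.int(L, k))
      rb <- strsplit(seg, "")[[1]]
      read_b <- rb
      if (lab == "N") {
        read_b[at] <- "N"
      } else {
        read_b[at] <- vapply(rb[at], function(b) sample(setdiff(alpha, b), 1L),
                             character(1))
      }
      read <- paste(read_b, collapse = "")
      md <- md_from_mismatches(rb, at)
      opt <- c(sprintf("NM:i:%d", k), sprintf("MD:Z:%s", md),
               sprintf("AS:i:%d", draw_as(lab)))
      line <- paste(id, 0L, ref_name, pos, 60L, sprintf("%dM", L), "*", 0L,
                    0L, read, qual, paste(opt, collapse = "\t"), sep = "\t")
    } else if (lab == "C") {
      cb <- max(1L, round(ratio[i] * L))
      m <- L - cb
      read <- paste0(substr(ref_seq, pos, pos + m - 1L),
                     paste(sample(alpha, cb, replace = TRUE), collapse = ""))
      opt <- c("NM:i:0", sprintf("MD:Z:%d", m), sprintf("AS:i:%d", draw_as(lab)))
      line <- paste(id, 0L, ref_name, pos, 60L, sprintf("%dM%dS", m, cb),
                    "*", 0L, 0L, read, qual, paste(opt, collapse = "\t"),
                    sep = "\t")
    } else {  # O: indel-only; insertions and deletions alternate
      k <- max(1L, round(ratio[i] * L))
      if (i %% 2L == 0L || k >= L - 1L) {   # deletion of k reference bases
        a <- (L %/% 2L)
        b <- L - a
        read <- paste0(substr(ref_seq, pos, pos + a - 1L),
                       substr(ref_seq, pos + a + k, pos + a + k + b - 1L))
        delseq <- substr(ref_seq, pos + a, pos + a + k - 1L)
        md <- sprintf("%d^%s%d", a, delseq, b)
        cig <- sprintf("%dM%dD%dM", a, k, b)
      } else {                              # insertion of k novel bases
        a <- (L - k) %/% 2L
        b <- L - k - a
        read <- paste0(substr(ref_seq, pos, pos + a - 1L),
                       paste(sample(alpha, k, replace = TRUE), collapse = ""),
                       substr(ref_seq, pos + a, pos + a + b - 1L))
        md <- sprintf("%d", a + b)
        cig <- sprintf("%dM%dI%dM", a, k, b)
      }
      opt <- c(sprintf("NM:i:%d", k), sprintf("MD:Z:%s", md),
               sprintf("AS:i:%d", draw_as(lab)))
      line <- paste(id, 0L, ref_name, pos, 60L, cig, "*", 0L, 0L, read,
                    qual, paste(opt, collapse = "\t"), sep = "\t")
    }
    bases_out[i] <- read
    lines <- c(lines, line, rec2)
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "fixture.sam")
  writeLines(c(header, lines), sam)

  reads <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(bases_out),
    quality = ShortRead::FastqQuality(Biostrings::BStringSet(rep(qual, n_reads))),
    id = Biostrings::BStringSet(ids))
  fastq <- file.path(dir, "fixture.fastq")
  write_fastq(reads, fastq)

  truth <- factor(labels, levels = LABELS)
  truth_file <- file.path(dir, "truth.tsv")
  write.table(data.frame(read_id = ids, label = labels),
              truth_file, sep = "\t", quote = FALSE, row.names = FALSE)

  list(sam = sam, fastq = fastq, reads = reads, truth = truth,
       truth_file = truth_file, reference = reference, ratio = ratio)
}

# MD string for a fully-matched span with substitutions at 1-based positions
# `at`; `ref_bases` is the reference segment as a character vector.
md_from_mismatches <- function(ref_bases, at) {
  if (!length(at)) return(as.character(length(ref_bases)))
  runs <- diff(c(0L, at)) - 1L
  tail_run <- length(ref_bases) - at[length(at)]
  paste0(paste0(runs, ref_bases[at], collapse = ""), tail_run)
}
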