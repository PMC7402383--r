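#' Read a FASTQ file of sequencing reads
#'
#' Thin wrapper around \code{ShortRead::readFastq} that validates the records.
#' Qualities are Phred+33 (the fixed offset used throughout the package; all
#' modern Illumina data); gzip-compressed files are read transparently.
#'
#' @param path Path to a FASTQ file (optionally .gz).
#' @return A \code{\link[ShortRead]{ShortReadQ}} object.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  fq <- ShortRead::readFastq(path)
  w_seq <- BiocGenerics::width(ShortRead::sread(fq))
  w_q <- BiocGenerics::width(Biostrings::quality(Biostrings::quality(fq)))
  bad <- which(w_seq != w_q)
  if (length(bad))
    stop("FASTQ parse error: sequence/quality length mismatch at record ", bad[1])
  fq
}

#' Write reads to a FASTQ file
#'
#' @param reads A \code{ShortReadQ} object.
#' @param path Output path; an existing file is overwritten. A ".gz" suffix
#'   triggers compression.
#' @return Invisibly, \code{path}.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is(reads, "ShortReadQ"))
  if (file.exists(path)) file.remove(path)
  ShortRead::writeFastq(reads, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read assembled scaffolds from FASTA
#'
#' Sequences are uppercased; characters other than A/C/G/T are treated as
#' ambiguous downstream (a warning is emitted if any fall outside the IUPAC
#' alphabet).
#'
#' @param path Path to a FASTA file (optionally .gz); multi-line sequences
#'   allowed.
#' @return A \code{\link[Biostrings]{DNAStringSet}}, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  scaf <- Biostrings::readDNAStringSet(path)
  if (length(scaf) && any(BiocGenerics::width(scaf) == 0L))
    stop("empty scaffold sequence in ", path)
  # DNAStringSet is already uppercase-normalized and IUPAC-restricted;
  # non-ACGT IUPAC codes survive and are counted as ambiguous by consumers.
  amb <- sum(Biostrings::alphabetFrequency(scaf, collapse = TRUE)[
    setdiff(names(Biostrings::alphabetFrequency(scaf, collapse = TRUE)),
            c("A", "C", "G", "T", "N", "-", "+", "."))])
  if (amb > 0)
    warning(amb, " non-ACGTN IUPAC bases present; counted as ambiguous")
  scaf
}

#' Uniformly sample reads from a FASTQ file or an in-memory read set
#'
#' Draws \code{min(n, total)} distinct reads uniformly without replacement.
#' Given a file path, a single-pass streaming reservoir sampler
#' (\code{ShortRead::FastqSampler}) is used, so arbitrarily large files are
#' handled in one pass and bounded memory. Given an already-loaded
#' \code{ShortReadQ}, an index sample is drawn. The same \code{(input, n,
#' seed)} always yields the identical sample.
#'
#' @param reads A FASTQ path or a \code{ShortReadQ}.
#' @param n Sample size; default one million reads.
#' @param seed Integer seed controlling the draw.
#' @param bypass If \code{TRUE}, skip sampling and return all reads.
#' @return A \code{ShortReadQ} with \code{min(n, total)} reads.
#' @export
sample_reads <- function(reads, n = 1e6, seed = 1L, bypass = FALSE) {
  if (!bypass) {
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
      stop("sample size n must be a positive integer")
    n <- as.integer(n)
  }
  if (is.character(reads)) {
    if (bypass) return(read_fastq(reads))
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
    sampler <- ShortRead::FastqSampler(reads, n = n, ordered = TRUE)
    on.exit(close(sampler), add = TRUE)
    return(ShortRead::yield(sampler))
  }
  stopifnot(is(reads, "ShortReadQ"))
  if (bypass || length(reads) <= n) return(reads)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  reads[sort(sample.int(length(reads), n))]
}

# Restore (or clear) the global RNG state captured before a seeded section,
# so library calls do not perturb the caller's random stream.
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Integer Phred scores of a read set
#'
#' Decodes the Phred+33 quality strings into an integer matrix with one row
#' per read; rows of short reads are right-padded with \code{NA}.
#'
#' @param reads A \code{ShortReadQ}.
#' @return Integer matrix, reads x cycles.
#' @export
phred_matrix <- function(reads) {
  stopifnot(is(reads, "ShortReadQ"))
  as(Biostrings::quality(reads), "matrix")
}

#' @rdname phred_matrix
#' @return \code{read_ids}: character vector of read identifiers (the part of
#'   the FASTQ header before the first whitespace).
#' @export
read_ids <- function(reads) {
  sub("\\s.*$", "", as.character(ShortRead::id(reads)))
}
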