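#' Digest a SAM file into per-read alignment observations
#'
#' Reduces the SAM output of one aligner run to one observation per sampled
#' read: mapped or not, the number of reported mapping locations
#' (multiplicity), substitution and indel counts, clipped bases, and the
#' aligner's alignment score, together with the derived mismatch/clip/N
#' density ratios.
#'
#' Multiplicity counts the primary record plus any secondary (FLAG 0x100) or
#' supplementary (0x800) record plus every alternative hit listed in the
#' primary record's \code{XA} tag; mapping quality is not consulted.
#' Substitutions are taken from the \code{MD} tag when present (exact
#' substituted positions), otherwise as \code{NM} minus inserted plus deleted
#' bases, since \code{NM} conflates indels with substitutions. Clip bases sum
#' soft (S) and hard (H) CIGAR operations over both ends; hard-clipped bases
#' are added back to the read length so ratios are over the full read.
#'
#' @param sam Path to a SAM (or BAM) file with a header; unmapped reads must
#'   be present as FLAG 0x4 records.
#' @param reads The sampled \code{ShortReadQ} that was aligned. Supplies the
#'   authoritative read length and N content (primary SAM records may be
#'   hard-clipped or reverse-complemented). Reads in the SAM but absent from
#'   the sample are skipped with a warning.
#' @return A \code{data.frame} with one row per sampled read: \code{read_id},
#'   \code{read_length}, \code{has_n}, \code{mapped}, \code{multiplicity},
#'   \code{substitutions}, \code{insertion_bases}, \code{deletion_bases},
#'   \code{clip_bases}, \code{alignment_score}, \code{mismatch_ratio},
#'   \code{clip_ratio}, \code{n_ratio}, \code{indel_ratio}.
#' @export
digest_sam <- function(sam, reads) {
  stopifnot(is(reads, "ShortReadQ"))
  ids <- read_ids(reads)
  if (anyDuplicated(ids)) stop("sampled read ids are not distinct")
  lens <- BiocGenerics::width(reads)
  n_in_read <- lens - rowSums(
    Biostrings::alphabetFrequency(ShortRead::sread(reads))[,
      c("A", "C", "G", "T"), drop = FALSE])

  bam <- as_bam_path(sam)
  rec <- scanBam(bam, param = ScanBamParam(
    what = c("qname", "flag", "cigar"),
    tag = c("NM", "MD", "AS", "XA")))[[1]]

  known <- match(rec$qname, ids)
  if (anyNA(known)) {
    warning(length(unique(rec$qname[is.na(known)])),
            " SAM read(s) not in the sampled set; skipped")
    keep <- !is.na(known)
    rec$qname <- rec$qname[keep]
    rec$flag <- rec$flag[keep]
    rec$cigar <- rec$cigar[keep]
    rec$tag <- lapply(rec$tag, `[`, keep)
  }
  get_tag <- function(name, idx) {
    v <- rec$tag[[name]]
    if (is.null(v)) rep(NA_integer_, length(idx)) else v[idx]
  }

  flag <- rec$flag
  unmapped <- bitwAnd(flag, 0x4L) > 0L
  secondary <- bitwAnd(flag, 0x100L) > 0L | bitwAnd(flag, 0x800L) > 0L
  primary <- !unmapped & !secondary

  n <- length(ids)
  obs <- data.frame(
    read_id = ids, read_length = lens,
    has_n = n_in_read > 0L, mapped = FALSE, multiplicity = 0L,
    substitutions = 0L, insertion_bases = 0L, deletion_bases = 0L,
    clip_bases = 0L, alignment_score = NA_integer_,
    stringsAsFactors = FALSE)

  seen <- unique(rec$qname)
  missing <- setdiff(ids, seen)
  if (length(missing))
    stop(length(missing), " sampled read(s) absent from SAM (first: ",
         missing[1], "); unmapped reads must be emitted as FLAG 4 records")

  # per-read extra records (secondary + supplementary)
  extra <- table(factor(rec$qname[secondary], levels = ids))

  pi <- which(primary)
  pidx <- match(ids, rec$qname[pi])      # primary record per read, if any
  has_primary <- !is.na(pidx)
  p <- pi[pidx[has_primary]]             # row indices into rec for primaries
  rid <- which(has_primary)              # rows of obs with a primary alignment

  if (length(p)) {
    cig <- rec$cigar[p]
    ops <- cigarOpTable(cig)
    ins <- ops[, "I"]
    del <- ops[, "D"]
    clip <- ops[, "S"] + ops[, "H"]
    nm <- get_tag("NM", p)
    md <- get_tag("MD", p)
    subs <- ifelse(!is.na(md), md_substitutions(md),
                   pmax(0L, ifelse(is.na(nm), NA_integer_, nm) - ins - del))
    if (anyNA(subs)) {
      warning(sum(is.na(subs)),
              " mapped record(s) lack both MD and NM tags; substitutions set to 0")
      subs[is.na(subs)] <- 0L
    }
    xa_hits <- xa_count(as.character(get_tag("XA", p)))
    obs$mapped[rid] <- TRUE
    obs$multiplicity[rid] <- 1L + as.integer(extra[rid]) + xa_hits
    obs$substitutions[rid] <- as.integer(subs)
    obs$insertion_bases[rid] <- as.integer(ins)
    obs$deletion_bases[rid] <- as.integer(del)
    obs$clip_bases[rid] <- as.integer(clip)
    obs$alignment_score[rid] <- get_tag("AS", p)
  }

  obs$mismatch_ratio <- obs$substitutions / obs$read_length
  obs$clip_ratio <- obs$clip_bases / obs$read_length
  obs$n_ratio <- as.numeric(n_in_read) / obs$read_length
  obs$indel_ratio <- (obs$insertion_bases + obs$deletion_bases) / obs$read_length
  obs
}

# Accepts a SAM or BAM path; converts SAM text to a temporary BAM.
as_bam_path <- function(sam) {
  if (grepl("\\.bam$", sam, ignore.case = TRUE)) return(sam)
  dest <- tempfile(fileext = "")
  asBam(sam, dest, overwrite = TRUE, indexDestination = FALSE)
}

#' Count substitutions recorded in SAM MD tags
#'
#' The MD tag interleaves match-run lengths, substituted reference bases
#' (single letters) and deletions (\code{^} followed by the deleted reference
#' bases). Substitutions are the single letters not preceded by \code{^};
#' insertions do not appear in MD at all.
#'
#' @param md Character vector of MD tag values (without the "MD:Z:" prefix).
#' @return Integer vector of substitution counts; \code{NA} in, \code{NA} out.
#' @export
md_substitutions <- function(md) {
  vapply(md, function(m) {
    if (is.na(m)) return(NA_integer_)
    body <- gsub("\\^[A-Za-z]+", "", m)   # drop deletion runs
    sum(strsplit(gsub("[0-9]+", "", body), "")[[1]] %in%
          c(LETTERS, letters))
  }, integer(1), USE.NAMES = FALSE)
}

# Number of alternative hits in an XA:Z: tag value ("chr,pos,CIGAR,NM;" ...)
xa_count <- function(xa) {
  ifelse(is.na(xa) | !nzchar(xa), 0L,
         vapply(xa, function(x) sum(strsplit(x, "")[[1]] == ";"), integer(1),
                USE.NAMES = FALSE))
}
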