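suppressPackageStartupMessages({
  library(Biostrings)
  library(ShortRead)
})

# Build a ShortReadQ in code from bases + integer Phred scores.
make_reads <- function(bases, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(bases), function(n) rep(40L, n))
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(bases))
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), character(1))
  ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(bases),
    quality = ShortRead::FastqQuality(Biostrings::BStringSet(qstr)),
    id = Biostrings::BStringSet(ids))
}

# Write a SAM file from a header + record lines.
write_sam <- function(records, ref_len = 1000L, ref = "ref") {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref, ref_len),
               records), path)
  path
}

sam_line <- function(qname, flag, cigar, seq, rname = "ref", pos = 10L,
                     mapq = 60L, tags = character(0)) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}

# ---- independent brute-force label oracle -------------------------------
# Re-derives the seven-way label for each read straight from raw SAM text
# and the read sequences, sharing no code with the package: its own CIGAR
# tokenizer, MD walk and flag arithmetic.
oracle_labels <- function(sam_path, reads) {
  ids <- sub("\\s.*$", "", as.character(ShortRead::id(reads)))
  seqs <- as.character(ShortRead::sread(reads))
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qn <- vapply(fields, `[`, "", 1)
  fl <- as.integer(vapply(fields, `[`, "", 2))

  get_tag_val <- function(f, prefix) {
    hit <- grep(prefix, f[-(1:11)], value = TRUE, fixed = TRUE)
    if (!length(hit)) NA_character_ else sub(prefix, "", hit[1], fixed = TRUE)
  }
  cigar_tab <- function(cig) {
    if (cig == "*") return(c(S = 0, H = 0, I = 0, D = 0))
    lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    ops <- regmatches(cig, gregexpr("[A-Z=]", cig))[[1]]
    vapply(c("S", "H", "I", "D"), function(o) sum(lens[ops == o]), numeric(1))
  }
  md_subs <- function(md) {
    if (is.na(md)) return(NA_integer_)
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
    sum(grepl("^[A-Z]$", toks))
  }

  vapply(ids, function(id) {
    if (grepl("N", seqs[ids == id], fixed = TRUE)) return("N")
    rows <- which(qn == id)
    primary <- rows[bitwAnd(fl[rows], 0x904L) == 0L]   # not unmapped/sec/supp
    if (!length(primary)) return("F")
    f <- fields[[primary[1]]]
    n_loc <- 1L + sum(bitwAnd(fl[rows], 0x100L) > 0L | bitwAnd(fl[rows], 0x800L) > 0L)
    xa <- get_tag_val(f, "XA:Z:")
    if (!is.na(xa)) n_loc <- n_loc + lengths(regmatches(xa, gregexpr(";", xa)))
    if (n_loc > 1L) return("M")
    ct <- cigar_tab(f[6])
    subs <- md_subs(get_tag_val(f, "MD:Z:"))
    if (is.na(subs)) {
      nm <- as.integer(get_tag_val(f, "NM:i:"))
      subs <- if (is.na(nm)) 0L else nm - ct[["I"]] - ct[["D"]]
    }
    if (subs == 0L && ct[["S"]] + ct[["H"]] == 0L && ct[["I"]] + ct[["D"]] == 0L)
      return("P")
    if (subs >= 1L) return("S")
    if (ct[["S"]] + ct[["H"]] >= 1L) return("C")
    "O"
  }, character(1), USE.NAMES = FALSE)
}

# Seven hand-written SAM records, one per label, with their ground truth.
canonical_records <- function() {
  s100 <- strrep("G", 100)
  withN <- paste0(strrep("G", 95), "NNNNN")
  list(
    reads = make_reads(c(withN, rep(s100, 6)),
                       ids = sprintf("r%d", 1:7)),
    sam = write_sam(c(
      sam_line("r1", 0L, "100M", withN, tags = c("NM:i:5", "MD:Z:95GGGGG")),
      sam_line("r2", 4L, "*", s100, rname = "*", pos = 0L, mapq = 0L),
      sam_line("r3", 0L, "100M", s100,
               tags = c("NM:i:0", "MD:Z:100", "XA:Z:ref,+300,100M,0;")),
      sam_line("r4", 0L, "100M", s100, tags = c("NM:i:0", "MD:Z:100")),
      sam_line("r5", 0L, "100M", s100, tags = c("NM:i:2", "MD:Z:10G0G88")),
      sam_line("r6", 0L, "60M40S", s100, tags = c("NM:i:0", "MD:Z:60")),
      sam_line("r7", 0L, "50M1I49M", s100, tags = c("NM:i:1", "MD:Z:99")))),
    truth = c("N", "F", "M", "P", "S", "C", "O"))
}

dna_of_lengths <- function(lens, letter = "A") {
  Biostrings::DNAStringSet(vapply(lens, function(n)
    strrep(letter, n), character(1)))
}

# brute-force contiguity oracle: sort descending, cumulative sum, scan for
# the first index reaching x% of the denominator
brute_nx_lx <- function(lens, x, denom = sum(lens)) {
  w <- sort(lens, decreasing = TRUE)
  cs <- cumsum(w)
  k <- which(cs >= x / 100 * denom)[1]
  c(nx = w[k], lx = k)
}

# Expected PM% straight from fixture ground truth: unmapped reads plus
# error-carrying reads whose planted ratio exceeds the threshold.
oracle_pm <- function(truth, ratio, th = 0.3) {
  n <- length(truth)
  100 * (sum(truth == "F") +
           sum(truth %in% c("S", "C", "N", "O") & ratio > th)) / n
}
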