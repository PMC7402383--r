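#' Align sampled reads to an assembly with bwa
#'
#' Optional convenience wrapper used by the command-line pipeline when no
#' pre-computed SAM is supplied: runs \code{bwa mem} (local alignment) and/or
#' \code{bwa aln} + \code{bwa samse} (end-to-end, "backtrack") on the sampled
#' FASTQ against the assembly. The analysis core never depends on this; any
#' SAM from any single-end aligner can be supplied instead.
#'
#' @param assembly Assembly FASTA path (indexed on first use).
#' @param fastq Reads to align.
#' @param out_sam Output SAM path.
#' @param mode \code{"mem"} or \code{"backtrack"}.
#' @param threads Threads passed to bwa.
#' @return \code{out_sam}, invisibly. The exact command lines run are
#'   attached as attribute \code{"commands"} for report provenance.
#' @export
align_bwa <- function(assembly, fastq, out_sam,
                      mode = c("mem", "backtrack"), threads = 1L) {
  mode <- match.arg(mode)
  if (Sys.which("bwa") == "")
    stop("bwa executable not found on PATH; supply a SAM file instead")
  cmds <- character(0)
  run <- function(args, stdout = "") {
    cmds <<- c(cmds, paste("bwa", paste(args, collapse = " ")))
    status <- system2("bwa", args, stdout = stdout, stderr = FALSE)
    if (!identical(status, 0L)) stop("bwa ", args[1], " failed")
  }
  if (!file.exists(paste0(assembly, ".bwt"))) run(c("index", assembly))
  if (mode == "mem") {
    run(c("mem", "-t", threads, assembly, fastq), stdout = out_sam)
  } else {
    sai <- tempfile(fileext = ".sai")
    on.exit(unlink(sai), add = TRUE)
    run(c("aln", "-t", threads, "-f", sai, assembly, fastq))
    run(c("samse", "-f", out_sam, assembly, sai, fastq))
  }
  invisible(structure(out_sam, commands = cmds))
}
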