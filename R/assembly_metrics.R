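#' Assembly contiguity and composition statistics
#'
#' Computes the scaffold-length and composition summary of an assembly:
#' scaffold count, assembly size, maximum scaffold, Nx and Lx values, GC
#' percentage and unknown bases per 100 kbp.
#'
#' Nx is the length of the scaffold at which the cumulative length of
#' scaffolds sorted in descending order first reaches x\% of the assembly
#' size; Lx is the number of scaffolds in that cumulative prefix (the ">="
#' crossing convention). The GC denominator excludes N and ambiguous bases.
#' When \code{reference_length} is supplied, NGx/LGx are computed against
#' that length instead of the assembly size (NA where the assembly never
#' reaches x\% of the reference).
#'
#' @param scaffolds A \code{DNAStringSet} of assembled scaffolds, or a path
#'   to a FASTA file.
#' @param x_n Percentages for Nx (default 25, 50, 75).
#' @param x_l Percentages for Lx (default 80, 90, 99).
#' @param reference_length Optional known genome size in bp for NGx/LGx.
#' @return An object of class \code{assembly_stats} (a list).
#' @export
contiguity_stats <- function(scaffolds, x_n = c(25, 50, 75),
                             x_l = c(80, 90, 99), reference_length = NULL) {
  if (is.character(scaffolds)) scaffolds <- read_fasta(scaffolds)
  stopifnot(is(scaffolds, "DNAStringSet"))
  if (length(scaffolds) == 0L) stop("empty assembly")

  w <- sort(BiocGenerics::width(scaffolds), decreasing = TRUE)
  total <- sum(as.numeric(w))
  csum <- cumsum(as.numeric(w))

  nx_at <- function(x, denom) {
    k <- which(csum >= x / 100 * denom)
    if (!length(k)) return(c(NA_real_, NA_real_))
    c(w[k[1]], k[1])
  }
  nx <- vapply(x_n, nx_at, numeric(2), denom = total)
  lx <- vapply(x_l, nx_at, numeric(2), denom = total)

  af <- Biostrings::alphabetFrequency(scaffolds, collapse = TRUE)
  acgt <- af[c("A", "C", "G", "T")]
  n_count <- total - sum(acgt)

  out <- list(
    n_scaffolds = length(scaffolds),
    assembly_size = total,
    max_scaffold = w[1],
    nx = setNames(as.integer(nx[1, ]), paste0("N", x_n)),
    lx = setNames(as.integer(lx[2, ]), paste0("L", x_l)),
    gc_pct = 100 * sum(acgt[c("C", "G")]) / sum(acgt),
    ns_per_100kbp = n_count / total * 1e5
  )
  if (!is.null(reference_length)) {
    stopifnot(reference_length > 0)
    ngx <- vapply(x_n, nx_at, numeric(2), denom = reference_length)
    lgx <- vapply(x_l, nx_at, numeric(2), denom = reference_length)
    out$ngx <- setNames(as.integer(ngx[1, ]), paste0("NG", x_n))
    out$lgx <- setNames(as.integer(lgx[2, ]), paste0("LG", x_l))
    out$reference_length <- reference_length
  }
  structure(out, class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Assembly: %d scaffolds, %.0f bp (max %.0f)\n",
              x$n_scaffolds, x$assembly_size, x$max_scaffold))
  cat("  ", paste(names(x$nx), x$nx, sep = "=", collapse = "  "), "\n")
  cat("  ", paste(names(x$lx), x$lx, sep = "=", collapse = "  "), "\n")
  cat(sprintf("  GC%% %.2f   Ns/100kbp %.2f\n", x$gc_pct, x$ns_per_100kbp))
  invisible(x)
}
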