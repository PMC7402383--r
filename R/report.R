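#' Run the pre-assembly pipeline
#'
#' Samples reads from a FASTQ file, computes the pre-assembly quality
#' summary, and writes \code{sampled.fastq}, \code{preassembly.json} and
#' \code{pre_report.html} into the output directory. The sampled FASTQ is
#' written out so the exact same sample can be fed to external aligners and
#' to the post-assembly stage.
#'
#' @param fastq Input FASTQ path.
#' @param output_dir Output directory (created if needed).
#' @param sample_size Number of reads to sample (default one million).
#' @param bypass_sampling Analyze all reads without sampling.
#' @param seed Integer seed for the sample draw.
#' @param q_grid Phred grid for the \%HighQ distribution.
#' @return Invisibly, the report bundle (a list) with elements
#'   \code{summary}, \code{sampled_fastq}, \code{input}, \code{n_sampled}.
#' @export
run_pre <- function(fastq, output_dir, sample_size = 1e6,
                    bypass_sampling = FALSE, seed = 1L,
                    q_grid = c(10L, 15L, 20L, 25L, 30L, 35L, 40L)) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- sample_reads(fastq, n = sample_size, seed = seed,
                        bypass = bypass_sampling)
  sampled <- file.path(output_dir, "sampled.fastq")
  write_fastq(reads, sampled)
  summ <- summarize_preassembly(reads, q_grid = q_grid)
  bundle <- list(
    input = normalizePath(fastq),
    n_sampled = length(reads),
    sample_size = if (bypass_sampling) NA else sample_size,
    bypass_sampling = bypass_sampling,
    seed = seed,
    sampled_fastq = sampled,
    summary = unclass(summ))
  json <- bundle
  json$sampled_fastq <- basename(sampled)   # keep the bundle path-stable
  write_json_bundle(json, file.path(output_dir, "preassembly.json"))
  writeLines(render_pre_html(bundle), file.path(output_dir, "pre_report.html"))
  invisible(bundle)
}

#' Run the post-assembly pipeline
#'
#' Digests one or two SAM files of the sampled reads aligned to the assembly
#' (one per aligner strategy), labels every read, computes per-aligner PM\%
#' breakdowns and the final averaged PM\% with its pass/fail verdict, and
#' computes the assembly contiguity table. Writes
#' \code{postassembly_<aligner>.json} per run, \code{pm_summary.json},
#' \code{assembly_stats.json} and \code{post_report.html}.
#'
#' @param fastq Path to the (sampled) FASTQ that was aligned.
#' @param assembly Path to the assembly FASTA.
#' @param sam Named character vector of 1 or 2 SAM paths; names identify the
#'   aligner runs (e.g. \code{c(mem = "...", backtrack = "...")}).
#' @param output_dir Output directory.
#' @param th Thresholds from \code{\link{thresholds}}.
#' @param priority Label priority, see \code{\link{label_reads}}.
#' @return Invisibly, the report bundle: per-aligner profiles and PM
#'   breakdowns, \code{final_pm}, \code{verdict}, assembly stats.
#' @export
run_post <- function(fastq, assembly, sam, output_dir, th = thresholds(),
                     priority = "SC") {
  if (length(sam) < 1L || length(sam) > 2L)
    stop("supply one or two SAM files (named by aligner)")
  if (is.null(names(sam)) || any(!nzchar(names(sam))))
    names(sam) <- paste0("aligner", seq_along(sam))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  reads <- read_fastq(fastq)
  runs <- lapply(names(sam), function(al) {
    obs <- digest_sam(sam[[al]], reads)
    lab <- label_reads(obs, priority = priority)
    prof <- profile_labels(lab, obs, aligner = al)
    pm <- compute_pm(prof, th)
    scores <- alignment_score_stats(prof)
    out <- list(aligner = al,
                n_reads = prof$n_reads,
                fractions = as.list(prof$fractions),
                counts = as.list(prof$counts),
                highly_mapped_pct = as.list(pm$highly_mapped_pct),
                poorly_mapped_pct = as.list(pm$poorly_mapped_pct),
                pm_pct = pm$pm_pct,
                alignment_scores = scores,
                ratio_histograms = ratio_histograms(prof))
    write_json_bundle(out, file.path(output_dir,
                                     sprintf("postassembly_%s.json", al)))
    list(json = out, profile = prof, pm = pm)
  })
  names(runs) <- names(sam)

  pms <- vapply(runs, function(r) r$pm$pm_pct, numeric(1))
  final_pm <- if (length(pms) == 2L) average_pm(pms[1], pms[2]) else pms[[1]]
  verdict <- pass_assessment(final_pm, th)
  pm_summary <- list(
    per_aligner_pm_pct = as.list(pms),
    final_pm_pct = final_pm,
    final_pm_display = format_pct(final_pm),
    pm_pass_threshold = th$pm_pass,
    verdict = if (verdict) "pass" else "fail",
    single_aligner_mode = length(pms) == 1L,
    thresholds = unclass(th))
  write_json_bundle(pm_summary, file.path(output_dir, "pm_summary.json"))

  astats <- contiguity_stats(assembly)
  write_json_bundle(unclass(astats), file.path(output_dir, "assembly_stats.json"))

  bundle <- list(runs = lapply(runs, `[[`, "json"),
                 pm_summary = pm_summary,
                 assembly_stats = unclass(astats),
                 fastq = normalizePath(fastq),
                 assembly = normalizePath(assembly))
  writeLines(render_post_html(bundle), file.path(output_dir, "post_report.html"))
  invisible(bundle)
}

# Histograms of the per-label error-density ratios (20 bins over [0, 1]).
ratio_histograms <- function(prof) {
  brk <- seq(0, 1, by = 0.05)
  one <- function(lab, col) {
    v <- prof$obs[[col]][prof$labels == lab]
    v <- v[!is.na(v)]
    if (!length(v)) return(list())
    h <- hist(pmin(v, 1), breaks = brk, plot = FALSE)
    setNames(as.list(h$counts), paste0("le", brk[-1]))
  }
  list(S_mismatch = one("S", "mismatch_ratio"),
       C_clip = one("C", "clip_ratio"),
       N_n = one("N", "n_ratio"),
       O_indel = one("O", "indel_ratio"))
}

write_json_bundle <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a JSON report bundle
#' @param path Path to a JSON file written by the pipeline.
#' @return The parsed list.
#' @export
read_json_bundle <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
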