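# Self-contained HTML rendering: the JSON bundle holds every number, the
# HTML is a pure view of it (inline CSS, no external assets).

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_page <- function(title, body) {
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "h1{color:#234}.headline{font-size:2.2em;font-weight:bold}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #bbb;padding:0.3em 0.8em;text-align:right}",
    "th{background:#eef}td:first-child,th:first-child{text-align:left}",
    ".bar{display:inline-block;height:0.9em;background:#48c}",
    ".barneg{display:inline-block;height:0.9em;background:#c44}",
    ".note{color:#666;font-style:italic}",
    ".pass{color:#1a7a1a}.fail{color:#a11}",
    "</style></head><body>",
    sprintf("<h1>%s</h1>", html_escape(title)),
    body,
    "</body></html>")
}

html_table <- function(df, header = names(df)) {
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  c("<table>",
    paste0("<tr>", paste0("<th>", html_escape(header), "</th>",
                          collapse = ""), "</tr>"),
    rows, "</table>")
}

html_placeholder <- function(what) {
  sprintf("<p class='note'>%s: not computed</p>", html_escape(what))
}

# horizontal CSS bar, width in percent of scale
html_bar <- function(pct, scale = 100, neg = FALSE) {
  sprintf("<span class='%s' style='width:%.1fpx'></span> %s",
          if (neg) "barneg" else "bar",
          3 * abs(pct) / scale * 100, format_pct(pct))
}

LABEL_DESCRIPTIONS <- c(
  P = "Uniquely mapped, perfect match (no errors)",
  S = "Uniquely mapped with substitution errors",
  C = "Uniquely mapped, contains clips",
  O = "Uniquely mapped with other errors (indels)",
  M = "Multi-mapped (repeats: more than one reported location)",
  F = "Failed to map to the assembly",
  N = "Read contains ambiguous bases (N)")

render_pre_html <- function(bundle) {
  s <- bundle$summary
  cf <- unlist(s$category_fractions)
  body <- c(
    sprintf("<p>Input: <code>%s</code> &mdash; %d reads analyzed%s</p>",
            html_escape(bundle$input), bundle$n_sampled,
            if (isTRUE(bundle$bypass_sampling)) " (sampling bypassed)"
            else sprintf(" (sampled, seed %d)", bundle$seed)),
    "<h2>Read quality categories</h2>",
    html_table(data.frame(
      Category = c("High-quality (every base Q20+)",
                   "Medium-quality",
                   "Poor-quality (&gt;10% of bases Q14 or less)"),
      Percent = format_pct(100 * cf[c("HIGH", "MEDIUM", "POOR")])),
      header = c("Category", "% of reads")),
    "<h2>Basic statistics</h2>",
    html_table(data.frame(
      Measure = c("Number of reads", "Number of bases",
                  "Read length (min-max, mean)", "% of bases with Q30+"),
      Value = c(s$n_reads, s$n_bases,
                sprintf("%d-%d, %.1f", s$read_length$min, s$read_length$max,
                        s$read_length$mean),
                format_pct(s$pct_bases_ge_q30))),
      header = c("Measure", "Value")),
    "<h2>Base composition</h2>",
    html_table(data.frame(Base = names(s$base_composition),
                          Count = unlist(s$base_composition))),
    "<h2>%HighQ(q) over reads</h2>",
    if (length(s$highq_cdf))
      html_table(data.frame(
        q = sub("^q", "", names(s$highq_cdf)),
        mean = sprintf("%.3f", vapply(s$highq_cdf, `[[`, 0, "mean")),
        all_bases_high = format_pct(
          100 * vapply(s$highq_cdf, `[[`, 0, "frac_reads_all_high"))),
        header = c("q", "mean %HighQ(q)", "% reads with %HighQ(q)=100%"))
    else html_placeholder("%HighQ distribution"))
  html_page("Pre-assembly quality report", body)
}

render_post_html <- function(bundle) {
  pm <- bundle$pm_summary
  verdict <- identical(pm$verdict, "pass")
  body <- c(
    sprintf("<p class='headline'>PM%% = %s <span class='%s'>(%s)</span></p>",
            pm$final_pm_display, if (verdict) "pass" else "fail",
            toupper(pm$verdict)),
    sprintf("<p>Assessment rule: pass if PM%% &lt; %s. %s</p>",
            format_pct(pm$pm_pass_threshold),
            if (isTRUE(pm$single_aligner_mode))
              "Single-aligner mode: final PM% is the single run's value."
            else "Final PM% is the mean over the two aligner runs."),
    "<h2>Read labels</h2>",
    html_table(data.frame(Label = names(LABEL_DESCRIPTIONS),
                          Description = unname(LABEL_DESCRIPTIONS)),
               header = c("Label", "Description")),
    "<h2>Thresholds</h2>",
    html_table(data.frame(
      Threshold = c("Mismatch ratio (S)", "Clip ratio (C)", "N ratio (N)",
                    "Indel ratio (O)", "PM% pass cutoff"),
      Value = c(pm$thresholds$mismatch, pm$thresholds$clip, pm$thresholds$n,
                ifelse(is.na(pm$thresholds$other), "excluded",
                       pm$thresholds$other),
                pm$thresholds$pm_pass)),
      header = c("Threshold", "Value")),
    "<p class='note'>Only the clip-ratio default (0.3) is anchored in the",
    "method's description; mismatch/N/indel thresholds reuse it for",
    "uniformity and are configurable.</p>")

  for (run in bundle$runs) {
    fr <- unlist(run$fractions)
    hi <- unlist(run$highly_mapped_pct)
    po <- unlist(run$poorly_mapped_pct)
    body <- c(body,
      sprintf("<h2>Aligner: %s (PM%% = %s)</h2>", html_escape(run$aligner),
              format_pct(run$pm_pct)),
      "<table><tr><th>Label</th><th>% of reads</th>",
      "<th>highly mapped</th><th>poorly mapped</th></tr>",
      vapply(names(fr), function(L) sprintf(
        "<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
        L, format_pct(100 * fr[[L]]), html_bar(hi[[L]]),
        html_bar(po[[L]], neg = TRUE)), character(1)),
      "</table>",
      if (length(run$alignment_scores)) {
        meds <- vapply(run$alignment_scores, function(x)
          if (identical(x$n, 0L) || is.null(x$median)) NA_real_
          else as.numeric(x$median), numeric(1))
        html_table(data.frame(Label = names(meds),
                              Median_AS = ifelse(is.na(meds), "-", meds)),
                   header = c("Label", "Median alignment score"))
      } else html_placeholder("alignment scores"))
  }

  a <- bundle$assembly_stats
  body <- c(body, "<h2>Assembly contiguity</h2>",
    if (!is.null(a))
      html_table(data.frame(
        Metric = c("# Scaffolds", "Assembly size (bp)", "Max scaffold (bp)",
                   names(a$nx), names(a$lx), "GC%", "Ns per 100 kbp"),
        Value = c(a$n_scaffolds, a$assembly_size, a$max_scaffold,
                  a$nx, a$lx, sprintf("%.2f", a$gc_pct),
                  sprintf("%.2f", a$ns_per_100kbp))),
        header = c("Metric", "Value"))
    else html_placeholder("assembly contiguity"))
  html_page("Post-assembly mapping report", body)
}
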