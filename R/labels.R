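LABELS <- c("P", "S", "C", "O", "M", "F", "N")

#' Classification thresholds for the poorly-mapped statistic
#'
#' The clip-ratio threshold of 0.3 is the tool's documented default; the
#' mismatch, N and "other" (indel-density) thresholds default to the same
#' value for uniformity. \code{other} may be set to \code{NA} so that O-type
#' reads never count as poorly mapped (the stricter reading in which only
#' F/S/C/N contribute). \code{pm_pass} is the percentage below which (strict)
#' an assembly passes the assessment.
#'
#' @param clip,mismatch,n,other Per-label density-ratio thresholds in (0, 1];
#'   a read of that label is poorly mapped when its ratio strictly exceeds
#'   the threshold. \code{other} may be \code{NA}.
#' @param pm_pass PM\% pass cutoff in (0, 100]; default 20.
#' @return A named list of class \code{asmqc_thresholds}.
#' @export
thresholds <- function(clip = 0.3, mismatch = 0.3, n = 0.3, other = 0.3,
                       pm_pass = 20) {
  chk <- c(clip = clip, mismatch = mismatch, n = n)
  if (any(is.na(chk)) || any(chk <= 0) || any(chk > 1))
    stop("clip/mismatch/n thresholds must lie in (0, 1]")
  if (!is.na(other) && (other <= 0 || other > 1))
    stop("other threshold must lie in (0, 1] or be NA")
  if (is.na(pm_pass) || pm_pass <= 0 || pm_pass > 100)
    stop("pm_pass must lie in (0, 100]")
  structure(list(clip = clip, mismatch = mismatch, n = n, other = other,
                 pm_pass = pm_pass), class = "asmqc_thresholds")
}

#' Assign each read one of the seven mapping labels
#'
#' Labels are assigned by a fixed decision sequence: reads containing an
#' ambiguous base are N regardless of mapping outcome (the N screen precedes
#' mapping); unmapped reads are F; reads reported at more than one location
#' are M (repeats); uniquely mapped reads are P when the alignment has no
#' errors at all, S when it has at least one substitution, C when it contains
#' clipped bases, and O otherwise (indel errors only). A uniquely mapped read
#' with both substitutions and clips is therefore S under the default order;
#' pass \code{priority = "CS"} to place the clip test before the substitution
#' test.
#'
#' @param obs Observation table from \code{\link{digest_sam}}.
#' @param priority \code{"SC"} (default, substitutions first) or \code{"CS"}.
#' @return Factor of labels with levels P, S, C, O, M, F, N, one per read.
#' @export
label_reads <- function(obs, priority = c("SC", "CS")) {
  priority <- match.arg(priority)
  stopifnot(all(c("has_n", "mapped", "multiplicity", "substitutions",
                  "clip_bases", "insertion_bases", "deletion_bases") %in%
                  names(obs)))
  n <- nrow(obs)
  lab <- character(n)
  sub_first <- priority == "SC"
  has_sub <- obs$substitutions >= 1L
  has_clip <- obs$clip_bases >= 1L
  lab <- ifelse(obs$has_n, "N",
         ifelse(!obs$mapped, "F",
         ifelse(obs$multiplicity > 1L, "M",
         ifelse(!has_sub & !has_clip &
                  obs$insertion_bases + obs$deletion_bases == 0L, "P",
         if (sub_first) ifelse(has_sub, "S", ifelse(has_clip, "C", "O"))
         else           ifelse(has_clip, "C", ifelse(has_sub, "S", "O"))))))
  factor(lab, levels = LABELS)
}

#' Profile of label fractions for one aligner run
#'
#' @param labels Factor from \code{\link{label_reads}}.
#' @param obs Matching observation table from \code{\link{digest_sam}}.
#' @param aligner Name of the aligner run (for reports).
#' @return An object of class \code{label_profile}: label counts and
#'   fractions (summing to 1), with the per-read observations and labels
#'   attached for downstream ratio and score analyses.
#' @export
profile_labels <- function(labels, obs, aligner = "aligner") {
  if (length(labels) == 0L) stop("no labeled reads")
  stopifnot(length(labels) == nrow(obs))
  counts <- table(factor(labels, levels = LABELS))
  structure(list(
    aligner = aligner,
    n_reads = length(labels),
    counts = setNames(as.integer(counts), LABELS),
    fractions = setNames(as.numeric(counts) / length(labels), LABELS),
    labels = labels,
    obs = obs
  ), class = "label_profile")
}

#' @export
print.label_profile <- function(x, ...) {
  cat(sprintf("Label profile (%s, %d reads)\n", x$aligner, x$n_reads))
  print(round(100 * x$fractions, 1))
  invisible(x)
}

#' Decompose a label profile into highly- and poorly-mapped percentages
#'
#' P and M reads are always highly mapped; F reads are always poorly mapped.
#' S, C, N and O reads are split by their error-density ratio (mismatch,
#' clip, N and indel ratio respectively): the part whose ratio strictly
#' exceeds its threshold is poorly mapped. PM\% is the sum of the
#' poorly-mapped (negative-bar) percentages.
#'
#' @param profile A \code{label_profile}.
#' @param th Thresholds from \code{\link{thresholds}}.
#' @return An object of class \code{pm_breakdown} with per-label
#'   \code{highly_mapped_pct} and \code{poorly_mapped_pct} (each summing with
#'   the other to 100) and the scalar \code{pm_pct}.
#' @export
compute_pm <- function(profile, th = thresholds()) {
  stopifnot(is(profile, "label_profile"), is(th, "asmqc_thresholds"))
  obs <- profile$obs
  lab <- profile$labels
  n <- profile$n_reads
  poor_read <- (lab == "F") |
    (lab == "S" & obs$mismatch_ratio > th$mismatch) |
    (lab == "C" & obs$clip_ratio > th$clip) |
    (lab == "N" & obs$n_ratio > th$n) |
    (if (is.na(th$other)) rep(FALSE, n) else
       lab == "O" & obs$indel_ratio > th$other)
  poor_pct <- 100 * as.numeric(table(factor(lab[poor_read], levels = LABELS))) / n
  names(poor_pct) <- LABELS
  high_pct <- 100 * profile$fractions - poor_pct
  structure(list(
    aligner = profile$aligner,
    thresholds = th,
    highly_mapped_pct = high_pct,
    poorly_mapped_pct = poor_pct,
    pm_pct = sum(poor_pct)
  ), class = "pm_breakdown")
}

#' @export
print.pm_breakdown <- function(x, ...) {
  cat(sprintf("PM%% breakdown (%s): PM%% = %s\n", x$aligner,
              format_pct(x$pm_pct)))
  invisible(x)
}

#' Average the PM\% of two aligner runs
#'
#' Two alignment strategies (typically a local and an end-to-end aligner)
#' yield one PM\% each; the final statistic is their arithmetic mean. With a
#' single run the final PM\% is that run's value.
#'
#' @param pm_a,pm_b \code{pm_breakdown} objects or bare percentages;
#'   \code{pm_b} may be \code{NULL}.
#' @return Final PM\% at full precision (round only for display, see
#'   \code{\link{format_pct}}).
#' @export
average_pm <- function(pm_a, pm_b = NULL) {
  val <- function(x) if (is(x, "pm_breakdown")) x$pm_pct else as.numeric(x)
  if (is.null(pm_b)) val(pm_a) else mean(c(val(pm_a), val(pm_b)))
}

#' Pass/fail verdict for an assembly
#'
#' The dataset passes when the final PM\% is strictly below the pass
#' threshold (default: PM\% < 20).
#'
#' @param final_pm Final PM\% in [0, 100].
#' @param th Thresholds (only \code{pm_pass} is used).
#' @return \code{TRUE} (pass) or \code{FALSE} (fail).
#' @export
pass_assessment <- function(final_pm, th = thresholds()) {
  stopifnot(is.numeric(final_pm), final_pm >= 0, final_pm <= 100)
  final_pm < th$pm_pass
}

#' Per-label alignment-score distributions
#'
#' Summarizes the aligner-reported alignment scores (AS tag) of each mapped
#' label. Higher scores mean better alignments; on typical data the medians
#' decline from P to S to C.
#'
#' @param profile A \code{label_profile} whose observations carry alignment
#'   scores.
#' @param labels Labels to summarize (default P, S, C).
#' @return Named list per label: \code{n}, \code{median}, \code{q1},
#'   \code{q3}, and a score histogram; a label with no scored reads yields an
#'   empty summary.
#' @export
alignment_score_stats <- function(profile, labels = c("P", "S", "C")) {
  stopifnot(is(profile, "label_profile"))
  out <- lapply(labels, function(L) {
    sc <- profile$obs$alignment_score[profile$labels == L]
    sc <- sc[!is.na(sc)]
    if (!length(sc)) return(list(n = 0L))
    qs <- quantile(sc, c(0.25, 0.5, 0.75), names = FALSE)
    h <- table(sc)
    list(n = length(sc), q1 = qs[1], median = qs[2], q3 = qs[3],
         histogram = setNames(as.integer(h), names(h)))
  })
  setNames(out, labels)
}

#' Format a percentage for display
#'
#' Values are carried at full precision internally; only display is rounded,
#' to one decimal. Rounding is decimal-aware (the value is first snapped to
#' four decimal digits so binary float noise cannot flip a digit) and exact
#' halves round toward zero, reproducing the method's printed statistics
#' (e.g. a mean of 8.8 and 16.3, 12.55, displays as 12.5).
#'
#' @param x Numeric percentage (vectorized).
#' @return Character, e.g. \code{"12.5"}.
#' @export
format_pct <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- sprintf("%.4f", abs(v))
    int <- as.numeric(sub("\\..*$", "", s))
    frac <- sub("^.*\\.", "", s)
    tenth <- as.integer(substr(frac, 1, 1))
    rest <- as.integer(substr(frac, 2, 4))
    if (rest > 500L) tenth <- tenth + 1L
    if (tenth == 10L) { int <- int + 1; tenth <- 0L }
    sprintf("%s%.0f.%d", if (v < 0) "-" else "", int, tenth)
  }, character(1))
}
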