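test_that("run_pre reports an all-HIGH fixture as 100% high-quality", {
  fq <- tempfile(fileext = ".fastq")
  sim_quality_reads(100, category_mix = c(HIGH = 1, MEDIUM = 0, POOR = 0),
                    seed = 2, path = fq)
  out <- tempfile()
  bundle <- run_pre(fq, out, sample_size = 50, seed = 1)
  expect_equal(bundle$n_sampled, 50L)
  expect_equal(bundle$summary$category_fractions$HIGH, 1)
  expect_true(file.exists(file.path(out, "sampled.fastq")))
  json <- read_json_bundle(file.path(out, "preassembly.json"))
  expect_equal(json$summary$category_fractions$HIGH, 1)
  html <- readLines(file.path(out, "pre_report.html"))
  expect_true(any(grepl("100.0", html, fixed = TRUE)))
})

test_that("bypassing sampling analyzes every read", {
  fq <- tempfile(fileext = ".fastq")
  sim_quality_reads(10, seed = 3, path = fq)
  bundle <- run_pre(fq, tempfile(), bypass_sampling = TRUE)
  expect_equal(bundle$n_sampled, 10L)
})

test_that("pre-assembly JSON output is deterministic given config and seed", {
  fq <- tempfile(fileext = ".fastq")
  sim_quality_reads(60, seed = 5, path = fq)
  o1 <- tempfile(); o2 <- tempfile()
  run_pre(fq, o1, sample_size = 30, seed = 99)
  run_pre(fq, o2, sample_size = 30, seed = 99)
  j1 <- readLines(file.path(o1, "preassembly.json"))
  j2 <- readLines(file.path(o2, "preassembly.json"))
  expect_identical(j1, j2)
})

post_fixture <- function(seed = 41, n = 140, ...) {
  fx <- sim_labeled_sam(n_reads = n, seed = seed, ...)
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(fx$reference, fa)
  list(fx = fx, fa = fa)
}

test_that("run_post reproduces the unit-level PM% and fails a 20% fixture", {
  # fixture engineered to PM% = 20.0 under both "aligner" runs
  pf <- post_fixture(seed = 31, n = 100,
    label_mix = c(P = 0.5, S = 0, C = 0.5, O = 0, M = 0, F = 0, N = 0),
    ratio_params = list(S = list(lo = 0.02, hi = 0.4, frac_hi = 0.5),
                        C = list(lo = 0.10, hi = 0.5, frac_hi = 0.4),
                        N = list(lo = 0.05, hi = 0.5, frac_hi = 0.5),
                        O = list(lo = 0.02, hi = 0.4, frac_hi = 0.5)))
  out <- tempfile()
  bundle <- run_post(pf$fx$fastq, pf$fa,
                     c(a = pf$fx$sam, b = pf$fx$sam), out)
  expect_equal(bundle$pm_summary$final_pm_pct, 20)
  expect_equal(bundle$pm_summary$verdict, "fail")   # strict: 20 is not < 20
  expect_false(bundle$pm_summary$single_aligner_mode)
})

test_that("end-to-end JSON equals module-level recomputation", {
  pf <- post_fixture(seed = 43)
  out <- tempfile()
  bundle <- run_post(pf$fx$fastq, pf$fa, c(sim = pf$fx$sam), out)

  obs <- digest_sam(pf$fx$sam, pf$fx$reads)
  prof <- profile_labels(label_reads(obs), obs, aligner = "sim")
  pm <- compute_pm(prof)
  expect_equal(unlist(bundle$runs$sim$fractions), prof$fractions)
  expect_equal(bundle$runs$sim$pm_pct, pm$pm_pct)
  expect_equal(bundle$pm_summary$final_pm_pct, pm$pm_pct)
  expect_true(bundle$pm_summary$single_aligner_mode)

  ast <- contiguity_stats(pf$fa)
  expect_equal(bundle$assembly_stats$nx, ast$nx)
  expect_equal(bundle$assembly_stats$gc_pct, ast$gc_pct)
})

test_that("JSON bundles round-trip through write/read", {
  pf <- post_fixture(seed = 47, n = 70)
  out <- tempfile()
  bundle <- run_post(pf$fx$fastq, pf$fa, c(sim = pf$fx$sam), out)
  rt <- read_json_bundle(file.path(out, "pm_summary.json"))
  expect_equal(rt$final_pm_pct, bundle$pm_summary$final_pm_pct)
  expect_equal(rt$verdict, bundle$pm_summary$verdict)
  rt2 <- read_json_bundle(file.path(out, "postassembly_sim.json"))
  expect_equal(unlist(rt2$fractions), unlist(bundle$runs$sim$fractions))
})

test_that("the HTML report displays the final PM% value", {
  pf <- post_fixture(seed = 53, n = 70)
  out <- tempfile()
  bundle <- run_post(pf$fx$fastq, pf$fa, c(sim = pf$fx$sam), out)
  html <- paste(readLines(file.path(out, "post_report.html")), collapse = "\n")
  expect_true(grepl(paste0("PM% = ", bundle$pm_summary$final_pm_display),
                    html, fixed = TRUE))
  expect_true(grepl("N50", html, fixed = TRUE))
})

test_that("bwa-aligned fixture reads are classified sensibly end to end", {
  # error-free reads drawn from the reference should map perfectly;
  # random reads should largely fail to map
  pf <- post_fixture(seed = 59, n = 80,
    label_mix = c(P = 0.8, S = 0, C = 0, O = 0, M = 0, F = 0.2, N = 0))
  mem_sam <- tempfile(fileext = ".sam")
  bt_sam <- tempfile(fileext = ".sam")
  align_bwa(pf$fa, pf$fx$fastq, mem_sam, "mem")
  align_bwa(pf$fa, pf$fx$fastq, bt_sam, "backtrack")
  out <- tempfile()
  bundle <- run_post(pf$fx$fastq, pf$fa,
                     c(mem = mem_sam, backtrack = bt_sam), out)
  for (run in bundle$runs) {
    fr <- unlist(run$fractions)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_gt(fr[["P"]] + fr[["M"]], 0.5)  # planted perfect reads map
  }
  expect_true(bundle$pm_summary$final_pm_pct <= 100)
})
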