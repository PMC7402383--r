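test_that("the seven canonical records each get their defining label", {
  cr <- canonical_records()
  obs <- digest_sam(cr$sam, cr$reads)
  expect_equal(as.character(label_reads(obs)), cr$truth)
  # and the independent raw-SAM oracle agrees
  expect_equal(oracle_labels(cr$sam, cr$reads), cr$truth)
})

test_that("labeling agrees with the brute-force oracle on randomized records", {
  fx <- sim_labeled_sam(n_reads = 200, seed = 17)
  obs <- digest_sam(fx$sam, fx$reads)
  got <- as.character(label_reads(obs))
  expect_equal(got, as.character(fx$truth))
  expect_equal(got, oracle_labels(fx$sam, fx$reads))
})

test_that("the N screen precedes every mapping-based label", {
  withN <- paste0(strrep("A", 99), "N")
  reads <- make_reads(withN, ids = "r1")
  sam <- write_sam(sam_line("r1", 0L, "100M", withN,
                            tags = c("NM:i:1", "MD:Z:99A")))
  obs <- digest_sam(sam, reads)
  expect_equal(as.character(label_reads(obs)), "N")  # despite a clean mapping
})

test_that("substitutions-plus-clips reads follow the configured priority", {
  s100 <- strrep("A", 100)
  reads <- make_reads(s100, ids = "r1")
  sam <- write_sam(sam_line("r1", 0L, "80M20S", s100,
                            tags = c("NM:i:1", "MD:Z:40C39")))
  obs <- digest_sam(sam, reads)
  expect_equal(as.character(label_reads(obs, priority = "SC")), "S")
  expect_equal(as.character(label_reads(obs, priority = "CS")), "C")
})

test_that("label fractions partition to one", {
  fx <- sim_labeled_sam(n_reads = 210, seed = 4)
  obs <- digest_sam(fx$sam, fx$reads)
  prof <- profile_labels(label_reads(obs), obs)
  expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(prof$counts), prof$n_reads)
  # degenerate profiles
  allP <- profile_labels(factor(rep("P", 10), levels = c("P", "S", "C", "O", "M", "F", "N")),
                         data.frame(row.names = 1:10))
  expect_equal(unname(allP$fractions["P"]), 1)
  mix <- profile_labels(factor(c(rep("P", 4), "F"),
                               levels = c("P", "S", "C", "O", "M", "F", "N")),
                        data.frame(row.names = 1:5))
  expect_equal(unname(mix$fractions[c("P", "F")]), c(0.8, 0.2))
})

make_profile <- function(labels, obs_extra = list()) {
  n <- length(labels)
  obs <- data.frame(mismatch_ratio = rep(0, n), clip_ratio = rep(0, n),
                    n_ratio = rep(0, n), indel_ratio = rep(0, n),
                    alignment_score = rep(NA_integer_, n))
  for (nm in names(obs_extra)) obs[[nm]] <- obs_extra[[nm]]
  profile_labels(factor(labels, levels = c("P", "S", "C", "O", "M", "F", "N")),
                 obs)
}

test_that("PM% worked decompositions match hand arithmetic", {
  expect_equal(compute_pm(make_profile(rep("P", 50)))$pm_pct, 0)
  expect_equal(compute_pm(make_profile(c(rep("P", 90), rep("F", 10))))$pm_pct, 10)
  # 50 P + 50 C of which 20 clip at 0.5 (above 0.3) and 30 at 0.1
  prof <- make_profile(c(rep("P", 50), rep("C", 50)),
                       list(clip_ratio = c(rep(0, 50), rep(0.5, 20), rep(0.1, 30))))
  pm <- compute_pm(prof)
  expect_equal(pm$pm_pct, 20)
  expect_equal(unname(pm$poorly_mapped_pct["C"]), 20)
  expect_equal(unname(pm$highly_mapped_pct["C"]), 30)
})

test_that("PM% decomposition invariants hold on random fixtures", {
  th <- thresholds()
  for (seed in 1:10) {
    fx <- sim_labeled_sam(n_reads = 140, seed = seed)
    obs <- digest_sam(fx$sam, fx$reads)
    prof <- profile_labels(label_reads(obs), obs)
    pm <- compute_pm(prof, th)
    expect_equal(pm$pm_pct, sum(pm$poorly_mapped_pct))
    expect_equal(sum(pm$highly_mapped_pct) + sum(pm$poorly_mapped_pct), 100,
                 tolerance = 1e-6)
    expect_gte(pm$pm_pct, 100 * prof$fractions[["F"]] - 1e-9)
    expect_lte(pm$pm_pct,
               100 * (1 - prof$fractions[["P"]] - prof$fractions[["M"]]) + 1e-9)
    # matches the generator's ground truth exactly
    expect_equal(pm$pm_pct, oracle_pm(fx$truth, fx$ratio))
  }
})

test_that("raising any threshold never increases PM%", {
  fx <- sim_labeled_sam(n_reads = 210, seed = 23)
  obs <- digest_sam(fx$sam, fx$reads)
  prof <- profile_labels(label_reads(obs), obs)
  grid <- c(0.05, 0.15, 0.3, 0.45, 0.6, 1)
  for (which in c("clip", "mismatch", "n", "other")) {
    pms <- vapply(grid, function(t) {
      args <- list(clip = 0.3, mismatch = 0.3, n = 0.3, other = 0.3)
      args[[which]] <- t
      compute_pm(prof, do.call(thresholds, args))$pm_pct
    }, numeric(1))
    expect_true(all(diff(pms) <= 1e-9))
  }
  # excluding O entirely can only lower PM%
  pm_o <- compute_pm(prof, thresholds(other = NA))$pm_pct
  expect_lte(pm_o, compute_pm(prof, thresholds())$pm_pct)
})

test_that("two-aligner averaging reproduces the worked final PM%", {
  expect_equal(format_pct(average_pm(8.8, 16.3)), "12.5")
  expect_equal(average_pm(8.8, 16.3), 12.55)
  expect_equal(average_pm(7.3, 7.3), 7.3)
  expect_equal(average_pm(0, 100), 50)
  expect_equal(average_pm(9.9), 9.9)  # single-aligner mode
})

test_that("the pass verdict is strict at the PM% threshold", {
  expect_true(pass_assessment(12.5))
  expect_false(pass_assessment(20.0))
  expect_false(pass_assessment(59))
  expect_true(pass_assessment(19.999999))
  expect_false(pass_assessment(30, thresholds(pm_pass = 30)))
  expect_true(pass_assessment(29.9, thresholds(pm_pass = 30)))
})

test_that("alignment score medians decline from P to S to C on fixtures", {
  fx <- sim_labeled_sam(n_reads = 350, seed = 29)
  obs <- digest_sam(fx$sam, fx$reads)
  prof <- profile_labels(label_reads(obs), obs)
  st <- alignment_score_stats(prof)
  expect_gte(st$P$median, st$S$median)
  expect_gte(st$S$median, st$C$median)
  # constant scores give that constant as the median
  cst <- make_profile(rep("P", 5), list(alignment_score = rep(70L, 5)))
  expect_equal(alignment_score_stats(cst)$P$median, 70)
  # an empty label yields an empty summary, not an error
  expect_equal(alignment_score_stats(cst)$C$n, 0L)
})
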