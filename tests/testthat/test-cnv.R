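test_that("confidence filtering is strict below the LBF threshold", {
  calls <- rbind(call_row(lbf = 9.99), call_row(lbf = 10), call_row(lbf = 35),
                 call_row(lbf = 2), call_row(lbf = NA, caller = "noLBF"))
  kept <- filter_calls_by_confidence(calls, lbf_min = 10)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$lbf >= 10, na.rm = TRUE))
  expect_equal(sum(kept$lbf_flagged), 1)       # no-LBF caller passes, flagged
  expect_equal(nrow(filter_calls_by_confidence(calls[0, ])), 0)
})

test_that("reciprocal overlap fractions are computed per interval", {
  expect_equal(reciprocal_overlap(c(100, 200), c(100, 200)), c(1, 1))
  expect_equal(reciprocal_overlap(c(100, 200), c(300, 400)), c(0, 0))
  expect_equal(reciprocal_overlap(c(100, 200), c(150, 250)), c(0.5, 0.5))
  expect_equal(reciprocal_overlap(c(0, 1000), c(400, 500)), c(0.1, 1))
  expect_equal(reciprocal_overlap(c(100, 200), c(100, 200), "1", "2"),
               c(0, 0))
  # abutting half-open intervals do not overlap
  expect_equal(reciprocal_overlap(c(100, 200), c(200, 300)), c(0, 0))
})

test_that("consensus requires two callers passing reciprocal overlap", {
  two <- rbind(call_row(caller = "cA"), call_row(caller = "cB"),
               call_row(start = 50000, end = 60000, caller = "cC"))
  cons <- merge_consensus(two, threshold = 0.5)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_callers, 2)
  expect_equal(cons$callers, "cA,cB")

  solo <- call_row(caller = "only")
  expect_equal(nrow(merge_consensus(solo)), 0)

  # jittered trio: intersection and envelope conventions
  trio <- rbind(call_row(start = 1000, end = 2000, caller = "cA"),
                call_row(start = 1100, end = 2100, caller = "cB"),
                call_row(start = 950, end = 1900, caller = "cC"))
  cons3 <- merge_consensus(trio, threshold = 0.5)
  expect_equal(nrow(cons3), 1)
  expect_equal(cons3$start, 1100L)
  expect_equal(cons3$end, 1900L)
  expect_equal(cons3$env_start, 950L)
  expect_equal(cons3$env_end, 2100L)
  expect_equal(cons3$n_callers, 3)

  # different state or sample never merges
  mixed <- rbind(call_row(caller = "cA", state = "DEL"),
                 call_row(caller = "cB", state = "DUP"))
  expect_equal(nrow(merge_consensus(mixed)), 0)
})

test_that("consensus is invariant to caller and call order", {
  d <- toy_design(n_subjects = 150, cnv_loci = default_cnv_loci()[1:6, ])
  sim <- simulate_cnv_calls(d, default_caller_profiles(), seed = 30)
  calls <- do.call(rbind, sim$calls)
  base <- merge_consensus(calls)
  set.seed(31)
  for (rep in 1:3) {
    perm <- calls[sample.int(nrow(calls)), ]
    expect_identical(merge_consensus(perm), base)
  }
  # list-of-callers input, list order permuted
  expect_identical(merge_consensus(rev(sim$calls)), base)
})

test_that("dropping a caller never enlarges the consensus set", {
  d <- toy_design(n_subjects = 200, cnv_loci = default_cnv_loci()[1:6, ])
  sim <- simulate_cnv_calls(d, default_caller_profiles(), seed = 32)
  full <- merge_consensus(sim$calls)
  for (drop in seq_along(sim$calls)) {
    sub <- merge_consensus(sim$calls[-drop])
    expect_lte(nrow(sub), nrow(full))
  }
})

test_that("exclusion regions remove any 1-bp overlap but not abutment", {
  excl <- data.frame(chrom = "1", start = 5000L, end = 6000L, name = "x")
  ev <- rbind(call_row(start = 5200, end = 5800),     # inside
              call_row(start = 4000, end = 5001),     # 1-bp overlap
              call_row(start = 4000, end = 5000),     # abutting
              call_row(start = 6000, end = 7000),     # abutting right
              call_row(chrom = "2", start = 5200, end = 5800))
  out <- remove_excluded_regions(ev, excl)
  expect_equal(nrow(out), 3)
  expect_true(all(out$start %in% c(4000, 6000, 5200)))
})

test_that("catalog matching is reciprocal, state-aware and best-overlap", {
  catalog <- data.frame(
    region = c("rA", "rB", "rC"), chrom = c("1", "1", "1"),
    start = c(1000L, 10000L, 1200L), end = c(2000L, 11000L, 2200L),
    state = c("DEL", "DUP", "DEL"), source = "synthetic",
    freq = c(0.1, 0.01, 0.05), stringsAsFactors = FALSE)

  exact <- call_row(start = 1000, end = 2000)
  exact$env_start <- exact$start; exact$env_end <- exact$end
  m <- match_catalog(exact, catalog, 0.4)
  expect_equal(m$region, "rA")          # best overlap beats partial rC

  wrong_state <- call_row(start = 10000, end = 11000, state = "DEL")
  wrong_state$env_start <- 10000L; wrong_state$env_end <- 11000L
  expect_true(is.na(match_catalog(wrong_state, catalog, 0.4)$region))

  # 45% reciprocal overlap passes the 40% rule
  part <- call_row(start = 450, end = 1450)
  part$env_start <- 450L; part$env_end <- 1450L
  m2 <- match_catalog(part, catalog, 0.4)  # overlaps rA by 450/1000 = 45%
  expect_equal(m2$region, "rA")
  expect_equal(m2$match_frac, 0.45, tolerance = 1e-9)
  # at 50% it fails
  expect_true(is.na(match_catalog(part, catalog, 0.5)$region))
})

test_that("frequency classification splits at 1% carrier frequency", {
  counts <- stats::setNames(c(24L, 23L, 0L), c("x", "y", "z"))
  cls <- classify_frequency(counts, 2348, 0.01)
  expect_equal(cls$class, c("common", "rare", "rare"))
  expect_true(cls$absent[3])
  expect_error(classify_frequency(stats::setNames(10L, "w"), 5), "exceed")
})

test_that("CNV scores count class events with optional length filter", {
  matched <- rbind(call_row(start = 1000, end = 2000),
                   call_row(start = 9000, end = 9990),
                   call_row(sample = "S2", start = 1000, end = 2000))
  matched$region <- c("r1", "r2", "r1")
  matched$env_start <- matched$start
  matched$env_end <- matched$start + c(150000L, 90000L, 50000L)
  rc <- data.frame(region = c("r1", "r2"), carriers = c(2L, 1L),
                   freq = c(0.2, 0.1), class = c("rare", "rare"),
                   absent = FALSE, stringsAsFactors = FALSE)
  samples <- c("S1", "S2", "S3")
  sc <- build_cnv_scores(matched, rc, "rare", samples)
  expect_equal(unname(sc), c(2L, 1L, 0L))
  big <- build_cnv_scores(matched, rc, "rare", samples, min_length = 100000)
  expect_equal(unname(big), c(1L, 0L, 0L))  # 90-kb and 50-kb events dropped
  expect_equal(unname(build_cnv_scores(matched, rc, "common", samples)),
               c(0L, 0L, 0L))
})

test_that("genome-wide burden counts rare-locus events per subject", {
  samples <- sprintf("S%d", 1:500)
  # one common locus (200 carriers) and scattered singleton rare events
  common_ev <- data.frame(sample = samples[1:200], chrom = "2",
                          start = 100000L, end = 150000L, state = "DEL",
                          stringsAsFactors = FALSE)
  rare_ev <- data.frame(sample = c("S1", "S1", "S1", "S2"), chrom = "3",
                        start = c(1e6, 3e6, 5e6, 7e6),
                        end = c(1.2e6, 3.2e6, 5.2e6, 7.2e6), state = "DEL",
                        stringsAsFactors = FALSE)
  burden <- compute_burden(rbind(common_ev, rare_ev), samples,
                           common_freq = 0.01)
  expect_equal(unname(burden[c("S1", "S2", "S3")]), c(3L, 1L, 0L))
  loci <- attr(burden, "loci")
  expect_equal(nrow(loci), 5)
  expect_equal(max(loci$carriers), 200)

  # subjects with only common events have zero burden
  expect_equal(unname(burden["S100"]), 0L)

  # planted Poisson rate: mean burden within 3 SE of lambda
  lambda <- 0.4
  set.seed(33)
  k <- stats::rpois(length(samples), lambda)
  ev <- data.frame(sample = rep(samples, k), chrom = "4",
                   start = seq_len(sum(k)) * 100000L,
                   end = seq_len(sum(k)) * 100000L + 20000L,
                   state = "DUP", stringsAsFactors = FALSE)
  bur <- compute_burden(ev, samples, common_freq = 0.01)
  se <- sqrt(lambda / length(samples))
  expect_lt(abs(mean(bur) - lambda), 3 * se)
})

test_that("noise-free pipeline recovers the planted truth end to end", {
  loci <- default_cnv_loci()[c(1, 2, 3, 10, 40), ]
  d <- toy_design(n_subjects = 400, cnv_loci = loci)
  sim <- simulate_cnv_calls(d, perfect_profiles(), seed = 34)
  cons <- merge_consensus(do.call(rbind, sim$calls), threshold = 0.5)
  truth <- sim$truth$events
  expect_equal(nrow(cons), nrow(truth))
  expect_equal(cons$start, truth$start)
  expect_equal(cons$end, truth$end)
  expect_equal(cons$sample, truth$sample)
  expect_true(all(cons$n_callers == 3))

  catalog <- default_cnv_catalog()
  matched <- match_catalog(cons, catalog[catalog$region %in% loci$region, ],
                           0.4)
  expect_false(any(is.na(matched$region)))    # every planted event matched
  expect_identical(matched$region, truth$region)

  carriers <- carrier_matrix(matched, rownames(sim$truth$carriers),
                             loci$region)
  expect_identical(carriers == 1L, sim$truth$carriers)
})
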