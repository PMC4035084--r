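test_that("hard calls follow Hardy-Weinberg moments", {
  n <- 10000
  d <- toy_design(n_subjects = n, catalog = toy_catalog(1, freq = 0.5))
  gs <- simulate_genotypes(d, seed = 1)
  g <- gs$hard[, 1]
  se_mean <- sqrt(2 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(g) - 1.0), 3 * se_mean)
  props <- tabulate(g + 1L, 3) / n
  for (k in 1:3) {
    p <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(props[k] - p), 3 * sqrt(p * (1 - p) / n))
  }

  # monomorphic edges
  d0 <- toy_design(50, catalog = toy_catalog(1, freq = 0))
  expect_true(all(simulate_genotypes(d0, seed = 2)$hard == 0L))
  d1 <- toy_design(50, catalog = toy_catalog(1, freq = 1))
  expect_true(all(simulate_genotypes(d1, seed = 2)$hard == 2L))
})

test_that("probability blur hits the target info and degenerates at 1", {
  d <- toy_design(n_subjects = 10000, catalog = toy_catalog(1, freq = 0.3))
  gs <- simulate_genotypes(d, seed = 3)
  blurred <- blur_to_probabilities(gs, quality = 0.8, seed = 4, freq = 0.3)
  expect_true(all(abs(apply(blurred$prob, 1:2, sum) - 1) < 1e-9))
  dosage <- blurred$prob[, 1, 2] + 2 * blurred$prob[, 1, 3]
  expect_gt(info_statistic(dosage, 0.3), 0.75)
  expect_lt(info_statistic(dosage, 0.3), 0.85)

  # quality = 1: degenerate one-hot triples, e.g. het -> (0,1,0)
  exact <- blur_to_probabilities(gs, quality = 1, seed = 5, freq = 0.3)
  het <- which(gs$hard[, 1] == 1L)[1]
  expect_identical(unname(exact$prob[het, 1, ]), c(0, 1, 0))
  expect_equal(exact$prob[, 1, 2] + 2 * exact$prob[, 1, 3],
               as.numeric(gs$hard[, 1]), ignore_attr = TRUE)

  expect_error(blur_to_probabilities(gs, quality = 0), "quality")
  expect_error(blur_to_probabilities(gs, quality = 1.2), "quality")
})

test_that("proxy markers reach the target squared correlation", {
  d <- toy_design(n_subjects = 20000, catalog = toy_catalog(1, freq = 0.5))
  gs <- simulate_genotypes(d, seed = 6)

  ident <- simulate_proxy(gs, r2 = 1, seed = 7)
  expect_identical(unname(ident$hard), unname(gs$hard))

  pr <- simulate_proxy(gs, r2 = 0.8, seed = 8)
  r2 <- stats::cor(gs$hard[, 1], pr$hard[, 1])^2
  expect_gt(r2, 0.77); expect_lt(r2, 0.83)

  # near-independence limit: tiny target r2 gives near-zero correlation
  lo <- simulate_proxy(gs, r2 = 0.001, seed = 9)
  r2lo <- stats::cor(gs$hard[, 1], lo$hard[, 1])^2
  expect_lt(r2lo, 0.01)

  expect_error(simulate_proxy(gs, r2 = 0), "r2")
})

test_that("noise-free callers reproduce the planted truth; carrier frequency is honored", {
  loci <- default_cnv_loci()[1:5, ]
  d <- toy_design(n_subjects = 300, cnv_loci = loci)
  sim <- simulate_cnv_calls(d, perfect_profiles(), seed = 10)
  truth <- sim$truth$events
  for (cl in sim$calls) {
    expect_equal(nrow(cl), nrow(truth))
    expect_equal(cl$start, truth$start)
    expect_equal(cl$end, truth$end)
    expect_equal(cl$sample, truth$sample)
  }

  # planted common locus at 16.9%: carrier count within 3 binomial SEs
  n <- 2348
  d2 <- toy_design(n_subjects = n,
                   cnv_loci = default_cnv_loci()[1, , drop = FALSE])
  sim2 <- simulate_cnv_calls(d2, perfect_profiles(), seed = 11)
  carriers <- sum(sim2$truth$carriers)
  expect_lt(abs(carriers - n * 0.169), 3 * sqrt(n * 0.169 * (1 - 0.169)))

  # sensitivity 0 with spurious calls: nothing overlaps a planted locus
  blind <- list(caller_profile("b1", sensitivity = 0, false_call_rate = 0.5),
                caller_profile("b2", sensitivity = 0, false_call_rate = 0.5))
  sim3 <- simulate_cnv_calls(d2, blind, seed = 12)
  for (cl in sim3$calls) {
    loci1 <- d2$cnv_loci
    ov <- vapply(seq_len(nrow(cl)), function(i) {
      any(loci1$chrom == cl$chrom[i] & cl$start[i] < loci1$end &
            cl$end[i] > loci1$start)
    }, logical(1))
    expect_false(any(ov))
  }
})

test_that("phenotype variance components are calibrated analytically", {
  fr <- list(covariates = 0.083, grss = 0.031, cnv = 0.001)
  n <- 100000
  d <- simulation_design(n_subjects = n, variance_fractions = fr)
  gs <- simulate_genotypes(d, seed = 13)
  set.seed(14)
  carriers <- vapply(d$cnv_loci$freq,
                     function(q) stats::rbinom(n, 1L, q) == 1L, logical(n))
  dimnames(carriers) <- list(sprintf("S%04d", 1:n), d$cnv_loci$region)
  ph <- simulate_phenotypes(d, gs, carriers, seed = 15)
  truth <- attr(ph, "truth")
  bmi <- compute_bmi(ph$height, ph$weight)
  v_bmi <- stats::var(bmi)

  score <- as.numeric(gs$hard %*% d$catalog$beta)
  frac_g <- stats::var(truth$scale_grss * score) / v_bmi
  expect_lt(abs(frac_g - fr$grss), 0.005)

  eff <- d$cnv_loci$effect
  frac_c <- stats::var(truth$scale_cnv * as.numeric(carriers %*% eff)) / v_bmi
  expect_lt(abs(frac_c - fr$cnv), 0.005)

  b <- d$covariate_effects
  lp <- b[["PC1"]] * ph$PC1 + b[["PC4"]] * ph$PC4 + b[["PC8"]] * ph$PC8 +
    b[["sex"]] * ph$sex + b[["age"]] * ph$age + b[["AD"]] * ph$AD +
    b[["ND"]] * ph$ND + b[["PC1_sex"]] * ph$PC1 * ph$sex +
    b[["age_AD"]] * ph$age * ph$AD
  frac_cov <- stats::var(truth$scale_cov * lp) / v_bmi
  expect_lt(abs(frac_cov - fr$covariates), 0.005)

  # total variance solved from the residual SD
  expect_lt(abs(v_bmi - truth$v_total) / truth$v_total, 0.02)
})

test_that("mean BMI matches the design intercept", {
  d <- simulation_design(n_subjects = 2348)
  gs <- simulate_genotypes(d, seed = 16)
  set.seed(17)
  carriers <- vapply(d$cnv_loci$freq,
                     function(q) stats::rbinom(2348, 1L, q) == 1L,
                     logical(2348))
  dimnames(carriers) <- list(sprintf("S%04d", 1:2348), d$cnv_loci$region)
  ph <- simulate_phenotypes(d, gs, carriers, seed = 18)
  bmi <- compute_bmi(ph$height, ph$weight)
  expect_lt(abs(mean(bmi) - 27.63), 0.5)
})

test_that("a zero GRSS fraction leaves BMI independent of genotype", {
  r2 <- replicate(30, {
    d <- toy_design(n_subjects = 2348,
                    variance_fractions = list(covariates = 0.083, grss = 0,
                                              cnv = 0))
    gs <- simulate_genotypes(d, seed = NULL)
    ph <- simulate_phenotypes(d, gs, carriers = NULL, seed = NULL)
    score <- as.numeric(gs$hard %*% d$catalog$beta)
    bmi <- compute_bmi(ph$height, ph$weight)
    summary(stats::lm(bmi ~ score))$r.squared
  })
  expect_lt(mean(r2), 0.002)
})

test_that("single-SNP variance algebra solves the closed form", {
  # one SNP, f = 0.5, beta = 1, target fraction 0.5, no covariates:
  # raw genetic variance 2 * 0.5 * 0.5 = 0.5; with residual fraction 0.5 the
  # noise variance must equal the scaled genetic variance
  d <- simulation_design(
    n_subjects = 5000, catalog = toy_catalog(1, freq = 0.5, beta = 1),
    variance_fractions = list(covariates = 0, grss = 0.5, cnv = 0),
    residual_sd = sqrt(0.5))
  gs <- simulate_genotypes(d, seed = 19)
  ph <- simulate_phenotypes(d, gs, carriers = NULL, seed = 20)
  truth <- attr(ph, "truth")
  expect_equal(truth$v_total, 1.0, tolerance = 1e-12)
  expect_equal(truth$scale_grss, 1.0, tolerance = 1e-12)  # already 0.5 raw
})

test_that("identical seed and design give byte-identical cohorts", {
  d <- toy_design(n_subjects = 120)
  a <- simulate_cohort(d, seed = 99)
  b <- simulate_cohort(d, seed = 99)
  expect_identical(a$genotypes$hard, b$genotypes$hard)
  expect_identical(a$genotypes$prob, b$genotypes$prob)
  expect_identical(a$proxy$hard, b$proxy$hard)
  expect_identical(a$cnv$calls, b$cnv$calls)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_cohort(d, seed = 100)
  expect_false(identical(a$phenotypes$weight, c$phenotypes$weight))
})
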