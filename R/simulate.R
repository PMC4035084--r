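# Synthetic cohort generation.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: biallelic genotypes under Hardy-Weinberg equilibrium and linkage
# equilibrium, imputation-probability triples of configurable quality, proxy
# markers at configurable LD, three noisy CNV callers over planted loci, and
# BMI from a linear model whose covariate / SNP-score / CNV components are
# scaled analytically to hit target fractions of phenotypic variance.

#' Default synthetic SNP risk catalog
#'
#' A deterministic 32-SNP catalog: risk-allele frequencies evenly spread over
#' (0.1, 0.9) and per-allele effects evenly spread over 0.06-0.39 kg/m^2
#' (the magnitude range reported for validated common BMI loci). Risk allele
#' is always the ALT allele, with an unambiguous (non-A/T, non-C/G) allele
#' pair.
#'
#' @param n_snps number of SNPs.
#' @return a `variant_catalog` data.frame.
#' @export
default_snp_catalog <- function(n_snps = 32L) {
  freq <- seq(0.10, 0.90, length.out = n_snps)
  beta <- seq(0.06, 0.39, length.out = n_snps)
  out <- data.frame(
    snp_id = sprintf("snp%02d", seq_len(n_snps)),
    chrom = as.character(rep(1:22, length.out = n_snps)),
    pos = as.integer(1e6 + seq_len(n_snps) * 1e5),
    risk_allele = "G",
    other_allele = "A",
    beta = beta,
    freq = freq,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_catalog", "data.frame")
  out
}

#' Default planted CNV loci
#'
#' 84 loci emulating a literature catalog of BMI/obesity-associated CNVs:
#' three common loci (a 21-kb deletion at carrier frequency 16.9% — the only
#' locus with a BMI effect by default —, a 66-kb duplication at 1.2%, and a
#' 1440-kb deletion at 7.7%) plus 81 rare loci (< 1%) with mixed states and
#' lengths from 20 kb to 2 Mb. Loci are placed non-overlapping across
#' chromosomes 1-22.
#'
#' @return data.frame with columns region, chrom, start, end, state, freq,
#'   effect (relative BMI effect per carrier; rescaled by the phenotype
#'   generator to hit the CNV variance fraction).
#' @export
default_cnv_loci <- function() {
  n_rare <- 81L
  rare_freq <- seq(0.0005, 0.009, length.out = n_rare)
  rare_len <- round(exp(seq(log(2e4), log(2e6), length.out = n_rare)))
  rare_chrom <- rep(1:22, length.out = n_rare)
  rare_start <- 2e7 + (seq_len(n_rare) %/% 22L) * 1e7 +
    (seq_len(n_rare) %% 7L) * 3e6
  rare <- data.frame(
    region = sprintf("reg%02d", seq_len(n_rare)),
    chrom = as.character(rare_chrom),
    start = as.integer(rare_start),
    end = as.integer(rare_start + rare_len),
    state = rep(c("DEL", "DUP"), length.out = n_rare),
    freq = rare_freq,
    effect = 0,
    stringsAsFactors = FALSE
  )
  common <- data.frame(
    region = c("del16p-like", "dup1p-like", "del5q-like"),
    chrom = c("16", "1", "5"),
    start = as.integer(c(5e6, 8e6, 7e7)),
    end = as.integer(c(5e6 + 21000, 8e6 + 66000, 7e7 + 1440000)),
    state = c("DEL", "DUP", "DEL"),
    freq = c(0.169, 0.012, 0.077),
    effect = c(1, 0, 0),
    stringsAsFactors = FALSE
  )
  rbind(common, rare)
}

#' Default literature-style CNV catalog derived from the planted loci
#'
#' The catalog the matching stage consumes: the same 84 intervals as
#' [default_cnv_loci()], labelled as a synthetic source.
#'
#' @return data.frame in CNV-catalog format (see [read_cnv_catalog()]).
#' @export
default_cnv_catalog <- function() {
  loci <- default_cnv_loci()
  data.frame(region = loci$region, chrom = loci$chrom, start = loci$start,
             end = loci$end, state = loci$state, source = "synthetic",
             freq = loci$freq, stringsAsFactors = FALSE)
}

#' Default exclusion regions
#'
#' Telomere/centromere-like intervals (first 2 Mb of several chromosomes and
#' a mid-arm band) used to exercise the exclusion filter; placed away from
#' the default planted loci.
#'
#' @return BED-style data.frame.
#' @export
default_exclusion_regions <- function() {
  data.frame(
    chrom = as.character(c(1:22, 1:11)),
    start = as.integer(c(rep(0L, 22), rep(140000000L, 11))),
    end = as.integer(c(rep(2000000L, 22), rep(143000000L, 11))),
    name = c(sprintf("telomere_%d", 1:22), sprintf("centromere_%d", 1:11)),
    stringsAsFactors = FALSE
  )
}

# chromosome lengths defining the coordinate space for spurious calls
genome_table <- function() {
  data.frame(chrom = as.character(1:22),
             length = as.integer(round(seq(2.4e8, 5e7, length.out = 22))),
             stringsAsFactors = FALSE)
}

#' Caller error profile
#'
#' Describes one CNV caller's error model: detection sensitivity, Gaussian
#' boundary jitter, expected spurious calls per subject, and normal
#' parameters for the Log Bayes Factor of true and spurious calls. Callers
#' that do not emit an LBF (has_lbf = FALSE) report NA confidence.
#'
#' @param name caller label.
#' @param sensitivity detection probability for a carried event, in (0, 1].
#' @param boundary_jitter_sd SD (bp) of boundary error, >= 0.
#' @param false_call_rate expected spurious calls per subject (Poisson).
#' @param lbf_true,lbf_spurious length-2 numeric c(mean, sd) of LBF draws.
#' @param has_lbf whether the caller emits an LBF at all.
#' @return a `caller_profile` list.
#' @export
caller_profile <- function(name, sensitivity = 0.95, boundary_jitter_sd = 300,
                           false_call_rate = 0.25,
                           lbf_true = c(40, 12), lbf_spurious = c(8, 4),
                           has_lbf = TRUE) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, boundary_jitter_sd >= 0,
            false_call_rate >= 0)
  structure(list(name = name, sensitivity = sensitivity,
                 boundary_jitter_sd = boundary_jitter_sd,
                 false_call_rate = false_call_rate,
                 lbf_true = lbf_true, lbf_spurious = lbf_spurious,
                 has_lbf = has_lbf),
            class = "caller_profile")
}

#' Default trio of caller profiles
#'
#' Three callers with distinct error characteristics; callerA emits no LBF
#' (confidence filtering then passes its calls through, flagged), the other
#' two emit LBF with true calls well above and spurious calls mostly below
#' the default confidence threshold of 10.
#'
#' @return list of three `caller_profile`s.
#' @export
default_caller_profiles <- function() {
  list(
    caller_profile("callerA", sensitivity = 0.92, boundary_jitter_sd = 400,
                   false_call_rate = 0.20, has_lbf = FALSE),
    caller_profile("callerB", sensitivity = 0.95, boundary_jitter_sd = 250,
                   false_call_rate = 0.30),
    caller_profile("callerC", sensitivity = 0.90, boundary_jitter_sd = 600,
                   false_call_rate = 0.25)
  )
}

#' Simulation design
#'
#' Bundles everything the cohort generator needs. Variance fractions give
#' each component's target share of total phenotypic variance; scaling
#' constants are solved analytically (see [simulate_phenotypes()]) so the
#' shares hold exactly in expectation. Covariate marginals default to a
#' substance-use-enriched adult cohort: 57% female, age 39.9 (SD 9.0),
#' alcohol dependence 66%/31% (male/female), nicotine dependence 53%/46%.
#'
#' @param n_subjects cohort size (default 2348, split 1850/498 across two
#'   ancestry groups).
#' @param catalog SNP risk catalog (default [default_snp_catalog()]).
#' @param cnv_loci planted CNV loci (default [default_cnv_loci()]).
#' @param variance_fractions named list/vector with covariates, grss, cnv
#'   fractions of phenotypic variance; must sum to < 1.
#' @param residual_sd SD (kg/m^2) of the Gaussian noise term; with the
#'   default fractions this yields a total BMI SD of about 6 kg/m^2.
#' @param intercept mean BMI (kg/m^2).
#' @param imputation_quality target imputation info in (0, 1].
#' @param proxy_r2 target squared dosage correlation of proxy markers, (0, 1].
#' @param proxy_missing snp_ids with no adequate proxy (dropped from proxy
#'   genotypes); defaults to the last catalog SNP, leaving 31 of 32.
#' @param covariate_effects named numeric of relative covariate coefficients
#'   (PC1, PC4, PC8, sex, age, AD, ND, PC1_sex, age_AD).
#' @param covariate_marginals named list of marginal parameters (p_female,
#'   age_mean, age_sd, p_ad_male, p_ad_female, p_nd_male, p_nd_female).
#' @param n_group_a size of the first ancestry group.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_subjects = 2348L,
                              catalog = default_snp_catalog(),
                              cnv_loci = default_cnv_loci(),
                              variance_fractions = list(covariates = 0.083,
                                                        grss = 0.031,
                                                        cnv = 0.001),
                              residual_sd = 5.6,
                              intercept = 27.63,
                              imputation_quality = 0.95,
                              proxy_r2 = 0.8,
                              proxy_missing = NULL,
                              covariate_effects = c(PC1 = 0.30, PC4 = 0.10,
                                                    PC8 = 0.10, sex = -1.00,
                                                    age = 0.04, AD = -0.20,
                                                    ND = -0.06,
                                                    PC1_sex = 0.15,
                                                    age_AD = -0.02),
                              covariate_marginals = list(p_female = 0.5694,
                                                         age_mean = 39.9,
                                                         age_sd = 9.0,
                                                         p_ad_male = 0.665,
                                                         p_ad_female = 0.314,
                                                         p_nd_male = 0.525,
                                                         p_nd_female = 0.461),
                              n_group_a = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  fr <- unlist(variance_fractions)
  if (any(fr < 0) || sum(fr) >= 1) {
    stop("variance fractions must be non-negative and sum to < 1",
         call. = FALSE)
  }
  # boundary frequencies (monomorphic loci) are legal for the generator,
  # though the catalog readers require (0, 1)
  if (any(catalog$freq < 0 | catalog$freq > 1)) {
    stop("catalog frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(cnv_loci) && nrow(cnv_loci) > 0 &&
      any(cnv_loci$freq <= 0 | cnv_loci$freq >= 1)) {
    stop("CNV locus frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (imputation_quality <= 0 || imputation_quality > 1) {
    stop("imputation_quality must lie in (0, 1]", call. = FALSE)
  }
  if (proxy_r2 <= 0 || proxy_r2 > 1) {
    stop("proxy_r2 must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(proxy_missing)) {
    proxy_missing <- utils::tail(catalog$snp_id, 1)
  }
  if (is.null(n_group_a)) n_group_a <- round(n_subjects * 1850 / 2348)
  structure(list(n_subjects = n_subjects, catalog = catalog,
                 cnv_loci = cnv_loci,
                 variance_fractions = as.list(fr),
                 residual_sd = residual_sd, intercept = intercept,
                 imputation_quality = imputation_quality,
                 proxy_r2 = proxy_r2, proxy_missing = proxy_missing,
                 covariate_effects = covariate_effects,
                 covariate_marginals = covariate_marginals,
                 n_group_a = as.integer(n_group_a)),
            class = "simulation_design")
}

#' Simulate hard-call genotypes under HWE
#'
#' Each SNP's ALT (risk) dosage is drawn as Binomial(2, f) independently per
#' subject and locus (Hardy-Weinberg and linkage equilibrium).
#'
#' @param design a `simulation_design` (its catalog supplies frequencies).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return a `genotype_set` with hard calls.
#' @export
simulate_genotypes <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cat <- design$catalog
  if (nrow(cat) == 0) stop("catalog is empty", call. = FALSE)
  n <- design$n_subjects
  hard <- vapply(cat$freq, function(f) stats::rbinom(n, 2L, f),
                 integer(n))
  samples <- sprintf("S%04d", seq_len(n))
  dimnames(hard) <- list(samples, cat$snp_id)
  variants <- data.frame(snp_id = cat$snp_id, chrom = cat$chrom,
                         pos = cat$pos, ref = cat$other_allele,
                         alt = cat$risk_allele, stringsAsFactors = FALSE)
  genotype_set(variants, hard = hard, samples = samples)
}

#' Imputation info statistic
#'
#' Ratio of the observed dosage variance to the binomial variance 2f(1-f);
#' equals 1 for perfectly imputed (hard-call) dosages and shrinks toward 0
#' as imputed dosages regress to the allele-frequency mean.
#'
#' @param dosage numeric vector of dosages in \[0, 2\].
#' @param freq allele frequency.
#' @return the info statistic.
#' @export
info_statistic <- function(dosage, freq) {
  stats::var(dosage, na.rm = TRUE) / (2 * freq * (1 - freq))
}

# Expected info for the Gaussian-signal posterior model at noise sd tau:
# observe s = g + N(0, tau^2), form the HWE posterior over g in {0,1,2};
# info = Var(E[g|s]) / (2f(1-f)), computed by numerical integration.
blur_expected_info <- function(tau, f) {
  if (tau <= 0) return(1)
  prior <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  post_mean_sq <- function(s) {
    d0 <- prior[1] * stats::dnorm(s, 0, tau)
    d1 <- prior[2] * stats::dnorm(s, 1, tau)
    d2 <- prior[3] * stats::dnorm(s, 2, tau)
    tot <- d0 + d1 + d2
    ifelse(tot > 0, ((d1 + 2 * d2) / tot)^2, 0)
  }
  # E[m(s)^2] as a mixture over the true genotype, each component
  # integrated on a local window so narrow signal peaks are not missed
  e_m2 <- 0
  for (g in 0:2) {
    if (prior[g + 1] == 0) next
    e_m2 <- e_m2 + prior[g + 1] * stats::integrate(
      function(s) stats::dnorm(s, g, tau) * post_mean_sq(s),
      g - 12 * tau, g + 12 * tau, rel.tol = 1e-9)$value
  }
  (e_m2 - (2 * f)^2) / (2 * f * (1 - f))
}

# Solve the noise sd tau whose expected info equals the quality target.
calibrate_blur_tau <- function(f, quality) {
  if (quality >= 1) return(0)
  g <- function(log_tau) blur_expected_info(exp(log_tau), f) - quality
  stats::uniroot(g, lower = log(1e-3), upper = log(50), tol = 1e-10)$root |>
    exp()
}

#' Blur hard calls into imputation-probability triples
#'
#' Emulates imputation of configurable quality: a Gaussian intensity signal
#' s = g + N(0, tau^2) is observed for each true genotype g and converted to
#' the posterior P(g | s) under the Hardy-Weinberg prior at the SNP's allele
#' frequency. tau is calibrated per SNP by root-finding so that the expected
#' info statistic (dosage variance over 2f(1-f)) equals `quality`. At
#' quality = 1 the triples are exactly degenerate on the true genotype.
#'
#' @param gs `genotype_set` with hard calls.
#' @param quality target info in (0, 1].
#' @param seed integer seed or NULL.
#' @param freq per-variant allele frequencies; defaults to sample frequencies
#'   estimated from the hard calls.
#' @return the genotype set with a probability array added.
#' @export
blur_to_probabilities <- function(gs, quality, seed = NULL, freq = NULL) {
  if (quality <= 0) stop("quality must lie in (0, 1]", call. = FALSE)
  if (quality > 1) stop("quality must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(gs, "genotype_set"), !is.null(gs$hard))
  n <- length(gs$samples); m <- nrow(gs$variants)
  if (is.null(freq)) {
    freq <- colMeans(gs$hard, na.rm = TRUE) / 2
  }
  freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
  prob <- array(NA_real_, dim = c(n, m, 3),
                dimnames = list(gs$samples, gs$variants$snp_id, NULL))
  tau_cache <- new.env(parent = emptyenv())
  for (j in seq_len(m)) {
    f <- freq[j]
    key <- sprintf("%.12g", f)
    if (is.null(tau_cache[[key]])) {
      tau_cache[[key]] <- calibrate_blur_tau(f, quality)
    }
    tau <- tau_cache[[key]]
    g <- gs$hard[, j]
    ok <- !is.na(g)
    if (tau == 0) {
      p <- matrix(0, nrow = n, ncol = 3)
      p[cbind(seq_len(n), g + 1L)] <- 1
      p[!ok, ] <- NA_real_
      prob[, j, ] <- p
      next
    }
    s <- g + stats::rnorm(n, 0, tau)
    prior <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    d <- cbind(prior[1] * stats::dnorm(s, 0, tau),
               prior[2] * stats::dnorm(s, 1, tau),
               prior[3] * stats::dnorm(s, 2, tau))
    d <- d / rowSums(d)
    d[!ok, ] <- NA_real_
    prob[, j, ] <- d
  }
  gs$prob <- prob
  gs
}

# Flip probability theta giving squared allelic correlation r2 at frequency f.
proxy_flip_prob <- function(f, r2) {
  if (r2 >= 1) return(0)
  r_target <- sqrt(r2)
  g <- function(theta) {
    p2 <- f + theta * (1 - 2 * f)
    f * (1 - f) * (1 - 2 * theta) / sqrt(f * (1 - f) * p2 * (1 - p2)) -
      r_target
  }
  stats::uniroot(g, lower = 0, upper = 0.5 - 1e-12, tol = 1e-12)$root
}

#' Simulate proxy markers at a target LD
#'
#' For each SNP, each of the two haplotype alleles is copied to the proxy
#' with a flip probability chosen (by root-finding) so the squared allelic —
#' and hence dosage — correlation with the original equals `r2` in
#' expectation. r2 = 1 reproduces the originals exactly.
#'
#' @param gs `genotype_set` with hard calls.
#' @param r2 target squared correlation in (0, 1].
#' @param seed integer seed or NULL.
#' @param drop snp_ids to omit from the proxy set (markers with no adequate
#'   proxy); default none.
#' @return a `genotype_set` of proxy hard calls.
#' @export
simulate_proxy <- function(gs, r2, seed = NULL, drop = character(0)) {
  if (r2 <= 0 || r2 > 1) stop("r2 must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(gs, "genotype_set"), !is.null(gs$hard))
  keep <- !gs$variants$snp_id %in% drop
  hard <- gs$hard[, keep, drop = FALSE]
  variants <- gs$variants[keep, , drop = FALSE]
  n <- nrow(hard)
  freq <- pmin(pmax(colMeans(hard, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
  proxy <- hard
  for (j in seq_len(ncol(hard))) {
    theta <- proxy_flip_prob(freq[j], r2)
    if (theta == 0) next
    g <- hard[, j]
    # haplotype alleles: g==1 -> (1, 0); flips independent per haplotype
    a1 <- as.integer(g >= 1)
    a2 <- as.integer(g == 2)
    f1 <- stats::rbinom(n, 1L, theta)
    f2 <- stats::rbinom(n, 1L, theta)
    proxy[, j] <- abs(a1 - f1) + abs(a2 - f2)
    proxy[is.na(g), j] <- NA_integer_
  }
  variants$snp_id <- paste0(variants$snp_id, "_proxy")
  colnames(proxy) <- variants$snp_id
  genotype_set(variants, hard = proxy, samples = gs$samples)
}

#' Simulate multi-caller CNV call sets over planted loci
#'
#' Each subject carries each planted locus independently at its frequency.
#' Each caller detects a carried event with its sensitivity, jitters both
#' boundaries by Gaussian error, and draws an LBF from its true-call
#' distribution. Spurious calls arrive per subject as Poisson with the
#' caller's false-call rate, placed uniformly on the genome outside planted
#' loci with log-normal lengths and LBFs from the spurious distribution.
#'
#' @param design a `simulation_design` (supplies loci and cohort size).
#' @param profiles list of >= 2 [caller_profile()]s.
#' @param seed integer seed or NULL.
#' @return list with `calls` (named list of per-caller call data.frames) and
#'   `truth` (list: `carriers` subjects x loci logical matrix, `events`
#'   data.frame of true events).
#' @export
simulate_cnv_calls <- function(design, profiles = default_caller_profiles(),
                               seed = NULL) {
  if (length(profiles) < 2) stop("need at least 2 caller profiles", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  loci <- design$cnv_loci
  n <- design$n_subjects
  samples <- sprintf("S%04d", seq_len(n))
  nl <- nrow(loci)
  carriers <- matrix(stats::rbinom(n * nl, 1L, rep(loci$freq, each = n)) == 1L,
                     nrow = n, dimnames = list(samples, loci$region))
  idx <- which(carriers, arr.ind = TRUE)
  events <- data.frame(
    sample = samples[idx[, 1]],
    chrom = loci$chrom[idx[, 2]],
    start = loci$start[idx[, 2]],
    end = loci$end[idx[, 2]],
    state = loci$state[idx[, 2]],
    region = loci$region[idx[, 2]],
    stringsAsFactors = FALSE
  )
  events <- events[order(events$sample, events$chrom, events$start), ]
  rownames(events) <- NULL
  genome <- genome_table()

  one_caller <- function(prof) {
    det <- stats::rbinom(nrow(events), 1L, prof$sensitivity) == 1L
    tru <- events[det, , drop = FALSE]
    if (nrow(tru) > 0) {
      js <- round(stats::rnorm(nrow(tru), 0, prof$boundary_jitter_sd))
      je <- round(stats::rnorm(nrow(tru), 0, prof$boundary_jitter_sd))
      start <- pmax(0, tru$start + js)
      end <- tru$end + je
      swap <- end <= start
      end[swap] <- start[swap] + pmax(1L, tru$end[swap] - tru$start[swap])
      lbf <- if (prof$has_lbf) {
        pmax(0, stats::rnorm(nrow(tru), prof$lbf_true[1], prof$lbf_true[2]))
      } else NA_real_
      tru_calls <- data.frame(sample = tru$sample, chrom = tru$chrom,
                              start = as.integer(start),
                              end = as.integer(end), state = tru$state,
                              copy_number = ifelse(tru$state == "DEL", 1L, 3L),
                              lbf = lbf, caller = prof$name,
                              stringsAsFactors = FALSE)
    } else {
      tru_calls <- NULL
    }
    n_spur <- stats::rpois(n, prof$false_call_rate)
    total <- sum(n_spur)
    if (total > 0) {
      subj <- rep(samples, n_spur)
      len <- pmax(1000L, as.integer(round(stats::rlnorm(total, log(3e4), 0.8))))
      chrom_i <- sample.int(nrow(genome), total, replace = TRUE)
      start <- integer(total); chrom <- character(total)
      for (k in seq_len(total)) {
        for (try in 1:50) {
          ci <- if (try == 1) chrom_i[k] else sample.int(nrow(genome), 1)
          st <- as.integer(floor(stats::runif(1, 0,
                                              genome$length[ci] - len[k])))
          hit <- loci$chrom == genome$chrom[ci] &
            st < loci$end & (st + len[k]) > loci$start
          if (!any(hit)) { chrom[k] <- genome$chrom[ci]; start[k] <- st; break }
        }
      }
      state <- sample(c("DEL", "DUP"), total, replace = TRUE)
      lbf <- if (prof$has_lbf) {
        pmax(0, stats::rnorm(total, prof$lbf_spurious[1], prof$lbf_spurious[2]))
      } else NA_real_
      spur_calls <- data.frame(sample = subj, chrom = chrom, start = start,
                               end = as.integer(start + len), state = state,
                               copy_number = ifelse(state == "DEL", 1L, 3L),
                               lbf = lbf, caller = prof$name,
                               stringsAsFactors = FALSE)
    } else {
      spur_calls <- NULL
    }
    out <- rbind(tru_calls, spur_calls)
    if (is.null(out)) {
      out <- data.frame(sample = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        state = character(0), copy_number = integer(0),
                        lbf = numeric(0), caller = character(0),
                        stringsAsFactors = FALSE)
    }
    out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  }

  calls <- lapply(profiles, one_caller)
  names(calls) <- vapply(profiles, `[[`, character(1), "name")
  list(calls = calls, truth = list(carriers = carriers, events = events))
}

# Analytic mean and variance of the covariate linear predictor under the
# generator's marginals (sex Bernoulli; age Normal independent of the rest;
# AD and ND Bernoulli with sex-dependent rates, conditionally independent
# given sex; PCs standard Normal independent of everything).
covariate_lp_moments <- function(effects, marg) {
  pF <- marg$p_female
  eD <- (1 - pF) * marg$p_ad_male + pF * marg$p_ad_female
  eN <- (1 - pF) * marg$p_nd_male + pF * marg$p_nd_female
  vD <- eD * (1 - eD); vN <- eN * (1 - eN); vS <- pF * (1 - pF)
  covSD <- pF * marg$p_ad_female - pF * eD
  covSN <- pF * marg$p_nd_female - pF * eN
  eDN <- (1 - pF) * marg$p_ad_male * marg$p_nd_male +
    pF * marg$p_ad_female * marg$p_nd_female
  covDN <- eDN - eD * eN
  mu_a <- marg$age_mean; v_a <- marg$age_sd^2
  b <- effects
  # PC blocks: E[PC]=0 and PC independent of all else, so each PC block is
  # uncorrelated with the rest; PC1 enters both alone and via PC1*sex.
  var_pc1 <- b[["PC1"]]^2 + 2 * b[["PC1"]] * b[["PC1_sex"]] * pF +
    b[["PC1_sex"]]^2 * pF
  var_pc <- var_pc1 + b[["PC4"]]^2 + b[["PC8"]]^2
  # age enters alone and via age*AD: U = age*(b_a + b_adInt*D) + rest
  ca <- b[["age"]]; ci <- b[["age_AD"]]
  var_age_part <- v_a * (ca^2 + 2 * ca * ci * eD + ci^2 * eD)  # E[(ca+ci D)^2]
  cD <- b[["AD"]] + mu_a * ci
  var_disc <- cD^2 * vD + b[["sex"]]^2 * vS + b[["ND"]]^2 * vN +
    2 * cD * b[["sex"]] * covSD + 2 * cD * b[["ND"]] * covDN +
    2 * b[["sex"]] * b[["ND"]] * covSN
  mean_lp <- b[["sex"]] * pF + ca * mu_a + b[["AD"]] * eD + b[["ND"]] * eN +
    ci * mu_a * eD
  list(mean = mean_lp, var = var_pc + var_age_part + var_disc)
}

#' Simulate BMI phenotypes with calibrated variance fractions
#'
#' BMI = intercept + covariate predictor + c * (sum_i beta_i g_i) + CNV term
#' + Gaussian noise. The genetic component's raw variance under HWE/LE is
#' sum_i 2 f_i (1-f_i) beta_i^2; the covariate predictor's variance is
#' computed analytically from the design marginals; the CNV term's raw
#' variance is sum_l effect_l^2 q_l (1-q_l) over carrier frequencies q_l.
#' Each component is rescaled so its share of total phenotypic variance
#' (total = residual_sd^2 / residual fraction) equals its target exactly in
#' expectation. Components are mean-centered so mean BMI equals the
#' intercept. Height is drawn per sex and weight back-computed so the QC
#' stage can recompute BMI from height and weight.
#'
#' @param design a `simulation_design`.
#' @param genotypes `genotype_set` of true hard calls for the catalog SNPs.
#' @param carriers subjects x loci logical carrier matrix (from
#'   [simulate_cnv_calls()] truth), or NULL when the CNV fraction is 0.
#' @param seed integer seed or NULL.
#' @return phenotype data.frame (subject_id, ancestry, sex, age, AD, ND,
#'   PC1, PC4, PC8, height, weight) with attribute `truth` recording the
#'   total variance and the solved component scales.
#' @export
simulate_phenotypes <- function(design, genotypes, carriers = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  marg <- design$covariate_marginals
  fr <- design$variance_fractions
  res_frac <- 1 - fr$covariates - fr$grss - fr$cnv
  if (res_frac <= 0) stop("variance fractions must sum to < 1", call. = FALSE)
  v_total <- design$residual_sd^2 / res_frac

  sex <- stats::rbinom(n, 1L, marg$p_female)           # 1 = female
  age <- stats::rnorm(n, marg$age_mean, marg$age_sd)
  ad <- stats::rbinom(n, 1L, ifelse(sex == 1, marg$p_ad_female, marg$p_ad_male))
  nd <- stats::rbinom(n, 1L, ifelse(sex == 1, marg$p_nd_female, marg$p_nd_male))
  pc1 <- stats::rnorm(n); pc4 <- stats::rnorm(n); pc8 <- stats::rnorm(n)
  b <- design$covariate_effects
  lp_cov <- b[["PC1"]] * pc1 + b[["PC4"]] * pc4 + b[["PC8"]] * pc8 +
    b[["sex"]] * sex + b[["age"]] * age + b[["AD"]] * ad + b[["ND"]] * nd +
    b[["PC1_sex"]] * pc1 * sex + b[["age_AD"]] * age * ad
  mom <- covariate_lp_moments(b, marg)
  s_cov <- if (fr$covariates > 0) sqrt(fr$covariates * v_total / mom$var) else 0

  beta <- design$catalog$beta
  f <- design$catalog$freq
  score <- as.numeric(genotypes$hard %*% beta)
  v_g_raw <- sum(2 * f * (1 - f) * beta^2)
  s_g <- if (fr$grss > 0) sqrt(fr$grss * v_total / v_g_raw) else 0
  e_score <- sum(beta * 2 * f)

  if (fr$cnv > 0) {
    if (is.null(carriers)) stop("cnv fraction > 0 needs a carrier matrix",
                                call. = FALSE)
    eff <- design$cnv_loci$effect
    q <- design$cnv_loci$freq
    v_c_raw <- sum(eff^2 * q * (1 - q))
    if (v_c_raw <= 0) {
      stop("cnv variance fraction > 0 but no locus has a nonzero effect",
           call. = FALSE)
    }
    lp_cnv <- as.numeric(carriers %*% eff)
    s_c <- sqrt(fr$cnv * v_total / v_c_raw)
    e_cnv <- sum(eff * q)
  } else {
    lp_cnv <- 0; s_c <- 0; e_cnv <- 0
  }

  bmi <- design$intercept +
    s_cov * (lp_cov - mom$mean) +
    s_g * (score - e_score) +
    s_c * (lp_cnv - e_cnv) +
    stats::rnorm(n, 0, design$residual_sd)

  height <- ifelse(sex == 1, stats::rnorm(n, 1.64, 0.06),
                   stats::rnorm(n, 1.78, 0.07))
  height <- pmin(pmax(height, 1.45), 1.98)
  weight <- bmi * height^2
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    ancestry = rep(c("groupA", "groupB"),
                   c(design$n_group_a, n - design$n_group_a)),
    sex = sex, age = age, AD = ad, ND = nd,
    PC1 = pc1, PC4 = pc4, PC8 = pc8,
    height = height, weight = weight,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(v_total = v_total, scale_cov = s_cov,
                             scale_grss = s_g, scale_cnv = s_c,
                             fractions = fr)
  out
}

#' Simulate a full cohort
#'
#' Runs the whole generator under one seed: HWE hard calls at the catalog
#' frequencies, imputation-probability triples at the design quality, proxy
#' hard calls at the design r2 (omitting `proxy_missing` SNPs), three-caller
#' CNV call sets over the planted loci, and BMI phenotypes calibrated to the
#' design's variance fractions.
#'
#' @param design a `simulation_design`.
#' @param profiles caller profiles for the CNV generator.
#' @param seed integer seed.
#' @return list with `design`, `genotypes` (hard + probability triples),
#'   `proxy`, `cnv` (calls + truth) and `phenotypes`.
#' @export
simulate_cohort <- function(design = simulation_design(),
                            profiles = default_caller_profiles(),
                            seed = 1L) {
  set.seed(seed)
  gs <- simulate_genotypes(design, seed = NULL)
  gs <- blur_to_probabilities(gs, design$imputation_quality, seed = NULL,
                              freq = design$catalog$freq)
  proxy <- simulate_proxy(gs, design$proxy_r2, seed = NULL,
                          drop = design$proxy_missing)
  cnv <- simulate_cnv_calls(design, profiles, seed = NULL)
  phen <- simulate_phenotypes(design, gs, cnv$truth$carriers, seed = NULL)
  list(design = design, genotypes = gs, proxy = proxy, cnv = cnv,
       phenotypes = phen, seed = seed)
}
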