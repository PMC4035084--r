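# SNP genetic risk sum scores (GRSS).
#
# Six methods: {count, weighted} x {proxy hard calls, imputed hard calls,
# imputation probabilities}. Scores are averages of beta-weighted risk-allele
# dosages; the denominator convention (per counted allele, 2n, for hard-call
# methods; per SNP, n, for probability methods) only changes the scale, and
# downstream association statistics are invariant to it.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize a genotype set's alleles with a risk catalog
#'
#' Matches each catalog SNP to a variant by `snp_id` and determines whether
#' the risk allele is the VCF ALT or REF allele, attempting a strand flip
#' (base complement) when the direct comparison fails. Palindromic A/T and
#' C/G SNPs cannot be disambiguated by strand and are flagged; they are
#' excluded unless `allow_ambiguous = TRUE`.
#'
#' @param gs a `genotype_set`.
#' @param catalog a `variant_catalog`.
#' @param allow_ambiguous keep palindromic SNPs (assuming the reported
#'   strand) instead of excluding them.
#' @return data.frame, one row per catalog SNP: snp_id, col (variant column
#'   index or NA), risk_is_alt, ambiguous, usable.
#' @export
harmonize_alleles <- function(gs, catalog, allow_ambiguous = FALSE) {
  col <- match(catalog$snp_id, gs$variants$snp_id)
  risk_is_alt <- rep(NA, nrow(catalog))
  ambiguous <- rep(FALSE, nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    j <- col[i]
    if (is.na(j)) next
    risk <- toupper(catalog$risk_allele[i])
    other <- toupper(catalog$other_allele[i])
    ref <- toupper(gs$variants$ref[j]); alt <- toupper(gs$variants$alt[j])
    ambiguous[i] <- identical(sort(c(risk, other)),
                              sort(unname(.complement[c(risk, other)])))
    if (risk == alt && other == ref) {
      risk_is_alt[i] <- TRUE
    } else if (risk == ref && other == alt) {
      risk_is_alt[i] <- FALSE
    } else {
      flip_r <- unname(.complement[risk]); flip_o <- unname(.complement[other])
      if (identical(flip_r, alt) && identical(flip_o, ref)) {
        risk_is_alt[i] <- TRUE
      } else if (identical(flip_r, ref) && identical(flip_o, alt)) {
        risk_is_alt[i] <- FALSE
      } else {
        stop("alleles for ", catalog$snp_id[i],
             " do not match the catalog even after strand flip (",
             risk, "/", other, " vs ", alt, "/", ref, ")", call. = FALSE)
      }
    }
  }
  usable <- !is.na(col) & !is.na(risk_is_alt) &
    (!ambiguous | allow_ambiguous)
  data.frame(snp_id = catalog$snp_id, col = col, risk_is_alt = risk_is_alt,
             ambiguous = ambiguous, usable = usable, stringsAsFactors = FALSE)
}

#' Risk-allele dosage from a hard-call genotype
#'
#' @param genotype character of two alleles (e.g. `c("G","A")`) or a single
#'   "G/A" string; NA or "./." for missing.
#' @param risk_allele,other_allele catalog alleles for this SNP.
#' @return integer count of risk alleles (0, 1, 2) or NA when missing.
#' @export
risk_dosage_from_hardcall <- function(genotype, risk_allele, other_allele) {
  if (length(genotype) == 1 && (is.na(genotype) || genotype %in% c("./.", "."))) {
    return(NA_integer_)
  }
  alleles <- if (length(genotype) == 1) {
    strsplit(genotype, "[/|]")[[1]]
  } else genotype
  if (any(is.na(alleles) | alleles == ".")) return(NA_integer_)
  ok <- alleles %in% c(risk_allele, other_allele)
  if (!all(ok)) {
    stop("genotype allele(s) ", paste(alleles[!ok], collapse = ","),
         " not among catalog alleles ", risk_allele, "/", other_allele,
         " (possible strand/orientation fault)", call. = FALSE)
  }
  sum(alleles == risk_allele)
}

#' Risk-allele dosage from a genotype-probability triple
#'
#' The expected risk-allele count p = 0*P(0) + 1*P(1) + 2*P(2), with the
#' triple ordered by risk-allele count.
#'
#' @param triple numeric length 3, non-negative, summing to 1 within 1e-6.
#' @return dosage in \[0, 2\].
#' @export
risk_dosage_from_probabilities <- function(triple) {
  if (length(triple) != 3 || anyNA(triple) || any(triple < 0) ||
      abs(sum(triple) - 1) > 1e-6) {
    stop("malformed genotype-probability triple", call. = FALSE)
  }
  triple[2] + 2 * triple[3]
}

#' Expected dosage for a missing genotype
#'
#' Missing SNP information is scored at its expectation under HWE from the
#' sample risk-allele frequency, p = 2f.
#'
#' @param freq risk-allele frequency in (0, 1).
#' @return dosage 2f.
#' @export
impute_missing_dosage <- function(freq) {
  if (any(!is.finite(freq) | freq <= 0 | freq >= 1)) {
    stop("allele frequency must lie strictly in (0, 1)", call. = FALSE)
  }
  2 * freq
}

#' Build the subjects x SNPs risk-dosage matrix
#'
#' Orients genotypes to the catalog risk allele and fills missing entries
#' with 2f from the sample allele frequency (computed over non-missing
#' subjects in this genotype set), per the missing-data policy. Probability
#' dosages use the expected risk-allele count of each triple.
#'
#' @param gs a `genotype_set`.
#' @param catalog a `variant_catalog` restricted to the SNPs to score.
#' @param source "hard" for hard calls, "prob" for probability triples.
#' @param impute_missing fill missing entries with 2f (default) or keep NA.
#' @param allow_ambiguous passed to [harmonize_alleles()].
#' @return numeric matrix, one column per usable catalog SNP, with the
#'   harmonization table as attribute `harmonization`.
#' @export
risk_dosage_matrix <- function(gs, catalog, source = c("hard", "prob"),
                               impute_missing = TRUE,
                               allow_ambiguous = FALSE) {
  source <- match.arg(source)
  harm <- harmonize_alleles(gs, catalog, allow_ambiguous = allow_ambiguous)
  use <- which(harm$usable)
  if (length(use) == 0) stop("no usable catalog SNPs in genotype set",
                             call. = FALSE)
  n <- length(gs$samples)
  out <- matrix(NA_real_, nrow = n, ncol = length(use),
                dimnames = list(gs$samples, harm$snp_id[use]))
  for (k in seq_along(use)) {
    i <- use[k]; j <- harm$col[i]
    if (source == "hard") {
      d <- as.numeric(gs$hard[, j])
      if (!harm$risk_is_alt[i]) d <- 2 - d
    } else {
      if (is.null(gs$prob)) stop("genotype set has no probability triples",
                                 call. = FALSE)
      p <- gs$prob[, j, ]
      d <- if (harm$risk_is_alt[i]) p[, 2] + 2 * p[, 3] else p[, 2] + 2 * p[, 1]
    }
    if (impute_missing && anyNA(d)) {
      f <- mean(d, na.rm = TRUE) / 2
      if (is.nan(f) || f <= 0 || f >= 1) f <- catalog$freq[i]
      d[is.na(d)] <- impute_missing_dosage(f)
    }
    out[, k] <- d
  }
  attr(out, "harmonization") <- harm
  out
}

#' Compute a genetic risk sum score
#'
#' score_subject = sum_i beta_i p_i / D with D = 2n (per counted allele,
#' the hard-call convention) or n (per SNP, the probability convention),
#' where n is the number of SNPs in the score. Count scores use beta = 1.
#'
#' @param dosages subjects x SNPs risk-dosage matrix.
#' @param weights per-SNP effect sizes in column order, or NULL for a count
#'   score.
#' @param denominator "per_allele" (2n) or "per_snp" (n).
#' @return named numeric vector of per-subject scores; subjects with all
#'   dosages missing are NA.
#' @export
compute_grss <- function(dosages, weights = NULL,
                         denominator = c("per_allele", "per_snp")) {
  denominator <- match.arg(denominator)
  m <- ncol(dosages)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) {
    stop("need one weight per dosage column", call. = FALSE)
  }
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  d <- if (denominator == "per_allele") 2 * m else m
  all_missing <- apply(dosages, 1, function(r) all(is.na(r)))
  dos <- dosages
  dos[is.na(dos)] <- 0          # partial missingness already imputed upstream
  score <- as.numeric(dos %*% weights) / d
  score[all_missing] <- NA_real_
  stats::setNames(score, rownames(dosages))
}

#' All six GRSS methods for a cohort
#'
#' Computes proxy count/weighted (hard calls on the proxy marker set,
#' per-allele denominator), imputed count/weighted (hard calls, per-allele)
#' and probability count/weighted (probability dosages, per-SNP) scores.
#'
#' @param imputed `genotype_set` with hard calls and probability triples for
#'   the catalog SNPs.
#' @param catalog the risk catalog.
#' @param proxy optional proxy `genotype_set`; proxy variant ids may carry a
#'   "_proxy" suffix on the catalog snp_id. NULL skips proxy scores.
#' @param allow_ambiguous passed through to harmonization.
#' @return data.frame keyed by subject_id with one column per method.
#' @export
grss_all_methods <- function(imputed, catalog, proxy = NULL,
                             allow_ambiguous = FALSE) {
  beta_for <- function(ids) catalog$beta[match(ids, catalog$snp_id)]
  hard <- risk_dosage_matrix(imputed, catalog, "hard",
                             allow_ambiguous = allow_ambiguous)
  prob <- risk_dosage_matrix(imputed, catalog, "prob",
                             allow_ambiguous = allow_ambiguous)
  out <- data.frame(
    subject_id = imputed$samples,
    imputed_count = compute_grss(hard, NULL, "per_allele"),
    imputed_weighted = compute_grss(hard, beta_for(colnames(hard)),
                                    "per_allele"),
    prob_count = compute_grss(prob, NULL, "per_snp"),
    prob_weighted = compute_grss(prob, beta_for(colnames(prob)), "per_snp"),
    stringsAsFactors = FALSE
  )
  if (!is.null(proxy)) {
    base_ids <- sub("_proxy$", "", proxy$variants$snp_id)
    pcat <- catalog[match(base_ids, catalog$snp_id), , drop = FALSE]
    pcat <- pcat[!is.na(pcat$snp_id), , drop = FALSE]
    pcat$snp_id <- paste0(pcat$snp_id, "_proxy")
    # proxy markers carry the same allele pair as the SNP they stand in for
    phard <- risk_dosage_matrix(proxy, pcat, "hard",
                                allow_ambiguous = allow_ambiguous)
    out$proxy_count <- compute_grss(phard, NULL, "per_allele")
    out$proxy_weighted <- compute_grss(phard, beta_for(sub("_proxy$", "",
                                                           colnames(phard))),
                                       "per_allele")
  }
  rownames(out) <- NULL
  out
}

#' Compare two GRSS effect sizes
#'
#' z = (ES_a - ES_b) / sqrt(SE_a^2 + SE_b^2), with a two-sided p-value from
#' the standard normal distribution. Used to test whether scoring methods
#' yield different BMI effect sizes.
#'
#' @param es_a,se_a,es_b,se_b effect estimates and standard errors of the
#'   two methods' regression coefficients.
#' @return list with `z` and `p`.
#' @export
compare_effect_sizes <- function(es_a, se_a, es_b, se_b) {
  if (se_a <= 0 || se_b <= 0) {
    stop("standard errors must be positive", call. = FALSE)
  }
  z <- (es_a - es_b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
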