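# Shared in-code fixtures: everything is generated, nothing is stored.

# a small catalog with hand-pickable frequencies/effects
toy_catalog <- function(n = 4, freq = NULL, beta = NULL) {
  cat <- default_snp_catalog(n)
  if (!is.null(freq)) cat$freq <- freq
  if (!is.null(beta)) cat$beta <- beta
  cat
}

# default toy design drops the CNV phenotype component so phenotypes can be
# simulated without a carrier matrix; tests that need it pass fractions in
toy_design <- function(n_subjects = 200, ...) {
  dots <- list(...)
  if (is.null(dots$variance_fractions)) {
    dots$variance_fractions <- list(covariates = 0.083, grss = 0.031, cnv = 0)
  }
  do.call(simulation_design, c(list(n_subjects = n_subjects), dots))
}

# noise-free caller trio: consensus must equal planted truth exactly
perfect_profiles <- function() {
  list(
    caller_profile("pA", sensitivity = 1, boundary_jitter_sd = 0,
                   false_call_rate = 0),
    caller_profile("pB", sensitivity = 1, boundary_jitter_sd = 0,
                   false_call_rate = 0),
    caller_profile("pC", sensitivity = 1, boundary_jitter_sd = 0,
                   false_call_rate = 0)
  )
}

# one CNV call row
call_row <- function(sample = "S1", chrom = "1", start = 1000L, end = 2000L,
                     state = "DEL", lbf = 40, caller = "cA") {
  data.frame(sample = sample, chrom = chrom, start = as.integer(start),
             end = as.integer(end), state = state,
             copy_number = if (state == "DEL") 1L else 3L, lbf = lbf,
             caller = caller, stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
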