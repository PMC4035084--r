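#' Read a risk-variant catalog
#'
#' The catalog is a tab-separated table with one row per risk SNP and header
#' columns `snp_id`, `chrom`, `pos`, `risk_allele`, `other_allele`, `beta`
#' (per-allele effect in kg/m^2) and `freq` (risk-allele frequency).
#' Rows are returned in file order.
#'
#' @param path TSV file.
#' @return a data.frame of class `variant_catalog`, one row per SNP.
#' @export
read_variant_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp_id", "chrom", "pos", "risk_allele", "other_allele",
                "beta", "freq")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("variant catalog is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$snp_id)) {
    stop("duplicate snp_id in variant catalog: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  tab$beta <- as.numeric(tab$beta)
  tab$freq <- as.numeric(tab$freq)
  tab$pos <- as.integer(tab$pos)
  if (nrow(tab) > 0 && any(!is.finite(tab$freq) | tab$freq <= 0 | tab$freq >= 1)) {
    stop("risk-allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  class(tab) <- c("variant_catalog", "data.frame")
  tab
}

#' Write a risk-variant catalog
#' @param catalog data.frame with the catalog columns.
#' @param path output TSV path.
#' @export
write_variant_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-caller CNV calls
#'
#' Expects a TSV with columns `sample`, `chrom`, `start`, `end`, `state`
#' (DEL or DUP), `copy_number`, `lbf` (Log Bayes Factor; NA for callers that
#' do not emit one) and `caller`. Coordinates are 0-based half-open.
#'
#' @param path TSV file.
#' @return data.frame of calls with intervals `start < end`.
#' @export
read_cnv_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  required <- c("sample", "chrom", "start", "end", "state", "copy_number",
                "lbf", "caller")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("CNV call table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$lbf <- as.numeric(tab$lbf)
  bad_state <- !tab$state %in% c("DEL", "DUP")
  if (any(bad_state)) {
    stop("unknown CNV state token(s): ",
         paste(unique(tab$state[bad_state]), collapse = ", "), call. = FALSE)
  }
  if (any(tab$start >= tab$end)) {
    stop("CNV intervals must satisfy start < end (0-based half-open)",
         call. = FALSE)
  }
  tab
}

#' @rdname read_cnv_calls
#' @param calls data.frame of CNV calls.
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file (e.g. exclusion regions)
#'
#' Standard 3+ column BED: chrom, start, end, optional name. 0-based
#' half-open, no header.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0 && any(out$start >= out$end)) {
    stop("BED intervals must satisfy start < end", call. = FALSE)
  }
  out
}

#' @rdname read_bed
#' @param intervals data.frame with chrom/start/end (and optionally name).
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, intersect(c("chrom", "start", "end", "name"),
                                names(intervals)), drop = FALSE]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a literature CNV-region catalog
#'
#' TSV with columns `region` (cytoband-style label), `chrom`, `start`, `end`,
#' `state` (DEL/DUP), `source`, `freq` (frequency reported by the source).
#'
#' @param path TSV file.
#' @return data.frame of catalog regions.
#' @export
read_cnv_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("region", "chrom", "start", "end", "state", "source", "freq")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("CNV catalog is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(tab$start >= tab$end)) {
    stop("catalog intervals must satisfy start < end", call. = FALSE)
  }
  if (!all(tab$state %in% c("DEL", "DUP"))) {
    stop("catalog state must be DEL or DUP", call. = FALSE)
  }
  tab
}

#' Read a phenotype/covariate table
#'
#' TSV with one row per subject. Expected columns include `subject_id`,
#' `height` (m), `weight` (kg), `sex`, `age`, `AD`, `ND`, `ancestry` and any
#' principal-component columns (`PC*`). Missing values are `NA`.
#'
#' @param path TSV file.
#' @return data.frame of subject records.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!"subject_id" %in% names(tab)) {
    stop("phenotype table is missing column: subject_id", call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame of subject records.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genotypes: VCF in, VCF out
# ---------------------------------------------------------------------------

#' Construct a genotype set
#'
#' The in-memory genotype container: a subjects x variants hard-call dosage
#' matrix counting ALT alleles (NA = missing), an optional subjects x
#' variants x 3 array of genotype-probability triples ordered by ALT-allele
#' count (0, 1, 2), and the variant table (snp_id, chrom, pos, ref, alt).
#'
#' @param variants data.frame with columns snp_id, chrom, pos, ref, alt.
#' @param hard integer matrix (subjects x variants) of ALT dosages or NULL.
#' @param prob 3-d array (subjects x variants x 3) or NULL.
#' @param samples character vector of subject ids.
#' @return an object of class `genotype_set`.
#' @export
genotype_set <- function(variants, hard = NULL, prob = NULL, samples = NULL) {
  if (is.null(samples)) {
    samples <- if (!is.null(hard)) rownames(hard) else dimnames(prob)[[1]]
  }
  if (is.null(samples)) stop("samples could not be inferred", call. = FALSE)
  structure(list(variants = variants, hard = hard, prob = prob,
                 samples = samples),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d subjects x %d variants (%s%s)\n",
              length(x$samples), nrow(x$variants),
              if (!is.null(x$hard)) "hard calls" else "",
              if (!is.null(x$prob)) ", probability triples" else ""))
  invisible(x)
}

#' Read genotypes from a VCF
#'
#' Reads hard calls (GT), dosages (DS) or genotype-probability triples (GP)
#' into a [genotype_set()]. GP triples are validated (sum within
#' \[0.99, 1.01\]) and renormalized to sum exactly 1; missing entries are
#' flagged `NA`, never silently zeroed. VCF positions (1-based) are converted
#' to the package's 0-based convention on read.
#'
#' @param path VCF file (plain or bgzipped).
#' @param mode one of "hard", "dosage", "probability".
#' @return a `genotype_set`. In dosage mode the fractional dosages are stored
#'   in the `dosage` element.
#' @export
read_genotypes <- function(path, mode = c("hard", "dosage", "probability")) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {          # single-variant VCFs collapse to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  variants <- data.frame(
    snp_id = as.character(fix[, "ID"]),
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]) - 1L,     # to 0-based
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  fmt_field <- c(hard = "GT", dosage = "DS", probability = "GP")[[mode]]
  fmt_keys <- unique(unlist(strsplit(unname(vcf@gt[, "FORMAT"]), ":")))
  if (!fmt_field %in% fmt_keys) {
    stop("requested FORMAT field ", fmt_field, " absent from VCF", call. = FALSE)
  }
  raw <- vcfR::extract.gt(vcf, element = fmt_field)  # variants x samples
  samples <- colnames(raw)
  n <- length(samples); m <- nrow(variants)

  hard <- NULL; prob <- NULL; dosage <- NULL
  if (mode == "hard") {
    gt <- t(raw)                                      # subjects x variants
    alt_count <- function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
    }
    hard <- matrix(vapply(gt, alt_count, integer(1)), nrow = n,
                   dimnames = list(samples, variants$snp_id))
  } else if (mode == "dosage") {
    dosage <- matrix(as.numeric(t(raw)), nrow = n,
                     dimnames = list(samples, variants$snp_id))
  } else {
    prob <- array(NA_real_, dim = c(n, m, 3),
                  dimnames = list(samples, variants$snp_id, NULL))
    for (j in seq_len(m)) {
      triples <- strsplit(raw[j, ], ",")
      for (i in seq_len(n)) {
        tr <- suppressWarnings(as.numeric(triples[[i]]))
        if (length(tr) != 3 || anyNA(tr)) next                 # stays NA
        s <- sum(tr)
        if (s < 0.99 || s > 1.01) {
          stop(sprintf("GP triple for %s/%s sums to %.4f (outside [0.99, 1.01])",
                       samples[i], variants$snp_id[j], s), call. = FALSE)
        }
        prob[i, j, ] <- tr / s
      }
    }
  }
  out <- genotype_set(variants, hard = hard, prob = prob, samples = samples)
  out$dosage <- dosage
  out
}

#' Write a genotype set as a VCF
#'
#' Emits a minimal VCF 4.2 with GT (and GP when probability triples are
#' present, DS always derivable). 0-based internal positions are converted
#' back to VCF's 1-based convention. The output is plain text.
#'
#' @param gs a `genotype_set` with hard calls.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(gs, path) {
  stopifnot(inherits(gs, "genotype_set"), !is.null(gs$hard))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT dosage\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities (0,1,2 ALT copies)\">"
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gs$samples), collapse = "\t"), con)
  has_gp <- !is.null(gs$prob)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(gs$variants))) {
    v <- gs$variants[j, ]
    g <- gs$hard[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    if (has_gp) {
      gp <- apply(gs$prob[, j, , drop = FALSE], 1, function(p) {
        if (anyNA(p)) "." else paste(formatC(p, digits = 6, format = "g"),
                                     collapse = ",")
      })
      ds <- ifelse(is.na(g), ".",
                   formatC(gs$prob[, j, 2] + 2 * gs$prob[, j, 3],
                           digits = 6, format = "g"))
      cells <- paste(gt, ds, gp, sep = ":")
      fmt <- "GT:DS:GP"
    } else {
      ds <- ifelse(is.na(g), ".", formatC(g, format = "d"))
      cells <- paste(gt, ds, sep = ":")
      fmt <- "GT:DS"
    }
    writeLines(paste(c(v$chrom, v$pos + 1L, v$snp_id, v$ref, v$alt, ".",
                       "PASS", ".", fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}
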