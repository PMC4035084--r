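# CNV consensus, filtering, catalog matching and aggregate scores.
#
# All intervals are 0-based half-open; overlap length of [a1,a2) and [b1,b2)
# is max(0, min(a2,b2) - max(a1,b1)), so abutting intervals do not overlap.

#' Filter CNV calls by caller confidence
#'
#' Retains calls with Log Bayes Factor >= `lbf_min` ("less than ten were
#' removed", so the threshold itself is kept). Calls from callers that emit
#' no LBF (NA) are retained and flagged in the `lbf_flagged` column.
#'
#' @param calls CNV call data.frame (see [read_cnv_calls()]).
#' @param lbf_min confidence threshold (default 10).
#' @param verbose log counts in/out.
#' @return the filtered calls with an `lbf_flagged` logical column.
#' @export
filter_calls_by_confidence <- function(calls, lbf_min = 10, verbose = FALSE) {
  keep <- is.na(calls$lbf) | calls$lbf >= lbf_min
  out <- calls[keep, , drop = FALSE]
  out$lbf_flagged <- is.na(out$lbf)
  stage_log("lbf_filter", nrow(calls), nrow(out), verbose = verbose)
  rownames(out) <- NULL
  out
}

#' Reciprocal overlap of two intervals
#'
#' Returns the overlap length as a fraction of each interval's own length:
#' `c(fraction_of_a, fraction_of_b)`. Intervals on different chromosomes or
#' disjoint intervals return `c(0, 0)`.
#'
#' @param a,b intervals as `c(start, end)` (0-based half-open).
#' @param chrom_a,chrom_b optional chromosome labels.
#' @return numeric length 2.
#' @export
reciprocal_overlap <- function(a, b, chrom_a = NULL, chrom_b = NULL) {
  if (!is.null(chrom_a) && !is.null(chrom_b) && chrom_a != chrom_b) {
    return(c(0, 0))
  }
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  c(ov / (a[2] - a[1]), ov / (b[2] - b[1]))
}

# vectorized overlap length of one interval against many
.overlap_len <- function(s, e, starts, ends) {
  pmax(0, pmin(e, ends) - pmax(s, starts))
}

# union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

#' Merge per-caller calls into consensus CNVs
#'
#' Within each sample, chromosome and state, calls whose pairwise reciprocal
#' overlaps both reach `threshold` are grouped by connected components of
#' the pairwise-pass relation. A component supported by at least
#' `min_callers` distinct callers emits one consensus event whose interval
#' is the intersection of its supporters and whose boundary envelope is
#' their union. The result is independent of caller and call order.
#'
#' @param calls a single call data.frame or a list of per-caller data.frames
#'   (rbound internally); pre-filter with [filter_calls_by_confidence()].
#' @param threshold reciprocal-overlap threshold (default 0.5).
#' @param min_callers distinct callers required (default 2).
#' @return data.frame of consensus events: sample, chrom, start, end, state,
#'   env_start, env_end, n_callers, callers (comma-joined, sorted).
#' @export
merge_consensus <- function(calls, threshold = 0.5, min_callers = 2L) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      state = character(0), env_start = integer(0),
                      env_end = integer(0), n_callers = integer(0),
                      callers = character(0), stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  # canonical order makes the result permutation-invariant
  calls <- calls[order(calls$sample, calls$chrom, calls$state, calls$start,
                       calls$end, calls$caller), , drop = FALSE]
  groups <- split(seq_len(nrow(calls)),
                  paste(calls$sample, calls$chrom, calls$state, sep = "\r"))
  res <- list()
  for (g in groups) {
    k <- length(g)
    parent <- seq_len(k)
    if (k > 1) {
      s <- calls$start[g]; e <- calls$end[g]; len <- e - s
      for (i in seq_len(k - 1)) {
        ov <- .overlap_len(s[i], e[i], s[(i + 1):k], e[(i + 1):k])
        pass <- ov / len[i] >= threshold & ov / len[(i + 1):k] >= threshold
        for (j in which(pass)) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, i + j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(k), function(i) .uf_find(parent, i), integer(1))
    for (comp in split(seq_len(k), roots)) {
      rows <- g[comp]
      callers <- sort(unique(calls$caller[rows]))
      if (length(callers) < min_callers) next
      i_start <- max(calls$start[rows]); i_end <- min(calls$end[rows])
      if (i_start >= i_end) {
        # chained component with empty global intersection: fall back to the
        # widest pairwise intersection between calls from distinct callers
        best <- c(NA_integer_, NA_integer_); best_len <- -1L
        for (ii in seq_along(rows)) for (jj in seq_along(rows)) {
          if (jj <= ii) next
          if (calls$caller[rows[ii]] == calls$caller[rows[jj]]) next
          ps <- max(calls$start[rows[ii]], calls$start[rows[jj]])
          pe <- min(calls$end[rows[ii]], calls$end[rows[jj]])
          if (pe - ps > best_len) { best <- c(ps, pe); best_len <- pe - ps }
        }
        if (best_len <= 0) next
        i_start <- best[1]; i_end <- best[2]
      }
      res[[length(res) + 1]] <- data.frame(
        sample = calls$sample[rows[1]], chrom = calls$chrom[rows[1]],
        start = as.integer(i_start), end = as.integer(i_end),
        state = calls$state[rows[1]],
        env_start = as.integer(min(calls$start[rows])),
        env_end = as.integer(max(calls$end[rows])),
        n_callers = length(callers),
        callers = paste(callers, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$sample, out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove events overlapping excluded regions
#'
#' Any event overlapping an exclusion interval by >= 1 bp is removed
#' (abutting intervals under half-open coordinates do not overlap).
#'
#' @param events consensus-event data.frame (chrom, start, end).
#' @param exclusions BED-style data.frame (chrom, start, end).
#' @param verbose log counts in/out.
#' @return filtered events.
#' @export
remove_excluded_regions <- function(events, exclusions, verbose = FALSE) {
  if (nrow(events) == 0 || nrow(exclusions) == 0) {
    stage_log("exclusion_filter", nrow(events), nrow(events), verbose = verbose)
    return(events)
  }
  hit <- vapply(seq_len(nrow(events)), function(i) {
    same <- exclusions$chrom == events$chrom[i]
    any(same & events$start[i] < exclusions$end &
          events$end[i] > exclusions$start)
  }, logical(1))
  out <- events[!hit, , drop = FALSE]
  stage_log("exclusion_filter", nrow(events), nrow(out), verbose = verbose)
  rownames(out) <- NULL
  out
}

#' Match consensus events to a literature CNV catalog
#'
#' An event and a catalog region are considered the same region when their
#' states match and the shared length is at least `threshold` of both the
#' event and the catalog interval (reciprocal; one-way-only candidates are
#' counted in the `one_way` attribute). Each event is assigned to at most
#' one region: the best reciprocal overlap (largest minimum fraction) wins,
#' ties broken by the smaller catalog interval, then by region label.
#'
#' @param events consensus events.
#' @param catalog CNV-region catalog (see [read_cnv_catalog()]).
#' @param threshold overlap fraction (default 0.4).
#' @return events with added columns `region` (NA when unmatched),
#'   `match_frac` (minimum of the two fractions); attribute `one_way` counts
#'   candidates passing in only one direction.
#' @export
match_catalog <- function(events, catalog, threshold = 0.4) {
  region <- rep(NA_character_, nrow(events))
  frac <- rep(NA_real_, nrow(events))
  one_way <- 0L
  if (nrow(events) > 0) {
    cat_len <- catalog$end - catalog$start
    for (i in seq_len(nrow(events))) {
      cand <- which(catalog$chrom == events$chrom[i] &
                      catalog$state == events$state[i])
      if (length(cand) == 0) next
      ov <- .overlap_len(events$start[i], events$end[i],
                         catalog$start[cand], catalog$end[cand])
      fe <- ov / (events$end[i] - events$start[i])
      fc <- ov / cat_len[cand]
      pass <- fe >= threshold & fc >= threshold
      one_way <- one_way + sum(xor(fe >= threshold, fc >= threshold))
      if (!any(pass)) next
      score <- pmin(fe, fc)
      ord <- order(-score[pass], cat_len[cand[pass]],
                   catalog$region[cand[pass]])
      best <- cand[pass][ord[1]]
      region[i] <- catalog$region[best]
      frac[i] <- pmin(fe, fc)[match(best, cand)]
    }
  }
  out <- events
  out$region <- region
  out$match_frac <- frac
  attr(out, "one_way") <- one_way
  out
}

#' Per-subject, per-region binary carrier matrix
#'
#' A subject carrying one or more matched events in a region codes 1 for
#' that region; deletion and duplication regions are distinct catalog rows
#' and therefore distinct columns.
#'
#' @param matched events with a `region` column (from [match_catalog()]).
#' @param samples full cohort sample vector (zero rows for non-carriers).
#' @param regions catalog region labels defining the columns.
#' @return integer matrix, subjects x regions.
#' @export
carrier_matrix <- function(matched, samples, regions) {
  m <- matrix(0L, nrow = length(samples), ncol = length(regions),
              dimnames = list(samples, regions))
  hit <- matched[!is.na(matched$region), , drop = FALSE]
  if (nrow(hit) > 0) {
    ij <- cbind(match(hit$sample, samples), match(hit$region, regions))
    ij <- ij[stats::complete.cases(ij), , drop = FALSE]
    m[ij] <- 1L
  }
  m
}

#' Classify regions as common or rare by carrier frequency
#'
#' frequency = carriers / n_subjects; regions at frequency >= `common_freq`
#' are common, others rare. Regions with zero carriers are rare and flagged
#' absent.
#'
#' @param carriers integer carrier matrix (from [carrier_matrix()]) or a
#'   named vector of carrier counts.
#' @param n_subjects cohort size.
#' @param common_freq frequency threshold (default 0.01).
#' @return data.frame: region, carriers, freq, class, absent.
#' @export
classify_frequency <- function(carriers, n_subjects, common_freq = 0.01) {
  counts <- if (is.matrix(carriers)) colSums(carriers) else carriers
  if (any(counts > n_subjects)) {
    stop("carrier counts cannot exceed n_subjects", call. = FALSE)
  }
  freq <- counts / n_subjects
  data.frame(region = names(counts), carriers = as.integer(counts),
             freq = freq,
             class = ifelse(freq >= common_freq, "common", "rare"),
             absent = counts == 0L, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Aggregate CNV count scores over catalog regions
#'
#' Per-subject count of matched catalog-region events in the requested
#' frequency class, optionally restricted to events whose boundary envelope
#' is at least `min_length` bp (the large-CNV score).
#'
#' @param matched events with `region` (and `env_start`/`env_end` when a
#'   length filter is used).
#' @param region_class data.frame from [classify_frequency()].
#' @param class_filter "rare" or "common".
#' @param samples full cohort sample vector.
#' @param min_length optional minimum envelope length in bp.
#' @return named integer vector of per-subject scores.
#' @export
build_cnv_scores <- function(matched, region_class, class_filter, samples,
                             min_length = NULL) {
  keep_regions <- region_class$region[region_class$class == class_filter]
  ev <- matched[!is.na(matched$region) & matched$region %in% keep_regions, ,
                drop = FALSE]
  if (!is.null(min_length) && nrow(ev) > 0) {
    env_len <- ev$env_end - ev$env_start
    ev <- ev[env_len >= min_length, , drop = FALSE]
  }
  counts <- table(factor(ev$sample, levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Genome-wide rare CNV burden
#'
#' Clusters all consensus events (across subjects, within chromosome and
#' state) by the reciprocal-overlap relation into loci, computes each
#' locus's carrier frequency over the whole cohort, and counts per subject
#' the events belonging to loci below the common-frequency threshold.
#'
#' @param events all consensus events for the cohort.
#' @param samples full cohort sample vector.
#' @param common_freq rarity threshold on locus carrier frequency.
#' @param threshold reciprocal-overlap threshold for locus grouping.
#' @return named integer vector of per-subject rare-event counts, with the
#'   locus table (chrom, start, end, state, carriers, freq) as attribute
#'   `loci`.
#' @export
compute_burden <- function(events, samples, common_freq = 0.01,
                           threshold = 0.5) {
  n_subjects <- length(samples)
  burden <- stats::setNames(integer(n_subjects), samples)
  if (nrow(events) == 0) {
    attr(burden, "loci") <- data.frame()
    return(burden)
  }
  events <- events[order(events$chrom, events$state, events$start,
                         events$end, events$sample), , drop = FALSE]
  groups <- split(seq_len(nrow(events)),
                  paste(events$chrom, events$state, sep = "\r"))
  locus_id <- integer(nrow(events))
  next_id <- 0L
  for (g in groups) {
    k <- length(g)
    parent <- seq_len(k)
    if (k > 1) {
      s <- events$start[g]; e <- events$end[g]; len <- e - s
      for (i in seq_len(k - 1)) {
        ov <- .overlap_len(s[i], e[i], s[(i + 1):k], e[(i + 1):k])
        pass <- ov / len[i] >= threshold & ov / len[(i + 1):k] >= threshold
        for (j in which(pass)) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, i + j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(k), function(i) .uf_find(parent, i), integer(1))
    ids <- match(roots, unique(roots))
    locus_id[g] <- next_id + ids
    next_id <- next_id + max(ids)
  }
  loci <- do.call(rbind, lapply(split(seq_len(nrow(events)), locus_id),
    function(rows) {
      data.frame(chrom = events$chrom[rows[1]],
                 start = min(events$start[rows]),
                 end = max(events$end[rows]),
                 state = events$state[rows[1]],
                 carriers = length(unique(events$sample[rows])),
                 stringsAsFactors = FALSE)
    }))
  loci$freq <- loci$carriers / n_subjects
  rare_ids <- as.integer(rownames(loci))[loci$freq < common_freq]
  rare_ev <- events[locus_id %in% rare_ids, , drop = FALSE]
  counts <- table(factor(rare_ev$sample, levels = samples))
  burden <- stats::setNames(as.integer(counts), samples)
  attr(burden, "loci") <- loci
  burden
}
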