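#' Compute body mass index
#'
#' @param height height in meters (> 0).
#' @param weight weight in kilograms.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(height, weight) {
  if (any(!is.na(height) & height <= 0)) {
    stop("height must be positive", call. = FALSE)
  }
  weight / height^2
}

# QC bounds. The rule text is strict ("< 1.4 or > 2 meters"), so the
# boundary values themselves are retained.
.qc_bounds <- list(height = c(1.4, 2.0), weight = c(38, 166),
                   bmi = c(14.5, 60))

#' Apply phenotype exclusion rules
#'
#' Removes subjects with missing height or weight, height outside
#' \[1.4, 2.0\] m, weight outside \[38, 166\] kg, or BMI outside
#' \[14.5, 60\] kg/m^2 (all bounds inclusive: only strictly out-of-range
#' values are dropped, as likely data-entry errors or eating/syndromic
#' disorders). BMI is recomputed from height and weight even when a `bmi`
#' column is present; a supplied value differing by more than 0.1 kg/m^2 is
#' reported in the log but does not itself exclude.
#'
#' @param records phenotype data.frame with `subject_id`, `height`, `weight`.
#' @return list with `retained` (records passing QC, with a recomputed `bmi`
#'   column) and `log` (data.frame: subject_id, rule, value per removal,
#'   plus any bmi-mismatch notes).
#' @export
apply_exclusions <- function(records) {
  if (nrow(records) == 0) {
    return(list(retained = cbind(records, bmi = numeric(0)),
                log = data.frame(subject_id = character(0),
                                 rule = character(0), value = numeric(0))))
  }
  h <- records$height; w <- records$weight
  bmi <- ifelse(is.na(h) | is.na(w) | h <= 0, NA_real_, w / h^2)
  log_entries <- list()
  note <- function(id, rule, value) {
    data.frame(subject_id = id, rule = rule, value = value,
               stringsAsFactors = FALSE)
  }
  if ("bmi" %in% names(records)) {
    mism <- !is.na(records$bmi) & !is.na(bmi) & abs(records$bmi - bmi) > 0.1
    if (any(mism)) {
      log_entries <- c(log_entries, list(
        note(records$subject_id[mism], "bmi_mismatch", records$bmi[mism])))
    }
  }
  miss <- is.na(h) | is.na(w)
  b <- .qc_bounds
  bad_h <- !miss & (h < b$height[1] | h > b$height[2])
  bad_w <- !miss & !bad_h & (w < b$weight[1] | w > b$weight[2])
  bad_b <- !miss & !bad_h & !bad_w & (bmi < b$bmi[1] | bmi > b$bmi[2])
  if (any(miss)) log_entries <- c(log_entries, list(
    note(records$subject_id[miss], "missing_height_or_weight", NA_real_)))
  if (any(bad_h)) log_entries <- c(log_entries, list(
    note(records$subject_id[bad_h], "height_out_of_range", h[bad_h])))
  if (any(bad_w)) log_entries <- c(log_entries, list(
    note(records$subject_id[bad_w], "weight_out_of_range", w[bad_w])))
  if (any(bad_b)) log_entries <- c(log_entries, list(
    note(records$subject_id[bad_b], "bmi_out_of_range", bmi[bad_b])))
  drop <- miss | bad_h | bad_w | bad_b
  retained <- records[!drop, , drop = FALSE]
  retained$bmi <- bmi[!drop]
  log <- if (length(log_entries)) do.call(rbind, log_entries) else
    data.frame(subject_id = character(0), rule = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  rownames(retained) <- NULL
  list(retained = retained, log = log)
}

#' Classify bodyweight category from BMI
#'
#' Categories by greatest satisfied threshold, thresholds inclusive:
#' overweight >= 25, obese class I >= 30, II >= 35, III >= 40 kg/m^2.
#' Classes nest, so use [obesity_indicators()] for the cumulative binary
#' codings association and prediction models consume.
#'
#' @param bmi numeric BMI vector.
#' @return factor with levels under/normal, overweight, obese I, II, III.
#' @export
classify_bodyweight <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 25, 30, 35, 40, Inf), right = FALSE,
      labels = c("under/normal", "overweight", "obese I", "obese II",
                 "obese III"))
}

#' @rdname classify_bodyweight
#' @return for `obesity_indicators`, an integer matrix with one cumulative
#'   indicator column per class (`overweight` = BMI >= 25 ... `obese_III` =
#'   BMI >= 40); indicators are monotone across columns.
#' @export
obesity_indicators <- function(bmi) {
  cbind(overweight = as.integer(bmi >= 25),
        obese_I = as.integer(bmi >= 30),
        obese_II = as.integer(bmi >= 35),
        obese_III = as.integer(bmi >= 40))
}
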