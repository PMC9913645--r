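## Patient-level hold-out splitting and cohort summaries.

#' Patient-level hold-out split
#'
#' Randomly partitions patients (never individual images, so no patient
#' straddles the two sets) into mutually exclusive training and testing sets.
#' The training set receives `ceiling(ratio * n_patients)` patients, which
#' for a 93-patient cohort at ratio 0.8 gives the conventional 75/18 split.
#'
#' @param cohort An `rtn_cohort`, or a data.frame with a `patient_id` column.
#' @param ratio Training fraction, in (0, 1). Default 0.8 (the 8:2 rule).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List of class `"cohort_split"` with `train`/`test` (integer row
#'   indices into the image/meta table), `train_patients`, `test_patients`,
#'   `ratio` and `seed`.
#' @export
holdout_split <- function(cohort, ratio = 0.8, seed = 1L) {
  meta <- if (inherits(cohort, "rtn_cohort")) cohort$meta else cohort
  if (is.null(meta$patient_id)) stop("cohort must have patient_id")
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1) stop("ratio must be in (0,1)")
  patients <- unique(meta$patient_id)
  n <- length(patients)
  if (n < 2) stop("need at least 2 patients to split")
  set.seed(seed)
  n_train <- min(n - 1L, max(1L, ceiling(ratio * n)))
  train_pat <- sample(patients, n_train)
  test_pat <- setdiff(patients, train_pat)
  structure(list(train = which(meta$patient_id %in% train_pat),
                 test = which(meta$patient_id %in% test_pat),
                 train_patients = train_pat, test_patients = test_pat,
                 ratio = ratio, seed = seed),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("Patient-level hold-out split (ratio %.2f, seed %d)\n", x$ratio, x$seed))
  cat(sprintf("  train: %d patients (%d images); test: %d patients (%d images)\n",
              length(x$train_patients), length(x$train),
              length(x$test_patients), length(x$test)))
  invisible(x)
}

#' Positive fraction per cohort, at the patient level
#'
#' The fraction of PD-1-positive patients in each cohort, reported as a
#' percentage rounded to one decimal place (a patient is counted once however
#' many images they contribute).
#'
#' @param meta Data.frame with `patient_id`, `label` and a `cohort` column
#'   (values `"train"`/`"test"`), e.g. [pd1_reference_cohort()]; alternatively
#'   pass an `rtn_cohort` plus a `split`.
#' @param split Optional `cohort_split` used to derive the cohort column.
#' @return Named numeric vector of percentages, one entry per cohort.
#' @export
cohort_proportions <- function(meta, split = NULL) {
  if (inherits(meta, "rtn_cohort")) meta <- meta$meta
  if (!is.null(split)) {
    meta$cohort <- NA_character_
    meta$cohort[split$train] <- "train"
    meta$cohort[split$test] <- "test"
  }
  if (is.null(meta$cohort)) stop("need a cohort column or a split")
  pat <- meta[!duplicated(meta$patient_id), ]
  out <- tapply(pat$label, pat$cohort, function(l) round(100 * mean(l), 1))
  out[order(match(names(out), c("train", "test")))]
}

#' Patient-level characteristics of the 93-patient development cohort
#'
#' The hepatocellular-carcinoma cohort on which ResTransNet was developed,
#' reconstructed at the patient level from its published summary counts:
#' 75 training patients (16 PD-1-positive, of whom 13 male; 59 negative, of
#' whom 54 male) and 18 testing patients (9 positive and 9 negative, 8 male
#' and 1 female in each). Used for cohort-arithmetic checks such as the
#' 21.3% / 50% positive fractions.
#'
#' @return Data.frame with `patient_id`, `cohort`, `label`, `sex` (93 rows).
#' @export
pd1_reference_cohort <- function() {
  blocks <- rbind(
    data.frame(cohort = "train", label = 1L, sex = rep(c("M", "F"), c(13, 3))),
    data.frame(cohort = "train", label = 0L, sex = rep(c("M", "F"), c(54, 5))),
    data.frame(cohort = "test",  label = 1L, sex = rep(c("M", "F"), c(8, 1))),
    data.frame(cohort = "test",  label = 0L, sex = rep(c("M", "F"), c(8, 1))))
  data.frame(patient_id = sprintf("P%02d", seq_len(nrow(blocks))), blocks,
             stringsAsFactors = FALSE)
}
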