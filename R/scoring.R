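# Vascular assessment rules and the KS* adjustment.

#' Does a vessel qualify for counting?
#'
#' On maximum-intensity-projection images only prominent vessels are counted
#' towards breast vascularity: a vessel qualifies when it is at least 3 cm
#' long and at least 2 mm in diameter (both thresholds inclusive).
#'
#' @param length_mm,diameter_mm Numeric vectors of vessel length and diameter
#'   in millimetres; must be positive.
#' @return Logical vector.
#' @examples
#' qualify_vessel(30, 2)    # boundary: qualifies
#' qualify_vessel(29, 2.5)  # too short
#' @export
qualify_vessel <- function(length_mm, diameter_mm) {
  if (anyNA(length_mm) || anyNA(diameter_mm) ||
      any(length_mm <= 0) || any(diameter_mm <= 0)) {
    stop("vessel length and diameter must be positive", call. = FALSE)
  }
  length_mm >= 30 & diameter_mm >= 2
}

#' Count qualifying vessels
#'
#' @param vessels Data frame with columns `length_mm` and `diameter_mm`, one
#'   row per observed vessel (may have zero rows).
#' @return Integer count of vessels satisfying [qualify_vessel()].
#' @export
count_qualifying_vessels <- function(vessels) {
  vessels <- as.data.frame(vessels)
  if (nrow(vessels) == 0L) return(0L)
  sum(qualify_vessel(vessels$length_mm, vessels$diameter_mm))
}

#' Increased ipsilateral breast vascularity
#'
#' The lesion-bearing breast shows increased vascularity when it has at least
#' two more qualifying vessels than the contralateral breast.
#'
#' @param ipsilateral_count,contralateral_count Non-negative integer vectors
#'   of qualifying-vessel counts.
#' @return Logical vector, `TRUE` where `ipsilateral - contralateral >= 2`.
#' @examples
#' assess_increased_vascularity(5, 2)  # TRUE
#' assess_increased_vascularity(3, 2)  # FALSE
#' assess_increased_vascularity(2, 0)  # TRUE (difference exactly 2)
#' @export
assess_increased_vascularity <- function(ipsilateral_count, contralateral_count) {
  if (anyNA(ipsilateral_count) || anyNA(contralateral_count) ||
      any(ipsilateral_count < 0) || any(contralateral_count < 0)) {
    stop("vessel counts must be non-negative", call. = FALSE)
  }
  ipsilateral_count - contralateral_count >= 2
}

#' Adjust the Kaiser score by the vascular assessment (KS*)
#'
#' A lesion scoring 7 or less whose breast shows increased ipsilateral
#' vascularity *and* a positive adjacent vessel sign simultaneously has its
#' Kaiser score raised by 3; all other lesions keep their score. Lesions
#' scoring 8 or more already carry a high probability of malignancy, so no
#' points are added. The adjusted score KS* therefore stays within 1..11
#' (7 + 3 = 10) and never decreases.
#'
#' @param ks Integer vector of Kaiser scores in 1..11.
#' @param increased_vascularity,avs_present Logical vectors (recycled).
#' @return Integer vector of adjusted scores KS*.
#' @examples
#' adjust_score(3, TRUE, TRUE)   # 6
#' adjust_score(7, TRUE, TRUE)   # 10
#' adjust_score(8, TRUE, TRUE)   # 8, unchanged
#' adjust_score(5, FALSE, TRUE)  # 5, both signs required
#' @export
adjust_score <- function(ks, increased_vascularity, avs_present) {
  if (anyNA(ks) || any(ks < 1) || any(ks > 11) || any(ks != round(ks))) {
    stop("ks must be integers in 1..11", call. = FALSE)
  }
  ks <- as.integer(ks)
  up <- ks <= 7L & as.logical(increased_vascularity) & as.logical(avs_present)
  ks + 3L * up
}

#' Translate a Kaiser score into a BI-RADS band
#'
#' Scores 1-4 correspond to BI-RADS 2/3 (at most 2% likelihood of
#' malignancy), 5-7 to BI-RADS 4, and 8-11 to BI-RADS 5 (at least 95%
#' likelihood).
#'
#' @param score Integer vector of (possibly adjusted) Kaiser scores in 1..11.
#' @return Character vector with values `"2/3"`, `"4"`, `"5"`.
#' @export
translate_to_birads <- function(score) {
  if (anyNA(score) || any(score < 1) || any(score > 11) ||
      any(score != round(score))) {
    stop("score must be integers in 1..11", call. = FALSE)
  }
  c("2/3", "2/3", "2/3", "2/3", "4", "4", "4", "5", "5", "5", "5")[score]
}

#' Score a lesion cohort (KS, KS*, BI-RADS)
#'
#' Derives the increased-vascularity flag from the vessel counts, assigns the
#' Kaiser score from the feature columns via `tree`, applies the KS*
#' adjustment using the adjacent-vessel-sign flag, and appends BI-RADS bands
#' for both scores. Scoring is pure: re-scoring a scored cohort recomputes
#' the same columns.
#'
#' @param cohort Data frame with the five Kaiser feature columns plus
#'   `ipsi_vessels`, `contra_vessels` and logical `avs_present` (see
#'   [read_cohort_csv()] for the on-disk schema).
#' @param tree A valid [score_tree()].
#' @return `cohort` with columns `increased_vascularity` (logical), `ks`,
#'   `ks_star` (integer), `birads_ks` and `birads` (band of KS*) appended or
#'   overwritten.
#' @export
score_cohort <- function(cohort, tree) {
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  need <- c("ipsi_vessels", "contra_vessels", "avs_present")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort$increased_vascularity <-
    assess_increased_vascularity(cohort$ipsi_vessels, cohort$contra_vessels)
  cohort$ks <- assign_kaiser_score(cohort, tree)
  cohort$ks_star <- adjust_score(cohort$ks, cohort$increased_vascularity,
                                 as.logical(cohort$avs_present))
  cohort$birads_ks <- translate_to_birads(cohort$ks)
  cohort$birads <- translate_to_birads(cohort$ks_star)
  cohort
}
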