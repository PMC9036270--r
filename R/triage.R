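# Anatomical clusters and urgency triage.
#
# Diagnoses map onto six anatomical clusters along the visual axis (plus an
# `other` sentinel for out-of-vocabulary gold labels such as
# endophthalmitis). Urgency is binary: URGENT conditions need rapid
# specialist referral (peripheral retina, vitreous hemorrhage, all optic
# nerve/circulation disease, post-chiasmal disease, and the endophthalmitis
# sentinel), while floaters/PVD, other macular disease, lens/cornea problems
# and migraine are NON_URGENT.

#' Anatomical cluster of a diagnosis
#'
#' @param dx Diagnosis id, or the `"other"` sentinel.
#' @param kb A `vision_kb`.
#' @return A cluster id (see [cluster_labels()]).
#' @export
#' @examples
#' cluster_of("vitreous_hemorrhage", builtin_kb())
cluster_of <- function(dx, kb) {
  if (identical(dx, other_sentinel())) return(other_sentinel())
  i <- match(dx, kb$diagnoses$id)
  if (is.na(i)) stop("unmapped diagnosis id: ", dx, call. = FALSE)
  kb$diagnoses$cluster[[i]]
}

#' Urgency class of a diagnosis
#'
#' The `"other"` sentinel (endophthalmitis, a vitreous infection) counts as
#' URGENT.
#'
#' @inheritParams cluster_of
#' @return `"URGENT"` or `"NON_URGENT"`.
#' @export
#' @examples
#' urgency_of("migraine", builtin_kb())
urgency_of <- function(dx, kb) {
  if (identical(dx, other_sentinel())) return("URGENT")
  i <- match(dx, kb$diagnoses$id)
  if (is.na(i)) stop("unmapped diagnosis id: ", dx, call. = FALSE)
  kb$diagnoses$urgency[[i]]
}

#' Predicted urgency of a case from its differential
#'
#' A case is flagged by the urgency of the top-ranked diagnosis of its
#' differential.
#'
#' @param diff A `vl_differential` (non-empty).
#' @param kb A `vision_kb`.
#' @return `"URGENT"` or `"NON_URGENT"`.
#' @export
predicted_urgency <- function(diff, kb) {
  if (!nrow(diff)) stop("empty differential", call. = FALSE)
  urgency_of(diff$dx[[1L]], kb)
}

# Urgency flag implied by a referrer's diagnosis: a referral without an
# attempted diagnosis carries a NON_URGENT flag; otherwise the flag of the
# named diagnosis.
referrer_urgency <- function(referrer_dx, kb) {
  if (is.na(referrer_dx) || !nzchar(referrer_dx)) return("NON_URGENT")
  urgency_of(referrer_dx, kb)
}
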