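# High/low-exposure subgrouping of welders by the recent cumulative
# exposure index: HEX iff CEI over the past three months strictly exceeds
# 0.04 mg/m^3 yr ("exceeding" is strict — a welder at exactly 0.04 is LEX).

#' Classify welders into HEX/LEX exposure subgroups
#'
#' @param records Cohort data.frame (see [read_cohort_table()]); controls
#'   are dropped from the output.
#' @param threshold CEI_3M threshold in mg/m^3 yr (default 0.04).
#' @return Data.frame with columns `subject_id`, `label` ("HEX"/"LEX"),
#'   `cei_3m`.
#' @export
classify_exposure <- function(records, threshold = 0.04) {
  welders <- records[records$group == "welder", , drop = FALSE]
  if (nrow(welders) == 0L)
    return(data.frame(subject_id = character(), label = character(),
                      cei_3m = numeric(), stringsAsFactors = FALSE))
  if (any(is.na(welders$cei_3m)))
    stop("classify_exposure: welder(s) with missing cei_3m: ",
         paste(welders$subject_id[is.na(welders$cei_3m)], collapse = ", "),
         call. = FALSE)
  data.frame(subject_id = welders$subject_id,
             label = ifelse(welders$cei_3m > threshold, "HEX", "LEX"),
             cei_3m = welders$cei_3m,
             stringsAsFactors = FALSE)
}
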