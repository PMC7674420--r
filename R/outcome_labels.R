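#' Relative body-weight change
#'
#' Computes the dimensionless relative change
#' \eqn{\Delta w = (w_{after} - w_{before}) / w_{before}} between the start and
#' end of an intervention period. Non-positive or missing weights yield `NA`
#' (a missing-value signal, not an error), which downstream classification
#' maps to the `excluded` state.
#'
#' @param w_before,w_after body weight in kg at the start/end of the period;
#'   vectors are recycled to a common length.
#' @return numeric vector of relative changes (fractions, e.g. -0.02 = 2\% loss).
#' @examples
#' relative_change(100, 98)   # -0.02
#' relative_change(70, 70.7)  # +0.01
#' @export
relative_change <- function(w_before, w_after) {
  dw <- (w_after - w_before) / w_before
  dw[!is.finite(w_before) | !is.finite(w_after) |
       w_before <= 0 | w_after <= 0] <- NA_real_
  dw
}

#' Classify responder / non-responder from relative weight change
#'
#' Any weight loss, however small, counts as response: `delta_w < 0` is
#' `"responder"`, `delta_w >= 0` (no change or gain) is `"non_responder"`,
#' and a missing `delta_w` (e.g. a dropout with no final weight) is
#' `"excluded"`. Exactly-zero change is taken literally as non-response;
#' no tolerance band is applied.
#'
#' @param delta_w numeric vector of relative weight changes, `NA` allowed.
#' @return character vector in `{"responder", "non_responder", "excluded"}`.
#' @export
classify_responder <- function(delta_w) {
  out <- ifelse(is.na(delta_w), "excluded",
                ifelse(delta_w < 0, "responder", "non_responder"))
  as.character(out)
}

#' Outcome labels for a cohort table
#'
#' Applies [relative_change()] and [classify_responder()] to every
#' (participant, period) observation of a cohort table.
#'
#' @param cohort a cohort table as produced by [simulate_cohort()] or read
#'   with [read_cohort_tsv()]: columns `sample_id`, `w_before`, `w_after`.
#' @return data.frame with columns `sample_id`, `delta_w`, `class`, and the
#'   numeric `y` used for modelling (1 = responder, 0 = non-responder,
#'   `NA` = excluded).
#' @export
responder_labels <- function(cohort) {
  dw <- relative_change(cohort$w_before, cohort$w_after)
  cl <- classify_responder(dw)
  data.frame(sample_id = cohort$sample_id,
             delta_w = dw,
             class = cl,
             y = ifelse(cl == "excluded", NA_real_,
                        as.numeric(cl == "responder")),
             stringsAsFactors = FALSE)
}

#' Write outcome labels as TSV
#' @param labels data.frame from [responder_labels()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  write.table(labels[, c("sample_id", "delta_w", "class")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
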