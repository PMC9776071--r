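#' Load the packaged reference case-study summaries
#'
#' Summary measurements for three carotid endarterectomy patients from a
#' published FSI case study (plaque component volumes, thinnest fibrous cap,
#' TAWSS region-of-interest statistics, peak plaque stresses), packaged so
#' the cross-case comparison arithmetic can be validated without patient
#' data.
#'
#' @return Named list of three per-case summary lists.
#' @export
reference_case_summaries <- function() {
  path <- system.file("extdata", "case_study_reference.json",
                      package = "plaquescan")
  jsonlite::fromJSON(path, simplifyVector = FALSE)$patients
}

reference_printed_comparisons <- function() {
  path <- system.file("extdata", "case_study_reference.json",
                      package = "plaquescan")
  jsonlite::fromJSON(path)$printed_comparisons
}

#' Validate comparison arithmetic against reference printed values
#'
#' Recomputes every cross-case comparison (component-volume and TAWSS fold
#' ratios, maximum-stress percent differences) from the supplied per-case
#' summaries and checks each against the reference study's printed value.
#' Published tables mix rounding and truncation in the last digit, so a
#' computed value passes when it agrees with the printed one within one
#' unit in the last printed decimal.
#'
#' @param reports Named list of three per-case summaries (default: the
#'   packaged reference values themselves, which must reproduce every
#'   printed comparison).
#' @return Data frame `id`, `computed`, `printed`, `tolerance`, `pass`.
#' @export
validate_against_reference <- function(reports = reference_case_summaries()) {
  if (is.null(reports) || length(reports) == 0)
    stop("no case reports supplied")
  if (length(reports) != 3)
    stop("expected exactly three case reports")
  cmp <- compare_patients(reports)
  ref <- reference_printed_comparisons()
  out <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    computed <- comparison_value(cmp, r$quantity, r$case_a, r$case_b)
    tol <- 10^(-r$digits)
    data.frame(id = r$id, computed = computed, printed = r$printed,
               tolerance = tol,
               pass = is.finite(computed) &&
                 abs(computed - r$printed) <= tol + 1e-12)
  }))
  rownames(out) <- NULL
  out
}
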