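#' Laplace-law circumferential wall stress surrogate
#'
#' Thin-wall hoop stress `sigma(s, t) = p(t) r(s) / h(s)` along the CCA-ICA
#' path (the diseased conduit), reported in kPa. This is a labelled
#' surrogate for the finite-element maximum principal stress: it validates
#' the ROI and comparison machinery, not patient-specific stress magnitudes.
#'
#' @param geometry A `vessel_geometry`.
#' @param pressure Pressure `waveform` in mmHg (converted internally to Pa).
#' @param branches Branch path (default CCA then ICA).
#' @return A `stress_field`: `arclength_mm` (continuous along the path),
#'   `times`, `sigma_kPa` (sections x times), `peak_index` (time of maximum
#'   pressure), `surrogate = TRUE`.
#' @export
laplace_stress <- function(geometry, pressure, branches = c("cca", "ica")) {
  stopifnot(inherits(pressure, "waveform"))
  s_all <- numeric(0); r_all <- numeric(0); h_all <- numeric(0)
  offset <- 0
  for (bn in branches) {
    b <- geometry$branches[[bn]]
    h <- b$r_outer - b$r_lumen
    if (any(h <= 0)) stop("non-positive wall thickness in branch ", bn)
    s_all <- c(s_all, offset + b$arclength)
    r_all <- c(r_all, b$r_lumen)
    h_all <- c(h_all, h)
    offset <- offset + max(b$arclength)
  }
  p_pa <- pressure$values * mmHg_to_Pa
  sigma <- outer(r_all / h_all, p_pa) / 1000  # kPa
  structure(list(arclength_mm = s_all, times = pressure$times,
                 sigma_kPa = sigma,
                 peak_index = which.max(pressure$values),
                 surrogate = TRUE),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("Stress field: %d sections x %d times, peak-systole max %.1f kPa%s\n",
              length(x$arclength_mm), length(x$times),
              max(x$sigma_kPa[, x$peak_index]),
              if (isTRUE(x$surrogate)) " [surrogate]" else ""))
  invisible(x)
}

#' Stress ROI statistics around the peak-stress plane
#'
#' Locates the cross-section with the maximal peak-systole stress (earliest
#' section on ties), centres a window of `length` mm on it (default 13 mm),
#' and returns mean, SD and maximum over the window. A vessel shorter than
#' the window truncates it with a warning.
#'
#' @param field A `stress_field`.
#' @param length Window length (mm).
#' @return List `mean`, `sd`, `max`, `central_s_mm`, `n`, `values`.
#' @export
stress_roi_stats <- function(field, length = 13) {
  prof <- field$sigma_kPa[, field$peak_index]
  s <- field$arclength_mm
  ic <- which.max(prof)  # earliest on ties
  s_c <- s[ic]
  lo <- s_c - length / 2
  hi <- s_c + length / 2
  if (lo < min(s) || hi > max(s)) {
    warning("stress ROI window truncated at the vessel end")
    lo <- max(lo, min(s)); hi <- min(hi, max(s))
  }
  sel <- s >= lo & s <= hi
  vals <- prof[sel]
  list(mean = mean(vals), sd = if (sum(sel) > 1) sd(vals) else 0,
       max = max(vals), central_s_mm = s_c, n = sum(sel), values = vals)
}

# truncate towards zero at a number of decimals (printed-precision helper)
trunc_digits <- function(x, digits) trunc(x * 10^digits) / 10^digits

#' Pairwise comparison of per-case summaries
#'
#' Fold ratios for component volumes and mean TAWSS, and percent differences
#' for maximum stress computed as `100 * (a - b) / b` relative to the
#' smaller-valued case, over all ordered case pairs.
#'
#' @param summaries Named list (>= 2) of per-case summaries, each a list
#'   with any of `calcification_volume_mm3`, `lipid_volume_mm3`,
#'   `tawss_mean_pa`, `stress_max_kpa`.
#' @return Data frame `quantity`, `case_a`, `case_b`, `type`
#'   (`"fold"`/`"pct_diff"`), `value` (raw), `printed_1dp` (truncated to one
#'   decimal). Zero-denominator ratios are `NA` (undefined).
#' @export
compare_patients <- function(summaries) {
  if (length(summaries) < 2) stop("need at least two case summaries")
  ids <- names(summaries) %||% paste0("case", seq_along(summaries))
  if (is.null(names(summaries))) names(summaries) <- ids
  fold_q <- c(calcification_volume_mm3 = "calcification_volume",
              lipid_volume_mm3 = "lipid_volume",
              tawss_mean_pa = "tawss_mean")
  rows <- list()
  for (a in ids) for (b in setdiff(ids, a)) {
    for (fq in names(fold_q)) {
      va <- summaries[[a]][[fq]]; vb <- summaries[[b]][[fq]]
      if (is.null(va) || is.null(vb)) next
      val <- if (vb == 0) NA_real_ else va / vb
      rows[[length(rows) + 1]] <- data.frame(
        quantity = fold_q[[fq]], case_a = a, case_b = b, type = "fold",
        value = val)
    }
    va <- summaries[[a]][["stress_max_kpa"]]
    vb <- summaries[[b]][["stress_max_kpa"]]
    if (!is.null(va) && !is.null(vb) && vb != 0) {
      rows[[length(rows) + 1]] <- data.frame(
        quantity = "stress_max", case_a = a, case_b = b, type = "pct_diff",
        value = 100 * (va - vb) / vb)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$printed_1dp <- trunc_digits(out$value, 1)
  out
}

# look up one comparison value
comparison_value <- function(cmp, quantity, case_a, case_b) {
  row <- cmp$quantity == quantity & cmp$case_a == case_a &
    cmp$case_b == case_b
  if (!any(row)) stop("comparison not found: ", quantity, " ", case_a,
                      " vs ", case_b)
  cmp$value[row][1]
}
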