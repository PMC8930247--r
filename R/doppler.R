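#' Renal Doppler resistive index
#'
#' `RI = (PSV - EDV) / PSV`, the dimensionless downstream-resistance
#' measure computed from the peak systolic (PSV) and end diastolic
#' (EDV) blood-flow velocities of a spectral Doppler trace.  `RI` lies
#' in \[0, 1\] for physiologic inputs (`0 <= EDV <= PSV`): absent
#' diastolic flow gives 1, no diastolic drop gives 0.  The index is
#' scale-invariant, so the velocity unit (cm/s vs m/s) does not matter
#' as long as both inputs share it.
#'
#' @param psv Peak systolic velocity (`> 0`); vectorized.
#' @param edv End diastolic velocity; vectorized.
#' @return Numeric vector of resistive indices.  Values for
#'   non-physiologic inputs (`edv < 0` or `edv > psv`) are still
#'   computed; use [batch_ri] to have them flagged.
#' @examples
#' resistive_index(100, 37)   # 0.63
#' @export
resistive_index <- function(psv, edv) {
  if (any(!is.finite(psv)) || any(psv <= 0)) {
    stop("`psv` must be positive and finite", call. = FALSE)
  }
  (psv - edv) / psv
}

#' Resistive indices and per-group summaries for a measurement table
#'
#' Adds `ri` and `valid` columns to a table of Doppler velocity pairs
#' and summarizes the valid rows per group.  A row is valid when
#' `psv > 0` and `0 <= edv <= psv`; invalid rows keep their computed
#' `ri` (so artifact-laden clinical exports stay auditable) but are
#' flagged, excluded from the summary and counted.
#'
#' @param table Data frame with numeric columns `psv` and `edv`;
#'   optional columns `subject_id`, `group` (missing `group` puts all
#'   rows in group `"all"`) and any others (e.g. a measurement `site`)
#'   are carried through untouched.
#' @return A `ri_batch` list: `table` (input + `ri`, `valid`) and
#'   `summary` (per group: `n` valid rows, arithmetic `mean`, sample
#'   `sd` — `NA` when `n = 1` — and `n_invalid`).  Groups with no valid
#'   rows are dropped from the summary with a warning.
#' @examples
#' d <- data.frame(group = c("A", "A"), psv = c(100, 90), edv = c(37, 27))
#' batch_ri(d)$summary
#'
#' # a small synthetic measurement table ships with the package
#' csv <- system.file("extdata", "doppler_synthetic.csv",
#'                    package = "knlmeans")
#' batch_ri(read.csv(csv))
#' @export
batch_ri <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("psv", "edv") %in% names(table)))
  if (!"group" %in% names(table)) table$group <- "all"
  valid <- is.finite(table$psv) & is.finite(table$edv) &
    table$psv > 0 & table$edv >= 0 & table$edv <= table$psv
  ri <- rep(NA_real_, nrow(table))
  pos <- is.finite(table$psv) & table$psv > 0
  ri[pos] <- (table$psv[pos] - table$edv[pos]) / table$psv[pos]
  table$ri <- ri
  table$valid <- valid
  groups <- unique(table$group)
  rows <- lapply(groups, function(g) {
    in_g <- table$group == g
    v <- table$ri[in_g & valid]
    if (!length(v)) {
      warning("group '", g, "' has no valid measurements; omitted",
              call. = FALSE)
      return(NULL)
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               n_invalid = sum(in_g & !valid))
  })
  summary <- do.call(rbind, rows)
  structure(list(table = table, summary = summary), class = "ri_batch")
}

#' @export
print.ri_batch <- function(x, ...) {
  cat(sprintf("Doppler resistive index: %d rows (%d invalid)\n",
              nrow(x$table), sum(!x$table$valid)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
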