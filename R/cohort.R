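#' Batch-fit the decay curves of a sample cohort
#'
#' Fits every curve of every sample record: low-field (<= 10 MHz) curves
#' with a two-component model (components `"a"` and `"b"`), high-field
#' curves mono-exponentially (at 100 MHz a single exponential reproduces
#' the delay dependence of the integrated intense peak). Individual fit
#' failures are logged and the run continues; a failed curve leaves its
#' quantity `NA` for that sample.
#'
#' @param records List of `sample_record` objects (see
#'   [simulate_cohort()]), each with at least one valid curve.
#' @param fit_inversion_eff Passed to [fit_decay()] for inversion-recovery
#'   curves.
#' @return A list with `records` (input records with `fits` filled in),
#'   `table` (one tidy row per sample: `sample_id`, `group`, and the
#'   recovered `t1a_ms`, `t1b_ms`, `t1_100mhz_ms`, `t2a_ms`, `t2b_ms`,
#'   `t2_100mhz_ms`), and `failures` (data frame of sample/curve/message).
#' @export
run_cohort <- function(records, fit_inversion_eff = FALSE) {
  if (!is.list(records) || length(records) == 0L)
    stop("empty cohort", call. = FALSE)
  failures <- data.frame(sample_id = character(), curve = character(),
                         message = character())
  rows <- vector("list", length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (!is.list(rec$curves) || length(rec$curves) == 0L)
      stop(sprintf("sample %s has no curves", rec$sample_id), call. = FALSE)
    fits <- list()
    row <- list(sample_id = rec$sample_id, group = rec$group,
                t1a_ms = NA_real_, t1b_ms = NA_real_,
                t1_100mhz_ms = NA_real_, t2a_ms = NA_real_,
                t2b_ms = NA_real_, t2_100mhz_ms = NA_real_)
    for (nm in names(rec$curves)) {
      cv <- rec$curves[[nm]]
      fit <- tryCatch({
        if (!inherits(cv, "decay_curve")) stop("not a decay_curve")
        nc <- if (cv$larmor_mhz <= 10) 2L else 1L
        fit_decay(cv, nc, fit_inversion_eff = fit_inversion_eff)
      }, error = function(e) relaxation_fit(converged = FALSE,
                                            message = conditionMessage(e)))
      fits[[nm]] <- fit
      if (!fit$converged) {
        failures <- rbind(failures, data.frame(
          sample_id = rec$sample_id, curve = nm, message = fit$message))
        next
      }
      is_t1 <- identical(fit$sequence_kind, "inversion_recovery")
      tc_ms <- vapply(fit$components, function(cm)
        1000 * cm$time_constant, numeric(1))
      if (fit$larmor_mhz <= 10 && length(tc_ms) == 2L) {
        if (is_t1) { row$t1a_ms <- tc_ms[1]; row$t1b_ms <- tc_ms[2] }
        else { row$t2a_ms <- tc_ms[1]; row$t2b_ms <- tc_ms[2] }
      } else if (fit$larmor_mhz > 10) {
        if (is_t1) row$t1_100mhz_ms <- tc_ms[1]
        else row$t2_100mhz_ms <- tc_ms[1]
      }
    }
    records[[k]]$fits <- fits
    rows[[k]] <- as.data.frame(row)
  }
  list(records = records, table = do.call(rbind, rows), failures = failures)
}

range_overlap <- function(x, y) {
  r1 <- range(x, na.rm = TRUE); r2 <- range(y, na.rm = TRUE)
  inter <- max(0, min(r1[2], r2[2]) - max(r1[1], r2[1]))
  uni <- (r1[2] - r1[1]) + (r2[2] - r2[1]) - inter
  if (uni == 0) return(1)  # both ranges degenerate and coincident
  inter / uni
}

#' Summarise relaxation quantities by group
#'
#' Descriptive per-group statistics of each relaxation quantity in a tidy
#' cohort table, plus a range-overlap comparison between the two groups.
#' For each quantity the overlap coefficient is
#' `|intersection| / |union|` of the two groups' observed `[min, max]`
#' ranges; the verdict is `"similar"` when every quantity's overlap
#' reaches the threshold. No inferential test is performed: the comparison
#' is deliberately descriptive.
#'
#' @param table Tidy per-sample table as returned by [run_cohort()]
#'   (`$table`): columns `sample_id`, `group`, and numeric quantities.
#' @param threshold Overlap coefficient required to call a quantity
#'   "similar" (default 0.5).
#' @return A list with `summary` (group x quantity count/mean/sd/min/max),
#'   `overlap` (per-quantity overlap coefficients), and `verdict`
#'   (`"similar"` or `"distinct"`).
#' @export
summarize_groups <- function(table, threshold = 0.5) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  groups <- unique(table$group)
  if (length(groups) != 2L)
    stop("need exactly 2 groups with >= 2 samples each", call. = FALSE)
  counts <- table(table$group)
  if (any(counts < 2L))
    stop("each group needs >= 2 samples (SD undefined otherwise)",
         call. = FALSE)
  qcols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("sample_id"))
  out <- list(); ov <- list()
  for (q in qcols) {
    for (g in groups) {
      v <- table[[q]][table$group == g]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        group = g, quantity = q, n = length(v),
        mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
    }
    ov[[length(ov) + 1L]] <- data.frame(
      quantity = q,
      overlap = range_overlap(table[[q]][table$group == groups[1]],
                              table[[q]][table$group == groups[2]]))
  }
  summary <- do.call(rbind, out)
  overlap <- do.call(rbind, ov)
  list(summary = summary, overlap = overlap,
       verdict = if (all(overlap$overlap >= threshold)) "similar"
                 else "distinct",
       threshold = threshold)
}
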