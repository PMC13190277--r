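#' @title I-F curves and evoked firing
#' @description
#' Spike counts per current step across the two-repeat 1-s protocol, the
#' evoked firing frequency per level (mean count over repeats; counts over a
#' 1-s step are frequencies in Hz), and the maximum spike firing frequency.
#' @name firing-analysis
NULL

#' Build an I-F curve from the two protocol repeats
#'
#' Counts detected spikes within each step window for every current level of
#' both repeats and averages them per level. Levels present in only one
#' repeat use that repeat alone and are flagged.
#'
#' @param repeat1,repeat2 Sweep families (lists of [voltage_sweep()] with
#'   step descriptors); `repeat2` may be `NULL` for a single run.
#' @param ... Passed to [detect_spikes()].
#' @return An `if_curve`: `current_pA` (sorted grid), `counts` (levels x
#'   repeats matrix), `evoked_freq_Hz` (repeat-mean count / step duration),
#'   `max_freq_Hz`, `max_freq_at_pA` (lowest current achieving it),
#'   `single_repeat_levels` (flagged levels).
#' @export
build_if_curve <- function(repeat1, repeat2 = NULL, ...) {
  fam <- list(repeat1, repeat2)
  fam <- fam[!vapply(fam, is.null, TRUE)]
  if (!length(fam) || !length(fam[[1]]))
    stop("empty step grid", call. = FALSE)
  count_family <- function(sweeps) {
    amps <- vapply(sweeps, function(s) s$step$amplitude_pA, 0)
    cnt <- vapply(sweeps, function(s) {
      ev <- detect_spikes(s, ...)
      if (!length(ev)) return(0L)
      rate <- s$sampling_rate
      on <- round(s$step$onset_s * rate) + 1L
      off <- round((s$step$onset_s + s$step$duration_s) * rate)
      pk <- vapply(ev, `[[`, 0L, "peak_index")
      sum(pk >= on & pk <= off)
    }, 0L)
    dur <- vapply(sweeps, function(s) s$step$duration_s, 0)
    data.frame(amp = amps, count = cnt, dur = dur)
  }
  tabs <- lapply(fam, count_family)
  grid <- sort(unique(unlist(lapply(tabs, `[[`, "amp"))))
  counts <- sapply(tabs, function(tb) tb$count[match(grid, tb$amp)])
  counts <- matrix(counts, nrow = length(grid))
  dur <- tabs[[1]]$dur[match(grid, tabs[[1]]$amp)]
  dur[is.na(dur)] <- tabs[[length(tabs)]]$dur[match(grid, tabs[[length(tabs)]]$amp)][is.na(dur)]
  mean_cnt <- rowMeans(counts, na.rm = TRUE)
  freq <- mean_cnt / dur
  imax <- which.max(freq)     # ties -> lowest current (which.max takes first)
  structure(list(current_pA = grid, counts = counts,
                 evoked_freq_Hz = freq,
                 max_freq_Hz = max(freq),
                 max_freq_at_pA = grid[imax],
                 single_repeat_levels = grid[apply(is.na(counts), 1, any)]),
            class = "if_curve")
}

#' @export
print.if_curve <- function(x, ...) {
  cat(sprintf("<if_curve> %d levels [%g, %g] pA; max %g Hz at %g pA\n",
              length(x$current_pA), min(x$current_pA), max(x$current_pA),
              x$max_freq_Hz, x$max_freq_at_pA))
  invisible(x)
}

#' Maximum spike firing frequency of an I-F curve
#'
#' The maximum over current levels of the repeat-averaged evoked frequency
#' (whole-step mean rate). With `definition = "inv_min_isi"` the maximum
#' instantaneous rate (reciprocal of the smallest inter-spike interval) can
#' be requested instead; the mean-rate reading is the default, consistent
#' with the per-step evoked-frequency definition.
#'
#' @param curve An `if_curve` from [build_if_curve()].
#' @param definition `"mean_rate"` or `"inv_min_isi"`.
#' @param repeats For `"inv_min_isi"`, the original sweep families.
#' @param ... Passed to [detect_spikes()] for the ISI variant.
#' @return Maximum frequency in Hz, attribute `at_pA` = lowest current
#'   achieving it.
#' @export
max_firing_frequency <- function(curve, definition = "mean_rate",
                                 repeats = NULL, ...) {
  definition <- match.arg(definition, c("mean_rate", "inv_min_isi"))
  if (definition == "mean_rate") {
    stopifnot(inherits(curve, "if_curve"))
    return(structure(curve$max_freq_Hz, at_pA = curve$max_freq_at_pA))
  }
  if (is.null(repeats)) stop("inv_min_isi needs the sweep families",
                             call. = FALSE)
  best <- 0; at <- NA_real_
  for (fam in repeats) for (s in fam) {
    ev <- detect_spikes(s, ...)
    if (length(ev) < 2) next
    pk <- vapply(ev, `[[`, 0L, "peak_index")
    isi_s <- min(diff(pk)) / s$sampling_rate
    f <- 1 / isi_s
    if (f > best) { best <- f; at <- s$step$amplitude_pA }
  }
  structure(best, at_pA = at)
}

#' Long-format evoked-frequency table
#'
#' One row per positive current level per cell, zero-spike levels retained
#' (they carry information for the log1p firing model).
#'
#' @param curves Named list of `if_curve` objects, one per cell; names are
#'   cell identifiers.
#' @param meta Optional data frame keyed by `cell_id` with the design
#'   columns (`animal_id`, `group`, `hemisphere`, `layer`, `sex`, ...) to
#'   join onto the rows.
#' @return A tibble with columns `cell_id`, `current_pA`, `spike_freq_Hz`
#'   (plus any joined design columns), `outcome_name = "evoked_freq_Hz"`
#'   and `outcome_value` mirroring `spike_freq_Hz` so the result round-trips
#'   through [validate_cell_table()] when design columns are present.
#' @export
evoked_frequency_long_table <- function(curves, meta = NULL) {
  stopifnot(is.list(curves), !is.null(names(curves)))
  rows <- lapply(names(curves), function(id) {
    cv <- curves[[id]]
    pos <- cv$current_pA > 0
    tibble::tibble(cell_id = id, current_pA = cv$current_pA[pos],
                   spike_freq_Hz = cv$evoked_freq_Hz[pos])
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    stopifnot("cell_id" %in% names(meta))
    out <- merge(out, meta, by = "cell_id", sort = FALSE)
  }
  out$outcome_name <- "evoked_freq_Hz"
  out$outcome_value <- out$spike_freq_Hz
  tibble::as_tibble(out)
}
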