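#' @title Native sweep file format
#' @description
#' Sweeps are stored as tab-separated text with a commented metadata header:
#' a format line, the sampling rate, the unit convention, and one `# sweep:`
#' line per sweep carrying its id, start time and (if known) step descriptor.
#' The body has columns `sweep_id`, `voltage_mV`, `current_pA`. Values are
#' written with 17 significant digits so that a write/read round trip is
#' bit-for-bit exact. Vendor acquisition formats are an extension point, not
#' parsed here.
#' @name sweep-format
NULL

fmt_num <- function(x) sprintf("%.17g", x)

#' Write voltage sweeps to the native tabular format
#'
#' @param sweeps A list of [voltage_sweep()] objects (may be empty; an empty
#'   collection produces a header-only file).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sweeps()]
#' @export
write_sweeps <- function(sweeps, path) {
  if (inherits(sweeps, "voltage_sweep")) sweeps <- list(sweeps)
  stopifnot(is.list(sweeps))
  for (sw in sweeps) {
    if (!inherits(sw, "voltage_sweep")) stop("not a voltage_sweep")
    validate_sweep(sw)
  }
  rate <- if (length(sweeps)) sweeps[[1]]$sampling_rate else 50000
  if (length(sweeps) > 1 &&
      length(unique(vapply(sweeps, `[[`, 0, "sampling_rate"))) != 1)
    stop("all sweeps in one file must share a sampling rate", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# aisephys-sweeps v1",
    paste0("# sampling_rate_hz: ", fmt_num(rate)),
    "# units: voltage=mV current=pA time=s"), con)
  for (sw in sweeps) {
    hdr <- sprintf("# sweep: id=%s t0=%s", sw$sweep_id, fmt_num(sw$t0))
    if (!is.null(sw$step))
      hdr <- paste0(hdr, sprintf(
        " baseline_pA=%s amplitude_pA=%s onset_s=%s duration_s=%s",
        fmt_num(sw$step$baseline_pA), fmt_num(sw$step$amplitude_pA),
        fmt_num(sw$step$onset_s), fmt_num(sw$step$duration_s)))
    writeLines(hdr, con)
  }
  writeLines("sweep_id\tvoltage_mV\tcurrent_pA", con)
  for (sw in sweeps) {
    writeLines(paste(sw$sweep_id, fmt_num(sw$voltage), fmt_num(sw$current),
                     sep = "\t"), con)
  }
  invisible(path)
}

parse_kv <- function(s) {
  # "id=a t0=0 amplitude_pA=-100" -> named character vector
  parts <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Read voltage sweeps from the native tabular format
#'
#' @param path File written by [write_sweeps()] (or conforming to the format
#'   documented in [sweep-format]).
#' @return A list of [voltage_sweep()] objects in file order.
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("aisephys-sweeps", hdr[1]))
    stop("format error: missing 'aisephys-sweeps' format header", call. = FALSE)
  rate_line <- grep("^# sampling_rate_hz:", hdr, value = TRUE)
  if (!length(rate_line))
    stop("format error: header must declare sampling_rate_hz", call. = FALSE)
  rate <- as.numeric(sub("^# sampling_rate_hz:", "", rate_line[1]))
  if (!is.finite(rate) || rate <= 0)
    stop("format error: sampling rate must be positive", call. = FALSE)
  if (!any(grepl("^# units:", hdr)))
    stop("format error: header must declare units", call. = FALSE)

  sweep_meta <- list()
  for (h in grep("^# sweep:", hdr, value = TRUE)) {
    kv <- parse_kv(sub("^# sweep:", "", h))
    if (!"id" %in% names(kv))
      stop("format error: sweep header without id", call. = FALSE)
    sweep_meta[[kv[["id"]]]] <- kv
  }

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(list())
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(cols, c("sweep_id", "voltage_mV", "current_pA")))
    stop("format error: unexpected column header", call. = FALSE)
  if (length(body) == 1) return(list())
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = cols, colClasses =
                             c("character", "numeric", "numeric"))
  if (anyNA(dat$voltage_mV) || anyNA(dat$current_pA))
    stop("integrity error: voltage/current rows incomplete", call. = FALSE)

  ids <- unique(dat$sweep_id)
  lapply(ids, function(id) {
    rows <- dat[dat$sweep_id == id, , drop = FALSE]
    meta <- sweep_meta[[id]]
    t0 <- if (!is.null(meta) && "t0" %in% names(meta))
      as.numeric(meta[["t0"]]) else 0
    step <- NULL
    if (!is.null(meta) && all(c("baseline_pA", "amplitude_pA", "onset_s",
                                "duration_s") %in% names(meta)))
      step <- step_descriptor(as.numeric(meta[["baseline_pA"]]),
                              as.numeric(meta[["amplitude_pA"]]),
                              as.numeric(meta[["onset_s"]]),
                              as.numeric(meta[["duration_s"]]))
    voltage_sweep(rows$voltage_mV, rows$current_pA, sampling_rate = rate,
                  sweep_id = id, t0 = t0, step = step)
  })
}

## ---- cell tables -----------------------------------------------------------

cell_factor_levels <- list(
  group = c("sham", "stroke"),
  hemisphere = c("contralesional", "ipsilesional"),
  layer = c("L2/3", "L5"),
  sex = c("female", "male"),
  gfp = c("negative", "positive", "unknown"))

canonicalise_level <- function(x, field) {
  lv <- cell_factor_levels[[field]]
  idx <- match(tolower(trimws(x)), tolower(lv))
  out <- lv[idx]
  bad <- which(is.na(idx) & !is.na(x))
  if (length(bad))
    stop(sprintf(
      "validation error: unknown %s level(s) %s at row(s) %s (allowed: %s)",
      field, paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(bad, 10), collapse = ", "),
      paste(lv, collapse = ", ")), call. = FALSE)
  factor(out, levels = lv)
}

#' Read a long-format cell/measurement table
#'
#' Reads a delimited table of per-cell measurements with the factorial design
#' columns (`animal_id`, `group`, `hemisphere`, `layer`, `sex`, optionally
#' `gfp`) plus `outcome_name` and `outcome_value`. Factor levels are validated
#' case-insensitively and canonicalised to `sham/stroke`,
#' `contralesional/ipsilesional`, `L2/3`/`L5`, `female/male`,
#' `negative/positive/unknown` (first level is the modelling reference).
#' Additional columns (e.g. `cell_id`, `current_pA`) pass through untouched.
#'
#' @param path CSV file path.
#' @return A tibble of validated cell records.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#", check.names = FALSE)
  validate_cell_table(dat)
}

#' Validate and canonicalise a cell table held in memory
#'
#' @param dat A data frame with the columns described in [read_cell_table()].
#' @return A tibble with canonicalised factor columns.
#' @export
validate_cell_table <- function(dat) {
  need <- c("animal_id", "group", "hemisphere", "layer", "sex",
            "outcome_name", "outcome_value")
  missing <- setdiff(need, names(dat))
  if (length(missing))
    stop("validation error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (f in c("group", "hemisphere", "layer", "sex"))
    dat[[f]] <- canonicalise_level(as.character(dat[[f]]), f)
  if ("gfp" %in% names(dat))
    dat$gfp <- canonicalise_level(as.character(dat$gfp), "gfp")
  dat$animal_id <- as.character(dat$animal_id)
  dat$outcome_value <- as.numeric(dat$outcome_value)
  if (anyNA(dat$outcome_value) || any(!is.finite(dat$outcome_value)))
    stop("validation error: outcome_value must be finite", call. = FALSE)
  tibble::as_tibble(dat)
}

#' Write a cell table as CSV
#'
#' @param dat Cell table (tibble/data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(dat, path) {
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- fluorescence profiles -------------------------------------------------

#' Read a fluorescence line profile
#'
#' Two-column CSV (`arc_length_um`, `intensity`); `#` lines are comments.
#'
#' @param path CSV file path.
#' @return A [fluorescence_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, comment.char = "#")
  if (!all(c("arc_length_um", "intensity") %in% names(dat)))
    stop("format error: profile needs arc_length_um and intensity columns",
         call. = FALSE)
  fluorescence_profile(dat$arc_length_um, dat$intensity, source = "tabular")
}

#' Write a fluorescence line profile
#'
#' @param profile A [fluorescence_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fluorescence_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aisephys-profile v1 (arc length um, intensity a.u.)", con)
  writeLines("arc_length_um,intensity", con)
  writeLines(paste(fmt_num(profile$arc_length_um), fmt_num(profile$intensity),
                   sep = ","), con)
  invisible(path)
}
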