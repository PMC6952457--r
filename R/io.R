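#' @include AllClasses.R
NULL

## shortest decimal that round-trips to the same double (diff-stable output)
.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

.readMeta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- regmatches(body, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", body))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  meta
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty file: ", path, call. = FALSE)
  isMeta <- grepl("^#", lines)
  meta <- .readMeta(lines[isMeta])
  body <- lines[!isMeta & nzchar(trimws(lines))]
  if (length(body) < 2)
    stop("malformed file (no data rows): ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  list(meta = meta, data = df)
}

#' Read and write peak tables
#'
#' The peak-table CSV dialect is comma-separated with `.` decimals, a
#' `# dose_kGy=<value>` metadata line (plus optional `# source=`) before the
#' header `symbol,two_sin_theta,recip_d[,intensity]`. Numbers are written
#' with shortest round-trip precision, so write-then-read is lossless.
#'
#' @param path file path.
#' @return `readPeakTable()` returns a [PeakTable-class].
#' @seealso [readXY()] for the two-column intensity-only dialect.
#' @export
readPeakTable <- function(path) {
  tb <- .readTable(path)
  df <- tb$data
  need <- c("symbol", "two_sin_theta", "recip_d")
  if (!all(need %in% names(df)))
    stop("malformed peak table ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(tb$meta$dose_kGy))
    stop("peak table ", path, " lacks a '# dose_kGy=' metadata line",
         call. = FALSE)
  peakTable(dose = as.numeric(tb$meta$dose_kGy),
            symbol = df$symbol,
            twoSinTheta = df$two_sin_theta,
            recipD = df$recip_d,
            intensity = if ("intensity" %in% names(df)) df$intensity
                        else NA_real_,
            source = if (is.null(tb$meta$source)) path else tb$meta$source)
}

#' @param x a [PeakTable-class] object.
#' @rdname readPeakTable
#' @export
writePeakTable <- function(x, path) {
  stopifnot(is(x, "PeakTable"))
  p <- x@peaks
  hasI <- any(!is.na(p$intensity))
  lines <- c(
    sprintf("# dose_kGy=%s", .fmtNum(x@dose)),
    if (nzchar(x@source)) sprintf("# source=%s", x@source),
    paste0("symbol,two_sin_theta,recip_d", if (hasI) ",intensity"),
    paste0(p$symbol, ",", .fmtNum(p$twoSinTheta), ",", .fmtNum(p$recipD),
           if (hasI) paste0(",", .fmtNum(p$intensity)) else ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ASCII "XY" diffractogram
#'
#' Minimal dialect for intensity-only input: whitespace- or tab-separated
#' `2sin(theta)` and intensity columns, `#` comments allowed. Reciprocal
#' d-spacings are unknown in this dialect and stored as `NA`.
#'
#' @param path file path.
#' @param dose absorbed dose tag in kGy (default 0).
#' @return a [PeakTable-class] with `NA` `recipD`.
#' @export
readXY <- function(path, dose = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("empty XY file: ", path, call. = FALSE)
  fields <- strsplit(trimws(body), "[\t ,]+")
  if (any(lengths(fields) < 2))
    stop("malformed XY file ", path, ": line with fewer than two columns",
         call. = FALSE)
  x <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  if (any(is.na(x)) || any(is.na(y)))
    stop("malformed XY file ", path, ": non-numeric values", call. = FALSE)
  ord <- order(x)
  peakTable(dose = dose, symbol = make.unique(LETTERS[(seq_along(x) - 1) %% 26 + 1]),
            twoSinTheta = x[ord], recipD = NA_real_, intensity = y[ord],
            source = path)
}

#' Read and write dose series
#'
#' Dose-series CSV dialect: `# label=` and `# units=` metadata lines, then a
#' `dose_kGy,value` header and one row per dose. Lossless to full double
#' precision.
#'
#' @param path file path.
#' @return `readDoseSeries()` returns a [DoseSeries-class].
#' @export
readDoseSeries <- function(path) {
  tb <- .readTable(path)
  df <- tb$data
  if (!all(c("dose_kGy", "value") %in% names(df)))
    stop("malformed dose series ", path, ": need columns dose_kGy,value",
         call. = FALSE)
  doseSeries(label = if (is.null(tb$meta$label)) basename(path)
                     else tb$meta$label,
             units = if (is.null(tb$meta$units)) "" else tb$meta$units,
             doses = df$dose_kGy, values = df$value)
}

#' @param x a [DoseSeries-class] object.
#' @rdname readDoseSeries
#' @export
writeDoseSeries <- function(x, path) {
  stopifnot(is(x, "DoseSeries"))
  lines <- c(sprintf("# label=%s", x@label),
             sprintf("# units=%s", x@units),
             "dose_kGy,value",
             paste0(.fmtNum(x@doses), ",", .fmtNum(x@values)))
  writeLines(lines, path)
  invisible(path)
}
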