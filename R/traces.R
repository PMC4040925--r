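#' Construct an intensity trace
#'
#' A trace is a vector of photon counts (or arbitrary intensity units) in
#' consecutive time bins from one detection channel.
#'
#' @param counts numeric vector of non-negative counts per bin (length >= 2).
#' @param bin_width bin width in seconds (> 0).
#' @param channel channel label, `"G"` or `"R"`.
#' @param dark_rate detector dark count rate in counts/s (metadata; used by
#'   quality control to form background-corrected count rates).
#' @return an object of class `intensity_trace` with fields `counts`,
#'   `bin_width`, `channel`, `count_rate` (total counts / duration, counts/s)
#'   and `dark_rate`.
#' @examples
#' tr <- intensity_trace(rpois(1000, 2), 1e-3, "G")
#' tr$count_rate
#' @export
intensity_trace <- function(counts, bin_width, channel = c("G", "R"),
                            dark_rate = 0) {
  channel <- match.arg(channel)
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("trace must contain at least 2 bins")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  structure(
    list(counts = counts, bin_width = bin_width, channel = channel,
         count_rate = sum(counts) / (length(counts) * bin_width),
         dark_rate = dark_rate),
    class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> channel %s: %d bins of %.3g s (%.1f s), %.0f counts/s\n",
              x$channel, length(x$counts), x$bin_width,
              length(x$counts) * x$bin_width, x$count_rate))
  invisible(x)
}

#' Read a two-channel trace CSV
#'
#' Expects columns `time_s`, `counts_green`, `counts_red` with dot-decimal
#' numbers.  The bin width is taken from the first two time stamps.
#'
#' @param path file path.
#' @param dark_rate dark count rate metadata attached to both channels.
#' @return list with elements `green` and `red` ([intensity_trace]s).
#' @seealso [write_trace_csv()]
#' @export
read_trace_csv <- function(path, dark_rate = 0) {
  df <- read_checked_csv(path, c("time_s", "counts_green", "counts_red"))
  if (nrow(df) < 2) stop("trace file has fewer than 2 rows: ", path)
  dt <- df$time_s[2] - df$time_s[1]
  if (!is.finite(dt) || dt <= 0) stop("non-increasing time axis in ", path)
  list(green = intensity_trace(df$counts_green, dt, "G", dark_rate),
       red   = intensity_trace(df$counts_red, dt, "R", dark_rate))
}

#' Write a two-channel trace CSV
#'
#' @param green,red [intensity_trace]s on the same bin grid.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(green, red, path) {
  stopifnot(inherits(green, "intensity_trace"), inherits(red, "intensity_trace"))
  if (length(green$counts) != length(red$counts) ||
      green$bin_width != red$bin_width)
    stop("green and red traces must share one bin grid")
  n <- length(green$counts)
  df <- data.frame(time_s = (seq_len(n) - 1) * green$bin_width,
                   counts_green = green$counts, counts_red = red$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Strict CSV reader: required columns must exist and parse as dot-decimal
# numerics; comma-decimal dialects are rejected with an explicit message.
read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    if (is.character(v)) {
      if (any(grepl(",", v, fixed = TRUE)))
        stop("column '", col, "' in ", path,
             " contains comma decimals; dot-decimal CSV required")
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("column '", col, "' in ", path,
             " is not numeric at data line ", bad[1])
      df[[col]] <- vn
    }
    if (anyNA(df[[col]]))
      stop("column '", col, "' in ", path, " has missing values at data line ",
           which(is.na(df[[col]]))[1])
  }
  df
}
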