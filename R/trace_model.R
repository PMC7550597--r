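#' Construct a calcium transient trace
#'
#' A `calcium_trace` holds one cell's fluorescence intensity time series
#' (arbitrary units, AU) sampled at a fixed frame rate, together with a cell
#' identifier and a free-form provenance tag.
#'
#' @param intensities Numeric vector of fluorescence intensities (AU), one
#'   value per frame, in acquisition order. Must be finite and of length >= 2.
#' @param cell_id Character identifier for the cell.
#' @param sampling_hz Sampling rate in frames per second (default 5).
#' @param source_tag Free-form provenance string.
#' @return An object of class `calcium_trace`.
#' @examples
#' tr <- calcium_trace(20 + c(0, 50, 100, 40, 10, 2), cell_id = "c1")
#' length(tr$intensities)
#' @export
calcium_trace <- function(intensities, cell_id = "cell", sampling_hz = 5,
                          source_tag = "") {
  if (!is.numeric(intensities) || length(intensities) < 2)
    stop("intensities must be a numeric vector of length >= 2")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite (no NA/NaN/Inf)")
  if (!is.numeric(sampling_hz) || length(sampling_hz) != 1 || sampling_hz <= 0)
    stop("sampling_hz must be a single positive number")
  structure(
    list(cell_id = as.character(cell_id)[1],
         intensities = as.numeric(intensities),
         sampling_hz = as.numeric(sampling_hz),
         source_tag = as.character(source_tag)[1]),
    class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> cell '%s': %d frames @ %g Hz (%.1f s)\n",
              x$cell_id, length(x$intensities), x$sampling_hz,
              length(x$intensities) / x$sampling_hz))
  invisible(x)
}

#' Plot a trace with optional detected-peak markers
#'
#' @param x A `calcium_trace`.
#' @param peaks Optional data frame of peak boundaries (as returned by
#'   [detect_peaks()]) to overlay: peak maxima are marked with triangles,
#'   left/right boundaries with vertical dashes.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.calcium_trace <- function(x, peaks = NULL, ...) {
  t <- (seq_along(x$intensities) - 1) / x$sampling_hz
  graphics::plot(t, x$intensities, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (AU)", main = x$cell_id, ...)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    graphics::points(t[peaks$max_idx], x$intensities[peaks$max_idx],
                     pch = 25, bg = "red")
    graphics::abline(v = t[c(peaks$left_idx, peaks$right_idx)],
                     col = "grey60", lty = 3)
  }
  invisible(x)
}

.norm_names <- function(x) tolower(gsub("[. ]", "_", x))

#' Read calcium traces from a CSV file
#'
#' Accepts two layouts, auto-detected from the header:
#' \describe{
#'   \item{long}{columns `cell_id`, `frame`, `intensity`; one row per frame
#'     per cell. Rows are ordered by `frame` within each cell regardless of
#'     row order in the file.}
#'   \item{wide}{a `frame` column followed by one intensity column per cell,
#'     column names taken as cell ids.}
#' }
#' Traces containing missing or non-finite intensities are dropped with a
#' warning; the remaining traces are returned.
#'
#' @param path Path to a CSV file with a header row.
#' @param sampling_hz Sampling rate to attach to each trace (default 5).
#' @return Named list of [calcium_trace()] objects.
#' @export
read_traces <- function(path, sampling_hz = 5) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("unparsable trace file '", path,
                                          "': ", conditionMessage(e)))
  nm <- .norm_names(names(df))
  long <- all(c("cell_id", "frame", "intensity") %in% nm)
  traces <- list()
  dropped <- character(0)
  if (long) {
    names(df) <- nm
    for (id in unique(df$cell_id)) {
      sub <- df[df$cell_id == id, , drop = FALSE]
      sub <- sub[order(sub$frame), , drop = FALSE]
      y <- suppressWarnings(as.numeric(sub$intensity))
      if (anyNA(y) || !all(is.finite(y)) || length(y) < 2) {
        dropped <- c(dropped, as.character(id))
      } else {
        traces[[as.character(id)]] <-
          calcium_trace(y, cell_id = id, sampling_hz = sampling_hz,
                        source_tag = path)
      }
    }
  } else if ("frame" %in% nm) {
    names(df) <- ifelse(nm == "frame", "frame", names(df))
    df <- df[order(df$frame), , drop = FALSE]
    for (col in setdiff(names(df), "frame")) {
      y <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(y) || !all(is.finite(y)) || length(y) < 2) {
        dropped <- c(dropped, col)
      } else {
        traces[[col]] <- calcium_trace(y, cell_id = col,
                                       sampling_hz = sampling_hz,
                                       source_tag = path)
      }
    }
  } else {
    stop("unparsable trace file '", path,
         "': header must contain 'frame' (wide) or cell_id/frame/intensity (long)")
  }
  if (length(dropped) > 0)
    warning("dropped trace(s) with missing/non-finite intensities: ",
            paste(dropped, collapse = ", "))
  traces
}

#' Write calcium traces to a long-format CSV file
#'
#' Intensities are written with 17 significant digits so that
#' `read_traces(write_traces(x))` round-trips every finite double bit-exactly.
#'
#' @param traces Named list of [calcium_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id,
               frame = seq_along(tr$intensities),
               intensity = sprintf("%.17g", tr$intensities),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak- or cell-level label table
#'
#' Cell tables need columns `cell_id` and `label`; peak tables additionally
#' need `peak_index`. Labels must be `normal` or `abnormal`
#' (case-insensitive). Duplicate keys or unknown label strings are errors.
#'
#' @param path Path to a CSV file with a header row.
#' @param level `"cell"` or `"peak"`.
#' @return Data frame with the key column(s) and a `label` factor with
#'   levels `normal`, `abnormal`.
#' @export
read_labels <- function(path, level = c("cell", "peak")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path)
  names(df) <- .norm_names(names(df))
  need <- if (level == "peak") c("cell_id", "peak_index", "label")
          else c("cell_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("label file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  lab <- tolower(trimws(as.character(df$label)))
  bad <- which(!lab %in% c("normal", "abnormal"))
  if (length(bad) > 0)
    stop("unknown label '", df$label[bad[1]], "' in row ", bad[1],
         " of ", path, " (expected normal/abnormal)")
  key <- if (level == "peak") paste(df$cell_id, df$peak_index, sep = "\r")
         else as.character(df$cell_id)
  if (anyDuplicated(key))
    stop("duplicate key(s) in label file ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  df$label <- factor(lab, levels = c("normal", "abnormal"))
  df[, need, drop = FALSE]
}

#' Write a label table to CSV
#'
#' @param labels Data frame with `cell_id`, optional `peak_index`, and `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
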