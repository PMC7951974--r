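# Reading and writing the spikefinder column-CSV dialect.
#
# Dialect: UTF-8, comma-separated, one header row of column labels, one
# neuron per column, samples at 100 Hz top to bottom. Columns may have
# different lengths; shorter columns are padded at the bottom with empty
# cells. Empty cells anywhere else are treated as corruption.

#' Construct a paired recording
#'
#' Couples one neuron's fluorescence trace with its ground-truth spike
#' counts at a common sampling rate.
#'
#' @param trace Numeric fluorescence values, all finite.
#' @param spikes Non-negative integer spike counts, same length as `trace`.
#' @param dataset_id,neuron_id Labels.
#' @param fs Sampling rate in Hz (default 100).
#' @return An object of class `recording` with fields `trace`, `spikes`,
#'   `dataset_id`, `neuron_id`, `fs`.
#' @export
recording <- function(trace, spikes, dataset_id = "dataset", neuron_id = "0",
                      fs = 100) {
  if (length(trace) != length(spikes)) {
    stop_param("trace and spikes must have equal length (",
               length(trace), " vs ", length(spikes), ")")
  }
  if (any(!is.finite(trace))) stop_param("trace contains non-finite values")
  if (any(!is.finite(spikes)) || any(spikes < 0) ||
      any(abs(spikes - round(spikes)) > 1e-6)) {
    stop_param("spikes must be non-negative integers")
  }
  structure(
    list(trace = as.numeric(trace), spikes = as.integer(round(spikes)),
         dataset_id = as.character(dataset_id),
         neuron_id = as.character(neuron_id),
         fs = check_number(fs, "fs", lower = 0, strict_lower = TRUE)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording %s/%s: %d samples at %g Hz, %d spikes\n",
              x$dataset_id, x$neuron_id, length(x$trace), x$fs,
              sum(x$spikes)))
  invisible(x)
}

#' Read a spikefinder-dialect column CSV
#'
#' Each column is one neuron's sequence; trailing empty cells (bottom
#' padding of ragged columns) are trimmed. An empty cell in the interior of
#' a column, or any non-numeric cell, is a format error. For
#' `kind = "spikes"` values must additionally be non-negative and within
#' `1e-6` of an integer; they are rounded to integers.
#'
#' @param path Path to the CSV file.
#' @param kind `"calcium"` (real-valued) or `"spikes"` (validated counts).
#' @return Named list of numeric vectors, one per column, names taken from
#'   the header row.
#' @export
read_column_csv <- function(path, kind = c("calcium", "spikes")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, strip.white = TRUE)
  out <- vector("list", ncol(df))
  names(out) <- names(df)
  for (j in seq_along(df)) {
    label <- names(df)[j]
    vals <- df[[j]]
    empty <- !nzchar(vals)
    last <- if (all(empty)) 0L else max(which(!empty))
    if (last > 0L && any(empty[seq_len(last)])) {
      row <- which(empty[seq_len(last)])[1L]
      stop_format("column '", label, "': empty cell in the interior at row ",
                  row, " (only bottom padding may be empty)")
    }
    kept <- vals[seq_len(last)]
    x <- suppressWarnings(as.numeric(kept))
    if (anyNA(x)) {
      row <- which(is.na(x))[1L]
      stop_format("column '", label, "': non-numeric cell '", kept[row],
                  "' at row ", row)
    }
    if (kind == "spikes" && last > 0L) {
      if (any(x < -1e-6)) {
        stop_format("column '", label, "': negative spike count")
      }
      if (any(abs(x - round(x)) > 1e-6)) {
        stop_format("column '", label,
                    "': spike count not an integer within tolerance")
      }
      x <- pmax(round(x), 0)
    }
    out[[j]] <- x
  }
  out
}

#' Write sequences as a spikefinder-dialect column CSV
#'
#' Sequences become columns under a header of their names (0-based indices
#' when unnamed); shorter columns are bottom-padded with empty cells.
#' Values are written with 17 significant digits so doubles round-trip
#' exactly.
#'
#' @param seqs Non-empty list of numeric vectors.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_column_csv <- function(seqs, path) {
  if (!is.list(seqs) || length(seqs) < 1L) {
    stop_param("'seqs' must be a non-empty list of numeric vectors")
  }
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- as.character(seq_along(seqs) - 1L)
  }
  nmax <- max(vapply(seqs, length, integer(1)))
  cols <- lapply(seqs, function(x) {
    s <- sprintf("%.17g", as.numeric(x))
    c(s, rep("", nmax - length(x)))
  })
  mat <- do.call(cbind, cols)
  lines <- c(paste(labels, collapse = ","),
             apply(mat, 1L, paste, collapse = ","))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Pair calcium and spike columns into recordings
#'
#' Column `j` of the calcium file is paired with column `j` of the spikes
#' file. Length differences of at most 2 samples (off-by-one resampling
#' artifacts, a 10-20 ms trim at 100 Hz) are absorbed by trimming both to
#' the shorter length; larger differences are an error.
#'
#' @param calcium_seqs,spike_seqs Lists of sequences as returned by
#'   [read_column_csv()]; must have the same number of columns.
#' @param dataset_id Dataset label stamped onto every recording.
#' @param fs Sampling rate in Hz.
#' @return List of [recording()] objects; `neuron_id`s are the calcium
#'   column labels (column indices when unnamed).
#' @export
pair_recordings <- function(calcium_seqs, spike_seqs, dataset_id = "dataset",
                            fs = 100) {
  if (length(calcium_seqs) != length(spike_seqs)) {
    stop_format("column-count mismatch: ", length(calcium_seqs),
                " calcium vs ", length(spike_seqs), " spike columns")
  }
  labels <- names(calcium_seqs)
  if (is.null(labels)) labels <- as.character(seq_along(calcium_seqs) - 1L)
  out <- vector("list", length(calcium_seqs))
  for (j in seq_along(calcium_seqs)) {
    tr <- calcium_seqs[[j]]
    sp <- spike_seqs[[j]]
    if (abs(length(tr) - length(sp)) > 2L) {
      stop_format("column '", labels[j], "': length mismatch of ",
                  abs(length(tr) - length(sp)), " samples (> 2)")
    }
    n <- min(length(tr), length(sp))
    out[[j]] <- recording(tr[seq_len(n)], sp[seq_len(n)],
                          dataset_id = dataset_id, neuron_id = labels[j],
                          fs = fs)
  }
  out
}
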