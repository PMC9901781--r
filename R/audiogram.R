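#' Standard audiometric test frequencies
#'
#' The eleven pure-tone frequencies routinely recorded during cochlear-implant
#' candidacy evaluation, in Hz. Octave frequencies (250, 500, 1000, 2000,
#' 4000, 8000 Hz) are tested almost universally; the inter-octave frequencies
#' (750, 1500, 3000, 6000 Hz) and 125 Hz are tested less consistently, which
#' is what drives structured missingness in real audiogram tables.
#'
#' @return Numeric vector of 11 frequencies in Hz, strictly ascending.
#' @export
audiogram_frequencies <- function() {
  c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
}

#' Construct an audiogram matrix
#'
#' An `audiogram_matrix` is a numeric matrix with one row per audiogram and
#' one column per test frequency, holding pure-tone thresholds in dB HL.
#' Missing thresholds are `NA`; during loading (before cleaning) unparseable
#' cells are carried as `NaN`, a sentinel distinct from missing.
#'
#' @param values Numeric matrix, instances x frequencies.
#' @param frequencies Numeric vector of column frequencies in Hz, strictly
#'   ascending, one per column.
#' @param ids Optional character vector of per-instance identifiers.
#' @return An object of class `audiogram_matrix`.
#' @export
audiogram_matrix <- function(values, frequencies = audiogram_frequencies(),
                             ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  frequencies <- as.numeric(frequencies)
  if (ncol(values) != length(frequencies)) {
    stop("`values` must have one column per frequency (", length(frequencies),
         "), got ", ncol(values), call. = FALSE)
  }
  if (length(frequencies) > 1 && any(diff(frequencies) <= 0)) {
    stop("`frequencies` must be strictly ascending", call. = FALSE)
  }
  colnames(values) <- as.character(frequencies)
  if (!is.null(ids)) {
    if (length(ids) != nrow(values)) {
      stop("`ids` must have one entry per instance", call. = FALSE)
    }
    rownames(values) <- as.character(ids)
  }
  structure(values, frequencies = frequencies, class = "audiogram_matrix")
}

#' @export
print.audiogram_matrix <- function(x, ...) {
  n_miss <- sum(is.na(unclass(x)))
  cat(sprintf("<audiogram_matrix> %d audiograms x %d frequencies (%s Hz), %d missing cells\n",
              nrow(x), ncol(x),
              paste(attr(x, "frequencies"), collapse = "/"), n_miss))
  invisible(x)
}

#' @export
`[.audiogram_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, , drop = FALSE]
  audiogram_matrix(out, frequencies = attr(x, "frequencies"))
}

# internal: TRUE where genuinely missing (NA but not the NaN invalid sentinel)
is_missing <- function(values) {
  is.na(values) & !is.nan(values)
}

#' Load an audiogram table from delimited text
#'
#' Reads a CSV with one column per requested frequency (header = frequency in
#' Hz). Cells may be numeric, empty (missing), or free text such as "NR".
#' Non-numeric cells are mapped to an invalid sentinel (`NaN`) pending
#' [clean_thresholds()]; the original cell text is preserved internally so
#' cleaning can recognize no-response tokens. Columns other than the
#' requested frequencies (ids, demographics) are carried along untouched.
#'
#' @param path Path to a delimited text file.
#' @param frequencies Frequencies (Hz) whose columns must be present.
#' @param sep Field separator (default comma).
#' @return A raw `audiogram_matrix` (uncleaned; may contain `NaN` sentinels).
#' @export
load_audiograms <- function(path, frequencies = audiogram_frequencies(),
                            sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, strip.white = TRUE)
  if (nrow(df) == 0) stop("empty input: no audiograms in ", path, call. = FALSE)
  want <- as.character(as.numeric(frequencies))
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required frequency column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw_chr <- as.matrix(df[, want, drop = FALSE])
  parsed <- suppressWarnings(matrix(as.numeric(raw_chr), nrow = nrow(raw_chr)))
  empty <- !nzchar(raw_chr) | toupper(raw_chr) %in% c("NA")
  values <- parsed
  values[empty] <- NA_real_
  invalid <- is.na(parsed) & !empty           # text that failed to parse
  values[invalid] <- NaN
  m <- audiogram_matrix(values, frequencies = frequencies)
  extra <- df[, setdiff(names(df), want), drop = FALSE]
  if (ncol(extra) > 0) attr(m, "extra") <- extra
  attr(m, "raw_text") <- raw_chr
  m
}

#' Clean audiogram thresholds
#'
#' Applies the preprocessing rules used for cochlear-implant-candidate
#' audiogram tables:
#' \enumerate{
#'   \item no-response tokens (audiometer maximum reached) become 120 dB;
#'   \item remaining invalid cells (unparseable text, or numbers outside a
#'     plausibility window) become missing;
#'   \item numeric values inside the plausibility window are clipped to
#'     \[0, 120\] dB;
#'   \item instances with every feature missing are removed.
#' }
#' Cleaning is total (never errors) and idempotent.
#'
#' @param raw An `audiogram_matrix`, typically from [load_audiograms()].
#' @param no_response_tokens Character tokens (case-insensitive, whitespace
#'   trimmed) meaning "no response at maximum output".
#' @param plausible Length-2 numeric window; values outside it are treated as
#'   invalid (missing) rather than clipped.
#' @return A cleaned `audiogram_matrix`: all observed values in \[0, 120\],
#'   no invalid sentinels, no all-missing rows.
#' @export
clean_thresholds <- function(raw,
                             no_response_tokens = c("NR", "No response"),
                             plausible = c(-20, 200)) {
  stopifnot(inherits(raw, "audiogram_matrix"))
  values <- unclass(raw)
  attributes(values) <- list(dim = dim(values), dimnames = dimnames(values))
  tokens <- toupper(trimws(no_response_tokens))
  raw_text <- attr(raw, "raw_text")
  if (!is.null(raw_text)) {
    nr <- matrix(toupper(trimws(raw_text)) %in% tokens, nrow = nrow(values))
    values[nr] <- 120
  }
  values[is.nan(values)] <- NA_real_
  out_of_window <- !is.na(values) &
    (values < plausible[1] | values > plausible[2])
  values[out_of_window] <- NA_real_
  values <- pmin(pmax(values, 0), 120)
  keep <- rowSums(!is.na(values)) > 0
  m <- audiogram_matrix(values[keep, , drop = FALSE],
                        frequencies = attr(raw, "frequencies"))
  extra <- attr(raw, "extra")
  if (!is.null(extra)) attr(m, "extra") <- extra[keep, , drop = FALSE]
  m
}

#' Keep only complete audiograms
#'
#' Complete case analysis: retains instances with zero missing features,
#' preserving order. May return an empty matrix.
#'
#' @param m A cleaned `audiogram_matrix`.
#' @return An `audiogram_matrix` of fully observed instances.
#' @export
complete_cases <- function(m) {
  filter_by_missing_count(m, 0L)
}

#' Filter audiograms by missing-feature count
#'
#' Retains instances with at most `cap` missing features, preserving order.
#' `cap = 0` is complete case analysis; `cap = n_features` is the identity.
#'
#' @param m A cleaned `audiogram_matrix`.
#' @param cap Maximum number of missing features per retained instance.
#' @return Filtered `audiogram_matrix`.
#' @export
filter_by_missing_count <- function(m, cap) {
  stopifnot(inherits(m, "audiogram_matrix"))
  cap <- as.integer(cap)
  if (cap < 0 || cap > ncol(m)) {
    stop("`cap` must be in [0, ", ncol(m), "]", call. = FALSE)
  }
  keep <- rowSums(is.na(unclass(m))) <= cap
  out <- audiogram_matrix(unclass(m)[keep, , drop = FALSE],
                          frequencies = attr(m, "frequencies"))
  extra <- attr(m, "extra")
  if (!is.null(extra)) attr(out, "extra") <- extra[keep, , drop = FALSE]
  out
}

#' Write an audiogram matrix to CSV
#'
#' Inverse of [load_audiograms()] for cleaned data: one column per frequency,
#' missing cells written empty, any carried-through extra columns appended.
#'
#' @param m An `audiogram_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audiograms <- function(m, path) {
  stopifnot(inherits(m, "audiogram_matrix"))
  df <- as.data.frame(unclass(m), check.names = FALSE)
  extra <- attr(m, "extra")
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
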