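# Per-residue intrinsic disorder tracks.
#
# Disorder probabilities (pD, in [0,1]) are produced by external
# predictors; this module parses their per-residue output, provides a
# clearly labelled naive propensity-based stand-in so the pipeline is
# testable offline, and binarizes tracks at a threshold.  The stand-in is
# a smoothed composition score, not a re-implementation of any
# machine-learning predictor, and is never expected to reproduce one.

#' Create a disorder profile
#'
#' @param record_id Identifier of the protein the track belongs to.
#' @param pd Numeric vector of per-residue disorder probabilities in
#'   `[0, 1]`.
#' @param positions Optional residue numbers (default `1..n`).
#' @param residues Optional residue letters, retained for pairing checks.
#' @param source Free text describing where the track came from, e.g.
#'   `"prdos-export"`, `"naive-standin"`, `"synthetic"`.
#' @param threshold Binary-call cutoff in `(0, 1)`; default 0.5, the
#'   midpoint of the probability scale.
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(record_id, pd, positions = NULL,
                             residues = NULL, source = "unknown",
                             threshold = 0.5) {
  pd <- as.numeric(pd)
  if (length(pd) == 0L) {
    stop("disorder profile '", record_id, "': empty track")
  }
  bad <- which(!is.finite(pd) | pd < 0 | pd > 1)
  if (length(bad) > 0L) {
    stop("disorder profile '", record_id, "': pd value ", pd[bad[1L]],
         " at position ", bad[1L], " outside [0, 1]")
  }
  if (is.null(positions)) {
    positions <- seq_along(pd)
  }
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(pd))
  if (!is.null(residues)) {
    stopifnot(length(residues) == length(pd))
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("disorder threshold must lie strictly between 0 and 1")
  }
  structure(
    list(record_id = record_id, pd = pd, positions = positions,
         residues = residues, source = source, threshold = threshold),
    class = "disorder_profile"
  )
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("<disorder_profile> ", x$record_id, ": ", length(x$pd),
      " residues, pd in [", format(min(x$pd), digits = 3), ", ",
      format(max(x$pd), digits = 3), "], source ", x$source,
      ", threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Read a per-residue disorder track
#'
#' Two dialects are accepted.  `"generic"` is a tab-separated file with a
#' header and columns `residue_number`, `residue`, `pd`.  `"prdos-export"`
#' is the downloadable per-residue CSV of the PrDOS server: optional `#`
#' comment lines followed by rows `residue_letter,residue_number,
#' probability[,binary_call]`.  In both cases probabilities are validated
#' into `[0, 1]` and residue numbering must be strictly increasing.
#'
#' @param path Path to the track file.
#' @param dialect `"generic"` or `"prdos-export"`.
#' @param record_id Identifier for the track; default the file base name.
#' @param threshold Binary-call cutoff stored on the profile.
#' @return A [disorder_profile()].
#' @export
read_disorder_profile <- function(path, dialect = c("generic", "prdos-export"),
                                  record_id = NULL, threshold = 0.5) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "generic") {
    df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    need <- c("residue_number", "residue", "pd")
    if (!all(need %in% names(df))) {
      stop("generic disorder track '", path, "': expected header columns ",
           paste(need, collapse = ", "))
    }
    num <- as.integer(df$residue_number)
    res <- toupper(df$residue)
    pd <- suppressWarnings(as.numeric(df$pd))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), ",")
    if (any(lengths(fields) < 3L)) {
      stop("prdos-export track '", path, "': expected comma-separated rows ",
           "residue_letter,residue_number,probability")
    }
    res <- toupper(vapply(fields, `[`, character(1), 1L))
    num <- suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 2L)))
    pd <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  }
  bad <- which(!is.finite(pd) | pd < 0 | pd > 1)
  if (length(bad) > 0L) {
    stop("disorder track '", path, "': probability outside [0, 1] at data ",
         "row ", bad[1L], " (value ", df_or(pd, bad[1L]), ")")
  }
  if (anyNA(num) || any(diff(num) <= 0)) {
    stop("disorder track '", path, "': residue numbering must be strictly ",
         "increasing")
  }
  disorder_profile(record_id, pd, positions = num, residues = res,
                   source = if (dialect == "generic") "generic" else
                     "prdos-export",
                   threshold = threshold)
}

df_or <- function(x, i) format(x[i])

#' Write a disorder track in the generic dialect
#'
#' @param profile A [disorder_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder_profile <- function(profile, path) {
  stopifnot(inherits(profile, "disorder_profile"))
  res <- profile$residues
  if (is.null(res)) res <- rep("X", length(profile$pd))
  df <- data.frame(residue_number = profile$positions, residue = res,
                   pd = sprintf("%.6f", profile$pd))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.load_disorder_propensity <- function() {
  path <- system.file("extdata", "scales", "topidp2008.txt",
                      package = "seqflex", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  fields <- strsplit(trimws(data), "\\s+")
  setNames(as.numeric(vapply(fields, `[`, character(1), 2L)),
           toupper(vapply(fields, `[`, character(1), 1L)))[AA_CANONICAL]
}

#' Naive offline disorder stand-in scorer
#'
#' Scores each residue by a packaged per-residue disorder-propensity table
#' (TOP-IDP), smooths under `window` exactly like a flexibility profile,
#' and min-max rescales into `[0, 1]` using the table's own extrema --
#' not the sequence's -- so scores are comparable across proteins.  This
#' is a deterministic composition heuristic that exists so the pipeline
#' runs with no external predictor; it is labelled `"naive-standin"` and
#' makes no claim to match any predictor's output.
#'
#' @param record A [sequence_record()].
#' @param window A [window_spec()].
#' @param threshold Binary-call cutoff stored on the profile.
#' @return A [disorder_profile()] with source `"naive-standin"`.
#' @export
naive_disorder_score <- function(record, window = window_spec(),
                                 threshold = 0.5) {
  stopifnot(inherits(record, "sequence_record"),
            inherits(window, "window_spec"))
  tab <- .load_disorder_propensity()
  chars <- residue_chars(record)
  v <- tab[chars]
  v[chars == "X"] <- mean(tab)
  smoothed <- .windowed_average(unname(v), window)
  pd <- (smoothed - min(tab)) / (max(tab) - min(tab))
  disorder_profile(record$id, pd, positions = residue_numbers(record),
                   residues = chars, source = "naive-standin",
                   threshold = threshold)
}

#' Binarize a disorder track
#'
#' @param profile A [disorder_profile()].
#' @return Logical vector: `pd >= threshold` per residue.
#' @export
binarize_disorder <- function(profile) {
  stopifnot(inherits(profile, "disorder_profile"))
  profile$pd >= profile$threshold
}
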