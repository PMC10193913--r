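# Sequence and segment-annotation I/O.
#
# Residue coordinates throughout the package are 1-based and inclusive at
# both ends, in the numbering of the full-length protein.  Records may store
# a fragment of that protein; `numbering_offset` (residue number of the
# first stored character minus one) keeps fragment slices addressable by
# full-length residue numbers.

#' @importFrom stats sd setNames rnorm runif plogis qlogis wilcox.test p.adjust cor
#' @importFrom utils read.delim write.table
NULL

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_CANONICAL, "X")
HELIX_CLASSES <- c("alpha", "pi", "three10", "loop", "unknown")

#' Create a sequence record
#'
#' A sequence record holds an identifier, a free-text description, the
#' residue string (20 canonical one-letter codes plus `X` for an unknown
#' residue), and a numbering offset so that stored fragments keep the
#' residue numbering of the full-length protein.
#'
#' @param id Identifier (accession or free text).
#' @param residues Residue string; lower case is accepted and uppercased.
#' @param description Free-text description.
#' @param numbering_offset Residue number of the first stored character
#'   minus one.  The default 0 means the record starts at residue 1.
#' @return An object of class `sequence_record`.
#' @examples
#' rec <- sequence_record("toy", "ILTFVLLLNML", numbering_offset = 662)
#' residue_numbers(rec)
#' @export
sequence_record <- function(id, residues, description = "", numbering_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("sequence record '", id, "': residue string is empty")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop("sequence record '", id, "': illegal residue character '",
         chars[bad[1L]], "' at position ", bad[1L],
         " (allowed: 20 canonical one-letter codes and X)")
  }
  numbering_offset <- as.integer(numbering_offset)
  stopifnot(length(numbering_offset) == 1L, !is.na(numbering_offset))
  structure(
    list(id = id, description = description, residues = residues,
         numbering_offset = numbering_offset),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  n <- nchar(x$residues)
  cat("<sequence_record> ", x$id,
      if (nzchar(x$description)) paste0(" | ", x$description) else "",
      "\n  residues ", x$numbering_offset + 1L, "-", x$numbering_offset + n,
      " (", n, " aa)\n", sep = "")
  invisible(x)
}

#' @export
length.sequence_record <- function(x) nchar(x$residues)

#' Residue numbers of a sequence record
#'
#' @param record A [sequence_record()].
#' @return Integer vector of full-length residue numbers, one per stored
#'   residue.
#' @export
residue_numbers <- function(record) {
  stopifnot(inherits(record, "sequence_record"))
  record$numbering_offset + seq_len(nchar(record$residues))
}

# Split a record's residue string into a character vector.
residue_chars <- function(record) {
  strsplit(record$residues, "", fixed = TRUE)[[1]]
}

# The FASTA description has no standard slot for a numbering offset, so a
# token "offset=<int>" in the description line is written and recognised.
.parse_offset_token <- function(desc) {
  m <- regmatches(desc, regexpr("(?:^|\\s)offset=(-?[0-9]+)", desc))
  if (length(m) == 0L) {
    return(list(offset = 0L, description = desc))
  }
  off <- as.integer(sub(".*offset=", "", m))
  desc <- trimws(gsub("(?:^|\\s)offset=-?[0-9]+", "", desc))
  list(offset = off, description = desc)
}

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and validated against the 20 canonical residue
#' codes plus `X`; gap characters and other non-standard letters (B, Z, U,
#' O, `*`) are rejected with the offending position named.  A description
#' token `offset=<int>` is interpreted as the record's numbering offset
#' (see [sequence_record()]), so fragment fixtures keep full-length residue
#' numbering through a round-trip.
#'
#' @param path Path to a FASTA file.  Any line wrapping is accepted.
#' @return A list of [sequence_record()] objects, file order preserved.
#'   An empty file yields an empty list.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(raw)))
  if (length(nonempty) == 0L) {
    return(list())
  }
  first <- nonempty[1L]
  if (!startsWith(trimws(raw[first]), ">")) {
    stop("not FASTA: line ", first, " ('", raw[first],
         "') does not start a '>' header")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e))
  )
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    parts <- strsplit(header, "\\s+")[[1]]
    id <- parts[1L]
    desc <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else ""
    tok <- .parse_offset_token(desc)
    out[[i]] <- sequence_record(id, as.character(set[[i]]),
                                description = tok$description,
                                numbering_offset = tok$offset)
  }
  out
}

#' Write sequence records to a FASTA file
#'
#' Output wraps at 60 columns.  Non-zero numbering offsets are stored as an
#' `offset=<int>` description token so that [read_fasta()] round-trips them.
#'
#' @param records A [sequence_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "sequence_record")))
  headers <- vapply(records, function(r) {
    desc <- r$description
    if (r$numbering_offset != 0L) {
      desc <- trimws(paste(desc, paste0("offset=", r$numbering_offset)))
    }
    if (nzchar(desc)) paste(r$id, desc) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Create a segment annotation
#'
#' A named residue range of a protein with a helix-class label.  Classes
#' distinguish segments that stay canonically alpha-helical from those that
#' transition to the non-canonical pi (wider, 4.4 residues/turn) or 3-10
#' (tighter, i to i+3 hydrogen bonding) forms, plus loops.
#'
#' @param protein_id Identifier matching a [sequence_record()].
#' @param segment_name Free-text segment label (e.g. `"S4"`, `"PH2"`).
#' @param start,end 1-based inclusive residue numbers, `start <= end`.
#' @param helix_class One of `"alpha"`, `"pi"`, `"three10"`, `"loop"`,
#'   `"unknown"`.
#' @return An object of class `segment_annotation`.
#' @export
segment_annotation <- function(protein_id, segment_name, start, end,
                               helix_class = "unknown") {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end)) {
    stop("segment '", segment_name, "': start/end must be integers")
  }
  if (start > end) {
    stop("segment '", segment_name, "' of '", protein_id,
         "': start (", start, ") > end (", end, ")")
  }
  if (!(helix_class %in% HELIX_CLASSES)) {
    stop("segment '", segment_name, "': unknown helix_class '", helix_class,
         "' (allowed: ", paste(HELIX_CLASSES, collapse = ", "), ")")
  }
  structure(
    list(protein_id = protein_id, segment_name = segment_name,
         start = start, end = end, helix_class = helix_class),
    class = "segment_annotation"
  )
}

#' @export
print.segment_annotation <- function(x, ...) {
  cat("<segment_annotation> ", x$protein_id, " ", x$segment_name, " ",
      x$start, "-", x$end, " [", x$helix_class, "]\n", sep = "")
  invisible(x)
}

SEGMENT_TABLE_HEADER <- c("protein_id", "segment_name", "start", "end",
                          "helix_class")

#' Read a segment-annotation table
#'
#' Tab-separated with header columns `protein_id`, `segment_name`, `start`,
#' `end`, `helix_class`.  Coordinates are 1-based inclusive; helix classes
#' are validated against the allowed set.
#'
#' @param path Path to the table.
#' @return A list of [segment_annotation()] objects, row order preserved.
#' @seealso [segments_as_data_frame()] for a tabular view.
#' @export
read_segment_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!identical(names(df), SEGMENT_TABLE_HEADER)) {
    stop("segment table '", path, "': expected header ",
         paste(SEGMENT_TABLE_HEADER, collapse = "\t"), " but found ",
         paste(names(df), collapse = "\t"))
  }
  lapply(seq_len(nrow(df)), function(i) {
    segment_annotation(df$protein_id[i], df$segment_name[i],
                       df$start[i], df$end[i], df$helix_class[i])
  })
}

#' Write a segment-annotation table
#'
#' @param annotations List of [segment_annotation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(annotations, path) {
  df <- segments_as_data_frame(annotations)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert segment annotations to a data frame
#'
#' @param annotations List of [segment_annotation()] objects.
#' @return A data frame with one row per annotation.
#' @export
segments_as_data_frame <- function(annotations) {
  if (inherits(annotations, "segment_annotation")) {
    annotations <- list(annotations)
  }
  stopifnot(all(vapply(annotations, inherits, logical(1),
                       "segment_annotation")))
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(protein_id = a$protein_id, segment_name = a$segment_name,
               start = a$start, end = a$end, helix_class = a$helix_class,
               stringsAsFactors = FALSE)
  }))
}

#' Extract an annotated segment from a sequence record
#'
#' Slices the inclusive residue range of `annotation` out of `record`,
#' honouring the record's numbering offset; the returned fragment keeps the
#' full-length residue numbering.
#'
#' @param record A [sequence_record()].
#' @param annotation A [segment_annotation()], or anything with `start`,
#'   `end` fields.
#' @return A [sequence_record()] of length `end - start + 1`.
#' @examples
#' rec <- sequence_record("frag", "ILTFVLLLNML", numbering_offset = 662)
#' extract_segment(rec, segment_annotation("frag", "mid", 665, 667))
#' @export
extract_segment <- function(record, annotation) {
  stopifnot(inherits(record, "sequence_record"))
  start <- as.integer(annotation$start)
  end <- as.integer(annotation$end)
  lo <- record$numbering_offset + 1L
  hi <- record$numbering_offset + nchar(record$residues)
  if (start > end) {
    stop("segment range ", start, "-", end, " is inverted")
  }
  if (start < lo || end > hi) {
    stop("segment ", start, "-", end, " outside record '", record$id,
         "' which spans residues ", lo, "-", hi)
  }
  i <- start - record$numbering_offset
  j <- end - record$numbering_offset
  name <- if (!is.null(annotation$segment_name)) annotation$segment_name else ""
  desc <- trimws(paste(record$description,
                       if (nzchar(name)) paste0("[", name, "]") else ""))
  sequence_record(record$id, substr(record$residues, i, j),
                  description = desc, numbering_offset = start - 1L)
}
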