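# Per-residue flexibility scales.
#
# A flexibility scale maps each of the 20 canonical residues to a positive
# value in normalized-B-factor units; larger means a more flexible
# side-chain.  The packaged default is the average normalized B-factor
# flexibility scale of Vihinen, Torkkila & Riikonen (1994, Proteins 19,
# 141-149), the standard sequence-based flexibility propensity compiled
# from large sets of refined crystal structures.

PACKAGED_SCALES <- c("vihinen1994")

#' Create a flexibility scale
#'
#' @param values Named numeric vector with exactly one positive, finite
#'   value per canonical residue letter.
#' @param provenance Free-text provenance (source and calibration state).
#' @return An object of class `flexibility_scale`.
#' @export
flexibility_scale <- function(values, provenance = "user-supplied") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  names(values) <- toupper(names(values))
  missing <- setdiff(AA_CANONICAL, names(values))
  if (length(missing) > 0L) {
    stop("flexibility scale is missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(values), AA_CANONICAL)
  if (length(extra) > 0L) {
    stop("flexibility scale has non-canonical entries: ",
         paste(extra, collapse = ", "))
  }
  values <- values[AA_CANONICAL]
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- names(values)[!is.finite(values) | values <= 0]
    stop("flexibility scale values must be finite and > 0; offending: ",
         paste(bad, collapse = ", "))
  }
  structure(list(values = values, provenance = provenance),
            class = "flexibility_scale")
}

#' @export
print.flexibility_scale <- function(x, ...) {
  cat("<flexibility_scale> ", x$provenance, "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

# Value contributed by one residue letter; X gets the unweighted mean of
# the 20 canonical values so profile arithmetic stays defined.
scale_values_for <- function(scale, chars) {
  v <- scale$values[chars]
  v[chars == "X"] <- mean(scale$values)
  unname(v)
}

.scale_file_for <- function(name) {
  system.file("extdata", "scales", paste0(name, ".txt"),
              package = "seqflex", mustWork = TRUE)
}

#' Load a flexibility scale
#'
#' `source` is either the name of a packaged scale (currently
#' `"vihinen1994"`, the default) or the path to a two-column text file
#' (residue letter, value; `#` lines are provenance comments and are
#' retained as the scale's provenance).
#'
#' @param source Packaged scale name or file path.
#' @return A [flexibility_scale()].
#' @examples
#' sc <- load_flex_scale()
#' sc$values["L"] > sc$values["F"]  # Leu more flexible than Phe
#' @export
load_flex_scale <- function(source = "vihinen1994") {
  stopifnot(is.character(source), length(source) == 1L)
  path <- if (source %in% PACKAGED_SCALES) .scale_file_for(source) else source
  if (!file.exists(path)) {
    stop("flexibility scale source '", source,
         "' is neither a packaged scale (",
         paste(PACKAGED_SCALES, collapse = ", "), ") nor an existing file")
  }
  lines <- readLines(path, warn = FALSE)
  comments <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  data <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  fields <- strsplit(trimws(data), "\\s+")
  if (any(lengths(fields) != 2L)) {
    stop("scale file '", path, "': expected two whitespace-separated ",
         "columns (residue letter, value)")
  }
  letters <- toupper(vapply(fields, `[`, character(1), 1L))
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  if (anyNA(vals)) {
    stop("scale file '", path, "': non-numeric value in column 2")
  }
  provenance <- if (length(comments) > 0L) {
    paste(comments, collapse = " | ")
  } else {
    paste0("file:", path)
  }
  flexibility_scale(setNames(vals, letters), provenance = provenance)
}

#' Write a flexibility scale to a file
#'
#' Two-column text (residue letter, value) with the provenance stored as
#' leading `#` comment lines, the format accepted by [load_flex_scale()].
#'
#' @param scale A [flexibility_scale()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flex_scale <- function(scale, path) {
  stopifnot(inherits(scale, "flexibility_scale"))
  con <- file(path, "w")
  on.exit(close(con))
  for (line in strsplit(scale$provenance, " | ", fixed = TRUE)[[1]]) {
    writeLines(paste("#", line), con)
  }
  writeLines(sprintf("%s\t%.6g", names(scale$values), scale$values), con)
  invisible(path)
}
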