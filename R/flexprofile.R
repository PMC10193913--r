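# Core flexibility computations: B-factor standardization, windowed
# per-residue flexibility profiles, segment mean flexibility (mBf), and
# affine scale calibration against reference mBf anchors.

#' Create a raw B-factor series
#'
#' Holds per-residue thermal factors from a structure together with their
#' sample mean and sample (n-1) standard deviation, the two quantities a
#' per-structure standardization needs.
#'
#' @param values Numeric vector of raw B-factors, length >= 2.
#' @return An object of class `bfactor_series` with fields `values`,
#'   `mean`, `sd`.
#' @export
bfactor_series <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("B-factor series needs length >= 2 for normalization")
  }
  if (any(!is.finite(values))) {
    stop("B-factor series contains non-finite values")
  }
  structure(list(values = values, mean = mean(values), sd = sd(values)),
            class = "bfactor_series")
}

#' Standardize a B-factor series
#'
#' Per-structure standardization `(B - Bm) / Bsd` with the sample mean `Bm`
#' and sample (n-1) standard deviation `Bsd`, so the output has mean 0 and
#' sample SD 1 exactly.  This is how raw crystallographic thermal factors
#' are made comparable across structures before being aggregated into a
#' per-residue flexibility propensity scale.
#'
#' @param series A [bfactor_series()] or a raw numeric vector.
#' @return Numeric vector of normalized B-factors.
#' @examples
#' normalize_bfactors(c(10, 20, 30))  # -1, 0, 1
#' @export
normalize_bfactors <- function(series) {
  if (!inherits(series, "bfactor_series")) {
    series <- bfactor_series(series)
  }
  if (series$sd == 0) {
    stop("degenerate B-factor series: sample SD is zero")
  }
  (series$values - series$mean) / series$sd
}

#' Create a smoothing window specification
#'
#' A symmetric positive weight vector of odd width summing to one, used to
#' average each residue's scale value with its N- and C-terminal
#' neighbours.  The default width-3 window with weights (0.25, 0.5, 0.25)
#' weights the residue itself twice as much as each immediate neighbour.
#'
#' @param width Odd integer >= 1.
#' @param weights Positive symmetric numeric vector of length `width`
#'   summing to 1; default is a binomial-taper over the window.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 3L, weights = NULL) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L || width %% 2L == 0L) {
    stop("window width must be an odd integer >= 1")
  }
  if (is.null(weights)) {
    weights <- if (width == 1L) 1 else {
      w <- choose(width - 1L, 0:(width - 1L))
      w / sum(w)
    }
  }
  weights <- as.numeric(weights)
  if (length(weights) != width) {
    stop("weights must have length ", width)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("window weights must be positive and finite")
  }
  if (max(abs(weights - rev(weights))) > 1e-12) {
    stop("window weights must be symmetric about the center")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("window weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  structure(list(width = width, weights = weights), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("<window_spec> width", x$width, "weights",
      paste(format(x$weights), collapse = " "), "\n")
  invisible(x)
}

# Weighted moving average with truncation at the termini: remaining
# weights are renormalized to sum 1 so every output stays a convex
# combination of the input values.
.windowed_average <- function(v, window) {
  n <- length(v)
  h <- (window$width - 1L) %/% 2L
  if (h == 0L) {
    return(v)
  }
  num <- numeric(n)
  den <- numeric(n)
  for (d in -h:h) {
    w <- window$weights[d + h + 1L]
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w * v[src[ok]]
    den[ok] <- den[ok] + w
  }
  num / den
}

#' Compute a per-residue flexibility profile
#'
#' Assigns each residue its scale value and averages it with its sequence
#' neighbours under `window`, truncating and renormalizing at the termini.
#' Every profile value is therefore a convex combination of scale values
#' and lies within the scale's range.  `X` contributes the unweighted mean
#' of the 20 scale values.
#'
#' @param record A [sequence_record()].
#' @param scale A [flexibility_scale()]; default the packaged scale.
#' @param window A [window_spec()]; default width 3, weights
#'   (0.25, 0.5, 0.25).
#' @return An object of class `flex_profile` with fields `record_id`,
#'   `positions`, `residues`, `nbf`, `scale_provenance`, `window`.
#' @examples
#' p <- flex_profile(sequence_record("toy", "ILTFVLLLNML"))
#' range(p$nbf)
#' @export
flex_profile <- function(record, scale = load_flex_scale(),
                         window = window_spec()) {
  stopifnot(inherits(record, "sequence_record"),
            inherits(scale, "flexibility_scale"),
            inherits(window, "window_spec"))
  chars <- residue_chars(record)
  v <- scale_values_for(scale, chars)
  structure(
    list(record_id = record$id,
         positions = residue_numbers(record),
         residues = chars,
         nbf = .windowed_average(v, window),
         scale_provenance = scale$provenance,
         window = window),
    class = "flex_profile"
  )
}

#' @export
print.flex_profile <- function(x, ...) {
  cat("<flex_profile> ", x$record_id, ": ", length(x$nbf), " residues (",
      min(x$positions), "-", max(x$positions), "), nBf in [",
      format(min(x$nbf), digits = 4), ", ",
      format(max(x$nbf), digits = 4), "]\n  scale: ",
      x$scale_provenance, "\n", sep = "")
  invisible(x)
}

#' Write a flexibility profile table
#'
#' Tab-separated columns `residue_number`, `residue`, `nbf`.
#'
#' @param profile A [flex_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flex_profile <- function(profile, path) {
  stopifnot(inherits(profile, "flex_profile"))
  df <- data.frame(residue_number = profile$positions,
                   residue = profile$residues,
                   nbf = sprintf("%.6f", profile$nbf))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve a start-end residue range against a profile's positions; errors
# name the valid numbered span.
.profile_slice <- function(profile, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (start > end) {
    stop("range ", start, "-", end, " is inverted")
  }
  lo <- min(profile$positions)
  hi <- max(profile$positions)
  if (start < lo || end > hi) {
    stop("range ", start, "-", end, " outside profile '",
         profile$record_id, "' (residues ", lo, "-", hi, ")")
  }
  which(profile$positions >= start & profile$positions <= end)
}

#' Segment mean flexibility (mBf)
#'
#' The arithmetic mean of the profile values over an inclusive residue
#' range: a positive index where larger means a more flexible segment.
#' Two companions are carried along: `relative = 1/mbf`, the form used
#' when flexibilities are plotted as bar heights, and `literal_eq2 =
#' -mbf`, the sign-carrying mean some formulations write; the positive
#' `mbf` is the quantity used in every comparison here.
#'
#' @param profile A [flex_profile()].
#' @param start,end 1-based inclusive residue numbers in the profile's
#'   numbering.
#' @return An object of class `mean_flexibility` with fields `mbf`, `n`,
#'   `relative`, `literal_eq2`.
#' @export
segment_mbf <- function(profile, start, end) {
  stopifnot(inherits(profile, "flex_profile"))
  idx <- .profile_slice(profile, start, end)
  mbf <- mean(profile$nbf[idx])
  structure(
    list(mbf = mbf, n = length(idx), relative = 1 / mbf,
         literal_eq2 = -mbf, start = as.integer(start),
         end = as.integer(end), record_id = profile$record_id),
    class = "mean_flexibility"
  )
}

#' @export
print.mean_flexibility <- function(x, ...) {
  cat("<mean_flexibility> ", x$record_id, " ", x$start, "-", x$end,
      ": mBf = ", format(x$mbf, digits = 4), " (n = ", x$n,
      ", 1/mBf = ", format(x$relative, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Relative flexibility (1/mBf)
#'
#' @param mf A [segment_mbf()] result or a positive scalar mBf.
#' @return The reciprocal mean flexibility.
#' @export
relative_flexibility <- function(mf) {
  mbf <- if (inherits(mf, "mean_flexibility")) mf$mbf else as.numeric(mf)
  if (!is.finite(mbf) || mbf <= 0) {
    stop("relative flexibility requires mbf > 0")
  }
  1 / mbf
}

#' Calibrate a scale against reference mBf anchors
#'
#' Applies one global affine transform (a single gain and offset shared by
#' all 20 residues) to `scale`, chosen by least squares so that the mBf
#' values the transformed scale assigns to the anchor segments match the
#' anchor targets.  Because the transform is global and the gain is kept
#' positive, the residue ordering -- the scale's scientific content --
#' is preserved by construction.  Segment mBf is itself affine in the
#' scale, so the fit reduces to ordinary least squares of the targets on
#' the raw segment mBf values.
#'
#' @param scale A [flexibility_scale()].
#' @param window A [window_spec()] used when evaluating anchor segments.
#' @param anchors A list of anchors, each a list with fields `record` (a
#'   [sequence_record()]), optional `start`/`end` (default: the whole
#'   record), and `target` (the reference mBf).  An empty list returns
#'   `scale` unchanged.
#' @return A calibrated [flexibility_scale()]; provenance records the
#'   fitted gain and offset.  If the anchors cannot identify a gain (all
#'   raw mBf values equal) an offset-only fit is returned with a warning,
#'   likewise if the fitted gain is not positive.
#' @export
calibrate_scale <- function(scale, window = window_spec(), anchors = list()) {
  stopifnot(inherits(scale, "flexibility_scale"),
            inherits(window, "window_spec"), is.list(anchors))
  if (length(anchors) == 0L) {
    return(scale)
  }
  raw <- vapply(anchors, function(a) {
    stopifnot(inherits(a$record, "sequence_record"), is.numeric(a$target))
    p <- flex_profile(a$record, scale, window)
    start <- if (is.null(a$start)) min(p$positions) else a$start
    end <- if (is.null(a$end)) max(p$positions) else a$end
    segment_mbf(p, start, end)$mbf
  }, numeric(1))
  targets <- vapply(anchors, function(a) as.numeric(a$target), numeric(1))
  offset_only <- function(reason) {
    warning("calibration gain not identifiable (", reason,
            "); falling back to offset-only fit")
    c(gain = 1, offset = mean(targets) - mean(raw))
  }
  fit <- if (length(anchors) == 1L || max(raw) - min(raw) < 1e-12) {
    offset_only("anchor mBf values are indistinguishable")
  } else {
    g <- sum((raw - mean(raw)) * (targets - mean(targets))) /
      sum((raw - mean(raw))^2)
    if (g <= 0) {
      offset_only("least-squares gain is non-positive")
    } else {
      c(gain = g, offset = mean(targets) - g * mean(raw))
    }
  }
  values <- fit[["gain"]] * scale$values + fit[["offset"]]
  if (any(values <= 0)) {
    stop("calibration produced non-positive scale values; anchor targets ",
         "are incompatible with a positive flexibility scale")
  }
  flexibility_scale(
    values,
    provenance = sprintf(
      "%s | affine-calibrated on %d anchor(s): gain %.6g, offset %.6g",
      scale$provenance, length(anchors), fit[["gain"]], fit[["offset"]])
  )
}
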