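# Flexibility-versus-disorder discrepancy analysis.
#
# Flexibility (nBf) and disorder (pD) are related but not equivalent
# residue attributes: a disordered stretch can be built from rigid
# side-chains and vice versa.  Aligning the two tracks residue by residue
# and forming the reciprocal quotients nBf/pD and pD/nBf highlights
# positions where the two parameters are markedly disproportional.

#' Pair a flexibility profile with a disorder track
#'
#' Aligns the two tracks residue by residue.  Lengths must agree exactly
#' (no silent truncation) and, where the disorder track carries residue
#' letters, they must match the profile's at every position.  Disorder
#' values are clamped to `[epsilon, 1]` so the reciprocal quotient is
#' defined where a predictor reports pD = 0.
#'
#' @param flex A [flex_profile()].
#' @param dis A [disorder_profile()].
#' @param epsilon Lower clamp for pD; default 0.01, below the reporting
#'   resolution of typical predictors.
#' @return An object of class `paired_profile`.
#' @export
pair_profiles <- function(flex, dis, epsilon = 0.01) {
  stopifnot(inherits(flex, "flex_profile"),
            inherits(dis, "disorder_profile"))
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must lie strictly between 0 and 1")
  }
  n_f <- length(flex$nbf)
  n_d <- length(dis$pd)
  if (n_f != n_d) {
    stop("cannot pair profiles: flexibility track has ", n_f,
         " residues but disorder track has ", n_d)
  }
  if (!is.null(dis$residues)) {
    mism <- which(flex$residues != dis$residues & dis$residues != "X")
    if (length(mism) > 0L) {
      i <- mism[1L]
      stop("residue mismatch at position ", flex$positions[i], ": profile '",
           flex$record_id, "' has ", flex$residues[i],
           " but disorder track has ", dis$residues[i])
    }
  }
  structure(
    list(record_id = flex$record_id, positions = flex$positions,
         residues = flex$residues, nbf = flex$nbf,
         pd_clamped = pmin(pmax(dis$pd, epsilon), 1),
         epsilon = epsilon),
    class = "paired_profile"
  )
}

#' Reciprocal discrepancy quotients
#'
#' The "white" track is nBf/pD (flexibility per unit disorder) and the
#' "black" track its reciprocal pD/nBf; their product is 1 at every
#' residue.  A residue where the two parameters are proportional sits
#' near the bulk of both tracks; disproportional residues stand out in
#' one of them.
#'
#' @param paired A [pair_profiles()] result.
#' @return An object of class `discrepancy_quotients` with fields
#'   `white`, `black`, `epsilon`, plus the positions and residues.
#' @export
discrepancy_quotients <- function(paired) {
  stopifnot(inherits(paired, "paired_profile"))
  if (any(paired$nbf <= 0)) {
    stop("cannot form quotients: non-positive flexibility value at position ",
         paired$positions[which(paired$nbf <= 0)[1L]])
  }
  structure(
    list(record_id = paired$record_id, positions = paired$positions,
         residues = paired$residues, white = paired$nbf / paired$pd_clamped,
         black = paired$pd_clamped / paired$nbf, epsilon = paired$epsilon),
    class = "discrepancy_quotients"
  )
}

#' Dispersion statistics of the discrepancy quotient
#'
#' Sample standard deviation of the raw nBf/pD ("white") track and its
#' standard error of the mean, `sem = sd / sqrt(n)`.  A protein whose two
#' parameters track each other closely has small dispersion; linker- and
#' turret-rich domains disperse widely.
#'
#' @param quotients A [discrepancy_quotients()] result.
#' @return An object of class `dispersion_stats` with fields `sd`, `sem`,
#'   `n`.
#' @export
dispersion_stats <- function(quotients) {
  stopifnot(inherits(quotients, "discrepancy_quotients"))
  n <- length(quotients$white)
  if (n < 2L) {
    stop("dispersion statistics need n >= 2 residues")
  }
  s <- sd(quotients$white)
  structure(list(sd = s, sem = s / sqrt(n), n = n,
                 record_id = quotients$record_id),
            class = "dispersion_stats")
}

#' @export
print.dispersion_stats <- function(x, ...) {
  cat("<dispersion_stats> ", x$record_id, ": sd ", format(x$sd, digits = 4),
      ", sem ", format(x$sem, digits = 4), ", n ", x$n, "\n", sep = "")
  invisible(x)
}

#' Flag residues with remarkable flexibility/disorder discrepancy
#'
#' Works on the log of the white quotient, the only scale on which the
#' two reciprocal quotient tracks are symmetric: a residue is flagged
#' when its log-quotient deviates from the track mean by more than `k`
#' track standard deviations.  Deviations above the mean are
#' `"flexible-but-ordered"` (high nBf relative to pD); below,
#' `"rigid-but-disordered"`.
#'
#' @param quotients A [discrepancy_quotients()] result with >= 3 residues.
#' @param k Positive flagging threshold in SD units; default 2.
#' @return A data frame with one row per flagged residue: `position`,
#'   `residue`, `quotient` (white), `z` (log-scale z-score), `direction`.
#'   Zero rows (with a warning) when the log-quotient track has zero
#'   variance.
#' @export
flag_discrepant <- function(quotients, k = 2) {
  stopifnot(inherits(quotients, "discrepancy_quotients"))
  if (!is.numeric(k) || k <= 0) {
    stop("flagging threshold k must be positive")
  }
  n <- length(quotients$white)
  if (n < 3L) {
    stop("discrepancy flagging needs >= 3 residues")
  }
  lw <- log(quotients$white)
  s <- sd(lw)
  empty <- data.frame(position = integer(0), residue = character(0),
                      quotient = numeric(0), z = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (s == 0) {
    warning("log-quotient track has zero variance; nothing to flag")
    return(empty)
  }
  z <- (lw - mean(lw)) / s
  hit <- which(abs(z) > k)
  if (length(hit) == 0L) {
    return(empty)
  }
  data.frame(
    position = quotients$positions[hit],
    residue = quotients$residues[hit],
    quotient = quotients$white[hit],
    z = z[hit],
    direction = ifelse(z[hit] > 0, "flexible-but-ordered",
                       "rigid-but-disordered"),
    stringsAsFactors = FALSE
  )
}

#' Full per-residue discrepancy table
#'
#' The tabular form written by the pipeline: one row per residue with both
#' tracks, both quotients, the log-scale z-score, and the flag/direction
#' columns.
#'
#' @param paired A [pair_profiles()] result.
#' @param k Flagging threshold, as in [flag_discrepant()].
#' @return A data frame with columns `residue_number`, `residue`, `nbf`,
#'   `pd`, `white`, `black`, `z`, `flag`, `direction`.
#' @export
discrepancy_table <- function(paired, k = 2) {
  stopifnot(inherits(paired, "paired_profile"))
  q <- discrepancy_quotients(paired)
  lw <- log(q$white)
  s <- sd(lw)
  z <- if (length(lw) < 2L || s == 0) rep(0, length(lw)) else
    (lw - mean(lw)) / s
  flag <- s > 0 & abs(z) > k
  data.frame(
    residue_number = q$positions,
    residue = q$residues,
    nbf = paired$nbf,
    pd = paired$pd_clamped,
    white = q$white,
    black = q$black,
    z = z,
    flag = flag,
    direction = ifelse(!flag, "", ifelse(z > 0, "flexible-but-ordered",
                                         "rigid-but-disordered")),
    stringsAsFactors = FALSE
  )
}
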