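# Seeded synthetic-data generation and parameter-recovery experiments.
#
# The generator emulates the statistical structure the discrepancy
# analysis assumes: sequences over the 20-letter alphabet with
# controllable flexibility composition, disorder tracks that follow a
# logistic link on the smoothed flexibility profile plus Gaussian noise
# (so flexible regions tend to be disordered and vice versa), and a small
# number of injected "discrepancy" sites where that link is deliberately
# violated by a stated number of log-quotient standard deviations.

#' Create a synthetic-data configuration
#'
#' @param length Sequence length; must be at least the window width.
#' @param target_mbf Optional target mean flexibility for the whole
#'   sequence (see [generate_sequence()]), or `NULL`.
#' @param pool Optional residue pool instead of a numeric target:
#'   `"stiff"` (bottom scale quartile) or `"flexible"` (top quartile).
#' @param rho Target Pearson correlation between smoothed flexibility and
#'   disorder, in `[-1, 1]`.
#' @param noise_sd Gaussian noise SD on the logistic link scale.
#' @param n_sites Number of injected discrepancy sites.
#' @param effect Injection magnitude, in SD units of the baseline
#'   log-quotient track; `>= 0`.
#' @param seed Integer seed; every generator output is deterministic in
#'   it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(length = 300L, target_mbf = NULL, pool = NULL,
                             rho = 0.8, noise_sd = 0.1, n_sites = 0L,
                             effect = 3, seed = 1L) {
  length <- as.integer(length)
  n_sites <- as.integer(n_sites)
  stopifnot(length >= 1L, is.numeric(rho), rho >= -1, rho <= 1,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(effect), effect >= 0)
  if (n_sites < 0L || n_sites > length) {
    stop("n_sites must lie in [0, length]")
  }
  if (!is.null(pool)) {
    pool <- match.arg(pool, c("stiff", "flexible"))
  }
  structure(
    list(length = length, target_mbf = target_mbf, pool = pool, rho = rho,
         noise_sd = noise_sd, n_sites = n_sites, effect = effect,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> length ", x$length,
      if (!is.null(x$target_mbf)) paste0(", target_mbf ", x$target_mbf),
      if (!is.null(x$pool)) paste0(", pool ", x$pool),
      ", rho ", x$rho, ", noise_sd ", x$noise_sd, ", n_sites ", x$n_sites,
      ", effect ", x$effect, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Bottom/top quartile of the scale, 5 residues each.
.scale_pool <- function(scale, which) {
  ord <- names(sort(scale$values))
  if (which == "stiff") ord[1:5] else rev(ord)[1:5]
}

#' Generate a random protein sequence
#'
#' Residues are drawn uniformly from the 20-letter alphabet (or from the
#' stiff/flexible quartile pool when `config$pool` is set).  When
#' `config$target_mbf` is given, single-residue substitutions are then
#' applied greedily -- always the substitution that most reduces the gap
#' to the target, ties broken by leftmost position -- until no
#' substitution improves it further; the achieved whole-sequence mBf is
#' required to land within 0.05 of the target.  Deterministic for a
#' fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param scale A [flexibility_scale()].
#' @param window A [window_spec()]; `config$length` must be >= its width.
#' @return A [sequence_record()] with the resolved configuration attached
#'   as attribute `"config"`.
#' @export
generate_sequence <- function(config, scale = load_flex_scale(),
                              window = window_spec()) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(scale, "flexibility_scale"))
  if (config$length < window$width) {
    stop("sequence length must be >= window width")
  }
  target <- config$target_mbf
  if (!is.null(target)) {
    if (target < min(scale$values) || target > max(scale$values)) {
      stop("target_mbf ", target, " is outside the scale range [",
           format(min(scale$values)), ", ", format(max(scale$values)), "]")
    }
  }
  alphabet <- if (is.null(config$pool)) AA_CANONICAL else
    .scale_pool(scale, config$pool)
  set.seed(config$seed)
  chars <- sample(alphabet, config$length, replace = TRUE)
  if (!is.null(target)) {
    mbf_of <- function(ch) {
      mean(.windowed_average(scale_values_for(scale, ch), window))
    }
    gap <- abs(mbf_of(chars) - target)
    # each pass evaluates every single-residue substitution and applies
    # the best strict improvement; stops at a local optimum
    repeat {
      best <- list(gap = gap, pos = NA_integer_, aa = NA_character_)
      for (pos in seq_along(chars)) {
        old <- chars[pos]
        for (aa in AA_CANONICAL) {
          if (aa == old) next
          chars[pos] <- aa
          g <- abs(mbf_of(chars) - target)
          if (g < best$gap - 1e-15) {
            best <- list(gap = g, pos = pos, aa = aa)
          }
        }
        chars[pos] <- old
      }
      if (is.na(best$pos)) break
      chars[best$pos] <- best$aa
      gap <- best$gap
      if (gap <= 1e-9) break
    }
    if (gap > 0.05) {
      stop("could not reach target_mbf ", target, " within 0.05 (achieved ",
           "gap ", format(gap), ")")
    }
  }
  rec <- sequence_record(paste0("synthetic-seed", config$seed),
                         paste(chars, collapse = ""),
                         description = "synthetic")
  attr(rec, "config") <- config
  rec
}

#' Generate a synthetic disorder track coupled to a flexibility profile
#'
#' The baseline track is `pd = plogis(a * u + noise)` where `u` is the
#' standardized smoothed flexibility (the profile values) and `a =
#' noise_sd * rho / sqrt(1 - rho^2)`, the gain for which the linearized
#' link attains the target correlation `rho`.  At `n_sites` randomly
#' chosen positions the link is then violated: the disorder value is
#' moved so the log-quotient `log(nbf/pd)` shifts by `effect` baseline
#' SDs in a random direction, and the position and direction are
#' returned as ground truth.  Deterministic for a fixed seed (the track
#' uses `seed + 1` so it is independent of the sequence draw).
#'
#' @param profile A [flex_profile()].
#' @param config A [synthetic_config()].
#' @return A list with elements `profile` (a [disorder_profile()] with
#'   source `"synthetic"`), `truth` (data frame `position`, `direction`),
#'   and `config`.
#' @export
generate_disorder_track <- function(profile, config) {
  stopifnot(inherits(profile, "flex_profile"),
            inherits(config, "synthetic_config"))
  n <- length(profile$nbf)
  if (config$n_sites > n) {
    stop("n_sites exceeds profile length")
  }
  set.seed(config$seed + 1L)
  s <- sd(profile$nbf)
  u <- if (is.na(s) || s == 0) rep(0, n) else
    (profile$nbf - mean(profile$nbf)) / s
  a <- if (abs(config$rho) >= 1 || config$noise_sd == 0) {
    sign(config$rho)  # noiseless link: correlation is 1 in magnitude
  } else {
    config$noise_sd * config$rho / sqrt(1 - config$rho^2)
  }
  link <- a * u + rnorm(n, 0, config$noise_sd)
  pd <- plogis(link)
  q0 <- log(profile$nbf / pmax(pd, 1e-12))
  sdq <- sd(q0)
  truth <- data.frame(position = integer(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (config$n_sites > 0L && config$effect > 0 && sdq > 0) {
    sites <- sort(sample.int(n, config$n_sites))
    up <- sample(c(TRUE, FALSE), config$n_sites, replace = TRUE)
    shift <- ifelse(up, 1, -1) * config$effect * sdq
    q_target <- q0[sites] + shift
    pd[sites] <- pmin(pmax(profile$nbf[sites] * exp(-q_target), 1e-6), 1)
    truth <- data.frame(
      position = profile$positions[sites],
      direction = ifelse(up, "flexible-but-ordered",
                         "rigid-but-disordered"),
      stringsAsFactors = FALSE)
  }
  dis <- disorder_profile(profile$record_id, pd,
                          positions = profile$positions,
                          residues = profile$residues,
                          source = "synthetic")
  list(profile = dis, truth = truth, config = config)
}

#' Discrepancy-site recovery experiment
#'
#' For each of `n_seeds` seeds (offsets of `config$seed`): generate a
#' sequence and a coupled disorder track with injected discrepancy
#' sites, run the pairing / quotient / flagging pipeline with the given
#' clamp and threshold, and score the flagged positions against the
#' injected truth.  Sensitivity is pooled TP / injected, precision is
#' pooled TP / flagged, and the false-positive rate is pooled
#' non-injected flags over non-injected residues (under `n_sites = 0`
#' this is the null flag rate of the procedure).
#'
#' @param config A [synthetic_config()]; its `seed` is the base seed.
#' @param n_seeds Number of independent replicates, >= 1.
#' @param scale,window Scale and window used throughout.
#' @param epsilon pD clamp, as in [pair_profiles()].
#' @param k Flagging threshold, as in [flag_discrepant()].
#' @return An object of class `recovery_report`: list with `sensitivity`,
#'   `precision`, `false_positive_rate`, `per_seed` (data frame with one
#'   row per seed), and the resolved `config`.
#' @export
recovery_experiment <- function(config, n_seeds = 100L,
                                scale = load_flex_scale(),
                                window = window_spec(),
                                epsilon = 0.01, k = 2) {
  stopifnot(inherits(config, "synthetic_config"), n_seeds >= 1L)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 2L
    rec <- generate_sequence(cfg, scale, window)
    prof <- flex_profile(rec, scale, window)
    track <- generate_disorder_track(prof, cfg)
    paired <- pair_profiles(prof, track$profile, epsilon = epsilon)
    flags <- suppressWarnings(
      flag_discrepant(discrepancy_quotients(paired), k = k))
    truth_pos <- track$truth$position
    tp <- sum(flags$position %in% truth_pos)
    fp <- sum(!(flags$position %in% truth_pos))
    rows[[i]] <- data.frame(
      seed = cfg$seed, n = cfg$length, injected = length(truth_pos),
      flagged = nrow(flags), tp = tp, fp = fp,
      fn = length(truth_pos) - tp)
  }
  per_seed <- do.call(rbind, rows)
  total_inj <- sum(per_seed$injected)
  total_flag <- sum(per_seed$flagged)
  total_tp <- sum(per_seed$tp)
  total_fp <- sum(per_seed$fp)
  clean <- sum(per_seed$n) - total_inj
  structure(
    list(sensitivity = if (total_inj > 0) total_tp / total_inj else NA_real_,
         precision = if (total_flag > 0) total_tp / total_flag else NA_real_,
         false_positive_rate = if (clean > 0) total_fp / clean else NA_real_,
         per_seed = per_seed, config = config, n_seeds = n_seeds, k = k,
         epsilon = epsilon),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$n_seeds, " seeds, length ", x$config$length,
      ", n_sites ", x$config$n_sites, ", effect ", x$config$effect,
      ", k ", x$k, "\n  sensitivity ", format(x$sensitivity, digits = 3),
      ", precision ", format(x$precision, digits = 3),
      ", false-positive rate ",
      format(x$false_positive_rate, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to files
#'
#' Writes the generated sequence (FASTA), disorder track (generic
#' dialect), ground-truth injection table and the resolved configuration,
#' the file bundle the `simulate` command produces.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory, created if missing.
#' @param scale,window Scale and window used for the profile.
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_bundle <- function(config, out_dir,
                                   scale = load_flex_scale(),
                                   window = window_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- generate_sequence(config, scale, window)
  prof <- flex_profile(rec, scale, window)
  track <- generate_disorder_track(prof, config)
  paths <- c(
    fasta = file.path(out_dir, "synthetic.fasta"),
    track = file.path(out_dir, "synthetic_disorder.tsv"),
    truth = file.path(out_dir, "synthetic_truth.tsv"),
    config = file.path(out_dir, "synthetic_config.txt"))
  write_fasta(rec, paths[["fasta"]])
  write_disorder_profile(track$profile, paths[["track"]])
  write.table(track$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- config
  writeLines(c(
    paste0("length=", cfg$length),
    paste0("target_mbf=", if (is.null(cfg$target_mbf)) "" else cfg$target_mbf),
    paste0("pool=", if (is.null(cfg$pool)) "" else cfg$pool),
    paste0("rho=", cfg$rho),
    paste0("noise_sd=", cfg$noise_sd),
    paste0("n_sites=", cfg$n_sites),
    paste0("effect=", cfg$effect),
    paste0("seed=", cfg$seed)), paths[["config"]])
  invisible(paths)
}
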