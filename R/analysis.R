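# Helix-class grouping, pi-versus-3_10 comparison, and the end-to-end
# pipeline.
#
# Segments annotated as transitioning to the non-canonical pi or 3-10
# helical forms are grouped by class and their segment mean flexibilities
# compared; in ion-channel transmembrane domains the pi-transiting S6
# regions are expected to be markedly more rigid than the 3-10-transiting
# S4b regions.

#' Group annotated segments by helix class
#'
#' Computes the segment mean flexibility (mBf) of every annotation
#' against its protein's profile and groups the results by helix class.
#'
#' @param profiles A list of [flex_profile()] objects.
#' @param annotations A list of [segment_annotation()] objects; each
#'   `protein_id` must match a profile's `record_id`.
#' @return An object of class `helix_class_groups`: a named list (one
#'   element per class present) of data frames with columns `protein_id`,
#'   `segment_name`, `start`, `end`, `mbf`, `n`.
#' @export
group_segments <- function(profiles, annotations) {
  if (inherits(profiles, "flex_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "flex_profile")))
  ids <- vapply(profiles, `[[`, character(1), "record_id")
  rows <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "segment_annotation"))
    hit <- which(ids == a$protein_id)
    if (length(hit) == 0L) {
      stop("no profile for protein_id '", a$protein_id, "' (segment '",
           a$segment_name, "')")
    }
    mf <- segment_mbf(profiles[[hit[1L]]], a$start, a$end)
    data.frame(protein_id = a$protein_id, segment_name = a$segment_name,
               start = a$start, end = a$end, helix_class = a$helix_class,
               mbf = mf$mbf, n = mf$n, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  groups <- if (is.null(df)) list() else split(df, df$helix_class)
  structure(groups, class = "helix_class_groups")
}

#' @export
print.helix_class_groups <- function(x, ...) {
  cat("<helix_class_groups>\n")
  for (cl in names(x)) {
    cat("  ", cl, ": ", nrow(x[[cl]]), " segment(s), mean mBf ",
        format(mean(x[[cl]]$mbf), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Compare mean flexibility between two helix classes
#'
#' Reports per-class means and sample SDs of segment mBf, the difference
#' of means `mean(class_b) - mean(class_a)`, and a two-sided
#' Wilcoxon rank-sum test as a descriptive helper statistic (segments are
#' not independent draws, so no inferential claim is attached).
#'
#' @param groups A [group_segments()] result.
#' @param class_a,class_b Helix classes to compare; defaults `"pi"` and
#'   `"three10"`, so a positive difference means the 3-10 group is more
#'   flexible.
#' @return An object of class `helix_class_comparison` with fields
#'   `class_a`, `class_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`,
#'   `n_b`, `difference`, `statistic`, `p_value`, `segments`.
#' @export
compare_helix_classes <- function(groups, class_a = "pi",
                                  class_b = "three10") {
  stopifnot(inherits(groups, "helix_class_groups"))
  for (cl in c(class_a, class_b)) {
    if (is.null(groups[[cl]]) || nrow(groups[[cl]]) == 0L) {
      stop("helix class '", cl, "' has no segments")
    }
  }
  a <- groups[[class_a]]$mbf
  b <- groups[[class_b]]$mbf
  wt <- suppressWarnings(wilcox.test(b, a, alternative = "two.sided"))
  structure(
    list(class_a = class_a, class_b = class_b,
         mean_a = mean(a), mean_b = mean(b),
         sd_a = if (length(a) > 1L) sd(a) else NA_real_,
         sd_b = if (length(b) > 1L) sd(b) else NA_real_,
         n_a = length(a), n_b = length(b),
         difference = mean(b) - mean(a),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         segments = rbind(groups[[class_a]], groups[[class_b]])),
    class = "helix_class_comparison"
  )
}

#' @export
print.helix_class_comparison <- function(x, ...) {
  cat("<helix_class_comparison> ", x$class_b, " - ", x$class_a, "\n",
      "  mBf ", x$class_a, ": ", format(x$mean_a, digits = 4), " (sd ",
      format(x$sd_a, digits = 3), ", n ", x$n_a, ")\n",
      "  mBf ", x$class_b, ": ", format(x$mean_b, digits = 4), " (sd ",
      format(x$sd_b, digits = 3), ", n ", x$n_b, ")\n",
      "  difference: ", format(x$difference, digits = 4),
      "; rank-sum W = ", format(x$statistic),
      ", two-sided p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Resolve pipeline configuration
#'
#' Fills defaults for the decision parameters of [run_full_analysis()]:
#' `scale` (packaged scale name or file), `window_width`,
#' `window_weights` (comma-separated string or numeric vector), `epsilon`
#' (pD clamp), `k` (flagging threshold), `threshold` (binary disorder
#' cutoff), `class_a`, `class_b` (helix classes compared).
#'
#' @param config A named list overriding any of the defaults.
#' @return A named list with every parameter resolved.
#' @export
resolve_config <- function(config = list()) {
  defaults <- list(scale = "vihinen1994", window_width = 3L,
                   window_weights = NULL, epsilon = 0.01, k = 2,
                   threshold = 0.5, class_a = "pi", class_b = "three10")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.character(cfg$window_weights)) {
    cfg$window_weights <- as.numeric(strsplit(cfg$window_weights, ",")[[1]])
  }
  cfg
}

.write_config <- function(cfg, window, scale, path) {
  lines <- c(
    paste0("scale=", cfg$scale),
    paste0("scale_provenance=", scale$provenance),
    paste0("window_width=", window$width),
    paste0("window_weights=", paste(format(window$weights), collapse = ",")),
    paste0("epsilon=", format(cfg$epsilon)),
    paste0("k=", format(cfg$k)),
    paste0("threshold=", format(cfg$threshold)),
    paste0("class_a=", cfg$class_a),
    paste0("class_b=", cfg$class_b)
  )
  writeLines(lines, path)
}

#' Run the full flexibility/disorder analysis pipeline
#'
#' Reads sequences and segment annotations, computes a flexibility
#' profile per protein, pairs each profile with its disorder track where
#' one is supplied (the discrepancy stage is skipped, with a logged
#' notice, for proteins without a track), groups segments by helix class
#' and compares two classes when both are present.  All decision
#' parameters (scale provenance, window, epsilon, k, threshold) are
#' logged and written next to the outputs, and the run is deterministic:
#' identical inputs and config give byte-identical outputs.
#'
#' @param fasta Path to a FASTA file of protein sequences.
#' @param segments Path to a segment-annotation table
#'   (see [read_segment_table()]), or `NULL` to skip segment analysis.
#' @param disorder_tracks Optional named character vector of per-protein
#'   disorder-track paths (generic dialect), names matching record ids.
#' @param config Named list of overrides, see [resolve_config()].
#' @param out_dir Output directory, created if missing.
#' @param quiet Suppress progress messages (they go to `stderr`).
#' @return Invisibly, a list with elements `profiles`, `discrepancy`
#'   (per-protein tables), `dispersion` (data frame), `groups`,
#'   `comparison` (or `NULL`), `config`, `files`.
#' @export
run_full_analysis <- function(fasta, segments = NULL, disorder_tracks = NULL,
                              config = list(), out_dir = "seqflex-out",
                              quiet = FALSE) {
  note <- function(...) if (!quiet) message("seqflex: ", ...)
  cfg <- resolve_config(config)
  window <- window_spec(cfg$window_width, cfg$window_weights)
  scale <- load_flex_scale(cfg$scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note("scale: ", scale$provenance)
  note("window width ", window$width, ", weights ",
       paste(format(window$weights), collapse = " "),
       "; epsilon ", cfg$epsilon, "; k ", cfg$k,
       "; threshold ", cfg$threshold)

  records <- read_fasta(fasta)
  if (length(records) == 0L) {
    stop("pipeline stage seq_io: no sequences in '", fasta, "'")
  }
  note(length(records), " sequence(s) read from ", fasta)

  files <- character(0)
  profiles <- list()
  disc_tables <- list()
  disp_rows <- list()
  for (rec in records) {
    prof <- tryCatch(flex_profile(rec, scale, window), error = function(e)
      stop("pipeline stage flexprofile ('", rec$id, "'): ",
           conditionMessage(e)))
    profiles[[rec$id]] <- prof
    f <- file.path(out_dir, paste0(rec$id, "_profile.tsv"))
    write_flex_profile(prof, f)
    files <- c(files, f)

    track_path <- if (rec$id %in% names(disorder_tracks))
      disorder_tracks[[rec$id]] else NULL
    if (is.null(track_path) || is.na(track_path)) {
      note("no disorder track for '", rec$id,
           "'; discrepancy stage skipped")
      next
    }
    dis <- tryCatch(
      read_disorder_profile(track_path, "generic", record_id = rec$id,
                            threshold = cfg$threshold),
      error = function(e) stop("pipeline stage disorder ('", rec$id, "'): ",
                               conditionMessage(e)))
    paired <- tryCatch(pair_profiles(prof, dis, epsilon = cfg$epsilon),
                       error = function(e)
                         stop("pipeline stage discrepancy ('", rec$id,
                              "'): ", conditionMessage(e)))
    tab <- discrepancy_table(paired, k = cfg$k)
    disc_tables[[rec$id]] <- tab
    f <- file.path(out_dir, paste0(rec$id, "_discrepancy.tsv"))
    num <- vapply(tab, is.numeric, logical(1)) &
      !names(tab) %in% c("residue_number")
    out <- tab
    out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    ds <- dispersion_stats(discrepancy_quotients(paired))
    disp_rows[[rec$id]] <- data.frame(protein_id = rec$id,
                                      sd = ds$sd, sem = ds$sem, n = ds$n,
                                      stringsAsFactors = FALSE)
  }

  dispersion <- do.call(rbind, disp_rows)
  if (!is.null(dispersion)) {
    f <- file.path(out_dir, "dispersion_summary.tsv")
    out <- dispersion
    out$sd <- sprintf("%.6f", out$sd)
    out$sem <- sprintf("%.6f", out$sem)
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  groups <- NULL
  comparison <- NULL
  if (!is.null(segments)) {
    anns <- tryCatch(read_segment_table(segments), error = function(e)
      stop("pipeline stage seq_io (segments): ", conditionMessage(e)))
    groups <- group_segments(unname(profiles), anns)
    f <- file.path(out_dir, "segment_mbf.tsv")
    seg_df <- do.call(rbind, unname(lapply(groups, identity)))
    if (!is.null(seg_df)) {
      seg_df$mbf <- sprintf("%.6f", seg_df$mbf)
      write.table(seg_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    have_both <- !is.null(groups[[cfg$class_a]]) &&
      !is.null(groups[[cfg$class_b]])
    if (have_both) {
      comparison <- compare_helix_classes(groups, cfg$class_a, cfg$class_b)
      f <- file.path(out_dir, "helix_class_comparison.tsv")
      cmp_df <- data.frame(
        class_a = comparison$class_a, class_b = comparison$class_b,
        mean_a = sprintf("%.6f", comparison$mean_a),
        mean_b = sprintf("%.6f", comparison$mean_b),
        difference = sprintf("%.6f", comparison$difference),
        statistic = comparison$statistic,
        p_value = sprintf("%.6g", comparison$p_value))
      write.table(cmp_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      note("helix-class comparison ", cfg$class_b, " - ", cfg$class_a,
           ": difference ", format(comparison$difference, digits = 4))
    } else {
      note("helix classes '", cfg$class_a, "' and '", cfg$class_b,
           "' not both present; comparison skipped")
    }
  }

  f <- file.path(out_dir, "config.txt")
  .write_config(cfg, window, scale, f)
  files <- c(files, f)
  invisible(list(profiles = profiles, discrepancy = disc_tables,
                 dispersion = dispersion, groups = groups,
                 comparison = comparison, config = cfg, files = files))
}

#' All pairwise helix-class comparisons
#'
#' Runs [compare_helix_classes()] for every unordered pair of classes
#' present in `groups` and applies a Benjamini-Hochberg correction to the
#' rank-sum p-values, since more than one comparison is made.
#'
#' @param groups A [group_segments()] result with >= 2 classes.
#' @return A data frame with one row per pair: `class_a`, `class_b`,
#'   `mean_a`, `mean_b`, `difference`, `p_value`, `p_adjusted`.
#' @export
compare_all_helix_classes <- function(groups) {
  stopifnot(inherits(groups, "helix_class_groups"))
  classes <- names(groups)
  if (length(classes) < 2L) {
    stop("need at least two helix classes for pairwise comparisons")
  }
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    cmp <- compare_helix_classes(groups, p[1L], p[2L])
    data.frame(class_a = p[1L], class_b = p[2L], mean_a = cmp$mean_a,
               mean_b = cmp$mean_b, difference = cmp$difference,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$p_adjusted <- p.adjust(df$p_value, method = "BH")
  df
}
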