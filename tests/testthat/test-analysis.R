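test_that("segments group by helix class with per-segment mBf", {
  sc <- load_flex_scale()
  recs <- lapply(1:4, function(i) random_record(50, seed = 7000 + i,
                                                id = paste0("p", i)))
  profs <- lapply(recs, flex_profile, scale = sc)
  anns <- c(
    lapply(1:6, function(i) segment_annotation(
      paste0("p", 1 + (i %% 4)), paste0("pi", i), 5 + i, 20 + i, "pi")),
    lapply(1:4, function(i) segment_annotation(
      paste0("p", 1 + (i %% 4)), paste0("s4-", i), 25, 40, "three10"))
  )
  g <- group_segments(profs, anns)
  expect_named(g, c("pi", "three10"), ignore.order = TRUE)
  expect_equal(nrow(g$pi), 6)
  expect_equal(nrow(g$three10), 4)
  expect_true(all(g$pi$helix_class == "pi"))

  # recomputation oracle: group mbf equals segment_mbf per segment
  for (cl in names(g)) {
    for (r in seq_len(nrow(g[[cl]]))) {
      row <- g[[cl]][r, ]
      prof <- profs[[match(row$protein_id, sapply(recs, `[[`, "id"))]]
      expect_equal(row$mbf, segment_mbf(prof, row$start, row$end)$mbf)
    }
  }

  expect_length(group_segments(profs, list()), 0)
  expect_error(group_segments(profs, list(segment_annotation(
    "absent", "s", 1, 5, "pi"))), "no profile for protein_id 'absent'")
})

test_that("class comparison reports an exact difference of means", {
  profs <- lapply(1:2, function(i) flex_profile(
    random_record(40, seed = 7100 + i, id = paste0("q", i))))
  anns <- list(
    segment_annotation("q1", "a1", 1, 10, "pi"),
    segment_annotation("q1", "a2", 11, 20, "pi"),
    segment_annotation("q2", "b1", 1, 10, "three10"),
    segment_annotation("q2", "b2", 11, 20, "three10"))
  g <- group_segments(profs, anns)
  cmp <- compare_helix_classes(g, "pi", "three10")
  expect_equal(cmp$difference,
               mean(g$three10$mbf) - mean(g$pi$mbf))

  # identical groups give difference zero
  anns_same <- list(
    segment_annotation("q1", "a1", 1, 10, "pi"),
    segment_annotation("q1", "b1", 1, 10, "three10"))
  cmp0 <- compare_helix_classes(group_segments(profs[1], anns_same))
  expect_equal(cmp0$difference, 0)

  expect_error(compare_helix_classes(g, "pi", "loop"), "'loop' has no")
})

test_that("stiff-pool vs flexible-pool segments recover the expected sign", {
  sc <- load_flex_scale()
  win <- window_spec()
  hits <- 0
  for (s in 1:100) {
    stiff <- generate_sequence(synthetic_config(length = 12, pool = "stiff",
                                                seed = 8000 + s), sc, win)
    flexi <- generate_sequence(synthetic_config(length = 12,
                                                pool = "flexible",
                                                seed = 9000 + s), sc, win)
    m_pi <- segment_mbf(flex_profile(stiff, sc, win), 1, 12)$mbf
    m_310 <- segment_mbf(flex_profile(flexi, sc, win), 1, 12)$mbf
    hits <- hits + (m_310 > m_pi)
  }
  expect_gte(hits, 95)
})

test_that("all-pairwise comparisons carry a BH correction", {
  profs <- list(flex_profile(random_record(60, seed = 7500, id = "r1")))
  anns <- list(
    segment_annotation("r1", "a", 1, 10, "pi"),
    segment_annotation("r1", "b", 11, 20, "pi"),
    segment_annotation("r1", "c", 21, 30, "three10"),
    segment_annotation("r1", "d", 31, 40, "three10"),
    segment_annotation("r1", "e", 41, 50, "loop"),
    segment_annotation("r1", "f", 51, 60, "loop"))
  df <- compare_all_helix_classes(group_segments(profs, anns))
  expect_equal(nrow(df), 3)
  expect_equal(df$p_adjusted, p.adjust(df$p_value, "BH"))
})

test_that("the pipeline bundle is deterministic and composable", {
  dir <- withr::local_tempdir()
  inp <- toy_inputs(dir)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  b1 <- suppressMessages(run_full_analysis(
    inp$fasta, inp$segs, inp$tracks, out_dir = out1))
  b2 <- suppressMessages(run_full_analysis(
    inp$fasta, inp$segs, inp$tracks, out_dir = out2))

  # byte-identical outputs across two runs
  f1 <- sort(list.files(out1, full.names = TRUE))
  f2 <- sort(list.files(out2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  expect_true(file.exists(file.path(out1, "config.txt")))

  # composition: bundle numbers equal the single operations
  recs <- read_fasta(inp$fasta)
  profA <- flex_profile(recs[[1]])
  expect_equal(b1$profiles$toyA$nbf, profA$nbf)
  paired <- pair_profiles(profA, read_disorder_profile(
    inp$tracks[["toyA"]], "generic", record_id = "toyA"))
  ds <- dispersion_stats(discrepancy_quotients(paired))
  expect_equal(b1$dispersion$sd[b1$dispersion$protein_id == "toyA"], ds$sd)
  expect_equal(b1$dispersion$sem[b1$dispersion$protein_id == "toyA"], ds$sem)
  cmp <- compare_helix_classes(group_segments(
    lapply(recs, flex_profile), read_segment_table(inp$segs)))
  expect_equal(b1$comparison$difference, cmp$difference)
})

test_that("the pipeline degrades gracefully without disorder tracks", {
  dir <- withr::local_tempdir()
  inp <- toy_inputs(dir)
  msgs <- capture.output(
    b <- run_full_analysis(inp$fasta, inp$segs, disorder_tracks = NULL,
                           out_dir = file.path(dir, "deg")),
    type = "message")
  expect_true(any(grepl("discrepancy stage skipped", msgs)))
  expect_length(b$discrepancy, 0)
  expect_null(b$dispersion)
  expect_s3_class(b$comparison, "helix_class_comparison")

  # a protein with no track is skipped, others still analysed
  b2 <- suppressMessages(run_full_analysis(
    inp$fasta, inp$segs, inp$tracks[1], out_dir = file.path(dir, "one")))
  expect_named(b2$discrepancy, "toyA")
})

test_that("pipeline errors carry the failing stage name", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.fasta")
  writeLines("garbage", bad)
  expect_error(suppressMessages(run_full_analysis(bad, NULL)), "stage|FASTA")
  expect_error(resolve_config(list(nope = 1)), "unknown config key")
})
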