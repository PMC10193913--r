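# Shared fixtures built in code.

# Complete 20-residue toy scale with a few hand-set values for worked
# examples (G = 3, A = 1, V = 2; everything else 1.5).
toy_scale <- function() {
  v <- setNames(rep(1.5, 20), seqflex:::AA_CANONICAL)
  v["G"] <- 3.0
  v["A"] <- 1.0
  v["V"] <- 2.0
  flexibility_scale(v, provenance = "toy")
}

random_record <- function(n, seed, id = paste0("rnd", seed)) {
  set.seed(seed)
  sequence_record(id, paste(sample(seqflex:::AA_CANONICAL, n,
                                   replace = TRUE), collapse = ""))
}

# Independent brute-force windowed average: explicit double loop over
# positions and window offsets with terminal renormalization.
brute_force_profile <- function(record, scale, window) {
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  vals <- vapply(chars, function(ch) {
    if (ch == "X") mean(scale$values) else unname(scale$values[ch])
  }, numeric(1))
  n <- length(vals)
  h <- (window$width - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (d in -h:h) {
      j <- i + d
      if (j >= 1L && j <= n) {
        w <- window$weights[d + h + 1L]
        num <- num + w * vals[j]
        den <- den + w
      }
    }
    out[i] <- num / den
  }
  out
}

write_generic_track <- function(path, positions, residues, pd) {
  df <- data.frame(residue_number = positions, residue = residues, pd = pd)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_inputs <- function(dir) {
  fasta <- seqflex_example("toy/toy_proteins.fasta")
  segs <- seqflex_example("toy/toy_segments.tsv")
  # deterministic synthetic disorder tracks for two of the three proteins
  recs <- read_fasta(fasta)
  tracks <- c(
    toyA = file.path(dir, "toyA_dis.tsv"),
    toyB = file.path(dir, "toyB_dis.tsv"))
  write_disorder_profile(naive_disorder_score(recs[[1]]), tracks[["toyA"]])
  write_disorder_profile(naive_disorder_score(recs[[2]]), tracks[["toyB"]])
  list(fasta = fasta, segs = segs, tracks = tracks)
}

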