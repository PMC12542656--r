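# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive re-implementations kept separate from the package
# code paths they check.

# exhaustive affine-gap Smith-Waterman score (gap of length g costs
# go + g*ge, matching the package's stated convention)
sw_oracle_score <- function(q, s, mat, go = 11, ge = 1) {
  m <- nchar(q); n <- nchar(s)
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(-1e9, m + 1, n + 1)
  Y <- matrix(-1e9, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      sc <- mat[qv[i - 1], sv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      if (M[i, j] < 0) M[i, j] <- 0
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# brute-force N50/L50/N90/L90 straight from the definition
nl_oracle <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  cum <- 0
  for (i in seq_along(s)) {
    cum <- cum + s[i]
    if (cum >= frac * tot) return(c(N = s[i], L = i))
  }
}

# distinct canonical k-mer count by brute force
distinct_canonical_oracle <- function(seqs, k) {
  km <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }))
  km <- km[!grepl("N", km)]
  rc <- vapply(km, function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1))
  length(unique(pmin(km, rc)))
}

# reads drawn uniformly from a genome, optional substitution errors;
# tiling guarantees the stated coverage precondition over every base
# (purely random positions leave occasional zero-coverage bases)
sim_genome_reads <- function(genome, coverage, read_len = 150,
                             error_rate = 0, tile = FALSE) {
  n <- ceiling(coverage * nchar(genome) / read_len)
  pos <- sample(nchar(genome) - read_len + 1L, n, replace = TRUE)
  if (tile) {
    tiles <- unique(c(seq(1L, nchar(genome) - read_len + 1L,
                          by = read_len %/% 2L),
                      nchar(genome) - read_len + 1L))
    pos <- c(tiles, pos[seq_len(max(0L, n - length(tiles)))])
  }
  reads <- substring(genome, pos, pos + read_len - 1L)
  flip <- runif(n) < 0.5
  reads[flip] <- revcomp(reads[flip])
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      v <- strsplit(r, "")[[1]]
      hit <- which(runif(length(v)) < error_rate)
      for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      paste(v, collapse = "")
    }, character(1))
  }
  unname(reads)
}

as_read_set <- function(seqs, sample_id = "s1", prefix = "r") {
  data.frame(id = sprintf("%s%05d", prefix, seq_along(seqs)),
             sample_id = sample_id, sequence = seqs, mate = "unpaired",
             quality = strrep("I", nchar(seqs)))
}

operon_span_of <- function(genomes, gid) {
  f <- genomes$features[genomes$features$genome_id == gid &
                          genomes$features$in_operon, , drop = FALSE]
  list(seq = substr(genomes$genomes$sequence[genomes$genomes$id == gid],
                    min(f$start) + 1L, max(f$end)),
       families = f$family)
}

is_substring_either <- function(needle, haystacks) {
  any(grepl(needle, haystacks, fixed = TRUE) |
        grepl(revcomp(needle), haystacks, fixed = TRUE))
}

# lazily built shared fixtures (heavy objects computed once per run)
.fx <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_cfg <- function() fixture("cfg", function() synth_config(seed = 101L))
fx_panel <- function() fixture("panel", function() {
  make_reference_panel(fx_cfg())
})
fx_genomes <- function() fixture("genomes", function() {
  plant_genomes(fx_panel(), fx_cfg())
})
fx_sim <- function() fixture("sim", function() {
  simulate_metagenome(synth_config(seed = 77L, n_genomes = 3L,
                                   coverage_per_sample = 1,
                                   background_fraction = 0.2,
                                   radii = c(5, 20, 100), n_per_ring = 2L))
})

# the 20 seeded noisy assemblies shared by the reconstruction and operon
# acceptance checks: 20x coverage, 0.5% substitution error
fx_noisy_assemblies <- function() fixture("noisy20", function() {
  panel <- fx_panel()
  genomes <- fx_genomes()
  out <- vector("list", 20L)
  for (r in seq_len(20L)) {
    set.seed(9000L + r)
    gid <- genomes$genomes$id[(r - 1L) %% nrow(genomes$genomes) + 1L]
    gen <- genomes$genomes$sequence[genomes$genomes$id == gid]
    reads <- sim_genome_reads(gen, coverage = 20, error_rate = 0.005)
    contigs <- assemble_multi_k(reads, assembly_config())
    out[[r]] <- list(gid = gid, genome = gen, reads = reads,
                     span = operon_span_of(genomes, gid), contigs = contigs)
  }
  out
})
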