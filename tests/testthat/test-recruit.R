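test_that("six-frame translation follows the genetic code and ambiguity rules", {
  fr <- translate_six_frames("ATGAAA")
  expect_identical(fr[["+1"]], "MK")
  expect_identical(translate_six_frames("TTTCAT")[["-1"]], "MK")
  expect_identical(translate_six_frames("ATGNAA")[["+1"]], "MX")
  expect_identical(translate_six_frames("TAA")[["+1"]], "*")
  # trailing partial codons are dropped
  expect_identical(translate_six_frames("ATGAAAC")[["+1"]], "MK")
  expect_identical(nchar(translate_six_frames("AC")[["+1"]]), 0L)
})

test_that("Karlin-Altschul statistics follow the closed form", {
  ka0 <- evalue_ka(0, 50, 1e5)
  expect_equal(ka0$evalue, 50 * 1e5 * 0.041, tolerance = 1e-9)
  k1 <- evalue_ka(40, 50, 1e5)
  k2 <- evalue_ka(40, 50, 2e5)
  expect_equal(k2$evalue / k1$evalue, 2, tolerance = 1e-12)
  # independent re-computation of the closed form
  S <- 100; m <- 50; n <- 1e5
  bits <- (0.267 * S - log(0.041)) / log(2)
  ref <- m * n * 2^(-bits)
  got <- evalue_ka(S, m, n)
  expect_equal(got$bitscore, bits, tolerance = 1e-12)
  expect_equal(got$evalue, ref, tolerance = 1e-12)
  expect_gt(evalue_ka(50, 50, 1e5)$evalue, evalue_ka(60, 50, 1e5)$evalue)
})

test_that("seeded alignment equals the exhaustive Smith-Waterman oracle", {
  sc <- genetarget:::.aa_scoring()
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(42)
  reported <- 0L
  for (i in 1:40) {
    q <- paste(sample(aas, sample(30:60, 1), replace = TRUE), collapse = "")
    if (runif(1) < 0.6) {
      v <- strsplit(q, "")[[1]]
      hit <- sample(length(v), round(length(v) * 0.3))
      for (x in hit) v[x] <- sample(aas, 1)
      s <- paste(v, collapse = "")
    } else {
      s <- paste(sample(aas, sample(30:60, 1), replace = TRUE), collapse = "")
    }
    a <- seed_and_extend(q, s)
    if (!is.null(a)) {
      reported <- reported + 1L
      expect_equal(a$score, sw_oracle_score(q, s, sc$mat))
      expect_equal(a$identity, a$matches / a$aln_len)
    }
  }
  expect_gt(reported, 10L)
  # identical sequences: full-length identity 1, diagonal BLOSUM score
  q <- paste(sample(aas, 50, replace = TRUE), collapse = "")
  a <- seed_and_extend(q, q)
  expect_equal(a$identity, 1)
  expect_equal(a$aln_len, 50L)
  expect_equal(a$score, sum(diag(sc$mat)[match(strsplit(q, "")[[1]],
                                               rownames(sc$mat))]))
  # reversing the query destroys the seeds
  qr <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
  expect_null(seed_and_extend(qr, q))
})

test_that("recruitment is a best-hit rule with deterministic tie-breaks", {
  panel <- fx_panel()
  g <- fx_genomes()
  f <- g$features[g$features$in_operon, ][1, ]
  gen <- g$genomes$sequence[g$genomes$id == f$genome_id]
  read <- substr(gen, f$start + 31L, f$start + 180L)
  rs <- as_read_set(c(read, revcomp(read)))
  rr <- recruit_reads(rs, panel, mode = "relaxed")
  expect_equal(nrow(rr$reads), 2L)
  h <- rr$hits
  expect_equal(h$identity, c(1, 1))
  expect_identical(h$subject_id, rep(f$panel_id, 2))
  # frame signs flip with the read orientation
  expect_true(xor(startsWith(h$frame[1], "-"), startsWith(h$frame[2], "-")))
  # reruns give identical hit tables
  rr2 <- recruit_reads(rs, panel, mode = "relaxed")
  expect_identical(rr$all_hits, rr2$all_hits)
  expect_error(recruit_reads(rs, panel[0, ], mode = "relaxed"), "empty")
})

test_that("random reads are rejected at the stringent threshold", {
  panel <- fx_panel()
  set.seed(7)
  bg <- as_read_set(random_dna(300, 150), prefix = "bg")
  rr <- recruit_reads(bg, panel, mode = "stringent")
  expect_equal(nrow(rr$reads), 0L)
})

test_that("disabling seeds can only add recruited reads, never remove", {
  panel <- fx_panel()[1:8, ]
  class(panel) <- c("ref_panel", "data.frame")
  g <- fx_genomes()
  f <- g$features[g$features$in_operon, ][2, ]
  gen <- g$genomes$sequence[g$genomes$id == f$genome_id]
  set.seed(11)
  pos <- sample(seq(f$start + 1L, f$end - 150L), 10)
  reads <- as_read_set(substring(gen, pos, pos + 149L))
  seeded <- recruit_reads(reads, panel, mode = "relaxed")
  exhaustive <- recruit_reads(reads, panel, mode = "relaxed", seeded = FALSE)
  expect_true(all(seeded$reads$id %in% exhaustive$reads$id))
})

test_that("mate rescue recruits the partner of a recruited read only when enabled", {
  panel <- fx_panel()
  g <- fx_genomes()
  f <- g$features[g$features$in_operon, ][1, ]
  gen <- g$genomes$sequence[g$genomes$id == f$genome_id]
  inside <- substr(gen, f$start + 11L, f$start + 160L)
  set.seed(27)
  rs <- data.frame(id = c("p/1", "p/2"), sample_id = "s1",
                   sequence = c(inside, random_dna(1, 150)),
                   mate = c("1", "2"),
                   quality = strrep("I", 150))
  plain <- recruit_reads(rs, panel, mode = "relaxed")
  expect_true("p/1" %in% plain$reads$id)
  expect_false("p/2" %in% plain$reads$id)
  rescued <- recruit_reads(rs, panel, mode = "relaxed", mate_rescue = TRUE)
  expect_setequal(rescued$reads$id, c("p/1", "p/2"))
})

test_that("paired reads merge by overlap with quality-aware mismatch calls", {
  set.seed(3)
  frag <- random_dna(1, 150)
  r1 <- substr(frag, 1, 100)
  r2 <- revcomp(substr(frag, 51, 150))
  rs <- data.frame(id = c("p/1", "p/2"), sample_id = "s1",
                   sequence = c(r1, r2), mate = c("1", "2"),
                   quality = c(strrep("I", 100), strrep("I", 100)))
  m <- merge_pairs(rs)
  expect_equal(nrow(m), 1L)
  expect_identical(m$sequence, frag)
  # non-overlapping mates pass through unchanged
  rs2 <- data.frame(id = c("q/1", "q/2"), sample_id = "s1",
                    sequence = c(random_dna(1, 80), random_dna(1, 80)),
                    mate = c("1", "2"),
                    quality = c(strrep("I", 80), strrep("I", 80)))
  m2 <- merge_pairs(rs2)
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$sequence, rs2$sequence)
  # a single overlap mismatch resolves toward the higher quality base
  r1m <- r1
  substr(r1m, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r1, 60, 60))[1]
  q1 <- strrep("#", 100) # low quality on read 1
  rs3 <- data.frame(id = c("z/1", "z/2"), sample_id = "s1",
                    sequence = c(r1m, r2), mate = c("1", "2"),
                    quality = c(q1, strrep("I", 100)))
  m3 <- merge_pairs(rs3)
  expect_equal(nrow(m3), 1L)
  expect_identical(m3$sequence, frag) # read 2's base wins
})
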