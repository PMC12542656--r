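test_that("contiguity statistics match the definition on worked examples", {
  s <- assembly_stats(c(80, 70, 50, 30, 20))
  expect_equal(s$N50, 70L); expect_equal(s$L50, 2L)
  expect_equal(s$N90, 30L); expect_equal(s$L90, 4L)
  s2 <- assembly_stats(c(50, 50, 50, 50))
  expect_equal(s2$N50, 50L); expect_equal(s2$L50, 2L)
  expect_equal(s2$N90, 50L); expect_equal(s2$L90, 4L)
  s3 <- assembly_stats(100)
  expect_equal(unlist(s3[c("N50", "L50", "N90", "L90")]),
               c(N50 = 100L, L50 = 1L, N90 = 100L, L90 = 1L))
  expect_equal(assembly_stats(integer(0))$n_contigs, 0L)
  expect_error(assembly_stats(c(10, 0)), "positive")
})

test_that("contiguity statistics equal brute-force enumeration on random sets", {
  set.seed(41)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    s <- assembly_stats(lens)
    o50 <- nl_oracle(lens, 0.5); o90 <- nl_oracle(lens, 0.9)
    expect_equal(c(s$N50, s$L50, s$N90, s$L90),
                 unname(c(o50["N"], o50["L"], o90["N"], o90["L"])))
    expect_lte(s$N90, s$N50)
    expect_lte(s$L50, s$L90)
  }
})

test_that("Bray-Curtis matches hand arithmetic and the vegan implementation", {
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), 4 / 6)
  expect_equal(bray_curtis(c(2, 1, 0), c(2, 1, 0)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
  skip_if_not_installed("vegan")
  set.seed(43)
  m <- matrix(rpois(60, 5), nrow = 6)
  ours <- outer(1:6, 1:6, Vectorize(function(i, j) {
    bray_curtis(m[i, ], m[j, ])
  }))
  theirs <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("Bray-Curtis is symmetric, bounded and zero only at equality", {
  set.seed(44)
  for (i in 1:50) {
    x <- rpois(10, 3); y <- rpois(10, 3)
    if (sum(x) + sum(y) == 0) next
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
    if (d == 0) expect_identical(x, y)
  }
})

test_that("read mapping assigns by shared k-mers with the tie rule", {
  panel <- fx_panel()
  reps <- setNames(panel$nt[panel$family %in% c("amoA", "amoB")][1:4],
                   panel$id[panel$family %in% c("amoA", "amoB")][1:4])
  set.seed(45)
  pos <- sample(nchar(reps[1]) - 150, 5)
  reads <- as_read_set(substring(reps[1], pos, pos + 149))
  mp <- map_reads(reads, reps)
  expect_equal(unname(mp$matrix[1, names(reps)[1]]), 5L)
  expect_equal(sum(mp$matrix), 5L)
  # no shared k-mer leaves a read unmapped
  mp0 <- map_reads(as_read_set(random_dna(1, 100), prefix = "u"), reps)
  expect_equal(sum(mp0$matrix), 0L)
  expect_equal(mp0$n_unmapped, 1L)
  # a read equidistant between duplicate representatives is dropped
  dup_reps <- c(a = unname(reps[1]), b = unname(reps[1]))
  mp2 <- map_reads(as_read_set(substr(reps[1], 10, 160)), dup_reps)
  expect_equal(sum(mp2$matrix), 0L)
  expect_equal(mp2$n_ambiguous, 1L)
})

test_that("planted abundances are recovered through mapping", {
  panel <- fx_panel()
  reps <- setNames(panel$nt[panel$family == "amoA"][1:4],
                   panel$id[panel$family == "amoA"][1:4])
  truth <- c(40, 20, 10, 5)
  set.seed(46)
  reads <- do.call(rbind, lapply(1:4, function(i) {
    pos <- sample(nchar(reps[i]) - 120, truth[i], replace = TRUE)
    as_read_set(substring(reps[i], pos, pos + 119),
                prefix = sprintf("v%d_", i))
  }))
  mp <- map_reads(reads, reps)
  got <- mp$matrix[1, names(reps)]
  expect_gte(cor(got, truth), 0.99)
  expect_equal(sum(mp$matrix) + mp$n_ambiguous + mp$n_unmapped, sum(truth))
})

test_that("DDR recovers an exactly linear similarity decay with r2 = 1", {
  des <- ring_design()
  D <- as.matrix(dist(des[, c("x", "y")]))
  S <- 0.8 - 0.045 * log10(pmax(D, 1))
  diag(S) <- 1
  dimnames(S) <- list(des$sample_id, des$sample_id)
  fit <- fit_ddr(NULL, des, similarity = S)
  expect_equal(fit$slope, -0.045, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # constant similarity gives slope 0
  S0 <- matrix(0.5, nrow(des), nrow(des),
               dimnames = list(des$sample_id, des$sample_id))
  expect_equal(fit_ddr(NULL, des, similarity = S0)$slope, 0,
               tolerance = 1e-12)
  # too few usable pairs is an error
  des2 <- des[1:2, ]
  S2 <- S[1:2, 1:2]
  expect_error(fit_ddr(NULL, des2, similarity = S2), "3 sample pairs")
})

test_that("TAR recovers an exact power law with r2 = 1", {
  radii <- c(5, 10, 20, 50, 100, 200)
  area <- pi * radii^2
  fit <- fit_tar(NULL, NULL, richness = 300 * area^0.016, area = area)
  expect_equal(fit$slope, 0.016, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  flat <- fit_tar(NULL, NULL, richness = rep(100, 6), area = area)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_tar(NULL, NULL, richness = c(10, 20), area = area[1:2]),
               "3 areas")
})

test_that("clade assignment is nearest-reference with threshold and ties", {
  panel <- fx_panel()
  ref <- panel[panel$family == "amoA" & !is.na(panel$clade), ][1, ]
  got <- assign_clade(ref$aa, panel)
  expect_identical(got$clade, ref$clade)
  expect_equal(got$identity, 1)
  # heavy mutants fall below the threshold
  set.seed(47)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- paste(sample(aas, nchar(ref$aa), replace = TRUE), collapse = "")
  expect_identical(assign_clade(rnd, panel)$clade, "unclassified")
  # a moderate mutant keeps its clade
  v <- strsplit(ref$aa, "")[[1]]
  hit <- sample(length(v), round(length(v) * 0.2))
  for (x in hit) v[x] <- sample(aas, 1)
  mut <- paste(v, collapse = "")
  expect_identical(assign_clade(mut, panel)$clade, ref$clade)
})

test_that("neighbour joining solves the three-taxon case in closed form", {
  # sequences with known pairwise p-distances; a non-repetitive backbone
  # keeps the global alignment strictly diagonal
  set.seed(49)
  base <- random_dna(1, 200)
  mk <- function(s, k, offset) {
    v <- strsplit(s, "")[[1]]
    idx <- seq(offset, by = 7, length.out = k)
    for (i in idx) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  # disjoint mutation sets with a mutated outgroup keep all three
  # solved branch lengths positive despite the convex Poisson correction
  s <- c(a = mk(base, 4, 5), b = mk(base, 10, 1), c = mk(base, 20, 3))
  tr <- nj_tree(s, type = "nt")
  expect_s3_class(tr, "phylo")
  D <- matrix(0, 3, 3, dimnames = list(names(s), names(s)))
  for (i in 1:2) for (j in (i + 1):3) {
    v1 <- strsplit(s[[i]], "")[[1]]; v2 <- strsplit(s[[j]], "")[[1]]
    p <- mean(v1 != v2)
    D[i, j] <- D[j, i] <- -log(1 - p)
  }
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(bl[["a"]], (D["a", "b"] + D["a", "c"] - D["b", "c"]) / 2,
               tolerance = 1e-12)
  expect_equal(bl[["b"]], (D["a", "b"] + D["b", "c"] - D["a", "c"]) / 2,
               tolerance = 1e-12)
  # duplicate sequences form a zero-length cherry
  tr2 <- nj_tree(c(x = base, y = base, z = mk(base, 16, 3)), type = "nt")
  cherry <- tr2$edge.length[tr2$edge[, 2] %in% which(tr2$tip.label %in%
                                                       c("x", "y"))]
  expect_equal(unname(cherry), c(0, 0))
  expect_error(nj_tree(c(a = base, b = base)), "3 sequences")
})

test_that("neighbour joining recovers topology from additive distances", {
  skip_if_not_installed("phangorn")
  set.seed(48)
  for (i in 1:10) {
    tr <- ape::rtree(6)
    D <- cophenetic(tr)
    rec <- nj_from_dist(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), rec), 0)
  }
})
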