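test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- synth_config(seed = 5L, n_genomes = 2L, coverage_per_sample = 0.5,
                      radii = c(5, 20, 100), n_per_ring = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_metagenome(cfg, out_dir = d1)
  s2 <- simulate_metagenome(cfg, out_dir = d2)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$reads, s2$reads)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
})

test_that("panel identities separate families, paralogs and clades", {
  panel <- fx_panel()
  gid <- function(a, b) {
    sc <- genetarget:::.aa_scoring()
    x <- genetarget:::.cpp_align(a, b, sc$mat, sc$alphabet, 11L, 1L, TRUE)
    x$matches / x$aln_len
  }
  amoA <- panel$aa[panel$family == "amoA"]
  pmoA <- panel$aa[panel$family == "pmoA"]
  within <- outer(seq_along(amoA), seq_along(amoA), Vectorize(function(i, j) {
    if (i < j) gid(amoA[i], amoA[j]) else NA_real_
  }))
  between <- outer(seq_along(amoA), seq_along(pmoA),
                   Vectorize(function(i, j) gid(amoA[i], pmoA[j])))
  expect_gt(min(within, na.rm = TRUE), 0.6)
  expect_gt(mean(within, na.rm = TRUE), mean(between))
  expect_true(all(between > 0.3 & between < 0.6))
  # config with no pmo members yields an amo-only panel
  cfg0 <- synth_config(seed = 3L, n_ref_families = c(amoA = 4L, amoB = 2L,
                                                     amoC = 2L))
  p0 <- make_reference_panel(cfg0)
  expect_true(all(startsWith(p0$family, "amo")))
  # a within-family divergence above the paralog split is rejected
  expect_error(synth_config(within_divergence = 0.5,
                            paralog_divergence = 0.3), "paralog")
})

test_that("planted operons have the configured layout, gaps and CDS", {
  cfg <- fx_cfg()
  panel <- fx_panel()
  g <- fx_genomes()
  for (gi in seq_len(nrow(g$genomes))) {
    gid <- g$genomes$id[gi]
    f <- g$features[g$features$genome_id == gid & g$features$in_operon, ,
                    drop = FALSE]
    layout <- trimws(strsplit(g$layouts[gi], ",")[[1]])
    ford <- f[order(f$start), ]
    got <- if (unique(f$strand) == "-") rev(ford$family) else ford$family
    expect_identical(got, layout)
    gaps <- ford$start[-1] - ford$end[-nrow(ford)]
    expect_true(all(gaps >= cfg$intergenic_gap_bp[1] &
                      gaps <= cfg$intergenic_gap_bp[2]))
    # every planted CDS translates back to its panel protein exactly
    for (i in seq_len(nrow(f))) {
      cds <- substr(g$genomes$sequence[gi], f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") cds <- revcomp(cds)
      aa <- sub("\\*$", "", translate_six_frames(cds)[["+1"]])
      expect_identical(aa, panel$aa[panel$id == f$panel_id[i]])
    }
  }
  # amoX-bearing layout puts the 4th CDS downstream of amoB along the strand
  gx <- g$genomes$id[vapply(seq_len(nrow(g$genomes)), function(i) {
    grepl("amoX", g$layouts[i])
  }, logical(1))][1]
  fx <- g$features[g$features$genome_id == gx & g$features$in_operon, ]
  fx <- fx[order(fx$start), ]
  fams <- if (unique(fx$strand) == "-") rev(fx$family) else fx$family
  expect_gt(which(fams == "amoX"), which(fams == "amoB"))
})

test_that("error-free reads are exact genome substrings and origins conserve counts", {
  cfg <- synth_config(seed = 21L, n_genomes = 2L, error_rate = 0,
                      background_fraction = 0, coverage_per_sample = 0.3,
                      radii = c(5, 20), n_per_ring = 2L)
  panel <- make_reference_panel(cfg)
  g <- plant_genomes(panel, cfg)
  sim <- simulate_samples(g, cfg)
  expect_identical(sort(sim$reads$id), sort(sim$origin$read_id))
  for (i in sample(nrow(sim$reads), 25)) {
    gid <- sim$origin$origin[sim$origin$read_id == sim$reads$id[i]]
    gen <- g$genomes$sequence[g$genomes$id == gid]
    expect_true(grepl(sim$reads$sequence[i], gen, fixed = TRUE) ||
                  grepl(revcomp(sim$reads$sequence[i]), gen, fixed = TRUE))
  }
  # per-sample counts match the origin table exactly
  tab <- table(sim$reads$sample_id)
  tab2 <- table(sub("_r.*$", "", sim$origin$read_id))
  expect_equal(as.vector(tab), as.vector(tab2))
})

test_that("background fraction is honoured within binomial tolerance", {
  cfg <- synth_config(seed = 31L, n_genomes = 2L, background_fraction = 0.9,
                      coverage_per_sample = 3, radii = c(5, 20, 100),
                      n_per_ring = 4L)
  panel <- make_reference_panel(cfg)
  g <- plant_genomes(panel, cfg)
  sim <- simulate_samples(g, cfg)
  frac <- mean(sim$origin$origin == "background")
  expect_gt(nrow(sim$origin), 1e4)
  expect_gte(frac, 0.85)
})

test_that("planted chimeras are exact splices with recorded crossover", {
  panel <- fx_panel()
  parents <- setNames(panel$nt[panel$family == "amoA"],
                      panel$id[panel$family == "amoA"])
  pc <- plant_chimeras(parents, 5, seed = 4L)
  for (i in 1:5) {
    tr <- pc$truth[i, ]
    a <- parents[[tr$parent_a]]; b <- parents[[tr$parent_b]]
    x <- tr$crossover
    expect_gte(x, floor(0.3 * nchar(a)))
    expect_lte(x, ceiling(0.7 * nchar(a)))
    expect_identical(pc$chimeras$sequence[i],
                     paste0(substr(a, 1, x), substr(b, x + 1, nchar(b))))
  }
  # identical parents are rejected by the identity precondition
  twins <- c(p1 = parents[[1]], p2 = parents[[1]])
  expect_error(plant_chimeras(twins, 1, seed = 1L), "eligible")
})

test_that("the nested ring design has the documented geometry", {
  d <- ring_design()
  expect_equal(nrow(d), 25L)
  expect_equal(sum(d$ring_radius == 0), 1L)
  expect_equal(as.vector(table(d$ring_radius[d$ring_radius > 0])),
               rep(4L, 6L))
  r <- sqrt(d$x^2 + d$y^2)
  expect_equal(r, d$ring_radius, tolerance = 1e-9)
})

test_that("community truth hits the planted scaling slopes by construction", {
  cfg <- synth_config(seed = 13L)
  des <- ring_design(cfg$radii, cfg$n_per_ring, seed = cfg$seed + 11L)
  com <- simulate_community(des, cfg)
  expect_equal(unname(rowSums(com$matrix)), rep(1, nrow(des)),
               tolerance = 1e-12)
  fd <- fit_ddr(com$matrix, des)
  ft <- fit_tar(com$matrix, des)
  expect_lt(abs(fd$slope - cfg$ddr_slope_true), 1e-6)
  expect_lt(abs(ft$slope - cfg$tar_z_true), 5e-4)
})
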