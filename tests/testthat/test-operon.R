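mk_calls <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(gene_id = sprintf("g%02d", i), contig_id = r$ctg,
               start = r$s, end = r$e, strand = r$st, partial = FALSE,
               aa_sequence = "M", family = r$fam, bitscore = 100)
  }))
  out
}

test_that("a planted C-A-B cluster is a canonical complete operon", {
  calls <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                    list(ctg = "c1", s = 650L, e = 1400L, st = "+",
                         fam = "amoA"),
                    list(ctg = "c1", s = 1450L, e = 1950L, st = "+",
                         fam = "amoB"))
  ops <- detect_operons(calls)
  expect_equal(nrow(ops), 1L)
  expect_identical(ops$completeness_class, "complete_CAB")
  expect_true(ops$canonical_order)
  expect_true(ops$same_strand)
  expect_equal(ops$max_gap_bp, 50L)
  expect_equal(ops$n_genes, 3L)
  # the same cluster on the minus strand keeps its canonical order
  calls_m <- calls
  calls_m$strand <- "-"
  calls_m$family <- rev(calls$family)
  ops_m <- detect_operons(calls_m)
  expect_identical(ops_m$completeness_class, "complete_CAB")
  expect_true(ops_m$canonical_order)
})

test_that("completeness classes follow the subunit content", {
  ab <- mk_calls(list(ctg = "c1", s = 0L, e = 700L, st = "+", fam = "amoA"),
                 list(ctg = "c1", s = 750L, e = 1250L, st = "+",
                      fam = "amoB"))
  expect_identical(detect_operons(ab)$completeness_class, "partial:AB")
  abcx <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                   list(ctg = "c1", s = 650L, e = 1400L, st = "+",
                        fam = "amoA"),
                   list(ctg = "c1", s = 1450L, e = 1950L, st = "+",
                        fam = "amoB"),
                   list(ctg = "c1", s = 2000L, e = 2600L, st = "+",
                        fam = "amoX"))
  expect_identical(detect_operons(abcx)$completeness_class, "complete_ABCX")
  de <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                 list(ctg = "c1", s = 650L, e = 1400L, st = "+",
                      fam = "amoA"),
                 list(ctg = "c1", s = 1450L, e = 1950L, st = "+",
                      fam = "amoB"),
                 list(ctg = "c1", s = 2000L, e = 2700L, st = "+",
                      fam = "amoD"),
                 list(ctg = "c1", s = 2750L, e = 3300L, st = "+",
                      fam = "amoE"))
  expect_identical(detect_operons(de)$completeness_class, "extended_DE")
  expect_equal(nrow(detect_operons(de[0, ])), 0L)
})

test_that("clusters split at the gap threshold and never span contigs", {
  far <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                  list(ctg = "c1", s = 1200L, e = 1900L, st = "+",
                       fam = "amoA"),
                  list(ctg = "c2", s = 0L, e = 500L, st = "+", fam = "amoB"))
  ops <- detect_operons(far, max_gap = 500L)
  expect_equal(nrow(ops), 3L)
  expect_false(any(ops$completeness_class == "complete_CAB"))
  # raising max_gap can only merge, never lose completeness
  ops2 <- detect_operons(far, max_gap = 700L)
  n_complete <- function(x) sum(startsWith(x$completeness_class, "complete"))
  expect_gte(nrow(ops) - nrow(ops2), 0L)
  expect_gte(n_complete(ops2), n_complete(ops))
})

test_that("the call set is invariant to gene input order", {
  calls <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                    list(ctg = "c1", s = 650L, e = 1400L, st = "+",
                         fam = "amoA"),
                    list(ctg = "c1", s = 1450L, e = 1950L, st = "+",
                         fam = "amoB"),
                    list(ctg = "c2", s = 10L, e = 710L, st = "-",
                         fam = "amoA"))
  ops1 <- detect_operons(calls)
  set.seed(33)
  for (i in 1:5) {
    ops2 <- detect_operons(calls[sample(nrow(calls)), ])
    expect_identical(ops1, ops2)
  }
})

test_that("overlapping multi-frame calls resolve to the stronger annotation", {
  calls <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                    list(ctg = "c1", s = 650L, e = 1400L, st = "+",
                         fam = "amoA"),
                    list(ctg = "c1", s = 1450L, e = 1950L, st = "+",
                         fam = "amoB"))
  shadow <- calls[2, ]
  shadow$gene_id <- "shadow"
  shadow$family <- "amoX"
  shadow$start <- 700L; shadow$end <- 1300L
  shadow$bitscore <- 10
  ops <- detect_operons(rbind(calls, shadow))
  expect_identical(ops$completeness_class, "complete_CAB")
  expect_false(grepl("shadow", ops$gene_ids))
})

test_that("neighbour annotation applies the any-overlap window rule", {
  calls <- mk_calls(list(ctg = "c1", s = 1000L, e = 1600L, st = "+",
                         fam = "amoC"),
                    list(ctg = "c1", s = 1650L, e = 2400L, st = "+",
                         fam = "amoA"),
                    list(ctg = "c1", s = 2450L, e = 2950L, st = "+",
                         fam = "amoB"))
  nb1 <- data.frame(gene_id = "n1", contig_id = "c1", start = 3450L,
                    end = 4150L, strand = "+", partial = FALSE,
                    aa_sequence = "M", family = "other", bitscore = 50)
  edge <- data.frame(gene_id = "n2", contig_id = "c1", start = 4949L,
                     end = 5600L, strand = "+", partial = FALSE,
                     aa_sequence = "M", family = "other", bitscore = 50)
  outside <- data.frame(gene_id = "n3", contig_id = "c1", start = 4950L,
                        end = 5600L, strand = "+", partial = FALSE,
                        aa_sequence = "M", family = "other", bitscore = 50)
  all_calls <- rbind(calls, nb1, edge, outside)
  op <- detect_operons(all_calls)[1, ]
  nb <- annotate_neighbors(op, all_calls, window_bp = 2000L)
  expect_setequal(nb$gene_id, c("n1", "n2")) # 1-bp overlap counts
  expect_equal(nrow(annotate_neighbors(op, rbind(calls), 2000L)), 0L)
})

test_that("the operon summary reports lenient and strict counts", {
  calls <- mk_calls(list(ctg = "c1", s = 0L, e = 600L, st = "+", fam = "amoC"),
                    list(ctg = "c1", s = 650L, e = 1400L, st = "+",
                         fam = "amoA"),
                    list(ctg = "c1", s = 1450L, e = 1950L, st = "+",
                         fam = "amoB"),
                    # complete but non-canonical order on c2
                    list(ctg = "c2", s = 0L, e = 750L, st = "+", fam = "amoA"),
                    list(ctg = "c2", s = 800L, e = 1400L, st = "+",
                         fam = "amoC"),
                    list(ctg = "c2", s = 1450L, e = 1950L, st = "+",
                         fam = "amoB"),
                    list(ctg = "c3", s = 0L, e = 700L, st = "+", fam = "amoA"))
  ops <- detect_operons(calls)
  sm <- operon_summary(ops, label = "targeted")
  cab <- sm[sm$completeness_class == "complete_CAB", ]
  expect_equal(cab$n, 2L)
  expect_equal(cab$n_strict, 1L)
  expect_equal(sm$n[sm$completeness_class == "partial:A"], 1L)
  expect_identical(unique(sm$label), "targeted")
  expect_equal(nrow(operon_summary(ops[0, ])), 0L)
})
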