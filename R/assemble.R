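# Multi-k de Bruijn assembly of recruited reads. K-mers are stored in
# canonical form (lexicographic min of k-mer and reverse complement; k odd
# so no k-mer is its own reverse complement). No abundance cutoff is
# applied: every observed k-mer enters the graph with count >= 1. Graph
# cleaning is limited to clipping short count-1 tips; bubbles are kept so
# allelic variants survive as separate contigs.

#' Merge overlapping read pairs
#'
#' Native overlap-based merging of paired-end reads: if the suffix of the
#' forward read overlaps the prefix of the reverse-complemented mate by at
#' least `min_overlap` bases with a mismatch fraction at most
#' `max_mismatch_frac`, the pair is replaced by the merged fragment
#' (mismatches resolved toward the higher base quality, ties to read 1).
#' Non-overlapping pairs pass through unchanged.
#'
#' @param reads a read-set data frame with `mate` labels; mates are matched
#'   by id after stripping `/1`,`/2` suffixes.
#' @param min_overlap minimum overlap length (bp).
#' @param max_mismatch_frac maximum fraction of mismatching overlap columns.
#' @return a read-set data frame of merged plus unmerged reads.
#' @export
merge_pairs <- function(reads, min_overlap = 10L, max_mismatch_frac = 0.1) {
  base_id <- sub("/[12]$", "", reads$id)
  is1 <- reads$mate == "1"
  is2 <- reads$mate == "2"
  pairable <- intersect(base_id[is1], base_id[is2])
  keep <- rep(TRUE, nrow(reads))
  merged <- list()
  for (b in pairable) {
    i1 <- which(is1 & base_id == b)[1]
    i2 <- which(is2 & base_id == b)[1]
    m <- .merge_one_pair(reads$sequence[i1], reads$sequence[i2],
                         reads$quality[i1], reads$quality[i2],
                         min_overlap, max_mismatch_frac)
    if (!is.null(m)) {
      keep[c(i1, i2)] <- FALSE
      merged[[length(merged) + 1L]] <- data.frame(
        id = b, sample_id = reads$sample_id[i1], sequence = m$seq,
        mate = "unpaired", quality = m$qual)
    }
  }
  out <- reads[keep, , drop = FALSE]
  if (length(merged)) out <- rbind(out, do.call(rbind, merged))
  rownames(out) <- NULL
  out
}

.merge_one_pair <- function(s1, s2, q1, q2, min_overlap, max_mm) {
  r2 <- revcomp(s2)
  q2r <- if (is.na(q2) || is.null(q2)) NA_character_ else
    paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  n1 <- nchar(s1); n2 <- nchar(r2)
  best <- NULL
  for (ov in seq(min(n1, n2), min_overlap)) {
    a <- substr(s1, n1 - ov + 1L, n1)
    b <- substr(r2, 1L, ov)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    mm <- which(av != bv)
    if (length(mm) / ov <= max_mm) {
      best <- list(ov = ov, mm = mm, av = av, bv = bv)
      break # largest overlap first
    }
  }
  if (is.null(best)) return(NULL)
  ov <- best$ov
  ovseq <- best$av
  if (length(best$mm)) {
    q1v <- if (!is.na(q1)) utf8ToInt(substr(q1, n1 - ov + 1L, n1)) else
      rep(40L, ov)
    q2v <- if (!is.na(q2r)) utf8ToInt(substr(q2r, 1L, ov)) else rep(40L, ov)
    use2 <- best$mm[q2v[best$mm] > q1v[best$mm]]
    ovseq[use2] <- best$bv[use2]
  }
  mseq <- paste0(substr(s1, 1L, n1 - ov), paste(ovseq, collapse = ""),
                 substr(r2, ov + 1L, n2))
  mq <- strrep("I", nchar(mseq))
  list(seq = mseq, qual = mq)
}

#' Build a de Bruijn graph of canonical k-mers
#'
#' @param reads read-set data frame or character vector of sequences.
#' @param k odd k-mer size.
#' @return list of class `dbg` with `k` and `counts` (named integer vector
#'   over canonical k-mers). K-mers containing N are skipped.
#' @export
build_dbg <- function(reads, k) {
  if (k %% 2L == 0L) stop("k must be odd")
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0) {
    out <- list(k = k, counts = setNames(integer(0), character(0)))
    class(out) <- "dbg"
    return(out)
  }
  kc <- .cpp_kmer_counts(seqs, k)
  out <- list(k = k, counts = setNames(kc$count, kc$kmer))
  class(out) <- "dbg"
  out
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k=%d, %d canonical k-mers, total count %d\n",
              x$k, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Compact a de Bruijn graph into unitigs
#'
#' Maximal non-branching paths of the graph, emitted once each in
#' canonical orientation with their mean k-mer count as coverage. Unitigs
#' shorter than `tip_len_factor * k` whose k-mers all have count 1 are
#' clipped when they hang off a branching node (tips) or bridge two
#' junctions in parallel to better-supported sequence (error arms), and
#' the graph is recompacted; paths with any k-mer count >= 2 are never
#' clipped, so genuine variants survive as bubbles.
#'
#' @param dbg a [build_dbg()] graph.
#' @param tip_len_factor clipping length threshold in units of k.
#' @param clip_tips disable to keep all count-1 side paths.
#' @param max_artifact_len error side paths are bounded by the read
#'   length; passing it widens the clipping limit accordingly.
#' @return data frame with `sequence`, `k_origin`, `mean_coverage`.
#' @export
unitigs <- function(dbg, tip_len_factor = 2, clip_tips = TRUE,
                    max_artifact_len = 0) {
  if (length(dbg$counts) == 0) {
    return(data.frame(sequence = character(0), k_origin = integer(0),
                      mean_coverage = numeric(0)))
  }
  res <- .cpp_unitigs(names(dbg$counts), unname(dbg$counts), dbg$k,
                      tip_len_factor, clip_tips, max_artifact_len)
  data.frame(sequence = res$sequence, k_origin = rep(dbg$k, nrow(res)),
             mean_coverage = res$mean_coverage)
}

#' Assembly configuration
#'
#' @param k_list ascending odd k-mer sizes. The full-scale analogue spans
#'   29-141; the desk-scale default is 21, 33, 55, 77.
#' @param min_contig_len contigs shorter than this are dropped (bp).
#' @param tip_len_factor tip clipping threshold in units of k.
#' @param merge_identity containment identity for cross-k consensus merging.
#' @return list of class `assembly_config`.
#' @export
assembly_config <- function(k_list = c(21L, 33L, 55L, 77L),
                            min_contig_len = 200L, tip_len_factor = 2,
                            merge_identity = 0.99) {
  k_list <- as.integer(k_list)
  if (any(k_list %% 2L == 0L)) stop("all k must be odd")
  if (is.unsorted(k_list, strictly = TRUE)) stop("k_list must be ascending")
  structure(list(k_list = k_list, min_contig_len = min_contig_len,
                 tip_len_factor = tip_len_factor,
                 merge_identity = merge_identity),
            class = "assembly_config")
}

#' Multi-k assembly with cross-k consensus merging
#'
#' Runs [build_dbg()] + [unitigs()] at every k in ascending order, feeding
#' each k the contigs of the previous k alongside the reads (iterative
#' multi-k). All per-k contigs are pooled; exact duplicates and sequences
#' contained in a longer contig at >= `merge_identity` over their full
#' length (reverse-complement aware) are removed, and contigs shorter than
#' `min_contig_len` are dropped.
#'
#' @param reads read-set data frame or character vector.
#' @param config an [assembly_config()].
#' @return contig data frame: `id`, `sequence` (canonical orientation),
#'   `k_origin`, `mean_coverage`.
#' @export
assemble_multi_k <- function(reads, config = assembly_config()) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  max_rl <- if (length(seqs)) max(nchar(seqs)) else 0L
  pool <- data.frame(sequence = character(0), k_origin = integer(0),
                     mean_coverage = numeric(0))
  prev <- character(0)
  for (k in config$k_list) {
    if (k > max_rl) {
      warning(sprintf("k=%d exceeds all read lengths; skipped", k))
      next
    }
    dbg <- build_dbg(c(seqs, prev), k)
    u <- unitigs(dbg, tip_len_factor = config$tip_len_factor,
                 max_artifact_len = max_rl)
    if (nrow(u)) pool <- rbind(pool, u)
    # feed forward only contigs clearly longer than the residual-artifact
    # scale (error side paths are bounded by read length plus k), so
    # surviving count-1 junk is not reinforced at the next k
    prev <- u$sequence[nchar(u$sequence) >= 2L * (max_rl + k)]
  }
  consensus <- .consensus_merge(pool, config$merge_identity)
  consensus <- consensus[nchar(consensus$sequence) >= config$min_contig_len, ,
                         drop = FALSE]
  if (nrow(consensus)) {
    ord <- order(-nchar(consensus$sequence), consensus$sequence)
    consensus <- consensus[ord, , drop = FALSE]
    consensus$id <- sprintf("ctg%05d", seq_len(nrow(consensus)))
    consensus <- consensus[, c("id", "sequence", "k_origin", "mean_coverage")]
  } else {
    consensus$id <- character(0)
    consensus <- consensus[, c("id", "sequence", "k_origin", "mean_coverage")]
  }
  rownames(consensus) <- NULL
  consensus
}

# remove exact duplicates and contigs contained in a longer contig
.consensus_merge <- function(pool, merge_identity) {
  if (nrow(pool) == 0) return(pool)
  pool$sequence <- canonical(pool$sequence)
  ord <- order(-nchar(pool$sequence), pool$sequence, -pool$mean_coverage)
  pool <- pool[ord, , drop = FALSE]
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  n <- nrow(pool)
  if (n <= 1) return(pool)
  keep <- rep(TRUE, n)
  seqs <- pool$sequence
  rcs <- revcomp(seqs)
  cand <- .cpp_candidate_pairs(seqs, 21L)
  sc <- .nt_scoring()
  # containment at >= 0.99 identity implies most canonical 31-mers of the
  # shorter survive in the longer; cheap prefilter before aligning
  kmf <- 31L
  km_list <- lapply(seqs, function(s) {
    if (nchar(s) < kmf) character(0) else
      unique(canonical(kmers_of(s, kmf)))
  })
  for (i in seq(n, 2)) {
    s <- seqs[i]; r <- rcs[i]; L <- nchar(s)
    for (j in cand[[i]]) {
      if (!keep[j]) next
      big <- seqs[j]
      if (grepl(s, big, fixed = TRUE) || grepl(r, big, fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
      if (merge_identity < 1) {
        if (length(km_list[[i]]) == 0 ||
            mean(km_list[[i]] %in% km_list[[j]]) <
              max(0, 1 - kmf * (1 - merge_identity) * 2)) next
        for (q in c(s, r)) {
          cont <- .anchored_containment(q, big, merge_identity)
          if (is.na(cont)) {
            a <- .cpp_align(q, big, sc$mat, sc$alphabet, 5L, 2L, FALSE)
            cont <- a$aln_len > 0 && a$matches / L >= merge_identity
          }
          if (cont) {
            keep[i] <- FALSE
            break
          }
        }
        if (!keep[i]) break
      }
    }
  }
  pool[keep, , drop = FALSE]
}

# gap-free containment test of q in big: anchor shared 31-mers to fix the
# offset, then compare directly. TRUE/FALSE when an anchor offset exists,
# NA when no anchor is found (caller falls back to full alignment, which
# also covers containment with indels).
.anchored_containment <- function(q, big, merge_identity, k = 31L) {
  L <- nchar(q)
  if (L < k) return(NA)
  anchors <- unique(as.integer(seq(1L, L - k + 1L, length.out = 8L)))
  tried <- integer(0)
  found <- FALSE
  for (p in anchors) {
    loc <- regexpr(substr(q, p, p + k - 1L), big, fixed = TRUE)
    if (loc < 0) next
    off <- as.integer(loc) - p
    if (off %in% tried) next
    tried <- c(tried, off)
    found <- TRUE
    if (off < 0 || off + L > nchar(big)) next
    b2 <- substr(big, off + 1L, off + L)
    mism <- sum(charToRaw(q) != charToRaw(b2))
    if ((L - mism) / L >= merge_identity) return(TRUE)
  }
  if (found) FALSE else NA
}

#' Check that a contig is spelled by a walk in a graph
#'
#' Every consensus contig must be re-threadable through at least one k's
#' de Bruijn graph (no hallucinated sequence).
#'
#' @param sequence contig sequence.
#' @param dbg a [build_dbg()] graph.
#' @return `TRUE` iff all canonical k-mers of the contig are graph nodes.
#' @export
contig_in_dbg <- function(sequence, dbg) {
  km <- canonical(kmers_of(sequence, dbg$k))
  all(km %in% names(dbg$counts))
}
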