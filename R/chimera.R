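# Chimera (bimera) screening of assembled sequences. One crossover-
# maximisation score serves both modes: candidate parents come from a
# user-supplied reference set (reference mode) or from the other queries
# under an abundance-skew rule (de novo mode). The three-way verdict
# vocabulary is {chimeric, non_chimeric, unclassified}.

#' Chimera-detection parameters
#'
#' @param d_min minimum match gain of the two-parent model over the best
#'   single parent for a chimeric verdict.
#' @param min_seg_frac minimum fraction of query columns each parent
#'   segment must cover.
#' @param min_seg_identity minimum identity of each parent segment.
#' @param skew coverage ratio parents must exceed in de novo mode.
#' @param top_n number of candidate parents scored per query.
#' @return list of class `chimera_params`.
#' @export
chimera_params <- function(d_min = 3L, min_seg_frac = 0.2,
                           min_seg_identity = 0.8, skew = 2.0, top_n = 4L) {
  structure(list(d_min = d_min, min_seg_frac = min_seg_frac,
                 min_seg_identity = min_seg_identity, skew = skew,
                 top_n = top_n), class = "chimera_params")
}

# per-query-position match profile of query vs one parent, in the chosen
# orientation; returns logical vector of length nchar(query)
.match_profile <- function(query, parent) {
  sc <- .nt_scoring()
  a <- .cpp_align(query, parent, sc$mat, sc$alphabet, 5L, 2L, TRUE)
  qa <- strsplit(a$q_aln, "")[[1]]
  sa <- strsplit(a$s_aln, "")[[1]]
  qpos <- cumsum(qa != "-")
  keep <- qa != "-"
  prof <- logical(nchar(query))
  hit <- keep & qa == sa & sa != "-" & qa != "N"
  prof[qpos[hit]] <- TRUE
  prof
}

# rank candidate parents by local alignment score; a shared-k-mer count
# preselects the pool so only the most promising references are aligned
.rank_parents <- function(query, parents, top_n, seed_k = 12L) {
  sc <- .nt_scoring()
  rcq <- revcomp(query)
  k <- min(seed_k, nchar(query))
  shared_f <- vapply(parents, function(p) {
    .cpp_shared_kmers(query, p, k)
  }, numeric(1))
  shared_r <- vapply(parents, function(p) {
    .cpp_shared_kmers(rcq, p, k)
  }, numeric(1))
  shared <- pmax(shared_f, shared_r)
  pool <- order(-shared, seq_along(parents))
  pool <- pool[shared[pool] > 0]
  pool <- head(pool, top_n + 2L)
  out <- data.frame(index = integer(0), score = numeric(0),
                    orient = character(0))
  for (i in pool) {
    best <- 0; orient <- "+"
    for (o in c("+", "-")) {
      q <- if (o == "+") query else rcq
      if ((if (o == "+") shared_f else shared_r)[i] == 0) next
      a <- .cpp_align(q, parents[i], sc$mat, sc$alphabet, 5L, 2L, FALSE)
      if (a$score > best) { best <- a$score; orient <- o }
    }
    if (best > 0) {
      out <- rbind(out, data.frame(index = i, score = best, orient = orient))
    }
  }
  out <- out[order(-out$score, out$index), , drop = FALSE]
  head(out, top_n)
}

# core verdict for one query against a fixed parent pool
.judge_query <- function(query_id, query, parent_ids, parents, params) {
  verdict <- function(class, pa = NA_character_, pb = NA_character_,
                      xo = NA_integer_, d = NA_integer_,
                      ia = NA_real_, ib = NA_real_, reason = "") {
    data.frame(query_id = query_id, classification = class,
               parent_a = pa, parent_b = pb, crossover = xo,
               d_score = d, seg_identity_a = ia, seg_identity_b = ib,
               reason = reason)
  }
  L <- nchar(query)
  if (L < 15L) return(verdict("unclassified", reason = "query too short"))
  if (length(parents) < 2L) {
    return(verdict("non_chimeric", reason = "fewer than 2 candidate parents"))
  }
  ranked <- .rank_parents(query, parents, params$top_n)
  if (nrow(ranked) < 2L) {
    return(verdict("non_chimeric", reason = "fewer than 2 aligned parents"))
  }
  # orientation of the query follows its best-scoring parent
  q <- if (ranked$orient[1] == "+") query else revcomp(query)
  profs <- lapply(ranked$index, function(i) .match_profile(q, parents[i]))
  tot <- vapply(profs, sum, numeric(1))
  best_single <- max(tot)
  pref <- lapply(profs, cumsum)
  nc <- nrow(ranked)
  best <- list(M = -Inf)
  for (ai in seq_len(nc)) for (bi in seq_len(nc)) {
    if (ai == bi) next
    # M(x) = matches to A on columns < x plus matches to B on columns >= x
    Mx <- c(0, pref[[ai]]) + tot[bi] - c(0, pref[[bi]])
    x <- which.max(Mx) - 1L
    M <- Mx[x + 1L]
    ok_x <- which(Mx == M) - 1L
    # prefer a maximising crossover satisfying the segment rules
    seg_ok <- vapply(ok_x, function(xx) {
      xx >= params$min_seg_frac * L && (L - xx) >= params$min_seg_frac * L &&
        (xx == 0 || c(0, pref[[ai]])[xx + 1L] / xx >= params$min_seg_identity) &&
        (xx == L ||
           (tot[bi] - c(0, pref[[bi]])[xx + 1L]) / (L - xx) >=
             params$min_seg_identity)
    }, logical(1))
    if (any(seg_ok)) x <- ok_x[which(seg_ok)[1]]
    if (M > best$M) {
      ia <- if (x > 0) c(0, pref[[ai]])[x + 1L] / x else 0
      ib <- if (x < L) (tot[bi] - c(0, pref[[bi]])[x + 1L]) / (L - x) else 0
      best <- list(M = M, ai = ai, bi = bi, x = x, ia = ia, ib = ib,
                   seg_ok = x >= params$min_seg_frac * L &&
                     (L - x) >= params$min_seg_frac * L &&
                     ia >= params$min_seg_identity &&
                     ib >= params$min_seg_identity)
    }
  }
  d <- as.integer(best$M - best_single)
  pa <- parent_ids[ranked$index[best$ai]]
  pb <- parent_ids[ranked$index[best$bi]]
  if (d >= params$d_min && isTRUE(best$seg_ok)) {
    verdict("chimeric", pa, pb, best$x, d, best$ia, best$ib)
  } else if (d >= 1L) {
    verdict("unclassified", pa, pb, best$x, d, best$ia, best$ib,
            reason = "ambiguous crossover gain")
  } else {
    verdict("non_chimeric", d = d)
  }
}

#' Reference-based chimera detection
#'
#' Judges each query against a nucleotide reference set: candidate parents
#' are the top-scoring references, the two-parent crossover model is
#' maximised over all ordered parent pairs and crossover columns, and the
#' verdict follows the match gain `d_score` of that model over the best
#' single parent.
#'
#' @param queries data frame (`id`, `sequence`) or named character vector
#'   of nucleotide queries.
#' @param refs data frame (`id`, `sequence`) or named character vector of
#'   reference sequences (>= 2).
#' @param params a [chimera_params()].
#' @return verdict data frame: `query_id`, `classification`, `parent_a`,
#'   `parent_b`, `crossover` (0-based query column), `d_score`, per-segment
#'   identities and a `reason`.
#' @export
detect_ref <- function(queries, refs, params = chimera_params()) {
  queries <- .as_seq_df(queries)
  refs <- .as_seq_df(refs)
  if (nrow(refs) < 2L) stop("reference set must contain >= 2 sequences")
  out <- lapply(seq_len(nrow(queries)), function(i) {
    .judge_query(queries$id[i], queries$sequence[i], refs$id, refs$sequence,
                 params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' De novo chimera detection
#'
#' Same crossover model as [detect_ref()], but candidate parents for each
#' query are the other queries whose coverage is at least `skew` times the
#' query's own coverage; queries are processed in decreasing coverage
#' order. A chimera formed during assembly is expected to be less abundant
#' than its parents.
#'
#' @param queries data frame with `id`, `sequence` and `coverage`
#'   (e.g. contig `mean_coverage`).
#' @param params a [chimera_params()].
#' @return verdict data frame as in [detect_ref()].
#' @export
detect_denovo <- function(queries, params = chimera_params()) {
  stopifnot(all(c("id", "sequence", "coverage") %in% names(queries)))
  queries <- queries[order(-queries$coverage, queries$id), , drop = FALSE]
  out <- lapply(seq_len(nrow(queries)), function(i) {
    eligible <- queries$coverage >= params$skew * queries$coverage[i] &
      seq_len(nrow(queries)) != i
    .judge_query(queries$id[i], queries$sequence[i],
                 queries$id[eligible], queries$sequence[eligible], params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate chimera verdicts per gene family
#'
#' @param verdicts verdict data frame.
#' @param family optional family label per verdict row (single group if
#'   omitted).
#' @return data frame of counts and fractions per classification per
#'   family; fractions sum to 1 within each family.
#' @export
chimera_report <- function(verdicts, family = NULL) {
  if (nrow(verdicts) == 0) stop("no verdicts to report")
  if (is.null(family)) family <- rep("all", nrow(verdicts))
  classes <- c("chimeric", "non_chimeric", "unclassified")
  out <- list()
  for (f in sort(unique(family))) {
    v <- verdicts$classification[family == f]
    if (length(v) == 0) {
      warning("empty family group omitted: ", f)
      next
    }
    counts <- vapply(classes, function(cl) sum(v == cl), integer(1))
    out[[length(out) + 1L]] <- data.frame(
      family = f, classification = classes, count = counts,
      fraction = counts / length(v))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.as_seq_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(x[, c("id", "sequence")])
  }
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(x))
  data.frame(id = ids, sequence = unname(x))
}
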