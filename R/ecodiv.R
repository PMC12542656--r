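# Assembly-quality metrics, abundance matrices by k-mer read assignment,
# Bray-Curtis community comparison, distance-decay (DDR) and taxa-area
# (TAR) slope estimation, nearest-reference clade assignment, and
# neighbour-joining trees from Poisson-corrected distances.

#' Assembly contiguity statistics
#'
#' N50/N90 are the contig length at which the cumulative length of
#' contigs, sorted descending, first reaches 50%/90% of the total; L50/L90
#' are the number of contigs needed to reach it.
#'
#' @param contig_lengths positive integer vector.
#' @return list of class `assembly_stats`: `n_contigs`, `total_len`,
#'   `N50`, `N90`, `L50`, `L90`.
#' @export
assembly_stats <- function(contig_lengths) {
  if (length(contig_lengths) == 0) {
    return(structure(list(n_contigs = 0L, total_len = 0L, N50 = NA_integer_,
                          N90 = NA_integer_, L50 = NA_integer_,
                          L90 = NA_integer_), class = "assembly_stats"))
  }
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  cs <- cumsum(s)
  tot <- cs[length(cs)]
  i50 <- which(cs >= 0.5 * tot)[1]
  i90 <- which(cs >= 0.9 * tot)[1]
  structure(list(n_contigs = length(s), total_len = as.integer(tot),
                 N50 = as.integer(s[i50]), N90 = as.integer(s[i90]),
                 L50 = i50, L90 = i90), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d contigs, %d bp | N50=%d L50=%d | N90=%d L90=%d\n",
              x$n_contigs, x$total_len, x$N50, x$L50, x$N90, x$L90))
  invisible(x)
}

#' Assign reads to gene representatives by shared k-mers
#'
#' Each read goes to the representative sharing the most canonical
#' 31-mers with it (both orientations are implicit in canonical form);
#' ties are dropped as ambiguous and reads sharing no k-mer are unmapped.
#'
#' @param reads read-set data frame with `sample_id`.
#' @param representatives named character vector or data frame
#'   (`id`, `sequence`) of dereplicated gene representatives.
#' @param k k-mer size.
#' @return list: `matrix` (samples x representatives count matrix),
#'   `n_ambiguous`, `n_unmapped`.
#' @export
map_reads <- function(reads, representatives, k = 31L) {
  reps <- .as_seq_df(representatives)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(reps))) {
    for (km in unique(canonical(kmers_of(reps$sequence[i], k)))) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  samples <- sort(unique(reads$sample_id))
  mat <- matrix(0L, nrow = length(samples), ncol = nrow(reps),
                dimnames = list(samples, reps$id))
  n_amb <- 0L; n_un <- 0L
  for (r in seq_len(nrow(reads))) {
    km <- canonical(kmers_of(reads$sequence[r], k))
    if (length(km) == 0) { n_un <- n_un + 1L; next }
    hits <- unlist(lapply(unique(km), function(x) idx[[x]]),
                   use.names = FALSE)
    if (length(hits) == 0) { n_un <- n_un + 1L; next }
    tab <- tabulate(hits, nbins = nrow(reps))
    mx <- max(tab)
    best <- which(tab == mx)
    if (length(best) > 1L) { n_amb <- n_amb + 1L; next }
    srow <- match(reads$sample_id[r], samples)
    mat[srow, best] <- mat[srow, best] + 1L
  }
  list(matrix = mat, n_ambiguous = n_amb, n_unmapped = n_un)
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)` for non-negative abundance vectors.
#'
#' @param x,y equal-length non-negative numeric vectors, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

# pairwise similarity (1 - Bray-Curtis) matrix; rows of m are samples
.similarity_matrix <- function(m, relative = TRUE) {
  if (relative) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  n <- nrow(m)
  S <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    S[i, j] <- S[j, i] <- 1 - bray_curtis(m[i, ], m[j, ])
  }
  S
}

.slope_fit <- function(x, y) {
  fit <- lm(y ~ x)
  # exact constructions fit perfectly; the p-value caveat is expected
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_points = length(x)), class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope = %.4g (intercept %.4g), r2 = %.3f, P = %.3g, n = %d\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n_points))
  invisible(x)
}

#' Distance-decay relationship (DDR)
#'
#' OLS regression of community similarity (1 - Bray-Curtis) on
#' log10(pairwise geographic distance in metres). Zero-distance pairs are
#' excluded (log undefined).
#'
#' @param mat samples x variants abundance matrix (rownames = sample ids),
#'   or `NULL` when `similarity` is given.
#' @param design sample-design data frame ([read_design()]).
#' @param similarity optional precomputed similarity matrix overriding
#'   `mat`.
#' @param relative compare relative abundances (default) or raw counts.
#' @param mantel also compute a Mantel permutation p-value (999
#'   permutations; requires the vegan package).
#' @return `slope_fit` with the turnover slope `d` (optionally `mantel_p`).
#' @export
fit_ddr <- function(mat, design, similarity = NULL, relative = TRUE,
                    mantel = FALSE) {
  if (is.null(similarity)) {
    similarity <- .similarity_matrix(mat, relative = relative)
  }
  ids <- rownames(similarity)
  di <- match(ids, design$sample_id)
  if (anyNA(di)) stop("similarity rows missing from design")
  D <- as.matrix(stats::dist(design[di, c("x", "y")]))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]; s <- similarity[iu]
  keep <- d > 0
  if (sum(keep) < 3) stop("need >= 3 sample pairs with positive distance")
  out <- .slope_fit(log10(d[keep]), s[keep])
  if (mantel) {
    if (!requireNamespace("vegan", quietly = TRUE)) {
      warning("vegan not available; Mantel test skipped")
    } else {
      mt <- vegan::mantel(as.dist(log10(pmax(D, min(d[keep])))),
                          as.dist(1 - similarity), permutations = 999)
      out$mantel_p <- mt$signif
    }
  }
  out
}

#' Taxa-area relationship (TAR)
#'
#' Pools the samples lying within each ring radius of the nested design,
#' counts the variants present (abundance > 0) in the pool, and regresses
#' log10(richness) on log10(area = pi * r^2). The slope is the
#' accumulation exponent `z`.
#'
#' @param mat samples x variants abundance matrix, or `NULL` when
#'   `richness`/`area` are given directly.
#' @param design sample-design data frame.
#' @param richness,area optional precomputed vectors overriding `mat`.
#' @return `slope_fit` with slope `z`.
#' @export
fit_tar <- function(mat, design, richness = NULL, area = NULL) {
  if (is.null(richness)) {
    radii <- sort(unique(design$ring_radius[design$ring_radius > 0]))
    if (length(radii) < 3) stop("need >= 3 nested ring radii")
    ids <- rownames(mat)
    di <- match(ids, design$sample_id)
    if (anyNA(di)) stop("matrix rows missing from design")
    rr <- design$ring_radius[di]
    richness <- vapply(radii, function(r) {
      pooled <- colSums(mat[rr <= r, , drop = FALSE])
      sum(pooled > 0)
    }, numeric(1))
    area <- pi * radii^2
  }
  keep <- richness > 0
  if (sum(keep) < 3) stop("need >= 3 areas with positive richness")
  .slope_fit(log10(area[keep]), log10(richness[keep]))
}

#' Nearest-reference clade assignment
#'
#' Global-alignment identity of a query protein to every clade-labelled
#' reference; the nearest label is returned when identity >= the
#' threshold, else `unclassified`. Ties go to the lexicographically
#' smallest label and are flagged ambiguous.
#'
#' @param query_aa character vector of query proteins.
#' @param panel a [ref_panel()] with clade-labelled references.
#' @param min_identity assignment threshold.
#' @return data frame `clade`, `identity`, `ref_id`, `ambiguous`.
#' @export
assign_clade <- function(query_aa, panel, min_identity = 0.5) {
  refs <- panel[!is.na(panel$clade), , drop = FALSE]
  if (nrow(refs) == 0) stop("panel has no clade-labelled references")
  sc <- .aa_scoring()
  out <- lapply(query_aa, function(q) {
    idents <- vapply(refs$aa, function(ref) {
      a <- .cpp_align(q, ref, sc$mat, sc$alphabet, 11L, 1L, TRUE)
      ungapped <- sum(strsplit(a$q_aln, "")[[1]] != "-" &
                        strsplit(a$s_aln, "")[[1]] != "-")
      if (ungapped == 0) 0 else a$matches / a$aln_len
    }, numeric(1))
    mx <- max(idents)
    if (mx < min_identity) {
      return(data.frame(clade = "unclassified", identity = mx,
                        ref_id = NA_character_, ambiguous = FALSE))
    }
    best <- which(idents == mx)
    lab <- sort(refs$clade[best])
    data.frame(clade = lab[1], identity = mx,
               ref_id = refs$id[best[order(refs$clade[best])[1]]],
               ambiguous = length(unique(refs$clade[best])) > 1)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neighbour-joining tree from Poisson-corrected distances
#'
#' Pairwise p-distances (proportion of mismatching ungapped columns of a
#' global alignment) with Poisson correction `d = -ln(1 - p)` (p capped at
#' 0.95), then Saitou-Nei neighbour joining; negative branch lengths are
#' clamped to zero.
#'
#' @param sequences named character vector (>= 3) of protein or nucleotide
#'   sequences.
#' @param type `"aa"` or `"nt"`.
#' @param path optional output path for the Newick file.
#' @return an `ape::phylo` tree.
#' @export
#' Neighbour joining from a distance matrix
#'
#' The tree-building step of [nj_tree()]: Saitou-Nei neighbour joining
#' with negative branch lengths clamped to zero.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return an `ape::phylo` tree.
#' @export
nj_from_dist <- function(D) {
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

nj_tree <- function(sequences, type = c("aa", "nt"), path = NULL) {
  type <- match.arg(type)
  if (length(sequences) < 3) stop("need >= 3 sequences for a tree")
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(sequences))
  n <- length(sequences)
  sc <- if (type == "aa") .aa_scoring() else .nt_scoring()
  go <- if (type == "aa") 11L else 5L
  ge <- if (type == "aa") 1L else 2L
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- .cpp_align(sequences[i], sequences[j], sc$mat, sc$alphabet,
                    go, ge, TRUE)
    qa <- strsplit(a$q_aln, "")[[1]]; sa <- strsplit(a$s_aln, "")[[1]]
    ug <- qa != "-" & sa != "-"
    p <- if (sum(ug) == 0) 0.95 else sum(qa[ug] != sa[ug]) / sum(ug)
    p <- min(p, 0.95)
    D[i, j] <- D[j, i] <- -log(1 - p)
  }
  tr <- nj_from_dist(D)
  if (!is.null(path)) ape::write.tree(tr, path)
  tr
}
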