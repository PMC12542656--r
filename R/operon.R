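# Operon architecture detection on annotated contigs. Completeness is
# defined by co-occurrence of subunits on one contig (operons never span
# contigs); gene order and strand are reported as flags, not required,
# because amo subunits can scatter across a genome in some lineages.

#' Detect amo operons on annotated contigs
#'
#' Clusters amo-family gene calls on each contig whenever consecutive
#' calls are separated by at most `max_gap` bp; each cluster becomes an
#' operon call. Completeness classes: `complete_CAB` (amoC+amoA+amoB),
#' `complete_ABCX` (additionally amoX), `extended_DE` (CAB plus amoD or
#' amoE), otherwise `partial:<subunits>`. Overlapping amo calls at one
#' locus are resolved toward the higher bit score before clustering.
#'
#' @param gene_calls annotated gene calls ([annotate_stringent()]).
#' @param max_gap maximum intergenic distance within one operon (bp).
#' @return operon data frame: `operon_id`, `contig_id`, `start`, `end`,
#'   `completeness_class`, `subunits`, `gene_ids`, `same_strand`,
#'   `canonical_order`, `max_gap_bp`, `n_genes`.
#' @export
detect_operons <- function(gene_calls, max_gap = 500L) {
  empty <- data.frame(operon_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      completeness_class = character(0),
                      subunits = character(0), gene_ids = character(0),
                      same_strand = logical(0), canonical_order = logical(0),
                      max_gap_bp = integer(0), n_genes = integer(0))
  if (is.null(gene_calls) || nrow(gene_calls) == 0) return(empty)
  amo <- gene_calls[startsWith(gene_calls$family, "amo"), , drop = FALSE]
  if (nrow(amo) == 0) return(empty)
  amo <- .drop_overlaps(amo)
  out <- list()
  for (ctg in sort(unique(amo$contig_id))) {
    g <- amo[amo$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    gaps <- if (nrow(g) > 1) g$start[-1] - g$end[-nrow(g)] else integer(0)
    cluster <- cumsum(c(0L, as.integer(gaps > max_gap)))
    for (cl in unique(cluster)) {
      gg <- g[cluster == cl, , drop = FALSE]
      ggaps <- if (nrow(gg) > 1) gg$start[-1] - gg$end[-nrow(gg)] else 0L
      fams <- gg$family
      cls <- .completeness_class(fams)
      same_strand <- length(unique(gg$strand)) == 1L
      # order along the strand: reverse the positional order on '-'
      ord_fams <- if (same_strand && gg$strand[1] == "-") rev(fams) else fams
      canonical_order <- length(ord_fams) >= 3 &&
        identical(ord_fams[1:3], c("amoC", "amoA", "amoB"))
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, start = min(gg$start), end = max(gg$end),
        completeness_class = cls,
        subunits = paste(fams, collapse = ","),
        gene_ids = paste(gg$gene_id, collapse = ","),
        same_strand = same_strand, canonical_order = canonical_order,
        max_gap_bp = as.integer(max(ggaps)), n_genes = nrow(gg))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  res$operon_id <- sprintf("operon%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("operon_id", "contig_id", "start", "end", "completeness_class",
          "subunits", "gene_ids", "same_strand", "canonical_order",
          "max_gap_bp", "n_genes")]
}

.completeness_class <- function(fams) {
  u <- unique(fams)
  has_cab <- all(c("amoA", "amoB", "amoC") %in% u)
  if (has_cab && any(c("amoD", "amoE") %in% u)) return("extended_DE")
  if (has_cab && "amoX" %in% u) return("complete_ABCX")
  if (has_cab) return("complete_CAB")
  paste0("partial:", paste(sort(sub("^amo", "", u)), collapse = ""))
}

# resolve competing calls at one locus toward the higher bit score:
# multi-frame shadow ORFs overlap a real gene substantially, while calls
# of adjacent operon genes may brush each other by a few codons (a start
# scan can extend slightly into the neighbour), so only overlaps covering
# more than 30% of the shorter call are treated as the same locus
.drop_overlaps <- function(calls, max_overlap_frac = 0.3) {
  if (is.null(calls$bitscore)) calls$bitscore <- 0
  ord <- order(calls$contig_id, -calls$bitscore,
               -(calls$end - calls$start), calls$gene_id)
  calls <- calls[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    for (j in prior) {
      if (calls$contig_id[j] != calls$contig_id[i]) next
      ov <- min(calls$end[i], calls$end[j]) -
        max(calls$start[i], calls$start[j])
      shorter <- min(calls$end[i] - calls$start[i],
                     calls$end[j] - calls$start[j])
      if (ov > max_overlap_frac * shorter) {
        keep[i] <- FALSE
        break
      }
    }
  }
  calls[keep, , drop = FALSE]
}

#' Annotate genes neighbouring an operon
#'
#' Non-amo gene calls with any overlap of the window extending
#' `window_bp` up- and downstream of the operon span.
#'
#' @param operon_call one row of [detect_operons()] output.
#' @param gene_calls all annotated gene calls on the contigs.
#' @param window_bp window size on each side (bp).
#' @return the neighbouring gene calls (possibly zero rows).
#' @export
annotate_neighbors <- function(operon_call, gene_calls, window_bp = 2000L) {
  lo <- max(0L, operon_call$start - window_bp)
  hi <- operon_call$end + window_bp
  members <- strsplit(operon_call$gene_ids, ",")[[1]]
  nb <- gene_calls[gene_calls$contig_id == operon_call$contig_id &
                     !(gene_calls$gene_id %in% members) &
                     !startsWith(gene_calls$family, "amo") &
                     gene_calls$start < hi & gene_calls$end > lo, ,
                   drop = FALSE]
  rownames(nb) <- NULL
  nb
}

#' Summarise operon calls per completeness class
#'
#' Reports lenient counts (co-occurrence only) and strict counts
#' (additionally same strand and canonical C-A-B order).
#'
#' @param operon_calls output of [detect_operons()].
#' @param label optional assembly label column value.
#' @return data frame `completeness_class`, `n`, `n_strict` (plus `label`),
#'   deterministically ordered.
#' @export
operon_summary <- function(operon_calls, label = NULL) {
  if (is.null(operon_calls) || nrow(operon_calls) == 0) {
    out <- data.frame(completeness_class = character(0), n = integer(0),
                      n_strict = integer(0))
    if (!is.null(label)) out$label <- character(0)
    return(out)
  }
  cls <- sort(unique(operon_calls$completeness_class))
  out <- data.frame(
    completeness_class = cls,
    n = vapply(cls, function(cl) {
      sum(operon_calls$completeness_class == cl)
    }, integer(1)),
    n_strict = vapply(cls, function(cl) {
      sum(operon_calls$completeness_class == cl & operon_calls$same_strand &
            operon_calls$canonical_order)
    }, integer(1)),
    row.names = NULL)
  if (!is.null(label)) out$label <- label
  out
}
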