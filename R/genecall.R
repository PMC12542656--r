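# ORF prediction on contigs, stringent re-annotation against the panel,
# and greedy redundancy removal. Contigs arriving here are near-complete
# genes, so a stop-to-stop ORF scan with start-codon preference stands in
# for an HMM gene finder.

#' Annotation configuration
#'
#' @param min_orf_aa minimum ORF length in residues.
#' @param stringent_evalue,stringent_identity thresholds of the
#'   high-specificity re-annotation stage.
#' @param derep_identity,derep_coverage greedy clustering thresholds:
#'   identity over at least this fraction of the shorter sequence.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(min_orf_aa = 60L, stringent_evalue = 1e-5,
                              stringent_identity = 0.3,
                              derep_identity = 0.95, derep_coverage = 0.9) {
  if (min_orf_aa < 20L) stop("min_orf_aa must be >= 20")
  structure(list(min_orf_aa = as.integer(min_orf_aa),
                 stringent_evalue = stringent_evalue,
                 stringent_identity = stringent_identity,
                 derep_identity = derep_identity,
                 derep_coverage = derep_coverage),
            class = "annotation_config")
}

#' Call open reading frames on contigs
#'
#' Scans all six frames for maximal stop-to-stop intervals; within each
#' interval the call starts at the first ATG/GTG/TTG codon if one exists,
#' else at the interval start (flagged `partial`). Coordinates are 0-based
#' half-open on the contig forward strand; the stop codon is excluded, so
#' the protein length is exactly `(end - start) / 3`. Calls may overlap
#' across frames.
#'
#' @param contigs contig data frame (`id`, `sequence`) or named character
#'   vector.
#' @param config an [annotation_config()].
#' @return gene-call data frame: `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `partial`, `aa_sequence`.
#' @export
call_orfs <- function(contigs, config = annotation_config()) {
  if (is.character(contigs)) {
    contigs <- data.frame(id = names(contigs), sequence = unname(contigs))
  }
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    calls <- .orfs_one(contigs$sequence[i], config$min_orf_aa)
    if (nrow(calls)) {
      calls$contig_id <- contigs$id[i]
      out[[length(out) + 1L]] <- calls
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), partial = logical(0),
                      aa_sequence = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start, res$end, res$strand), ,
             drop = FALSE]
  res$gene_id <- sprintf("%s_g%02d", res$contig_id,
                         as.integer(stats::ave(seq_len(nrow(res)),
                                               res$contig_id,
                                               FUN = seq_along)))
  rownames(res) <- NULL
  res[, c("gene_id", "contig_id", "start", "end", "strand", "partial",
          "aa_sequence")]
}

.orfs_one <- function(seq, min_orf_aa) {
  L <- nchar(seq)
  res <- list()
  if (L < 3L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), partial = logical(0),
                      aa_sequence = character(0)))
  }
  starts_ok <- c("ATG", "GTG", "TTG")
  for (strand in c("+", "-")) {
    work <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ln <- ((L - f) %/% 3L) * 3L
      if (ln < 3L) next
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(work, f + 1L, f + ln)),
        if.fuzzy.codon = "X"))
      aa <- strsplit(prot, "")[[1]]
      stops <- which(aa == "*")
      bounds <- c(0L, stops, length(aa) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        i1 <- bounds[b] + 1L
        i2 <- bounds[b + 1L] - 1L
        if (i2 - i1 + 1L < min_orf_aa) next
        codons <- substring(work, f + 3L * (seq(i1, i2) - 1L) + 1L,
                            f + 3L * seq(i1, i2))
        hit <- which(codons %in% starts_ok)
        bounded <- b > 1L || b < length(bounds) - 1L
        if (length(hit)) {
          j <- i1 + hit[1] - 1L
          partial <- FALSE
        } else if (bounded) {
          # no start codon but anchored by a stop: truncated gene
          j <- i1
          partial <- TRUE
        } else {
          # neither a start codon nor a bounding stop anywhere in this
          # frame: not a credible coding signal
          next
        }
        if (i2 - j + 1L < min_orf_aa) next
        w_start <- f + 3L * (j - 1L)
        w_end <- f + 3L * i2
        if (strand == "+") {
          s0 <- w_start; e0 <- w_end
        } else {
          s0 <- L - w_end; e0 <- L - w_start
        }
        res[[length(res) + 1L]] <- data.frame(
          start = s0, end = e0, strand = strand, partial = partial,
          aa_sequence = substr(prot, j, i2))
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), partial = logical(0),
                      aa_sequence = character(0)))
  }
  do.call(rbind, res)
}

#' Stringent re-annotation of gene calls against the panel
#'
#' Each call's protein is searched against the panel with the
#' high-specificity threshold (default e <= 1e-5, identity >= 0.3); the
#' best hit's family is assigned when both thresholds pass, otherwise the
#' call is `unassigned`.
#'
#' @param gene_calls data frame from [call_orfs()].
#' @param panel a [ref_panel()].
#' @param config an [annotation_config()].
#' @return the gene calls with `family`, `best_subject`, `identity`,
#'   `evalue`, `bitscore` columns.
#' @export
annotate_stringent <- function(gene_calls, panel,
                               config = annotation_config()) {
  n <- nrow(gene_calls)
  fam <- rep("unassigned", n)
  subj <- rep(NA_character_, n)
  idt <- rep(NA_real_, n); ev <- rep(NA_real_, n); bs <- rep(NA_real_, n)
  db_res <- sum(nchar(panel$aa))
  for (i in seq_len(n)) {
    b <- .best_panel_hit(gene_calls$aa_sequence[i], panel, db_res)
    if (is.null(b)) next
    subj[i] <- panel$id[b$row]
    idt[i] <- b$identity; ev[i] <- b$evalue; bs[i] <- b$bitscore
    if (b$evalue <= config$stringent_evalue &&
        b$identity >= config$stringent_identity) {
      fam[i] <- panel$family[b$row]
    }
  }
  gene_calls$family <- fam
  gene_calls$best_subject <- subj
  gene_calls$identity <- idt
  gene_calls$evalue <- ev
  gene_calls$bitscore <- bs
  gene_calls
}

# best panel hit of one protein: highest bitscore, ties by identity then id
.best_panel_hit <- function(aa, panel, db_res = sum(nchar(panel$aa)),
                            k_aa = 5L) {
  best <- NULL
  for (s in seq_len(nrow(panel))) {
    a <- seed_and_extend(aa, panel$aa[s], k_aa = k_aa)
    if (is.null(a)) next
    ke <- evalue_ka(a$score, nchar(aa), db_res)
    cand <- list(row = s, score = a$score, bitscore = ke$bitscore,
                 evalue = ke$evalue, identity = a$identity)
    if (is.null(best) || cand$bitscore > best$bitscore ||
        (cand$bitscore == best$bitscore && cand$identity > best$identity) ||
        (cand$bitscore == best$bitscore && cand$identity == best$identity &&
           panel$id[s] < panel$id[best$row])) {
      best <- cand
    }
  }
  best
}

#' Keep only target-family gene calls
#'
#' @param gene_calls annotated gene calls.
#' @param target_families family prefixes retained.
#' @return the targeted subset.
#' @export
targeted_genes <- function(gene_calls, target_families = c("amo", "pmo")) {
  gene_calls[substr(gene_calls$family, 1, 3) %in% target_families, ,
             drop = FALSE]
}

#' Greedy redundancy removal
#'
#' CD-HIT-style greedy incremental clustering: sequences sorted by length
#' descending (ties by id), each joining the first representative it
#' matches at >= `derep_identity` over >= `derep_coverage` of the shorter
#' sequence, else founding a new cluster. Nucleotide comparisons are
#' reverse-complement aware.
#'
#' @param sequences character vector.
#' @param ids identifiers (default from names or positional).
#' @param config an [annotation_config()].
#' @param type `"nt"` or `"aa"`.
#' @return list with `representatives` (ids), `cluster_map` (data frame
#'   `id`, `representative`).
#' @export
dereplicate <- function(sequences, ids = NULL,
                        config = annotation_config(), type = c("nt", "aa")) {
  type <- match.arg(type)
  if (length(sequences) == 0) stop("no sequences to dereplicate")
  if (is.null(ids)) {
    ids <- if (!is.null(names(sequences))) names(sequences) else
      sprintf("seq%04d", seq_along(sequences))
  }
  ord <- order(-nchar(sequences), ids)
  sequences <- sequences[ord]; ids <- ids[ord]
  reps <- integer(0)
  assign_to <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (r in reps) {
      if (.derep_match(sequences[i], sequences[r], config, type)) {
        assign_to[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign_to[i] <- i
    }
  }
  list(representatives = ids[reps],
       cluster_map = data.frame(id = ids, representative = ids[assign_to]))
}

.derep_match <- function(short, long, config, type) {
  Ls <- nchar(short)
  sc <- if (type == "nt") .nt_scoring() else .aa_scoring()
  go <- if (type == "nt") 5L else 11L
  ge <- if (type == "nt") 2L else 1L
  cands <- if (type == "nt") c(short, revcomp(short)) else short
  for (q in cands) {
    a <- .cpp_align(q, long, sc$mat, sc$alphabet, go, ge, FALSE)
    if (a$aln_len == 0) next
    cov <- (a$q_end - a$q_start) / Ls
    if (cov >= config$derep_coverage &&
        a$matches / a$aln_len >= config$derep_identity) {
      return(TRUE)
    }
  }
  FALSE
}
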