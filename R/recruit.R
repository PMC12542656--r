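# Translated homology search of reads against the reference panel.
# Alignment scoring is BLOSUM62 with affine gaps (existence 11, extension 1)
# and Karlin-Altschul statistics with the standard gapped constants
# (lambda = 0.267, K = 0.041); seeding is by shared exact amino-acid
# k-mers (k = 5), after which the seeded pair is aligned by full
# Smith-Waterman so reported scores are exact.

.score_cache <- new.env(parent = emptyenv())

# BLOSUM62 (from Biostrings) reordered so X is last (unknown residues map
# there and never count as matches).
.aa_scoring <- function() {
  if (is.null(.score_cache$aa)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    ord <- c(setdiff(rownames(m), c("X")), "X")
    m <- m[ord, ord]
    storage.mode(m) <- "integer"
    .score_cache$aa <- list(mat = m, alphabet = paste(ord, collapse = ""))
  }
  .score_cache$aa
}

.nt_scoring <- function(match = 2L, mismatch = -3L) {
  key <- paste0("nt", match, "_", mismatch)
  if (is.null(.score_cache[[key]])) {
    ab <- c("A", "C", "G", "T", "N")
    m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
    diag(m) <- match
    m["N", ] <- mismatch; m[, "N"] <- mismatch  # N never matches
    storage.mode(m) <- "integer"
    .score_cache[[key]] <- list(mat = m, alphabet = "ACGTN")
  }
  .score_cache[[key]]
}

#' Six-frame translation
#'
#' Standard genetic code (translation table 11); stops become `*`, codons
#' containing N become `X`, reverse frames translate the reverse
#' complement, and trailing partial codons are dropped.
#'
#' @param dna a single DNA string over ACGTN.
#' @return named character vector of 6 protein strings
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
translate_six_frames <- function(dna) {
  frames <- .six_frames(dna)
  setNames(vapply(frames, `[`, character(1), 1),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# vectorised six-frame translation for a set of sequences;
# returns list of 6 character vectors in frame order +1,+2,+3,-1,-2,-3
.six_frames <- function(seqs) {
  n <- length(seqs)
  rc <- revcomp(seqs)
  one <- function(src, off) {
    ln <- nchar(src) - off
    ln <- pmax(0L, (ln %/% 3L) * 3L)
    out <- character(n)
    ok <- ln >= 3L
    if (any(ok)) {
      sub <- substr(src[ok], off + 1L, off + ln[ok])
      out[ok] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(sub), if.fuzzy.codon = "X"))
    }
    out
  }
  c(lapply(0:2, function(f) one(seqs, f)),
    lapply(0:2, function(f) one(rc, f)))
}

#' Bit score and e-value from a raw alignment score
#'
#' Karlin-Altschul statistics for gapped BLOSUM62 alignments:
#' `bitscore = (lambda * S - ln K) / ln 2` and
#' `evalue = m * n * 2^(-bitscore)`.
#'
#' @param raw_score raw substitution-matrix score(s).
#' @param query_len query length in residues (m).
#' @param db_residues total residues in the database (n).
#' @param lambda,K Karlin-Altschul constants.
#' @return data frame with columns `bitscore` and `evalue`.
#' @export
evalue_ka <- function(raw_score, query_len, db_residues,
                      lambda = 0.267, K = 0.041) {
  bits <- (lambda * raw_score - log(K)) / log(2)
  data.frame(bitscore = bits,
             evalue = as.numeric(query_len) * db_residues * 2^(-bits))
}

#' Seeded local alignment of two protein sequences
#'
#' Reports the maximal-scoring local alignment (BLOSUM62, gap existence 11,
#' extension 1) provided the pair shares at least one exact `k_aa`-mer
#' seed; without a seed no alignment is reported (score 0). Whenever a seed
#' exists the reported score equals unrestricted Smith-Waterman, because
#' the extension is a full dynamic program over the seeded pair.
#'
#' @param query_aa,subject_aa protein strings.
#' @param k_aa seed length in residues.
#' @param gap_open,gap_ext affine gap costs.
#' @param seeded if `FALSE`, skip the seed requirement (exhaustive mode).
#' @return `NULL` when no alignment is reported, else a list with `score`,
#'   `matches`, `aln_len`, `gaps`, `identity` and 0-based half-open
#'   `q_start`,`q_end`,`s_start`,`s_end`.
#' @export
seed_and_extend <- function(query_aa, subject_aa, k_aa = 5L,
                            gap_open = 11L, gap_ext = 1L, seeded = TRUE) {
  if (!nzchar(query_aa) || !nzchar(subject_aa)) return(NULL)
  if (seeded && .cpp_shared_kmers(query_aa, subject_aa, k_aa) == 0) {
    return(NULL)
  }
  sc <- .aa_scoring()
  a <- .cpp_align(query_aa, subject_aa, sc$mat, sc$alphabet,
                  gap_open, gap_ext, FALSE)
  if (a$score <= 0) return(NULL)
  a$gaps <- a$aln_len - (a$q_end - a$q_start)  +
    a$aln_len - (a$s_end - a$s_start)
  a$identity <- a$matches / a$aln_len
  a
}

# seed index: environment mapping each aa k-mer to panel row indices
.panel_seed_index <- function(panel, k_aa) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(panel))) {
    for (km in unique(kmers_of(panel$aa[i], k_aa))) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  idx
}

#' Recruit reads homologous to the reference panel
#'
#' Translated best-hit search of every read (six frames) against the panel.
#' A read is recruited iff its best hit (highest bit score; ties broken by
#' higher identity, then lexicographic subject id) passes the mode's
#' e-value cutoff, has identity >= `min_identity`, and belongs to a target
#' family. `relaxed` mode (e <= 1) is the over-inclusive capture used
#' before assembly; `stringent` mode (e <= 1e-5) is the high-specificity
#' re-annotation threshold.
#'
#' @param reads a read-set data frame ([read_fastq()]).
#' @param panel a [ref_panel()].
#' @param mode `"relaxed"` or `"stringent"`.
#' @param min_identity identity threshold (fraction of alignment columns).
#' @param evalue_max override the mode's e-value cutoff.
#' @param target_families families counted as targets (prefix match).
#' @param k_aa seed length.
#' @param seeded use k-mer seeding (see [seed_and_extend()]).
#' @param mate_rescue also recruit the unrecruited partner of every
#'   recruited read (off by default; mates are otherwise treated
#'   independently).
#' @return list of class `recruit_result`: `reads` (recruited subset),
#'   `hits` (their best hits with assigned `family`), and `all_hits`
#'   (best hit per read that had any alignment).
#' @export
recruit_reads <- function(reads, panel, mode = c("relaxed", "stringent"),
                          min_identity = 0.3, evalue_max = NULL,
                          target_families = c("amo", "pmo"), k_aa = 5L,
                          seeded = TRUE, mate_rescue = FALSE) {
  mode <- match.arg(mode)
  if (is.null(panel) || nrow(panel) == 0) stop("empty reference panel")
  if (is.null(evalue_max)) {
    evalue_max <- if (mode == "relaxed") 1 else 1e-5
  }
  db_res <- sum(nchar(panel$aa))
  idx <- if (seeded) .panel_seed_index(panel, k_aa) else NULL
  sc <- .aa_scoring()
  frames <- .six_frames(reads$sequence)
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  n <- nrow(reads)
  best <- vector("list", n)
  for (i in seq_len(n)) {
    b <- NULL
    for (f in 1:6) {
      prot <- frames[[f]][i]
      if (nchar(prot) < k_aa) next
      cand <- if (seeded) {
        u <- unique(unlist(lapply(unique(kmers_of(prot, k_aa)),
                                  function(km) idx[[km]]), use.names = FALSE))
        u
      } else seq_len(nrow(panel))
      if (length(cand) == 0) next
      for (s in cand) {
        a <- .cpp_align(prot, panel$aa[s], sc$mat, sc$alphabet, 11L, 1L, FALSE)
        if (a$score <= 0) next
        ke <- evalue_ka(a$score, nchar(prot), db_res)
        id <- a$matches / a$aln_len
        better <- is.null(b) ||
          ke$bitscore > b$bitscore ||
          (ke$bitscore == b$bitscore && id > b$identity) ||
          (ke$bitscore == b$bitscore && id == b$identity &&
             panel$id[s] < b$subject_id)
        if (better) {
          b <- list(query_id = reads$id[i], subject_id = panel$id[s],
                    subject_row = s, frame = frame_names[f],
                    raw_score = a$score, bitscore = ke$bitscore,
                    evalue = ke$evalue, identity = id,
                    matches = a$matches, aln_len = a$aln_len,
                    gaps = a$aln_len - (a$q_end - a$q_start) +
                      a$aln_len - (a$s_end - a$s_start),
                    q_start = a$q_start, q_end = a$q_end,
                    s_start = a$s_start, s_end = a$s_end)
        }
      }
    }
    best[[i]] <- b
  }
  have <- !vapply(best, is.null, logical(1))
  hits <- if (any(have)) {
    do.call(rbind, lapply(best[have], function(b) {
      as.data.frame(b, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(query_id = character(0), subject_id = character(0),
               subject_row = integer(0), frame = character(0),
               raw_score = numeric(0), bitscore = numeric(0),
               evalue = numeric(0), identity = numeric(0),
               matches = integer(0), aln_len = integer(0), gaps = integer(0),
               q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0))
  }
  if (nrow(hits)) {
    hits$family <- panel$family[hits$subject_row]
    fam_prefix <- substr(hits$family, 1, 3)
    hits$recruited <- hits$evalue <= evalue_max &
      hits$identity >= min_identity &
      fam_prefix %in% target_families
  } else {
    hits$family <- character(0)
    hits$recruited <- logical(0)
  }
  rec_ids <- hits$query_id[hits$recruited]
  if (mate_rescue && any(reads$mate %in% c("1", "2"))) {
    base <- sub("/[12]$", "", reads$id)
    rec_base <- unique(base[reads$id %in% rec_ids])
    rec_ids <- union(rec_ids,
                     reads$id[base %in% rec_base &
                                reads$mate %in% c("1", "2")])
  }
  res <- list(reads = reads[reads$id %in% rec_ids, , drop = FALSE],
              hits = hits[hits$recruited, , drop = FALSE],
              all_hits = hits,
              mode = mode, evalue_max = evalue_max,
              min_identity = min_identity)
  class(res) <- "recruit_result"
  res
}

#' @export
print.recruit_result <- function(x, ...) {
  cat(sprintf("recruit_result: %d/%d reads recruited (mode %s, e<=%g, id>=%g)\n",
              nrow(x$reads), nrow(x$all_hits), x$mode, x$evalue_max,
              x$min_identity))
  if (nrow(x$hits)) {
    print(table(x$hits$family))
  }
  invisible(x)
}
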