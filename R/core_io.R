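# Readers and writers for the plain-text formats the toolkit exchanges:
# FASTA, FASTQ (gzip-transparent), the sample-design TSV, GFF3 and hit
# tables. Coordinates are 0-based half-open internally everywhere;
# conversion to 1-based inclusive happens only at the GFF3 boundary.

#' Read a FASTA file
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return data frame with columns `id` (header token before the first
#'   whitespace), `desc` (full header) and `sequence` (uppercased), in file
#'   order. An empty file yields a zero-row frame with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(0), desc = character(0),
                      sequence = character(0)))
  }
  if (!startsWith(trimws(first[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: sequence line before header at line %d of %s",
                 nonblank[1], path))
  }
  ss <- Biostrings::readBStringSet(path)
  desc <- names(ss)
  data.frame(id = sub("\\s.*$", "", desc),
             desc = desc,
             sequence = toupper(as.character(ss)),
             row.names = NULL)
}

#' Write a FASTA file
#'
#' @param ids sequence identifiers (full headers allowed).
#' @param sequences character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(ids, sequences, path, width = 70L) {
  stopifnot(length(ids) == length(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- sequences[i]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Four-line records, plain or gzipped. Mate labels are parsed from
#' `/1`-`/2` id suffixes or `1:`/`2:` comment prefixes.
#'
#' @param path FASTQ path (`.gz` transparent).
#' @param sample_id sample of origin recorded on every read.
#' @return data frame (`read_set`) with columns `id`, `sample_id`,
#'   `sequence`, `mate` (`"1"`, `"2"` or `"unpaired"`) and `quality`.
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    return(data.frame(id = character(0), sample_id = character(0),
                      sequence = character(0), mate = character(0),
                      quality = character(0)))
  }
  if (length(lines) %% 4 != 0) {
    stop(sprintf("truncated FASTQ record at record %d of %s",
                 length(lines) %/% 4 + 1, path))
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- toupper(lines[seq(2, length(lines), by = 4)])
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("FASTQ sequence/quality length mismatch for record '%s'",
                 sub("^@", "", hdr[bad[1]])))
  }
  if (any(!startsWith(hdr, "@"))) {
    stop("malformed FASTQ header (missing '@') in ", path)
  }
  full <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", full)
  comment <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  mate <- rep("unpaired", length(id))
  mate[grepl("/1$", id)] <- "1"
  mate[grepl("/2$", id)] <- "2"
  mate[mate == "unpaired" & grepl("^1:", comment)] <- "1"
  mate[mate == "unpaired" & grepl("^2:", comment)] <- "2"
  data.frame(id = id, sample_id = rep(sample_id, length(id)),
             sequence = seq, mate = mate, quality = qual)
}

#' Write a read set as FASTQ
#'
#' @param reads a read-set data frame (see [read_fastq()]).
#' @param path output path; a `.gz` suffix selects gzip.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- reads$quality
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  qual[is.na(qual)] <- strrep("I", nchar(reads$sequence[is.na(qual)]))
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", qual)
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Read / write the sample-design table
#'
#' TSV with columns `sample_id`, `x`, `y` (metres from the central point)
#' and `ring_radius` (metres; 0 for the central sample).
#'
#' @param path TSV path.
#' @return data frame (`sample_design`).
#' @export
read_design <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "x", "y", "ring_radius")
  if (!all(need %in% names(d))) {
    stop("design table must have columns: ", paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_design
#' @param design a sample-design data frame.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene and operon calls as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive convention of GFF3. Operons are written as `operon` features
#' with child `gene` features linked through `Parent`.
#'
#' @param gene_calls data frame of gene calls (`contig_id`, `start`, `end`,
#'   `strand`, `family`, optional `gene_id`, `partial`).
#' @param path output path.
#' @param operon_calls optional operon table (`operon_id`, `contig_id`,
#'   `start`, `end`, `gene_ids` comma-separated).
#' @export
write_gff3 <- function(gene_calls, path, operon_calls = NULL) {
  lines <- "##gff-version 3"
  esc <- function(x) gsub("[;=,\t]", "_", x)
  if (!is.null(operon_calls) && nrow(operon_calls)) {
    op <- sprintf("%s\tgenetarget\toperon\t%d\t%d\t.\t%s\t.\tID=%s;completeness=%s",
                  operon_calls$contig_id, operon_calls$start + 1L,
                  operon_calls$end, ".",
                  esc(operon_calls$operon_id),
                  esc(operon_calls$completeness_class))
    lines <- c(lines, op)
  }
  if (nrow(gene_calls)) {
    ids <- if (!is.null(gene_calls$gene_id)) gene_calls$gene_id else
      sprintf("gene%04d", seq_len(nrow(gene_calls)))
    parent <- rep("", nrow(gene_calls))
    if (!is.null(operon_calls) && nrow(operon_calls) &&
        !is.null(operon_calls$gene_ids)) {
      for (i in seq_len(nrow(operon_calls))) {
        members <- strsplit(operon_calls$gene_ids[i], ",")[[1]]
        parent[ids %in% members] <-
          paste0(";Parent=", esc(operon_calls$operon_id[i]))
      }
    }
    fam <- if (!is.null(gene_calls$family)) gene_calls$family else "unassigned"
    g <- sprintf("%s\tgenetarget\tgene\t%d\t%d\t.\t%s\t0\tID=%s;family=%s%s",
                 gene_calls$contig_id, gene_calls$start + 1L, gene_calls$end,
                 gene_calls$strand, esc(ids), esc(fam), parent)
    lines <- c(lines, g)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return list with data frames `genes` and `operons`, coordinates
#'   converted back to 0-based half-open.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(list(genes = data.frame(contig_id = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0), gene_id = character(0),
                                   family = character(0), parent = character(0)),
                operons = data.frame(operon_id = character(0),
                                     contig_id = character(0),
                                     start = integer(0), end = integer(0),
                                     completeness_class = character(0))))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tab <- do.call(rbind, f)
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0,
           sub(paste0("^.*", key, "="), "", m), NA_character_)
  }
  atr <- tab[, 9]
  type <- tab[, 3]
  genes <- data.frame(
    contig_id = tab[type == "gene", 1],
    start = as.integer(tab[type == "gene", 4]) - 1L,
    end = as.integer(tab[type == "gene", 5]),
    strand = tab[type == "gene", 7],
    gene_id = vapply(atr[type == "gene"], attr_get, character(1), key = "ID"),
    family = vapply(atr[type == "gene"], attr_get, character(1), key = "family"),
    parent = vapply(atr[type == "gene"], function(a) {
      p <- attr_get(a, "Parent"); if (is.na(p)) "" else p
    }, character(1)),
    row.names = NULL)
  operons <- data.frame(
    operon_id = vapply(atr[type == "operon"], attr_get, character(1), key = "ID"),
    contig_id = tab[type == "operon", 1],
    start = as.integer(tab[type == "operon", 4]) - 1L,
    end = as.integer(tab[type == "operon", 5]),
    completeness_class = vapply(atr[type == "operon"], attr_get, character(1),
                                key = "completeness"),
    row.names = NULL)
  list(genes = genes, operons = operons)
}

#' Construct and validate a reference panel
#'
#' A reference panel is the labelled protein database standing in for a
#' curated functional-gene database: one row per reference protein with a
#' gene-family label (`amoA`..`amoX`, `pmoA`..`pmoC`, `other`), a domain
#' label (`archaea`, `bacteria`, `unknown`) and an optional clade label
#' (e.g. `NP-gamma`, `NT-alpha`) used for nearest-reference classification.
#'
#' @param id unique identifiers.
#' @param family gene-family labels.
#' @param domain domain labels.
#' @param clade clade labels (NA allowed).
#' @param aa protein sequences (>= 30 residues over the 20 standard amino
#'   acids plus X).
#' @param nt optional nucleotide CDS for each record (used as the
#'   nucleotide reference for chimera screening and genome planting).
#' @return data frame of class `ref_panel`.
#' @export
ref_panel <- function(id, family, domain = "unknown", clade = NA_character_,
                      aa, nt = NA_character_) {
  fam_ok <- c("amoA", "amoB", "amoC", "amoD", "amoE", "amoX",
              "pmoA", "pmoB", "pmoC", "other")
  n <- length(id)
  family <- rep_len(family, n); domain <- rep_len(domain, n)
  clade <- rep_len(clade, n); nt <- rep_len(nt, n)
  if (anyDuplicated(id)) stop("panel ids must be unique")
  if (!all(family %in% fam_ok)) {
    stop("unknown family label(s): ",
         paste(setdiff(family, fam_ok), collapse = ", "))
  }
  if (!all(domain %in% c("archaea", "bacteria", "unknown"))) {
    stop("domain labels must be archaea/bacteria/unknown")
  }
  if (any(nchar(aa) < 30)) stop("panel proteins must be >= 30 residues")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", aa))) {
    stop("panel proteins may contain only the 20 standard residues plus X")
  }
  out <- data.frame(id = id, family = family, domain = domain, clade = clade,
                    aa = toupper(aa), nt = nt, row.names = NULL)
  class(out) <- c("ref_panel", "data.frame")
  out
}

#' Read / write a reference panel FASTA
#'
#' Labels travel in the header as `id|family|domain|clade` with `NA`
#' placeholders, so a panel FASTA is self-describing.
#'
#' @param path FASTA path of panel proteins.
#' @param nt_path optional FASTA of matching nucleotide CDS (same ids).
#' @return a `ref_panel`.
#' @export
read_reference_panel <- function(path, nt_path = NULL) {
  fa <- read_fasta(path)
  if (nrow(fa) == 0) stop("empty reference panel: ", path)
  parts <- strsplit(fa$id, "|", fixed = TRUE)
  get <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[i] else "NA"
  }, character(1))
  id <- get(1); family <- get(2); domain <- get(3); clade <- get(4)
  domain[domain == "NA"] <- "unknown"
  clade[clade == "NA"] <- NA_character_
  nt <- NA_character_
  if (!is.null(nt_path)) {
    fn <- read_fasta(nt_path)
    fid <- vapply(strsplit(fn$id, "|", fixed = TRUE), `[`, character(1), 1)
    nt <- fn$sequence[match(id, fid)]
  }
  ref_panel(id = id, family = family, domain = domain, clade = clade,
            aa = fa$sequence, nt = nt)
}

#' @rdname read_reference_panel
#' @param panel a `ref_panel`.
#' @export
write_reference_panel <- function(panel, path, nt_path = NULL) {
  hdr <- paste(panel$id, panel$family, panel$domain,
               ifelse(is.na(panel$clade), "NA", panel$clade), sep = "|")
  write_fasta(hdr, panel$aa, path)
  if (!is.null(nt_path)) {
    keep <- !is.na(panel$nt)
    write_fasta(hdr[keep], panel$nt[keep], nt_path)
  }
  invisible(path)
}

#' Write a hit table
#'
#' Twelve-column tabular alignment convention: query, subject, identity,
#' alignment length, mismatches, gap opens, query/subject start and end
#' (1-based inclusive on output), e-value, bit score, plus a `frame` column.
#'
#' @param hits hit data frame from [recruit_reads()] or
#'   [annotate_stringent()].
#' @param path output TSV.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    query = hits$query_id, subject = hits$subject_id,
    identity = round(hits$identity, 4), aln_len = hits$aln_len,
    mismatches = hits$aln_len - hits$matches - hits$gaps,
    gaps = hits$gaps,
    q_start = hits$q_start + 1L, q_end = hits$q_end,
    s_start = hits$s_start + 1L, s_end = hits$s_end,
    evalue = signif(hits$evalue, 4), bitscore = round(hits$bitscore, 1),
    frame = hits$frame)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
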