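# Orchestration of the full targeted-assembly route: relaxed recruitment,
# multi-k assembly, ORF calling, stringent re-annotation, dereplication,
# chimera screening, operon detection and the diversity statistics, with
# every stage's outputs written and a deterministic manifest.

#' Pipeline configuration
#'
#' @param reads read-set data frame, or character vector of FASTQ paths
#'   (sample id taken from the file name).
#' @param panel a [ref_panel()] or path to a panel FASTA.
#' @param design optional sample-design data frame or TSV path.
#' @param out_dir output directory.
#' @param seed seed propagated to all stochastic steps.
#' @param assembly an [assembly_config()].
#' @param annotation an [annotation_config()].
#' @param chimera a [chimera_params()].
#' @param max_gap operon clustering gap (bp).
#' @param per_sample assemble each sample's recruited reads separately
#'   instead of pooling (single-sample-style arm).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, panel, design = NULL,
                            out_dir = tempfile("genetarget_run_"),
                            seed = 1L,
                            assembly = assembly_config(),
                            annotation = annotation_config(),
                            chimera = chimera_params(),
                            max_gap = 500L, per_sample = FALSE) {
  if (is.character(reads)) {
    missing <- reads[!file.exists(reads)]
    if (length(missing)) stop("read file(s) not found: ",
                              paste(missing, collapse = ", "))
  }
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("panel file not found: ", panel)
  } else if (is.null(panel) || nrow(panel) == 0) {
    stop("a non-empty reference panel is required")
  }
  if (is.character(design) && !file.exists(design)) {
    stop("design file not found: ", design)
  }
  structure(list(reads = reads, panel = panel, design = design,
                 out_dir = out_dir, seed = as.integer(seed),
                 assembly = assembly, annotation = annotation,
                 chimera = chimera, max_gap = max_gap,
                 per_sample = per_sample),
            class = "pipeline_config")
}

# nucleotide sequence of a gene call on its contig (forward-strand coords)
gene_nt_sequences <- function(gene_calls, contigs) {
  vapply(seq_len(nrow(gene_calls)), function(i) {
    ctg <- contigs$sequence[match(gene_calls$contig_id[i], contigs$id)]
    s <- substr(ctg, gene_calls$start[i] + 1L, gene_calls$end[i])
    if (gene_calls$strand[i] == "-") revcomp(s) else s
  }, character(1))
}

#' Run the targeted-assembly pipeline
#'
#' Executes recruit(relaxed) -> assemble (multi-k) -> call_orfs ->
#' annotate(stringent) -> dereplicate -> chimera (ref + de novo) ->
#' detect_operons -> diversity statistics, writing every stage's outputs
#' under the configured directory together with a manifest (parameters,
#' seed, file checksums, stable manifest hash). Any stage failure aborts
#' with the stage name; earlier outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @return list of class `targeted_run` with all stage results and the
#'   manifest.
#' @export
run_targeted <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }
  set.seed(config$seed)

  panel <- if (is.character(config$panel)) {
    nt_path <- sub("\\.faa$|\\.fasta$", ".fna", config$panel)
    read_reference_panel(config$panel,
                         nt_path = if (file.exists(nt_path) &&
                                       nt_path != config$panel) nt_path)
  } else config$panel
  reads <- if (is.character(config$reads)) {
    do.call(rbind, lapply(config$reads, function(p) {
      read_fastq(p, sample_id = sub("\\.(fastq|fq)(\\.gz)?$", "", basename(p)))
    }))
  } else config$reads
  design <- if (is.character(config$design)) read_design(config$design)
    else config$design

  rec <- stage("recruit", recruit_reads(reads, panel, mode = "relaxed"))
  write_fasta(rec$reads$id, rec$reads$sequence,
              file.path(out, "recruited.fasta"))
  write_hits(rec$hits, file.path(out, "hits.tsv"))

  contigs <- stage("assemble", {
    if (config$per_sample && !is.null(rec$reads$sample_id)) {
      pieces <- lapply(split(rec$reads, rec$reads$sample_id),
                       assemble_multi_k, config = config$assembly)
      pool <- do.call(rbind, lapply(pieces, function(p) {
        p[, c("sequence", "k_origin", "mean_coverage")]
      }))
      merged <- .consensus_merge(pool, config$assembly$merge_identity)
      merged <- merged[nchar(merged$sequence) >=
                         config$assembly$min_contig_len, , drop = FALSE]
      if (nrow(merged)) {
        ordm <- order(-nchar(merged$sequence), merged$sequence)
        merged <- merged[ordm, , drop = FALSE]
        merged$id <- sprintf("ctg%05d", seq_len(nrow(merged)))
      } else merged$id <- character(0)
      rownames(merged) <- NULL
      merged[, c("id", "sequence", "k_origin", "mean_coverage")]
    } else {
      assemble_multi_k(rec$reads, config$assembly)
    }
  })
  write_fasta(sprintf("%s k_origin=%s cov=%.1f", contigs$id,
                      contigs$k_origin, contigs$mean_coverage),
              contigs$sequence, file.path(out, "contigs.fasta"))

  calls <- stage("call_orfs", call_orfs(contigs, config$annotation))
  ann <- stage("annotate", annotate_stringent(calls, panel,
                                              config$annotation))
  targeted <- targeted_genes(ann)
  targeted$nt_sequence <- if (nrow(targeted))
    gene_nt_sequences(targeted, contigs) else character(0)

  derep <- stage("dereplicate", {
    if (nrow(targeted)) {
      dereplicate(setNames(targeted$nt_sequence, targeted$gene_id),
                  config = config$annotation, type = "nt")
    } else list(representatives = character(0),
                cluster_map = data.frame(id = character(0),
                                         representative = character(0)))
  })
  reps <- targeted[targeted$gene_id %in% derep$representatives, ,
                   drop = FALSE]
  write_fasta(sprintf("%s family=%s", reps$gene_id, reps$family),
              reps$nt_sequence, file.path(out, "genes.fasta"))
  write.table(ann[, setdiff(names(ann), "nt_sequence")],
              file.path(out, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  verdicts <- stage("chimera", {
    refdb <- panel[!is.na(panel$nt), , drop = FALSE]
    v_ref <- if (nrow(reps) && nrow(refdb) >= 2) {
      detect_ref(data.frame(id = reps$gene_id, sequence = reps$nt_sequence),
                 data.frame(id = refdb$id, sequence = refdb$nt),
                 config$chimera)
    } else NULL
    v_dn <- if (nrow(reps) >= 2) {
      cov <- contigs$mean_coverage[match(reps$contig_id, contigs$id)]
      detect_denovo(data.frame(id = reps$gene_id,
                               sequence = reps$nt_sequence,
                               coverage = cov), config$chimera)
    } else NULL
    list(ref = v_ref, denovo = v_dn)
  })
  if (!is.null(verdicts$ref)) {
    write.table(verdicts$ref, file.path(out, "chimera_ref.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(verdicts$denovo)) {
    write.table(verdicts$denovo, file.path(out, "chimera_denovo.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  operons <- stage("operons", detect_operons(ann, max_gap = config$max_gap))
  write.table(operons, file.path(out, "operons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gff3(ann, file.path(out, "calls.gff3"), operon_calls = operons)

  divers <- stage("diversity", {
    stats <- assembly_stats(nchar(contigs$sequence))
    res <- list(assembly_stats = stats)
    if (nrow(reps) > 0) {
      mp <- map_reads(reads, setNames(reps$nt_sequence, reps$gene_id))
      res$matrix <- mp$matrix
      write.table(mp$matrix, file.path(out, "matrix.tsv"), sep = "\t",
                  quote = FALSE)
      if (!is.null(design) && nrow(mp$matrix) >= 4 && ncol(mp$matrix) >= 2 &&
          sum(rowSums(mp$matrix) > 0) >= 4) {
        res$ddr <- tryCatch(fit_ddr(mp$matrix, design),
                            error = function(e) NULL)
        res$tar <- tryCatch(fit_tar(mp$matrix, design),
                            error = function(e) NULL)
      }
      arch_A <- reps[reps$family == "amoA", , drop = FALSE]
      if (nrow(arch_A) && any(!is.na(panel$clade))) {
        cl <- assign_clade(arch_A$aa_sequence, panel)
        cl$gene_id <- arch_A$gene_id
        res$clades <- cl
        write.table(cl, file.path(out, "clades.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      if (nrow(reps) >= 3) {
        res$tree <- nj_tree(setNames(reps$aa_sequence, reps$gene_id),
                            type = "aa", path = file.path(out, "tree.nwk"))
      }
    }
    res
  })

  files <- sort(list.files(out, full.names = TRUE, recursive = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "genetarget",
    version = as.character(utils::packageVersion("genetarget")),
    seed = config$seed,
    stages = stages,
    parameters = list(k_list = config$assembly$k_list,
                      min_contig_len = config$assembly$min_contig_len,
                      stringent_evalue = config$annotation$stringent_evalue,
                      derep_identity = config$annotation$derep_identity,
                      max_gap = config$max_gap,
                      per_sample = config$per_sample),
    files = as.list(setNames(unname(sums), basename(names(sums)))),
    manifest_hash = unname(tools::md5sum(
      written_to <- {
        tmp <- tempfile()
        writeLines(paste(basename(names(sums)), unname(sums)), tmp)
        tmp
      }))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- list(recruit = rec, contigs = contigs, gene_calls = ann,
              targeted = targeted, derep = derep, representatives = reps,
              chimera = verdicts, operons = operons, diversity = divers,
              manifest = manifest, out_dir = out)
  class(res) <- "targeted_run"
  res
}

#' @export
print.targeted_run <- function(x, ...) {
  cat("targeted-assembly run:", x$out_dir, "\n")
  cat(sprintf("  %d reads recruited, %d contigs, %d targeted genes (%d reps), %d operon calls\n",
              nrow(x$recruit$reads), nrow(x$contigs), nrow(x$targeted),
              nrow(x$representatives), nrow(x$operons)))
  invisible(x)
}

#' Evaluate a run against planted ground truth
#'
#' @param run a `targeted_run`.
#' @param sim output of [simulate_metagenome()] (or a compatible list with
#'   `genomes`, `origin`, `reads`, `config`).
#' @return list of metrics: recruiter recall (error-free target reads fully
#'   inside a planted CDS) and precision (recruited reads of target
#'   origin), per-family gene counts vs truth, and the fraction of planted
#'   complete operons recovered with the correct completeness class.
#' @export
evaluate_against_truth <- function(run, sim) {
  origin <- sim$origin
  feats <- sim$genomes$features
  rl <- sim$config$read_length
  target_feat <- feats[substr(feats$family, 1, 3) %in% c("amo", "pmo"), ,
                       drop = FALSE]
  inside <- rep(FALSE, nrow(origin))
  if (!is.null(origin$pos)) {
    for (i in which(origin$origin != "background")) {
      f <- target_feat[target_feat$genome_id == origin$origin[i], ,
                       drop = FALSE]
      inside[i] <- any(origin$pos[i] - 1L >= f$start &
                         origin$pos[i] - 1L + rl <= f$end)
    }
  }
  recruited <- origin$read_id %in% run$recruit$reads$id
  recall <- if (any(inside)) mean(recruited[inside]) else NA_real_
  precision <- if (any(recruited)) {
    mean(origin$origin[recruited] != "background")
  } else NA_real_
  fam_truth <- table(target_feat$family)
  fam_found <- table(run$representatives$family)
  planted_class <- vapply(split(feats[feats$in_operon, ],
                                feats$genome_id[feats$in_operon]),
                          function(f) .completeness_class(f$family),
                          character(1))
  complete <- planted_class[!startsWith(planted_class, "partial")]
  recovered <- vapply(names(complete), function(g) {
    complete[[g]] %in% run$operons$completeness_class
  }, logical(1))
  list(recruit_recall = recall, recruit_precision = precision,
       family_counts_truth = fam_truth, family_counts_found = fam_found,
       planted_operon_classes = planted_class,
       operon_class_recovered = recovered,
       operon_recovery = if (length(recovered)) mean(recovered) else NA_real_)
}
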