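# Synthetic-metagenome generator with planted ground truth: a labelled
# reference panel emulating a curated amo/pmo protein database, genomes
# carrying planted amo operons, a nested ring sampling design, a spatial
# community with calibrated distance-decay and taxa-area slopes, seeded
# read simulation, and planted chimeras. Identical configurations
# (including the seed) reproduce byte-identical outputs.

#' Synthetic-data configuration
#'
#' Defaults describe a realistic intertidal-sediment survey at desk
#' scale: a 25-sample nested ring design, 150-bp reads,
#' substitution-only sequencing error, and planted spatial-scaling
#' slopes typical of bacterial amo communities at this extent
#' (DDR d = -0.045, TAR z = 0.016).
#'
#' @param seed integer seed driving every random choice.
#' @param n_ref_families named integer vector of per-family reference
#'   counts.
#' @param n_genomes genomes carrying planted operons.
#' @param operon_layouts subunit orders, comma-separated.
#' @param intergenic_gap_bp length-2 range of intergenic gaps.
#' @param read_length read length (bp).
#' @param coverage_per_sample fold coverage of the genome set per sample.
#' @param error_rate per-base substitution probability (<= 0.05).
#' @param background_fraction fraction of reads from random non-target DNA.
#' @param ddr_slope_true planted distance-decay slope d.
#' @param tar_z_true planted taxa-area exponent z.
#' @param ddr_intercept similarity intercept of the planted decay line.
#' @param within_divergence,clade_divergence,paralog_divergence per-branch
#'   substitution fractions of the panel generator.
#' @param radii ring radii of the sampling design (m).
#' @param n_per_ring samples per ring (plus one central sample).
#' @param plant_neighbor also plant a non-amo decoy gene near each operon.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_ref_families = c(amoA = 8L, amoB = 4L, amoC = 4L,
                                            amoX = 3L, amoD = 2L, amoE = 2L,
                                            pmoA = 4L, pmoB = 3L, pmoC = 3L,
                                            other = 3L),
                         n_genomes = 6L,
                         operon_layouts = c("amoC,amoA,amoB",
                                            "amoC,amoA,amoB,amoX",
                                            "amoC,amoA,amoB,amoD,amoE"),
                         intergenic_gap_bp = c(20L, 120L),
                         read_length = 150L,
                         coverage_per_sample = 2,
                         error_rate = 0.005,
                         background_fraction = 0.3,
                         ddr_slope_true = -0.045,
                         tar_z_true = 0.016,
                         ddr_intercept = 0.55,
                         within_divergence = 0.12,
                         clade_divergence = 0.08,
                         paralog_divergence = 0.30,
                         radii = c(5, 10, 20, 50, 100, 200),
                         n_per_ring = 4L,
                         plant_neighbor = TRUE) {
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]")
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must be in [0, 1)")
  }
  if (within_divergence >= paralog_divergence) {
    stop("within-family divergence must be below the paralog divergence")
  }
  if (any(n_ref_families < 0) || n_genomes < 0) stop("counts must be >= 0")
  structure(list(seed = as.integer(seed), n_ref_families = n_ref_families,
                 n_genomes = as.integer(n_genomes),
                 operon_layouts = operon_layouts,
                 intergenic_gap_bp = intergenic_gap_bp,
                 read_length = as.integer(read_length),
                 coverage_per_sample = coverage_per_sample,
                 error_rate = error_rate,
                 background_fraction = background_fraction,
                 ddr_slope_true = ddr_slope_true, tar_z_true = tar_z_true,
                 ddr_intercept = ddr_intercept,
                 within_divergence = within_divergence,
                 clade_divergence = clade_divergence,
                 paralog_divergence = paralog_divergence,
                 radii = radii, n_per_ring = as.integer(n_per_ring),
                 plant_neighbor = plant_neighbor),
            class = "synth_config")
}

.residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_protein <- function(len) {
  # proteins begin with the initiator methionine
  paste0("M", paste(sample(.residues, len - 1L, replace = TRUE),
                    collapse = ""))
}

.mutate_protein <- function(aa, rate) {
  v <- strsplit(aa, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  hit <- hit[hit > 1L] # keep the initiator M
  for (i in hit) v[i] <- sample(setdiff(.residues, v[i]), 1)
  paste(v, collapse = "")
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate & v %in% c("A", "C", "G", "T"))
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

# reverse-translate a protein with uniform synonymous codon choice and a
# random stop codon appended
.reverse_translate <- function(aa, stop_codon = TRUE) {
  tab <- .codon_table()
  v <- strsplit(aa, "")[[1]]
  codons <- vapply(v, function(r) {
    cs <- tab[[r]]
    cs[sample.int(length(cs), 1)]
  }, character(1))
  out <- paste(codons, collapse = "")
  if (stop_codon) out <- paste0(out, sample(c("TAA", "TAG", "TGA"), 1))
  out
}

#' Generate a labelled synthetic reference panel
#'
#' Family ancestor proteins (A subunits 250 +/- 30 residues, others
#' 200 +/- 30) are drawn from a uniform residue model; amo/pmo paralog
#' pairs share a superfamily ancestor so their members sit at 40-50%
#' identity, while within-family members diverge by point substitution and
#' stay above 60% identity. Archaeal amoA members carry clade labels
#' (NP-*/NT-*) arranged as clade subtrees. Every record also gets a
#' reverse-translated nucleotide CDS.
#'
#' @param config a [synth_config()].
#' @return a [ref_panel()].
#' @export
make_reference_panel <- function(config = synth_config()) {
  set.seed(config$seed + 101L)
  nf <- config$n_ref_families
  fams <- names(nf)[nf > 0]
  len_of <- function(fam) {
    mu <- if (grepl("A$", fam)) 250 else 200
    max(60L, as.integer(round(rnorm(1, mu, 30))))
  }
  supers <- list(A = c("amoA", "pmoA"), B = c("amoB", "pmoB"),
                 C = c("amoC", "pmoC"))
  anc <- list()
  for (su in names(supers)) {
    present <- intersect(supers[[su]], fams)
    if (!length(present)) next
    root <- .random_protein(len_of(present[1]))
    for (f in present) {
      anc[[f]] <- .mutate_protein(root, config$paralog_divergence / 2)
    }
  }
  for (f in setdiff(fams, unlist(supers))) {
    anc[[f]] <- .random_protein(len_of(f))
  }
  clades <- c("NP-gamma", "NP-zeta", "NP-eta", "NT-alpha", "NT-gamma")
  rows <- list()
  for (f in fams) {
    n <- nf[[f]]
    if (f == "amoA") {
      n_arch <- min(n, max(2L, n - 2L))
      arch_anc <- .mutate_protein(anc[[f]], config$within_divergence / 2)
      bact_anc <- .mutate_protein(anc[[f]], config$within_divergence / 2)
      clade_anc <- lapply(clades, function(cl) {
        .mutate_protein(arch_anc, config$clade_divergence)
      })
      names(clade_anc) <- clades
      for (i in seq_len(n)) {
        if (i <= n_arch) {
          cl <- clades[(i - 1L) %% length(clades) + 1L]
          aa <- .mutate_protein(clade_anc[[cl]],
                                config$clade_divergence / 2)
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("amoA_%02d", i), family = "amoA",
            domain = "archaea", clade = cl, aa = aa)
        } else {
          aa <- .mutate_protein(bact_anc, config$within_divergence / 2)
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("amoA_%02d", i), family = "amoA",
            domain = "bacteria", clade = NA_character_, aa = aa)
        }
      }
    } else {
      dom <- switch(f, amoB = , amoC = , amoX = "archaea",
                    amoD = , amoE = "bacteria",
                    pmoA = , pmoB = , pmoC = "bacteria", "unknown")
      for (i in seq_len(n)) {
        aa <- .mutate_protein(anc[[f]], config$within_divergence / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%02d", f, i), family = f, domain = dom,
          clade = NA_character_, aa = aa)
      }
    }
  }
  tab <- do.call(rbind, rows)
  nt <- vapply(tab$aa, .reverse_translate, character(1))
  ref_panel(id = tab$id, family = tab$family, domain = tab$domain,
            clade = tab$clade, aa = tab$aa, nt = unname(nt))
}

#' Plant operon-bearing genomes
#'
#' Each genome is i.i.d. random background DNA with one operon inserted:
#' the panel's nucleotide CDS of the configured subunits in the configured
#' order, separated by random intergenic gaps, on a random strand.
#' Optionally a non-amo decoy gene is planted downstream within the
#' neighbour window. All coordinates are recorded as ground truth.
#'
#' @param panel a [ref_panel()] with nucleotide CDS.
#' @param config a [synth_config()].
#' @return list: `genomes` (data frame `id`, `sequence`), `features`
#'   (ground-truth gene coordinates: `genome_id`, `family`, `panel_id`,
#'   `start`, `end`, `strand`, `in_operon`), `layouts`.
#' @export
plant_genomes <- function(panel, config = synth_config()) {
  set.seed(config$seed + 202L)
  gaps <- config$intergenic_gap_bp
  genomes <- list(); feats <- list(); layouts <- character(0)
  pick_counter <- new.env(parent = emptyenv())
  pick_member <- function(fam) {
    rows <- which(panel$family == fam)
    if (!length(rows)) stop("panel lacks family required by layout: ", fam)
    cnt <- get0(fam, envir = pick_counter, ifnotfound = 0L)
    assign(fam, cnt + 1L, envir = pick_counter)
    rows[(cnt %% length(rows)) + 1L]
  }
  for (g in seq_len(config$n_genomes)) {
    layout <- config$operon_layouts[(g - 1L) %% length(config$operon_layouts) + 1L]
    fams <- trimws(strsplit(layout, ",")[[1]])
    strand <- sample(c("+", "-"), 1)
    seg <- ""
    rel <- list()
    for (fi in seq_along(fams)) {
      row <- pick_member(fams[fi])
      cds <- panel$nt[row]
      if (fi > 1L) {
        gap <- sample(seq(gaps[1], gaps[2]), 1)
        seg <- paste0(seg, random_dna(1, gap))
      }
      rel[[fi]] <- c(start = nchar(seg), end = nchar(seg) + nchar(cds),
                     row = row)
      seg <- paste0(seg, cds)
    }
    if (strand == "-") {
      seg_len <- nchar(seg)
      seg <- revcomp(seg)
      rel <- lapply(rel, function(r) {
        c(start = seg_len - r[["end"]], end = seg_len - r[["start"]],
          row = r[["row"]])
      })
    }
    left <- random_dna(1, 600)
    genome <- paste0(left, seg)
    off <- nchar(left)
    for (fi in seq_along(rel)) {
      r <- rel[[fi]]
      feats[[length(feats) + 1L]] <- data.frame(
        genome_id = sprintf("genome%02d", g),
        family = panel$family[r[["row"]]],
        panel_id = panel$id[r[["row"]]],
        start = off + r[["start"]], end = off + r[["end"]],
        strand = strand, in_operon = TRUE)
    }
    if (config$plant_neighbor && any(panel$family == "other")) {
      drow <- pick_member("other")
      gap <- sample(200:500, 1)
      genome <- paste0(genome, random_dna(1, gap))
      dstart <- nchar(genome)
      genome <- paste0(genome, panel$nt[drow])
      feats[[length(feats) + 1L]] <- data.frame(
        genome_id = sprintf("genome%02d", g), family = "other",
        panel_id = panel$id[drow], start = dstart,
        end = dstart + nchar(panel$nt[drow]), strand = "+",
        in_operon = FALSE)
    }
    genome <- paste0(genome, random_dna(1, 600))
    genomes[[g]] <- data.frame(id = sprintf("genome%02d", g),
                               sequence = genome)
    layouts <- c(layouts, layout)
  }
  list(genomes = do.call(rbind, genomes),
       features = do.call(rbind, feats),
       layouts = layouts)
}

#' Nested ring sampling design
#'
#' One central sample plus `n_per_ring` samples on each ring, emulating a
#' nested survey around a central point.
#'
#' @param radii ring radii (m).
#' @param n_per_ring samples per ring.
#' @param seed optional seed randomising the ring rotation angles.
#' @return sample-design data frame (`sample_id`, `x`, `y`, `ring_radius`).
#' @export
ring_design <- function(radii = c(5, 10, 20, 50, 100, 200), n_per_ring = 4L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list(data.frame(sample_id = "S01", x = 0, y = 0, ring_radius = 0))
  sid <- 1L
  for (ri in seq_along(radii)) {
    rot <- if (is.null(seed)) (ri - 1) * pi / 8 else runif(1, 0, 2 * pi)
    ang <- rot + 2 * pi * (seq_len(n_per_ring) - 1) / n_per_ring
    for (a in ang) {
      sid <- sid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%02d", sid),
        x = radii[ri] * cos(a), y = radii[ri] * sin(a),
        ring_radius = radii[ri])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spatially structured community with calibrated scaling slopes
#'
#' Builds a noise-free abundance matrix over the sample design whose
#' distance-decay and taxa-area statistics hit the planted slopes by
#' construction. Target similarities `s0 + d * log10(dist)` are projected
#' onto the samples' average-linkage dendrogram; every internal node
#' becomes a "block" variant shared equally by its member samples, which
#' realises the projected (ultrametric) similarities exactly under equal
#' per-sample totals. The internal slope is root-found so the fitted DDR
#' slope equals the planted `d`. Cumulative ring richness is topped up to
#' `round(R0 * area^z)` with singleton variants, planting the TAR
#' exponent. A private filler variant per sample normalises totals to 1.
#'
#' @param design a [ring_design()] data frame.
#' @param config a [synth_config()].
#' @return list of class `synth_community`: `matrix` (samples x variants,
#'   abundances summing to 1 per sample), `design`, `variant_type`,
#'   `ddr_slope_true`, `tar_z_true`.
#' @export
simulate_community <- function(design, config = synth_config()) {
  set.seed(config$seed + 303L)
  n <- nrow(design)
  D <- as.matrix(stats::dist(design[, c("x", "y")]))
  hc <- hclust(as.dist(D), method = "average")
  merges <- hc$merge
  # members of each internal node
  members <- vector("list", nrow(merges))
  node_members <- function(idx) {
    if (idx < 0) return(-idx)
    members[[idx]]
  }
  for (k in seq_len(nrow(merges))) {
    members[[k]] <- c(node_members(merges[k, 1]), node_members(merges[k, 2]))
  }
  L <- log10(pmax(D, 1e-9))
  # ultrametric projection of the target similarities for internal slope m
  node_values <- function(m) {
    v <- numeric(nrow(merges))
    for (k in seq_len(nrow(merges))) {
      a <- node_members(merges[k, 1]); b <- node_members(merges[k, 2])
      raw <- mean(config$ddr_intercept + m * L[a, b])
      ch <- c(if (merges[k, 1] > 0) v[merges[k, 1]],
              if (merges[k, 2] > 0) v[merges[k, 2]])
      v[k] <- min(c(raw, ch))
    }
    v
  }
  sim_from_values <- function(v) {
    S <- matrix(NA_real_, n, n)
    for (k in seq_len(nrow(merges))) {
      a <- node_members(merges[k, 1]); b <- node_members(merges[k, 2])
      S[a, b] <- v[k]; S[b, a] <- v[k]
    }
    diag(S) <- 1
    S
  }
  iu <- upper.tri(D) & D > 0
  fitted_slope <- function(m) {
    S <- sim_from_values(node_values(m))
    coef(lm(S[iu] ~ L[iu]))[2]
  }
  target <- config$ddr_slope_true
  m_star <- uniroot(function(m) fitted_slope(m) - target,
                    interval = c(3 * target, target / 10),
                    tol = 1e-10)$root
  v <- node_values(m_star)
  if (any(v <= 0)) stop("planted similarity line goes non-positive; raise ddr_intercept")
  # block abundances: value minus parent value (root keeps its full value)
  parent_val <- numeric(nrow(merges))
  parent_val[nrow(merges)] <- 0
  for (k in seq(nrow(merges), 1)) {
    for (side in 1:2) {
      ch <- merges[k, side]
      if (ch > 0) parent_val[ch] <- v[k]
    }
  }
  a_block <- v - parent_val
  mat <- matrix(0, nrow = n, ncol = nrow(merges),
                dimnames = list(design$sample_id,
                                sprintf("block%03d", seq_len(nrow(merges)))))
  for (k in seq_len(nrow(merges))) mat[members[[k]], k] <- a_block[k]
  vtype <- rep("block", ncol(mat))
  # TAR top-up: cumulative ring richness -> round(R0 * area^z)
  radii <- sort(unique(design$ring_radius[design$ring_radius > 0]))
  area <- pi * radii^2
  z <- config$tar_z_true
  base <- vapply(radii, function(r) {
    inside <- design$ring_radius <= r
    sum(colSums(mat[inside, , drop = FALSE] > 0) > 0) + sum(inside)
  }, numeric(1))   # blocks present + one private per sample
  az <- area^z
  R0 <- max(ceiling((base + length(radii)) / az))
  repeat {
    Rk <- round(R0 * az)
    Nk <- Rk - base
    if (all(Nk >= 0) && all(diff(Nk) >= 0)) break
    R0 <- R0 + 1L
  }
  tk <- diff(c(0, Nk))
  delta <- 1e-3
  extra <- list()
  for (ri in seq_along(radii)) {
    if (tk[ri] == 0) next
    ring_samples <- which(design$ring_radius == radii[ri])
    cols <- matrix(0, nrow = n, ncol = tk[ri])
    for (tvar in seq_len(tk[ri])) {
      s <- ring_samples[(tvar - 1L) %% length(ring_samples) + 1L]
      cols[s, tvar] <- delta
    }
    colnames(cols) <- sprintf("tar_r%g_%04d", radii[ri], seq_len(tk[ri]))
    extra[[length(extra) + 1L]] <- cols
  }
  if (length(extra)) {
    add <- do.call(cbind, extra)
    mat <- cbind(mat, add)
    vtype <- c(vtype, rep("tar", ncol(add)))
  }
  # private filler per sample normalises totals to 1
  priv <- diag(1 - rowSums(mat))
  if (any(diag(priv) <= 0)) stop("per-sample budget exceeded; lower ddr_intercept")
  colnames(priv) <- sprintf("private_%s", design$sample_id)
  mat <- cbind(mat, priv)
  vtype <- c(vtype, rep("private", n))
  structure(list(matrix = mat, design = design, variant_type = vtype,
                 ddr_slope_true = config$ddr_slope_true,
                 tar_z_true = config$tar_z_true),
            class = "synth_community")
}

#' Multinomial count sampling of a community
#'
#' Draws per-sample read counts from the noise-free truth abundances,
#' the stochastic observation layer on top of [simulate_community()].
#'
#' @param community a `synth_community`.
#' @param n_reads counts drawn per sample.
#' @param seed RNG seed.
#' @return samples x variants integer count matrix.
#' @export
sample_counts <- function(community, n_reads = 50000L, seed = 1L) {
  set.seed(seed)
  m <- community$matrix
  out <- t(apply(m, 1, function(p) rmultinom(1, n_reads, p)[, 1]))
  dimnames(out) <- dimnames(m)
  out
}

#' Simulate per-sample shotgun reads from planted genomes
#'
#' Genome abundances per sample follow a Gaussian spatial kernel around a
#' genome-specific epicenter sample; reads are drawn uniformly along the
#' chosen genome on a random strand with substitution errors, mixed with
#' i.i.d. random background reads at the configured fraction. Per-read
#' origins are recorded as ground truth.
#'
#' @param genomes output of [plant_genomes()].
#' @param config a [synth_config()].
#' @param design optional [ring_design()]; defaults to the config's design.
#' @param out_dir optional directory for per-sample FASTQ files.
#' @return list: `reads` (read-set data frame), `origin` (data frame
#'   `read_id`, `origin`), `design`, `genome_weights`
#'   (genomes x samples).
#' @export
simulate_samples <- function(genomes, config = synth_config(),
                             design = NULL, out_dir = NULL) {
  set.seed(config$seed + 404L)
  if (is.null(design)) {
    design <- ring_design(config$radii, config$n_per_ring,
                          seed = config$seed + 11L)
  }
  G <- nrow(genomes$genomes)
  n <- nrow(design)
  epi <- sample.int(n, G, replace = TRUE)
  tau <- 60
  W <- matrix(0, nrow = G, ncol = n,
              dimnames = list(genomes$genomes$id, design$sample_id))
  for (g in seq_len(G)) {
    dd <- sqrt((design$x - design$x[epi[g]])^2 +
                 (design$y - design$y[epi[g]])^2)
    W[g, ] <- exp(-dd^2 / (2 * tau^2)) + 0.05
  }
  W <- sweep(W, 2, colSums(W), "/")
  glen <- nchar(genomes$genomes$sequence)
  rl <- config$read_length
  n_target <- as.integer(round(config$coverage_per_sample * sum(glen) / rl))
  bf <- config$background_fraction
  n_bg <- as.integer(round(n_target * bf / (1 - bf)))
  all_reads <- list(); all_origin <- list()
  for (s in seq_len(n)) {
    gsel <- sample.int(G, n_target, replace = TRUE, prob = W[, s])
    pos <- vapply(gsel, function(g) {
      sample.int(max(1L, glen[g] - rl + 1L), 1)
    }, integer(1))
    fwd <- runif(n_target) < 0.5
    seqs <- substr(genomes$genomes$sequence[gsel], pos, pos + rl - 1L)
    seqs[!fwd] <- revcomp(seqs[!fwd])
    if (config$error_rate > 0) {
      seqs <- vapply(seqs, .mutate_dna, character(1),
                     rate = config$error_rate)
    }
    ids <- sprintf("%s_r%05d", design$sample_id[s], seq_len(n_target + n_bg))
    origin <- data.frame(
      read_id = ids,
      origin = c(genomes$genomes$id[gsel], rep("background", n_bg)),
      pos = c(pos, rep(NA_integer_, n_bg)),
      fwd = c(fwd, rep(NA, n_bg)))
    bg <- if (n_bg > 0) random_dna(n_bg, rl) else character(0)
    rd <- data.frame(id = ids, sample_id = design$sample_id[s],
                     sequence = c(unname(seqs), bg), mate = "unpaired",
                     quality = strrep("I", rl))
    all_reads[[s]] <- rd
    all_origin[[s]] <- origin
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fastq(rd, file.path(out_dir,
                                paste0(design$sample_id[s], ".fastq")))
    }
  }
  list(reads = do.call(rbind, all_reads),
       origin = do.call(rbind, all_origin),
       design = design, genome_weights = W)
}

#' Plant chimeric splices of parent sequences
#'
#' Each chimera is the prefix of parent A up to a random crossover in
#' [0.3, 0.7] of its length joined to the suffix of parent B, recorded
#' with its parents and crossover.
#'
#' @param sequences named character vector of parent sequences (>= 2,
#'   pairwise identity <= `max_parent_identity`).
#' @param n number of chimeras.
#' @param seed RNG seed.
#' @param max_parent_identity parents more similar than this are not
#'   spliced.
#' @return list: `chimeras` (data frame `id`, `sequence`), `truth`
#'   (`id`, `parent_a`, `parent_b`, `crossover`).
#' @export
plant_chimeras <- function(sequences, n, seed = 1L,
                           max_parent_identity = 0.95) {
  set.seed(seed)
  if (length(sequences) < 2) stop("need >= 2 parent sequences")
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("parent%02d", seq_along(sequences))
  sc <- .nt_scoring()
  pairs <- t(combn(length(sequences), 2))
  ok <- apply(pairs, 1, function(p) {
    a <- .cpp_align(sequences[p[1]], sequences[p[2]], sc$mat, sc$alphabet,
                    5L, 2L, TRUE)
    a$matches / max(nchar(sequences[p[1]]), nchar(sequences[p[2]])) <=
      max_parent_identity
  })
  pairs <- pairs[ok, , drop = FALSE]
  # both orders of each eligible pair are usable
  pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  if (n > nrow(pairs)) {
    stop(sprintf("requested %d chimeras but only %d eligible parent pairs",
                 n, nrow(pairs)))
  }
  sel <- sample.int(nrow(pairs), n)
  out <- list(); truth <- list()
  for (i in seq_len(n)) {
    pa <- pairs[sel[i], 1]; pb <- pairs[sel[i], 2]
    la <- nchar(sequences[pa])
    x <- as.integer(round(runif(1, 0.3, 0.7) * la))
    chim <- paste0(substr(sequences[pa], 1, x),
                   substr(sequences[pb], x + 1, nchar(sequences[pb])))
    out[[i]] <- data.frame(id = sprintf("chimera%03d", i), sequence = chim)
    truth[[i]] <- data.frame(id = sprintf("chimera%03d", i),
                             parent_a = ids[pa], parent_b = ids[pb],
                             crossover = x)
  }
  list(chimeras = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' One-call synthetic metagenome
#'
#' Panel, planted genomes, sampling design, calibrated community and
#' per-sample reads from one configuration; optionally written to disk
#' (panel FASTA pair, genomes FASTA, design TSV, per-sample FASTQ,
#' ground-truth JSON).
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return list: `panel`, `genomes`, `design`, `community`, `reads`,
#'   `origin`, `config`.
#' @export
simulate_metagenome <- function(config = synth_config(), out_dir = NULL) {
  panel <- make_reference_panel(config)
  genomes <- plant_genomes(panel, config)
  design <- ring_design(config$radii, config$n_per_ring,
                        seed = config$seed + 11L)
  community <- simulate_community(design, config)
  sim <- simulate_samples(genomes, config, design = design,
                          out_dir = if (is.null(out_dir)) NULL else
                            file.path(out_dir, "reads"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reference_panel(panel, file.path(out_dir, "panel.faa"),
                          nt_path = file.path(out_dir, "panel.fna"))
    write_fasta(genomes$genomes$id, genomes$genomes$sequence,
                file.path(out_dir, "genomes.fna"))
    write_design(design, file.path(out_dir, "design.tsv"))
    jsonlite::write_json(
      list(features = genomes$features, origin = sim$origin,
           ddr_slope_true = config$ddr_slope_true,
           tar_z_true = config$tar_z_true),
      file.path(out_dir, "truth.json"), dataframe = "rows")
  }
  list(panel = panel, genomes = genomes, design = design,
       community = community, reads = sim$reads, origin = sim$origin,
       config = config)
}
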