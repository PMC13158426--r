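#' Synthetic experiment configuration
#'
#' Parameters of the synthetic multi-tissue, two-sex, five-timepoint
#' endurance-training experiment. Defaults emulate the study design at desk
#' scale: n = 5 replicates per tissue x sex x timepoint cell, timepoints
#' 0 (sedentary) / 1 / 2 / 4 / 8 weeks, negative-binomial counts with
#' variance `mu + alpha * mu^2`, a gene density of ~10 genes per Mb, base
#' mean counts spanning 2^6..2^12 (the adequately-expressed regime the
#' detection filters select for), lncRNAs 4-fold less abundant and
#' GC-poorer than coding genes, and planted training effects of |log2FC| 2.
#'
#' @param seed Root seed; all outputs are a deterministic function of it.
#' @param n_tissues,n_chromosomes,chrom_length,n_genes Layout scale.
#' @param lnc_fraction Fraction of genes that are lncRNAs, in (0, 1).
#' @param replicates_per_cell Replicates per tissue x sex x timepoint.
#' @param timepoints Ordered weeks; must include 0 (sedentary control).
#' @param sexes Sex labels (male/female).
#' @param nb_dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param base_mean_log_range log2 range (lo, hi) of base mean counts.
#' @param lnc_mean_shift log2 offset of lncRNA abundance (negative).
#' @param gc_target_coding,gc_target_lnc Per-biotype GC targets (%).
#' @param n_de_genes_per_cell Planted differential genes per
#'   tissue x sex x training-timepoint cell.
#' @param de_log2fc Planted effect size (|log2FC|).
#' @param n_planted_triads Planted cis lncRNA-peak-gene triads.
#' @param triad_r_target Target trajectory correlation of planted triads.
#' @param triad_max_tss_distance Max planted peak-summit-to-TSS distance.
#' @param n_decoy_peaks Decoy ATAC peaks placed uniformly.
#' @param decoy_null_fraction Fraction of decoys with flat (null)
#'   trajectories; the rest respond to training but independently of any
#'   lncRNA.
#' @param peak_width Emitted (pre-trim) peak width in bp.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_tissues = 2, n_chromosomes = 4,
                       chrom_length = 2.5e7, n_genes = 1000,
                       lnc_fraction = 0.3, replicates_per_cell = 5,
                       timepoints = c(0, 1, 2, 4, 8),
                       sexes = c("male", "female"),
                       nb_dispersion = 0.1,
                       base_mean_log_range = c(6, 12),
                       lnc_mean_shift = -2,
                       gc_target_coding = 50, gc_target_lnc = 44,
                       n_de_genes_per_cell = 10, de_log2fc = 2,
                       n_planted_triads = 10, triad_r_target = 0.9,
                       triad_max_tss_distance = 5000,
                       n_decoy_peaks = 500, decoy_null_fraction = 0.2,
                       peak_width = 400) {
  cfg <- as.list(environment())
  if (!(lnc_fraction > 0 && lnc_fraction < 1)) .fail("lnc_fraction must lie in (0, 1)")
  if (!0 %in% timepoints) .fail("timepoints must include 0 (sedentary control)")
  if (any(c(n_tissues, n_chromosomes, n_genes, replicates_per_cell) < 1))
    .fail("all design counts must be >= 1")
  if (nb_dispersion <= 0) .fail("nb_dispersion must be positive")
  if (seed < 0 || seed >= 2^31) .fail("seed must be a non-negative 31-bit integer")
  if (abs(triad_r_target) > 1) .fail("triad_r_target must lie in [-1, 1]")
  class(cfg) <- "sim_config"
  cfg
}

.TISSUES <- c("liver", "kidney", "lung", "heart", "WAT", "BAT", "SKMGN",
              "hypothalamus")

# internal: column labels of the per-tissue log2FC effect matrices
.cell_cols <- function(sexes, weeks) {
  as.vector(outer(weeks, sexes, function(w, s) paste0(s, "_w", w)))
}

# internal: non-overlapping uniform gene placement on one chromosome.
# Returns integer start offsets for spans `spans` on [0, len).
.place_spans <- function(spans, len) {
  total <- sum(spans)
  if (total > 0.85 * len)
    .fail("layout-infeasible: %d bp of gene span on a %d bp chromosome", total, len)
  free <- len - total
  gaps <- rexp(length(spans) + 1)
  gaps <- floor(gaps / sum(gaps) * free)
  starts <- cumsum(gaps[-length(gaps)] + c(0, spans[-length(spans)]))
  as.integer(starts)
}

#' Simulate transcript sequences for an annotation
#'
#' Draws one i.i.d. nucleotide sequence per gene with length equal to the
#' gene's exonic length and GC probability set to the biotype's target.
#' Genes flagged for planted ORFs receive an in-frame `ATG` ... stop span of
#' at least 36 nt built from non-stop codons (when the transcript is long
#' enough).
#'
#' @param ann Gene annotation.
#' @param gc_targets Named numeric vector of GC targets (%) per biotype
#'   (`protein_coding`, `lncRNA`, `other`); values in `[0, 100]`.
#' @param planted_orfs Named integer vector per biotype: how many ORFs to
#'   plant per sequence (0 or 1 supported).
#' @param seed Substream seed.
#' @return Named character vector of sequences.
#' @export
simulate_sequences <- function(ann, gc_targets = c(protein_coding = 50,
                                                   lncRNA = 44, other = 50),
                               planted_orfs = c(protein_coding = 1,
                                                lncRNA = 0, other = 0),
                               seed = 1) {
  if (any(gc_targets < 0 | gc_targets > 100))
    .fail("gc targets must lie in [0, 100]")
  set.seed(seed)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  codons <- setdiff(codons, .STOPS)
  seqs <- vapply(seq_len(nrow(ann)), function(i) {
    len <- as.integer(ann$exonic_length[i])
    g <- gc_targets[[ann$biotype[i]]] / 100
    s <- paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                      prob = c((1 - g) / 2, (1 - g) / 2, g / 2, g / 2)),
               collapse = "")
    n_orf <- planted_orfs[[ann$biotype[i]]] %||% 0
    if (n_orf > 0 && len >= 42) {
      k <- min((len %/% 3) - 4, 48)  # internal codons
      orf <- paste0("ATG", paste(sample(codons, k, replace = TRUE),
                                 collapse = ""), "TAA")
      pos <- sample.int(len - nchar(orf) + 1L, 1L)
      substr(s, pos, pos + nchar(orf) - 1L) <- orf
    }
    s
  }, character(1))
  setNames(seqs, ann$gene_id)
}

#' Simulate a full multi-tissue training experiment
#'
#' Generates annotation, transcript sequences, RNA-seq counts, ATAC-seq
#' peaks and counts, sample sheets and ground truth under the configured
#' design. Counts are negative-binomial with gene-specific base means and a
#' global dispersion; planted differential genes have their mean shifted by
#' `de_log2fc` in the flagged tissue x sex x timepoint cells; each planted
#' triad comprises a lncRNA, an ATAC peak near a coding gene's TSS (within
#' `triad_max_tss_distance`, and within 500 kb of the lncRNA midpoint) whose
#' accessibility trajectory shares a latent timewise signal with the lncRNA
#' at approximately `triad_r_target` correlation, plus decoy peaks with
#' independent trajectories. All randomness flows from the root seed via
#' named substreams (one per artifact), so the same seed reproduces every
#' output bit-identically.
#'
#' @param config A [sim_config()].
#' @return A `sim_experiment` list: `annotation`, `sequences`, `rna_counts`,
#'   `rna_meta`, `peaks`, `atac_counts`, `atac_meta`, `truth` (list
#'   `planted_de`, `planted_triads`, `config`), `chrom_lengths`, `tissues`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tissues <- rep_len(.TISSUES, cfg$n_tissues)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  weeks <- sort(setdiff(cfg$timepoints, 0))
  cols <- .cell_cols(cfg$sexes, weeks)

  ## --- layout: genes, exons, strands, biotypes -------------------------
  set.seed(substream_seed(cfg$seed, "layout"))
  n_ex <- sample.int(5L, cfg$n_genes, replace = TRUE)
  gene_chrom <- chroms[rep_len(seq_len(cfg$n_chromosomes), cfg$n_genes)]
  ex_lens <- lapply(n_ex, function(k) pmin(pmax(round(rlnorm(k, log(250), 0.6)), 50), 2000))
  in_lens <- lapply(n_ex, function(k) if (k > 1)
    pmin(pmax(round(rlnorm(k - 1, log(800), 0.8)), 60), 5000) else integer(0))
  spans <- mapply(function(e, i) sum(e) + sum(i), ex_lens, in_lens)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  biotype <- ifelse(runif(cfg$n_genes) < cfg$lnc_fraction, "lncRNA", "protein_coding")
  gene_id <- ifelse(biotype == "lncRNA",
                    sprintf("LNC%05d", seq_len(cfg$n_genes)),
                    sprintf("PCG%05d", seq_len(cfg$n_genes)))
  starts <- integer(cfg$n_genes)
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    starts[idx] <- .place_spans(spans[idx], cfg$chrom_length)
  }
  exons <- lapply(seq_len(cfg$n_genes), function(i) {
    off <- starts[i] + cumsum(c(0, head(ex_lens[[i]], -1) + in_lens[[i]]))
    cbind(start = off, end = off + ex_lens[[i]])
  })
  ann <- .make_annotation(gene_id, gene_chrom, starts, starts + spans,
                          strand, biotype, exons)

  ## --- base means ------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "means"))
  lo <- cfg$base_mean_log_range[1]; hi <- cfg$base_mean_log_range[2]
  mu <- 2^runif(cfg$n_genes, lo, hi)
  mu[biotype == "lncRNA"] <- mu[biotype == "lncRNA"] * 2^cfg$lnc_mean_shift
  names(mu) <- gene_id

  ## --- planted differential genes --------------------------------------
  set.seed(substream_seed(cfg$seed, "de"))
  L <- lapply(setNames(tissues, tissues), function(ti)
    matrix(0, cfg$n_genes, length(cols), dimnames = list(gene_id, cols)))
  planted_de <- list()
  if (cfg$n_de_genes_per_cell > 0) {
    for (ti in tissues) for (sx in cfg$sexes) for (w in weeks) {
      gsel <- sample.int(cfg$n_genes, cfg$n_de_genes_per_cell)
      sgn <- sample(c(-1, 1), cfg$n_de_genes_per_cell, replace = TRUE)
      L[[ti]][cbind(gsel, match(paste0(sx, "_w", w), cols))] <- sgn * cfg$de_log2fc
      planted_de[[length(planted_de) + 1L]] <- data.frame(
        gene_id = gene_id[gsel], tissue = ti, sex = sx, timepoint_weeks = w,
        true_log2fc = sgn * cfg$de_log2fc, stringsAsFactors = FALSE)
    }
  }
  planted_de <- if (length(planted_de)) do.call(rbind, planted_de) else
    data.frame(gene_id = character(0), tissue = character(0),
               sex = character(0), timepoint_weeks = numeric(0),
               true_log2fc = numeric(0))

  ## --- planted cis triads ----------------------------------------------
  set.seed(substream_seed(cfg$seed, "triads"))
  half_pk <- cfg$peak_width %/% 2
  peak_list <- list()
  P <- list()  # per-tissue peak effect rows, bound later
  triad_rec <- list()
  if (cfg$n_planted_triads > 0) {
    lnc_idx <- which(biotype == "lncRNA")
    cod_idx <- which(biotype == "protein_coding")
    margin <- 500000 - cfg$triad_max_tss_distance - cfg$peak_width
    cand <- do.call(rbind, lapply(lnc_idx, function(li) {
      ok <- cod_idx[gene_chrom[cod_idx] == gene_chrom[li] &
                      abs(ann$tss[cod_idx] - ann$midpoint[li]) <= margin]
      if (!length(ok)) return(NULL)
      cbind(lnc = li, cod = ok)
    }))
    if (is.null(cand) || length(unique(cand[, "lnc"])) < cfg$n_planted_triads)
      .fail("layout-infeasible: only %d lncRNAs have a coding gene within the pairing window",
            length(unique(cand[, "lnc"])))
    pick_lnc <- sample(unique(cand[, "lnc"]), cfg$n_planted_triads)
    used_cod <- integer(0)
    for (t_i in seq_along(pick_lnc)) {
      li <- pick_lnc[t_i]
      opts <- setdiff(cand[cand[, "lnc"] == li, "cod"], used_cod)
      if (!length(opts)) opts <- cand[cand[, "lnc"] == li, "cod"]
      ci <- if (length(opts) == 1L) opts else sample(opts, 1)
      used_cod <- c(used_cod, ci)
      d <- sample.int(cfg$triad_max_tss_distance + 1L, 1L) - 1L
      side <- sample(c(-1L, 1L), 1L)
      summit <- min(max(ann$tss[ci] + side * d, half_pk),
                    cfg$chrom_length - half_pk)
      pid <- sprintf("peak_triad_%03d", t_i)
      peak_list[[length(peak_list) + 1L]] <- data.frame(
        peak_id = pid, chrom = gene_chrom[ci],
        start = as.integer(summit - half_pk),
        end = as.integer(summit + half_pk),
        summit = as.integer(summit), stringsAsFactors = FALSE)
      eff <- matrix(0, length(tissues), length(cols),
                    dimnames = list(tissues, cols))
      for (ti in tissues) {
        z <- rnorm(length(cols))
        s <- z / max(abs(z)) * cfg$de_log2fc
        L[[ti]][li, ] <- s
        u <- cfg$triad_r_target * z +
          sqrt(1 - cfg$triad_r_target^2) * rnorm(length(cols))
        eff[ti, ] <- u / max(abs(u)) * cfg$de_log2fc
      }
      P[[pid]] <- eff
      triad_rec[[t_i]] <- data.frame(
        lnc_id = gene_id[li], peak_id = pid, gene_id = gene_id[ci],
        true_r = cfg$triad_r_target, tss_distance = abs(summit - ann$tss[ci]),
        stringsAsFactors = FALSE)
    }
  }

  ## --- decoy peaks ------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "decoys"))
  if (cfg$n_decoy_peaks > 0) {
    dch <- sample(chroms, cfg$n_decoy_peaks, replace = TRUE)
    dsum <- floor(runif(cfg$n_decoy_peaks, half_pk, cfg$chrom_length - half_pk))
    is_null <- runif(cfg$n_decoy_peaks) < cfg$decoy_null_fraction
    for (i in seq_len(cfg$n_decoy_peaks)) {
      pid <- sprintf("peak_decoy_%04d", i)
      peak_list[[length(peak_list) + 1L]] <- data.frame(
        peak_id = pid, chrom = dch[i],
        start = as.integer(dsum[i] - half_pk), end = as.integer(dsum[i] + half_pk),
        summit = as.integer(dsum[i]), stringsAsFactors = FALSE)
      eff <- matrix(0, length(tissues), length(cols),
                    dimnames = list(tissues, cols))
      if (!is_null[i]) for (ti in tissues) {
        z <- rnorm(length(cols))
        eff[ti, ] <- z / max(abs(z)) * cfg$de_log2fc
      }
      P[[pid]] <- eff
    }
  }
  peaks <- if (length(peak_list)) do.call(rbind, peak_list) else
    data.frame(peak_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), summit = integer(0))
  planted_triads <- if (length(triad_rec)) do.call(rbind, triad_rec) else
    data.frame(lnc_id = character(0), peak_id = character(0),
               gene_id = character(0), true_r = numeric(0),
               tss_distance = numeric(0))
  if (nrow(planted_triads)) {
    # triad lncRNAs carry the shared latent trajectory, which supersedes any
    # fixed-effect DE planting for those genes
    planted_de <- planted_de[!planted_de$gene_id %in% planted_triads$lnc_id, ,
                             drop = FALSE]
    # ground truth records the *actual* nearest coding TSS of each planted
    # peak (almost always the gene it was planted next to)
    nt <- assign_nearest_tss(peaks[match(planted_triads$peak_id, peaks$peak_id), ,
                                   drop = FALSE], ann)
    hit <- match(planted_triads$peak_id, nt$peak_id)
    planted_triads$gene_id <- nt$gene_id[hit]
    planted_triads$tss_distance <- nt$distance_to_tss[hit]
  }

  ## --- sample sheets ----------------------------------------------------
  design <- expand.grid(rep = seq_len(cfg$replicates_per_cell),
                        timepoint_weeks = cfg$timepoints, sex = cfg$sexes,
                        tissue = tissues, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  design <- design[c("tissue", "sex", "timepoint_weeks", "rep")]
  rna_meta <- data.frame(
    sample_id = sprintf("%s_%s_w%g_r%d", design$tissue, design$sex,
                        design$timepoint_weeks, design$rep),
    design[c("tissue", "sex", "timepoint_weeks")], stringsAsFactors = FALSE)
  atac_meta <- rna_meta
  atac_meta$sample_id <- paste0("atac_", rna_meta$sample_id)

  ## --- RNA counts -------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "rna_counts"))
  size <- 1 / cfg$nb_dispersion
  rna_counts <- matrix(0L, cfg$n_genes, nrow(rna_meta),
                       dimnames = list(gene_id, rna_meta$sample_id))
  for (j in seq_len(nrow(rna_meta))) {
    sm <- rna_meta[j, ]
    lfc <- if (sm$timepoint_weeks == 0) 0 else
      L[[sm$tissue]][, paste0(sm$sex, "_w", sm$timepoint_weeks)]
    rna_counts[, j] <- rnbinom(cfg$n_genes, mu = mu * 2^lfc, size = size)
  }

  ## --- ATAC counts ------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "atac_counts"))
  n_pk <- nrow(peaks)
  atac_counts <- matrix(0L, n_pk, nrow(atac_meta),
                        dimnames = list(peaks$peak_id, atac_meta$sample_id))
  if (n_pk > 0) {
    mu_pk <- 2^runif(n_pk, 5, 10)
    for (j in seq_len(nrow(atac_meta))) {
      sm <- atac_meta[j, ]
      lfc <- if (sm$timepoint_weeks == 0) rep(0, n_pk) else
        vapply(peaks$peak_id, function(pid)
          P[[pid]][sm$tissue, paste0(sm$sex, "_w", sm$timepoint_weeks)],
          numeric(1))
      atac_counts[, j] <- rnbinom(n_pk, mu = mu_pk * 2^lfc, size = size)
    }
  }

  ## --- sequences --------------------------------------------------------
  seqs <- simulate_sequences(
    ann,
    gc_targets = c(protein_coding = cfg$gc_target_coding,
                   lncRNA = cfg$gc_target_lnc, other = cfg$gc_target_coding),
    seed = substream_seed(cfg$seed, "sequences"))

  structure(list(
    annotation = ann, sequences = seqs,
    rna_counts = .set_units(rna_counts, "raw"), rna_meta = rna_meta,
    peaks = peaks, atac_counts = .set_units(atac_counts, "raw"),
    atac_meta = atac_meta,
    truth = list(planted_de = planted_de, planted_triads = planted_triads,
                 config = cfg),
    chrom_lengths = setNames(rep(cfg$chrom_length, cfg$n_chromosomes), chroms),
    tissues = tissues
  ), class = "sim_experiment")
}

#' Write a simulated experiment to disk in standard formats
#'
#' Annotation as GTF-style text, sequences as FASTA, counts as TSV, sample
#' sheets as TSV, peaks as BED6, ground truth as TSV plus a JSON config
#' echo.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_annotation(sim$annotation, fp("annotation.gtf"))
  write_fasta(sim$sequences, fp("transcripts.fa"))
  write_matrix(sim$rna_counts, fp("rna_counts.tsv"), id_col = "gene_id")
  write_sample_sheet(sim$rna_meta, fp("rna_samples.tsv"))
  write_bed_peaks(sim$peaks, fp("peaks.bed"))
  write_matrix(sim$atac_counts, fp("atac_counts.tsv"), id_col = "peak_id")
  write_sample_sheet(sim$atac_meta, fp("atac_samples.tsv"))
  write.table(sim$truth$planted_de, fp("truth_planted_de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$planted_triads, fp("truth_planted_triads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth$config), fp("sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("synthetic training experiment: %d genes (%d lncRNA) x %d samples, %d tissue(s)\n",
              nrow(x$annotation), sum(x$annotation$biotype == "lncRNA"),
              ncol(x$rna_counts), length(unique(x$tissues))))
  cat(sprintf("peaks: %d (%d planted triads); planted DE records: %d; seed %d\n",
              nrow(x$peaks), nrow(x$truth$planted_triads),
              nrow(x$truth$planted_de), cfg$seed))
  invisible(x)
}
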