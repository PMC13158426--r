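#' Pipeline configuration
#'
#' Bundles either a [sim_config()] (simulate mode) or a set of input paths,
#' together with thresholds, modes, the seed and the output directory.
#' Exactly one of `simulate` / `paths` must be given.
#'
#' @param simulate A [sim_config()], or NULL.
#' @param paths Named list of input files (`annotation`, `fasta`,
#'   `rna_counts`, `rna_samples`, `peaks`, `atac_counts`, `atac_samples`,
#'   optionally `lnc_mirna`, `mirna_mrna`, `gmt`), or NULL.
#' @param thresholds Named list overriding threshold defaults (see
#'   [pipeline_defaults()]).
#' @param modes Named list: `de_engine` (`"welch_logcpm"`), `correlation`
#'   (`"concat_sexes"`/`"per_sex"`), `delnc` (`"nominal"`/`"stringent"`).
#' @param seed Integer seed for every stochastic stage.
#' @param outdir Output directory.
#' @param focus_lnc Optional lncRNA id for the ceRNA network stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, thresholds = list(),
                            modes = list(), seed = 1, outdir = tempfile("lnclink_run_"),
                            focus_lnc = NULL) {
  if (is.null(simulate) == is.null(paths))
    .fail("exactly one of simulate/paths must be supplied")
  th <- utils::modifyList(pipeline_defaults(), thresholds)
  md <- utils::modifyList(list(de_engine = "welch_logcpm",
                               correlation = "concat_sexes",
                               delnc = "nominal"), modes)
  if (th$p_max < 0 || th$r_min < -1 || th$pair_window <= 0)
    .fail("thresholds out of range")
  structure(list(simulate = simulate, paths = paths, thresholds = th,
                 modes = md, seed = as.integer(seed), outdir = outdir,
                 focus_lnc = focus_lnc),
            class = "pipeline_config")
}

#' Default pipeline thresholds
#'
#' All defaults follow the analysis conventions documented throughout the
#' package: CPM > 0.5 in >= 2 samples, mean FPKM >= 1, DELnc at p <= 0.01
#' and |log2FC| >= 1, peaks trimmed to 200 bp with >= 10 reads in >= 4
#' samples, sex-meta FDR <= 0.05, +/-500 kb pairing, triads at r >= 0.5,
#' 6 fuzzy clusters with fuzzifier 1.25 over >= 3 observed timepoints.
#'
#' @return Named list of thresholds.
#' @export
pipeline_defaults <- function() {
  list(min_cpm = 0.5, min_cpm_samples = 2, min_mean_fpkm = 1,
       p_max = 0.01, lfc_min = 1.0, fdr_max_stringent = 0.10,
       lfc_min_stringent = 0.5,
       peak_width = 200, peak_min_reads = 10, peak_min_samples = 4,
       peak_fdr_max = 0.05, pair_window = 500000, r_min = 0.5,
       min_timepoints = 3, n_clusters = 6, fuzzifier = 1.25,
       fold_max_len = 300, enrich_fdr = 0.05)
}

# internal: write a TSV plus a sidecar JSON schema
.emit <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(table = name, columns = names(df),
         types = unname(vapply(df, function(x) class(x)[1], character(1))),
         n_rows = nrow(df)),
    file.path(dir, paste0(name, ".schema.json")), auto_unbox = TRUE)
  invisible(path)
}

#' Validate a pipeline input bundle
#'
#' Cross-checks the sample sheets against the count matrices, the FASTA ids
#' against the annotation, and chromosome-name consistency between peaks
#' and annotation.
#'
#' @param bundle List with `annotation`, `sequences`, `rna_counts`,
#'   `rna_meta`, `peaks`, `atac_counts`, `atac_meta` (e.g. a
#'   `sim_experiment` or the loaded `paths` inputs).
#' @return data.frame report with columns `level` (`"fatal"`/`"warning"`)
#'   and `message`; zero rows when the bundle is clean.
#' @export
validate_inputs <- function(bundle) {
  rep <- list()
  add <- function(level, msg) rep[[length(rep) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  miss <- setdiff(colnames(bundle$rna_counts), bundle$rna_meta$sample_id)
  if (length(miss)) add("fatal", sprintf(
    "RNA count column(s) missing from sample sheet: %s", paste(miss, collapse = ", ")))
  if (!is.null(bundle$atac_counts) && nrow(bundle$atac_counts)) {
    miss <- setdiff(colnames(bundle$atac_counts), bundle$atac_meta$sample_id)
    if (length(miss)) add("fatal", sprintf(
      "ATAC count column(s) missing from sample sheet: %s", paste(miss, collapse = ", ")))
    badc <- setdiff(unique(bundle$peaks$chrom), unique(bundle$annotation$chrom))
    if (length(badc)) add("warning", sprintf(
      "peak chromosome(s) absent from annotation: %s", paste(badc, collapse = ", ")))
  }
  mg <- setdiff(rownames(bundle$rna_counts), bundle$annotation$gene_id)
  if (length(mg)) add("warning", sprintf(
    "%d count-matrix gene(s) missing from annotation", length(mg)))
  if (!is.null(bundle$sequences)) {
    mf <- setdiff(names(bundle$sequences), bundle$annotation$gene_id)
    if (length(mf)) add("warning", sprintf(
      "%d FASTA id(s) absent from annotation", length(mf)))
  }
  if (!length(rep))
    return(data.frame(level = character(0), message = character(0)))
  do.call(rbind, rep)
}

# internal: load a paths-mode input bundle
.load_bundle <- function(paths) {
  list(
    annotation = read_annotation(paths$annotation),
    sequences = if (!is.null(paths$fasta)) read_fasta(paths$fasta),
    rna_counts = read_matrix(paths$rna_counts),
    rna_meta = read_sample_sheet(paths$rna_samples),
    peaks = if (!is.null(paths$peaks)) read_bed_peaks(paths$peaks) else
      data.frame(peak_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), summit = integer(0)),
    atac_counts = if (!is.null(paths$atac_counts)) read_matrix(paths$atac_counts),
    atac_meta = if (!is.null(paths$atac_samples)) read_sample_sheet(paths$atac_samples),
    chrom_lengths = NULL
  )
}

#' Run the full lncRNA-chromatin analysis pipeline
#'
#' Executes, in order: detection/expression filters, timewise
#' sex-stratified differential expression, differential-lncRNA calling,
#' Z-score trajectories and sex-specificity classes, fuzzy temporal
#' clustering, sequence features, peak processing (trim / filter / per-sex
#' F-test / Fisher sex meta-analysis / weighted FDR), lncRNA-peak pairing
#' and correlation (with the 2D distance-correlation density),
#' activity-score triads, the optional ceRNA network, and optional gene-set
#' enrichment. Every stage writes TSV outputs with sidecar JSON schemas to
#' `outdir`, plus a run manifest; the run is a pure function of
#' (inputs, config, seed), so a rerun is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage_log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    stage_log <<- c(stage_log, msg)
    message(msg)
  }

  bundle <- if (!is.null(config$simulate)) {
    sim <- simulate_experiment(config$simulate)
    write_sim_experiment(sim, file.path(config$outdir, "inputs"))
    sim
  } else .load_bundle(config$paths)
  rep <- validate_inputs(bundle)
  if (any(rep$level == "fatal"))
    .fail("input validation failed: %s", paste(rep$message[rep$level == "fatal"],
                                               collapse = "; "))
  ann <- bundle$annotation
  counts <- bundle$rna_counts
  meta <- bundle$rna_meta
  tissues <- unique(meta$tissue)
  lengths <- setNames(ann$exonic_length, ann$gene_id)

  ## stage 1: filters ----------------------------------------------------
  tiss_of <- meta$tissue[match(colnames(counts), meta$sample_id)]
  detected <- filter_detected(counts, tissue = tiss_of,
                              min_cpm = th$min_cpm, min_samples = th$min_cpm_samples)
  expressed_lnc <- lapply(setNames(tissues, tissues), function(ti) {
    sel <- colnames(counts)[tiss_of == ti]
    fp <- fpkm(counts[, sel, drop = FALSE], lengths)
    filter_expressed_lnc(fp, ann, min_mean_fpkm = th$min_mean_fpkm)
  })
  filt <- do.call(rbind, lapply(tissues, function(ti)
    data.frame(tissue = ti, gene_id = detected[[ti]],
               expressed_lnc = detected[[ti]] %in% expressed_lnc[[ti]])))
  .emit(filt, config$outdir, "01_filters")
  note("filters: %d genes in, %s detected per tissue", nrow(counts),
       paste(vapply(detected[tissues], length, integer(1)), collapse = "/"))

  ## stage 2: differential expression ------------------------------------
  de <- do.call(rbind, lapply(tissues, function(ti) {
    sel <- colnames(counts)[tiss_of == ti]
    de_timewise(counts[detected[[ti]], sel, drop = FALSE],
                meta[meta$sample_id %in% sel, ], engine = config$modes$de_engine)
  }))
  class(de) <- c("de_result", "data.frame")
  .emit(de, config$outdir, "02_de")

  ## stage 3: differential-lncRNA calling --------------------------------
  de <- call_delnc(de, mode = config$modes$delnc, p_max = th$p_max,
                   lfc_min = th$lfc_min, fdr_max = th$fdr_max_stringent,
                   lfc_min_stringent = th$lfc_min_stringent)
  biot <- setNames(ann$biotype, ann$gene_id)
  delnc <- lapply(setNames(tissues, tissues), function(ti) {
    g <- unique(de$gene_id[de$tissue == ti & de$is_differential])
    intersect(g[biot[g] == "lncRNA"], expressed_lnc[[ti]])
  })
  deg <- lapply(setNames(tissues, tissues), function(ti) {
    g <- unique(de$gene_id[de$tissue == ti & de$is_differential])
    g[biot[g] == "protein_coding"]
  })
  delnc_tab <- do.call(rbind, lapply(tissues, function(ti)
    if (length(delnc[[ti]])) data.frame(tissue = ti, gene_id = delnc[[ti]])))
  if (is.null(delnc_tab))
    delnc_tab <- data.frame(tissue = character(0), gene_id = character(0))
  .emit(delnc_tab, config$outdir, "03_delnc")
  note("delnc: %s differential lncRNAs per tissue",
       paste(vapply(delnc[tissues], length, integer(1)), collapse = "/"))

  ## stage 4: trajectories and sex patterns -------------------------------
  traj <- zscore_trajectories(de, unlist(delnc, use.names = FALSE))
  .emit(traj$summary, config$outdir, "04_trajectories")
  lnc_de <- de[biot[de$gene_id] == "lncRNA", ]
  sexpat <- classify_sex_patterns(lnc_de)
  .emit(sexpat, config$outdir, "04_sex_patterns")

  ## stage 5: fuzzy temporal clustering ----------------------------------
  cluster_models <- list()
  memb_tab <- list(); center_tab <- list(); core_sets <- list()
  for (ti in tissues) {
    dg <- unique(c(delnc[[ti]], deg[[ti]]))
    dsub <- de[de$tissue == ti & de$gene_id %in% dg, ]
    if (!nrow(dsub)) next
    for (sx in unique(dsub$sex)) {
      prof <- tryCatch(
        prepare_profiles(dsub[dsub$sex == sx, ], min_timepoints = th$min_timepoints),
        error = function(e) NULL)
      if (is.null(prof) || nrow(prof) < 2) next
      k <- min(th$n_clusters, nrow(prof) - 1)
      if (k < 2) next
      cm <- fuzzy_cmeans(prof, n_clusters = k, m = th$fuzzifier,
                         seed = substream_seed(config$seed, paste0("cluster_", ti, "_", sx)))
      cluster_models[[paste(ti, sx, sep = "_")]] <- cm
      memb_tab[[length(memb_tab) + 1L]] <- data.frame(
        tissue = ti, sex = sx, gene_id = rownames(cm$memberships),
        cluster = colnames(cm$memberships)[max.col(cm$memberships, "first")],
        membership = apply(cm$memberships, 1, max))
      center_tab[[length(center_tab) + 1L]] <- data.frame(
        tissue = ti, sex = sx, cluster = rownames(cm$centers), cm$centers,
        check.names = FALSE)
      for (cl in names(cm$core_members)) {
        ids <- cm$core_members[[cl]]
        if (length(ids))
          core_sets[[paste(ti, sx, cl, sep = "_")]] <- ids
      }
    }
  }
  memb <- if (length(memb_tab)) do.call(rbind, memb_tab) else
    data.frame(tissue = character(0), sex = character(0), gene_id = character(0),
               cluster = character(0), membership = numeric(0))
  rownames(memb) <- NULL
  .emit(memb, config$outdir, "05_cluster_memberships")
  cent <- if (length(center_tab)) do.call(rbind, center_tab) else
    data.frame(tissue = character(0), sex = character(0), cluster = character(0))
  rownames(cent) <- NULL
  .emit(cent, config$outdir, "05_cluster_centers")
  if (length(core_sets))
    write_gmt(core_sets, file.path(config$outdir, "05_cluster_cores.gmt"))

  ## stage 6: sequence features ------------------------------------------
  feats <- comparisons <- NULL
  if (!is.null(bundle$sequences)) {
    all_diff <- unique(c(unlist(delnc, use.names = FALSE),
                         unlist(deg, use.names = FALSE)))
    all_diff <- intersect(all_diff, names(bundle$sequences))
    feats <- if (length(all_diff))
      feature_table(bundle$sequences[all_diff], fold_max_len = th$fold_max_len)
    else data.frame(gene_id = character(0), length_nt = integer(0),
                    gc_pct = numeric(0), n_orfs = integer(0),
                    fold_score = numeric(0))
    feats$biotype <- unname(biot[feats$gene_id])
    .emit(feats, config$outdir, "06_features")
    comparisons <- do.call(rbind, lapply(tissues, function(ti) {
      a <- feats[feats$gene_id %in% delnc[[ti]], ]
      b <- feats[feats$gene_id %in% deg[[ti]], ]
      if (nrow(a) < 3 || nrow(b) < 3) return(NULL)
      do.call(rbind, lapply(c("length", "gc", "fold"), function(fe) {
        va <- switch(fe, length = log2(a$length_nt), gc = a$gc_pct, fold = a$fold_score)
        vb <- switch(fe, length = log2(b$length_nt), gc = b$gc_pct, fold = b$fold_score)
        mw <- compare_feature_distributions(va, vb, "mannwhitney")
        data.frame(tissue = ti, feature = fe, test = "mannwhitney",
                   stat = mw$stat, p = mw$p)
      }))
    }))
    if (is.null(comparisons))
      comparisons <- data.frame(tissue = character(0), feature = character(0),
                                test = character(0), stat = numeric(0), p = numeric(0))
    .emit(comparisons, config$outdir, "06_feature_comparisons")
  }

  ## stage 7: peak processing --------------------------------------------
  peak_meta_res <- NULL; peak_de <- NULL; diff_peaks <- NULL
  pk <- bundle$peaks
  have_atac <- !is.null(bundle$atac_counts) && nrow(pk) > 0
  if (have_atac) {
    pk <- trim_peaks(pk, width = th$peak_width, chrom_lengths = bundle$chrom_lengths)
    keep <- filter_peaks(bundle$atac_counts, peaks = pk,
                         min_reads = th$peak_min_reads,
                         min_samples = th$peak_min_samples,
                         chroms_allowed = unique(ann$chrom))
    note("peaks: %d in, %d pass the read-support filter", nrow(pk), length(keep))
    pk <- pk[pk$peak_id %in% keep, , drop = FALSE]
    pc <- bundle$atac_counts[keep, , drop = FALSE]
    am <- bundle$atac_meta
    atiss <- am$tissue[match(colnames(pc), am$sample_id)]
    pvals <- list()
    for (ti in tissues) {
      sel <- colnames(pc)[atiss == ti]
      sub <- pc[, sel, drop = FALSE]
      msub <- am[match(sel, am$sample_id), ]
      sf <- median_of_ratios_factors(sub)
      lx <- log2(sweep(sub, 2, sf, "/") + 1)
      pm <- vapply(c("male", "female"), function(sx) {
        idx <- which(msub$sex == sx)
        ftest_any_timepoint(lx[, idx, drop = FALSE], msub$timepoint_weeks[idx])
      }, numeric(nrow(sub)))
      mr <- meta_training_response(pm, tissue = NULL, fdr_max = th$peak_fdr_max)
      mr$tissue <- ti
      mr$feature_id <- rownames(sub)
      pvals[[ti]] <- mr
    }
    peak_meta_res <- do.call(rbind, pvals)
    if (length(tissues) > 1) {
      # adjust across tissues with tissue as the weighting covariate
      peak_meta_res$adj_p <- grouped_bh(peak_meta_res$meta_p, peak_meta_res$tissue)
      peak_meta_res$is_differential <- peak_meta_res$adj_p <= th$peak_fdr_max
    }
    rownames(peak_meta_res) <- NULL
    .emit(peak_meta_res, config$outdir, "07_peak_meta")
    peak_de <- de_timewise(pc, am)
    diff_peaks <- lapply(setNames(tissues, tissues), function(ti)
      peak_meta_res$feature_id[peak_meta_res$tissue == ti & peak_meta_res$is_differential])
    note("peaks: %s training-differential per tissue",
         paste(vapply(diff_peaks[tissues], length, integer(1)), collapse = "/"))
  }

  ## stages 8-9: pairing, correlation, density, triads --------------------
  pairs_all <- list(); triads_all <- list(); density <- list()
  if (have_atac) {
    for (ti in tissues) {
      lnc_ann <- ann[ann$gene_id %in% delnc[[ti]], , drop = FALSE]
      dpk <- pk[pk$peak_id %in% diff_peaks[[ti]], , drop = FALSE]
      pr <- pair_lnc_peaks(lnc_ann, dpk, window = th$pair_window)
      if (nrow(pr)) {
        pr <- correlate_pairs(pr, de[de$tissue == ti & de$gene_id %in% lnc_ann$gene_id, ],
                              peak_de[peak_de$tissue == ti, ],
                              mode = config$modes$correlation)
      } else pr$r <- numeric(0)
      if (nrow(pr)) {
        density[[ti]] <- density_summary(pr, ann, pk, window = th$pair_window)
        nt <- assign_nearest_tss(dpk[dpk$peak_id %in% pr$peak_id, , drop = FALSE], ann)
        tri <- build_triads(pr, nt, de[de$tissue == ti, ], r_min = th$r_min)
      } else {
        tri <- build_triads(pr, data.frame(peak_id = character(0),
                                           gene_id = character(0),
                                           distance_to_tss = numeric(0)))
      }
      if (nrow(pr)) pairs_all[[ti]] <- cbind(tissue = ti, pr)
      if (nrow(tri)) triads_all[[ti]] <- cbind(tissue = ti, tri)
      note("link %s: %d pairs, %d triads", ti, nrow(pr), nrow(tri))
    }
  }
  pairs_tab <- if (length(pairs_all)) do.call(rbind, pairs_all) else
    data.frame(tissue = character(0), lnc_id = character(0),
               peak_id = character(0), midpoint_distance = numeric(0),
               r = numeric(0), n_points = integer(0))
  rownames(pairs_tab) <- NULL
  .emit(pairs_tab, config$outdir, "08_pairs")
  dens_tab <- do.call(rbind, lapply(names(density), function(ti) {
    kk <- density[[ti]]$kde
    if (is.null(kk)) return(NULL)
    data.frame(tissue = ti,
               distance = rep(kk$x, times = length(kk$y)),
               r = rep(kk$y, each = length(kk$x)),
               density = as.vector(kk$z))
  }))
  if (is.null(dens_tab))
    dens_tab <- data.frame(tissue = character(0), distance = numeric(0),
                           r = numeric(0), density = numeric(0))
  .emit(dens_tab, config$outdir, "08_density_grid")
  triads_tab <- if (length(triads_all)) do.call(rbind, triads_all) else
    data.frame(tissue = character(0), lnc_id = character(0),
               peak_id = character(0), gene_id = character(0),
               distance_to_tss = numeric(0), r = numeric(0),
               activity_score = numeric(0), gene_direction = character(0))
  rownames(triads_tab) <- NULL
  .emit(triads_tab, config$outdir, "09_triads")

  ## stage 10: ceRNA network ----------------------------------------------
  net <- NULL
  if (!is.null(config$paths$lnc_mirna) && !is.null(config$paths$mirna_mrna) &&
      !is.null(config$focus_lnc)) {
    lm_ <- read_interactions(config$paths$lnc_mirna, "lnc_mirna")
    mm_ <- read_interactions(config$paths$mirna_mrna, "mirna_mrna")
    up <- unique(de$gene_id[de$is_differential %in% TRUE & de$log2fc > 0 &
                              biot[de$gene_id] == "protein_coding"])
    net <- build_cerna_network(lm_, mm_, up, config$focus_lnc)
    write_cerna_network(net, file.path(config$outdir, "10_network_edges.tsv"),
                        file.path(config$outdir, "10_network_summary.json"))
  } else {
    .emit(data.frame(source_id = character(0), target_id = character(0),
                     kind = character(0)), config$outdir, "10_network_edges")
  }

  ## stage 11: enrichment -------------------------------------------------
  enr <- NULL
  if (!is.null(config$paths$gmt)) {
    sets <- read_gmt(config$paths$gmt)
    universe <- ann$gene_id[ann$biotype == "protein_coding"]
    enr <- do.call(rbind, lapply(c("up", "down"), function(dd) {
      q <- unique(triads_tab$gene_id[triads_tab$gene_direction == dd])
      if (!length(q)) return(NULL)
      cbind(direction = dd, hypergeom_enrich(q, universe, sets,
                                             fdr_max = th$enrich_fdr))
    }))
  }
  if (is.null(enr))
    enr <- data.frame(direction = character(0), set_id = character(0),
                      set_size = integer(0), overlap = integer(0),
                      p = numeric(0), adj_p = numeric(0), is_enriched = logical(0))
  .emit(enr, config$outdir, "11_enrichment")

  ## manifest -------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(list(simulate = if (!is.null(config$simulate))
    unclass(config$simulate), paths = config$paths,
    thresholds = th, modes = config$modes, seed = config$seed),
    auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- file.path(config$outdir, ".config.json")
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package = "lnclink",
    package_version = as.character(utils::packageVersion("lnclink")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    stages = c("filters", "de", "delnc", "trajectories", "clustering",
               "features", "peaks", "pairing", "triads", "network",
               "enrichment"),
    log = stage_log
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(outdir = config$outdir, de = de, delnc = delnc, deg = deg,
                 trajectories = traj, sex_patterns = sexpat,
                 clusters = cluster_models, features = feats,
                 feature_comparisons = comparisons,
                 peak_meta = peak_meta_res, peak_de = peak_de,
                 pairs = pairs_tab, density = density, triads = triads_tab,
                 network = net, enrichment = enr, validation = rep))
}
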