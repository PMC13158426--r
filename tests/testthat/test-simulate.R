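test_that("the same seed reproduces every artifact bit-identically", {
  cfg <- sim_config(seed = 21, n_tissues = 1, n_genes = 150,
                    n_de_genes_per_cell = 3, n_planted_triads = 2,
                    n_decoy_peaks = 20)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$rna_counts, b$rna_counts)
  expect_identical(a$atac_counts, b$atac_counts)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
})

test_that("a degenerate config yields empty ground truth and null genes", {
  cfg <- sim_config(seed = 3, n_tissues = 1, n_genes = 100,
                    n_de_genes_per_cell = 0, n_planted_triads = 0,
                    n_decoy_peaks = 10)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$truth$planted_de), 0L)
  expect_equal(nrow(sim$truth$planted_triads), 0L)
})

test_that("count-matrix dimensions match the design", {
  cfg <- sim_config(seed = 4, n_tissues = 2, n_genes = 120,
                    replicates_per_cell = 3, n_planted_triads = 0,
                    n_decoy_peaks = 5)
  sim <- simulate_experiment(cfg)
  expect_equal(dim(sim$rna_counts), c(120, 2 * 2 * 5 * 3))
  expect_equal(nrow(sim$rna_meta), ncol(sim$rna_counts))
  expect_true(all(sim$rna_counts >= 0))
  expect_true(all(sim$rna_counts == floor(sim$rna_counts)))
})

test_that("realized lncRNA GC tracks the target within 2 points", {
  sim <- simulate_experiment(sim_config(seed = 1, n_tissues = 1, n_genes = 300,
                                        n_planted_triads = 0, n_decoy_peaks = 0))
  lnc <- sim$annotation$gene_id[sim$annotation$biotype == "lncRNA"]
  # independent recount: tally characters directly, no Biostrings
  gc_tally <- vapply(sim$sequences[lnc], function(s) {
    ch <- strsplit(s, "")[[1]]
    100 * sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
  }, numeric(1))
  expect_lt(abs(mean(gc_tally) - 44), 2)
  # and lncRNAs are GC-poorer and less abundant than coding genes
  cod <- sim$annotation$gene_id[sim$annotation$biotype == "protein_coding"]
  expect_lt(mean(gc_tally), mean(gc_content(sim$sequences[cod])))
  expect_lt(mean(sim$rna_counts[lnc, ]), mean(sim$rna_counts[cod, ]))
})

test_that("planted effects are recovered near their nominal size", {
  cfg <- sim_config(seed = 5, n_tissues = 1, n_genes = 400,
                    n_de_genes_per_cell = 8, n_planted_triads = 0,
                    n_decoy_peaks = 0)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth$planted_de
  meta <- sim$rna_meta
  ratios <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- meta$sample_id[meta$sex == truth$sex[i] &
                           meta$timepoint_weeks == truth$timepoint_weeks[i]]
    ct <- meta$sample_id[meta$sex == truth$sex[i] & meta$timepoint_weeks == 0]
    log2(mean(sim$rna_counts[truth$gene_id[i], tr]) /
           mean(sim$rna_counts[truth$gene_id[i], ct]))
  }, numeric(1))
  # NB noise in a 5-vs-5 mean ratio has log2 sd ~0.2-0.4 depending on the
  # gene's mean, so the bulk (not all) of planted genes land within 0.5
  dev <- abs(ratios - truth$true_log2fc)
  expect_gt(mean(dev <= 0.5), 0.8)
  expect_lt(median(dev), 0.25)
})

test_that("planted triads satisfy their geometric and correlation contracts", {
  cfg <- sim_config(seed = 6, n_tissues = 1, n_genes = 500,
                    n_planted_triads = 8, n_decoy_peaks = 50)
  sim <- simulate_experiment(cfg)
  tri <- sim$truth$planted_triads
  expect_equal(nrow(tri), 8L)
  expect_true(all(tri$tss_distance <= cfg$triad_max_tss_distance))
  ann <- sim$annotation
  pk <- sim$peaks[match(tri$peak_id, sim$peaks$peak_id), ]
  mid <- ann$midpoint[match(tri$lnc_id, ann$gene_id)]
  expect_true(all(abs(mid - pk$summit) <= 500000))
  expect_true(all(ann$chrom[match(tri$lnc_id, ann$gene_id)] == pk$chrom))
  # realized trajectory correlation stays near the target
  de <- de_timewise(sim$rna_counts, sim$rna_meta)
  pde <- de_timewise(sim$atac_counts, sim$atac_meta)
  pairs <- data.frame(lnc_id = tri$lnc_id, peak_id = tri$peak_id,
                      midpoint_distance = abs(mid - pk$summit))
  cp <- correlate_pairs(pairs, de[de$gene_id %in% tri$lnc_id, ], pde)
  expect_true(all(cp$r >= cfg$triad_r_target - 0.15))
})

test_that("infeasible layouts are rejected", {
  expect_error(
    simulate_experiment(sim_config(seed = 7, n_chromosomes = 1,
                                   chrom_length = 5e4, n_genes = 200)),
    "layout-infeasible")
})

test_that("sequence simulation honors GC boundaries and planted ORFs", {
  ann <- data.frame(gene_id = c("a", "b"), chrom = "chr1", start = c(0, 2000),
                    end = c(1000, 3000), strand = "+",
                    biotype = c("lncRNA", "protein_coding"))
  ann$exons <- list(cbind(start = 0L, end = 300L), cbind(start = 2000L, end = 2300L))
  ann$exonic_length <- c(300, 300)
  at_only <- simulate_sequences(ann, gc_targets = c(protein_coding = 0,
                                                    lncRNA = 0, other = 0),
                                planted_orfs = c(protein_coding = 0,
                                                 lncRNA = 0, other = 0),
                                seed = 1)
  expect_true(all(strsplit(at_only[["a"]], "")[[1]] %in% c("A", "T")))
  with_orf <- simulate_sequences(ann, seed = 2)
  hits <- find_orfs(with_orf["b"], both_strands = FALSE)
  expect_gte(nrow(hits[hits$length_nt >= 30 & !hits$open_ended, ]), 1L)
  expect_identical(simulate_sequences(ann, seed = 3),
                   simulate_sequences(ann, seed = 3))
  expect_error(simulate_sequences(ann, gc_targets = c(protein_coding = 101,
                                                      lncRNA = 44, other = 50)),
               "gc targets")
})

test_that("written artifacts round-trip through the readers", {
  sim <- simulate_experiment(sim_config(seed = 8, n_tissues = 1, n_genes = 60,
                                        n_planted_triads = 2, n_decoy_peaks = 5))
  dir <- withr::local_tempdir()
  write_sim_experiment(sim, dir)
  ann2 <- read_annotation(file.path(dir, "annotation.gtf"))
  expect_equal(ann2$gene_id, sim$annotation$gene_id)
  expect_equal(ann2$exons, sim$annotation$exons, ignore_attr = TRUE)
  counts2 <- read_matrix(file.path(dir, "rna_counts.tsv"))
  expect_equal(unname(counts2), unname(sim$rna_counts), ignore_attr = TRUE)
  expect_identical(read_fasta(file.path(dir, "transcripts.fa")), sim$sequences)
  pk2 <- read_bed_peaks(file.path(dir, "peaks.bed"))
  expect_equal(pk2$start, sim$peaks$start)
  expect_equal(pk2$summit, sim$peaks$summit)
})
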