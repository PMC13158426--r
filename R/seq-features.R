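#' GC content of nucleotide sequences
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous `N` bases are excluded from
#' the denominator. A sequence consisting only of `N` returns `NA`.
#'
#' @param seq Character vector of sequences over `{A, C, G, T, N}`.
#' @return Numeric vector of GC percentages.
#' @export
gc_content <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  fr <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(fr)
  out <- 100 * (fr[, "G"] + fr[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

.STOPS <- c("TAA", "TAG", "TGA")

# Forward-strand ORF scan of one sequence: for each frame, split the codon
# stream at stop codons; within each stop-bounded span report the outermost
# (first) start codon. Coordinates are 0-based half-open on the scanned
# strand's sequence.
.scan_orfs_fwd <- function(seq, min_len, start_codon, include_open_ended) {
  n <- nchar(seq)
  hits <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 1) next
    starts <- frame + 3 * (seq_len(ncod) - 1)
    codons <- substring(seq, starts + 1, starts + 3)
    is_stop <- codons %in% .STOPS
    is_start <- codons == start_codon
    span_id <- cumsum(c(0, head(is_stop, -1)))
    for (sp in split(seq_len(ncod), span_id)) {
      st <- sp[is_start[sp]]
      if (!length(st)) next
      a <- st[1]  # outermost start in this stop-bounded span
      last <- sp[length(sp)]
      open_ended <- !is_stop[last]
      if (open_ended && !include_open_ended) next
      s0 <- starts[a]
      e0 <- starts[last] + 3
      if (e0 - s0 < min_len) next
      hits[[length(hits) + 1L]] <- data.frame(
        frame = frame, start = s0, end = e0, length_nt = e0 - s0,
        open_ended = open_ended, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, hits)
}

#' Scan sequences for open reading frames
#'
#' Finds every maximal start-to-stop span of at least `min_len` nt in all
#' three frames, optionally on both strands. Within one stop-bounded span
#' only the outermost (longest) ORF per frame is reported. ORFs reaching
#' the sequence end without an in-frame stop are reported with
#' `open_ended = TRUE` (configurable). Minus-strand coordinates refer to
#' the reverse-complemented sequence.
#'
#' @param seqs Named character vector of sequences.
#' @param min_len Minimum ORF length in nt (start through stop inclusive).
#' @param start_codon Required start codon.
#' @param both_strands Scan the reverse complement as well.
#' @param include_open_ended Keep ORFs lacking an in-frame stop.
#' @return data.frame with `seq_id`, `strand`, `frame`, `start`, `end`,
#'   `length_nt`, `open_ended`.
#' @export
find_orfs <- function(seqs, min_len = 30, start_codon = "ATG",
                      both_strands = TRUE, include_open_ended = TRUE) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  out <- lapply(names(seqs), function(id) {
    fw <- .scan_orfs_fwd(seqs[[id]], min_len, start_codon, include_open_ended)
    res <- if (!is.null(fw)) cbind(seq_id = id, strand = "+", fw)
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[[id]])))
      rv <- .scan_orfs_fwd(rc, min_len, start_codon, include_open_ended)
      if (!is.null(rv)) res <- rbind(res, cbind(seq_id = id, strand = "-", rv))
    }
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(seq_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      length_nt = integer(0), open_ended = logical(0)))
  rownames(out) <- NULL
  out[c("seq_id", "strand", "frame", "start", "end", "length_nt", "open_ended")]
}

#' Secondary-structure folding score (base-pair maximization proxy)
#'
#' A dynamic-programming proxy for folding propensity: maximizes the total
#' weight of nested Watson-Crick + GU base pairs with a minimum hairpin
#' loop of `min_loop` unpaired bases. `"nussinov_pairs"` weights every pair
#' 1 (score = minus the maximum pair count); `"stacking_toy"` weights
#' GC = 3, AU = 2, GU = 1. More negative scores indicate more pairing. This
#' is deliberately not a thermodynamic nearest-neighbor minimum free
#' energy; it is used only for group-level distribution comparisons.
#'
#' @param seq A single sequence (character scalar).
#' @param scoring `"nussinov_pairs"` or `"stacking_toy"`.
#' @param min_loop Minimum unpaired loop length.
#' @param max_len Length cap (the DP is O(n^3)).
#' @return List with `score` (<= 0) and dot-bracket `structure`.
#' @export
fold_score <- function(seq, scoring = c("nussinov_pairs", "stacking_toy"),
                       min_loop = 3, max_len = 3000) {
  scoring <- match.arg(scoring)
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  if (nchar(seq) > max_len)
    .fail("sequence length %d exceeds the %d-nt cap; truncate or chunk the input",
          nchar(seq), max_len)
  mode <- if (scoring == "nussinov_pairs") 0L else 1L
  res <- .nussinov_fold(toupper(seq), mode, as.integer(min_loop))
  list(seq_id = names(seq) %||% NA_character_, score = res$score,
       structure = res$structure)
}

#' Compare feature distributions between two groups
#'
#' Two-sided Mann-Whitney U or Kolmogorov-Smirnov test, used for
#' differential-lncRNA versus differential-coding-gene comparisons of
#' transcript length (log2 nt), exonic GC (%), folding score and
#' expression level.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 3).
#' @param test `"mannwhitney"` or `"ks"`.
#' @return List with `stat` and `p`.
#' @export
compare_feature_distributions <- function(values_a, values_b,
                                          test = c("mannwhitney", "ks")) {
  test <- match.arg(test)
  if (length(values_a) < 3L || length(values_b) < 3L)
    .fail("each group needs at least 3 values")
  if (test == "mannwhitney") {
    ht <- stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                             exact = FALSE, correct = TRUE)
  } else {
    ht <- suppressWarnings(stats::ks.test(values_a, values_b,
                                          alternative = "two.sided"))
  }
  list(stat = unname(ht$statistic), p = unname(ht$p.value))
}

#' Per-transcript sequence feature table
#'
#' Computes transcript length, exonic GC content, ORF count and folding
#' score for a set of transcript sequences. Folding uses at most the first
#' `fold_max_len` nt of each transcript (a fixed-length 5' window keeps the
#' O(n^3) DP tractable and removes the length confound from the folding
#' comparison).
#'
#' @param seqs Named character vector of spliced transcript sequences.
#' @param fold_max_len 5' window length for folding; `0` skips folding.
#' @param scoring Folding weight scheme, see [fold_score()].
#' @return data.frame with `gene_id`, `length_nt`, `gc_pct`, `n_orfs`,
#'   `fold_score`.
#' @export
feature_table <- function(seqs, fold_max_len = 300,
                          scoring = "nussinov_pairs") {
  orfs <- find_orfs(seqs)
  n_orfs <- table(factor(orfs$seq_id, levels = names(seqs)))
  fold <- if (fold_max_len > 0) {
    vapply(seqs, function(s) {
      fold_score(substr(s, 1, fold_max_len), scoring = scoring)$score
    }, numeric(1))
  } else rep(NA_real_, length(seqs))
  data.frame(
    gene_id = names(seqs),
    length_nt = nchar(seqs),
    gc_pct = gc_content(seqs),
    n_orfs = as.integer(n_orfs),
    fold_score = unname(fold),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
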