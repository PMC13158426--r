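# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Brute-force folding oracle: exhaustively enumerates every nested pairing
# (no memoization) and returns the best total pair weight. Feasible for
# sequences up to ~12 nt.
bf_pair_weight <- function(a, b, mode) {
  pair <- paste0(a, b)
  w <- switch(pair,
              "GC" = , "CG" = 3,
              "AT" = , "TA" = , "AU" = , "UA" = 2,
              "GT" = , "TG" = , "GU" = , "UG" = 1,
              0)
  if (mode == "nussinov_pairs" && w > 0) 1 else w
}

bf_fold_best <- function(seq, mode = "nussinov_pairs", min_loop = 3) {
  s <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i, j - 1)                       # j unpaired
    for (k in i:(j - min_loop - 1)) {
      w <- bf_pair_weight(s[k + 1], s[j + 1], mode)  # 0-based -> 1-based
      if (w > 0) {
        left <- if (k > i) rec(i, k - 1) else 0
        inner <- rec(k + 1, j - 1)
        best <- max(best, left + inner + w)
      }
    }
    best
  }
  n <- length(s)
  if (n < 2) return(0)
  -rec(0, n - 1)
}

# Naive ORF oracle: test every position for a start codon, walk codon by
# codon to the first in-frame stop (or sequence end), then keep only the
# outermost ORF per frame and stop.
bf_orf_scan <- function(seq, min_len = 30, include_open_ended = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  hits <- list()
  for (p in seq_len(max(n - 2, 0))) {
    if (substr(seq, p, p + 2) != "ATG") next
    q <- p
    end <- NA
    open <- TRUE
    while (q + 2 <= n) {
      if (substr(seq, q, q + 2) %in% stops) { end <- q + 2; open <- FALSE; break }
      q <- q + 3
    }
    if (open) end <- q - 1  # last complete codon
    len <- end - p + 1
    if (len < min_len) next
    if (open && !include_open_ended) next
    hits[[length(hits) + 1]] <- data.frame(
      frame = (p - 1) %% 3, start = p - 1, end = end, length_nt = len,
      open_ended = open)
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  # outermost per (frame, end): the smallest start wins
  h <- h[order(h$frame, h$end, h$start), ]
  h[!duplicated(h[c("frame", "end")]), , drop = FALSE]
}

# Exhaustive hypergeometric upper tail.
bf_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# Brute-force nearest coding TSS.
bf_nearest_tss <- function(summit, chrom, ann) {
  cc <- ann[ann$biotype == "protein_coding" & ann$chrom == chrom, ]
  d <- abs(summit - cc$tss)
  o <- order(d, cc$gene_id)
  list(gene_id = cc$gene_id[o[1]], distance = d[o[1]])
}

# Adjusted Rand index between two label vectors (contingency formula).
rand_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Flood-fill connected components on an undirected edge list.
bf_components <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$source_id[i]; b <- edges$target_id[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  n_comp <- 0
  for (v in nodes) {
    if (seen[v]) next
    n_comp <- n_comp + 1
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[u]) next
      seen[u] <- TRUE
      queue <- c(queue, adj[[u]])
    }
  }
  n_comp
}

# Random DNA sequence.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
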