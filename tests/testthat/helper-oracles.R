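# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately re-derive everything from raw exon
# matrices with naive loops and their own key encodings.

brute_level_set <- function(ann, level, ignore_strand = FALSE) {
  out <- character(0)
  tx <- transcripts(ann)
  for (i in seq_len(nrow(tx))) {
    ex <- ann$exons[[i]]
    k <- nrow(ex)
    if (k < 2L) next
    st <- if (ignore_strand) "." else tx$strand[i]
    a <- ex[-k, 2] + 1
    b <- ex[-1L, 1] - 1
    out <- c(out, switch(level,
      boundary = paste(tx$chrom[i], st, c(a, b)),
      junction = paste(tx$chrom[i], st, a, b),
      chain = paste(tx$chrom[i], st, paste(a, b, collapse = " "))))
  }
  unique(out)
}

brute_jaccard <- function(T1, T2, level, ignore_strand = FALSE) {
  a <- brute_level_set(T1, level, ignore_strand)
  b <- brute_level_set(T2, level, ignore_strand)
  u <- length(union(a, b))
  if (u == 0L) NA_real_ else length(intersect(a, b)) / u
}

# O(n^2) all-pairs intron-retention classifier with inline geometry and no
# span prefilter.
brute_ir_flags <- function(assembly, cr = 0.5, lr = 0, partial = TRUE,
                           entire = TRUE, ignore_strand = FALSE) {
  tx <- transcripts(assembly)
  n <- nrow(tx)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    tex <- assembly$exons[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      if (tx$chrom[i] != tx$chrom[j]) next
      if (!ignore_strand && tx$strand[i] != tx$strand[j]) next
      rex <- assembly$exons[[j]]
      if (nrow(rex) < 2L) next
      pt <- tx$abundance[i]; pr <- tx$abundance[j]
      gate <- if (is.na(pt) && is.na(pr)) TRUE
        else if (is.na(pr)) TRUE
        else if (is.na(pt) || pt == 0) pr > 0
        else pr / pt >= cr
      if (!gate) next
      k <- nrow(rex)
      ia <- rex[-k, 2] + 1
      ib <- rex[-1L, 1] - 1
      hit <- FALSE
      if (partial) {
        s <- tex[1, 1]; e <- tex[1, 2]
        for (m in seq_along(ia))
          if (s > ia[m] && s <= ib[m] && e > ib[m] &&
              (ib[m] - s + 1) / (ib[m] - ia[m] + 1) >= lr) hit <- TRUE
        s <- tex[nrow(tex), 1]; e <- tex[nrow(tex), 2]
        for (m in seq_along(ia))
          if (e >= ia[m] && e < ib[m] && s < ia[m] &&
              (e - ia[m] + 1) / (ib[m] - ia[m] + 1) >= lr) hit <- TRUE
      }
      if (entire && !hit)
        for (m in seq_along(ia))
          if (any(tex[, 1] <= ia[m] & tex[, 2] >= ib[m])) hit <- TRUE
      if (hit) { flagged[i] <- TRUE; break }
    }
  }
  flagged
}

# All-pairs transcript matcher.
brute_match_flags <- function(assembly, reference, frac = 0.8,
                              reciprocal = TRUE) {
  atx <- transcripts(assembly)
  rtx <- transcripts(reference)
  matched <- logical(nrow(atx))
  chains <- function(ex) {
    k <- nrow(ex)
    if (k < 2L) return(NULL)
    cbind(ex[-k, 2] + 1, ex[-1L, 1] - 1)
  }
  for (i in seq_len(nrow(atx))) {
    ca <- chains(assembly$exons[[i]])
    for (j in seq_len(nrow(rtx))) {
      if (atx$chrom[i] != rtx$chrom[j] || atx$strand[i] != rtx$strand[j]) next
      cr <- chains(reference$exons[[j]])
      if (!is.null(ca) && !is.null(cr)) {
        if (nrow(ca) == nrow(cr) && all(ca == cr)) matched[i] <- TRUE
      } else if (is.null(ca) && is.null(cr)) {
        ov <- min(atx$end[i], rtx$end[j]) - max(atx$start[i], rtx$start[j]) + 1
        la <- atx$end[i] - atx$start[i] + 1
        lr <- rtx$end[j] - rtx$start[j] + 1
        ok <- if (reciprocal) ov >= frac * la && ov >= frac * lr
              else ov >= frac * la
        if (ok) matched[i] <- TRUE
      }
      if (matched[i]) break
    }
  }
  matched
}

# Random assembly on a 10-bp coordinate grid so exon lengths are >= 10 and
# gaps >= 9 (always a valid model). Several transcripts share each locus so
# pairwise interactions actually occur.
random_assembly <- function(n, seed, n_chrom = 2, na_abundance = 0.1,
                            zero_abundance = 0.05) {
  set.seed(seed)
  n_loci <- max(1L, ceiling(n / 6))
  txs <- vector("list", n)
  for (i in seq_len(n)) {
    locus <- sample.int(n_loci, 1)
    base <- locus * 100000
    k <- sample(1:5, 1)
    pos <- sort(sample(seq(base, base + 5000, by = 10), 2 * k))
    ex <- cbind(pos[seq(1, 2 * k, 2)], pos[seq(2, 2 * k, 2)])
    ab <- round(runif(1, 0, 20), 2)
    u <- runif(1)
    if (u < na_abundance) ab <- NA_real_
    else if (u < na_abundance + zero_abundance) ab <- 0
    txs[[i]] <- transcript(
      sprintf("tx%04d", i), sprintf("locus%03d", locus),
      paste0("chr", 1 + (locus %% n_chrom)),
      sample(c("+", "-"), 1), ex, abundance = ab)
  }
  as_annotation(txs, name = sprintf("random%d", seed))
}

# A pair of annotations with partially shared content, for similarity tests.
random_annotation_pair <- function(seed) {
  set.seed(seed)
  sim <- simulate_annotation_pair(
    n_shared = sample(1:5, 1), n_private = sample(0:4, 1),
    n_subchain = 0, seed = seed)
  list(T1 = sim$T1, T2 = sim$T2)
}

# First half of `a` plus first half of `b` (ids prefixed), used to build
# assemblies that partially match a reference.
bind_ann_halves <- function(a, b) {
  ka <- a[seq_len(ceiling(length(a) / 2))]
  kb <- b[seq_len(ceiling(length(b) / 2))]
  txs <- c(
    lapply(seq_len(length(ka)), function(i) get_transcript(ka, i)),
    lapply(seq_len(length(kb)), function(i) {
      t <- get_transcript(kb, i)
      t$transcript_id <- paste0("q.", t$transcript_id)
      t
    }))
  as_annotation(txs, name = "mixed")
}
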