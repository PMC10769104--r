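#' Jaccard similarity of two annotations
#'
#' Measures the structural similarity of two annotations as the Jaccard
#' index |S(T1) n S(T2)| / |S(T1) u S(T2)|, where S is the set constructor
#' selected by `level`: intron-exon boundaries, junctions, or full intron
#' chains (see [boundary_set()]). All multi-exon transcripts participate;
#' single-exon transcripts carry no splice structure and contribute nothing.
#'
#' @param T1,T2 `annotation` objects.
#' @param level `"boundary"`, `"junction"` or `"chain"`.
#' @param ignore_strand If `TRUE`, strand is ignored when comparing
#'   structures.
#' @return A number in \[0, 1\], or `NA` when both sets are empty (the
#'   similarity is undefined, which is reported as such rather than as 0).
#' @examples
#' pair <- example_annotation_pair()
#' annotation_jaccard(pair$T1, pair$T2, "boundary")  # 5/6
#' annotation_jaccard(pair$T1, pair$T2, "junction")  # 5/8
#' annotation_jaccard(pair$T1, pair$T2, "chain")     # 1/3
#' @export
annotation_jaccard <- function(T1, T2,
                               level = c("boundary", "junction", "chain"),
                               ignore_strand = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(T1, "annotation"), inherits(T2, "annotation"))
  f <- switch(level, boundary = boundary_set, junction = junction_set,
              chain = chain_set)
  jaccard(f(T1, ignore_strand = ignore_strand),
          f(T2, ignore_strand = ignore_strand))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Pair genes of two annotations by shared boundaries
#'
#' Two genes g1 in T1 and g2 in T2 form a pair when they share at least one
#' intron-exon boundary, i.e. B(g1) n B(g2) is non-empty. Only multi-exon
#' genes (genes with at least one multi-exon transcript) participate. One
#' gene may appear in several pairs. For every pair the Jaccard similarity
#' at the boundary, junction and intron-chain level is computed from the
#' gene-level sets; the boundary value is positive by construction.
#'
#' @param T1,T2 `annotation` objects.
#' @param ignore_strand If `TRUE`, boundaries on different strands may match.
#' @return A data frame of class `"gene_pairs"` with columns `gene_a`,
#'   `gene_b`, `jacc_boundary`, `jacc_junction`, `jacc_chain`, sorted by
#'   gene ids.
#' @examples
#' pair <- example_annotation_pair()
#' pair_genes(pair$T1, pair$T2)
#' @export
pair_genes <- function(T1, T2, ignore_strand = FALSE) {
  stopifnot(inherits(T1, "annotation"), inherits(T2, "annotation"))
  sets_a <- gene_level_sets(T1, ignore_strand)
  sets_b <- gene_level_sets(T2, ignore_strand)
  # invert: boundary key -> gene ids, then join on keys
  map_a <- boundary_gene_map(sets_a)
  map_b <- boundary_gene_map(sets_b)
  common <- intersect(names(map_a), names(map_b))
  cand <- unique(do.call(rbind, lapply(common, function(k)
    expand.grid(gene_a = map_a[[k]], gene_b = map_b[[k]],
                stringsAsFactors = FALSE))))
  if (is.null(cand) || nrow(cand) == 0L) {
    cand <- data.frame(gene_a = character(0), gene_b = character(0),
                       stringsAsFactors = FALSE)
  }
  cand <- cand[order(cand$gene_a, cand$gene_b), , drop = FALSE]
  res <- data.frame(
    gene_a = cand$gene_a, gene_b = cand$gene_b,
    jacc_boundary = rep(NA_real_, nrow(cand)),
    jacc_junction = rep(NA_real_, nrow(cand)),
    jacc_chain = rep(NA_real_, nrow(cand)), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    a <- sets_a[[res$gene_a[i]]]
    b <- sets_b[[res$gene_b[i]]]
    res$jacc_boundary[i] <- jaccard(a$boundary, b$boundary)
    res$jacc_junction[i] <- jaccard(a$junction, b$junction)
    res$jacc_chain[i] <- jaccard(a$chain, b$chain)
  }
  rownames(res) <- NULL
  class(res) <- c("gene_pairs", "data.frame")
  res
}

gene_level_sets <- function(ann, ignore_strand = FALSE) {
  multi <- ann$tx$n_exons > 1L
  gids <- sort(unique(ann$tx$gene_id[multi]))
  sets <- lapply(gids, function(g) {
    idx <- which(ann$tx$gene_id == g)
    list(boundary = ann_keys(ann, boundary_keys_one, idx, ignore_strand),
         junction = ann_keys(ann, junction_keys_one, idx, ignore_strand),
         chain = ann_keys(ann, chain_key_one, idx, ignore_strand))
  })
  names(sets) <- gids
  sets
}

boundary_gene_map <- function(sets) {
  if (length(sets) == 0L) return(list())
  keys <- unlist(lapply(sets, `[[`, "boundary"), use.names = FALSE)
  genes <- rep(names(sets), vapply(sets, function(s) length(s$boundary),
                                   integer(1)))
  split(genes, keys)
}

#' Jaccard similarity of a single gene pair
#'
#' @param T1,T2 `annotation` objects.
#' @param gene_a Gene id in `T1`; `gene_b` gene id in `T2`.
#' @param gene_b See `gene_a`.
#' @param level `"boundary"`, `"junction"` or `"chain"`.
#' @param ignore_strand Ignore strand in the comparison.
#' @return Jaccard index of the gene-level sets (multi-exon transcripts
#'   only), `NA` if both sets are empty.
#' @export
gene_pair_jaccard <- function(T1, T2, gene_a, gene_b,
                              level = c("boundary", "junction", "chain"),
                              ignore_strand = FALSE) {
  level <- match.arg(level)
  f <- switch(level, boundary = boundary_set, junction = junction_set,
              chain = chain_set)
  a <- T1[which(T1$tx$gene_id == gene_a & T1$tx$n_exons > 1L)]
  b <- T2[which(T2$tx$gene_id == gene_b & T2$tx$n_exons > 1L)]
  jaccard(f(a, ignore_strand = ignore_strand),
          f(b, ignore_strand = ignore_strand))
}

#' Distribution of per-pair Jaccard similarities
#'
#' Bins the per-gene-pair Jaccard values at one level and reports the 25th,
#' 50th and 75th percentiles. Percentiles use the nearest-rank rule on the
#' raw values: the p-th percentile of n sorted values is the value at rank
#' `ceiling(p * n)`.
#'
#' @param pairs A `"gene_pairs"` data frame from [pair_genes()], or a
#'   numeric vector of Jaccard values.
#' @param level Which level's values to use when `pairs` is a data frame.
#' @param breaks Histogram bin boundaries over \[0, 1\].
#' @return List with `histogram` (data frame: `bin_lo`, `bin_hi`, `count`)
#'   and `quartiles` (named vector: `q25`, `q50`, `q75`).
#' @export
jaccard_distribution <- function(pairs,
                                 level = c("boundary", "junction", "chain"),
                                 breaks = seq(0, 1, by = 0.05)) {
  level <- match.arg(level)
  v <- if (is.numeric(pairs)) pairs
       else pairs[[paste0("jacc_", level)]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no Jaccard values to summarise")
  bins <- cut(v, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bins))
  vs <- sort(v)
  nr <- function(p) vs[ceiling(p * length(vs))]
  list(histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1L], count = counts),
       quartiles = c(q25 = nr(0.25), q50 = nr(0.50), q75 = nr(0.75)))
}

#' Fraction of a gene-pair catalog recovered by boundary pairing
#'
#' Given an external catalog of gene pairs (for instance pairs of RefSeq and
#' Ensembl gene ids related through gene nomenclature), computes the
#' fraction of catalog pairs that also appear among the pairs constructed by
#' [pair_genes()].
#'
#' @param pairs A `"gene_pairs"` data frame.
#' @param catalog Data frame or two-column matrix whose first column holds
#'   ids in the `gene_a` namespace and second column ids in `gene_b`.
#' @return Fraction in \[0, 1\]; `NaN` if the catalog is empty.
#' @export
validate_pairs_against_catalog <- function(pairs, catalog) {
  catalog <- as.data.frame(catalog, stringsAsFactors = FALSE)
  if (ncol(catalog) < 2L) stop("catalog must have two columns")
  have <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  want <- paste(catalog[[1]], catalog[[2]], sep = "\r")
  if (length(want) == 0L) return(NaN)
  sum(want %in% have) / length(want)
}
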