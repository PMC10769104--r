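#' Introns of a transcript
#'
#' The introns are the gaps between consecutive exons, in 1-based inclusive
#' coordinates: intron start = previous exon end + 1, intron end = next exon
#' start - 1. A transcript with k exons has k - 1 introns; single-exon
#' transcripts have none. Length-1 introns are permitted.
#'
#' @param t A `transcript`, or a two-column exon matrix.
#' @return A two-column matrix (start, end) with one row per intron; zero
#'   rows for single-exon transcripts.
#' @examples
#' t <- transcript("t", "g", "chr1", "+",
#'                 cbind(c(1, 201, 401), c(100, 300, 500)))
#' introns(t)
#' @export
introns <- function(t) {
  ex <- if (inherits(t, "transcript")) t$exons else t
  exon_introns(ex)
}

exon_introns <- function(ex) {
  k <- nrow(ex)
  if (k < 2L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = unname(ex[-k, 2]) + 1, end = unname(ex[-1L, 1]) - 1)
}

# ---- canonical set keys ------------------------------------------------
# Boundaries, junctions and intron chains are represented as canonical
# character keys that embed chromosome and strand, so that set algebra is
# plain set algebra on strings. Strand-blind comparisons substitute ".".

set_strand <- function(strand, ignore_strand) if (ignore_strand) "." else strand

boundary_keys_one <- function(chrom, strand, ex, ignore_strand = FALSE) {
  intr <- exon_introns(ex)
  if (nrow(intr) == 0L) return(character(0))
  pos <- unique(c(intr[, 1], intr[, 2]))
  paste0(chrom, ":", set_strand(strand, ignore_strand), ":", pos)
}

junction_keys_one <- function(chrom, strand, ex, ignore_strand = FALSE) {
  intr <- exon_introns(ex)
  if (nrow(intr) == 0L) return(character(0))
  paste0(chrom, ":", set_strand(strand, ignore_strand), ":",
         intr[, 1], "-", intr[, 2])
}

chain_key_one <- function(chrom, strand, ex, ignore_strand = FALSE) {
  intr <- exon_introns(ex)
  if (nrow(intr) == 0L) return(character(0))
  paste0(chrom, ":", set_strand(strand, ignore_strand), ":",
         paste0(intr[, 1], "-", intr[, 2], collapse = ","))
}

# Apply a per-transcript key builder over (a subset of) an annotation and
# collapse to set semantics.
ann_keys <- function(ann, builder, idx = NULL, ignore_strand = FALSE) {
  if (is.null(idx)) idx <- seq_len(nrow(ann$tx))
  keys <- unlist(lapply(idx, function(i)
    builder(ann$tx$chrom[i], ann$tx$strand[i], ann$exons[[i]], ignore_strand)),
    use.names = FALSE)
  unique(keys)
}

resolve_set_input <- function(x) {
  if (inherits(x, "transcript"))
    return(as_annotation(list(x), name = "transcript"))
  if (inherits(x, "annotation")) return(x)
  stop("expected a 'transcript' or 'annotation' object")
}

#' Boundary, junction and intron-chain sets
#'
#' These three set constructors summarise splice structure at increasing
#' resolution. The boundary set B contains the genomic positions where exons
#' meet introns (splice-site coordinates; transcript start/end positions are
#' not boundaries). The junction set J contains introns as (start, end)
#' pairs. The chain set C contains the full ordered intron chain of each
#' multi-exon transcript. Single-exon transcripts contribute nothing to any
#' of the three sets. For a gene or an annotation the sets are unions over
#' member transcripts, with set semantics (duplicates collapse).
#'
#' Each element is encoded as a canonical string key embedding chromosome
#' and strand (e.g. `"chr1:+:201"`, `"chr1:+:201-300"`,
#' `"chr1:+:201-300,401-500"`), so identity across annotations is exact
#' string equality.
#'
#' @param x A `transcript` or `annotation`.
#' @param genes Optional character vector of gene ids restricting the union
#'   to those genes (used for gene-level sets B(g), J(g), C(g)).
#' @param ignore_strand If `TRUE`, strand is ignored when forming keys.
#' @return Character vector of unique set keys.
#' @examples
#' ann <- example_ir_assembly()
#' length(boundary_set(ann))
#' length(junction_set(ann))
#' length(chain_set(ann))
#' @export
boundary_set <- function(x, genes = NULL, ignore_strand = FALSE) {
  ann <- resolve_set_input(x)
  ann_keys(ann, boundary_keys_one, idx = gene_idx(ann, genes), ignore_strand)
}

#' @rdname boundary_set
#' @export
junction_set <- function(x, genes = NULL, ignore_strand = FALSE) {
  ann <- resolve_set_input(x)
  ann_keys(ann, junction_keys_one, idx = gene_idx(ann, genes), ignore_strand)
}

#' @rdname boundary_set
#' @export
chain_set <- function(x, genes = NULL, ignore_strand = FALSE) {
  ann <- resolve_set_input(x)
  ann_keys(ann, chain_key_one, idx = gene_idx(ann, genes), ignore_strand)
}

gene_idx <- function(ann, genes) {
  if (is.null(genes)) return(NULL)
  idx <- which(ann$tx$gene_id %in% genes)
  if (length(idx) == 0L)
    stop("no transcripts for gene(s): ", paste(genes, collapse = ", "))
  idx
}

# Chain keys per transcript (NA for single-exon); used by matching and
# intersection/union construction.
transcript_chain_keys <- function(ann, ignore_strand = FALSE) {
  vapply(seq_len(nrow(ann$tx)), function(i) {
    k <- chain_key_one(ann$tx$chrom[i], ann$tx$strand[i], ann$exons[[i]],
                       ignore_strand)
    if (length(k) == 0L) NA_character_ else k
  }, character(1))
}
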