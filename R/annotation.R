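#' Construct a transcript
#'
#' A transcript is an ordered set of exons on one chromosome and strand,
#' together with its identifiers, an optional predicted abundance (as
#' reported by assemblers such as StringTie or Scallop) and an optional
#' biotype label (as carried by Ensembl-style annotations).
#'
#' @param transcript_id Character scalar, unique within an annotation.
#' @param gene_id Character scalar.
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param exons Two-column numeric matrix (start, end) of 1-based inclusive
#'   exon coordinates. Rows are sorted genomically; consecutive exons must be
#'   separated by a gap of at least 1 bp.
#' @param abundance Non-negative numeric or `NA` when unknown.
#' @param biotype Character scalar; `""` when absent.
#'
#' @return An object of class `"transcript"`.
#' @examples
#' t <- transcript("t1", "g1", "chr1", "+", cbind(c(100, 300), c(200, 400)))
#' introns(t)
#' @export
transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                       abundance = NA_real_, biotype = "") {
  exons <- check_exons(exons, transcript_id)
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.' for transcript ", transcript_id)
  if (!is.na(abundance) && abundance < 0)
    stop("negative abundance for transcript ", transcript_id)
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons,
    abundance = as.numeric(abundance),
    biotype = as.character(biotype)
  ), class = "transcript")
}

# Validate/normalise an exon matrix: sort, check gaps, merge zero-gap exons.
check_exons <- function(exons, id = "?", merge_adjacent = FALSE) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript ", id, " has no exons")
  if (any(exons[, 1] < 1)) stop("exon start < 1 in transcript ", id)
  if (any(exons[, 2] < exons[, 1])) stop("exon end < start in transcript ", id)
  exons <- exons[order(exons[, 1], exons[, 2]), , drop = FALSE]
  if (nrow(exons) > 1L) {
    gap <- exons[-1L, 1] - exons[-nrow(exons), 2] - 1
    if (any(gap < 1)) {
      if (!merge_adjacent || any(gap < 0))
        stop("overlapping or zero-gap exons in transcript ", id)
      exons <- merge_zero_gaps(exons)
    }
  }
  exons
}

merge_zero_gaps <- function(exons) {
  out <- exons[1L, , drop = FALSE]
  for (i in seq_len(nrow(exons))[-1L]) {
    if (exons[i, 1] == out[nrow(out), 2] + 1)
      out[nrow(out), 2] <- exons[i, 2]
    else
      out <- rbind(out, exons[i, , drop = FALSE])
  }
  out
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s:%s  %d exon(s), span [%d, %d]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              as.integer(min(x$exons[, 1])), as.integer(max(x$exons[, 2]))))
  if (!is.na(x$abundance)) cat(sprintf("  abundance: %g\n", x$abundance))
  if (nzchar(x$biotype)) cat(sprintf("  biotype: %s\n", x$biotype))
  invisible(x)
}

#' Build an annotation from a list of transcripts
#'
#' An annotation is a named collection of transcripts grouped into genes by
#' their `gene_id`. Transcript identifiers must be unique.
#'
#' @param transcripts List of [transcript()] objects.
#' @param name Character label used in printing and reports.
#' @return An object of class `"annotation"`.
#' @examples
#' ann <- as_annotation(list(
#'   transcript("t1", "g1", "chr1", "+", cbind(c(100, 300), c(200, 400)))
#' ), name = "toy")
#' ann
#' @export
as_annotation <- function(transcripts, name = "annotation") {
  stopifnot(is.list(transcripts))
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tx <- data.frame(
    transcript_id = ids,
    gene_id = vapply(transcripts, function(t) t$gene_id, character(1)),
    chrom = vapply(transcripts, function(t) t$chrom, character(1)),
    strand = vapply(transcripts, function(t) t$strand, character(1)),
    abundance = vapply(transcripts, function(t) t$abundance, numeric(1)),
    biotype = vapply(transcripts, function(t) t$biotype, character(1)),
    start = vapply(transcripts, function(t) min(t$exons[, 1]), numeric(1)),
    end = vapply(transcripts, function(t) max(t$exons[, 2]), numeric(1)),
    n_exons = vapply(transcripts, function(t) nrow(t$exons), integer(1)),
    stringsAsFactors = FALSE
  )
  new_annotation(tx, lapply(transcripts, `[[`, "exons"), name = name)
}

# Low-level constructor; exons is a list of matrices parallel to tx rows,
# meta an optional list of raw GTF record text for byte-preserving output.
new_annotation <- function(tx, exons, name = "annotation", meta = NULL) {
  rownames(tx) <- NULL
  structure(list(name = name, tx = tx, exons = exons, meta = meta),
            class = "annotation")
}

#' Number of transcripts in an annotation
#' @param x An `annotation`.
#' @export
length.annotation <- function(x) nrow(x$tx)

#' Subset an annotation by transcript index or id
#'
#' @param x An `annotation`.
#' @param i Integer/logical index into transcripts, or character vector of
#'   transcript ids.
#' @param ... Ignored.
#' @return An `annotation` containing the selected transcripts.
#' @export
`[.annotation` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$tx$transcript_id)
  if (anyNA(i)) stop("unknown transcript id or index")
  new_annotation(x$tx[i, , drop = FALSE], x$exons[i], name = x$name,
                 meta = if (!is.null(x$meta)) x$meta[i])
}

#' Extract one transcript from an annotation
#' @param ann An `annotation`.
#' @param i Index or transcript id.
#' @return A `transcript` object.
#' @export
get_transcript <- function(ann, i) {
  if (is.character(i)) i <- match(i, ann$tx$transcript_id)
  if (is.na(i) || i < 1 || i > nrow(ann$tx)) stop("unknown transcript")
  r <- ann$tx[i, ]
  transcript(r$transcript_id, r$gene_id, r$chrom, r$strand, ann$exons[[i]],
             abundance = r$abundance, biotype = r$biotype)
}

#' Transcript table of an annotation
#'
#' @param ann An `annotation`.
#' @return A data frame with one row per transcript (id, gene, chrom, strand,
#'   abundance, biotype, span and exon count).
#' @export
transcripts <- function(ann) {
  stopifnot(inherits(ann, "annotation"))
  ann$tx
}

#' Gene identifiers of an annotation
#' @param ann An `annotation`.
#' @param multi_exon_only If `TRUE`, keep only genes that have at least one
#'   multi-exon transcript (the genes that carry splice structure).
#' @export
gene_ids <- function(ann, multi_exon_only = FALSE) {
  g <- ann$tx$gene_id
  if (multi_exon_only) g <- g[ann$tx$n_exons > 1L]
  sort(unique(g))
}

#' @export
print.annotation <- function(x, ...) {
  n <- nrow(x$tx)
  cat(sprintf("annotation '%s': %d transcript(s), %d gene(s), %d multi-exon\n",
              x$name, n, length(unique(x$tx$gene_id)),
              sum(x$tx$n_exons > 1L)))
  if (n > 0L)
    cat("  chromosomes:", paste(sort(unique(x$tx$chrom)), collapse = ", "),
        "\n")
  ps <- attr(x, "parse_summary")
  if (!is.null(ps))
    cat(sprintf("  parsed: %d exon, %d transcript, %d other record(s); %d merged exon pair(s); %d dropped transcript(s)\n",
                ps$n_exon_records, ps$n_transcript_records, ps$n_other_records,
                ps$n_merged, length(ps$dropped)))
  invisible(x)
}

#' @export
summary.annotation <- function(object, ...) {
  tx <- object$tx
  out <- list(
    name = object$name,
    n_transcripts = nrow(tx),
    n_genes = length(unique(tx$gene_id)),
    n_multi_exon = sum(tx$n_exons > 1L),
    n_single_exon = sum(tx$n_exons == 1L),
    with_abundance = sum(!is.na(tx$abundance)),
    biotypes = sort(table(tx$biotype[nzchar(tx$biotype)]), decreasing = TRUE)
  )
  class(out) <- "summary.annotation"
  out
}

#' @export
print.summary.annotation <- function(x, ...) {
  cat(sprintf("annotation '%s'\n", x$name))
  cat(sprintf("  transcripts: %d (%d multi-exon, %d single-exon) in %d genes\n",
              x$n_transcripts, x$n_multi_exon, x$n_single_exon, x$n_genes))
  cat(sprintf("  with abundance: %d\n", x$with_abundance))
  if (length(x$biotypes))
    cat("  biotypes:",
        paste(sprintf("%s=%d", names(x$biotypes), x$biotypes), collapse = ", "),
        "\n")
  invisible(x)
}

# Combine annotations; transcript ids colliding across parts are made unique.
bind_annotations <- function(anns, name = "combined") {
  tx <- do.call(rbind, lapply(anns, function(a) a$tx))
  exons <- do.call(c, lapply(anns, function(a) a$exons))
  meta <- if (all(vapply(anns, function(a) !is.null(a$meta), logical(1))))
    do.call(c, lapply(anns, function(a) a$meta)) else NULL
  if (anyDuplicated(tx$transcript_id)) {
    warning("duplicated transcript ids across combined annotations; renaming")
    tx$transcript_id <- make.unique(tx$transcript_id, sep = "_")
  }
  new_annotation(tx, exons, name = name, meta = meta)
}
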