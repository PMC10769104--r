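#' Parameters for intron-retention classification
#'
#' @param coverage_ratio Threshold on the abundance ratio p(r)/p(t) between
#'   the reference transcript r and the candidate t; a candidate can only be
#'   flagged against references at least this abundant relative to it.
#'   Default 0.5. The comparison is inclusive (>=), so the default flags a
#'   reference with exactly half the candidate's abundance.
#' @param length_ratio Threshold in \[0, 1\] on the fraction of a reference
#'   intron covered by the candidate's terminal exon; gates only the partial
#'   criteria (1 and 2). Default 0.
#' @param partial Enable partial intron retention, criteria 1 and 2.
#'   The CLI's `-po` option disables this, keeping entire retention only.
#'   Default `TRUE`.
#' @param entire Enable entire intron retention, criterion 3. The CLI's
#'   `-wo` option disables this, keeping partial retention only. Default
#'   `TRUE`.
#' @param ignore_strand If `TRUE`, candidate/reference pairs may differ in
#'   strand. Default `FALSE`: strands must be equal, and `"."` only pairs
#'   with `"."`.
#' @return An object of class `"ir_params"`.
#' @examples
#' ir_params()
#' ir_params(coverage_ratio = 0.3, length_ratio = 0.5)
#' @export
ir_params <- function(coverage_ratio = 0.5, length_ratio = 0,
                      partial = TRUE, entire = TRUE, ignore_strand = FALSE) {
  if (!is.numeric(coverage_ratio) || coverage_ratio < 0)
    stop("coverage_ratio must be a non-negative number")
  if (!is.numeric(length_ratio) || length_ratio < 0 || length_ratio > 1)
    stop("length_ratio must be in [0, 1]")
  if (!partial && !entire)
    stop("at least one of 'partial' and 'entire' must be enabled")
  structure(list(coverage_ratio = coverage_ratio,
                 length_ratio = length_ratio,
                 partial = isTRUE(partial), entire = isTRUE(entire),
                 ignore_strand = isTRUE(ignore_strand)),
            class = "ir_params")
}

#' @export
print.ir_params <- function(x, ...) {
  cat(sprintf("ir_params: coverage_ratio=%g length_ratio=%g partial=%s entire=%s ignore_strand=%s\n",
              x$coverage_ratio, x$length_ratio, x$partial, x$entire,
              x$ignore_strand))
  invisible(x)
}

#' Abundance gate between a candidate and a reference transcript
#'
#' A reference r can support an intron-retention call on a candidate t only
#' if p(r)/p(t) >= cr. Degenerate abundances follow a documented convention:
#' if p(t) is zero or unknown the ratio is treated as unbounded, so the gate
#' passes whenever p(r) > 0; if p(r) is unknown the gate passes (a missing
#' abundance is not taken as evidence against retention); if both are
#' unknown the gate passes (abundance-blind fallback).
#'
#' @param p_t Abundance of the candidate transcript t (`NA` = unknown).
#' @param p_r Abundance of the reference transcript r (`NA` = unknown).
#' @param cr Coverage-ratio threshold (non-negative).
#' @return Logical scalar.
#' @examples
#' coverage_gate(10, 5, 0.5)    # TRUE: 5/10 meets the threshold
#' coverage_gate(10, 4.9, 0.5)  # FALSE
#' coverage_gate(0, 1, 0.5)     # TRUE: unbounded ratio convention
#' @export
coverage_gate <- function(p_t, p_r, cr = 0.5) {
  if ((!is.na(p_t) && p_t < 0) || (!is.na(p_r) && p_r < 0))
    stop("abundances must be non-negative")
  if (is.na(p_t) && is.na(p_r)) return(TRUE)
  if (is.na(p_r)) return(TRUE)
  if (is.na(p_t) || p_t == 0) return(p_r > 0)
  p_r / p_t >= cr
}

# ---- geometric criteria -------------------------------------------------
# Each helper returns the partial-overlap ratio (criteria 1/2) or TRUE/FALSE
# (criterion 3) for a candidate exon matrix against a reference intron set.
# The inner endpoint of the terminal exon must fall strictly inside the
# intron: full containment of the intron is criterion 3's territory, keeping
# "partial" and "entire" disjoint for a given reference intron.

crit1_ratio <- function(t_ex, r_intr) {
  if (nrow(r_intr) == 0L) return(NA_real_)
  s <- t_ex[1, 1]; e <- t_ex[1, 2]
  hit <- which(s > r_intr[, 1] & s <= r_intr[, 2] & e > r_intr[, 2])
  if (length(hit) == 0L) return(NA_real_)
  b <- r_intr[hit[1], 2]
  (b - s + 1) / (r_intr[hit[1], 2] - r_intr[hit[1], 1] + 1)
}

crit2_ratio <- function(t_ex, r_intr) {
  if (nrow(r_intr) == 0L) return(NA_real_)
  k <- nrow(t_ex)
  s <- t_ex[k, 1]; e <- t_ex[k, 2]
  hit <- which(e >= r_intr[, 1] & e < r_intr[, 2] & s < r_intr[, 1])
  if (length(hit) == 0L) return(NA_real_)
  a <- r_intr[hit[1], 1]
  (e - a + 1) / (r_intr[hit[1], 2] - r_intr[hit[1], 1] + 1)
}

crit3_hit <- function(t_ex, r_intr) {
  if (nrow(r_intr) == 0L) return(FALSE)
  for (i in seq_len(nrow(r_intr)))
    if (any(t_ex[, 1] <= r_intr[i, 1] & t_ex[, 2] >= r_intr[i, 2]))
      return(TRUE)
  FALSE
}

strand_compatible <- function(s1, s2, ignore_strand = FALSE) {
  ignore_strand || s1 == s2
}

#' Structural intron-retention criteria
#'
#' The three criteria compare a candidate transcript t against a multi-exon
#' reference transcript r from the same assembly (abundance is gated
#' separately; see [coverage_gate()]):
#' \describe{
#'   \item{criterion 1 (partial, left)}{the genomically first exon of t
#'     starts strictly inside an intron of r and extends past the intron
#'     into r's following exon; the fraction of the intron covered must be
#'     at least `lr`.}
#'   \item{criterion 2 (partial, right)}{mirror image: the last exon of t
#'     starts before an intron of r and ends strictly inside it.}
#'   \item{criterion 3 (entire)}{some exon of t fully contains an intron
#'     of r (closed-interval containment).}
#' }
#' "First"/"last" are genomic (leftmost/rightmost), which makes criteria 1
#' and 2 mirror images and strand-symmetric.
#'
#' @param t,r `transcript` objects on the same chromosome with compatible
#'   strands.
#' @param lr Length-ratio threshold for the partial criteria.
#' @param ignore_strand Allow differing strands.
#' @return Logical scalar.
#' @examples
#' r <- transcript("r", "g", "chr1", "+", cbind(c(1, 201), c(100, 300)), 10)
#' t <- transcript("t", "g", "chr1", "+", cbind(150, 250), 8)
#' ir_criterion1(t, r)            # TRUE: covers the intron tail
#' ir_criterion1(t, r, lr = 0.6)  # FALSE: covers only 51%
#' @export
ir_criterion1 <- function(t, r, lr = 0, ignore_strand = FALSE) {
  if (!same_locus(t, r, ignore_strand)) return(FALSE)
  ratio <- crit1_ratio(t$exons, exon_introns(r$exons))
  !is.na(ratio) && ratio >= lr
}

#' @rdname ir_criterion1
#' @export
ir_criterion2 <- function(t, r, lr = 0, ignore_strand = FALSE) {
  if (!same_locus(t, r, ignore_strand)) return(FALSE)
  ratio <- crit2_ratio(t$exons, exon_introns(r$exons))
  !is.na(ratio) && ratio >= lr
}

#' @rdname ir_criterion1
#' @export
ir_criterion3 <- function(t, r, ignore_strand = FALSE) {
  if (!same_locus(t, r, ignore_strand)) return(FALSE)
  crit3_hit(t$exons, exon_introns(r$exons))
}

same_locus <- function(t, r, ignore_strand) {
  t$chrom == r$chrom && strand_compatible(t$strand, r$strand, ignore_strand)
}

#' Classify every transcript of an assembly for intron retention
#'
#' A transcript t is flagged if some other transcript r of the same assembly
#' (same chromosome, compatible strand, overlapping genomic span, multi-exon)
#' passes the abundance gate p(r)/p(t) >= coverage_ratio and supports one of
#' the enabled criteria (see [ir_criterion1()]). One transcript may satisfy
#' several criteria, with the same or different references; all firing
#' (criterion, reference) pairs are recorded as evidence. References may
#' themselves be flagged: classification is single-pass, with no iterative
#' removal, and the verdict does not depend on the iteration order over
#' references.
#'
#' Candidate references are found with an interval index over transcript
#' spans; a reference whose span does not overlap t's span cannot satisfy
#' any criterion, so the prefilter is a pure optimisation.
#'
#' @param assembly An `annotation` (an assembler's output with abundances).
#' @param params An [ir_params()] object.
#' @return An object of class `"ir_calls"`: a list with `calls` (data frame
#'   with columns `transcript_id`, `flagged`, `crit1`, `crit2`, `crit3`),
#'   `evidence` (per-transcript data frames with columns `criterion`,
#'   `ref_id`, `abundance_ratio`, `overlap_ratio`) and `params`.
#' @examples
#' calls <- ir_classify(example_ir_assembly())
#' calls
#' @export
ir_classify <- function(assembly, params = ir_params()) {
  stopifnot(inherits(assembly, "annotation"))
  if (!inherits(params, "ir_params")) stop("params must be an ir_params object")
  tx <- assembly$tx
  n <- nrow(tx)
  calls <- data.frame(transcript_id = tx$transcript_id,
                      flagged = logical(n), crit1 = logical(n),
                      crit2 = logical(n), crit3 = logical(n),
                      stringsAsFactors = FALSE)
  evidence <- rep(list(empty_evidence()), n)
  names(evidence) <- tx$transcript_id
  if (n >= 2L) {
    intr <- lapply(assembly$exons, exon_introns)
    gr <- GenomicRanges::GRanges(tx$chrom,
                                 IRanges::IRanges(tx$start, tx$end))
    hits <- GenomicRanges::findOverlaps(gr, gr)
    qi <- S4Vectors_queryHits(hits)
    si <- S4Vectors_subjectHits(hits)
    keep <- qi != si & tx$n_exons[si] > 1L &
      (params$ignore_strand | tx$strand[qi] == tx$strand[si])
    qi <- qi[keep]; si <- si[keep]
    blind_warned <- FALSE
    for (h in seq_along(qi)) {
      i <- qi[h]; j <- si[h]
      if (is.na(tx$abundance[i]) && is.na(tx$abundance[j]) && !blind_warned) {
        message("transcripts without abundance encountered; ",
                "abundance gate passes for such pairs (abundance-blind fallback)")
        blind_warned <- TRUE
      }
      if (!coverage_gate(tx$abundance[i], tx$abundance[j],
                         params$coverage_ratio)) next
      ratio <- if (is.na(tx$abundance[i]) || is.na(tx$abundance[j]) ||
                   tx$abundance[i] == 0) NA_real_
               else tx$abundance[j] / tx$abundance[i]
      if (params$partial) {
        r1 <- crit1_ratio(assembly$exons[[i]], intr[[j]])
        if (!is.na(r1) && r1 >= params$length_ratio) {
          calls$crit1[i] <- TRUE
          evidence[[i]] <- rbind(evidence[[i]], data.frame(
            criterion = 1L, ref_id = tx$transcript_id[j],
            abundance_ratio = ratio, overlap_ratio = r1,
            stringsAsFactors = FALSE))
        }
        r2 <- crit2_ratio(assembly$exons[[i]], intr[[j]])
        if (!is.na(r2) && r2 >= params$length_ratio) {
          calls$crit2[i] <- TRUE
          evidence[[i]] <- rbind(evidence[[i]], data.frame(
            criterion = 2L, ref_id = tx$transcript_id[j],
            abundance_ratio = ratio, overlap_ratio = r2,
            stringsAsFactors = FALSE))
        }
      }
      if (params$entire && crit3_hit(assembly$exons[[i]], intr[[j]])) {
        calls$crit3[i] <- TRUE
        evidence[[i]] <- rbind(evidence[[i]], data.frame(
          criterion = 3L, ref_id = tx$transcript_id[j],
          abundance_ratio = ratio, overlap_ratio = NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  calls$flagged <- calls$crit1 | calls$crit2 | calls$crit3
  evidence <- lapply(evidence, function(e)
    e[order(e$criterion, e$ref_id), , drop = FALSE])
  structure(list(calls = calls, evidence = evidence, params = params),
            class = "ir_calls")
}

empty_evidence <- function() {
  data.frame(criterion = integer(0), ref_id = character(0),
             abundance_ratio = numeric(0), overlap_ratio = numeric(0),
             stringsAsFactors = FALSE)
}

# thin indirection so the only S4Vectors touch points are in one place
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' @export
print.ir_calls <- function(x, ...) {
  n <- nrow(x$calls)
  cat(sprintf("ir_calls: %d/%d transcript(s) flagged (criterion 1: %d, 2: %d, 3: %d)\n",
              sum(x$calls$flagged), n, sum(x$calls$crit1), sum(x$calls$crit2),
              sum(x$calls$crit3)))
  print(x$params)
  invisible(x)
}

#' @export
summary.ir_calls <- function(object, ...) {
  flagged <- object$calls[object$calls$flagged, , drop = FALSE]
  cat(sprintf("%d flagged transcript(s):\n", nrow(flagged)))
  for (i in seq_len(nrow(flagged))) {
    crits <- c(1, 2, 3)[c(flagged$crit1[i], flagged$crit2[i], flagged$crit3[i])]
    cat(sprintf("  %s: criterion %s\n", flagged$transcript_id[i],
                paste(crits, collapse = ",")))
  }
  invisible(object)
}

#' Partition an assembly into intron-retention and kept subsets
#'
#' Splits an assembly into the transcripts flagged by [ir_classify()] and
#' the remainder. The two parts are disjoint and their union is the input.
#'
#' @inheritParams ir_classify
#' @return An object of class `"ir_partition"`: list with `ir` and `kept`
#'   annotations and the underlying `calls`.
#' @examples
#' p <- ir_partition(example_ir_assembly())
#' transcripts(p$ir)$transcript_id    # t2, t3, t4
#' transcripts(p$kept)$transcript_id  # t1
#' @export
ir_partition <- function(assembly, params = ir_params()) {
  calls <- ir_classify(assembly, params)
  flagged <- calls$calls$flagged
  out <- list(ir = assembly[which(flagged)], kept = assembly[which(!flagged)],
              calls = calls)
  out$ir$name <- paste0(assembly$name, ".ir")
  out$kept$name <- paste0(assembly$name, ".kept")
  class(out) <- "ir_partition"
  out
}

#' @export
print.ir_partition <- function(x, ...) {
  cat(sprintf("ir_partition: %d flagged, %d kept\n",
              length(x$ir), length(x$kept)))
  print(x$calls$params)
  invisible(x)
}
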