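#' Match an assembly against a reference annotation
#'
#' Implements transcript-level matching as used for assembly benchmarking:
#' an assembled multi-exon transcript matches when its intron chain
#' (chromosome, strand and the ordered junction coordinates) is exactly
#' identical to that of a reference transcript; an assembled single-exon
#' transcript matches when it overlaps a single-exon reference transcript
#' significantly (by default at least 80% of both transcripts' lengths —
#' reciprocal overlap; set `reciprocal = FALSE` to require only 80% of the
#' assembled transcript's length). Precision is the number of matching
#' assembled transcripts divided by the number of assembled transcripts;
#' the raw matching count is proportional to recall.
#'
#' @param assembly,reference `annotation` objects.
#' @param single_exon_overlap Minimum overlap fraction for single-exon
#'   matching, default 0.8.
#' @param reciprocal If `TRUE` (default) the overlap must cover both the
#'   assembled and the reference transcript; if `FALSE` only the assembled
#'   one.
#' @param dedupe If `TRUE`, `n_matching` counts distinct matched reference
#'   transcripts instead of matched assembled transcripts (two assembled
#'   copies of one reference chain then count once). Precision always uses
#'   the matched assembled count as its numerator.
#' @param ignore_strand Ignore strand in both matching rules.
#' @return An object of class `"match_report"`: list with `transcripts`
#'   (data frame: `transcript_id`, `matched`, `matched_reference_id`,
#'   `match_type`), `n_assembled`, `n_matching`, `precision`.
#' @examples
#' ref <- example_ir_assembly()
#' match_transcripts(ref, ref)$precision  # 1 by identity
#' @export
match_transcripts <- function(assembly, reference, single_exon_overlap = 0.8,
                              reciprocal = TRUE, dedupe = FALSE,
                              ignore_strand = FALSE) {
  stopifnot(inherits(assembly, "annotation"), inherits(reference, "annotation"))
  n <- nrow(assembly$tx)
  res <- data.frame(transcript_id = assembly$tx$transcript_id,
                    matched = logical(n),
                    matched_reference_id = NA_character_,
                    match_type = NA_character_,
                    stringsAsFactors = FALSE)

  # multi-exon: exact intron-chain lookup
  ref_keys <- transcript_chain_keys(reference, ignore_strand)
  ref_multi <- which(!is.na(ref_keys))
  chain_index <- ref_index_first(ref_keys[ref_multi],
                                 reference$tx$transcript_id[ref_multi])
  asm_keys <- transcript_chain_keys(assembly, ignore_strand)
  multi <- which(!is.na(asm_keys))
  hit <- chain_index[asm_keys[multi]]
  res$matched[multi] <- !is.na(hit)
  res$matched_reference_id[multi] <- unname(hit)
  res$match_type[multi[!is.na(hit)]] <- "chain"

  # single-exon: significant overlap with a single-exon reference transcript
  asm_se <- which(assembly$tx$n_exons == 1L)
  ref_se <- which(reference$tx$n_exons == 1L)
  if (length(asm_se) && length(ref_se)) {
    gr_a <- GenomicRanges::GRanges(assembly$tx$chrom[asm_se],
      IRanges::IRanges(assembly$tx$start[asm_se], assembly$tx$end[asm_se]))
    gr_r <- GenomicRanges::GRanges(reference$tx$chrom[ref_se],
      IRanges::IRanges(reference$tx$start[ref_se], reference$tx$end[ref_se]))
    ov <- GenomicRanges::findOverlaps(gr_a, gr_r)
    qi <- S4Vectors_queryHits(ov); si <- S4Vectors_subjectHits(ov)
    best_frac <- rep(-Inf, length(asm_se))
    for (h in seq_along(qi)) {
      i <- asm_se[qi[h]]; r <- ref_se[si[h]]
      if (!strand_compatible(assembly$tx$strand[i], reference$tx$strand[r],
                             ignore_strand)) next
      ovlen <- min(assembly$tx$end[i], reference$tx$end[r]) -
        max(assembly$tx$start[i], reference$tx$start[r]) + 1
      la <- assembly$tx$end[i] - assembly$tx$start[i] + 1
      lr <- reference$tx$end[r] - reference$tx$start[r] + 1
      frac <- if (reciprocal) min(ovlen / la, ovlen / lr) else ovlen / la
      ok <- frac >= single_exon_overlap
      k <- qi[h]
      rid <- reference$tx$transcript_id[r]
      if (ok && (frac > best_frac[k] ||
                 (frac == best_frac[k] &&
                  rid < res$matched_reference_id[i]))) {
        best_frac[k] <- frac
        res$matched[i] <- TRUE
        res$matched_reference_id[i] <- rid
        res$match_type[i] <- "single_exon"
      }
    }
  }

  n_matching <- if (dedupe)
    length(unique(res$matched_reference_id[res$matched]))
  else sum(res$matched)
  structure(list(transcripts = res, n_assembled = n,
                 n_matching = n_matching,
                 precision = if (n == 0L) NA_real_ else sum(res$matched) / n,
                 assembly_name = assembly$name,
                 reference_name = reference$name),
            class = "match_report")
}

# chain key -> reference id, ties resolved to the lexicographically first id
ref_index_first <- function(keys, ids) {
  ord <- order(keys, ids)
  keys <- keys[ord]; ids <- ids[ord]
  first <- !duplicated(keys)
  structure(ids[first], names = keys[first])
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: '%s' vs reference '%s'\n", x$assembly_name,
              x$reference_name))
  cat(sprintf("  assembled: %d  matching: %d  precision: %.4f\n",
              x$n_assembled, x$n_matching, x$precision))
  invisible(x)
}

#' Adjusted precision of two assemblies against one reference
#'
#' When two assemblies disagree in opposite directions on precision and
#' matching count, their precisions are compared after adjusting the
#' matching counts to be equal: the assembly with the larger matching count
#' has its lowest-abundance transcripts removed one at a time (ties broken
#' lexicographically by transcript id, so the trace is deterministic) until
#' its matching count equals the other's; its precision at that point is
#' the adjusted precision. If the counts are already equal the raw
#' precisions are returned unchanged.
#'
#' @param assembly_a,assembly_b `annotation` objects evaluated against the
#'   same `reference`. The higher-recall one must carry abundances.
#' @param reference Reference `annotation`.
#' @param ... Passed to [match_transcripts()].
#' @return An object of class `"adjusted_precision"`: list with
#'   `precision_a`, `precision_b` (raw), `adjusted_side` (`"a"`, `"b"` or
#'   `"none"`), `adjusted_precision` (precision of the adjusted side after
#'   removal; equals its raw precision when no adjustment is needed),
#'   `n_matching_target`, and `trace` (data frame of removals:
#'   `transcript_id`, `abundance`, `was_matched`, `n_matching_after`).
#' @export
adjusted_precision <- function(assembly_a, assembly_b, reference, ...) {
  rep_a <- match_transcripts(assembly_a, reference, ...)
  rep_b <- match_transcripts(assembly_b, reference, ...)
  out <- list(precision_a = rep_a$precision, precision_b = rep_b$precision,
              n_matching_a = rep_a$n_matching, n_matching_b = rep_b$n_matching,
              adjusted_side = "none",
              adjusted_precision = NA_real_,
              n_matching_target = min(rep_a$n_matching, rep_b$n_matching),
              trace = data.frame(transcript_id = character(0),
                                 abundance = numeric(0),
                                 was_matched = logical(0),
                                 n_matching_after = integer(0),
                                 stringsAsFactors = FALSE))
  if (rep_a$n_matching == rep_b$n_matching) {
    class(out) <- "adjusted_precision"
    return(out)
  }
  if (rep_a$n_matching > rep_b$n_matching) {
    out$adjusted_side <- "a"; high <- assembly_a; high_rep <- rep_a
    target <- rep_b$n_matching
  } else {
    out$adjusted_side <- "b"; high <- assembly_b; high_rep <- rep_b
    target <- rep_a$n_matching
  }
  tx <- high$tx
  matched <- high_rep$transcripts$matched
  ord <- order(tx$abundance, tx$transcript_id)  # lowest abundance first
  removed <- logical(nrow(tx))
  n_match <- sum(matched)
  trace <- list()
  for (i in ord) {
    if (n_match <= target) break
    removed[i] <- TRUE
    if (matched[i]) n_match <- n_match - 1L
    trace[[length(trace) + 1L]] <- data.frame(
      transcript_id = tx$transcript_id[i], abundance = tx$abundance[i],
      was_matched = matched[i], n_matching_after = n_match,
      stringsAsFactors = FALSE)
  }
  out$trace <- if (length(trace)) do.call(rbind, trace) else out$trace
  remaining <- sum(!removed)
  out$adjusted_precision <- if (remaining == 0L) NA_real_ else
    sum(matched & !removed) / remaining
  class(out) <- "adjusted_precision"
  out
}

#' @export
print.adjusted_precision <- function(x, ...) {
  cat(sprintf("raw precisions: a=%.4f (n_matching %d), b=%.4f (n_matching %d)\n",
              x$precision_a, x$n_matching_a, x$precision_b, x$n_matching_b))
  if (x$adjusted_side == "none") {
    cat("matching counts equal; no adjustment needed\n")
  } else {
    cat(sprintf("adjusted side '%s': removed %d transcript(s), adjusted precision %.4f at n_matching %d\n",
                x$adjusted_side, nrow(x$trace), x$adjusted_precision,
                x$n_matching_target))
  }
  invisible(x)
}

#' Count matched transcripts per reference biotype
#'
#' Each matched assembled transcript contributes one count to the biotype of
#' the reference transcript it matched; unmatched transcripts contribute to
#' no bucket, so bucket totals sum to the matched assembled count.
#'
#' @param report A `"match_report"` from [match_transcripts()].
#' @param reference The reference `annotation` the report was computed
#'   against (its transcripts should carry biotypes; empty biotypes are
#'   reported under `""`).
#' @return Named integer vector of counts, sorted decreasingly.
#' @export
stratify_by_biotype <- function(report, reference) {
  stopifnot(inherits(report, "match_report"), inherits(reference, "annotation"))
  hit <- report$transcripts$matched_reference_id[report$transcripts$matched]
  bt <- reference$tx$biotype[match(hit, reference$tx$transcript_id)]
  if (length(bt) == 0L) return(integer(0))
  sort(table(bt), decreasing = TRUE) |> c()
}

#' Intersection and union of two annotations
#'
#' Composite references built from a reference and a query annotation using
#' the same matching predicate as [match_transcripts()] (exact intron-chain
#' equality for multi-exon transcripts, "=" class-code semantics; reciprocal
#' 80% overlap for single-exon transcripts). The intersection keeps the
#' query transcripts that match the reference. The union keeps all
#' reference transcripts plus the query transcripts that do not match.
#'
#' @param reference,query `annotation` objects.
#' @param ... Passed to [match_transcripts()].
#' @return An `annotation`.
#' @export
annotation_intersection <- function(reference, query, ...) {
  rep <- match_transcripts(query, reference, ...)
  out <- query[which(rep$transcripts$matched)]
  out$name <- paste0(reference$name, ".intersect.", query$name)
  out
}

#' @rdname annotation_intersection
#' @export
annotation_union <- function(reference, query, ...) {
  rep <- match_transcripts(query, reference, ...)
  novel <- query[which(!rep$transcripts$matched)]
  bind_annotations(list(reference, novel),
                   name = paste0(reference$name, ".union.", query$name))
}

#' Precision/matching sweep over an intron-retention threshold
#'
#' For each grid value, sets the varied parameter (`lr` = length ratio, `cr`
#' = coverage ratio) in `params`, filters the assembly with
#' [ir_partition()], evaluates the kept part against the reference with
#' [match_transcripts()], and records precision and matching count. This
#' traces the precision-sensitivity trade-off of the filter.
#'
#' @param assembly,reference `annotation` objects.
#' @param params Base [ir_params()].
#' @param vary `"lr"` or `"cr"`.
#' @param grid Sorted numeric vector of threshold values.
#' @param ... Passed to [match_transcripts()].
#' @return Data frame of class `"sweep_result"` with columns `threshold`,
#'   `precision`, `n_matching`, `n_kept`, `n_flagged`.
#' @export
threshold_sweep <- function(assembly, reference, params = ir_params(),
                            vary = c("lr", "cr"), grid, ...) {
  vary <- match.arg(vary)
  if (is.unsorted(grid)) stop("grid must be sorted increasingly")
  rows <- lapply(grid, function(v) {
    p <- params
    if (vary == "lr") p$length_ratio <- v else p$coverage_ratio <- v
    part <- ir_partition(assembly, p)
    rep <- match_transcripts(part$kept, reference, ...)
    data.frame(threshold = v, precision = rep$precision,
               n_matching = rep$n_matching, n_kept = length(part$kept),
               n_flagged = length(part$ir))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
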