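#' Read a GTF file into an annotation
#'
#' Parses transcript and exon records from a GTF file (plain or gzipped)
#' into an [as_annotation()] model. The parser tolerates the attribute
#' dialects of Ensembl, GENCODE, RefSeq, CHM13, StringTie and Scallop
#' outputs: attribute values may be quoted or bare, keys may repeat, and
#' per-transcript abundance and biotype are looked up through configurable
#' key lists (the first key present wins). Records other than `transcript`
#' and `exon` are ignored but counted in the parse summary attached to the
#' result (see [print.annotation()]).
#'
#' Exons listed out of order are sorted. Exactly adjacent exons (gap 0) are
#' merged with a warning, since a zero-length intron is meaningless.
#' Transcripts whose exons overlap are either repaired (overlapping exons
#' merged) or dropped, per `malformed`; either way they are reported.
#'
#' @param path Path to a GTF file (optionally gzip-compressed).
#' @param name Label for the annotation; defaults to the file name.
#' @param abundance_keys Attribute names tried in order for the per-transcript
#'   abundance. The default covers StringTie (`cov`, `FPKM`, `TPM`) and
#'   Scallop (`cov`, `RPKM`) outputs. Absent everywhere: abundance `NA`.
#' @param biotype_keys Attribute names tried in order for the transcript
#'   biotype (Ensembl vs GENCODE dialects). Absent: `""`.
#' @param malformed `"repair"` (merge overlapping exons) or `"drop"`.
#' @param quiet Suppress per-transcript repair messages.
#' @return An `annotation`. Transcripts have genomically sorted exons;
#'   the original record text of unmodified transcripts is retained so that
#'   [write_gtf()] can reproduce it byte-identically.
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path, name = basename(path),
                     abundance_keys = c("cov", "FPKM", "TPM", "RPKM"),
                     biotype_keys = c("transcript_biotype", "transcript_type"),
                     malformed = c("repair", "drop"),
                     quiet = FALSE) {
  malformed <- match.arg(malformed)
  if (!file.exists(path)) stop("cannot read GTF file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop("malformed GTF record (fewer than 8 fields) at line ", lineno[which(nf < 8L)[1]])
  feature <- vapply(fields, `[[`, character(1), 3L)

  is_exon <- feature == "exon"
  is_tx <- feature == "transcript"
  n_other <- sum(!is_exon & !is_tx)

  parse_rec <- function(i) {
    f <- fields[[i]]
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start)
      stop("invalid coordinates at line ", lineno[i])
    strand <- f[7]
    if (strand == "*") strand <- "."
    if (!strand %in% c("+", "-", "."))
      stop("invalid strand '", strand, "' at line ", lineno[i])
    list(chrom = f[1], start = start, end = end, strand = strand,
         attrs = parse_gtf_attrs(if (length(f) >= 9L) f[9] else ""),
         raw = lines[lineno[i]], line = lineno[i])
  }

  tx_recs <- lapply(which(is_tx), parse_rec)
  exon_recs <- lapply(which(is_exon), parse_rec)

  exon_tx_id <- vapply(exon_recs, function(r) {
    id <- r$attrs["transcript_id"]
    if (is.na(id)) stop("exon without transcript_id at line ", r$line)
    unname(id)
  }, character(1))
  tx_ids <- vapply(tx_recs, function(r) {
    id <- r$attrs["transcript_id"]
    if (is.na(id)) NA_character_ else unname(id)
  }, character(1))
  tx_by_id <- tx_recs[!is.na(tx_ids)]
  names(tx_by_id) <- tx_ids[!is.na(tx_ids)]
  if (anyDuplicated(names(tx_by_id))) {
    warning("duplicated transcript records; keeping the first of each")
    tx_by_id <- tx_by_id[!duplicated(names(tx_by_id))]
  }

  ids <- unique(exon_tx_id)
  groups <- split(seq_along(exon_recs), factor(exon_tx_id, levels = ids))

  out_tx <- vector("list", length(ids))
  out_exons <- vector("list", length(ids))
  out_meta <- vector("list", length(ids))
  dropped <- character(0)
  n_merged <- 0L

  first_attr <- function(attr_list, keys) {
    for (a in attr_list) for (k in keys) if (!is.na(a[k])) return(unname(a[k]))
    NA_character_
  }

  for (j in seq_along(ids)) {
    id <- ids[j]
    recs <- exon_recs[groups[[j]]]
    chrom <- unique(vapply(recs, `[[`, character(1), "chrom"))
    strand <- unique(vapply(recs, `[[`, character(1), "strand"))
    if (length(chrom) > 1L || length(strand) > 1L)
      stop("transcript ", id, " spans multiple chromosomes/strands (line ",
           recs[[length(recs)]]$line, ")")
    ex <- cbind(vapply(recs, `[[`, numeric(1), "start"),
                vapply(recs, `[[`, numeric(1), "end"))
    ord <- order(ex[, 1], ex[, 2])
    ex <- ex[ord, , drop = FALSE]
    recs <- recs[ord]
    modified <- FALSE
    if (nrow(ex) > 1L) {
      gap <- ex[-1L, 1] - ex[-nrow(ex), 2] - 1
      if (any(gap < 0)) {
        if (malformed == "drop") {
          if (!quiet) message("dropping transcript ", id, ": overlapping exons")
          dropped <- c(dropped, id)
          next
        }
        if (!quiet) message("repairing transcript ", id, ": overlapping exons merged")
        ex <- merge_overlaps(ex)
        modified <- TRUE
      } else if (any(gap == 0)) {
        warning("merging zero-gap adjacent exons in transcript ", id)
        ex <- merge_zero_gaps(ex)
        n_merged <- n_merged + 1L
        modified <- TRUE
      }
    }
    trec <- tx_by_id[[id]]
    attr_sources <- c(if (!is.null(trec)) list(trec$attrs),
                      lapply(recs, `[[`, "attrs"))
    ab_chr <- first_attr(attr_sources, abundance_keys)
    ab <- if (is.na(ab_chr)) NA_real_ else suppressWarnings(as.numeric(ab_chr))
    if (!is.na(ab) && ab < 0) stop("negative abundance for transcript ", id)
    bt <- first_attr(attr_sources, biotype_keys)
    if (is.na(bt)) bt <- ""
    gid <- first_attr(attr_sources, "gene_id")
    if (is.na(gid)) stop("exon without gene_id for transcript ", id,
                         " at line ", recs[[1]]$line)
    out_tx[[j]] <- data.frame(
      transcript_id = id, gene_id = gid, chrom = chrom, strand = strand,
      abundance = ab, biotype = bt,
      start = min(ex[, 1]), end = max(ex[, 2]), n_exons = nrow(ex),
      stringsAsFactors = FALSE)
    out_exons[[j]] <- ex
    colnames(out_exons[[j]]) <- c("start", "end")
    out_meta[[j]] <- if (modified) NULL else
      list(tx = if (is.null(trec)) NULL else trec$raw,
           exons = vapply(recs, `[[`, character(1), "raw"))
  }

  keep_j <- !vapply(out_tx, is.null, logical(1))
  ann <- new_annotation(do.call(rbind, out_tx[keep_j]), out_exons[keep_j],
                        name = name, meta = out_meta[keep_j])
  if (is.null(ann$tx)) ann <- empty_annotation(name)
  attr(ann, "parse_summary") <- list(
    n_exon_records = sum(is_exon), n_transcript_records = sum(is_tx),
    n_other_records = n_other, n_merged = n_merged, dropped = dropped)
  ann
}

empty_annotation <- function(name = "annotation") {
  new_annotation(data.frame(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0), abundance = numeric(0),
    biotype = character(0), start = numeric(0), end = numeric(0),
    n_exons = integer(0), stringsAsFactors = FALSE),
    list(), name = name, meta = list())
}

merge_overlaps <- function(ex) {
  out <- ex[1L, , drop = FALSE]
  for (i in seq_len(nrow(ex))[-1L]) {
    if (ex[i, 1] <= out[nrow(out), 2] + 1)
      out[nrow(out), 2] <- max(out[nrow(out), 2], ex[i, 2])
    else
      out <- rbind(out, ex[i, , drop = FALSE])
  }
  out
}

# Parse a GTF attribute block into a named character vector. Handles quoted
# values (possibly containing ';' or spaces) and bare values; repeated keys
# (e.g. GENCODE 'tag') are kept, with lookups returning the first.
parse_gtf_attrs <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(character(0))
  m <- regmatches(s, gregexpr('[^ ;\t]+ +"[^"]*"|[^ ;\t]+ +[^ ;"\t]+',
                              s, perl = TRUE))[[1]]
  if (length(m) == 0L) return(character(0))
  keys <- sub("^([^ ]+) +.*$", "\\1", m)
  vals <- sub("^[^ ]+ +", "", m)
  quoted <- startsWith(vals, "\"")
  vals[quoted] <- substr(vals[quoted], 2L, nchar(vals[quoted]) - 1L)
  names(vals) <- keys
  vals
}

#' Write an annotation to a GTF file
#'
#' Emits one `transcript` record followed by its `exon` records for each
#' transcript. For transcripts read by [read_gtf()] and not modified since,
#' the original record text is written back byte-identically; otherwise
#' canonical records are generated. Output re-read with [read_gtf()] yields
#' an equal model.
#'
#' @param ann An `annotation`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation"))
  lines <- character(0)
  n <- nrow(ann$tx)
  for (i in seq_len(n)) {
    m <- if (!is.null(ann$meta)) ann$meta[[i]] else NULL
    if (!is.null(m) && !is.null(m$exons)) {
      if (!is.null(m$tx)) lines <- c(lines, m$tx)
      lines <- c(lines, m$exons)
    } else {
      lines <- c(lines, format_gtf_records(ann$tx[i, ], ann$exons[[i]]))
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  tryCatch(writeLines(lines, con), finally = close(con))
  invisible(path)
}

format_gtf_records <- function(r, ex) {
  extra <- character(0)
  if (!is.na(r$abundance)) extra <- c(extra, sprintf('cov "%g";', r$abundance))
  if (nzchar(r$biotype))
    extra <- c(extra, sprintf('transcript_biotype "%s";', r$biotype))
  base <- sprintf('gene_id "%s"; transcript_id "%s";', r$gene_id,
                  r$transcript_id)
  attr_tx <- paste(c(base, extra), collapse = " ")
  tx_line <- paste(r$chrom, "irtoolkit", "transcript",
                   format_coord(r$start), format_coord(r$end),
                   ".", r$strand, ".", attr_tx, sep = "\t")
  exon_lines <- vapply(seq_len(nrow(ex)), function(k) {
    paste(r$chrom, "irtoolkit", "exon",
          format_coord(ex[k, 1]), format_coord(ex[k, 2]),
          ".", r$strand, ".",
          paste0(base, sprintf(' exon_number "%d";', k)), sep = "\t")
  }, character(1))
  c(tx_line, exon_lines)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
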