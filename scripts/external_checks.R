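#!/usr/bin/env Rscript
# Optional full-genome comparisons against pinned external inputs. These
# reproduce the published cross-annotation statistics but require large
# downloads, so they are not part of the default test run.
#
# Usage:
#   Rscript scripts/external_checks.R --a <annotationA.gtf[.gz]> \
#       --b <annotationB.gtf[.gz]> [--catalog pairs.tsv] [--out out.json]
#
# Typical pinned inputs:
#   * Ensembl release 107 (GRCh38.p13) vs RefSeq release 110 (GRCh38.p14):
#     expected Jaccard ~0.69/0.57 (boundary/junction) and ~0.19 (chain).
#   * T2T-CHM13 Ensembl vs CHM13: expected ~0.91 (boundary and junction)
#     and ~0.80 (chain).
#   * --catalog: two-column TSV of gene-id pairs (e.g. derived from HGNC);
#     the recovered fraction is reported (~94.1% for RefSeq/Ensembl).

suppressPackageStartupMessages({
  library(irtoolkit)
  library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
path_a <- get_arg("--a")
path_b <- get_arg("--b")
catalog_path <- get_arg("--catalog")
out_path <- get_arg("--out", "results/external_checks.json")
if (is.null(path_a) || is.null(path_b))
  stop("usage: external_checks.R --a A.gtf --b B.gtf [--catalog pairs.tsv] [--out out.json]")

message("reading ", path_a)
T1 <- read_gtf(path_a)
message("reading ", path_b)
T2 <- read_gtf(path_b)

res <- list(
  boundary_jaccard = annotation_jaccard(T1, T2, "boundary"),
  junction_jaccard = annotation_jaccard(T1, T2, "junction"),
  chain_jaccard = annotation_jaccard(T1, T2, "chain"),
  n_transcripts_a = length(T1),
  n_transcripts_b = length(T2))

if (!is.null(catalog_path)) {
  message("pairing genes")
  pg <- pair_genes(T1, T2)
  catalog <- read.delim(catalog_path, header = TRUE,
                        stringsAsFactors = FALSE)
  res$n_gene_pairs <- nrow(pg)
  res$n_catalog_pairs <- nrow(catalog)
  res$catalog_recovery_percent <-
    100 * validate_pairs_against_catalog(pg, catalog)
}

dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
write_json(res, out_path, auto_unbox = TRUE, digits = NA)
cat(toJSON(res, auto_unbox = TRUE, digits = NA), "\n")
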