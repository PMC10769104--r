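#' Worked example: two small annotations with known Jaccard similarities
#'
#' Builds a pair of toy annotations, T1 and T2, whose structural similarity
#' is known exactly: each annotation holds one gene with two transcripts.
#' Both share a six-exon transcript (five junctions, ten boundaries). T1
#' additionally has a two-exon transcript whose single junction skips from
#' the first junction's donor to the second junction's acceptor (both
#' positions already shared), adding no new boundary; T2 additionally has a
#' three-exon transcript whose two junctions reuse one shared boundary each
#' and introduce one private boundary each. The resulting Jaccard indices
#' are 5/6 at the boundary level (10 shared of 12), 5/8 at the junction
#' level (5 shared of 8) and 1/3 at the intron-chain level (1 shared of 3).
#'
#' @return List with `annotation` elements `T1` and `T2`.
#' @examples
#' pair <- example_annotation_pair()
#' annotation_jaccard(pair$T1, pair$T2, "junction")
#' @export
example_annotation_pair <- function() {
  shared_exons <- cbind(c(101, 301, 501, 701, 901, 1101),
                        c(200, 400, 600, 800, 1000, 1200))
  # junctions of the shared chain: [201,300] [401,500] [601,700] [801,900]
  # [1001,1100]; boundaries: 201 300 401 500 601 700 801 900 1001 1100
  t1a <- transcript("T1.1", "G1", "chr1", "+", shared_exons)
  # skip: one junction [201,500], endpoints both shared boundaries
  t1b <- transcript("T1.2", "G1", "chr1", "+", cbind(c(141, 501), c(200, 560)))
  t2a <- transcript("T2.1", "G1", "chr1", "+", shared_exons)
  # two junctions [201,320] and [421,500]; 320 and 421 are private to T2
  t2b <- transcript("T2.2", "G1", "chr1", "+",
                    cbind(c(141, 321, 501), c(200, 420, 560)))
  list(T1 = as_annotation(list(t1a, t1b), name = "T1"),
       T2 = as_annotation(list(t2a, t2b), name = "T2"))
}

#' Worked example: a four-transcript assembly with one intron-retention
#' event per criterion
#'
#' Builds a small assembly in which transcript `t1` (five exons, four
#' introns, abundance 10) is the high-abundance reference and the other
#' three each exhibit exactly one retention criterion against it, with
#' abundance ratios above the default coverage-ratio 0.5: `t2` (abundance 6)
#' starts inside `t1`'s second intron and spans into the following exon
#' (criterion 1, overlap ratio 0.5); `t3` (abundance 7) ends inside `t1`'s
#' fourth intron (criterion 2, overlap ratio 0.5); `t4` (abundance 8) has an
#' exon fully covering `t1`'s second intron (criterion 3). At default
#' parameters the partition flags t2, t3, t4 and keeps t1.
#'
#' @return An `annotation` of four transcripts with abundances.
#' @examples
#' p <- ir_partition(example_ir_assembly())
#' transcripts(p$ir)$transcript_id
#' @export
example_ir_assembly <- function() {
  t1 <- transcript("t1", "G1", "chr1", "+",
                   cbind(c(101, 301, 501, 701, 901),
                         c(200, 400, 600, 800, 1000)), abundance = 10)
  t2 <- transcript("t2", "G1", "chr1", "+",
                   cbind(c(451, 701, 901), c(600, 800, 1000)), abundance = 6)
  t3 <- transcript("t3", "G1", "chr1", "+",
                   cbind(c(101, 301, 501, 701), c(200, 400, 600, 850)),
                   abundance = 7)
  t4 <- transcript("t4", "G1", "chr1", "+",
                   cbind(c(101, 301, 701, 901), c(200, 600, 800, 1000)),
                   abundance = 8)
  as_annotation(list(t1, t2, t3, t4), name = "ir_example")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Random exon matrix starting at `at`.
rand_exons <- function(n_exons, at, exon_len = c(50, 300),
                       intron_len = c(60, 500)) {
  el <- sample(exon_len[1]:exon_len[2], n_exons, replace = TRUE)
  il <- if (n_exons > 1L)
    sample(intron_len[1]:intron_len[2], n_exons - 1L, replace = TRUE)
  else integer(0)
  starts <- at + cumsum(c(0, el[-n_exons] + il))
  cbind(starts, starts + el - 1)
}

#' Simulate a pair of annotations with known structural similarity
#'
#' Constructively builds two annotations whose Jaccard similarity at every
#' level is known exactly from the construction, for use as an oracle in
#' testing. Three kinds of genes are generated, each in its own disjoint
#' coordinate window so no structure is shared by accident:
#' \describe{
#'   \item{shared}{an identical multi-exon transcript in both annotations
#'     (shared at all three levels);}
#'   \item{chain-private}{a transcript present in only one annotation, with
#'     entirely novel junctions (shared at no level);}
#'   \item{subchain-private}{on a shared gene with k junctions, each side
#'     additionally receives a distinct sub-chain of the shared chain (side
#'     one: junctions 1..k-1; side two: junctions 2..k), which adds private
#'     chains but no new junction or boundary.}
#' }
#' The expected Jaccard values are accumulated during construction by
#' counting the boundary/junction/chain elements each unit contributes, and
#' are returned alongside the annotations.
#'
#' @param n_shared Number of shared genes.
#' @param n_private Number of chain-private genes per annotation.
#' @param n_subchain Number of shared genes that also receive side-specific
#'   sub-chains (requires `n_subchain <= n_shared`; sub-chains need at
#'   least 2 junctions, so these genes get at least 3 exons).
#' @param exons_per_tx Range (min, max) of exon counts per transcript.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `T1`, `T2` (annotations) and `truth` (named numeric:
#'   expected `boundary`, `junction`, `chain` Jaccard).
#' @examples
#' sim <- simulate_annotation_pair(n_shared = 2, n_private = 2, seed = 7)
#' sim$truth["chain"]
#' annotation_jaccard(sim$T1, sim$T2, "chain")
#' @export
simulate_annotation_pair <- function(n_shared = 5, n_private = 3,
                                     n_subchain = 0,
                                     exons_per_tx = c(2, 6), seed = 1) {
  if (n_subchain > n_shared)
    stop("n_subchain cannot exceed n_shared (sub-chains live on shared genes)")
  if (n_shared + n_private < 1) stop("nothing to simulate")
  with_seed(seed, {
    t1 <- list(); t2 <- list()
    nB_shared <- 0L; nJ_shared <- 0L
    nB_priv <- 0L; nJ_priv <- 0L   # totals over both private sides
    nC_shared <- n_shared
    nC_priv <- 2L * n_private + 2L * n_subchain
    cursor <- 1000
    win <- function(ex) max(ex[, 2]) + 10000
    for (g in seq_len(n_shared)) {
      k <- sample(seq(max(exons_per_tx[1], if (g <= n_subchain) 3 else 2),
                      max(exons_per_tx[2], 3)), 1)
      ex <- rand_exons(k, cursor)
      cursor <- win(ex)
      gid <- sprintf("SG%03d", g)
      t1[[length(t1) + 1L]] <- transcript(sprintf("%s.A", gid), gid, "chr1",
                                          "+", ex)
      t2[[length(t2) + 1L]] <- transcript(sprintf("%s.B", gid), gid, "chr1",
                                          "+", ex)
      nJ_shared <- nJ_shared + (k - 1L)
      nB_shared <- nB_shared + 2L * (k - 1L)
      if (g <= n_subchain) {
        # side-specific sub-chains: drop the last / the first junction
        exA <- ex[-nrow(ex), , drop = FALSE]        # junctions 1..k-2? no:
        exA[nrow(exA), 2] <- ex[nrow(ex), 2]        # keep last exon end
        exB <- ex[-1L, , drop = FALSE]
        exB[1L, 1] <- ex[1L, 1]
        t1[[length(t1) + 1L]] <- transcript(sprintf("%s.subA", gid), gid,
                                            "chr1", "+", exA)
        t2[[length(t2) + 1L]] <- transcript(sprintf("%s.subB", gid), gid,
                                            "chr1", "+", exB)
      }
    }
    for (g in seq_len(n_private)) {
      for (side in c("A", "B")) {
        k <- sample(seq(max(exons_per_tx[1], 2), max(exons_per_tx[2], 2)), 1)
        ex <- rand_exons(k, cursor)
        cursor <- win(ex)
        gid <- sprintf("P%s%03d", side, g)
        tr <- transcript(sprintf("%s.1", gid), gid, "chr1", "+", ex)
        if (side == "A") t1[[length(t1) + 1L]] <- tr
        else t2[[length(t2) + 1L]] <- tr
        nJ_priv <- nJ_priv + (k - 1L)
        nB_priv <- nB_priv + 2L * (k - 1L)
      }
    }
    truth <- c(
      boundary = nB_shared / (nB_shared + nB_priv),
      junction = nJ_shared / (nJ_shared + nJ_priv),
      chain = nC_shared / (nC_shared + nC_priv))
    list(T1 = as_annotation(t1, name = "sim.T1"),
         T2 = as_annotation(t2, name = "sim.T2"),
         truth = truth)
  })
}

#' Simulate an assembly with planted intron-retention events
#'
#' Builds an assembly of clean background transcripts plus planted
#' intron-retention events with known truth labels. Each event occupies its
#' own coordinate window and consists of a four-exon reference transcript r
#' and a candidate t constructed to satisfy exactly the requested criterion
#' against r and nothing else: for criterion 1, t starts inside r's second
#' intron (covering the fraction `overlap` of it) and continues with r's
#' remaining structure; criterion 2 is the mirror image; for criterion 3, t
#' is r with its second intron retained (the flanking exons merged). The
#' abundance of r is `ratio` times the abundance of t, so an event is
#' recoverable exactly when `ratio >=` the classifier's coverage ratio (and
#' `overlap >=` its length ratio for partial events). Background transcripts
#' and references are unflaggable by construction.
#'
#' @param n_background Number of clean background transcripts.
#' @param events Data frame with columns `criterion` (1, 2 or 3), `ratio`
#'   (abundance ratio p(r)/p(t) > 0) and optionally `overlap` (intron
#'   overlap fraction in (0, 1) for partial events; default 0.5).
#' @param base_abundance Abundance given to each candidate t.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `assembly` (an `annotation`) and `truth` (data frame:
#'   `transcript_id`, `flagged`, `criterion`, `ratio`, `overlap`).
#' @examples
#' sim <- simulate_ir_assembly(
#'   n_background = 3,
#'   events = data.frame(criterion = c(1, 3), ratio = c(1, 0.8)), seed = 2)
#' calls <- ir_classify(sim$assembly)
#' all(calls$calls$flagged == sim$truth$flagged)
#' @export
simulate_ir_assembly <- function(n_background = 10,
                                 events = data.frame(criterion = integer(0),
                                                     ratio = numeric(0)),
                                 base_abundance = 10, seed = 1) {
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    if (!all(events$criterion %in% 1:3)) stop("criterion must be 1, 2 or 3")
    if (any(events$ratio <= 0)) stop("ratio must be positive")
  }
  if (is.null(events$overlap)) events$overlap <- rep(0.5, nrow(events))
  if (nrow(events) > 0 && any(events$overlap <= 0 | events$overlap >= 1))
    stop("overlap must be strictly between 0 and 1")
  with_seed(seed, {
    txs <- list()
    truth <- list()
    cursor <- 1000
    for (b in seq_len(n_background)) {
      k <- sample(2:5, 1)
      ex <- rand_exons(k, cursor)
      cursor <- max(ex[, 2]) + 10000
      id <- sprintf("bg.%03d", b)
      txs[[length(txs) + 1L]] <- transcript(id, paste0("g.", id), "chr1", "+",
                                            ex, abundance = runif(1, 5, 50))
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, flagged = FALSE, criterion = NA_integer_,
        ratio = NA_real_, overlap = NA_real_, stringsAsFactors = FALSE)
    }
    for (e in seq_len(nrow(events))) {
      crit <- events$criterion[e]
      ratio <- events$ratio[e]
      ovf <- events$overlap[e]
      r_ex <- rand_exons(4, cursor, exon_len = c(100, 200),
                         intron_len = c(100, 200))
      cursor <- max(r_ex[, 2]) + 10000
      intr <- exon_introns(r_ex)
      t_ex <- switch(as.character(crit),
        "1" = {
          # first exon starts inside intron 2, covers `ovf` of it
          len <- intr[2, 2] - intr[2, 1] + 1
          s <- intr[2, 2] - max(1, round(ovf * len)) + 1
          if (s <= intr[2, 1]) s <- intr[2, 1] + 1
          rbind(c(s, r_ex[3, 2]), r_ex[4, ])
        },
        "2" = {
          len <- intr[2, 2] - intr[2, 1] + 1
          en <- intr[2, 1] + max(1, round(ovf * len)) - 1
          if (en >= intr[2, 2]) en <- intr[2, 2] - 1
          rbind(r_ex[1, ], c(r_ex[2, 1], en))
        },
        "3" = rbind(r_ex[1, ], c(r_ex[2, 1], r_ex[3, 2]), r_ex[4, ]))
      gid <- sprintf("g.ir.%03d", e)
      tid <- sprintf("ir.t.%03d", e)
      rid <- sprintf("ir.r.%03d", e)
      txs[[length(txs) + 1L]] <- transcript(
        rid, gid, "chr1", "+", r_ex, abundance = base_abundance * ratio)
      txs[[length(txs) + 1L]] <- transcript(
        tid, gid, "chr1", "+", t_ex, abundance = base_abundance)
      real_ov <- if (crit == 1) {
        (intr[2, 2] - t_ex[1, 1] + 1) / (intr[2, 2] - intr[2, 1] + 1)
      } else if (crit == 2) {
        (t_ex[nrow(t_ex), 2] - intr[2, 1] + 1) / (intr[2, 2] - intr[2, 1] + 1)
      } else NA_real_
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = rid, flagged = FALSE, criterion = NA_integer_,
        ratio = NA_real_, overlap = NA_real_, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = tid, flagged = TRUE, criterion = as.integer(crit),
        ratio = ratio, overlap = real_ov, stringsAsFactors = FALSE)
    }
    assembly <- as_annotation(txs, name = "sim.assembly")
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(transcript_id = character(0), flagged = logical(0),
                 criterion = integer(0), ratio = numeric(0),
                 overlap = numeric(0), stringsAsFactors = FALSE)
    # report truth in assembly order
    truth <- truth[match(assembly$tx$transcript_id, truth$transcript_id), ]
    rownames(truth) <- NULL
    list(assembly = assembly, truth = truth)
  })
}
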