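test_that("self-matching yields precision 1 and exactness of chain matching", {
  sim <- simulate_ir_assembly(
    n_background = 8,
    events = data.frame(criterion = c(1, 3), ratio = c(1, 1)), seed = 51)
  ann <- sim$assembly
  rep <- match_transcripts(ann, ann)
  expect_equal(rep$precision, 1)
  expect_equal(rep$n_matching, length(ann))

  # shifting one junction by 1 bp breaks the match
  ref <- as_annotation(list(
    transcript("r", "g", "chr1", "+", cbind(c(1, 201), c(100, 300)))))
  shifted <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(c(1, 202), c(100, 300)))))
  expect_equal(match_transcripts(shifted, ref)$n_matching, 0L)
  same_chain <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(c(21, 201), c(100, 280)))))
  expect_equal(match_transcripts(same_chain, ref)$n_matching, 1L)
  expect_equal(match_transcripts(same_chain, ref)$transcripts$match_type,
               "chain")
})

test_that("single-exon transcripts match by reciprocal overlap", {
  ref <- as_annotation(list(
    transcript("r", "g", "chr1", "+", cbind(1, 1000))))
  ok <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(101, 1000))))  # 900/1000 both
  expect_equal(match_transcripts(ok, ref)$n_matching, 1L)
  short <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(201, 1000))))  # 800/1000 = 0.8
  expect_equal(match_transcripts(short, ref)$n_matching, 1L)
  shorter <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(202, 1000))))  # 799/1000 < 0.8
  expect_equal(match_transcripts(shorter, ref)$n_matching, 0L)
  # non-reciprocal mode requires 80% of the assembled transcript only
  tiny <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(1, 100))))
  expect_equal(match_transcripts(tiny, ref)$n_matching, 0L)
  expect_equal(match_transcripts(tiny, ref, reciprocal = FALSE)$n_matching, 1L)
  # a multi-exon transcript never matches a single-exon reference
  multi <- as_annotation(list(
    transcript("q", "g", "chr1", "+", cbind(c(1, 501), c(400, 1000)))))
  expect_equal(match_transcripts(multi, ref)$n_matching, 0L)
  # strandedness applies to single-exon matching too
  minus <- as_annotation(list(
    transcript("q", "g", "chr1", "-", cbind(101, 1000))))
  expect_equal(match_transcripts(minus, ref)$n_matching, 0L)
  expect_equal(match_transcripts(minus, ref,
                                 ignore_strand = TRUE)$n_matching, 1L)
})

test_that("match reports equal the all-pairs brute-force matcher", {
  for (seed in 1:8) {
    asm <- random_assembly(40, 700 + seed)
    ref <- random_assembly(40, 700 + seed + 100)
    # make some real matches by splicing reference transcripts in
    both <- match_transcripts(asm, ref)
    expect_identical(both$transcripts$matched, brute_match_flags(asm, ref))
    self <- match_transcripts(asm, asm)
    expect_true(all(self$transcripts$matched))
    # mixed: half the reference is shared
    mixed <- bind_ann_halves(asm, ref)
    repm <- match_transcripts(mixed, ref)
    expect_identical(repm$transcripts$matched, brute_match_flags(mixed, ref))
    expect_true(repm$n_matching >= length(ref) %/% 2)
  }
})

test_that("dedupe counts distinct matched references", {
  r <- transcript("r", "g", "chr1", "+", cbind(c(1, 201), c(100, 300)),
                  abundance = 1)
  a1 <- transcript("a1", "g", "chr1", "+", cbind(c(11, 201), c(100, 290)),
                   abundance = 2)
  a2 <- transcript("a2", "g", "chr1", "+", cbind(c(21, 201), c(100, 280)),
                   abundance = 3)
  asm <- as_annotation(list(a1, a2))
  ref <- as_annotation(list(r))
  plain <- match_transcripts(asm, ref)
  expect_equal(plain$n_matching, 2L)
  expect_equal(plain$precision, 1)
  dd <- match_transcripts(asm, ref, dedupe = TRUE)
  expect_equal(dd$n_matching, 1L)
  expect_equal(dd$precision, 1)  # precision numerator is matched assembled
})

test_that("adjusted precision removes lowest-abundance transcripts until counts equalise", {
  # A: 6 matching / 10 assembled; B: 5 matching / 8 assembled.
  # A's two lowest-abundance transcripts are one unmatched (ab 0.5) and one
  # matched (ab 1); after removing both, 5 matching / 8 remaining = 0.625.
  ref_txs <- lapply(1:6, function(i)
    transcript(sprintf("r%d", i), sprintf("g%d", i), "chr1", "+",
               cbind(c(1, 201) + i * 10000, c(100, 300) + i * 10000)))
  ref <- as_annotation(ref_txs, name = "ref")
  match_tx <- function(id, i, ab)
    transcript(id, sprintf("g%d", i), "chr1", "+",
               cbind(c(11, 201) + i * 10000, c(100, 290) + i * 10000),
               abundance = ab)
  nomatch_tx <- function(id, i, ab)
    transcript(id, paste0("n", id), "chr2", "+",
               cbind(c(1, 201) + i * 10000, c(100, 300) + i * 10000),
               abundance = ab)
  A <- as_annotation(c(
    lapply(1:6, function(i) match_tx(sprintf("am%d", i), i, i)),
    lapply(1:4, function(i) nomatch_tx(sprintf("an%d", i), i,
                                       c(0.5, 5, 6, 7)[i]))), name = "A")
  B <- as_annotation(c(
    lapply(1:5, function(i) match_tx(sprintf("bm%d", i), i, i)),
    lapply(1:3, function(i) nomatch_tx(sprintf("bn%d", i), i, i))),
    name = "B")
  res <- adjusted_precision(A, B, ref)
  expect_equal(res$precision_a, 0.6)
  expect_equal(res$precision_b, 5 / 8)
  expect_equal(res$adjusted_side, "a")
  expect_equal(nrow(res$trace), 2L)
  expect_equal(res$trace$transcript_id, c("an1", "am1"))
  expect_equal(res$adjusted_precision, 0.625)
  expect_equal(res$trace$n_matching_after[2], 5L)

  # equal counts: no adjustment
  res_eq <- adjusted_precision(B, B, ref)
  expect_equal(res_eq$adjusted_side, "none")
  expect_equal(res_eq$precision_a, res_eq$precision_b)
  expect_equal(nrow(res_eq$trace), 0L)
})

test_that("abundance ties break lexicographically so the trace is deterministic", {
  ref <- as_annotation(list(
    transcript("r1", "g1", "chr1", "+", cbind(c(1, 201), c(100, 300)))))
  mk <- function(ids) as_annotation(c(
    list(transcript("keep", "g1", "chr1", "+",
                    cbind(c(1, 201), c(100, 300)), abundance = 9)),
    lapply(ids, function(id)
      transcript(id, paste0("g", id), "chr5", "+", cbind(c(1, 201) , c(100, 300)),
                 abundance = 1))), name = "tied")
  A <- mk(c("zz", "aa", "mm"))
  B <- as_annotation(list(transcript("b1", "gb", "chr9", "+",
                                     cbind(1, 100), abundance = 1)),
                     name = "B")
  r1 <- adjusted_precision(A, B, ref)
  r2 <- adjusted_precision(A, B, ref)
  expect_identical(r1$trace, r2$trace)
  # the tied, unmatched transcripts go first in id order; removal stops as
  # soon as the matching counts are equal (1 vs 0 -> remove until 0)
  expect_equal(r1$trace$transcript_id[1:3], c("aa", "mm", "zz"))
})

test_that("biotype stratification conserves the matched count", {
  ref_txs <- c(
    lapply(1:3, function(i)
      transcript(sprintf("pc%d", i), sprintf("g%d", i), "chr1", "+",
                 cbind(c(1, 201) + i * 10000, c(100, 300) + i * 10000),
                 biotype = "protein_coding")),
    lapply(1:2, function(i)
      transcript(sprintf("ri%d", i), sprintf("h%d", i), "chr1", "+",
                 cbind(c(1, 401) + (i + 4) * 10000, c(100, 500) + (i + 4) * 10000),
                 biotype = "retained_intron")))
  ref <- as_annotation(ref_txs, name = "ref")
  asm <- ref  # identity assembly
  rep <- match_transcripts(asm, ref)
  bt <- stratify_by_biotype(rep, ref)
  expect_equal(sum(bt), rep$n_matching)
  expect_equal(unname(bt["protein_coding"]), 3L)
  expect_equal(unname(bt["retained_intron"]), 2L)
  # empty match set gives empty counts
  far <- as_annotation(list(transcript("x", "gx", "chrZ", "+",
                                       cbind(c(1, 201), c(100, 300)))))
  rep0 <- match_transcripts(far, ref)
  expect_length(stratify_by_biotype(rep0, ref), 0L)
  # random fixture conservation
  for (seed in 1:4) {
    asm2 <- bind_ann_halves(random_assembly(30, 800 + seed), ref)
    rep2 <- match_transcripts(asm2, ref)
    bt2 <- stratify_by_biotype(rep2, ref)
    expect_equal(sum(bt2), rep2$n_matching)
  }
})

test_that("intersection and union follow exact-match semantics", {
  pair <- example_annotation_pair()
  # query == reference: intersection keeps every query transcript, union is
  # the reference alone
  inter <- annotation_intersection(pair$T1, pair$T1)
  expect_equal(length(inter), length(pair$T1))
  uni <- annotation_union(pair$T1, pair$T1)
  expect_equal(length(uni), length(pair$T1))
  # disjoint annotations: empty intersection, additive union
  other <- as_annotation(list(
    transcript("z", "gz", "chr8", "-", cbind(c(1, 201), c(100, 300)))),
    name = "other")
  expect_equal(length(annotation_intersection(pair$T1, other)), 0L)
  expect_equal(length(annotation_union(pair$T1, other)),
               length(pair$T1) + 1L)
  # half-overlapping pair: sizes agree with the brute-force matcher
  for (seed in 1:4) {
    q <- bind_ann_halves(random_assembly(20, 900 + seed),
                         random_assembly(20, 950 + seed))
    r <- random_assembly(20, 950 + seed)
    flags <- brute_match_flags(q, r)
    expect_equal(length(annotation_intersection(r, q)), sum(flags))
    expect_equal(length(suppressWarnings(annotation_union(r, q))),
                 length(r) + sum(!flags))
  }
})

test_that("threshold sweeps are consistent with direct runs and monotone", {
  sim <- simulate_ir_assembly(
    n_background = 6,
    events = data.frame(criterion = c(1, 2, 3, 1),
                        ratio = c(1, 0.8, 0.6, 0.45)), seed = 61)
  asm <- sim$assembly
  ref <- asm[which(!sim$truth$flagged)]  # the clean part as reference
  one <- threshold_sweep(asm, ref, vary = "cr", grid = 0.5)
  direct <- match_transcripts(ir_partition(asm, ir_params())$kept, ref)
  expect_equal(one$precision, direct$precision)
  expect_equal(one$n_matching, direct$n_matching)

  grid <- c(0.3, 0.5, 0.7, 1.1)
  sw <- threshold_sweep(asm, ref, vary = "cr", grid = grid)
  expect_equal(sw$threshold, grid)
  # raising cr shrinks the flagged set, so the kept set and matches grow
  expect_true(all(diff(sw$n_flagged) <= 0))
  expect_true(all(diff(sw$n_kept) >= 0))
  expect_true(all(diff(sw$n_matching) >= 0))

  # lr = 1 with partial-only criteria flags nothing (partial overlap < 1)
  swl <- threshold_sweep(asm, ref, params = ir_params(entire = FALSE),
                         vary = "lr", grid = c(0, 0.5, 1))
  expect_equal(swl$n_flagged[swl$threshold == 1], 0)
  expect_error(threshold_sweep(asm, ref, vary = "cr", grid = c(1, 0.5)),
               "sorted")

  # filtering never increases the assembled or matching counts
  full <- match_transcripts(asm, ref)
  kept_rep <- match_transcripts(ir_partition(asm)$kept, ref)
  expect_lte(kept_rep$n_matching, full$n_matching)
  expect_lte(kept_rep$n_assembled, full$n_assembled)
})
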