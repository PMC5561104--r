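test_that("majority vote reproduces hand-computed consensus intervals", {
  A <- gr0("chr1", c(10, 50), c(30, 60))
  B <- gr0("chr1", 20, 40)
  C <- gr0("chr1", c(25, 55), c(35, 58))
  r2 <- refgen(list(A, B, C), tau = 2)
  expect_same_intervals(r2$intervals,
                        data.frame(chrom = "chr1", s0 = c(20, 55),
                                   e0 = c(35, 58)))
  expect_equal(S4Vectors::mcols(r2$intervals)$support, c(3L, 2L))

  r1 <- refgen(list(A, B, C), tau = 1)
  expect_same_intervals(r1$intervals,
                        data.frame(chrom = "chr1", s0 = c(10, 50),
                                   e0 = c(40, 60)))
  r3 <- refgen(list(A, B, C), tau = 3)
  expect_same_intervals(r3$intervals,
                        data.frame(chrom = "chr1", s0 = 25, e0 = 30))
})

test_that("tau is validated and fractional tau rounds up", {
  sets <- list(gr0("chr1", 0, 10), gr0("chr1", 5, 15))
  expect_error(refgen(sets, tau = 0), "tau")
  expect_error(refgen(sets, tau = 3), "tau")
  expect_error(refgen(list(), tau = 1), "at least one")
  expect_error(refgen(sets, tau = 1.5, tau_mode = "fraction"), "\\(0, 1\\]")
  # 75% of 4 inputs -> 3; 75% of 6 -> 5 (ceil)
  sets4 <- replicate(4, gr0("chr1", 0, 10))
  expect_equal(refgen(sets4, 0.75, tau_mode = "fraction")$tau, 3L)
  sets6 <- replicate(6, gr0("chr1", 0, 10))
  expect_equal(refgen(sets6, 0.75, tau_mode = "fraction")$tau, 5L)
})

test_that("vote agrees with the per-base bitmap oracle at every tau", {
  set.seed(101)
  lens <- toy_lens(3, 50000)
  n_instances <- 60
  for (inst in seq_len(n_instances)) {
    n_sets <- sample(2:8, 1)
    sets <- random_instance(n_sets, lens)
    bm <- bitmap_vote(sets, lens)
    prev <- NULL
    for (tau in seq_len(n_sets)) {
      got <- refgen(sets, tau)$intervals
      exp_df <- bitmap_consensus(bm, tau)
      expect_same_intervals(got, exp_df)
      expect_equal(S4Vectors::mcols(got)$support,
                   exp_df$support[order(exp_df$chrom, exp_df$s0)])
      # support bounds
      expect_true(all(S4Vectors::mcols(got)$support >= tau))
      expect_true(all(S4Vectors::mcols(got)$support <= n_sets))
      # tau-nesting: consensus(tau) genomic set contains consensus(tau+1)
      if (!is.null(prev)) {
        expect_equal(sum(width(GenomicRanges::setdiff(got, prev))), 0)
      }
      prev <- got
    }
    # tau = 1 is the collapsed union
    uni <- bed0(collapse_intervals(do.call(c, sets)))
    uni <- uni[order(uni$chrom, uni$s0), ]
    got1 <- bed0(refgen(sets, 1)$intervals)
    rownames(uni) <- rownames(got1) <- NULL
    expect_equal(got1, uni)
  }
})

test_that("vote is invariant under permutation of input sets", {
  set.seed(202)
  lens <- toy_lens(2, 20000)
  sets <- random_instance(5, lens)
  base <- refgen(sets, 3)$intervals
  for (k in 1:5) {
    perm <- sample(seq_along(sets))
    got <- refgen(sets[perm], 3)$intervals
    expect_equal(bed0(got), bed0(base))
  }
})

test_that("within-set duplicate peaks contribute a single vote", {
  dup <- gr0("chr1", c(10, 12), c(30, 28))  # overlapping within one set
  other <- gr0("chr1", 15, 25)
  r2 <- refgen(list(dup, other), tau = 2)
  expect_same_intervals(r2$intervals,
                        data.frame(chrom = "chr1", s0 = 15, e0 = 25))
})

test_that("minimum-length filter drops short consensus runs", {
  sets <- list(gr0("chr1", c(0, 100), c(10, 103)),
               gr0("chr1", c(0, 100), c(10, 103)))
  expect_length(refgen(sets, 2)$intervals, 2)
  expect_length(refgen(sets, 2, min_len = 5)$intervals, 1)
})

test_that("hierarchical build chains replicate, context and reference votes", {
  # one study, two replicates: all-replicates rule = intersection
  plan <- list(ctxA = list(study1 = list(gr0("chr1", 0, 10),
                                         gr0("chr1", 5, 15))))
  b <- build_reference(plan)
  expect_same_intervals(b$study_cistromes$ctxA$study1,
                        data.frame(chrom = "chr1", s0 = 5, e0 = 10))

  # context vote: 4 studies at fraction 0.75 -> effective tau 3
  shared <- gr0("chr1", 100, 200)
  plan <- list(ctx = list(s1 = list(shared), s2 = list(shared),
                          s3 = list(shared),
                          s4 = list(gr0("chr1", 500, 600))))
  b <- build_reference(plan)
  expect_same_intervals(b$context_cistromes$ctx,
                        data.frame(chrom = "chr1", s0 = 100, e0 = 200))

  # reference level: union over context cistromes (tau = 1)
  plan <- list(c1 = list(s = list(gr0("chr1", 0, 10))),
               c2 = list(s = list(gr1 <- gr0("chr1", 100, 110))))
  b <- build_reference(plan)
  expect_same_intervals(b$reference$intervals,
                        data.frame(chrom = "chr1", s0 = c(0, 100),
                                   e0 = c(10, 110)))
  expect_error(build_reference(list(ctx = list())), "no studies")
})

test_that("co-occurrence classes are assigned and partition the reference", {
  ref <- gr0("chr1", c(20, 55), c(35, 58))
  ctx1 <- gr0("chr1", 20, 35)
  ctx2 <- gr0("chr1", c(25, 56), c(30, 58))
  cl <- classify_cooccurrence(ref, list(a = ctx1, b = ctx2))
  expect_equal(cl$table$class, c("C2", "C1"))
  expect_equal(cl$table$contexts, c("a,b", "b"))

  # single context: everything C1
  cl1 <- classify_cooccurrence(ref, list(only = gr0("chr1", 0, 1000)))
  expect_true(all(cl1$table$class == "C1"))

  # partition property on random synthetic inputs
  set.seed(33)
  lay <- toy_genome(2, 2e5)
  truth <- simulate_truth(lay, 80, seed = 12)
  studies <- simulate_studies(truth, lay, n_studies = 6, sensitivity = 0.8,
                              noise_per_study = 20, seed = 12)
  plan <- list(cA = list(s1 = studies[1:2]), cB = list(s1 = studies[3:4]),
               cC = list(s1 = studies[5:6]))
  plan <- lapply(plan, function(ctx) lapply(ctx, function(s) unname(s)))
  b <- build_reference(plan, context_tau = 1, context_tau_mode = "count")
  cl <- classify_cooccurrence(b$reference, b$context_cistromes)
  expect_equal(sum(cl$counts), length(b$reference$intervals))
  expect_true(all(cl$table$k >= 1 & cl$table$k <= 3))
})

test_that("sites outside every context error for built references, class C0 otherwise", {
  ctxs <- list(a = gr0("chr1", 0, 10))
  fake <- refgen(list(gr0("chr1", 100, 110)), 1)
  expect_error(classify_cooccurrence(fake, ctxs), "overlap no context")
  expect_warning(cl <- classify_cooccurrence(gr0("chr1", 100, 110), ctxs),
                 "C0")
  expect_equal(cl$table$class, "C0")
})

test_that("feature overlap honours replicate-support rules", {
  ref <- gr0("chr1", c(0, 100), c(50, 150))
  r1 <- gr0("chr1", 10, 20)
  r2 <- gr0("chr1", 200, 210)
  r3 <- gr0("chr1", 30, 40)
  # site 1 overlaps replicates {1,3}: hit at min_support 2 (2-of-3 rule)
  ann <- annotate_overlap(ref, list(chiapet = list(r1, r2, r3)),
                          min_support = c(chiapet = 2))
  expect_equal(unname(ann$hits[, "chiapet"]), c(TRUE, FALSE))
  expect_equal(unname(ann$fractions["chiapet"]), 0.5)

  # min_support = group size: hit iff all replicates overlap
  all3 <- annotate_overlap(ref, list(g = list(r1, gr0("chr1", 15, 25), r3)),
                           min_support = c(g = 3))
  expect_equal(unname(all3$hits[, "g"]), c(TRUE, FALSE))

  # empty feature set: fraction 0 everywhere
  none <- annotate_overlap(ref, list(empty = GenomicRanges::GRanges()))
  expect_equal(unname(none$fractions["empty"]), 0)

  expect_error(annotate_overlap(ref, list(g = list(r1)),
                                min_support = c(nope = 1)),
               "unknown group")
  expect_error(annotate_overlap(ref, list(g = list(r1)),
                                min_support = c(g = 2)), "min_support")
})
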