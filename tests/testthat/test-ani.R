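test_that("reference selection maximizes length x contiguity and is symmetric", {
  mk <- function(id, lens) {
    structure(list(genome_id = id, contig_names = paste0("c", seq_along(lens)),
                   contig_lengths = lens, total_length = sum(lens)),
              class = "genome_sketch")
  }
  a <- mk("a", rep(5e5, 10))   # 5 Mb, mean 0.5 Mb -> 2.5e12
  b <- mk("b", 4e6)            # 4 Mb, mean 4 Mb  -> 1.6e13
  expect_identical(select_reference(a, b)$reference$genome_id, "b")
  expect_identical(select_reference(b, a)$reference$genome_id, "b")

  # tie on score: lexicographically smaller id is reference, both orders
  x <- mk("x", 1e6); y <- mk("y", 1e6)
  expect_identical(select_reference(x, y)$reference$genome_id, "x")
  expect_identical(select_reference(y, x)$reference$genome_id, "x")
})

test_that("query fragmentation yields nonoverlapping 20-kb chunks with retained tails", {
  p <- sketch_params()
  mk_sketch <- function(len) sketch_genome(c(ctg = random_genome(len, seed = len)), p)

  f50 <- fragment_query(mk_sketch(50000), p)
  expect_identical(f50$chunks$end - f50$chunks$start, c(20000L, 20000L, 10000L))

  f20 <- fragment_query(mk_sketch(20000), p)
  expect_identical(nrow(f20$chunks), 1L)

  f300 <- fragment_query(mk_sketch(300), p)
  expect_identical(nrow(f300$chunks), 1L)
  expect_identical(f300$chunks$end, 300L)

  # seed x-coordinates are chunk-relative and within the chunk
  expect_true(all(f50$seeds$x >= 0 & f50$seeds$x < p$chunk_size))
})

test_that("orthology filter keeps high scorers, drops 2-anchor and duplicate-span chains", {
  p <- sketch_params()
  ch <- function(score, n, r1, r2, chunk = 1L) data.table::data.table(
    chunk_id = chunk, ref_contig = 1L, strand = 0L, score = score,
    n_anchors = n, q_first = 0L, q_last = 100L, r_first = r1, r_last = r2)
  chains <- data.table::rbindlist(list(
    ch(100, 5, 1000L, 3000L),          # best: selected
    ch(90, 5, 1000L, 3000L),           # identical span: rejected
    ch(80, 2, 50000L, 60000L),         # two anchors: never selected
    ch(70, 4, 2200L, 3400L)            # ~65% of its span overlaps: rejected
  ))
  sel <- select_orthologous_chains(chains, p)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$score, 100)

  # 40% overlap is below the 50% bound: selected
  chains2 <- data.table::rbindlist(list(
    ch(100, 5, 1000L, 2985L),          # span [1000, 3000)
    ch(70, 4, 2200L, 3985L)            # span [2200, 4000): 800/2000 = 40%
  ))
  sel2 <- select_orthologous_chains(chains2, p)
  expect_identical(nrow(sel2), 2L)
})

test_that("per-chunk ANI follows (alpha/M)^(1/k) with the flanked-seed fallback", {
  p <- sketch_params()
  full <- chunk_ani(list(alpha = 120, m = 120, m_lr = 120, span_lr = 19000), p)
  expect_identical(full$ani, 1)

  zero <- chunk_ani(list(alpha = 0, m = 100, m_lr = 0, span_lr = 0), p)
  expect_identical(zero$ani, 0)
  expect_false(zero$lr_used)

  base <- chunk_ani(list(alpha = 80, m = 100, m_lr = 80, span_lr = 100), p)
  expect_equal(base$ani, 0.8^(1 / 15))
  expect_equal(base$ani, 0.98523, tolerance = 1e-4)
  expect_false(base$lr_used)   # span too short for the LR heuristic
  expect_identical(base$weight, 100)

  # partial homology: alpha/m low but alpha/m_lr high over a long span
  lr <- chunk_ani(list(alpha = 60, m = 150, m_lr = 62, span_lr = 8000), p)
  expect_true(lr$lr_used)
  expect_equal(lr$ani, (60 / 62)^(1 / 15))
  expect_identical(lr$weight, 62)

  # alpha capped at m_lr: ratio clamps to 1
  cap <- chunk_ani(list(alpha = 65, m = 150, m_lr = 62, span_lr = 8000), p)
  expect_identical(cap$ani, 1)
})

test_that("the weighted mean combines chunks as stated", {
  expect_equal(combine_ani(0.97, 12), 0.97)
  expect_equal(combine_ani(c(0.90, 1.00), c(10, 30)), 0.975)
  expect_equal(combine_ani(rep(0.93, 7), c(5, 1, 9, 2, 8, 4, 6)), 0.93)
  expect_error(combine_ani(numeric(), numeric()), "no weighted chunks")
})

test_that("aligned fraction recovers a 40% reference slice", {
  p <- sketch_params()
  g <- random_genome(500000, seed = 81)
  ref <- sketch_genome(c(ctg = g), p, genome_id = "ref")
  slice <- sketch_genome(c(slice = substring(g, 50001, 250000)), p,
                         genome_id = "slice")
  r <- compare_pair(ref, slice)
  expect_gte(r$af_query, 0.97)
  expect_lt(abs(r$af_ref - 0.40), 0.03)
  expect_identical(r$query_id, "slice")   # smaller genome becomes query

  none <- aligned_fraction(
    data.table::data.table(q_first_abs = integer(), q_last_abs = integer(),
                           r_first = integer(), r_last = integer()),
    ref, slice, p)
  expect_identical(none$af_query, 0)
  expect_identical(none$af_ref, 0)
})

test_that("AF gate suppresses output when both fractions are below 15%", {
  p <- sketch_params()
  core <- random_genome(40000, seed = 83)
  a <- sketch_genome(
    c(ctg = paste0(random_genome(460000, seed = 84), core)), p, "a")
  b <- sketch_genome(
    c(ctg = paste0(core, random_genome(460000, seed = 85))), p, "b")
  r <- compare_pair(a, b)
  expect_true(r$screen_pass)      # shared core keeps putative ANI high
  expect_lt(r$af_ref, 0.15)
  expect_lt(r$af_query, 0.15)
  expect_false(r$af_pass)
  expect_true(is.na(r$ani))
  expect_identical(nrow(results_table(list(r))), 0L)
})

test_that("bootstrap CI: absent at <=10 chunks, zero-width when constant, seeded", {
  p <- sketch_params()
  ten <- data.table::data.table(ani = runif(10, 0.9, 1), weight = rep(10, 10))
  expect_null(bootstrap_ci(ten, p))

  const <- data.table::data.table(ani = rep(0.97, 50), weight = rep(7, 50))
  ci <- bootstrap_ci(const, p)
  expect_equal(ci, c(0.97, 0.97))

  vary <- data.table::data.table(ani = runif(40, 0.95, 0.99),
                                 weight = runif(40, 50, 200))
  c1 <- bootstrap_ci(vary, p, rng_seed = 11)
  c2 <- bootstrap_ci(vary, p, rng_seed = 11)
  c3 <- bootstrap_ci(vary, p, rng_seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
  expect_lt(c1[1], c1[2])
})

test_that("self-comparison returns ANI 1 with near-complete AF", {
  p <- sketch_params()
  a <- sketch_genome(c(ctg = random_genome(200000, seed = 87)), p, "a")
  r <- compare_pair(a, a)
  expect_identical(r$ani, 1)
  expect_gte(r$af_query, 0.99)
  expect_gte(r$af_ref, 0.99)
})

test_that("unrelated genomes are screened out; fingerprints must match", {
  p <- sketch_params()
  a <- sketch_genome(c(ctg = random_genome(500000, seed = 88)), p, "a")
  b <- sketch_genome(c(ctg = random_genome(500000, seed = 89)), p, "b")
  r <- compare_pair(a, b)
  expect_false(r$screen_pass)
  expect_true(is.na(r$ani))
  expect_identical(r$putative_ani, 0)

  other <- sketch_genome(c(ctg = random_genome(30000, seed = 90)),
                         sketch_params(c = 100), "o")
  expect_error(compare_pair(a, other), "fingerprint")
})

test_that("comparison is symmetric in argument order, chains and CI included", {
  p <- sketch_params()
  pr <- sketch_pair(150000, 0.03, seed = 91, params = p)
  r1 <- compare_pair(pr$a, pr$b, p, seed = 5L)
  r2 <- compare_pair(pr$b, pr$a, p, seed = 5L)
  for (f in c("query_id", "ref_id", "ani", "ani_raw", "af_query", "af_ref",
              "ci90", "n_chunks", "putative_ani", "aligned_bases")) {
    expect_identical(r1[[f]], r2[[f]])
  }
  expect_equal(r1$chunk_estimates, r2$chunk_estimates)
})

test_that("deleting reference contigs never increases reference-side coverage", {
  p <- sketch_params()
  g <- random_genome(200000, seed = 93)
  # query: the same genome in 10-kb contigs (low contiguity keeps it query)
  qs <- seq(1, 200000, by = 10000)
  qry <- sketch_genome(setNames(substring(g, qs, pmin(qs + 9999, 200000)),
                                paste0("q", seq_along(qs))), p, "query")
  # reference: 30-kb contigs, deleted in nested subsets
  rs <- seq(1, 200000, by = 30000)
  ref_contigs <- setNames(substring(g, rs, pmin(rs + 29999, 200000)),
                          paste0("r", seq_along(rs)))
  keep_sets <- list(1:7, c(1:3, 5:7), c(1:3, 6:7))
  cov <- vapply(keep_sets, function(ks) {
    ref <- sketch_genome(ref_contigs[ks], p, "ref")
    compare_pair(qry, ref)$aligned_bases
  }, 0)
  expect_true(all(diff(cov) <= 0))
})
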