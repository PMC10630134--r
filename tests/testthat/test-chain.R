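test_that("anchor collection finds diagonals, strands, and repeat multiplicity", {
  p <- tiny_params()
  g <- random_genome(30000, seed = 41)
  ref <- sketch_genome(c(ctg = g), p, genome_id = "ref")

  # chunk identical to a reference region: all anchors on one diagonal
  chunk_seq <- substring(g, 5001, 9000)
  csk <- sketch_genome(c(chunk = chunk_seq), p)
  chunk_seeds <- data.table::data.table(pos = csk$seeds$pos,
                                        hash = csk$seeds$hash,
                                        strand = csk$seeds$strand)
  anchors <- collect_anchors(chunk_seeds, ref$seeds, p)
  expect_gt(nrow(anchors), 10)
  diag_anchors <- anchors[anchors$y - anchors$x == 5000, ]
  expect_identical(unique(diag_anchors$strand), 0L)
  expect_gte(nrow(diag_anchors), nrow(csk$seeds))  # every chunk seed matches
  # output sorted lexicographically
  expect_false(is.unsorted(anchors$x))

  # reverse-complemented chunk: all true anchors on the reverse strand
  rc_sk <- sketch_genome(c(chunk = revcomp(chunk_seq)), p)
  rc_seeds <- data.table::data.table(pos = rc_sk$seeds$pos,
                                     hash = rc_sk$seeds$hash,
                                     strand = rc_sk$seeds$strand)
  rc_anchors <- collect_anchors(rc_seeds, ref$seeds, p)
  expect_gt(mean(rc_anchors$strand == 1L), 0.95)

  # a hash occurring 3 times in the reference gives 3 anchors at one x
  rep_ref <- data.table::data.table(hash = "deadbeef00000000",
                                    contig = 1L, pos = c(10L, 500L, 900L),
                                    strand = 0L)
  data.table::setkey(rep_ref, hash)
  one <- data.table::data.table(pos = 7L, hash = "deadbeef00000000",
                                strand = 0L)
  a3 <- collect_anchors(one, rep_ref, p)
  expect_identical(nrow(a3), 3L)
  expect_identical(unique(a3$x), 7L)
})

test_that("chain score is 20 minus the diagonal offset", {
  expect_identical(chain_score(100, 100, 50, 50), 20)
  expect_identical(chain_score(100, 105, 50, 50), 15)
  expect_identical(chain_score(150, 250, 50, 50), -80)
})

test_that("DP base cases: single anchor and one collinear pair", {
  one <- data.table::data.table(x = 5L, y = 9L)
  dp <- chain_anchors_banded(one)
  expect_identical(dp$f, 0)
  expect_identical(dp$pred, 0L)

  two <- data.table::data.table(x = c(5L, 30L), y = c(9L, 34L))
  dp2 <- chain_anchors_banded(two)
  expect_identical(dp2$f, c(0, 20))
  expect_identical(dp2$pred, c(0L, 1L))
})

test_that("unbanded DP equals the exhaustive oracle (scores and predecessors)", {
  set.seed(51)
  for (rep in 1:60) {
    a <- random_anchors(sample(2:120, 1))
    dp <- chain_anchors_banded(a, banded = FALSE)
    oracle <- dp_oracle(a$x, a$y)
    expect_identical(dp$f, oracle$f)
    expect_identical(dp$pred, oracle$pred)
  }
})

test_that("the band severs chains across large query gaps", {
  p <- sketch_params()  # band_b = 2500
  # two collinear clusters separated by 5000 on x
  a <- data.table::data.table(
    x = c(0L, 100L, 200L, 5200L, 5300L, 5400L),
    y = c(0L, 100L, 200L, 5200L, 5300L, 5400L))
  dp <- chain_anchors_banded(a, p)
  chains <- backtrack_chains(a, dp$f, dp$pred)
  expect_gte(length(chains), 2)
  # all anchors collinear and close: exactly one chain with the full path
  b <- data.table::data.table(x = (0:9) * 50L, y = (0:9) * 50L + 7L)
  dpb <- chain_anchors_banded(b, p)
  ch <- backtrack_chains(b, dpb$f, dpb$pred)
  expect_length(ch, 1)
  expect_identical(ch[[1]]$idx, 1:10)
  expect_identical(ch[[1]]$score, 9 * 20)
})

test_that("backtracked chains partition anchors and scores recompute exactly", {
  set.seed(61)
  for (rep in 1:20) {
    a <- random_anchors(80)
    dp <- chain_anchors_banded(a, banded = FALSE)
    chains <- backtrack_chains(a, dp$f, dp$pred)
    used <- unlist(lapply(chains, `[[`, "idx"))
    expect_identical(anyDuplicated(used), 0L)     # chains share no anchors
    for (ch in chains) {
      idx <- ch$idx
      # strictly increasing in both coordinates
      expect_true(all(diff(a$x[idx]) > 0) || length(idx) == 1)
      expect_true(all(diff(a$y[idx]) > 0) || length(idx) == 1)
      # score equals independent recomputation over consecutive pairs
      sc <- 0
      if (length(idx) > 1) for (t in 2:length(idx)) {
        sc <- sc + chain_score(a$x[idx[t]], a$y[idx[t]],
                               a$x[idx[t - 1]], a$y[idx[t - 1]])
      }
      expect_equal(ch$score, sc)
    }
  }
})

test_that("chaining is deterministic, including under exact score ties", {
  # two equal-score predecessors for the third anchor: earliest j must win
  # (0,10) and (10,0) both score 10 into (20,20)
  a <- data.table::data.table(x = c(0L, 10L, 20L), y = c(10L, 0L, 20L))
  data.table::setorder(a, x, y)
  dp1 <- chain_anchors_banded(a, banded = FALSE)
  dp2 <- chain_anchors_banded(a, banded = FALSE)
  expect_identical(dp1, dp2)
  expect_identical(dp1$pred[3], 1L)

  set.seed(71)
  a2 <- random_anchors(150)
  r1 <- backtrack_chains(a2, chain_anchors_banded(a2)$f,
                         chain_anchors_banded(a2)$pred)
  r2 <- backtrack_chains(a2, chain_anchors_banded(a2)$f,
                         chain_anchors_banded(a2)$pred)
  expect_identical(r1, r2)
})
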