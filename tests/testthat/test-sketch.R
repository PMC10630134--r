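test_that("canonical hashing is reverse-complement symmetric with opposite strands", {
  h <- canonical_kmer_hash(c("AAAAAAAAAAAAAAA", "TTTTTTTTTTTTTTT"))
  expect_identical(h$hash[1], h$hash[2])
  expect_false(h$strand[1] == h$strand[2])

  set.seed(42)
  for (i in 1:20) {
    km <- random_genome(15, seed = i)
    h2 <- canonical_kmer_hash(c(km, revcomp(km)))
    expect_identical(h2$hash[1], h2$hash[2])
  }
})

test_that("hashing is a bijection on canonical k-mer classes (all 4^7 7-mers)", {
  b <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(b, b, b, b, b, b, b,
                                       stringsAsFactors = FALSE))
  expect_length(kmers, 4^7)
  h <- canonical_kmer_hash(kmers)
  # odd k: no palindromes, so exactly 4^7/2 canonical classes
  expect_identical(length(unique(h$hash)), as.integer(4^7 / 2))
  # collisions occur only between a k-mer and its reverse complement
  split_by_hash <- split(kmers, h$hash)
  same_class <- vapply(split_by_hash, function(g) {
    length(g) == 2 && g[2] == revcomp(g[1])
  }, TRUE)
  expect_true(all(same_class))
})

test_that("ambiguous k-mers signal NA", {
  h <- canonical_kmer_hash(c("ACGTNACGTACGTAC", "acgtacgtacgtacg"))
  expect_true(is.na(h$hash[1]))
  expect_true(is.na(h$hash[2]))  # lowercase is not uppercased at this layer
})

test_that("FracMinHash selection: rate 1 selects all; density matches binomial oracle", {
  h <- canonical_kmer_hash(vapply(1:200, function(i)
    random_genome(15, seed = i), ""))$hash
  expect_true(all(fracminhash_select(h, 1)))

  # mean selected fraction over 50 random 500-kb genomes within 3 SE of 1/c
  p <- sketch_params()
  n_windows <- 500000 - p$k + 1
  fracs <- vapply(1:50, function(i) {
    sk <- sketch_genome(c(ctg = random_genome(500000, seed = 1000 + i)), p)
    nrow(sk$seeds) / n_windows
  }, 0)
  se <- sqrt((1 / p$c) * (1 - 1 / p$c) / (n_windows * 50))
  expect_lt(abs(mean(fracs) - 1 / p$c), 3 * se)
})

test_that("sketching is deterministic and gzip-transparent", {
  g <- random_genome(40000, seed = 5)
  p <- sketch_params()
  s1 <- sketch_genome(c(ctg = g), p, genome_id = "x")
  s2 <- sketch_genome(c(ctg = g), p, genome_id = "x")
  expect_equal(s1$seeds, s2$seeds)
  expect_identical(s1$markers, s2$markers)

  plain <- tempfile(fileext = ".fa"); gz <- tempfile(fileext = ".fa.gz")
  write_fasta(c(ctg = g), plain)
  write_fasta(c(ctg = g), gz)
  sp <- sketch_genome(plain, p); sg <- sketch_genome(gz, p)
  expect_equal(sp$seeds, sg$seeds)
  expect_identical(sp$markers, sg$markers)
})

test_that("degenerate inputs: short contigs, empty files, all-N sequence", {
  p <- sketch_params()
  short <- sketch_genome(c(ctg = random_genome(p$k - 1, seed = 1)), p)
  expect_identical(nrow(short$seeds), 0L)
  expect_length(short$markers, 0)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(sketch_genome(empty, p), "no sequence|cannot read")

  expect_warning(
    ns <- sketch_genome(c(ctg = strrep("N", 5000)), p),
    "no valid"
  )
  expect_identical(nrow(ns$seeds), 0L)
})

test_that("repetitive-seed masking follows the 2500/c rule", {
  p <- sketch_params()  # c = 125 -> threshold 20
  expect_identical(p$mask_threshold, 20L)
  expect_identical(sketch_params(c = 30)$mask_threshold, 83L)

  mk <- function(h, times) data.table::data.table(
    hash = rep(h, times), contig = 1L, pos = seq_len(times) * 50L,
    strand = 0L)
  seeds <- data.table::rbindlist(list(mk("aa", 21), mk("bb", 20), mk("cc", 3)))
  masked <- mask_repetitive_seeds(seeds, p)
  expect_false("aa" %in% masked$hash)   # 21 > 20: removed entirely
  expect_identical(sum(masked$hash == "bb"), 20L)
  expect_identical(sum(masked$hash == "cc"), 3L)

  # identity when nothing exceeds the threshold
  below <- data.table::rbindlist(list(mk("bb", 20), mk("cc", 3)))
  expect_equal(mask_repetitive_seeds(below, p), below)

  # monotonicity: lowering the threshold never increases surviving positions
  g <- random_genome(50000, seed = 9)
  sk <- sketch_genome(c(ctg = g), tiny_params())
  sizes <- vapply(c(20L, 10L, 5L, 2L, 1L), function(th) {
    nrow(mask_repetitive_seeds(sk$seeds, tiny_params(mask_threshold = th)))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("sketch of the reverse-complemented genome has the same hash key set", {
  g <- random_genome(30000, seed = 11)
  p <- tiny_params()
  s1 <- sketch_genome(c(ctg = g), p)
  s2 <- sketch_genome(c(ctg = revcomp(g)), p)
  expect_setequal(unique(s1$seeds$hash), unique(s2$seeds$hash))
  expect_identical(s1$markers, s2$markers)
})

test_that("sketch files round-trip bit-exactly and reject corruption", {
  g <- random_genome(30000, seed = 13)
  sk <- sketch_genome(c(ctg = g), sketch_params(), genome_id = "g")
  path <- tempfile(fileext = ".ske")
  write_sketch(sk, path)
  back <- read_sketch(path)
  expect_equal(back, sk)
  expect_equal(back$seeds, sk$seeds)
  expect_identical(back$markers, sk$markers)

  bad <- tempfile(fileext = ".ske")
  writeLines("not a sketch", bad)
  expect_error(read_sketch(bad), "corrupted|not a chainani")
  saveRDS(list(magic = "something-else"), bad)
  expect_error(read_sketch(bad), "not a chainani sketch")
})

test_that("marker count on a 1-Mb genome matches the binomial oracle", {
  p <- sketch_params()
  sk <- sketch_genome(c(ctg = random_genome(1e6, seed = 17)), p)
  n_windows <- 1e6 - p$marker_k + 1
  expected <- n_windows / p$marker_c
  sd5 <- 5 * sqrt(n_windows * (1 / p$marker_c) * (1 - 1 / p$marker_c))
  expect_lt(abs(length(sk$markers) - expected), sd5)
})
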