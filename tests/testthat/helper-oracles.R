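# Independent oracles and tiny fixture builders, used across test files.

# Exhaustive O(N^2) chaining DP, written directly from the recurrence
# f(i) = max(max_{j<i} f(j) + 20 - |(y_i-y_j)-(x_i-x_j)|, 0) over strict
# predecessors; ties in the argmax go to the smallest j; pred = 0 when
# f(i) = 0. Vectorized over j but otherwise naive.
dp_oracle <- function(x, y) {
  n <- length(x)
  f <- numeric(n); pred <- integer(n)
  for (i in seq_len(n)) {
    js <- which(x[seq_len(i - 1)] < x[i] & y[seq_len(i - 1)] < y[i])
    if (length(js)) {
      s <- f[js] + 20 - abs((y[i] - y[js]) - (x[i] - x[js]))
      b <- which.max(s)  # first maximum = smallest j
      if (s[b] > 0) { f[i] <- s[b]; pred[i] <- js[b]; next }
    }
    f[i] <- 0; pred[i] <- 0L
  }
  list(f = f, pred = pred)
}

# random sorted anchor instance for DP tests
random_anchors <- function(n, range = 2000L) {
  m <- unique(data.frame(x = sample.int(range, n, replace = TRUE),
                         y = sample.int(range, n, replace = TRUE)))
  m <- m[order(m$x, m$y), ]
  rownames(m) <- NULL
  m
}

# exact forward k-mer set of a genome's contigs (substring based, no hashing)
kmer_set <- function(records, k) {
  unique(unlist(lapply(records, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE))
}

# Mash-style Jaccard ANI baseline: j = |A∩B|/|A∪B|, ANI = (2j/(1+j))^(1/k)
jaccard_ani <- function(records_a, records_b, k = 21) {
  A <- kmer_set(records_a, k); B <- kmer_set(records_b, k)
  i <- length(intersect(A, B))
  j <- i / (length(A) + length(B) - i)
  (2 * j / (1 + j))^(1 / k)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# denser parameters for small test genomes (keeps invariants k < l, c < c_m)
tiny_params <- function(c = 20, marker_c = 100, k = 13L, marker_k = 17L, ...) {
  sketch_params(k = k, c = c, marker_k = marker_k, marker_c = marker_c, ...)
}

# simulated mutated pair of sketches with single-contig genomes
sketch_pair <- function(length, theta, seed, params = sketch_params(),
                        ids = c("a", "b")) {
  g <- random_genome(length, seed = seed)
  m <- mutate_genome(g, theta, seed = seed + 1L)
  list(a = sketch_genome(c(ctg = g), params, genome_id = ids[1]),
       b = sketch_genome(c(ctg = m$sequence), params, genome_id = ids[2]),
       realized = m$realized_mismatches, original = g,
       mutated = m$sequence)
}
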