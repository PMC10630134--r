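#' Collect anchors between a query chunk and a reference
#'
#' An anchor is an exact seed match: a (query position, reference position)
#' pair whose canonical k-mer hashes agree. One anchor is produced per
#' (chunk seed, reference occurrence) pair; masked reference hashes are
#' absent from the reference seed table and so produce no anchors. The
#' relative strand of an anchor is the XOR of the two seeds' strand flags.
#'
#' @param chunk_seeds data.table with columns `pos` (0-based, chunk-relative),
#'   `hash`, `strand` for the query chunk, sorted by `pos`.
#' @param ref_seeds data.table with columns `hash`, `contig`, `pos`, `strand`
#'   (a sketch's `seeds` table), keyed by `hash`.
#' @param params A [sketch_params()] object (unused fields reserved).
#' @return data.table with columns `x` (query), `y` (reference), `ref_contig`,
#'   `strand` (0 same-strand, 1 opposite), sorted lexicographically by
#'   `(x, y)`.
#' @export
collect_anchors <- function(chunk_seeds, ref_seeds, params = sketch_params()) {
  if (nrow(chunk_seeds) == 0 || nrow(ref_seeds) == 0) {
    return(data.table(x = integer(), y = integer(), ref_contig = integer(),
                      strand = integer()))
  }
  q <- data.table(hash = chunk_seeds$hash, x = chunk_seeds$pos,
                  qstrand = chunk_seeds$strand)
  hits <- ref_seeds[q, nomatch = NULL, on = "hash", allow.cartesian = TRUE]
  if (nrow(hits) == 0) {
    return(data.table(x = integer(), y = integer(), ref_contig = integer(),
                      strand = integer()))
  }
  out <- data.table(x = hits$x, y = hits$pos, ref_contig = hits$contig,
                    strand = as.integer(xor(hits$qstrand == 1L,
                                            hits$strand == 1L)))
  setorder(out, x, y)
  out
}

#' Chaining score between two anchors
#'
#' `S(i, j) = 20 - |(y_j - y_i) - (x_j - x_i)|`: a fixed match bonus minus the
#' absolute diagonal drift between the anchors. Overlapping k-mers are
#' deliberately not penalized — every seed arising from homology should stay
#' in the chain, because the chain's anchor count is the identity statistic.
#'
#' @param x_i,y_i,x_j,y_j Anchor coordinates (the `j` anchor precedes `i`).
#' @return Numeric score (can be negative for large drift).
#' @export
#' @examples
#' chain_score(100, 100, 50, 50)   # collinear: 20
#' chain_score(100, 105, 50, 50)   # offset 5: 15
chain_score <- function(x_i, y_i, x_j, y_j) {
  20 - abs((y_i - y_j) - (x_i - x_j))
}

#' Banded chaining dynamic program
#'
#' Computes, for anchors sorted lexicographically by `(x, y)`, the optimal
#' chain score ending at each anchor:
#' `f(i) = max(max_j f(j) + S(i, j), 0)` over strict predecessors
#' (`x_j < x_i` and `y_j < y_i`). The band scans at most `band_a` previous
#' anchors and stops early once the query gap `x_i - x_j` exceeds `band_b`,
#' giving `O(band_a * N)` worst-case work. Ties in the argmax go to the
#' earliest anchor; `pred` is 0 whenever `f(i) = 0`.
#'
#' Anchors must all belong to one (reference contig, strand) group; for
#' reverse-strand groups pass mirrored reference coordinates
#' (`y' = contig_length - k - y`) so the same increasing-order DP applies.
#'
#' @param anchors data.table (or data.frame) with integer columns `x`, `y`,
#'   sorted lexicographically by `(x, y)`.
#' @param params A [sketch_params()] object supplying `band_a` and `band_b`.
#' @param banded If `FALSE`, disable the band (scan all predecessors); used
#'   for oracle comparisons.
#' @return List with numeric `f` and integer `pred` (1-based; 0 = none).
#' @export
chain_anchors_banded <- function(anchors, params = sketch_params(),
                                 banded = TRUE) {
  n <- nrow(anchors)
  if (n == 0) return(list(f = numeric(), pred = integer()))
  a <- if (banded) params$band_a else n
  b <- if (banded) as.double(params$band_b) else Inf
  .chain_dp_cpp(as.integer(anchors$x), as.integer(anchors$y), as.integer(a), b)
}

#' Backtrack disjoint optimal chains
#'
#' Partitions the anchors into disjoint sets with a union–find structure,
#' uniting each anchor with its optimal predecessor; within each set the
#' anchor with maximal `f` is backtracked through the predecessor pointers to
#' yield one chain. Chains from different sets share no anchors; an anchor of
#' a set that the winning backtrack path skips is *not* emitted as an extra
#' chain.
#'
#' @param anchors data.table with columns `x`, `y` (sorted as for the DP).
#' @param f,pred Output of [chain_anchors_banded()].
#' @return List of chains; each chain is a list with `idx` (anchor row
#'   indices, in chain order) and `score` (`f` at the terminal anchor).
#' @export
backtrack_chains <- function(anchors, f, pred) {
  n <- nrow(anchors)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    if (pred[i] > 0L) {
      ri <- find(i); rj <- find(pred[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  chains <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    best <- members[which.max(f[members])]  # which.max -> smallest index on ties
    path <- integer()
    i <- best
    while (i > 0L) {
      path <- c(path, i)
      i <- pred[i]
    }
    chains[[length(chains) + 1L]] <- list(idx = rev(path), score = f[best])
  }
  chains
}

# Chain one (ref_contig, strand) anchor group of a chunk. `grp` has columns
# x, y (original reference coordinates). Returns a list of chain records:
# anchor x positions, original-y span, anchor count, score.
chain_anchor_group <- function(grp, contig_len, params, strand) {
  k <- params$k
  ych <- if (strand == 1L) contig_len - k - grp$y else grp$y
  dt <- data.table(x = grp$x, y = ych, y_orig = grp$y)
  setorder(dt, x, y)
  dp <- chain_anchors_banded(dt, params)
  chains <- backtrack_chains(dt, dp$f, dp$pred)
  lapply(chains, function(ch) {
    xs <- dt$x[ch$idx]
    yo <- dt$y_orig[ch$idx]
    list(anchors_x = xs, anchors_y = yo,
         q_first = min(xs), q_last = max(xs),
         r_first = min(yo), r_last = max(yo),
         n_anchors = length(ch$idx), score = ch$score)
  })
}
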