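#' Choose reference and query roles for a genome pair
#'
#' The genome with the larger score, total sequence length times mean contig
#' length, becomes the reference; the other is fragmented into chunks. The
#' rule favors the more contiguous assembly as reference and, because it
#' depends only on the two sketches, makes the whole comparison symmetric in
#' argument order. Ties break toward the lexicographically smaller
#' `genome_id`.
#'
#' @param sketch_a,sketch_b `genome_sketch` objects.
#' @return List with elements `reference` and `query`.
#' @export
select_reference <- function(sketch_a, sketch_b) {
  score <- function(s) s$total_length * mean(s$contig_lengths)
  sa <- score(sketch_a); sb <- score(sketch_b)
  a_is_ref <- if (sa != sb) sa > sb else {
    if (sketch_a$genome_id != sketch_b$genome_id)
      sketch_a$genome_id < sketch_b$genome_id
    else TRUE
  }
  if (a_is_ref) list(reference = sketch_a, query = sketch_b)
  else          list(reference = sketch_b, query = sketch_a)
}

#' Fragment a query sketch into nonoverlapping chunks
#'
#' Each contig is split into consecutive `[i*chunk_size, (i+1)*chunk_size)`
#' windows (0-based, half-open); the trailing partial window is kept as its
#' own chunk so fragmented assemblies lose no sequence. Seed positions are
#' re-expressed relative to their chunk start.
#'
#' @param query_sketch A `genome_sketch`.
#' @param params A [sketch_params()] object.
#' @return List with `chunks` (data.table: `chunk_id`, `contig`, `start`,
#'   `end`) and `seeds` (data.table: `chunk_id`, `x`, `hash`, `strand`).
#' @export
fragment_query <- function(query_sketch, params = sketch_params()) {
  cs <- params$chunk_size
  lens <- query_sketch$contig_lengths
  per_contig <- pmax(1L, as.integer(ceiling(lens / cs)))
  offset <- c(0L, cumsum(per_contig))  # chunk_id offset per contig
  chunk_list <- lapply(seq_along(lens), function(i) {
    n <- per_contig[i]
    start <- (seq_len(n) - 1L) * cs
    data.table(chunk_id = offset[i] + seq_len(n), contig = i,
               start = start, end = pmin(start + cs, lens[i]))
  })
  chunks <- rbindlist(chunk_list)
  sd <- query_sketch$seeds
  if (nrow(sd) > 0) {
    seeds <- data.table(
      chunk_id = offset[sd$contig] + sd$pos %/% cs + 1L,
      x = sd$pos %% cs, hash = sd$hash, strand = sd$strand)
    setorder(seeds, chunk_id, x)
  } else {
    seeds <- data.table(chunk_id = integer(), x = integer(),
                        hash = character(), strand = integer())
  }
  list(chunks = chunks, seeds = seeds)
}

# ---- interval bookkeeping for the greedy orthology filter ----

# intervals: 2-column matrix (start, end), half-open, disjoint, sorted
interval_overlap <- function(intervals, s, e) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  sum(pmax(0, pmin(intervals[, 2], e) - pmax(intervals[, 1], s)))
}

interval_union_add <- function(intervals, s, e) {
  m <- rbind(intervals, c(s, e))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    last <- nrow(out)
    if (m[i, 1] <= out[last, 2]) out[last, 2] <- max(out[last, 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

#' Greedy selection of orthologous chains
#'
#' Homologous chains from all chunks are visited in decreasing score order
#' (deterministic tie-break); a chain is selected iff it has at least
#' `min_chain_anchors` anchors and its reference-coordinate span overlaps the
#' union of already-selected spans by less than `overlap_frac` of its own
#' span length. This suppresses one-to-many paralog mappings, leaving a
#' minimally overlapping ("orthologous") set.
#'
#' @param chains data.table of homologous chains with columns `chunk_id`,
#'   `ref_contig`, `strand`, `score`, `n_anchors`, `q_first`, `q_last`
#'   (chunk-relative), `r_first`, `r_last` (reference coordinates).
#' @param params A [sketch_params()] object.
#' @return The selected subset (same columns), in selection order.
#' @export
select_orthologous_chains <- function(chains, params = sketch_params()) {
  if (nrow(chains) == 0) return(chains)
  cand <- chains[n_anchors >= params$min_chain_anchors]
  if (nrow(cand) == 0) return(cand)
  setorder(cand, -score, chunk_id, ref_contig, strand, r_first)
  k <- params$k
  unions <- list()  # per ref_contig interval union
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ctg <- as.character(cand$ref_contig[i])
    s <- cand$r_first[i]; e <- cand$r_last[i] + k
    len <- e - s
    ov <- interval_overlap(unions[[ctg]], s, e)
    if (ov < params$overlap_frac * len) {
      keep[i] <- TRUE
      unions[[ctg]] <- interval_union_add(unions[[ctg]], s, e)
    }
  }
  cand[keep]
}

#' Per-chunk ANI estimate
#'
#' Base estimate `(alpha / M)^(1/k)`: under independent substitution each
#' seed k-mer survives as an exact match (anchor) with probability
#' `ANI^k`. When only part of a chunk is homologous (incompleteness,
#' structural variation), `M` overcounts; the flanked-seed variant
#' `ANI_LR = (alpha / M_LR)^(1/k)` restricts to seeds between the leftmost
#' and rightmost anchor, and is used instead when it exceeds `lr_ani_gate`
#' and the flanked span exceeds `lr_min_span` bases. The chunk's weight for
#' the final mean is `M`, or `M_LR` when the heuristic fires.
#'
#' @param stats List or one-row data.frame with `alpha` (anchors in
#'   orthologous chains on the chunk), `m` (seeds in chunk), `m_lr` (seeds
#'   between the flanking anchors), `span_lr` (bases between the flanking
#'   anchors, k-mer inclusive).
#' @param params A [sketch_params()] object.
#' @return List with `ani`, `weight`, `lr_used`. Chunks with `m = 0` are the
#'   caller's to skip.
#' @export
chunk_ani <- function(stats, params = sketch_params()) {
  alpha <- stats$alpha; m <- stats$m; m_lr <- stats$m_lr
  stopifnot(m > 0)
  k <- params$k
  base <- (min(alpha, m) / m)^(1 / k)
  if (alpha > 0 && !is.null(m_lr) && !is.na(m_lr) && m_lr > 0) {
    ani_lr <- (min(alpha, m_lr) / m_lr)^(1 / k)
    if (ani_lr > params$lr_ani_gate && stats$span_lr > params$lr_min_span) {
      return(list(ani = ani_lr, weight = m_lr, lr_used = TRUE))
    }
  }
  list(ani = base, weight = m, lr_used = FALSE)
}

#' Combine per-chunk ANI estimates
#'
#' Weighted mean with weights `M` (or `M_LR`), the number of seeds behind
#' each chunk's estimate.
#'
#' @param ani Numeric vector of per-chunk estimates.
#' @param weight Numeric vector of weights (sum must be positive).
#' @return The weighted-mean ANI.
#' @export
combine_ani <- function(ani, weight) {
  if (length(ani) == 0 || sum(weight) <= 0) {
    stop("no weighted chunks: no alignment")
  }
  weighted.mean(ani, weight)
}

#' Aligned fraction from selected chains
#'
#' Each chain covers `(last anchor - first anchor) + 2c` bases — the `2c`
#' term compensates for seeds near the chain edges missed by subsampling —
#' computed independently on query and reference coordinates. The per-genome
#' AF is the summed coverage divided by total genome length, capped at 1.
#'
#' @param selected data.table of orthologous chains carrying absolute query
#'   coordinates `q_first_abs`, `q_last_abs` and reference coordinates
#'   `r_first`, `r_last`.
#' @param query_sketch,ref_sketch The two `genome_sketch` objects.
#' @param params A [sketch_params()] object.
#' @return List with `af_query`, `af_ref`, `aligned_bases` (reference-side
#'   covered bases, uncapped).
#' @export
aligned_fraction <- function(selected, query_sketch, ref_sketch,
                             params = sketch_params()) {
  if (is.null(selected) || nrow(selected) == 0) {
    return(list(af_query = 0, af_ref = 0, aligned_bases = 0))
  }
  twoc <- 2 * params$c
  q_cov <- sum(selected$q_last_abs - selected$q_first_abs + twoc)
  r_cov <- sum(selected$r_last - selected$r_first + twoc)
  list(af_query = min(1, q_cov / query_sketch$total_length),
       af_ref = min(1, r_cov / ref_sketch$total_length),
       aligned_bases = r_cov)
}

# run expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  expr
}

#' Bootstrap confidence interval for the final ANI
#'
#' Resamples chunks with replacement (`bootstrap_iters` times, n = chunk
#' count), recomputes the weighted-mean ANI per resample, and returns the
#' 5th and 95th percentiles as a 90% interval. Produced only when there are
#' strictly more than `bootstrap_min_chunks` chunks. The interval reflects
#' seeding/sampling variance only, not systematic bias.
#'
#' @param chunk_estimates data.table or data.frame with columns `ani`,
#'   `weight` (one row per contributing chunk).
#' @param params A [sketch_params()] object.
#' @param rng_seed Integer seed; results are reproducible given the seed and
#'   global RNG state is untouched.
#' @return Numeric `c(low, high)` or `NULL` when too few chunks.
#' @export
bootstrap_ci <- function(chunk_estimates, params = sketch_params(),
                         rng_seed = 1L) {
  n <- nrow(chunk_estimates)
  if (n <= params$bootstrap_min_chunks) return(NULL)
  ani <- chunk_estimates$ani; w <- chunk_estimates$weight
  means <- with_seed(rng_seed, {
    vapply(seq_len(params$bootstrap_iters), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      weighted.mean(ani[idx], w[idx])
    }, 0)
  })
  unname(quantile(means, c(0.05, 0.95)))
}

#' Compare two genome sketches: ANI, AF, confidence interval
#'
#' Runs the full pipeline on a pair: marker screen, reference selection,
#' query chunking, anchoring, banded chaining, greedy orthology filtering,
#' per-chunk ANI with the flanked-seed heuristic, seed-weighted mean ANI,
#' aligned fractions, bootstrap CI and (optionally) learned debiasing. The
#' result is bit-identical under argument swap.
#'
#' @param sketch_a,sketch_b `genome_sketch` objects with identical parameter
#'   fingerprints.
#' @param params A [sketch_params()] object; defaults to `sketch_a`'s.
#' @param debias_model Optional `debias_model` (see [train_debias()]).
#' @param seed Integer RNG seed; affects only the bootstrap CI, never the
#'   ANI.
#' @param screen If `FALSE`, skip the marker screen.
#' @param force_debias Apply the debias model even when `params$c` is below
#'   the auto-enable threshold.
#' @return An object of class `ani_result` with fields `query_id`, `ref_id`,
#'   `ani` (fraction; `NA` when screened out or below the AF gate), `ani_raw`
#'   (pre-debias), `af_query`, `af_ref`, `ci90`, `n_chunks`, `putative_ani`,
#'   `aligned_bases`, `debiased`, `screen_pass`, `af_pass`,
#'   `chunk_estimates`, `features`.
#' @export
#' @examples
#' g <- random_genome(60000, seed = 7)
#' p <- sketch_params()
#' a <- sketch_genome(c(ctg = g), p, genome_id = "a")
#' b <- sketch_genome(c(ctg = mutate_genome(g, 0.02, seed = 8)$sequence),
#'                    p, genome_id = "b")
#' compare_pair(a, b)
compare_pair <- function(sketch_a, sketch_b, params = sketch_a$params,
                         debias_model = NULL, seed = 1L, screen = TRUE,
                         force_debias = FALSE) {
  check_fingerprints(sketch_a, sketch_b)
  if (!identical(params_fingerprint(params), sketch_a$fingerprint)) {
    stop("params do not match the sketches' parameter fingerprint")
  }

  scr <- if (screen) screen_pair(sketch_a, sketch_b, params)
         else list(pass = TRUE, putative_ani = NA_real_)
  roles <- select_reference(sketch_a, sketch_b)
  empty <- empty_result(roles, scr, params)
  if (!scr$pass) return(empty)

  ref <- roles$reference; qry <- roles$query
  frag <- fragment_query(qry, params)
  if (nrow(frag$seeds) == 0 || nrow(ref$seeds) == 0) return(empty)

  chains <- homologous_chains(frag, ref, params)
  if (nrow(chains) == 0) return(empty)
  selected <- select_orthologous_chains(chains, params)
  if (nrow(selected) == 0) return(empty)

  # absolute query coordinates for AF
  selected <- merge(selected, frag$chunks[, .(chunk_id, start, qcontig = contig)],
                    by = "chunk_id", sort = TRUE)
  selected[, `:=`(q_first_abs = start + q_first, q_last_abs = start + q_last)]

  est <- chunk_estimates(selected, frag$seeds, params)
  if (nrow(est) == 0 || sum(est$weight) <= 0) return(empty)
  ani_raw <- combine_ani(est$ani, est$weight)
  af <- aligned_fraction(selected, qry, ref, params)
  af_pass <- max(af$af_query, af$af_ref) >= params$af_threshold
  ci <- bootstrap_ci(est, params, rng_seed = seed)

  res <- structure(list(
    query_id = qry$genome_id, ref_id = ref$genome_id,
    ani = if (af_pass) ani_raw else NA_real_,
    ani_raw = ani_raw,
    af_query = af$af_query, af_ref = af$af_ref,
    ci90 = ci, n_chunks = nrow(est),
    putative_ani = scr$putative_ani,
    aligned_bases = af$aligned_bases,
    debiased = FALSE, screen_pass = TRUE, af_pass = af_pass,
    chunk_estimates = est,
    features = result_features(ani_raw, est, selected, qry, ref, params),
    query_name = qry$contig_names[1], ref_name = ref$contig_names[1],
    params = params
  ), class = "ani_result")

  if (!is.null(debias_model)) {
    res <- apply_debias(debias_model, res, params, force = force_debias)
  }
  res
}

empty_result <- function(roles, scr, params) {
  structure(list(
    query_id = roles$query$genome_id, ref_id = roles$reference$genome_id,
    ani = NA_real_, ani_raw = NA_real_, af_query = 0, af_ref = 0,
    ci90 = NULL, n_chunks = 0L, putative_ani = scr$putative_ani,
    aligned_bases = 0, debiased = FALSE, screen_pass = scr$pass,
    af_pass = FALSE, chunk_estimates = NULL, features = NULL,
    query_name = roles$query$contig_names[1],
    ref_name = roles$reference$contig_names[1],
    params = params
  ), class = "ani_result")
}

# anchor + chain every chunk of the fragmented query against the reference
homologous_chains <- function(frag, ref, params) {
  qseeds <- frag$seeds
  hits <- ref$seeds[qseeds, nomatch = NULL, on = "hash",
                    allow.cartesian = TRUE]
  if (nrow(hits) == 0) {
    return(data.table(chunk_id = integer(), ref_contig = integer(),
                      strand = integer(), score = numeric(),
                      n_anchors = integer(), q_first = integer(),
                      q_last = integer(), r_first = integer(),
                      r_last = integer()))
  }
  anchors <- data.table(chunk_id = hits$chunk_id, x = hits$x, y = hits$pos,
                        ref_contig = hits$contig,
                        strand = as.integer(xor(hits$i.strand == 1L,
                                                hits$strand == 1L)))
  setorder(anchors, chunk_id, ref_contig, strand, x, y)
  groups <- split(anchors,
                  by = c("chunk_id", "ref_contig", "strand"), sorted = TRUE)
  recs <- vector("list", 0L)
  for (grp in groups) {
    ctg_len <- ref$contig_lengths[grp$ref_contig[1]]
    chs <- chain_anchor_group(grp, ctg_len, params, grp$strand[1])
    for (ch in chs) {
      recs[[length(recs) + 1L]] <- data.table(
        chunk_id = grp$chunk_id[1], ref_contig = grp$ref_contig[1],
        strand = grp$strand[1], score = ch$score, n_anchors = ch$n_anchors,
        q_first = ch$q_first, q_last = ch$q_last,
        r_first = ch$r_first, r_last = ch$r_last)
    }
  }
  rbindlist(recs)
}

# per-chunk sufficient statistics + estimates from the selected chains
chunk_estimates <- function(selected, chunk_seeds, params) {
  by_chunk <- selected[, .(alpha = sum(n_anchors), flank_lo = min(q_first),
                           flank_hi = max(q_last)), by = chunk_id]
  m_all <- chunk_seeds[, .(m = .N), by = chunk_id]
  st <- merge(by_chunk, m_all, by = "chunk_id", sort = TRUE)
  st <- st[m > 0]
  if (nrow(st) == 0) return(data.table(chunk_id = integer(), ani = numeric(),
                                       weight = numeric(), lr_used = logical()))
  xs <- split(chunk_seeds$x, chunk_seeds$chunk_id)
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    x <- xs[[as.character(st$chunk_id[i])]]
    m_lr <- sum(x >= st$flank_lo[i] & x <= st$flank_hi[i])
    est <- chunk_ani(list(alpha = st$alpha[i], m = st$m[i], m_lr = m_lr,
                          span_lr = st$flank_hi[i] - st$flank_lo[i] + params$k),
                     params)
    out[[i]] <- data.table(chunk_id = st$chunk_id[i], ani = est$ani,
                           weight = est$weight, lr_used = est$lr_used)
  }
  rbindlist(out)
}

# five debias features, computed at compare time
result_features <- function(ani_raw, est, selected, qry, ref, params) {
  k <- params$k
  list(
    ani = ani_raw,
    chunk_ani_sd = if (nrow(est) >= 2) sd(est$ani) else 0,
    ref_p90_contig_len = unname(quantile(ref$contig_lengths, 0.9)),
    query_p90_contig_len = unname(quantile(qry$contig_lengths, 0.9)),
    mean_chain_len = mean(selected$r_last - selected$r_first + k)
  )
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI comparison: query '%s' vs reference '%s'\n",
              x$query_id, x$ref_id))
  if (!x$screen_pass) {
    cat(sprintf("  screened out (putative ANI %.2f%% <= %.0f%%)\n",
                100 * x$putative_ani,
                100 * x$params$marker_ani_threshold))
    return(invisible(x))
  }
  if (is.na(x$ani)) {
    cat("  no ANI reported")
    if (!x$af_pass) cat(sprintf(" (aligned fraction below %.0f%% gate)",
                                100 * x$params$af_threshold))
    cat("\n")
  } else {
    cat(sprintf("  ANI: %.2f%%%s\n", 100 * x$ani,
                if (x$debiased) " (debiased)" else ""))
    if (!is.null(x$ci90))
      cat(sprintf("  90%% CI: [%.2f%%, %.2f%%] (%d chunks)\n",
                  100 * x$ci90[1], 100 * x$ci90[2], x$n_chunks))
  }
  cat(sprintf("  AF query: %.2f%%  AF reference: %.2f%%\n",
              100 * x$af_query, 100 * x$af_ref))
  invisible(x)
}

#' Tabulate comparison results
#'
#' Formats a list of [compare_pair()] results as the tab-separated record the
#' command-line interface emits: `Ref_file`, `Query_file`, `ANI`,
#' `Align_fraction_ref`, `Align_fraction_query`, `Ref_name`, `Query_name`
#' (ANI and AF as percentages with 2 decimals), plus `CI_5`/`CI_95` when
#' `ci = TRUE`. Results without a reportable ANI (screen failure or AF gate)
#' are dropped. Rows are sorted by (query, reference) so output never depends
#' on scheduling.
#'
#' @param results List of `ani_result` objects.
#' @param ci Include bootstrap CI columns.
#' @return A `data.frame` (possibly 0-row).
#' @export
results_table <- function(results, ci = FALSE) {
  keep <- Filter(function(r) r$screen_pass && r$af_pass && !is.na(r$ani),
                 results)
  rows <- lapply(keep, function(r) {
    row <- data.frame(
      Ref_file = r$ref_id, Query_file = r$query_id,
      ANI = sprintf("%.2f", 100 * r$ani),
      Align_fraction_ref = sprintf("%.2f", 100 * r$af_ref),
      Align_fraction_query = sprintf("%.2f", 100 * r$af_query),
      Ref_name = r$ref_name, Query_name = r$query_name,
      stringsAsFactors = FALSE)
    if (ci) {
      row$CI_5 <- if (is.null(r$ci90)) "NA" else sprintf("%.2f", 100 * r$ci90[1])
      row$CI_95 <- if (is.null(r$ci90)) "NA" else sprintf("%.2f", 100 * r$ci90[2])
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c("Ref_file", "Query_file", "ANI", "Align_fraction_ref",
              "Align_fraction_query", "Ref_name", "Query_name",
              if (ci) c("CI_5", "CI_95"))
    as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  out[order(out$Query_file, out$Ref_file), , drop = FALSE]
}
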