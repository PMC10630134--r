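#' Sketching and comparison parameters
#'
#' Bundles every tunable of the pipeline. All comparisons are parameterized by
#' exactly one `sketch_params` object, and sketches made under different
#' sketching parameters refuse to be compared (fingerprint check).
#'
#' @param k Seed k-mer length (bases). Seeds are the dense k-mer set used for
#'   anchoring and chaining.
#' @param c Seed subsampling rate: an expected `1/c` fraction of k-mers is
#'   selected by FracMinHash. Runtime and sketch size scale as `1/c`.
#'   Presets: 30 (slow, most accurate AF, N50 ~ 3 kb), 70 (medium),
#'   125 (default), 200 (fast, >95% ANI genomes).
#' @param marker_k Marker ℓ-mer length (bases); markers are the very sparse
#'   set used only for the max-containment ANI screen.
#' @param marker_c Marker subsampling rate (`c_m`), must exceed `c`.
#' @param chunk_size Query fragment length in bases; ANI is estimated per
#'   chunk and averaged.
#' @param band_b Chaining band: maximum anchor gap on the query in bases.
#' @param band_a Maximum number of predecessors scanned in the chaining DP;
#'   default `max(1, band_b %/% c)`.
#' @param mask_threshold Seeds occurring more than this many times in a genome
#'   are masked; default `max(1, band_b %/% c)` (20 at defaults).
#' @param marker_ani_threshold Screen gate: pairs proceed only if the
#'   marker-based putative ANI exceeds this (strict `>`).
#' @param af_threshold Minimum aligned fraction (either genome) for an ANI to
#'   be reported.
#' @param lr_ani_gate,lr_min_span Gates for the flanked-seed (`M_LR`) per-chunk
#'   heuristic: the truncated estimate is used only when it exceeds
#'   `lr_ani_gate` and the flanked span exceeds `lr_min_span` bases
#'   (default `4*c`).
#' @param min_chain_anchors Minimum anchors for a chain to be eligible as
#'   orthologous.
#' @param overlap_frac Maximum reference-span overlap (fraction of the
#'   candidate chain's span) with already-selected chains.
#' @param bootstrap_iters,bootstrap_min_chunks Bootstrap resamples for the 90%
#'   CI, and the minimum chunk count (strict `>`) for a CI to be produced.
#' @param debias_ani_gate,debias_min_aligned,debias_auto_c Debiasing is applied
#'   only above this ANI, above this many aligned bases, and (by default) only
#'   when `c >= debias_auto_c`.
#'
#' @return An object of class `sketch_params` (a validated list).
#' @export
#' @examples
#' p <- sketch_params()
#' p$band_a  # 2500 %/% 125 = 20
sketch_params <- function(k = 15L, c = 125, marker_k = 21L, marker_c = 1000,
                          chunk_size = 20000L, band_b = 2500,
                          band_a = NULL, mask_threshold = NULL,
                          marker_ani_threshold = 0.80, af_threshold = 0.15,
                          lr_ani_gate = 0.950, lr_min_span = NULL,
                          min_chain_anchors = 3L, overlap_frac = 0.50,
                          bootstrap_iters = 100L, bootstrap_min_chunks = 10L,
                          debias_ani_gate = 0.90, debias_min_aligned = 150000,
                          debias_auto_c = 70) {
  k <- as.integer(k); marker_k <- as.integer(marker_k)
  if (is.null(band_a)) band_a <- max(1L, as.integer(band_b %/% c))
  if (is.null(mask_threshold)) mask_threshold <- max(1L, as.integer(band_b %/% c))
  if (is.null(lr_min_span)) lr_min_span <- 4 * c
  p <- list(
    k = k, c = c, marker_k = marker_k, marker_c = marker_c,
    chunk_size = as.integer(chunk_size), band_b = band_b,
    band_a = as.integer(band_a), mask_threshold = as.integer(mask_threshold),
    marker_ani_threshold = marker_ani_threshold, af_threshold = af_threshold,
    lr_ani_gate = lr_ani_gate, lr_min_span = lr_min_span,
    min_chain_anchors = as.integer(min_chain_anchors),
    overlap_frac = overlap_frac,
    bootstrap_iters = as.integer(bootstrap_iters),
    bootstrap_min_chunks = as.integer(bootstrap_min_chunks),
    debias_ani_gate = debias_ani_gate,
    debias_min_aligned = debias_min_aligned,
    debias_auto_c = debias_auto_c
  )
  validate_sketch_params(p)
  structure(p, class = "sketch_params")
}

validate_sketch_params <- function(p) {
  stopifnot(
    p$k >= 1L, p$k <= 31L, p$marker_k >= 1L, p$marker_k <= 31L,
    p$k < p$marker_k,
    p$c >= 1, p$marker_c >= 1, p$c < p$marker_c,
    p$chunk_size > 2L * p$k,
    p$band_a >= 1L, p$mask_threshold >= 1L,
    p$marker_ani_threshold > 0, p$marker_ani_threshold < 1,
    p$af_threshold > 0, p$af_threshold < 1,
    p$lr_ani_gate > 0, p$lr_ani_gate < 1,
    p$overlap_frac > 0, p$overlap_frac < 1,
    p$bootstrap_iters >= 1L, p$bootstrap_min_chunks >= 0L
  )
  invisible(p)
}

#' @export
print.sketch_params <- function(x, ...) {
  cat("Sketch/comparison parameters:\n")
  cat(sprintf("  seeds:   k = %d, c = %g (mask > %d occurrences)\n",
              x$k, x$c, x$mask_threshold))
  cat(sprintf("  markers: l = %d, c_m = %g, screen ANI > %.2f\n",
              x$marker_k, x$marker_c, x$marker_ani_threshold))
  cat(sprintf("  chunks:  %d bp; chain band A = %d, B = %g\n",
              x$chunk_size, x$band_a, x$band_b))
  cat(sprintf("  gates:   AF >= %.2f; LR heuristic > %.3f ANI, > %g bp span\n",
              x$af_threshold, x$lr_ani_gate, x$lr_min_span))
  invisible(x)
}

#' Preset parameter sets for the seed sampling rate
#'
#' Maps the named presets to `c` values 30 (slow), 70 (medium), 200 (fast);
#' `default` is `c = 125`.
#'
#' @param preset One of `"slow"`, `"medium"`, `"fast"`, `"default"`.
#' @param ... Further overrides passed to [sketch_params()].
#' @return A `sketch_params` object.
#' @export
preset_params <- function(preset = c("default", "slow", "medium", "fast"), ...) {
  preset <- match.arg(preset)
  cval <- switch(preset, slow = 30, medium = 70, fast = 200, default = 125)
  args <- list(...)
  if (is.null(args$c)) args$c <- cval  # explicit c overrides the preset
  do.call(sketch_params, args)
}

# Digest over the fields that determine sketch content. Two sketches compare
# only if these agree.
params_fingerprint <- function(p) {
  digest::digest(list(format = 1L, k = p$k, c = p$c, marker_k = p$marker_k,
                      marker_c = p$marker_c,
                      mask_threshold = p$mask_threshold),
                 algo = "xxhash64")
}
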