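#' Max-containment index of two marker sets
#'
#' `|A ∩ B| / min(|A|, |B|)`. Normalizing by the smaller set makes the index
#' robust to one-sided incompleteness: if one assembly is a subset of the
#' other, the index stays near 1 where Jaccard would drop.
#'
#' @param markers_a,markers_b Character vectors of marker hashes.
#' @return Fraction in `[0, 1]`, or `NA` with a warning if either set is
#'   empty (unscreenable genome).
#' @export
max_containment <- function(markers_a, markers_b) {
  na <- length(unique(markers_a)); nb <- length(unique(markers_b))
  if (na == 0 || nb == 0) {
    warning("empty marker set: genome cannot be screened")
    return(NA_real_)
  }
  length(intersect(markers_a, markers_b)) / min(na, nb)
}

#' Marker-based putative ANI from a containment index
#'
#' `ANI_FMH = containment^(1/l)`: under the independent-substitution model an
#' ℓ-mer survives unmutated with probability `(1 - theta)^l`, so the
#' containment of the marker sets estimates `(ANI)^l`.
#'
#' @param containment Fraction in `[0, 1]`.
#' @param l Marker length in bases.
#' @return ANI estimate in `[0, 1]` (`NA` propagates).
#' @export
#' @examples
#' ani_fmh(0.5, 21)  # 0.96753...
ani_fmh <- function(containment, l) {
  stopifnot(l >= 1)
  if (is.na(containment)) return(NA_real_)
  stopifnot(containment >= 0, containment <= 1)
  containment^(1 / l)
}

#' Screen a genome pair by marker max-containment
#'
#' Computes the putative ANI from the two sketches' marker sets and compares
#' it against the screen threshold (strict `>`). Pairs with an unscreenable
#' genome (no markers) pass with a warning so that the comparison can still
#' proceed.
#'
#' @param sketch_a,sketch_b `genome_sketch` objects with matching parameter
#'   fingerprints.
#' @param params A [sketch_params()] object.
#' @return List with `pass` (logical) and `putative_ani` (fraction, `NA` if
#'   unscreenable).
#' @export
screen_pair <- function(sketch_a, sketch_b, params = sketch_params()) {
  check_fingerprints(sketch_a, sketch_b)
  cont <- max_containment(sketch_a$markers, sketch_b$markers)
  pa <- ani_fmh(cont, params$marker_k)
  if (is.na(pa)) {
    return(list(pass = TRUE, putative_ani = NA_real_))
  }
  list(pass = pa > params$marker_ani_threshold, putative_ani = pa)
}

check_fingerprints <- function(a, b) {
  if (!identical(a$fingerprint, b$fingerprint)) {
    stop("sketch parameter fingerprints differ between '", a$genome_id,
         "' and '", b$genome_id, "'; re-sketch with identical parameters")
  }
  invisible(TRUE)
}

#' Inverted marker index for many-vs-many screening
#'
#' Maps every marker hash to the set of genomes containing it, so that a
#' query genome's marker intersection with *all* references is obtained in
#' time proportional to the query's marker count plus the number of similar
#' genomes, rather than by touching every reference.
#'
#' @param sketches List of `genome_sketch` objects (all same fingerprint).
#' @return An object of class `marker_index`.
#' @export
build_marker_index <- function(sketches) {
  stopifnot(length(sketches) >= 1)
  fps <- vapply(sketches, function(s) s$fingerprint, "")
  if (length(unique(fps)) != 1) stop("sketches have differing parameter fingerprints")
  tabs <- lapply(seq_along(sketches), function(i) {
    m <- sketches[[i]]$markers
    if (length(m) == 0) return(NULL)
    data.table(marker = m, genome = i)
  })
  table <- rbindlist(tabs[!vapply(tabs, is.null, TRUE)])
  if (nrow(table) == 0) table <- data.table(marker = character(), genome = integer())
  setkey(table, marker)
  structure(list(
    table = table,
    genome_marker_counts = vapply(sketches, function(s) length(s$markers), 0L),
    genome_ids = vapply(sketches, function(s) s$genome_id, ""),
    fingerprint = fps[[1]]
  ), class = "marker_index")
}

#' Query a marker index
#'
#' Returns, for every indexed genome sharing at least one marker with the
#' query, the exact marker intersection size, the max-containment index and
#' the putative ANI. Identical to pairwise [screen_pair()] on every pair.
#'
#' @param index A `marker_index`.
#' @param markers Character vector of query marker hashes.
#' @param params A [sketch_params()] object.
#' @return data.table with columns `genome` (index), `intersection`,
#'   `containment`, `putative_ani`, `pass`.
#' @export
query_marker_index <- function(index, markers, params = sketch_params()) {
  nq <- length(unique(markers))
  if (nq == 0) {
    warning("empty marker set: genome cannot be screened")
    return(data.table(genome = seq_along(index$genome_marker_counts),
                      intersection = NA_integer_, containment = NA_real_,
                      putative_ani = NA_real_, pass = TRUE))
  }
  hits <- index$table[data.table(marker = unique(markers)), nomatch = NULL,
                      on = "marker"]
  counts <- hits[, .(intersection = .N), by = genome]
  counts[, containment := intersection /
           pmin(nq, index$genome_marker_counts[genome])]
  counts[, putative_ani := containment^(1 / params$marker_k)]
  counts[, pass := putative_ani > params$marker_ani_threshold]
  setorder(counts, genome)
  counts[]
}

#' @export
print.marker_index <- function(x, ...) {
  cat(sprintf("Inverted marker index: %d genomes, %d marker entries\n",
              length(x$genome_marker_counts), nrow(x$table)))
  invisible(x)
}
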