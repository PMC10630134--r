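#' Random i.i.d. genome sequence
#'
#' Uniform A/C/G/T string, reproducible by seed. The substrate for all
#' synthetic experiments.
#'
#' @param length Sequence length in bases (>= 1).
#' @param seed Integer RNG seed (global RNG state is untouched).
#' @return A single character string.
#' @export
random_genome <- function(length, seed = 1L) {
  stopifnot(length >= 1)
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
}

#' Mutate a sequence under independent substitution
#'
#' Every base is independently changed to one of the three other letters with
#' probability `theta`; the true ANI of the pair is `1 - theta` by
#' construction. The realized mismatch count is returned for exact truth
#' bookkeeping.
#'
#' @param sequence A/C/G/T string.
#' @param theta Per-base substitution probability in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return List with `sequence` (mutated) and `realized_mismatches`.
#' @export
mutate_genome <- function(sequence, theta, seed = 1L) {
  stopifnot(theta >= 0, theta < 1)
  n <- nchar(sequence)
  if (theta == 0) return(list(sequence = sequence, realized_mismatches = 0L))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    v <- strsplit(sequence, "", fixed = TRUE)[[1]]
    hit <- which(runif(n) < theta)
    if (length(hit)) {
      # draw one of the 3 *other* bases uniformly
      cur <- match(v[hit], bases)
      off <- sample.int(3L, length(hit), replace = TRUE)
      v[hit] <- bases[((cur - 1L + off) %% 4L) + 1L]
    }
    list(sequence = paste(v, collapse = ""),
         realized_mismatches = length(hit))
  })
}

#' Simulation specification for MAG-quality degradation
#'
#' @param base_length Genome length in bases.
#' @param theta Per-base substitution probability.
#' @param target_n50 Target contig N50 in bases (`Inf` = no fragmentation).
#' @param completeness Fraction of sequence retained in `(0, 1]`.
#' @param contamination Fraction of foreign (unrelated random) sequence
#'   appended, relative to `base_length` (>= 0).
#' @param seed Integer RNG seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(base_length = 1e6, theta = 0.02, target_n50 = Inf,
                     completeness = 1, contamination = 0, seed = 1L) {
  stopifnot(theta >= 0, theta < 1, completeness > 0, completeness <= 1,
            contamination >= 0, target_n50 > 0)
  structure(list(base_length = base_length, theta = theta,
                 target_n50 = target_n50, completeness = completeness,
                 contamination = contamination, seed = as.integer(seed)),
            class = "sim_spec")
}

# contig N50: length L such that >= 50% of bases lie in contigs >= L
contig_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

# random fragment lengths approximating an exponential process whose
# length-weighted median (N50) is ~target
fragment_lengths <- function(total, target_n50) {
  if (!is.finite(target_n50) || target_n50 >= total) return(total)
  mu <- target_n50 / 1.678  # N50 of exponential fragments ~ 1.678 * mean
  lens <- numeric(0)
  left <- total
  while (left > 0) {
    l <- max(1, round(stats::rexp(1, rate = 1 / mu)))
    l <- min(l, left)
    lens <- c(lens, l)
    left <- left - l
  }
  lens
}

#' Degrade a genome to MAG-like quality
#'
#' Fragments the sequence into contigs at random breakpoints approximating
#' `target_n50`, drops randomly chosen contigs down to the requested
#' completeness, and appends contamination contigs drawn from an independent
#' random genome (evolutionarily unrelated, as in foreign-bin
#' contamination).
#'
#' @param sequence The genome string to degrade.
#' @param spec A [sim_spec()]; its `theta`/`base_length` fields are ignored
#'   here (mutation is applied separately by [mutate_genome()]).
#' @return List with `records` (named character vector of contigs) and
#'   `truth` (realized N50, retained fraction, contamination bases).
#' @export
degrade_genome <- function(sequence, spec) {
  n <- nchar(sequence)
  with_seed(spec$seed + 7L, {
    lens <- fragment_lengths(n, spec$target_n50)
    ends <- cumsum(lens)
    starts <- c(1, head(ends, -1) + 1)
    contigs <- substring(sequence, starts, ends)
    # drop random contigs until the retained total reaches completeness
    ord <- sample.int(length(contigs))
    target <- spec$completeness * n
    cum <- cumsum(nchar(contigs[ord]))
    keep_n <- which(cum >= target)[1]
    if (is.na(keep_n)) keep_n <- length(ord)
    # keep whichever side of the target is closer, but never zero contigs
    if (keep_n > 1 &&
        abs(cum[keep_n - 1] - target) < abs(cum[keep_n] - target)) {
      keep_n <- keep_n - 1L
    }
    kept <- sort(ord[seq_len(keep_n)])
    contigs <- contigs[kept]
    if (length(contigs) == 0) stop("completeness too low: no contigs survive")
    retained <- sum(nchar(contigs)) / n
    contam_bases <- round(spec$contamination * n)
    if (contam_bases > 0) {
      foreign <- random_genome(contam_bases,
                               seed = spec$seed + 104729L)
      flens <- fragment_lengths(contam_bases, spec$target_n50)
      fends <- cumsum(flens)
      fstarts <- c(1, head(fends, -1) + 1)
      contigs <- c(contigs, substring(foreign, fstarts, fends))
    }
    names(contigs) <- sprintf("contig_%04d", seq_along(contigs))
    list(records = contigs,
         truth = list(realized_n50 = contig_n50(nchar(contigs)),
                      retained_fraction = retained,
                      contamination_bases = contam_bases,
                      n_contigs = length(contigs)))
  })
}

#' Simulate a genome pair with known ANI
#'
#' Generates a random base genome, a mutated copy at substitution rate
#' `theta` (true ANI `1 - theta`), and degrades the copy per the
#' specification. The truth record carries everything needed to score an
#' estimator.
#'
#' @param spec A [sim_spec()].
#' @return List with `original` (named character vector, single contig),
#'   `derived` (degraded multi-contig records), and `truth` (theta, true ANI,
#'   realized mismatches, degradation stats).
#' @export
sim_genome_pair <- function(spec) {
  g <- random_genome(spec$base_length, seed = spec$seed)
  mut <- mutate_genome(g, spec$theta, seed = spec$seed + 1L)
  deg <- degrade_genome(mut$sequence, spec)
  list(original = c(genome = g), derived = deg$records,
       truth = c(list(theta = spec$theta, true_ani = 1 - spec$theta,
                      realized_mismatches = mut$realized_mismatches),
                 deg$truth))
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(length(records) >= 1, !is.null(names(records)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(path)
}
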