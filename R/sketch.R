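#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; accepts plain or
#' gzip-compressed multi-record FASTA. Sequences are uppercased.
#'
#' @param path Path to a FASTA/FASTA.gz file.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("cannot read FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(ss) == 0) stop("no sequence in FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  # keep only the first word of each header, as aligners do
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  seqs
}

#' Sketch a genome: FracMinHash seeds and marker ℓ-mers
#'
#' Extracts an expected `1/c` fraction of canonical k-mers as *seeds*
#' (position-resolved, used for anchoring/chaining) and an expected
#' `1/marker_c` fraction of canonical ℓ-mers as *markers* (a hash set used
#' only for the max-containment screen). Seeds occurring more than
#' `mask_threshold` times in the genome are masked as repetitive. Windows
#' containing non-ACGT characters are skipped.
#'
#' @param x A FASTA path, a named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param params A [sketch_params()] object.
#' @param genome_id Label for the genome; defaults to the file path (or
#'   `"genome"` for in-memory input).
#' @return An object of class `genome_sketch`: a list with `genome_id`,
#'   `contig_names`, `contig_lengths`, `total_length`, `seeds` (a data.table
#'   with columns `hash`, `contig` (1-based index), `pos` (0-based), `strand`),
#'   `markers` (sorted character vector of hex hashes), `params`, and
#'   `fingerprint`.
#' @export
#' @examples
#' g <- random_genome(50000, seed = 1)
#' sk <- sketch_genome(c(ctg1 = g), sketch_params())
#' sk
sketch_genome <- function(x, params = sketch_params(), genome_id = NULL) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
    if (is.null(names(seqs))) names(seqs) <- paste0("contig_", seq_along(seqs))
  } else if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
             file.exists(x)) {
    if (is.null(genome_id)) genome_id <- x
    seqs <- read_fasta(x)
  } else if (is.character(x)) {
    seqs <- toupper(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("contig_", seq_along(seqs))
  } else {
    stop("x must be a FASTA path, character vector, or DNAStringSet")
  }
  if (length(seqs) == 0) stop("no sequence records")
  if (is.null(genome_id)) genome_id <- "genome"
  validate_sketch_params(params)

  contig_lengths <- unname(nchar(seqs))
  seed_parts <- vector("list", length(seqs))
  marker_parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) >= params$k) {
      sd <- .fmh_seeds_cpp(s, params$k, params$c)
      if (length(sd$hash)) {
        seed_parts[[i]] <- data.table(hash = sd$hash, contig = i,
                                      pos = sd$pos, strand = sd$strand)
      }
    }
    if (nchar(s) >= params$marker_k) {
      mk <- .fmh_seeds_cpp(s, params$marker_k, params$marker_c)
      marker_parts[[i]] <- mk$hash
    }
  }
  seeds <- rbindlist(seed_parts[!vapply(seed_parts, is.null, TRUE)])
  if (nrow(seeds) == 0) {
    seeds <- data.table(hash = character(), contig = integer(),
                        pos = integer(), strand = integer())
  }
  seeds <- mask_repetitive_seeds(seeds, params)
  setkey(seeds, hash)
  markers <- sort(unique(unlist(marker_parts, use.names = FALSE)))
  if (is.null(markers)) markers <- character()

  if (any(contig_lengths >= params$k) && nrow(seeds) == 0 &&
      length(markers) == 0) {
    warning("no valid k-mer windows in '", genome_id,
            "' (all-N or highly ambiguous sequence?)")
  }

  structure(list(
    genome_id = genome_id,
    contig_names = names(seqs),
    contig_lengths = contig_lengths,
    total_length = sum(contig_lengths),
    seeds = seeds,
    markers = markers,
    params = params,
    fingerprint = params_fingerprint(params)
  ), class = "genome_sketch")
}

#' Mask repetitive seeds
#'
#' Removes every seed hash whose total occurrence count across the genome
#' exceeds `params$mask_threshold` (`band_b %/% c`, i.e. 2500/c at defaults,
#' with a floor of 1). Small seed k-mers are otherwise too repetitive on
#' large genomes and flood the chaining band.
#'
#' @param seeds data.table with columns `hash`, `contig`, `pos`, `strand`.
#' @param params A [sketch_params()] object.
#' @return The filtered data.table (all positions of over-represented hashes
#'   removed).
#' @export
mask_repetitive_seeds <- function(seeds, params) {
  if (nrow(seeds) == 0) return(seeds)
  seeds[, n_occ := .N, by = hash]
  out <- seeds[n_occ <= params$mask_threshold]
  out[, n_occ := NULL]
  seeds[, n_occ := NULL]
  out
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("Genome sketch '%s'\n", x$genome_id))
  cat(sprintf("  %d contig(s), %s bp total\n", length(x$contig_names),
              format(x$total_length, big.mark = ",")))
  cat(sprintf("  %d seed positions (k=%d, c=%g), %d markers (l=%d, c_m=%g)\n",
              nrow(x$seeds), x$params$k, x$params$c,
              length(x$markers), x$params$marker_k, x$params$marker_c))
  invisible(x)
}

SKETCH_MAGIC <- "chainani-sketch"
SKETCH_FORMAT_VERSION <- 1L

#' Write / read a genome sketch file
#'
#' Sketch files are a versioned serialized container: a magic tag, format
#' version, the sketching parameters, the contig table, the seed table and
#' the marker set. Reading a sketch back yields an object identical to the
#' one written (bit-exact round trip), so downstream commands accept sketch
#' files and FASTA interchangeably.
#'
#' @param sketch A `genome_sketch`.
#' @param path Output (input) file path; conventionally `*.ske`.
#' @return `write_sketch` returns `path` invisibly; `read_sketch` returns the
#'   `genome_sketch`.
#' @export
write_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "genome_sketch"))
  payload <- list(magic = SKETCH_MAGIC, version = SKETCH_FORMAT_VERSION,
                  sketch = sketch)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable sketch file: ", path))
  if (!is.list(payload) || !identical(payload$magic, SKETCH_MAGIC)) {
    stop("not a chainani sketch file: ", path)
  }
  if (!identical(payload$version, SKETCH_FORMAT_VERSION)) {
    stop("unsupported sketch format version in ", path)
  }
  payload$sketch
}

# Load an input that may be a FASTA file or a sketch file.
load_genome_input <- function(path, params) {
  if (grepl("\\.ske$", path)) {
    sk <- read_sketch(path)
  } else {
    sk <- sketch_genome(path, params)
  }
  if (!identical(sk$fingerprint, params_fingerprint(params))) {
    stop("sketch '", path, "' was made under different sketching parameters")
  }
  sk
}
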