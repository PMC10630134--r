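#' Compare query genomes against reference genomes
#'
#' Every query×reference pair is screened (pairwise, or through the inverted
#' marker index when there are many queries) and compared with
#' [compare_pair()]. All sketches are held in memory.
#'
#' @param queries,references Lists of `genome_sketch` objects (a single
#'   sketch is accepted).
#' @param params A [sketch_params()] object.
#' @param use_index Force the inverted marker index on/off; by default it is
#'   used when there are at least 100 queries.
#' @param debias_model Optional `debias_model`.
#' @param seed Integer seed (bootstrap only).
#' @return List of `ani_result` objects (screened-out pairs are empty
#'   records when screening was pairwise, and omitted under the index;
#'   [results_table()] output is identical either way).
#' @export
ani_dist <- function(queries, references, params = sketch_params(),
                     use_index = NULL, debias_model = NULL, seed = 1L) {
  queries <- as_sketch_list(queries)
  references <- as_sketch_list(references)
  if (is.null(use_index)) use_index <- length(queries) >= 100
  results <- list()
  if (use_index) {
    idx <- build_marker_index(references)
    for (q in queries) {
      hits <- query_marker_index(idx, q$markers, params)
      hits <- hits[pass == TRUE]
      for (i in seq_len(nrow(hits))) {
        r <- references[[hits$genome[i]]]
        res <- compare_pair(q, r, params, debias_model = debias_model,
                            seed = seed, screen = FALSE)
        res$putative_ani <- hits$putative_ani[i]
        results[[length(results) + 1L]] <- res
      }
    }
  } else {
    for (q in queries) for (r in references) {
      results[[length(results) + 1L]] <-
        compare_pair(q, r, params, debias_model = debias_model, seed = seed)
    }
  }
  results
}

#' All-vs-all comparisons (lower triangle)
#'
#' Because the comparison is symmetric, only the `n(n-1)/2` unordered pairs
#' are computed. The inverted marker index is always used for screening.
#'
#' @param sketches List of `genome_sketch` objects (>= 2).
#' @inheritParams ani_dist
#' @return List of `ani_result` objects, one per unordered pair that passed
#'   the screen.
#' @export
ani_triangle <- function(sketches, params = sketch_params(),
                         debias_model = NULL, seed = 1L) {
  sketches <- as_sketch_list(sketches)
  stopifnot(length(sketches) >= 2)
  idx <- build_marker_index(sketches)
  results <- list()
  for (i in seq_len(length(sketches) - 1L)) {
    hits <- query_marker_index(idx, sketches[[i]]$markers, params)
    hits <- hits[pass == TRUE & genome > i]
    for (jj in seq_len(nrow(hits))) {
      j <- hits$genome[jj]
      res <- compare_pair(sketches[[i]], sketches[[j]], params,
                          debias_model = debias_model, seed = seed,
                          screen = FALSE)
      res$putative_ani <- hits$putative_ani[jj]
      results[[length(results) + 1L]] <- res
    }
  }
  results
}

#' Square symmetric ANI matrix from triangle results
#'
#' PHYLIP-style square matrix for clustering input: ANI in percent, 100 on
#' the diagonal, 0 for pairs with no reportable ANI.
#'
#' @param results Output of [ani_triangle()].
#' @param sketches The same sketch list the triangle was computed on.
#' @return A numeric matrix with genome ids as dimnames.
#' @export
ani_matrix <- function(results, sketches) {
  sketches <- as_sketch_list(sketches)
  ids <- vapply(sketches, function(s) s$genome_id, "")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (r in results) {
    if (r$screen_pass && r$af_pass && !is.na(r$ani)) {
      m[r$query_id, r$ref_id] <- m[r$ref_id, r$query_id] <- 100 * r$ani
    }
  }
  m
}

#' Sketch FASTA files into a sketch database directory
#'
#' Writes one `.ske` sketch file per genome plus a `markers.rds` side file
#' holding only the marker sets and parameter fingerprint, so that
#' [ani_search()] can screen a database without loading full sketches.
#'
#' @param fasta_paths Character vector of FASTA/FASTA.gz paths.
#' @param out_dir Output directory (created if needed).
#' @param params A [sketch_params()] object.
#' @return Invisibly, the written sketch paths. Per-file read errors are
#'   reported as warnings; an error is raised if every input fails.
#' @export
sketch_directory <- function(fasta_paths, out_dir, params = sketch_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ids <- character(); markers <- list(); counts <- integer()
  for (p in fasta_paths) {
    sk <- tryCatch(sketch_genome(p, params), error = function(e) {
      warning("skipping '", p, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(sk)) next
    out <- file.path(out_dir, paste0(
      sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(p)), ".ske"))
    write_sketch(sk, out)
    written <- c(written, out)
    ids <- c(ids, sk$genome_id)
    markers[[length(markers) + 1L]] <- sk$markers
    counts <- c(counts, length(sk$markers))
  }
  if (length(written) == 0) stop("no input FASTA could be sketched")
  saveRDS(list(magic = "chainani-markers", version = 1L,
               fingerprint = params_fingerprint(params),
               files = basename(written), genome_ids = ids,
               markers = markers, marker_counts = counts),
          file.path(out_dir, "markers.rds"), version = 3)
  invisible(written)
}

#' Search query genomes against a sketch database
#'
#' Memory-lean counterpart of [ani_dist()]: only the database's marker sets
#' are resident; a reference's full sketch is loaded from disk only when its
#' marker-based putative ANI clears the screen for some query, then
#' discarded. Results are identical to [ani_dist()] on the same genomes.
#'
#' @param queries List of `genome_sketch` objects (or a single one).
#' @param db_dir Directory written by [sketch_directory()].
#' @param params A [sketch_params()] object; its fingerprint must match the
#'   database's.
#' @inheritParams ani_dist
#' @return List of `ani_result` objects for screen-passing pairs.
#' @export
ani_search <- function(queries, db_dir, params = sketch_params(),
                       debias_model = NULL, seed = 1L) {
  queries <- as_sketch_list(queries)
  mpath <- file.path(db_dir, "markers.rds")
  if (!file.exists(mpath)) stop("no markers.rds in sketch database: ", db_dir)
  db <- readRDS(mpath)
  if (!identical(db$magic, "chainani-markers")) {
    stop("corrupted marker store: ", mpath)
  }
  if (!identical(db$fingerprint, params_fingerprint(params))) {
    stop("sketch database '", db_dir,
         "' was built under different sketching parameters")
  }
  results <- list()
  for (q in queries) {
    if (!identical(q$fingerprint, db$fingerprint)) {
      stop("query '", q$genome_id, "' fingerprint does not match database")
    }
    for (i in seq_along(db$files)) {
      cont <- max_containment(q$markers, db$markers[[i]])
      pa <- ani_fmh(cont, params$marker_k)
      if (!is.na(pa) && pa <= params$marker_ani_threshold) next
      ref <- read_sketch(file.path(db_dir, db$files[i]))  # loaded per candidate
      res <- compare_pair(q, ref, params, debias_model = debias_model,
                          seed = seed, screen = FALSE)
      res$putative_ani <- pa
      results[[length(results) + 1L]] <- res
      rm(ref)
    }
  }
  results
}

as_sketch_list <- function(x) {
  if (inherits(x, "genome_sketch")) list(x) else x
}
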