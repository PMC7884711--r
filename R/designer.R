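#' Generate random candidate peptides
#'
#' Candidate sequences are all-L (uppercase). Lengths are uniform on
#' `len_range` and residues uniform on the 20-letter alphabet; generation is
#' a pure function of `(k, len_range, seed)`.
#'
#' @param k number of candidates.
#' @param len_range inclusive length range (default 10-20 residues).
#' @param seed integer seed.
#' @return A data frame of class `"design_pool"` with columns `sequence`,
#'   `origin`, `parent1`, `parent2`.
#' @export
random_peptides <- function(k, len_range = c(10L, 20L), seed = 1L) {
  stopifnot(k >= 0, length(len_range) == 2L)
  if (len_range[1] < 1L || len_range[1] > len_range[2])
    stop("invalid length range", call. = FALSE)
  set.seed(seed)
  if (k == 0) return(empty_pool())
  lens <- sample(seq(len_range[1], len_range[2]), k, replace = TRUE)
  chars <- sample(AA_ALPHABET, sum(lens), replace = TRUE)
  stops <- cumsum(lens)
  seqs <- substring(paste(chars, collapse = ""), stops - lens + 1L, stops)
  structure(data.frame(sequence = seqs, origin = "random",
                       parent1 = NA_character_, parent2 = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("design_pool", "data.frame"))
}

empty_pool <- function() {
  structure(data.frame(sequence = character(), origin = character(),
                       parent1 = character(), parent2 = character(),
                       stringsAsFactors = FALSE),
            class = c("design_pool", "data.frame"))
}

#' Recombination operators
#'
#' `crossover_sequences()` joins the first `cut` residues of `a` to the
#' residues of `b` after position `cut` (single-point crossover at a shared
#' cut). `fuse_sequences()` concatenates `a` and `b` and truncates the tail
#' to `max_len` residues.
#'
#' @param a,b parent sequences (character scalars).
#' @param cut crossover point, `1 <= cut < min(nchar(a), nchar(b))`.
#' @param max_len tandem-fusion length cap (default 24).
#' @export
crossover_sequences <- function(a, b, cut) {
  stopifnot(cut >= 1, cut < nchar(a), cut < nchar(b))
  paste0(substr(a, 1L, cut), substr(b, cut + 1L, nchar(b)))
}

#' @rdname crossover_sequences
#' @export
fuse_sequences <- function(a, b, max_len = 24L) {
  substr(paste0(a, b), 1L, max_len)
}

#' Recombine library peptides into new candidates
#'
#' Builds `k` candidates from seeded-random pairs of distinct library
#' parents, by single-point crossover or tandem fusion (chosen 50/50).
#' Parents are case-folded to L-form. Candidates outside 10-24 residues are
#' rejected at source; duplicates (against the pool and the library) are
#' dropped and regenerated up to a retry cap, after which a partial pool is
#' returned with a warning and attribute `incomplete = TRUE`.
#'
#' @param library list of `peptide` objects (at least 2).
#' @param k number of candidates requested.
#' @param seed integer seed.
#' @param len_limits inclusive candidate length bounds.
#' @param max_attempts retry cap on total generation attempts.
#' @return A `"design_pool"` data frame; `parent1`/`parent2` hold library
#'   ids.
#' @export
recombine_library <- function(library, k, seed = 1L,
                              len_limits = c(10L, 24L),
                              max_attempts = 50L * k + 100L) {
  library <- as_peptide_list(library)
  if (length(library) < 2L)
    stop("need at least 2 library peptides", call. = FALSE)
  set.seed(seed)
  lib_seq <- toupper(vapply(library, `[[`, character(1), "sequence"))
  lib_id <- vapply(library, `[[`, character(1), "id")
  seen <- new.env(parent = emptyenv())
  for (s in lib_seq) assign(s, TRUE, envir = seen)
  out_seq <- character(k); out_or <- character(k)
  out_p1 <- character(k); out_p2 <- character(k)
  got <- 0L; attempts <- 0L
  while (got < k && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(length(library), 2L)
    a <- lib_seq[ij[1]]; b <- lib_seq[ij[2]]
    if (runif(1) < 0.5) {
      m <- min(nchar(a), nchar(b))
      if (m < 2L) next
      cand <- crossover_sequences(a, b, sample.int(m - 1L, 1L))
      origin <- "crossover"
    } else {
      cand <- fuse_sequences(a, b, len_limits[2])
      origin <- "fusion"
    }
    if (nchar(cand) < len_limits[1] || nchar(cand) > len_limits[2]) next
    if (!is.null(seen[[cand]])) next
    assign(cand, TRUE, envir = seen)
    got <- got + 1L
    out_seq[got] <- cand; out_or[got] <- origin
    out_p1[got] <- lib_id[ij[1]]; out_p2[got] <- lib_id[ij[2]]
  }
  if (got < k)
    warning("retry cap reached: returning ", got, " of ", k, " candidates")
  pool <- structure(data.frame(sequence = out_seq[seq_len(got)],
                               origin = out_or[seq_len(got)],
                               parent1 = out_p1[seq_len(got)],
                               parent2 = out_p2[seq_len(got)],
                               stringsAsFactors = FALSE),
                    class = c("design_pool", "data.frame"))
  attr(pool, "incomplete") <- got < k
  pool
}

#' Assemble a candidate pool
#'
#' Default pool composition is 50% random sequences (10-20 residues) and
#' 50% library recombinants, deduplicated on exact sequence (first
#' occurrence kept).
#'
#' @param library list of `peptide` objects.
#' @param n_total total pool size before dedup (default 200000).
#' @param seed integer seed.
#' @return A `"design_pool"` data frame.
#' @export
build_design_pool <- function(library, n_total = 200000L, seed = 1L) {
  n_rand <- n_total %/% 2L
  pool <- rbind(random_peptides(n_rand, seed = seed),
                recombine_library(library, n_total - n_rand,
                                  seed = seed + 1L))
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  rownames(pool) <- NULL
  class(pool) <- c("design_pool", "data.frame")
  pool
}

#' Score and rank design candidates
#'
#' Each candidate is featurized, transformed with the bundle's stored
#' parameters, restricted to the bundle's selected features, and scored by
#' the forest. The top `top_k` by predicted log10 intensity are returned,
#' descending, with ties broken by sequence lexicographic order.
#'
#' @param bundle a [train_model()] bundle.
#' @param pool a `"design_pool"` data frame.
#' @param top_k how many designs to return (default 9).
#' @param aaindex scale battery.
#' @return A data frame `rank`, `sequence`, `origin`, `parent1`, `parent2`,
#'   `predicted` (log10 A.U.).
#' @export
rank_candidates <- function(bundle, pool, top_k = 9L,
                            aaindex = load_aaindex()) {
  if (nrow(pool) == 0L) stop("empty candidate pool", call. = FALSE)
  stopifnot(top_k >= 1L)
  peptides <- lapply(seq_len(nrow(pool)), function(i)
    validate_peptide(pool$sequence[i], sprintf("cand_%06d", i)))
  pred <- predict_peptides(bundle, peptides, aaindex)
  # C locale so lexicographic tie-breaks are platform-stable
  o <- order(-pred, xtfrm(factor(pool$sequence,
                                 levels = sort(unique(pool$sequence),
                                               method = "radix"))))
  o <- o[seq_len(min(top_k, nrow(pool)))]
  out <- data.frame(rank = seq_along(o), sequence = pool$sequence[o],
                    origin = pool$origin[o], parent1 = pool$parent1[o],
                    parent2 = pool$parent2[o], predicted = unname(pred[o]),
                    stringsAsFactors = FALSE)
  out
}

#' @rdname rank_candidates
#' @param designs output of `rank_candidates()`.
#' @param csv_path,fasta_path output paths (either may be `NULL`).
#' @export
write_designs <- function(designs, csv_path = NULL, fasta_path = NULL) {
  if (!is.null(csv_path))
    write.csv(designs, csv_path, row.names = FALSE, na = "")
  if (!is.null(fasta_path))
    write_fasta(lapply(seq_len(nrow(designs)), function(i)
      validate_peptide(designs$sequence[i],
                       sprintf("design_%02d", designs$rank[i]))),
      fasta_path)
  invisible(designs)
}
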