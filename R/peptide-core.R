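#' Peptide objects with per-residue chirality
#'
#' A peptide is a sequence over the 20 canonical amino-acid letters where
#' letter case encodes chirality: uppercase = L-residue, lowercase =
#' D-residue. Chirality is carried in the data model but ignored by all
#' descriptor computations, which case-fold to the parent residue.
#'
#' @param raw character scalar, the amino-acid sequence (case significant).
#' @param id text label for the peptide.
#' @param is_linear logical; `TRUE` for unmodified linear peptides.
#' @return An object of class `"peptide"` with fields `id`, `sequence` and
#'   `is_linear`.
#' @examples
#' validate_peptide("KLPVM", "cpp63")
#' validate_peptide("rrrrrrrrrcqcrrkn", "cpp80")  # all-D nona-arginine variant
#' @export
validate_peptide <- function(raw, id = "peptide", is_linear = TRUE) {
  if (length(raw) != 1L || !is.character(raw))
    stop("`raw` must be a single character string", call. = FALSE)
  seq <- gsub("[[:space:]]", "", raw)
  if (!nzchar(seq))
    stop("peptide '", id, "': empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(toupper(chars) %in% AA_ALPHABET))
  if (length(bad))
    stop("peptide '", id, "': non-canonical character '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  structure(list(id = as.character(id), sequence = seq,
                 is_linear = isTRUE(is_linear)),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$id, ": ", x$sequence, " (", peptide_length(x),
      " aa, ", sum(residue_chirality(x) == "D"), " D-residues",
      if (!x$is_linear) ", non-linear", ")\n", sep = "")
  invisible(x)
}

#' @rdname validate_peptide
#' @param p a `peptide` object.
#' @export
peptide_length <- function(p) nchar(p$sequence)

#' @rdname validate_peptide
#' @return `residue_chirality()` returns a character vector of "L"/"D" per
#'   residue, derived from letter case alone.
#' @export
residue_chirality <- function(p) {
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  ifelse(chars %in% AA_ALPHABET, "L", "D")
}

as_peptide_list <- function(x) {
  if (inherits(x, "peptide")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "peptide")))
  x
}

#' Read and write peptide FASTA
#'
#' Case-preserving FASTA I/O (standard readers upper-case sequences, which
#' would erase the chirality encoding). Headers become peptide ids; wrapped
#' sequence lines are concatenated. Every record is validated.
#'
#' @param path file path (or connection) of a FASTA file.
#' @return `read_fasta()`: a list of [validate_peptide()] objects in file
#'   order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA (no leading '>'): ", path, call. = FALSE)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  out <- vector("list", sum(hdr))
  for (i in seq_along(out)) {
    body <- lines[rec == i & !hdr]
    seq <- paste(trimws(body), collapse = "")
    if (!nzchar(seq))
      stop("FASTA record '", ids[i], "': empty sequence", call. = FALSE)
    out[[i]] <- validate_peptide(seq, ids[i])
  }
  out
}

#' @rdname read_fasta
#' @param peptides list of `peptide` objects.
#' @param width line-wrap width for sequences.
#' @export
write_fasta <- function(peptides, path, width = 60L) {
  peptides <- as_peptide_list(peptides)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in peptides) {
    writeLines(paste0(">", p$id), con)
    s <- p$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write CPP screening tables
#'
#' The screening-table schema is comma-delimited UTF-8 with header columns
#' `id, sequence, intensity_au, max_od_pct, source` (one row per screened
#' peptide). `intensity_au` is the TAMRA penetration fluorescence in
#' arbitrary units; `max_od_pct` the maximum OD600 of the treated culture as
#' a percentage of the untreated control. Empty cells or "." are missing
#' values (`NA`), never zeros.
#'
#' @param path CSV file path.
#' @param cell_type one of `"ecoli"`, `"hek293"`, `"cho"`.
#' @return A data frame of class `"cpp_screen"` with columns `id`,
#'   `sequence`, `intensity_au`, `max_od_pct`, `source`, `cell_type`.
#' @examples
#' # packaged synthetic example mirroring the schema
#' f <- system.file("extdata", "example_screen_synthetic.csv",
#'                  package = "cppscreen")
#' read_screen_table(f)
#' @export
read_screen_table <- function(path, cell_type = c("ecoli", "hek293", "cho")) {
  cell_type <- match.arg(cell_type)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "."),
                 fileEncoding = "UTF-8")
  need <- c("id", "sequence", "intensity_au", "max_od_pct", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("screening table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$intensity_au <- as.numeric(df$intensity_au)
  df$max_od_pct <- as.numeric(df$max_od_pct)
  if (any(df$intensity_au < 0, na.rm = TRUE))
    stop("negative intensity_au in screening table", call. = FALSE)
  if (any(df$max_od_pct < 0, na.rm = TRUE))
    stop("negative max_od_pct in screening table", call. = FALSE)
  src_ok <- c("cppsite", "literature", "manual", "designed")
  if (any(!is.na(df$source) & !(df$source %in% src_ok)))
    stop("unknown source tag; expected one of ",
         paste(src_ok, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(df))) validate_peptide(df$sequence[i], df$id[i])
  df <- df[need]
  df$cell_type <- cell_type
  class(df) <- c("cpp_screen", "data.frame")
  df
}

#' @rdname read_screen_table
#' @param screen a `cpp_screen` data frame.
#' @export
write_screen_table <- function(screen, path) {
  out <- as.data.frame(screen)[c("id", "sequence", "intensity_au",
                                 "max_od_pct", "source")]
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_screen_table
#' @export
screen_peptides <- function(screen) {
  lapply(seq_len(nrow(screen)), function(i)
    validate_peptide(screen$sequence[i], screen$id[i]))
}

#' Library inclusion criteria
#'
#' The screening-library filter keeps peptides of 5-24 residues, all-L
#' chirality (unless the id is whitelisted, as the screen's single all-D
#' entry was), and linear chemistry. Linearity is carried as metadata since
#' it is not derivable from sequence text.
#'
#' @param min_len,max_len inclusive length bounds (residues).
#' @param require_all_L reject peptides with D-residues unless whitelisted.
#' @param whitelist character vector of peptide ids exempt from the
#'   chirality rule.
#' @param require_linear reject non-linear peptides.
#' @return An object of class `"library_criteria"`.
#' @export
library_criteria <- function(min_len = 5L, max_len = 24L,
                             require_all_L = TRUE, whitelist = character(),
                             require_linear = TRUE) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 require_all_L = isTRUE(require_all_L),
                 whitelist = as.character(whitelist),
                 require_linear = isTRUE(require_linear)),
            class = "library_criteria")
}

#' Filter a peptide set by library-inclusion criteria
#'
#' Partitions the input into kept and rejected peptides; each rejected entry
#' carries the first failed criterion (checked in order: length, chirality,
#' linearity).
#'
#' @param peptides list of `peptide` objects.
#' @param criteria a [library_criteria()] object.
#' @return A list with elements `kept` (list of peptides) and `rejected`
#'   (data frame with columns `id` and `reason`).
#' @export
filter_library <- function(peptides, criteria = library_criteria()) {
  peptides <- as_peptide_list(peptides)
  reasons <- vapply(peptides, function(p) {
    len <- peptide_length(p)
    if (len < criteria$min_len || len > criteria$max_len) return("length")
    if (criteria$require_all_L && any(residue_chirality(p) == "D") &&
        !(p$id %in% criteria$whitelist)) return("chirality")
    if (criteria$require_linear && !p$is_linear) return("linearity")
    ""
  }, character(1))
  keep <- reasons == ""
  list(kept = peptides[keep],
       rejected = data.frame(
         id = vapply(peptides[!keep], `[[`, character(1), "id"),
         reason = reasons[!keep], stringsAsFactors = FALSE))
}

#' Expected rarity of a restriction recognition site
#'
#' For a site of `site_len` bases, one random occurrence is expected every
#' `4^site_len` bp. An 18-bp meganuclease site (I-SceI) is expected about
#' once per 7e10 bp, which is why delivering the enzyme cuts a site-bearing
#' plasmid but effectively never the host genome.
#'
#' @param site_len recognition-site length in bases.
#' @return Expected base pairs per random site occurrence.
#' @export
recognition_site_rarity <- function(site_len = 18L) {
  stopifnot(site_len >= 1)
  4^site_len
}
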