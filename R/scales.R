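# Vendored per-residue scale tables. Loaded once per session and cached.

the <- new.env(parent = emptyenv())

scale_file <- function(name) {
  path <- system.file("extdata", name, package = "cppscreen")
  if (!nzchar(path)) stop("vendored table not found: ", name, call. = FALSE)
  path
}

#' Load the vendored 85-scale index battery
#'
#' Tab-delimited battery of per-residue numerical scales following AAIndex1
#' record semantics (accession, description, 20 residue values in canonical
#' order). The packaged default is a documented synthetic stand-in: published
#' anchor scales plus frozen seeded composite scales (see the methods
#' vignette). Any file in the same format can be swapped in.
#'
#' @param path optional path to an alternative battery file.
#' @return A list with `accession`, `description`, and `values` (matrix of
#'   scales x 20 residues, columns in canonical alphabet order).
#' @export
load_aaindex <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$aaindex)) return(the$aaindex)
    path <- scale_file("aaindex85_synthetic.tsv")
    cache <- TRUE
  } else cache <- FALSE
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!identical(names(df)[1:2], c("accession", "description")) ||
      !identical(names(df)[-(1:2)], AA_ALPHABET))
    stop("malformed scale battery: expected columns accession, description, ",
         paste(AA_ALPHABET, collapse = ""), call. = FALSE)
  vals <- as.matrix(df[, AA_ALPHABET])
  if (anyNA(vals))
    stop("scale battery has missing residue values (rows: ",
         paste(df$accession[apply(is.na(vals), 1L, any)], collapse = ", "),
         ")", call. = FALSE)
  rownames(vals) <- df$accession
  out <- list(accession = df$accession, description = df$description,
              values = vals)
  if (cache) the$aaindex <- out
  out
}

#' @rdname load_aaindex
#' @importFrom utils read.delim
#' @export
load_pka_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$pka)) return(the$pka)
    path <- scale_file("pka_emboss.tsv")
    cache <- TRUE
  } else cache <- FALSE
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("group", "type", "pka") %in% names(df)),
            all(df$type %in% c("acid", "base")),
            all(df$pka > 0 & df$pka < 14),
            all(c("Nterm", "Cterm") %in% df$group))
  out <- structure(df, class = c("pka_table", "data.frame"))
  if (cache) the$pka <- out
  out
}

# single vendored scale by accession (full-precision row of the battery)
get_scale <- function(accession) {
  aai <- load_aaindex()
  i <- match(accession, aai$accession)
  if (is.na(i)) stop("scale not in battery: ", accession, call. = FALSE)
  aai$values[i, ]
}
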