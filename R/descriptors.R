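#' Sequence descriptors: composition, dipeptides, scale averages
#'
#' The descriptor set is 505-dimensional: 20 amino-acid composition
#' fractions, 400 ordered dipeptide fractions, and 85 sequence-averaged
#' per-residue scales from the vendored battery. D-residues are case-folded
#' to their parent letter; chirality has no descriptor representation
#' because per-residue scales are defined for L-residues only.
#'
#' @param p a `peptide` object (see [validate_peptide()]).
#' @return `aa_composition()`: named numeric vector of length 20 summing
#'   to 1, in canonical alphabet order `ACDEFGHIKLMNPQRSTVWY`.
#' @export
aa_composition <- function(p) {
  codes <- seq_codes(p)
  counts <- tabulate(codes, nbins = 20L)
  out <- counts / length(codes)
  names(out) <- paste0("AAC_", AA_ALPHABET)
  out
}

seq_codes <- function(p) {
  chars <- strsplit(toupper(p$sequence), "", fixed = TRUE)[[1]]
  match(chars, AA_ALPHABET)
}

#' @rdname aa_composition
#' @return `dipeptide_composition()`: named numeric vector of length 400
#'   (ordered pairs, first residue outermost); fractions of adjacent pairs
#'   over `length - 1`, all zero for single-residue peptides.
#' @export
dipeptide_composition <- function(p) {
  codes <- seq_codes(p)
  n <- length(codes)
  counts <- numeric(400L)
  if (n >= 2L) {
    idx <- (codes[-n] - 1L) * 20L + codes[-1L]
    counts <- tabulate(idx, nbins = 400L) / (n - 1L)
  }
  names(counts) <- paste0("DPC_", rep(AA_ALPHABET, each = 20L),
                          rep(AA_ALPHABET, times = 20L))
  counts
}

#' @rdname aa_composition
#' @param aaindex a scale battery from [load_aaindex()].
#' @return `aaindex_features()`: named numeric vector of length 85; entry i
#'   is the arithmetic mean of scale i over the (case-folded) residues.
#' @export
aaindex_features <- function(p, aaindex = load_aaindex()) {
  codes <- seq_codes(p)
  out <- as.numeric(aaindex$values[, codes, drop = FALSE] %*%
                      rep(1 / length(codes), length(codes)))
  names(out) <- paste0("AAI_", aaindex$accession)
  out
}

#' Featurize peptides into the 505-column descriptor matrix
#'
#' Concatenates `[composition | dipeptide | scale averages]` with canonical,
#' version-stable column names and order.
#'
#' @param p a `peptide` object.
#' @param aaindex scale battery, see [load_aaindex()].
#' @return `featurize()`: named numeric vector of length 505.
#' @export
featurize <- function(p, aaindex = load_aaindex()) {
  c(aa_composition(p), dipeptide_composition(p), aaindex_features(p, aaindex))
}

#' @rdname featurize
#' @param peptides list of `peptide` objects (or a `cpp_screen` data frame).
#' @return `featurize_set()`: numeric matrix, peptides x 505, rownames are
#'   peptide ids.
#' @export
featurize_set <- function(peptides, aaindex = load_aaindex()) {
  if (inherits(peptides, "cpp_screen")) peptides <- screen_peptides(peptides)
  peptides <- as_peptide_list(peptides)
  X <- t(vapply(peptides, featurize, numeric(505L), aaindex = aaindex))
  rownames(X) <- vapply(peptides, `[[`, character(1), "id")
  X
}

#' Log-scale and normalize a feature matrix and target
#'
#' Features are mapped by the signed log `sl(x) = sign(x) * log(1 + |x|)`
#' (defined for the zeros and negatives that compositions and scale averages
#' contain), then centered and scaled per feature. The target is
#' `log10(intensity_au)`: the efficiency cutoff of 2.5 sits inside log10 of
#' the screen's intensity range, so base 10 is the scale the cutoff lives
#' on. Constant features get scale 1 (centered only). Fitted parameters are
#' reusable on new data via [apply_transform()].
#'
#' @param X raw feature matrix (peptides x features).
#' @param intensity_au positive penetration intensities (A.U.), one per row.
#' @param normalization `"zscore"` (default) or `"minmax"`.
#' @return A list with `params` (class `"transform_params"`), `X_t`
#'   (transformed features) and `y_t` (log10 intensities; `NULL` when
#'   `intensity_au` is).
#' @export
fit_transform <- function(X, intensity_au = NULL,
                          normalization = c("zscore", "minmax")) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  if (!is.null(intensity_au)) {
    if (anyNA(intensity_au) || any(intensity_au <= 0))
      stop("intensities must be positive and non-missing", call. = FALSE)
    stopifnot(length(intensity_au) == nrow(X))
  }
  S <- signed_log(X)
  if (normalization == "zscore") {
    center <- colMeans(S)
    scale_ <- apply(S, 2L, sd)
  } else {
    center <- apply(S, 2L, min)
    scale_ <- apply(S, 2L, max) - center
  }
  scale_[!is.finite(scale_) | scale_ <= 0] <- 1
  params <- structure(list(kind = "signed_log_then_zscore",
                           normalization = normalization,
                           center = center, scale = scale_,
                           target_log_base = 10,
                           feature_names = colnames(X)),
                      class = "transform_params")
  list(params = params,
       X_t = apply_transform(params, X),
       y_t = if (is.null(intensity_au)) NULL else log10(intensity_au))
}

signed_log <- function(x) sign(x) * log1p(abs(x))

#' @rdname fit_transform
#' @param params a `transform_params` object from [fit_transform()].
#' @export
apply_transform <- function(params, X) {
  stopifnot(inherits(params, "transform_params"))
  if (!is.null(params$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), params$feature_names))
    X <- X[, params$feature_names, drop = FALSE]
  S <- signed_log(X)
  sweep(sweep(S, 2L, params$center, "-"), 2L, params$scale, "/")
}

#' Henderson-Hasselbalch net charge and isoelectric point
#'
#' The net charge at a given pH is the sum over ionizable groups of their
#' expected protonation-state charge:
#' `+ sum_basic 1/(1 + 10^(pH - pKa)) - sum_acidic 1/(1 + 10^(pKa - pH))`,
#' counting both termini once and side chains of D, E, C, Y, H, K, R (case-
#' folded). The isoelectric point is the pH at which this monotone function
#' crosses zero, found by bisection on [0, 14].
#'
#' @param p a `peptide` object.
#' @param pH solution pH in `[0, 14]`.
#' @param pka ionizable-group pKa table, see [load_pka_table()] (EMBOSS
#'   values by default).
#' @return `net_charge()`: net charge in elementary charges.
#' @export
net_charge <- function(p, pH = 7, pka = load_pka_table()) {
  stopifnot(pH >= 0, pH <= 14)
  chars <- strsplit(toupper(p$sequence), "", fixed = TRUE)[[1]]
  groups <- c("Nterm", "Cterm", chars[chars %in%
                setdiff(pka$group, c("Nterm", "Cterm"))])
  i <- match(groups, pka$group)
  pos <- pka$type[i] == "base"
  sum(ifelse(pos, 1 / (1 + 10^(pH - pka$pka[i])),
             -1 / (1 + 10^(pka$pka[i] - pH))))
}

#' @rdname net_charge
#' @param tol bisection tolerance in pH units.
#' @return `isoelectric_point()`: pH at zero net charge.
#' @export
isoelectric_point <- function(p, pka = load_pka_table(), tol = 1e-4) {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH; positive at 0, negative at 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(p, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' GRAVY hydropathy and disorder proxy
#'
#' `gravy()` is the grand average of hydropathy: the mean Kyte-Doolittle
#' value over (case-folded) residues. `disorder_proxy()` is the mean of a
#' per-residue disorder-propensity scale (TOP-IDP) linearly rescaled to
#' `[0, 1]`; it is a documented stand-in for predictor-based disorder scores
#' and is used only for descriptive analytics.
#'
#' @param p a `peptide` object.
#' @return `gravy()`: mean hydropathy (dimensionless, roughly -4.5..4.5).
#' @export
gravy <- function(p) {
  kd <- get_scale("KYTJ820101")
  mean(kd[seq_codes(p)])
}

#' @rdname gravy
#' @return `disorder_proxy()`: mean rescaled disorder propensity in [0, 1].
#' @export
disorder_proxy <- function(p) {
  s <- get_scale("TOPIDP0801")
  s <- (s - min(s)) / (max(s) - min(s))
  mean(s[seq_codes(p)])
}

#' Physicochemical property profile
#'
#' One-row summary of the properties the screen analytics compare between
#' efficient and inefficient peptides: net charge at pH 7, isoelectric
#' point, GRAVY hydropathy, disorder proxy, and length.
#'
#' @param p a `peptide` object, or a list of them.
#' @param pka pKa table, see [load_pka_table()].
#' @return A data frame with columns `id`, `length`, `net_charge_pH7`, `pI`,
#'   `gravy`, `disorder_proxy`.
#' @export
property_profile <- function(p, pka = load_pka_table()) {
  peptides <- as_peptide_list(p)
  do.call(rbind, lapply(peptides, function(q) data.frame(
    id = q$id, length = peptide_length(q),
    net_charge_pH7 = net_charge(q, 7, pka),
    pI = isoelectric_point(q, pka),
    gravy = gravy(q), disorder_proxy = disorder_proxy(q),
    stringsAsFactors = FALSE)))
}
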