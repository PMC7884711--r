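#' Toxicity classification at the max-OD cutoff
#'
#' A peptide is cytotoxic when the treated culture's maximum OD600 falls
#' below `cutoff` percent of the untreated control; the boundary counts as
#' safe. Missing measurements are left unclassified (`NA`).
#'
#' @param max_od_pct max-OD ratios in percent (>= 0 where observed).
#' @param cutoff percent cutoff (default 50).
#' @return Character vector of `"cytotoxic"` / `"safe"` / `NA`.
#' @export
toxicity_class <- function(max_od_pct, cutoff = 50) {
  stopifnot(all(max_od_pct >= 0, na.rm = TRUE))
  ifelse(is.na(max_od_pct), NA_character_,
         ifelse(max_od_pct < cutoff, "cytotoxic", "safe"))
}

#' Compare a property between the most and least efficient peptides
#'
#' Ranks the screen by raw penetration intensity, takes the top and bottom
#' `n_top`/`n_bottom` peptides, computes the requested physicochemical
#' property for each, and runs a Welch (unequal-variance) two-sample
#' two-sided t-test. No multiple-testing correction is applied across
#' properties.
#'
#' @param screen a `cpp_screen` data frame with observed `intensity_au`.
#' @param property one of `"net_charge_pH7"`, `"pI"`, `"gravy"`,
#'   `"disorder_proxy"`, `"length"`.
#' @param n_top,n_bottom group sizes (default 15 each).
#' @param profile optional precomputed [property_profile()] for the screen
#'   (must be aligned by `id`).
#' @return A one-row data frame of class `"group_comparison"`: `property`,
#'   `mean_top`, `mean_bottom`, `t_statistic`, `p_value`, `n_top`,
#'   `n_bottom`.
#' @export
group_compare <- function(screen, property = c("net_charge_pH7", "pI",
                                               "gravy", "disorder_proxy",
                                               "length"),
                          n_top = 15L, n_bottom = 15L, profile = NULL) {
  property <- match.arg(property)
  obs <- screen[!is.na(screen$intensity_au), , drop = FALSE]
  if (nrow(obs) < n_top + n_bottom)
    stop("need at least ", n_top + n_bottom,
         " records with observed intensity", call. = FALSE)
  if (is.null(profile)) profile <- property_profile(screen_peptides(obs))
  vals <- profile[[property]][match(obs$id, profile$id)]
  o <- order(-obs$intensity_au)
  top <- vals[o[seq_len(n_top)]]
  bottom <- vals[rev(o)[seq_len(n_bottom)]]
  if (sd(top) == 0 && sd(bottom) == 0 && mean(top) == mean(bottom)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(top, bottom, var.equal = FALSE)
  }
  structure(data.frame(property = property, mean_top = mean(top),
                       mean_bottom = mean(bottom),
                       t_statistic = unname(tt$statistic),
                       p_value = tt$p.value,
                       n_top = n_top, n_bottom = n_bottom,
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Pearson correlation with a fitted line
#'
#' Pearson r with a two-sided p-value from the t-distribution and the
#' least-squares line, as used for permeability-vs-toxicity and
#' cross-cell-type comparisons. Zero-variance input yields `r = NA` with
#' `degenerate = TRUE` rather than an error.
#'
#' @param x,y equal-length numeric vectors (n >= 3); incomplete pairs are
#'   dropped.
#' @return A list: `r`, `p_value`, `slope`, `intercept`, `n`, `degenerate`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = n, degenerate = TRUE))
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
  slope <- r * sd(y) / sd(x)
  list(r = r, p_value = p, slope = slope,
       intercept = mean(y) - slope * mean(x), n = n, degenerate = FALSE)
}

#' Descriptive screen report
#'
#' Bundles the standard descriptive analytics for one screen: toxicity
#' classes and counts, the four property comparisons between the top and
#' bottom 15 peptides, and the permeability-toxicity correlation.
#'
#' @param screen a `cpp_screen` data frame.
#' @param cutoffs a [thresholds()] object.
#' @param n_top,n_bottom group sizes for the property comparisons.
#' @return A list: `classes` (per-peptide data frame), `class_counts`,
#'   `comparisons` (4-row data frame), `perm_tox` (from [correlate()]).
#' @export
analyze_screen <- function(screen, cutoffs = thresholds(), n_top = 15L,
                           n_bottom = 15L) {
  tox <- toxicity_class(screen$max_od_pct, cutoffs$toxicity_cutoff_pct)
  profile <- property_profile(screen_peptides(screen))
  comparisons <- do.call(rbind, lapply(
    c("disorder_proxy", "pI", "net_charge_pH7", "gravy"),
    function(pr) group_compare(screen, pr, n_top, n_bottom,
                               profile = profile)))
  ok <- !is.na(screen$intensity_au) & !is.na(screen$max_od_pct)
  perm_tox <- if (sum(ok) >= 3L)
    correlate(log10(screen$intensity_au[ok]), screen$max_od_pct[ok])
  else NULL
  list(classes = data.frame(id = screen$id, toxicity = tox,
                            stringsAsFactors = FALSE),
       class_counts = c(cytotoxic = sum(tox == "cytotoxic", na.rm = TRUE),
                        safe = sum(tox == "safe", na.rm = TRUE),
                        unclassified = sum(is.na(tox))),
       comparisons = comparisons,
       perm_tox = perm_tox)
}
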