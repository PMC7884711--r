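#' Parameters of the synthetic screen generator
#'
#' The generator emulates a 98-peptide bacterial CPP screen: per-peptide
#' cationic composition bias, log10 penetration intensity driven positively
#' by net charge and negatively by hydropathy with Gaussian noise,
#' intensities clipped to the instrument-like range 13-4043 A.U., and
#' toxicity drawn independently of intensity (the screens this emulates
#' found no permeability-toxicity correlation). Defaults are the generator's
#' stated world and are not tuned per test; see the methods vignette.
#'
#' @param n_peptides library size (default 98).
#' @param len_range peptide length range, residues (default 5-24).
#' @param bias_range per-peptide K/R mixing-weight range (uniform draw).
#' @param beta0 baseline log10 intensity.
#' @param beta_charge effect per unit net charge on log10 intensity.
#' @param beta_gravy effect per GRAVY unit on log10 intensity.
#' @param sigma Gaussian noise sd on the log10 scale.
#' @param clip_range intensity clip range in A.U.
#' @param tox_base_pct,tox_sd_pct mean and sd of safe peptides' max-OD
#'   percentage (truncated-normal on [50, 107]).
#' @param tox_frac_cytotoxic fraction of cytotoxic peptides; exactly
#'   `round(n_peptides * tox_frac_cytotoxic)` peptides are drawn cytotoxic
#'   (uniform max-OD on [14, 50)), independent of intensity.
#' @param seed integer seed.
#' @return An object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_peptides = 98L, len_range = c(5L, 24L),
                              bias_range = c(0, 0.6), beta0 = 1.8,
                              beta_charge = 0.22, beta_gravy = -0.25,
                              sigma = 0.35, clip_range = c(13, 4043),
                              tox_base_pct = 90, tox_sd_pct = 12,
                              tox_frac_cytotoxic = 10 / 98, seed = 1L) {
  stopifnot(n_peptides >= 2L, sigma >= 0, all(clip_range > 0),
            clip_range[1] < clip_range[2],
            len_range[1] >= 1L, len_range[1] <= len_range[2],
            tox_frac_cytotoxic >= 0, tox_frac_cytotoxic <= 1)
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate a CPP screen with known ground truth
#'
#' Sequences are sampled residue-by-residue: with the peptide's bias weight
#' a residue is K or R (uniformly), otherwise uniform over the 20-letter
#' alphabet. The true log10 intensity is
#' `beta0 + beta_charge * net_charge(pH 7) + beta_gravy * GRAVY + N(0, sigma)`,
#' exponentiated and clipped to `clip_range`. Toxicity is drawn
#' independently of intensity.
#'
#' @param params a [simulation_params()] object.
#' @return A list with `screen` (a `cpp_screen` data frame) and `truth`
#'   (per-peptide data frame: `id`, `sequence`, `net_charge`, `gravy`,
#'   `linear_predictor`, `log10_intensity` (pre-clip, with noise),
#'   `clipped`, `cytotoxic`); `params` is attached as an attribute of
#'   `truth`.
#' @export
simulate_screen <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_peptides
  lens <- sample(seq(params$len_range[1], params$len_range[2]), n,
                 replace = TRUE)
  bias <- runif(n, params$bias_range[1], params$bias_range[2])
  seqs <- vapply(seq_len(n), function(i) {
    cationic <- runif(lens[i]) < bias[i]
    res <- ifelse(cationic, sample(c("K", "R"), lens[i], replace = TRUE),
                  sample(AA_ALPHABET, lens[i], replace = TRUE))
    paste(res, collapse = "")
  }, character(1))
  ids <- sprintf("syn_%03d", seq_len(n))
  peptides <- lapply(seq_len(n), function(i) validate_peptide(seqs[i], ids[i]))
  charge <- vapply(peptides, net_charge, numeric(1))
  grav <- vapply(peptides, gravy, numeric(1))
  lin <- params$beta0 + params$beta_charge * charge +
    params$beta_gravy * grav
  y_log <- lin + rnorm(n, sd = params$sigma)
  intensity <- pmin(pmax(10^y_log, params$clip_range[1]),
                    params$clip_range[2])
  clipped <- 10^y_log < params$clip_range[1] |
    10^y_log > params$clip_range[2]

  n_cyto <- round(n * params$tox_frac_cytotoxic)
  cyto <- logical(n)
  if (n_cyto > 0) cyto[sample.int(n, n_cyto)] <- TRUE
  max_od <- numeric(n)
  max_od[cyto] <- runif(sum(cyto), 14, 50)
  if (any(!cyto)) {  # truncated normal on [50, 107] via inverse CDF
    lo <- stats::pnorm(50, params$tox_base_pct, params$tox_sd_pct)
    hi <- stats::pnorm(107, params$tox_base_pct, params$tox_sd_pct)
    u <- runif(sum(!cyto), lo, hi)
    max_od[!cyto] <- stats::qnorm(u, params$tox_base_pct, params$tox_sd_pct)
  }

  screen <- data.frame(id = ids, sequence = seqs,
                       intensity_au = intensity, max_od_pct = max_od,
                       source = "manual", cell_type = "ecoli",
                       stringsAsFactors = FALSE)
  class(screen) <- c("cpp_screen", "data.frame")
  truth <- data.frame(id = ids, sequence = seqs, net_charge = charge,
                      gravy = grav, linear_predictor = lin,
                      log10_intensity = y_log, clipped = clipped,
                      cytotoxic = cyto, stringsAsFactors = FALSE)
  attr(truth, "params") <- params
  list(screen = screen, truth = truth)
}

#' Parameter-recovery check on a simulated screen
#'
#' Runs the full pipeline (featurize, transform, Pearson selection,
#' cross-validated forest) on a simulated screen and reports the
#' out-of-fold R2 against the noise ceiling `1 - sigma^2 / var(y)`, the best
#' R2 any model could reach given the injected noise. At default generator
#' parameters the pipeline is expected to recover at least 70% of that
#' ceiling.
#'
#' @param sim output of [simulate_screen()].
#' @param config a [model_config()]; the default uses 50 selected features.
#' @param k folds (default 10).
#' @param cutoffs a [thresholds()] object.
#' @return A list: `r_squared`, `rmse`, `accuracy_pct`, `noise_ceiling`,
#'   `ceiling_ratio`, `cv` (the full `cv_report`).
#' @export
recover_parameters <- function(sim, config = model_config(n_features = 50L),
                               k = 10L, cutoffs = thresholds()) {
  params <- attr(sim$truth, "params")
  stopifnot(inherits(params, "simulation_params"))
  X <- featurize_set(sim$screen)
  tr <- fit_transform(X, sim$screen$intensity_au)
  cv <- cross_validate(tr$X_t, tr$y_t, config, k = k, cutoffs = cutoffs)
  ceiling_ <- 1 - params$sigma^2 / var(tr$y_t)
  list(r_squared = cv$r_squared, rmse = cv$rmse,
       accuracy_pct = cv$accuracy_pct, noise_ceiling = ceiling_,
       ceiling_ratio = cv$r_squared / ceiling_, cv = cv)
}

#' @rdname simulate_screen
#' @param sim output of [simulate_screen()].
#' @param screen_path,truth_path output CSV paths (`truth_path` may be
#'   `NULL`).
#' @export
write_simulated_screen <- function(sim, screen_path, truth_path = NULL) {
  write_screen_table(sim$screen, screen_path)
  if (!is.null(truth_path))
    write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(screen_path)
}
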