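# Shared fixtures (generated in code, cached across test files) and
# independent brute-force oracles used by the property tests.

fixture_env <- new.env(parent = emptyenv())

get_sim <- function(n = 40L, seed = 11L) {
  key <- sprintf("sim_%d_%d", n, seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <-
      simulate_screen(simulation_params(n_peptides = n, seed = seed))
  fixture_env[[key]]
}

get_transformed <- function(n = 40L, seed = 11L) {
  key <- sprintf("tr_%d_%d", n, seed)
  if (is.null(fixture_env[[key]])) {
    sim <- get_sim(n, seed)
    X <- featurize_set(sim$screen)
    fixture_env[[key]] <- fit_transform(X, sim$screen$intensity_au)
  }
  fixture_env[[key]]
}

# direct-formula Pearson coefficient (oracle, independent of stats::cor)
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  s <- sqrt(sum(dx^2) * sum(dy^2))
  if (s == 0) 0 else sum(dx * dy) / s
}

# hand-written Welch t statistic and two-sided p (oracle)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Henderson-Hasselbalch net charge recomputed directly from the vendored
# pKa file (independent of net_charge())
charge_oracle <- function(sequence, pH) {
  pka <- read.delim(system.file("extdata", "pka_emboss.tsv",
                                package = "cppscreen"),
                    comment.char = "#", stringsAsFactors = FALSE)
  rows <- c("Nterm", "Cterm",
            strsplit(toupper(sequence), "")[[1]])
  rows <- rows[rows %in% pka$group]
  i <- match(rows, pka$group)
  sum(ifelse(pka$type[i] == "base",
             1 / (1 + 10^(pH - pka$pka[i])),
             -1 / (1 + 10^(pka$pka[i] - pH))))
}

random_test_peptide <- function(len) {
  validate_peptide(paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                len, replace = TRUE), collapse = ""),
                   sprintf("rnd%d", len))
}
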