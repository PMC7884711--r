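test_that("composition blocks satisfy their identities", {
  a <- aa_composition(validate_peptide("AAAA"))
  expect_equal(unname(a["AAC_A"]), 1)
  expect_equal(sum(a), 1)

  k <- aa_composition(validate_peptide("KLPVM"))
  expect_equal(unname(k[c("AAC_K", "AAC_L", "AAC_P", "AAC_V", "AAC_M")]),
               rep(0.2, 5))
  expect_equal(unname(aa_composition(validate_peptide("rr"))["AAC_R"]), 1)

  d <- dipeptide_composition(validate_peptide("ACAC"))
  expect_equal(unname(d["DPC_AC"]), 2 / 3)
  expect_equal(unname(d["DPC_CA"]), 1 / 3)
  expect_equal(sum(d), 1)
  expect_equal(sum(dipeptide_composition(validate_peptide("K"))), 0)

  set.seed(42)  # property: identities hold across random peptides
  for (len in c(1L, 2L, 5L, 24L)) {
    p <- random_test_peptide(len)
    expect_equal(sum(aa_composition(p)), 1, tolerance = 1e-9)
    if (len >= 2)
      expect_equal(sum(dipeptide_composition(p)), 1, tolerance = 1e-9)
  }
})

test_that("scale-average features are residue means and order-invariant", {
  aai <- load_aaindex()
  fa <- aaindex_features(validate_peptide("A"))
  expect_equal(unname(fa), unname(aai$values[, "A"]))
  fag <- aaindex_features(validate_peptide("AG"))
  expect_equal(unname(fag),
               unname((aai$values[, "A"] + aai$values[, "G"]) / 2))
  # permutation and case invariance
  expect_equal(aaindex_features(validate_peptide("KLPVM")),
               aaindex_features(validate_peptide("MVPLK")))
  expect_equal(featurize(validate_peptide("KLPVM")),
               featurize(validate_peptide("klpvm")))
})

test_that("featurize yields exactly 505 named features", {
  set.seed(7)
  for (len in c(1L, 5L, 24L)) {
    fv <- featurize(random_test_peptide(len))
    expect_length(fv, 505L)
    expect_false(anyNA(fv))
  }
  expect_error(validate_peptide("", "x"))
  X <- featurize_set(list(validate_peptide("KLPVM", "a"),
                          validate_peptide("RRR", "b")))
  expect_equal(dim(X), c(2L, 505L))
  expect_equal(rownames(X), c("a", "b"))
})

test_that("fit_transform: signed log + z-score, reusable params, log10 target", {
  tr <- get_transformed(40L)
  X_t <- tr$X_t
  # non-constant columns standardized; constant columns exactly zero
  sds <- apply(X_t, 2, sd)
  expect_equal(unname(colMeans(X_t)), rep(0, ncol(X_t)), tolerance = 1e-9)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-9))
  const_cols <- which(apply(X_t, 2, function(c) all(c == c[1])))
  expect_true(all(X_t[, const_cols] == 0))

  # stored params reproduce the training transform bit-for-bit
  sim <- get_sim(40L)
  X <- featurize_set(sim$screen)
  expect_identical(apply_transform(tr$params, X), X_t)

  # affine part inverts within 1e-9
  back <- sweep(sweep(X_t, 2, tr$params$scale, "*"), 2, tr$params$center, "+")
  expect_equal(back, sign(X) * log1p(abs(X)), tolerance = 1e-9)

  expect_equal(tr$y_t, log10(sim$screen$intensity_au))
  expect_equal(log10(4043), 3.6066, tolerance = 5e-4)
  expect_error(fit_transform(X, c(0, rep(1, 39))), "positive")
})

test_that("net charge matches the Henderson-Hasselbalch oracle and is monotone", {
  r9 <- validate_peptide("RRRRRRRRR")
  expect_equal(net_charge(r9, 7), charge_oracle("RRRRRRRRR", 7),
               tolerance = 1e-12)
  expect_equal(net_charge(r9, 7), 8.98, tolerance = 0.01)
  g5 <- validate_peptide("GGGGG")
  expect_equal(net_charge(g5, 7), -0.0241, tolerance = 1e-3)
  expect_equal(net_charge(g5, 7), charge_oracle("GGGGG", 7),
               tolerance = 1e-12)

  set.seed(13)  # property: charge non-increasing in pH, limits ordered
  for (i in 1:5) {
    p <- random_test_peptide(sample(3:20, 1))
    ph <- sort(runif(6, 0, 14))
    ch <- vapply(ph, function(x) net_charge(p, x), numeric(1))
    expect_true(all(diff(ch) <= 1e-12))
    expect_gt(net_charge(p, 0), net_charge(p, 14))
  }
})

test_that("isoelectric point is the net-charge zero crossing", {
  pka <- load_pka_table()
  g5 <- validate_peptide("GGGGG")
  mid <- (pka$pka[pka$group == "Nterm"] + pka$pka[pka$group == "Cterm"]) / 2
  expect_equal(isoelectric_point(g5), mid, tolerance = 1e-3)

  r9 <- validate_peptide("RRRRRRRRR")
  expect_gt(isoelectric_point(r9), 10)

  set.seed(29)
  for (i in 1:5) {
    p <- random_test_peptide(sample(3:20, 1))
    pi_ <- isoelectric_point(p)
    expect_lt(abs(net_charge(p, pi_)), 1e-3)
    # dense-grid brute-force zero search agrees within 1e-3
    grid <- seq(0, 14, by = 5e-4)
    ch <- vapply(grid, function(x) net_charge(p, x), numeric(1))
    brute <- grid[which.max(ch <= 0)]
    expect_equal(pi_, brute, tolerance = 1e-3)
    # appending an arginine never lowers the pI
    pr <- validate_peptide(paste0(p$sequence, "R"))
    expect_gte(isoelectric_point(pr) - pi_, -1e-4)
  }
})

test_that("gravy and disorder proxy", {
  expect_equal(gravy(validate_peptide("AAA")), 1.8)
  expect_equal(gravy(validate_peptide("R")), -4.5)
  expect_equal(gravy(validate_peptide("KLPVM")),
               mean(c(-3.9, 3.8, -1.6, 4.2, 1.9)))
  expect_equal(gravy(validate_peptide("KLPVM")),
               gravy(validate_peptide("MVPLK")))

  set.seed(5)
  for (i in 1:5) {
    d <- disorder_proxy(random_test_peptide(sample(1:24, 1)))
    expect_true(d >= 0 && d <= 1)
  }
  expect_gt(disorder_proxy(validate_peptide("RRRRRRRRR")),
            disorder_proxy(validate_peptide("IIIIIIIII")))
})

test_that("property_profile aggregates per peptide", {
  prof <- property_profile(list(validate_peptide("KLPVM", "a"),
                                validate_peptide("RRRRRRRRR", "b")))
  expect_equal(prof$id, c("a", "b"))
  expect_equal(prof$length, c(5L, 9L))
  expect_true(all(prof$pI >= 0 & prof$pI <= 14))
  expect_gt(prof$net_charge_pH7[2], prof$net_charge_pH7[1])
})
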