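test_that("net charge follows Henderson-Hasselbalch summation", {
  expect_equal(net_charge("GG", include_termini = FALSE), 0)
  expect_gt(net_charge("KK"), net_charge("K"))
  expect_equal(net_charge("RQIKIWFQNRRMKWKK"),
               oracle_net_charge("RQIKIWFQNRRMKWKK", 7.4), tolerance = 1e-9)
  set.seed(3)
  for (i in 1:10) {
    p <- random_peptide(sample(6:15, 1))
    pH <- runif(1, 1, 13)
    expect_equal(net_charge(p, pH), oracle_net_charge(p, pH),
                 tolerance = 1e-9, info = p)
  }
  # monotone non-increasing in pH on a 0.5-unit grid
  grid <- seq(0, 14, by = 0.5)
  for (p in c("ACDEFGHIK", "KKKKKK", "DDEEYY")) {
    ch <- vapply(grid, function(x) net_charge(p, x), numeric(1))
    expect_true(all(diff(ch) <= 1e-12), info = p)
  }
})

test_that("isoelectric point zeroes the charge and matches a grid scan", {
  set.seed(5)
  for (i in 1:12) {
    p <- random_peptide(sample(6:15, 1))
    pI <- isoelectric_point(p)
    expect_lt(abs(net_charge(p, pI)), 1e-3)
  }
  expect_gt(isoelectric_point("KKKKKKKKK"), isoelectric_point("DDDDDDDDD"))
  # exhaustive grid-scan oracle
  grid <- seq(0, 14, by = 1e-4)
  ch <- abs(vapply(grid, function(x) net_charge("ACDEFGHIK", x), numeric(1)))
  expect_equal(isoelectric_point("ACDEFGHIK"), grid[which.min(ch)],
               tolerance = 1e-3)
})

test_that("Eisenberg mean is a table-lookup average, permutation-invariant", {
  sc <- eisenberg_scale()
  expect_equal(eisenberg_mean("I"), sc[["I"]])
  expect_equal(eisenberg_mean("AI"), (sc[["A"]] + sc[["I"]]) / 2)
  set.seed(8)
  p <- random_peptide(12)
  shuf <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(eisenberg_mean(p), eisenberg_mean(shuf), tolerance = 1e-12)
})

test_that("hydrophobic moment matches closed forms and trig summation", {
  sc <- eisenberg_scale()
  expect_equal(hydrophobic_moment("W"), abs(sc[["W"]]))
  expect_equal(hydrophobic_moment("GG"), sc[["G"]] * cos(50 * pi / 180),
               tolerance = 1e-10)
  set.seed(12)
  for (i in 1:10) {
    p <- random_peptide(sample(5:15, 1))
    h <- sc[strsplit(p, "")[[1]]]
    ang <- seq_along(h) * 100 * pi / 180
    mu <- sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(h)
    expect_equal(hydrophobic_moment(p), mu, tolerance = 1e-10, info = p)
    # phase invariance: a constant angular offset leaves the magnitude alone
    off <- runif(1, 0, 2 * pi)
    mu_off <- sqrt(sum(h * sin(ang + off))^2 + sum(h * cos(ang + off))^2) /
      length(h)
    expect_equal(mu, mu_off, tolerance = 1e-10)
  }
})

test_that("aromaticity, aliphatic and instability indices hit forced values", {
  expect_equal(aromaticity("FWY"), 1.0)
  expect_equal(aromaticity("AAAA"), 0.0)
  expect_equal(aromaticity("FAAA"), 0.25)
  expect_equal(aliphatic_index("AAAA"), 100.0)
  expect_equal(aliphatic_index("VVVV"), 290.0)
  expect_equal(aliphatic_index("GGGG"), 0.0)
  expect_equal(instability_index("A"), 0.0)
  dw <- pepgen:::diwv_table()
  # II = (10/L) * sum of dipeptide weights
  expect_equal(instability_index("AC"), (10 / 2) * dw["A", "C"],
               ignore_attr = TRUE)
  expect_equal(instability_index("ACD"),
               (10 / 3) * (dw["A", "C"] + dw["C", "D"]), ignore_attr = TRUE)
})

test_that("descriptor table agrees with a two-pass statistics oracle", {
  set.seed(17)
  x <- corpus(sprintf("p%02d", 1:30),
              vapply(sample(9:15, 30, TRUE), random_peptide, character(1)))
  d <- describe_peptides(x)
  expect_equal(nrow(d), 30L)
  expect_true(all(is.finite(as.matrix(
    d[, c("charge", "eisenberg_hydrophobicity", "hydrophobic_moment",
          "length", "isoelectric_point", "aromaticity", "charge_density",
          "aliphatic_index", "instability_index", "hydrophobic_ratio")]
  ))))
  # column means/SDs vs independent streaming oracle
  mu <- vapply(d$sequence, pepgen::hydrophobic_moment, numeric(1))
  expect_equal(mean(d$hydrophobic_moment), sum(mu) / length(mu),
               tolerance = 1e-9)
  expect_equal(sd(d$hydrophobic_moment),
               sqrt(oracle_two_pass_var(mu)), tolerance = 1e-9)
  # permuting the corpus permutes rows identically
  perm <- sample(30)
  expect_equal(describe_peptides(x[perm, ]), d[perm, ],
               ignore_attr = TRUE)
  # permutation-invariant descriptors stay put under residue shuffles
  p <- d$sequence[1]
  shuf <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(net_charge(shuf), net_charge(p), tolerance = 1e-12)
  expect_equal(aromaticity(shuf), aromaticity(p))
  expect_equal(aliphatic_index(shuf), aliphatic_index(p))
})

test_that("min-max scaling maps the reference into [0,1] and inverts exactly", {
  set.seed(19)
  x <- corpus(sprintf("p%02d", 1:20),
              vapply(sample(9:15, 20, TRUE), random_peptide, character(1)))
  d <- describe_peptides(x)
  params <- fit_scaling(d)
  s <- apply_scaling(d, params)
  for (f in params$feature) {
    expect_gte(min(s[[f]]), 0)
    expect_lte(max(s[[f]]), 1)
    expect_equal(min(s[[f]]), 0)
    expect_equal(max(s[[f]]), 1)
  }
  back <- apply_scaling(s, params, invert = TRUE)
  for (f in params$feature) {
    expect_equal(back[[f]], d[[f]], tolerance = 1e-12)
  }
  # constant column dropped with a warning
  d2 <- d
  d2$length <- 12
  expect_warning(p2 <- fit_scaling(d2), "constant")
  expect_false("length" %in% p2$feature)
  # single-row reference: every column constant
  expect_warning(fit_scaling(d[1, ]), "constant")
})

test_that("centroid distances equal the naive per-row norm oracle", {
  set.seed(23)
  ref <- describe_peptides(
    corpus(sprintf("r%02d", 1:50),
           vapply(sample(9:15, 50, TRUE), random_peptide, character(1)))
  )
  qry <- describe_peptides(
    corpus(sprintf("q%02d", 1:50),
           vapply(sample(9:15, 50, TRUE), random_peptide, character(1)))
  )
  params <- fit_scaling(ref)
  rs <- apply_scaling(ref, params)
  qs <- apply_scaling(qry, params)
  out <- euclidean_to_centroid(qs, rs, params$feature)
  centroid <- colMeans(as.matrix(rs[params$feature]))
  naive <- apply(as.matrix(qs[params$feature]), 1,
                 function(r) sqrt(sum((r - centroid)^2)))
  expect_equal(out$centroid_distance, unname(naive), tolerance = 1e-12)
  expect_equal(attr(out, "mean"), mean(naive), tolerance = 1e-12)
  # a query equal to the centroid is at distance zero
  q0 <- qs[1, ]
  for (f in params$feature) q0[[f]] <- centroid[[f]]
  expect_equal(euclidean_to_centroid(q0, rs,
                                     params$feature)$centroid_distance, 0)
  expect_error(euclidean_to_centroid(qs["id"], rs),
               class = "pepgen_schema_error")
})

test_that("Welch's t-test matches the Welch-Satterthwaite formula", {
  same <- c(1, 2, 3, 4, 5)
  res0 <- welch_ttest(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 4, 6, 8, 10)
  res <- welch_ttest(a, b)
  orc <- oracle_welch(a, b)
  expect_equal(res$t, orc$t, tolerance = 1e-9)
  expect_equal(res$df, orc$df, tolerance = 1e-9)
  expect_equal(res$p, orc$p, tolerance = 1e-9)
  # antisymmetry
  swap <- welch_ttest(b, a)
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  expect_error(welch_ttest(1, c(1, 2)), class = "pepgen_stat_error")
  expect_error(welch_ttest(c(1, 1), c(2, 2)), class = "pepgen_stat_error")
})

test_that("random baseline is uniform over residues and seeded", {
  expect_equal(nrow(random_baseline(0)), 0L)
  expect_identical(random_baseline(25, seed = 6), random_baseline(25, seed = 6))
  big <- random_baseline(10000, seed = 42)
  freqs <- table(strsplit(paste(big$sequence, collapse = ""), "")[[1]])
  freqs <- freqs / sum(freqs)
  expect_length(freqs, 20L)
  expect_true(all(abs(freqs - 0.05) < 0.01))
})

test_that("helical baseline is amphipathic by construction", {
  hel <- helical_baseline(200, seed = 9)
  expect_identical(hel, helical_baseline(200, seed = 9))
  mu_h <- vapply(hel$sequence, hydrophobic_moment, numeric(1))
  expect_true(all(mu_h > 0))
  rnd <- random_baseline(200, seed = 9)
  mu_r <- vapply(rnd$sequence, hydrophobic_moment, numeric(1))
  expect_gt(mean(mu_h), mean(mu_r))
})
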