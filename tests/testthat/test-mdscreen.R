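test_that("multi-model PDB round-trips and enforces a consistent roster", {
  traj <- synth_trajectory(c(2, 0, 3), n_residues = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_equal(back$atoms$chain, traj$atoms$chain)
  expect_equal(back$atoms$resid, traj$atoms$resid)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)

  # single-model file reads as one frame
  one <- synth_trajectory(1, n_residues = 3)
  lines <- readLines({ write_trajectory(one, f); f })
  writeLines(lines[!grepl("^(MODEL|ENDMDL)", lines)], f)
  expect_equal(dim(read_trajectory(f)$coords)[1], 1L)

  # roster mismatch names the offending model
  write_trajectory(traj, f)
  lines <- readLines(f)
  atom_lines <- grep("^ATOM", lines)
  second_model_first_atom <- atom_lines[9]   # 8 atoms per model
  writeLines(lines[-second_model_first_atom], f)
  err <- expect_error(read_trajectory(f), class = "pepgen_format_error")
  expect_match(conditionMessage(err), "2")
})

test_that("PDB coordinates agree with the bio3d reader", {
  skip_if_not_installed("bio3d")
  traj <- synth_trajectory(c(1, 3), n_residues = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  ours <- read_trajectory(f)
  ref <- bio3d::read.pdb(f, multi = TRUE)
  expect_equal(dim(ref$xyz)[1], 2L)
  expect_equal(matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE),
               ours$coords[1, , ], tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("residue contacts respect the closed 4 A threshold", {
  mk <- function(d) {
    atoms <- tibble::tibble(name = "CA", resname = "ALA",
                            chain = c("A", "B"), resid = c(1L, 1L),
                            element = "C")
    coords <- array(0, dim = c(1, 2, 3))
    coords[1, 2, 1] <- d
    structure(list(atoms = atoms, coords = coords),
              class = "pep_trajectory")
  }
  expect_equal(nrow(residue_contacts(mk(3.9), 1, "A", "B")), 1L)
  expect_equal(nrow(residue_contacts(mk(4.0), 1, "A", "B")), 1L)
  expect_equal(nrow(residue_contacts(mk(4.1), 1, "A", "B")), 0L)
  expect_error(residue_contacts(mk(3), 1, "A", "Z"),
               class = "pepgen_lookup_error")
})

test_that("residue contacts equal the all-pairs brute-force oracle", {
  set.seed(33)
  for (i in 1:20) {
    traj <- random_toy_traj()
    got <- residue_contacts(traj, 1, "A", "B")
    want <- oracle_contacts(traj, 1, "A", "B")
    got_m <- as.matrix(got)
    dimnames(got_m) <- NULL
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(got_m, want, ignore_attr = TRUE, info = paste("frame", i))
    # hydrogen inclusion flag widens (or keeps) the pair set
    got_h <- residue_contacts(traj, 1, "A", "B", heavy_only = FALSE)
    expect_gte(nrow(got_h), nrow(got))
  }
})

test_that("contact series reproduce engineered schedules frame by frame", {
  sched <- c(2L, 2L, 2L)
  traj <- synth_trajectory(sched, n_residues = 5)
  s <- contact_series(traj, "A", "B")
  expect_equal(s$contacts, sched)
  # per-frame oracle recomputation on a 20-frame synthetic trajectory
  sched2 <- sample(0:5, 20, replace = TRUE)
  traj2 <- synth_trajectory(sched2, n_residues = 5)
  s2 <- contact_series(traj2, "A", "B")
  oracle <- vapply(seq_along(sched2), function(f)
    nrow(oracle_contacts(traj2, f, "A", "B")), integer(1))
  expect_equal(s2$contacts, oracle)
  # positive-residue selection on a peptide without R/K/H errors out
  expect_error(contact_series(traj, "A", "B", selection = "positive"),
               class = "pepgen_config_error")
})

test_that("contact variance is the unbiased sample variance", {
  expect_equal(contact_variance(c(5, 5, 5)), 0)
  expect_equal(contact_variance(c(1, 2, 3, 4, 5)), 2.5)
  expect_error(contact_variance(7), class = "pepgen_stat_error")
  set.seed(44)
  x <- rpois(100, 6)
  expect_equal(contact_variance(x), oracle_two_pass_var(x),
               tolerance = 1e-10)
  # invariant under frame reordering; scales by c^2
  expect_equal(contact_variance(sample(x)), contact_variance(x))
  expect_equal(contact_variance(3 * x), 9 * contact_variance(x),
               tolerance = 1e-10)
  expect_equal(contact_variance(x, population = TRUE),
               contact_variance(x) * 99 / 100)
})

test_that("distance statistics track per-frame minimum heavy-atom distances", {
  traj <- synth_trajectory(c(1, 0), n_residues = 3)
  # residue A1-B1: 3.5 A in frame 1, 8 A in frame 2
  st <- distance_stats(traj, c("A", 1), c("B", 1))
  expect_equal(st$mean, mean(c(3.5, 8)))
  expect_equal(st$sd, sd(c(3.5, 8)))
  static <- synth_trajectory(c(2, 2), n_residues = 3)
  st0 <- distance_stats(static, c("A", 1), c("B", 1))
  expect_equal(st0$sd, 0)
  expect_equal(st0$mean, 3.5)
  expect_error(distance_stats(traj, c("A", 99), c("B", 1)),
               class = "pepgen_lookup_error")
  # brute-force oracle on a random 10-frame trajectory
  set.seed(55)
  rt <- random_toy_traj(n_atoms = 18, n_frames = 10)
  got <- distance_stats(rt, c("A", 2), c("B", 2))
  per_frame <- vapply(1:10, function(f) {
    ia <- which(rt$atoms$chain == "A" & rt$atoms$resid == 2 &
                  rt$atoms$element != "H")
    ib <- which(rt$atoms$chain == "B" & rt$atoms$resid == 2 &
                  rt$atoms$element != "H")
    min(vapply(ia, function(i) min(vapply(ib, function(j)
      sqrt(sum((rt$coords[f, i, ] - rt$coords[f, j, ])^2)),
      numeric(1))), numeric(1)))
  }, numeric(1))
  expect_equal(got$mean, mean(per_frame), tolerance = 1e-10)
  expect_equal(got$sd, sd(per_frame), tolerance = 1e-10)
})

test_that("screening applies closed cut-offs and never drops records", {
  rec <- tibble::tibble(
    peptide_id = c("a", "b", "c", "d"),
    contact_variance = c(3.0, 3.01, 0.5, 1.0),
    binding_energy = c(-20, -25, -10, NA)
  )
  out <- screen_peptides(rec)
  expect_equal(nrow(out), 4L)
  expect_equal(out$passes_variance, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$passes_energy, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$passes_both, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(out$energy_missing[4])

  none <- screen_peptides(dplyr::mutate(rec, contact_variance = 99))
  expect_equal(sum(none$passes_variance), 0L)
  expect_equal(nrow(none), 4L)
})

test_that("planted 127-record fixture yields exactly 57 variance passes", {
  rec <- synth_contact_records(127, 57, cutoff = 3, seed = 2024)
  out <- screen_peptides(rec)
  expect_equal(sum(out$passes_variance), 57L)
  expect_equal(nrow(out), 127L)
})

test_that("top-k ranking follows energy, then variance, then id", {
  rec <- tibble::tibble(
    peptide_id = c("p1", "p2", "p3"),
    contact_variance = c(1, 2, 0.5),
    binding_energy = c(-18, -22, -18)
  )
  top <- rank_top_k(screen_peptides(rec), k = 20)
  expect_equal(top$peptide_id, c("p2", "p3", "p1"))
  expect_equal(top$rank, 1:3)

  set.seed(66)
  rec2 <- tibble::tibble(
    peptide_id = sprintf("r%02d", 1:30),
    contact_variance = round(runif(30, 0, 2), 1),
    binding_energy = -sample(seq(17, 26, 0.5), 30, replace = TRUE)
  )
  scr <- screen_peptides(rec2)
  top2 <- rank_top_k(scr, k = 10)
  # full-sort oracle
  ord <- order(-abs(rec2$binding_energy), rec2$contact_variance,
               rec2$peptide_id)
  expect_equal(top2$peptide_id, rec2$peptide_id[ord][1:10])
  expect_error(rank_top_k(scr, k = 0), class = "pepgen_config_error")
})

test_that("cell-penetrating peptide fusion is a plain N-terminal prefix", {
  expect_equal(fuse_cpp("AAA"), "RQIKIWFQNRRMKWKKAAA")
  expect_equal(fuse_cpp("AAA", cpp = ""), "AAA")
  expect_equal(nchar(fuse_cpp("ACDEFGHIK")), 16 + 9)
  expect_error(fuse_cpp("AAA", cpp = "ZZZ"),
               class = "pepgen_validation_error")
})
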