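test_that("read_structure retains heavy atoms and collects HET codes", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(f, resnos = 1)
  s <- read_structure(f, chain = "A")
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atoms), 5)
  expect_length(s$het_codes, 0)

  het <- c(
    pdb_line(100, "PB", "GDP", "A", 200, 1, 1, 1, elem = "P", record = "HETATM"),
    pdb_line(101, "MG", "MG", "A", 201, 2, 2, 2, elem = "MG", record = "HETATM")
  )
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(f2, resnos = 1:2, het_lines = het)
  s2 <- read_structure(f2, chain = "A")
  expect_true("GDP" %in% s2$het_codes)
  expect_setequal(s2$het_codes, c("GDP", "MG"))
})

test_that("read_structure drops hydrogens and resolves altlocs by occupancy", {
  extra <- c(
    pdb_line(90, "H", "ALA", "A", 1, 0, 0.5, 1, elem = "H"),
    # two altlocs of residue 9 CA: B has higher occupancy and must win
    pdb_line(91, "CA", "ALA", "A", 9, 10, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(92, "CA", "ALA", "A", 9, 11, 0, 0, occ = 0.6, alt = "B"),
    # tie at residue 10: first in file wins
    pdb_line(93, "CA", "ALA", "A", 10, 20, 0, 0, occ = 0.5, alt = "A"),
    pdb_line(94, "CA", "ALA", "A", 10, 21, 0, 0, occ = 0.5, alt = "B")
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(f, resnos = 1, extra_lines = extra)
  s <- read_structure(f, chain = "A")
  expect_false(any(s$atoms$elem == "H"))
  expect_equal(s$atoms$x[s$atoms$resno == 9], 11)
  expect_equal(s$atoms$x[s$atoms$resno == 10], 20)
})

test_that("read_structure errors name missing chains and bad lines", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(f, resnos = 1:2, chain = "B")
  expect_error(read_structure(f, chain = "Z"), "available chains.*B")
  s <- read_structure(f, chain = "B")
  expect_equal(unique(s$atoms$chain), "B")

  bad <- readLines(f)
  bad[3] <- paste0(substr(bad[3], 1, 30), "  xx.xxx", substr(bad[3], 39, nchar(bad[3])))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_structure(f2, chain = "B"), "line 3")
})

test_that("write/read round trip preserves coordinates to 3 decimals", {
  set.seed(11)
  cs <- noisy_coordset(matrix(rnorm(30, sd = 5), 10, 3), 2, 0.1)
  s <- calpha_structure(cs, 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f, chain = "A")
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("nucleotide state classification follows the ligand map", {
  expect_equal(classify_nucleotide_state(c("GNP", "MG")), "GTP")
  expect_equal(classify_nucleotide_state(c("MG")), "APO")
  expect_equal(classify_nucleotide_state(character(0)), "APO")
  expect_equal(classify_nucleotide_state(c("GTP", "GDP")), "UNKNOWN")
  expect_equal(classify_nucleotide_state(c("GSP")), "GTP")
  # pure function of het_codes and map: custom map overrides
  expect_equal(classify_nucleotide_state("XYZ", ligand_map = c(XYZ = "GTP")), "GTP")
})

test_that("extract_calpha intersects shared C-alpha positions in order", {
  mk <- function(resnos) {
    f <- tempfile(fileext = ".pdb")
    write_test_pdb(f, resnos = resnos)
    on.exit(unlink(f))
    read_structure(f, chain = "A")
  }
  s1 <- mk(1:20); s2 <- mk(3:25); s3 <- mk(c(3:10, 12:22))
  cs <- extract_calpha(list(s1, s2), states = c("APO", "APO"))
  expect_equal(cs$labels, as.character(3:20))
  cs3 <- extract_calpha(list(s1, s2, s3), states = rep("APO", 3))
  expect_equal(cs3$labels, as.character(c(3:10, 12:20)))
  cs_clip <- extract_calpha(list(s1, s2), residue_range = c(5, 8),
                            states = c("APO", "APO"))
  expect_equal(cs_clip$labels, as.character(5:8))
  expect_error(extract_calpha(list(mk(1:5), mk(50:55)),
                              states = c("APO", "APO")), "no shared")
})

test_that("superpose recovers rigid motions and refuses degenerate cores", {
  set.seed(21)
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  fit <- superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$xyz, X, tolerance = 1e-10)

  R <- random_rotation()
  Y <- X %*% t(R) + matrix(rep(c(3, -2, 7), each = 10), 10)
  fit2 <- superpose(Y, X)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit2$R), 1, tolerance = 1e-9)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line + 1), "degenerate")
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("superpose attains the global rigid-motion minimum", {
  set.seed(22)
  for (rep in 1:5) {
    X <- matrix(rnorm(30, sd = 3), 10, 3)
    Y <- X + matrix(rnorm(30, sd = 1), 10, 3)
    ours <- superpose(Y, X)$rmsd
    # independent cross-check
    expect_equal(ours,
                 bio3d::rmsd(as.numeric(t(X)), as.numeric(t(Y)), fit = TRUE),
                 tolerance = 1e-3)
    # no sampled rotation+optimal translation beats the returned fit
    Xc <- sweep(X, 2, colMeans(X))
    Yc <- sweep(Y, 2, colMeans(Y))
    grid_best <- min(vapply(1:400, function(i) {
      sqrt(mean(rowSums((Yc %*% t(random_rotation()) - Xc)^2)))
    }, numeric(1)))
    expect_lte(ours, grid_best + 1e-9)
  }
})

test_that("superpose RMSD is invariant to rigid motions of the mobile set", {
  set.seed(23)
  X <- matrix(rnorm(36, sd = 3), 12, 3)
  Y <- X + matrix(rnorm(36, sd = 0.8), 12, 3)
  base <- superpose(Y, X)$rmsd
  for (i in 1:5) {
    Y2 <- Y %*% t(random_rotation()) + matrix(rep(rnorm(3, sd = 10), each = 12), 12)
    expect_equal(superpose(Y2, X)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("pairwise_rmsd is symmetric, zero-diagonal and self-consistent", {
  set.seed(24)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  ident <- noisy_coordset(base, 3, 0)
  expect_lt(max(pairwise_rmsd(ident)), 1e-9)

  cs <- noisy_coordset(base, 4, 0.7)
  M <- pairwise_rmsd(cs)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(M[i, j],
                 superpose(matrix(cs$coords[i, ], ncol = 3, byrow = TRUE),
                           matrix(cs$coords[j, ], ncol = 3, byrow = TRUE))$rmsd)
  }
  # triangle inequality
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(M[i, j], M[i, k] + M[k, j] + 1e-9)
})

test_that("superpose_ensemble brings members into a common frame", {
  set.seed(25)
  sp <- synthetic_spec(n_residues = 40, n_per_state = c(5, 5), seed = 9)
  cs <- make_two_state_ensemble(sp)
  # scatter by random rigid motions, then recover
  scattered <- cs
  for (i in seq_len(nrow(cs$coords))) {
    xyz <- matrix(cs$coords[i, ], ncol = 3, byrow = TRUE)
    xyz <- xyz %*% t(random_rotation()) + matrix(rep(rnorm(3, sd = 20), each = nrow(xyz)), nrow(xyz))
    scattered$coords[i, ] <- as.numeric(t(xyz))
  }
  fitted <- superpose_ensemble(scattered)
  d <- pairwise_rmsd(fitted)
  expect_equal(max(abs(d - pairwise_rmsd(cs))), 0, tolerance = 1e-6)
  # after superposition, raw coordinate spread matches fitted RMSD scale
  expect_lt(sqrt(mean((fitted$coords[1, ] - fitted$coords[2, ])^2) * 3),
            d[1, 2] + 0.1)
})

test_that("ensemble manifests round-trip through the synthetic writer", {
  dir <- withr::local_tempdir()
  sp <- synthetic_spec(n_residues = 30, n_per_state = c(3, 3), seed = 4)
  manifest <- write_synthetic_benchmark(sp, dir)
  ens <- read_ensemble_manifest(manifest)
  expect_length(ens$structures, 6)
  expect_equal(ens$states, rep(c("GDP", "GTP"), each = 3))
  cs0 <- make_two_state_ensemble(sp)
  cs1 <- extract_calpha(ens$structures, states = ens$states)
  expect_equal(cs1$coords, cs0$coords, tolerance = 1e-3, ignore_attr = TRUE)
})
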