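# Structure model: PDB parsing, charges, helical filament construction,
# native-contact detection, archive round trips.

test_that("load_structure parses beads, flags and ligand heavy atoms", {
  pdb <- tempfile(fileext = ".pdb")
  res <- rbind(
    toy_residue("A", 1, "ALA", 0, 0, 0),
    toy_residue("A", 2, "GLY", 3.8, 0, 0),
    toy_residue("A", 3, "ASP", 7.6, 0, 0))
  het <- data.frame(name = c("O1B", "O2B", "O3B", "PB", "MG"),
                    resid = c("ADP", "ADP", "ADP", "ADP", "MG"),
                    chain = "A", resno = 900:904,
                    x = 0:4, y = 5, z = 5, stringsAsFactors = FALSE)
  write_toy_pdb(pdb, res, het)

  ref <- load_structure(pdb, flexible_regions = list(2))
  expect_equal(nrow(ref$beads), 3L)
  expect_equal(ref$beads$x, c(0, 3.8, 7.6))
  expect_equal(ref$beads$flexible, c(FALSE, TRUE, FALSE))
  # ligand atoms = non-hydrogen HETATM count (independent text scan)
  n_het <- sum(grepl("^HETATM", readLines(pdb)))
  expect_equal(nrow(ref$ligand), n_het)
  # charges: ADP oxygens -1, Mg +2, Asp bead -1
  expect_equal(sum(ref$ligand$charge[ref$ligand$parent == "ADP"]), -3)
  expect_equal(ref$ligand$charge[ref$ligand$parent == "Mg"], 2)
  expect_equal(ref$beads$charge, c(0, 0, -1))

  expect_error(load_structure(pdb, flexible_regions = list(9)),
               "outside sequence")
})

test_that("load_structure reports residues without C-alpha", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CB  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "END"), pdb)
  expect_error(load_structure(pdb), "missing C-alpha.*A:2")
})

test_that("charge assignment follows the interface electrostatics rules", {
  xyz <- cbind(3.8 * (0:4), 0, 0)
  beads <- data.frame(chain = "A", resno = 1:5,
                      resid = c("ASP", "GLU", "LYS", "ARG", "HIS"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  ref <- assign_charges(reference_structure(beads))
  expect_equal(ref$beads$charge, c(-1, -1, 1, 1, 0.5))
  ref2 <- assign_charges(reference_structure(beads),
                         charge_options(q_his = 0.1))
  expect_equal(ref2$beads$charge[5], 0.1)
  beads$resid <- "GLY"
  expect_equal(assign_charges(reference_structure(beads))$beads$charge,
               rep(0, 5))
  beads$resid[1] <- "XYZ"
  expect_warning(assign_charges(reference_structure(beads)), "unknown")
})

test_that("helical parameters give the 13-subunit repeat exactly", {
  hp <- helical_params()
  expect_identical(hp$repeat_length_nm, 13 * 2.759)
  expect_equal(hp$repeat_length_nm, 35.867)
  expect_equal(hp$net_twist_deg, 3.2, tolerance = 1e-12)
})

test_that("build_filament applies the screw transform per subunit", {
  beads <- data.frame(chain = "F", resno = 1:2, resid = "GLY",
                      x = c(5, 8), y = c(0, 0), z = c(0, 1))
  sub <- reference_structure(beads, label = "actin_subunit")

  # n = 1: identity
  f1 <- build_filament(sub, 1)
  expect_equal(f1$beads[, c("x", "y", "z")], sub$beads[, c("x", "y", "z")])

  # n = 2 with 180 deg / 1 nm: second subunit rotated and lifted
  f2 <- build_filament(sub, 2, helical_params(180, 1, 2))
  s2 <- f2$beads[f2$beads$subunit == 2, ]
  expect_equal(s2$x, -beads$x, tolerance = 1e-12)
  expect_equal(s2$y, beads$y, tolerance = 1e-12)
  expect_equal(s2$z, beads$z + 10, tolerance = 1e-12)

  # defaults: subunit-k centroid z = k * rise + subunit-0 centroid z (exact)
  f <- build_filament(sub, 5)
  cz <- tapply(f$beads$z, f$beads$subunit, mean)
  expect_equal(as.numeric(diff(cz)), rep(27.59, 4), tolerance = 1e-12)
  expect_error(build_filament(sub, 0), "n must be")
})

test_that("native pair rule: 4.5 A heavy-atom cutoff with sequence gate", {
  mk <- function(gap) {
    # residues 1 and 11 carry side-chain atoms `gap` apart; their C-alphas
    # are 10 A apart and all other residues are far away
    res <- do.call(rbind, lapply(1:11, function(i) {
      if (i == 1)
        toy_residue("A", i, "ALA", 0, 0, 0,
                    data.frame(name = "CB", x = 0, y = 1.5, z = 0))
      else if (i == 11)
        toy_residue("A", i, "ALA", 10, 0, 0,
                    data.frame(name = "CB", x = 0, y = 1.5 + gap, z = 0))
      else toy_residue("A", i, "ALA", 0, 0, 50 * i)
    }))
    pdb <- tempfile(fileext = ".pdb")
    write_toy_pdb(pdb, res)
    build_topology(load_structure(pdb))
  }
  close_topo <- mk(4.4)
  far_topo <- mk(4.6)
  pair_in <- function(topo, i, j)
    !is.null(topo$native) && any(topo$native$i == i & topo$native$j == j)
  expect_true(pair_in(close_topo, 1, 11))
  expect_false(pair_in(far_topo, 1, 11))
  # r0 is the C-alpha - C-alpha distance
  r0 <- close_topo$native$r0[close_topo$native$i == 1 &
                               close_topo$native$j == 11]
  expect_equal(r0, 10, tolerance = 1e-9)
})

test_that("native detection matches a brute-force all-pairs oracle", {
  set.seed(4)
  xyz <- motorscape:::.bead_helix(10)
  # pseudo side-chain atoms push some pairs under the cutoff
  res <- do.call(rbind, lapply(1:10, function(i)
    toy_residue("A", i, "ALA", xyz[i, 1], xyz[i, 2], xyz[i, 3],
                data.frame(name = "CB", x = xyz[i, 1] * 1.3,
                           y = xyz[i, 2] * 1.3, z = xyz[i, 3]))))
  pdb <- tempfile(fileext = ".pdb")
  write_toy_pdb(pdb, res)
  ref <- load_structure(pdb)
  topo <- build_topology(ref, cutoff = 4.5, min_seq_sep = 4)

  # independent O(n^2) scan over all heavy-atom pairs
  h <- ref$heavy
  oracle <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    if (j - i < 4) next
    hi <- h[h$resno == i, c("x", "y", "z")]
    hj <- h[h$resno == j, c("x", "y", "z")]
    dmin <- min(sqrt(outer(rowSums(hi^2), rowSums(hj^2), "+") -
                       2 * as.matrix(hi) %*% t(as.matrix(hj))))
    if (dmin < 4.5) oracle <- rbind(oracle, c(i, j))
  }
  got <- if (is.null(topo$native)) matrix(0, 0, 2) else
    as.matrix(topo$native[, c("i", "j")])
  expect_true(nrow(got) > 0)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE],
               ignore_attr = TRUE)

  # partition: every eligible pair is native xor nonnative, exactly once
  keys <- function(m) paste(m[, 1], m[, 2])
  eligible <- NULL
  for (i in 1:10) for (j in 1:10)
    if (j - i >= 4) eligible <- rbind(eligible, c(i, j))
  nat <- keys(got)
  non <- keys(as.matrix(topo$nonnative[, c("i", "j")]))
  expect_length(intersect(nat, non), 0)
  expect_setequal(c(nat, non), keys(eligible))
})

test_that("flexible residues drop angle/dihedral/native but keep bonds", {
  xyz <- motorscape:::.bead_helix(12)
  sysA <- chain_system(xyz)
  sysB <- chain_system(xyz, flexible = 6L)
  tA <- build_topology(reference_structure(
    data.frame(chain = "A", resno = 1:12, resid = "GLY",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])))
  ref <- reference_structure(
    data.frame(chain = "A", resno = 1:12, resid = "GLY",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  ref$beads$flexible[6] <- TRUE
  tB <- build_topology(ref)
  expect_equal(nrow(tB$bonds), nrow(tA$bonds))
  expect_true(all(tB$angles$j != 6 & tB$angles$i != 6 & tB$angles$k != 6))
  expect_equal(nrow(tA$angles) - nrow(tB$angles), 3L)
  expect_equal(nrow(tA$dihedrals) - nrow(tB$dihedrals), 4L)
  if (!is.null(tB$native))
    expect_true(all(tB$native$i != 6 & tB$native$j != 6))
  # nonnative repulsion keeps the flexible residue
  expect_true(any(tB$nonnative$i == 6 | tB$nonnative$j == 6))
  expect_s3_class(sysA, "cg_system")
  expect_s3_class(sysB, "cg_system")
})

test_that("model archive round-trips positions, charges and flags", {
  ms <- mini()
  dir <- tempfile()
  write_model(ms$myosin, dir)
  back <- read_model(dir)
  expect_equal(back$beads$x, ms$myosin$beads$x, tolerance = 1e-9)
  expect_equal(back$beads$charge, ms$myosin$beads$charge)
  expect_equal(back$beads$flexible, ms$myosin$beads$flexible)
  expect_equal(back$ligand$charge, ms$myosin$ligand$charge)
  expect_equal(back$label, ms$myosin$label)
})
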