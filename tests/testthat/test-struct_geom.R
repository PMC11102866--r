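test_that("kabsch_superpose recovers exact rigid transforms", {
  pc <- simulate_point_cloud(n_atoms = 50, angle_deg = 0,
                             translation = c(0, 0, 0), seed = 20)
  sp <- kabsch_superpose(pc$mobile, pc$reference)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)

  pc37 <- simulate_point_cloud(n_atoms = 60, angle_deg = 37, seed = 21)
  sp37 <- kabsch_superpose(pc37$mobile, pc37$reference)
  expect_equal(sp37$rmsd, 0, tolerance = 1e-9)
  expect_equal(rotation_angle(sp37$rotation), 37, tolerance = 1e-9)
  expect_equal(det(sp37$rotation), 1, tolerance = 1e-6)

  # degenerate input
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("noisy superposition rmsd matches the noise level", {
  pc <- simulate_point_cloud(n_atoms = 100, angle_deg = 25, noise_sd = 0.1,
                             seed = 22)
  sp <- kabsch_superpose(pc$mobile, pc$reference)
  expect_equal(sp$rmsd, 0.1 * sqrt(3), tolerance = 0.2)
})

test_that("kabsch agrees with the quaternion oracle to 1e-6 (oracle)", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    P <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    Q <- sweep(P %*% t(random_rotation()), 2, rnorm(3), `+`) +
      matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_quaternion_rmsd(P, Q),
                 tolerance = 1e-6)
  }
})

test_that("superposition rmsd is invariant under rigid transforms of inputs", {
  set.seed(24)
  P <- matrix(rnorm(60, sd = 8), ncol = 3)
  Q <- P %*% t(random_rotation()) + matrix(rnorm(60, sd = 0.2), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  R2 <- random_rotation()
  moved <- kabsch_superpose(sweep(P %*% t(R2), 2, c(3, 1, -9), `+`), Q)$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("residue_rmsd isolates displaced residues after anchored superposition", {
  set.seed(25)
  core <- fixture_atoms("A", 1:20, "CA", "C",
                        matrix(rnorm(60, sd = 10), ncol = 3), "ALA")
  tail <- fixture_atoms("B", 1:5, "CA", "C",
                        matrix(rnorm(15, sd = 10), ncol = 3), "ARG")
  m1 <- structure_model(rbind(core, tail))
  zero <- residue_rmsd(m1, m1)
  expect_true(all(zero$rmsd_ca < 1e-12))

  shifted <- rbind(core, tail)
  i <- shifted$chain == "B" & shifted$resno == 3
  shifted$x[i] <- shifted$x[i] + 1.0
  m2 <- structure_model(shifted)
  rr <- residue_rmsd(m2, m1, anchor_chains = "A")
  expect_equal(rr$rmsd_ca[rr$chain == "B" & rr$resno == 3], 1.0,
               tolerance = 1e-9)
  expect_true(all(rr$rmsd_ca[!(rr$chain == "B" & rr$resno == 3)] < 1e-9))

  # block displacement is recovered as an elevated block
  block <- rbind(core, tail)
  j <- block$chain == "B"
  block$y[j] <- block$y[j] + 0.8
  rb <- residue_rmsd(structure_model(block), m1, anchor_chains = "A")
  expect_true(all(abs(rb$rmsd_ca[rb$chain == "B"] - 0.8) < 1e-9))

  # a rigidly moved copy has identically zero residue rmsd
  sp <- list(rotation = random_rotation(), translation = c(4, -2, 7))
  m3 <- apply_superposition(m1, structure(sp, class = "Superposition"))
  rr3 <- residue_rmsd(m3, m1)
  expect_true(all(rr3$rmsd_ca < 1e-9))
})

test_that("detect_clashes applies vdW radii minus tolerance", {
  at <- function(x, chain) structure_model(fixture_atoms(
    chain, 1L, "C1", "C", matrix(c(x, 0, 0), ncol = 3)))
  expect_equal(nrow(detect_clashes(at(0, "X"), at(3.5, "Y"))), 0L)
  rep25 <- detect_clashes(at(0, "X"), at(2.5, "Y"))
  expect_equal(nrow(rep25), 1L)
  expect_equal(rep25$overlap, 0.5)    # 1.7 + 1.7 - 0.4 - 2.5
  expect_equal(rep25$distance, 2.5)

  # hydrogens ignored; unknown elements are errors without a default
  h <- structure_model(fixture_atoms("H", 1L, "H1", "H",
                                     matrix(c(2.0, 0, 0), ncol = 3)))
  expect_equal(nrow(detect_clashes(at(0, "X"), h)), 0L)
  q <- structure_model(fixture_atoms("Q", 1L, "XX", "XX",
                                     matrix(c(2.0, 0, 0), ncol = 3)))
  expect_error(detect_clashes(at(0, "X"), q), "radius")
  expect_equal(nrow(detect_clashes(at(0, "X"), q, default_radius = 0.1)), 0L)
})

test_that("clash detection is symmetric and monotone in tolerance", {
  set.seed(26)
  mk <- function(chain) structure_model(fixture_atoms(
    chain, 1:30, "C1", "C", matrix(rnorm(90, sd = 3), ncol = 3)))
  a <- mk("A"); b <- mk("B")
  ab <- detect_clashes(a, b); ba <- detect_clashes(b, a)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sort(ab$distance), sort(ba$distance))
  loose <- detect_clashes(a, b, tolerance = 0.8)
  expect_lte(nrow(loose), nrow(ab))
  key <- function(r) paste(r$resno_i, r$resno_j)
  expect_true(all(key(loose) %in% key(ab)))
})

test_that("anchor_contacts measures arginine-to-minor-groove distances", {
  dna <- fixture_atoms("I", 1L, "O2", "O", matrix(c(0, 0, 0), ncol = 3), "DC")
  arg_near <- fixture_atoms("P", 77L, "NH1", "N", matrix(c(3, 0, 0), ncol = 3),
                            "ARG")
  m <- structure_model(rbind(dna, arg_near))
  ac <- anchor_contacts(m, data.frame(chain = "P", resno = 77L,
                                      atoms = "NH1,NH2"))
  expect_true(ac$occupied)
  expect_equal(ac$distance, 3.0)

  arg_far <- arg_near; arg_far$x <- 6
  m2 <- structure_model(rbind(dna, arg_far))
  ac2 <- anchor_contacts(m2, data.frame(chain = "P", resno = 77L,
                                        atoms = "NH1,NH2"))
  expect_false(ac2$occupied)
  expect_error(anchor_contacts(m2, data.frame(chain = "P", resno = 99L,
                                              atoms = "NH1")), "absent")
})

test_that("dock_dbd is exact on an identical duplex and translates along the helix", {
  set.seed(27)
  nuc <- simulate_bdna_duplex(40)
  dbd_dna <- simulate_bdna_duplex(13)
  prot <- fixture_atoms("D", 1:6, "CA", "C",
                        matrix(rnorm(18, sd = 4) + 15, ncol = 3), "ARG")
  prot$occ <- 1
  dbd <- structure_model(rbind(as.data.frame(dbd_dna), prot))
  map1 <- data.frame(dbd_chain = rep(c("I", "J"), each = 13),
                     dbd_resno = rep(1:13, 2),
                     nuc_chain = rep(c("I", "J"), each = 13),
                     nuc_resno = rep(1:13, 2))
  d1 <- dock_dbd(dbd, nuc, map1)
  expect_equal(d1$superposition$rmsd, 0, tolerance = 1e-9)
  expect_equal(coords(d1$docked), coords(dbd), tolerance = 1e-9)

  # 10 bp downstream on an ideal 10-bp/turn duplex: one full helical turn,
  # i.e. a pure 34 Angstrom rise along the axis
  map2 <- map1; map2$nuc_resno <- map2$nuc_resno + 10L
  d2 <- dock_dbd(dbd, nuc, map2)
  expect_equal(d2$superposition$rmsd, 0, tolerance = 1e-9)
  delta <- coords(d2$docked) - coords(d1$docked)
  expect_equal(max(abs(sweep(delta, 2, c(0, 0, 34)))), 0, tolerance = 1e-6)
  # combined model keeps factor and nucleosome atoms distinguishable
  expect_true(any(startsWith(d2$combined$chain, "F.")))
  expect_error(dock_dbd(dbd, nuc, map1[0, ]), "missing")
})

test_that("unwrap_angle recovers constructed reorientations", {
  arc0 <- simulate_unwrap_arc(angle_deg = 0, seed = 27)
  expect_equal(unwrap_angle(arc0$bound, arc0$free, arc0$bp_pairs,
                            core_chains = "A"), 0, tolerance = 1e-6)

  arc <- simulate_unwrap_arc(angle_deg = 50, seed = 28)
  expect_equal(unwrap_angle(arc$bound, arc$free, arc$bp_pairs,
                            core_chains = "A"), 50, tolerance = 0.5)
  # symmetry
  expect_equal(unwrap_angle(arc$free, arc$bound, arc$bp_pairs,
                            core_chains = "A"), 50, tolerance = 0.5)
  expect_error(unwrap_angle(arc$bound, arc$free, arc$bp_pairs[1:3, ]),
               "too short")
})
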