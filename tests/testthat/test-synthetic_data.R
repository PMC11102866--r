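test_that("generators are pure functions of their spec (seed determinism)", {
  s1 <- simulate_seen_counts(seen_sim_spec(c(pos1 = 0, pos2 = 2),
                                           reads_per_fraction = 2000, seed = 30))
  s2 <- simulate_seen_counts(seen_sim_spec(c(pos1 = 0, pos2 = 2),
                                           reads_per_fraction = 2000, seed = 30))
  expect_identical(s1, s2)

  f1 <- simulate_fragments(fragment_sim_spec(n_fragments = 500, seed = 31))
  f2 <- simulate_fragments(fragment_sim_spec(n_fragments = 500, seed = 31))
  expect_identical(f1, f2)

  t1 <- simulate_fret_traces(fret_sim_spec(n_molecules = 5, seed = 32))
  t2 <- simulate_fret_traces(fret_sim_spec(n_molecules = 5, seed = 32))
  expect_identical(t1, t2)

  # and the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_fragments(fragment_sim_spec(
    n_fragments = 100, seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("null SeEN-seq simulation gives statistically flat enrichment", {
  sim <- simulate_seen_counts(seen_sim_spec(
    setNames(rep(0, 139), paste0("pos", 1:139)),
    reads_per_fraction = 1e5, replicates = 1, seed = 33))
  sc <- enrichment_scores(sim$counts, "widom601")
  e <- sc$enrichment[sc$status == "ok" & sc$construct_id != "widom601"]
  expect_gt(length(e), 130)
  # per-construct counts ~575; binomial noise on log2 ratio ~0.09, plus a
  # shared spike-in term that correlates all constructs (~0.015 on the mean)
  expect_lt(abs(mean(e)), 0.05)
  expect_lt(sd(e), 0.2)
})

test_that("a single enriched position is recovered within 3 sigma", {
  e <- setNames(rep(0, 139), paste0("pos", 1:139)); e[70] <- 3
  sim <- simulate_seen_counts(seen_sim_spec(e, reads_per_fraction = 1e5,
                                            replicates = 1, seed = 34))
  ct <- sim$counts
  n <- ct$count[ct$construct_id == "pos70" & ct$fraction == "bound"]
  sc <- enrichment_scores(ct, "widom601")
  est <- sc$enrichment[sc$construct_id == "pos70"]
  cnt <- function(id, fr) ct$count[ct$construct_id == id & ct$fraction == fr]
  sigma <- sqrt(1 / cnt("pos70", "bound") + 1 / cnt("pos70", "unbound") +
                  1 / cnt("widom601", "bound") + 1 / cnt("widom601", "unbound")) / log(2)
  expect_lt(abs(est - 3), 3 * sigma)
})

test_that("fragment generator matches the dyad-map midpoint rule exactly", {
  sim <- simulate_fragments(fragment_sim_spec(
    dyads = 90L, weights = 1, length_dist = c(`147` = 1),
    n_fragments = 200, seed = 35))
  expect_true(all(dyad_positions(sim$fragments) == 89L))  # 0-based
  expect_true(all(sim$fragments$end - sim$fragments$start == 147L))

  # mixture weights land within binomial 3 sigma
  sim3 <- simulate_fragments(fragment_sim_spec(n_fragments = 2e4, seed = 36))
  emp <- table(factor(sim3$truth$fragment_dyad, levels = c(73, 87, 108))) / 2e4
  for (k in 1:3) {
    w <- sim3$truth$weights[k]
    expect_lt(abs(emp[k] - w), 3 * sqrt(w * (1 - w) / 2e4))
  }

  # lengths that do not fit the reference edge are never emitted
  lens <- sim3$fragments$end - sim3$fragments$start
  expect_true(all(sim3$fragments$start >= 0))
  expect_true(all(sim3$fragments$end <= 180))
  expect_true(all(lens %in% 145:147))
})

test_that("fret generator emulates states, bleaching and donor-only traces", {
  spec <- fret_sim_spec(tau_low_s = 1e9, tau_high_s = 1e9, noise_sd = 0,
                        bleach_mean_acceptor_s = 1e9, bleach_mean_donor_s = 1e9,
                        donor_only_fraction = 0, multistep_fraction = 0,
                        n_molecules = 3, n_frames = 50, seed = 37)
  sim <- simulate_fret_traces(spec)
  E <- fret_efficiency(sim$traces$donor, sim$traces$acceptor,
                       correction_factors(0.1, 1))
  expect_equal(unique(round(E, 10)), 0.75)  # wrapped start, no transitions

  spec2 <- fret_sim_spec(donor_only_fraction = 0.3, n_molecules = 200,
                         seed = 38)
  sim2 <- simulate_fret_traces(spec2)
  frac <- mean(sim2$truth$class == "donor_only")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
  # donor-only traces have no acceptor signal
  donly <- sim2$traces$molecule_id %in%
    sim2$truth$molecule_id[sim2$truth$class == "donor_only"]
  expect_lt(mean(sim2$traces$acceptor[donly]), 3 * spec2$noise_sd)
})

test_that("coordinate generators reproduce their stated transforms", {
  pc <- simulate_point_cloud(angle_deg = 37, noise_sd = 0.05, seed = 39)
  sp <- kabsch_superpose(pc$mobile, pc$reference)
  expect_equal(rotation_angle(sp$rotation), 37, tolerance = 0.2)
  expect_equal(sp$rmsd, 0.05 * sqrt(3), tolerance = 0.25)

  arc <- simulate_unwrap_arc(angle_deg = 120, seed = 40)
  expect_equal(unwrap_angle(arc$bound, arc$free, arc$bp_pairs,
                            core_chains = "A"), 120, tolerance = 0.5)
})
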