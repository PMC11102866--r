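# Seeded synthetic-data generators emulating every input the pipeline
# consumes, each returning the simulated dataset plus a ground-truth sidecar
# for parameter-recovery tests. Generators are pure functions of their spec
# (which includes the seed): the caller's RNG state is saved and restored.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# ---- SeEN-seq counts --------------------------------------------------------

#' Specification for a synthetic SeEN-seq experiment
#'
#' @param enrichment Numeric vector of true log2 enrichments, one per tiled
#'   construct (names become construct ids; unnamed vectors get
#'   `pos1..posN`).
#' @param reads_per_fraction Sequencing depth per (replicate, fraction).
#' @param replicates Number of replicates.
#' @param spike_fraction Expected read fraction of the spike-in construct in
#'   the unbound library.
#' @param spike_id Spike-in construct id.
#' @param seed RNG seed.
#' @return A `SeenSeqSimSpec` list.
#' @export
seen_sim_spec <- function(enrichment, reads_per_fraction = 1e5L,
                          replicates = 3L, spike_fraction = 0.2,
                          spike_id = "widom601", seed = 1L) {
  stopifnot(reads_per_fraction > 0, replicates >= 1,
            spike_fraction > 0, spike_fraction < 1)
  if (is.null(names(enrichment)))
    names(enrichment) <- paste0("pos", seq_along(enrichment))
  structure(list(enrichment = enrichment,
                 reads_per_fraction = as.integer(reads_per_fraction),
                 replicates = as.integer(replicates),
                 spike_fraction = spike_fraction, spike_id = spike_id,
                 seed = as.integer(seed)),
            class = "SeenSeqSimSpec")
}

#' Simulate a SeEN-seq count table
#'
#' Unbound counts are multinomial with uniform construct probabilities plus
#' the spike-in; bound counts are multinomial with probabilities
#' proportional to `unbound_prob * 2^enrichment` (spike-in enrichment 0).
#'
#' @param spec A [seen_sim_spec()].
#' @return List with `counts` (a count table) and `truth` (data.frame
#'   `construct_id`, `enrichment`).
#' @export
simulate_seen_counts <- function(spec) {
  stopifnot(inherits(spec, "SeenSeqSimSpec"))
  .with_seed(spec$seed, {
    e <- spec$enrichment
    n <- length(e)
    ids <- c(names(e), spec$spike_id)
    p_u <- c(rep((1 - spec$spike_fraction) / n, n), spec$spike_fraction)
    p_b <- p_u * c(2^e, 1)
    p_b <- p_b / sum(p_b)
    rows <- list()
    for (rep_i in seq_len(spec$replicates)) {
      cu <- as.integer(rmultinom(1, spec$reads_per_fraction, p_u))
      cb <- as.integer(rmultinom(1, spec$reads_per_fraction, p_b))
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = rep(ids, 2L),
        replicate = rep_i,
        fraction = rep(c("unbound", "bound"), each = length(ids)),
        count = c(cu, cb))
    }
    list(counts = do.call(rbind, rows),
         truth = data.frame(construct_id = ids, enrichment = c(e, 0)))
  })
}

# ---- MNase fragments --------------------------------------------------------

#' Specification for a synthetic MNase fragment ensemble
#'
#' @param dyads 1-based dyad positions of the nucleosome registers.
#' @param weights Mixture weights (sum 1).
#' @param length_dist Named numeric: fragment-length distribution. Default
#'   uniform over 145-147 bp (full protection minus 0-2 bp end trimming).
#' @param n_fragments Number of fragments.
#' @param ref_length Reference construct length in bp.
#' @param ref_id Reference id.
#' @param condition `minus_factor` or `plus_factor` label.
#' @param trim_offset Extra 5' shift in bp for asymmetric trimming (default
#'   0: fragments centered on the dyad).
#' @param seed RNG seed.
#' @return A `FragmentSimSpec` list.
#' @export
fragment_sim_spec <- function(dyads = c(73L, 87L, 108L),
                              weights = c(0.5, 0.3, 0.2),
                              length_dist = c(`145` = 1/3, `146` = 1/3,
                                              `147` = 1/3),
                              n_fragments = 1e5L, ref_length = 180L,
                              ref_id = "endo180",
                              condition = "minus_factor",
                              trim_offset = 0L, seed = 1L) {
  stopifnot(length(dyads) == length(weights),
            abs(sum(weights) - 1) < 1e-9, all(weights > 0),
            n_fragments > 0, !is.null(names(length_dist)))
  structure(list(dyads = as.integer(dyads), weights = weights,
                 length_dist = length_dist / sum(length_dist),
                 n_fragments = as.integer(n_fragments),
                 ref_length = as.integer(ref_length), ref_id = ref_id,
                 condition = condition, trim_offset = as.integer(trim_offset),
                 seed = as.integer(seed)),
            class = "FragmentSimSpec")
}

#' Simulate MNase fragments around known dyads
#'
#' Fragment starts are placed so the half-open-interval midpoint rule
#' recovers the drawn dyad exactly: `start = dyad0 - floor((L - 1) / 2)`
#' with `dyad0` the 0-based dyad.
#'
#' @param spec A [fragment_sim_spec()].
#' @return List with `fragments` (data.frame `ref_id`, `start`, `end`,
#'   `condition`) and `truth` (`dyads`, `weights`, per-fragment `dyad`).
#' @export
simulate_fragments <- function(spec) {
  stopifnot(inherits(spec, "FragmentSimSpec"))
  .with_seed(spec$seed, {
    comp <- sample.int(length(spec$dyads), spec$n_fragments, replace = TRUE,
                       prob = spec$weights)
    dyad1 <- spec$dyads[comp]
    lens <- as.integer(names(spec$length_dist))
    # near the construct ends only the more-trimmed footprints fit; condition
    # the length draw per register so every fragment stays on the reference
    L <- integer(spec$n_fragments)
    for (k in seq_along(spec$dyads)) {
      d0 <- spec$dyads[k] - 1L
      fits <- d0 - (lens - 1L) %/% 2L + spec$trim_offset >= 0L &
        d0 - (lens - 1L) %/% 2L + spec$trim_offset + lens <= spec$ref_length
      if (!any(fits))
        stop("no footprint length fits the reference at dyad ", spec$dyads[k])
      i <- comp == k
      pick <- sample.int(sum(fits), sum(i), replace = TRUE,
                         prob = spec$length_dist[fits])
      L[i] <- lens[fits][pick]
    }
    start <- (dyad1 - 1L) - (L - 1L) %/% 2L + spec$trim_offset
    frags <- data.frame(ref_id = spec$ref_id, start = start,
                        end = start + L, condition = spec$condition)
    list(fragments = frags,
         truth = list(dyads = spec$dyads, weights = spec$weights,
                      fragment_dyad = dyad1))
  })
}

# ---- smFRET traces ----------------------------------------------------------

#' Specification for synthetic two-state smFRET traces
#'
#' Defaults describe the wild-type-like experiment: exponential dwells in the
#' low-FRET (unwrapped, factor-bound) and high-FRET (wrapped) states, 10-s
#' frames over 30-min videos, single-step photobleaching of each fluorophore
#' and a donor-only population.
#'
#' @param tau_low_s,tau_high_s Mean dwell times of the low-/high-FRET state.
#' @param E_low,E_high True FRET efficiencies of the two states (defaults
#'   0.25/0.75, straddling the 0.48 threshold).
#' @param alpha,gamma Channel correction factors baked into the emitted
#'   intensities.
#' @param intensity_total Total photon rate per frame (a.u.).
#' @param noise_sd Gaussian intensity noise s.d. per channel (a.u.).
#' @param frame_interval_s Frame interval; excitation is pulsed (sub-frame),
#'   so the hidden state is sampled instantaneously at frame midpoints.
#' @param n_frames Frames per video.
#' @param bleach_mean_acceptor_s,bleach_mean_donor_s Mean (exponential)
#'   photobleach times.
#' @param donor_only_fraction Fraction of molecules lacking an acceptor.
#' @param multistep_fraction Fraction of molecules with a two-step acceptor
#'   bleach (QC bait).
#' @param n_molecules Number of molecules.
#' @param seed RNG seed.
#' @return A `FretSimSpec` list.
#' @export
fret_sim_spec <- function(tau_low_s = 16.4, tau_high_s = 20.27,
                          E_low = 0.25, E_high = 0.75,
                          alpha = 0.1, gamma = 1,
                          intensity_total = 1000, noise_sd = 30,
                          frame_interval_s = 10, n_frames = 180L,
                          bleach_mean_acceptor_s = 600,
                          bleach_mean_donor_s = 1500,
                          donor_only_fraction = 0.15,
                          multistep_fraction = 0.05,
                          n_molecules = 300L, seed = 1L) {
  stopifnot(tau_low_s > 0, tau_high_s > 0, E_low >= 0, E_high <= 1,
            E_low < E_high, frame_interval_s > 0, n_frames >= 8,
            donor_only_fraction >= 0, donor_only_fraction < 1,
            multistep_fraction >= 0, multistep_fraction < 1)
  structure(list(tau_low_s = tau_low_s, tau_high_s = tau_high_s,
                 E_low = E_low, E_high = E_high, alpha = alpha, gamma = gamma,
                 intensity_total = intensity_total, noise_sd = noise_sd,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 bleach_mean_acceptor_s = bleach_mean_acceptor_s,
                 bleach_mean_donor_s = bleach_mean_donor_s,
                 donor_only_fraction = donor_only_fraction,
                 multistep_fraction = multistep_fraction,
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "FretSimSpec")
}

#' Packaged smFRET simulation presets
#'
#' `"WT"`: low-FRET mean dwell 16.4 s, high-FRET 20.27 s, 10-s frames.
#' `"D159A"`: low-FRET 9.19 s, high-FRET 16.44 s, 6-s frames (the mutant was
#' imaged faster). Dwell means are the reported per-state averages for the
#' two protein variants; all other parameters are the generator defaults.
#'
#' @param name `"WT"` or `"D159A"`.
#' @param ... Overrides passed to [fret_sim_spec()] (e.g. `seed`,
#'   `n_molecules`).
#' @return A `FretSimSpec`.
#' @export
fret_preset <- function(name = c("WT", "D159A"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    WT = list(tau_low_s = 16.4, tau_high_s = 20.27,
              frame_interval_s = 10, n_frames = 180L),
    D159A = list(tau_low_s = 9.19, tau_high_s = 16.44,
                 frame_interval_s = 6, n_frames = 300L))
  do.call(fret_sim_spec, utils::modifyList(args, list(...)))
}

#' Simulate two-channel smFRET intensity traces
#'
#' Continuous-time two-state alternation (starting wrapped) is sampled
#' instantaneously at frame midpoints. Pre-bleach intensities are `donor =
#' T(1 - E)`, `acceptor = gamma T E + alpha * donor`; after the acceptor
#' bleach the donor recovers to `T` and the acceptor retains leakage only;
#' after the donor bleach both channels drop to background. Donor-only
#' molecules emit donor signal only. A small multi-step population bleaches
#' its acceptor in two partial steps.
#'
#' @param spec A [fret_sim_spec()].
#' @return List with `traces` (a trace table) and `truth` (per-molecule
#'   data.frame: `molecule_id`, `class`, `t_acceptor_bleach_s`,
#'   `t_donor_bleach_s`, `n_low_dwells`).
#' @export
simulate_fret_traces <- function(spec) {
  stopifnot(inherits(spec, "FretSimSpec"))
  .with_seed(spec$seed, {
    dt <- spec$frame_interval_s
    nf <- spec$n_frames
    tmid <- (seq_len(nf) - 1) * dt + dt / 2
    total <- spec$intensity_total
    traces <- vector("list", spec$n_molecules)
    truth <- vector("list", spec$n_molecules)
    for (m in seq_len(spec$n_molecules)) {
      id <- sprintf("mol%04d", m)
      u <- runif(1)
      cls <- if (u < spec$donor_only_fraction) "donor_only"
             else if (u < spec$donor_only_fraction + spec$multistep_fraction)
               "multi_step" else "fret"
      t_a <- rexp(1, 1 / spec$bleach_mean_acceptor_s)
      t_d <- rexp(1, 1 / spec$bleach_mean_donor_s)
      if (cls == "donor_only") {
        donor <- ifelse(tmid < t_d, total, 0)
        acceptor <- rep(0, nf)
        n_low <- 0L
      } else {
        # alternating renewal path, wrapped (high-FRET) start
        ev_t <- 0; ev_low <- FALSE; t <- 0; low <- FALSE
        horizon <- nf * dt
        while (t < horizon) {
          t <- t + rexp(1, 1 / if (low) spec$tau_low_s else spec$tau_high_s)
          low <- !low
          ev_t <- c(ev_t, t); ev_low <- c(ev_low, low)
        }
        st_low <- ev_low[findInterval(tmid, ev_t)]
        n_low <- sum(rle(st_low)$values)
        E <- ifelse(st_low, spec$E_low, spec$E_high)
        donor <- total * (1 - E)
        acceptor <- spec$gamma * total * E + spec$alpha * donor
        if (cls == "multi_step") {
          half <- tmid >= t_a / 2 & tmid < t_a
          acceptor[half] <- spec$alpha * donor[half] +
            0.5 * (acceptor[half] - spec$alpha * donor[half])
        }
        ab <- tmid >= t_a
        donor[ab] <- total
        acceptor[ab] <- spec$alpha * total
        db <- tmid >= t_d
        donor[db] <- 0
        acceptor[db] <- 0
      }
      donor <- donor + rnorm(nf, 0, spec$noise_sd)
      acceptor <- acceptor + rnorm(nf, 0, spec$noise_sd)
      traces[[m]] <- data.frame(molecule_id = id,
                                frame_index = seq_len(nf) - 1L,
                                time_s = (seq_len(nf) - 1) * dt,
                                donor = donor, acceptor = acceptor)
      truth[[m]] <- data.frame(molecule_id = id, class = cls,
                               t_acceptor_bleach_s = t_a,
                               t_donor_bleach_s = t_d,
                               n_low_dwells = n_low)
    }
    list(traces = do.call(rbind, traces), truth = do.call(rbind, truth))
  })
}

# ---- coordinate fixtures ----------------------------------------------------

.rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Simulate a point cloud under a known rigid transform
#'
#' @param n_atoms Number of pseudo-atoms (carbon, chain A).
#' @param angle_deg,axis Rotation applied to the copy.
#' @param translation Length-3 translation (Angstrom).
#' @param noise_sd Gaussian coordinate noise added to the mobile copy.
#' @param seed RNG seed.
#' @return List with `reference` and `mobile` `StructureModel`s, plus the
#'   true `rotation` and `translation`.
#' @export
simulate_point_cloud <- function(n_atoms = 100L, angle_deg = 37,
                                 axis = c(0, 0, 1),
                                 translation = c(5, -3, 2), noise_sd = 0,
                                 seed = 1L) {
  .with_seed(seed, {
    X <- matrix(rnorm(n_atoms * 3, sd = 10), ncol = 3)
    R <- .rotation_matrix(axis, angle_deg)
    Y <- sweep(X %*% t(R), 2, translation, `+`) +
      matrix(rnorm(n_atoms * 3, sd = noise_sd), ncol = 3)
    mk <- function(M) structure_model(data.frame(
      chain = "A", resno = seq_len(n_atoms), resname = "GLY", atom = "CA",
      element = "C", x = M[, 1], y = M[, 2], z = M[, 3]))
    list(reference = mk(X), mobile = mk(Y), rotation = R,
         translation = translation)
  })
}

#' Simulate a wrapped-DNA arc and an unwrapped copy
#'
#' Base-pair centers lie on a circular arc (the DNA path around the histone
#' core); the copy has its terminal `segment_bp` base pairs rotated by
#' `angle_deg` about the arc normal through the hinge base pair. Both models
#' share an identical pseudo-histone core (chain A C-alphas) used as the
#' superposition anchor. Paired C1' atoms sit on either side of each center,
#' so [base_pair_centers()] recovers the path exactly.
#'
#' @param n_bp Total base pairs in the arc.
#' @param segment_bp Terminal base pairs that unwrap.
#' @param angle_deg Unwrap angle (degrees, `[0, 180]`).
#' @param radius Superhelix path radius (Angstrom, default 42).
#' @param deg_per_bp Arc degrees per base pair along the wrap (default 4).
#' @param noise_sd Gaussian coordinate noise on both copies.
#' @param seed RNG seed.
#' @return List with `free`, `bound` (`StructureModel`s), `bp_pairs` (for
#'   the rotated terminal segment) and `angle_deg`.
#' @export
simulate_unwrap_arc <- function(n_bp = 40L, segment_bp = 20L, angle_deg = 50,
                                radius = 42, deg_per_bp = 4, noise_sd = 0,
                                seed = 1L) {
  stopifnot(angle_deg >= 0, angle_deg <= 180, segment_bp >= 4,
            segment_bp < n_bp)
  .with_seed(seed, {
    phi <- (seq_len(n_bp) - 1) * deg_per_bp * pi / 180
    ctr <- cbind(radius * cos(phi), radius * sin(phi), 0)
    # C1' atoms flank each center along the z normal
    mk_dna <- function(centers) {
      up <- centers; up[, 3] <- up[, 3] + 5
      dn <- centers; dn[, 3] <- dn[, 3] - 5
      rbind(
        data.frame(chain = "I", resno = seq_len(n_bp), resname = "DA",
                   atom = "C1'", element = "C",
                   x = up[, 1], y = up[, 2], z = up[, 3]),
        data.frame(chain = "J", resno = seq_len(n_bp), resname = "DT",
                   atom = "C1'", element = "C",
                   x = dn[, 1], y = dn[, 2], z = dn[, 3]))
    }
    core <- data.frame(chain = "A", resno = seq_len(30L), resname = "ALA",
                       atom = "CA", element = "C",
                       x = rnorm(30, sd = 8), y = rnorm(30, sd = 8),
                       z = rnorm(30, sd = 8))
    free_dna <- mk_dna(ctr)
    hinge_i <- n_bp - segment_bp        # last wrapped base pair
    Rz <- .rotation_matrix(c(0, 0, 1), angle_deg)
    ctr_b <- ctr
    idx <- (hinge_i + 1L):n_bp
    ctr_b[idx, ] <- sweep(sweep(ctr[idx, , drop = FALSE], 2, ctr[hinge_i, ]) %*%
                            t(Rz), 2, ctr[hinge_i, ], `+`)
    bound_dna <- mk_dna(ctr_b)
    jitter <- function(df) {
      if (noise_sd > 0) {
        df$x <- df$x + rnorm(nrow(df), 0, noise_sd)
        df$y <- df$y + rnorm(nrow(df), 0, noise_sd)
        df$z <- df$z + rnorm(nrow(df), 0, noise_sd)
      }
      df
    }
    list(free = structure_model(jitter(rbind(core, free_dna))),
         bound = structure_model(jitter(rbind(core, bound_dna))),
         bp_pairs = data.frame(chain_i = "I", res_i = idx,
                               chain_j = "J", res_j = idx),
         angle_deg = angle_deg)
  })
}

#' Ideal straight B-DNA duplex backbone
#'
#' P and C1' pseudo-atoms for both strands of an ideal straight duplex
#' (3.4 Angstrom rise, 36 degrees twist: exactly 10 bp/turn), rising along
#' z. Useful as a docking template and for helical-geometry tests.
#'
#' @param n_bp Number of base pairs.
#' @param chain_i,chain_j Chain ids for the two strands.
#' @param resno_offset First residue number minus one.
#' @return A `StructureModel`.
#' @export
simulate_bdna_duplex <- function(n_bp = 21L, chain_i = "I", chain_j = "J",
                                 resno_offset = 0L) {
  i <- seq_len(n_bp)
  tw <- (i - 1) * 36 * pi / 180
  z <- (i - 1) * 3.4
  mk <- function(chain, phase, r, atom) {
    data.frame(chain = chain, resno = i + resno_offset, resname = "DA",
               atom = atom, element = substr(atom, 1, 1),
               x = r * cos(tw + phase), y = r * sin(tw + phase), z = z)
  }
  structure_model(rbind(
    mk(chain_i, 0, 9.4, "P"), mk(chain_i, 0.3, 8.9, "C1'"),
    mk(chain_j, pi * 0.85, 9.4, "P"), mk(chain_j, pi * 0.85 - 0.3, 8.9, "C1'")))
}
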