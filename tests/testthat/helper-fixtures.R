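# Small fixture builders shared across test files.

fixture_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

# minimal count table: named vectors of bound/unbound counts per replicate
fixture_counts <- function(bound, unbound, replicate = 1L) {
  data.frame(
    construct_id = c(names(bound), names(unbound)),
    replicate = replicate,
    fraction = rep(c("bound", "unbound"), c(length(bound), length(unbound))),
    count = c(unname(bound), unname(unbound)))
}

# tiny protein/DNA model builders
fixture_atoms <- function(chain, resno, atom, element, xyz, resname = "GLY") {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# a noiseless accepted-by-construction FRET trace: high/low alternation,
# acceptor bleach after `pre` frames, donor bleach after `dpost` more frames
fixture_trace <- function(states, pre = length(states), total = 1000,
                          post_accept = 10L, post_donor = 5L, dt = 10,
                          E_high = 0.75, E_low = 0.25, alpha = 0,
                          noise_sd = 0, seed = 42L) {
  E <- ifelse(states == "H", E_high, E_low)
  donor <- total * (1 - E)
  acceptor <- total * E + alpha * donor
  donor <- c(donor, rep(total, post_accept), rep(0, post_donor))
  acceptor <- c(acceptor, rep(alpha * total, post_accept), rep(0, post_donor))
  n <- length(donor)
  set.seed(seed)
  data.frame(molecule_id = "m1", frame_index = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1) * dt,
             donor = donor + rnorm(n, 0, noise_sd),
             acceptor = acceptor + rnorm(n, 0, noise_sd))
}
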