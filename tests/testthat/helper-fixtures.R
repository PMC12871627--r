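# Shared fixtures: constructed (mostly noiseless) traces and synthetic
# structures used across test files.

# Piecewise-constant two-channel trace. `acc_levels`/`don_levels` are the
# segment levels, `acc_steps`/`don_steps` the first frame of each new
# segment (1-based).
make_step_trace <- function(n = 800,
                            acc_levels = 80, acc_steps = integer(0),
                            don_levels = 20, don_steps = integer(0),
                            noise_sd = 0, seed = 1, id = "fix") {
  set.seed(seed)
  piecewise <- function(levels, steps) {
    bounds <- c(1L, steps, n + 1L)
    out <- numeric(n)
    for (i in seq_along(levels))
      out[bounds[i]:(bounds[i + 1] - 1L)] <- levels[i]
    out
  }
  acc <- piecewise(acc_levels, acc_steps)
  don <- piecewise(don_levels, don_steps)
  if (noise_sd > 0) {
    acc <- acc + rnorm(n, 0, noise_sd)
    don <- don + rnorm(n, 0, noise_sd)
  }
  structure(list(molecule_id = id, donor = don, acceptor = acc,
                 frame_interval_s = 0.1, truth = NULL),
            class = "intensity_trace")
}

# A canonical analyzable trace: acceptor bleaches at frame a_bleach,
# donor at d_bleach, FRET level E, gamma 1, zero background.
make_good_trace <- function(n = 800, a_bleach = 300, d_bleach = 600,
                            E = 0.8, total = 100, noise_sd = 0, seed = 1,
                            id = "good") {
  make_step_trace(
    n = n,
    acc_levels = c(total * E, 0, 0), acc_steps = c(a_bleach, d_bleach),
    don_levels = c(total * (1 - E), total, 0), don_steps = c(a_bleach, d_bleach),
    noise_sd = noise_sd, seed = seed, id = id)
}

# Hand-built qc_result for compute_fret arithmetic tests.
make_qc <- function(step_frame, gamma, background = 0, id = "fix") {
  structure(list(molecule_id = id, accepted = TRUE,
                 acceptor_bleach = list(channel = "acceptor",
                                        step_frame = step_frame,
                                        step_size = NA_real_,
                                        n_steps_detected = 1L),
                 donor_bleach = NULL, gamma = gamma,
                 background = background, reject_reason = NA_character_),
            class = "qc_result")
}

# Synthetic structure fixtures ------------------------------------------

# A lone attachment atom at `at`, optionally with extra atoms.
atom_df <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                    name = "CB") {
  data.frame(chain = chain, resno = resno, name = name,
             elem = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# A planar wall of atoms at x = x0 spanning [-half, half]^2 in y, z.
wall_atoms <- function(x0, half = 30, step = 2, resno_start = 1000L) {
  g <- seq(-half, half, by = step)
  gr <- expand.grid(y = g, z = g)
  data.frame(chain = "W", resno = resno_start + seq_len(nrow(gr)),
             name = "O", elem = "O", x = x0, y = gr$y, z = gr$z)
}

# Random rigid motion (rotation + translation), seeded.
rigid_motion <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 20))
}

apply_rigid <- function(df, motion) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$t, "+")
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}
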