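#' Simulation parameters for synthetic smFRET traces
#'
#' Bundles everything the trace generator needs: acquisition geometry
#' (frames, frame interval), the discrete FRET states a molecule can
#' occupy, photon budget and noise, the per-molecule gamma distribution,
#' and single-step photobleaching rates for both dyes.  Defaults emulate a
#' typical TIRF acquisition: 100-ms frames over 80 s with an
#' EMCCD-scale photon budget.
#'
#' @param n_molecules number of molecules in an ensemble
#' @param n_frames frames per trace (default 800, i.e. 80 s at 100 ms)
#' @param frame_interval_s frame integration time in seconds
#' @param states list of `c(E, weight)` pairs (or a 2-column matrix):
#'   true FRET efficiencies in `[0, 1]` and their mixing weights
#'   (weights must sum to 1)
#' @param total_intensity mean total photons/frame emitted via the FRET
#'   pair (sets the scale of both channels)
#' @param noise_sd additive Gaussian noise SD per channel, photons/frame
#' @param gamma_mean,gamma_sd per-molecule detection-correction factor
#'   gamma is drawn from N(gamma_mean, gamma_sd) truncated to positive
#' @param donor_bleach_rate,acceptor_bleach_rate exponential
#'   photobleaching rates, 1/s
#' @param background constant offset added to both channels, photons/frame
#' @param seed master seed; per-molecule seeds are derived from it
#' @return an object of class `sim_params`
#' @export
sim_params <- function(n_molecules = 100,
                       n_frames = 800,
                       frame_interval_s = 0.1,
                       states = list(c(0.5, 1)),
                       total_intensity = 500,
                       noise_sd = 25,
                       gamma_mean = 1,
                       gamma_sd = 0.1,
                       donor_bleach_rate = 0.015,
                       acceptor_bleach_rate = 0.04,
                       background = 20,
                       seed = 1L) {
  if (is.matrix(states)) states <- lapply(seq_len(nrow(states)), function(i) states[i, ])
  st <- do.call(rbind, lapply(states, function(s) {
    assert_that(length(s) == 2, "each state must be (E_true, weight)")
    as.numeric(s)
  }))
  colnames(st) <- c("E_true", "weight")
  assert_that(all(st[, "E_true"] >= 0 & st[, "E_true"] <= 1),
              "state efficiencies must lie in [0, 1]")
  assert_that(abs(sum(st[, "weight"]) - 1) < 1e-8, "state weights must sum to 1")
  assert_that(n_molecules >= 1 && n_frames >= 1, "n_molecules and n_frames must be >= 1")
  assert_that(frame_interval_s > 0, "frame_interval_s must be positive")
  assert_that(total_intensity >= 0 && noise_sd >= 0 && background >= 0,
              "intensities and noise must be non-negative")
  assert_that(donor_bleach_rate >= 0 && acceptor_bleach_rate >= 0,
              "bleach rates must be non-negative")
  assert_that(gamma_mean > 0 && gamma_sd >= 0, "gamma_mean must be positive")
  structure(list(
    n_molecules = as.integer(n_molecules), n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s, states = st,
    total_intensity = total_intensity, noise_sd = noise_sd,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    donor_bleach_rate = donor_bleach_rate,
    acceptor_bleach_rate = acceptor_bleach_rate,
    background = background, seed = as.integer(seed)
  ), class = "sim_params")
}

# Draw a single-step bleach frame from an exponential waiting time.
# Returns the 1-based index of the first bleached frame, or NA if the dye
# survives the record.
draw_bleach_frame <- function(rate, n_frames, dt) {
  if (rate <= 0) return(NA_integer_)
  t <- stats::rexp(1, rate)
  f <- floor(t / dt) + 1L
  if (f > n_frames) NA_integer_ else as.integer(f)
}

#' Simulate one donor/acceptor intensity trace
#'
#' Generates a two-channel photon time series for a single molecule in a
#' fixed FRET state with single-step stochastic photobleaching of each
#' dye.  Before acceptor bleach the acceptor emits
#' `total_intensity * E` and the donor `total_intensity * (1 - E) / gamma`;
#' after acceptor bleach the donor recovers to the full gamma-scaled
#' total `total_intensity / gamma`; after donor bleach both channels fall
#' to background.  Additive Gaussian noise is applied per channel.
#'
#' @param params a [sim_params()] object
#' @param molecule_seed integer seed for this molecule (reproducible)
#' @param molecule_id identifier stored on the trace
#' @param E_true,gamma_true optional overrides; by default `E_true` is
#'   sampled from `params$states` and gamma from the truncated normal
#' @return an `intensity_trace`: list with `molecule_id`, `donor`,
#'   `acceptor`, `frame_interval_s` and a `truth` record
#'   (`E_true`, `gamma_true`, `acceptor_bleach_frame`,
#'   `donor_bleach_frame`; bleach frames are the first bleached frame,
#'   NA when the dye survives the record)
#' @export
simulate_trace <- function(params, molecule_seed, molecule_id = 1L,
                           E_true = NULL, gamma_true = NULL) {
  stopifnot(inherits(params, "sim_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(molecule_seed))

  if (is.null(E_true)) {
    k <- sample.int(nrow(params$states), 1, prob = params$states[, "weight"])
    E_true <- unname(params$states[k, "E_true"])
  }
  E_true <- unname(E_true)
  if (is.null(gamma_true)) {
    gamma_true <- 0
    while (gamma_true <= 0)
      gamma_true <- stats::rnorm(1, params$gamma_mean, params$gamma_sd)
  }
  n <- params$n_frames
  dt <- params$frame_interval_s
  ba <- draw_bleach_frame(params$acceptor_bleach_rate, n, dt)
  bd <- draw_bleach_frame(params$donor_bleach_rate, n, dt)
  # donor bleach silences the pair entirely; if the donor dies first the
  # acceptor never bleaches on its own within the FRET record
  if (!is.na(bd) && !is.na(ba) && bd <= ba) ba <- NA_integer_

  tot <- params$total_intensity
  acc <- rep(tot * E_true, n)
  don <- rep(tot * (1 - E_true) / gamma_true, n)
  if (!is.na(ba)) {
    acc[ba:n] <- 0
    don[ba:n] <- tot / gamma_true
  }
  if (!is.na(bd)) {
    acc[bd:n] <- 0
    don[bd:n] <- 0
  }
  acc <- acc + params$background
  don <- don + params$background
  if (params$noise_sd > 0) {
    acc <- acc + stats::rnorm(n, 0, params$noise_sd)
    don <- don + stats::rnorm(n, 0, params$noise_sd)
  }
  structure(list(
    molecule_id = molecule_id,
    donor = don, acceptor = acc,
    frame_interval_s = dt,
    truth = list(E_true = E_true, gamma_true = gamma_true,
                 acceptor_bleach_frame = ba, donor_bleach_frame = bd)
  ), class = "intensity_trace")
}

#' Simulate an ensemble of traces
#'
#' Draws each molecule's FRET state from the state weights and its gamma
#' from the truncated normal, then simulates every trace with a seed
#' derived from `(params$seed, molecule_id)` so the ensemble is
#' order-independent and reproducible.
#'
#' @param params a [sim_params()] object
#' @return list of `intensity_trace` objects, length `params$n_molecules`
#' @export
simulate_ensemble <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  lapply(seq_len(params$n_molecules), function(i) {
    simulate_trace(params, derive_seed(params$seed, i), molecule_id = i)
  })
}

# Save/restore the global RNG state so simulate_trace is a pure function
# of its seed and does not disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read trace ensembles as plain tabular text
#'
#' One long-format TSV per ensemble (`molecule_id`, `frame`, `donor`,
#' `acceptor`) plus an optional sidecar truth table.  Round-trips through
#' [read_traces()].
#'
#' @param traces list of `intensity_trace`
#' @param path TSV path for the intensity table
#' @param truth_path optional TSV path for the ground-truth sidecar
#' @return `path`, invisibly
#' @export
write_traces <- function(traces, path, truth_path = NULL) {
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id,
               frame = seq_along(tr$donor),
               donor = tr$donor, acceptor = tr$acceptor)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    tt <- do.call(rbind, lapply(traces, function(tr) {
      if (is.null(tr$truth)) return(NULL)
      data.frame(molecule_id = tr$molecule_id,
                 E_true = tr$truth$E_true, gamma_true = tr$truth$gamma_true,
                 acceptor_bleach_frame = tr$truth$acceptor_bleach_frame,
                 donor_bleach_frame = tr$truth$donor_bleach_frame)
    }))
    utils::write.table(tt, truth_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_traces
#' @param frame_interval_s frame interval to stamp on the traces read back
#' @export
read_traces <- function(path, truth_path = NULL, frame_interval_s = 0.1) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  truth <- if (!is.null(truth_path))
    utils::read.table(truth_path, sep = "\t", header = TRUE) else NULL
  ids <- unique(tab$molecule_id)
  lapply(ids, function(id) {
    sub <- tab[tab$molecule_id == id, ]
    sub <- sub[order(sub$frame), ]
    tr <- structure(list(molecule_id = id, donor = sub$donor,
                         acceptor = sub$acceptor,
                         frame_interval_s = frame_interval_s, truth = NULL),
                    class = "intensity_trace")
    if (!is.null(truth)) {
      r <- truth[truth$molecule_id == id, ]
      if (nrow(r) == 1)
        tr$truth <- list(E_true = r$E_true, gamma_true = r$gamma_true,
                         acceptor_bleach_frame = r$acceptor_bleach_frame,
                         donor_bleach_frame = r$donor_bleach_frame)
    }
    tr
  })
}
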