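#' Compute the gamma-corrected FRET efficiency series of an accepted trace
#'
#' Per frame, `E = I_A / (I_A + gamma * I_D)` with the molecule's own
#' gamma, evaluated over the frames strictly before the acceptor bleach
#' and after subtraction of the per-trace baseline measured beyond the
#' donor bleach.  Values are deliberately NOT clipped to `[0, 1]`: the
#' histogram range (-0.25 to 1.25) is chosen to accommodate noise
#' excursions.  Frames whose corrected denominator is non-positive are
#' dropped and counted; a trace losing more than `max_drop_frac` of its
#' frames is rejected.
#'
#' @param trace an `intensity_trace`
#' @param qc the accepted `qc_result` for this trace ([select_trace()])
#' @param max_drop_frac maximum tolerated fraction of dropped frames
#' @return a `fret_trace`: list with `molecule_id`, `E` (efficiency
#'   series), `gamma`, `n_dropped`
#' @export
compute_fret <- function(trace, qc, max_drop_frac = 0.2) {
  stopifnot(inherits(trace, "intensity_trace"), inherits(qc, "qc_result"))
  assert_that(isTRUE(qc$accepted), "compute_fret requires an accepted trace")
  b <- qc$acceptor_bleach$step_frame
  assert_that(b >= 2, "no pre-bleach frames")
  bg <- if (is.finite(qc$background)) qc$background else 0
  idx <- seq_len(b - 1L)
  ia <- trace$acceptor[idx] - bg
  id <- trace$donor[idx] - bg
  den <- ia + qc$gamma * id
  ok <- is.finite(den) & den > 0
  n_dropped <- sum(!ok)
  if (n_dropped > max_drop_frac * length(idx))
    stop(structure(class = c("smfretr_qc_error", "error", "condition"),
                   list(message = sprintf(
                     "trace %s: %d/%d frames dropped (denominator <= 0)",
                     trace$molecule_id, n_dropped, length(idx)),
                     call = sys.call(), reject_reason = "fret_dropped_frames")))
  structure(list(molecule_id = trace$molecule_id,
                 E = (ia / den)[ok], gamma = qc$gamma,
                 n_dropped = n_dropped),
            class = "fret_trace")
}

#' Histogram bin edges used throughout: 40 equal bins from -0.25 to 1.25
#' @return numeric vector of 41 edges
#' @export
fret_bin_edges <- function() seq(-0.25, 1.25, length.out = 41L)

# Bin efficiency values on the standard grid: half-open [left, right),
# final bin closed. Values outside the range are discarded.
bin_fret_values <- function(values) {
  edges <- fret_bin_edges()
  inside <- values >= edges[1] & values <= edges[41]
  v <- values[inside]
  k <- findInterval(v, edges, rightmost.closed = TRUE)
  tabulate(k, nbins = 40L)
}

#' Build the summed, trace-normalized FRET histogram
#'
#' Traces with more than `min_points` efficiency values are retained;
#' each retained trace's values are distributed into 40 bins spanning
#' -0.25 to 1.25 and the per-bin counts are divided by the trace's number
#' of in-range points, so every molecule contributes total weight 1
#' regardless of how long it survived.  Weights are then summed over
#' traces.
#'
#' @param fret_traces list of `fret_trace` (or a single numeric vector of
#'   efficiencies, treated as one trace)
#' @param min_points traces must have strictly more than this many points
#' @return a `fret_histogram`: list with `bin_edges` (41), `mids` (40),
#'   `weights` (40, summing to the number of retained traces),
#'   `n_molecules`, `n_excluded_short`, `n_out_of_range`
#' @export
build_histogram <- function(fret_traces, min_points = 20L) {
  if (is.numeric(fret_traces))
    fret_traces <- list(structure(list(molecule_id = 1L, E = fret_traces,
                                       gamma = NA_real_, n_dropped = 0L),
                                  class = "fret_trace"))
  keep <- vapply(fret_traces, function(ft) length(ft$E) > min_points, TRUE)
  short <- sum(!keep)
  fret_traces <- fret_traces[keep]
  if (length(fret_traces) == 0)
    stop_param("no traces longer than ", min_points, " points")
  edges <- fret_bin_edges()
  weights <- numeric(40L)
  oor <- 0L
  n_used <- 0L
  for (ft in fret_traces) {
    counts <- bin_fret_values(ft$E)
    n_in <- sum(counts)
    oor <- oor + (length(ft$E) - n_in)
    if (n_in == 0) next
    weights <- weights + counts / n_in
    n_used <- n_used + 1L
  }
  structure(list(bin_edges = edges, mids = (edges[-41] + edges[-1]) / 2,
                 weights = weights, n_molecules = n_used,
                 n_excluded_short = short, n_out_of_range = oor),
            class = "fret_histogram")
}

# Sum-of-Gaussians model evaluated at x for a parameter vector
# c(A1, mu1, sd1, A2, mu2, sd2, ...).
gaussian_sum <- function(x, par) {
  k <- length(par) / 3
  y <- 0
  for (i in seq_len(k)) {
    A <- par[3 * i - 2]; mu <- par[3 * i - 1]; s <- par[3 * i]
    y <- y + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  y
}

# Shared-width variant: par = c(A1..Ak, mu1..muk, s).
gaussian_sum_shared <- function(x, par) {
  k <- (length(par) - 1) / 2
  s <- par[2 * k + 1]
  y <- 0
  for (i in seq_len(k))
    y <- y + par[i] * exp(-(x - par[k + i])^2 / (2 * s^2))
  y
}

#' Decompose a FRET histogram into a sum of Gaussian components
#'
#' Nonlinear least squares of `sum_i A_i exp(-(x - mu_i)^2 / (2 sd_i^2))`
#' against bin centers vs weights (Levenberg-Marquardt with box bounds).
#' The fractional area of a component is its analytic area share
#' `A_i sd_i / sum_j A_j sd_j`, the convention under which figure-legend
#' areas sum to ~100%.  When `init` is supplied the fit is a single
#' deterministic Levenberg-Marquardt refinement of those means (the user
#' is asserting a component hypothesis; wandering off to a
#' marginally-lower-SSE merged solution would discard it).  Without
#' `init`, the k initial means sit at the weighted quantiles of the
#' histogram and 5 deterministically jittered restarts guard against
#' local minima; the best-SSE fit wins.  Components are reported
#' sorted by mean.  Standard deviations are bounded below by half the bin
#' width; a component pinned at that bound is flagged.
#'
#' With `shared_sd = TRUE` all components are constrained to one common
#' width — the standard identifiability device when decomposing strongly
#' overlapping peaks, where an unconstrained fit can let one broad
#' component swallow a neighbour; published histogram decompositions of
#' this kind report near-equal component widths, which this constraint
#' makes explicit.
#'
#' @param hist a `fret_histogram`
#' @param n_components number of Gaussians (1-4)
#' @param shared_sd constrain all components to a single common width
#' @param init optional numeric vector of initial component means
#' @param n_restarts jittered restarts around the initialization;
#'   default 5 when `init` is `NULL`, else 0
#' @return a `gaussian_mixture_fit`: list with `components` (data.frame:
#'   `mean`, `sd`, `fractional_area`, `amplitude`, `sd_at_bound`),
#'   `residual_sse`, `n_components`, `bic`, `converged`
#' @export
fit_mixture <- function(hist, n_components, init = NULL, n_restarts = NULL,
                        shared_sd = FALSE) {
  if (is.null(n_restarts)) n_restarts <- if (is.null(init)) 5L else 0L
  stopifnot(inherits(hist, "fret_histogram"))
  assert_that(n_components >= 1 && n_components <= 4,
              "n_components must be between 1 and 4")
  x <- hist$mids
  y <- hist$weights
  binw <- diff(hist$bin_edges[1:2])
  sd_min <- binw / 2
  k <- as.integer(n_components)

  if (is.null(init)) {
    # place initial means at the (i - 1/2)/k weighted quantiles of the
    # histogram so they start inside the mass, not at the range edges
    cw <- cumsum(y) / sum(y)
    init_means <- vapply(seq_len(k), function(i) {
      q <- (i - 0.5) / k
      x[which(cw >= q)[1]]
    }, 0)
  } else {
    assert_that(length(init) == k, "init must supply one mean per component")
    init_means <- as.numeric(init)
  }
  amp0 <- max(y) / k
  sd0 <- 0.08

  if (shared_sd) {
    lower <- c(rep(0, k), rep(-0.25, k), sd_min)
    upper <- c(rep(Inf, k), rep(1.25, k), 1.5)
  } else {
    lower <- rep(c(0, -0.25, sd_min), k)
    upper <- rep(c(Inf, 1.25, 1.5), k)
  }

  run_fit <- function(means, amps, sds) {
    start <- if (shared_sd) c(amps, means, sds[1])
             else as.numeric(rbind(amps, means, sds))
    names(start) <- paste0("p", seq_along(start))
    df <- data.frame(x = x, y = y)
    model_fn <- if (shared_sd) "gaussian_sum_shared" else "gaussian_sum"
    fml <- stats::as.formula(paste0(
      "y ~ ", model_fn, "(x, c(", paste(names(start), collapse = ","), "))"))
    tryCatch({
      fit <- minpack.lm::nlsLM(fml, data = df, start = as.list(start),
                               lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-12, ptol = 1e-12))
      list(par = stats::coef(fit), sse = sum(stats::resid(fit)^2), ok = TRUE)
    }, error = function(e) list(par = NULL, sse = Inf, ok = FALSE))
  }

  # deterministic jitter sequence for the multistart
  jit <- function(r) (((seq_len(k) * 7 + r * 13) %% 11) - 5) / 5  # in [-1, 1]
  cands <- list(run_fit(init_means, rep(amp0, k), rep(sd0, k)))
  for (r in seq_len(n_restarts)) {
    m <- pmin(pmax(init_means + 0.08 * jit(r), -0.2), 1.2)
    s <- pmax(sd0 * (1 + 0.5 * jit(r + 3) * 0.5), sd_min * 1.5)
    cands[[r + 1L]] <- run_fit(m, rep(amp0, k), s)
  }
  sses <- vapply(cands, function(cc) cc$sse, 0)
  best <- cands[[which.min(sses)]]
  if (!best$ok)
    stop(structure(class = c("smfretr_fit_error", "error", "condition"),
                   list(message = "mixture fit failed to converge from all starts",
                        call = sys.call(), n_components = k)))
  par <- best$par
  if (shared_sd) {
    A <- par[seq_len(k)]; mu <- par[(k + 1):(2 * k)]
    s <- rep(par[2 * k + 1], k)
  } else {
    A <- par[seq(1, 3 * k, 3)]; mu <- par[seq(2, 3 * k, 3)]
    s <- par[seq(3, 3 * k, 3)]
  }
  ord <- order(mu)
  A <- A[ord]; mu <- mu[ord]; s <- s[ord]
  areas <- A * s
  frac <- if (sum(areas) > 0) areas / sum(areas) else rep(NA_real_, k)
  n_obs <- length(y)
  n_par <- if (shared_sd) 2 * k + 1 else 3 * k
  bic <- n_obs * log(best$sse / n_obs) + n_par * log(n_obs)
  structure(list(
    components = data.frame(mean = unname(mu), sd = unname(s),
                            fractional_area = unname(frac),
                            amplitude = unname(A),
                            sd_at_bound = unname(s <= sd_min * (1 + 1e-6))),
    residual_sse = best$sse, n_components = k, bic = bic, converged = TRUE
  ), class = "gaussian_mixture_fit")
}

#' Sample efficiencies from a Gaussian mixture
#'
#' Draws `n` values from `sum_i w_i N(mu_i, sd_i)`; used to rebuild
#' histograms from published fit parameters (peak positions and
#' fractional areas) when no raw traces exist.
#'
#' @param n number of samples
#' @param means,sds,weights component parameters; weights are normalized
#' @param seed RNG seed
#' @return numeric vector of length `n`
#' @export
sample_mixture <- function(n, means, sds, weights, seed = 1L) {
  assert_that(length(means) == length(sds) && length(means) == length(weights),
              "means, sds and weights must have equal length")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  w <- weights / sum(weights)
  comp <- sample.int(length(means), n, replace = TRUE, prob = w)
  stats::rnorm(n, means[comp], sds[comp])
}

#' Evaluate a noiseless histogram directly from mixture parameters
#'
#' Bin weights are the mixture density evaluated at bin centers times the
#' bin width (times `total_weight`) — the exact noiseless limit of the
#' sum-of-Gaussians model that [fit_mixture()] fits, so fitting this
#' histogram must recover the generating parameters to optimizer
#' precision.  Used as an oracle in tests and for fit validation.
#'
#' @inheritParams sample_mixture
#' @param total_weight total histogram weight (e.g. number of molecules)
#' @return a `fret_histogram`
#' @export
mixture_histogram <- function(means, sds, weights, total_weight = 1) {
  edges <- fret_bin_edges()
  mids <- (edges[-41] + edges[-1]) / 2
  binw <- diff(edges[1:2])
  w <- weights / sum(weights)
  dens <- numeric(40L)
  for (i in seq_along(means))
    dens <- dens + w[i] * stats::dnorm(mids, means[i], sds[i])
  structure(list(bin_edges = edges, mids = mids,
                 weights = dens * binw * total_weight,
                 n_molecules = NA_integer_, n_excluded_short = 0L,
                 n_out_of_range = 0L),
            class = "fret_histogram")
}

#' Write a FRET histogram as TSV (bin_left, bin_right, weight)
#' @param hist a `fret_histogram`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(
    data.frame(bin_left = hist$bin_edges[-41], bin_right = hist$bin_edges[-1],
               weight = hist$weights),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
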