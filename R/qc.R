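#' Detect intensity steps by penalized binary segmentation
#'
#' Fits a piecewise-constant model to a photon time series by recursive
#' binary splitting: a segment is split at the point that maximally
#' reduces the residual sum of squares, and the split is kept only when
#' the reduction exceeds `penalty`.  With the default penalty
#' (`2 * sigma^2 * log(n)`, sigma estimated robustly from successive
#' differences) this is a BIC-style rule that returns no steps on
#' constant noise and localizes large single steps to the frame.
#'
#' @param series numeric photon series
#' @param max_steps maximum number of change points returned
#' @param min_segment minimum frames per segment on either side of a step
#' @param penalty SSE-reduction threshold for accepting a split;
#'   `NULL` for the automatic noise-scaled default
#' @return integer vector of step frames, sorted; each is the 1-based
#'   index of the FIRST frame at the new intensity level (empty when no
#'   step is found)
#' @export
detect_steps <- function(series, max_steps = 4L, min_segment = 5L,
                         penalty = NULL) {
  n <- length(series)
  if (n < 2 * min_segment)
    stop(structure(class = c("smfretr_qc_error", "error", "condition"),
                   list(message = "series too short for step detection",
                        call = sys.call(), reject_reason = "too_short")))
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(series)) / sqrt(2)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-8
    penalty <- 2 * sigma^2 * log(n)
  }

  # best single split of series[a:b]; returns c(gain, split_index) where
  # split_index is the first frame of the right segment
  best_split <- function(a, b) {
    x <- series[a:b]
    m <- length(x)
    if (m < 2 * min_segment) return(c(0, NA))
    cs <- cumsum(x)
    tot <- cs[m]
    k <- seq(min_segment, m - min_segment)  # size of left segment
    sse_gain <- cs[k]^2 / k + (tot - cs[k])^2 / (m - k) - tot^2 / m
    i <- which.max(sse_gain)
    c(sse_gain[i], a + k[i])
  }

  steps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) > 0 && length(steps) < max_steps) {
    gains <- vapply(queue, function(seg) best_split(seg[1], seg[2])[1], 0)
    j <- which.max(gains)
    if (gains[j] <= penalty) break
    seg <- queue[[j]]
    sp <- best_split(seg[1], seg[2])[2]
    steps <- c(steps, as.integer(sp))
    queue[[j]] <- NULL
    queue <- c(queue, list(c(seg[1], sp - 1L)), list(c(as.integer(sp), seg[2])))
  }
  sort(steps)
}

# Mean level of series on [from, to]; NA-safe for degenerate windows.
segment_mean <- function(series, from, to) {
  from <- max(1L, from); to <- min(length(series), to)
  if (to < from) return(NA_real_)
  mean(series[from:to])
}

# Classify detected steps as up/down using segment means around each step.
step_sizes <- function(series, steps) {
  if (length(steps) == 0) return(numeric(0))
  bounds <- c(1L, steps, length(series) + 1L)
  lev <- vapply(seq_len(length(bounds) - 1), function(i)
    segment_mean(series, bounds[i], bounds[i + 1] - 1L), 0)
  diff(lev)
}

#' Select analyzable molecules (single acceptor bleach before single donor bleach)
#'
#' Runs step detection on both channels and accepts a trace only when the
#' acceptor shows exactly one downward step, the donor exactly one
#' downward step, and the acceptor step precedes the donor step — i.e.
#' one acceptor dye photobleaching before one donor dye, the signature of
#' a single FRET pair with a usable gamma calibration jump.  The donor's
#' upward recovery step at acceptor bleach is expected and does not count
#' against the molecule.  Accepted traces get a per-molecule gamma
#' estimated from the intensity jumps at acceptor bleach
#' ([estimate_gamma()]) after per-trace background subtraction (baseline =
#' mean of both channels after donor bleach).
#'
#' @param trace an `intensity_trace`
#' @param min_segment,penalty forwarded to [detect_steps()]
#' @param gamma_window frames averaged on each side of the acceptor
#'   bleach for the gamma estimate
#' @param gamma_bounds sanity range; gamma outside it rejects the trace
#' @return a `qc_result`: list with `molecule_id`, `accepted`,
#'   `acceptor_bleach` / `donor_bleach` (step frame, size, count),
#'   `gamma`, `background`, `reject_reason` (one of `no_acceptor_bleach`,
#'   `no_donor_bleach`, `multi_step`, `order_violation`, `too_short`,
#'   `gamma_invalid`, or `NA` when accepted)
#' @export
select_trace <- function(trace, min_segment = 5L, penalty = NULL,
                         gamma_window = 20L, gamma_bounds = c(0.2, 5)) {
  stopifnot(inherits(trace, "intensity_trace"))
  res <- list(molecule_id = trace$molecule_id, accepted = FALSE,
              acceptor_bleach = NULL, donor_bleach = NULL,
              gamma = NA_real_, background = NA_real_,
              reject_reason = NA_character_)
  class(res) <- "qc_result"
  n <- length(trace$donor)
  if (n < 2 * min_segment || n != length(trace$acceptor)) {
    res$reject_reason <- "too_short"
    return(res)
  }
  sa <- detect_steps(trace$acceptor, min_segment = min_segment, penalty = penalty)
  sd_ <- detect_steps(trace$donor, min_segment = min_segment, penalty = penalty)
  asz <- step_sizes(trace$acceptor, sa)
  dsz <- step_sizes(trace$donor, sd_)
  a_down <- sa[asz < 0]
  d_down <- sd_[dsz < 0]
  if (length(a_down) > 1 || length(d_down) > 1) {
    res$reject_reason <- "multi_step"
    return(res)
  }
  if (length(a_down) == 0) {
    res$reject_reason <- "no_acceptor_bleach"
    return(res)
  }
  if (length(d_down) == 0) {
    res$reject_reason <- "no_donor_bleach"
    return(res)
  }
  if (a_down >= d_down) {
    res$reject_reason <- "order_violation"
    return(res)
  }
  res$acceptor_bleach <- list(channel = "acceptor", step_frame = a_down,
                              step_size = asz[match(a_down, sa)],
                              n_steps_detected = length(sa))
  res$donor_bleach <- list(channel = "donor", step_frame = d_down,
                           step_size = dsz[match(d_down, sd_)],
                           n_steps_detected = length(sd_))
  # per-trace baseline: both channels after the donor has bleached.
  # A genuine donor bleach leaves BOTH channels at the shared background
  # level, and a genuine acceptor bleach holds the acceptor at that same
  # level until the donor dies; a marginal noise step violates these, so
  # they separate real photobleaching from spurious change points.
  if (d_down < n) {
    don_after <- mean(trace$donor[(d_down + 1L):n])
    acc_after <- mean(trace$acceptor[(d_down + 1L):n])
    d_step <- dsz[match(d_down, sd_)]
    if (abs(don_after - acc_after) > 0.25 * abs(d_step) + 1e-9) {
      res$reject_reason <- "no_donor_bleach"
      return(res)
    }
    res$background <- mean(c(don_after, acc_after))
    a_step <- asz[match(a_down, sa)]
    if (d_down - a_down > 1) {
      acc_mid <- mean(trace$acceptor[(a_down + 1L):(d_down - 1L)])
      if (abs(acc_mid - res$background) > 0.25 * abs(a_step) + 1e-9) {
        res$reject_reason <- "no_acceptor_bleach"
        return(res)
      }
    }
  } else res$background <- 0
  g <- tryCatch(
    estimate_gamma(trace, res$acceptor_bleach, window = gamma_window,
                   donor_bleach_frame = d_down),
    error = function(e) NA_real_)
  if (!is.finite(g) || g < gamma_bounds[1] || g > gamma_bounds[2]) {
    res$reject_reason <- "gamma_invalid"
    return(res)
  }
  res$gamma <- g
  res$accepted <- TRUE
  res
}

#' Estimate the per-molecule gamma factor from the acceptor-bleach jump
#'
#' gamma corrects for unequal detection efficiency and quantum yield
#' between the two channels.  At acceptor photobleaching the acceptor
#' signal drops and the donor recovers; the ratio of the two jumps is the
#' field-standard per-molecule estimate
#' `gamma = (A_pre - A_post) / (D_post - D_pre)`,
#' with channel means taken over `window` frames on each side of the step
#' (the step frame itself and one guard frame on each side excluded).
#' Background cancels in both differences, so no prior subtraction is
#' required.
#'
#' @param trace an `intensity_trace`
#' @param acceptor_bleach bleach call with `step_frame` (first bleached
#'   frame), e.g. from [select_trace()]
#' @param window frames averaged on each side of the step
#' @param donor_bleach_frame optional donor bleach frame; the post-bleach
#'   window is truncated to stay before it
#' @return positive finite gamma, or an error of class
#'   `smfretr_qc_error` with reject code `gamma_invalid`
#' @export
estimate_gamma <- function(trace, acceptor_bleach, window = 20L,
                           donor_bleach_frame = NULL) {
  b <- acceptor_bleach$step_frame
  n <- length(trace$donor)
  pre_to <- b - 2L               # guard frame before the step
  pre_from <- max(1L, pre_to - window + 1L)
  post_from <- b + 1L            # guard frame after the step
  post_to <- min(n, post_from + window - 1L)
  if (!is.null(donor_bleach_frame) && is.finite(donor_bleach_frame))
    post_to <- min(post_to, donor_bleach_frame - 1L)
  if (pre_to < pre_from || post_to < post_from)
    stop(structure(class = c("smfretr_qc_error", "error", "condition"),
                   list(message = "insufficient frames around acceptor bleach",
                        call = sys.call(), reject_reason = "gamma_invalid")))
  a_pre <- segment_mean(trace$acceptor, pre_from, pre_to)
  a_post <- segment_mean(trace$acceptor, post_from, post_to)
  d_pre <- segment_mean(trace$donor, pre_from, pre_to)
  d_post <- segment_mean(trace$donor, post_from, post_to)
  g <- (a_pre - a_post) / (d_post - d_pre)
  if (!is.finite(g) || g <= 0)
    stop(structure(class = c("smfretr_qc_error", "error", "condition"),
                   list(message = "non-positive or non-finite gamma",
                        call = sys.call(), reject_reason = "gamma_invalid")))
  g
}

#' QC an ensemble and summarize accept/reject counts
#'
#' @param traces list of `intensity_trace`
#' @param ... forwarded to [select_trace()]
#' @return list with `results` (one `qc_result` per trace) and `summary`
#'   (named counts: accepted plus each reject code; counts partition the
#'   input exactly)
#' @export
qc_ensemble <- function(traces, ...) {
  results <- lapply(traces, select_trace, ...)
  codes <- vapply(results, function(r)
    if (r$accepted) "accepted" else r$reject_reason, "")
  all_codes <- c("accepted", "no_acceptor_bleach", "no_donor_bleach",
                 "multi_step", "order_violation", "too_short", "gamma_invalid")
  summary <- vapply(all_codes, function(cd) sum(codes == cd), 0L)
  list(results = results, summary = summary)
}
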