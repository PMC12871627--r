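#' Förster distance model
#'
#' The FRET efficiency between a donor/acceptor pair separated by a
#' distance R follows `E = 1 / (1 + (R/R0)^6)`, where the Förster radius
#' R0 is the distance at which E = 0.5.  For the dye pair used here a
#' working value of R0 = 5.8 nm is adopted (calibrated per dye pair at
#' 5.85 and 5.80 nm; see [calibrate_R0()]).
#'
#' @param R0 Förster radius in nm (must be positive)
#' @return an object of class `forster_model`
#' @export
forster_model <- function(R0 = 5.8) {
  assert_that(is.numeric(R0) && length(R0) == 1 && is.finite(R0) && R0 > 0,
              "R0 must be a single positive number (nm)")
  structure(list(R0 = R0), class = "forster_model")
}

#' Convert FRET efficiency to inter-dye distance
#'
#' Inverts the Förster relation: `R = R0 * ((1 - E) / E)^(1/6)`.
#' Strictly decreasing in E.  Fit means that fall at or outside the
#' physical range (E <= 0 or >= 1, which histogram fits occasionally
#' produce) are clamped to `[0.01, 0.99]` when `clamp = TRUE` and the
#' result is flagged; with `clamp = FALSE` they raise a domain error.
#'
#' @param E efficiency vector, each in (0, 1)
#' @param model a [forster_model()] (default R0 = 5.8 nm)
#' @param clamp clamp out-of-range efficiencies for reporting
#' @return distances in nm; attribute `clamped` marks clamped entries
#' @seealso [format_distance()] for 0.1-nm reporting
#' @export
fret_to_distance <- function(E, model = forster_model(), clamp = FALSE) {
  stopifnot(inherits(model, "forster_model"))
  clamped <- E <= 0 | E >= 1
  if (any(clamped) && !clamp)
    stop_param("E must lie strictly within (0, 1); got ",
               paste(signif(E[clamped], 3), collapse = ", "))
  Ec <- ifelse(clamped, pmin(pmax(E, 0.01), 0.99), E)
  R <- model$R0 * ((1 - Ec) / Ec)^(1 / 6)
  if (any(clamped)) attr(R, "clamped") <- clamped
  R
}

#' Convert inter-dye distance to FRET efficiency
#'
#' `E = 1 / (1 + (R/R0)^6)`; exact inverse of [fret_to_distance()].
#'
#' @param R distance vector in nm, each positive
#' @param model a [forster_model()]
#' @return efficiencies in (0, 1)
#' @export
distance_to_fret <- function(R, model = forster_model()) {
  stopifnot(inherits(model, "forster_model"))
  assert_that(all(is.finite(R) & R > 0), "R must be positive (nm)")
  1 / (1 + (R / model$R0)^6)
}

#' Report a distance to 0.1 nm
#'
#' Distances are conventionally printed to one decimal, rounding halves
#' up; the raw value should always be retained alongside.
#'
#' @param R distance in nm
#' @return numeric rounded to one decimal
#' @export
format_distance <- function(R) round_half_up(R, 1)

#' Calibrate the Förster radius from reference distances
#'
#' Given pairs of a measured efficiency and a structure-derived reference
#' distance, solves for R0.  A single pair has the closed form
#' `R0 = R_ref * (E / (1 - E))^(1/6)`; multiple pairs are pooled by least
#' squares on predicted vs measured efficiency.
#'
#' @param pairs data.frame with columns `E_measured` (each in (0, 1)) and
#'   `R_reference` (nm, positive); optional `label`
#' @return a `forster_model` with extra fields `per_pair_R0` and
#'   `residuals` (E_pred - E_measured at the pooled R0)
#' @export
calibrate_R0 <- function(pairs) {
  assert_that(is.data.frame(pairs) && nrow(pairs) >= 1,
              "pairs must be a non-empty data.frame")
  assert_that(all(c("E_measured", "R_reference") %in% names(pairs)),
              "pairs needs columns E_measured and R_reference")
  E <- pairs$E_measured; R <- pairs$R_reference
  assert_that(all(E > 0 & E < 1), "E_measured must lie in (0, 1)")
  assert_that(all(R > 0), "R_reference must be positive")
  per_pair <- R * (E / (1 - E))^(1 / 6)
  if (nrow(pairs) == 1) {
    R0 <- per_pair
  } else {
    # stationary point of the least-squares objective: the gradient is
    # negative below every per-pair root and positive above, so a root
    # bracket around the per-pair estimates always exists
    grad <- function(r0) {
      Ep <- 1 / (1 + (R / r0)^6)
      dEp <- 6 * r0^5 * R^6 / (r0^6 + R^6)^2
      sum(2 * (Ep - E) * dEp)
    }
    lo <- min(per_pair) * 0.9; hi <- max(per_pair) * 1.1
    R0 <- tryCatch(
      stats::uniroot(grad, c(lo, hi), tol = 1e-13, extendInt = "upX")$root,
      error = function(e) {
        obj <- function(r0) sum((1 / (1 + (R / r0)^6) - E)^2)
        stats::optimize(obj, c(lo / 2, hi * 2), tol = 1e-12)$minimum
      })
  }
  m <- forster_model(R0)
  m$per_pair_R0 <- per_pair
  m$residuals <- 1 / (1 + (R / R0)^6) - E
  m
}
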