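#' Normalized puncta-intensity time course of one cell
#'
#' For each frame of a TIRF stack, takes the mean background-corrected
#' intensity over the cell-footprint mask, then normalizes the series by
#' its first frame — so the output starts at exactly 1 and
#' expression-level differences between cells cancel.
#'
#' @param stack numeric array `T x H x W` (frames first), or a list of
#'   `H x W` matrices
#' @param mask logical `H x W` footprint mask with at least one TRUE
#'   pixel; `NULL` for an Otsu threshold of the temporal mean image
#' @param background scalar or per-frame vector subtracted before
#'   averaging; `NULL` estimates it as the per-frame 5th-percentile pixel
#'   value outside the mask (fallback: whole frame)
#' @return numeric series of length T, first element exactly 1;
#'   attributes `raw_means` and `background_used`
#' @export
puncta_timecourse <- function(stack, mask = NULL, background = NULL) {
  if (is.list(stack))
    stack <- aperm(simplify2array(stack), c(3, 1, 2))
  assert_that(is.array(stack) && length(dim(stack)) == 3,
              "stack must be a T x H x W array")
  nt <- dim(stack)[1]
  if (is.null(mask)) mask <- otsu_mask(apply(stack, c(2, 3), mean))
  assert_that(is.logical(mask) && all(dim(mask) == dim(stack)[2:3]),
              "mask must be a logical H x W matrix")
  assert_that(any(mask), "mask must contain at least one TRUE pixel")
  if (is.null(background)) {
    outside <- !mask
    background <- vapply(seq_len(nt), function(t) {
      fr <- stack[t, , ]
      px <- if (any(outside)) fr[outside] else fr
      stats::quantile(px, 0.05, names = FALSE)
    }, 0)
  }
  if (length(background) == 1) background <- rep(background, nt)
  assert_that(length(background) == nt,
              "background must be scalar or length T")
  raw <- vapply(seq_len(nt), function(t) mean(stack[t, , ][mask]), 0)
  corrected <- raw - background
  if (corrected[1] <= 0)
    stop_param("first-frame footprint mean is non-positive after ",
               "background correction; cannot normalize")
  out <- corrected / corrected[1]
  attr(out, "raw_means") <- raw
  attr(out, "background_used") <- background
  out
}

# Otsu's threshold on a grayscale image; returns the above-threshold mask.
otsu_mask <- function(img, n_breaks = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(img > rng[1])  # flat image: empty mask
  edges <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = n_breaks)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_breaks + 1L)]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  thr <- mids[which.max(between)]
  img > thr
}

#' Aggregate per-cell time courses into mean and SEM series
#'
#' @param series_list list of equal-length numeric series, one per cell
#' @return list with `mean`, `sem` (`sd/sqrt(n)`, 0 when n = 1), `n`
#' @export
aggregate_cells <- function(series_list) {
  assert_that(is.list(series_list) && length(series_list) >= 1,
              "need at least one cell series")
  len <- vapply(series_list, length, 0L)
  assert_that(length(unique(len)) == 1, "all series must have equal length")
  m <- do.call(rbind, lapply(series_list, as.numeric))
  n <- nrow(m)
  sem <- if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  list(mean = colMeans(m), sem = sem, n = n)
}

#' Crosslink efficiency from band densitometry
#'
#' Fraction of protein captured in the crosslinked dimer band:
#' `dimer / (monomer + dimer)` per lane, reported as percent rounded to
#' the nearest integer.
#'
#' @param bands data.frame with columns `lane`, `monomer_intensity`,
#'   `dimer_intensity` (arbitrary densitometry units, non-negative,
#'   positive total per lane)
#' @return data.frame with `lane`, `efficiency_pct` (integer percent) and
#'   `efficiency_raw` (unrounded proportion)
#' @export
crosslink_efficiency <- function(bands) {
  assert_that(is.data.frame(bands) && nrow(bands) >= 1,
              "bands must be a non-empty data.frame")
  assert_that(all(c("lane", "monomer_intensity", "dimer_intensity") %in%
                    names(bands)),
              "bands needs columns lane, monomer_intensity, dimer_intensity")
  m <- bands$monomer_intensity; d <- bands$dimer_intensity
  assert_that(all(m >= 0 & d >= 0), "band intensities must be non-negative")
  assert_that(all(m + d > 0), "monomer + dimer must be positive per lane")
  p <- d / (m + d)
  data.frame(lane = bands$lane,
             efficiency_pct = as.integer(round_half_up(100 * p)),
             efficiency_raw = p)
}

#' Read a TIFF stack as a T x H x W array
#' @param path TIFF file with one page per frame
#' @return numeric array, frames first
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  aperm(simplify2array(pages), c(3, 1, 2))
}
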