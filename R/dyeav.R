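#' Structure model for dye accessible-volume simulation
#'
#' A minimal atomic model: one row per atom with chain, residue number,
#' atom name, element and coordinates in ångströms.  Build one from a PDB
#' file (parsed with bio3d) or directly from a data.frame, e.g. for
#' synthetic test fixtures.
#'
#' @param x path to a PDB file, a `bio3d` `pdb` object, or a data.frame
#'   with columns `chain`, `resno`, `name`, `elem`, `x`, `y`, `z`
#' @param source identifier recorded on the model
#' @return an object of class `structure_model` (data.frame of atoms with
#'   attribute `source`)
#' @export
structure_model <- function(x, source = NULL) {
  if (is.character(x) && length(x) == 1) {
    pdb <- bio3d::read.pdb(x)
    return(structure_model(pdb, source = if (is.null(source)) x else source))
  }
  if (inherits(x, "pdb")) {
    a <- x$atom
    df <- data.frame(chain = a$chain, resno = a$resno, name = a$elety,
                     elem = a$elesy, x = a$x, y = a$y, z = a$z,
                     stringsAsFactors = FALSE)
    df <- df[is.finite(df$x) & is.finite(df$y) & is.finite(df$z), ]
    attr(df, "source") <- source
    class(df) <- c("structure_model", "data.frame")
    return(df)
  }
  assert_that(is.data.frame(x), "x must be a path, pdb object, or data.frame")
  need <- c("chain", "resno", "name", "x", "y", "z")
  assert_that(all(need %in% names(x)),
              "atoms need columns chain, resno, name, x, y, z")
  if (!"elem" %in% names(x)) x$elem <- substr(x$name, 1, 1)
  assert_that(all(is.finite(x$x) & is.finite(x$y) & is.finite(x$z)),
              "coordinates must be finite")
  attr(x, "source") <- source
  class(x) <- c("structure_model", "data.frame")
  x
}

#' Describe a dye labeling site
#'
#' A cysteine-labeled site: the residue the maleimide linker attaches to,
#' the geometry of the tether, and how many dye positions to sample.
#' Defaults describe a generic maleimide-linked cyanine/AF-type dye:
#' 21 Å linker reach, 5 Å dye radius, 100 sampled positions.
#'
#' @param chain chain identifier
#' @param residue residue number (source-PDB author numbering, 1-based)
#' @param linker_length maximum dye-center reach from the attachment
#'   atom, Å
#' @param linker_width linker thickness, Å (recorded; the single-sphere
#'   accessible-volume model does not use it)
#' @param dye_radius effective dye radius, Å
#' @param n_samples number of accepted dye positions to draw
#' @param seed RNG seed for the rejection sampler
#' @return an object of class `dye_site`
#' @export
dye_site <- function(chain, residue, linker_length = 21, linker_width = 4.5,
                     dye_radius = 5, n_samples = 100L, seed = 1L) {
  assert_that(linker_length > 0, "linker_length must be positive")
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  structure(list(chain = chain, residue = residue,
                 linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "dye_site")
}

# Locate the attachment atom for a site: the residue's CB, else CA (the
# glycine case, which gets 1.5 A of extra reach to stand in for the
# missing side-chain bond). Returns index into the atom table plus the
# effective linker length.
attachment_atom <- function(structure, site) {
  rows <- which(structure$chain == site$chain & structure$resno == site$residue)
  if (length(rows) == 0)
    stop_param("residue ", site$chain, ":", site$residue, " not found in structure")
  nm <- toupper(trimws(structure$name[rows]))
  i <- rows[match("CB", nm)]
  extra <- 0
  if (is.na(i)) {
    i <- rows[match("CA", nm)]
    extra <- 1.5
  }
  if (is.na(i)) {  # synthetic fixtures may carry arbitrary atom names
    i <- rows[1]
  }
  list(index = i, linker_length = site$linker_length + extra)
}

# Deterministic local orthonormal frame anchored at atom `idx`: axes
# follow the structure under rigid motion, so seeded sampling commutes
# with rotation/translation. Falls back to the identity when the
# structure has too few non-collinear atoms.
local_frame <- function(xyz, idx) {
  A <- xyz[idx, ]
  others <- setdiff(seq_len(nrow(xyz)), idx)
  if (length(others) == 0) return(diag(3))
  d <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - A)^2))
  ord <- others[order(d, others)]
  e1 <- xyz[ord[1], ] - A
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- NULL
  for (j in ord[-1]) {
    v <- xyz[j, ] - A
    v <- v - sum(v * e1) * e1
    if (sqrt(sum(v^2)) > 1e-6) {
      e2 <- v / sqrt(sum(v^2))
      break
    }
  }
  if (is.null(e2)) return(diag(3))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

#' Sample accessible dye-center positions at a labeling site
#'
#' Rejection sampling of the dye's accessible volume: candidate centers
#' are drawn uniformly from the sphere of radius `linker_length` around
#' the attachment atom (CB, or CA + 1.5 Å for glycine) and kept when no
#' protein atom lies within `dye_radius + clash_probe` of the center.
#' Candidates are drawn in a local frame that follows the structure, so
#' the seeded sample is exactly equivariant under rigid motion of the
#' input.  Deterministic under `site$seed`.
#'
#' @param structure a [structure_model()]
#' @param site a [dye_site()]
#' @param clash_probe extra clearance added to `dye_radius`, Å
#' @param max_attempts attempt cap for the rejection sampler
#' @return matrix `n_samples` x 3 of dye-center coordinates (Å), with
#'   attribute `acceptance_rate`; raises a buried-site error when the
#'   acceptance rate at the attempt cap falls below 1%
#' @export
sample_dye_positions <- function(structure, site, clash_probe = 2,
                                 max_attempts = NULL) {
  stopifnot(inherits(structure, "structure_model"), inherits(site, "dye_site"))
  att <- attachment_atom(structure, site)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  A <- xyz[att$index, ]
  L <- att$linker_length
  clash <- site$dye_radius + clash_probe
  frame <- local_frame(xyz, att$index)
  if (is.null(max_attempts)) max_attempts <- 400L * site$n_samples

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(site$seed)

  accepted <- matrix(numeric(0), ncol = 3)
  tried <- 0L
  batch <- max(site$n_samples * 4L, 256L)
  while (nrow(accepted) < site$n_samples && tried < max_attempts) {
    m <- min(batch, max_attempts - tried)
    # uniform in the unit ball, expressed in the local frame
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- L * stats::runif(m)^(1 / 3)
    cand <- sweep(u * r, 1, 0, "+") %*% t(frame)
    cand <- sweep(cand, 2, A, "+")
    tried <- tried + m
    # min distance from each candidate to any protein atom
    ok <- vapply(seq_len(m), function(i) {
      dd <- (xyz[, 1] - cand[i, 1])^2 + (xyz[, 2] - cand[i, 2])^2 +
        (xyz[, 3] - cand[i, 3])^2
      min(dd) >= clash^2
    }, TRUE)
    accepted <- rbind(accepted, cand[ok, , drop = FALSE])
  }
  rate <- nrow(accepted) / tried
  if (nrow(accepted) < site$n_samples) {
    if (rate < 0.01)
      stop(structure(class = c("smfretr_buried_site_error", "error", "condition"),
                     list(message = sprintf(
                       "site %s:%s is buried: acceptance rate %.3f%% at attempt cap",
                       site$chain, site$residue, 100 * rate),
                       call = sys.call())))
    stop_param("could not draw ", site$n_samples,
               " accessible positions within the attempt cap")
  }
  out <- accepted[seq_len(site$n_samples), , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  attr(out, "acceptance_rate") <- rate
  out
}

#' Mean inter-dye distance between two labeling sites
#'
#' Samples the accessible volume at each site and averages the Euclidean
#' distance over all cross pairs of sampled centers (samples at the two
#' sites are independent, so every A-B pair is an equally valid draw of
#' the dye-dye distance).
#'
#' @param structure a [structure_model()]
#' @param siteA,siteB [dye_site()] objects
#' @param clash_probe forwarded to [sample_dye_positions()]
#' @return mean distance in nm, with attributes `sd_nm` (SD over cross
#'   pairs), `acceptance_rates`, and `attachment_distance_nm`
#' @export
mean_dye_distance <- function(structure, siteA, siteB, clash_probe = 2) {
  pa <- sample_dye_positions(structure, siteA, clash_probe = clash_probe)
  pb <- sample_dye_positions(structure, siteB, clash_probe = clash_probe)
  # all cross-pair distances, in A
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  aa <- attachment_atom(structure, siteA)
  ab <- attachment_atom(structure, siteB)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  datt <- sqrt(sum((xyz[aa$index, ] - xyz[ab$index, ])^2))
  out <- mean(d) / 10
  attr(out, "sd_nm") <- stats::sd(as.numeric(d)) / 10
  attr(out, "acceptance_rates") <- c(A = attr(pa, "acceptance_rate"),
                                     B = attr(pb, "acceptance_rate"))
  attr(out, "attachment_distance_nm") <- datt / 10
  out
}

#' Dense-grid reference for the accessible-volume model
#'
#' Deterministic brute-force evaluation of the same accessible volume:
#' enumerates a cubic grid of spacing `grid_step` inside the linker
#' sphere, applies the identical clash rule, and returns the accessible
#' centroid and grid points.  Serves as an independent oracle for the
#' rejection sampler (the uniform-ball mean must converge to the grid
#' mean).
#'
#' @inheritParams sample_dye_positions
#' @param grid_step grid spacing in Å
#' @return list with `points` (matrix of accessible grid points, Å),
#'   `centroid`, `n_total`, `n_accessible`
#' @export
av_grid_reference <- function(structure, site, clash_probe = 2,
                              grid_step = 0.5) {
  stopifnot(inherits(structure, "structure_model"), inherits(site, "dye_site"))
  att <- attachment_atom(structure, site)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  A <- xyz[att$index, ]
  L <- att$linker_length
  clash <- site$dye_radius + clash_probe
  g <- seq(-L, L, by = grid_step)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= L^2, , drop = FALSE]
  pts <- sweep(pts, 2, A, "+")
  ok <- vapply(seq_len(nrow(pts)), function(i) {
    dd <- (xyz[, 1] - pts[i, 1])^2 + (xyz[, 2] - pts[i, 2])^2 +
      (xyz[, 3] - pts[i, 3])^2
    min(dd) >= clash^2
  }, TRUE)
  acc <- pts[ok, , drop = FALSE]
  list(points = acc, centroid = colMeans(acc),
       n_total = nrow(pts), n_accessible = nrow(acc))
}

#' Tabulate mean dye distances for a list of site pairs
#'
#' @param structure a [structure_model()]
#' @param pairs list of `list(label =, siteA =, siteB =)` entries
#' @param path optional TSV output path
#' @return data.frame with pair label, mean distance (nm), SD (nm) and
#'   per-site acceptance rates
#' @export
dye_distance_table <- function(structure, pairs, path = NULL) {
  rows <- lapply(pairs, function(p) {
    d <- mean_dye_distance(structure, p$siteA, p$siteB)
    ar <- attr(d, "acceptance_rates")
    data.frame(label = p$label, mean_nm = as.numeric(d),
               sd_nm = attr(d, "sd_nm"),
               acceptance_A = ar[["A"]], acceptance_B = ar[["B"]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
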