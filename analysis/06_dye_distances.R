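#!/usr/bin/env Rscript
# Stage 6: accessible-volume dye-distance prediction on a synthetic
# structure. Builds an idealized parallel two-helix dimer in code (no
# coordinate files shipped), attaches dye sites at matched residues on
# the two chains, and compares the rejection-sampling mean inter-dye
# distance against the deterministic dense-grid reference.
#
# The helix geometry is the standard alpha-helix parametrization
# (2.3 A radius, 1.5 A rise and 100 degrees turn per residue); the two
# helix axes run parallel 12 A apart, a coiled-coil-like spacing.

library(smfretr)

helix <- function(n_res, chain, offset = c(0, 0, 0)) {
  i <- seq_len(n_res)
  data.frame(chain = chain, resno = i, name = "CB", elem = "C",
             x = offset[1] + 2.3 * cos(i * 100 * pi / 180),
             y = offset[2] + 2.3 * sin(i * 100 * pi / 180),
             z = offset[3] + 1.5 * i)
}
s <- structure_model(rbind(helix(40, "A"), helix(40, "B", c(12, 0, 0))),
                     source = "synthetic two-helix dimer")

mk <- function(chain, res, seed) {
  dye_site(chain, res, linker_length = 21, dye_radius = 5,
           n_samples = 100, seed = seed)
}
pairs <- list(
  list(label = "10:10'", siteA = mk("A", 10, 1), siteB = mk("B", 10, 2)),
  list(label = "20:20'", siteA = mk("A", 20, 3), siteB = mk("B", 20, 4)),
  list(label = "10:30", siteA = mk("A", 10, 5), siteB = mk("A", 30, 6)))

tab <- dye_distance_table(s, pairs, path = "results/dye_distances.tsv")
print(tab, row.names = FALSE, digits = 3)

# oracle cross-check on the first pair with a denser sampler
big <- list(siteA = mk("A", 10, 7), siteB = mk("B", 10, 8))
big$siteA$n_samples <- 2000L; big$siteB$n_samples <- 2000L
d_mc <- as.numeric(mean_dye_distance(s, big$siteA, big$siteB))
gA <- av_grid_reference(s, big$siteA, grid_step = 1.2)
gB <- av_grid_reference(s, big$siteB, grid_step = 1.2)
cross <- sqrt(pmax(outer(rowSums(gA$points^2), rowSums(gB$points^2), "+") -
                     2 * gA$points %*% t(gB$points), 0))
cat(sprintf("\n10:10' mean distance: sampler %.3f nm, grid reference %.3f nm\n",
            d_mc, mean(cross) / 10))
cat("wrote results/dye_distances.tsv\n")
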