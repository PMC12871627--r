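test_that("all sampled dye centers stay within linker reach", {
  s <- structure_model(atom_df(matrix(0, 1, 3)))
  site <- dye_site("A", 1, linker_length = 15, dye_radius = 0,
                   n_samples = 500, seed = 2)
  pos <- sample_dye_positions(s, site, clash_probe = 0)
  expect_equal(nrow(pos), 500)
  expect_true(all(sqrt(rowSums(pos^2)) <= 15 + 1e-9))
  # identical under the same seed
  expect_identical(pos, sample_dye_positions(s, site, clash_probe = 0))
})

test_that("a fully enclosed attachment site raises a buried-site error", {
  g <- seq(-24, 24, by = 3)
  lat <- as.matrix(expand.grid(x = g, y = g, z = g))
  lat <- lat[rowSums(lat^2) > 4 & rowSums(lat^2) <= 24^2, ]
  s <- structure_model(rbind(atom_df(matrix(0, 1, 3)),
                             atom_df(lat, chain = "S",
                                     resno = 100 + seq_len(nrow(lat)),
                                     name = "O")))
  site <- dye_site("A", 1, linker_length = 21, dye_radius = 5,
                   n_samples = 50, seed = 1)
  expect_error(sample_dye_positions(s, site, max_attempts = 20000),
               class = "smfretr_buried_site_error")
})

test_that("half-space occlusion displaces the mean position as the grid oracle says", {
  s <- structure_model(rbind(atom_df(matrix(0, 1, 3)), wall_atoms(x0 = 6)))
  site <- dye_site("A", 1, linker_length = 12, dye_radius = 3,
                   n_samples = 3000, seed = 8)
  pos <- sample_dye_positions(s, site, clash_probe = 2)
  oracle <- av_grid_reference(s, site, clash_probe = 2, grid_step = 0.4)
  expect_lt(oracle$centroid[["x"]], -1)  # pushed away from the wall
  expect_lt(max(abs(colMeans(pos) - oracle$centroid)), 0.5)
})

test_that("point-dye limit returns the attachment-atom separation", {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0))
  s <- structure_model(atom_df(xyz))
  mk <- function(res) dye_site("A", res, linker_length = 1e-6,
                               dye_radius = 0, n_samples = 50, seed = res)
  d <- mean_dye_distance(s, mk(1), mk(2), clash_probe = 0)
  expect_equal(as.numeric(d), 5, tolerance = 1e-6)
})

test_that("mean distance with finite linkers respects the reach bounds", {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0))
  s <- structure_model(atom_df(xyz))
  mk <- function(res) dye_site("A", res, linker_length = 10,
                               dye_radius = 0, n_samples = 300, seed = res)
  d <- as.numeric(mean_dye_distance(s, mk(1), mk(2), clash_probe = 0))
  expect_gte(d, 5 - 2)
  expect_lte(d, 5 + 2)
})

test_that("mean dye distance is symmetric in site order", {
  s <- structure_model(rbind(atom_df(rbind(c(0, 0, 0), c(30, 4, -2))),
                             wall_atoms(x0 = 12, half = 20)))
  a <- dye_site("A", 1, linker_length = 9, dye_radius = 2, n_samples = 200,
                seed = 5)
  b <- dye_site("A", 2, linker_length = 9, dye_radius = 2, n_samples = 200,
                seed = 6)
  expect_equal(as.numeric(mean_dye_distance(s, a, b)),
               as.numeric(mean_dye_distance(s, b, a)), tolerance = 1e-12)
})

test_that("toy two-site mean distance matches the dense-grid oracle", {
  s <- structure_model(rbind(
    atom_df(rbind(c(0, 0, 0), c(40, 0, 0))),
    wall_atoms(x0 = 8, half = 25, step = 2),
    wall_atoms(x0 = 32, half = 25, step = 2, resno_start = 5000L)))
  mk <- function(res) dye_site("A", res, linker_length = 10, dye_radius = 2.5,
                               n_samples = 1500, seed = 10 + res)
  d_mc <- as.numeric(mean_dye_distance(s, mk(1), mk(2), clash_probe = 2)) * 10
  gA <- av_grid_reference(s, mk(1), clash_probe = 2, grid_step = 1.2)
  gB <- av_grid_reference(s, mk(2), clash_probe = 2, grid_step = 1.2)
  cross <- sqrt(pmax(outer(rowSums(gA$points^2), rowSums(gB$points^2), "+") -
                       2 * gA$points %*% t(gB$points), 0))
  expect_lt(abs(d_mc - mean(cross)), 1)  # within 1 A
})

test_that("rigid motion of the structure leaves seeded distances unchanged", {
  xyz <- rbind(c(0, 0, 0), c(3, 1, 0.5), c(-1, 4, 2), c(35, -2, 1),
               c(37, 2, -1), c(33, 0, 3))
  s <- structure_model(atom_df(xyz))
  mk <- function(res) dye_site("A", res, linker_length = 8, dye_radius = 0.5,
                               n_samples = 400, seed = 3 + res)
  d0 <- as.numeric(mean_dye_distance(s, mk(1), mk(4), clash_probe = 0.5))
  for (sd in 1:3) {
    s2 <- structure_model(apply_rigid(atom_df(xyz), rigid_motion(sd)))
    d1 <- as.numeric(mean_dye_distance(s2, mk(1), mk(4), clash_probe = 0.5))
    expect_lt(abs(d1 - d0), 1e-6)
  }
})

test_that("the sampler's standard error shrinks roughly as one over sqrt(n)", {
  s <- structure_model(atom_df(rbind(c(0, 0, 0), c(30, 0, 0))))
  est <- function(n, seed) {
    a <- dye_site("A", 1, linker_length = 10, dye_radius = 0,
                  n_samples = n, seed = seed)
    b <- dye_site("A", 2, linker_length = 10, dye_radius = 0,
                  n_samples = n, seed = seed + 1000)
    as.numeric(mean_dye_distance(s, a, b, clash_probe = 0))
  }
  sd_small <- sd(vapply(1:40, function(i) est(25, i), 0))
  sd_large <- sd(vapply(1:40, function(i) est(400, 100 + i), 0))
  ratio <- sd_small / sd_large  # expect ~ sqrt(400/25) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("glycine-style sites fall back to CA with extended reach", {
  df <- data.frame(chain = "A", resno = c(1, 1, 2),
                   name = c("CA", "N", "CB"), elem = c("C", "N", "C"),
                   x = c(0, 1.4, 30), y = 0, z = 0)
  s <- structure_model(df)
  site <- dye_site("A", 1, linker_length = 10, dye_radius = 0,
                   n_samples = 200, seed = 4)
  pos <- sample_dye_positions(s, site, clash_probe = 0)
  # reach extends to linker_length + 1.5 about the CA
  expect_true(all(sqrt(rowSums(pos^2)) <= 11.5 + 1e-9))
  expect_gt(max(sqrt(rowSums(pos^2))), 10)
  expect_error(sample_dye_positions(s, dye_site("B", 9)), "not found")
})
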