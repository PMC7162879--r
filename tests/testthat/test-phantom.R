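# Segmentation, boundary extraction, property assignment and synthetic
# scenes.

test_that("uniform stacks segment into a single label", {
  stack <- array(0.5, c(8, 8, 3))
  vol <- smooth_and_segment(stack, 1, spacing = 1e-3)
  expect_equal(unique(as.integer(vol$labels)), 0L)
  expect_equal(vol$dims, c(8, 8, 3))
})

test_that("an isolated salt voxel takes its surrounding label", {
  # two-tone slice: dark left half, bright right half, one bright voxel
  # deep inside the dark half
  sl <- matrix(0.1, 16, 16)
  sl[, 9:16] <- 0.9
  sl[8, 3] <- 0.9
  stack <- array(rep(sl, 3), c(16, 16, 3))
  vol <- smooth_and_segment(stack, 2, spacing = 1e-3)
  # the salt voxel is smoothed and despeckled into the dark cluster
  expect_equal(vol$labels[8, 3, 2], vol$labels[8, 5, 2])
  expect_equal(vol$labels[8, 3, 2], 0L)
  # far field on each side keeps two distinct labels
  expect_equal(vol$labels[8, 1, 1], 0L)
  expect_equal(vol$labels[8, 16, 1], 1L)
})

test_that("block checkerboard yields exactly the requested two classes", {
  blk <- kronecker(matrix(c(0, 1, 1, 0), 2, 2), matrix(1, 8, 8))
  stack <- array(rep(blk, 2), c(16, 16, 2))
  vol <- smooth_and_segment(stack, 2, spacing = 1e-3)
  expect_setequal(unique(as.integer(vol$labels)), c(0L, 1L))
})

test_that("segmentation is idempotent on piecewise-constant stacks", {
  sl <- matrix(0.2, 12, 12); sl[4:9, 4:9] <- 0.8
  stack <- array(rep(sl, 4), c(12, 12, 4))
  v1 <- smooth_and_segment(stack, 2, spacing = 1e-3)
  v2 <- smooth_and_segment(array(as.numeric(v1$labels), dim = v1$dims), 2,
                           spacing = 1e-3)
  expect_equal(v2$labels, v1$labels)
  expect_error(smooth_and_segment(stack, 500), "distinct grey levels")
})

test_that("ball boundary sits at the transition radius with radial normals", {
  n <- 21; r_vox <- 6
  ctr <- (n + 1) / 2
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  inside <- with(idx, (i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2) <= r_vox^2
  lab <- array(0L, c(n, n, n)); lab[as.matrix(idx)[inside, ]] <- 1L
  vol <- labeled_volume(lab, 1e-3)
  surf <- extract_boundary(vol, 1L, n_directions = 256)
  d <- sqrt(rowSums(sweep(surf$points, 2, surf$centroid, `-`)^2))
  # independent oracle: exhaustive label-transition scan of the grid
  expect_true(all(abs(d - r_vox * 1e-3) <= 1.5e-3))
  expect_equal(sqrt(rowSums(surf$normals^2)), rep(1, nrow(surf$normals)),
               tolerance = 1e-9)
  radial <- sweep(surf$points, 2, surf$centroid, `-`)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_gt(mean(rowSums(radial * surf$normals)), 0.95)
})

test_that("slab faces and single voxels give axis-aligned normals", {
  lab <- array(0L, c(12, 12, 12)); lab[, , 5:7] <- 1L
  vol <- labeled_volume(lab, 1e-3)
  surf <- extract_boundary(vol, 1L, n_directions = 4096)
  # the radial directions nearest +/- z exit through the large faces with
  # normals within the angular resolution of the direction set
  up <- which.max(surf$normals[, 3]); dn <- which.min(surf$normals[, 3])
  expect_gt(surf$normals[up, 3], 0.998)
  expect_lt(surf$normals[dn, 3], -0.998)
  expect_gt(surf$points[up, 3], 6.5e-3)  # beyond the top face plane
  expect_lt(surf$points[dn, 3], 4.5e-3)
  # degenerate single-voxel tissue: 6 face centres
  lab2 <- array(0L, c(5, 5, 5)); lab2[3, 3, 3] <- 1L
  s2 <- extract_boundary(labeled_volume(lab2, 1e-3), 1L)
  expect_equal(nrow(s2$points), 6L)
  expect_equal(sort(colSums(abs(s2$normals))), c(2, 2, 2))
  expect_error(extract_boundary(vol, 7L), "not present")
})

test_that("property assignment follows the majority voxel label", {
  # all-liver volume
  lab <- array(0L, c(8, 8, 8))
  vol <- labeled_volume(lab, 2.5e-3)
  grid <- build_grid(0.02, 0.005)
  scene <- assign_properties(vol, list(`0` = "Liver"), grid)
  expect_true(all(scene$v == 1578 & scene$rho == 1050 &
                    scene$a == 0.45 & scene$y == 1.05))
  # half liver / half fat slab, split across the cell boundary
  lab2 <- array(0L, c(8, 8, 8)); lab2[5:8, , ] <- 1L
  vol2 <- labeled_volume(lab2, 2.5e-3)
  scene2 <- assign_properties(vol2, list(`0` = "Liver", `1` = "Fat"), grid)
  bc <- cell_barycenters(grid)
  # brute-force voxel counting: cells left of x = 0.01 are all liver
  expect_true(all(scene2$v[bc[, 1] < 0.01] == 1578))
  expect_true(all(scene2$v[bc[, 1] > 0.01] == 1430))
  expect_error(assign_properties(vol2, list(`0` = "Liver"), grid),
               "unmapped")
})

test_that("assignment conserves label volume fractions", {
  lab <- array(0L, c(10, 10, 10)); lab[1:3, , ] <- 1L
  vol <- labeled_volume(lab, 2e-3)
  grid <- build_grid(0.02, 0.004)
  scene <- assign_properties(vol, list(`0` = "Water", `1` = "Muscle"), grid)
  vol_frac_vox <- mean(lab == 1L) * 0.02^3
  vol_frac_cells <- sum(cell_volumes(grid)[scene$label == 1L])
  expect_lt(abs(vol_frac_cells - vol_frac_vox), max(cell_volumes(grid)) * 25)
})

test_that("synthetic scenes are deterministic and correctly layered", {
  a <- synthetic_scene("water_tank", seed = 4,
                       params = list(dims = c(0.06, 0.05, 0.05)))
  expect_equal(unique(as.integer(a$volume$labels)), 0L)
  expect_true(all(a$scene$v == 1482))
  b <- synthetic_scene("water_tank", seed = 4,
                       params = list(dims = c(0.06, 0.05, 0.05)))
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(a$scene$rho, b$scene$rho)

  lb <- synthetic_scene("layered_breast", seed = 1,
                        params = list(surfaces = FALSE))
  expect_setequal(unique(as.integer(lb$volume$labels)), 0:4)
  # radial sampling oracle: labels are monotone from core outwards along
  # random directions through the hemisphere centre
  ctr <- c(0.05, 0.03, 0.03)
  dirs <- random_unit_vectors(100, seed = 9)
  dirs[, 1] <- -abs(dirs[, 1])  # into the hemisphere
  rank_of <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 4)  # breast<fat<skin<water
  for (k in seq_len(nrow(dirs))) {
    rs <- seq(1e-3, 0.028, by = 1e-3)
    pts <- outer(rs, dirs[k, ]) + rep(ctr, each = length(rs))
    labs <- usforward:::.volume_label_at(lb$volume, pts)
    labs <- labs[!is.na(labs) & labs != 4L]
    expect_true(all(diff(rank_of[as.character(labs)]) >= 0),
                label = paste("direction", k))
  }
})
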