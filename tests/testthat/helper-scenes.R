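# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

# Small homogeneous water box with mild random property perturbations:
# a Born-regime scene for operator and solver checks.
random_contrast_scene <- function(n_side = 6, rho_amp = 0.05, v_amp = 0.02,
                                  seed = 7) {
  dims <- rep(0.005 * n_side, 3)
  sc <- synthetic_scene("homogeneous",
                        params = list(dims = dims, voxel = 0.005,
                                      base_h = 0.005))
  scene <- sc$scene
  set.seed(seed)
  n <- scene$grid$n_cells
  scene$rho <- scene$rho * (1 + rho_amp * stats::runif(n, -1, 1))
  scene$v <- scene$v * (1 + v_amp * stats::runif(n, -1, 1))
  scene
}

# The layered-breast scene with an embedded lens implant (PZT-5A inner,
# LiNbO3 outer, 1 mm / 2 mm) used by the solver-convergence checks.
breast_lens_scene <- function() {
  if (!is.null(.fixtures$breast_lens)) return(.fixtures$breast_lens)
  sc <- synthetic_scene("layered_breast", seed = 1)
  spec <- implant_spec("lens", c("PZT-5A", "LiNbO3"), c(1, 2),
                       position = c(0.042, 0.03, 0.03), axis = c(-1, 0, 0))
  scene <- embed_implant(sc$scene, build_implant(spec))
  .fixtures$breast_lens <- scene
  scene
}

breast_lens_solution <- function() {
  if (!is.null(.fixtures$breast_sol)) return(.fixtures$breast_sol)
  scene <- breast_lens_scene()
  src <- source_transducer(center = scene$source_center,
                           normal = scene$source_normal)
  .fixtures$breast_sol <- cg_solve(scene, src, 5e6)
  .fixtures$breast_sol
}

# Random unit vector triples for geometry property tests.
random_unit_vectors <- function(n, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}
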