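# fixtures are built in code at test time; nothing on disk

# plain water cylinder, no target
water_phantom <- function(n = 32L, voxel = 2, radius = 28) {
  make_phantom(phantom_spec(
    c(n, n, 1L), voxel,
    body = list(type = "cylinder", center = c(0, 0, 0), radius = radius)))
}

# water cylinder with a small centred spherical target (2-D slab)
small_target_phantom <- function(n = 32L, voxel = 2, body_r = 28,
                                 target_r = 8, target_center = c(0, 0, 0)) {
  make_phantom(phantom_spec(
    c(n, n, 1L), voxel,
    body = list(type = "cylinder", center = c(0, 0, 0), radius = body_r),
    structures = list(target = list(type = "sphere",
                                    center = target_center,
                                    radius = target_r))))
}

# mirror-symmetric phantom for the symmetry oracle
symmetric_phantom <- function() {
  ph <- make_phantom(phantom_spec(
    c(64L, 64L, 1L), 2,
    body = list(type = "cylinder", center = c(0, 0, 0), radius = 60),
    structures = list(target = list(type = "cylinder",
                                    center = c(0, 0, 0), radius = 10))))
  ph$structures$ring10 <- expand_ring(ph, "target", 10)
  ph$structures$skin <- skin_shell(ph, 5)
  ph
}

# small desk config for optimizer unit tests
tiny_config <- function(stages = 2L, generations = 3L, population = 5L,
                        polish = 50L) {
  cfg <- default_config()
  cfg$arc <- list(start = -70, stop = 70, stages = as.integer(stages))
  cfg$ga$generations <- as.integer(generations)
  cfg$ga$population <- as.integer(population)
  cfg$ga$runts <- 1L
  cfg$ga$polish_iters <- as.integer(polish)
  cfg
}

# the frozen-window DVH objective is discontinuous exactly at a dose-volume
# window's far edge; finite-difference checks are only valid away from it.
# TRUE when every DV residual sits at least `margin` Gy from its edge.
clear_of_window_edges <- function(dose, terms, phantom, windows,
                                  margin = 0.1) {
  body_idx <- which(phantom$structures[[phantom$body_name]])
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    idx <- match(which(phantom$structures[[tm$structure]]), body_idx)
    w <- windows[[k]]
    if (!is.null(w$dp) && w$dp > 0 &&
        min(abs((dose[idx] - tm$dv_plus) - w$dp)) < margin) return(FALSE)
    if (!is.null(w$dm) && w$dm < 0 &&
        min(abs((dose[idx] - tm$dv_minus) - w$dm)) < margin) return(FALSE)
  }
  TRUE
}

# dense random toy influence + quadratic-friendly terms for gradient tests
toy_problem <- function(n_vox = 12L, n_beam = 5L, seed = 1L) {
  set.seed(seed)
  ph <- make_phantom(phantom_spec(
    c(n_vox, 1L, 1L), 2,
    body = list(type = "box", center = c(0, 0, 0),
                half_size = c(n_vox, 2, 2))))
  ph$structures$target <- ph$structures$body &
    array(seq_len(n_vox) <= ceiling(n_vox / 2), dim = c(n_vox, 1, 1))
  ph$structures$oar <- ph$structures$body & !ph$structures$target
  D <- Matrix::Matrix(matrix(runif(n_vox * n_beam, 0, 2), n_vox, n_beam),
                      sparse = TRUE)
  infl <- structure(list(D = methods::as(D, "CsparseMatrix"),
                         body_idx = which(ph$structures$body),
                         block_ncol = n_beam),
                    class = "dose_influence")
  list(phantom = ph, influence = infl)
}
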