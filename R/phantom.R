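#' Synthetic voxel phantoms
#'
#' A phantom is a voxel grid of relative stopping powers (RSP, water = 1)
#' plus named binary structure masks (body, target, organs at risk, and
#' derived rings/shells). All geometry is in millimetres; world coordinates
#' are voxel centres with the origin at the grid centre, and rasterization
#' is by voxel-centre containment (no partial volumes).
#'
#' @name phantom
NULL

axis_centers <- function(n, d) (seq_len(n) - 0.5 - n / 2) * d

#' Describe a synthetic phantom as geometric primitives
#'
#' @param grid_shape integer 3-vector, voxel counts per axis (x, y, z).
#' @param voxel_size numeric 3-vector (or scalar), mm per axis.
#' @param body list describing the exterior: `type` ("cylinder" or
#'   "ellipsoid"), `center` (mm), `radius` (mm, scalar for cylinder in the
#'   axial plane, 3-vector for ellipsoid), optional `rsp` (default 1).
#' @param structures named list of primitives inside the body; each has
#'   `type` ("sphere", "cylinder" or "box"), `center`, `radius`
#'   (or `half_size` for boxes), optional `rsp` override.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size, body, structures = list()) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L,
            all(grid_shape >= 1), all(voxel_size > 0))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 body = body, structures = structures),
            class = "phantom_spec")
}

primitive_extent <- function(prim) {
  c3 <- function(v) if (length(v) == 2L) c(v, 0) else v
  ctr <- c3(prim$center %||% c(0, 0, 0))
  r <- switch(prim$type,
    sphere    = rep(prim$radius, 3L),
    cylinder  = c(prim$radius, prim$radius,
                  prim$half_length %||% Inf),
    ellipsoid = prim$radius,
    box       = prim$half_size,
    stop_dnarc("unknown primitive type: ", prim$type))
  list(lo = ctr - r, hi = ctr + r, center = ctr)
}

primitive_mask <- function(prim, cx, cy, cz) {
  ext <- primitive_extent(prim)
  ctr <- ext$center
  grid3 <- function(fx, fy, fz) {
    # outer sums of per-axis terms, returned as an nx x ny x nz array
    a <- outer(fx, fy, "+")
    outer(a, fz, "+")
  }
  switch(prim$type,
    sphere = {
      r2 <- grid3((cx - ctr[1])^2, (cy - ctr[2])^2, (cz - ctr[3])^2)
      r2 <= prim$radius^2
    },
    cylinder = {
      r2 <- outer((cx - ctr[1])^2, (cy - ctr[2])^2, "+")
      inplane <- r2 <= prim$radius^2
      hl <- prim$half_length %||% Inf
      zin <- abs(cz - ctr[3]) <= hl
      outer(inplane, zin, "&")
    },
    ellipsoid = {
      r <- prim$radius
      q <- grid3(((cx - ctr[1]) / r[1])^2, ((cy - ctr[2]) / r[2])^2,
                 ((cz - ctr[3]) / r[3])^2)
      q <= 1
    },
    box = {
      h <- prim$half_size
      grid3(ifelse(abs(cx - ctr[1]) <= h[1], 0, 1),
            ifelse(abs(cy - ctr[2]) <= h[2], 0, 1),
            ifelse(abs(cz - ctr[3]) <= h[3], 0, 1)) == 0
    },
    stop_dnarc("unknown primitive type: ", prim$type))
}

#' Rasterize a phantom specification onto its voxel grid
#'
#' Masks are rasterized by voxel-centre containment. RSP is 0 outside the
#' body and the body RSP (default 1, water) inside, with optional
#' per-structure overrides.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: list with `grid_shape`, `voxel_size`,
#'   `rsp` (3-d array), `structures` (named list of logical arrays),
#'   `body_name`, and `isocentre` (mm; the target centroid when a structure
#'   named `"target"` exists, else the grid origin).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  cx <- axis_centers(gs[1], vs[1])
  cy <- axis_centers(gs[2], vs[2])
  cz <- axis_centers(gs[3], vs[3])
  half <- gs * vs / 2
  check_inside <- function(prim, name) {
    ext <- primitive_extent(prim)
    lo <- ext$lo; hi <- ext$hi
    # infinite extents span the grid; single-voxel (thin-slab) axes are 2-D
    # replications, so primitives may be clipped there
    fin <- is.finite(lo) & is.finite(hi) & gs > 1L
    if (any(lo[fin] < -half[fin] - 1e-9) || any(hi[fin] > half[fin] + 1e-9))
      stop_dnarc("primitive '", name, "' extends outside the grid",
                 class = "dnarc_geometry_error")
  }
  check_inside(spec$body, "body")
  body <- primitive_mask(spec$body, cx, cy, cz)
  rsp <- array(0, dim = gs)
  rsp[body] <- spec$body$rsp %||% 1
  structures <- list(body = body)
  for (nm in names(spec$structures)) {
    prim <- spec$structures[[nm]]
    check_inside(prim, nm)
    m <- primitive_mask(prim, cx, cy, cz) & body
    if (nm == "target" && !any(m))
      stop_dnarc("target has zero volume after rasterization",
                 class = "dnarc_validation_error")
    structures[[nm]] <- m
    if (!is.null(prim$rsp)) rsp[m] <- prim$rsp
  }
  iso <- c(0, 0, 0)
  if (!is.null(structures$target)) {
    idx <- which(structures$target, arr.ind = TRUE)
    iso <- c(mean(cx[idx[, 1]]), mean(cy[idx[, 2]]), mean(cz[idx[, 3]]))
  }
  structure(list(grid_shape = gs, voxel_size = vs, rsp = rsp,
                 structures = structures, body_name = "body",
                 isocentre = iso,
                 axes = list(x = cx, y = cy, z = cz)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom:", paste(x$grid_shape, collapse = " x "), "voxels @",
      paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  for (nm in names(x$structures))
    cat(sprintf("  %-10s %6d voxels\n", nm, sum(x$structures[[nm]])))
  invisible(x)
}

voxel_coords <- function(phantom, idx) {
  ai <- arrayInd(idx, phantom$grid_shape)
  cbind(phantom$axes$x[ai[, 1]], phantom$axes$y[ai[, 2]],
        phantom$axes$z[ai[, 3]])
}

# min distance from each row of A to the point set B (both n x 3, mm)
cross_mindist <- function(A, B, chunk = 4000L) {
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, "+") - 2 * Ab %*% t(B)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1L, min)))
  }
  out
}

mask_shift <- function(m, ax, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[ax]
  if (n == 1L) return(out)
  idx_src <- lapply(d, seq_len); idx_dst <- idx_src
  if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
  else        { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
  do.call(`[<-`, c(list(out), idx_dst,
                   list(do.call(`[`, c(list(m), idx_src)))))
}

# voxels of `mask` with a face neighbour outside it (inner surface), or
# complement voxels with a face neighbour inside it (outer surface).
# Neighbourhoods only extend along axes with more than one voxel, so a thin
# slab behaves as a 2-D region.
mask_surface <- function(mask, outer = FALSE) {
  d <- dim(mask)
  nb_out <- array(FALSE, d)  # mask voxels touching the complement
  nb_in <- array(FALSE, d)   # complement voxels touching the mask
  for (ax in which(d > 1L)) for (by in c(-1L, 1L)) {
    nb_in <- nb_in | mask_shift(mask, ax, by)
    nb_out <- nb_out | mask_shift(!mask, ax, by)
  }
  # grid boundary faces count as "outside"
  for (ax in which(d > 1L)) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- c(1L, d[ax])
    nb_out <- do.call(`[<-`, c(list(nb_out), idx, list(TRUE)))
  }
  if (outer) (!mask) & nb_in else mask & nb_out
}

#' Expand a structure into a surrounding ring of healthy tissue
#'
#' Returns the in-body voxels whose centre lies within `margin` mm
#' (Euclidean, honouring anisotropic voxels) of the structure's surface
#' voxel centres, excluding the structure itself. Used e.g. for the 10 mm
#' ring of healthy tissue surrounding a scanning target volume.
#'
#' @param phantom a [make_phantom()] result.
#' @param structure structure name.
#' @param margin ring width in mm (> 0).
#' @return logical mask array.
#' @export
expand_ring <- function(phantom, structure, margin) {
  stopifnot(inherits(phantom, "phantom"), margin > 0)
  m <- phantom$structures[[structure]]
  if (is.null(m)) stop_dnarc("unknown structure name: ", structure)
  body <- phantom$structures[[phantom$body_name]]
  ring <- array(FALSE, phantom$grid_shape)
  if (!any(m)) return(ring)
  surf <- mask_surface(m)
  cand <- which(body & !m)
  if (!length(cand)) return(ring)
  d <- cross_mindist(voxel_coords(phantom, cand),
                     voxel_coords(phantom, which(surf)))
  ring[cand[d <= margin + 1e-9]] <- TRUE
  ring
}

#' In-body shell of given thickness at the body surface
#'
#' Voxels inside the body within `thickness` mm of the nearest voxel centre
#' outside the body (the skin layer, e.g. 5 mm = 0.5 cm skin).
#'
#' @inheritParams expand_ring
#' @param thickness shell thickness in mm (> 0).
#' @return logical mask array.
#' @export
skin_shell <- function(phantom, thickness) {
  stopifnot(inherits(phantom, "phantom"), thickness > 0)
  body <- phantom$structures[[phantom$body_name]]
  if (!any(body)) stop_dnarc("body mask is empty")
  out_surf <- mask_surface(body, outer = TRUE)
  shell <- array(FALSE, phantom$grid_shape)
  inb <- which(body)
  if (!any(out_surf)) { shell[inb] <- TRUE; return(shell) }  # body fills grid
  d <- cross_mindist(voxel_coords(phantom, inb),
                     voxel_coords(phantom, which(out_surf)))
  shell[inb[d <= thickness + 1e-9]] <- TRUE
  shell
}

#' Partition the body into target / ring / skin / healthy regions
#'
#' Precedence target > ring > skin guarantees no voxel is double-counted;
#' `healthy` is the remainder of the body and is the region over which
#' integral dose is accumulated.
#'
#' @inheritParams expand_ring
#' @param ring_margin ring width around the target, mm.
#' @param skin_thickness skin shell thickness, mm.
#' @return named list of four disjoint logical masks covering the body.
#' @export
region_partition <- function(phantom, ring_margin = 10, skin_thickness = 5) {
  body <- phantom$structures[[phantom$body_name]]
  target <- phantom$structures$target %||% array(FALSE, phantom$grid_shape)
  ring <- phantom$structures$ring10 %||%
    expand_ring(phantom, "target", ring_margin)
  skin <- phantom$structures$skin %||% skin_shell(phantom, skin_thickness)
  ring <- ring & !target
  skin <- skin & !target & !ring
  healthy <- body & !target & !ring & !skin
  list(target = target, ring = ring, skin = skin, healthy = healthy)
}

#' Reference planning phantom
#'
#' Desk-scale axial slab mimicking an intracranial planning geometry: a
#' water cylinder body (r = 60 mm) on a 64 x 64 grid of 2 mm voxels (one
#' 2 mm slice), a spherical target (r = 12 mm) offset laterally toward the
#' patient's right, and an abutting cylindrical organ at risk (r = 6 mm)
#' on the target's medial side. Derived structures `ring10` (10 mm ring)
#' and `skin` (5 mm shell) are attached, plus `brain` (body minus skin).
#'
#' @param nz number of axial slices (default 1).
#' @return a `phantom`.
#' @export
reference_phantom <- function(nz = 1L) {
  spec <- phantom_spec(
    grid_shape = c(64L, 64L, nz), voxel_size = 2,
    body = list(type = "cylinder", center = c(0, 0, 0), radius = 60),
    structures = list(
      target = list(type = "sphere", center = c(-15, 0, 0), radius = 12),
      oar = list(type = "cylinder", center = c(3, 0, 0), radius = 6)))
  ph <- make_phantom(spec)
  ph$structures$ring10 <- expand_ring(ph, "target", 10)
  ph$structures$skin <- skin_shell(ph, 5)
  ph$structures$brain <- ph$structures$body & !ph$structures$skin
  ph
}
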