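#' Arc discretization, energy layers and spot placement
#'
#' An arc plan carries one energy layer (beam range) per gantry control
#' point. Control points are refined in evolutionary stages: stage s has
#' 2^s + 1 evenly spaced angles, each later stage inserting midpoints
#' between the angles of the previous one, so that stage 1 has 3 control
#' points and seven stages over a 140 degree arc yield 129.
#'
#' @name plan_model
NULL

#' Control-point angles of an evolutionary stage
#'
#' @param arc_start,arc_stop arc end angles in degrees; a descending span
#'   (`arc_stop < arc_start`) enumerates the arc in that direction.
#' @param stage stage number (>= 1); stage s yields `2^s + 1` angles.
#' @return numeric vector of gantry angles, from `arc_start` to `arc_stop`;
#'   the angles of stage s-1 appear at every second position.
#' @export
stage_angles <- function(arc_start, arc_stop, stage) {
  if (stage < 1) stop_dnarc("stage must be >= 1")
  if (arc_stop == arc_start) stop_dnarc("arc span must be nonzero")
  n <- 2^stage
  arc_start + (0:n) * (arc_stop - arc_start) / n
}

# target WET samples from one gantry angle: per target voxel, the WET depth
# along the ray through that voxel, plus its BEV lateral position
target_wet_table <- function(phantom, gantry_angle) {
  tgt <- phantom$structures$target
  if (is.null(tgt) || !any(tgt)) stop_dnarc("phantom has no target voxels")
  fr <- gantry_frame(gantry_angle)
  P <- voxel_coords(phantom, which(tgt))
  rel <- sweep(P, 2, phantom$isocentre)
  u <- as.numeric(rel %*% fr$e1)
  v <- as.numeric(rel %*% fr$e2)
  tproj <- as.numeric(rel %*% fr$dir)
  # one ray march per distinct lateral position (0.5 mm dedup)
  key <- paste(round(u * 2), round(v * 2))
  wet <- numeric(length(u))
  for (k in unique(key)) {
    j <- which(key == k)
    tr <- ray_trace(phantom, gantry_angle, c(mean(u[j]), mean(v[j])))
    if (!tr$hit) { wet[j] <- NA_real_; next }
    # t of these voxels along this ray, measured from the ray start
    t_here <- tproj[j] + sum((phantom$isocentre - tr$p0) * tr$frame$dir)
    wet[j] <- approx(c(0, tr$t), c(0, tr$wet), xout = t_here, rule = 2)$y
  }
  data.frame(u = u, v = v, wet = wet)
}

#' Candidate energy layers (ranges) for a gantry angle
#'
#' Uniformly spaced WET ranges covering the span of target WET depths seen
#' from this angle, endpoints rounded outward to multiples of the spacing.
#'
#' @param phantom a `phantom` with a nonempty target.
#' @param gantry_angle degrees.
#' @param spacing_wet layer spacing in cm WET (default 0.5, i.e. 5 mm).
#' @return increasing numeric vector of ranges (cm).
#' @export
candidate_energy_layers <- function(phantom, gantry_angle,
                                    spacing_wet = 0.5) {
  tw <- target_wet_table(phantom, gantry_angle)
  w <- tw$wet[is.finite(tw$wet)]
  if (!length(w))
    stop_dnarc("target not intersected from angle ", gantry_angle)
  lo <- floor(min(w) / spacing_wet + 1e-9) * spacing_wet
  hi <- ceiling(max(w) / spacing_wet - 1e-9) * spacing_wet
  seq(lo, hi, by = spacing_wet)
}

#' Spot positions for one (angle, range) energy layer
#'
#' Beam's-eye-view lattice points at `pitch` spacing, aligned to the
#' isocentre projection, covering the target cross-section at the iso-WET
#' surface of this range plus a one-pitch margin (axis-neighbour dilation
#' of the cross-section membership on the lattice; margin spots must still
#' intersect the patient). A lattice point belongs to the cross-section
#' when some target voxel lies within half a voxel of it laterally and
#' within half a voxel of water-equivalent path of the iso-WET surface
#' longitudinally; this voxel-centre convention is symmetric under mirror
#' reflection (no floor tie-breaks). Deterministic row-major ordering
#' (v rows, then u).
#'
#' @param phantom a `phantom`.
#' @param gantry_angle degrees.
#' @param range_R layer range, cm WET.
#' @param pitch lateral spot spacing, mm (default 4).
#' @return n x 2 matrix of (u, v) positions in mm; zero rows when the layer
#'   covers no target cross-section at this angle.
#' @export
place_spots <- function(phantom, gantry_angle, range_R, pitch = 4) {
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("u", "v")))
  tw <- target_wet_table(phantom, gantry_angle)
  ok <- is.finite(tw$wet)
  if (!any(ok)) return(empty)
  tw <- tw[ok, , drop = FALSE]
  hu <- max(phantom$voxel_size) / 2 + 1e-9   # lateral half-voxel, mm
  hw <- max(phantom$voxel_size) / 20 + 1e-9  # longitudinal half-voxel, cm WET
  us <- seq(floor(min(tw$u) / pitch) - 1L,
            ceiling(max(tw$u) / pitch) + 1L) * pitch
  vs <- seq(floor(min(tw$v) / pitch) - 1L,
            ceiling(max(tw$v) / pitch) + 1L) * pitch
  band <- tw[abs(tw$wet - range_R) <= hw, , drop = FALSE]
  in_section <- matrix(FALSE, length(us), length(vs))
  if (nrow(band)) {
    for (i in seq_along(us)) for (j in seq_along(vs))
      in_section[i, j] <- any(abs(band$u - us[i]) <= hu &
                                abs(band$v - vs[j]) <= hu)
  }
  if (!any(in_section)) return(empty)
  keep <- in_section
  ni <- nrow(keep); nj <- ncol(keep)
  if (ni > 1) {
    keep[-1, ] <- keep[-1, ] | in_section[-ni, ]
    keep[-ni, ] <- keep[-ni, ] | in_section[-1, ]
  }
  if (nj > 1) {
    keep[, -1] <- keep[, -1] | in_section[, -nj]
    keep[, -nj] <- keep[, -nj] | in_section[, -1]
  }
  # margin spots must still intersect the patient
  body <- phantom$structures[[phantom$body_name]]
  fr <- gantry_frame(gantry_angle)
  B <- sweep(voxel_coords(phantom, which(body)), 2, phantom$isocentre)
  bu <- as.numeric(B %*% fr$e1); bv <- as.numeric(B %*% fr$e2)
  idx <- which(keep, arr.ind = TRUE)
  hits <- vapply(seq_len(nrow(idx)), function(k)
    any(abs(bu - us[idx[k, 1]]) <= hu & abs(bv - vs[idx[k, 2]]) <= hu),
    TRUE)
  idx <- idx[hits, , drop = FALSE]
  if (!nrow(idx)) return(empty)
  ord <- order(vs[idx[, 2]], us[idx[, 1]])  # row-major in BEV
  cbind(u = us[idx[ord, 1]], v = vs[idx[ord, 2]])
}

#' Set the collimation mode of an arc plan
#'
#' In `per_beamlet_edge` mode each beamlet's trimmer edges are placed at
#' the beam's-eye-view target boundary along each lateral axis (evaluated
#' on the iso-WET band of the beamlet's range) whenever that boundary lies
#' within 3 sigma of the spot centre (sigma at the Bragg peak); otherwise
#' the side is left open. The returned plan is flagged for beamlet-weight
#' re-optimization.
#'
#' @param plan an `arc_plan`.
#' @param mode `"none"` or `"per_beamlet_edge"`.
#' @param phantom the phantom the plan was built on.
#' @param band_halfwidth half-width (cm WET) of the iso-WET band used to
#'   read the target cross-section (default: half the layer spacing).
#' @return the plan with `collimation` filled per spot and
#'   `needs_weight_optimization = TRUE` when edges were added.
#' @export
set_collimation <- function(plan, mode = c("per_beamlet_edge", "none"),
                            phantom, band_halfwidth = 0.25) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "arc_plan"))
  if (mode == "none") {
    plan$collimation <- lapply(plan$spots, function(s) vector("list", nrow(s)))
    plan$collimated <- FALSE
    return(plan)
  }
  hv <- max(phantom$voxel_size) / 2
  rowtol <- max(max(phantom$voxel_size), 2)
  for (ci in seq_len(nrow(plan$control_points))) {
    ang <- plan$control_points$angle[ci]
    R <- plan$control_points$range[ci]
    tw <- target_wet_table(phantom, ang)
    band <- tw[is.finite(tw$wet) & abs(tw$wet - R) <= band_halfwidth, ,
               drop = FALSE]
    spots <- plan$spots[[ci]]
    edges <- vector("list", nrow(spots))
    if (nrow(spots)) {
      s0 <- default_sigma0(R)
      spk <- lateral_sigma(R, R, s0)
      for (si in seq_len(nrow(spots))) {
        u0 <- spots[si, 1]; v0 <- spots[si, 2]
        e <- list(u = c(-Inf, Inf), v = c(-Inf, Inf))
        if (nrow(band)) {
          rowi <- abs(band$v - v0) <= rowtol
          su <- if (any(rowi)) band$u[rowi] else band$u
          lo <- min(su) - hv - u0; hi <- max(su) + hv - u0
          if (abs(lo) <= 3 * spk) e$u[1] <- lo
          if (abs(hi) <= 3 * spk) e$u[2] <- hi
          coli <- abs(band$u - u0) <= rowtol
          sv <- if (any(coli)) band$v[coli] else band$v
          lo <- min(sv) - hv - v0; hi <- max(sv) + hv - v0
          if (abs(lo) <= 3 * spk) e$v[1] <- lo
          if (abs(hi) <= 3 * spk) e$v[2] <- hi
        }
        edges[[si]] <- if (all(!is.finite(unlist(e)))) NULL else e
      }
    }
    plan$collimation[[ci]] <- edges
  }
  plan$collimated <- TRUE
  plan$needs_weight_optimization <- TRUE
  plan
}

#' Beamlet list of an arc plan
#'
#' Expands the plan's control points, spots and collimation state into a
#' flat list of [beamlet()] objects in control-point then row-major spot
#' order (matching the plan's weight vector layout).
#'
#' @param plan an `arc_plan`.
#' @param sigma_t trimmer penumbra sigma at the surface, mm.
#' @return list of beamlets.
#' @export
plan_beamlets <- function(plan, sigma_t = 1.1) {
  out <- list()
  for (ci in seq_len(nrow(plan$control_points))) {
    ang <- plan$control_points$angle[ci]
    R <- plan$control_points$range[ci]
    spots <- plan$spots[[ci]]
    col <- plan$collimation[[ci]]
    for (si in seq_len(nrow(spots))) {
      out[[length(out) + 1L]] <-
        beamlet(ang, R, spots[si, ], collimation = col[[si]],
                sigma_t = sigma_t)
    }
  }
  out
}

#' @export
print.arc_plan <- function(x, ...) {
  cat("arc_plan:", nrow(x$control_points), "control points,",
      sum(vapply(x$spots, nrow, 0L)), "beamlets,",
      if (isTRUE(x$collimated)) "collimated" else "uncollimated", "\n")
  if (!is.null(x$normalization))
    cat("  normalization factor:", signif(x$normalization, 5), "\n")
  if (!is.null(x$fitness)) cat("  objective F:", signif(x$fitness, 5), "\n")
  invisible(x)
}
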