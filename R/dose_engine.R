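#' Analytic pencil-beam dose engine
#'
#' Beamlet dose columns are composed as pristine Bragg depth dose (sampled
#' at the water-equivalent depth projected onto the central ray) times a
#' lateral fluence profile (bivariate normal broadened by multiple Coulomb
#' scattering, optionally truncated by erf-smoothed trimmer edges).
#' Conventions: geometry in mm, water-equivalent thickness (WET) and beam
#' ranges in cm, gantry angle 0 deg enters anteriorly with angles
#' increasing toward patient-left, beams lie in the axial plane.
#'
#' @name dose_engine
NULL

BRAGG_RANGE_SPAN <- c(2, 32)  # cm, validated span of the depth-dose model

#' Beam's-eye-view frame for a gantry angle
#'
#' @param gantry_angle degrees.
#' @return list with unit vectors `source` (towards the source), `dir`
#'   (beam travel), `e1` (lateral, in-plane) and `e2` (axial).
#' @export
gantry_frame <- function(gantry_angle) {
  a <- gantry_angle * pi / 180
  s <- c(sin(a), cos(a), 0)
  list(source = s, dir = -s, e1 = c(cos(a), -sin(a), 0), e2 = c(0, 0, 1))
}

#' Construct a beamlet
#'
#' @param gantry_angle degrees.
#' @param range_R beam range in cm WET (80\% distal fall-off position).
#' @param spot_xy length-2 lateral spot position in the beam's-eye view, mm.
#' @param sigma0 in-air spot sigma at the surface, mm (default: machine
#'   stand-in [default_sigma0()]).
#' @param collimation `NULL` (open) or a list with elements `u` and `v`,
#'   each `c(lo, hi)` trimmer edge offsets from the spot centre in mm
#'   (`-Inf`/`Inf` = side open).
#' @param sigma_t trimmer edge penumbra sigma at the surface, mm.
#' @return object of class `beamlet`.
#' @export
beamlet <- function(gantry_angle, range_R, spot_xy = c(0, 0),
                    sigma0 = default_sigma0(range_R), collimation = NULL,
                    sigma_t = 1.1) {
  if (range_R <= 0) stop_dnarc("range_R must be positive")
  if (sigma0 <= 0) stop_dnarc("sigma0 must be positive")
  if (!is.null(collimation)) {
    for (ax in c("u", "v")) {
      e <- collimation[[ax]] %||% c(-Inf, Inf)
      if (e[1] >= e[2])
        stop_dnarc("inverted trimmer edges on axis ", ax)
      collimation[[ax]] <- e
    }
  }
  structure(list(gantry_angle = gantry_angle, range_R = range_R,
                 spot_xy = as.numeric(spot_xy), sigma0 = sigma0,
                 collimation = collimation, sigma_t = sigma_t),
            class = "beamlet")
}

#' In-air surface spot sigma as a function of range
#'
#' Linear machine stand-in: 6 mm at R = 5 cm down to 3 mm at R = 25 cm,
#' clipped to that interval (low-energy beams have larger spots).
#'
#' @param range_R cm.
#' @return sigma in mm.
#' @export
default_sigma0 <- function(range_R) clamp_num(6.75 - 0.15 * range_R, 3, 6)

#' Cumulative water-equivalent thickness along a central ray
#'
#' Marches the ray with step half the smallest voxel dimension, summing
#' RSP x step. Depth is geometric distance from the first in-body sample.
#'
#' @param phantom a `phantom`.
#' @param gantry_angle degrees.
#' @param spot_xy lateral spot offset in the beam's-eye view, mm.
#' @return data.frame with `depth` (mm, from body entry) and `wet` (cm);
#'   zero rows with attribute `hit = FALSE` if the ray misses the body.
#' @export
wet_along_ray <- function(phantom, gantry_angle, spot_xy = c(0, 0)) {
  r <- ray_trace(phantom, gantry_angle, spot_xy)
  if (!r$hit) {
    out <- data.frame(depth = numeric(0), wet = numeric(0))
    attr(out, "hit") <- FALSE
    return(out)
  }
  keep <- r$t >= r$t_entry - 1e-9 & r$t <= r$t_exit + 1e-9
  out <- data.frame(depth = r$t[keep] - r$t_entry, wet = r$wet[keep])
  attr(out, "hit") <- TRUE
  out
}

# internal ray march; t measured from a start point outside the grid
ray_trace <- function(phantom, gantry_angle, spot_xy = c(0, 0),
                      iso = phantom$isocentre) {
  fr <- gantry_frame(gantry_angle)
  gs <- phantom$grid_shape; vs <- phantom$voxel_size
  half <- gs * vs / 2
  T0 <- sqrt(sum(half^2)) + max(vs)
  p0 <- iso + spot_xy[1] * fr$e1 + spot_xy[2] * fr$e2 - T0 * fr$dir
  h <- min(vs) / 2
  tmax <- 2 * T0
  tm <- seq(h / 2, tmax, by = h)            # segment midpoints
  px <- p0[1] + tm * fr$dir[1]
  py <- p0[2] + tm * fr$dir[2]
  pz <- p0[3] + tm * fr$dir[3]
  ix <- floor((px + half[1]) / vs[1]) + 1
  iy <- floor((py + half[2]) / vs[2]) + 1
  iz <- floor((pz + half[3]) / vs[3]) + 1
  ok <- ix >= 1 & ix <= gs[1] & iy >= 1 & iy <= gs[2] & iz >= 1 & iz <= gs[3]
  rsp <- numeric(length(tm))
  if (any(ok))
    rsp[ok] <- phantom$rsp[cbind(ix[ok], iy[ok], iz[ok])]
  wet <- cumsum(rsp * h) / 10               # cm
  inb <- which(rsp > 0)
  hit <- length(inb) > 0
  list(hit = hit, p0 = p0, frame = fr, step = h,
       t = tm + h / 2,                      # segment end positions
       wet = wet,
       t_entry = if (hit) tm[inb[1]] - h / 2 else NA_real_,
       t_exit = if (hit) tm[inb[length(inb)]] + h / 2 else NA_real_)
}

# t position at which cumulative WET first reaches w (NA if never)
ray_wet_crossing <- function(trace, w) {
  k <- which(trace$wet >= w)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  if (k == 1L) return(trace$t[1])
  t0 <- trace$t[k - 1]; t1 <- trace$t[k]
  w0 <- trace$wet[k - 1]; w1 <- trace$wet[k]
  if (w1 <= w0) return(t1)
  t0 + (w - w0) / (w1 - w0) * (t1 - t0)
}

bragg_curve <- function(range_R) {
  key <- sprintf("bragg_%.4f", range_R)
  cached <- .dnarc_cache[[key]]
  if (!is.null(cached)) return(cached)
  R <- range_R
  sigma_R <- 0.012 * R^0.935                 # cm, range straggling
  dz <- min(0.005, sigma_R / 6)
  z <- seq(0, R + 10 * sigma_R + 1.5, by = dz)
  u <- R - z
  eps <- 0.1                                 # low-energy tail fraction
  ucap <- pmax(u, dz / 2)
  d0 <- ifelse(u > 0,
               17.93 * ucap^(-0.435) + (0.444 + 31.7 * eps / R) * ucap^0.565,
               0)
  K <- ceiling(5 * sigma_R / dz)
  kz <- dz * seq(-K, K)                      # symmetric, odd length
  kern <- exp(-kz^2 / (2 * sigma_R^2))
  kern <- kern / sum(kern)
  n <- length(d0); m <- length(kern)
  conv <- stats::convolve(c(d0, numeric(m)), rev(kern), type = "open")
  # align: full convolution index offset (m-1)/2 on each side
  off <- (m - 1) / 2
  dd <- conv[(off + 1):(off + n)]
  dd <- dd / max(dd)
  out <- list(z = z, d = dd, peak_z = z[which.max(dd)])
  assign(key, out, envir = .dnarc_cache)
  out
}

#' Pristine Bragg depth-dose (relative)
#'
#' Analytic power-law stopping curve with Gaussian range straggling
#' (sigma_R = 0.012 R^0.935 cm), peak-normalized to 1. The curve has an
#' entrance plateau below the peak, a single maximum near `range_R`, and a
#' near-zero distal tail.
#'
#' @param range_R beam range in cm (validated against the supported span).
#' @param wet_depth water-equivalent depth(s) in cm; must be >= 0.
#' @return relative dose, same length as `wet_depth`.
#' @export
pristine_bragg <- function(range_R, wet_depth) {
  if (range_R < BRAGG_RANGE_SPAN[1] || range_R > BRAGG_RANGE_SPAN[2])
    stop_dnarc("range_R outside supported span [",
               BRAGG_RANGE_SPAN[1], ", ", BRAGG_RANGE_SPAN[2], "] cm")
  if (any(wet_depth < 0)) stop_dnarc("negative depth")
  bc <- bragg_curve(range_R)
  approx(bc$z, bc$d, xout = wet_depth, yleft = bc$d[1], yright = 0,
         rule = 2)$y * (wet_depth <= max(bc$z))
}

#' Lateral beamlet sigma at depth
#'
#' Multiple-Coulomb-scattering growth sigma_MCS(d) = k R (d/R)^1.7 cm with
#' k = 0.025, added in quadrature to the in-air surface sigma.
#'
#' @param range_R cm.
#' @param wet_depth cm (>= 0); growth saturates at the range.
#' @param sigma0 surface sigma, mm.
#' @return sigma in mm.
#' @export
lateral_sigma <- function(range_R, wet_depth, sigma0) {
  ratio <- clamp_num(wet_depth / range_R, 0, 1)
  mcs <- 10 * 0.025 * range_R * ratio^1.7   # mm
  sqrt(sigma0^2 + mcs^2)
}

edge_sigma <- function(range_R, wet_depth, sigma_t = 1.1) {
  ratio <- clamp_num(wet_depth / range_R, 0, 1)
  mcs <- 10 * 0.025 * range_R * ratio^1.7
  sqrt(sigma_t^2 + mcs^2)
}

#' Lateral fluence profile of a beamlet at depth
#'
#' Uncollimated: normalized bivariate normal with [lateral_sigma()].
#' Collimated: the same kernel multiplied per trimmer edge by an
#' erf-smoothed step with depth-broadened penumbra sigma, so the collimated
#' profile never exceeds the uncollimated one.
#'
#' @param beamlet a [beamlet()].
#' @param wet_depth cm; scalar or one value per offset row.
#' @param offsets n x 2 matrix of (du, dv) offsets from the spot centre, mm.
#' @return fluence weights (1/mm^2), length n.
#' @export
lateral_profile <- function(beamlet, wet_depth, offsets) {
  offsets <- matrix(offsets, ncol = 2)
  du <- offsets[, 1]; dv <- offsets[, 2]
  sg <- lateral_sigma(beamlet$range_R, wet_depth, beamlet$sigma0)
  f <- exp(-(du^2 + dv^2) / (2 * sg^2)) / (2 * pi * sg^2)
  col <- beamlet$collimation
  if (!is.null(col)) {
    st <- edge_sigma(beamlet$range_R, wet_depth, beamlet$sigma_t)
    eu <- col$u; ev <- col$v
    if (is.finite(eu[2])) f <- f * pnorm((eu[2] - du) / st)
    if (is.finite(eu[1])) f <- f * pnorm((du - eu[1]) / st)
    if (is.finite(ev[2])) f <- f * pnorm((ev[2] - dv) / st)
    if (is.finite(ev[1])) f <- f * pnorm((dv - ev[1]) / st)
  }
  f
}

# cached per-phantom geometry: in-body voxel linear indices and coordinates
phantom_geometry <- function(phantom) {
  body_idx <- which(phantom$structures[[phantom$body_name]])
  list(body_idx = body_idx, coords = voxel_coords(phantom, body_idx))
}

#' Dose column of one beamlet on the phantom grid
#'
#' Dose is deposited to in-body voxels as Bragg depth-dose (at the voxel's
#' projected depth along the central ray) times the lateral profile at the
#' voxel's beam's-eye-view offset. Support is truncated at `cutoff` times
#' the column maximum.
#'
#' @param phantom a `phantom`.
#' @param blet a [beamlet()].
#' @param cutoff relative support truncation (default 1e-3).
#' @param geom optional precomputed [phantom_geometry()] (performance).
#' @return list with `idx` (in-body voxel positions, indices into
#'   `geom$body_idx` order), `val` (Gy per unit weight) and `n_body`.
#' @export
beamlet_dose <- function(phantom, blet, cutoff = 1e-3, geom = NULL) {
  stopifnot(inherits(blet, "beamlet"))
  if (is.null(geom)) geom <- phantom_geometry(phantom)
  tr <- ray_trace(phantom, blet$gantry_angle, blet$spot_xy)
  n <- length(geom$body_idx)
  if (!tr$hit) {
    warning("beamlet ray misses the body; zero dose column")
    return(list(idx = integer(0), val = numeric(0), n_body = n))
  }
  fr <- tr$frame
  rel <- sweep(geom$coords, 2, tr$p0)
  tv <- rel %*% fr$dir
  du <- rel %*% fr$e1
  dv <- rel %*% fr$e2
  wetv <- approx(c(0, tr$t), c(0, tr$wet), xout = tv, rule = 2)$y
  # lateral prefilter: beyond ~5 sigma at the deepest point nothing survives
  smax <- lateral_sigma(blet$range_R, blet$range_R, blet$sigma0)
  lat_lim <- 5 * smax
  sel <- which(abs(du) <= lat_lim & abs(dv) <= lat_lim &
                 wetv <= blet$range_R + 2 & tv >= tr$t_entry - max(
                   phantom$voxel_size))
  if (!length(sel)) return(list(idx = integer(0), val = numeric(0), n_body = n))
  b <- pristine_bragg(blet$range_R, pmax(wetv[sel], 0))
  f <- lateral_profile(blet, pmax(wetv[sel], 0), cbind(du[sel], dv[sel]))
  dose <- b * f
  # the truncation threshold uses the open-field column maximum so that a
  # collimated column's support is a subset of its uncollimated column's
  # (dominance survives sparsification)
  if (is.null(blet$collimation)) {
    mx <- max(dose)
  } else {
    open <- blet; open$collimation <- NULL
    mx <- max(b * lateral_profile(open, pmax(wetv[sel], 0),
                                  cbind(du[sel], dv[sel])))
  }
  if (mx <= 0) return(list(idx = integer(0), val = numeric(0), n_body = n))
  keep <- dose >= cutoff * mx
  list(idx = sel[keep], val = dose[keep], n_body = n)
}

#' Assemble a dose-influence matrix
#'
#' Sparse matrix mapping beamlet weights to voxel doses: column j is the
#' [beamlet_dose()] of beamlet j; `dose = D \%*\% w`. Rows are the in-body
#' voxels of the phantom in `body_idx` order.
#'
#' @param phantom a `phantom`.
#' @param beamlets list of [beamlet()] objects (nonempty).
#' @param cutoff per-column relative support truncation.
#' @return object of class `dose_influence`: list with sparse `D`
#'   (voxel x beamlet), `beamlets`, and `body_idx`.
#' @export
build_influence <- function(phantom, beamlets, cutoff = 1e-3) {
  stopifnot(length(beamlets) > 0)
  geom <- phantom_geometry(phantom)
  cols <- lapply(beamlets, function(b)
    beamlet_dose(phantom, b, cutoff = cutoff, geom = geom))
  ii <- unlist(lapply(cols, `[[`, "idx"), use.names = FALSE)
  jj <- rep(seq_along(cols), vapply(cols, function(c) length(c$idx), 0L))
  xx <- unlist(lapply(cols, `[[`, "val"), use.names = FALSE)
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(geom$body_idx), length(cols)))
  structure(list(D = D, beamlets = beamlets, body_idx = geom$body_idx),
            class = "dose_influence")
}

#' Dose vector (over in-body voxels) for a weight vector
#' @param influence a [build_influence()] result.
#' @param w non-negative beamlet weights.
#' @return numeric vector of voxel doses (Gy), in `body_idx` order.
#' @export
influence_dose <- function(influence, w) {
  as.numeric(influence$D %*% w)
}

# expand an in-body dose vector to the full grid array
dose_to_grid <- function(phantom, dose_body, body_idx = NULL) {
  if (is.null(body_idx))
    body_idx <- which(phantom$structures[[phantom$body_name]])
  g <- array(0, phantom$grid_shape)
  g[body_idx] <- dose_body
  g
}
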