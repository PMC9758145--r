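#' DVH-based quadratic penalty objective
#'
#' The plan objective is a sum over structures k of mean squared windowed
#' dose residuals:
#' F = sum_k (1/T_k) sum_{i in tau_k} [ b+ c^2_(0,inf)(d_i - d+)
#'   + b- c^2_(-inf,0)(d_i - d-) + bV+ c^2_(0,DeltaD+)(d_i - dV+)
#'   + bV- c^2_(DeltaD-,0)(d_i - dV-) ],
#' where c_(a,b)(x) = x inside [a, b] and 0 outside, and DeltaD is the gap
#' between the current DVH dose at volume level V and the dose-volume
#' threshold. All four penalty kinds are optional per structure.
#'
#' @name objective
NULL

#' Window (clamp-to-zero) function
#'
#' `clamp(x, a, b)` returns `x` when `a <= x <= b` and 0 otherwise
#' (infinite bounds allowed).
#'
#' @param x,a,b numeric (Gy); `a <= b`.
#' @return windowed value(s).
#' @export
clamp <- function(x, a, b) {
  if (any(a > b)) stop_dnarc("window bounds inverted (a > b)")
  x * (x >= a & x <= b)
}

#' One per-structure objective term
#'
#' @param structure structure name in the phantom.
#' @param d_plus,b_plus overdose threshold (Gy) and weight.
#' @param d_minus,b_minus underdose threshold (Gy) and weight.
#' @param v_plus,dv_plus,bv_plus dose-volume overdose: volume level (%),
#'   dose threshold (Gy), weight.
#' @param v_minus,dv_minus,bv_minus dose-volume underdose triple.
#' @return object of class `objective_term`.
#' @export
objective_term <- function(structure,
                           d_plus = NULL, b_plus = 0,
                           d_minus = NULL, b_minus = 0,
                           v_plus = NULL, dv_plus = NULL, bv_plus = 0,
                           v_minus = NULL, dv_minus = NULL, bv_minus = 0) {
  for (b in c(b_plus, b_minus, bv_plus, bv_minus))
    if (b < 0) stop_dnarc("negative penalty weight")
  for (v in c(v_plus, v_minus))
    if (!is.null(v) && (v <= 0 || v > 100))
      stop_dnarc("volume level must be in (0, 100]")
  for (d in c(d_plus, d_minus, dv_plus, dv_minus))
    if (!is.null(d) && d < 0) stop_dnarc("negative dose threshold")
  structure(list(structure = structure,
                 d_plus = d_plus, b_plus = b_plus,
                 d_minus = d_minus, b_minus = b_minus,
                 v_plus = v_plus, dv_plus = dv_plus, bv_plus = bv_plus,
                 v_minus = v_minus, dv_minus = dv_minus, bv_minus = bv_minus),
            class = "objective_term")
}

# dose values of a structure from either a full grid array or an
# in-body dose vector
structure_dose <- function(dose, mask, phantom, body_idx = NULL) {
  if (is.array(dose)) return(dose[mask])
  if (is.null(body_idx))
    body_idx <- which(phantom$structures[[phantom$body_name]])
  dose[match(which(mask), body_idx)]
}

# exact (unbinned) DVH dose at volume level p%: minimum dose received by
# the hottest p% of the structure
dose_at_volume <- function(doses, p) {
  as.numeric(quantile(doses, probs = 1 - p / 100, type = 7, names = FALSE))
}

#' Dose-volume window gap
#'
#' DeltaD = D_planned(V) - threshold: the (signed) amount by which the
#' current DVH dose at volume level V misses the dose-volume threshold.
#' Overdose terms penalize voxels with excess in (0, DeltaD]; underdose
#' terms penalize deficits in [DeltaD, 0).
#'
#' @param dose dose grid (array) or in-body dose vector.
#' @param structure logical mask (nonempty).
#' @param V volume level in % (0 < V <= 100).
#' @param threshold dose-volume threshold, Gy.
#' @param side `"over"` or `"under"`.
#' @param phantom required when `dose` is an in-body vector.
#' @return DeltaD in Gy.
#' @export
dvh_window <- function(dose, structure, V, threshold,
                       side = c("over", "under"), phantom = NULL) {
  side <- match.arg(side)
  if (!any(structure)) stop_dnarc("empty structure")
  if (V <= 0 || V > 100) stop_dnarc("V must be in (0, 100]")
  d <- structure_dose(dose, structure, phantom)
  dose_at_volume(d, V) - threshold
}

term_windows <- function(dose, terms, phantom, body_idx = NULL) {
  lapply(terms, function(tm) {
    m <- phantom$structures[[tm$structure]]
    d <- structure_dose(dose, m, phantom, body_idx)
    list(
      dp = if (!is.null(tm$v_plus) && tm$bv_plus > 0)
        dose_at_volume(d, tm$v_plus) - tm$dv_plus else NULL,
      dm = if (!is.null(tm$v_minus) && tm$bv_minus > 0)
        dose_at_volume(d, tm$v_minus) - tm$dv_minus else NULL)
  })
}

# core evaluation: F and (optionally) dF/dd over in-body voxels.
# `idx_list` gives each term's voxel positions in the dose vector.
objective_eval <- function(dose_body, terms, idx_list, windows,
                           gradient = FALSE, n_body = length(dose_body)) {
  F <- 0
  g <- if (gradient) numeric(n_body) else NULL
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    idx <- idx_list[[k]]
    Tk <- length(idx)
    if (!Tk) next
    d <- dose_body[idx]
    acc <- numeric(Tk)
    gacc <- if (gradient) numeric(Tk) else NULL
    add <- function(res, beta) {
      F <<- F + beta * sum(res^2) / Tk
      if (gradient) gacc <<- gacc + 2 * beta * res / Tk
    }
    if (!is.null(tm$d_plus) && tm$b_plus > 0)
      add(clamp(d - tm$d_plus, 0, Inf), tm$b_plus)
    if (!is.null(tm$d_minus) && tm$b_minus > 0)
      add(clamp(d - tm$d_minus, -Inf, 0), tm$b_minus)
    w <- windows[[k]]
    if (!is.null(w$dp) && w$dp > 0)
      add(clamp(d - tm$dv_plus, 0, w$dp), tm$bv_plus)
    if (!is.null(w$dm) && w$dm < 0)
      add(clamp(d - tm$dv_minus, w$dm, 0), tm$bv_minus)
    if (gradient) g[idx] <- g[idx] + gacc
  }
  list(F = F, grad = g)
}

term_indices <- function(terms, phantom, body_idx = NULL) {
  if (is.null(body_idx))
    body_idx <- which(phantom$structures[[phantom$body_name]])
  lapply(terms, function(tm) {
    m <- phantom$structures[[tm$structure]]
    if (is.null(m)) stop_dnarc("missing structure: ", tm$structure)
    match(which(m), body_idx)
  })
}

#' Evaluate the DVH-penalty objective F
#'
#' @param dose dose grid array, or in-body dose vector matching the
#'   phantom's body voxels.
#' @param terms list of [objective_term()]s.
#' @param phantom the `phantom`.
#' @param windows optional precomputed dose-volume window gaps (from the
#'   current iterate); recomputed from `dose` when `NULL`.
#' @return scalar F >= 0.
#' @export
objective_F <- function(dose, terms, phantom, windows = NULL) {
  body_idx <- which(phantom$structures[[phantom$body_name]])
  dose_body <- if (is.array(dose)) dose[body_idx] else dose
  idx <- term_indices(terms, phantom, body_idx)
  if (is.null(windows))
    windows <- term_windows(dose_body, terms, phantom, body_idx)
  objective_eval(dose_body, terms, idx, windows)$F
}

#' Gradient of F with respect to beamlet weights
#'
#' Chain rule through the dose-influence matrix:
#' dF/dw_j = sum_i (dF/dd_i) D_ij. Dose-volume windows are frozen at the
#' supplied (or current) iterate.
#'
#' @param weights beamlet weight vector.
#' @param influence a [build_influence()] result.
#' @param terms list of [objective_term()]s.
#' @param phantom the `phantom`.
#' @param windows optional frozen window gaps.
#' @return list with `F`, `grad` (per beamlet) and `windows` used.
#' @export
objective_gradient <- function(weights, influence, terms, phantom,
                               windows = NULL) {
  if (length(weights) != ncol(influence$D))
    stop_dnarc("weight vector length does not match influence columns")
  dose <- influence_dose(influence, weights)
  idx <- term_indices(terms, phantom, influence$body_idx)
  if (is.null(windows))
    windows <- term_windows(dose, terms, phantom, influence$body_idx)
  ev <- objective_eval(dose, terms, idx, windows, gradient = TRUE,
                       n_body = nrow(influence$D))
  list(F = ev$F, grad = as.numeric(Matrix::crossprod(influence$D, ev$grad)),
       windows = windows)
}

#' Cumulative dose-volume histogram
#'
#' @param dose dose grid array or in-body dose vector.
#' @param structure logical mask (nonempty).
#' @param bin_width histogram bin width in Gy (default 0.1).
#' @param phantom required when `dose` is an in-body vector.
#' @return object of class `dvh_curve`: data.frame with `dose` (bin edges,
#'   Gy) and `volume` (cumulative %, non-increasing, 100 at dose 0), with
#'   the raw voxel doses kept as an attribute for mean-dose readout.
#' @export
compute_dvh <- function(dose, structure, bin_width = 0.1, phantom = NULL) {
  if (!any(structure)) stop_dnarc("empty structure")
  d <- structure_dose(dose, structure, phantom)
  dvh_from_doses(d, bin_width)
}

dvh_from_doses <- function(d, bin_width = 0.1) {
  edges <- seq(0, (floor(max(d) / bin_width) + 2) * bin_width,
               by = bin_width)
  vol <- vapply(edges, function(e) 100 * mean(d >= e - 1e-12), 0)
  out <- data.frame(dose = edges, volume = vol)
  attr(out, "voxel_doses") <- d
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Read a metric off a DVH curve
#'
#' `"D<p>"` metrics return the dose at cumulative volume p% by linear
#' interpolation of the curve; `"Dmean"` uses the underlying voxel doses;
#' `"V<x>"` returns the volume (%) at dose x Gy.
#'
#' @param curve a [compute_dvh()] result.
#' @param metric e.g. `"D2"`, `"D50"`, `"D90"`, `"D95"`, `"Dmean"`, `"V20"`.
#' @return Gy for D-metrics, % for V-metrics.
#' @export
dvh_metric <- function(curve, metric) {
  if (metric == "Dmean") return(mean(attr(curve, "voxel_doses")))
  if (grepl("^V", metric)) {
    x <- as.numeric(sub("^V", "", metric))
    return(approx(curve$dose, curve$volume, xout = x, rule = 2)$y)
  }
  p <- as.numeric(sub("^D", "", metric))
  if (is.na(p) || p <= 0 || p > 100)
    stop_dnarc("volume level must be in (0, 100]")
  v <- curve$volume; dz <- curve$dose
  i <- max(which(v >= p))
  if (i == length(v)) return(dz[i])
  if (v[i] == v[i + 1]) return(dz[i])
  dz[i] + (dz[i + 1] - dz[i]) * (v[i] - p) / (v[i] - v[i + 1])
}

#' Integral dose to distant healthy tissue
#'
#' Sum of dose x voxel volume over the body excluding the target, its
#' surrounding ring, and the skin shell (Gy cm^3).
#'
#' @param dose dose grid array or in-body dose vector.
#' @param phantom the `phantom`.
#' @param ring_margin,skin_thickness region definition, mm.
#' @return integral dose in Gy cm^3.
#' @export
integral_dose <- function(dose, phantom, ring_margin = 10,
                          skin_thickness = 5) {
  reg <- region_partition(phantom, ring_margin, skin_thickness)
  d <- structure_dose(dose, reg$healthy, phantom)
  vol_cm3 <- prod(phantom$voxel_size) / 1000
  sum(d) * vol_cm3
}

#' Normalize a plan to prescription coverage
#'
#' Scales all beamlet weights by one global factor so that the target dose
#' at the given volume level equals the prescription, as read off the
#' package's binned DVH curve (an exact voxel-quantile scaling followed by
#' one fixed-point refinement against the curve readout, so the reported
#' coverage agrees with the prescription to within interpolation residual,
#' always inside one DVH bin).
#'
#' @param plan an `arc_plan` with optimized weights.
#' @param influence the plan's [build_influence()] matrix.
#' @param phantom the `phantom`.
#' @param prescription Gy (default 50).
#' @param level volume level % (default 95, i.e. D95).
#' @param bin_width DVH readout bin width, Gy.
#' @return the plan with scaled weights and `normalization` set.
#' @export
normalize_plan <- function(plan, influence, phantom, prescription = 50,
                           level = 95, bin_width = 0.1) {
  w <- unlist(plan$weights, use.names = FALSE)
  dose <- influence_dose(influence, w)
  tgt <- phantom$structures$target
  dt <- structure_dose(dose, tgt, phantom, influence$body_idx)
  dp <- dose_at_volume(dt, level)
  if (!is.finite(dp) || dp <= 0) stop_dnarc("zero target dose")
  f <- prescription / dp
  # refine against the binned-curve readout used for reporting
  curve <- dvh_from_doses(dt * f, bin_width = bin_width)
  dp2 <- dvh_metric(curve, paste0("D", level))
  if (is.finite(dp2) && dp2 > 0) f <- f * prescription / dp2
  plan$weights <- lapply(plan$weights, function(x) x * f)
  plan$normalization <- (plan$normalization %||% 1) * f
  plan
}
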