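#' Staged genetic optimizer for arc energy-layer selection
#'
#' Each candidate plan (member) is a haploid chromosome: one energy-layer
#' index per control point. Every generation each member's beamlet weights
#' are re-optimized by projected gradient descent, members are ranked by
#' the DVH objective F, the best member (alpha) is cloned into the next
#' generation, non-runt members mate with rank-weighted partners, and the
#' worst members (runts) are replaced by fresh random members. Stages
#' refine the arc by midpoint insertion; loci decided in earlier stages
#' are locked.
#'
#' @name optimizer
NULL

#' Planning problem context
#'
#' Precomputes and caches everything that is a pure function of the
#' phantom and machine settings: per-angle candidate layers, per-layer
#' spot grids, and per-(angle, layer) dose-influence blocks. Shared across
#' members, generations and seeds.
#'
#' @param phantom a `phantom` with target (and any structures the
#'   objective terms reference).
#' @param config a [default_config()]-style list (phantom-independent
#'   entries are used: arc, spot pitch, layer spacing, objective, ...).
#' @return an environment of class `dna_problem`.
#' @export
dna_problem <- function(phantom, config = default_config()) {
  prob <- new.env(parent = emptyenv())
  prob$phantom <- phantom
  prob$config <- config
  prob$geom <- phantom_geometry(phantom)
  prob$terms <- config_terms(config, phantom)
  prob$term_idx <- term_indices(prob$terms, phantom, prob$geom$body_idx)
  prob$cache <- new.env(parent = emptyenv())
  class(prob) <- "dna_problem"
  prob
}

angle_key <- function(angle) sprintf("a%.6f", angle)

problem_layers <- function(prob, angle) {
  key <- paste0("layers_", angle_key(angle))
  val <- prob$cache[[key]]
  if (is.null(val)) {
    val <- candidate_energy_layers(prob$phantom, angle,
                                   prob$config$layer_spacing)
    assign(key, val, envir = prob$cache)
  }
  val
}

problem_spots <- function(prob, angle, range_R) {
  key <- paste0("spots_", angle_key(angle), sprintf("_r%.3f", range_R))
  val <- prob$cache[[key]]
  if (is.null(val)) {
    val <- place_spots(prob$phantom, angle, range_R, prob$config$spot_pitch)
    assign(key, val, envir = prob$cache)
  }
  val
}

# uncollimated influence block for one (angle, layer): dgCMatrix over
# in-body voxels x spots of that layer
problem_block <- function(prob, angle, range_R) {
  key <- paste0("block_", angle_key(angle), sprintf("_r%.3f", range_R))
  val <- prob$cache[[key]]
  if (is.null(val)) {
    spots <- problem_spots(prob, angle, range_R)
    n <- length(prob$geom$body_idx)
    if (!nrow(spots)) {
      val <- new("dgCMatrix", i = integer(0), x = numeric(0), p = 0L,
                 Dim = c(n, 0L))
    } else {
      cols <- lapply(seq_len(nrow(spots)), function(si) {
        beamlet_dose(prob$phantom,
                     beamlet(angle, range_R, spots[si, ]),
                     cutoff = prob$config$dose_cutoff, geom = prob$geom)
      })
      ii <- unlist(lapply(cols, `[[`, "idx"), use.names = FALSE)
      jj <- rep(seq_along(cols), vapply(cols, function(c) length(c$idx), 0L))
      xx <- unlist(lapply(cols, `[[`, "val"), use.names = FALSE)
      val <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                  dims = c(n, length(cols)))
    }
    assign(key, val, envir = prob$cache)
  }
  val
}

member_blocks <- function(prob, angles, loci) {
  lapply(seq_along(angles), function(i) {
    layers <- problem_layers(prob, angles[i])
    problem_block(prob, angles[i], layers[loci[i]])
  })
}

member_influence <- function(prob, angles, loci) {
  blocks <- member_blocks(prob, angles, loci)
  D <- fast_cbind(blocks)
  structure(list(D = D, body_idx = prob$geom$body_idx,
                 block_ncol = vapply(blocks, ncol, 0L)),
            class = "dose_influence")
}

new_chromosome <- function(loci, locked, weights, created) {
  list(loci = as.integer(loci), locked = locked, weights = weights,
       fitness = NA_real_, created = created)
}

# uniform positive weight initialization scaled so the mean target dose is
# near the prescription
init_weights <- function(prob, D, ncols_per_cp) {
  tgt_rows <- prob$term_idx[[which(vapply(prob$terms, function(t)
    t$structure == "target", TRUE))[1]]]
  per_unit <- sum(D[tgt_rows, , drop = FALSE]) / length(tgt_rows)
  w0 <- if (per_unit > 0) prob$config$prescription / per_unit else 1
  split_by_block(rep(w0, sum(ncols_per_cp)), ncols_per_cp)
}

#' Initialize a population for one evolutionary stage
#'
#' Unlocked loci are drawn uniformly from the candidate layers of their
#' control point; locked loci are copied from the carried-over template
#' (the previous stage's alpha). Weights start uniform positive.
#'
#' @param prob a [dna_problem()].
#' @param angles stage control-point angles.
#' @param P population size (>= 3).
#' @param template optional list with `loci` and `locked` for carried-over
#'   control points.
#' @param created_from starting value of the member creation counter.
#' @return list of chromosomes (the population).
#' @export
init_population <- function(prob, angles, P, template = NULL,
                            created_from = 1L) {
  n_layers <- vapply(angles, function(a) length(problem_layers(prob, a)), 0L)
  if (any(n_layers == 0L))
    stop_dnarc("an angle has no candidate energy layers")
  locked <- template$locked %||% rep(FALSE, length(angles))
  base_loci <- template$loci %||% rep(1L, length(angles))
  lapply(seq_len(P), function(m) {
    loci <- base_loci
    for (i in which(!locked)) loci[i] <- sample.int(n_layers[i], 1L)
    new_chromosome(loci, locked, weights = NULL,
                   created = created_from + m - 1L)
  })
}

#' Optimize a member's beamlet weights
#'
#' Projected gradient descent on F over non-negative weights with a
#' Barzilai-Borwein initial step and backtracking; dose-volume windows are
#' recomputed once per outer iteration and frozen inside the line search.
#' A step is accepted only if it lowers F, so F is non-increasing.
#'
#' @param member a chromosome (its `weights` warm-start the solver; `NULL`
#'   starts from a uniform positive vector).
#' @param influence the member's `dose_influence`.
#' @param prob the [dna_problem()] (objective terms, hyperparameters).
#' @param iters outer iterations.
#' @return the member with updated `weights` and `fitness`.
#' @export
optimize_weights <- function(member, influence, prob,
                             iters = prob$config$ga$weight_iters) {
  D <- influence$D
  ncp <- influence$block_ncol
  w <- if (is.null(member$weights)) {
    unlist(init_weights(prob, D, ncp), use.names = FALSE)
  } else unlist(member$weights, use.names = FALSE)
  terms <- prob$terms; idx <- prob$term_idx
  phantom <- prob$phantom
  dose <- as.numeric(D %*% w)
  windows <- term_windows(dose, terms, phantom, influence$body_idx)
  ev <- objective_eval(dose, terms, idx, windows, gradient = TRUE,
                       n_body = nrow(D))
  Fcur <- ev$F
  if (!is.finite(Fcur)) stop_dnarc("non-finite objective")
  s <- NULL; w_prev <- NULL; g_prev <- NULL
  for (it in seq_len(iters)) {
    g <- as.numeric(Matrix::crossprod(D, ev$grad))
    if (!is.null(w_prev)) {
      dw <- w - w_prev; dg <- g - g_prev
      denom <- sum(dw * dg)
      s <- if (denom > 0) sum(dw * dw) / denom else s * 2
    }
    if (is.null(s) || !is.finite(s) || s <= 0) {
      gn <- sqrt(sum(g^2))
      s <- if (gn > 0) 0.1 * max(sum(w^2), 1)^0.5 / gn else 1
    }
    accepted <- FALSE
    for (bt in 1:25) {
      w2 <- pmax(0, w - s * g)
      dose2 <- as.numeric(D %*% w2)
      F2 <- objective_eval(dose2, terms, idx, windows, n_body = nrow(D))$F
      if (F2 < Fcur - 1e-14 * max(1, Fcur)) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break
    w_prev <- w; g_prev <- g
    w <- w2; dose <- dose2
    windows <- term_windows(dose, terms, phantom, influence$body_idx)
    ev <- objective_eval(dose, terms, idx, windows, gradient = TRUE,
                         n_body = nrow(D))
    # with refreshed windows F could tick up for DV terms; keep the frozen
    # value if so (reported F stays monotone)
    Fcur <- min(F2, ev$F)
  }
  member$weights <- split_by_block(w, ncp)
  member$fitness <- Fcur
  member
}

#' Rank a population by fitness
#'
#' Ascending F (rank 1 = alpha); ties broken by member creation index,
#' older first. Fitness is compared at 9 significant digits so that the
#' ranking is invariant to floating-point summation-order noise (members
#' of a degenerate solution space can agree in F to near machine
#' precision).
#'
#' @param pop list of evaluated chromosomes.
#' @return the population reordered by rank.
#' @export
rank_members <- function(pop) {
  Fv <- vapply(pop, `[[`, 0, "fitness")
  if (any(!is.finite(Fv))) stop_dnarc("unevaluated member in ranking")
  pop[order(signif(Fv, 9), vapply(pop, `[[`, 0L, "created"))]
}

#' Rank-linear partner selection probabilities
#'
#' p(rank r) = 2 (P - r + 1) / (P (P + 1)): the best-ranked member is P
#' times more likely to be chosen than the worst.
#'
#' @param P population size.
#' @return probability vector over ranks 1..P.
#' @export
mating_probabilities <- function(P) 2 * (P - seq_len(P) + 1) / (P * (P + 1))

#' Draw a mating partner for a parent
#'
#' Rank-linear probabilities, excluding the parent itself
#' (renormalized).
#'
#' @param ranked population ordered by [rank_members()].
#' @param parent_rank rank of the mating parent.
#' @return the partner chromosome.
#' @export
select_partner <- function(ranked, parent_rank) {
  P <- length(ranked)
  if (P < 2) stop_dnarc("need at least two members to mate")
  p <- mating_probabilities(P)
  p[parent_rank] <- 0
  r <- sample.int(P, 1L, prob = p / sum(p))
  ranked[[r]]
}

#' Mate two chromosomes
#'
#' Each unlocked locus is copied from the parent or the partner with
#' probability 1/2; locked loci are copied verbatim. The child's weight
#' block at each control point is warm-started from whichever parent
#' supplied that allele.
#'
#' @param parent,partner chromosomes with equal locus counts and locks.
#' @param created creation index for the child.
#' @return the child chromosome (fitness unset).
#' @export
mate <- function(parent, partner, created) {
  if (length(parent$loci) != length(partner$loci) ||
      !identical(parent$locked, partner$locked))
    stop_dnarc("locus count or locked-mask mismatch")
  n <- length(parent$loci)
  from_partner <- runif(n) < 0.5
  from_partner[parent$locked] <- FALSE
  loci <- ifelse(from_partner, partner$loci, parent$loci)
  weights <- parent$weights
  if (!is.null(weights) && !is.null(partner$weights))
    weights[from_partner] <- partner$weights[from_partner]
  new_chromosome(loci, parent$locked, weights, created)
}

evaluate_member <- function(prob, angles, member, iters) {
  infl <- member_influence(prob, angles, member$loci)
  # a changed locus invalidates that control point's weight block length
  if (!is.null(member$weights)) {
    ok <- vapply(seq_along(member$weights), function(i)
      length(member$weights[[i]]) == infl$block_ncol[i], TRUE)
    if (!all(ok)) {
      w0 <- init_weights(prob, infl$D, infl$block_ncol)
      member$weights[!ok] <- w0[!ok]
    }
  }
  optimize_weights(member, infl, prob, iters)
}

#' Advance a population by one generation
#'
#' Next generation = alpha clone + offspring of the non-runt, non-alpha
#' members (each mated with a rank-weighted partner) + fresh random
#' members replacing the runts; then every member's weights are
#' re-optimized and F re-evaluated.
#'
#' @param prob a [dna_problem()].
#' @param angles stage control-point angles.
#' @param pop evaluated population.
#' @param counter current creation counter value.
#' @return list with the new `pop` and updated `counter`.
#' @export
evolve_generation <- function(prob, angles, pop, counter) {
  cfg <- prob$config$ga
  P <- length(pop)
  ranked <- rank_members(pop)
  alpha <- ranked[[1L]]
  n_off <- P - 1L - cfg$runts
  offspring <- list()
  if (n_off > 0) {
    for (r in 2:(1 + n_off)) {
      partner <- select_partner(ranked, r)
      offspring[[length(offspring) + 1L]] <-
        mate(ranked[[r]], partner, counter)
      counter <- counter + 1L
    }
  }
  fresh <- init_population(prob, angles, cfg$runts,
                           template = list(loci = alpha$loci,
                                           locked = alpha$locked),
                           created_from = counter)
  counter <- counter + cfg$runts
  newpop <- c(list(alpha), offspring, fresh)
  newpop <- lapply(newpop, function(m)
    evaluate_member(prob, angles, m, cfg$weight_iters))
  list(pop = newpop, counter = counter)
}

#' Carry a stage's alpha into the next, finer stage
#'
#' The next stage's control points come from [stage_angles()]; loci at
#' carried-over angles are locked to the alpha's values, midpoint loci are
#' unlocked.
#'
#' @param alpha the finished stage's best chromosome.
#' @param stage the finished stage number.
#' @return template (`loci`, `locked`) for the next stage's
#'   [init_population()].
#' @export
advance_stage <- function(alpha, stage) {
  n_old <- length(alpha$loci)
  n_new <- 2L * n_old - 1L
  loci <- integer(n_new); locked <- logical(n_new)
  old_pos <- seq(1L, n_new, by = 2L)
  loci[old_pos] <- alpha$loci
  locked[old_pos] <- TRUE
  loci[-old_pos] <- 1L
  list(loci = loci, locked = locked)
}

chromosome_plan <- function(prob, angles, member) {
  cps <- data.frame(index = seq_along(angles), angle = angles,
                    range = vapply(seq_along(angles), function(i)
                      problem_layers(prob, angles[i])[member$loci[i]], 0),
                    locked = member$locked)
  spots <- lapply(seq_along(angles), function(i)
    problem_spots(prob, angles[i], cps$range[i]))
  structure(list(control_points = cps, spots = spots,
                 collimation = lapply(spots, function(s)
                   vector("list", nrow(s))),
                 weights = member$weights, loci = member$loci,
                 collimated = FALSE, normalization = 1,
                 fitness = member$fitness),
            class = "arc_plan")
}

# influence matrix for a (possibly collimated) plan; collimated columns are
# computed directly (not cached — they depend on the plan's edges)
plan_influence <- function(prob, plan) {
  if (!isTRUE(plan$collimated)) {
    blocks <- lapply(seq_len(nrow(plan$control_points)), function(i)
      problem_block(prob, plan$control_points$angle[i],
                    plan$control_points$range[i]))
    return(structure(list(D = fast_cbind(blocks),
                          body_idx = prob$geom$body_idx,
                          block_ncol = vapply(blocks, ncol, 0L)),
                     class = "dose_influence"))
  }
  blets <- plan_beamlets(plan, sigma_t = prob$config$sigma_t)
  geom <- prob$geom
  cols <- lapply(blets, function(b)
    beamlet_dose(prob$phantom, b, cutoff = prob$config$dose_cutoff,
                 geom = geom))
  ii <- unlist(lapply(cols, `[[`, "idx"), use.names = FALSE)
  jj <- rep(seq_along(cols), vapply(cols, function(c) length(c$idx), 0L))
  xx <- unlist(lapply(cols, `[[`, "val"), use.names = FALSE)
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(geom$body_idx), length(cols)))
  structure(list(D = D, body_idx = geom$body_idx,
                 block_ncol = vapply(plan$spots, nrow, 0L)),
            class = "dose_influence")
}

#' Run the staged genetic arc optimization
#'
#' Runs evolutionary stages 1..S over the configured arc, each stage with
#' G generations of the genetic lifecycle, locking each stage's energy
#' choices before midpoint refinement. The final alpha becomes the plan;
#' with collimation enabled, per-beamlet trimmer edges are applied to the
#' alpha and its weights re-optimized before D95 normalization.
#'
#' @param prob a [dna_problem()] (or a `phantom`, in which case `config`
#'   builds the problem).
#' @param seed integer seed; the run is a pure function of (config, seed).
#' @param config used only when `prob` is a phantom.
#' @return list of class `dna_run`: `plan` (normalized `arc_plan`),
#'   `trace` (per-generation best/mean F), `seed`, and `chromosome`.
#' @export
run_dna <- function(prob, seed = 1L, config = default_config()) {
  if (inherits(prob, "phantom")) prob <- dna_problem(prob, config)
  cfg <- prob$config
  ga <- cfg$ga
  trace <- list()
  template <- NULL
  counter <- 1L
  alpha <- NULL
  for (stage in seq_len(cfg$arc$stages)) {
    angles <- stage_angles(cfg$arc$start, cfg$arc$stop, stage)
    if (stage > 1L) template <- advance_stage(alpha, stage - 1L)
    set.seed(rng_substream(seed, "init", stage))
    pop <- init_population(prob, angles, ga$population, template, counter)
    counter <- counter + ga$population
    # carry the previous alpha's weights into every member at the locked loci
    if (!is.null(template) && !is.null(alpha$weights)) {
      old_pos <- seq(1L, length(template$loci), by = 2L)
      pop <- lapply(pop, function(m) {
        w <- vector("list", length(template$loci))
        w[old_pos] <- alpha$weights
        m$weights <- NULL  # lengths unknown at new loci; re-init in evaluate
        m$warm <- w
        m
      })
    }
    pop <- lapply(pop, function(m) {
      if (!is.null(m$warm)) {
        infl <- member_influence(prob, angles, m$loci)
        w0 <- init_weights(prob, infl$D, infl$block_ncol)
        keep <- vapply(seq_along(m$warm), function(i)
          !is.null(m$warm[[i]]) &&
            length(m$warm[[i]]) == infl$block_ncol[i], TRUE)
        w0[keep] <- m$warm[keep]
        m$weights <- w0
        m$warm <- NULL
      }
      m
    })
    pop <- lapply(pop, function(m)
      evaluate_member(prob, angles, m, ga$weight_iters))
    best <- min(vapply(pop, `[[`, 0, "fitness"))
    trace[[length(trace) + 1L]] <-
      data.frame(stage = stage, generation = 0L, best_F = best,
                 mean_F = mean(vapply(pop, `[[`, 0, "fitness")))
    for (gen in seq_len(ga$generations)) {
      set.seed(rng_substream(seed, "gen", stage, gen))
      st <- evolve_generation(prob, angles, pop, counter)
      pop <- st$pop; counter <- st$counter
      Fv <- vapply(pop, `[[`, 0, "fitness")
      trace[[length(trace) + 1L]] <-
        data.frame(stage = stage, generation = gen, best_F = min(Fv),
                   mean_F = mean(Fv))
    }
    alpha <- rank_members(pop)[[1L]]
  }
  angles <- stage_angles(cfg$arc$start, cfg$arc$stop, cfg$arc$stages)
  # final weight polish of the winning chromosome
  infl <- member_influence(prob, angles, alpha$loci)
  alpha <- optimize_weights(alpha, infl, prob, ga$polish_iters)
  plan <- chromosome_plan(prob, angles, alpha)
  if (identical(cfg$collimation, "per_beamlet_edge")) {
    plan <- set_collimation(plan, "per_beamlet_edge", prob$phantom,
                            band_halfwidth = cfg$layer_spacing / 2)
    infl <- plan_influence(prob, plan)
    member <- alpha; member$weights <- plan$weights
    member <- optimize_weights(member, infl, prob, ga$polish_iters)
    plan$weights <- member$weights
    plan$fitness <- member$fitness
    plan$needs_weight_optimization <- FALSE
  }
  plan <- normalize_plan(plan, infl, prob$phantom, cfg$prescription,
                         cfg$norm_level)
  structure(list(plan = plan, trace = do.call(rbind, trace), seed = seed,
                 chromosome = alpha, config_hash = config_hash(cfg)),
            class = "dna_run")
}

#' @export
print.dna_run <- function(x, ...) {
  cat("dna_run (seed ", x$seed, "): final F = ",
      signif(x$plan$fitness, 5), "\n", sep = "")
  print(x$plan)
  invisible(x)
}

#' Optimize a static multi-field comparison plan
#'
#' Builds an intensity-modulated plan with every candidate energy layer at
#' each given field angle (no genetic search is needed: the layer set is
#' fixed) and optimizes all beamlet weights with the same projected
#' gradient solver and objective as the arc runs.
#'
#' @param prob a [dna_problem()].
#' @param field_angles gantry angles of the fields (default right-lateral
#'   and apex).
#' @param iters weight-optimizer iterations.
#' @return an `arc_plan` (one "control point" per field-layer pair),
#'   unnormalized.
#' @export
optimize_static_plan <- function(prob, field_angles = c(270, 0),
                                 iters = 400) {
  rows <- list()
  for (a in field_angles) {
    for (R in problem_layers(prob, a))
      rows[[length(rows) + 1L]] <- list(angle = a, range = R)
  }
  angles <- vapply(rows, `[[`, 0, "angle")
  ranges <- vapply(rows, `[[`, 0, "range")
  blocks <- lapply(seq_along(rows), function(i)
    problem_block(prob, angles[i], ranges[i]))
  D <- fast_cbind(blocks)
  infl <- structure(list(D = D, body_idx = prob$geom$body_idx,
                         block_ncol = vapply(blocks, ncol, 0L)),
                    class = "dose_influence")
  member <- new_chromosome(rep(1L, length(rows)),
                           rep(FALSE, length(rows)), NULL, 1L)
  member <- optimize_weights(member, infl, prob, iters)
  cps <- data.frame(index = seq_along(rows), angle = angles, range = ranges,
                    locked = FALSE)
  spots <- lapply(seq_along(rows), function(i)
    problem_spots(prob, angles[i], ranges[i]))
  structure(list(control_points = cps, spots = spots,
                 collimation = lapply(spots, function(s)
                   vector("list", nrow(s))),
                 weights = member$weights, loci = member$loci,
                 collimated = FALSE, normalization = 1,
                 fitness = member$fitness),
            class = "arc_plan")
}
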