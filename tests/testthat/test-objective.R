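test_that("the window function clamps outside [a, b]", {
  expect_identical(clamp(5, 0, Inf), 5)
  expect_identical(clamp(-3, 0, Inf), 0)
  expect_identical(clamp(-3, -Inf, 0), -3)
  expect_equal(clamp(c(-1, 0.5, 2), 0, 1), c(0, 0.5, 0))
  expect_error(clamp(1, 2, 0))
})

test_that("dose-volume window gaps read off the DVH", {
  ph <- small_target_phantom()
  tgt <- ph$structures$target
  n <- sum(tgt)
  # construct doses so the hottest 20% sit at exactly 55 Gy
  d <- array(0, ph$grid_shape)
  doses <- rep(40, n); doses[seq_len(ceiling(0.25 * n))] <- 55
  d[tgt] <- doses
  expect_equal(dvh_window(d, tgt, V = 20, threshold = 50, side = "over"), 5)
  # uniform dose at threshold: zero gap
  d[tgt] <- 50
  expect_equal(dvh_window(d, tgt, V = 50, threshold = 50, side = "under"), 0)
  # under-side with current dose above threshold: positive gap -> no penalty
  d[tgt] <- 60
  expect_gt(dvh_window(d, tgt, V = 95, threshold = 50, side = "under"), 0)
  expect_error(dvh_window(d, array(FALSE, ph$grid_shape), 50, 50))
})

test_that("objective F evaluates the windowed quadratic penalty", {
  ph <- small_target_phantom()
  tgt <- ph$structures$target
  # one-voxel hand check: d = 55, d+ = 50, beta+ = 1 -> F = 25 / T
  d <- array(0, ph$grid_shape)
  d[ph$structures$body] <- 50
  idx <- which(tgt)[1]
  d[idx] <- 55
  terms <- list(objective_term("target", d_plus = 50, b_plus = 1))
  expect_equal(objective_F(d, terms, ph), 25 / sum(tgt))

  # all doses at thresholds -> F = 0
  d[tgt] <- 50
  terms0 <- list(objective_term("target", d_plus = 50, b_plus = 2,
                                d_minus = 50, b_minus = 3))
  expect_equal(objective_F(d, terms0, ph), 0)

  # doubling every beta doubles F
  set.seed(3)
  d[ph$structures$body] <- runif(sum(ph$structures$body), 30, 70)
  t1 <- list(objective_term("target", d_plus = 45, b_plus = 2,
                            d_minus = 55, b_minus = 1))
  t2 <- list(objective_term("target", d_plus = 45, b_plus = 4,
                            d_minus = 55, b_minus = 2))
  expect_equal(objective_F(d, t2, ph), 2 * objective_F(d, t1, ph))
  expect_gte(objective_F(d, t1, ph), 0)

  # invariance to voxel enumeration order: permuting the dose values of
  # voxels inside the structure leaves F unchanged
  db <- d[ph$structures$body]
  tgt_in_body <- which(tgt)[order(which(tgt))]
  pos <- match(tgt_in_body, which(ph$structures$body))
  db2 <- db; db2[pos] <- db[sample(pos)]
  expect_equal(objective_F(db2, t1, ph), objective_F(db, t1, ph))
})

test_that("objective gradient matches central finite differences", {
  for (inst in 1:5) {
    tp <- toy_problem(seed = inst)
    terms <- list(
      objective_term("target", d_minus = 50, b_minus = 2,
                     d_plus = 55, b_plus = 1,
                     v_minus = 83, dv_minus = 48, bv_minus = 3),
      objective_term("oar", d_plus = 20, b_plus = 1.5,
                     v_plus = 37, dv_plus = 15, bv_plus = 2))
    set.seed(100 + inst)
    for (try in 1:50) {  # sample away from frozen dose-volume window edges
      w <- runif(ncol(tp$influence$D), 5, 30)
      g <- objective_gradient(w, tp$influence, terms, tp$phantom)
      if (clear_of_window_edges(influence_dose(tp$influence, w), terms,
                                tp$phantom, g$windows)) break
    }
    fd <- vapply(seq_along(w), function(j) {
      h <- 1e-4 * max(1, abs(w[j]))
      wp <- w; wp[j] <- w[j] + h
      wm <- w; wm[j] <- w[j] - h
      Fp <- objective_F(influence_dose(tp$influence, wp), terms,
                        tp$phantom, windows = g$windows)
      Fm <- objective_F(influence_dose(tp$influence, wm), terms,
                        tp$phantom, windows = g$windows)
      (Fp - Fm) / (2 * h)
    }, 0)
    scale <- max(abs(fd), abs(g$grad), 1e-8)
    expect_lt(max(abs(g$grad - fd)) / scale, 1e-5)
  }

  # zero residual everywhere -> zero gradient
  tp <- toy_problem()
  terms <- list(objective_term("target", d_plus = 1e6, b_plus = 1,
                               d_minus = 0, b_minus = 1))
  g0 <- objective_gradient(rep(1, ncol(tp$influence$D)), tp$influence,
                           terms, tp$phantom)
  expect_identical(g0$grad, rep(0, ncol(tp$influence$D)))

  # pure-overdose term with all residuals overdosed: gradient >= 0
  terms_od <- list(objective_term("target", d_plus = 0.1, b_plus = 1))
  god <- objective_gradient(rep(10, ncol(tp$influence$D)), tp$influence,
                            terms_od, tp$phantom)
  expect_true(all(god$grad >= 0))
})

test_that("DVH curves and metrics invert known mixtures", {
  ph <- small_target_phantom()
  tgt <- ph$structures$target
  n <- sum(tgt)
  d <- array(0, ph$grid_shape)

  # uniform dose: step DVH, all Dp equal
  d[tgt] <- 50
  cv <- compute_dvh(d, tgt)
  expect_equal(cv$volume[1], 100)
  expect_true(all(diff(cv$volume) <= 0))
  for (m in c("D2", "D50", "D95"))
    expect_equal(dvh_metric(cv, m), 50, tolerance = 0.1)

  # half 0 Gy, half 10 Gy: V(5) = 50%
  doses <- rep(0, n); doses[seq_len(floor(n / 2))] <- 10
  d[tgt] <- doses
  cv2 <- compute_dvh(d, tgt)
  expect_equal(dvh_metric(cv2, "V5"), 100 * floor(n / 2) / n,
               tolerance = 0.5)

  # two-level mixture 40% at 30 Gy / 60% at 60 Gy: D50 = 60, D90 = 30
  doses <- c(rep(30, round(0.4 * n)), rep(60, n - round(0.4 * n)))
  d[tgt] <- doses
  cv3 <- compute_dvh(d, tgt)
  expect_equal(dvh_metric(cv3, "D50"), 60, tolerance = 0.11)
  expect_equal(dvh_metric(cv3, "D90"), 30, tolerance = 0.11)
  expect_equal(dvh_metric(cv3, "Dmean"), mean(doses), tolerance = 1e-12)

  # monotone quantiles for an arbitrary dose distribution
  set.seed(9)
  d[tgt] <- runif(n, 0, 70)
  cv4 <- compute_dvh(d, tgt)
  expect_gte(dvh_metric(cv4, "D2"), dvh_metric(cv4, "D50"))
  expect_gte(dvh_metric(cv4, "D50"), dvh_metric(cv4, "D95"))
  expect_error(dvh_metric(cv4, "D0"))
})

test_that("integral dose sums the healthy region with voxel volume", {
  ph <- reference_phantom()
  reg <- region_partition(ph)
  d <- array(0, ph$grid_shape)
  expect_equal(integral_dose(d, ph), 0)

  # uniform 1 Gy over the healthy region: count x 8 mm^3 / 1000
  d[reg$healthy] <- 1
  expect_equal(integral_dose(d, ph), sum(reg$healthy) * 8 / 1000)

  # region algebra matches brute-force mask set operations
  manual <- ph$structures$body & !ph$structures$target &
    !expand_ring(ph, "target", 10) & !skin_shell(ph, 5)
  d2 <- array(0, ph$grid_shape)
  d2[ph$structures$body] <- 2
  expect_equal(integral_dose(d2, ph), sum(manual) * 2 * 8 / 1000)
})

test_that("plan normalization scales to prescription coverage", {
  ph <- small_target_phantom(n = 64L, body_r = 60, target_r = 10,
                             target_center = c(-10, 0, 0))
  ph$structures$ring10 <- expand_ring(ph, "target", 10)
  prob <- dna_problem(ph, tiny_config(stages = 1L, generations = 2L))
  run <- run_dna(prob, seed = 4)
  infl <- dnarc:::plan_influence(prob, run$plan)
  dose <- influence_dose(infl, unlist(run$plan$weights))
  cv <- compute_dvh(dose, ph$structures$target, phantom = ph)
  expect_equal(dvh_metric(cv, "D95"), 50, tolerance = 0.1)

  # a uniformly conformal plan at half prescription normalizes by 2
  half <- run$plan
  half$weights <- lapply(half$weights, function(x) x / 2)
  half$normalization <- 1
  renorm <- normalize_plan(half, infl, ph)
  expect_equal(renorm$normalization, 2, tolerance = 0.01)

  # relative DVH shape is invariant under normalization
  dose2 <- influence_dose(infl, unlist(renorm$weights))
  expect_equal(dose2 / max(dose2), dose / max(dose), tolerance = 1e-9)
})
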