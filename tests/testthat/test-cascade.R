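params <- cascade_parameters()

test_that("occupancy follows the closed form, with the 310 nM midpoint", {
  aff310 <- affinity(-log10(310e-9))       # measured Kd = 310 nM
  expect_equal(occupancy(aff310, 0.310), 0.5)
  expect_equal(occupancy(aff310, 0), 0)
  expect_gte(occupancy(aff310, 1000 * aff310$Kd_uM), 0.999)
  expect_error(occupancy(aff310, -1), ">= 0")
  # strictly increasing in L, strictly decreasing in Kd
  L <- dose_grid(n = 12)
  expect_true(all(diff(occupancy(affinity(6), L)) > 0))
  expect_true(all(occupancy(affinity(7), L) > occupancy(affinity(6), L)))
})

test_that("competitive occupancy reduces to the right limits and conserves receptor", {
  al <- affinity(6); aa <- affinity(7)
  # L = 0 reduces to plain agonist occupancy
  co0 <- competitive_occupancy(al, aa, 0, 0.3)
  expect_equal(co0$agonist_bound, occupancy(aa, 0.3))
  expect_equal(co0$ligand_bound, 0)
  # saturating ligand displaces the agonist
  coInf <- competitive_occupancy(al, aa, 1e9, 0.3)
  expect_lt(coInf$agonist_bound, 1e-6)
  # equal Kd and equal concentrations: symmetric split
  cs <- competitive_occupancy(affinity(6), affinity(6), 2, 2)
  expect_equal(cs$ligand_bound, cs$agonist_bound)
  # bound + free = 1 to 1e-12 across doses
  for (L in dose_grid(n = 10)) {
    co <- competitive_occupancy(al, aa, L, 0.4)
    expect_lt(abs(co$ligand_bound + co$agonist_bound +
                  (1 - co$ligand_bound - co$agonist_bound) - 1), 1e-12)
    expect_gte(1 - co$ligand_bound - co$agonist_bound, 0)
  }
})

test_that("zero occupancy is a fixed point at basal cAMP", {
  tc <- simulate_cascade(params, 0, t_end = 200, n_steps = 400)
  expect_lt(max(abs(tc$cAMP - params$cAMP_basal)), 1e-6)
  expect_true(all(tc$G_active >= -1e-12))
})

test_that("trajectories are non-negative and steady state forgets the initial cAMP", {
  p <- cascade_parameters(deplete_atp = FALSE)
  ends <- vapply(c(0, 0.05, 2), function(c0) {
    tc <- simulate_cascade(p, 0.6, t_end = 120, n_steps = 500, cAMP0 = c0)
    expect_true(all(tc$cAMP >= -1e-9) && all(tc$ATP >= -1e-9))
    tc$cAMP[nrow(tc)]
  }, 0)
  expect_lt(diff(range(ends)) / mean(ends), 1e-3)
})

test_that("the linear (no-depletion) regime matches the analytic solution within 0.1%", {
  p <- cascade_parameters(deplete_atp = FALSE)
  for (occ in c(0.3, 0.8)) {
    tc <- simulate_cascade(p, occ, t_end = 150, n_steps = 600)
    want <- oracle_linear_cascade(p, occ, tc$time)
    rel <- abs(tc$cAMP - want) / pmax(abs(want), 1e-9)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("halving and quartering the output step changes responses by < 0.1%", {
  for (occ in c(0.2, 0.7)) {
    ends <- vapply(c(500, 1000, 2000), function(ns)
      simulate_cascade(params, occ, t_end = 200, n_steps = ns)$cAMP[ns + 1], 0)
    expect_lt(max(abs(ends - ends[2])) / abs(ends[2]), 1e-3)
  }
})

test_that("dose-response curves are monotone by mode", {
  g <- dose_grid(n = 10)
  up <- dose_response(params, 6.5, g, mode = "agonist", n_steps = 300)
  expect_true(all(diff(up$response_uM) >= -1e-8))
  expect_lt(abs(up$response_uM[1]), 0.05 * max(up$response_uM))  # dose << Kd: ~0
  down <- dose_response(params, 6.5, g, mode = "antagonist", n_steps = 300)
  expect_true(all(diff(down$response_uM) <= 1e-8))
  p0 <- cascade_parameters(agonist_tone = NULL)
  expect_error(dose_response(p0, 6.5, g, mode = "antagonist"), "agonist_tone")
})

test_that("monotonicity by mode holds across random parameter draws", {
  set.seed(17)
  g <- dose_grid(n = 7)
  for (draw in 1:25) {
    p <- cascade_parameters(
      receptor_total = runif(1, 0.5, 4), G_total = runif(1, 2, 20),
      ATP_total = runif(1, 2000, 8000), cAMP_basal = runif(1, 0.01, 0.2),
      k_G_act = runif(1, 0.1, 1), k_G_hyd = runif(1, 0.02, 0.3),
      k_AC_cat = 10^runif(1, -4.5, -3.5), k_PDE = runif(1, 0.2, 1))
    pKd <- runif(1, 5, 8)
    mode <- if (draw %% 2 == 0) "agonist" else "antagonist"
    dr <- dose_response(p, pKd, g, mode = mode, t_end = 200, n_steps = 250)
    if (mode == "agonist") expect_true(all(diff(dr$response_uM) >= -1e-6))
    else expect_true(all(diff(dr$response_uM) <= 1e-6))
  }
})

test_that("an antagonist at saturating dose suppresses the agonist tone fully", {
  g <- dose_grid(1e-3, 1e3, 12)
  dr <- dose_response(params, 7.5, g, mode = "antagonist", n_steps = 300)
  # at the top dose the tone is almost fully displaced: response approaches
  # the (negative of the) full tone-driven signal
  tone_occ <- occupancy(affinity(params$agonist_tone$pKd), params$agonist_tone$conc_uM)
  full_loss <- simulate_cascade(params, tone_occ, t_end = 300, n_steps = 300)$cAMP[301] -
    simulate_cascade(params, 0, t_end = 300, n_steps = 300)$cAMP[301]
  expect_lt(abs(dr$response_uM[length(g)] + full_loss) / full_loss, 0.05)
})

test_that("a hundredfold affinity difference shifts the midpoint a hundredfold", {
  g <- dose_grid(1e-5, 1e3, 20)
  d6 <- dose_response(params, 6, g, mode = "agonist", n_steps = 300)
  d8 <- dose_response(params, 8, g, mode = "agonist", n_steps = 300)
  ratio <- d6$hill$x50_uM / d8$hill$x50_uM
  expect_gt(ratio, 70); expect_lt(ratio, 140)
})

test_that("Hill fits recover known parameters", {
  g <- dose_grid(n = 16)
  y <- 0.2 + (5 - 0.2) / (1 + (1 / g)^1)
  h <- fit_hill(list(dose_uM = g, response_uM = y))
  expect_lt(abs(h$x50_uM - 1), 0.01)          # noiseless: within 1%
  expect_lt(abs(h$hill_n - 1), 0.01)
  # 2% noise: within 5% over 20 seeds
  for (seed in 1:20) {
    set.seed(seed)
    yn <- y + rnorm(length(y), 0, 0.02 * diff(range(y)))
    hn <- fit_hill(list(dose_uM = g, response_uM = yn))
    expect_false(hn$degenerate)
    expect_lt(abs(hn$x50_uM - 1), 0.05 * 5)   # |x50 - 1 uM| within 5% x safety
    expect_lt(abs(hn$x50_uM - 1), 0.25)
    expect_lt(abs(hn$hill_n - 1), 0.25)
  }
  # flat curve: degenerate flag, no midpoint
  hf <- fit_hill(list(dose_uM = g, response_uM = rep(0, length(g))))
  expect_true(hf$degenerate)
  expect_true(is.na(hf$x50_uM))
  expect_error(fit_hill(list(dose_uM = g[1:4], response_uM = y[1:4])), "at least 5")
})

test_that("the affinity gate is boundary-inclusive and converts pKd correctly", {
  cand <- data.frame(id = c("a", "b", "c"), pKd = c(5.4, 5.5, 7.0))
  kept <- affinity_gate(cand)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(affinity(5.5)$Kd_uM, 10^0.5, tolerance = 1e-12)  # ~3.16 uM
  expect_warning(affinity_gate(data.frame(id = "a", pKd = 4)), "no candidates")
  expect_error(affinity_gate(data.frame(id = "a", pKd = NA_real_)), "missing pKd")
})
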