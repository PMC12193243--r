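test_that("Bliss expectation composes independent effects", {
  expect_equal(bliss_expected(c(0, 0)), 0)
  expect_equal(bliss_expected(c(0.2, 0.3)), 0.44)
  expect_equal(bliss_expected(c(0.2, 0.3, 0.5)), 0.72)
  expect_equal(bliss_expected(c(0.3, 0.2)), bliss_expected(c(0.2, 0.3)))
  expect_warning(e <- bliss_expected(c(1.2, 0.3)), "clamped")
  expect_equal(e, 1)
})

test_that("worked 2x2 surface scores 6.0 points and classifies additive", {
  surf <- data.frame(a = c(0, 1, 0, 1), b = c(0, 0, 1, 1),
                     inhibition_pct = c(0, 20, 30, 50))
  res <- bliss_synergy_score(surf)
  expect_equal(res$score, 6)
  expect_identical(res$classification, "additive")
  expect_equal(res$excess$expected_pct, 44)
})

test_that("score is zero on a surface built from its own margins", {
  e_a <- c(0.1, 0.35, 0.6); e_b <- c(0.15, 0.4, 0.7, 0.85)
  grid <- expand.grid(a = c(0, 1, 3, 9), b = c(0, 2, 6, 18, 54))
  eff <- function(d, doses, e) if (d == 0) 0 else e[match(d, doses)]
  grid$inhibition_pct <- 100 * mapply(function(a, b)
    1 - (1 - eff(a, c(1, 3, 9), e_a)) * (1 - eff(b, c(2, 6, 18, 54), e_b)),
    grid$a, grid$b)
  res <- bliss_synergy_score(grid)
  expect_equal(res$score, 0, tolerance = 1e-12)
  expect_equal(max(abs(res$excess$excess)), 0, tolerance = 1e-12)
})

test_that("score shifts by c when every combination cell is raised by c", {
  tab <- simulate_viability_timecourse(two_drug_design(), two_drug_model(),
                                       noise_cv = 0.05, seed = 2)
  surf <- viability_surface(tab)
  base <- bliss_synergy_score(surf)$score
  combo <- surf$a > 0 & surf$b > 0
  shifted <- surf
  shifted$inhibition_pct[combo] <- shifted$inhibition_pct[combo] + 7.5
  expect_equal(bliss_synergy_score(shifted)$score, base + 7.5, tolerance = 1e-9)
})

test_that("drug order permutation leaves scores unchanged", {
  tab <- simulate_viability_timecourse(two_drug_design(), two_drug_model(tau = 1.4),
                                       noise_cv = 0.02, seed = 5)
  surf <- viability_surface(tab)
  res1 <- bliss_synergy_score(surf)
  res2 <- bliss_synergy_score(surf[, c("b", "a", "inhibition_pct")])
  expect_equal(res2$score, res1$score, tolerance = 1e-12)
})

test_that("missing single-agent margins are a named error", {
  surf <- data.frame(a = c(0, 0, 1), b = c(0, 2, 2), inhibition_pct = c(0, 30, 50))
  expect_error(bliss_synergy_score(surf), "margin for a at dose 1")
})

test_that("bootstrap CI brackets the point score on replicate surfaces", {
  tab <- simulate_viability_timecourse(two_drug_design(), two_drug_model(),
                                       noise_cv = 0.05, n_replicates = 4, seed = 6)
  x0 <- tab[tab$time_h == 0, ]; x1 <- tab[tab$time_h == 72, ]
  ctrl_fold <- mean(x1$signal[x1$is_control]) / mean(x0$signal[x0$is_control])
  surf <- data.frame(x1[, c("a", "b", "replicate")],
                     inhibition_pct = 100 * (1 - (x1$signal / x0$signal) / ctrl_fold))
  res <- bliss_synergy_score(surf, n_boot = 100, seed = 1)
  expect_length(res$ci, 2L)
  expect_lte(res$ci[1], res$score)
  expect_gte(res$ci[2], res$score)
})

test_that("slice at fixed dose 0 reduces to the 2-drug score", {
  model <- drug_effect_model(list(
    a = list(ec50 = 10, hill = 1.2, emax = 0.9),
    b = list(ec50 = 50, hill = 1.0, emax = 0.8),
    c = list(ec50 = 5, hill = 1.5, emax = 0.7)), tau = 1.3)
  des <- expand.grid(a = c(0, 5, 15, 45), b = c(0, 25, 75, 225),
                     c = c(0, 2, 6, 18))
  tab <- simulate_viability_timecourse(des, model, noise_cv = 0, seed = 3)
  surf <- viability_surface(tab)
  slices <- conditional_slice_scores(surf, "c")
  two_drug <- bliss_synergy_score(surf[surf$c == 0, c("a", "b", "inhibition_pct")])
  expect_equal(slices$score[slices$fixed_dose == 0], two_drug$score,
               tolerance = 1e-10)

  expect_error(conditional_slice_scores(surf, "c", fixed_doses = 7),
               "not on the c axis")
  expect_error(conditional_slice_scores(surf[, c("a", "b", "inhibition_pct")], "c"),
               "3-drug")
})

test_that("planted synergy grows with the fixed drug's dose below saturation", {
  # weak-effect regime: the tau-driven excess increases with total effect
  model <- drug_effect_model(list(
    a = list(ec50 = 10, hill = 1.2, emax = 0.2),
    b = list(ec50 = 50, hill = 1.0, emax = 0.2),
    c = list(ec50 = 5, hill = 1.5, emax = 0.2)), tau = 1.3)
  des <- expand.grid(a = c(0, 2, 5, 10), b = c(0, 10, 25, 50), c = c(0, 1, 2, 4))
  surf <- viability_surface(
    simulate_viability_timecourse(des, model, noise_cv = 0, seed = 3))
  slices <- conditional_slice_scores(surf, "c")
  pos <- slices[slices$fixed_dose > 0, ]
  expect_true(all(diff(pos$score) > 0))

  # brute-force recomputation of every slice score from first principles
  margin <- function(drug, dose) {
    if (dose == 0) return(0)
    row <- surf[surf[[drug]] == dose &
                  rowSums(surf[, c("a", "b", "c")] > 0) == 1, ]
    min(max(row$inhibition_pct / 100, 0), 1)
  }
  for (f in slices$fixed_dose) {
    cells <- surf[surf$c == f & rowSums(surf[, c("a", "b", "c")] > 0) >= 2, ]
    exc <- vapply(seq_len(nrow(cells)), function(i) {
      e <- c(margin("a", cells$a[i]), margin("b", cells$b[i]),
             margin("c", cells$c[i]))
      cells$inhibition_pct[i] - 100 * (1 - prod(1 - e))
    }, numeric(1))
    expect_equal(slices$score[slices$fixed_dose == f], mean(exc),
                 tolerance = 1e-10)
  }
})

test_that("Bliss-consistent slices stay inside the additivity band under noise", {
  model <- drug_effect_model(list(
    a = list(ec50 = 10, hill = 1.2, emax = 0.9),
    b = list(ec50 = 50, hill = 1.0, emax = 0.8),
    c = list(ec50 = 5, hill = 1.5, emax = 0.7)), tau = 1)
  des <- expand.grid(a = c(0, 3, 8, 20, 50, 120), b = c(0, 15, 40, 100, 250, 600),
                     c = c(0, 2, 6, 18))
  for (s in 1:3) {
    tab <- simulate_viability_timecourse(des, model, noise_cv = 0.01, seed = s)
    slices <- conditional_slice_scores(viability_surface(tab), "c")
    expect_true(all(abs(slices$score) <= 10))
  }
})
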