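test_that("shipped rule sets carry the published parameter values", {
  h1 <- hypothesis1()
  expect_equal(h1$init_life, c(0, 36))
  expect_equal(h1$init_prol, c(33, 87))
  expect_equal(h1$n_crit, 5)
  expect_equal(h1$c_envfactor, 1.9)
  expect_equal(h1$c_amount, 1)
  expect_equal(h1$off_life$kind, "uniform")
  expect_equal(c(h1$off_life$lo, h1$off_life$hi), c(0, 18))
  expect_equal(h1$off_prol$kind, "coupled")
  expect_equal(h1$off_prol$base, 33)
  expect_equal(c(h1$off_prol$lo, h1$off_prol$hi), c(0, 54))

  h2 <- hypothesis2()
  expect_equal(h2$init_life, c(0, 45))
  expect_equal(h2$init_prol, c(41, 103))
  expect_equal(h2$n_crit, 5)  # inherited unchanged
  expect_equal(h2$off_life$kind, "coupled")
  expect_equal(h2$off_life$sign, 1)
  expect_equal(c(h2$off_life$lo, h2$off_life$hi), c(0, 45))
  expect_equal(h2$off_prol$kind, "uniform")
  expect_equal(c(h2$off_prol$lo, h2$off_prol$hi), c(41, 103))
})

test_that("the two rule sets differ only in the lifespan/proliferation draws", {
  h1 <- hypothesis1()
  h2 <- hypothesis2()
  changed <- c("name", "init_life", "init_prol", "off_life", "off_prol")
  for (f in setdiff(names(h1), changed)) {
    expect_identical(h1[[f]], h2[[f]])
  }
  for (f in setdiff(changed, "name")) {
    expect_false(identical(h1[[f]], h2[[f]]))
  }
})

test_that("initial draws are uniform on the inclusive integer lattice", {
  set.seed(421)
  n <- 1e5
  d <- draw_engraftment_params(hypothesis1(), type = "initial", n = n)
  expect_true(all(d$t_life %in% 0:36))
  expect_true(all(d$t_prol %in% 33:87))
  # goodness of fit against the discrete uniform pmf
  gof <- chisq.test(tabulate(d$t_life + 1, nbins = 37), p = rep(1 / 37, 37))
  expect_gt(gof$p.value, 0.001)
  gof2 <- chisq.test(tabulate(d$t_prol - 32, nbins = 55), p = rep(1 / 55, 55))
  expect_gt(gof2$p.value, 0.001)
})

test_that("offspring draws follow the environment-coupled formulas", {
  set.seed(7)
  # c = 19: 19/1.9 = 10, so T_prol = 23 + U[0, 54] under hypothesis 1
  d <- draw_engraftment_params(hypothesis1(), c_patch = 19,
                               type = "offspring", n = 2e4)
  expect_true(all(d$t_prol >= 23 & d$t_prol <= 77))
  expect_equal(min(d$t_prol), 23)
  expect_equal(max(d$t_prol), 77)
  expect_true(all(d$t_life %in% 0:18))
  # at c = 0 the formula reduces to the initial interval [33, 87]
  d0 <- draw_engraftment_params(hypothesis1(), c_patch = 0,
                                type = "offspring", n = 2e4)
  expect_equal(range(d0$t_prol), c(33, 87))
  # hypothesis 2: T_life = c/1.9 + n, support [10, 55] at c = 19
  e <- draw_engraftment_params(hypothesis2(), c_patch = 19,
                               type = "offspring", n = 2e4)
  expect_equal(range(e$t_life), c(10, 55))
  expect_true(all(e$t_prol %in% 41:103))
  # high concentration floors a negative formula value at 1
  set.seed(8)
  f <- draw_engraftment_params(hypothesis1(), c_patch = 70,
                               type = "offspring", n = 1e4)
  expect_equal(min(f$t_prol), 1)
  expect_true(all(f$t_prol >= 1))
})

test_that("substrate shifts the offspring draws in opposite directions", {
  set.seed(99)
  n <- 2e4
  # hypothesis 1: offspring T_prol stochastically decreasing in c_patch
  lo <- draw_engraftment_params(hypothesis1(), 0, "offspring", n)$t_prol
  hi <- draw_engraftment_params(hypothesis1(), 19, "offspring", n)$t_prol
  grid <- 0:110
  expect_true(all(ecdf(hi)(grid) >= ecdf(lo)(grid)))
  expect_lt(mean(hi), mean(lo))
  # hypothesis 2: offspring T_life stochastically increasing in c_patch
  lo2 <- draw_engraftment_params(hypothesis2(), 0, "offspring", n)$t_life
  hi2 <- draw_engraftment_params(hypothesis2(), 19, "offspring", n)$t_life
  expect_true(all(ecdf(hi2)(grid) <= ecdf(lo2)(grid)))
  expect_gt(mean(hi2), mean(lo2))
})

test_that("perturbation scales parameters and interval endpoints by 1 + delta", {
  expect_equal(perturb_ruleset(hypothesis1(), "n_crit", 0.05)$n_crit, 5.25)
  expect_equal(perturb_ruleset(hypothesis1(), "c_amount", -0.05)$c_amount, 0.95)
  expect_equal(
    perturb_ruleset(hypothesis1(), "c_envfactor", 0.05)$c_envfactor,
    1.9 * 1.05
  )
  p <- perturb_ruleset(hypothesis1(), "t_life", -0.05)
  expect_equal(p$init_life, c(0, 34.2))
  expect_equal(c(p$off_life$lo, p$off_life$hi), c(0, 17.1))
  # integer draws fall on the lattice of the scaled interval
  set.seed(5)
  d <- draw_engraftment_params(p, type = "initial", n = 1e4)
  expect_true(all(d$t_life %in% 0:34))
  expect_equal(max(d$t_life), 34)
  # coupled specs scale their deterministic part too
  q <- perturb_ruleset(hypothesis1(), "t_prol", 0.05)
  expect_equal(q$off_prol$scale, 1.05)
  expect_equal(q$init_prol, c(33, 87) * 1.05)
  # delta = 0 is the identity on all numeric content
  z <- perturb_ruleset(hypothesis1(), "t_life", 0)
  expect_equal(z$init_life, hypothesis1()$init_life)
  expect_equal(z$off_life, hypothesis1()$off_life)
})
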