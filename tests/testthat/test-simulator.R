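immortal_rules <- function(base = hypothesis1(), t = 1e6) {
  base$init_life <- c(t, t)
  base$init_prol <- c(t, t)
  base$off_life <- uniform_spec(t, t)
  base$off_prol <- uniform_spec(t, t)
  base
}

test_that("identical seeds give bit-identical trajectories", {
  a <- simulate_engraftment(hypothesis1(), n_steps = 15, seed = 11,
                            n_cells = 5000, compute_cvhv = TRUE)
  b <- simulate_engraftment(hypothesis1(), n_steps = 15, seed = 11,
                            n_cells = 5000, compute_cvhv = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$totals, b$totals)
  expect_identical(a$substrate, b$substrate)
  c <- simulate_engraftment(hypothesis1(), n_steps = 15, seed = 12,
                            n_cells = 5000, compute_cvhv = FALSE)
  expect_false(identical(a$totals, c$totals))
})

test_that("seeding respects the engraftment probability", {
  # degenerate probability: everyone engrafts, nobody is motile
  s1 <- quick_sim(n_cells = 3000, engraft_prob = 1, n_steps = 2)
  expect_equal(s1$engrafted_t0, 3000)
  expect_true(all(s1$totals$motile == 0))
  # empty seeding is the identity
  s0 <- quick_sim(n_cells = 0, n_steps = 2)
  expect_equal(s0$engrafted_t0, 0)
  expect_true(all(s0$totals$engrafted == 0))
  # engrafted count at t = 0 is Binomial(n, p): check the mean within 4 SD
  s <- quick_sim(n_cells = 20000, n_steps = 1, seed = 3)
  expect_lt(abs(s$engrafted_t0 - 19000), 4 * sqrt(20000 * 0.95 * 0.05))
  expect_error(
    simulate_engraftment(hypothesis1(), n_cells = 32769, n_steps = 1),
    "exceeds the number of patches"
  )
})

test_that("seeding modes: instant cull removes non-engrafters, grace gives one step", {
  si <- simulate_engraftment(hypothesis1(), n_steps = 3, seed = 21,
                             n_cells = 10000, compute_cvhv = FALSE,
                             seeding_mode = "instant_cull")
  expect_true(all(si$totals$motile == 0))
  expect_true(all(si$totals$attachments == 0))
  sg <- simulate_engraftment(hypothesis1(), n_steps = 3, seed = 21,
                             n_cells = 10000, compute_cvhv = FALSE,
                             seeding_mode = "one_step_grace")
  expect_gt(sg$totals$attachments[1], 0)  # motile cells attach in step 1
  expect_gt(sg$totals$culled[1], 0)       # the rest are eliminated
  expect_true(all(sg$totals$motile == 0)) # none survive past step 1
  # with the threshold at 100 no motile cell can attach after t = 0
  blocked <- hypothesis1()
  blocked$n_crit <- 100
  sb <- simulate_engraftment(blocked, n_steps = 3, seed = 22,
                             n_cells = 10000, engraft_prob = 0.5,
                             compute_cvhv = FALSE,
                             seeding_mode = "one_step_grace")
  expect_true(all(sb$totals$attachments == 0))
})

test_that("per-step bookkeeping conserves the engrafted population", {
  s <- simulate_engraftment(hypothesis1(), n_steps = 40, seed = 31,
                            n_cells = 15000, compute_cvhv = FALSE)
  tot <- s$totals
  prev <- c(s$engrafted_t0, head(tot$engrafted, -1))
  expect_equal(
    tot$engrafted,
    prev + tot$attachments + tot$births - tot$deaths
  )
  expect_equal(s$occupancy_violations, 0)
})

test_that("immortal, non-proliferating populations are constant", {
  s <- simulate_engraftment(immortal_rules(), n_steps = 20, seed = 41,
                            n_cells = 4000, engraft_prob = 1,
                            compute_cvhv = FALSE)
  expect_true(all(s$totals$engrafted == 4000))
  expect_true(all(s$totals$deaths == 0))
  expect_true(all(s$totals$births == 0))
})

test_that("cohort survival without proliferation tracks the discrete-uniform form", {
  # T_life ~ U{0..36}: the fraction of the t0 cohort alive after step t
  # is (36 - t)/37
  s <- simulate_engraftment(hypothesis1(), n_steps = 36, seed = 51,
                            n_cells = 20000, engraft_prob = 1,
                            proliferation = FALSE, compute_cvhv = FALSE)
  frac <- s$totals$engrafted / s$engrafted_t0
  for (t in c(5, 15, 25, 35)) {
    p <- (36 - t) / 37
    se <- sqrt(p * (1 - p) / s$engrafted_t0)
    expect_lt(abs(frac[t] - p), 5 * se)
  }
})

test_that("slice extraction partitions the engrafted population", {
  s <- simulate_engraftment(hypothesis1(), n_steps = 10, seed = 61,
                            n_cells = 8000, record_steps = 10,
                            compute_cvhv = FALSE, keep_positions = TRUE)
  pos <- s$positions[["10"]]
  total <- s$totals$engrafted[10]
  expect_equal(nrow(pos), total)
  per_slice <- vapply(
    lattice_coords(),
    function(z) nrow(extract_slice(pos, "z", z)),
    integer(1)
  )
  expect_equal(sum(per_slice), total)
  # recorded slice counts agree with extraction
  traj <- s$trajectory
  for (z in c(-15, 0, 14)) {
    expect_equal(
      traj$n_cells[traj$slice == z],
      nrow(extract_slice(pos, "z", z))
    )
  }
  one <- extract_slice(data.frame(x = 0, y = 0, z = 5), "z", 5)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one), c(x = 0, y = 0))
  expect_equal(nrow(extract_slice(pos, "z", 5 + 0)), per_slice[22])
  expect_error(extract_slice(pos, "z", 16), "outside lattice bounds")
})

test_that("heading quantization maps onto the 26 lattice directions", {
  q <- recell:::.cpp_quantize_direction
  expect_equal(q(c(1, 0, 0)), c(1, 0, 0))
  expect_equal(q(c(-0.2, 5, 0.1)), c(0, 1, 0))
  expect_equal(q(c(0.9, 0.9, 0.9)), c(1, 1, 1))
  expect_equal(q(c(0, 0, -3)), c(0, 0, -1))
  ahead <- recell:::.cpp_ahead_directions
  for (h in list(c(1, 0, 0), c(0.3, -0.8, 0.5), c(0, 0, 1), c(-1, -1, -1))) {
    m <- ahead(h)
    expect_equal(dim(m), c(3, 3))
    # each row is a valid lattice direction
    expect_true(all(m %in% -1:1))
    expect_true(all(rowSums(abs(m)) >= 1))
    # the straight-ahead row is the quantized heading
    expect_equal(m[1, ], q(h))
  }
})

test_that("time-scale calibration reproduces the published rates", {
  cal <- calibrate_time_scale(32, 1000, 80, 28)
  expect_equal(cal$patch_size_um, 31.25)
  expect_equal(round(cal$step_rate_per_min, 3), 0.002)
  expect_lt(abs(cal$velocity_um_per_min - 0.06), 0.005)
  # doubling the duration halves both rates
  cal2 <- calibrate_time_scale(32, 1000, 80, 56)
  expect_equal(cal2$step_rate_per_min, cal$step_rate_per_min / 2)
  expect_equal(cal2$velocity_um_per_min, cal$velocity_um_per_min / 2)
  expect_error(calibrate_time_scale(0, 1000, 80, 28), "positive")
  expect_error(calibrate_time_scale(32, -5, 80, 28), "positive")
})
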