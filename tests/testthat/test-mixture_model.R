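test_that("quadratic coefficients match direct arithmetic on the printed formulas", {
  pair <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 3.3)
  co <- mixture_coefficients(pair, 0.5)
  # frozen oracle values (direct evaluation, see helper; the bracket
  # (1-k)R + k = 2.15 at k = 0.5, R = 3.3)
  expect_equal(co$a1, -0.4055, tolerance = 1e-12)
  expect_equal(co$a2, 0.79866125, tolerance = 1e-12)
  expect_equal(co$a3, 1.0145640375, tolerance = 1e-12)
  orc <- oracle_coefficients(0.17, 0.25, 3.3, 1.69, 6.57, 0.5)
  expect_equal(unlist(co[c("a1", "a2", "a3")]), orc, tolerance = 1e-12,
               ignore_attr = TRUE)
  # boundary cases: one species' bracket vanishes
  expect_equal(mixture_coefficients(pair, 1)$a1, -0.25)
  pair1 <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 1)
  expect_equal(mixture_coefficients(pair1, 0)$a1, -0.17)
})

test_that("coefficient and velocity input validation", {
  pair <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 3.3)
  expect_error(mixture_coefficients(pair, 1.2), "mole fraction")
  expect_error(mixture_coefficients(pair, -0.1), "mole fraction")
  expect_error(motor_species("x", -1, 0.2), "vmax")
  expect_error(motor_species("x", 1, 1.2), "curvature")
  expect_error(mixture_pair(tbl_sk(), tbl_wt()), "swap")
  expect_error(mixture_pair(tbl_wt(), tbl_sk(), force_ratio = -2), "force_ratio")
})

test_that("mixture velocity: boundaries exact, worked example, oracle agreement", {
  pair <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 3.3)
  v <- solve_mixture_velocity(pair, c(0, 0.5, 1))
  expect_equal(v[1], 1.69, tolerance = 1e-9)
  expect_equal(v[3], 6.57, tolerance = 1e-9)
  # frozen value from the bisection oracle
  expect_equal(v[2], 2.8480652544127, tolerance = 1e-10)

  # randomized parameter sweep: invariants and oracle equivalence
  set.seed(101)
  for (i in 1:40) {
    vs <- runif(1, 0.2, 4); vf <- vs * runif(1, 1, 8)
    cs <- runif(1, 0.05, 0.6); cf <- runif(1, 0.05, 0.6)
    R <- exp(runif(1, log(0.1), log(10)))
    k <- runif(1)
    p <- mixture_pair(motor_species("s", vs, cs), motor_species("f", vf, cf), R)
    co <- mixture_coefficients(p, k)
    expect_lt(co$a1, 0)
    expect_gt(co$a3, 0)
    v1 <- solve_mixture_velocity(p, k)
    expect_equal(v1, oracle_root(cs, cf, R, vs, vf, k), tolerance = 1e-8)
    # unique positive root: product of roots = a3/a1 < 0, so the other is negative
    expect_gt(v1, 0)
  }
})

test_that("predict_curve: degeneracy, monotonicity, near-linearity at unit ratio", {
  same <- mixture_pair(motor_species("a", 2, 0.17), motor_species("b", 2, 0.25),
                       force_ratio = 5)
  expect_equal(predict_curve(same, c(0, 0.5, 1))$velocity_um_s, rep(2, 3))

  pair <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 3.3)
  kv <- seq(0, 1, length.out = 101)
  v <- solve_mixture_velocity(pair, kv)
  expect_true(all(diff(v) > 0))
  expect_equal(v[1], 1.69, tolerance = 1e-9)
  expect_equal(v[101], 6.57, tolerance = 1e-9)

  # S532P/WT-style pair at unit ratio and equal curvatures: near-linear
  p1 <- mixture_pair(motor_species("s", 0.62, 0.17),
                     motor_species("f", 1.69, 0.17), force_ratio = 1)
  v1 <- solve_mixture_velocity(p1, kv)
  chord <- 0.62 + kv * (1.69 - 0.62)
  expect_lt(max(abs(v1 - chord)), 0.05 * (1.69 - 0.62))
})

test_that("equal-force reference sits above a fitted ratio > 1 curve", {
  ref <- equal_force_reference(tbl_wt(), tbl_sk(), seq(0, 1, by = 0.1))
  expect_equal(ref$velocity_um_s[1], 1.69, tolerance = 1e-9)
  expect_equal(ref$velocity_um_s[11], 6.57, tolerance = 1e-9)
  fitted <- predict_curve(mixture_pair(tbl_wt(), tbl_sk(), 3.3),
                          seq(0, 1, by = 0.1))
  interior <- 2:10
  expect_true(all(ref$velocity_um_s[interior] > fitted$velocity_um_s[interior]))
  same <- equal_force_reference(motor_species("a", 2, 0.17),
                                motor_species("b", 2, 0.25), c(0, 0.5, 1))
  expect_equal(same$velocity_um_s, rep(2, 3))
})

test_that("force-ratio fit recovers noiseless data exactly and matches a grid oracle", {
  pair <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 2)
  d <- predict_curve(pair, seq(0, 1, length.out = 6))
  names(d)[2] <- "velocity_um_s"
  fit <- fit_force_ratio(d, pair$slow, pair$fast)
  expect_equal(fit$estimate, 2, tolerance = 1e-6)

  # 5% multiplicative noise: estimate within 10% of truth and equal to an
  # exhaustive 1e4-point grid search of the same objective
  gen <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 3.3)
  dn <- simulate_mixture_dataset(gen, seq(0, 1, length.out = 6),
                                 noise_cv = 0.05, replicates = 3, seed = 1)
  fitn <- fit_force_ratio(dn, gen$slow, gen$fast)
  expect_lt(abs(fitn$estimate - 3.3) / 3.3, 0.10)
  grid <- exp(seq(log(0.05), log(20), length.out = 1e4))
  obj <- vapply(grid, function(r) {
    p <- mixture_pair(gen$slow, gen$fast, r)
    sum((dn$velocity_um_s - solve_mixture_velocity(p, dn$k))^2)
  }, numeric(1))
  expect_equal(fitn$estimate, grid[which.min(obj)], tolerance = 1e-3)
})

test_that("unit-ratio pair fits inside the reported interval", {
  gen <- mixture_pair(tbl_s532p(), tbl_wt(), force_ratio = 1)
  d <- simulate_mixture_dataset(gen, seq(0, 1, length.out = 6),
                                noise_cv = 0.05, replicates = 3, seed = 11)
  fit <- fit_force_ratio(d, gen$slow, gen$fast)
  expect_gt(fit$estimate, 0.7)
  expect_lt(fit$estimate, 1.3)
})

test_that("fit validation and degenerate data", {
  d <- data.frame(k = c(0, 0.5), velocity_um_s = c(1, 2))
  expect_error(fit_force_ratio(d, tbl_wt(), tbl_sk()), "3 distinct")
  dd <- data.frame(k = c(0, 0.5, 1), velocity_um_s = rep(1.5, 3))
  expect_warning(f <- fit_force_ratio(dd, tbl_wt(), tbl_sk()), "degenerate")
  expect_true(is.finite(f$estimate))
})

test_that("bootstrap: degenerate case, reproducibility, validation", {
  pair <- mixture_pair(tbl_wt(), tbl_sk(), force_ratio = 2)
  d <- predict_curve(pair, seq(0, 1, length.out = 6))
  names(d)[2] <- "velocity_um_s"
  ratio <- 1.69 / 6.57
  # zero-width vmax CI + noiseless single observations: all estimates equal
  b0 <- bootstrap_force_ratio(d, pair$slow, pair$fast,
                              vmax_ratio_ci = c(ratio, ratio),
                              iterations = 25, seed = 5)
  expect_length(b0$bootstrap_samples, 25)
  expect_equal(diff(range(b0$bootstrap_samples)), 0, tolerance = 1e-6)
  expect_equal(diff(b0$ci95), 0, tolerance = 1e-6)
  expect_true(b0$ci95[1] <= b0$estimate && b0$estimate <= b0$ci95[2])

  dn <- simulate_mixture_dataset(pair, seq(0, 1, length.out = 6),
                                 noise_cv = 0.05, replicates = 3, seed = 3)
  b1 <- bootstrap_force_ratio(dn, pair$slow, pair$fast,
                              vmax_ratio_ci = ratio * c(0.92, 1.08),
                              iterations = 40, seed = 9)
  b2 <- bootstrap_force_ratio(dn, pair$slow, pair$fast,
                              vmax_ratio_ci = ratio * c(0.92, 1.08),
                              iterations = 40, seed = 9)
  expect_identical(b1$bootstrap_samples, b2$bootstrap_samples)
  expect_true(b1$ci95[1] <= b1$estimate && b1$estimate <= b1$ci95[2])
  # resampling mode draws different iterates
  b3 <- bootstrap_force_ratio(dn, pair$slow, pair$fast,
                              vmax_ratio_ci = ratio * c(0.92, 1.08),
                              iterations = 40, seed = 9,
                              resample_observations = TRUE)
  expect_false(identical(b1$bootstrap_samples, b3$bootstrap_samples))

  expect_error(bootstrap_force_ratio(dn, pair$slow, pair$fast,
                                     vmax_ratio_ci = ratio * c(0.9, 1.1),
                                     iterations = 0), "iterations")
  expect_error(bootstrap_force_ratio(dn, pair$slow, pair$fast,
                                     vmax_ratio_ci = c(0.5, 0.6),
                                     iterations = 5), "bracket")
})
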