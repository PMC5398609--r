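test_that("birth and death probabilities interpolate b0/d0 to theta", {
  p <- growth_params(b0 = 0.8, theta = 0.08, d0 = 0, K = 50)
  expect_equal(birth_probability(0, p), 0.8)
  expect_equal(birth_probability(50, p), 0.08)
  expect_equal(birth_probability(25, p), 0.44)
  expect_equal(death_probability(0, p), 0)
  expect_equal(death_probability(50, p), 0.08)
  expect_equal(death_probability(25, p), 0.04)
})

test_that("parameter ordering d0 < theta < b0 is enforced", {
  expect_error(growth_params(0.5, 0.6, 0, 10), "theta")
  expect_error(growth_params(0.5, 0.1, 0.2, 10), "theta")
  expect_error(growth_params(0.5, 0.2, 0.6, 10), "d0")
  expect_error(growth_params(0.5, 0.2, 0, 0.5), "K")
})

test_that("negative birth rates fold into mortality and rates clamp to [0,1]", {
  p <- growth_params(b0 = 0.8, theta = 0.7, d0 = 0, K = 10)
  # below the fold threshold N = b0 K / (b0 - theta) = 80 (and with raw
  # delta still below 1) nothing changes
  r12 <- effective_rates(12, p)
  expect_equal(r12$beta, birth_probability(12, p))
  expect_equal(r12$delta, death_probability(12, p))
  # raw delta above 1 clamps even while beta is still positive
  expect_equal(effective_rates(40, p)$delta, 1)
  # above it, beta* = 0 and delta* = |beta| + delta (clamped to 1)
  r100 <- effective_rates(100, p)
  expect_equal(r100$beta, 0)
  expect_equal(r100$delta,
               min(1, abs(birth_probability(100, p)) +
                        death_probability(100, p)))
  r1000 <- effective_rates(1000, p)
  expect_equal(r1000$delta, 1)
  expect_true(all(unlist(effective_rates(0:1000, p)) >= 0))
  expect_true(all(unlist(effective_rates(0:1000, p)) <= 1))
})

test_that("the transition kernel is the double-binomial convolution", {
  # N = 2 with beta = delta = 1/2: brute-force enumeration of all
  # (birth1, birth2, death1, death2) outcomes, each with probability 1/16
  p <- growth_params(b0 = 1, theta = 0.5, d0 = 0, K = 2)
  brute <- numeric(5)
  for (b1 in 0:1) for (b2 in 0:1) for (d1 in 0:1) for (d2 in 0:1) {
    M <- 2 + b1 + b2 - d1 - d2
    brute[M + 1] <- brute[M + 1] + 1 / 16
  }
  k <- transition_kernel(2, p)
  expect_equal(k$prob, brute)
  expect_equal(k$prob[k$states == 3], 0.25)
  # no more than N births: T(5|2) lies outside the support
  expect_true(all(k$states <= 4))
  # empty state is absorbing
  k0 <- transition_kernel(0, p)
  expect_equal(k0$prob, 1)
})

test_that("transition kernels are normalised for random valid parameters", {
  set.seed(91)
  for (i in 1:25) {
    b0 <- runif(1, 0.05, 1)
    d0 <- runif(1, 0, b0 * 0.5)
    theta <- runif(1, d0 + 1e-3, b0 - 1e-3)
    K <- sample(1:300, 1)
    p <- growth_params(b0, theta, d0, K)
    for (N in c(0L, 1L, 2L, 17L, 200L))
      expect_equal(sum(transition_kernel(N, p)$prob), 1, tolerance = 1e-12)
  }
})

test_that("step_growth matches its transition kernel (chi-square oracle)", {
  p <- growth_params(b0 = 1, theta = 0.5, d0 = 0, K = 2)
  set.seed(11)
  sims <- step_growth(rep(2L, 1e5), p)
  k <- transition_kernel(2, p)
  obs <- tabulate(sims + 1L, nbins = length(k$prob))
  expect_gt(stats::chisq.test(obs, p = k$prob)$p.value, 0.01)
  # a second, asymmetric case at N = 7
  p2 <- growth_params(b0 = 0.6, theta = 0.1, d0 = 0.02, K = 10)
  set.seed(12)
  sims2 <- step_growth(rep(7L, 1e5), p2)
  k2 <- transition_kernel(7, p2)
  obs2 <- tabulate(sims2 + 1L, nbins = length(k2$prob))
  keep <- k2$prob * 1e5 >= 5  # bins with adequate expected counts
  expect_gt(stats::chisq.test(obs2[keep], p = k2$prob[keep],
                              rescale.p = TRUE)$p.value, 0.01)
})

test_that("step_growth keeps N = K stationary in expectation", {
  p <- growth_params(b0 = 0.8, theta = 0.4, d0 = 0, K = 50)
  set.seed(5)
  deltas <- step_growth(rep(50L, 1e5), p) - 50L
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 4 * se)
})

test_that("the deterministic growth limit is the Forward-Euler logistic map", {
  p <- growth_params(b0 = 0.3, theta = 0.03, d0 = 0, K = 50)
  n <- 10
  for (i in 1:500) n <- step_growth(n, p, deterministic = TRUE)
  expect_equal(n, 50, tolerance = 1e-9)
  # one deterministic step equals N + r N (1 - N/K)
  expect_equal(step_growth(10, p, deterministic = TRUE),
               10 + 0.3 * 10 * (1 - 10 / 50))
})

test_that("the master equation conserves mass and reproduces the kernel", {
  p <- growth_params(b0 = 0.3, theta = 0.15, d0 = 0, K = 10)
  # a point mass at N = 0 is absorbing
  st0 <- master_equation_state(c(1, rep(0, 40)))
  expect_equal(master_equation_step(st0, p)$prob[1], 1)
  # one step from a point mass at N = 2 is exactly transition_kernel(2)
  st2 <- master_equation_state(c(0, 0, 1, rep(0, 38)))
  k <- transition_kernel(2, p)
  stepped <- master_equation_step(st2, p)
  expect_equal(stepped$prob[1:5], k$prob, tolerance = 1e-14)
  expect_equal(sum(stepped$prob), 1, tolerance = 1e-12)
})

test_that("master-equation equilibrium matches the analytic approximation", {
  p <- growth_params(b0 = 0.3, theta = 0.15, d0 = 0, K = 10)
  st <- master_equation_state(c(rep(0, 10), 1, rep(0, 30)))
  st <- master_equation_run(st, p, 500)
  expect_equal(sum(st$prob), 1, tolerance = 1e-9)
  expect_lt(abs(master_equation_mean(st, exclude_zero = TRUE) -
                  effective_K_approx(p)), 0.2)
})

test_that("master-equation mean matches the stochastic ensemble at small K", {
  p <- growth_params(b0 = 0.3, theta = 0.15, d0 = 0, K = 10)
  st <- master_equation_state(c(rep(0, 10), 1, rep(0, 30)))
  st <- master_equation_run(st, p, 200)
  me_mean <- master_equation_mean(st, exclude_zero = TRUE)
  set.seed(31)
  counts <- rep(10L, 4000)
  for (i in 1:200) counts <- step_growth(counts, p)
  alive <- counts > 0
  mc_mean <- mean(counts[alive])
  mc_se <- sd(counts[alive]) / sqrt(sum(alive))
  expect_lt(abs(me_mean - mc_mean), 4 * mc_se)
})

test_that("a heavily truncated master equation reports its leak", {
  p <- growth_params(b0 = 0.9, theta = 0.5, d0 = 0, K = 20)
  st <- master_equation_state(c(rep(0, 20), 1, rep(0, 2)))  # N_max = 22
  expect_warning(master_equation_step(st, p), "leak")
})

test_that("the effective carrying capacity approximation has its landmarks", {
  # theta = b0 / 2, d0 = 0: deviation is exactly 1/2 for every b0
  for (b0 in c(0.1, 0.3, 0.8, 1))
    expect_equal(effective_K_approx(growth_params(b0, b0 / 2, 0, 50)),
                 49.5)
  expect_equal(effective_K_approx(growth_params(0.8, 0.4, 0, 50)), 49.5)
  # theta -> 0 at fixed b0: <N> -> K
  expect_equal(effective_K_approx(growth_params(0.8, 1e-9, 0, 50)), 50,
               tolerance = 1e-7)
})

test_that("the deviation term has the documented shape", {
  # all curves intersect at alpha = 1/2 with f = 1/2
  for (b0 in c(0.1, 0.3, 0.8, 1))
    expect_equal(deviation_term(0.5, b0), 0.5)
  expect_equal(deviation_term(0.875, 0.8), 0.4375)
  expect_equal(deviation_term(1e-12, 0.8), 0, tolerance = 1e-11)
  # for b0 > 0.5 the maximum sits where alpha * b0 = 1/2
  alpha <- seq(0.01, 0.99, by = 0.0001)
  f <- deviation_term(alpha, 0.8)
  expect_equal(alpha[which.max(f)] * 0.8, 0.5, tolerance = 1e-3)
  # deviation_term equals K - <N> of the approximation when d0 = 0
  p <- growth_params(0.8, 0.7, 0, 50)
  expect_equal(deviation_term(0.7 / 0.8, 0.8),
               50 - effective_K_approx(p))
})

test_that("simulated effective K shows the K - 1/2 law at theta = b0/2", {
  est1 <- estimate_effective_K(growth_params(0.8, 0.4, 0, 50),
                               n_realizations = 60, seed = 101)
  expect_lt(abs(est1$mean - 49.5), 3 * est1$sem)
  est2 <- estimate_effective_K(growth_params(0.008, 0.004, 0, 50),
                               n_steps = 3000, burn_in = 1500,
                               n_realizations = 60, seed = 102)
  expect_lt(abs(est2$mean - 49.5), 3 * est2$sem)
})

test_that("fluctuations are non-monotone in theta when b0 = 0.8", {
  dev <- vapply(c(0.7, 0.4, 0.08), function(th) {
    est <- estimate_effective_K(growth_params(0.8, th, 0, 50),
                                n_realizations = 60,
                                seed = 7000 + round(1000 * th))
    50 - est$mean
  }, numeric(1))
  expect_gt(dev[2], dev[1])  # theta 0.7 -> 0.4 increases the deviation
  expect_gt(dev[2], dev[3])  # theta 0.4 -> 0.08 decreases it again
})

test_that("extinct realizations are excluded and reported", {
  # tiny K with violent turnover: extinctions happen
  p <- growth_params(b0 = 0.9, theta = 0.85, d0 = 0.5, K = 2)
  est <- estimate_effective_K(p, n_realizations = 200, n_steps = 60,
                              burn_in = 10, seed = 5)
  expect_gt(est$n_extinct, 0)
  expect_equal(est$n_surviving + est$n_extinct, 200)
  expect_error(estimate_effective_K(p, n_realizations = 2, n_steps = 3000,
                                    burn_in = 0, seed = 6),
               "extinct")
})
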