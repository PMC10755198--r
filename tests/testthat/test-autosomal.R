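test_that("monomorphic states are fixed points of the autosomal recursion", {
  p_nomut <- frc_params(0.3, 0.4, 0, 1.5)
  expect_equal(next_generation(c(pp = 1, pm = 0, mm = 0), p_nomut),
               c(pp = 1, pm = 0, mm = 0))
  # all-mutant broods are 100% mm; normalization removes the (1-s) factor
  p <- frc_params(0.3, 0.5, 1e-5, 2)
  expect_equal(next_generation(c(pp = 0, pm = 0, mm = 1), p),
               c(pp = 0, pm = 0, mm = 1))
})

test_that("one generation matches the brute-force mating enumeration oracle", {
  cases <- expand.grid(h = c(0, 0.3, 0.95), s = c(0.2, 1), mu = c(0, 1e-5, 1e-3),
                       C = c(1, 1.5, 100))
  states <- random_autosomal_states(3)
  for (k in seq_len(nrow(cases))) {
    p <- frc_params(cases$h[k], cases$s[k], cases$mu[k], cases$C[k])
    for (f in states) {
      expect_equal(unname(next_generation(f, p)),
                   oracle_next_gen_auto(f, p$h, p$s, p$mu, p$C),
                   tolerance = 1e-13)
    }
  }
})

test_that("at C = 1 with no mutation the recursion collapses to textbook viability selection", {
  h <- 0.5; s <- 0.4
  p <- frc_params(h, s, 0, 1)
  for (f in c(list(c(0.25, 0.5, 0.25)), random_autosomal_states(4, seed = 7))) {
    q <- 0.5 * f[2] + f[3]
    hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    w <- c(1, 1 - h * s, 1 - s)
    expect_equal(unname(next_generation(f, p)), hw * w / sum(hw * w),
                 tolerance = 1e-13)
  }
})

test_that("the state stays normalized generation after generation", {
  p <- frc_params(0.2, 0.8, 1e-4, 1.5)
  f <- c(0.6, 0.3, 0.1)
  for (i in 1:50) {
    f <- next_generation(f, p)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0))
  }
  expect_error(next_generation(c(0.5, 0.5, 0.5), p), "normalized")
})

test_that("census helpers compute the stated quantities", {
  expect_equal(adult_mutant_freq(c(1, 0, 0)), 0)
  expect_equal(adult_mutant_freq(c(0, 1, 0)), 0.5)
  expect_equal(adult_mutant_freq(c(0.25, 0.5, 0.25)), 0.5)
  expect_equal(gametic_freq(0, 1e-5), 1e-5)
  expect_equal(gametic_freq(1, 1e-5), 1)
  expect_equal(gametic_freq(0.5, 1e-5), 0.500005)
})

test_that("equilibria recover classical balance without compensation", {
  eq <- frc_equilibrium(frc_params(0.5, 0.2, 1e-5, 1))
  expect_true(eq$converged)
  expect_equal(eq$q_gametic, 1e-5 / 0.1, tolerance = 0.005)

  # recessive case: square-root balance
  eq_rec <- frc_equilibrium(frc_params(0, 0.5, 1e-7, 1))
  expect_equal(eq_rec$q_gametic, sqrt(1e-7 / 0.5), tolerance = 0.005)
})

test_that("full compensation raises the adult equilibrium by 2 - hs", {
  om <- frc_omega(frc_params(0.5, 0.2, 1e-5, 2))
  expect_true(om$converged)
  expect_equal(om$omega, 1.9, tolerance = 0.005)
  # identity at C = 1
  om1 <- frc_omega(frc_params(0.5, 0.2, 1e-5, 1))
  expect_equal(om1$omega, 1, tolerance = 1e-9)
})

test_that("the recessive lethal fold increase approaches sqrt(3/2)", {
  hi <- frc_equilibrium(frc_params(0, 1, 1e-7, 100))
  lo <- frc_equilibrium(frc_params(0, 1, 1e-7, 1))
  expect_true(hi$converged && lo$converged)
  expect_equal(hi$q_gametic / lo$q_gametic, sqrt(1.5), tolerance = 0.005)
})

test_that("low and high starts converge to the same interior equilibrium", {
  for (par in list(c(0.5, 0.2, 2), c(0.05, 0.05, 2), c(0.95, 0.9, 1.5), c(0, 1, 100))) {
    eq <- frc_equilibrium(frc_params(par[1], par[2], 1e-5, par[3]))
    expect_true(eq$converged, label = sprintf("h=%g s=%g C=%g", par[1], par[2], par[3]))
    expect_lt(eq$start_agreement, 1e-6)
  }
})

test_that("the fold increase is invariant to the mutation rate", {
  omegas <- vapply(c(1e-5, 1e-7, 1e-9), function(mu)
    frc_omega(frc_params(0.5, 0.2, mu, 2))$omega, numeric(1))
  expect_lt(diff(range(omegas)) / mean(omegas), 0.01)
})
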