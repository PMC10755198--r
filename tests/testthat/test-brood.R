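# The brood pipeline is built generically (segregation -> mutation ->
# selection -> release); these tests pin it, term by term, to the
# hand-written per-mating-type numerators of the model's derivation.

test_that("Mendelian segregation gives exact offspring proportions", {
  expect_equal(mendelian_brood(c("pm", "pm")), c(pp = 0.25, pm = 0.5, mm = 0.25))
  expect_equal(mendelian_brood(c("pp", "pp")), c(pp = 1, pm = 0, mm = 0))
  expect_equal(mendelian_brood(c("pp", "mm")), c(pp = 0, pm = 1, mm = 0))
  expect_equal(mendelian_brood(c("mY", "pm"), "sexlinked"),
               c(m.pY = 0.25, m.mY = 0.25, f.pp = 0, f.pm = 0.25, f.mm = 0.25))
  expect_equal(sum(mendelian_brood(c("pY", "pm"), "sexlinked")), 1)
  expect_error(mendelian_brood(c("pp", "pY"), "sexlinked"), "father")
  expect_error(mendelian_brood(c("pY", "mY"), "sexlinked"), "maternal")
  expect_error(mendelian_brood(c("xx", "pp")), "genotype")
})

test_that("within-brood mutation moves the stated mass and conserves the total", {
  mu <- 1e-3
  d <- apply_brood_mutation(c(pp = 0.5, pm = 0.5, mm = 0), mu)
  expect_equal(unname(d), c(0.5 * (1 - 2 * mu), 0.5 * (1 - mu) + 0.5 * 2 * mu, 0.5 * mu))
  expect_equal(apply_brood_mutation(c(pp = 0, pm = 0, mm = 1), mu),
               c(pp = 0, pm = 0, mm = 1))
  d0 <- c(pp = 0.2, pm = 0.3, mm = 0.5)
  expect_identical(apply_brood_mutation(d0, 0), d0)

  # mass conservation across all 12 mating types and several rates
  for (mu in c(1e-9, 1e-5, 1e-3, 0.01)) {
    for (pair in list(c("pp", "pp"), c("pp", "pm"), c("pp", "mm"),
                      c("pm", "pm"), c("pm", "mm"), c("mm", "mm"))) {
      expect_equal(sum(apply_brood_mutation(mendelian_brood(pair), mu)), 1,
                   tolerance = 1e-14)
    }
    for (f_ in c("pY", "mY")) for (m_ in c("pp", "pm", "mm")) {
      expect_equal(sum(apply_brood_mutation(
        mendelian_brood(c(f_, m_), "sexlinked"), mu)), 1, tolerance = 1e-14)
    }
  }
})

# literal transcriptions of the six autosomal per-type numerators
autosomal_numerators <- function(mu, h, s) {
  hs <- h * s
  list(
    c((1 - 2 * mu), 2 * mu * (1 - hs), 0),
    c(0.5 * (1 - 2 * mu), (0.5 * (1 - mu) + 0.5 * 2 * mu) * (1 - hs), 0.5 * mu * (1 - s)),
    c(0, (1 - mu) * (1 - hs), mu * (1 - s)),
    c(0.25 * (1 - 2 * mu), (0.5 * (1 - mu) + 0.25 * 2 * mu) * (1 - hs),
      (0.25 + 0.5 * mu) * (1 - s)),
    c(0, 0.5 * (1 - mu) * (1 - hs), (0.5 + 0.5 * mu) * (1 - s)),
    c(0, 0, 1 * (1 - s))
  )
}

# literal transcriptions of the six sex-linked per-type numerators,
# order (male pY, male mY, female pp, female pm, female mm)
sexlinked_numerators <- function(mu, h, s) {
  hs <- h * s
  list(
    c(0.5 * (1 - mu), 0.5 * mu * (1 - s), 0.5 * (1 - 2 * mu),
      0.5 * 2 * mu * (1 - hs), 0),
    c(0.25 * (1 - mu), (0.25 + 0.25 * mu) * (1 - s), 0.25 * (1 - 2 * mu),
      (0.25 * (1 - mu) + 0.25 * 2 * mu) * (1 - hs), 0.25 * mu * (1 - s)),
    c(0, 0.5 * (1 - s), 0, 0.5 * (1 - mu) * (1 - hs), 0.5 * mu * (1 - s)),
    c(0.5 * (1 - mu), 0.5 * mu * (1 - s), 0, 0.5 * (1 - mu) * (1 - hs),
      0.5 * mu * (1 - s)),
    c(0.25 * (1 - mu), (0.25 + 0.25 * mu) * (1 - s), 0,
      0.25 * (1 - mu) * (1 - hs), (0.25 + 0.25 * mu) * (1 - s)),
    c(0, 0.5 * (1 - s), 0, 0, 0.5 * (1 - s))
  )
}

test_that("the generic pipeline reproduces all 12 hand-written mating-type listings", {
  mu <- 2e-3; h <- 0.4; s <- 0.7; C <- 1.5
  p <- frc_params(h, s, mu, C)

  pairs_a <- list(c("pp", "pp"), c("pp", "pm"), c("pp", "mm"),
                  c("pm", "pm"), c("pm", "mm"), c("mm", "mm"))
  nums_a <- autosomal_numerators(mu, h, s)
  for (i in 1:6) {
    bo <- brood_outcome(pairs_a[[i]], p)
    Z <- sum(nums_a[[i]])
    expect_equal(unname(bo$proportions), nums_a[[i]] / Z, tolerance = 1e-13,
                 label = sprintf("autosomal type %d proportions", i))
    expect_equal(bo$Z, Z, tolerance = 1e-13)
    expect_equal(bo$B, min(Z * C, 1), tolerance = 1e-13)
    expect_equal(sum(bo$proportions), 1, tolerance = 1e-12)
  }
  # type 6 post-selection size is exactly 1 - s
  expect_equal(brood_outcome(c("mm", "mm"), p)$Z, 1 - s, tolerance = 1e-13)

  pairs_x <- list(c("pY", "pp"), c("pY", "pm"), c("pY", "mm"),
                  c("mY", "pp"), c("mY", "pm"), c("mY", "mm"))
  nums_x <- sexlinked_numerators(mu, h, s)
  for (i in 1:6) {
    bo <- brood_outcome(pairs_x[[i]], p, "sexlinked")
    Z <- sum(nums_x[[i]])
    expect_equal(unname(bo$proportions), nums_x[[i]] / Z, tolerance = 1e-13,
                 label = sprintf("sex-linked type %d proportions", i))
    expect_equal(bo$Z, Z, tolerance = 1e-13)
    expect_equal(sum(bo$proportions), 1, tolerance = 1e-12)
  }
})

test_that("selection weights and extinct broods behave as specified", {
  p0 <- frc_params(0, 0, 1e-5, 1)
  sel <- apply_selection(c(pp = 0.3, pm = 0.4, mm = 0.3), p0)
  expect_equal(sel$Z, 1)
  expect_equal(unname(sel$proportions), c(0.3, 0.4, 0.3))

  lethal <- frc_params(0, 1, 1e-5, 1)
  expect_error(apply_selection(c(pp = 0, pm = 0, mm = 1), lethal), "brood extinct")
})

test_that("compensated brood size is capped, monotone, and inert at C = 1", {
  expect_equal(brood_size_after_frc(0.70, 1.5), 1)
  expect_equal(brood_size_after_frc(0.5, 1.5), 0.75)
  expect_equal(brood_size_after_frc(0.9, 1), 0.9)
  Z <- seq(0, 1, by = 0.05)
  for (C in c(1, 1.2, 2, 100)) {
    B <- brood_size_after_frc(Z, C)
    expect_true(all(diff(B) >= 0))
    expect_true(all(B <= 1))
    expect_true(all(brood_size_after_frc(0.4, c(1, C)) ==
                      cummax(brood_size_after_frc(0.4, c(1, C)))))
  }
})
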