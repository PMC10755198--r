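# Independent brute-force oracles for the one-generation recursions.
#
# These deliberately take a different route from the package: they enumerate
# ORDERED parental pairs (so like x unlike doubling falls out of the loop
# rather than being coded), build each brood by looping over the parents'
# gamete combinations allele by allele, and apply mutation/selection/release
# per brood. Used to cross-check next_generation()* on arbitrary states.

# gamete allele distribution, indexed 1 = wildtype, 2 = mutant
.or_gam <- list(pp = c(1, 0), pm = c(0.5, 0.5), mm = c(0, 1))

oracle_next_gen_auto <- function(f, h, s, mu, C) {
  genos <- c("pp", "pm", "mm")
  w <- c(1, 1 - h * s, 1 - s)
  total <- c(0, 0, 0)
  for (a in 1:3) for (b in 1:3) {
    M <- f[a] * f[b]
    if (M == 0) next
    # brood from gamete enumeration: genotype index = #mutant alleles + 1
    brood <- c(0, 0, 0)
    ga <- .or_gam[[genos[a]]]
    gb <- .or_gam[[genos[b]]]
    for (i in 1:2) for (j in 1:2)
      brood[(i - 1) + (j - 1) + 1] <- brood[(i - 1) + (j - 1) + 1] + ga[i] * gb[j]
    # one-way mutation within the brood
    brood <- c(brood[1] * (1 - 2 * mu),
               brood[2] * (1 - mu) + brood[1] * 2 * mu,
               brood[3] + brood[2] * mu)
    num <- brood * w
    Z <- sum(num)
    if (Z == 0) next
    B <- min(Z * C, 1)
    total <- total + M * B * num / Z
  }
  total / sum(total)
}

oracle_next_gen_x <- function(state, h, s, mu, C, dimorphic = FALSE) {
  m <- state[1:2]
  fe <- state[3:5]
  fgenos <- c("pp", "pm", "mm")
  tot_m <- c(0, 0)
  tot_f <- c(0, 0, 0)
  for (a in 1:2) for (b in 1:3) {
    M <- m[a] * fe[b]
    if (M == 0) next
    fx <- if (a == 1) c(1, 0) else c(0, 1)     # father's X allele
    mx <- .or_gam[[fgenos[b]]]
    sons <- 0.5 * mx                            # (pY, mY)
    dau <- c(0, 0, 0)
    for (i in 1:2) for (j in 1:2)
      dau[(i - 1) + (j - 1) + 1] <- dau[(i - 1) + (j - 1) + 1] + 0.5 * fx[i] * mx[j]
    sons <- c(sons[1] * (1 - mu), sons[2] + sons[1] * mu)
    dau <- c(dau[1] * (1 - 2 * mu), dau[2] * (1 - mu) + dau[1] * 2 * mu,
             dau[3] + dau[2] * mu)
    num_m <- sons * c(1, 1 - s)
    num_f <- dau * c(1, 1 - h * s, 1 - s)
    if (dimorphic) {
      Zm <- sum(num_m)
      Zf <- sum(num_f)
      if (Zm > 0) tot_m <- tot_m + M * min(Zm * C, 0.5) * num_m / Zm
      if (Zf > 0) tot_f <- tot_f + M * min(Zf * C, 0.5) * num_f / Zf
    } else {
      Z <- sum(num_m) + sum(num_f)
      if (Z == 0) next
      B <- min(Z * C, 1)
      tot_m <- tot_m + M * B * num_m / Z
      tot_f <- tot_f + M * B * num_f / Z
    }
  }
  c(tot_m / sum(tot_m), tot_f / sum(tot_f))
}

# random normalized states under a fixed seed, for property-style loops
random_autosomal_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- stats::runif(3)
    x / sum(x)
  })
}

random_sexlinked_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- stats::runif(2)
    f <- stats::runif(3)
    c(m / sum(m), f / sum(f))
  })
}
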