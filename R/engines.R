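# One-generation recursions and equilibrium solvers.
#
# The brood outcome of each mating type (surviving genotype proportions and
# compensated brood size) depends only on the model parameters, never on the
# adult state, so each solver precomputes a small "kernel" matrix once and the
# per-generation update reduces to a mating-frequency vector times that
# matrix. Mating types that leave no survivors (possible only when s = 1 and
# the brood is all-mutant) contribute nothing.

AUTOSOMAL_PAIRS <- list(c("pp", "pp"), c("pp", "pm"), c("pp", "mm"),
                        c("pm", "pm"), c("pm", "mm"), c("mm", "mm"))
SEXLINKED_PAIRS <- list(c("pY", "pp"), c("pY", "pm"), c("pY", "mm"),
                        c("mY", "pp"), c("mY", "pm"), c("mY", "mm"))

# column i of the returned matrix is B_i * P(g)_i
autosomal_kernel <- function(params) {
  K <- matrix(0, 3, 6)
  for (i in 1:6) {
    dist <- apply_brood_mutation(mendelian_brood(AUTOSOMAL_PAIRS[[i]]), params$mu)
    num <- dist * fitness_weights(params, "autosomal")
    Z <- sum(num)
    if (Z > 0) K[, i] <- (num / Z) * min(Z * params$C, 1)
  }
  K
}

# For the pooled sex-linked model the whole brood shares one compensated size
# B = min(Z * C, 1); for the dimorphic model each sex's half-brood is
# compensated on its own, capped at its half-share: B_sex = min(Z_sex * C, 0.5).
sexlinked_kernel <- function(params, dimorphic = FALSE) {
  Km <- matrix(0, 2, 6)
  Kf <- matrix(0, 3, 6)
  for (i in 1:6) {
    dist <- apply_brood_mutation(mendelian_brood(SEXLINKED_PAIRS[[i]], "sexlinked"),
                                 params$mu)
    num <- dist * fitness_weights(params, "sexlinked")
    num_m <- num[1:2]
    num_f <- num[3:5]
    if (dimorphic) {
      Zm <- sum(num_m)
      Zf <- sum(num_f)
      if (Zm > 0) Km[, i] <- (num_m / Zm) * min(Zm * params$C, 0.5)
      if (Zf > 0) Kf[, i] <- (num_f / Zf) * min(Zf * params$C, 0.5)
    } else {
      Z <- sum(num)
      if (Z > 0) {
        B <- min(Z * params$C, 1)
        Km[, i] <- (num_m / Z) * B
        Kf[, i] <- (num_f / Z) * B
      }
    }
  }
  list(Km = Km, Kf = Kf)
}

autosomal_matings <- function(f) {
  c(f[1]^2, 2 * f[1] * f[2], 2 * f[1] * f[3],
    f[2]^2, 2 * f[2] * f[3], f[3]^2)
}

sexlinked_matings <- function(m, f) {
  c(m[1] * f[1], m[1] * f[2], m[1] * f[3],
    m[2] * f[1], m[2] * f[2], m[2] * f[3])
}

step_autosomal <- function(f, K) {
  num <- drop(K %*% autosomal_matings(f))
  num / sum(num)
}

step_sexlinked <- function(state, K) {
  M <- sexlinked_matings(state[1:2], state[3:5])
  num_m <- drop(K$Km %*% M)
  num_f <- drop(K$Kf %*% M)
  c(num_m / sum(num_m), num_f / sum(num_f))
}

#' One generation of the autosomal recursion
#'
#' Advances the adult genotype frequencies by one generation: the six mating
#' types form at random-mating frequencies, each produces a brood subject to
#' Mendelian segregation, within-brood mutation, viability selection, and
#' competitive release, and surviving offspring are pooled and renormalized.
#'
#' @param state Adult genotype frequencies `c(pp, pm, mm)`, summing to 1
#'   (see [autosomal_state()]).
#' @param params An [frc_params()] object.
#' @return The next generation's adult state, a normalized vector of 3.
#' @examples
#' p <- frc_params(0.5, 0.2, 1e-5, 1.5)
#' next_generation(autosomal_state(0.25, 0.5, 0.25), p)
#' @export
next_generation <- function(state, params) {
  params <- as_frc_params(params)
  check_state(state, "autosomal state")
  out <- step_autosomal(unname(state), autosomal_kernel(params))
  stats::setNames(out, AUTOSOMAL_GENOTYPES)
}

#' One generation of the sex-linked recursion
#'
#' As [next_generation()] but for an XY locus: matings are male genotype by
#' female genotype, broods are 50:50 male:female, hemizygous mutant males have
#' fitness `1 - s`, and compensation pools the whole brood, so a dead male can
#' be replaced by a surviving sister. Male and female offspring are
#' renormalized separately.
#'
#' @param state Adult state `c(m.pY, m.mY, f.pp, f.pm, f.mm)` with the male
#'   pair and female triple each summing to 1 (see [sexlinked_state()]).
#' @param params An [frc_params()] object.
#' @return The next generation's state, same shape, per-sex normalized.
#' @export
next_generation_x <- function(state, params) {
  params <- as_frc_params(params)
  check_state(state[1:2], "male state")
  check_state(state[3:5], "female state")
  out <- step_sexlinked(unname(state), sexlinked_kernel(params))
  stats::setNames(out, SEXLINKED_GENOTYPES)
}

#' One generation of the sex-linked recursion with within-sex compensation
#'
#' For species so sexually dimorphic that a dead male can only be replaced by
#' a brother and a dead female only by a sister: each sex's half of the brood
#' is compensated independently, `B_sex = min(Z_sex * C, 0.5)`, where `Z_sex`
#' is that sex's post-selection share and 0.5 its share of an all-wildtype
#' brood. With `C = 1` this coincides with [next_generation_x()] exactly.
#'
#' @inheritParams next_generation_x
#' @return The next generation's state, same shape, per-sex normalized.
#' @export
next_generation_dimorphic <- function(state, params) {
  params <- as_frc_params(params)
  check_state(state[1:2], "male state")
  check_state(state[3:5], "female state")
  out <- step_sexlinked(unname(state), sexlinked_kernel(params, dimorphic = TRUE))
  stats::setNames(out, SEXLINKED_GENOTYPES)
}

#' Mutant allele frequency among adults
#'
#' Autosomal: half the heterozygote frequency plus the mutant homozygote
#' frequency. Sex-linked: one third of alleles are in males, so
#' `q = f_male(mY)/3 + 2 * (f_fem(pm)/2 + f_fem(mm))/3`.
#'
#' @param state An autosomal (length 3) or sex-linked (length 5) adult state.
#' @return Mutant allele frequency in `[0, 1]`.
#' @export
adult_mutant_freq <- function(state) {
  if (length(state) == 3L) {
    0.5 * state[[2]] + state[[3]]
  } else if (length(state) == 5L) {
    state[[2]] / 3 + 2 * (0.5 * state[[4]] + state[[5]]) / 3
  } else {
    stop("`state` must have length 3 (autosomal) or 5 (sex-linked)", call. = FALSE)
  }
}

#' Gametic-census allele frequency
#'
#' Most of classical theory censuses allele frequencies at the gamete stage,
#' after mutation but before fertilization and selection; one extra round of
#' mutation converts the adult frequency to that census.
#'
#' @param q_adult Adult mutant allele frequency.
#' @param mu Mutation rate.
#' @return `q_adult + (1 - q_adult) * mu`.
#' @export
gametic_freq <- function(q_adult, mu) q_adult + (1 - q_adult) * mu

#' Affected-male frequency at a sex-linked locus
#'
#' The census classically used for sex-linked lethals: mutant males arise from
#' carrier mothers (half of whose sons inherit the mutation) plus fresh
#' mutation, `q = f_fem(pm)/2 + mu`.
#'
#' @param state A sex-linked adult state (length 5).
#' @param mu Mutation rate.
#' @return Frequency of affected males at birth.
#' @export
affected_male_freq <- function(state, mu) {
  if (length(state) != 5L)
    stop("`state` must be a sex-linked state of length 5", call. = FALSE)
  state[[4]] / 2 + mu
}

# Core fixed-point loop; `step` is a closure over the precomputed kernel.
# Stopping requires (a) the per-generation relative change of both allele
# frequencies to fall below rel_tol, and (b) the estimated remaining distance
# to the fixed point to fall below rel_tol as well. Near a geometrically
# contracting fixed point consecutive steps shrink by the contraction factor
# lambda, so the residual is approximately dq * lambda / (1 - lambda)
# (Aitken's estimate); without (b) the iterate halts O(rel_tol / (1 - lambda))
# away, which under weak selection is orders of magnitude short of the
# tolerance and would defeat the dual-start agreement check.
iterate_fixed_point <- function(step, state, qfun, settings) {
  q <- qfun(state)
  it <- 0
  converged <- FALSE
  dq_prev <- NA_real_
  repeat {
    state_next <- step(state)
    q_next <- qfun(state_next)
    it <- it + 1
    dq <- abs(q_next - q)
    state <- state_next
    tol_abs <- settings$rel_tol * max(min(q, 1 - q), 1e-300)
    if (dq == 0) {
      q <- q_next
      converged <- TRUE
      break
    }
    if (!is.na(dq_prev) && dq < dq_prev && dq <= tol_abs) {
      lambda <- dq / dq_prev
      if (dq * lambda / (1 - lambda) <= tol_abs) {
        q <- q_next
        converged <- TRUE
        break
      }
    }
    dq_prev <- dq
    q <- q_next
    if (it >= settings$max_iter) break
  }
  list(state = state, q = q, iterations = it, converged = converged)
}

#' Solve for the mutation-selection equilibrium
#'
#' Iterates the one-generation recursion to its fixed point. By default the
#' solver is run from both an extremely low (1e-9) and an extremely high
#' (1 - 1e-9) starting mutant frequency (each embedded as Hardy-Weinberg
#' genotype proportions) and the result is flagged converged only when both
#' trajectories agree; see [frc_solver()].
#'
#' @param params An [frc_params()] object.
#' @param model `"autosomal"`, `"sexlinked"` (pooled-brood compensation), or
#'   `"dimorphic"` (within-sex compensation).
#' @param settings An [frc_solver()] object.
#' @return An object of class `"frc_equilibrium"`: a list with the adult and
#'   gametic equilibrium mutant frequencies `q_adult`, `q_gametic`, the
#'   affected-male frequency `q_affected_males` (sex-linked models only,
#'   otherwise `NA`), the final genotype state, total `iterations` across
#'   starts, a `converged` flag, and `start_agreement` (the relative
#'   difference between the two starts' solutions; `NA` when `dual_start` is
#'   off).
#' @examples
#' \donttest{
#' frc_equilibrium(frc_params(h = 0.5, s = 0.2, mu = 1e-5, C = 2))
#' }
#' @export
frc_equilibrium <- function(params,
                            model = c("autosomal", "sexlinked", "dimorphic"),
                            settings = frc_solver()) {
  params <- as_frc_params(params)
  model <- match.arg(model)
  if (!inherits(settings, "frc_solver"))
    stop("`settings` must be created with frc_solver()", call. = FALSE)

  if (model == "autosomal") {
    K <- autosomal_kernel(params)
    step <- function(f) step_autosomal(f, K)
  } else {
    K <- sexlinked_kernel(params, dimorphic = (model == "dimorphic"))
    step <- function(st) step_sexlinked(st, K)
  }

  low <- iterate_fixed_point(step, unname(hw_state(settings$start_low, model)),
                             adult_mutant_freq, settings)
  iterations <- low$iterations
  converged <- low$converged
  start_agreement <- NA_real_
  if (settings$dual_start) {
    high <- iterate_fixed_point(step, unname(hw_state(settings$start_high, model)),
                                adult_mutant_freq, settings)
    iterations <- iterations + high$iterations
    start_agreement <- abs(low$q - high$q) / max(low$q, 1e-300)
    converged <- converged && high$converged &&
      start_agreement < 10 * settings$rel_tol
  }

  state <- low$state
  names(state) <- if (model == "autosomal") AUTOSOMAL_GENOTYPES else SEXLINKED_GENOTYPES
  q_adult <- low$q
  structure(list(model = model, params = params, settings = settings,
                 q_adult = q_adult,
                 q_gametic = gametic_freq(q_adult, params$mu),
                 q_affected_males = if (model == "autosomal") NA_real_
                                    else affected_male_freq(state, params$mu),
                 state = state, iterations = iterations,
                 converged = converged, start_agreement = start_agreement),
            class = "frc_equilibrium")
}

#' @export
print.frc_equilibrium <- function(x, ...) {
  cat(sprintf("Mutation-selection equilibrium (%s model)\n", x$model))
  cat(sprintf("  h = %g, s = %g, mu = %g, C = %g\n",
              x$params$h, x$params$s, x$params$mu, x$params$C))
  cat(sprintf("  q_adult   = %.8g\n  q_gametic = %.8g\n", x$q_adult, x$q_gametic))
  if (!is.na(x$q_affected_males))
    cat(sprintf("  affected-male frequency = %.8g\n", x$q_affected_males))
  cat(sprintf("  iterations = %d, converged = %s", as.integer(x$iterations),
              x$converged))
  if (!is.na(x$start_agreement))
    cat(sprintf(", dual-start agreement = %.3g", x$start_agreement))
  cat("\n")
  invisible(x)
}

# census accessor shared by frc_omega() and frc_grid()
census_value <- function(eq, census) {
  switch(census,
         adult = eq$q_adult,
         gametic = eq$q_gametic,
         affected_males = {
           if (is.na(eq$q_affected_males))
             stop("the affected-male census applies only to sex-linked models",
                  call. = FALSE)
           eq$q_affected_males
         },
         stop(sprintf("unknown census '%s'", census), call. = FALSE))
}

#' Fold increase in equilibrium frequency attributable to compensation
#'
#' Solves the model twice, at the supplied `C` and at the baseline `C = 1`
#' (compensation absent), and returns the ratio of the equilibrium
#' frequencies. The baseline is always the simulated `C = 1` equilibrium, not
#' a closed form, so the ratio is internally consistent for all three models.
#'
#' The default census is the adult allele frequency: under full compensation
#' the adult-census fold increase at autosomal loci equals `2 - h*s` exactly
#' (see the package vignette), which is the scale on which results are
#' reported. The gametic and affected-male censuses are available via
#' `census`.
#'
#' @inheritParams frc_equilibrium
#' @param census `"adult"`, `"gametic"`, or `"affected_males"`.
#' @return An object of class `"frc_omega"`: a list with `omega` (the fold
#'   increase), `percent_increase` (`100 * (omega - 1)`), `census`, and the
#'   two underlying [frc_equilibrium()] results `frc` and `baseline`.
#' @examples
#' \donttest{
#' frc_omega(frc_params(h = 0.5, s = 0.2, mu = 1e-5, C = 2))  # about 1.9
#' }
#' @export
frc_omega <- function(params,
                      model = c("autosomal", "sexlinked", "dimorphic"),
                      census = c("adult", "gametic", "affected_males"),
                      settings = frc_solver()) {
  params <- as_frc_params(params)
  model <- match.arg(model)
  census <- match.arg(census)
  frc <- frc_equilibrium(params, model, settings)
  baseline <- frc_equilibrium(frc_params(params$h, params$s, params$mu, C = 1),
                              model, settings)
  omega <- census_value(frc, census) / census_value(baseline, census)
  structure(list(omega = omega, percent_increase = 100 * (omega - 1),
                 census = census, model = model, frc = frc, baseline = baseline,
                 converged = frc$converged && baseline$converged),
            class = "frc_omega")
}

#' @export
print.frc_omega <- function(x, ...) {
  cat(sprintf("Fold increase under compensation (%s model, %s census)\n",
              x$model, x$census))
  cat(sprintf("  omega = %.6g (%.4g%% increase), C = %g vs C = 1%s\n",
              x$omega, x$percent_increase, x$frc$params$C,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}
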