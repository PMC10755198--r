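#' Model parameters for brood-structured mutation-selection balance
#'
#' Bundles the four parameters of the compensation model: dominance `h`,
#' selection coefficient `s`, mutation rate `mu`, and the competitive release
#' coefficient `C`. Genotype fitnesses are 1 for wildtype homozygotes (and
#' hemizygous wildtype males), `1 - h*s` for heterozygotes, and `1 - s` for
#' mutant homozygotes (and hemizygous mutant males). Mutation is one-way,
#' wildtype to mutant; back mutation is taken to be negligible.
#'
#' `C` scales the survival of brood members remaining after within-brood
#' selection: a brood reduced to relative size `Z` is restored to
#' `min(Z * C, 1)`. `C = 1` encodes the complete absence of reproductive
#' compensation and is the baseline against which fold increases are measured.
#'
#' @param h Dominance coefficient in `[0, 1]`: the fraction of the homozygote
#'   fitness cost expressed in the heterozygote (`h = 0` recessive, `h = 1`
#'   fully dominant).
#' @param s Selection coefficient in `[0, 1]` against the mutant homozygote
#'   (or hemizygous mutant male); `s = 1` is lethal.
#' @param mu Per-allele wildtype-to-mutant mutation rate per generation, in
#'   `[0, 0.01]`. The closed-form references assume mutants are rare, hence
#'   the conservative cap. `mu = 0` is accepted for single-generation
#'   calculations but makes the equilibrium trivially mutation-free.
#' @param C Competitive release coefficient, `>= 1`.
#'
#' @return An object of class `"frc_params"`: a validated list with elements
#'   `h`, `s`, `mu`, `C`.
#'
#' @examples
#' frc_params(h = 0.5, s = 0.2, mu = 1e-5, C = 1.5)
#'
#' @seealso [frc_solver()], [frc_equilibrium()]
#' @export
frc_params <- function(h, s, mu = 1e-5, C = 1) {
  check_scalar(h, "h", 0, 1)
  check_scalar(s, "s", 0, 1)
  check_scalar(mu, "mu", 0, 0.01)
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C < 1)
    stop("`C` must be a single numeric value >= 1 (C = 1 encodes absent compensation)",
         call. = FALSE)
  if (s == 0 && C > 1)
    warning("s = 0 with C > 1: selection is absent, so the mutant frequency ",
            "is not held at mutation-selection balance and the equilibrium ",
            "solvers may not converge", call. = FALSE)
  structure(list(h = h, s = s, mu = mu, C = C), class = "frc_params")
}

check_scalar <- function(x, name, lo, hi) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single numeric value in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

as_frc_params <- function(params) {
  if (inherits(params, "frc_params")) return(params)
  if (is.list(params) && all(c("h", "s", "mu", "C") %in% names(params)))
    return(frc_params(params$h, params$s, params$mu, params$C))
  stop("`params` must be an `frc_params` object; see ?frc_params", call. = FALSE)
}

#' @export
print.frc_params <- function(x, ...) {
  cat(sprintf("Compensation model parameters: h = %g, s = %g, mu = %g, C = %g\n",
              x$h, x$s, x$mu, x$C))
  if (x$C == 1) cat("  (C = 1: reproductive compensation absent)\n")
  invisible(x)
}

#' Solver settings for the fixed-point equilibrium iteration
#'
#' @param rel_tol Relative convergence tolerance: iteration stops once the
#'   adult mutant frequency changes by less than this factor between
#'   consecutive generations (applied to both the mutant and the wildtype
#'   allele frequency; see Details).
#' @param max_iter Iteration cap. Exceeding it flags the result as
#'   non-converged rather than raising an error.
#' @param start_low Initial mutant frequency for the low start.
#' @param start_high Initial mutant frequency for the high start.
#' @param dual_start If `TRUE` (the default) the solver is run from both
#'   starting frequencies and the result is only flagged converged when the
#'   two trajectories agree to within `10 * rel_tol`.
#'
#' @details
#' Convergence requires `|q' - q| <= rel_tol * min(q, 1 - q)`, i.e. the
#' relative change of both the mutant and the wildtype allele frequency must
#' fall below `rel_tol`. Monitoring the mutant frequency alone would stop the
#' high-start trajectory immediately: the all-mutant state is an (unstable)
#' fixed point of the recursion under one-way mutation, and within 1e-9 of it
#' the mutant frequency moves by far less than `rel_tol` per generation even
#' though the trajectory eventually escapes to the interior equilibrium.
#'
#' @return An object of class `"frc_solver"`.
#' @examples
#' frc_solver(rel_tol = 1e-8)
#' @export
frc_solver <- function(rel_tol = 1e-7, max_iter = 1e7, start_low = 1e-9,
                       start_high = 1 - 1e-9, dual_start = TRUE) {
  if (!is.numeric(rel_tol) || length(rel_tol) != 1L || is.na(rel_tol) ||
      rel_tol <= 0 || rel_tol >= 1)
    stop("`rel_tol` must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(max_iter) || length(max_iter) != 1L || is.na(max_iter) || max_iter < 1)
    stop("`max_iter` must be a positive number", call. = FALSE)
  if (!is.numeric(start_low) || !is.numeric(start_high) ||
      !(0 < start_low && start_low < start_high && start_high < 1))
    stop("starting frequencies must satisfy 0 < start_low < start_high < 1",
         call. = FALSE)
  structure(list(rel_tol = rel_tol, max_iter = as.numeric(max_iter),
                 start_low = start_low, start_high = start_high,
                 dual_start = isTRUE(dual_start)),
            class = "frc_solver")
}

#' Adult genotype-frequency state for an autosomal locus
#'
#' @param f_pp,f_pm,f_mm Frequencies of the wildtype homozygote, heterozygote,
#'   and mutant homozygote among adults. Must sum to 1 (tolerance 1e-8); the
#'   returned vector is renormalized to sum to 1 exactly.
#' @return A named numeric vector `c(pp, pm, mm)`.
#' @examples
#' autosomal_state(0.25, 0.5, 0.25)
#' @export
autosomal_state <- function(f_pp, f_pm, f_mm) {
  f <- c(pp = f_pp, pm = f_pm, mm = f_mm)
  check_state(f, "autosomal state")
  f / sum(f)
}

#' Adult genotype-frequency state for a sex-linked (XY) locus
#'
#' Males carry one X allele plus the Y chromosome (two genotypes); females
#' carry two X alleles (three genotypes). The male and female distributions
#' are normalized separately.
#'
#' @param m_pY,m_mY Genotype frequencies among males.
#' @param f_pp,f_pm,f_mm Genotype frequencies among females.
#' @return A named numeric vector `c(m.pY, m.mY, f.pp, f.pm, f.mm)` in which
#'   the male pair and the female triple each sum to 1.
#' @examples
#' sexlinked_state(1, 0, 1, 0, 0)
#' @export
sexlinked_state <- function(m_pY, m_mY, f_pp, f_pm, f_mm) {
  m <- c(m.pY = m_pY, m.mY = m_mY)
  f <- c(f.pp = f_pp, f.pm = f_pm, f.mm = f_mm)
  check_state(m, "male state")
  check_state(f, "female state")
  c(m / sum(m), f / sum(f))
}

check_state <- function(f, what) {
  if (any(!is.finite(f)) || any(f < 0))
    stop(sprintf("%s must be non-negative and finite", what), call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8)
    stop(sprintf("%s must be normalized (frequencies sum to %.10g, not 1)",
                 what, sum(f)), call. = FALSE)
  invisible(f)
}

# Hardy-Weinberg embedding of a scalar starting frequency, used to build the
# solver's initial states.
hw_state <- function(q0, model) {
  p0 <- 1 - q0
  if (model == "autosomal") {
    c(pp = p0^2, pm = 2 * p0 * q0, mm = q0^2)
  } else {
    c(m.pY = p0, m.mY = q0, f.pp = p0^2, f.pm = 2 * p0 * q0, f.mm = q0^2)
  }
}
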