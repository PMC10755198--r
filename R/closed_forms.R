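# Closed-form reference results from classical mutation-selection balance
# theory, used as validation baselines and for the breakdown threshold.
#
# The recessive autosomal forms are implemented with the square root
# restored: q = sqrt(mu/s) without compensation and q = sqrt(3*mu/2) for a
# recessive lethal under full compensation. Some renderings drop the radical,
# but sqrt(3/2) = 1.2247 is the only reading consistent with the classical
# sources and with the 1.22-fold increase those two forms imply; the
# as-printed radical-free variants are kept behind `as_printed = TRUE` for
# transparency.

#' Closed-form equilibrium frequency without compensation
#'
#' Classical mutation-selection balance (gametic census). Autosomal:
#' `mu/(h*s)` for semidominant mutations, `sqrt(mu/s)` for recessive
#' (`h = 0`). Sex-linked: `3*mu/(2*h*s + s)`, which reduces to `3*mu` for a
#' recessive lethal on the affected-male census.
#'
#' The sex-linked semidominant form rests on additional algebraic
#' approximations and is not exactly reproduced by the brood recursion; it is
#' provided as a reference baseline (see [validate_standard_results()]).
#'
#' @param mu Mutation rate.
#' @param h Dominance coefficient.
#' @param s Selection coefficient (`> 0`).
#' @param locus_mode `"autosomal"` or `"sexlinked"`.
#' @param as_printed Use the radical-free variant of the recessive autosomal
#'   form (`mu/s` instead of `sqrt(mu/s)`).
#' @return Equilibrium mutant frequency.
#' @examples
#' q_no_frc(1e-5, 0.5, 0.2)                 # 1e-4
#' q_no_frc(1e-7, 0, 1)                     # sqrt(1e-7), recessive lethal
#' q_no_frc(1e-7, 0, 1, "sexlinked")        # 3e-7
#' @export
q_no_frc <- function(mu, h, s, locus_mode = c("autosomal", "sexlinked"),
                     as_printed = FALSE) {
  locus_mode <- match.arg(locus_mode)
  if (s <= 0) stop("the closed forms require s > 0", call. = FALSE)
  if (locus_mode == "autosomal") {
    if (h > 0) mu / (h * s)
    else if (as_printed) mu / s
    else sqrt(mu / s)
  } else {
    3 * mu / (2 * h * s + s)
  }
}

#' Closed-form equilibrium frequency under full compensation
#'
#' Autosomal semidominant: `mu * (2 - h*s) / (h*s)`, i.e. the no-compensation
#' balance scaled by the fold increase `2 - h*s`; this holds when the
#' competitive release coefficient is large enough to restore every brood
#' (`h*s <= 2 * (1 - 1/C)`, see [frc_breakdown()]). Autosomal recessive
#' lethal: `sqrt(3*mu/2)`. Sex-linked recessive lethal (affected-male
#' census): `4*mu`.
#'
#' @inheritParams q_no_frc
#' @param as_printed Use the radical-free variant of the recessive lethal
#'   autosomal form (`3*mu/2`).
#' @return Equilibrium mutant frequency.
#' @examples
#' q_full_frc(1e-5, 0.5, 0.2)        # 1.9e-4 = 1.9 * q_no_frc
#' q_full_frc(1e-7, 0, 1)            # sqrt(1.5e-7)
#' q_full_frc(1e-7, 0, 1, "sexlinked")  # 4e-7
#' @export
q_full_frc <- function(mu, h, s, locus_mode = c("autosomal", "sexlinked"),
                       as_printed = FALSE) {
  locus_mode <- match.arg(locus_mode)
  if (locus_mode == "autosomal") {
    if (h > 0) mu * (2 - h * s) / (h * s)
    else {
      if (s != 1)
        stop("the recessive autosomal full-compensation form is only available for lethals (s = 1)",
             call. = FALSE)
      if (as_printed) 3 * mu / 2 else sqrt(3 * mu / 2)
    }
  } else {
    if (h != 0 || s != 1)
      stop("the sex-linked full-compensation closed form is only available for recessive lethals (h = 0, s = 1)",
           call. = FALSE)
    4 * mu
  }
}

#' Closed-form fold increase for autosomal semidominant mutations
#'
#' Under compensation strong enough to restore every brood, the equilibrium
#' frequency of an autosomal semidominant mutation rises by the factor
#' `2 - h*s`: heterozygotes lost from predominantly wildtype broods are
#' replaced by siblings of whom roughly half carry the mutation, halving the
#' effective selection against carriers as `h*s` becomes small.
#'
#' @param h Dominance coefficient.
#' @param s Selection coefficient.
#' @return `2 - h*s`. Vectorized.
#' @examples
#' omega_closed_form(0.5, 0.2)  # 1.9
#' @export
omega_closed_form <- function(h, s) 2 - h * s

#' Effective heterozygote fitness under full compensation
#'
#' In a wildtype-by-carrier mating, dead heterozygous offspring are replaced
#' in proportion to the surviving brood, so the carrier's effective fitness
#' rises from `1 - h*s` to `1 - h*s / (2 - h*s)`. Substituting this effective
#' selection into the classical balance `q = mu / (h_eff * s_eff)` reproduces
#' [q_full_frc()].
#'
#' @inheritParams omega_closed_form
#' @return Effective heterozygote fitness. Vectorized.
#' @export
het_fitness_frc <- function(h, s) 1 - h * s / (2 - h * s)

#' Where full compensation breaks down
#'
#' A brood can lose at most a fraction `F = 1 - 1/C` of its members and still
#' be restored to full size. With mutants rare, brood mortality is dominated
#' by heterozygotes in wildtype-by-carrier matings, who make up half the
#' brood, so full restoration fails once `h*s/2 > F`, i.e. above the
#' threshold `h*s = 2*F`. Below the threshold the percent increase in
#' equilibrium frequency is linear in `h*s`; above it the increase falls off.
#'
#' @param C Competitive release coefficient, `>= 1`.
#' @return An object of class `"frc_breakdown"`: a list with `F` (the
#'   replaceable brood fraction) and `hs_threshold = 2 * F`.
#' @examples
#' frc_breakdown(1.5)  # F = 1/3, threshold = 2/3
#' @export
frc_breakdown <- function(C) {
  if (!is.numeric(C) || any(C < 1)) stop("`C` must be >= 1", call. = FALSE)
  Fcrit <- 1 - 1 / C
  structure(list(F = Fcrit, hs_threshold = 2 * Fcrit), class = "frc_breakdown")
}

#' @export
print.frc_breakdown <- function(x, ...) {
  cat(sprintf("Replaceable brood fraction F = %.4g; full compensation fails above h*s = %.4g\n",
              x$F, x$hs_threshold))
  invisible(x)
}
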