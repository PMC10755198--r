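# Single-brood pipeline: Mendelian segregation -> within-brood mutation ->
# viability selection -> competitive release. Broods are always measured
# relative to an all-wildtype brood of size 1.

AUTOSOMAL_GENOTYPES <- c("pp", "pm", "mm")
SEXLINKED_GENOTYPES <- c("m.pY", "m.mY", "f.pp", "f.pm", "f.mm")

# allele distribution (p, m) of the gametes produced by one diploid genotype
gamete_dist <- function(genotype) {
  switch(genotype,
         pp = c(p = 1, m = 0),
         pm = c(p = 0.5, m = 0.5),
         mm = c(p = 0, m = 1),
         stop(sprintf("unknown genotype '%s'", genotype), call. = FALSE))
}

#' Mendelian offspring distribution of one mating
#'
#' Exact expected genotype proportions among the offspring of a single parental
#' pair, before mutation and selection. For sex-linked loci the pair is
#' (father, mother); the brood is 50:50 male:female, sons inherit the mother's
#' X allele plus the Y, and daughters one X allele from each parent.
#'
#' @param parents Character vector of two parental genotypes. Autosomal:
#'   both among `"pp"`, `"pm"`, `"mm"`. Sex-linked: father first, one of
#'   `"pY"`, `"mY"`, then mother among `"pp"`, `"pm"`, `"mm"`.
#' @param locus_mode `"autosomal"` or `"sexlinked"`.
#' @return Named numeric vector of offspring genotype proportions summing
#'   to 1: `c(pp, pm, mm)` or `c(m.pY, m.mY, f.pp, f.pm, f.mm)`.
#' @examples
#' mendelian_brood(c("pm", "pm"))                  # 25/50/25
#' mendelian_brood(c("mY", "pm"), "sexlinked")
#' @export
mendelian_brood <- function(parents, locus_mode = c("autosomal", "sexlinked")) {
  locus_mode <- match.arg(locus_mode)
  if (length(parents) != 2L)
    stop("`parents` must name exactly two parental genotypes", call. = FALSE)
  if (locus_mode == "autosomal") {
    g1 <- unname(gamete_dist(parents[1]))  # (p, m)
    g2 <- unname(gamete_dist(parents[2]))
    c(pp = g1[1] * g2[1],
      pm = g1[1] * g2[2] + g1[2] * g2[1],
      mm = g1[2] * g2[2])
  } else {
    father <- parents[1]
    mother <- parents[2]
    if (!father %in% c("pY", "mY"))
      stop("sex-linked matings are father x mother; the first genotype must be 'pY' or 'mY'",
           call. = FALSE)
    if (!mother %in% c("pp", "pm", "mm"))
      stop("the maternal genotype must be one of 'pp', 'pm', 'mm'", call. = FALSE)
    fx <- if (father == "pY") c(1, 0) else c(0, 1)  # father's X allele (p, m)
    mx <- unname(gamete_dist(mother))
    sons <- 0.5 * mx                                # X from mother, plus Y
    daughters <- 0.5 * c(fx[1] * mx[1],
                         fx[1] * mx[2] + fx[2] * mx[1],
                         fx[2] * mx[2])
    stats::setNames(c(sons, daughters), SEXLINKED_GENOTYPES)
  }
}

#' Apply within-brood mutation to an offspring genotype distribution
#'
#' Mutation acts on brood genotypes: a proportion `2*mu` of wildtype
#' homozygotes become heterozygous, a proportion `mu` of heterozygotes become
#' mutant homozygotes, and (sex-linked) a proportion `mu` of hemizygous
#' wildtype males become hemizygous mutants. There is no back mutation, and
#' total mass is conserved exactly.
#'
#' @param dist Named genotype distribution as returned by [mendelian_brood()].
#' @param mu Mutation rate per allele per generation.
#' @return Distribution of the same shape, still summing to 1.
#' @export
apply_brood_mutation <- function(dist, mu) {
  if (length(dist) == 3L) {
    c(pp = dist[["pp"]] * (1 - 2 * mu),
      pm = dist[["pm"]] * (1 - mu) + dist[["pp"]] * 2 * mu,
      mm = dist[["mm"]] + dist[["pm"]] * mu)
  } else if (length(dist) == 5L) {
    c(m.pY = dist[["m.pY"]] * (1 - mu),
      m.mY = dist[["m.mY"]] + dist[["m.pY"]] * mu,
      f.pp = dist[["f.pp"]] * (1 - 2 * mu),
      f.pm = dist[["f.pm"]] * (1 - mu) + dist[["f.pp"]] * 2 * mu,
      f.mm = dist[["f.mm"]] + dist[["f.pm"]] * mu)
  } else {
    stop("`dist` must be an autosomal (3) or sex-linked (5) genotype distribution",
         call. = FALSE)
  }
}

# fitness weights in genotype order
fitness_weights <- function(params, locus_mode) {
  hs <- params$h * params$s
  if (locus_mode == "autosomal") c(1, 1 - hs, 1 - params$s)
  else c(1, 1 - params$s, 1, 1 - hs, 1 - params$s)
}

#' Within-brood viability selection
#'
#' Weights each brood genotype by its fitness (wildtype 1, heterozygote
#' `1 - h*s`, mutant homozygote and hemizygous mutant male `1 - s`). The sum
#' of the weighted terms is the relative brood size after selection, `Z`;
#' the normalized terms are the genotype proportions among survivors.
#'
#' @param dist Post-mutation genotype distribution (autosomal length 3 or
#'   sex-linked length 5).
#' @param params An [frc_params()] object.
#' @return A list with `numerators` (the unnormalized weighted terms),
#'   `Z`, and `proportions` (numerators / Z).
#' @export
apply_selection <- function(dist, params) {
  params <- as_frc_params(params)
  mode <- if (length(dist) == 3L) "autosomal" else "sexlinked"
  num <- dist * fitness_weights(params, mode)
  Z <- sum(num)
  if (Z == 0)
    stop("brood extinct: all offspring genotypes have zero fitness", call. = FALSE)
  list(numerators = num, Z = Z, proportions = num / Z)
}

#' Brood size after reproductive compensation
#'
#' Competitive release restores a brood reduced to relative size `Z` up to
#' `Z * C`, capped at the size of an all-wildtype brood (1).
#'
#' @param Z Relative brood size after selection, in `[0, 1]`.
#' @param C Competitive release coefficient, `>= 1`. `C = 1` leaves the brood
#'   unchanged. Vectorized over both arguments.
#' @return `pmin(Z * C, 1)`.
#' @examples
#' brood_size_after_frc(0.7, 1.5)   # fully restored: 1
#' brood_size_after_frc(0.5, 1.5)   # 0.75
#' @export
brood_size_after_frc <- function(Z, C) {
  if (any(Z < 0 | Z > 1)) stop("`Z` must lie in [0, 1]", call. = FALSE)
  if (any(C < 1)) stop("`C` must be >= 1", call. = FALSE)
  pmin(Z * C, 1)
}

#' Full brood outcome for one mating type
#'
#' Runs the complete pipeline for a single parental pair: Mendelian
#' segregation, within-brood mutation, viability selection, and competitive
#' release. Compensation is genotype-blind: survivors' gain in numbers is
#' independent of which genotypes survived.
#'
#' @inheritParams mendelian_brood
#' @param params An [frc_params()] object.
#' @return An object of class `"frc_brood"`: a list with `proportions`
#'   (surviving genotype proportions, summing to 1), `Z` (relative brood size
#'   after selection), and `B` (relative brood size after compensation,
#'   `min(Z * C, 1)`).
#' @examples
#' brood_outcome(c("pm", "pm"), frc_params(0.5, 0.2, 1e-5, 1.5))
#' @export
brood_outcome <- function(parents, params,
                          locus_mode = c("autosomal", "sexlinked")) {
  locus_mode <- match.arg(locus_mode)
  params <- as_frc_params(params)
  dist <- apply_brood_mutation(mendelian_brood(parents, locus_mode), params$mu)
  sel <- apply_selection(dist, params)
  structure(list(parents = parents, locus_mode = locus_mode,
                 proportions = sel$proportions, Z = sel$Z,
                 B = brood_size_after_frc(sel$Z, params$C)),
            class = "frc_brood")
}

#' @export
print.frc_brood <- function(x, ...) {
  cat(sprintf("Brood of %s x %s (%s): Z = %.6g, B = %.6g\n",
              x$parents[1], x$parents[2], x$locus_mode, x$Z, x$B))
  print(round(x$proportions, 6))
  invisible(x)
}
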