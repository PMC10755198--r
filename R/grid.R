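# Parameter-grid sweeps, the percent-increase regression, and the validation
# table against the classical closed forms.

#' Sweep the equilibrium solver over a dominance/selection grid
#'
#' Solves the chosen model to equilibrium for every combination of `h`, `s`,
#' and `C`, together with the simulated `C = 1` baseline for the same cell
#' (computed once per `(h, s)` and shared across `C` values), and records the
#' fold increase attributable to compensation. The defaults are the standard
#' survey grid: `h` from 0.05 to 0.95 and `s` from 0.05 to 0.9 in steps of
#' 0.05, `C` in `{1.1, 1.2, 1.5, 2}`, `mu = 1e-5`. Everything is
#' deterministic; repeated runs are bit-identical.
#'
#' @param model `"autosomal"`, `"sexlinked"`, or `"dimorphic"`.
#' @param h_values,s_values Grid values for dominance and selection.
#' @param C_values Competitive release coefficients to sweep (each `> 1`).
#' @param mu Mutation rate used for every cell.
#' @param census Census used for `q_frc`, `q_baseline` and hence `omega`;
#'   the adult census (default) is the scale on which the autosomal fold
#'   increase equals `2 - h*s` exactly under full compensation.
#' @param settings An [frc_solver()] object.
#' @param verbose Print a progress line per grid cell.
#' @return A data frame with one row per `(h, s, C)` cell: `model`, `census`,
#'   `h`, `s`, `C`, `mu`, `q_frc`, `q_baseline`, `omega`,
#'   `percent_increase`, `converged` (both solves), and the iteration counts
#'   of both solves.
#' @examples
#' \donttest{
#' g <- frc_grid(h_values = c(0.1, 0.5), s_values = c(0.1, 0.5), C_values = 2)
#' g[, c("h", "s", "omega")]
#' }
#' @export
frc_grid <- function(model = c("autosomal", "sexlinked", "dimorphic"),
                     h_values = seq(0.05, 0.95, by = 0.05),
                     s_values = seq(0.05, 0.9, by = 0.05),
                     C_values = c(1.1, 1.2, 1.5, 2),
                     mu = 1e-5,
                     census = c("adult", "gametic", "affected_males"),
                     settings = frc_solver(),
                     verbose = FALSE) {
  model <- match.arg(model)
  census <- match.arg(census)
  if (any(C_values <= 1))
    stop("`C_values` must all exceed 1; the C = 1 baseline is computed automatically",
         call. = FALSE)
  cells <- expand.grid(h = h_values, s = s_values, C = C_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$h, cells$s, cells$C), , drop = FALSE]
  rownames(cells) <- NULL

  baseline_cache <- new.env(parent = emptyenv())
  n <- nrow(cells)
  q_frc <- q_baseline <- numeric(n)
  conv <- logical(n)
  it_frc <- it_base <- integer(n)
  for (i in seq_len(n)) {
    h <- cells$h[i]; s <- cells$s[i]; C <- cells$C[i]
    key <- paste(h, s)
    base <- baseline_cache[[key]]
    if (is.null(base)) {
      base <- frc_equilibrium(frc_params(h, s, mu, C = 1), model, settings)
      baseline_cache[[key]] <- base
    }
    eq <- frc_equilibrium(frc_params(h, s, mu, C), model, settings)
    q_frc[i] <- census_value(eq, census)
    q_baseline[i] <- census_value(base, census)
    conv[i] <- eq$converged && base$converged
    it_frc[i] <- as.integer(eq$iterations)
    it_base[i] <- as.integer(base$iterations)
    if (verbose)
      message(sprintf("h=%.2f s=%.2f C=%.2f: omega=%.5f%s", h, s, C,
                      q_frc[i] / q_baseline[i], if (conv[i]) "" else " (not converged)"))
  }
  omega <- q_frc / q_baseline
  data.frame(model = model, census = census,
             h = cells$h, s = cells$s, C = cells$C, mu = mu,
             q_frc = q_frc, q_baseline = q_baseline,
             omega = omega, percent_increase = 100 * (omega - 1),
             converged = conv, iterations_frc = it_frc,
             iterations_baseline = it_base,
             stringsAsFactors = FALSE)
}

#' Regression of percent increase on h*s over the linear portion of a grid
#'
#' Restricts the grid records to the cells where compensation can fully
#' restore every brood -- strictly `h*s < 2 * (1 - 1/C)`, the linearity
#' threshold of [frc_breakdown()] -- and fits an ordinary least-squares line
#' of the percent increase in equilibrium frequency on `h*s`. On the
#' autosomal grid the fit recovers an intercept of 100 and a slope of -100,
#' the regression form of the fold increase `2 - h*s`.
#'
#' @param records A data frame from [frc_grid()].
#' @param C Which competitive release coefficient's records to fit.
#' @return Named numeric vector `c(intercept, slope)` with the fitted `lm`
#'   attached as attribute `"fit"`.
#' @examples
#' \donttest{
#' g <- frc_grid(C_values = 2)
#' fit_percent_increase(g, C = 2)
#' }
#' @export
fit_percent_increase <- function(records, C) {
  if (!all(c("h", "s", "C", "percent_increase") %in% names(records)))
    stop("`records` must be a grid data frame from frc_grid()", call. = FALSE)
  if (C <= 1) stop("`C` must exceed 1", call. = FALSE)
  sub <- records[records$C == C, , drop = FALSE]
  sub <- sub[sub$h * sub$s < frc_breakdown(C)$hs_threshold, , drop = FALSE]
  if (nrow(sub) < 3)
    stop(sprintf("fewer than 3 grid cells lie in the linear portion (h*s < %g) for C = %g",
                 frc_breakdown(C)$hs_threshold, C), call. = FALSE)
  sub$hs <- sub$h * sub$s
  fit <- stats::lm(percent_increase ~ hs, data = sub)
  out <- c(intercept = unname(stats::coef(fit)[1]),
           slope = unname(stats::coef(fit)[2]))
  attr(out, "fit") <- fit
  out
}

#' Check the recursion against the classical closed forms
#'
#' Runs the equilibrium solvers in the regimes where classical
#' mutation-selection balance theory gives closed-form answers and tabulates
#' simulated against expected frequencies. With `C = 1` the recursions must
#' reproduce the standard results; with compensation high enough to restore
#' every brood (`C = 100`) they must reproduce the published full-compensation
#' results for recessive lethals.
#'
#' The sex-linked semidominant baseline is tabulated but not held to the 1%
#' bar (`asserted = FALSE`): its derivation makes additional algebraic
#' approximations that the recursion does not share, and the deviation is
#' expected.
#'
#' @param mu Mutation rate for every check.
#' @param settings An [frc_solver()] object.
#' @return A data frame with one row per check: the regime, model, census,
#'   parameters, expected and simulated frequencies, relative error, whether
#'   the row is asserted, and a pass flag (relative error below 1% or row not
#'   asserted).
#' @examples
#' \donttest{
#' validate_standard_results()
#' }
#' @export
validate_standard_results <- function(mu = 1e-7, settings = frc_solver()) {
  rows <- list(
    list(check = "autosomal semidominant, no compensation",
         model = "autosomal", census = "gametic", h = 0.5, s = 0.2, C = 1,
         expected = q_no_frc(mu, 0.5, 0.2), asserted = TRUE),
    list(check = "autosomal recessive, no compensation",
         model = "autosomal", census = "gametic", h = 0, s = 0.5, C = 1,
         expected = q_no_frc(mu, 0, 0.5), asserted = TRUE),
    list(check = "autosomal recessive lethal, full compensation",
         model = "autosomal", census = "gametic", h = 0, s = 1, C = 100,
         expected = q_full_frc(mu, 0, 1), asserted = TRUE),
    list(check = "sex-linked semidominant, no compensation",
         model = "sexlinked", census = "gametic", h = 0.5, s = 0.2, C = 1,
         expected = q_no_frc(mu, 0.5, 0.2, "sexlinked"), asserted = FALSE),
    list(check = "sex-linked recessive lethal, no compensation",
         model = "sexlinked", census = "affected_males", h = 0, s = 1, C = 1,
         expected = q_no_frc(mu, 0, 1, "sexlinked"), asserted = TRUE),
    list(check = "sex-linked recessive lethal, full compensation",
         model = "sexlinked", census = "affected_males", h = 0, s = 1, C = 100,
         expected = q_full_frc(mu, 0, 1, "sexlinked"), asserted = TRUE)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    eq <- suppressWarnings(
      frc_equilibrium(frc_params(r$h, r$s, mu, r$C), r$model, settings))
    simulated <- census_value(eq, r$census)
    rel_error <- abs(simulated / r$expected - 1)
    data.frame(check = r$check, model = r$model, census = r$census,
               h = r$h, s = r$s, mu = mu, C = r$C,
               expected = r$expected, simulated = simulated,
               rel_error = rel_error, converged = eq$converged,
               asserted = r$asserted,
               pass = !r$asserted || (rel_error < 0.01 && eq$converged),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export grid records to CSV or JSON
#'
#' @param records A data frame from [frc_grid()] (or any data frame).
#' @param path Output file path.
#' @param format `"csv"` (header row, fixed column order) or `"json"` (array
#'   of row objects). Floating-point values are written with 10 significant
#'   digits.
#' @return `path`, invisibly.
#' @export
export_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    num <- vapply(records, is.double, logical(1))
    records[num] <- lapply(records[num], signif, digits = 10)
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = 10,
                         pretty = TRUE)
  }
  invisible(path)
}
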