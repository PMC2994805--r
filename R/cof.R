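#' Observed epidemiological targets for the Closeness-of-Fit
#'
#' The six outcomes the grid search is scored against: population
#' prevalence (reported in per-mille so the point value is 1.5), and the
#' recurrence rates (percent) in non-twin siblings, offspring of conjugal
#' MS couples (a point estimate of ~10% with no published range), parents
#' and children, second degree relatives (aunts/uncles) and third degree
#' relatives (first cousins).
#'
#' @return A tibble with columns `outcome`, `obs_low`, `obs_high`, `E`
#'   (the point value entering the CoF) and `unit`.
#' @export
fit_targets <- function() {
  tibble::tribble(
    ~outcome,             ~obs_low, ~obs_high, ~E,   ~unit,
    "prevalence",          1.0,      2.0,       1.5,  "per-mille",
    "sibling",             2.9,      3.8,       3.0,  "percent",
    "conjugal_offspring", 10.0,     10.0,      10.0,  "percent",
    "parent_child",        1.8,      2.1,       2.0,  "percent",
    "aunt_uncle",          0.9,      1.6,       1.0,  "percent",
    "first_cousin",        0.9,      0.9,       0.9,  "percent"
  )
}

#' Closeness-of-Fit statistic
#'
#' For each target with observed point value `E` and model-predicted high
#' and low estimates `H` and `L` (the predictions at the two ends of the
#' solved `x` range), the squared summed relative deviation
#' `[(H - E)/E + (L - E)/E]^2` is computed and the per-target terms are
#' summed. The statistic is unit-free (invariant to rescaling `H`, `L`,
#' `E` of a target by a common factor). By analogy with a chi-square on
#' one degree of freedom, a total below 4 is considered a reasonable fit.
#'
#' @param H,L Predicted high and low estimates, one per target.
#' @param E Observed point values, same length; targets with `E = 0` are
#'   dropped with a warning.
#' @return The scalar sum of squared deviations.
#' @examples
#' cof(H = 4, L = 3, E = 3) # (1/3 + 0)^2
#' @export
cof <- function(H, L, E) {
  stopifnot(length(H) == length(L), length(H) == length(E))
  bad <- E == 0
  if (any(bad)) {
    warning("Dropping ", sum(bad), " target(s) with E = 0.", call. = FALSE)
    H <- H[!bad]; L <- L[!bad]; E <- E[!bad]
  }
  sum(((H - E) / E + (L - E) / E)^2)
}

#' Sweep the (r, n) grid and score each configuration
#'
#' For every combination of frequency ratio `r` and threshold `n`: solves
#' the locus-count constraint for the admissible `x` range, evaluates the
#' predicted prevalence and relative recurrence rates at the two ends of
#' that range, and scores the configuration with the Closeness-of-Fit
#' against [fit_targets()]. High/low predictions are taken over the range
#' endpoints only. Cells with no admissible `x` are flagged infeasible and
#' carry `NA` predictions.
#'
#' @param r_grid Frequency ratios to scan.
#' @param n_range Threshold values to scan.
#' @param composition Dominance composition of the non-HLA loci (see
#'   [ms_model()]).
#' @param targets Target table for the CoF; drop rows to probe the effect
#'   of individual targets.
#' @param tol,x_scan Passed to [solve_x()].
#' @param x_ranges Optional data frame with columns `r`, `n`, `x_low`,
#'   `x_high` giving externally fixed locus-count ranges per cell (e.g.
#'   [published_x_ranges()]); cells present there skip the scan and are
#'   evaluated at the given bounds. The literal scan and the published
#'   ranges differ for some cells because the original program's exact
#'   tolerance convention is not recoverable.
#' @param ... Further arguments to [ms_model()] (e.g. `pt1_star`,
#'   `pt0_star`, `h`, `h_m`).
#' @return An `ms_sweep` tibble, one row per `(r, n)`, with the solved `x`
#'   bounds, low/high predictions per outcome (probabilities) and `cof`.
#' @examples
#' sw <- sweep_grid(r_grid = c(2, 4), n_range = 12:14,
#'                  composition = c(dominant = 0.2, recessive = 0.8))
#' find_optimum(sw)
#' @export
sweep_grid <- function(r_grid = c(0.25, 0.33, 0.5, 1, 2, 4, 8, 16),
                       n_range = 5:60,
                       composition = c(dominant = 0.2, recessive = 0.8),
                       targets = fit_targets(), tol = 0.05,
                       x_scan = c(4, 2000), x_ranges = NULL, ...) {
  grid <- tidyr::expand_grid(r = r_grid, n = n_range)
  rows <- purrr::pmap_dfr(grid, function(r, n) {
    params <- ms_model(n = n, r = r, composition = composition, ...)
    fixed <- if (is.null(x_ranges)) NULL else
      dplyr::filter(x_ranges, abs(.data$r - !!r) < 1e-9, .data$n == !!n)
    if (!is.null(fixed) && nrow(fixed) == 1) {
      sol <- tibble::tibble(
        x_continuous = solve_x_root(n, r, params$c_star),
        x_low = as.integer(fixed$x_low), x_high = as.integer(fixed$x_high),
        feasible = TRUE
      )
    } else {
      sol <- solve_x(n = n, r = r, c_star = params$c_star, tol = tol,
                     x_scan = x_scan)
    }
    base <- tibble::tibble(r = r, n = as.integer(n),
                           x_continuous = sol$x_continuous,
                           x_low = sol$x_low, x_high = sol$x_high,
                           feasible = sol$feasible)
    if (!sol$feasible) return(dplyr::mutate(base, cof = NA_real_))
    ends <- unique(c(sol$x_low, sol$x_high))
    preds <- predict_rates(params, x = ends)
    wide <- preds |>
      dplyr::group_by(.data$outcome) |>
      dplyr::summarise(low = min(.data$rate), high = max(.data$rate)) |>
      tidyr::pivot_wider(names_from = "outcome",
                         values_from = c("low", "high"),
                         names_glue = "{outcome}_{.value}")
    scored <- cof_score(wide, targets)
    dplyr::bind_cols(base, wide, cof = scored)
  })
  attr(rows, "targets") <- targets
  attr(rows, "composition") <- normalize_composition(composition)
  attr(rows, "tol") <- tol
  class(rows) <- c("ms_sweep", class(rows))
  rows
}

cof_score <- function(wide, targets) {
  scale <- ifelse(targets$unit == "per-mille", 1000, 100)
  H <- purrr::map2_dbl(targets$outcome, scale,
                       ~ wide[[paste0(.x, "_high")]] * .y)
  L <- purrr::map2_dbl(targets$outcome, scale,
                       ~ wide[[paste0(.x, "_low")]] * .y)
  cof(H, L, targets$E)
}

#' Best-fitting configuration of a sweep
#'
#' @param sweep An `ms_sweep` from [sweep_grid()].
#' @param threshold CoF value below which a configuration counts as an
#'   acceptable fit (default 4, the one-degree-of-freedom chi-square
#'   critical value).
#' @return The feasible row with minimal CoF (ties broken by smaller `n`,
#'   then smaller `r`), with the acceptable set (`cof < threshold`)
#'   attached as attribute `"acceptable"`.
#' @export
find_optimum <- function(sweep, threshold = 4) {
  ok <- dplyr::filter(sweep, .data$feasible, is.finite(.data$cof))
  if (nrow(ok) == 0) stop("All grid cells are infeasible.", call. = FALSE)
  best <- ok |>
    dplyr::arrange(.data$cof, .data$n, .data$r) |>
    dplyr::slice(1)
  attr(best, "acceptable") <- dplyr::filter(ok, .data$cof < threshold)
  best
}

#' @export
tidy.ms_sweep <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(
      cols = dplyr::matches("_(low|high)$") & !dplyr::starts_with("x_"),
      names_to = c("outcome", "bound"),
      names_pattern = "(.*)_(low|high)",
      values_to = "rate"
    ) |>
    dplyr::select("r", "n", "x_low", "x_high", "feasible", "outcome",
                  "bound", "rate", "cof")
}

#' @export
glance.ms_sweep <- function(x, ...) {
  opt <- find_optimum(x)
  tibble::tibble(
    n_cells = nrow(x),
    n_feasible = sum(x$feasible),
    n_acceptable = nrow(attr(opt, "acceptable")),
    min_cof = opt$cof,
    optimum_n = opt$n,
    optimum_r = opt$r,
    optimum_x_low = opt$x_low,
    optimum_x_high = opt$x_high
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Heatmap of the Closeness-of-Fit surface
#'
#' @param object An `ms_sweep` from [sweep_grid()].
#' @param threshold Cells with CoF below this are outlined.
#' @param ... Unused.
#' @return A ggplot object: log10 CoF over the `(n, r)` grid.
#' @export
autoplot.ms_sweep <- function(object, threshold = 4, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$feasible)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$n), factor(.data$r))) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$cof))) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$cof < threshold),
                       fill = NA, colour = "white", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "log10 CoF", direction = -1) +
    ggplot2::labs(x = "loci required (n)", y = "frequency ratio (r)",
                  title = "Closeness of Fit over the model grid",
                  subtitle = sprintf("outlined: CoF < %g", threshold))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted recurrence profile across relative classes
#'
#' @param params An [ms_model()] object.
#' @param x Locus counts at which to evaluate (e.g. a solved range's
#'   endpoints).
#' @return A ggplot object of predicted rates by relative class.
#' @export
plot_recurrence_profile <- function(params, x = params$x) {
  df <- predict_rates(params, x = x)
  ggplot2::ggplot(df, ggplot2::aes(.data$outcome, 100 * .data$rate,
                                   colour = factor(.data$x))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "predicted rate (%)", colour = "x loci") +
    ggplot2::coord_flip()
}

#' Published locus-count ranges per grid cell
#'
#' The integer `x` ranges the original analysis reported for each `(r, n)`
#' cell (its scan tolerance convention is not exactly recoverable, so a
#' literal `C* +/- 0.05` scan reproduces these only approximately). Useful
#' as the `x_ranges` argument of [sweep_grid()] to evaluate predictions at
#' the published locus counts.
#'
#' @return A tibble with columns `r`, `n`, `x_low`, `x_high`.
#' @export
published_x_ranges <- function() {
  path <- system.file("extdata", "published_x_ranges.tsv",
                      package = "mssusmod")
  tibble::as_tibble(utils::read.delim(path))
}
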