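#' Epidemiological constants used by the model
#'
#' The scalar observations that anchor the model: the population prevalence
#' of MS, twin and family concordance rates, and the HLA carrier
#' frequencies in the general and case populations (northern European /
#' North American estimates).
#'
#' @return A named list: `p_ms` (0.0015, midpoint of the 0.1-0.2%
#'   prevalence range), `cr_mz` (0.25), `cr_dz` (0.054), `cr_s` (0.029),
#'   `h` (0.24), `h_m` (0.55), `a_hm` (0.328, case allele frequency),
#'   `p_mse_max` (0.0015, bound on non-genetic MS), `c_star_max` (0.79,
#'   the upper limit of `C*` as the penetrance ratio grows), and the twin
#'   table counts (`twin_table`).
#' @export
epi_constants <- function() {
  list(
    p_ms = 0.0015, cr_mz = 0.25, cr_dz = 0.054, cr_s = 0.029,
    h = 0.24, h_m = 0.55, a_hm = 0.328,
    p_mse_max = 0.0015, c_star_max = 0.79,
    twin_table = twin_table()
  )
}

#' Monozygotic twin concordance split by proband HLA status
#'
#' Pair counts of concordant and discordant MZ twin pairs by whether the
#' proband carries the HLA allele, with the published proband-wise rates
#' carried as data (their ascertainment correction is not reproducible
#' from the printed counts).
#'
#' @return A tibble, one row per proband HLA stratum.
#' @export
twin_table <- function() {
  tibble::tibble(
    proband_hla = c("positive", "negative"),
    concordant = c(9L, 11L),
    discordant = c(31L, 42L),
    probandwise = c(0.31, 0.29)
  )
}

#' Penetrance adjusted for the shared intrauterine environment
#'
#' Dizygotic twins of an MS proband have a higher recurrence risk (5.4%)
#' than non-twin siblings (2.9%) despite identical genetic sharing; the
#' ratio estimates the effect of the shared intrauterine / early postnatal
#' environment. Dividing the monozygotic concordance rate by it yields the
#' adjusted penetrance `CR_IG = CR_MZ * (CR_S / CR_DZ)` that applies to an
#' identical genotype outside a shared intrauterine environment.
#'
#' @param cr_mz Proband-wise monozygotic twin concordance rate.
#' @param cr_dz Dizygotic twin concordance rate.
#' @param cr_s Non-twin sibling concordance rate.
#' @return A list: `cr_ig` (the adjusted penetrance, 0.134 at the
#'   defaults) and `dz_sib_ratio` (1.86).
#' @export
adjusted_penetrance <- function(cr_mz = 0.25, cr_dz = 0.054, cr_s = 0.029) {
  stopifnot(cr_mz >= 0, cr_mz <= 1, cr_dz > 0, cr_dz <= 1, cr_s > 0,
            cr_s <= 1)
  if (cr_dz < cr_s) {
    warning("cr_dz < cr_s: the adjustment would inflate rather than ",
            "shrink the penetrance.", call. = FALSE)
  }
  list(cr_ig = cr_mz * cr_s / cr_dz, dz_sib_ratio = cr_dz / cr_s)
}

#' Proportion of the population genetically susceptible to MS
#'
#' Point estimate `P(G) = P(MS) / b'` where `b'` is the adjusted penetrance
#' of an identical genotype, and the worst-case upper bound `2 P(MS) / b'`
#' from partitioning susceptible genotypes into above- and below-average
#' penetrance classes (the bound is attained when the classes are equally
#' frequent). The bound is capped at 1.
#'
#' @param p_ms Population prevalence of MS.
#' @param b_prime Adjusted penetrance (`CR_IG`).
#' @return A tibble with columns `point` and `bound`.
#' @examples
#' pg_point_and_bound() # 1.1% and 2.2%
#' @export
pg_point_and_bound <- function(p_ms = 0.0015, b_prime = 0.134) {
  stopifnot(b_prime > 0, p_ms >= 0)
  point <- p_ms / b_prime
  tibble::tibble(point = point, bound = pmin(1, 2 * point))
}

#' Lower bound on genetic MS from the Finland twin cohort
#'
#' A population-based cohort of monozygotic twin pairs: concordant pairs
#' among the participating subset, up-weighted by the ascertained-to-
#' participating ratio and divided by the cohort size, bound the rate of
#' genetic MS from below.
#'
#' @param concordant Concordant pairs among participants.
#' @param ascertained_pairs Pairs with at least one affected twin.
#' @param participating_pairs Pairs that participated.
#' @param cohort_pairs Total twin pairs in the cohort.
#' @return Rate per 100,000 population.
#' @examples
#' finland_lower_bound() # 204 per 100,000
#' @export
finland_lower_bound <- function(concordant = 3, ascertained_pairs = 21,
                                participating_pairs = 10,
                                cohort_pairs = 3083) {
  if (participating_pairs < 1) {
    stop("`participating_pairs` must be at least 1.", call. = FALSE)
  }
  stopifnot(concordant >= 0, ascertained_pairs >= 0, cohort_pairs >= 1)
  1e5 * concordant * (ascertained_pairs / participating_pairs) / cohort_pairs
}

#' Pairwise and adjusted concordance rates from the twin table
#'
#' Pairwise concordance is `C / (C + D)` per proband HLA stratum. The
#' published proband-wise rates are taken as data and down-weighted by the
#' sibling/DZ ratio to remove the shared intrauterine effect.
#'
#' @param table A tibble as returned by [twin_table()].
#' @param sib_dz_ratio `CR_S / CR_DZ` (default 2.9/5.4).
#' @return The input with columns `pairwise` and `adjusted` added.
#' @export
twin_table_stats <- function(table = twin_table(),
                             sib_dz_ratio = 2.9 / 5.4) {
  stopifnot(all(c("concordant", "discordant") %in% names(table)))
  dplyr::mutate(
    table,
    pairwise = ifelse(.data$concordant + .data$discordant > 0,
                      .data$concordant / (.data$concordant + .data$discordant),
                      NA_real_),
    adjusted = .data$probandwise * sib_dz_ratio
  )
}

#' Allelic odds ratio between cases and controls
#'
#' @param a_case Allele frequency among cases.
#' @param a_control Allele frequency among controls.
#' @return The odds ratio `[a1/(1-a1)] / [a0/(1-a0)]`; 0 or infinite
#'   frequencies are flagged with a warning and give 0/`Inf`/`NaN`.
#' @examples
#' allelic_odds_ratio(0.328, 0.128) # 3.3, the HLA calibration value
#' @export
allelic_odds_ratio <- function(a_case, a_control) {
  check_prob(a_case, "a_case"); check_prob(a_control, "a_control")
  if (any(a_case %in% c(0, 1)) || any(a_control %in% c(0, 1))) {
    warning("Degenerate allele frequency: odds ratio is 0 or infinite.",
            call. = FALSE)
  }
  (a_case / (1 - a_case)) / (a_control / (1 - a_control))
}

#' Bounds on the HLA-positive vs HLA-negative penetrance split
#'
#' The observed HLA-negative case fraction `C_obs` reflects the true
#' susceptible fraction `C_true` filtered through the penetrances:
#' `C_obs = C_true Pt0 / [(1 - C_true) Pt1 + C_true Pt0]`. Since `C*` has
#' an upper limit (`c_star_max`), `C_true <= c_star_max (1 - h)` and the
#' penetrance ratio `Pt1 / Pt0` is bounded above by the value that
#' reconciles `C_obs` with that maximal `C_true`. The mean-penetrance
#' constraint `(1 - C_obs) Pt1 + C_obs Pt0 = Pt_mean` then pins the
#' extreme `Pt1` and `Pt0`.
#'
#' @param pt_mean Mean penetrance (MZ concordance, 0.25).
#' @param c_obs Observed HLA-negative case fraction.
#' @param h HLA carrier frequency.
#' @param c_star_max Upper limit of `C*` (0.79).
#' @return A tibble: `ratio_max` (max `Pt1/Pt0`, ~1.8), `pt1_max`,
#'   `pt0_min`.
#' @export
penetrance_bounds <- function(pt_mean = 0.25, c_obs = 0.45, h = 0.24,
                              c_star_max = 0.79) {
  check_prob(pt_mean, "pt_mean"); check_prob(c_obs, "c_obs")
  check_prob(h, "h")
  c_true_max <- c_star_max * (1 - h)
  if (c_true_max <= 0 || c_true_max >= 1 || c_obs <= 0 || c_obs >= 1) {
    stop("Infeasible constraint set for the penetrance bounds.",
         call. = FALSE)
  }
  # C_obs = C_true Pt0 / [(1 - C_true) Pt1 + C_true Pt0] at C_true max
  ratio_max <- c_true_max * (1 - c_obs) / (c_obs * (1 - c_true_max))
  if (ratio_max < 1 - 1e-9) {
    stop("Infeasible constraint set: c_star_max below the observed C*.",
         call. = FALSE)
  }
  pt0_min <- pt_mean / ((1 - c_obs) * ratio_max + c_obs)
  tibble::tibble(ratio_max = ratio_max,
                 pt1_max = ratio_max * pt0_min,
                 pt0_min = pt0_min)
}

#' Lower bound on the genetic fraction of MS among affected relatives
#'
#' Non-genetic MS is independent of family history, so its rate among
#' relatives of a proband cannot exceed the population bound; the genetic
#' fraction of concordant cases is therefore at least
#' `1 - p_mse_max / CR`.
#'
#' @param cr Observed recurrence (concordance) rate in the relative class.
#' @param p_mse_max Upper bound on the rate of non-genetic MS.
#' @return The bound, clipped to `[0, 1]`.
#' @examples
#' genetic_fraction_lower_bound(0.029) # 0.948, i.e. >95% of familial MS
#' @export
genetic_fraction_lower_bound <- function(cr, p_mse_max = 0.0015) {
  stopifnot(cr > 0, p_mse_max >= 0)
  pmin(1, pmax(0, 1 - p_mse_max / cr))
}

#' The full scalar derivation chain
#'
#' Runs the chain of derivations from the raw epidemiological constants to
#' the quantities the model consumes, one labelled row each: the HLA allele
#' frequency, the baseline-adjusted HLA-negative fraction `C*`, the
#' DZ/sibling ratio, the adjusted penetrance, the susceptible-fraction
#' point estimate and bound, the sibling HLA-sharing probability, the
#' Finland cohort bound, the pairwise twin concordance, and the HLA
#' allelic odds ratio.
#'
#' @param constants A list from [epi_constants()].
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @examples
#' derivation_chain()
#' @export
derivation_chain <- function(constants = epi_constants()) {
  k <- constants
  a_h <- allele_from_carrier(k$h)
  pen <- adjusted_penetrance(k$cr_mz, k$cr_dz, k$cr_s)
  pg <- pg_point_and_bound(k$p_ms, pen$cr_ig)
  tt <- twin_table_stats(k$twin_table, k$cr_s / k$cr_dz)
  tibble::tribble(
    ~quantity, ~value, ~unit,
    "hla_allele_freq", a_h, "frequency",
    "c_star", c_star(1 - k$h_m, k$h), "ratio",
    "dz_sib_ratio", pen$dz_sib_ratio, "ratio",
    "adjusted_penetrance", pen$cr_ig, "probability",
    "p_genetic_point", pg$point, "probability",
    "p_genetic_bound", pg$bound, "probability",
    "p_hla_sibling", p_hla_shared("sibling", a_h, TRUE), "probability",
    "finland_bound", finland_lower_bound(), "per 100,000",
    "pairwise_concordance_hla_pos", tt$pairwise[tt$proband_hla == "positive"],
    "probability",
    "allelic_odds_ratio", allelic_odds_ratio(k$a_hm, a_h), "ratio"
  )
}
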