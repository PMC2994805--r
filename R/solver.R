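#' HLA-negative fraction implied by the locus-count structure
#'
#' For a susceptible individual needing `n` of `x + 1` loci (the HLA locus
#' plus `x` non-HLA loci, with non-HLA susceptible-state frequency `h/r`),
#' the probability that none of the `n` involved loci is the HLA locus is
#' the falling-factorial ratio
#' \deqn{\prod_{k=0}^{n-1} \frac{x - k}{x + r - k}.}
#' Setting this equal to `C*` is the constraint that ties `x` to `(n, r)`.
#' The ratio is strictly increasing in `x`, strictly decreasing in `r`, and
#' equals 0 at `x = n - 1`.
#'
#' @param x Number of non-HLA loci (integer or real, `x >= n - 1`).
#'   Vectorised.
#' @param n Threshold number of loci (`n >= 0`; `n = 0` gives 1).
#' @param r Frequency-of-susceptibility ratio, positive.
#' @return The ratio, a value in `[0, 1)`.
#' @examples
#' hla_negative_fraction(5, n = 5, r = 1) # 1/6
#' @export
hla_negative_fraction <- function(x, n, r) {
  stopifnot(n >= 0, n == round(n), r > 0)
  if (n == 0) return(rep(1, length(x)))
  if (any(x < n - 1)) {
    stop("`x` must be at least n - 1.", call. = FALSE)
  }
  exp(lgamma(x + 1) - lgamma(x - n + 1) - lgamma(x + r + 1) +
        lgamma(x + r - n + 1))
}

#' Solve the locus-count constraint for x
#'
#' Finds the values of `x` (number of non-HLA susceptibility loci)
#' compatible with the observed HLA-negative fraction: the continuous root
#' of `hla_negative_fraction(x, n, r) = c_star`, and the integer range of
#' `x` in `[max(n, x_scan[1]), x_scan[2]]` whose ratio falls within
#' `c_star +/- tol` (inclusive bounds on the unrounded `c_star` by
#' default). Vectorised over `(n, r)` pairs.
#'
#' @param n Threshold locus count(s).
#' @param r Frequency ratio(s), recycled against `n`.
#' @param c_star Target HLA-negative fraction ratio (default
#'   `0.45 / 0.76`).
#' @param tol Half-width of the acceptance band around `c_star`.
#' @param x_scan Integer scan bounds, default `c(4, 2000)`.
#' @param inclusive Include the band endpoints (default `TRUE`).
#' @param rounded_c_star Round `c_star` to 2 decimals before solving, an
#'   alternative convention for table forensics.
#' @return A tibble with one row per `(n, r)`: `x_continuous` (real root,
#'   bisected to 1e-10), `x_low`, `x_high`, `n_solutions`, `feasible`.
#'   Empty integer ranges are reported with `feasible = FALSE` and `NA`
#'   bounds, not an error.
#' @examples
#' solve_x(n = 4, r = 2) # continuous root 15.9
#' @export
solve_x <- function(n, r, c_star = mssusmod::c_star(), tol = 0.05,
                    x_scan = c(4, 2000), inclusive = TRUE,
                    rounded_c_star = FALSE) {
  stopifnot(c_star > 0, c_star < 1, tol >= 0)
  cs <- if (rounded_c_star) round(c_star, 2) else c_star
  grid <- vctrs_recycle(n = n, r = r)
  purrr::pmap_dfr(grid, function(n, r) {
    root <- solve_x_root(n, r, cs)
    xs <- seq.int(max(n, x_scan[1]), x_scan[2])
    frac <- hla_negative_fraction(xs, n, r)
    keep <- if (inclusive) abs(frac - cs) <= tol else abs(frac - cs) < tol
    hit <- xs[keep]
    tibble::tibble(
      n = as.integer(n), r = r, c_star = cs, tol = tol,
      x_continuous = root,
      x_low = if (length(hit)) min(hit) else NA_integer_,
      x_high = if (length(hit)) max(hit) else NA_integer_,
      n_solutions = length(hit),
      feasible = length(hit) > 0
    )
  })
}

solve_x_root <- function(n, r, cs) {
  f <- function(x) hla_negative_fraction(x, n, r) - cs
  lo <- n - 1 + 1e-9
  hi <- max(n + 1, 4 * r * n)
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  tibble::as_tibble(lapply(args, rep_len, len))
}

#' Predicted population prevalence of MS
#'
#' Evaluates the model prevalence: summing over the individual's HLA state
#' `i` (Bernoulli with carrier probability `h`), the adjusted penetrance
#' `Pt_i*` times the probability that at least `n - i` of the `x` non-HLA
#' loci are in a susceptible state (binomial with success probability
#' `h/r`). Because all dominance modes share the same susceptible-state
#' frequency `h/r`, the three per-mode binomials collapse into one.
#'
#' @param params An [ms_model()] object.
#' @param x Number of non-HLA loci; defaults to `params$x`. Vectorised.
#' @return Predicted prevalence (probability), same length as `x`.
#' @examples
#' prevalence(ms_model(n = 1, r = 2, x = 2, pt_star = 1)) # 0.41146
#' @export
prevalence <- function(params, x = params$x) {
  stopifnot(inherits(params, "ms_model"))
  if (is.null(x)) stop("`x` is not set; supply it or solve with solve_x().",
                       call. = FALSE)
  pt <- c(params$pt0_star, params$pt1_star)
  out <- numeric(length(x))
  for (i in 0:1) {
    out <- out + pt[i + 1] * stats::dbinom(i, 1, params$h) *
      (1 - stats::pbinom(params$n - i - 1, x, params$f))
  }
  out
}

#' Limiting prevalence as the non-HLA state frequency vanishes
#'
#' Under the locus-count constraint, as `r` grows the number of loci `x`
#' grows in step and the binomial count of susceptible non-HLA loci tends
#' to a Poisson with mean
#' `lambda = h C*^{1/n} / (1 - C*^{1/n})`. The prevalence then tends to
#' `Pt* [h P(Pois >= n - 1) + (1 - h) P(Pois >= n)]`, the floor below
#' which no configuration with this threshold can push the predicted
#' prevalence (1.27% at `n = 5` with the default constants).
#'
#' @param n Threshold locus count.
#' @param h HLA carrier frequency.
#' @param c_star Target HLA-negative fraction ratio.
#' @param pt_star Adjusted penetrance.
#' @return The limiting prevalence (probability).
#' @examples
#' limit_prevalence(5) # 0.0127
#' @export
limit_prevalence <- function(n, h = 0.24, c_star = mssusmod::c_star(),
                             pt_star = 0.134) {
  stopifnot(n >= 1, c_star > 0, c_star < 1)
  root <- c_star^(1 / n)
  lambda <- h * root / (1 - root)
  pt_star * (h * stats::ppois(n - 2, lambda, lower.tail = FALSE) +
               (1 - h) * stats::ppois(n - 1, lambda, lower.tail = FALSE))
}

# recurrence risk ---------------------------------------------------------

#' Recurrence risk in a relative of an MS proband
#'
#' Probability that a relative of the stated class develops MS, given the
#' proband's HLA status. The proband's parents must jointly carry
#' susceptible states at `n` loci (`n - 1` non-HLA loci when the proband is
#' HLA-positive); those "necessarily present" loci are split over the
#' dominance classes proportionally to the locus composition
#' (largest-remainder rounding) and transmit with the conditional
#' probabilities `P_A1`/`P_A2`/`P_A3`, while the remaining loci carry the
#' baseline frequency `h/r`. The relative's HLA state follows `P_H` (or
#' `P_h1`), and the risk is the penetrance-weighted probability that the
#' relative's total count of susceptible loci reaches `n`, computed as the
#' complement of the convolution of the per-class binomials. Dizygotic
#' twins share sibling transmission genetics but use the unadjusted
#' penetrance (`Pt_i* * dz_sib_ratio`); monozygotic twins share the
#' genotype and return the unadjusted penetrance directly.
#'
#' @param params An [ms_model()] object.
#' @param relative Relative class (see [relative_classes()]).
#' @param proband_hla_positive Does the proband carry the HLA allele? (For
#'   conjugal offspring: does at least one affected parent carry it?)
#' @param x Number of non-HLA loci; defaults to `params$x`.
#' @return Recurrence probability.
#' @examples
#' p <- ms_model(n = 13, r = 4, x = 103,
#'               composition = c(dominant = 0.2, recessive = 0.8))
#' recurrence_risk(p, "sibling", proband_hla_positive = TRUE)
#' @export
recurrence_risk <- function(params, relative = "sibling",
                            proband_hla_positive = TRUE, x = params$x) {
  stopifnot(inherits(params, "ms_model"))
  relative <- match_relative(relative)
  if (is.null(x)) stop("`x` is not set; supply it or solve with solve_x().",
                       call. = FALSE)
  stopifnot(length(x) == 1, x >= params$n)
  n <- params$n
  pen_scale <- if (relative %in% c("mz_twin", "dz_twin")) params$dz_sib_ratio else 1
  pt <- pmin(1, c(params$pt0_star, params$pt1_star) * pen_scale)
  if (relative == "mz_twin") {
    # identical genotype: susceptible with certainty, unadjusted penetrance
    return(pt[as.integer(proband_hla_positive) + 1])
  }

  x_split <- partition_counts(x, params$composition)
  necessary <- if (proband_hla_positive) n - 1L else n
  if (relative == "conjugal_offspring") {
    # both parents are probands, so each parent's necessary combination is
    # present: the child is conditioned on ~2x the usual locus set (capped
    # at x), each locus transmitting with the conjugal mixture forms
    necessary <- min(2L * necessary, x)
  }
  n_split <- partition_counts(necessary, x_split)
  if (any(n_split > x_split)) {
    stop("Infeasible partition: more necessary loci than loci of that mode.",
         call. = FALSE)
  }

  a <- c(state_allele_freq("dominant", params$f),
         state_allele_freq("recessive", params$f),
         state_allele_freq("mixed", params$f))
  p_share <- vapply(seq_along(.modes), function(k) {
    p_state_shared(relative, .modes[k], a[k], n = n, x = x)
  }, numeric(1))

  cond_pmf <- 1
  for (k in seq_along(n_split)) {
    if (n_split[k] == 0) next
    cond_pmf <- convolve_pmf(cond_pmf,
                             stats::dbinom(0:n_split[k], n_split[k], p_share[k]))
  }
  x_free <- x - sum(n_split)

  p_hla <- p_hla_shared(relative, params$a_h, proband_hla_positive,
                        params$conjugal_ph_corrected)
  risk <- 0
  d <- seq_along(cond_pmf) - 1
  for (i in 0:1) {
    p_i <- if (i == 1) p_hla else 1 - p_hla
    # P(relative's total susceptible-locus count < n | HLA state i)
    p_below <- sum(cond_pmf * stats::pbinom(n - 1 - i - d, x_free, params$f))
    risk <- risk + pt[i + 1] * p_i * (1 - p_below)
  }
  risk
}

convolve_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Expected recurrence risk, averaged over the proband's HLA status
#'
#' Weights the HLA-positive- and HLA-negative-proband recurrence risks by
#' the case HLA distribution: `E(CR) = (1 - C) P(MS_H+) + C P(MS_H-)`
#' (valid when `Pt1 = Pt0`). For conjugal offspring both parents are
#' probands, so the HLA-negative branch (neither parent carries) has
#' weight `C^2`.
#'
#' @inheritParams recurrence_risk
#' @return Expected recurrence probability.
#' @export
expected_recurrence <- function(params, relative = "sibling",
                                x = params$x) {
  relative <- match_relative(relative)
  w_neg <- if (relative == "conjugal_offspring") params$C^2 else params$C
  pos <- recurrence_risk(params, relative, TRUE, x)
  neg <- recurrence_risk(params, relative, FALSE, x)
  (1 - w_neg) * pos + w_neg * neg
}

#' Model predictions for all relative classes at given locus counts
#'
#' @param params An [ms_model()] object.
#' @param x Vector of non-HLA locus counts to evaluate (e.g. the low and
#'   high ends of a solved range).
#' @param relatives Relative classes to include.
#' @return A tibble, one row per `(x, outcome)`, with the predicted rate
#'   and its HLA-positive/HLA-negative proband components (`NA` for
#'   prevalence).
#' @export
predict_rates <- function(params, x = params$x,
                          relatives = c("sibling", "parent_child",
                                        "conjugal_offspring", "aunt_uncle",
                                        "first_cousin")) {
  stopifnot(inherits(params, "ms_model"))
  purrr::map_dfr(x, function(xi) {
    rel_rows <- purrr::map_dfr(relatives, function(rel) {
      tibble::tibble(
        outcome = rel,
        rate = expected_recurrence(params, rel, x = xi),
        rate_hla_pos = recurrence_risk(params, rel, TRUE, x = xi),
        rate_hla_neg = recurrence_risk(params, rel, FALSE, x = xi)
      )
    })
    dplyr::bind_rows(
      tibble::tibble(outcome = "prevalence",
                     rate = prevalence(params, xi),
                     rate_hla_pos = NA_real_, rate_hla_neg = NA_real_),
      rel_rows
    ) |>
      dplyr::mutate(x = xi, .before = 1)
  })
}
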