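#' Allele frequency from carrier (dominant) frequency
#'
#' Under Hardy-Weinberg equilibrium the probability of carrying at least one
#' copy of an allele with frequency `a` is `2a - a^2`. This inverts that
#' relation, returning the root of the quadratic that lies in `[0, 1]`.
#'
#' @param h Carrier probability (probability of at least one copy), in
#'   `[0, 1]`. Vectorised.
#' @return Allele frequency `a = 1 - sqrt(1 - h)`.
#' @examples
#' allele_from_carrier(0.24) # 0.128, the HLA DRB1*1501 allele frequency
#' @seealso [carrier_from_allele()]
#' @export
allele_from_carrier <- function(h) {
  check_prob(h, "h")
  1 - sqrt(1 - h)
}

#' @rdname allele_from_carrier
#' @param a Allele frequency in `[0, 1]`. Vectorised.
#' @export
carrier_from_allele <- function(a) {
  check_prob(a, "a")
  2 * a - a^2
}

#' Allele frequency implied by a susceptible-state frequency
#'
#' At a non-HLA locus the "frequency of susceptibility" `f` is the
#' probability that a random individual is in a susceptible allelic state.
#' Depending on the dominance mode of the locus this implies an allele
#' frequency: dominant `a = 1 - sqrt(1 - f)` (state = at least one copy),
#' recessive `a = sqrt(f)` (state = homozygous), mixed `a = f / 2` (one
#' dominant-acting and one recessive-acting allele, each at frequency `a`,
#' with combined state frequency `2a`).
#'
#' @param mode One of `"dominant"`, `"recessive"`, `"mixed"`.
#' @param f Susceptible-state frequency in `[0, 1]`. Vectorised.
#' @return Allele frequency in `[0, 1]`.
#' @examples
#' state_allele_freq("recessive", 0.12)
#' @export
state_allele_freq <- function(mode, f) {
  mode <- match_mode(mode)
  check_prob(f, "f")
  switch(mode,
    dominant  = 1 - sqrt(1 - f),
    recessive = sqrt(f),
    mixed     = f / 2
  )
}

#' @rdname state_allele_freq
#' @param a Allele frequency in `[0, 1]`.
#' @return `state_freq()` returns the susceptible-state frequency implied by
#'   an allele frequency (the inverse map).
#' @export
state_freq <- function(mode, a) {
  mode <- match_mode(mode)
  check_prob(a, "a")
  switch(mode,
    dominant  = 2 * a - a^2,
    recessive = a^2,
    mixed     = 2 * a
  )
}

#' HLA-negative fraction among susceptibles, baseline-adjusted
#'
#' Converts the fraction `C` of susceptible individuals lacking the HLA
#' allele into `C* = C / (1 - h)`, removing the baseline probability of
#' non-carriage so that `C*` depends only on the locus-count structure.
#'
#' @param C Fraction of susceptible (case) individuals without the HLA
#'   allele, in `[0, 1]`.
#' @param h HLA carrier frequency in the general population, in `[0, 1)`.
#' @return `C / (1 - h)`, unrounded (0.5921 for the default constants
#'   `C = 0.45`, `h = 0.24`).
#' @export
c_star <- function(C = 0.45, h = 0.24) {
  check_prob(C, "C")
  check_prob(h, "h")
  if (any(h >= 1)) {
    stop("`h` = 1 gives an invalid parameterization (division by zero).",
         call. = FALSE)
  }
  C / (1 - h)
}

# relative classes and degree-of-sharing metadata -------------------------

#' Relative classes recognised by the model
#'
#' @return A tibble with one row per relative class: the class name, the
#'   coefficient of genetic sharing with the proband, and the degree label.
#' @export
relative_classes <- function() {
  tibble::tibble(
    relative = c("mz_twin", "dz_twin", "sibling", "parent_child",
                 "aunt_uncle", "first_cousin", "conjugal_offspring"),
    sharing  = c(1, 0.5, 0.5, 0.5, 0.25, 0.125, NA_real_),
    degree   = c("identical", "first", "first", "first",
                 "second", "third", "offspring of two probands")
  )
}

.relatives <- c("mz_twin", "dz_twin", "sibling", "parent_child",
                "aunt_uncle", "first_cousin", "conjugal_offspring")
.modes <- c("dominant", "recessive", "mixed")

match_mode <- function(mode) match.arg(mode, .modes)
match_relative <- function(relative) match.arg(relative, .relatives)

# transmission probabilities ----------------------------------------------

#' Probability a relative carries the HLA susceptibility allele
#'
#' Closed forms for the probability that a relative of an MS proband carries
#' at least one copy of the HLA allele, conditional on the proband's own
#' HLA status. For an HLA-positive proband this is the quantity `P_H`
#' (62.0% for siblings at `a = 0.128`); for an HLA-negative proband it is
#' `P_h1`. The forms are the printed approximations: `P_H` treats the
#' proband as having a single transmitting parent and so slightly
#' mis-states the exact conditional probability (see
#' [p_hla_shared_exact()]); `P_h1` for siblings is exact.
#'
#' @param relative Relative class (see [relative_classes()]); `mz_twin`
#'   shares the genotype identically and returns 1 or 0.
#' @param a HLA allele frequency in `[0, 1]`.
#' @param proband_positive Does the proband carry the allele?
#' @param conjugal_ph_corrected For `conjugal_offspring` only: the printed
#'   form is `0.5 (1 + 2a + a^2)` where every analogous formula has `-a^2`;
#'   set `TRUE` to use the sign-corrected form.
#' @return A probability.
#' @export
p_hla_shared <- function(relative, a, proband_positive = TRUE,
                         conjugal_ph_corrected = FALSE) {
  relative <- match_relative(relative)
  check_prob(a, "a")
  if (relative == "mz_twin") {
    return(if (proband_positive) rep(1, length(a)) else rep(0, length(a)))
  }
  if (proband_positive) {
    switch(relative,
      dz_twin      = ,
      sibling      = ,
      parent_child = 0.5 * (1 + 2 * a - a^2),
      aunt_uncle   = 0.25 * (1 + 6 * a - 3 * a^2),
      first_cousin = 0.125 * (1 + 14 * a - 7 * a^2),
      conjugal_offspring =
        if (conjugal_ph_corrected) 0.5 * (1 + 2 * a - a^2)
        else 0.5 * (1 + 2 * a + a^2)
    )
  } else {
    switch(relative,
      dz_twin      = ,
      sibling      = ,
      parent_child = ,
      conjugal_offspring = a - 0.25 * a^2,
      aunt_uncle   = 1.5 * a - 0.56 * a^2,
      first_cousin = 1.75 * a - 0.77 * a^2
    )
  }
}

#' Probability a relative shares a susceptible state at a conditioned locus
#'
#' For a locus known to be in a susceptible state in (at least one of) the
#' proband's parents, returns the probability that the relative is also in a
#' susceptible state there, by relative class and dominance mode. These are
#' the printed closed forms; the mixed mode is the blend
#' `P_A3 = (1 - a/2) P_A1 + (a/2) P_A2` where `a/2` is the probability that
#' the conditioned state was the recessive one. `dz_twin` and `sibling`
#' share identical transmission genetics (the dizygotic difference enters
#' through penetrance, not transmission). `conjugal_offspring` requires
#' `n` and `x`: with two affected parents the chance that both are in a
#' susceptible state at a given locus is `(n/x)^2`, and the printed mixture
#' weighs a both-parents branch against the one-parent branch.
#'
#' @inheritParams p_hla_shared
#' @param mode Dominance mode of the locus.
#' @param n,x Threshold and total non-HLA locus count, used only for
#'   `conjugal_offspring`.
#' @return A probability, `P_A1`, `P_A2` or `P_A3` for the requested class.
#' @export
p_state_shared <- function(relative, mode, a, n = NULL, x = NULL) {
  relative <- match_relative(relative)
  mode <- match_mode(mode)
  check_prob(a, "a")
  if (relative == "mz_twin") return(rep(1, length(a)))
  if (relative == "conjugal_offspring") {
    return(p_state_shared_conjugal(mode, a, n, x))
  }
  pa1 <- switch(relative,
    dz_twin = , sibling = , parent_child = 0.5 * (1 + 2 * a - a^2),
    aunt_uncle   = 0.25 * (1 + 6 * a - 3 * a^2),
    first_cousin = 0.125 * (1 + 14 * a - 7 * a^2)
  )
  if (mode == "dominant") return(pa1)
  pa2 <- switch(relative,
    dz_twin = , sibling = 0.25 * (1 + a)^2,
    parent_child = a,
    aunt_uncle   = 0.0625 * (1 + 3 * a)^2,
    first_cousin = 0.015625 * (1 + 7 * a)^2
  )
  if (mode == "recessive") return(pa2)
  (1 - a / 2) * pa1 + (a / 2) * pa2
}

p_state_shared_conjugal <- function(mode, a, n, x) {
  if (is.null(n) || is.null(x)) {
    stop("conjugal_offspring transmission needs `n` and `x`.", call. = FALSE)
  }
  if (any(x <= 0)) stop("`x` must be positive.", call. = FALSE)
  if (any(n < 1) || any(n > x)) {
    stop("conjugal transmission requires 1 <= n <= x.", call. = FALSE)
  }
  w <- (n / x)^2
  pa1 <- (1 - w) * 0.5 * (1 + 2 * a - a^2) +
    w * (0.75 + 0.5 * a - 0.25 * a^2)
  if (mode == "dominant") return(pa1)
  # one-parent branch keeps the sibling-strength form; with weight w both
  # parents are in the state and a recessive child is homozygous for sure
  pa2 <- (1 - w) * 0.25 * (1 + a)^2 + w
  if (mode == "recessive") return(pa2)
  (1 - a / 2) * pa1 + (a / 2) * pa2
}

#' Full transmission-probability set for a relative class
#'
#' Assembles the conditional sharing probabilities used by the recurrence
#' equations into one row: `p_H` (relative carries HLA given HLA-positive
#' proband), `p_h1` (given HLA-negative proband), `p_A1`/`p_A2`/`p_A3`
#' (relative in a susceptible state at a conditioned dominant / recessive /
#' mixed locus) and the unconditional baseline `f = h/r`.
#'
#' @inheritParams p_hla_shared
#' @param a_h HLA allele frequency.
#' @param f Susceptible-state frequency at non-HLA loci (`h/r`).
#' @param n,x Passed through for `conjugal_offspring`.
#' @return A tibble with columns `relative`, `p_H`, `p_h1`, `p_A1`, `p_A2`,
#'   `p_A3`, `p_baseline`.
#' @examples
#' transmission_probs("sibling", a_h = allele_from_carrier(0.24), f = 0.12)
#' @export
transmission_probs <- function(relative, a_h, f, n = NULL, x = NULL,
                               conjugal_ph_corrected = FALSE) {
  relative <- match_relative(relative)
  tibble::tibble(
    relative = relative,
    p_H  = p_hla_shared(relative, a_h, TRUE, conjugal_ph_corrected),
    p_h1 = p_hla_shared(relative, a_h, FALSE),
    p_A1 = p_state_shared(relative, "dominant",
                          state_allele_freq("dominant", f), n, x),
    p_A2 = p_state_shared(relative, "recessive",
                          state_allele_freq("recessive", f), n, x),
    p_A3 = p_state_shared(relative, "mixed",
                          state_allele_freq("mixed", f), n, x),
    p_baseline = f
  )
}

# exact-enumeration diagnostics -------------------------------------------

#' Exact sibling HLA-sharing probability by enumeration
#'
#' The printed sibling form `P_H = 0.5 (1 + 2a - a^2)` is derived assuming a
#' single transmitting parent; the exact conditional probability that a
#' sibling carries the allele given the proband carries at least one copy
#' differs slightly. This computes the exact value by enumerating all
#' parental diplotypes and both siblings' transmissions, as a diagnostic; it
#' is never substituted for the printed form.
#'
#' @param a Allele frequency (scalar).
#' @param proband_positive Condition on the proband carrying (`TRUE`) or
#'   lacking (`FALSE`) the allele.
#' @return The exact conditional probability.
#' @export
p_hla_shared_exact <- function(a, proband_positive = TRUE) {
  stopifnot(length(a) == 1)
  check_prob(a, "a")
  # parental alleles: mother (m1, m2), father (f1, f2), each Bernoulli(a);
  # each child draws one maternal and one paternal slot independently.
  g <- expand.grid(m1 = 0:1, m2 = 0:1, f1 = 0:1, f2 = 0:1,
                   pm = 1:2, pf = 1:2, sm = 1:2, sf = 1:2)
  al <- function(x) a^x * (1 - a)^(1 - x)
  w <- al(g$m1) * al(g$m2) * al(g$f1) * al(g$f2) * 0.25 * 0.25
  mom <- cbind(g$m1, g$m2); dad <- cbind(g$f1, g$f2)
  pro <- mom[cbind(seq_len(nrow(g)), g$pm)] + dad[cbind(seq_len(nrow(g)), g$pf)]
  sib <- mom[cbind(seq_len(nrow(g)), g$sm)] + dad[cbind(seq_len(nrow(g)), g$sf)]
  keep <- if (proband_positive) pro >= 1 else pro == 0
  sum(w[keep & sib >= 1]) / sum(w[keep])
}

check_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must lie in [0, 1].", name), call. = FALSE)
  }
  invisible(p)
}
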