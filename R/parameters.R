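#' Specify one configuration of the multilocus threshold model
#'
#' Bundles the epidemiological constants and the free model choices into a
#' validated parameter object. Susceptibility is the "n-of-x" threshold:
#' an individual is genetically susceptible iff at least `n` of the `x + 1`
#' susceptibility loci (the HLA locus plus `x` non-HLA loci) are in a
#' susceptible allelic state. The mean susceptible-state frequency at
#' non-HLA loci is tied to the HLA carrier frequency by `f = h / r`.
#'
#' @param n Number of loci required in a susceptible state (threshold).
#' @param r Ratio of the HLA carrier frequency to the mean non-HLA
#'   susceptible-state frequency (`r = h / f`), positive.
#' @param x Total number of non-HLA susceptibility loci. If `NULL`, left
#'   unset; [solve_x()] finds the values compatible with `C*`.
#' @param h HLA carrier frequency in the general population.
#' @param h_m HLA carrier frequency among MS cases.
#' @param composition Named fractions of `dominant`, `recessive` and
#'   `mixed` loci among the `x` non-HLA loci; must sum to 1.
#' @param pt_star Mean adjusted penetrance Pt* (monozygotic concordance
#'   down-weighted for the shared intrauterine environment).
#' @param pt1_star,pt0_star Adjusted penetrances for HLA-positive and
#'   HLA-negative susceptible genotypes; default to `pt_star`.
#' @param C Fraction of susceptible individuals without the HLA allele;
#'   defaults to the observed case fraction `1 - h_m` (valid when
#'   `pt1 = pt0`).
#' @param p_ms_target Target population prevalence of MS.
#' @param dz_sib_ratio Dizygotic-twin to sibling concordance ratio
#'   (5.4/2.9); inflates penetrance for `dz_twin` recurrence.
#' @param conjugal_ph_corrected Use the sign-corrected conjugal `P_H`.
#' @return An object of class `ms_model`: a list with the supplied values
#'   plus derived quantities `a_h` (HLA allele frequency), `f = h/r` and
#'   `c_star = C / (1 - h)`.
#' @examples
#' ms_model(n = 13, r = 4, composition = c(dominant = 0.2, recessive = 0.8))
#' @export
ms_model <- function(n, r, x = NULL, h = 0.24, h_m = 0.55,
                     composition = c(dominant = 0, recessive = 1, mixed = 0),
                     pt_star = 0.134, pt1_star = pt_star, pt0_star = pt_star,
                     C = 1 - h_m, p_ms_target = 0.0015,
                     dz_sib_ratio = 5.4 / 2.9,
                     conjugal_ph_corrected = FALSE) {
  stopifnot(length(n) == 1, n >= 1, n == round(n), length(r) == 1, r > 0)
  check_prob(h, "h"); check_prob(h_m, "h_m"); check_prob(C, "C")
  check_prob(pt1_star, "pt1_star"); check_prob(pt0_star, "pt0_star")
  composition <- normalize_composition(composition)
  f <- h / r
  if (f > 1) {
    stop("`h / r` exceeds 1: invalid susceptible-state frequency.",
         call. = FALSE)
  }
  params <- structure(list(
    n = as.integer(n), r = r, x = if (is.null(x)) NULL else as.integer(x),
    h = h, h_m = h_m, composition = composition,
    pt1_star = pt1_star, pt0_star = pt0_star,
    C = C, p_ms_target = p_ms_target, dz_sib_ratio = dz_sib_ratio,
    conjugal_ph_corrected = conjugal_ph_corrected,
    a_h = allele_from_carrier(h), f = f, c_star = c_star(C, h)
  ), class = "ms_model")
  params
}

normalize_composition <- function(composition) {
  full <- c(dominant = 0, recessive = 0, mixed = 0)
  if (is.null(names(composition)) || !all(names(composition) %in% names(full))) {
    stop("`composition` must be named with dominant/recessive/mixed.",
         call. = FALSE)
  }
  full[names(composition)] <- composition
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8) {
    stop("`composition` fractions must be non-negative and sum to 1.",
         call. = FALSE)
  }
  full / sum(full)
}

#' @export
print.ms_model <- function(x, ...) {
  comp <- paste(sprintf("%s %.0f%%", names(x$composition),
                        100 * x$composition), collapse = ", ")
  cat("<ms_model> n-of-x threshold susceptibility model\n")
  cat(sprintf("  threshold n = %d, frequency ratio r = %g (f = h/r = %.4g)\n",
              x$n, x$r, x$f))
  cat(sprintf("  x = %s non-HLA loci (%s)\n",
              if (is.null(x$x)) "unsolved" else x$x, comp))
  cat(sprintf("  h = %.3g (a_h = %.4g), C = %.3g, C* = %.4g\n",
              x$h, x$a_h, x$C, x$c_star))
  cat(sprintf("  penetrance Pt1* = %.3g, Pt0* = %.3g (DZ/sib ratio %.3g)\n",
              x$pt1_star, x$pt0_star, x$dz_sib_ratio))
  invisible(x)
}

#' Partition integer counts proportionally (largest-remainder rounding)
#'
#' Splits an integer total over the dominance classes in proportion to the
#' given weights, assigning leftover units to the largest fractional
#' remainders (ties to the earlier class). Used both to split the `x`
#' non-HLA loci into `(x1, x2, x3)` and to split the `n` (or `n - 1`) loci
#' "necessarily present" in the proband's parents into `(n1, n2, n3)`
#' proportionally to `(x1, x2, x3)`.
#'
#' @param total Non-negative integer to split.
#' @param weights Non-negative weights (need not sum to 1).
#' @return Integer vector of the same length as `weights`, summing to
#'   `total`.
#' @export
partition_counts <- function(total, weights) {
  stopifnot(total >= 0, total == round(total), all(weights >= 0),
            sum(weights) > 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Read a model configuration from YAML or JSON
#'
#' Keys mirror the model symbols: `n`, `r`, `x`, `h`, `h_m`, `composition`
#' (named list), `pt_star`, `pt1_star`, `pt0_star`, `C`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [ms_model()] object.
#' @export
ms_model_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$composition)) cfg$composition <- unlist(cfg$composition)
  do.call(ms_model, cfg)
}
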