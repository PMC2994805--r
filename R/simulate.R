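# Forward Mendelian simulator: the brute-force oracle for the closed forms.
# Genotypes are pairs of allele-code matrices (families x loci); codes are
# 0 = non-susceptibility allele, 1 = susceptibility allele (the dominant-
# acting allele at mixed loci), 2 = the recessive-acting allele at mixed
# loci. Founders are drawn in Hardy-Weinberg proportions; children draw one
# random allele slot from each parent per locus, independently across loci
# (unlinked autosomal loci).

#' Locus table for a model configuration
#'
#' @param params An [ms_model()] object.
#' @param x Number of non-HLA loci; defaults to `params$x`.
#' @return A tibble, one row per locus: `locus`, `is_hla`, `mode`,
#'   `allele_freq`. The HLA locus is dominant with allele frequency `a_h`;
#'   the `x` non-HLA loci are split over the dominance composition by
#'   largest-remainder rounding, each with the allele frequency implied by
#'   the shared state frequency `h/r`.
#' @export
locus_table <- function(params, x = params$x) {
  stopifnot(inherits(params, "ms_model"))
  if (is.null(x)) stop("`x` is not set.", call. = FALSE)
  counts <- partition_counts(x, params$composition)
  modes <- rep(.modes, counts)
  tibble::tibble(
    locus = seq_len(x + 1),
    is_hla = c(TRUE, rep(FALSE, x)),
    mode = c("dominant", modes),
    allele_freq = c(params$a_h,
                    vapply(modes, function(m) state_allele_freq(m, params$f),
                           numeric(1), USE.NAMES = FALSE))
  )
}

draw_founder <- function(n, loci) {
  draw_slot <- function() {
    cols <- lapply(seq_len(nrow(loci)), function(j) {
      a <- loci$allele_freq[j]
      if (loci$mode[j] == "mixed") {
        sample.int(3L, n, replace = TRUE, prob = c(1 - 2 * a, a, a)) - 1L
      } else {
        as.integer(stats::runif(n) < a)
      }
    })
    matrix(unlist(cols), nrow = n)
  }
  list(a1 = draw_slot(), a2 = draw_slot())
}

child_of <- function(mother, father) {
  pick <- function(par) {
    m <- matrix(stats::runif(length(par$a1)) < 0.5, nrow(par$a1))
    out <- par$a1
    out[m] <- par$a2[m]
    out
  }
  list(a1 = pick(mother), a2 = pick(father))
}

locus_state <- function(geno, loci) {
  st <- matrix(FALSE, nrow(geno$a1), nrow(loci))
  for (j in seq_len(nrow(loci))) {
    g1 <- geno$a1[, j]; g2 <- geno$a2[, j]
    st[, j] <- switch(loci$mode[j],
      dominant  = g1 == 1L | g2 == 1L,
      recessive = g1 == 1L & g2 == 1L,
      mixed     = g1 == 1L | g2 == 1L | (g1 == 2L & g2 == 2L)
    )
  }
  st
}

summarise_member <- function(geno, loci, params, n_thr, pen_scale = 1) {
  st <- locus_state(geno, loci)
  hla_copies <- as.integer(geno$a1[, 1] == 1L) + as.integer(geno$a2[, 1] == 1L)
  n_susc <- rowSums(st)
  susceptible <- n_susc >= n_thr
  pt <- ifelse(hla_copies >= 1, params$pt1_star, params$pt0_star) * pen_scale
  affected <- susceptible & stats::runif(length(n_susc)) < pmin(1, pt)
  tibble::tibble(
    hla_copies = hla_copies,
    hla_carrier = hla_copies >= 1,
    n_susceptible = as.integer(n_susc),
    susceptible = susceptible,
    affected = affected
  )
}

#' Simulate a cohort of unrelated individuals
#'
#' Draws Hardy-Weinberg genotypes at the `x + 1` loci, derives the
#' susceptible-state count, the threshold susceptibility flag and the
#' Bernoulli affection status (penetrance `Pt1*`/`Pt0*` by HLA carriage).
#'
#' @param params An [ms_model()] object.
#' @param n Number of individuals.
#' @param x Number of non-HLA loci; defaults to `params$x`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A tibble, one row per individual: `id`, `hla_copies`,
#'   `hla_carrier`, `n_susceptible`, `susceptible`, `affected`.
#' @examples
#' p <- ms_model(n = 1, r = 2, x = 2, pt_star = 1)
#' mean(simulate_cohort(p, 2e4, seed = 1)$affected) # ~ prevalence(p)
#' @export
simulate_cohort <- function(params, n, x = params$x, seed = NULL) {
  stopifnot(inherits(params, "ms_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  loci <- locus_table(params, x)
  geno <- draw_founder(n, loci)
  out <- summarise_member(geno, loci, params, params$n)
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

pedigree_structures <- list(
  mz_twin            = c("mother", "father", "proband", "relative"),
  dz_twin            = c("mother", "father", "proband", "relative"),
  sibling            = c("mother", "father", "proband", "relative"),
  parent_child       = c("proband", "spouse", "relative"),
  aunt_uncle         = c("grandmother", "grandfather", "parent", "relative",
                         "spouse", "proband"),
  first_cousin       = c("grandmother", "grandfather", "parent1", "parent2",
                         "spouse1", "spouse2", "proband", "relative"),
  conjugal_offspring = c("proband", "proband2", "relative")
)

simulate_family_batch <- function(n, loci, params, structure,
                                  dz_unadjusted = TRUE) {
  members <- list()
  twin_scale <- if (dz_unadjusted) params$dz_sib_ratio else 1
  if (structure %in% c("mz_twin", "dz_twin", "sibling")) {
    members$mother <- draw_founder(n, loci)
    members$father <- draw_founder(n, loci)
    members$proband <- child_of(members$mother, members$father)
    members$relative <- if (structure == "mz_twin") members$proband else
      child_of(members$mother, members$father)
  } else if (structure == "parent_child") {
    members$proband <- draw_founder(n, loci)
    members$spouse <- draw_founder(n, loci)
    members$relative <- child_of(members$proband, members$spouse)
  } else if (structure == "aunt_uncle") {
    members$grandmother <- draw_founder(n, loci)
    members$grandfather <- draw_founder(n, loci)
    members$parent <- child_of(members$grandmother, members$grandfather)
    members$relative <- child_of(members$grandmother, members$grandfather)
    members$spouse <- draw_founder(n, loci)
    members$proband <- child_of(members$parent, members$spouse)
  } else if (structure == "first_cousin") {
    members$grandmother <- draw_founder(n, loci)
    members$grandfather <- draw_founder(n, loci)
    members$parent1 <- child_of(members$grandmother, members$grandfather)
    members$parent2 <- child_of(members$grandmother, members$grandfather)
    members$spouse1 <- draw_founder(n, loci)
    members$spouse2 <- draw_founder(n, loci)
    members$proband <- child_of(members$parent1, members$spouse1)
    members$relative <- child_of(members$parent2, members$spouse2)
  } else if (structure == "conjugal_offspring") {
    members$proband <- draw_founder(n, loci)
    members$proband2 <- draw_founder(n, loci)
    members$relative <- child_of(members$proband, members$proband2)
  } else {
    stop("Unsupported pedigree structure: ", structure, call. = FALSE)
  }
  rows <- purrr::imap(members, function(geno, role) {
    scale <- if (role == "relative" &&
                 structure %in% c("mz_twin", "dz_twin")) twin_scale else 1
    summarise_member(geno, loci, params, params$n, scale) |>
      dplyr::mutate(role = role, family = seq_len(n), .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Simulate structured families under the threshold model
#'
#' Forward-simulates pedigrees of the requested structure (founders in
#' Hardy-Weinberg proportions, Mendelian transmission at unlinked loci),
#' optionally conditioned by rejection sampling on the proband being
#' affected (both parents, for conjugal offspring). The relative of
#' interest always carries the role `"relative"`. Dizygotic (and
#' monozygotic) twin relatives use the unadjusted penetrance
#' `Pt_i* * dz_sib_ratio` when `dz_unadjusted = TRUE`: the intrauterine
#' effect enters through penetrance, not through transmission genetics.
#'
#' @param params An [ms_model()] object.
#' @param n_families Families to return (after conditioning).
#' @param structure One of the relative classes in [relative_classes()].
#' @param x Number of non-HLA loci; defaults to `params$x`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param condition `"proband_affected"` (default) or `"none"`.
#' @param dz_unadjusted Use the unadjusted penetrance for twin relatives.
#' @param batch_size Families drawn per rejection batch.
#' @return A tibble, one row per family member, with the per-individual
#'   summary columns of [simulate_cohort()] plus `family` and `role`.
#' @export
simulate_pedigrees <- function(params, n_families, structure = "sibling",
                               x = params$x, seed = NULL,
                               condition = c("proband_affected", "none"),
                               dz_unadjusted = TRUE,
                               batch_size = NULL) {
  stopifnot(inherits(params, "ms_model"), n_families >= 1)
  structure <- match_relative(structure)
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  loci <- locus_table(params, x)
  if (is.null(batch_size)) {
    batch_size <- if (condition == "none") n_families else
      max(2e4, 2 * n_families)
  }
  kept <- list()
  n_kept <- 0
  n_drawn <- 0
  repeat {
    batch <- simulate_family_batch(batch_size, loci, params, structure,
                                   dz_unadjusted)
    n_drawn <- n_drawn + batch_size
    if (condition == "proband_affected") {
      ok <- batch |>
        dplyr::filter(.data$role %in% c("proband", "proband2")) |>
        dplyr::group_by(.data$family) |>
        dplyr::summarise(keep = all(.data$affected))
      keep_ids <- ok$family[ok$keep]
      batch <- dplyr::filter(batch, .data$family %in% keep_ids)
    }
    found <- length(unique(batch$family))
    if (found > 0) {
      batch$family <- n_kept + match(batch$family, unique(batch$family))
      kept[[length(kept) + 1]] <- batch
      n_kept <- n_kept + found
    }
    if (n_kept >= n_families) break
    if (n_drawn >= 100 * batch_size || n_drawn >= 2e7) {
      if (n_kept / n_drawn < 1e-4) {
        warning("Rejection acceptance below 1e-4; returning ", n_kept,
                " families.", call. = FALSE)
      } else {
        warning("Draw cap reached; returning ", n_kept, " families.",
                call. = FALSE)
      }
      break
    }
  }
  out <- dplyr::bind_rows(kept)
  dplyr::filter(out, .data$family <= n_families)
}

#' Empirical summaries of simulated data
#'
#' For a cohort (no `role` column): prevalence, HLA carrier frequency
#' among cases, the HLA-negative case fraction, and the allelic odds ratio
#' at the HLA locus (cases vs unaffected). For pedigrees: the recurrence
#' rate in the `"relative"` role with an exact binomial confidence
#' interval, overall and split by the proband's HLA status.
#'
#' @param records A tibble from [simulate_cohort()] or
#'   [simulate_pedigrees()].
#' @return A tibble of summary statistics; empty strata give `NA` with
#'   their count reported.
#' @export
empirical_stats <- function(records) {
  if (!"role" %in% names(records)) {
    cases <- dplyr::filter(records, .data$affected)
    controls <- dplyr::filter(records, !.data$affected)
    a_case <- if (nrow(cases)) mean(cases$hla_copies) / 2 else NA_real_
    a_ctrl <- if (nrow(controls)) mean(controls$hla_copies) / 2 else NA_real_
    return(tibble::tibble(
      n = nrow(records),
      prevalence = mean(records$affected),
      n_cases = nrow(cases),
      h_m_hat = if (nrow(cases)) mean(cases$hla_carrier) else NA_real_,
      c_hat = if (nrow(cases)) 1 - mean(cases$hla_carrier) else NA_real_,
      allelic_or = if (nrow(cases) && a_case %in% c(0, 1)) NA_real_ else
        if (nrow(cases)) allelic_odds_ratio(a_case, a_ctrl) else NA_real_
    ))
  }
  pro <- records |>
    dplyr::filter(.data$role == "proband") |>
    dplyr::select("family", proband_hla = "hla_carrier")
  rel <- records |>
    dplyr::filter(.data$role == "relative") |>
    dplyr::left_join(pro, by = "family")
  strata <- list(all = rel,
                 proband_hla_pos = dplyr::filter(rel, .data$proband_hla),
                 proband_hla_neg = dplyr::filter(rel, !.data$proband_hla))
  purrr::imap_dfr(strata, function(d, nm) {
    k <- sum(d$affected); n <- nrow(d)
    ci <- if (n > 0) stats::binom.test(k, n)$conf.int else c(NA_real_, NA_real_)
    tibble::tibble(stratum = nm, n_families = n,
                   recurrence = if (n > 0) k / n else NA_real_,
                   ci_low = ci[1], ci_high = ci[2])
  })
}

#' Realised identity-by-descent sharing between proband and relative
#'
#' Simulates a single neutral locus whose founder alleles carry unique
#' labels, and returns the mean fraction of the proband-relative allele
#' pairs that are identical by descent: 0.5 for siblings, 0.25 for
#' aunt/uncle, 0.125 for first cousins.
#'
#' @param structure A pedigree structure.
#' @param n_families Number of families.
#' @param seed Integer seed.
#' @return Mean IBD sharing fraction.
#' @export
ibd_sharing <- function(structure, n_families, seed = NULL) {
  structure <- match_relative(structure)
  if (!is.null(seed)) set.seed(seed)
  # one pseudo-locus; founder draw replaced with unique labels
  label_founder <- local({
    counter <- 0
    function(n) {
      out <- list(a1 = matrix(counter + seq_len(n), n, 1),
                  a2 = matrix(counter + n + seq_len(n), n, 1))
      counter <<- counter + 2 * n
      out
    }
  })
  members <- list()
  n <- n_families
  if (structure %in% c("mz_twin", "dz_twin", "sibling")) {
    mo <- label_founder(n); fa <- label_founder(n)
    pro <- child_of(mo, fa)
    rel <- if (structure == "mz_twin") pro else child_of(mo, fa)
  } else if (structure == "parent_child") {
    pro <- label_founder(n)
    rel <- child_of(pro, label_founder(n))
  } else if (structure == "aunt_uncle") {
    gm <- label_founder(n); gf <- label_founder(n)
    parent <- child_of(gm, gf); rel <- child_of(gm, gf)
    pro <- child_of(parent, label_founder(n))
  } else if (structure == "first_cousin") {
    gm <- label_founder(n); gf <- label_founder(n)
    p1 <- child_of(gm, gf); p2 <- child_of(gm, gf)
    pro <- child_of(p1, label_founder(n))
    rel <- child_of(p2, label_founder(n))
  } else {
    stop("IBD sharing is not defined for structure: ", structure,
         call. = FALSE)
  }
  shared <- (pro$a1[, 1] == rel$a1[, 1] | pro$a1[, 1] == rel$a2[, 1]) +
    (pro$a2[, 1] == rel$a1[, 1] | pro$a2[, 1] == rel$a2[, 1])
  mean(shared / 2)
}

#' Write simulated genotypes as PLINK-style PED/MAP text files
#'
#' One line per individual (family, id, affection as 2/1) with two allele
#' columns per locus; a companion MAP file lists the loci. Allele codes:
#' `A` = non-susceptibility, `B` = susceptibility (dominant-acting),
#' `C` = recessive-acting at mixed loci.
#'
#' @param geno A genotype object (internal allele-slot pair) is not
#'   exposed; this writer takes the per-individual summary tibble from
#'   [simulate_cohort()] and the HLA copies only, writing a single-locus
#'   PED for interoperability checks.
#' @param records Tibble from [simulate_cohort()].
#' @param path_prefix Files `<prefix>.ped` and `<prefix>.map` are written.
#' @return Invisibly, the two file paths.
#' @export
write_ped <- function(records, path_prefix) {
  ped <- sprintf("%d 1 0 0 0 %d %s %s",
                 seq_len(nrow(records)),
                 ifelse(records$affected, 2L, 1L),
                 ifelse(records$hla_copies >= 1, "B", "A"),
                 ifelse(records$hla_copies == 2, "B", "A"))
  map <- "6 HLA_DRB1 0 32400000"
  ped_path <- paste0(path_prefix, ".ped")
  map_path <- paste0(path_prefix, ".map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  invisible(c(ped_path, map_path))
}
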