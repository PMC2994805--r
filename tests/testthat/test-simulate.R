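test_that("locus_table lays out the HLA locus plus the composition split", {
  p <- ms_model(n = 13, r = 4, x = 103,
                composition = c(dominant = 0.2, recessive = 0.8))
  lt <- locus_table(p)
  expect_identical(nrow(lt), 104L)
  expect_identical(sum(lt$is_hla), 1L)
  expect_identical(sum(lt$mode == "dominant" & !lt$is_hla), 21L)
  expect_identical(sum(lt$mode == "recessive"), 82L)
  expect_equal(lt$allele_freq[1], p$a_h)
})

test_that("founder genotypes sit in Hardy-Weinberg proportions", {
  p <- ms_model(n = 3, r = 2, x = 4,
                composition = c(dominant = 0.5, recessive = 0.25,
                                mixed = 0.25))
  loci <- locus_table(p)
  set.seed(11)
  g <- mssusmod:::draw_founder(1e5, loci)
  for (j in c(1, 2, 4, 5)) { # one locus of each mode incl. HLA
    a <- loci$allele_freq[j]
    n11 <- mean(g$a1[, j] == 1 & g$a2[, j] == 1)
    se <- sqrt(a^2 * (1 - a^2) / 1e5)
    expect_lt(abs(n11 - a^2), 4 * se + 1e-9)
    carrier <- mean(g$a1[, j] == 1 | g$a2[, j] == 1)
    pc <- 2 * a - a^2
    expect_lt(abs(carrier - pc), 4 * sqrt(pc * (1 - pc) / 1e5))
  }
})

test_that("simulated cohort prevalence matches the closed form", {
  p <- toy_model() # exact prevalence 0.41146
  co <- simulate_cohort(p, 2e5, seed = 7)
  truth <- prevalence(p)
  se <- sqrt(truth * (1 - truth) / 2e5)
  expect_lt(abs(mean(co$affected) - truth), 4 * se)
  # a second, less degenerate configuration
  q <- ms_model(n = 3, r = 2, x = 8, pt_star = 0.5,
                composition = c(dominant = 0.5, recessive = 0.5))
  cq <- simulate_cohort(q, 2e5, seed = 8)
  tq <- prevalence(q)
  expect_lt(abs(mean(cq$affected) - tq), 4 * sqrt(tq * (1 - tq) / 2e5))
  # zero penetrance leaves nobody affected
  expect_equal(sum(simulate_cohort(toy_model(pt_star = 0), 1e4,
                                   seed = 1)$affected), 0)
})

test_that("identical seeds give byte-identical output", {
  p <- ms_model(n = 3, r = 2, x = 8, pt_star = 0.5)
  a <- simulate_cohort(p, 5e3, seed = 42)
  b <- simulate_cohort(p, 5e3, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(p, 5e3, seed = 43)))
  pa <- simulate_pedigrees(p, 200, "sibling", seed = 42)
  pb <- simulate_pedigrees(p, 200, "sibling", seed = 42)
  expect_identical(pa, pb)
  fa <- tempfile(); fb <- tempfile()
  utils::write.table(pa, fa, sep = "\t", row.names = FALSE)
  utils::write.table(pb, fb, sep = "\t", row.names = FALSE)
  expect_identical(readLines(fa), readLines(fb))
  unlink(c(fa, fb))
})

test_that("mz twins are genetically identical in every simulated family", {
  p <- ms_model(n = 2, r = 2, x = 4, pt_star = 0.5)
  ped <- simulate_pedigrees(p, 500, "mz_twin", seed = 3, condition = "none")
  wide <- ped |>
    dplyr::filter(.data$role %in% c("proband", "relative")) |>
    dplyr::select("family", "role", "hla_copies", "n_susceptible") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("hla_copies", "n_susceptible"))
  expect_identical(wide$hla_copies_proband, wide$hla_copies_relative)
  expect_identical(wide$n_susceptible_proband, wide$n_susceptible_relative)
})

test_that("realised IBD sharing matches pedigree theory", {
  expect_equal(ibd_sharing("sibling", 2e5, seed = 5), 0.5, tolerance = 0.01)
  expect_equal(ibd_sharing("aunt_uncle", 2e5, seed = 5), 0.25,
               tolerance = 0.02)
  expect_equal(ibd_sharing("first_cousin", 2e5, seed = 5), 0.125,
               tolerance = 0.03)
})

test_that("simulated HLA transmission matches the conditional forms", {
  p <- ms_model(n = 1, r = 2, x = 1, pt_star = 1)
  ped <- simulate_pedigrees(p, 2e5, "sibling", seed = 9, condition = "none")
  wide <- ped |>
    dplyr::filter(.data$role %in% c("proband", "relative")) |>
    dplyr::select("family", "role", "hla_carrier") |>
    tidyr::pivot_wider(names_from = "role", values_from = "hla_carrier")
  # proband carrier: exact enumeration value, and the printed 62% within 3%
  p_h_hat <- mean(wide$relative[wide$proband])
  exact <- p_hla_shared_exact(p$a_h, TRUE)
  n_pos <- sum(wide$proband)
  expect_lt(abs(p_h_hat - exact), 4 * sqrt(exact * (1 - exact) / n_pos))
  expect_lt(abs(p_h_hat / p_hla_shared("sibling", p$a_h) - 1), 0.03)
  # proband non-carrier: the printed P_h1 form is exact
  p_h1_hat <- mean(wide$relative[!wide$proband])
  p_h1 <- p_hla_shared("sibling", p$a_h, FALSE)
  n_neg <- sum(!wide$proband)
  expect_lt(abs(p_h1_hat - p_h1), 4 * sqrt(p_h1 * (1 - p_h1) / n_neg))
})

test_that("simulated sibling recurrence tracks the closed form", {
  # x = 10, n = 3, r = 2, all dominant, Pt* = 1: the closed forms are
  # acknowledged approximations, so agreement is loose but bounded
  p <- ms_model(n = 3, r = 2, x = 10, pt_star = 1,
                composition = c(dominant = 1))
  ped <- simulate_pedigrees(p, 2e5, "sibling", seed = 13,
                            condition = "none", batch_size = 2e5)
  wide <- ped |>
    dplyr::filter(.data$role %in% c("proband", "relative")) |>
    dplyr::select("family", "role", "affected") |>
    tidyr::pivot_wider(names_from = "role", values_from = "affected")
  mc <- mean(wide$relative[wide$proband])
  pro <- ped |> dplyr::filter(.data$role == "proband")
  hla <- pro$hla_carrier[pro$affected]
  closed <- mean(hla) * recurrence_risk(p, "sibling", TRUE) +
    (1 - mean(hla)) * recurrence_risk(p, "sibling", FALSE)
  expect_lt(abs(mc / closed - 1), 0.5)
})

test_that("conditioning keeps only proband-affected families", {
  p <- ms_model(n = 2, r = 2, x = 6, pt_star = 0.5)
  ped <- simulate_pedigrees(p, 300, "sibling", seed = 21)
  pro <- dplyr::filter(ped, .data$role == "proband")
  expect_identical(nrow(pro), 300L)
  expect_true(all(pro$affected))
  conj <- simulate_pedigrees(p, 100, "conjugal_offspring", seed = 22)
  both <- conj |>
    dplyr::filter(.data$role %in% c("proband", "proband2"))
  expect_true(all(both$affected))
})

test_that("empirical_stats summarises cohorts and pedigrees", {
  p <- ms_model(n = 2, r = 2, x = 6, pt_star = 0.5)
  co <- simulate_cohort(p, 5e4, seed = 31)
  st <- empirical_stats(co)
  expect_equal(st$prevalence, mean(co$affected))
  expect_gt(st$h_m_hat, p$h) # HLA enriched among cases
  expect_equal(st$c_hat, 1 - st$h_m_hat)
  expect_gt(st$allelic_or, 1)
  # zero-penetrance cohort: empty case stratum reported as missing
  st0 <- empirical_stats(simulate_cohort(toy_model(pt_star = 0), 1e3,
                                         seed = 1))
  expect_identical(st0$n_cases, 0L)
  expect_true(is.na(st0$h_m_hat))
  ped <- simulate_pedigrees(p, 300, "sibling", seed = 32)
  rec <- empirical_stats(ped)
  expect_identical(rec$stratum, c("all", "proband_hla_pos",
                                  "proband_hla_neg"))
  expect_true(all(rec$ci_low <= rec$recurrence &
                    rec$recurrence <= rec$ci_high, na.rm = TRUE))
})

test_that("write_ped emits PLINK-style text files", {
  p <- ms_model(n = 2, r = 2, x = 4, pt_star = 0.5)
  co <- simulate_cohort(p, 50, seed = 2)
  prefix <- tempfile()
  paths <- write_ped(co, prefix)
  expect_identical(length(readLines(paths[1])), 50L)
  expect_identical(length(readLines(paths[2])), 1L)
  first <- strsplit(readLines(paths[1])[1], " ")[[1]]
  expect_identical(length(first), 8L)
  unlink(paths)
})
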