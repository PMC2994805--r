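test_that("the HLA-negative fraction is a monotone falling-factorial ratio", {
  expect_equal(hla_negative_fraction(5, n = 5, r = 1), 1 / 6)
  expect_equal(hla_negative_fraction(10, n = 0, r = 2), 1)
  expect_equal(hla_negative_fraction(4, n = 5, r = 1), 0) # x = n - 1
  xs <- seq(6, 200, by = 1)
  frac <- hla_negative_fraction(xs, n = 6, r = 2)
  expect_true(all(diff(frac) > 0)) # increasing in x
  for (x in c(10, 50)) {
    by_r <- vapply(c(0.5, 1, 2, 4), function(r)
      hla_negative_fraction(x, n = 6, r = r), numeric(1))
    expect_true(all(diff(by_r) < 0)) # decreasing in r
  }
  expect_error(hla_negative_fraction(3, n = 5, r = 1), "at least")
})

test_that("solve_x finds the worked-example root and literal scan ranges", {
  sol <- solve_x(n = 4, r = 2)
  expect_equal(round(sol$x_continuous, 1), 15.9)
  expect_equal(solve_x(n = 1, r = 1, c_star = 0.5)$x_continuous, 1,
               tolerance = 1e-8)
  # telescoped fraction (x-4)/(x+1) in C* +/- 0.05 admits 10..12
  sol2 <- solve_x(n = 5, r = 1, c_star = 0.5921, tol = 0.05)
  expect_identical(sol2$x_low, 10L)
  expect_identical(sol2$x_high, 12L)
  # an empty band is reported, not thrown
  sol3 <- solve_x(n = 5, r = 1, c_star = 0.6, tol = 1e-6)
  expect_false(sol3$feasible)
  expect_true(is.na(sol3$x_low))
  # vectorised over (n, r) pairs
  expect_identical(nrow(solve_x(n = c(4, 5), r = c(2, 1))), 2L)
})

test_that("prevalence matches exhaustive locus-state enumeration", {
  expect_equal(prevalence(toy_model()), 0.411456, tolerance = 1e-6)
  for (cfg in list(list(n = 1, r = 2, x = 2, pt = 1),
                   list(n = 3, r = 1, x = 7, pt = 0.5),
                   list(n = 5, r = 4, x = 12, pt = 0.134))) {
    p <- ms_model(n = cfg$n, r = cfg$r, x = cfg$x, pt_star = cfg$pt)
    expect_equal(prevalence(p), enum_prevalence(p), tolerance = 1e-12)
  }
  # differing penetrance by HLA state
  p <- ms_model(n = 4, r = 2, x = 10, pt1_star = 0.3, pt0_star = 0.1)
  expect_equal(prevalence(p), enum_prevalence(p), tolerance = 1e-12)
  expect_equal(prevalence(ms_model(n = 3, r = 2, x = 8, pt_star = 0)), 0)
})

test_that("prevalence is non-increasing in the threshold n", {
  prev <- vapply(2:10, function(n)
    prevalence(ms_model(n = n, r = 2, x = 20)), numeric(1))
  expect_true(all(diff(prev) < 0))
})

test_that("the Poisson limit matches the finite-r prevalence", {
  expect_equal(round(100 * limit_prevalence(5), 2), 1.27)
  expect_equal(round(100 * limit_prevalence(10), 2), 0.29)
  expect_equal(limit_prevalence(5, pt_star = 0), 0)
  for (n in c(5, 10, 15)) {
    root <- solve_x(n = n, r = 1e6)$x_continuous
    p <- ms_model(n = n, r = 1e6)
    finite <- prevalence(p, x = round(root))
    expect_equal(finite / limit_prevalence(n), 1, tolerance = 1e-3)
  }
})

test_that("sibling recurrence matches the direct toy evaluation", {
  p <- toy_model() # x = 2, n = 1, all dominant, Pt* = 1
  ph <- p_hla_shared("sibling", p$a_h)
  expect_equal(recurrence_risk(p, "sibling", TRUE),
               1 - (1 - ph) * (1 - p$f)^2, tolerance = 1e-12)
  expect_equal(recurrence_risk(p, "sibling", TRUE), 0.7056, tolerance = 5e-3)
  expect_equal(recurrence_risk(toy_model(pt_star = 0), "sibling"), 0)
})

test_that("dominant loci make sibling and parent/child risks coincide", {
  p <- ms_model(n = 6, r = 2, x = 20, composition = c(dominant = 1))
  expect_identical(recurrence_risk(p, "sibling", TRUE),
                   recurrence_risk(p, "parent_child", TRUE))
  expect_identical(expected_recurrence(p, "sibling"),
                   expected_recurrence(p, "parent_child"))
  # any recessive loci tip the balance towards siblings
  q <- ms_model(n = 6, r = 2, x = 20, composition = c(recessive = 1))
  expect_gt(expected_recurrence(q, "sibling"),
            expected_recurrence(q, "parent_child"))
  q2 <- ms_model(n = 6, r = 2, x = 20,
                 composition = c(dominant = 0.5, recessive = 0.5))
  expect_gt(expected_recurrence(q2, "sibling"),
            expected_recurrence(q2, "parent_child"))
})

test_that("family information raises risk above the population prevalence", {
  for (r in c(0.25, 1, 4, 16)) {
    for (n in c(5, 12, 18)) {
      sol <- solve_x(n = n, r = r)
      if (!sol$feasible) next
      p <- ms_model(n = n, r = r)
      x <- sol$x_low
      expect_gte(expected_recurrence(p, "sibling", x = x),
                 prevalence(p, x = x))
    }
  }
})

test_that("recurrence risks order by relationship degree", {
  p <- ms_model(n = 13, r = 4, composition = c(dominant = 0.2,
                                               recessive = 0.8))
  rates <- vapply(c("sibling", "aunt_uncle", "first_cousin"),
                  function(rel) expected_recurrence(p, rel, x = 103),
                  numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("sibling and parent/child predictions track the published cell", {
  # 20% dominant / 80% recessive, r = 4, n = 13, published x = 100..107:
  # the table prints sibling 3.5-4.2% and parent/child 1.6-2.1%
  p <- ms_model(n = 13, r = 4, composition = c(dominant = 0.2,
                                               recessive = 0.8))
  sib <- 100 * vapply(c(100, 107), function(x)
    expected_recurrence(p, "sibling", x = x), numeric(1))
  pc <- 100 * vapply(c(100, 107), function(x)
    expected_recurrence(p, "parent_child", x = x), numeric(1))
  expect_equal(sib, c(3.5, 4.2), tolerance = 0.05)
  expect_equal(pc, c(1.6, 2.1), tolerance = 0.1)
})

test_that("dz twins use the unadjusted penetrance", {
  p <- ms_model(n = 6, r = 2, x = 20)
  expect_equal(recurrence_risk(p, "dz_twin", TRUE),
               recurrence_risk(p, "sibling", TRUE) * p$dz_sib_ratio,
               tolerance = 1e-12)
  # mz twins: identical genotype, unadjusted penetrance
  expect_equal(recurrence_risk(p, "mz_twin", TRUE),
               p$pt1_star * p$dz_sib_ratio)
})

test_that("expected recurrence mixes proband HLA branches by C", {
  p <- ms_model(n = 6, r = 2, x = 20, C = 0)
  expect_equal(expected_recurrence(p, "sibling"),
               recurrence_risk(p, "sibling", TRUE))
  p2 <- ms_model(n = 6, r = 2, x = 20)
  pos <- recurrence_risk(p2, "sibling", TRUE)
  neg <- recurrence_risk(p2, "sibling", FALSE)
  expect_equal(expected_recurrence(p2, "sibling"),
               0.55 * pos + 0.45 * neg)
  # conjugal offspring: both parents are probands, weight C^2
  posc <- recurrence_risk(p2, "conjugal_offspring", TRUE)
  negc <- recurrence_risk(p2, "conjugal_offspring", FALSE)
  expect_equal(expected_recurrence(p2, "conjugal_offspring"),
               (1 - 0.45^2) * posc + 0.45^2 * negc)
})

test_that("predict_rates returns a tidy prediction set", {
  p <- ms_model(n = 6, r = 2, x = 20)
  pr <- predict_rates(p, x = c(20, 25))
  expect_s3_class(pr, "tbl_df")
  expect_identical(nrow(pr), 12L)
  expect_true(all(pr$rate >= 0 & pr$rate <= 1))
  expect_true(all(is.na(pr$rate_hla_pos[pr$outcome == "prevalence"])))
})
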