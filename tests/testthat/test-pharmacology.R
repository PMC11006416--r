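test_that("synthetic drugs satisfy their constructor contract", {
  d <- synthetic_drug(c(gKr = 0.05, pCa = 1.2))
  expect_equal(unname(d["gKr"]), 0.05)
  expect_equal(unname(d["pCa"]), 1.2)
  expect_equal(unname(d[c("gNa", "gKs")]), c(1, 1))
  expect_error(synthetic_drug(c(bogus = 0.5)), "named")
  expect_error(synthetic_drug(c(gKr = -0.1)), ">= 0")
  set.seed(1)
  r <- random_drug(4, 0.5, 1.5)
  expect_equal(sum(r != 1), 4)
  expect_true(all(r[r != 1] >= 0.5 & r[r != 1] <= 1.5))
  expect_identical(random_drug(seed = 42), random_drug(seed = 42))
})

test_that("random drugs select targets uniformly", {
  set.seed(6)
  counts <- integer(9)
  names(counts) <- conductance_names()
  n <- 10000
  for (k in seq_len(n)) {
    d <- random_drug(4)
    counts[d != 1] <- counts[d != 1] + 1L
  }
  expect_true(all(abs(counts / n - 4 / 9) < 0.02))
})

test_that("drug application is multiplicative and clips to the domain", {
  g <- conductance_set()
  d1 <- synthetic_drug(c(gKr = 0.05, pCa = 1.20))
  gd <- apply_drug(g, d1)
  expect_equal(unname(gd["gKr"]), 0.05)
  expect_equal(unname(gd["pCa"]), 1.20)
  expect_equal(unname(gd[c("gNa", "gNaL", "gto", "gKs", "gK1", "gNCX",
                           "pNaK")]), rep(1, 7))
  expect_equal(unclass(apply_drug(g, synthetic_drug())), unclass(g))
  # composition equals the element-wise product of factors
  a <- synthetic_drug(c(gNa = 0.8, gKs = 1.3))
  b <- synthetic_drug(c(gNa = 1.2, gK1 = 0.6))
  expect_equal(unclass(apply_drug(apply_drug(g, a), b)),
               unclass(apply_drug(g, synthetic_drug(
                 c(gNa = 0.8 * 1.2, gKs = 1.3, gK1 = 0.6)))))
  expect_warning(apply_drug(as_conductance_set(rep(1.5, 9)),
                            synthetic_drug(c(pCa = 1.5))), "clip")
})

test_that("the EAD drug grid spans the documented ten-step block schedule", {
  grid <- ead_drug_grid()
  expect_length(grid, 10)
  expect_equal(sapply(grid, `[[`, "gKr"), seq(0.05, 0.14, by = 0.01))
  expect_equal(sapply(grid, `[[`, "pCa"), seq(1.20, 1.38, by = 0.02))
})

test_that("the pore-block model follows its closed form", {
  expect_equal(pore_block(0, 100, 1), 1)
  expect_equal(pore_block(100, 100, 1), 0.5)
  expect_equal(pore_block(100, 100, 7), 0.5)
  expect_equal(pore_block(300, 100, 2), 1 / 10)
  # strictly decreasing in concentration; bounded in (0, 1]
  cs <- seq(0, 1000, by = 50)
  s <- pore_block(cs, 100, 1.5)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
  # increasing Hill coefficient deepens block above the IC50
  expect_lt(pore_block(300, 100, 3), pore_block(300, 100, 1))
  # brute-force oracle
  set.seed(2)
  for (k in 1:20) {
    C <- runif(1, 0, 500); ic <- runif(1, 10, 200); h <- runif(1, 0.5, 3)
    expect_equal(pore_block(C, ic, h), 1 / (1 + (C / ic)^h),
                 tolerance = 1e-12)
  }
  expect_error(pore_block(10, 100, 1, unit = "nM", ic50_unit = "uM"), "unit")
})

test_that("success classification uses the closed mu +/- (0.15 + sigma) band", {
  set.seed(3)
  dist <- reference_distribution(rnorm(2000, mean = 0.6, sd = 0.1))
  expect_true(success_classify(dist$mu, dist))
  expect_true(success_classify(dist$mu + 0.15 + dist$sigma, dist))
  expect_true(success_classify(dist$mu - 0.15 - dist$sigma, dist))
  expect_false(success_classify(dist$mu + 0.15 + dist$sigma + 1e-9, dist))
  # summary statistics always recomputed from the samples
  expect_equal(dist$mu, mean(dist$samples))
  expect_equal(dist$sigma, sd(dist$samples))
})

test_that("success tabulation mirrors the successful/unsuccessful/ratio layout", {
  flags <- c(rep(TRUE, 3), rep(FALSE, 10), rep(TRUE, 9))
  targets <- c(rep("GKr", 13), rep("GKs", 9))
  tab <- tabulate_success(flags, targets)
  expect_equal(tab["Successful", "GKr"], 3)
  expect_equal(tab["Unsuccessful", "GKr"], 10)
  expect_equal(tab["Ratio", "GKr"], 0.23)
  expect_equal(tab["Ratio", "GKs"], 1)
  # conservation per target and in total
  expect_equal(tab["Successful", "Total"] + tab["Unsuccessful", "Total"],
               length(flags))
})

test_that("population calibration accepts members in sequence order", {
  # vacuous biomarker ranges: acceptance reduces to the abnormality filter,
  # and members must be the first candidates of the sequence that pass it
  wide <- lapply(biomarker_ranges(), function(r) c(-1e9, 1e9))
  pop <- build_population(2, ranges = wide, protocol = fast_protocol())
  expect_length(pop$members, 2)
  cands <- sobol_conductance_samples(16, 0.5, 1.5)
  expected <- list()
  for (g in cands) {
    ap1 <- simulate_ap(g, fast_protocol())
    ap2 <- integrate_beat(attr(ap1, "state"), g, fast_protocol())$trace
    if (!detect_abnormality(list(ap1, ap2)) &&
        !inherits(try(compute_biomarkers(ap2), silent = TRUE), "try-error"))
      expected[[length(expected) + 1]] <- g
    if (length(expected) == 2) break
  }
  expect_equal(unclass(pop$members[[1]]), unclass(expected[[1]]))
  expect_equal(unclass(pop$members[[2]]), unclass(expected[[2]]))
  # real ranges: all members re-validate against the filters
  pop2 <- build_population(3, protocol = pacing_protocol())
  for (i in seq_along(pop2$members)) {
    b <- compute_biomarkers(pop2$traces[[i]])
    expect_true(within_ranges(b, biomarker_ranges()))
    expect_false(detect_ead(pop2$traces[[i]]))
  }
  expect_gte(pop2$provenance$candidates_tried, 3)
})
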