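test_that("Gumbel-minimum ML fit recovers known parameters at n = 10000", {
  x <- withr::with_seed(1, rgumbel_min(10000, location = 32, scale = 5.5))
  fit <- fit_gumbel_min(x)
  expect_lt(abs(fit$location - 32), 0.3)
  expect_lt(abs(fit$scale - 5.5), 0.2)
  # equivariance: shifting the sample shifts location only
  fit5 <- fit_gumbel_min(x + 5)
  expect_lt(abs(fit5$location - (fit$location + 5)), 1e-6)
  expect_lt(abs(fit5$scale - fit$scale), 1e-6)
  expect_error(fit_gumbel_min(rep(3, 50)), "degenerate")
  expect_error(fit_gumbel_min(1:10), "at least 30")
  td <- generics::tidy(fit)
  expect_identical(td$term, c("location", "scale"))
  expect_identical(generics::glance(fit)$nobs, 10000L)
})

test_that("binned log-odds match hand-computed frequencies", {
  # toy 3-bin histograms: counts (2,1,1) vs (1,1,2)
  real <- c(0.005, 0.005, 0.015, 0.025)
  bgr <- c(0.005, 0.015, 0.025, 0.025)
  bl <- binned_logodds(real, bgr, bin_width = 0.01)
  lo <- bl$logodds[bl$count_real > 0 & bl$count_bgr > 0]
  expect_equal(lo, c(log(2), 0, log(0.5)))
  # identical samples give all-zero defined bins
  same <- binned_logodds(real, real)
  expect_true(all(same$logodds[!is.na(same$logodds)] == 0))
})

test_that("sigmoid fit recovers generating parameters within 10%", {
  a <- 1.0; b <- 0.5; c <- 10
  x <- seq(-0.6, -0.01, by = 0.01)
  clean <- tibble::tibble(bin_center = x, logodds = a / (b + exp(c * x)))
  fit0 <- fit_sigmoid(clean)
  expect_lt(abs(fit0$a - a) / a, 0.01)
  expect_lt(abs(fit0$b - b) / b, 0.01)
  expect_lt(abs(fit0$c - c) / c, 0.01)
  expect_lt(fit0$rss, 1e-8)
  noisy <- tibble::tibble(
    bin_center = x,
    logodds = a / (b + exp(c * x)) + withr::with_seed(5, rnorm(length(x), 0, 0.01)))
  fit1 <- fit_sigmoid(noisy)
  expect_lt(abs(fit1$a - a) / a, 0.10)
  expect_lt(abs(fit1$b - b) / b, 0.10)
  expect_lt(abs(fit1$c - c) / c, 0.10)
  # deterministic: refitting the same data reproduces the same triple
  expect_identical(generics::tidy(fit1), generics::tidy(fit_sigmoid(noisy)))
  expect_error(fit_sigmoid(clean[1:3, ]), "at least 5")
})

test_that("discrete frequency estimation reproduces the plant log-odds", {
  stab <- estimate_discrete_frequencies(rep(c(1, 0), c(98, 2)),
                                        rep(c(1, 0), c(25, 75)))
  expect_equal(round(stab$logodds_present, 2), 1.37)
  expect_equal(round(stab$logodds_absent, 3), -3.624)
  # zero background cell falls back to the pseudo-count
  cons <- estimate_discrete_frequencies(rep(c(1, 0), c(69, 31)),
                                        rep(0, 100), pseudo_count = 1 / 3000)
  expect_identical(cons$p_bgr, 1 / 3000)
  expect_equal(cons$logodds_present, log(0.69 * 3000))
  same <- estimate_discrete_frequencies(c(1, 0, 1), c(1, 0, 1))
  expect_identical(same$logodds_present, 0)
  expect_identical(same$logodds_absent, 0)
})

test_that("conservation profiling finds designed blocks at the 0.75 threshold", {
  # 18 identical-family profile: everything conserved, one block
  fams18 <- setNames(replicate(18, rep(strrep("ACGTA", 4) , 3),
                               simplify = FALSE), paste0("f", 1:18))
  prof18 <- conservation_profile(fams18)
  expect_true(all(prof18$profile$n_conserved == 18))
  expect_identical(nrow(prof18$blocks), 1L)
  expect_identical(c(prof18$blocks$start, prof18$blocks$end), c(1L, 20L))

  # 4-family fixture: positions 2-13 and 16-19 conserved in 3 of 4 families
  base <- strrep("A", 21)
  conserved_member <- function(positions) {
    s <- withr::with_seed(8, random_nt(21))
    for (p in setdiff(1:21, positions)) substr(s, p, p) <- "N" # see below
    s
  }
  mk_family <- function(conserve) {
    # members agree exactly at `conserve`; position-wise random elsewhere
    vapply(1:4, function(k) {
      s <- random_nt(21)
      for (p in conserve) substr(s, p, p) <- substr(base, p, p)
      s
    }, character(1))
  }
  fams <- withr::with_seed(11, list(
    f1 = mk_family(c(2:13, 16:19)), f2 = mk_family(c(2:13, 16:19)),
    f3 = mk_family(c(2:13, 16:19)), f4 = mk_family(integer(0))))
  prof <- conservation_profile(fams)
  expect_true(all(prof$profile$n_conserved[c(2:13, 16:19)] >= 3))
  blocks <- prof$blocks
  expect_true(any(blocks$start == 2 & blocks$end == 13))
  expect_true(any(blocks$start == 16 & blocks$end == 19))

  # permutation invariance in family and member order
  prof_perm <- conservation_profile(rev(lapply(fams, rev)))
  expect_identical(prof$profile$n_conserved, prof_perm$profile$n_conserved)

  # a 0.8 modal fraction misses the 0.9 within-family bar
  five <- list(f = c(rep("AAAAA", 4), "AACAA"), g = rep("AAAAA", 2))
  p5 <- conservation_profile(five)
  expect_false(unname(p5$per_family["f", 3]))
  expect_message(conservation_profile(list(a = "ACGT", b = c("AAAA", "AAAA"))),
                 "fewer than 2")
})

test_that("the center-star family aligner produces usable equal-length rows", {
  fam <- c("TGACAGAAGAGAGTGAGCACA", "TGACAGAAGAGAGTGAGCACA",
           "TGACAGAAGAGGTGAGCACA") # one member with a 1-nt deletion
  al <- align_family(fam)
  expect_identical(length(unique(nchar(al))), 1L)
  expect_identical(gsub("-", "", al), fam)
})

test_that("cross-validated nucleus frequency behaves at the extremes", {
  same <- rep("TGACAGAAGAGAGTGAGCACA", 20)
  expect_identical(nucleus_frequency_cv(same, seed = 1), 1)
  distinct <- withr::with_seed(4, vapply(1:20, function(i) {
    s <- random_nt(21); substr(s, 5, 5) <- c("A", "C", "G", "T")[(i %% 4) + 1]
    paste0(substr(s, 1, 4), sprintf("%02d", i), substr(s, 7, 21))
  }, character(1)))
  # every nucleus made unique by an index stamp at positions 5-6
  expect_identical(nucleus_frequency_cv(distinct, seed = 1), 0)
  # 10 families x 10 members with shared family nuclei: every held-out mature
  # finds a family mate in training
  ds <- make_dataset(synthetic_spec(seed = 6))
  expect_identical(nucleus_frequency_cv(ds$matures, seed = 2), 1)
  expect_error(nucleus_frequency_cv(same[1:5]), "at least")
})

test_that("excision length selection follows the CDF with a tail constraint", {
  lens <- rep(c(100L, 400L), c(96, 4))
  expect_identical(select_excision_length(lens, 0.96), 100L)
  expect_error(select_excision_length(lens, 1.0), "best feasible coverage")
  many <- withr::with_seed(7, as.integer(round(rgamma(400, shape = 4, rate = 0.025))))
  expect_identical(select_excision_length(many, 1.0, min_tail_sample = 1L),
                   max(many))
  # monotone non-decreasing in coverage
  covs <- c(0.5, 0.7, 0.9, 0.96)
  sel <- vapply(covs, function(cv) {
    select_excision_length(many, cv, min_tail_sample = 5L)
  }, integer(1))
  expect_true(all(diff(sel) >= 0))
  # agrees with a direct order-statistics quantile on the same draw
  expect_gte(mean(many <= sel[4]), 0.96)
  expect_lt(mean(many <= sel[4] - 1L), 0.96)
})

test_that("the KS statistic equals a brute-force ECDF supremum", {
  expect_identical(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_identical(ks_two_sample(1:5, 11:20)$statistic, 1)
  withr::with_seed(12, {
    for (case in 1:20) {
      x <- rnorm(sample(5:40, 1))
      y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
      expect_equal(ks_two_sample(x, y)$statistic, brute_ks_statistic(x, y))
    }
  })
})

test_that("|MFE|-vs-length regression recovers planted slopes", {
  lens <- rep(seq(60, 300, by = 20), each = 5)
  exact <- mfe_length_regression(lens, -0.5 * lens)
  expect_equal(exact$slope, 0.5)
  expect_true(all(exact$bins$sd_abs_mfe == 0))
  expect_equal(mfe_length_regression(lens, rep(-40, length(lens)))$slope, 0)
  noisy_mfe <- withr::with_seed(9,
    -(0.48 * lens + rnorm(length(lens), 0, 0.02 * lens)))
  noisy <- mfe_length_regression(lens, noisy_mfe)
  expect_lt(abs(noisy$slope - 0.48), 0.02)
})
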