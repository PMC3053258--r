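test_that("normalized MFE is per-nucleotide and length-invariant", {
  expect_identical(normalized_mfe(-100, 250), -0.4)
  expect_identical(normalized_mfe(0, 100), 0)
  # equal per-nt energy at different lengths gives equal normalized values
  expect_identical(normalized_mfe(-40, 100), normalized_mfe(-120, 300))
  expect_error(normalized_mfe(-10, 0), "positive")
})

test_that("mononucleotide shuffling preserves the nucleotide histogram", {
  expect_identical(shuffle_sequence("AAAA", "mono"), "AAAA")
  withr::with_seed(1, {
    for (case in 1:20) {
      s <- random_nt(sample(20:200, 1))
      sh <- shuffle_sequence(s, "mono")
      expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
    }
  })
})

test_that("dinucleotide shuffling preserves the 16-entry dinucleotide table", {
  withr::with_seed(2, {
    changed <- 0
    for (case in 1:30) {
      s <- random_nt(sample(20:200, 1))
      sh <- shuffle_sequence(s, "di")
      expect_identical(dinucleotide_table(sh), dinucleotide_table(s))
      n <- nchar(s)
      expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
      expect_identical(substr(sh, n, n), substr(s, n, n))
      if (sh != s) changed <- changed + 1
    }
    expect_gt(changed, 20) # the shuffle actually permutes long sequences
  })
})

test_that("stability p-value follows p = max(R,1)/(N+1)", {
  expect_identical(shuffle_pvalue(49, 999), 0.049)
  expect_identical(shuffle_pvalue(0, 999), 0.001) # formula floor
  expect_identical(shuffle_pvalue(999, 999), 0.999)
})

test_that("a planted stem-loop is called stable and a recount agrees", {
  s <- perfect_stem_seq(27, loop_len = 6, seed = 10) # 60-nt hairpin
  res <- stability_pvalue(s, n_shuffles = 99, seed = 123)
  expect_identical(res$rel, 1L)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$p_value, 0)
  # independent recount: regenerate the same shuffle ensemble, refold each
  # sequence one at a time, and count the at-least-as-stable ones
  shuffles <- withr::with_seed(123, vapply(1:99, function(i) {
    shuffle_sequence(s, "mono")
  }, character(1)))
  mfes <- vapply(shuffles, function(x) fold(x)$mfe, double(1))
  R <- sum(mfes <= fold(s)$mfe + 1e-9)
  expect_identical(res$R, R)
  expect_identical(res$p_value, shuffle_pvalue(R, 99))
})

test_that("most 300-nt coding-like backgrounds are not called stable", {
  # real plant precursors are ~0.98 stable while 300-nt coding backgrounds
  # fall to ~0.2; a dozen backgrounds should be mostly unstable
  seqs <- withr::with_seed(3, replicate(12, plantpin:::codon_background(300)))
  rel <- vapply(seq_along(seqs), function(i) {
    stability_pvalue(seqs[i], n_shuffles = 99, seed = 100 + i)$rel
  }, integer(1))
  expect_lte(mean(rel), 0.5)
})

test_that("nucleus conservation is an exact positional 2-12 match", {
  lib <- c("TGACAGAAGAGAGTGAGCACA", "TTGGACTGAAGGGAGCTCCCT")
  expect_identical(nucleus_conserved(lib[1], lib), 1L) # reflexive
  expect_identical(nucleus_conserved(lib[1], rev(lib)), 1L) # order-invariant
  # differences at position 1 and beyond 12 do not matter
  probe <- lib[1]
  substr(probe, 1, 1) <- "C"
  substr(probe, 13, 21) <- "CCCCCCCCC"
  expect_identical(nucleus_conserved(probe, lib), 1L)
  # a single nucleus mismatch at position 5 breaks the match
  probe2 <- lib[1]
  substr(probe2, 5, 5) <- ifelse(substr(probe2, 5, 5) == "A", "C", "A")
  expect_identical(nucleus_conserved(probe2, lib), 0L)
  expect_message(out <- nucleus_conserved("ACGTAC", lib), "shorter")
  expect_identical(out, 0L)
})

test_that("star presence honors the positional slack", {
  dup <- tibble::tibble(star_start = 100L, star_end = 121L)
  on_star <- tibble::tibble(start = 100L, end = 121L, count = 1L)
  expect_identical(star_present(dup, on_star), 1L)
  shifted <- tibble::tibble(start = 98L, end = 119L, count = 1L) # -2 nt slack
  expect_identical(star_present(dup, shifted), 1L)
  outside <- tibble::tibble(start = 60L, end = 81L, count = 1L)
  expect_identical(star_present(dup, outside), 0L)
  expect_identical(star_present(dup, on_star[0, ]), 0L)
})

test_that("signature log-odds matches a direct likelihood computation", {
  params <- default_parameter_set()
  dup <- tibble::tibble(star_start = 120L, star_end = 141L)
  # 5-read fixture: mature stack, jittered mature, star read, two scattered
  reads <- tibble::tibble(
    start = c(20L, 21L, 120L, 60L, 90L), end = c(41L, 42L, 141L, 81L, 111L),
    count = c(50L, 3L, 2L, 1L, 1L))
  got <- signature_logodds(300L, dup, 20L, 41L, reads, params)
  # direct summation: reads 1-3 consistent (5' within 2 nt of mature/star 5'),
  # loop is [41, 120) so the 60- and 90-start reads sit inside it: consistent
  k <- 0
  n <- sum(reads$count)
  p <- params$signature_geometric_p
  q <- ((2 * 2 + 1) * 2 + (120 - 41)) / 300
  expect_equal(got$loglik_real, log(p) + k * log(1 - p))
  expect_equal(got$loglik_bgr, (n - k) * log(q) + k * log(1 - q))
  expect_equal(got$logodds, got$loglik_real - got$loglik_bgr)
  expect_gt(got$logodds, 0)

  # scattered reads outside mature/star/loop are inconsistent and penalized
  dup2 <- tibble::tibble(star_start = 40L, star_end = 61L)
  scattered <- tibble::tibble(start = c(0L, 80L, 140L, 200L, 230L),
                              end = c(0L, 80L, 140L, 200L, 230L) + 21L,
                              count = rep(1L, 5))
  got2 <- signature_logodds(300L, dup2, 0L, 21L, scattered, params)
  k2 <- 4 # all but the mature-start read miss mature/star 5' ends and the loop
  q2 <- ((2 * 2 + 1) * 2 + (40 - 21)) / 300
  expect_equal(got2$loglik_real, log(p) + k2 * log(1 - p))
  expect_equal(got2$loglik_bgr, (5 - k2) * log(q2) + k2 * log(1 - q2))
  expect_lt(got2$logodds, 0)

  # doubling every count doubles both log-likelihoods' read-dependent parts
  dbl <- dplyr::mutate(reads, count = count * 2L)
  got_dbl <- signature_logodds(300L, dup, 20L, 41L, dbl, params)
  expect_identical(got_dbl$n_inconsistent, 2L * got$n_inconsistent)
  expect_equal(got_dbl$loglik_bgr, 2 * got$loglik_bgr)
})
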