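#' Fit the Gumbel (minimum extreme-value) family by maximum likelihood
#'
#' The minimum-Gumbel density is
#' `f(x) = (1/scale) exp(z - exp(z))`, `z = (x - location)/scale`; its
#' distribution function is `1 - exp(-exp(z))`. Fitting is maximum likelihood
#' via BFGS from a method-of-moments start (`scale0 = sd * sqrt(6)/pi`,
#' `location0 = mean + gamma * scale0`). The object also carries the sum of
#' absolute differences between the fitted and empirical CDFs at the sample
#' points, as a fit-quality diagnostic.
#'
#' @param x numeric sample (>= 30 values, not all equal).
#' @return an object of class `gumbel_fit` with elements `location`, `scale`,
#'   `loglik`, `cdf_abs_error`, `n`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_gumbel_min <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 30) abort("need at least 30 samples to fit the Gumbel family")
  if (sd(x) == 0) abort("degenerate (constant) sample; Gumbel fit undefined")
  gamma_e <- 0.5772156649015329
  scale0 <- sd(x) * sqrt(6) / pi
  loc0 <- mean(x) + gamma_e * scale0
  nll <- function(par) {
    beta <- exp(par[2])
    z <- (x - par[1]) / beta
    length(x) * log(beta) - sum(z) + sum(exp(z))
  }
  opt <- optim(c(loc0, log(scale0)), nll, method = "BFGS")
  location <- opt$par[1]
  scale <- exp(opt$par[2])
  fitted_cdf <- 1 - exp(-exp((sort(x) - location) / scale))
  emp <- seq_along(x) / length(x)
  structure(list(location = location, scale = scale, loglik = -opt$value,
                 cdf_abs_error = sum(abs(fitted_cdf - emp)), n = length(x)),
            class = "gumbel_fit")
}

#' Draw from the minimum-Gumbel distribution
#'
#' @param n number of draws.
#' @param location,scale distribution parameters (`scale > 0`).
#' @return numeric vector; `P(X <= x) = 1 - exp(-exp((x-location)/scale))`.
#' @export
rgumbel_min <- function(n, location, scale) {
  location + scale * log(-log(runif(n)))
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("<gumbel_fit (minimum)> location = %.4f, scale = %.4f (n = %d)\n",
              x$location, x$scale, x$n))
  cat(sprintf("  loglik = %.2f, sum |CDF error| = %.3f\n", x$loglik, x$cdf_abs_error))
  invisible(x)
}

#' Binned log-odds of normalized MFE between real and background precursors
#'
#' Both samples are histogrammed on a shared grid of fixed-width bins
#' (0.01 by default) and the per-bin log-odds `ln(freq_real / freq_bgr)` is
#' computed for every bin populated in both samples.
#'
#' @param real_mfe_normalized,bgr_mfe_normalized numeric samples of
#'   length-normalized MFE.
#' @param bin_width histogram bin width.
#' @return a tibble of class `binned_logodds` with columns `bin_left`,
#'   `bin_center`, `count_real`, `count_bgr`, `logodds` (`NA` where either
#'   count is zero).
#' @export
binned_logodds <- function(real_mfe_normalized, bgr_mfe_normalized,
                           bin_width = 0.01) {
  stopifnot(length(real_mfe_normalized) > 0, length(bgr_mfe_normalized) > 0)
  all_x <- c(real_mfe_normalized, bgr_mfe_normalized)
  lo <- floor(min(all_x) / bin_width) * bin_width
  hi <- ceiling(max(all_x) / bin_width + 1e-9) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  cr <- hist(real_mfe_normalized, breaks = breaks, plot = FALSE)$counts
  cb <- hist(bgr_mfe_normalized, breaks = breaks, plot = FALSE)$counts
  fr <- cr / sum(cr)
  fb <- cb / sum(cb)
  out <- tibble(
    bin_left = breaks[-length(breaks)],
    bin_center = breaks[-length(breaks)] + bin_width / 2,
    count_real = cr, count_bgr = cb,
    logodds = ifelse(cr > 0 & cb > 0, log(fr / fb), NA_real_))
  class(out) <- c("binned_logodds", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' @importFrom graphics hist
NULL

#' Fit the modified sigmoid to binned MFE log-odds
#'
#' Fits `f(x) = a / (b + exp(c x))` to `(bin center, log-odds)` pairs by
#' nonlinear least squares. The surface is numerically ill-conditioned when
#' `b` is negligible against `exp(c x)` over the observed range, so the solver
#' multi-starts over `c` in `{5, 15, 30, 45, 60}`; for each start `a` and `b`
#' are solved by the inner linearization `a - b y = y exp(c x)` (ordinary
#' least squares) and the triple is then refined with Levenberg-Marquardt.
#' The best residual sum of squares wins.
#'
#' @param binned a `binned_logodds` object, or any data frame with
#'   `bin_center` and `logodds` columns (at least 5 defined bins).
#' @param c_starts multi-start grid for the exponent.
#' @return an object of class `sigmoid_fit` with `a`, `b`, `c`, `rss`, `n`,
#'   and the (x, y) data. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_sigmoid <- function(binned, c_starts = c(5, 15, 30, 45, 60)) {
  df <- as.data.frame(binned)
  df <- df[is.finite(df$logodds), c("bin_center", "logodds")]
  if (nrow(df) < 5) abort("need at least 5 defined bins to fit the sigmoid")
  x <- df$bin_center; y <- df$logodds
  best <- NULL
  for (c0 in c_starts) {
    ex <- exp(c0 * x)
    # inner linearization: a - b*y = y*exp(c x)
    ab <- tryCatch(coef(lm(I(y * ex) ~ I(-y))), error = function(e) NULL)
    if (is.null(ab) || any(!is.finite(ab))) next
    a0 <- unname(ab[1]); b0 <- abs(unname(ab[2]))
    if (!is.finite(b0) || b0 <= 0) b0 <- max(abs(a0) / max(abs(y)), 1e-8)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (b + exp(c * x)),
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(-Inf, 1e-300, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                   rss = rss)
    }
  }
  if (is.null(best)) abort("sigmoid fit failed to converge from all starts")
  structure(c(best, list(n = length(x), x = x, y = y)), class = "sigmoid_fit")
}

#' @importFrom stats residuals
NULL

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> f(x) = a/(b + exp(c x)); a = %.6g, b = %.6g, c = %.4f\n",
              x$a, x$b, x$c))
  cat(sprintf("  rss = %.4g over %d bins\n", x$rss, x$n))
  invisible(x)
}

#' Discrete feature frequencies with pseudo-count substitution
#'
#' Estimates the frequency of a binary feature in the real and background
#' sets; any zero cell is replaced by the pseudo-count (and one minus it for a
#' full cell), so the log-odds are always defined. Returns the log-odds of
#' both the feature-present and feature-absent outcomes.
#'
#' @param real_flags,bgr_flags logical/0-1 vectors of feature values.
#' @param pseudo_count replacement frequency for empty cells (1/3000 is the
#'   shipped value for the background conserved-nucleus cell).
#' @return list with `p_real`, `p_bgr`, `logodds_present`, `logodds_absent`.
#' @export
estimate_discrete_frequencies <- function(real_flags, bgr_flags,
                                          pseudo_count = 1 / 3000) {
  freq <- function(flags) {
    if (!length(flags)) return(pseudo_count)
    p <- mean(as.integer(flags))
    if (p <= 0) pseudo_count else if (p >= 1) 1 - pseudo_count else p
  }
  p_real <- freq(real_flags)
  p_bgr <- freq(bgr_flags)
  list(p_real = p_real, p_bgr = p_bgr,
       logodds_present = discrete_logodds(p_real, p_bgr),
       logodds_absent = discrete_logodds(1 - p_real, 1 - p_bgr))
}

#' Positional conservation profile across miRNA families
#'
#' Within each family (a set of aligned, equal-length mature sequences) a
#' position is conserved when the modal non-gap residue reaches the
#' within-family threshold (0.9), with gaps counting as mismatches. The
#' profile counts, per position, how many families are conserved there;
#' conserved blocks are maximal runs of positions reaching the across-family
#' fraction threshold (0.75). Families with fewer than 2 members are excluded
#' with a notice.
#'
#' @param families a named list of character vectors; members of a family must
#'   share one aligned length (gap character `-` allowed).
#' @param within_threshold within-family modal-residue fraction for a
#'   conserved position.
#' @param across_threshold across-family fraction defining conserved blocks.
#' @return an object of class `conservation_profile`: list with `profile`
#'   (tibble `position`, `n_conserved`, `fraction`), `blocks` (tibble `start`,
#'   `end`), `per_family` (logical matrix), `n_families`.
#' @export
conservation_profile <- function(families, within_threshold = 0.9,
                                 across_threshold = 0.75) {
  sizes <- vapply(families, length, integer(1))
  if (any(sizes < 2)) {
    inform(sprintf("excluding %d famil%s with fewer than 2 members",
                   sum(sizes < 2), ifelse(sum(sizes < 2) == 1, "y", "ies")))
    families <- families[sizes >= 2]
  }
  if (!length(families)) abort("no family with >= 2 members")
  fam_cons <- map(families, function(members) {
    members <- toupper(members)
    lens <- unique(nchar(members))
    if (length(lens) != 1) {
      abort("family members must be aligned to a single length (use align_family())")
    }
    mat <- do.call(rbind, strsplit(members, "", fixed = TRUE))
    apply(mat, 2, function(col) {
      col <- col[col != "-"]
      if (!length(col)) return(FALSE)
      max(table(col)) / nrow(mat) >= within_threshold
    })
  })
  max_len <- max(vapply(fam_cons, length, integer(1)))
  per_family <- do.call(rbind, map(fam_cons, function(v) {
    c(v, rep(FALSE, max_len - length(v)))
  }))
  counts <- colSums(per_family)
  frac <- counts / length(families)
  ok <- frac >= across_threshold
  blocks <- if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tibble(start = starts[r$values], end = ends[r$values])
  } else {
    tibble(start = integer(), end = integer())
  }
  structure(list(
    profile = tibble(position = seq_len(max_len), n_conserved = as.integer(counts),
                     fraction = frac),
    blocks = blocks, per_family = per_family, n_families = length(families),
    within_threshold = within_threshold, across_threshold = across_threshold),
    class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d families, %d positions\n",
              x$n_families, nrow(x$profile)))
  if (nrow(x$blocks)) {
    cat(sprintf("  conserved blocks (>= %.2f of families): %s\n", x$across_threshold,
                paste(sprintf("%d-%d", x$blocks$start, x$blocks$end), collapse = ", ")))
  } else cat("  no conserved blocks\n")
  invisible(x)
}

#' Align a miRNA family by center-star alignment
#'
#' A convenience aligner for unaligned family members: the member with the
#' highest summed pairwise score is the center; all others are globally
#' aligned to it (match/mismatch/gap = +1/-1/-2 via Biostrings) and the
#' pairwise gaps are merged into one multiple alignment. This is a simple
#' internal aligner, not a CLUSTAL reimplementation; pre-aligned input can be
#' passed straight to [conservation_profile()].
#'
#' @param members character vector of (unaligned) sequences.
#' @return character vector of gapped sequences of equal length.
#' @export
align_family <- function(members) {
  members <- normalize_seq(members)
  if (length(members) < 2) return(members)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = FALSE)
  pa <- function(a, b) {
    Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sub_mat,
                                  gapOpening = 0, gapExtension = 2,
                                  type = "global")
  }
  score_sum <- vapply(seq_along(members), function(i) {
    sum(vapply(seq_along(members)[-i], function(j) {
      Biostrings::score(pa(members[i], members[j]))
    }, double(1)))
  }, double(1))
  center_i <- which.max(score_sum)
  center <- members[center_i]
  alns <- map(members[-center_i], function(m) pa(center, m))
  # merge: collect, per center position boundary, the max insertion length
  ins_len <- matrix(0L, nrow = length(alns), ncol = nchar(center) + 1L)
  parsed <- map(seq_along(alns), function(k) {
    al <- alns[[k]]
    pc <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sc <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    pos <- 0L
    segs <- vector("list", nchar(center) + 1L)
    cur <- character(0)
    aligned_at <- rep("-", nchar(center))
    for (t in seq_along(pc)) {
      if (pc[t] == "-") {
        cur <- c(cur, sc[t])
      } else {
        segs[[pos + 1L]] <- cur
        cur <- character(0)
        pos <- pos + 1L
        aligned_at[pos] <- sc[t]
      }
    }
    segs[[pos + 1L]] <- cur
    ins_len[k, ] <<- vapply(segs, length, integer(1))
    list(segs = segs, aligned = aligned_at)
  })
  max_ins <- apply(ins_len, 2, max)
  build <- function(aligned, segs) {
    out <- character(0)
    for (p in 0:nchar(center)) {
      seg <- segs[[p + 1L]]
      out <- c(out, seg, rep("-", max_ins[p + 1L] - length(seg)))
      if (p < nchar(center)) out <- c(out, aligned[p + 1L])
    }
    paste(out, collapse = "")
  }
  center_chars <- strsplit(center, "")[[1]]
  center_row <- build(center_chars, c(list(character(0)),
                                      rep(list(character(0)), nchar(center))))
  rows <- map_chr(parsed, function(p) build(p$aligned, p$segs))
  out <- character(length(members))
  out[center_i] <- center_row
  out[-center_i] <- rows
  out
}

#' Cross-validated frequency of nucleus conservation
#'
#' The mature library is shuffled once, split into 10 disjoint folds, and per
#' fold the fraction of held-out matures whose nucleus (positions 2-12 by
#' default) matches the nucleus of any training mature is recorded; the
#' 10-fold mean is returned.
#'
#' @param matures character vector of mature sequences (>= 10).
#' @param positions 1-based inclusive nucleus range.
#' @param folds number of folds.
#' @param seed integer seed for the single shuffle.
#' @return the mean conserved frequency in `[0, 1]`.
#' @export
nucleus_frequency_cv <- function(matures, positions = c(2L, 12L), folds = 10L,
                                 seed = 1L) {
  if (is.data.frame(matures)) matures <- matures$sequence
  if (length(matures) < folds) abort(sprintf("need at least %d matures", folds))
  matures <- normalize_seq(matures)
  nuclei <- substr(matures, positions[1], positions[2])
  perm <- withr::with_seed(seed, sample.int(length(nuclei)))
  shuffled <- nuclei[perm]
  fold_of <- rep_len(seq_len(folds), length(nuclei))
  freqs <- map_dbl(seq_len(folds), function(f) {
    test <- shuffled[fold_of == f]
    train <- shuffled[fold_of != f]
    mean(test %in% train)
  })
  mean(freqs)
}

#' Choose a precursor excision length from a length distribution
#'
#' Returns the smallest observed length `L` whose empirical CDF reaches the
#' requested coverage while at least `min_tail_sample` precursors have length
#' within `window` nt of `L` (so that parameters can still be estimated from
#' an adequate sample near the chosen length).
#'
#' @param precursor_lengths integer vector of known precursor lengths.
#' @param coverage target fraction of precursors covered, in `(0, 1]`.
#' @param min_tail_sample minimum sample size near the chosen length.
#' @param window half-width (nt) of the near-`L` estimation window.
#' @return the selected length (integer).
#' @export
select_excision_length <- function(precursor_lengths, coverage,
                                   min_tail_sample = 30L, window = 30L) {
  stopifnot(length(precursor_lengths) > 0, coverage > 0, coverage <= 1)
  lens <- sort(precursor_lengths)
  cands <- unique(lens)
  cdf <- ecdf(lens)
  tail_ok <- vapply(cands, function(L) {
    sum(abs(lens - L) <= window) >= min_tail_sample
  }, logical(1))
  cov_ok <- cdf(cands) >= coverage
  sel <- cands[cov_ok & tail_ok]
  if (!length(sel)) {
    feasible <- cands[tail_ok]
    best <- if (length(feasible)) max(cdf(feasible)) else 0
    abort(sprintf("coverage %.3f unattainable with tail sample >= %d; best feasible coverage %.3f",
                  coverage, min_tail_sample, best))
  }
  sel[1]
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value is
#' the asymptotic KS formula (via [stats::ks.test()]).
#'
#' @param x,y numeric samples (each >= 5 values).
#' @return a tibble with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 5 || length(y) < 5) abort("need at least 5 values per sample")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Linear dependence of |MFE| on precursor length
#'
#' Groups |MFE| into length bins, reports the per-bin mean and standard
#' deviation, and the least-squares slope of mean |MFE| against mean length.
#'
#' @param lengths precursor lengths (nt).
#' @param mfe minimum free energies (kcal/mol; absolute value is taken).
#' @param bin_width length-bin width (nt).
#' @return list with `slope`, `intercept`, and `bins` (tibble `mean_length`,
#'   `mean_abs_mfe`, `sd_abs_mfe`, `n`).
#' @export
mfe_length_regression <- function(lengths, mfe, bin_width = 10) {
  stopifnot(length(lengths) == length(mfe))
  df <- tibble(length = lengths, abs_mfe = abs(mfe)) |>
    mutate(bin = floor(.data$length / bin_width)) |>
    group_by(.data$bin) |>
    summarise(mean_length = mean(.data$length),
              mean_abs_mfe = mean(.data$abs_mfe),
              sd_abs_mfe = ifelse(dplyr::n() > 1, sd(.data$abs_mfe), 0),
              n = dplyr::n(), .groups = "drop")
  if (nrow(df) < 2) abort("need at least 2 length bins")
  fit <- lm(mean_abs_mfe ~ mean_length, data = df)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       bins = select(df, -"bin"))
}
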