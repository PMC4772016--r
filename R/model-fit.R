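#' Tabulate link counts for contig pairs
#'
#' Counts inter-contig pairs per unordered contig pair; a convenience input
#' for [estimate_noise_product()].
#'
#' @param pairs tibble with columns `chr1`, `chr2` (contig ids); intra-contig
#'   rows are ignored.
#' @return tibble with columns `contig1`, `contig2`, `n` (`contig1 < contig2`).
#' @export
contig_pair_counts <- function(pairs) {
  inter <- pairs[pairs$chr1 != pairs$chr2, , drop = FALSE]
  if (nrow(inter) == 0) {
    return(tibble(contig1 = character(0), contig2 = character(0),
                  n = integer(0)))
  }
  a <- pmin(inter$chr1, inter$chr2)
  b <- pmax(inter$chr1, inter$chr2)
  tibble(contig1 = a, contig2 = b) %>%
    dplyr::count(.data$contig1, .data$contig2, name = "n")
}

#' Estimate the expected number of noise pairs (N * p_n)
#'
#' Noise pairs sample the genome independently, so for an unrelated contig
#' pair `(i, j)` the expected link count is `2 N p_n l_i l_j / G^2`. The
#' estimator tabulates link densities `n_ij / (l_i l_j)` over a random sample
#' of contig pairs, drops the top and bottom `trim` fraction of the densities
#' (removing genuinely linked neighbours and repeat-inflated outliers), and
#' inverts the expectation on the retained pairs:
#' \deqn{\widehat{N p_n} = \frac{G^2 \sum n_{ij}}{2 \sum l_i l_j}.}
#'
#' @param counts contig-pair link counts from [contig_pair_counts()] (pairs
#'   absent from the table count as zero links).
#' @param contigs tibble with columns `contig`, `length`.
#' @param G effective genome size (bp); defaults to the summed contig length.
#' @param trim fraction trimmed from each tail of the density distribution
#'   (default 0.01).
#' @param n_sample number of random contig pairs sampled (default 50000; all
#'   pairs are used when fewer exist).
#' @param seed integer seed for the contig-pair sample.
#' @return the estimated expected noise-pair count (nonnegative scalar) with
#'   attribute `n_retained`.
#' @export
estimate_noise_product <- function(counts, contigs, G = sum(contigs$length),
                                   trim = 0.01, n_sample = 50000, seed = 1) {
  assert_that(trim >= 0 && trim < 0.5, "`trim` must be in [0, 0.5)")
  nc <- nrow(contigs)
  assert_that(nc >= 2, "need at least 2 contigs")
  n_all <- nc * (nc - 1) / 2
  assert_that(n_all >= 10, "need at least 10 contig pairs")
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  if (n_all <= n_sample) {
    idx <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
  } else {
    ij <- with_seed(derive_seed(seed, "noise-sample"), {
      i <- sample.int(nc, 2 * n_sample, replace = TRUE)
      j <- sample.int(nc, 2 * n_sample, replace = TRUE)
      keep <- i != j
      unique(cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE])[
        seq_len(n_sample), , drop = FALSE]
    })
    i <- ij[, 1]; j <- ij[, 2]
  }
  cnt <- setNames(counts$n, key(match(counts$contig1, contigs$contig),
                                 match(counts$contig2, contigs$contig)))
  nij <- cnt[key(i, j)]
  nij[is.na(nij)] <- 0
  lij <- contigs$length[i] * contigs$length[j]
  dens <- nij / lij
  if (all(dens == 0)) {
    warn("all sampled contig-pair densities are zero; returning 0")
    est <- 0
    retained <- length(dens)
  } else {
    ord <- order(dens)
    k <- floor(trim * length(dens))
    keep <- ord[seq(k + 1, length(dens) - k)]
    est <- G^2 * sum(nij[keep]) / (2 * sum(lij[keep]))
    retained <- length(keep)
    if (est == 0 && sum(nij) > 0) {
      # noise so sparse that quantile trimming removed every nonzero count:
      # switch to value-based exclusion over the full contig-pair population
      # (a count is kept while compatible with the Poisson noise expectation)
      warn(paste("quantile trimming removed every linked contig pair",
                 "(sparse counts); using value-based exclusion instead"))
      est <- noise_product_value_excluded(counts, contigs, G)
    }
  }
  structure(max(est, 0), n_retained = retained)
}

# full-population noise estimate: all-zero pairs enter the denominator in
# closed form; observed counts are excluded when they exceed the 0.999
# Poisson quantile of the current noise expectation; iterated to a fix point
noise_product_value_excluded <- function(counts, contigs, G) {
  l <- contigs$length
  sum_lij_all <- (sum(l)^2 - sum(l^2)) / 2
  li <- l[match(counts$contig1, contigs$contig)]
  lj <- l[match(counts$contig2, contigs$contig)]
  lij <- li * lj
  est <- G^2 * sum(counts$n) / (2 * sum_lij_all)
  for (it in 1:4) {
    mu <- 2 * est * lij / G^2
    keep <- counts$n <= pmax(1, stats::qpois(0.999, mu))
    est_new <- G^2 * sum(counts$n[keep]) /
      (2 * (sum_lij_all - sum(lij[!keep])))
    if (abs(est_new - est) < 1e-6 * max(est, 1)) {
      est <- est_new
      break
    }
    est <- est_new
  }
  est
}

#' Edge-corrected separation histogram
#'
#' A separation `x` can only be observed inside a contig of length `l_i` from
#' one of `max(0, l_i - x)` start positions, so raw separation counts are
#' biased against large `x` on a fragmented assembly. The corrected histogram
#' multiplies the width-normalised counts at separation `x` by
#' `G / sum_i max(0, l_i - x)`, yielding an estimate proportional to
#' `N f(x)` free of finite-contig edge bias.
#'
#' @param separations numeric vector of intra-contig pair separations (bp).
#' @param contig_lengths numeric vector of contig lengths (bp).
#' @param G effective genome size (bp); defaults to the summed contig length.
#' @param bins number of log-spaced bins (default 200) or an explicit vector
#'   of strictly increasing bin edges.
#' @param max_sep upper edge of the histogram (bp; default the largest
#'   observed separation).
#' @return a tibble with columns `lo`, `hi`, `mid` (geometric midpoint),
#'   `count`, `density` (count per bp), `correction`, `corrected`
#'   (`~ N f(mid)`), and `usable` (FALSE where no contig admits the
#'   separation).
#' @export
separation_histogram <- function(separations, contig_lengths,
                                 G = sum(contig_lengths), bins = 200,
                                 max_sep = max(separations)) {
  separations <- separations[separations >= 1]
  if (length(bins) == 1) {
    # separations are integers: log-spaced edges snapped to whole bp so no
    # bin is narrower than 1 bp
    edges <- unique(floor(exp(seq(log(1), log(max_sep + 1),
                                  length.out = bins + 1))))
  } else {
    edges <- bins
  }
  assert_that(all(diff(edges) > 0), "bin edges must be strictly increasing")
  cut_idx <- findInterval(separations, edges, rightmost.closed = TRUE)
  cut_idx <- cut_idx[cut_idx >= 1 & cut_idx <= length(edges) - 1]
  count <- tabulate(cut_idx, nbins = length(edges) - 1)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  mid <- sqrt(lo * hi)
  denom <- vapply(mid, function(x) sum(pmax(0, contig_lengths - x)),
                  numeric(1))
  usable <- denom > 0
  correction <- ifelse(usable, G / denom, NA_real_)
  tibble(
    lo = lo, hi = hi, mid = mid, count = count,
    density = count / (hi - lo),
    correction = correction,
    corrected = .data$density * correction,
    usable = usable
  )
}

#' Fit the exponential-mixture separation model by least squares
#'
#' Fits `N f(x) = N p_n / G + N (1 - p_n) f'(x)` to an edge-corrected
#' separation histogram with the noise floor `N p_n / G` held fixed at the
#' [estimate_noise_product()] estimate. Rates are selected greedily on a
#' log-spaced grid with component amplitudes solved by nonnegative least
#' squares at each step, then polished by Nelder-Mead on the log rates.
#' Degenerate solutions (two rates within 1%) are merged; `K` is reduced with
#' a warning when the histogram has fewer than `3 K` usable bins.
#'
#' @param hist a [separation_histogram()] tibble.
#' @param noise_product the estimated expected noise-pair count (`N p_n`).
#' @param K number of exponential components (default 3).
#' @param G effective genome size (bp).
#' @param max_span truncation of the exponential part (bp).
#' @param n_grid size of the log-spaced rate grid (default 40).
#' @return a [link_model()] with attribute `residual` (residual sum of
#'   squares of the fit).
#' @export
fit_mixture <- function(hist, noise_product, K = 3, G,
                        max_span = 150000, n_grid = 40) {
  usable <- hist$usable & is.finite(hist$corrected)
  h <- hist[usable, , drop = FALSE]
  if (nrow(h) < 3 * K) {
    K_new <- max(1, floor(nrow(h) / 3))
    warn(sprintf("only %d usable bins: reducing K from %d to %d",
                 nrow(h), K, K_new))
    K <- K_new
  }
  x <- h$mid
  # weight bins by width/correction: least squares in raw-count space, so a
  # wide sparse tail bin and a narrow dense short-range bin count equitably
  wgt <- (h$hi - h$lo) / h$correction
  y <- pmax(h$corrected - noise_product / G, 0)

  lo_rate <- 0.1 / max_span
  hi_rate <- 0.1
  basis <- function(rates) {
    Z <- 1 - exp(-rates * max_span)
    vapply(seq_along(rates), function(k) {
      b <- rates[k] * exp(-rates[k] * x) / Z[k]
      b[x > max_span] <- 0
      b
    }, numeric(length(x)))
  }
  nnls_fit <- function(rates) {
    B <- basis(rates) * wgt
    A <- tryCatch(solve_nnls(B, y * wgt), error = function(e) rep(0, ncol(B)))
    list(A = A, rss = sum((y * wgt - B %*% A)^2))
  }

  grid <- exp(seq(log(lo_rate), log(hi_rate), length.out = n_grid))
  chosen <- numeric(0)
  for (k in seq_len(K)) {    # greedy forward selection of rates
    cand <- setdiff(grid, chosen)
    rss <- vapply(cand, function(r) nnls_fit(c(chosen, r))$rss, numeric(1))
    chosen <- c(chosen, cand[which.min(rss)])
  }
  opt <- stats::optim(log(chosen), function(lr) nnls_fit(exp(lr))$rss,
                      method = "L-BFGS-B",
                      lower = log(lo_rate), upper = log(hi_rate),
                      control = list(maxit = 500))
  rates <- exp(opt$par)
  fit <- nnls_fit(rates)
  A <- fit$A
  keep <- A > 0
  if (!any(keep)) { keep[which.max(A)] <- TRUE; A[which.max(A)] <- 1e-12 }
  rates <- rates[keep]; A <- A[keep]

  N_signal <- sum(A)
  N <- N_signal + noise_product
  p_n <- if (N > 0) noise_product / N else 0
  model <- link_model(
    G = G, N = N, p_n = p_n,
    components = tibble(weight = A / sum(A), rate = rates),
    max_span = max_span
  )
  attr(model, "residual") <- fit$rss
  model
}

# nonnegative least squares via active-set (Lawson-Hanson); small K only
solve_nnls <- function(B, y) {
  k <- ncol(B)
  best <- NULL
  # enumerate active sets: k is tiny (<= 6), so 2^k subsets is cheapest
  for (mask in seq_len(2^k) - 1) {
    on <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(on) == 0) {
      cand <- rep(0, k)
    } else {
      beta <- tryCatch(qr.solve(B[, on, drop = FALSE], y),
                       error = function(e) NULL)
      if (is.null(beta) || any(beta < 0)) next
      cand <- rep(0, k)
      cand[on] <- beta
    }
    rss <- sum((y - B %*% cand)^2)
    if (is.null(best) || rss < best$rss) best <- list(coef = cand, rss = rss)
  }
  best$coef
}
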