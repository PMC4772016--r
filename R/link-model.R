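#' Construct a Chicago pair-separation likelihood model
#'
#' The separation `x` (bp) of a proximity-ligation read pair is modelled as a
#' two-part density: with probability `p_n` the pair is "noise" (its two ends
#' sample the genome independently, giving a uniform density `1/G`), and with
#' probability `1 - p_n` it is a true ligation product whose separation
#' follows a mixture of exponential distributions truncated at `max_span`
#' (the input DNA fragment length caps the achievable separation):
#' \deqn{f(x) = p_n/G + (1 - p_n) \sum_k a_k \lambda_k e^{-\lambda_k x} / Z_k,}
#' with \eqn{Z_k = 1 - e^{-\lambda_k M}} renormalising each truncated
#' component.
#'
#' @param G effective genome size (bp).
#' @param N total number of usable read pairs.
#' @param p_n noise fraction in `[0, 1]`.
#' @param components tibble with columns `weight` and `rate` (1/bp); weights
#'   must sum to 1, rates must be positive. Stored in canonical order of
#'   strictly decreasing rate; components closer than 1% in rate are merged.
#' @param max_span support cutoff (bp) of the exponential part, i.e. the
#'   input DNA fragment length.
#' @return an object of class `link_model`.
#' @examples
#' m <- link_model(G = 5e7, N = 1e5, p_n = 0.01)
#' pair_density(c(0, 1000, 2e5), m)
#' @export
link_model <- function(G, N, p_n,
                       components = chicago_mixture(),
                       max_span = 150000) {
  components <- as_tibble(components)
  assert_that(all(c("weight", "rate") %in% names(components)),
              "`components` needs columns `weight` and `rate`")
  assert_that(G > 0, "`G` must be positive")
  assert_that(N >= 0, "`N` must be nonnegative")
  assert_that(p_n >= 0 && p_n <= 1, "`p_n` must lie in [0, 1]")
  assert_that(all(components$rate > 0), "all mixture rates must be positive")
  assert_that(abs(sum(components$weight) - 1) <= 1e-9,
              "mixture weights must sum to 1")
  assert_that(max_span > 0, "`max_span` must be positive")
  components <- merge_close_rates(components)
  components <- components[order(components$rate, decreasing = TRUE), ]
  structure(
    list(G = as.numeric(G), N = as.numeric(N), p_n = as.numeric(p_n),
         components = components, max_span = as.numeric(max_span)),
    class = "link_model"
  )
}

# components whose rates differ by < 1% are indistinguishable at fit
# resolution; pool their weights
merge_close_rates <- function(components) {
  components <- components[order(components$rate, decreasing = TRUE), ]
  keep <- rep(TRUE, nrow(components))
  for (i in seq_len(nrow(components))[-1]) {
    j <- max(which(keep[seq_len(i - 1)]))
    if (abs(components$rate[i] - components$rate[j]) <
        0.01 * components$rate[j]) {
      components$weight[j] <- components$weight[j] + components$weight[i]
      keep[i] <- FALSE
    }
  }
  components[keep, ]
}

#' @export
print.link_model <- function(x, ...) {
  cat("<link_model>\n")
  cat(sprintf("  G = %.4g bp, N = %.4g pairs, p_n = %.4g, max_span = %g bp\n",
              x$G, x$N, x$p_n, x$max_span))
  cat(sprintf("  %d exponential component(s):\n", nrow(x$components)))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("    weight %.4f  rate %.4g /bp  (mean %.0f bp)\n",
                x$components$weight[i], x$components$rate[i],
                1 / x$components$rate[i]))
  }
  invisible(x)
}

# per-component truncation normalisers
trunc_norm <- function(model) 1 - exp(-model$components$rate * model$max_span)

#' Pair-separation probability density
#'
#' Evaluates the separation density of the link model: a uniform noise floor
#' `p_n / G` (for all separations up to the genome size) plus the truncated
#' exponential mixture.
#'
#' @param x separations (bp), nonnegative.
#' @param model a [link_model()].
#' @return density values (1/bp), strictly positive.
#' @export
pair_density <- function(x, model) {
  assert_that(all(x >= 0), "separations must be nonnegative")
  w <- model$components$weight
  lam <- model$components$rate
  Z <- trunc_norm(model)
  sig <- numeric(length(x))
  ok <- x <= model$max_span
  if (any(ok)) {
    xs <- x[ok]
    acc <- numeric(length(xs))
    for (k in seq_along(lam)) {
      acc <- acc + w[k] * lam[k] * exp(-lam[k] * xs) / Z[k]
    }
    sig[ok] <- acc
  }
  model$p_n / model$G + (1 - model$p_n) * sig
}

log_noise_floor <- function(model) {
  log(max(model$p_n / model$G, .DENS_FLOOR))
}

# per-pair LLR contribution of an observed separation: log f(d) - log(p_n/G)
llr_terms <- function(d, model) {
  log(pmax(pair_density(d, model), .DENS_FLOOR)) - log_noise_floor(model)
}

#' Implied genomic separation of a spanning pair under a join hypothesis
#'
#' Given two contigs laid left-to-right with a gap `g` between them and a
#' relative orientation `o`, a read pair with offsets `x1` (within contig 1,
#' own coordinates) and `x2` (within contig 2) implies a genomic separation:
#' the distance from the read on contig 1 to the gap, plus `g`, plus the
#' distance from the gap to the read on contig 2.
#'
#' @param x1,x2 read offsets (bp, 0-based) within contigs 1 and 2.
#' @param l1,l2 contig lengths (bp).
#' @param g gap size (bp), finite and nonnegative.
#' @param orientation one of `"++"`, `"+-"`, `"-+"`, `"--"` giving the strand
#'   of each contig in the layout.
#' @return implied separations (bp), always `>= g`.
#' @export
implied_separation <- function(x1, x2, l1, l2, g, orientation) {
  assert_that(is.finite(g) && g >= 0,
              "gap must be finite and nonnegative for an implied separation")
  assert_that(all(x1 >= 0 & x1 < l1) && all(x2 >= 0 & x2 < l2),
              "offsets must lie within contig bounds")
  left <- switch(substr(orientation, 1, 1),
                 "+" = l1 - x1,
                 "-" = x1,
                 abort("bad orientation"))
  right <- switch(substr(orientation, 2, 2),
                  "+" = x2,
                  "-" = l2 - x2,
                  abort("bad orientation"))
  left + g + right
}

#' Probability that a random pair spans a candidate join
#'
#' The spanning probability `P0` is the chance that a single read pair, with
#' one end placed uniformly on the genome and separation drawn from the pair
#' density, lands with one end in contig 1 and the other in contig 2 across a
#' gap of size `g`:
#' \deqn{P_0 = \frac{1}{G}\int f(x)\, c(x)\, dx,\quad
#'       c(x) = \max(0, \min(l_1, l_2, x - g, l_1 + l_2 + g - x)).}
#' The integral is evaluated in closed form for each exponential component
#' (the spanning-count kernel `c(x)` is piecewise linear) plus the uniform
#' noise term `p_n l_1 l_2 / G^2`.
#'
#' @param l1,l2 contig lengths (bp), positive. Vectorised.
#' @param g gap sizes (bp), finite and nonnegative. Vectorised.
#' @param model a [link_model()].
#' @return spanning probabilities in `[0, 1]`.
#' @export
span_probability <- function(l1, l2, g, model) {
  assert_that(all(l1 > 0) && all(l2 > 0), "contig lengths must be positive")
  assert_that(all(is.finite(g) & g >= 0), "gaps must be finite and nonnegative")
  nn <- max(length(l1), length(l2), length(g))
  l1 <- rep_len(as.numeric(l1), nn)
  l2 <- rep_len(as.numeric(l2), nn)
  g <- rep_len(as.numeric(g), nn)
  mn <- pmin(l1, l2)
  mx <- pmax(l1, l2)
  M <- model$max_span
  w <- model$components$weight
  lam <- model$components$rate
  Z <- trunc_norm(model)

  # closed-form \int_s^t lambda e^{-lambda x} (alpha + beta x) dx
  piece <- function(lam, s, t, alpha, beta) {
    s2 <- pmin(pmax(s, 0), M)
    t2 <- pmin(pmax(t, 0), M)
    bad <- t2 <= s2
    val <- exp(-lam * s2) * (alpha + beta * s2 + beta / lam) -
      exp(-lam * t2) * (alpha + beta * t2 + beta / lam)
    val[bad] <- 0
    val
  }

  sig <- numeric(nn)
  for (k in seq_along(lam)) {
    ik <- piece(lam[k], g, g + mn, -g, 1) +
      piece(lam[k], g + mn, g + mx, mn, 0) +
      piece(lam[k], g + mx, g + l1 + l2, g + l1 + l2, -1)
    sig <- sig + w[k] * ik / Z[k]
  }
  p0 <- model$p_n * l1 * l2 / model$G^2 + (1 - model$p_n) * sig / model$G
  pmin(pmax(p0, 0), 1)
}

#' Join log-likelihood of observed spanning pairs (up to a shared constant)
#'
#' Scores the hypothesis that two contigs are joined at gap `g` with
#' orientation `o`, given the `n` pairs observed to span them with offsets
#' `(x1, x2)`: the non-spanning pairs contribute
#' `(N - n) log(1 - P0)` and each spanning pair contributes the log density
#' of its implied separation. The combinatorial prefactor `N!/(N-n)!` of the
#' full likelihood is omitted: `n` is identical across every pair of
#' hypotheses the pipeline compares (gap vs gap, orientation vs orientation,
#' join vs no join), so the prefactor cancels in all ratios.
#'
#' @param offsets tibble (or data frame) with columns `x1`, `x2`; may have
#'   zero rows.
#' @inheritParams implied_separation
#' @param model a [link_model()].
#' @return a log-likelihood in nats (up to an additive constant shared across
#'   `g` and `orientation`).
#' @export
join_log_likelihood <- function(offsets, l1, l2, g, orientation, model) {
  d <- if (nrow(offsets) > 0) {
    implied_separation(offsets$x1, offsets$x2, l1, l2, g, orientation)
  } else numeric(0)
  if (any(d < 0)) abort("internal error: negative implied separation")
  p0 <- span_probability(l1, l2, g, model)
  (model$N - length(d)) * log1p(-p0) +
    sum(log(pmax(pair_density(d, model), .DENS_FLOOR)))
}

#' Log-likelihood ratio supporting a contig join
#'
#' `join_llr()` compares the join hypothesis at finite gap `g` against the
#' unlinked hypothesis (`g = infinity`), under which every observed pair is
#' scored as noise (density `p_n/G`) and the spanning term vanishes:
#' \deqn{LLR = \log L(g, o) - \log L(g = \infty)
#'     = (N - n)\log(1 - P_0) + \sum_i \left[\log f(d_i) - \log(p_n/G)\right].}
#' Positive values support the join. With `g = Inf` the ratio is identically
#' zero. Pairs whose implied separation exceeds `max_span` fall on the noise
#' floor and contribute 0.
#'
#' @inheritParams join_log_likelihood
#' @param g gap size (bp); may be `Inf`, in which case 0 is returned.
#' @return LLR in nats.
#' @export
join_llr <- function(offsets, l1, l2, g, orientation, model) {
  if (is.infinite(g)) return(0)
  n <- nrow(offsets)
  if (model$p_n == 0 && n > 0) {
    warn("degenerate model: p_n = 0 with linking pairs; LLR is +Inf")
    return(Inf)
  }
  d <- if (n > 0) {
    implied_separation(offsets$x1, offsets$x2, l1, l2, g, orientation)
  } else numeric(0)
  if (any(d < 0)) abort("internal error: negative implied separation")
  p0 <- span_probability(l1, l2, g, model)
  (model$N - n) * log1p(-p0) + sum(llr_terms(d, model))
}

#' Broom-style tidiers for link models
#'
#' `tidy()` returns one row per mixture component; `glance()` returns a
#' one-row summary of the global parameters.
#'
#' @param x a [link_model()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy link_model
#' @export
tidy.link_model <- function(x, ...) {
  Z <- trunc_norm(x)
  tibble(
    component = seq_len(nrow(x$components)),
    weight = x$components$weight,
    rate = x$components$rate,
    mean_separation = 1 / x$components$rate -
      x$max_span * exp(-x$components$rate * x$max_span) / Z
  )
}

#' @rdname tidy.link_model
#' @method glance link_model
#' @export
glance.link_model <- function(x, ...) {
  tibble(
    G = x$G, N = x$N, p_n = x$p_n, max_span = x$max_span,
    n_components = nrow(x$components),
    mean_separation = sum(tidy(x)$weight * tidy(x)$mean_separation),
    residual = attr(x, "residual") %||% NA_real_
  )
}

#' Serialise / deserialise a link model as JSON
#'
#' @param model a [link_model()].
#' @param path file path.
#' @return `read_link_model()` returns a [link_model()];
#'   `write_link_model()` returns `path` invisibly.
#' @export
write_link_model <- function(model, path) {
  jsonlite::write_json(
    list(G = model$G, N = model$N, p_n = model$p_n,
         weights = model$components$weight,
         rates = model$components$rate,
         max_span = model$max_span),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_link_model
#' @export
read_link_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  link_model(G = x$G, N = x$N, p_n = x$p_n,
             components = tibble(weight = x$weights, rate = x$rates),
             max_span = x$max_span)
}
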