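#' Log-likelihood ratio for a heterozygous inversion
#'
#' Tests a candidate inversion `[b1, b2)` against mapped pairs of the
#' surrounding region. Under the heterozygous hypothesis each pair originates
#' from the inverted haplotype with probability 1/2; a read mapped inside the
#' inversion then appears at the reflected coordinate
#' `x -> b1 + b2 - 1 - x`. The per-pair likelihood is therefore an equal
#' mixture of the separation density at the observed separation `d_ref` and
#' at the separation `d_inv` implied by reflecting in-interval read
#' coordinates:
#' \deqn{LLR = \sum_i \log\left[\tfrac12 f(d_{ref,i}) +
#'   \tfrac12 f(d_{inv,i})\right] - \log f(d_{ref,i}).}
#' Pairs with both or neither end inside the interval contribute exactly 0
#' (reflection preserves their separations); only breakpoint-straddling pairs
#' are informative. Positive values favour the inversion.
#'
#' @param pairs pair tibble with `pos1`, `pos2` (single region/contig).
#' @param b1,b2 inversion breakpoints (bp, `b1 < b2`, 0-based half-open).
#' @param model a [link_model()].
#' @return the LLR (nats), with attribute `n_informative`; 0 with attribute
#'   `flagged = TRUE` when no pair overlaps
#'   `[b1 - max_span, b2 + max_span)`.
#' @export
inversion_llr <- function(pairs, b1, b2, model) {
  assert_that(b1 < b2, "`b1` must be < `b2`")
  x1 <- pairs$pos1
  x2 <- pairs$pos2
  near <- pmax(x1, x2) >= b1 - model$max_span &
    pmin(x1, x2) < b2 + model$max_span
  x1 <- x1[near]; x2 <- x2[near]
  if (length(x1) == 0) {
    out <- 0
    attr(out, "flagged") <- TRUE
    attr(out, "n_informative") <- 0L
    return(out)
  }
  refl <- function(x) ifelse(x >= b1 & x < b2, b1 + b2 - 1 - x, x)
  d_ref <- abs(x2 - x1)
  d_inv <- abs(refl(x2) - refl(x1))
  f_ref <- pmax(pair_density(d_ref, model), .DENS_FLOOR)
  f_inv <- pmax(pair_density(d_inv, model), .DENS_FLOOR)
  out <- sum(log(0.5 * f_ref + 0.5 * f_inv) - log(f_ref))
  attr(out, "flagged") <- FALSE
  attr(out, "n_informative") <- sum(d_ref != d_inv)
  out
}

#' Classify an inversion LLR
#'
#' Labels a candidate as `"inversion"` iff the LLR strictly exceeds the
#' threshold (a score exactly at the threshold is called `"reference"`).
#'
#' @param llr LLR value(s) in nats.
#' @param threshold decision threshold (default 0).
#' @return character vector of labels.
#' @export
classify_inversion <- function(llr, threshold = 0) {
  ifelse(as.numeric(llr) > threshold, "inversion", "reference")
}

#' Sensitivity and specificity of the inversion discriminator by simulation
#'
#' Runs `n_trials` heterozygous-inversion trials and `n_trials` null trials
#' of length-`L` candidate intervals (breakpoint masking `W` applied to
#' both), scores each with [inversion_llr()] at the known breakpoints
#' (detection, not discovery), and classifies at the given threshold.
#' Sensitivity is the fraction of heterozygous trials called inversions;
#' specificity the fraction of null trials called reference. Binomial 95%
#' confidence intervals are Wilson intervals.
#'
#' @param L inversion length (bp).
#' @param W breakpoint masking distance (bp).
#' @param n_trials trials per arm.
#' @param config a [sim_config()], typically [calibrate_sim_config()].
#' @param model the [link_model()] used for scoring; defaults to the model
#'   implied by `config` (same mixture, noise and pair count).
#' @param seed integer seed.
#' @param threshold LLR decision threshold (default 0).
#' @param flank region flank per side (bp, default 100 kbp).
#' @return one-row tibble `L`, `W`, `n_trials`, `sensitivity`, `sens_lo`,
#'   `sens_hi`, `specificity`, `spec_lo`, `spec_hi`, with attribute `trials`
#'   (per-trial tibble).
#' @export
evaluate_discriminator <- function(L, W, n_trials, config,
                                   model = NULL, seed = 1,
                                   threshold = 0, flank = 1e5) {
  assert_that(n_trials >= 1, "`n_trials` must be >= 1")
  if (is.null(model)) {
    model <- link_model(G = config$genome_length, N = config$n_pairs,
                        p_n = config$noise_fraction,
                        components = config$mixture,
                        max_span = config$max_fragment_length)
  }
  one <- function(i, het) {
    tr <- simulate_inversion_trial(L, W, het, config,
                                   seed = derive_seed(seed, paste0(
                                     "trial-", het, "-", i)),
                                   flank = flank)
    llr <- inversion_llr(tr, attr(tr, "b1"), attr(tr, "b2"), model)
    tibble(trial = i, het = het, llr = as.numeric(llr),
           n_informative = attr(llr, "n_informative"),
           call = classify_inversion(llr, threshold))
  }
  trials <- bind_rows(
    purrr::map_dfr(seq_len(n_trials), one, het = TRUE),
    purrr::map_dfr(seq_len(n_trials), one, het = FALSE)
  )
  wilson <- function(k, n) {
    z <- 1.959964
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
  }
  k_sens <- sum(trials$call == "inversion" & trials$het)
  k_spec <- sum(trials$call == "reference" & !trials$het)
  ci_sens <- wilson(k_sens, n_trials)
  ci_spec <- wilson(k_spec, n_trials)
  out <- tibble(
    L = L, W = W, n_trials = n_trials,
    sensitivity = k_sens / n_trials,
    sens_lo = ci_sens[1], sens_hi = ci_sens[2],
    specificity = k_spec / n_trials,
    spec_lo = ci_spec[1], spec_hi = ci_spec[2]
  )
  attr(out, "trials") <- trials
  out
}
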