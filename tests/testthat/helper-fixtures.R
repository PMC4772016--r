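# shared fixtures: small models and simulated data sets built in code

# a mid-sized model with the default calibrated mixture
default_model <- function(G = 5e7, N = 1e5, p_n = 0.01) {
  link_model(G = G, N = N, p_n = p_n)
}

# single-exponential model: closed forms are easy to verify by hand
single_exp_model <- function(rate = 1e-3, G = 1e7, N = 1e4, p_n = 0.02,
                             max_span = 1e5) {
  link_model(G = G, N = N, p_n = p_n,
             components = tibble::tibble(weight = 1, rate = rate),
             max_span = max_span)
}

# simulate intra-contig offsets for a clean contig of length `len` under a
# model: pair starts uniform, separations from the truncated mixture,
# conditioned on both ends inside the contig
sim_contig_offsets <- function(len, model, pairs_per_bp, seed) {
  withr::with_seed(seed, {
    n <- rpois(1, pairs_per_bp * len)
    x1 <- runif(n, 0, len)
    k <- sample.int(nrow(model$components), n, replace = TRUE,
                    prob = model$components$weight)
    lam <- model$components$rate[k]
    u <- runif(n)
    d <- -log(1 - u * (1 - exp(-lam * model$max_span))) / lam
    x2 <- x1 + d * sample(c(-1, 1), n, replace = TRUE)
    keep <- x2 >= 0 & x2 < len
    lo <- floor(pmin(x1, x2)[keep])
    hi <- floor(pmax(x1, x2)[keep])
    tibble::tibble(x1 = lo, x2 = hi)
  })
}

# a small simulated assembly + library, reused across scaffolder tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- calibrate_sim_config(genome_length = 4e6, n_chromosomes = 2,
                                  contig_law = law_lognormal_n50(30000),
                                  seed = 42)
      fr <- fragment_into_contigs(cfg)
      sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
      cache <<- list(cfg = cfg, fr = fr, sim = sim,
                     model = link_model(G = cfg$genome_length,
                                        N = cfg$n_pairs,
                                        p_n = cfg$noise_fraction,
                                        components = cfg$mixture,
                                        max_span = cfg$max_fragment_length))
    }
    cache
  }
})

# brute-force join LLR straight from the likelihood definition (independent
# of the package's span/implied-separation code paths)
brute_join_llr <- function(offsets, l1, l2, g, orientation, model) {
  if (is.infinite(g)) return(0)
  o1 <- substr(orientation, 1, 1)
  o2 <- substr(orientation, 2, 2)
  d <- vapply(seq_len(nrow(offsets)), function(i) {
    a <- if (o1 == "+") l1 - offsets$x1[i] else offsets$x1[i]
    b <- if (o2 == "+") offsets$x2[i] else l2 - offsets$x2[i]
    a + g + b
  }, numeric(1))
  p0 <- stats::integrate(function(x) {
    pair_density(x, model) *
      pmax(0, pmin(l1, l2, x - g, l1 + l2 + g - x))
  }, g, g + l1 + l2, subdivisions = 4000, rel.tol = 1e-10)$value / model$G
  (model$N - length(d)) * log1p(-p0) +
    sum(log(pair_density(d, model)) - log(model$p_n / model$G))
}
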