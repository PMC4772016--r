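test_that("simulated genomes have the requested length, determinism and base mix", {
  skip_if_not_installed("Biostrings")
  g4 <- simulate_genome(4, seed = 3)
  expect_equal(Biostrings::width(g4), 4)
  expect_true(all(strsplit(as.character(g4[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  g1 <- simulate_genome(1e6, seed = 1)
  g2 <- simulate_genome(1e6, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  freq <- Biostrings::alphabetFrequency(g1, baseOnly = TRUE)[1, 1:4] / 1e6
  expect_true(all(abs(freq - 0.25) < 0.005))  # ~11.5 binomial SDs at n=1e6
  expect_error(simulate_genome(0), "positive")
})

test_that("fragmentation tiles the genome without overlap and tracks truth", {
  cfg <- sim_config(genome_length = 1e5, contig_law = law_constant(10000),
                    gap_length = 0, max_fragment_length = 5e4, seed = 2)
  fr <- fragment_into_contigs(cfg)
  expect_equal(nrow(fr$contigs), 10)
  expect_equal(n50(fr$contigs$length), 10000)
  expect_equal(sum(fr$contigs$length), 1e5)

  cfg2 <- sim_config(genome_length = 5e7, seed = 7,
                     contig_law = law_lognormal(log(30000), 0.5))
  fr2 <- fragment_into_contigs(cfg2)
  # intervals pairwise disjoint per chromosome
  tt <- fr2$truth[order(fr2$truth$chrom, fr2$truth$start), ]
  by_chr <- split(tt, tt$chrom)
  for (b in by_chr) expect_true(all(diff(b$start) >= (b$end - b$start)[-nrow(b)]))
  expect_true(all(tt$end > tt$start))
  expect_lte(sum(fr2$contigs$length), 5e7)
  # lognormal law with 30-kb median: N50 within 2x
  expect_gt(n50(fr2$contigs$length), 15000)
  expect_lt(n50(fr2$contigs$length), 60000)
})

test_that("chimera injection pairs distant contigs and conserves sequence", {
  cfg <- sim_config(genome_length = 1e7, contig_law = law_constant(20000),
                    seed = 5)
  fr <- fragment_into_contigs(cfg)
  # rate 0: identity
  r0 <- inject_chimeras(fr$contigs, fr$truth, 0, seed = 1)
  expect_identical(r0$contigs, fr$contigs)
  expect_equal(nrow(r0$chimeras), 0)
  # rate 1 on 10 contigs: 5 joins
  sub <- fr$contigs[1:10, ]
  subt <- fr$truth[fr$truth$contig %in% sub$contig, ]
  r1 <- inject_chimeras(sub, subt, 1, seed = 1)
  expect_equal(nrow(r1$chimeras), 5)
  expect_equal(sum(r1$contigs$length), sum(sub$length))
  expect_true(all(r1$chimeras$breakpoint >= 1000))
  expect_true(all(r1$chimeras$breakpoint <=
                    r1$contigs$length[match(r1$chimeras$contig,
                                            r1$contigs$contig)] - 1000))
  # truth carries both parts with consistent within-contig intervals
  for (i in seq_len(nrow(r1$chimeras))) {
    parts <- r1$truth[r1$truth$contig == r1$chimeras$contig[i], ]
    expect_equal(nrow(parts), 2)
    expect_equal(sort(parts$c_start), c(0, r1$chimeras$breakpoint[i]))
  }
  expect_warning(inject_chimeras(sub[1, ], subt, 1, seed = 1), "fewer than 2")
})

test_that("noise-only pairs are uniform; long-separation fraction matches", {
  G <- 5e7
  cfg <- sim_config(genome_length = G, contig_law = law_constant(30000),
                    noise_fraction = 1, n_pairs = 40000, seed = 13)
  fr <- fragment_into_contigs(cfg)
  sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  gp <- sim$genome_pairs
  d <- abs(gp$pos2 - gp$pos1)
  # P(|U1 - U2| > s) = (1 - s/G)^2 for iid uniforms on one chromosome
  s <- 5e5
  expected <- (1 - s / G)^2
  observed <- mean(d > s)
  se <- sqrt(expected * (1 - expected) / nrow(gp))
  expect_lt(abs(observed - expected), 4 * se)
  # positions cover the genome uniformly (chi-square on deciles, generous)
  cnt <- table(cut(gp$pos1, breaks = seq(0, G, length.out = 11)))
  expect_gt(stats::chisq.test(cnt)$p.value, 1e-4)
})

test_that("signal separations follow the truncated mixture", {
  lam <- 5e-4
  M <- 1e5
  cfg <- sim_config(genome_length = 5e7, contig_law = law_constant(30000),
                    mixture = tibble::tibble(weight = 1, rate = lam),
                    max_fragment_length = M, noise_fraction = 0,
                    n_pairs = 50000, seed = 21)
  fr <- fragment_into_contigs(cfg)
  sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  d <- abs(sim$genome_pairs$pos2 - sim$genome_pairs$pos1)
  mean_expected <- 1 / lam - M / (exp(lam * M) - 1)
  expect_lt(abs(mean(d) - mean_expected) / mean_expected, 0.02)
  expect_lte(max(d), M)
})

test_that("simulation is deterministic and lifting round-trips exactly", {
  cfg <- sim_config(genome_length = 2e6, n_pairs = 5000, seed = 31,
                    contig_law = law_constant(25000))
  fr <- fragment_into_contigs(cfg)
  s1 <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  s2 <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  expect_identical(s1$pairs, s2$pairs)
  # round trip contig -> genome recovers original coordinates
  back <- lift_to_genome(s1$pairs, fr$truth)
  orig <- s1$genome_pairs[match(s1$pairs$id, s1$genome_pairs$id), ]
  expect_equal(back$pos1, orig$pos1)
  expect_equal(back$pos2, orig$pos2)
  expect_identical(back$chr1, orig$chr1)
  expect_identical(back$strand1, orig$strand1)
  expect_identical(back$strand2, orig$strand2)
})

test_that("mapq degradation and duplicates are simulated on request", {
  cfg <- sim_config(genome_length = 2e6, n_pairs = 4000, seed = 8,
                    contig_law = law_constant(25000),
                    mapq_degraded_frac = 0.2, dup_rate = 0.1)
  fr <- fragment_into_contigs(cfg)
  sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  gp <- sim$genome_pairs
  expect_equal(mean(gp$mapq1 < 20), 0.2, tolerance = 0.05)
  expect_equal(sum(gp$dup), 400)
  dups <- gp[gp$dup, ]
  orig <- gp[!gp$dup, ]
  key <- function(x) paste(x$chr1, x$pos1, x$chr2, x$pos2)
  expect_true(all(key(dups) %in% key(orig)))  # exact coordinate repeats
})

test_that("noise calibration reproduces the spurious-link target", {
  G <- 5e7
  win <- 5e5
  n_pairs <- 2e5
  p_n <- calibrate_noise_fraction(n_pairs, G, spurious_per_window_pair = 1,
                                  window = win)
  cfg <- sim_config(genome_length = G, contig_law = law_constant(30000),
                    noise_fraction = p_n, n_pairs = n_pairs, seed = 17)
  fr <- fragment_into_contigs(cfg)
  sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
  gp <- sim$genome_pairs[sim$genome_pairs$noise, ]
  # count links between all unordered pairs of disjoint 500-kb windows that
  # are far apart (unrelated); mean should be ~1
  w1 <- floor(gp$pos1 / win)
  w2 <- floor(gp$pos2 / win)
  far <- abs(w1 - w2) >= 3
  nw <- floor(G / win)
  n_far_pairs <- sum(pmax(0, nw - (0:(nw - 1)) - 3))
  mean_links <- sum(far) / n_far_pairs
  se <- sqrt(sum(far)) / n_far_pairs
  expect_lt(abs(mean_links - 1), 4 * se + 0.05)
})

test_that("separation histogram converges to the configured mixture", {
  # least-squares distance of the empirical separation histogram to the
  # true density decreases as the library grows
  mix <- chicago_mixture()
  M <- 1.5e5
  m <- link_model(G = 1e9, N = 1, p_n = 0, components = mix, max_span = M)
  dist_for <- function(n, seed) {
    withr::with_seed(seed, {
      k <- sample.int(3, n, TRUE, prob = mix$weight)
      u <- runif(n)
      d <- -log(1 - u * (1 - exp(-mix$rate[k] * M))) / mix$rate[k]
    })
    # distance of the empirical CDF to the true truncated-mixture CDF
    grid <- seq(100, M, length.out = 200)
    Z <- 1 - exp(-mix$rate * M)
    cdf <- vapply(grid, function(x) {
      sum(mix$weight * (1 - exp(-mix$rate * x)) / Z)
    }, numeric(1))
    sqrt(mean((stats::ecdf(d)(grid) - cdf)^2))
  }
  expect_lt(dist_for(1e6, 5), dist_for(1e4, 5))
})

test_that("inversion trials: identity, interior reflection, masking, edge case", {
  cfg <- calibrate_sim_config(genome_length = 5e7, seed = 3)
  # het = FALSE, W = 0: plain pairs over the region
  tr <- simulate_inversion_trial(5000, 0, het = FALSE, cfg, seed = 4)
  expect_false(attr(tr, "het"))
  expect_true(all(tr$pos1 >= 0 & tr$pos1 < 2e5 + 5000))
  # het pairs with both ends inside keep their separation
  trh <- simulate_inversion_trial(20000, 0, het = TRUE, cfg, seed = 4)
  b1 <- attr(trh, "b1"); b2 <- attr(trh, "b2")
  trn <- simulate_inversion_trial(20000, 0, het = FALSE, cfg, seed = 4)
  both_in <- function(x) x$pos1 >= b1 & x$pos1 < b2 & x$pos2 >= b1 & x$pos2 < b2
  expect_equal(sort(abs(trh$pos2 - trh$pos1)[both_in(trh)]),
               sort(abs(trn$pos2 - trn$pos1)[both_in(trn)]))
  # masking removes every read within W of either breakpoint
  trw <- simulate_inversion_trial(5000, 1000, het = TRUE, cfg, seed = 9)
  b1 <- attr(trw, "b1"); b2 <- attr(trw, "b2")
  nearbp <- function(x) abs(x - b1) < 1000 | abs(x - b2) < 1000
  expect_false(any(nearbp(trw$pos1) | nearbp(trw$pos2)))
  # W large enough to empty the interior: flagged
  tr0 <- simulate_inversion_trial(1000, 600, het = TRUE, cfg, seed = 2)
  expect_true(attr(tr0, "flagged"))
})

test_that("one-end-inside het pairs match a brute-force reflection oracle", {
  # enumerate a grid of end positions, reflect with the same rule the
  # simulator documents, and compare implied separations
  L <- 1000; flank <- 2000
  b1 <- flank; b2 <- flank + L
  xs_out <- seq(0, b1 - 1, by = 97)
  xs_in <- seq(b1, b2 - 1, by = 53)
  refl <- function(x) ifelse(x >= b1 & x < b2, b1 + b2 - 1 - x, x)
  for (xo in xs_out) {
    for (xi in xs_in) {
      d_ref <- abs(xi - xo)
      d_inv <- abs(refl(xi) - refl(xo))
      # brute force: reflected coordinate of the inside end
      expect_equal(d_inv, abs((b1 + b2 - 1 - xi) - xo))
      # reflection shifts the separation by b1 + b2 - 1 - 2 * xi
      expect_equal(d_inv - d_ref, b1 + b2 - 1 - 2 * xi)
    }
  }
})
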