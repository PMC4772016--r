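#' Default Chicago separation mixture
#'
#' A three-component exponential mixture, truncated at 150 kbp, calibrated by
#' least squares so that its per-separation-bin physical coverage profile
#' (sum of pair separations per genome bp, in bins 0-1, 1-5, 5-10, 10-25,
#' 25-50 and 50-150 kbp) matches the profile of a single lane of sequencing
#' from two 150-kbp-input Chicago libraries: 3.8, 8.4, 8.6, 18.6, 13.5 and
#' 6.5x. See `vignette("chiscaf-methods")` for the calibration.
#'
#' @return tibble with columns `weight`, `rate` (1/bp).
#' @export
chicago_mixture <- function() {
  tibble(
    weight = c(0.68605862, 0.18780384, 0.12613754),
    rate = c(1.7108687e-03, 1.7964100e-04, 6.1667283e-05)
  )
}

#' Reference per-bin physical coverage profile
#'
#' The per-separation-bin physical coverage (bp of pair span per genome bp)
#' that the default simulator emulates: a single sequencing lane from two
#' 150-kbp-input Chicago libraries.
#'
#' @return tibble with columns `lo`, `hi` (bin edges, bp) and `coverage`.
#' @export
chicago_coverage_bins <- function() {
  tibble(
    lo = c(0, 1e3, 5e3, 1e4, 2.5e4, 5e4),
    hi = c(1e3, 5e3, 1e4, 2.5e4, 5e4, 2e5),
    coverage = c(3.8, 8.4, 8.6, 18.6, 13.5, 6.5)
  )
}

# mean separation of the truncated mixture
mixture_mean <- function(mixture, max_span) {
  Z <- 1 - exp(-mixture$rate * max_span)
  sum(mixture$weight *
        (1 / mixture$rate - max_span * exp(-mixture$rate * max_span) / Z))
}

#' Convert a spurious-link calibration into a noise fraction
#'
#' The background noise of a Chicago library is summarised as the expected
#' number of spurious links between two unrelated genomic windows of size
#' `window`. A noise pair places both ends independently and uniformly, so a
#' given unordered window pair receives `2 N p_n (window/G)^2` expected
#' links, giving
#' \deqn{p_n = \frac{s\, G^2}{2\, \mathrm{window}^2\, N}}
#' for a target of `s` spurious links per window pair.
#'
#' @param n_pairs total pair count `N`.
#' @param G genome size (bp).
#' @param spurious_per_window_pair target spurious links per unrelated window
#'   pair (default 1).
#' @param window window size (bp, default 500 kbp).
#' @return the noise fraction `p_n`.
#' @export
calibrate_noise_fraction <- function(n_pairs, G,
                                     spurious_per_window_pair = 1,
                                     window = 5e5) {
  p <- spurious_per_window_pair * G^2 / (2 * window^2 * n_pairs)
  assert_that(p <= 1,
              "calibration infeasible: fewer total pairs than implied noise pairs")
  p
}

#' Simulation configuration for a synthetic Chicago library
#'
#' Collects every knob of the simulator: genome and contig geometry, the
#' separation mixture, the noise level, library size and read-level
#' nuisances. Defaults emulate the 150-kbp-input ("L1+L2") regime; use
#' [calibrate_sim_config()] to derive `n_pairs` and `noise_fraction` from the
#' published coverage profile and spurious-link rate.
#'
#' @param genome_length total genome size (bp); must exceed
#'   `max_fragment_length`.
#' @param n_chromosomes number of equally sized chromosomes (default 1).
#' @param contig_law contig length law: one of [law_constant()],
#'   [law_uniform()], [law_lognormal()].
#' @param gap_length unassembled gap between consecutive contigs (bp).
#' @param max_fragment_length input-DNA size cap on pair separations (bp).
#' @param mixture tibble (`weight`, `rate`) of exponential components;
#'   weights must sum to 1 and rates be positive.
#' @param noise_fraction probability that a pair is noise.
#' @param n_pairs total number of simulated pairs.
#' @param chimera_rate probability per contig of entering a chimeric join
#'   (see [inject_chimeras()]).
#' @param mapq_high,mapq_low simulated map quality for clean/degraded ends.
#' @param mapq_degraded_frac fraction of ends downgraded to `mapq_low`
#'   (exercises the mapq filter).
#' @param dup_rate fraction of pairs duplicated as exact coordinate repeats
#'   (exercises the duplicate filter).
#' @param seed integer seed; identical config + seed give identical output.
#' @return a `sim_config` object (a validated list).
#' @export
sim_config <- function(genome_length = 5e7,
                       n_chromosomes = 1,
                       contig_law = law_lognormal_n50(30000),
                       gap_length = 100,
                       max_fragment_length = 150000,
                       mixture = chicago_mixture(),
                       noise_fraction = 0.01,
                       n_pairs = 1e5,
                       chimera_rate = 0,
                       mapq_high = 60, mapq_low = 10,
                       mapq_degraded_frac = 0,
                       dup_rate = 0,
                       seed = 1) {
  mixture <- as_tibble(mixture)
  assert_that(abs(sum(mixture$weight) - 1) <= 1e-9,
              "mixture weights must sum to 1")
  assert_that(all(mixture$rate > 0), "mixture rates must be positive")
  assert_that(noise_fraction >= 0 && noise_fraction <= 1,
              "`noise_fraction` must lie in [0, 1]")
  assert_that(genome_length > max_fragment_length,
              "`genome_length` must exceed `max_fragment_length`")
  assert_that(n_pairs >= 1, "`n_pairs` must be >= 1")
  assert_that(chimera_rate >= 0 && chimera_rate <= 1,
              "`chimera_rate` must lie in [0, 1]")
  structure(
    list(genome_length = genome_length, n_chromosomes = n_chromosomes,
         contig_law = contig_law, gap_length = gap_length,
         max_fragment_length = max_fragment_length, mixture = mixture,
         noise_fraction = noise_fraction, n_pairs = n_pairs,
         chimera_rate = chimera_rate, mapq_high = mapq_high,
         mapq_low = mapq_low, mapq_degraded_frac = mapq_degraded_frac,
         dup_rate = dup_rate, seed = seed),
    class = "sim_config"
  )
}

#' Calibrate a simulation to the published library profile
#'
#' Derives `n_pairs` and `noise_fraction` so the simulated library matches
#' (a) the total per-bin physical coverage of the reference profile
#' ([chicago_coverage_bins()]), giving a signal pair count of
#' `coverage * G / E[separation]`, and (b) the spurious-link noise
#' calibration of [calibrate_noise_fraction()].
#'
#' @inheritParams sim_config
#' @param coverage_bins reference physical coverage profile.
#' @param spurious_per_window_pair,window noise calibration (see
#'   [calibrate_noise_fraction()]).
#' @param ... passed through to [sim_config()].
#' @return a `sim_config`.
#' @export
calibrate_sim_config <- function(genome_length = 5e7,
                                 coverage_bins = chicago_coverage_bins(),
                                 spurious_per_window_pair = 1,
                                 window = 5e5,
                                 mixture = chicago_mixture(),
                                 max_fragment_length = 150000,
                                 ...) {
  total_cov <- sum(coverage_bins$coverage)
  n_signal <- total_cov * genome_length /
    mixture_mean(mixture, max_fragment_length)
  n_noise <- spurious_per_window_pair * genome_length^2 / (2 * window^2)
  n_pairs <- round(n_signal + n_noise)
  sim_config(genome_length = genome_length, mixture = mixture,
             max_fragment_length = max_fragment_length,
             n_pairs = n_pairs,
             noise_fraction = n_noise / n_pairs, ...)
}

#' Contig length laws
#'
#' Small constructors describing how draft-assembly contig lengths are drawn:
#' a fixed length, uniform between bounds, or lognormal.
#' `law_lognormal_n50()` parameterises the lognormal by its length-weighted
#' median (approximately the N50 of the resulting assembly),
#' `exp(meanlog + sdlog^2)`.
#'
#' @param length,min,max,meanlog,sdlog,n50 law parameters (bp).
#' @return a law object used by [fragment_into_contigs()].
#' @name contig_laws
#' @export
law_constant <- function(length) {
  structure(list(law = "constant", length = length), class = "contig_law")
}

#' @rdname contig_laws
#' @export
law_uniform <- function(min, max) {
  structure(list(law = "uniform", min = min, max = max), class = "contig_law")
}

#' @rdname contig_laws
#' @export
law_lognormal <- function(meanlog, sdlog) {
  structure(list(law = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "contig_law")
}

#' @rdname contig_laws
#' @export
law_lognormal_n50 <- function(n50, sdlog = 0.4) {
  law_lognormal(meanlog = log(n50) - sdlog^2, sdlog = sdlog)
}

draw_lengths <- function(law, n) {
  switch(law$law,
         constant = rep(law$length, n),
         uniform = runif(n, law$min, law$max),
         lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
         abort(paste("unknown contig length law:", law$law)))
}

#' Simulate a random genome sequence
#'
#' I.i.d. uniform A/C/G/T bases; deterministic for a fixed seed. Sequence
#' content never influences the link model (pairs are coordinates), so this
#' is only needed when FASTA output is wanted.
#'
#' @param length sequence length (bp), positive.
#' @param seed integer seed.
#' @param name sequence identifier.
#' @return a `Biostrings::DNAStringSet` of length 1.
#' @export
simulate_genome <- function(length, seed = 1, name = "chr1") {
  assert_that(length >= 1, "`length` must be positive")
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("simulate_genome() needs the Biostrings package")
  }
  seqs <- with_seed(derive_seed(seed, paste0("genome-", name)), {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- name
  out
}

#' Fragment a genome into draft-assembly contigs with truth tracking
#'
#' Tiles each chromosome with contigs drawn from the configured length law,
#' separated by unassembled gaps of `gap_length` bp; a draw overshooting the
#' chromosome end is truncated (and noted). Each contig receives a uniform
#' random placement strand, emulating the arbitrary orientation of
#' de-novo-assembled contigs. The returned truth map records every contig's
#' source interval, enabling exact downstream QC.
#'
#' @param config a [sim_config()].
#' @return a list with elements `chromosomes` (tibble `chrom`, `length`),
#'   `contigs` (tibble `contig`, `length`) and `truth` (tibble `contig`,
#'   `part`, `c_start`, `c_end`, `chrom`, `start`, `end`, `strand`;
#'   coordinates 0-based half-open).
#' @export
fragment_into_contigs <- function(config) {
  chrom_len <- floor(config$genome_length / config$n_chromosomes)
  chroms <- tibble(
    chrom = sprintf("chr%d", seq_len(config$n_chromosomes)),
    length = rep(chrom_len, config$n_chromosomes)
  )
  chroms$length[config$n_chromosomes] <-
    config$genome_length - chrom_len * (config$n_chromosomes - 1)
  truth <- with_seed(derive_seed(config$seed, "fragment"), {
    purrr::map_dfr(seq_len(nrow(chroms)), function(ci) {
      L <- chroms$length[ci]
      # draw in batches until the chromosome is tiled
      lens <- numeric(0)
      pos <- 0
      repeat {
        batch <- ceiling(pmax(draw_lengths(config$contig_law, 64), 1))
        for (l in batch) {
          if (pos >= L) break
          l <- min(l, L - pos)   # truncate at chromosome end
          lens <- c(lens, l)
          pos <- pos + l + config$gap_length
        }
        if (pos >= L) break
      }
      starts <- cumsum(c(0, head(lens, -1) + config$gap_length))
      tibble(chrom = chroms$chrom[ci], start = starts,
             end = starts + lens,
             strand = sample(c("+", "-"), length(lens), replace = TRUE))
    })
  })
  truth <- truth %>%
    mutate(contig = sprintf("ctg%05d", row_number()),
           part = 1L, c_start = 0, c_end = .data$end - .data$start) %>%
    select("contig", "part", "c_start", "c_end",
           "chrom", "start", "end", "strand")
  list(
    chromosomes = chroms,
    contigs = tibble(contig = truth$contig,
                     length = truth$c_end - truth$c_start),
    truth = truth
  )
}

#' Inject chimeric misjoins into a simulated contig set
#'
#' Selects `round(rate * n)` contigs (rounded down to an even count), pairs
#' them at random, and concatenates each pair into a single chimeric contig
#' (the second partner strand-flipped with probability 1/2). Pairings whose
#' partners lie within `min_distance` on the same chromosome are reshuffled,
#' so injected joins are genomically distant. Total sequence is conserved and
#' every junction is recorded, providing labelled positives for misjoin
#' detection.
#'
#' @param contigs,truth output of [fragment_into_contigs()].
#' @param rate probability per contig of entering a chimeric join.
#' @param seed integer seed.
#' @param min_distance minimum genomic separation (bp) demanded between
#'   partners on the same chromosome.
#' @return a list `contigs`, `truth`, `chimeras` (tibble `contig`,
#'   `breakpoint`, `source1`, `source2`).
#' @export
inject_chimeras <- function(contigs, truth, rate, seed = 1,
                            min_distance = 2e6) {
  assert_that(rate >= 0 && rate <= 1, "`rate` must lie in [0, 1]")
  empty <- tibble(contig = character(0), breakpoint = numeric(0),
                  source1 = character(0), source2 = character(0))
  if (rate == 0) return(list(contigs = contigs, truth = truth,
                             chimeras = empty))
  if (nrow(contigs) < 2) {
    warn("fewer than 2 contigs: no chimeras injected")
    return(list(contigs = contigs, truth = truth, chimeras = empty))
  }
  n_sel <- 2 * floor(round(rate * nrow(contigs)) / 2)
  if (n_sel < 2) return(list(contigs = contigs, truth = truth,
                             chimeras = empty))
  sel <- with_seed(derive_seed(seed, "chimera-select"), {
    s <- sample(contigs$contig, n_sel)
    # reshuffle pairings until partners are genomically distant
    for (try in 1:25) {
      a <- s[seq(1, n_sel, by = 2)]
      b <- s[seq(2, n_sel, by = 2)]
      pa <- truth[match(a, truth$contig), ]
      pb <- truth[match(b, truth$contig), ]
      close <- pa$chrom == pb$chrom &
        abs((pa$start + pa$end) - (pb$start + pb$end)) / 2 < min_distance
      if (!any(close)) break
      s <- sample(s)
    }
    list(a = a, b = b, flip = runif(length(a)) < 0.5)
  })
  a <- sel$a; b <- sel$b; flip <- sel$flip
  la <- contigs$length[match(a, contigs$contig)]
  lb <- contigs$length[match(b, contigs$contig)]
  new_name <- paste0(a, "_", b)

  flip_parts <- function(parts, total_len) {
    parts %>% mutate(
      c_start0 = total_len - .data$c_end,
      c_end = total_len - .data$c_start,
      c_start = .data$c_start0,
      strand = ifelse(.data$strand == "+", "-", "+")
    ) %>% select(-"c_start0")
  }

  new_truth <- purrr::map_dfr(seq_along(a), function(i) {
    pa <- truth %>% filter(.data$contig == a[i])
    pb <- truth %>% filter(.data$contig == b[i])
    if (flip[i]) pb <- flip_parts(pb, lb[i])
    pb <- pb %>% mutate(c_start = .data$c_start + la[i],
                        c_end = .data$c_end + la[i])
    bind_rows(pa, pb) %>%
      mutate(contig = new_name[i]) %>%
      arrange(.data$c_start) %>%
      mutate(part = row_number())
  })
  keep_truth <- truth %>% filter(!(.data$contig %in% c(a, b)))
  truth2 <- bind_rows(keep_truth, new_truth)
  contigs2 <- bind_rows(
    contigs %>% filter(!(.data$contig %in% c(a, b))),
    tibble(contig = new_name, length = la + lb)
  )
  list(contigs = contigs2, truth = truth2,
       chimeras = tibble(contig = new_name, breakpoint = la,
                         source1 = a, source2 = b))
}

# inverse-CDF sampler for the truncated exponential mixture
rtrunc_mixture <- function(n, mixture, max_span) {
  k <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  lam <- mixture$rate[k]
  u <- runif(n)
  -log1p(-u * (1 - exp(-lam * max_span))) / lam
}

#' Simulate a Chicago read-pair library over a genome
#'
#' With probability `noise_fraction` a pair's two loci are independent and
#' uniform over the genome (chimeric ligation noise); otherwise the first
#' locus is uniform and the separation is drawn from the truncated
#' exponential mixture, with a uniform random direction (draws leaving the
#' chromosome are rejected and redrawn). Read strands are independent and
#' uniform: Chicago pair geometry carries no strand information. Pairs are
#' lifted onto the draft contigs via the truth map; pairs with an end in an
#' unassembled gap are dropped from the contig-coordinate table.
#'
#' @param genome tibble (`chrom`, `length`) as from [fragment_into_contigs()].
#' @param truth truth map (see [fragment_into_contigs()]).
#' @param config a [sim_config()].
#' @return list with `pairs` (contig coordinates), `genome_pairs` (genome
#'   coordinates, all pairs, with a logical `noise` column) and
#'   `n_dropped_gap`.
#' @export
simulate_chicago_pairs <- function(genome, truth, config) {
  assert_that(nrow(truth) > 0, "empty truth map")
  n <- config$n_pairs
  gp <- with_seed(derive_seed(config$seed, "pairs"), {
    noise <- runif(n) < config$noise_fraction
    n_noi <- sum(noise)
    n_sig <- n - n_noi
    draw_locus <- function(m) {
      ci <- sample.int(nrow(genome), m, replace = TRUE,
                       prob = genome$length)
      tibble(chrom = genome$chrom[ci],
             pos = floor(runif(m) * genome$length[ci]))
    }
    # signal pairs: locus 1 uniform, separation from the truncated mixture
    sig <- NULL
    if (n_sig > 0) {
      need <- n_sig
      acc <- vector("list", 0)
      while (need > 0) {
        l1 <- draw_locus(need)
        d <- rtrunc_mixture(need, config$mixture,
                            config$max_fragment_length)
        dir <- sample(c(-1, 1), need, replace = TRUE)
        p2 <- floor(l1$pos + dir * d)
        len <- genome$length[match(l1$chrom, genome$chrom)]
        ok <- p2 >= 0 & p2 < len
        acc[[length(acc) + 1]] <-
          tibble(chr1 = l1$chrom[ok], pos1 = l1$pos[ok],
                 chr2 = l1$chrom[ok], pos2 = p2[ok])
        need <- need - sum(ok)
      }
      sig <- bind_rows(acc)
    }
    noi <- NULL
    if (n_noi > 0) {
      e1 <- draw_locus(n_noi); e2 <- draw_locus(n_noi)
      noi <- tibble(chr1 = e1$chrom, pos1 = e1$pos,
                    chr2 = e2$chrom, pos2 = e2$pos)
    }
    gp <- bind_rows(sig, noi)
    gp$noise <- rep(c(FALSE, TRUE), c(n - n_noi, n_noi))
    gp$strand1 <- sample(c("+", "-"), n, replace = TRUE)
    gp$strand2 <- sample(c("+", "-"), n, replace = TRUE)
    degraded <- function(m) {
      ifelse(runif(m) < config$mapq_degraded_frac,
             config$mapq_low, config$mapq_high)
    }
    gp$mapq1 <- degraded(n)
    gp$mapq2 <- degraded(n)
    gp$dup <- FALSE
    if (config$dup_rate > 0) {
      nd <- floor(config$dup_rate * n)
      if (nd > 0) {
        dups <- gp[sample.int(n, nd), ]
        dups$dup <- TRUE
        gp <- bind_rows(gp, dups)
      }
    }
    gp$id <- sprintf("pair%07d", seq_len(nrow(gp)))
    gp[, c("id", "chr1", "pos1", "chr2", "pos2", "strand1", "strand2",
           "mapq1", "mapq2", "dup", "noise")]
  })
  lifted <- lift_to_contigs(gp, truth)
  list(pairs = lifted$pairs, genome_pairs = gp,
       n_dropped_gap = lifted$n_dropped)
}

# map one set of genome coordinates onto contig coordinates; NA where the
# position falls in an unassembled gap
lift_end <- function(chrom, pos, strand, truth) {
  out_contig <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_real_, length(pos))
  out_strand <- strand
  for (ch in unique(truth$chrom)) {
    tt <- truth[truth$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    sel <- which(chrom == ch)
    if (length(sel) == 0) next
    idx <- findInterval(pos[sel], tt$start)
    inside <- idx >= 1 & pos[sel] < tt$end[pmax(idx, 1)]
    sel_in <- sel[inside]
    ti <- idx[inside]
    fwd <- tt$strand[ti] == "+"
    out_contig[sel_in] <- tt$contig[ti]
    out_pos[sel_in] <- ifelse(
      fwd,
      tt$c_start[ti] + (pos[sel_in] - tt$start[ti]),
      tt$c_start[ti] + (tt$end[ti] - 1 - pos[sel_in])
    )
    out_strand[sel_in] <- ifelse(
      fwd, strand[sel_in],
      ifelse(strand[sel_in] == "+", "-", "+")
    )
  }
  list(contig = out_contig, pos = out_pos, strand = out_strand)
}

#' Lift genome-coordinate pairs onto contig coordinates (and back)
#'
#' `lift_to_contigs()` maps both ends of each pair through the truth map,
#' dropping pairs with an end in an unassembled gap; read strands flip on
#' minus-strand contig placements. `lift_to_genome()` is its exact inverse
#' for pairs wholly inside contigs.
#'
#' @param pairs pair tibble (`chr*`, `pos*`, `strand*` columns) in genome
#'   (respectively contig) coordinates.
#' @param truth the truth map.
#' @return `lift_to_contigs()`: list(`pairs`, `n_dropped`);
#'   `lift_to_genome()`: a pair tibble in genome coordinates.
#' @export
lift_to_contigs <- function(pairs, truth) {
  e1 <- lift_end(pairs$chr1, pairs$pos1, pairs$strand1, truth)
  e2 <- lift_end(pairs$chr2, pairs$pos2, pairs$strand2, truth)
  keep <- !is.na(e1$contig) & !is.na(e2$contig)
  out <- pairs[keep, , drop = FALSE]
  out$chr1 <- e1$contig[keep]; out$pos1 <- e1$pos[keep]
  out$strand1 <- e1$strand[keep]
  out$chr2 <- e2$contig[keep]; out$pos2 <- e2$pos[keep]
  out$strand2 <- e2$strand[keep]
  list(pairs = out, n_dropped = sum(!keep))
}

#' @rdname lift_to_contigs
#' @export
lift_to_genome <- function(pairs, truth) {
  unlift <- function(contig, cpos, strand) {
    df <- tibble(q = seq_along(contig), contig = contig, cpos = cpos)
    j <- dplyr::inner_join(df, truth, by = "contig",
                           relationship = "many-to-many")
    j <- j[j$cpos >= j$c_start & j$cpos < j$c_end, , drop = FALSE]
    ti <- j[match(df$q, j$q), , drop = FALSE]
    fwd <- ti$strand == "+"
    within <- ti$cpos - ti$c_start
    list(chrom = ti$chrom,
         pos = ifelse(fwd, ti$start + within, ti$end - 1 - within),
         strand = ifelse(fwd, strand, ifelse(strand == "+", "-", "+")))
  }
  e1 <- unlift(pairs$chr1, pairs$pos1, pairs$strand1)
  e2 <- unlift(pairs$chr2, pairs$pos2, pairs$strand2)
  out <- pairs
  out$chr1 <- e1$chrom; out$pos1 <- e1$pos; out$strand1 <- e1$strand
  out$chr2 <- e2$chrom; out$pos2 <- e2$pos; out$strand2 <- e2$strand
  out
}

#' Simulate one heterozygous-inversion (or null) trial
#'
#' Simulates Chicago pairs over a region of `L + 2 * flank` bp containing a
#' candidate inversion `[b1, b2)` of length `L` centred in the region. Under
#' `het = TRUE` each pair is assigned independently at random (probability
#' 1/2) to the inverted haplotype, and its read coordinates inside `[b1, b2)`
#' are reflected (`x -> b1 + b2 - 1 - x`, strand flipped), exactly as mapped
#' reads from the inverted haplotype would appear against the reference.
#' Reads within `W` of either breakpoint are then removed (both arms),
#' emulating unmappable repeat flanks. The local pair rate and noise follow
#' the configuration, so trial statistics depend only on the per-bp signal
#' rate, the mixture, and the spurious-link density, not on the genome size.
#'
#' @param L inversion length (bp), `>= 1`.
#' @param W breakpoint masking distance (bp), `>= 0`.
#' @param het logical: simulate a heterozygous inversion (TRUE) or an
#'   unmodified null region (FALSE).
#' @param config a [sim_config()] (typically from [calibrate_sim_config()]).
#' @param seed integer seed.
#' @param flank flank length on each side of the inversion (bp).
#' @return a pair tibble in region coordinates (`chr* = "region"`), with
#'   attributes `b1`, `b2`, `L`, `W`, `het`, `n_informative` (pairs with
#'   exactly one end inside the inversion after masking) and `flagged`
#'   (TRUE when no informative pairs remain).
#' @export
simulate_inversion_trial <- function(L, W, het, config, seed = 1,
                                     flank = 1e5) {
  assert_that(L >= 1, "`L` must be >= 1")
  assert_that(W >= 0, "`W` must be >= 0")
  R <- L + 2 * flank
  b1 <- flank; b2 <- flank + L
  G <- config$genome_length
  rate_sig <- config$n_pairs * (1 - config$noise_fraction) / G
  mu_noise <- config$n_pairs * config$noise_fraction * (R / G)^2
  # seed tag excludes `het`: a heterozygous trial and its matched null share
  # the underlying pair draw, differing only in the coordinate editing
  out <- with_seed(derive_seed(seed, sprintf("inv-%d-%d", L, W)), {
    n_sig <- rpois(1, rate_sig * R)
    x1 <- runif(n_sig, 0, R)
    d <- rtrunc_mixture(n_sig, config$mixture, config$max_fragment_length)
    x2 <- x1 + d * sample(c(-1, 1), n_sig, replace = TRUE)
    keep <- x2 >= 0 & x2 < R
    x1 <- floor(x1[keep]); x2 <- floor(x2[keep])
    n_noi <- rpois(1, mu_noise)
    if (n_noi > 0) {
      x1 <- c(x1, floor(runif(n_noi, 0, R)))
      x2 <- c(x2, floor(runif(n_noi, 0, R)))
    }
    s1 <- sample(c("+", "-"), length(x1), replace = TRUE)
    s2 <- sample(c("+", "-"), length(x1), replace = TRUE)
    if (het && length(x1) > 0) {
      hap <- runif(length(x1)) < 0.5
      refl <- function(x, s) {
        inside <- hap & x >= b1 & x < b2
        list(x = ifelse(inside, b1 + b2 - 1 - x, x),
             s = ifelse(inside, ifelse(s == "+", "-", "+"), s))
      }
      r1 <- refl(x1, s1); r2 <- refl(x2, s2)
      x1 <- r1$x; s1 <- r1$s; x2 <- r2$x; s2 <- r2$s
    }
    if (W > 0 && length(x1) > 0) {
      near <- function(x) abs(x - b1) < W | abs(x - b2) < W
      bad <- near(x1) | near(x2)
      x1 <- x1[!bad]; x2 <- x2[!bad]
      s1 <- s1[!bad]; s2 <- s2[!bad]
    }
    tibble(id = sprintf("pair%06d", seq_along(x1)),
           chr1 = "region", pos1 = x1, chr2 = "region", pos2 = x2,
           strand1 = s1, strand2 = s2,
           mapq1 = config$mapq_high, mapq2 = config$mapq_high,
           dup = FALSE)
  })
  in1 <- out$pos1 >= b1 & out$pos1 < b2
  in2 <- out$pos2 >= b1 & out$pos2 < b2
  n_inf <- sum(xor(in1, in2))
  attr(out, "b1") <- b1; attr(out, "b2") <- b2
  attr(out, "L") <- L; attr(out, "W") <- W; attr(out, "het") <- het
  attr(out, "n_informative") <- n_inf
  attr(out, "flagged") <- n_inf == 0
  out
}
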