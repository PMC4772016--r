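# chiscaf

Likelihood-based genome scaffolding with *in vitro* proximity-ligation
("Chicago") read pairs, in R.

## The problem

Draft genome assemblies from short reads fragment at repeats, typically into
contigs of tens of kilobases. Chicago libraries — proximity-ligation read
pairs generated from chromatin reconstituted *in vitro* on high-molecular-
weight DNA — link loci up to the input fragment length (~150 kbp) with a
smooth, noise-poor separation profile and no confounding biological contact
signal, and can lift such drafts to chromosome-arm-scale scaffolds from a
single sequencing lane. chiscaf is for people who want that scaffolding
logic as an inspectable, testable R package: assembly developers, method
benchmarkers, and anyone studying what proximity-ligation evidence can and
cannot decide.

## The model

The separation `x` of a mapped pair follows a noise-plus-signal density

    f(x) = p_n / G + (1 - p_n) * sum_k a_k * lam_k * exp(-lam_k * x) / Z_k

(truncated at the input fragment length `M`, with `Z_k = 1 - exp(-lam_k M)`;
`G` = genome size, `p_n` = noise fraction). Two contigs at gap `g` and
orientation `o`, linked by `n` pairs with implied separations `d_i` out of
`N` total, have join likelihood

    L(l1, l2, g, o) ∝ (1 - P0)^(N - n) * prod_i f(d_i),
    P0 = (1/G) ∫ f(x) c(x) dx,
    c(x) = max(0, min(l1, l2, x - g, l1 + l2 + g - x)),

and every pipeline decision — orienting contigs by dynamic programming,
accepting joins/insertions/inversions, breaking low-support positions,
estimating gap sizes — maximises the log-likelihood ratio of joined versus
unlinked. A repeat-robust break score virtually masks the most supportive
1-kbp bins to one side of a candidate breakpoint, exposing misjoins propped
up by a single repeat cluster. A maximum-likelihood discriminator for
heterozygous inversions scores each pair as an equal mixture of the
reference and the reflected-coordinate haplotype.

Everything is tibble-in, tibble-out: pair tables, contig tables, scaffold
layouts and QC reports are plain data frames, with `tidy()`/`glance()`
methods for fitted objects and `plot_*()` helpers for diagnostics. The
package also contains a calibrated synthetic-library simulator with exact
truth tracking, so every algorithm is testable without external data. See
`vignette("chiscaf-methods")` for the full model and the design decisions.

## Worked example

Simulate a 10-Mbp two-chromosome genome fragmented into ~28-kbp-N50 contigs,
generate a calibrated Chicago library over it, scaffold, and QC against the
simulator's truth map:

```r
library(chiscaf)

cfg <- calibrate_sim_config(genome_length = 1e7, n_chromosomes = 2,
                            contig_law = law_lognormal_n50(30000), seed = 1)
fr  <- fragment_into_contigs(cfg)
sim <- simulate_chicago_pairs(fr$chromosomes, fr$truth, cfg)
res <- run_hirise(fr$contigs, sim$pairs,
                  config = hirise_config(seed = 1, w = 3))
res
#> <hirise_result>
#>   377 contigs -> 22 scaffolds; scaffold N50 647409 bp (input N50 28081 bp)

tidy(res$model)       # fitted separation mixture (3 components)
#> # A tibble: 3 x 4
#>   component weight      rate mean_separation
#>       <int>  <dbl>     <dbl>           <dbl>
#> 1         1  0.690 0.00170              588.
#> 2         2  0.198 0.000170            5869.
#> 3         3  0.112 0.0000593          16846.

qc <- qc_metrics(res$layout, res$contigs, fr$truth)
dplyr::select(qc, n50, misjoin_frac_5k, strand_switches, gap_discrepancy_p95)
#> # A tibble: 1 x 4
#>      n50 misjoin_frac_5k strand_switches gap_discrepancy_p95
#>    <dbl>           <dbl>           <int>               <dbl>
#> 1 647409               0               0                 501
```

The contig N50 rose 23-fold with zero truth-misjoins and zero orientation
switches; 95% of ~50-kbp marker separations are within ~500 bp of their
reference values. The fitted mixture recovers the generating rates
(1.71e-3, 1.80e-4, 6.17e-5 per bp). `write_agp()`, `write_scaffold_fasta()`
and `write_pairs()` emit the standard formats.

The inversion discriminator and its evaluation harness:

```r
ev <- evaluate_discriminator(L = 5000, W = 0, n_trials = 100,
                             config = calibrate_sim_config(seed = 1), seed = 1)
dplyr::select(ev, L, W, sensitivity, specificity)
#> # A tibble: 1 x 4
#>       L     W sensitivity specificity
#>   <dbl> <dbl>       <dbl>       <dbl>
#> 1  5000     0        0.97        0.99
```

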