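#' Truth-based assembly QC metrics
#'
#' Plants synthetic markers every `spacing` bp along each scaffold, maps them
#' to reference coordinates through the truth map, and computes the
#' long-range accuracy metrics: (a) scaffold N50; (b) the misjoin metric at
#' each anchoring threshold -- a scaffold is anchored to a chromosome when
#' some tiling window of that size contains markers and all of them map to
#' that chromosome, and a scaffold anchored to two or more chromosomes is
#' misjoined (reported as the fraction of assembly span in misjoined
#' scaffolds); (c) the strand-switch density: consecutive markers on the same
#' reference chromosome whose reference orientation disagrees, per assembly
#' bp; and (d) the gap-size discrepancy: for marker pairs separated by
#' 49.5-50 kbp in the assembly, the 95th percentile of the absolute
#' difference between assembly and reference separation.
#'
#' Markers are truth coordinates, not literal k-mers: on simulated data every
#' contig base has a known reference position, so k-mer uniqueness machinery
#' is unnecessary.
#'
#' @param layout layout tibble.
#' @param contigs tibble `contig`, `length`.
#' @param truth truth map.
#' @param spacing marker spacing (bp, default 1000).
#' @param anchor_thresholds anchoring window sizes (bp).
#' @param gap_window assembly-separation window (bp) for the discrepancy
#'   metric.
#' @return one-row tibble: `n50`, `total_span`, `misjoin_frac_5k` (etc. per
#'   threshold), `n_misjoined_scaffolds`, `strand_switches`,
#'   `strand_switch_density`, `gap_discrepancy_p95`, `n_marker_pairs`,
#'   `n_scaffolds_unanchored`; attribute `markers` holds the marker table.
#' @export
qc_metrics <- function(layout, contigs, truth, spacing = 1000,
                       anchor_thresholds = c(5e3, 1e4, 5e4),
                       gap_window = c(49500, 50000)) {
  lay <- layout %>%
    left_join(contigs, by = "contig") %>%
    group_by(.data$scaffold) %>%
    arrange(.data$idx, .by_group = TRUE) %>%
    mutate(start = cumsum(dplyr::lag(.data$length, default = 0) +
                            .data$gap_before),
           end = .data$start + .data$length) %>%
    ungroup()
  spans <- lay %>%
    group_by(.data$scaffold) %>%
    summarise(span = max(.data$end), .groups = "drop")

  # markers: every `spacing` bp of scaffold coordinate that lands in a contig
  markers <- purrr::map_dfr(seq_len(nrow(lay)), function(i) {
    row <- lay[i, ]
    s0 <- ceiling(row$start / spacing) * spacing
    pos <- seq(s0, row$end - 1, by = spacing)
    if (length(pos) == 0) return(NULL)
    off <- pos - row$start                       # offset in layout direction
    cpos <- if (row$orientation == "+") off else row$length - 1 - off
    tibble(scaffold = row$scaffold, apos = pos, contig = row$contig,
           cpos = cpos, lay_or = row$orientation)
  })
  # map through (possibly multi-part) truth placements
  tj <- dplyr::inner_join(markers, truth, by = "contig",
                          relationship = "many-to-many") %>%
    filter(.data$cpos >= .data$c_start, .data$cpos < .data$c_end) %>%
    mutate(
      rpos = ifelse(.data$strand == "+",
                    .data$start + (.data$cpos - .data$c_start),
                    .data$end - 1 - (.data$cpos - .data$c_start)),
      ror = ifelse((.data$strand == "+") == (.data$lay_or == "+"), "+", "-")
    ) %>%
    select("scaffold", "apos", "chrom", "rpos", "ror") %>%
    arrange(.data$scaffold, .data$apos)

  # (b) anchoring / misjoins per threshold
  misjoin <- vapply(anchor_thresholds, function(Tw) {
    anch <- tj %>%
      mutate(win = floor(.data$apos / Tw)) %>%
      group_by(.data$scaffold, .data$win) %>%
      summarise(one = dplyr::n_distinct(.data$chrom) == 1,
                chrom = dplyr::first(.data$chrom), .groups = "drop") %>%
      filter(.data$one) %>%
      distinct(.data$scaffold, .data$chrom) %>%
      dplyr::count(.data$scaffold, name = "n_chrom")
    bad <- anch$scaffold[anch$n_chrom >= 2]
    sum(spans$span[spans$scaffold %in% bad]) / sum(spans$span)
  }, numeric(1))
  mis_sc <- unique(unlist(lapply(anchor_thresholds, function(Tw) {
    anch <- tj %>%
      mutate(win = floor(.data$apos / Tw)) %>%
      group_by(.data$scaffold, .data$win) %>%
      summarise(one = dplyr::n_distinct(.data$chrom) == 1,
                chrom = dplyr::first(.data$chrom), .groups = "drop") %>%
      filter(.data$one) %>%
      distinct(.data$scaffold, .data$chrom) %>%
      dplyr::count(.data$scaffold, name = "n_chrom")
    anch$scaffold[anch$n_chrom >= 2]
  })))

  # (c) strand switches between consecutive same-chromosome markers
  sw <- tj %>%
    group_by(.data$scaffold) %>%
    mutate(switch = .data$chrom == dplyr::lag(.data$chrom) &
             .data$ror != dplyr::lag(.data$ror)) %>%
    ungroup()
  n_switch <- sum(sw$switch, na.rm = TRUE)

  # (d) gap-size discrepancy over ~50-kbp marker pairs
  disc <- tj %>%
    group_by(.data$scaffold) %>%
    arrange(.data$apos, .by_group = TRUE) %>%
    mutate(lead_apos = dplyr::lead(.data$apos, round(gap_window[2] / spacing)),
           lead_rpos = dplyr::lead(.data$rpos, round(gap_window[2] / spacing)),
           lead_chrom = dplyr::lead(.data$chrom,
                                    round(gap_window[2] / spacing))) %>%
    ungroup() %>%
    filter(!is.na(.data$lead_apos),
           .data$lead_apos - .data$apos >= gap_window[1],
           .data$lead_apos - .data$apos <= gap_window[2],
           .data$chrom == .data$lead_chrom) %>%
    mutate(d = abs((.data$lead_apos - .data$apos) -
                     abs(.data$lead_rpos - .data$rpos)))
  p95 <- if (nrow(disc) > 0) {
    as.numeric(quantile(disc$d, 0.95, names = FALSE))
  } else NA_real_

  unanchored <- setdiff(spans$scaffold, unique(tj$scaffold))
  out <- tibble(
    n50 = n50(spans$span),
    total_span = sum(spans$span),
    n_misjoined_scaffolds = length(mis_sc),
    strand_switches = n_switch,
    strand_switch_density = n_switch / sum(spans$span),
    gap_discrepancy_p95 = p95,
    n_marker_pairs = nrow(disc),
    n_scaffolds_unanchored = length(unanchored)
  )
  for (i in seq_along(anchor_thresholds)) {
    out[[sprintf("misjoin_frac_%gk", anchor_thresholds[i] / 1000)]] <-
      misjoin[i]
  }
  attr(out, "markers") <- tj
  out
}
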