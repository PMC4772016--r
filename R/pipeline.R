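#' Run the full proximity-ligation scaffolding pipeline
#'
#' Orchestrates the complete workflow on a draft assembly and mapped Chicago
#' pairs: (1) optional repeat masking from a shotgun depth track and pair
#' filtering (map quality, duplicates, masks, promiscuous windows); (2)
#' likelihood-model fitting (noise product, edge-corrected separation
#' histogram, exponential-mixture least squares); (3) a pre-pass breaking
#' low-support positions inside the input contigs; (4) link-graph
#' construction, component partitioning, edge filtering, spanning-forest
#' linearization and orientation DP giving seed scaffolds; (5) merging within
#' components, local order/orientation refinement, iterative joining across
#' the pool; (6) a post-pass breaking low-support scaffold joins, a final
#' refinement, and maximum-likelihood gap estimation. Deterministic for a
#' fixed config.
#'
#' @param contigs tibble `contig`, `length`.
#' @param pairs pair tibble in contig coordinates (`chr1`, `pos1`, `chr2`,
#'   `pos2`, `strand1`, `strand2`, `mapq1`, `mapq2`, `dup`).
#' @param depth optional shotgun depth track (`chrom`, `start`, `end`,
#'   `depth`) for repeat masking.
#' @param config a [hirise_config()].
#' @param model optional pre-fitted [link_model()]; fitted from the data
#'   when NULL.
#' @return a `hirise_result`: list with `layout` (tibble `scaffold`, `idx`,
#'   `contig`, `orientation`, `gap_before`), `contigs` (post-break contig
#'   table), `model`, `breaks` (pre-pass), `junctions` (post-pass audit),
#'   `filter_tally`, `report` (stage counts), `config`.
#' @export
run_hirise <- function(contigs, pairs, depth = NULL,
                       config = hirise_config(), model = NULL) {
  report <- list(n_contigs_in = nrow(contigs), n_pairs_in = nrow(pairs))
  verbose <- isTRUE(getOption("chiscaf.verbose"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed after %s: %s", name,
                    paste(names(report), unlist(report), sep = "=",
                          collapse = ", "),
                    conditionMessage(e)))
    })
    if (verbose) {
      message(sprintf("[chiscaf] %-10s %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    out
  }

  masks <- NULL
  if (!is.null(depth)) {
    mk <- stage("mask", mask_high_depth(depth, config$mask_target))
    masks <- mk$intervals
    report$masked_fraction <- mk$masked_fraction
  }
  filt <- stage("filter", filter_pairs(pairs, masks, config))
  report$filter <- filt$tally
  usable <- filt$pairs
  report$n_pairs_usable <- nrow(usable)

  if (nrow(usable) == 0) {
    layout <- tibble(scaffold = contigs$contig, idx = 1L,
                     contig = contigs$contig, orientation = "+",
                     gap_before = 0)
    return(new_hirise_result(layout, contigs, NULL, config, report))
  }

  if (is.null(model)) {
    model <- stage("fit", {
      G <- sum(contigs$length)
      intra <- usable[usable$chr1 == usable$chr2, , drop = FALSE]
      seps <- abs(intra$pos2 - intra$pos1)
      counts <- contig_pair_counts(usable)
      # the trim must cover the genuinely linked contig pairs; scale it to
      # the observed linked fraction (the default 1% presumes assemblies of
      # tens of thousands of contigs where neighbours are vanishingly rare)
      linked_frac <- nrow(counts) / choose(nrow(contigs), 2)
      trim_used <- min(0.2, max(config$trim, 2 * linked_frac))
      report$noise_trim <- trim_used
      np <- estimate_noise_product(counts, contigs, G = G,
                                   trim = trim_used, seed = config$seed)
      h <- separation_histogram(seps, contigs$length, G = G,
                                max_sep = config$max_span)
      fit_mixture(h, np, K = config$K, G = G, max_span = config$max_span)
    })
  }
  report$model <- glance(model)

  # pre-pass: break low-support positions inside input contigs
  graph <- stage("graph", build_link_graph(usable, contigs))
  brk <- stage("prebreak", detect_breaks(graph, model, config))
  report$n_prebreaks <- nrow(brk)
  if (nrow(brk) > 0) {
    ap <- apply_breaks(brk, contigs, usable)
    contigs <- ap$contigs
    usable <- ap$pairs
    graph <- build_link_graph(usable, contigs)
  }

  part <- stage("partition", partition_components(graph, config$cluster_cap))
  report$t_L <- part$t_L
  comp <- part$components
  report$n_components <- length(unique(comp$component))

  # per-component seeding and merging
  t_seed <- Sys.time()
  layouts <- list()
  for (cid in sort(unique(comp$component))) {
    members <- comp$contig[comp$component == cid]
    sub <- subset_graph(graph, members)
    if (length(members) == 1 || nrow(sub$edges) == 0) {
      layouts[[length(layouts) + 1]] <- singleton_layout(members)
      next
    }
    fe <- filter_edges(sub, t_L = part$t_L,
                       tail_exclude = config$tail_exclude)
    lin <- linearize_graph(fe$graph, model, config$g_o)
    seeded <- unlist(lin$paths)
    lay <- bind_rows(
      purrr::imap_dfr(lin$paths, function(p, i) {
        o <- orient_path(p, sub, model, k = config$k, g_o = config$g_o)
        tibble(scaffold = sprintf("seed%03d_%04d", cid, i),
               idx = seq_along(p), contig = p,
               orientation = o$orientation, gap_before = config$g_o)
      }),
      singleton_layout(setdiff(members, seeded))
    )
    lay$gap_before[lay$idx == 1] <- 0
    mg <- merge_within_component(lay, sub, model, config)
    layouts[[length(layouts) + 1]] <- mg$layout %>%
      mutate(scaffold = paste0("c", cid, "_", .data$scaffold))
  }
  layout <- bind_rows(layouts)
  if (verbose) {
    message(sprintf("[chiscaf] %-10s %.1fs", "seed+merge",
                    as.numeric(Sys.time() - t_seed, units = "secs")))
  }
  report$n_seed_scaffolds <- length(unique(layout$scaffold))

  layout <- stage("refine1",
                  refine_local(layout, graph, model, w = config$w,
                               g_o = config$g_o))
  jn <- stage("join", iterative_join(layout, graph, model, config))
  layout <- jn$layout
  report$n_joins <- sum(jn$log$accepted)

  pb <- stage("postbreak",
              break_scaffold_joins(layout, graph, model, config))
  layout <- pb$layout
  report$n_postbreaks <- sum(pb$junctions$broken)

  layout <- stage("refine2",
                  refine_local(layout, graph, model, w = config$w,
                               g_o = config$g_o))

  layout <- stage("gaps", estimate_layout_gaps(layout, graph, model, config))
  layout <- rename_scaffolds(layout, contigs)
  res <- new_hirise_result(layout, contigs, model, config, report)
  res$breaks <- brk
  res$junctions <- pb$junctions
  res$filter_tally <- filt$tally
  res
}

singleton_layout <- function(contigs_chr) {
  if (length(contigs_chr) == 0) {
    return(tibble(scaffold = character(0), idx = integer(0),
                  contig = character(0), orientation = character(0),
                  gap_before = numeric(0)))
  }
  tibble(scaffold = paste0("single_", contigs_chr), idx = 1L,
         contig = contigs_chr, orientation = "+", gap_before = 0)
}

subset_graph <- function(graph, members) {
  e <- graph$edges[graph$edges$contig1 %in% members &
                     graph$edges$contig2 %in% members, , drop = FALSE]
  structure(list(nodes = graph$nodes[graph$nodes$contig %in% members, ],
                 edges = e,
                 internal = graph$internal[
                   graph$internal$contig %in% members, ]),
            class = "link_graph")
}

# estimate the gap before every non-first layout entry from its edge with
# the previous contig
estimate_layout_gaps <- function(layout, graph, model, config) {
  ctx <- make_ctx(graph$edges, graph$nodes, model, g_o = config$g_o)
  out <- layout
  for (s in unique(layout$scaffold)) {
    ix <- which(layout$scaffold == s)
    ix <- ix[order(layout$idx[ix])]
    if (length(ix) < 2) next
    for (q in 2:length(ix)) {
      a <- layout$contig[ix[q - 1]]; b <- layout$contig[ix[q]]
      oa <- layout$orientation[ix[q - 1]]; ob <- layout$orientation[ix[q]]
      e <- if (a < b) ctx$edges[[paste(a, b, sep = "\r")]] else NULL
      swap <- FALSE
      if (a > b) {
        er <- ctx$edges[[paste(b, a, sep = "\r")]]
        if (!is.null(er)) e <- list(x1 = er$x2, x2 = er$x1)
      }
      if (is.null(e)) {
        out$gap_before[ix[q]] <- config$g_o
        next
      }
      est <- estimate_gap(tibble(x1 = e$x1, x2 = e$x2),
                          ctx$len[[a]], ctx$len[[b]],
                          paste0(oa, ob), model, g_default = config$g_o)
      out$gap_before[ix[q]] <- round(est$gap)
    }
  }
  out
}

# stable public scaffold names, largest span first
rename_scaffolds <- function(layout, contigs) {
  spans <- layout %>%
    left_join(contigs, by = "contig") %>%
    group_by(.data$scaffold) %>%
    summarise(span = sum(.data$length) + sum(.data$gap_before),
              first = min(.data$contig), .groups = "drop") %>%
    arrange(desc(.data$span), .data$first)
  map <- setNames(sprintf("scaffold_%05d", seq_len(nrow(spans))),
                  spans$scaffold)
  layout$scaffold <- map[layout$scaffold]
  layout %>% arrange(.data$scaffold, .data$idx)
}

new_hirise_result <- function(layout, contigs, model, config, report) {
  structure(list(layout = layout, contigs = contigs, model = model,
                 config = config, report = report),
            class = "hirise_result")
}

#' @export
print.hirise_result <- function(x, ...) {
  g <- glance(x)
  cat("<hirise_result>\n")
  cat(sprintf("  %d contigs -> %d scaffolds; scaffold N50 %.0f bp (input N50 %.0f bp)\n",
              g$n_contigs, g$n_scaffolds, g$n50_scaffold, g$n50_contig))
  invisible(x)
}

#' Tidy the scaffold layout of a pipeline result
#'
#' `tidy()` returns the per-contig layout table; `glance()` returns one row
#' of assembly-level summaries.
#'
#' @param x a `hirise_result`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy hirise_result
#' @export
tidy.hirise_result <- function(x, ...) x$layout

#' @rdname tidy.hirise_result
#' @method glance hirise_result
#' @export
glance.hirise_result <- function(x, ...) {
  spans <- x$layout %>%
    left_join(x$contigs, by = "contig") %>%
    group_by(.data$scaffold) %>%
    summarise(span = sum(.data$length) + sum(.data$gap_before),
              .groups = "drop")
  tibble(
    n_contigs = nrow(x$contigs),
    n_scaffolds = nrow(spans),
    n50_contig = n50(x$contigs$length),
    n50_scaffold = n50(spans$span),
    total_span = sum(spans$span),
    n_prebreaks = x$report$n_prebreaks %||% 0L,
    n_postbreaks = x$report$n_postbreaks %||% 0L
  )
}
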