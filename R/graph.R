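#' Pipeline configuration
#'
#' All tunable parameters of the scaffolding pipeline in one place. Automatic
#' thresholds (`t_L`, `t_p`, `d_m`, depth thresholds) are chosen at run time
#' by their respective stages; the values here control how.
#'
#' @param mapq_min minimum map quality on both ends (default 20).
#' @param mask_target target masked fraction of the assembly (default 0.005).
#' @param promiscuous_window window size (bp) for the promiscuous-window pair
#'   filter (default 1000).
#' @param promiscuous_contig_limit maximum number of distinct other contigs a
#'   window may be linked to (default 4).
#' @param promiscuous_min_links minimum links for a window-contig connection
#'   to count (default 2).
#' @param cluster_cap maximum component size as a fraction of the contig
#'   count when choosing the link threshold `t_L` (default 0.05).
#' @param tail_exclude upper-tail fraction excluded when choosing the
#'   promiscuity thresholds `t_p` and `d_m` (default 0.05).
#' @param k orientation-DP lookback: links up to `k` positions back inform
#'   each orientation choice (default 2).
#' @param w refinement window size; cost grows as `w! 2^w` (default 4, capped
#'   at 5).
#' @param g_o standard gap size (bp) used when scoring candidate joins
#'   (default 1000).
#' @param stride support-profile grid spacing (bp, default 500).
#' @param n_mask,w_mask robust-support masking (default 3 bins of 1000 bp).
#' @param thr_raw,thr_robust break thresholds (nats) on the raw and robust
#'   support scores. `thr_raw` defaults to 0 (a position is suspect when
#'   breaking is likelier than keeping). `thr_robust = NULL` (default)
#'   auto-calibrates to 75% of the model's no-support spanning penalty at a
#'   nominal 25-kbp junction: masking concentrated support near contig ends
#'   always drives the robust score somewhat negative, so the robust break
#'   criterion requires the score to approach the no-information floor.
#' @param rounds iterative-join rounds (default 3).
#' @param K mixture components fitted (default 3).
#' @param trim minimum trimmed fraction per tail in the noise-product
#'   estimate (default 0.01); the pipeline widens it to twice the observed
#'   linked-contig-pair fraction when that is larger.
#' @param max_span support cutoff of the fitted separation model (bp): the
#'   input-DNA fragment length (default 150 kbp).
#' @param break_iterations break/rescaffold iterations: one pre-pass on input
#'   contigs and one post-pass on scaffold joins per iteration (default 1).
#' @param seed integer seed for the (few) randomised steps, e.g. the
#'   contig-pair sample of the noise estimate.
#' @return a `hirise_config` list.
#' @export
hirise_config <- function(mapq_min = 20, mask_target = 0.005,
                          promiscuous_window = 1000,
                          promiscuous_contig_limit = 4,
                          promiscuous_min_links = 2,
                          cluster_cap = 0.05, tail_exclude = 0.05,
                          k = 2, w = 4, g_o = 1000,
                          stride = 500, n_mask = 3, w_mask = 1000,
                          thr_raw = 0, thr_robust = NULL,
                          rounds = 3, K = 3, max_span = 150000,
                          trim = 0.01, break_iterations = 1, seed = 1) {
  assert_that(k >= 1, "`k` must be >= 1")
  assert_that(w >= 2 && w <= 5, "`w` must be in [2, 5] (cost grows as w!2^w)")
  assert_that(cluster_cap >= 0 && cluster_cap <= 1,
              "`cluster_cap` must lie in [0, 1]")
  assert_that(tail_exclude >= 0 && tail_exclude <= 1,
              "`tail_exclude` must lie in [0, 1]")
  structure(as.list(environment()), class = "hirise_config")
}

#' Mask high-depth (repeat-like) intervals from a shotgun depth track
#'
#' Repetitive regions attract misleading proximity-ligation links. Given a
#' per-interval read-depth track, this finds all maximal intervals with depth
#' exceeding `t1` that contain at least one base exceeding `t2`. The pair
#' `(t1, t2)` is searched on the depth quantile grid (with `t1 = t2 / 2`) so
#' that the masked fraction of the assembly is the largest value not
#' exceeding `mask_target`; ties break toward masking the most extreme depth.
#'
#' @param depth tibble with columns `chrom`, `start`, `end`, `depth`
#'   (0-based half-open intervals covering the assembly).
#' @param mask_target target masked fraction (default 0.005).
#' @return list with `intervals` (tibble `chrom`, `start`, `end`), `t1`,
#'   `t2`, and `masked_fraction`.
#' @export
mask_high_depth <- function(depth, mask_target = 0.005) {
  total <- sum(depth$end - depth$start)
  vals <- sort(unique(depth$depth), decreasing = TRUE)
  if (length(vals) <= 1) {
    warn("flat depth track: nothing to mask")
    return(list(intervals = tibble(chrom = character(0), start = numeric(0),
                                   end = numeric(0)),
                t1 = Inf, t2 = Inf, masked_fraction = 0))
  }
  mask_for <- function(t2) {
    t1 <- t2 / 2
    depth %>%
      group_by(.data$chrom) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      mutate(over = .data$depth > t1,
             run = cumsum(!.data$over | .data$start !=
                            dplyr::lag(.data$end, default = -1) |
                            !dplyr::lag(.data$over, default = FALSE))) %>%
      filter(.data$over) %>%
      group_by(.data$chrom, .data$run) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                peak = max(.data$depth), .groups = "drop") %>%
      filter(.data$peak > t2) %>%
      select("chrom", "start", "end")
  }
  best <- NULL
  # candidates sit just below each observed depth so the strict comparisons
  # can fire on the depth values actually present
  for (t2 in vals - 0.5) { # descending: most extreme masks first
    iv <- mask_for(t2)
    frac <- sum(iv$end - iv$start) / total
    if (frac <= mask_target) {
      best <- list(intervals = iv, t1 = t2 / 2, t2 = t2,
                   masked_fraction = frac)
    } else break         # masked fraction grows as t2 decreases
  }
  if (is.null(best) || nrow(best$intervals) == 0) {
    if (is.null(best)) {
      best <- list(intervals = tibble(chrom = character(0),
                                      start = numeric(0), end = numeric(0)),
                   t1 = Inf, t2 = Inf, masked_fraction = 0)
    }
  }
  best
}

# TRUE for positions falling inside any mask interval (per contig)
in_mask <- function(chrom, pos, masks) {
  if (is.null(masks) || nrow(masks) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(masks$chrom)) {
    mi <- masks[masks$chrom == ch, ]
    mi <- mi[order(mi$start), ]
    sel <- which(chrom == ch)
    if (length(sel) == 0) next
    idx <- findInterval(pos[sel], mi$start)
    hit[sel] <- idx >= 1 & pos[sel] < mi$end[pmax(idx, 1)]
  }
  hit
}

#' Filter mapped pairs before graph construction
#'
#' Applies, in order: the map-quality filter (both ends at or above
#' `mapq_min`), duplicate removal, mask filtering (either end inside a masked
#' interval), and the promiscuous-window filter: any fixed
#' `promiscuous_window`-bp tile linked to more than `promiscuous_contig_limit`
#' other contigs by at least `promiscuous_min_links` links (tallied on the
#' post-mapq/duplicate/mask set) has all its links removed. Each pair is
#' tallied under the first rule that rejects it, so the tallies plus the
#' retained count reconstruct the input count exactly.
#'
#' @param pairs pair tibble (`chr*`, `pos*`, `mapq*`, `dup`).
#' @param masks mask intervals (tibble `chrom`, `start`, `end`) or NULL.
#' @param config a [hirise_config()].
#' @return list with `pairs` (retained) and `tally` (tibble `reason`, `n`).
#' @export
filter_pairs <- function(pairs, masks = NULL, config = hirise_config()) {
  n0 <- nrow(pairs)
  bad_mapq <- pairs$mapq1 < config$mapq_min | pairs$mapq2 < config$mapq_min
  dup <- !bad_mapq & pairs$dup
  masked <- !bad_mapq & !dup &
    (in_mask(pairs$chr1, pairs$pos1, masks) |
       in_mask(pairs$chr2, pairs$pos2, masks))
  keep <- !(bad_mapq | dup | masked)
  kept <- pairs[keep, , drop = FALSE]

  # promiscuous 1-kbp windows: fixed tiles, tallied on the filtered set
  win <- config$promiscuous_window
  w1 <- paste0(kept$chr1, ":", floor(kept$pos1 / win))
  w2 <- paste0(kept$chr2, ":", floor(kept$pos2 / win))
  inter <- kept$chr1 != kept$chr2
  wc <- bind_rows(
    tibble(window = w1[inter], other = kept$chr2[inter]),
    tibble(window = w2[inter], other = kept$chr1[inter])
  )
  promiscuous_windows <- character(0)
  if (nrow(wc) > 0) {
    promiscuous_windows <- wc %>%
      dplyr::count(.data$window, .data$other) %>%
      filter(.data$n >= config$promiscuous_min_links) %>%
      dplyr::count(.data$window) %>%
      filter(.data$n > config$promiscuous_contig_limit) %>%
      pull(.data$window)
  }
  promiscuous <- w1 %in% promiscuous_windows | w2 %in% promiscuous_windows
  out <- kept[!promiscuous, , drop = FALSE]
  tally <- tibble(
    reason = c("low_mapq", "duplicate", "masked", "promiscuous", "retained"),
    n = c(sum(bad_mapq), sum(dup), sum(masked), sum(promiscuous), nrow(out))
  )
  stopifnot(sum(tally$n) == n0)
  list(pairs = out, tally = tally,
       promiscuous_windows = promiscuous_windows)
}

#' Build the contig-contig link graph
#'
#' Contigs are nodes (carrying their lengths); each linked contig pair is an
#' undirected edge labelled with the full collection of paired read offsets
#' (positions within each contig's own coordinates). Intra-contig pairs are
#' not edges: they are routed to a per-contig internal-offset store and fuel
#' the break-support profiles.
#'
#' @param pairs filtered pair tibble.
#' @param contigs tibble `contig`, `length`.
#' @return a `link_graph`: list with `nodes`, `edges` (tibble `contig1`,
#'   `contig2`, `n`, `offsets` list-column of tibbles `x1`, `x2`) and
#'   `internal` (tibble `contig`, `offsets`).
#' @export
build_link_graph <- function(pairs, contigs) {
  unknown <- setdiff(unique(c(pairs$chr1, pairs$chr2)), contigs$contig)
  if (length(unknown) > 0) {
    abort(paste("pairs reference unknown contig(s):",
                paste(head(unknown, 5), collapse = ", ")))
  }
  intra <- pairs$chr1 == pairs$chr2
  internal <- pairs[intra, , drop = FALSE] %>%
    group_by(contig = .data$chr1) %>%
    summarise(offsets = list(tibble(x1 = pos1, x2 = pos2)),
              .groups = "drop")
  inter <- pairs[!intra, , drop = FALSE]
  if (nrow(inter) > 0) {
    flip <- inter$chr1 > inter$chr2
    c1 <- ifelse(flip, inter$chr2, inter$chr1)
    c2 <- ifelse(flip, inter$chr1, inter$chr2)
    p1 <- ifelse(flip, inter$pos2, inter$pos1)
    p2 <- ifelse(flip, inter$pos1, inter$pos2)
    edges <- tibble(contig1 = c1, contig2 = c2, x1 = p1, x2 = p2) %>%
      group_by(.data$contig1, .data$contig2) %>%
      summarise(n = dplyr::n(), offsets = list(tibble(x1 = x1, x2 = x2)),
                .groups = "drop")
  } else {
    edges <- tibble(contig1 = character(0), contig2 = character(0),
                    n = integer(0), offsets = list())
  }
  structure(list(nodes = contigs, edges = edges, internal = internal),
            class = "link_graph")
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf("<link_graph> %d contigs, %d edges, %d links, %d contigs with internal pairs\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$n), nrow(x$internal)))
  invisible(x)
}

#' Partition the link graph into components under a link threshold
#'
#' Chooses the smallest integer link threshold `t_L` such that, keeping only
#' edges with at least `t_L` links, no connected component contains more than
#' `cluster_cap` of the contigs; returns the component assignment under that
#' threshold. If no threshold up to the maximum link count works, every
#' contig becomes a singleton (with a warning).
#'
#' @param graph a [build_link_graph()] object.
#' @param cluster_cap maximum component size as a fraction of the contig
#'   count (default 0.05).
#' @return list with `components` (tibble `contig`, `component`), `t_L`.
#' @export
partition_components <- function(graph, cluster_cap = 0.05) {
  assert_that(nrow(graph$nodes) > 0, "empty graph")
  n_contig <- nrow(graph$nodes)
  cap <- cluster_cap * n_contig
  # the subgraph only changes at observed link counts, so scan those; the
  # reported t_L is the smallest INTEGER with the property, i.e. one past
  # the previous observed count
  thresholds <- sort(unique(c(1, graph$edges$n)))
  t_L <- NA_integer_
  comp <- NULL
  for (j in seq_along(thresholds)) {
    t <- thresholds[j]
    e <- graph$edges[graph$edges$n >= t, , drop = FALSE]
    ig <- igraph::graph_from_data_frame(
      e[, c("contig1", "contig2")], directed = FALSE,
      vertices = graph$nodes$contig
    )
    cc <- igraph::components(ig)
    if (max(cc$csize) <= cap) {
      t_L <- if (j == 1) as.integer(t) else
        as.integer(thresholds[j - 1] + 1)
      comp <- tibble(contig = names(cc$membership),
                     component = as.integer(cc$membership))
      break
    }
  }
  if (is.na(t_L)) {
    warn("no link threshold satisfies the cluster cap; returning singletons")
    t_L <- max(graph$edges$n, 0) + 1L
    comp <- tibble(contig = graph$nodes$contig,
                   component = seq_len(n_contig))
  }
  list(components = comp, t_L = t_L)
}

#' Remove edges of promiscuous contigs
#'
#' A contig is promiscuous when its graph degree per bp of length exceeds
#' `t_p`, or when it has at least `t_L` links to more than `d_m` distinct
#' contigs; both thresholds are set at the `1 - tail_exclude` quantile of
#' their respective distributions, excluding the upper tail. All edges
#' incident to promiscuous contigs are removed.
#'
#' @param graph a [build_link_graph()] object (typically one component).
#' @param t_L link threshold from [partition_components()].
#' @param tail_exclude upper-tail fraction to exclude (default 0.05).
#' @return list with `graph` (filtered), `t_p`, `d_m`, and
#'   `promiscuous` (contig ids).
#' @export
filter_edges <- function(graph, t_L = 2, tail_exclude = 0.05) {
  e <- graph$edges
  if (nrow(e) == 0 || tail_exclude == 0) {
    return(list(graph = graph, t_p = Inf, d_m = Inf,
                promiscuous = character(0)))
  }
  deg <- tibble(contig = c(e$contig1, e$contig2)) %>%
    dplyr::count(.data$contig, name = "degree") %>%
    left_join(graph$nodes, by = "contig") %>%
    mutate(ratio = .data$degree / .data$length)
  strong <- tibble(contig = c(e$contig1, e$contig2),
                   n = rep(e$n, 2)) %>%
    filter(.data$n >= t_L) %>%
    dplyr::count(.data$contig, name = "n_strong")
  deg <- deg %>% left_join(strong, by = "contig") %>%
    mutate(n_strong = dplyr::coalesce(.data$n_strong, 0L))
  t_p <- as.numeric(quantile(deg$ratio, 1 - tail_exclude, names = FALSE))
  d_m <- as.numeric(quantile(deg$n_strong, 1 - tail_exclude, names = FALSE))
  promiscuous <- deg$contig[deg$ratio > t_p | deg$n_strong > d_m]
  e2 <- e[!(e$contig1 %in% promiscuous | e$contig2 %in% promiscuous), ,
          drop = FALSE]
  g2 <- graph
  g2$edges <- e2
  list(graph = g2, t_p = t_p, d_m = d_m, promiscuous = promiscuous)
}

#' Extract high-confidence linear seed paths
#'
#' Scores every edge by its best-orientation join LLR at the standard gap,
#' drops unsupported edges (LLR <= 0), finds the maximum-support spanning
#' forest (Kruskal on negated scores: the support score is a gain, not a
#' cost), then linearizes by three rounds of deleting all degree-1 nodes
#' followed by all nodes of degree greater than 2. Remaining components with
#' a simple-path topology are emitted as ordered contig sequences; everything
#' else returns to the singleton pool (and re-enters at the merge stage).
#'
#' @param graph a (filtered) [build_link_graph()] object.
#' @param model a [link_model()].
#' @param g_o standard gap (bp) for edge scoring.
#' @return list with `paths` (list of character vectors of contig ids) and
#'   `edge_scores` (tibble `contig1`, `contig2`, `n`, `llr`, `orientation`).
#' @export
linearize_graph <- function(graph, model, g_o = 1000) {
  e <- graph$edges
  if (nrow(e) == 0) {
    return(list(paths = list(),
                edge_scores = tibble(contig1 = character(0),
                                     contig2 = character(0), n = integer(0),
                                     llr = numeric(0),
                                     orientation = character(0))))
  }
  sc <- score_edges(e, graph$nodes, model, g_o)
  keep <- sc$llr > 0
  es <- sc[keep, , drop = FALSE]
  if (nrow(es) == 0) return(list(paths = list(), edge_scores = sc))
  ig <- igraph::graph_from_data_frame(
    es[, c("contig1", "contig2")], directed = FALSE,
    vertices = unique(c(es$contig1, es$contig2))
  )
  igraph::E(ig)$weight <- -es$llr
  msf <- igraph::mst(ig)
  for (round in 1:3) {
    d1 <- igraph::V(msf)[igraph::degree(msf) == 1]
    msf <- igraph::delete_vertices(msf, d1)
    dh <- igraph::V(msf)[igraph::degree(msf) > 2]
    msf <- igraph::delete_vertices(msf, dh)
  }
  comps <- igraph::components(msf)
  paths <- list()
  for (ci in seq_len(comps$no)) {
    vs <- names(comps$membership)[comps$membership == ci]
    if (length(vs) < 2) next
    sub <- igraph::induced_subgraph(msf, vs)
    degs <- igraph::degree(sub)
    if (max(degs) > 2 || sum(degs == 1) != 2) next  # not a simple path
    ends <- names(degs)[degs == 1]
    p <- igraph::shortest_paths(sub, from = ends[1], to = ends[2],
                                weights = NA)$vpath[[1]]
    if (length(p) != length(vs)) next               # cycle remnant
    paths[[length(paths) + 1]] <- names(p)
  }
  # deterministic order: by first contig id
  if (length(paths) > 1) {
    paths <- paths[order(vapply(paths, `[`, character(1), 1))]
  }
  list(paths = paths, edge_scores = sc)
}

# best-orientation join LLR for every edge at gap g_o, vectorised over all
# links of all edges at once
score_edges <- function(edges, nodes, model, g_o) {
  if (nrow(edges) == 0) {
    return(tibble(contig1 = character(0), contig2 = character(0),
                  n = integer(0), llr = numeric(0),
                  orientation = character(0)))
  }
  l1 <- nodes$length[match(edges$contig1, nodes$contig)]
  l2 <- nodes$length[match(edges$contig2, nodes$contig)]
  idx <- rep(seq_len(nrow(edges)), edges$n)
  x1 <- unlist(lapply(edges$offsets, `[[`, "x1"), use.names = FALSE)
  x2 <- unlist(lapply(edges$offsets, `[[`, "x2"), use.names = FALSE)
  L1 <- l1[idx]; L2 <- l2[idx]
  dens <- function(d) {
    s <- rowsum(llr_terms(d, model), idx)
    out <- numeric(nrow(edges))
    out[as.integer(rownames(s))] <- s
    out
  }
  span_pen <- (model$N - edges$n) * log1p(-span_probability(l1, l2, g_o, model))
  scores <- cbind(
    `++` = dens((L1 - x1) + g_o + x2),
    `+-` = dens((L1 - x1) + g_o + (L2 - x2)),
    `-+` = dens(x1 + g_o + x2),
    `--` = dens(x1 + g_o + (L2 - x2))
  ) + span_pen
  best <- max.col(scores, ties.method = "first")
  tibble(contig1 = edges$contig1, contig2 = edges$contig2, n = edges$n,
         llr = scores[cbind(seq_len(nrow(scores)), best)],
         orientation = colnames(scores)[best])
}
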