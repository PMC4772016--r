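#' Orient an ordered contig path by dynamic programming
#'
#' Each contig in an ordered path can enter the assembly in forward or
#' reverse orientation. The optimal assignment maximises the summed join LLR
#' over all linked contig pairs within `k` positions of one another (gaps
#' implied by the intervening contig lengths plus one standard gap per step).
#' The `k`-step dependency structure makes the maximum computable exactly by
#' DP over the orientations of the last `k` contigs; links that jump over
#' small intercalated contigs are what make `k > 1` valuable. Note that with
#' offset-resolved link scoring the objective is not invariant under flipping
#' every orientation at a fixed order (the mirror layout is instead reached
#' by reversing the order as well), so the argmax is returned as found;
#' enumeration order makes it deterministic.
#'
#' @param path character vector of contig ids in layout order.
#' @param graph a [build_link_graph()] (or any list with `edges`, `nodes`).
#' @param model a [link_model()].
#' @param k lookback (default 2).
#' @param g_o standard per-step gap (bp).
#' @return list with `orientation` (character vector) and `score` (total
#'   summed join LLR over pairs within `k` steps).
#' @export
orient_path <- function(path, graph, model, k = 2, g_o = 1000) {
  n <- length(path)
  if (n == 1) return(list(orientation = "+", score = 0))
  ctx <- make_ctx(graph$edges, graph$nodes, model, g_o = g_o,
                  horizon = Inf)
  len <- ctx$len[path]
  # gap between path positions i < j: intervening lengths + one g_o per step
  gap_ij <- function(i, j) {
    sum(len[seq(i + 1, length.out = j - i - 1)]) + (j - i) * g_o
  }
  ors <- c("+", "-")
  # pairwise score matrices m[[i]][[j-i]][oi, oj]
  m <- vector("list", n)
  for (j in 2:n) {
    for (i in max(1, j - k):(j - 1)) {
      g <- gap_ij(i, j)
      mat <- matrix(0, 2, 2, dimnames = list(ors, ors))
      for (oi in ors) for (oj in ors) {
        mat[oi, oj] <- score_pair(path[i], path[j], oi, oj, g, ctx)
      }
      if (is.null(m[[j]])) m[[j]] <- list()
      m[[j]][[as.character(i)]] <- mat
    }
  }
  # DP over states = orientations of the last k contigs (as bit vectors)
  kk <- min(k, n - 1)
  n_states <- 2^kk
  state_or <- function(s) {  # orientation vector (oldest..newest) of state s
    ors[1 + ((s %/% 2^((kk - 1):0)) %% 2)]
  }
  states <- lapply(seq_len(n_states) - 1, state_or)
  # initialise at position kk+1 prefix: enumerate orientations of 1..kk fully
  # (cheap since kk <= k small), rolling in pair scores among the prefix
  score <- rep(-Inf, n_states)
  back <- vector("list", n)
  prefix_sets <- as.matrix(expand.grid(rep(list(ors), kk),
                                       stringsAsFactors = FALSE))
  for (r in seq_len(nrow(prefix_sets))) {
    o <- prefix_sets[r, ]
    val <- 0
    if (kk > 1) {
      for (j in 2:kk) for (i in max(1, j - k):(j - 1)) {
        val <- val + m[[j]][[as.character(i)]][o[i], o[j]]
      }
    }
    s <- sum((o == "-") * 2^((kk - 1):0)) + 1
    if (val > score[s]) score[s] <- val
  }
  for (pos in seq(kk + 1, n)) {
    new_score <- rep(-Inf, n_states)
    new_back <- vector("list", n_states)
    for (s in seq_len(n_states)) {
      if (!is.finite(score[s])) next
      prev_or <- states[[s]]  # orientations of pos-kk .. pos-1
      for (oi in ors) {
        add <- 0
        for (back_i in seq_len(kk)) {
          i <- pos - kk + back_i - 1
          if (i < max(1, pos - k)) next
          add <- add + m[[pos]][[as.character(i)]][prev_or[back_i], oi]
        }
        ns <- sum((c(prev_or[-1], oi) == "-") * 2^((kk - 1):0)) + 1
        cand <- score[s] + add
        if (cand > new_score[ns]) {
          new_score[ns] <- cand
          new_back[[ns]] <- c(s, oi)
        }
      }
    }
    score <- new_score
    back[[pos]] <- new_back
  }
  s_best <- which.max(score)
  total <- score[s_best]
  # backtrack
  orientation <- character(n)
  s <- s_best
  for (pos in seq(n, kk + 1)) {
    bk <- back[[pos]][[s]]
    orientation[pos] <- bk[2]
    s <- as.integer(bk[1])
  }
  orientation[seq_len(kk)] <- states[[s]]
  list(orientation = orientation, score = total)
}

#' Classify contig ends as free or buried
#'
#' A contig end is free when it faces outward at a scaffold terminus (both
#' ends of a singleton are free) and buried when it is internal to a
#' scaffold. Ends are labelled in each contig's own coordinates
#' (`"start"` = coordinate 0 side, `"end"` = coordinate `length` side).
#'
#' @param layout a layout tibble (`scaffold`, `idx`, `contig`, `orientation`,
#'   `gap_before`).
#' @return tibble `contig`, `end`, `free`.
#' @export
classify_ends <- function(layout) {
  layout %>%
    group_by(.data$scaffold) %>%
    mutate(m = dplyr::n()) %>%
    ungroup() %>%
    tidyr::crossing(end = c("start", "end")) %>%
    dplyr::rowwise() %>%
    mutate(side = end_side(.data$orientation, .data$end),
           free = (.data$side == "left" & .data$idx == 1) |
             (.data$side == "right" & .data$idx == .data$m)) %>%
    ungroup() %>%
    select("contig", "end", "free")
}

#' Merge seed scaffolds and singletons within a component
#'
#' Computes the join LLR at the standard gap for every candidate contig-end
#' pair connected by an edge, then walks the candidates in decreasing score
#' order. Depending on whether the two ends are free or buried and on which
#' scaffolds they live, the implied move is an end-to-end join, the insertion
#' of one scaffold into the gap next to a buried end, the inversion of the
#' segment between two same-scaffold ends, or the best of the four end-to-end
#' joinings of two scaffolds. A move is accepted iff the summed LLR change
#' over all affected contig pairs is positive; the pool is updated live, so
#' later candidates see earlier acceptances.
#'
#' @param layout starting layout tibble (seeds plus singletons).
#' @param graph a [build_link_graph()] restricted to the component.
#' @param model a [link_model()].
#' @param config a [hirise_config()].
#' @return list `layout` (merged), `log` (per-candidate audit tibble).
#' @export
merge_within_component <- function(layout, graph, model,
                                   config = hirise_config()) {
  ctx <- make_ctx(graph$edges, graph$nodes, model, g_o = config$g_o)
  cand <- end_pair_candidates(graph$edges, graph$nodes, model, config$g_o)
  cand <- cand[cand$score > 0, , drop = FALSE]
  pool <- pool_from_layout(layout)
  res <- run_moves(pool, cand, ctx, allow_same_scaffold = TRUE,
                   conflict = "none")
  list(layout = pool_to_layout(res$pool), log = res$log)
}

#' Local order-and-orientation refinement by sliding-window enumeration
#'
#' Slides a window of `w` contigs along each scaffold; at each position all
#' `w! 2^w` orderings and orientations of the window contigs are scored
#' (flanking contigs fixed, within-window and window-flank link terms
#' evaluated at standard gaps) and the best is kept when it improves the
#' incumbent. Passes repeat until no window improves. For scaffolds of at
#' most `w` contigs this is a single exhaustive enumeration, hence exact.
#' The returned layout never scores below the input.
#'
#' @param layout layout tibble (one or more scaffolds).
#' @param graph a [build_link_graph()].
#' @param model a [link_model()].
#' @param w window size, 2..5 (cost grows as `w! 2^w`).
#' @param g_o standard gap (bp) used for scoring candidate arrangements.
#' @param max_passes maximum sweeps per scaffold (default 3); after the
#'   first pass only windows near an accepted rearrangement are revisited.
#' @param reach scoring horizon (bp) during refinement: pairs further apart
#'   in the layout contribute no ordering information worth the enumeration
#'   cost (default 60 kbp; capped by the model's `max_span`).
#' @return refined layout tibble.
#' @export
refine_local <- function(layout, graph, model, w = 4, g_o = 1000,
                         max_passes = 3, reach = 60000) {
  assert_that(w >= 2 && w <= 5,
              "`w` must be in [2, 5]: enumeration cost grows as w!2^w")
  ctx <- make_ctx(graph$edges, graph$nodes, model, g_o = g_o,
                  horizon = min(reach, model$max_span))
  perms <- all_permutations(w)
  orient_sets <- as.matrix(expand.grid(rep(list(c("+", "-")), w),
                                       stringsAsFactors = FALSE))
  out <- lapply(split(seq_len(nrow(layout)), layout$scaffold), function(ix) {
    o <- ix[order(layout$idx[ix])]
    ch <- chain_new(layout$contig[o], layout$orientation[o],
                    rep(g_o, length(o)))
    refine_chain(ch, ctx, w, perms, orient_sets, max_passes)
  })
  purrr::map_dfr(names(out), function(s) {
    ch <- out[[s]]
    tibble(scaffold = s, idx = seq_along(ch$contig), contig = ch$contig,
           orientation = ch$orientation, gap_before = ch$gap_before)
  })
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

refine_chain <- function(ch, ctx, w, perms, orient_sets, max_passes) {
  m <- chain_len(ch)
  if (m < 2) return(ch)
  ww <- min(w, m)
  if (ww < w) {
    perms <- all_permutations(ww)
    orient_sets <- as.matrix(expand.grid(rep(list(c("+", "-")), ww),
                                         stringsAsFactors = FALSE))
  }
  dirty <- rep(TRUE, m)   # positions worth revisiting
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    next_dirty <- rep(FALSE, m)
    for (p in seq_len(m - ww + 1)) {
      core <- p:(p + ww - 1)
      if (!any(dirty[core])) next
      wix <- window_around(ch, p, p + ww - 1, ctx)
      win <- chain_slice(ch, wix)
      core_w <- core - min(wix) + 1
      best_val <- window_best(win, core_w, NULL, NULL, ctx,
                              incumbent = TRUE)
      sweep <- window_best(win, core_w, perms, orient_sets, ctx)
      if (sweep$val > best_val + 1e-9) {
        ch$contig[core] <- win$contig[core_w][sweep$perm]
        ch$orientation[core] <- sweep$orientation
        improved <- TRUE
        touch <- max(1, p - ww):min(m, p + 2 * ww - 1)
        next_dirty[touch] <- TRUE
      }
    }
    dirty <- next_dirty
    if (!improved) break
  }
  ch
}

# Score all (perm, orientation-set) arrangements of the core slots of a
# window. Pair evaluations are shared across the 2^w orientation sets of a
# permutation: each affected pair is scored once per needed orientation
# variant and the per-arrangement totals assembled by indexing.
window_best <- function(win, core_w, perms, orient_sets, ctx,
                        incumbent = FALSE) {
  if (incumbent) {
    return(score_chain(win, ctx, focus = core_w))
  }
  mw <- chain_len(win)
  ww <- length(core_w)
  best <- list(val = -Inf, perm = NULL, orientation = NULL)
  or_mat <- orient_sets == "-"   # logical: TRUE = minus
  for (ri in seq_len(nrow(perms))) {
    cand <- win
    cand$contig[core_w] <- win$contig[core_w][perms[ri, ]]
    co <- chain_coords(cand, ctx)
    # pairs touching the core within the horizon, with slot bookkeeping
    slot_of <- integer(mw)            # 0 = flank (orientation fixed)
    slot_of[core_w] <- seq_len(ww)
    pi <- integer(0); pj <- integer(0); pgap <- numeric(0)
    for (i in seq_len(mw - 1)) {
      for (j in (i + 1):mw) {
        gap <- co$start[j] - co$end[i]
        if (gap > ctx$horizon) break
        if (slot_of[i] == 0 && slot_of[j] == 0) next
        pi <- c(pi, i); pj <- c(pj, j); pgap <- c(pgap, max(gap, 0))
      }
    }
    if (length(pi) == 0) next
    npair <- length(pi)
    # variant values: columns (oa,ob) in {++, +-, -+, --}
    V <- matrix(NA_real_, npair, 4)
    for (q in seq_len(npair)) {
      a <- cand$contig[pi[q]]; b <- cand$contig[pj[q]]
      oa_set <- if (slot_of[pi[q]] > 0) c("+", "-") else
        cand$orientation[pi[q]]
      ob_set <- if (slot_of[pj[q]] > 0) c("+", "-") else
        cand$orientation[pj[q]]
      for (oa in oa_set) for (ob in ob_set) {
        cidx <- 2 * (oa == "-") + (ob == "-") + 1
        V[q, cidx] <- score_pair(a, b, oa, ob, pgap[q], ctx)
      }
    }
    fixed_a <- cand$orientation[pi] == "-"
    fixed_b <- cand$orientation[pj] == "-"
    sa <- slot_of[pi]; sb <- slot_of[pj]
    for (si in seq_len(nrow(or_mat))) {
      o <- or_mat[si, ]
      a_minus <- ifelse(sa > 0, o[pmax(sa, 1)], fixed_a)
      b_minus <- ifelse(sb > 0, o[pmax(sb, 1)], fixed_b)
      val <- sum(V[cbind(seq_len(npair), 2 * a_minus + b_minus + 1)])
      if (val > best$val) {
        best <- list(val = val, perm = perms[ri, ],
                     orientation = ifelse(o, "-", "+"))
      }
    }
  }
  best
}

#' Iterative end-to-end and intercalating scaffold joining
#'
#' Pools all scaffolds and repeats rounds of joining: every round scores all
#' candidate contig-end pairs across scaffolds, sorts them by decreasing
#' score, and greedily accepts non-conflicting moves (end-to-end joins and
#' insertions) whose summed LLR change is positive. A move conflicts when it
#' touches a scaffold already modified in the same round. Rounds stop early
#' when nothing is accepted; the total LLR never decreases.
#'
#' @inheritParams merge_within_component
#' @param rounds maximum number of rounds (default 3).
#' @return list `layout`, `log` (audit tibble with a `round` column).
#' @export
iterative_join <- function(layout, graph, model, config = hirise_config(),
                           rounds = config$rounds) {
  assert_that(rounds >= 1, "`rounds` must be >= 1")
  ctx <- make_ctx(graph$edges, graph$nodes, model, g_o = config$g_o)
  cand <- end_pair_candidates(graph$edges, graph$nodes, model, config$g_o)
  cand <- cand[cand$score > 0, , drop = FALSE]
  pool <- pool_from_layout(layout)
  logs <- list()
  for (rd in seq_len(rounds)) {
    res <- run_moves(pool, cand, ctx, allow_same_scaffold = FALSE,
                     conflict = "round")
    pool <- res$pool
    lg <- res$log
    lg$round <- rd
    logs[[rd]] <- lg
    if (!any(lg$accepted)) break
  }
  list(layout = pool_to_layout(pool), log = bind_rows(logs))
}

#' Detect low-support positions within contigs
#'
#' Computes the robust support profile of every contig with internal pairs
#' and extracts maximal runs of grid positions where the raw or the robust
#' score falls below its threshold. Runs closer than 300 bp are merged;
#' segments lying entirely within 1 kbp of a contig end are discarded. Each
#' remaining segment yields one break at its midpoint, or breaks at both
#' segment ends when the segment exceeds 1000 bp (a long weak stretch is cut
#' out whole). Contigs without internal pairs are skipped: an all-noise
#' profile carries no localisation signal.
#'
#' @param graph a [build_link_graph()] (uses `internal` offsets and `nodes`).
#' @param model a [link_model()].
#' @param config a [hirise_config()] (thresholds, stride, masking).
#' @return tibble `contig`, `pos`, `seg_start`, `seg_end`.
#' @export
detect_breaks <- function(graph, model, config = hirise_config()) {
  thr_robust <- resolve_thr_robust(config, model)
  out <- list()
  for (i in seq_len(nrow(graph$internal))) {
    ctg <- graph$internal$contig[i]
    len <- graph$nodes$length[match(ctg, graph$nodes$contig)]
    off <- graph$internal$offsets[[i]]
    prof <- robust_support_profile(len, off, model, stride = config$stride,
                                   n_mask = config$n_mask,
                                   w_mask = config$w_mask)
    if (nrow(prof) == 0) next
    low <- prof$llr < config$thr_raw | prof$robust_llr < thr_robust
    if (!any(low)) next
    runs <- rle(low)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    segs <- tibble(start = prof$pos[starts[runs$values]],
                   end = prof$pos[ends[runs$values]])
    # merge segments within 300 bp
    if (nrow(segs) > 1) {
      keep <- list(segs[1, ])
      for (r in 2:nrow(segs)) {
        last <- keep[[length(keep)]]
        if (segs$start[r] - last$end <= 300) {
          last$end <- segs$end[r]
          keep[[length(keep)]] <- last
        } else keep[[length(keep) + 1]] <- segs[r, ]
      }
      segs <- bind_rows(keep)
    }
    # drop segments entirely within 1 kbp of a contig end
    segs <- segs[!(segs$end <= 1000 | segs$start >= len - 1000), ,
                 drop = FALSE]
    if (nrow(segs) == 0) next
    # a single junction produces a robust-score dip up to about
    # (n_mask + 1) * w_mask wide on each side (inside that range the top
    # n_mask masked bins still eat essentially all one-sided support), so
    # only segments beyond that footprint indicate an extended weak region
    # and are cut at both ends; shorter segments break once, at the midpoint
    double_cut <- max(1000,
                      2 * (config$n_mask + 1) * config$w_mask + config$stride)
    brk <- purrr::map_dfr(seq_len(nrow(segs)), function(r) {
      s <- segs$start[r]; e <- segs$end[r]
      pos <- if (e - s > double_cut) c(s, e) else (s + e) / 2
      tibble(pos = pos, seg_start = s, seg_end = e)
    })
    brk <- brk[brk$pos > 1000 & brk$pos < len - 1000, , drop = FALSE]
    if (nrow(brk) > 0) {
      brk$contig <- ctg
      out[[length(out) + 1]] <- brk
    }
  }
  if (length(out) == 0) {
    return(tibble(contig = character(0), pos = numeric(0),
                  seg_start = numeric(0), seg_end = numeric(0)))
  }
  bind_rows(out) %>% select("contig", "pos", "seg_start", "seg_end")
}

#' Apply breakpoints: split contigs and remap pairs (and truth)
#'
#' Splits each broken contig into segments at the given positions, renaming
#' segments `<contig>.1`, `<contig>.2`, ...; pair coordinates are remapped
#' onto the segments and the truth map (when given) is carried through,
#' splitting placements at the cut.
#'
#' @param breaks tibble `contig`, `pos` (from [detect_breaks()]).
#' @param contigs tibble `contig`, `length`.
#' @param pairs pair tibble in contig coordinates.
#' @param truth optional truth map.
#' @return list `contigs`, `pairs`, `truth`, `segments` (the remap table).
#' @export
apply_breaks <- function(breaks, contigs, pairs, truth = NULL) {
  if (nrow(breaks) == 0) {
    return(list(contigs = contigs, pairs = pairs, truth = truth,
                segments = tibble(contig = character(0),
                                  seg_start = numeric(0),
                                  seg_end = numeric(0),
                                  new_contig = character(0))))
  }
  segs <- breaks %>%
    group_by(.data$contig) %>%
    summarise(cuts = list(sort(unique(floor(.data$pos)))), .groups = "drop") %>%
    left_join(contigs, by = "contig") %>%
    purrr::pmap_dfr(function(contig, cuts, length) {
      edges <- c(0, cuts, length)
      tibble(contig = contig,
             seg_start = head(edges, -1), seg_end = edges[-1],
             new_contig = sprintf("%s.%d", contig, seq_len(length(edges) - 1)))
    })
  new_contigs <- bind_rows(
    contigs %>% filter(!(.data$contig %in% segs$contig)),
    segs %>% transmute(contig = .data$new_contig,
                       length = .data$seg_end - .data$seg_start)
  )
  remap_end <- function(ctg, pos) {
    hit <- match(ctg, segs$contig)
    todo <- which(!is.na(hit))
    out_ctg <- ctg
    out_pos <- pos
    if (length(todo) > 0) {
      df <- tibble(q = todo, contig = ctg[todo], pos = pos[todo])
      j <- dplyr::inner_join(df, segs, by = "contig",
                             relationship = "many-to-many")
      j <- j[j$pos >= j$seg_start & j$pos < j$seg_end, , drop = FALSE]
      ord <- match(df$q, j$q)
      out_ctg[todo] <- j$new_contig[ord]
      out_pos[todo] <- j$pos[ord] - j$seg_start[ord]
    }
    list(contig = out_ctg, pos = out_pos)
  }
  e1 <- remap_end(pairs$chr1, pairs$pos1)
  e2 <- remap_end(pairs$chr2, pairs$pos2)
  new_pairs <- pairs
  new_pairs$chr1 <- e1$contig; new_pairs$pos1 <- e1$pos
  new_pairs$chr2 <- e2$contig; new_pairs$pos2 <- e2$pos

  new_truth <- truth
  if (!is.null(truth)) {
    untouched <- truth %>% filter(!(.data$contig %in% segs$contig))
    touched <- truth %>% filter(.data$contig %in% segs$contig)
    new_truth <- bind_rows(
      untouched,
      dplyr::inner_join(touched, segs, by = "contig",
                        relationship = "many-to-many") %>%
        mutate(ov_start = pmax(.data$c_start, .data$seg_start),
               ov_end = pmin(.data$c_end, .data$seg_end)) %>%
        filter(.data$ov_end > .data$ov_start) %>%
        mutate(
          start2 = ifelse(.data$strand == "+",
                          .data$start + (.data$ov_start - .data$c_start),
                          .data$start + (.data$c_end - .data$ov_end)),
          end2 = .data$start2 + (.data$ov_end - .data$ov_start),
          c_start2 = .data$ov_start - .data$seg_start,
          c_end2 = .data$ov_end - .data$seg_start
        ) %>%
        transmute(contig = .data$new_contig, part = 1L,
                  c_start = .data$c_start2, c_end = .data$c_end2,
                  chrom = .data$chrom, start = .data$start2,
                  end = .data$end2, strand = .data$strand) %>%
        group_by(.data$contig) %>%
        arrange(.data$c_start, .by_group = TRUE) %>%
        mutate(part = row_number()) %>%
        ungroup()
    )
  }
  list(contigs = new_contigs, pairs = new_pairs, truth = new_truth,
       segments = segs)
}

#' Break low-support scaffold joins
#'
#' Maps every inter-contig pair of each scaffold into scaffold coordinates
#' and evaluates the join support (raw and robust) at each junction between
#' adjacent contigs. Junctions where either score falls below its threshold
#' are cut, splitting the scaffold. This is the post-scaffolding counterpart
#' of the pre-pass contig breaking in [detect_breaks()].
#'
#' @param layout layout tibble.
#' @param graph a [build_link_graph()] (edge offsets are used).
#' @param model a [link_model()].
#' @param config a [hirise_config()].
#' @return list `layout` (with splits applied), `junctions` (audit tibble
#'   `scaffold`, `after_idx`, `llr`, `robust_llr`, `broken`).
#' @export
break_scaffold_joins <- function(layout, graph, model,
                                 config = hirise_config()) {
  thr_robust <- resolve_thr_robust(config, model)
  ctx <- make_ctx(graph$edges, graph$nodes, model, g_o = config$g_o)
  audits <- list()
  new_chains <- list()
  counter <- 0
  for (s in unique(layout$scaffold)) {
    sub <- layout[layout$scaffold == s, , drop = FALSE]
    sub <- sub[order(sub$idx), ]
    ch <- chain_new(sub$contig, sub$orientation, sub$gap_before)
    m <- chain_len(ch)
    if (m < 2) {
      counter <- counter + 1
      new_chains[[sprintf("sc%06d", counter)]] <- ch
      next
    }
    co <- chain_coords(ch, ctx)
    # scaffold-coordinate offsets of all pairs between scaffold contigs
    sp <- scaffold_pair_positions(ch, co, ctx)
    total <- co$end[m]
    cut_after <- logical(m - 1)
    aud <- tibble(scaffold = s, after_idx = seq_len(m - 1),
                  llr = NA_real_, robust_llr = NA_real_, broken = FALSE)
    for (j in seq_len(m - 1)) {
      J <- co$start[j + 1]  # junction coordinate
      raw <- junction_support(sp, J, total, model)
      rob <- junction_support(sp, J, total, model,
                              n_mask = config$n_mask,
                              w_mask = config$w_mask)
      aud$llr[j] <- raw
      aud$robust_llr[j] <- rob
      if (raw < config$thr_raw || rob < thr_robust) {
        cut_after[j] <- TRUE
        aud$broken[j] <- TRUE
      }
    }
    audits[[length(audits) + 1]] <- aud
    piece <- cumsum(c(0, cut_after))
    for (pc in unique(piece)) {
      counter <- counter + 1
      new_chains[[sprintf("sc%06d", counter)]] <-
        chain_slice(ch, which(piece == pc))
    }
  }
  pool <- pool_new(new_chains)
  list(layout = pool_to_layout(pool),
       junctions = if (length(audits)) bind_rows(audits) else
         tibble(scaffold = character(0), after_idx = integer(0),
                llr = numeric(0), robust_llr = numeric(0),
                broken = logical(0)))
}

# scaffold-coordinate positions (x1 < x2) of all inter-contig pairs of a
# chain, with their separation terms
scaffold_pair_positions <- function(ch, co, ctx) {
  m <- chain_len(ch)
  xs1 <- list(); xs2 <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (co$start[j] - co$end[i] > ctx$horizon) break
      a <- ch$contig[i]; b <- ch$contig[j]
      e <- if (a < b) ctx$edges[[paste(a, b, sep = "\r")]] else NULL
      if (a > b) {
        er <- ctx$edges[[paste(b, a, sep = "\r")]]
        if (!is.null(er)) e <- list(x1 = er$x2, x2 = er$x1)
      }
      if (is.null(e)) next
      pa <- if (ch$orientation[i] == "+") co$start[i] + e$x1 else
        co$end[i] - 1 - e$x1
      pb <- if (ch$orientation[j] == "+") co$start[j] + e$x2 else
        co$end[j] - 1 - e$x2
      xs1[[length(xs1) + 1]] <- pa
      xs2[[length(xs2) + 1]] <- pb
    }
  }
  x1 <- unlist(xs1) %||% numeric(0)
  x2 <- unlist(xs2) %||% numeric(0)
  lo <- pmin(x1, x2)
  hi <- pmax(x1, x2)
  tibble(x1 = lo, x2 = hi)
}

# support of a single scaffold position: same score as support_profile but
# evaluated at one coordinate, with optional robust masking
junction_support <- function(sp, J, total, model, n_mask = 0, w_mask = 1000) {
  str <- which(sp$x1 < J & sp$x2 >= J)
  terms <- if (length(str)) llr_terms(sp$x2[str] - sp$x1[str], model) else
    numeric(0)
  p0 <- span_probability(max(J, 1), max(total - J, 1), 0, model)
  raw <- (model$N - length(str)) * log1p(-p0) + sum(terms)
  if (n_mask == 0 || length(str) == 0) return(raw)
  removal <- function(coord) {
    s <- rowsum(terms, floor(coord / w_mask))
    s <- sort(s[s > 0], decreasing = TRUE)
    sum(head(s, n_mask))
  }
  raw - max(removal(J - 1 - sp$x1[str]), removal(sp$x2[str] - J))
}

# default robust-break threshold: 90% of the no-support spanning penalty at
# a nominal deep junction (25 kbp on each side), i.e. the masked support must
# fall essentially to the no-information floor. Clean contigs reach only
# about half of this even where masking removes all their concentrated
# support near an end.
resolve_thr_robust <- function(config, model) {
  config$thr_robust %||%
    (0.9 * model$N * log1p(-span_probability(25000, 25000, 0, model)))
}

#' Maximum-likelihood gap estimation
#'
#' Maximises the join LLR over the gap size on a log-spaced grid (with local
#' refinement around the grid optimum) for a fixed contig pair and
#' orientation. The confidence interval is the LLR-drop-of-2 region around
#' the maximum; the estimate is floored at 0.
#'
#' @param offsets tibble `x1`, `x2` of linking pair offsets.
#' @param l1,l2 contig lengths (bp).
#' @param orientation orientation of the pair (`"++"` etc.).
#' @param model a [link_model()].
#' @param g_default returned (flagged) when no informative pairs exist.
#' @return one-row tibble `gap`, `lo`, `hi`, `llr`, `estimable`.
#' @export
estimate_gap <- function(offsets, l1, l2, orientation, model,
                         g_default = 1000) {
  base <- if (nrow(offsets) > 0) {
    implied_separation(offsets$x1, offsets$x2, l1, l2, 0, orientation)
  } else numeric(0)
  informative <- base[base <= model$max_span]
  if (length(informative) == 0) {
    return(tibble(gap = g_default, lo = NA_real_, hi = NA_real_,
                  llr = NA_real_, estimable = FALSE))
  }
  grid <- unique(c(0, exp(seq(log(10), log(model$max_span),
                              length.out = 48))))
  lfun <- function(g) {
    vapply(g, function(gg) {
      sum(llr_terms(base + gg, model)) +
        (model$N - length(base)) *
        log1p(-span_probability(l1, l2, gg, model))
    }, numeric(1))
  }
  vals <- lfun(grid)
  i <- which.max(vals)
  lo_b <- grid[max(i - 1, 1)]
  hi_b <- grid[min(i + 1, length(grid))]
  opt <- optimise(function(g) -lfun(g), interval = c(lo_b, hi_b))
  g_hat <- max(opt$minimum, 0)
  l_hat <- -opt$objective
  if (vals[i] > l_hat) { g_hat <- grid[i]; l_hat <- vals[i] }
  ok <- vals >= l_hat - 2
  lo <- min(grid[ok])
  hi <- max(grid[ok])
  tibble(gap = g_hat, lo = lo, hi = hi, llr = l_hat, estimable = TRUE)
}
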