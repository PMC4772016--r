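# Internal scaffolding engine: chains, scoring context, move evaluation.
#
# A "chain" is the light-weight internal form of one scaffold: a list with
# character vector `contig`, character vector `orientation` and numeric
# vector `gap_before` (gap preceding each contig; the first entry is 0).
# Exported functions convert to/from the tidy layout tibble.

chain_new <- function(contig, orientation = rep("+", length(contig)),
                      gap_before = rep(0, length(contig))) {
  gap_before[1] <- 0
  list(contig = contig, orientation = orientation, gap_before = gap_before)
}

chain_len <- function(chain) length(chain$contig)

# reverse a chain: order and orientations flip, internal gaps reverse
chain_reverse <- function(chain) {
  m <- chain_len(chain)
  if (m == 0) return(chain)
  internal <- if (m > 1) rev(chain$gap_before[-1]) else numeric(0)
  chain_new(rev(chain$contig),
            ifelse(rev(chain$orientation) == "+", "-", "+"),
            c(0, internal))
}

chain_concat <- function(a, b, gap) {
  chain_new(c(a$contig, b$contig),
            c(a$orientation, b$orientation),
            c(a$gap_before, gap, if (chain_len(b) > 1) b$gap_before[-1]))
}

chain_slice <- function(chain, idx) {
  ch <- chain_new(chain$contig[idx], chain$orientation[idx],
                  chain$gap_before[idx])
  ch
}

# reverse the block lo..hi in place
chain_reverse_block <- function(chain, lo, hi) {
  m <- chain_len(chain)
  block <- chain_slice(chain, lo:hi)
  rb <- chain_reverse(block)
  # boundary gaps are retained; internal block gaps travel with the reversal
  gap_into <- chain$gap_before[lo]
  out <- chain
  out$contig[lo:hi] <- rb$contig
  out$orientation[lo:hi] <- rb$orientation
  out$gap_before[lo:hi] <- c(gap_into, rb$gap_before[-1])
  out
}

# layout coordinates of a chain under the given gaps
chain_coords <- function(chain, ctx) {
  len <- ctx$len[chain$contig]
  start <- cumsum(c(0, head(len, -1) + chain$gap_before[-1]))
  list(start = start, end = start + len, len = len)
}

# scoring context: contig lengths, hashed edge store, model, memo cache
make_ctx <- function(edges, nodes, model, g_o = 1000, horizon = NULL) {
  len <- setNames(as.numeric(nodes$length), nodes$contig)
  e_env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(edges) > 0) {
    keys <- paste(edges$contig1, edges$contig2, sep = "\r")
    for (i in seq_len(nrow(edges))) {
      assign(keys[i], edges$offsets[[i]], envir = e_env)
    }
  }
  Z <- trunc_norm(model)
  list(len = len, edges = e_env, model = model, g_o = g_o,
       horizon = horizon %||% model$max_span,
       # flattened model constants for the scoring hot path
       w = model$components$weight, lam = model$components$rate, Z = Z,
       wlz = model$components$weight * model$components$rate / Z,
       p_n = model$p_n, G = model$G, N = model$N, M = model$max_span,
       log_noise = log_noise_floor(model),
       memo = new.env(hash = TRUE, parent = emptyenv()))
}

# lean pair-density LLR terms (no validation; d >= 0 guaranteed by geometry)
fast_terms <- function(d, ctx) {
  sig <- numeric(length(d))
  ok <- d <= ctx$M
  if (any(ok)) {
    ds <- d[ok]
    acc <- 0
    for (k in seq_along(ctx$lam)) {
      acc <- acc + ctx$wlz[k] * exp(-ctx$lam[k] * ds)
    }
    sig[ok] <- acc
  }
  log(pmax(ctx$p_n / ctx$G + (1 - ctx$p_n) * sig, .DENS_FLOOR)) -
    ctx$log_noise
}

# lean scalar spanning probability (same closed form as span_probability)
fast_p0 <- function(l1, l2, g, ctx) {
  mn <- min(l1, l2); mx <- max(l1, l2)
  M <- ctx$M
  tot <- 0
  for (k in seq_along(ctx$lam)) {
    lam <- ctx$lam[k]
    pc <- function(s, t, alpha, beta) {
      s2 <- min(max(s, 0), M); t2 <- min(max(t, 0), M)
      if (t2 <= s2) return(0)
      exp(-lam * s2) * (alpha + beta * s2 + beta / lam) -
        exp(-lam * t2) * (alpha + beta * t2 + beta / lam)
    }
    ik <- pc(g, g + mn, -g, 1) + pc(g + mn, g + mx, mn, 0) +
      pc(g + mx, g + l1 + l2, g + l1 + l2, -1)
    tot <- tot + ctx$w[k] * ik / ctx$Z[k]
  }
  min(max(ctx$p_n * l1 * l2 / ctx$G^2 + (1 - ctx$p_n) * tot / ctx$G, 0), 1)
}

# offsets of the edge between a (left) and b (right), in that order
edge_offsets <- function(a, b, ctx) {
  if (a < b) return(ctx$edges[[paste(a, b, sep = "\r")]])
  er <- ctx$edges[[paste(b, a, sep = "\r")]]
  if (is.null(er)) NULL else list(x1 = er$x2, x2 = er$x1)
}

# join LLR of the ordered oriented pair (a left of b) at the given gap;
# memoised because move evaluation revisits the same (pair, o, gap) often
score_pair <- function(a, b, oa, ob, gap, ctx) {
  key <- paste(a, b, oa, ob, round(gap))
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)
  la <- ctx$len[[a]]; lb <- ctx$len[[b]]
  e <- edge_offsets(a, b, ctx)
  if (is.null(e)) {
    n <- 0L
    dens <- 0
  } else {
    d <- (if (oa == "+") la - e$x1 else e$x1) + gap +
      (if (ob == "+") e$x2 else lb - e$x2)
    n <- length(d)
    dens <- sum(fast_terms(d, ctx))
  }
  val <- dens + (ctx$N - n) * log1p(-fast_p0(la, lb, gap, ctx))
  ctx$memo[[key]] <- val
  val
}

# total LLR of a chain: sum of pair scores over all contig pairs whose
# layout gap is within the horizon. `focus`: only count pairs touching
# these indices (terms not involving them are constant across compared
# arrangements and may be skipped).
score_chain <- function(chain, ctx, focus = NULL) {
  m <- chain_len(chain)
  if (m < 2) return(0)
  co <- chain_coords(chain, ctx)
  total <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      gap <- co$start[j] - co$end[i]
      if (gap > ctx$horizon) break
      if (!is.null(focus) && !(i %in% focus) && !(j %in% focus)) next
      total <- total + score_pair(chain$contig[i], chain$contig[j],
                                  chain$orientation[i],
                                  chain$orientation[j], max(gap, 0), ctx)
    }
  }
  total
}

# indices of chain contigs within `horizon` layout distance of core lo..hi
window_around <- function(chain, lo, hi, ctx) {
  co <- chain_coords(chain, ctx)
  a <- lo
  while (a > 1 && co$start[lo] - co$end[a - 1] <= ctx$horizon) a <- a - 1
  b <- hi
  m <- chain_len(chain)
  while (b < m && co$start[b + 1] - co$end[hi] <= ctx$horizon) b <- b + 1
  a:b
}

# ---- pool: a mutable set of chains -----------------------------------------

pool_new <- function(chains) {
  p <- new.env(parent = emptyenv())
  p$chains <- chains
  loc <- character(0)
  for (s in names(chains)) {
    loc[chains[[s]]$contig] <- s
  }
  p$loc <- loc
  p$counter <- length(chains)
  p
}

pool_from_layout <- function(layout) {
  chains <- lapply(split(seq_len(nrow(layout)), layout$scaffold),
                   function(ix) {
                     o <- ix[order(layout$idx[ix])]
                     chain_new(layout$contig[o], layout$orientation[o],
                               layout$gap_before[o])
                   })
  pool_new(chains)
}

pool_to_layout <- function(pool) {
  chains <- pool$chains
  purrr::map_dfr(names(chains), function(s) {
    ch <- chains[[s]]
    tibble(scaffold = s, idx = seq_along(ch$contig), contig = ch$contig,
           orientation = ch$orientation, gap_before = ch$gap_before)
  })
}

pool_replace <- function(pool, drop_ids, new_chains) {
  for (s in drop_ids) pool$chains[[s]] <- NULL
  for (s in names(new_chains)) {
    pool$chains[[s]] <- new_chains[[s]]
    pool$loc[new_chains[[s]]$contig] <- s
  }
  invisible(pool)
}

pool_new_id <- function(pool) {
  pool$counter <- pool$counter + 1
  sprintf("pl%06d", pool$counter)
}

# layout side ("left"/"right") on which a given contig end faces, given the
# contig's orientation within its chain
end_side <- function(orientation, end) {
  if ((end == "start") == (orientation == "+")) "left" else "right"
}

# ---- candidate generation and move evaluation ------------------------------

# all-orientation edge scores mapped to contig-end pairs: joining
# (c1, end1) to (c2, end2) at the standard gap corresponds to the layout
# c1 (e1 facing right) | gap | c2 (e2 facing left)
end_pair_candidates <- function(edges, nodes, model, g_o) {
  if (nrow(edges) == 0) {
    return(tibble(contig1 = character(0), end1 = character(0),
                  contig2 = character(0), end2 = character(0),
                  score = numeric(0)))
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
  pen <- (model$N - edges$n) * log1p(-span_probability(l1, l2, g_o, model))
  combos <- list(  # orientation of (left=c1, right=c2) and the end labels
    list(o = "++", e1 = "end", e2 = "start",
         d = (L1 - x1) + g_o + x2),
    list(o = "+-", e1 = "end", e2 = "end",
         d = (L1 - x1) + g_o + (L2 - x2)),
    list(o = "-+", e1 = "start", e2 = "start",
         d = x1 + g_o + x2),
    list(o = "--", e1 = "start", e2 = "end",
         d = x1 + g_o + (L2 - x2))
  )
  purrr::map_dfr(combos, function(cb) {
    tibble(contig1 = edges$contig1, end1 = cb$e1,
           contig2 = edges$contig2, end2 = cb$e2,
           score = dens(cb$d) + pen)
  })
}

# orient chain A so that the end (contig, end) of A faces the join side
orient_for_join <- function(chain, contig, end, face) {
  idx <- match(contig, chain$contig)
  side <- end_side(chain$orientation[idx], end)
  if (face == "right") {
    if (side == "left") chain_reverse(chain) else chain
  } else {
    if (side == "right") chain_reverse(chain) else chain
  }
}

# delta of joining oriented chains A (right end) and B (left end) at gap g_o
eval_join <- function(A, B, ctx) {
  co_a <- chain_coords(A, ctx)
  co_b <- chain_coords(B, ctx)
  ma <- chain_len(A)
  ja <- window_around(A, ma, ma, ctx)
  jb <- window_around(B, 1, 1, ctx)
  tA <- chain_slice(A, ja)
  hB <- chain_slice(B, jb)
  joined <- chain_concat(tA, hB, ctx$g_o)
  delta <- score_chain(joined, ctx) - score_chain(tA, ctx) -
    score_chain(hB, ctx)
  list(delta = delta, chain = chain_concat(A, B, ctx$g_o))
}

# delta of inserting chain F between positions p and p+1 of chain S
eval_insert <- function(S, F, p, ctx) {
  core <- window_around(S, max(p, 1), min(p + 1, chain_len(S)), ctx)
  win <- chain_slice(S, core)
  pw <- p - min(core) + 1      # slot position within the window
  left <- chain_slice(win, seq_len(pw))
  right <- chain_slice(win, seq(pw + 1, chain_len(win)))
  new_win <- chain_concat(chain_concat(left, F, ctx$g_o), right, ctx$g_o)
  delta <- score_chain(new_win, ctx) -
    score_chain(win, ctx) - score_chain(F, ctx)
  full_left <- chain_slice(S, seq_len(p))
  full_right <- chain_slice(S, seq(p + 1, chain_len(S)))
  newS <- chain_concat(chain_concat(full_left, F, ctx$g_o), full_right,
                       ctx$g_o)
  list(delta = delta, chain = newS)
}

# delta of reversing block lo..hi of chain S
eval_invert <- function(S, lo, hi, ctx) {
  core <- window_around(S, lo, hi, ctx)
  win <- chain_slice(S, core)
  lo_w <- lo - min(core) + 1
  hi_w <- hi - min(core) + 1
  new_win <- chain_reverse_block(win, lo_w, hi_w)
  delta <- score_chain(new_win, ctx) - score_chain(win, ctx)
  list(delta = delta, chain = chain_reverse_block(S, lo, hi))
}

# Process candidate end-pair joins in decreasing score order, evaluating the
# move each implies against the live pool and accepting positive-delta moves.
# conflict = "none": always evaluate against the current pool (sequential,
# used within components). conflict = "round": skip candidates touching a
# scaffold already modified in this round (used by iterative joining).
run_moves <- function(pool, cand, ctx, allow_same_scaffold = TRUE,
                      conflict = c("none", "round")) {
  conflict <- match.arg(conflict)
  cand <- cand[order(-cand$score, cand$contig1, cand$end1,
                     cand$contig2, cand$end2), , drop = FALSE]
  touched <- character(0)
  log <- list()
  for (r in seq_len(nrow(cand))) {
    c1 <- cand$contig1[r]; e1 <- cand$end1[r]
    c2 <- cand$contig2[r]; e2 <- cand$end2[r]
    s1 <- unname(pool$loc[c1]); s2 <- unname(pool$loc[c2])
    if (is.na(s1) || is.na(s2)) next   # contig outside this pool
    if (conflict == "round" && (s1 %in% touched || s2 %in% touched)) next
    ch1 <- pool$chains[[s1]]; ch2 <- pool$chains[[s2]]
    res <- NULL
    kind <- NA_character_
    if (s1 != s2) {
      i1 <- match(c1, ch1$contig); i2 <- match(c2, ch2$contig)
      side1 <- end_side(ch1$orientation[i1], e1)
      side2 <- end_side(ch2$orientation[i2], e2)
      free1 <- (side1 == "left" && i1 == 1) ||
        (side1 == "right" && i1 == chain_len(ch1))
      free2 <- (side2 == "left" && i2 == 1) ||
        (side2 == "right" && i2 == chain_len(ch2))
      if (free1 && free2) {
        kind <- "join"
        A <- orient_for_join(ch1, c1, e1, "right")
        B <- orient_for_join(ch2, c2, e2, "left")
        res <- eval_join(A, B, ctx)
      } else if (xor(free1, free2)) {
        kind <- "insert"
        if (free1) {   # insert scaffold of c1 next to buried end of c2
          host <- ch2; hc <- c2; hi_ <- i2
          hside <- side2
          Fch <- orient_for_join(ch1, c1, e1,
                                 if (hside == "right") "left" else "right")
        } else {
          host <- ch1; hc <- c1; hi_ <- i1
          hside <- side1
          Fch <- orient_for_join(ch2, c2, e2,
                                 if (hside == "right") "left" else "right")
        }
        p <- if (hside == "right") hi_ else hi_ - 1
        if (p >= 1 && p < chain_len(host)) {
          res <- eval_insert(host, Fch, p, ctx)
        } else {       # buried label stale at a terminus: treat as join
          kind <- "join"
          if (p < 1) {
            res <- eval_join(Fch, host, ctx)
          } else {
            res <- eval_join(host, Fch, ctx)
          }
        }
      } else {
        kind <- "join4"  # both buried: best of four end-to-end joinings
        best <- NULL
        for (ra in c(FALSE, TRUE)) {
          for (rb in c(FALSE, TRUE)) {
            A <- if (ra) chain_reverse(ch1) else ch1
            B <- if (rb) chain_reverse(ch2) else ch2
            cur <- eval_join(A, B, ctx)
            if (is.null(best) || cur$delta > best$delta) best <- cur
          }
        }
        res <- best
      }
      if (!is.null(res) && res$delta > 1e-9) {
        sid <- pool_new_id(pool)
        pool_replace(pool, c(s1, s2), setNames(list(res$chain), sid))
        touched <- c(touched, s1, s2, sid)
        log[[length(log) + 1]] <- tibble(
          kind = kind, contig1 = c1, contig2 = c2,
          score = cand$score[r], delta = res$delta, accepted = TRUE)
      } else if (!is.null(res)) {
        log[[length(log) + 1]] <- tibble(
          kind = kind, contig1 = c1, contig2 = c2,
          score = cand$score[r], delta = res$delta, accepted = FALSE)
      }
    } else if (allow_same_scaffold) {
      i1 <- match(c1, ch1$contig); i2 <- match(c2, ch1$contig)
      if (i1 == i2) next
      lo <- min(i1, i2); hi <- max(i1, i2)
      slo <- end_side(ch1$orientation[lo],
                      if (lo == i1) e1 else e2)
      shi <- end_side(ch1$orientation[hi],
                      if (hi == i2) e2 else e1)
      block <- NULL
      if (slo == "right" && shi == "right") {
        block <- c(lo + 1, hi)
      } else if (slo == "left" && shi == "left") {
        block <- c(lo, hi - 1)
      } else if (slo == "right" && shi == "left" && hi > lo + 1) {
        block <- c(lo + 1, hi - 1)
      }
      if (is.null(block) || block[1] > block[2]) next
      kind <- "invert"
      res <- eval_invert(ch1, block[1], block[2], ctx)
      if (res$delta > 1e-9) {
        sid <- pool_new_id(pool)
        pool_replace(pool, s1, setNames(list(res$chain), sid))
        touched <- c(touched, s1, sid)
      }
      log[[length(log) + 1]] <- tibble(
        kind = kind, contig1 = c1, contig2 = c2,
        score = cand$score[r], delta = res$delta,
        accepted = res$delta > 1e-9)
    }
  }
  list(pool = pool,
       log = if (length(log)) bind_rows(log) else
         tibble(kind = character(0), contig1 = character(0),
                contig2 = character(0), score = numeric(0),
                delta = numeric(0), accepted = logical(0)))
}
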