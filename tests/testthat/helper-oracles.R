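# brute-force oracles shared by the scaffolder and acceptance tests

# exhaustive 2^n orientation search over the same objective as orient_path
brute_orient <- function(path, graph, model, k, g_o = 1000) {
  ctx <- chiscaf:::make_ctx(graph$edges, graph$nodes, model, g_o = g_o,
                            horizon = Inf)
  n <- length(path)
  len <- ctx$len[path]
  gap_ij <- function(i, j) {
    sum(len[seq(i + 1, length.out = j - i - 1)]) + (j - i) * g_o
  }
  grid <- expand.grid(rep(list(c("+", "-")), n), stringsAsFactors = FALSE)
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    o <- unlist(grid[r, ])
    v <- 0
    for (j in 2:n) {
      for (i in max(1, j - k):(j - 1)) {
        v <- v + chiscaf:::score_pair(path[i], path[j], o[i], o[j],
                                      gap_ij(i, j), ctx)
      }
    }
    if (v > best) best <- v
  }
  best
}

# exhaustive n! 2^n arrangement search over the refine_local objective
brute_arrange <- function(contigs, graph, model, g_o = 1000, reach = 60000) {
  ctx <- chiscaf:::make_ctx(graph$edges, graph$nodes, model, g_o = g_o,
                            horizon = min(reach, model$max_span))
  n <- length(contigs)
  perms <- chiscaf:::all_permutations(n)
  ors <- expand.grid(rep(list(c("+", "-")), n), stringsAsFactors = FALSE)
  best <- -Inf
  for (p in seq_len(nrow(perms))) {
    for (r in seq_len(nrow(ors))) {
      ch <- chiscaf:::chain_new(contigs[perms[p, ]],
                                unlist(ors[r, ]), rep(g_o, n))
      v <- chiscaf:::score_chain(ch, ctx)
      if (v > best) best <- v
    }
  }
  best
}

layout_score <- function(layout, graph, model, g_o = 1000, reach = 60000) {
  ctx <- chiscaf:::make_ctx(graph$edges, graph$nodes, model, g_o = g_o,
                            horizon = min(reach, model$max_span))
  sum(vapply(unique(layout$scaffold), function(s) {
    sub <- layout[layout$scaffold == s, ]
    sub <- sub[order(sub$idx), ]
    chiscaf:::score_chain(chiscaf:::chain_new(sub$contig, sub$orientation,
                                              rep(g_o, nrow(sub))), ctx)
  }, numeric(1)))
}
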