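#' Per-position break/join support along a contig
#'
#' At each grid position `i` the support score is the log-likelihood ratio of
#' keeping the contig joined at `i` (gap 0, orientation `++` between the two
#' fragments `[0, i)` and `[i, len)`) versus breaking it (the two fragments
#' unlinked). A pair straddles `i` when `x1 < i <= x2`; its implied
#' separation under the joined hypothesis at gap 0 is simply `x2 - x1`, so
#' \deqn{L_i = (N - n_i)\log(1 - P_0(i, len - i)) +
#'       \sum_{straddling} [\log f(x_2 - x_1) - \log(p_n/G)].}
#' Positions with no straddling pairs carry only the (negative)
#' spanning-penalty term; deep valleys flag candidate misjoins.
#'
#' @param length contig length (bp).
#' @param offsets tibble with columns `x1`, `x2`: intra-contig pair offsets
#'   (0-based; rows with `x1 > x2` are swapped internally).
#' @param model a [link_model()].
#' @param stride grid spacing (bp), default 500.
#' @return a tibble with columns `pos`, `n_span`, `llr`. Empty (zero rows,
#'   with attribute `flagged = TRUE`) when the contig is shorter than
#'   `2 * stride`.
#' @export
support_profile <- function(length, offsets, model, stride = 500) {
  assert_that(stride >= 1, "`stride` must be >= 1")
  if (length < 2 * stride) {
    out <- tibble(pos = numeric(0), n_span = integer(0), llr = numeric(0))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  pos <- seq(stride, length - stride, by = stride)
  x1 <- pmin(offsets$x1, offsets$x2)
  x2 <- pmax(offsets$x1, offsets$x2)
  terms <- if (nrow(offsets) > 0) llr_terms(x2 - x1, model) else numeric(0)

  # difference-array accumulation: pair (x1, x2) straddles grid positions in
  # (x1, x2], i.e. indices lo..hi below
  np <- base::length(pos)
  dens <- numeric(np + 1)
  cnt <- numeric(np + 1)
  if (base::length(terms) > 0) {
    lo <- floor(x1 / stride) + 1          # first index with pos > x1
    hi <- pmin(floor(x2 / stride), np)    # last index with pos <= x2
    ok <- lo <= hi & lo <= np
    lo <- lo[ok]; hi <- hi[ok]; tt <- terms[ok]
    for (j in seq_along(lo)) {
      dens[lo[j]] <- dens[lo[j]] + tt[j]
      dens[hi[j] + 1] <- dens[hi[j] + 1] - tt[j]
      cnt[lo[j]] <- cnt[lo[j]] + 1
      cnt[hi[j] + 1] <- cnt[hi[j] + 1] - 1
    }
  }
  dens <- cumsum(dens)[seq_len(np)]
  n_span <- cumsum(cnt)[seq_len(np)]
  p0 <- span_probability(pos, length - pos, 0, model)
  tibble(
    pos = pos,
    n_span = as.integer(n_span),
    llr = (model$N - n_span) * log1p(-p0) + dens
  )
}

#' Repeat-robust support profile
#'
#' A single repeat copy can produce a tight cluster of spurious links that
#' props up the support score across a misjoin. The robust score virtually
#' masks up to `n_mask` bins of size `w_mask` on one side of each candidate
#' breakpoint -- left or right, whichever masking lowers the score more --
#' removing the bins whose straddling pairs contribute the largest positive
#' density terms. Masked pairs are treated as unobserved (they leave both the
#' spanning count and the total pair count), so the score change is exactly
#' the removed density contribution.
#'
#' @inheritParams support_profile
#' @param n_mask maximum number of masked bins (default 3).
#' @param w_mask bin width (bp, default 1000).
#' @return the [support_profile()] tibble with an extra column `robust_llr`.
#' @export
robust_support_profile <- function(length, offsets, model, stride = 500,
                                   n_mask = 3, w_mask = 1000) {
  assert_that(n_mask >= 0, "`n_mask` must be >= 0")
  assert_that(w_mask >= 1, "`w_mask` must be >= 1")
  prof <- support_profile(length, offsets, model, stride)
  if (nrow(prof) == 0) {
    prof$robust_llr <- numeric(0)
    return(prof)
  }
  if (n_mask == 0 || nrow(offsets) == 0) {
    prof$robust_llr <- prof$llr
    return(prof)
  }
  x1 <- pmin(offsets$x1, offsets$x2)
  x2 <- pmax(offsets$x1, offsets$x2)
  terms <- llr_terms(x2 - x1, model)
  np <- nrow(prof)
  # expand (pair, straddled grid index) once, then group: left-side bins are
  # indexed by the distance of x1 below the breakpoint, right-side by x2
  lo <- floor(x1 / stride) + 1
  hi <- pmin(floor(x2 / stride), np)
  ok <- lo <= hi & lo <= np
  lo <- lo[ok]; hi <- hi[ok]
  reps <- hi - lo + 1
  pair_idx <- rep(which(ok), reps)
  pos_idx <- sequence(reps, from = lo, by = 1)
  pos_bp <- prof$pos[pos_idx]
  tvec <- terms[pair_idx]
  top_removal <- function(bin) {
    nb <- max(bin) + 1
    key <- pos_idx * nb + bin
    s <- rowsum(tvec, key, reorder = FALSE)
    kk <- as.numeric(rownames(s))
    pos_of <- as.integer(kk %/% nb)
    val <- s[, 1]
    keep <- val > 0
    pos_of <- pos_of[keep]; val <- val[keep]
    if (length(val) == 0) return(numeric(np))
    ord <- order(pos_of, -val)
    pos_of <- pos_of[ord]; val <- val[ord]
    rank <- stats::ave(val, pos_of, FUN = seq_along)
    sel <- rank <= n_mask
    s2 <- rowsum(val[sel], pos_of[sel], reorder = FALSE)
    out <- numeric(np)
    out[as.integer(rownames(s2))] <- s2[, 1]
    out
  }
  rem_l <- top_removal(floor((pos_bp - 1 - x1[pair_idx]) / w_mask))
  rem_r <- top_removal(floor((x2[pair_idx] - pos_bp) / w_mask))
  prof$robust_llr <- prof$llr - pmax(rem_l, rem_r)
  prof
}
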