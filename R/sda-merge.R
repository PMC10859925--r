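# Segment bookkeeping over a fixed epoch matrix. Prefix sums make segment
# means and adjacent Ward distances O(d) per query.

seg_prefix <- function(x) {
  x <- as.matrix(x)
  rbind(0, apply(x, 2, cumsum))
}

seg_mean <- function(pref, from, to) {
  # [from, to) in 0-based epochs
  (pref[to + 1L, ] - pref[from + 1L, ]) / (to - from)
}

adjacent_ward <- function(pref, boundaries) {
  nb <- length(boundaries)
  if (nb < 3) return(numeric(0))
  vapply(seq_len(nb - 2), function(i) {
    a <- list(n = boundaries[i + 1] - boundaries[i],
              mu = seg_mean(pref, boundaries[i], boundaries[i + 1]))
    b <- list(n = boundaries[i + 2] - boundaries[i + 1],
              mu = seg_mean(pref, boundaries[i + 1], boundaries[i + 2]))
    ward_distance(a, b)
  }, numeric(1))
}

#' Merge segments that are too short
#'
#' Any segment of `min_len` epochs or fewer is merged with whichever of its
#' two temporal neighbours is closer by Ward distance, repeatedly, until
#' every remaining segment is longer than `min_len` (or a single segment
#' remains). The shortest offending segment is processed first; ties break
#' leftmost, and a neighbour tie merges left. `min_len = 0` is a no-op.
#'
#' @param p A [segment_partition()].
#' @param x Epochs x dims feature matrix the partition lives over.
#' @param min_len Minimum state length `L`, in epochs.
#' @return A [segment_partition()].
#' @export
merge_short_segments <- function(p, x, min_len) {
  if (min_len <= 0) return(p)
  pref <- seg_prefix(x)
  b <- p$boundaries
  repeat {
    lens <- diff(b)
    if (length(lens) <= 1) break
    off <- which(lens <= min_len)
    if (length(off) == 0) break
    i <- off[which.min(lens[off])]          # shortest, ties leftmost
    left_d <- if (i > 1) {
      ward_distance(
        list(n = lens[i - 1], mu = seg_mean(pref, b[i - 1], b[i])),
        list(n = lens[i], mu = seg_mean(pref, b[i], b[i + 1]))
      )
    } else Inf
    right_d <- if (i < length(lens)) {
      ward_distance(
        list(n = lens[i], mu = seg_mean(pref, b[i], b[i + 1])),
        list(n = lens[i + 1], mu = seg_mean(pref, b[i + 1], b[i + 2]))
      )
    } else Inf
    drop <- if (left_d <= right_d) i else i + 1L
    b <- b[-(drop)]
  }
  segment_partition(b[-c(1, length(b))], p$n_epochs)
}

#' Merge adjacent segments that are too close
#'
#' While the smallest Ward distance between adjacent segments, `D_min`,
#' satisfies `D_min <= W * D_avg` — where `D_avg` is the mean adjacent-pair
#' Ward distance of the *current* partition — the closest pair is merged
#' and both quantities recomputed. Stops when `D_min > W * D_avg` or one
#' segment remains. Two equal-distance partitions (`D_min = D_avg`) never
#' merge for `W < 1`.
#'
#' @param p A [segment_partition()].
#' @param x Epochs x dims feature matrix.
#' @param w Merge coefficient `W` in (0, 1); default 0.3.
#' @return A [segment_partition()].
#' @export
merge_close_segments <- function(p, x, w = 0.3) {
  if (w <= 0 || w >= 1) abort("w must lie strictly between 0 and 1")
  pref <- seg_prefix(x)
  b <- p$boundaries
  repeat {
    if (length(b) <= 2) break
    dists <- adjacent_ward(pref, b)
    d_min <- min(dists)
    if (d_min > w * mean(dists)) break
    i <- which.min(dists)                   # ties leftmost
    b <- b[-(i + 1L)]
  }
  segment_partition(b[-c(1, length(b))], p$n_epochs)
}
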