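#' Segment partition of an epoch sequence
#'
#' A partition of the retained epoch sequence into time-continuous states,
#' stored as strictly increasing boundary indices that include 0 and
#' `n_epochs`; state `i` covers the half-open range `[b_i, b_{i+1})` in
#' 0-based epoch coordinates.
#'
#' @param boundaries Integer vector of boundaries. 0 and `n_epochs` are
#'   added if absent.
#' @param n_epochs Total number of epochs tiled by the partition.
#' @return An object of class `segment_partition`.
#' @examples
#' segment_partition(c(120), n_epochs = 935)
#' @export
segment_partition <- function(boundaries, n_epochs) {
  b <- sort(unique(as.integer(c(0L, boundaries, n_epochs))))
  if (any(b < 0) || any(b > n_epochs)) {
    abort("boundaries must lie in [0, n_epochs]")
  }
  if (length(b) < 2) abort("partition needs at least one segment")
  structure(list(boundaries = b, n_epochs = as.integer(n_epochs)),
            class = "segment_partition")
}

#' @export
#' @method print segment_partition
print.segment_partition <- function(x, ...) {
  cat(sprintf("<segment_partition> %d states over %d epochs\n",
              n_states(x), x$n_epochs))
  print(tidy(x))
  invisible(x)
}

#' Number of states in a partition
#' @param p A [segment_partition()].
#' @return Integer count of segments.
#' @export
n_states <- function(p) length(p$boundaries) - 1L

#' Per-epoch state labels of a partition
#' @param p A [segment_partition()].
#' @return Integer vector of length `n_epochs`, states numbered from 1.
#' @export
state_labels <- function(p) {
  rep(seq_len(n_states(p)), diff(p$boundaries))
}

interior_boundaries <- function(p) {
  b <- p$boundaries
  b[-c(1L, length(b))]
}

#' Tidy a segment partition into a state table
#'
#' @param x A [segment_partition()].
#' @param epoch_len_s Epoch length in seconds used for the duration column.
#' @param ... Unused.
#' @return A tibble with `state_id`, `start_epoch`, `end_epoch` (half-open)
#'   and `duration_s`.
#' @export
tidy.segment_partition <- function(x, epoch_len_s = 1, ...) {
  b <- x$boundaries
  tibble::tibble(
    state_id = seq_len(n_states(x)),
    start_epoch = b[-length(b)],
    end_epoch = b[-1],
    duration_s = diff(b) * epoch_len_s
  )
}

#' Write / read a segment partition as a delimited table
#'
#' The on-disk format is the tidy state table (`state_id`, `start_epoch`,
#' `end_epoch`, `duration_s`); the round trip reproduces boundary indices
#' exactly.
#'
#' @param partition A [segment_partition()].
#' @param path Output CSV path.
#' @param epoch_len_s Epoch length in seconds (duration column only).
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a [segment_partition()].
#' @export
write_partition <- function(partition, path, epoch_len_s = 1) {
  utils::write.csv(tidy(partition, epoch_len_s = epoch_len_s), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("state_id", "start_epoch", "end_epoch")
  if (!all(need %in% names(tab))) {
    abort("malformed partition file: expected state_id,start_epoch,end_epoch columns")
  }
  tab <- tab[order(tab$start_epoch), ]
  if (any(tab$start_epoch[-1] != tab$end_epoch[-nrow(tab)]) && nrow(tab) > 1) {
    abort("malformed partition file: segments do not tile the epoch range")
  }
  segment_partition(tab$end_epoch[-nrow(tab)], n_epochs = tab$end_epoch[nrow(tab)])
}

#' Maximum boundary deviation between two partitions
#'
#' Greedy one-to-one matching of interior boundaries by position; partitions
#' must have the same number of states.
#'
#' @param p,q Two [segment_partition()] objects over the same epoch range.
#' @return Largest absolute difference between matched interior boundaries,
#'   in epochs.
#' @export
boundary_deviation <- function(p, q) {
  bp <- interior_boundaries(p)
  bq <- interior_boundaries(q)
  if (length(bp) != length(bq)) {
    abort("partitions have different numbers of states")
  }
  if (length(bp) == 0) return(0)
  max(abs(bp - bq))
}
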