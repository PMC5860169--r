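# Half-open integer interval sets on a single sequence, kept as a two-column
# matrix of disjoint, sorted [start, end) rows. Used by the HSP filters, which
# need union widths and the length of the covered run at either end of a
# candidate interval -- queries interval containers do not expose directly.

iv_empty <- function() matrix(numeric(0), ncol = 2L)

# merge a set of raw intervals into canonical disjoint sorted form
iv_merge <- function(ivs) {
  ivs <- ivs[ivs[, 2] > ivs[, 1], , drop = FALSE]
  if (nrow(ivs) <= 1L) return(ivs)
  ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
  out <- matrix(0, nrow(ivs), 2)
  k <- 1L
  out[1, ] <- ivs[1, ]
  for (i in 2:nrow(ivs)) {
    if (ivs[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], ivs[i, 2])
    } else {
      k <- k + 1L
      out[k, ] <- ivs[i, ]
    }
  }
  out[seq_len(k), , drop = FALSE]
}

iv_add <- function(set, start, end) {
  iv_merge(rbind(set, c(start, end)))
}

iv_width <- function(set) {
  if (nrow(set) == 0L) return(0)
  sum(set[, 2] - set[, 1])
}

# total number of positions of [start, end) covered by the set
iv_overlap <- function(set, start, end) {
  if (nrow(set) == 0L || end <= start) return(0)
  lo <- pmax(set[, 1], start)
  hi <- pmin(set[, 2], end)
  sum(pmax(hi - lo, 0))
}

# length of the covered run beginning exactly at `start` (0 if uncovered);
# set rows are maximal, so the run is bounded by one row
iv_left_run <- function(set, start, end) {
  if (nrow(set) == 0L) return(0)
  hit <- set[, 1] <= start & set[, 2] > start
  if (!any(hit)) return(0)
  min(set[hit, 2][1], end) - start
}

# covered run ending exactly at `end`
iv_right_run <- function(set, start, end) {
  if (nrow(set) == 0L) return(0)
  hit <- set[, 1] < end & set[, 2] >= end
  if (!any(hit)) return(0)
  end - max(set[hit, 1][1], start)
}
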