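# Internal helpers shared across modules.

# Indices of strict local maxima of x; a flat plateau that is higher than both
# neighbours contributes its *last* sample. Endpoints never qualify.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope forward across plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  idx <- cumsum(nz)
  filled <- c(0, s[nz])[idx + 1L]          # 0 until the first non-zero slope
  # a maximum ends where a (possibly carried) rise is followed by a fall
  rise_before <- c(0, filled)              # slope arriving at sample i
  fall_after <- c(s, 0)                    # immediate slope leaving sample i
  which(rise_before > 0 & fall_after < 0)
}

local_minima <- function(x) local_maxima(-x)

# Merge sorted, non-overlapping intervals (matrix with columns start, end)
# whose gaps are smaller than `gap`; then drop intervals shorter than `min_len`.
merge_intervals <- function(mat, gap = 0, min_len = 0) {
  if (is.null(mat) || nrow(mat) == 0L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  o <- order(mat[, 1L])
  mat <- mat[o, , drop = FALSE]
  out <- list(mat[1L, ])
  for (i in seq_len(nrow(mat))[-1L]) {
    last <- out[[length(out)]]
    if (mat[i, 1L] - last[2L] < gap) {
      last[2L] <- max(last[2L], mat[i, 2L])
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- mat[i, ]
    }
  }
  res <- do.call(rbind, out)
  res <- res[res[, 2L] - res[, 1L] >= min_len, , drop = FALSE]
  dimnames(res) <- list(NULL, c("start", "end"))
  res
}

# Total overlap (seconds) between one interval and a set of intervals.
interval_overlap <- function(start, end, mat) {
  if (is.null(mat) || nrow(mat) == 0L) return(0)
  sum(pmax(0, pmin(end, mat[, 2L]) - pmax(start, mat[, 1L])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
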