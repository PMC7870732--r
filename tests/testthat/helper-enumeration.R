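# All non-negative integer k-tuples summing to `total`, one per row.
compositions_k <- function(total, k) {
  if (k == 1) return(matrix(total, 1, 1))
  out <- vector("list", total + 1)
  for (first in 0:total) {
    rest <- compositions_k(total - first, k - 1)
    out[[first + 1]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}
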