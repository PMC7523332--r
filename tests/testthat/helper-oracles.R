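# Independent enumeration oracle for the exact two-sided rank-sum p:
# brute force over all C(N, n1) rank assignments via combn.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sums <- combn(N, n1, FUN = function(idx) sum(r[idx]))
  lo <- mean(sums <= w)
  hi <- mean(sums >= w)
  min(1, 2 * min(lo, hi))
}
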