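# Independent brute-force oracles, kept free of package internals.

# Tukey-fence oracle: quartiles by explicit linear interpolation on the
# sorted sample (h = (n-1)p + 1), fences at 1.5 IQR.
oracle_tukey_keep <- function(values) {
  s <- sort(values)
  n <- length(s)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- interp_q(0.25)
  q3 <- interp_q(0.75)
  iqr <- q3 - q1
  values >= q1 - 1.5 * iqr & values <= q3 + 1.5 * iqr
}

# brute-force disc membership by per-pixel centre distance
oracle_disc_values <- function(mat, center, radius) {
  out <- c()
  for (r in seq_len(nrow(mat))) {
    for (cc in seq_len(ncol(mat))) {
      if ((r - center[1])^2 + (cc - center[2])^2 <= radius^2) {
        out <- c(out, mat[r, cc])
      }
    }
  }
  out
}

default_truth <- truth_bundle()
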