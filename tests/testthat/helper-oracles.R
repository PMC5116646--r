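# Independent brute-force oracles for the sinogram-domain operations.
# Deliberately written as naive per-bin loops straight from the blend
# definition, sharing no code with the package implementations.

oracle_replace_trace <- function(pkv, pprior, mask) {
  out <- pkv
  for (v in seq_len(nrow(mask))) {
    b <- 1L
    n <- ncol(mask)
    while (b <= n) {
      if (!mask[v, b]) { b <- b + 1L; next }
      first <- b
      while (b <= n && mask[v, b]) b <- b + 1L
      last <- b - 1L
      jj <- first - 1L; jr <- last + 1L
      for (k in first:last) {
        if (jj >= 1L && jr <= n) {
          delta <- last - first + 1L
          dl <- pkv[v, jj] - pprior[v, jj]
          dr <- pkv[v, jr] - pprior[v, jr]
          off <- ((jr - k) * dl + (k - jj) * dr) / (delta + 1)
        } else if (jj >= 1L) {
          off <- pkv[v, jj] - pprior[v, jj]
        } else if (jr <= n) {
          off <- pkv[v, jr] - pprior[v, jr]
        } else {
          off <- 0
        }
        out[v, k] <- pprior[v, k] + off
      }
    }
  }
  out
}

oracle_limar_interp <- function(pkv, mask) {
  out <- pkv
  for (v in seq_len(nrow(mask))) {
    b <- 1L
    n <- ncol(mask)
    while (b <= n) {
      if (!mask[v, b]) { b <- b + 1L; next }
      first <- b
      while (b <= n && mask[v, b]) b <- b + 1L
      last <- b - 1L
      jj <- first - 1L; jr <- last + 1L
      for (k in first:last) {
        if (jj >= 1L && jr <= n) {
          delta <- last - first + 1L
          out[v, k] <- ((jr - k) * pkv[v, jj] + (k - jj) * pkv[v, jr]) /
            (delta + 1)
        } else if (jj >= 1L) {
          out[v, k] <- pkv[v, jj]
        } else if (jr <= n) {
          out[v, k] <- pkv[v, jr]
        }
      }
    }
  }
  out
}

# Random small sinogram pair + trace mask for oracle comparisons.
random_trace_case <- function(m = 8, n = 12, p_flag = 0.3) {
  pkv <- matrix(rnorm(m * n, 2, 1), m, n)
  pprior <- matrix(rnorm(m * n, 2, 1), m, n)
  mask <- matrix(runif(m * n) < p_flag, m, n)
  list(pkv = pkv, pprior = pprior, mask = mask)
}

make_sino <- function(values, detector_spacing = 1) {
  sinogram(values, seq(0, 180, length.out = nrow(values) + 1)[seq_len(nrow(values))],
           detector_spacing)
}
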