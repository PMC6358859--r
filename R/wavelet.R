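# Periodized orthogonal Daubechies wavelet transform.
#
# The curtaining filter needs a 2D multilevel DWT; the transform here is the
# standard orthonormal construction on a circulant grid: analysis rows are
# even shifts of the scaling filter h and of its conjugate quadrature mirror
# g[k] = (-1)^k h[L-1-k], so the synthesis operator is the transpose.

# Scaling (lowpass decomposition) filter taps, standard Daubechies values.
DAUBECHIES_FILTERS <- list(
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780794, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933,
          -0.00039174037337694705, -0.0048703529934515741,
          0.0087460940474057766, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.00047248457391328279,
          -0.28401554296154691, -0.015829105256349306,
          0.58535468365420673, 0.67563073629728976,
          0.31287159091429995, 0.054415842243104008),
  db15 = c(6.133359913305752e-08, -6.3168823258816645e-07,
           1.8112704079405772e-06, 3.36298718173758e-06,
           -2.8133296266047814e-05, 2.5792699155318936e-05,
           0.00015589648992059973, -0.00035956524436246879,
           -0.00037348235413761698, 0.0019433239803822114,
           -0.00024175649076162427, -0.0064877345603157454,
           0.0051010003604075429, 0.015083918027835902,
           -0.020810050169693083, -0.025767007328439964,
           0.054780550584507613, 0.033877143923507685,
           -0.11112093603723169, -0.039666176555790945,
           0.19014671400712299, 0.065282952848772821,
           -0.28888259656696563, -0.19320413960914543,
           0.33900253545473152, 0.64581314035742432,
           0.4926317717081396, 0.20602386398699574,
           0.046743394892766271, 0.0045385373615788992)
)

wavelet_filters <- function(wavelet) {
  h <- DAUBECHIES_FILTERS[[wavelet]]
  if (is.null(h)) {
    rlang::abort(sprintf(
      "Unknown wavelet '%s'; available: %s.",
      wavelet, paste(names(DAUBECHIES_FILTERS), collapse = ", ")
    ))
  }
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(lo = h, hi = g, length = L)
}

# N x N orthonormal single-level periodized DWT matrix: first N/2 rows are
# even circular shifts of lo, last N/2 of hi. Cached per (N, wavelet).
dwt_matrix_cache <- new.env(parent = emptyenv())

dwt_matrix <- function(n, wavelet) {
  key <- paste0(wavelet, "_", n)
  if (!is.null(dwt_matrix_cache[[key]])) return(dwt_matrix_cache[[key]])
  f <- wavelet_filters(wavelet)
  if (n %% 2 != 0) rlang::abort("DWT length must be even.")
  W <- matrix(0, n, n)
  idx0 <- seq_len(f$length) - 1L
  for (s in seq_len(n / 2) - 1L) {
    cols <- (2L * s + idx0) %% n + 1L
    # circular placement: accumulate in case the filter wraps onto itself
    for (k in seq_along(cols)) {
      W[s + 1L, cols[k]] <- W[s + 1L, cols[k]] + f$lo[k]
      W[n / 2 + s + 1L, cols[k]] <- W[n / 2 + s + 1L, cols[k]] + f$hi[k]
    }
  }
  dwt_matrix_cache[[key]] <- W
  W
}

# Multilevel 2D DWT of matrix x (rows = y, cols = x). Returns list of level
# objects holding the three detail blocks plus the final approximation.
dwt2_forward <- function(x, wavelet, levels) {
  out <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    n <- nrow(cur); m <- ncol(cur)
    if (n %% 2 != 0 || m %% 2 != 0) {
      rlang::abort("Image dimensions must be divisible by 2^levels.")
    }
    Wn <- dwt_matrix(n, wavelet)
    Wm <- dwt_matrix(m, wavelet)
    z <- Wn %*% cur %*% t(Wm)
    out[[l]] <- list(
      # block naming: first index y-band, second x-band (a = approx, d = detail)
      ad = z[seq_len(n / 2), m / 2 + seq_len(m / 2), drop = FALSE],
      da = z[n / 2 + seq_len(n / 2), seq_len(m / 2), drop = FALSE],
      dd = z[n / 2 + seq_len(n / 2), m / 2 + seq_len(m / 2), drop = FALSE]
    )
    cur <- z[seq_len(n / 2), seq_len(m / 2), drop = FALSE]
  }
  list(levels = out, approx = cur, wavelet = wavelet)
}

dwt2_inverse <- function(decomp) {
  cur <- decomp$approx
  for (l in rev(seq_along(decomp$levels))) {
    b <- decomp$levels[[l]]
    n <- 2L * nrow(cur); m <- 2L * ncol(cur)
    z <- rbind(cbind(cur, b$ad), cbind(b$da, b$dd))
    Wn <- dwt_matrix(n, decomp$wavelet)
    Wm <- dwt_matrix(m, decomp$wavelet)
    cur <- t(Wn) %*% z %*% Wm
  }
  cur
}
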