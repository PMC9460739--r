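# Periodized dyadic discrete wavelet transform and band energies.
#
# The band-energy features rest on a 3-level dyadic decomposition of a
# 1-second, 64-sample epoch: detail level 1 spans Beta [16,32] Hz, level 2
# Alpha [8,16] Hz, level 3 Theta [4,8] Hz, and the level-3 approximation
# Delta [0,4] Hz. Periodic (circular) boundary handling keeps coefficient
# counts exact powers of two and makes Parseval's relation exact for an
# orthonormal filter pair.

# Orthonormal Daubechies scaling (low-pass) filters; the quadrature-mirror
# high-pass is derived below. "dbN" has N vanishing moments and 2N taps.
.db_scaling <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157,
          0.6308807679298589, -0.027983769416859854,
          -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db6 = rev(c(-0.0010773010853084796, 0.004777257510945511,
              0.0005538422011614961, -0.03158203931748603,
              0.027522865530305727, 0.09750160558732304,
              -0.12976686756726194, -0.22626469396543983,
              0.31525035170919763, 0.7511339080210954,
              0.49462389039845306, 0.11154074335010947)),
  db8 = rev(c(-0.00011747678412476953, 0.0006754494064505693,
              -0.00039174037337694705, -0.004870352993451574,
              0.008746094047405777, 0.013981027917398282,
              -0.044088253930794755, -0.017369301001807547,
              0.12874742662047847, 0.0004724845739132828,
              -0.2840155429615469, -0.015829105256349306,
              0.5853546836542067, 0.6756307362972898,
              0.31287159091429995, 0.05441584224310401))
)

dwt_filters <- function(wavelet = "db8") {
  if (identical(wavelet, "db1")) wavelet <- "haar"
  h <- .db_scaling[[wavelet]]
  if (is.null(h)) {
    eeg_abort("eegdwt_bad_wavelet",
              sprintf("unknown wavelet '%s'; available: %s", wavelet,
                      paste(names(.db_scaling), collapse = ", ")))
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # QMF high-pass
  list(h = h, g = g)
}

# One analysis step as an (n/2 x n) matrix acting on row-signals:
# a[k] = sum_j f[j] * x[(2(k-1) + j - 1) mod n + 1]
.dwt_step_matrix <- function(n, f) {
  M <- matrix(0, n / 2, n)
  for (j in seq_along(f)) {
    cols <- ((2 * (seq_len(n / 2) - 1) + (j - 1)) %% n) + 1
    M[cbind(seq_len(n / 2), cols)] <- M[cbind(seq_len(n / 2), cols)] + f[j]
  }
  M
}

# Cache of per-(n, wavelet) step matrices: transforming many epochs then
# reduces to a handful of matrix products.
.dwt_cache <- new.env(parent = emptyenv())

.dwt_step_matrices <- function(n, wavelet) {
  key <- paste0(wavelet, "_", n)
  m <- .dwt_cache[[key]]
  if (is.null(m)) {
    f <- dwt_filters(wavelet)
    m <- list(H = .dwt_step_matrix(n, f$h), G = .dwt_step_matrix(n, f$g))
    .dwt_cache[[key]] <- m
  }
  m
}

#' Periodized discrete wavelet transform
#'
#' Decomposes one signal (or the rows of a matrix of signals) with a
#' periodized orthonormal DWT. Circular boundary handling keeps the
#' transform orthonormal, so the summed squared coefficients equal the
#' summed squared samples exactly (Parseval).
#'
#' @param x Numeric vector, or a matrix with one signal per row. Length
#'   (or column count) must be divisible by `2^levels`.
#' @param wavelet Wavelet name: `"haar"` (alias `"db1"`), `"db2"`, `"db4"`,
#'   `"db6"` or `"db8"`.
#' @param levels Number of decomposition levels.
#' @return A list with detail coefficient blocks `d1` ... `d<levels>`
#'   (finest first) and the final approximation `a<levels>`; each element
#'   is a vector (or matrix with one row per input signal).
#' @export
dwt_periodic <- function(x, wavelet = "db8", levels = 3) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  n <- ncol(X)
  if (n %% 2^levels != 0 || n < 2^levels) {
    eeg_abort("eegdwt_bad_length",
              sprintf("signal length %d is not divisible by 2^%d", n, levels))
  }
  out <- vector("list", levels + 1)
  names(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  A <- X
  for (lev in seq_len(levels)) {
    M <- .dwt_step_matrices(ncol(A), wavelet)
    out[[lev]] <- A %*% t(M$G)
    A <- A %*% t(M$H)
  }
  out[[levels + 1]] <- A
  if (vec) out <- lapply(out, drop)
  out
}

#' Dyadic frequency-band map
#'
#' Maps DWT components to EEG bands for a 3-level decomposition at 64 Hz:
#' detail 1 is Beta \[16,32\] Hz, detail 2 Alpha \[8,16\] Hz, detail 3
#' Theta \[4,8\] Hz and the approximation Delta \[0,4\] Hz. The intervals
#' partition \[0, fs/2\]; each detail's upper edge is `fs / 2^level`.
#'
#' @param fs Sampling rate in Hz (64 after down-sampling).
#' @param levels Decomposition depth.
#' @return Data frame with columns `band`, `component`, `f_lo`, `f_hi`.
#' @export
band_map <- function(fs = 64, levels = 3) {
  stopifnot(levels == 3)
  data.frame(
    band = c("delta", "theta", "alpha", "beta"),
    component = c("a3", "d3", "d2", "d1"),
    f_lo = c(0, fs / 16, fs / 8, fs / 4),
    f_hi = c(fs / 16, fs / 8, fs / 4, fs / 2),
    stringsAsFactors = FALSE
  )
}

# Row-wise band energies for a matrix of 64-sample traces; returns an
# (nrow x 4) matrix with columns delta/theta/alpha/beta.
.dwt_band_energy_matrix <- function(X, wavelet = "db8") {
  if (ncol(X) != 64) {
    eeg_abort("eegdwt_bad_length",
              sprintf("expected 64-sample traces (1 s at 64 Hz), got %d", ncol(X)))
  }
  cf <- dwt_periodic(X, wavelet = wavelet, levels = 3)
  E <- cbind(
    delta = rowSums(cf$a3^2),
    theta = rowSums(cf$d3^2),
    alpha = rowSums(cf$d2^2),
    beta  = rowSums(cf$d1^2)
  )
  E
}

#' DWT band energies of a 1-second epoch trace
#'
#' Computes absolute Delta/Theta/Alpha/Beta energies of a 64-sample trace
#' at 64 Hz as the sums of squared periodized-DWT coefficients at the
#' levels given by [band_map()]. With an orthonormal wavelet the four
#' energies sum to the total signal energy `sum(x^2)`.
#'
#' @param x Numeric vector of length 64.
#' @param wavelet Orthonormal wavelet name (default `"db8"`).
#' @return Named numeric vector `c(delta, theta, alpha, beta)`, all `>= 0`.
#' @export
dwt_band_energies <- function(x, wavelet = "db8") {
  if (length(x) != 64) {
    eeg_abort("eegdwt_bad_length",
              sprintf("expected a 64-sample trace, got length %d", length(x)))
  }
  drop(.dwt_band_energy_matrix(matrix(x, nrow = 1), wavelet = wavelet))
}

#' Relative band energies
#'
#' Divides each band energy by the sum over all four bands, giving
#' unit-free spectral fractions that sum to 1.
#'
#' @param energies Named or positional numeric vector of 4 non-negative
#'   band energies (delta, theta, alpha, beta).
#' @return Numeric vector of 4 fractions summing to 1.
#' @export
relative_energy <- function(energies) {
  if (length(energies) != 4 || any(energies < 0)) {
    eeg_abort("eegdwt_bad_energies", "need 4 non-negative band energies")
  }
  tot <- sum(energies)
  if (tot == 0) {
    eeg_abort("eegdwt_degenerate_epoch",
              "zero total energy: degenerate epoch, excluded downstream")
  }
  energies / tot
}

#' Theta/Beta ratio (TBR)
#'
#' The ratio of Theta-band to Beta-band energy, a workload/engagement
#' marker. Identical whether computed from absolute or relative energies,
#' since the normalizing total cancels.
#'
#' @param e_theta Theta-band energy (absolute or relative).
#' @param e_beta Beta-band energy on the same scale; must be positive.
#' @return `e_theta / e_beta`.
#' @export
theta_beta_ratio <- function(e_theta, e_beta) {
  if (any(e_beta == 0)) {
    eeg_abort("eegdwt_zero_beta", "Beta energy is zero; TBR undefined for this epoch")
  }
  e_theta / e_beta
}
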