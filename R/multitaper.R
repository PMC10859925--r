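# Discrete prolate spheroidal sequences and Thomson multitaper estimation.
# Tapers come from the symmetric tridiagonal eigenproblem; concentration
# eigenvalues from the sinc kernel quadratic form. Both are cached per
# (n, nw, k) since every 1-s epoch of a recording shares them.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n Taper length in samples.
#' @param nw Time half-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return List with `tapers` (n x k matrix, unit energy columns) and
#'   `eigenvalues` (spectral concentrations, decreasing).
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k >= n) abort("need more samples than tapers")
  w <- nw / n
  t0 <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  diag_off <- t0[-1] * (n - t0[-1]) / 2
  tm <- matrix(0, n, n)
  tm[cbind(seq_len(n), seq_len(n))] <- diag_main
  tm[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  tm[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  ev <- eigen(tm, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit energy; polarity: symmetric tapers positive mean, antisymmetric
  # positive initial slope (the conventional choice)
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2 == 1) {
      if (sum(v) < 0) v <- -v
    } else {
      if (v[2] - v[1] < 0) v <- -v
    }
    tapers[, j] <- v
  }
  # concentration eigenvalues via the band-limiting (sinc) kernel
  dt <- outer(t0, t0, "-")
  kern <- sin(2 * pi * w * dt) / (pi * dt)
  kern[cbind(seq_len(n), seq_len(n))] <- 2 * w
  lambda <- vapply(seq_len(k), function(j) {
    v <- tapers[, j]
    as.numeric(v %*% kern %*% v)
  }, numeric(1))
  lambda <- pmin(pmax(lambda, 0), 1)
  out <- list(tapers = tapers, eigenvalues = lambda)
  .dpss_cache[[key]] <- out
  out
}

# complex eigenspectra of one epoch: returns array [n_freq, n_channels, k]
# for the one-sided frequency grid freqs = (0:(n/2)) * sfreq / n
epoch_eigenspectra <- function(x, tapers) {
  n <- ncol(x)
  nch <- nrow(x)
  k <- ncol(tapers$tapers)
  nf <- n %/% 2 + 1
  tx <- t(x)                               # samples x channels
  out <- array(complex(real = 0), dim = c(nf, nch, k))
  for (j in seq_len(k)) {
    out[, , j] <- stats::mvfft(tx * tapers$tapers[, j])[seq_len(nf), ,
                                                        drop = FALSE]
  }
  out
}

# Thomson adaptive weighting of eigenspectra for one channel.
# sk: n_freq x k matrix of |X_k(f)|^2; returns the adaptively weighted PSD.
adaptive_psd <- function(sk, lambda, var_x, tol = 1e-8, max_iter = 100) {
  k <- length(lambda)
  if (k < 2) return(sk[, 1])
  s <- rowMeans(sk[, 1:2, drop = FALSE])
  bias <- (1 - lambda) * var_x
  for (it in seq_len(max_iter)) {
    d2 <- outer(s, lambda)^2 /
      (outer(s, lambda) + matrix(bias, nrow(sk), k, byrow = TRUE))^2
    s_new <- rowSums(d2 * sk) / rowSums(d2)
    if (max(abs(s_new - s)) <= tol * max(s_new, 1e-300)) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}
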