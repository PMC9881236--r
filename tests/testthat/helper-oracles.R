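# Brute-force transcriptions of the estimators, kept deliberately naive
# (scalar loops, literal formulas) so they are independent of the
# vectorized implementations they check.

# Normalized channel correlation: literal triple loop.
brute_profile <- function(u) {
  M <- nrow(u); K <- ncol(u)
  r <- complex(M - 1)
  for (m in 1:(M - 1)) {
    acc <- 0i; n <- 0
    for (k in 1:K) for (i in 1:(M - m)) {
      a <- u[i, k]; b <- u[i + m, k]
      if (Mod(a) > 0 && Mod(b) > 0) {
        acc <- acc + a * Conj(b) / (Mod(a) * Mod(b))
        n <- n + 1
      }
    }
    r[m] <- if (n > 0) acc / n else 0i
  }
  r
}

brute_slsc <- function(u, q) {
  r <- brute_profile(u)
  s <- 0
  for (m in 1:q) s <- s + Re(r[m])
  s
}

# Literal arctangent form of the 2-D autocorrelation phase (single pixel).
brute_kasai_phase <- function(U) {
  K <- length(U)
  num <- 0; den <- 0
  for (k in 1:(K - 1)) {
    I0 <- Re(U[k]); Q0 <- Im(U[k])
    I1 <- Re(U[k + 1]); Q1 <- Im(U[k + 1])
    num <- num + (Q1 * I0 - Q0 * I1)
    den <- den + (I1 * I0 + Q1 * Q0)
  }
  atan2(num, den)
}

# Steady-state-initialized IIR filtering by brute force: prepend a long
# run of the series' DC projection so the recursion reaches its steady
# state before the data start, then run a literal direct-form I loop.
brute_projection_filter <- function(b, a, x, n_burn = 1000) {
  c0 <- mean(x)
  xx <- c(rep(c0, n_burn), x)
  n <- length(xx); nb <- length(b); na <- length(a)
  y <- complex(n)
  for (k in 1:n) {
    acc <- 0i
    for (j in 1:nb) if (k - j + 1 >= 1) acc <- acc + b[j] * xx[k - j + 1]
    if (na > 1) for (j in 2:na) if (k - j + 1 >= 1) acc <- acc - a[j] * y[k - j + 1]
    y[k] <- acc
  }
  y[(n_burn + 1):n]
}

# Full adaptive pipeline by brute force: filter each channel, measure
# SLSC, beamsum, estimate phase and velocity, pick the coherence-argmax
# with ties to the lowest filter index.
brute_cacf <- function(data, filters, q, acq) {
  if (length(dim(data)) == 4) {
    d <- dim(data)
    data <- array(data[, , , 1], d[1:3])
  }
  P <- dim(data)[1]; M <- dim(data)[2]; K <- dim(data)[3]
  nf <- length(filters)
  slsc <- matrix(0, P, nf); vel <- matrix(0, P, nf)
  for (f in seq_len(nf)) {
    filt <- filters[[f]]
    for (p in 1:P) {
      u <- matrix(0i, M, K)
      for (i in 1:M) {
        xi <- data[p, i, ]
        u[i, ] <- if (filt$kind == "identity") xi
                  else brute_projection_filter(filt$b, filt$a, xi)
      }
      slsc[p, f] <- brute_slsc(u, q)
      U <- complex(K)
      for (k in 1:K) U[k] <- sum(u[, k])
      phi <- brute_kasai_phase(U)
      vel[p, f] <- -100 * acq$c * acq$prf * phi / (4 * pi * acq$f0)
    }
  }
  sel <- integer(P)
  for (p in 1:P) {
    best <- 1
    for (f in 2:nf) if (slsc[p, f] > slsc[p, best]) best <- f
    sel[p] <- best
  }
  list(selection = sel, slsc = slsc,
       velocity = vel[cbind(1:P, sel)])
}

# Small ensemble with controllable structure for the oracle instances.
random_ensemble <- function(P, M, K, seed, grid = NULL, acq = NULL) {
  set.seed(seed)
  if (is.null(acq))
    acq <- acq_params(3.5e6, 3000, n_channels = M, ensemble = K)
  if (is.null(grid)) grid <- image_grid(P, 1)
  data <- array(complex(real = rnorm(P * M * K),
                        imaginary = rnorm(P * M * K)), c(P, M, K, 1))
  channel_ensemble(data, grid, acq)
}
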