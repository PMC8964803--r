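# Independent reference implementations (straight loops, naive DFT sums)
# used as oracles against the package's operators, plus small fixture
# builders. Everything is generated in code under fixed seeds.

rcmat <- function(nr, nc) {
  matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)), nr, nc)
}

rcstack <- function(S, n) {
  array(complex(real = rnorm(S * S * n), imaginary = rnorm(S * S * n)),
        dim = c(S, S, n))
}

# random valid geometry: object, probe, positions, and a positive data stack
tiny_instance <- function(seed, H = 8, W = 8, S = 4, n = 5) {
  set.seed(seed)
  obj <- rcmat(H, W)
  probe <- rcmat(S, S)
  positions <- cbind(sample(0:(H - S), n, replace = TRUE),
                     sample(0:(W - S), n, replace = TRUE))
  d <- array(runif(S * S * n, 0.1, 2), dim = c(S, S, n))
  list(obj = obj, probe = probe, positions = positions, d = d,
       shape = c(H, W), S = S, n = n)
}

# <a, b> = sum conj(a) b over all elements
cip <- function(a, b) sum(Conj(a) * b)

# explicit double-loop patch extraction and probe multiplication
oracle_apply_Q <- function(obj, probe, positions) {
  S <- nrow(probe); n <- nrow(positions)
  out <- array(complex(1), dim = c(S, S, n))
  for (j in seq_len(n)) {
    r <- positions[j, 1]; c <- positions[j, 2]
    for (a in seq_len(S)) for (b in seq_len(S))
      out[a, b, j] <- probe[a, b] * obj[r + a, c + b]
  }
  out
}

# naive O(S^4) orthonormal 2-D DFT
oracle_dft2 <- function(x) {
  S <- nrow(x)
  out <- matrix(complex(1), S, S)
  for (u in 0:(S - 1)) for (v in 0:(S - 1)) {
    acc <- 0 + 0i
    for (a in 0:(S - 1)) for (b in 0:(S - 1))
      acc <- acc + x[a + 1, b + 1] * exp(-2i * pi * (u * a + v * b) / S)
    out[u + 1, v + 1] <- acc / S
  }
  out
}

# scalar-loop Poisson ML cost
oracle_cost <- function(obj, d, probe, positions, eps = 1e-32) {
  w <- pty_forward(obj, probe, positions)
  acc <- 0
  for (k in seq_along(w)) {
    aw <- Mod(w[k])
    acc <- acc + aw^2
    if (d[k] > 0) acc <- acc - 2 * d[k] * log(max(aw, eps))
  }
  acc
}

# direct sliding-window SSIM with a Gaussian window, interior mean
oracle_ssim <- function(a, b, data_range, radius = 7, sigma = 1.5) {
  k1 <- dnorm(seq(-radius, radius), sd = sigma)
  k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  nr <- nrow(a); nc <- ncol(a)
  vals <- c()
  for (i in (radius + 1):(nr - radius)) for (j in (radius + 1):(nc - radius)) {
    wa <- a[(i - radius):(i + radius), (j - radius):(j + radius)]
    wb <- b[(i - radius):(i + radius), (j - radius):(j + radius)]
    mua <- sum(kern * wa); mub <- sum(kern * wb)
    va <- sum(kern * wa^2) - mua^2; vb <- sum(kern * wb^2) - mub^2
    vab <- sum(kern * wa * wb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * vab + C2)) /
                    ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# small noise-free star dataset shared by solver/partition tests
star_dataset <- function(size = 128, S = 32, step = 8, jitter = 2, seed = 3) {
  obj <- pty_star(size)
  probe <- pty_probe(S, "disk")
  scan <- pty_scan(size, size, S, step = step, jitter = jitter, seed = seed)
  pty_simulate(obj, probe, scan)
}
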