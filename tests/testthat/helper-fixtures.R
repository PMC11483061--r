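## Small in-code fixtures shared across test files.

## A trajectory holding two single-atom molecules at a controlled sequence
## of separations along x (first molecule at the origin).
twoParticleTraj <- function(separations, L = 100) {
  nf <- length(separations)
  coords <- array(0, dim = c(nf, 2L, 3L))
  coords[, 2L, 1L] <- separations
  Trajectory(times = seq_len(nf) - 1, coords = coords, box = L,
             particles = particleTable(c(1L, 2L)), wrapped = TRUE)
}

## Exact multi-exponential correlation curve (no noise).
exactExpCurve <- function(lag, weights, taus) {
  val <- rowSums(vapply(seq_along(weights),
                        function(i) weights[i] * exp(-lag / taus[i]),
                        numeric(length(lag))))
  new("CorrelationCurve", lag = lag, value = val,
      spread = rep(NA_real_, length(lag)), counts = rep(1, length(lag)),
      metadata = list())
}

## Brute-force O(N^2) minimum-image molecular contact check for one frame.
bruteContacts <- function(coords, molecule, heavy, L, cutoff) {
  ids <- sort(unique(molecule))
  out <- NULL
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ai <- which(molecule == ids[i] & heavy)
    aj <- which(molecule == ids[j] & heavy)
    hit <- FALSE
    for (a in ai) for (b in aj) {
      dx <- coords[a, ] - coords[b, ]
      dx <- dx - L * round(dx / L)
      if (sum(dx^2) < cutoff^2) { hit <- TRUE; break }
    }
    out <- rbind(out, c(ids[i], ids[j], hit))
  }
  out
}

## Default telegraph study mixture: survival times 0.1 / 3 / 60 ns with
## per-component on-rates proportional to the off-rates, so every
## component has the same stationary contact probability (ACF amplitudes
## equal the mixture weights) and the stationary plateau stays small.
telegraphMixture <- function() {
  data.frame(weight = c(0.4, 0.3, 0.3), kOff = c(10, 1 / 3, 1 / 60),
             kOn = 0.01 * c(10, 1 / 3, 1 / 60))
}
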