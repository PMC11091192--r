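# Small shared fixtures, all built in code.

# a rigid straight rod along x with unit bonds, as a 1-frame ensemble array
rodFrames <- function(n, nFrames = 1) {
  fr <- array(0, dim = c(n, 3, nFrames))
  fr[, 1, ] <- seq_len(n) - 1
  fr
}

# all beads coincident
pointFrames <- function(n, nFrames = 1) array(0, dim = c(n, 3, nFrames))

# random Gaussian cloud frames, deterministic
cloudFrames <- function(n, nFrames, sd = 2, seed = 1) {
  set.seed(seed)
  array(rnorm(n * 3 * nFrames, 0, sd), dim = c(n, 3, nFrames))
}

# brute-force contact map oracle (plain R triple loop)
bruteContactMap <- function(frames, A) {
  n <- dim(frames)[1]; nf <- dim(frames)[3]
  acc <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    d <- as.matrix(dist(frames[, , f]))
    acc <- acc + (d < A)
  }
  dimnames(acc) <- NULL
  acc / nf
}

# brute-force triplet oracle
bruteTriplet <- function(frames, vp, thr) {
  n <- dim(frames)[1]; nf <- dim(frames)[3]
  acc <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    d <- as.matrix(dist(frames[, , f]))
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (d[vp + 1, j] < thr && d[vp + 1, k] < thr && d[j, k] < thr)
        acc[j, k] <- acc[j, k] + 1
    }
  }
  acc / nf
}

# tiny two-type locus profile used across prismr/epi tests
tinyProfile <- function(n = 120, seed = 3) plantedProfile(
  nBeads = n, nTypes = 2, siteFraction = 0.8, binBp = 500, seed = seed)
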