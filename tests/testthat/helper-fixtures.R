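# Shared fixtures: small noiseless phantoms and an independent ODE oracle
# for the 2CXM residue function.

smallPhantomConfig <- function(gridSize = 48, nSlices = 2, noiseSd = 0,
                               seed = 3, ...) {
  phantomConfig(gridSize = gridSize, nSlices = nSlices, noiseSd = noiseSd,
                seed = seed, ...)
}

# residue function by direct stiff ODE integration (deSolve), independent
# of the closed-form implementation: evolve (Cp, Ce) from the delta-input
# initial condition Cp(0) = (Fp/60)/vp and read off (vp Cp + ve Ce)/(Fp/60)
odeResidue <- function(fp, ps, vp, ve, times) {
  fs <- fp / 60
  pss <- ps / 60
  rhs <- function(t, y, p) {
    list(c((-fs * y[1] + pss * (y[2] - y[1])) / vp,
           pss * (y[1] - y[2]) / ve))
  }
  out <- deSolve::ode(c(fs / vp, 0), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  (vp * out[, 2] + ve * out[, 3]) / fs
}

# random valid 2CXM parameter draw
randomKineticParams <- function() {
  kineticParameters(fp = runif(1, 0.2, 5), ps = runif(1, 0.05, 3),
                    vp = runif(1, 0.02, 0.2), ve = runif(1, 0.05, 0.5))
}

# brute-force per-pixel vote count (loop form, oracle for the combiner)
bruteForceVote <- function(masks, minVotes) {
  dims <- dim(masks[[1]])
  out <- array(FALSE, dims)
  for (i in seq_len(length(masks[[1]]))) {
    votes <- 0
    for (m in masks) if (m[i]) votes <- votes + 1
    out[i] <- votes >= minVotes
  }
  out
}

# exact two-sided Mann-Whitney p by enumeration with pairwise U counting
# (independent of the rank-based implementation)
enumMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  uOf <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  uObs <- uOf(a, b)
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= uObs + 1e-9), mean(us >= uObs - 1e-9)))
}
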