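## Shared fixtures, memoised so expensive simulations are built once per
## test run (test files run in one session).

.fx <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

default_truth <- function() fixture("truth1", sim_truth(seed = 1))

## small two-block contact matrix: within-block 8, cross-block 2
two_block_matrix <- function(nb = 10, within = 8, cross = 2, res = 1e4) {
  n <- 2 * nb
  m <- matrix(cross, n, n)
  m[1:nb, 1:nb] <- within
  m[(nb + 1):n, (nb + 1):n] <- within
  contact_matrix("chrF", res, m)
}

## smooth power-law decay matrix (its own expectation, scaled)
decay_matrix <- function(n = 60, scale = 100, res = 1e4) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  contact_matrix("chrD", res, scale * (1 + d)^(-1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_len = 1e5) {
  start <- floor(runif(n, 0, max_len - 200))
  width <- ceiling(runif(n, 1, 150))
  intervals(sample(chroms, n, replace = TRUE), start, start + width,
            name = paste0("iv", seq_len(n)),
            score = round(runif(n), 3),
            strand = sample(c("+", "-", "."), n, replace = TRUE))
}

## toy PWM scoring +1 per matching consensus base, -1 otherwise
match_pwm <- function(consensus, name = "toy") {
  bases <- strsplit(consensus, "")[[1]]
  w <- matrix(-1, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(bases)) w[bases[k], k] <- 1
  pwm(w, name = name, threshold = length(bases))
}

## brute-force per-bp overlap oracle for small coordinates
bp_overlap_oracle <- function(a, b) {
  ## returns logical: does interval a overlap any interval in b, per bp mask
  vapply(seq_len(nrow(a)), function(i) {
    cov <- rep(FALSE, max(a$end[i], if (nrow(b)) max(b$end) else 0))
    for (j in seq_len(nrow(b))) {
      if (b$chrom[j] != a$chrom[i]) next
      cov[(b$start[j] + 1):b$end[j]] <- TRUE
    }
    any(cov[(a$start[i] + 1):a$end[i]])
  }, logical(1))
}
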