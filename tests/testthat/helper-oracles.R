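# Independent oracles, deliberately implemented apart from the package
# code paths they check.

# Exact Poisson upper tail by direct pmf summation.
poissonTailOracle <- function(observed, lambda) {
  if (observed == 0) return(1)
  kmax <- max(observed + 200, ceiling(lambda + 50 * sqrt(lambda) + 200))
  sum(stats::dpois(observed:kmax, lambda))
}

# Two-sided Fisher p-value by hypergeometric enumeration (the sum of all
# tables with probability not exceeding the observed one, with the same
# relative tolerance fisher.test documents).
fisherOracle <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact sharing probability by brute-force enumeration over founder
# genotypes and every transmission choice; tractable for tiny pedigrees.
bruteForceSharing <- function(ped, q, eventFn) {
  m <- members(ped)
  ord <- topoOrder(ped)
  p <- 1 - q
  hw <- c(p^2, 2 * p * q, q^2)
  geno <- list() # id -> copies, grown along the recursion
  total <- 0
  recurse <- function(i, prob) {
    if (prob == 0) return()
    if (i > length(ord)) {
      if (eventFn(geno)) total <<- total + prob
      return()
    }
    id <- ord[i]
    row <- m[m$id == id, ]
    if (is.na(row$fatherId)) {
      for (g in 0:2) {
        geno[[id]] <<- g
        recurse(i + 1, prob * hw[g + 1])
      }
    } else {
      gf <- geno[[row$fatherId]]
      gm <- geno[[row$motherId]]
      for (af in 0:1) for (am in 0:1) {
        pf <- if (af == 1) gf / 2 else 1 - gf / 2
        pm <- if (am == 1) gm / 2 else 1 - gm / 2
        geno[[id]] <<- af + am
        recurse(i + 1, prob * pf * pm)
      }
    }
  }
  recurse(1, 1)
  total
}

# Deterministic base seed for every stochastic test in the suite.
TEST_SEED <- 20260924
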