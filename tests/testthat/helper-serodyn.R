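# Shared fixtures for the test suite (built in code, no stored data).

# the all-reference female individual (every C_genotype = 2)
refRecord <- function(sex = "female") referenceGenotype(sex = sex)

# a deliberately mixed genotype used across tests
mixedRecord <- function() {
  genotypeRecord("MX1", "female", "unaffected",
                 list(rs11178998 = c("A", "G"), rs4290270 = c("T", "A"),
                      rs7305115 = c("G", "A"), HTTLPR = c("L", "S"),
                      uVNTR = c("4R", "3R")))
}

# random non-negative states spanning several orders of magnitude
randomStates <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- stats::runif(8, 0, 1) * 10^sample(-3:2, 8, replace = TRUE)
    names(s) <- speciesNames()
    s
  })
}

# random Vmax triples representative of the calibrated range
randomVmaxes <- function(n, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vmaxSet(tph2 = stats::runif(1, 800, 3200),
            sert = stats::runif(1, 50, 250),
            maoa = stats::runif(1, 20, 140))
  })
}

# independent brute-force two-sided Mann-Whitney p-value by enumeration of
# all group labelings (oracle for small samples)
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ustat <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- ustat(x, y)
  combs <- utils::combn(seq_along(pooled), n1)
  us <- apply(combs, 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# independent transcription of the Kruskal-Wallis H with tie correction
handKruskalH <- function(samples) {
  g <- rep(seq_along(samples), lengths(samples))
  r <- rank(unlist(samples))
  n <- length(r)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  tie_tab <- table(r)
  h / (1 - sum(tie_tab^3 - tie_tab) / (n^3 - n))
}

# independent transcription of Dunn's pairwise z (published rank formula)
handDunnZ <- function(samples, i, j) {
  g <- rep(seq_along(samples), lengths(samples))
  r <- rank(unlist(samples))
  n <- length(r)
  tie_tab <- table(r)
  sigma2 <- (n * (n + 1) / 12 - sum(tie_tab^3 - tie_tab) /
               (12 * (n - 1))) *
    (1 / length(samples[[i]]) + 1 / length(samples[[j]]))
  (mean(r[g == i]) - mean(r[g == j])) / sqrt(sigma2)
}
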