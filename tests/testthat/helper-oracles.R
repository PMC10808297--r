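# Independent brute-force reference implementations used as oracles.
# Deliberately naive (explicit loops, no shared code with the package).

bruteChao1 <- function(v) {
  sobs <- 0; n1 <- 0; n2 <- 0
  for (x in v) {
    if (x > 0) sobs <- sobs + 1
    if (x == 1) n1 <- n1 + 1
    if (x == 2) n2 <- n2 + 1
  }
  sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

bruteShannon <- function(v) {
  N <- sum(v)
  h <- 0
  for (x in v) if (x > 0) h <- h - (x / N) * log(x / N)
  h
}

# Spearman rho as explicit covariance of mid-ranks
bruteSpearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sxy <- sxx <- syy <- 0
  for (i in seq_along(rx)) {
    sxy <- sxy + (rx[i] - mx) * (ry[i] - my)
    sxx <- sxx + (rx[i] - mx)^2
    syy <- syy + (ry[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

bruteSpearmanPT <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Retained edge set (as sorted "a|b" keys) by exhaustive pair loop
bruteEdgeSet <- function(m, rThr, pThr) {
  taxa <- rownames(m)
  out <- character(0)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      if (length(unique(m[i, ])) < 2 || length(unique(m[j, ])) < 2) next
      r <- bruteSpearmanRho(m[i, ], m[j, ])
      p <- bruteSpearmanPT(r, ncol(m))
      if (abs(r) > rThr && p < pThr)
        out <- c(out, paste(sort(c(taxa[i], taxa[j])), collapse = "|"))
    }
  }
  sort(out)
}

# Faunal indices by explicit per-taxon accumulation from a long table
# with columns guild, cp, group, abundance
bruteFaunal <- function(tab) {
  e <- b <- s <- ba1 <- fu2 <- 0
  for (i in seq_len(nrow(tab))) {
    g <- tab$guild[i]; a <- tab$abundance[i]
    cp <- tab$cp[i]; letter <- substr(g, 1, 2)
    if (g == "Ba1") { e <- e + 3.2 * a; ba1 <- ba1 + a }
    if (g == "Fu2") { e <- e + 0.8 * a; b <- b + 0.8 * a; fu2 <- fu2 + a }
    if (g == "Ba2") b <- b + 0.8 * a
    if (letter %in% c("Ba", "Fu", "Om", "Ca") && cp >= 3)
      s <- s + c(`3` = 1.8, `4` = 3.2, `5` = 5.0)[[as.character(cp)]] * a
  }
  EI <- if (e + b > 0) 100 * e / (e + b) else NA_real_
  SI <- if (s + b > 0) 100 * s / (s + b) else NA_real_
  BI <- if (e + s + b > 0) 100 * b / (e + s + b) else NA_real_
  CI <- if (3.2 * ba1 + 0.8 * fu2 > 0)
    100 * 0.8 * fu2 / (3.2 * ba1 + 0.8 * fu2) else NA_real_
  free <- tab$group != "PP"
  MI <- if (sum(tab$abundance[free]) > 0)
    sum(tab$cp[free] * tab$abundance[free]) / sum(tab$abundance[free]) else NA_real_
  PPI <- if (sum(tab$abundance[!free]) > 0)
    sum(tab$cp[!free] * tab$abundance[!free]) / sum(tab$abundance[!free]) else NA_real_
  gtot <- tapply(tab$abundance, factor(tab$group, c("BF", "FF", "PP", "OP")),
                 sum, default = 0)
  TD <- if (sum(gtot) > 0) 1 / sum((gtot / sum(gtot))^2) else NA_real_
  c(EI = EI, SI = SI, BI = BI, CI = CI, TD = TD, MI = MI, PPI = PPI)
}

bruteFootprint <- function(N, W, m) N * (0.1 * (W / m) + 0.273 * W^0.75)

# Polygon area by the shoelace formula
shoelace <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}
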