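# Independent oracles, deliberately written without reference to the package
# internals they check.

# box counting by explicit double loop over the box grid
brute_box_count <- function(mask, eps) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0L
  for (bi in seq_len(ceiling(nr / eps))) {
    for (bj in seq_len(ceiling(nc / eps))) {
      rows <- ((bi - 1) * eps + 1):min(bi * eps, nr)
      cols <- ((bj - 1) * eps + 1):min(bj * eps, nc)
      if (any(mask[rows, cols])) n <- n + 1L
    }
  }
  n
}

# pooled two-sample t from the textbook formula
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# one-way ANOVA from explicit sums of squares
anova_oracle <- function(groups) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Pearson r and its t-transform p from first principles
cor_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# two-sided Fisher exact p by hypergeometric enumeration (point-prob rule)
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p0 <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# AUC as the fraction of concordant (control > case) pairs, ties count half;
# orientation: lower values in the case group indicate disease
auc_oracle <- function(controls, cases) {
  s <- 0
  for (u in controls) for (v in cases) s <- s + (u > v) + 0.5 * (u == v)
  s / (length(controls) * length(cases))
}
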