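# Independent oracles used across the suite. These are deliberately plain
# transcriptions of the definitions, kept separate from the package's
# vectorised implementations.

# Biweight midcorrelation, straight from the weight formula.
oracle_bicor <- function(x, y) {
  transform <- function(v) {
    m <- median(v)
    d <- median(abs(v - m))
    if (d == 0) return(v - mean(v))     # same fallback rule as production
    u <- (v - m) / (9 * d)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - m) * w
  }
  zx <- transform(x)
  zy <- transform(y)
  list(r = sum(zx * zy) / sqrt(sum(zx^2) * sum(zy^2)), zx = zx, zy = zy)
}

# Two-sided permutation p-value for bicor. The biweight transform of each
# vector depends only on that vector, so permuting y permutes its
# transformed values; the null is generated by matrix algebra over B
# sampled permutations.
oracle_perm_pvalue <- function(x, y, B = 1e5) {
  o <- oracle_bicor(x, y)
  n <- length(x)
  perms <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  rb <- colSums(o$zx * matrix(o$zy[perms], n, B)) /
    sqrt(sum(o$zx^2) * sum(o$zy^2))
  p <- (1 + sum(abs(rb) >= abs(o$r) - 1e-12)) / (B + 1)
  list(p = p, r = o$r)
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) foreground draws from a background with K marked genes.
oracle_hypergeom_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # mark genes 1..K
  mean(hits >= k)
}

# Trimmed median by explicit sort-and-trim enumeration.
oracle_trimmed_median <- function(x, trim = 0.1) {
  k <- floor(trim * length(x))
  s <- sort(x)
  kept <- s[seq(k + 1, length(x) - k)]
  median(kept)
}

# Small design + expression pair used by several tests.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  design <- sim_design(cfg)
  c(sim_expression(design, cfg), list(design = design, config = cfg))
}

# Sample selector against a design table.
pick <- function(meta, organ, group, sex) {
  meta$sample_id[meta$organ == organ & meta$group == group & meta$sex == sex]
}

# Tiny on-disk fixtures.
write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
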