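# Shared fixtures: tiny in-code datasets used across test files.

# A deterministic staged dataset: `n_genes` x sum(ns) standard-normal
# values with generic stage labels.
tiny_dataset <- function(n_genes = 6, ns = c(4, 4, 4), seed = 1) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(sum(ns)))
  values <- matrix(rnorm(n_genes * sum(ns)), n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   samples))
  stages <- c("stage1", "stage2", "stage3")[seq_along(ns)]
  expression_dataset(values, setNames(rep(stages, ns), samples), stages)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent Benjamini-Hochberg step-up oracle: textbook loop, written
# against the definition rather than any library routine.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# Triple-loop topological overlap oracle.
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- colSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}
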