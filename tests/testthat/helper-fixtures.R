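# Shared fixtures, built in code at test time.

# tiny labeled base: two well-separated classes in 2-D
tiny_base <- function() {
  feature_matrix(
    rbind(c(0, 0), c(2, 0), c(4, 4)),
    sample_ids = c("a1", "a2", "b1"),
    labels = c("A", "A", "B")
  )
}

# unvectorized scalar reference for the full indicator: one sample at a
# time, one class at a time, straight from the formulas
scalar_reference_scores <- function(pool, protos, temperature = 1) {
  C <- length(protos$class_labels)
  out <- matrix(0, nrow(pool$features), 1 + 2 * C)
  for (i in seq_len(nrow(pool$features))) {
    x <- pool$features[i, ]
    d <- numeric(C)
    for (c in seq_len(C)) {
      s <- 0
      for (j in seq_along(x)) s <- s + (x[j] - protos$prototypes[c, j])^2
      d[c] <- sqrt(s)
    }
    num <- exp(-(d - min(d)) / temperature)
    p <- num / sum(num)
    e <- 0
    for (c in seq_len(C)) if (p[c] > 0) e <- e - p[c] * log2(p[c])
    out[i, ] <- c(e, d, p)
  }
  colnames(out) <- c("entropy", paste0("d_", protos$class_labels),
                     paste0("p_", protos$class_labels))
  out
}

# random prototype set and pool in d dimensions
random_protos <- function(C, d, seed) {
  set.seed(seed)
  base <- feature_matrix(
    matrix(rnorm(2 * C * d), 2 * C, d),
    labels = rep(sprintf("c%02d", seq_len(C)), each = 2)
  )
  compute_prototypes(base)
}

random_pool <- function(n, d, seed) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(n * d), n, d))
}
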