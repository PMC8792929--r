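test_that("prototypes are per-class coordinate-wise means in label order", {
  p <- compute_prototypes(tiny_base())
  expect_equal(p$class_labels, c("A", "B"))
  expect_equal(unname(p$prototypes["A", ]), c(1, 0))
  expect_equal(unname(p$prototypes["B", ]), c(4, 4))

  # three-point class, mean by hand: (1+3+5)/3 = 3, (2+4+0)/3 = 2
  base <- feature_matrix(rbind(c(1, 2), c(3, 4), c(5, 0), c(9, 9)),
                         labels = c("A", "A", "A", "B"))
  p2 <- compute_prototypes(base)
  expect_equal(unname(p2$prototypes["A", ]), c(3, 2))

  # single sample per class: prototype equals the sample
  one <- feature_matrix(rbind(c(1, 7), c(-2, 3)), labels = c("x", "y"))
  expect_equal(unname(compute_prototypes(one)$prototypes),
               rbind(c(1, 7), c(-2, 3)))
})

test_that("prototype computation rejects degenerate input", {
  single <- feature_matrix(rbind(c(0, 0), c(1, 1)), labels = c("A", "A"))
  expect_error(compute_prototypes(single), "at least 2")
  part <- feature_matrix(rbind(c(0, 0), c(1, 1)),
                         labels = c("A", UNLABELED))
  expect_error(compute_prototypes(part), "UNLABELED")
})

test_that("distances to prototypes are Euclidean, in class order", {
  base <- feature_matrix(rbind(c(3, 4), c(0, 0)), labels = c("A", "B"))
  p <- compute_prototypes(base)
  d <- distances_to_prototypes(c(0, 0), p)
  expect_equal(unname(d), c(5, 0)) # 3-4-5 triangle; self-distance zero
  expect_equal(names(d), c("A", "B"))

  base2 <- feature_matrix(rbind(c(0, 0), c(2, 2)), labels = c("A", "B"))
  d2 <- distances_to_prototypes(c(1, 1), compute_prototypes(base2))
  expect_equal(unname(d2), c(sqrt(2), sqrt(2)))

  expect_error(distances_to_prototypes(c(1, 2, 3), p), "dimension mismatch")
})

test_that("proportional distribution is the softmax of negated distances", {
  # independently evaluated: exp(-d) / sum(exp(-d)) for d = (1,2,3)
  expect_equal(round(proportional_distribution(c(1, 2, 3)), 5),
               c(0.66524, 0.24473, 0.09003))
  # equal distances: uniform, any C, any common value
  for (C in c(2, 4, 6)) {
    expect_equal(proportional_distribution(rep(17.3, C)), rep(1 / C, C))
  }
  # smaller distance gets strictly larger share
  p <- proportional_distribution(c(0.5, 1.2, 3))
  expect_true(all(diff(p) < 0))
  expect_error(proportional_distribution(c(1, 2), temperature = 0),
               "positive")
  expect_error(proportional_distribution(c(1, Inf)), "finite")
})

test_that("temperature flattens the distribution", {
  d <- c(1, 2, 5)
  cold <- proportional_distribution(d, temperature = 0.5)
  warm <- proportional_distribution(d, temperature = 10)
  expect_true(max(warm) < max(cold))
  expect_true(distance_entropy(warm) > distance_entropy(cold))
})

test_that("distance-entropy has the closed-form extremes", {
  expect_equal(distance_entropy(rep(1 / 6, 6)), log2(6), tolerance = 1e-12)
  expect_equal(distance_entropy(rep(1 / 2, 2)), 1, tolerance = 1e-12)
  expect_equal(distance_entropy(c(1, 0, 0)), 0) # 0 log 0 := 0
  # frozen composition of both formulas for dists = (0,10,10,10,10,10):
  # p1 = 1/(1+5e^-10), entropy computed by scalar arithmetic
  p <- proportional_distribution(c(0, 10, 10, 10, 10, 10))
  expect_equal(distance_entropy(p), 0.003601623544, tolerance = 1e-9)
  expect_error(distance_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("score_pool matches the unvectorized scalar reference", {
  protos <- random_protos(C = 6, d = 64, seed = 42)
  pool <- random_pool(200, 64, seed = 43)
  st <- score_pool(pool, protos)
  ref <- scalar_reference_scores(pool, protos)
  for (col in colnames(ref)) {
    expect_lt(max(abs(st[[col]] - ref[, col])), 1e-9)
  }
  # also at a non-default temperature
  st2 <- score_pool(pool, protos, temperature = 2.5)
  ref2 <- scalar_reference_scores(pool, protos, temperature = 2.5)
  expect_lt(max(abs(st2$entropy - ref2[, "entropy"])), 1e-9)
})

test_that("score_pool keeps row order and handles edge geometry", {
  base <- feature_matrix(rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10),
                               c(-10, 0), c(0, -10)),
                         labels = sprintf("c%d", 1:6))
  protos <- compute_prototypes(base)
  pts <- feature_matrix(rbind(c(5, 5), c(0, 0.01)),
                        sample_ids = c("p1", "p2"))
  st <- score_pool(pts, protos)
  expect_equal(st$sample_id, c("p1", "p2"))
  # a sample at a prototype scores far lower than one between clusters
  expect_gt(st$entropy[1], st$entropy[2])
  expect_error(score_pool(random_pool(3, 5, 1), protos),
               "dimension mismatch")
})

test_that("selection picks extremes with lexicographic tie-break", {
  protos <- random_protos(C = 3, d = 2, seed = 1)
  pool <- random_pool(3, 2, seed = 2)
  st <- score_pool(pool, protos)
  st$entropy <- c(0.1, 2.5, 1.0)
  st$sample_id <- c("a", "b", "c")
  expect_equal(select_samples(st, 1, "high")$selected_ids, "b")
  expect_equal(select_samples(st, 1, "low")$selected_ids, "a")
  st$entropy <- c(1.0, 1.0, 0.5)
  expect_equal(select_samples(st, 1, "high")$selected_ids, "a")
  expect_warning(sel <- select_samples(st, 10, "high"), "only 3")
  expect_equal(sort(sel$selected_ids), c("a", "b", "c"))
})

test_that("per-class balanced selection takes k from each class", {
  protos <- random_protos(C = 2, d = 2, seed = 5)
  pool <- random_pool(8, 2, seed = 6)
  st <- score_pool(pool, protos)
  labs <- rep(c("A", "B"), each = 4)
  sel <- select_samples(st, 2, "high", per_class_balanced = TRUE,
                        labels = labs)
  expect_length(sel$selected_ids, 4)
  picked_classes <- labs[match(sel$selected_ids, st$sample_id)]
  expect_equal(unname(table(picked_classes)), c(2L, 2L), ignore_attr = TRUE)
  expect_error(select_samples(st, 2, "high", per_class_balanced = TRUE),
               "labels")
})
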