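test_that("find_k_nearest_minority matches a brute-force oracle", {
  # 1-D minority values {2, 3, 9}: nearest neighbour of centroid 2 is 3
  ds <- enus_dataset(paste0("r", 1:5),
                     data.frame(v = c(5, 6, 2, 3, 9)),
                     c("B", "B", "M", "M", "M"), positive_class = "M")
  nn <- find_k_nearest_minority(ds, 3, k = 1)
  expect_equal(as.integer(nn), 4L)

  # k >= m - 1 returns all other minority records, ordered by distance
  nn_all <- find_k_nearest_minority(ds, 3, k = 10)
  expect_equal(as.integer(nn_all), c(4L, 5L))
  # instrumented scan cost is d * (m - 1)
  expect_equal(attr(nn_all, "feature_diff_ops"), 1 * 2)

  # equal-distance duplicates resolve by record order
  tie <- enus_dataset(paste0("t", 1:4),
                      data.frame(v = c(4, 4, 2, 4)),
                      c("B", "M", "M", "M"), positive_class = "M")
  expect_equal(as.integer(find_k_nearest_minority(tie, 3, k = 2)),
               oracle_knn(tie, 3, 2))

  # property: equality with the oracle on 100 random small instances
  withr::with_seed(99, {
    for (i in 1:100) {
      m <- sample(2:12, 1)
      d <- random_imbalanced(m, sample(1:6, 1), d = sample(1:4, 1),
                             seed = 1000 + i)
      cen <- sample(which(d$y == "M"), 1)
      k <- sample(1:6, 1)
      expect_equal(as.integer(find_k_nearest_minority(d, cen, k)),
                   oracle_knn(d, cen, k))
    }
  })

  expect_error(find_k_nearest_minority(ds, 1, k = 1), "minority")
  one <- enus_dataset(c("a", "b"), data.frame(v = c(1, 2)), c("B", "M"),
                      positive_class = "M")
  expect_error(find_k_nearest_minority(one, 2, k = 1), "fewer than 2")
})

test_that("synthesize_record interpolates each feature with its own uniform weight", {
  cen <- c(a = 2, b = 5)
  nb <- c(a = 6, b = 5)
  set.seed(1)
  out <- synthesize_record(cen, nb)
  # value_f = centroid_f + u_f * (neighbor_f - centroid_f), exactly
  expect_equal(out$values[["a"]], 2 + out$trace$u[1] * 4)
  expect_equal(out$values[["b"]], 5)  # zero difference: copies centroid
  expect_true(out$values[["a"]] >= 2 && out$values[["a"]] < 6)

  # identical parents give an exact copy regardless of the draws
  same <- synthesize_record(cen, cen)
  expect_equal(same$values, cen)

  expect_error(synthesize_record(c(a = 1), c(b = 1)), "schema")
})

test_that("enus_balance reproduces the worked toy example and its invariants", {
  toy <- toy_train()  # 2 minority, 5 majority
  bal <- enus_balance(toy, sampler_config(k = 5, seed = 42), trace = TRUE)
  expect_equal(n_records(bal), 10)
  expect_equal(unname(class_counts(bal)), c(5, 5))
  # three synthetic records appended, originals untouched
  expect_equal(sum(grepl("^synthetic-", bal$ids)), 3)
  expect_equal(bal$x[1:7, ], toy$x)
  expect_identical(bal$y[1:7], toy$y)

  # envelope: every synthetic feature value lies between its parents
  tr <- attr(bal, "synthesis_trace")
  xm <- feature_matrix(toy)
  for (t in tr) {
    ci <- match(t$centroid_id, toy$ids)
    ni <- match(t$neighbor_id, toy$ids)
    expect_true(all(t$values >= pmin(xm[ci, ], xm[ni, ]) &
                      t$values <= pmax(xm[ci, ], xm[ni, ])))
  }

  # operation count: d * (m - 1) feature differences per synthesis
  ops <- attr(bal, "op_counts")
  expect_equal(ops$feature_diff_ops, 3 * 2 * (2 - 1))
  expect_equal(ops$feature_diff_ops, ops$expected)

  # already balanced input is returned unchanged
  eq <- random_imbalanced(6, 6, seed = 2)
  expect_identical(enus_balance(eq, sampler_config(seed = 1)), eq)

  # determinism: same (train, config, seed) is byte-identical
  b2 <- enus_balance(toy, sampler_config(k = 5, seed = 42), trace = TRUE)
  expect_identical(bal, b2)

  # single-class input errors
  onecl <- dataset_subset(toy, toy$y == "B")
  expect_error(enus_balance(onecl, sampler_config(seed = 1)), "both classes")
})

test_that("lone-minority fallback duplicates and strict-nearest policy works", {
  lone <- enus_dataset(paste0("r", 1:5),
                       data.frame(a = c(1, 2, 3, 4, 7), b = c(2, 3, 1, 5, 7)),
                       c("B", "B", "B", "B", "M"), positive_class = "M")
  bal <- enus_balance(lone, sampler_config(seed = 3))
  expect_equal(unname(class_counts(bal)), c(4, 4))
  syn <- feature_matrix(bal)[bal$y == "M", ][-1, , drop = FALSE]
  for (i in 1:3) expect_equal(unname(syn[i, ]), c(7, 7))
  expect_error(enus_balance(lone, sampler_config(seed = 3, fallback = "error")),
               "single member")

  # strict-nearest always interpolates against the single nearest record
  ds <- enus_dataset(paste0("r", 1:6),
                     data.frame(v = c(9, 9, 9, 1, 2, 8)),
                     c("B", "B", "B", "M", "M", "M"), positive_class = "M")
  bal2 <- enus_balance(ds, sampler_config(k = 2, seed = 7,
                                          neighbor_choice = "strict-nearest"),
                       trace = TRUE)
  for (t in attr(bal2, "synthesis_trace")) {
    ci <- match(t$centroid_id, ds$ids)
    expect_equal(match(t$neighbor_id, ds$ids),
                 oracle_knn(ds, ci, 1)[1])
  }
})

test_that("duplicate_balance balances by resampling existing records", {
  toy <- toy_train()
  bal <- duplicate_balance(toy, seed = 5)
  expect_equal(n_records(bal), 10)
  expect_equal(unname(class_counts(bal)), c(5, 5))
  # every appended record is identical to some original minority record
  xm <- feature_matrix(toy)[toy$y == "M", , drop = FALSE]
  app <- feature_matrix(bal)[8:10, , drop = FALSE]
  for (i in 1:3)
    expect_true(any(apply(xm, 1, function(r) all(r == app[i, ]))))

  expect_identical(duplicate_balance(random_imbalanced(4, 4, seed = 1),
                                     seed = 2),
                   random_imbalanced(4, 4, seed = 1))

  # degenerate equivalence: with an all-identical minority, ENUS output
  # equals duplication record-wise (ids aside)
  ident <- enus_dataset(paste0("r", 1:7),
                        data.frame(a = c(1, 2, 3, 4, 5, 6, 6),
                                   b = c(9, 8, 7, 6, 5, 4, 4)),
                        c("B", "B", "B", "B", "B", "M", "M"),
                        positive_class = "M")
  e <- enus_balance(ident, sampler_config(seed = 11))
  d <- duplicate_balance(ident, seed = 11)
  expect_equal(e$x, d$x)
  expect_identical(e$y, d$y)
})

test_that("balance property holds over random imbalanced fixtures", {
  withr::with_seed(17, {
    for (i in 1:20) {
      ds <- random_imbalanced(sample(2:10, 1), sample(11:30, 1),
                              d = sample(2:5, 1), seed = 200 + i)
      b1 <- enus_balance(ds, sampler_config(seed = i))
      b2 <- duplicate_balance(ds, seed = i)
      expect_equal(sum(b1$y == "M"), sum(b1$y == "B"))
      expect_equal(sum(b2$y == "M"), sum(b2$y == "B"))
    }
  })
})
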