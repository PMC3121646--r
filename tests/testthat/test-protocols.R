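# Cross-validation protocols: bookkeeping, pairing, leakage, and the
# unlabeled-test precision/recall estimator.

fast_specs <- function(cfg = NULL) {
  list(lda = classifier_spec("lda", "lda", seed = 1),
       knn = classifier_spec("knn", "knn", params = list(k = 5), seed = 2))
}

test_that("cv_level0 emits exactly K x n paired records per model", {
  cfg <- small_mixture(seed = 20, per_class = 15)
  d <- generate_mixture(cfg)
  cv <- cv_level0(fast_specs(), d, cv_config(n_folds = 5, K = 3, seed = 7))
  for (m in cv$models) {
    expect_equal(nrow(m$records), 3 * 45)
    expect_equal(nrow(m$probs), 3 * 45)
  }
  # paired design: identical instances and provenance across models
  a <- cv$models[[1]]$records
  b <- cv$models[[2]]$records
  expect_identical(a$instance_id, b$instance_id)
  expect_identical(a$rep_idx, b$rep_idx)
  expect_identical(a$fold, b$fold)
})

test_that("within each repeat the folds partition the instances", {
  cfg <- small_mixture(seed = 21, per_class = 17)
  d <- generate_mixture(cfg)
  cv <- cv_level0(fast_specs()[1], d,
                  cv_config(n_folds = 5, K = 2, seed = 3))
  rec <- cv$models[[1]]$records
  for (k in unique(rec$rep_idx)) {
    ids <- rec$instance_id[rec$rep_idx == k]
    expect_equal(sort(ids), sort(d$instance_ids))  # each exactly once
  }
})

test_that("a single repeat covers each instance exactly once", {
  cfg <- small_mixture(seed = 22, per_class = 10, C = 5)
  d <- generate_mixture(cfg)   # n = 50
  cv <- cv_level0(fast_specs()[1], d, cv_config(K = 1, n_folds = 5,
                                                seed = 1))
  rec <- cv$models[[1]]$records
  expect_equal(nrow(rec), 50)
  expect_equal(sort(rec$instance_id), sort(d$instance_ids))
})

test_that("cv_level0 is reproducible and guards degenerate classes", {
  cfg <- small_mixture(seed = 23)
  d <- generate_mixture(cfg)
  c1 <- cv_level0(fast_specs(), d, cv_config(n_folds = 4, K = 2, seed = 5))
  c2 <- cv_level0(fast_specs(), d, cv_config(n_folds = 4, K = 2, seed = 5))
  expect_identical(c1$models, c2$models)
  tiny <- labeled_dataset(matrix(rnorm(12), 6, 2),
                          c("a", "a", "a", "a", "a", "b"))
  expect_error(cv_level0(fast_specs()[1], tiny, cv_config()),
               "fewer than 2")
})

test_that("a perfectly separated model yields a constant PIN of 1", {
  cfg <- mixture_config(C = 3, sizes = rep(12, 3), d = 4, sigma = 1e-3,
                        separability = 5, seed = 24)
  d <- generate_mixture(cfg)
  cv <- cv_level0(list(classifier_spec("lda", "lda")), d,
                  cv_config(n_folds = 4, K = 1, seed = 2))
  a1 <- estimate_pins_A1(cv)
  expect_true(all(a1$pin_functions$lda$values == 1))
})

test_that("a chance-level model calibrates to its overall precision", {
  cfg <- small_mixture(seed = 25, per_class = 100)
  d <- generate_mixture(cfg)
  spec <- list(noise = classifier_spec("noise", "noise", seed = 1))
  cv <- cv_level0(spec, d, cv_config(n_folds = 5, K = 2, seed = 9))
  a1 <- estimate_pins_A1(cv)
  rec <- a1$records$noise
  overall <- mean(rec$predicted_class == rec$true_class)
  # near-constant: almost all mass close to the overall precision (the
  # few extreme MaxP knots carry single records and fluctuate)
  expect_lt(mean(abs(rec$pin - overall)), 0.05)
  expect_lt(sd(rec$pin), 0.05)
})

test_that("identical models get identical PIN functions", {
  cfg <- small_mixture(seed = 26)
  d <- generate_mixture(cfg)
  specs <- list(m1 = classifier_spec("m1", "lda"),
                m2 = classifier_spec("m2", "lda"))
  cv <- cv_level0(specs, d, cv_config(n_folds = 4, K = 1, seed = 4))
  a1 <- estimate_pins_A1(cv)
  expect_equal(a1$pin_functions$m1$knots, a1$pin_functions$m2$knots)
  expect_equal(a1$pin_functions$m1$values, a1$pin_functions$m2$values)
})

test_that("apply_A2 clamps test PIN to the training range and sizes match", {
  cfg <- small_mixture(seed = 27, per_class = 25)
  both <- generate_mixture(cfg, n_test = 40)
  specs <- fast_specs()
  cv <- cv_level0(specs, both$train, cv_config(n_folds = 5, K = 2,
                                               seed = 6))
  a1 <- estimate_pins_A1(cv, seed = 6)
  a2 <- apply_A2(specs, both$train, both$test$features,
                 a1$pin_functions, seed = 6,
                 test_ids = both$test$instance_ids,
                 true_labels = setNames(both$test$labels,
                                        both$test$instance_ids))
  expect_equal(nrow(a2$combined), nrow(both$test$features))
  for (m in names(specs)) {
    pf <- a1$pin_functions[[m]]
    r <- a2$per_model[[m]]
    expect_true(all(r$pin >= min(pf$values) - 1e-12 &
                      r$pin <= max(pf$values) + 1e-12))
  }
  # single model: the combination is that model
  a2one <- apply_A2(specs[1], both$train, both$test$features,
                    a1$pin_functions[1], seed = 6)
  expect_equal(a2one$combined$predicted_class,
               a2one$per_model[[1]]$predicted_class)
  expect_error(apply_A2(specs, both$train,
                        both$test$features[, 1:2], a1$pin_functions),
               "columns")
})

test_that("double_cv books KK x n records and never leaks the outer fold", {
  cfg <- small_mixture(seed = 28, per_class = 12)
  d <- generate_mixture(cfg)   # n = 36
  dcv <- double_cv(fast_specs(), d,
                   cv_config(n_folds = 3, K = 1, KK = 2, seed = 11))
  expect_equal(nrow(dcv$combined), 2 * 36)
  for (m in dcv$per_model) expect_equal(nrow(m), 2 * 36)
  # within each pass the outer folds partition the data
  for (kk in 1:2) {
    ids <- dcv$combined$instance_id[dcv$combined$pass == kk]
    expect_equal(sort(ids), sort(d$instance_ids))
  }
  # no outer-fold instance contributed to the PIN fit applied to it
  for (entry in dcv$audit)
    expect_length(intersect(entry$outer_ids, entry$inner_ids), 0)
})

test_that("double_cv is reproducible under its seed", {
  cfg <- small_mixture(seed = 29, per_class = 8)
  d <- generate_mixture(cfg)
  args <- list(fast_specs()[1], d,
               cv_config(n_folds = 3, K = 1, KK = 1, seed = 13))
  d1 <- do.call(double_cv, args)
  d2 <- do.call(double_cv, args)
  expect_identical(d1$combined, d2$combined)
})

test_that("double-CV precision of the Bayes oracle matches its accuracy", {
  cfg <- mixture_config(C = 3, sizes = rep(60, 3), d = 4,
                        separability = 1.5, seed = 31)
  d <- generate_mixture(cfg)
  spec <- list(bayes = classifier_spec(
    "bayes", "bayes_oracle", params = list(cfg = cfg)))
  dcv <- double_cv(spec, d, cv_config(n_folds = 3, K = 1, KK = 1,
                                      seed = 15))
  prec <- mean(dcv$combined$predicted_class == dcv$combined$true_class)
  # expected accuracy of the Bayes rule = E[max_k p(k | x)], estimated
  # on a large independent draw
  big <- generate_mixture(mixture_config(C = 3, sizes = rep(4000, 3),
                                         d = 4, separability = 1.5,
                                         seed = 31), seed = 99)
  acc <- mean(apply(bayes_posterior(cfg, big$features), 1, max))
  se <- sqrt(acc * (1 - acc) / nrow(dcv$combined))
  expect_lt(abs(prec - acc), 3 * se + 0.02)
})

test_that("estimate_test_pr multiplies subset sizes by training precision", {
  # pin mode: subset of 100 with P_xv = 0.7 -> 70 estimated correct
  xv <- data.frame(instance_id = paste0("x", 1:10),
                   predicted_class = "a",
                   true_class = rep(c("a", "b"), c(7, 3)),
                   pin = 0.5)
  test <- data.frame(instance_id = paste0("t", 1:100),
                     predicted_class = "a", pin = runif(100, 0.6, 1))
  out <- estimate_test_pr(test, xv, thresholds = 0.2, score = "pin")
  expect_equal(out$subset_size, 100)
  expect_equal(out$est_correct, 70)
  expect_equal(out$P, 0.7)
  expect_equal(out$R, 0.7)
  # at a = 0 the subset is everything and R = P
  out0 <- estimate_test_pr(test, xv, thresholds = 0, score = "pin")
  expect_equal(out0$subset_size, 100)
  expect_equal(out0$P, out0$R)
})

test_that("class-specific test estimation sums per-class estimates", {
  # classes (sizes, precisions) = (40, 0.9), (60, 0.5) -> 66 correct
  xv <- data.frame(
    instance_id = paste0("x", 1:20),
    predicted_class = rep(c("A", "B"), each = 10),
    true_class = c(rep("A", 9), "B", rep("B", 5), rep("A", 5)),
    pic = 0.5)
  test <- data.frame(instance_id = paste0("t", 1:100),
                     predicted_class = rep(c("A", "B"), c(40, 60)),
                     pic = 0.8)
  out <- estimate_test_pr(test, xv, thresholds = 0.3, score = "pic")
  expect_equal(out$subset_size, 100)
  expect_equal(out$est_correct, 40 * 0.9 + 60 * 0.5)
  expect_equal(out$P, 0.66)
  expect_equal(out$R, 0.66)
  # empty subset reported as undefined precision
  none <- estimate_test_pr(test, xv, thresholds = 0.95, score = "pic")
  expect_true(is.na(none$P))
  expect_equal(none$subset_size, 0)
})
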