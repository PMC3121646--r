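# The maximum-PIN combiner, vote and stacking baselines, and the
# leave-one-out contribution analysis.

mk_model <- function(pins, classes, truth = NULL, id = "m") {
  df <- data.frame(instance_id = paste0("i", seq_along(pins)),
                   model_id = id, predicted_class = classes, pin = pins,
                   stringsAsFactors = FALSE)
  if (!is.null(truth)) df$true_class <- truth
  df
}

test_that("combine_pin picks the model with the highest PIN", {
  models <- list(a = mk_model(0.4, "k1", id = "a"),
                 b = mk_model(0.7, "k2", id = "b"),
                 c = mk_model(0.5, "k1", id = "c"))
  out <- combine_pin(models)
  expect_equal(out$predicted_class, "k2")
  expect_equal(out$max_pin, 0.7)
  expect_equal(out$winning_model_id, "b")
})

test_that("unanimous agreement yields that class at the shared PIN", {
  models <- list(a = mk_model(c(0.6, 0.6), c("k1", "k2"), id = "a"),
                 b = mk_model(c(0.6, 0.6), c("k1", "k2"), id = "b"))
  out <- combine_pin(models, seed = 3)
  expect_equal(out$predicted_class, c("k1", "k2"))
  expect_equal(out$max_pin, c(0.6, 0.6))
})

test_that("MaxPIN dominates every individual model's PIN", {
  set.seed(8)
  n <- 200
  models <- lapply(c("a", "b", "c"), function(id)
    mk_model(runif(n), sample(c("k1", "k2"), n, TRUE), id = id))
  out <- combine_pin(models, seed = 1)
  for (m in models) expect_true(all(out$max_pin >= m$pin))
})

test_that("PIN ties are broken uniformly at random but reproducibly", {
  n <- 10000
  models <- list(a = mk_model(rep(0.5, n), rep("k1", n), id = "a"),
                 b = mk_model(rep(0.5, n), rep("k2", n), id = "b"))
  out1 <- combine_pin(models, seed = 42)
  out2 <- combine_pin(models, seed = 42)
  expect_identical(out1, out2)
  wins_a <- sum(out1$winning_model_id == "a")
  # binomial 3-sigma band around n/2
  expect_lt(abs(wins_a - n / 2), 3 * sqrt(n * 0.25))
})

test_that("combine_pin validates its inputs", {
  m <- mk_model(c(0.1, 0.2), c("k1", "k1"))
  expect_error(combine_pin(list(m)), ">= 2 models")
  m2 <- m; m2$instance_id <- rev(m2$instance_id)
  expect_error(combine_pin(list(a = m, b = m2)), "aligned")
})

test_that("vote_combine takes the plurality and is seeded on ties", {
  models <- list(a = mk_model(0.5, "A", id = "a"),
                 b = mk_model(0.5, "A", id = "b"),
                 c = mk_model(0.5, "B", id = "c"))
  expect_equal(vote_combine(models)$predicted_class, "A")
  tie <- list(a = mk_model(0.5, "A", id = "a"),
              b = mk_model(0.5, "A", id = "b"),
              c = mk_model(0.5, "B", id = "c"),
              d = mk_model(0.5, "B", id = "d"),
              e = mk_model(0.5, "C", id = "e"))
  picks <- vapply(1:40, function(s)
    vote_combine(tie, seed = s)$predicted_class, "")
  expect_true(all(picks %in% c("A", "B")))
  expect_true(all(c("A", "B") %in% picks))
  expect_identical(vote_combine(tie, seed = 7),
                   vote_combine(tie, seed = 7))
  one <- vote_combine(list(a = mk_model(0.5, "Z", id = "a")))
  expect_equal(one$predicted_class, "Z")
})

test_that("stack1 recovers truth from a perfect level-0 classifier", {
  set.seed(31)
  n <- 60
  classes <- c("a", "b", "c")
  truth <- sample(classes, n, TRUE)
  onehot <- vapply(classes, function(k) as.numeric(truth == k),
                   numeric(n))
  # one-hot rows sum to 1, so the intercept makes this rank-deficient
  expect_warning(fit <- stack1_fit(list(perfect = onehot), truth, classes),
                 "rank-deficient")
  expect_equal(predict(fit, list(perfect = onehot)), truth)
})

test_that("stack1 with constant blocks predicts the modal class", {
  truth <- c(rep("a", 7), rep("b", 3))
  block <- matrix(1 / 2, 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(fit <- stack1_fit(list(m = block), truth, c("a", "b")),
                 "rank-deficient")
  expect_true(all(suppressWarnings(
    predict(fit, list(m = block))) == "a"))
})

test_that("stack1 coefficients match the normal-equations oracle", {
  set.seed(33)
  n <- 80
  classes <- c("a", "b", "c")
  truth <- sample(classes, n, TRUE)
  blocks <- lapply(1:2, function(i) {
    g <- matrix(rexp(n * 3), n, 3, dimnames = list(NULL, classes))
    g / rowSums(g)
  })
  names(blocks) <- c("m1", "m2")
  # rows of each block sum to 1, so the intercept makes the design
  # rank-deficient; least-squares *fitted values* are still unique and
  # must match the generic QR oracle
  expect_warning(fit <- stack1_fit(blocks, truth, classes),
                 "rank-deficient")
  X <- cbind(1, do.call(cbind, blocks))
  qx <- qr(X)
  for (k in classes) {
    y <- as.numeric(truth == k)
    oracle_fitted <- qr.fitted(qx, y)
    got_fitted <- X %*% fit$coefficients[, k]
    expect_equal(as.numeric(got_fitted), as.numeric(oracle_fitted),
                 tolerance = 1e-8)
  }
})

test_that("stack2 recovers truth, is seeded, and has the right width", {
  set.seed(35)
  n <- 90
  classes <- c("a", "b", "c")
  truth <- sample(classes, n, TRUE)
  onehot <- vapply(classes, function(k) as.numeric(truth == k),
                   numeric(n))
  fit <- stack2_fit(list(perfect = onehot), list(perfect = truth),
                    truth, classes, seed = 2)
  expect_equal(predict(fit, list(perfect = onehot),
                       list(perfect = truth)), truth)
  fit2 <- stack2_fit(list(perfect = onehot), list(perfect = truth),
                     truth, classes, seed = 2)
  expect_identical(predict(fit, list(perfect = onehot),
                           list(perfect = truth)),
                   predict(fit2, list(perfect = onehot),
                           list(perfect = truth)))
  # dimensional bookkeeping: L = 5 models, C = 21 classes -> 110 columns
  C <- 21; L <- 5
  cls21 <- paste0("k", 1:C)
  tr <- c(cls21, sample(cls21, 29, TRUE))   # every class represented
  blocks <- replicate(L, {
    g <- matrix(rexp(50 * C), 50, C, dimnames = list(NULL, cls21))
    g / rowSums(g)
  }, simplify = FALSE)
  names(blocks) <- paste0("m", 1:L)
  preds <- setNames(replicate(L, sample(cls21, 50, TRUE),
                              simplify = FALSE), names(blocks))
  f <- stack2_fit(blocks, preds, tr, cls21, seed = 1, ntree = 20)
  expect_length(f$feature_names, L * C + L)
})

test_that("a redundant model contributes nothing; small L errors", {
  set.seed(37)
  n <- 300
  truth <- sample(c("k1", "k2"), n, TRUE)
  # continuous pins: the only PIN ties are within the duplicated pair,
  # whose members predict identically
  base <- mk_model(runif(n),
                   sample(c("k1", "k2"), n, TRUE), truth, id = "a")
  twin <- base; twin$model_id <- "a_copy"
  other <- mk_model(runif(n),
                    sample(c("k1", "k2"), n, TRUE), truth, id = "b")
  models <- list(a = base, a_copy = twin, b = other)
  tab <- contribution_analysis(models, precisions = c(0.3, 0.4), seed = 1)
  expect_true(all(abs(tab["a", ]) < 1e-9, na.rm = TRUE))
  expect_error(contribution_analysis(models[1:2], 0.3), ">= 3 models")
})

test_that("withholding the only expert on a class lowers recall", {
  # model 'expert' alone is right on class k3 with high PIN; two clones
  # are good on k1/k2 but wrong on k3
  set.seed(39)
  n <- 300
  truth <- sample(c("k1", "k2", "k3"), n, TRUE)
  clone_pred <- ifelse(truth == "k3",
                       sample(c("k1", "k2"), n, TRUE),
                       truth)
  clone <- mk_model(ifelse(truth == "k3", 0.3, 0.8), clone_pred, truth,
                    id = "c1")
  clone2 <- clone; clone2$model_id <- "c2"
  expert <- mk_model(ifelse(truth == "k3", 0.9, 0.2),
                     ifelse(truth == "k3", "k3",
                            sample(c("k1", "k2"), n, TRUE)),
                     truth, id = "expert")
  tab <- contribution_analysis(list(c1 = clone, c2 = clone2,
                                    expert = expert),
                               precisions = c(0.7), seed = 1)
  expect_gt(tab["expert", 1], 0)
})
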