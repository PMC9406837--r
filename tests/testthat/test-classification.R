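toy_X <- rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1))
toy_y <- c("normal", "normal", "malignant", "malignant")

test_that("the SVM boundary bisects parallel clusters at the margin midpoint", {
  m <- train_linear_svm(toy_X, toy_y, C = 1)
  expect_equal(svm_predict(m, toy_X), toy_y)  # separable: perfect training fit

  # x-intercept of the decision boundary (scores along y = 0.5)
  f <- function(x) svm_predict(m, cbind(x, 0.5), type = "score")
  xint <- uniroot(f, c(0, 3))$root
  expect_lt(abs(xint - 1.5), 0.2)

  # grid-search hinge-loss oracle (w2 = 0 by symmetry of the clusters)
  ys <- ifelse(toy_y == "malignant", 1, -1)
  grid <- expand.grid(w1 = seq(0.05, 3, 0.05), b = seq(-4, 2, 0.05))
  obj <- mapply(function(w1, b) hinge_objective(w1, b, toy_X, ys, C = 1),
                grid$w1, grid$b)
  best <- grid[which.min(obj), ]
  oracle_xint <- -best$b / best$w1
  expect_lt(abs(oracle_xint - 1.5), 0.2)
  expect_lt(abs(xint - oracle_xint), 0.3)
})

test_that("duplicating training points leaves the decision function alone", {
  m1 <- train_linear_svm(toy_X, toy_y)
  m2 <- train_linear_svm(rbind(toy_X, toy_X), c(toy_y, toy_y))
  grid <- cbind(runif(20, -1, 4), runif(20, -1, 2))
  s1 <- svm_predict(m1, grid, type = "score")
  s2 <- svm_predict(m2, grid, type = "score")
  expect_equal(sign(s1), sign(s2))
  expect_equal(s1 / sqrt(sum(m1$w^2)), s2 / sqrt(sum(m2$w^2)), tolerance = 1e-6)
})

test_that("flipping the labels flips every prediction", {
  m1 <- train_linear_svm(toy_X, toy_y)
  flipped <- ifelse(toy_y == "normal", "malignant", "normal")
  m2 <- train_linear_svm(toy_X, flipped)
  grid <- cbind(runif(10, -1, 4), runif(10, -1, 2))
  p1 <- svm_predict(m1, grid)
  p2 <- svm_predict(m2, grid)
  expect_true(all(p1 != p2))
})

test_that("SVM prediction contracts: tie rule, empty input, width check", {
  m <- structure(list(w = 1, b = 0, center = 0, scale = 1, C = 1,
                      positive = "malignant", negative = "normal"),
                 class = "linear_svm")
  expect_equal(svm_predict(m, matrix(0)), "malignant")  # boundary -> positive
  expect_equal(svm_predict(m, matrix(numeric(0), 0, 1)), character(0))
  mm <- train_linear_svm(toy_X, toy_y)
  expect_error(svm_predict(mm, matrix(0, 1, 3)), "width")
  expect_error(train_linear_svm(toy_X, rep("normal", 4)), "two classes")
})

test_that("the ANN separates the separable toy within 200 epochs", {
  set.seed(51)
  # two linearly separable blocks with a unit margin along x
  Xtr <- rbind(cbind(runif(20, -1, 1), runif(20, -1, 1)),
               cbind(runif(20, 2, 4), runif(20, -1, 1)))
  ytr <- rep(c("normal", "malignant"), each = 20)
  Xval <- rbind(cbind(runif(10, -1, 1), runif(10, -1, 1)),
                cbind(runif(10, 2, 4), runif(10, -1, 1)))
  yval <- rep(c("normal", "malignant"), each = 10)
  m <- train_ann(Xtr, ytr, train_config(max_epochs = 200, seed = 7),
                 Xval, yval)
  expect_equal(ann_predict(m, Xval)$labels, yval)
  expect_lte(nrow(m$log), 200)
})

test_that("training is deterministic and the stop reason is always set", {
  set.seed(52)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), 10)
  cfg <- train_config(max_epochs = 30, patience = 1, seed = 3)
  m1 <- train_ann(X, y, cfg, X, y)
  m2 <- train_ann(X, y, cfg, X, y)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$log, m2$log)
  expect_true(m1$stop_reason %in% c("patience", "max_epochs"))
})

test_that("early stopping restores the best-validation checkpoint", {
  set.seed(53)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c("a", "b"), 15)
  Xv <- matrix(rnorm(20), 10, 2)
  yv <- rep(c("a", "b"), 5)
  m <- train_ann(X, y, train_config(max_epochs = 100, patience = 3, seed = 9),
                 Xv, yv)
  expect_lte(m$best_val_loss, m$log$val_loss[nrow(m$log)] + 1e-12)
  expect_equal(m$best_val_loss, min(m$log$val_loss))
})

test_that("non-finite inputs surface as a divergence error with the epoch", {
  X <- matrix(c(NaN, 1, 2, 3), 2, 2)
  y <- c("a", "b")
  expect_error(train_ann(X, y, train_config(max_epochs = 5), X, y),
               "diverged.*epoch 1")
})

test_that("ANN scores are softmax probabilities consistent with the labels", {
  set.seed(54)
  X <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 2), 15, 2))
  y <- rep(c("normal", "malignant"), each = 15)
  m <- train_ann(X, y, train_config(max_epochs = 50, seed = 2), X, y)
  p <- ann_predict(m, X)
  expect_equal(unname(rowSums(p$scores)), rep(1, 30), tolerance = 1e-12)
  expect_equal(p$labels,
               m$classes[apply(p$scores, 1, which.max)])
  same <- ann_predict(m, X[c(1, 1), ])
  expect_equal(same$scores[1, ], same$scores[2, ])
  expect_error(ann_predict(m, matrix(0, 1, 5)), "width")
})

test_that("MSE loss is available and trains on the toy", {
  set.seed(55)
  X <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 3), 15, 2))
  y <- rep(c("a", "b"), each = 15)
  m <- train_ann(X, y, train_config(max_epochs = 300, seed = 1,
                                    learning_rate = 0.05, loss = "mse"),
                 X, y)
  expect_gte(mean(ann_predict(m, X)$labels == y), 0.9)
})
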