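test_that("hidden-node sizing rule rounds up", {
  expect_identical(hidden_nodes(10, 2), 6L)
  expect_identical(hidden_nodes(9, 2), 6L)   # forces ceiling
  expect_identical(hidden_nodes(2, 2), 2L)
  expect_identical(hidden_nodes(1, 2), 2L)
  expect_error(hidden_nodes(0, 2))
})

test_that("min-max normalization maps to [0,1] with clipping", {
  x <- cbind(a = c(0, 5, 10), b = c(-2, 0, 2))
  b <- normalize_fit(x)
  xn <- normalize_apply(b, x)
  expect_equal(unname(xn[, 1]), c(0, 0.5, 1))
  expect_equal(unname(apply(xn, 2, min)), c(0, 0))
  expect_equal(unname(apply(xn, 2, max)), c(1, 1))
  # out-of-range values clip
  expect_equal(unname(normalize_apply(b, cbind(a = 20, b = -7))[1, ]), c(1, 0))
  # constant feature rejected by name
  expect_error(normalize_fit(cbind(a = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(1234)
  for (trial in 1:5) {
    ni <- sample(2:4, 1); nh <- sample(2:4, 1); no <- sample(2:4, 1)
    n <- sample(3:8, 1)
    x <- matrix(runif(n * ni), n, ni)
    targets <- matrix(runif(n * no), n, no)
    np <- nh * ni + nh + no * nh + no
    par <- runif(np, -0.5, 0.5)
    ga <- seedvision:::bpnn_gradient(par, x, targets, ni, nh, no)
    h <- 1e-5
    gn <- vapply(seq_len(np), function(i) {
      e <- rep(0, np); e[i] <- h
      (seedvision:::bpnn_loss(par + e, x, targets, ni, nh, no) -
         seedvision:::bpnn_loss(par - e, x, targets, ni, nh, no)) / (2 * h)
    }, 0)
    expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-8)), 1e-6)
  }
})

test_that("training converges on separable blobs and is deterministic", {
  set.seed(7)
  x <- rbind(matrix(rnorm(200, 0.2, 0.05), ncol = 2),
             matrix(rnorm(200, 0.8, 0.05), ncol = 2))
  y <- rep(c("good", "ng"), each = 100)
  fit <- bpnn(x, y, cfg = train_config(rng_seed = 3))
  expect_true(fit$converged)
  expect_lt(fit$final_mse, 0.01)
  expect_gte(mean(predict(fit, x)$label == y), 0.99)
  # same data + same seed -> bit-identical weights
  fit2 <- bpnn(x, y, cfg = train_config(rng_seed = 3))
  expect_identical(coef(fit), coef(fit2))
  # different seed -> different weights
  fit3 <- bpnn(x, y, cfg = train_config(rng_seed = 4))
  expect_false(identical(coef(fit), coef(fit3)))
  # held-out data from the same generator classifies >= 0.95
  set.seed(99)
  xh <- rbind(matrix(rnorm(200, 0.2, 0.05), ncol = 2),
              matrix(rnorm(200, 0.8, 0.05), ncol = 2))
  expect_gte(mean(predict(fit, xh)$label == y), 0.95)
})

test_that("one sample per class is memorized", {
  x <- rbind(c(0, 0), c(1, 1))
  fit <- suppressWarnings(bpnn(x, c("good", "ng"),
                               cfg = train_config(max_epochs = 5000)))
  expect_equal(as.character(predict(fit, x)$label), c("good", "ng"))
})

test_that("prediction applies the argmax with a conservative tie rule", {
  set.seed(2)
  x <- rbind(matrix(runif(20, 0, 0.4), ncol = 2),
             matrix(runif(20, 0.6, 1), ncol = 2))
  y <- rep(c("good", "ng"), each = 10)
  fit <- suppressWarnings(bpnn(x, y, cfg = train_config(max_epochs = 200)))
  p <- predict(fit, x)
  expect_named(p, c("label", "outputs"))
  lab <- ifelse(p$outputs[, 1] > p$outputs[, 2], "good", "ng")
  expect_equal(as.character(p$label), lab)
  expect_error(predict(fit, matrix(0, 1, 5)), "expected 2")
  expect_error(bpnn(cbind(c(1, NA), c(0, 1)), c("good", "ng")), "NA|NaN")
})

test_that("non-convergence is flagged but the model is returned", {
  set.seed(4)
  x <- matrix(runif(80), ncol = 2)  # unlearnable labels, tiny budget
  y <- rep(c("good", "ng"), 20)
  expect_warning(fit <- bpnn(x, y, cfg = train_config(max_epochs = 5)),
                 "did not reach")
  expect_false(fit$converged)
  expect_equal(fit$epochs, 5L)
})

test_that("the AND rule combines per-aspect decisions", {
  expect_equal(combine_labels("good", "good"), "good")
  expect_equal(combine_labels("good", "ng"), "ng")
  expect_equal(combine_labels("ng", "good"), "ng")
  expect_equal(combine_labels("ng", "ng"), "ng")
  expect_equal(combine_labels(c("good", "good"), c("good", "ng")),
               c("good", "ng"))
})

test_that("formula interface and JSON round trip reproduce predictions", {
  set.seed(12)
  d <- data.frame(u = c(runif(30, 0, 0.4), runif(30, 0.6, 1)),
                  v = runif(60),
                  label = rep(c("good", "ng"), each = 30))
  fit <- suppressWarnings(bpnn(label ~ u + v, data = d,
                               cfg = train_config(max_epochs = 500)))
  p1 <- predict(fit, d[, c("u", "v")])
  path <- tempfile(fileext = ".json")
  write_bpnn(fit, path)
  back <- read_bpnn(path)
  p2 <- predict(back, d[, c("u", "v")])
  expect_equal(p2$outputs, p1$outputs, tolerance = 1e-12)
  expect_equal(as.character(p2$label), as.character(p1$label))
  unlink(path)
  # print/summary/plot methods run quietly
  expect_output(print(fit), "Back-propagation")
  expect_output(print(summary(fit)), "free parameters")
  pdf(NULL); plot(fit); dev.off()
})
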