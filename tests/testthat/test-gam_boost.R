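test_that("fit_stump solves the textbook cases", {
  s <- fit_stump(c(1, 2, 3, 4), c(-1, -1, 1, 1))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$left, -1)
  expect_equal(s$right, 1)
  expect_equal(s$sse, 0)

  # zero residuals -> zero leaves
  s0 <- fit_stump(c(1, 5, 2, 9), rep(0, 4))
  expect_equal(s0$left, 0)
  expect_equal(s0$right, 0)
  expect_equal(s0$sse, 0)

  # constant feature -> degenerate stump at -Inf with mean leaves
  sc <- fit_stump(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_equal(sc$threshold, -Inf)
  expect_equal(sc$left, 3)
  expect_equal(sc$right, 3)

  expect_error(fit_stump(1, 1), "at least 2")
  expect_error(fit_stump(1:3, 1:2), "same length")
})

test_that("fit_stump matches an exhaustive split-scan oracle on random data", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- if (i %% 3 == 0) sample(1:6, n, replace = TRUE) else rnorm(n)
    r <- rnorm(n)
    got <- fit_stump(x, r)
    want <- brute_stump(x, r)
    expect_equal(got$sse, want$sse, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("gaussian deviance is the residual sum of squares", {
  expect_equal(gaussian_deviance(c(1, 2), c(1, 2)), 0)
  expect_equal(gaussian_deviance(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(7)
  y <- rnorm(100)
  yh <- rnorm(100)
  expect_equal(gaussian_deviance(y, yh), sum((y - yh)^2), tolerance = 1e-12)
  expect_error(gaussian_deviance(1:3, 1:2), "length")
})

test_that("a self-predicting feature drives the training deviance to zero", {
  y <- rep(c(0, 1), each = 50)
  x <- matrix(y + 0, dimnames = list(NULL, "x"))
  fit <- gam_boost_fit(x, y, n_rounds = 200, learning_rate = 0.5)
  expect_lt(max(abs(fit$fitted.values - y)), 1e-3)
  expect_lt(fit$deviance, 1e-5)
})

test_that("the eta -> 0 limit reduces to the intercept-only null model", {
  set.seed(3)
  y <- rbinom(80, 1, 0.4)
  x <- matrix(rnorm(80), dimnames = list(NULL, "x"))
  fit <- gam_boost_fit(x, y, n_rounds = 1, learning_rate = 1e-8)
  expect_equal(unname(coef(fit)), mean(y), tolerance = 1e-6)
  expect_equal(fit$fitted.values, rep(mean(y), 80), tolerance = 1e-6)

  fit0 <- gam_boost_fit(matrix(numeric(0), 80, 0), y, n_rounds = 5)
  expect_equal(fit0$fitted.values, rep(mean(y), 80))
})

test_that("a planted step in one feature is recovered as a step near the true location", {
  set.seed(9)
  x <- runif(2000, -1, 1)
  y <- as.numeric(x > 0)
  d <- data.frame(x = x, y = y)
  fit <- gam_boost(y ~ x, d, n_rounds = 150, learning_rate = 0.5)
  grid <- data.frame(x = seq(-1, 1, by = 0.01))
  pred <- predict(fit, grid)
  crossings <- grid$x[which(diff(pred > 0.5) != 0)]
  expect_lt(max(abs(crossings)), 0.1)
  # monotone step: low plateau near 0, high plateau near 1
  expect_lt(mean(pred[grid$x < -0.2]), 0.1)
  expect_gt(mean(pred[grid$x > 0.2]), 0.9)
})

test_that("training deviance is non-increasing for any learning rate", {
  set.seed(11)
  for (eta in c(0.05, 0.3, 1)) {
    x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(100, 1, plogis(x[, 1]))
    for (policy in c("cyclic", "best")) {
      fit <- gam_boost_fit(x, y, n_rounds = 60, learning_rate = eta,
                           feature_policy = policy)
      expect_true(all(diff(c(fit$null_deviance, fit$deviance_trace)) <=
                        1e-10 * fit$null_deviance))
    }
  }
})

test_that("predictions decompose exactly into intercept plus per-feature shapes", {
  set.seed(13)
  x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(x[, 1] - x[, 3]))
  fit <- gam_boost_fit(x, y, n_rounds = 80)
  xnew <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))

  pred <- predict(fit, xnew)
  terms <- predict(fit, xnew, type = "terms")
  expect_equal(pred, rowSums(terms) + attr(terms, "constant"),
               tolerance = 1e-12)

  # independent route: evaluate the raw eta-scaled stump list directly
  direct <- rep(fit$intercept, nrow(xnew))
  for (s in seq_len(nrow(fit$stumps))) {
    st <- fit$stumps[s, ]
    xv <- xnew[, st$feature]
    direct <- direct + ifelse(xv <= st$threshold, st$left, st$right)
  }
  expect_equal(pred, direct, tolerance = 1e-12)

  # exported tables reproduce predict() when evaluated by hand
  tabs <- shape_functions(fit)
  byhand <- rep(fit$intercept, nrow(xnew))
  for (j in names(tabs)) {
    tab <- tabs[[j]]
    idx <- findInterval(xnew[, j], tab$upper[-nrow(tab)],
                        left.open = TRUE) + 1L
    byhand <- byhand + tab$value[idx]
  }
  expect_equal(pred, byhand, tolerance = 1e-12)
})

test_that("refitting identical data is bit-identical and row order is irrelevant", {
  set.seed(17)
  x <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(200, 1, 0.5)
  f1 <- gam_boost_fit(x, y, n_rounds = 40)
  f2 <- gam_boost_fit(x, y, n_rounds = 40)
  expect_identical(f1$stumps, f2$stumps)
  expect_identical(f1$fitted.values, f2$fitted.values)

  perm <- sample(200)
  f3 <- gam_boost_fit(x[perm, ], y[perm], n_rounds = 40)
  expect_equal(f3$stumps, f1$stumps, tolerance = 1e-12)
  xnew <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(f3, xnew), predict(f1, xnew), tolerance = 1e-12)
})

test_that("with eta = 1 a single-feature fit converges to the regressogram over split cells", {
  # tied x values force cells; the converged additive fit must equal the
  # per-cell mean response computed directly
  x <- rep(c(1, 2, 3, 4), times = c(5, 3, 6, 4))
  set.seed(19)
  y <- rbinom(length(x), 1, c(0.1, 0.9, 0.4, 0.7)[match(x, 1:4)])
  fit <- gam_boost_fit(matrix(x, dimnames = list(NULL, "x")), y,
                       n_rounds = 300, learning_rate = 1)
  cellmean <- tapply(y, x, mean)
  pred <- predict(fit, matrix(unique(x), dimnames = list(NULL, "x")))
  expect_equal(unname(pred),
               as.numeric(cellmean[as.character(unique(x))]),
               tolerance = 1e-8)
})

test_that("input contracts are enforced", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(gam_boost_fit(x, rnorm(10)), "binary")
  expect_error(gam_boost_fit(x, rep(1, 9)), "nrow")
  expect_error(gam_boost_fit(x, rep(1, 10), n_rounds = 0), "n_rounds")
  expect_error(gam_boost_fit(x, rep(1, 10), learning_rate = 1.2),
               "learning_rate")

  fit <- gam_boost_fit(x, rbinom(10, 1, 0.5), n_rounds = 5)
  expect_error(predict(fit, x[, "a", drop = FALSE]), "missing")
  xx <- cbind(x, c = rnorm(10))
  expect_error(predict(fit, xx), "unknown")
})

test_that("models serialize to JSON and round-trip predictions bit-exactly", {
  set.seed(23)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  # include a constant column so a -Inf threshold goes through JSON
  x[, 2] <- 1
  y <- rbinom(100, 1, 0.5)
  fit <- gam_boost_fit(x, y, n_rounds = 30)
  expect_true(any(!is.finite(fit$stumps$threshold)))

  path <- withr::local_tempfile(fileext = ".json")
  write_gam_boost(fit, path)
  back <- read_gam_boost(path)
  expect_identical(back$stumps, fit$stumps)
  expect_identical(back$intercept, fit$intercept)
  xnew <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  xnew[, 2] <- 1
  expect_identical(predict(back, xnew), predict(fit, xnew))
})

test_that("formula interface, methods and diagnostics behave like a standard model object", {
  set.seed(29)
  d <- data.frame(a = rnorm(150), b = rnorm(150))
  d$y <- rbinom(150, 1, plogis(d$a))
  fit <- gam_boost(y ~ a + b, d, n_rounds = 40)

  expect_s3_class(fit, "gam_boost")
  expect_named(coef(fit), "(Intercept)")
  expect_equal(fitted(fit) + residuals(fit), d$y, tolerance = 1e-12)
  expect_equal(deviance(fit), sum(residuals(fit)^2), tolerance = 1e-10)
  expect_equal(deviance(fit),
               -2 * (fit$diagnostics$logLik_fitted -
                       fit$diagnostics$logLik_saturated),
               tolerance = 1e-9)

  s <- summary(fit)
  expect_s3_class(s, "summary.gam_boost")
  expect_equal(sum(s$features$n_stumps), 2 * 40)
  expect_output(print(fit), "Gradient-boosted stump GAM")
  expect_output(print(s), "Shape functions")

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(150L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
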