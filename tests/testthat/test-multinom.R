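simulate_multinom_data <- function(n, K, P, seed) {
  set.seed(seed)
  X <- cbind(intercept = 1,
             matrix(rnorm(n * (P - 1)), n,
                    dimnames = list(NULL, paste0("x", seq_len(P - 1)))))
  B <- matrix(runif((K - 1) * P, -1, 1), K - 1, P)
  eta <- cbind(0, X %*% t(B))
  p <- exp(eta) / rowSums(exp(eta))
  y <- factor(apply(p, 1, function(pr) sample(seq_len(K), 1, prob = pr)))
  list(X = X, y = y, B = B)
}

test_that("two-level fits reduce to binary logistic regression", {
  set.seed(21)
  n <- 400
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 - 0.9 * x + 0.5 * z))
  f <- fit_multinomial(cbind(intercept = 1, x = x, z = z),
                       factor(y, levels = c(0, 1)))
  g <- stats::glm(y ~ x + z, family = binomial)
  expect_true(f$converged)
  expect_equal(unname(f$coef[1, ]), unname(coef(g)), tolerance = 1e-6)
  se_glm <- summary(g)$coefficients[, "Std. Error"]
  expect_equal(unname(f$se[1, ]), unname(se_glm), tolerance = 1e-5)
})

test_that("saturated 2x2 design reproduces the closed-form cross-ratio", {
  # x=0: {A:10, B:10}; x=1: {A:5, B:20}  =>  OR for B vs A on x = 4.0
  x <- rep(c(0, 1), times = c(20, 25))
  y <- c(rep(c("A", "B"), times = c(10, 10)),
         rep(c("A", "B"), times = c(5, 20)))
  f <- fit_multinomial(cbind(intercept = 1, x = x),
                       factor(y), reference = "A")
  expect_equal(exp(f$coef["B", "x"]), 4.0, tolerance = 1e-6)
  # saturated-model identity: fitted cell probabilities = empirical shares
  p <- predict(f)
  expect_equal(unname(p[1, "B"]), 10 / 20, tolerance = 1e-8)
  expect_equal(unname(p[45, "B"]), 20 / 25, tolerance = 1e-8)
})

test_that("coefficients match an independent reference fit on random data", {
  skip_if_not_installed("nnet")
  specs <- expand.grid(K = 2:4, P = 2:4)
  i_case <- 0
  for (r in seq_len(nrow(specs))) {
    for (rep in 1:3) {
      if (i_case >= 20) break
      i_case <- i_case + 1
      dat <- simulate_multinom_data(n = 200, K = specs$K[r], P = specs$P[r],
                                    seed = 1000 + i_case)
      f <- fit_multinomial(dat$X, dat$y)
      df <- data.frame(dat$X[, -1, drop = FALSE])
      ref <- nnet::multinom(dat$y ~ ., data = df, trace = FALSE,
                            reltol = 1e-13, maxit = 500)
      rc <- coef(ref)
      if (is.null(dim(rc))) rc <- matrix(rc, nrow = 1)
      expect_equal(unname(f$coef), unname(rc),
                   tolerance = 1e-4,
                   label = sprintf("case %d (K=%d P=%d)", i_case,
                                   specs$K[r], specs$P[r]))
    }
  }
  expect_equal(i_case, 20)
})

test_that("fitted probabilities sum to one and the score vanishes", {
  dat <- simulate_multinom_data(n = 500, K = 4, P = 3, seed = 77)
  f <- fit_multinomial(dat$X, dat$y)
  p <- predict(f)
  expect_true(all(abs(rowSums(p) - 1) < 1e-10))
  # score at the optimum: X'(Y_k - p_k) for each non-reference class
  for (k in 2:4) {
    g <- crossprod(dat$X, (as.integer(dat$y) == k) - p[, k])
    expect_lt(max(abs(g)), 1e-6 * nrow(dat$X))
  }
  # covariance is symmetric positive semidefinite
  expect_equal(f$vcov, t(f$vcov), tolerance = 1e-10)
  expect_true(all(eigen(f$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("rank deficiency errors name the collinear column", {
  X <- cbind(intercept = 1, a = rnorm(50), twice_a = 0)
  X[, "twice_a"] <- 2 * X[, "a"]
  y <- factor(sample(c("u", "v"), 50, TRUE))
  expect_error(fit_multinomial(X, y), "twice_a")
})

test_that("separation is flagged, and ridge returns a finite shrunk fit", {
  # y constant given x: complete separation
  x <- c(rep(0, 20), rep(1, 20))
  y <- factor(c(rep("A", 20), rep("B", 20)))
  X <- cbind(intercept = 1, x = x)
  expect_warning(f0 <- fit_multinomial(X, y), "separation")
  expect_false(f0$converged)
  f1 <- fit_multinomial(X, y, ridge = 1e-2)
  expect_true(all(is.finite(f1$coef)))
  expect_true(all(is.finite(f1$se)))
})

test_that("Wald odds-ratio intervals follow normal-quantile arithmetic", {
  dat <- simulate_multinom_data(n = 300, K = 3, P = 2, seed = 5)
  f <- fit_multinomial(dat$X, dat$y)
  tab <- wald_intervals(f, level = 0.95)
  z <- qnorm(0.975)
  i <- 2L
  expect_equal(tab$odds_ratio[i], exp(tab$estimate[i]))
  expect_equal(tab$lower[i], exp(tab$estimate[i] - z * tab$se[i]))
  expect_equal(tab$upper[i], exp(tab$estimate[i] + z * tab$se[i]))
  # default 97.5% two-sided level uses z ~ 2.2414
  tab975 <- wald_intervals(f)
  expect_equal(attr(tab975, "z"), qnorm((1 + 0.975) / 2), tolerance = 1e-12)
  expect_true(all((tab975$lower > 1 | tab975$upper < 1) == tab975$significant))
  expect_error(wald_intervals(f, level = 0.4), "level")
  # b = ln 2 with s -> 0 collapses to (2, 2)
  f$coef[1, 1] <- log(2); f$se[1, 1] <- 1e-12
  t2 <- wald_intervals(f)
  expect_equal(t2$lower[1], 2, tolerance = 1e-6)
  expect_equal(t2$upper[1], 2, tolerance = 1e-6)
})

test_that("interval coverage of true coefficients is near nominal", {
  # 50 replicates at n = 2000 from a fixed truth; 95% Wald intervals
  B <- matrix(c(0.4, -0.8, 0.6,
                -0.5, 0.5, -0.7), 2, 3, byrow = TRUE)
  z <- qnorm(0.975)
  covered <- 0L; total <- 0L
  for (rep in 1:50) {
    set.seed(4000 + rep)
    n <- 2000
    X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n))
    eta <- cbind(0, X %*% t(B))
    p <- exp(eta) / rowSums(exp(eta))
    y <- factor(apply(p, 1, function(pr) sample(1:3, 1, prob = pr)))
    f <- fit_multinomial(X, y)
    lo <- f$coef - z * f$se
    hi <- f$coef + z * f$se
    covered <- covered + sum(lo <= B & B <= hi)
    total <- total + length(B)
  }
  coverage <- covered / total
  # nominal 0.95; Monte-Carlo half-width ~ 0.025 at 300 draws
  expect_gt(coverage, 0.90)
  expect_lt(coverage, 0.99)
})
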