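test_that("the product-limit curve matches hand computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(0, 1, 2, 3))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  # censoring shrinks risk sets without adding steps
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(0, 1, 3))
  expect_equal(km2$survival, c(1, 2/3, 0))
  # no events: flat at 1
  km3 <- km_estimate(c(5, 7), c(0, 0))
  expect_equal(km3$survival, 1)
  expect_error(km_estimate(numeric(), integer()), "at least one")
})

test_that("without censoring the KM curve equals one minus the empirical CDF", {
  set.seed(37)
  for (r in 1:20) {
    t <- round(rexp(40, 0.1), 2) + 0.01
    km <- km_estimate(t, rep(1, 40))
    ec <- ecdf(t)
    expect_equal(km$survival[-1], 1 - ec(km$time[-1]), tolerance = 1e-12)
  }
})

test_that("the log-rank statistic matches the hand-computed worked example", {
  # group A dies at t = 1, 2; group B at t = 3, 4; no censoring:
  # O_A = 2, E_A = 5/6, V = 17/36, chi2 = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(lr$statistic, 49/17, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(49/17, 1, lower.tail = FALSE), tolerance = 1e-12)
  # identical groups: no signal
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # doubling every subject increases the statistic (more information)
  lr2 <- logrank_test(rep(c(1, 2, 3, 4), 2), rep(1, 8), rep(c("B", "B", "A", "A"), 2))
  expect_gt(lr2$statistic, lr$statistic)
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two")
})

test_that("the log-rank statistic agrees with survdiff and the Cox score test", {
  set.seed(41)
  for (r in 1:25) {
    n <- 30 + r
    sv <- null_surv(n, rate = 0.05)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(sv$event) == 0) next
    lr <- logrank_test(sv$time, sv$event, g)
    sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-8)
    # classical equivalence with the Cox score test on untied data
    fit <- fit_cox(data.frame(g = g), sv$time, sv$event)
    expect_equal(lr$statistic, fit$score_test, tolerance = 1e-6)
  }
})

test_that("Cox estimates match a grid-search partial-likelihood oracle on the 4-subject toy", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  # hand-written partial likelihood: risk sets {1,2,3,4},{2,3,4},{3,4},{4}
  loglik <- function(b) 2 * b - (log(2 * exp(b) + 2) + log(exp(b) + 2) +
                                   log(exp(b) + 1))
  grid <- seq(-5, 5, by = 1e-5)
  b_oracle <- grid[which.max(loglik(grid))]
  fit <- fit_cox(data.frame(x = x), t, e)
  expect_lt(abs(fit$terms$estimate - b_oracle), 1e-4)
  expect_equal(fit$terms$hr, exp(fit$terms$estimate))
  expect_equal(fit$terms$ci_low, exp(fit$terms$estimate - qnorm(0.975) * fit$terms$se))
})

test_that("a balanced covariate with exchangeable outcomes gives HR near 1", {
  set.seed(43)
  n <- 400
  sv <- null_surv(n, rate = 0.03)
  fit <- fit_cox(data.frame(g = rep(0:1, n / 2)), sv$time, sv$event)
  expect_lt(abs(fit$terms$estimate), 0.3)
  expect_false(fit$flagged)
})

test_that("replicating every subject leaves beta unchanged and shrinks the SE by sqrt(2)", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  f1 <- fit_cox(data.frame(x = x), t, e, ties = "breslow")
  f2 <- fit_cox(data.frame(x = rep(x, 2)), rep(t, 2), rep(e, 2), ties = "breslow")
  expect_equal(f2$terms$estimate, f1$terms$estimate, tolerance = 1e-8)
  expect_equal(f1$terms$se / f2$terms$se, sqrt(2), tolerance = 1e-8)
})

test_that("degenerate Cox inputs are reported, not silently fitted", {
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1)
  expect_error(fit_cox(data.frame(flat = rep(1, 4)), t, e), "flat")
  expect_error(fit_cox(data.frame(x = c(1, 0, 1, 0)), t, c(0, 0, 0, 0)), "event")
  # perfect separation: monotone likelihood must be flagged
  fs <- fit_cox(data.frame(x = c(1, 1, 1, 0, 0, 0)),
                c(1, 2, 3, 10, 11, 12), rep(1, 6))
  expect_true(fs$flagged)
})

test_that("the cutoff scan reproduces exhaustive enumeration on an 8-subject toy", {
  score <- c(0.1, 0.25, 0.3, 0.42, 0.55, 0.61, 0.8, 0.95)
  time <- c(2, 5, 3, 9, 14, 11, 16, 20)
  event <- c(1, 1, 1, 1, 0, 1, 1, 0)
  sc <- scan_cutoffs(score, time, event, min_group = 2)
  or <- scan_oracle(score, time, event, min_group = 2)
  expect_equal(sc$candidates$cutoff, or$candidates)
  expect_equal(sc$candidates$p_value, or$p, tolerance = 1e-9)
  expect_equal(sc$cutoff, or$cutoff)
  expect_equal(sc$p_value, or$p_min, tolerance = 1e-9)
})

test_that("the selected p is the minimum over IQR-window candidates (100 random instances)", {
  set.seed(47)
  for (r in 1:100) {
    n <- 30 + (r %% 20)
    sv <- null_surv(n, rate = 0.05)
    score <- rnorm(n)
    sc <- scan_cutoffs(score, sv$time, sv$event)
    expect_equal(sc$p_value, min(sc$candidates$p_value))
    qr <- ecdf(score)(sc$candidates$cutoff)
    expect_true(all(qr >= 0.25 & qr <= 0.75))
    expect_true(all(sc$candidates$n_high >= 5 & sc$candidates$n_low >= 5))
    # ties resolve to the smallest cutoff
    best <- sc$candidates$cutoff[sc$candidates$p_value == sc$p_value]
    expect_equal(sc$cutoff, min(best))
  }
})

test_that("a perfectly separated cohort splits between the score clusters with HR < 1", {
  # the low cluster (all early deaths) ends exactly at the window edge, so
  # the clean between-cluster split is a candidate and no impure split can
  # beat it
  score <- c(seq(0.1, 0.2, length.out = 5), seq(2.1, 3.5, length.out = 15))
  time <- c(1:5, 101:115)
  event <- rep(1, 20)
  sc <- scan_cutoffs(score, time, event)
  expect_gte(sc$cutoff, 0.2)
  expect_lt(sc$cutoff, 2.1)
  expect_lt(sc$fit$terms$hr, 1)
  expect_true(sc$fit$flagged)   # separation is surfaced, not hidden
})

test_that("BH adjustment follows the step-up formula with an FDR-10% default", {
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$q_value, rep(0.04, 4))
  expect_true(all(adj$significant))
  expect_equal(bh_adjust(0.037)$q_value, 0.037)
  # q = 0.099 is significant at the default threshold; 0.11 is not
  expect_identical(bh_adjust(c(0.099))$significant, TRUE)
  expect_identical(bh_adjust(c(0.11))$significant, FALSE)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(53)
  p <- runif(50)
  q <- bh_adjust(p)$q_value
  # monotone in sorted-p order and permutation-equivariant
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  prm <- sample(50)
  expect_equal(bh_adjust(p[prm])$q_value, q[prm])
})

test_that("two-variable models adjust the signature term on per-covariate complete cases", {
  set.seed(59)
  n <- 600
  z <- rnorm(n)
  noise_cov <- sample(c("x", "y"), n, replace = TRUE)
  h <- 0.012 * exp(-0.8 * z)
  t_ev <- rexp(n, h); t_cn <- pmin(rexp(n, 0.004), 240)
  clin <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                         time = pmin(t_ev, t_cn),
                         event = as.integer(t_ev <= t_cn),
                         noise_cov = noise_cov)
  uni <- fit_cox(data.frame(signature = z), clin$time, clin$event)
  tv <- two_variable_cox(clin, z, "noise_cov")
  # a covariate independent of score and outcome leaves the signature HR alone
  expect_lt(abs(log(tv$signature$hr) - log(uni$terms$hr)), 0.1)
  expect_identical(tv$n_used, as.integer(n))
  # determinism: same inputs, same fit
  tv2 <- two_variable_cox(clin, z, "noise_cov")
  expect_identical(tv$signature, tv2$signature)
})

test_that("adjusting for a planted confounder attenuates the signature HR toward 1", {
  set.seed(61)
  n <- 800
  conf <- rbinom(n, 1, 0.5)
  score <- rnorm(n, mean = 1.2 * conf)       # score correlated with confounder
  h <- 0.012 * exp(1.0 * conf)               # outcome driven by confounder only
  t_ev <- rexp(n, h); t_cn <- pmin(rexp(n, 0.004), 240)
  clin <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                         time = pmin(t_ev, t_cn),
                         event = as.integer(t_ev <= t_cn),
                         conf = ifelse(conf == 1, "yes", "no"))
  unadj <- fit_cox(data.frame(signature = score), clin$time, clin$event)
  adj <- two_variable_cox(clin, score, "conf")
  expect_lt(abs(log(adj$signature$hr)), abs(log(unadj$terms$hr)))
})

test_that("missingness is handled per model: complete cases used, all-missing rejected", {
  sv <- null_surv(100, rate = 0.05)
  clin <- tibble::tibble(sample_id = sprintf("s%d", 1:100),
                         time = sv$time, event = sv$event,
                         partial = c(rep("a", 40), rep("b", 30), rep("missing", 30)),
                         gone = rep(NA_character_, 100))
  sc <- rnorm(100)
  tv <- two_variable_cox(clin, sc, "partial")
  expect_identical(tv$n_used, 70L)
  expect_error(two_variable_cox(clin, sc, "gone"), "non-missing")
})
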