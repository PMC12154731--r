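test_that("reactive fraction is the label mean", {
  expect_equal(reactive_fraction(c(1, 1, 0, 0)), 0.5)
  expect_equal(reactive_fraction(rep(1L, 500)), 1)
  expect_error(reactive_fraction(integer(0)), class = "lapnet_contract")
  # seeded Markov series recovers its stationary fraction
  s <- generate_label_series(5000, 0.9, mean_run = 10, seed = 21)
  expect_lt(abs(reactive_fraction(s) - 0.9), 0.02)
})

test_that("run lengths partition the series", {
  rl <- run_lengths(c(1, 1, 0, 1))
  expect_equal(rl$reactive, c(2L, 1L))
  expect_equal(rl$nonreactive, 1L)
  expect_equal(run_lengths(rep(0L, 7))$nonreactive, 7L)
  set.seed(13)
  for (i in 1:20) {
    x <- rbinom(sample(5:60, 1), 1, runif(1, 0.2, 0.8))
    rl <- run_lengths(x)
    expect_equal(sum(rl$reactive) + sum(rl$nonreactive), length(x))
  }
})

test_that("the exact runs test matches brute-force enumeration", {
  # full enumeration of all arrangements for small n
  brute_p <- function(x) {
    n1 <- sum(x); n <- length(x)
    pos <- utils::combn(n, n1)
    allR <- apply(pos, 2, function(p) {
      y <- integer(n); y[p] <- 1L; length(rle(y)$lengths)
    })
    tab <- table(allR) / ncol(pos)
    robs <- length(rle(x)$lengths)
    p_obs <- tab[[as.character(robs)]]
    sum(tab[tab <= p_obs * (1 + 1e-9)])
  }
  expect_equal(runs_test(c(1, 1, 0, 0))$p.value, brute_p(c(1, 1, 0, 0)))
  set.seed(31)
  for (i in 1:10) {
    x <- rbinom(sample(6:12, 1), 1, 0.5)
    if (length(unique(x)) < 2) next
    expect_equal(runs_test(x)$p.value, brute_p(x), tolerance = 1e-12)
  }
  # strict alternation has far too many runs: randomness rejected
  alt <- rep(c(1L, 0L), 10)
  rt <- runs_test(alt)
  expect_lt(rt$p.value, 0.05)
  expect_equal(rt$verdict, "nonrandom")
  expect_error(runs_test(rep(1L, 10)), class = "lapnet_contract")
})

test_that("exact and normal-approximation branches agree for moderate n", {
  set.seed(77)
  x <- rbinom(150, 1, 0.5)
  p_exact <- runs_test(x, exact_max = 200)$p.value
  p_norm <- runs_test(x, exact_max = 10)$p.value
  expect_lt(abs(p_exact - p_norm), 0.05)
  expect_equal(runs_test(x, exact_max = 10)$method, "normal approximation")
})

test_that("confidence summaries aggregate per predicted class", {
  s <- label_series(c(1, 1, 0, 0), confidences = c(1, 1, 1, 1))
  cs <- confidence_summary(s)
  expect_equal(cs$summary$mean, c(1, 1))
  s2 <- label_series(c(1, 1, 0), confidences = c(0.8, 1.0, 0.7))
  cs2 <- confidence_summary(s2)
  expect_equal(cs2$summary$mean[cs2$summary$class == "reactive"], 0.9)
  expect_equal(nrow(cs2$values), 3L)
  expect_error(confidence_summary(label_series(c(1, 0))),
               class = "lapnet_contract")
  expect_error(label_series(c(1, 0), confidences = c(0.2, 0.9)),
               class = "lapnet_validation")
})

test_that("single-component fits are the closed-form mean and MLE sd", {
  set.seed(6)
  x <- rnorm(400, 5, 0.3)
  fit <- fit_distance_mixture(x, k = 1)
  expect_equal(fit$means, mean(x))
  expect_equal(fit$sds, sqrt(mean((x - mean(x))^2)))
  expect_equal(fit$weights, 1)
  expect_true(fit$converged)
})

test_that("EM log-likelihood traces are monotone and beat a grid-search oracle", {
  set.seed(14)
  x <- c(rnorm(300, 2.0, 0.1), rnorm(200, 3.0, 0.12))
  fit <- fit_distance_mixture(x, k = 2, seed = 2)
  expect_true(all(diff(fit$trace) > -1e-6 * abs(fit$loglik)))
  # brute-force grid search over means/sds/weights cannot beat EM
  grid <- expand.grid(m1 = seq(1.8, 2.2, by = 0.05),
                      m2 = seq(2.8, 3.2, by = 0.05),
                      s = c(0.08, 0.1, 0.12, 0.15),
                      w = seq(0.4, 0.8, by = 0.1))
  grid_ll <- max(apply(grid, 1, function(g)
    lapnet:::mixture_loglik(x, c(g[4], 1 - g[4]), c(g[1], g[2]),
                            c(g[3], g[3]))))
  expect_gte(fit$loglik, grid_ll - 1e-6)
  # parameters land near the generator within sampling noise
  expect_lt(max(abs(fit$means - c(2, 3))), 0.05)
})

test_that("three-component recovery stays within the repeated-fit spread", {
  d <- generate_distance_series(n = 5000, seed = 9)$distance
  fit <- fit_distance_mixture(d, k = 3, seed = 1)
  expect_equal(fit$k, 3L)
  expect_true(all(abs(fit$means - c(2.71, 2.88, 3.05)) < 0.02))
  expect_true(all(abs(fit$weights - c(0.29, 0.42, 0.29)) < 0.12))
  expect_true(all(diff(fit$trace) > -1e-6 * abs(fit$loglik)))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  d <- generate_distance_series(n = 3000, seed = 17)$distance
  fit <- fit_distance_mixture(d, k = 3, seed = 1)
  mc <- mclust::Mclust(d, G = 3, modelNames = "V", verbose = FALSE)
  expect_gte(fit$loglik, mc$loglik - 0.5)
  expect_lt(max(abs(sort(fit$means) - sort(mc$parameters$mean))), 0.02)
})

test_that("degenerate components are pruned and flagged", {
  x <- c(rep(2, 60), rnorm(300, 3, 0.1))
  fit <- fit_distance_mixture(x, k = 3, seed = 2)
  expect_true(fit$pruned)
  expect_lt(fit$k, 3L)
  expect_error(fit_distance_mixture(rnorm(25), k = 3),
               class = "lapnet_contract")
})

test_that("BIC reports cover the requested component counts", {
  d <- generate_distance_series(n = 1500, seed = 8)$distance
  bic <- mixture_bic(d, k_values = 1:3, seed = 1, restarts = 4)
  expect_equal(bic$k, 1:3)
  expect_true(all(is.finite(bic$bic)))
})

test_that("trajectory reports bundle the headline statistics", {
  s <- generate_label_series(400, 0.5, mean_run = 4, seed = 2)
  s$confidence <- runif(400, 0.9, 1)
  d <- generate_distance_series(n = 600, seed = 3)$distance
  rep <- trajectory_report(s, d, k = 3, seed = 1)
  expect_equal(rep$n_frames, 400L)
  expect_true(rep$reactive_fraction > 0 && rep$reactive_fraction < 1)
  expect_true(all(c("runs", "p_value", "verdict") %in% names(rep$runs_test)))
  expect_equal(length(rep$distance_mixture$means), 3L)
  # CSV round-trips
  p <- withr::local_tempfile(fileext = ".csv")
  write_label_series(s, p)
  s2 <- read_label_series(p)
  expect_equal(s2$label, s$label)
  expect_equal(s2$confidence, s$confidence, tolerance = 1e-12)
})
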