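test_that("prior sampling is seeded and has the right moments", {
  e1 <- sample_prior(2, 50000, prior_spec(sigma = 2), seed = 5)
  e2 <- sample_prior(2, 50000, prior_spec(sigma = 2), seed = 5)
  expect_identical(e1$draws, e2$draws)
  expect_lt(max(abs(colMeans(e1$draws))), 3 * 2 / sqrt(50000))
  expect_equal(unname(apply(e1$draws, 2, var)), c(4, 4), tolerance = 0.05)
  expect_error(sample_prior(2, 0), "n >= 1")
  expect_error(prior_spec(sigma = -1), "positive")
})

test_that("the posterior with no evidence is the prior", {
  post <- posterior(
    bind_events(choice_event("a", one_hot_options("only"), "only"))[0, ] |>
      choice_data(),
    n = 1000, seed = 2
  )
  expect_equal(post$log_weights, rep(0, 1000))
  expect_equal(post$ess, 1000)
})

test_that("forced sampling (100% box) leaves utilities at the prior", {
  sc <- kushnir_scenario(100)
  post <- posterior(sc$data, n = 20000, seed = 3, ess_warn = 0)
  # moment-matched Gaussian symmetrized KL between weighted and unweighted
  # marginals; uninformative events should leave it at zero
  skl <- vapply(seq_along(post$features), function(j) {
    x <- post$draws[, j]
    p <- exp(post$log_weights - max(post$log_weights))
    p <- p / sum(p)
    m1 <- sum(p * x); v1 <- sum(p * (x - m1)^2)
    m0 <- mean(x); v0 <- var(x)
    0.5 * ((v1 / v0 + v0 / v1 - 2) + (m1 - m0)^2 * (1 / v0 + 1 / v1)) / 2
  }, numeric(1))
  expect_lt(max(skl), 0.01)
})

test_that("rarer targets give stronger inferred preferences", {
  p18 <- posterior(kushnir_scenario(18)$data, n = 50000, seed = 7, ess_warn = 0)
  p50 <- posterior(kushnir_scenario(50)$data, n = 50000, seed = 7, ess_warn = 0)
  expect_gt(posterior_mean(p18)["target"], posterior_mean(p50)["target"])
})

test_that("importance sampling agrees with the grid quadrature oracle", {
  opts <- one_hot_options(c("x", "y"))
  data <- bind_events(
    repeat_events("a", opts, "x", 5),
    repeat_events("a", opts, "y", 2)
  )
  pg <- posterior(data, method = "grid")
  pi <- posterior(data, n = 50000, seed = 13, ess_warn = 0)
  # combined MC standard error of the weighted mean per coordinate
  p <- exp(pi$log_weights - max(pi$log_weights))
  p <- p / sum(p)
  for (j in 1:2) {
    mu_i <- sum(p * pi$draws[, j])
    se <- sqrt(sum(p^2 * (pi$draws[, j] - mu_i)^2))
    expect_lt(abs(mu_i - posterior_mean(pg)[j]), 3 * se + 1e-3)
  }
  # evidence agrees too
  expect_equal(pi$log_evidence, pg$log_evidence, tolerance = 0.02)
  pred_g <- predictive_choice(pg, opts)
  pred_i <- predictive_choice(pi, opts)
  expect_lt(abs(pred_g$prob[1] - pred_i$prob[1]),
            3 * sqrt(pred_i$se[1]^2 + pred_g$se[1]^2) + 1e-3)
  expect_error(posterior(kushnir_scenario(50, opt_out = TRUE)$data,
                         method = "grid"), "d <= 3")
})

test_that("predictive choice is exchangeable over never-observed options", {
  post <- sample_prior(c("u", "v", "z"), 30000, seed = 9)
  pred <- predictive_choice(post, one_hot_options(c("u", "v", "z")))
  expect_equal(sum(pred$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(pred$prob - 1 / 3) < 3 * pred$se + 1e-3))
  pred_max <- predictive_choice(post, one_hot_options(c("u", "v", "z")),
                                rule = "max")
  expect_true(all(abs(pred_max$prob - 1 / 3) < 3 * pred_max$se + 1e-3))
  expect_error(predictive_choice(post, one_hot_options(character(0))), "empty")
})

test_that("a low effective sample size triggers a warning", {
  opts <- one_hot_options(c("x", "y"))
  data <- repeat_events("a", opts, "x", 40)
  expect_warning(posterior(data, n = 200, seed = 1), "effective sample size")
})

test_that("offer predictions are insensitive to the prior scale", {
  for (cond in c(100, 50, 18)) {
    p <- vapply(c(0.5, 1, 2), function(s) {
      pred <- kushnir_predict(cond, prior = prior_spec(s), n = 30000, seed = 11)
      pred$prob[pred$option == "target"]
    }, numeric(1))
    expect_lt(diff(range(p)), 0.06)
  }
})

test_that("tidy and glance summarize an ensemble", {
  post <- posterior(kushnir_scenario(18)$data, n = 5000, seed = 4, ess_warn = 0)
  td <- tidy(post)
  expect_equal(td$term, c("target", "alternative", "distractor"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(post)
  expect_equal(gl$n_draws, 5000)
  expect_true(is.finite(gl$log_evidence))
  expect_s3_class(autoplot(post), "ggplot")
})
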