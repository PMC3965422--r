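test_that("one symmetric two-option event has marginal likelihood 1/2", {
  opts <- one_hot_options(c("a", "b"))
  d <- bind_events(choice_event("kid", opts, "a"))
  for (m in c("shared", "individual")) {
    ml <- log_marginal_likelihood(d, m, n = 50000, seed = 21)
    expect_lt(abs(ml$log_ml - log(0.5)), 3 * ml$mc_se)
  }
})

test_that("the individual model decomposes over agents", {
  w <- c(f1 = 1, f2 = -1)
  data <- generate_dataset(population_spec(
    list(a = w, b = -w, c = 2 * w), baseline_pool(),
    options_per_event = 2, events_per_agent = 8, seed = 22
  ))
  whole <- log_marginal_likelihood(data, "individual", n = 3000, seed = 23)
  parts <- vapply(c("a", "b", "c"), function(ag) {
    sub <- choice_data(dplyr::filter(data, .data$agent == ag))
    log_marginal_likelihood(sub, "individual", n = 3000, seed = 23)$log_ml
  }, numeric(1))
  expect_equal(whole$log_ml, sum(parts), tolerance = 1e-10)
})

test_that("the shared-model estimate matches a dense 1-D quadrature", {
  opts <- tibble::tibble(option = c("x", "null"), multiplicity = 1,
                         fx = c(1, 0))
  d <- bind_events(
    choice_event("a", opts, "x", 1),
    choice_event("a", opts, "x", 2),
    choice_event("a", opts, "null", 3)
  )
  ml <- log_marginal_likelihood(d, "shared", n = 50000, seed = 24)
  oracle <- log(stats::integrate(function(w) {
    stats::plogis(w)^2 * (1 - stats::plogis(w)) * stats::dnorm(w)
  }, -10, 10)$value)
  expect_lt(abs(ml$log_ml - oracle), 3 * ml$mc_se)
})

test_that("with no data the model posterior equals its prior", {
  mp <- model_posterior(bind_events(), prior_m1 = 0.3, n = 100, seed = 1)
  expect_equal(mp$posterior_m1, 0.3)
  expect_equal(mp$posterior_m1 + mp$posterior_m2, 1)
  expect_error(model_posterior(bind_events(), prior_m1 = 1), "strictly")
})

test_that("shared-preference data raise the shared model's posterior", {
  w <- c(f1 = 1, f2 = -1)
  data <- generate_dataset(population_spec(
    list(a = w, b = w, c = w), baseline_pool(),
    options_per_event = 2, events_per_agent = 20, seed = 25
  ))
  mp <- model_posterior(data, prior_m1 = 0.5, n = 4000, seed = 26)
  expect_gt(mp$posterior_m1, 0.5)
})

test_that("strongly heterogeneous agents overwhelm the simpler model", {
  w <- c(f1 = 1, f2 = -1)
  data <- generate_dataset(population_spec(
    list(a = w + 2, b = w - 2, c = w + c(2, -2)), baseline_pool(),
    options_per_event = 2, events_per_agent = 100, seed = 27
  ))
  mp <- model_posterior(data, prior_m1 = 0.5, n = 4000, seed = 28)
  expect_gt(mp$posterior_m2, 0.9)
})

test_that("Occam's razor favors the shared model across replicates", {
  w <- c(f1 = 1, f2 = -1)
  lbf <- vapply(1:15, function(r) {
    data <- generate_dataset(population_spec(
      list(a = w, b = w, c = w), baseline_pool(),
      options_per_event = 2, events_per_agent = 10, seed = 100 + r
    ))
    mp <- model_posterior(data, prior_m1 = 0.5, n = 2000, seed = 200 + r)
    mp$log_ml_m1 - mp$log_ml_m2
  }, numeric(1))
  expect_gt(mean(lbf), 0)
})

test_that("more heterogeneous data never favor the individual model less", {
  w <- c(f1 = 1, f2 = -1)
  med_m2 <- vapply(c(25, 250), function(n_ev) {
    p2 <- vapply(1:5, function(r) {
      data <- generate_dataset(population_spec(
        list(a = w + 1.5, b = w - 1.5), baseline_pool(),
        options_per_event = 2, events_per_agent = n_ev, seed = 300 + r
      ))
      model_posterior(data, prior_m1 = 0.5, n = 2000,
                      seed = 400 + r)$posterior_m2
    }, numeric(1))
    median(p2)
  }, numeric(1))
  expect_gte(med_m2[2], med_m2[1])
})

test_that("next-choice prediction mixes the two models exactly", {
  world <- repacholi_world()
  data <- repacholi_simulate(world, n_background = 5, seed = 31)
  mixed <- predict_next_choice(data, "actor", world$offer, prior_m1 = 0.6,
                               n = 1500, seed = 32)
  only1 <- predict_next_choice(data, "actor", world$offer, prior_m1 = 1,
                               n = 1500, seed = 32)
  only2 <- predict_next_choice(data, "actor", world$offer, prior_m1 = 0,
                               n = 1500, seed = 32)
  pm1 <- mixed$posterior_m1[1]
  expect_equal(mixed$prob,
               pm1 * only1$prob + (1 - pm1) * only2$prob,
               tolerance = 1e-12)
  expect_equal(sum(mixed$prob), 1, tolerance = 1e-12)
})

test_that("pinned models reproduce the two developmental response patterns", {
  world <- repacholi_world()
  data <- repacholi_simulate(world, n_background = 20, seed = 33)
  # shared model only: dominated by the child's own cracker preference
  p1 <- predict_next_choice(data, "actor", world$offer, prior_m1 = 1,
                            n = 2000, seed = 34)
  expect_gt(p1$prob[p1$option == "cracker"], 0.5)
  # individual model only: reflects the actor's broccoli demonstration
  p2 <- predict_next_choice(data, "actor", world$offer, prior_m1 = 0,
                            n = 2000, seed = 34)
  expect_gt(p2$prob[p2$option == "broccoli"], 0.5)
})

test_that("model comparison tidiers are Bayes-consistent", {
  w <- c(f1 = 1, f2 = -1)
  data <- generate_dataset(population_spec(
    list(a = w, b = w), baseline_pool(), 2, 10, seed = 35
  ))
  mp <- model_posterior(data, prior_m1 = 0.7, n = 1000, seed = 36)
  td <- tidy(mp)
  expect_equal(sum(td$posterior), 1, tolerance = 1e-12)
  lo <- log(0.7 / 0.3) + mp$log_ml_m1 - mp$log_ml_m2
  expect_equal(td$posterior[1], stats::plogis(lo), tolerance = 1e-12)
  expect_equal(glance(mp)$log_bayes_factor, mp$log_ml_m1 - mp$log_ml_m2)
  expect_s3_class(autoplot(mp), "ggplot")
})
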