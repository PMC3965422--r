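test_that("category models validate their feature partition", {
  expect_error(category_model(list(a = 1:2, b = 2:3)), "partition")
  cm <- category_model(list(a = 1:2, b = 3:4), shared = 5:6,
                       feature_rate = 0.25)
  expect_equal(cm$d, 6)
  expect_error(sample_category_objects(cm, "zzz", 10), "unknown category")
})

test_that("category sampling respects blocks and the feature rate", {
  cm <- category_model(list(a = 1:2, b = 3:4), shared = 5:6)
  off <- sample_category_objects(category_model(list(a = 1:2, b = 3:4), 5:6,
                                                feature_rate = 0), "a", 50)
  expect_true(all(off == 0))
  on <- sample_category_objects(category_model(list(a = 1:2, b = 3:4), 5:6,
                                               feature_rate = 1), "a", 50)
  expect_true(all(on[, c(1, 2, 5, 6)] == 1))
  expect_true(all(on[, 3:4] == 0))
  half <- sample_category_objects(cm, "a", 10000, seed = 8)
  rates <- colMeans(half)
  expect_true(all(abs(rates[c(1, 2, 5, 6)] - 0.5) < 3 * sqrt(0.25 / 10000)))
  expect_true(all(rates[3:4] == 0))
})

test_that("no reaction leaves the hidden object at the category prior", {
  cm <- default_category_model()
  post <- sample_prior(cm$features, 5000, seed = 41)
  h <- hidden_object_posterior(post, "none", cm, "trained", n = 20000,
                               seed = 42)
  rates <- colMeans(h$feature_samples)
  active <- c(cm$blocks$trained, cm$shared)
  expect_true(all(abs(rates[active] - 0.5) < 3 * sqrt(0.25 / 20000) + 0.01))
  expect_equal(h$acceptance, 1)
})

test_that("a dislike reaction screens the utility below zero", {
  cm <- default_category_model()
  tr <- fawcett_training("4of4", cm, seed = 43)
  post <- posterior(tr$actor1, n = 10000, seed = 44, ess_warn = 0)
  h_none <- hidden_object_posterior(post, "none", cm, "trained",
                                    n = 20000, seed = 45)
  h_dis <- hidden_object_posterior(post, "dislike", cm, "trained",
                                   n = 20000, seed = 45)
  u <- function(h) mean(rowSums(h$actor_samples * h$feature_samples))
  expect_lt(u(h_dis), 0)
  expect_lt(u(h_dis), u(h_none))
})

test_that("a favorite constraint with an empty comparison pool is vacuous", {
  cm <- default_category_model()
  post <- sample_prior(cm$features, 2000, seed = 46)
  h0 <- hidden_object_posterior(post, "favorite", cm, "trained",
                                n = 5000, seed = 47, n_candidates = 0)
  hn <- hidden_object_posterior(post, "none", cm, "trained",
                                n = 5000, seed = 47)
  expect_identical(h0$feature_samples, hn$feature_samples)
  # and with candidates it concentrates on liked features
  h10 <- hidden_object_posterior(post, "favorite", cm, "trained",
                                 n = 20000, seed = 47, n_candidates = 10)
  expect_lt(h10$acceptance, 0.5)
  u <- function(h) mean(rowSums(h$actor_samples * h$feature_samples))
  expect_gt(u(h10), u(hn))
})

test_that("an unsatisfiable constraint asks for more draws", {
  cm <- category_model(list(a = 1), feature_rate = 1)
  happy <- sample_prior("f1", 100, prior_spec(sigma = 0.01, mean = 10),
                        seed = 1)
  expect_error(
    hidden_object_posterior(happy, "dislike", cm, "a", n = 500, seed = 48),
    "never satisfied"
  )
})

test_that("symmetric information predicts indifference between hidden objects", {
  cm <- default_category_model()
  post <- sample_prior(cm$features, 5000, seed = 49)
  h1 <- hidden_object_posterior(post, "none", cm, "trained", n = 5000, seed = 50)
  h2 <- hidden_object_posterior(post, "none", cm, "trained", n = 5000, seed = 51)
  child <- sample_prior(cm$features, 5000, seed = 52)
  pred <- predict_hidden_choice(child, h1, h2, n = 20000, seed = 53)
  expect_lt(abs(pred$prob - 0.5), 3 * pred$se + 0.01)
})

test_that("without shared features nothing transfers across categories", {
  pred <- fawcett_predict("positive", "different", "4of4",
                          n = 5000, seed = 54,
                          cat = default_category_model(shared_k = 0),
                          n_hidden = 8000)
  expect_lt(abs(pred$prob - 0.5), 0.02)
})

test_that("shared features open a monotone transfer pathway", {
  dev <- vapply(c(0, 2, 4), function(k) {
    p <- fawcett_predict("positive", "different", "4of4",
                         n = 5000, seed = 55,
                         cat = default_category_model(shared_k = k),
                         n_hidden = 8000)
    abs(p$prob - 0.5)
  }, numeric(1))
  expect_gte(dev[2], dev[1] - 0.02)
  expect_gte(dev[3], dev[2] - 0.02)
  expect_gt(dev[3], dev[1])
})
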