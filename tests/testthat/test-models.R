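# Simulated fish-season datasets for model-fitting checks. Fixed effects are
# planted on the link scale; fish get Gaussian random intercepts.
sim_poisson_data <- function(n_fish = 50, per_fish = 8, season_beta = 0,
                             intercept = 1, re_sd = 0.3, seed = 1) {
  set.seed(seed)
  fish <- sprintf("F%03d", seq_len(n_fish))
  re <- rnorm(n_fish, 0, re_sd)
  d <- expand.grid(fish = fish, rep = seq_len(per_fish),
                   stringsAsFactors = FALSE)
  d$season <- sample(c("winter", "spring", "summer", "fall"), nrow(d), TRUE)
  eta <- intercept + season_beta * (d$season == "fall") +
    re[match(d$fish, fish)]
  d$y <- rpois(nrow(d), exp(eta))
  d
}

test_that("intercept-only poisson recovers log of a constant response", {
  d <- data.frame(fish = rep(sprintf("F%02d", 1:10), each = 4), y = 3)
  spec <- model_spec("y", "poisson", fixed = character(), random = "fish")
  fit <- fit_behaviour_model(spec, d)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients$estimate[1]), log(3),
               tolerance = 0.01)
  # response-scale prediction with random effects at zero
  expect_equal(predict_effects(fit, data.frame(row = 1)), 3, tolerance = 0.01)
})

test_that("parsimony-within-2 rule follows the printed examples", {
  # fewest parameters within 2 AIC units wins
  expect_equal(select_by_parsimony(c(100.0, 101.5), c(5, 3)), 2L)
  # outside the window the best-AIC model stands
  expect_equal(select_by_parsimony(c(100.0, 102.5), c(5, 3)), 1L)
  # single candidate -> itself
  expect_equal(select_by_parsimony(107.3, 4), 1L)
  # ties on parameter count -> lower AIC
  expect_equal(select_by_parsimony(c(100.0, 101.5, 101.0), c(5, 3, 3)), 3L)
  # non-finite candidates are excluded
  expect_equal(select_by_parsimony(c(Inf, 101.5), c(2, 3)), 2L)
  expect_error(select_by_parsimony(c(Inf, Inf), c(2, 3)), "no convergent")
})

test_that("fixed-effect subsets respect the interaction constraint", {
  subsets <- all_fixed_subsets(c("origin", "season", "origin:season"))
  expect_equal(length(subsets), 5L)  # {}, {o}, {s}, {o,s}, {o,s,o:s}
  has_int <- vapply(subsets, function(s) "origin:season" %in% s, logical(1))
  for (s in subsets[has_int])
    expect_true(all(c("origin", "season") %in% s))
  expect_error(model_spec("y", "poisson", fixed = c("origin:season")),
               "both main effects")
})

test_that("selection drops a null effect and keeps a planted one", {
  d <- sim_poisson_data(n_fish = 60, per_fish = 8, season_beta = 0.8,
                        seed = 4)
  d$origin <- sample(c("stocked", "wild"), nrow(d), TRUE)  # null effect
  spec <- model_spec("y", "poisson", fixed = c("origin", "season"),
                     random = "fish")
  sel <- select_behaviour_model(spec, d)
  expect_true("season" %in% sel$best$fixed)
  expect_false("origin" %in% sel$best$fixed)
  # the selected AIC is within the window of the minimum
  expect_lte(sel$best$aic, min(sel$table$aic[is.finite(sel$table$aic)]) + 2)
  # selection is reproducible
  sel2 <- select_behaviour_model(spec, d)
  expect_equal(sel2$best$fixed, sel$best$fixed)
  expect_equal(sel2$best$aic, sel$best$aic)
})

test_that("beta mixed model recovers a planted logit mean", {
  set.seed(9)
  n_fish <- 50; per_fish <- 10
  fish <- sprintf("F%03d", seq_len(n_fish))
  re <- rnorm(n_fish, 0, 0.2)
  d <- expand.grid(fish = fish, rep = seq_len(per_fish),
                   stringsAsFactors = FALSE)
  mu <- plogis(1.0 + re[match(d$fish, fish)])
  phi <- 20
  d$y <- rbeta(nrow(d), mu * phi, (1 - mu) * phi)
  spec <- model_spec("y", "beta", fixed = character(), random = "fish")
  fit <- fit_behaviour_model(spec, d)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients$estimate[1]), 1.0, tolerance = 0.15)
})

test_that("lognormal and tweedie families fit and predict sensibly", {
  set.seed(12)
  d <- sim_poisson_data(n_fish = 40, per_fish = 6, seed = 12)
  d$dist <- exp(rnorm(nrow(d), log(2), 0.4))          # positive distances
  spec_ln <- model_spec("dist", "lognormal", fixed = character(),
                        random = "fish")
  fit_ln <- fit_behaviour_model(spec_ln, d)
  expect_true(fit_ln$converged)
  # exp(mu-hat) close to the lognormal median 2
  expect_equal(predict_effects(fit_ln, data.frame(row = 1)), 2,
               tolerance = 0.15)

  d$zi <- d$dist * rbinom(nrow(d), 1, 0.7)            # zero-inflated
  spec_tw <- model_spec("zi", "tweedie", fixed = character(),
                        random = "fish")
  fit_tw <- fit_behaviour_model(spec_tw, d)
  expect_true(fit_tw$converged)
  expect_equal(predict_effects(fit_tw, data.frame(row = 1)),
               mean(d$zi), tolerance = 0.15)
})

test_that("two-level contrasts equal the unadjusted z-test", {
  d <- sim_poisson_data(n_fish = 40, per_fish = 6, seed = 3)
  d$origin <- sample(c("stocked", "wild"), nrow(d), TRUE)
  spec <- model_spec("y", "poisson", fixed = "origin", random = "fish")
  fit <- fit_behaviour_model(spec, d)
  ct <- marginal_contrasts(fit, "origin")
  expect_equal(nrow(ct$contrasts), 1L)
  z <- ct$contrasts$z
  expect_equal(ct$contrasts$p_adjusted, 2 * pnorm(-abs(z)),
               tolerance = 1e-6)
})

test_that("a planted large fall effect is detected by Tukey contrasts", {
  d <- sim_poisson_data(n_fish = 60, per_fish = 8, season_beta = 1.2,
                        seed = 8)
  spec <- model_spec("y", "poisson", fixed = "season", random = "fish")
  fit <- fit_behaviour_model(spec, d)
  ct <- marginal_contrasts(fit, "season")
  expect_equal(nrow(ct$contrasts), choose(4, 2))
  fall_rows <- grepl("fall", ct$contrasts$pair)
  expect_true(all(ct$contrasts$significant[fall_rows]))
  expect_true(all(ct$contrasts$p_adjusted >= 0 &
                    ct$contrasts$p_adjusted <= 1))
})

test_that("predictions are monotone along a planted length effect", {
  set.seed(21)
  d <- sim_poisson_data(n_fish = 40, per_fish = 6, seed = 21)
  d$length_mm <- runif(nrow(d), 300, 800)
  d$y <- rpois(nrow(d), exp(0.5 + 0.002 * d$length_mm))
  spec <- model_spec("y", "poisson", fixed = "length_mm", random = "fish")
  fit <- fit_behaviour_model(spec, d)
  grid <- data.frame(length_mm = seq(300, 800, by = 100))
  pred <- predict_effects(fit, grid)
  expect_true(all(diff(pred) > 0))
  # unseen factor level guard
  d$origin <- factor(sample(c("stocked", "wild"), nrow(d), TRUE))
  spec2 <- model_spec("y", "poisson", fixed = "origin", random = "fish")
  fit2 <- fit_behaviour_model(spec2, d)
  expect_error(predict_effects(fit2, data.frame(origin = "hybrid")),
               "unseen")
})

test_that("numeric random effects are binned before fitting", {
  d <- sim_poisson_data(n_fish = 30, per_fish = 6, seed = 14)
  d$days_positions <- runif(nrow(d), 1, 90)
  spec <- model_spec("y", "poisson", fixed = character(),
                     random = c("fish", "days_positions"))
  fit <- fit_behaviour_model(spec, d)
  expect_true(fit$converged)
  expect_true(is.factor(fit$data$days_positions))
  expect_lte(nlevels(fit$data$days_positions), 5L)
})
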