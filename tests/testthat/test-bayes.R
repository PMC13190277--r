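# a hand-made posterior_summary for exercising the EMM machinery without MCMC
fake_posterior <- function(draws, formula, grid, transform = "identity") {
  trm <- terms(formula)
  structure(list(
    draws = draws, coef_names = colnames(draws),
    spec = list(transform = transform, random_slope = FALSE),
    make_X = function(nd) model.matrix(trm, nd),
    grid = grid, chains = 1, iterations = nrow(draws), warmup = 0,
    n_draws = nrow(draws)), class = "posterior_summary")
}

test_that("draw accounting multiplies out the sampling protocol", {
  expect_equal(post_warmup_draws(4, 50000, 10000), 160000)
  expect_equal(post_warmup_draws(4, 2000, 500), 6000)
  expect_error(post_warmup_draws(4, 1000, 1000))
})

test_that("evidence-ratio categories map the published cut-offs", {
  expect_equal(bf_category(c(0.3, 1, 1.16, 3, 9.52, 10, 15.1, 100, 100.01)),
               c("none", "none", "anecdotal", "anecdotal", "moderate",
                 "moderate", "strong", "strong", "extreme"))
})

test_that("directional evidence ratios count draws on the hypothesised side", {
  h <- directional_bf(c(-1, -2, -3, 1), "<")
  expect_equal(h$posterior_prob, 0.75)
  expect_equal(h$evidence_ratio, 3.0)
  expect_equal(h$bf_category, "anecdotal")   # boundary belongs to the lower band
  expect_false(h$capped)
  # symmetric draws: evidence ratio near 1
  set.seed(21)
  sym <- c(rnorm(5000), -rnorm(5000))
  hs <- directional_bf(sym, ">")
  expect_equal(hs$evidence_ratio, 1, tolerance = 0.05)
  # all draws on one side: capped at the draw count
  hc <- directional_bf(c(-1, -2, -0.5), "<")
  expect_true(hc$capped)
  expect_equal(hc$evidence_ratio, Inf)
  expect_equal(hc$n_draws, 3)
})

test_that("opposite directions have reciprocal evidence ratios", {
  set.seed(22)
  for (k in 1:100) {
    draws <- rnorm(400, mean = runif(1, -1, 1))
    lt <- directional_bf(draws, "<")
    gt <- directional_bf(draws, ">")
    if (!lt$capped && !gt$capped)
      expect_equal(lt$evidence_ratio * gt$evidence_ratio, 1,
                   tolerance = 1e-9)
  }
})

test_that("EMM grid averaging matches a hand computation on fixed draws", {
  grid <- expand.grid(group = c("sham", "stroke"),
                      hemisphere = c("contralesional", "ipsilesional"))
  set.seed(23)
  draws <- matrix(rnorm(10 * 4), 10, 4)
  colnames(draws) <- c("(Intercept)", "groupstroke",
                       "hemisphereipsilesional",
                       "groupstroke:hemisphereipsilesional")
  post <- fake_posterior(draws, ~ group * hemisphere, grid,
                         transform = "log")
  emm <- emmeans_posterior(post, by = "group")
  # hand computation: sham = b0 + b_hemi/2; stroke adds group terms
  eta_sham <- draws[, 1] + 0.5 * draws[, 3]
  eta_stroke <- draws[, 1] + draws[, 2] + 0.5 * (draws[, 3] + draws[, 4])
  expect_equal(emm$emm_link[emm$group == "sham"], mean(eta_sham))
  expect_equal(emm$emm_link[emm$group == "stroke"], mean(eta_stroke))
  # log transform: response-scale EMM is the mean of exponentiated draws
  expect_equal(emm$emm_response[emm$group == "sham"], mean(exp(eta_sham)))
  expect_equal(unname(quantile(exp(eta_stroke), 0.05)),
               emm$resp_lo90[emm$group == "stroke"])
  # grand EMM equals the mean of the level EMMs (balanced two-level factor)
  grand <- emmeans_posterior(post, by = character())
  expect_equal(grand$emm_link, mean(c(eta_sham, eta_stroke)))
})

test_that("intercept-only EMMs reproduce the posterior intercept", {
  grid <- data.frame(group = factor(c("sham", "stroke")))
  draws <- matrix(rnorm(50), 50, 1,
                  dimnames = list(NULL, "(Intercept)"))
  post <- fake_posterior(draws, ~ 1, grid)
  emm <- emmeans_posterior(post)
  expect_equal(emm$emm_link, mean(draws))
  expect_equal(emm$emm_response, mean(draws))
})

test_that("EMM machinery agrees with the emmeans package on lm coefficients", {
  skip_if_not_installed("emmeans")
  ct <- simulate_cohort(cohort_spec(effects = c(groupstroke = -0.7,
                                                sexmale = 0.4)), seed = 24)
  fit <- lm(outcome_value ~ group * hemisphere * sex * layer, data = ct)
  draws <- matrix(coef(fit), 1, dimnames = list(NULL, names(coef(fit))))
  grid <- expand.grid(group = levels(ct$group),
                      hemisphere = levels(ct$hemisphere),
                      sex = levels(ct$sex), layer = levels(ct$layer))
  post <- fake_posterior(draws, ~ group * hemisphere * sex * layer, grid)
  for (by in list("group", "sex", c("group", "sex"))) {
    mine <- emmeans_posterior(post, by = by)
    ref <- as.data.frame(suppressMessages(
      emmeans::emmeans(fit, by)))
    expect_equal(sort(mine$emm_link), sort(ref$emmean), tolerance = 1e-9)
  }
})

test_that("back-transformed EMMs preserve the link-scale ordering", {
  grid <- expand.grid(group = c("sham", "stroke"),
                      sex = c("female", "male"))
  set.seed(25)
  draws <- matrix(rnorm(200 * 4, sd = 2), 200, 4)
  colnames(draws) <- c("(Intercept)", "groupstroke", "sexmale",
                       "groupstroke:sexmale")
  for (tr in c("log", "log1p")) {
    post <- fake_posterior(abs(draws), ~ group * sex, grid, transform = tr)
    emm <- emmeans_posterior(post, by = c("group", "sex"))
    expect_equal(order(emm$emm_link), order(emm$emm_response))
  }
})

test_that("hierarchical fit is seeded, diagnosed, and recovers a group effect", {
  ct <- simulate_cohort(cohort_spec(effects = c(groupstroke = -0.7)),
                        seed = 26)
  spec <- model_spec("ap_threshold_mV")
  post <- fit_hierarchical(ct, spec, chains = 2, iterations = 1500,
                           warmup = 400, seed = 5)
  expect_s3_class(post, "posterior_summary")
  expect_equal(post$n_draws, 2 * 1100)
  expect_true(all(c("rhat", "ess") %in% names(post$diagnostics)))
  expect_true(all(is.finite(post$diagnostics$rhat)))
  cd <- contrast_draws(post, "group", "stroke", "sham")
  ci <- quantile(cd, c(0.05, 0.95))
  expect_lt(ci[1], 0)              # effect direction detectable
  expect_lt(abs(mean(cd) - (-0.7)), 1.5)
  # reproducibility under the same seed
  post2 <- fit_hierarchical(ct, spec, chains = 2, iterations = 1500,
                            warmup = 400, seed = 5)
  expect_identical(post$draws, post2$draws)
  post3 <- fit_hierarchical(ct, spec, chains = 2, iterations = 1500,
                            warmup = 400, seed = 6)
  expect_false(identical(post$draws, post3$draws))
})

test_that("a single animal is rejected", {
  ct <- simulate_cohort(cohort_spec(), seed = 27)
  one <- ct[ct$animal_id == ct$animal_id[1], ]
  expect_error(fit_hierarchical(one, model_spec("ap_threshold_mV"),
                                chains = 1, iterations = 200, warmup = 50),
               "two animals")
})

test_that("random-intercept-only GFP model runs on sham data", {
  ct <- simulate_cohort(cohort_spec(), seed = 28)
  sham <- ct[ct$group == "sham", ]
  spec <- model_spec("ap_threshold_mV", fixed = "gfp",
                     random_slope = FALSE)
  post <- fit_hierarchical(sham, spec, chains = 2, iterations = 800,
                           warmup = 200, seed = 8)
  emm <- emmeans_posterior(post, by = "gfp")
  expect_equal(nrow(emm), 2)
  cd <- contrast_draws(post, "gfp", "positive", "negative")
  expect_length(cd, post$n_draws)
})

# synthetic saturating I-F long table with a group shift on the log1p scale
make_if_data <- function(group_shift = 0, seed = 1, n_levels = 8,
                         current_effect = TRUE) {
  ct <- simulate_cohort(cohort_spec(cells_per_stratum = 1, sd_intercept = 0.3,
                                    sd_slope = 0.1, sd_resid = 0),
                        seed = seed)
  cur <- seq(25, 500, length.out = n_levels)
  long <- merge(ct, data.frame(current_pA = cur), by = NULL)
  sat <- if (current_effect) 2.2 * (1 - exp(-long$current_pA / 150)) else 0
  eta <- 0.6 + sat + group_shift * (long$group == "stroke") +
    long$outcome_value * 0 +
    (long$outcome_value - mean(long$outcome_value)) / 50   # animal structure
  set.seed(seed + 1)
  eta <- eta + rnorm(length(eta), 0, 0.15)
  long$spike_freq_Hz <- pmax(expm1(eta), 0)
  long
}

test_that("current-adjusted model recovers a group shift and needs a current column", {
  long <- make_if_data(group_shift = -0.5, seed = 31)
  m1 <- fit_if_model(long, "current_independent", n_knots = 4, chains = 2,
                     iterations = 1000, warmup = 300, seed = 9)
  cd <- contrast_draws(m1, "group", "stroke", "sham")
  ci <- quantile(cd, c(0.05, 0.95))
  expect_gt(-0.5, ci[1] - 0.2)
  expect_lt(-0.5, ci[2] + 0.2)
  expect_lt(mean(cd), 0)
  bad <- long[, setdiff(names(long), "current_pA")]
  expect_error(fit_if_model(bad), "current_pA")
})

test_that("spline basis coefficients stay near zero without a current effect", {
  long <- make_if_data(group_shift = 0, seed = 32, current_effect = FALSE)
  m1 <- fit_if_model(long, "current_independent", n_knots = 4, chains = 2,
                     iterations = 1000, warmup = 300, seed = 10)
  basis_cols <- grep("^current", m1$coef_names, value = TRUE)
  for (bc in basis_cols) {
    ci <- quantile(m1$draws[, bc], c(0.05, 0.95))
    expect_true(ci[1] < 0 && ci[2] > 0 ||
                  max(abs(ci)) < 0.01)   # tight near zero
  }
})

test_that("model comparison prefers the generating structure and detects ties", {
  long <- make_if_data(group_shift = -0.4, seed = 33)
  m1 <- fit_if_model(long, "current_independent", n_knots = 4, chains = 2,
                     iterations = 1000, warmup = 300, seed = 11)
  m2 <- fit_if_model(long, "current_dependent", chains = 2,
                     iterations = 1000, warmup = 300, seed = 11)
  cmp <- compare_if_models(m1, m2)
  expect_true(cmp$preferred %in% c("m1", "indeterminate"))
  # identical models: indeterminate by construction
  cmp_same <- compare_if_models(m1, m1)
  expect_equal(cmp_same$preferred, "indeterminate")
  expect_equal(cmp_same$elpd_diff, 0)
  # mismatched outcomes are an error
  long2 <- make_if_data(group_shift = 0.8, seed = 34)
  m3 <- fit_if_model(long2, "current_independent", n_knots = 4, chains = 2,
                     iterations = 600, warmup = 200, seed = 12)
  expect_error(compare_if_models(m1, m3), "different outcomes")
})
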