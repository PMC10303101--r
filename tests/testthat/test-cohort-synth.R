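test_that("default study spec carries the full published panel", {
  spec <- default_study_spec()
  m <- spec$marginals

  expect_equal(sum(m$role == "element"), 31)
  expect_equal(spec$n, 95)
  expect_equal(sum(m$role %in% c("clinical", "derived")), 25)

  ba <- m[m$name == "Ba", ]
  expect_equal(ba$mean, 1.29)
  expect_equal(ba$sd, 1.63)
  expect_equal(c(ba$min, ba$max), c(0.04, 11.00))

  bmi <- m[m$name == "bmi", ]
  expect_equal(c(bmi$mean, bmi$sd), c(32.7, 5.7))

  # auxiliary variables needed by the index formulas are present
  expect_true(all(c("hdl", "ggt", "sex", "age") %in% m$name))
})

test_that("lognormal moment inversion is exact (analytic oracle)", {
  # closed-form lognormal moments as the oracle
  ln_mean <- function(mu, sigma) exp(mu + sigma^2 / 2)
  ln_sd <- function(mu, sigma) sqrt((exp(sigma^2) - 1)) * ln_mean(mu, sigma)

  p <- lognormal_params_from_moments(1.29, 1.63)
  expect_equal(ln_mean(p$mu, p$sigma), 1.29, tolerance = 1e-9)
  expect_equal(ln_sd(p$mu, p$sigma), 1.63, tolerance = 1e-9)

  # standard lognormal: mean e^{1/2}, sd sqrt((e-1)e) -> (mu, sigma) = (0, 1)
  p <- lognormal_params_from_moments(exp(0.5), sqrt((exp(1) - 1) * exp(1)))
  expect_equal(p$mu, 0, tolerance = 1e-9)
  expect_equal(p$sigma, 1, tolerance = 1e-9)

  # degenerate limit: vanishing sd -> sigma -> 0, mu -> log(mean)
  p <- lognormal_params_from_moments(1.0, 1e-9)
  expect_lt(p$sigma, 1e-8)
  expect_equal(p$mu, 0, tolerance = 1e-8)

  expect_error(lognormal_params_from_moments(-1, 1), class = "autocmap_invalid_argument")
  expect_error(lognormal_params_from_moments(1, 0), class = "autocmap_invalid_argument")
})

test_that("simulation is seed-deterministic and respects truncation bounds", {
  spec <- default_study_spec()
  c1 <- simulate_cohort(spec, n = 95, seed = 7)
  c2 <- simulate_cohort(spec, n = 95, seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(simulate_cohort(spec, seed = 1)), 95)

  sampled <- spec$marginals[!spec$marginals$family %in% c("derived", "bernoulli"), ]
  for (k in seq_len(nrow(sampled))) {
    x <- c1[[sampled$name[k]]]
    expect_true(all(x >= sampled$min[k] & x <= sampled$max[k]),
                info = sampled$name[k])
  }
  expect_false(any(is.na(as.matrix(c1[, -1]))))

  expect_error(simulate_cohort(spec, n = 1, seed = 1),
               class = "autocmap_invalid_argument")
})

test_that("unknown variables in the latent structure are rejected", {
  spec <- default_study_spec()
  bad <- latent_structure(tibble::tibble(variable = "not_a_var",
                                         factor = "f", loading = 0.5))
  expect_error(simulate_cohort(spec, structure = bad, seed = 1),
               class = "autocmap_schema_error")
})

test_that("calibrated marginals recover the published element means", {
  spec <- default_study_spec()
  elements <- spec$marginals[spec$marginals$role == "element", ]
  n <- 1e5
  for (k in seq_len(nrow(elements))) {
    x <- sample_marginal(spec, elements$name[k], n, seed = 11)
    se <- elements$sd[k] / sqrt(n)
    expect_lt(abs(mean(x) - elements$mean[k]), 3 * se)
  }
})

test_that("derived indices are consistent with the sampled primitives", {
  co <- simulate_cohort(default_study_spec(), n = 50, seed = 3)
  expect_equal(co$fli, fatty_liver_index(co$tg, co$bmi, co$ggt, co$wc))
  expect_equal(co$obesity, as.integer(co$bmi > 30))
  expect_equal(co$ti,
               toxicity_index(co[, toxic_elements(), drop = FALSE]))
})

test_that("shared latent factors plant the intended correlation structure", {
  ps <- planted_spec(per_factor = 3, loading = 0.7)
  co <- simulate_cohort(ps, n = 1e4, seed = 5)
  vars <- names(ps$factor_of)
  cm <- cor(as.matrix(co[, vars]))
  same <- outer(ps$factor_of, ps$factor_of, "==") & upper.tri(cm)
  cross <- outer(ps$factor_of, ps$factor_of, "!=") & upper.tri(cm)
  expect_gt(min(cm[same]), max(cm[cross]))
})
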