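test_that("GEE matches an independent reference implementation on a frozen fixture", {
  # Expected values computed once with statsmodels' GEE (Gaussian family,
  # exchangeable covariance, robust covariance) on the identical fixture;
  # agreement was observed to ~1e-10.
  df <- make_gee_fixture()
  fit <- fit_gee(df, terms = c("neuron_type", "phase"))
  expect_equal(unname(fit$coefficients),
               c(0.2474066602, 0.0601527222, -0.0554845029), tolerance = 1e-8)
  # Mancl-DeRouen SEs against statsmodels cov_type="bias_reduced"
  expect_equal(unname(fit$robust_se),
               c(0.0071028511, 0.0107248741, 0.0111401462), tolerance = 1e-6)
  plain <- fit_gee(df, terms = c("neuron_type", "phase"), cov_type = "robust")
  expect_equal(unname(plain$robust_se),
               c(0.0044087529, 0.0066839146, 0.0070304626), tolerance = 1e-6)
  expect_lt(abs(fit$rho - -0.040827418290169434), 1e-7)
  expect_identical(fit$n_clusters, 8L)
})

test_that("one observation per cluster reduces GEE to OLS", {
  set.seed(5)
  df <- data.frame(slice_id = sprintf("s%02d", 1:30),
                   neuron_type = rep(c("AVP", "VIP"), 15),
                   delta_r = rnorm(30, 0.1, 0.05))
  fit <- fit_gee(df, terms = "neuron_type")
  ols <- lm(delta_r ~ neuron_type, df)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
})

test_that("GEE estimates are invariant to row order and cluster relabeling", {
  df <- make_gee_fixture()
  fit <- fit_gee(df, terms = c("neuron_type", "phase"))
  set.seed(8)
  df2 <- df[sample(nrow(df)), ]
  fit2 <- fit_gee(df2, terms = c("neuron_type", "phase"))
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit$robust_se, fit2$robust_se, tolerance = 1e-10)
  df3 <- df
  df3$slice_id <- paste0("zz_", df3$slice_id)
  fit3 <- fit_gee(df3, terms = c("neuron_type", "phase"))
  expect_equal(fit$coefficients, fit3$coefficients, tolerance = 1e-12)
})

test_that("GEE degenerate designs raise specific errors", {
  df <- make_gee_fixture()
  expect_error(fit_gee(df[df$slice_id == "s1", ]), "single cluster")
  df$dup <- df$neuron_type
  expect_error(fit_gee(df, terms = c("neuron_type", "dup")), "aliased")
  expect_error(fit_gee(df[df$neuron_type == "AVP", ], terms = "neuron_type"),
               "single level")
})

test_that("GEE type-I error is nominal under the clustered null world", {
  # 20 slices x 8 ROIs, slice random effect SD 0.03, ROI noise SD 0.02,
  # true effect 0; 500 seeded replicates
  set.seed(2024)
  rej <- replicate(500, {
    df <- do.call(rbind, lapply(1:20, function(i)
      data.frame(slice_id = sprintf("s%02d", i),
                 delta_r = rnorm(1, 0, 0.03) + rnorm(8, 0, 0.02))))
    fit_gee(df)$p_value[[1]] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("a true AVP/VIP contrast is recovered within 2 robust SE", {
  set.seed(99)
  hits <- replicate(60, {
    df <- do.call(rbind, lapply(1:16, function(i) {
      nt <- if (i <= 8) "AVP" else "VIP"
      data.frame(slice_id = sprintf("s%02d", i), neuron_type = nt,
                 delta_r = 0.18 + 0.10 * (nt == "VIP") +
                   rnorm(1, 0, 0.03) + rnorm(6, 0, 0.02))
    }))
    fit <- fit_gee(df, terms = "neuron_type")
    abs(fit$coefficients[["neuron_typeVIP"]] - 0.10) <=
      2 * fit$robust_se[["neuron_typeVIP"]]
  })
  expect_gte(mean(hits), 0.90)
})

test_that("exchangeable robust SEs approach OLS SEs when clustering vanishes", {
  set.seed(31)
  df <- do.call(rbind, lapply(1:50, function(i)
    data.frame(slice_id = sprintf("s%02d", i),
               delta_r = rnorm(6, 0.1, 0.02))))  # no cluster effect
  fit <- fit_gee(df)
  ols_se <- summary(lm(delta_r ~ 1, df))$coefficients[1, 2]
  expect_lt(abs(fit$robust_se[[1]] / ols_se - 1), 0.10)
  ind <- fit_gee(df, corstr = "independence")
  expect_identical(ind$rho, 0)
})

test_that("cross-solution z comparisons follow the stated arithmetic", {
  mk <- function(est, se) {
    structure(list(coefficients = c("(Intercept)" = est),
                   robust_se = c("(Intercept)" = se)), class = "gee_fit")
  }
  same <- compare_across_solutions(mk(0.1, 0.02), mk(0.1, 0.02), "(Intercept)")
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)

  cmp <- compare_across_solutions(mk(0.10, 0.02), mk(0.02, 0.02),
                                  "(Intercept)", n_comparisons = 4)
  expect_equal(cmp$z, 2.828, tolerance = 1e-3)
  expect_equal(cmp$alpha_adjusted, 0.0125)

  # antisymmetry under swapping fits
  rev <- compare_across_solutions(mk(0.02, 0.02), mk(0.10, 0.02), "(Intercept)")
  expect_equal(rev$z, -cmp$z)

  expect_error(compare_across_solutions(mk(1, 1), mk(1, 1), "phase"), "absent")
})

test_that("equal true effects rarely produce |z| > 1.96 across solutions", {
  set.seed(17)
  flags <- replicate(100, {
    mkdat <- function() do.call(rbind, lapply(1:12, function(i)
      data.frame(slice_id = sprintf("s%02d", i),
                 delta_r = 0.2 + rnorm(1, 0, 0.03) + rnorm(5, 0, 0.02))))
    fa <- fit_gee(mkdat()); fb <- fit_gee(mkdat())
    abs(compare_across_solutions(fa, fb, "(Intercept)")$z) < 1.96
  })
  expect_gte(mean(flags), 0.88)
})

test_that("paired t-test matches hand calculations and handles degeneracy", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$t, 0)

  res <- paired_t(c(0, 0, 0), c(1, 2, 3))  # differences 1,2,3: sd 1, n 3
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)

  deg <- paired_t(c(1, 1, 1), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_identical(deg$p, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("inference results serialize with coefficient and comparison tables", {
  df <- make_gee_fixture()
  fit <- fit_gee(df, terms = "neuron_type")
  fit2 <- fit_gee(transform(df, delta_r = delta_r + rnorm(nrow(df), 0, 0.01)),
                  terms = "neuron_type")
  cmp <- compare_across_solutions(fit, fit2, "neuron_typeVIP", n_comparisons = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_inference(fit, p, comparisons = list(cmp))
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_identical(obj$model$n_clusters, 8L)
  expect_identical(obj$coefficients$term, c("(Intercept)", "neuron_typeVIP"))
  expect_equal(obj$cross_model$alpha_adjusted, 0.025)
})
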