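test_that("spec construction validates the causal graph", {
  sp <- default_sem_spec()
  expect_setequal(sp$parents[["OC"]],
                  c("conductivity", "pH", "humidity", "precipitation",
                    "C3_macrothermal"))
  expect_setequal(sp$parents[["taxon"]], driver_names())
  expect_identical(soilniche:::sink_node(sp), "taxon")
  # the taxon node is terminal: feeding it back creates a cycle
  edges <- rbind(sp$edges, data.frame(parent = "taxon", child = "pH"))
  expect_error(sem_spec(edges, exogenous = sp$exogenous), "exogenous|cycle")
  cyc <- data.frame(parent = c("a", "b"), child = c("b", "a"))
  expect_error(sem_spec(cyc, exogenous = character(0)), "cycle")
  # free-parameter counting on a two-variable model: 1 path + 1 residual
  # variance + 1 exogenous variance
  two <- sem_spec(data.frame(parent = "x", child = "y"), exogenous = "x")
  expect_equal(soilniche:::n_free_params(two), 3)
  expect_identical(build_spec(NULL)$edges, sp$edges)
  expect_equal(nrow(tidy(sp)), 23)
})

test_that("a saturated model reproduces S and hits the perfect-fit indices", {
  d <- small_sim(500, seed = 4)
  # x -> y alone is saturated for two variables: df = 0, S = implied
  two <- sem_spec(data.frame(parent = "x", child = "y"), exogenous = "x")
  f <- fit_sem(data.frame(x = d$x1, y = d$y1), two)
  expect_equal(f$indices$df, 0)
  expect_equal(f$indices$chi2, 0, tolerance = 1e-8)
  expect_equal(f$indices$cfi, 1)
  expect_equal(f$indices$rmsea, 0)
  expect_equal(f$indices$srmr, 0, tolerance = 1e-8)
  expect_equal(unname(f$sigma_hat), unname(f$S), tolerance = 1e-10)
  # identity S = implied covariance gives ideal indices for any model
  full <- fit_sem(d, small_spec())
  id <- soilniche:::fit_indices(full$sigma_hat, full$sigma_hat, full$n,
                                soilniche:::n_free_params(small_spec()))
  expect_equal(id$chi2, 0, tolerance = 1e-8)
  expect_equal(id$cfi, 1)
  expect_equal(id$rmsea, 0)
  expect_equal(id$srmr, 0, tolerance = 1e-10)
})

test_that("equation-wise estimates minimize the ML discrepancy", {
  d <- small_sim(2000, seed = 7)
  f <- fit_sem(d, small_spec())
  oracle <- small_fml_oracle(f$S)
  est <- setNames(f$coefficients$estimate,
                  paste(f$coefficients$child, f$coefficients$parent))
  expect_equal(unname(est["y1 x1"]), oracle$par[1], tolerance = 1e-4)
  expect_equal(unname(est["y1 x2"]), oracle$par[2], tolerance = 1e-4)
  expect_equal(unname(est["y2 y1"]), oracle$par[3], tolerance = 1e-4)
  expect_equal(unname(est["y2 x2"]), oracle$par[4], tolerance = 1e-4)
  # and the package's own F_ML at its estimates is no worse than the
  # brute-force minimum
  expect_lte(f$indices$f_ml, oracle$value + 1e-6)
})

test_that("standardization identity recovers unstandardized coefficients", {
  d <- small_sim(300, seed = 9)
  f <- fit_sem(d, small_spec())
  back <- f$coefficients$std_estimate *
    f$sds[f$coefficients$child] / f$sds[f$coefficients$parent]
  expect_equal(unname(back), f$coefficients$estimate, tolerance = 1e-10)
})

test_that("conditional prediction uses parents only and matches OLS", {
  cfg <- default_generator_config(n_samples = 400, seed = 2)
  ds <- generate_dataset(cfg)
  d <- dplyr::bind_cols(ds$env,
                        taxon = as.numeric(abund_matrix(ds$abundances)))
  sp <- default_sem_spec()
  f <- fit_sem(d, sp)
  pred <- predict_conditional(f, d)
  # independent regression oracle
  ols <- lm(taxon ~ MAT + humidity + precipitation + C3_macrothermal +
              C3_mesothermal + C4_megathermal + OC + conductivity + pH,
            data = d)
  expect_equal(pred, unname(fitted(ols)), tolerance = 1e-9)
  # permuting the taxon column changes nothing
  d2 <- d
  d2$taxon <- sample(d2$taxon)
  expect_equal(predict_conditional(f, d2), pred)
  expect_error(predict_conditional(f, d[, 1:3]), "missing parent")
  # (near-)noise-free world: predictions recover observations; exactly
  # noise-free is degenerate (singular implied covariance) and refused
  cfg0 <- cfg
  cfg0$residual_sds["taxon"] <- 1e-7
  ds0 <- generate_dataset(cfg0)
  d0 <- dplyr::bind_cols(ds0$env,
                         taxon = as.numeric(abund_matrix(ds0$abundances)))
  f0 <- fit_sem(d0, sp)
  expect_equal(predict_conditional(f0, d0), d0$taxon, tolerance = 1e-5)
  cfg00 <- cfg
  cfg00$residual_sds["taxon"] <- 0
  ds00 <- generate_dataset(cfg00)
  d00 <- dplyr::bind_cols(ds00$env,
                          taxon = as.numeric(abund_matrix(ds00$abundances)))
  expect_error(fit_sem(d00, sp), "not invertible")
})

test_that("hold-out split semantics and determinism", {
  cfg <- default_generator_config(n_samples = 1381, seed = 6)
  ds <- generate_dataset(cfg)
  d <- dplyr::bind_cols(ds$env,
                        taxon = as.numeric(abund_matrix(ds$abundances)))
  hv <- holdout_validate(d, default_sem_spec(), n_train = 1000, seed = 1)
  expect_equal(hv$metrics$n_test, 381)
  expect_equal(nrow(hv$predictions), 381)
  hv2 <- holdout_validate(d, default_sem_spec(), n_train = 1000, seed = 1)
  expect_identical(hv$metrics, hv2$metrics)
  expect_error(holdout_validate(d, default_sem_spec(), n_train = 2000),
               "smaller")
})

test_that("batch fitting isolates per-taxon failures", {
  cfg <- default_generator_config(
    n_samples = 300, seed = 10,
    taxon_coeffs = matrix(rep(c(-0.2, -0.4, -0.2, 0, 0.1, 0.2, -0.1, -0.1, 0),
                              3) * c(1, 2, 3),
                          nrow = 3, byrow = TRUE,
                          dimnames = list(paste0("tx", 1:3), driver_names())),
    taxon_residual_sds = c(1, 1, 1))
  ds <- generate_dataset(cfg)
  # plant a constant taxon row
  ab <- tibble::as_tibble(ds$abundances)
  ab[ab$taxon_id == "tx2", -1] <- as.list(rep(1, ncol(ab) - 1))
  batch <- fit_many(abundance_table(ab, "values"), ds$env)
  expect_equal(nrow(batch), 3)
  expect_identical(batch$ok, c(TRUE, FALSE, TRUE))
  expect_match(batch$error[2], "zero-variance")
  g <- glance(batch)
  expect_equal(g$n_ok, 2)
  expect_true(is.finite(g$mean_cfi))
})
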