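proj_fixture <- function(n = 2000, seed = 31) {
  tc <- matrix(c(-0.22, -0.46, -0.21, 0.03, 0.06, 0.19, -0.12, -0.08, -0.03,
                 -0.22, 0, -0.37, -2.8, 0.74, 2.9, 0.11, -0.01, 0.11),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("cyano", "bacilli"),
                               c("MAT", "humidity", "precipitation",
                                 "C3_macrothermal", "C3_mesothermal",
                                 "C4_megathermal", "OC", "conductivity",
                                 "pH")))
  cfg <- default_generator_config(n_samples = n, seed = seed,
                                  taxon_coeffs = tc,
                                  taxon_residual_sds = c(0.5, 0.5))
  ds <- generate_dataset(cfg)
  list(ds = ds, batch = fit_many(ds$abundances, ds$env))
}

test_that("identity scenarios project to fitted values with ~zero lnfold", {
  fx <- proj_fixture()
  scen <- fx$ds$env[c("sample_id", "MAT", "humidity", "precipitation",
                      "pH", "conductivity")]
  fut <- project_future(fx$batch, fx$ds$env, scen)
  # propagated drivers + fitted-value semantics: prediction from observed
  # exogenous equals the reduced-form fitted values; lnfold of future vs
  # the identically-computed projection is exactly zero
  fut2 <- project_future(fx$batch, fx$ds$env, scen)
  lf <- lnfold_change(fut, fut2)
  expect_lt(max(abs(abund_matrix(lf))), 1e-12)
  expect_setequal(attr(fut, "propagated"),
                  c("C3_macrothermal", "C3_mesothermal", "C4_megathermal",
                    "OC"))
  # supplying the observed endogenous drivers gives conditional fitted values
  scen_full <- fx$ds$env[c("sample_id", driver_names())]
  fut3 <- project_future(fx$batch, fx$ds$env, scen_full)
  expect_equal(as.numeric(abund_matrix(fut3)["cyano", ]),
               predict_conditional(fx$batch$fit[[1]],
                                   as.data.frame(fx$ds$env)),
               tolerance = 1e-9)
  expect_error(project_future(fx$batch, fx$ds$env, scen[, 1:3]),
               "exogenous")
})

test_that("projection is linear and matches the one-sd interpretation", {
  # calibrate the cyanobacterial taxon to unit variance so its raw paths are
  # also its standardized paths (humidity is exogenous with unit sd)
  tc <- matrix(c(-0.22, -0.46, -0.21, 0.03, 0.06, 0.19, -0.12, -0.08, -0.03),
               nrow = 1, dimnames = list("cyano", driver_names()))
  cfg0 <- default_generator_config(n_samples = 2, taxon_coeffs = tc,
                                   taxon_residual_sds = 0.5)
  std0 <- true_standardized_paths(cfg0)
  var_taxon <- (0.46 / abs(std0$std_path[std0$parent == "humidity"]))^2
  var_lin <- var_taxon - 0.5^2
  cfg <- default_generator_config(n_samples = 2000, seed = 31,
                                  taxon_coeffs = tc,
                                  taxon_residual_sds = sqrt(1 - var_lin))
  ds <- generate_dataset(cfg)
  batch <- fit_many(ds$abundances, ds$env)
  fx <- list(ds = ds, batch = batch)
  base <- fx$ds$env[c("sample_id", driver_names())]
  f1 <- fx$batch$fit[[1]]
  sd_h <- sd(fx$ds$env$humidity)
  sd_t <- f1$sds["taxon"]
  up1 <- dplyr::mutate(base, humidity = humidity + sd_h)
  up2 <- dplyr::mutate(base, humidity = humidity + 2 * sd_h)
  p0 <- abund_matrix(project_future(fx$batch, fx$ds$env, base))["cyano", ]
  p1 <- abund_matrix(project_future(fx$batch, fx$ds$env, up1))["cyano", ]
  p2 <- abund_matrix(project_future(fx$batch, fx$ds$env, up2))["cyano", ]
  # doubling the driver change doubles the abundance change
  expect_equal(p2 - p0, 2 * (p1 - p0), tolerance = 1e-9)
  # a +1 sd humidity shift moves the standardized prediction by the
  # standardized humidity path (~ -0.46 for this fixture taxon)
  cf <- f1$coefficients
  std_h <- cf$std_estimate[cf$child == "taxon" & cf$parent == "humidity"]
  expect_equal(unname(mean((p1 - p0) / sd_t)), unname(std_h),
               tolerance = 1e-9)
  expect_lt(abs(std_h - (-0.46)), 0.08)
})

test_that("lnfold changes use the half-minimum zero replacement", {
  cur <- abundance_table(matrix(c(0.066, 0, 0.934, 1),
                                2, dimnames = list(c("a", "b"),
                                                   c("s1", "s2"))),
                         mode = "values")
  fut <- abundance_table(matrix(c(0.132, 0.5, 0, 0.5), 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))),
                         mode = "values")
  lf <- lnfold_change(cur, fut)
  expect_equal(attr(lf, "zero_replacement"), 0.033)
  m <- abund_matrix(lf)
  expect_equal(m["a", "s1"], log(2), tolerance = 1e-12)
  expect_equal(m["b", "s1"], log(0.5 / 0.033), tolerance = 1e-12)
  expect_equal(m["a", "s2"], log(0.033 / 0.934), tolerance = 1e-12)
  zero <- abundance_table(matrix(0, 1, 1, dimnames = list("a", "s")),
                          "values")
  expect_error(lnfold_change(zero, zero), "zero replacement undefined")
})

test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  m <- matrix(c(1, 0, 3, 2, 2, 0, 1, 0, 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("u", "v", "w")))
  D <- bray_curtis(abundance_table(m, "counts"))
  expect_equal(D["u", "v"], 0.75)      # (1+2+3)/(3+4+... ) hand-checked
  expect_equal(D["u", "w"], 0)         # identical samples
  disjoint <- matrix(c(1, 0, 0, 2), 2,
                     dimnames = list(c("a", "b"), c("u", "v")))
  expect_equal(bray_curtis(abundance_table(disjoint, "counts"))["u", "v"], 1)
  expect_true(all(diag(D) == 0))
  bad <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("u", "v")))
  expect_error(bray_curtis(abundance_table(bad, "counts")), "zero total")
})

test_that("PCoA recovers a planted planar configuration", {
  withr::with_seed(8, {
    pts <- cbind(rnorm(15), rnorm(15))
    rownames(pts) <- sprintf("p%02d", 1:15)
    D <- as.matrix(dist(pts))
    ord <- pcoa_ordination(D, n_axes = 2)
    expect_true(all(diff(ord$eigenvalues) <= 1e-8))
    rec <- as.matrix(ord$coordinates[, c("axis_1", "axis_2")])
    # Procrustes alignment (rotation/reflection/translation) onto the truth
    pr <- vegan::procrustes(pts, rec)
    expect_lt(sum(pr$residuals^2), 1e-8)
    # double-centered inner-product rows sum to zero
    G <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
    expect_lt(max(abs(rowSums(G))), 1e-8)
  })
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("displacement is a per-site Euclidean distance", {
  coords <- tibble::tibble(
    sample_id = c("s1_now", "s2_now", "s1_fut", "s2_fut"),
    axis_1 = c(0, 1, 3, 1), axis_2 = c(0, 1, 4, 1))
  d <- displacement(coords, c("s1_now", "s2_now"), c("s1_fut", "s2_fut"),
                    site_ids = c("s1", "s2"))
  expect_equal(d$displacement, c(5, 0))   # translation by (3,4) and identity
  expect_true(all(d$displacement >= 0))
  expect_error(displacement(coords, "nope", "s1_fut"), "unmatched")
})

test_that("functional projection is the community-weighted gene profile", {
  A <- matrix(c(2, 1, 1, 3), 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
  tt <- tibble::tibble(taxon_id = c("t1", "t2"), g1 = c(1, 0), g2 = c(2, 3))
  gp <- functional_projection(abundance_table(A, "counts"), tt)
  # brute-force double loop oracle
  oracle <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  for (g in 1:2) for (s in 1:2) for (tx in 1:2) {
    oracle[g, s] <- oracle[g, s] + tt[[g + 1]][tx] * A[tx, s]
  }
  oracle <- sweep(oracle, 2, colSums(oracle), "/")
  expect_equal(abund_matrix(gp), oracle)
  # identity trait table returns the (renormalized) taxon profile
  idt <- tibble::tibble(taxon_id = c("t1", "t2"), t1 = c(1, 0), t2 = c(0, 1))
  gid <- functional_projection(abundance_table(A, "counts"), idt)
  expect_equal(unname(abund_matrix(gid)),
               unname(sweep(A, 2, colSums(A), "/")))
  # non-overlapping taxa are dropped with a reported fraction
  expect_message(
    part <- functional_projection(abundance_table(A, "counts"), tt[1, ]),
    "50.0%")
  expect_equal(attr(part, "dropped_fraction"), 0.5)
  expect_error(functional_projection(abundance_table(A, "counts"),
                                     tibble::tibble(taxon_id = "zz", g = 1)),
               "no taxa shared")
})

test_that("inverse-distance gridding interpolates exactly at data points", {
  pts <- tibble::tibble(lon = c(140, 141, 142, 140.5),
                        lat = c(-30, -31, -30.5, -30.2),
                        value = c(5, 5, 5, 5))
  g <- grid_interpolate(pts, resolution = 0.2)
  expect_true(all(abs(g$value[!is.na(g$value)] - 5) < 1e-9))
  # grid spacing is the requested resolution
  expect_true(all(abs(diff(sort(unique(g$lon))) - 0.2) < 1e-9))
  pts2 <- pts
  pts2$value <- c(1, 2, 3, 4)
  g2 <- grid_interpolate(pts2, resolution = 0.5)
  at_point <- g2[abs(g2$lon - 140) < 1e-9 & abs(g2$lat - (-30)) < 1e-9, ]
  expect_equal(at_point$value, 1)
  expect_error(grid_interpolate(pts[1:2, ]), "nrow")
  flat <- tibble::tibble(lon = c(1, 1, 1), lat = c(1, 2, 3), value = 1:3)
  expect_error(grid_interpolate(flat), "degenerate")
})
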