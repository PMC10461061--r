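#' Configure the synthetic-data generator
#'
#' Bundles everything [generate_dataset()] needs to draw samples from a known
#' causal world: exogenous drivers are multivariate normal with the given
#' means and covariance; every endogenous variable is its structural linear
#' combination of parents plus an independent normal residual, evaluated in
#' topological order; taxon abundances are the final endogenous variables.
#'
#' @param n_samples Number of samples to draw.
#' @param structural_coeffs Named list: for each endogenous variable of the
#'   spec, a named numeric vector of coefficients over exactly its parents.
#' @param residual_sds Named nonnegative vector, one entry per endogenous
#'   variable.
#' @param exogenous_cov Symmetric positive-definite covariance of the
#'   exogenous block (named rows/cols).
#' @param exogenous_means Named mean vector for the exogenous block (default
#'   all zero).
#' @param intercepts Optional named intercepts for endogenous variables
#'   (default 0, except the taxon default below).
#' @param taxon_coeffs Optional matrix (taxa x parents-of-taxon, named) to
#'   generate several taxa sharing the same driver world; overrides the taxon
#'   entry of `structural_coeffs`.
#' @param taxon_residual_sds Residual sds per taxon when `taxon_coeffs` is
#'   given.
#' @param squash How to map taxon linear responses to abundances:
#'   `"truncate"` (clamp at 0, the default), `"none"` (raw linear), or
#'   `"logistic"` (`plogis`, for relative-abundance semantics).
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A list of class `generator_config`.
#' @seealso [default_generator_config()] for the packaged study-like world.
#' @export
generator_config <- function(n_samples, structural_coeffs, residual_sds,
                             exogenous_cov, exogenous_means = NULL,
                             intercepts = NULL, taxon_coeffs = NULL,
                             taxon_residual_sds = NULL,
                             squash = c("truncate", "none", "logistic"),
                             seed = NULL) {
  squash <- match.arg(squash)
  stopifnot(n_samples >= 1)
  if (!isSymmetric(unname(exogenous_cov), tol = 1e-10)) {
    stop("exogenous_cov must be symmetric", call. = FALSE)
  }
  ev <- eigen(exogenous_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("exogenous_cov must be positive-definite", call. = FALSE)
  if (any(residual_sds < 0)) stop("residual_sds must be nonnegative", call. = FALSE)
  if (!is.null(taxon_residual_sds) && any(taxon_residual_sds < 0)) {
    stop("taxon_residual_sds must be nonnegative", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         structural_coeffs = structural_coeffs,
         residual_sds = residual_sds,
         exogenous_cov = exogenous_cov,
         exogenous_means = exogenous_means,
         intercepts = intercepts,
         taxon_coeffs = taxon_coeffs,
         taxon_residual_sds = taxon_residual_sds,
         squash = squash, seed = seed),
    class = "generator_config")
}

#' Packaged study-like generator configuration
#'
#' A fixed causal world over the nine drivers matching the default topology:
#' standardized exogenous drivers with moderate correlations, vegetation
#' responding to climate, organic carbon to its five parents, and a default
#' taxon whose nine direct paths are the published Synechococcophycideae
#' standardized coefficients (MAT -0.22, humidity -0.46, precipitation -0.21,
#' C3 macrothermal 0.03, C3 mesothermal 0.06, C4 megathermal 0.19, OC -0.12,
#' conductivity -0.08, pH -0.03). The taxon intercept of 10 keeps abundances
#' positive so truncation at zero essentially never binds and linear recovery
#' stays exact.
#'
#' @inheritParams generator_config
#' @param taxon Name of the taxon node (matching the spec the config will be
#'   used with).
#' @return A [generator_config()].
#' @export
default_generator_config <- function(n_samples = 1381, seed = NULL,
                                     taxon = "taxon",
                                     taxon_coeffs = NULL,
                                     taxon_residual_sds = NULL) {
  exog <- c(sn_climate, "pH", "conductivity")
  cv <- diag(5)
  dimnames(cv) <- list(exog, exog)
  cv["MAT", "humidity"] <- cv["humidity", "MAT"] <- -0.3
  cv["MAT", "precipitation"] <- cv["precipitation", "MAT"] <- -0.2
  cv["humidity", "precipitation"] <- cv["precipitation", "humidity"] <- 0.5
  cv["pH", "conductivity"] <- cv["conductivity", "pH"] <- 0.4
  coeffs <- list(
    C3_macrothermal = c(MAT = -0.4, humidity = 0.3, precipitation = 0.3),
    C3_mesothermal  = c(MAT = -0.3, humidity = 0.4, precipitation = 0.2),
    C4_megathermal  = c(MAT = 0.5, humidity = -0.2, precipitation = 0.3),
    OC = c(conductivity = -0.2, pH = -0.3, humidity = 0.3,
           precipitation = 0.2, C3_macrothermal = 0.3))
  coeffs[[taxon]] <- c(
    MAT = -0.22, humidity = -0.46, precipitation = -0.21,
    C3_macrothermal = 0.03, C3_mesothermal = 0.06, C4_megathermal = 0.19,
    OC = -0.12, conductivity = -0.08, pH = -0.03)
  rsd <- c(C3_macrothermal = 0.8, C3_mesothermal = 0.8, C4_megathermal = 0.8,
           OC = 0.8)
  rsd[taxon] <- 1
  ints <- setNames(rep(0, length(rsd)), names(rsd))
  ints[taxon] <- 10
  generator_config(n_samples, coeffs, rsd, cv,
                   exogenous_means = setNames(rep(0, 5), exog),
                   intercepts = ints,
                   taxon_coeffs = taxon_coeffs,
                   taxon_residual_sds = taxon_residual_sds,
                   seed = seed)
}

#' Generate a synthetic dataset from a causal network
#'
#' @param config A [generator_config()] dimensionally consistent with `spec`.
#' @param spec A [sem_spec()] (default: the packaged topology).
#' @return A list of class `synthetic_dataset` with `env` (sample-by-driver
#'   tibble), `abundances` (taxa-by-sample abundance table in `"values"`
#'   mode), and `true_coeffs` (the generating parameters, including the
#'   population standardized paths of every taxon).
#' @export
generate_dataset <- function(config, spec = default_sem_spec()) {
  stopifnot(inherits(config, "generator_config"), inherits(spec, "sem_spec"))
  taxon <- sink_node(spec)
  exog <- spec$exogenous
  cv <- config$exogenous_cov
  if (!setequal(rownames(cv), exog)) {
    stop("exogenous_cov names do not match the spec's exogenous set",
         call. = FALSE)
  }
  drivers <- setdiff(spec$endogenous, taxon)
  for (v in c(drivers, taxon)) {
    cf <- config$structural_coeffs[[v]]
    if (v == taxon && !is.null(config$taxon_coeffs)) next
    if (is.null(cf) || !setequal(names(cf), spec$parents[[v]])) {
      stop("structural_coeffs[['", v, "']] must cover exactly its parents",
           call. = FALSE)
    }
    if (is.na(config$residual_sds[v])) {
      stop("residual_sds missing entry for '", v, "'", call. = FALSE)
    }
  }
  tc <- config$taxon_coeffs
  if (!is.null(tc)) {
    if (!setequal(colnames(tc), spec$parents[[taxon]])) {
      stop("taxon_coeffs columns must match the taxon node's parents",
           call. = FALSE)
    }
    if (is.null(rownames(tc))) {
      rownames(tc) <- sprintf("taxon_%03d", seq_len(nrow(tc)))
    }
    trs <- config$taxon_residual_sds
    if (is.null(trs) || length(trs) != nrow(tc)) {
      stop("taxon_residual_sds must have one entry per taxon", call. = FALSE)
    }
  }

  n <- config$n_samples
  mu <- config$exogenous_means %||% setNames(rep(0, length(exog)), exog)
  out <- with_seed_or_not(config$seed, {
    L <- chol(cv[exog, exog])
    X <- matrix(rnorm(n * length(exog)), n) %*% L
    X <- sweep(X, 2, mu[exog], "+")
    colnames(X) <- exog
    icpt_v <- function(v) {
      i <- config$intercepts[v]
      if (is.null(config$intercepts) || is.na(i)) 0 else unname(i)
    }
    for (v in drivers) {
      cf <- config$structural_coeffs[[v]]
      lin <- icpt_v(v) + X[, names(cf), drop = FALSE] %*% cf
      s <- config$residual_sds[v]
      X <- cbind(X, as.numeric(lin) + if (s > 0) rnorm(n, 0, s) else 0)
      colnames(X)[ncol(X)] <- v
    }
    make_taxon <- function(cf, s, icp) {
      lin <- icp + as.numeric(X[, names(cf), drop = FALSE] %*% cf) +
        if (s > 0) rnorm(n, 0, s) else 0
      switch(config$squash,
             none = lin, truncate = pmax(lin, 0), logistic = stats::plogis(lin))
    }
    if (is.null(tc)) {
      A <- matrix(make_taxon(config$structural_coeffs[[taxon]],
                             config$residual_sds[taxon], icpt_v(taxon)),
                  nrow = 1, dimnames = list(taxon, NULL))
    } else {
      A <- t(vapply(seq_len(nrow(tc)), function(i) {
        make_taxon(setNames(tc[i, ], colnames(tc)),
                   config$taxon_residual_sds[i], icpt_v(taxon))
      }, numeric(n)))
      rownames(A) <- rownames(tc)
    }
    list(X = X, A = A)
  })
  sample_ids <- sprintf("s%04d", seq_len(n))
  env <- tibble::as_tibble(out$X[, c(exog, drivers), drop = FALSE])
  env <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), env)
  colnames(out$A) <- sample_ids
  structure(
    list(env = env_table(env, require = character(0)),
         abundances = abundance_table(out$A, mode = "values"),
         true_coeffs = list(
           structural_coeffs = config$structural_coeffs,
           taxon_coeffs = tc,
           residual_sds = config$residual_sds,
           taxon_residual_sds = config$taxon_residual_sds,
           exogenous_cov = cv,
           std_paths = true_standardized_paths(config, spec))),
    class = "synthetic_dataset")
}

#' Population standardized paths implied by a generator configuration
#'
#' Computes the model-implied covariance from the true generating parameters
#' and converts each taxon path to the standardized scale
#' (coefficient * sd(parent) / sd(taxon)).
#'
#' @inheritParams generate_dataset
#' @return A tibble with `taxon_id`, `parent`, and `std_path`.
#' @export
true_standardized_paths <- function(config, spec = default_sem_spec()) {
  taxon <- sink_node(spec)
  coef_list <- if (is.null(config$taxon_coeffs)) {
    stats::setNames(list(config$structural_coeffs[[taxon]]), taxon)
  } else {
    tcs <- config$taxon_coeffs
    rn <- rownames(tcs) %||% sprintf("taxon_%03d", seq_len(nrow(tcs)))
    stats::setNames(lapply(seq_len(nrow(tcs)),
                           function(i) setNames(tcs[i, ], colnames(tcs))), rn)
  }
  purrr::imap_dfr(coef_list, function(cf, tx) {
    sc <- config$structural_coeffs
    sc[[taxon]] <- cf
    rsd <- config$residual_sds
    rsd[taxon] <- if (is.null(config$taxon_coeffs)) rsd[taxon] else
      config$taxon_residual_sds[match(tx, names(coef_list))]
    ctab <- purrr::imap_dfr(sc[spec$endogenous], function(v, ch) {
      tibble::tibble(child = ch, parent = names(v), estimate = unname(v))
    })
    sig <- implied_sigma(spec, ctab, rsd^2, config$exogenous_cov)
    sds <- sqrt(diag(sig))
    tibble::tibble(taxon_id = tx, parent = names(cf),
                   std_path = unname(cf) * sds[names(cf)] / sds[taxon])
  })
}

#' Simulate abundances along a single environmental gradient
#'
#' Evaluates a Huisman-Olff-Fresco response curve on a regular gradient over
#' \[0, 1\] and adds normal noise truncated at zero.
#'
#' @param model_type HOF type, `"I"`..`"VII"`.
#' @param params Named parameter vector for the type (see [hof_curve()]).
#' @param n_points Number of gradient points.
#' @param noise_sd Standard deviation of additive normal noise.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A tibble with columns `gradient` and `abundance`.
#' @export
generate_hof_gradient <- function(model_type, params, n_points,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(n_points >= 2, noise_sd >= 0)
  x <- seq(0, 1, length.out = n_points)
  mu <- hof_curve(x, model_type, params)
  y <- with_seed_or_not(seed, mu + if (noise_sd > 0) rnorm(n_points, 0, noise_sd) else 0)
  tibble::tibble(gradient = x, abundance = pmax(y, 0))
}

#' Simulate a Yule tree with a Brownian trait
#'
#' Draws a pure-birth (Yule) tree, rescales it to unit depth, and evolves a
#' trait by Brownian motion from a root value of 0, so each tip trait has
#' variance `brownian_sd^2` (times its root-to-tip depth, = 1).
#'
#' @param n_tips Number of tips (at least 3).
#' @param brownian_sd Brownian-motion rate (per unit branch length); 0 gives
#'   a constant zero trait.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A list with `tree` (an `ape::phylo`) and `trait` (named numeric
#'   vector over tips).
#' @export
generate_tree_and_trait <- function(n_tips, brownian_sd, seed = NULL) {
  if (n_tips < 3) stop("n_tips must be at least 3", call. = FALSE)
  stopifnot(brownian_sd >= 0)
  with_seed_or_not(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    trait <- if (brownian_sd == 0) {
      setNames(rep(0, n_tips), tree$tip.label)
    } else {
      phytools::fastBM(tree, a = 0, sig2 = brownian_sd^2)
    }
    list(tree = tree, trait = trait[tree$tip.label])
  })
}

#' Multinomial sequencing counts from relative abundances
#'
#' Emulates sequencing: each sample column of a relative abundance table is
#' replaced by one multinomial draw of size `depth` from its proportions.
#'
#' @param relabund Relative-mode abundance table (columns summing to 1 within
#'   1e-8).
#' @param depth Reads per sample.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A counts-mode abundance table.
#' @export
multinomial_counts <- function(relabund, depth, seed = NULL) {
  stopifnot(depth >= 1)
  m <- abund_matrix(relabund)
  cs <- colSums(m)
  bad <- which(abs(cs - 1) > 1e-8)
  if (length(bad)) {
    stop("column(s) not summing to 1: ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  }
  counts <- with_seed_or_not(seed,
    apply(m, 2, function(p) rmultinom(1, size = depth, prob = p)))
  dimnames(counts) <- dimnames(m)
  abundance_table(counts, mode = "counts")
}
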