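#' Fit a recursive observed-variable structural equation model
#'
#' Estimates every structural equation of a [sem_spec()] by ordinary least
#' squares, which coincides with maximum likelihood for recursive models with
#' uncorrelated residuals, then evaluates the usual covariance-structure fit
#' machinery: the implied covariance is assembled from the reduced form
#' \eqn{y = (I-B)^{-1}(\Gamma x + \zeta)}, the ML discrepancy is
#' \eqn{F_{ML} = \ln|\hat\Sigma| - \ln|S| + tr(S\hat\Sigma^{-1}) - p}, and
#' \eqn{\chi^2 = (n-1) F_{ML}} with the sample covariance \eqn{S} on the
#' \eqn{n-1} denominator (Wishart convention). CFI is computed against the
#' independence baseline (all variances free, covariances zero), RMSEA as
#' \eqn{\sqrt{\max(\chi^2-df,0)/(df\,(n-1))}}, and SRMR as the root mean
#' square of covariance residuals standardized by the observed standard
#' deviations, over the lower triangle including the diagonal.
#'
#' Standardized path coefficients are `estimate * sd(parent) / sd(child)`: a
#' one-standard-deviation increase in the parent moves the child's prediction
#' by that many of its own standard deviations.
#'
#' @param data A data frame containing a column for every variable in `spec`
#'   (environment drivers joined with one taxon abundance column). Rows with
#'   missing values in those columns are dropped with a message.
#' @param spec A [sem_spec()].
#' @param response Name of the node treated as the modeled taxon; defaults to
#'   the unique childless endogenous node.
#' @return An object of class `sem_fit`: coefficient table (`coefficients`),
#'   intercepts, residual variances `psi`, exogenous covariance `phi`, implied
#'   covariance `sigma_hat`, sample covariance `S`, per-equation `r2`, fit
#'   `indices`, `n`, and the `spec`.
#' @export
fit_sem <- function(data, spec, response = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  response <- response %||% sink_node(spec)
  vars <- spec$variables
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("data is missing model variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[vars])
  keep <- complete.cases(X)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X)
  p <- length(vars)
  if (n <= p) stop("need more observations than variables", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  }

  S <- cov(X)                       # denominator n - 1 throughout
  phi <- S[spec$exogenous, spec$exogenous, drop = FALSE]

  coef_rows <- list()
  intercepts <- numeric(0)
  psi <- numeric(0)
  r2 <- numeric(0)
  for (child in spec$endogenous) {
    pa <- spec$parents[[child]]
    xm <- cbind(`(Intercept)` = 1, X[, pa, drop = FALSE])
    qr_x <- qr(xm)
    if (qr_x$rank < ncol(xm)) {
      stop("singular design for equation of '", child, "'", call. = FALSE)
    }
    beta <- qr.coef(qr_x, X[, child])
    res <- X[, child] - xm %*% beta
    sse <- sum(res^2)
    k <- ncol(xm)
    sigma2_ols <- sse / (n - k)
    se <- sqrt(diag(chol2inv(qr.R(qr_x))) * sigma2_ols)
    intercepts[child] <- beta[1]
    psi[child] <- sse / (n - 1)
    r2[child] <- 1 - psi[child] / S[child, child]
    if (length(pa)) {
      est <- beta[-1]
      coef_rows[[child]] <- tibble::tibble(
        child = child, parent = pa,
        estimate = unname(est),
        std_estimate = unname(est) * sds[pa] / sds[child],
        std_error = unname(se[-1]),
        p_value = 2 * pnorm(-abs(unname(est) / unname(se[-1]))))
    }
  }
  coefficients <- dplyr::bind_rows(coef_rows)

  sigma_hat <- implied_sigma(spec, coefficients, psi, phi)
  indices <- fit_indices(S, sigma_hat, n, n_free_params(spec))

  structure(
    list(coefficients = coefficients, intercepts = intercepts, psi = psi,
         phi = phi, sigma_hat = sigma_hat, S = S, r2 = r2, sds = sds,
         indices = indices, n = n, spec = spec, response = response),
    class = "sem_fit")
}

# model-implied covariance from structural parameters, ordered as
# spec$variables (exogenous block first)
implied_sigma <- function(spec, coefficients, psi, phi) {
  endog <- spec$endogenous
  exog <- spec$exogenous
  ne <- length(endog)
  B <- matrix(0, ne, ne, dimnames = list(endog, endog))
  G <- matrix(0, ne, length(exog), dimnames = list(endog, exog))
  for (i in seq_len(nrow(coefficients))) {
    ch <- coefficients$child[i]; pa <- coefficients$parent[i]
    if (pa %in% exog) G[ch, pa] <- coefficients$estimate[i]
    else B[ch, pa] <- coefficients$estimate[i]
  }
  A <- solve(diag(ne) - B)
  Psi <- diag(psi[endog], ne)
  syy <- A %*% (G %*% phi %*% t(G) + Psi) %*% t(A)
  syx <- A %*% G %*% phi
  sig <- rbind(cbind(phi, t(syx)), cbind(syx, syy))
  dimnames(sig) <- list(c(exog, endog), c(exog, endog))
  sig <- (sig + t(sig)) / 2
  sig[spec$variables, spec$variables]
}

# ML discrepancy and the standard fit indices
fit_indices <- function(S, sigma_hat, n, t_free) {
  p <- ncol(S)
  sigma_inv <- tryCatch(solve(sigma_hat), error = function(e)
    stop("implied covariance is not invertible (degenerate model, e.g. a ",
         "zero residual variance)", call. = FALSE))
  f_ml <- as.numeric(
    determinant(sigma_hat)$modulus - determinant(S)$modulus +
      sum(diag(S %*% sigma_inv)) - p)
  f_ml <- max(f_ml, 0)              # clip tiny negative rounding
  chi2 <- (n - 1) * f_ml
  df <- p * (p + 1) / 2 - t_free
  if (df < 0) stop("negative degrees of freedom: model over-parameterized",
                   call. = FALSE)
  # independence baseline: variances free, covariances zero
  f_b <- sum(log(diag(S))) - as.numeric(determinant(S)$modulus)
  chi2_b <- (n - 1) * f_b
  df_b <- p * (p - 1) / 2
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  d <- sqrt(diag(S))
  resid_std <- (S - sigma_hat) / outer(d, d)
  srmr <- sqrt(mean(resid_std[lower.tri(resid_std, diag = TRUE)]^2))
  p_value <- if (df == 0) NA_real_ else pchisq(chi2, df, lower.tail = FALSE)
  list(f_ml = f_ml, chi2 = chi2, df = df, p_value = p_value, cfi = cfi,
       rmsea = rmsea, srmr = srmr, chi2_baseline = chi2_b, df_baseline = df_b)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> n =", x$n, "\n")
  cat(sprintf("  chi2 = %.3f (df = %d, p = %s), CFI = %.3f, RMSEA = %.3f, SRMR = %.4f\n",
              x$indices$chi2, x$indices$df,
              format.pval(x$indices$p_value, digits = 3),
              x$indices$cfi, x$indices$rmsea, x$indices$srmr))
  cat(sprintf("  R2[%s] = %.3f\n", x$response, x$r2[x$response]))
  invisible(x)
}

#' @export
tidy.sem_fit <- function(x, ...) x$coefficients

#' @rdname fit_sem
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, chi2 = x$indices$chi2, df = x$indices$df,
    p_value = x$indices$p_value, cfi = x$indices$cfi,
    rmsea = x$indices$rmsea, srmr = x$indices$srmr,
    r2_response = unname(x$r2[x$response]))
}

#' Conditional prediction of a node from its parents
#'
#' Fitted-value semantics: the prediction for `node` is its equation's
#' intercept plus coefficients times the *observed* parent columns in
#' `new_data`. The node's own column, if present, is never used.
#'
#' @param fit A [fit_sem()] result.
#' @param new_data Data frame with all parent columns of `node`.
#' @param node Endogenous node to predict; defaults to the fit's response.
#' @return Numeric vector of predictions, one per row of `new_data`.
#' @export
predict_conditional <- function(fit, new_data, node = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  node <- node %||% fit$response
  pa <- fit$spec$parents[[node]]
  if (is.null(pa)) stop("'", node, "' is not an endogenous node", call. = FALSE)
  miss <- setdiff(pa, names(new_data))
  if (length(miss)) {
    stop("new_data is missing parent column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cf <- fit$coefficients[fit$coefficients$child == node, ]
  est <- setNames(cf$estimate, cf$parent)
  as.numeric(fit$intercepts[node] +
               as.matrix(as.data.frame(new_data)[pa]) %*% est[pa])
}

#' Hold-out validation of a causal network
#'
#' Randomly splits the samples into a training set of `n_train` rows and a
#' test set of the remainder, fits the network on the training rows and
#' predicts the response on the test rows from their observed drivers,
#' reporting the Pearson correlation and R-squared (1 - SSE/SST) between
#' observed and predicted abundances.
#'
#' @inheritParams fit_sem
#' @param n_train Training-set size (default 1000, the split used with 1,381
#'   soil samples leaving 381 for validation).
#' @param seed Integer seed for the split; `NULL` uses the session RNG.
#' @return A list with `metrics` (one-row tibble: `n_train`, `n_test`,
#'   `pearson_r`, `r_squared`), `predictions` (tibble of observed/predicted),
#'   and the training `fit`.
#' @export
holdout_validate <- function(data, spec, n_train = 1000, seed = NULL,
                             response = NULL) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n_train >= n) stop("n_train must be smaller than the number of samples",
                         call. = FALSE)
  idx <- with_seed_or_not(seed, sample.int(n, n_train))
  fit <- fit_sem(data[idx, , drop = FALSE], spec, response = response)
  test <- data[-idx, , drop = FALSE]
  pred <- predict_conditional(fit, test)
  obs <- test[[fit$response]]
  r <- stats::cor(obs, pred)
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  list(metrics = tibble::tibble(n_train = n_train, n_test = n - n_train,
                                pearson_r = r, r_squared = r2),
       predictions = tibble::tibble(observed = obs, predicted = pred),
       fit = fit)
}

#' Fit one causal network per taxon
#'
#' Applies [fit_sem()] to every row of an abundance table, substituting each
#' taxon's abundances for the spec's response node. Per-taxon failures (e.g.
#' a zero-variance taxon) are recorded and never abort the batch.
#'
#' @param abund Abundance table (wide tibble, taxa as rows).
#' @param env Environment table sharing sample ids with `abund`.
#' @param spec A [sem_spec()]; default topology if omitted.
#' @return A tibble of class `sem_fit_batch`: one row per taxon with `ok`,
#'   fit indices, the response-equation R2, an `error` message for failures,
#'   and the `sem_fit` objects in the `fit` list-column.
#' @export
fit_many <- function(abund, env, spec = default_sem_spec()) {
  response <- sink_node(spec)
  samples <- shared_samples(abund, env)
  envd <- as.data.frame(env)[match(samples, env$sample_id), , drop = FALSE]
  mat <- abund_matrix_raw(tibble::as_tibble(abund))[, samples, drop = FALSE]
  rows <- purrr::map(rownames(mat), function(tx) {
    dat <- envd
    dat[[response]] <- mat[tx, ]
    res <- tryCatch(fit_sem(dat, spec, response = response),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "sem_fit")) {
      dplyr::bind_cols(tibble::tibble(taxon_id = tx, ok = TRUE),
                       glance(res),
                       tibble::tibble(error = NA_character_, fit = list(res)))
    } else {
      tibble::tibble(taxon_id = tx, ok = FALSE, error = res, fit = list(NULL))
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sem_fit_batch", class(out))
  attr(out, "spec") <- spec
  out
}

#' @rdname fit_many
#' @param x A `sem_fit_batch`.
#' @param ... Unused.
#' @export
glance.sem_fit_batch <- function(x, ...) {
  ok <- x[x$ok, ]
  tibble::tibble(n_taxa = nrow(x), n_ok = nrow(ok),
                 mean_cfi = mean(ok$cfi), mean_r2 = mean(ok$r2_response))
}
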