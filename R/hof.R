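hof_types <- c("I", "II", "III", "IV", "V", "VI", "VII")

hof_param_names <- function(type) {
  switch(type,
         I   = c("M", "a"),
         II  = c("M", "a", "b"),
         III = c("M", "a", "b", "c"),
         IV  = c("M", "a", "b", "c"),
         V   = c("M", "a", "b", "c", "d"),
         VI  = c("M", "a", "b", "c", "d2", "h"),
         VII = c("M", "a", "b", "c", "d2", "h", "b2"),
         stop("unknown HOF type '", type, "'", call. = FALSE))
}

# overflow-safe exp
.e <- function(u) exp(pmin(u, 700))

# the shared skewless peak building block used by types IV, VI and VII
hof_peak <- function(x, a, b, c) 1 / ((1 + .e(a + b * x)) * (1 + .e(c - b * x)))

#' Evaluate a Huisman-Olff-Fresco response curve
#'
#' The seven-model hierarchy of species response shapes along a gradient
#' `x` in \[0, 1\]: flat (I), monotone sigmoid (II), sigmoid with a plateau
#' below the maximum (III), symmetric unimodal (IV), skewed unimodal (V),
#' and bimodal (VI, VII). The bimodal types are a type-IV peak plus a second
#' peak shifted by `d2` with height fraction `h`; type VII gives the second
#' peak its own width parameter `b2`.
#'
#' Formulas (with `M` the scale): I `M/(1+e^a)`; II `M/(1+e^(a+bx))`;
#' III `M/((1+e^(a+bx))(1+e^c))`; IV `M/((1+e^(a+bx))(1+e^(c-bx)))`;
#' V `M/((1+e^(a+bx))(1+e^(c+dx)))`; VI `M (f(x) + h f(x-d2))` with `f` the
#' type-IV kernel; VII as VI with width `b2` in the second kernel.
#'
#' @param x Gradient vector (values in \[0, 1\]).
#' @param type HOF type, one of `"I"`..`"VII"`.
#' @param params Named parameter vector; required names per type: I `M,a`;
#'   II `M,a,b`; III/IV `M,a,b,c`; V `M,a,b,c,d`; VI `M,a,b,c,d2,h`;
#'   VII `M,a,b,c,d2,h,b2`. `M > 0`, `d2` in (0,1), `h` in (0,1].
#' @return Numeric response vector, values in `(0, M*(1+h))`.
#' @export
#' @examples
#' hof_curve(seq(0, 1, 0.25), "I", c(M = 1, a = 0))
hof_curve <- function(x, type, params) {
  type <- match.arg(type, hof_types)
  need <- hof_param_names(type)
  if (!all(need %in% names(params)) || length(params) != length(need)) {
    stop("type ", type, " needs exactly parameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  p <- as.list(params[need])
  if (p$M <= 0) stop("M must be positive", call. = FALSE)
  with(p, switch(type,
    I   = rep(M / (1 + .e(a)), length(x)),
    II  = M / (1 + .e(a + b * x)),
    III = M / ((1 + .e(a + b * x)) * (1 + .e(c))),
    IV  = M * hof_peak(x, a, b, c),
    V   = M / ((1 + .e(a + b * x)) * (1 + .e(c + d * x))),
    VI  = M * (hof_peak(x, a, b, c) + h * hof_peak(x - d2, a, b, c)),
    VII = M * (hof_peak(x, a, b, c) + h * hof_peak(x - d2, a, b2, c))))
}

# unconstrained optimizer space <-> natural parameters.
# M = exp(t), d2 = plogis(t), h = plogis(t); everything else raw.
hof_theta_to_params <- function(theta, type) {
  nm <- hof_param_names(type)
  p <- setNames(theta, nm)
  p["M"] <- exp(p["M"])
  if ("d2" %in% nm) p["d2"] <- stats::plogis(p[["d2"]])
  if ("h" %in% nm) p["h"] <- stats::plogis(p[["h"]])
  p
}

# validation-free curve on optimizer-space parameters (hot path)
hof_mu_theta <- function(theta, type, x) {
  M <- exp(min(theta[1], 700))
  switch(type,
    I   = rep.int(M / (1 + .e(theta[2])), length(x)),
    II  = M / (1 + .e(theta[2] + theta[3] * x)),
    III = M / ((1 + .e(theta[2] + theta[3] * x)) * (1 + .e(theta[4]))),
    IV  = M * hof_peak(x, theta[2], theta[3], theta[4]),
    V   = M / ((1 + .e(theta[2] + theta[3] * x)) *
                 (1 + .e(theta[4] + theta[5] * x))),
    VI  = M * (hof_peak(x, theta[2], theta[3], theta[4]) +
                 stats::plogis(theta[6]) *
                   hof_peak(x - stats::plogis(theta[5]),
                            theta[2], theta[3], theta[4])),
    VII = M * (hof_peak(x, theta[2], theta[3], theta[4]) +
                 stats::plogis(theta[6]) *
                   hof_peak(x - stats::plogis(theta[5]),
                            theta[2], theta[7], theta[4])))
}

hof_rss <- function(theta, type, xs, ys) {
  mu <- hof_mu_theta(theta, type, xs)
  if (any(!is.finite(mu))) return(1e10)
  sum((ys - mu)^2)
}

sigm <- function(u) 1 / (1 + .e(u))

# analytic gradient of the RSS in optimizer space. Building block: for a
# peak P = s(a+bx) s(c-bx) (s the inverse logit), dP/da = -P(1-s(a+bx)),
# dP/dc = -P(1-s(c-bx)), dP/db = P x (s(a+bx)-s(c-bx)).
hof_rss_grad <- function(theta, type, xs, ys) {
  mu <- hof_mu_theta(theta, type, xs)
  if (any(!is.finite(mu))) return(rep(0, length(theta)))
  r <- ys - mu
  M <- exp(min(theta[1], 700))
  g <- switch(type,
    II = {
      su <- sigm(theta[2] + theta[3] * xs)
      da <- -mu * (1 - su)
      cbind(mu, da, da * xs)
    },
    III = {
      su <- sigm(theta[2] + theta[3] * xs)
      sc <- sigm(theta[4])
      da <- -mu * (1 - su)
      cbind(mu, da, da * xs, -mu * (1 - sc))
    },
    IV = {
      su <- sigm(theta[2] + theta[3] * xs)
      sv <- sigm(theta[4] - theta[3] * xs)
      cbind(mu, -mu * (1 - su), mu * xs * (su - sv), -mu * (1 - sv))
    },
    V = {
      su <- sigm(theta[2] + theta[3] * xs)
      sw <- sigm(theta[4] + theta[5] * xs)
      da <- -mu * (1 - su)
      dc <- -mu * (1 - sw)
      cbind(mu, da, da * xs, dc, dc * xs)
    },
    VI = , VII = {
      d2 <- stats::plogis(theta[5]); h <- stats::plogis(theta[6])
      b2 <- if (type == "VII") theta[7] else theta[3]
      x2 <- xs - d2
      su1 <- sigm(theta[2] + theta[3] * xs)
      sv1 <- sigm(theta[4] - theta[3] * xs)
      su2 <- sigm(theta[2] + b2 * x2)
      sv2 <- sigm(theta[4] - b2 * x2)
      P1 <- su1 * sv1; P2 <- su2 * sv2
      da <- -M * (P1 * (1 - su1) + h * P2 * (1 - su2))
      dc <- -M * (P1 * (1 - sv1) + h * P2 * (1 - sv2))
      db1 <- M * P1 * xs * (su1 - sv1)
      db2 <- M * h * P2 * x2 * (su2 - sv2)
      dd2 <- -M * h * P2 * b2 * (su2 - sv2) * d2 * (1 - d2)
      dh <- M * P2 * h * (1 - h)
      if (type == "VII") cbind(mu, da, db1, dc, dd2, dh, db2)
      else cbind(mu, da, db1 + db2, dc, dd2, dh)
    })
  as.numeric(-2 * crossprod(g, r))
}

# heuristic start in optimizer space: place a peak (or step) where the data
# put it
hof_start <- function(type, xs, ys) {
  m <- xs[which.max(ys)]
  # constant data has no defined trend; either sign works as a start
  up <- isTRUE(suppressWarnings(stats::cor(xs, ys)) >= 0)
  b0 <- if (up) -8 else 8
  switch(type,
    II  = c(0, 0, b0),
    III = c(0, 0, b0, -2),
    IV  = c(log(4), -10 * m, 10, 10 * m),
    V   = c(log(4), -10 * m, 10, 10 * m, -10),
    VI  = c(log(4), -10 * m, 10, 10 * m, 0, -2),
    VII = c(log(4), -10 * m, 10, 10 * m, 0, -2, 10))
}

hof_random_start <- function(type) {
  k <- length(hof_param_names(type))
  th <- runif(k, -5, 5)
  # width-like entries benefit from a larger range
  th[1] <- runif(1, -1, 1.5)
  if (type %in% c("II", "III", "IV", "V", "VI", "VII")) th[3] <- runif(1, -40, 40)
  if (type == "VII") th[7] <- runif(1, -40, 40)
  th
}

hof_fit_one <- function(type, xs, ys, n_restarts) {
  n <- length(xs)
  if (type == "I") {
    mu <- mean(ys)
    params <- c(M = 2 * max(mu, 1e-12), a = 0)
    rss <- sum((ys - mu)^2)
    return(list(params = params, rss = rss, converged = TRUE))
  }
  starts <- c(list(hof_start(type, xs, ys)),
              lapply(seq_len(n_restarts), function(i) hof_random_start(type)))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, hof_rss, gr = hof_rss_grad, type = type, xs = xs, ys = ys,
            method = "BFGS", control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(opt)) {
      opt <- tryCatch(
        optim(st, hof_rss, type = type, xs = xs, ys = ys,
              method = "Nelder-Mead", control = list(maxit = 500)),
        error = function(e) NULL)
    }
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) {
    return(list(params = NULL, rss = NA_real_, converged = FALSE))
  }
  # a fit that ran out of iterations is still usable; record it as converged
  # unless the optimizer failed outright
  list(params = hof_theta_to_params(best$par, type), rss = best$value,
       converged = TRUE)
}

hof_aicc <- function(rss, n, npar) {
  k <- npar + 1                      # + residual variance
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Fit all seven HOF response models to one gradient
#'
#' Internally rescales the gradient to \[0, 1\] and the abundances to maximum
#' 1, then fits each model type by Gaussian nonlinear least squares from a
#' heuristic start plus `n_restarts` random restarts. Taxa with fewer than
#' `min_occ` positive observations are skipped with a reason rather than
#' fitted.
#'
#' @param x Gradient values (any scale).
#' @param y Abundances (nonnegative).
#' @param min_occ Minimum number of positive observations (default 10).
#' @param n_restarts Random restarts per type (default 5).
#' @param seed Integer seed for the restarts; `NULL` uses the session RNG.
#' @return A tibble of class `hof_fits` with one row per type: `type`,
#'   `params` (list, on the internal scale), `rss`, `logLik`, `aicc`,
#'   `converged`. Attributes carry the scaled data and scales. If the
#'   occurrence filter rejects the taxon the tibble is empty and attribute
#'   `skip_reason` explains why.
#' @export
fit_hof_all <- function(x, y, min_occ = 10, n_restarts = 5, seed = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n_occ <- sum(y > 0)
  x_range <- range(x)
  skel <- tibble::tibble(type = character(), params = list(),
                         rss = numeric(), logLik = numeric(),
                         aicc = numeric(), converged = logical())
  if (n_occ < min_occ) {
    out <- skel
    attr(out, "skip_reason") <- paste0("minimum occurrence not met (", n_occ,
                                       " < ", min_occ, ")")
    attr(out, "n_occurrences") <- n_occ
    class(out) <- c("hof_fits", class(out))
    return(out)
  }
  if (diff(x_range) == 0) stop("gradient has zero range", call. = FALSE)
  xs <- (x - x_range[1]) / diff(x_range)
  y_scale <- max(y)
  ys <- y / y_scale
  n <- length(xs)
  rows <- with_seed_or_not(seed, lapply(hof_types, function(tp) {
    f <- hof_fit_one(tp, xs, ys, n_restarts)
    npar <- length(hof_param_names(tp))
    ll <- if (is.na(f$rss)) NA_real_ else
      -n / 2 * (log(2 * pi * max(f$rss, 1e-300) / n) + 1)
    tibble::tibble(type = tp, params = list(f$params), rss = f$rss,
                   logLik = ll,
                   aicc = if (is.na(f$rss)) NA_real_ else hof_aicc(f$rss, n, npar),
                   converged = f$converged)
  }))
  out <- dplyr::bind_rows(rows)
  attr(out, "xs") <- xs
  attr(out, "ys") <- ys
  attr(out, "x_range") <- x_range
  attr(out, "y_scale") <- y_scale
  attr(out, "n_occurrences") <- n_occ
  class(out) <- c("hof_fits", class(out))
  out
}

hof_complexity <- function(types) match(types, hof_types)

#' Select the best HOF model by AICc with bootstrap stabilisation
#'
#' Picks the AICc-minimal converged type, then re-selects on `n_boot`
#' bootstrap resamples of the observations; if the AICc choice is not the
#' modal bootstrap choice, the modal choice wins. Ties go to the
#' lower-complexity type.
#'
#' @param fits A [fit_hof_all()] result.
#' @param n_boot Number of bootstrap resamples (default 5).
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @param n_restarts Random restarts for the bootstrap refits (default 1,
#'   plus the heuristic start).
#' @return A list with `chosen_type`, `aicc_type` and `bootstrap_types`.
#' @export
select_model <- function(fits, n_boot = 5, seed = NULL, n_restarts = 1) {
  stopifnot(inherits(fits, "hof_fits"))
  ok <- fits[fits$converged & !is.na(fits$aicc), ]
  if (nrow(ok) == 0) stop("no converged HOF fit", call. = FALSE)
  aicc_type <- ok$type[order(ok$aicc, hof_complexity(ok$type))][1]
  xs <- attr(fits, "xs"); ys <- attr(fits, "ys")
  boot_types <- with_seed_or_not(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(xs), replace = TRUE)
    bt <- vapply(hof_types, function(tp) {
      f <- hof_fit_one(tp, xs[idx], ys[idx], n_restarts)
      if (!f$converged || is.na(f$rss)) return(NA_real_)
      hof_aicc(f$rss, length(idx), length(hof_param_names(tp)))
    }, numeric(1))
    if (all(is.na(bt))) NA_character_ else
      hof_types[order(bt, hof_complexity(hof_types), na.last = TRUE)][1]
  }, character(1)))
  tab <- table(factor(boot_types[!is.na(boot_types)], levels = hof_types))
  chosen <- aicc_type
  if (sum(tab) > 0) {
    modal <- names(tab)[tab == max(tab)]
    modal <- modal[order(hof_complexity(modal))][1]
    if (tab[aicc_type] < max(tab)) chosen <- modal
  }
  list(chosen_type = chosen, aicc_type = aicc_type,
       bootstrap_types = boot_types)
}

#' Extract niche optimum and edges from a fitted response curve
#'
#' Evaluates the chosen curve on a dense grid and applies the interpretation
#' rules: type I (flat) and monotone types II/III have no optimum; the
#' optimum of a unimodal type is the interior maximum of the fitted curve;
#' bimodal types VI/VII whose interior optima all lie within
#' `edge_tolerance` of the gradient range ends are interpreted as having no
#' optimum. Niche edges are the inflection points of the fitted curve
#' flanking the optimum; when a side has no interior inflection the range
#' end is used and flagged.
#'
#' @param type Chosen HOF type.
#' @param params Parameter vector on the internal \[0, 1\] gradient scale.
#' @param x_range Numeric length-2: the original gradient range.
#' @param edge_tolerance Fraction of the gradient span within which an
#'   optimum counts as "at the range edge" (default 0.05).
#' @param grid_n Grid resolution (default 2001).
#' @return A list: `optimum` (primary, in original gradient units, `NA` if
#'   none), `optima` (all interior maxima), `low_edge`, `high_edge`, and a
#'   character vector `flags`.
#' @export
niche_metrics <- function(type, params, x_range, edge_tolerance = 0.05,
                          grid_n = 2001) {
  xs <- seq(0, 1, length.out = grid_n)
  yv <- hof_curve(xs, type, params)
  to_orig <- function(u) x_range[1] + u * diff(x_range)
  none <- function(flags) list(optimum = NA_real_, optima = numeric(0),
                               low_edge = NA_real_, high_edge = NA_real_,
                               flags = flags)
  if (type %in% c("I", "II", "III")) {
    return(none(if (type == "I") "flat_no_optimum" else "monotone_no_optimum"))
  }
  # interior local maxima on the dense grid
  i <- which(diff(sign(diff(yv))) < 0) + 1
  i <- i[i > 1 & i < grid_n]
  if (!length(i)) return(none("no_interior_maximum"))
  if (type %in% c("VI", "VII")) {
    at_edge <- xs[i] <= edge_tolerance | xs[i] >= 1 - edge_tolerance
    if (all(at_edge)) return(none("optima_at_range_edges"))
  }
  opt_i <- i[which.max(yv[i])]
  flags <- character(0)
  d2 <- diff(yv, differences = 2)          # second derivative sign pattern
  sgn <- sign(d2)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0) + 1
  lo <- flips[flips < opt_i - 1]
  hi <- flips[flips > opt_i - 1]
  if (length(lo)) low_edge <- xs[max(lo) + 1] else {
    low_edge <- 0; flags <- c(flags, "low_edge_at_range_end")
  }
  if (length(hi)) high_edge <- xs[min(hi) + 1] else {
    high_edge <- 1; flags <- c(flags, "high_edge_at_range_end")
  }
  list(optimum = to_orig(xs[opt_i]), optima = to_orig(xs[i]),
       low_edge = to_orig(low_edge), high_edge = to_orig(high_edge),
       flags = if (length(flags)) flags else "ok")
}

#' Fit a niche response model for one taxon on one gradient
#'
#' One-stop wrapper: [fit_hof_all()] + [select_model()] + [niche_metrics()]
#' on columns of a data frame.
#'
#' @param data A data frame.
#' @param gradient,abundance Column names (strings) or bare column names of
#'   the gradient and abundance.
#' @param min_occ,n_restarts,n_boot,edge_tolerance,seed Passed to the
#'   component steps.
#' @return An object of class `hof_fit`: the per-type `fits`, `chosen_type`,
#'   `bootstrap_types`, `niche`, `n_occurrences`, `x_range` and the data.
#' @export
fit_hof <- function(data, gradient, abundance, min_occ = 10, n_restarts = 5,
                    n_boot = 5, edge_tolerance = 0.05, seed = NULL) {
  x <- dplyr::pull(data, {{ gradient }})
  y <- dplyr::pull(data, {{ abundance }})
  fits <- fit_hof_all(x, y, min_occ = min_occ, n_restarts = n_restarts,
                      seed = seed)
  if (nrow(fits) == 0) {
    return(structure(list(fits = fits, chosen_type = NA_character_,
                          bootstrap_types = character(0),
                          niche = NULL, n_occurrences = attr(fits, "n_occurrences"),
                          skip_reason = attr(fits, "skip_reason"),
                          x_range = range(x), x = x, y = y),
                     class = "hof_fit"))
  }
  sel <- select_model(fits, n_boot = n_boot, seed = seed)
  params <- fits$params[[match(sel$chosen_type, fits$type)]]
  niche <- niche_metrics(sel$chosen_type, params, attr(fits, "x_range"),
                         edge_tolerance = edge_tolerance)
  structure(list(fits = fits, chosen_type = sel$chosen_type,
                 aicc_type = sel$aicc_type,
                 bootstrap_types = sel$bootstrap_types, niche = niche,
                 n_occurrences = attr(fits, "n_occurrences"),
                 skip_reason = NULL,
                 x_range = attr(fits, "x_range"),
                 y_scale = attr(fits, "y_scale"), x = x, y = y),
            class = "hof_fit")
}

#' @export
print.hof_fit <- function(x, ...) {
  if (!is.null(x$skip_reason)) {
    cat("<hof_fit> skipped:", x$skip_reason, "\n")
    return(invisible(x))
  }
  cat("<hof_fit> chosen type", x$chosen_type,
      "(AICc choice", paste0(x$aicc_type, ";"),
      "bootstrap:", paste(x$bootstrap_types, collapse = ","), ")\n")
  if (is.na(x$niche$optimum)) {
    cat("  no niche optimum (", paste(x$niche$flags, collapse = ", "), ")\n")
  } else {
    cat(sprintf("  optimum %.4g, edges [%.4g, %.4g]\n",
                x$niche$optimum, x$niche$low_edge, x$niche$high_edge))
  }
  invisible(x)
}

#' @export
tidy.hof_fit <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x$fits), -"params")
}

#' @rdname fit_hof
#' @param x A `hof_fit`.
#' @param ... Unused.
#' @export
glance.hof_fit <- function(x, ...) {
  if (!is.null(x$skip_reason)) {
    return(tibble::tibble(type = NA_character_, optimum = NA_real_,
                          low_edge = NA_real_, high_edge = NA_real_,
                          n_occurrences = x$n_occurrences,
                          flags = x$skip_reason))
  }
  tibble::tibble(type = x$chosen_type, optimum = x$niche$optimum,
                 low_edge = x$niche$low_edge, high_edge = x$niche$high_edge,
                 n_occurrences = x$n_occurrences,
                 flags = paste(x$niche$flags, collapse = ";"))
}

#' Niche records for every taxon along one gradient
#'
#' Applies [fit_hof()] to each row of an abundance table against a chosen
#' environmental gradient and collects the niche records (the CSV-exportable
#' summary: taxon, gradient, chosen type, optimum, edges, flags).
#'
#' @param abund Abundance table (taxa as rows).
#' @param env Environment table sharing samples with `abund`.
#' @param gradient Name of the env column to use as gradient.
#' @param ... Passed to [fit_hof()].
#' @return A tibble with one row per taxon and a `fit` list-column.
#' @export
fit_niche_all <- function(abund, env, gradient, ...) {
  samples <- shared_samples(abund, env)
  x <- env[[gradient]][match(samples, env$sample_id)]
  m <- abund_matrix_raw(tibble::as_tibble(abund))[, samples, drop = FALSE]
  purrr::map_dfr(rownames(m), function(tx) {
    f <- fit_hof(tibble::tibble(g = x, a = m[tx, ]), g, a, ...)
    dplyr::bind_cols(tibble::tibble(taxon_id = tx, gradient = gradient),
                     glance(f), tibble::tibble(fit = list(f)))
  })
}

#' @rdname fit_hof
#' @param object A `hof_fit`.
#' @export
autoplot.hof_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "gradient", y = "abundance")
  if (is.null(x_range <- object$x_range) || !is.null(object$skip_reason)) {
    return(p)
  }
  xs <- seq(0, 1, length.out = 400)
  params <- object$fits$params[[match(object$chosen_type, object$fits$type)]]
  curve_df <- tibble::tibble(
    x = x_range[1] + xs * diff(x_range),
    y = hof_curve(xs, object$chosen_type, params) * object$y_scale)
  p <- p + ggplot2::geom_line(data = curve_df, colour = "steelblue",
                              linewidth = 1) +
    ggplot2::ggtitle(paste("HOF type", object$chosen_type))
  if (!is.na(object$niche$optimum)) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$niche$optimum,
                          linetype = "dashed") +
      ggplot2::geom_vline(xintercept = c(object$niche$low_edge,
                                         object$niche$high_edge),
                          linetype = "dotted", colour = "grey40")
  }
  p
}
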