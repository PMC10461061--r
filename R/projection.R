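#' Project taxon abundances under a future driver scenario
#'
#' Pushes a scenario of future exogenous drivers through the fitted
#' structural equations: endogenous drivers not supplied by the scenario
#' (e.g. future vegetation or organic carbon) are propagated through their
#' equations in topological order, then every taxon's abundance is predicted
#' from its fitted equation. Negative predictions are truncated to 0 and
#' counted.
#'
#' @param fits A `sem_fit_batch` from [fit_many()] (or a single `sem_fit`).
#' @param current Current [env_table()]; every scenario sample must appear
#'   here (sample ids are matched).
#' @param scenario Tibble with `sample_id`, all exogenous driver columns,
#'   and optionally future values for endogenous drivers (supplied columns
#'   win over propagation).
#' @return A `"values"`-mode abundance table (taxa x samples) of predicted
#'   future abundances; attribute `n_truncated` counts clamped predictions
#'   and attribute `propagated` names the drivers that were propagated.
#' @export
project_future <- function(fits, current, scenario) {
  if (inherits(fits, "sem_fit")) {
    fits <- tibble::tibble(taxon_id = fits$response, ok = TRUE,
                           fit = list(fits))
  }
  ok <- fits[fits$ok, ]
  if (!nrow(ok)) stop("no successful fits to project from", call. = FALSE)
  f1 <- ok$fit[[1]]
  spec <- f1$spec
  taxon <- f1$response
  scenario <- tibble::as_tibble(scenario)
  miss_s <- setdiff(current$sample_id, scenario$sample_id)
  if (length(miss_s)) {
    stop("scenario missing sample(s): ", paste(head(miss_s, 5), collapse = ", "),
         call. = FALSE)
  }
  scenario <- scenario[match(current$sample_id, scenario$sample_id), ]
  miss_x <- setdiff(spec$exogenous, names(scenario))
  if (length(miss_x)) {
    stop("scenario missing exogenous driver(s): ",
         paste(miss_x, collapse = ", "), call. = FALSE)
  }
  drivers <- setdiff(spec$endogenous, taxon)
  future <- as.data.frame(scenario[intersect(names(scenario),
                                             c("sample_id", spec$variables))])
  propagated <- character(0)
  for (v in drivers) {
    if (!v %in% names(future)) {
      future[[v]] <- predict_conditional(f1, future, node = v)
      propagated <- c(propagated, v)
    }
  }
  preds <- vapply(seq_len(nrow(ok)), function(i) {
    predict_conditional(ok$fit[[i]], future)
  }, numeric(nrow(future)))
  m <- t(preds)
  dimnames(m) <- list(ok$taxon_id, scenario$sample_id)
  n_trunc <- sum(m < 0)
  m[m < 0] <- 0
  out <- abundance_table(m, mode = "values")
  attr(out, "n_truncated") <- n_trunc
  attr(out, "propagated") <- propagated
  out
}

#' ln-fold changes between current and future abundances
#'
#' `ln(future / current)` per cell. To avoid infinite changes at zeros, any
#' zero in either matrix is first replaced by half the lowest positive
#' *current* value over the taxon set being analyzed (e.g. a lowest current
#' relative abundance of 0.066 gives a replacement of 0.033).
#'
#' @param current,future Wide taxa-by-sample tables with matching taxa and
#'   samples.
#' @return A tibble of ln-fold changes (same shape); attribute
#'   `zero_replacement` holds the replacement value.
#' @export
lnfold_change <- function(current, future) {
  mc <- abund_matrix(current)
  mf <- abund_matrix(future)
  if (!identical(dim(mc), dim(mf)) ||
      !identical(rownames(mc), rownames(mf)) ||
      !identical(colnames(mc), colnames(mf))) {
    mf <- tryCatch(mf[rownames(mc), colnames(mc), drop = FALSE],
                   error = function(e) stop("current and future tables do not match",
                                            call. = FALSE))
  }
  pos <- mc[mc > 0]
  if (!length(pos)) stop("no positive current abundance: zero replacement undefined",
                         call. = FALSE)
  repl <- 0.5 * min(pos)
  mc[mc == 0] <- repl
  mf[mf == 0] <- repl
  out <- abundance_table(log(mf / mc), mode = "values")
  attr(out, "zero_replacement") <- repl
  out
}

#' Bray-Curtis dissimilarities between samples
#'
#' `BC(u, v) = sum|u - v| / sum(u + v)` over the taxa of each sample pair;
#' symmetric with zero diagonal and values in \[0, 1\].
#'
#' @param tbl Wide taxa-by-sample table with nonnegative values.
#' @return A symmetric dissimilarity matrix (samples x samples).
#' @export
bray_curtis <- function(tbl) {
  m <- abund_matrix(tbl)
  if (any(m < 0)) stop("negative abundance values", call. = FALSE)
  zero <- colnames(m)[colSums(m) == 0]
  if (length(zero)) {
    stop("sample(s) with zero total: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Principal coordinates of a dissimilarity matrix
#'
#' Metric ordination by Gower double-centering of `-D^2/2` and
#' eigendecomposition; axes are ordered by eigenvalue, and axes belonging to
#' negative eigenvalues are dropped (the eigenvalues themselves are
#' reported).
#'
#' @param D Square symmetric dissimilarity matrix (or `dist`).
#' @param n_axes Number of axes to return (default 2; capped at the number
#'   of positive-eigenvalue axes).
#' @return A list of class `pcoa_ord`: `coordinates` (tibble `sample_id`,
#'   `axis_1`, ...), `eigenvalues` (all, nonincreasing), `n_negative`.
#' @export
pcoa_ordination <- function(D, n_axes = 2) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("D must be square and symmetric", call. = FALSE)
  }
  ids <- rownames(D) %||% sprintf("s%04d", seq_len(nrow(D)))
  res <- ape::pcoa(as.dist(D))
  ev <- res$values$Eigenvalues
  vec <- res$vectors
  n_axes <- min(n_axes, ncol(vec))
  coords <- tibble::as_tibble(vec[, seq_len(n_axes), drop = FALSE],
                              .name_repair = ~ paste0("axis_", seq_len(n_axes)))
  structure(list(coordinates = dplyr::bind_cols(
                   tibble::tibble(sample_id = ids), coords),
                 eigenvalues = ev, n_negative = sum(ev < 0)),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("<pcoa_ord>", nrow(x$coordinates), "samples,",
      ncol(x$coordinates) - 1, "axes kept;",
      x$n_negative, "negative eigenvalue(s)\n")
  invisible(x)
}

#' Per-site ordination displacement between two periods
#'
#' Euclidean distance between a site's (axis 1, axis 2) positions in the two
#' periods of a stacked current+future ordination.
#'
#' @param ord A [pcoa_ordination()] result on the stacked matrix (or its
#'   `coordinates` tibble).
#' @param current_ids,future_ids Sample ids of the same sites in the two
#'   periods, aligned element-wise.
#' @param site_ids Optional site names (defaults to `current_ids`).
#' @return A tibble: `site`, `displacement` (>= 0).
#' @export
displacement <- function(ord, current_ids, future_ids, site_ids = NULL) {
  coords <- if (inherits(ord, "pcoa_ord")) ord$coordinates else ord
  stopifnot(length(current_ids) == length(future_ids))
  i <- match(current_ids, coords$sample_id)
  j <- match(future_ids, coords$sample_id)
  if (anyNA(i) || anyNA(j)) stop("unmatched site id(s)", call. = FALSE)
  dx <- coords$axis_1[i] - coords$axis_1[j]
  dy <- coords$axis_2[i] - coords$axis_2[j]
  tibble::tibble(site = site_ids %||% current_ids,
                 displacement = sqrt(dx^2 + dy^2))
}

#' Community-weighted functional profiles from a gene copy table
#'
#' Projects taxon abundances onto gene (e.g. KEGG Ortholog) relative
#' abundances: the per-sample gene profile is the trait-table transpose
#' times the sample's abundance column, renormalized to relative mode. Taxa
#' absent from the trait table are dropped and the dropped fraction
#' reported.
#'
#' @param abund Wide taxa-by-sample abundance table (nonnegative).
#' @param trait_table Tibble `taxon_id` plus one nonnegative column per gene
#'   (copy numbers).
#' @return A relative-mode gene-by-sample abundance table; attribute
#'   `dropped_fraction` is the fraction of taxa without a trait entry.
#' @export
functional_projection <- function(abund, trait_table) {
  A <- abund_matrix(abund)
  tt <- tibble::as_tibble(trait_table)
  genes <- setdiff(names(tt), "taxon_id")
  shared <- intersect(rownames(A), tt$taxon_id)
  if (!length(shared)) stop("no taxa shared with the trait table", call. = FALSE)
  dropped <- 1 - length(shared) / nrow(A)
  if (dropped > 0) {
    message(sprintf("dropping %.1f%% of taxa without a trait-table match",
                    100 * dropped))
  }
  Tm <- as.matrix(as.data.frame(tt)[match(shared, tt$taxon_id), genes])
  rownames(Tm) <- shared
  G <- t(Tm) %*% A[shared, , drop = FALSE]
  cs <- colSums(G)
  if (any(cs == 0)) stop("sample(s) with zero total gene abundance", call. = FALSE)
  out <- abundance_table(sweep(G, 2, cs, "/"), mode = "relative")
  attr(out, "dropped_fraction") <- dropped
  out
}

#' Inverse-distance-weighted gridding of point values
#'
#' Interpolates irregular lon/lat point values onto a regular square grid
#' (default 0.2 degree resolution) covering the bounding box, for simple
#' continental maps of ln-fold change or displacement. Power-2
#' inverse-distance weights over neighbours within `cutoff` degrees; cells
#' with no neighbour inside the cutoff are `NA`; a grid node coinciding with
#' a data point takes that point's value exactly.
#'
#' @param data Tibble with `lon`, `lat` and a value column.
#' @param value Name of the value column (default `"value"`).
#' @param resolution Grid spacing in degrees (default 0.2).
#' @param power IDW exponent (default 2).
#' @param cutoff Masking radius in degrees (default 2).
#' @return A tibble: `lon`, `lat`, `value` (one row per grid cell).
#' @export
grid_interpolate <- function(data, value = "value", resolution = 0.2,
                             power = 2, cutoff = 2) {
  stopifnot(resolution > 0, nrow(data) >= 3)
  lon <- data$lon; lat <- data$lat; v <- data[[value]]
  if (diff(range(lon)) == 0 || diff(range(lat)) == 0) {
    stop("degenerate bounding box", call. = FALSE)
  }
  gx <- seq(min(lon), max(lon), by = resolution)
  gy <- seq(min(lat), max(lat), by = resolution)
  grid <- expand.grid(lon = gx, lat = gy, KEEP.OUT.ATTRS = FALSE)
  val <- vapply(seq_len(nrow(grid)), function(i) {
    d2 <- (lon - grid$lon[i])^2 + (lat - grid$lat[i])^2
    hit <- which(d2 < 1e-18)
    if (length(hit)) return(v[hit[1]])
    near <- d2 <= cutoff^2
    if (!any(near)) return(NA_real_)
    w <- 1 / d2[near]^(power / 2)
    sum(w * v[near]) / sum(w)
  }, numeric(1))
  tibble::tibble(lon = grid$lon, lat = grid$lat, value = val)
}

#' @rdname grid_interpolate
#' @param grid A gridded tibble from `grid_interpolate()`.
#' @export
plot_grid_map <- function(grid) {
  ggplot2::ggplot(grid[!is.na(grid$value), ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude")
}
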