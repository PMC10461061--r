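#' Assemble the taxa-by-driver standardized coefficient matrix
#'
#' Collects the nine standardized direct paths of every successful fit in a
#' [fit_many()] batch into one wide tibble, columns in the canonical driver
#' order (MAT, humidity, precipitation, C3 macrothermal, C3 mesothermal,
#' C4 megathermal, OC, conductivity, pH). Failed fits are dropped and listed
#' in attribute `excluded`.
#'
#' @param fits A `sem_fit_batch` from [fit_many()], or a named list of
#'   `sem_fit` objects.
#' @param driver_order Column order (default [driver_names()] with the Fig-2
#'   family grouping: climate, vegetation, soil).
#' @return A tibble: `taxon_id` plus one column per driver.
#' @export
coefficient_matrix <- function(fits, driver_order = c(
                                 sn_climate, sn_vegetation, sn_soil)) {
  if (inherits(fits, "sem_fit_batch")) {
    fit_list <- setNames(fits$fit, fits$taxon_id)
    excluded <- fits$taxon_id[!fits$ok]
    fit_list <- fit_list[fits$ok]
  } else {
    fit_list <- fits
    excluded <- names(fit_list)[!vapply(fit_list, inherits, logical(1), "sem_fit")]
    fit_list <- fit_list[setdiff(names(fit_list), excluded)]
  }
  if (!length(fit_list)) stop("no successful fits", call. = FALSE)
  parent_sets <- lapply(fit_list, function(f) sort(f$spec$parents[[f$response]]))
  if (length(unique(parent_sets)) != 1) {
    stop("fits have inconsistent topologies", call. = FALSE)
  }
  miss <- setdiff(driver_order, parent_sets[[1]])
  if (length(miss)) {
    stop("fit topology lacks direct path(s) from: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- purrr::imap_dfr(fit_list, function(f, tx) {
    cf <- f$coefficients[f$coefficients$child == f$response, ]
    std <- setNames(cf$std_estimate, cf$parent)[driver_order]
    dplyr::bind_cols(tibble::tibble(taxon_id = tx),
                     tibble::as_tibble(as.list(std)))
  })
  if (length(excluded)) {
    message("excluding ", length(excluded), " failed fit(s): ",
            paste(head(excluded, 5), collapse = ", "))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Ternary soil/vegetation/climate coordinates
#'
#' Converts a taxa-by-driver coefficient table into the relative influence of
#' the three driver families: each axis is 100 times the sum of absolute
#' standardized coefficients in that family divided by the sum of all nine
#' absolute coefficients, so the three axes sum to 100. The transform is
#' invariant to rescaling a taxon's coefficient vector by a positive
#' constant.
#'
#' @param coeffs Tibble with `taxon_id` and the nine driver columns (as from
#'   [coefficient_matrix()]).
#' @return A tibble: `taxon_id`, `soil`, `vegetation`, `climate` (percent).
#' @export
#' @examples
#' cm <- tibble::tibble(taxon_id = "t", MAT = 0.2, humidity = 0.2,
#'   precipitation = 0.2, C3_macrothermal = 0.2, C3_mesothermal = 0.2,
#'   C4_megathermal = 0.2, OC = 0.2, conductivity = 0.2, pH = 0.2)
#' ternary_coordinates(cm)
ternary_coordinates <- function(coeffs) {
  fam <- driver_families()
  miss <- setdiff(driver_names(), names(coeffs))
  if (length(miss)) {
    stop("missing coefficient column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- abs(as.matrix(as.data.frame(coeffs)[driver_names()]))
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("all-zero coefficient row(s): ",
         paste(coeffs$taxon_id[tot == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    taxon_id = coeffs$taxon_id,
    soil = 100 * rowSums(m[, fam$soil, drop = FALSE]) / tot,
    vegetation = 100 * rowSums(m[, fam$vegetation, drop = FALSE]) / tot,
    climate = 100 * rowSums(m[, fam$climate, drop = FALSE]) / tot)
}

#' Ward clustering of taxa into environmental response groups
#'
#' Hierarchically clusters the taxa-by-driver coefficient rows with Euclidean
#' distances and Ward's minimum-variance linkage (`hclust` method
#' `"ward.D2"`). With `k = "auto"`, average silhouette widths are scanned
#' over `k_range` and the maximizer chosen; the default `k = 10` matches the
#' grouping used for the ternary/niche displays. Agglomeration is
#' deterministic; ties are broken by row order.
#'
#' @param coeffs Tibble with `taxon_id` and driver columns.
#' @param k Number of groups (default 10) or `"auto"`.
#' @param k_range Candidate group counts scanned in auto mode (default 2:15).
#' @return A list of class `ward_clusters`: `labels` (tibble `taxon_id`,
#'   `cluster`), `k`, `hclust`, and `silhouette` (tibble of average
#'   silhouette width per candidate `k`).
#' @export
ward_cluster <- function(coeffs, k = 10, k_range = 2:15) {
  m <- as.matrix(as.data.frame(coeffs)[setdiff(names(coeffs), "taxon_id")])
  rownames(m) <- coeffs$taxon_id
  d <- dist(m)
  hc <- hclust(d, method = "ward.D2")
  k_range <- k_range[k_range < nrow(m)]
  sil <- purrr::map_dfr(k_range, function(kk) {
    lab <- cutree(hc, kk)
    sw <- cluster::silhouette(lab, d)
    tibble::tibble(k = kk, avg_silhouette = mean(sw[, "sil_width"]))
  })
  if (identical(k, "auto")) {
    k <- sil$k[which.max(sil$avg_silhouette)]
  }
  if (k > nrow(m)) stop("k exceeds the number of taxa", call. = FALSE)
  labels <- cutree(hc, k)
  structure(list(labels = tibble::tibble(taxon_id = rownames(m),
                                         cluster = unname(labels)),
                 k = k, hclust = hc, silhouette = sil),
            class = "ward_clusters")
}

#' @export
print.ward_clusters <- function(x, ...) {
  cat("<ward_clusters> k =", x$k, "groups over", nrow(x$labels), "taxa\n")
  print(table(x$labels$cluster))
  invisible(x)
}

#' @rdname ward_cluster
#' @param x,object A `ward_clusters`.
#' @param ... Unused.
#' @export
tidy.ward_clusters <- function(x, ...) x$labels

#' @rdname ward_cluster
#' @export
autoplot.ward_clusters <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$avg_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of groups",
                  y = "average silhouette width")
}

#' Ternary scatter of driver-family influence
#'
#' Projects the soil/vegetation/climate percentages onto the 2-D simplex and
#' draws the taxa, optionally coloured by cluster.
#'
#' @param ternary Tibble from [ternary_coordinates()].
#' @param labels Optional tibble (`taxon_id`, `cluster`) from
#'   [ward_cluster()].
#' @return A ggplot.
#' @export
plot_ternary <- function(ternary, labels = NULL) {
  df <- ternary
  if (!is.null(labels)) df <- dplyr::left_join(df, labels, by = "taxon_id")
  # barycentric -> planar: corners soil (0,0), vegetation (1,0),
  # climate (0.5, sqrt(3)/2)
  df$px <- (df$vegetation + df$climate / 2) / 100
  df$py <- sqrt(3) / 2 * df$climate / 100
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey50") +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::annotate("text", x = c(0, 1, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.04),
                      label = c("soil", "vegetation", "climate"))
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)),
                            size = 2) +
      ggplot2::labs(colour = "group")
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
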