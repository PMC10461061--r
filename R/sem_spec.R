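#' Specify a recursive causal network (path-analysis model)
#'
#' A `sem_spec` describes a directed acyclic graph over observed variables:
#' which variables are exogenous (freely correlated, no parents) and which
#' directed edges carry free path coefficients. Every endogenous variable gets
#' a free intercept and residual variance; the exogenous covariance matrix is
#' saturated.
#'
#' @param edges A data frame with columns `parent` and `child`, one row per
#'   directed path.
#' @param exogenous Character vector of exogenous variable names.
#' @param variables Optional full variable set; defaults to the union of edge
#'   endpoints and `exogenous`. Any declared variable missing from both is an
#'   isolated exogenous variable.
#' @return An object of class `sem_spec` with components `variables`, `edges`,
#'   `exogenous`, `endogenous` (in topological order), and `parents` (named
#'   list).
#' @seealso [default_sem_spec()] for the packaged soil-bacteria topology.
#' @export
#' @examples
#' sem_spec(data.frame(parent = "x", child = "y"), exogenous = "x")
sem_spec <- function(edges, exogenous, variables = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges <- dplyr::mutate(edges,
                         parent = as.character(.data$parent),
                         child = as.character(.data$child))
  exogenous <- as.character(exogenous)
  vars <- union(variables %||% character(0),
                union(unique(c(edges$parent, edges$child)), exogenous))
  undeclared <- setdiff(c(edges$parent, edges$child), vars)
  if (length(undeclared)) {
    stop("undeclared variable(s): ", paste(unique(undeclared), collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$child %in% exogenous)) {
    bad <- intersect(unique(edges$child), exogenous)
    stop("exogenous variable(s) cannot have parents: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) {
    stop("duplicated edge", call. = FALSE)
  }
  endog <- setdiff(vars, exogenous)
  endog <- topo_sort(endog, edges)   # errors on cycles
  parents <- lapply(setNames(endog, endog),
                    function(v) edges$parent[edges$child == v])
  structure(
    list(variables = c(exogenous, endog), edges = edges,
         exogenous = exogenous, endogenous = endog, parents = parents),
    class = "sem_spec")
}

# Kahn's algorithm over the endogenous set; exogenous nodes have no parents
# by construction so only endogenous ordering matters
topo_sort <- function(endog, edges) {
  order <- character(0)
  remaining <- endog
  placed <- setdiff(unique(c(edges$parent, edges$child)), endog)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      all(edges$parent[edges$child == v] %in% c(placed, order))
    }, logical(1))]
    if (!length(ready)) {
      stop("cycle detected among: ", paste(remaining, collapse = ", "),
           call. = FALSE)
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default soil-bacteria causal topology
#'
#' The packaged network links the nine environmental drivers to one taxon
#' node. Climate (MAT, humidity, precipitation), pH and conductivity are
#' exogenous and freely correlated. Each vegetation coverage depends on the
#' three climate variables; organic carbon depends on conductivity, pH,
#' humidity, precipitation and C3 macrothermal coverage; the taxon node
#' depends on all nine drivers.
#'
#' @param taxon Name of the terminal taxon node (default `"taxon"`).
#' @return A [sem_spec()].
#' @export
default_sem_spec <- function(taxon = "taxon") {
  veg_edges <- expand.grid(parent = sn_climate, child = sn_vegetation,
                           stringsAsFactors = FALSE)
  oc_edges <- data.frame(
    parent = c("conductivity", "pH", "humidity", "precipitation",
               "C3_macrothermal"),
    child = "OC")
  taxon_edges <- data.frame(parent = driver_names(), child = taxon)
  sem_spec(rbind(veg_edges, oc_edges, taxon_edges),
           exogenous = c(sn_climate, "pH", "conductivity"))
}

#' Build a causal-network spec from a config list
#'
#' Thin constructor over [sem_spec()] accepting the list form produced by
#' reading a YAML/JSON network description: `list(edges = <data frame or list
#' of c(parent, child)>, exogenous = <chr>, variables = <chr>)`.
#'
#' @param config A list with `edges`, `exogenous` and optionally `variables`,
#'   or `NULL` for the default topology.
#' @param taxon Taxon-node name used when `config` is `NULL`.
#' @return A [sem_spec()].
#' @export
build_spec <- function(config = NULL, taxon = "taxon") {
  if (is.null(config)) return(default_sem_spec(taxon))
  edges <- config$edges
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      data.frame(parent = e[[1]], child = e[[2]])
    }))
  }
  sem_spec(edges, exogenous = config$exogenous, variables = config$variables)
}

# number of free parameters in the covariance structure: one per edge, one
# residual variance per endogenous variable, and the saturated exogenous
# covariance block (means/intercepts are saturated and do not enter)
n_free_params <- function(spec) {
  q <- length(spec$exogenous)
  nrow(spec$edges) + length(spec$endogenous) + q * (q + 1) / 2
}

# the unique childless endogenous node, used as the default response
sink_node <- function(spec) {
  sinks <- setdiff(spec$endogenous, spec$edges$parent)
  if (length(sinks) != 1) {
    stop("response node is ambiguous (", length(sinks),
         " childless endogenous nodes); pass `response` explicitly",
         call. = FALSE)
  }
  sinks
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("<sem_spec> ", length(x$variables), " variables, ",
      nrow(x$edges), " paths\n", sep = "")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n", sep = "")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.sem_spec <- function(x, ...) x$edges
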