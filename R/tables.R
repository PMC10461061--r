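#' Abundance tables
#'
#' An abundance table is a wide tibble with a `taxon_id` column followed by
#' one numeric column per sample (taxa as rows, matching the usual OTU-table
#' orientation). The table's `mode` attribute records whether the values are
#' sequencing `"counts"` or `"relative"` abundances; in relative mode every
#' sample column must sum to 1 (within 1e-8).
#'
#' @param x A data frame with a `taxon_id` column and numeric sample columns,
#'   or a numeric matrix with taxa as rownames and samples as colnames.
#' @param mode `"counts"`, `"relative"`, or `"values"` for unconstrained
#'   model-scale quantities (synthetic linear abundances, projections).
#' @param validate Check the mode invariants (nonnegative values; relative
#'   columns summing to 1)? `"values"` mode has none.
#' @return A tibble of class `sn_abund` with attribute `abund_mode`.
#' @export
#' @examples
#' m <- matrix(c(6, 4, 1, 9), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' abundance_table(m, mode = "counts")
abundance_table <- function(x, mode = c("counts", "relative", "values"),
                            validate = TRUE) {
  mode <- match.arg(mode)
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
    dup <- colnames(x)[duplicated(colnames(x))]
    if (length(dup)) {
      stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    }
    x <- tibble::as_tibble(x, rownames = "taxon_id")
  }
  x <- tibble::as_tibble(x)
  if (!"taxon_id" %in% names(x)) {
    stop("abundance table needs a 'taxon_id' column", call. = FALSE)
  }
  x$taxon_id <- as.character(x$taxon_id)
  x <- dplyr::relocate(x, "taxon_id")
  dup <- x$taxon_id[duplicated(x$taxon_id)]
  if (length(dup)) {
    stop("duplicated taxon id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- names(x)[-1][duplicated(names(x)[-1])]
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  vals <- abund_matrix_raw(x)
  if (validate && mode != "values") {
    if (any(!is.finite(vals))) stop("non-finite abundance values", call. = FALSE)
    if (any(vals < 0)) stop("abundance values must be nonnegative", call. = FALSE)
    if (mode == "relative") {
      cs <- colSums(vals)
      bad <- which(abs(cs - 1) > 1e-8)
      if (length(bad)) {
        stop("relative-mode columns must sum to 1; offending sample(s): ",
             paste(colnames(vals)[bad], collapse = ", "), call. = FALSE)
      }
    }
  }
  attr(x, "abund_mode") <- mode
  class(x) <- c("sn_abund", class(x))
  x
}

#' @rdname abundance_table
#' @param tbl An abundance table (or any wide taxa-by-samples tibble).
#' @export
abund_mode <- function(tbl) attr(tbl, "abund_mode")

# matrix view without class checks (taxa x samples)
abund_matrix_raw <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "taxon_id")])
  if (!is.numeric(m)) stop("non-numeric abundance values", call. = FALSE)
  rownames(m) <- tbl$taxon_id
  m
}

#' @rdname abundance_table
#' @export
abund_matrix <- function(tbl) abund_matrix_raw(tibble::as_tibble(tbl))

#' Environment tables
#'
#' A sample-by-driver tibble with a `sample_id` column, the nine environmental
#' drivers (see [driver_names()]) and optional `lon`/`lat` coordinates in
#' decimal degrees. Units follow field convention: MAT in degrees C, humidity
#' in %, precipitation in mm, vegetation coverages as fractions, conductivity
#' in dS/m, OC in %, pH unitless.
#'
#' @param x A data frame with `sample_id` and (at least) the driver columns
#'   present in `require`.
#' @param require Driver columns that must be present; defaults to all nine.
#' @return A tibble of class `sn_env`.
#' @export
env_table <- function(x, require = driver_names()) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    stop("environment table needs a 'sample_id' column", call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(require, names(x))
  if (length(miss)) {
    stop("missing required environment column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(names(x), "sample_id")
  bad <- num[!vapply(x[num], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric environment column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(attr(x, "log10_transformed"))) {
    attr(x, "log10_transformed") <- character(0)
  }
  class(x) <- unique(c("sn_env", class(x)))
  x
}

# samples shared between an abundance table and an env table, in env order
shared_samples <- function(abund, env) {
  s <- intersect(env$sample_id, setdiff(names(abund), "taxon_id"))
  if (!length(s)) stop("no shared samples between tables", call. = FALSE)
  s
}
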