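#' Read and write abundance, environment and taxonomy tables
#'
#' Abundance tables are TSV with taxa as rows; the first line is a metadata
#' comment `# mode: counts|relative|values` written by [write_abundance()] so
#' a round trip preserves the mode. Environment tables are CSV with a
#' `sample_id` column; taxonomy maps are TSV with `taxon_id` plus the lineage
#' ranks kingdom..genus (empty cells mark unassigned levels). Trees travel as
#' newick via [ape::read.tree()]/[ape::write.tree()].
#'
#' @param path File to read or write.
#' @param mode Abundance mode; `"auto"` (default) takes the file's metadata
#'   line, falling back to `"counts"` when all values are whole numbers and
#'   `"relative"` otherwise.
#' @return `read_abundance()` an abundance table; `read_env()` an [env_table()];
#'   `read_taxonomy()` a taxonomy tibble. Writers return `path` invisibly.
#' @name soilniche_io
NULL

#' @rdname soilniche_io
#' @export
read_abundance <- function(path, mode = "auto") {
  first <- readLines(path, n = 1)
  file_mode <- NULL
  if (grepl("^#\\s*mode:", first)) {
    file_mode <- trimws(sub("^#\\s*mode:", "", first))
  }
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(tbl)[1] <- "taxon_id"
  if (mode == "auto") {
    m <- abund_matrix_raw(tbl)
    mode <- file_mode %||%
      (if (all(m == round(m))) "counts" else "relative")
  }
  abundance_table(tbl, mode = mode)
}

#' @rdname soilniche_io
#' @param tbl Table to write.
#' @export
write_abundance <- function(tbl, path) {
  mode <- abund_mode(tbl) %||% "values"
  writeLines(paste0("# mode: ", mode), path)
  readr::write_tsv(tibble::as_tibble(tbl), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname soilniche_io
#' @param require Driver columns that must be present.
#' @export
read_env <- function(path, require = driver_names()) {
  env_table(readr::read_csv(path, show_col_types = FALSE), require = require)
}

#' @rdname soilniche_io
#' @export
write_env <- function(tbl, path) {
  readr::write_csv(tibble::as_tibble(tbl), path)
  invisible(path)
}

# lineage ranks, coarse to fine
sn_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' @rdname soilniche_io
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(tx)[1] <- "taxon_id"
  miss <- setdiff(sn_ranks, names(tx))
  if (length(miss)) {
    stop("taxonomy missing rank column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- tx$taxon_id[duplicated(tx$taxon_id)]
  if (length(dup)) {
    stop("duplicated taxon id(s) in taxonomy: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tx)
}

#' @rdname soilniche_io
#' @export
write_taxonomy <- function(tbl, path) {
  readr::write_tsv(tibble::as_tibble(tbl), path)
  invisible(path)
}

#' Rarefy a counts table to fixed depth
#'
#' Standardizes per-sample sampling effort by drawing exactly `depth` reads
#' without replacement from each sample (default 22,500 reads). Samples with
#' fewer total reads than `depth` are dropped and reported, never up-sampled.
#'
#' @param tbl Counts-mode abundance table.
#' @param depth Target reads per sample (default 22500).
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A counts-mode abundance table whose retained columns each sum to
#'   exactly `depth`; dropped sample ids are in attribute `dropped_samples`.
#' @export
rarefy <- function(tbl, depth = 22500, seed = NULL) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (!identical(abund_mode(tbl), "counts")) {
    stop("rarefy() needs a counts-mode table", call. = FALSE)
  }
  m <- abund_matrix(tbl)
  totals <- colSums(m)
  drop <- colnames(m)[totals < depth]
  if (length(drop)) {
    message("dropping ", length(drop), " sample(s) below depth ", depth, ": ",
            paste(drop, collapse = ", "))
  }
  keep <- m[, totals >= depth, drop = FALSE]
  if (ncol(keep) == 0) stop("no sample reaches the rarefaction depth",
                            call. = FALSE)
  # vegan heuristically warns when a table has no singleton counts; harmless
  # for synthetic fixtures
  rar <- with_seed_or_not(seed,
    t(suppressWarnings(vegan::rrarefy(t(keep), depth))))
  out <- abundance_table(rar, mode = "counts")
  attr(out, "dropped_samples") <- drop
  out
}

#' Correct abundances for 16S rRNA gene copy number
#'
#' Divides each taxon row by its gene copy number and renormalizes every
#' sample column to relative abundances.
#'
#' @param tbl Abundance table (counts or relative).
#' @param copy_numbers Named positive vector of per-taxon copy numbers; taxa
#'   without an entry get copy number 1 (reported via a message).
#' @return A relative-mode abundance table.
#' @export
copy_number_correct <- function(tbl, copy_numbers) {
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive", call. = FALSE)
  m <- abund_matrix(tbl)
  cn <- copy_numbers[rownames(m)]
  missing <- rownames(m)[is.na(cn)]
  if (length(missing)) {
    message(length(missing), " taxon/taxa without a copy number, using 1: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    cn[is.na(cn)] <- 1
  }
  corr <- m / cn
  rel <- sweep(corr, 2, colSums(corr), "/")
  abundance_table(rel, mode = "relative")
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums rows sharing the same lineage prefix up to `rank`. Taxa unassigned at
#' `rank` (or at any level above it) are pooled under
#' `"...;Unclassified_<deepest assigned name>"`. Column sums are preserved.
#'
#' @param tbl Abundance table.
#' @param taxonomy Taxonomy tibble from [read_taxonomy()] (columns
#'   `taxon_id`, kingdom..genus; `NA`/empty = unassigned).
#' @param rank One of phylum, class, order, family, genus.
#' @return An abundance table (same mode) whose `taxon_id` is the
#'   semicolon-joined lineage prefix.
#' @export
aggregate_rank <- function(tbl, taxonomy, rank) {
  rank <- match.arg(rank, sn_ranks[-1])
  m <- abund_matrix(tbl)
  miss <- setdiff(rownames(m), taxonomy$taxon_id)
  if (length(miss)) {
    stop("taxa missing from taxonomy: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  upto <- sn_ranks[seq_len(match(rank, sn_ranks))]
  lin <- as.matrix(taxonomy[match(rownames(m), taxonomy$taxon_id), upto])
  lin[lin == "" | is.na(lin)] <- NA_character_
  labels <- apply(lin, 1, function(lv) {
    assigned <- which(!is.na(lv))
    # unassigned anywhere in the prefix pools the row under its deepest
    # assigned ancestor
    if (length(assigned) == length(lv) &&
        all(assigned == seq_along(lv))) {
      paste(lv, collapse = ";")
    } else {
      k <- if (length(assigned)) max(which(cumsum(is.na(lv)) == 0)) else 0
      parent <- if (k > 0) lv[k] else "Root"
      paste(c(lv[seq_len(k)], paste0("Unclassified_", parent)), collapse = ";")
    }
  })
  agg <- rowsum(m, group = labels)
  abundance_table(agg, mode = abund_mode(tbl) %||% "values")
}

#' Log-transform skewed environmental drivers
#'
#' Applies a log10 transform to conductivity, OC, humidity, precipitation and
#' the C3 vegetation coverages to meet the linearity assumptions of the
#' causal network; pH and the remaining drivers are left untouched. A second
#' call on an already-transformed table is refused.
#'
#' @param env An [env_table()].
#' @param pseudo_offset Optional positive offset added to any to-be-logged
#'   column containing zeros (e.g. vegetation coverage zeros). Without it,
#'   nonpositive values are an error naming the sample and column; data are
#'   never silently altered.
#' @return The transformed [env_table()]; transformed columns are recorded in
#'   attribute `log10_transformed`.
#' @export
transform_env <- function(env, pseudo_offset = NULL) {
  stopifnot(inherits(env, "sn_env") || is.data.frame(env))
  env <- env_table(env, require = character(0))
  targets <- intersect(c("conductivity", "OC", "humidity", "precipitation",
                         "C3_macrothermal", "C3_mesothermal"), names(env))
  done <- attr(env, "log10_transformed")
  if (length(done)) {
    stop("table already log10-transformed (", paste(done, collapse = ", "),
         "); refusing to transform twice", call. = FALSE)
  }
  offset_used <- character(0)
  for (col in targets) {
    v <- env[[col]]
    if (any(v <= 0, na.rm = TRUE)) {
      if (is.null(pseudo_offset)) {
        bad <- env$sample_id[which(v <= 0)]
        stop("nonpositive value(s) in '", col, "' (sample(s) ",
             paste(head(bad, 5), collapse = ", "),
             "); supply pseudo_offset to proceed", call. = FALSE)
      }
      stopifnot(pseudo_offset > 0)
      v <- v + pseudo_offset
      offset_used <- c(offset_used, col)
    }
    env[[col]] <- log10(v)
  }
  attr(env, "log10_transformed") <- targets
  attr(env, "pseudo_offset_columns") <- offset_used
  env
}
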