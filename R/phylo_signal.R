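#' Abouheif phylogenetic proximity matrix
#'
#' Topology-only proximity between tips: `a[i, j]` is the product, over the
#' internal nodes on the path from tip `i` to tip `j` (including the MRCA),
#' of one over that node's number of direct descendants. The diagonal is 0.
#' Branch lengths are ignored by construction, which distinguishes this
#' proximity from branch-length-aware alternatives.
#'
#' @param tree A rooted `ape::phylo` with unique tip labels and at least 3
#'   tips.
#' @return A symmetric n x n matrix with zero diagonal, dimnames = tip
#'   labels.
#' @export
#' @examples
#' star <- ape::stree(5, type = "star")
#' abouheif_proximity(star)[1, 2]  # 1/5
abouheif_proximity <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3) stop("tree needs at least 3 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels", call. = FALSE)
  }
  # number of direct descendants of each internal node
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1
  # ancestor chain (excluding the tip itself) for every tip, tip -> root
  anc <- lapply(seq_len(n), function(i) {
    out <- integer(0)
    v <- parent[i]
    while (v != 0) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  })
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    ai <- anc[[i]]
    for (j in seq(i + 1, n)) {
      aj <- anc[[j]]
      mrca <- ai[match(TRUE, ai %in% aj)]
      path <- c(ai[seq_len(match(mrca, ai))], aj[seq_len(match(mrca, aj) - 1)])
      A[i, j] <- A[j, i] <- prod(1 / dd[path])
    }
  }
  A
}

# center a trait and align it with a proximity matrix
align_trait <- function(trait, A) {
  if (!is.null(names(trait))) {
    miss <- setdiff(rownames(A), names(trait))
    if (length(miss)) {
      stop("trait missing tip(s): ", paste(head(miss, 5), collapse = ", "),
           call. = FALSE)
    }
    trait <- trait[rownames(A)]
  } else if (length(trait) != nrow(A)) {
    stop("trait length does not match the proximity matrix", call. = FALSE)
  }
  if (var(trait) == 0) stop("trait has zero variance", call. = FALSE)
  trait
}

#' Global phylogenetic signal: Abouheif's Cmean
#'
#' Moran-form autocorrelation of a trait with the Abouheif proximity:
#' \eqn{C = (n/S_0)\, \sum_{i \ne j} a_{ij} z_i z_j / \sum_i z_i^2} with `z`
#' the centered trait and `S0` the sum of off-diagonal proximities. The
#' p-value is a one-sided (greater) permutation test with
#' `(hits + 1) / (n_perm + 1)`, testing for trait conservation.
#'
#' @param trait Named numeric vector over tips (or unnamed, matrix order).
#' @param A Proximity matrix from [abouheif_proximity()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A list of class `cmean_test`: `cmean`, `p_value`, `n_perm`, `n`.
#' @export
cmean_test <- function(trait, A, n_perm = 999, seed = NULL) {
  trait <- align_trait(trait, A)
  n <- length(trait)
  z <- trait - mean(trait)
  s0 <- sum(A)
  stat <- function(zv) (n / s0) * sum(zv * (A %*% zv)) / sum(zv^2)
  obs <- stat(z)
  perm <- with_seed_or_not(seed, {
    Z <- vapply(seq_len(n_perm), function(b) z[sample.int(n)], numeric(n))
    colSums(Z * (A %*% Z)) * (n / s0) / colSums(Z^2)
  })
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  structure(list(cmean = obs, p_value = p, n_perm = n_perm, n = n),
            class = "cmean_test")
}

#' @export
print.cmean_test <- function(x, ...) {
  cat(sprintf("Abouheif's Cmean = %.4f (one-sided p = %.4g, %d permutations, %d tips)\n",
              x$cmean, x$p_value, x$n_perm, x$n))
  invisible(x)
}

#' @export
tidy.cmean_test <- function(x, ...) {
  tibble::tibble(cmean = x$cmean, p_value = x$p_value, n_perm = x$n_perm,
                 n = x$n)
}

#' Local phylogenetic signal: per-tip local Moran's I (LIPA)
#'
#' With `W` the row-normalized Abouheif proximity and `z` the centered trait,
#' \eqn{I_i = z_i \sum_j W_{ij} z_j / (\sum_k z_k^2 / n)}. The mean of the
#' per-tip values equals the global Moran statistic under the same `W`.
#' Significance is assessed by conditional permutation: tip `i`'s value is
#' held fixed while the remaining values are permuted; the reported p-value
#' is two-sided. A Benjamini-Hochberg adjusted column is included but
#' significance is flagged at unadjusted `p < alpha`, matching the common
#' LIPA display convention.
#'
#' @inheritParams cmean_test
#' @param alpha Significance threshold for the `significant` flag (default
#'   0.05).
#' @return A tibble: `taxon_id`, `trait`, `local_i`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
local_moran <- function(trait, A, n_perm = 999, seed = NULL, alpha = 0.05) {
  trait <- align_trait(trait, A)
  n <- length(trait)
  z <- trait - mean(trait)
  rs <- rowSums(A)
  if (any(rs == 0)) stop("isolated tip(s) with zero proximity", call. = FALSE)
  W <- A / rs
  m2 <- sum(z^2) / n
  obs <- z * as.numeric(W %*% z) / m2
  pvals <- with_seed_or_not(seed, vapply(seq_len(n), function(i) {
    zo <- z[-i]
    P <- vapply(seq_len(n_perm), function(b) zo[sample.int(n - 1)],
                numeric(n - 1))
    lag <- as.numeric(W[i, -i] %*% P)
    ip <- z[i] * lag / m2
    p_up <- (sum(ip >= obs[i]) + 1) / (n_perm + 1)
    p_lo <- (sum(ip <= obs[i]) + 1) / (n_perm + 1)
    min(1, 2 * min(p_up, p_lo))
  }, numeric(1)))
  tibble::tibble(taxon_id = rownames(A), trait = unname(trait),
                 local_i = unname(obs), p_value = pvals,
                 p_adjusted = stats::p.adjust(pvals, "BH"),
                 significant = pvals < alpha)
}

#' Occupancy filter for phylogenetic-signal analyses
#'
#' Retains taxa present (value > 0) in strictly more than `min_samples`
#' samples — the "more than 200 soil samples" rule at the packaged default.
#'
#' @param tbl Abundance table.
#' @param min_samples Occupancy threshold (default 200; strict `>`).
#' @return A tibble: `taxon_id`, `n_present`, `retained`.
#' @export
filter_taxa_for_signal <- function(tbl, min_samples = 200) {
  m <- abund_matrix(tbl)
  occ <- rowSums(m > 0)
  tibble::tibble(taxon_id = rownames(m), n_present = as.integer(occ),
                 retained = unname(occ > min_samples))
}
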