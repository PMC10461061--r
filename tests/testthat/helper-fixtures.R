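# shared fixtures and independent oracles, built in code

tiny_counts <- function() {
  m <- matrix(c(6, 4, 0,
                1, 9, 5,
                3, 0, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2", "s3")))
  abundance_table(m, mode = "counts")
}

tiny_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    kingdom = "Bacteria",
    phylum = c("Acidobacteria", "Acidobacteria", "Firmicutes"),
    class = c("Acidobacteriia", NA, "Bacilli"),
    order = NA_character_, family = NA_character_, genus = NA_character_)
}

# two exogenous, two endogenous variables: y1 <- x1 + x2, y2 <- y1 + x2
small_spec <- function() {
  sem_spec(data.frame(parent = c("x1", "x2", "y1", "x2"),
                      child = c("y1", "y1", "y2", "y2")),
           exogenous = c("x1", "x2"))
}

small_sim <- function(n, seed, b = c(b11 = 0.7, b12 = -0.4, b21 = 0.5,
                                     b22 = 0.3),
                      psi = c(1, 1), phi_r = 0.3) {
  withr::with_seed(seed, {
    x1 <- rnorm(n)
    x2 <- phi_r * x1 + sqrt(1 - phi_r^2) * rnorm(n)
    y1 <- b["b11"] * x1 + b["b12"] * x2 + rnorm(n, 0, sqrt(psi[1]))
    y2 <- b["b21"] * y1 + b["b22"] * x2 + rnorm(n, 0, sqrt(psi[2]))
    data.frame(x1 = x1, x2 = x2, y1 = y1, y2 = y2)
  })
}

# hand-derived implied covariance for the small model above (independent of
# the package's reduced-form code), over (x1, x2, y1, y2)
small_sigma_oracle <- function(th) {
  b11 <- th[1]; b12 <- th[2]; b21 <- th[3]; b22 <- th[4]
  p1 <- exp(th[5]); p2 <- exp(th[6])
  f11 <- exp(th[7]); f22 <- exp(th[8]); f12 <- tanh(th[9]) * sqrt(f11 * f22)
  vy1 <- b11^2 * f11 + b12^2 * f22 + 2 * b11 * b12 * f12 + p1
  cy1x1 <- b11 * f11 + b12 * f12
  cy1x2 <- b11 * f12 + b12 * f22
  cy2x1 <- b21 * cy1x1 + b22 * f12
  cy2x2 <- b21 * cy1x2 + b22 * f22
  vy2 <- b21^2 * vy1 + b22^2 * f22 + 2 * b21 * b22 * cy1x2 + p2
  cy2y1 <- b21 * vy1 + b22 * cy1x2
  matrix(c(f11, f12, cy1x1, cy2x1,
           f12, f22, cy1x2, cy2x2,
           cy1x1, cy1x2, vy1, cy2y1,
           cy2x1, cy2x2, cy2y1, vy2), 4, 4,
         dimnames = list(c("x1", "x2", "y1", "y2"),
                         c("x1", "x2", "y1", "y2")))
}

# brute-force ML discrepancy minimizer for the small model
small_fml_oracle <- function(S, start = NULL) {
  fml <- function(th) {
    sig <- small_sigma_oracle(th)
    d <- determinant(sig)$modulus
    if (!is.finite(d)) return(1e10)
    as.numeric(d - determinant(S)$modulus + sum(diag(S %*% solve(sig))) - 4)
  }
  st <- start %||% c(0, 0, 0, 0, 0, 0,
                     log(S["x1", "x1"]), log(S["x2", "x2"]), 0)
  opt <- optim(st, fml, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt2 <- optim(opt$par, fml, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  list(par = opt2$par, value = opt2$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index (hand implementation, independent of any package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
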