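# Independent dense oracles used to cross-check the production paths.

# H assembled by the conditional-expectation (projection) formula:
#   H22 = G, H12 = A12 A22^-1 G, H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21
dense_h <- function(A, geno_idx, G) {
  n <- nrow(A)
  ng <- setdiff(seq_len(n), geno_idx)
  A11 <- A[ng, ng, drop = FALSE]
  A12 <- A[ng, geno_idx, drop = FALSE]
  A22 <- A[geno_idx, geno_idx, drop = FALSE]
  A22i <- solve(A22)
  H <- matrix(0, n, n)
  H[ng, ng] <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  H[ng, geno_idx] <- A12 %*% A22i %*% G
  H[geno_idx, ng] <- t(H[ng, geno_idx, drop = FALSE])
  H[geno_idx, geno_idx] <- G
  H
}

# GLS/BLUP on a dense toy: b = (X'V^-1 X)^-1 X'V^-1 y,
# u = s2u K Za' V^-1 (y - X b), with V the record covariance matrix.
gls_blup <- function(X, Za, Zp, y, K, s2u, s2pe, s2e) {
  V <- s2u * Za %*% K %*% t(Za) + s2pe * tcrossprod(Zp) +
    s2e * diag(nrow(X))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2u * K %*% t(Za) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b), u = as.numeric(u))
}

# small pedigree helpers -------------------------------------------------

ped_from_text <- function(txt) {
  as_pedigree(utils::read.csv(text = txt, colClasses = "character",
                              strip.white = TRUE))
}

# founders A,B; full sibs C,D = A x B; X = C x D (inbred, f = 0.25)
ped_fullsib_mating <- function() ped_from_text(
  "animal,sire,dam,birth_year
   A,0,0,2000
   B,0,0,2000
   C,A,B,2001
   D,A,B,2001
   X,C,D,2002")

# deterministic random pedigree via the simulator
rand_ped <- function(seed, n_founders = 40, n_generations = 5,
                     n_matings = 20, offspring_per_mating = 2) {
  simulate_pedigree(sim_config(seed = seed, n_founders = n_founders,
                               n_generations = n_generations,
                               n_matings = n_matings,
                               offspring_per_mating = offspring_per_mating))
}

# one small fitted dataset shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_dataset(sim_config(seed = 11))
    cache
  }
})

small_spec <- function() model_spec(0.3, 0.2, 0.5)

# intercept-only model spec for minimal design tests
intercept_spec <- function(...) model_spec(..., fixed = ~1)
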