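#' Configuration of the iterative SNP-weighting scheme
#'
#' Controls the weighted single-step iterations: weights start at 1
#' (iteration 1 is plain ssGBLUP), then each iteration backsolves SNP
#' effects from the genotyped animals' GEBV, converts them to nonlinear-A
#' weights `ct^(|e_i|/SD(e) - 2)`, rescales the weights to keep their sum at
#' the SNP count, rebuilds G* and H-inverse, and re-solves the model.
#'
#' @param ct departure-from-normality constant, >= 1. `ct = 1` keeps all
#'   weights at 1 (normally distributed SNP effects); values tried in
#'   practice include 1.05, 1.125 (default), 1.5 and 2.
#' @param n_iter number of solve iterations (default 5).
#' @param sd_cap cap on the standardized effect `|e_i|/SD(e)` entering the
#'   exponent (default 5), preventing single-SNP weight explosions at large
#'   `ct`.
#' @param blend_alpha blending weight for `G* = alpha G + (1-alpha) A22`,
#'   reapplied at every iteration.
#' @return object of class `weighting_config`.
#' @export
weighting_config <- function(ct = 1.125, n_iter = 5L, sd_cap = 5,
                             blend_alpha = 0.95) {
  stopifnot(ct >= 1, n_iter >= 1, sd_cap > 0,
            blend_alpha > 0, blend_alpha <= 1)
  structure(list(ct = ct, n_iter = as.integer(n_iter), sd_cap = sd_cap,
                 blend_alpha = blend_alpha),
            class = "weighting_config")
}

#' Backsolve SNP effects from genomic breeding values
#'
#' `u_snp = lambda D Z' G*^-1 u_geno`: the allele-substitution effects that
#' decompose the genotyped animals' (G)EBV over the SNP panel under the
#' current weights. On an unblended full-rank panel,
#' `Z u_snp` reconstructs `u_geno` exactly because
#' `lambda Z D Z' G^-1 = I` when `G = lambda Z D Z'`.
#'
#' @param u_geno GEBV of the genotyped animals, in Z row order.
#' @param Z centered genotype matrix.
#' @param d per-SNP weights (diagonal of D).
#' @param Gstar_inv inverse of the (blended) genomic relationship matrix.
#' @param lam scaling constant lambda.
#' @return numeric vector of per-SNP effects.
#' @export
backsolve_snp_effects <- function(u_geno, Z, d, Gstar_inv, lam) {
  stopifnot(length(u_geno) == nrow(Z), length(d) == ncol(Z))
  as.numeric(lam * d * crossprod(Z, Gstar_inv %*% u_geno))
}

#' Nonlinear-A SNP weights
#'
#' `d_i = ct^(min(|e_i|/SD(e), sd_cap) - 2)`, VanRaden's departure-from-
#' normality weighting: SNPs whose backsolved effect exceeds two standard
#' deviations are up-weighted, smaller effects down-weighted, and `ct = 1`
#' leaves every weight at 1. `SD` is the population standard deviation
#' (divisor N) of the effects vector.
#'
#' @param effects backsolved per-SNP effects.
#' @param ct constant >= 1.
#' @param sd_cap cap on the standardized absolute effect.
#' @return unnormalized positive weight vector.
#' @export
nonlinear_a_weights <- function(effects, ct, sd_cap = 5) {
  stopifnot(ct >= 1, sd_cap > 0)
  n <- length(effects)
  s <- sqrt(sum((effects - mean(effects))^2) / n)
  if (s == 0)
    stop("SD of SNP effects is zero (degenerate backsolve); cannot weight")
  ct^(pmin(abs(effects) / s, sd_cap) - 2)
}

#' Trace-preserving weight normalization
#'
#' Rescales new weights so that their sum (the trace of D) equals the trace
#' of the previous weights: since iteration 1 starts from D = I, the trace
#' stays at the SNP count N for every iteration.
#'
#' @param d_new unnormalized weights.
#' @param d_old previous iteration's weights.
#' @return rescaled weights with `sum(d) == sum(d_old)`.
#' @export
normalize_weights <- function(d_new, d_old) {
  stopifnot(all(d_new > 0), all(d_old > 0), length(d_new) == length(d_old))
  d_new * (sum(d_old) / sum(d_new))
}
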