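#' Construct the partial dataset for LR validation
#'
#' The partial dataset keeps pedigree and genotypes untouched and removes
#' phenotype records with `record_year > cutoff_year` (recent years set to
#' missing), mirroring a real evaluation run some years earlier.
#'
#' @param ph phenotype data.frame.
#' @param cutoff_year last record year retained.
#' @return phenotype data.frame with the late records dropped.
#' @export
make_partial <- function(ph, cutoff_year) {
  keep <- ph$record_year <= cutoff_year
  if (!any(keep))
    stop("partial dataset empty: cutoff_year ", cutoff_year,
         " precedes all record years")
  ph[keep, , drop = FALSE]
}

#' Select the validation population
#'
#' Validation animals are the young genotyped animals: genotyped, born after
#' `birth_year_min`, optionally restricted to a given subset (e.g. females)
#' and optionally required to carry no record in the partial dataset.
#'
#' @param ped a `pedigree`.
#' @param genotyped_ids ids of genotyped animals.
#' @param birth_year_min animals born strictly after this year are selected.
#' @param females optional id vector; when given, selection is restricted to
#'   it (sex is not part of the pedigree file).
#' @param no_records_in optional phenotype data.frame (normally the partial
#'   dataset); animals with records in it are excluded.
#' @return character vector of validation ids.
#' @export
select_validation <- function(ped, genotyped_ids, birth_year_min,
                              females = NULL, no_records_in = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- match(genotyped_ids, ped$id)
  if (anyNA(idx)) stop("genotyped ids not in pedigree")
  sel <- genotyped_ids[!is.na(ped$birth_year[idx]) &
                         ped$birth_year[idx] > birth_year_min]
  if (!is.null(females)) sel <- intersect(sel, as.character(females))
  if (!is.null(no_records_in))
    sel <- setdiff(sel, as.character(no_records_in$animal))
  if (!length(sel))
    stop("empty validation set (birth_year_min = ", birth_year_min, ")")
  sel
}

#' LR-method validation metrics
#'
#' Given the validation animals' breeding values estimated from the partial
#' (`u_p`) and whole (`u_w`) datasets, computes the four linear-regression
#' validation statistics:
#' \describe{
#'   \item{acc}{prediction accuracy
#'     `sqrt(cov(u_p, u_w) / ((1 - f_bar) sigma2_u))`; 1 for a perfect
#'     evaluation. The raw covariance ratio is also returned (`acc2`).
#'     A negative covariance yields `acc = 0` with a warning.}
#'   \item{mu}{population bias `mean(u_p) - mean(u_w)`; 0 when unbiased.}
#'   \item{b_wp}{dispersion `cov(u_w, u_p) / var(u_p)`; 1 when estimates are
#'     neither inflated nor deflated.}
#'   \item{b_pw}{slope `cov(u_p, u_w) / var(u_w)`, the ratio of partial to
#'     whole reliabilities; 1 when reliabilities agree.}
#' }
#' Covariances and variances use the sample (n-1) convention.
#'
#' @param u_p,u_w equal-length numeric vectors over the validation animals,
#'   aligned by animal.
#' @param f_bar mean inbreeding coefficient of the validation animals.
#' @param sigma2_u additive genetic variance.
#' @return object of class `lr_metrics`: list with `acc`, `acc2`, `mu`,
#'   `b_wp`, `b_pw`, `n_validation`, `f_bar`, `sigma2_u`.
#' @export
lr_metrics <- function(u_p, u_w, f_bar, sigma2_u) {
  if (length(u_p) != length(u_w)) stop("u_p and u_w lengths differ")
  n <- length(u_p)
  if (n < 2) stop("validation set must contain at least 2 animals")
  stopifnot(sigma2_u > 0, f_bar >= 0, f_bar < 1)
  vp <- stats::var(u_p); vw <- stats::var(u_w)
  if (vp == 0 || vw == 0)
    stop("zero variance in breeding values over the validation set")
  cv <- stats::cov(u_p, u_w)
  ratio <- cv / ((1 - f_bar) * sigma2_u)
  if (cv < 0) {
    warning("negative covariance between partial and whole EBV; acc set to 0")
    acc <- 0
  } else acc <- sqrt(ratio)
  structure(list(acc = acc, acc2 = ratio,
                 mu = mean(u_p) - mean(u_w),
                 b_wp = cv / vp, b_pw = cv / vw,
                 n_validation = n, f_bar = f_bar, sigma2_u = sigma2_u),
            class = "lr_metrics")
}

#' @export
print.lr_metrics <- function(x, ...) {
  cat("LR validation (n =", x$n_validation, ")\n")
  cat(sprintf("  accuracy   acc  = %.4f  (cov ratio %.4f)\n", x$acc, x$acc2))
  cat(sprintf("  bias       mu   = %+.4f\n", x$mu))
  cat(sprintf("  dispersion b_wp = %.4f\n", x$b_wp))
  cat(sprintf("  slope      b_pw = %.4f\n", x$b_pw))
  invisible(x)
}
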