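#' Specify the univariate repeatability model
#'
#' The trait is analyzed with a univariate repeatability animal model:
#' fixed herd-year-season of calving, standardized days in milk (linear +
#' quadratic) and standardized calving age with constant, linear and
#' quadratic regressions nested within parity; random permanent-environment,
#' additive-genetic and residual effects. Variance components are inputs
#' (configuration or simulation truth); they are not estimated here.
#'
#' @param sigma2_u additive genetic variance (> 0).
#' @param sigma2_pe permanent-environment variance (> 0).
#' @param sigma2_e residual variance (> 0).
#' @param fixed optional one-sided formula replacing the default fixed-effect
#'   layout; it is evaluated on the phenotype table after `hys_f`/`parity_f`
#'   factors and `dim_std`/`ca_std` standardized covariates are added.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(sigma2_u, sigma2_pe, sigma2_e, fixed = NULL) {
  stopifnot(sigma2_u > 0, sigma2_pe > 0, sigma2_e > 0)
  if (is.null(fixed))
    fixed <- ~ parity_f + hys_f + dim_std + I(dim_std^2) +
      parity_f:ca_std + parity_f:I(ca_std^2)
  structure(list(sigma2_u = sigma2_u, sigma2_pe = sigma2_pe,
                 sigma2_e = sigma2_e, fixed = fixed),
            class = "model_spec")
}

#' Read a phenotype file
#'
#' CSV with header `animal,parity,hys,dim,calving_age,record_year,y`.
#'
#' @param path file path.
#' @return data.frame of records.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("animal", "parity", "hys", "dim", "calving_age", "record_year", "y")
  if (!all(need %in% names(df)))
    stop("phenotype file needs columns: ", paste(need, collapse = ","))
  df$animal <- as.character(df$animal)
  df
}

#' Write a phenotype table
#' @param ph phenotype data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.csv(ph, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_phenotypes <- function(ph, ped) {
  need <- c("animal", "parity", "hys", "dim", "calving_age", "record_year", "y")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(ph$parity %in% 1:5)) stop("parity must be in 1..5")
  if (any(ph$dim <= 0 | ph$dim > 50)) stop("dim must be in (0, 50]")
  bad <- setdiff(as.character(ph$animal), ped$id)
  if (length(bad))
    stop("phenotyped animals not in pedigree: ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(TRUE)
}

zstd <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Build design matrices for the repeatability model
#'
#' Constructs the fixed-effect matrix X (treatment coding, reference level
#' dropped per factor; empty columns removed), the record-to-animal incidence
#' Za over the whole pedigree, and the record-to-permanent-environment
#' incidence Zp over the animals that carry records. `dim` and `calving_age`
#' are z-standardized with the mean/sd of the analyzed dataset, so a partial
#' dataset is standardized on its own records.
#'
#' @param ph phenotype data.frame (see [read_phenotypes()]).
#' @param spec a [model_spec()].
#' @param ped a `pedigree`.
#' @return list with sparse `X`, `Za`, `Zp`, response `y`, `pe_ids` (animals
#'   with records, in Zp column order) and the standardization constants.
#' @export
build_design <- function(ph, spec, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "pedigree"))
  validate_phenotypes(ph, ped)
  df <- data.frame(
    parity_f = droplevels(factor(ph$parity)),
    hys_f = droplevels(factor(ph$hys)),
    dim_std = zstd(ph$dim),
    ca_std = zstd(ph$calving_age)
  )
  X <- stats::model.matrix(spec$fixed, df)
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design rank deficient; offending columns: ",
         paste(drop_cols, collapse = ", "))
  }
  acode <- match(as.character(ph$animal), ped$id)
  m <- nrow(ph)
  Za <- Matrix::sparseMatrix(i = seq_len(m), j = acode, x = 1,
                             dims = c(m, ped$n))
  pe_ids <- sort(unique(acode))
  Zp <- Matrix::sparseMatrix(i = seq_len(m), j = match(acode, pe_ids), x = 1,
                             dims = c(m, length(pe_ids)))
  list(X = methods::as(X, "CsparseMatrix"), Za = Za, Zp = Zp,
       y = as.numeric(ph$y), pe_ids = ped$id[pe_ids],
       fixed_names = colnames(X),
       std = list(dim = c(mean(ph$dim), stats::sd(ph$dim)),
                  ca = c(mean(ph$calving_age), stats::sd(ph$calving_age))))
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the symmetric sparse coefficient matrix and right-hand side of the
#' repeatability-model MME with variance ratios
#' `lambda_a = sigma2_e / sigma2_u` on the relationship-inverse block and
#' `lambda_pe = sigma2_e / sigma2_pe` on the permanent-environment block.
#'
#' @param design output of [build_design()].
#' @param spec a [model_spec()].
#' @param Kinv sparse inverse relationship matrix over the whole pedigree
#'   (A-inverse for pedigree BLUP, H-inverse for single-step).
#' @return list with `C` (sparse symmetric), `rhs`, and the block layout.
#' @export
assemble_mme <- function(design, spec, Kinv) {
  X <- design$X; Za <- design$Za; Zp <- design$Zp; y <- design$y
  if (nrow(Kinv) != ncol(Za)) stop("Kinv dimension != pedigree size")
  la <- spec$sigma2_e / spec$sigma2_u
  lpe <- spec$sigma2_e / spec$sigma2_pe
  C <- rbind(
    cbind(Matrix::crossprod(X), Matrix::crossprod(X, Za),
          Matrix::crossprod(X, Zp)),
    cbind(Matrix::crossprod(Za, X), Matrix::crossprod(Za) + la * Kinv,
          Matrix::crossprod(Za, Zp)),
    cbind(Matrix::crossprod(Zp, X), Matrix::crossprod(Zp, Za),
          Matrix::crossprod(Zp) +
            lpe * Matrix::Diagonal(ncol(Zp)))
  )
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Za, y)),
           as.numeric(Matrix::crossprod(Zp, y)))
  list(C = Matrix::forceSymmetric(C), rhs = rhs,
       blocks = c(fixed = ncol(X), animal = ncol(Za), pe = ncol(Zp)))
}

#' Solve the mixed-model equations
#'
#' Direct sparse Cholesky factorization (default up to 20,000 equations) or
#' Jacobi-preconditioned conjugate gradients for larger systems.
#'
#' @param C sparse symmetric coefficient matrix.
#' @param rhs right-hand side.
#' @param method `"direct"`, `"pcg"`, or `"auto"` (direct below 20k equations).
#' @param tol relative-residual convergence tolerance for PCG (and the
#'   accepted residual for the direct solve).
#' @param max_iter PCG iteration cap.
#' @return list with `sol`, `method`, `rel_residual`, `iterations`.
#' @export
solve_mme <- function(C, rhs, method = c("auto", "direct", "pcg"),
                      tol = 1e-8, max_iter = 10000L) {
  method <- match.arg(method)
  neq <- length(rhs)
  if (method == "auto") method <- if (neq <= 20000L) "direct" else "pcg"
  if (method == "direct") {
    if (!methods::is(C, "dsCMatrix")) C <- Matrix::forceSymmetric(C)
    ch <- Matrix::Cholesky(C, LDL = TRUE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, rhs))
    it <- 1L
  } else {
    dinv <- 1 / Matrix::diag(C)
    x <- numeric(neq)
    r <- rhs
    z <- dinv * r
    p <- z
    rz <- sum(r * z)
    nrhs <- sqrt(sum(rhs^2))
    it <- 0L
    while (sqrt(sum(r^2)) / nrhs > tol) {
      it <- it + 1L
      if (it > max_iter)
        stop("PCG did not converge in ", max_iter,
             " iterations; relative residual ",
             format(sqrt(sum(r^2)) / nrhs, digits = 3))
      Ap <- as.numeric(C %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      z <- dinv * r
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    sol <- x
  }
  rres <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2)) / sqrt(sum(rhs^2))
  list(sol = sol, method = method, rel_residual = rres, iterations = it)
}
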