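#' Fit a pedigree or single-step genomic repeatability model
#'
#' The single entry point for the three evaluation methods:
#' \describe{
#'   \item{`"ablup"`}{BLUP with the pedigree relationship matrix A only.}
#'   \item{`"ssgblup"`}{single-step GBLUP: A and the VanRaden genomic
#'     relationship matrix G of the genotyped animals combined into H,
#'     all animals evaluated jointly through the sparse H-inverse.}
#'   \item{`"wssgblup"`}{weighted single-step GBLUP: iteratively re-weights
#'     the SNPs in G by the nonlinear-A scheme (iteration 1 is ssGBLUP) and
#'     re-solves; the per-iteration weights, SNP effects and solutions are
#'     kept in the returned `trace`.}
#' }
#' Breeding values `u` are returned for every pedigree animal; animals
#' without records receive parent-average (or genomically propagated)
#' values through the relationship structure.
#'
#' @param data phenotype data.frame with columns
#'   `animal, parity, hys, dim, calving_age, record_year, y`.
#' @param pedigree a `pedigree` (see [as_pedigree()]).
#' @param spec a [model_spec()] (variance components + fixed-effect layout).
#' @param genotypes a `geno_matrix` of the genotyped animals (required for
#'   the genomic methods; ignored with a message by `"ablup"`).
#' @param method `"ablup"`, `"ssgblup"` or `"wssgblup"`.
#' @param weights a [weighting_config()] (used by `"wssgblup"`; its
#'   `blend_alpha` is also the blending used by `"ssgblup"`).
#' @param maf_min MAF threshold applied to `genotypes` (`NULL` to skip QC).
#' @param tune rescale G to the A22 scale before blending (off by default).
#' @param solver,tol,max_iter passed to [solve_mme()].
#' @param dataset_tag free label (`"whole"`/`"partial"`) carried in the fit.
#' @return object of class `ssblup`; see [print.ssblup()], [summary.ssblup()],
#'   [predict.ssblup()], [plot.ssblup()].
#' @examples
#' sim <- sim_dataset(sim_config(seed = 42, n_founders = 40, n_matings = 20,
#'                               offspring_per_mating = 2, n_snps = 100))
#' spec <- model_spec(0.3, 0.2, 0.5)
#' fit <- ssblup(sim$phenotypes, sim$ped, spec, genotypes = sim$geno,
#'               method = "ssgblup")
#' fit
#' cor(predict(fit)[sim$genotyped_ids], sim$truth$tbv[sim$genotyped_ids])
#' @export
ssblup <- function(data, pedigree, spec, genotypes = NULL,
                   method = c("ablup", "ssgblup", "wssgblup"),
                   weights = weighting_config(),
                   maf_min = 0.01, tune = FALSE,
                   solver = c("auto", "direct", "pcg"),
                   tol = 1e-8, max_iter = 10000L,
                   dataset_tag = "whole") {
  method <- match.arg(method)
  solver <- match.arg(solver)
  stopifnot(inherits(pedigree, "pedigree"), inherits(spec, "model_spec"),
            inherits(weights, "weighting_config"))
  cl <- match.call()
  design <- build_design(data, spec, pedigree)
  Ainv <- a_inverse(pedigree)

  if (method == "ablup") {
    if (!is.null(genotypes))
      message("method 'ablup': genotype data ignored")
    ans <- solve_tagged(design, spec, Ainv, solver, tol, max_iter)
    return(new_ssblup(cl, method, spec, weights, design, ans,
                      kernel = "A", dataset_tag, pedigree,
                      geno_meta = NULL, trace = NULL))
  }

  if (is.null(genotypes)) stop("method '", method, "' requires genotypes")
  stopifnot(inherits(genotypes, "geno_matrix"))
  g <- if (is.null(maf_min)) genotypes else qc_filter(genotypes, maf_min)
  bad <- setdiff(g$animal_id, pedigree$id)
  if (length(bad))
    stop("genotyped animals not in pedigree: ",
         paste(utils::head(bad, 10), collapse = ", "))
  geno_idx <- match(g$animal_id, pedigree$id)
  Z <- center_genotypes(g)
  A22 <- a_matrix(pedigree, g$animal_id)
  geno_meta <- list(n_snps = g$N, lam = g$lam, snp_id = g$snp_id,
                    animal_id = g$animal_id)

  n_iter <- if (method == "ssgblup") 1L else weights$n_iter
  d <- rep(1, g$N)
  trace <- vector("list", n_iter)
  ans <- NULL
  for (t in seq_len(n_iter)) {
    G <- g_matrix(Z, d, g$lam)
    if (tune) G <- tune_g(G, A22)
    Gstar <- blend_g(G, A22, weights$blend_alpha)
    Hinv <- h_inverse(Ainv, A22, Gstar, geno_idx)
    ans <- solve_tagged(design, spec, Hinv, solver, tol, max_iter)
    Gstar_inv <- chol2inv(chol(Gstar))
    eff <- backsolve_snp_effects(ans$u[geno_idx], Z, d, Gstar_inv, g$lam)
    trace[[t]] <- list(t = t, d = d, effects = eff,
                       u = ans$u, fixed = ans$fixed, pe = ans$pe,
                       solver = ans$solver)
    if (t < n_iter)
      d <- normalize_weights(
        nonlinear_a_weights(eff, weights$ct, weights$sd_cap), d)
  }
  new_ssblup(cl, method, spec, weights, design, ans,
             kernel = if (method == "ssgblup") "H" else "H-weighted",
             dataset_tag, pedigree, geno_meta,
             trace = if (method == "wssgblup") trace else NULL)
}

solve_tagged <- function(design, spec, Kinv, solver, tol, max_iter) {
  mme <- assemble_mme(design, spec, Kinv)
  res <- solve_mme(mme$C, mme$rhs, solver, tol, max_iter)
  b <- mme$blocks
  fixed <- stats::setNames(res$sol[seq_len(b["fixed"])], design$fixed_names)
  u <- res$sol[b["fixed"] + seq_len(b["animal"])]
  pe <- stats::setNames(res$sol[b["fixed"] + b["animal"] + seq_len(b["pe"])],
                        design$pe_ids)
  list(fixed = fixed, u = u, pe = pe,
       solver = res[c("method", "rel_residual", "iterations")])
}

new_ssblup <- function(cl, method, spec, weights, design, ans, kernel,
                       dataset_tag, pedigree, geno_meta, trace) {
  u <- stats::setNames(ans$u, pedigree$id)
  fitted <- as.numeric(design$X %*% ans$fixed + design$Za %*% ans$u +
                         design$Zp %*% ans$pe)
  structure(list(call = cl, method = method, spec = spec, weights = weights,
                 fixed = ans$fixed, u = u, pe = ans$pe,
                 fitted = fitted, y = design$y,
                 residuals = design$y - fitted,
                 solver = ans$solver, kernel = kernel,
                 dataset_tag = dataset_tag,
                 n_records = length(design$y),
                 pedigree_ids = pedigree$id,
                 geno = geno_meta, trace = trace),
            class = "ssblup")
}

#' @export
print.ssblup <- function(x, ...) {
  lab <- c(ablup = "pedigree BLUP (A)",
           ssgblup = "single-step GBLUP (H)",
           wssgblup = "SNP-weighted single-step GBLUP")[x$method]
  cat(lab, " [", x$dataset_tag, " data]\n", sep = "")
  cat("  ", x$n_records, " records, ", length(x$u), " animals",
      if (!is.null(x$geno))
        paste0(", ", length(x$geno$animal_id), " genotyped x ",
               x$geno$n_snps, " SNPs"), "\n", sep = "")
  if (!is.null(x$trace))
    cat("  ", length(x$trace), " weighting iterations (ct = ",
        x$weights$ct, ")\n", sep = "")
  cat("  solver: ", x$solver$method, ", relative residual ",
      format(x$solver$rel_residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted evaluation
#'
#' @param object an `ssblup` fit.
#' @param ... unused.
#' @export
summary.ssblup <- function(object, ...) {
  s <- list(fit = object,
            ebv = stats::quantile(object$u, c(0, .25, .5, .75, 1)),
            sd_ebv = stats::sd(object$u),
            resid_sd = stats::sd(object$residuals))
  if (!is.null(object$trace)) {
    last <- object$trace[[length(object$trace)]]
    s$weight_range <- range(last$d)
    s$top_snps <- utils::head(
      order(abs(last$effects), decreasing = TRUE), 10)
  }
  class(s) <- "summary.ssblup"
  s
}

#' @export
print.summary.ssblup <- function(x, ...) {
  print(x$fit)
  cat("  EBV quantiles:\n")
  print(signif(x$ebv, 4))
  cat("  sd(EBV) =", signif(x$sd_ebv, 4),
      "; sd(residual) =", signif(x$resid_sd, 4), "\n")
  if (!is.null(x$weight_range))
    cat("  final SNP weights in [", signif(x$weight_range[1], 4), ", ",
        signif(x$weight_range[2], 4), "]\n", sep = "")
  invisible(x)
}

#' @export
coef.ssblup <- function(object, ...) object$fixed

#' @export
fitted.ssblup <- function(object, ...) object$fitted

#' @export
residuals.ssblup <- function(object, ...) object$residuals

#' Extract predictions from a fit
#'
#' `type = "ebv"` (default) returns the estimated breeding values, for the
#' requested animals or all pedigree animals; `type = "response"` returns
#' the record-level fitted values `X b + Za u + Zp pe`.
#'
#' @param object an `ssblup` fit.
#' @param ids optional animal ids (EBV only).
#' @param type `"ebv"` or `"response"`.
#' @param ... unused.
#' @export
predict.ssblup <- function(object, ids = NULL, type = c("ebv", "response"),
                           ...) {
  type <- match.arg(type)
  if (type == "response") return(object$fitted)
  if (is.null(ids)) return(object$u)
  out <- object$u[ids]
  if (anyNA(out)) stop("ids not in pedigree: ",
                       paste(utils::head(ids[is.na(out)], 5), collapse = ", "))
  out
}

#' Diagnostic plot
#'
#' For weighted fits, plots the final per-SNP weights against SNP index
#' (a Manhattan-style view of where weight concentrated); otherwise plots
#' record-level fitted values against observations.
#'
#' @param x an `ssblup` fit.
#' @param ... passed to the underlying plot call.
#' @export
plot.ssblup <- function(x, ...) {
  if (!is.null(x$trace)) {
    last <- x$trace[[length(x$trace)]]
    graphics::plot(seq_along(last$d), last$d, type = "h",
                   xlab = "SNP index", ylab = "weight",
                   main = paste0("SNP weights, iteration ", last$t,
                                 " (ct = ", x$weights$ct, ")"), ...)
    graphics::abline(h = 1, lty = 2, col = "grey40")
  } else {
    graphics::plot(x$fitted, x$y, xlab = "fitted", ylab = "observed",
                   main = paste("Fitted vs observed,", x$method), ...)
    graphics::abline(0, 1, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' LR validation of two fits
#'
#' Computes the LR metrics over a validation set from a partial-data fit
#' and a whole-data fit. For weighted fits the metrics are computed for
#' every iteration pair in the traces; otherwise a single row is returned.
#'
#' @param fit_p fit on the partial dataset.
#' @param fit_w fit on the whole dataset (same method/settings).
#' @param validation_ids validation animal ids.
#' @param ped the `pedigree` (for the mean inbreeding of the validation set).
#' @param sigma2_u additive variance used in the accuracy denominator;
#'   defaults to the whole-data fit's value (set `which_sigma2 = "partial"`
#'   to take the partial fit's).
#' @param which_sigma2 `"whole"` or `"partial"`.
#' @return data.frame with one row per iteration: method, iteration, ct,
#'   acc, acc2, mu, b_wp, b_pw, n_validation, f_bar.
#' @export
lr_validate <- function(fit_p, fit_w, validation_ids, ped,
                        sigma2_u = NULL,
                        which_sigma2 = c("whole", "partial")) {
  which_sigma2 <- match.arg(which_sigma2)
  stopifnot(inherits(fit_p, "ssblup"), inherits(fit_w, "ssblup"))
  if (is.null(sigma2_u))
    sigma2_u <- if (which_sigma2 == "whole") fit_w$spec$sigma2_u
                else fit_p$spec$sigma2_u
  miss <- setdiff(validation_ids,
                  intersect(names(fit_p$u), names(fit_w$u)))
  if (length(miss))
    stop("validation animals missing from the fits: ",
         paste(utils::head(miss, 10), collapse = ", "))
  fbar <- mean(inbreeding(ped)[validation_ids])
  one <- function(up, uw, it) {
    m <- lr_metrics(up, uw, fbar, sigma2_u)
    data.frame(method = fit_w$method, iteration = it,
               ct = if (fit_w$method == "wssgblup") fit_w$weights$ct else NA,
               acc = m$acc, acc2 = m$acc2, mu = m$mu,
               b_wp = m$b_wp, b_pw = m$b_pw,
               n_validation = m$n_validation, f_bar = m$f_bar)
  }
  if (!is.null(fit_p$trace) && !is.null(fit_w$trace)) {
    k <- min(length(fit_p$trace), length(fit_w$trace))
    out <- do.call(rbind, lapply(seq_len(k), function(t) {
      up <- stats::setNames(fit_p$trace[[t]]$u, fit_p$pedigree_ids)
      uw <- stats::setNames(fit_w$trace[[t]]$u, fit_w$pedigree_ids)
      one(up[validation_ids], uw[validation_ids], t)
    }))
  } else {
    out <- one(fit_p$u[validation_ids], fit_w$u[validation_ids], 1L)
  }
  rownames(out) <- NULL
  out
}
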