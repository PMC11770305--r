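#' Run the whole/partial evaluation grid
#'
#' Orchestrates the full validation workflow on one dataset: build the
#' partial phenotype table, select the validation population (young
#' genotyped animals), fit every requested method on both datasets, and
#' compute the LR metrics for each method (per iteration and per `ct` for
#' the weighted method) — the method-by-metric grid of a standard
#' partial/whole validation study.
#'
#' @param ped a `pedigree`.
#' @param geno a `geno_matrix` (genotyped subset).
#' @param ph whole-dataset phenotype data.frame.
#' @param spec a [model_spec()].
#' @param cutoff_year last record year kept in the partial dataset.
#' @param validation_birth_year validation animals are genotyped animals
#'   born strictly after this year.
#' @param methods subset of `c("ablup", "ssgblup", "wssgblup")`.
#' @param cts `ct` values for the weighted method (one grid row each).
#' @param n_iter weighting iterations.
#' @param females optional id vector restricting validation to females.
#' @param require_no_partial_records exclude validation animals carrying
#'   records in the partial dataset.
#' @param blend_alpha,sd_cap weighting-scheme settings (see
#'   [weighting_config()]).
#' @param maf_min,solver,tol passed to [ssblup()].
#' @param keep_fits return the fitted objects as well.
#' @return list with `metrics` (data.frame: dataset-pairing metrics per
#'   method/iteration/ct), `validation_ids`, and optionally `fits`.
#' @export
run_pipeline <- function(ped, geno, ph, spec, cutoff_year,
                         validation_birth_year,
                         methods = c("ablup", "ssgblup", "wssgblup"),
                         cts = 1.5, n_iter = 5L, females = NULL,
                         require_no_partial_records = FALSE,
                         blend_alpha = 0.95, sd_cap = 5,
                         maf_min = 0.01, solver = "auto", tol = 1e-8,
                         keep_fits = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  partial <- make_partial(ph, cutoff_year)
  val <- select_validation(
    ped, geno$animal_id, validation_birth_year, females = females,
    no_records_in = if (require_no_partial_records) partial else NULL)
  fits <- list()
  rows <- list()
  fit1 <- function(method, data, tag, ct = 1.125) {
    ssblup(data, ped, spec,
           genotypes = if (method == "ablup") NULL else geno,
           method = method,
           weights = weighting_config(ct = ct, n_iter = n_iter,
                                      sd_cap = sd_cap,
                                      blend_alpha = blend_alpha),
           maf_min = maf_min, solver = solver, tol = tol,
           dataset_tag = tag)
  }
  for (m in setdiff(methods, "wssgblup")) {
    fw <- fit1(m, ph, "whole")
    fp <- fit1(m, partial, "partial")
    rows[[m]] <- lr_validate(fp, fw, val, ped)
    if (keep_fits) fits[[m]] <- list(whole = fw, partial = fp)
  }
  if ("wssgblup" %in% methods) for (ct in cts) {
    key <- paste0("wssgblup_ct", ct)
    fw <- fit1("wssgblup", ph, "whole", ct)
    fp <- fit1("wssgblup", partial, "partial", ct)
    rows[[key]] <- lr_validate(fp, fw, val, ped)
    if (keep_fits) fits[[key]] <- list(whole = fw, partial = fp)
  }
  out <- list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
              validation_ids = val)
  if (keep_fits) out$fits <- fits
  out
}

#' Write solutions to a CSV file
#'
#' Layout `effect,level,solution` with effects `fixed`, `animal` (EBV for
#' every pedigree animal) and `pe`, mirroring common breeding-software
#' solution files.
#'
#' @param fit an `ssblup` fit.
#' @param path output path.
#' @export
write_solutions <- function(fit, path) {
  stopifnot(inherits(fit, "ssblup"))
  lines <- c("effect,level,solution",
             paste("fixed", gsub(",", ";", names(fit$fixed)),
                   fmt_num(fit$fixed), sep = ","),
             paste("animal", names(fit$u), fmt_num(fit$u), sep = ","),
             paste("pe", names(fit$pe), fmt_num(fit$pe), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a solutions CSV written by [write_solutions()]
#'
#' @param path file path.
#' @return list with named vectors `fixed`, `u`, `pe`.
#' @export
read_solutions <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric"))
  pick <- function(eff) {
    s <- df[df$effect == eff, ]
    stats::setNames(s$solution, s$level)
  }
  list(fixed = pick("fixed"), u = pick("animal"), pe = pick("pe"))
}

#' Write per-iteration SNP effects and weights
#'
#' One `snp_weights_t<t>.csv` per weighting iteration, with columns
#' `snp_id,effect,weight`.
#'
#' @param fit a `wssgblup` fit (with a trace).
#' @param outdir output directory.
#' @export
write_snp_weights <- function(fit, outdir) {
  stopifnot(inherits(fit, "ssblup"))
  if (is.null(fit$trace)) stop("fit has no weighting trace")
  for (tr in fit$trace) {
    writeLines(c("snp_id,effect,weight",
                 paste(fit$geno$snp_id, fmt_num(tr$effects),
                       fmt_num(tr$d), sep = ",")),
               file.path(outdir, sprintf("snp_weights_t%d.csv", tr$t)))
  }
  invisible(outdir)
}
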