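#' Simulation configuration
#'
#' Defines a fully seeded synthetic dataset emulating the structure a
#' single-step evaluation of an early-lactation milk trait assumes: a
#' multi-generation pedigree with discrete generations and random mating, a
#' genotyped subset, an oligogenic trait (a few large QTL on a polygenic
#' SNP background), repeated records per cow under a repeatability model,
#' and record years supporting a partial/whole phenotype split.
#'
#' Default variance components give heritability 0.30 and repeatability
#' 0.50 on a unit total variance, with the trait mean on the mmol/L scale
#' of milk citrate; the herd-year-season effect variance (0.2) and the
#' first-calving age of 2 years (one parity per year) are typical of dairy
#' recording data.
#'
#' @param seed integer seed; fully determines all outputs.
#' @param n_founders founder-generation size.
#' @param n_generations total number of discrete generations (founders
#'   included).
#' @param n_matings matings per non-founder generation.
#' @param offspring_per_mating offspring per mating.
#' @param n_snps SNP panel size.
#' @param n_qtl number of causal SNPs (must be >= 1 and <= `n_snps`).
#' @param founder_freq_range uniform range of founder allele frequencies.
#' @param sigma2_u,sigma2_pe,sigma2_e additive, permanent-environment and
#'   residual variances.
#' @param sigma2_hys variance of the (fixed-in-estimation) herd-year-season
#'   effects.
#' @param qtl_effect `"two_point"` (equal magnitudes, random signs; the
#'   oligogenic default) or `"gamma"` (gamma(0.4) magnitudes, random signs).
#' @param records_per_animal_range inclusive integer range of records per cow.
#' @param n_hys_levels number of herd-year-season classes.
#' @param year_range `(first, last)` birth years; generations are mapped
#'   evenly onto it. Record years follow as `birth_year + 1 + parity`.
#' @param prop_genotyped fraction of animals genotyped (sampled uniformly).
#' @param phenotype_cutoff_year last record year kept in the partial dataset.
#' @param validation_birth_year validation animals are genotyped females
#'   born strictly after this year.
#' @param trait_mean overall trait mean (mmol/L).
#' @param sim_fixed_effects draw herd-year-season, days-in-milk and
#'   calving-age effects (`TRUE`); `FALSE` yields records that are pure
#'   `TBV + pe + e`.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 60L, n_generations = 4L,
                       n_matings = 30L, offspring_per_mating = 3L,
                       n_snps = 200L, n_qtl = 5L,
                       founder_freq_range = c(0.1, 0.9),
                       sigma2_u = 0.3, sigma2_pe = 0.2, sigma2_e = 0.5,
                       sigma2_hys = 0.2,
                       qtl_effect = c("two_point", "gamma"),
                       records_per_animal_range = c(1L, 3L),
                       n_hys_levels = 8L,
                       year_range = c(2010L, 2019L),
                       prop_genotyped = 0.3,
                       phenotype_cutoff_year = 2016L,
                       validation_birth_year = 2015L,
                       trait_mean = 9.04,
                       sim_fixed_effects = TRUE) {
  qtl_effect <- match.arg(qtl_effect)
  stopifnot(n_qtl >= 1, n_qtl <= n_snps, seed == as.integer(seed),
            sigma2_u > 0, sigma2_pe >= 0, sigma2_e >= 0,
            prop_genotyped > 0, prop_genotyped <= 1,
            n_generations >= 1, founder_freq_range[1] > 0,
            founder_freq_range[2] < 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: `n_founders` unrelated founders, then per
#' generation `n_matings` sire-dam pairs drawn at random from the previous
#' generation (males as sires, females as dams, so selfing is impossible),
#' each producing `offspring_per_mating` offspring of random sex. Birth
#' years map generations evenly onto `year_range`. Sexes are returned in
#' the `sex` element (`"M"`/`"F"`), aligned with `id`.
#'
#' @param cfg a [sim_config()].
#' @return a `pedigree` with an extra `sex` element.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  years <- round(seq(cfg$year_range[1], cfg$year_range[2],
                     length.out = max(cfg$n_generations, 2)))[
                       seq_len(cfg$n_generations)]
  id <- sprintf("A%06d", seq_len(cfg$n_founders))
  sire <- dam <- rep("0", cfg$n_founders)
  by <- rep(years[1], cfg$n_founders)
  sex <- sample(c("M", "F"), cfg$n_founders, replace = TRUE)
  gen_ids <- id
  nid <- cfg$n_founders
  if (cfg$n_generations > 1) for (g in 2:cfg$n_generations) {
    males <- gen_ids[sex[match(gen_ids, id)] == "M"]
    females <- gen_ids[sex[match(gen_ids, id)] == "F"]
    if (!length(males)) males <- gen_ids
    if (!length(females)) females <- gen_ids
    n_off <- cfg$n_matings * cfg$offspring_per_mating
    s <- rep(sample(males, cfg$n_matings, replace = TRUE),
             each = cfg$offspring_per_mating)
    d <- rep(sample(females, cfg$n_matings, replace = TRUE),
             each = cfg$offspring_per_mating)
    clash <- s == d                     # only possible under a fallback pool
    while (any(clash)) {
      d[clash] <- sample(females, sum(clash), replace = TRUE)
      clash <- s == d
    }
    kid <- sprintf("A%06d", nid + seq_len(n_off))
    nid <- nid + n_off
    id <- c(id, kid); sire <- c(sire, s); dam <- c(dam, d)
    by <- c(by, rep(years[g], n_off))
    sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
    gen_ids <- kid
  }
  ped <- as_pedigree(data.frame(animal = id, sire = sire, dam = dam,
                                birth_year = by))
  ped$sex <- sex[match(ped$id, id)]
  ped
}

drop_gamete <- function(dos) {
  # one transmitted allele per locus from a parent dosage vector
  (dos == 2) + (dos == 1) * stats::rbinom(length(dos), 1, 0.5)
}

#' Simulate genotypes by gene dropping
#'
#' Founder dosages are Binomial(2, p_i) with per-SNP founder frequencies
#' drawn uniformly from `founder_freq_range`; descendants receive one
#' Mendelian-sampled allele per locus from each parent. Loci are unlinked.
#' All pedigree animals are genotyped here; the analysis subset is drawn by
#' [sim_dataset()].
#'
#' @param ped a `pedigree` (ordered).
#' @param cfg a [sim_config()].
#' @return a `geno_matrix` over all pedigree animals.
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  p0 <- stats::runif(cfg$n_snps, cfg$founder_freq_range[1],
                     cfg$founder_freq_range[2])
  M <- matrix(0, ped$n, cfg$n_snps)
  for (i in seq_len(ped$n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    M[i, ] <- if (s == 0 && d == 0) stats::rbinom(cfg$n_snps, 2, p0)
    else drop_gamete(M[s, ]) + drop_gamete(M[d, ])
  }
  genotype_matrix(M, ped$id, sprintf("snp%04d", seq_len(cfg$n_snps)))
}

#' Simulate true breeding values and repeated phenotype records
#'
#' True breeding values are the dosage-weighted sum of the QTL effects,
#' centered and rescaled so that their variance among founders equals
#' `sigma2_u`. Each cow (females only) receives 1 to several records
#' `y = mean + hys + f(dim) + f(calving age, parity) + TBV + pe + e`
#' with a per-animal permanent-environment effect and record-specific
#' residual; record years follow the birth year (first calving at age 2,
#' one parity per year).
#'
#' @param ped a `pedigree` with a `sex` element.
#' @param geno full-pedigree `geno_matrix` from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `tbv` (named vector), `pe` (named vector), `qtl`
#'   (data.frame snp_id, effect on the rescaled trait scale), and
#'   `phenotypes` (record data.frame).
#' @export
simulate_trait <- function(ped, geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_qtl < 1) stop("n_qtl must be >= 1; trait undefined without QTL")
  set.seed(cfg$seed + 2L)
  qtl <- sort(sample.int(cfg$n_snps, cfg$n_qtl))
  eff <- switch(cfg$qtl_effect,
                two_point = sample(c(-1, 1), cfg$n_qtl, replace = TRUE),
                gamma = stats::rgamma(cfg$n_qtl, shape = 0.4) *
                  sample(c(-1, 1), cfg$n_qtl, replace = TRUE))
  raw <- as.numeric(geno$M[, qtl, drop = FALSE] %*% eff)
  fo <- ped$sire == 0 & ped$dam == 0
  v0 <- stats::var(raw[fo])
  if (v0 == 0) stop("QTL monomorphic among founders; increase n_qtl or MAF")
  sc <- sqrt(cfg$sigma2_u / v0)
  tbv <- (raw - mean(raw[fo])) * sc
  names(tbv) <- ped$id
  pe <- stats::rnorm(ped$n, 0, sqrt(cfg$sigma2_pe))
  names(pe) <- ped$id
  hys_eff <- if (cfg$sim_fixed_effects)
    stats::rnorm(cfg$n_hys_levels, 0, sqrt(cfg$sigma2_hys)) else
      numeric(cfg$n_hys_levels)
  cows <- which(ped$sex == "F")
  lo <- cfg$records_per_animal_range[1]; hi <- cfg$records_per_animal_range[2]
  nrec <- sample(seq(lo, hi), length(cows), replace = TRUE)
  ai <- rep(cows, nrec)
  parity <- unlist(lapply(nrec, seq_len), use.names = FALSE)
  m <- length(ai)
  dim <- sample.int(50L, m, replace = TRUE)
  ca <- 24 + 12 * (parity - 1) + round(stats::rnorm(m, 0, 1.5))
  hys <- sample.int(cfg$n_hys_levels, m, replace = TRUE)
  zd <- (dim - 25) / 15
  zc <- (ca - mean(ca)) / max(stats::sd(ca), 1e-8)
  fixed <- if (cfg$sim_fixed_effects)
    hys_eff[hys] + cfg$trait_mean - 0.4 * zd + 0.15 * zd^2 +
      (0.06 + 0.02 * parity) * zc - 0.03 * zc^2
  else numeric(m)
  e <- stats::rnorm(m, 0, sqrt(cfg$sigma2_e))
  y <- fixed + tbv[ai] + pe[ai] + e
  ph <- data.frame(animal = ped$id[ai], parity = parity, hys = hys,
                   dim = dim, calving_age = ca,
                   record_year = ped$birth_year[ai] + 1L + parity,
                   y = as.numeric(y))
  list(tbv = tbv, pe = pe,
       qtl = data.frame(snp_id = geno$snp_id[qtl], effect = eff * sc),
       phenotypes = ph)
}

#' Simulate a complete dataset
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and [simulate_trait()]
#' under `cfg` and draws the genotyped subset (`prop_genotyped`, uniform
#' over the pedigree). The full-pedigree genotypes are kept in `geno_all`
#' (the simulation truth); `geno` holds the genotyped-subset matrix with
#' allele frequencies recomputed on that subset, which is what an analysis
#' would observe.
#'
#' @param cfg a [sim_config()].
#' @return list of class `ssblup_sim`: `ped`, `geno`, `geno_all`,
#'   `genotyped_ids`, `phenotypes`, `truth`, `cfg`.
#' @export
sim_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno_all <- simulate_genotypes(ped, cfg)
  tr <- simulate_trait(ped, geno_all, cfg)
  set.seed(cfg$seed + 3L)
  k <- max(2L, round(cfg$prop_genotyped * ped$n))
  gids <- sort(sample(ped$id, min(k, ped$n)))
  geno <- genotype_matrix(geno_all$M[match(gids, ped$id), , drop = FALSE],
                          gids, geno_all$snp_id)
  structure(list(ped = ped, geno = geno, geno_all = geno_all,
                 genotyped_ids = gids, phenotypes = tr$phenotypes,
                 truth = list(tbv = tr$tbv, pe = tr$pe, qtl = tr$qtl),
                 cfg = cfg),
            class = "ssblup_sim")
}

#' @export
print.ssblup_sim <- function(x, ...) {
  cat("Simulated dataset: ", x$ped$n, " animals, ",
      length(x$genotyped_ids), " genotyped, ",
      nrow(x$phenotypes), " records, ", x$cfg$n_snps, " SNPs (",
      nrow(x$truth$qtl), " QTL)\n", sep = "")
  invisible(x)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write a simulated dataset to plain-text files
#'
#' Writes `pedigree.csv`, `genotypes.txt` (BLUPF90 dialect, genotyped subset),
#' `genotypes.csv` (CSV dialect), `phenotypes.csv`, `sex.csv`,
#' `truth_tbv.csv`, `truth_qtl.csv` and `config.yaml` (seed echo) with fixed
#' number formatting, so identical configurations produce byte-identical
#' files. The files round-trip through [read_dataset()].
#'
#' @param sim a `ssblup_sim` from [sim_dataset()].
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  stopifnot(inherits(sim, "ssblup_sim"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  write_pedigree(sim$ped, file.path(outdir, "pedigree.csv"))
  write_genotypes(sim$geno, file.path(outdir, "genotypes.txt"), "blupf90")
  write_genotypes(sim$geno, file.path(outdir, "genotypes.csv"), "csv")
  ph <- sim$phenotypes
  writeLines(c("animal,parity,hys,dim,calving_age,record_year,y",
               paste(ph$animal, ph$parity, ph$hys, ph$dim, ph$calving_age,
                     ph$record_year, fmt_num(ph$y), sep = ",")),
             file.path(outdir, "phenotypes.csv"))
  writeLines(c("animal,sex", paste(sim$ped$id, sim$ped$sex, sep = ",")),
             file.path(outdir, "sex.csv"))
  writeLines(c("animal,tbv",
               paste(names(sim$truth$tbv), fmt_num(sim$truth$tbv), sep = ",")),
             file.path(outdir, "truth_tbv.csv"))
  writeLines(c("snp_id,effect",
               paste(sim$truth$qtl$snp_id, fmt_num(sim$truth$qtl$effect),
                     sep = ",")),
             file.path(outdir, "truth_qtl.csv"))
  cfg <- sim$cfg
  class(cfg) <- NULL
  cfg$qtl_effect <- cfg$qtl_effect[1]
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory containing the dataset files.
#' @return list with `ped`, `geno`, `phenotypes`, `sex`, `truth`, `cfg`.
#' @export
read_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  sex <- utils::read.csv(file.path(dir, "sex.csv"),
                         colClasses = "character")
  ped$sex <- sex$sex[match(ped$id, sex$animal)]
  geno <- read_genotypes(file.path(dir, "genotypes.csv"))
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  tbv_df <- utils::read.csv(file.path(dir, "truth_tbv.csv"))
  tbv <- stats::setNames(tbv_df$tbv, tbv_df$animal)
  qtl <- utils::read.csv(file.path(dir, "truth_qtl.csv"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  list(ped = ped, geno = geno, phenotypes = ph, sex = sex,
       truth = list(tbv = tbv, qtl = qtl), cfg = cfg)
}
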