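test_that("ssblup objects expose the standard modelling methods", {
  sim <- small_sim()
  fit <- ssblup(sim$phenotypes, sim$ped, small_spec(), sim$geno,
                method = "ssgblup")
  expect_s3_class(fit, "ssblup")
  expect_output(print(fit), "single-step GBLUP")
  expect_output(print(summary(fit)), "EBV quantiles")
  expect_named(coef(fit))
  expect_length(predict(fit), sim$ped$n)
  expect_equal(length(fitted(fit)), nrow(sim$phenotypes))
  expect_equal(residuals(fit), sim$phenotypes$y - fitted(fit))
  expect_equal(unname(predict(fit, ids = sim$genotyped_ids[1:3])),
               unname(fit$u[sim$genotyped_ids[1:3]]))
  expect_error(predict(fit, ids = "ghost"), "not in pedigree")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("ablup ignores genotypes with a message; genomic methods need them", {
  sim <- small_sim()
  expect_message(ssblup(sim$phenotypes, sim$ped, small_spec(), sim$geno,
                        method = "ablup"), "ignored")
  expect_error(ssblup(sim$phenotypes, sim$ped, small_spec(),
                      method = "ssgblup"), "requires genotypes")
})

test_that("repeated runs with the same inputs are identical", {
  sim <- small_sim()
  f1 <- ssblup(sim$phenotypes, sim$ped, small_spec(), sim$geno,
               method = "wssgblup",
               weights = weighting_config(ct = 1.5, n_iter = 2))
  f2 <- ssblup(sim$phenotypes, sim$ped, small_spec(), sim$geno,
               method = "wssgblup",
               weights = weighting_config(ct = 1.5, n_iter = 2))
  expect_identical(f1$u, f2$u)
  expect_identical(f1$trace[[2]]$d, f2$trace[[2]]$d)
})

test_that("genomic information improves EBV accuracy for genotyped animals", {
  better <- 0
  for (s in 1:10) {
    sim <- sim_dataset(sim_config(seed = 200 + s, prop_genotyped = 0.5))
    spec <- small_spec()
    fa <- ssblup(sim$phenotypes, sim$ped, spec, method = "ablup")
    fg <- ssblup(sim$phenotypes, sim$ped, spec, sim$geno,
                 method = "ssgblup")
    ids <- sim$genotyped_ids
    ca <- cor(fa$u[ids], sim$truth$tbv[ids])
    cg <- cor(fg$u[ids], sim$truth$tbv[ids])
    if (cg > ca) better <- better + 1
  }
  expect_gte(better, 8)
})

test_that("solution files round-trip and weighted fits emit weight files", {
  sim <- small_sim()
  fit <- ssblup(sim$phenotypes, sim$ped, small_spec(), sim$geno,
                method = "wssgblup",
                weights = weighting_config(ct = 1.5, n_iter = 2))
  f <- tempfile(fileext = ".csv")
  write_solutions(fit, f)
  sol <- read_solutions(f)
  expect_equal(sol$u, fit$u, tolerance = 1e-10)
  expect_equal(sol$fixed, fit$fixed, tolerance = 1e-10,
               ignore_attr = TRUE)
  d <- tempfile(); dir.create(d)
  write_snp_weights(fit, d)
  expect_setequal(list.files(d), c("snp_weights_t1.csv", "snp_weights_t2.csv"))
  w2 <- read.csv(file.path(d, "snp_weights_t2.csv"))
  expect_equal(w2$weight, fit$trace[[2]]$d, tolerance = 1e-10)
})

test_that("lr_validate matches lr_metrics and errors on missing animals", {
  sim <- small_sim()
  spec <- small_spec()
  part <- make_partial(sim$phenotypes, sim$cfg$phenotype_cutoff_year)
  fw <- ssblup(sim$phenotypes, sim$ped, spec, sim$geno, method = "ssgblup")
  fp <- ssblup(part, sim$ped, spec, sim$geno, method = "ssgblup",
               dataset_tag = "partial")
  val <- select_validation(sim$ped, sim$genotyped_ids,
                           sim$cfg$validation_birth_year)
  tab <- lr_validate(fp, fw, val, sim$ped)
  ref <- suppressWarnings(
    lr_metrics(fp$u[val], fw$u[val],
               mean(inbreeding(sim$ped)[val]), spec$sigma2_u))
  expect_equal(tab$b_wp, ref$b_wp)
  expect_equal(tab$mu, ref$mu)
  expect_error(lr_validate(fp, fw, c(val, "ghost"), sim$ped), "missing")
})

test_that("the CLI runs simulate, fit and validate end to end", {
  td <- tempfile(); dir.create(td)
  sim <- suppressMessages(cli_main(c(
    "simulate", "--out", file.path(td, "data"), "--seed", "19",
    "--n-snps", "100")))
  expect_true(file.exists(file.path(td, "data", "pedigree.csv")))
  expect_true(file.exists(file.path(td, "data", "manifest.yaml")))
  common <- c("--pedigree", file.path(td, "data", "pedigree.csv"),
              "--genotypes", file.path(td, "data", "genotypes.csv"),
              "--phenotypes", file.path(td, "data", "phenotypes.csv"),
              "--sigma2-u", "0.3", "--sigma2-pe", "0.2", "--sigma2-e", "0.5")
  suppressMessages(cli_main(c("fit", common, "--method", "ssgblup",
                              "--dataset", "whole",
                              "--out", file.path(td, "whole"))))
  suppressMessages(cli_main(c("fit", common, "--method", "ssgblup",
                              "--dataset", "partial", "--cutoff-year", "2016",
                              "--out", file.path(td, "partial"))))
  m <- suppressWarnings(suppressMessages(cli_main(c(
    "validate",
    "--pedigree", file.path(td, "data", "pedigree.csv"),
    "--genotypes", file.path(td, "data", "genotypes.csv"),
    "--partial-solutions", file.path(td, "partial", "solutions_partial.csv"),
    "--whole-solutions", file.path(td, "whole", "solutions_whole.csv"),
    "--validation-birth-year", "2015", "--sigma2-u", "0.3",
    "--out", file.path(td, "val")))))
  expect_s3_class(m, "lr_metrics")
  expect_true(all(is.finite(c(m$acc, m$mu, m$b_wp, m$b_pw))))
  # identical solution files give the textbook identities
  m0 <- suppressMessages(cli_main(c(
    "validate",
    "--pedigree", file.path(td, "data", "pedigree.csv"),
    "--genotypes", file.path(td, "data", "genotypes.csv"),
    "--partial-solutions", file.path(td, "whole", "solutions_whole.csv"),
    "--whole-solutions", file.path(td, "whole", "solutions_whole.csv"),
    "--validation-birth-year", "2015", "--sigma2-u", "0.3",
    "--out", file.path(td, "val0"))))
  expect_equal(m0$mu, 0)
  expect_equal(m0$b_wp, 1)
  expect_equal(m0$b_pw, 1)
})

test_that("the pipeline subcommand reproduces the method grid on a fixture", {
  td <- tempfile(); dir.create(td)
  res <- suppressWarnings(suppressMessages(cli_main(c(
    "pipeline", "--out", td, "--seed", "23", "--n-snps", "100",
    "--cts", "1.5", "--n-iter", "2"))))
  expect_true(file.exists(file.path(td, "lr_metrics.csv")))
  tab <- read.csv(file.path(td, "lr_metrics.csv"))
  expect_setequal(unique(tab$method), c("ablup", "ssgblup", "wssgblup"))
  expect_true(all(is.finite(tab$acc)))
  expect_true(all(is.finite(tab$b_pw)))
  # same seed twice writes identical data files
  td2 <- tempfile()
  suppressWarnings(suppressMessages(cli_main(c(
    "pipeline", "--out", td2, "--seed", "23", "--n-snps", "100",
    "--cts", "1.5", "--n-iter", "2"))))
  expect_identical(readLines(file.path(td, "data", "phenotypes.csv")),
                   readLines(file.path(td2, "data", "phenotypes.csv")))
})

test_that("a validation set of one animal is rejected", {
  expect_error(lr_metrics(3, 4, 0, 1), "at least 2")
})
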