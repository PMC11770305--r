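one_rec_ph <- function(ids, y = seq_along(ids), year = 2015) {
  data.frame(animal = ids, parity = 1, hys = 1, dim = 25,
             calving_age = 24, record_year = year, y = y)
}

test_that("build_design: intercept-only, nesting layout, standardization", {
  ped <- ped_from_text("animal,sire,dam,birth_year
                        A,0,0,2000")
  d <- build_design(one_rec_ph("A"), intercept_spec(1, 1, 1), ped)
  expect_equal(as.matrix(d$X), matrix(1), ignore_attr = TRUE)

  sim <- small_sim()
  ph <- sim$phenotypes[sim$phenotypes$parity <= 2, ]
  d2 <- build_design(ph, small_spec(), sim$ped)
  cn <- colnames(d2$X)
  # calving-age constant/linear/quadratic nested in 2 parities:
  # constants = intercept + parity contrast, plus 2 x linear + 2 x quadratic
  expect_equal(sum(grepl("ca_std", cn)), 4)
  expect_true("(Intercept)" %in% cn)
  expect_equal(sum(cn == "parity_f2"), 1)
  X <- as.matrix(d2$X)
  expect_equal(mean(X[, "dim_std"]), 0, tolerance = 1e-12)
  expect_equal(sd(X[, "dim_std"]), 1, tolerance = 1e-12)
})

test_that("standardization is recomputed on the analyzed (partial) dataset", {
  sim <- small_sim()
  part <- make_partial(sim$phenotypes, sim$cfg$phenotype_cutoff_year)
  d <- build_design(part, small_spec(), sim$ped)
  expect_equal(d$std$dim, c(mean(part$dim), sd(part$dim)))
})

test_that("rank-deficient fixed designs are reported with column names", {
  ped <- ped_from_text("animal,sire,dam,birth_year
                        A,0,0,2000
                        B,0,0,2000")
  ph <- one_rec_ph(c("A", "B", "A"))
  ph$dim <- c(10, 20, 30)
  spec <- model_spec(1, 1, 1, fixed = ~ dim_std + I(2 * dim_std))
  expect_error(build_design(ph, spec, ped), "rank deficient")
})

test_that("phenotype validation catches bad parity, DIM, unknown animals", {
  ped <- ped_from_text("animal,sire,dam,birth_year
                        A,0,0,2000")
  ph <- one_rec_ph("A")
  expect_error(build_design(transform(ph, parity = 7),
                            small_spec(), ped), "parity")
  expect_error(build_design(transform(ph, dim = 60),
                            small_spec(), ped), "dim")
  expect_error(build_design(transform(ph, animal = "Z"),
                            small_spec(), ped), "not in pedigree")
})

test_that("MME with identity kernel reduces to closed-form ridge", {
  set.seed(21)
  n <- 8
  ped <- as_pedigree(data.frame(animal = letters[1:n], sire = "0",
                                dam = "0", birth_year = 2000))
  ph <- one_rec_ph(letters[1:n], y = rnorm(n))
  spec <- intercept_spec(2, 1, 4)        # la = 2, lpe = 4
  d <- build_design(ph, spec, ped)
  mme <- assemble_mme(d, spec, Matrix::Diagonal(n))
  sol <- solve_mme(mme$C, mme$rhs)$sol
  W <- cbind(1, diag(n), diag(n))        # intercept | animal | pe
  P <- diag(c(0, rep(2, n), rep(4, n)))
  ref <- solve(crossprod(W) + P, crossprod(W, ph$y))
  expect_equal(sol, as.numeric(ref), tolerance = 1e-10)
})

test_that("solutions are invariant to record order", {
  sim <- small_sim()
  spec <- small_spec()
  f1 <- ssblup(sim$phenotypes, sim$ped, spec, method = "ablup")
  set.seed(2)
  f2 <- ssblup(sim$phenotypes[sample(nrow(sim$phenotypes)), ],
               sim$ped, spec, method = "ablup")
  expect_equal(f1$u, f2$u, tolerance = 1e-9)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
})

test_that("large sigma2_pe limit reproduces the fixed-animal-effect model", {
  set.seed(31)
  n <- 12
  ped <- as_pedigree(data.frame(animal = sprintf("i%02d", 1:n), sire = "0",
                                dam = "0", birth_year = 2000))
  ids <- rep(ped$id, each = 3)
  ph <- data.frame(animal = ids, parity = rep(1:3, n), hys = 1,
                   dim = sample(1:50, 3 * n, TRUE), calving_age = 24,
                   record_year = 2015, y = rnorm(3 * n, rep(rnorm(n), each = 3)))
  # tiny additive variance shrinks u to ~0; huge pe variance frees pe
  spec <- model_spec(1e-8, 1e8, 1,
                     fixed = ~ dim_std + I(dim_std^2))
  fit <- ssblup(ph, ped, spec, method = "ablup")
  ref <- lm(y ~ dim_std + I(dim_std^2) + factor(animal),
            data = transform(ph, dim_std = (dim - mean(dim)) / sd(dim)))
  expect_equal(fitted(fit), unname(fitted(ref)), tolerance = 1e-4)
})

test_that("direct and PCG solvers agree on a 500-animal system", {
  ped <- rand_ped(13, n_founders = 100, n_generations = 5, n_matings = 50)
  expect_equal(ped$n, 500)
  set.seed(13)
  rec <- sample(ped$id, 300)
  ph <- data.frame(animal = rep(rec, 2), parity = rep(1:2, each = 300),
                   hys = sample(1:5, 600, TRUE), dim = sample(1:50, 600, TRUE),
                   calving_age = sample(22:40, 600, TRUE),
                   record_year = 2015, y = rnorm(600))
  spec <- small_spec()
  d <- build_design(ph, spec, ped)
  mme <- assemble_mme(d, spec, a_inverse(ped))
  s1 <- solve_mme(mme$C, mme$rhs, "direct")
  s2 <- solve_mme(mme$C, mme$rhs, "pcg", tol = 1e-10)
  expect_lt(max(abs(s1$sol - s2$sol)), 1e-6)
  expect_error(solve_mme(mme$C, mme$rhs, "pcg", tol = 1e-12, max_iter = 2L),
               "PCG did not converge")
})

test_that("pedigree BLUP matches the dense GLS oracle on a 5-animal toy", {
  ped <- ped_fullsib_mating()
  set.seed(41)
  ph <- data.frame(animal = rep(c("C", "D", "X"), each = 2),
                   parity = rep(1:2, 3), hys = 1,
                   dim = sample(1:50, 6), calving_age = 24,
                   record_year = 2015, y = rnorm(6, 5))
  spec <- intercept_spec(0.4, 0.3, 0.6)
  fit <- ssblup(ph, ped, spec, method = "ablup")
  d <- build_design(ph, spec, ped)
  ref <- gls_blup(as.matrix(d$X), as.matrix(d$Za), as.matrix(d$Zp),
                  ph$y, a_matrix(ped), 0.4, 0.3, 0.6)
  expect_equal(unname(fit$u), ref$u, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), ref$b, tolerance = 1e-8)
})

test_that("unrecorded offspring of recorded parents get the parent average", {
  ped <- ped_from_text("animal,sire,dam,birth_year
                        S,0,0,2000
                        D,0,0,2000
                        K,S,D,2001")
  set.seed(5)
  ph <- one_rec_ph(rep(c("S", "D"), each = 3), y = rnorm(6))
  ph$parity <- rep(1:3, 2)
  fit <- ssblup(ph, ped, intercept_spec(1, 1, 1), method = "ablup")
  expect_equal(unname(fit$u["K"]),
               unname((fit$u["S"] + fit$u["D"]) / 2), tolerance = 1e-8)
})

test_that("predictions are invariant to the factor reference level", {
  sim <- small_sim()
  spec1 <- model_spec(0.3, 0.2, 0.5, fixed = ~ hys_f + dim_std)
  spec2 <- model_spec(0.3, 0.2, 0.5,
                      fixed = ~ stats::relevel(hys_f, ref = "3") + dim_std)
  f1 <- ssblup(sim$phenotypes, sim$ped, spec1, method = "ablup")
  f2 <- ssblup(sim$phenotypes, sim$ped, spec2, method = "ablup")
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-8)
  expect_equal(f1$u, f2$u, tolerance = 1e-8)
})

test_that("single-step with G* equal to A22 collapses to pedigree BLUP", {
  sim <- small_sim()
  spec <- small_spec()
  d <- build_design(sim$phenotypes, spec, sim$ped)
  Ai <- a_inverse(sim$ped)
  gid <- sim$genotyped_ids
  A22 <- a_matrix(sim$ped, gid)
  Hi <- h_inverse(Ai, A22, A22, match(gid, sim$ped$id))
  m1 <- assemble_mme(d, spec, Ai)
  m2 <- assemble_mme(d, spec, Hi)
  expect_equal(solve_mme(m1$C, m1$rhs)$sol, solve_mme(m2$C, m2$rhs)$sol,
               tolerance = 1e-7)
})
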