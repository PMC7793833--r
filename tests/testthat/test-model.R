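test_that("fixed-effects-only fit equals ordinary least squares", {
  ped <- as_ped_table(trio_df())
  phe <- as_pheno_table(data.frame(
    animal = c("s", "d", "o", "o"), trait = "H",
    cg = c("c1", "c1", "c2", "c2"), value = c(1, 2, 3, 5)), ped)
  vc <- variance_components(matrix(1), 1, 1, traits = "H")
  fit <- solve_mme(phe, ainverse(ped), vc, random = character(0))
  ols <- coef(lm(value ~ 0 + cg, data = phe))
  expect_equal(unname(sort(fit$beta)), unname(sort(ols)), tolerance = 1e-10)
})

test_that("animal-model solutions match a hand-assembled dense system", {
  ped <- as_ped_table(data.frame(id = c("s", "d", "o1", "o2"),
                                 sire = c("0", "0", "s", "s"),
                                 dam = c("0", "0", "d", "d")))
  phe <- as_pheno_table(data.frame(animal = c("s", "d", "o1", "o2"), trait = "H",
                                   cg = c("c1", "c1", "c2", "c2"),
                                   value = c(1.0, 2.0, 1.5, 2.5)), ped)
  vc <- variance_components(matrix(2), 3, 4, traits = "H")
  fit <- solve_mme(phe, ainverse(ped), vc)
  A <- unclass(build_A(ped))
  X <- model.matrix(~ 0 + cg, phe)
  V <- 2 * A + 3 * diag(4) + 4 * diag(4)
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, phe$value)))
  ahat <- 2 * A %*% solve(V, phe$value - X %*% beta)
  expect_equal(unname(fit$a[, 1]), unname(as.numeric(ahat)), tolerance = 1e-8)
  expect_equal(unname(sort(fit$beta)), unname(sort(as.numeric(beta))),
               tolerance = 1e-8)
})

test_that("solutions are invariant to record and animal permutations and
           repeated records are absorbed by the permanent-environment term", {
  s <- small_sim(seed = 71)
  sim <- s$sim
  vc <- variance_components(sim$truth$G0, sim$truth$D0, sim$truth$R0)
  Kinv <- ainverse(sim$ped)
  fit1 <- solve_mme(sim$phenotypes, Kinv, vc)
  idx <- sample(nrow(sim$phenotypes))
  phe2 <- as_pheno_table(as.data.frame(sim$phenotypes)[idx, , drop = FALSE],
                         sim$ped)
  fit2 <- solve_mme(phe2, Kinv, vc)
  expect_equal(fit1$a, fit2$a, tolerance = 1e-8)
  expect_equal(sort(fit1$beta), sort(fit2$beta), tolerance = 1e-8)
  expect_equal(fit1$d[names(fit2$d)], fit2$d, tolerance = 1e-8)
})

test_that("single-step solutions collapse to pedigree BLUP when G = A22", {
  s <- small_sim(seed = 73)
  sim <- s$sim
  vc <- variance_components(sim$truth$G0, sim$truth$D0, sim$truth$R0)
  ped <- sim$ped
  A <- build_A(ped)
  gids <- sim$genotypes$ids
  A22 <- extract_A22(A, gids)
  Hinv <- build_Hinv(ainverse(ped), A22, A22)
  fit_blup <- solve_mme(sim$phenotypes, ainverse(ped), vc)
  fit_ss <- solve_mme(sim$phenotypes, Hinv, vc)
  expect_equal(fit_blup$a, fit_ss$a, tolerance = 1e-6)
})

test_that("aliased fixed effects are reported by name", {
  ped <- as_ped_table(trio_df())
  phe <- as_pheno_table(data.frame(
    animal = c("s", "d", "o"), trait = "B", cg = c("c1", "c1", "c2"),
    value = c(1, 2, 3), zebu = c(0, 0, 1), het = c(0, 0, 1)), ped)
  vc <- variance_components(matrix(1), 1, 1, traits = "B")
  expect_error(solve_mme(phe, ainverse(ped), vc), "aliased")
})

test_that("metafounder rescaling of genetic parameters is exact arithmetic", {
  vc <- variance_components(G0 = matrix(c(0.013, 0.008, 0.008, 0.018), 2),
                            D0 = c(0.009, 0.013), R0 = c(0.060, 0.074))
  # gamma = 0: nothing changes
  g0 <- metafounder_set(c("H", "B"), matrix(0, 2, 2))
  gp0 <- genetic_params(vc, g0)
  gp_none <- genetic_params(vc)
  expect_equal(gp0$h2, gp_none$h2)
  expect_equal(gp0$k, c(H = 1, B = 1))
  # gamma_H = 0.61 gives scale factor 0.695
  g1 <- metafounder_set(c("H", "B"), matrix(c(0.61, 0.46, 0.46, 0.53), 2))
  gp1 <- genetic_params(vc, g1)
  expect_equal(unname(gp1$k["H"]), 1 - 0.61 / 2)
  expect_equal(unname(gp1$scaled_va["H"]), 0.013 * 0.695)
  # invariance of ratios under global rescaling of all components
  vc2 <- variance_components(10 * vc$G0, 10 * vc$D0, 10 * vc$R0)
  gp2 <- genetic_params(vc2, g1)
  expect_equal(gp2$h2, gp1$h2)
  expect_equal(gp2$repeatability, gp1$repeatability)
  expect_equal(gp2$r_a, gp1$r_a)
})

test_that("published variance components reproduce the printed parameters", {
  ref <- read.csv(system.file("extdata", "variance_components_reference.csv",
                              package = "mfssgblup"), comment.char = "#")
  bb <- ref[ref$model == "blup" & ref$trait == "B", ]
  vc <- list(G0 = diag(c(0.003, bb$sigma_a)), D0 = c(0.018, bb$sigma_d),
             R0 = c(0.060, bb$sigma_e), traits = c("H", "B"))
  gp <- genetic_params(vc)
  expect_equal(round(unname(gp$h2["B"]), 2), 0.25)
  expect_equal(round(unname(gp$repeatability["B"]), 2), 0.31)
})

test_that("AI-REML recovers components on a small model-matched simulation", {
  cfg <- sim_config(n_founders = c(H = 40), n_markers = 20, n_gen = 3,
                    n_per_gen = 120, f_drift = c(H = 0.1), p_pure = c(H = 1),
                    mask_both = 0, mask_sire = 0, mask_dam = 0,
                    genotyping_fraction = 0.05, rec_probs = c(0, 0, 1),
                    bv_base = "plain")
  pools <- simulate_founder_pools(cfg, seed = 75)
  sim <- simulate_population(cfg, pools, seed = 75)
  vc <- aireml(sim$phenotypes, ainverse(sim$ped), tol = 1e-6, max_iter = 40)
  expect_true(vc$converged)
  h <- h2_se(vc, "H")
  expect_lt(abs(h$h2 - 0.25), 3 * h$se)
  # likelihood never decreases across EM fallback steps
  ll <- vc$trace$loglik
  em_rows <- which(vc$trace$step == "em")
  em_rows <- em_rows[em_rows > 1]
  expect_true(all(ll[em_rows] >= ll[em_rows - 1] - 1e-6))
  # standard errors are positive and finite
  expect_true(all(is.finite(vc$se) & vc$se > 0))
})

test_that("a zero additive variance collapses to the boundary and is flagged", {
  cfg <- sim_config(n_founders = c(H = 60), n_markers = 20, n_gen = 3,
                    n_per_gen = 180, f_drift = c(H = 0.1), p_pure = c(H = 1),
                    mask_both = 0, mask_sire = 0, mask_dam = 0,
                    genotyping_fraction = 0.05, rec_probs = c(0, 0, 1),
                    G0 = matrix(c(1e-12, 0, 0, 1e-12), 2),
                    D0 = diag(c(0.15, 0.15)), R0 = c(0.6, 0.6),
                    bv_base = "plain")
  pools <- simulate_founder_pools(cfg, seed = 77)
  sim <- simulate_population(cfg, pools, seed = 77)
  expect_lt(max(abs(sim$truth$a_true)), 1e-4)   # zero genetic variance
  vc <- suppressWarnings(aireml(sim$phenotypes, ainverse(sim$ped),
                                tol = 1e-4, max_iter = 40))
  # estimate collapses to a small fraction of the phenotypic variance and
  # is flagged as statistically indistinguishable from the boundary
  expect_lt(vc$G0[1, 1], 0.1 * var(sim$phenotypes$value))
  expect_true(any(vc$boundary[grep("^a:", names(vc$boundary))]))
})

test_that("permanent-environment warning fires for single-record traits", {
  ped <- as_ped_table(data.frame(id = c("s", "d", "o"), sire = c("0", "0", "s"),
                                 dam = c("0", "0", "d")))
  phe <- as_pheno_table(data.frame(animal = c("s", "d", "o"), trait = "H",
                                   cg = "c1", value = c(1, 2, 3)), ped)
  msgs <- character()
  withCallingHandlers(
    try(aireml(phe, ainverse(ped), max_iter = 1), silent = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("single records", msgs)))
})
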