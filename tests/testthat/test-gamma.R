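test_that("identity-covariance GLS reduces to plain group means", {
  ped <- hz_f1_ped(seed = 51)
  gids <- grep("^[HZ]", ped$id, value = TRUE)
  set.seed(52)
  M <- matrix(sample(0:2, length(gids) * 20, TRUE), length(gids), 20)
  G <- geno_matrix(M, ids = gids)
  means <- gls_gene_content_means(G, ped, identity_v = TRUE)
  grp <- ped$founder_group[match(gids, ped$id)]
  for (b in c("H", "Z")) {
    expect_equal(unname(means$mu[, b]),
                 unname(colMeans(M[grp == b, , drop = FALSE])), tolerance = 1e-10)
  }
  # monomorphic-zero marker gives zero means in every pool
  M2 <- cbind(M, 0L)
  means2 <- gls_gene_content_means(geno_matrix(M2, ids = gids), ped,
                                   identity_v = TRUE)
  expect_equal(unname(means2$mu[21, ]), c(0, 0), tolerance = 1e-10)
})

test_that("GLS on disconnected purebred families equals family-wise GLS", {
  # two unrelated purebred families: block-diagonal V, estimates decouple
  df <- data.frame(
    id = c("h1", "h2", "h3", "z1", "z2", "z3"),
    sire = c("0", "0", "h1", "0", "0", "z1"),
    dam = c("0", "0", "h2", "0", "0", "z2"),
    breed_code = c("H", "H", NA, "Z", "Z", NA))
  ped <- as_ped_table(df)
  ped$founder_group <- ifelse(is.na(ped$sire), ped$breed_code, NA)
  set.seed(53)
  M <- matrix(sample(0:2, 6 * 30, TRUE), 6, 30)
  G <- geno_matrix(M, ids = df$id)
  means <- gls_gene_content_means(G, ped, lambda = 1e-3)
  pm <- partial_matrices(ped)
  lam <- 1e-3
  for (b in c("H", "Z")) {
    fam <- if (b == "H") c("h1", "h2", "h3") else c("z1", "z2", "z3")
    Vb <- unclass(pm$partial[[b]])[fam, fam]
    Vfull <- Reduce(`+`, lapply(pm$partial, function(m) unclass(m)[fam, fam]))
    diag(Vfull) <- diag(Vfull) + lam * mean(diag(
      Reduce(`+`, lapply(pm$partial, unclass)) +
        Reduce(`+`, lapply(pm$segregation, unclass))))
    q <- rep(1, 3)
    byhand <- as.numeric(solve(t(q) %*% solve(Vfull, q)) %*%
                           (t(q) %*% solve(Vfull, M[match(fam, G$ids), ])))
    expect_equal(unname(means$mu[, b]), byhand, tolerance = 1e-8)
  }
})

test_that("gamma estimation is 2x the covariance of means with PSD projection", {
  mu <- matrix(rep(c(1, 1.4), each = 5), 5, 2)   # identical across markers
  means <- structure(list(mu = mu, pools = c("H", "Z"), lambda = 1,
                          n_genotyped = 10), class = "gene_content_means")
  g0 <- estimate_gamma(means)
  expect_equal(unname(g0$gamma), matrix(0, 2, 2))
  # algebraic identity: 2 cov(mu) = 8 cov(mu / 2)
  set.seed(54)
  mu2 <- matrix(rnorm(200), 100, 2)
  means2 <- structure(list(mu = mu2, pools = c("H", "Z"), lambda = 1,
                           n_genotyped = 10), class = "gene_content_means")
  g2 <- estimate_gamma(means2)
  expect_equal(g2$gamma, metafounder_set(c("H", "Z"), 8 * cov(mu2 / 2))$gamma)
  # Cauchy-Schwarz after projection
  expect_lte(g2$gamma[1, 2]^2, prod(diag(g2$gamma)) + 1e-12)
  # the GLS estimate itself is a sample covariance, hence PSD already
  expect_false(attr(g2, "projected"))
  # the projection guard clips negative eigenvalues of supplied matrices
  ind <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 0.2), 3)
  expect_lt(min(eigen(ind, symmetric = TRUE)$values), 0)
  expect_message(pr <- psd_project(ind), "projecting")
  expect_true(pr$projected)
  expect_gt(min(eigen(pr$m, symmetric = TRUE)$values), -1e-10)
  expect_error(psd_project(ind, error = TRUE), "semidefinite")
})

test_that("gamma estimates are invariant to marker and animal order", {
  s <- small_sim(seed = 55, missing_rate = 0)
  sim <- s$sim
  pedm <- add_metafounders(sim$ped, sim$mf_rules)
  G <- sim$genotypes
  g1 <- estimate_gamma(gls_gene_content_means(G, pedm))
  pm <- sample(ncol(G$M)); am <- sample(length(G$ids))
  G2 <- geno_matrix(G$M[am, pm], ids = G$ids[am],
                    markers = G$markers[pm])
  g2 <- estimate_gamma(gls_gene_content_means(G2, pedm))
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-8)
})

test_that("GLS errors when a pool has no genotyped ancestry", {
  ped <- hz_f1_ped(seed = 57)
  hids <- grep("^H", ped$id, value = TRUE)
  set.seed(58)
  G <- geno_matrix(matrix(sample(0:2, length(hids) * 10, TRUE), length(hids), 10),
                   ids = hids)
  expect_error(gls_gene_content_means(G, ped), "no genotyped ancestry")
})

test_that("moment estimator needs data and agrees with GLS on complete panels", {
  G1 <- geno_matrix(matrix(0:1, 2, 1, dimnames = list(c("a", "b"), NULL)))
  expect_error(naive_gamma(G1, c(a = "H", b = "H")), "2 markers")
  G2 <- geno_matrix(matrix(sample(0:2, 10, TRUE), 2, 5,
                           dimnames = list(c("a", "b"), NULL)))
  expect_error(naive_gamma(G2, c(a = "H", b = "Z")), "fewer than 2")
  # two identical groups give equal diagonal and off-diagonal entries
  set.seed(59)
  M <- matrix(rbinom(40 * 60, 2, 0.4), 40, 60)
  G3 <- geno_matrix(M, ids = paste0("a", 1:40))
  grp <- stats::setNames(rep(c("H", "Z"), each = 20), G3$ids)
  # same animals in both groups: exactly equal entries
  grp_same <- stats::setNames(rep("H", 40), G3$ids)
  g_same <- naive_gamma(G3, c(grp_same[1:20], stats::setNames(rep("Z", 20), G3$ids[1:20])))
  expect_equal(g_same$gamma[1, 1], g_same$gamma[2, 2])
  expect_equal(g_same$gamma[1, 1], g_same$gamma[1, 2])
  # deep complete purebred pedigrees: GLS close to the moment estimator
  cfg <- sim_config(n_founders = c(H = 40, Z = 40), n_markers = 600,
                    n_gen = 2, n_per_gen = 60, p_pure = c(H = 0.5, Z = 0.5),
                    mask_both = 0, mask_sire = 0, mask_dam = 0,
                    genotyping_fraction = 1, missing_rate = 0)
  pools <- simulate_founder_pools(cfg, seed = 60)
  sim <- simulate_population(cfg, pools, seed = 60)
  pedm <- add_metafounders(sim$ped, sim$mf_rules)
  gls <- estimate_gamma(gls_gene_content_means(sim$genotypes, pedm))
  comp <- breed_composition(pedm)
  pure <- comp$ids[comp$fractions[, "H"] == 1 | comp$fractions[, "Z"] == 1]
  pure <- intersect(pure, sim$genotypes$ids)
  grp2 <- stats::setNames(ifelse(comp$fractions[match(pure, comp$ids), "H"] == 1,
                                 "H", "Z"), pure)
  mom <- naive_gamma(sim$genotypes, grp2)
  expect_lt(max(abs(gls$gamma[c("H", "Z"), c("H", "Z")] - mom$gamma)), 0.05)
})

test_that("drift toward a single ancestral pool collapses gamma to one value", {
  cfg <- sim_config(n_founders = c(H = 30, Z = 30), n_markers = 3000,
                    f_drift = c(H = 1e-4, Z = 1e-4))
  pools <- simulate_founder_pools(cfg, seed = 61)
  tg <- pools$true_gamma$gamma
  expect_lt(max(abs(tg - tg[1, 1])), 0.05 * max(abs(tg), 0.1))
})
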