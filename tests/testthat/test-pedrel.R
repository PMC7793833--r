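test_that("breed composition follows gamete-origin probabilities", {
  # purebred founder, F1 and backcross coefficients enumerate exactly
  df <- data.frame(
    id = c("h1", "h2", "z1", "f1", "bc"),
    sire = c("0", "0", "0", "h1", "h2"),
    dam = c("0", "0", "0", "z1", "f1"),
    breed_code = c("H", "H", "Z", NA, NA), stringsAsFactors = FALSE)
  ped <- as_ped_table(df)
  ped$founder_group <- ifelse(is.na(ped$sire), ped$breed_code, NA)
  bc <- breed_composition(ped)
  expect_equal(bc$fractions["h1", ], c(H = 1, Z = 0))
  expect_equal(bc$heterozygosity[["h1"]], 0)
  expect_equal(bc$fractions["f1", ], c(H = 0.5, Z = 0.5))
  expect_equal(bc$het[["f1", "H:Z"]], 1.0)
  expect_equal(bc$recloss[["f1", "H:Z"]], 0.5)
  expect_equal(bc$fractions["bc", ], c(H = 0.75, Z = 0.25))
  expect_equal(bc$het[["bc", "H:Z"]], 0.5)   # sire pure H, dam F1
})

test_that("tabular A handles metafounder self-relationships", {
  ped <- as_ped_table(trio_df(), mf_rules = c(HH = "H", ZZ = "Z"))
  mfs <- metafounder_set(c("H", "Z"), matrix(c(0.61, 0.34, 0.34, 0.96), 2))
  A <- build_A(ped)
  Ag <- build_A(ped, mfs)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["o", "o"], 1)
  expect_equal(Ag["s", "s"], 1 + 0.61 / 2)   # founder under gamma_H = 0.61
  expect_equal(Ag["d", "d"], 1 + 0.96 / 2)
  # Gamma = 0 reduces exactly to the standard matrix
  A0 <- build_A(ped, metafounder_set(c("H", "Z"), matrix(0, 2, 2)))
  keep <- !ped$is_metafounder
  expect_equal(unclass(A0)[keep, keep], unclass(A)[keep, keep])
  expect_error(build_A(ped, metafounder_set("H", matrix(0.5))), "labels")
})

test_that("metafounder augmentation never decreases relationships and bounds diagonals", {
  ped <- random_crossbred_ped(8, 30, seed = 6)
  pedm <- add_metafounders(
    as_ped_table(data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                            breed_code = ped$founder_group)),
    mf_rules = c(H = "H", Z = "Z"))
  mfs <- metafounder_set(c("H", "Z"), matrix(c(0.5, 0.2, 0.2, 0.8), 2))
  keep <- !pedm$is_metafounder
  A <- unclass(build_A(pedm))[keep, keep]
  Ag <- unclass(build_A(pedm, mfs))[keep, keep]
  expect_true(all(Ag - A > -1e-12))
  expect_true(all(diag(Ag) >= 1 - 1e-12))
  # the [1, 1 + max(gamma)/2] diagonal band applies to pedigrees without
  # within-pedigree inbreeding (founders related only through the pools)
  pedf <- add_metafounders(
    as_ped_table(data.frame(id = hz_f1_ped()$id, sire = hz_f1_ped()$sire,
                            dam = hz_f1_ped()$dam,
                            breed_code = hz_f1_ped()$founder_group)),
    mf_rules = c(H = "H", Z = "Z"))
  Agf <- unclass(build_A(pedf, mfs))[!pedf$is_metafounder, !pedf$is_metafounder]
  expect_true(all(diag(Agf) >= 1 - 1e-12))
  expect_true(all(diag(Agf) <= 1 + max(mfs$gamma) / 2 + 1e-12))
})

test_that("inbreeding is diagonal minus one in every matrix kind", {
  ped <- fullsib_ped()
  A <- build_A(ped)
  expect_equal(unname(inbreeding(A)["x"]), 0.25)
  pedm <- as_ped_table(trio_df(), mf_rules = c(HH = "H", ZZ = "Z"))
  mfs <- metafounder_set(c("H", "Z"), matrix(c(0.61, 0.3, 0.3, 0.9), 2))
  expect_equal(unname(inbreeding(build_A(pedm, mfs))["s"]), 0.61 / 2)
  # fully heterozygous animal under 0.5 frequencies: diagonal 0, F = -1
  G <- geno_matrix(matrix(1L, 1, 10, dimnames = list("a", NULL)))
  expect_equal(unname(inbreeding(build_G(G, "half"))["a"]), -1)
})

test_that("partial matrices reproduce single-breed, F1 and sum identities", {
  # single breed: A^b equals A, no segregation
  ped1 <- random_crossbred_ped(6, 20, seed = 9)
  ped1$founder_group[!is.na(ped1$founder_group)] <- "H"
  pm1 <- partial_matrices(ped1)
  expect_equal(unclass(pm1$partial$H), unclass(build_A(ped1)), ignore_attr = TRUE)
  # F1 diagonal splits half/half
  ped <- hz_f1_ped()
  pm <- partial_matrices(ped)
  f1 <- grep("^F1_", ped$id, value = TRUE)[1]
  expect_equal(pm$partial$H[f1, f1], 0.5)
  expect_equal(pm$partial$Z[f1, f1], 0.5)
  # random crossbred pedigree incl. backcrosses: sum identity to 1e-8
  ped2 <- random_crossbred_ped(10, 50, seed = 11)
  pm2 <- partial_matrices(ped2)
  tot <- Reduce(`+`, lapply(pm2$partial, unclass)) +
    Reduce(`+`, lapply(pm2$segregation, unclass))
  expect_lt(max(abs(tot - unclass(build_A(ped2)))), 1e-8)
  # backcross partial diagonal from enumerated gamete-origin coefficients:
  # sire F1 (f_H = 1/2), dam pure H -> ((1/2)^2 + 1)/2 = 0.625
  df <- data.frame(id = c("h1", "h2", "z1", "f1", "bc"),
                   sire = c("0", "0", "0", "h1", "h2"),
                   dam = c("0", "0", "0", "z1", "f1"),
                   breed_code = c("H", "H", "Z", NA, NA))
  ped3 <- as_ped_table(df)
  ped3$founder_group <- ifelse(is.na(ped3$sire), ped3$breed_code, NA)
  pm3 <- partial_matrices(ped3)
  expect_equal(pm3$partial$H["bc", "bc"], 0.625)
  expect_equal(pm3$partial$Z["bc", "bc"], 0.125)
  expect_equal(pm3$segregation[["H:Z"]]["bc", "bc"], 0.25)
})

test_that("gene-drop oracle matches A and pool-restricted partials", {
  ped <- hz_f1_ped(n_h = 8, n_z = 8, n_f1 = 10, n_pure = 10, seed = 3)
  n_drops <- 4000
  Ad <- gene_drop_ibd(ped, n_drops = n_drops, seed = 5)
  A <- build_A(ped)
  mc_se <- 3 * 0.5 / sqrt(n_drops)     # binomial bound on an IBD proportion
  expect_lt(max(abs(unclass(Ad) - unclass(A))), 4 * mc_se)
  pm <- partial_matrices(ped)
  for (b in c("H", "Z")) {
    Ab <- gene_drop_ibd(ped, n_drops = n_drops, seed = 6, pool = b)
    expect_lt(max(abs(unclass(Ab) - unclass(pm$partial[[b]]))), 4 * mc_se)
  }
})

test_that("relationship inversion matches Henderson rules and handles jitter", {
  I3 <- rel_matrix(diag(3), "A", ids = letters[1:3])
  expect_equal(unclass(invert_relationship(I3)), diag(3), ignore_attr = TRUE)
  # non-inbred trio: Henderson's rules give the sparse inverse directly
  ped <- as_ped_table(trio_df())
  A <- build_A(ped)
  Ainv <- invert_relationship(A)
  H <- diag(3) ; rownames(H) <- colnames(H) <- c("s", "d", "o")
  d_o <- 0.5                                 # 1/2 - 1/4 (F_s + F_d), no inbreeding
  H["o", "o"] <- H["o", "o"] - 1 + 1 / d_o
  for (p in c("s", "d")) {
    H[p, p] <- H[p, p] + 0.25 / d_o
    H[p, "o"] <- H["o", p] <- -0.5 / d_o
  }
  H["s", "d"] <- H["d", "s"] <- 0.25 / d_o
  expect_equal(unclass(Ainv)[rownames(H), rownames(H)], H, tolerance = 1e-10)
  # singular matrix succeeds with jitter and reports otherwise
  S <- rel_matrix(matrix(c(1, 1, 1, 1), 2), "A", ids = c("a", "b"))
  expect_error(invert_relationship(S), "eigenvalue")
  expect_message(invert_relationship(S, jitter = 1e-8), "jitter")
})

test_that("A22 extraction preserves order and symmetry", {
  ped <- random_crossbred_ped(6, 24, seed = 13)
  A <- build_A(ped)
  expect_equal(unclass(extract_A22(A, ped$id)), unclass(A), ignore_attr = TRUE)
  one <- extract_A22(A, ped$id[5])
  expect_equal(dim(one), c(1L, 1L))
  sub <- extract_A22(A, sample(ped$id, 10))
  expect_symmetric(sub)
  expect_error(extract_A22(A, "ghost"), "not in relationship")
})

test_that("pedigree-structured sparse inverse equals the dense inverse", {
  ped <- random_crossbred_ped(8, 40, seed = 17)
  ai <- ainverse(ped)
  A <- unclass(build_A(ped))
  expect_lt(max(abs(as.matrix(ai$Ainv) - solve(A))), 1e-8)
  expect_equal(ai$logdet, as.numeric(determinant(A)$modulus), tolerance = 1e-8)
  # with metafounders and Gamma
  pedm <- add_metafounders(
    as_ped_table(data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                            breed_code = ped$founder_group)),
    mf_rules = c(H = "H", Z = "Z"))
  mfs <- metafounder_set(c("H", "Z"), matrix(c(0.6, 0.25, 0.25, 0.9), 2))
  aim <- ainverse(pedm, mfs)
  Am <- unclass(build_A(pedm, mfs))
  expect_lt(max(abs(as.matrix(aim$Ainv) - solve(Am))), 1e-8)
  expect_equal(aim$logdet, as.numeric(determinant(Am)$modulus), tolerance = 1e-8)
})
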