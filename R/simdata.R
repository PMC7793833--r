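#' Configuration of the synthetic multibreed population
#'
#' The defaults emulate the structure of a multibreed beef-cattle
#' tick-count evaluation: two purebred founder pools (Hereford-like `H`
#' and Zebu-like `Z`) derived from one ancestral population (so the true
#' ancestral relationship matrix Gamma is positive), crossbred descendants
#' capped at 3/4 Zebu ancestry, roughly 44% of animals with both parents
#' unknown, 20% with unknown sire and 0.24% with unknown dam, 28% of
#' animals genotyped, 1-3 repeated records per phenotyped animal, and a
#' bivariate (purebred/crossbred) repeatability model with heritability
#' 0.25 and repeatability 0.40 per trait.
#'
#' @param n_founders named integer vector: founders per pool.
#' @param n_markers number of unlinked biallelic markers.
#' @param anc_freq_range range of ancestral allele frequencies (uniform).
#' @param f_drift named per-pool drift parameter in `[0, 1)` (Balding-
#'   Nichols); 0 means no drift from the ancestral pool.
#' @param n_gen number of non-founder generations.
#' @param n_per_gen offspring per generation.
#' @param p_pure named probabilities that a mating is purebred within each
#'   pool; the remainder are crosses/composites.
#' @param max_zebu maximum Zebu ancestry fraction allowed in offspring.
#' @param mask_both,mask_sire,mask_dam per-animal probabilities that a
#'   non-founder has both / only the sire / only the dam parent slot
#'   masked in the released pedigree.
#' @param genotyping_fraction fraction of animals genotyped.
#' @param missing_rate fraction of released genotype calls set missing.
#' @param G0 2x2 additive (co)variance matrix (traits H, B).
#' @param D0 2x2 permanent-environment covariance matrix (diagonal used).
#' @param R0 length-2 residual variances.
#' @param cg_size target contemporary-group size.
#' @param cg_sd SD of contemporary-group effects.
#' @param beta_zebu,beta_het,beta_recloss effects of the Zebu-fraction,
#'   heterozygosity and recombination-loss covariates.
#' @param beta_age linear and quadratic age effects on the centred,
#'   decade-scaled age (age - 527.5)/100.
#' @param rec_probs probabilities of 1, 2 and 3 records per animal.
#' @param age_range recording age range in days.
#' @param base_year birth year of the first non-founder generation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = c(H = 120, Z = 80),
                       n_markers = 1000,
                       anc_freq_range = c(0.1, 0.9),
                       f_drift = c(H = 0.10, Z = 0.20),
                       n_gen = 4, n_per_gen = 250,
                       p_pure = c(H = 0.30, Z = 0.10),
                       max_zebu = 0.75,
                       mask_both = 0.44, mask_sire = 0.20, mask_dam = 0.0024,
                       genotyping_fraction = 0.28,
                       missing_rate = 0.009,
                       G0 = matrix(c(0.25, 0.125, 0.125, 0.25), 2),
                       D0 = diag(c(0.15, 0.15)),
                       R0 = c(0.60, 0.60),
                       cg_size = 25, cg_sd = 0.45,
                       beta_zebu = -0.15, beta_het = 0.10, beta_recloss = -0.05,
                       beta_age = c(0.05, -0.02),
                       rec_probs = c(0.055, 0.443, 0.502),
                       age_range = c(326, 729),
                       base_year = 2008,
                       bv_base = c("gamma", "plain")) {
  bv_base <- match.arg(bv_base)
  pools <- names(n_founders)
  stopifnot(!is.null(pools), length(pools) >= 1,
            setequal(names(f_drift), pools))
  probs <- c(mask_both, mask_sire, mask_dam, genotyping_fraction,
             missing_rate, unname(p_pure))
  stopifnot(all(probs >= 0 & probs <= 1), mask_both + mask_sire + mask_dam <= 1)
  G0 <- as.matrix(G0); D0 <- as.matrix(D0)
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("G0 must be positive semidefinite")
  }
  if (min(eigen(D0, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("D0 must be positive semidefinite")
  }
  stopifnot(all(R0 > 0), length(R0) == 2)
  stopifnot(abs(sum(rec_probs) - 1) < 1e-8, all(rec_probs >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate related founder pools (Balding-Nichols drift)
#'
#' Ancestral frequencies pi_j ~ Uniform(range); each pool drifts with
#' parameter F so that p_bj ~ Beta(pi_j (1-F)/F, (1-pi_j)(1-F)/F) (F = 0
#' keeps p = pi).  The true ancestral relationship matrix is defined as
#' 8 times the covariance, across markers, of the pool frequency vectors.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list with `freq` (pools x markers), `anc_freq`, and
#'   `true_gamma` (a [metafounder_set()]).
#' @export
simulate_founder_pools <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  s <- cfg$n_markers
  pools <- names(cfg$n_founders)
  pi_j <- stats::runif(s, cfg$anc_freq_range[1], cfg$anc_freq_range[2])
  freq <- matrix(NA_real_, length(pools), s, dimnames = list(pools, NULL))
  for (b in pools) {
    Fb <- cfg$f_drift[[b]]
    if (Fb <= 0) {
      freq[b, ] <- pi_j
    } else {
      a1 <- pi_j * (1 - Fb) / Fb
      a2 <- (1 - pi_j) * (1 - Fb) / Fb
      freq[b, ] <- stats::rbeta(s, a1, a2)
    }
  }
  tg <- 8 * stats::cov(t(freq))
  if (length(pools) == 1) tg <- matrix(tg, 1, 1)
  list(freq = freq, anc_freq = pi_j,
       true_gamma = metafounder_set(pools, tg))
}

#' Simulate a multibreed population with known truth
#'
#' Builds a true pedigree (founder pools, crosses and composites under the
#' mating plan), gene-drops unlinked markers from the pool frequencies,
#' draws true breeding values from N(0, G0 kron A) with A computed on the
#' true pedigree, adds permanent-environment and residual effects for 1-3
#' repeated records, then releases a masked pedigree (unknown-parent
#' classes), a partially genotyped marker panel and the phenotype table.
#'
#' @param cfg a [sim_config()].
#' @param pools result of [simulate_founder_pools()].
#' @param seed RNG seed.
#' @return list with elements `ped` (masked [ped_table], no metafounders),
#'   `ped_true` (complete [ped_table]), `genotypes` ([geno_matrix()] of the
#'   genotyped subset, with missingness), `phenotypes` (`pheno_table`),
#'   `mf_rules` (breed-code to metafounder-label map for the masked
#'   pedigree) and `truth` (true breeding values, pool frequencies, true
#'   Gamma, variance components, trait assignment, realised masking and
#'   genotyping rates).
#' @export
simulate_population <- function(cfg, pools, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed + 1L)
  pool_names <- names(cfg$n_founders)
  two_pool <- all(c("H", "Z") %in% pool_names)

  ## ---- true pedigree ----
  n_f <- sum(cfg$n_founders)
  id <- paste0("A", seq_len(n_f))
  pool_of <- rep(pool_names, cfg$n_founders)
  sex <- unlist(lapply(cfg$n_founders, function(k) rep(c("M", "F"), length.out = k)),
                use.names = FALSE)
  sire <- rep(NA_character_, n_f)
  dam <- rep(NA_character_, n_f)
  year <- rep(cfg$base_year - 1L, n_f)
  fz <- if (two_pool) as.numeric(pool_of == "Z") else numeric(n_f)

  next_id <- n_f + 1L
  for (g in seq_len(cfg$n_gen)) {
    prev <- seq_len(length(id))
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    for (k in seq_len(cfg$n_per_gen)) {
      type <- .draw_mating_type(cfg, pool_names)
      pick <- .pick_parents(type, males, females, fz, pool_of, cfg$max_zebu, two_pool)
      id <- c(id, paste0("A", next_id))
      sire <- c(sire, id[pick[1]])
      dam <- c(dam, id[pick[2]])
      sex <- c(sex, sample(c("M", "F"), 1))
      year <- c(year, cfg$base_year + g - 1L)
      fz <- c(fz, (fz[pick[1]] + fz[pick[2]]) / 2)
      p1 <- pool_of[pick[1]]; p2 <- pool_of[pick[2]]
      pool_of <- c(pool_of, if (!is.na(p1) && !is.na(p2) && p1 == p2) p1 else NA_character_)
      next_id <- next_id + 1L
    }
  }
  n <- length(id)
  breed_code <- ifelse(!is.na(pool_of), pool_of,
                       ifelse(two_pool & fz == 0, "H",
                              ifelse(two_pool & fz == 1, "Z", "B")))
  ped_true <- as_ped_table(data.frame(
    id = id, sire = sire, dam = dam, birth_year = year, sex = sex,
    breed_code = breed_code, stringsAsFactors = FALSE))
  ped_true$founder_group <- ifelse(is.na(ped_true$sire) & is.na(ped_true$dam),
                                   ped_true$breed_code, NA_character_)

  ## ---- gene drop ----
  s <- cfg$n_markers
  H1 <- matrix(0L, n, s)
  H2 <- matrix(0L, n, s)
  idx <- .ped_idx(ped_true)
  for (i in seq_len(n)) {
    if (is.na(idx$si[i])) {
      pb <- pools$freq[ped_true$founder_group[i], ]
      H1[i, ] <- stats::rbinom(s, 1L, pb)
      H2[i, ] <- stats::rbinom(s, 1L, pb)
    } else {
      sI <- idx$si[i]; dI <- idx$di[i]
      pick <- stats::runif(s) < 0.5
      H1[i, ] <- ifelse(pick, H1[sI, ], H2[sI, ])
      pick <- stats::runif(s) < 0.5
      H2[i, ] <- ifelse(pick, H1[dI, ], H2[dI, ])
    }
  }
  M_all <- H1 + H2

  ## ---- true breeding values ----
  ## bv_base "gamma": a ~ N(0, G0 kron A(Gamma_true)) on the true pedigree
  ## with the founder pools as metafounders, so the trait architecture is
  ## consistent with the marker-implied ancestral relatedness (true Gamma
  ## > 0).  bv_base "plain": unrelated founders (model-matched textbook
  ## case for estimator checks).
  if (cfg$bv_base == "gamma") {
    rules <- stats::setNames(pool_names, pool_names)
    pedg <- add_metafounders(ped_true, rules, default_group = pool_names[1])
    Atr <- unclass(build_A(pedg, pools$true_gamma))
    keep_a <- !pedg$is_metafounder
    Ra <- chol(Atr + diag(1e-8, nrow(Atr)))
    Zg <- matrix(stats::rnorm(2L * nrow(Atr)), nrow(Atr), 2L)
    a_all <- crossprod(Ra, Zg) %*% chol(cfg$G0 + diag(1e-12, 2))
    a_true <- a_all[keep_a, , drop = FALSE][match(ped_true$id, pedg$id[keep_a]), , drop = FALSE]
  } else {
    A <- unclass(build_A(ped_true))
    Ra <- chol(A + diag(1e-10, n))
    Z2 <- matrix(stats::rnorm(2L * n), n, 2L)
    a_true <- crossprod(Ra, Z2) %*% chol(cfg$G0 + diag(1e-12, 2))
  }
  rownames(a_true) <- ped_true$id
  colnames(a_true) <- c("H", "B")

  ## ---- phenotypes ----
  comp <- breed_composition(ped_true)
  fz_ped <- if (two_pool) comp$fractions[, "Z"] else numeric(n)
  is_founder <- is.na(ped_true$sire)
  trait <- rep(NA_character_, n)
  trait[!is_founder & fz_ped == 0] <- "H"
  trait[!is_founder & fz_ped > 0 & fz_ped <= cfg$max_zebu + 1e-9] <- "B"
  phen <- which(!is.na(trait))
  ti <- match(trait[phen], c("H", "B"))
  d_true <- stats::rnorm(length(phen), 0, sqrt(diag(cfg$D0)[ti]))
  nrec <- sample(1:3, length(phen), replace = TRUE, prob = cfg$rec_probs)

  cg_key <- paste0(trait[phen], ped_true$birth_year[phen])
  cg <- character(length(phen))
  for (is in split(seq_along(phen), cg_key)) {
    k <- max(1L, round(length(is) / cfg$cg_size))
    cg[is] <- paste0(cg_key[is], "_", sample(rep_len(seq_len(k), length(is))))
  }
  cg_levels <- unique(cg)
  cg_eff <- stats::setNames(stats::rnorm(length(cg_levels), 0, cfg$cg_sd), cg_levels)

  rows <- rep(seq_along(phen), nrec)
  age <- stats::runif(length(rows), cfg$age_range[1], cfg$age_range[2])
  age_s <- (age - mean(cfg$age_range)) / 100
  het <- comp$heterozygosity[phen]
  rec <- comp$recombination_loss[phen]
  e <- stats::rnorm(length(rows), 0, sqrt(cfg$R0[ti[rows]]))
  yv <- cg_eff[cg[rows]] +
    cfg$beta_zebu * fz_ped[phen][rows] +
    cfg$beta_het * het[rows] +
    cfg$beta_recloss * rec[rows] +
    cfg$beta_age[1] * age_s + cfg$beta_age[2] * age_s^2 +
    a_true[cbind(phen[rows], ti[rows])] + d_true[rows] + e

  phe <- data.frame(
    animal = ped_true$id[phen][rows], trait = trait[phen][rows],
    cg = unname(cg[rows]), age = age, value = unname(yv),
    zebu = fz_ped[phen][rows], het = het[rows], recloss = rec[rows],
    stringsAsFactors = FALSE)

  ## ---- masking ----
  non_founder <- which(!is_founder)
  u <- stats::runif(length(non_founder))
  both <- u < cfg$mask_both
  sire_only <- !both & u < cfg$mask_both + cfg$mask_sire
  dam_only <- !both & !sire_only & u < cfg$mask_both + cfg$mask_sire + cfg$mask_dam
  ped_rel <- data.frame(
    id = ped_true$id, sire = ped_true$sire, dam = ped_true$dam,
    birth_year = ped_true$birth_year, sex = ped_true$sex,
    breed_code = ped_true$breed_code, stringsAsFactors = FALSE)
  ped_rel$sire[non_founder[both | sire_only]] <- NA_character_
  ped_rel$dam[non_founder[both | dam_only]] <- NA_character_
  ped_masked <- as_ped_table(ped_rel)

  ## ---- genotyped subset ----
  n_geno <- max(2L, round(cfg$genotyping_fraction * n))
  geno_rows <- sort(sample.int(n, n_geno))
  Mg <- M_all[geno_rows, , drop = FALSE]
  if (cfg$missing_rate > 0) {
    mi <- which(stats::runif(length(Mg)) < cfg$missing_rate)
    Mg[mi] <- NA_integer_
  }
  genotypes <- geno_matrix(Mg, ids = ped_true$id[geno_rows])

  mf_rules <- stats::setNames(pool_names, pool_names)
  if (two_pool) mf_rules <- c(mf_rules, B = "B")

  n_ped <- nrow(ped_masked)
  miss_s <- is.na(ped_masked$sire); miss_d <- is.na(ped_masked$dam)
  list(
    ped = ped_masked, ped_true = ped_true,
    genotypes = genotypes, phenotypes = as_pheno_table(phe, ped_true),
    mf_rules = mf_rules,
    truth = list(
      a_true = a_true, pool_freq = pools$freq, true_gamma = pools$true_gamma,
      G0 = cfg$G0, D0 = cfg$D0, R0 = cfg$R0,
      trait = stats::setNames(trait, ped_true$id),
      cg_effects = cg_eff,
      masking = c(both = mean(both), sire_only = mean(sire_only),
                  dam_only = mean(dam_only)),
      overall_unknown = c(both = mean(miss_s & miss_d),
                          sire_only = mean(miss_s & !miss_d),
                          dam_only = mean(!miss_s & miss_d)),
      genotyped_fraction = n_geno / n_ped,
      haplotypes = NULL
    )
  )
}

.draw_mating_type <- function(cfg, pool_names) {
  pp <- cfg$p_pure[intersect(names(cfg$p_pure), pool_names)]
  u <- stats::runif(1)
  cum <- cumsum(pp)
  k <- which(u < cum)
  if (length(k)) names(pp)[k[1]] else "X"
}

.pick_parents <- function(type, males, females, fz, pool_of, max_zebu, two_pool) {
  if (type != "X") {
    ms <- males[!is.na(pool_of[males]) & pool_of[males] == type]
    fs <- females[!is.na(pool_of[females]) & pool_of[females] == type]
    if (length(ms) > 0 && length(fs) > 0) return(c(resample(ms), resample(fs)))
  }
  # cross/composite mating: offspring Zebu fraction capped; avoid purebred pairs
  for (try in 1:50) {
    si <- resample(males)
    dmax <- 2 * max_zebu - fz[si]
    cand <- females[fz[females] <= dmax + 1e-9]
    if (length(cand) == 0) next
    di <- resample(cand)
    same_pool <- !is.na(pool_of[si]) && !is.na(pool_of[di]) &&
      pool_of[si] == pool_of[di]
    if (same_pool && pool_of[si] != "Z") next   # would be a purebred mating
    if (two_pool && fz[si] == 1 && fz[di] == 1) next
    return(c(si, di))
  }
  c(resample(males), resample(females))
}

# sample() without the length-1 surprise
resample <- function(x) x[sample.int(length(x), 1L)]
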