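# Small pedigrees and populations built in code for the test suite.

# two founders and their offspring, with breed codes
trio_df <- function() {
  data.frame(id = c("s", "d", "o"), sire = c("0", "0", "s"),
             dam = c("0", "0", "d"), birth_year = c(2000, 2000, 2001),
             sex = c("M", "F", "M"), breed_code = c("HH", "ZZ", "HZ"),
             stringsAsFactors = FALSE)
}

# full-sib mating: offspring of full sibs has F = 0.25
fullsib_ped <- function() {
  as_ped_table(data.frame(
    id = c("a", "b", "c", "d", "x"),
    sire = c("0", "0", "a", "a", "c"),
    dam = c("0", "0", "b", "b", "d"), stringsAsFactors = FALSE))
}

# Hereford x Zebu crossbreeding pedigree: purebred lines plus F1s only
# (no post-F1 crosses), founder groups set for gene-drop oracles
hz_f1_ped <- function(n_h = 6, n_z = 6, n_f1 = 8, n_pure = 8, seed = 1) {
  set.seed(seed)
  hm <- paste0("H", seq_len(n_h)); zm <- paste0("Z", seq_len(n_z))
  sexes <- rep(c("M", "F"), length.out = n_h)
  df <- data.frame(id = c(hm, zm), sire = "0", dam = "0",
                   birth_year = 2000,
                   sex = c(sexes, rep(c("M", "F"), length.out = n_z)),
                   breed_code = c(rep("H", n_h), rep("Z", n_z)),
                   stringsAsFactors = FALSE)
  hs <- hm[df$sex[seq_len(n_h)] == "M"]; hd <- hm[df$sex[seq_len(n_h)] == "F"]
  zs <- zm[df$sex[n_h + seq_len(n_z)] == "M"]; zd <- zm[df$sex[n_h + seq_len(n_z)] == "F"]
  kids <- data.frame(
    id = c(paste0("F1_", seq_len(n_f1)), paste0("P_", seq_len(n_pure))),
    sire = c(sample(hs, n_f1, TRUE), sample(hs, n_pure, TRUE)),
    dam = c(sample(zd, n_f1, TRUE), sample(hd, n_pure, TRUE)),
    birth_year = 2001, sex = sample(c("M", "F"), n_f1 + n_pure, TRUE),
    breed_code = NA, stringsAsFactors = FALSE)
  ped <- as_ped_table(rbind(df, kids))
  ped$founder_group <- ifelse(is.na(ped$sire), ped$breed_code, NA)
  ped
}

# random multi-generation crossbred pedigree (includes backcrosses)
random_crossbred_ped <- function(n_founders = 10, n_desc = 40, seed = 2) {
  set.seed(seed)
  id <- paste0("f", seq_len(n_founders))
  grp <- sample(c("H", "Z"), n_founders, TRUE)
  sire <- dam <- rep(NA_character_, n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  for (k in seq_len(n_desc)) {
    males <- which(sex == "M"); females <- which(sex == "F")
    s <- sample(males, 1); d <- sample(females, 1)
    id <- c(id, paste0("x", k))
    sire <- c(sire, id[s]); dam <- c(dam, id[d])
    sex <- c(sex, sample(c("M", "F"), 1))
    grp <- c(grp, NA)
  }
  ped <- as_ped_table(data.frame(id = id, sire = sire, dam = dam,
                                 stringsAsFactors = FALSE))
  ped$founder_group <- grp[match(ped$id, id)]
  ped
}

# small study-shaped simulated population (fast defaults, overridable)
small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_founders = c(H = 30, Z = 20), n_markers = 150,
         n_gen = 3, n_per_gen = 60, genotyping_fraction = 0.4),
    list(...))
  cfg <- do.call(sim_config, args)
  pools <- simulate_founder_pools(cfg, seed = seed)
  list(cfg = cfg, pools = pools,
       sim = simulate_population(cfg, pools, seed = seed))
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(unclass(m) - t(unclass(m)))), tol)
}
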