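#' Forward split of phenotyped animals by birth year
#'
#' Validation animals are the phenotyped animals born in `split_year`;
#' training animals are those born earlier.  Records of validation animals
#' are withheld from the prediction fit.
#'
#' @param phe phenotype table.
#' @param ped pedigree supplying birth years.
#' @param split_year validation birth year.
#' @return list with `training` and `validation` phenotype tables and
#'   `validation_ids`.
#' @export
forward_split <- function(phe, ped, split_year) {
  by <- ped$birth_year[match(phe$animal, ped$id)]
  if (all(is.na(by))) stop("no birth years available")
  val <- !is.na(by) & by == split_year
  trn <- !is.na(by) & by < split_year
  if (!any(val)) stop("empty validation set for split year ", split_year)
  if (!any(trn)) stop("empty training set for split year ", split_year)
  list(training = phe[trn, , drop = FALSE],
       validation = phe[val, , drop = FALSE],
       validation_ids = unique(phe$animal[val]))
}

#' Phenotypes adjusted for fixed effects
#'
#' y* = y - X beta_hat per record, with beta_hat estimated from a model
#' using all data, then averaged within animal across repeated records.
#'
#' @param phe phenotype table (the records to adjust).
#' @param full_fit a [solve_mme()] result fitted on all data; its fixed
#'   design and estimates are re-applied to `phe`.
#' @return named numeric vector of per-animal mean adjusted phenotypes.
#' @export
adjusted_phenotypes <- function(phe, full_fit) {
  m <- full_fit$mme
  full <- m$phe
  kc <- intersect(c("animal", "trait", "cg", "value", "age"), names(full))
  key <- match(do.call(paste, c(phe[kc], sep = "\r")),
               do.call(paste, c(full[kc], sep = "\r")))
  if (anyNA(key)) stop("records to adjust are not part of the full-data fit")
  Xb <- as.numeric(m$X %*% full_fit$beta)[key]
  ystar <- phe$value - Xb
  out <- tapply(ystar, phe$animal, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Predictive ability with bootstrap standard error
#'
#' Pearson correlation between adjusted phenotypes and (G)EBVs over the
#' validation animals; the standard error is the SD of the correlation
#' over non-parametric bootstrap resamples of animals.
#'
#' @param ystar named vector of per-animal adjusted phenotypes.
#' @param ebv named vector of (G)EBVs.
#' @param ids validation animal ids.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed RNG seed for the resampling.
#' @return list `cor`, `se`, `n`.
#' @export
predictive_ability <- function(ystar, ebv, ids, n_boot = 5000, seed = 1) {
  stopifnot(n_boot >= 100)
  ids <- intersect(ids, intersect(names(ystar), names(ebv)))
  n <- length(ids)
  if (n < 3) stop("fewer than 3 validation animals")
  x <- as.numeric(ystar[ids]); y <- as.numeric(ebv[ids])
  r <- stats::cor(x, y)
  set.seed(seed)
  rb <- vapply(seq_len(n_boot), function(b) {
    k <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(x[k], y[k]))
  }, 0)
  list(cor = r, se = stats::sd(rb, na.rm = TRUE), n = n)
}

#' Bias (inflation) regression
#'
#' Ordinary least-squares regression of adjusted phenotypes on (G)EBVs
#' with intercept; a slope of 1 denotes no bias.
#'
#' @inheritParams predictive_ability
#' @return list `slope`, `se`, `n`.
#' @export
bias_slope <- function(ystar, ebv, ids) {
  ids <- intersect(ids, intersect(names(ystar), names(ebv)))
  if (length(ids) < 3) stop("fewer than 3 validation animals")
  x <- as.numeric(ebv[ids]); y <- as.numeric(ystar[ids])
  if (stats::var(x) < 1e-14) stop("zero variance in EBVs")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]), se = unname(sm["x", "Std. Error"]),
       n = length(ids))
}

#' Relationship structures for the three evaluation models
#'
#' Prepares the inverse relationship structure used by [solve_mme()] for
#' pedigree BLUP, single-step GBLUP, or single-step GBLUP with
#' metafounders (Gamma-augmented pedigree plus a 0.5-frequency genomic
#' matrix).
#'
#' @param ped masked [ped_table] without metafounders.
#' @param model `"blup"`, `"ssgblup"` or `"ssgblupm"`.
#' @param genotypes a [geno_matrix()] (imputed if needed) for the genomic
#'   models.
#' @param mf_rules breed-code to metafounder-label map (ssgblupm).
#' @param mfs a [metafounder_set()] (ssgblupm).
#' @param weights blending weights passed to [build_Hinv()].
#' @return list with `Kinv` (for [solve_mme()]) and `ped_used`.
#' @export
model_relationships <- function(ped, model = c("blup", "ssgblup", "ssgblupm"),
                                genotypes = NULL, mf_rules = NULL, mfs = NULL,
                                weights = c(0.95, 0.05)) {
  model <- match.arg(model)
  if (model == "blup") {
    return(list(Kinv = ainverse(ped), ped_used = ped))
  }
  if (is.null(genotypes)) stop("genomic models need genotypes")
  G <- if (anyNA(genotypes$M)) impute_simple(genotypes) else genotypes
  gids <- intersect(G$ids, ped$id)
  G <- geno_matrix(G$M[match(gids, G$ids), , drop = FALSE], ids = gids)
  if (model == "ssgblup") {
    Ainv <- ainverse(ped)
    A <- build_A(ped)
    A22 <- extract_A22(A, gids)
    Gm <- build_G(G, mode = "observed")
    Hinv <- build_Hinv(Ainv, A22, Gm, weights = weights)
    return(list(Kinv = Hinv, ped_used = ped))
  }
  if (is.null(mf_rules) || is.null(mfs)) stop("ssgblupm needs mf_rules and mfs")
  pedm <- add_metafounders(ped, mf_rules)
  Ainv <- ainverse(pedm, mfs)
  Ag <- build_A(pedm, mfs)
  A22 <- extract_A22(Ag, gids)
  Gm <- build_G(G, mode = "half")
  Hinv <- build_Hinv(Ainv, A22, Gm, weights = weights)
  list(Kinv = Hinv, ped_used = pedm)
}

#' Forward validation of the three evaluation models
#'
#' Fits the model on all data to obtain fixed-effect-adjusted phenotypes,
#' refits on the training records only, and reports per-breed predictive
#' ability (with bootstrap SE) and the bias regression slope for the
#' validation animals.
#'
#' @param phe phenotype table.
#' @param ped masked pedigree.
#' @param vc [variance_components()] used for prediction (REML estimates
#'   or known values).
#' @param split_year validation birth year.
#' @param models character subset of `c("blup", "ssgblup", "ssgblupm")`.
#' @param genotypes,mf_rules,mfs,weights passed to
#'   [model_relationships()].
#' @param n_boot,seed bootstrap settings.
#' @return data frame: model, trait, n, predictive_ability, boot_se,
#'   bias_slope, slope_se.
#' @export
run_forward_validation <- function(phe, ped, vc, split_year,
                                   models = c("blup", "ssgblup", "ssgblupm"),
                                   genotypes = NULL, mf_rules = NULL,
                                   mfs = NULL, weights = c(0.95, 0.05),
                                   n_boot = 1000, seed = 1) {
  sp <- forward_split(phe, ped, split_year)
  out <- list()
  for (mod in models) {
    rel <- model_relationships(ped, mod, genotypes, mf_rules, mfs, weights)
    full_fit <- solve_mme(phe, rel$Kinv, vc)
    ystar <- adjusted_phenotypes(sp$validation, full_fit)
    train_fit <- solve_mme(sp$training, rel$Kinv, vc)
    for (tr in sort(unique(sp$validation$trait))) {
      vids <- unique(sp$validation$animal[sp$validation$trait == tr])
      ebv <- stats::setNames(train_fit$a[, tr][match(vids, rownames(train_fit$a))], vids)
      pa <- predictive_ability(ystar, ebv, vids, n_boot = n_boot, seed = seed)
      bs <- bias_slope(ystar, ebv, vids)
      out[[length(out) + 1L]] <- data.frame(
        model = mod, trait = tr, n = pa$n,
        predictive_ability = pa$cor, boot_se = pa$se,
        bias_slope = bs$slope, slope_se = bs$se)
    }
  }
  do.call(rbind, out)
}
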