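#' SNP quality-control thresholds
#'
#' Defaults follow common practice for bovine SNP panels: marker call rate
#' >= 0.98, minor allele frequency >= 0.03, Hardy-Weinberg chi-square
#' p >= 1e-7, near-perfect collinearity |r| > 0.98 (adjacent markers plus
#' exact duplicate columns), sample call rate >= 0.90, sample
#' heterozygosity within 3 SD of the panel mean, and near-duplicate sample
#' similarity > 0.995.
#'
#' @param marker_cr,maf,hwe_p,collinearity_r,sample_cr,het_sd,dup_similarity
#'   thresholds as described above.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(marker_cr = 0.98, maf = 0.03, hwe_p = 1e-7,
                          collinearity_r = 0.98, sample_cr = 0.90,
                          het_sd = 3, dup_similarity = 0.995) {
  stopifnot(marker_cr > 0, marker_cr <= 1, maf > 0, maf < 0.5,
            hwe_p > 0, hwe_p < 1, sample_cr > 0, sample_cr <= 1, het_sd > 0)
  structure(list(marker_cr = marker_cr, maf = maf, hwe_p = hwe_p,
                 collinearity_r = collinearity_r, sample_cr = sample_cr,
                 het_sd = het_sd, dup_similarity = dup_similarity),
            class = "qc_thresholds")
}

# 1-df Hardy-Weinberg chi-square p-value from genotype counts
.hwe_pvalue <- function(col) {
  g <- col[!is.na(col)]
  n <- length(g)
  if (n == 0) return(NA_real_)
  n0 <- sum(g == 0L); n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  p <- (n1 + 2 * n2) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  keep <- e > 0
  x2 <- sum((o[keep] - e[keep])^2 / e[keep])
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Quality control of a genotype matrix
#'
#' Removes samples failing call rate, heterozygosity deviation, or
#' near-duplicate similarity, then markers failing call rate, MAF,
#' Hardy-Weinberg equilibrium, duplicated physical position, or
#' collinearity (exact duplicate columns and adjacent pairs with
#' |r| above the threshold; the later marker is dropped).
#'
#' @param G a [geno_matrix()].
#' @param marker_info optional data frame with columns `marker`, `chrom`,
#'   `pos` used for the duplicate-position rule.
#' @param t a [qc_thresholds()].
#' @param check_duplicates compute pairwise sample similarity (quadratic in
#'   the number of animals); disable for large panels.
#' @return list with `genotypes` (filtered [geno_matrix()]) and
#'   `exclusions` (data frame: id, type, rule, statistic, threshold).
#' @export
qc_filter <- function(G, marker_info = NULL, t = qc_thresholds(),
                      check_duplicates = TRUE) {
  stopifnot(inherits(G, "geno_matrix"))
  excl <- list()
  note <- function(id, type, rule, stat, thr) {
    excl[[length(excl) + 1L]] <<- data.frame(
      id = id, type = type, rule = rule,
      statistic = stat, threshold = thr, stringsAsFactors = FALSE)
  }
  M <- G$M

  # -- samples --
  cr <- rowMeans(!is.na(M))
  for (i in which(cr < t$sample_cr)) note(G$ids[i], "sample", "call_rate", cr[i], t$sample_cr)
  drop_s <- cr < t$sample_cr
  het <- rowMeans(M == 1L, na.rm = TRUE)
  mu <- mean(het[!drop_s]); sdv <- stats::sd(het[!drop_s])
  if (is.finite(sdv) && sdv > 0) {
    dev <- abs(het - mu) / sdv
    for (i in which(!drop_s & dev > t$het_sd)) note(G$ids[i], "sample", "het_deviation", dev[i], t$het_sd)
    drop_s <- drop_s | dev > t$het_sd
  }
  if (check_duplicates && sum(!drop_s) >= 2) {
    keep_i <- which(!drop_s)
    sim <- .sample_similarity(M[keep_i, , drop = FALSE])
    idx <- which(sim > t$dup_similarity & upper.tri(sim), arr.ind = TRUE)
    if (nrow(idx) > 0) {
      for (r in seq_len(nrow(idx))) {
        j <- keep_i[idx[r, 2]]   # drop the later sample of each pair
        if (!drop_s[j]) {
          note(G$ids[j], "sample", "duplicate_sample", sim[idx[r, 1], idx[r, 2]], t$dup_similarity)
          drop_s[j] <- TRUE
        }
      }
    }
  }
  M <- M[!drop_s, , drop = FALSE]

  # -- markers --
  mcr <- colMeans(!is.na(M))
  obs <- pmax(colSums(!is.na(M)), 1L)
  p <- colSums(M, na.rm = TRUE) / (2 * obs)
  maf <- pmin(p, 1 - p)
  hwe <- apply(M, 2L, .hwe_pvalue)
  drop_m <- logical(ncol(M))
  for (j in which(mcr < t$marker_cr)) note(G$markers[j], "marker", "call_rate", mcr[j], t$marker_cr)
  drop_m <- drop_m | mcr < t$marker_cr
  for (j in which(!drop_m & maf < t$maf)) note(G$markers[j], "marker", "maf", maf[j], t$maf)
  drop_m <- drop_m | maf < t$maf
  for (j in which(!drop_m & !is.na(hwe) & hwe < t$hwe_p)) note(G$markers[j], "marker", "hwe", hwe[j], t$hwe_p)
  drop_m <- drop_m | (!is.na(hwe) & hwe < t$hwe_p)
  if (!is.null(marker_info)) {
    mi <- marker_info[match(G$markers, marker_info$marker), ]
    key <- paste(mi$chrom, mi$pos)
    key[is.na(mi$chrom)] <- NA
    dup <- duplicated(key) & !is.na(key)
    for (j in which(!drop_m & dup)) note(G$markers[j], "marker", "duplicate_position", NA_real_, NA_real_)
    drop_m <- drop_m | dup
  }
  # collinearity: exact duplicate columns anywhere + adjacent-pair correlation
  keep_j <- which(!drop_m)
  if (length(keep_j) >= 2) {
    Mi <- M[, keep_j, drop = FALSE]
    Mi0 <- Mi; Mi0[is.na(Mi0)] <- 9L
    colkey <- apply(Mi0, 2L, paste, collapse = "")
    dupcol <- duplicated(colkey)
    for (k in which(dupcol)) note(G$markers[keep_j[k]], "marker", "collinearity", 1, t$collinearity_r)
    dropped <- dupcol
    for (k in seq_len(length(keep_j) - 1L)) {
      if (dropped[k] || dropped[k + 1L]) next
      r <- suppressWarnings(stats::cor(Mi[, k], Mi[, k + 1L], use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > t$collinearity_r) {
        note(G$markers[keep_j[k + 1L]], "marker", "collinearity", abs(r), t$collinearity_r)
        dropped[k + 1L] <- TRUE
      }
    }
    drop_m[keep_j[dropped]] <- TRUE
  }
  if (all(drop_m)) stop("quality control removed all markers")
  out <- geno_matrix(M[, !drop_m, drop = FALSE],
                     ids = G$ids[!drop_s], markers = G$markers[!drop_m])
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), type = character(0), rule = character(0),
               statistic = numeric(0), threshold = numeric(0))
  list(genotypes = out, exclusions = exclusions)
}

# proportion of identically called markers for every sample pair
.sample_similarity <- function(M) {
  n <- nrow(M)
  s <- ncol(M)
  same <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (g in 0:2) {
    Ind <- (!is.na(M) & M == g) * 1
    same <- same + tcrossprod(Ind)
  }
  Obs <- (!is.na(M)) * 1
  both <- tcrossprod(Obs)
  sim <- same / pmax(both, 1)
  sim[both == 0] <- 0
  sim
}

#' Fill missing genotypes with the rounded per-marker mean
#'
#' Missing entries are replaced by `round(2 p_j)` (nearest of 0/1/2), a
#' deliberately simple rule for the low missingness remaining after quality
#' control.  Observed entries are never modified.
#'
#' @param G a post-QC [geno_matrix()].
#' @return a complete [geno_matrix()].
#' @export
impute_simple <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  M <- G$M
  allmiss <- colSums(!is.na(M)) == 0
  if (any(allmiss)) {
    stop("markers with no observed genotypes (should have failed QC): ",
         paste(utils::head(G$markers[allmiss], 5), collapse = ", "))
  }
  if (anyNA(M)) {
    fill <- as.integer(pmin(pmax(round(2 * G$p), 0), 2))
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- fill[idx[, 2]]
  }
  geno_matrix(M, ids = G$ids, markers = G$markers)
}

#' Genomic relationship matrix (VanRaden form)
#'
#' G = (M - P)(M - P)' / (2 sum_j p_j (1 - p_j)).  With
#' `mode = "observed"`, realised allele frequencies of the genotyped
#' animals are used; with `mode = "half"` every locus uses p = 0.5 (the
#' maximum-heterozygosity reference used by the metafounder model), so the
#' denominator is s/2 and a fully homozygous animal has diagonal 2 while a
#' fully heterozygous one has diagonal 0.
#'
#' @param G a complete [geno_matrix()].
#' @param mode `"observed"` or `"half"`.
#' @return a [rel_matrix()] of kind `"G"` or `"G_gamma"`.
#' @export
build_G <- function(G, mode = c("observed", "half")) {
  mode <- match.arg(mode)
  stopifnot(inherits(G, "geno_matrix"))
  if (anyNA(G$M)) stop("genotype matrix has missing values; impute first")
  p <- if (mode == "half") rep(0.5, ncol(G$M)) else G$p
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero scaling denominator")
  Z <- sweep(G$M, 2L, 2 * p, `-`)
  Gm <- tcrossprod(Z) / denom
  rel_matrix(Gm, kind = if (mode == "half") "G_gamma" else "G",
             ids = G$ids)
}

#' Single-step combined relationship inverse H^-1
#'
#' H^-1 = A^-1 + [0 0; 0 (w_G G + w_A A22)^-1 - A22^-1] on the genotyped
#' block.  Supplying the Gamma-augmented A^-1, A22(Gamma) and the
#' 0.5-frequency G yields H(Gamma)^-1.
#'
#' @param Ainv inverse pedigree relationship matrix: a [rel_matrix()] or
#'   the list returned by [ainverse()].
#' @param A22 pedigree relationships among genotyped animals
#'   ([extract_A22()]).
#' @param G genomic relationship matrix over the same animals in the same
#'   order.
#' @param weights blending weights `c(w_G, w_A)`, summing to 1
#'   (default `c(0.95, 0.05)`).
#' @return list with `Hinv` (sparse symmetric `Matrix`), `ids`, `logdet`
#'   (log determinant of H when `Ainv` came from [ainverse()], else `NA`).
#' @export
build_Hinv <- function(Ainv, A22, G, weights = c(0.95, 0.05)) {
  stopifnot(length(weights) == 2, abs(sum(weights) - 1) < 1e-8)
  if (inherits(Ainv, "rel_matrix")) {
    Ainv <- list(Ainv = Matrix::Matrix(unclass(Ainv), sparse = TRUE),
                 ids = rownames(Ainv), logdet = NA_real_)
  }
  ids <- Ainv$ids
  g_ids <- rownames(A22)
  if (!is.null(G) && !identical(rownames(G), g_ids)) {
    stop("G and A22 id maps differ")
  }
  if (length(g_ids) == 0) {
    return(list(Hinv = Ainv$Ainv, ids = ids, logdet = Ainv$logdet))
  }
  pos <- match(g_ids, ids)
  if (anyNA(pos)) stop("genotyped ids missing from pedigree inverse")
  A22m <- unclass(A22)
  Gm <- unclass(G)
  blend <- weights[1] * Gm + weights[2] * A22m
  ev <- eigen(blend, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("blended matrix not positive definite (smallest eigenvalue ",
         format(min(ev), digits = 4), ")")
  }
  chB <- chol(blend)
  chA22 <- tryCatch(chol(A22m), error = function(e)
    stop("A22 not positive definite"))
  corr <- chol2inv(chB) - chol2inv(chA22)
  n <- length(ids)
  Hinv <- Ainv$Ainv + Matrix::sparseMatrix(
    i = rep(pos, times = length(pos)),
    j = rep(pos, each = length(pos)),
    x = as.vector(corr), dims = c(n, n), symmetric = FALSE)
  Hinv <- Matrix::forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
  logdet <- if (is.na(Ainv$logdet)) NA_real_ else
    Ainv$logdet + 2 * sum(log(diag(chB))) - 2 * sum(log(diag(chA22)))
  list(Hinv = as(Hinv, "CsparseMatrix"), ids = ids, logdet = logdet)
}
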