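#' Metafounder sets
#'
#' Ordered metafounder labels together with the Gamma matrix of ancestral
#' self- (diagonal) and cross- (off-diagonal) relationships.  Gamma is the
#' relationship among the finite ancestral gamete pools: a founder linked to
#' a pool with self-relationship gamma gets diagonal 1 + gamma/2 in the
#' augmented numerator relationship matrix A(Gamma).
#'
#' @param labels character vector of metafounder labels.
#' @param gamma symmetric numeric matrix, same order as `labels`.
#' @return object of class `metafounder_set`.
#' @export
metafounder_set <- function(labels, gamma) {
  gamma <- as.matrix(gamma)
  labels <- as.character(labels)
  if (nrow(gamma) != length(labels) || ncol(gamma) != length(labels)) {
    stop("gamma dimension does not match metafounder labels")
  }
  if (max(abs(gamma - t(gamma))) > 1e-8) stop("gamma must be symmetric")
  gamma <- (gamma + t(gamma)) / 2
  dimnames(gamma) <- list(labels, labels)
  structure(list(labels = labels, gamma = gamma), class = "metafounder_set")
}

#' @export
print.metafounder_set <- function(x, ...) {
  cat("metafounder_set with", length(x$labels), "groups\n")
  print(round(x$gamma, 3))
  invisible(x)
}

#' Summary statistics of the unique Gamma elements
#'
#' Mean, minimum and maximum over the unique (upper-triangle including
#' diagonal) elements of Gamma.
#'
#' @param mfs a [metafounder_set()].
#' @return named list `mean`, `min`, `max`, `n_unique`.
#' @export
gamma_summary <- function(mfs) {
  u <- mfs$gamma[upper.tri(mfs$gamma, diag = TRUE)]
  list(mean = mean(u), min = min(u), max = max(u), n_unique = length(u))
}

#' Tagged relationship matrices
#'
#' A numeric symmetric matrix with an id map and a kind tag
#' (`"A"`, `"A_gamma"`, `"A22"`, `"G"`, `"Hinv"`, ...).
#'
#' @param m numeric matrix.
#' @param kind character tag.
#' @param ids identifiers for rows/columns.
#' @return object of class `rel_matrix` (a matrix with attributes).
#' @export
rel_matrix <- function(m, kind, ids = rownames(m)) {
  m <- as.matrix(m)
  if (is.null(ids) && nrow(m) > 0) stop("ids required")
  if (anyDuplicated(ids)) stop("duplicated ids in relationship matrix")
  if (length(m) > 0 && max(abs(m - t(m))) > 1e-10) {
    stop("relationship matrix not symmetric")
  }
  dimnames(m) <- list(ids, ids)
  structure(m, kind = kind, class = c("rel_matrix", "matrix", "array"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix [%s]: %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE], 4))
  invisible(x)
}

#' Breed composition from pedigree
#'
#' Computes for every individual the expected fraction of alleles tracing
#' to each founder pool (metafounder group), the pairwise parental
#' heterozygosity terms f_kk' (probability that one allele comes from pool k
#' and the other from pool k'), and the recombination-loss covariate
#' 2 f_k f_k' from the individual's own fractions.  Founders (and
#' metafounder pseudo-individuals) are indicators of their own group;
#' descendants average their parents.
#'
#' @param ped a [ped_table] with metafounders, or a plain pedigree whose
#'   founders carry `founder_group`.
#' @return object of class `breed_comp`: list with `ids`, `fractions`
#'   (n x pools), `het` and `recloss` (n x pool-pairs), and for
#'   convenience `heterozygosity`/`recombination_loss` (row sums over pairs).
#' @export
breed_composition <- function(ped) {
  stopifnot(inherits(ped, "ped_table"))
  pools <- metafounder_labels(ped)
  if (length(pools) == 0) pools <- sort(unique(stats::na.omit(ped$founder_group)))
  if (length(pools) == 0) stop("no founder groups defined in pedigree")
  n <- nrow(ped)
  idx <- .ped_idx(ped)
  Fm <- matrix(0, n, length(pools), dimnames = list(ped$id, pools))
  base <- ped$is_metafounder | (is.na(idx$si) & is.na(idx$di))
  for (i in seq_len(n)) {
    if (base[i]) {
      g <- ped$founder_group[i]
      if (is.na(g)) stop("founder ", ped$id[i], " has no founder group")
      Fm[i, g] <- 1
    } else {
      fs <- if (!is.na(idx$si[i])) Fm[idx$si[i], ] else .group_indicator(ped, i, pools)
      fd <- if (!is.na(idx$di[i])) Fm[idx$di[i], ] else .group_indicator(ped, i, pools)
      Fm[i, ] <- (fs + fd) / 2
    }
  }
  pairs <- if (length(pools) >= 2) utils::combn(pools, 2, simplify = FALSE) else list()
  pair_names <- vapply(pairs, paste, "", collapse = ":")
  het <- matrix(0, n, length(pairs), dimnames = list(ped$id, pair_names))
  rec <- matrix(0, n, length(pairs), dimnames = list(ped$id, pair_names))
  for (i in seq_len(n)) {
    if (base[i]) next
    s <- idx$si[i]; d <- idx$di[i]
    fsv <- if (!is.na(s)) Fm[s, ] else .group_indicator(ped, i, pools)
    fdv <- if (!is.na(d)) Fm[d, ] else .group_indicator(ped, i, pools)
    for (j in seq_along(pairs)) {
      k <- pairs[[j]][1]; kp <- pairs[[j]][2]
      het[i, j] <- fsv[k] * fdv[kp] + fsv[kp] * fdv[k]
    }
  }
  for (j in seq_along(pairs)) {
    rec[, j] <- 2 * Fm[, pairs[[j]][1]] * Fm[, pairs[[j]][2]]
  }
  structure(list(
    ids = ped$id, pools = pools, fractions = Fm, het = het, recloss = rec,
    heterozygosity = rowSums(het), recombination_loss = rowSums(rec)
  ), class = "breed_comp")
}

# pool indicator used for a missing parent slot of a (part-)founder
.group_indicator <- function(ped, i, pools) {
  g <- ped$founder_group[i]
  if (is.na(g)) stop("animal ", ped$id[i], " has a missing parent but no founder group")
  ind <- stats::setNames(numeric(length(pools)), pools)
  ind[g] <- 1
  ind
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds A (or the metafounder-augmented A(Gamma)) by the recursions
#' a(i,j) = (a(sire,j) + a(dam,j))/2 and a(i,i) = 1 + a(sire,dam)/2.  With
#' a metafounder set, the metafounder block is initialised to Gamma so that
#' founders linked to a pool with self-relationship gamma get diagonal
#' 1 + gamma/2.  Without one, metafounder rows (if present) are zero
#' (equivalent to Gamma = 0) and founders are unrelated with diagonal 1.
#'
#' @param ped a [ped_table].
#' @param mfs optional [metafounder_set()]; labels must match the
#'   pedigree's metafounder labels.
#' @return a [rel_matrix()] of kind `"A"` or `"A_gamma"`.
#' @export
build_A <- function(ped, mfs = NULL) {
  stopifnot(inherits(ped, "ped_table"))
  n <- nrow(ped)
  idx <- .ped_idx(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  is_mf <- ped$is_metafounder
  if (!is.null(mfs)) {
    labs <- metafounder_labels(ped)
    if (!setequal(mfs$labels, labs) || length(labs) == 0) {
      stop("gamma labels do not match pedigree metafounder labels")
    }
    mf_rows <- which(is_mf)
    ord <- match(ped$founder_group[mf_rows], mfs$labels)
    A[mf_rows, mf_rows] <- mfs$gamma[ord, ord]
  }
  for (i in seq_len(n)) {
    if (is_mf[i]) next
    s <- idx$si[i]; d <- idx$di[i]
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (!is.na(s)) row <- row + A[s, prev] / 2
    if (!is.na(d)) row <- row + A[d, prev] / 2
    A[i, prev] <- row
    A[prev, i] <- row
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + asd / 2
  }
  rel_matrix(A, kind = if (is.null(mfs)) "A" else "A_gamma")
}

#' Inbreeding coefficients from a relationship matrix
#'
#' F_i = diagonal(i) - 1.  Under the metafounder model founders linked to a
#' pool with self-relationship gamma have F = gamma/2; a maximally
#' heterozygous animal in the 0.5-frequency genomic matrix has F = -1.
#'
#' @param R a [rel_matrix()] of kind A, A_gamma, G or G_gamma.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(R) {
  stopifnot(inherits(R, "rel_matrix"))
  stats::setNames(diag(unclass(R)) - 1, rownames(R))
}

#' Breed-of-origin partial relationship matrices
#'
#' Splits the numerator relationship matrix of a crossbred pedigree into
#' per-pool partial matrices A^b and per-pair segregation matrices
#' A^(b,b'), such that sum_b A^b + sum_(b<b') A^(b,b') = A elementwise.
#' Off-diagonals follow the usual parent-average recursion; diagonals are
#' ((f^b_sire)^2 + (f^b_dam)^2)/2 + a^b(sire,dam)/2 for the partial
#' matrices and f^b_sire f^b'_sire + f^b_dam f^b'_dam + a^(bb')(sire,dam)/2
#' for the segregation matrices.  Base animals are indicators of their own
#' pool.  Metafounder pseudo-individuals are not part of the decomposition:
#' animals whose parents are metafounders are treated as base animals of
#' their founder group.
#'
#' @param ped a [ped_table].
#' @param comp a [breed_composition()] of the same pedigree (computed if
#'   missing).
#' @return list with `pools`, `partial` (named list of [rel_matrix()]),
#'   `segregation` (named list, names `"b:b'"`), over non-metafounder
#'   animals.  The sum identity is verified internally to 1e-8.
#' @export
partial_matrices <- function(ped, comp = breed_composition(ped)) {
  stopifnot(inherits(ped, "ped_table"))
  pools <- comp$pools
  keep <- !ped$is_metafounder
  ids <- ped$id[keep]
  n <- length(ids)
  idx <- .ped_idx(ped)
  # remap parent indices into the animal-only ordering; metafounder parent -> NA
  si <- match(ped$sire[keep], ids)
  di <- match(ped$dam[keep], ids)
  Fm <- comp$fractions[keep, , drop = FALSE]
  grp <- ped$founder_group[keep]
  base <- is.na(si) & is.na(di)

  part <- lapply(pools, function(b) matrix(0, n, n, dimnames = list(ids, ids)))
  names(part) <- pools
  pairs <- if (length(pools) >= 2) utils::combn(pools, 2, simplify = FALSE) else list()
  seg <- lapply(pairs, function(p) matrix(0, n, n, dimnames = list(ids, ids)))
  names(seg) <- vapply(pairs, paste, "", collapse = ":")

  pf <- function(j, i) {
    # pool fractions of parent slot (sire j of animal i); base indicator if unknown
    if (!is.na(j)) stats::setNames(Fm[j, ], pools) else {
      g <- grp[i]
      if (is.na(g)) stop("animal ", ids[i], " lacks founder group for missing parent")
      ind <- stats::setNames(numeric(length(pools)), pools)
      ind[g] <- 1
      ind
    }
  }
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    s <- si[i]; d <- di[i]
    if (base[i]) {
      g <- grp[i]
      if (is.na(g)) stop("base animal ", ids[i], " has no founder group")
      part[[g]][i, i] <- 1
      next
    }
    fs <- pf(s, i); fd <- pf(d, i)
    for (b in pools) {
      M <- part[[b]]
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + M[s, prev] / 2
      if (!is.na(d)) row <- row + M[d, prev] / 2
      M[i, prev] <- row; M[prev, i] <- row
      absd <- if (!is.na(s) && !is.na(d)) M[s, d] else 0
      M[i, i] <- (fs[b]^2 + fd[b]^2) / 2 + absd / 2
      part[[b]] <- M
    }
    for (j in seq_along(pairs)) {
      b <- pairs[[j]][1]; bp <- pairs[[j]][2]
      M <- seg[[j]]
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + M[s, prev] / 2
      if (!is.na(d)) row <- row + M[d, prev] / 2
      M[i, prev] <- row; M[prev, i] <- row
      ssd <- if (!is.na(s) && !is.na(d)) M[s, d] else 0
      M[i, i] <- fs[b] * fs[bp] + fd[b] * fd[bp] + ssd / 2
      seg[[j]] <- M
    }
  }
  tot <- Reduce(`+`, part)
  if (length(seg)) tot <- tot + Reduce(`+`, seg)
  Afull <- unclass(build_A(ped))[keep, keep, drop = FALSE]
  err <- max(abs(tot - Afull))
  if (err > 1e-8) {
    stop("internal error: partial matrices do not sum to A (max dev ",
         format(err), ")")
  }
  list(
    pools = pools,
    partial = stats::setNames(
      lapply(pools, function(b) rel_matrix(part[[b]], kind = paste0("A_", b))),
      pools),
    segregation = lapply(seg, function(m) rel_matrix(m, kind = "A_seg")),
    ids = ids
  )
}

#' Invert a relationship matrix
#'
#' Dense inversion through the Cholesky factorisation, with an optional
#' ridge jitter for near-singular inputs.
#'
#' @param R a [rel_matrix()].
#' @param jitter ridge added to the diagonal when the matrix is not
#'   positive definite; `0` disables the retry and makes non-PD an error.
#' @return a [rel_matrix()] holding the inverse (kind suffixed `_inv`).
#' @export
invert_relationship <- function(R, jitter = 0) {
  m <- unclass(R)
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (jitter <= 0) {
      stop("matrix not positive definite (smallest eigenvalue ",
           format(ev_min, digits = 4), "); consider a jitter")
    }
    message("invert_relationship: adding jitter ", format(jitter),
            " (smallest eigenvalue ", format(ev_min, digits = 4), ")")
    ch <- chol(m + diag(jitter, nrow(m)))
  }
  inv <- chol2inv(ch)
  rel_matrix(inv, kind = paste0(attr(R, "kind"), "_inv"), ids = rownames(R))
}

#' Principal submatrix for genotyped animals
#'
#' @param R a [rel_matrix()].
#' @param ids animal ids (typically the genotype-file order).
#' @return a [rel_matrix()] of kind `"<kind>22"` in the requested order.
#' @export
extract_A22 <- function(R, ids) {
  miss <- setdiff(ids, rownames(R))
  if (length(miss) > 0) {
    stop("ids not in relationship matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  sub <- unclass(R)[ids, ids, drop = FALSE]
  rel_matrix(sub, kind = paste0(attr(R, "kind"), "22"), ids = ids)
}

#' Sparse inverse of A or A(Gamma) from the pedigree structure
#'
#' Uses the generalised decomposition A = T D T' with T the
#' parent-contribution triangle and D block-diagonal (Gamma on the
#' metafounder block, Mendelian sampling variances elsewhere), so that
#' A^-1 = (I - P)' D^-1 (I - P) is sparse.  Exactly matches the inverse of
#' [build_A()] (tested); used to assemble mixed-model equations.
#'
#' @param ped a [ped_table].
#' @param mfs optional [metafounder_set()].  Without it, metafounder rows
#'   are dropped and parents pointing at them are treated as unknown.
#' @param jitter ridge added to Gamma if it is singular.
#' @return list with `Ainv` (sparse `dgCMatrix`), `ids`, `logdet`
#'   (log determinant of A or A(Gamma)).
#' @export
ainverse <- function(ped, mfs = NULL, jitter = 1e-8) {
  stopifnot(inherits(ped, "ped_table"))
  if (is.null(mfs)) {
    keep <- !ped$is_metafounder
    ids <- ped$id[keep]
    si <- match(ped$sire[keep], ids)
    di <- match(ped$dam[keep], ids)
    A <- unclass(build_A(ped))[keep, keep, drop = FALSE]
    n <- length(ids)
    dvec <- numeric(n)
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      dvec[i] <- A[i, i] -
        (if (!is.na(s)) A[s, s] / 4 else 0) -
        (if (!is.na(d)) A[d, d] / 4 else 0) -
        (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
    }
    Dinv <- Matrix::Diagonal(x = 1 / dvec)
    Tm <- .parent_triangle(si, di, n)
    Ainv <- Matrix::t(Tm) %*% Dinv %*% Tm
    logdet <- sum(log(dvec))
  } else {
    ids <- ped$id
    n <- length(ids)
    si <- match(ped$sire, ids)
    di <- match(ped$dam, ids)
    A <- unclass(build_A(ped, mfs))
    mf <- which(ped$is_metafounder)
    ord <- match(ped$founder_group[mf], mfs$labels)
    Gmm <- mfs$gamma[ord, ord, drop = FALSE]
    ev <- eigen(Gmm, symmetric = TRUE)
    if (min(ev$values) < 1e-10) {
      Gmm <- Gmm + diag(max(jitter, 1e-10), nrow(Gmm))
      message("ainverse: gamma block singular, jitter ", format(jitter), " applied")
    }
    dvec <- numeric(n)
    for (i in seq_len(n)) {
      if (i %in% mf) next
      s <- si[i]; d <- di[i]
      dvec[i] <- A[i, i] -
        (if (!is.na(s)) A[s, s] / 4 else 0) -
        (if (!is.na(d)) A[d, d] / 4 else 0) -
        (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
    }
    anim <- setdiff(seq_len(n), mf)
    Ginv <- solve(Gmm)
    grid <- expand.grid(r = mf, c = mf)
    Dinv <- Matrix::sparseMatrix(
      i = c(anim, grid$r), j = c(anim, grid$c),
      x = c(1 / dvec[anim], as.vector(Ginv)), dims = c(n, n)
    )
    Tm <- .parent_triangle(si, di, n)
    Ainv <- Matrix::t(Tm) %*% Dinv %*% Tm
    logdet <- determinant(Gmm, logarithm = TRUE)$modulus + sum(log(dvec[-mf]))
  }
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  list(Ainv = as(Ainv, "CsparseMatrix"), ids = ids, logdet = as.numeric(logdet))
}

# (I - P): identity minus halved parent pointers
.parent_triangle <- function(si, di, n) {
  ii <- seq_len(n); jj <- seq_len(n); xx <- rep(1, n)
  ks <- which(!is.na(si)); kd <- which(!is.na(di))
  ii <- c(ii, ks, kd)
  jj <- c(jj, si[ks], di[kd])
  xx <- c(xx, rep(-0.5, length(ks)), rep(-0.5, length(kd)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Gene-dropping estimate of (partial) relationships
#'
#' Drops unique founder alleles through the pedigree and estimates the
#' numerator relationship matrix as the average identity-by-descent count
#' over replicate drops.  With `pool`, only allele pairs whose shared
#' founder allele originates from that pool are counted, giving the
#' IBD-restricted partial relationship matrix.  This is the Monte-Carlo
#' oracle used by the test suite.
#'
#' @param ped a [ped_table] (metafounder rows are treated as pool labels,
#'   not dropped individuals).
#' @param n_drops number of replicate allele drops.
#' @param seed RNG seed.
#' @param pool optional founder-pool label restricting the IBD count.
#' @return a [rel_matrix()] over non-metafounder animals.
#' @export
gene_drop_ibd <- function(ped, n_drops = 10000, seed = 1, pool = NULL) {
  stopifnot(inherits(ped, "ped_table"))
  set.seed(seed)
  keep <- !ped$is_metafounder
  ids <- ped$id[keep]
  n <- length(ids)
  si <- match(ped$sire[keep], ids)
  di <- match(ped$dam[keep], ids)
  grp <- ped$founder_group[keep]
  X1 <- matrix(0L, n, n_drops)
  X2 <- matrix(0L, n, n_drops)
  allele_pool <- character(2 * n)
  nxt <- 1L
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s)) {
      X1[i, ] <- nxt
      allele_pool[nxt] <- grp[i]
      nxt <- nxt + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      X1[i, ] <- ifelse(pick, X1[s, ], X2[s, ])
    }
    if (is.na(d)) {
      X2[i, ] <- nxt
      allele_pool[nxt] <- grp[i]
      nxt <- nxt + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      X2[i, ] <- ifelse(pick, X1[d, ], X2[d, ])
    }
  }
  in_pool <- function(a) if (is.null(pool)) TRUE else allele_pool[a] == pool
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m <- (X1[i, ] == X1[j, ]) * in_pool(X1[i, ]) +
           (X1[i, ] == X2[j, ]) * in_pool(X1[i, ]) +
           (X2[i, ] == X1[j, ]) * in_pool(X2[i, ]) +
           (X2[i, ] == X2[j, ]) * in_pool(X2[i, ])
      A[i, j] <- A[j, i] <- mean(m) / 2
    }
  }
  rel_matrix(A, kind = if (is.null(pool)) "A_genedrop" else paste0("A_genedrop_", pool))
}

#' Export a relationship matrix as labelled CSV (dense) or COO triplets
#' @param R a [rel_matrix()].
#' @param path output file.
#' @param format `"csv"` (dense, labelled) or `"coo"` (lower-triangle
#'   `i j value` triplets with an id header comment).
#' @export
write_relationship <- function(R, path, format = c("csv", "coo")) {
  format <- match.arg(format)
  m <- unclass(R)
  if (format == "csv") {
    utils::write.csv(as.data.frame(m), path, quote = FALSE)
  } else {
    idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
    con <- file(path, "w")
    writeLines(paste0("# ids: ", paste(rownames(m), collapse = ",")), con)
    utils::write.table(data.frame(i = idx[, 1], j = idx[, 2], x = m[idx]),
                       con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(path)
}
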