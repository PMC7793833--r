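#' Generalised least squares estimates of per-pool gene-content means
#'
#' For every marker i, fits the linear model
#' m_i = Q mu_i + (within- and across-pool polygenic terms) + e_i, where
#' m_i are the observed gene contents of the genotyped animals and the rows
#' of Q hold their pool ancestry fractions.  Because the per-marker genetic
#' scale multiplies every covariance identically, a single shared
#' covariance V = sum_b A^b + sum_(b<b') A^(b,b') + lambda I over genotyped
#' animals is factorised once and reused for all markers, giving the BLUE
#' mu_hat_i = (Q' V^-1 Q)^-1 Q' V^-1 m_i.
#'
#' @param G a complete [geno_matrix()] (genotyped animals).
#' @param ped a [ped_table] containing all genotyped animals.
#' @param comp a [breed_composition()] of `ped` (computed if missing).
#' @param partials result of [partial_matrices()] (computed if missing).
#' @param lambda ridge ratio added to the diagonal of V, as a fraction of
#'   its mean diagonal (default 1e-3).
#' @param identity_v use V = I instead of the pedigree covariance (the
#'   lambda -> infinity limit; pool means become GLS means under
#'   independence).
#' @return object of class `gene_content_means`: list with `mu` (markers x
#'   pools matrix of BLUEs), `pools`, `lambda`, `n_genotyped`.
#' @export
gls_gene_content_means <- function(G, ped, comp = NULL, partials = NULL,
                                   lambda = 1e-3, identity_v = FALSE) {
  stopifnot(inherits(G, "geno_matrix"), inherits(ped, "ped_table"))
  if (anyNA(G$M)) stop("genotype matrix has missing values; impute first")
  if (is.null(comp)) comp <- breed_composition(ped)
  miss <- setdiff(G$ids, ped$id)
  if (length(miss) > 0) {
    stop("genotyped animals absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  pools <- comp$pools
  Q <- comp$fractions[match(G$ids, comp$ids), , drop = FALSE]
  support <- colSums(Q)
  if (any(support < 1e-12)) {
    stop("no genotyped ancestry for pool(s): ",
         paste(pools[support < 1e-12], collapse = ", "),
         " (merge groups or drop them)")
  }
  if (identity_v) {
    Vinv_Q <- Q
    QVQ <- crossprod(Q)
    B <- solve(QVQ, t(Q))              # pools x animals
  } else {
    if (is.null(partials)) partials <- partial_matrices(ped, comp)
    gi <- match(G$ids, partials$ids)
    V <- Reduce(`+`, lapply(partials$partial, function(m) unclass(m)[gi, gi]))
    if (length(partials$segregation)) {
      V <- V + Reduce(`+`, lapply(partials$segregation, function(m) unclass(m)[gi, gi]))
    }
    lam <- lambda * mean(diag(V))
    diag(V) <- diag(V) + lam
    ch <- chol(V)
    Vinv_Q <- backsolve(ch, forwardsolve(t(ch), Q))
    QVQ <- crossprod(Q, Vinv_Q)
    B <- solve(QVQ, t(Vinv_Q))         # pools x animals
  }
  mu <- t(B %*% G$M)                   # markers x pools
  dimnames(mu) <- list(G$markers, pools)
  structure(list(mu = mu, pools = pools,
                 lambda = if (identity_v) Inf else lambda,
                 n_genotyped = length(G$ids)),
            class = "gene_content_means")
}

#' Estimate the metafounder relationship matrix Gamma
#'
#' Gamma_hat = 2 * Sigma_hat, where Sigma_hat is the empirical covariance
#' matrix (across markers, mean-centred, divisor s - 1) of the estimated
#' per-pool gene-content means.  If Gamma_hat is not positive
#' semidefinite, it is projected to the nearest PSD matrix by clipping
#' negative eigenvalues at zero (with a message, never silently).
#'
#' @param means a `gene_content_means` object from
#'   [gls_gene_content_means()].
#' @param project_psd clip negative eigenvalues (default `TRUE`).
#' @return a [metafounder_set()]; attribute `"projected"` records whether
#'   PSD projection changed the estimate.
#' @export
estimate_gamma <- function(means, project_psd = TRUE) {
  stopifnot(inherits(means, "gene_content_means"))
  mu <- means$mu
  if (nrow(mu) < 2) stop("at least 2 markers required to estimate gamma")
  bad <- colSums(is.finite(mu)) == 0
  if (any(bad)) stop("all-NaN mean column for pool(s): ",
                     paste(means$pools[bad], collapse = ", "))
  g <- 2 * stats::cov(mu)
  pr <- psd_project(g, error = !project_psd)
  out <- metafounder_set(means$pools, pr$m)
  attr(out, "projected") <- pr$projected
  out
}

#' Project a symmetric matrix to the nearest positive semidefinite matrix
#'
#' Negative eigenvalues are clipped at zero.  A sample covariance is PSD
#' by construction, so for [estimate_gamma()] this is a numerical guard
#' (externally supplied or edited Gamma matrices need not be PSD); any
#' actual projection is reported with a message, never silent.
#'
#' @param m symmetric matrix.
#' @param error error instead of projecting.
#' @return list `m` (PSD matrix), `projected` (logical).
#' @export
psd_project <- function(m, error = FALSE) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) >= -1e-10) {
    return(list(m = m, projected = FALSE))
  }
  if (error) stop("matrix not positive semidefinite")
  message("projecting to nearest PSD matrix (eigenvalues clipped: ",
          paste(format(ev$values[ev$values < 0], digits = 3), collapse = ", "), ")")
  vals <- pmax(ev$values, 0)
  m2 <- ev$vectors %*% diag(vals, length(vals)) %*% t(ev$vectors)
  list(m = (m2 + t(m2)) / 2, projected = TRUE)
}

#' Moment cross-check estimator of Gamma from purebred genotypes
#'
#' Replaces the GLS BLUEs with the observed within-group mean gene
#' contents of genotyped purebred animals; Gamma_hat = 2 * covariance of
#' those means across markers.  A simple sanity check for the GLS
#' estimator on deep, completely genotyped pedigrees.
#'
#' @param G a complete [geno_matrix()].
#' @param groups named character vector: animal id -> pool label (only
#'   genotyped purebreds should appear).
#' @return a [metafounder_set()].
#' @export
naive_gamma <- function(G, groups) {
  stopifnot(inherits(G, "geno_matrix"))
  if (ncol(G$M) < 2) stop("at least 2 markers required")
  groups <- groups[names(groups) %in% G$ids]
  labs <- sort(unique(unname(groups)))
  sizes <- table(factor(unname(groups), levels = labs))
  if (any(sizes < 2)) {
    stop("groups with fewer than 2 genotyped members: ",
         paste(labs[sizes < 2], collapse = ", "))
  }
  mu <- sapply(labs, function(b) {
    colMeans(G$M[match(names(groups)[groups == b], G$ids), , drop = FALSE])
  })
  metafounder_set(labs, 2 * stats::cov(mu))
}
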