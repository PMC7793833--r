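#' Variance components of the bivariate repeatability model
#'
#' @param G0 additive (co)variance matrix (traits x traits).
#' @param D0 permanent-environment variances (diagonal matrix or vector).
#' @param R0 residual variances (vector, one per trait).
#' @param traits trait labels.
#' @return a `variance_components` object.
#' @export
variance_components <- function(G0, D0, R0, traits = c("H", "B")) {
  G0 <- as.matrix(G0)
  if (is.matrix(D0)) D0 <- diag(D0)
  nt <- length(traits)
  stopifnot(nrow(G0) == nt, length(D0) == nt, length(R0) == nt)
  dimnames(G0) <- list(traits, traits)
  structure(list(G0 = G0, D0 = stats::setNames(as.numeric(D0), traits),
                 R0 = stats::setNames(as.numeric(R0), traits), traits = traits),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (traits:", paste(x$traits, collapse = ", "), ")\n")
  cat("additive G0:\n"); print(round(x$G0, 4))
  cat("permanent environment:", round(x$D0, 4), "\n")
  cat("residual:", round(x$R0, 4), "\n")
  if (!is.null(x$se)) cat("SEs available; converged:", x$converged,
                          "in", x$iterations, "iterations\n")
  invisible(x)
}

# ---- design matrices -------------------------------------------------------

# Fixed-effect design: contemporary groups as cross-classified factor (no
# intercept; CG levels are nested in trait) plus covariates.  Breed-
# composition covariates enter only for traits where they vary; age enters
# centred and decade-scaled, linear + quadratic, per trait.
.build_fixed <- function(phe) {
  nr <- nrow(phe)
  cg <- factor(phe$cg)
  X <- Matrix::sparseMatrix(i = seq_len(nr), j = as.integer(cg),
                            x = 1, dims = c(nr, nlevels(cg)))
  cols <- paste0("cg:", levels(cg))
  addcol <- function(X, v, nm) {
    if (all(abs(v) < 1e-12) || stats::sd(v) < 1e-12) return(X)
    X2 <- cbind(X, Matrix::Matrix(v, ncol = 1, sparse = TRUE))
    cols <<- c(cols, nm)
    X2
  }
  traits <- sort(unique(phe$trait))
  for (cv in intersect(c("zebu", "het", "recloss"), names(phe))) {
    for (tr in traits) {
      v <- ifelse(phe$trait == tr, phe[[cv]], 0)
      if (stats::sd(v[phe$trait == tr]) > 1e-12) {
        X <- addcol(X, v, paste0(cv, ":", tr))
      }
    }
  }
  if ("age" %in% names(phe)) {
    age_s <- (phe$age - 527.5) / 100
    for (tr in traits) {
      sel <- phe$trait == tr
      X <- addcol(X, ifelse(sel, age_s, 0), paste0("age:", tr))
      X <- addcol(X, ifelse(sel, age_s^2, 0), paste0("age2:", tr))
    }
  }
  colnames(X) <- cols
  # aliasing check on the (small) normal-equation block
  XtX <- as.matrix(Matrix::crossprod(X))
  qrd <- qr(XtX)
  if (qrd$rank < ncol(X)) {
    bad <- cols[qrd$pivot[(qrd$rank + 1):ncol(X)]]
    stop("confounded fixed effects (aliased columns): ",
         paste(bad, collapse = ", "))
  }
  X
}

# ---- mixed-model equations -------------------------------------------------

#' Assemble and solve Henderson's mixed-model equations
#'
#' Bivariate repeatability animal model: y = X beta + Z_a a + Z_d d + e
#' with a ~ N(0, G0 kron K), d ~ N(0, diag(D0 by trait)), residual
#' variances per trait.  The relationship structure K enters through its
#' inverse (pedigree A^-1, H^-1 or H(Gamma)^-1); metafounder
#' pseudo-animals receive solutions like any other animal.
#'
#' @param phe a `pheno_table` (columns animal, trait, cg, value, optional
#'   covariates).
#' @param Kinv list with `Ainv`/`Hinv` sparse inverse, `ids`, `logdet`
#'   (as returned by [ainverse()] or [build_Hinv()]).
#' @param vc a [variance_components()].
#' @param random random terms to include (`"a"` additive, `"pe"`
#'   permanent environment); empty gives a fixed-effects-only
#'   (weighted least squares) fit.
#' @return list with `beta` (named), `a` (animals x traits EBV matrix),
#'   `d` (named pe solutions), `loglik` (restricted log-likelihood, up to
#'   a constant), `yPy`, `factor` internals for reuse.
#' @export
solve_mme <- function(phe, Kinv, vc, random = c("a", "pe")) {
  mme <- .assemble_mme(phe, Kinv, vc, random)
  .solve_assembled(mme)
}

.assemble_mme <- function(phe, Kinv, vc, random = c("a", "pe")) {
  stopifnot(is.data.frame(phe), nrow(phe) > 0)
  traits <- vc$traits
  ti <- match(phe$trait, traits)
  if (anyNA(ti)) stop("phenotype trait codes not covered by variance components")
  Kmat <- if (!is.null(Kinv$Ainv)) Kinv$Ainv else Kinv$Hinv
  ids <- Kinv$ids
  pos <- match(phe$animal, ids)
  if (anyNA(pos)) stop("phenotyped animals missing from relationship structure")
  nr <- nrow(phe)
  nK <- length(ids)
  nt <- length(traits)

  X <- .build_fixed(phe)
  p <- ncol(X)
  blocks <- list(X)
  use_a <- "a" %in% random
  use_d <- "pe" %in% random
  if (use_a) {
    Za <- Matrix::sparseMatrix(i = seq_len(nr), j = (ti - 1L) * nK + pos,
                               x = 1, dims = c(nr, nt * nK))
    blocks <- c(blocks, list(Za))
  }
  d_ids <- unique(phe$animal)
  if (use_d) {
    dpos <- match(phe$animal, d_ids)
    Zd <- Matrix::sparseMatrix(i = seq_len(nr), j = dpos,
                               x = 1, dims = c(nr, length(d_ids)))
    blocks <- c(blocks, list(Zd))
  }
  W <- do.call(cbind, blocks)
  rvar <- vc$R0[ti]
  Rinv <- Matrix::Diagonal(x = 1 / rvar)
  y <- phe$value
  C <- Matrix::crossprod(W, Rinv %*% W)
  rhs <- as.numeric(Matrix::crossprod(W, y / rvar))

  G0inv <- NULL
  d_trait <- stats::setNames(phe$trait[!duplicated(phe$animal)], d_ids)
  dvar <- vc$D0[match(d_trait, traits)]
  off_a <- p
  off_d <- p + if (use_a) nt * nK else 0L
  if (use_a) {
    G0inv <- solve(vc$G0)
    GK <- Matrix::kronecker(Matrix::Matrix(G0inv, sparse = TRUE), Kmat)
    ia <- off_a + seq_len(nt * nK)
    C[ia, ia] <- C[ia, ia] + GK
  }
  if (use_d) {
    idd <- off_d + seq_len(length(d_ids))
    C <- C + Matrix::sparseMatrix(i = idd, j = idd, x = 1 / dvar,
                                  dims = dim(C))
  }
  C <- Matrix::forceSymmetric(C)
  list(C = C, rhs = rhs, W = W, X = X, y = y, rvar = rvar, ti = ti,
       traits = traits, ids = ids, d_ids = d_ids, d_trait = d_trait,
       dvar = dvar, p = p, nK = nK, nt = nt, use_a = use_a, use_d = use_d,
       off_a = off_a, off_d = off_d, G0inv = G0inv, vc = vc,
       K_logdet = Kinv$logdet, phe = phe)
}

.solve_assembled <- function(m) {
  ch <- tryCatch(Matrix::Cholesky(m$C, LDL = FALSE, perm = TRUE),
                 error = function(e) stop("coefficient matrix not positive definite: ",
                                          conditionMessage(e)))
  sol <- as.numeric(Matrix::solve(ch, m$rhs))
  beta <- stats::setNames(sol[seq_len(m$p)], colnames(m$X))
  a <- NULL
  if (m$use_a) {
    a <- matrix(sol[m$off_a + seq_len(m$nt * m$nK)], m$nK, m$nt,
                dimnames = list(m$ids, m$traits))
  }
  d <- if (m$use_d) stats::setNames(sol[m$off_d + seq_len(length(m$d_ids))], m$d_ids)
  fitted <- as.numeric(m$W %*% sol)
  ehat <- m$y - fitted
  yPy <- sum(m$y^2 / m$rvar) - sum(sol * m$rhs)
  logdetC <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  loglik <- -0.5 * (as.numeric(logdetC) + sum(log(m$rvar)) + yPy +
    (if (m$use_a) m$nK * determinant(m$vc$G0, logarithm = TRUE)$modulus +
       m$nt * (if (is.null(m$K_logdet) || is.na(m$K_logdet)) 0 else m$K_logdet)
     else 0) +
    (if (m$use_d) sum(log(m$dvar)) else 0))
  list(beta = beta, a = a, d = d, fitted = fitted, residuals = ehat,
       sol = sol, yPy = yPy, loglik = as.numeric(loglik), cholC = ch, mme = m)
}

# ---- AI-REML ---------------------------------------------------------------

# parameter vector layout for nt traits:
# vech(G0) (column-wise lower triangle), D0 diag, R0 diag
.vc_to_theta <- function(vc) {
  nt <- length(vc$traits)
  g <- vc$G0[lower.tri(vc$G0, diag = TRUE)]
  c(g, vc$D0, vc$R0)
}

.theta_to_vc <- function(theta, traits) {
  nt <- length(traits)
  ng <- nt * (nt + 1) / 2
  G0 <- matrix(0, nt, nt)
  G0[lower.tri(G0, diag = TRUE)] <- theta[seq_len(ng)]
  G0 <- G0 + t(G0) - diag(diag(G0), nt)
  variance_components(G0, theta[ng + seq_len(nt)],
                      theta[ng + nt + seq_len(nt)], traits)
}

.theta_valid <- function(theta, traits, floor = 1e-10) {
  nt <- length(traits)
  vc <- .theta_to_vc(theta, traits)
  ev <- eigen(vc$G0, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > floor && all(vc$D0 > floor) && all(vc$R0 > floor)
}

#' Default REML starting values
#'
#' Splits the raw phenotypic variance of each trait into additive,
#' permanent-environment and residual parts (half / quarter / quarter)
#' with a moderate positive starting genetic correlation.
#'
#' @param phe phenotype table.
#' @param traits trait labels.
#' @param split proportions (additive, pe, residual).
#' @param cor_a starting genetic correlation between traits.
#' @return a [variance_components()].
#' @export
default_starts <- function(phe, traits = sort(unique(phe$trait)),
                           split = c(0.50, 0.25, 0.25), cor_a = 0.3) {
  vy <- vapply(traits, function(tr) stats::var(phe$value[phe$trait == tr]), 0)
  vy[!is.finite(vy) | vy <= 0] <- mean(vy[is.finite(vy) & vy > 0])
  G0 <- diag(split[1] * vy, length(traits))
  if (length(traits) == 2) {
    G0[1, 2] <- G0[2, 1] <- cor_a * sqrt(G0[1, 1] * G0[2, 2])
  }
  variance_components(G0, split[2] * vy, split[3] * vy, traits)
}

#' AI-REML variance-component estimation
#'
#' Average-information REML for the bivariate repeatability animal model.
#' Each iteration assembles and factorises the mixed-model equations,
#' computes the restricted likelihood, its score (using exact traces from
#' the inverse coefficient matrix) and the average-information matrix, and
#' takes a Newton step; whenever the AI update leaves the parameter space
#' or decreases the likelihood, an EM step (which cannot decrease it) is
#' used instead.  Standard errors come from the inverse AI matrix at
#' convergence.
#'
#' @param phe phenotype table.
#' @param Kinv relationship inverse (see [solve_mme()]).
#' @param starts starting [variance_components()]
#'   (default [default_starts()]).
#' @param tol convergence tolerance on the maximum relative parameter
#'   change.
#' @param max_iter maximum number of iterations.
#' @param verbose print the iteration trace.
#' @return a [variance_components()] with fields `se`, `vcov` (inverse AI),
#'   `loglik`, `iterations`, `converged`, `boundary`, `trace`.
#' @export
aireml <- function(phe, Kinv, starts = NULL, tol = 1e-8, max_iter = 60,
                   verbose = FALSE) {
  traits <- sort(unique(phe$trait))
  if (identical(sort(traits), c("B", "H"))) traits <- c("H", "B")
  if (is.null(starts)) starts <- default_starts(phe, traits)
  stopifnot(identical(starts$traits, traits))
  single_rec <- tapply(phe$animal, phe$trait, function(a) max(table(a))) == 1L
  if (any(single_rec)) {
    warning("trait(s) with single records per animal: ",
            paste(names(single_rec)[single_rec], collapse = ", "),
            " (permanent-environment variance weakly identifiable)")
  }
  theta <- .vc_to_theta(starts)
  nt <- length(traits)
  ng <- nt * (nt + 1) / 2
  npar <- ng + 2 * nt
  state <- .reml_state(phe, Kinv, .theta_to_vc(theta, traits))
  trace <- data.frame(iter = 0, loglik = state$fit$loglik,
                      step = "start", max_rel_change = NA)
  AI <- NULL
  converged <- FALSE
  floor_scale <- 1e-8 * stats::var(phe$value)
  for (it in seq_len(max_iter)) {
    sc <- state$score
    AI <- state$AI
    step <- tryCatch(solve(AI, sc), error = function(e) NULL)
    took <- "ai"
    theta_new <- if (!is.null(step)) theta + step else NULL
    if (is.null(theta_new) || !.theta_valid(theta_new, traits, floor_scale)) {
      theta_new <- state$em
      took <- "em"
    }
    state_new <- .reml_state(phe, Kinv, .theta_to_vc(theta_new, traits))
    if (took == "ai" && state_new$fit$loglik < state$fit$loglik - 1e-8) {
      # step-halving, then EM as the safe fallback
      ok <- FALSE
      for (h in 1:4) {
        cand <- theta + step / 2^h
        if (!.theta_valid(cand, traits, floor_scale)) next
        cs <- .reml_state(phe, Kinv, .theta_to_vc(cand, traits))
        if (cs$fit$loglik >= state$fit$loglik - 1e-8) {
          theta_new <- cand; state_new <- cs; took <- paste0("ai/2^", h); ok <- TRUE
          break
        }
      }
      if (!ok) {
        theta_new <- state$em
        state_new <- .reml_state(phe, Kinv, .theta_to_vc(theta_new, traits))
        took <- "em"
      }
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-10))
    trace <- rbind(trace, data.frame(iter = it, loglik = state_new$fit$loglik,
                                     step = took, max_rel_change = rel))
    if (verbose) {
      message(sprintf("it %2d [%s] logL = %.6f, max rel change = %.3g",
                      it, took, state_new$fit$loglik, rel))
    }
    theta <- theta_new
    state <- state_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 0) {
    warning("AI-REML did not reach tolerance ", tol, " in ", max_iter,
            " iterations (last relative change ",
            format(utils::tail(trace$max_rel_change, 1), digits = 3), ")")
  }
  vc <- .theta_to_vc(theta, traits)
  AIfinal <- state$AI
  vcov <- tryCatch(solve(AIfinal), error = function(e) matrix(NA, npar, npar))
  pn <- .theta_names(traits)
  dimnames(vcov) <- list(pn, pn)
  vc$se <- stats::setNames(sqrt(pmax(diag(vcov), 0)), pn)
  vc$vcov <- vcov
  vc$loglik <- state$fit$loglik
  vc$iterations <- nrow(trace) - 1L
  vc$converged <- converged
  # flag components indistinguishable from the zero boundary
  vc$boundary <- stats::setNames(is.finite(vc$se) & theta < 2 * vc$se, pn)
  vc$trace <- trace
  vc
}

.theta_names <- function(traits) {
  nt <- length(traits)
  gn <- outer(traits, traits, function(a, b) paste0("a:", a, b))
  gn <- gn[lower.tri(gn, diag = TRUE)]
  c(gn, paste0("pe:", traits), paste0("e:", traits))
}

# one REML iteration state: fit, dense inverse of C, score, AI matrix,
# and the EM-updated parameter vector
.reml_state <- function(phe, Kinv, vc) {
  m <- .assemble_mme(phe, Kinv, vc)
  fit <- .solve_assembled(m)
  nC <- ncol(m$C)
  Cinv <- as.matrix(Matrix::solve(fit$cholC, diag(nC)))
  traits <- m$traits
  nt <- m$nt
  nK <- m$nK
  ng <- nt * (nt + 1) / 2
  G0inv <- m$G0inv
  Kmat <- if (!is.null(Kinv$Ainv)) Kinv$Ainv else Kinv$Hinv
  Ksum <- .sym_triplets(Kmat)
  Ahat <- fit$a
  Py <- fit$residuals / m$rvar

  # trait-block traces of K^-1 * C^{aa}
  TrA <- matrix(0, nt, nt)
  for (k in seq_len(nt)) for (l in seq_len(nt)) {
    rows <- m$off_a + (k - 1L) * nK + Ksum$i
    colsv <- m$off_a + (l - 1L) * nK + Ksum$j
    TrA[k, l] <- sum(Ksum$x * Cinv[cbind(rows, colsv)])
  }
  Q <- as.matrix(t(Ahat) %*% (Kmat %*% Ahat))

  # pe and residual bookkeeping
  d_tr <- m$d_trait
  dd_diag <- diag(Cinv)[m$off_d + seq_len(length(m$d_ids))]
  ehat <- fit$residuals
  Wmat <- m$W

  Es <- .vech_basis(nt)
  score <- numeric(ng + 2 * nt)
  Fm <- matrix(0, nrow(phe), ng + 2 * nt)
  em <- numeric(ng + 2 * nt)

  for (gidx in seq_len(ng)) {
    E <- Es[[gidx]]
    B <- G0inv %*% E %*% G0inv
    trP <- nK * sum(diag(E %*% G0inv)) - sum(B * TrA)
    quad <- sum(B * Q)
    score[gidx] <- -0.5 * (trP - quad)
    U <- Ahat %*% G0inv %*% E
    pos <- match(phe$animal, m$ids)
    fvec <- U[cbind(pos, m$ti)]
    Fm[, gidx] <- fvec
  }
  G0em <- (Q + TrA) / nK
  em[seq_len(ng)] <- G0em[lower.tri(G0em, diag = TRUE)]

  for (k in seq_len(nt)) {
    tr <- traits[k]
    ink <- d_tr == tr
    ndk <- sum(ink)
    sdk <- m$vc$D0[k]
    dk <- fit$d[ink]
    ck <- sum(dd_diag[ink])
    trP <- ndk / sdk - ck / sdk^2
    quad <- sum(dk^2) / sdk^2
    score[ng + k] <- -0.5 * (trP - quad)
    em[ng + k] <- if (ndk > 0) (sum(dk^2) + ck) / ndk else sdk
    fvec <- numeric(nrow(phe))
    sel <- d_tr[match(phe$animal, m$d_ids)] == tr
    fvec[sel] <- fit$d[match(phe$animal[sel], m$d_ids)] / sdk
    Fm[, ng + k] <- fvec
  }

  for (k in seq_len(nt)) {
    sel <- m$ti == k
    nk <- sum(sel)
    sek <- m$vc$R0[k]
    Wk <- Wmat[sel, , drop = FALSE]
    Ss <- .sym_triplets(Matrix::crossprod(Wk))
    trWCW <- sum(Ss$x * Cinv[cbind(Ss$i, Ss$j)])
    trP <- nk / sek - trWCW / sek^2
    quad <- sum(ehat[sel]^2) / sek^2
    score[ng + nt + k] <- -0.5 * (trP - quad)
    em[ng + nt + k] <- (sum(ehat[sel]^2) + trWCW) / nk
    fvec <- numeric(nrow(phe))
    fvec[sel] <- ehat[sel] / sek
    Fm[, ng + nt + k] <- fvec
  }

  # AI matrix: 0.5 * F' P F
  WtRF <- Matrix::crossprod(Wmat, Fm / m$rvar)
  CW <- Matrix::solve(fit$cholC, WtRF)
  PF <- Fm / m$rvar - (Wmat %*% CW) / m$rvar
  AI <- 0.5 * crossprod(Fm, as.matrix(PF))
  AI <- (AI + t(AI)) / 2

  list(fit = fit, score = score, AI = AI, em = em)
}

# triplet (i, j, x) representation with BOTH triangles of a symmetric
# sparse matrix (Matrix stores dsCMatrix as one triangle)
.sym_triplets <- function(M) {
  Mg <- as(as(M, "generalMatrix"), "TsparseMatrix")
  data.frame(i = Mg@i + 1L, j = Mg@j + 1L, x = Mg@x)
}

# symmetric basis matrices for vech(G0)
.vech_basis <- function(nt) {
  idx <- which(lower.tri(diag(nt), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(k) {
    E <- matrix(0, nt, nt)
    E[idx[k, 1], idx[k, 2]] <- 1
    E[idx[k, 2], idx[k, 1]] <- 1
    E
  })
}

#' Genetic parameters with metafounder rescaling
#'
#' Converts (co)variance components to the unrelated-base scale and
#' computes heritability, repeatability and the cross-trait genetic
#' correlation.  With a metafounder set, additive variances are multiplied
#' by k_b = 1 - gamma_b / 2 and the additive covariance by
#' 1 - gamma_bb' / 2; without one all factors are 1.
#'
#' @param vc a [variance_components()] (or list with `G0`, `D0`, `R0`).
#' @param mfs optional [metafounder_set()].
#' @param trait_pools named map from trait label to metafounder label
#'   (default identity on the traits).
#' @return list with per-trait `scaled_va`, `sigma_p`, `h2`, `repeatability`,
#'   the cross-trait `r_a`, and the scale factors `k`.
#' @export
genetic_params <- function(vc, mfs = NULL, trait_pools = NULL) {
  traits <- if (!is.null(vc$traits)) vc$traits else colnames(vc$G0)
  nt <- length(traits)
  D0 <- if (is.matrix(vc$D0)) diag(vc$D0) else vc$D0
  if (is.null(trait_pools)) trait_pools <- stats::setNames(traits, traits)
  k <- rep(1, nt)
  kxy <- 1
  if (!is.null(mfs)) {
    gsub <- mfs$gamma[trait_pools[traits], trait_pools[traits], drop = FALSE]
    k <- 1 - diag(gsub) / 2
    if (nt == 2) kxy <- 1 - gsub[1, 2] / 2
  }
  va <- diag(vc$G0) * k
  sp <- va + D0 + vc$R0
  if (any(sp <= 0)) stop("non-positive phenotypic variance")
  h2 <- va / sp
  rep_ <- (va + D0) / sp
  r_a <- if (nt == 2) {
    cov_s <- vc$G0[1, 2] * kxy
    cov_s / sqrt(va[1] * va[2])
  } else NA_real_
  list(traits = traits,
       scaled_va = stats::setNames(va, traits),
       sigma_p = stats::setNames(sp, traits),
       h2 = stats::setNames(h2, traits),
       repeatability = stats::setNames(rep_, traits),
       r_a = r_a,
       k = stats::setNames(k, traits), k_cross = kxy)
}

#' Delta-method standard error of heritability from an AI-REML fit
#'
#' @param vc a converged [aireml()] result with `vcov`.
#' @param trait trait label.
#' @return list `h2`, `se`.
#' @export
h2_se <- function(vc, trait) {
  traits <- vc$traits
  k <- match(trait, traits)
  pn <- .theta_names(traits)
  va <- vc$G0[k, k]; vd <- vc$D0[k]; ve <- vc$R0[k]
  sp <- va + vd + ve
  grad <- stats::setNames(numeric(length(pn)), pn)
  grad[paste0("a:", trait, trait)] <- (sp - va) / sp^2
  grad[paste0("pe:", trait)] <- -va / sp^2
  grad[paste0("e:", trait)] <- -va / sp^2
  V <- vc$vcov[names(grad), names(grad)]
  list(h2 = va / sp, se = sqrt(max(as.numeric(t(grad) %*% V %*% grad), 0)))
}
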