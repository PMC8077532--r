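#' Read a rooted, branch-length-bearing Newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]: the tree must carry
#' branch lengths (time units for a time-calibrated tree) and unique tip
#' labels; polytomies are permitted.
#'
#' @param path Newick file, or a Newick string via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) abort("could not parse Newick input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has missing branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  tree
}

#' Attach data taxa to tree tips by substitution
#'
#' Renames designated tips so that taxa measured in the data but absent from
#' the tree occupy the positions of close relatives — e.g. placing two
#' undescribed *Tropheops* forms at the tips of congeners with which the
#' genus forms a well-supported, short-branched clade. Branch lengths are
#' untouched.
#'
#' @param tree a `phylo`.
#' @param mapping named character vector: `names` are the data taxa, values
#'   the tree tips they replace.
#' @return the relabelled `phylo`.
#' @export
substitute_taxa <- function(tree, mapping) {
  if (length(mapping) == 0) return(tree)
  if (anyDuplicated(unname(mapping)) || anyDuplicated(names(mapping))) {
    abort("substitution mapping must be injective")
  }
  idx <- match(unname(mapping), tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0("unknown tip(s): ",
                 paste(mapping[is.na(idx)], collapse = ", "),
                 "; available tips: ",
                 paste(tree$tip.label, collapse = ", ")))
  }
  tree$tip.label[idx] <- names(mapping)
  tree
}

#' Expected trait covariance among taxa under Brownian motion
#'
#' Builds the phylogenetic variance-covariance matrix: entry (i, j) is the
#' shared root-to-MRCA path length of tips i and j, and the diagonal holds
#' the root-to-tip depths. Computed by accumulating each edge's length over
#' the outer product of its descendant tips, which reproduces MRCA depths
#' without explicit pairwise MRCA searches.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree) {
  if (!ape::is.rooted(tree)) abort("phylo_vcv needs a rooted tree")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # postorder sweep: descendant-tip indicator per node
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (k in seq_len(nrow(po$edge))) {
    tips <- desc[[po$edge[k, 2]]]
    V[tips, tips] <- V[tips, tips] + po$edge.length[k]
  }
  V
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries by `lambda`, leaving
#' tip variances unchanged — for an ultrametric tree, the matrix equivalent
#' of multiplying every internal branch by `lambda`. `lambda = 1` preserves
#' the Brownian structure; `lambda = 0` yields the star phylogeny.
#'
#' @param V covariance matrix from [phylo_vcv()].
#' @param lambda value in `[0, 1]`.
#' @return transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("lambda must be a single value in [0, 1]")
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

# GLS fit of y ~ X under covariance V (up to scale); returns ML pieces.
.gls_core <- function(X, y, V) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    # PSD-singular V (e.g. zero-length branches): eigen-based square root
    ei <- eigen(V, symmetric = TRUE)
    vals <- pmax(ei$values, 0)
    if (min(ei$values) < -1e-8 * max(vals)) abort("covariance not PSD")
    R <- t(ei$vectors %*% (t(ei$vectors) * sqrt(vals + 1e-12)))
    logdet <- sum(log(vals + 1e-12))
  } else {
    logdet <- 2 * sum(log(diag(R)))
  }
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  qr_fit <- qr(Xt)
  if (qr_fit$rank < ncol(X)) abort("singular design matrix")
  beta <- qr.coef(qr_fit, yt)
  resid_t <- yt - Xt %*% beta
  rss <- sum(resid_t^2)
  sigma2_ml <- rss / n
  logLik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdet + n)
  XtX_inv <- chol2inv(qr.R(qr_fit))
  list(beta = beta, rss = rss, sigma2_ml = sigma2_ml, logLik = logLik,
       XtX_inv = XtX_inv, logdet = logdet, resid = y - X %*% beta)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Fits a linear regression whose error covariance follows the
#' lambda-transformed phylogenetic covariance matrix. The strength of
#' phylogenetic signal, lambda, is estimated by maximising the Gaussian
#' profile likelihood (ML, not REML) over `[0, 1]` by bounded 1-D
#' optimisation, with both interval endpoints evaluated explicitly so
#' boundary maxima are never missed. `lambda = 0` collapses to ordinary
#' least squares; `lambda = 1` is the full Brownian covariance.
#'
#' @param data data frame with one row per taxon.
#' @param formula model formula, e.g. `y ~ x`.
#' @param tree rooted `phylo`; tips must cover the data taxa.
#' @param taxon column of `data` naming the taxa (tidy-eval; default
#'   `taxon`).
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return a `cf_pgls` object: use [tidy()] for the coefficient table,
#'   [glance()] for lambda, log-likelihood, R2, sigma2 and AIC;
#'   `$residuals` holds per-taxon residuals.
#' @export
pgls_fit <- function(data, formula, tree, taxon = taxon, lambda = "ML") {
  taxa <- as.character(dplyr::pull(data, {{ taxon }}))
  if (anyDuplicated(taxa)) abort("duplicate taxa in data")
  missing_tips <- setdiff(taxa, tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("taxa absent from tree: ", paste(missing_tips, collapse = ", ")))
  }
  mf <- stats::model.frame(formula, data = data)
  if (nrow(mf) != nrow(data)) abort("missing values in model variables")
  y <- stats::model.response(mf)
  X <- model.matrix(formula, data = data)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1) abort("fewer taxa than parameters + 1")
  if (n < 4) abort("pgls_fit needs at least 4 taxa")
  V <- phylo_vcv(tree)[taxa, taxa]

  prof <- function(lam) .gls_core(X, y, lambda_transform(V, lam))$logLik
  if (identical(lambda, "ML")) {
    opt <- optimize(prof, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, prof(0), prof(1))
    lam_hat <- cand[which.max(ll)]
    ml_search <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      abort("lambda must be 'ML' or a value in [0, 1]")
    }
    lam_hat <- lambda
    ml_search <- FALSE
  }
  fit <- .gls_core(X, y, lambda_transform(V, lam_hat))
  # unbiased scale for coefficient standard errors
  sigma2_hat <- fit$rss / (n - p)
  se <- sqrt(diag(fit$XtX_inv) * sigma2_hat)
  null_fit <- .gls_core(matrix(1, n, 1), y, lambda_transform(V, lam_hat))
  r2 <- 1 - fit$rss / null_fit$rss

  structure(list(
    lambda = lam_hat,
    ml_lambda = ml_search,
    coefficients = setNames(as.numeric(fit$beta), colnames(X)),
    se = setNames(as.numeric(se), colnames(X)),
    logLik = fit$logLik,
    logLik_bounds = c(`0` = prof(0), `1` = prof(1)),
    sigma2 = fit$sigma2_ml,
    residuals = setNames(as.numeric(fit$resid), taxa),
    fitted = setNames(as.numeric(X %*% fit$beta), taxa),
    r.squared = r2,
    n = n, p = p,
    df.residual = n - p,
    formula = formula,
    taxa = taxa,
    data = as_tibble(data)
  ), class = "cf_pgls")
}

#' @export
print.cf_pgls <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS (%s lambda = %.4f), n = %d taxa\n",
              if (x$ml_lambda) "ML" else "fixed", x$lambda, x$n))
  print(tidy(x))
  cat(sprintf("logLik = %.4f, R2 = %.4f\n", x$logLik, x$r.squared))
  invisible(x)
}

#' @rdname pgls_fit
#' @param x a `cf_pgls`.
#' @param ... unused.
#' @export
#' @exportS3Method generics::tidy
tidy.cf_pgls <- function(x, ...) {
  est <- x$coefficients
  tstat <- est / x$se
  tibble(term = names(est), estimate = unname(est), std.error = unname(x$se),
         statistic = unname(tstat),
         p.value = 2 * pt(abs(tstat), x$df.residual, lower.tail = FALSE))
}

#' @rdname pgls_fit
#' @export
#' @exportS3Method generics::glance
glance.cf_pgls <- function(x, ...) {
  k <- x$p + 1 + as.integer(x$ml_lambda)  # betas + sigma2 (+ lambda)
  tibble(lambda = x$lambda, logLik = x$logLik, AIC = -2 * x$logLik + 2 * k,
         sigma2 = x$sigma2, r.squared = x$r.squared, n = x$n,
         df.residual = x$df.residual)
}

#' Phylogenetic size correction of eye area
#'
#' Linearises raw eye area by a square-root transform, regresses it on
#' standard length by lambda-ML PGLS, and returns the per-taxon residuals —
#' "residual eye areas" free of allometric and phylogenetic structure, ready
#' for downstream regression against rest or day/night preference.
#'
#' @param data data frame with one row per taxon.
#' @param tree rooted `phylo`.
#' @param taxon,standard_length,eye_area tidy-eval column names.
#' @param lambda passed to [pgls_fit()].
#' @return the input tibble plus `sqrt_eye_area` and `residual_eye_area`
#'   columns; the underlying fit is attached as attribute `fit`.
#' @export
phylo_size_correct <- function(data, tree, taxon = taxon,
                               standard_length = standard_length,
                               eye_area = eye_area, lambda = "ML") {
  sl <- dplyr::pull(data, {{ standard_length }})
  ea <- dplyr::pull(data, {{ eye_area }})
  taxa <- as.character(dplyr::pull(data, {{ taxon }}))
  bad <- which(!is.finite(sl) | !is.finite(ea) | sl <= 0 | ea <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive measurement for taxon: ",
                 paste(taxa[bad], collapse = ", ")))
  }
  dd <- tibble(taxon = taxa, standard_length = sl, sqrt_eye_area = sqrt(ea))
  fit <- pgls_fit(dd, sqrt_eye_area ~ standard_length, tree, taxon = taxon,
                  lambda = lambda)
  out <- as_tibble(data)
  out$sqrt_eye_area <- dd$sqrt_eye_area
  out$residual_eye_area <- unname(fit$residuals[taxa])
  attr(out, "fit") <- fit
  out
}

#' Simulate tip traits under Brownian motion
#'
#' Draws replicate trait vectors from a multivariate normal with mean
#' `root_value` and covariance `rate` times the tree's covariance matrix.
#'
#' @param tree rooted `phylo`.
#' @param rate Brownian rate (trait variance per unit branch length), >= 0.
#' @param root_value trait value at the root.
#' @param n_sims number of replicates.
#' @param seed optional integer seed for reproducibility.
#' @return `n_tips x n_sims` matrix, rownames = tip labels.
#' @export
simulate_bm <- function(tree, rate = 1, root_value = 0, n_sims = 1,
                        seed = NULL) {
  if (rate < 0) abort("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  V <- phylo_vcv(tree)
  n <- nrow(V)
  if (rate == 0) {
    return(matrix(root_value, n, n_sims, dimnames = list(rownames(V), NULL)))
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ei <- eigen(V, symmetric = TRUE)
    R <- t(ei$vectors %*% (t(ei$vectors) * sqrt(pmax(ei$values, 0))))
  }
  Z <- matrix(rnorm(n * n_sims), n, n_sims)
  out <- root_value + sqrt(rate) * crossprod(R, Z)
  rownames(out) <- rownames(V)
  out
}

# one-way F statistics, vectorised over the columns of Y (n x S)
.anova_F_cols <- function(Y, g) {
  g <- factor(g)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  n <- nrow(Y)
  k <- nlevels(g)
  ng <- as.numeric(table(g))
  gs <- rowsum(Y, g)                      # k x S group sums
  tot <- colSums(Y)
  ssb <- colSums(gs^2 / ng) - tot^2 / n
  sst <- colSums(Y^2) - tot^2 / n
  ssw <- sst - ssb
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  Fv[ssb <= .Machine$double.eps * pmax(sst, 1)] <- 0
  Fv
}

#' Simulation-based phylogenetic ANOVA
#'
#' Compares the observed one-way ANOVA F statistic for a trait across groups
#' of taxa against a null distribution of F statistics computed on traits
#' simulated under Brownian motion on the tree. The Brownian rate and root
#' are estimated from the observed trait by ML under the BM model (GLS mean
#' as root; mean squared phylogenetically standardised deviation as rate).
#' The p-value uses the add-one correction
#' `p = (1 + #\{F_null >= F_obs\}) / (1 + n_sims)` so it is never exactly 0.
#'
#' @param data data frame with one row per taxon.
#' @param trait,group,taxon tidy-eval column names.
#' @param tree rooted `phylo` covering the taxa.
#' @param n_sims number of Brownian simulations.
#' @param seed optional seed.
#' @return a `cf_panova` object; [glance()] gives a one-row summary.
#' @export
phylo_anova <- function(data, trait, group, tree, taxon = taxon,
                        n_sims = 1000, seed = NULL) {
  y <- dplyr::pull(data, {{ trait }})
  g <- factor(dplyr::pull(data, {{ group }}))
  taxa <- as.character(dplyr::pull(data, {{ taxon }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep]); taxa <- taxa[keep]
  if (nlevels(g) < 2) abort("phylo_anova needs >= 2 groups")
  if (any(table(g) < 1)) abort("group with zero taxa after matching to tree")
  missing_tips <- setdiff(taxa, tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("taxa absent from tree: ",
                 paste(missing_tips, collapse = ", ")))
  }
  tree_use <- ape::keep.tip(tree, taxa)
  V <- phylo_vcv(tree_use)[taxa, taxa]
  n <- length(y)

  F_obs <- .anova_F_cols(y, g)
  if (F_obs == 0 && var(y) == 0) {
    # constant trait: nothing to test, every null F ties or exceeds 0
    return(structure(list(F_obs = 0, F_null = rep(NA_real_, n_sims),
                          p_phylo = 1, n_sims = n_sims, n = n,
                          rate = 0, root = y[1]), class = "cf_panova"))
  }
  # BM ML estimates of root and rate from the observed trait
  ones <- matrix(1, n, 1)
  fit0 <- .gls_core(ones, y, V)
  root <- as.numeric(fit0$beta)
  rate <- as.numeric(fit0$sigma2_ml)
  sims <- simulate_bm(tree_use, rate = rate, root_value = root,
                      n_sims = n_sims, seed = seed)[taxa, , drop = FALSE]
  F_null <- .anova_F_cols(sims, g)
  p <- (1 + sum(F_null >= F_obs)) / (1 + n_sims)
  structure(list(F_obs = unname(F_obs), F_null = unname(F_null), p_phylo = p,
                 n_sims = n_sims, n = n, rate = rate, root = root),
            class = "cf_panova")
}

#' @export
print.cf_panova <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F = %.4g, p_phylo = %.4g (%d BM simulations, %d taxa)\n",
              x$F_obs, x$p_phylo, x$n_sims, x$n))
  invisible(x)
}

#' @rdname phylo_anova
#' @param x a `cf_panova`.
#' @param ... unused.
#' @export
#' @exportS3Method generics::glance
glance.cf_panova <- function(x, ...) {
  tibble(statistic = x$F_obs, p.value = x$p_phylo, n_sims = x$n_sims,
         n = x$n, bm_rate = x$rate, bm_root = x$root)
}
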