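test_that("read_newick parses small trees and validates input", {
  t2 <- read_newick(text = "(A:1,B:1);")
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(unname(diag(phylo_vcv(t2))), c(1, 1))

  t3 <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(max(ape::node.depth.edgelength(t3)), 2)

  expect_error(read_newick(text = "(A,B);"), "branch lengths")
  expect_error(read_newick(text = "(A:1,A:1);"), "duplicate")
})

test_that("trees round-trip through write/read preserving structure", {
  tree <- generate_tree(50, seed = 14)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, path)
  back <- read_newick(path)
  expect_true(ape::all.equal.phylo(tree, back, use.edge.length = TRUE,
                                   tolerance = 1e-8))
})

test_that("taxon substitution renames exactly the mapped tips", {
  tree <- read_newick(text = "((gracilior:1,microstoma:1):1,(other1:1.5,other2:1.5):0.5);")
  expect_equal(substitute_taxa(tree, c(gracilior = "gracilior"))$tip.label,
               tree$tip.label)
  sub <- substitute_taxa(tree, c(red_cheek = "gracilior",
                                 red_fin = "microstoma"))
  expect_equal(sum(sub$tip.label != tree$tip.label), 2)
  expect_setequal(setdiff(sub$tip.label, tree$tip.label),
                  c("red_cheek", "red_fin"))
  expect_equal(sub$edge.length, tree$edge.length)
  expect_error(substitute_taxa(tree, c(x = "absent_tip")), "available tips")
})

test_that("swapping two tip labels permutes the covariance matrix", {
  tree <- generate_tree(8, seed = 4)
  V <- phylo_vcv(tree)
  swapped <- tree
  swapped$tip.label[match(c("s1", "s5"), swapped$tip.label)] <- c("s5", "s1")
  V2 <- phylo_vcv(swapped)
  # after the label swap, looking up "s1" must return what "s5" held before
  swap <- rownames(V)
  names(swap) <- swap
  swap[c("s1", "s5")] <- c("s5", "s1")
  expect_equal(unname(V2[names(swap), names(swap)]),
               unname(V[swap, swap]))
  expect_equal(V2["s1", "s1"], V["s5", "s5"])
})

test_that("phylo_vcv reproduces MRCA-depth path arithmetic", {
  V2 <- phylo_vcv(read_newick(text = "(A:1,B:1);"))
  expect_equal(unname(V2), diag(2))
  V3 <- phylo_vcv(read_newick(text = "((A:1,B:1):1,C:2);"))
  expect_equal(unname(diag(V3)), rep(2, 3))
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(V3["B", "C"], 0)
})

test_that("phylo_vcv equals the ape oracle on random trees, incl. polytomies", {
  for (s in 1:5) {
    tree <- ape::rtree(12, rooted = TRUE)
    V <- phylo_vcv(tree)
    expect_equal(V, ape::vcv(tree)[rownames(V), colnames(V)], tolerance = 1e-12)
  }
  # polytomy
  poly <- read_newick(text = "((A:1,B:1,C:1):0.5,D:1.5);")
  expect_equal(phylo_vcv(poly), ape::vcv(poly)[LETTERS[1:4], LETTERS[1:4]])
})

test_that("phylo covariance matrices are symmetric PSD", {
  for (s in 1:10) {
    tree <- generate_tree(15, seed = 100 + s)
    V <- phylo_vcv(tree)
    expect_equal(V, t(V))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
    expect_true(all(V[upper.tri(V)] <= min(diag(V)) + 1e-12))
  }
})

test_that("lambda transform scales shared history only", {
  V <- phylo_vcv(read_newick(text = "((A:1,B:1):1,C:2);"))
  expect_equal(lambda_transform(V, 1), V)
  V0 <- lambda_transform(V, 0)
  expect_equal(unname(V0), diag(diag(V)))
  expect_equal(lambda_transform(V, 0.5)["A", "B"], 0.5)
  expect_equal(diag(lambda_transform(V, 0.5)), diag(V))
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
})

test_that("PGLS at lambda = 0 equals ordinary least squares", {
  tree <- generate_tree(12, seed = 31)
  d <- generate_traits(tree, slope = 1.5, noise_rate = 0.4, seed = 32)
  fit <- pgls_fit(d, y ~ x, tree, lambda = 0)
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$residuals), unname(stats::residuals(ols)),
               tolerance = 1e-10)
})

test_that("PGLS at lambda = 1 equals a dense-matrix GLS hand computation", {
  tree <- read_newick(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  d <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                      x = c(0.1, 0.4, 1.2, 2.0),
                      y = c(0.5, 0.8, 2.6, 4.4))
  fit <- pgls_fit(d, y ~ x, tree, lambda = 1)
  V <- ape::vcv(tree)[d$taxon, d$taxon]
  X <- cbind(1, d$x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-10)
  # ML log-likelihood from the explicit multivariate normal density
  r <- d$y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / 4
  ll <- -0.5 * (4 * log(2 * pi * s2) + log(det(V)) + 4)
  expect_equal(fit$logLik, ll, tolerance = 1e-8)
})

test_that("PGLS agrees with nlme::gls under a fixed-lambda correlation", {
  skip_if_not_installed("nlme")
  tree <- generate_tree(20, seed = 71)
  d <- generate_traits(tree, slope = 2, lambda_true = 1, noise_rate = 1,
                       seed = 72)
  fit <- pgls_fit(d, y ~ x, tree, lambda = 1)
  dd <- as.data.frame(d)
  rownames(dd) <- dd$taxon
  g <- nlme::gls(y ~ x, data = dd,
                 correlation = ape::corBrownian(1, tree, form = ~taxon),
                 method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("ML lambda is a genuine profile-likelihood maximum", {
  for (s in 1:5) {
    tree <- generate_tree(25, seed = 300 + s)
    d <- generate_traits(tree, slope = 2, lambda_true = runif(1),
                         noise_rate = 1, seed = 400 + s)
    fit <- pgls_fit(d, y ~ x, tree)
    expect_gte(fit$logLik, max(fit$logLik_bounds) - 1e-6)
    expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  }
})

test_that("PGLS recovers slope and lambda in a reduced simulation", {
  set.seed(510)
  tree <- generate_tree(30, seed = 510)
  fits <- purrr::map(1:40, function(i) {
    d <- generate_traits(tree, slope = 2, lambda_true = 1, noise_rate = 0.5,
                         seed = 1000 + i)
    f <- pgls_fit(d, y ~ x, tree)
    tibble::tibble(slope = f$coefficients[["x"]], lambda = f$lambda)
  }) |> purrr::list_rbind()
  se <- sd(fits$slope) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$slope) - 2), 2 * se + 1e-8)
  expect_gte(median(fits$lambda), 0.8)
})

test_that("pgls_fit rejects unusable designs", {
  tree <- generate_tree(6, seed = 2)
  d <- generate_traits(tree, seed = 3)
  expect_error(pgls_fit(d[1:3, ], y ~ x, ape::keep.tip(tree, d$taxon[1:3])),
               "at least 4")
  d$z <- d$x
  expect_error(pgls_fit(d, y ~ x + z, tree), "singular")
  expect_error(pgls_fit(dplyr::mutate(d, taxon = "nope"), y ~ x, tree),
               "absent|duplicate")
})

test_that("phylogenetic size correction recovers exact fits and deviations", {
  tree <- generate_tree(12, seed = 81)
  sl <- seq(3, 8, length.out = 12)
  d <- tibble::tibble(taxon = tree$tip.label, standard_length = sl,
                      eye_area = (0.5 + 0.3 * sl)^2)
  out <- phylo_size_correct(d, tree)
  expect_equal(out$residual_eye_area, rep(0, 12), tolerance = 1e-9)

  # shifting all standard lengths leaves the residual ranking unchanged
  set.seed(82)
  dev <- rnorm(12, 0, 0.2)
  d2 <- dplyr::mutate(d, eye_area = (0.5 + 0.3 * sl + dev)^2)
  r1 <- phylo_size_correct(d2, tree, lambda = 0)$residual_eye_area
  d3 <- dplyr::mutate(d2, standard_length = standard_length + 10)
  r2 <- phylo_size_correct(d3, tree, lambda = 0)$residual_eye_area
  expect_equal(order(r1), order(r2))
  # injected deviations recovered up to the fitted line (lambda = 0 = OLS)
  expect_equal(r1, unname(stats::residuals(lm(dev ~ sl))) , tolerance = 1e-9)

  expect_error(phylo_size_correct(
    dplyr::mutate(d, eye_area = dplyr::if_else(taxon == "s3", -1, eye_area)),
    tree), "s3")
})

test_that("simulate_bm matches its first and second moments", {
  tree <- generate_tree(5, seed = 61)
  expect_equal(unname(simulate_bm(tree, rate = 0, root_value = 3, n_sims = 4)),
               matrix(3, 5, 4))
  # 2-tip star: unit tip variance, zero cross-covariance
  star <- read_newick(text = "(A:1,B:1);")
  X <- simulate_bm(star, rate = 1, n_sims = 10000, seed = 62)
  S <- stats::cov(t(X))
  expect_equal(unname(diag(S)), c(1, 1), tolerance = 0.06)
  expect_lt(abs(S[1, 2]), 0.04)
  # 5-taxon tree: empirical covariance converges to rate * V entrywise
  X5 <- simulate_bm(tree, rate = 2.5, root_value = 1, n_sims = 10000, seed = 63)
  V <- phylo_vcv(tree)
  S5 <- stats::cov(t(X5))
  expect_equal(unname(S5), unname(2.5 * V), tolerance = 0.08)
  expect_equal(unname(rowMeans(X5)), rep(1, 5), tolerance = 0.08)
  # determinism
  expect_equal(simulate_bm(tree, n_sims = 3, seed = 9),
               simulate_bm(tree, n_sims = 3, seed = 9))
})

test_that("phylo_anova returns p = 1 for constant traits", {
  tree <- generate_tree(8, seed = 91)
  d <- tibble::tibble(taxon = tree$tip.label, trait = rep(2, 8),
                      grp = rep(c("a", "b"), 4))
  res <- phylo_anova(d, trait, grp, tree, n_sims = 99, seed = 92)
  expect_equal(res$F_obs, 0)
  expect_equal(res$p_phylo, 1)
})

test_that("phylo_anova p-value replays exactly from its seeded draws", {
  tree <- generate_tree(10, seed = 95)
  d <- generate_traits(tree, seed = 96)
  d$grp <- rep(c("a", "b"), 5)
  res <- phylo_anova(d, y, grp, tree, n_sims = 3, seed = 97)
  # manual replication: same rate/root estimates, same seeded draws, same F
  V <- phylo_vcv(tree)[d$taxon, d$taxon]
  Vi <- solve(V)
  one <- rep(1, 10)
  root <- as.numeric(solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% d$y))
  r <- d$y - root
  rate <- as.numeric(t(r) %*% Vi %*% r) / 10
  sims <- simulate_bm(ape::keep.tip(tree, d$taxon), rate = rate,
                      root_value = root, n_sims = 3, seed = 97)[d$taxon, ]
  f_of <- function(y) {
    a <- anova(lm(y ~ factor(d$grp)))
    a$`F value`[1]
  }
  F_null <- apply(sims, 2, f_of)
  F_obs <- f_of(d$y)
  expect_equal(res$F_obs, F_obs, tolerance = 1e-10)
  expect_equal(sort(res$F_null), sort(F_null), tolerance = 1e-10)
  expect_equal(res$p_phylo, (1 + sum(F_null >= F_obs)) / 4)
})

test_that("phylo_anova on a star tree approaches the classical ANOVA p", {
  star <- ape::stree(16, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$root.edge <- 0  # mark the basal polytomy as a true root
  set.seed(130)
  d <- tibble::tibble(taxon = star$tip.label, trait = rnorm(16),
                      grp = rep(c("a", "b"), each = 8))
  res <- phylo_anova(d, trait, grp, star, n_sims = 4000, seed = 131)
  classical <- one_way_anova(d, trait, grp)$p.value[1]
  expect_lt(abs(res$p_phylo - classical), 0.05)
})

test_that("phylo_anova validates groups and taxa", {
  tree <- generate_tree(6, seed = 1)
  d <- tibble::tibble(taxon = tree$tip.label, trait = rnorm(6),
                      grp = rep("a", 6))
  expect_error(phylo_anova(d, trait, grp, tree), ">= 2 groups")
  d$grp <- rep(c("a", "b"), 3)
  d$taxon[1] <- "missing_taxon"
  expect_error(phylo_anova(d, trait, grp, tree), "absent")
})
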