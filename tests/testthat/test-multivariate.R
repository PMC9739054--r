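# fit a small multi-trait trial and return the standardized matrix
fit_matrix <- function(traits = c("GY", "PHT", "SF", "HI"), seed = 4,
                       standardize = TRUE) {
  sim <- simulate_fieldbook(traits = traits,
                            grand_mean = c(4, 50, 60, 30)[seq_along(traits)],
                            genotype_sd = c(1.25, 12, 19, 7)[seq_along(traits)],
                            error_sd = c(0.15, 0.5, 1.7, 3)[seq_along(traits)],
                            seed = seed)
  fits <- lapply(traits, function(tr) augmented_rcbd(sim$fieldbook, tr))
  build_trait_matrix(fits, standardize = standardize)
}

test_that("standardization centres and scales every column", {
  m <- cbind(x = c(1, 3))
  rownames(m) <- c("a", "b")
  tm <- build_trait_matrix(data.frame(genotype = c("a", "b"), x = c(1, 3)))
  expect_equal(as.numeric(tm), c(-1, 1) / sqrt(2))
  expect_error(
    build_trait_matrix(data.frame(genotype = c("a", "b"), x = c(2, 2))),
    "constant")
  set.seed(14)
  for (i in 1:10) {
    d <- as.data.frame(matrix(rnorm(60), 10))
    d$genotype <- sprintf("g%d", 1:10)
    tm <- build_trait_matrix(d)
    expect_true(all(abs(colMeans(tm)) < 1e-9))
    expect_true(all(abs(apply(tm, 2, sd) - 1) < 1e-9))
  }
})

test_that("missing cells fail loudly or impute on request", {
  d <- data.frame(genotype = c("a", "b", "c"), x = c(1, NA, 3),
                  y = c(2, 1, 0))
  expect_error(build_trait_matrix(d), "genotype 'b', trait 'x'")
  tm <- build_trait_matrix(d, impute = "mean", standardize = FALSE)
  expect_equal(tm["b", "x"], 2)
})

test_that("two perfectly correlated traits load entirely on PC1", {
  d <- data.frame(genotype = sprintf("g%d", 1:6), x = 1:6,
                  y = 2 * (1:6) + 3)
  p <- trait_pca(build_trait_matrix(d), n_components = 1)
  expect_equal(p$proportion[1L], 100)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
})

test_that("eigenvalues match a brute-force eigen-solver", {
  set.seed(15)
  for (i in 1:10) {
    d <- as.data.frame(matrix(rnorm(60), 10, 6))
    d$genotype <- sprintf("g%d", 1:10)
    tm <- build_trait_matrix(d)
    p <- trait_pca(tm, n_components = 3)
    want <- eigen(cov(tm), symmetric = TRUE)$values
    expect_equal(p$eigenvalues, want, tolerance = 1e-8)
    # eigenvalues of a standardized matrix sum to the trait count
    expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-9)
    expect_lte(sum(p$proportion_retained), 100 + 1e-9)
    # squared cosines over all components sum to one
    pall <- trait_pca(tm, n_components = 6)
    expect_equal(unname(rowSums(pall$cos2)), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("scores are uncorrelated and the solution ignores row order", {
  tm <- fit_matrix()
  p <- trait_pca(tm, n_components = 2)
  sc <- cor(p$scores)
  expect_lt(max(abs(sc[upper.tri(sc)])), 1e-8)
  perm <- sample(nrow(tm))
  tmp <- tm[perm, ]
  attr(tmp, "standardized") <- TRUE
  class(tmp) <- class(tm)
  p2 <- trait_pca(tmp, n_components = 2)
  expect_equal(p2$eigenvalues, p$eigenvalues, tolerance = 1e-10)
  expect_equal(p2$loadings, p$loadings, tolerance = 1e-8)
  expect_equal(p2$scores[rownames(tm), ], p$scores, tolerance = 1e-8)
})

test_that("varimax rotation redistributes but preserves retained variance", {
  tm <- fit_matrix()
  p0 <- trait_pca(tm, n_components = 2)
  p1 <- trait_pca(tm, n_components = 2, rotation = "varimax")
  expect_equal(sum(p1$loadings^2), sum(p0$loadings^2), tolerance = 1e-9)
  expect_equal(sum(p1$eigenvalues_retained),
               sum(p0$eigenvalues_retained), tolerance = 1e-9)
  expect_identical(p1$rotation_applied, "varimax")
  # deterministic sign convention: dominant loading positive
  for (k in 1:2) {
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, k])), k], 0)
    expect_gt(p0$loadings[which.max(abs(p0$loadings[, k])), k], 0)
  }
})

test_that("pca rejects impossible component counts", {
  tm <- fit_matrix(traits = c("GY", "PHT"))
  expect_error(trait_pca(tm, n_components = 5), "n_components")
  raw <- fit_matrix(standardize = FALSE)
  expect_error(trait_pca(raw), "standardized")
})

test_that("correlations carry exact t-test p-values", {
  tm <- fit_matrix()
  cm <- trait_correlations(tm)
  expect_equal(diag(cm$r), rep(1, ncol(tm)), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1))
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(tm[, i], tm[, j])
    expect_equal(cm$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cm$p[i, j], ct$p.value, tolerance = 1e-12)
  }
  # antithetic pair
  d <- data.frame(genotype = sprintf("g%d", 1:5), x = 1:5, y = -(1:5))
  cm2 <- trait_correlations(build_trait_matrix(d))
  expect_equal(cm2$r[1, 2], -1)
  expect_true(cm2$significant[1, 2])
  expect_error(trait_correlations(tm[1:2, ]), "at least 3")
  holm <- trait_correlations(tm, adjust = "holm")
  expect_true(all(holm$p >= cm$p - 1e-15))
})

test_that("clustering recovers well-separated synthetic groups", {
  set.seed(16)
  m <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10))
  rownames(m) <- sprintf("g%d", 1:20)
  d <- data.frame(genotype = rownames(m), m)
  tc <- trait_clusters(build_trait_matrix(d), k = 2)
  expect_equal(length(unique(tc$assignments[1:10])), 1L)
  expect_equal(length(unique(tc$assignments[11:20])), 1L)
  expect_false(tc$assignments[1] == tc$assignments[11])
})

test_that("ward merge heights never decrease", {
  set.seed(17)
  for (i in 1:5) {
    d <- as.data.frame(matrix(rnorm(50), 10))
    d$genotype <- sprintf("g%d", 1:10)
    tc <- trait_clusters(build_trait_matrix(d), k = 3)
    expect_true(all(diff(tc$heights) >= -1e-12))
  }
})

test_that("degenerate cluster inputs are handled", {
  d <- data.frame(genotype = "only", x = 1, y = 2)
  tc <- trait_clusters(build_trait_matrix(d, standardize = FALSE), k = 1)
  expect_equal(tc$assignments, c(only = 1L))
  expect_length(tc$heights, 0L)
  tm <- fit_matrix()
  expect_error(trait_clusters(tm, k = 0), "k must")
  expect_error(trait_clusters(tm, k = 99), "k must")
})

test_that("ranking honours trait directions and dominance", {
  reg <- trait_registry(c("GY", "CWSI", "RCI"),
                        direction = c("higher_better", "lower_better",
                                      "lower_better"))
  m <- cbind(GY = c(9, 5, 7, 1), CWSI = c(0.2, 0.6, 0.4, 0.9),
             RCI = c(5, 20, 10, 40))
  rownames(m) <- c("best", "mid2", "mid1", "worst")
  rk <- rank_genotypes(m, reg, n_top = 1, n_low = 1)
  expect_equal(rk$genotype, c("best", "mid1", "mid2", "worst"))
  expect_equal(rk$final_rank, 1:4)
  expect_equal(rk$class, c("top", "intermediate", "intermediate", "low"))
  # brute-force composite on the same toy
  expect_equal(rk$composite,
               rowMeans(cbind(rank(-m[, 1]), rank(m[, 2]),
                              rank(m[, 3])))[rk$genotype],
               ignore_attr = TRUE)
})

test_that("ranking is invariant to positive rescaling and sign flips", {
  reg <- trait_registry(c("A", "B"),
                        direction = c("higher_better", "lower_better"))
  set.seed(18)
  m <- cbind(A = rnorm(8), B = rnorm(8))
  rownames(m) <- sprintf("g%d", 1:8)
  rk0 <- rank_genotypes(m, reg, n_top = 2, n_low = 2)
  m2 <- m; m2[, "A"] <- m2[, "A"] * 37.5
  expect_equal(rank_genotypes(m2, reg, n_top = 2, n_low = 2), rk0)
  # negating a lower_better trait and flipping its direction: same ranks
  reg2 <- trait_registry(c("A", "B"), direction = "higher_better")
  m3 <- m; m3[, "B"] <- -m3[, "B"]
  expect_equal(rank_genotypes(m3, reg2, n_top = 2, n_low = 2)$final_rank,
               rk0$final_rank)
  # missing direction is a configuration error
  expect_error(rank_genotypes(cbind(m, C = rnorm(8)), reg), "not in registry")
  # final ranks are always a permutation-with-ties
  expect_equal(sum(rk0$final_rank), sum(1:8))
})
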