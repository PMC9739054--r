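#' Build the standardized genotype-by-trait matrix
#'
#' Assembles adjusted genotype means into a genotypes x traits matrix and
#' z-standardizes each column (n-1 denominator), the input expected by the
#' multivariate screening layer.
#'
#' @param x either a named list of [augmented_rcbd()] fits (names become
#'   trait names; unnamed lists take each fit's trait) or a data frame
#'   with a `genotype` column and one numeric column per trait.
#' @param traits optional subset of traits to keep.
#' @param standardize z-standardize columns (default `TRUE`).
#' @param impute `"fail"` (default) stops on a missing cell naming
#'   genotype and trait; `"mean"` replaces it with the column mean.
#' @return A numeric matrix of class `"trait_matrix"` (genotype ids as row
#'   names) with attribute `standardized`.
#' @export
#' @examples
#' sim <- simulate_fieldbook(traits = c("GY", "PHT"), seed = 5)
#' fits <- lapply(c("GY", "PHT"), function(tr)
#'   augmented_rcbd(sim$fieldbook, tr))
#' tm <- build_trait_matrix(fits)
#' round(colMeans(tm), 12)
build_trait_matrix <- function(x, traits = NULL, standardize = TRUE,
                               impute = c("fail", "mean")) {
  impute <- match.arg(impute)
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1L), "augmented_rcbd"))) {
    nm <- names(x)
    if (is.null(nm) || any(!nzchar(nm)))
      nm <- vapply(x, `[[`, character(1L), "trait")
    genos <- sort(unique(unlist(lapply(x, function(f) f$means$genotype))))
    m <- matrix(NA_real_, length(genos), length(x),
                dimnames = list(genos, nm))
    for (k in seq_along(x)) {
      mk <- x[[k]]$means
      m[mk$genotype, k] <- mk$adjusted_mean
    }
  } else if (is.data.frame(x)) {
    if (!"genotype" %in% names(x))
      stop("data frame input needs a 'genotype' column", call. = FALSE)
    cols <- setdiff(names(x), "genotype")
    m <- as.matrix(x[cols])
    rownames(m) <- x$genotype
  } else {
    stop("x must be a list of augmented_rcbd fits or a data frame",
         call. = FALSE)
  }
  if (!is.null(traits)) m <- m[, traits, drop = FALSE]
  if (anyNA(m)) {
    if (impute == "fail") {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing cell: genotype '", rownames(m)[idx[1L]], "', trait '",
           colnames(m)[idx[2L]], "' (enable impute = \"mean\" to fill)",
           call. = FALSE)
    }
    for (k in seq_len(ncol(m)))
      m[is.na(m[, k]), k] <- mean(m[, k], na.rm = TRUE)
  }
  if (standardize) {
    sds <- apply(m, 2L, sd)
    if (any(sds == 0))
      stop("cannot standardize constant trait column(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  structure(m, standardized = standardize,
            class = c("trait_matrix", class(m)))
}

#' Principal component analysis of the trait matrix
#'
#' Eigen-decomposition of the correlation structure of the standardized
#' genotype-by-trait matrix.  Loadings are variable coordinates
#' (eigenvector times the square root of the eigenvalue, i.e. the
#' correlation of each trait with each component); the squared cosine of
#' each genotype measures how well the retained components represent it.
#' Component signs are fixed so that each loading column's
#' largest-magnitude entry is positive, making output reproducible across
#' linear-algebra backends.  Optionally the retained loadings are varimax-
#' rotated; rotation redistributes, but preserves, the retained variance.
#'
#' @param tm a [build_trait_matrix()] matrix (standardized).
#' @param n_components number of components to retain (default 2).
#' @param rotation `"none"` (default) or `"varimax"`.
#' @return An object of class `"trait_pca"`: list with `eigenvalues`,
#'   `proportion` and `cumulative` (percent), `loadings` (traits x
#'   retained components), `scores` (genotypes x retained components),
#'   `cos2` (per genotype, over retained components), and
#'   `rotation_applied`.
#' @export
#' @examples
#' sim <- simulate_fieldbook(traits = c("GY", "PHT", "SF"), seed = 9)
#' tm <- build_trait_matrix(lapply(c("GY", "PHT", "SF"), function(tr)
#'   augmented_rcbd(sim$fieldbook, tr)))
#' trait_pca(tm, n_components = 2)
trait_pca <- function(tm, n_components = 2,
                      rotation = c("none", "varimax")) {
  rotation <- match.arg(rotation)
  if (!isTRUE(attr(tm, "standardized")))
    stop("trait matrix must be standardized", call. = FALSE)
  p <- ncol(tm)
  if (n_components < 1L || n_components > p)
    stop("n_components must lie in [1, ", p, "]", call. = FALSE)
  pc <- prcomp(tm, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  if (n_components > sum(eig > 1e-12))
    stop("n_components exceeds the rank of the trait matrix", call. = FALSE)
  prop <- 100 * eig / sum(eig)

  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE] *
    rep(pc$sdev[keep], each = p)                 # variable coordinates
  scores_all <- pc$x
  scores <- scores_all[, keep, drop = FALSE]

  # deterministic sign: largest |loading| per column positive
  for (k in keep) {
    s <- sign(load[which.max(abs(load[, k])), k])
    if (s < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }

  if (rotation == "varimax" && n_components > 1L) {
    vr <- varimax(load, normalize = FALSE)
    std_scores <- scores %*% diag(1 / pc$sdev[keep], n_components)
    load <- load %*% vr$rotmat
    ssl <- colSums(load^2)
    # rotated scores: rotate the unit-variance scores, rescale so each
    # component's score variance equals its redistributed eigenvalue
    scores <- (std_scores %*% vr$rotmat) %*% diag(sqrt(ssl), n_components)
    # order rotated components by explained variance, re-fix signs
    o <- order(ssl, decreasing = TRUE)
    load <- load[, o, drop = FALSE]
    scores <- scores[, o, drop = FALSE]
    for (k in keep) {
      s <- sign(load[which.max(abs(load[, k])), k])
      if (s < 0) { load[, k] <- -load[, k]; scores[, k] <- -scores[, k] }
    }
    eig_ret <- colSums(load^2)
  } else {
    eig_ret <- eig[keep]
  }
  dimnames(load) <- list(colnames(tm), paste0("PC", keep))
  dimnames(scores) <- list(rownames(tm), paste0("PC", keep))

  d2 <- rowSums(scores_all^2)
  cos2 <- sweep(scores^2, 1L, d2, "/")

  structure(list(eigenvalues = eig,
                 eigenvalues_retained = as.numeric(eig_ret),
                 proportion = prop, cumulative = cumsum(prop),
                 proportion_retained = 100 * as.numeric(eig_ret) / sum(eig),
                 loadings = load, scores = scores, cos2 = cos2,
                 rotation_applied = rotation, n_components = n_components),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  cat("Trait PCA (", x$n_components, " retained component(s), rotation: ",
      x$rotation_applied, ")\n", sep = "")
  tab <- rbind(`Explained variance (eigenvalue)` = x$eigenvalues_retained,
               `Proportion of total variance (%)` = x$proportion_retained,
               `Cumulative (%)` = cumsum(x$proportion_retained))
  colnames(tab) <- colnames(x$loadings)
  cat("\nLoadings:\n")
  print(round(x$loadings, digits))
  cat("\n")
  print(round(tab, digits))
  invisible(x)
}

#' Pairwise trait correlations with significance mask
#'
#' Pearson correlations between trait columns with two-sided p-values from
#' the exact t transform `t = r sqrt((n-2)/(1-r^2))`; the mask marks
#' pairs significant at `alpha`.  No multiplicity correction is applied by
#' default; `adjust = "holm"` is available.
#'
#' @param tm a [build_trait_matrix()] matrix (or any numeric matrix with
#'   >= 3 rows).
#' @param alpha significance level for the mask.
#' @param adjust p-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method).
#' @return A list of class `"trait_correlations"` with `r`, `p`,
#'   `significant` (logical matrix) and `alpha`.
#' @export
trait_correlations <- function(tm, alpha = 0.05, adjust = "none") {
  n <- nrow(tm)
  if (n < 3L) stop("need at least 3 genotypes", call. = FALSE)
  sds <- apply(tm, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance trait(s): correlation undefined for ",
         paste(colnames(tm)[sds == 0], collapse = ", "), call. = FALSE)
  r <- cor(tm)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  if (adjust != "none") {
    lower <- lower.tri(p)
    p[lower] <- p.adjust(p[lower], method = adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  structure(list(r = r, p = p, significant = p < alpha, alpha = alpha),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (mask at alpha = ", x$alpha, ")\n",
      sep = "")
  disp <- round(x$r, digits)
  disp[!x$significant] <- NA
  print(disp, na.print = ".")
  invisible(x)
}

#' Hierarchical clustering of genotypes
#'
#' Agglomerative clustering on Euclidean distances between standardized
#' genotype rows.  Ward linkage (`hclust` method `ward.D2`, on distances)
#' is the default; the cut at `k` gives cluster assignments.
#'
#' @param tm a [build_trait_matrix()] matrix.
#' @param k number of clusters for the cut (default 3).
#' @param linkage `"ward"`, `"complete"` or `"average"`.
#' @return A list of class `"trait_clusters"` with `hclust` (the merge
#'   tree), `heights`, `assignments` (named integer vector) and `k`.
#' @export
trait_clusters <- function(tm, k = 3, linkage = c("ward", "complete",
                                                  "average")) {
  linkage <- match.arg(linkage)
  n <- nrow(tm)
  if (k < 1L || k > n)
    stop("k must lie in [1, ", n, "]", call. = FALSE)
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average")[[linkage]]
  if (n == 1L)
    return(structure(list(hclust = NULL, heights = numeric(0),
                          assignments = setNames(1L, rownames(tm)), k = 1L,
                          linkage = linkage),
                     class = "trait_clusters"))
  hc <- hclust(dist(tm), method = method)
  structure(list(hclust = hc, heights = hc$height,
                 assignments = cutree(hc, k = k), k = k,
                 linkage = linkage),
            class = "trait_clusters")
}

#' @export
print.trait_clusters <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage), cut at k = ",
      x$k, "\n", sep = "")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' @export
plot.trait_clusters <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", cex = 0.6,
       main = "Genotype dendrogram", ...)
  invisible(x)
}

#' Composite rank-sum screening of genotypes
#'
#' Ranks genotypes per trait so that rank 1 is the most favourable value
#' according to the trait's registered selection direction, averages the
#' per-trait ranks (optionally weighted) into a composite score, and
#' classifies the best `n_top` genotypes as `"top"` and the worst `n_low`
#' as `"low"`.  Ties take average ranks, so the result is invariant to
#' positive rescaling of any trait.
#'
#' @param x a numeric genotype-by-trait matrix (e.g. unstandardized
#'   adjusted means from [build_trait_matrix()] with
#'   `standardize = FALSE`) or a data frame with a `genotype` column.
#' @param registry a [trait_registry()] providing a direction for every
#'   ranked trait.
#' @param weights optional named numeric vector of trait weights.
#' @param n_top,n_low sizes of the top and low tolerance classes
#'   (defaults 10 and 5).
#' @return A data frame of class `"genotype_ranking"`: per-trait ranks,
#'   `composite`, `final_rank`, `class`.
#' @export
#' @examples
#' reg <- trait_registry(c("GY", "CWSI"), direction =
#'   c("higher_better", "lower_better"))
#' m <- cbind(GY = c(5, 3, 4), CWSI = c(0.4, 0.9, 0.5))
#' rownames(m) <- c("A", "B", "C")
#' rank_genotypes(m, reg, n_top = 1, n_low = 1)
rank_genotypes <- function(x, registry, weights = NULL, n_top = 10,
                           n_low = 5) {
  if (is.data.frame(x)) {
    if (!"genotype" %in% names(x))
      stop("data frame input needs a 'genotype' column", call. = FALSE)
    m <- as.matrix(x[setdiff(names(x), "genotype")])
    rownames(m) <- x$genotype
  } else m <- as.matrix(x)
  stopifnot(inherits(registry, "trait_registry"))
  dirs <- trait_direction(registry, colnames(m))
  n <- nrow(m)
  ranks <- m
  for (k in seq_len(ncol(m))) {
    v <- if (dirs[k] == "higher_better") -m[, k] else m[, k]
    ranks[, k] <- rank(v, ties.method = "average")
  }
  if (is.null(weights)) {
    weights <- rep(1, ncol(m))
  } else {
    weights <- weights[colnames(m)]
    if (anyNA(weights))
      stop("weights must be named for every ranked trait", call. = FALSE)
  }
  composite <- as.numeric(ranks %*% weights) / sum(weights)
  final <- rank(composite, ties.method = "average")
  cls <- rep("intermediate", n)
  cls[final <= n_top] <- "top"
  cls[final > n - n_low] <- "low"
  out <- data.frame(genotype = rownames(m), ranks, composite = composite,
                    final_rank = final, class = cls,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$final_rank), ]
  rownames(out) <- NULL
  class(out) <- c("genotype_ranking", "data.frame")
  out
}

#' @export
print.genotype_ranking <- function(x, ...) {
  cat("Composite rank-sum screening of", nrow(x), "genotypes\n")
  print.data.frame(head(as.data.frame(x), 15L), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 15L) cat("...", nrow(x) - 15L, "more rows\n")
  invisible(x)
}
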