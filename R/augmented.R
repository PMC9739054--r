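#' Fit the augmented randomized complete block analysis for one trait
#'
#' Implements the classical check-based analysis of an augmented RCBD:
#' block effects are estimated from the replicated checks, test genotypes
#' are adjusted by their block's effect, and the total sum of squares is
#' partitioned into Block (ignoring genotypes), Genotype (eliminating
#' blocks) -- itself split into a Check row and a combined Test +
#' Test-vs-Check row -- and a check-only Residual with `(b-1)(c-1)` degrees
#' of freedom.  Standard errors for the four comparison classes of the
#' design accompany the table.
#'
#' Checks must be observed in every block; a test genotype with a missing
#' value is dropped for the trait with a warning, a check with a missing
#' value is an error because block effects depend on it.
#'
#' @param fb a [fieldbook()].
#' @param trait name of the trait column to analyse.
#' @param alpha significance level used for critical differences.
#'
#' @return An object of class `"augmented_rcbd"`: a list with components
#'   `trait`, `data` (rows used), `grand_mean` (mean of adjusted means),
#'   `block_effects`, `means` (per-genotype adjusted-mean table), `anova`
#'   (five-source table), `anova_dual` (the ignoring/eliminating dual),
#'   `test_split` (among-test and test-vs-check split of the combined row),
#'   `errors` (comparison standard errors and critical differences), and
#'   the design sizes `b`, `c`, `t`.
#' @seealso [estimate_block_effects()], [adjust_means()],
#'   [comparison_errors()], [variability()].
#' @export
#' @examples
#' sim <- simulate_fieldbook(seed = 42)
#' fit <- augmented_rcbd(sim$fieldbook, "GY")
#' fit
#' summary(fit)
#' head(coef(fit))
augmented_rcbd <- function(fb, trait, alpha = 0.05) {
  stopifnot(inherits(fb, "fieldbook"))
  if (!trait %in% fieldbook_traits(fb))
    stop("trait '", trait, "' not present in field book", call. = FALSE)
  validate_fieldbook(fb)

  d <- as.data.frame(fb)[c("genotype", "block", "is_check", trait)]
  names(d)[4L] <- "y"

  # missing-value policy: drop tests, refuse missing checks
  if (anyNA(d$y)) {
    miss <- d[is.na(d$y), , drop = FALSE]
    if (any(miss$is_check))
      stop("check '", miss$genotype[miss$is_check][1L],
           "' has a missing value for trait '", trait,
           "'; block effects are not estimable", call. = FALSE)
    warning("dropping ", nrow(miss), " test plot(s) with missing '",
            trait, "'", call. = FALSE)
    d <- d[!is.na(d$y), , drop = FALSE]
  }

  blocks <- sort(unique(d$block))
  checks <- sort(unique(d$genotype[d$is_check]))
  tests <- sort(unique(d$genotype[!d$is_check]))
  b <- length(blocks); cch <- length(checks); tt <- length(tests)
  if (b < 2L || cch < 2L)
    stop("augmented analysis needs at least 2 blocks and 2 checks",
         call. = FALSE)
  chk <- d[d$is_check, , drop = FALSE]
  got <- table(factor(chk$genotype, checks), factor(chk$block, blocks))
  if (any(got != 1L)) {
    bad <- which(got != 1L, arr.ind = TRUE)[1L, ]
    stop("incomplete design: check '", checks[bad[1L]],
         "' missing from block '", blocks[bad[2L]], "'", call. = FALSE)
  }

  ## block effects from checks
  check_block_mean <- tapply(chk$y, factor(chk$block, blocks), mean)
  check_grand <- mean(chk$y)
  beff <- check_block_mean - check_grand      # sums to zero

  ## adjusted means
  check_mean <- tapply(chk$y, factor(chk$genotype, checks), mean)
  tst <- d[!d$is_check, , drop = FALSE]
  means <- rbind(
    data.frame(genotype = checks, source = "check", block = NA_character_,
               raw_mean = as.numeric(check_mean),
               block_adjustment = 0,
               adjusted_mean = as.numeric(check_mean),
               stringsAsFactors = FALSE),
    if (nrow(tst)) data.frame(genotype = tst$genotype, source = "test",
                              block = tst$block, raw_mean = tst$y,
                              block_adjustment = -as.numeric(beff[tst$block]),
                              adjusted_mean = tst$y -
                                as.numeric(beff[tst$block]),
                              stringsAsFactors = FALSE))
  rownames(means) <- NULL

  ## ANOVA partition
  N <- nrow(d)
  ybar <- mean(d$y)
  ss_total <- sum((d$y - ybar)^2)

  # check-only two-way residual
  rmat <- matrix(chk$y[order(match(chk$genotype, checks),
                             match(chk$block, blocks))],
                 nrow = cch, ncol = b, byrow = TRUE)
  ss_res <- sum((rmat - rowMeans(rmat) -
                   rep(colMeans(rmat), each = cch) + mean(rmat))^2)
  df_res <- (b - 1L) * (cch - 1L)

  # blocks ignoring genotypes (unequal block sizes allowed)
  bsum <- tapply(d$y, factor(d$block, blocks), sum)
  bn <- tapply(d$y, factor(d$block, blocks), length)
  ss_block_ign <- sum(bsum^2 / bn) - sum(d$y)^2 / N

  # genotypes eliminating blocks, by subtraction
  ss_geno_elim <- ss_total - ss_block_ign - ss_res

  # dual convention: genotypes ignoring blocks / blocks eliminating genotypes
  gsum <- tapply(d$y, d$genotype, sum)
  gn <- tapply(d$y, d$genotype, length)
  ss_geno_ign <- sum(gsum^2 / gn) - sum(d$y)^2 / N
  ss_block_elim <- ss_total - ss_geno_ign - ss_res

  # check row (balanced over blocks) and combined test row by subtraction
  ss_check <- b * sum((check_mean - mean(check_mean))^2)
  ss_test_combined <- ss_geno_elim - ss_check

  # internal split of the combined row: among adjusted tests + remainder
  adj_t <- means$adjusted_mean[means$source == "test"]
  ss_among_tests <- if (tt > 1L) sum((adj_t - mean(adj_t))^2) else 0
  ss_test_vs_check <- ss_test_combined - ss_among_tests

  df <- c(b - 1L, cch + tt - 1L, cch - 1L, tt, df_res)
  ss <- c(ss_block_ign, ss_geno_elim, ss_check, ss_test_combined, ss_res)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  mse <- ms[5L]
  fv <- c(ms[1:4] / mse, NA_real_)
  pv <- c(pf(fv[1:4], df[1:4], df_res, lower.tail = FALSE), NA_real_)
  tab <- data.frame(
    source = c("Block (ignoring genotypes)",
               "Genotype (eliminating blocks)", "Check",
               "Test and Test vs. Check", "Residuals"),
    df = df, sum_sq = ss, mean_sq = ms, f_value = fv, p_value = pv,
    stringsAsFactors = FALSE)

  dual <- data.frame(
    source = c("Genotype (ignoring blocks)",
               "Block (eliminating genotypes)"),
    df = c(cch + tt - 1L, b - 1L),
    sum_sq = c(ss_geno_ign, ss_block_elim),
    stringsAsFactors = FALSE)

  errs <- comparison_errors(mse, df_res, b = b, c = cch, alpha = alpha)

  structure(list(trait = trait, data = d,
                 grand_mean = mean(means$adjusted_mean),
                 block_effects = setNames(as.numeric(beff), blocks),
                 means = means, anova = tab, anova_dual = dual,
                 test_split = c(among_tests = ss_among_tests,
                                test_vs_check = ss_test_vs_check),
                 errors = errs, b = b, c = cch, t = tt, alpha = alpha,
                 call = match.call()),
            class = "augmented_rcbd")
}

#' Estimate block effects from the replicated checks
#'
#' The effect of a block is the mean of its check observations minus the
#' grand mean of all check observations; effects sum to zero.
#'
#' @inheritParams augmented_rcbd
#' @return Named numeric vector of block effects.
#' @export
#' @examples
#' fb <- fieldbook(genotype = rep(c("C1", "C2"), 2),
#'                 block = rep(c("B1", "B2"), each = 2),
#'                 is_check = TRUE, GY = c(10, 12, 14, 16))
#' estimate_block_effects(fb, "GY")   # -2, +2
estimate_block_effects <- function(fb, trait) {
  augmented_rcbd(fb, trait)$block_effects
}

#' Adjusted genotype means for one trait
#'
#' Test genotypes are adjusted by subtracting their block's estimated
#' effect; check genotypes take the unadjusted mean over their replicates.
#'
#' @inheritParams augmented_rcbd
#' @return Data frame with columns `genotype`, `source`, `block`,
#'   `raw_mean`, `block_adjustment`, `adjusted_mean`.
#' @export
adjust_means <- function(fb, trait) {
  augmented_rcbd(fb, trait)$means
}

#' Standard errors for the four comparison classes of an augmented RCBD
#'
#' @param mse residual (error) mean square.
#' @param df_resid residual degrees of freedom.
#' @param b number of blocks.
#' @param c number of checks.
#' @param alpha significance level for the critical differences.
#' @return Data frame with one row per comparison class (`check_vs_check`,
#'   `test_same_block`, `test_diff_block`, `test_vs_check`) and columns
#'   `se` and `cd` (critical difference at `alpha`).
#' @export
#' @examples
#' comparison_errors(1, 12, b = 4, c = 5)
comparison_errors <- function(mse, df_resid, b, c, alpha = 0.05) {
  .check_scalar(mse, "mse", 0)
  if (df_resid < 1L)
    stop("residual degrees of freedom must be >= 1; comparison errors ",
         "are undefined", call. = FALSE)
  se <- c(check_vs_check = sqrt(2 * mse / b),
          test_same_block = sqrt(2 * mse),
          test_diff_block = sqrt(2 * mse * (1 + 1 / c)),
          test_vs_check = sqrt(mse * (1 + 1 / b + 1 / c + 1 / (b * c))))
  tcrit <- qt(1 - alpha / 2, df_resid)
  data.frame(comparison = names(se), se = as.numeric(se),
             cd = as.numeric(tcrit * se), row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.augmented_rcbd <- function(x, ...) {
  cat("Augmented RCBD fit for trait '", x$trait, "'\n", sep = "")
  cat("Design: ", x$b, " blocks, ", x$c, " checks, ", x$t,
      " test genotypes (N = ", nrow(x$data), ")\n", sep = "")
  cat("Grand mean of adjusted means:", format(x$grand_mean, digits = 5), "\n")
  cat("Block effects:\n")
  print(round(x$block_effects, 4))
  invisible(x)
}

#' @export
summary.augmented_rcbd <- function(object, ...) {
  structure(list(fit = object), class = "summary.augmented_rcbd")
}

#' @export
print.summary.augmented_rcbd <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAnalysis of variance:\n")
  tab <- fit$anova
  tab$stars <- ifelse(is.na(tab$p_value), "",
                      ifelse(tab$p_value < 0.01, "**",
                             ifelse(tab$p_value < 0.05, "*", "ns")))
  print(data.frame(tab[1L], lapply(tab[2:6], function(z)
    ifelse(is.na(z), "", format(round(z, 4)))), stars = tab$stars),
    row.names = FALSE)
  cat("\nComparison standard errors (alpha = ", fit$alpha, "):\n", sep = "")
  print(fit$errors, row.names = FALSE)
  invisible(x)
}

#' @export
anova.augmented_rcbd <- function(object, ...) object$anova

#' @export
coef.augmented_rcbd <- function(object, ...) {
  setNames(object$means$adjusted_mean, object$means$genotype)
}

#' @export
fitted.augmented_rcbd <- function(object, ...) {
  d <- object$data
  adj <- coef(object)
  # tests are saturated (fitted = observed); checks: mean + block effect
  ifelse(d$is_check,
         adj[d$genotype] + object$block_effects[d$block],
         d$y)
}

#' @export
residuals.augmented_rcbd <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Predict adjusted genotype values
#'
#' Without `newdata`, returns fitted values.  With `newdata` (a data frame
#' with a `genotype` column and optionally a `block` column), returns the
#' adjusted mean of each genotype, plus the estimated block effect when a
#' block is supplied.
#'
#' @param object an [augmented_rcbd()] fit.
#' @param newdata optional data frame.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.augmented_rcbd <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (!"genotype" %in% names(newdata))
    stop("newdata must contain a 'genotype' column", call. = FALSE)
  adj <- coef(object)
  unknown <- setdiff(newdata$genotype, names(adj))
  if (length(unknown))
    stop("unknown genotype(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- adj[as.character(newdata$genotype)]
  if ("block" %in% names(newdata)) {
    be <- object$block_effects[as.character(newdata$block)]
    be[is.na(be)] <- 0
    out <- out + be
  }
  unname(out)
}

#' Simulate trait vectors from a fitted augmented RCBD
#'
#' Parametric simulation: each simulated observation is the fitted value
#' for its plot (for checks, adjusted mean plus block effect; tests are
#' reproduced at their adjusted mean plus block effect) plus Gaussian
#' error at the residual mean square.
#'
#' @param object an [augmented_rcbd()] fit.
#' @param nsim number of simulated trait vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Data frame with `nsim` columns, one row per plot of the fit.
#' @export
simulate.augmented_rcbd <- function(object, nsim = 1, seed = NULL, ...) {
  mse <- object$anova$mean_sq[object$anova$source == "Residuals"]
  adj <- coef(object)
  d <- object$data
  mu <- adj[d$genotype] + object$block_effects[d$block]
  .with_seed(seed, {
    out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0,
                                                    sqrt(mse))))
    names(out) <- paste0("sim_", seq_len(nsim))
    rownames(out) <- NULL
    out
  })
}

#' Plot adjusted genotype means
#'
#' Dot chart of adjusted means, checks highlighted, with the grand mean as
#' a reference line.
#'
#' @param x an [augmented_rcbd()] fit.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.augmented_rcbd <- function(x, ...) {
  m <- x$means[order(x$means$adjusted_mean), ]
  dotchart(m$adjusted_mean, labels = m$genotype,
           pch = ifelse(m$source == "check", 19, 1),
           xlab = paste("adjusted mean of", x$trait),
           main = paste("Augmented RCBD:", x$trait), cex = 0.6, ...)
  abline(v = x$grand_mean, lty = 2)
  invisible(x)
}
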