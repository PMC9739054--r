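#' Variance components from an augmented-design fit
#'
#' The environmental variance `EV` is the residual (check) mean square.
#' With `method = "means"` (default) the phenotypic variance `PV` is the
#' variance of the adjusted genotype means and `GV = PV - EV`; with
#' `method = "ms"` the genotypic variance is the adjusted Genotype mean
#' square minus `EV` and `PV = GV + EV`.  In both cases a negative `GV` is
#' truncated at zero (a known artifact of unreplicated designs) with a
#' diagnostic message, and `PV` is re-derived as `GV + EV` so the identity
#' `PV = GV + EV` holds exactly.
#'
#' @param fit an [augmented_rcbd()] fit.
#' @param method `"means"` (variance of adjusted means) or `"ms"`
#'   (mean-square based).
#' @return A list with `PV`, `GV`, `EV` and `mean` (mean of adjusted
#'   means, the denominator used by coefficients of variation).
#' @export
#' @examples
#' sim <- simulate_fieldbook(seed = 7)
#' variance_components(augmented_rcbd(sim$fieldbook, "GY"))
variance_components <- function(fit, method = c("means", "ms")) {
  stopifnot(inherits(fit, "augmented_rcbd"))
  method <- match.arg(method)
  ev <- fit$anova$mean_sq[fit$anova$source == "Residuals"]
  gv <- if (method == "means") {
    var(fit$means$adjusted_mean) - ev
  } else {
    fit$anova$mean_sq[fit$anova$source ==
                        "Genotype (eliminating blocks)"] - ev
  }
  if (gv < 0) {
    message("genotypic variance estimate negative (", format(gv, digits = 4),
            "); truncated at 0")
    gv <- 0
  }
  list(PV = gv + ev, GV = gv, EV = ev, mean = fit$grand_mean)
}

# category bounds applied half-open: [0, b1) low, [b1, b2) medium,
# [b2, Inf) high -- boundary values go to the higher category
.cv_category <- function(x, bounds) {
  ifelse(x < bounds[1L], "low", ifelse(x < bounds[2L], "medium", "high"))
}

#' Coefficients of variation with breeder categories
#'
#' Computes the genotypic, phenotypic and environmental coefficients of
#' variation, `100 * sqrt(V) / mean`, and classifies GCV and PCV as low,
#' medium or high against `bounds` (default `[0,10)` low, `[10,20)`
#' medium, `>= 20` high; boundary values fall in the higher category).
#'
#' @param components list with `PV`, `GV`, `EV` as returned by
#'   [variance_components()].
#' @param mean trait mean (must be positive).
#' @param bounds strictly increasing pair of category bounds, percent.
#' @return A list with `GCV`, `PCV`, `ECV` (percent) and
#'   `gcv_category`, `pcv_category`.
#' @export
coefficients_of_variation <- function(components, mean,
                                      bounds = c(10, 20)) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0)
    stop("coefficient of variation undefined: mean must be positive",
         call. = FALSE)
  if (length(bounds) != 2L || diff(bounds) <= 0)
    stop("bounds must be a strictly increasing pair", call. = FALSE)
  gcv <- 100 * sqrt(components$GV) / mean
  pcv <- 100 * sqrt(components$PV) / mean
  ecv <- 100 * sqrt(components$EV) / mean
  list(GCV = gcv, PCV = pcv, ECV = ecv,
       gcv_category = .cv_category(gcv, bounds),
       pcv_category = .cv_category(pcv, bounds))
}

#' Broad-sense heritability and genetic advance
#'
#' `h2 = GV / PV`; the expected gain from selecting the best fraction at
#' intensity `k` is `GA = k * sqrt(PV) * h2`, and `GAM = 100 * GA / mean`
#' expresses it as a percent of the trait mean.  The default
#' `k = 2.063` corresponds to 5% selection.
#'
#' @inheritParams coefficients_of_variation
#' @param k standardized selection intensity (default 2.063, 5% selection).
#' @return A list with `h2`, `GA` (trait units), `GAM` (percent) and
#'   `gam_category` (same bounds as the coefficients of variation).
#' @export
#' @examples
#' genetic_advance(list(PV = 1.54, GV = 1.52), mean = 4, k = 2.063)
genetic_advance <- function(components, mean = NA_real_, k = 2.063,
                            bounds = c(10, 20)) {
  .check_scalar(k, "k", 0, strict = TRUE)
  pv <- components$PV; gv <- components$GV
  if (pv < 0 || gv < 0 || gv > pv)
    stop("need 0 <= GV <= PV", call. = FALSE)
  if (pv == 0) {
    warning("PV = 0; genetic advance set to 0", call. = FALSE)
    return(list(h2 = NA_real_, GA = 0, GAM = 0, gam_category = "low"))
  }
  h2 <- gv / pv
  ga <- k * sqrt(pv) * h2
  gam <- if (is.finite(mean) && mean > 0) 100 * ga / mean else NA_real_
  list(h2 = h2, GA = ga, GAM = gam,
       gam_category = if (is.na(gam)) NA_character_
       else .cv_category(gam, bounds))
}

#' Per-trait genetic-variability report
#'
#' Fits the augmented-design analysis for each requested trait and tabulates
#' variance components, coefficients of variation with categories,
#' broad-sense heritability, genetic advance and GA as percent of mean.
#'
#' @param fb a [fieldbook()].
#' @param traits traits to report (default all trait columns).
#' @param k selection intensity (default 2.063, 5% selection).
#' @param method variance-component estimator, see [variance_components()].
#' @param bounds category bounds for CVs and GAM.
#' @return A data frame of class `"variability_report"` with one row per
#'   trait and columns `trait`, `mean`, `PV`, `GV`, `EV`, `GCV`,
#'   `gcv_category`, `PCV`, `pcv_category`, `ECV`, `h2`, `GA`, `GAM`,
#'   `gam_category`.
#' @export
#' @examples
#' sim <- simulate_fieldbook(traits = c("GY", "PHT"),
#'                           grand_mean = c(4, 50),
#'                           genotype_sd = c(1.25, 12),
#'                           error_sd = c(0.15, 0.6), seed = 3)
#' variability(sim$fieldbook)
variability <- function(fb, traits = NULL, k = 2.063,
                        method = c("means", "ms"), bounds = c(10, 20)) {
  stopifnot(inherits(fb, "fieldbook"))
  method <- match.arg(method)
  if (is.null(traits)) traits <- fieldbook_traits(fb)
  rows <- lapply(traits, function(tr) {
    fit <- augmented_rcbd(fb, tr)
    vc <- variance_components(fit, method = method)
    cv <- coefficients_of_variation(vc, vc$mean, bounds = bounds)
    ga <- genetic_advance(vc, vc$mean, k = k, bounds = bounds)
    data.frame(trait = tr, mean = vc$mean, PV = vc$PV, GV = vc$GV,
               EV = vc$EV, GCV = cv$GCV, gcv_category = cv$gcv_category,
               PCV = cv$PCV, pcv_category = cv$pcv_category, ECV = cv$ECV,
               h2 = ga$h2, GA = ga$GA, GAM = ga$GAM,
               gam_category = ga$gam_category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variability_report", "data.frame")
  out
}

#' @export
print.variability_report <- function(x, digits = 3, ...) {
  cat("Genetic variability report (", nrow(x), " trait(s))\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], function(z) signif(z, digits))
  print(y, row.names = FALSE)
  invisible(x)
}
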