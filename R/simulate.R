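#' Simulate an augmented-design field book with known ground truth
#'
#' Generates a trial laid out like the wheat screening design it emulates:
#' `n_checks` replicated check genotypes in each of `n_blocks` blocks and
#' `n_tests` unreplicated test genotypes assigned to blocks round-robin in
#' id order.  Each observation is
#' `grand_mean + genotype effect + block effect + Gaussian error`, so every
#' downstream estimator can be tested against the returned truth.
#'
#' Defaults emulate a 46-genotype trial (5 checks x 4 blocks + 41 tests)
#' on a grain-yield-like scale (mean about 4 g per plant, strong genotypic
#' signal relative to plot error).
#'
#' @param n_blocks number of blocks (default 4).
#' @param n_checks number of replicated checks (default 5).
#' @param n_tests number of unreplicated test genotypes (default 41).
#' @param traits character vector of trait names to simulate.
#' @param grand_mean overall mean per trait (recycled).
#' @param genotype_sd standard deviation of random genotype effects per
#'   trait (recycled); ignored for traits given in `genotype_effects`.
#' @param error_sd plot-error standard deviation per trait (recycled).
#' @param block_effects optional numeric vector of length `n_blocks`
#'   (must sum to zero); drawn from `N(0, block_sd)` and centred otherwise.
#' @param block_sd standard deviation for generated block effects.
#' @param genotype_effects optional matrix (genotype x trait) of fixed
#'   genotype effects; rows named by genotype id.
#' @param treatment treatment label stored in the field book.
#' @param seed optional integer seed.
#'
#' @return A list with elements `fieldbook` (a [fieldbook()]) and `truth`
#'   (list with `grand_mean`, `genotype_effects` matrix, `block_effects`,
#'   `error_sd` per trait).
#' @export
#' @examples
#' sim <- simulate_fieldbook(seed = 1)
#' sim$fieldbook
simulate_fieldbook <- function(n_blocks = 4, n_checks = 5, n_tests = 41,
                               traits = "GY", grand_mean = 4,
                               genotype_sd = 1.25, error_sd = 0.15,
                               block_effects = NULL, block_sd = 0.35,
                               genotype_effects = NULL, treatment = "DS",
                               seed = NULL) {
  .check_scalar(n_blocks, "n_blocks", 1)
  .check_scalar(n_checks, "n_checks", 1)
  .check_scalar(n_tests, "n_tests", 0)
  ntr <- length(traits)
  grand_mean <- rep_len(grand_mean, ntr)
  genotype_sd <- rep_len(genotype_sd, ntr)
  error_sd <- rep_len(error_sd, ntr)
  if (any(error_sd < 0)) stop("error_sd must be >= 0", call. = FALSE)
  if (any(genotype_sd < 0)) stop("genotype_sd must be >= 0", call. = FALSE)

  checks <- sprintf("CHK%d", seq_len(n_checks))
  tests <- sprintf("T%02d", seq_len(n_tests))
  blocks <- sprintf("B%d", seq_len(n_blocks))

  .with_seed(seed, {
    if (is.null(block_effects)) {
      block_effects <- rnorm(n_blocks, 0, block_sd)
      block_effects <- block_effects - mean(block_effects)
    } else {
      if (length(block_effects) != n_blocks)
        stop("block_effects must have length n_blocks", call. = FALSE)
      if (abs(sum(block_effects)) > 1e-8)
        stop("block_effects must sum to zero", call. = FALSE)
    }
    names(block_effects) <- blocks

    geno <- c(checks, tests)
    eff <- matrix(rnorm(length(geno) * ntr) * rep(genotype_sd,
                                                  each = length(geno)),
                  nrow = length(geno), ncol = ntr,
                  dimnames = list(geno, traits))
    if (!is.null(genotype_effects)) {
      ge <- as.matrix(genotype_effects)
      eff[rownames(ge), colnames(ge)] <- ge
    }

    # layout: all checks in every block, tests dealt round-robin in id order
    g_col <- c(rep(checks, times = n_blocks),
               tests)
    b_col <- c(rep(blocks, each = n_checks),
               blocks[((seq_len(n_tests) - 1L) %% n_blocks) + 1L])
    chk_col <- c(rep(TRUE, n_checks * n_blocks), rep(FALSE, n_tests))

    obs <- lapply(seq_len(ntr), function(k) {
      grand_mean[k] + eff[g_col, k] + block_effects[b_col] +
        rnorm(length(g_col), 0, error_sd[k])
    })
    names(obs) <- traits

    fb <- do.call(fieldbook,
                  c(list(genotype = g_col, block = b_col, is_check = chk_col,
                         treatment = treatment), obs))
    list(fieldbook = fb,
         truth = list(grand_mean = setNames(grand_mean, traits),
                      genotype_effects = eff,
                      block_effects = block_effects,
                      error_sd = setNames(error_sd, traits)))
  })
}

#' Simulate a canopy thermal image with known ground truth
#'
#' Canopy pixels (an elliptical patch covering `canopy_fraction` of the
#' grid) are drawn from `N(canopy_temp_mean, canopy_temp_sd)`; background
#' pixels sit at `canopy_temp_mean + background_offset` with a small fixed
#' jitter (sd 0.1 degC) so a temperature-gap segmentation is well posed.
#'
#' @param n_rows,n_cols grid shape in pixels.
#' @param canopy_fraction fraction of pixels belonging to the canopy,
#'   strictly inside (0, 1).
#' @param canopy_temp_mean true mean canopy temperature, degC.
#' @param canopy_temp_sd canopy pixel standard deviation, degC.
#' @param background_offset background minus canopy mean temperature, degC.
#' @param ambient_temp ambient air temperature stored with the image, degC.
#' @param plant_id identifier for the simulated plant.
#' @param seed optional integer seed.
#'
#' @return A list with `image` (a [thermal_image()]), `mask` (logical
#'   ground-truth canopy mask) and `truth` (list with `canopy_temp_mean`,
#'   `canopy_mean_realized`, the realized mean of the drawn canopy pixels).
#' @export
simulate_thermal_image <- function(n_rows = 64, n_cols = 64,
                                   canopy_fraction = 0.4,
                                   canopy_temp_mean = 24,
                                   canopy_temp_sd = 0.3,
                                   background_offset = 5,
                                   ambient_temp = 25,
                                   plant_id = "sim", seed = NULL) {
  .check_scalar(n_rows, "n_rows", 1)
  .check_scalar(n_cols, "n_cols", 1)
  if (!is.numeric(canopy_fraction) || length(canopy_fraction) != 1L ||
      canopy_fraction <= 0 || canopy_fraction >= 1)
    stop("canopy_fraction must lie strictly in (0, 1)", call. = FALSE)
  .check_scalar(canopy_temp_sd, "canopy_temp_sd", 0)

  # deterministic elliptical canopy: the round(f*N) pixels closest to the
  # grid centre in normalized coordinates
  rr <- (row(matrix(0, n_rows, n_cols)) - (n_rows + 1) / 2) / n_rows
  cc <- (col(matrix(0, n_rows, n_cols)) - (n_cols + 1) / 2) / n_cols
  r2 <- rr^2 + cc^2
  n_can <- max(1L, round(canopy_fraction * n_rows * n_cols))
  thr <- sort(r2)[n_can]
  mask <- r2 <= thr
  # ties at the threshold radius could overshoot; trim deterministically
  if (sum(mask) > n_can) {
    extra <- which(mask & r2 == thr)
    mask[extra[seq_len(sum(mask) - n_can)]] <- FALSE
  }

  .with_seed(seed, {
    px <- matrix(0, n_rows, n_cols)
    px[mask] <- rnorm(sum(mask), canopy_temp_mean, canopy_temp_sd)
    px[!mask] <- rnorm(sum(!mask), canopy_temp_mean + background_offset, 0.1)
    img <- thermal_image(px, ambient_temp = ambient_temp,
                         plant_id = plant_id)
    list(image = img, mask = mask,
         truth = list(canopy_temp_mean = canopy_temp_mean,
                      canopy_mean_realized = mean(px[mask])))
  })
}

#' Simulate a weekly SPAD senescence series with known loss rate
#'
#' SPAD greenness declines linearly at `daily_loss_rate` percent of the
#' initial reading per day (the stay-green endpoint model), observed at
#' weekly intervals with optional Gaussian reading noise.  The noise-free
#' maturity reading satisfies `flsm(initial, SPAD_m, days) ==
#' daily_loss_rate`, which parameter-recovery tests exploit.
#'
#' @param initial_spad SPAD reading just after stress (`SPAD_a`).
#' @param daily_loss_rate true senescence rate, percent of `SPAD_a` lost
#'   per day.
#' @param n_weeks number of weekly readings (default 6).
#' @param days_to_maturity days from ten days after anthesis to
#'   physiological maturity.
#' @param noise_sd reading noise standard deviation.
#' @param seed optional integer seed.
#'
#' @return A list with `series` (data frame `week`, `day`, `spad`),
#'   `spad_a`, `spad_m` (noise-free maturity reading) and `truth`
#'   (`daily_loss_rate`).
#' @export
simulate_senescence_series <- function(initial_spad = 50, daily_loss_rate = 1,
                                       n_weeks = 6, days_to_maturity = 42,
                                       noise_sd = 0, seed = NULL) {
  .check_scalar(initial_spad, "initial_spad", 0, strict = TRUE)
  .check_scalar(daily_loss_rate, "daily_loss_rate", 0)
  .check_scalar(n_weeks, "n_weeks", 1)
  .check_scalar(days_to_maturity, "days_to_maturity", 0, strict = TRUE)
  .check_scalar(noise_sd, "noise_sd", 0)
  .with_seed(seed, {
    day <- 7 * (seq_len(n_weeks) - 1L)
    clean <- pmax(0, initial_spad * (1 - daily_loss_rate * day / 100))
    spad <- clean + rnorm(n_weeks, 0, noise_sd)
    spad_m <- max(0, initial_spad *
                    (1 - daily_loss_rate * days_to_maturity / 100))
    list(series = data.frame(week = seq_len(n_weeks), day = day,
                             spad = spad),
         spad_a = initial_spad, spad_m = spad_m,
         truth = list(daily_loss_rate = daily_loss_rate))
  })
}
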