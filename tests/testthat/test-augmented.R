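test_that("block effects follow the check means", {
  fb <- toy_fieldbook(check_vals = c(10, 12, 14, 16))
  expect_equal(estimate_block_effects(fb, "GY"),
               c(B1 = -2, B2 = 2))
  fb0 <- toy_fieldbook(check_vals = c(7, 7, 7, 7))
  expect_equal(estimate_block_effects(fb0, "GY"), c(B1 = 0, B2 = 0))
})

test_that("block effects equal a least-squares fit on check data", {
  set.seed(11)
  for (i in 1:10) {
    fb <- random_fieldbook(n_blocks = sample(2:5, 1),
                           n_checks = sample(2:5, 1))
    eff <- estimate_block_effects(fb, "GY")
    chk <- as.data.frame(fb)[fb$is_check, ]
    m <- lm(GY ~ 0 + factor(block) + factor(genotype),
            data = chk,
            contrasts = list(`factor(genotype)` = "contr.sum"))
    ls_eff <- coef(m)[grep("block", names(coef(m)))]
    expect_equal(unname(eff), unname(ls_eff - mean(ls_eff)),
                 tolerance = 1e-10)
  }
})

test_that("adjusted means subtract the block effect for tests only", {
  fb <- toy_fieldbook(check_vals = c(10, 12, 14, 16),
                      test_vals = 20, test_blocks = "B2")  # B2 effect +2
  am <- adjust_means(fb, "GY")
  expect_equal(am$adjusted_mean[am$genotype == "T1"], 18)
  # checks: plain mean over replicates, adjustment zero
  expect_equal(am$adjusted_mean[am$genotype == "C1"], mean(c(10, 14)))
  expect_true(all(am$block_adjustment[am$source == "check"] == 0))
})

test_that("noise-free simulation recovers genotype values exactly", {
  sim <- simulate_fieldbook(grand_mean = 10, error_sd = 0, seed = 21)
  fit <- augmented_rcbd(sim$fieldbook, "GY")
  truth <- 10 + sim$truth$genotype_effects[names(coef(fit)), "GY"]
  expect_equal(coef(fit), truth, tolerance = 1e-10)
  # environmental variance collapses with the noise
  expect_equal(variance_components(fit)$EV, 0, tolerance = 1e-18)
})

test_that("ANOVA degrees of freedom and additivity hold on any design", {
  fit <- augmented_rcbd(simulate_fieldbook(seed = 1)$fieldbook, "GY")
  expect_equal(fit$anova$df, c(3L, 45L, 4L, 41L, 12L))
  set.seed(12)
  for (i in 1:8) {
    b <- sample(2:5, 1); cc <- sample(2:5, 1); tt <- sample(1:12, 1)
    fb <- random_fieldbook(b, cc, tt)
    a <- augmented_rcbd(fb, "GY")$anova
    expect_equal(a$df, c(b - 1L, cc + tt - 1L, cc - 1L, tt,
                         (b - 1L) * (cc - 1L)))
    # Block + Genotype + Residual df = N - 1
    expect_equal(a$df[1L] + a$df[2L] + a$df[5L], b * cc + tt - 1L)
    expect_equal(a$mean_sq[a$df > 0], (a$sum_sq / a$df)[a$df > 0])
  }
})

test_that("sums of squares match the least-squares decomposition", {
  # 2-block/2-check/2-test toy and larger random designs
  set.seed(13)
  for (i in 1:10) {
    fb <- if (i <= 3) toy_fieldbook(check_vals = rnorm(4, 10),
                                    test_vals = rnorm(2, 10))
          else random_fieldbook(sample(2:4, 1), sample(2:4, 1),
                                sample(2:8, 1))
    a <- augmented_rcbd(fb, "GY")$anova
    o <- lm_anova_oracle(fb, "GY")
    expect_equal(a$sum_sq[1L], o$block, tolerance = 1e-8)
    expect_equal(a$sum_sq[2L], o$genotype, tolerance = 1e-8)
    expect_equal(a$sum_sq[5L], o$resid, tolerance = 1e-8)
    # check + combined test row partition the genotype SS
    expect_equal(a$sum_sq[3L] + a$sum_sq[4L], a$sum_sq[2L],
                 tolerance = 1e-10)
  }
})

test_that("constant observations give zero sums of squares", {
  fb <- toy_fieldbook(check_vals = rep(5, 4), test_vals = c(5, 5))
  a <- augmented_rcbd(fb, "GY")$anova
  expect_equal(a$sum_sq, rep(0, 5), tolerance = 1e-20)
})

test_that("shifting one block moves its effect, not test adjusted means", {
  sim <- simulate_fieldbook(seed = 31)
  fb <- sim$fieldbook
  fit0 <- augmented_rcbd(fb, "GY")
  fb$GY[fb$block == "B2"] <- fb$GY[fb$block == "B2"] + 5
  fit1 <- augmented_rcbd(fb, "GY")
  shift <- fit1$block_effects - fit0$block_effects
  # B2 moves up by 5 minus the induced grand-mean shift; others move down
  expect_equal(unname(shift["B2"] - mean(shift[c("B1", "B3", "B4")])), 5)
  # with sum-to-zero block effects the whole adjusted-mean vector shifts
  # uniformly by 5/b: every genotype comparison is untouched
  delta <- coef(fit1) - coef(fit0)
  expect_equal(unname(delta), rep(5 / 4, length(delta)), tolerance = 1e-10)
})

test_that("missing checks are fatal, missing tests are dropped", {
  fb <- toy_fieldbook()
  fb$GY[1L] <- NA   # a check value
  expect_error(augmented_rcbd(fb, "GY"), "block effects are not estimable")
  fb <- toy_fieldbook()
  fb$GY[5L] <- NA   # a test value
  expect_warning(fit <- augmented_rcbd(fb, "GY"), "dropping 1 test plot")
  expect_equal(fit$t, 1L)
  expect_error(augmented_rcbd(toy_fieldbook()[1:4, ], "XX"), "not present")
})

test_that("incomplete designs are rejected with block and check named", {
  fb <- toy_fieldbook()[-1L, ]   # C1 missing from B1
  attr(fb, "traits") <- "GY"
  class(fb) <- c("fieldbook", "data.frame")
  expect_error(augmented_rcbd(fb, "GY"), "check 'C1' missing from block 'B1'")
})

test_that("comparison standard errors follow the design formulas", {
  ce0 <- comparison_errors(0, 12, b = 4, c = 5)
  expect_equal(ce0$se, rep(0, 4))
  ce <- comparison_errors(1, 12, b = 4, c = 5)
  expect_equal(ce$se[ce$comparison == "check_vs_check"], sqrt(0.5))
  expect_equal(ce$se[ce$comparison == "test_same_block"], sqrt(2))
  expect_equal(ce$se[ce$comparison == "test_diff_block"], sqrt(2 * 1.2))
  expect_equal(ce$se[ce$comparison == "test_vs_check"],
               sqrt(1 + 1 / 4 + 1 / 5 + 1 / 20))
  # different-block comparisons are never more precise than same-block
  expect_gte(ce$se[ce$comparison == "test_diff_block"],
             ce$se[ce$comparison == "test_same_block"])
  # critical differences widen as alpha tightens
  ce32 <- comparison_errors(1, 12, b = 4, c = 5, alpha = 0.32)
  expect_true(all(ce$cd > ce32$cd))
  expect_error(comparison_errors(1, 0, b = 4, c = 5), "undefined")
})

test_that("model methods behave like a classed fit", {
  sim <- simulate_fieldbook(seed = 41)
  fit <- augmented_rcbd(sim$fieldbook, "GY")
  expect_s3_class(fit, "augmented_rcbd")
  expect_named(coef(fit))
  expect_length(coef(fit), 46L)
  # tests are saturated: residuals vanish there, not for checks
  r <- residuals(fit)
  expect_true(all(abs(r[!fit$data$is_check]) < 1e-12))
  expect_gt(max(abs(r[fit$data$is_check])), 0)
  expect_equal(fitted(fit) + r, fit$data$y)
  # predictions recover adjusted means, plus block effect when asked
  nd <- data.frame(genotype = c("T01", "CHK1"), block = c("B1", "B2"))
  expect_equal(predict(fit, nd),
               unname(coef(fit)[nd$genotype] +
                        fit$block_effects[nd$block]))
  expect_error(predict(fit, data.frame(genotype = "NOPE")), "unknown")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(fit$data), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  expect_output(print(summary(fit)), "Analysis of variance")
  expect_s3_class(anova(fit), "data.frame")
})
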