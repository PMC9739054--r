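# tiny deterministic field book: 2 checks x 2 blocks + tests
toy_fieldbook <- function(check_vals = c(10, 12, 14, 16),
                          test_vals = c(20, 22),
                          test_blocks = c("B1", "B2")) {
  nt <- length(test_vals)
  fieldbook(
    genotype = c("C1", "C2", "C1", "C2", sprintf("T%d", seq_len(nt))),
    block    = c("B1", "B1", "B2", "B2", test_blocks[seq_len(nt)]),
    is_check = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, nt)),
    GY       = c(check_vals, test_vals))
}

# random valid field book for round-trip and oracle checks
random_fieldbook <- function(n_blocks = 3, n_checks = 3, n_tests = 7) {
  simulate_fieldbook(n_blocks = n_blocks, n_checks = n_checks,
                     n_tests = n_tests, grand_mean = 10, genotype_sd = 2,
                     error_sd = 1)$fieldbook
}

# sequential least-squares decomposition: the independent ANOVA oracle
lm_anova_oracle <- function(fb, trait) {
  d <- as.data.frame(fb)
  d$y <- d[[trait]]
  m <- stats::lm(y ~ factor(block) + factor(genotype), data = d)
  a <- stats::anova(m)
  list(block = a$`Sum Sq`[1L], genotype = a$`Sum Sq`[2L],
       resid = a$`Sum Sq`[3L], df = a$Df)
}
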