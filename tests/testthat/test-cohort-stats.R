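test_that("Pearson chi-squared matches the closed form", {
  t <- contingency_test(c(10, 10, 10, 10), "chisq")
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 1)
  set.seed(31)
  for (i in 1:50) {
    tab <- rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1))[, 1]
    if (any(tab[c(1, 3)] + tab[c(2, 4)] == 0) ||
        any(tab[1:2] + tab[3:4] == 0)) next
    got <- contingency_test(tab, "chisq")
    want <- pearson_closed_form(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got$statistic, want, tolerance = 1e-12)
    expect_equal(got$p_value, stats::pchisq(want, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact equals exhaustive hypergeometric enumeration", {
  t <- contingency_test(c(3, 1, 1, 3), "fisher")
  expect_equal(t$p_value, 34 / 70, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:60) {
    repeat {
      tab <- rmultinom(1, sample(8:40, 1), runif(4, 0.05, 1))[, 1]
      if (all(tab[1:2] + tab[3:4] > 0) && all(tab[c(1, 3)] + tab[c(2, 4)] > 0))
        break
    }
    got <- contingency_test(tab, "fisher")$p_value
    want <- fisher_enumeration_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, want, tolerance = 1e-7,
                 label = paste(tab, collapse = ","))
  }
})

test_that("contingency_test validates tables and flags small expecteds", {
  expect_error(contingency_test(c(0, 0, 3, 4)), "empty margin")
  expect_error(contingency_test(c(1, -1, 3, 4)), "non-negative")
  expect_error(contingency_test(c(1, 2, 3)), "2x2")
  t <- contingency_test(c(2, 3, 1, 4), "chisq")
  expect_match(t$notes, "expected count < 5")
  # Yates variant is distinct and more conservative here
  ty <- contingency_test(c(12, 3, 4, 11), "chisq_yates")
  tp <- contingency_test(c(12, 3, 4, 11), "chisq")
  expect_gt(ty$p_value, tp$p_value)
})

test_that("Mann-Whitney exact agrees with permutation enumeration", {
  t <- rank_test(list(c(1, 2, 3), c(4, 5, 6)), "mann_whitney")
  expect_equal(unname(t$statistic), 0)
  expect_equal(t$p_value, 0.1)
  expect_identical(t$method, "mann_whitney_exact")
  set.seed(17)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(1:50, n1 + n2)  # tie-free
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    got <- rank_test(list(x, y), "mann_whitney")$p_value
    expect_equal(got, mw_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U statistics are complementary and symmetric", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1))
    u1 <- rank_test(list(x, y), "mann_whitney")
    u2 <- rank_test(list(y, x), "mann_whitney")
    expect_equal(unname(u1$statistic) + unname(u2$statistic),
                 length(x) * length(y))
    expect_equal(u1$p_value, u2$p_value, tolerance = 1e-12)
  }
  ident <- rank_test(list(c(1, 2, 3), c(1, 2, 3)), "mann_whitney")
  expect_gte(ident$p_value, 0.99)
})

test_that("Kruskal-Wallis handles k >= 3 groups and degenerate input", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  t <- rank_test(same, "kruskal_wallis")
  expect_lt(abs(t$statistic), 1e-9)
  expect_error(rank_test(list(1:3, 4:6), "kruskal_wallis"), ">= 3")
  expect_error(rank_test(list(1:3, numeric(0)), "mann_whitney"),
               "empty sample")
  expect_error(rank_test(list(1:3, 4:6, 7:9), "mann_whitney"), "exactly 2")
})

test_that("paired t test matches the closed form and rejects degeneracy", {
  t <- paired_t_test(c(1, 2, 3), c(0, 0, 0), normality_check = FALSE)
  expect_equal(unname(t$statistic), 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(t$p_value, 0.0741799, tolerance = 1e-6)
  t0 <- paired_t_test(c(0, 2, 0, 2), c(1, 1, 1, 1), normality_check = FALSE)
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p_value, 1)
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "degenerate pairs")
  expect_error(paired_t_test(c(1, 2), c(0, 0)), "at least 3")
  tn <- paired_t_test(c(1.2, 2.1, 3.3, 4.0), c(0.9, 2.0, 2.8, 3.1))
  expect_match(tn$notes, "shapiro_x_p")
})

test_that("group-label swap leaves two-sided p-values unchanged", {
  tab <- c(9, 21, 17, 13)
  swap <- c(17, 13, 9, 21)
  for (m in c("chisq", "chisq_yates", "fisher")) {
    expect_equal(contingency_test(tab, m)$p_value,
                 contingency_test(swap, m)$p_value, tolerance = 1e-12)
  }
})

test_that("lethal-phase analysis reproduces the printed CI deficit", {
  counts <- printed_counts()
  blast <- counts[counts$panel == "blastula", ]
  hatch <- counts[counts$panel == "hatch", ]
  df <- data.frame(cross = blast$group,
                   blastula_yes = blast$yes, blastula_n = blast$n,
                   hatch_yes = hatch$yes[match(blast$group, hatch$group)],
                   hatch_n = hatch$n[match(blast$group, hatch$group)])
  rep <- lethal_phase_analysis(df)
  ci <- rep[rep$cross == "ci", ]
  expect_equal(ci$deficit_pct, 100 * (45 / 159 - 48 / 2397), tolerance = 1e-9)
  expect_gt(ci$deficit_pct, 26)
  expect_lt(ci$p_value, 2e-16)  # at/below the reporting floor
  # non-CI crosses: blastulation and hatch rates agree (no second phase)
  other <- rep[rep$cross != "ci", ]
  expect_true(all(other$p_value > 0.01))
  expect_true(all(abs(other$deficit_pct) < 10))
  # equal rates: deficit 0, p = 1
  eq <- lethal_phase_analysis(data.frame(
    cross = "toy", blastula_yes = 30, blastula_n = 100,
    hatch_yes = 30, hatch_n = 100))
  expect_equal(eq$deficit_pct, 0)
  expect_equal(eq$p_value, 1)
  expect_error(lethal_phase_analysis(data.frame(cross = "x")), "missing")
})

test_that("simulated CI deficit matches the fate-model algebra", {
  co <- simulate_cohort(default_fate_params(), 10000, seed = 77)
  rep <- lethal_phase_analysis(co)
  ci <- rep[rep$cross == "ci", ]
  p <- default_fate_params()$ci
  # expected deficit: haploids that blastulate but never hatch, plus
  # diploids that blastulate and fail to hatch
  want <- 100 * (p$p_complete_loss * p$p_blastula_given_haploid *
                   (1 - p$p_hatch_given_haploid) +
                 p$p_normal * p$p_blastula_given_diploid *
                   (1 - p$p_hatch_given_diploid))
  se <- 100 * sqrt(0.3 * 0.7 / 10000) * 2  # conservative 2-proportion bound
  expect_lt(abs(ci$deficit_pct - want), 3 * se)
})

test_that("defect-rate report reproduces printed attrition percentages", {
  counts <- printed_counts()
  adults <- counts[counts$panel == "egg_to_adult", ]
  rep <- defect_rate_report(
    data.frame(group = adults$group, affected = adults$yes,
               total = adults$n),
    comparisons = list(list(a = "ci", b = "wild_type", method = "fisher")))
  expect_equal(round(rep$proportions$pct[rep$proportions$group == "ci"]), 69)
  expect_equal(round(rep$proportions$pct[rep$proportions$group ==
                                           "wild_type"]), 95)
  expect_lt(rep$tests$p_value, 1e-10)
  expect_error(defect_rate_report(
    data.frame(group = "g", affected = 0, total = 0)), "zero total")
  expect_error(defect_rate_report(
    data.frame(group = "g", affected = 1, total = 2),
    comparisons = list(list(a = "g", b = "nope"))), "unknown group")
})
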