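test_that("dosage banding partitions [0, Inf) at the midpoint cuts", {
  expect_identical(classify_gene_dosage(0), "ABSENT")
  expect_identical(classify_gene_dosage(100), "DISOMIC")
  expect_identical(classify_gene_dosage(52.3), "HEMIZYGOUS")
  # band edges belong to the upper band (half-open on the right)
  expect_identical(classify_gene_dosage(c(24.999, 25, 74.999, 75, 124.9, 125,
                                          1e6)),
                   c("ABSENT", "HEMIZYGOUS", "HEMIZYGOUS", "DISOMIC",
                     "DISOMIC", "AMPLIFIED", "AMPLIFIED"))
  expect_error(classify_gene_dosage(-1), ">= 0")
  # partition: a dense grid maps to exactly one state each, monotonically
  grid <- seq(0, 300, by = 0.25)
  states <- classify_gene_dosage(grid)
  expect_false(anyNA(states))
  ord <- match(states, c("ABSENT", "HEMIZYGOUS", "DISOMIC", "AMPLIFIED"))
  expect_true(all(diff(ord) >= 0))
})

test_that("arm calls are majority votes with concordance", {
  a <- call_arm_dosage(c("HEMIZYGOUS", "HEMIZYGOUS", "HEMIZYGOUS",
                         "HEMIZYGOUS", "DISOMIC"), arm = "2L")
  expect_identical(a$state, "HEMIZYGOUS")
  expect_equal(a$concordance, 0.8)
  b <- call_arm_dosage(rep("DISOMIC", 5))
  expect_identical(b$state, "DISOMIC")
  expect_equal(b$concordance, 1.0)
  c <- call_arm_dosage(c("ABSENT", "ABSENT", "HEMIZYGOUS", "HEMIZYGOUS",
                         "DISOMIC"))
  expect_identical(c$state, "ambiguous")
  expect_equal(c$concordance, 0.4)
  expect_error(call_arm_dosage(rep("DISOMIC", 4)), "five gene states")
  expect_error(call_arm_dosage(c(rep("DISOMIC", 4), "weird")), "unknown")
})

test_that("arm calls are invariant to gene order", {
  states <- c("HEMIZYGOUS", "DISOMIC", "HEMIZYGOUS", "HEMIZYGOUS", "AMPLIFIED")
  base <- call_arm_dosage(states)
  set.seed(1)
  for (i in 1:20) {
    perm <- call_arm_dosage(sample(states))
    expect_identical(perm$state, base$state)
    expect_equal(perm$concordance, base$concordance)
  }
})

test_that("transgene presence requires both depth and evenness", {
  lay <- toy_layout(c(a1 = 1000L), transgene_length = 720L)
  gm <- 50
  # uniform half-coverage: present, evenness 1, ~50%
  prof <- toy_profile(lay, list(a1 = 50, egfp = 25))
  tg <- call_transgene_presence(prof, transgene_interval(lay), gm)
  expect_true(tg$present)
  expect_equal(tg$evenness, 1.0)
  expect_equal(tg$percent, 50)
  # all-zero: absent
  prof0 <- toy_profile(lay, list(a1 = 50, egfp = 0))
  tg0 <- call_transgene_presence(prof0, transgene_interval(lay), gm)
  expect_false(tg0$present)
  expect_equal(tg0$evenness, 0)
  expect_equal(tg0$percent, 0)
  # depth piled into 2 of 10 bins: fails evenness despite high mean
  tr <- prof0$tracks
  tr$egfp[1:144] <- 200   # bins 1-2 of 10 over 720 bp
  profu <- depth_profile("u", tr, lay)
  tgu <- call_transgene_presence(profu, transgene_interval(lay), gm)
  expect_gte(tgu$percent, 25)
  expect_equal(tgu$evenness, 0.2)
  expect_false(tgu$present)
  # too short for 10 bins
  lay2 <- toy_layout(c(a1 = 100L), transgene_length = 8L)
  prof2 <- toy_profile(lay2, list(a1 = 10, egfp = 5))
  expect_error(call_transgene_presence(prof2, transgene_interval(lay2), gm),
               "shorter than 10")
})

arm_call_of <- function(arm, state) {
  call_arm_dosage(rep(state, 5), arm = arm)
}

test_that("sex inference follows Y presence and X dosage", {
  expect_identical(infer_sex(arm_call_of("Y", "HEMIZYGOUS"),
                             arm_call_of("X", "HEMIZYGOUS")), "male")
  expect_identical(infer_sex(arm_call_of("Y", "ABSENT"),
                             arm_call_of("X", "DISOMIC")), "female")
  ambiguous_y <- call_arm_dosage(c("ABSENT", "ABSENT", "HEMIZYGOUS",
                                   "HEMIZYGOUS", "DISOMIC"), arm = "Y")
  expect_identical(infer_sex(ambiguous_y, arm_call_of("X", "DISOMIC")),
                   "undetermined")
  expect_identical(infer_sex(arm_call_of("Y", "ABSENT"),
                             arm_call_of("X", "AMPLIFIED")), "undetermined")
})

make_arm_calls <- function(states) {
  lapply(names(states), function(a) arm_call_of(a, states[[a]]))
}

tg_present <- list(present = TRUE, evenness = 1, percent = 50)
tg_absent <- list(present = FALSE, evenness = 0, percent = 0)

test_that("ploidy verdicts follow the marker + dosage rules", {
  male_diploid <- make_arm_calls(c(Y = "HEMIZYGOUS", X = "HEMIZYGOUS",
                                   `2L` = "DISOMIC", `2R` = "DISOMIC",
                                   `3L` = "DISOMIC", `3R` = "DISOMIC",
                                   `4` = "DISOMIC"))
  v <- call_ploidy(male_diploid, tg_present)
  expect_identical(v$ploidy, "diploid")
  expect_identical(v$sex, "male")

  haploid <- make_arm_calls(c(Y = "ABSENT", X = "DISOMIC",
                              `2L` = "DISOMIC", `2R` = "DISOMIC",
                              `3L` = "DISOMIC", `3R` = "DISOMIC",
                              `4` = "DISOMIC"))
  v <- call_ploidy(haploid, tg_absent)
  expect_identical(v$ploidy, "haploid")
  expect_identical(v$sex, "female")

  aneu <- make_arm_calls(c(Y = "ABSENT", X = "DISOMIC",
                           `2L` = "HEMIZYGOUS", `2R` = "DISOMIC",
                           `3L` = "DISOMIC", `3R` = "DISOMIC",
                           `4` = "DISOMIC"))
  v <- call_ploidy(aneu, tg_present)
  expect_identical(v$ploidy, "segmental_aneuploid")

  # no paternal marker present and an arm lost: not classifiable
  v <- call_ploidy(aneu, tg_absent)
  expect_identical(v$ploidy, "ambiguous")

  expect_error(call_ploidy(male_diploid[-3], tg_present), "missing arm")
})

test_that("noise-free simulated karyotypes are recovered exactly", {
  layout <- build_layout(60000, 1000, seed = 0)
  truth <- c(diploid_xy = "diploid", diploid_xx = "diploid",
             haploid_maternal = "haploid", arm_loss = "segmental_aneuploid")
  sexes <- c(diploid_xy = "male", diploid_xx = "female",
             haploid_maternal = "female", arm_loss = "female")
  for (label in names(truth)) {
    prof <- simulate_depth(layout, karyotype_preset(label), 50, "none",
                           seed = 1)
    call <- call_embryo(prof, layout)
    expect_identical(call$ploidy, unname(truth[label]), label = label)
    expect_identical(call$sex, unname(sexes[label]), label = label)
  }
})
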