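# Cohort-level statistics: the test battery for lethal phases and defect
# rates. Wrappers keep a uniform TestResult surface over the base-R tests
# (the same implementations the original analyses were run with).

test_result <- function(method, statistic, p_value, n, notes = "") {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n = n, notes = notes),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.6g (n = %s)%s\n", x$method,
              if (is.na(x$statistic)) "-" else format(x$statistic),
              x$p_value, paste(x$n, collapse = ", "),
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == 2L)) stop_bad("contingency table must be 2x2")
    m <- table
  } else if (is.numeric(table) && length(table) == 4L) {
    m <- matrix(table, 2L, 2L, byrow = TRUE)
  } else {
    stop_bad("table must be a 2x2 matrix or a length-4 vector (a,b,c,d)")
  }
  if (any(m < 0) || any(m != round(m))) stop_bad("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_bad("empty margin in contingency table")
  }
  m
}

#' 2x2 contingency-table test
#'
#' `chisq` is the uncorrected Pearson test (statistic
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`, df = 1); `chisq_yates` applies the Yates
#' continuity correction; `fisher` is the two-sided exact test, summing all
#' hypergeometric tables with probability at most that of the observed table.
#' No continuity correction is applied by default because the source analyses
#' never state a variant; both are exposed. When any expected count is below
#' 5, the chi-squared result carries a note.
#'
#' @param table 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise
#'   (rows = groups, columns = outcome yes/no).
#' @param method `"chisq"`, `"chisq_yates"` or `"fisher"`.
#' @return A `TestResult`.
#' @export
contingency_test <- function(table, method = c("chisq", "chisq_yates",
                                               "fisher")) {
  method <- match.arg(method)
  m <- as_2x2(table)
  n <- rowSums(m)
  if (method == "fisher") {
    ft <- stats::fisher.test(m, alternative = "two.sided")
    return(test_result("fisher_exact_two_sided", NA_real_, ft$p.value, n))
  }
  correct <- method == "chisq_yates"
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  notes <- if (any(expected < 5)) "expected count < 5" else ""
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  test_result(if (correct) "chisq_yates" else "chisq_pearson",
              unname(ct$statistic), ct$p.value, n, notes)
}

#' Rank-based comparison of distributions
#'
#' `mann_whitney` compares exactly two samples: exact p by enumeration when
#' the pooled size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections. The reported statistic
#' is U for the first sample (U1 + U2 = n1 n2). `kruskal_wallis` compares
#' three or more samples by the tie-corrected chi-squared approximation.
#'
#' @param samples List of numeric vectors.
#' @param method `"mann_whitney"` or `"kruskal_wallis"`.
#' @return A `TestResult`.
#' @export
rank_test <- function(samples, method = c("mann_whitney", "kruskal_wallis")) {
  method <- match.arg(method)
  if (!is.list(samples) || any(!vapply(samples, is.numeric, logical(1)))) {
    stop_bad("'samples' must be a list of numeric vectors")
  }
  if (any(lengths(samples) == 0)) stop_bad("empty sample")
  if (method == "mann_whitney") {
    if (length(samples) != 2L) stop_bad("mann_whitney takes exactly 2 samples")
    x <- samples[[1]]; y <- samples[[2]]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 12L) && !ties
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    test_result(if (exact) "mann_whitney_exact" else "mann_whitney_normal",
                unname(wt$statistic), wt$p.value, lengths(samples),
                if (ties && exact) "ties" else "")
  } else {
    if (length(samples) < 3L) stop_bad("kruskal_wallis needs >= 3 samples")
    kt <- stats::kruskal.test(samples)
    test_result("kruskal_wallis", unname(kt$statistic), kt$p.value,
                lengths(samples))
  }
}

#' Two-sided paired t test with optional normality pre-check
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on the paired differences d, df = n - 1.
#' With `normality_check`, Shapiro-Wilk p-values for each margin are recorded
#' in the notes (the pre-check the source analyses ran before pairing).
#'
#' @param x,y Paired numeric vectors (same length, >= 3 pairs).
#' @param normality_check Run Shapiro-Wilk on each margin (default TRUE).
#' @return A `TestResult`.
#' @export
paired_t_test <- function(x, y, normality_check = TRUE) {
  if (length(x) != length(y)) stop_bad("x and y must be paired (same length)")
  if (length(x) < 3L) stop_bad("need at least 3 pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop_bad("degenerate pairs: zero-variance differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  notes <- ""
  if (normality_check) {
    sw <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                               error = function(e) NA_real_)
    notes <- sprintf("shapiro_x_p=%.4g; shapiro_y_p=%.4g", sw(x), sw(y))
  }
  test_result("paired_t_two_sided", unname(tt$statistic), tt$p.value,
              length(x), notes)
}

cohort_counts <- function(cohort) {
  validate_cohort(cohort)
  crosses <- unique(cohort$cross)
  do.call(rbind, lapply(crosses, function(cr) {
    d <- cohort[cohort$cross == cr, ]
    data.frame(cross = cr,
               blastula_yes = sum(d$reached_blastula),
               blastula_n = nrow(d),
               hatch_yes = sum(d$hatched),
               hatch_n = nrow(d),
               stringsAsFactors = FALSE)
  }))
}

#' Lethal-phase analysis: blastulation rate versus hatch rate
#'
#' For each cross, compares the fraction of embryos that reached the
#' blastoderm stage with the fraction that hatched (pooled chi-squared on the
#' 2x2 of counts). The blastulation-minus-hatch deficit estimates the second
#' (post-blastoderm) lethal phase: embryos that develop past cycle 10 but
#' never hatch — in the CI cross, predominantly maternal-only haploids.
#'
#' @param x Either a `CohortTable` or a counts data.frame with columns
#'   cross, blastula_yes, blastula_n, hatch_yes, hatch_n.
#' @param method Contingency method (default `"chisq"`, the pooled test used
#'   on these data).
#' @return data.frame per cross: blastulation_pct, hatch_pct, deficit_pct,
#'   statistic, p_value, method.
#' @export
lethal_phase_analysis <- function(x, method = "chisq") {
  counts <- if (inherits(x, "CohortTable")) cohort_counts(x) else x
  req <- c("cross", "blastula_yes", "blastula_n", "hatch_yes", "hatch_n")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop_bad("missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(counts)), function(i) {
    ci <- counts[i, ]
    if (ci$blastula_n == 0 || ci$hatch_n == 0) {
      stop_bad("zero embryos scored for cross ", ci$cross)
    }
    tr <- contingency_test(c(ci$blastula_yes, ci$blastula_n - ci$blastula_yes,
                             ci$hatch_yes, ci$hatch_n - ci$hatch_yes),
                           method = method)
    data.frame(cross = ci$cross,
               blastulation_pct = 100 * ci$blastula_yes / ci$blastula_n,
               hatch_pct = 100 * ci$hatch_yes / ci$hatch_n,
               deficit_pct = 100 * (ci$blastula_yes / ci$blastula_n -
                                      ci$hatch_yes / ci$hatch_n),
               statistic = tr$statistic, p_value = tr$p_value,
               method = tr$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Defect-rate report with pairwise comparisons
#'
#' Takes per-group counts of affected/total (abnormal embryos, division
#' errors, or adults among hatched eggs for egg-to-adult attrition), computes
#' proportions, and runs the requested pairwise 2x2 comparisons.
#'
#' @param counts data.frame with columns group, affected, total.
#' @param comparisons List of `list(a = <group>, b = <group>, method = ...)`;
#'   method defaults to `"fisher"`.
#' @return list(proportions = data.frame(group, affected, total, pct),
#'   tests = data.frame of one row per comparison).
#' @export
defect_rate_report <- function(counts, comparisons = list()) {
  req <- c("group", "affected", "total")
  if (!all(req %in% names(counts))) {
    stop_bad("counts must have columns group, affected, total")
  }
  if (any(counts$total <= 0)) {
    stop_bad("group with zero total: ",
             paste(counts$group[counts$total <= 0], collapse = ", "))
  }
  if (any(counts$affected > counts$total)) stop_bad("affected > total")
  props <- data.frame(group = counts$group, affected = counts$affected,
                      total = counts$total,
                      pct = 100 * counts$affected / counts$total,
                      stringsAsFactors = FALSE)
  tests <- lapply(comparisons, function(cmp) {
    method <- cmp$method %||% "fisher"
    ia <- match(cmp$a, counts$group)
    ib <- match(cmp$b, counts$group)
    if (is.na(ia) || is.na(ib)) {
      stop_bad("unknown group in comparison: ",
               paste(setdiff(c(cmp$a, cmp$b), counts$group), collapse = ", "))
    }
    tr <- contingency_test(c(counts$affected[ia],
                             counts$total[ia] - counts$affected[ia],
                             counts$affected[ib],
                             counts$total[ib] - counts$affected[ib]),
                           method = method)
    data.frame(group_a = cmp$a, group_b = cmp$b, method = tr$method,
               statistic = tr$statistic, p_value = tr$p_value,
               stringsAsFactors = FALSE)
  })
  list(proportions = props,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(group_a = character(), group_b = character(),
                    method = character(), statistic = numeric(),
                    p_value = numeric()))
}

#' Egg-to-adult attrition from a cohort table
#'
#' Adults among hatched eggs, per cross.
#'
#' @param cohort A `CohortTable`.
#' @return data.frame(group, affected = adults, total = hatched, pct).
#' @export
egg_to_adult_counts <- function(cohort) {
  validate_cohort(cohort)
  crosses <- unique(cohort$cross)
  out <- do.call(rbind, lapply(crosses, function(cr) {
    d <- cohort[cohort$cross == cr, ]
    data.frame(group = cr, affected = sum(d$adult), total = sum(d$hatched),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Printed per-group counts shipped with the package
#'
#' The study's printed 2x2-style counts (hatch and blastulation rates,
#' stage-wise abnormality frequencies, transgene-positive fractions,
#' egg-to-adult survival), reconstructed where only a percentage and N were
#' printed by round-half-up of percent x N. The reconstruction rule is
#' recorded in the `note` column.
#'
#' @return data.frame with columns panel, group, yes, n, pct_printed, note.
#' @export
printed_counts <- function() {
  path <- system.file("extdata", "printed_counts.tsv",
                      package = "embryoploidy", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "")
}
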