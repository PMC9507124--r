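# Dosage banding, arm calls, transgene presence, sex, and ploidy verdicts.

DOSAGE_STATES <- c("ABSENT", "HEMIZYGOUS", "DISOMIC", "AMPLIFIED")

#' Classify a percent depth into a dosage band
#'
#' Bands are midpoint cuts between the nominal anchors 0 / 50 / 100 / 150%
#' of mean genome depth, half-open on the right:
#' ABSENT `[0, 25)`, HEMIZYGOUS `[25, 75)`, DISOMIC `[75, 125)`,
#' AMPLIFIED `[125, Inf)`. The banding is a partition of `[0, Inf)`:
#' every non-negative value maps to exactly one state.
#'
#' @param percent_depth Non-negative numeric (vectorized).
#' @return Character vector of dosage states.
#' @export
classify_gene_dosage <- function(percent_depth) {
  if (!is.numeric(percent_depth) || any(is.na(percent_depth))) {
    stop_bad("percent_depth must be numeric and non-missing")
  }
  if (any(percent_depth < 0)) stop_bad("percent_depth must be >= 0")
  as.character(cut(percent_depth, breaks = c(0, 25, 75, 125, Inf),
                   labels = DOSAGE_STATES, right = FALSE))
}

#' Majority-vote dosage call for one chromosome arm
#'
#' The arm's five marker genes vote; "multiple genes" agreeing is
#' operationalized as a strict majority (>= 3 of 5, concordance >= 0.6).
#' Below that the arm is flagged `ambiguous`.
#'
#' @param gene_states Character vector of exactly five dosage states.
#' @param arm Arm name carried into the result.
#' @return An `ArmCall`: list(arm, state, per_gene, concordance).
#' @export
call_arm_dosage <- function(gene_states, arm = NA_character_) {
  if (length(gene_states) != 5L) {
    stop_bad("an arm call needs exactly five gene states, got ",
             length(gene_states))
  }
  if (!all(gene_states %in% DOSAGE_STATES)) {
    stop_bad("unknown dosage state: ",
             paste(setdiff(gene_states, DOSAGE_STATES), collapse = ", "))
  }
  counts <- table(factor(gene_states, levels = DOSAGE_STATES))
  top <- max(counts)
  structure(list(
    arm = arm,
    state = if (top >= 3L) names(counts)[which.max(counts)] else "ambiguous",
    per_gene = gene_states,
    concordance = top / 5
  ), class = "ArmCall")
}

#' @export
print.ArmCall <- function(x, ...) {
  cat(sprintf("ArmCall %s: %s (concordance %.1f)\n", x$arm, x$state,
              x$concordance))
  invisible(x)
}

#' Transgene presence from depth
#'
#' Mirrors the sequencing-based transgene check: the transgene is called
#' present when its mean depth is meaningful (percent depth at or above the
#' ABSENT/HEMIZYGOUS cut, default 25%) AND reads are distributed evenly
#' across its whole length (at least `evenness_threshold` of 10 equal bins
#' have nonzero mean depth, default 9 of 10). The evenness clause guards
#' against spurious pile-ups in a few bins mimicking presence.
#'
#' @param profile A `DepthProfile`.
#' @param transgene Interval list (seqname, start, end), e.g.
#'   [transgene_interval()].
#' @param genome_mean Mean genome depth (> 0).
#' @param percent_threshold Presence cut on percent depth (default 25).
#' @param evenness_threshold Minimum fraction of nonzero bins (default 0.9).
#' @param n_bins Number of equal-length bins (default 10).
#' @return list(present, evenness, percent).
#' @export
call_transgene_presence <- function(profile, transgene, genome_mean,
                                    percent_threshold = 25,
                                    evenness_threshold = 0.9, n_bins = 10) {
  if (!is.numeric(genome_mean) || genome_mean <= 0) {
    stop_bad("undefined normalization: mean genome depth must be > 0")
  }
  tr <- profile$tracks[[transgene$seqname]]
  if (is.null(tr)) stop_bad("profile missing transgene sequence ",
                            transgene$seqname)
  x <- tr[(transgene$start + 1):transgene$end]
  L <- length(x)
  if (L < n_bins) stop_bad("transgene shorter than ", n_bins, " bp")
  edges <- floor(L * (0:n_bins) / n_bins)
  bin_means <- vapply(seq_len(n_bins), function(b) {
    mean(x[(edges[b] + 1):edges[b + 1]])
  }, numeric(1))
  percent <- 100 * mean(x) / genome_mean
  evenness <- mean(bin_means > 0)
  list(present = percent >= percent_threshold &&
         evenness >= evenness_threshold,
       evenness = evenness, percent = percent)
}

#' Infer embryo sex from the Y and X arm calls
#'
#' Male: Y material present (HEMIZYGOUS or DISOMIC band) with a hemizygous X.
#' Female: no Y material with X in the DISOMIC band (true diploid XX, or a
#' maternal-only haploid whose single X self-normalizes to ~100%).
#' Anything else (including ambiguous arm calls) is undetermined.
#'
#' @param y_arm,x_arm `ArmCall`s for the Y and X arms.
#' @return `"male"`, `"female"` or `"undetermined"`.
#' @export
infer_sex <- function(y_arm, x_arm) {
  y <- y_arm$state
  x <- x_arm$state
  if (y %in% c("HEMIZYGOUS", "DISOMIC") && identical(x, "HEMIZYGOUS")) {
    "male"
  } else if (identical(y, "ABSENT") && identical(x, "DISOMIC")) {
    "female"
  } else {
    "undetermined"
  }
}

#' Embryo ploidy verdict from arm calls and paternal markers
#'
#' Because percent depth is self-relative (a haploid genome reads ~100%
#' everywhere), haploidy is only diagnosable through declared paternal-only
#' markers — by default the transgene and the Y:
#' \itemize{
#'   \item diploid: transgene present and every non-sex arm DISOMIC;
#'   \item haploid: every paternal marker absent and every non-sex arm
#'     DISOMIC;
#'   \item segmental_aneuploid: some non-sex arm HEMIZYGOUS or ABSENT while at
#'     least one paternal marker is present;
#'   \item ambiguous: anything else.
#' }
#' Sex arms (X, Y) are excluded from the deviation test: a hemizygous X is
#' dosage-normal in males.
#'
#' @param arm_calls Named list of `ArmCall`s covering all nuclear arms.
#' @param transgene Presence triple from [call_transgene_presence()].
#' @param paternal_markers Paternal-only signal names; subset of
#'   `c("egfp", "Y")`.
#' @param embryo_id Identifier carried into the call.
#' @param transgene_interval_name Sequence name of the transgene (reporting).
#' @return A `PloidyCall`: list(embryo_id, transgene_present,
#'   transgene_evenness, transgene_percent, sex, ploidy, arm_calls).
#' @export
call_ploidy <- function(arm_calls, transgene, paternal_markers = c("egfp", "Y"),
                        embryo_id = NA_character_) {
  arms <- vapply(arm_calls, function(a) a$arm, character(1))
  names(arm_calls) <- arms
  need <- sub("^chr", "", NUCLEAR_ARMS)
  have <- sub("^chr", "", arms)
  if (!all(need %in% have)) {
    stop_bad("missing arm call(s): ",
             paste(setdiff(need, have), collapse = ", "))
  }
  get_arm <- function(a) arm_calls[[arms[match(a, have)]]]
  autosomes <- setdiff(need, c("X", "Y"))
  auto_states <- vapply(autosomes, function(a) get_arm(a)$state, character(1))

  paternal_markers <- sub("^chr", "", paternal_markers)
  marker_present <- vapply(paternal_markers, function(m) {
    if (m == "egfp") isTRUE(transgene$present)
    else !get_arm(m)$state %in% c("ABSENT", "ambiguous")
  }, logical(1))
  marker_absent <- vapply(paternal_markers, function(m) {
    if (m == "egfp") !isTRUE(transgene$present)
    else identical(get_arm(m)$state, "ABSENT")
  }, logical(1))

  all_disomic <- all(auto_states == "DISOMIC")
  ploidy <- if (isTRUE(transgene$present) && all_disomic) {
    "diploid"
  } else if (all(marker_absent) && all_disomic) {
    "haploid"
  } else if (any(auto_states %in% c("HEMIZYGOUS", "ABSENT")) &&
             any(marker_present)) {
    "segmental_aneuploid"
  } else {
    "ambiguous"
  }
  structure(list(
    embryo_id = embryo_id,
    transgene_present = isTRUE(transgene$present),
    transgene_evenness = transgene$evenness,
    transgene_percent = transgene$percent,
    sex = infer_sex(get_arm("Y"), get_arm("X")),
    ploidy = ploidy,
    arm_calls = arm_calls
  ), class = "PloidyCall")
}

#' @export
print.PloidyCall <- function(x, ...) {
  cat(sprintf("PloidyCall <%s>: %s, sex %s, transgene %s (%.1f%%, evenness %.1f)\n",
              x$embryo_id, x$ploidy, x$sex,
              if (x$transgene_present) "present" else "absent",
              x$transgene_percent, x$transgene_evenness))
  for (a in x$arm_calls) {
    cat(sprintf("  %-6s %-11s concordance %.1f\n", a$arm, a$state,
                a$concordance))
  }
  invisible(x)
}

#' Full per-embryo verdict from a depth profile
#'
#' Runs the whole caller: mean genome depth, per-gene percent depths, dosage
#' banding, per-arm majority votes, transgene presence, sex, ploidy class,
#' and the mitochondrially normalized depth ratio.
#'
#' @param profile A `DepthProfile`.
#' @param layout A `GenomeLayout` (its `genes` are the marker annotation).
#' @param paternal_markers Passed to [call_ploidy()].
#' @param percent_threshold,evenness_threshold Passed to
#'   [call_transgene_presence()].
#' @return A `PloidyCall` with attached `$gene_summaries` data.frame and
#'   `$mito_ratio`.
#' @export
call_embryo <- function(profile, layout, paternal_markers = c("egfp", "Y"),
                        percent_threshold = 25, evenness_threshold = 0.9) {
  gm <- mean_genome_depth(profile, layout)
  if (gm <= 0) stop_bad("undefined normalization: mean genome depth is zero")
  summ <- compute_gene_summaries(profile, layout$genes, gm)
  summ$state <- classify_gene_dosage(summ$percent_depth)
  arm_calls <- lapply(nuclear_arms(layout), function(arm) {
    call_arm_dosage(summ$state[summ$seqname == arm],
                    arm = sub("^chr", "", arm))
  })
  tg <- call_transgene_presence(profile, transgene_interval(layout), gm,
                                percent_threshold = percent_threshold,
                                evenness_threshold = evenness_threshold)
  call <- call_ploidy(arm_calls, tg, paternal_markers = paternal_markers,
                      embryo_id = profile$embryo_id)
  call$gene_summaries <- summ
  call$mean_genome_depth <- gm
  call$mito_ratio <- tryCatch(mito_normalized_depth(profile, layout),
                              error = function(e) NA_real_)
  call
}

#' Gene-by-embryo percent-depth matrix
#'
#' Convenience for heatmap-style summaries: rows are marker genes, columns
#' are embryos, entries are percent depth.
#'
#' @param calls List of `PloidyCall`s from [call_embryo()].
#' @return Numeric matrix (genes x embryos).
#' @export
percent_depth_matrix <- function(calls) {
  stopifnot(length(calls) > 0)
  genes <- calls[[1]]$gene_summaries$gene
  m <- vapply(calls, function(cl) cl$gene_summaries$percent_depth,
              numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes,
                              vapply(calls, `[[`, character(1), "embryo_id")))
  m
}
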