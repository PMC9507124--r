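# Karyotypes: per-sequence copy numbers for one embryo.

#' Construct a karyotype
#'
#' A karyotype assigns an integer copy number to every layout sequence, plus a
#' depth multiplier for the mitochondrion (mitochondrial copy number per cell
#' is orders of magnitude above nuclear and is modeled as a free scale).
#' Copies are interpreted against the diploid baseline: depth scales as
#' `copies / 2`.
#'
#' @param copies Named integer vector: sequence name -> copy number. Nuclear
#'   arms must be in 0..3; the negative control is forced to 0.
#' @param mito_scale Positive depth multiplier for the mitochondrion relative
#'   to one nuclear copy (default 100: mitochondrial depth far above nuclear).
#' @param label Free-text label (e.g. "diploid_xy").
#' @return A `Karyotype` object.
#' @export
karyotype <- function(copies, mito_scale = 100, label = "custom") {
  if (!is.numeric(copies) || is.null(names(copies))) {
    stop_bad("'copies' must be a named numeric vector")
  }
  if (any(copies < 0) || any(copies != round(copies))) {
    stop_bad("copy numbers must be non-negative integers")
  }
  check_scalar_number(mito_scale, "mito_scale", positive = TRUE)
  structure(list(copies = round(copies), mito_scale = mito_scale,
                 label = label),
            class = "Karyotype")
}

#' Standard karyotype presets
#'
#' Presets for the embryo classes the dosage analysis distinguishes:
#' \describe{
#'   \item{diploid_xy}{male diploid: X = 1, Y = 1, autosomes = 2.}
#'   \item{diploid_xx}{female diploid: X = 2, Y = 0, autosomes = 2.}
#'   \item{haploid_maternal}{maternal-only haploid: every maternal arm at 1
#'     copy, Y = 0, transgene = 0 (both paternal markers absent).}
#'   \item{arm_loss}{segmental aneuploid: diploid female having lost one copy
#'     of `lost_arm` (default chr2L).}
#' }
#' Diploid presets carry `transgene_copies` copies of the transgene (default
#' 1: fathers homozygous for the transgene give every diploid offspring one
#' copy); haploids always carry 0.
#'
#' @param label One of `"diploid_xy"`, `"diploid_xx"`, `"haploid_maternal"`,
#'   `"arm_loss"`.
#' @param transgene_copies Transgene copies for diploid presets.
#' @param lost_arm Arm losing one copy for the `arm_loss` preset.
#' @param mito_scale Passed to [karyotype()].
#' @return A `Karyotype`.
#' @export
karyotype_preset <- function(label = c("diploid_xy", "diploid_xx",
                                       "haploid_maternal", "arm_loss"),
                             transgene_copies = 1, lost_arm = "chr2L",
                             mito_scale = 100) {
  label <- match.arg(label)
  base <- c(chrY = 0, chrX = 2, chr2L = 2, chr2R = 2, chr3L = 2, chr3R = 2,
            chr4 = 2, chrM = 1, egfp = transgene_copies, neg_control = 0)
  copies <- switch(label,
    diploid_xy = { base[["chrX"]] <- 1; base[["chrY"]] <- 1; base },
    diploid_xx = base,
    haploid_maternal = {
      base[NUCLEAR_ARMS] <- 1; base[["chrY"]] <- 0; base[["egfp"]] <- 0; base
    },
    arm_loss = {
      if (!lost_arm %in% NUCLEAR_ARMS) stop_bad("unknown arm: ", lost_arm)
      base[[lost_arm]] <- base[[lost_arm]] - 1; base
    })
  karyotype(copies, mito_scale = mito_scale, label = label)
}

#' @export
print.Karyotype <- function(x, ...) {
  cat("Karyotype <", x$label, "> mito_scale=", x$mito_scale, "\n", sep = "")
  print(x$copies)
  invisible(x)
}

#' Closed-form expected percent depth for a sequence
#'
#' Noise-free expectation of the percent-depth statistic for genes on
#' `seqname`: `100 * copies(seqname) / weighted-mean nuclear copies`, where
#' the weighted mean is over nuclear-arm lengths (the genome-mean
#' denominator). This is the analytic oracle against which simulated profiles
#' are checked.
#'
#' @param layout A `GenomeLayout`.
#' @param kt A `Karyotype`.
#' @param seqname Sequence name(s).
#' @return Numeric percent-depth expectation(s).
#' @export
expected_percent_depth <- function(layout, kt, seqname) {
  arms <- nuclear_arms(layout)
  lens <- stats::setNames(layout$sequences$length, layout$sequences$name)
  miss <- setdiff(c(arms, seqname), names(kt$copies))
  if (length(miss)) stop_bad("karyotype missing sequences: ",
                             paste(miss, collapse = ", "))
  mean_copies <- sum(lens[arms] * kt$copies[arms]) / sum(lens[arms])
  if (mean_copies <= 0) stop_bad("all nuclear copies are zero")
  100 * unname(kt$copies[seqname]) / mean_copies
}
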