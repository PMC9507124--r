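# Independent oracles and small fixtures used across the suite.

# Two-sided Fisher p by exhaustive enumeration of the hypergeometric support:
# sum the probability of every table (same margins) whose probability is at
# most that of the observed table.
fisher_enumeration_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-squared closed form for a 2x2 table.
pearson_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) assignments
# of the pooled observations to the first sample (tie-free inputs only).
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_stat(seq_len(n1))
  center <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_stat)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}

# A minimal unvalidated layout for unit tests of the depth statistics:
# arbitrary arms/lengths, no marker genes unless supplied.
toy_layout <- function(arm_lengths, mito_length = 100, transgene_length = 50) {
  seqs <- data.frame(
    name = c(names(arm_lengths), "chrM", "egfp", "neg_control"),
    length = c(unname(arm_lengths), mito_length, transgene_length, 714L),
    role = c(rep("nuclear_arm", length(arm_lengths)), "mitochondrion",
             "transgene", "negative_control"),
    stringsAsFactors = FALSE
  )
  structure(list(sequences = seqs,
                 genes = data.frame(gene = character(), seqname = character(),
                                    start = integer(), end = integer()),
                 baseline_copy = stats::setNames(
                   rep(2L, nrow(seqs)), seqs$name),
                 seed = 0L),
            class = "GenomeLayout")
}

# Constant-depth profile over a toy layout.
toy_profile <- function(layout, depths, embryo_id = "toy") {
  tracks <- lapply(stats::setNames(seq_len(nrow(layout$sequences)),
                                   layout$sequences$name), function(i) {
    rep(depths[[layout$sequences$name[i]]] %||% 0,
        layout$sequences$length[i])
  })
  depth_profile(embryo_id, tracks, layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
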