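# Depth ingestion and the percent-depth statistic.
#
# Coordinate convention: 0-based, half-open everywhere internally; BED and
# bedGraph files keep their native convention at I/O. Zero-depth positions
# are real zeros: bedGraph gaps are densified to 0 on read.

#' Read a 4-column bedGraph into a dense depth profile
#'
#' Intervals (chrom, 0-based start, half-open end, depth) may appear in any
#' order but must not overlap. Positions not covered by any interval get
#' depth 0; an empty file yields an all-zero profile.
#'
#' @param path bedGraph path.
#' @param layout A `GenomeLayout` declaring sequence names and lengths.
#' @param embryo_id Identifier for the returned profile (default: file name).
#' @return A `DepthProfile` with one dense track per layout sequence.
#' @export
read_depth_bedgraph <- function(path, layout,
                                embryo_id = sub("\\.[^.]*$", "", basename(path))) {
  stopifnot(inherits(layout, "GenomeLayout"))
  tracks <- lapply(stats::setNames(layout$sequences$length,
                                   layout$sequences$name), numeric)
  if (!file.exists(path)) stop_bad("no such file: ", path)
  if (file.size(path) == 0) {
    return(depth_profile(embryo_id, tracks, layout))
  }
  nf <- utils::count.fields(path, sep = "")
  if (!is.null(nf) && any(nf != 4L)) {
    stop_bad("malformed bedGraph line ", which(nf != 4L)[1], " in ", path,
             " (expected 4 fields)")
  }
  d <- utils::read.table(path, header = FALSE, sep = "",
                         col.names = c("chrom", "start", "end", "depth"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (nrow(d) == 0) return(depth_profile(embryo_id, tracks, layout))
  bad <- which(d$depth < 0)
  if (length(bad)) stop_bad("negative depth at line ", bad[1], " in ", path)
  bad <- which(d$start < 0 | d$start >= d$end |
               d$start != round(d$start) | d$end != round(d$end))
  if (length(bad)) stop_bad("invalid interval at line ", bad[1], " in ", path)
  unknown <- setdiff(unique(d$chrom), layout$sequences$name)
  if (length(unknown)) {
    stop_bad("bedGraph names unknown sequence(s): ",
             paste(unknown, collapse = ", "))
  }
  for (nm in unique(d$chrom)) {
    L <- seq_length(layout, nm)
    di <- d[d$chrom == nm, , drop = FALSE]
    if (any(di$end > L)) {
      stop_bad("interval beyond end of ", nm, " (", L, " bp) at line ",
               which(d$chrom == nm)[which(di$end > L)[1]])
    }
    o <- order(di$start)
    di <- di[o, , drop = FALSE]
    if (nrow(di) > 1L) {
      ov <- which(di$end[-nrow(di)] > di$start[-1L])
      if (length(ov)) {
        i <- ov[1]
        stop_bad(sprintf(
          "overlapping intervals on %s: [%d,%d) and [%d,%d)",
          nm, di$start[i], di$end[i], di$start[i + 1], di$end[i + 1]))
      }
    }
    w <- as.integer(di$end - di$start)
    tr <- tracks[[nm]]
    tr[sequence(w, from = as.integer(di$start) + 1L)] <- rep(di$depth, w)
    tracks[[nm]] <- tr
  }
  depth_profile(embryo_id, tracks, layout)
}

#' Read marker-gene intervals from a BED file
#'
#' Requires at least 4 columns (chrom, start, end, name); score and strand
#' are accepted and discarded (depth is strandless).
#'
#' @param path BED path.
#' @param layout A `GenomeLayout` used to validate sequence names and bounds.
#' @return data.frame with columns gene, seqname, start, end (0-based
#'   half-open).
#' @export
read_annotation_bed <- function(path, layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop_bad("BED must have >= 4 columns")
  out <- data.frame(gene = as.character(d[[4]]), seqname = as.character(d[[1]]),
                    start = as.integer(d[[2]]), end = as.integer(d[[3]]),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$seqname), layout$sequences$name)
  if (length(unknown)) stop_bad("BED names unknown sequence(s): ",
                                paste(unknown, collapse = ", "))
  if (any(out$start >= out$end) || any(out$start < 0)) {
    bad <- which(out$start >= out$end | out$start < 0)[1]
    stop_bad("invalid BED interval at line ", bad, " (start >= end)")
  }
  lens <- stats::setNames(layout$sequences$length, layout$sequences$name)
  if (any(out$end > lens[out$seqname])) {
    stop_bad("BED interval beyond declared sequence length")
  }
  if (anyDuplicated(out$gene)) {
    stop_bad("duplicate gene name in BED: ",
             out$gene[anyDuplicated(out$gene)])
  }
  out
}

#' Mean genome depth of a profile
#'
#' Length-weighted mean of per-position depth over the nuclear-arm sequences
#' only. The mitochondrion, transgene and negative control are excluded: the
#' mitochondrion is an independent normalizer at a free (high) copy number and
#' the transgene is a query, so either would distort a short synthetic
#' genome's denominator.
#'
#' @param profile A `DepthProfile`.
#' @param layout A `GenomeLayout`.
#' @return Non-negative scalar.
#' @export
mean_genome_depth <- function(profile, layout) {
  arms <- nuclear_arms(layout)
  miss <- setdiff(arms, names(profile$tracks))
  if (length(miss)) stop_bad("profile missing arms: ",
                             paste(miss, collapse = ", "))
  total_len <- sum(lengths(profile$tracks[arms]))
  if (total_len == 0) stop_bad("total nuclear length is zero")
  sum(vapply(profile$tracks[arms], sum, numeric(1))) / total_len
}

#' Per-gene mean depth and percent depth
#'
#' For each gene, computes the mean depth across the gene and the percent
#' depth: 100 x (mean gene depth) / (mean genome depth) — the dosage
#' statistic. Gene order is preserved.
#'
#' @param profile A `DepthProfile`.
#' @param genes data.frame of gene intervals (gene, seqname, start, end), as
#'   in `layout$genes` or from [read_annotation_bed()].
#' @param genome_mean Mean genome depth (> 0), from [mean_genome_depth()].
#' @return data.frame `GeneDepthSummary`: gene, seqname, mean_depth,
#'   percent_depth.
#' @export
compute_gene_summaries <- function(profile, genes, genome_mean) {
  if (!is.numeric(genome_mean) || length(genome_mean) != 1L ||
      genome_mean <= 0) {
    stop_bad("undefined normalization: mean genome depth must be > 0")
  }
  mean_depth <- vapply(seq_len(nrow(genes)), function(i) {
    tr <- profile$tracks[[genes$seqname[i]]]
    if (is.null(tr)) stop_bad("profile missing sequence ", genes$seqname[i])
    mean(tr[(genes$start[i] + 1):genes$end[i]])
  }, numeric(1))
  data.frame(gene = genes$gene, seqname = genes$seqname,
             mean_depth = mean_depth,
             percent_depth = 100 * mean_depth / genome_mean,
             stringsAsFactors = FALSE)
}

#' Mitochondrially normalized genome depth
#'
#' Ratio of the mean nuclear genome depth to the mean mitochondrial depth.
#' Because mitochondrial copy number per embryo should be unaffected by
#' chromosome-loss events, this ratio tracks genuine genome-wide depth
#' deficits independent of sequencing input. Scale-invariant: multiplying all
#' depths by a constant leaves it unchanged.
#'
#' @param profile A `DepthProfile`.
#' @param layout A `GenomeLayout`.
#' @return Positive scalar.
#' @export
mito_normalized_depth <- function(profile, layout) {
  mito <- seq_by_role(layout, "mitochondrion")
  tr <- profile$tracks[[mito]]
  if (is.null(tr)) stop_bad("profile missing mitochondrial track")
  m <- mean(tr)
  if (m <= 0) stop_bad("mitochondrial depth is zero; ratio undefined")
  mean_genome_depth(profile, layout) / m
}
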