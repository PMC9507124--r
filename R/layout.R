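# Miniature genome layout: chromosome arms, marker genes, auxiliary sequences.

#' Default relative arm lengths for the miniature genome
#'
#' Relative sizes mirror the proportions of the *D. simulans* (droSim1)
#' assembly: the five major arms (X, 2L, 2R, 3L, 3R) carry nearly all the
#' sequence, while the dot (4th) chromosome and the assembled Y are small.
#' These proportions matter: the percent-depth statistic normalizes each gene
#' by the genome-wide mean depth, so the genome must be predominantly
#' autosomal for hemizygous X/Y genes in males to read near the nominal 50%
#' band and for maternal-only haploids to self-normalize near 100%.
#'
#' @format Named numeric vector of length 7 (fractions of the largest arm).
#' @export
default_arm_weights <- c(
  chrY = 0.10, chrX = 0.63, chr2L = 0.84, chr2R = 0.77,
  chr3L = 0.87, chr3R = 1.00, chr4 = 0.10
)

NUCLEAR_ARMS <- names(default_arm_weights)

#' Build the miniature reference genome layout
#'
#' Constructs the synthetic multi-chromosome reference used throughout the
#' package: seven nuclear arms (Y, X, 2L, 2R, 3L, 3R, 4), each carrying five
#' evenly spaced, non-overlapping marker genes; a mitochondrial sequence; an
#' `egfp` transgene on its own contig (the paternal marker); and a randomized
#' 714-bp negative-control sequence that never receives reads.
#'
#' @param arm_length_bp Length in bp of the largest arm (3R); other arms are
#'   scaled by `arm_weights`.
#' @param gene_length_bp Length in bp of each marker gene. Five genes must fit
#'   in every arm with positive gaps.
#' @param seed Integer seed (used when base sequences are materialized, e.g.
#'   by [write_genome_fasta()]).
#' @param arm_weights Named relative lengths for the seven arms; defaults to
#'   [default_arm_weights].
#' @param mito_length_bp Mitochondrial genome length (default 19,500 bp).
#' @param transgene_length_bp Transgene length (default 720 bp).
#' @return A `GenomeLayout`: list with `sequences` (name, length, role),
#'   `genes` (gene, seqname, start, end; 0-based half-open), `baseline_copy`
#'   (copies in the diploid-female reference state) and `seed`.
#' @examples
#' layout <- build_layout(100000, 1000, seed = 0)
#' nrow(layout$genes)  # 35 marker genes
#' @export
build_layout <- function(arm_length_bp = 100000, gene_length_bp = 1000,
                         seed = 0, arm_weights = default_arm_weights,
                         mito_length_bp = 19500, transgene_length_bp = 720) {
  check_scalar_number(arm_length_bp, "arm_length_bp", positive = TRUE, integer = TRUE)
  check_scalar_number(gene_length_bp, "gene_length_bp", positive = TRUE, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  if (!is.numeric(arm_weights) || is.null(names(arm_weights)) ||
      !setequal(names(arm_weights), NUCLEAR_ARMS) || any(arm_weights <= 0)) {
    stop_bad("'arm_weights' must be positive and named for the seven arms: ",
             paste(NUCLEAR_ARMS, collapse = ", "))
  }
  arm_weights <- arm_weights[NUCLEAR_ARMS]
  arm_len <- as.integer(round(arm_weights * arm_length_bp))

  genes <- vector("list", length(NUCLEAR_ARMS))
  for (i in seq_along(NUCLEAR_ARMS)) {
    arm <- NUCLEAR_ARMS[i]
    L <- arm_len[i]
    if (5L * gene_length_bp >= L) {
      stop_bad(sprintf(
        "five genes of %d bp cannot fit in arm %s (%d bp) with positive gaps",
        gene_length_bp, arm, L))
    }
    # five evenly spaced genes: gaps of equal size between/around them
    gap <- (L - 5L * gene_length_bp) / 6
    starts <- as.integer(round(gap * seq_len(5) + gene_length_bp * (0:4)))
    genes[[i]] <- data.frame(
      gene = sprintf("%s_g%d", sub("^chr", "", arm), seq_len(5)),
      seqname = arm,
      start = starts,
      end = starts + as.integer(gene_length_bp),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, genes)

  sequences <- data.frame(
    name = c(NUCLEAR_ARMS, "chrM", "egfp", "neg_control"),
    length = c(arm_len, as.integer(mito_length_bp),
               as.integer(transgene_length_bp), 714L),
    role = c(rep("nuclear_arm", 7L), "mitochondrion", "transgene",
             "negative_control"),
    stringsAsFactors = FALSE
  )
  baseline <- c(chrY = 0L, chrX = 2L, chr2L = 2L, chr2R = 2L, chr3L = 2L,
                chr3R = 2L, chr4 = 2L, chrM = 1L, egfp = 0L, neg_control = 0L)

  layout <- structure(
    list(sequences = sequences, genes = genes, baseline_copy = baseline,
         seed = as.integer(seed)),
    class = "GenomeLayout"
  )
  validate_layout(layout)
  layout
}

#' Validate a GenomeLayout's structural invariants
#'
#' Checks that gene intervals lie within their sequence, genes on a sequence
#' do not overlap, each nuclear arm carries exactly five genes, and exactly
#' one transgene, mitochondrion and negative control are present.
#'
#' @param layout A `GenomeLayout`.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  seqs <- layout$sequences
  genes <- layout$genes
  for (role in c("mitochondrion", "transgene", "negative_control")) {
    if (sum(seqs$role == role) != 1L) {
      stop_bad("layout must contain exactly one ", role, " sequence")
    }
  }
  if (seqs$length[seqs$role == "negative_control"] != 714L) {
    stop_bad("negative-control sequence must be 714 bp")
  }
  if (anyDuplicated(genes$gene)) stop_bad("duplicate gene names in layout")
  lens <- stats::setNames(seqs$length, seqs$name)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$seqname %in% seqs$name) stop_bad("gene on unknown sequence: ", g$gene)
    if (g$start < 0 || g$end > lens[[g$seqname]] || g$start >= g$end) {
      stop_bad("gene interval outside its sequence: ", g$gene)
    }
  }
  for (s in unique(genes$seqname)) {
    gs <- genes[genes$seqname == s, ]
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1L && any(gs$end[-nrow(gs)] > gs$start[-1L])) {
      stop_bad("overlapping genes on ", s)
    }
  }
  arms <- seqs$name[seqs$role == "nuclear_arm"]
  n_per_arm <- table(factor(genes$seqname, levels = arms))
  if (any(n_per_arm != 5L)) stop_bad("each nuclear arm must carry five genes")
  invisible(layout)
}

#' Names of the nuclear-arm sequences in a layout
#' @param layout A `GenomeLayout`.
#' @return Character vector of arm sequence names.
#' @export
nuclear_arms <- function(layout) {
  layout$sequences$name[layout$sequences$role == "nuclear_arm"]
}

seq_length <- function(layout, name) {
  i <- match(name, layout$sequences$name)
  if (is.na(i)) stop_bad("unknown sequence: ", name)
  layout$sequences$length[i]
}

seq_by_role <- function(layout, role) {
  layout$sequences$name[layout$sequences$role == role]
}

#' Transgene interval of a layout
#' @param layout A `GenomeLayout`.
#' @return List with `seqname`, `start`, `end` (0-based half-open).
#' @export
transgene_interval <- function(layout) {
  tg <- seq_by_role(layout, "transgene")
  list(seqname = tg, start = 0L, end = seq_length(layout, tg))
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", nrow(x$sequences), "sequences,",
      nrow(x$genes), "marker genes\n")
  cat("  nuclear arms:", paste(nuclear_arms(x), collapse = ", "), "\n")
  cat("  total nuclear length:",
      sum(x$sequences$length[x$sequences$role == "nuclear_arm"]), "bp\n")
  invisible(x)
}

#' Write the layout's sequences as FASTA
#'
#' Materializes uppercase random bases for every sequence (seeded by the
#' layout's seed, so re-writing is reproducible) and writes one FASTA record
#' per sequence.
#'
#' @param layout A `GenomeLayout`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(layout, path) {
  seqs <- with_substream(substream_seed(layout$seed, "fasta"), {
    vapply(seq_len(nrow(layout$sequences)), function(i) {
      paste(sample(c("A", "C", "G", "T"), layout$sequences$length[i],
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- layout$sequences$name
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write the layout's marker genes as 6-column BED
#'
#' Coordinates are 0-based half-open (BED native); strand is a "+"
#' placeholder as depth is strandless.
#'
#' @param layout A `GenomeLayout`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(layout, path) {
  g <- layout$genes
  bed <- data.frame(g$seqname, g$start, g$end, g$gene, 0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the layout's sequence manifest as TSV
#'
#' @param layout A `GenomeLayout`.
#' @param path Output TSV path (columns: name, length, role).
#' @return `path`, invisibly.
#' @export
write_sequence_manifest <- function(layout, path) {
  utils::write.table(layout$sequences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sequence manifest written by [write_sequence_manifest()]
#'
#' Reconstructs a `GenomeLayout` from a manifest TSV plus a genes BED. The
#' baseline copy state is the diploid female reference.
#'
#' @param manifest_path TSV with columns name, length, role.
#' @param genes_bed_path BED of marker genes (may be `NULL` for no genes).
#' @return A `GenomeLayout`.
#' @export
read_layout <- function(manifest_path, genes_bed_path = NULL) {
  seqs <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("name", "length", "role") %in% names(seqs))) {
    stop_bad("manifest must have columns name, length, role")
  }
  genes <- data.frame(gene = character(), seqname = character(),
                      start = integer(), end = integer())
  layout <- structure(
    list(sequences = seqs, genes = genes,
         baseline_copy = stats::setNames(
           ifelse(seqs$role == "nuclear_arm", 2L,
                  ifelse(seqs$role == "mitochondrion", 1L, 0L)), seqs$name),
         seed = 0L),
    class = "GenomeLayout"
  )
  if (!is.null(genes_bed_path)) {
    layout$genes <- read_annotation_bed(genes_bed_path, layout)
  }
  layout
}
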