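# Per-embryo depth-profile simulation and bedGraph output.

#' Construct a depth profile
#'
#' @param embryo_id Identifier.
#' @param tracks Named list of non-negative numeric vectors, one per layout
#'   sequence, length equal to the sequence length.
#' @param layout Optional `GenomeLayout` to validate names/lengths against.
#' @return A `DepthProfile`.
#' @export
depth_profile <- function(embryo_id, tracks, layout = NULL) {
  if (!is.list(tracks) || is.null(names(tracks))) {
    stop_bad("'tracks' must be a named list")
  }
  for (nm in names(tracks)) {
    if (any(tracks[[nm]] < 0)) stop_bad("negative depth on ", nm)
  }
  if (!is.null(layout)) {
    for (nm in names(tracks)) {
      if (length(tracks[[nm]]) != seq_length(layout, nm)) {
        stop_bad("track length mismatch for ", nm)
      }
    }
  }
  structure(list(embryo_id = as.character(embryo_id), tracks = tracks),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat("DepthProfile <", x$embryo_id, ">:", length(x$tracks), "sequences,",
      sum(lengths(x$tracks)), "positions\n")
  invisible(x)
}

#' Simulate a per-position depth profile for one embryo
#'
#' Emulates the depth-of-coverage track produced by upstream alignment and
#' `bedtools genomecov`. Under `noise = "none"`, every position of sequence
#' `s` has depth `target_coverage * copies(s) / 2` (the mitochondrion uses
#' `mito_scale` in place of copy number, and copies are relative to the
#' diploid baseline). Under `noise = "poisson"`, each position is an
#' independent Poisson draw with that mean, modelling shot noise in read
#' counts. Sequences at zero copies (e.g. the Y and transgene of a
#' maternal-only haploid, and always the negative control) receive no reads.
#'
#' @param layout A `GenomeLayout`.
#' @param kt A `Karyotype` covering every layout sequence (the negative
#'   control is forced to 0 copies).
#' @param target_coverage Mean depth of a disomic position (> 0).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed; identical seeds give bit-identical profiles.
#' @param embryo_id Identifier stored in the profile.
#' @return A `DepthProfile`.
#' @export
simulate_depth <- function(layout, kt, target_coverage = 50,
                           noise = c("poisson", "none"), seed = 0,
                           embryo_id = kt$label) {
  stopifnot(inherits(layout, "GenomeLayout"), inherits(kt, "Karyotype"))
  noise <- match.arg(noise)
  check_scalar_number(target_coverage, "target_coverage", positive = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)

  copies <- kt$copies
  nc <- seq_by_role(layout, "negative_control")
  copies[nc] <- 0
  miss <- setdiff(layout$sequences$name, names(copies))
  if (length(miss)) {
    stop_bad("karyotype missing sequences: ", paste(miss, collapse = ", "))
  }

  mito <- seq_by_role(layout, "mitochondrion")
  tracks <- with_substream(seed, {
    out <- vector("list", nrow(layout$sequences))
    names(out) <- layout$sequences$name
    for (i in seq_len(nrow(layout$sequences))) {
      nm <- layout$sequences$name[i]
      L <- layout$sequences$length[i]
      mult <- if (nm == mito) kt$mito_scale else copies[[nm]]
      mu <- target_coverage * mult / 2
      out[[nm]] <- if (mu == 0) {
        integer(L)
      } else if (noise == "none") {
        rep.int(mu, L)
      } else {
        stats::rpois(L, mu)
      }
    }
    out
  })
  depth_profile(embryo_id, tracks, layout)
}

#' Write a depth profile as 4-column bedGraph
#'
#' Consecutive equal-depth positions are run-length collapsed into 0-based
#' half-open intervals; zero-depth runs are omitted (readers densify gaps
#' back to depth 0).
#'
#' @param profile A `DepthProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  rows <- lapply(names(profile$tracks), function(nm) {
    r <- rle(as.numeric(profile$tracks[[nm]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = nm, start = starts[keep], end = ends[keep],
               depth = r$values[keep])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) rows <- data.frame(chrom = character(), start = integer(),
                                        end = integer(), depth = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
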