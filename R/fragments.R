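#' Read fragment intervals from BED3 or BEDPE
#'
#' Reads paired-end sequencing fragments (MNase-seq, ATAC-seq, cfDNA) as
#' genomic intervals. Coordinates are 0-based, half-open throughout the
#' package (BED convention): `start` is inclusive, `end` exclusive. BEDPE
#' records are collapsed to the outermost span of the two mates; mates mapped
#' to different chromosomes are rejected with a warning. Gzipped files are
#' read transparently.
#'
#' @param path Path to a BED3 (or wider; extra columns ignored) or BEDPE file.
#' @param dialect `"bed3"` or `"bedpe"`.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `length`,
#'   one row per fragment in input order.
#' @export
read_fragments <- function(path, dialect = c("bed3", "bedpe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) nrl_validation_error(sprintf("file not found: %s", path))
  dt <- fread_maybe_gz(path, colClasses = "character")
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), length = numeric()))
  }
  need <- if (dialect == "bed3") 3L else 6L
  if (ncol(dt) < need) {
    nrl_validation_error(sprintf("%s requires at least %d columns, found %d",
                                 dialect, need, ncol(dt)))
  }
  to_num <- function(col, what) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) | x != floor(x) | x < 0)
    if (length(bad)) {
      nrl_validation_error(sprintf("parse error at line %d: %s '%s' is not a non-negative integer",
                                   bad[1L], what, col[bad[1L]]))
    }
    x
  }
  if (dialect == "bed3") {
    frags <- data.table::data.table(
      chrom = dt[[1L]],
      start = to_num(dt[[2L]], "start"),
      end = to_num(dt[[3L]], "end")
    )
  } else {
    s1 <- to_num(dt[[2L]], "start1"); e1 <- to_num(dt[[3L]], "end1")
    s2 <- to_num(dt[[5L]], "start2"); e2 <- to_num(dt[[6L]], "end2")
    same <- dt[[1L]] == dt[[4L]]
    if (any(!same)) {
      warning(sprintf("rejected %d BEDPE record(s) with mates on different chromosomes",
                      sum(!same)))
    }
    frags <- data.table::data.table(
      chrom = dt[[1L]][same],
      start = pmin(s1, s2)[same],
      end = pmax(e1, e2)[same]
    )
  }
  bad <- which(frags$start >= frags$end)
  if (length(bad)) {
    nrl_validation_error(sprintf("validation error at line %d: start (%d) >= end (%d)",
                                 bad[1L], frags$start[bad[1L]], frags$end[bad[1L]]))
  }
  frags$length <- frags$end - frags$start
  frags[]
}

#' Write fragments to BED3 or BEDPE
#'
#' Tab-separated, no header, 0-based half-open coordinates; a `.gz` suffix
#' triggers gzip compression. The BEDPE dialect writes 10 columns with the
#' two 1 bp fragment endpoints as mates (original mate extents are not
#' retained after collapsing to the outer span), so re-reading reproduces
#' the fragment exactly.
#'
#' @param fragments Fragment table as returned by [read_fragments()].
#' @param path Output path.
#' @param dialect `"bed3"` or `"bedpe"`.
#' @return The path, invisibly.
#' @export
write_fragments <- function(fragments, path, dialect = c("bed3", "bedpe")) {
  dialect <- match.arg(dialect)
  fragments <- validate_fragments(fragments)
  out <- if (dialect == "bed3") {
    fragments[, c("chrom", "start", "end")]
  } else {
    data.table::data.table(
      chrom1 = fragments$chrom, start1 = fragments$start,
      end1 = fragments$start + 1,
      chrom2 = fragments$chrom, start2 = fragments$end - 1,
      end2 = fragments$end,
      name = sprintf("frag%d", seq_len(nrow(fragments))), score = 0L,
      strand1 = "+", strand2 = "-")
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

validate_fragments <- function(fragments) {
  fragments <- data.table::as.data.table(fragments)
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(fragments))) {
    nrl_validation_error("fragments need columns chrom, start, end")
  }
  if (nrow(fragments) && any(fragments$start < 0 | fragments$start >= fragments$end)) {
    nrl_validation_error("fragments must satisfy 0 <= start < end")
  }
  if (!"length" %in% names(fragments)) fragments$length <- fragments$end - fragments$start
  fragments
}

#' Filter fragments by length
#'
#' Retains fragments with `min_len <= length <= max_len`. The default window
#' used by the dyad-based estimators is 100-200 bp: the mononucleosome
#' fraction (about a 147 bp protected footprint plus partial linker).
#'
#' @param fragments Fragment table.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The retained fragments; retained/discarded counts are logged.
#' @export
filter_by_length <- function(fragments, min_len = 100, max_len = 200) {
  if (!(min_len > 0 && min_len <= max_len)) {
    nrl_validation_error("need 0 < min_len <= max_len")
  }
  fragments <- validate_fragments(fragments)
  keep <- fragments$length >= min_len & fragments$length <= max_len
  nrl_log(sprintf("length filter [%g, %g]: retained %d, discarded %d",
                  min_len, max_len, sum(keep), sum(!keep)))
  if (!any(keep)) nrl_log("length filter produced an empty fragment set")
  fragments[keep]
}

#' Construct a dyad track
#'
#' A dyad track holds, per chromosome, a sorted vector of point coordinates:
#' either nucleosome dyads (fragment midpoints) or fragment 5' starts. It is
#' the input to all phasogram-based estimators.
#'
#' @param x A numeric vector (assigned to chromosome `"chr1"`), a named list
#'   of numeric vectors, or a data frame with columns `chrom` and `pos`.
#' @param source `"dyad"` or `"start"`.
#' @return An object of class `dyad_track`.
#' @export
dyad_track <- function(x, source = c("dyad", "start")) {
  source <- match.arg(source)
  positions <- if (is.numeric(x)) {
    list(chr1 = x)
  } else if (is.data.frame(x)) {
    split(as.numeric(x$pos), x$chrom)
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else {
    nrl_validation_error("cannot build a dyad track from this input")
  }
  positions <- positions[order(names(positions))]
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  structure(list(positions = positions, source = source), class = "dyad_track")
}

#' @export
print.dyad_track <- function(x, ...) {
  n <- sum(lengths(x$positions))
  cat(sprintf("<dyad_track> source=%s, %d positions on %d chromosome(s)\n",
              x$source, n, length(x$positions)))
  invisible(x)
}

n_positions <- function(track) sum(lengths(track$positions))

#' Compute nucleosome dyads from fragments
#'
#' The dyad of each fragment is the midpoint between its start and end
#' coordinates, `floor((start + end) / 2)` — deterministic, avoiding half-bp
#' positions. For odd-length fragments this is the unique central base of the
#' half-open interval. Output is sorted per chromosome, so the result does not
#' depend on the input order.
#'
#' @param fragments Fragment table.
#' @return A [dyad_track()] with `source = "dyad"`.
#' @export
compute_dyads <- function(fragments) {
  fragments <- validate_fragments(fragments)
  dyad_track(data.frame(chrom = fragments$chrom,
                        pos = (fragments$start + fragments$end) %/% 2),
             source = "dyad")
}

#' Extract fragment 5' start coordinates
#'
#' For single-end-style phasograms where only the fragment start (nucleosome
#' entry side) is known. Output sorted per chromosome.
#'
#' @param fragments Fragment table.
#' @return A [dyad_track()] with `source = "start"`.
#' @export
fragment_starts <- function(fragments) {
  fragments <- validate_fragments(fragments)
  dyad_track(data.frame(chrom = fragments$chrom, pos = fragments$start),
             source = "start")
}
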