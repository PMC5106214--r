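#' Read a titration table
#'
#' Reads delimited text with header columns `concentration_uM`, `response`
#' and optionally `replicate_id`; curve metadata is supplied as arguments
#' (or via a pipeline manifest).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param ... metadata passed to [titration_curve()].
#' @return A [titration_curve()].
#' @export
read_titration <- function(path, sep = "\t", ...) {
  d <- read.table(path, header = TRUE, sep = sep)
  req <- c("concentration_uM", "response")
  if (!all(req %in% names(d)))
    stop("titration file needs columns: ", paste(req, collapse = ", "))
  rid <- if ("replicate_id" %in% names(d)) d$replicate_id else 1L
  titration_curve(d$concentration_uM, d$response, replicate_id = rid, ...)
}

#' Write a titration curve to delimited text
#' @param curve a [titration_curve()].
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
write_titration <- function(curve, path, sep = "\t") {
  stopifnot(inherits(curve, "titration_curve"))
  write.table(curve$points, path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a sensogram trace
#'
#' Reads delimited text with header columns `time_s`, `signal_nm`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param ... metadata passed to [sensogram_trace()] (`phase`,
#'   `protein_conc_uM`, `template_label`).
#' @return A [sensogram_trace()].
#' @export
read_sensogram <- function(path, sep = "\t", ...) {
  d <- read.table(path, header = TRUE, sep = sep)
  req <- c("time_s", "signal_nm")
  if (!all(req %in% names(d)))
    stop("sensogram file needs columns: ", paste(req, collapse = ", "))
  sensogram_trace(d$time_s, d$signal_nm, ...)
}

#' Write a sensogram trace to delimited text
#' @param trace a [sensogram_trace()].
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
write_sensogram <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "sensogram_trace"))
  write.table(data.frame(time_s = trace$time, signal_nm = trace$signal),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a per-base track
#'
#' Imports a standard bedGraph (0-based half-open intervals) and expands it
#' to per-base arrays over the chromosomes given in `sizes`. Overlapping
#' intervals are an input error.
#'
#' @param path bedGraph file path.
#' @param sizes named numeric vector of chromosome lengths (bp), or a
#'   two-column chrom-sizes file path.
#' @param total_reads total mapped reads for RPM scaling; defaults to the
#'   sum of the track.
#' @param genome genome label.
#' @return A [coverage_track()].
#' @export
read_bedgraph_track <- function(path, sizes, total_reads = NULL,
                                genome = "toy") {
  if (is.character(sizes) && length(sizes) == 1) {
    sz <- read.table(sizes, header = FALSE,
                     col.names = c("chrom", "size"))
    sizes <- setNames(sz$size, sz$chrom)
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!all(as.character(GenomicRanges::seqnames(gr)) %in% names(sizes)))
    stop("bedGraph contains chromosomes absent from the sizes table")
  spl <- split(gr, as.character(GenomicRanges::seqnames(gr)))
  red <- unlist(lapply(spl, function(g)
    sum(IRanges::width(IRanges::reduce(IRanges::ranges(g))))))
  tot <- unlist(lapply(spl, function(g) sum(IRanges::width(g))))
  if (any(red < tot)) stop("overlapping bedGraph intervals are not allowed")
  values <- lapply(names(sizes), function(ch) {
    v <- numeric(sizes[[ch]])
    if (ch %in% names(spl)) {
      g <- spl[[ch]]
      st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
      if (any(en > sizes[[ch]])) stop("interval beyond chromosome end: ", ch)
      sc <- g$score
      for (k in seq_along(st)) v[st[k]:en[k]] <- sc[k]
    }
    v
  })
  names(values) <- names(sizes)
  coverage_track(values, total_reads = total_reads, genome = genome)
}

#' Write a coverage track as bedGraph
#'
#' Run-length compresses each chromosome and writes standard bedGraph
#' (0-based half-open). Zero-valued runs are omitted.
#'
#' @param track a [coverage_track()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  runs <- do.call(rbind, lapply(names(track$values), function(ch) {
    r <- rle(track$values[[ch]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = st[keep], end = en[keep],
               score = r$values[keep])
  }))
  if (is.null(runs)) stop("track is all zero; nothing to write")
  gr <- GenomicRanges::GRanges(
    runs$chrom, IRanges::IRanges(runs$start, runs$end), score = runs$score,
    seqinfo = GenomeInfoDb::Seqinfo(names(track$values),
                                    lengths(track$values)))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read an anchor table
#'
#' Reads a BED-like delimited text table with header columns `name`,
#' `chrom`, `pos` (1-based), `orientation`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param ... passed to [anchor_set()] (`kind`, `exclude`).
#' @return An [anchor_set()].
#' @export
read_anchor_table <- function(path, sep = "\t", ...) {
  d <- read.table(path, header = TRUE, sep = sep,
                  colClasses = c(orientation = "character"))
  anchor_set(d, ...)
}

#' Write an anchor table
#' @param anchors an [anchor_set()].
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
write_anchor_table <- function(anchors, path, sep = "\t") {
  stopifnot(inherits(anchors, "anchor_set"))
  write.table(anchors$entries, path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an ensemble profile to delimited text
#'
#' Columns: `offset_bp`, `summed_signal`, `normalized_signal` (if
#' control-normalized), `n_anchors_covered`.
#'
#' @param profile an [aggregate_at_anchors()] result.
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
write_ensemble_profile <- function(profile, path, sep = "\t") {
  stopifnot(inherits(profile, "ensemble_profile"))
  p <- profile$profile
  names(p)[names(p) == "n_anchors"] <- "n_anchors_covered"
  write.table(p, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
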