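#' Construct a per-base coverage track
#'
#' Per-base ChIP-seq signal for a genome, held as one numeric vector per
#' chromosome (1-based positions). `total_reads` is the number of mapped
#' reads the track was built from, used for reads-per-million scaling.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param total_reads total mapped reads (`> 0`); defaults to the sum of
#'   the values (appropriate for raw read-count tracks).
#' @param genome genome label.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, total_reads = NULL, genome = "toy") {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("coverage values must be non-negative")
  if (is.null(total_reads))
    total_reads <- sum(vapply(values, sum, numeric(1)))
  if (total_reads <= 0) stop("total_reads must be positive")
  structure(list(values = values, total_reads = total_reads,
                 genome = genome, normalized = FALSE),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track (%s): %d chromosomes, %.3g Mb, %s\n",
              x$genome, length(x$values),
              sum(lengths(x$values)) / 1e6,
              if (x$normalized) "RPM-normalized"
              else sprintf("%.3g mapped reads", x$total_reads)))
  invisible(x)
}

#' Chromosome lengths of a coverage track
#' @param track a [coverage_track()].
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(track) lengths(track$values)

#' Reads-per-million normalization
#'
#' Scales every per-base value by `1e6 / total_reads`, the standard
#' sequencing-depth normalization for coverage tracks.
#'
#' @param track a [coverage_track()].
#' @return A normalized `coverage_track` (marked `normalized = TRUE`).
#' @export
rpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$total_reads <= 0) stop("total_reads must be positive")
  out <- track
  out$values <- lapply(track$values, function(v) v * 1e6 / track$total_reads)
  out$normalized <- TRUE
  out
}

#' Construct a subtelomere anchor set
#'
#' Alignment anchors for ensemble (meta-profile) aggregation: one entry per
#' subtelomere, giving the anchor coordinate (1-based) and the direction in
#' which the centromere lies (`"+"` = increasing coordinates, i.e. a
#' left-arm telomere; `"-"` = decreasing, a right arm). Anchors may mark
#' the chromosome end itself or the ARS consensus sequence in the
#' subtelomeric core X element (C-ACS). Entries named in `exclude` are
#' dropped; by default the two telomeres conventionally left out of yeast
#' subtelomere ensembles (TEL01R, TEL13R) are excluded, leaving at most 30
#' of the 32 chromosome ends.
#'
#' @param entries data frame with columns `name`, `chrom`, `pos` (1-based
#'   bp), `orientation` (`"+"` or `"-"`).
#' @param kind `"C_ACS"` (two-sided window) or `"chromosome_end"`
#'   (one-sided window toward the centromere).
#' @param exclude character vector of entry names to drop.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(entries, kind = c("C_ACS", "chromosome_end"),
                       exclude = c("TEL01R", "TEL13R")) {
  kind <- match.arg(kind)
  req <- c("name", "chrom", "pos", "orientation")
  if (!all(req %in% names(entries)))
    stop("entries need columns: ", paste(req, collapse = ", "))
  if (!all(entries$orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  if (any(entries$pos < 1)) stop("anchor positions are 1-based (>= 1)")
  entries <- entries[!entries$name %in% exclude, , drop = FALSE]
  if (nrow(entries) > 32) stop("more than 32 anchors")
  if (anyDuplicated(entries$name)) stop("duplicate anchor names")
  rownames(entries) <- NULL
  structure(list(entries = entries, kind = kind, exclude = exclude),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set (%s): %d anchors (excluded: %s)\n", x$kind,
              nrow(x$entries), paste(x$exclude, collapse = ", ")))
  invisible(x)
}

#' Anchor-aligned ensemble aggregation
#'
#' Builds the subtelomeric meta-profile: for each anchor a window of the
#' coverage track is extracted, oriented so that negative offsets point
#' toward the chromosome end and positive offsets toward the centromere,
#' then summed element-wise across anchors. For `C_ACS` anchors the window
#' is two-sided (`-window .. +window`); for `chromosome_end` anchors it is
#' one-sided (`0 .. window`, toward the centromere). Windows running past a
#' chromosome boundary are truncated and the number of anchors actually
#' covering each offset is recorded.
#'
#' @param track a [coverage_track()].
#' @param anchors an [anchor_set()].
#' @param window half-window (C-ACS) or window (chromosome end) size in bp;
#'   default 14000.
#' @return An object of class `ensemble_profile`: data frame `profile`
#'   with columns `offset_bp`, `summed_signal`, `n_anchors`, plus `window`
#'   and `kind`.
#' @export
aggregate_at_anchors <- function(track, anchors, window = 14000) {
  stopifnot(inherits(track, "coverage_track"), inherits(anchors, "anchor_set"))
  offs <- if (anchors$kind == "C_ACS") seq(-window, window) else seq(0, window)
  total <- numeric(length(offs))
  count <- integer(length(offs))
  for (j in seq_len(nrow(anchors$entries))) {
    a <- anchors$entries[j, ]
    v <- track$values[[a$chrom]]
    if (is.null(v)) stop("anchor chromosome not in track: ", a$chrom)
    if (a$pos > length(v)) stop("anchor beyond chromosome end: ", a$name)
    dir <- if (a$orientation == "+") 1L else -1L
    pos <- a$pos + dir * offs
    ok <- pos >= 1L & pos <= length(v)
    total[ok] <- total[ok] + v[pos[ok]]
    count[ok] <- count[ok] + 1L
  }
  structure(
    list(profile = data.frame(offset_bp = offs, summed_signal = total,
                              n_anchors = count),
         window = window, kind = anchors$kind),
    class = "ensemble_profile"
  )
}

#' @export
print.ensemble_profile <- function(x, ...) {
  p <- x$profile
  cat(sprintf("Ensemble profile (%s, window %d bp): offsets %d..%d\n",
              x$kind, x$window, min(p$offset_bp), max(p$offset_bp)))
  cat(sprintf("  signal total %.4g; %d anchors at fully covered offsets\n",
              sum(p$summed_signal), max(p$n_anchors)))
  if (!is.null(p$normalized_signal))
    cat(sprintf("  control-normalized; mean ratio %.3g\n",
                mean(p$normalized_signal)))
  invisible(x)
}

#' Per-base normalization of an ensemble profile to a control
#'
#' Element-wise ratio of a signal meta-profile to a control (e.g. sir3
#' deletion) meta-profile on the identical offset grid. Offsets where the
#' control is zero are rescued with a pseudocount equal to the smallest
#' positive control value (scale-free policy) and flagged in the
#' `control_zero` column.
#'
#' @param signal,control [aggregate_at_anchors()] results on the same grid.
#' @return The `signal` profile with added `normalized_signal` and
#'   `control_zero` columns.
#' @export
normalize_to_control <- function(signal, control) {
  stopifnot(inherits(signal, "ensemble_profile"),
            inherits(control, "ensemble_profile"))
  if (!identical(signal$profile$offset_bp, control$profile$offset_bp))
    stop("offset grids differ between signal and control profiles")
  ctrl <- control$profile$summed_signal
  zero <- ctrl <= 0
  if (all(zero)) stop("control profile is all zero")
  eps <- min(ctrl[!zero])
  denom <- ifelse(zero, eps, ctrl)
  out <- signal
  out$profile$normalized_signal <- signal$profile$summed_signal / denom
  out$profile$control_zero <- zero
  out
}

#' Delta-CT qPCR fold enrichment
#'
#' Computes ChIP-qPCR fold enrichment with the delta-CT method: for each
#' sample, locus and biological replicate, `E = 2^(CT_ref - CT_target)`
#' normalizes the target locus to a reference gene (default `cup1`)
#' amplified from the same material; per-replicate enrichments are then
#' averaged and expressed relative to the control sample (default
#' `sir3d`). Averaging enrichments per replicate (rather than averaging
#' CTs first) propagates replicate scatter into the reported SD.
#'
#' @param ct data frame with columns `sample`, `locus`, `replicate`, `ct`;
#'   each sample/replicate must include the reference locus.
#' @param reference_gene reference locus name (default `"cup1"`).
#' @param control_sample control sample name (default `"sir3d"`).
#' @return Data frame with one row per sample x locus: mean `enrichment`
#'   (over replicates), `sd_enrichment`, `n_replicates`, and
#'   `fold_vs_control`.
#' @export
qpcr_fold_enrichment <- function(ct, reference_gene = "cup1",
                                 control_sample = "sir3d") {
  req <- c("sample", "locus", "replicate", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  if (!reference_gene %in% ct$locus)
    stop("reference gene not present: ", reference_gene)
  if (!control_sample %in% ct$sample)
    stop("control sample not present: ", control_sample)
  ref <- ct[ct$locus == reference_gene, ]
  tgt <- ct[ct$locus != reference_gene, ]
  key <- function(d) paste(d$sample, d$replicate, sep = "\r")
  ref_ct <- setNames(ref$ct, key(ref))
  miss <- !key(tgt) %in% names(ref_ct)
  if (any(miss))
    stop("missing reference CT for: ",
         paste(unique(tgt$sample[miss]), collapse = ", "))
  tgt$enrich <- 2^(ref_ct[key(tgt)] - tgt$ct)
  agg <- do.call(rbind, lapply(
    split(tgt, list(tgt$sample, tgt$locus), drop = TRUE),
    function(d) data.frame(sample = d$sample[1], locus = d$locus[1],
                           enrichment = mean(d$enrich),
                           sd_enrichment = if (nrow(d) > 1) sd(d$enrich)
                                           else NA_real_,
                           n_replicates = nrow(d))
  ))
  ctrl <- agg[agg$sample == control_sample, c("locus", "enrichment")]
  names(ctrl)[2] <- "control_enrichment"
  agg <- merge(agg, ctrl, by = "locus", all.x = TRUE)
  agg$fold_vs_control <- agg$enrichment / agg$control_enrichment
  agg$control_enrichment <- NULL
  agg <- agg[order(agg$sample, agg$locus),
             c("sample", "locus", "enrichment", "sd_enrichment",
               "n_replicates", "fold_vs_control")]
  rownames(agg) <- NULL
  agg
}
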