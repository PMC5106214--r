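# small deterministic track: one chromosome with a distinctive ramp
ramp_track <- function(n_chrom = 1, len = 2000) {
  v <- seq_len(len) + 10 * sin(seq_len(len) / 50)
  values <- setNames(replicate(n_chrom, v, simplify = FALSE),
                     sprintf("chr%02d", seq_len(n_chrom)))
  coverage_track(values, total_reads = 1e6)
}

test_that("RPM normalization scales by mapped-read depth and conserves mass", {
  tr <- coverage_track(list(chr1 = c(4, 0, 2)), total_reads = 2e6)
  rpm <- rpm_normalize(tr)
  expect_equal(rpm$values$chr1, c(2, 0, 1))
  # track already at 1e6 reads is unchanged
  tr1 <- coverage_track(list(chr1 = c(4, 0, 2)), total_reads = 1e6)
  expect_equal(rpm_normalize(tr1)$values$chr1, c(4, 0, 2))
  # conservation: undoing the scaling restores the original sum
  expect_equal(sum(rpm$values$chr1) * 2e6 / 1e6, sum(tr$values$chr1))
  expect_error(coverage_track(list(chr1 = c(-1, 2))), "non-negative")
})

test_that("orientation maps a right-arm window onto the reversed slice", {
  tr <- ramp_track()
  v <- tr$values$chr01
  w <- 100
  # right-arm anchor: centromere toward decreasing coordinates
  anc <- anchor_set(data.frame(name = "A1", chrom = "chr01", pos = 1500,
                               orientation = "-"), kind = "C_ACS",
                    exclude = character())
  prof <- aggregate_at_anchors(tr, anc, window = w)
  expect_equal(prof$profile$summed_signal, v[seq(1500 + w, 1500 - w)])
  # left-arm anchor reads the forward slice
  ancL <- anchor_set(data.frame(name = "A1", chrom = "chr01", pos = 500,
                                orientation = "+"), kind = "C_ACS",
                     exclude = character())
  profL <- aggregate_at_anchors(tr, ancL, window = w)
  expect_equal(profL$profile$summed_signal, v[seq(500 - w, 500 + w)])
})

test_that("aggregation is linear: 30 identical subtelomeres give 30x one", {
  tr30 <- ramp_track(n_chrom = 30)
  one <- anchor_set(data.frame(name = "A01", chrom = "chr01", pos = 500,
                               orientation = "+"), kind = "C_ACS",
                    exclude = character())
  all30 <- anchor_set(data.frame(name = sprintf("A%02d", 1:30),
                                 chrom = sprintf("chr%02d", 1:30),
                                 pos = 500, orientation = "+"),
                      kind = "C_ACS", exclude = character())
  p1 <- aggregate_at_anchors(tr30, one, window = 200)
  p30 <- aggregate_at_anchors(tr30, all30, window = 200)
  expect_equal(p30$profile$summed_signal, 30 * p1$profile$summed_signal)
  expect_equal(p30$profile$n_anchors, rep(30L, nrow(p30$profile)))
  # all-zero track gives an all-zero profile
  z <- coverage_track(list(chr01 = numeric(2000)), total_reads = 1)
  pz <- aggregate_at_anchors(z, one, window = 200)
  expect_true(all(pz$profile$summed_signal == 0))
})

test_that("mirroring a chromosome and flipping orientation is invariant", {
  tr <- ramp_track()
  v <- tr$values$chr01
  mirrored <- coverage_track(list(chr01 = rev(v)), total_reads = 1e6)
  anc <- anchor_set(data.frame(name = "A1", chrom = "chr01", pos = 600,
                               orientation = "+"), kind = "C_ACS",
                    exclude = character())
  anc_m <- anchor_set(data.frame(name = "A1", chrom = "chr01",
                                 pos = length(v) - 600 + 1,
                                 orientation = "-"), kind = "C_ACS",
                      exclude = character())
  p <- aggregate_at_anchors(tr, anc, window = 150)
  pm <- aggregate_at_anchors(mirrored, anc_m, window = 150)
  expect_equal(pm$profile$summed_signal, p$profile$summed_signal)
})

test_that("windows past the chromosome boundary are truncated and counted", {
  tr <- ramp_track()
  anc <- anchor_set(data.frame(name = "A1", chrom = "chr01", pos = 50,
                               orientation = "+"), kind = "C_ACS",
                    exclude = character())
  p <- aggregate_at_anchors(tr, anc, window = 100)
  prof <- p$profile
  expect_equal(prof$n_anchors[prof$offset_bp < -49], rep(0L, 51))
  expect_equal(prof$summed_signal[prof$offset_bp < -49], rep(0, 51))
  expect_true(all(prof$n_anchors[prof$offset_bp >= -49] == 1L))
  # chromosome-end anchors use a one-sided window toward the centromere
  end_anc <- anchor_set(data.frame(name = "A1", chrom = "chr01", pos = 1,
                                   orientation = "+"),
                        kind = "chromosome_end", exclude = character())
  pe <- aggregate_at_anchors(tr, end_anc, window = 100)
  expect_equal(pe$profile$offset_bp, 0:100)
  expect_equal(pe$profile$summed_signal, tr$values$chr01[1:101])
})

test_that("default exclusions drop TEL01R and TEL13R", {
  entries <- data.frame(name = c("TEL01L", "TEL01R", "TEL13R", "TEL02L"),
                        chrom = "chr01", pos = c(10, 1990, 1980, 20),
                        orientation = c("+", "-", "-", "+"))
  anc <- anchor_set(entries, kind = "C_ACS")
  expect_equal(anc$entries$name, c("TEL01L", "TEL02L"))
})

test_that("control normalization is exact, flagged at zero-control bins", {
  tr <- ramp_track()
  anc <- anchor_set(data.frame(name = "A1", chrom = "chr01", pos = 500,
                               orientation = "+"), kind = "C_ACS",
                    exclude = character())
  p <- aggregate_at_anchors(tr, anc, window = 100)
  self <- normalize_to_control(p, p)
  expect_equal(self$profile$normalized_signal,
               rep(1, nrow(self$profile)))
  # signal = 3 x control gives a flat ratio of 3
  tr3 <- coverage_track(lapply(tr$values, `*`, 3), total_reads = 1e6)
  p3 <- aggregate_at_anchors(tr3, anc, window = 100)
  expect_equal(normalize_to_control(p3, p)$profile$normalized_signal,
               rep(3, nrow(p$profile)))
  # zero-control bins are rescued by the smallest positive control value
  ctrl_v <- rep(2, 2000); ctrl_v[460] <- 0; ctrl_v[470] <- 0.5
  ctrl <- coverage_track(list(chr01 = ctrl_v), total_reads = 1e6)
  pc <- aggregate_at_anchors(ctrl, anc, window = 100)
  norm <- normalize_to_control(p, pc)
  zero_off <- norm$profile$offset_bp == -40  # position 460
  expect_true(norm$profile$control_zero[zero_off])
  expect_true(is.finite(norm$profile$normalized_signal[zero_off]))
  expect_equal(norm$profile$normalized_signal[zero_off],
               p$profile$summed_signal[zero_off] / 0.5)
  # mismatched grids are rejected
  p_small <- aggregate_at_anchors(tr, anc, window = 50)
  expect_error(normalize_to_control(p, p_small), "grids differ")
})

test_that("delta-CT fold enrichment follows the per-replicate policy", {
  mk <- function(sample, locus, cts)
    data.frame(sample = sample, locus = locus,
               replicate = seq_along(cts), ct = cts)
  # target at reference parity everywhere: enrichment and fold are 1
  ct <- rbind(mk("WT", "telV", c(12, 12, 12)),
              mk("WT", "cup1", c(12, 12, 12)),
              mk("sir3d", "telV", c(12, 12, 12)),
              mk("sir3d", "cup1", c(12, 12, 12)))
  out <- qpcr_fold_enrichment(ct)
  expect_equal(out$fold_vs_control, c(1, 1))
  # one cycle below reference in the sample only: two-fold enrichment
  ct2 <- rbind(mk("WT", "telV", c(11, 11, 11)),
               mk("WT", "cup1", c(12, 12, 12)),
               mk("sir3d", "telV", c(12, 12, 12)),
               mk("sir3d", "cup1", c(12, 12, 12)))
  out2 <- qpcr_fold_enrichment(ct2)
  expect_equal(out2$fold_vs_control[out2$sample == "WT"], 2)
  # replicate scatter: mean of per-replicate enrichments, not 2^(mean dCT)
  ct3 <- rbind(mk("WT", "telV", c(10, 10.5, 11)),
               mk("WT", "cup1", c(12, 12, 12)),
               mk("sir3d", "telV", c(12, 12, 12)),
               mk("sir3d", "cup1", c(12, 12, 12)))
  out3 <- qpcr_fold_enrichment(ct3)
  per_rep <- mean(2^(12 - c(10, 10.5, 11)))       # 2.9428
  ct_mean <- 2^(12 - mean(c(10, 10.5, 11)))       # 2.8284
  expect_equal(out3$enrichment[out3$sample == "WT"], per_rep)
  expect_false(isTRUE(all.equal(per_rep, ct_mean)))
  expect_error(qpcr_fold_enrichment(ct[ct$locus != "cup1", ]),
               "reference gene")
})

test_that("bedGraph and anchor tables round-trip through disk", {
  sim <- simulate_coverage(sim_config(seed = 4, n_chrom = 2,
                                      chrom_length = 8000,
                                      anchor_offset = 500))
  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph_track(sim$signal, bg)
  back <- read_bedgraph_track(bg, sizes = chrom_sizes(sim$signal),
                              total_reads = sim$signal$total_reads)
  expect_equal(back$values, sim$signal$values, tolerance = 1e-9)
  # anchor table round trip preserves entries and exclusions
  at <- tempfile(fileext = ".tsv")
  write_anchor_table(sim$anchors, at)
  anc2 <- read_anchor_table(at, kind = "C_ACS")
  expect_equal(anc2$entries, sim$anchors$entries)
})
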