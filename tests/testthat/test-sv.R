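# a tiny reference with known GATC positions for hand-computed distances
sv_fixture_index <- function() {
  s <- paste0(strrep("A", 1046), "GATC",          # cut at 1046
              strrep("C", 1026), "GATC",          # cut at 2076
              strrep("T", 5000))
  digest_genome(Biostrings::DNAStringSet(c(chr1 = s, chr2 = strrep("A", 8000))),
                enzyme("GATC", 0))
}

test_that("facing-end distances follow the 3'/5' terminus convention", {
  idx <- sv_fixture_index()
  expect_equal(idx$sites$chr1, c(1046L, 2076L))
  # upstream plus-strand segment ending at a cut: distance 0
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 1000,
         strand = "+", cigar = "46M54S"),
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 5000,
         strand = "+", cigar = "46S54M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 5010,
         strand = "-", cigar = "100M")
  ), chromsizes = chromsizes(idx))
  ct <- annotate_sv(call_contacts(aln, "mask"), idx, tolerance = 5)
  expect_equal(ct$end1, 1046L)
  expect_equal(ct$dist1, 0)
  # downstream end at 5000 is deep in the cut-free tail: flagged
  expect_true(ct$sv_flag)
  # minus-strand downstream segment whose read-5' end is ref_end
  aln2 <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 1000,
         strand = "+", cigar = "46M54S"),
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 2022,
         strand = "-", cigar = "54M46S", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 2000,
         strand = "+", cigar = "100M")
  ), chromsizes = chromsizes(idx))
  ct2 <- annotate_sv(call_contacts(aln2, "mask"), idx, tolerance = 5)
  expect_equal(ct2$end2, 2076L)
  expect_equal(ct2$dist2, 0)
  expect_false(ct2$sv_flag)
})

test_that("flag_sv semantics: either end distal trips the flag", {
  idx <- sv_fixture_index()
  mk <- function(up_start) make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = up_start,
         strand = "+", cigar = "46M54S"),
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 2076,
         strand = "+", cigar = "46S54M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 2100,
         strand = "-", cigar = "70S30M")
  ), chromsizes = chromsizes(idx))
  both_proximal <- annotate_sv(call_contacts(mk(1000), "mask"), idx,
                               tolerance = 5)
  expect_false(both_proximal$sv_flag)
  one_distal <- annotate_sv(call_contacts(mk(1500), "mask"), idx,
                            tolerance = 5)
  expect_equal(one_distal$dist1, 500)
  expect_true(one_distal$sv_flag)
  # distances are recorded regardless of the flag
  expect_true(all(c("dist1", "dist2") %in% names(both_proximal)))
})

test_that("default tolerance is the motif length plus one", {
  idx <- sv_fixture_index()
  expect_equal(pairwalk:::default_sv_tolerance(idx), 5L)
})

test_that("breakpoints come only from flagged, strictly adjacent junctions", {
  idx <- sv_fixture_index()
  # read-through SV junction: chr1 tail fused to chr2
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 4951,
         strand = "+", cigar = "50M50S"),
    list(read_id = "r", mate = "R1", chrom = "chr2", ref_start = 2999,
         strand = "+", cigar = "50S50M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr2", ref_start = 3050,
         strand = "-", cigar = "100M")
  ), chromsizes = chromsizes(idx))
  bp <- call_breakpoints(aln, idx, tolerance = 5)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$chromA, "chr1")
  expect_equal(bp$posA, 5001L)
  expect_equal(bp$chromB, "chr2")
  expect_equal(bp$posB, 3000L)
  expect_equal(bp$source, "adjacent_softclip")
  # proper ligation junction at cut sites yields nothing
  proper <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 996,
         strand = "+", cigar = "50M50S"),
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 2076,
         strand = "+", cigar = "50S50M", supp = TRUE)
  ), chromsizes = chromsizes(idx))
  expect_equal(nrow(call_breakpoints(proper, idx, tolerance = 5)), 0)
  # a 10-base unread gap forfeits single-base resolution
  gapped <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 4951,
         strand = "+", cigar = "45M55S"),
    list(read_id = "r", mate = "R1", chrom = "chr2", ref_start = 2999,
         strand = "+", cigar = "55S45M", supp = TRUE)
  ), chromsizes = chromsizes(idx))
  expect_equal(nrow(call_breakpoints(gapped, idx, tolerance = 5,
                                     max_junction_gap = 0)), 0)
  expect_equal(nrow(call_breakpoints(gapped, idx, tolerance = 5,
                                     max_junction_gap = 10)), 1)
})

test_that("planted breakpoints are recovered exactly at 1 bp", {
  cfg <- sim_config(seed = 53, n_read_pairs = 400,
                    fragments_per_molecule = c(0, 1),
                    fraction_sv_junctions = 0.5)
  sim <- simulate_hic(cfg)
  aln <- trim_multimap(filter_mapq(sim$alignments, 30))
  bp <- call_breakpoints(aln, sim$cutsites, tolerance = 5)
  expect_identical(breakpoint_keys(bp),
                   breakpoint_keys(sim$truth$breakpoints))
  # every planted junction end is at least the configured distance out
  expect_true(all(pmin(bp$dA, bp$dB) >= cfg$sv_distal_min))
  # intra- and inter-chromosomal breakpoints both occur and are reported
  expect_gt(sum(bp$chromA == bp$chromB), 0)
  expect_gt(sum(bp$chromA != bp$chromB), 0)
})

test_that("breakpoints are a subset of SV-flagged adjacent contacts", {
  cfg <- sim_config(seed = 59, n_read_pairs = 300,
                    fraction_sv_junctions = 0.3)
  sim <- simulate_hic(cfg)
  res <- pairwalk_call(sim$alignments, cutsites = sim$cutsites,
                       policy = "all")
  flagged <- res$contacts[res$contacts$sv_flag &
                            res$contacts$junction_class == "adjacent_softclip", ]
  expect_true(all(res$breakpoints$read_id %in% flagged$read_id))
  expect_equal(nrow(res$breakpoints), nrow(flagged))
})
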