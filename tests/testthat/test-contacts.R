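test_that("a clean 1+1 pair yields a UU contact at the 5' ends", {
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 100,
         strand = "+", cigar = "50M"),
    list(read_id = "r", mate = "R2", chrom = "chr2", ref_start = 500,
         strand = "-", cigar = "50M")
  ))
  ct <- call_contacts(aln, "mask")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$pair_type, "UU")
  expect_equal(ct$junction_class, "mate_paired")
  # 5' convention: ref_start + 1 on plus, ref_end on minus
  expect_equal(ct$pos1, 101L)
  expect_equal(ct$pos2, 550L)
  expect_equal(pair_types(ct)$pair_type, "UU")
})

test_that("mask rescues a 2+1 chimera whose 3' segment mirrors the mate", {
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 100,
         strand = "+", cigar = "50M50S"),
    list(read_id = "r", mate = "R1", chrom = "chr3", ref_start = 8000,
         strand = "+", cigar = "50S50M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr3", ref_start = 8100,
         strand = "-", cigar = "100M")
  ))
  ct <- call_contacts(aln, "mask")
  expect_equal(ct$pair_type, "RU")
  expect_equal(ct$chrom1, "chr1")
  expect_equal(ct$pos1, 101L)
  expect_equal(ct$chrom2, "chr3")
  expect_equal(ct$pos2, 8200L)   # R2 minus-strand 5' end
  expect_equal(ct$junction_class, "adjacent_softclip")
  # if the mirror is on the wrong strand, no rescue
  aln2 <- aln
  aln2$strand[3] <- "+"
  aln2 <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 100,
         strand = "+", cigar = "50M50S"),
    list(read_id = "r", mate = "R1", chrom = "chr3", ref_start = 8000,
         strand = "+", cigar = "50S50M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr3", ref_start = 8100,
         strand = "+", cigar = "100M")
  ))
  ct2 <- call_contacts(aln2, "mask")
  expect_equal(nrow(ct2), 0)
  expect_equal(pair_types(ct2)$pair_type, "MU")
})

test_that("mask masks complex configurations and codes missing mates", {
  three_plus_one <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 100,
         strand = "+", cigar = "30M70S"),
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 900,
         strand = "+", cigar = "30S30M40S", supp = TRUE),
    list(read_id = "r", mate = "R1", chrom = "chr2", ref_start = 300,
         strand = "+", cigar = "60S40M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr2", ref_start = 500,
         strand = "-", cigar = "100M")
  ))
  ct <- call_contacts(three_plus_one, "mask")
  expect_equal(nrow(ct), 0)
  expect_equal(pair_types(ct)$pair_type, "MM")
  solo <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 100,
         strand = "+", cigar = "100M")
  ))
  expect_equal(pair_types(call_contacts(solo, "mask"))$pair_type, "UN")
})

test_that("the all policy walks a four-locus chimeric read", {
  # four loci on R1, R2 re-reading the last locus from the far end
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 1000,
         strand = "+", cigar = "25M75S"),
    list(read_id = "r", mate = "R1", chrom = "chr2", ref_start = 2000,
         strand = "+", cigar = "25S25M50S", supp = TRUE),
    list(read_id = "r", mate = "R1", chrom = "chr3", ref_start = 3000,
         strand = "+", cigar = "50S25M25S", supp = TRUE),
    list(read_id = "r", mate = "R1", chrom = "chr4", ref_start = 4000,
         strand = "+", cigar = "75S25M", supp = TRUE),
    list(read_id = "r", mate = "R2", chrom = "chr4", ref_start = 4100,
         strand = "-", cigar = "100M")
  ))
  ct <- call_contacts(aln, "all")
  expect_equal(nrow(ct), 3)
  expect_equal(ct$contact_index, 1:3)
  expect_equal(ct$chrom1, c("chr1", "chr2", "chr3"))
  expect_equal(ct$chrom2, c("chr2", "chr3", "chr4"))
  expect_equal(ct$pair_type, rep("RR", 3))
  expect_equal(ct$junction_class, rep("adjacent_softclip", 3))
})

test_that("self-ligation collapses to a merged single-segment walk", {
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 1000,
         strand = "+", cigar = "100M"),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 1100,
         strand = "-", cigar = "100M")
  ))
  ct <- call_contacts(aln, "all")
  expect_equal(nrow(ct), 0)
  expect_equal(pair_types(ct)$pair_type, "UU")
  # but mask still reports the pair
  expect_equal(nrow(call_contacts(aln, "mask")), 1)
  # beyond the merge window the two segments stay distinct loci
  far <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 1000,
         strand = "+", cigar = "100M"),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 9000,
         strand = "-", cigar = "100M")
  ))
  ct2 <- call_contacts(far, "all")
  expect_equal(nrow(ct2), 1)
  expect_equal(ct2$junction_class, "mate_paired")
})

test_that("all contains the mask UU contact for non-merging pairs", {
  set.seed(31)
  for (i in 1:20) {
    aln <- make_segments(list(
      list(read_id = "r", mate = "R1", chrom = "chr1",
           ref_start = sample(1000:5000, 1), strand = sample(c("+", "-"), 1),
           cigar = "100M"),
      list(read_id = "r", mate = "R2", chrom = "chr2",
           ref_start = sample(1000:5000, 1), strand = sample(c("+", "-"), 1),
           cigar = "100M")
    ))
    m <- call_contacts(aln, "mask")
    a <- call_contacts(aln, "all")
    expect_equal(nrow(a), 1)
    cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
    expect_equal(as.data.frame(a[, cols]), as.data.frame(m[, cols]))
  }
})

test_that("random walks match a per-read brute-force enumerator", {
  cfg <- sim_config(seed = 41, n_read_pairs = 400,
                    fragments_per_molecule = rep(0.2, 5),
                    fraction_sv_junctions = 0.1)
  sim <- simulate_hic(cfg)
  aln <- trim_multimap(sim$alignments)
  ord <- chromsizes(aln)$chrom
  for (policy in c("mask", "all")) {
    got <- call_contacts(aln, policy)
    want <- oracle_contacts(as.data.frame(aln), policy)
    expect_identical(contact_keys(got, ord), contact_keys(want, ord))
  }
})

test_that("canonicalization is an idempotent side swap", {
  aln <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr2", ref_start = 100,
         strand = "+", cigar = "50M"),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 500,
         strand = "-", cigar = "50M")
  ), chromsizes = tibble::tibble(chrom = c("chr1", "chr2"),
                                 length = c(10000L, 10000L)))
  ct <- call_contacts(aln, "mask")
  can <- canonicalize_contacts(ct)
  expect_equal(can$chrom1, "chr1")
  expect_equal(can$chrom2, "chr2")
  expect_true(can$flipped)
  expect_equal(can$strand1, "-")
  # annotations swap with their sides
  expect_equal(can$end1, ct$end2)
  can2 <- canonicalize_contacts(can)
  expect_identical(as.data.frame(can2), as.data.frame(can))
  # intra-chromosomal position ordering
  aln2 <- make_segments(list(
    list(read_id = "r", mate = "R1", chrom = "chr1", ref_start = 5000,
         strand = "+", cigar = "50M"),
    list(read_id = "r", mate = "R2", chrom = "chr1", ref_start = 100,
         strand = "+", cigar = "50M")
  ))
  can3 <- canonicalize_contacts(call_contacts(aln2, "mask"))
  expect_lte(can3$pos1, can3$pos2)
  expect_error(canonicalize_contacts(ct, chrom_order = "chrX"),
               "unknown chromosome")
})
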