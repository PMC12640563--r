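test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 101, n_read_pairs = 60,
                    fraction_sv_junctions = 0.2)
  a <- simulate_hic(cfg)
  b <- simulate_hic(cfg)
  expect_identical(as.data.frame(a$alignments), as.data.frame(b$alignments))
  expect_identical(a$truth$junctions, b$truth$junctions)
  expect_identical(as.character(a$genome), as.character(b$genome))
  c2 <- simulate_hic(sim_config(seed = 102, n_read_pairs = 60,
                                fraction_sv_junctions = 0.2))
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("motif density matches the 4^-|motif| expectation", {
  cfg <- sim_config(seed = 103, n_chromosomes = 2,
                    chromosome_length = 200000L, n_read_pairs = 1)
  gen <- simulate_genome(cfg)
  lambda <- 200000 / 4^4
  for (chr in names(gen$occurrences)) {
    n <- length(gen$occurrences[[chr]])
    expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  }
})

test_that("re-digestion of the simulated genome matches the naive-scan truth", {
  cfg <- sim_config(seed = 107, n_read_pairs = 1)
  sim <- simulate_hic(cfg)
  idx <- digest_genome(sim$genome, cfg$enzyme)
  expect_identical(idx$sites, sim$cutsites$sites)
})

test_that("emitted SAM parses back to the in-memory segments exactly", {
  cfg <- sim_config(seed = 109, n_read_pairs = 200,
                    fraction_sv_junctions = 0.2)
  sim <- simulate_hic(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  emit_sam(sim, sam)
  back <- read_alignments(sam)
  cols <- c("read_id", "mate", "chrom", "ref_start", "ref_end", "strand",
            "mapq", "cigar", "read_start", "read_end", "read_length",
            "is_soft_clipped", "flag")
  expect_identical(as.data.frame(sim$alignments[, cols]),
                   as.data.frame(back[, cols]))
  # aligned SEQ segments equal the genomic sequence they claim
  set.seed(1)
  for (i in sample(nrow(back), 40)) {
    s <- back[i, ]
    ref <- as.character(Biostrings::subseq(sim$genome[[s$chrom]],
                                           s$ref_start + 1, s$ref_end))
    w <- oracle_cigar_walk(s$cigar, s$strand)
    qs <- substr(s$seq, w$clip_left + 1, w$clip_left + w$aligned_query)
    expect_identical(qs, ref)
  }
})

test_that("molecule structure respects the planted junction grammar", {
  cfg <- sim_config(seed = 113, n_read_pairs = 300,
                    fraction_sv_junctions = 0.5,
                    fragments_per_molecule = c(0, 1))
  sim <- simulate_hic(cfg)
  jn <- sim$truth$junctions
  # sv fraction within 3 binomial sd of the configured rate
  p <- 0.5; n <- nrow(jn)
  expect_lt(abs(mean(jn$type == "sv") - p), 3 * sqrt(p * (1 - p) / n))
  # proper junctions carry the duplicated-motif overlap, sv junctions none
  expect_true(all(jn$expected_overlap[jn$type == "proper"] == 4L))
  expect_true(all(jn$expected_overlap[jn$type == "sv"] == 0L))
  # every sv junction end is distal, every proper end at/near its cut;
  # the junction coordinate sits just past the aligned base on each side
  jA <- ifelse(jn$strandA == "+", jn$posA, jn$posA - 1L)
  jB <- ifelse(jn$strandB == "+", jn$posB - 1L, jn$posB)
  dA <- nearest_cut_distance(sim$cutsites, jn$chromA, jA)
  dB <- nearest_cut_distance(sim$cutsites, jn$chromB, jB)
  sv <- jn$type == "sv"
  expect_true(all(pmin(dA[sv], dB[sv]) >= cfg$sv_distal_min))
  expect_true(all(dA[!sv] <= 4 & dB[!sv] <= 4))
  # all-proper configuration plants no breakpoints
  clean <- simulate_hic(sim_config(seed = 127, n_read_pairs = 50,
                                   fraction_sv_junctions = 0))
  expect_equal(nrow(clean$truth$breakpoints), 0)
})

test_that("observed overlaps at junctions equal the motif length", {
  cfg <- sim_config(seed = 131, n_read_pairs = 200,
                    fragments_per_molecule = c(0, 1),
                    fraction_sv_junctions = 0)
  sim <- simulate_hic(cfg)
  adj <- find_adjacent_pairs(sim$alignments)
  expect_equal(nrow(adj), nrow(sim$truth$junctions))
  expect_true(all(adj$overlap_len == 4L))
  # without motif duplication the flanks abut instead
  cfg2 <- sim_config(seed = 131, n_read_pairs = 100,
                     fragments_per_molecule = c(0, 1),
                     fraction_sv_junctions = 0,
                     duplicate_motif_at_junction = FALSE)
  sim2 <- simulate_hic(cfg2)
  adj2 <- find_adjacent_pairs(sim2$alignments)
  expect_true(all(adj2$overlap_len == 0L))
  expect_true(all(adj2$gap_len == 0L))
})

test_that("single-fragment molecules yield plain unclipped pairs", {
  cfg <- sim_config(seed = 137, n_read_pairs = 50,
                    fragments_per_molecule = 1)
  sim <- simulate_hic(cfg)
  expect_equal(nrow(sim$alignments), 100)
  expect_true(all(!sim$alignments$is_soft_clipped))
  expect_true(all(sim$alignments$cigar == "150M"))
})

test_that("low-MAPQ injection marks whole reads below the filter", {
  cfg <- sim_config(seed = 139, n_read_pairs = 200,
                    fraction_low_mapq = 0.25)
  sim <- simulate_hic(cfg)
  by_read <- tapply(sim$alignments$mapq, sim$alignments$read_id, unique)
  expect_true(all(lengths(by_read) == 1))
  frac <- mean(unlist(by_read) == 10)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
  kept <- filter_mapq(sim$alignments, 30)
  expect_true(all(kept$mapq == 60))
})

test_that("end-to-end recovery of planted walks for multiple seeds", {
  for (seed in c(211, 223)) {
    cfg <- sim_config(seed = seed, n_read_pairs = 150,
                      fraction_sv_junctions = 0.2)
    sim <- simulate_hic(cfg)
    res <- pairwalk_call(sim$alignments, cutsites = sim$cutsites,
                         policy = "all")
    ord <- chromsizes(sim$alignments)$chrom
    expect_identical(contact_keys(res$contacts, ord),
                     contact_keys(sim$truth$contacts_all, ord))
    expect_identical(breakpoint_keys(res$breakpoints),
                     breakpoint_keys(sim$truth$breakpoints))
    # zero SV flags on proper junctions
    jn <- sim$truth$junctions
    flagged <- res$contacts[res$contacts$sv_flag &
                              res$contacts$junction_class != "mate_paired", ]
    expect_equal(sort(paste(flagged$read_id, flagged$contact_index)),
                 sort(paste(jn$read_id, jn$junction_index)[jn$type == "sv"]))
  }
})
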