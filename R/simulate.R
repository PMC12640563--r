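# Ground-truth simulator. Emulates what a soft-clipping local aligner
# produces for sticky-end proximity-ligation products: each molecule is a
# walk of genomic fragments joined either at restriction cut sites
# (proper ligation; the single reconstituted motif aligns redundantly into
# BOTH flanking segments) or at positions distal from any cut site
# (planted SV junctions with known 1 bp breakpoints). Sequencing errors
# and bisulfite conversion are not simulated: the pipeline's contract
# begins at aligned records, so records are synthesized directly.

#' Simulation configuration
#'
#' Defaults describe a small but realistic single-cell Hi-C experiment on a
#' random genome: a DpnII-like 4-cutter (GATC, expected site spacing
#' 4^4 = 256 bp), 150 bp paired-end reads, walks of one to five fragments
#' dominated by two-fragment molecules, 80%/20% cis/trans ligation, a 10%
#' SV-junction rate, and motif duplication at every proper junction.
#'
#' Molecule geometry is chosen so truth is exact: all junctions fall within
#' R1, the last fragment is at least one read long so R2 lies entirely
#' within it, and interior fragments are 25 bp or longer.
#'
#' @param seed Integer seed; all simulator output is deterministic given it.
#' @param n_chromosomes,chromosome_length Genome shape (uniform random
#'   sequence).
#' @param enzyme An [enzyme()]; default DpnII-like `GATC` cut at offset 0.
#' @param n_read_pairs Number of molecules (one read pair each).
#' @param read_length Read length in bp; must be at least
#'   `2 * nchar(motif) + 20`.
#' @param fragments_per_molecule Probability vector over walk sizes
#'   k = 1, 2, ... .
#' @param fraction_sv_junctions Probability that a junction is a planted SV
#'   junction rather than a proper cut-site ligation.
#' @param sv_distal_min Minimum distance (bp) of a planted SV junction end
#'   from any cut site.
#' @param fraction_trans Probability that consecutive fragments lie on
#'   different chromosomes.
#' @param duplicate_motif_at_junction If `TRUE`, alignments flanking a
#'   proper junction both include the junction motif (the multimapping
#'   artifact); the motif appears once in the molecule.
#' @param fraction_low_mapq Fraction of reads whose segments all get
#'   MAPQ 10 (below the usual filter) instead of 60.
#' @return A `pairwalk_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 100000L,
                       enzyme = pairwalk::enzyme("GATC", 0L, "DpnII"),
                       n_read_pairs = 1000L,
                       read_length = 150L,
                       fragments_per_molecule = c(0.25, 0.45, 0.2, 0.07, 0.03),
                       fraction_sv_junctions = 0.1,
                       sv_distal_min = 50L,
                       fraction_trans = 0.2,
                       duplicate_motif_at_junction = TRUE,
                       fraction_low_mapq = 0) {
  stopifnot(
    inherits(enzyme, "pairwalk_enzyme"),
    read_length >= 2L * nchar(enzyme$motif) + 20L,
    fraction_sv_junctions >= 0, fraction_sv_junctions <= 1,
    fraction_trans >= 0, fraction_trans <= 1,
    fraction_low_mapq >= 0, fraction_low_mapq <= 1,
    all(fragments_per_molecule >= 0), sum(fragments_per_molecule) > 0
  )
  if (fraction_trans > 0 && n_chromosomes < 2L) {
    stop("fraction_trans > 0 requires at least two chromosomes", call. = FALSE)
  }
  kmax <- length(fragments_per_molecule)
  if (kmax > 1L) {
    max_each <- (read_length - 20L) %/% (kmax - 1L)
    if (max_each < 25L) {
      stop("read_length too short for ", kmax, "-fragment walks", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
      chromosome_length = as.integer(chromosome_length), enzyme = enzyme,
      n_read_pairs = as.integer(n_read_pairs),
      read_length = as.integer(read_length),
      fragments_per_molecule = fragments_per_molecule /
        sum(fragments_per_molecule),
      fraction_sv_junctions = fraction_sv_junctions,
      sv_distal_min = as.integer(sv_distal_min),
      fraction_trans = fraction_trans,
      duplicate_motif_at_junction = isTRUE(duplicate_motif_at_junction),
      fraction_low_mapq = fraction_low_mapq
    ),
    class = "pairwalk_sim_config"
  )
}

# character-by-character motif scan, independent of the Biostrings-backed
# digestion path; returns 0-based occurrence starts
naive_motif_scan <- function(seq_chars, motif) {
  m <- nchar(motif)
  L <- length(seq_chars)
  if (L < m) return(integer())
  mm <- strsplit(motif, "")[[1]]
  idx <- seq_len(L - m + 1L)
  keep <- rep(TRUE, length(idx))
  for (j in seq_len(m)) {
    keep <- keep & seq_chars[idx + j - 1L] == mm[j]
  }
  idx[keep] - 1L
}

#' Simulate a random reference genome and its cut-site truth
#'
#' @param config A [sim_config()] (its `seed` is applied).
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `cutsites`
#'   (a `pairwalk_cutsites` built by a naive character scan, independent of
#'   [digest_genome()]) and `occurrences` (0-based motif start positions
#'   per chromosome).
#' @export
simulate_genome <- function(config) {
  with_sim_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    chars <- lapply(chroms, function(.)
      sample(c("A", "C", "G", "T"), config$chromosome_length, replace = TRUE))
    names(chars) <- chroms
    genome <- Biostrings::DNAStringSet(
      vapply(chars, paste0, "", collapse = "")
    )
    names(genome) <- chroms
    occ <- lapply(chars, naive_motif_scan, motif = config$enzyme$motif)
    sites <- lapply(occ, function(q)
      sort(unique(q + config$enzyme$cut_offset)))
    cutsites <- new_cutsites(
      sites,
      stats::setNames(rep(config$chromosome_length, length(chroms)), chroms),
      list(config$enzyme)
    )
    list(genome = genome, cutsites = cutsites, occurrences = occ)
  })
}

with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate ligation products and aligner-style records with truth
#'
#' Generates `n_read_pairs` molecules over a fresh random genome, derives
#' the records a soft-clipping aligner would emit for their paired-end
#' reads, and returns them together with per-read ground truth. By
#' construction every junction of a molecule is read through by R1 and the
#' last fragment is covered at its far end by R2, so every planted
#' junction's overlap, contacts and breakpoints are exactly known.
#'
#' @param config A [sim_config()].
#' @return A `pairwalk_sim` list: `config`, `genome`, `cutsites` (naive-
#'   scan truth), `alignments` (segments tibble as [read_alignments()]
#'   would produce, `chromsizes` attached), and `truth` with tibbles
#'   `fragments`, `junctions` (expected overlaps, facing ends, breakpoint
#'   coordinates), `contacts_all`, `contacts_mask` and `breakpoints`.
#' @export
simulate_hic <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  with_sim_seed(config$seed + 1L, {
    sim_molecules(config, gen)
  })
}

sim_molecules <- function(config, gen) {
  rl <- config$read_length
  m <- nchar(config$enzyme$motif)
  kmax <- length(config$fragments_per_molecule)
  chroms <- names(gen$genome)
  clen <- config$chromosome_length
  occ <- gen$occurrences
  pair_cache <- new.env(parent = emptyenv())

  frag_rows <- list(); junc_rows <- list(); seg_rows <- list()
  low_mapq <- stats::runif(config$n_read_pairs) < config$fraction_low_mapq

  for (mol in seq_len(config$n_read_pairs)) {
    read_id <- sprintf("sim%06d", mol)
    k <- sample.int(kmax, 1L, prob = config$fragments_per_molecule)
    orient <- sample(c("+", "-"), k, replace = TRUE)
    chrom_i <- character(k)
    chrom_i[1L] <- sample(chroms, 1L)
    if (k > 1L) for (i in 2:k) {
      chrom_i[i] <- if (stats::runif(1L) < config$fraction_trans) {
        sample(setdiff(chroms, chrom_i[i - 1L]), 1L)
      } else {
        chrom_i[i - 1L]
      }
    }
    as_cond <- function(type) if (type == "proper") "cut" else "sv"
    if (k == 1L) {
      jt <- character()
      windows <- list(c(rl + 20L, rl + 200L))
    } else {
      # interior fragment lengths share the R1 budget; a fragment with one
      # cut-anchored end and one SV end must be long enough that its own
      # anchor site stays distal from the SV end
      budget <- rl - 20L
      mixed_lo <- max(25L, config$sv_distal_min + 1L)
      for (draw in seq_len(100L)) {
        jt <- ifelse(stats::runif(k - 1L) < config$fraction_sv_junctions,
                     "sv", "proper")
        lo <- vapply(seq_len(k - 1L), function(i) {
          conds <- c(if (i == 1L) "none" else as_cond(jt[i - 1L]),
                     as_cond(jt[i]))
          if (setequal(conds, c("cut", "sv"))) mixed_lo else 25L
        }, 0L)
        if (sum(lo) + 2L * (k - 1L) <= budget) break
        if (draw == 100L) {
          stop("read_length too short for ", k, "-fragment walks with ",
               "SV junctions at sv_distal_min = ", config$sv_distal_min,
               call. = FALSE)
        }
      }
      slack <- (budget - sum(lo)) %/% (k - 1L)
      windows <- c(lapply(lo, function(l) c(l, l + slack)),
                   list(c(rl, rl + 100L)))
    }
    gs <- integer(k); ge <- integer(k)
    for (i in seq_len(k)) {
      left_cond <- if (i == 1L) "none" else as_cond(jt[i - 1L])
      right_cond <- if (i == k) "none" else as_cond(jt[i])
      fr <- sample_fragment(
        chrom_i[i], orient[i], left_cond, right_cond, windows[[i]],
        occ, gen$cutsites, clen, m, config$sv_distal_min, pair_cache
      )
      gs[i] <- fr[1L]; ge[i] <- fr[2L]
    }
    L_i <- ge - gs
    p <- cumsum(c(0L, L_i))           # p[i] = molecule start of fragment i
    mol_len <- p[k + 1L]
    ext <- c(0L, ifelse(jt == "proper" & config$duplicate_motif_at_junction,
                        m, 0L))

    # R1 segments: fragment i spans molecule [a, b)
    a <- p[seq_len(k)] - ext
    b <- c(p[seq_len(k)][-1L], rl)
    if (k == 1L) b <- rl
    g_lo <- ifelse(orient == "+", gs + (a - p[seq_len(k)]),
                   ge - (b - p[seq_len(k)]))
    g_hi <- ifelse(orient == "+", gs + (b - p[seq_len(k)]),
                   ge - (a - p[seq_len(k)]))
    # R2: single full-length segment in the last fragment
    t0 <- (mol_len - rl) - p[k]
    r2_strand <- if (orient[k] == "+") "-" else "+"
    r2_lo <- if (orient[k] == "+") gs[k] + t0 else gs[k]
    r2_hi <- if (orient[k] == "+") ge[k] else ge[k] - t0
    mapq <- if (low_mapq[mol]) 10L else 60L

    r1_flag_base <- FLAG_PAIRED + FLAG_R1 +
      ifelse(orient == "-", FLAG_REVERSE, 0L) +
      (if (r2_strand == "-") FLAG_MREVERSE else 0L)
    r1_flag <- r1_flag_base + c(0L, rep(FLAG_SUPPLEMENTARY, k - 1L))
    r2_flag <- FLAG_PAIRED + FLAG_R2 +
      (if (r2_strand == "-") FLAG_REVERSE else 0L) +
      (if (orient[1L] == "-") FLAG_MREVERSE else 0L)

    clipL <- a
    clipR <- rl - b
    cig_r1 <- ifelse(
      orient == "+",
      paste0(ifelse(clipL > 0L, paste0(clipL, "S"), ""), b - a, "M",
             ifelse(clipR > 0L, paste0(clipR, "S"), "")),
      paste0(ifelse(clipR > 0L, paste0(clipR, "S"), ""), b - a, "M",
             ifelse(clipL > 0L, paste0(clipL, "S"), ""))
    )
    seg_rows[[mol]] <- list(
      read_id = rep(read_id, k + 1L),
      mate = c(rep("R1", k), "R2"),
      chrom = c(chrom_i, chrom_i[k]),
      ref_start = c(g_lo, r2_lo),
      ref_end = c(g_hi, r2_hi),
      strand = c(orient, r2_strand),
      mapq = rep(mapq, k + 1L),
      cigar = c(cig_r1, paste0(rl, "M")),
      read_start = c(a, 0L),
      read_end = c(b, rl),
      flag = c(r1_flag, r2_flag),
      frag_index = c(seq_len(k), k)
    )
    frag_rows[[mol]] <- list(
      read_id = rep(read_id, k), frag_index = seq_len(k), chrom = chrom_i,
      gs = gs, ge = ge, orient = orient, core_len = L_i,
      mol_start = p[seq_len(k)], low_mapq = rep(low_mapq[mol], k),
      k = rep(k, k)
    )
    if (k > 1L) {
      upo <- orient[-k]; dno <- orient[-1L]
      junc_rows[[mol]] <- list(
        read_id = rep(read_id, k - 1L), junction_index = seq_len(k - 1L),
        type = jt,
        chromA = chrom_i[-k],
        posA = ifelse(upo == "+", ge[-k], gs[-k] + 1L),
        strandA = upo,
        chromB = chrom_i[-1L],
        posB = ifelse(dno == "+", gs[-1L] + 1L, ge[-1L]),
        strandB = dno,
        expected_overlap = ext[-1L],
        low_mapq = rep(low_mapq[mol], k - 1L)
      )
    }
  }

  bind_row_lists <- function(rows) {
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0L) return(NULL)
    cols <- names(rows[[1L]])
    tibble::as_tibble(stats::setNames(
      lapply(cols, function(cn) {
        unlist(lapply(rows, `[[`, cn), use.names = FALSE)
      }), cols))
  }
  segments <- bind_row_lists(seg_rows)
  alignments <- alignment_segments(
    read_id = segments$read_id, chrom = segments$chrom,
    pos = segments$ref_start + 1L, strand = segments$strand,
    mapq = segments$mapq, cigar = segments$cigar, flag = segments$flag
  )
  stopifnot(identical(alignments$ref_end, as.integer(segments$ref_end)),
            identical(alignments$read_start, as.integer(segments$read_start)),
            identical(alignments$read_end, as.integer(segments$read_end)))
  alignments$frag_index <- segments$frag_index
  attr(alignments, "chromsizes") <- tibble::tibble(
    chrom = chroms, length = rep(clen, length(chroms))
  )
  fragments <- bind_row_lists(frag_rows)
  junctions <- bind_row_lists(junc_rows)
  if (is.null(junctions)) {
    junctions <- tibble::tibble(
      read_id = character(), junction_index = integer(),
      type = character(), chromA = character(), posA = integer(),
      strandA = character(), chromB = character(),
      posB = integer(), strandB = character(),
      expected_overlap = integer(), low_mapq = logical())
  }
  truth <- build_truth(config, fragments, junctions)
  structure(
    list(config = config, genome = gen$genome, cutsites = gen$cutsites,
         alignments = alignments,
         truth = c(list(fragments = fragments, junctions = junctions), truth)),
    class = "pairwalk_sim"
  )
}

# expected contacts and breakpoints, from fragment geometry alone
build_truth <- function(config, fragments, junctions) {
  pos5 <- ifelse(fragments$orient == "+", fragments$gs + 1L, fragments$ge)
  f <- fragments
  f$pos5 <- pos5
  up <- f[f$frag_index < f$k, , drop = FALSE]
  dn <- f[f$frag_index > 1L, , drop = FALSE]
  contacts_all <- tibble::tibble(
    read_id = up$read_id,
    contact_index = up$frag_index,
    chrom1 = up$chrom, pos1 = up$pos5, strand1 = up$orient,
    chrom2 = dn$chrom, pos2 = dn$pos5, strand2 = dn$orient,
    low_mapq = up$low_mapq
  )
  k1 <- f[f$k == 1L & f$frag_index == 1L, , drop = FALSE]
  mask_k1 <- tibble::tibble(
    read_id = k1$read_id, pair_type = rep("UU", nrow(k1)),
    chrom1 = k1$chrom, pos1 = as.integer(k1$pos5), strand1 = k1$orient,
    chrom2 = k1$chrom,
    pos2 = as.integer(ifelse(k1$orient == "+", k1$ge, k1$gs + 1L)),
    strand2 = as.character(ifelse(k1$orient == "+", "-", "+")),
    low_mapq = k1$low_mapq
  )
  f2a <- f[f$k == 2L & f$frag_index == 1L, , drop = FALSE]
  f2b <- f[f$k == 2L & f$frag_index == 2L, , drop = FALSE]
  mask_k2 <- tibble::tibble(
    read_id = f2a$read_id, pair_type = rep("RU", nrow(f2a)),
    chrom1 = f2a$chrom, pos1 = as.integer(f2a$pos5), strand1 = f2a$orient,
    chrom2 = f2b$chrom,
    pos2 = as.integer(ifelse(f2b$orient == "+", f2b$ge, f2b$gs + 1L)),
    strand2 = as.character(ifelse(f2b$orient == "+", "-", "+")),
    low_mapq = f2a$low_mapq
  )
  sv <- junctions[junctions$type == "sv", , drop = FALSE]
  breakpoints <- tibble::tibble(
    read_id = sv$read_id,
    chromA = sv$chromA, posA = sv$posA, strandA = sv$strandA,
    chromB = sv$chromB, posB = sv$posB, strandB = sv$strandB,
    low_mapq = sv$low_mapq
  )
  list(
    contacts_all = contacts_all,
    contacts_mask = dplyr::bind_rows(mask_k1, mask_k2),
    breakpoints = breakpoints
  )
}

# sample one fragment's genomic core [gs, ge) on `chrom` subject to the
# junction conditions at its molecule-left and -right ends
sample_fragment <- function(chrom, orient, left_cond, right_cond, window,
                            occ, cutsites, clen, m, sv_min, pair_cache) {
  # translate molecule-side conditions to genomic-end conditions
  if (orient == "+") {
    gs_cond <- left_cond; ge_cond <- right_cond; anchor_shift <- m
  } else {
    gs_cond <- right_cond; ge_cond <- left_cond; anchor_shift <- 0L
  }
  q <- occ[[chrom]]
  lo <- window[1L]; hi <- window[2L]
  sites <- cutsites$sites[[chrom]]
  distal <- function(pos) {
    if (length(sites) == 0L) return(TRUE)
    i <- findInterval(pos, sites)
    d1 <- if (i >= 1L) pos - sites[i] else Inf
    d2 <- if (i < length(sites)) sites[i + 1L] - pos else Inf
    min(d1, d2) >= sv_min
  }
  ok_bounds <- function(gs, ge) {
    gs >= m && ge + m <= clen && ge - gs >= lo && ge - gs <= hi
  }
  if (gs_cond == "cut" && ge_cond == "cut") {
    pr <- occ_pairs(chrom, q, lo, hi, pair_cache)
    if (pr$total == 0L) {
      stop("no motif-occurrence pair with spacing in [", lo, ", ", hi,
           "] on ", chrom, "; enlarge the genome", call. = FALSE)
    }
    r <- sample.int(pr$total, 1L)
    i <- findInterval(r - 1L, pr$cum) + 1L
    j <- pr$jlo[i] + (r - c(0L, pr$cum)[i]) - 1L
    gs <- q[i] + anchor_shift
    ge <- q[j] + anchor_shift
    if (!ok_bounds(gs, ge)) return(Recall(chrom, orient, left_cond,
                                          right_cond, window, occ, cutsites,
                                          clen, m, sv_min, pair_cache))
    return(c(gs, ge))
  }
  for (try in seq_len(1000L)) {
    if (gs_cond == "cut") {
      gs <- q[sample.int(length(q), 1L)] + anchor_shift
      ge <- gs + sample.int(hi - lo + 1L, 1L) + lo - 1L
    } else if (ge_cond == "cut") {
      ge <- q[sample.int(length(q), 1L)] + anchor_shift
      gs <- ge - (sample.int(hi - lo + 1L, 1L) + lo - 1L)
    } else {
      gs <- sample.int(clen - hi - 2L * m, 1L) + m
      ge <- gs + sample.int(hi - lo + 1L, 1L) + lo - 1L
    }
    if (!ok_bounds(gs, ge)) next
    if (gs_cond == "sv" && !distal(gs)) next
    if (ge_cond == "sv" && !distal(ge)) next
    return(c(as.integer(gs), as.integer(ge)))
  }
  stop("could not place a fragment on ", chrom,
       " satisfying the junction conditions", call. = FALSE)
}

# cache of occurrence pairs (i, j) with q[j] - q[i] in [lo, hi]
occ_pairs <- function(chrom, q, lo, hi, cache) {
  key <- paste(chrom, lo, hi, sep = ":")
  if (!is.null(cache[[key]])) return(cache[[key]])
  n <- length(q)
  jlo <- findInterval(q + lo, q, left.open = TRUE) + 1L
  jhi <- findInterval(q + hi, q)
  counts <- pmax(0L, jhi - jlo + 1L)
  cum <- cumsum(counts)
  res <- list(total = if (n) cum[n] else 0L, cum = cum, jlo = jlo)
  cache[[key]] <- res
  res
}
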