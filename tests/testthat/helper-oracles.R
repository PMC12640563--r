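# Independent oracles and fixture builders. These re-derive expected
# results by direct definition (character scans, op-by-op CIGAR walks,
# per-read enumeration) and never share code with the implementation paths
# they check.

# character-by-character motif scan returning 0-based cut positions,
# honouring cut offset and (for non-palindromic motifs) both strands
oracle_digest <- function(seq_string, motif, cut_offset = 0L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  scan <- function(pattern) {
    m <- nchar(pattern)
    hits <- integer()
    if (nchar(seq_string) < m) return(hits)
    for (i in seq_len(nchar(seq_string) - m + 1L)) {
      if (substr(seq_string, i, i + m - 1L) == pattern) {
        hits <- c(hits, i - 1L)
      }
    }
    hits
  }
  m <- nchar(motif)
  sites <- scan(motif) + cut_offset
  if (rc(motif) != motif) {
    sites <- c(sites, scan(rc(motif)) + (m - cut_offset))
  }
  sort(unique(sites))
}

# op-by-op CIGAR walk: query/reference consumption and clip lengths
oracle_cigar_walk <- function(cigar, strand) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  qlen <- 0L; rlen <- 0L; clip_l <- 0L; clip_r <- 0L
  seen_body <- FALSE
  for (i in seq_along(ops)) {
    o <- ops[i]; l <- nums[i]
    if (o %in% c("S", "H")) {
      if (seen_body) clip_r <- clip_r + l else clip_l <- clip_l + l
    } else {
      seen_body <- TRUE
      if (o %in% c("M", "I", "=", "X")) qlen <- qlen + l
      if (o %in% c("M", "D", "N", "=", "X")) rlen <- rlen + l
    }
  }
  read_length <- qlen + clip_l + clip_r
  rs <- if (strand == "-") clip_r else clip_l
  list(aligned_query = qlen, ref_len = rlen, clip_left = clip_l,
       clip_right = clip_r, read_length = read_length,
       read_start = rs, read_end = rs + qlen)
}

random_cigar <- function(read_length = 100L) {
  # clip - body(M with occasional I/D) - clip; body starts/ends with M
  n_body <- sample(1:5, 1)
  body_ops <- "M"
  if (n_body > 1) {
    for (i in seq_len(n_body - 1)) {
      body_ops <- c(body_ops, sample(c("I", "D"), 1), "M")
    }
  }
  lens <- sample(1:20, length(body_ops), replace = TRUE)
  q_used <- sum(lens[body_ops %in% c("M", "I")])
  clip_total <- max(0L, read_length - q_used)
  cl <- sample(0:clip_total, 1)
  cr <- clip_total - cl
  parts <- c(
    if (cl > 0) paste0(cl, "S"),
    paste0(lens, body_ops),
    if (cr > 0) paste0(cr, "S")
  )
  paste(parts, collapse = "")
}

# build a segments tibble from compact per-segment specs
make_segments <- function(specs, chromsizes = NULL) {
  flag <- vapply(specs, function(s) {
    f <- 1L + if (s$mate == "R2") 128L else 64L
    if (s$strand == "-") f <- f + 16L
    if (isTRUE(s$supp)) f <- f + 2048L
    f
  }, 0L)
  out <- alignment_segments(
    read_id = vapply(specs, `[[`, "", "read_id"),
    chrom = vapply(specs, `[[`, "", "chrom"),
    pos = vapply(specs, function(s) as.integer(s$ref_start) + 1L, 0L),
    strand = vapply(specs, `[[`, "", "strand"),
    mapq = vapply(specs, function(s) as.integer(s$mapq %||% 60L), 0L),
    cigar = vapply(specs, `[[`, "", "cigar"),
    flag = flag
  )
  ord <- order(match(out$read_id, unique(out$read_id)), out$mate,
               out$read_start)
  out <- out[ord, ]
  if (is.null(chromsizes)) {
    chromsizes <- tibble::tibble(
      chrom = sort(unique(out$chrom)), length = 1000000L
    )
  }
  attr(out, "chromsizes") <- chromsizes
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain data.frame content, with stage-statistics attributes stripped
unattr <- function(x) {
  x <- as.data.frame(x)
  extra <- setdiff(names(attributes(x)), c("names", "class", "row.names"))
  for (a in extra) attr(x, a) <- NULL
  x
}

# per-read enumeration of expected contacts, by direct policy definition
oracle_contacts <- function(aln, policy, window = 500L) {
  p5 <- function(s) if (s$strand == "+") s$ref_start + 1L else s$ref_end
  rows <- list()
  for (rid in unique(aln$read_id)) {
    r <- aln[aln$read_id == rid, ]
    c1 <- r[r$mate == "R1", ]; c1 <- c1[order(c1$read_start), ]
    c2 <- r[r$mate == "R2", ]; c2 <- c2[order(c2$read_start), ]
    pair_of <- function(sa, sb) {
      data.frame(read_id = rid, chrom1 = sa$chrom, pos1 = p5(sa),
                 strand1 = sa$strand, chrom2 = sb$chrom, pos2 = p5(sb),
                 strand2 = sb$strand)
    }
    matches <- function(sa, sb) {
      sa$chrom == sb$chrom && sa$strand != sb$strand &&
        abs(p5(sa) - p5(sb)) <= window
    }
    if (policy == "mask") {
      if (nrow(c1) == 1 && nrow(c2) == 1) {
        rows[[length(rows) + 1]] <- pair_of(c1[1, ], c2[1, ])
      } else if (nrow(c1) == 2 && nrow(c2) == 1 &&
                 matches(c1[2, ], c2[1, ])) {
        rows[[length(rows) + 1]] <- pair_of(c1[1, ], c2[1, ])
      } else if (nrow(c1) == 1 && nrow(c2) == 2 &&
                 matches(c2[2, ], c1[1, ])) {
        rows[[length(rows) + 1]] <- pair_of(c2[1, ], c1[1, ])
      }
    } else {
      walk <- list()
      for (i in seq_len(nrow(c1))) walk[[length(walk) + 1]] <- c1[i, ]
      r2_idx <- rev(seq_len(nrow(c2)))
      if (nrow(c1) > 0 && nrow(c2) > 0 &&
          matches(c1[nrow(c1), ], c2[nrow(c2), ])) {
        r2_idx <- r2_idx[-1]
      }
      for (i in r2_idx) walk[[length(walk) + 1]] <- c2[i, ]
      if (length(walk) >= 2) {
        for (i in seq_len(length(walk) - 1)) {
          rows[[length(rows) + 1]] <- pair_of(walk[[i]], walk[[i + 1]])
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(read_id = character(), chrom1 = character(),
                      pos1 = integer(), strand1 = character(),
                      chrom2 = character(), pos2 = integer(),
                      strand2 = character()))
  }
  do.call(rbind, rows)
}

# canonical sorted key set for contact comparison, swapping sides into
# upper-triangle order under the given chromosome order
contact_keys <- function(df, chrom_order) {
  if (nrow(df) == 0) return(character())
  r1 <- match(df$chrom1, chrom_order); r2 <- match(df$chrom2, chrom_order)
  sw <- r1 > r2 | (r1 == r2 & df$pos1 > df$pos2)
  k1 <- paste(df$chrom1, df$pos1, df$strand1)
  k2 <- paste(df$chrom2, df$pos2, df$strand2)
  sort(paste(df$read_id, ifelse(sw, k2, k1), ifelse(sw, k1, k2)))
}

breakpoint_keys <- function(df) {
  sort(paste(df$read_id, df$chromA, df$posA, df$chromB, df$posB))
}

# independent line-level validation of a 4DN pairs file
validate_pairs_file <- function(path, expect_cols = NULL) {
  lines <- readLines(path)
  errs <- character()
  if (length(lines) == 0 || lines[1] != "## pairs format v1.0") {
    errs <- c(errs, "missing '## pairs format v1.0' first line")
  }
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(hdr) < length(lines[seq_along(hdr)])) {
    errs <- c(errs, "header lines not contiguous at top")
  }
  cs_lines <- grep("^#chromsize: \\S+ \\d+$", hdr, value = TRUE)
  if (length(cs_lines) == 0) errs <- c(errs, "no #chromsize lines")
  chrom_order <- sub("^#chromsize: (\\S+) \\d+$", "\\1", cs_lines)
  col_line <- grep("^#columns:", hdr, value = TRUE)
  if (length(col_line) != 1) errs <- c(errs, "need exactly one #columns line")
  cols <- strsplit(sub("^#columns: *", "", col_line), " ")[[1]]
  core <- c("readID", "chrom1", "pos1", "chrom2", "pos2", "strand1",
            "strand2", "pair_type")
  if (!identical(cols[seq_along(core)], core)) {
    errs <- c(errs, "core columns wrong or out of order")
  }
  if (!is.null(expect_cols) && !identical(cols, expect_cols)) {
    errs <- c(errs, "column declaration mismatch")
  }
  if (length(body) > 0) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != length(cols))) {
      errs <- c(errs, "row with wrong field count")
    }
    c1 <- vapply(fields, `[[`, "", 2); p1 <- as.integer(vapply(fields, `[[`, "", 3))
    c2 <- vapply(fields, `[[`, "", 4); p2 <- as.integer(vapply(fields, `[[`, "", 5))
    r1 <- match(c1, chrom_order); r2 <- match(c2, chrom_order)
    if (anyNA(r1) || anyNA(r2)) errs <- c(errs, "undeclared chromosome in body")
    if (any(p1 < 1) || any(p2 < 1)) errs <- c(errs, "non-positive position")
    if (any(r1 > r2 | (r1 == r2 & p1 > p2))) {
      errs <- c(errs, "row violates upper-triangle ordering")
    }
    key <- cbind(r1, r2, p1, p2)
    resorted <- key[do.call(order, as.data.frame(key)), , drop = FALSE]
    if (!all(resorted == key)) {
      errs <- c(errs, "rows not sorted by chrom1-chrom2-pos1-pos2")
    }
  }
  errs
}
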