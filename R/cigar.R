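# CIGAR arithmetic. All reference/read coordinates in this package are
# 0-based half-open; read coordinates are in ORIGINAL read orientation
# (as sequenced), so minus-strand records flip their clip sides.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_ALIGNED_OPS <- c("M", "I", "=", "X")   # consume query, aligned
REF_OPS <- c("M", "D", "N", "=", "X")        # consume reference
CLIP_OPS <- c("S", "H")

#' Parse CIGAR strings into operation/length pairs
#'
#' @param cigar Character vector of CIGAR strings.
#' @return A list (one element per input) of data frames with columns `op`
#'   and `len`. `"*"` yields a zero-row frame.
#' @examples
#' parse_cigar("10S30M5I25M30S")
#' @export
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  out <- purrr::map2(m, cigar, function(mm, cg) {
    if (is.na(cg) || cg == "*") {
      return(data.frame(op = character(), len = integer()))
    }
    consumed <- sum(nchar(mm[, 1L]))
    if (consumed != nchar(cg)) {
      stop("malformed CIGAR string: ", cg, call. = FALSE)
    }
    data.frame(op = mm[, 3L], len = as.integer(mm[, 2L]))
  })
  out
}

cigar_op_sums <- function(ops) {
  list(
    aligned_query = sum(ops$len[ops$op %in% QUERY_ALIGNED_OPS]),
    ref_len = sum(ops$len[ops$op %in% REF_OPS]),
    clip_left = {
      i <- which(!ops$op %in% CLIP_OPS)
      if (length(i) == 0L) sum(ops$len) else sum(ops$len[seq_len(min(i) - 1L)])
    },
    clip_right = {
      i <- which(!ops$op %in% CLIP_OPS)
      if (length(i) == 0L) 0L
      else sum(ops$len[seq_len(nrow(ops)) > max(i)])
    }
  )
}

#' Read- and reference-span arithmetic for CIGAR strings
#'
#' Computes, for each alignment record, the aligned query length, the
#' reference span length, the clip lengths, and the half-open span the
#' alignment occupies on the original read. For a minus-strand record the
#' clips reported by the aligner are in reference orientation and are
#' flipped back to read orientation.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param strand Character vector, `"+"` or `"-"`, recycled if length 1.
#' @return A tibble with one row per input: `aligned_query`, `ref_len`,
#'   `clip_left`, `clip_right` (reference orientation), `read_length`
#'   (including hard-clipped bases), `read_start`, `read_end` (0-based
#'   half-open, original read orientation) and `is_soft_clipped`.
#' @examples
#' cigar_spans("50M50S", c("+", "-"))
#' @export
cigar_spans <- function(cigar, strand = "+") {
  n <- max(length(cigar), length(strand))
  cigar <- rep_len(cigar, n)
  strand <- rep_len(strand, n)
  parsed <- parse_cigar(cigar)
  rows <- purrr::map2(parsed, strand, function(ops, st) {
    s <- cigar_op_sums(ops)
    read_length <- s$aligned_query + s$clip_left + s$clip_right
    read_start <- if (st == "-") s$clip_right else s$clip_left
    c(
      aligned_query = s$aligned_query, ref_len = s$ref_len,
      clip_left = s$clip_left, clip_right = s$clip_right,
      read_length = read_length,
      read_start = read_start, read_end = read_start + s$aligned_query,
      is_soft_clipped = as.integer(any(ops$op == "S"))
    )
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(
      aligned_query = integer(), ref_len = integer(), clip_left = integer(),
      clip_right = integer(), read_length = integer(),
      read_start = integer(), read_end = integer(),
      is_soft_clipped = logical()
    ))
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$is_soft_clipped <- as.logical(out$is_soft_clipped)
  out
}

# fast single-CIGAR parser for the trimming hot path
cigar_ops_fast <- function(cg) {
  list(
    op = strsplit(gsub("[0-9]+", "", cg), "", fixed = TRUE)[[1L]],
    len = as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cg), " ",
                              fixed = TRUE)[[1L]])
  )
}

cigar_string_fast <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0L) return("*")
  g <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  first <- !duplicated(g)
  merged <- as.integer(rowsum(len, g))
  paste0(merged, op[first], collapse = "")
}

# Remove `n_query` aligned query bases from one reference-orientation side
# of a CIGAR, converting removed query-consuming ops to soft clip and
# dropping reference-only ops (D/N) stranded at the new alignment edge.
# Takes and returns list(op, len); adds ref_removed and all_removed.
trim_cigar <- function(ops, n_query, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(n_query >= 0L)
  if (side == "right") {
    res <- trim_cigar(list(op = rev(ops$op), len = rev(ops$len)),
                      n_query, "left")
    res$op <- rev(res$op); res$len <- rev(res$len)
    return(res)
  }
  op <- ops$op; len <- ops$len
  i <- 1L
  hard <- 0L; soft <- 0L
  # existing clips on this side
  while (i <= length(op) && (op[i] == "S" || op[i] == "H")) {
    if (op[i] == "H") hard <- hard + len[i] else soft <- soft + len[i]
    i <- i + 1L
  }
  remaining <- as.integer(n_query)
  ref_removed <- 0L
  while (i <= length(op) && remaining > 0L) {
    o <- op[i]; l <- len[i]
    if (o == "M" || o == "I" || o == "=" || o == "X") {
      take <- min(l, remaining)
      soft <- soft + take
      if (o != "I") ref_removed <- ref_removed + take
      remaining <- remaining - take
      if (take == l) {
        i <- i + 1L
      } else {
        len[i] <- l - take
      }
    } else if (o == "D" || o == "N" || o == "P") {
      if (o != "P") ref_removed <- ref_removed + l
      i <- i + 1L
    } else {
      stop("unexpected clip op inside alignment: ", o, call. = FALSE)
    }
  }
  # drop reference-only ops stranded at the new edge
  while (i <= length(op) &&
         (op[i] == "D" || op[i] == "N" || op[i] == "P")) {
    if (op[i] != "P") ref_removed <- ref_removed + len[i]
    i <- i + 1L
  }
  body_op <- if (i <= length(op)) op[i:length(op)] else character()
  body_len <- if (i <= length(op)) len[i:length(op)] else integer()
  all_removed <- !any(body_op %in% QUERY_ALIGNED_OPS)
  head_op <- c("H", "S")[c(hard > 0L, soft > 0L)]
  head_len <- c(hard, soft)[c(hard > 0L, soft > 0L)]
  list(
    op = c(head_op, body_op),
    len = c(head_len, body_len),
    ref_removed = ref_removed,
    all_removed = all_removed
  )
}
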