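#' Parse a CIGAR string
#'
#' @param cigar CIGAR string, e.g. `"21M1I29M"`, or `"*"`.
#' @return Data.frame with columns `len` (integer) and `op` (character), in
#'   order; zero rows for `"*"`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(len = integer(), op = character(), stringsAsFactors = FALSE))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (nchar(cigar) != sum(nchar(toks))) stop("malformed CIGAR: ", cigar)
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = sub("^[0-9]+", "", toks),
    stringsAsFactors = FALSE
  )
}

# ops that consume reference bases
.REF_OPS <- c("M", "D", "N", "=", "X")

#' Reference span of a CIGAR
#'
#' Number of reference bases consumed: the sum of lengths of M/D/N/=/X
#' operations.
#'
#' @param cigar CIGAR string.
#' @return Integer reference span (0 for fully clipped reads).
#' @export
cigar_reference_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% .REF_OPS])
}

#' Read aligned reads from a text SAM file
#'
#' Minimal SAM reader sufficient for desk-scale checks: header lines are
#' skipped; unmapped records (rname `*` or flag 0x4) are dropped.
#'
#' @param path Path to a SAM file.
#' @return Data.frame with columns `qname`, `flag`, `contig`, `pos` (0-based
#'   leftmost reference position), `cigar`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(), flag = integer(), contig = character(),
                      pos = integer(), cigar = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) stop("malformed SAM record (fewer than 11 fields)")
  out <- data.frame(
    qname = vapply(f, `[[`, "", 1L),
    flag = as.integer(vapply(f, `[[`, "", 2L)),
    contig = vapply(f, `[[`, "", 3L),
    pos = as.integer(vapply(f, `[[`, "", 4L)) - 1L,   # SAM POS is 1-based
    cigar = vapply(f, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
  out[out$contig != "*" & bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]
}

#' Fraction of region-overlapping reads carrying an insertion
#'
#' For a fixed genomic region, counts reads whose CIGAR-derived reference span
#' intersects the region, and among those, reads with at least one insertion
#' (`I`) anchored inside the region. An insertion is anchored at the reference
#' position immediately preceding the inserted bases. Reads containing any
#' soft-clip (`S`) operation are excluded from numerator and denominator.
#' Hard clips are ignored; `=`/`X` count as `M`.
#'
#' This mirrors the check used to confirm a single-nucleotide insertion at an
#' edited locus across sequencing replicates.
#'
#' @param reads Data.frame as from [read_sam()].
#' @param contig Region contig name.
#' @param start,end Region interval, 0-based half-open.
#' @return List with `n_overlapping`, `n_with_insertion`, `fraction`
#'   (`NA` when no read overlaps).
#' @export
count_insertion_fraction <- function(reads, contig, start, end) {
  stopifnot(start < end)
  n_over <- 0L
  n_ins <- 0L
  reads <- reads[reads$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(reads))) {
    ops <- parse_cigar(reads$cigar[i])
    if (any(ops$op == "S")) next   # soft-clipped reads excluded entirely
    span <- sum(ops$len[ops$op %in% .REF_OPS])
    r0 <- reads$pos[i]
    if (r0 >= end || r0 + span <= start) next
    n_over <- n_over + 1L
    # walk the CIGAR tracking the reference cursor to anchor insertions
    ref <- r0
    has_ins <- FALSE
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]
      if (op == "I") {
        anchor <- ref - 1L   # ref base immediately preceding the insertion
        if (anchor >= start && anchor < end) has_ins <- TRUE
      } else if (op %in% .REF_OPS) {
        ref <- ref + ops$len[j]
      }
    }
    if (has_ins) n_ins <- n_ins + 1L
  }
  list(
    n_overlapping = n_over,
    n_with_insertion = n_ins,
    fraction = if (n_over > 0L) n_ins / n_over else NA_real_
  )
}

#' Parse a samtools-style region string
#'
#' `"contig:start-end"` with 1-based closed coordinates by default (as in
#' samtools); set `one_based = FALSE` for 0-based half-open input. The return
#' value is always 0-based half-open.
#'
#' @param region Region string.
#' @param one_based Interpret coordinates as 1-based closed (default `TRUE`).
#' @return List with `contig`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(region, one_based = TRUE) {
  m <- regmatches(region, regexec("^(.+):([0-9,]+)-([0-9,]+)$", region))[[1L]]
  if (length(m) != 4L) stop("cannot parse region string: ", region)
  s <- as.integer(gsub(",", "", m[3L]))
  e <- as.integer(gsub(",", "", m[4L]))
  if (one_based) s <- s - 1L
  if (s >= e) stop("empty region: ", region)
  list(contig = m[2L], start = s, end = e)
}
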