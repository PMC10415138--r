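#' Polypyrimidine-tract length by the sliding-window rule
#'
#' Scans the 3'-terminal interval of an intron (at most 50 nt) with sliding
#' windows of `window` nt (step 1) and computes the pyrimidine fraction
#' (C or T; U is accepted as T) in each. The tract is anchored at the
#' earliest window start from which every window through the end of the
#' interval has pyrimidine fraction at or above `threshold` ("rises to 0.5
#' and stays high"); its length is the distance from that start to the
#' interval end. Returns 0 when no such start exists or the interval is
#' shorter than one window. `N` counts as non-pyrimidine.
#'
#' @param seq Character string: the 3'-terminal intron interval (5'->3'),
#'   length `min(50, intron length)`.
#' @param window Window size in nt (default 5).
#' @param threshold Minimum pyrimidine fraction (default 0.5).
#' @return Integer tract length in nt.
#' @export
py_tract_length <- function(seq, window = 5L, threshold = 0.5) {
  x <- strsplit(toupper(seq), "")[[1L]]
  x[x == "U"] <- "T"
  if (!all(x %in% c("A", "C", "G", "T", "N"))) {
    stop("invalid characters in sequence (expected A/C/G/T/N/U)")
  }
  W <- length(x)
  if (W < window) return(0L)
  pyr <- as.integer(x %in% c("C", "T"))
  cs <- c(0L, cumsum(pyr))
  starts <- seq_len(W - window + 1L)
  f <- (cs[starts + window] - cs[starts]) / window
  ok <- f >= threshold
  if (!any(ok)) return(0L)
  bad <- which(!ok)
  p_star <- if (length(bad) == 0L) 1L else max(bad) + 1L
  if (p_star > length(starts)) return(0L)
  W - p_star + 1L
}

#' Weight-matrix splice-site model
#'
#' A position-specific probability model for scoring splice-site windows in
#' bits: `score = sum_pos log2(p(base, pos) / q(base))`. Serves as the
#' self-contained default scorer; externally trained maximum-entropy score
#' tables can be supplied via [read_maxent_table()] instead.
#'
#' @param probs 4 x k numeric matrix of per-position base probabilities with
#'   rownames `A,C,G,T`; columns must sum to 1.
#' @param background Length-4 background distribution (default uniform).
#' @return Object of class `splice_site_model` (kind `"wmm"`).
#' @export
wmm_model <- function(probs, background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(is.matrix(probs), nrow(probs) == 4L)
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "T")
  stopifnot(identical(sort(rownames(probs)), c("A", "C", "G", "T")))
  if (any(abs(colSums(probs) - 1) > 1e-9)) stop("wmm columns must sum to 1")
  if (any(background <= 0)) stop("background must be strictly positive")
  structure(list(kind = "wmm", probs = probs[c("A", "C", "G", "T"), , drop = FALSE],
                 background = background[c("A", "C", "G", "T")], width = ncol(probs)),
            class = "splice_site_model")
}

# consensus-weighted column: prob `w` on the consensus base, rest shared
.wmm_col <- function(consensus, w = 0.7) {
  p <- rep((1 - w) / 3, 4); names(p) <- c("A", "C", "G", "T")
  p[consensus] <- w
  p
}

#' Default donor (5'SS) scoring model
#'
#' 9-mer window: 3 exonic + 6 intronic positions around the donor site, with
#' the mammalian consensus (c)AG|GTAAGT weighted at each position and the
#' near-invariant GT strongly weighted.
#'
#' @return A `splice_site_model` of width 9.
#' @export
default_donor_model <- function() {
  cons <- c("C", "A", "G", "G", "T", "A", "A", "G", "T")
  w <- c(.4, .6, .75, .95, .95, .6, .65, .75, .5)
  wmm_model(mapply(.wmm_col, cons, w))
}

#' Default acceptor (3'SS) scoring model
#'
#' 23-mer window: 20 intronic + 3 exonic positions. The intronic positions
#' favor pyrimidines (the polypyrimidine tract), ending in the near-invariant
#' AG, followed by a weakly G-biased exonic start.
#'
#' @return A `splice_site_model` of width 23.
#' @export
default_acceptor_model <- function() {
  py <- c(A = .12, C = .36, G = .12, T = .40)
  cols <- matrix(rep(py, 17L), nrow = 4, dimnames = list(names(py), NULL))
  cols <- cbind(cols, .wmm_col("C", .5), .wmm_col("A", .95), .wmm_col("G", .95),
                .wmm_col("G", .45), .wmm_col("T", .3), .wmm_col("C", .3))
  wmm_model(cols)
}

#' Read a tabulated k-mer score table
#'
#' Reads a two-column TSV (`kmer`, `score`) such as an externally computed
#' maximum-entropy score table, for direct-lookup scoring.
#'
#' @param path Path to the TSV file (header required).
#' @param default Score returned for k-mers absent from the table; `NULL`
#'   (default) makes missing k-mers an error.
#' @return Object of class `splice_site_model` (kind `"maxent_table"`).
#' @export
read_maxent_table <- function(path, default = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(ncol(df) >= 2L)
  kmers <- toupper(df[[1L]])
  if (anyDuplicated(kmers)) stop("duplicate k-mers in score table")
  width <- unique(nchar(kmers))
  if (length(width) != 1L) stop("k-mers of mixed width in score table")
  scores <- as.numeric(df[[2L]])
  names(scores) <- kmers
  structure(list(kind = "maxent_table", table = scores, width = width,
                 default = default),
            class = "splice_site_model")
}

#' Score a splice-site window
#'
#' Weight-matrix models score in bits (`sum log2(p/q)` over positions);
#' table models look the k-mer up directly. Sequences containing `N` score
#' `NA`.
#'
#' @param seq Character vector of k-mers matching the model width.
#' @param model A `splice_site_model`.
#' @return Numeric score vector (bits for wmm models).
#' @export
score_splice_site <- function(seq, model) {
  stopifnot(inherits(model, "splice_site_model"))
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad_width <- !is.na(seq) & nchar(seq) != model$width
  if (any(bad_width)) stop("sequence length does not match model width ", model$width)
  if (model$kind == "maxent_table") {
    out <- unname(model$table[seq])
    miss <- !is.na(seq) & !grepl("N", seq) & is.na(out)
    if (any(miss)) {
      if (is.null(model$default)) stop("k-mer absent from score table: ", seq[miss][1L])
      out[miss] <- model$default
    }
    out[grepl("N", seq)] <- NA_real_
    return(out)
  }
  lo <- log2(model$probs / model$background)   # 4 x width
  vapply(seq, function(s) {
    if (is.na(s) || grepl("N", s)) return(NA_real_)
    b <- strsplit(s, "")[[1L]]
    ri <- match(b, rownames(lo))
    if (anyNA(ri)) stop("invalid base in ", s)
    sum(lo[cbind(ri, seq_along(b))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter to introns with a single reported donor-acceptor pairing
#'
#' An intron is kept only if its donor coordinate pairs with exactly one
#' acceptor coordinate in the data and vice versa, restricting the analysis
#' to constitutively defined splice sites.
#'
#' @param introns Data.frame of intron records (`contig`, `start`, `end`,
#'   `strand`).
#' @return The retained subset of `introns`.
#' @export
unique_ss_filter <- function(introns) {
  if (nrow(introns) == 0L) return(introns)
  donor_pos <- ifelse(introns$strand == "-", introns$end, introns$start)
  accept_pos <- ifelse(introns$strand == "-", introns$start, introns$end)
  dkey <- paste(introns$contig, introns$strand, donor_pos)
  akey <- paste(introns$contig, introns$strand, accept_pos)
  pair <- !duplicated(paste(dkey, akey))
  n_acc_per_donor <- tapply(akey[pair], dkey[pair], function(x) length(unique(x)))
  n_don_per_accept <- tapply(dkey[pair], akey[pair], function(x) length(unique(x)))
  keep <- n_acc_per_donor[dkey] == 1L & n_don_per_accept[akey] == 1L
  introns[keep, , drop = FALSE]
}

# strand-oriented sequence of [start, end) on `contig`; 0-based half-open
.extract_seq <- function(genome, contig, start, end, strand) {
  if (!contig %in% names(genome)) stop("contig not in genome: ", contig)
  len <- Biostrings::width(genome[contig])
  if (start < 0L || end > len) stop("interval outside contig bounds: ",
                                    contig, ":", start, "-", end)
  s <- Biostrings::subseq(genome[[contig]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Compute per-intron sequence features
#'
#' For every intron: length, GC fraction (N excluded from the denominator),
#' donor and acceptor scores on MaxEntScan-convention windows (9-mer: 3 exonic
#' + 6 intronic; 23-mer: 20 intronic + 3 exonic), and polypyrimidine-tract
#' length over the terminal `min(50, length)` nt (including the acceptor AG
#' unless `py_offset` shifts the interval). Minus-strand introns are handled
#' in transcript orientation.
#'
#' @param introns Data.frame of intron records (`feature_id` or `intron_id`,
#'   `gene_id`, `contig`, `start`, `end`, `strand`).
#' @param genome Named `DNAStringSet` as from [read_genome_fasta()].
#' @param donor_model,acceptor_model `splice_site_model` objects; defaults are
#'   the built-in weight matrices.
#' @param py_offset Number of terminal nt to exclude from the PY-tract
#'   interval (default 0, i.e. the acceptor AG is included).
#' @return Data.frame of class `feature_table` with one row per intron:
#'   `intron_id`, `gene_id`, `intron_length`, `gc_fraction`, `ss5_score`,
#'   `ss3_score`, `py_tract_length`.
#' @export
compute_features <- function(introns, genome,
                             donor_model = default_donor_model(),
                             acceptor_model = default_acceptor_model(),
                             py_offset = 0L) {
  id <- if ("intron_id" %in% names(introns)) introns$intron_id else introns$feature_id
  n <- nrow(introns)
  out <- data.frame(
    intron_id = id, gene_id = introns$gene_id,
    intron_length = introns$end - introns$start,
    gc_fraction = NA_real_, ss5_score = NA_real_, ss3_score = NA_real_,
    py_tract_length = NA_integer_, stringsAsFactors = FALSE
  )
  don_ex <- 3L; don_in <- donor_model$width - 3L
  acc_ex <- 3L; acc_in <- acceptor_model$width - 3L
  for (i in seq_len(n)) {
    ctg <- introns$contig[i]; s <- introns$start[i]; e <- introns$end[i]
    str <- introns$strand[i]
    seq <- .extract_seq(genome, ctg, s, e, str)
    b <- strsplit(seq, "")[[1L]]
    acgt <- b[b != "N"]
    out$gc_fraction[i] <- if (length(acgt)) mean(acgt %in% c("G", "C")) else NA_real_
    W <- min(50L, nchar(seq) - py_offset)
    out$py_tract_length[i] <- if (W >= 1L) {
      py_tract_length(substr(seq, nchar(seq) - py_offset - W + 1L,
                             nchar(seq) - py_offset))
    } else 0L
    clen <- Biostrings::width(genome[ctg])
    # donor window: exonic flank + intron start (transcript orientation)
    don <- tryCatch({
      if (str == "-") .extract_seq(genome, ctg, e - don_in, e + don_ex, "-")
      else .extract_seq(genome, ctg, s - don_ex, s + don_in, "+")
    }, error = function(e) NA_character_)
    acc <- tryCatch({
      if (str == "-") .extract_seq(genome, ctg, s - acc_ex, s + acc_in, "-")
      else .extract_seq(genome, ctg, e - acc_in, e + acc_ex, "+")
    }, error = function(e) NA_character_)
    out$ss5_score[i] <- if (is.na(don)) NA_real_ else score_splice_site(don, donor_model)
    out$ss3_score[i] <- if (is.na(acc)) NA_real_ else score_splice_site(acc, acceptor_model)
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Flag snoRNA-hosting introns
#'
#' An intron hosts a snoRNA if a snoRNA interval is fully contained in it
#' (strand-agnostic by default); set `partial = TRUE` to accept any overlap.
#'
#' @param introns Data.frame of intron records.
#' @param snorna Data.frame of snoRNA records (`contig`, `start`, `end`).
#' @param partial Accept partial overlap instead of containment.
#' @return Logical vector aligned with `introns` rows.
#' @export
annotate_snorna_overlap <- function(introns, snorna, partial = FALSE) {
  flag <- logical(nrow(introns))
  if (nrow(snorna) == 0L || nrow(introns) == 0L) return(flag)
  for (ctg in unique(introns$contig)) {
    ii <- which(introns$contig == ctg)
    ss <- snorna[snorna$contig == ctg, , drop = FALSE]
    if (nrow(ss) == 0L) next
    ir <- IRanges::IRanges(start = introns$start[ii] + 1L, end = introns$end[ii])
    sr <- IRanges::IRanges(start = ss$start + 1L, end = ss$end)
    hits <- IRanges::findOverlaps(sr, ir,
                                  type = if (partial) "any" else "within")
    flag[ii[unique(S4Vectors::subjectHits(hits))]] <- TRUE
  }
  flag
}
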