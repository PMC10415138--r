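#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and `U` is mapped to `T`, so RNA FASTA files are
#' accepted transparently. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; names are the first whitespace-delimited
#'   token of each header line.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write a genome FASTA file
#'
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read genomic annotation (GTF or BED) into 0-based half-open records
#'
#' All internal coordinates in this package are 0-based half-open regardless of
#' the source dialect: GTF's 1-based closed intervals are converted on read,
#' BED intervals pass through unchanged. When a GTF carries exon but no intron
#' records, introns can be derived per transcript as the gaps between
#' consecutive exons.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"bed"`.
#' @param derive_introns If `TRUE` (default) and the file contains no rows with
#'   `feature_kind == "intron"`, intron records are added as inter-exon gaps of
#'   each transcript (requires `transcript_id` attributes in GTF input).
#' @return A data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `feature_kind`, `gene_id`, `feature_id`.
#' @export
read_annotation <- function(path, dialect = c("gtf", "bed"), derive_introns = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    ann <- data.frame(
      contig = as.character(df$seqnames),
      start = df$start - 1L,          # GTF is 1-based closed
      end = df$end,
      strand = as.character(df$strand),
      feature_kind = as.character(df$type),
      gene_id = if ("gene_id" %in% names(df)) as.character(df$gene_id) else NA_character_,
      feature_id = .pick_feature_id(df),
      stringsAsFactors = FALSE
    )
    if ("transcript_id" %in% names(df)) {
      ann$transcript_id <- as.character(df$transcript_id)
    } else {
      ann$transcript_id <- NA_character_
    }
  } else {
    ann <- .read_bed(path)
  }
  if (any(ann$start >= ann$end)) {
    bad <- which(ann$start >= ann$end)[1L]
    stop("start >= end after coordinate conversion at record ", bad)
  }
  if (any(ann$feature_kind %in% c("exon", "intron") & !ann$strand %in% c("+", "-"))) {
    stop("exon/intron records must have strand '+' or '-'")
  }
  if (derive_introns && !any(ann$feature_kind == "intron")) {
    ann <- rbind(ann, derive_intron_records(ann))
  }
  rownames(ann) <- NULL
  ann
}

.pick_feature_id <- function(df) {
  if ("feature_id" %in% names(df)) return(as.character(df$feature_id))
  id <- rep(NA_character_, nrow(df))
  for (col in c("exon_id", "transcript_id", "gene_id")) {
    if (col %in% names(df)) {
      take <- is.na(id) & !is.na(df[[col]])
      id[take] <- as.character(df[[col]][take])
    }
  }
  id
}

.read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  nm <- if ("name" %in% names(df)) as.character(df$name) else NA_character_
  data.frame(
    contig = as.character(df$seqnames),
    start = df$start - 1L,            # GRanges is 1-based; BED file values restored
    end = df$end,
    strand = as.character(df$strand),
    feature_kind = "bed",
    gene_id = nm,
    feature_id = nm,
    transcript_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Derive intron records from exon annotation
#'
#' Introns are the gaps between consecutive exons of the same transcript
#' (falling back to `gene_id` where `transcript_id` is absent). Intron ids are
#' `<gene_id>.i<k>` numbered 5' to 3' along the transcript strand.
#'
#' @param ann Annotation data.frame as returned by [read_annotation()].
#' @return Data.frame of intron records in the same schema.
#' @export
derive_intron_records <- function(ann) {
  ex <- ann[ann$feature_kind == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) return(ann[0, , drop = FALSE])
  key <- ifelse(is.na(ex$transcript_id), ex$gene_id, ex$transcript_id)
  out <- lapply(split(ex, key), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    if (n < 2L) return(NULL)
    if (any(e$start[-1] < e$end[-n])) {
      stop("overlapping exons within transcript ", key[1])
    }
    istart <- e$end[-n]
    iend <- e$start[-1]
    minus <- e$strand[1] == "-"
    ord <- if (minus) rev(seq_len(n - 1L)) else seq_len(n - 1L)
    data.frame(
      contig = e$contig[1], start = istart, end = iend, strand = e$strand[1],
      feature_kind = "intron", gene_id = e$gene_id[1],
      feature_id = paste0(e$gene_id[1], ".i", ord),
      transcript_id = e$transcript_id[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write annotation records to GTF or BED
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' converted back to the dialect's convention, so a read/write round trip
#' preserves file coordinates exactly.
#'
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    attrs <- sprintf('gene_id "%s"; feature_id "%s";', ann$gene_id, ann$feature_id)
    has_tx <- "transcript_id" %in% names(ann) & !is.na(ann$transcript_id)
    if (any(has_tx)) {
      attrs[has_tx] <- sprintf('gene_id "%s"; transcript_id "%s"; feature_id "%s";',
                               ann$gene_id[has_tx], ann$transcript_id[has_tx],
                               ann$feature_id[has_tx])
    }
    lines <- sprintf("%s\tintronscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     ann$contig, ann$feature_kind, ann$start + 1L, ann$end,
                     ann$strand, attrs)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     ann$contig, ann$start, ann$end,
                     ifelse(is.na(ann$feature_id), ".", ann$feature_id),
                     ann$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV count matrix
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' Entries must be non-negative integers; missing cells, duplicated feature
#' ids and empty sample columns are rejected.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, rows = features, columns = samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("count table needs a feature column plus >=1 sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicated feature id: ", ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (any(is.na(vals)) || any(vals == "")) stop("missing cells in count table")
  num <- suppressWarnings(as.numeric(vals))
  if (any(is.na(num))) stop("non-numeric entry in count table")
  if (any(num < 0)) stop("negative entry in count table")
  if (any(num != round(num))) stop("non-integer entry in count table")
  m <- matrix(as.integer(num), nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1L]))
  m
}

#' Write a count matrix as TSV
#'
#' @param m Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_col Name of the feature-id column in the header.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
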