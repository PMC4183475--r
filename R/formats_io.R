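# Readers and writers for the external artifacts the pipeline consumes and
# produces: FASTA (aligned and unaligned), sample maps, taxonomy tables,
# region annotations and OTU tables.  Newick trees go through ape.
#
# All readers validate and fail loudly, naming the offending record; none
# silently skips malformed input.  Coordinates in annotation tables are
# 0-based half-open, stated in the file header.

#' Read a FASTA file
#'
#' Reads DNA sequences (aligned or unaligned) into a named character vector.
#' Sequences are uppercased on read; gap characters (`-`) are retained so
#' alignment files round-trip.  Sequence ids (the first whitespace-delimited
#' token of each header) must be unique and every record non-empty.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences over
#'   `A,C,G,T,N,-`; names are ids, the remainder of each header line is kept
#'   in the `"description"` attribute (a character vector parallel to the
#'   sequences).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[[1L]], ">"))
    stop("not a FASTA file (no '>' header): ", path)
  hdr <- startsWith(lines, ">")
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("FASTA record with empty id at header #", which(!nzchar(ids))[1L])
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", .msg_id(ids[duplicated(ids)][1L]))
  seqs <- vapply(split(lines[!hdr], factor(rec[!hdr], levels = seq_along(ids))),
                 paste, character(1), collapse = "")
  seqs <- toupper(seqs)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty FASTA record: ", .msg_id(ids[empty][1L]))
  bad <- !.is_dna(seqs)
  if (any(bad))
    stop("non-DNA characters in FASTA record ", .msg_id(ids[bad][1L]),
         " (allowed: ", paste(SEQ_ALPHABET, collapse = ""), ")")
  names(seqs) <- ids
  attr(seqs, "description") <- unname(desc)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  desc <- attr(seqs, "description")
  hdr <- paste0(">", names(seqs),
                if (!is.null(desc)) ifelse(nzchar(desc), paste0(" ", desc), "")
                else "")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    out[[i]] <- c(hdr[[i]], substring(s, starts, pmin(starts + width - 1L,
                                                      nchar(s))))
  }
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read a sample map
#'
#' Tab-separated file with columns `sample_id`, `barcode`, `treatment`,
#' `plot`.  Validates that barcodes are DNA of one common length and that
#' every pair of barcodes differs at >= `min_barcode_dist` positions (the
#' multiplexing design guarantee that makes 1-mismatch demultiplexing
#' unambiguous).
#'
#' @param path Path to the TSV.
#' @param min_barcode_dist Minimum pairwise Hamming distance between
#'   barcodes.
#' @return `data.frame` with character columns `sample_id`, `barcode`,
#'   `treatment`, `plot`.
#' @export
read_sample_map <- function(path, min_barcode_dist = 4L) {
  if (!file.exists(path)) stop("sample map not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "barcode", "treatment", "plot")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample map missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  validate_sample_map(df, min_barcode_dist = min_barcode_dist)
  df
}

#' Validate a sample map
#'
#' @param map Sample-map `data.frame` (see [read_sample_map()]).
#' @param min_barcode_dist Minimum pairwise barcode Hamming distance.
#' @return `map`, invisibly; errors on violation.
#' @export
validate_sample_map <- function(map, min_barcode_dist = 4L) {
  if (anyDuplicated(map$sample_id))
    stop("duplicate sample_id: ",
         .msg_id(map$sample_id[duplicated(map$sample_id)][1L]))
  bad <- !.is_dna(map$barcode, allow = DNA_BASES)
  if (any(bad))
    stop("non-DNA barcode for sample ", .msg_id(map$sample_id[bad][1L]))
  if (length(unique(nchar(map$barcode))) > 1L)
    stop("barcodes differ in length")
  n <- nrow(map)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- .hamming(map$barcode[[i]], map$barcode[[j]])
        if (d < min_barcode_dist)
          stop("barcodes of samples ", .msg_id(map$sample_id[[i]]), " and ",
               .msg_id(map$sample_id[[j]]), " differ at only ", d,
               " position(s); design requires >= ", min_barcode_dist)
      }
    }
  }
  invisible(map)
}

#' Write a sample map
#' @param map Sample-map `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- taxonomy lineages ------------------------------------------------------

#' Parse a rank-delimited lineage string
#'
#' Lineages run phylum > class > order > family > genus > species and may
#' terminate early; a named rank implies all shallower ranks are named.
#'
#' @param x Lineage string, taxa separated by `;`.
#' @param sep Separator.
#' @return Named character vector (names are rank names), possibly empty.
#' @export
parse_lineage <- function(x, sep = ";") {
  parts <- strsplit(x, sep, fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) > length(TAX_RANKS))
    stop("lineage has more than ", length(TAX_RANKS), " ranks: ", x)
  stats::setNames(parts, TAX_RANKS[seq_along(parts)])
}

#' Serialize a lineage to a string
#' @param lineage Named character vector as returned by [parse_lineage()].
#' @param sep Separator.
#' @return Single string.
#' @export
lineage_string <- function(lineage, sep = ";") {
  paste(lineage, collapse = sep)
}

#' Read a taxonomy table
#'
#' Tab-separated file `id<TAB>lineage` with `;`-delimited lineages.
#'
#' @param path Path to the TSV (no header).
#' @return Named list of lineages (named character vectors).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "lineage"),
                          colClasses = "character")
  if (anyDuplicated(df$id))
    stop("duplicate taxonomy id: ", .msg_id(df$id[duplicated(df$id)][1L]))
  out <- lapply(df$lineage, parse_lineage)
  names(out) <- df$id
  out
}

#' Write a taxonomy table
#' @param taxonomy Named list of lineages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lines <- paste(names(taxonomy),
                 vapply(taxonomy, lineage_string, character(1)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- region annotation ------------------------------------------------------

#' Read a region annotation
#'
#' Tab-separated table with columns `start`, `end`, `label` and a `frame`
#' column on the first row.  Coordinates are 0-based half-open over the
#' reference alignment; labels are `exon` or `intron` and must tile the
#' alignment without gaps or overlaps.
#'
#' @param path Path to the TSV (comment lines start with `#`).
#' @return `data.frame` with integer `start`, `end` and character `label`;
#'   the reading-frame offset of the first exon column is kept in the
#'   `"frame"` attribute.
#' @export
read_region_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("start", "end", "label", "frame")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  ann <- region_annotation(df$start, df$end, df$label,
                           frame = df$frame[[1L]])
  ann
}

#' Construct and validate a region annotation
#'
#' @param start,end Integer vectors, 0-based half-open over alignment
#'   columns.
#' @param label Character vector, `"exon"` or `"intron"`.
#' @param frame Reading-frame offset (0, 1 or 2) of the first exon column.
#' @return Validated annotation `data.frame` with `"frame"` attribute.
#' @export
region_annotation <- function(start, end, label, frame = 0L) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  if (!all(df$label %in% c("exon", "intron")))
    stop("annotation labels must be 'exon' or 'intron'")
  if (any(df$end <= df$start))
    stop("annotation region with end <= start at row ",
         which(df$end <= df$start)[1L])
  if (nrow(df) > 1L && any(df$start[-1L] != df$end[-nrow(df)]))
    stop("annotation regions must tile the alignment (no gaps/overlaps)")
  if (df$start[[1L]] != 0L)
    stop("annotation must start at column 0")
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  attr(df, "frame") <- frame
  df
}

#' Write a region annotation
#' @param ann Annotation `data.frame` (see [region_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_annotation <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open alignment columns", con)
  df <- ann
  df$frame <- attr(ann, "frame")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-column region labels
#'
#' Expands an annotation into one `"exon"`/`"intron"` label per alignment
#' column.
#'
#' @param ann Annotation `data.frame`.
#' @param n_col Alignment length; must equal the annotated extent.
#' @return Character vector of length `n_col`.
#' @export
region_labels <- function(ann, n_col) {
  if (max(ann$end) != n_col)
    stop("annotation covers ", max(ann$end), " columns but alignment has ",
         n_col)
  rep(ann$label, ann$end - ann$start)
}

# ---- OTU tables -------------------------------------------------------------

#' Construct an OTU table
#'
#' @param counts Integer matrix, OTUs in rows, samples in columns; row and
#'   column names required and unique.
#' @param taxonomy Optional named character vector of lineage strings, one
#'   per OTU.
#' @return An object of class `gp_otu_table`.
#' @export
otu_table_gp <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if ((is.null(rownames(counts)) && nrow(counts) > 0L) ||
      (is.null(colnames(counts)) && ncol(counts) > 0L))
    stop("OTU table needs row (OTU) and column (sample) names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("OTU table ids must be unique")
  if (length(counts) && (any(counts < 0) || any(counts != round(counts))))
    stop("OTU table counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(taxonomy)) {
    taxonomy <- stats::setNames(rep("", nrow(counts)), rownames(counts))
  } else {
    if (!all(rownames(counts) %in% names(taxonomy)))
      stop("taxonomy missing for some OTUs")
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "gp_otu_table")
}

#' @method print gp_otu_table
#' @export
print.gp_otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples;",
      sum(x$counts), "reads\n")
  invisible(x)
}

#' Write an OTU table to TSV
#'
#' One row per OTU: `otu_id`, one column per sample, then `taxonomy`.
#'
#' @param table A `gp_otu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "gp_otu_table"))
  ids <- rownames(table$counts) %||% character(0)
  df <- data.frame(otu_id = ids,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$taxonomy <- unname(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table from TSV
#' @param path Path written by [write_otu_table()].
#' @return A `gp_otu_table`.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("OTU table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df)[1L], "otu_id") ||
      !identical(names(df)[length(df)], "taxonomy"))
    stop("OTU table must have 'otu_id' first and 'taxonomy' last")
  samples <- names(df)[-c(1L, length(df))]
  counts <- as.matrix(df[samples])
  suppressWarnings(storage.mode(counts) <- "integer")
  if (length(counts) && anyNA(counts))
    stop("non-integer count in OTU table: ", path)
  rownames(counts) <- df$otu_id
  if (nrow(counts) && any(counts < 0))
    stop("negative count in OTU table for OTU ",
         .msg_id(df$otu_id[which(rowSums(counts < 0) > 0)[1L]]))
  otu_table_gp(counts, stats::setNames(df$taxonomy, df$otu_id))
}
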