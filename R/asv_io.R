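# Readers and writers for the tabular and sequence formats the rest of the
# package consumes.  All tables are plain TSV: tab separated, UTF-8, no
# quoting, lines starting with '#' ignored.  ASV tables are oriented
# rows = ASVs, columns = samples; transposed input is never auto-detected.

IUPAC_CHARS <- c("A", "C", "G", "T", "-", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct an ASV count table
#'
#' An `asv_table` is a non-negative integer-valued matrix with ASVs as rows
#' and samples as columns, the package's central container for denoised
#' amplicon counts.
#'
#' @param counts Numeric matrix of non-negative integers (values are stored
#'   as doubles so counts above `.Machine$integer.max` survive intact).
#' @param asv_ids,sample_ids Unique character vectors naming rows and
#'   columns; taken from `dimnames(counts)` when omitted.
#' @return An object of class `asv_table`: the counts matrix with row and
#'   column names set.
#' @export
asv_table <- function(counts, asv_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(asv_ids) || is.null(sample_ids))
    stop("asv_table requires ASV ids and sample ids")
  asv_ids <- as.character(asv_ids)
  sample_ids <- as.character(sample_ids)
  if (length(asv_ids) != nrow(counts))
    stop("length of asv_ids (", length(asv_ids), ") != number of rows (",
         nrow(counts), ")")
  if (length(sample_ids) != ncol(counts))
    stop("length of sample_ids (", length(sample_ids),
         ") != number of columns (", ncol(counts), ")")
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV id: ", asv_ids[duplicated(asv_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  storage.mode(counts) <- "double"
  if (length(counts) && (anyNA(counts) || any(counts < 0) ||
                         any(counts != trunc(counts))))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(asv_ids, sample_ids)
  class(counts) <- c("asv_table", "matrix", "array")
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat("ASV count table: ", nrow(x), " ASVs x ", ncol(x), " samples, total ",
      format(sum(x), big.mark = ","), " reads\n", sep = "")
  invisible(x)
}

#' @export
`[.asv_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("asv_table", "matrix", "array")
  out
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Read an ASV count table from TSV
#'
#' Expects a header row of sample ids (first cell is the ASV-id column
#' label) and one row per ASV.  Cells must be non-negative integers;
#' malformed cells and duplicate ids raise errors naming the offending
#' row or column.
#'
#' @param path Path to a tab-separated file.
#' @return An [asv_table].
#' @seealso [write_asv_table()]
#' @export
read_asv_table <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 1L) stop("malformed header in ", path)
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         sample_ids[duplicated(sample_ids)][1L])
  asv_ids <- df[[1L]]
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV id: ", asv_ids[duplicated(asv_ids)][1L])
  n <- nrow(df)
  counts <- matrix(0, n, length(sample_ids),
                   dimnames = list(asv_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- df[[j + 1L]]
    bad <- !grepl("^[0-9]+$", cell)
    if (any(bad))
      stop("non-integer count at ASV '", asv_ids[which(bad)[1L]],
           "', sample '", sample_ids[j], "': '", cell[which(bad)[1L]], "'")
    counts[, j] <- as.numeric(cell)
  }
  asv_table(counts, asv_ids, sample_ids)
}

#' Write an ASV count table as TSV
#'
#' Inverse of [read_asv_table()]: the written file re-reads to an identical
#' counts matrix (integer-exact; counts are formatted without scientific
#' notation).
#'
#' @param table An [asv_table].
#' @param path Output path.
#' @export
write_asv_table <- function(table, path) {
  stopifnot(inherits(table, "asv_table"))
  cells <- matrix(format(unclass(table), scientific = FALSE, trim = TRUE),
                  nrow = nrow(table), ncol = ncol(table))
  lines <- paste(c("asv_id", colnames(table)), collapse = "\t")
  if (nrow(table))
    lines <- c(lines, vapply(seq_len(nrow(table)), function(i)
      paste(c(rownames(table)[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read an ASV taxonomy table
#'
#' Two tab-separated columns: ASV id and a semicolon-joined lineage
#' (domain down to genus, at most seven ranks; empty ranks allowed).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A named list mapping ASV id to a character vector of lineage
#'   ranks, of class `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("taxonomy file needs two columns: ", path)
  taxonomy_table(stats::setNames(
    lapply(df[[2L]], function(s) trimws(strsplit(s, ";", fixed = TRUE)[[1L]])),
    df[[1L]]))
}

#' @rdname read_taxonomy
#' @param lineages Named list of character lineage vectors (one per ASV).
#' @export
taxonomy_table <- function(lineages) {
  if (is.null(names(lineages)) || anyDuplicated(names(lineages)))
    stop("taxonomy requires unique ASV ids")
  if (any(vapply(lineages, length, 1L) > 7L))
    stop("lineage longer than 7 ranks")
  structure(lineages, class = "taxonomy_table")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("Taxonomy for", length(x), "ASVs\n")
  invisible(x)
}

#' Write a taxonomy table as TSV
#' @param taxonomy A `taxonomy_table`.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(asv_id = names(taxonomy),
                   lineage = vapply(taxonomy, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read sample metadata (sample to group mapping)
#'
#' Two tab-separated columns: sample id and group label.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A named character vector (sample id -> group label) of class
#'   `sample_metadata`.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("metadata file needs two columns: ", path)
  sample_metadata(stats::setNames(df[[2L]], df[[1L]]))
}

#' @rdname read_metadata
#' @param groups Named character vector mapping sample id to group label.
#' @export
sample_metadata <- function(groups) {
  groups <- vapply(groups, as.character, "")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("metadata requires unique sample ids")
  if (any(!nzchar(groups))) stop("empty group label")
  structure(groups, class = "sample_metadata")
}

#' Write sample metadata as TSV
#' @param metadata A `sample_metadata`.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = names(metadata),
                   group = as.character(metadata), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Construct a nucleotide alignment
#'
#' Alignments are stored as character matrices (rows = sequences,
#' columns = positions) over the IUPAC nucleotide alphabet plus `-` and
#' `N`.  `U` is normalized to `T` on construction, and case is folded to
#' upper.
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix of single characters with row names.
#' @return A character matrix of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("alignment requires unique sequence ids")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("ragged alignment: sequence lengths ", paste(lens, collapse = ", "))
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  bad <- matrix(!(m %in% IUPAC_CHARS), nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid character '", m[idx[1L], idx[2L]], "' in sequence '",
         rownames(m)[idx[1L]], "' at position ", idx[2L])
  }
  class(m) <- c("dna_alignment", "matrix", "array")
  m
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("Alignment: ", nrow(x), " sequences x ", ncol(x), " positions\n",
      sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Strict reader: all records must have equal length and use only IUPAC
#' nucleotide characters (plus `-`); violations raise errors naming the
#' sequence and position.  `U` is normalized to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A [dna_alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  seqs <- gsub("[ \t]", "", seqs)
  if (length(seqs) != length(ids)) stop("FASTA record without sequence")
  names(seqs) <- ids
  dna_alignment(seqs)
}

#' Write an alignment as FASTA
#' @param alignment A [dna_alignment].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(alignment, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    s <- paste(alignment[i, ], collapse = "")
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", rownames(alignment)[i]), chunks), con)
  }
  invisible(NULL)
}
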