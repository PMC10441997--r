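#' Construct and validate an ASV count table
#'
#' The count table is the substrate of every downstream stage: a non-negative
#' integer matrix with taxa as rows and samples as columns, both uniquely
#' named. All `microstab` functions accept and return plain matrices in this
#' orientation.
#'
#' @param counts Numeric matrix of non-negative integers (taxa x samples).
#' @param taxon_ids Optional row names; defaults to existing `rownames(counts)`.
#' @param sample_ids Optional column names; defaults to `colnames(counts)`.
#' @return The validated integer matrix with dimnames set.
#' @examples
#' asv_table(matrix(0:5, 2, 3, dimnames = list(c("t1", "t2"), c("s1", "s2", "s3"))))
#' @export
asv_table <- function(counts, taxon_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids))
    stopf("ASV table needs taxon and sample identifiers")
  rownames(counts) <- as.character(taxon_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_asv_table(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Validate ASV table invariants
#'
#' Checks unique identifiers and non-negative integral counts; stops with the
#' offending identifier or cell coordinates otherwise.
#'
#' @param counts Matrix to check.
#' @return Invisibly, `counts`.
#' @export
validate_asv_table <- function(counts) {
  if (!is.matrix(counts)) stopf("ASV table must be a matrix")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup)) stopf("duplicate taxon identifier(s): %s", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup)) stopf("duplicate sample identifier(s): %s", paste(dup, collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-integer or negative count at taxon '%s', sample '%s' (value %s)",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
          counts[bad[1, 1], bad[1, 2]])
  }
  invisible(counts)
}

#' Read an ASV count table from TSV
#'
#' @param path Tab-separated file; first column (or row, for
#'   `orientation = "samples_rows"`) holds identifiers.
#' @param orientation `"taxa_rows"` (default) if rows are taxa, else
#'   `"samples_rows"`; output is always taxa x samples.
#' @return Validated integer matrix (taxa x samples).
#' @export
read_asv_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  ids <- as.character(raw[[1]])
  hdr <- colnames(raw)[-1]
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup)) stopf("duplicate identifier(s) in header: %s", paste(dup, collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate identifier(s) in first column: %s", paste(dup, collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  asv_table(m)
}

#' Write an ASV count table as TSV
#'
#' @param counts Validated ASV table.
#' @param path Output file.
#' @param orientation Written layout; the reader's flag mirrors it.
#' @param id_column Header of the identifier column.
#' @export
write_asv_table <- function(counts, path, orientation = c("taxa_rows", "samples_rows"),
                            id_column = "taxon_id") {
  orientation <- match.arg(orientation)
  validate_asv_table(counts)
  m <- if (orientation == "samples_rows") t(counts) else counts
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata (sample_id, group)
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @param counts Optional ASV table; if given, every sample must have exactly
#'   one group row.
#' @return data.frame with character `sample_id` and factor `group`.
#' @export
read_sample_metadata <- function(path, counts = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stopf("metadata must have columns 'sample_id' and 'group'")
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stopf("duplicate sample_id in metadata: %s", paste(dup, collapse = ", "))
  df$group <- factor(df$group)
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), df$sample_id)
    if (length(missing))
      stopf("samples without metadata: %s", paste(missing, collapse = ", "))
  }
  df
}

#' Rarefy an ASV table to even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads;
#' samples with fewer total reads are dropped with a message. Taxon rows are
#' retained even when their rarefied count is zero everywhere.
#'
#' @param counts ASV table.
#' @param depth Target reads per sample (the documented default for the mouse
#'   diet dataset this pipeline was built around is 16866; synthetic runs set
#'   their own).
#' @param seed Integer seed; subsampling is deterministic given it.
#' @return Rarefied ASV table (possibly with fewer samples).
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  validate_asv_table(counts)
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stopf("depth must be a positive integer")
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stopf("all samples have fewer than %d reads", depth)
  if (any(!keep))
    msgf("rarefy: dropping %d sample(s) below depth %d: %s",
         sum(!keep), depth, paste(colnames(counts)[!keep], collapse = ", "))
  kept <- counts[, keep, drop = FALSE]
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(kept), sample = depth))))
  out <- matrix(as.integer(out), nrow(kept), ncol(kept), dimnames = dimnames(kept))
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param counts ASV table with strictly positive sample totals.
#' @return Numeric matrix, each sample column summing to 1.
#' @export
to_relative_abundance <- function(counts) {
  validate_asv_table(counts)
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero)) stopf("zero-total sample(s): %s", paste(zero, collapse = ", "))
  sweep(counts, 2, totals, "/")
}

#' Read a rooted phylogenetic tree from Newick
#'
#' @param path Newick file with branch lengths.
#' @param taxon_ids Optional identifier namespace; leaves absent from it are
#'   an error when provided.
#' @return An [ape::read.tree()] `phylo` object, rooted, with branch lengths.
#' @export
read_tree <- function(path, taxon_ids = NULL) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) NULL)
  if (is.null(tr)) stopf("cannot parse Newick file '%s'", path)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stopf("tree in '%s' lacks branch lengths", path)
  if (!ape::is.rooted(tr)) stopf("tree in '%s' is not rooted", path)
  if (!is.null(taxon_ids)) {
    extra <- setdiff(tr$tip.label, taxon_ids)
    if (length(extra))
      stopf("tree leaves absent from the taxon table: %s", paste(extra, collapse = ", "))
  }
  tr
}
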