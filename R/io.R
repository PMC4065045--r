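## File-format readers and writers: counts TSV, GMT annotation sets, SIF and
## two-column edge lists, BED6+multiplicity alignments, exon-table TSV,
## plain-text seed lists, GraphML export.

#' Write a count matrix with gene lengths as TSV
#'
#' Layout: gene_id, length, then one column per sample; the header encodes
#' subset and condition as \code{<subset>_<condition>}.
#'
#' @param se a \code{SummarizedExperiment} with assay \code{counts} and
#'   \code{rowData(se)$length}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCountsTSV <- function(se, path) {
  counts <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(se),
                   length = SummarizedExperiment::rowData(se)$length,
                   counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV written by [writeCountsTSV()]
#'
#' @param path input file.
#' @return a \code{SummarizedExperiment} with assay \code{counts},
#'   \code{rowData} column \code{length}, and \code{colData} columns
#'   \code{subset}/\code{condition} parsed from the sample names.
#' @export
readCountsTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(colnames(df)[1:2] == c("gene_id", "length"))
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  parts <- strsplit(colnames(counts), "_", fixed = TRUE)
  cd <- S4Vectors::DataFrame(
    subset = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, function(p) paste(p[-1], collapse = "_"), ""))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = df$length, row.names = df$gene_id),
    colData = cd)
}

#' Read annotation sets in GMT format
#'
#' One term per line: term, description, then tab-separated member symbols.
#'
#' @param path GMT file.
#' @return named list of character vectors of members; the description is
#'   kept in the attribute \code{description}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[`, "", 2L)
  sets
}

#' Write annotation sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-term description (recycled).
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read an interaction table (SIF or two/three-column TSV)
#'
#' SIF lines look like \code{A pp B} (whitespace separated); TSV lines have
#' two symbol columns and optionally a provenance column.  Lines with fewer
#' than the required fields raise an error naming the line number.
#'
#' @param path input file.
#' @param format "sif" or "tsv"; guessed from the extension by default.
#' @return data.frame with columns from, to (and provenance if present).
#' @export
readInteractions <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (format == "sif") {
    fields <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
      stop("malformed SIF line ", lineno[bad[1]], ": need 'A <type> B'")
    data.frame(from = vapply(fields, `[`, "", 1L),
               to = vapply(fields, `[`, "", 3L),
               provenance = vapply(fields, `[`, "", 2L))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop("malformed edge line ", lineno[bad[1]], ": need two columns")
    out <- data.frame(from = vapply(fields, `[`, "", 1L),
                      to = vapply(fields, `[`, "", 2L))
    if (all(lengths(fields) >= 3L))
      out$provenance <- vapply(fields, `[`, "", 3L)
    out
  }
}

#' Write a network as SIF
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output file.
#' @param type interaction type string written between the endpoints.
#' @return invisibly, the path.
#' @export
writeSIF <- function(net, path, type = "pp") {
  el <- igraph::as_edgelist(displayGraph(net))
  writeLines(paste(el[, 1], type, el[, 2]), path)
  invisible(path)
}

#' Write a network as a two-column TSV edge list
#' @inheritParams writeSIF
#' @export
writeEdgeTSV <- function(net, path) {
  el <- igraph::as_edgelist(displayGraph(net))
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a network (or a subnetwork of it) as GraphML
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output file.
#' @param nodes optional node subset to export (induced subgraph).
#' @return invisibly, the path.
#' @export
writeGraphML <- function(net, path, nodes = NULL) {
  g <- displayGraph(net)
  if (!is.null(nodes)) {
    keep <- igraph::V(g)$name %in% matchSymbols(net, nodes)
    g <- igraph::induced_subgraph(g, which(keep))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read alignment intervals from BED6 plus a multiplicity column
#'
#' Columns: chrom, start (0-based), end, name, score, strand, multiplicity.
#' Coordinates are converted to the internal 1-based closed convention.
#'
#' @param path BED-like file.
#' @return a \code{GRanges} with metadata columns read_id and multiplicity.
#' @export
readAlignmentsBED <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "multiplicity"))
  if (any(df$end <= df$start))
    stop("alignment record with end <= start at line ",
         which(df$end <= df$start)[1])
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end), strand = df$strand)
  gr$read_id <- df$name
  gr$multiplicity <- as.integer(df$multiplicity)
  gr
}

#' Write alignment intervals as BED6 plus multiplicity
#' @param aln a \code{GRanges} with read_id and multiplicity columns.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAlignmentsBED <- function(aln, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(aln)),
    start = GenomicRanges::start(aln) - 1L,
    end = GenomicRanges::end(aln),
    name = aln$read_id, score = 0L,
    strand = as.character(GenomicRanges::strand(aln)),
    multiplicity = aln$multiplicity)
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text seed list (one symbol per line)
#'
#' Blank lines and lines starting with \code{#} are skipped; duplicates
#' (case-insensitive) are removed keeping the first spelling.
#'
#' @param path text file.
#' @return character vector of unique symbols.
#' @export
readSeedList <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("seed list is empty: ", path)
  x[!duplicated(toupper(x))]
}

#' Read an exon table TSV
#'
#' Columns gene_id, transcript_id, chrom, start, end, strand, biotype with
#' 0-based half-open coordinates (converted internally).
#'
#' @param path TSV file.
#' @return data.frame of exon records (internal 1-based closed start/end).
#' @export
readExonTable <- function(path) {
  df <- utils::read.delim(path)
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand",
            "biotype")
  if (!all(need %in% colnames(df)))
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start))
    stop("exon record with end <= start for gene ",
         df$gene_id[which(df$end <= df$start)[1]])
  df$start <- df$start + 1L
  df
}

#' Write an exon table TSV (0-based half-open on disk)
#' @param exons data.frame in the internal 1-based closed convention.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeExonTable <- function(exons, path) {
  out <- exons
  out$start <- out$start - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exons from a GTF file
#'
#' Keeps \code{exon} features and the attribute keys gene_id, transcript_id
#' and gene_biotype, converting to the internal exon-table layout.
#'
#' @param path GTF file.
#' @return data.frame like [readExonTable()] returns.
#' @export
readExonGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype
             else if (!is.null(gr$gene_type)) gr$gene_type
             else rep(NA_character_, length(gr))
  data.frame(gene_id = gr$gene_id, transcript_id = gr$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             biotype = biotype)
}
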