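#' Read a gene-level count table
#'
#' Expects a TSV with header `gene_id`, `species`, then one column per
#' library named `<protein|input>_<timepoint>[_rep<k>]`. Validation is
#' strict: duplicate gene ids are an error naming the id and the lines
#' involved, species tags outside target/spikein and negative or
#' non-numeric counts are errors with line numbers. Lengths are supplied
#' separately ([readGeneLengths()]) or attached later.
#'
#' @param path TSV file.
#' @param lengths optional named vector of gene lengths (nt) to attach;
#'   genes without a length get NA (allowed until FPKM computation).
#' @return a [RIPCountSet].
#' @export
readCountTable <- function(path, lengths = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("gene_id", "species")))
    stop("count table must start with columns 'gene_id' and 'species'", call. = FALSE)
  dup <- duplicated(df$gene_id) | duplicated(df$gene_id, fromLast = TRUE)
  if (any(dup)) {
    id <- df$gene_id[duplicated(df$gene_id)][1L]
    lines <- which(df$gene_id == id) + 1L  # +1 for the header line
    stop(sprintf("duplicate gene id '%s' on lines %s", id,
                 paste(lines, collapse = " and ")), call. = FALSE)
  }
  badSp <- !df$species %in% .SPECIES_LEVELS
  if (any(badSp))
    stop(sprintf("unknown species tag '%s' on line %d",
                 df$species[badSp][1L], which(badSp)[1L] + 1L), call. = FALSE)
  cnt <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(cnt)) {
    badCol <- which(!vapply(df[, -(1:2), drop = FALSE], is.numeric, logical(1)))[1L]
    stop("non-numeric counts in column '", colnames(cnt)[badCol], "'", call. = FALSE)
  }
  neg <- which(rowSums(cnt < 0) > 0)
  if (length(neg))
    stop("negative counts on line(s) ", paste(neg + 1L, collapse = ", "),
         call. = FALSE)
  rownames(cnt) <- df$gene_id
  len <- rep(NA_real_, nrow(cnt))
  if (!is.null(lengths)) len <- unname(lengths[df$gene_id])
  RIPCountSet(counts = cnt, species = df$species, lengthNt = len)
}

#' Write a count table TSV
#'
#' Columns `gene_id`, `species`, then one column per library;
#' deterministic lexicographic row order. Round-trips through
#' [readCountTable()].
#'
#' @param x a [RIPCountSet].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCountTable <- function(x, path) {
  ord <- order(rownames(x))
  df <- data.frame(gene_id = rownames(x)[ord],
                   species = rowData(x)$species[ord],
                   assay(x, "counts")[ord, , drop = FALSE],
                   check.names = FALSE)
  .writeTSV(df, path)
}

#' Read gene lengths
#'
#' TSV with columns `gene_id` and `length_nt` (nucleotides).
#'
#' @param path TSV file.
#' @return named numeric vector of lengths.
#' @export
readGeneLengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_nt") %in% colnames(df)))
    stop("length table needs columns 'gene_id' and 'length_nt'", call. = FALSE)
  if (any(df$length_nt <= 0) || anyDuplicated(df$gene_id))
    stop("lengths must be positive and gene ids unique", call. = FALSE)
  stats::setNames(df$length_nt, df$gene_id)
}

#' Gene lengths from a GFF3/GTF annotation
#'
#' Optional helper: the length of a gene is the width of the union of
#' its exon intervals (1-based inclusive coordinates as in GTF/GFF).
#' Requires the rtracklayer and GenomicRanges packages.
#'
#' @param path GFF3 or GTF file.
#' @param geneField attribute naming the gene (default `"gene_id"`).
#' @return named numeric vector of lengths.
#' @export
lengthsFromGFF <- function(path, geneField = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("lengthsFromGFF requires the rtracklayer and GenomicRanges packages",
         call. = FALSE)
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  gene <- S4Vectors::mcols(gr)[[geneField]]
  if (is.null(gene)) stop("no '", geneField, "' attribute in the annotation",
                          call. = FALSE)
  byGene <- GenomicRanges::split(gr, gene)
  vapply(GenomicRanges::width(GenomicRanges::reduce(byGene)), sum, numeric(1))
}

#' Read a per-gene covariate table
#'
#' TSV with columns `gene_id`, `tail_length` (mean poly(A)-tail length
#' in nt, > 0) and `te` (translational efficiency, log2). An optional
#' `time_point` column allows per-time-point covariates.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readCovariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tail_length", "te")
  if (!all(need %in% colnames(df)))
    stop("covariate table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$tail_length <= 0, na.rm = TRUE))
    stop("tail lengths must be positive", call. = FALSE)
  key <- if ("time_point" %in% colnames(df))
    paste(df$gene_id, df$time_point) else df$gene_id
  if (anyDuplicated(key))
    stop("one row per (gene, time point) required", call. = FALSE)
  df
}

#' Read a gene-set file
#'
#' One gene id per line; `#` starts a comment; blank lines are ignored;
#' duplicates are collapsed. An empty result is a warning, not an error.
#'
#' @param path text file.
#' @return character vector (a set: unique, order not meaningful).
#' @export
readGeneSet <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  out <- unique(lines[nzchar(lines)])
  if (!length(out)) warning("empty gene set: ", path, call. = FALSE)
  out
}

#' Write a gene-set file
#'
#' @param genes character vector of ids.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(sort(unique(genes)), path)
  invisible(path)
}

#' Write an expression (FPKM) matrix TSV
#'
#' Columns `gene_id`, `species`, then libraries; values at 6 significant
#' digits, lexicographic row order. The spike-in normalization state is
#' recorded in a `# normalized:` header comment and restored by
#' [readExpressionMatrix()].
#'
#' @param x an [FPKMSet].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  ord <- order(rownames(x))
  df <- data.frame(gene_id = rownames(x)[ord],
                   species = rowData(x)$species[ord],
                   assay(x, "fpkm")[ord, , drop = FALSE],
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# normalized: ", tolower(isNormalized(x))), con)
  utils::write.table(.signifCols(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  normalized <- grepl("normalized:\\s*true", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  f <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(f) <- df$gene_id
  cd <- .parseLibraryName(colnames(f))
  cd$time_point <- factor(cd$time_point, levels = unique(cd$time_point))
  se <- SummarizedExperiment(
    assays = list(fpkm = f),
    rowData = DataFrame(species = df$species,
                        length_nt = rep(NA_real_, nrow(f))),
    colData = DataFrame(cd))
  metadata(se)$normalized <- normalized
  new("FPKMSet", se)
}

#' Write / read a binding table TSV
#'
#' Columns `gene_id` then one `<protein>_<timepoint>` column per
#' (protein, time point); 6 significant digits, lexicographic rows.
#'
#' @param x a [BindingSet].
#' @param path file.
#' @return `writeBindingTable` the path invisibly; `readBindingTable` a
#'   [BindingSet].
#' @export
writeBindingTable <- function(x, path) {
  ord <- order(rownames(x))
  df <- data.frame(gene_id = rownames(x)[ord],
                   assay(x, "log2binding")[ord, , drop = FALSE],
                   check.names = FALSE)
  .writeTSV(.signifCols(df), path)
}

#' @rdname writeBindingTable
#' @export
readBindingTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  b <- as.matrix(df[, -1L, drop = FALSE])
  rownames(b) <- df$gene_id
  cd <- .parseLibraryName(colnames(b))
  se <- SummarizedExperiment(
    assays = list(log2binding = b),
    colData = DataFrame(protein = cd$protein,
                        time_point = factor(cd$time_point,
                                            levels = unique(cd$time_point)),
                        row.names = colnames(b)))
  new("BindingSet", se)
}

#' Write the planted truth of a synthetic run
#'
#' @param truth a [SyntheticTruth].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  aff <- truth@logAffinity
  colnames(aff) <- paste0("log_affinity_", tolower(colnames(aff)))
  rate <- truth@decayRate
  colnames(rate) <- paste0("decay_rate_interval", seq_len(ncol(rate)))
  df <- data.frame(gene_id = truth@geneId, spikein = truth@spikein,
                   length_nt = truth@lengthNt, aff,
                   tail_length = truth@tailLength, te = truth@te,
                   initial_abundance = truth@initialAbundance, rate,
                   check.names = FALSE)
  df <- df[order(df$gene_id), ]
  .writeTSV(.signifCols(df), path)
}
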