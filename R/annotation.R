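#' Load a gene annotation as a gene table
#'
#' Reads gene records from GFF3/GTF (via rtracklayer), BED (0-based
#' half-open, converted on load; requires an extra `biotype` column), or a
#' plain TSV with columns `gene_id, chromosome, start, end, strand, biotype`.
#' Only protein-coding genes are kept. The strand-aware transcription start
#' site (TSS) is the 5' end of the gene: `start` on `+`, `end` on `-`.
#' When a gene_id appears more than once the longest span is kept (the
#' number of collapsed entries is reported). Records are returned grouped by
#' chromosome and sorted by `(tss, gene_id)` within chromosome, so downstream
#' pairing is deterministic under TSS ties.
#'
#' @param path path to the annotation file.
#' @param format one of `"gff3"`, `"gtf"`, `"bed"`, `"tsv"`.
#' @param biotype_keep biotypes retained; default `"protein_coding"`.
#' @return a `data.frame` with columns `gene_id`, `chromosome`, `strand`,
#'   `start`, `end`, `tss`, `biotype`, sorted by chromosome then TSS.
#' @export
load_gene_annotation <- function(path, format = c("gff3", "gtf", "bed", "tsv"),
                                 biotype_keep = "protein_coding") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- switch(format,
    gff3 = ,
    gtf = .genes_from_gxf(path, format),
    bed = .genes_from_bed(path),
    tsv = .genes_from_tsv(path)
  )
  if (anyNA(tab$strand) || any(!tab$strand %in% c("+", "-"))) {
    stop("annotation has records without a usable strand (+/-)")
  }
  tab <- tab[tab$biotype %in% biotype_keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("no genes with biotype in {", paste(biotype_keep, collapse = ", "),
         "} found in ", path)
  }
  as_gene_table(tab)
}

.genes_from_gxf <- function(path, format) {
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e))
  )
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) gr <- gr[as.character(mc$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("gene_biotype", "biotype", "gene_type"), names(mc))[1]
  id_col <- intersect(c("gene_id", "ID", "Name"), names(mc))[1]
  if (is.na(id_col)) stop("no gene identifier attribute (gene_id/ID) in ", path)
  biotype <- if (is.na(bt_col)) rep(NA_character_, length(gr)) else
    as.character(mc[[bt_col]])
  data.frame(
    gene_id = sub("^gene:", "", as.character(mc[[id_col]])),
    chromosome = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
}

.genes_from_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed",
                        extraCols = c(biotype = "character")),
    error = function(e) stop("failed to parse ", path, " as bed: ",
                             conditionMessage(e))
  )
  # rtracklayer converts BED 0-based half-open to 1-based inclusive
  data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$name),
    chromosome = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    biotype = as.character(S4Vectors::mcols(gr)$biotype),
    stringsAsFactors = FALSE
  )
}

.genes_from_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("gene TSV ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  tab[, need]
}

#' Assemble a validated gene table from a data.frame
#'
#' Computes the strand-aware TSS, collapses duplicated gene ids to the
#' longest span, and sorts by chromosome then `(tss, gene_id)`.
#'
#' @param df data.frame with `gene_id, chromosome, start, end, strand` and
#'   optionally `biotype`.
#' @return sorted gene table data.frame.
#' @export
as_gene_table <- function(df) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end", "strand") %in% names(df)))
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  if (any(df$start > df$end)) stop("gene records with start > end")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  dt <- data.table::as.data.table(df)
  if (anyDuplicated(dt$gene_id)) {
    n0 <- nrow(dt)
    dt[, span := end - start + 1L]
    data.table::setorder(dt, gene_id, -span)
    dt <- dt[!duplicated(gene_id)]
    dt[, span := NULL]
    message(sprintf("collapsed %d duplicated annotation entries (longest span kept)",
                    n0 - nrow(dt)))
  }
  dt[, tss := data.table::fifelse(strand == "+", as.numeric(start), as.numeric(end))]
  data.table::setorder(dt, chromosome, tss, gene_id)
  out <- as.data.frame(dt[, .(gene_id, chromosome, strand, start, end, tss, biotype)])
  rownames(out) <- NULL
  out
}

#' Write a gene table to TSV or GFF3
#'
#' @param genes gene table from [load_gene_annotation()] or [simulate_genome()].
#' @param path output path.
#' @param format `"tsv"` or `"gff3"`.
#' @export
write_gene_table <- function(genes, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(
      genes[, c("gene_id", "chromosome", "start", "end", "strand", "biotype")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chromosome,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- genes$gene_id
    S4Vectors::mcols(gr)$gene_id <- genes$gene_id
    S4Vectors::mcols(gr)$biotype <- genes$biotype
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}
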