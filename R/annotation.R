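## Annotation and interval file I/O.  All dialect handling (GFF3 1-based
## closed, BED 0-based half-open) is localized here; everything downstream
## works on GRanges.

#' Read a gene annotation into a GenomeLayout
#'
#' Reads a gene annotation in GFF3 or BED (3/6/12 column) dialect and returns
#' a [GenomeLayout-class].  GFF3 coordinates are 1-based closed, BED 0-based
#' half-open; both are converted to the internal convention.  Records sharing
#' a `gene_id` are collapsed to a single interval spanning their union.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the file extension when
#'   missing.
#' @param chromSizes optional path to a two-column `chrom.sizes` TSV or a
#'   named numeric vector; when absent, chromosome lengths are inferred as
#'   the maximum gene end per chromosome.
#' @param feature for GFF3, the feature type to keep (default `"gene"`; if no
#'   record has that type all records are used).
#' @return A [GenomeLayout-class].
#' @export
readAnnotation <- function(path, format = c("gff3", "bed"),
                           chromSizes = NULL, feature = "gene") {
    if (missing(format)) {
        format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
            "gff3" else "bed"
    }
    format <- match.arg(format)
    gr <- tryCatch(
        rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
        error = function(e) stop("failed to parse ", path, " as ", format,
                                 ": ", conditionMessage(e)))
    if (format == "gff3") {
        if (!is.null(gr$type) && any(gr$type == feature))
            gr <- gr[gr$type == feature]
        id <- if (!is.null(gr$ID)) as.character(gr$ID)
              else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
              else if (!is.null(gr$Name)) as.character(gr$Name)
              else paste0("gene", seq_along(gr))
    } else {
        id <- if (!is.null(gr$name)) as.character(gr$name)
              else paste0("gene", seq_along(gr))
    }
    bad <- !(as.character(strand(gr)) %in% c("+", "-"))
    if (any(bad))
        stop("rejected record(s) with unknown strand: line(s) ",
             paste(head(which(bad), 5), collapse = ", "))
    ## collapse isoforms / duplicate ids to one interval per gene_id
    sp <- split(gr, id)
    rng <- unlist(range(sp, ignore.strand = TRUE))
    strand(rng) <- vapply(sp, function(x) as.character(strand(x))[1],
                          character(1))
    genes <- GRanges(seqnames(rng), ranges(rng), strand = strand(rng),
                     gene_id = names(rng))
    names(genes) <- NULL
    if (is.character(chromSizes)) chromSizes <- readChromSizes(chromSizes)
    GenomeLayout(genes, chromSizes)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with columns chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "size"),
                      colClasses = c("character", "numeric"))
    structure(tab$size, names = tab$chrom)
}

#' Write a chrom.sizes file
#' @param chromSizes named numeric vector.
#' @param path output path.
#' @export
writeChromSizes <- function(chromSizes, path) {
    write.table(data.frame(names(chromSizes), as.integer(chromSizes)),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
}

#' Write a GenomeLayout's genes as GFF3
#'
#' @param layout A [GenomeLayout-class].
#' @param path output path.
#' @export
writeAnnotationGff3 <- function(layout, path) {
    g <- layoutGenes(layout)
    mcols(g) <- S4Vectors::DataFrame(source = "txinit", type = "gene",
                                     ID = g$gene_id)
    rtracklayer::export(g, path, format = "gff3")
    invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED3/BED6 file (0-based half-open).
#' @param provenance free-text label stored in `metadata()$provenance`.
#' @param chromSizes optional named lengths used to bound-check the regions.
#' @return Sorted `GRanges`; names come from the BED name column if present.
#' @export
readRegionsBed <- function(path, provenance = path, chromSizes = NULL) {
    gr <- rtracklayer::import(path, format = "bed")
    if (!is.null(gr$name)) names(gr) <- gr$name
    gr <- sort(gr, ignore.strand = TRUE)
    if (!is.null(chromSizes)) {
        lens <- chromSizes[as.character(seqnames(gr))]
        if (anyNA(lens) || any(end(gr) > lens) || any(start(gr) < 1L))
            stop("region(s) outside chromosome bounds in ", path)
    }
    S4Vectors::metadata(gr)$provenance <- provenance
    gr
}

#' Write regions as BED6
#'
#' Writes a `GRanges` as BED6 (0-based half-open).  For IAR sets produced by
#' [extractIars()], `name` is the nearest gene, `score` the distance to it and
#' `strand` the nearest gene's strand; for plain region sets the region names
#' (or `region<i>`) are used with score 0.
#'
#' @param gr `GRanges`, optionally with `nearest_gene_id`,
#'   `distance_to_gene`, `nearest_gene_strand` metadata columns.
#' @param path output path.
#' @export
writeRegionsBed <- function(gr, path) {
    nm <- if (!is.null(gr$nearest_gene_id)) gr$nearest_gene_id
          else if (!is.null(names(gr)) && length(gr)) names(gr)
          else if (length(gr)) paste0("region", seq_along(gr))
          else character(0)
    score <- if (!is.null(gr$distance_to_gene)) gr$distance_to_gene
             else rep(0L, length(gr))
    strd <- if (!is.null(gr$nearest_gene_strand)) gr$nearest_gene_strand
            else as.character(strand(gr))
    strd[strd == "*"] <- "."
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      name = nm, score = score, strand = strd)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
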