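#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bases.
#'
#' @param path Path to the file.
#' @return A `Seqinfo` genome.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  make_genome(tab$chrom, tab$length)
}

#' Write a chrom.sizes file
#' @param genome A `Seqinfo` genome.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(sprintf("%s\t%d", GenomeInfoDb::seqnames(genome),
                     GenomeInfoDb::seqlengths(genome)), path)
  invisible(path)
}

#' Read a BED file of genomic regions
#'
#' Accepts BED3-BED6 (tab-delimited, 0-based half-open); `track`, `browser`
#' and `#` comment lines are skipped. Records on chromosomes absent from the
#' genome are dropped with a warning tally by default, or rejected.
#'
#' @param path Path to the BED file.
#' @param genome A `Seqinfo` genome.
#' @param on_unknown_chrom `"skip"` (default: drop with a warning) or
#'   `"error"`.
#' @return A `GRanges`; the number of skipped records is attached as
#'   attribute `"n_skipped"`.
#' @export
read_bed <- function(path, genome, on_unknown_chrom = c("skip", "error")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  gr <- rtracklayer::import(path, format = "bed")
  n_skipped <- 0L
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  known <- chroms %in% GenomeInfoDb::seqnames(genome)
  if (!all(known)) {
    if (on_unknown_chrom == "error") {
      check_chroms(chroms, genome, what = sprintf("BED record in '%s'", path))
    }
    n_skipped <- sum(!known)
    warning(sprintf("%d BED record(s) on chromosomes absent from the genome skipped",
                    n_skipped), call. = FALSE)
    gr <- gr[known]
  }
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomeInfoDb::seqnames(gr)),
    ranges = IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr),
    seqinfo = genome
  )
  if (!is.null(gr$name)) out$name <- gr$name
  validate_regions(out, genome, what = sprintf("BED record in '%s'", path))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write regions as sorted BED
#'
#' Emits BED4 (chrom, start, end, name) in 0-based half-open coordinates,
#' sorted by chromosome then start. Unnamed regions get `"."`.
#'
#' @param regions A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  regions <- sort(regions, ignore.strand = TRUE)
  nm <- if (is.null(regions$name)) rep(".", length(regions)) else regions$name
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomeInfoDb::seqnames(regions)),
                   GenomicRanges::start(regions) - 1L,
                   GenomicRanges::end(regions),
                   nm)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited lines: set name, description, member genes. Duplicate
#' members within a set are deduplicated and empty sets dropped, each with a
#' warning; totals are attached as attributes for machine-readable logs.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene ids, with a parallel
#'   `"descriptions"` attribute, plus `"n_dup_members"` and
#'   `"n_empty_sets"` tallies.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short)) {
    stop(sprintf("GMT parse error: line %d of '%s' has fewer than 3 fields",
                 short[1L], path))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated gene-set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1)))
  if (n_dup > 0L) {
    warning(sprintf("%d duplicated member(s) within gene sets deduplicated", n_dup),
            call. = FALSE)
    members <- lapply(members, unique)
  }
  empty <- vapply(members, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("%d empty gene set(s) dropped", sum(empty)), call. = FALSE)
    members <- members[!empty]; ids <- ids[!empty]; desc <- desc[!empty]
  }
  names(members) <- ids
  attr(members, "descriptions") <- stats::setNames(desc, ids)
  attr(members, "n_dup_members") <- n_dup
  attr(members, "n_empty_sets") <- sum(empty)
  members
}

#' Write a GMT gene-set collection
#' @param gene_sets Named list of character vectors; an optional
#'   `"descriptions"` attribute supplies the second column.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  desc <- attr(gene_sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(gene_sets)),
                                             names(gene_sets))
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, desc[[id]], gene_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-delimited gene table
#'
#' Canonical annotation fixture format: columns `gene_id`, `chrom`,
#' `strand`, `tss` (0-based TSS offset), with a header line.
#'
#' @param path Path to the table.
#' @param genome A `Seqinfo` genome.
#' @param on_unknown_chrom `"skip"` or `"error"`.
#' @return A data.frame with columns gene_id, chrom, strand, tss and an
#'   `"n_skipped"` attribute.
#' @export
read_gene_table <- function(path, genome, on_unknown_chrom = c("skip", "error")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[need]
  n_skipped <- 0L
  known <- tab$chrom %in% GenomeInfoDb::seqnames(genome)
  if (!all(known)) {
    if (on_unknown_chrom == "error") {
      check_chroms(tab$chrom, genome, what = sprintf("gene in '%s'", path))
    }
    n_skipped <- sum(!known)
    warning(sprintf("%d gene(s) on chromosomes absent from the genome skipped",
                    n_skipped), call. = FALSE)
    tab <- tab[known, , drop = FALSE]
  }
  check_genes(tab, genome)
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Write a gene table
#' @param genes Gene annotation data.frame (gene_id, chrom, strand, tss).
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared gene-annotation validation.
check_genes <- function(genes, genome) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  lens <- GenomeInfoDb::seqlengths(genome)[genes$chrom]
  bad <- which(genes$tss < 0 | genes$tss >= lens)
  if (length(bad)) {
    stop(sprintf("TSS of gene '%s' (%s:%.0f) outside chromosome bounds",
                 genes$gene_id[bad[1L]], genes$chrom[bad[1L]], genes$tss[bad[1L]]))
  }
  invisible(TRUE)
}

#' Read gene TSSs from a minimal GTF
#'
#' Parses records of the requested feature type (default `"gene"`) and
#' reduces them to one TSS per gene: the annotated 5' end, and when a gene
#' carries several records the 5'-most position on its strand. GTF 1-based
#' closed coordinates are converted to 0-based TSS offsets.
#'
#' @param path Path to the GTF file.
#' @param genome A `Seqinfo` genome.
#' @param feature GTF feature type to use (`"gene"` or e.g. `"transcript"`).
#' @param on_unknown_chrom `"skip"` or `"error"`.
#' @return A gene annotation data.frame (gene_id, chrom, strand, tss).
#' @export
read_gtf_genes <- function(path, genome, feature = "gene",
                           on_unknown_chrom = c("skip", "error")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  gr <- rtracklayer::import(path, format = "gtf", feature.type = feature)
  if (length(gr) == 0L) stop("no '", feature, "' records in GTF: ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("GTF records lack a gene_id attribute")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("GTF gene records must be stranded")
  tss0 <- ifelse(strand == "+",
                 GenomicRanges::start(gr) - 1L,   # 5' end, 0-based
                 GenomicRanges::end(gr) - 1L)
  tab <- data.frame(gene_id = gr$gene_id,
                    chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    strand = strand,
                    tss = as.numeric(tss0),
                    stringsAsFactors = FALSE)
  # 5'-most TSS per gene: minimum offset on +, maximum on -
  tab <- do.call(rbind, lapply(split(tab, tab$gene_id), function(g) {
    pick <- if (g$strand[1L] == "+") which.min(g$tss) else which.max(g$tss)
    g[pick, , drop = FALSE]
  }))
  rownames(tab) <- NULL
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  n_skipped <- 0L
  known <- tab$chrom %in% GenomeInfoDb::seqnames(genome)
  if (!all(known)) {
    if (on_unknown_chrom == "error") {
      check_chroms(tab$chrom, genome, what = sprintf("gene in '%s'", path))
    }
    n_skipped <- sum(!known)
    warning(sprintf("%d gene(s) on chromosomes absent from the genome skipped",
                    n_skipped), call. = FALSE)
    tab <- tab[known, , drop = FALSE]
  }
  check_genes(tab, genome)
  attr(tab, "n_skipped") <- n_skipped
  tab
}
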