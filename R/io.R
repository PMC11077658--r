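#' Read a VCF into a genotype matrix
#'
#' Ingests bi-allelic SNP rows (single-base REF and ALT); multi-allelic
#' and indel rows are skipped with a logged count.  `./.` (or `.|.`) is
#' missing; phased and unphased separators are both accepted.  RAD-locus
#' ids are taken from the CHROM column.
#'
#' @param path VCF 4.x file with GT fields.
#' @param popmap named character vector (id -> population), e.g. from
#'   [read_popmap()]; individuals absent from the map get population
#'   `"unknown"`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0) stop("empty VCF body: no variant records in ", path)
  if (!"GT" %in% unlist(strsplit(v@gt[, "FORMAT"], ":"))) {
    stop("VCF has no GT field")
  }
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!ok)
  if (skipped > 0) {
    message("skipped ", skipped, " non-bi-allelic-SNP record(s)")
  }
  if (!any(ok)) stop("no bi-allelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  code <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(al) {
      if (any(al == ".") || length(al) != 2) NA_integer_
      else sum(as.integer(al))
    }, 0L)
  }
  calls <- vapply(seq_len(nrow(gt)), function(r) code(gt[r, ]),
                  integer(ncol(gt)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = ncol(gt))
  rownames(calls) <- colnames(gt)
  locus_ids <- fix[ok, "CHROM"]
  ids <- rownames(calls)
  pops <- if (is.null(popmap)) setNames(rep("unknown", length(ids)), ids)
  else setNames(popmap[ids], ids)
  if (any(is.na(pops))) {
    stop("individuals missing from the population map: ",
         paste(ids[is.na(pops)], collapse = ", "))
  }
  genotype_matrix(calls, locus_ids, pops)
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' GT-only body; missing calls written as `./.`; CHROM carries the
#' RAD-locus id and POS numbers SNPs within each locus.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tealdemog",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(G$calls)),
                     collapse = "\t")), con)
  pos <- stats::ave(seq_along(G$locus_ids), G$locus_ids,
                    FUN = seq_along)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (s in seq_along(G$locus_ids)) {
    g <- G$calls[, s]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(G$locus_ids[s], pos[s],
                       paste0(G$locus_ids[s], "_", pos[s]), "A", "T", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write population maps
#'
#' Tab-separated, two columns (id, population) with an optional third
#' group column for AMOVA-style hierarchies.
#'
#' @param path file path.
#' @return `read_popmap()`: named character vector id -> population, with
#'   a `groups` attribute (population -> group) when a third column is
#'   present.
#' @export
read_popmap <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("popmap needs at least two columns (id, pop)")
  if (anyDuplicated(tab[[1]])) stop("duplicate ids in popmap")
  out <- setNames(as.character(tab[[2]]), tab[[1]])
  if (ncol(tab) >= 3) {
    g <- unique(tab[, 2:3])
    if (anyDuplicated(g[[1]])) {
      stop("a population maps to more than one group")
    }
    attr(out, "groups") <- setNames(as.character(g[[2]]), g[[1]])
  }
  out
}

#' @rdname read_popmap
#' @param pops named character vector (id -> population).
#' @param groups optional named vector (population -> group).
#' @export
write_popmap <- function(pops, path, groups = NULL) {
  tab <- data.frame(id = names(pops), pop = unname(pops))
  if (!is.null(groups)) tab$group <- unname(groups[tab$pop])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Ids are parsed from headers up to the first whitespace; sequences are
#' upper-cased.  Ragged (unequal-length) records and duplicate ids are
#' errors.
#'
#' @param path FASTA file.
#' @param popmap optional named vector (id -> population).
#' @return a [sequence_alignment()] (population `"unknown"` when no map is
#'   given).
#' @export
read_fasta <- function(path, popmap = NULL) {
  dna <- ape::read.FASTA(path)
  ids <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- lengths(dna)
  if (length(unique(lens)) != 1) {
    stop("unequal sequence lengths; offending record: ",
         ids[which(lens != lens[1])[1]])
  }
  seqs <- vapply(as.character(dna), function(x)
    toupper(paste(x, collapse = "")), "")
  pops <- if (is.null(popmap)) rep("unknown", length(ids))
  else unname(popmap[ids])
  if (any(is.na(pops))) {
    stop("sequences missing from the population map: ",
         paste(ids[is.na(pops)], collapse = ", "))
  }
  sequence_alignment(seqs, ids, pops)
}

#' Write a sequence alignment as FASTA
#'
#' @param aln a [sequence_alignment()].
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "sequence_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$sequences)) {
    writeLines(c(paste0(">", aln$ids[i]), aln$sequences[i]), con)
  }
  invisible(path)
}
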