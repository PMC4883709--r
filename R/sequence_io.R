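#' Promoter sets: TSS-anchored sequence windows
#'
#' A `promoter_set` holds one uppercase DNA sequence per gene, all cut with the
#' same coordinate window relative to the transcription start site (TSS = 0,
#' upstream negative, half-open interval `[start, end)`). Sequences may be
#' shorter than the window when the source chromosome ended inside it; the
#' actual offset of the first base of each sequence is kept in `start_offsets`.
#'
#' @param sequences named character vector of uppercase DNA over {A,C,G,T,N}
#' @param region integer length-2, `c(start_offset, end_offset)` relative to TSS
#' @param start_offsets optional named integer vector: offset of each
#'   sequence's first base (defaults to `region[1]` for all genes)
#' @return an object of class `promoter_set`
#' @export
promoter_set <- function(sequences, region, start_offsets = NULL) {
  if (length(region) != 2L || region[1] >= region[2])
    stop("region must be c(start, end) with start < end")
  region <- as.integer(region)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by gene ID")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequences with characters outside {A,C,G,T,N}: ",
         paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
  width <- region[2] - region[1]
  if (any(nchar(sequences) > width))
    stop("sequence longer than the declared region width")
  if (is.null(start_offsets)) {
    start_offsets <- setNames(rep(region[1], length(sequences)), names(sequences))
  } else {
    start_offsets <- start_offsets[names(sequences)]
  }
  structure(list(region = region, sequences = sequences,
                 start_offsets = as.integer(start_offsets)),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d genes, region [%d, %d) relative to TSS\n",
              length(x$sequences), x$region[1], x$region[2]))
  invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$sequences)

gene_ids <- function(promoters) names(promoters$sequences)

#' Expression table: per-gene treatment/control ratios
#'
#' @param ratios named numeric vector of strictly positive expression ratios
#' @return object of class `expression_table` (a named numeric vector)
#' @export
expression_table <- function(ratios) {
  if (is.null(names(ratios)) || anyDuplicated(names(ratios)))
    stop("ratios must be uniquely named by gene ID")
  if (any(!is.finite(ratios) | ratios <= 0))
    stop("expression ratios must be finite and strictly positive")
  r <- as.numeric(ratios)
  names(r) <- names(ratios)
  structure(r, class = "expression_table")
}

#' Read a FASTA file of gene sequences
#'
#' The gene ID is the first whitespace-delimited token of each header; the
#' rest of the description is dropped. Sequences are uppercased and restricted
#' to the {A,C,G,T,N} alphabet.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate gene ID in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(dss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequences: ", paste(ids[bad], collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param sequences named character vector
#' @param path output file
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 80L)
  invisible(path)
}

#' Read a two-column expression table
#'
#' Expects a TSV/CSV with a header containing columns `gene_id` and `ratio`.
#'
#' @param path file path; the delimiter is sniffed from the header line
#' @return an [expression_table()]
#' @export
read_expression_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  r <- suppressWarnings(as.numeric(df$ratio))
  bad <- which(!is.finite(r) | r <= 0)
  if (length(bad) > 0L)
    stop("non-numeric or non-positive ratio at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  expression_table(setNames(r, df$gene_id))
}

#' Write an expression table as TSV
#' @param expr an [expression_table()]
#' @param path output file
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(data.frame(gene_id = names(expr), ratio = as.numeric(expr)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from 6-column BED or GFF3
#'
#' Returns one TSS per gene: for BED (0-based half-open), TSS = start for `+`
#' and end - 1 for `-`; for GFF3 (1-based closed), gene features only, TSS =
#' start - 1 for `+` and end - 1 for `-` (converted to 0-based).
#'
#' @param path annotation file
#' @param format "bed" or "gff3" (guessed from the extension by default)
#' @return data.frame with columns gene_id, chromosome, tss, strand
#' @export
read_annotations <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"))
    ann <- data.frame(gene_id = df$name, chromosome = df$chrom,
                      tss = ifelse(df$strand == "+", df$start, df$end - 1L),
                      strand = df$strand, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) >= 9L]
    keep <- vapply(f, function(x) x[3] == "gene", logical(1))
    f <- f[keep]
    if (length(f) == 0L) stop("no gene features in GFF3: ", path)
    attr9 <- vapply(f, `[`, character(1), 9L)
    id <- sub(".*ID=([^;]+).*", "\\1", attr9)
    strand <- vapply(f, `[`, character(1), 7L)
    start <- as.integer(vapply(f, `[`, character(1), 4L))
    end <- as.integer(vapply(f, `[`, character(1), 5L))
    ann <- data.frame(gene_id = id,
                      chromosome = vapply(f, `[`, character(1), 1L),
                      tss = ifelse(strand == "+", start - 1L, end - 1L),
                      strand = strand, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotations")
  if (any(!ann$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(ann$tss < 0L)) stop("negative TSS coordinate")
  ann
}

#' Extract TSS-anchored promoter windows from a genome
#'
#' For `+` strand genes, returns `genome[[chrom]][tss + start, tss + end)`
#' (0-based genomic coordinates); for `-` strand genes, the reverse complement
#' of the mirrored window, so returned sequences always read 5'->3' toward the
#' TSS. Windows are truncated at chromosome ends (shorter sequence retained,
#' truncation reported via a warning); genes whose window is empty after
#' truncation are dropped with a warning.
#'
#' @param genome named character vector (or list) of chromosome sequences
#' @param annotations data.frame as returned by [read_annotations()]
#' @param region `c(start_offset, end_offset)` relative to TSS, half-open
#' @return a [promoter_set()]
#' @export
extract_promoters <- function(genome, annotations, region) {
  if (region[1] >= region[2]) stop("region start must be < end")
  region <- as.integer(region)
  seqs <- character(0); offs <- integer(0)
  truncated <- character(0); dropped <- character(0)
  for (i in seq_len(nrow(annotations))) {
    g <- annotations[i, ]
    if (!g$chromosome %in% names(genome))
      stop("chromosome absent from genome: ", g$chromosome)
    chrom <- genome[[g$chromosome]]
    L <- nchar(chrom)
    if (g$strand == "+") {
      lo <- g$tss + region[1]; hi <- g$tss + region[2]   # 0-based half-open
    } else {
      lo <- g$tss - region[2] + 1L; hi <- g$tss - region[1] + 1L
    }
    clo <- max(lo, 0L); chi <- min(hi, L)
    if (chi <= clo) { dropped <- c(dropped, g$gene_id); next }
    s <- substr(chrom, clo + 1L, chi)
    if (g$strand == "-") s <- revcomp(s)
    # actual TSS-relative offset of the first returned base
    off <- if (g$strand == "+") clo - g$tss else g$tss - chi + 1L
    if (chi - clo < hi - lo) truncated <- c(truncated, g$gene_id)
    seqs[g$gene_id] <- toupper(s)
    offs[g$gene_id] <- off
  }
  if (length(truncated) > 0L)
    warning(length(truncated), " promoter(s) truncated at chromosome ends: ",
            paste(utils::head(truncated, 5), collapse = ", "))
  if (length(dropped) > 0L)
    warning(length(dropped), " gene(s) dropped (empty window): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (length(seqs) == 0L) stop("no promoters extracted")
  promoter_set(seqs, region, start_offsets = offs)
}

#' Collapse genes with byte-identical promoters
#'
#' Genes sharing an identical promoter sequence are merged to one record whose
#' ID is the lexicographically smallest member; the merged expression ratio is
#' the geometric mean of the member ratios. Idempotent.
#'
#' @param promoters a [promoter_set()]
#' @param expr an [expression_table()] covering all promoter genes
#' @return list with elements `promoters`, `expr`, and `mapping` (data.frame
#'   representative -> member)
#' @export
merge_identical_promoters <- function(promoters, expr) {
  ids <- gene_ids(promoters)
  if (!all(ids %in% names(expr))) stop("every merged gene needs a ratio")
  grp <- split(ids, promoters$sequences[ids])
  reps <- vapply(grp, function(m) sort(m)[1], character(1))
  new_ratio <- vapply(grp, function(m) geometric_mean(as.numeric(expr[m])),
                      numeric(1))
  ord <- order(match(reps, ids))   # keep original record order
  reps <- reps[ord]; grp <- grp[ord]; new_ratio <- new_ratio[ord]
  mapping <- data.frame(
    representative = rep(reps, lengths(grp)),
    member = unlist(grp, use.names = FALSE),
    stringsAsFactors = FALSE)
  seqs <- setNames(names(grp), reps)     # names(grp) are the sequences
  offs <- promoters$start_offsets[match(reps, ids)]
  list(promoters = promoter_set(seqs, promoters$region,
                                start_offsets = setNames(offs, reps)),
       expr = expression_table(setNames(new_ratio, reps)),
       mapping = mapping)
}

#' Pair a promoter set with an expression table
#'
#' Genes present in only one of the two inputs are dropped; the number dropped
#' is reported with a message.
#'
#' @inheritParams merge_identical_promoters
#' @return list(promoters, expr) restricted to the common genes
#' @export
pair_genes <- function(promoters, expr) {
  common <- intersect(gene_ids(promoters), names(expr))
  n_drop <- length(gene_ids(promoters)) + length(names(expr)) - 2L * length(common)
  if (length(common) == 0L) stop("no genes shared between promoters and expression")
  if (n_drop > 0L) message(n_drop, " gene(s) present in only one input dropped")
  keep <- promoters$sequences[common]
  list(promoters = promoter_set(keep, promoters$region,
                                start_offsets = promoters$start_offsets[
                                  match(common, gene_ids(promoters))] |>
                                  setNames(common)),
       expr = expression_table(setNames(as.numeric(expr[common]), common)))
}

#' Crop a promoter set to a sub-window
#'
#' Restricts every sequence to the part overlapping `region` (TSS-relative,
#' half-open). Genes with no sequence in the sub-window are kept with an empty
#' string removed.
#'
#' @param promoters a [promoter_set()]
#' @param region `c(start, end)` sub-window, must overlap the stored region
#' @return a [promoter_set()] with the narrowed region
#' @export
subset_region <- function(promoters, region) {
  region <- as.integer(region)
  if (region[1] >= region[2]) stop("region start must be < end")
  lo <- max(region[1], promoters$region[1])
  hi <- min(region[2], promoters$region[2])
  if (lo >= hi) stop("requested region does not overlap the promoter window")
  ids <- gene_ids(promoters)
  starts <- promoters$start_offsets
  ends <- starts + nchar(promoters$sequences)
  clo <- pmax(lo, starts); chi <- pmin(hi, ends)
  keep <- chi > clo
  seqs <- substr(promoters$sequences[keep],
                 clo[keep] - starts[keep] + 1L,
                 chi[keep] - starts[keep])
  promoter_set(setNames(seqs, ids[keep]), c(lo, hi),
               start_offsets = setNames(clo[keep], ids[keep]))
}
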