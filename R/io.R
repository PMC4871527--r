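# Readers/writers for the tabular and FASTA inputs of the pipeline.

#' Read an annotated somatic mutation table
#'
#' Reads a tab-separated mutation table (a MAF-minimal projection at protein
#' level). Required columns: `sample_id`, `gene`, `protein_id`,
#' `variant_class`, `position`, `ref_aa`, `alt_aa`, `rna_reads_ref`,
#' `rna_reads_alt`, `in_dbsnp`, `somatic`. Lines starting with `#` are
#' ignored. Unknown columns are preserved as opaque annotations and row order
#' is kept. Variant class spellings are normalized through the MAF dialect
#' map (see [normalize_variant_class()]).
#'
#' @param path Path to a TSV file with a header row.
#' @return A validated data.frame, one row per mutation.
#' @seealso [write_mutation_table()], [filter_mutations()]
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) {
    stop("mutation table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  missing <- setdiff(MUTATION_COLUMNS, names(df))
  if (length(missing)) {
    stop("mutation table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    for (col in c("position", "rna_reads_ref", "rna_reads_alt")) {
      df[[col]] <- integer(0)
    }
    for (col in c("in_dbsnp", "somatic")) df[[col]] <- logical(0)
    return(validate_mutations(df))
  }
  parse_count <- function(col) {
    x <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(x)) {
      stop("mutation table '", path, "': unparseable ", col, " at data row ",
           which(is.na(x))[1L], call. = FALSE)
    }
    x
  }
  df$position <- parse_count("position")
  df$rna_reads_ref <- parse_count("rna_reads_ref")
  df$rna_reads_alt <- parse_count("rna_reads_alt")
  parse_flag <- function(col) {
    x <- toupper(trimws(df[[col]]))
    out <- x %in% c("TRUE", "T", "1", "YES")
    bad <- !(x %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO"))
    if (any(bad)) {
      stop("mutation table '", path, "': unparseable ", col, " at data row ",
           which(bad)[1L], call. = FALSE)
    }
    out
  }
  df$in_dbsnp <- parse_flag("in_dbsnp")
  df$somatic <- parse_flag("somatic")
  df$variant_class <- normalize_variant_class(df$variant_class)
  df$ref_aa <- toupper(df$ref_aa)
  df$alt_aa <- toupper(df$alt_aa)
  validate_mutations(df)
  df
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]: writes a TSV that round-trips every
#' field, including any extra annotation columns.
#'
#' @param mutations Mutation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  validate_mutations(mutations)
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The record identifier is the first whitespace-delimited token of the
#' header. Sequences are upper-cased; duplicate identifiers and residues
#' outside the 20 standard amino acids plus `X` are rejected.
#'
#' @param path FASTA file of protein sequences.
#' @param cds Optional named character vector of coding sequences keyed by
#'   protein id, attached to the matching records.
#' @return Named list of [protein_record()] objects keyed by protein id.
#' @export
read_protein_fasta <- function(path, cds = NULL) {
  if (!file.exists(path)) {
    stop("protein FASTA not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate protein id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(as.character(aa))
  out <- lapply(seq_along(ids), function(i) {
    protein_record(ids[i], seqs[i],
                   cds = if (!is.null(cds) && ids[i] %in% names(cds))
                     cds[[ids[i]]] else NULL)
  })
  names(out) <- ids
  out
}

#' Write protein records as FASTA
#'
#' @param proteome Named list of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteome, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteome, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(proteome, `[[`, character(1), "protein_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read per-sample MHC allele calls
#'
#' Accepts either a plain list (one allele per line; all assigned to
#' `sample_id`) or a two-column TSV with header `sample_id`, `allele`.
#'
#' @param path Input path.
#' @param sample_id Sample to assign when the file is a plain one-per-line
#'   list.
#' @param typed_loci,total_loci Locus coverage recorded on every returned
#'   allele set (see [allele_set()]).
#' @return Named list of [allele_set()] objects keyed by sample id.
#' @export
read_allele_sets <- function(path, sample_id = "sample", typed_loci = 1L,
                             total_loci = 3L) {
  if (!file.exists(path)) {
    stop("allele list not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
  if (length(lines) == 0L) stop("allele list '", path, "' is empty", call. = FALSE)
  if (grepl("\t", lines[1L]) && identical(strsplit(lines[1L], "\t")[[1L]][1:2],
                                          c("sample_id", "allele"))) {
    parts <- strsplit(lines[-1L], "\t")
    df <- data.frame(sample_id = vapply(parts, `[`, character(1), 1L),
                     allele = vapply(parts, `[`, character(1), 2L),
                     stringsAsFactors = FALSE)
    split_alleles <- split(df$allele, df$sample_id)
  } else {
    split_alleles <- stats::setNames(list(lines), sample_id)
  }
  lapply(stats::setNames(names(split_alleles), names(split_alleles)),
         function(s) allele_set(s, split_alleles[[s]], typed_loci = typed_loci,
                                total_loci = total_loci))
}
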