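# Core record types: proteins, mutations, allele sets, and the filter audit.
# Mutation tables are plain data.frames with a fixed set of required columns;
# extra columns travel along untouched (opaque annotations).

#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
VARIANT_CLASSES <- c("missense", "inframe_indel", "frameshift", "nonsense",
                     "synonymous")

# Spelling map from MAF-style (and in-house) class labels to the canonical
# enum. Unknown spellings are errors, never silently dropped.
#' @keywords internal
VARIANT_CLASS_DIALECT <- c(
  missense            = "missense",
  Missense_Mutation   = "missense",
  inframe_indel       = "inframe_indel",
  In_Frame_Del        = "inframe_indel",
  In_Frame_Ins        = "inframe_indel",
  frameshift          = "frameshift",
  Frame_Shift_Del     = "frameshift",
  Frame_Shift_Ins     = "frameshift",
  nonsense            = "nonsense",
  Nonsense_Mutation   = "nonsense",
  synonymous          = "synonymous",
  Silent              = "synonymous"
)

#' @keywords internal
MUTATION_COLUMNS <- c("sample_id", "gene", "protein_id", "variant_class",
                      "position", "ref_aa", "alt_aa", "rna_reads_ref",
                      "rna_reads_alt", "in_dbsnp", "somatic")

#' Construct a protein record
#'
#' A protein record holds the wild-type amino-acid sequence for a gene
#' carrying mutations, in 1-based residue coordinates, optionally together
#' with its coding sequence (needed to translate frameshift tails when no
#' precomputed tail is supplied).
#'
#' @param protein_id Identifier (first whitespace-delimited FASTA header token).
#' @param sequence Amino-acid string over the 20 standard residues plus `X`.
#' @param gene Gene symbol (defaults to `protein_id`).
#' @param cds Optional nucleotide coding sequence; when present it must be at
#'   least three times the protein length.
#' @return An object of class `protein_record`.
#' @examples
#' protein_record("Bat1a", "MSFSGFFVVPSPSSSVGN")
#' @export
protein_record <- function(protein_id, sequence, gene = protein_id, cds = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L, nzchar(protein_id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("protein '", protein_id, "': sequence must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA_STANDARD, "X"))
  if (length(bad)) {
    stop("protein '", protein_id, "': illegal residue character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cds)) {
    cds <- toupper(cds)
    if (nchar(cds) < 3L * nchar(sequence)) {
      stop("protein '", protein_id, "': cds shorter than 3 x protein length",
           call. = FALSE)
    }
  }
  structure(list(protein_id = protein_id, gene = gene,
                 sequence = sequence, cds = cds),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$protein_id, " (", x$gene, "), ",
      nchar(x$sequence), " aa",
      if (!is.null(x$cds)) paste0(", cds ", nchar(x$cds), " nt"), "\n", sep = "")
  invisible(x)
}

#' Normalize variant class spellings
#'
#' Maps MAF-style spellings (e.g. `Missense_Mutation`, `Frame_Shift_Del`,
#' `Silent`) and the canonical lower-case names onto the internal enum
#' `missense` / `inframe_indel` / `frameshift` / `nonsense` / `synonymous`.
#' Unknown spellings raise an error rather than being dropped.
#'
#' @param x Character vector of class labels.
#' @return Character vector of canonical class names.
#' @export
normalize_variant_class <- function(x) {
  out <- VARIANT_CLASS_DIALECT[x]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown variant class spelling(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

# Validate a mutation table (data.frame with the required columns), checking
# the per-record invariants. Returns the table invisibly.
#' Validate a mutation table
#'
#' Checks the structural invariants of an annotated somatic mutation table:
#' required columns present, canonical variant classes, 1-based positions,
#' nonnegative integer read counts, and for missense records a single-residue
#' substitution with `ref_aa != alt_aa`.
#'
#' @param mutations A data.frame with the columns listed in
#'   [read_mutation_table()].
#' @return The table, invisibly; errors describe the first violation found.
#' @export
validate_mutations <- function(mutations) {
  missing <- setdiff(MUTATION_COLUMNS, names(mutations))
  if (length(missing)) {
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(mutations) == 0L) return(invisible(mutations))
  bad_class <- setdiff(unique(mutations$variant_class), VARIANT_CLASSES)
  if (length(bad_class)) {
    stop("non-canonical variant class(es): ",
         paste(sQuote(bad_class), collapse = ", "),
         "; run normalize_variant_class() first", call. = FALSE)
  }
  if (any(mutations$position < 1L)) {
    stop("mutation positions must be >= 1 (1-based residue coordinates)",
         call. = FALSE)
  }
  counts <- c(mutations$rna_reads_ref, mutations$rna_reads_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("RNA read counts must be nonnegative integers", call. = FALSE)
  }
  mis <- mutations$variant_class == "missense"
  if (any(mis)) {
    ok <- nchar(mutations$ref_aa[mis]) == 1L &
      nchar(mutations$alt_aa[mis]) == 1L &
      mutations$ref_aa[mis] != mutations$alt_aa[mis]
    if (!all(ok)) {
      i <- which(mis)[which(!ok)[1L]]
      stop("missense record ", i, " (", mutations$gene[i],
           ") must have single, distinct ref/alt residues", call. = FALSE)
    }
  }
  invisible(mutations)
}

#' Construct a per-sample MHC class I allele set
#'
#' @param sample_id Sample identifier.
#' @param alleles Character vector of MHC-I allele names (e.g. two mouse
#'   H-2 alleles, or one/two HLA-A alleles).
#' @param typed_loci Number of class I loci the calls cover.
#' @param total_loci Number of class I loci in the organism (3 for human).
#' @param unambiguous Whether the allele calls are unambiguous; ambiguous
#'   samples are excluded from cohort burden analysis.
#' @return An object of class `allele_set`.
#' @export
allele_set <- function(sample_id, alleles, typed_loci = 1L, total_loci = 3L,
                       unambiguous = TRUE) {
  if (typed_loci < 1L || typed_loci > total_loci) {
    stop("typed_loci must satisfy 1 <= typed_loci <= total_loci", call. = FALSE)
  }
  if (unambiguous && length(alleles) == 0L) {
    stop("an unambiguous allele set must name at least one allele", call. = FALSE)
  }
  structure(list(sample_id = sample_id, alleles = unique(alleles),
                 typed_loci = as.integer(typed_loci),
                 total_loci = as.integer(total_loci),
                 unambiguous = isTRUE(unambiguous)),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set> ", x$sample_id, ": ",
      paste(x$alleles, collapse = ", "),
      " (", x$typed_loci, "/", x$total_loci, " loci",
      if (!x$unambiguous) ", ambiguous", ")\n", sep = "")
  invisible(x)
}

#' @keywords internal
new_funnel_audit <- function(n_input, n_after_somatic, n_after_dbsnp,
                             n_after_expression, n_after_class) {
  counts <- c(n_input = n_input, n_after_somatic = n_after_somatic,
              n_after_dbsnp = n_after_dbsnp,
              n_after_expression = n_after_expression,
              n_after_class = n_after_class)
  if (any(diff(counts) > 0)) {
    stop("funnel audit counts must be monotone nonincreasing", call. = FALSE)
  }
  structure(as.list(counts), class = "funnel_audit")
}

#' @export
print.funnel_audit <- function(x, ...) {
  cat("Mutation filtering funnel:\n")
  cat(sprintf("  %-22s %d\n", "input", x$n_input))
  cat(sprintf("  %-22s %d\n", "somatic", x$n_after_somatic))
  cat(sprintf("  %-22s %d\n", "not in dbSNP", x$n_after_dbsnp))
  cat(sprintf("  %-22s %d\n", "transcribed", x$n_after_expression))
  cat(sprintf("  %-22s %d\n", "eligible class", x$n_after_class))
  invisible(x)
}

#' @export
as.integer.funnel_audit <- function(x, ...) {
  c(n_input = x$n_input, n_after_somatic = x$n_after_somatic,
    n_after_dbsnp = x$n_after_dbsnp, n_after_expression = x$n_after_expression,
    n_after_class = x$n_after_class)
}
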