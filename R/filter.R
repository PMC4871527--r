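# The mutation-filtering funnel: somatic -> dbSNP -> expression -> class.

#' Filter somatic mutations through the candidate-neoantigen funnel
#'
#' Applies the four filtering rules in fixed order: (1) keep somatic,
#' tumor-specific records; (2) remove variants flagged in dbSNP; (3) require
#' RNA-seq evidence of expression (`rna_reads_alt >= min_alt_reads`; only
#' reads supporting the mutated allele are gated, wild-type read counts of
#' zero are permitted); (4) keep only variant classes expected to yield T
#' cell epitopes (nonsense and synonymous mutations are dropped by default).
#' A stage-by-stage audit is returned so that alternative orders can be
#' compared.
#'
#' @param mutations Mutation data.frame (see [read_mutation_table()]).
#' @param min_alt_reads Minimum RNA-seq reads supporting the mutant allele
#'   (default 1; 0 disables the expression filter).
#' @param keep_classes Variant classes retained at the class stage.
#' @return A list with elements `mutations` (the retained rows, input order
#'   preserved) and `audit` (a `funnel_audit` with counts
#'   `n_input`, `n_after_somatic`, `n_after_dbsnp`, `n_after_expression`,
#'   `n_after_class`).
#' @examples
#' m <- data.frame(sample_id = "s", gene = c("g1", "g2"), protein_id = "p",
#'                 variant_class = c("missense", "nonsense"), position = 5L,
#'                 ref_aa = c("A", "Q"), alt_aa = c("V", "*"),
#'                 rna_reads_ref = 3L, rna_reads_alt = c(4L, 2L),
#'                 in_dbsnp = FALSE, somatic = TRUE)
#' m$alt_aa <- c("V", "X")
#' filter_mutations(m)$audit
#' @export
filter_mutations <- function(mutations,
                             min_alt_reads = 1L,
                             keep_classes = c("missense", "inframe_indel",
                                              "frameshift")) {
  if (length(min_alt_reads) != 1L || is.na(min_alt_reads) || min_alt_reads < 0) {
    stop("min_alt_reads must be a nonnegative count", call. = FALSE)
  }
  bad <- setdiff(keep_classes, VARIANT_CLASSES)
  if (length(bad)) {
    stop("unknown variant class(es) in keep_classes: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  validate_mutations(mutations)
  n_input <- nrow(mutations)
  m <- mutations[mutations$somatic, , drop = FALSE]
  n_somatic <- nrow(m)
  m <- m[!m$in_dbsnp, , drop = FALSE]
  n_dbsnp <- nrow(m)
  m <- m[m$rna_reads_alt >= min_alt_reads, , drop = FALSE]
  n_expr <- nrow(m)
  m <- m[m$variant_class %in% keep_classes, , drop = FALSE]
  n_class <- nrow(m)
  list(mutations = m,
       audit = new_funnel_audit(n_input, n_somatic, n_dbsnp, n_expr, n_class))
}
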