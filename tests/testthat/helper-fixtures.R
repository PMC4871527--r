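# Shared fixture builders and independent oracles.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# One-row mutation data.frame with sensible defaults.
mut_row <- function(sample_id = "s1", gene = "g", protein_id = gene,
                    variant_class = "missense", position = 10L,
                    ref_aa = "A", alt_aa = "V", rna_reads_ref = 5L,
                    rna_reads_alt = 5L, in_dbsnp = FALSE, somatic = TRUE) {
  data.frame(sample_id = sample_id, gene = gene, protein_id = protein_id,
             variant_class = variant_class, position = position,
             ref_aa = ref_aa, alt_aa = alt_aa,
             rna_reads_ref = rna_reads_ref, rna_reads_alt = rna_reads_alt,
             in_dbsnp = in_dbsnp, somatic = somatic,
             stringsAsFactors = FALSE)
}

random_protein_seq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Independent window oracle: every substring of each requested length,
# filtered by overlap with the novel positions.
brute_force_windows <- function(ctx, lengths = 8:11) {
  L <- nchar(ctx$mut_sequence)
  starts <- integer(0); lens <- integer(0)
  for (k in sort(lengths)) {
    if (k > L) next
    for (s in seq_len(L - k + 1L)) {
      if (any(ctx$novel_positions >= s & ctx$novel_positions <= s + k - 1L)) {
        starts <- c(starts, s); lens <- c(lens, k)
      }
    }
  }
  data.frame(sequence = substring(ctx$mut_sequence, starts, starts + lens - 1L),
             start = starts, length = lens, stringsAsFactors = FALSE)
}
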