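# Mutant protein contexts, class I 8-11mer candidate windows, and long
# vaccine peptide design.

#' Build the mutant protein context for one mutation
#'
#' Applies a protein-level variant to its wild-type sequence and records the
#' novel residue positions that any candidate epitope must overlap:
#' \describe{
#'   \item{missense}{single substitution; one novel position.}
#'   \item{inframe_indel}{`ref_aa` residues at `position` replaced by
#'     `alt_aa`; novel positions are the inserted residues plus one flanking
#'     residue on each side of the junction, so junction-spanning windows are
#'     always enumerated.}
#'   \item{frameshift}{wild-type prefix up to `position - 1` concatenated
#'     with the novel C-terminal tail, taken from `alt_aa` when precomputed
#'     or translated from the shifted reading frame of the coding sequence;
#'     every tail residue is novel.}
#' }
#'
#' @param protein A [protein_record()].
#' @param mutation One-row mutation data.frame (or a list with the same
#'   fields).
#' @param tail_cap Maximum frameshift tail length retained (longer tails are
#'   truncated with a warning).
#' @return An object of class `mutant_context` with fields `protein_id`,
#'   `gene`, `wt_sequence`, `mut_sequence`, `novel_positions` (1-based
#'   indices into `mut_sequence`).
#' @examples
#' p <- protein_record("Bat1a", "MSFSGFFVVPSPSSSVGN")
#' m <- list(sample_id = "ID8", gene = "Bat1a", protein_id = "Bat1a",
#'           variant_class = "missense", position = 4L, ref_aa = "S",
#'           alt_aa = "P", rna_reads_ref = 79L, rna_reads_alt = 15L,
#'           in_dbsnp = FALSE, somatic = TRUE)
#' apply_mutation(p, m)
#' @export
apply_mutation <- function(protein, mutation, tail_cap = 50L) {
  stopifnot(inherits(protein, "protein_record"))
  mutation <- as.list(mutation)
  wt <- protein$sequence
  L <- nchar(wt)
  pos <- as.integer(mutation$position)
  if (is.na(pos) || pos < 1L || pos > L) {
    stop("position ", mutation$position, " out of range for protein '",
         protein$protein_id, "' (length ", L, ")", call. = FALSE)
  }
  vc <- mutation$variant_class
  ref <- toupper(mutation$ref_aa)
  alt <- toupper(mutation$alt_aa)

  if (vc == "missense") {
    if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt) {
      stop("missense variant must substitute one residue for a different one (",
           mutation$gene, " ", ref, pos, alt, ")", call. = FALSE)
    }
    found <- substr(wt, pos, pos)
    if (found != ref) {
      stop("reference mismatch at ", protein$protein_id, ":", pos,
           ": expected '", ref, "', found '", found, "'", call. = FALSE)
    }
    mut <- wt
    substr(mut, pos, pos) <- alt
    novel <- pos
  } else if (vc == "inframe_indel") {
    nref <- nchar(ref)
    if (nref > 0L) {
      found <- substr(wt, pos, pos + nref - 1L)
      if (found != ref) {
        stop("reference mismatch at ", protein$protein_id, ":", pos,
             ": expected '", ref, "', found '", found, "'", call. = FALSE)
      }
    }
    mut <- paste0(substr(wt, 1L, pos - 1L), alt,
                  substr(wt, pos + nref, L))
    nalt <- nchar(alt)
    inserted <- if (nalt > 0L) seq.int(pos, pos + nalt - 1L) else integer(0)
    junction <- c(pos - 1L, pos + nalt)
    novel <- sort(unique(c(inserted, junction)))
    novel <- novel[novel >= 1L & novel <= nchar(mut)]
  } else if (vc == "frameshift") {
    if (nzchar(alt)) {
      tail <- alt
    } else if (!is.null(protein$cds)) {
      tail <- translate_frameshift(protein$cds, shift_codon = pos,
                                   deletion = 1L)
    } else {
      stop("unresolvable frameshift at ", protein$protein_id, ":", pos,
           ": no precomputed tail and no coding sequence", call. = FALSE)
    }
    if (nchar(tail) > tail_cap) {
      warning("frameshift tail at ", protein$protein_id, ":", pos,
              " truncated from ", nchar(tail), " to ", tail_cap, " residues")
      tail <- substr(tail, 1L, tail_cap)
    }
    if (!nzchar(tail)) {
      stop("frameshift at ", protein$protein_id, ":", pos,
           " yields an empty novel tail (immediate stop codon)", call. = FALSE)
    }
    mut <- paste0(substr(wt, 1L, pos - 1L), tail)
    novel <- seq.int(pos, pos + nchar(tail) - 1L)
  } else {
    stop("variant class '", vc, "' does not create novel peptide sequence",
         call. = FALSE)
  }

  structure(list(protein_id = protein$protein_id, gene = mutation$gene,
                 wt_sequence = wt, mut_sequence = mut,
                 novel_positions = as.integer(novel)),
            class = "mutant_context")
}

#' @export
print.mutant_context <- function(x, ...) {
  cat("<mutant_context> ", x$protein_id, " (", x$gene, "): ",
      nchar(x$wt_sequence), " aa -> ", nchar(x$mut_sequence), " aa, ",
      length(x$novel_positions), " novel position(s) at [",
      paste(range(x$novel_positions), collapse = "-"), "]\n", sep = "")
  invisible(x)
}

#' Enumerate class I candidate peptide windows
#'
#' Returns every 8-11mer substring of the mutant sequence that overlaps at
#' least one novel residue position: the candidate set handed to MHC class I
#' binding prediction. Windows are unique by (start, length) and sorted by
#' (length, start).
#'
#' @param ctx A `mutant_context` from [apply_mutation()].
#' @param lengths Window lengths; must lie within the class I range 8-11
#'   unless `allow_any_length = TRUE`.
#' @param allow_any_length Override the 8-11 restriction (e.g. for
#'   exploratory scans); lengths must still be positive.
#' @return data.frame with columns `sequence`, `start`, `length`
#'   (coordinates refer to the mutant sequence).
#' @examples
#' p <- protein_record("Bat1a", "MSFSGFFVVPSPSSSVGN")
#' m <- list(gene = "Bat1a", variant_class = "missense", position = 4L,
#'           ref_aa = "S", alt_aa = "P")
#' nrow(enumerate_class1_windows(apply_mutation(p, m)))
#' @export
enumerate_class1_windows <- function(ctx, lengths = 8:11,
                                     allow_any_length = FALSE) {
  stopifnot(inherits(ctx, "mutant_context"))
  lengths <- sort(unique(as.integer(lengths)))
  if (!allow_any_length && (any(lengths < 8L) || any(lengths > 11L))) {
    stop("window lengths must lie in the MHC class I range 8-11 ",
         "(set allow_any_length = TRUE to override)", call. = FALSE)
  }
  if (any(lengths < 1L)) stop("window lengths must be positive", call. = FALSE)
  L <- nchar(ctx$mut_sequence)
  novel <- ctx$novel_positions
  starts_all <- integer(0); lens_all <- integer(0)
  for (k in lengths) {
    if (k > L) next
    lo <- max(1L, min(novel) - k + 1L)
    hi <- min(L - k + 1L, max(novel))
    if (hi < lo) next
    starts <- lo:hi
    # keep windows intersecting the (possibly non-contiguous) novel set
    keep <- vapply(starts, function(s) any(novel >= s & novel <= s + k - 1L),
                   logical(1))
    starts <- starts[keep]
    starts_all <- c(starts_all, starts)
    lens_all <- c(lens_all, rep.int(k, length(starts)))
  }
  data.frame(sequence = substring(ctx$mut_sequence, starts_all,
                                  starts_all + lens_all - 1L),
             start = starts_all, length = lens_all,
             stringsAsFactors = FALSE)
}

#' Enumerate candidate windows for a whole mutation table
#'
#' Convenience wrapper around [apply_mutation()] and
#' [enumerate_class1_windows()] for a filtered mutation table, keyed so that
#' downstream counting can group windows by mutation.
#'
#' @param mutations Filtered mutation data.frame.
#' @param proteome Named list of [protein_record()]s covering every
#'   `protein_id` in `mutations`.
#' @param lengths Window lengths (default 8-11).
#' @return data.frame with columns `mutation_idx` (row index into
#'   `mutations`), `sample_id`, `gene`, `sequence`, `start`, `length`.
#' @export
mutant_windows <- function(mutations, proteome, lengths = 8:11) {
  validate_mutations(mutations)
  missing <- setdiff(unique(mutations$protein_id), names(proteome))
  if (length(missing)) {
    stop("proteome is missing protein(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(mutations)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- apply_mutation(proteome[[mutations$protein_id[i]]], mutations[i, ])
    w <- enumerate_class1_windows(ctx, lengths)
    if (nrow(w)) {
      w$mutation_idx <- i
      pieces[[i]] <- w
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    return(data.frame(mutation_idx = integer(0), sample_id = character(0),
                      gene = character(0), sequence = character(0),
                      start = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    mutation_idx = unlist(lapply(pieces, `[[`, "mutation_idx")),
    sequence = unlist(lapply(pieces, `[[`, "sequence")),
    start = unlist(lapply(pieces, `[[`, "start")),
    length = unlist(lapply(pieces, `[[`, "length")),
    stringsAsFactors = FALSE)
  out$sample_id <- mutations$sample_id[out$mutation_idx]
  out$gene <- mutations$gene[out$mutation_idx]
  out[, c("mutation_idx", "sample_id", "gene", "sequence", "start", "length")]
}

#' Design a synthetic long vaccine peptide
#'
#' Centers the mutated region in a long peptide with `flank` wild-type
#' residues on each side: for an interior missense mutation this is the
#' classic 29mer with the mutant residue at offset 15. The peptide is
#' clipped, not padded, at protein termini (a mutation at residue 4 yields an
#' 18mer), and a frameshift peptide is the upstream flank plus the entire
#' novel tail.
#'
#' @param ctx A `mutant_context`.
#' @param flank Number of wild-type residues on each side of the novel
#'   region (default 14, giving 29mers).
#' @return The vaccine peptide (character scalar).
#' @examples
#' p <- protein_record("Bat1a", "MSFSGFFVVPSPSSSVGN")
#' m <- list(gene = "Bat1a", variant_class = "missense", position = 4L,
#'           ref_aa = "S", alt_aa = "P")
#' design_vaccine_peptide(apply_mutation(p, m))  # "MSFPGFFVVPSPSSSVGN"
#' @export
design_vaccine_peptide <- function(ctx, flank = 14L) {
  stopifnot(inherits(ctx, "mutant_context"))
  if (flank < 0L) stop("flank must be nonnegative", call. = FALSE)
  L <- nchar(ctx$mut_sequence)
  p_min <- min(ctx$novel_positions)
  p_max <- max(ctx$novel_positions)
  substr(ctx$mut_sequence, max(1L, p_min - flank), min(L, p_max + flank))
}

#' Translate a frameshifted reading frame
#'
#' Rebuilds the downstream coding sequence after an indel that shifts the
#' reading frame, and translates from the first affected codon until (and
#' excluding) the first stop codon. If no stop is reached, translation runs
#' to the last complete codon and the result carries attribute
#' `open_ended = TRUE`.
#'
#' @param cds Coding sequence (A/C/G/T only; ambiguity codes are rejected).
#' @param shift_codon 1-based index of the first codon affected by the
#'   frameshift.
#' @param deletion Number of bases deleted at the start of that codon.
#' @param insertion Bases inserted at the same point (after any deletion).
#' @return The novel peptide tail, possibly empty, with attribute
#'   `open_ended` (TRUE when no stop codon terminated the tail).
#' @examples
#' translate_frameshift("ATGGCTTAA", shift_codon = 2, deletion = 1)  # "L"
#' @export
translate_frameshift <- function(cds, shift_codon, deletion = 0L,
                                 insertion = "") {
  cds <- toupper(cds)
  insertion <- toupper(insertion)
  if (nchar(cds) < 3L) stop("cds must be at least one codon", call. = FALSE)
  if (grepl("[^ACGT]", cds) || (nzchar(insertion) && grepl("[^ACGT]", insertion))) {
    stop("ambiguous or non-nucleotide character in coding sequence",
         call. = FALSE)
  }
  n_codons <- nchar(cds) %/% 3L
  if (shift_codon < 1L || shift_codon > n_codons) {
    stop("shift_codon ", shift_codon, " beyond coding sequence (",
         n_codons, " codons)", call. = FALSE)
  }
  if ((nchar(insertion) - deletion) %% 3L == 0L) {
    stop("indel of net length ", nchar(insertion) - deletion,
         " bases does not shift the reading frame", call. = FALSE)
  }
  at <- 3L * (shift_codon - 1L) + 1L
  downstream <- substr(cds, at, nchar(cds))
  if (deletion >= nchar(downstream)) {
    stop("deletion of ", deletion, " bases exceeds remaining coding sequence",
         call. = FALSE)
  }
  shifted <- paste0(insertion, substr(downstream, deletion + 1L,
                                      nchar(downstream)))
  n_complete <- (nchar(shifted) %/% 3L) * 3L
  if (n_complete == 0L) {
    return(structure("", open_ended = TRUE))
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(shifted, 1L, n_complete))))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    structure(substr(aa, 1L, stop_at - 1L), open_ended = FALSE)
  } else {
    structure(aa, open_ended = TRUE)
  }
}

#' Write candidate windows as FASTA
#'
#' Record ids follow `sample|gene|variant|start|length`.
#'
#' @param windows Window data.frame from [mutant_windows()].
#' @param mutations The mutation table the windows were derived from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, mutations, path) {
  m <- mutations[windows$mutation_idx, ]
  ids <- paste(m$sample_id, m$gene,
               paste0(m$ref_aa, m$position, m$alt_aa),
               windows$start, windows$length, sep = "|")
  seqs <- Biostrings::AAStringSet(windows$sequence)
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
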