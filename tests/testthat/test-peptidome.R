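# Mutant contexts, window enumeration, vaccine peptide design, and
# frameshift translation.

test_that("missense application substitutes a single residue and records it", {
  p <- protein_record("Bat1a", "MSFSGFFVVPSPSSSVGN")
  m <- mut_row(gene = "Bat1a", protein_id = "Bat1a", position = 4L,
               ref_aa = "S", alt_aa = "P")
  ctx <- apply_mutation(p, m)
  expect_equal(ctx$mut_sequence, "MSFPGFFVVPSPSSSVGN")
  expect_equal(ctx$novel_positions, 4L)
  expect_equal(nchar(ctx$mut_sequence), nchar(ctx$wt_sequence))
})

test_that("reference mismatches and synonymous-style input are rejected", {
  p <- protein_record("p", "ACDEFGHIKLMNPQRSTVWY")
  expect_error(apply_mutation(p, mut_row(position = 3L, ref_aa = "E",
                                         alt_aa = "K")),
               "expected 'E', found 'D'")
  expect_error(apply_mutation(p, mut_row(position = 3L, ref_aa = "D",
                                         alt_aa = "D")),
               "different")
  expect_error(apply_mutation(p, mut_row(position = 99L)), "out of range")
})

test_that("frameshift context appends the novel tail and marks every tail residue novel", {
  p <- protein_record("Mtdh", "AAAAASITLSKGDSDNSSSLMNPQ")
  m <- mut_row(gene = "Mtdh", variant_class = "frameshift", position = 20L,
               ref_aa = "", alt_aa = "HVTRHRQAQVKC")
  ctx <- apply_mutation(p, m)
  expect_true(endsWith(ctx$mut_sequence, "SITLSKGDSDNSSSHVTRHRQAQVKC"))
  expect_equal(length(ctx$novel_positions), 12L)
  expect_equal(ctx$novel_positions, 20:31)
  # no tail and no cds: unresolvable
  expect_error(apply_mutation(p, mut_row(variant_class = "frameshift",
                                         position = 20L, ref_aa = "",
                                         alt_aa = "")),
               "unresolvable")
  # overly long tails are capped with a warning
  expect_warning(
    apply_mutation(p, mut_row(variant_class = "frameshift", position = 20L,
                              ref_aa = "", alt_aa = strrep("AC", 30L))),
    "truncated")
})

test_that("in-frame indels mark inserted residues plus junction flanks as novel", {
  p <- protein_record("p", "ACDEFGHIKLMNPQRSTVWY")
  # delete DE (positions 3-4)
  ctx <- apply_mutation(p, mut_row(variant_class = "inframe_indel",
                                   position = 3L, ref_aa = "DE", alt_aa = ""))
  expect_equal(ctx$mut_sequence, "ACFGHIKLMNPQRSTVWY")
  expect_equal(ctx$novel_positions, c(2L, 3L))
  # insert WW at position 3
  ctx2 <- apply_mutation(p, mut_row(variant_class = "inframe_indel",
                                    position = 3L, ref_aa = "", alt_aa = "WW"))
  expect_equal(ctx2$mut_sequence, "ACWWDEFGHIKLMNPQRSTVWY")
  expect_equal(ctx2$novel_positions, 2:5)
})

test_that("missense application is an involution under ref/alt swap", {
  set.seed(7)
  for (i in 1:25) {
    wt <- random_protein_seq(sample(30:80, 1))
    pos <- sample(nchar(wt), 1)
    ref <- substr(wt, pos, pos)
    alt <- sample(setdiff(AA20, ref), 1)
    p <- protein_record("p", wt)
    ctx <- apply_mutation(p, mut_row(position = pos, ref_aa = ref, alt_aa = alt))
    back <- apply_mutation(protein_record("p", ctx$mut_sequence),
                           mut_row(position = pos, ref_aa = alt, alt_aa = ref))
    expect_identical(back$mut_sequence, wt)
  }
})

test_that("window enumeration matches closed forms at interior and terminal positions", {
  wt <- random_protein_seq(40)
  pos <- 20L
  ref <- substr(wt, pos, pos)
  ctx <- apply_mutation(protein_record("p", wt),
                        mut_row(position = pos, ref_aa = ref,
                                alt_aa = setdiff(AA20, ref)[1]))
  w <- enumerate_class1_windows(ctx)
  expect_equal(nrow(w), 8L + 9L + 10L + 11L)  # 38 for an interior missense
  expect_false(any(duplicated(w[, c("start", "length")])))
  expect_true(all(diff(order(w$length, w$start)) == 1L))  # sorted

  ref1 <- substr(wt, 1, 1)
  ctx1 <- apply_mutation(protein_record("p", wt),
                         mut_row(position = 1L, ref_aa = ref1,
                                 alt_aa = setdiff(AA20, ref1)[1]))
  w1 <- enumerate_class1_windows(ctx1)
  expect_equal(nrow(w1), 4L)  # one placement per length covers residue 1
  expect_true(all(w1$start == 1L))
})

test_that("window enumeration agrees with the brute-force all-substrings oracle", {
  set.seed(11)
  for (i in 1:200) {
    wt <- random_protein_seq(sample(30:120, 1))
    pos <- sample(nchar(wt), 1)
    ref <- substr(wt, pos, pos)
    ctx <- apply_mutation(protein_record("p", wt),
                          mut_row(position = pos, ref_aa = ref,
                                  alt_aa = sample(setdiff(AA20, ref), 1)))
    got <- enumerate_class1_windows(ctx)
    want <- brute_force_windows(ctx)
    expect_equal(got[order(got$length, got$start), ],
                 want[order(want$length, want$start), ], ignore_attr = TRUE)
  }
  # frameshift contexts too
  for (i in 1:30) {
    wt <- random_protein_seq(sample(40:100, 1))
    pos <- sample(15:(nchar(wt) - 5), 1)
    tail <- random_protein_seq(sample(5:20, 1))
    ctx <- apply_mutation(protein_record("p", wt),
                          mut_row(variant_class = "frameshift", position = pos,
                                  ref_aa = "", alt_aa = tail))
    got <- enumerate_class1_windows(ctx)
    want <- brute_force_windows(ctx)
    expect_equal(got[order(got$length, got$start), ],
                 want[order(want$length, want$start), ], ignore_attr = TRUE)
  }
})

test_that("every missense window differs from the same-coordinate wild-type substring", {
  set.seed(13)
  for (i in 1:40) {
    wt <- random_protein_seq(sample(30:80, 1))
    pos <- sample(nchar(wt), 1)
    ref <- substr(wt, pos, pos)
    ctx <- apply_mutation(protein_record("p", wt),
                          mut_row(position = pos, ref_aa = ref,
                                  alt_aa = sample(setdiff(AA20, ref), 1)))
    w <- enumerate_class1_windows(ctx)
    wt_slices <- substring(wt, w$start, w$start + w$length - 1L)
    expect_true(all(w$sequence != wt_slices))
  }
})

test_that("out-of-range window lengths require an explicit override", {
  wt <- random_protein_seq(40)
  ref <- substr(wt, 20, 20)
  ctx <- apply_mutation(protein_record("p", wt),
                        mut_row(position = 20L, ref_aa = ref,
                                alt_aa = setdiff(AA20, ref)[1]))
  expect_error(enumerate_class1_windows(ctx, lengths = 7:11), "8-11")
  expect_silent(enumerate_class1_windows(ctx, lengths = 12L,
                                         allow_any_length = TRUE))
})

test_that("vaccine peptides center the mutation and clip at protein termini", {
  # interior missense in a 29-residue context: full 29mer, mutation at offset 15
  p <- protein_record("Dync1h1", "KDRAATSPALFNRCVLNWFGDWSTEALYQ")
  ctx <- apply_mutation(p, mut_row(position = 15L, ref_aa = "V", alt_aa = "E"))
  pep <- design_vaccine_peptide(ctx)
  expect_equal(pep, "KDRAATSPALFNRCELNWFGDWSTEALYQ")
  expect_equal(nchar(pep), 29L)
  expect_equal(substr(pep, 15, 15), "E")

  # N-terminal mutation: left flank clipped, no padding
  p2 <- protein_record("Bat1a", "MSFSGFFVVPSPSSSVGN")
  ctx2 <- apply_mutation(p2, mut_row(position = 4L, ref_aa = "S", alt_aa = "P"))
  expect_equal(design_vaccine_peptide(ctx2), "MSFPGFFVVPSPSSSVGN")  # 18mer
})

test_that("designed peptide length follows the clipping formula", {
  set.seed(17)
  flank <- 14L
  for (i in 1:50) {
    wt <- random_protein_seq(sample(30:90, 1))
    pos <- sample(nchar(wt), 1)
    ref <- substr(wt, pos, pos)
    ctx <- apply_mutation(protein_record("p", wt),
                          mut_row(position = pos, ref_aa = ref,
                                  alt_aa = sample(setdiff(AA20, ref), 1)))
    pep <- design_vaccine_peptide(ctx, flank = flank)
    L <- nchar(ctx$mut_sequence)
    expect_equal(nchar(pep),
                 min(pos + flank, L) - max(1L, pos - flank) + 1L)
    if (pos > flank && pos + flank <= L) expect_equal(nchar(pep), 29L)
  }
})

test_that("frameshift translation follows the shifted frame to the first stop", {
  # 1-base deletion after the first codon: shifted frame CTT|AA -> "L"
  tail <- translate_frameshift("ATGGCTTAA", shift_codon = 2L, deletion = 1L)
  expect_equal(as.character(tail), "L")
  expect_true(attr(tail, "open_ended"))  # no stop before the incomplete codon

  # shifted frame whose first codon is a stop: empty tail
  tail2 <- translate_frameshift("ATGGTAAGCA", shift_codon = 2L, deletion = 1L)
  expect_equal(as.character(tail2), "")
  expect_false(attr(tail2, "open_ended"))

  # stop inside the shifted frame terminates (and is excluded):
  # shifted frame AAT TGA ... -> "N"
  tail3 <- translate_frameshift("ATGGAATTGACCC", shift_codon = 2L,
                                deletion = 1L)
  expect_equal(as.character(tail3), "N")
  expect_false(attr(tail3, "open_ended"))

  expect_error(translate_frameshift("ATGNCT", 1L, deletion = 1L), "ambiguous")
  expect_error(translate_frameshift("ATGGCT", 5L, deletion = 1L), "beyond")
  expect_error(translate_frameshift("ATGGCTAAA", 2L, deletion = 3L),
               "does not shift")
})
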