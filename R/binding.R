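# Uniform interface over MHC class I affinity predictors: a seeded synthetic
# predictor for tests and simulations, parsers for external predictor
# output, and threshold classification.

# Deterministic hash of a character vector onto [0, 1). A polynomial rolling
# hash modulo a Mersenne-adjacent prime with two multiplicative mixing steps;
# vectorized over keys so millions of peptide-allele pairs hash in seconds.
# The hash, not a sequential RNG stream, makes synthetic affinities
# order-independent: the value for (peptide, allele, seed) never depends on
# what else was scored in the same call.
#' @keywords internal
hash_unit <- function(keys) {
  M <- 2147483629
  n <- length(keys)
  if (n == 0L) return(numeric(0))
  codes <- stats::setNames(as.numeric(32:126),
                           strsplit(intToUtf8(32:126), "")[[1L]])
  h <- numeric(n)
  nc <- nchar(keys)
  for (k in seq_len(max(nc))) {
    live <- nc >= k  # each key hashes only its own characters
    ch <- substr(keys[live], k, k)
    code <- unname(codes[ch])
    code[is.na(code)] <- 0  # non-ASCII
    h[live] <- (h[live] * 131 + code) %% M
  }
  h <- (h * 48271 + 11) %% 2147483647
  h <- (h * 48271 + 11) %% 2147483647
  h / 2147483647
}

#' Synthetic MHC class I affinity predictor
#'
#' A deterministic stand-in for an external binding predictor, used by the
#' simulators and tests. Each (peptide, allele, seed) triple is mapped
#' through a stable hash to an IC50 drawn log-uniformly from `ic50_range`
#' (default 1-50000 nM, the span of typical predictor output). Peptides
#' containing any planted anchor motif are instead mapped uniformly into
#' `motif_range` (default below the 100 nM high-affinity threshold), which
#' is how simulations plant known binders. Identical inputs always give
#' identical output, independent of call order.
#'
#' @param peptides Character vector of 8-11mer peptides.
#' @param alleles Character vector of allele names; every (peptide, allele)
#'   pair is scored.
#' @param seed Integer seed entering the hash.
#' @param strong_motifs Optional character vector of planted anchor motifs.
#' @param ic50_range Background IC50 range in nM (log-uniform).
#' @param motif_range IC50 range for motif-matched peptides (uniform).
#' @return data.frame of binding calls: `peptide`, `allele`, `ic50_nM`.
#' @examples
#' synthetic_predict(c("SIINFEKL", "AAAAAAAAA"), "H-2-Kb", seed = 1)
#' @export
synthetic_predict <- function(peptides, alleles, seed,
                              strong_motifs = NULL,
                              ic50_range = c(1, 50000),
                              motif_range = c(1, 99.9)) {
  if (length(alleles) == 0L) {
    stop("at least one allele is required", call. = FALSE)
  }
  if (length(peptides) == 0L) {
    return(data.frame(peptide = character(0), allele = character(0),
                      ic50_nM = numeric(0), stringsAsFactors = FALSE))
  }
  stopifnot(length(ic50_range) == 2L, all(ic50_range > 0),
            ic50_range[1] < ic50_range[2],
            length(motif_range) == 2L, all(motif_range > 0))
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- hash_unit(paste(grid$peptide, grid$allele, as.integer(seed), sep = "|"))
  lo <- log10(ic50_range[1]); hi <- log10(ic50_range[2])
  ic50 <- 10^(lo + u * (hi - lo))
  if (length(strong_motifs)) {
    hit <- rep(FALSE, nrow(grid))
    for (motif in strong_motifs) {
      hit <- hit | grepl(motif, grid$peptide, fixed = TRUE)
    }
    ic50[hit] <- motif_range[1] + u[hit] * (motif_range[2] - motif_range[1])
  }
  data.frame(peptide = grid$peptide, allele = grid$allele, ic50_nM = ic50,
             stringsAsFactors = FALSE)
}

#' Parse external predictor output into binding calls
#'
#' Two dialects are supported: `"tsv"`, a minimal headered table with
#' columns `peptide`, `allele`, `ic50_nM`; and `"netmhcpan"`, whitespace-
#' separated columnar text in the style of NetMHCpan output, with
#' configurable column positions. In both dialects, lines starting with `#`
#' (banners) and blank lines are skipped, and affinities are read in nM.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"netmhcpan"`.
#' @param columns For the `netmhcpan` dialect, a named integer vector giving
#'   the 1-based positions of the `peptide`, `allele` and `ic50` columns.
#' @return data.frame of binding calls: `peptide`, `allele`, `ic50_nM`.
#' @export
parse_predictions <- function(path, dialect = c("tsv", "netmhcpan"),
                              columns = c(peptide = 2L, allele = 1L,
                                          ic50 = 3L)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("prediction file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (dialect == "tsv") {
    if (!length(lines)) stop("prediction file '", path, "' is empty", call. = FALSE)
    header <- strsplit(lines[1L], "\t")[[1L]]
    need <- c("peptide", "allele", "ic50_nM")
    idx <- match(need, header)
    if (anyNA(idx)) {
      stop("prediction table '", path, "' is missing column(s): ",
           paste(need[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    parts <- strsplit(lines[-1L], "\t")
    line_no <- line_no[-1L]
    pep <- vapply(parts, `[`, character(1), idx[1L])
    alle <- vapply(parts, `[`, character(1), idx[2L])
    aff_raw <- vapply(parts, `[`, character(1), idx[3L])
  } else {
    parts <- strsplit(trimws(lines), "\\s+")
    nmax <- max(columns)
    ok <- lengths(parts) >= nmax
    parts <- parts[ok]
    line_no <- line_no[ok]
    pep <- vapply(parts, `[`, character(1), columns[["peptide"]])
    alle <- vapply(parts, `[`, character(1), columns[["allele"]])
    aff_raw <- vapply(parts, `[`, character(1), columns[["ic50"]])
  }
  aff <- suppressWarnings(as.numeric(aff_raw))
  bad <- is.na(aff) | aff <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("prediction file '", path, "', line ", line_no[i],
         ": affinity must be a positive number, got '", aff_raw[i], "'",
         call. = FALSE)
  }
  data.frame(peptide = pep, allele = alle, ic50_nM = aff,
             stringsAsFactors = FALSE)
}

#' Write binding calls as TSV
#'
#' @param calls Binding call data.frame (`peptide`, `allele`, `ic50_nM`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_calls <- function(calls, path) {
  utils::write.table(calls[, c("peptide", "allele", "ic50_nM")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best predicted affinity over a mutation's windows and alleles
#'
#' Reduces the binding calls for one mutation to the single best (lowest
#' IC50) epitope over all candidate windows and all typed alleles — the
#' value reported per mutation in a vaccine panel. Exact ties are broken by
#' the lexicographically smallest (length, start) window, then allele order.
#'
#' @param calls Binding call data.frame covering every window-allele pair.
#' @param windows Window data.frame for the mutation
#'   (see [enumerate_class1_windows()]).
#' @param alleles An [allele_set()] or character vector of allele names.
#' @return A list with `ic50_nM`, `peptide`, `allele`, `start`, `length`.
#' @export
best_affinity_per_mutation <- function(calls, windows, alleles) {
  allele_names <- if (inherits(alleles, "allele_set")) alleles$alleles else alleles
  if (nrow(windows) == 0L) stop("no candidate windows supplied", call. = FALSE)
  grid <- expand.grid(widx = seq_len(nrow(windows)), allele = allele_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(windows$sequence[grid$widx], grid$allele, sep = "\r")
  idx <- match(key, paste(calls$peptide, calls$allele, sep = "\r"))
  if (anyNA(idx)) {
    gaps <- unique(paste0(windows$sequence[grid$widx[is.na(idx)]], " x ",
                          grid$allele[is.na(idx)]))
    stop("missing binding calls for ", length(gaps), " window-allele pair(s): ",
         paste(utils::head(gaps, 5L), collapse = "; "),
         if (length(gaps) > 5L) " ...", call. = FALSE)
  }
  ic50 <- calls$ic50_nM[idx]
  ord <- order(ic50, windows$length[grid$widx], windows$start[grid$widx],
               match(grid$allele, allele_names))
  best <- ord[1L]
  w <- grid$widx[best]
  list(ic50_nM = ic50[best], peptide = windows$sequence[w],
       allele = grid$allele[best], start = windows$start[w],
       length = windows$length[w])
}

#' Classify a predicted affinity against a threshold
#'
#' Strict inequality: a peptide binds iff `ic50_nM < threshold_nM`, so
#' boundary values are non-binders. Conventional thresholds are 100 nM
#' (high affinity), 500 nM (intermediate), and 1500 nM (relaxed, as used to
#' admit candidates to a vaccine panel).
#'
#' @param ic50_nM Predicted affinity (nM); vectorized.
#' @param threshold_nM Positive threshold (nM).
#' @return Logical vector: TRUE where the peptide is called a binder.
#' @examples
#' classify_binder(c(103, 1160, 1500), 1500)  # TRUE TRUE FALSE
#' @export
classify_binder <- function(ic50_nM, threshold_nM) {
  if (length(threshold_nM) != 1L || is.na(threshold_nM) || threshold_nM <= 0) {
    stop("threshold_nM must be a single positive number", call. = FALSE)
  }
  if (any(ic50_nM <= 0)) stop("ic50_nM must be positive", call. = FALSE)
  ic50_nM < threshold_nM
}
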