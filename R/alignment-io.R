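#' Construct a marker alignment
#'
#' Validates and uppercases a set of aligned DNA sequences for one locus.
#' Sequences must be equal length, taxa unique, alphabet restricted to
#' A/C/G/T/N/-.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param locus Locus name.
#' @return Object of class `marker_alignment` with fields `locus`, `taxa`,
#'   `seqs`.
#' @export
marker_alignment <- function(seqs, locus = "locus") {
  if (!is.character(seqs) || length(seqs) == 0) {
    abort("`seqs` must be a non-empty named character vector.")
  }
  taxa <- names(seqs)
  if (is.null(taxa) || any(taxa == "")) abort("Every sequence needs a taxon name.")
  if (anyDuplicated(taxa)) {
    abort(sprintf("Duplicate taxon name(s): %s",
                  paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (any(lens != lens[1])) {
    bad <- taxa[lens != lens[1]][1]
    abort(sprintf(
      "Ragged alignment: '%s' has length %d, expected %d.",
      bad, nchar(seqs[[bad]]), lens[1]
    ))
  }
  if (lens[1] < 1) abort("Alignment length must be >= 1.")
  found <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(found, c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    abort(sprintf("Invalid alignment characters: %s", paste(bad, collapse = " ")))
  }
  structure(list(locus = locus, taxa = taxa, seqs = seqs),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> locus %s: %d taxa x %d sites\n",
              x$locus, length(x$taxa), nchar(x$seqs[[1]])))
  invisible(x)
}

# character matrix, rows = taxa
seq_matrix <- function(aln) {
  stopifnot(inherits(aln, "marker_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$taxa
  m
}

#' Read an aligned multi-FASTA file
#'
#' Preserves record order, uppercases and validates that all records have
#' equal length (the input contract is a pre-computed alignment).
#'
#' @param path FASTA file path.
#' @param locus Locus name; defaults to the file name without extension.
#' @return A `marker_alignment`.
#' @export
read_alignment_fasta <- function(path, locus = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0) {
    abort(sprintf("Empty FASTA file: %s", path))
  }
  seqs <- vapply(as.character(recs), function(x) paste(x, collapse = ""), character(1))
  locus <- locus %||% sub("\\.[^.]*$", "", basename(path))
  marker_alignment(setNames(seqs, names(recs)), locus = locus)
}

#' Write a marker alignment as FASTA
#'
#' @param aln A `marker_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "marker_alignment"))
  lines <- as.vector(rbind(paste0(">", aln$taxa), aln$seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Concatenate marker alignments over a shared taxon set
#'
#' @param alignments List of `marker_alignment` objects with identical taxon
#'   sets (order may differ; the first alignment's order wins).
#' @param locus Name for the concatenated locus; default joins the input
#'   locus names with "_".
#' @return A `marker_alignment` whose length is the sum of input lengths.
#' @export
#' @examples
#' a <- marker_alignment(c(A = "ACGT", B = "ACGA"), locus = "ITS")
#' b <- marker_alignment(c(B = "GG", A = "GT"), locus = "LSU")
#' concatenate_alignments(list(a, b))
concatenate_alignments <- function(alignments, locus = NULL) {
  if (length(alignments) == 0) abort("Nothing to concatenate.")
  for (a in alignments) stopifnot(inherits(a, "marker_alignment"))
  taxa <- alignments[[1]]$taxa
  for (a in alignments[-1]) {
    if (!setequal(a$taxa, taxa)) {
      only_a <- setdiff(a$taxa, taxa); only_1 <- setdiff(taxa, a$taxa)
      abort(sprintf(
        "Taxon sets differ between '%s' and '%s' (only in former: %s; only in latter: %s).",
        a$locus, alignments[[1]]$locus,
        paste(only_a, collapse = ",") , paste(only_1, collapse = ",")
      ))
    }
  }
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a) a$seqs[[tx]], character(1)), collapse = "")
  }, character(1))
  locus <- locus %||% paste(vapply(alignments, `[[`, character(1), "locus"),
                            collapse = "_")
  marker_alignment(setNames(seqs, taxa), locus = locus)
}
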