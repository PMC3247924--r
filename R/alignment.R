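## Reading, encoding and filtering of protein multiple sequence alignments.

#' Read a protein multiple sequence alignment
#'
#' FASTA parsing is delegated to Biostrings; Stockholm files are parsed with
#' a small line-oriented reader (sequence lines only, `#` annotation and
#' `//` terminators skipped). Characters are upper-cased and both `.` and
#' `-` are normalized to the gap symbol `-`.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return A [ProteinMSA-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "AC-E"), fa)
#' readAlignment(fa)
#' @export
readAlignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) == 0L) stop("empty alignment file: ", path)
    ids <- names(seqs)
    strings <- as.character(seqs)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
    if (!length(lines)) stop("empty alignment file: ", path)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed Stockholm sequence line: ", lines[bad][1L])
    ids0 <- vapply(parts, `[[`, "", 1L)
    seq0 <- vapply(parts, `[[`, "", 2L)
    # interleaved blocks: concatenate per id, keeping first-seen order
    ids <- unique(ids0)
    strings <- vapply(ids, function(i) paste(seq0[ids0 == i], collapse = ""), "")
  }
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    off <- ids[which(lens != lens[1L])[1L]]
    stop("ragged alignment: sequence '", off, "' has length ",
         lens[lens != lens[1L]][1L], " but '", ids[1L], "' has ", lens[1L])
  }
  ProteinMSA(unname(strings), ids = ids)
}

#' Write an alignment to FASTA
#'
#' @param aln a [ProteinMSA-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "ProteinMSA"))
  strings <- apply(aln@chars, 1L, paste, collapse = "")
  x <- Biostrings::BStringSet(setNames(strings, aln@ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Encode an alignment as integers and one-hot indicators
#'
#' Amino acids map to 1..20 in alphabetical one-letter order and the gap to
#' 21 (see [aaAlphabet()]). Ambiguity codes (B, Z, X, U, O) and any other
#' unexpected character are collapsed onto the gap state with a warning.
#' The indicator matrix `M` replaces each alignment column by 21 binary
#' columns, exactly one of which is 1 in every row.
#'
#' @param aln a [ProteinMSA-class].
#' @return An [EncodedMSA-class].
#' @examples
#' enc <- encodeAlignment(ProteinMSA(c("AC-", "ACD")))
#' enc@A
#' @export
encodeAlignment <- function(aln) {
  stopifnot(is(aln, "ProteinMSA"))
  aa <- aaAlphabet()
  A <- matrix(match(aln@chars, aa), nrow(aln@chars), ncol(aln@chars))
  if (anyNA(A)) {
    bad <- unique(aln@chars[is.na(A)])
    warning("non-standard characters mapped to gap: ",
            paste(bad, collapse = " "))
    A[is.na(A)] <- .GAP
  }
  n <- nrow(A); p <- ncol(A)
  j <- as.vector(A) + rep((seq_len(p) - 1L) * .NSTATE, each = n)
  M <- Matrix::sparseMatrix(i = rep.int(seq_len(n), p), j = j, x = 1,
                            dims = c(n, .NSTATE * p))
  columnMap <- lapply(seq_len(p), function(i) ((i - 1L) * .NSTATE) + seq_len(.NSTATE))
  new("EncodedMSA", A = A, M = M, columnMap = columnMap, aaOrder = aa,
      columnLabels = aln@columnLabels)
}

#' Reconstruct alignment characters from integer codes
#'
#' @param enc an [EncodedMSA-class].
#' @return character matrix over [aaAlphabet()].
#' @export
decodeAlignment <- function(enc) {
  stopifnot(is(enc, "EncodedMSA"))
  matrix(enc@aaOrder[enc@A], nrow(enc@A), ncol(enc@A))
}

#' Remove gap-rich alignment columns
#'
#' Columns whose gap fraction strictly exceeds `cutoff` are dropped; the
#' surviving columns keep their original numbers in `columnLabels` so that
#' links can be reported against the unfiltered alignment or a structure.
#'
#' @param aln a [ProteinMSA-class].
#' @param cutoff maximum tolerated gap fraction (default 0.5).
#' @return A [ProteinMSA-class] restricted to the kept columns.
#' @examples
#' aln <- ProteinMSA(c("A-C", "A-C", "AAC"))
#' columnLabels(filterGapColumns(aln))
#' @export
filterGapColumns <- function(aln, cutoff = 0.5) {
  stopifnot(is(aln, "ProteinMSA"), cutoff >= 0, cutoff <= 1)
  gapFrac <- colMeans(aln@chars == "-")
  keep <- gapFrac <= cutoff
  if (!any(keep)) stop("all columns exceed the gap cutoff of ", cutoff)
  new("ProteinMSA", ids = aln@ids, chars = aln@chars[, keep, drop = FALSE],
      columnLabels = aln@columnLabels[keep],
      moleculeLabels = if (length(aln@moleculeLabels))
        aln@moleculeLabels[keep] else integer())
}

#' Mean and s.d. of pairwise sequence identity
#'
#' Identity of a sequence pair is the number of matching positions divided
#' by the number of positions where both sequences are non-gap; a pair with
#' no comparable positions has identity 0. The mean and standard deviation
#' are taken over all unordered pairs.
#'
#' @param aln a [ProteinMSA-class].
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' pairwiseIdentity(ProteinMSA(c("ACDE", "ACDE")))
#' @export
pairwiseIdentity <- function(aln) {
  stopifnot(is(aln, "ProteinMSA"))
  enc <- encodeAlignment(aln)
  nongap <- (enc@A != .GAP) * 1
  # matches between residue characters: inner product of the one-hot rows,
  # with the gap indicator columns removed
  gapCols <- .GAP + (seq_len(ncol(enc@A)) - 1L) * .NSTATE
  Mng <- enc@M[, -gapCols, drop = FALSE]
  matches <- as.matrix(Matrix::tcrossprod(Mng))
  comparable <- tcrossprod(nongap)
  ut <- upper.tri(matches)
  ident <- ifelse(comparable[ut] > 0, matches[ut] / comparable[ut], 0)
  c(mean = mean(ident),
    sd = if (length(ident) > 1L) stats::sd(ident) else 0)
}

#' Write the encoded matrices to TSV (debugging aid)
#'
#' @param enc an [EncodedMSA-class].
#' @param prefix output path prefix; writes `<prefix>.A.tsv` and
#'   `<prefix>.M.tsv`.
#' @return The two paths, invisibly.
#' @export
writeEncodedTSV <- function(enc, prefix) {
  pa <- paste0(prefix, ".A.tsv")
  pm <- paste0(prefix, ".M.tsv")
  write.table(enc@A, pa, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.matrix(enc@M), pm, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(pa, pm))
}
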