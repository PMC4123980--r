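# Sequence input/output and coding-sequence quality control.
#
# Sequences are plain upper-case character strings over {A,C,G,T, IUPAC
# ambiguity codes, N, -}; a dataset is a named character vector (names are
# specimen/marker ids, unique). Specimen metadata travels separately as a
# data.frame keyed by id.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

VALID_CHARS <- c(names(IUPAC_CODES), "-")

#' Read sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a named character vector of
#' upper-case DNA sequences. `U` is mapped to `T`. Ids are taken as the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty).
#' @details Malformed input (sequence data before the first header, an entry
#'   with no sequence lines, characters outside the IUPAC alphabet) raises an
#'   error naming the offending line. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("malformed FASTA: line ", idx[1], " precedes any '>' header")
  }
  grp <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste0,
                 character(1), collapse = "")
  out <- rep("", length(ids))
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  if (any(out == "")) {
    bad <- which(out == "")[1]
    stop("malformed FASTA: entry '", ids[bad], "' (line ",
         idx[which(is_hdr)[bad]], ") has no sequence")
  }
  out <- toupper(out)
  out <- gsub("U", "T", out, fixed = TRUE)
  bad_char <- grepl(paste0("[^", paste(VALID_CHARS, collapse = ""), "]"), out)
  if (any(bad_char)) {
    b <- which(bad_char)[1]
    stop("malformed FASTA: entry '", ids[b], "' contains characters outside ",
         "the IUPAC DNA alphabet")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated, UTF-8, with a header row. Column `id` is required; the
#' conventional columns are `marker`, `country`, `province`, `region`,
#' `host` and `species_label`.
#'
#' @param path Path to the TSV file.
#' @param required Character vector of columns that must be present.
#' @return A data.frame, one row per specimen record.
#' @export
read_metadata <- function(path, required = c("id", "marker")) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  md
}

#' Filter barcode-compliant sequences
#'
#' A sequence is barcode compliant when its count of unambiguous bases
#' (A/C/G/T) strictly exceeds `min_len`; ambiguity codes, N and gaps do not
#' count towards the length but are retained in the sequence.
#'
#' @param seqs Named character vector of sequences.
#' @param min_len Minimum length (strict `>`); default 500, the standard
#'   barcode-compliance bound for COI-5'.
#' @return List with elements `kept` and `dropped` (named character vectors);
#'   the two partition the input.
#' @export
filter_barcode_compliant <- function(seqs, min_len = 500L) {
  stopifnot(min_len >= 1L)
  n_acgt <- nchar(gsub("[^ACGT]", "", seqs))
  list(kept = seqs[n_acgt > min_len], dropped = seqs[n_acgt <= min_len])
}

#' The invertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map (NCBI translation table 5), as used for
#' mitochondrial COI; stops are TAA and TAG.
#'
#' @return Named character vector mapping the 64 codons to amino acids
#'   (`*` for stop).
#' @export
invert_mito_code <- function() {
  Biostrings::getGeneticCode("SGC4")
}

#' Screen a coding sequence for stop codons and gaps
#'
#' Mirrors the translate-and-inspect screen applied to barcode records:
#' a sequence fails if it contains any gap character or any internal stop
#' codon in the reading frame. Frame `"auto"` tries offsets 0, 1, 2 and keeps
#' the lowest offset with zero stops (with a warning if several qualify).
#'
#' @param seq A single sequence string.
#' @param genetic_code Codon table; default [invert_mito_code()].
#' @param frame_offset 0, 1, 2 or `"auto"`.
#' @return List with `pass` (logical), `frame` (offset used, or NA),
#'   `reasons` (character), and `stop_codons` (1-based codon indices within
#'   the chosen frame).
#' @export
translation_qc <- function(seq, genetic_code = invert_mito_code(),
                           frame_offset = "auto") {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  reasons <- character(0)
  if (grepl("-", seq, fixed = TRUE)) reasons <- c(reasons, "contains gap characters")
  stops_in_frame <- function(off) {
    s <- substring(seq, off + 1L)
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return(integer(0))
    codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    aa <- genetic_code[codons]
    unname(which(!is.na(aa) & aa == "*"))
  }
  if (identical(frame_offset, "auto")) {
    stops <- lapply(0:2, stops_in_frame)
    ok <- which(vapply(stops, length, 1L) == 0L)
    if (length(ok) == 0L) {
      frame <- NA_integer_
      stop_idx <- stops[[1]]
      reasons <- c(reasons, "internal stop codon(s) in every reading frame")
    } else {
      if (length(ok) > 1L)
        warning("multiple stop-free frames (", paste(ok - 1L, collapse = ", "),
                "); using the lowest offset")
      frame <- ok[1] - 1L
      stop_idx <- integer(0)
    }
  } else {
    stopifnot(frame_offset %in% 0:2)
    frame <- as.integer(frame_offset)
    stop_idx <- stops_in_frame(frame)
    if (length(stop_idx))
      reasons <- c(reasons, paste0("internal stop codon at codon position(s) ",
                                   paste(stop_idx, collapse = ", ")))
  }
  list(pass = length(reasons) == 0L, frame = frame,
       reasons = reasons, stop_codons = stop_idx)
}

#' Build a frame-anchored alignment matrix
#'
#' COI barcode fragments are indel-free coding sequences, so column homology
#' can be established without progressive alignment: each record is slid
#' ungapped against a reference (the longest record) to the offset maximising
#' base matches, and the alignment is trimmed to the window covered by every
#' record (or padded with N when `pad = TRUE`).
#'
#' @param seqs Named character vector of QC-passing, same-marker sequences.
#' @param frame_offset Codon phase of reference column 1 (0, 1, 2, or
#'   `"auto"` to take it from [translation_qc()] of the reference).
#' @param pad If `TRUE`, keep the union window and pad missing flanks with N;
#'   default `FALSE` trims to the intersection window.
#' @return A character matrix (rows = records, columns = sites) of single
#'   characters, with attributes `frame_offset` and class
#'   `"barcode_alignment"`. Row order follows the input.
#' @export
build_alignment <- function(seqs, frame_offset = "auto", pad = FALSE) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  lens <- nchar(seqs)
  ref_i <- which.max(lens)
  ref <- charvec(seqs[[ref_i]])
  offs <- vapply(seq_along(seqs), function(i) {
    if (i == ref_i) return(0L)
    best_shift(charvec(seqs[[i]]), ref)
  }, integer(1))
  # record i occupies reference coordinates (offs[i]+1) .. (offs[i]+lens[i])
  if (pad) {
    lo <- min(offs) + 1L
    hi <- max(offs + lens)
  } else {
    lo <- max(offs) + 1L
    hi <- min(offs + lens)
  }
  if (hi < lo) stop("records share no overlapping window")
  ncol_out <- hi - lo + 1L
  mat <- matrix("N", nrow = length(seqs), ncol = ncol_out,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    v <- charvec(seqs[[i]])
    src <- (lo - offs[i]):(hi - offs[i])
    ok <- src >= 1L & src <= lens[i]
    mat[i, ok] <- v[src[ok]]
  }
  ref_frame <- if (identical(frame_offset, "auto")) {
    qc <- suppressWarnings(translation_qc(seqs[[ref_i]]))
    if (is.na(qc$frame)) 0L else qc$frame
  } else as.integer(frame_offset)
  # phase of the first retained column, in 0:2
  attr(mat, "frame_offset") <- (ref_frame + lo - 1L) %% 3L
  class(mat) <- c("barcode_alignment", class(mat))
  mat
}

#' Coerce sequences or a matrix to an alignment matrix
#'
#' Equal-length sequences are split into a character matrix without any
#' shifting; used when the input is already aligned.
#'
#' @param x Named character vector of equal-length sequences, or a character
#'   matrix.
#' @param frame_offset Codon phase of column 1.
#' @return A `"barcode_alignment"` character matrix.
#' @export
as_alignment <- function(x, frame_offset = 0L) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    stopifnot(length(unique(nchar(x))) == 1L)
    mat <- do.call(rbind, lapply(x, charvec))
    rownames(mat) <- names(x)
  }
  attr(mat, "frame_offset") <- as.integer(frame_offset)
  class(mat) <- c("barcode_alignment", "matrix", "array")
  mat
}

#' Collapse an alignment matrix back to sequence strings
#'
#' @param aln A `"barcode_alignment"` matrix.
#' @return Named character vector of sequences.
#' @export
alignment_to_seqs <- function(aln) {
  setNames(apply(unclass(aln), 1L, paste0, collapse = ""), rownames(aln))
}

charvec <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Ungapped shift of `qry` against `ref` maximising exact base matches over
# the overlap; ties resolved towards the smallest |shift|, then the smaller
# shift. Returns the offset of qry position 1 in ref coordinates (may be
# negative when qry starts before ref).
best_shift <- function(qry, ref) {
  nq <- length(qry); nr <- length(ref)
  shifts <- (-(nq - 1L)):(nr - 1L)
  score <- vapply(shifts, function(sh) {
    i <- max(1L, sh + 1L):min(nr, sh + nq)
    sum(ref[i] == qry[i - sh] & ref[i] %in% c("A", "C", "G", "T"))
  }, numeric(1))
  cand <- which(score == max(score))
  cand <- cand[order(abs(shifts[cand]), shifts[cand])]
  as.integer(shifts[cand[1]])
}
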