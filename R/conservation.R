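## Conserved-charged-residue detection from a multiple alignment.

NEGATIVE_AA <- c("D", "E")
POSITIVE_AA <- c("R", "K")

#' Classify alignment columns by conserved charge
#'
#' Flags columns of a multiple protein alignment where every sequence
#' carries a residue of the same charge class: negative (Asp/Glu) or
#' positive (Arg/Lys; histidine optionally counted positive). Such columns
#' locate side chains whose charge, the property the long-range
#' electrostatics of catalysis cares about, is preserved across the family
#' even when the residue identity is not. Gaps and unknown residues always
#' break conservation.
#'
#' @param alignment a named character vector of equal-length aligned
#'   sequences, a data frame with columns `name` and `sequence`, or a
#'   `Biostrings::AAStringSet`.
#' @param histidine_positive count His in the positive class? Default
#'   `FALSE` (His is only partially protonated at physiological pH).
#' @param exact_identity additionally require a single residue identity,
#'   not just a shared charge class. Default `FALSE`.
#' @return a tibble of class `alignment_column_report`: `position`,
#'   `residues` (the column letters, in input order), `charge_class`
#'   (`"negative"`, `"positive"`, `"mixed"` or `"uncharged"`) and
#'   `conserved`.
#' @export
conserved_charged_columns <- function(alignment, histidine_positive = FALSE,
                                      exact_identity = FALSE) {
  seqs <- alignment_to_strings(alignment)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort("Ragged alignment: sequences differ in length.")
  }
  n <- lens[1]
  if (n == 0) abort("Empty alignment.")
  positive <- POSITIVE_AA
  if (histidine_positive) positive <- c(positive, "H")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  out <- vector("list", n)
  for (j in seq_len(n)) {
    letters_j <- mat[, j]
    is_neg <- letters_j %in% NEGATIVE_AA
    is_pos <- letters_j %in% positive
    has_charge <- is_neg | is_pos
    cls <- if (all(is_neg)) "negative"
      else if (all(is_pos)) "positive"
      else if (any(has_charge)) "mixed"
      else "uncharged"
    conserved <- cls %in% c("negative", "positive")
    if (conserved && exact_identity) conserved <- length(unique(letters_j)) == 1
    out[[j]] <- tibble(position = j,
                       residues = paste(letters_j, collapse = ""),
                       charge_class = cls, conserved = conserved)
  }
  rep <- dplyr::bind_rows(out)
  structure(rep, class = c("alignment_column_report", class(tibble())))
}

alignment_to_strings <- function(alignment) {
  if (is.data.frame(alignment)) {
    if (!all(c("name", "sequence") %in% names(alignment))) {
      abort("Alignment data frame needs columns `name` and `sequence`.")
    }
    return(setNames(as.character(alignment$sequence), alignment$name))
  }
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet")) {
    return(setNames(as.character(alignment), names(alignment)))
  }
  if (is.character(alignment)) return(alignment)
  abort("Unsupported alignment representation.")
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned (equal-length) protein FASTA file.
#' @return named character vector of sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    return(setNames(as.character(aa), sub("\\s.*$", "", names(aa))))
  }
  ## minimal fallback parser
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  names_out <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  setNames(unname(seqs), names_out)
}
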