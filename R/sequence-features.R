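#' All k-mer feature names over the 26-symbol alphabet
#'
#' @param k Word length (1, 2 or 3).
#' @param alphabet Symbol set (default: the 26-letter extended amino
#'   acid alphabet A-Z).
#' @return Character vector of the \code{26^k} k-mers in lexicographic
#'   order.
#' @export
kmer_feature_names <- function(k, alphabet = default_config()$alphabet) {
  stopifnot(k %in% 1:3)
  out <- alphabet
  for (i in seq_len(k - 1)) out <- as.vector(outer(out, alphabet, paste0))
  sort(out)
}

#' Overlapping k-mer frequencies of a protein sequence
#'
#' Counts all overlapping windows of length \code{k} and normalises by
#' the window count \code{L - k + 1}. With \code{dense = TRUE} the full
#' \code{26^k}-dimensional vector is returned with absent k-mers as 0;
#' otherwise only observed k-mers are reported.
#'
#' @param sequence One-letter amino acid string over the 26-symbol
#'   alphabet (each chain is an independent unit; k-mers never span
#'   chains).
#' @param k Word length in \{1, 2, 3\}.
#' @param dense Return the full dense vector (default FALSE).
#' @param alphabet Symbol set.
#' @return Named numeric vector of frequencies summing to 1 (all-zero
#'   with a warning when the sequence is shorter than \code{k}).
#' @export
kmer_frequencies <- function(sequence, k, dense = FALSE,
                             alphabet = default_config()$alphabet) {
  stopifnot(k %in% 1:3, is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    stop("sequence contains symbols outside the alphabet: ",
         paste(bad, collapse = ", "))
  }
  L <- length(chars)
  if (L < k) {
    warning("sequence shorter than k = ", k, "; returning all-zero vector")
    out <- if (dense) {
      stats::setNames(numeric(length(alphabet)^k), kmer_feature_names(k, alphabet))
    } else {
      stats::setNames(numeric(0), character(0))
    }
    return(out)
  }
  n_win <- L - k + 1
  words <- substring(sequence, seq_len(n_win), seq_len(n_win) + k - 1)
  tab <- table(words)
  freqs <- as.numeric(tab) / n_win
  names(freqs) <- names(tab)
  if (dense) {
    all_names <- kmer_feature_names(k, alphabet)
    out <- stats::setNames(numeric(length(all_names)), all_names)
    out[names(freqs)] <- freqs
    out
  } else {
    freqs[order(names(freqs))]
  }
}

#' Side-chain chemical-class (CPAASC) frequencies
#'
#' Assigns every residue to exactly one of 8 mutually exclusive
#' side-chain chemistry classes -- aliphatic apolar, aromatic, polar
#' uncharged, positively charged, negatively charged, sulfur-containing,
#' hydroxyl-containing, and special (Gly/Pro) -- and returns the class
#' frequencies (class count / sequence length). Symbols outside the
#' class map fall into the configured fallback class with a warning.
#'
#' @param sequence One-letter amino acid string.
#' @param config Configuration list carrying the class map.
#' @return Named numeric vector of length 8 summing to 1.
#' @export
cpaasc_frequencies <- function(sequence, config = default_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  chars <- strsplit(toupper(sequence), "")[[1]]
  classes <- config$cpaasc_classes
  lookup <- stats::setNames(rep(names(classes), lengths(classes)),
                            unlist(classes))
  cls <- lookup[chars]
  if (anyNA(cls)) {
    warning("symbols without a side-chain class (",
            paste(unique(chars[is.na(cls)]), collapse = ", "),
            ") counted as ", config$cpaasc_fallback)
    cls[is.na(cls)] <- config$cpaasc_fallback
  }
  counts <- table(factor(cls, levels = names(classes)))
  out <- as.numeric(counts) / length(chars)
  names(out) <- names(classes)
  out
}

#' CPAASC feature names, in export order
#' @return Character vector of length 8.
#' @export
cpaasc_feature_names <- function() names(.cpaasc_classes)

#' Read sequences from a FASTA file
#'
#' Sequence-only entry point for the compositional features when no
#' structure is available.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not FASTA format: ", path)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  toupper(gsub("[ \t]", "", seqs))
}
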