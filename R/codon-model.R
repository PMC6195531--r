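#' Canonical codon alphabet
#'
#' The 64 DNA codons in canonical alphabetical order (AAA ... TTT). This
#' ordering defines the column layout of every frequency matrix and output
#' table produced by the package, so results from different stages can be
#' joined positionally as well as by codon name.
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' head(codon_alphabet())
codon_alphabet <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
}

# cached copies used internally; alphabetical order throughout
.CODONS <- NULL
.CODON_TO_AA <- NULL

.codons <- function() {
  if (is.null(.CODONS)) {
    utils::assignInMyNamespace(".CODONS", codon_alphabet())
  }
  .CODONS
}

#' Standard genetic code as a codon -> amino acid map
#'
#' Translation table 1: 61 sense codons mapping to the 20 amino acids
#' (one-letter symbols) and the three stop codons (TAA, TAG, TGA) mapping
#' to \code{"*"}. Codons are in canonical alphabetical order.
#'
#' @return Named character vector of length 64 (names are codons).
#' @export
#' @examples
#' genetic_code()[c("ATG", "AGG", "TAA")]
genetic_code <- function() {
  if (is.null(.CODON_TO_AA)) {
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace(".CODON_TO_AA", gc[.codons()])
  }
  .CODON_TO_AA
}

#' Synonymous codon families
#'
#' Partition of the 64 codons into the 20 amino-acid families plus the stop
#' family (\code{"*"}). Families are disjoint and cover all 64 codons; e.g.
#' the arginine family is \{CGT, CGC, CGA, CGG, AGA, AGG\} and the glutamine
#' family is \{CAA, CAG\}.
#'
#' @return Named list: amino-acid symbol -> character vector of codons.
#' @export
#' @examples
#' codon_families()[["R"]]
codon_families <- function() {
  gc <- genetic_code()
  split(names(gc), unname(gc))
}

#' Clean a raw CDS and cut it into frame-0 codons
#'
#' Whitespace is stripped, the sequence uppercased and RNA \code{U}
#' converted to \code{T}. The sequence is then chunked into consecutive
#' triplets starting at the first base (full-length CDS are assumed to be
#' in frame); 1-2 trailing leftover bases are dropped with a warning.
#' Codons containing any character outside \{A,C,G,T\} (e.g. \code{N}) are
#' by default excluded from the returned list with a warning; in
#' \code{"strict"} mode the whole record is rejected.
#'
#' @param raw_sequence Single nucleotide string.
#' @param policy \code{"exclude"} (default) drops ambiguous codons;
#'   \code{"strict"} errors on any ambiguous codon.
#' @param id Optional record id used in messages.
#' @return Character vector of valid codons.
#' @export
#' @examples
#' clean_and_frame("atgagGcaa")
clean_and_frame <- function(raw_sequence, policy = c("exclude", "strict"),
                            id = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw_sequence), length(raw_sequence) == 1)
  who <- if (is.null(id)) "sequence" else sprintf("record '%s'", id)
  s <- toupper(gsub("\\s", "", raw_sequence))
  s <- chartr("U", "T", s)
  if (!nzchar(s)) {
    stop(sprintf("%s is empty after whitespace removal", who), call. = FALSE)
  }
  n <- nchar(s)
  rem <- n %% 3
  if (rem > 0) {
    warning(sprintf("%s: %d trailing base(s) dropped (length %d not a multiple of 3)",
                    who, rem, n), call. = FALSE)
    s <- substr(s, 1, n - rem)
  }
  if (!nzchar(s)) stop(sprintf("%s has no complete codon", who), call. = FALSE)
  starts <- seq(1, nchar(s), by = 3)
  cods <- substring(s, starts, starts + 2)
  ok <- !grepl("[^ACGT]", cods)
  if (!all(ok)) {
    if (policy == "strict") {
      stop(sprintf("%s contains %d ambiguous codon(s) (strict mode)",
                   who, sum(!ok)), call. = FALSE)
    }
    warning(sprintf("%s: %d ambiguous codon(s) excluded from counting",
                    who, sum(!ok)), call. = FALSE)
    cods <- cods[ok]
  }
  if (length(cods) == 0) {
    stop(sprintf("%s has no valid codons after cleaning", who), call. = FALSE)
  }
  cods
}

#' Count codons into a 64-dimensional frequency vector
#'
#' Counts every codon of a cleaned CDS over the full 64-codon alphabet
#' (canonical alphabetical order; zeros allowed, stop codons included) and
#' converts counts to percentages of the total codons counted.
#'
#' @param codons Character vector of codons, e.g. from
#'   \code{\link{clean_and_frame}}.
#' @return Object of class \code{codon_freq}: list with \code{counts}
#'   (named integer, length 64), \code{percentages} (named numeric, sums
#'   to 100) and \code{total_codons}.
#' @export
#' @examples
#' count_codons(c("ATG", "AGG", "CAA"))$percentages[c("ATG", "AGG", "CAA")]
count_codons <- function(codons) {
  if (length(codons) == 0) stop("empty codon list", call. = FALSE)
  idx <- match(codons, .codons())
  if (anyNA(idx)) {
    stop(sprintf("invalid codon(s): %s",
                 paste(unique(codons[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  counts <- tabulate(idx, nbins = 64L)
  names(counts) <- .codons()
  total <- length(codons)
  structure(
    list(counts = counts,
         percentages = 100 * counts / total,
         total_codons = total),
    class = "codon_freq"
  )
}

#' @export
print.codon_freq <- function(x, ...) {
  cat(sprintf("<codon_freq> %d codons; top used:\n", x$total_codons))
  top <- sort(x$percentages[x$counts > 0], decreasing = TRUE)
  print(utils::head(round(top, 3)))
  invisible(x)
}

#' Translate a codon list under the standard genetic code
#'
#' @param codons Character vector of valid codons.
#' @param stop_symbol Symbol used for stop codons (default \code{"*"}).
#' @return Single amino-acid string.
#' @export
#' @examples
#' translate_codons(c("ATG", "AGG", "TGG"))
translate_codons <- function(codons, stop_symbol = "*") {
  gc <- genetic_code()
  aa <- gc[codons]
  if (anyNA(aa)) {
    stop(sprintf("invalid codon(s): %s",
                 paste(unique(codons[is.na(aa)]), collapse = ", ")),
         call. = FALSE)
  }
  aa[aa == "*"] <- stop_symbol
  paste(aa, collapse = "")
}

#' Construct a CDS record
#'
#' A validated in-memory record holding a cleaned, frame-0 codon list next
#' to the raw input sequence.
#'
#' @param id Record identifier.
#' @param raw_sequence Raw nucleotide string.
#' @param class_label Optional class label (e.g. \code{"thermophile"}).
#' @param organism Optional organism name.
#' @param policy Cleaning policy, see \code{\link{clean_and_frame}}.
#' @return Object of class \code{cds_record}.
#' @export
cds_record <- function(id, raw_sequence, class_label = NA_character_,
                       organism = NA_character_,
                       policy = c("exclude", "strict")) {
  policy <- match.arg(policy)
  codons <- clean_and_frame(raw_sequence, policy = policy, id = id)
  structure(
    list(id = id, raw_sequence = raw_sequence, codons = codons,
         class_label = class_label, organism = organism),
    class = "cds_record"
  )
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s: %d codons%s\n", x$id, length(x$codons),
              if (is.na(x$class_label)) "" else paste0(" [", x$class_label, "]")))
  invisible(x)
}
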