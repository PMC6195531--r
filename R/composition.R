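#' AT- or GC-richness of codons
#'
#' A codon is AT-rich when at least two of its three bases are A or T, and
#' GC-rich otherwise; because base counts sum to 3 the two labels are
#' mutually exclusive and exhaustive (32 of the 64 codons are AT-rich).
#'
#' @param codons Character vector of codons.
#' @return Character vector of \code{"AT_RICH"} / \code{"GC_RICH"}.
#' @export
#' @examples
#' classify_richness(c("CAA", "AGG"))
classify_richness <- function(codons) {
  .check_codons(codons)
  at <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("A", "T")),
               integer(1))
  ifelse(at >= 2, "AT_RICH", "GC_RICH")
}

#' A/T- or G/C-ending of codons (wobble position)
#'
#' Determined solely by the third (wobble) base: A or T gives
#' \code{"AT_END"}, G or C gives \code{"GC_END"}.
#'
#' @param codons Character vector of codons.
#' @return Character vector of \code{"AT_END"} / \code{"GC_END"}.
#' @export
#' @examples
#' classify_ending(c("CAA", "AGG"))
classify_ending <- function(codons) {
  .check_codons(codons)
  third <- substr(codons, 3, 3)
  ifelse(third %in% c("A", "T"), "AT_END", "GC_END")
}

.check_codons <- function(codons) {
  bad <- setdiff(codons, .codons())
  if (length(bad) > 0) {
    stop(sprintf("invalid codon(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Nucleotide-composition summary of a preferred codon set
#'
#' Percentages of AT-rich vs GC-rich codons and of A/T-ending vs
#' G/C-ending codons over a set of preferred codons (typically the
#' positive contributors of an abundance analysis), each pair of
#' percentages summing to 100.
#'
#' @param preferred Non-empty character vector of codons.
#' @return Object of class \code{composition_summary}: list with
#'   \code{preferred_set}, \code{n}, \code{pct_at_rich},
#'   \code{pct_gc_rich}, \code{pct_at_end}, \code{pct_gc_end}.
#' @export
#' @examples
#' composition_summary(c("AGG", "GAC", "CAA", "TTT"))
composition_summary <- function(preferred) {
  preferred <- unique(as.character(preferred))
  if (length(preferred) == 0) {
    stop("preferred codon set is empty", call. = FALSE)
  }
  .check_codons(preferred)
  rich <- classify_richness(preferred)
  endn <- classify_ending(preferred)
  structure(
    list(preferred_set = preferred,
         n = length(preferred),
         pct_at_rich = 100 * mean(rich == "AT_RICH"),
         pct_gc_rich = 100 * mean(rich == "GC_RICH"),
         pct_at_end = 100 * mean(endn == "AT_END"),
         pct_gc_end = 100 * mean(endn == "GC_END")),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> %d preferred codons\n", x$n))
  cat(sprintf("  AT-rich %.1f%% / GC-rich %.1f%%; A/T-ending %.1f%% / G/C-ending %.1f%%\n",
              x$pct_at_rich, x$pct_gc_rich, x$pct_at_end, x$pct_gc_end))
  invisible(x)
}

#' The six extremophile classes of the comparative design
#'
#' @return Character vector of canonical class names.
#' @export
extremophile_classes <- function() {
  c("thermophile", "psychrophile", "acidophile",
    "alkaliphile", "halophile", "barophile")
}

#' Cross-class codon harmony table
#'
#' Tabulates, over all 64 codons, membership in the preferred
#' (positively contributing) codon set of each extremophile class, the
#' number of classes sharing each codon, and the codons never preferred by
#' any class.
#'
#' @param preferred_by_class Named list mapping class name -> character
#'   vector of preferred codons. Names must come from \code{classes}.
#' @param classes Allowed class names (default the six canonical
#'   extremophile classes).
#' @return Object of class \code{harmony_table}: data.frame with 64 rows
#'   (one per codon), one logical column per class, and
#'   \code{shared_count}; attribute \code{never_preferred}.
#' @export
harmony_table <- function(preferred_by_class,
                          classes = extremophile_classes()) {
  if (length(preferred_by_class) == 0 || is.null(names(preferred_by_class)) ||
      any(!nzchar(names(preferred_by_class)))) {
    stop("preferred_by_class must be a non-empty named list", call. = FALSE)
  }
  unknown <- setdiff(names(preferred_by_class), classes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown class label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(names(preferred_by_class))) {
    stop("duplicate class labels", call. = FALSE)
  }
  for (s in preferred_by_class) .check_codons(s)
  member <- vapply(preferred_by_class, function(s) .codons() %in% s,
                   logical(64))
  member <- matrix(member, nrow = 64,
                   dimnames = list(.codons(), names(preferred_by_class)))
  shared <- rowSums(member)
  df <- data.frame(codon = .codons(), member, shared_count = shared,
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  structure(df,
            never_preferred = .codons()[shared == 0],
            class = c("harmony_table", "data.frame"))
}

#' Codons preferred by no class
#'
#' @param harmony A \code{harmony_table}.
#' @return Character vector of codons with zero shared count.
#' @export
never_preferred <- function(harmony) {
  stopifnot(inherits(harmony, "harmony_table"))
  attr(harmony, "never_preferred")
}

#' @export
print.harmony_table <- function(x, ...) {
  k <- ncol(x) - 2L
  cat(sprintf("<harmony_table> 64 codons x %d classes; %d codons never preferred\n",
              k, length(attr(x, "never_preferred"))))
  top <- x[order(-x$shared_count), c("codon", "shared_count")]
  print(utils::head(top, 6), row.names = FALSE)
  invisible(x)
}
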