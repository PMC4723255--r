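#' A restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition sequence over \code{A,C,G,T}.
#' @param cut_offset 0-based position of the cut within the recognition
#'   sequence (0 = before the first base).
#' @return An object of class \code{restriction_enzyme}.
#' @examples
#' re_taqai()  # TaqaI cuts T/CGA
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition))
    stop_rm("recognition sequence must be non-empty over A,C,G,T")
  cut_offset <- as.integer(cut_offset)
  stopifnot(cut_offset >= 0, cut_offset <= nchar(recognition))
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' TaqaI preset (T/CGA)
#' @rdname restriction_enzyme
#' @export
re_taqai <- function() restriction_enzyme("TaqaI", "TCGA", 1L)

as_dna <- function(seq) {
  if (is(seq, "DNAString")) seq else Biostrings::DNAString(toupper(seq))
}

#' Locate restriction cut positions on a sequence
#'
#' Scans the forward strand for every (possibly overlapping) occurrence
#' of the recognition sequence; occurrences containing N are not
#' matched. For palindromic sites such as TaqaI's TCGA this is strand
#' complete.
#'
#' @param seq DNA sequence: character string or \code{DNAString}.
#' @param enzyme a [restriction_enzyme()].
#' @return Ascending integer vector of 0-based cut coordinates (the
#'   position of the base immediately after the cut).
#' @examples
#' find_sites("AATCGAAA", re_taqai())  # 3
#' find_sites("TCGATCGA", re_taqai())  # 1 5
#' @export
find_sites <- function(seq, enzyme = re_taqai()) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  m <- Biostrings::matchPattern(enzyme$recognition, as_dna(seq), fixed = TRUE)
  sort(BiocGenerics::start(m) - 1L + enzyme$cut_offset)
}

#' Fragment lengths from an in-silico digestion
#'
#' Internal fragments run between consecutive cut positions. The two
#' chromosome-terminal pieces (start to first cut, last cut to end) are
#' excluded by default because they carry only one ligatable cut end;
#' set \code{include_terminal = TRUE} to keep them.
#'
#' @inheritParams find_sites
#' @param include_terminal include the two terminal pieces?
#' @return Integer vector of fragment lengths (empty when there are
#'   fewer than 2 cut sites and \code{include_terminal} is FALSE).
#' @export
digest_fragments <- function(seq, enzyme = re_taqai(),
                             include_terminal = FALSE) {
  seq <- as_dna(seq)
  cuts <- find_sites(seq, enzyme)
  internal <- if (length(cuts) >= 2) diff(cuts) else integer(0)
  if (!include_terminal) return(internal)
  n <- length(seq)
  if (length(cuts) == 0) return(n)
  c(cuts[1L], internal, n - cuts[length(cuts)])
}

#' Summarize an in-silico genome digestion
#'
#' Per-chromosome recognition-site counts and fragment-length
#' distributions, plus the count of fragments whose length falls in
#' \code{[window_lo, window_hi]} (bounds inclusive by default) - the
#' expected RAD tag yield for a size-selection window.
#'
#' @param genome path to a (multi-)FASTA file, or a \code{DNAStringSet}.
#' @param enzyme a [restriction_enzyme()].
#' @param window_lo,window_hi size-selection window in bp.
#' @param include_terminal count chromosome-terminal pieces? See
#'   [digest_fragments()].
#' @param inclusive treat the window bounds as inclusive (default) or
#'   strict.
#' @return An object of class \code{digest_summary}: a list with
#'   \code{per_chrom} (data.frame: chrom, n_sites, n_fragments,
#'   n_in_window), \code{fragment_lengths} (named list per chromosome),
#'   \code{n_in_window}, \code{window} and the conventions used.
#' @export
summarize_digest <- function(genome, enzyme = re_taqai(),
                             window_lo = 400, window_hi = 600,
                             include_terminal = FALSE, inclusive = TRUE) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop_rm("genome FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  stopifnot(is(genome, "DNAStringSet"))
  if (length(genome) == 0) stop_rm("empty genome")
  names(genome) <- sub("\\s.*$", "", names(genome))

  lens <- lapply(seq_along(genome), function(i)
    digest_fragments(genome[[i]], enzyme, include_terminal))
  names(lens) <- names(genome)
  n_sites <- vapply(seq_along(genome), function(i)
    length(find_sites(genome[[i]], enzyme)), integer(1))
  in_win <- vapply(lens, function(x) {
    if (inclusive) sum(x >= window_lo & x <= window_hi)
    else sum(x > window_lo & x < window_hi)
  }, numeric(1))

  structure(list(
    per_chrom = data.frame(
      chrom = names(genome), n_sites = n_sites,
      n_fragments = lengths(lens), n_in_window = as.integer(in_win),
      stringsAsFactors = FALSE),
    fragment_lengths = lens,
    n_in_window = as.integer(sum(in_win)),
    window = c(lo = window_lo, hi = window_hi),
    include_terminal = include_terminal, inclusive = inclusive,
    enzyme = enzyme$name),
    class = "digest_summary")
}

#' @export
print.digest_summary <- function(x, ...) {
  cat("<digest_summary> enzyme ", x$enzyme, ", ",
      nrow(x$per_chrom), " sequences, ",
      sum(x$per_chrom$n_sites), " sites, ",
      x$n_in_window, " fragments in [", x$window["lo"], ",",
      x$window["hi"], "]\n", sep = "")
  invisible(x)
}

#' Check RAD tag yield against a target range
#'
#' @param summary a [summarize_digest()] result.
#' @param lo,hi inclusive bounds on the acceptable number of
#'   size-selected fragments (default 100,000-150,000).
#' @return \code{"PASS"} or \code{"FAIL"}.
#' @export
tag_yield_check <- function(summary, lo = 100000, hi = 150000) {
  stopifnot(inherits(summary, "digest_summary"))
  if (summary$n_in_window >= lo && summary$n_in_window <= hi) "PASS" else "FAIL"
}

#' Fragment counts under all terminal/bound conventions
#'
#' Computes the in-window fragment count under each combination of
#' terminal-fragment inclusion and inclusive/strict window bounds, for
#' comparing against an externally printed figure whose convention is
#' unknown.
#'
#' @inheritParams summarize_digest
#' @return data.frame with columns \code{include_terminal},
#'   \code{inclusive} and \code{n_in_window}.
#' @export
digest_convention_grid <- function(genome, enzyme = re_taqai(),
                                   window_lo = 400, window_hi = 600) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  grid <- expand.grid(include_terminal = c(FALSE, TRUE),
                      inclusive = c(TRUE, FALSE))
  grid$n_in_window <- vapply(seq_len(nrow(grid)), function(i)
    summarize_digest(genome, enzyme, window_lo, window_hi,
                     include_terminal = grid$include_terminal[i],
                     inclusive = grid$inclusive[i])$n_in_window,
    integer(1))
  grid
}

#' Write a digestion summary TSV
#'
#' @param summary a [summarize_digest()] result.
#' @param path output TSV path.
#' @param histogram_path optional path for the full per-length histogram.
#' @param binwidth histogram bin width in bp.
#' @return \code{path}, invisibly.
#' @export
write_digest_summary <- function(summary, path, histogram_path = NULL,
                                 binwidth = 10) {
  write.table(summary$per_chrom, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(histogram_path)) {
    all_len <- unlist(summary$fragment_lengths, use.names = FALSE)
    if (length(all_len)) {
      bin <- (all_len %/% binwidth) * binwidth
      h <- as.data.frame(table(bin), stringsAsFactors = FALSE)
      names(h) <- c("bin_start", "count")
      write.table(h, histogram_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      writeLines("bin_start\tcount", histogram_path)
    }
  }
  invisible(path)
}
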