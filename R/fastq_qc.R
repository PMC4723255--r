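#' A single sequencing read
#'
#' Container for one FASTQ record: identifier, bases and per-base Phred
#' quality scores. Bases and qualities must have equal length.
#'
#' @param read_id character identifier.
#' @param bases character string over \code{A,C,G,T,N} (case-insensitive).
#' @param quals integer vector of Phred scores, one per base, all >= 0.
#' @return An object of class \code{seq_read}.
#' @examples
#' seq_read("r1", "ACGT", c(30, 30, 30, 30))
#' @export
seq_read <- function(read_id, bases, quals) {
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop_rm("invalid record '", read_id, "': ", nchar(bases),
            " bases but ", length(quals), " quality values")
  if (length(quals) && any(quals < 0))
    stop_rm("invalid record '", read_id, "': negative quality score")
  structure(list(read_id = read_id, bases = toupper(bases), quals = quals),
            class = "seq_read")
}

#' @export
print.seq_read <- function(x, ...) {
  cat("<seq_read>", x$read_id, " (", nchar(x$bases), " bp)\n", sep = "")
  invisible(x)
}

#' Trim low-quality bases from both read ends
#'
#' Removes the terminal runs of bases whose quality is strictly below
#' \code{q}, scanning inward from the 5' end and from the 3' end.
#' Interior low-quality bases are never removed. May return an empty
#' read. Idempotent.
#'
#' @param read a [seq_read()].
#' @param q Phred threshold; bases with quality < \code{q} are trimmed
#'   from the ends (default 20).
#' @return The trimmed \code{seq_read} (identifier preserved).
#' @examples
#' r <- seq_read("r1", "AACCGGTT", c(10, 10, 30, 30, 30, 30, 10, 30))
#' trim_read(r, 20)$bases  # "CCGGTT": interior Q10 base kept
#' @export
trim_read <- function(read, q = 20) {
  stopifnot(inherits(read, "seq_read"))
  ok <- read$quals >= q
  if (!any(ok)) return(seq_read(read$read_id, "", integer(0)))
  i <- which(ok)
  from <- i[1L]; to <- i[length(i)]
  seq_read(read$read_id,
           substr(read$bases, from, to),
           read$quals[from:to])
}

#' Length check after trimming
#'
#' @param read a trimmed [seq_read()].
#' @param min_len minimum retained length in bases (default 50).
#' @return \code{TRUE} iff the read has at least \code{min_len} bases.
#' @export
passes_length <- function(read, min_len = 50) {
  stopifnot(inherits(read, "seq_read"))
  nchar(read$bases) >= min_len
}

.standards <- list(
  strict   = cbind(q = c(10, 13, 20), frac = c(0.07, 0.07, 0.15)),
  moderate = cbind(q = c(10, 13, 20), frac = c(0.10, 0.14, 0.20)),
  relax    = cbind(q = c(10, 13),     frac = c(0.15, 0.20)),
  none     = NULL
)

match_standard <- function(standard) {
  standard <- tolower(standard)
  if (standard %in% c("notfilter", "nofilter")) standard <- "none"
  match.arg(standard, names(.standards))
}

#' Classify a read under a filtering standard
#'
#' The four filtering standards discard a read when the fraction of its
#' bases below a quality cutoff exceeds a percentage (strict inequality
#' on both the fraction and the quality):
#' \describe{
#'   \item{strict}{> 7\% bases Q<10, or > 7\% Q<13, or > 15\% Q<20}
#'   \item{moderate}{> 10\% Q<10, or > 14\% Q<13, or > 20\% Q<20}
#'   \item{relax}{> 15\% Q<10, or > 20\% Q<13}
#'   \item{none}{keep everything}
#' }
#'
#' @param read a non-empty [seq_read()].
#' @param standard one of \code{"strict"}, \code{"moderate"},
#'   \code{"relax"}, \code{"none"}.
#' @return \code{"KEEP"} or \code{"DISCARD"}.
#' @export
classify_read <- function(read, standard = "relax") {
  stopifnot(inherits(read, "seq_read"))
  standard <- match_standard(standard)
  if (standard == "none") return("KEEP")
  n <- length(read$quals)
  if (n == 0L) stop_rm("classify_read: empty read '", read$read_id,
                       "' (fractions undefined)")
  tab <- .standards[[standard]]
  for (k in seq_len(nrow(tab))) {
    if (sum(read$quals < tab[k, "q"]) / n > tab[k, "frac"]) return("DISCARD")
  }
  "KEEP"
}

#' Filtering policy for FASTQ streams
#'
#' @param standard filtering standard, see [classify_read()].
#' @param trim_end_quality Phred threshold for end trimming (default 20).
#' @param min_length_after_trim minimum post-trim length (default 50).
#' @return An object of class \code{filter_policy}.
#' @export
filter_policy <- function(standard = "relax", trim_end_quality = 20,
                          min_length_after_trim = 50) {
  stopifnot(min_length_after_trim >= 1, trim_end_quality >= 0)
  structure(list(standard = match_standard(standard),
                 trim_end_quality = trim_end_quality,
                 min_length_after_trim = min_length_after_trim),
            class = "filter_policy")
}

#' Filter a FASTQ file
#'
#' Each read is end-trimmed at \code{trim_end_quality}, discarded if its
#' trimmed length is below \code{min_length_after_trim}, then classified
#' under the policy's standard. Retained reads are written in input
#' order.
#'
#' @param input path to a FASTQ file (gzip accepted).
#' @param output path for the filtered FASTQ, or \code{NULL} to skip
#'   writing.
#' @param policy a [filter_policy()].
#' @param quality_scoring \code{"phred"} (Phred+33, default),
#'   \code{"illumina"} (Phred+64) or \code{"solexa"}.
#' @param stats_path optional path for a two-line TSV with the counts.
#' @return Invisibly, a list with \code{stats} (named counts:
#'   \code{n_input}, \code{n_discarded_length},
#'   \code{n_discarded_quality}, \code{n_retained}) and \code{reads}
#'   (the retained reads as a list of [seq_read()]).
#' @export
filter_fastq <- function(input, output = NULL, policy = filter_policy(),
                         quality_scoring = "phred", stats_path = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  fq <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input,
      quality.scoring = quality_scoring)),
    error = function(e) stop_rm("malformed FASTQ '", input, "': ",
                                conditionMessage(e)))
  ids <- names(fq)
  qual_ints <- as(Biostrings::quality(fq), "IntegerList")
  seqs <- as.character(fq)
  n <- length(fq)

  kept <- vector("list", n)
  n_len <- 0L; n_qual <- 0L; n_keep <- 0L
  for (i in seq_len(n)) {
    r <- seq_read(ids[i] %||% paste0("read", i), seqs[i], qual_ints[[i]])
    r <- trim_read(r, policy$trim_end_quality)
    if (!passes_length(r, policy$min_length_after_trim)) {
      n_len <- n_len + 1L
      next
    }
    if (classify_read(r, policy$standard) == "DISCARD") {
      n_qual <- n_qual + 1L
      next
    }
    n_keep <- n_keep + 1L
    kept[[n_keep]] <- r
  }
  kept <- kept[seq_len(n_keep)]

  if (!is.null(output)) write_fastq(kept, output)
  stats <- c(n_input = n, n_discarded_length = n_len,
             n_discarded_quality = n_qual, n_retained = n_keep)
  if (!is.null(stats_path))
    write.table(data.frame(metric = names(stats), count = unname(stats)),
                stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(stats = stats, reads = kept))
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads list of [seq_read()].
#' @param path output path; \code{.gz} suffix enables compression.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    con <- file(path, "w"); close(con)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "bases"))
  names(dna) <- vapply(reads, `[[`, "", "read_id")
  quals <- Biostrings::PhredQuality(vapply(reads, function(r)
    if (length(r$quals)) intToUtf8(r$quals + 33L) else "", ""))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(dna, quals), path,
    compress = grepl("\\.gz$", path))
  invisible(path)
}
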