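#' Parse samtools pileup text
#'
#' Reads 6-column (or 5-column, quality-less) samtools pileup/mpileup
#' text and decodes the bases column into per-position allele
#' summaries. Reference matches (\code{.}/\code{,}), mismatches
#' (ACGT/acgt), insertions/deletions (\code{+n<seq>}/\code{-n<seq>},
#' attached to the preceding read observation), read starts
#' (\code{^} + mapping quality) and ends (\code{$}) follow the samtools
#' conventions; \code{*}, \code{>}, \code{<} and N observations are
#' counted as skipped.
#'
#' Depth conservation: for every line,
#' \code{n_ref + n_mismatch + n_skipped == depth}. Insertion/deletion
#' events ride on a read observation and do not consume depth; their
#' counts appear as alleles (\code{ins:SEQ} / \code{del:SEQ}) on top of
#' the base-level decomposition.
#'
#' @param input path to a pileup file (gzip accepted) or a character
#'   vector of pileup lines.
#' @param full also return the serialized per-line allele table
#'   (slower; used by [parse_pileup_line()]).
#' @param min_base_q if >= 0, base observations with Phred quality
#'   below this are masked as skipped (default: off; calling is
#'   count-based).
#' @return A data.frame with one row per line: \code{chrom},
#'   \code{pos}, \code{ref}, \code{depth}, \code{n_ref},
#'   \code{n_skipped}, \code{mut_allele} (dominant non-reference
#'   allele, \code{NA} if none), \code{mut_count}, \code{mut_ratio},
#'   \code{mut_total} (all non-reference evidence) and, when
#'   \code{full}, \code{alleles}.
#' @export
parse_pileup <- function(input, full = FALSE, min_base_q = -1L) {
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    dt <- data.table::fread(input, header = FALSE, sep = "\t", quote = "",
                            colClasses = "character", fill = TRUE)
  } else {
    if (length(input) == 0)
      return(empty_pileup_df(full))
    dt <- data.table::fread(text = input, header = FALSE, sep = "\t",
                            quote = "", colClasses = "character", fill = TRUE)
  }
  if (nrow(dt) == 0) return(empty_pileup_df(full))
  if (!ncol(dt) %in% c(5L, 6L))
    stop_rm("pileup parse error at line 1: expected 5 or 6 tab-separated ",
            "columns, found ", ncol(dt))
  bad_cols <- which(dt[[3]] == "" | is.na(dt[[5]]) | dt[[5]] == "")
  depth <- suppressWarnings(as.integer(dt[[4]]))
  zero <- !is.na(depth) & depth == 0L
  if (any(is.na(depth)))
    stop_rm("pileup parse error at line ", which(is.na(depth))[1],
            ": non-integer depth field")
  if (length(bad_cols) && !all(zero[bad_cols]))
    stop_rm("pileup parse error at line ",
            setdiff(bad_cols, which(zero))[1], ": missing column")

  quals <- if (ncol(dt) == 6L) dt[[6]] else character(0)
  bases <- dt[[5]]
  bases[zero] <- ""
  dec <- .decode_pileup_cpp(bases, dt[[3]],
                            if (length(quals)) quals else character(0),
                            as.integer(min_base_q), full)
  bad <- which(nzchar(dec$error))
  if (length(bad))
    stop_rm("pileup parse error at line ", bad[1], ": ", dec$error[bad[1]])
  mism <- which(dec$n_obs != depth & !zero)
  if (length(mism))
    stop_rm("pileup inconsistency at line ", mism[1], " (",
            dt[[1]][mism[1]], ":", dt[[2]][mism[1]], "): declared depth ",
            depth[mism[1]], " but decoded ", dec$n_obs[mism[1]],
            " observations")

  out <- data.frame(
    chrom = dt[[1]], pos = as.integer(dt[[2]]), ref = toupper(dt[[3]]),
    depth = depth, n_ref = dec$n_ref, n_skipped = dec$n_skipped,
    mut_allele = dec$mut_allele, mut_count = dec$mut_count,
    mut_ratio = ifelse(depth > 0, dec$mut_count / depth, 0),
    mut_total = dec$mut_total, stringsAsFactors = FALSE)
  if (full) out$alleles <- dec$alleles
  out
}

empty_pileup_df <- function(full = FALSE) {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), depth = integer(0),
                    n_ref = integer(0), n_skipped = integer(0),
                    mut_allele = character(0), mut_count = integer(0),
                    mut_ratio = numeric(0), mut_total = integer(0),
                    stringsAsFactors = FALSE)
  if (full) out$alleles <- character(0)
  out
}

#' Parse a single pileup line into a site summary
#'
#' @param line one pileup text line.
#' @return An object of class \code{pileup_site}: list with
#'   \code{chrom}, \code{pos}, \code{ref}, \code{depth}, \code{n_ref},
#'   \code{n_skipped}, \code{base_counts} (named integer vector over
#'   mismatch bases and \code{ins:SEQ}/\code{del:SEQ} alleles),
#'   \code{mut_allele}, \code{mut_count}, \code{mut_total}.
#' @examples
#' parse_pileup_line("chr1\t101\tA\t5\t.,GG,\tIIIII")
#' @export
parse_pileup_line <- function(line) {
  df <- parse_pileup(line, full = TRUE)
  if (nrow(df) != 1) stop_rm("expected exactly one pileup line")
  counts <- integer(0)
  if (nzchar(df$alleles)) {
    parts <- strsplit(strsplit(df$alleles, ";", fixed = TRUE)[[1]], "=",
                      fixed = TRUE)
    counts <- setNames(vapply(parts, function(p) as.integer(p[2]), 0L),
                       vapply(parts, `[[`, "", 1))
  }
  structure(list(chrom = df$chrom, pos = df$pos, ref = df$ref,
                 depth = df$depth, n_ref = df$n_ref,
                 n_skipped = df$n_skipped, base_counts = counts,
                 mut_allele = if (is.na(df$mut_allele)) NULL else df$mut_allele,
                 mut_count = df$mut_count, mut_total = df$mut_total),
            class = "pileup_site")
}

#' @export
print.pileup_site <- function(x, ...) {
  cat("<pileup_site> ", x$chrom, ":", x$pos, " ref=", x$ref,
      " depth=", x$depth, " n_ref=", x$n_ref,
      if (length(x$base_counts))
        paste0(" [", paste(names(x$base_counts), x$base_counts,
                           sep = ":", collapse = " "), "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Mutant ratio of a pileup site
#'
#' Fraction of reads carrying the dominant non-reference allele (SNP
#' base or specific indel sequence); 0 when the site has no mutant
#' observations. Ties between alleles are broken in favour of SNP bases
#' (A,C,G,T order) over indels, then lexicographically.
#'
#' @param site a [parse_pileup_line()] result, or one row of a
#'   [parse_pileup()] data.frame.
#' @return Numeric fraction between 0 and 1.
#' @export
site_mutant_ratio <- function(site) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    site <- as.list(site)
  }
  if (site$depth == 0) stop_rm("mutant ratio undefined at depth 0 (",
                               site$chrom, ":", site$pos, ")")
  site$mut_count / site$depth
}
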