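#' Calling thresholds
#'
#' A mutant site must be covered by at least \code{min_depth} reads, of
#' which at least \code{min_mut_reads} carry the mutant allele, with a
#' mutant ratio strictly above \code{min_mut_ratio} and at or above
#' \code{hetero_prop_level} (the minimum mutant proportion for a
#' candidate heterozygous call). Sites at or above
#' \code{homo_prop_level} are genotyped homozygous.
#'
#' @param min_depth minimum read depth (default 3).
#' @param min_mut_reads minimum mutant-allele reads (default 3, i.e.
#'   "more than 2").
#' @param min_mut_ratio exclusive mutant-ratio floor (default 0.20).
#' @param hetero_prop_level inclusive proportion bound for calling /
#'   HET genotyping (default 0.3).
#' @param homo_prop_level inclusive proportion bound for HOM genotyping
#'   (default 0.8; a pragmatic convention, not a pipeline constant).
#' @return An object of class \code{call_params}.
#' @export
call_params <- function(min_depth = 3, min_mut_reads = 3,
                        min_mut_ratio = 0.20, hetero_prop_level = 0.3,
                        homo_prop_level = 0.8) {
  stopifnot(min_mut_reads >= 1, min_depth >= 1,
            min_mut_ratio >= 0, min_mut_ratio < hetero_prop_level,
            hetero_prop_level <= homo_prop_level, homo_prop_level <= 1)
  structure(list(min_depth = min_depth, min_mut_reads = min_mut_reads,
                 min_mut_ratio = min_mut_ratio,
                 hetero_prop_level = hetero_prop_level,
                 homo_prop_level = homo_prop_level),
            class = "call_params")
}

call_decision <- function(depth, mut_count, p) {
  ratio <- ifelse(depth > 0, mut_count / depth, 0)
  depth >= p$min_depth & mut_count >= p$min_mut_reads &
    ratio > p$min_mut_ratio & ratio >= p$hetero_prop_level
}

#' Call a variant at one pileup site
#'
#' @param site a [parse_pileup_line()] result or single-row
#'   [parse_pileup()] data.frame.
#' @param p a [call_params()].
#' @return A single-row variant data.frame (see [call_variants()]) or
#'   \code{NULL} for no-call.
#' @export
call_site <- function(site, p = call_params()) {
  if (inherits(site, "pileup_site"))
    site <- data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                       depth = site$depth,
                       mut_allele = site$mut_allele %||% NA_character_,
                       mut_count = site$mut_count,
                       stringsAsFactors = FALSE)
  stopifnot(is.data.frame(site), nrow(site) == 1)
  if (is.na(site$mut_allele) || site$mut_count == 0) return(NULL)
  if (!call_decision(site$depth, site$mut_count, p)) return(NULL)
  variant_from_allele(site, p)
}

variant_from_allele <- function(df, p) {
  # df: chrom,pos,ref,depth,mut_allele,mut_count (>=1 rows, all callable)
  allele <- df$mut_allele
  ratio <- df$mut_count / df$depth
  vtype <- ifelse(startsWith(allele, "ins:"), "INS",
                  ifelse(startsWith(allele, "del:"), "DEL", "SNP"))
  seq <- sub("^(ins|del):", "", allele)
  ref <- toupper(df$ref)
  # VCF-style anchored alleles: insertion REF=R ALT=R+seq at the anchor
  # base; deletion REF=R+seq ALT=R (deleted bases follow the anchor)
  out_ref <- ifelse(vtype == "DEL", paste0(ref, seq), ref)
  out_alt <- ifelse(vtype == "INS", paste0(ref, seq),
                    ifelse(vtype == "DEL", ref, seq))
  data.frame(chrom = df$chrom, pos = df$pos, ref = out_ref, alt = out_alt,
             vtype = vtype, depth = df$depth, mut_reads = df$mut_count,
             mut_ratio = ratio,
             genotype = ifelse(ratio >= p$homo_prop_level, "HOM", "HET"),
             stringsAsFactors = FALSE)
}

check_sorted <- function(df, what = "pileup") {
  if (nrow(df) < 2) return(invisible(TRUE))
  new_chrom <- df$chrom != c(df$chrom[1], df$chrom[-nrow(df)])
  dpos <- c(1L, diff(df$pos))
  bad <- which(!new_chrom & dpos <= 0)
  # chromosomes must form contiguous blocks
  blocks <- rle(df$chrom)$values
  if (anyDuplicated(blocks))
    stop_rm("unsorted ", what, ": chromosome ",
            blocks[anyDuplicated(blocks)], " appears in multiple blocks")
  if (length(bad))
    stop_rm("unsorted ", what, " at ", df$chrom[bad[1]], ":",
            df$pos[bad[1]])
  invisible(TRUE)
}

#' Call variants across a parsed pileup
#'
#' Applies [call_site()]'s thresholds to every position of a sorted
#' pileup in one order-preserving pass.
#'
#' @param pileup a [parse_pileup()] data.frame (or a pileup file path),
#'   sorted by (chrom, pos).
#' @param p a [call_params()].
#' @return A variant data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{vtype} (SNP/INS/DEL), \code{depth},
#'   \code{mut_reads}, \code{mut_ratio}, \code{genotype} (HET/HOM).
#' @export
call_variants <- function(pileup, p = call_params()) {
  if (is.character(pileup)) pileup <- parse_pileup(pileup)
  check_sorted(pileup)
  keep <- !is.na(pileup$mut_allele) &
    call_decision(pileup$depth, pileup$mut_count, p)
  if (!any(keep)) return(empty_variant_df())
  variant_from_allele(pileup[keep, , drop = FALSE], p)
}

empty_variant_df <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vtype = character(0), depth = integer(0),
             mut_reads = integer(0), mut_ratio = numeric(0),
             genotype = character(0), stringsAsFactors = FALSE)
}

#' Write / read SnpInfo TSV
#'
#' Plain tab-separated per-variant output with a fixed header (chrom,
#' pos, ref, alt, vtype, depth, mut_reads, mut_ratio, genotype); round
#' trips losslessly.
#'
#' @param calls a [call_variants()] data.frame.
#' @param path file path.
#' @return \code{path} (write) or the calls data.frame (read).
#' @export
write_snpinfo <- function(calls, path) {
  stopifnot(all(snpinfo_cols %in% names(calls)))
  df <- calls[, snpinfo_cols, drop = FALSE]
  df$mut_ratio <- sprintf("%.10g", df$mut_ratio)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snpinfo
#' @export
read_snpinfo <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character"))
  rownames(df) <- NULL
  df
}

#' Export variant calls as minimal VCF 4.2
#'
#' @param calls a [call_variants()] data.frame.
#' @param path output path.
#' @param sample sample name for the single genotype column.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=MR,Number=1,Type=Integer,Description=\"Mutant reads\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  rows <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          sprintf("DP=%d;MR=%d", calls$depth, calls$mut_reads), "GT",
          ifelse(calls$genotype == "HOM", "1/1", "0/1"), sep = "\t")
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
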