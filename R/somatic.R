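#' Two-sample marker detection parameters
#'
#' Treat-side sites must pass the [call_params()] thresholds; the same
#' position in the control sample must be covered by at least
#' \code{control_min_depth} reads with fewer than
#' \code{control_max_mut_reads} mutant reads and a mutant ratio below
#' \code{control_max_mut_ratio} (all bounds exclusive on the mutant
#' side). Post-filters then require treat depth of at least
#' \code{post_min_treat_depth} with at most \code{post_max_control_mut}
#' mutant reads in the control, and eliminate every surviving marker
#' that lies within \code{min_spacing_bp} of another.
#'
#' @param control_min_depth minimum control coverage (default 10).
#' @param control_max_mut_reads exclusive bound on control mutant reads
#'   (default 2, i.e. "fewer than 2").
#' @param control_max_mut_ratio exclusive bound on control mutant ratio
#'   (default 0.04).
#' @param call a [call_params()] for the treat side.
#' @param post_min_treat_depth post-filter minimum treat depth
#'   (default 8).
#' @param post_max_control_mut post-filter maximum control mutant reads
#'   (default 0, "none in the other").
#' @param min_spacing_bp markers closer than this are all removed
#'   (default 10).
#' @return An object of class \code{somatic_params}.
#' @export
somatic_params <- function(control_min_depth = 10,
                           control_max_mut_reads = 2,
                           control_max_mut_ratio = 0.04,
                           call = call_params(),
                           post_min_treat_depth = 8,
                           post_max_control_mut = 0,
                           min_spacing_bp = 10) {
  stopifnot(control_min_depth >= 0, control_max_mut_reads >= 0,
            control_max_mut_ratio >= 0, min_spacing_bp >= 1,
            inherits(call, "call_params"))
  structure(list(control_min_depth = control_min_depth,
                 control_max_mut_reads = control_max_mut_reads,
                 control_max_mut_ratio = control_max_mut_ratio,
                 call = call,
                 post_min_treat_depth = post_min_treat_depth,
                 post_max_control_mut = post_max_control_mut,
                 min_spacing_bp = min_spacing_bp),
            class = "somatic_params")
}

#' Is a control-sample site clean reference?
#'
#' True iff the site is covered by at least \code{control_min_depth}
#' reads, carries fewer than \code{control_max_mut_reads} mutant reads
#' (any non-reference evidence: mismatches and indels), and its mutant
#' ratio is below \code{control_max_mut_ratio}.
#'
#' @param site a [parse_pileup_line()] result or rows of a
#'   [parse_pileup()] data.frame (vectorized).
#' @param p a [somatic_params()].
#' @return Logical (one per row).
#' @export
is_clean_control <- function(site, p = somatic_params()) {
  if (inherits(site, "pileup_site"))
    site <- data.frame(depth = site$depth, mut_total = site$mut_total)
  ratio <- ifelse(site$depth > 0, site$mut_total / site$depth, 0)
  site$depth >= p$control_min_depth &
    site$mut_total < p$control_max_mut_reads &
    ratio < p$control_max_mut_ratio
}

marker_cols <- c(snpinfo_cols, "direction", "control_depth",
                 "control_mut_reads")

empty_marker_df <- function() {
  cbind(empty_variant_df(),
        data.frame(direction = character(0), control_depth = integer(0),
                   control_mut_reads = integer(0), stringsAsFactors = FALSE))
}

#' One-direction treat-versus-control comparison
#'
#' Emits a marker for each position where the treat sample yields a
#' variant call and the control sample has a clean-reference site at
#' the same position. Positions absent from the control pileup are not
#' emitted (no evidence of clean coverage).
#'
#' @param treat,control [parse_pileup()] data.frames (or pileup file
#'   paths), sorted by (chrom, pos), against the same reference.
#' @param p a [somatic_params()].
#' @param direction label attached to emitted records.
#' @return A marker data.frame: SnpInfo columns plus \code{direction},
#'   \code{control_depth}, \code{control_mut_reads}.
#' @export
somatic_one_direction <- function(treat, control, p = somatic_params(),
                                  direction = "A_vs_B") {
  if (is.character(treat)) treat <- parse_pileup(treat)
  if (is.character(control)) control <- parse_pileup(control)
  check_sorted(treat, "treat pileup")
  check_sorted(control, "control pileup")
  if (nrow(treat) && nrow(control) &&
      !any(unique(treat$chrom) %in% unique(control$chrom)))
    stop_rm("no chromosome shared between treat (",
            paste(unique(treat$chrom), collapse = ","), ") and control (",
            paste(unique(control$chrom), collapse = ","), ") pileups")

  calls <- call_variants(treat, p$call)
  if (nrow(calls) == 0) return(empty_marker_df())

  ctl <- data.table::as.data.table(
    control[, c("chrom", "pos", "depth", "mut_total")])
  data.table::setnames(ctl, c("depth", "mut_total"),
                       c("control_depth", "control_mut_reads"))
  m <- data.table::as.data.table(calls)
  m <- merge(m, ctl, by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  has_ctl <- !is.na(m$control_depth)
  clean <- rep(FALSE, nrow(m))
  clean[has_ctl] <- is_clean_control(
    data.frame(depth = m$control_depth[has_ctl],
               mut_total = m$control_mut_reads[has_ctl]), p)
  m <- as.data.frame(m[clean, ])
  if (nrow(m) == 0) return(empty_marker_df())
  m$direction <- direction
  m[, marker_cols]
}

#' Bidirectional two-sample marker discovery
#'
#' Runs [somatic_one_direction()] with A as treat against B as control
#' and vice versa, tagging each record with its direction, and returns
#' the union sorted by (chrom, pos).
#'
#' @param pileup_a,pileup_b [parse_pileup()] data.frames or pileup file
#'   paths for the two samples.
#' @param p a [somatic_params()].
#' @return A marker data.frame (see [somatic_one_direction()]).
#' @export
somatic_bidirectional <- function(pileup_a, pileup_b, p = somatic_params()) {
  if (is.character(pileup_a)) pileup_a <- parse_pileup(pileup_a)
  if (is.character(pileup_b)) pileup_b <- parse_pileup(pileup_b)
  ab <- somatic_one_direction(pileup_a, pileup_b, p, "A_vs_B")
  ba <- somatic_one_direction(pileup_b, pileup_a, p, "B_vs_A")
  out <- rbind(ab, ba)
  out <- out[order(out$chrom, out$pos, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage and spacing post-filters
#'
#' Filter 1 keeps markers whose treat depth is at least
#' \code{post_min_treat_depth} and whose control mutant-read count is
#' at most \code{post_max_control_mut}. Filter 2 then eliminates, per
#' chromosome, every surviving marker that lies within
#' \code{min_spacing_bp} of another survivor - both members of a close
#' pair are removed, and chains of closely spaced markers are removed
#' entirely.
#'
#' @param markers a marker data.frame from [somatic_bidirectional()].
#' @param p a [somatic_params()].
#' @return The filtered marker data.frame (a subset of the input).
#' @export
apply_post_filters <- function(markers, p = somatic_params()) {
  if (nrow(markers) == 0) return(markers)
  m <- markers[markers$depth >= p$post_min_treat_depth &
                 markers$control_mut_reads <= p$post_max_control_mut, ,
               drop = FALSE]
  if (nrow(m) < 2) { rownames(m) <- NULL; return(m) }
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  keep <- logical(nrow(m))
  for (ch in unique(m$chrom)) {
    i <- which(m$chrom == ch)
    pos <- m$pos[i]
    gap_prev <- c(Inf, diff(pos))
    gap_next <- c(diff(pos), Inf)
    keep[i] <- gap_prev >= p$min_spacing_bp & gap_next >= p$min_spacing_bp
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a marker table TSV
#'
#' @param markers a marker data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_markers <- function(markers, path) {
  df <- markers[, intersect(c(marker_cols,
                              setdiff(names(markers), marker_cols)),
                            names(markers)), drop = FALSE]
  if ("mut_ratio" %in% names(df))
    df$mut_ratio <- sprintf("%.10g", df$mut_ratio)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", ref = "character",
                            alt = "character"))
}
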