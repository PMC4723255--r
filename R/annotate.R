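#' Annotation window parameters
#'
#' TSS and TTS regions are windows around the transcription start /
#' terminate sites, measured strand-aware (upstream and downstream
#' relative to the direction of transcription).
#'
#' @param tss_upstream,tss_downstream window around the TSS in bp
#'   (default 1000 each side).
#' @param tts_upstream,tts_downstream window around the TTS in bp
#'   (default 500 each side).
#' @return An object of class \code{annotation_params}.
#' @export
annotation_params <- function(tss_upstream = 1000, tss_downstream = 1000,
                              tts_upstream = 500, tts_downstream = 500) {
  stopifnot(tss_upstream >= 0, tss_downstream >= 0,
            tts_upstream >= 0, tts_downstream >= 0)
  structure(list(tss_upstream = tss_upstream,
                 tss_downstream = tss_downstream,
                 tts_upstream = tts_upstream,
                 tts_downstream = tts_downstream),
            class = "annotation_params")
}

#' Parse gene models from GFF3
#'
#' Builds one gene model per mRNA/transcript feature, collecting its
#' exon, CDS and UTR children through \code{Parent} attributes. The TSS
#' is the transcript 5' end respecting strand; the TTS is the 3' end.
#' GTF input is accepted as well (\code{transcript} features).
#'
#' @param path GFF3 (or GTF) file path.
#' @return An object of class \code{gene_models}: a named list of
#'   transcript models (\code{tx_id}, \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tx_start}, \code{tx_end}, \code{exons},
#'   \code{cds}, \code{utr5}, \code{utr3} as 2-column start/end
#'   matrices, \code{tss}, \code{tts}), ordered by (chrom, start,
#'   tx_id).
#' @export
parse_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop_rm("GFF parse error in '", path,
                                             "': ", conditionMessage(e)))
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr)))
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, "") else
    rep(NA_character_, length(gr))

  is_tx <- type %in% c("mRNA", "transcript")
  if (!any(is_tx)) return(structure(list(), class = "gene_models"))
  tx_idx <- which(is_tx)
  child_types <- c(exon = "exon", cds = "CDS",
                   utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  is_child <- type %in% child_types
  if (any(is_child & is.na(parents))) {
    i <- which(is_child & is.na(parents))[1]
    stop_rm("GFF parse error: ", type[i], " feature at ",
            as.character(GenomicRanges::seqnames(gr))[i], ":",
            BiocGenerics::start(gr)[i], " has no Parent attribute")
  }

  models <- lapply(tx_idx, function(i) {
    tid <- ids[i]
    if (is.na(tid)) stop_rm("GFF parse error: transcript without ID")
    kids <- which(parents == tid)
    ivals <- function(what) {
      j <- kids[type[kids] == child_types[[what]]]
      if (!length(j)) return(matrix(integer(0), ncol = 2,
                                    dimnames = list(NULL, c("start", "end"))))
      m <- cbind(start = BiocGenerics::start(gr)[j],
                 end = BiocGenerics::end(gr)[j])
      m[order(m[, "start"]), , drop = FALSE]
    }
    strand <- as.character(BiocGenerics::strand(gr))[i]
    s <- BiocGenerics::start(gr)[i]; e <- BiocGenerics::end(gr)[i]
    list(tx_id = tid, gene_id = parents[i] %||% tid,
         chrom = as.character(GenomicRanges::seqnames(gr))[i],
         strand = strand, tx_start = s, tx_end = e,
         exons = ivals("exon"), cds = ivals("cds"),
         utr5 = ivals("utr5"), utr3 = ivals("utr3"),
         tss = if (strand == "-") e else s,
         tts = if (strand == "-") s else e)
  })
  names(models) <- vapply(models, `[[`, "", "tx_id")
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0, "tx_start"),
               names(models))
  structure(models[ord], class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", length(x), " transcripts on ",
      length(unique(vapply(x, `[[`, "", "chrom"))), " sequences\n",
      sep = "")
  invisible(x)
}

region_levels <- c("CDS", "EXON_UTR5", "EXON_UTR3", "INTRON",
                   "TSS_REGION", "TTS_REGION", "INTERGENIC")

mat_gr <- function(models, what) {
  pieces <- lapply(models, function(m) {
    iv <- m[[what]]
    if (nrow(iv) == 0) return(NULL)
    GenomicRanges::GRanges(m$chrom,
                           IRanges::IRanges(iv[, "start"], iv[, "end"]),
                           tx_id = m$tx_id, gene_id = m$gene_id)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces))
    return(GenomicRanges::GRanges(tx_id = character(0),
                                  gene_id = character(0)))
  suppressWarnings(do.call(c, unname(pieces)))
}

window_gr <- function(models, at, up, down) {
  gr <- lapply(models, function(m) {
    anchor <- m[[at]]
    lo <- if (m$strand == "-") anchor - down else anchor - up
    hi <- if (m$strand == "-") anchor + up else anchor + down
    GenomicRanges::GRanges(m$chrom, IRanges::IRanges(max(1, lo), hi),
                           tx_id = m$tx_id, gene_id = m$gene_id)
  })
  suppressWarnings(do.call(c, unname(gr)))
}

build_region_index <- function(models, params) {
  body_gr <- suppressWarnings(do.call(c, unname(lapply(models, function(m)
    GenomicRanges::GRanges(m$chrom,
                           IRanges::IRanges(m$tx_start, m$tx_end),
                           tx_id = m$tx_id, gene_id = m$gene_id)))))
  list(CDS = mat_gr(models, "cds"),
       EXON_UTR5 = mat_gr(models, "utr5"),
       EXON_UTR3 = mat_gr(models, "utr3"),
       INTRON = body_gr,  # gene body; exon tiers take precedence
       TSS_REGION = window_gr(models, "tss", params$tss_upstream,
                              params$tss_downstream),
       TTS_REGION = window_gr(models, "tts", params$tts_upstream,
                              params$tts_downstream))
}

#' Locate variants relative to gene models
#'
#' Assigns each variant exactly one region category with precedence
#' CDS > 5'UTR exon > 3'UTR exon > intron (gene body) > TSS window >
#' TTS window > intergenic; a variant inside the TSS window of one gene
#' but the body of another takes the gene-body category. When several
#' transcripts match at the winning tier, the lexicographically
#' smallest transcript id is reported (all matches are kept in the
#' \code{cds_tx} attribute used for effect calculation).
#'
#' @param variants a variant or marker data.frame (needs \code{chrom},
#'   \code{pos}).
#' @param models a [parse_gff3()] result.
#' @param params an [annotation_params()].
#' @return The input data.frame with \code{region}, \code{gene_id} and
#'   \code{tx_id} columns appended.
#' @export
locate_variants <- function(variants, models, params = annotation_params()) {
  stopifnot(inherits(models, "gene_models"))
  n <- nrow(variants)
  region <- rep("INTERGENIC", n)
  gene_id <- rep(NA_character_, n)
  tx_id <- rep(NA_character_, n)
  cds_tx <- vector("list", n)
  if (n == 0 || length(models) == 0) {
    out <- cbind(variants, region = region, gene_id = gene_id,
                 tx_id = tx_id, stringsAsFactors = FALSE)
    attr(out, "cds_tx") <- cds_tx
    return(out)
  }
  ann_chroms <- unique(vapply(models, `[[`, "", "chrom"))
  missing_chrom <- setdiff(unique(variants$chrom), ann_chroms)
  if (length(missing_chrom))
    warning("chromosome(s) absent from annotation, set INTERGENIC: ",
            paste(missing_chrom, collapse = ", "), call. = FALSE)

  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1))
  idx <- build_region_index(models, params)
  unassigned <- rep(TRUE, n)
  for (cat in names(idx)) {
    if (!any(unassigned)) break
    hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, idx[[cat]]))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    use <- unassigned[qh]
    if (!any(use)) next
    qh <- qh[use]; sh <- sh[use]
    txs <- idx[[cat]]$tx_id[sh]; genes <- idx[[cat]]$gene_id[sh]
    for (q in unique(qh)) {
      sel <- qh == q
      best <- order(txs[sel])[1]
      region[q] <- cat
      tx_id[q] <- txs[sel][best]
      gene_id[q] <- genes[sel][best]
      if (cat == "CDS") cds_tx[[q]] <- sort(unique(txs[sel]))
    }
    unassigned[unique(qh)] <- FALSE
  }
  out <- cbind(variants, region = region, gene_id = gene_id, tx_id = tx_id,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cds_tx") <- cds_tx
  out
}

#' Coding effect of a SNP inside a CDS
#'
#' Extracts the reference codon using the transcript's strand and
#' reading frame, substitutes the alternate base, and translates both
#' codons with the standard genetic code.
#'
#' @param chrom,pos,ref,alt the SNP (1-based genomic coordinate;
#'   \code{ref}/\code{alt} are forward-strand bases).
#' @param model one transcript model from [parse_gff3()].
#' @param genome a \code{DNAStringSet} (or FASTA path) holding the
#'   reference.
#' @return One of \code{"SYNONYMOUS"}, \code{"NONSYNONYMOUS"},
#'   \code{"STOP_GAIN"}, \code{"STOP_LOSS"}.
#' @export
coding_effect <- function(chrom, pos, ref, alt, model, genome) {
  if (is.character(genome) && file.exists(genome[1]))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  gref <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (gref != toupper(ref))
    stop_rm("reference mismatch at ", chrom, ":", pos, ": variant ref '",
            ref, "' but genome has '", gref, "'")

  cds <- model$cds
  hit <- which(pos >= cds[, "start"] & pos <= cds[, "end"])
  if (length(hit) != 1)
    stop_rm("position ", chrom, ":", pos, " is not inside the CDS of ",
            model$tx_id)
  widths <- cds[, "end"] - cds[, "start"] + 1L
  if (model$strand == "-") {
    cds_pos <- sum(widths[cds[, "start"] > pos]) +
      (cds[hit, "end"] - pos + 1L)
  } else {
    cds_pos <- sum(widths[cds[, "end"] < pos]) + (pos - cds[hit, "start"] + 1L)
  }
  cds_seq <- cds_sequence(model, genome)
  stopifnot(substr(cds_seq, cds_pos, cds_pos) ==
              strand_base(ref, model$strand))

  codon_i <- (cds_pos - 1L) %/% 3L
  codon_from <- codon_i * 3L + 1L
  if (codon_from + 2L > nchar(cds_seq))
    stop_rm("partial terminal codon in ", model$tx_id)
  ref_codon <- substr(cds_seq, codon_from, codon_from + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - codon_from + 1L, cds_pos - codon_from + 1L) <-
    strand_base(alt, model$strand)

  aa <- Biostrings::GENETIC_CODE[c(ref_codon, alt_codon)]
  if (aa[1] == aa[2]) "SYNONYMOUS"
  else if (aa[2] == "*") "STOP_GAIN"
  else if (aa[1] == "*") "STOP_LOSS"
  else "NONSYNONYMOUS"
}

strand_base <- function(b, strand) {
  if (strand == "-") chartr("ACGT", "TGCA", toupper(b)) else toupper(b)
}

#' Spliced CDS sequence of a transcript (5' to 3')
#' @param model a transcript model from [parse_gff3()].
#' @param genome a \code{DNAStringSet}.
#' @return Character string.
#' @export
cds_sequence <- function(model, genome) {
  cds <- model$cds
  parts <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(genome[[model$chrom]],
                                    cds[i, "start"], cds[i, "end"])), "")
  s <- paste(parts, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

effect_severity <- c(STOP_GAIN = 1, STOP_LOSS = 2, NONSYNONYMOUS = 3,
                     SYNONYMOUS = 4)

#' Annotate variants with region and coding effect
#'
#' Runs [locate_variants()] then computes [coding_effect()] for SNPs in
#' CDS. When several transcripts' CDS overlap a SNP, the most severe
#' effect is reported (stop gain > stop loss > nonsynonymous >
#' synonymous; ties to the lexicographically smallest transcript).
#' InDels in CDS get effect \code{NA}; variants outside CDS get
#' \code{NONCODING}.
#'
#' @inheritParams locate_variants
#' @param genome a \code{DNAStringSet} or FASTA path (needed for
#'   effects; pass \code{NULL} to annotate regions only).
#' @return The variants with \code{region}, \code{gene_id},
#'   \code{tx_id} and \code{effect} columns.
#' @export
annotate_variants <- function(variants, models, genome = NULL,
                              params = annotation_params()) {
  ann <- locate_variants(variants, models, params)
  cds_tx <- attr(ann, "cds_tx")
  is_snp <- if ("vtype" %in% names(ann)) ann$vtype == "SNP"
            else nchar(ann$ref) == 1 & nchar(ann$alt) == 1
  effect <- ifelse(ann$region == "CDS" & !is_snp, NA_character_,
                   "NONCODING")
  if (!is.null(genome) && is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  for (i in which(ann$region == "CDS" & is_snp)) {
    if (is.null(genome)) { effect[i] <- NA_character_; next }
    txs <- cds_tx[[i]] %||% ann$tx_id[i]
    effs <- vapply(txs, function(t)
      coding_effect(ann$chrom[i], ann$pos[i], ann$ref[i], ann$alt[i],
                    models[[t]], genome), "")
    best <- order(effect_severity[effs], txs)[1]
    effect[i] <- effs[best]
    ann$tx_id[i] <- txs[best]
    ann$gene_id[i] <- models[[txs[best]]]$gene_id
  }
  ann$effect <- effect
  attr(ann, "cds_tx") <- NULL
  ann
}

#' Region and effect distribution of annotated variants
#'
#' @param annotated an [annotate_variants()] result.
#' @return List with \code{regions} and \code{effects} data.frames
#'   (category, count, fraction); fractions sum to 1 within each
#'   partition (empty input gives empty tables).
#' @export
summarize_annotation <- function(annotated) {
  dist_tab <- function(x, levels) {
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(category = character(0), count = integer(0),
                        fraction = numeric(0)))
    tab <- table(factor(x, levels = levels))
    data.frame(category = names(tab), count = as.integer(tab),
               fraction = as.numeric(tab) / length(x),
               stringsAsFactors = FALSE)
  }
  list(regions = dist_tab(annotated$region, region_levels),
       effects = dist_tab(
         annotated$effect[annotated$effect %in% names(effect_severity)],
         names(effect_severity)))
}

#' InDel length distribution
#'
#' Separate length histograms for insertions and deletions plus class
#' fractions over all InDels (1 bp; 2-5 bp; 6-22 bp; >22 bp).
#'
#' @param variants a variant data.frame with \code{vtype}, \code{ref},
#'   \code{alt} columns.
#' @return List with \code{insertions} and \code{deletions} histograms
#'   (length, count) and \code{class_fractions}.
#' @export
indel_length_summary <- function(variants) {
  ind <- variants[variants$vtype %in% c("INS", "DEL"), , drop = FALSE]
  len <- abs(nchar(ind$alt) - nchar(ind$ref))
  hist_of <- function(l) {
    if (!length(l)) return(data.frame(length = integer(0),
                                      count = integer(0)))
    tab <- table(l)
    data.frame(length = as.integer(names(tab)), count = as.integer(tab))
  }
  cls <- if (length(len)) c(
    `1bp` = mean(len == 1), `2-5bp` = mean(len >= 2 & len <= 5),
    `6-22bp` = mean(len >= 6 & len <= 22), `>22bp` = mean(len > 22))
  else c(`1bp` = NA_real_, `2-5bp` = NA_real_, `6-22bp` = NA_real_,
         `>22bp` = NA_real_)
  list(insertions = hist_of(len[ind$vtype == "INS"]),
       deletions = hist_of(len[ind$vtype == "DEL"]),
       class_fractions = cls)
}

#' Select markers flanking a target locus
#'
#' Returns the markers within a genetic-distance bound of a target
#' interval, ranked by distance, for marker-assisted selection. Genetic
#' distance is approximated from physical distance with a constant
#' cM/Mb rate (a genetic map is not used); the approximation is
#' recorded in the output.
#'
#' @param markers a marker data.frame (\code{chrom}, \code{pos}).
#' @param target_chrom,target_start,target_end the target locus
#'   (1-based inclusive interval; point locus when \code{target_end}
#'   is omitted).
#' @param cm_bound maximum approximate genetic distance in cM
#'   (default 1.5).
#' @param cm_per_mb physical-to-genetic conversion rate (default 4
#'   cM/Mb, a typical genome-wide average for rice).
#' @param window_bp optional physical window in bp; overrides
#'   \code{cm_bound} when given.
#' @return The selected markers with \code{distance_bp} and
#'   \code{approx_cm} columns, ordered by distance (empty with a
#'   warning if the chromosome carries no markers).
#' @export
select_linked_markers <- function(markers, target_chrom, target_start,
                                  target_end = target_start,
                                  cm_bound = 1.5, cm_per_mb = 4,
                                  window_bp = NULL) {
  on_chrom <- markers[markers$chrom == target_chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0) {
    warning("no markers on target chromosome ", target_chrom,
            call. = FALSE)
    out <- cbind(markers[0, , drop = FALSE],
                 data.frame(distance_bp = integer(0),
                            approx_cm = numeric(0)))
    return(out)
  }
  d <- pmax(0L, pmax(target_start - on_chrom$pos,
                     on_chrom$pos - target_end))
  cm <- d / 1e6 * cm_per_mb
  keep <- if (!is.null(window_bp)) d <= window_bp else cm <= cm_bound
  out <- on_chrom[keep, , drop = FALSE]
  out$distance_bp <- d[keep]
  out$approx_cm <- cm[keep]
  out <- out[order(out$distance_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
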