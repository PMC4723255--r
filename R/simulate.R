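#' Simulation specification
#'
#' The stated world for the package's fixtures: a small multi-chromosome
#' genome with planted restriction sites, non-overlapping gene models,
#' divergent variants between two varieties A and B, and per-sample
#' pileups at Poisson depth with a uniform per-base error model.
#' Identical seeds give identical outputs.
#'
#' @param seed integer RNG seed (derived sub-seeds stay below 2^31).
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 200000).
#' @param gc_fraction genome GC content (default 0.43, rice-like).
#' @param n_genes total gene models (default 20).
#' @param n_snps,n_indels planted divergent SNPs / InDels
#'   (defaults 100 / 20).
#' @param het_fraction fraction of planted variants heterozygous in
#'   their carrier (default 0: homozygous).
#' @param mean_depth mean sequencing depth per position (default 20).
#' @param error_rate per-base sequencing error rate (default 0.01).
#' @param min_spacing minimum distance between planted variants in bp
#'   (default 150; clears the 10 bp marker spacing rule and the longest
#'   30 bp InDel).
#' @param site_seq restriction recognition sequence planted by
#'   [make_genome()] (default TCGA).
#' @param site_spacing distance between planted restriction sites
#'   (default 500 bp).
#' @param indel_len_probs length distribution for planted InDels over
#'   1..30 bp; the default puts 52.8\% on 1 bp, 31.2\% on 2-5 bp and
#'   0.27\% above 22 bp, matching typical inter-variety rice InDel
#'   spectra.
#' @return An object of class \code{sim_spec}.
#' @export
sim_spec <- function(seed = 1, n_chroms = 2, chrom_length = 200000,
                     gc_fraction = 0.43, n_genes = 20, n_snps = 100,
                     n_indels = 20, het_fraction = 0, mean_depth = 20,
                     error_rate = 0.01, min_spacing = 150,
                     site_seq = "TCGA", site_spacing = 500,
                     indel_len_probs = NULL) {
  if (is.null(indel_len_probs)) {
    p <- numeric(30)
    p[1] <- 0.528
    p[2:5] <- 0.312 / 4
    p[6:22] <- (1 - 0.528 - 0.312 - 0.0027) / 17
    p[23:30] <- 0.0027 / 8
    indel_len_probs <- p / sum(p)
  }
  stopifnot(seed == as.integer(seed), n_chroms >= 1, chrom_length >= 1000,
            gc_fraction >= 0, gc_fraction <= 1, n_genes >= 0,
            n_snps >= 0, n_indels >= 0, het_fraction >= 0,
            het_fraction <= 1, mean_depth >= 0, error_rate >= 0,
            error_rate <= 1, min_spacing >= 31,
            length(indel_len_probs) == 30)
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_length = chrom_length, gc_fraction = gc_fraction,
                 n_genes = n_genes, n_snps = n_snps, n_indels = n_indels,
                 het_fraction = het_fraction, mean_depth = mean_depth,
                 error_rate = error_rate, min_spacing = min_spacing,
                 site_seq = toupper(site_seq), site_spacing = site_spacing,
                 indel_len_probs = indel_len_probs),
            class = "sim_spec")
}

BASES <- c("A", "C", "G", "T")

random_chrom <- function(len, gc) {
  paste(sample(BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

purge_motif <- function(s, motif) {
  # destroy every occurrence by flipping its middle base; rescan since
  # a replacement can (rarely) recreate an overlapping occurrence
  mid <- (nchar(motif) + 1L) %/% 2L
  repeat {
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(s)
    at <- hits + mid - 1L
    for (p in at) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(BASES, cur), 1)
    }
  }
}

#' Generate a random genome with planted restriction sites
#'
#' Draws each chromosome at the requested GC content, removes every
#' accidental occurrence of the recognition sequence, then plants sites
#' at regular spacing so the digestion ground truth is exact.
#'
#' @param spec a [sim_spec()].
#' @param plant_sites plant regularly spaced recognition sites
#'   (default TRUE).
#' @param purge_sites destroy accidental occurrences first
#'   (default TRUE; required for an exact site truth).
#' @return List with \code{genome} (a \code{DNAStringSet}, chromosomes
#'   \code{chr1..chrN}) and \code{sites} (per-chromosome 1-based start
#'   positions of planted recognition sites).
#' @export
make_genome <- function(spec, plant_sites = TRUE, purge_sites = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  motif <- spec$site_seq
  mlen <- nchar(motif)
  if (plant_sites && spec$chrom_length < spec$site_spacing + mlen)
    stop_rm("chrom_length too small for the requested site spacing")
  chroms <- vector("list", spec$n_chroms)
  sites <- vector("list", spec$n_chroms)
  for (i in seq_len(spec$n_chroms)) {
    s <- random_chrom(spec$chrom_length, spec$gc_fraction)
    if (purge_sites) s <- purge_motif(s, motif)
    pos <- integer(0)
    if (plant_sites) {
      pos <- seq.int(spec$site_spacing, spec$chrom_length - mlen,
                     by = spec$site_spacing)
      for (p in pos) substr(s, p, p + mlen - 1L) <- motif
      if (purge_sites) {
        # planting can butt new letters against old ones; verify
        found <- gregexpr(motif, s, fixed = TRUE)[[1]]
        if (!identical(as.integer(found), as.integer(pos)))
          s <- repair_sites(s, motif, pos)
      }
    }
    chroms[[i]] <- s
    sites[[i]] <- pos
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- paste0("chr", seq_len(spec$n_chroms))
  names(sites) <- names(genome)
  list(genome = genome, sites = sites)
}

repair_sites <- function(s, motif, want) {
  repeat {
    found <- as.integer(gregexpr(motif, s, fixed = TRUE)[[1]])
    extra <- setdiff(found, want)
    if (!length(extra)) return(s)
    for (p in extra) {
      # flip a base of the accidental occurrence that lies outside
      # every wanted site
      cand <- setdiff(p:(p + nchar(motif) - 1L),
                      unlist(lapply(want, function(w)
                        w:(w + nchar(motif) - 1L))))
      if (!length(cand)) stop_rm("cannot repair overlapping planted sites")
      q <- cand[1]
      cur <- substr(s, q, q)
      substr(s, q, q) <- sample(setdiff(BASES, cur), 1)
    }
  }
}

sense_codons <- function() {
  all3 <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                          BASES, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Plant gene models into a genome
#'
#' Lays out non-overlapping genes (5'UTR, 1-3 CDS exons separated by
#' introns, 3'UTR) on random strands, writes a valid coding sequence
#' (ATG start, no internal stops, TAA stop, length divisible by 3) into
#' the genome, and emits matching GFF3.
#'
#' @param spec a [sim_spec()].
#' @param genome a \code{DNAStringSet} from [make_genome()].
#' @return List with \code{genome} (updated), \code{gff_lines}
#'   (character vector of GFF3 text), and \code{truth} (list of
#'   per-transcript structures mirroring [parse_gff3()] models).
#' @export
make_annotation <- function(spec, genome) {
  stopifnot(inherits(spec, "sim_spec"), is(genome, "DNAStringSet"))
  set.seed(spec$seed + 1L)
  n_per <- ceiling(spec$n_genes / length(genome))
  codons <- sense_codons()
  gff <- c("##gff-version 3")
  truth <- list()
  g <- 0L
  chrom_strings <- as.list(as.character(genome))

  for (ci in seq_along(genome)) {
    if (g >= spec$n_genes) break
    n_here <- min(n_per, spec$n_genes - g)
    if (n_here == 0) next
    slot <- as.integer(spec$chrom_length) %/% (n_here + 1L)
    if (slot < 6000)
      stop_rm("insufficient space: ", n_here, " genes on a ",
              spec$chrom_length, " bp chromosome")
    for (k in seq_len(n_here)) {
      g <- g + 1L
      strand <- sample(c("+", "-"), 1)
      n_cds <- sample(1:3, 1)
      cds_lens <- 3L * sample(40:80, n_cds, replace = TRUE)
      intron_lens <- if (n_cds > 1) sample(100:300, n_cds - 1L,
                                           replace = TRUE) else integer(0)
      utr5_len <- sample(80:200, 1)
      utr3_len <- sample(80:200, 1)
      start <- (k - 1L) * slot + slot %/% 3L

      # genomic layout left to right; transcription order depends on
      # strand
      pieces_len <- c(utr5_len, as.vector(rbind(cds_lens,
                                                c(intron_lens, NA))))
      pieces_len <- pieces_len[!is.na(pieces_len)]
      pieces_len <- c(pieces_len, utr3_len)
      if (strand == "-") pieces_len <- rev(pieces_len)
      kinds <- c("utr5", as.vector(rbind(rep("cds", n_cds),
                                         c(rep("intron", n_cds - 1L), NA))))
      kinds <- c(kinds[!is.na(kinds)], "utr3")
      if (strand == "-") kinds <- rev(kinds)
      ends <- start + cumsum(pieces_len) - 1L
      starts <- c(start, head(ends, -1) + 1L)
      iv <- data.frame(kind = kinds, start = starts, end = ends)

      # write coding sequence into the genome
      cds_iv <- iv[iv$kind == "cds", , drop = FALSE]
      total_cds <- sum(cds_iv$end - cds_iv$start + 1L)
      ncod <- total_cds %/% 3L
      coding <- paste0("ATG",
                       paste(sample(codons, ncod - 2L, replace = TRUE),
                             collapse = ""), "TAA")
      genomic_cds <- if (strand == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(coding))) else coding
      off <- 0L
      for (r in seq_len(nrow(cds_iv))) {
        w <- cds_iv$end[r] - cds_iv$start[r] + 1L
        substr(chrom_strings[[ci]], cds_iv$start[r], cds_iv$end[r]) <-
          substr(genomic_cds, off + 1L, off + w)
        off <- off + w
      }

      chrom <- names(genome)[ci]
      gid <- sprintf("gene%03d", g)
      tid <- sprintf("gene%03d.1", g)
      tx_start <- min(iv$start); tx_end <- max(iv$end)
      mat <- function(kind) {
        m <- as.matrix(iv[iv$kind == kind, c("start", "end"),
                          drop = FALSE])
        storage.mode(m) <- "integer"
        dimnames(m) <- list(NULL, c("start", "end"))
        m
      }
      # exons: UTR runs are contiguous with their flanking CDS exon
      exon_iv <- iv[iv$kind != "intron", , drop = FALSE]
      exons <- list(); cur <- NULL
      for (r in seq_len(nrow(exon_iv))) {
        if (is.null(cur)) cur <- c(exon_iv$start[r], exon_iv$end[r])
        else if (exon_iv$start[r] == cur[2] + 1L) cur[2] <- exon_iv$end[r]
        else { exons[[length(exons) + 1L]] <- cur
               cur <- c(exon_iv$start[r], exon_iv$end[r]) }
      }
      exons[[length(exons) + 1L]] <- cur
      exon_mat <- do.call(rbind, exons)
      storage.mode(exon_mat) <- "integer"
      dimnames(exon_mat) <- list(NULL, c("start", "end"))

      model <- list(tx_id = tid, gene_id = gid, chrom = chrom,
                    strand = strand, tx_start = tx_start, tx_end = tx_end,
                    exons = exon_mat, cds = mat("cds"),
                    utr5 = mat("utr5"), utr3 = mat("utr3"),
                    tss = if (strand == "-") tx_end else tx_start,
                    tts = if (strand == "-") tx_start else tx_end)
      truth[[tid]] <- model

      row <- function(type, s, e, attrs)
        paste(chrom, "radmarker_sim", type, s, e, ".", strand, ".",
              attrs, sep = "\t")
      gff <- c(gff,
               row("gene", tx_start, tx_end, paste0("ID=", gid)),
               row("mRNA", tx_start, tx_end,
                   paste0("ID=", tid, ";Parent=", gid)))
      for (r in seq_len(nrow(exon_mat)))
        gff <- c(gff, row("exon", exon_mat[r, 1], exon_mat[r, 2],
                          paste0("ID=", tid, ".exon", r, ";Parent=", tid)))
      for (kind in c("cds", "utr5", "utr3")) {
        type <- c(cds = "CDS", utr5 = "five_prime_UTR",
                  utr3 = "three_prime_UTR")[[kind]]
        m <- mat(kind)
        for (r in seq_len(nrow(m)))
          gff <- c(gff, row(type, m[r, 1], m[r, 2],
                            paste0("ID=", tid, ".", kind, r,
                                   ";Parent=", tid)))
      }
    }
  }
  out_genome <- Biostrings::DNAStringSet(unlist(chrom_strings))
  names(out_genome) <- names(genome)
  list(genome = out_genome, gff_lines = gff, truth = truth)
}

#' Plant divergent variants between two varieties
#'
#' Samples SNP and InDel positions (respecting a minimum spacing),
#' assigns each to carrier variety A or B, records the truth table, and
#' applies the edits to per-variety genome copies.
#'
#' @param spec a [sim_spec()].
#' @param genome the reference \code{DNAStringSet} (after
#'   [make_annotation()] if gene content is wanted).
#' @param candidate_regions optional data.frame (\code{chrom},
#'   \code{start}, \code{end}) restricting where variants are planted
#'   (e.g. CDS intervals).
#' @return List with \code{genome_a}, \code{genome_b}
#'   (\code{DNAStringSet}s with edits applied) and \code{truth}: a
#'   data.frame with \code{chrom}, \code{pos} (anchored, 1-based),
#'   \code{ref}, \code{alt} (VCF-style anchored alleles), \code{vtype},
#'   \code{carrier} (A/B), \code{zygosity} (HOM/HET), \code{indel_len}.
#' @export
plant_variants <- function(spec, genome, candidate_regions = NULL) {
  stopifnot(inherits(spec, "sim_spec"), is(genome, "DNAStringSet"))
  set.seed(spec$seed + 2L)
  n_total <- spec$n_snps + spec$n_indels
  if (n_total == 0)
    return(list(genome_a = genome, genome_b = genome,
                truth = empty_truth_df()))

  chrom_names <- names(genome)
  chrom_len <- setNames(BiocGenerics::width(genome), chrom_names)
  margin <- 60L
  chosen <- data.frame(chrom = character(0), pos = integer(0))
  tries <- 0L
  while (nrow(chosen) < n_total) {
    tries <- tries + 1L
    if (tries > n_total * 200L)
      stop_rm("cannot satisfy min_spacing = ", spec$min_spacing,
              " for ", n_total, " variants; enlarge the genome")
    if (is.null(candidate_regions)) {
      ch <- sample(chrom_names, 1)
      p <- sample.int(chrom_len[[ch]] - 2L * margin, 1) + margin
    } else {
      r <- candidate_regions[sample.int(nrow(candidate_regions), 1), ]
      ch <- r$chrom
      p <- sample(seq.int(r$start, r$end), 1)
    }
    same <- chosen$pos[chosen$chrom == ch]
    if (length(same) && min(abs(same - p)) < spec$min_spacing) next
    chosen <- rbind(chosen, data.frame(chrom = ch, pos = as.integer(p)))
  }

  vtype <- c(rep("SNP", spec$n_snps),
             sample(c("INS", "DEL"), spec$n_indels, replace = TRUE))
  vtype <- sample(vtype)  # shuffle across positions
  ref <- alt <- character(n_total)
  ilen <- integer(n_total)
  for (i in seq_len(n_total)) {
    ch <- chosen$chrom[i]; p <- chosen$pos[i]
    base <- as.character(Biostrings::subseq(genome[[ch]], p, p))
    if (vtype[i] == "SNP") {
      ref[i] <- base
      alt[i] <- sample(setdiff(BASES, base), 1)
    } else if (vtype[i] == "INS") {
      ilen[i] <- sample(30, 1, prob = spec$indel_len_probs)
      ref[i] <- base
      alt[i] <- paste0(base, paste(sample(BASES, ilen[i], replace = TRUE),
                                   collapse = ""))
    } else {
      ilen[i] <- sample(30, 1, prob = spec$indel_len_probs)
      ref[i] <- as.character(Biostrings::subseq(genome[[ch]], p,
                                                p + ilen[i]))
      alt[i] <- base
    }
  }
  truth <- data.frame(chrom = chosen$chrom, pos = chosen$pos, ref = ref,
                      alt = alt, vtype = vtype,
                      carrier = sample(c("A", "B"), n_total,
                                       replace = TRUE),
                      zygosity = ifelse(runif(n_total) < spec$het_fraction,
                                        "HET", "HOM"),
                      indel_len = ilen, stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$pos), ]
  rownames(truth) <- NULL

  list(genome_a = apply_edits(genome, truth[truth$carrier == "A", ]),
       genome_b = apply_edits(genome, truth[truth$carrier == "B", ]),
       truth = truth)
}

empty_truth_df <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
              alt = character(0), vtype = character(0),
              carrier = character(0), zygosity = character(0),
              indel_len = integer(0), stringsAsFactors = FALSE)
}

apply_edits <- function(genome, truth) {
  out <- genome
  for (ch in unique(truth$chrom)) {
    t <- truth[truth$chrom == ch, ]
    at <- IRanges::IRanges(
      start = ifelse(t$vtype == "SNP", t$pos, t$pos + 1L),
      end = ifelse(t$vtype == "DEL", t$pos + t$indel_len,
                   ifelse(t$vtype == "SNP", t$pos, t$pos)))
    value <- ifelse(t$vtype == "SNP", t$alt,
                    ifelse(t$vtype == "INS", substring(t$alt, 2), ""))
    out[[ch]] <- Biostrings::replaceAt(out[[ch]], at,
                                       Biostrings::DNAStringSet(value))
  }
  out
}

#' Simulate a samtools pileup for one variety
#'
#' Per reference position, depth is Poisson(\code{mean_depth}); each
#' read observation reports the variety allele with probability
#' 1 - \code{error_rate}, otherwise a uniformly chosen different base.
#' InDel observations use samtools pileup syntax at the anchor
#' position, with \code{*} placeholders across deleted spans;
#' heterozygous sites draw each read's haplotype uniformly. A random
#' tenth of lines carry \code{^}+mapping-quality / \code{$}
#' decorations.
#'
#' @param spec a [sim_spec()].
#' @param genome the reference \code{DNAStringSet}.
#' @param truth truth table from [plant_variants()].
#' @param sample_id \code{"A"} or \code{"B"}.
#' @param path output pileup path, or \code{NULL} to return lines only.
#' @return List with \code{lines} (pileup text), \code{path}, and
#'   \code{site_stats}: for every truth anchor position in this sample,
#'   the realized \code{depth}, \code{alt_reads} (reads supporting the
#'   planted allele) and \code{err_reads} (error observations).
#' @export
simulate_pileup <- function(spec, genome, truth, sample_id = "A",
                            path = NULL) {
  stopifnot(inherits(spec, "sim_spec"), sample_id %in% c("A", "B"))
  set.seed(spec$seed + 3L + (sample_id == "B"))
  all_lines <- list()
  stats <- list()

  for (ch in names(genome)) {
    refv <- strsplit(as.character(genome[[ch]]), "")[[1]]
    L <- length(refv)
    d <- rpois(L, spec$mean_depth)
    mine <- truth[truth$chrom == ch & truth$carrier == sample_id, ,
                  drop = FALSE]
    here <- truth[truth$chrom == ch, , drop = FALSE]

    ern <- rbinom(L, d, spec$error_rate)
    span_pos <- integer(0)
    dels <- mine[mine$vtype == "DEL", , drop = FALSE]
    if (nrow(dels))
      span_pos <- unlist(mapply(function(p, l) seq.int(p + 1L, p + l),
                                dels$pos, dels$indel_len,
                                SIMPLIFY = FALSE))
    ern[span_pos] <- 0L

    k <- d - ern                       # reads showing the variety allele
    alt_n <- integer(L)
    allele <- refv                     # per-position variety base for
                                       # drawing "wrong" error bases
    nd <- (k + 1L) %/% 2L
    main <- paste0(strrep(".", nd), strrep(",", k - nd))

    if (nrow(mine)) {
      for (r in seq_len(nrow(mine))) {
        p <- mine$pos[r]
        if (d[p] == 0) next
        token <- switch(mine$vtype[r],
          SNP = mine$alt[r],
          INS = paste0(".+", mine$indel_len[r], substring(mine$alt[r], 2)),
          DEL = paste0(".-", mine$indel_len[r], substring(mine$ref[r], 2)))
        a <- if (mine$zygosity[r] == "HET") rbinom(1, k[p], 0.5) else k[p]
        restk <- k[p] - a
        nd2 <- (restk + 1L) %/% 2L
        if (mine$vtype[r] == "SNP") {
          main[p] <- paste0(strrep(toupper(token), (a + 1L) %/% 2L),
                            strrep(tolower(token), a %/% 2L),
                            strrep(".", nd2), strrep(",", restk - nd2))
          allele[p] <- mine$alt[r]
        } else {
          main[p] <- paste0(strrep(token, a),
                            strrep(".", nd2), strrep(",", restk - nd2))
        }
        alt_n[p] <- a
      }
      # deleted spans: supporting reads show '*'
      for (r in which(mine$vtype == "DEL")) {
        sp <- seq.int(mine$pos[r] + 1L, mine$pos[r] + mine$indel_len[r])
        for (p in sp) {
          if (d[p] == 0) next
          a <- if (mine$zygosity[r] == "HET") rbinom(1, d[p], 0.5)
               else d[p]
          restk <- d[p] - a
          nd2 <- (restk + 1L) %/% 2L
          main[p] <- paste0(strrep("*", a),
                            strrep(".", nd2), strrep(",", restk - nd2))
        }
      }
    }

    ep <- which(ern > 0L)
    if (length(ep)) {
      others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                      G = c("A", "C", "T"), T = c("A", "C", "G"))
      reps <- rep(ep, ern[ep])
      wrong <- others[cbind(match(allele[reps], BASES),
                            sample.int(3L, length(reps), replace = TRUE))]
      agg <- data.table::data.table(p = reps, b = wrong)
      agg <- agg[, list(s = paste(b, collapse = "")), by = "p"]
      main[agg$p] <- paste0(main[agg$p], agg$s)
    }

    deco <- runif(L)
    pre <- deco < 0.1 & d > 0
    main[pre] <- paste0("^I", main[pre])
    post <- deco > 0.9 & d > 0
    main[post] <- paste0(main[post], "$")

    keep <- which(d > 0L)
    all_lines[[ch]] <- if (length(keep))
      paste(ch, keep, refv[keep], d[keep], main[keep],
            strrep("I", d[keep]), sep = "\t") else character(0)
    if (nrow(here))
      stats[[ch]] <- data.frame(chrom = ch, pos = here$pos,
                                depth = d[here$pos],
                                alt_reads = alt_n[here$pos],
                                err_reads = ern[here$pos],
                                stringsAsFactors = FALSE)
  }
  lines <- unlist(all_lines, use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  list(lines = lines, path = path,
       site_stats = if (length(stats)) do.call(rbind, stats)
                    else data.frame(chrom = character(0), pos = integer(0),
                                    depth = integer(0),
                                    alt_reads = integer(0),
                                    err_reads = integer(0)))
}

#' Score called markers against the planted truth
#'
#' A marker matches a truth row when chromosome, anchored position and
#' the ref/alt alleles agree. Precision is matched/called (NA when
#' nothing was called); recall is matched/planted.
#'
#' @param markers a marker or variant data.frame (\code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{vtype}).
#' @param truth the [plant_variants()] truth table (optionally
#'   subset, e.g. to threshold-eligible sites).
#' @return List with \code{precision}, \code{recall},
#'   \code{n_called}, \code{n_truth}, \code{n_matched} and a
#'   \code{by_type} data.frame.
#' @export
evaluate_calls <- function(markers, truth) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "|")
  mk <- key(markers); tk <- key(truth)
  matched_m <- mk %in% tk
  matched_t <- tk %in% mk
  by_type <- do.call(rbind, lapply(unique(truth$vtype), function(v) {
    sel <- truth$vtype == v
    data.frame(vtype = v, n_truth = sum(sel),
               recall = if (any(sel)) mean(matched_t[sel]) else NA_real_)
  }))
  list(precision = if (nrow(markers)) mean(matched_m) else NA_real_,
       recall = if (nrow(truth)) mean(matched_t) else NA_real_,
       n_called = nrow(markers), n_truth = nrow(truth),
       n_matched = sum(matched_t), by_type = by_type)
}

#' Threshold eligibility of planted sites from realized counts
#'
#' Determines, by direct arithmetic on the simulator's recorded
#' per-site read counts (independent of the pileup parser and calling
#' code), which planted variants satisfy every detection condition:
#' treat-side calling thresholds, the clean-control rule, and the
#' coverage post-filter.
#'
#' @param truth [plant_variants()] truth table.
#' @param stats_a,stats_b \code{site_stats} from [simulate_pileup()]
#'   for samples A and B.
#' @param p a [somatic_params()].
#' @return Logical vector along \code{truth} rows.
#' @export
truth_eligibility <- function(truth, stats_a, stats_b,
                              p = somatic_params()) {
  key <- function(df) paste(df$chrom, df$pos)
  ia <- match(key(truth), key(stats_a))
  ib <- match(key(truth), key(stats_b))
  # pick treat-side counts from the carrier's table, control from the other
  td <- ifelse(truth$carrier == "A", stats_a$depth[ia], stats_b$depth[ib])
  ta <- ifelse(truth$carrier == "A", stats_a$alt_reads[ia],
               stats_b$alt_reads[ib])
  cd <- ifelse(truth$carrier == "A", stats_b$depth[ib], stats_a$depth[ia])
  ce <- ifelse(truth$carrier == "A", stats_b$err_reads[ib],
               stats_a$err_reads[ia])
  ratio <- ifelse(td > 0, ta / td, 0)
  cratio <- ifelse(cd > 0, ce / cd, 0)
  cp <- p$call
  td >= cp$min_depth & ta >= cp$min_mut_reads & ratio > cp$min_mut_ratio &
    ratio >= cp$hetero_prop_level &
    cd >= p$control_min_depth & ce < p$control_max_mut_reads &
    cratio < p$control_max_mut_ratio &
    td >= p$post_min_treat_depth & ce <= p$post_max_control_mut
}

#' Generate a complete fixture dataset on disk
#'
#' Runs [make_genome()], [make_annotation()], [plant_variants()] and
#' [simulate_pileup()] for both varieties, writing \code{genome.fa},
#' \code{genes.gff3}, \code{A.pileup}, \code{B.pileup},
#' \code{truth.tsv} and \code{sites.tsv} under \code{outdir}.
#'
#' @param spec a [sim_spec()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the file paths and the in-memory
#'   objects (\code{genome}, \code{models_truth}, \code{truth},
#'   \code{stats_a}, \code{stats_b}).
#' @export
simulate_dataset <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_genome(spec)
  ann <- make_annotation(spec, gen$genome)
  pv <- plant_variants(spec, ann$genome)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                gff = file.path(outdir, "genes.gff3"),
                a = file.path(outdir, "A.pileup"),
                b = file.path(outdir, "B.pileup"),
                truth = file.path(outdir, "truth.tsv"),
                sites = file.path(outdir, "sites.tsv"))
  Biostrings::writeXStringSet(ann$genome, paths$genome)
  writeLines(ann$gff_lines, paths$gff)
  pa <- simulate_pileup(spec, ann$genome, pv$truth, "A", paths$a)
  pb <- simulate_pileup(spec, ann$genome, pv$truth, "B", paths$b)
  write.table(pv$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(chrom = rep(names(gen$sites),
                                     lengths(gen$sites)),
                         pos = unlist(gen$sites, use.names = FALSE)),
              paths$sites, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, genome = ann$genome,
                 models_truth = ann$truth, truth = pv$truth,
                 stats_a = pa$site_stats, stats_b = pb$site_stats,
                 sites = gen$sites))
}
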