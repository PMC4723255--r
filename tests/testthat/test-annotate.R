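# a hand-written two-gene GFF3: geneA (+, single exon) and geneB (-)
# whose TSS window overlaps geneA's body
tiny_gff <- function() {
  path <- tempfile(fileext = ".gff3")
  row <- function(type, s, e, strand, attrs)
    paste("chr1", "test", type, s, e, ".", strand, ".", attrs, sep = "\t")
  writeLines(c(
    "##gff-version 3",
    row("gene", 1001, 2000, "+", "ID=geneA"),
    row("mRNA", 1001, 2000, "+", "ID=geneA.1;Parent=geneA"),
    row("exon", 1001, 2000, "+", "ID=geneA.1.e1;Parent=geneA.1"),
    row("five_prime_UTR", 1001, 1100, "+", "ID=geneA.1.u5;Parent=geneA.1"),
    row("CDS", 1101, 1900, "+", "ID=geneA.1.c1;Parent=geneA.1"),
    row("three_prime_UTR", 1901, 2000, "+", "ID=geneA.1.u3;Parent=geneA.1"),
    row("gene", 2500, 3400, "-", "ID=geneB"),
    row("mRNA", 2500, 3400, "-", "ID=geneB.1;Parent=geneB"),
    row("exon", 2500, 2900, "-", "ID=geneB.1.e1;Parent=geneB.1"),
    row("exon", 3100, 3400, "-", "ID=geneB.1.e2;Parent=geneB.1"),
    row("CDS", 2500, 2900, "-", "ID=geneB.1.c1;Parent=geneB.1"),
    row("CDS", 3100, 3400, "-", "ID=geneB.1.c2;Parent=geneB.1")),
    path)
  path
}

test_that("parse_gff3 builds strand-aware gene models", {
  models <- parse_gff3(tiny_gff())
  expect_length(models, 2)
  a <- models[["geneA.1"]]
  expect_equal(a$tss, 1001)
  expect_equal(a$tts, 2000)
  expect_equal(a$gene_id, "geneA")
  b <- models[["geneB.1"]]
  expect_equal(b$strand, "-")
  expect_equal(b$tss, 3400)   # 5' end on the minus strand
  expect_equal(b$tts, 2500)
  expect_equal(nrow(b$cds), 2)
})

test_that("generated GFF3 round-trips to the construction truth", {
  ss <- shared_sim()
  models <- parse_gff3(ss$sim$paths$gff)
  truth <- ss$sim$models_truth
  expect_equal(length(models), length(truth))
  for (tx in names(truth)) {
    expect_identical(models[[tx]]$cds, truth[[tx]]$cds)
    expect_identical(models[[tx]]$exons, truth[[tx]]$exons)
    expect_equal(models[[tx]]$tss, truth[[tx]]$tss)
    expect_equal(models[[tx]]$tts, truth[[tx]]$tts)
    expect_equal(models[[tx]]$strand, truth[[tx]]$strand)
  }
})

test_that("locate_variants assigns one category with documented precedence", {
  models <- parse_gff3(tiny_gff())
  v <- data.frame(
    chrom = "chr1",
    pos = c(1500,   # CDS of geneA
            1050,   # 5'UTR exon
            1950,   # 3'UTR exon
            3000,   # intron of geneB
            501,    # TSS-500 of geneA (+ strand)
            2100,   # downstream of geneA TTS (within 500) and within
                    # geneB TTS window: TTS_REGION
            50000), # far away
    ref = "A", alt = "C", vtype = "SNP", stringsAsFactors = FALSE)
  ann <- locate_variants(v, models)
  expect_equal(ann$region,
               c("CDS", "EXON_UTR5", "EXON_UTR3", "INTRON", "TSS_REGION",
                 "TTS_REGION", "INTERGENIC"))
  expect_equal(ann$gene_id[1], "geneA")
  # gene body beats another gene's flanking window: geneB TSS is 3400,
  # its +-1000 window covers 2400..4400 but position 3000 is geneB body
  expect_equal(ann$region[4], "INTRON")
  # unknown chromosome falls back to INTERGENIC with a warning
  expect_warning(
    ann2 <- locate_variants(data.frame(chrom = "chrZ", pos = 1,
                                       ref = "A", alt = "C"), models),
    "absent")
  expect_equal(ann2$region, "INTERGENIC")
})

test_that("coding_effect translates codons on both strands", {
  # genome: geneA.1 CDS 11..22 on + is ATG GAA TGG TAA
  seq <- paste0(strrep("T", 10), "ATGGAATGGTAA", strrep("T", 10))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  model <- list(tx_id = "tx1", gene_id = "g1", chrom = "chr1",
                strand = "+", tx_start = 11, tx_end = 22,
                exons = cbind(start = 11L, end = 22L),
                cds = cbind(start = 11L, end = 22L),
                utr5 = cbind(start = integer(0), end = integer(0)),
                utr3 = cbind(start = integer(0), end = integer(0)),
                tss = 11, tts = 22)
  # GAA -> GAG (pos 16 A->G): synonymous Glu
  expect_equal(coding_effect("chr1", 16, "A", "G", model, genome),
               "SYNONYMOUS")
  # TGG -> TGA (pos 19 G->A at codon pos 3): stop gain
  expect_equal(coding_effect("chr1", 19, "G", "A", model, genome),
               "STOP_GAIN")
  # TAA -> CAA at the terminal codon: stop loss
  expect_equal(coding_effect("chr1", 20, "T", "C", model, genome),
               "STOP_LOSS")
  # GAA -> CAA (pos 14 G->C): nonsynonymous Glu->Gln
  expect_equal(coding_effect("chr1", 14, "G", "C", model, genome),
               "NONSYNONYMOUS")
  # reference disagreement is an error
  expect_error(coding_effect("chr1", 16, "C", "G", model, genome),
               "reference mismatch")

  # minus strand: reverse complement of the same CDS
  seq2 <- paste0(strrep("T", 10),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString("ATGGAATGGTAA"))), strrep("T", 10))
  genome2 <- Biostrings::DNAStringSet(c(chr1 = seq2))
  model2 <- model
  model2$strand <- "-"
  # genomic 11..22 is TTACCATTCCAT; CDS base 6 (the GAA codon's A) sits
  # at genomic position 22 - 6 + 1 = 17, genomic base T; alt C on the
  # coding strand is G on the genome
  expect_equal(coding_effect("chr1", 17, "T", "C", model2, genome2),
               "SYNONYMOUS")
})

test_that("coding_effect agrees with a whole-CDS translation oracle", {
  ss <- shared_sim()
  models <- parse_gff3(ss$sim$paths$gff)
  genome <- ss$sim$genome
  set.seed(55)
  checked <- 0
  for (i in 1:60) {
    m <- models[[sample(length(models), 1)]]
    r <- sample(nrow(m$cds), 1)
    pos <- sample(m$cds[r, "start"]:m$cds[r, "end"], 1)
    ref <- as.character(Biostrings::subseq(genome[[m$chrom]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- coding_effect(m$chrom, pos, ref, alt, m, genome)

    # oracle: translate the full CDS from a mutated genome copy
    mut <- genome
    mut[[m$chrom]] <- Biostrings::replaceLetterAt(
      mut[[m$chrom]], pos, alt)
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_sequence(m, genome)),
      no.init.codon = TRUE))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_sequence(m, mut)), no.init.codon = TRUE))
    want <- if (aa_ref == aa_alt) "SYNONYMOUS" else {
      d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
      ra <- substr(aa_ref, d, d); ma <- substr(aa_alt, d, d)
      if (ma == "*") "STOP_GAIN" else if (ra == "*") "STOP_LOSS"
      else "NONSYNONYMOUS"
    }
    expect_equal(eff, want, info = paste(m$tx_id, pos, ref, alt))
    checked <- checked + 1
  }
  expect_equal(checked, 60)
})

test_that("summarize_annotation yields fractions that sum to one", {
  ann <- data.frame(region = c(rep("CDS", 40), rep("INTERGENIC", 60)),
                    effect = c(rep("SYNONYMOUS", 15),
                               rep("NONSYNONYMOUS", 25), rep(NA, 60)))
  s <- summarize_annotation(ann)
  expect_equal(s$regions$fraction[s$regions$category == "CDS"], 0.4)
  expect_equal(s$regions$fraction[s$regions$category == "INTERGENIC"], 0.6)
  expect_equal(sum(s$regions$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(s$effects$fraction), 1, tolerance = 1e-9)
  empty <- summarize_annotation(data.frame(region = character(0),
                                           effect = character(0)))
  expect_equal(nrow(empty$regions), 0)
})

test_that("indel_length_summary classifies lengths", {
  v <- data.frame(
    vtype = c(rep("INS", 5), rep("DEL", 5), "INS"),
    ref = c(rep("A", 5), rep("AGGG", 5), "A"),
    alt = c(rep("AT", 5), rep("A", 5),
            paste0("A", strrep("C", 30))), stringsAsFactors = FALSE)
  s <- indel_length_summary(v)
  expect_equal(unname(s$class_fractions["1bp"]), 5 / 11)
  expect_equal(max(s$insertions$length), 30)
  expect_equal(s$deletions$count[s$deletions$length == 3], 5)
  expect_equal(sum(s$class_fractions), 1)
  none <- indel_length_summary(v[0, ])
  expect_equal(nrow(none$insertions), 0)
})

test_that("select_linked_markers ranks by approximate genetic distance", {
  m <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  pos = c(1100000, 1500000, 1000000),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  # target locus at chr1:1000000; 100 kb -> 0.4 cM at 4 cM/Mb
  sel <- select_linked_markers(m, "chr1", 1000000)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$approx_cm, 0.4)
  # a wider bound admits the 500 kb marker (2 cM)
  sel2 <- select_linked_markers(m, "chr1", 1000000, cm_bound = 3)
  expect_equal(sel2$distance_bp, c(100000, 500000))
  # physical window overrides
  sel3 <- select_linked_markers(m, "chr1", 1000000, window_bp = 600000)
  expect_equal(nrow(sel3), 2)
  expect_warning(none <- select_linked_markers(m, "chr9", 1), "no markers")
  expect_equal(nrow(none), 0)
})

test_that("annotate_variants partitions simulated markers", {
  ss <- shared_sim()
  models <- parse_gff3(ss$sim$paths$gff)
  ann <- annotate_variants(ss$sim$truth, models, ss$sim$genome)
  expect_false(any(is.na(ann$region)))
  expect_true(all(ann$region %in% c("CDS", "EXON_UTR5", "EXON_UTR3",
                                    "INTRON", "TSS_REGION", "TTS_REGION",
                                    "INTERGENIC")))
  is_cds_snp <- ann$region == "CDS" & ann$vtype == "SNP"
  expect_true(all(ann$effect[is_cds_snp] %in%
                    c("SYNONYMOUS", "NONSYNONYMOUS", "STOP_GAIN",
                      "STOP_LOSS")))
  expect_true(all(ann$effect[ann$region != "CDS"] == "NONCODING"))
  expect_true(all(is.na(ann$effect[ann$region == "CDS" &
                                     ann$vtype != "SNP"])))
})
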