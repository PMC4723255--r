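test_that("identical seeds give byte-identical outputs", {
  spec <- sim_spec(seed = 12, n_chroms = 1, chrom_length = 20000,
                   n_genes = 2, n_snps = 5, n_indels = 2)
  g1 <- make_genome(spec); g2 <- make_genome(spec)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  a1 <- make_annotation(spec, g1$genome)
  a2 <- make_annotation(spec, g2$genome)
  expect_identical(a1$gff_lines, a2$gff_lines)
  v1 <- plant_variants(spec, a1$genome)
  v2 <- plant_variants(spec, a2$genome)
  expect_identical(v1$truth, v2$truth)
  p1 <- simulate_pileup(spec, a1$genome, v1$truth, "A")
  p2 <- simulate_pileup(spec, a2$genome, v2$truth, "A")
  expect_identical(p1$lines, p2$lines)
  # a different seed changes the world
  g3 <- make_genome(sim_spec(seed = 13, n_chroms = 1,
                             chrom_length = 20000))
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
})

test_that("make_genome plants exactly the requested restriction sites", {
  spec <- sim_spec(seed = 14, n_chroms = 1, chrom_length = 5600,
                   site_spacing = 500)
  g <- make_genome(spec)
  expect_equal(g$sites$chr1, seq(500, 5500, by = 500))
  # cut offset 1 puts each cut at the planted 1-based start position
  expect_equal(find_sites(g$genome[[1]], re_taqai()), g$sites$chr1)
  # gc_fraction 0 gives an A/T genome (recognition sites aside)
  at <- make_genome(sim_spec(seed = 15, n_chroms = 1,
                             chrom_length = 2000, gc_fraction = 0),
                    plant_sites = FALSE)
  expect_equal(sort(unique(strsplit(as.character(at$genome[[1]]),
                                    "")[[1]])), c("A", "T"))
})

test_that("make_annotation writes valid gene structures", {
  spec <- sim_spec(seed = 16, n_chroms = 1, chrom_length = 100000,
                   n_genes = 5)
  ann <- make_annotation(spec, make_genome(spec)$genome)
  expect_length(ann$truth, 5)
  for (m in ann$truth) {
    w <- sum(m$cds[, "end"] - m$cds[, "start"] + 1)
    expect_equal(w %% 3, 0)
    s <- cds_sequence(m, ann$genome)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 3), "ATG")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
  # zero genes: header-only GFF3
  none <- make_annotation(sim_spec(seed = 16, n_chroms = 1,
                                   chrom_length = 100000, n_genes = 0),
                          make_genome(spec)$genome)
  expect_equal(none$gff_lines, "##gff-version 3")
})

test_that("plant_variants records a consistent truth table", {
  spec <- sim_spec(seed = 17, n_chroms = 2, chrom_length = 50000,
                   n_snps = 50, n_indels = 10)
  g <- make_genome(spec)
  pv <- plant_variants(spec, g$genome)
  expect_equal(nrow(pv$truth), 60)
  # every ref allele matches the reference genome
  for (i in seq_len(nrow(pv$truth))) {
    t <- pv$truth[i, ]
    expect_equal(as.character(Biostrings::subseq(
      g$genome[[t$chrom]], t$pos, t$pos + nchar(t$ref) - 1L)), t$ref)
  }
  # spacing respected per chromosome
  for (ch in unique(pv$truth$chrom)) {
    pos <- sort(pv$truth$pos[pv$truth$chrom == ch])
    if (length(pos) > 1) expect_true(all(diff(pos) >= spec$min_spacing))
  }
  # a deletion shortens the carrier genome by its length
  dels <- pv$truth[pv$truth$vtype == "DEL", ]
  if (nrow(dels)) {
    by_carrier <- split(dels, dels$carrier)
    for (car in names(by_carrier)) {
      gv <- if (car == "A") pv$genome_a else pv$genome_b
      d <- by_carrier[[car]]
      shift <- sum(nchar(d$ref) - nchar(d$alt)) -
        sum(nchar(pv$truth$alt[pv$truth$carrier == car &
                                 pv$truth$vtype == "INS"]) -
            nchar(pv$truth$ref[pv$truth$carrier == car &
                                 pv$truth$vtype == "INS"]))
      expect_equal(sum(BiocGenerics::width(g$genome)) -
                     sum(BiocGenerics::width(gv)), shift)
    }
  }
  # zero variants leave the varieties identical
  pv0 <- plant_variants(sim_spec(seed = 17, n_chroms = 1,
                                 chrom_length = 5000, n_snps = 0,
                                 n_indels = 0), g$genome[1])
  expect_identical(as.character(pv0$genome_a),
                   as.character(pv0$genome_b))
  expect_equal(nrow(pv0$truth), 0)
})

test_that("simulate_pileup reflects alleles, depth and error rate", {
  # noiseless HOM sites show only mutant observations
  spec <- sim_spec(seed = 18, n_chroms = 1, chrom_length = 10000,
                   n_snps = 5, n_indels = 2, error_rate = 0,
                   mean_depth = 12)
  g <- make_genome(spec)
  pv <- plant_variants(spec, g$genome)
  sp <- simulate_pileup(spec, g$genome, pv$truth, "A")
  df <- parse_pileup(sp$lines)
  mine <- pv$truth[pv$truth$carrier == "A", ]
  idx <- match(paste(mine$chrom, mine$pos), paste(df$chrom, df$pos))
  cov <- !is.na(idx)
  expect_true(all(df$mut_count[idx[cov]] == df$depth[idx[cov]]))
  # positions carried by B are clean in A
  theirs <- pv$truth[pv$truth$carrier == "B", ]
  idx2 <- match(paste(theirs$chrom, theirs$pos), paste(df$chrom, df$pos))
  expect_true(all(df$mut_total[idx2[!is.na(idx2)]] == 0))

  # zero depth produces no lines
  sp0 <- simulate_pileup(sim_spec(seed = 18, n_chroms = 1,
                                  chrom_length = 2000, mean_depth = 0,
                                  n_snps = 0, n_indels = 0),
                         g$genome[1], empty_truth(), "A")
  expect_length(sp0$lines, 0)

  # aggregate mismatch rate at non-variant sites tracks the error rate
  spec_e <- sim_spec(seed = 19, n_chroms = 1, chrom_length = 50000,
                     n_snps = 0, n_indels = 0, error_rate = 0.01)
  ge <- make_genome(spec_e)
  dfe <- parse_pileup(simulate_pileup(spec_e, ge$genome, empty_truth(),
                                      "A")$lines)
  n_obs <- sum(dfe$depth)
  rate <- sum(dfe$mut_total) / n_obs
  se <- sqrt(0.01 * 0.99 / n_obs)
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("evaluate_calls computes precision and recall", {
  truth <- data.frame(chrom = "chr1", pos = 1:10 * 100, ref = "A",
                      alt = "G", vtype = "SNP", stringsAsFactors = FALSE)
  calls <- truth
  perfect <- evaluate_calls(calls, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  nothing <- evaluate_calls(calls[0, ], truth)
  expect_true(is.na(nothing$precision))
  expect_equal(nothing$recall, 0)

  miss1 <- evaluate_calls(calls[-1, ], truth)
  expect_equal(miss1$recall, 0.9)
  expect_equal(miss1$precision, 1)
  # a wrong allele is a false positive, not a match
  wrong <- calls
  wrong$alt[1] <- "T"
  ev <- evaluate_calls(wrong, truth)
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 0.9)
})

test_that("simulate_dataset writes a complete fixture directory", {
  ss <- shared_sim()
  for (p in ss$sim$paths) expect_true(file.exists(p))
  truth_back <- read.delim(ss$sim$paths$truth,
                           colClasses = c(ref = "character",
                                          alt = "character"))
  expect_equal(nrow(truth_back), nrow(ss$sim$truth))
})
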