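# shared builders and independent oracles for the test suite

mk_read <- function(quals, bases = NULL, id = "r") {
  if (is.null(bases))
    bases <- paste(rep_len(c("A", "C", "G", "T"), length(quals)),
                   collapse = "")
  seq_read(id, bases, quals)
}

random_read <- function(len = 84) {
  mk_read(sample(0:41, len, replace = TRUE),
          paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = ""))
}

# brute-force per-base tally oracle for the filtering standards
oracle_classify <- function(read, standard) {
  tab <- switch(standard,
    strict   = list(c(10, 0.07), c(13, 0.07), c(20, 0.15)),
    moderate = list(c(10, 0.10), c(13, 0.14), c(20, 0.20)),
    relax    = list(c(10, 0.15), c(13, 0.20)),
    none     = list())
  n <- length(read$quals)
  for (cond in tab) {
    below <- 0
    for (q in read$quals) if (q < cond[1]) below <- below + 1
    if (below / n > cond[2]) return("DISCARD")
  }
  "KEEP"
}

# naive O(n*m) sliding-window motif scan (digestion oracle)
oracle_find_sites <- function(seq, motif, cut_offset) {
  seq <- toupper(as.character(seq)); m <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(max(0, nchar(seq) - m + 1)))
    if (substr(seq, i, i + m - 1) == motif) hits <- c(hits, i)
  hits - 1L + cut_offset
}

# build one pileup line from explicit allele counts; returns the line
# and the expected decode. Indels ride on reference-match observations
# (samtools semantics), '^'/'$' decorations added at random.
random_pileup_site <- function(chrom = "chr1", pos = 100L) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  n_ref <- sample(2:12, 1)
  mis_bases <- sample(setdiff(c("A", "C", "G", "T"), ref),
                      sample(0:2, 1))
  mis_counts <- setNames(sample(1:4, length(mis_bases), replace = TRUE),
                         mis_bases)
  n_star <- sample(0:2, 1)
  n_indel_alleles <- sample(0:2, 1)
  indels <- integer(0)
  if (n_indel_alleles > 0) {
    keys <- unique(replicate(n_indel_alleles, paste0(
      sample(c("ins", "del"), 1), ":",
      paste(sample(c("A", "C", "G", "T"), sample(1:5, 1), replace = TRUE),
            collapse = ""))))
    indels <- setNames(sample(1:2, length(keys), replace = TRUE), keys)
  }
  if (sum(indels) > n_ref) n_ref <- sum(indels) + sample(1:3, 1)

  ref_tok <- sample(c(".", ","), n_ref, replace = TRUE)
  i <- 1L
  for (k in seq_along(indels)) {
    parts <- strsplit(names(indels)[k], ":", fixed = TRUE)[[1]]
    suffix <- paste0(if (parts[1] == "ins") "+" else "-",
                     nchar(parts[2]), parts[2])
    for (r in seq_len(indels[k])) {
      ref_tok[i] <- paste0(ref_tok[i], suffix)
      i <- i + 1L
    }
  }
  mis_tok <- unlist(lapply(seq_along(mis_counts), function(k) {
    b <- names(mis_counts)[k]
    sample(c(b, tolower(b)), mis_counts[k], replace = TRUE)
  }))
  toks <- sample(c(ref_tok, mis_tok, rep("*", n_star)))
  if (runif(1) < 0.3) toks[1] <- paste0("^F", toks[1])
  if (runif(1) < 0.3) toks[length(toks)] <- paste0(toks[length(toks)], "$")
  depth <- n_ref + sum(mis_counts) + n_star
  line <- paste(chrom, pos, ref, depth, paste(toks, collapse = ""),
                strrep("E", depth), sep = "\t")
  list(line = line, ref = ref, depth = depth, n_ref = n_ref,
       mis_counts = mis_counts, n_star = n_star, indels = indels)
}

# hand-built pileup line: n_ref reference reads + 'mut' reads of base
# 'alt' (or an indel token when alt is like "+2TT"/"-1A")
mk_pileup_line <- function(chrom, pos, ref, n_ref, mut = 0, alt = "G") {
  mut_tok <- if (grepl("^[+-]", alt)) strrep(paste0(".", alt), mut)
             else strrep(alt, mut)
  depth <- n_ref + mut  # an indel-carrying read still has one base obs
  bases <- paste0(strrep(".", n_ref), mut_tok)
  paste(chrom, pos, ref, depth, bases, strrep("I", depth), sep = "\t")
}

empty_truth <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vtype = character(0),
             carrier = character(0), zygosity = character(0),
             indel_len = integer(0), stringsAsFactors = FALSE)
}

# one small simulated dataset shared across tests (built once per run)
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    spec <- sim_spec(seed = 42, n_chroms = 1, chrom_length = 60000,
                     n_genes = 6, n_snps = 30, n_indels = 8)
    dir <- file.path(tempdir(), "radmarker-shared-sim")
    .shared$spec <- spec
    .shared$sim <- simulate_dataset(spec, dir)
  }
  list(spec = .shared$spec, sim = .shared$sim)
}
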