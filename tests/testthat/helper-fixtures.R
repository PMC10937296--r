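# Deterministic fixtures built in code.

# Ten-site filter toy with a hand-audited telescoping report.
# Six samples (3 reduced, 3 enlarged); thresholds: coverage >= 10, upper
# percentile disabled, >= 2 covered individuals per treatment, mean
# methylation within (0.05, 0.95).
#   sites 1-2: every cell below 10x        -> lost at the coverage stage
#   sites 3-5: covered in < 2 individuals of one treatment -> presence stage
#   site 6:    mean methylation 0.99       -> mean-methylation stage
#   sites 7-10: pass everything
make_filter_toy <- function() {
  sites <- data.frame(chrom = "chr1", pos = seq(100, 1000, by = 100))
  samples <- c("r1", "r2", "r3", "e1", "e2", "e3")
  tot <- matrix(20L, 10, 6, dimnames = list(NULL, samples))
  meth <- matrix(10L, 10, 6, dimnames = list(NULL, samples))
  tot[1:2, ] <- 5L; meth[1:2, ] <- 2L          # all cells < 10x
  tot[3, 4:5] <- 5L; meth[3, 4:5] <- 2L        # only e3 covered in enlarged
  tot[4, 1:2] <- 5L; meth[4, 1:2] <- 2L        # only r3 covered in reduced
  tot[5, c(4, 6)] <- 5L; meth[5, c(4, 6)] <- 2L # only e2 covered in enlarged
  meth[6, ] <- 20L; meth[6, 1] <- 19L          # mean methylation 0.99+
  design <- data.frame(
    bird_id = samples,
    treatment = factor(rep(c("reduced", "enlarged"), each = 3),
                       levels = c("reduced", "enlarged"))
  )
  cfg <- filter_config(min_coverage = 10, coverage_percentile_cut = 100,
                       min_individuals_per_group = 2)
  list(matrix = meth_matrix(sites, samples, meth, tot),
       design = design, config = cfg)
}

# GFF3 toy: one characterised plus-strand gene with both UTRs, one LOC and
# one characterised gene for flank tie-breaks, one minus-strand gene.
write_toy_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t10001\t20000\t.\t+\t.\tID=gene1;Name=GENE1",
    "chr1\ttoy\tmRNA\t10001\t20000\t.\t+\t.\tID=rna1;Parent=gene1",
    "chr1\ttoy\texon\t10001\t20000\t.\t+\t.\tID=exon1;Parent=rna1",
    "chr1\ttoy\tfive_prime_UTR\t10001\t10400\t.\t+\t.\tID=utr5;Parent=rna1",
    "chr1\ttoy\tthree_prime_UTR\t19700\t20000\t.\t+\t.\tID=utr3;Parent=rna1",
    "chr2\ttoy\tgene\t27400\t28000\t.\t+\t.\tID=gene2;Name=LOC555",
    "chr2\ttoy\tgene\t20000\t21500\t.\t+\t.\tID=gene3;Name=GENE3",
    "chr3\ttoy\tgene\t10001\t20000\t.\t-\t.\tID=gene4;Name=GENE4"
  )
  writeLines(lines, path)
  path
}

# six CpG positions hitting one annotation class each on the toy gene
# (with UTRs ranked above the gene body)
toy_annotation_sites <- function() {
  data.frame(
    chrom = "chr1",
    pos = c(9800L,   # TSS window  [9701, 10051]
            8500L,   # promoter    [8001, 10201], beats the upstream flank
            10300L,  # 5' UTR      (past the promoter's +200 bp edge)
            19800L,  # 3' UTR
            15000L,  # gene body
            25000L), # downstream flank (20001, 30000]
    expected = c("TSS", "promoter", "five_prime_UTR", "three_prime_UTR",
                 "gene_body", "downstream"),
    stringsAsFactors = FALSE
  )
}
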