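toy_loci <- function(starts, ends, chrom = "chr1") {
  data.frame(locus_id = sprintf("%s:%d-%d", chrom, starts + 1, ends),
             chrom = chrom, start = starts, end = ends, strand = "*",
             stringsAsFactors = FALSE)
}

toy_track <- function(starts, ends, chrom = "chr1", name = "trk",
                      kind = "CpG_island") {
  annotation_track(name, kind, data.frame(chrom = chrom, start = starts,
                                          end = ends, strand = "*"))
}

test_that("overlap flags use half-open arithmetic", {
  loci <- toy_loci(100, 200)
  expect_true(overlap_flags(loci, list(toy_track(199, 300)))$trk)   # 1 bp
  expect_false(overlap_flags(loci, list(toy_track(200, 300)))$trk)  # abutting
  expect_false(overlap_flags(loci, list(toy_track(50, 100)))$trk)
  expect_equal(ncol(overlap_flags(loci, list())), 1L)               # no tracks

  # chromosome absent from the track: flags are false, not an error
  expect_false(overlap_flags(loci, list(toy_track(100, 200,
                                                  chrom = "chr9")))$trk)
})

test_that("overlap flags equal a brute-force all-pairs scan on random fixtures", {
  set.seed(44)
  for (rep in 1:5) {
    ls <- sample.int(1e5, 200)
    loci <- toy_loci(ls, ls + sample.int(500, 200),
                     chrom = sample(c("chr1", "chr2"), 200, TRUE))
    loci$locus_id <- paste0(loci$locus_id, "_", seq_len(200))  # force unique
    ts <- sample.int(1e5, 300)
    iv <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), 300, TRUE),
                     start = ts, end = ts + sample.int(400, 300), strand = "*")
    track <- annotation_track("rand", "other", iv)
    expect_equal(overlap_flags(loci, list(track))$rand,
                 oracle_overlaps(loci, iv))
  }
})

test_that("gene mapping follows the strand-aware 10 kb promoter rule", {
  genes <- gene_models(data.frame(symbol = "G1", transcript = "NM_1",
                                  chrom = "chr1", start = 5000, end = 8000,
                                  strand = "+"))
  # within 10 kb upstream of the TSS at 5000
  expect_equal(map_to_genes(toy_loci(1000, 1200), genes)$category, "PRO")
  # inside the body
  expect_equal(map_to_genes(toy_loci(6000, 6100), genes)$category, "GB")
  # 15 kb upstream: outside the window
  big <- gene_models(data.frame(symbol = "G1", transcript = "NM_1",
                                chrom = "chr1", start = 20000, end = 23000,
                                strand = "+"))
  expect_equal(map_to_genes(toy_loci(4000, 4100), big)$category, "none")
  # promoter window excludes the TSS base itself (it belongs to the body)
  expect_equal(map_to_genes(toy_loci(4999, 5000), genes)$category, "PRO")
  expect_equal(map_to_genes(toy_loci(5000, 5001), genes)$category, "GB")

  expect_error(map_to_genes(toy_loci(1, 2), genes, upstream_window = 0),
               "upstream_window")
})

test_that("gene mapping is strand-symmetric under coordinate mirroring", {
  set.seed(5)
  L <- 1e6
  starts <- sample.int(L - 2000, 40)
  loci <- toy_loci(starts, starts + sample.int(1000, 40))
  loci$locus_id <- paste0(loci$locus_id, "_", seq_len(40))
  gs <- sample.int(L - 20000, 15)
  genes <- gene_models(data.frame(
    symbol = paste0("G", 1:15), transcript = paste0("NM_", 1:15),
    chrom = "chr1", start = gs, end = gs + sample(2000:8000, 15),
    strand = sample(c("+", "-"), 15, TRUE)))

  mirror_iv <- function(s, e) list(start = L - e, end = L - s)
  m_loci <- loci
  mi <- mirror_iv(loci$start, loci$end)
  m_loci$start <- mi$start; m_loci$end <- mi$end
  m_genes <- genes
  gi <- mirror_iv(genes$start, genes$end)
  m_genes$start <- gi$start; m_genes$end <- gi$end
  m_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  m_genes <- gene_models(m_genes[, setdiff(names(m_genes), "tss")])

  a <- map_to_genes(loci, genes)
  b <- map_to_genes(m_loci, m_genes)
  expect_equal(a$category, b$category)
  expect_equal(a$symbols, b$symbols)
})

test_that("bidirectional promoters need opposite strands; GB beats PRO", {
  genes <- gene_models(data.frame(
    symbol = c("R", "L"), transcript = c("NM_1", "NM_2"), chrom = "chr1",
    start = c(8000, 1000), end = c(12000, 3000), strand = c("+", "-")))
  # locus between the head-to-head pair: upstream of both TSSs
  expect_equal(map_to_genes(toy_loci(4000, 5000), genes)$category, "PRO2")

  same_strand <- gene_models(data.frame(
    symbol = c("A", "B"), transcript = c("NM_1", "NM_2"), chrom = "chr1",
    start = c(8000, 9000), end = c(12000, 13000), strand = "+"))
  expect_equal(map_to_genes(toy_loci(4000, 5000), same_strand)$category, "PRO")

  # locus in R's body and L's promoter zone: category GB, both genes listed
  overlapping <- gene_models(data.frame(
    symbol = c("R", "L"), transcript = c("NM_1", "NM_2"), chrom = "chr1",
    start = c(8000, 1000), end = c(12000, 8500), strand = c("+", "-")))
  hit <- map_to_genes(toy_loci(8100, 8200), overlapping)
  expect_equal(hit$category, "GB")
  expect_true(grepl("R", hit$symbols) && grepl("L", hit$symbols))
})

test_that("enrichment scores equal exhaustive hypergeometric summation", {
  r <- enrichment_score(3, 5, 6, 20)
  expect_equal(r$p, oracle_hyper_tail(3, 5, 6, 20), tolerance = 1e-12)
  expect_equal(r$score, -log10(oracle_hyper_tail(3, 5, 6, 20)),
               tolerance = 1e-12)

  expect_equal(enrichment_score(0, 5, 6, 20)$p, 1)
  expect_equal(enrichment_score(0, 5, 6, 20)$score, 0)
  expect_equal(enrichment_score(7, 7, 7, 7)$p, 1)    # certain event

  # monotone non-decreasing in overlap, and equal to the oracle throughout
  scores <- sapply(0:5, function(o) {
    r <- enrichment_score(o, 5, 6, 20)
    expect_equal(r$p, oracle_hyper_tail(o, 5, 6, 20), tolerance = 1e-12)
    r$score
  })
  expect_false(is.unsorted(scores))

  expect_error(enrichment_score(6, 5, 6, 20), "inconsistent")
  expect_error(enrichment_score(2, 5, 25, 20), "inconsistent")
})

test_that("candidate reports carry printed positions and sorted rows", {
  set.seed(10)
  k <- 4
  st <- paired_t_scan(toy_paired_matrix(matrix(rnorm(3 * k), 3, k),
                                        matrix(rnorm(3 * k, 1), 3, k)),
                      toy_samples(k))
  rep1 <- build_candidate_report(st)
  expect_equal(nrow(rep1), 3L)
  expect_false(is.unsorted(rep1$p_x1e6))
  # difference comes from the unrounded means, so it can differ from the
  # difference of the rounded means by up to one rounding unit
  expect_true(all(abs(rep1$difference -
                        (rep1$mean_case - rep1$mean_control)) <= 0.0105))
  expect_match(rep1$position[1], "^chr1:[0-9]+-[0-9]+$")

  expect_equal(nrow(build_candidate_report(st[0, ])), 0L)

  flags <- data.frame(locus_id = "nonexistent", cpg = TRUE)
  expect_error(build_candidate_report(st, flags), "unmatched")
})

test_that("transcribed candidate-table rows verify difference arithmetic", {
  tab <- read.delim(system.file("extdata", "candidate_loci.tsv",
                                package = "helpscan"))
  expect_equal(nrow(tab), 56L)
  # printed difference equals case minus control within rounding resolution
  expect_true(all(abs((tab$mean_case - tab$mean_control) - tab$difference)
                  <= 0.0105))
  # spot anchor: the autophagy-gene locus row
  row <- tab[tab$position == "chr6:106879977-106880120", ]
  expect_equal(row$mean_case - row$mean_control, -0.78)
})
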