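# Variant filtering, SNP index arithmetic, window scan, permutation
# thresholds and region calling.

toy_variant_table <- function() {
  # six records: one low parent depth, one low pool depth, one monomorphic,
  # one heterozygous parent, two clean
  data.frame(
    chrom = "Chr01", pos = 1:6 * 1000, ref = "A", alt = "T",
    P1_depth = c(2, 20, 20, 20, 20, 20),
    P2_depth = c(20, 20, 20, 20, 20, 20),
    P1_gt = c("1/1", "1/1", "0/0", "0/1", "1/1", "1/1"),
    P2_gt = c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),
    egusi_ref_depth = c(5, 1, 5, 5, 5, 5),
    egusi_alt_depth = c(5, 1, 5, 5, 5, 5),
    non_egusi_ref_depth = 5, non_egusi_alt_depth = 5,
    stringsAsFactors = FALSE)
}

test_that("variant filters drop exactly the failing records with a tally", {
  filt <- filter_variants(toy_variant_table(), parents = c("P1", "P2"))
  expect_equal(nrow(filt), 2)
  expect_equal(filt$pos, c(5000, 6000))
  tally <- attr(filt, "removal_tally")
  expect_equal(unname(tally[c("low_parent_depth", "low_pool_depth",
                              "parents_monomorphic",
                              "parent_heterozygous")]),
               c(1L, 1L, 1L, 1L))
})

test_that("a clean table passes unchanged and an empty one stays empty", {
  tab <- toy_variant_table()[5:6, ]
  filt <- filter_variants(tab, parents = c("P1", "P2"))
  expect_equal(nrow(filt), 2)
  expect_equal(sum(attr(filt, "removal_tally")), 0L)
  empty <- filter_variants(tab[0, ], parents = c("P1", "P2"))
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "removal_tally")), 0L)
  expect_error(filter_variants(tab[, 1:4], parents = c("P1", "P2")),
               "missing required columns")
})

test_that("SNP index and delta follow their definitions and bounds", {
  expect_equal(snp_index(10, 0), 0)
  expect_equal(snp_index(0, 12), 1)
  expect_equal(snp_index(7, 7), 0.5)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(-1, 5), "non-negative")
  expect_equal(delta_index(1.0, 0.5), 0.5)
  expect_equal(delta_index(0.5, 1.0), -0.5)
  expect_equal(delta_index(0.3, 0.3), 0)
  set.seed(41)
  idx <- snp_index(rpois(200, 10), rpois(200, 10))
  expect_true(all(idx >= 0 & idx <= 1, na.rm = TRUE))
})

test_that("a single SNP is covered by exactly window/step windows", {
  snps <- data.frame(chrom = "Chr06", pos = 7e6, delta = 0.5)
  scan <- window_scan(snps, window = 250000, step = 5000, min_snps = 1)
  def <- !is.na(scan$delta_mean)
  expect_equal(sum(def), 50)
  expect_true(all(scan$delta_mean[def] == 0.5))
  expect_true(all(scan$start[def] > 7e6 - 250000 & scan$start[def] <= 7e6))
  expect_true(all(scan$start %% 5000 == 0))
  expect_equal(scan$end - scan$start, rep(250000, nrow(scan)))
})

test_that("constant delta gives constant window means; sparse windows are undefined", {
  snps <- data.frame(chrom = "Chr01", pos = seq(1e4, 1e6, 1e4), delta = 0.2)
  scan <- window_scan(snps, window = 1e5, step = 2e4, min_snps = 3)
  def <- !is.na(scan$delta_mean)
  expect_true(any(def))
  expect_true(all(abs(scan$delta_mean[def] - 0.2) < 1e-12))
  lone <- window_scan(data.frame(chrom = "Chr01", pos = 5e5, delta = 1),
                      window = 1e5, step = 2e4, min_snps = 3)
  expect_true(all(is.na(lone$delta_mean)))
})

test_that("swapping the pools negates every delta and window mean", {
  set.seed(42)
  pos <- sort(sample.int(2e6, 150))
  re <- rpois(150, 15); ae <- rpois(150, 15)
  ro <- rpois(150, 15); ao <- rpois(150, 15)
  d1 <- delta_index(snp_index(re, ae), snp_index(ro, ao))
  d2 <- delta_index(snp_index(ro, ao), snp_index(re, ae))
  expect_equal(d1, -d2)
  s1 <- window_scan(data.frame(chrom = "C", pos = pos, delta = d1),
                    1e5, 2.5e4, 1)
  s2 <- window_scan(data.frame(chrom = "C", pos = pos, delta = d2),
                    1e5, 2.5e4, 1)
  expect_equal(s1$delta_mean, -s2$delta_mean)
})

test_that("permutation thresholds are deterministic and shrink with depth", {
  d30 <- rep(30, 8)
  t1 <- permutation_threshold(d30, d30, 20, 20, "BC1", 1000, 0.99, seed = 43)
  t2 <- permutation_threshold(d30, d30, 20, 20, "BC1", 1000, 0.99, seed = 43)
  expect_identical(t1, t2)
  expect_gt(t1, 0)
  # with enormous pools and depth the null concentrates at zero
  dbig <- rep(10000, 8)
  tbig <- permutation_threshold(dbig, dbig, 10000, 10000, "BC1", 500, 0.99,
                                seed = 44)
  expect_lt(tbig, 0.02)
  expect_lt(tbig, t1)
  expect_warning(
    permutation_threshold(d30, d30, 20, 20, "BC1", 50, 0.99, seed = 45),
    "unstable")
})

test_that("region calling merges runs and respects the step grid", {
  snps <- data.frame(chrom = "Chr01", pos = seq(1e4, 1e6, 1e4), delta = 0)
  scan <- window_scan(snps, 1e5, 2e4, 1)
  scan$threshold <- 0.3
  scan$significant <- FALSE
  expect_equal(nrow(call_regions(scan)), 0)
  # two separated runs of significant windows
  scan$significant[scan$start %in% c(1e5, 1.2e5, 1.4e5)] <- TRUE
  scan$significant[scan$start == 6e5] <- TRUE
  scan$delta_mean[scan$significant] <- 0.5
  regs <- call_regions(scan)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$from_bp, c(1e5, 6e5))
  expect_equal(regs$to_bp, c(2.4e5, 7e5))
  expect_true(all(regs$from_bp %% 2e4 == 0 & regs$to_bp %% 2e4 == 0))
})

test_that("a planted BC1 locus yields one containing region per affected chromosome", {
  p <- default_parents()
  g <- genome_spec(n_chrom = 3, length_bp = c(2e6, 2e6, 3e6),
                   length_cM = 82.2 * c(2, 2, 3) / 36.5)
  m <- epistasis_model(locus("eg", 3, 1.5e6, g), locus("su", 1, 1e6, g))
  bc1 <- make_cross("BC1F1", list(p$B3, p$B4), 120, m, g, seed = 46)
  pools <- make_pools(bc1, 20, seed = 47)
  snps <- lapply(stats::setNames(g$length_bp, g$chrom_names),
                 function(L) seq(12500, L, 25000))
  tab <- simulate_pooled_counts(bc1, pools, snps, mean_depth = 30, seed = 48)
  res <- bsa_scan(tab, design = "BC1", window = 250000, step = 25000,
                  n_perm = 1000, seed = 49)
  hit <- res$regions[res$regions$chrom == "Chr03" &
                       res$regions$from_bp <= 1.5e6 &
                       res$regions$to_bp >= 1.5e6, ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$peak_delta, 0.3)
})

test_that("two planted loci on different chromosomes give two regions", {
  # genotype-defined extreme pools in an F2: both loci fully differentiate
  p <- default_parents()
  g <- genome_spec(n_chrom = 3, length_bp = 2e6, length_cM = 82.2 * 2 / 36.5)
  m <- epistasis_model(locus("eg", 3, 1.5e6, g), locus("su", 1, 1e6, g))
  f2 <- make_cross("F2", list(p$B3, p$X1625), 600, m, g, seed = 50)
  lo <- which(f2$main_geno == "aa" & f2$supp_geno == "BB")
  hi <- which(f2$main_geno == "AA" & f2$supp_geno == "bb")
  pools <- list(egusi = lo[1:15], non_egusi = hi[1:15])
  snps <- lapply(stats::setNames(g$length_bp, g$chrom_names),
                 function(L) seq(12500, L, 25000))
  tab <- simulate_pooled_counts(f2, pools, snps, mean_depth = 30, seed = 51)
  res <- bsa_scan(tab, design = "F2", m_egusi = 15, m_other = 15,
                  window = 250000, step = 25000, n_perm = 1000, seed = 52)
  for (want in list(c("Chr03", 1.5e6), c("Chr01", 1e6))) {
    hit <- res$regions[res$regions$chrom == want[1] &
                         res$regions$from_bp <= as.numeric(want[2]) &
                         res$regions$to_bp >= as.numeric(want[2]), ]
    expect_equal(nrow(hit), 1)
  }
})
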