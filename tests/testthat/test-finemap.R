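# Graphical genotypes, recombinant constraints, interval narrowing,
# cosegregation, marker QC.

test_that("breakpoints are localized between informative markers", {
  panel <- data.frame(name = c("m1", "m2", "m3", "m4"), chrom = "Chr06",
                      pos_bp = c(100, 200, 300, 400))
  calls <- rbind(i1 = c("a", "a", "a", "a"),
                 i2 = c("a", "a", "h", "h"),
                 i3 = c("a", NA, "h", "h"))
  colnames(calls) <- panel$name
  gg <- graphical_genotype(panel, calls, rep("egusi", 3), "BC1")
  rec <- detect_recombinants(gg)
  expect_false(rec$recombinant[["i1"]])
  expect_equal(nrow(rec$breakpoints[["i1"]]), 0)
  expect_equal(rec$breakpoints[["i2"]]$left_marker, "m2")
  expect_equal(rec$breakpoints[["i2"]]$right_marker, "m3")
  # missing call is transparent: breakpoint spans m1..m3
  expect_equal(rec$breakpoints[["i3"]]$left_marker, "m1")
  expect_equal(rec$breakpoints[["i3"]]$right_marker, "m3")
})

test_that("individuals with no informative call are excluded with a warning", {
  panel <- data.frame(name = c("m1", "m2"), chrom = "Chr06",
                      pos_bp = c(100, 200))
  calls <- rbind(i1 = c("a", "a"), i2 = c(NA, NA))
  colnames(calls) <- panel$name
  gg <- graphical_genotype(panel, calls, c("egusi", "egusi"), "BC1")
  expect_warning(rec <- detect_recombinants(gg), "i2")
  expect_equal(rec$excluded, "i2")
})

test_that("phenotype constraints follow the recessive model", {
  panel <- data.frame(name = c("m1", "m2", "m3", "m4"), chrom = "Chr06",
                      pos_bp = c(100, 200, 300, 400))
  mk_gg <- function(calls1, pheno) {
    calls <- matrix(calls1, 1, dimnames = list("x", panel$name))
    graphical_genotype(panel, calls, pheno, "BC1")
  }
  # non-recombinant consistent: whole panel allowed
  allw <- phenotype_constraint(mk_gg(c("a", "a", "a", "a"), "egusi"), 1)
  expect_equal(allw$start_bp, 100)
  expect_equal(allw$end_bp, 400)
  # egusi, a then h: allowed left of the first inconsistent marker
  seg <- phenotype_constraint(mk_gg(c("a", "a", "h", "h"), "egusi"), 1)
  expect_equal(seg$start_bp, 100)
  expect_equal(seg$end_bp, 300)
  expect_equal(seg$right_marker, "m3")
  # egusi but all heterozygous: impossible under the model
  none <- phenotype_constraint(mk_gg(c("h", "h", "h", "h"), "egusi"), 1)
  expect_equal(nrow(none), 0)
  # unknown phenotype: no constraint
  unk <- phenotype_constraint(mk_gg(c("a", "h", "a", "h"), NA), 1)
  expect_equal(unk$start_bp, 100)
  expect_equal(unk$end_bp, 400)
})

test_that("the three published interval widths are reproduced by the fixtures", {
  # 19CB2 RAD panel: 452.7 kb, one inconsistent plant (B2-28)
  r1 <- narrow_interval(gg_19cb2())
  expect_equal(r1$interval$start_bp, 6910159)
  expect_equal(r1$interval$end_bp, 7362904)
  expect_equal(r1$interval$width_kb, 452.7)
  expect_equal(r1$inconsistent, "B2-28")
  # BC1F2 PCR-marker panel: 209.3 kb between N6-23 and N6-53
  r2 <- narrow_interval(gg_bc1f2())
  expect_equal(r2$interval$width_bp, 209320)
  expect_equal(r2$interval$width_kb, 209.3)
  expect_equal(r2$interval$left_marker, "N6-23")
  expect_equal(r2$interval$right_marker, "N6-53")
  expect_equal(r2$n_recombinant, 10)
  # 16CB1 recombinants: 15.7 kb between N6-25 and N6-43
  r3 <- narrow_interval(gg_16cb1())
  expect_equal(r3$interval$start_bp, 7040484)
  expect_equal(r3$interval$end_bp, 7056134)
  expect_equal(r3$interval$width_bp, 15650)
  expect_equal(r3$interval$width_kb, 15.7)
  expect_equal(r3$interval$left_marker, "N6-25")
  expect_equal(r3$interval$right_marker, "N6-43")
  expect_equal(length(r3$inconsistent), 0)
})

test_that("interval widths match the published marker distances", {
  panel <- chr6_marker_panel()
  w <- interval_width("N6-25", "N6-43", panel)
  expect_equal(w$width_bp, 15650)
  expect_equal(w$width_kb, 15.7)
  w2 <- interval_width("N6-23", "N6-53", panel)
  expect_equal(w2$width_bp, 209320)
  expect_equal(w2$width_kb, 209.3)
  expect_equal(interval_width("N6-25", "N6-25", panel)$width_bp, 0)
  other <- data.frame(name = "x", chrom = "Chr01", pos_bp = 100)
  expect_error(interval_width(panel[13, ], other[1, ]), "different chromosomes")
})

test_that("narrowing is monotone and order-invariant", {
  gg <- gg_16cb1()
  r_all <- narrow_interval(gg)
  # drop the two tightest recombinants: interval can only widen
  keep <- setdiff(rownames(gg$calls), c("16CB1-206", "16CB1-240"))
  gg_sub <- graphical_genotype(gg$markers, gg$calls[keep, ],
                               gg$phenotype[match(keep, rownames(gg$calls))],
                               "BC1")
  r_sub <- narrow_interval(gg_sub)
  expect_lte(r_sub$interval$start_bp, r_all$interval$start_bp)
  expect_gte(r_sub$interval$end_bp, r_all$interval$end_bp)
  # permuting individuals changes nothing
  set.seed(61)
  perm <- sample(nrow(gg$calls))
  gg_perm <- graphical_genotype(gg$markers, gg$calls[perm, ],
                                gg$phenotype[perm], "BC1")
  r_perm <- narrow_interval(gg_perm)
  expect_equal(r_perm$interval$start_bp, r_all$interval$start_bp)
  expect_equal(r_perm$interval$end_bp, r_all$interval$end_bp)
})

test_that("narrow_interval matches the brute-force consistency oracle", {
  set.seed(62)
  n_match <- 0
  for (case in 1:200) {
    gg <- random_gg(n_markers = sample(4:10, 1), n_ind = sample(3:20, 1),
                    design = sample(c("BC1", "selfed"), 1))
    orc <- oracle_narrow(gg)
    if (is.na(orc$start)) {
      expect_error(narrow_interval(gg))
      next
    }
    res <- narrow_interval(gg)
    expect_equal(res$interval$start_bp, orc$start)
    expect_equal(res$interval$end_bp, orc$end)
    expect_setequal(res$inconsistent, orc$inconsistent)
    n_match <- n_match + 1
  }
  expect_gt(n_match, 100)  # most random panels are solvable
})

test_that("fine-mapping fixtures from published positions contain a planted locus", {
  # simulated BC1 with the causal position inside the panel: the returned
  # interval always contains it, and more plants give narrower intervals
  p <- default_parents()
  g <- genome_spec(n_chrom = 2, length_bp = 8e6, length_cM = 82.2 * 8 / 36.5)
  m <- epistasis_model(locus("eg", 2, 7e6, g), locus("su", 1, 1e6, g))
  panel <- data.frame(name = sprintf("s%02d", 1:9), chrom = "Chr02",
                      pos_bp = seq(5e6, 8e6, length.out = 9))
  widths <- c()
  for (n in c(30, 120)) {
    pop <- make_cross("BC1F1", list(p$B3, p$B4), n, m, g, seed = 63 + n)
    calls <- marker_calls(pop, panel)
    gg <- graphical_genotype(panel, calls, pop$phenotype, "BC1")
    res <- narrow_interval(gg)
    expect_lte(res$interval$start_bp, 7e6)
    expect_gte(res$interval$end_bp, 7e6)
    widths <- c(widths, res$interval$width_bp)
  }
  expect_lte(widths[2], widths[1])
  expect_lt(widths[2], 3e6)  # far narrower than the panel span
})

test_that("cosegregation check flags mismatched plants and Haldane distances", {
  gg <- gg_16cb1()
  # markers inside the final interval cosegregate in the fixture
  expect_true(cosegregation_check(gg, "N6-32")$cosegregates)
  # a marker outside it does not (the recombinants disagree)
  chk <- cosegregation_check(gg, "N6-45")
  expect_false(chk$cosegregates)
  expect_true("16CB1-153" %in% chk$mismatched)
})

test_that("marker QC removes high-missingness and distorted markers", {
  set.seed(64)
  panel <- data.frame(name = c("good", "holey", "skewed"), chrom = "Chr06",
                      pos_bp = c(100, 200, 300))
  n <- 99
  calls <- cbind(good = sample(c("a", "h"), n, TRUE),
                 holey = ifelse(runif(n) < 0.65, NA, "a"),
                 skewed = c(rep("a", 80), rep("h", 19)))
  rownames(calls) <- sprintf("i%02d", 1:n)
  gg <- graphical_genotype(panel, calls, rep("egusi", n), "BC1")
  filt <- filter_markers(gg)
  expect_equal(gg$markers$name[gg$markers$name %in% filt$markers$name], "good")
  removed <- attr(filt, "removed")
  expect_equal(removed$reason[removed$name == "holey"], "excess_missing")
  expect_equal(removed$reason[removed$name == "skewed"],
               "segregation_distortion")
  # the 80:19 distortion corresponds to chi2 = 37.6
  expect_equal(round(chi_square_gof(c(80, 19), "1:1")$chi2, 1), 37.6)
  expect_error(filter_markers(gg, distortion_alpha = 1), "all markers removed")
})
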