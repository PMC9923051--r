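# Fixtures and independent oracles used across the test files.
# Marker names/positions follow the published chromosome-6 panel; the
# per-individual genotype calls are synthetic, constructed to encode the
# narrative recombinant constraints (the per-plant calls themselves are not
# tabulated in any source).

chr6_marker_panel <- function() {
  data.frame(
    type = c("InDel", "InDel", "dCAPS", "InDel", "dCAPS", "InDel", "InDel",
             "CAPS", "dCAPS", "CAPS", "dCAPS", "dCAPS", "dCAPS", "dCAPS",
             "dCAPS", "InDel", "InDel", "InDel", "InDel", "InDel", "InDel",
             "InDel"),
    name = c("N6-45", "N6-8", "N6-9", "N6-12", "N6-13", "N6-14", "N6-59",
             "N6-15", "N6-17", "N6-19", "N6-20", "N6-23", "N6-25", "N6-32",
             "N6-35", "N6-43", "N6-44", "N6-50", "N6-51", "N6-52", "N6-53",
             "N6-54"),
    chrom = "Chr06",
    pos_bp = c(6837093, 6924191, 6925595, 6927920, 6932817, 6949700,
               6952704, 6957443, 6977743, 6993638, 7004917, 7038080,
               7040484, 7046144, 7049047, 7056134, 7065300, 7086228,
               7112888, 7208182, 7247400, 7359713),
    enzyme = c(NA, NA, "HinfI", NA, "EcoRII", NA, NA, "AluI", "HaeIII",
               "TaqI", "TaqI", "MseI", "NlaIII", "NlaIII", "EcoRII", NA, NA,
               NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# call vector over a panel: `left_call` at positions <= boundary_left,
# `right_call` at positions >= boundary_right, NA between
split_calls <- function(panel, left_call, right_call, boundary_left,
                        boundary_right = boundary_left) {
  ifelse(panel$pos_bp <= boundary_left, left_call,
         ifelse(panel$pos_bp >= boundary_right, right_call, NA))
}

# BC1 (16CB1-style) fixture: five recombinants encoding the net
# constraints that flank the causal region with N6-25 and N6-43, plus
# cosegregating non-recombinants. Expected interval: 7,040,484-7,056,134.
gg_16cb1 <- function() {
  panel <- chr6_marker_panel()
  calls <- rbind(
    "16CB1-153" = split_calls(panel, "h", "a", 6952704, 6957443),
    "16CB1-229" = split_calls(panel, "h", "a", 6977743, 6993638),
    "16CB1-125" = split_calls(panel, "h", "a", 7004917, 7038080),
    "16CB1-206" = split_calls(panel, "h", "a", 7040484, 7046144),
    "16CB1-240" = split_calls(panel, "a", "h", 7049047, 7056134),
    "16CB1-007" = rep("a", nrow(panel)),
    "16CB1-008" = rep("a", nrow(panel)),
    "16CB1-011" = rep("h", nrow(panel)),
    "16CB1-012" = rep("h", nrow(panel)))
  colnames(calls) <- panel$name
  pheno <- c(rep("egusi", 7), "non_egusi", "non_egusi")
  graphical_genotype(panel, calls, pheno, design = "BC1")
}

# BC1 (19CB2-style) RAD fixture: synthetic SNP markers whose endpoint
# positions are the published QTL-interval bounds; B2-28 is the
# phenotype-inconsistent plant. Expected interval: 6,910,159-7,362,904.
gg_19cb2 <- function() {
  panel <- data.frame(
    name = c("rad_6800000", "rad_6910159", "rad_7000000", "rad_7100000",
             "rad_7200000", "rad_7362904", "rad_7450000"),
    chrom = "Chr06",
    pos_bp = c(6800000, 6910159, 7000000, 7100000, 7200000, 7362904,
               7450000),
    stringsAsFactors = FALSE)
  calls <- rbind(
    "B2-05" = c("h", "h", "a", "a", "a", "a", "a"),
    "B2-17" = c("a", "a", "a", "a", "a", "h", "h"),
    "B2-28" = rep("h", 7),
    "B2-01" = rep("a", 7),
    "B2-02" = rep("a", 7),
    "B2-03" = rep("h", 7))
  colnames(calls) <- panel$name
  pheno <- c("egusi", "egusi", "egusi", "egusi", "egusi", "non_egusi")
  graphical_genotype(panel, calls, pheno, design = "BC1")
}

# selfed BC1F2 fixture over the PCR-marker panel: ten recombinants whose
# tightest constraints terminate at N6-23 and N6-53.
# Expected interval: 7,038,080-7,247,400.
gg_bc1f2 <- function() {
  panel <- chr6_marker_panel()
  calls <- rbind(
    "B2F2-01" = split_calls(panel, "h", "a", 7038080, 7040484),
    "B2F2-02" = split_calls(panel, "a", "b", 7208182, 7247400),
    "B2F2-03" = split_calls(panel, "b", "a", 6952704, 6957443),
    "B2F2-04" = split_calls(panel, "h", "a", 6993638, 7004917),
    "B2F2-05" = split_calls(panel, "a", "h", 7247400, 7359713),
    "B2F2-06" = split_calls(panel, "h", "a", 6924191, 6925595),
    "B2F2-07" = split_calls(panel, "a", "h", 7247400, 7359713),
    "B2F2-08" = split_calls(panel, "b", "a", 6977743, 6993638),
    "B2F2-09" = split_calls(panel, "h", "a", 6949700, 6952704),
    "B2F2-10" = split_calls(panel, "a", "b", 7247400, 7359713),
    "B2F2-11" = rep("a", nrow(panel)),
    "B2F2-12" = rep("h", nrow(panel)),
    "B2F2-13" = rep("b", nrow(panel)))
  colnames(calls) <- panel$name
  pheno <- c(rep("egusi", 11), "non_egusi", "non_egusi")
  graphical_genotype(panel, calls, pheno, design = "selfed")
}

# --- brute-force oracle for narrow_interval -------------------------------
# A candidate position p is allowed for an individual iff some informative
# consistent marker q exists with no informative inconsistent marker
# strictly between q and p. Tests every marker position and inter-marker
# midpoint directly from this quantifier definition.
oracle_allowed_pos <- function(gg, i, p) {
  req <- egusimap:::required_classes(gg$phenotype[i], gg$design)
  if (is.null(req)) return(TRUE)
  cj <- gg$calls[i, ]
  inf <- which(!is.na(cj))
  if (!length(inf)) return(TRUE)
  cons <- cj[inf] %in% req
  pos <- gg$markers$pos_bp[inf]
  for (k in which(cons)) {
    lo <- min(pos[k], p); hi <- max(pos[k], p)
    between <- which(pos > lo & pos < hi)
    if (!any(!cons[between])) return(TRUE)
  }
  FALSE
}

oracle_narrow <- function(gg) {
  pos <- gg$markers$pos_bp
  n <- nrow(gg$calls)
  own_ok <- vapply(seq_len(n), function(i)
    any(vapply(pos, function(p) oracle_allowed_pos(gg, i, p), TRUE)), TRUE)
  use <- which(own_ok)
  allowed_all <- vapply(pos, function(p)
    all(vapply(use, function(i) oracle_allowed_pos(gg, i, p), TRUE)), TRUE)
  list(start = if (any(allowed_all)) min(pos[allowed_all]) else NA,
       end = if (any(allowed_all)) max(pos[allowed_all]) else NA,
       inconsistent = rownames(gg$calls)[!own_ok])
}

random_gg <- function(n_markers, n_ind, design = "BC1", missing_rate = 0.1) {
  panel <- data.frame(
    name = sprintf("m%02d", seq_len(n_markers)), chrom = "Chr06",
    pos_bp = sort(sample.int(1e6, n_markers)), stringsAsFactors = FALSE)
  classes <- if (design == "BC1") c("a", "h") else c("a", "h", "b")
  calls <- matrix(sample(classes, n_markers * n_ind, replace = TRUE),
                  n_ind, n_markers, dimnames = list(
                    sprintf("i%02d", seq_len(n_ind)), panel$name))
  calls[matrix(stats::runif(length(calls)) < missing_rate,
               n_ind)] <- NA_character_
  pheno <- sample(c("egusi", "non_egusi"), n_ind, replace = TRUE)
  graphical_genotype(panel, calls, pheno, design)
}

# --- brute-force oracle for restriction-site detection --------------------
# expands the IUPAC pattern (and its reverse complement) to the full set of
# concrete words, then scans every substring overlapping the SNP
expand_iupac <- function(pattern) {
  sets <- egusimap:::IUPAC[strsplit(pattern, "")[[1]]]
  do.call(paste0, do.call(expand.grid, c(sets, stringsAsFactors = FALSE)))
}

oracle_site_present <- function(seq, snp_pos, pattern) {
  words <- unique(c(expand_iupac(pattern),
                    expand_iupac(egusimap:::revcomp(pattern))))
  L <- nchar(pattern)
  for (s in seq_len(nchar(seq) - L + 1)) {
    if (s <= snp_pos && snp_pos <= s + L - 1 &&
        substr(seq, s, s + L - 1) %in% words)
      return(TRUE)
  }
  FALSE
}

random_context <- function(flank_len = 13) {
  bases <- c("A", "C", "G", "T")
  al <- sample(bases, 2)
  snp_context(paste(sample(bases, flank_len, TRUE), collapse = ""),
              al[1], al[2],
              paste(sample(bases, flank_len, TRUE), collapse = ""))
}

# small scaled genome used by simulation-heavy tests
mini_genome <- function(chr_mb = 2.5, n_chrom = 11) {
  genome_spec(n_chrom = n_chrom, length_bp = chr_mb * 1e6,
              length_cM = 82.2 * chr_mb / 36.5)
}
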