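# CAPS/dCAPS marker feasibility: allele-differential restriction sites
# around a SNP, and minimal-mismatch dCAPS primer proposals.

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# does IUPAC pattern match the concrete sequence `s` starting at `at`?
iupac_match_at <- function(pattern, s, at) {
  L <- nchar(pattern)
  if (at < 1 || at + L - 1 > nchar(s)) return(FALSE)
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(substr(s, at, at + L - 1), "")[[1]]
  all(mapply(function(p, b) b %in% IUPAC[[p]], pc, sc))
}

#' Built-in restriction enzyme table
#'
#' Read from the plain-text table shipped at
#' `inst/extdata/enzymes.tsv` (editable); includes the enzymes used for the
#' egusi CAPS/dCAPS markers (HinfI, EcoRII, AluI, HaeIII, TaqI, MseI,
#' NlaIII).
#'
#' @param path optional path to an alternative two-column TSV
#'   (`name`, `pattern`, IUPAC alphabet).
#' @return data frame with columns `name` and `pattern`.
#' @export
restriction_enzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "egusimap",
                        mustWork = TRUE)
  enz <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(enz)))
    stopf("enzyme table needs 'name' and 'pattern' columns")
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", enz$pattern)
  if (any(bad)) stopf("enzyme '%s' has a non-IUPAC pattern", enz$name[bad][1])
  enz
}

#' SNP context: a biallelic SNP with its flanking sequence
#'
#' @param flank5,flank3 uppercase ACGT flanking sequences (5' and 3' of the
#'   SNP); markers in practice use ~500 bp flanks, short flanks are fine for
#'   site screening.
#' @param ref,alt the two alleles, single differing bases.
#' @return object of class `snp_context`.
#' @export
snp_context <- function(flank5, ref, alt, flank3) {
  for (s in c(flank5, flank3)) if (!grepl("^[ACGT]*$", s))
    stopf("flanks must be uppercase ACGT")
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stopf("alleles must be single ACGT bases")
  if (ref == alt) stopf("ref and alt alleles must differ")
  structure(list(flank5 = flank5, ref = ref, alt = alt, flank3 = flank3,
                 snp_pos = nchar(flank5) + 1L),
            class = "snp_context")
}

allele_seq <- function(ctx, allele = c("ref", "alt")) {
  allele <- match.arg(allele)
  paste0(ctx$flank5, ctx[[allele]], ctx$flank3)
}

# enzyme patterns to test on the forward strand: the written pattern plus,
# for non-palindromic sites, its reverse complement (enzymes cut dsDNA)
strand_patterns <- function(pattern) {
  rc <- revcomp(pattern)
  unique(c(pattern, rc))
}

# is a site of `pattern` present at placement `at` in sequence `s`
# (either strand orientation)?
site_at <- function(pattern, s, at) {
  any(vapply(strand_patterns(pattern), iupac_match_at, TRUE, s = s, at = at))
}

#' Screen enzymes for CAPS (allele-differential restriction sites)
#'
#' For each enzyme, tests every placement of its recognition pattern that
#' overlaps the SNP position, on both allele sequences (forward strand;
#' non-palindromic patterns are also tested as their reverse complement).
#' An enzyme is a CAPS candidate when site presence differs between the
#' alleles with no introduced mismatch.
#'
#' @param ctx a [snp_context()].
#' @param enzymes enzyme table (default [restriction_enzymes()]).
#' @return data frame (class `caps_result`) with one row per detectable
#'   enzyme: `enzyme`, `pattern`, `site_in_ref`, `site_in_alt`,
#'   `site_offset` (placement start relative to the SNP), `mismatches` (0),
#'   `primer` (NA for plain CAPS); zero rows when no enzyme differentiates
#'   the alleles.
#' @examples
#' ctx <- snp_context("TTAG", "C", "A", "TTTT")
#' find_caps(ctx)  # AluI (AGCT) cuts the ref allele only
#' @export
find_caps <- function(ctx, enzymes = restriction_enzymes()) {
  sref <- allele_seq(ctx, "ref")
  salt <- allele_seq(ctx, "alt")
  out <- list()
  for (k in seq_len(nrow(enzymes))) {
    L <- nchar(enzymes$pattern[k])
    places <- seq(ctx$snp_pos - L + 1L, ctx$snp_pos)
    in_ref <- vapply(places, function(s) site_at(enzymes$pattern[k], sref, s),
                     TRUE)
    in_alt <- vapply(places, function(s) site_at(enzymes$pattern[k], salt, s),
                     TRUE)
    if (any(in_ref) != any(in_alt)) {
      hit <- places[which(in_ref | in_alt)[1]]
      out[[length(out) + 1L]] <- data.frame(
        enzyme = enzymes$name[k], pattern = enzymes$pattern[k],
        site_in_ref = any(in_ref), site_in_alt = any(in_alt),
        site_offset = hit - ctx$snp_pos, mismatches = 0L,
        primer = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(enzyme = character(), pattern = character(),
               site_in_ref = logical(), site_in_alt = logical(),
               site_offset = integer(), mismatches = integer(),
               primer = character(), stringsAsFactors = FALSE)
  class(res) <- c("caps_result", "data.frame")
  res
}

# all combinations of `mm` modified positions/bases within `cand` positions
# of sequence `s`; returns list of named base vectors (position -> new base)
modification_sets <- function(s, cand, mm) {
  if (mm == 0L) return(list(character(0)))
  pos_combos <- if (length(cand) == 1L && mm == 1L) list(cand) else
    utils::combn(cand, mm, simplify = FALSE)
  out <- list()
  for (pc in pos_combos) {
    choices <- lapply(pc, function(p)
      setdiff(c("A", "C", "G", "T"), substr(s, p, p)))
    grid <- do.call(expand.grid,
                    c(choices, list(stringsAsFactors = FALSE)))
    for (g in seq_len(nrow(grid)))
      out[[length(out) + 1L]] <-
        stats::setNames(as.character(grid[g, ]), pc)
  }
  out
}

apply_mods <- function(s, mods) {
  for (p in names(mods)) substr(s, as.integer(p), as.integer(p)) <- mods[[p]]
  s
}

#' Propose a dCAPS primer when no natural CAPS site exists
#'
#' Searches every placement of the enzyme pattern overlapping the SNP for a
#' set of at most `max_mismatches` primer-introduced base changes (at
#' placement positions strictly 5' of the SNP, i.e. inside the primer) such
#' that the modified site is present in exactly one allele's amplicon. The
#' minimal-mismatch solution is returned; among equals, the placement whose
#' start is nearest the SNP wins. The proposed primer runs from the
#' placement start to the base immediately 5' of the SNP, with the
#' modifications substituted.
#'
#' @param ctx a [snp_context()].
#' @param enzyme single-row enzyme table entry, or an enzyme name resolved
#'   against `enzymes`.
#' @param max_mismatches maximum introduced mismatches (default 1, standard
#'   dCAPS practice).
#' @param enzymes enzyme table for name lookup.
#' @return a one-row `caps_result` data frame, or `NULL` when no solution
#'   exists. If a natural CAPS site already distinguishes the alleles the
#'   function refuses (use [find_caps()]), except in the degenerate
#'   `max_mismatches = 0` case where it returns that natural result.
#' @export
design_dcaps <- function(ctx, enzyme, max_mismatches = 1,
                         enzymes = restriction_enzymes()) {
  if (is.character(enzyme)) {
    i <- match(enzyme, enzymes$name)
    if (is.na(i)) stopf("unknown enzyme '%s'", enzyme)
    enzyme <- enzymes[i, , drop = FALSE]
  }
  natural <- find_caps(ctx, enzyme)
  if (nrow(natural)) {
    if (max_mismatches == 0) return(natural)
    stopf("a natural CAPS site for %s already distinguishes the alleles",
          enzyme$name)
  }
  if (max_mismatches == 0) return(NULL)
  sref <- allele_seq(ctx, "ref")
  salt <- allele_seq(ctx, "alt")
  L <- nchar(enzyme$pattern)
  places <- seq(ctx$snp_pos - L + 1L, ctx$snp_pos)
  places <- places[places >= 1 & places + L - 1 <= nchar(sref)]
  # site presence over every placement overlapping the SNP (the rest of the
  # amplicon is identical between alleles, so sites there cut both equally)
  snp_site <- function(s) any(vapply(places, function(p)
    site_at(enzyme$pattern, s, p), TRUE))
  search_order <- places[order(ctx$snp_pos - places)]  # nearest SNP first
  for (mm in seq_len(max_mismatches)) {
    for (s0 in search_order) {
      cand <- seq(s0, s0 + L - 1L)
      cand <- cand[cand < ctx$snp_pos]
      if (length(cand) < mm) next
      for (mods in modification_sets(sref, cand, mm)) {
        mref <- apply_mods(sref, mods)
        malt <- apply_mods(salt, mods)
        ir <- snp_site(mref)
        ia <- snp_site(malt)
        if (xor(ir, ia)) {
          res <- data.frame(
            enzyme = enzyme$name, pattern = enzyme$pattern,
            site_in_ref = ir, site_in_alt = ia,
            site_offset = s0 - ctx$snp_pos, mismatches = mm,
            primer = substr(mref, s0, ctx$snp_pos - 1L),
            stringsAsFactors = FALSE)
          class(res) <- c("caps_result", "data.frame")
          return(res)
        }
      }
    }
  }
  NULL
}
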